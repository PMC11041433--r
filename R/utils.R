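# Shared internal helpers: classed conditions, seed hygiene, regression
# metrics.

# Signal a classed error so callers (and the CLI) can map failure modes
# to exit codes. `class` is one of the oxitone_* condition classes.
ox_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "oxitone_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

ox_warn <- function(msg, class = "oxitone_warning") {
  warning(structure(
    class = c(class, "oxitone_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG
# stream. All stochastic generator code goes through this.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Regression error metrics
#'
#' Coefficient of determination and the standard error magnitudes used to
#' evaluate SpO2 models. `r2` is computed against the variance of the
#' truth, so it can be negative for models worse than the mean predictor.
#'
#' @param predicted,truth Numeric vectors of equal length.
#' @return List with elements `r2`, `rmse`, `mse`, `mae`.
#' @export
#' @examples
#' regression_metrics(c(1, 2, 3), c(1.1, 1.9, 3.2))
regression_metrics <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth), length(truth) >= 1)
  res <- truth - predicted
  mse <- mean(res^2)
  sst <- sum((truth - mean(truth))^2)
  list(
    r2 = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
    rmse = sqrt(mse),
    mse = mse,
    mae = mean(abs(res))
  )
}
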