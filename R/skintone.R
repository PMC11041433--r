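# Skin-tone classification against a six-patch Fitzpatrick reference
# strip, and the tone-normalization coefficients that correct the
# skin-tone bias of the ratio of ratios.

#' Default Fitzpatrick reference-strip colors
#'
#' Six RGB triplets (0-255) indexed by Fitzpatrick class 1 (lightest) to
#' 6 (darkest), matching the swatches of a printed reference strip. The
#' synthetic fixture generator uses the same constants, so classification
#' tests are closed-loop.
#'
#' @return 6 x 3 numeric matrix with rownames `"1"`..`"6"` and colnames
#'   `r`, `g`, `b`.
#' @export
#' @examples
#' default_reference_strip()
default_reference_strip <- function() {
  m <- rbind(
    `1` = c(247, 228, 206),
    `2` = c(240, 207, 173),
    `3` = c(224, 177, 132),
    `4` = c(198, 134,  94),
    `5` = c(141,  85,  54),
    `6` = c( 84,  49,  34)
  )
  colnames(m) <- c("r", "g", "b")
  m
}

validate_strip <- function(strip) {
  if (!is.matrix(strip) || nrow(strip) != 6 || ncol(strip) != 3) {
    ox_stop("reference strip must be a 6 x 3 RGB matrix",
            "oxitone_config_error")
  }
  if (anyDuplicated(strip)) {
    ox_stop("reference strip has duplicate colors", "oxitone_config_error")
  }
  invisible(strip)
}

#' Mean RGB over a rectangular image region
#'
#' @param image Numeric array `height x width x 3`.
#' @param region Integer vector `c(x0, y0, x1, y1)`: 0-based, half-open
#'   pixel rectangle (columns `x0 <= x < x1`, rows `y0 <= y < y1`).
#' @return Named numeric triplet `(r, g, b)` of per-channel means.
#' @export
mean_rgb <- function(image, region) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3)
  region <- as.numeric(region)
  if (length(region) != 4) {
    ox_stop("region must be c(x0, y0, x1, y1)", "oxitone_region_error")
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  x0 <- region[1]; y0 <- region[2]; x1 <- region[3]; y1 <- region[4]
  if (x0 < 0 || y0 < 0 || x1 > w || y1 > h || x1 <= x0 || y1 <= y0) {
    ox_stop(sprintf("region (%g,%g,%g,%g) empty or outside the %dx%d image",
                    x0, y0, x1, y1, w, h),
            "oxitone_region_error")
  }
  sub <- image[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  c(r = mean(sub[, , 1]), g = mean(sub[, , 2]), b = mean(sub[, , 3]))
}

#' Luminance-weighted grayscale value of an RGB triplet
#'
#' Weighted sum `w_r R + w_g G + w_b B`. Default weights are the ITU-R
#' BT.601 luma coefficients (0.299, 0.587, 0.114), which sum to 1 so a
#' gray input maps to itself.
#'
#' @param rgb Numeric triplet `(r, g, b)`.
#' @param weights Length-3 channel weights.
#' @return Scalar grayscale value.
#' @export
luminance_gray <- function(rgb, weights = c(0.299, 0.587, 0.114)) {
  stopifnot(length(rgb) == 3, length(weights) == 3)
  sum(as.numeric(rgb) * weights)
}

#' Classify a skin patch on the Fitzpatrick scale
#'
#' Compares a measured mean-RGB patch against each reference-strip color
#' and returns the class with the smallest distance: straight-line
#' (Euclidean) distance in RGB space, or the absolute difference of
#' luminance-weighted grayscale values. Ties resolve to the lowest class
#' index.
#'
#' @param patch Numeric triplet `(r, g, b)`.
#' @param strip Reference strip (6 x 3 matrix), default
#'   [default_reference_strip()].
#' @param method `"rgb_euclidean"` (default) or `"luminance_gray"`.
#' @return Object of class `skin_tone_result`: list with
#'   `fitzpatrick_class` (1-6), `distances` (length 6), `method`.
#' @export
#' @examples
#' classify_tone(c(224, 177, 132))  # matches class 3 exactly
classify_tone <- function(patch, strip = default_reference_strip(),
                          method = c("rgb_euclidean", "luminance_gray")) {
  method <- match.arg(method)
  validate_strip(strip)
  patch <- as.numeric(patch)
  stopifnot(length(patch) == 3)
  if (method == "rgb_euclidean") {
    d <- sqrt(rowSums(sweep(strip, 2, patch)^2))
  } else {
    d <- abs(apply(strip, 1, luminance_gray) - luminance_gray(patch))
  }
  d <- unname(d)
  structure(list(fitzpatrick_class = which.min(d), distances = d,
                 method = method),
            class = "skin_tone_result")
}

#' @export
print.skin_tone_result <- function(x, ...) {
  cat(sprintf("Fitzpatrick class %d (%s; distance %.2f)\n",
              x$fitzpatrick_class, x$method,
              x$distances[x$fitzpatrick_class]))
  invisible(x)
}

#' Derive a tone-normalization coefficient
#'
#' The coefficient that rescales a tone's wavelength transmission ratio
#' onto the reference tone's: `ratio_reference / ratio_tone`. Applying it
#' to measurements from that tone removes the tone's systematic shift, by
#' construction equal to 1 for the reference tone itself.
#'
#' @param ratio_tone Transmission ratio measured on the target tone (> 0).
#' @param ratio_reference Same ratio measured on the reference tone (> 0).
#' @return Positive coefficient.
#' @export
derive_coefficient <- function(ratio_tone, ratio_reference) {
  if (any(!is.finite(ratio_tone)) || any(ratio_tone <= 0) ||
      any(!is.finite(ratio_reference)) || any(ratio_reference <= 0)) {
    ox_stop("transmission ratios must be positive and finite",
            "oxitone_domain_error")
  }
  ratio_reference / ratio_tone
}

#' Construct a calibration table
#'
#' Maps Fitzpatrick classes to tone-normalization coefficients for the
#' two wavelength pairs: `red_ir` (red vs infrared, commodity oximeters)
#' and `red_blue` (red vs blue, the smartphone screen pair). The
#' reference class must carry coefficient 1 for both pairs.
#'
#' @param coefficients Data frame with columns `class`, `red_ir`,
#'   `red_blue`.
#' @param reference_class Fitzpatrick class used as reference (default 3).
#' @return Object of class `calibration_table`.
#' @export
calibration_table <- function(coefficients, reference_class = 3) {
  stopifnot(is.data.frame(coefficients),
            all(c("class", "red_ir", "red_blue") %in% names(coefficients)))
  if (any(coefficients$red_ir <= 0) || any(coefficients$red_blue <= 0)) {
    ox_stop("calibration coefficients must be positive",
            "oxitone_config_error")
  }
  ref <- coefficients[coefficients$class == reference_class, ]
  if (nrow(ref) != 1 ||
      abs(ref$red_ir - 1) > 1e-12 || abs(ref$red_blue - 1) > 1e-12) {
    ox_stop("reference class must be present with coefficient 1 for both pairs",
            "oxitone_config_error")
  }
  structure(list(reference_class = reference_class,
                 coefficients = coefficients[order(coefficients$class), ]),
            class = "calibration_table")
}

#' Packaged tone-normalization coefficients
#'
#' The calibration constants for synthetic-skin tones of Fitzpatrick
#' classes 2, 3 and 5, with class 3 as the reference (coefficient 1):
#' class 5 has 0.8794 (red/IR) and 1.2396 (red/blue); class 2 has
#' 1.0326 (red/IR) and 1.0340 (red/blue).
#'
#' @return A [calibration_table].
#' @export
#' @examples
#' default_calibration_table()
default_calibration_table <- function() {
  calibration_table(data.frame(
    class = c(2, 3, 5),
    red_ir = c(1.0326, 1, 0.8794),
    red_blue = c(1.0340, 1, 1.2396)
  ), reference_class = 3)
}

#' Look up a calibration coefficient
#'
#' @param table A [calibration_table].
#' @param tone_class Fitzpatrick class.
#' @param pair `"red_blue"` (default) or `"red_ir"`.
#' @return Scalar coefficient.
#' @export
get_coefficient <- function(table, tone_class,
                            pair = c("red_blue", "red_ir")) {
  stopifnot(inherits(table, "calibration_table"))
  pair <- match.arg(pair)
  row <- table$coefficients[table$coefficients$class == tone_class, ]
  if (nrow(row) != 1) {
    ox_stop(sprintf("no calibration coefficient for Fitzpatrick class %s",
                    tone_class),
            "oxitone_calibration_error")
  }
  row[[pair]]
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Calibration table (reference class %d)\n", x$reference_class))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Serialize a calibration table to JSON
#' @param table A [calibration_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_table <- function(table, path) {
  stopifnot(inherits(table, "calibration_table"))
  jsonlite::write_json(
    list(reference_class = table$reference_class,
         coefficients = table$coefficients),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration table from JSON
#' @param path Path to a JSON file written by [write_calibration_table()].
#' @return A [calibration_table].
#' @export
read_calibration_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_table(as.data.frame(obj$coefficients),
                    reference_class = obj$reference_class)
}
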