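# Minimal portable-pixmap (PPM) raster I/O. Images are plain R arrays
# (height x width x 3, values 0..max_val); PPM is the only raster format
# read or written here, in ASCII (P3) by default so fixtures stay
# text-only. Binary P6 files are also readable.

#' Write an RGB image as a PPM file
#'
#' @param image Numeric array `height x width x 3` with values in
#'   `[0, max_val]`; values are rounded to integers on write.
#' @param path Output path.
#' @param max_val Maximum channel value (default 255).
#' @param ascii Write plain-text P3 (default) rather than binary P6.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(image, path, max_val = 255, ascii = TRUE) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3)
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- round(aperm(image, c(3, 2, 1)))   # channel fastest, row-major
  px <- pmin(pmax(as.integer(px), 0L), as.integer(max_val))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(w, h), as.character(max_val)), con)
    writeLines(paste(px, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P6\n%d %d\n%d\n", w, h, max_val), con, eos = NULL)
    writeBin(as.raw(px), con)
  }
  invisible(path)
}

#' Read a PPM image (P3 or P6)
#'
#' @param path Path to a `.ppm` file.
#' @return Numeric array `height x width x 3`.
#' @export
read_ppm <- function(path) {
  if (!file.exists(path)) {
    ox_stop(paste0("no such image: ", path), "oxitone_io_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P3", "P6")) {
    ox_stop(paste0(path, " is not a PPM image (magic '", magic, "')"),
            "oxitone_parse_error")
  }
  # header tokens: width, height, maxval (comments allowed)
  tokens <- character(0)
  buf <- character(0)
  while (length(tokens) < 3) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (length(ch) == 0 || ch == "") {
      ox_stop(paste0("truncated PPM header in ", path), "oxitone_parse_error")
    }
    if (ch == "#") {            # comment to end of line
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1))
        if (ch %in% c("\n", "")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf) > 0) {
        tokens <- c(tokens, paste(buf, collapse = ""))
        buf <- character(0)
      }
    } else {
      buf <- c(buf, ch)
    }
  }
  dims <- as.integer(tokens)
  w <- dims[1]; h <- dims[2]; max_val <- dims[3]
  n <- 3L * w * h
  if (magic == "P6") {
    px <- as.integer(readBin(con, "raw", n))
  } else {
    txt <- rawToChar(readBin(con, "raw", file.size(path)))
    px <- suppressWarnings(as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]]))
    px <- px[!is.na(px)]
  }
  if (length(px) < n) {
    ox_stop(paste0("truncated pixel data in ", path), "oxitone_parse_error")
  }
  arr <- aperm(array(as.numeric(px[seq_len(n)]), dim = c(3, w, h)), c(3, 2, 1))
  attr(arr, "max_val") <- max_val
  arr
}
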