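#' Export a matrix as a portable graymap (PGM)
#'
#' Writes a plain-text (P2) PGM image for quick external inspection of
#' patches, weight maps, or classification images. Values are mapped linearly
#' to gray levels with 0 at median gray, so negative weights appear dark and
#' positive weights light.
#'
#' @param x Numeric matrix.
#' @param path Output file path.
#' @param bits Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(x, path, bits = 8) {
  stopifnot(is.matrix(x), bits %in% c(8, 16))
  maxval <- 2^bits - 1
  lim <- max(abs(x))
  if (lim == 0) lim <- 1
  g <- round((x / lim + 1) / 2 * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(x), nrow(x)),
               sprintf("%d", maxval)), con)
  utils::write.table(g, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
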