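#' Read and write plain-text PGM images
#'
#' Eye-region crops are exchanged as plain (ASCII, `P2`) portable greymaps
#' so that fixtures and pipeline outputs stay text-only and dependency-free.
#' Intensities are stored 0..`maxval` and mapped to `[0, 1]` doubles in
#' memory (0 = black).
#'
#' @param path File path.
#' @return `read_pgm`: numeric matrix in `[0, 1]`, rows = image rows
#'   (y down), columns = x.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) fm_io_error(paste0("no such file: ", path))
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(),
              quiet = TRUE)
  if (length(tok) < 4 || tok[1] != "P2")
    fm_parse_error(paste0("not a plain P2 PGM: ", path))
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); mx <- as.numeric(tok[4])
  px <- as.numeric(tok[-(1:4)])
  if (length(px) != w * h)
    fm_parse_error(sprintf("PGM pixel count mismatch in %s (%d vs %d)",
                           path, length(px), w * h))
  matrix(px / mx, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param maxval Integer maximum grey value used on disk (default 255).
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  v <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  apply(v, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
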