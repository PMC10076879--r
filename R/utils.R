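#' Write a data.frame as TSV with stable numeric formatting
#'
#' Numeric columns are serialized at 9 significant digits so repeated runs
#' produce byte-identical tables; the write is atomic (temp file + rename).
#'
#' @param d data.frame.
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
writeTsv <- function(d, path) {
  d <- as.data.frame(d)
  for (j in seq_along(d)) {
    if (is.double(d[[j]]))
      d[[j]] <- formatC(d[[j]], digits = 9, format = "g")
  }
  tmp <- paste0(path, ".tmp")
  write.table(d, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

.readLinesOpt <- function(path) {
  if (is.null(path)) return(character(0))
  x <- readLines(path, warn = FALSE)
  trimws(x[nzchar(trimws(x))])
}
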