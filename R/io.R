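# CSV round-trips for records and lattice maps, with key-value sidecar
# metadata.

#' Write / read a luminescence record as CSV
#'
#' The matrix (locations x frames) is written as plain CSV; exposure and
#' lattice layout go to a `<path>.meta` key-value sidecar.
#'
#' @param record A [luminescence_record()].
#' @param path Output CSV path.
#' @export
write_record_csv <- function(record, path) {
  write.csv(record$values, path, row.names = FALSE)
  meta <- c(exposure = record$exposure, rows = record$rows,
            cols = record$cols)
  writeLines(paste(names(meta), meta, sep = "="), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_record_csv
#' @export
read_record_csv <- function(path) {
  vals <- as.matrix(read.csv(path, check.names = FALSE))
  meta <- strsplit(readLines(paste0(path, ".meta")), "=", fixed = TRUE)
  kv <- stats::setNames(vapply(meta, `[`, "", 2L),
                        vapply(meta, `[`, "", 1L))
  luminescence_record(unname(vals), as.numeric(kv[["exposure"]]),
                      rows = as.integer(kv[["rows"]]),
                      cols = as.integer(kv[["cols"]]))
}

#' Export a per-location quantity as a lattice CSV map
#'
#' Reshapes a length-`rows*cols` vector (row-major location order) into
#' its lattice layout and writes it as CSV, the format used for
#' posterior-mean, robustness and entropy maps.
#'
#' @param values Numeric vector of per-location values.
#' @param rows,cols Lattice dimensions.
#' @param path Output CSV path.
#' @export
write_lattice_csv <- function(values, rows, cols, path) {
  if (length(values) != rows * cols) .invalid("length mismatch")
  write.csv(matrix(values, rows, cols, byrow = TRUE), path,
            row.names = FALSE)
  invisible(path)
}
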