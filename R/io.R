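# Plain-text I/O for pipeline artifacts: XYZ point clouds and CSV tables.
# All writers use fixed numeric formatting (9 significant digits) so reruns
# with the same seed produce byte-identical files.

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 9, format = "g"))
}

#' Write a point cloud as XYZ text
#'
#' One `x y z` triple per line, space-separated, 9 significant digits.
#'
#' @param cloud Data frame with columns `x`, `y`, `z` (extra columns are
#'   dropped); must be non-empty.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path) {
  if (nrow(cloud) == 0L) {
    stop("refusing to write an empty point cloud", call. = FALSE)
  }
  lines <- paste(.fmt_num(cloud$x), .fmt_num(cloud$y), .fmt_num(cloud$z))
  writeLines(lines, path)
  invisible(path)
}

#' Read an XYZ text point cloud
#'
#' Accepts whitespace- or comma-separated `x y z` rows, with or without a
#' header line.
#'
#' @param path Input file path.
#' @return Data frame with columns `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  d <- utils::read.table(path, header = header, sep = sep,
                         strip.white = TRUE)
  if (ncol(d) < 3L) stop("expected at least 3 columns in ", path,
                         call. = FALSE)
  d <- d[, 1:3]
  names(d) <- c("x", "y", "z")
  d
}

#' Write a pipeline table as CSV
#'
#' Deterministic CSV writer (9 significant digits, no row names, `NA` for
#' missing values) used for every tabular artifact.
#'
#' @param table A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path) {
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a pipeline CSV table
#'
#' @param path Input file path.
#' @return Data frame (strings kept as character, `NA` preserved).
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
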