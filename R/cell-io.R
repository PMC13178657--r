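#' Construct a CellTable
#'
#' @param cellIds character cell identifiers (unique per patient).
#' @param x,y numeric coordinates in micrometres.
#' @param intensities numeric cells x markers matrix (named columns).
#' @return a validated \code{\link{CellTable}}.
#' @export
cellTable <- function(cellIds, x, y, intensities) {
  intensities <- as.matrix(intensities)
  new("CellTable", cellIds = as.character(cellIds),
      coords = cbind(x = as.numeric(x), y = as.numeric(y)),
      intensities = intensities)
}

#' Read / write a single-cell table
#'
#' Cell tables are comma-delimited with a one-line header: \code{cell_id},
#' \code{x}, \code{y} (micrometres, origin top-left, y downward) and one
#' intensity column per panel marker. Reading validates the schema against the
#' panel; missing columns are reported all at once.
#'
#' @param path file path.
#' @param panel a \code{\link{MarkerPanel}}; its marker set defines the
#'   required intensity columns.
#' @param cells a \code{\link{CellTable}}.
#' @return \code{readCellTable} returns a \code{\link{CellTable}};
#'   \code{writeCellTable} returns \code{path} invisibly.
#' @export
readCellTable <- function(path, panel) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y", markerNames(panel))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop(sprintf("cell table schema error; missing column(s): %s",
                 paste(missing, collapse = ", ")))
  ints <- as.matrix(df[, markerNames(panel), drop = FALSE])
  if (anyNA(ints)) stop("cell table contains missing intensities")
  if (any(ints < 0)) stop("cell table contains negative intensities")
  cellTable(df$cell_id, df$x, df$y, ints)
}

#' @rdname readCellTable
#' @export
writeCellTable <- function(cells, path) {
  df <- data.frame(cell_id = cellIds(cells),
                   x = cellCoords(cells)[, "x"],
                   y = cellCoords(cells)[, "y"],
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(cellIntensities(cells), check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.clinicalColumns <- c("patient_id", "ici_treated", "pfs_days", "pfs_event",
                      "os_days", "os_event", "treatment_line", "regimen",
                      "histology", "driver_status", "ecog_ps", "pdl1_tps")

#' Read / write the clinical metadata table
#'
#' One row per patient: identifiers, ICI-treatment flag, progression-free and
#' overall survival (days + 0/1 event flags), treatment line and regimen,
#' histology, driver-oncogene status, ECOG performance status and PD-L1 tumor
#' proportion score (percent; empty fields are kept as missing — missing data
#' are never imputed).
#'
#' @param path file path (CSV, empty fields encode missing values).
#' @param clinical a clinical data.frame as produced by
#'   \code{\link{generateCohort}}.
#' @return \code{readClinicalTable} returns a data.frame with one row per
#'   patient; \code{writeClinicalTable} returns \code{path} invisibly.
#' @export
readClinicalTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(.clinicalColumns, names(df))
  if (length(missing))
    stop(sprintf("clinical table schema error; missing column(s): %s",
                 paste(missing, collapse = ", ")))
  for (col in c("pfs_days", "os_days")) {
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop(sprintf("negative survival time in %s", col))
  }
  for (col in c("pfs_event", "os_event", "ici_treated")) {
    if (!all(df[[col]] %in% c(0L, 1L)))
      stop(sprintf("%s must be 0/1", col))
  }
  if (any(df$pdl1_tps < 0 | df$pdl1_tps > 100, na.rm = TRUE))
    stop("pdl1_tps must lie in [0, 100]")
  df
}

#' @rdname readClinicalTable
#' @export
writeClinicalTable <- function(clinical, path) {
  write.csv(clinical, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a samples x genes expression matrix
#'
#' Tab-separated, log-scale values; first column \code{sample_id}, remaining
#' columns one per gene symbol (unique).
#'
#' @param path file path.
#' @param mat numeric samples x genes matrix with sample row names.
#' @return \code{readExpressionMatrix} returns a numeric matrix;
#'   \code{writeExpressionMatrix} returns \code{path} invisibly.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id")
    stop("expression matrix must start with a sample_id column")
  genes <- names(df)[-1]
  if (anyDuplicated(genes)) stop("gene symbols must be unique")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' @rdname readExpressionMatrix
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), check.names = FALSE)
  df <- cbind(df, as.data.frame(mat, check.names = FALSE))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @importFrom utils read.delim write.table
NULL
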