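#' Read a per-cell table
#'
#' Reads a CSV or Parquet cell table written by [writeCellTable()] (or any
#' table with the required schema: `sample_id`, `cell_id`, `x`, `y`,
#' `nuclear_area` and one column per channel). Rows with missing coordinates
#' are rejected; label columns produced by later pipeline stages are
#' preserved when present.
#'
#' @param path file path.
#' @param format `"csv"` or `"parquet"`; inferred from the extension when
#'   omitted.
#' @return A validated [CellTable-class].
#' @export
readCellTable <- function(path, format = c("auto", "csv", "parquet")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.parquet$", path, ignore.case = TRUE)) "parquet" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "parquet") {
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  required <- c("sample_id", .requiredCellCols())
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cell table schema error; missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) && length(unique(df$sample_id)) > 1L)
    stop("a cell table file must contain a single sample_id")
  sid <- if (nrow(df)) as.character(df$sample_id[1L]) else sub("\\.[^.]*$", "", basename(path))
  if (anyNA(df$x) || anyNA(df$y)) stop("rows with missing coordinates are not allowed")
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id values in ", path)
  if (is.element("ispla_positive", names(df))) df$ispla_positive <- as.logical(df$ispla_positive)
  df$sample_id <- NULL
  cellTable(df, sid)
}

#' Write a per-cell table
#'
#' Lossless counterpart of [readCellTable()]: CSV output keeps full double
#' precision (15 significant digits); Parquet is exact.
#'
#' @param table a [CellTable-class].
#' @param path output path.
#' @param format `"csv"` or `"parquet"`; inferred from the extension when
#'   omitted.
#' @return `path`, invisibly.
#' @export
writeCellTable <- function(table, path, format = c("auto", "csv", "parquet")) {
  stopifnot(is(table, "CellTable"))
  validObject(table)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.parquet$", path, ignore.case = TRUE)) "parquet" else "csv"
  df <- cbind(sample_id = rep(sampleId(table), nrow(table@cells)), table@cells)
  if (!nrow(df)) df <- df[0, c("sample_id", names(table@cells)), drop = FALSE]
  if (format == "parquet") {
    arrow::write_parquet(df, path)
  } else {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = 15, format = "g"))
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Read / write sample metadata
#'
#' Sample metadata is a CSV with columns `sample_id`, `patient_id` and
#' `response_group`; response groups follow the RECIST 1.1 categories CR,
#' PR, SD, PD.
#'
#' @param path CSV path.
#' @return `readSampleMetadata`: a data.frame with a factor `response_group`.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("sample_id", "patient_id", "response_group"), names(df))
  if (length(missing))
    stop("metadata schema error; missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$response_group), c("CR", "PR", "SD", "PD"))
  if (length(bad))
    stop("unknown response group(s): ", paste(bad, collapse = ", "))
  df$response_group <- factor(df$response_group, levels = c("CR", "PR", "SD", "PD"))
  df
}

#' @rdname readSampleMetadata
#' @param metadata data.frame as returned by [readSampleMetadata()].
#' @export
writeSampleMetadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
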