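#' Read a beta-value matrix from TSV
#'
#' Expects probe ids in the first column and a header row of sample (or
#' cell-type/component) ids; all remaining cells numeric.
#'
#' @param path TSV file path.
#' @param validate check the beta-value contract (values in `[0, 1]`, no
#'   missing values); disable for factor matrices like `H`.
#' @return numeric matrix with dimnames.
#' @export
readBetaTSV <- function(path, validate = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- as.character(df[[1]])
  if (validate) M <- checkBetaMatrix(M, basename(path))
  M
}

#' Write a matrix to TSV with row ids in the first column
#'
#' @param M numeric matrix with dimnames.
#' @param path output TSV path.
#' @param idColumn name for the first (row id) column.
#' @return invisibly, `path`.
#' @export
writeBetaTSV <- function(M, path, idColumn = "probe_id") {
  df <- data.frame(rownames(M), M, check.names = FALSE,
    stringsAsFactors = FALSE
  )
  names(df)[1] <- idColumn
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a two-column sample label CSV
#'
#' @param path CSV with columns `sample_id,label` (header required).
#' @return named character vector of labels.
#' @export
readLabelsCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a survival CSV
#'
#' @param path CSV with columns `sample_id,time,event` and optionally
#'   `immune_fraction`.
#' @return data.frame.
#' @export
readSurvivalCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df))) {
    stop("survival CSV needs columns sample_id,time,event")
  }
  df
}
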