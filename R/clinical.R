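#' Clinical annotation table
#'
#' One row per sample: overall-survival time and event indicator, MYCN
#' amplification status, INSS stage, metastasis flag and therapy-response
#' label. "No response", relapse and partial response count as poor
#' response in the cohorts this package emulates.
#'
#' @param df data.frame with columns `sample_id`, `os_time` (days),
#'   `os_event` (logical, death observed), and optionally `mycn`
#'   (`"amplified"`, `"non_amplified"`, `"unknown"`), `inss_stage`
#'   (`"1","2","3","4","4S","unknown"`), `metastasis` (logical or NA) and
#'   `response` (`"good"`, `"poor"`, `"unknown"`). Missing optional columns
#'   are filled with `"unknown"`/`NA`.
#' @return A validated `clinical_table` data.frame.
#' @export
clinical_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("sample_id", "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing clinical columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in clinical table")
  df$os_time <- as.numeric(df$os_time)
  if (any(!is.finite(df$os_time)) || any(df$os_time < 0))
    stop("os_time must be finite and >= 0")
  df$os_event <- as.logical(df$os_event)
  if (anyNA(df$os_event)) stop("os_event must be TRUE/FALSE")
  if (is.null(df$mycn)) df$mycn <- "unknown"
  df$mycn <- as.character(df$mycn)
  bad <- setdiff(unique(df$mycn), c("amplified", "non_amplified", "unknown"))
  if (length(bad)) stop("invalid mycn value(s): ", paste(bad, collapse = ", "))
  if (is.null(df$inss_stage)) df$inss_stage <- "unknown"
  df$inss_stage <- as.character(df$inss_stage)
  bad <- setdiff(unique(df$inss_stage), c("1", "2", "3", "4", "4S", "unknown"))
  if (length(bad)) stop("invalid inss_stage value(s): ", paste(bad, collapse = ", "))
  if (is.null(df$metastasis)) df$metastasis <- NA
  df$metastasis <- as.logical(df$metastasis)
  if (is.null(df$response)) df$response <- "unknown"
  df$response <- as.character(df$response)
  bad <- setdiff(unique(df$response), c("good", "poor", "unknown"))
  if (length(bad)) stop("invalid response value(s): ", paste(bad, collapse = ", "))
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical table from CSV
#' @param path file path.
#' @return A `clinical_table`.
#' @export
read_clinical <- function(path) {
  clinical_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a clinical table to CSV
#' @param cl a `clinical_table`.
#' @param path output path.
#' @export
write_clinical <- function(cl, path) {
  utils::write.csv(as.data.frame(cl), path, row.names = FALSE)
  invisible(path)
}

# align a clinical table to the samples of an expression matrix; every
# analysis sample must have both an expression column and a clinical row
align_clinical <- function(m, clinical) {
  stopifnot(inherits(m, "expr_matrix"), inherits(clinical, "clinical_table"))
  miss <- setdiff(sample_ids(m), clinical$sample_id)
  if (length(miss))
    stop("samples without clinical rows: ",
         paste(utils::head(miss, 5), collapse = ", "))
  clinical[match(sample_ids(m), clinical$sample_id), , drop = FALSE]
}
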