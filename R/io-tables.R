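# Results writers share one code path: deterministic column order,
# rows sorted by P value (ties broken by id), fixed significant digits
# so a write-then-read round-trips exactly at the written precision.

write_result_table <- function(df, path, sort_p = NULL, id_col = NULL,
                               digits = 6L) {
  if (!is.data.frame(df) || nrow(df) == 0L)
    data_error("refusing to write an empty results table")
  if (!is.null(sort_p) && sort_p %in% names(df)) {
    ord <- order(df[[sort_p]], df[[id_col]], na.last = TRUE)
    df <- df[ord, , drop = FALSE]
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Write a per-probe audit table
#'
#' Rows are ordered by probe id. Columns: probe identity, hit count,
#' worst influence category and the per-threshold unreliability verdicts.
#'
#' @param audit data.frame from [audit_all()]`$probes`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_audit_table <- function(audit, path) {
  if (!is.data.frame(audit) || nrow(audit) == 0L)
    data_error("refusing to write an empty audit table")
  write_result_table(audit[order(audit$probe_id), , drop = FALSE], path)
}

#' Write a DMP association table
#'
#' Rows sorted by the t-test P value, ties broken by probe id (so output
#' order is deterministic). Column layout mirrors the unadjusted and
#' adjusted association summaries.
#'
#' @param dmp data.frame of per-probe association results.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dmp_table <- function(dmp, path) {
  pcol <- if ("p_ttest" %in% names(dmp)) "p_ttest" else "p_regression"
  write_result_table(dmp, path, sort_p = pcol, id_col = "probe_id")
}

#' Write allele-expression tables
#'
#' @param tab data.frame of abundances or per-allele/grouped test results.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(tab, path) {
  idc <- intersect(c("allele", "selector", "sample_id"), names(tab))[1]
  pcol <- intersect(c("p_value"), names(tab))
  write_result_table(tab, path,
                     sort_p = if (length(pcol)) pcol else NULL,
                     id_col = idc)
}

#' Read back a results table written by this package
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                    data.table = FALSE)
}
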