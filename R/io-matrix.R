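#' Read a probe-by-sample value matrix (beta values or detection P)
#'
#' One reader serves both the methylation beta matrix and the detection-P
#' matrix: the two share the same shape (first column `probe_id`, one
#' column per sample) and the same [0, 1] bounds. Empty cells and `NA`
#' stay missing — they are never coerced to zero.
#'
#' @param path TSV path.
#' @param kind `"beta"` or `"detp"`; only affects error messages.
#' @return numeric matrix with probe IDs as rownames and sample IDs as
#'   colnames.
#' @export
read_beta_matrix <- function(path, kind = c("beta", "detp")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) data_error(sprintf("%s matrix not found: %s", kind, path))
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           na.strings = c("", "NA"), data.table = FALSE)
  if (ncol(tab) < 2L)
    data_error(sprintf("%s matrix needs a probe_id column plus >=1 sample column", kind))
  probe_ids <- as.character(tab[[1L]])
  if (anyDuplicated(probe_ids))
    data_error(sprintf("%s matrix has duplicated probe ids", kind))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- probe_ids

  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, ]
    data_error(sprintf(
      "%s matrix value %.4g out of [0,1] at probe %s, sample %s (%d offending cell(s))",
      kind, m[i[1L], i[2L]], probe_ids[i[1L]], colnames(m)[i[2L]], nrow(bad)))
  }
  m
}

#' Write a probe-by-sample matrix as TSV
#'
#' @param m numeric matrix with probe rownames and sample colnames.
#' @param path output path.
#' @param digits significant digits written (default 6).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path, digits = 6L) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- data.table::data.table(probe_id = rownames(m))
  for (j in colnames(m)) out[[j]] <- signif(m[, j], digits)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
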