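#' Length-normalized, per-million-scaled allele abundances
#'
#' Converts per-allele read counts to transcript abundances: within each
#' sample, `rate = read_count / allele_length`, then rates are rescaled
#' so the sample's abundances sum to one million. Samples whose counts
#' are all zero cannot be normalized; they are flagged and their
#' abundances set to missing.
#'
#' @param counts allele-count data.frame (see [read_allele_counts()]).
#' @return data.frame `sample_id`, `gene`, `allele`, `abundance`, with
#'   attribute `flagged_samples` naming all-zero samples.
#' @export
normalize_abundance <- function(counts) {
  stopifnot(all(c("sample_id", "allele", "read_count", "allele_length")
                %in% names(counts)))
  rate <- counts$read_count / counts$allele_length
  tot <- tapply(rate, counts$sample_id, sum)
  denom <- as.numeric(tot[counts$sample_id])
  abundance <- ifelse(denom > 0, 1e6 * rate / denom, NA_real_)
  flagged <- names(tot)[tot == 0]
  if (length(flagged))
    warning(sprintf("%d sample(s) with all-zero counts flagged", length(flagged)))
  out <- data.frame(sample_id = counts$sample_id,
                    gene = counts$gene %||% NA_character_,
                    allele = counts$allele,
                    abundance = abundance,
                    stringsAsFactors = FALSE)
  attr(out, "flagged_samples") <- flagged
  out
}

#' Sublineage of a DQB1 allele name
#'
#' DQB1*03/*04 and DQB1*05/*06 form serologically and evolutionarily
#' distinct sublineages (lower- and higher-expressed, respectively).
#' Assignment is by the two-digit family after the `*`.
#'
#' @param allele character vector of allele names like `"DQB1*06:02"`.
#' @return character vector: `"DQB1_03_04"`, `"DQB1_05_06"` or `"other"`.
#' @export
sublineage_of <- function(allele) {
  fam <- sub("^[^*]*\\*([0-9]{2}).*$", "\\1", allele)
  out <- rep("other", length(allele))
  out[fam %in% c("03", "04")] <- "DQB1_03_04"
  out[fam %in% c("05", "06")] <- "DQB1_05_06"
  out
}

#' Compare every allele's expression to a reference allele
#'
#' Two-sided Wilcoxon rank-sum test of each non-reference allele's
#' abundance distribution against the reference allele's, pooling one
#' observation per carrying sample. Alleles observed in fewer than two
#' samples are flagged untested. Exact P values for tiny groups
#' (n < 10), normal approximation with tie correction otherwise.
#'
#' @param abund abundance table from [normalize_abundance()].
#' @param reference_allele default `"DQB1*06:02"`.
#' @param gene restrict to one gene label (default `"DQB1"`); `NULL`
#'   keeps all rows.
#' @return data.frame `allele`, `n`, `mean_abundance`, `p_value`, `flag`,
#'   ordered by allele name; the reference row carries `flag "reference"`.
#' @export
per_allele_vs_reference <- function(abund, reference_allele = "DQB1*06:02",
                                    gene = "DQB1") {
  if (!is.null(gene)) abund <- abund[abund$gene == gene, , drop = FALSE]
  abund <- abund[!is.na(abund$abundance), , drop = FALSE]
  ref <- abund$abundance[abund$allele == reference_allele]
  if (length(ref) < 2L)
    data_error(sprintf("reference allele %s observed in <2 samples",
                       reference_allele))
  alleles <- sort(unique(abund$allele))
  rows <- lapply(alleles, function(a) {
    x <- abund$abundance[abund$allele == a]
    if (a == reference_allele)
      return(data.frame(allele = a, n = length(x), mean_abundance = mean(x),
                        p_value = NA_real_, flag = "reference",
                        stringsAsFactors = FALSE))
    if (length(x) < 2L)
      return(data.frame(allele = a, n = length(x), mean_abundance = mean(x),
                        p_value = NA_real_, flag = "untested",
                        stringsAsFactors = FALSE))
    exact <- length(x) < 10L && length(ref) < 10L
    p <- suppressWarnings(
      wilcox.test(x, ref, alternative = "two.sided",
                  exact = exact, correct = TRUE)$p.value)
    data.frame(allele = a, n = length(x), mean_abundance = mean(x),
               p_value = p, flag = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Case-control comparison of aggregated allele expression
#'
#' Aggregates abundances within each sample over a selected allele set,
#' then compares the per-sample aggregates between cases and controls by
#' a two-sample t-test (sample-level aggregation avoids
#' pseudo-replication of multi-allele samples). Selectors:
#' \describe{
#'   \item{`non_reference`}{sum over the sample's alleles other than the
#'     reference allele.}
#'   \item{`sublineage_03_04`, `sublineage_05_06`}{sum over alleles of
#'     one DQB1 sublineage, always excluding the reference allele.}
#' }
#' Samples carrying no selected allele are excluded from the test.
#'
#' @param abund abundance table from [normalize_abundance()].
#' @param samples sample sheet with `sample_id` and `group`.
#' @param selector one of the selectors above.
#' @param reference_allele default `"DQB1*06:02"`.
#' @param gene gene label to restrict to (default `"DQB1"`).
#' @param var_equal Student (default) vs Welch.
#' @return one-row data.frame: `selector`, `n_control`, `n_case`,
#'   `mean_control`, `mean_case`, `difference` (case - control),
#'   `p_value`.
#' @export
grouped_comparison <- function(abund, samples,
                               selector = c("non_reference",
                                            "sublineage_03_04",
                                            "sublineage_05_06"),
                               reference_allele = "DQB1*06:02",
                               gene = "DQB1", var_equal = TRUE) {
  selector <- match.arg(selector)
  if (!is.null(gene)) abund <- abund[abund$gene == gene, , drop = FALSE]
  abund <- abund[!is.na(abund$abundance), , drop = FALSE]
  abund <- abund[abund$allele != reference_allele, , drop = FALSE]
  if (selector == "sublineage_03_04")
    abund <- abund[sublineage_of(abund$allele) == "DQB1_03_04", , drop = FALSE]
  if (selector == "sublineage_05_06")
    abund <- abund[sublineage_of(abund$allele) == "DQB1_05_06", , drop = FALSE]

  agg <- tapply(abund$abundance, abund$sample_id, sum)
  grp <- samples$group[match(names(agg), samples$sample_id)]
  x_ctl <- as.numeric(agg[!is.na(grp) & grp == "control"])
  x_cas <- as.numeric(agg[!is.na(grp) & grp == "case"])
  if (length(x_ctl) < 2L || length(x_cas) < 2L)
    data_error(sprintf("selector '%s': fewer than 2 samples in a group", selector))

  # zero-variance aggregates (degenerate fixtures) give a missing P
  # rather than an error
  p <- tryCatch(t.test(x_cas, x_ctl, var.equal = var_equal)$p.value,
                error = function(e) NA_real_)
  data.frame(selector = selector,
             n_control = length(x_ctl), n_case = length(x_cas),
             mean_control = mean(x_ctl), mean_case = mean(x_cas),
             difference = mean(x_cas) - mean(x_ctl),
             p_value = p,
             stringsAsFactors = FALSE)
}
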