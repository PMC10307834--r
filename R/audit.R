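#' Audit one probe against a SNP panel
#'
#' Collects every panel SNP whose genomic offset from the probe's binding
#' position falls inside an influence window and whose minor allele
#' frequency reaches the most permissive threshold under audit. A probe
#' is unreliable at threshold t when it has at least one hit with
#' `maf >= t` (any window — the conservative rule); the worst category
#' (ONSITE > NT5 > NT10) is reported at the lowest threshold.
#'
#' @param probe one-row probe record.
#' @param snps SNP table (any chromosomes; filtered internally).
#' @param maf_thresholds numeric MAF cutoffs, default `c(0.05, 0.01)`.
#'   Comparison is `>=` (the operative choice; see package vignette).
#' @return list with `probe_id`, `hits` (data.frame of position, maf,
#'   category), `n_hits`, `worst_category`, and one logical
#'   `unreliable_at_<t>` per threshold.
#' @export
audit_probe <- function(probe, snps, maf_thresholds = c(0.05, 0.01)) {
  stopifnot(length(maf_thresholds) >= 1L, all(maf_thresholds > 0))
  tmin <- min(maf_thresholds)
  same <- norm_chrom(snps$chromosome) == norm_chrom(probe$chromosome)
  snps <- snps[same & snps$maf >= tmin, , drop = FALSE]

  cat_ <- character(0)
  if (nrow(snps)) {
    offs <- as.integer(snps$position) - as.integer(probe$binding_pos)
    cat_ <- classify_offset(offs, probe$strand, probe$design_type)
    keep <- !is.na(cat_)
    snps <- snps[keep, , drop = FALSE]
    cat_ <- cat_[keep]
  }

  hits <- data.frame(position = as.integer(snps$position),
                     maf = as.numeric(snps$maf),
                     category = cat_,
                     stringsAsFactors = FALSE)
  out <- list(
    probe_id = probe$probe_id,
    hits = hits,
    n_hits = nrow(hits),
    worst_category = if (nrow(hits) == 0L) NA_character_ else
      names(which.max(category_severity[hits$category]))
  )
  for (t in sort(maf_thresholds, decreasing = TRUE)) {
    out[[threshold_flag_name(t)]] <- any(hits$maf >= t)
  }
  out
}

threshold_flag_name <- function(t) {
  sprintf("unreliable_at_%s", sub("^0\\.", "", format(t, trim = TRUE)))
}

#' Audit every probe in a manifest against a SNP panel
#'
#' The workhorse of the reliability stage. For each probe the SNP panel
#' is scanned for hits in the ONSITE / 5nt / 10nt windows and verdicts
#' are produced at each MAF threshold, together with the summary counts
#' reported for such audits: per-category probe counts, multi-SNP probe
#' counts, totals, and a positional histogram of affected probes.
#'
#' @param probes manifest data.frame (usually already region-restricted).
#' @param snps SNP panel data.frame from [read_af_panel()].
#' @param maf_thresholds numeric cutoffs, default `c(0.05, 0.01)`.
#' @param bin_width histogram bin width in bp (default 100,000).
#' @return list of class `hlameth_audit` with
#'   \describe{
#'     \item{probes}{per-probe data.frame: `probe_id`, `binding_pos`,
#'       `n_hits`, `n_onsite`, `n_nt5`, `n_nt10`, `worst_category`, and
#'       one `unreliable_at_*` column per threshold (all at the lowest
#'       threshold except the verdict columns).}
#'     \item{summary}{per-threshold data.frame of counts: probes with >=1
#'       ONSITE/NT5/NT10 hit, probes with multiple hits within all three
#'       windows and within ONSITE+NT5, and total unreliable probes.}
#'     \item{histogram}{per-threshold, per-bin counts of probes with >=1
#'       hit (bin start coordinates, `bin_width` wide).}
#'     \item{thresholds}{the MAF cutoffs used.}
#'   }
#' @export
audit_all <- function(probes, snps, maf_thresholds = c(0.05, 0.01),
                      bin_width = 100000L) {
  stopifnot(is.data.frame(probes), nrow(probes) >= 1L)
  tmin <- min(maf_thresholds)
  thresholds <- sort(maf_thresholds, decreasing = TRUE)

  # index panel by chromosome once; per-probe lookup is a binary search
  # over sorted positions, so the scan is O(log n + hits) per probe
  snps <- snps[snps$maf >= tmin, , drop = FALSE]
  snps$chromosome <- norm_chrom(snps$chromosome)
  panel <- split(snps[order(snps$position), c("position", "maf")],
                 norm_chrom(snps$chromosome[order(snps$position)]))

  n <- nrow(probes)
  per <- data.frame(probe_id = probes$probe_id,
                    chromosome = norm_chrom(probes$chromosome),
                    binding_pos = probes$binding_pos,
                    n_hits = 0L, n_onsite = 0L, n_nt5 = 0L, n_nt10 = 0L,
                    worst_category = NA_character_,
                    max_hit_maf = NA_real_,
                    stringsAsFactors = FALSE)
  for (t in thresholds) per[[threshold_flag_name(t)]] <- FALSE

  hit_list <- vector("list", n)
  for (i in seq_len(n)) {
    pr <- probes[i, ]
    chr <- panel[[norm_chrom(pr$chromosome)]]
    if (is.null(chr)) next
    lo <- pr$binding_pos - 15L; hi <- pr$binding_pos + 15L
    i1 <- findInterval(lo - 1L, chr$position) + 1L
    i2 <- findInterval(hi, chr$position)
    if (i2 < i1) next
    near <- chr[i1:i2, , drop = FALSE]
    cat_ <- classify_offset(near$position - pr$binding_pos,
                            pr$strand, pr$design_type)
    keep <- !is.na(cat_)
    if (!any(keep)) next
    near <- near[keep]; cat_ <- cat_[keep]
    per$n_hits[i]   <- length(cat_)
    per$n_onsite[i] <- sum(cat_ == "ONSITE")
    per$n_nt5[i]    <- sum(cat_ == "NT5")
    per$n_nt10[i]   <- sum(cat_ == "NT10")
    per$worst_category[i] <- names(which.max(category_severity[cat_]))
    per$max_hit_maf[i] <- max(near$maf)
    for (t in thresholds)
      per[[threshold_flag_name(t)]][i] <- any(near$maf >= t)
    hit_list[[i]] <- data.frame(probe_id = pr$probe_id,
                                position = near$position,
                                maf = near$maf, category = cat_,
                                stringsAsFactors = FALSE)
  }
  hits <- if (any(!vapply(hit_list, is.null, logical(1))))
    do.call(rbind, hit_list[!vapply(hit_list, is.null, logical(1))])
  else
    data.frame(probe_id = character(0), position = integer(0),
               maf = numeric(0), category = character(0))

  summarize_at <- function(t) {
    h <- hits[hits$maf >= t, , drop = FALSE]
    by_probe <- split(h$category, h$probe_id)
    n_multi_all <- sum(vapply(by_probe, length, integer(1)) >= 2L)
    n_multi_on5 <- sum(vapply(by_probe, function(cc)
      sum(cc %in% c("ONSITE", "NT5")), integer(1)) >= 2L)
    data.frame(
      maf_threshold   = t,
      n_probes        = nrow(probes),
      n_onsite_probes = length(unique(h$probe_id[h$category == "ONSITE"])),
      n_nt5_probes    = length(unique(h$probe_id[h$category == "NT5"])),
      n_nt10_probes   = length(unique(h$probe_id[h$category == "NT10"])),
      n_multi_snp_10nt = n_multi_all,
      n_multi_snp_5nt  = n_multi_on5,
      n_unreliable    = length(unique(h$probe_id)),
      stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, lapply(thresholds, summarize_at))

  hist_at <- function(t) {
    flagged <- per[per[[threshold_flag_name(t)]], , drop = FALSE]
    if (nrow(flagged) == 0L)
      return(data.frame(maf_threshold = numeric(0), bin_start = integer(0),
                        n_probes = integer(0)))
    bin <- (flagged$binding_pos %/% bin_width) * bin_width
    agg <- as.data.frame(table(bin), stringsAsFactors = FALSE)
    data.frame(maf_threshold = t,
               bin_start = as.integer(agg$bin),
               n_probes = as.integer(agg$Freq))
  }
  histogram <- do.call(rbind, lapply(thresholds, hist_at))

  structure(list(probes = per, hits = hits, summary = summary,
                 histogram = histogram, thresholds = thresholds,
                 bin_width = bin_width),
            class = "hlameth_audit")
}

#' @export
print.hlameth_audit <- function(x, ...) {
  cat("Probe reliability audit:", nrow(x$probes), "probes,",
      nrow(x$hits), "SNP hits\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Extract the unreliable-probe blocklist from an audit
#'
#' @param audit `hlameth_audit` object.
#' @param maf_threshold which audited threshold to use (default the
#'   lowest, i.e. the most conservative verdict).
#' @return character vector of probe IDs, sorted.
#' @export
audit_blocklist <- function(audit, maf_threshold = min(audit$thresholds)) {
  col <- threshold_flag_name(maf_threshold)
  if (!col %in% names(audit$probes))
    config_error(sprintf("audit was not run at MAF threshold %s", maf_threshold))
  sort(audit$probes$probe_id[audit$probes[[col]]])
}
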