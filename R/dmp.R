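#' Drop probes that fail detection in too many samples
#'
#' A probe is removed when its detection P value is `>= cut` in strictly
#' more than `frac` of the samples ("more than 10%": a probe failing in
#' exactly 10% of samples is kept). Missing detection-P cells count as
#' failures.
#'
#' @param betas probe-by-sample beta matrix.
#' @param detp detection-P matrix with identical dimnames.
#' @param cut detection-P failure cutoff (default 0.01).
#' @param frac maximum tolerated failure fraction (default 0.10, strict).
#' @return list with `betas` (filtered matrix) and `dropped` (probe IDs).
#' @export
filter_detection_p <- function(betas, detp, cut = 0.01, frac = 0.10) {
  if (!identical(dim(betas), dim(detp)) ||
      !identical(rownames(betas), rownames(detp)) ||
      !identical(colnames(betas), colnames(detp)))
    data_error("beta and detection-P matrices must share probe and sample axes")
  fail <- is.na(detp) | detp >= cut
  frac_fail <- rowMeans(fail)
  drop <- frac_fail > frac
  list(betas = betas[!drop, , drop = FALSE],
       dropped = rownames(betas)[drop])
}

#' Remove blocklisted probes from a beta matrix
#'
#' @param betas probe-by-sample matrix.
#' @param blocklist character vector of probe IDs (e.g. from published
#'   unreliable-probe lists or [audit_blocklist()]). IDs absent from the
#'   matrix are ignored with a warning.
#' @return list with `betas` and `dropped`.
#' @export
apply_blocklist <- function(betas, blocklist) {
  blocklist <- unique(as.character(blocklist))
  absent <- setdiff(blocklist, rownames(betas))
  if (length(absent))
    warning(sprintf("%d blocklist probe(s) not present in matrix", length(absent)))
  drop <- rownames(betas) %in% blocklist
  list(betas = betas[!drop, , drop = FALSE],
       dropped = rownames(betas)[drop])
}

#' Restrict a beta matrix to probes inside a genomic region
#'
#' Bounds are 1-based inclusive on both ends.
#'
#' @param betas probe-by-sample matrix.
#' @param manifest probe records covering (at least) the matrix rows.
#' @param region one-row region data.frame (see [hla_regions()]).
#' @return filtered matrix.
#' @export
subset_region <- function(betas, manifest, region) {
  idx <- match(rownames(betas), manifest$probe_id)
  if (anyNA(idx))
    data_error(sprintf("%d matrix probe(s) missing from manifest", sum(is.na(idx))))
  mf <- manifest[idx, ]
  keep <- norm_chrom(mf$chromosome) == norm_chrom(region$chromosome) &
    mf$binding_pos >= region$start & mf$binding_pos <= region$end
  betas[keep, , drop = FALSE]
}

#' Per-probe two-sample t-test of case vs control methylation
#'
#' Compares beta values between groups probe by probe. Student's
#' equal-variance test is the default (groups are balanced by design);
#' Welch is available by flag and recorded in the result's attributes.
#' Missing values are excluded pairwise per probe. The reported
#' `difference` is always case mean minus control mean, so negative
#' values mean hypomethylation in cases.
#'
#' @param betas probe-by-sample matrix.
#' @param samples sample sheet with `sample_id` and `group`.
#' @param var_equal Student (`TRUE`, default) or Welch (`FALSE`).
#' @return data.frame: `probe_id`, `n_control`, `n_case`,
#'   `mean_beta_control`, `mean_beta_case`, `difference`, `t_stat`,
#'   `p_ttest`, `flag` (`""`, `"untestable"` or `"zero_variance"`).
#' @export
dmp_ttest <- function(betas, samples, var_equal = TRUE) {
  grp <- align_groups(betas, samples)
  b_ctl <- betas[, grp == "control", drop = FALSE]
  b_cas <- betas[, grp == "case", drop = FALSE]

  n1 <- rowSums(!is.na(b_ctl)); n2 <- rowSums(!is.na(b_cas))
  m1 <- rowMeans(b_ctl, na.rm = TRUE); m2 <- rowMeans(b_cas, na.rm = TRUE)
  v1 <- row_var(b_ctl); v2 <- row_var(b_cas)

  diff <- m2 - m1
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- diff / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)

  flag <- rep("", nrow(betas))
  untestable <- n1 < 2 | n2 < 2
  zero_var <- !untestable & se == 0
  flag[zero_var] <- "zero_variance"
  flag[untestable] <- "untestable"
  p[untestable | zero_var] <- NA_real_
  tstat[untestable | zero_var] <- NA_real_

  out <- data.frame(probe_id = rownames(betas),
                    n_control = n1, n_case = n2,
                    mean_beta_control = m1, mean_beta_case = m2,
                    difference = diff, t_stat = tstat, p_ttest = p,
                    flag = flag, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "test") <- if (var_equal) "student" else "welch"
  out
}

#' Per-probe OLS regression of methylation on case status with covariates
#'
#' Fits `beta ~ case + covariates` by ordinary least squares for every
#' probe and reports the case-status coefficient with its P value plus
#' the P value of the first covariate (by default the HLA-DQB1*06:02
#' carrier flag, the confounder this design exists to adjust for).
#' Probes whose design matrix is rank-deficient after removing missing
#' values are flagged `inestimable` rather than erroring.
#'
#' @param betas probe-by-sample matrix.
#' @param samples sample sheet (needs `group` plus covariate columns).
#' @param covariates character vector of sample-sheet columns, default
#'   `"dqb1_0602_carrier"`.
#' @return data.frame: `probe_id`, `coef_regression` (case effect on the
#'   beta scale), `p_regression` (case term), `p_covariate` (first
#'   covariate), `flag`.
#' @export
dmp_regression <- function(betas, samples,
                           covariates = "dqb1_0602_carrier") {
  grp <- align_groups(betas, samples)
  ord <- match(colnames(betas), samples$sample_id)
  covs <- samples[ord, covariates, drop = FALSE]
  X <- cbind(`(Intercept)` = 1,
             case = as.numeric(grp == "case"),
             as.matrix(data.frame(lapply(covs, as.numeric))))
  colnames(X) <- c("(Intercept)", "case", covariates)
  fit_one <- function(y) {
    ok <- !is.na(y)
    Xi <- X[ok, , drop = FALSE]
    n <- sum(ok); p <- ncol(Xi)
    if (n <= p || qr(Xi)$rank < p)
      return(c(NA_real_, NA_real_, NA_real_, 1))
    fit <- lm.fit(Xi, y[ok])
    rdf <- n - p
    s2 <- sum(fit$residuals^2) / rdf
    XtX_inv <- chol2inv(chol(crossprod(Xi)))
    se <- sqrt(s2 * diag(XtX_inv))
    tv <- fit$coefficients / se
    pv <- 2 * pt(abs(tv), rdf, lower.tail = FALSE)
    c(fit$coefficients["case"], pv["case"], pv[covariates[1]], 0)
  }
  res <- t(apply(betas, 1L, fit_one))
  data.frame(probe_id = rownames(betas),
             coef_regression = res[, 1L],
             p_regression = res[, 2L],
             p_covariate = res[, 3L],
             flag = ifelse(res[, 4L] == 1, "inestimable", ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bonferroni family-wise significance flags
#'
#' The threshold is computed as `alpha_family / n_tests` at run time —
#' never hard-coded — and the comparison is strict (`p < threshold`).
#'
#' @param p numeric vector of P values (NA allowed, never significant).
#' @param alpha_family family-wise error rate, default 0.05.
#' @param n_tests number of tests; defaults to the number of non-missing
#'   P values supplied.
#' @return list with `threshold`, `n_tests` and logical `significant`.
#' @export
bonferroni <- function(p, alpha_family = 0.05, n_tests = sum(!is.na(p))) {
  if (n_tests < 1L) config_error("bonferroni needs n_tests >= 1")
  thr <- alpha_family / n_tests
  list(threshold = thr, n_tests = n_tests,
       significant = !is.na(p) & p < thr)
}

#' Compare nominally significant probe sets between two analyses
#'
#' Typically used for CD4+ vs CD8+ T-cell runs over the same probe
#' universe: reports per-set counts of probes at `p < p_cut`, their
#' intersection, and the hypo-/hypermethylated fractions (sign of the
#' case-minus-control difference) within each significant set.
#'
#' @param results_a,results_b DMP result data.frames (need `probe_id`,
#'   a P column and `difference`).
#' @param p_cut nominal cutoff, default 0.05.
#' @param p_col which P column to use, default `"p_ttest"`.
#' @return list of counts and fractions.
#' @export
compare_cell_types <- function(results_a, results_b, p_cut = 0.05,
                               p_col = "p_ttest") {
  sig <- function(r) r$probe_id[!is.na(r[[p_col]]) & r[[p_col]] < p_cut]
  sa <- sig(results_a); sb <- sig(results_b)
  hypo_frac <- function(r, ids) {
    d <- r$difference[r$probe_id %in% ids]
    if (!length(d)) return(NA_real_)
    mean(d < 0)
  }
  list(n_significant_a = length(sa),
       n_significant_b = length(sb),
       n_common = length(intersect(sa, sb)),
       hypo_fraction_a = hypo_frac(results_a, sa),
       hypo_fraction_b = hypo_frac(results_b, sb),
       hyper_fraction_a = 1 - hypo_frac(results_a, sa),
       hyper_fraction_b = 1 - hypo_frac(results_b, sb))
}

#' Run the full DMP pipeline on one beta matrix
#'
#' Fixed stage order: detection-P filter, blocklist removal, region
#' subset, then the unadjusted t-test and carrier-adjusted regression,
#' with Bonferroni flags computed from the number of probes actually
#' tested. Stage counts are returned so runs are auditable.
#'
#' @param betas beta matrix; @param detp detection-P matrix.
#' @param manifest probe records; @param samples sample sheet.
#' @param region one-row region data.frame.
#' @param blocklist probe IDs to drop (default none).
#' @param covariates regression covariates, default carrier status.
#' @param alpha_family family-wise alpha, default 0.05.
#' @param detection_p_cut,detection_sample_frac detection filter knobs.
#' @param var_equal Student (default) vs Welch t-test.
#' @param adjust run the adjusted regression too (default TRUE).
#' @return list of class `hlameth_dmp`: `results` (merged per-probe
#'   table), `counts` (stage ledger), `alpha_threshold`, `config`.
#' @export
run_dmp <- function(betas, detp, manifest, samples, region,
                    blocklist = character(0),
                    covariates = "dqb1_0602_carrier",
                    alpha_family = 0.05,
                    detection_p_cut = 0.01, detection_sample_frac = 0.10,
                    var_equal = TRUE, adjust = TRUE) {
  counts <- c(probes_in = nrow(betas))
  st <- filter_detection_p(betas, detp, detection_p_cut, detection_sample_frac)
  counts["dropped_detection_p"] <- length(st$dropped)
  st <- apply_blocklist(st$betas, blocklist)
  counts["dropped_blocklist"] <- length(st$dropped)
  b <- subset_region(st$betas, manifest, region)
  counts["in_region"] <- nrow(b)
  if (nrow(b) == 0L) data_error("no probes left after filtering")

  tt <- dmp_ttest(b, samples, var_equal = var_equal)
  res <- tt
  if (adjust) {
    rg <- dmp_regression(b, samples, covariates = covariates)
    res <- merge(tt, rg, by = "probe_id", sort = FALSE,
                 suffixes = c("", "_adj"))
    res$flag <- ifelse(res$flag_adj == "inestimable" & res$flag == "",
                       "inestimable", res$flag)
    res$flag_adj <- NULL
  }
  counts["tested"] <- sum(!is.na(res$p_ttest))

  bf <- bonferroni(res$p_ttest, alpha_family, n_tests = counts[["tested"]])
  res$significant_bonferroni <- bf$significant
  idx <- match(res$probe_id, manifest$probe_id)
  res <- cbind(res[, "probe_id", drop = FALSE],
               position = manifest$binding_pos[idx],
               gene = manifest$gene[idx], feature = manifest$feature[idx],
               res[, setdiff(names(res), "probe_id"), drop = FALSE])

  structure(list(results = res, counts = counts,
                 alpha_threshold = bf$threshold,
                 config = list(region = region, alpha_family = alpha_family,
                               detection_p_cut = detection_p_cut,
                               detection_sample_frac = detection_sample_frac,
                               covariates = if (adjust) covariates else character(0),
                               t_test = attr(tt, "test"))),
            class = "hlameth_dmp")
}

#' @export
print.hlameth_dmp <- function(x, ...) {
  cat("DMP pipeline:", x$counts[["probes_in"]], "probes in,",
      x$counts[["tested"]], "tested; Bonferroni threshold",
      format(x$alpha_threshold, digits = 3), "\n")
  cat(sum(x$results$significant_bonferroni), "probe(s) family-wise significant\n")
  invisible(x)
}

# ---- internals ----

align_groups <- function(betas, samples) {
  idx <- match(colnames(betas), samples$sample_id)
  if (anyNA(idx))
    data_error("matrix has sample column(s) absent from the sample sheet")
  grp <- samples$group[idx]
  if (sum(grp == "case") < 2L || sum(grp == "control") < 2L)
    data_error("need >=2 samples per group")
  grp
}

row_var <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  rowSums((m - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
}
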