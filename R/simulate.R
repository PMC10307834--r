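#' Build a simulation specification
#'
#' The generator's defaults encode the study design the package targets:
#' 42 cases / 42 controls, every case an HLA-DQB1*06:02 carrier versus 8
#' of 42 controls; planted methylation shifts of 0.02-0.05 (direct) and
#' 0.18 (carrier-mediated, the magnitude of a carrier-driven CpG); a SNP
#' panel whose MAF spectrum spans 0.001-0.5; and an allele-expression
#' model with one highly expressed reference allele. Beta noise uses a
#' concentration `beta_kappa` calibrated so per-probe SDs land around
#' 0.02-0.04.
#'
#' @param n_cases,n_controls group sizes (default 42 each).
#' @param carrier_count_cases,carrier_count_controls number of
#'   DQB1*06:02 carriers per group (defaults 42 and 8).
#' @param n_probes number of manifest probes (default 2000).
#' @param region one-row region data.frame (default the extended HLA
#'   region).
#' @param effect_probes data.frame with `mechanism`
#'   (`direct`/`carrier_mediated`/`null`) and `delta` (beta-scale shift);
#'   assigned to the first probes in manifest order. Default: five direct
#'   probes with deltas -0.02..-0.05 and three carrier-mediated probes
#'   with delta 0.18.
#' @param beta_kappa Beta-distribution concentration (default 250).
#' @param detection_fail_rate per-cell probability of a failed
#'   detection-P entry (default 0.002).
#' @param snp_plan data.frame with `probe_index`, `offset` (in [-15, 15])
#'   and `maf`, planting SNPs at exact offsets from named probes; `NULL`
#'   (default) plants one SNP on each of 10% of probes at random offsets.
#' @param n_background_snps extra panel SNPs at random positions
#'   (default 500).
#' @param allele_multiplier_case expression multiplier applied in cases
#'   to the targeted alleles (default 0.7, i.e. a 30% reduction).
#' @param multiplier_target `"non_reference"` (default) or
#'   `"sublineage_05_06"`.
#' @param expression_depth expected DQB1 read depth scale (default 2000).
#' @param nb_size negative-binomial size for read counts (default 20).
#' @param seed master seed (default 1).
#' @return list of class `hlameth_sim_spec`.
#' @export
simulation_spec <- function(n_cases = 42L, n_controls = 42L,
                            carrier_count_cases = 42L,
                            carrier_count_controls = 8L,
                            n_probes = 2000L,
                            region = hla_regions("hla_extended"),
                            effect_probes = NULL,
                            beta_kappa = 250,
                            detection_fail_rate = 0.002,
                            snp_plan = NULL,
                            n_background_snps = 500L,
                            allele_multiplier_case = 0.7,
                            multiplier_target = c("non_reference",
                                                  "sublineage_05_06"),
                            expression_depth = 2000,
                            nb_size = 20,
                            seed = 1L) {
  multiplier_target <- match.arg(multiplier_target)
  if (carrier_count_cases > n_cases || carrier_count_controls > n_controls)
    config_error("carrier counts cannot exceed group sizes")
  if (n_probes < 1L) config_error("n_probes must be >= 1")
  if (is.null(effect_probes))
    effect_probes <- data.frame(
      mechanism = c(rep("direct", 5L), rep("carrier_mediated", 3L)),
      delta = c(-c(0.02, 0.0275, 0.035, 0.0425, 0.05), rep(0.18, 3L)),
      stringsAsFactors = FALSE)
  stopifnot(all(effect_probes$mechanism %in%
                  c("direct", "carrier_mediated", "null")))
  if (!is.null(snp_plan))
    stopifnot(all(snp_plan$offset >= -15L & snp_plan$offset <= 15L),
              all(snp_plan$maf > 0 & snp_plan$maf <= 0.5))
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    carrier_count_cases = as.integer(carrier_count_cases),
    carrier_count_controls = as.integer(carrier_count_controls),
    n_probes = as.integer(n_probes), region = region,
    effect_probes = effect_probes, beta_kappa = beta_kappa,
    detection_fail_rate = detection_fail_rate,
    snp_plan = snp_plan, n_background_snps = as.integer(n_background_snps),
    allele_multiplier_case = allele_multiplier_case,
    multiplier_target = multiplier_target,
    expression_depth = expression_depth, nb_size = nb_size,
    seed = as.integer(seed)), class = "hlameth_sim_spec")
}

#' Generate a synthetic probe manifest
#'
#' Probes are placed uniformly in the spec's region with random strand
#' and design type (roughly 4:1 Type II:Type I, as on EPIC-class
#' arrays), sorted by position, with deterministic IDs.
#'
#' @param spec `hlameth_sim_spec`.
#' @return manifest data.frame (see [read_manifest()] for the schema).
#' @export
gen_manifest <- function(spec) {
  set.seed(derive_seed(spec$seed, "manifest"))
  n <- spec$n_probes
  pos <- sort(sample(spec$region$start:spec$region$end, n, replace = FALSE))
  genes <- c("HLA-A", "HLA-B", "HLA-DRA", "HLA-DRB1", "HLA-DQB1",
             "HLA-DPB1", "TNXB", "BTNL2", "GABBR1", "COL11A2", NA)
  feats <- c("Body", "TSS200", "TSS1500", "5'UTR", NA)
  data.frame(
    probe_id = sprintf("cg%08d", seq_len(n)),
    chromosome = spec$region$chromosome,
    binding_pos = pos,
    strand = sample(c("F", "R"), n, replace = TRUE),
    design_type = sample(c("I", "II"), n, replace = TRUE, prob = c(0.2, 0.8)),
    gene = sample(genes, n, replace = TRUE),
    feature = sample(feats, n, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic allele-frequency panel
#'
#' Plants SNPs at exact offsets from chosen probes (recording the
#' expected influence category for each) and adds background SNPs at
#' random positions with MAFs drawn from a mixture spanning 0.001-0.5.
#' Half of the emitted VCF `AF` values are encoded as the major-allele
#' frequency `1 - maf` to exercise frequency folding on read.
#'
#' @param spec `hlameth_sim_spec`.
#' @param manifest output of [gen_manifest()].
#' @return list: `snps` (data.frame ready for [write_af_vcf()], with
#'   `af` as emitted and `maf` as truth) and `truth` (per-SNP ledger:
#'   `planted`, `probe_id`, `offset`, `expected_category`, `maf`).
#' @export
gen_af_panel <- function(spec, manifest) {
  set.seed(derive_seed(spec$seed, "af_panel"))
  plan <- spec$snp_plan
  if (is.null(plan)) {
    k <- max(1L, round(spec$n_probes * 0.10))
    idx <- sort(sample(seq_len(spec$n_probes), k))
    plan <- data.frame(probe_index = idx,
                       offset = sample(-15:15, k, replace = TRUE),
                       maf = round(exp(runif(k, log(0.001), log(0.5))), 5))
  }
  pr <- manifest[plan$probe_index, ]
  planted <- data.frame(
    chromosome = pr$chromosome,
    position = pr$binding_pos + plan$offset,
    maf = plan$maf,
    planted = TRUE,
    probe_id = pr$probe_id,
    offset = plan$offset,
    expected_category = vapply(seq_len(nrow(plan)), function(i)
      classify_offset(plan$offset[i], pr$strand[i], pr$design_type[i]) %||%
        NA_character_, character(1)),
    stringsAsFactors = FALSE)

  nb <- spec$n_background_snps
  snps <- planted
  if (nb > 0L) {
    bg <- data.frame(
      chromosome = rep(spec$region$chromosome, nb),
      position = sample(spec$region$start:spec$region$end, nb),
      # mixture: half rare (0.001-0.01 log-uniform), half common (0.01-0.5)
      maf = round(ifelse(runif(nb) < 0.5,
                         exp(runif(nb, log(0.001), log(0.01))),
                         exp(runif(nb, log(0.01), log(0.5)))), 5),
      planted = FALSE, probe_id = NA_character_, offset = NA_integer_,
      expected_category = NA_character_, stringsAsFactors = FALSE)
    snps <- rbind(planted, bg)
  }
  # avoid positional collisions between planted and background records
  snps <- snps[!duplicated(snps$position) | snps$planted, , drop = FALSE]
  bases <- c("A", "C", "G", "T")
  snps$ref_allele <- sample(bases, nrow(snps), replace = TRUE)
  snps$alt_allele <- vapply(snps$ref_allele,
                            function(r) sample(setdiff(bases, r), 1L),
                            character(1))
  flip <- runif(nrow(snps)) < 0.5
  snps$af <- ifelse(flip, 1 - snps$maf, snps$maf)
  list(snps = snps,
       truth = snps[, c("chromosome", "position", "maf", "planted",
                        "probe_id", "offset", "expected_category")])
}

#' Generate a synthetic cohort sample sheet
#'
#' Exact carrier counts per group; age, sex and BMI from fixed plausible
#' distributions for an adult Japanese cohort.
#'
#' @param spec `hlameth_sim_spec`.
#' @return sample sheet data.frame.
#' @export
gen_cohort <- function(spec) {
  set.seed(derive_seed(spec$seed, "cohort"))
  n <- spec$n_cases + spec$n_controls
  group <- c(rep("case", spec$n_cases), rep("control", spec$n_controls))
  carrier <- c(seq_len(spec$n_cases) <= spec$carrier_count_cases,
               seq_len(spec$n_controls) <= spec$carrier_count_controls)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = group,
    dqb1_0602_carrier = carrier,
    age = round(pmin(pmax(rnorm(n, 40, 12), 18), 75)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    bmi = round(rnorm(n, 22.5, 3), 1),
    stringsAsFactors = FALSE)
}

#' Generate synthetic beta and detection-P matrices
#'
#' Null probes share one Beta(mu*kappa, (1-mu)*kappa) distribution in
#' both groups; `direct` effect probes shift the case mean by `delta`;
#' `carrier_mediated` probes shift the mean by `delta` for DQB1*06:02
#' carriers regardless of case status. A small fraction of detection-P
#' cells is set to failing values (>= 0.01) to exercise the filter.
#'
#' @param spec `hlameth_sim_spec`.
#' @param cohort output of [gen_cohort()].
#' @param manifest output of [gen_manifest()].
#' @return list: `betas`, `detp` (matrices) and `truth` (per-probe
#'   `mechanism` and `delta`).
#' @export
gen_beta <- function(spec, cohort, manifest) {
  set.seed(derive_seed(spec$seed, "beta"))
  n_p <- nrow(manifest); n_s <- nrow(cohort)
  # bimodal baseline typical of array data, kept away from the bounds
  lowhigh <- runif(n_p)
  mu <- ifelse(lowhigh < 0.4, runif(n_p, 0.05, 0.25),
        ifelse(lowhigh < 0.8, runif(n_p, 0.65, 0.92),
               runif(n_p, 0.3, 0.6)))

  mech <- rep("null", n_p); delta <- rep(0, n_p)
  ep <- spec$effect_probes
  if (nrow(ep) > n_p) config_error("more effect probes than probes")
  mech[seq_len(nrow(ep))] <- ep$mechanism
  delta[seq_len(nrow(ep))] <- ep$delta
  # keep shifted means inside (0.02, 0.98)
  needs_room <- mech != "null"
  mu[needs_room] <- pmin(pmax(mu[needs_room], 0.02 + pmax(-delta[needs_room], 0) + 0.05),
                         0.98 - pmax(delta[needs_room], 0) - 0.05)

  is_case <- cohort$group == "case"
  is_carrier <- cohort$dqb1_0602_carrier
  m <- matrix(rep(mu, n_s), nrow = n_p)
  for (i in which(mech == "direct")) m[i, is_case] <- mu[i] + delta[i]
  for (i in which(mech == "carrier_mediated")) m[i, is_carrier] <- mu[i] + delta[i]

  k <- spec$beta_kappa
  betas <- matrix(rbeta(n_p * n_s, c(m) * k, (1 - c(m)) * k), nrow = n_p)
  rownames(betas) <- manifest$probe_id
  colnames(betas) <- cohort$sample_id

  detp <- matrix(runif(n_p * n_s, 0, 0.005), nrow = n_p,
                 dimnames = dimnames(betas))
  failed <- matrix(runif(n_p * n_s) < spec$detection_fail_rate, nrow = n_p)
  detp[failed] <- runif(sum(failed), 0.01, 1)

  list(betas = betas, detp = detp,
       truth = data.frame(probe_id = manifest$probe_id,
                          mechanism = mech, delta = delta,
                          baseline_mu = mu, stringsAsFactors = FALSE))
}

# background transcripts from the other typed HLA genes: per-million
# standardization runs over the whole table, so DQB1 must not be the
# only gene or non-carrier DQB1 shares degenerate to exactly 1e6
background_gene_pool <- function() {
  data.frame(
    gene = c("DRA", "DPA1"),
    allele = c("DRA*01:01", "DPA1*01:03"),
    rel_expr = c(2.2, 0.9),
    length = c(1290L, 1250L),
    stringsAsFactors = FALSE)
}

# allele pool: reference allele distinctly high-expressed; 05/06
# sublineage intermediate, 03/04 lower — with per-allele lengths in nt
dqb1_allele_pool <- function() {
  data.frame(
    allele = c("DQB1*06:02", "DQB1*06:01", "DQB1*06:09", "DQB1*05:01",
               "DQB1*05:03", "DQB1*03:01", "DQB1*03:02", "DQB1*04:01"),
    rel_expr = c(1.0, 0.55, 0.8, 0.5, 0.6, 0.25, 0.3, 0.2),
    length = c(1101L, 1106L, 1099L, 1110L, 1103L, 1119L, 1115L, 1108L),
    freq = c(NA, 0.16, 0.04, 0.22, 0.10, 0.24, 0.12, 0.12),
    stringsAsFactors = FALSE)
}

#' Generate synthetic per-allele RNA read counts
#'
#' Each sample carries two DQB1 alleles consistent with its carrier
#' status (carriers get one DQB1*06:02 copy plus one non-reference
#' allele; non-carriers two non-reference alleles, possibly homozygous —
#' counts are then pooled into one row). Counts are negative-binomial
#' around `depth x copies x relative expression x length/1kb`; in case
#' samples the targeted alleles' expression is multiplied by
#' `allele_multiplier_case`. Transcripts from two background HLA genes
#' (never targeted by the multiplier) are included so that the
#' per-million standardization runs over the whole typed repertoire, as
#' it does for real abundance tables.
#'
#' @param spec `hlameth_sim_spec`.
#' @param cohort output of [gen_cohort()].
#' @return list: `counts` (allele-count data.frame) and `truth`
#'   (per-allele expected relative expression and the applied
#'   multiplier).
#' @export
gen_allele_counts <- function(spec, cohort) {
  set.seed(derive_seed(spec$seed, "alleles"))
  pool <- dqb1_allele_pool()
  nonref <- pool[pool$allele != "DQB1*06:02", ]
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    s <- cohort[i, ]
    alleles <- if (s$dqb1_0602_carrier)
      c("DQB1*06:02", sample(nonref$allele, 1L, prob = nonref$freq))
    else
      sample(nonref$allele, 2L, replace = TRUE, prob = nonref$freq)
    tab <- table(alleles)
    a <- pool[match(names(tab), pool$allele), ]
    e <- a$rel_expr
    targeted <- if (spec$multiplier_target == "non_reference")
      a$allele != "DQB1*06:02"
    else
      sublineage_of(a$allele) == "DQB1_05_06" & a$allele != "DQB1*06:02"
    if (s$group == "case")
      e[targeted] <- e[targeted] * spec$allele_multiplier_case
    bg <- background_gene_pool()
    gene_ <- c(rep("DQB1", length(tab)), bg$gene)
    allele_ <- c(names(tab), bg$allele)
    len_ <- c(a$length, bg$length)
    mu <- spec$expression_depth *
      c(as.integer(tab) * e * a$length / 1000,
        2 * bg$rel_expr * bg$length / 1000)   # two copies, not targeted
    rows[[i]] <- data.frame(
      sample_id = s$sample_id, gene = gene_, allele = allele_,
      read_count = rnbinom(length(mu), mu = mu, size = spec$nb_size),
      allele_length = len_, stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows)
  truth <- pool[, c("allele", "rel_expr", "length")]
  truth$case_multiplier <- ifelse(
    truth$allele == "DQB1*06:02", 1,
    ifelse(spec$multiplier_target == "non_reference" |
             sublineage_of(truth$allele) == "DQB1_05_06",
           spec$allele_multiplier_case, 1))
  bg <- background_gene_pool()
  truth <- rbind(truth,
                 data.frame(allele = bg$allele, rel_expr = bg$rel_expr,
                            length = bg$length, case_multiplier = 1))
  list(counts = counts, truth = truth)
}

#' Generate the complete synthetic study and write it to disk
#'
#' Runs every generator with stage seeds derived from the master seed
#' and writes `manifest.tsv`, `panel.vcf`, `beta.tsv`, `detp.tsv`,
#' `samples.tsv`, `allele_counts.tsv` and `truth.json` into `out_dir`.
#' Identical specs produce byte-identical files.
#'
#' @param spec `hlameth_sim_spec`.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing and returns the in-memory objects only.
#' @return list with all generated objects, the ground-truth ledger and
#'   (when written) the file paths.
#' @export
simulate_study <- function(spec, out_dir = NULL) {
  manifest <- gen_manifest(spec)
  panel <- gen_af_panel(spec, manifest)
  cohort <- gen_cohort(spec)
  meth <- gen_beta(spec, cohort, manifest)
  expr <- gen_allele_counts(spec, cohort)

  truth <- list(
    seed = spec$seed,
    probes = meth$truth,
    snps = panel$truth,
    alleles = expr$truth,
    design = list(n_cases = spec$n_cases, n_controls = spec$n_controls,
                  carrier_count_cases = spec$carrier_count_cases,
                  carrier_count_controls = spec$carrier_count_controls,
                  allele_multiplier_case = spec$allele_multiplier_case,
                  multiplier_target = spec$multiplier_target))

  out <- list(spec = spec, manifest = manifest, snps = panel$snps,
              cohort = cohort, betas = meth$betas, detp = meth$detp,
              allele_counts = expr$counts, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      manifest = file.path(out_dir, "manifest.tsv"),
      panel = file.path(out_dir, "panel.vcf"),
      beta = file.path(out_dir, "beta.tsv"),
      detp = file.path(out_dir, "detp.tsv"),
      samples = file.path(out_dir, "samples.tsv"),
      allele_counts = file.path(out_dir, "allele_counts.tsv"),
      truth = file.path(out_dir, "truth.json"))
    data.table::fwrite(manifest, paths$manifest, sep = "\t", na = "NA",
                       quote = FALSE)
    write_af_vcf(panel$snps, paths$panel)
    write_beta_matrix(meth$betas, paths$beta)
    write_beta_matrix(meth$detp, paths$detp)
    data.table::fwrite(cohort, paths$samples, sep = "\t", na = "NA",
                       quote = FALSE)
    data.table::fwrite(expr$counts, paths$allele_counts, sep = "\t",
                       na = "NA", quote = FALSE)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    out$paths <- paths
  }
  out
}
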