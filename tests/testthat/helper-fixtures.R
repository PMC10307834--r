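# fixture builders shared across test files; everything is generated in
# code — no stored binary data

make_probe <- function(probe_id = "cgTEST", chromosome = "6",
                       binding_pos = 1000L, strand = "F",
                       design_type = "II") {
  data.frame(probe_id = probe_id, chromosome = chromosome,
             binding_pos = as.integer(binding_pos), strand = strand,
             design_type = design_type, gene = NA_character_,
             feature = NA_character_, stringsAsFactors = FALSE)
}

make_snp <- function(position, maf = 0.1, chromosome = "6") {
  n <- length(position)
  data.frame(chromosome = rep_len(chromosome, n),
             position = as.integer(position),
             ref_allele = rep_len("A", n), alt_allele = rep_len("G", n),
             maf = rep_len(maf, n), stringsAsFactors = FALSE)
}

write_manifest_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

# minimal VCF writer for hand-built records; each body line is
# "chrom\tpos\tid\tref\talt\tinfo" and gets QUAL/FILTER filled in
write_vcf_fixture <- function(body, path = tempfile(fileext = ".vcf")) {
  parts <- strsplit(body, "\t", fixed = TRUE)
  rec <- vapply(parts, function(f) {
    stopifnot(length(f) == 6L)
    paste(c(f[1:5], ".", ".", f[6]), collapse = "\t")
  }, character(1))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##contig=<ID=6>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    rec), path)
  path
}

write_matrix_fixture <- function(m, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  path
}

# cohort with exact group sizes and carrier counts (no randomness)
make_cohort <- function(n_case = 42L, n_control = 42L,
                        carriers_case = n_case, carriers_control = 8L) {
  n <- n_case + n_control
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = factor(c(rep("case", n_case), rep("control", n_control)),
                   levels = c("control", "case")),
    dqb1_0602_carrier = c(seq_len(n_case) <= carriers_case,
                          seq_len(n_control) <= carriers_control),
    age = 40, sex = "F", bmi = 22,
    stringsAsFactors = FALSE)
}

# beta matrix with exactly the requested group means: values are the mean
# plus a +/-d zero-sum perturbation so t-tests are well defined
make_beta_rows <- function(mean_control, mean_case, cohort, d = 0.01) {
  stopifnot(length(mean_control) == length(mean_case))
  n_ctl <- sum(cohort$group == "control")
  n_cas <- sum(cohort$group == "case")
  stopifnot(n_ctl %% 2 == 0, n_cas %% 2 == 0)
  noise <- function(n) rep(c(-d, d), n / 2)
  m <- t(vapply(seq_along(mean_control), function(i) {
    row <- numeric(nrow(cohort))
    row[cohort$group == "case"] <- mean_case[i] + noise(n_cas)
    row[cohort$group == "control"] <- mean_control[i] + noise(n_ctl)
    row
  }, numeric(nrow(cohort))))
  rownames(m) <- sprintf("cgFIX%04d", seq_along(mean_control))
  colnames(m) <- cohort$sample_id
  m
}

# literal transcription of the published window table, kept independent
# of the implementation on purpose (the brute-force oracle)
oracle_category <- function(offset, strand, design_type) {
  if (strand == "F" && design_type == "I") {
    if (offset %in% c(-1, 0)) return("ONSITE")
    if (offset >= 1 && offset <= 5) return("NT5")
    if (offset >= 6 && offset <= 10) return("NT10")
  } else if (strand == "F" && design_type == "II") {
    if (offset == 0) return("ONSITE")
    if (offset >= 1 && offset <= 5) return("NT5")
    if (offset >= 6 && offset <= 10) return("NT10")
  } else if (strand == "R" && design_type == "I") {
    if (offset %in% c(1, 2)) return("ONSITE")
    if (offset >= -4 && offset <= 0) return("NT5")
    if (offset >= -9 && offset <= -5) return("NT10")
  } else if (strand == "R" && design_type == "II") {
    if (offset == 1) return("ONSITE")
    if (offset >= -4 && offset <= 0) return("NT5")
    if (offset >= -9 && offset <= -5) return("NT10")
  }
  NA_character_
}
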