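#' Read a population allele-frequency panel from VCF
#'
#' Streams a VCF 4.x allele-frequency panel (plain or gzipped) into a
#' table of single-nucleotide variants with folded minor allele
#' frequencies. Multi-allelic records are expanded to one row per
#' alternate allele; indels are skipped and counted; allele frequencies
#' above 0.5 are folded to `1 - f` so `maf` is always in [0, 0.5].
#'
#' @param path VCF path.
#' @param af_field INFO field holding the per-alt allele frequency
#'   (default `"AF"`); panels differ, so this is configuration, not code.
#' @return data.frame with columns `chromosome` (normalized), `position`,
#'   `ref_allele`, `alt_allele`, `maf`, and attributes
#'   `n_indels_skipped` and `n_missing_af`.
#' @export
read_af_panel <- function(path, af_field = "AF") {
  if (!file.exists(path)) data_error(sprintf("AF panel VCF not found: %s", path))
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unknown")),
    error = function(e) data_error(sprintf("malformed VCF '%s': %s",
                                           path, conditionMessage(e))))
  # one row per alternate allele; Number=A INFO fields expand in step
  vcf <- VariantAnnotation::expand(vcf)
  info <- VariantAnnotation::info(vcf)
  if (!af_field %in% colnames(info))
    config_error(sprintf("VCF INFO has no '%s' field (available: %s)",
                         af_field, paste(colnames(info), collapse = ", ")))

  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  af <- suppressWarnings(as.numeric(info[[af_field]]))

  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_indels <- sum(!snv)
  has_af <- !is.na(af)
  n_missing_af <- sum(snv & !has_af)
  if (n_missing_af > 0L)
    warning(sprintf("%d SNV record(s) without '%s' skipped", n_missing_af, af_field))
  keep <- snv & has_af

  maf <- af[keep]
  maf <- ifelse(maf > 0.5, 1 - maf, maf)

  out <- data.frame(
    chromosome = norm_chrom(GenomeInfoDb::seqnames(rr)[keep]),
    position   = GenomicRanges::start(rr)[keep],
    ref_allele = ref[keep],
    alt_allele = alt[keep],
    maf        = maf,
    stringsAsFactors = FALSE
  )
  attr(out, "n_indels_skipped") <- n_indels
  attr(out, "n_missing_af") <- n_missing_af
  out
}

#' Write a SNV table as a minimal VCF 4.2 allele-frequency panel
#'
#' Used by the synthetic-data generator. Each row becomes one VCF record
#' with an `AF` INFO value; `af` may be given on either strand of the
#' frequency (f or 1-f) — readers fold it back to the MAF.
#'
#' @param snps data.frame with `chromosome`, `position`, `ref_allele`,
#'   `alt_allele` and either `af` or `maf`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_af_vcf <- function(snps, path) {
  af <- snps$af %||% snps$maf
  stopifnot(!is.null(af), all(af >= 0 & af <= 1))
  ord <- order(snps$chromosome, snps$position, snps$alt_allele)
  snps <- snps[ord, , drop = FALSE]
  af <- af[ord]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hlameth_synthetic_panel",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    paste0("##contig=<ID=", unique(snps$chromosome), ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%s",
                  snps$chromosome, as.integer(snps$position),
                  snps$ref_allele, snps$alt_allele,
                  format(af, trim = TRUE, scientific = FALSE, digits = 6))
  writeLines(c(header, body), path)
  invisible(path)
}
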