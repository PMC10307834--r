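#' SNP influence windows for Infinium probes
#'
#' A SNP under the 3' end of an array probe weakens hybridization and
#' makes the measured methylation fraction unreliable; the effect is
#' strongest at the interrogated site and decays to negligible beyond
#' 10 nt. Influence is graded into three categories — `ONSITE` (the
#' interrogated CpG itself, plus the single-base-extension position for
#' Type I probes), `NT5` (1-5 nt from the 3' end) and `NT10` (6-10 nt).
#'
#' Offsets are genomic: SNP position minus the probe's annotated binding
#' position. The annotated position marks the target cytosine on
#' forward-strand probes and the adjacent guanine on reverse-strand
#' probes, so the four (strand, design) combinations each get their own
#' offset table:
#'
#' | strand | design | ONSITE  | NT5      | NT10     |
#' |--------|--------|---------|----------|----------|
#' | F      | I      | -1, 0   | 1..5     | 6..10    |
#' | F      | II     | 0       | 1..5     | 6..10    |
#' | R      | I      | 1, 2    | -4..0    | -9..-5   |
#' | R      | II     | 1       | -4..0    | -9..-5   |
#'
#' The three sets are pairwise disjoint; their union has 12 offsets for
#' design I and 11 for design II.
#'
#' @param strand `"F"` or `"R"`.
#' @param design_type `"I"` or `"II"`.
#' @return list with integer vectors `onsite`, `nt5`, `nt10` plus the
#'   `strand` and `design_type` echoed back.
#' @export
#' @examples
#' influence_window("F", "II")$onsite  # 0
#' influence_window("R", "I")$onsite   # 1 2
influence_window <- function(strand, design_type) {
  strand <- match.arg(strand, c("F", "R"))
  design_type <- match.arg(design_type, c("I", "II"))
  w <- switch(paste(strand, design_type),
    "F I"  = list(onsite = c(-1L, 0L), nt5 = 1:5,   nt10 = 6:10),
    "F II" = list(onsite = 0L,         nt5 = 1:5,   nt10 = 6:10),
    "R I"  = list(onsite = c(1L, 2L),  nt5 = -4:0,  nt10 = -9:-5),
    "R II" = list(onsite = 1L,         nt5 = -4:0,  nt10 = -9:-5)
  )
  w$strand <- strand
  w$design_type <- design_type
  w
}

#' Classify one SNP's influence on one probe
#'
#' @param probe one-row probe record (needs `chromosome`, `binding_pos`,
#'   `strand`, `design_type`).
#' @param snp one-row SNP record (needs `chromosome`, `position`).
#' @return `"ONSITE"`, `"NT5"`, `"NT10"`, or `NA_character_` when the SNP
#'   lies outside every influence window.
#' @export
classify_snp <- function(probe, snp) {
  if (norm_chrom(probe$chromosome) != norm_chrom(snp$chromosome))
    stop("classify_snp: probe and SNP are on different chromosomes")
  classify_offset(as.integer(snp$position) - as.integer(probe$binding_pos),
                  probe$strand, probe$design_type)
}

# vectorized kernel over offsets for a single (strand, design) case
classify_offset <- function(offset, strand, design_type) {
  w <- influence_window(strand, design_type)
  out <- rep(NA_character_, length(offset))
  out[offset %in% w$nt10]   <- "NT10"
  out[offset %in% w$nt5]    <- "NT5"
  out[offset %in% w$onsite] <- "ONSITE"
  out
}

# severity order used for worst-category reporting only
category_severity <- c(ONSITE = 3L, NT5 = 2L, NT10 = 1L)
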