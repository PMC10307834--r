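---
title: "SNP-aware probe auditing and case-control methylation analysis in the HLA region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-aware probe auditing and case-control methylation analysis in the HLA region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Infinium-style methylation arrays estimate the methylation fraction
(β value) of a CpG from the fluorescence of a probe that must hybridize
to the flanking sequence. In the HLA region on chromosome 6 — the most
polymorphic stretch of the human genome — population SNPs frequently sit
under the probe's 3′ end, weaken hybridization, and corrupt the measured
β. Standard published blocklists are built from cosmopolitan reference
panels (≈100 genomes per population) and miss population-specific
variants, so case–control methylation studies of the HLA region in a
specific population need a bespoke audit against a large
population-matched allele-frequency panel.

`hlameth` implements that audit, the downstream differentially
methylated position (DMP) analysis it protects, and the allele-level HLA
expression comparison that interprets the methylation signal — together
with a synthetic-data generator that makes the whole pipeline testable
without any external download.

## The probe-reliability model

The influence of a SNP on a probe is graded by its distance from the
probe's 3′ end, where perturbation of hybridization and of single-base
extension is strongest:

* **ONSITE** — the interrogated position itself (and, for Type I
  probes, the adjacent extension base);
* **NT5** — within 1–5 nt of the target site;
* **NT10** — within 6–10 nt. Beyond 10 nt the effect is negligible.

The manifest anchors each probe at the target cytosine on
forward-strand probes and at the adjacent guanine on reverse-strand
probes, so the genomic offsets (SNP position − binding position) that
fall in each category differ across the four strand × design cases:

| strand | design | ONSITE | NT5   | NT10   |
|--------|--------|--------|-------|--------|
| F      | I      | −1, 0  | 1..5  | 6..10  |
| F      | II     | 0      | 1..5  | 6..10  |
| R      | I      | 1, 2   | −4..0 | −9..−5 |
| R      | II     | 1      | −4..0 | −9..−5 |

All ranges are closed: a SNP exactly on a window boundary counts. The
three windows are disjoint by construction, and the test suite checks
the implementation against an independently transcribed brute-force
oracle over every offset in [−15, 15].

A probe is called **unreliable** at MAF threshold *t* when at least one
panel SNP with minor allele frequency ≥ *t* falls in *any* window — the
conservative rule. Two thresholds are audited by default, 0.05 and
0.01, and the unreliable set at 0.05 is necessarily nested inside the
set at 0.01. Where source material alternates between "MAF larger than"
and "MAF ≥", this package standardizes on **≥** and records the
operator in the run metadata. The severity ordering ONSITE > NT5 >
NT10 is used only to report a probe's worst hit; it does not affect the
verdict.

Allele frequencies are folded on read (`f > 0.5` becomes `1 − f`), so
the audit is insensitive to which allele the panel happens to report.
Multi-allelic panel records are expanded to one variant per alternate
allele (the panel's handling is not documented anywhere authoritative;
expansion is this package's choice and is exercised in tests). Indels
are skipped and counted — the window model is defined for single
nucleotide substitutions only.

## The DMP association model

The association stage runs in a fixed, logged order:

1. **Detection-P filter** — a probe is dropped when its detection P
   value is ≥ 0.01 in *strictly more than* 10% of samples. A probe
   failing in exactly 10% of samples is kept; missing detection-P cells
   count as failures.
2. **Blocklist removal** — externally published unreliable probes are
   consumed as a plain ID list, never recomputed.
3. **Region subset** — 1-based inclusive bounds on both ends; the three
   shipped regions are the extended HLA interval
   (chr6:26,000,000–35,000,000) and the class I / class II intervals.
4. **Tests** — per-probe two-sample *t*-test on β (case minus control),
   then per-probe OLS of β on case status plus the HLA-DQB1\*06:02
   carrier flag.

Choices a user should know about:

* **Student vs Welch.** The *t*-test flavor is not dictated by the
  design; with balanced groups the two nearly coincide, so Student is
  the default and Welch is available by flag. The choice is recorded in
  the output's attributes and in run metadata.
* **β scale.** Tests run on β directly (means and differences are
  reported on the β scale, matching how such results are tabulated),
  not on M-values.
* **Carrier adjustment.** Nearly all cases carry DQB1\*06:02 while a
  minority of controls do, so case status and carrier status are highly
  (but not perfectly) collinear; the carrier term is estimable from the
  variation among controls. A probe whose per-probe design matrix is
  genuinely rank-deficient (e.g. every tested sample a carrier) is
  flagged `inestimable` rather than crashing the run. Age, sex and BMI
  are accepted as extra covariates but off by default — the methylation
  stage adjusts for the carrier flag only.
* **Bonferroni.** The family-wise threshold is always computed as
  `alpha / n_tested` from the number of probes actually tested in the
  current run, never hard-coded from any published probe count; the
  comparison is strict (`p < threshold`).
* **Degenerate probes.** Zero-variance probes get a missing P with a
  `zero_variance` flag; groups with fewer than two non-missing values
  give `untestable`. NaN never propagates.

## The allele-expression model

Per-allele RNA read counts (from an upstream HLA typer) are converted
to transcript abundances: within each sample,

    rate_i  = count_i / length_i
    abund_i = 1e6 * rate_i / sum_j rate_j

so each sample's abundances sum to one million. Doubling every count
changes nothing (scale invariance); all-zero samples are flagged and
left missing.

Each non-reference allele is compared with the reference allele
(DQB1\*06:02 by default) by a two-sided Wilcoxon rank-sum test, pooling
one observation per carrying sample; alleles seen in fewer than two
samples are flagged untested. Ties use the normal approximation with
continuity/tie correction, with the exact method for groups under 10.

Group comparisons (cases vs controls) aggregate **per sample first** —
a sample's non-reference abundance is the sum over its non-reference
alleles — and then run a two-sample *t*-test on the per-sample
aggregates. The unit of analysis matters: pooling allele observations
across samples would pseudo-replicate multi-allele samples. The
aggregation unit is recorded in the output, because the convention is
not externally standardized. The sublineage selectors (DQB1\*03/\*04
vs \*05/\*06, assigned by the two-digit family after the `*`) always
exclude the reference allele, so the \*05/\*06 comparison is not
trivially dominated by the reference allele's high expression.

## What the synthetic generator emulates

The generator's defaults *are* the stated study world:

* 42 cases / 42 controls; every case a DQB1\*06:02 carrier, 8 of 42
  controls carriers.
* β noise: Beta(μκ, (1−μ)κ) with κ = 250, giving per-probe SDs of
  ≈0.02–0.04 at mid-range μ — the regime in which planted shifts of
  0.02–0.05 are detectable at n = 42/group. Baseline μ is bimodal
  (mostly low- or high-methylated probes), as on real arrays.
* Effect mechanisms: `direct` shifts the case mean by δ (defaults
  −0.02…−0.05, hypomethylation in cases); `carrier_mediated` shifts
  carriers' mean by δ (default +0.18, the magnitude of a strongly
  carrier-driven CpG) regardless of case status. The latter is the
  signature the adjustment stage exists to catch: significant
  unadjusted, null case term after adjustment, highly significant
  carrier term.
* SNP panel: planted SNPs at exact offsets from chosen probes (with
  their expected category recorded in the ground-truth ledger) plus
  background SNPs with MAF from a half-rare/half-common log-uniform
  mixture spanning 0.001–0.5. Half the emitted VCF `AF` values are
  encoded as major-allele frequencies to exercise folding.
* Expression: each sample carries two DQB1 alleles consistent with its
  carrier status; counts are negative-binomial (size 20, ≈25% CV)
  around depth × copies × relative expression × length/1 kb, with the
  reference allele distinctly high-expressed. Two background HLA genes
  (never targeted by the case multiplier) are included so the
  per-million standardization runs over a whole typed repertoire — with
  DQB1 alone, a non-carrier's non-reference share would be pinned at
  exactly 10^6 and group tests would degenerate.

### The null-calibration world

With the study's carrier imbalance (42/42 vs 8/42), the per-million
normalization makes the non-reference aggregate differ between groups
*even with no planted effect*: carriers' non-reference shares are
suppressed by the highly expressed reference allele. That difference is
a real compositional signal, not a false positive, so it cannot be used
to check type-I error. The null-calibration tests therefore equalize
carrier counts between groups (8 and 8), making the groups exchangeable
under a multiplier of 1.0; only then is a 5% rejection rate at α = 0.05
the correct expectation. The power tests keep the study's own carrier
structure.

### What a green test does and does not establish

The generator reproduces the *statistical structure* of the study —
group sizes, carrier imbalance, effect magnitudes, MAF spectrum, one
dominant reference allele — not its content. Probes are placed
uniformly (no CpG-island clustering), SNPs carry no linkage
disequilibrium, β values are Beta-distributed without array batch
structure, and the manifest is not the real one. Green tests establish
that the classifier matches the published window table exactly, that
the statistics are calibrated and powered in the stated regime, and
that the pipeline is deterministic — they do not reproduce any
published headline count (e.g. numbers of unreliable probes or of
Bonferroni-significant DMPs), which depend on the real panel, manifest
and cohort.

## Numerical and implementation choices

* All coordinates are 1-based inclusive; "chr6" and "6" are unified by
  prefix stripping before any join.
* The per-probe audit uses a binary search over the position-sorted
  panel (O(log n + hits) per probe).
* OLS is fitted per probe via `lm.fit` with standard errors from the
  Cholesky inverse of X′X; the vectorized t-test reproduces
  `stats::t.test` to 1e−12 (tested).
* Results tables are written with deterministic row order (P value,
  ties broken by probe ID) and 6 significant digits; write-then-read
  round-trips exactly at that precision.
* All randomness descends from one master seed through per-stage
  derived seeds, so regenerating any single stage never perturbs
  another; outputs contain no timestamps, making reruns byte-identical.

## Limitations

* The audit considers substitutions only; indels and structural
  variants in the probe footprint are out of scope.
* Type I probes are audited once per manifest entry; the M/U bead pair
  is not modelled separately (the window table is defined per assay
  type, not per bead).
* Family-wise control is Bonferroni only; no FDR alternatives.
* The expression stage consumes typed per-allele counts; HLA typing and
  read alignment are upstream concerns.
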