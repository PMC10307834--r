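#' Read an array manifest table
#'
#' Parses a tab-delimited manifest of probe records in the style of the
#' Infinium EPIC annotation file. The binding position is the genomic
#' coordinate of the target CpG cytosine for forward-strand probes and of
#' the adjacent guanine for reverse-strand probes (1-based). Column names
#' are configurable via `col_map` because manifest dialects vary.
#'
#' @param path path to a TSV file with a header row.
#' @param col_map named character vector mapping the canonical names
#'   `probe_id`, `chromosome`, `binding_pos`, `strand`, `design_type`
#'   (and optionally `gene`, `feature`) to the file's column names.
#' @return data.frame of probe records with normalized chromosomes,
#'   integer `binding_pos`, and `strand`/`design_type` validated against
#'   \{F, R\} and \{I, II\}.
#' @export
read_manifest <- function(path,
                          col_map = c(probe_id = "probe_id",
                                      chromosome = "chromosome",
                                      binding_pos = "binding_pos",
                                      strand = "strand",
                                      design_type = "design_type",
                                      gene = "gene",
                                      feature = "feature")) {
  if (!file.exists(path)) data_error(sprintf("manifest file not found: %s", path))
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE)
  required <- c("probe_id", "chromosome", "binding_pos", "strand", "design_type")
  missing_map <- setdiff(required, names(col_map))
  if (length(missing_map))
    config_error(sprintf("col_map lacks entries for: %s",
                         paste(missing_map, collapse = ", ")))
  missing_col <- setdiff(unname(col_map[required]), names(tab))
  if (length(missing_col))
    config_error(sprintf("manifest lacks required column(s): %s",
                         paste(missing_col, collapse = ", ")))

  out <- data.frame(
    probe_id    = tab[[col_map[["probe_id"]]]],
    chromosome  = norm_chrom(tab[[col_map[["chromosome"]]]]),
    binding_pos = suppressWarnings(as.integer(tab[[col_map[["binding_pos"]]]])),
    strand      = tab[[col_map[["strand"]]]],
    design_type = tab[[col_map[["design_type"]]]],
    stringsAsFactors = FALSE
  )
  for (opt in c("gene", "feature")) {
    cn <- if (opt %in% names(col_map)) col_map[[opt]] else opt
    out[[opt]] <- if (cn %in% names(tab)) tab[[cn]] else NA_character_
  }

  bad_pos    <- which(is.na(out$binding_pos) | out$binding_pos < 1L)
  bad_strand <- which(!out$strand %in% c("F", "R"))
  bad_design <- which(!out$design_type %in% c("I", "II"))
  bad <- sort(unique(c(bad_pos, bad_strand, bad_design)))
  if (length(bad)) {
    why <- vapply(bad, function(i) {
      parts <- c(
        if (i %in% bad_pos) sprintf("binding_pos '%s'", tab[[col_map[["binding_pos"]]]][i]),
        if (i %in% bad_strand) sprintf("strand '%s'", out$strand[i]),
        if (i %in% bad_design) sprintf("design_type '%s'", out$design_type[i])
      )
      sprintf("row %d (%s): invalid %s", i, out$probe_id[i],
              paste(parts, collapse = ", "))
    }, character(1))
    data_error(paste(c("manifest has invalid records:", why), collapse = "\n  "))
  }

  dup <- unique(out$probe_id[duplicated(out$probe_id)])
  if (length(dup))
    data_error(sprintf("manifest has duplicated probe_id(s): %s",
                       paste(dup, collapse = ", ")))
  out
}

#' Read a sample sheet
#'
#' Expects tab-delimited columns `sample_id`, `group` (case/control),
#' `dqb1_0602_carrier` (logical or 0/1), `age`, `sex`, `bmi`.
#'
#' @param path TSV path.
#' @return data.frame with `group` as factor (levels control, case) and
#'   logical `dqb1_0602_carrier`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) data_error(sprintf("sample sheet not found: %s", path))
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  required <- c("sample_id", "group", "dqb1_0602_carrier")
  missing_col <- setdiff(required, names(tab))
  if (length(missing_col))
    config_error(sprintf("sample sheet lacks column(s): %s",
                         paste(missing_col, collapse = ", ")))
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id))
    data_error("sample sheet has duplicated sample_id values")
  if (!all(tab$group %in% c("case", "control")))
    data_error("sample sheet group must be 'case' or 'control'")
  tab$group <- factor(tab$group, levels = c("control", "case"))
  tab$dqb1_0602_carrier <- as.logical(tab$dqb1_0602_carrier)
  if (anyNA(tab$dqb1_0602_carrier))
    data_error("dqb1_0602_carrier must be TRUE/FALSE (or 0/1)")
  tab
}

#' Read a per-allele RNA read-count table
#'
#' Expects tab-delimited columns `sample_id`, `gene`, `allele`,
#' `read_count`, `allele_length` (nt). One row per (sample, gene, allele).
#'
#' @param path TSV path.
#' @return validated data.frame of allele counts.
#' @export
read_allele_counts <- function(path) {
  if (!file.exists(path)) data_error(sprintf("allele count file not found: %s", path))
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  required <- c("sample_id", "gene", "allele", "read_count", "allele_length")
  missing_col <- setdiff(required, names(tab))
  if (length(missing_col))
    config_error(sprintf("allele count table lacks column(s): %s",
                         paste(missing_col, collapse = ", ")))
  tab$sample_id <- as.character(tab$sample_id)
  if (any(tab$read_count < 0)) data_error("read_count must be >= 0")
  if (any(tab$allele_length <= 0)) data_error("allele_length must be > 0")
  key <- paste(tab$sample_id, tab$gene, tab$allele, sep = "\r")
  if (anyDuplicated(key))
    data_error("allele count table has duplicated (sample, gene, allele) rows")
  tab
}
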