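#' Region definitions for the extended HLA locus (GRCh37/hg19)
#'
#' Ships the three genomic intervals used throughout the package as
#' 1-based inclusive coordinates on chromosome 6:
#' \describe{
#'   \item{hla_extended}{the HLA region plus flanks, 26,000,000-35,000,000 —
#'     the analysis universe for probe auditing and DMP testing.}
#'   \item{hla_class1}{5' end of HLA-F to 5' end of HLA-B,
#'     29,691,241-31,323,369.}
#'   \item{hla_class2}{5' end of HLA-DRA to 3' end of HLA-DPB2,
#'     32,407,619-33,086,926.}
#' }
#'
#' @param name optional region name; when given, returns that single
#'   region as a one-row data.frame.
#' @return data.frame with columns `name`, `chromosome`, `start`, `end`.
#' @export
#' @examples
#' hla_regions()
#' hla_regions("hla_class2")
hla_regions <- function(name = NULL) {
  regions <- data.frame(
    name       = c("hla_extended", "hla_class1", "hla_class2"),
    chromosome = c("6", "6", "6"),
    start      = c(26000000L, 29691241L, 32407619L),
    end        = c(35000000L, 31323369L, 33086926L),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) return(regions)
  hit <- regions[regions$name == name, , drop = FALSE]
  if (nrow(hit) == 0L)
    config_error(sprintf("unknown region name '%s' (known: %s)",
                         name, paste(regions$name, collapse = ", ")))
  hit
}

#' Build a region definition
#'
#' @param name region label.
#' @param chromosome chromosome name (normalized internally).
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return one-row data.frame region definition.
#' @export
region_definition <- function(name, chromosome, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    config_error(sprintf("invalid region '%s': need 1 <= start <= end", name))
  data.frame(name = name, chromosome = norm_chrom(chromosome),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Parse a region given as a name or "chrom:start-end" string
#'
#' Accepts either a named region from [hla_regions()] or a coordinate
#' string such as `"6:26000000-35000000"` (commas tolerated).
#'
#' @param spec character scalar.
#' @return one-row region data.frame.
#' @export
parse_region <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  if (spec %in% hla_regions()$name) return(hla_regions(spec))
  m <- regmatches(spec, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", spec))[[1]]
  if (length(m) != 4L)
    config_error(sprintf("cannot parse region '%s' (use a name or chrom:start-end)", spec))
  region_definition(spec, m[2],
                    as.integer(gsub(",", "", m[3])),
                    as.integer(gsub(",", "", m[4])))
}
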