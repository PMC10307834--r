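#' Normalize chromosome names
#'
#' Manifest and VCF dialects disagree on the `"chr"` prefix ("chr6" vs "6").
#' All joins in the package go through this stripping rule so the two
#' dialects compare equal.
#'
#' @param x character vector of chromosome names.
#' @return character vector without the `"chr"`/`"Chr"` prefix.
#' @export
#' @examples
#' norm_chrom(c("chr6", "6", "Chr6"))
norm_chrom <- function(x) {
  sub("^[Cc]hr", "", as.character(x))
}

#' Derive a stage-specific random seed from a master seed
#'
#' All randomness in a pipeline run flows from one top-level seed; each
#' stage derives its own seed deterministically so that re-ordering or
#' re-running stages never changes another stage's stream. Results stay
#' within the 32-bit signed integer range R requires.
#'
#' @param seed master seed (single integer).
#' @param stage character stage label, e.g. `"manifest"`.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(as.integer(charToRaw(as.character(stage))) *
             seq_along(charToRaw(as.character(stage))))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483563) + 1L
}

# internal: stop with a classed condition so the CLI can map errors to
# exit codes (config vs data errors)
config_error <- function(msg) {
  stop(structure(class = c("hlameth_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

data_error <- function(msg) {
  stop(structure(class = c("hlameth_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
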