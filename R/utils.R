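#' Round half away from zero
#'
#' Ratios and percentages in reports are rounded half-up (0.005 -> 0.01),
#' unlike [round()]'s round-half-even, so printed values match the usual
#' hand-calculated convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.335, 2) # 2.34, where round() gives 2.33 or 2.34 by FP luck
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# nucleotide sets used throughout; '-' is alignment gap, 'N' missing
NUCS <- c("A", "C", "G", "T")

is_called <- function(x) x %in% NUCS

#' Derive an independent per-locus seed from a root seed
#'
#' Simulation streams are derived from one root seed and the locus (or
#' replicate) index, so locus `i` is reproducible regardless of how many
#' loci are generated around it.
#'
#' @param root_seed integer root seed.
#' @param index locus or replicate index.
#' @return an integer seed below 2^31.
#' @export
locus_seed <- function(root_seed, index) {
  as.integer((as.numeric(root_seed) + 1000003 * as.numeric(index)) %% 2147483629)
}

# key for an accession set, used to group columns by identical carrier sets
set_key <- function(ids) paste(sort(ids), collapse = ",")

transition_pairs <- c(A = "G", G = "A", C = "T", T = "C")

is_transition <- function(from, to) {
  unname(transition_pairs[from] == to)
}
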