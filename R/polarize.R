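#' Polarize a biallelic site against the outgroup
#'
#' Orientation of a substitution between a focal allele class (the rare,
#' intermediate or minor side) and the rest: when the outgroup carries the
#' other allele, the mutation is new on the focal side (`derived_in_focus`);
#' when the outgroup carries the focal allele, the mutation occurred on the
#' other lineage (`ancient`); when the outgroup is missing, gapped, or
#' carries a third state, the direction cannot be read and the site is
#' `excluded`.
#'
#' @param focus_allele,other_allele the two alleles at the site (vectors
#'   recycle).
#' @param outgroup_state aligned outgroup base, `"-"`, or `NA`.
#' @return character vector in `{"derived_in_focus","ancient","excluded"}`.
#' @export
#' @examples
#' polarize_site("T", "C", "C") # derived_in_focus
#' polarize_site("T", "C", "G") # excluded
polarize_site <- function(focus_allele, other_allele, outgroup_state) {
  if (any(focus_allele == other_allele, na.rm = TRUE)) {
    abort("focus and other allele must differ", class = "rarehap_bad_input")
  }
  out <- rep("excluded", length(focus_allele))
  og <- ifelse(is.na(outgroup_state) | !(outgroup_state %in% NUCS),
               NA_character_, outgroup_state)
  out[!is.na(og) & og == other_allele] <- "derived_in_focus"
  out[!is.na(og) & og == focus_allele] <- "ancient"
  out
}

#' Derived/ancient/excluded tallies with relative rate
#'
#' @param derived,ancient,excluded counts.
#' @param label category label.
#' @return one-row tibble of class `rarehap_polarized`: counts, `total` and
#'   `ratio` (derived/ancient to 2 decimals, half-up; `NA` when ancient = 0).
#' @export
polarized_counts <- function(derived, ancient, excluded = 0, label = NA_character_) {
  stopifnot(derived >= 0, ancient >= 0, excluded >= 0)
  out <- tibble(
    label = label, derived = as.integer(derived),
    ancient = as.integer(ancient), excluded = as.integer(excluded),
    total = as.integer(derived + ancient + excluded),
    ratio = relative_rate(derived, ancient)
  )
  class(out) <- c("rarehap_polarized", class(out))
  out
}

#' Relative rate of derived to ancient mutations
#'
#' The relative evolutionary speed of the focal allele class: a value above 1
#' means the focal (e.g. rare) allele accumulated more new mutations than the
#' major allele did.  Reported half-up at `decimals` places to match usual
#' printed precision; `NA` (not an error) when there are no ancient
#' mutations.
#'
#' @param derived,ancient counts (vectors recycle).
#' @param decimals decimal places (default 2).
#' @return numeric vector.
#' @export
#' @examples
#' relative_rate(1497, 1052) # 1.42
#' relative_rate(182, 78)    # 2.33
relative_rate <- function(derived, ancient, decimals = 2) {
  ifelse(ancient > 0, round_half_up(derived / ancient, decimals), NA_real_)
}

#' Relative rate by focal-allele frequency bin
#'
#' Bins polarized SNPs by the frequency of their focal (minor or
#' haplotype-group) allele and reports per-bin derived/ancient counts and
#' the relative rate.  Under neutrality the odds that the minor allele is
#' the new mutation fall as its frequency rises, so the per-bin ratio
#' decays across bins.
#'
#' @param snps SNP tibble from [classify_snps()] (needs `freq` and
#'   `polarization`).
#' @param n_bins number of equal bins on (0,1) (default 10).
#' @return tibble of class `rarehap_ratefreq`: `bin`, `bin_low`, `bin_high`,
#'   `derived`, `ancient`, `ratio` (`NA` where ancient = 0).
#' @export
rate_by_frequency <- function(snps, n_bins = 10) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  pol <- snps[snps$polarization != "excluded", , drop = FALSE]
  idx <- pmin(findInterval(pol$freq, edges, left.open = FALSE), n_bins)
  out <- tibble(
    bin = seq_len(n_bins),
    bin_low = edges[-length(edges)],
    bin_high = edges[-1],
    derived = map_int(seq_len(n_bins), function(b) {
      sum(idx == b & pol$polarization == "derived_in_focus")
    }),
    ancient = map_int(seq_len(n_bins), function(b) {
      sum(idx == b & pol$polarization == "ancient")
    })
  ) |>
    mutate(ratio = relative_rate(.data$derived, .data$ancient))
  class(out) <- c("rarehap_ratefreq", class(out))
  out
}

#' Substitution-rate ratio between indel and non-indel loci
#'
#' Compares substitutions per aligned bp at loci carrying at least one indel
#' event with the same rate at indel-free loci.
#'
#' @param locus_summary tibble with one row per locus and columns
#'   `n_substitutions`, `length_bp` and `has_indel` (logical).
#' @return the ratio (indel-locus rate / non-indel-locus rate), or `NA` if
#'   either class is empty or the non-indel rate is zero.
#' @export
indel_vs_nonindel_rate <- function(locus_summary) {
  a <- locus_summary[locus_summary$has_indel, , drop = FALSE]
  b <- locus_summary[!locus_summary$has_indel, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) return(NA_real_)
  rate_a <- sum(a$n_substitutions) / sum(a$length_bp)
  rate_b <- sum(b$n_substitutions) / sum(b$length_bp)
  if (rate_b == 0) return(NA_real_)
  rate_a / rate_b
}
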