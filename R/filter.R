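#' Identity between the outgroup and the locus consensus
#'
#' Computed over columns where both the alignment's majority-consensus base
#' and the outgroup are called (`A/C/G/T`); gap and `N` columns are skipped.
#' The consensus rather than any single accession is used so the measure does
#' not privilege one accession.
#'
#' @param locus a [locus_alignment()] with an outgroup.
#' @return fraction of compared columns that match, or `NA` if none compare.
#' @export
outgroup_identity <- function(locus) {
  if (is.null(locus$outgroup)) return(NA_real_)
  st <- site_table(locus)
  ok <- !is.na(st$major_allele) & st$outgroup_state %in% NUCS
  if (!any(ok)) return(NA_real_)
  mean(st$major_allele[ok] == st$outgroup_state[ok])
}

#' Filter loci by accession count, length and outgroup identity
#'
#' Mirrors the standard locus-quality screen for multi-accession resequencing
#' panels: a locus is dropped when it has fewer than `min_accessions`
#' accessions, is shorter than `min_length` aligned bp, or (when an identity
#' threshold is requested) its outgroup identity is below
#' `min_outgroup_identity` — identity exactly at the threshold is kept.
#' Rules are tested in that order and the first failure is reported.
#'
#' @param loci list of [locus_alignment()] objects.
#' @param min_accessions minimum number of accessions (default 60).
#' @param min_length minimum alignment length in bp (default 400).
#' @param min_outgroup_identity minimum outgroup/consensus identity
#'   (default 0.85); `NULL` disables the identity rule.
#' @return list with `kept` (list of loci) and `report` (tibble
#'   `locus_id`, `kept`, `reason`; reason is `NA` for kept loci, otherwise
#'   one of `"too-few-accessions"`, `"too-short"`, `"no-outgroup"`,
#'   `"low-identity"`).
#' @export
filter_loci <- function(loci, min_accessions = 60, min_length = 400,
                        min_outgroup_identity = 0.85) {
  stopifnot(min_accessions > 0, min_length > 0)
  reason <- map_chr(loci, function(loc) {
    if (length(loc$accessions) < min_accessions) return("too-few-accessions")
    if (nchar(loc$accessions[[1]]) < min_length) return("too-short")
    if (!is.null(min_outgroup_identity)) {
      if (is.null(loc$outgroup)) return("no-outgroup")
      ident <- outgroup_identity(loc)
      if (is.na(ident) || ident < min_outgroup_identity) return("low-identity")
    }
    NA_character_
  })
  keep <- is.na(reason)
  list(
    kept = loci[keep],
    report = tibble(
      locus_id = map_chr(loci, "locus_id"),
      kept = keep,
      reason = reason
    )
  )
}
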