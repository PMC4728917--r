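#' Extent of a rare-allele pattern into the flanking sequence
#'
#' Given an extended alignment spanning the flanks of a core locus, walks
#' outward from the core edges in windows of `window_bp` and reports how far
#' the haplotype's fixed-substitution pattern persists: the extent on each
#' side ends at the start of the first full window containing zero sites
#' fixed between the haplotype members and the complement.  If a flank runs
#' out before an empty window is seen, that side is flagged truncated.
#'
#' @param extended_locus a [locus_alignment()] spanning the flanks.
#' @param members accession ids of the haplotype group.
#' @param core_start,core_end 0-based half-open bounds of the core locus
#'   within `extended_locus`.
#' @param window_bp window size for the disappearance test (default 500).
#' @param min_side_coverage called-fraction rule for a fixed site
#'   (default 0.8, as in [identify_haplotypes()]).
#' @return one-row tibble: `locus_id`, `core_bp`, `left_bp`, `right_bp`,
#'   `total_bp`, `truncated_left`, `truncated_right`.
#' @export
rare_allele_extent <- function(extended_locus, members, core_start, core_end,
                               window_bp = 500, min_side_coverage = 0.8) {
  m <- aln_matrix(extended_locus)
  stopifnot(all(members %in% rownames(m)), core_end > core_start,
            core_end <= ncol(m))
  others <- setdiff(rownames(m), members)
  fixed_col <- map_lgl(seq_len(ncol(m)), function(j) {
    a <- m[members, j]
    b <- m[others, j]
    ac <- a[a %in% NUCS]
    bc <- b[b %in% NUCS]
    length(ac) >= min_side_coverage * length(a) &&
      length(bc) >= min_side_coverage * length(b) &&
      length(unique(ac)) == 1 && length(unique(bc)) == 1 &&
      ac[1] != bc[1]
  })
  walk <- function(edge, dir) {
    ext <- 0L
    truncated <- FALSE
    repeat {
      if (dir < 0) {
        w_end <- edge - ext
        w_start <- w_end - window_bp
        if (w_start < 0) { truncated <- w_end > 0; break }
      } else {
        w_start <- edge + ext
        w_end <- w_start + window_bp
        if (w_end > ncol(m)) { truncated <- w_start < ncol(m); break }
      }
      if (!any(fixed_col[(w_start + 1):w_end])) break
      ext <- ext + window_bp
    }
    list(ext = ext, truncated = truncated)
  }
  left <- walk(core_start, -1L)
  right <- walk(core_end, +1L)
  tibble(
    locus_id = extended_locus$locus_id,
    core_bp = core_end - core_start,
    left_bp = left$ext,
    right_bp = right$ext,
    total_bp = (core_end - core_start) + left$ext + right$ext,
    truncated_left = left$truncated,
    truncated_right = right$truncated
  )
}
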