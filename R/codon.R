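#' Codon effects of classified SNPs in annotated coding frames
#'
#' For every SNP falling inside a coding frame of the locus, determines its
#' codon position (1, 2 or 3, relative to frame offset and strand) and
#' whether substituting the focal allele into the major-allele reference
#' codon is synonymous or nonsynonymous under the standard nuclear genetic
#' code.  Sites whose reference codon overlaps a gap or uncalled consensus
#' base are dropped, as are stop-containing reference codons.
#'
#' @param snps SNP tibble from [classify_snps()] for this locus.
#' @param locus the [locus_alignment()] with a `frames` annotation.
#' @return tibble: `locus_id`, `column`, `category`, `polarization`,
#'   `derived_freq`, `codon_position`, `effect`
#'   (`synonymous`/`nonsynonymous`).
#' @export
codon_effects <- function(snps, locus) {
  empty <- tibble(locus_id = character(), column = integer(),
                  category = character(), polarization = character(),
                  derived_freq = double(), codon_position = integer(),
                  effect = character())
  if (is.null(locus$frames) || nrow(locus$frames) == 0 || nrow(snps) == 0) {
    return(empty)
  }
  st <- site_table(locus)
  consensus <- st$major_allele  # indexed by column + 1
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  for (f in seq_len(nrow(locus$frames))) {
    fr <- locus$frames[f, ]
    in_frame <- snps$column >= fr$start & snps$column < fr$end
    for (r in which(in_frame)) {
      col <- snps$column[r]
      if (fr$strand == "+") {
        off <- col - fr$start - fr$frame_offset
        if (off < 0) next
        codon_cols <- fr$start + fr$frame_offset + (off %/% 3) * 3 + 0:2
      } else {
        off <- (fr$end - 1 - col) - fr$frame_offset
        if (off < 0) next
        codon_cols <- fr$end - 1 - fr$frame_offset - (off %/% 3) * 3 - (0:2)
      }
      if (min(codon_cols) < fr$start || max(codon_cols) >= fr$end) next
      pos <- match(col, codon_cols)
      ref <- consensus[codon_cols + 1]
      if (anyNA(ref) || !all(ref %in% NUCS)) next
      alt <- ref
      alt[pos] <- snps$focus_allele[r]
      if (fr$strand == "-") {
        ref <- comp[ref]
        alt <- comp[alt]
      }
      aa_ref <- code[[paste(ref, collapse = "")]]
      aa_alt <- code[[paste(alt, collapse = "")]]
      if (aa_ref == "*") next
      rows[[length(rows) + 1]] <- tibble(
        locus_id = snps$locus_id[r], column = col,
        category = snps$category[r], polarization = snps$polarization[r],
        derived_freq = snps$derived_freq[r],
        codon_position = as.integer(pos),
        effect = if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
      )
    }
  }
  if (length(rows) == 0) empty else bind_rows(rows)
}
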