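#' Per-column site table of a locus alignment
#'
#' Decomposes an alignment into one record per column.  Gap (`-`) and `N`
#' characters in accession rows count as missing for substitution analysis;
#' indels are handled separately by [detect_indels()].
#'
#' @param locus a [locus_alignment()].
#' @return tibble with one row per column: `column` (0-based), `n_called`,
#'   per-base counts `A`,`C`,`G`,`T`, `n_alleles`, `major_allele`,
#'   `minor_allele`, `minor_count` (for biallelic columns; the "minor" allele
#'   at an exact tie is the lexicographically smaller base) and
#'   `outgroup_state` (`NA` when absent or not called).
#' @export
#' @examples
#' loc <- locus_alignment("L", c(a = "AC", b = "AT"))
#' site_table(loc)
site_table <- function(locus) {
  m <- aln_matrix(locus)
  L <- ncol(m)
  counts <- vapply(NUCS, function(b) .colSums(m == b, nrow(m), L), numeric(L))
  if (L == 1) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, NUCS))
  n_called <- as.integer(rowSums(counts))
  n_alleles <- as.integer(rowSums(counts > 0))
  # order of NUCS is lexicographic, so which.max/min resolve ties as documented
  major_i <- max.col(counts, ties.method = "first")
  major <- ifelse(n_called > 0, NUCS[major_i], NA_character_)
  minor <- rep(NA_character_, L)
  minor_count <- rep(NA_integer_, L)
  bi <- which(n_alleles == 2)
  for (j in bi) {
    present <- which(counts[j, ] > 0)
    a <- NUCS[present]
    cnt <- counts[j, present]
    k <- if (cnt[1] == cnt[2]) 1L else which.min(cnt)
    minor[j] <- a[k]
    minor_count[j] <- as.integer(cnt[k])
    major[j] <- a[if (k == 1L) 2L else 1L]
  }
  og <- rep(NA_character_, L)
  if (!is.null(locus$outgroup)) {
    og_chars <- strsplit(locus$outgroup, "", fixed = TRUE)[[1]]
    og <- ifelse(og_chars %in% c(NUCS, "-"), og_chars, NA_character_)
  }
  tibble(
    locus_id = locus$locus_id,
    column = seq_len(L) - 1L,
    n_called = n_called,
    A = as.integer(counts[, "A"]), C = as.integer(counts[, "C"]),
    G = as.integer(counts[, "G"]), T = as.integer(counts[, "T"]),
    n_alleles = n_alleles,
    major_allele = major,
    minor_allele = minor,
    minor_count = minor_count,
    outgroup_state = og
  )
}
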