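# in-code fixtures and independent oracles shared across test files

# build a locus from explicit accession strings
make_locus <- function(..., outgroup = NULL, locus_id = "T1", frames = NULL) {
  locus_alignment(locus_id, c(...), outgroup = outgroup,
                  outgroup_id = if (is.null(outgroup)) NA_character_
                                else "outgroup",
                  frames = frames)
}

# a locus of n identical sequences of given length, with optional planted
# haplotype: carriers get a private base at each of `hap_cols` (1-based)
uniform_locus <- function(n = 10, len = 30, base = "A", carriers = NULL,
                          hap_cols = integer(), outgroup = TRUE,
                          locus_id = "U1") {
  m <- matrix(base, nrow = n, ncol = len,
              dimnames = list(sprintf("acc%03d", 1:n), NULL))
  for (j in hap_cols) m[carriers, j] <- "G"
  seqs <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  og <- if (outgroup) strrep(base, len) else NULL
  locus_alignment(locus_id, seqs, outgroup = og,
                  outgroup_id = if (outgroup) "outgroup" else NA_character_)
}

# independent naive Tajima's D: direct double loop over sequence pairs on
# complete-case columns, constants written out separately from the package
oracle_tajima <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  ok <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, ok, drop = FALSE]
  n <- nrow(m)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  if (S == 0 || n < 4) return(NA_real_)
  diffs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) diffs <- diffs + sum(m[i, ] != m[j, ])
  pi <- diffs / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# brute-force haplotype search: every accession subset (minority side) with
# >= min_fixed columns fixed against its complement
oracle_subsets <- function(locus, min_fixed = 5) {
  m <- rarehap::aln_matrix(locus)
  ids <- rownames(m)
  n <- length(ids)
  found <- list()
  for (k in 1:floor(n / 2)) {
    for (sub in utils::combn(ids, k, simplify = FALSE)) {
      comp <- setdiff(ids, sub)
      nfix <- 0
      for (j in seq_len(ncol(m))) {
        a <- m[sub, j]; b <- m[comp, j]
        ac <- a[a %in% c("A", "C", "G", "T")]
        bc <- b[b %in% c("A", "C", "G", "T")]
        if (length(ac) == length(a) && length(bc) >= 0.8 * length(b) &&
            length(unique(ac)) == 1 && length(unique(bc)) == 1 &&
            ac[1] != bc[1] && length(ac) > 0 && length(bc) > 0) {
          # minority side must be the carriers of the rarer allele (or the
          # lexicographically smaller base at an exact tie)
          if (length(ac) < length(bc) ||
              (length(ac) == length(bc) && ac[1] < bc[1])) nfix <- nfix + 1
        }
      }
      if (nfix >= min_fixed) found[[length(found) + 1]] <- sort(sub)
    }
  }
  unique(lapply(found, paste, collapse = ","))
}

small_sim_config <- function(...) {
  sim_config(n_accessions = 96, n_loci = 10, locus_length = 500, ...)
}
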