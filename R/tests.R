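#' Chi-square comparison of two relative rates
#'
#' 2x2 chi-square (without continuity correction) on the derived/ancient
#' counts of two site categories, testing whether their relative rates
#' differ.
#'
#' @param derived1,ancient1 counts for the first category.
#' @param derived2,ancient2 counts for the second category.
#' @return one-row tibble: `chi2`, `df`, `p_value`.
#' @export
relative_rate_test <- function(derived1, ancient1, derived2, ancient2) {
  tab <- matrix(c(derived1, ancient1, derived2, ancient2), nrow = 2)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(chi2 = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}

#' Two-sample permutation test on per-locus values
#'
#' Tests whether the mean of `a` exceeds the mean of `b` (one-sided) by
#' permuting group labels; used for per-locus Dxy comparisons between
#' haplotype classes.
#'
#' @param a,b numeric vectors (NAs dropped).
#' @param n_perm number of permutations (default 999).
#' @return one-row tibble: `mean_a`, `mean_b`, `diff`, `p_value`.
#' @export
permutation_test <- function(a, b, n_perm = 999) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a)
  more <- map_dbl(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), na)
    mean(pool[idx]) - mean(pool[-idx])
  })
  tibble(mean_a = mean(a), mean_b = mean(b), diff = obs,
         p_value = (1 + sum(more >= obs)) / (n_perm + 1))
}
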