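#' Random occurrence model for rare-allele types per locus
#'
#' If a rare-allele type arises independently at a locus with probability
#' `F1` (the observed fraction of loci with exactly one type), the expected
#' fraction of loci with `i` types is `F1^i`.  Observed and expected counts
#' are compared by a chi-square statistic with cells of expected count < 5
#' pooled into the adjacent lower-`i` cell (degrees of freedom = pooled
#' cells − 1).
#'
#' @param observed named integer vector: names are the number of rare-allele
#'   types `i` (1, 2, ...), values the number of loci with exactly `i` types.
#' @param n_loci total number of loci.
#' @param max_i largest `i` for which an expectation is reported (default 5).
#' @return object of class `rarehap_rom`: list with `F1`, `table` (tibble
#'   `i`, `observed`, `observed_prop`, `expected_prop`, `expected_count`),
#'   `chi2`, `df`, `p_value`, `pooling` (cell labels after pooling).
#' @export
#' @examples
#' m <- random_occurrence(c(`1` = 179, `2` = 26, `3` = 10, `4` = 4, `5` = 1), 939)
#' m$table$expected_prop[2] * 100 # 3.63
random_occurrence <- function(observed, n_loci, max_i = 5) {
  i_obs <- as.integer(names(observed))
  stopifnot(!anyNA(i_obs), all(observed >= 0), n_loci >= sum(observed))
  f1_count <- if (1 %in% i_obs) observed[[which(i_obs == 1)]] else 0
  F1 <- f1_count / n_loci
  if (F1 <= 0) {
    abort("no locus with exactly one rare-allele type; model undefined",
          class = "rarehap_model_undefined")
  }
  ii <- seq_len(max(max_i, max(i_obs)))
  obs_counts <- setNames(rep(0L, length(ii)), ii)
  obs_counts[as.character(i_obs)] <- observed
  exp_prop <- F1^ii
  exp_count <- n_loci * exp_prop
  tab <- tibble(
    i = ii,
    observed = as.integer(obs_counts),
    observed_prop = as.integer(obs_counts) / n_loci,
    expected_prop = exp_prop,
    expected_count = exp_count
  )
  # pool cells with expected < 5 upward (into the previous pooled cell)
  groups <- integer(length(ii))
  g <- 0
  for (k in seq_along(ii)) {
    if (k == 1 || exp_count[k] >= 5) g <- g + 1
    groups[k] <- g
  }
  pooled_obs <- tapply(tab$observed, groups, sum)
  pooled_exp <- tapply(exp_count, groups, sum)
  chi2 <- sum((pooled_obs - pooled_exp)^2 / pooled_exp)
  df <- length(pooled_obs) - 1
  pooling <- map_chr(split(ii, groups), ~ paste(range(.x), collapse = "-"))
  structure(
    list(F1 = F1, table = tab, chi2 = chi2, df = max(df, 1),
         p_value = stats::pchisq(chi2, max(df, 1), lower.tail = FALSE),
         pooling = unname(pooling)),
    class = "rarehap_rom"
  )
}

#' @export
print.rarehap_rom <- function(x, ...) {
  cat(sprintf("Random occurrence model: F1 = %.4f, chi2 = %.2f (df %d, P = %.3g)\n",
              x$F1, x$chi2, x$df, x$p_value))
  print(x$table)
  invisible(x)
}

#' Rare-allele occurrence per accession versus the binomial expectation
#'
#' Counts, for every accession, how many rare haplotypes it belongs to
#' across loci, and compares the histogram of those counts with the
#' expectation under uniform random placement, Binomial(`n_loci`, `p_hat`)
#' with `p_hat` the overall per-accession-per-locus membership probability.
#' Accessions in the two-sided binomial tail below `alpha` are flagged as
#' outliers.
#'
#' @param haps combined haplotype tibble over all loci.
#' @param accessions character vector of all accession ids.
#' @param n_loci number of loci analysed.
#' @param alpha two-sided tail probability for flagging (default 0.01).
#' @return object of class `rarehap_occurrence`: list with `p_hat`,
#'   `per_accession` (tibble `accession`, `n_rare`, `tail_prob`, `outlier`),
#'   `histogram` (tibble `k`, `observed`, `expected`) and `chi2_p` (goodness
#'   of fit of the histogram, tail cells pooled at expected < 5).
#' @export
accession_occurrence <- function(haps, accessions, n_loci, alpha = 0.01) {
  rare <- haps[haps$klass == "rare_typeII", , drop = FALSE]
  memb <- table(factor(unlist(rare$members), levels = accessions))
  n_rare <- as.integer(memb)
  p_hat <- sum(n_rare) / (n_loci * length(accessions))
  tail_prob <- map_dbl(n_rare, function(k) {
    lo <- stats::pbinom(k, n_loci, p_hat)
    hi <- stats::pbinom(k - 1, n_loci, p_hat, lower.tail = FALSE)
    min(1, 2 * min(lo, hi))
  })
  per_acc <- tibble(accession = accessions, n_rare = n_rare,
                    tail_prob = tail_prob, outlier = tail_prob < alpha)
  kk <- 0:max(n_rare, 1)
  hist_tab <- tibble(
    k = kk,
    observed = as.integer(table(factor(n_rare, levels = kk))),
    expected = length(accessions) * dbinom(kk, n_loci, p_hat)
  )
  # chi-square with cells of expected < 5 pooled into the previous cell
  exp_c <- hist_tab$expected
  groups <- integer(length(exp_c))
  g <- 0
  for (j in seq_along(exp_c)) {
    if (j == 1 || exp_c[j] >= 5) g <- g + 1
    groups[j] <- g
  }
  po <- tapply(hist_tab$observed, groups, sum)
  pe <- tapply(exp_c, groups, sum)
  chi2_p <- if (length(po) < 2 || any(pe == 0)) NA_real_ else {
    stats::pchisq(sum((po - pe)^2 / pe), length(po) - 1, lower.tail = FALSE)
  }
  structure(
    list(p_hat = p_hat, per_accession = per_acc, histogram = hist_tab,
         chi2_p = chi2_p),
    class = "rarehap_occurrence"
  )
}

#' Tajima's D for one locus
#'
#' The standard normalized difference between mean pairwise diversity and
#' the segregating-sites estimator of the population mutation rate, computed
#' over complete-case columns only (no gaps, no missing data in any
#' accession); the outgroup is not used.  Negative values indicate an excess
#' of rare variants.
#'
#' @param locus a [locus_alignment()].
#' @return one-row tibble of class `rarehap_tajima`: `locus_id`, `n`, `S`,
#'   `pi` (mean pairwise differences) and `D` (`NA` when `S` = 0 or
#'   `n` < 4).  The internal constants (a1, a2, b1, b2, c1, c2, e1, e2) are
#'   attached as attribute `"constants"`.
#' @export
tajima_d <- function(locus) {
  m <- aln_matrix(locus)
  n <- nrow(m)
  complete <- colSums(matrix(m %in% NUCS, nrow = n)) == n
  mc <- m[, complete, drop = FALSE]
  counts <- vapply(NUCS, function(b) .colSums(mc == b, n, ncol(mc)),
                   numeric(ncol(mc)))
  if (ncol(mc) == 1) counts <- matrix(counts, nrow = 1)
  seg <- rowSums(counts > 0) > 1
  S <- sum(seg)
  npairs <- n * (n - 1) / 2
  pi <- sum((npairs - rowSums(choose(counts[seg, , drop = FALSE], 2))) / npairs)
  k <- tibble(locus_id = locus$locus_id, n = n, S = as.integer(S),
              pi = pi, D = NA_real_)
  consts <- NULL
  if (S > 0 && n >= 4) {
    i <- seq_len(n - 1)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    k$D <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
    consts <- c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
                e1 = e1, e2 = e2)
  }
  attr(k, "constants") <- consts
  class(k) <- c("rarehap_tajima", class(k))
  k
}

#' Neutral unfolded site-frequency-spectrum expectation
#'
#' Under a standard constant-size neutral model the probability that a
#' polymorphic site has `i` derived copies in a sample of `n` is
#' `(1/i) / sum_{j=1}^{n-1} 1/j`.  Per-count probabilities are aggregated
#' into equal half-open frequency bins by `i/n`.
#'
#' @param n sample size (>= 2).
#' @param n_bins number of equal bins on (0,1) (default 10).
#' @return tibble: `bin`, `bin_low`, `bin_high`, `expected_prop` (sums to 1).
#' @seealso [neutral_sfs_probs()] for the unbinned per-count probabilities.
#' @export
#' @examples
#' neutral_sfs_probs(4)$prob[1]  # 6/11
#' expected_neutral_sfs(96)
expected_neutral_sfs <- function(n, n_bins = 10) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  p <- (1 / i) / sum(1 / i)
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(findInterval(i / n, edges), n_bins)
  tibble(
    bin = seq_len(n_bins),
    bin_low = edges[-length(edges)],
    bin_high = edges[-1],
    expected_prop = map_dbl(seq_len(n_bins), ~ sum(p[idx == .x]))
  )
}

#' Per-count neutral SFS probabilities
#'
#' The unbinned form of [expected_neutral_sfs()]: the probability that a
#' polymorphic site carries `i` derived copies, `(1/i)/a_{n-1}`.
#'
#' @param n sample size (>= 2).
#' @return tibble: `i`, `freq` (= i/n), `prob`.
#' @export
neutral_sfs_probs <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  tibble(i = i, freq = i / n, prob = (1 / i) / sum(1 / i))
}

#' Frequency excess relative to the neutral expectation
#'
#' @param observed_prop,expected_prop bin proportions (vectors recycle).
#' @return `observed/expected - 1`; errors when any expected proportion is
#'   not positive.
#' @export
frequency_excess <- function(observed_prop, expected_prop) {
  if (any(expected_prop <= 0)) {
    abort("expected proportion must be positive", class = "rarehap_bad_input")
  }
  observed_prop / expected_prop - 1
}

#' Binned unfolded SFS with neutral expectation and excess
#'
#' Bins polarized SNPs by derived-allele frequency into equal half-open bins
#' and attaches the neutral expectation for sample size `n` and the
#' per-bin frequency excess.  Sites with derived frequency exactly 1 would
#' be fixed differences and do not occur among polymorphic records.
#'
#' @param snps SNP tibble from [classify_snps()] (uses `derived_freq`;
#'   unpolarized records are dropped).
#' @param n sample size for the neutral expectation.
#' @param n_bins number of bins (default 10).
#' @param by_category also return per-category rows (`gSNP`, `rSNP` =
#'   nfSNP+dSNP) in addition to `all` (default TRUE).
#' @return tibble of class `rarehap_sfs`: `category`, `bin`, `bin_low`,
#'   `bin_high`, `observed`, `observed_prop`, `expected_prop`, `excess`.
#' @export
sfs_table <- function(snps, n, n_bins = 10, by_category = TRUE) {
  expd <- expected_neutral_sfs(n, n_bins)
  pol <- snps[!is.na(snps$derived_freq), , drop = FALSE]
  edges <- seq(0, 1, length.out = n_bins + 1)
  one <- function(sub, label) {
    idx <- pmin(findInterval(sub$derived_freq, edges, left.open = FALSE),
                n_bins)
    obs <- map_int(seq_len(n_bins), ~ sum(idx == .x))
    expd |>
      mutate(category = label,
             observed = obs,
             observed_prop = if (sum(obs) > 0) obs / sum(obs) else 0,
             excess = .data$observed_prop / .data$expected_prop - 1) |>
      relocate("category")
  }
  out <- one(pol, "all")
  if (by_category) {
    out <- bind_rows(
      out,
      one(pol[pol$category == "gSNP", , drop = FALSE], "gSNP"),
      one(pol[pol$category %in% c("nfSNP", "dSNP"), , drop = FALSE], "rSNP")
    )
  }
  class(out) <- c("rarehap_sfs", class(out))
  out
}

#' Ordinary least-squares quadratic fit of binned counts
#'
#' Fits `y = c0 + c1 x + c2 x^2` by OLS and extrapolates to `x = 1`, the
#' fixation end of the frequency axis.
#'
#' @param x bin midpoints (>= 3 values).
#' @param y counts.
#' @return object of class `rarehap_quadfit`: list with `coefficients`
#'   (`c0`, `c1`, `c2`), `r` (Pearson correlation of observed and fitted),
#'   `y_at_1` (`c0 + c1 + c2`), `fitted` and `data`.
#' @export
#' @examples
#' f <- quadratic_fit(c(0.1, 0.3, 0.5, 0.7), c(10, 4, 3, 5))
#' f$y_at_1
quadratic_fit <- function(x, y) {
  if (length(x) < 3) {
    abort("need at least 3 bins for a quadratic fit",
          class = "rarehap_insufficient_data")
  }
  fit <- lm(y ~ x + I(x^2))
  cf <- unname(coef(fit))
  structure(
    list(coefficients = c(c0 = cf[1], c1 = cf[2], c2 = cf[3]),
         r = stats::cor(y, fit$fitted.values),
         y_at_1 = sum(cf),
         fitted = unname(fit$fitted.values),
         data = tibble(x = x, y = y)),
    class = "rarehap_quadfit"
  )
}

#' @export
print.rarehap_quadfit <- function(x, ...) {
  cat(sprintf("y = %.1f + %.1f x + %.1f x^2  (r = %.2f, y(1) = %.1f)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$r, x$y_at_1))
  invisible(x)
}

#' Fixation probability proxy from high- and low-frequency counts
#'
#' The ratio of high-frequency (0.9–1) to low-frequency (0–0.1) derived SNP
#' counts, as a percentage to one decimal (half-up).
#'
#' @param high_count,low_count SNP counts in the top and bottom bins.
#' @return percentage; `NA` when `low_count` is 0.
#' @export
#' @examples
#' fixation_probability(882, 1378) # 64.0
fixation_probability <- function(high_count, low_count) {
  if (low_count <= 0) return(NA_real_)
  round_half_up(100 * high_count / low_count, 1)
}

#' Mean per-site divergence of accessions to the outgroup (Dxy)
#'
#' For each chosen accession, the fraction of columns at which it differs
#' from the outgroup, over columns where both are called; the result is the
#' mean over accessions.
#'
#' @param locus a [locus_alignment()] with an outgroup.
#' @param members accession ids to average over (default: all).
#' @return one-row tibble: `locus_id`, `n_members`, `dxy`, `n_sites` (mean
#'   number of compared columns); `dxy` is `NA` when no column compares.
#' @export
dxy <- function(locus, members = NULL) {
  if (is.null(locus$outgroup)) {
    abort("dxy requires an outgroup", class = "rarehap_bad_input")
  }
  members <- members %||% names(locus$accessions)
  og <- strsplit(locus$outgroup, "", fixed = TRUE)[[1]]
  og_ok <- og %in% NUCS
  per <- map_dbl(members, function(acc) {
    s <- strsplit(locus$accessions[[acc]], "", fixed = TRUE)[[1]]
    ok <- og_ok & s %in% NUCS
    if (!any(ok)) return(NA_real_)
    mean(s[ok] != og[ok])
  })
  n_sites <- map_dbl(members, function(acc) {
    s <- strsplit(locus$accessions[[acc]], "", fixed = TRUE)[[1]]
    sum(og_ok & s %in% NUCS)
  })
  tibble(locus_id = locus$locus_id, n_members = length(members),
         dxy = if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE),
         n_sites = mean(n_sites))
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; every other substitution is a
#' transversion.  Reported to three decimals, half-up; `NA` with a warning
#' when there is no transversion.
#'
#' @param from,to nucleotide vectors of equal length (e.g. ancestral and
#'   derived states).
#' @return the ratio.
#' @export
#' @examples
#' ts_tv(c("A", "C", "A", "G"), c("G", "T", "C", "T")) # 1
ts_tv <- function(from, to) {
  ok <- from %in% NUCS & to %in% NUCS & from != to
  ts <- sum(is_transition(from[ok], to[ok]))
  tv <- sum(ok) - ts
  if (tv == 0) {
    warn("no transversions; transition/transversion ratio undefined",
         class = "rarehap_undefined_ratio")
    return(NA_real_)
  }
  round_half_up(ts / tv, 3)
}
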