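test_that("random occurrence model reproduces the power-law expectations", {
  m <- random_occurrence(c(`1` = 179, `2` = 26, `3` = 10, `4` = 4, `5` = 1),
                         939)
  expect_equal(m$F1, 179 / 939)
  expect_equal(round_half_up(100 * m$table$expected_prop[2:5], 2),
               c(3.63, 0.69, 0.13, 0.03))
  expect_true(all(diff(m$table$expected_prop) < 0))
  # hand-computed chi2 with expected-below-5 cells pooled into cell 3
  f1 <- 179 / 939
  ec <- 939 * f1^(1:5)
  pooled_obs <- c(179, 26, 10 + 4 + 1)
  pooled_exp <- c(ec[1], ec[2], sum(ec[3:5]))
  expect_equal(m$chi2, sum((pooled_obs - pooled_exp)^2 / pooled_exp))
  expect_equal(m$df, 2)
  expect_equal(random_occurrence(c(`1` = 50), 100)$table$expected_prop[2],
               0.25)
  expect_error(random_occurrence(c(`2` = 5), 100),
               class = "rarehap_model_undefined")
})

test_that("accession occurrence matches the binomial placement model", {
  # uniform random placement: calibration of the goodness-of-fit p-value
  set.seed(99)
  accs <- sprintf("acc%03d", 1:96)
  nonsig <- 0
  for (rep in 1:40) {
    n_loci <- 200
    haps <- dplyr::bind_rows(lapply(seq_len(60), function(i) {
      tibble::tibble(locus_id = paste0("L", i), klass = "rare_typeII",
                     members = list(sample(accs, sample(1:9, 1))))
    }))
    occ <- accession_occurrence(haps, accs, n_loci)
    if (is.na(occ$chi2_p) || occ$chi2_p > 0.05) nonsig <- nonsig + 1
  }
  expect_gte(nonsig / 40, 0.9)
  # degenerate: no rare alleles anywhere
  occ0 <- accession_occurrence(
    tibble::tibble(locus_id = character(), klass = character(),
                   members = list()),
    accs, 100)
  expect_equal(occ0$histogram$observed[occ0$histogram$k == 0], 96L)
  expect_equal(occ0$p_hat, 0)
})

test_that("per-accession probability matches the worked membership example", {
  # 759 memberships over 939 loci x 96 accessions -> 0.8% per accession-locus
  expect_equal(round_half_up(100 * 759 / 939 / 96, 1), 0.8)
})

test_that("tajima_d matches an independent naive implementation", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(4:10, 1)
    len <- sample(12:40, 1)
    m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE,
                       prob = c(0.85, 0.05, 0.05, 0.05)),
                nrow = n, dimnames = list(sprintf("a%02d", 1:n), NULL))
    if (rep %% 7 == 0) m[1, 1] <- "N"  # missing data path
    seqs <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
    loc <- locus_alignment("T", seqs)
    got <- tajima_d(loc)$D
    want <- oracle_tajima(seqs)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("tajima_d handles degenerate and tiny inputs", {
  expect_true(is.na(tajima_d(uniform_locus(n = 8, len = 30))$D))
  # 4 sequences, one singleton SNP: hand calculation with n = 4 constants
  loc <- make_locus(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAC")
  res <- tajima_d(loc)
  expect_equal(res$S, 1L)
  expect_equal(res$pi, 3 / 6 * 1)  # 3 of 6 pairs differ at the one site
  a1 <- 1 + 1/2 + 1/3
  expect_equal(res$D, oracle_tajima(c(a = "AAAA", b = "AAAA", c = "AAAA",
                                      d = "AAAC")))
  expect_lt(res$D, 0)  # singleton excess drives D negative
  expect_equal(sign(res$D), sign(res$pi - res$S / a1))
})

test_that("neutral SFS expectation matches closed forms and sums to one", {
  expect_equal(neutral_sfs_probs(4)$prob[1], 6 / 11)
  for (n in 2:500) {
    expect_equal(sum(neutral_sfs_probs(n)$prob), 1)
  }
  sfs96 <- expected_neutral_sfs(96)
  expect_equal(sum(sfs96$expected_prop), 1)
  a96 <- sum(1 / seq_len(95))
  expect_equal(sfs96$expected_prop[1], sum((1 / (1:9)) / a96))
})

test_that("frequency excess is observed/expected minus one", {
  expect_equal(frequency_excess(0.2, 0.1), 1.0)
  expect_equal(frequency_excess(0.15, 0.15), 0)
  expect_equal(frequency_excess(0.194, 0.019), 0.194 / 0.019 - 1)
  expect_error(frequency_excess(0.1, 0), class = "rarehap_bad_input")
  for (x in c(0.01, 0.2, 0.9)) expect_equal(frequency_excess(x, x), 0)
})

test_that("quadratic_fit recovers exact quadratics and extrapolates", {
  x <- seq(0.05, 0.95, by = 0.1)
  y <- 3 - 2 * x + 5 * x^2
  f <- quadratic_fit(x, y)
  expect_lt(max(abs(f$coefficients - c(3, -2, 5))), 1e-9)
  expect_equal(f$r, 1)
  expect_equal(f$y_at_1, 6, tolerance = 1e-9)
  expect_error(quadratic_fit(c(1, 2), c(1, 2)),
               class = "rarehap_insufficient_data")
  td <- generics::tidy(f)
  expect_equal(td$term, c("c0", "c1", "c2"))
  expect_equal(generics::glance(f)$y_at_1, f$y_at_1)
})

test_that("fixation probability and abundance ratios match hand arithmetic", {
  expect_equal(fixation_probability(882, 1378), 64.0)
  expect_equal(fixation_probability(418, 5296), 7.9)
  expect_equal(fixation_probability(7, 7), 100.0)
  expect_true(is.na(fixation_probability(3, 0)))
})

test_that("dxy counts per-site differences to the outgroup", {
  loc <- make_locus(a = strrep("A", 100),
                    outgroup = paste0(strrep("C", 5), strrep("A", 95)))
  expect_equal(dxy(loc)$dxy, 0.05)
  same <- make_locus(a = "ACGT", outgroup = "ACGT")
  expect_equal(dxy(same)$dxy, 0)
  # invariant to accession order and to all-missing columns
  loc2 <- make_locus(a = paste0("NN", strrep("A", 98)),
                     b = paste0("NN", strrep("C", 98)),
                     outgroup = paste0("NN", strrep("A", 98)))
  expect_equal(dxy(loc2)$dxy, mean(c(0, 1)))
  expect_equal(dxy(loc2, c("b", "a"))$dxy, dxy(loc2, c("a", "b"))$dxy)
})

test_that("ts/tv ratio counts transition pairs", {
  expect_equal(ts_tv(c("A", "C", "A", "G"), c("G", "T", "C", "T")), 1.000)
  expect_warning(r <- ts_tv(c("A", "C"), c("G", "T")),
                 class = "rarehap_undefined_ratio")
  expect_true(is.na(r))
  from <- c(rep("A", 1102), rep("A", 1000))
  to <- c(rep("G", 1102), rep("C", 1000))
  expect_equal(ts_tv(from, to), 1.102)
})

test_that("codon effects follow the standard genetic code", {
  # 9-codon toy gene, frame covering the whole locus, strand +
  ref <- "ATGGGAGCTAAATTTCCCGGGTACTGA"  # M G A K F P G Y *
  frames <- tibble::tibble(locus_id = "G1", start = 0L, end = 27L,
                           frame_offset = 0L, strand = "+")
  # 20 copies of ref, one accession with planted SNPs
  seqs <- setNames(rep(ref, 20), sprintf("acc%03d", 1:20))
  alt <- ref
  substr(alt, 6, 6) <- "G"   # GGA -> GGG pos3 synonymous
  substr(alt, 12, 12) <- "G" # AAA -> AAG pos3 Lys->Lys synonymous
  substr(alt, 13, 13) <- "G" # TTT -> GTT pos1 Phe->Val nonsynonymous
  substr(alt, 17, 17) <- "T" # CCC -> CTC pos2 Pro->Leu nonsynonymous
  seqs[["acc001"]] <- alt
  loc <- locus_alignment("G1", seqs, outgroup = ref, outgroup_id = "og",
                         frames = frames)
  haps <- identify_haplotypes(loc)
  snps <- classify_snps(loc, haps)
  co <- codon_effects(snps, loc)
  co <- co[order(co$column), ]
  expect_equal(co$codon_position, c(3L, 3L, 1L, 2L))
  expect_equal(co$effect, c("synonymous", "synonymous",
                            "nonsynonymous", "nonsynonymous"))
  # ATG -> ATA on the minus strand of the reverse complement is detected
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  seqs2 <- setNames(rep(rc(ref), 20), sprintf("acc%03d", 1:20))
  alt2 <- rc(alt)
  seqs2[["acc001"]] <- alt2
  frames2 <- tibble::tibble(locus_id = "G2", start = 0L, end = 27L,
                            frame_offset = 0L, strand = "-")
  loc2 <- locus_alignment("G2", seqs2, outgroup = rc(ref),
                          outgroup_id = "og", frames = frames2)
  co2 <- codon_effects(classify_snps(loc2, identify_haplotypes(loc2)), loc2)
  expect_equal(sort(co2$codon_position), sort(co$codon_position))
  expect_equal(sort(co2$effect), sort(co$effect))
})

test_that("rare-allele extent walks outward until the pattern disappears", {
  # core of 300 bp, pattern continues 800 bp into each flank of 2000 bp
  n <- 40; L <- 4300
  m <- matrix("A", nrow = n, ncol = L,
              dimnames = list(sprintf("acc%03d", 1:n), NULL))
  carriers <- sprintf("acc%03d", 1:3)
  core_start <- 2000L; core_end <- 2300L
  for (j in seq(core_start + 20, core_end - 20, by = 40)) m[carriers, j] <- "G"
  for (j in seq(core_start - 780, core_start - 30, by = 120)) m[carriers, j] <- "G"
  for (j in seq(core_end + 30, core_end + 780, by = 120)) m[carriers, j] <- "G"
  loc <- locus_alignment("E1", setNames(apply(m, 1, paste, collapse = ""),
                                        rownames(m)))
  ext <- rare_allele_extent(loc, carriers, core_start, core_end)
  expect_equal(ext$core_bp, 300L)
  expect_true(abs(ext$left_bp - 800) <= 500)
  expect_true(abs(ext$right_bp - 800) <= 500)
  expect_equal(ext$total_bp, ext$core_bp + ext$left_bp + ext$right_bp)
  expect_false(ext$truncated_left || ext$truncated_right)

  # no fixed differences in the flanks: extent equals the core
  m2 <- m
  m2[, c(1:core_start, (core_end + 1):L)] <- "A"
  loc2 <- locus_alignment("E2", setNames(apply(m2, 1, paste, collapse = ""),
                                         rownames(m2)))
  ext2 <- rare_allele_extent(loc2, carriers, core_start, core_end)
  expect_equal(ext2$left_bp, 0L)
  expect_equal(ext2$right_bp, 0L)
  expect_equal(ext2$total_bp, 300L)

  # flank shorter than one window: truncated flag
  short <- locus_alignment("E3", setNames(
    apply(m[, 1800:2400], 1, paste, collapse = ""), rownames(m)))
  ext3 <- rare_allele_extent(short, carriers, 200L, 500L)
  expect_true(ext3$truncated_left)
})

test_that("statistical comparison helpers behave sanely", {
  rt <- relative_rate_test(1497, 1052, 1275, 1166)
  expect_equal(rt$df, 1)
  expect_lt(rt$p_value, 0.01)
  set.seed(5)
  pt <- permutation_test(rnorm(40, 1), rnorm(40, 0))
  expect_lt(pt$p_value, 0.05)
  pt0 <- permutation_test(rnorm(40), rnorm(40))
  expect_gt(pt0$p_value, 0.001)
})
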