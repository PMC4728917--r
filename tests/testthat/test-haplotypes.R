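test_that("carrier partitions group columns by identical carrier sets", {
  loc <- uniform_locus(n = 10, len = 30, carriers = c("acc001", "acc002"),
                       hap_cols = c(3, 9, 21))
  parts <- carrier_partitions(site_table(loc), loc)
  expect_equal(nrow(parts), 1)
  expect_equal(parts$carriers[[1]], c("acc001", "acc002"))
  expect_equal(parts$columns[[1]], c(2L, 8L, 20L))
})

test_that("columns with three alleles never enter a partition", {
  loc <- make_locus(a = "AAAA", b = "ACAA", c = "AGAA", d = "AAAA")
  parts <- carrier_partitions(site_table(loc), loc)
  expect_equal(nrow(parts), 0)
})

test_that("an implanted haplotype plus singleton noise is recovered exactly", {
  cfg <- small_sim_config()
  sim <- simulate_structured_locus(cfg, 21, rare_spec = list(c(8, 6)))
  parts <- carrier_partitions(site_table(sim$locus), sim$locus)
  truth_key <- paste(sim$hap_truth$carriers[[1]], collapse = ",")
  hit <- parts[vapply(parts$carriers, paste, "", collapse = ",") == truth_key, ,
               drop = FALSE]
  expect_equal(nrow(hit), 1)
  expect_gte(hit$n_columns[1], 6)  # implanted sites (+ any lucky background)
  expect_true(all(sim$hap_truth$columns[[1]] %in% hit$columns[[1]]))
})

test_that("identify_haplotypes recovers implants and labels frequencies", {
  loc <- uniform_locus(n = 96, len = 500,
                       carriers = sprintf("acc%03d", 1:5),
                       hap_cols = seq(10, 70, by = 10))
  haps <- identify_haplotypes(loc)
  expect_equal(haps$klass, c("rare_typeII", "major"))
  expect_equal(haps$n_supporting[1], 7)
  expect_equal(haps$freq[1], 5 / 96)

  # scattered singletons only: a dSNP locus
  m_cols <- c(5, 15, 25)
  loc2 <- uniform_locus(n = 96, len = 500)
  seqs <- strsplit(unname(loc2$accessions), "")
  for (k in seq_along(m_cols)) seqs[[k]][m_cols[k]] <- "T"
  loc2 <- locus_alignment("D1", setNames(
    vapply(seqs, paste, "", collapse = ""), names(loc2$accessions)))
  expect_equal(identify_haplotypes(loc2)$klass, "major")
})

test_that("rare and intermediate blocks coexist at a complex locus", {
  loc <- uniform_locus(n = 96, len = 500,
                       carriers = sprintf("acc%03d", 1:6),
                       hap_cols = seq(10, 60, by = 10))
  m <- aln_matrix(loc)
  for (j in seq(100, 160, by = 10)) m[sprintf("acc%03d", 20:39), j] <- "T"
  loc <- locus_alignment("C1", setNames(apply(m, 1, paste, collapse = ""),
                                        rownames(m)))
  haps <- identify_haplotypes(loc)
  expect_setequal(haps$klass, c("rare_typeII", "intermediate", "major"))
  expect_equal(classify_locus(haps)$locus_type, "complex")
})

test_that("classify_locus maps group counts to locus types", {
  loc_r <- uniform_locus(n = 96, len = 500,
                         carriers = sprintf("acc%03d", 1:5),
                         hap_cols = seq(10, 60, by = 10))
  expect_equal(classify_locus(identify_haplotypes(loc_r))$locus_type,
               "gSNP_locus")
  loc_d <- uniform_locus(n = 96, len = 500)
  expect_equal(classify_locus(identify_haplotypes(loc_d))$locus_type,
               "dSNP_locus")
  bad <- identify_haplotypes(loc_d)
  bad$klass <- "rare_typeII"
  expect_error(classify_locus(bad), class = "rarehap_invariant_violation")
})

test_that("group member sets partition the called accessions", {
  cfg <- small_sim_config()
  for (s in 1:20) {
    sim <- simulate_structured_locus(
      cfg, 100 + s,
      rare_spec = if (s %% 2) list(c(5, 7)) else list(c(3, 6), c(8, 9)),
      intermediate_spec = if (s %% 3 == 0) list(c(20, 8)) else NULL)
    haps <- identify_haplotypes(sim$locus)
    members <- unlist(haps$members)
    expect_equal(sort(members), sort(names(sim$locus$accessions)))
    expect_equal(anyDuplicated(members), 0)
  }
})

test_that("brute-force subset search agrees with carrier-partition discovery", {
  set.seed(404)
  for (rep in 1:12) {
    n <- sample(5:8, 1)
    len <- sample(20:30, 1)
    m <- matrix(sample(c("A", "C"), n * len, replace = TRUE, prob = c(0.9, 0.1)),
                nrow = n, dimnames = list(sprintf("acc%03d", 1:n), NULL))
    if (rep %% 2 == 0) {  # plant a clean 3-of-n haplotype on 5+ columns
      m[, ] <- "A"
      m[1:3, sample(len, 6)] <- "C"
    }
    loc <- locus_alignment("B1", setNames(apply(m, 1, paste, collapse = ""),
                                          rownames(m)))
    parts <- carrier_partitions(site_table(loc), loc)
    mine <- sort(unlist(lapply(
      parts$carriers[parts$n_columns >= 3], paste, collapse = ",")))
    brute <- sort(unlist(oracle_subsets(loc, min_fixed = 3)))
    expect_identical(mine, brute)
  }
})

test_that("raising min_fixed never increases the number of groups", {
  cfg <- small_sim_config()
  for (s in 1:8) {
    sim <- simulate_structured_locus(cfg, 300 + s, rare_spec = list(c(6, 8)))
    counts <- vapply(c(1, 3, 5, 8), function(k) {
      sum(identify_haplotypes(sim$locus, min_fixed = k)$klass != "major")
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("k >= 5 implants are always found and k = 4 never is", {
  cfg <- small_sim_config(theta_per_site = 0)  # no conflicting noise
  for (s in 1:10) {
    k <- if (s %% 2) 5 else 9
    sim <- simulate_structured_locus(cfg, 500 + s, rare_spec = list(c(6, k)))
    haps <- identify_haplotypes(sim$locus, min_fixed = 5)
    rare <- haps[haps$klass == "rare_typeII", ]
    expect_equal(nrow(rare), 1)
    expect_identical(sort(rare$members[[1]]), sim$hap_truth$carriers[[1]])
  }
  for (s in 1:10) {
    sim <- simulate_structured_locus(cfg, 600 + s, rare_spec = list(c(6, 4)))
    haps <- identify_haplotypes(sim$locus, min_fixed = 5)
    expect_equal(haps$klass, "major")
  }
})

test_that("classify_snps separates gSNPs from dispersed SNPs", {
  # rare haplotype on 6 columns plus one singleton elsewhere
  loc <- uniform_locus(n = 96, len = 500,
                       carriers = sprintf("acc%03d", 1:5),
                       hap_cols = seq(10, 60, by = 10))
  m <- aln_matrix(loc)
  m["acc050", 200] <- "T"
  loc <- locus_alignment("S1", setNames(apply(m, 1, paste, collapse = ""),
                                        rownames(m)),
                         outgroup = strrep("A", 500),
                         outgroup_id = "outgroup")
  haps <- identify_haplotypes(loc)
  snps <- classify_snps(loc, haps)
  expect_equal(sum(snps$category == "gSNP"), 6)
  expect_equal(sum(snps$category == "nfSNP"), 1)
  expect_equal(snps$freq_class[snps$category == "nfSNP"], "lt10")
  expect_true(all(snps$rare_typeI[snps$category == "nfSNP"]))
  # gSNPs supporting a rare group are never type I
  expect_false(any(snps$rare_typeI[snps$category == "gSNP"]))
  # all planted mutations are derived relative to the all-A outgroup
  expect_true(all(snps$polarization == "derived_in_focus"))

  # singleton at a locus with no haplotype is a dSNP
  locd <- uniform_locus(n = 96, len = 500)
  md <- aln_matrix(locd)
  md["acc007", 100] <- "T"
  locd <- locus_alignment("S2", setNames(apply(md, 1, paste, collapse = ""),
                                         rownames(md)),
                          outgroup = strrep("A", 500),
                          outgroup_id = "outgroup")
  snpd <- classify_snps(locd, identify_haplotypes(locd))
  expect_equal(snpd$category, "dSNP")
  expect_true(snpd$rare_typeI)
})

test_that("category counts match the generator ledger on structured data", {
  cfg <- small_sim_config()
  sim <- simulate_structured_locus(cfg, 909, rare_spec = list(c(7, 10)))
  haps <- identify_haplotypes(sim$locus)
  snps <- classify_snps(sim$locus, haps)
  implant_cols <- sim$hap_truth$columns[[1]]
  gsnp_cols <- snps$column[snps$category == "gSNP"]
  expect_true(all(implant_cols %in% gsnp_cols))
  # background singleton/low-frequency mutations are nfSNPs here
  bg <- sim$ledger[sim$ledger$lineage == "background", ]
  bg_cols <- bg$column[vapply(bg$carriers, length, 1L) < 48]
  expect_true(all(setdiff(bg_cols, gsnp_cols) %in%
                    snps$column[snps$category == "nfSNP"]))
})

test_that("mutation summary table satisfies its conservation identities", {
  cfg <- small_sim_config()
  out <- lapply(1:15, function(s) {
    sim <- simulate_structured_locus(
      cfg, 700 + s,
      rare_spec = if (s %% 3 == 0) list(c(5, 8)) else NULL,
      intermediate_spec = if (s %% 4 == 0) list(c(15, 7)) else NULL,
      locus_id = paste0("L", s))
    haps <- identify_haplotypes(sim$locus)
    list(haps = haps, cls = classify_locus(haps),
         snps = classify_snps(sim$locus, haps))
  })
  haps <- dplyr::bind_rows(lapply(out, `[[`, "haps"))
  cls <- dplyr::bind_rows(lapply(out, `[[`, "cls"))
  snps <- dplyr::bind_rows(lapply(out, `[[`, "snps"))
  tab <- tabulate_mutations(cls, haps, snps)
  expect_equal(tab$total, tab$derived + tab$ancient + tab$excluded)
  # category rows sum to the total row
  expect_equal(tab$total[tab$item == "total"],
               sum(tab$total[tab$item %in% c("gSNP", "nfSNP", "dSNP")]))
  expect_equal(tab$loci[tab$item == "total"], nrow(cls))
  # empty input gives an all-zero table
  empty <- tabulate_mutations(cls[0, ], haps[0, ], snps[0, ])
  expect_true(all(empty$total == 0))
})
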