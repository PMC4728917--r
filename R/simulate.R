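#' Simulation configuration
#'
#' Defaults emulate the kind of panel this package analyses: 96 accessions,
#' ~500 bp loci, mean pairwise diversity ~0.44%, outgroup divergence ~5%,
#' 23.4% of loci carrying at least one implanted rare haplotype (with the
#' count of distinct rare types per such locus following the empirical
#' 179:26:10:4:1 distribution), 22.4% carrying an intermediate haplotype,
#' implanted haplotypes separated from the rest by at least 5 fixed
#' substitutions (mean ~10), and occasional indels whose flanks can carry a
#' locally elevated substitution rate.
#'
#' @param n_accessions sample size (default 96).
#' @param n_loci number of loci (default 939).
#' @param locus_length alignment length in bp (default 500).
#' @param theta_per_site population mutation rate per site; equals the
#'   expected pairwise diversity (default 0.0044).
#' @param outgroup_divergence per-site divergence of the outgroup from the
#'   sample's ancestor (default 0.05).
#' @param ts_prob probability a substitution is a transition (default 0.55).
#' @param p_rare fraction of loci given rare implants (default 0.234).
#' @param rare_type_weights relative frequencies of 1..5 distinct rare types
#'   at a rare locus (default c(179, 26, 10, 4, 1)).
#' @param rare_carriers range of carriers per rare implant (default: 1 up to
#'   just under 10% of `n_accessions`, i.e. 1:9 for 96 accessions).
#' @param rare_fixed_mean mean number of fixed sites per implant above the
#'   minimum of 5 (default 5.2, giving mean ~10.2).
#' @param p_derived_rare probability an implanted rare fixed site is a new
#'   mutation on the rare lineage rather than on the major lineage
#'   (default 0.587).
#' @param p_intermediate fraction of loci given one intermediate implant
#'   (default 0.224).
#' @param intermediate_carriers carrier range for intermediates (default:
#'   10% up to just under 50% of `n_accessions`, i.e. 10:47 for 96).
#' @param p_derived_intermediate as `p_derived_rare`, for intermediates
#'   (default 0.522).
#' @param indel_prob probability a structured locus with implants carries a
#'   fixed indel on its first implanted group (default 0.15).
#' @param indel_len_range indel length range in bp (default 2:10).
#' @param indel_p_derived probability the indel is new on the implant
#'   lineage rather than on the major lineage (default 0.7).
#' @param indel_flank_bp flank window around an indel whose substitution
#'   rate is elevated (default 1000).
#' @param indel_flank_multiplier multiplier on the substitution rate in the
#'   flank window for the indel-carrying lineage; 1 means no elevation
#'   (default 1).
#' @param outgroup_error_rate probability an outgroup base is corrupted to a
#'   random third state, exercising "excluded" polarization paths
#'   (default 0).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 96, n_loci = 939, locus_length = 500,
                       theta_per_site = 0.0044, outgroup_divergence = 0.05,
                       ts_prob = 0.55,
                       p_rare = 0.234,
                       rare_type_weights = c(179, 26, 10, 4, 1),
                       rare_carriers = NULL,
                       rare_fixed_mean = 5.2,
                       p_derived_rare = 0.587,
                       p_intermediate = 0.224,
                       intermediate_carriers = NULL,
                       p_derived_intermediate = 0.522,
                       indel_prob = 0.15,
                       indel_len_range = 2:10,
                       indel_p_derived = 0.7,
                       indel_flank_bp = 1000,
                       indel_flank_multiplier = 1,
                       outgroup_error_rate = 0) {
  cfg <- as.list(environment())
  if (is.null(cfg$rare_carriers)) {
    cfg$rare_carriers <- seq_len(max(1, ceiling(n_accessions / 10) - 1))
  }
  if (is.null(cfg$intermediate_carriers)) {
    cfg$intermediate_carriers <-
      seq(max(1, ceiling(n_accessions / 10)),
          max(2, ceiling(n_accessions / 2) - 1))
  }
  stopifnot(cfg$n_accessions >= 2, cfg$locus_length >= 1,
            cfg$theta_per_site >= 0, cfg$theta_per_site <= 1,
            cfg$outgroup_divergence >= 0, cfg$outgroup_divergence <= 1,
            max(cfg$rare_carriers) < cfg$n_accessions / 2,
            max(cfg$intermediate_carriers) < cfg$n_accessions / 2)
  structure(cfg, class = "sim_config")
}

acc_names <- function(n) sprintf("acc%03d", seq_len(n))

mutate_base <- function(base, ts_prob) {
  if (runif(1) < ts_prob) return(unname(transition_pairs[base]))
  sample(setdiff(NUCS, c(base, transition_pairs[base])), 1)
}

# Kingman coalescent on n leaves: returns branches as (leaf set, length)
coalescent_branches <- function(n) {
  sets <- as.list(seq_len(n))
  blen <- numeric(n)
  branches <- list()
  k <- n
  while (k > 1) {
    t <- rexp(1, rate = k * (k - 1) / 2)
    blen <- blen + t
    pair <- sample.int(k, 2)
    for (p in pair) {
      branches[[length(branches) + 1]] <-
        list(leaves = sets[[p]], len = blen[p])
    }
    merged <- sort(c(sets[[pair[1]]], sets[[pair[2]]]))
    sets <- c(sets[-pair], list(merged))
    blen <- c(blen[-pair], 0)
    k <- k - 1
  }
  branches
}

#' Simulate one neutral locus
#'
#' Standard neutral coalescent: a Kingman genealogy on `n_accessions`
#' leaves, mutations placed as a Poisson process on branches at rate
#' `theta_per_site/2` per site per unit coalescent time, infinite-sites
#' placement on distinct uniformly chosen columns.  The outgroup is the
#' sample's ancestral sequence mutated independently at
#' `outgroup_divergence` per site, so polarization ground truth is exact up
#' to outgroup mutations hitting polymorphic columns.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for this locus.
#' @param locus_id identifier (default `"sim"`).
#' @return list with `locus` (a [locus_alignment()]) and `ledger` (tibble of
#'   planted mutations: `column`, `carriers` list-column, `ancestral`,
#'   `derived`, `lineage = "background"`).
#' @export
simulate_neutral_locus <- function(config, seed, locus_id = "sim") {
  set.seed(seed)
  n <- config$n_accessions
  L <- config$locus_length
  ids <- acc_names(n)
  anc <- sample(NUCS, L, replace = TRUE)
  m <- matrix(rep(anc, each = n), nrow = n, dimnames = list(ids, NULL))
  branches <- coalescent_branches(n)
  n_mut <- rpois(length(branches),
                 config$theta_per_site / 2 * L * map_dbl(branches, "len"))
  total <- sum(n_mut)
  ledger <- tibble(column = integer(), carriers = list(),
                   ancestral = character(), derived = character(),
                   lineage = character())
  if (total > 0) {
    cols <- sample.int(L, min(total, L))  # infinite sites: distinct columns
    ci <- 1
    rows <- list()
    for (b in seq_along(branches)) {
      if (n_mut[b] == 0) next
      for (kk in seq_len(n_mut[b])) {
        if (ci > length(cols)) break
        j <- cols[ci]; ci <- ci + 1
        new_base <- mutate_base(anc[j], config$ts_prob)
        carriers <- ids[branches[[b]]$leaves]
        m[carriers, j] <- new_base
        rows[[length(rows) + 1]] <- tibble(
          column = j - 1L, carriers = list(carriers),
          ancestral = anc[j], derived = new_base, lineage = "background"
        )
      }
    }
    if (length(rows) > 0) ledger <- bind_rows(rows)
  }
  og <- anc
  div <- runif(L) < config$outgroup_divergence
  for (j in which(div)) og[j] <- mutate_base(og[j], config$ts_prob)
  if (config$outgroup_error_rate > 0) {
    err <- runif(L) < config$outgroup_error_rate
    for (j in which(err)) og[j] <- sample(NUCS, 1)
  }
  locus <- locus_alignment(
    locus_id, setNames(apply(m, 1, paste, collapse = ""), ids),
    outgroup = paste(og, collapse = ""), outgroup_id = "outgroup"
  )
  list(locus = locus, ledger = ledger)
}

#' Simulate a locus with implanted haplotype structure
#'
#' A neutral background (as [simulate_neutral_locus()]) plus implanted
#' distinct haplotypes: each implant assigns `n_fixed` private fixed
#' substitutions, at columns untouched by background mutation, to a chosen
#' carrier set.  A fixed site is "derived" (new mutation on the implant
#' lineage: carriers get a new base, outgroup keeps the ancestral state) or
#' "ancient" (new on the major lineage: non-carriers get the new base while
#' carriers and outgroup keep the ancestral state).  Optionally a fixed
#' indel is placed on the first implant group, and the substitution rate in
#' its flank window elevated on the indel-carrying lineage by
#' `indel_flank_multiplier`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed for this locus.
#' @param rare_spec list of `c(n_carriers, n_fixed)` pairs for rare
#'   implants; `NULL` draws from the config defaults at a rare locus.
#' @param intermediate_spec same shape for intermediate implants.
#' @param with_indel force (`TRUE`/`FALSE`) or draw (`NULL`) the indel.
#' @param locus_id identifier.
#' @return list with `locus`, `ledger` (mutations incl. implant lineages),
#'   `hap_truth` (tibble: `klass`, `carriers` list-column, `n_fixed`,
#'   `columns` list-column) and `indel_truth` (tibble or NULL).
#' @export
simulate_structured_locus <- function(config, seed, rare_spec = NULL,
                                      intermediate_spec = NULL,
                                      with_indel = NULL, locus_id = "sim") {
  base <- simulate_neutral_locus(config, seed, locus_id)
  # continue this locus's RNG stream after the background draw
  n <- config$n_accessions
  L <- config$locus_length
  ids <- acc_names(n)
  m <- aln_matrix(base$locus)
  og <- strsplit(base$locus$outgroup, "", fixed = TRUE)[[1]]
  used_cols <- unique(base$ledger$column)  # 0-based
  ledger <- base$ledger
  if (is.null(rare_spec)) rare_spec <- list()
  if (is.null(intermediate_spec)) intermediate_spec <- list()
  specs <- c(map(rare_spec, ~ list(klass = "rare_typeII", n_car = .x[1],
                                   n_fix = .x[2], p_der = config$p_derived_rare)),
             map(intermediate_spec,
                 ~ list(klass = "intermediate", n_car = .x[1], n_fix = .x[2],
                        p_der = config$p_derived_intermediate)))
  taken <- character(0)  # carriers of earlier implants stay disjoint
  hap_rows <- list()
  for (sp in specs) {
    free_acc <- setdiff(ids, taken)
    if (length(free_acc) < sp$n_car) {
      abort("implant carriers exceed available accessions",
            class = "rarehap_config_error")
    }
    carriers <- sort(sample(free_acc, sp$n_car))
    taken <- c(taken, carriers)
    free_cols <- setdiff(seq_len(L) - 1L, used_cols)
    if (length(free_cols) < sp$n_fix) {
      abort("requested fixed sites exceed available columns",
            class = "rarehap_config_error")
    }
    cols <- sort(sample(free_cols, sp$n_fix))
    used_cols <- c(used_cols, cols)
    mut_rows <- list()
    for (j in cols) {
      anc_base <- m[setdiff(ids, carriers)[1], j + 1]
      new_base <- mutate_base(anc_base, config$ts_prob)
      derived_side <- if (runif(1) < sp$p_der) "focus" else "major"
      if (derived_side == "focus") {
        m[carriers, j + 1] <- new_base
        lineage <- paste0(sp$klass, "_derived")
        derived <- new_base
      } else {
        # new mutation on the major lineage: carriers and the outgroup keep
        # the ancestral state (the outgroup may still differ where its own
        # divergence hit this column, excluding the site downstream)
        m[setdiff(ids, carriers), j + 1] <- new_base
        lineage <- paste0(sp$klass, "_ancient")
        derived <- new_base
      }
      mut_rows[[length(mut_rows) + 1]] <- tibble(
        column = j, carriers = list(carriers), ancestral = anc_base,
        derived = derived, lineage = lineage
      )
    }
    ledger <- bind_rows(ledger, bind_rows(mut_rows))
    hap_rows[[length(hap_rows) + 1]] <- tibble(
      klass = sp$klass, carriers = list(carriers),
      n_fixed = sp$n_fix, columns = list(cols)
    )
  }
  hap_truth <- if (length(hap_rows)) bind_rows(hap_rows) else
    tibble(klass = character(), carriers = list(), n_fixed = integer(),
           columns = list())
  indel_truth <- NULL
  do_indel <- with_indel %||% (length(specs) > 0 &&
                                 runif(1) < config$indel_prob)
  if (isTRUE(do_indel)) {
    len <- sample(config$indel_len_range, 1)
    # keep off the edges and off implanted/background mutation columns, so
    # the gap cannot erase a planted fixed site
    cand <- setdiff(10:(L - len - 10L),
                    unique(unlist(map(used_cols, ~ (.x - len + 1):(.x)))))
    start <- if (length(cand)) cand[sample.int(length(cand), 1)] else 10L
    span <- (start + 1):(start + len)
    if (length(hap_rows) > 0) {
      carriers <- hap_truth$carriers[[1]]
    } else {
      carriers <- sort(sample(ids, sample(config$rare_carriers, 1)))
    }
    derived_indel <- runif(1) < config$indel_p_derived
    if (derived_indel) {
      m[carriers, span] <- "-"          # gap new on the implant lineage
    } else {
      m[setdiff(ids, carriers), span] <- "-"  # gap new on the major lineage
      carriers <- setdiff(ids, carriers)
    }
    indel_truth <- tibble(start = start, end = start + len, length = len,
                          carriers = list(sort(carriers)),
                          derived = derived_indel)
    mult <- config$indel_flank_multiplier
    if (mult > 1) {
      flank <- setdiff(
        intersect(seq_len(L) - 1L,
                  (start - config$indel_flank_bp):(start + len +
                                                     config$indel_flank_bp)),
        c(used_cols, (start):(start + len - 1L))
      )
      i_n <- seq_len(n - 1)
      extra_rate <- (mult - 1) * config$theta_per_site * sum(1 / i_n)
      n_extra <- rpois(1, extra_rate * length(flank))
      if (n_extra > 0 && length(flank) > 0) {
        cols <- sample(flank, min(n_extra, length(flank)))
        non_carriers <- setdiff(ids, carriers)
        for (j in cols) {
          anc_base <- m[if (length(non_carriers)) non_carriers[1] else 1, j + 1]
          new_base <- mutate_base(anc_base, config$ts_prob)
          m[carriers, j + 1] <- new_base
          ledger <- bind_rows(ledger, tibble(
            column = j, carriers = list(sort(carriers)),
            ancestral = anc_base, derived = new_base,
            lineage = "indel_flank"
          ))
          used_cols <- c(used_cols, j)
        }
      }
    }
  }
  locus <- locus_alignment(
    locus_id, setNames(apply(m, 1, paste, collapse = ""), ids),
    outgroup = paste(og, collapse = ""), outgroup_id = "outgroup"
  )
  list(locus = locus, ledger = ledger, hap_truth = hap_truth,
       indel_truth = indel_truth)
}

draw_rare_spec <- function(config) {
  n_types <- sample(seq_along(config$rare_type_weights), 1,
                    prob = config$rare_type_weights)
  map(seq_len(n_types), function(i) {
    c(sample(config$rare_carriers, 1),
      5L + rpois(1, config$rare_fixed_mean))
  })
}

#' Simulate a full dataset of loci to disk
#'
#' Writes one aligned FASTA per locus (outgroup as the last record), a
#' tab-separated manifest readable by [read_manifest()], and ground-truth
#' ledger TSVs (`truth_loci.tsv`, `truth_haplotypes.tsv`,
#' `truth_mutations.tsv`, `truth_indels.tsv`).  Per-locus random streams are
#' derived from `seed` and the locus index, so locus `i` is identical
#' whatever `n_loci` is.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param seed root integer seed.
#' @param overwrite allow writing into a directory that already contains a
#'   manifest (default FALSE).
#' @return invisibly, a list with `manifest` (tibble) and the three truth
#'   tibbles.
#' @export
simulate_dataset <- function(config, out_dir, seed, overwrite = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.tsv")
  if (file.exists(manifest_path) && !overwrite) {
    abort(paste0("refusing to overwrite ", manifest_path),
          class = "rarehap_exists")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man_rows <- list(); loci_rows <- list(); hap_rows <- list()
  mut_rows <- list(); indel_rows <- list()
  for (i in seq_len(config$n_loci)) {
    lseed <- locus_seed(seed, i)
    set.seed(lseed)
    has_rare <- runif(1) < config$p_rare
    has_int <- runif(1) < config$p_intermediate
    rs <- if (has_rare) draw_rare_spec(config) else NULL
    ispec <- if (has_int) {
      list(c(sample(config$intermediate_carriers, 1),
             5L + rpois(1, config$rare_fixed_mean)))
    } else NULL
    lid <- sprintf("L%04d", i)
    sim <- simulate_structured_locus(config, locus_seed(lseed, 1),
                                     rare_spec = rs,
                                     intermediate_spec = ispec,
                                     locus_id = lid)
    fa <- file.path(out_dir, paste0(lid, ".fasta"))
    write_locus_alignment(sim$locus, fa)
    man_rows[[i]] <- tibble(locus_id = lid, chrom = "chr1",
                            position = i * 100000L,
                            path = paste0(lid, ".fasta"),
                            outgroup_id = "outgroup")
    loci_rows[[i]] <- tibble(
      locus_id = lid,
      n_rare = sum(sim$hap_truth$klass == "rare_typeII"),
      n_intermediate = sum(sim$hap_truth$klass == "intermediate"),
      has_indel = !is.null(sim$indel_truth),
      locus_type = if (nrow(sim$hap_truth) == 0) "dSNP_locus"
                   else if (nrow(sim$hap_truth) == 1) "gSNP_locus"
                   else "complex"
    )
    if (nrow(sim$hap_truth) > 0) {
      hap_rows[[length(hap_rows) + 1]] <- sim$hap_truth |>
        mutate(locus_id = lid,
               carriers = map_chr(.data$carriers, paste, collapse = ","),
               columns = map_chr(.data$columns, paste, collapse = ",")) |>
        relocate("locus_id")
    }
    if (nrow(sim$ledger) > 0) {
      mut_rows[[length(mut_rows) + 1]] <- sim$ledger |>
        mutate(locus_id = lid,
               carriers = map_chr(.data$carriers, paste, collapse = ",")) |>
        relocate("locus_id")
    }
    if (!is.null(sim$indel_truth)) {
      indel_rows[[length(indel_rows) + 1]] <- sim$indel_truth |>
        mutate(locus_id = lid,
               carriers = map_chr(.data$carriers, paste, collapse = ",")) |>
        relocate("locus_id")
    }
  }
  manifest <- bind_rows(man_rows)
  truth_loci <- bind_rows(loci_rows)
  truth_haps <- if (length(hap_rows)) bind_rows(hap_rows) else tibble()
  truth_muts <- if (length(mut_rows)) bind_rows(mut_rows) else tibble()
  truth_indels <- if (length(indel_rows)) bind_rows(indel_rows) else tibble()
  readr::write_tsv(manifest, manifest_path)
  readr::write_tsv(truth_loci, file.path(out_dir, "truth_loci.tsv"))
  readr::write_tsv(truth_haps, file.path(out_dir, "truth_haplotypes.tsv"))
  readr::write_tsv(truth_muts, file.path(out_dir, "truth_mutations.tsv"))
  readr::write_tsv(truth_indels, file.path(out_dir, "truth_indels.tsv"))
  invisible(list(manifest = manifest, truth_loci = truth_loci,
                 truth_haplotypes = truth_haps, truth_mutations = truth_muts,
                 truth_indels = truth_indels))
}

#' Monte-Carlo false-positive rate of the haplotype criterion under
#' neutrality
#'
#' Simulates neutral loci (no implanted structure) and reports the fraction
#' on which [identify_haplotypes()] finds a distinct haplotype of the
#' requested frequency class, with an exact binomial confidence interval.
#' The default counts rare (below-10%) haplotypes — the false-positive rate
#' for calling a *rare allele* from random samples.  Deep coalescent clades
#' routinely accumulate five substitutions on a basal branch, but those
#' subtend large (intermediate- or major-frequency) groups; a small carrier
#' set with five private substitutions is what neutrality rarely produces.
#' `klass = "any"` counts every non-major group instead.
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicate loci (>= 100).
#' @param min_fixed haplotype criterion (default 5).
#' @param seed root seed.
#' @param klass `"rare_typeII"` (default) or `"any"`.
#' @return one-row tibble: `min_fixed`, `n_reps`, `n_positive`, `rate`,
#'   `ci_low`, `ci_high` (95% exact binomial).
#' @export
null_haplotype_rate <- function(config, n_reps, min_fixed = 5, seed = 1,
                                klass = c("rare_typeII", "any")) {
  stopifnot(n_reps >= 100)
  klass <- match.arg(klass)
  pos <- 0L
  for (i in seq_len(n_reps)) {
    sim <- simulate_neutral_locus(config, locus_seed(seed, i))
    hit <- tryCatch({
      haps <- identify_haplotypes(sim$locus, min_fixed = min_fixed)
      if (klass == "any") any(haps$klass != "major")
      else any(haps$klass == "rare_typeII")
    },
    # at permissive min_fixed the whole panel can fragment into candidate
    # groups; that is certainly a (spurious) distinct-haplotype call
    rarehap_degenerate_locus = function(e) TRUE)
    if (hit) pos <- pos + 1L
  }
  ci <- binom.test(pos, n_reps)$conf.int
  tibble(min_fixed = min_fixed, n_reps = n_reps, n_positive = pos,
         rate = pos / n_reps, ci_low = ci[1], ci_high = ci[2])
}
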