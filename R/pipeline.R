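#' Run the full classify-polarize-stats pipeline
#'
#' Reads a locus manifest, filters loci, discovers haplotypes, classifies
#' and polarizes SNPs and indels, computes the locus- and dataset-level
#' statistics, and writes all report tables to `out_dir`:
#' `loci.tsv`, `haplotypes.tsv`, `snps.tsv`, `polarized.tsv`, `indels.tsv`,
#' `sfs.tsv`, `fits.tsv`, `dxy.tsv`, `occurrence.tsv`, `codon.tsv`, a
#' per-category `summary.tsv` and a `run.json` with the configuration, seed,
#' versions and per-stage counts.  All tables are also returned.  The
#' pipeline is a pure function of (input files, configuration, seed);
#' nothing is written until every locus has been processed, so a failing
#' locus (reported by id) leaves no partial output.
#'
#' @param manifest manifest tibble from [read_manifest()] or a path.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param frames optional frames tibble from [read_frames()] or a path.
#' @param min_accessions,min_length,min_identity locus filters
#'   (see [filter_loci()]).
#' @param min_fixed,rare_cutoff,intermediate_cutoff haplotype criterion and
#'   frequency classes (see [identify_haplotypes()]).
#' @param sfs_bins number of SFS bins (default 10).
#' @param seed seed for the permutation test (default 1).
#' @return invisibly, a list with elements `report` (filter report), `loci`,
#'   `haplotypes`, `snps`, `indels`, `summary`, `polarized`, `sfs`, `fits`,
#'   `dxy`, `dxy_test`, `occurrence`, `random_occurrence`, `codon`,
#'   `indel_locus_rate`, `counts`.
#' @export
run_pipeline <- function(manifest, out_dir = NULL, frames = NULL,
                         min_accessions = 60, min_length = 400,
                         min_identity = 0.85, min_fixed = 5,
                         rare_cutoff = 0.10, intermediate_cutoff = 0.50,
                         sfs_bins = 10, seed = 1) {
  stopifnot(0 < rare_cutoff, rare_cutoff < intermediate_cutoff,
            intermediate_cutoff <= 0.5)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(frames)) frames <- read_frames(frames)
  if (nrow(manifest) == 0) {
    abort("no loci in manifest", class = "rarehap_no_loci")
  }
  loci <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    fr <- if (!is.null(frames)) {
      f <- frames[frames$locus_id == row$locus_id, , drop = FALSE]
      if (nrow(f)) f else NULL
    }
    tryCatch(read_locus_alignment(row, frames = fr),
             error = function(e) {
               abort(paste0("locus ", row$locus_id, ": ",
                            conditionMessage(e)),
                     class = "rarehap_locus_error")
             })
  })
  flt <- filter_loci(loci, min_accessions, min_length, min_identity)
  kept <- flt$kept
  per <- map(kept, function(loc) {
    haps <- identify_haplotypes(loc, min_fixed, rare_cutoff,
                                intermediate_cutoff)
    cls <- classify_locus(haps)
    snps <- classify_snps(loc, haps, rare_cutoff)
    indels <- detect_indels(loc, haps)
    taj <- tajima_d(loc)
    dx <- if (!is.null(loc$outgroup)) {
      bind_rows(map(unique(haps$klass), function(k) {
        mem <- unlist(haps$members[haps$klass == k])
        dxy(loc, mem) |> mutate(klass = k) |>
          relocate("locus_id", "klass")
      }))
    }
    co <- codon_effects(snps, loc)
    list(haps = haps, cls = cls, snps = snps, indels = indels, taj = taj,
         dx = dx, co = co,
         lsum = tibble(locus_id = loc$locus_id,
                       n_substitutions = nrow(snps),
                       length_bp = length(loc),
                       has_indel = nrow(indels) > 0))
  })
  haps <- bind_rows(map(per, "haps"))
  cls <- bind_rows(map(per, "cls"))
  snps <- bind_rows(map(per, "snps"))
  indels <- bind_rows(map(per, "indels"))
  taj <- bind_rows(map(per, "taj"))
  dxy_tbl <- bind_rows(map(per, "dx"))
  codon <- bind_rows(map(per, "co"))
  locus_summary <- bind_rows(map(per, "lsum"))
  summary_tab <- tabulate_mutations(cls, haps, snps)
  n_panel <- max(map_int(kept, ~ length(.x$accessions)))
  accessions <- sort(unique(unlist(map(kept, ~ names(.x$accessions)))))
  rom <- NULL
  counts_by_type <- table(cls$n_rare[cls$n_rare > 0])
  if (length(counts_by_type) > 0 && "1" %in% names(counts_by_type)) {
    rom <- random_occurrence(
      setNames(as.integer(counts_by_type), names(counts_by_type)),
      nrow(cls))
  }
  occ <- accession_occurrence(haps, accessions, nrow(cls))
  sfs <- sfs_table(snps, n_panel, sfs_bins)
  mid <- (sfs$bin_low + sfs$bin_high) / 2
  fits <- bind_rows(map(c("gSNP", "rSNP"), function(cat) {
    sub <- sfs[sfs$category == cat, , drop = FALSE]
    if (sum(sub$observed) < 3) return(NULL)
    f <- quadratic_fit((sub$bin_low + sub$bin_high) / 2, sub$observed)
    tibble(category = cat, c0 = f$coefficients[[1]], c1 = f$coefficients[[2]],
           c2 = f$coefficients[[3]], r = f$r, y_at_1 = f$y_at_1)
  }))
  set.seed(seed)
  dxy_test <- NULL
  if (nrow(dxy_tbl) > 0) {
    nm <- dxy_tbl$dxy[dxy_tbl$klass != "major"]
    mj <- dxy_tbl$dxy[dxy_tbl$klass == "major"]
    if (length(nm) > 1 && length(mj) > 1) {
      dxy_test <- permutation_test(nm, mj)
    }
  }
  loci_tab <- cls |>
    left_join(taj |> select("locus_id", "S", "pi", tajima_D = "D"),
              by = "locus_id") |>
    left_join(locus_summary |> select("locus_id", "length_bp", "has_indel"),
              by = "locus_id")
  counts <- list(
    n_input = nrow(manifest), n_kept = length(kept),
    n_dropped = nrow(manifest) - length(kept),
    n_gsnp_loci = sum(cls$locus_type == "gSNP_locus"),
    n_dsnp_loci = sum(cls$locus_type == "dSNP_locus"),
    n_complex_loci = sum(cls$locus_type == "complex"),
    n_snps = nrow(snps), n_indels = nrow(indels)
  )
  res <- list(
    report = flt$report, loci = loci_tab, haplotypes = haps, snps = snps,
    indels = indels, summary = summary_tab,
    polarized = summary_tab |>
      select("item", "total", "derived", "ancient", "excluded", "ratio"),
    sfs = sfs, fits = fits, dxy = dxy_tbl, dxy_test = dxy_test,
    occurrence = occ, random_occurrence = rom, codon = codon,
    indel_locus_rate = indel_vs_nonindel_rate(locus_summary),
    counts = counts
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))
    w(res$loci, "loci.tsv")
    w(haps |>
        mutate(members = map_chr(.data$members, paste, collapse = ","),
               supporting = map_chr(.data$supporting, paste, collapse = ",")),
      "haplotypes.tsv")
    w(snps, "snps.tsv")
    w(res$polarized, "polarized.tsv")
    w(indels |>
        mutate(present_in = map_chr(.data$present_in, paste, collapse = ",")),
      "indels.tsv")
    w(sfs, "sfs.tsv")
    if (nrow(fits)) w(fits, "fits.tsv")
    w(dxy_tbl, "dxy.tsv")
    w(occ$per_accession, "occurrence.tsv")
    if (nrow(codon)) w(codon, "codon.tsv")
    w(summary_tab, "summary.tsv")
    jsonlite::write_json(
      list(config = list(min_accessions = min_accessions,
                         min_length = min_length,
                         min_identity = min_identity, min_fixed = min_fixed,
                         rare_cutoff = rare_cutoff,
                         intermediate_cutoff = intermediate_cutoff,
                         sfs_bins = sfs_bins),
           seed = seed,
           versions = list(
             R = paste(R.version$major, R.version$minor, sep = "."),
             rarehap = as.character(utils::packageVersion("rarehap"))),
           counts = counts),
      file.path(out_dir, "run.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}

#' Audit a pipeline report directory
#'
#' Recomputes the per-category summary from the per-row tables written by
#' [run_pipeline()] and compares it with the `summary.tsv` on disk.
#'
#' @param dir report directory.
#' @return TRUE invisibly if every number matches; otherwise a tibble of
#'   mismatching cells is returned (visibly).
#' @export
audit_report <- function(dir) {
  summary_disk <- readr::read_tsv(file.path(dir, "summary.tsv"),
                                  show_col_types = FALSE)
  snps <- readr::read_tsv(file.path(dir, "snps.tsv"), show_col_types = FALSE)
  loci <- readr::read_tsv(file.path(dir, "loci.tsv"), show_col_types = FALSE)
  haps <- readr::read_tsv(file.path(dir, "haplotypes.tsv"),
                          show_col_types = FALSE)
  haps$members <- strsplit(haps$members, ",", fixed = TRUE)
  recomputed <- tabulate_mutations(loci, haps, snps)
  cmp <- tidyr::pivot_longer(summary_disk, -"item",
                             names_to = "col", values_to = "disk") |>
    left_join(tidyr::pivot_longer(recomputed, -"item",
                                  names_to = "col", values_to = "recomputed"),
              by = c("item", "col")) |>
    filter(!(is.na(.data$disk) & is.na(.data$recomputed)),
           is.na(.data$disk) | is.na(.data$recomputed) |
             abs(.data$disk - .data$recomputed) > 1e-9)
  if (nrow(cmp) == 0) invisible(TRUE) else cmp
}
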