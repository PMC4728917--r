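#' Group polymorphic columns by identical minor-allele carrier sets
#'
#' The mechanism behind haplotype discovery: every qualifying biallelic
#' column is assigned the set of accessions carrying its minor allele (at an
#' exact 50/50 tie the lexicographically smaller base counts as "minor"), and
#' columns sharing an identical carrier set are grouped.  A column qualifies
#' when at least `min_side_coverage` of the non-carrier side is called, so a
#' modest amount of missing data cannot manufacture or destroy a perfectly
#' co-segregating set.
#'
#' @param sites a site table from [site_table()].
#' @param locus the [locus_alignment()] the sites came from.
#' @param min_side_coverage minimum called fraction of the non-carrier side
#'   (default 0.8).
#' @return tibble with one row per carrier set: `carriers` (list-column of
#'   accession ids), `n_carriers`, `columns` (list-column of 0-based column
#'   indices) and `n_columns`.
#' @export
carrier_partitions <- function(sites, locus, min_side_coverage = 0.8) {
  m <- aln_matrix(locus)
  n_acc <- nrow(m)
  bi <- sites[sites$n_alleles == 2, , drop = FALSE]
  if (nrow(bi) == 0) {
    return(tibble(carriers = list(), n_carriers = integer(),
                  columns = list(), n_columns = integer()))
  }
  keys <- character(nrow(bi))
  carrier_sets <- vector("list", nrow(bi))
  keep <- logical(nrow(bi))
  for (r in seq_len(nrow(bi))) {
    j <- bi$column[r] + 1L
    carriers <- rownames(m)[m[, j] == bi$minor_allele[r]]
    n_other <- n_acc - length(carriers)
    called_other <- bi$n_called[r] - length(carriers)
    if (n_other > 0 && called_other / n_other >= min_side_coverage) {
      keep[r] <- TRUE
      carrier_sets[[r]] <- carriers
      keys[r] <- set_key(carriers)
    }
  }
  bi <- bi[keep, , drop = FALSE]
  keys <- keys[keep]
  carrier_sets <- carrier_sets[keep]
  split_idx <- unname(split(seq_along(keys), keys))
  tibble(
    carriers = map(split_idx, ~ sort(carrier_sets[[.x[1]]])),
    n_carriers = map_int(.data$carriers, length),
    columns = map(split_idx, ~ sort(bi$column[.x])),
    n_columns = map_int(.data$columns, length)
  ) |>
    arrange(dplyr::desc(.data$n_columns), .data$n_carriers,
            map_chr(.data$carriers, set_key))
}

#' Identify distinct haplotypes at a locus
#'
#' A distinct (non-major) haplotype is a set of accessions separated from the
#' rest by at least `min_fixed` perfectly co-segregating fixed substitutions.
#' Carrier sets qualifying with fewer supporting columns than `min_fixed` are
#' left as dispersed SNPs.  Qualifying sets that overlap without nesting are
#' resolved by keeping the one with more supporting sites, then the smaller
#' member set, then lexicographic order; nested qualifying sets are both kept
#' (a complex locus), with each accession assigned to the smallest qualifying
#' set containing it.  The complement of all non-major groups is the major
#' group.  Groups are labelled by frequency over called accessions:
#' `rare_typeII` below `rare_cutoff`, `intermediate` from `rare_cutoff` up to
#' (excluding) `intermediate_cutoff`, `major` otherwise.
#'
#' @param locus a [locus_alignment()].
#' @param min_fixed minimum number of fixed substitutions defining a distinct
#'   haplotype (default 5).
#' @param rare_cutoff strict upper frequency bound of rare haplotypes
#'   (default 0.10).
#' @param intermediate_cutoff strict upper frequency bound of intermediate
#'   haplotypes (default 0.50).
#' @param min_side_coverage passed to [carrier_partitions()].
#' @return tibble with one row per haplotype group: `locus_id`, `klass`,
#'   `members` (list-column), `n_members`, `freq`, `supporting` (list-column
#'   of 0-based columns), `n_supporting`.  The major group is always present
#'   (last row) with an empty supporting set.
#' @export
identify_haplotypes <- function(locus, min_fixed = 5, rare_cutoff = 0.10,
                                intermediate_cutoff = 0.50,
                                min_side_coverage = 0.8) {
  all_acc <- names(locus$accessions)
  st <- site_table(locus)
  m <- aln_matrix(locus)
  called_acc <- all_acc[rowSums(matrix(m %in% NUCS, nrow = nrow(m))) > 0]
  n_called_acc <- length(called_acc)
  parts <- carrier_partitions(st, locus, min_side_coverage)
  cand <- parts[parts$n_columns >= min_fixed & parts$n_carriers >= 1, ,
                drop = FALSE]
  # a candidate covering at least half the panel names the wrong side:
  # the complement is the distinct minority
  if (nrow(cand) > 0) {
    flip <- cand$n_carriers / n_called_acc >= 0.5
    cand$carriers[flip] <- map(cand$carriers[flip],
                               ~ setdiff(called_acc, .x))
    cand$n_carriers <- map_int(cand$carriers, length)
    cand <- cand[cand$n_carriers >= 1, , drop = FALSE]
  }
  accepted <- list()
  if (nrow(cand) > 0) {
    ord <- order(-cand$n_columns, cand$n_carriers,
                 map_chr(cand$carriers, set_key))
    for (i in ord) {
      s <- cand$carriers[[i]]
      compatible <- all(map_lgl(accepted, function(a) {
        ov <- length(intersect(s, a$members))
        ov == 0 || ov == length(s) || ov == length(a$members)
      }))
      if (compatible) {
        accepted[[length(accepted) + 1]] <-
          list(members = s, supporting = cand$columns[[i]])
      }
    }
  }
  # nested sets: each accession belongs to the smallest accepted set holding it
  final <- map(seq_along(accepted), function(i) {
    s <- accepted[[i]]$members
    inner <- unlist(map(accepted, function(a) {
      if (length(a$members) < length(s) && all(a$members %in% s)) a$members
    }))
    list(members = setdiff(s, inner), supporting = accepted[[i]]$supporting)
  })
  final <- keep(final, ~ length(.x$members) > 0)
  non_major_members <- unlist(map(final, "members"))
  major_members <- setdiff(called_acc, non_major_members)
  if (length(major_members) == 0) {
    abort(paste0("no accession remains in the major group at locus ",
                 locus$locus_id),
          class = "rarehap_degenerate_locus")
  }
  rows <- c(final, list(list(members = major_members, supporting = integer())))
  out <- tibble(
    locus_id = locus$locus_id,
    members = map(rows, "members"),
    n_members = map_int(rows, ~ length(.x$members)),
    supporting = map(rows, ~ as.integer(.x$supporting)),
    n_supporting = map_int(rows, ~ length(.x$supporting))
  ) |>
    mutate(freq = .data$n_members / n_called_acc)
  is_major <- seq_len(nrow(out)) == nrow(out)
  out$klass <- ifelse(is_major, "major",
                      ifelse(out$freq < rare_cutoff, "rare_typeII",
                             ifelse(out$freq < intermediate_cutoff,
                                    "intermediate", "major")))
  out |>
    select("locus_id", "klass", "members", "n_members", "freq",
           "supporting", "n_supporting") |>
    arrange(.data$klass == "major", dplyr::desc(.data$n_supporting))
}

#' Classify a locus from its haplotype groups
#'
#' A locus with only the major group is a `dSNP_locus` (its SNPs are
#' dispersed), with exactly one distinct non-major haplotype a `gSNP_locus`,
#' and with two or more non-major haplotypes `complex`.
#'
#' @param haps haplotype tibble from [identify_haplotypes()].
#' @return one-row tibble: `locus_id`, `locus_type`, `n_haplotypes` (count of
#'   non-major groups), `n_rare`, `n_intermediate`.
#' @export
classify_locus <- function(haps) {
  n_major <- sum(haps$klass == "major")
  if (n_major != 1) {
    abort(sprintf("locus %s has %d major groups; exactly one required",
                  haps$locus_id[1], n_major),
          class = "rarehap_invariant_violation")
  }
  n_rare <- sum(haps$klass == "rare_typeII")
  n_int <- sum(haps$klass == "intermediate")
  n_non_major <- n_rare + n_int
  tibble(
    locus_id = haps$locus_id[1],
    locus_type = if (n_non_major == 0) "dSNP_locus"
                 else if (n_non_major == 1) "gSNP_locus" else "complex",
    n_haplotypes = n_non_major,
    n_rare = n_rare,
    n_intermediate = n_int
  )
}
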