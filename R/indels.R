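#' Detect and polarize indel events at a locus
#'
#' Maximal gap runs are merged across accessions when they occupy an
#' identical span; runs that overlap another event's span without matching
#' it (different indel sizes between haplotypes) are excluded from
#' polarization.  An event is *fixed* when its carriers are exactly the
#' member set of one haplotype group.  A fixed event is polarized by the
#' outgroup over the span: outgroup fully ungapped (it matches the
#' non-indel state) makes the gap a new mutation in the carrying group
#' (`derived`); outgroup gapped over exactly the same span makes the
#' ungapped state of the complement the new mutation (`ancient`); a
#' partially gapped or mismatching outgroup span is `excluded`.
#'
#' @param locus a [locus_alignment()].
#' @param haps haplotype tibble from [identify_haplotypes()]; computed if
#'   omitted.
#' @return tibble of class `rarehap_indels`: `locus_id`, `start`, `end`
#'   (0-based half-open), `length`, `present_in` (list-column), `n_carriers`,
#'   `carrier_klass` (haplotype class of the carrying group, `NA` if not
#'   fixed), `fixed` (logical), `polarization`
#'   (`derived`/`ancient`/`excluded`).
#' @export
detect_indels <- function(locus, haps = NULL) {
  if (is.null(haps)) haps <- identify_haplotypes(locus)
  m <- aln_matrix(locus)
  runs <- list()
  for (acc in rownames(m)) {
    r <- rle(m[acc, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    gi <- which(r$values)
    for (g in gi) {
      runs[[length(runs) + 1]] <- list(acc = acc, start = starts[g],
                                       end = ends[g])
    }
  }
  empty <- tibble(
    locus_id = character(), start = integer(), end = integer(),
    length = integer(), present_in = list(), n_carriers = integer(),
    carrier_klass = character(), fixed = logical(), polarization = character()
  )
  class(empty) <- c("rarehap_indels", class(empty))
  if (length(runs) == 0) return(empty)
  span_key <- map_chr(runs, ~ paste(.x$start, .x$end, sep = "-"))
  by_span <- unname(split(runs, span_key))
  ev <- tibble(
    locus_id = locus$locus_id,
    start = map_int(by_span, ~ as.integer(.x[[1]]$start)),
    end = map_int(by_span, ~ as.integer(.x[[1]]$end)),
    present_in = map(by_span, ~ sort(map_chr(.x, "acc")))
  ) |>
    mutate(n_carriers = lengths(.data$present_in),
           length = .data$end - .data$start)
  # events overlapping another event's span but not equal to it: unequal
  # indel sizes between haplotypes, unusable for polarization
  overlapping <- map_lgl(seq_len(nrow(ev)), function(i) {
    any(ev$start < ev$end[i] & ev$end > ev$start[i] &
          !(ev$start == ev$start[i] & ev$end == ev$end[i]))
  })
  group_keys <- setNames(haps$klass, map_chr(haps$members, set_key))
  carrier_klass <- map_chr(ev$present_in, function(p) {
    k <- group_keys[set_key(p)]
    if (is.na(k)) NA_character_ else unname(k)
  })
  og_span_state <- function(start, end) {
    if (is.null(locus$outgroup)) return("missing")
    chars <- strsplit(substr(locus$outgroup, start + 1, end), "")[[1]]
    left_gap <- start > 0 && substr(locus$outgroup, start, start) == "-"
    right_gap <- end < nchar(locus$outgroup) &&
      substr(locus$outgroup, end + 1, end + 1) == "-"
    if (all(chars %in% NUCS)) "ungapped"
    else if (all(chars == "-") && !left_gap && !right_gap) "gapped_exact"
    else "uninformative"
  }
  polarization <- rep("excluded", nrow(ev))
  fixed <- !is.na(carrier_klass) & !overlapping
  for (i in which(fixed)) {
    og <- og_span_state(ev$start[i], ev$end[i])
    polarization[i] <- switch(og,
      ungapped = "derived",
      gapped_exact = "ancient",
      "excluded"
    )
  }
  ev$carrier_klass <- carrier_klass
  ev$fixed <- fixed
  ev$polarization <- polarization
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  class(ev) <- c("rarehap_indels", class(ev))
  ev
}

#' Relative rate of new indels in rare versus major alleles
#'
#' Counts indel events whose new (non-outgroup) state arose on the rare side
#' against those that arose on the major side, over loci holding one rare
#' haplotype: a `derived` event contributes to its carrying group's side and
#' an `ancient` event to the complementary side.
#'
#' @param indels combined event tibble from [detect_indels()].
#' @param decimals decimal places for the ratio (default 2).
#' @return one-row tibble: `rare_new`, `major_new`, `ratio`.
#' @export
indel_relative_rate <- function(indels, decimals = 2) {
  pol <- indels[indels$fixed & indels$polarization != "excluded", ,
                drop = FALSE]
  rare_new <- sum(pol$carrier_klass == "rare_typeII" &
                    pol$polarization == "derived") +
    sum(pol$carrier_klass == "major" & pol$polarization == "ancient")
  major_new <- sum(pol$carrier_klass == "major" &
                     pol$polarization == "derived") +
    sum(pol$carrier_klass == "rare_typeII" & pol$polarization == "ancient")
  tibble(rare_new = rare_new, major_new = major_new,
         ratio = relative_rate(rare_new, major_new, decimals))
}
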