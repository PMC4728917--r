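#' Classify and polarize the SNPs of a locus
#'
#' Every biallelic polymorphic column becomes one record.  Columns supporting
#' a distinct haplotype are gSNPs (fixed, "grouped" substitutions); the other
#' polymorphic columns are nfSNPs at haplotype-bearing (gSNP or complex) loci
#' and dSNPs at single-haplotype loci.  Columns with three or more alleles
#' are not classified.  Each record is polarized against the outgroup with
#' the focal allele being the haplotype-group allele for gSNPs and the minor
#' allele otherwise; low-frequency (`freq < rare_cutoff`) nfSNPs and dSNPs
#' are the type I rare substitutions.
#'
#' @param locus a [locus_alignment()].
#' @param haps haplotype tibble from [identify_haplotypes()].
#' @param rare_cutoff strict frequency bound of the low-frequency class
#'   (default 0.10).
#' @return tibble with one row per classified SNP: `locus_id`, `column`,
#'   `category` (gSNP/nfSNP/dSNP), `hap_klass` (haplotype class a gSNP
#'   supports, `NA` otherwise), `minor_count`, `n_called`, `freq`,
#'   `freq_class` (`lt10`/`ge10`), `rare_typeI` (logical), `focus_allele`,
#'   `other_allele`, `outgroup_state`, `polarization`, `derived_state`,
#'   `ancestral_state`, `derived_freq`.
#' @export
classify_snps <- function(locus, haps, rare_cutoff = 0.10) {
  st <- site_table(locus)
  bi <- st[st$n_alleles == 2, , drop = FALSE]
  cls <- classify_locus(haps)
  non_major <- haps[haps$klass != "major", , drop = FALSE]
  support_of <- integer(0)
  if (nrow(non_major) > 0) {
    support_of <- setNames(
      rep(seq_len(nrow(non_major)), times = non_major$n_supporting),
      as.character(unlist(non_major$supporting))
    )
  }
  if (nrow(bi) == 0) {
    return(tibble(
      locus_id = character(), column = integer(), category = character(),
      hap_klass = character(), minor_count = integer(), n_called = integer(),
      freq = double(), freq_class = character(), rare_typeI = logical(),
      focus_allele = character(), other_allele = character(),
      outgroup_state = character(), polarization = character(),
      derived_state = character(), ancestral_state = character(),
      derived_freq = double()
    ))
  }
  gi <- support_of[as.character(bi$column)]
  category <- ifelse(!is.na(gi), "gSNP",
                     if (cls$locus_type == "dSNP_locus") "dSNP" else "nfSNP")
  hap_klass <- ifelse(!is.na(gi), non_major$klass[gi], NA_character_)
  freq <- bi$minor_count / bi$n_called
  polar <- polarize_site(bi$minor_allele, bi$major_allele, bi$outgroup_state)
  derived_state <- dplyr::case_when(
    polar == "derived_in_focus" ~ bi$minor_allele,
    polar == "ancient" ~ bi$major_allele,
    TRUE ~ NA_character_
  )
  ancestral_state <- dplyr::case_when(
    polar == "derived_in_focus" ~ bi$major_allele,
    polar == "ancient" ~ bi$minor_allele,
    TRUE ~ NA_character_
  )
  derived_freq <- dplyr::case_when(
    polar == "derived_in_focus" ~ freq,
    polar == "ancient" ~ 1 - freq,
    TRUE ~ NA_real_
  )
  tibble(
    locus_id = locus$locus_id,
    column = bi$column,
    category = category,
    hap_klass = hap_klass,
    minor_count = bi$minor_count,
    n_called = bi$n_called,
    freq = freq,
    freq_class = ifelse(freq < rare_cutoff, "lt10", "ge10"),
    rare_typeI = category %in% c("nfSNP", "dSNP") & freq < rare_cutoff,
    focus_allele = bi$minor_allele,
    other_allele = bi$major_allele,
    outgroup_state = bi$outgroup_state,
    polarization = polar,
    derived_state = derived_state,
    ancestral_state = ancestral_state,
    derived_freq = derived_freq
  )
}

#' Summary of mutation classes across loci
#'
#' Builds the per-category mutation summary over a set of classified loci:
#' for gSNPs overall and split by the haplotype class they support
#' (rare type II, intermediate), and for nfSNPs and dSNPs overall and split
#' into the low-frequency (type I rare) and intermediate-frequency classes —
#' locus counts, haplotype counts, total sites, derived and ancient counts
#' and the relative rate.
#'
#' @param classifications tibble of locus classifications
#'   (rows from [classify_locus()]).
#' @param haps haplotype tibble over all loci.
#' @param snps SNP tibble over all loci (from [classify_snps()]).
#' @return tibble with columns `item`, `loci`, `haplotypes`, `total`,
#'   `derived`, `ancient`, `excluded`, `ratio`.
#' @export
tabulate_mutations <- function(classifications, haps, snps) {
  row_for <- function(item, loci, haplos, sub) {
    tibble(
      item = item,
      loci = loci,
      haplotypes = haplos,
      total = nrow(sub),
      derived = sum(sub$polarization == "derived_in_focus"),
      ancient = sum(sub$polarization == "ancient"),
      excluded = sum(sub$polarization == "excluded"),
      ratio = relative_rate(derived, ancient)
    )
  }
  gsnp <- snps[snps$category == "gSNP", , drop = FALSE]
  nf <- snps[snps$category == "nfSNP", , drop = FALSE]
  d <- snps[snps$category == "dSNP", , drop = FALSE]
  hap_loci <- sum(classifications$locus_type %in% c("gSNP_locus", "complex"))
  bind_rows(
    row_for("gSNP", hap_loci, sum(classifications$n_haplotypes), gsnp),
    row_for("rare_typeII", sum(classifications$n_rare > 0),
            sum(classifications$n_rare),
            gsnp[!is.na(gsnp$hap_klass) & gsnp$hap_klass == "rare_typeII", ]),
    row_for("intermediate", sum(classifications$n_intermediate > 0),
            sum(classifications$n_intermediate),
            gsnp[!is.na(gsnp$hap_klass) & gsnp$hap_klass == "intermediate", ]),
    row_for("nfSNP", hap_loci, NA_integer_, nf),
    row_for("rare_typeI_nf", NA_integer_, NA_integer_, nf[nf$rare_typeI, ]),
    row_for("intermediate_nf", NA_integer_, NA_integer_, nf[!nf$rare_typeI, ]),
    row_for("dSNP", sum(classifications$locus_type == "dSNP_locus"),
            NA_integer_, d),
    row_for("rare_typeI_d", NA_integer_, NA_integer_, d[d$rare_typeI, ]),
    row_for("intermediate_d", NA_integer_, NA_integer_, d[!d$rare_typeI, ]),
    row_for("total", nrow(classifications),
            sum(classifications$n_haplotypes), snps)
  )
}
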