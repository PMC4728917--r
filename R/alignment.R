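#' Per-locus multiple alignment of accessions with an optional outgroup
#'
#' The basic unit of analysis: equal-length aligned sequences of many
#' accessions of the focal species at one locus, optionally paired with an
#' aligned outgroup sequence of the same length and with coding-frame
#' annotation.  Sequences are stored upper-case over the alphabet
#' `{A,C,G,T,-,N}`; IUPAC ambiguity codes other than `N` are mapped to `N`
#' with a warning.
#'
#' @param locus_id locus identifier.
#' @param accessions named character vector of aligned sequences (names are
#'   accession ids, all unique; all sequences the same length).
#' @param chrom chromosome identifier (optional).
#' @param position 1-based reference position of the locus (optional).
#' @param outgroup aligned outgroup sequence of the same length, or `NULL`.
#' @param outgroup_id identifier of the outgroup record, or `NA`.
#' @param frames optional tibble of coding frames with columns
#'   `start`, `end` (0-based half-open locus coordinates), `frame_offset`
#'   (0..2) and `strand` (`"+"` or `"-"`).
#'
#' @return An object of class `locus_alignment`.
#' @export
#' @examples
#' locus_alignment("L1", c(a1 = "ACGT", a2 = "ACTT"), outgroup = "ACGT")
locus_alignment <- function(locus_id, accessions, chrom = NA_character_,
                            position = NA_integer_, outgroup = NULL,
                            outgroup_id = NA_character_, frames = NULL) {
  if (length(accessions) == 0) {
    abort("locus has no accession sequences", class = "rarehap_empty_input")
  }
  if (is.null(names(accessions)) || anyNA(names(accessions)) ||
      any(names(accessions) == "")) {
    abort("accession sequences must be named", class = "rarehap_bad_input")
  }
  if (anyDuplicated(names(accessions))) {
    abort(
      paste0("duplicate accession ids: ",
             paste(unique(names(accessions)[duplicated(names(accessions))]),
                   collapse = ", ")),
      class = "rarehap_duplicate_id"
    )
  }
  accessions <- clean_seq(accessions)
  len <- unique(nchar(accessions))
  if (length(len) != 1 || len[1] < 1) {
    abort("aligned sequences must all have the same positive length",
          class = "rarehap_malformed_alignment")
  }
  if (!is.null(outgroup)) {
    outgroup <- unname(clean_seq(outgroup))
    if (nchar(outgroup) != len) {
      abort("outgroup length differs from accession alignment length",
            class = "rarehap_malformed_alignment")
    }
  }
  if (!is.null(frames)) {
    frames <- as_tibble(frames)
    stopifnot(all(c("start", "end", "frame_offset", "strand") %in% names(frames)))
  }
  structure(
    list(locus_id = as.character(locus_id), chrom = as.character(chrom),
         position = as.integer(position), accessions = accessions,
         outgroup = outgroup, outgroup_id = as.character(outgroup_id),
         frames = frames),
    class = "locus_alignment"
  )
}

# uppercase; map ambiguity codes (other than N) to N, warn once
clean_seq <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN-]", x)
  if (any(bad)) {
    warn("ambiguity codes other than N mapped to N",
         class = "rarehap_ambiguity_warning")
    x[bad] <- gsub("[^ACGTN-]", "N", x[bad])
  }
  x
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf(
    "<locus_alignment> %s (%s:%s)\n  %d accessions x %d bp; outgroup: %s; frames: %s\n",
    x$locus_id, x$chrom, x$position, length(x$accessions),
    nchar(x$accessions[[1]]),
    if (is.null(x$outgroup)) "absent" else x$outgroup_id,
    if (is.null(x$frames)) "none" else nrow(x$frames)
  ))
  invisible(x)
}

#' @export
length.locus_alignment <- function(x) nchar(x$accessions[[1]])

#' Alignment as a character matrix
#'
#' @param locus a [locus_alignment()].
#' @param include_outgroup add the outgroup as a final row named by its id.
#' @return character matrix, accessions in rows, alignment columns in columns.
#' @export
aln_matrix <- function(locus, include_outgroup = FALSE) {
  seqs <- locus$accessions
  if (include_outgroup && !is.null(locus$outgroup)) {
    og <- setNames(locus$outgroup, locus$outgroup_id %||% "outgroup")
    seqs <- c(seqs, og)
  }
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' Read one locus alignment from an aligned FASTA file
#'
#' Reads an aligned FASTA (one file per locus) and attaches the outgroup when
#' the manifest row names a record id present in the file.
#'
#' @param manifest_row a one-row data frame (or named list) with at least
#'   `locus_id` and `path`; optional `chrom`, `position`, `outgroup_id`.
#'   `path` may be given directly via `path`.
#' @param path FASTA path; overrides `manifest_row$path`.
#' @param frames optional frames tibble for this locus (see
#'   [read_frames()]).
#' @return a [locus_alignment()].
#' @export
read_locus_alignment <- function(manifest_row, path = NULL, frames = NULL) {
  path <- path %||% manifest_row$path
  fa <- Biostrings::readBStringSet(path)
  if (length(fa) == 0) {
    abort(paste0("empty FASTA: ", path), class = "rarehap_empty_input")
  }
  ids <- names(fa)
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate record ids in ", path),
          class = "rarehap_duplicate_id")
  }
  seqs <- setNames(as.character(fa), ids)
  if (length(unique(nchar(seqs))) != 1) {
    abort(paste0("unequal sequence lengths in ", path),
          class = "rarehap_malformed_alignment")
  }
  og_id <- manifest_row$outgroup_id %||% NA_character_
  outgroup <- NULL
  if (!is.na(og_id) && og_id %in% ids) {
    outgroup <- seqs[[og_id]]
    seqs <- seqs[setdiff(ids, og_id)]
  } else {
    og_id <- NA_character_
  }
  locus_alignment(
    locus_id = manifest_row$locus_id,
    chrom = manifest_row$chrom %||% NA_character_,
    position = manifest_row$position %||% NA_integer_,
    accessions = seqs, outgroup = outgroup, outgroup_id = og_id,
    frames = frames
  )
}

#' Write a locus alignment to aligned FASTA
#'
#' The outgroup, when present, is written as the last record under its id, so
#' `read_locus_alignment()` round-trips the object.
#'
#' @param locus a [locus_alignment()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_locus_alignment <- function(locus, path) {
  seqs <- locus$accessions
  if (!is.null(locus$outgroup)) {
    seqs <- c(seqs, setNames(locus$outgroup, locus$outgroup_id))
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Read a locus manifest
#'
#' Tab-separated with header `locus_id chrom position path outgroup_id`.
#' Relative alignment paths are resolved against the manifest's directory.
#'
#' @param path manifest path.
#' @return tibble with one row per locus.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         locus_id = readr::col_character(),
                         chrom = readr::col_character(),
                         position = readr::col_integer(),
                         path = readr::col_character(),
                         outgroup_id = readr::col_character()
                       ))
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Read a coding-frame annotation file
#'
#' Tab-separated with header `locus_id start end frame_offset strand`;
#' coordinates 0-based half-open, strand `+` or `-`.
#'
#' @param path frames file path.
#' @return tibble of frames.
#' @export
read_frames <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    locus_id = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer(),
                    frame_offset = readr::col_integer(),
                    strand = readr::col_character()
                  ))
}
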