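#' Construct a region annotation
#'
#' Regions are 1-based, inclusive amino-acid intervals on a protein sequence,
#' the convention used for splice-isoform coordinates (e.g. the exon-16 span
#' aa 775-1468 of a long isoform, or the RG-rich domain aa 1061-1124).
#'
#' @param start,end 1-based inclusive amino-acid positions, `end >= start >= 1`.
#' @param label Optional region label.
#' @return A one-row tibble with columns `start`, `end`, `label`.
#' @examples
#' region(775, 1468, "exon16")
#' @export
region <- function(start, end, label = NA_character_) {
  start <- vctrs_int(start, "start")
  end <- vctrs_int(end, "end")
  if (any(start < 1L)) stop("region `start` must be >= 1", call. = FALSE)
  if (any(end < start)) stop("region `end` must be >= `start`", call. = FALSE)
  tibble::tibble(start = start, end = end, label = as.character(label))
}

# strict integer coercion shared by coordinate arguments
vctrs_int <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x != trunc(x))) {
    stop("`", what, "` must be a whole number", call. = FALSE)
  }
  as.integer(x)
}

#' Length of a region in residues
#'
#' Inclusive-span arithmetic: a region `(start, end)` covers
#' `end - start + 1` residues, so aa 775-1468 is 694 residues long.
#'
#' @param region A tibble from [region()] (or any data frame with `start`,
#'   `end` columns); rows are vectorized.
#' @return Integer vector of residue counts, one per row.
#' @examples
#' region_length(region(775, 1468)) # 694
#' @export
region_length <- function(region) {
  stopifnot(is.data.frame(region), all(c("start", "end") %in% names(region)))
  as.integer(region$end - region$start + 1L)
}

#' Remove a region from a protein sequence
#'
#' Models a splice-out at the protein level: residues inside the (1-based,
#' inclusive) region are deleted, everything else is preserved in order. The
#' result has length `nchar(seq) - region_length(region)`.
#'
#' @param seq Amino-acid string (single-letter codes).
#' @param region One-row region tibble, see [region()].
#' @return The spliced amino-acid string.
#' @examples
#' splice_out("ABCDE", region(2, 4)) # "AE"
#' @export
splice_out <- function(seq, region) {
  stopifnot(is.character(seq), length(seq) == 1L, nrow(region) == 1L)
  L <- nchar(seq)
  if (region$start > L || region$end > L) {
    stop("region [", region$start, ", ", region$end,
         "] out of bounds for sequence of length ", L, call. = FALSE)
  }
  paste0(substr(seq, 1L, region$start - 1L), substr(seq, region$end + 1L, L))
}

#' Convert a coding-sequence length to a protein length
#'
#' CDS lengths follow the stop-codon-excluded convention, so the protein
#' length is exactly `cds_length_nt / 3` (a 6687-nt CDS encodes 2229 aa).
#'
#' @param cds_length_nt Integer CDS length in nucleotides, divisible by 3.
#' @return Integer protein length in amino acids (vectorized).
#' @examples
#' cds_to_protein_length(6687) # 2229
#' @export
cds_to_protein_length <- function(cds_length_nt) {
  cds_length_nt <- vctrs_int(cds_length_nt, "cds_length_nt")
  if (any(cds_length_nt %% 3L != 0L)) {
    stop("CDS length not divisible by 3 (frame error); ",
         "lengths use the stop-codon-excluded convention", call. = FALSE)
  }
  cds_length_nt %/% 3L
}

#' Describe a long/short isoform pair
#'
#' Bundles a long-isoform protein with the coordinates of the region absent
#' from the short isoform and checks the coordinate arithmetic: the CDS
#' length (stop codon excluded) must equal three times the protein length,
#' and the removed region must lie within the parent sequence.
#'
#' @param id Identifier.
#' @param protein_seq Long-isoform amino-acid string.
#' @param cds_length_nt Optional CDS length in nt; validated against
#'   `nchar(protein_seq)` when given.
#' @param removed_region Optional one-row [region()] spliced out in the short
#'   isoform.
#' @return A one-row tibble with columns `id`, `protein_seq`, `cds_length_nt`,
#'   `removed_start`, `removed_end`, `short_seq` (the spliced sequence, or the
#'   parent when no region is given).
#' @export
isoform_record <- function(id, protein_seq, cds_length_nt = NA_integer_,
                           removed_region = NULL) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L)
  L <- nchar(protein_seq)
  if (!is.na(cds_length_nt) &&
      cds_to_protein_length(cds_length_nt) != L) {
    stop("cds_length_nt/3 (", cds_length_nt %/% 3L,
         ") does not match protein length (", L, ")", call. = FALSE)
  }
  if (is.null(removed_region)) {
    short <- protein_seq
    rs <- NA_integer_; re <- NA_integer_
  } else {
    short <- splice_out(protein_seq, removed_region)
    rs <- removed_region$start; re <- removed_region$end
  }
  tibble::tibble(
    id = as.character(id), protein_seq = protein_seq,
    cds_length_nt = as.integer(cds_length_nt),
    removed_start = rs, removed_end = re, short_seq = short
  )
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return Tibble with columns `id` (first word of the header) and `seq`.
#' @export
read_protein_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    id = vapply(strsplit(names(aas), "\\s+"), `[`, character(1), 1L),
    seq = unname(as.character(aas))
  )
}

#' Write protein sequences to FASTA
#'
#' @param sequences Tibble with `id` and `seq` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(sequences, path) {
  stopifnot(all(c("id", "seq") %in% names(sequences)))
  aas <- Biostrings::AAStringSet(sequences$seq)
  names(aas) <- sequences$id
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Read a region annotation table
#'
#' Tab-separated with columns `seq_id`, `start`, `end`, `label`; coordinates
#' are 1-based inclusive amino-acid positions.
#'
#' @param path TSV file path.
#' @return Tibble with those four columns.
#' @export
read_regions <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           seq_id = readr::col_character(),
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           label = readr::col_character()
                         ))
  need <- c("seq_id", "start", "end", "label")
  if (!all(need %in% names(tab))) {
    stop("region table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$start < 1L) || any(tab$end < tab$start)) {
    stop("invalid region coordinates (need 1 <= start <= end)", call. = FALSE)
  }
  tab
}
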