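.IUPAC_NT <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

#' Construct a marker alignment
#'
#' A marker alignment is a tibble with one row per record and columns
#' `id`, `lineage`, `parasitic` (logical, `NA` when unknown) and `seq`
#' (gapped, uppercase IUPAC nucleotides). All sequences must have equal
#' length; the common length is stored in the `alignment_length` attribute.
#'
#' @param seq Character vector of aligned (equal-length) nucleotide
#'   sequences. `U` is converted to `T`, lowercase is uppercased.
#' @param id Record identifiers (unique); defaults to `seq1..seqN`.
#' @param lineage Optional taxon labels.
#' @param parasitic Logical flag per record (`NA` = unknown).
#' @return A tibble of class `marker_alignment`.
#' @examples
#' aln <- marker_alignment(c("ATGAAA---", "ATGAAATTT"))
#' alignment_length(aln)
#' @export
marker_alignment <- function(seq, id = NULL, lineage = NA_character_,
                             parasitic = NA) {
  if (length(seq) == 0L) abort("Alignment has no records.")
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (is.null(id)) id <- paste0("seq", seq_along(seq))
  widths <- nchar(seq)
  if (length(unique(widths)) != 1L) {
    abort(paste0("Records have unequal lengths: ",
                 paste(sort(unique(widths)), collapse = ", ")))
  }
  if (anyDuplicated(id)) abort("Record ids must be unique.")
  bad <- setdiff(unique(strsplit(paste(seq, collapse = ""), "")[[1]]), .IUPAC_NT)
  if (length(bad) > 0L) {
    abort(paste0("Non-IUPAC characters in sequences: ",
                 paste(bad, collapse = " ")))
  }
  out <- tibble(id = as.character(id),
                lineage = rep_len(as.character(lineage), length(seq)),
                parasitic = rep_len(as.logical(parasitic), length(seq)),
                seq = seq)
  structure(out, class = c("marker_alignment", class(out)),
            alignment_length = widths[[1]])
}

#' Number of columns in an alignment
#'
#' @param x A `marker_alignment` or `residue_alignment`.
#' @return Integer column count.
#' @export
alignment_length <- function(x) attr(x, "alignment_length")

#' Read a gapped marker alignment from FASTA
#'
#' Headers may carry metadata in a pipe-delimited convention,
#' `id|lineage|parasitic`, where the third field is `parasite`,
#' `free-living`, `1`, `0` or absent. A sidecar TSV (columns `id`,
#' `lineage`, `parasitic` coded 0/1/NA) overrides header metadata.
#'
#' @param path Path to a FASTA file of equal-length aligned sequences.
#' @param metadata Optional path to the metadata TSV.
#' @return A [marker_alignment()].
#' @export
read_marker_fasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("Empty FASTA file: ", path))
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  ids <- map_chr(fields, 1)
  lineage <- map_chr(fields, ~ if (length(.x) >= 2) .x[[2]] else NA_character_)
  parasitic <- map_chr(fields, ~ if (length(.x) >= 3) .x[[3]] else NA_character_)
  parasitic <- dplyr::case_when(
    tolower(parasitic) %in% c("parasite", "parasitic", "1", "true") ~ TRUE,
    tolower(parasitic) %in% c("free-living", "free_living", "0", "false") ~ FALSE,
    TRUE ~ NA
  )
  aln <- marker_alignment(as.character(set), id = ids, lineage = lineage,
                          parasitic = parasitic)
  if (!is.null(metadata)) {
    meta <- readr::read_tsv(metadata, show_col_types = FALSE,
                            col_types = readr::cols(id = "c", lineage = "c",
                                                    parasitic = "d"))
    meta$parasitic <- as.logical(meta$parasitic)
    keep <- aln[, c("id", "seq")]
    merged <- left_join(keep, meta, by = "id")
    aln <- marker_alignment(merged$seq, id = merged$id,
                            lineage = merged$lineage,
                            parasitic = merged$parasitic)
  }
  aln
}

#' Write a marker alignment to FASTA
#'
#' Emits the pipe-delimited header convention understood by
#' [read_marker_fasta()].
#'
#' @param aln A `marker_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marker_fasta <- function(aln, path) {
  flag <- ifelse(is.na(aln$parasitic), "unknown",
                 ifelse(aln$parasitic, "parasite", "free-living"))
  headers <- paste(aln$id,
                   ifelse(is.na(aln$lineage), "NA", aln$lineage),
                   flag, sep = "|")
  writeLines(paste0(">", headers, "\n", aln$seq), path)
  invisible(path)
}

count_ambiguous <- function(seq) {
  nchar(gsub("[ACGT-]", "", seq))
}

nongap_length <- function(seq) {
  nchar(gsub("-", "", seq, fixed = TRUE))
}

#' Filter records by base quality and length
#'
#' Retains records whose ambiguous-base fraction, computed over non-gap
#' positions, is strictly below `max_ambiguous_fraction` (a 658-nt record
#' with 7 N's fails the 1% default; one with 6 passes), and, when
#' `required_length` is set, whose ungapped length equals it exactly
#' (the operational meaning of "full-length" for a 658-bp barcode).
#'
#' @param aln A `marker_alignment`.
#' @param max_ambiguous_fraction Maximum tolerated ambiguous fraction
#'   (strict `<`), default 0.01.
#' @param required_length Exact ungapped length to require, or `NULL`.
#' @return Filtered `marker_alignment` (possibly empty, with a warning).
#' @export
filter_quality <- function(aln, max_ambiguous_fraction = 0.01,
                           required_length = NULL) {
  stopifnot(max_ambiguous_fraction >= 0, max_ambiguous_fraction <= 1)
  ng <- nongap_length(aln$seq)
  amb <- count_ambiguous(aln$seq)
  frac <- ifelse(ng > 0, amb / ng, 1)
  keep <- frac < max_ambiguous_fraction
  if (!is.null(required_length)) keep <- keep & ng == required_length
  out <- aln[keep, , drop = FALSE]
  if (nrow(out) == 0L) warn("filter_quality removed every record.")
  structure(out, class = class(aln),
            alignment_length = attr(aln, "alignment_length"))
}

#' Collapse identical sequences into haplotypes
#'
#' Exact duplicates (string equality after uppercasing on read) are
#' collapsed; the first-seen record represents each haplotype.
#'
#' @param aln A `marker_alignment`.
#' @return A list with `alignment` (representatives only) and
#'   `haplotype_map`, a tibble with columns `representative` and `id`
#'   covering every input record.
#' @export
collapse_haplotypes <- function(aln) {
  rep_idx <- !duplicated(aln$seq)
  reps <- aln$id[rep_idx][match(aln$seq, aln$seq[rep_idx])]
  out <- aln[rep_idx, , drop = FALSE]
  out <- structure(out, class = class(aln),
                   alignment_length = attr(aln, "alignment_length"))
  list(alignment = out,
       haplotype_map = tibble(representative = reps, id = aln$id))
}

split_codons <- function(seq, frame_offset, n_codons) {
  starts <- frame_offset + 3L * (seq_len(n_codons) - 1L) + 1L
  substring(seq, starts, starts + 2L)
}

internal_stop_count <- function(aa) {
  # stops at the terminal residue are not internal
  core <- sub("\\*+$", "", aa)
  nchar(gsub("[^*]", "", core))
}

#' Translate a marker alignment to amino acids
#'
#' Codons are read from `frame_offset`; a trailing incomplete codon is
#' dropped (658 nt in frame 0 gives 219 residues). Fully gapped codons
#' translate to `-`, partially gapped or ambiguous codons to `X`. With
#' `frame = "auto"` the frame minimising internal stop codons summed over
#' records is chosen (ties break to the lowest offset). Records that
#' still contain internal stops under the chosen frame are flagged.
#'
#' @param aln A `marker_alignment`.
#' @param code A [genetic_code()]; default table 5.
#' @param frame `"auto"` or an explicit offset 0, 1 or 2.
#' @return A tibble of class `residue_alignment` with columns `id`, `aa`,
#'   `internal_stops`; attributes `alignment_length` (residue columns L),
#'   `frame_offset` and `table_id`.
#' @export
translate_alignment <- function(aln, code = genetic_code(5), frame = "auto") {
  len <- alignment_length(aln)
  translate_all <- function(off) {
    n_codons <- (len - off) %/% 3L
    map_chr(aln$seq, function(s) {
      paste(map_chr(split_codons(s, off, n_codons), translate_codon,
                    code = code), collapse = "")
    })
  }
  if (identical(frame, "auto")) {
    stops <- map_dbl(0:2, function(off) sum(internal_stop_count(translate_all(off))))
    frame <- which.min(stops) - 1L
  }
  frame <- as.integer(frame)
  stopifnot(frame %in% 0:2)
  aa <- translate_all(frame)
  n_stops <- internal_stop_count(aa)
  if (mean(n_stops > 0) > 0.5) {
    abort("No stop-free reading frame for more than half the records.")
  }
  out <- tibble(id = aln$id, aa = aa, internal_stops = n_stops)
  structure(out, class = c("residue_alignment", class(out)),
            alignment_length = (len - frame) %/% 3L,
            frame_offset = frame, table_id = code$table_id)
}

#' Per-codon-position nucleotide composition
#'
#' Base frequencies are computed over unambiguous, non-gap bases at each
#' of the three codon positions and overall. Mitochondrial barcodes are
#' expected to be AT-rich (the canonical datasets exceed 60% AT).
#'
#' @param aln A `marker_alignment`.
#' @param frame_offset Reading-frame offset (0, 1 or 2).
#' @return A tibble with columns `codon_position` (`"1"`, `"2"`, `"3"`,
#'   `"overall"`), `base` and `freq`; frequencies sum to 1 within each
#'   position.
#' @export
nucleotide_composition <- function(aln, frame_offset = 0L) {
  if (nrow(aln) == 0L) abort("Empty alignment.")
  chars <- strsplit(aln$seq, "")
  len <- alignment_length(aln)
  pos_of_col <- rep(NA_integer_, len)
  usable <- (frame_offset + 1L):len
  pos_of_col[usable] <- ((usable - frame_offset - 1L) %% 3L) + 1L
  tab <- function(cols) {
    v <- unlist(map(chars, ~ .x[cols]), use.names = FALSE)
    v <- v[v %in% c("A", "C", "G", "T")]
    if (length(v) == 0L) abort("No unambiguous bases to count.")
    cnt <- table(factor(v, levels = c("A", "C", "G", "T")))
    as.numeric(cnt) / sum(cnt)
  }
  rows <- map(1:3, function(p) {
    tibble(codon_position = as.character(p), base = c("A", "C", "G", "T"),
           freq = tab(which(pos_of_col == p)))
  })
  overall <- tibble(codon_position = "overall", base = c("A", "C", "G", "T"),
                    freq = tab(which(!is.na(pos_of_col))))
  bind_rows(rows, list(overall))
}

#' Overall AT content of an alignment
#'
#' @param aln A `marker_alignment`.
#' @param frame_offset Reading-frame offset.
#' @return Proportion f(A) + f(T) over unambiguous non-gap bases.
#' @export
at_content <- function(aln, frame_offset = 0L) {
  comp <- nucleotide_composition(aln, frame_offset)
  sum(comp$freq[comp$codon_position == "overall" & comp$base %in% c("A", "T")])
}

#' Amino acid composition with biochemical groups
#'
#' Residue frequencies are computed over non-gap, non-`X` positions of
#' the whole residue alignment; each residue is annotated with its
#' biochemical group so group frequencies are column sums.
#'
#' @param raln A `residue_alignment`.
#' @return A tibble with columns `residue`, `group`, `freq` (frequencies
#'   sum to 1).
#' @export
aa_composition <- function(raln) {
  v <- unlist(strsplit(raln$aa, ""), use.names = FALSE)
  v <- v[v %in% .AA20]
  cnt <- table(factor(v, levels = .AA20))
  tibble(residue = .AA20,
         group = aa_group(.AA20),
         freq = as.numeric(cnt) / sum(cnt))
}

#' Biochemical-group composition
#'
#' @param raln A `residue_alignment`.
#' @return A tibble with columns `group`, `freq` summing to 1.
#' @export
group_composition <- function(raln) {
  aa_composition(raln) |>
    group_by(group = .data$group) |>
    summarise(freq = sum(.data$freq), .groups = "drop")
}
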