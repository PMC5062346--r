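#' Default secondary-structure segment table for the COI barcode
#'
#' The 219-residue barcode region of COI comprises six transmembrane
#' helices connected by five loops; the loops total 60 residues, Loop 4-5
#' spans 10 residues, Helix 1 enters the region already truncated (the
#' forward primer sits inside it) and Helix 6 is cut short at the
#' C-terminal end. Exact boundary columns are not fixed by any published
#' table, so this default satisfies those constraints and is meant to be
#' edited: any tibble with columns `segment`, `type` (`"helix"`/`"loop"`),
#' `start`, `end` (1-based, inclusive, non-overlapping, sorted) works
#' wherever a segment table is accepted.
#'
#' @return A tibble with columns `segment`, `type`, `start`, `end`
#'   covering columns 1..219 (159 helix and 60 loop columns).
#' @export
coi_segments <- function() {
  tibble(
    segment = c("Helix 1", "Loop 1-2", "Helix 2", "Loop 2-3", "Helix 3",
                "Loop 3-4", "Helix 4", "Loop 4-5", "Helix 5", "Loop 5-6",
                "Helix 6"),
    type = c("helix", "loop", "helix", "loop", "helix", "loop", "helix",
             "loop", "helix", "loop", "helix"),
    start = c(1L, 24L, 36L, 65L, 75L, 98L, 116L, 146L, 156L, 186L, 196L),
    end   = c(23L, 35L, 64L, 74L, 97L, 115L, 145L, 155L, 185L, 195L, 219L)
  )
}

#' Read a segment table from TSV
#'
#' @param path TSV with columns `segment`, `type`, `start`, `end`
#'   (1-based inclusive).
#' @return A validated segment tibble.
#' @export
read_segments <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE)
  validate_segments(seg)
  seg
}

validate_segments <- function(segments) {
  need <- c("segment", "type", "start", "end")
  if (!all(need %in% names(segments))) {
    abort("Segment table needs columns segment, type, start, end.")
  }
  if (nrow(segments) == 0L) abort("Segment table is empty.")
  stopifnot(all(segments$start <= segments$end))
  ord <- order(segments$start)
  s <- segments[ord, ]
  if (nrow(s) > 1L && any(s$start[-1] <= s$end[-nrow(s)])) {
    abort("Segment intervals overlap.")
  }
  invisible(segments)
}

# Segment (and type) containing each 1-based column; NA outside all segments.
segment_of <- function(position, segments) {
  idx <- map_int(position, function(p) {
    hit <- which(segments$start <= p & segments$end >= p)
    if (length(hit) == 0L) NA_integer_ else hit[[1]]
  })
  tibble(segment = segments$segment[idx], segment_type = segments$type[idx])
}
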