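.BIN_LABELS <- c("(0.5,0.7]", "(0.7,0.9]", "(0.9,1.1]", ">1.1")

# Residues of one column after applying the gap policy.
column_states <- function(column, gap_policy = c("exclude", "as_state")) {
  gap_policy <- match.arg(gap_policy)
  if (gap_policy == "exclude") column <- column[!column %in% c("-", "X")]
  column
}

#' Shannon entropy of an alignment column
#'
#' H = -sum p_i log p_i over the residue states observed in the column.
#' Natural logarithm by default (the convention of the alignment editors
#' this mirrors); an invariant column has H = 0 and a uniform column over
#' k states has H = log k.
#'
#' @param column Character vector of one-letter residues for one column.
#' @param gap_policy `"exclude"` drops `-` and `X` before computing
#'   frequencies (default); `"as_state"` counts them as states.
#' @param base Logarithm base; default `exp(1)` for nats.
#' @return Entropy in nats (or the chosen base); `NA` with a warning for
#'   a column that is empty after the gap policy.
#' @examples
#' column_entropy(rep("A", 10))            # 0
#' column_entropy(c(rep("A", 5), rep("V", 5)))  # log(2)
#' @export
column_entropy <- function(column, gap_policy = c("exclude", "as_state"),
                           base = exp(1)) {
  states <- column_states(column, gap_policy)
  if (length(states) == 0L) {
    warn("Column is empty after gap exclusion; entropy undefined.")
    return(NA_real_)
  }
  p <- as.numeric(table(states)) / length(states)
  -sum(p * log(p, base = base))
}

#' Classify one alignment column
#'
#' The classification scheme, in order of precedence:
#' \itemize{
#'   \item `conserved`: exactly one residue state observed;
#'   \item `nonvariable_within_group`: several residues observed, but all
#'     in one biochemical group — treated as non-variable regardless of
#'     entropy;
#'   \item `nonvariable`: entropy below the threshold (default 0.5 nats);
#'   \item `variable`: everything else, binned by entropy into
#'     (0.5,0.7], (0.7,0.9], (0.9,1.1] and >1.1.
#' }
#'
#' @param column Character vector of residues (one column).
#' @param entropy_threshold Non-variability threshold in nats.
#' @param gap_policy Passed to [column_entropy()]; `X` is also ignored
#'   for group membership.
#' @return A list with `class`, `bin` (`NA` unless variable), `entropy`,
#'   `groups` (sorted group names observed).
#' @export
classify_site <- function(column, entropy_threshold = 0.5,
                          gap_policy = c("exclude", "as_state")) {
  gap_policy <- match.arg(gap_policy)
  states <- column_states(column, gap_policy)
  residues <- unique(states[!states %in% c("-", "X")])
  if (length(states) == 0L) {
    warn("Column is empty after gap exclusion; class undefined.")
    return(list(class = NA_character_, bin = NA_character_,
                entropy = NA_real_, groups = character(0)))
  }
  h <- column_entropy(column, gap_policy)
  groups <- sort(unique(aa_group(residues)))
  if (length(residues) == 1L && length(unique(states)) == 1L) {
    cls <- "conserved"; bin <- NA_character_
  } else if (length(residues) >= 2L && length(groups) == 1L) {
    cls <- "nonvariable_within_group"; bin <- NA_character_
  } else if (!is.na(h) && h < entropy_threshold) {
    cls <- "nonvariable"; bin <- NA_character_
  } else {
    cls <- "variable"
    bin <- .BIN_LABELS[findInterval(h, c(0.7, 0.9, 1.1)) + 1L]
  }
  list(class = cls, bin = bin, entropy = h, groups = groups)
}

#' Consensus conservation of a column
#'
#' A relaxation of strict conservation: the column counts as conserved
#' when its modal residue frequency (gaps excluded) reaches the
#' threshold. At threshold 1 this coincides with the strict `conserved`
#' class on gap-free columns; 0.995 is the conventional relaxed cutoff.
#'
#' @param column Character vector of residues.
#' @param threshold Proportion in (0, 1].
#' @return Logical; `FALSE` with a warning for an all-gap column.
#' @export
consensus_conserved <- function(column, threshold = 0.995) {
  stopifnot(threshold > 0, threshold <= 1)
  states <- column_states(column, "exclude")
  if (length(states) == 0L) {
    warn("All-gap column; consensus undefined, returning FALSE.")
    return(FALSE)
  }
  max(table(states)) / length(states) >= threshold
}

#' Detect internal deletions in a residue alignment
#'
#' Maximal internal runs of gap columns in each sequence become deletion
#' events. Terminal gap runs are treated as missing data by default
#' (partial sequences), not deletions.
#'
#' @param raln A `residue_alignment`.
#' @param terminal_policy `"ignore"` (default) or `"count"` terminal
#'   gap runs.
#' @return A list with `events` (tibble: `id`, `start`, `end`, `length`)
#'   and `per_sequence` (tibble: `id`, `n_events`, `deleted_residues`).
#' @export
detect_deletions <- function(raln, terminal_policy = c("ignore", "count")) {
  terminal_policy <- match.arg(terminal_policy)
  events <- map(seq_len(nrow(raln)), function(i) {
    chars <- strsplit(raln$aa[[i]], "")[[1]]
    r <- rle(chars == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gap_runs <- which(r$values)
    if (terminal_policy == "ignore") {
      gap_runs <- gap_runs[starts[gap_runs] != 1L &
                           ends[gap_runs] != length(chars)]
    }
    if (length(gap_runs) == 0L) return(NULL)
    tibble(id = raln$id[[i]], start = starts[gap_runs],
           end = ends[gap_runs], length = r$lengths[gap_runs])
  })
  events <- bind_rows(events)
  if (nrow(events) == 0L) {
    events <- tibble(id = character(), start = integer(), end = integer(),
                     length = integer())
  }
  per_seq <- tibble(id = raln$id) |>
    left_join(events |> group_by(id = .data$id) |>
                summarise(n_events = n(),
                          deleted_residues = sum(.data$length),
                          .groups = "drop"),
              by = "id") |>
    mutate(n_events = ifelse(is.na(.data$n_events), 0L, .data$n_events),
           deleted_residues = ifelse(is.na(.data$deleted_residues), 0L,
                                     .data$deleted_residues))
  list(events = events, per_sequence = per_seq)
}

#' Profile every column of a residue alignment
#'
#' The central per-site table: entropy, class, entropy bin, observed
#' biochemical groups, consensus fraction, gap count and
#' secondary-structure segment for each of the L alignment columns.
#'
#' @param raln A `residue_alignment`.
#' @param segments Segment tibble (see [coi_segments()]), or `NULL` for
#'   no structural annotation.
#' @param entropy_threshold Non-variability threshold in nats.
#' @param consensus_threshold Threshold for the relaxed consensus
#'   conservation flag.
#' @param gap_policy Gap handling for entropy and classification.
#' @return A tibble of class `site_profile`, one row per column, with
#'   columns `position`, `entropy`, `class`, `bin`, `groups` (list),
#'   `freqs` (list of named residue frequencies), `consensus_fraction`,
#'   `consensus_conserved`, `gap_count`, `segment`, `segment_type`,
#'   `min_ligand_distance`, `proximal`.
#' @export
profile_alignment <- function(raln, segments = coi_segments(),
                              entropy_threshold = 0.5,
                              consensus_threshold = 0.995,
                              gap_policy = "exclude") {
  L <- alignment_length(raln)
  mat <- do.call(rbind, strsplit(raln$aa, ""))
  rows <- map(seq_len(L), function(j) {
    col <- mat[, j]
    cls <- classify_site(col, entropy_threshold, gap_policy)
    states <- column_states(col, "exclude")
    freqs <- if (length(states)) {
      tb <- table(states); setNames(as.numeric(tb) / sum(tb), names(tb))
    } else setNames(numeric(0), character(0))
    cons_frac <- if (length(states)) max(freqs) else NA_real_
    tibble(position = j,
           entropy = cls$entropy,
           class = cls$class,
           bin = cls$bin,
           groups = list(cls$groups),
           freqs = list(freqs),
           consensus_fraction = cons_frac,
           consensus_conserved = !is.na(cons_frac) &&
             cons_frac >= consensus_threshold,
           gap_count = sum(col == "-"))
  })
  out <- bind_rows(rows)
  if (!is.null(segments)) {
    validate_segments(segments)
    out <- dplyr::bind_cols(out, segment_of(out$position, segments))
  } else {
    out$segment <- NA_character_
    out$segment_type <- NA_character_
  }
  out$min_ligand_distance <- NA_real_
  out$proximal <- NA
  structure(out, class = c("site_profile", class(out)))
}

#' Cross-tabulate helix/loop membership against a site predicate
#'
#' Builds the 2x2 contingency table (rows helix/loop, columns predicate
#' yes/no) used to test whether a class of sites is enriched in loops
#' relative to helices. Only columns assigned to a helix or loop segment
#' are counted, so the marginals equal the segment sizes.
#'
#' @param profile A `site_profile`.
#' @param predicate Either a character vector of classes (e.g.
#'   `"conserved"`, `c("variable")`) or a function taking the profile and
#'   returning a logical vector (e.g. `~ .x$entropy > 1.1`-style
#'   functions).
#' @return An integer matrix with dimnames `helix`/`loop` by
#'   `yes`/`no`.
#' @export
class_by_segment_table <- function(profile, predicate) {
  if (all(is.na(profile$segment_type))) abort("Profile has no segment labels.")
  hit <- if (is.character(predicate)) {
    profile$class %in% predicate
  } else if (is.function(predicate)) {
    predicate(profile)
  } else {
    abort("predicate must be a character vector of classes or a function.")
  }
  in_seg <- profile$segment_type %in% c("helix", "loop")
  tab <- table(factor(profile$segment_type[in_seg], c("helix", "loop")),
               factor(ifelse(hit[in_seg], "yes", "no"), c("yes", "no")))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(c("helix", "loop"), c("yes", "no")))
  m
}
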