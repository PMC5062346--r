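#' Empirical directional nucleotide substitution matrix
#'
#' Counts substitution events column by column, polarised against the
#' column's majority base as a simple ancestral proxy: in each alignment
#' column with a unique majority base, every sequence carrying a
#' different (unambiguous) base contributes one majority-to-minority
#' event. Columns with tied majorities are skipped, as are gap and
#' ambiguous characters. The 4 x 4 count matrix is rescaled so its
#' twelve off-diagonal entries sum to 100, making matrices from
#' different datasets directly comparable; an excess of C-to-T and
#' G-to-A over their reverse directions is the signature of oxidative
#' damage to mitochondrial DNA.
#'
#' @param aln A `marker_alignment` with at least two sequences.
#' @return A 4 x 4 matrix of class `substitution_matrix` (rows = from,
#'   columns = to, diagonal zero, off-diagonal sum 100), with the raw
#'   event count in attribute `n_events`.
#' @export
substitution_count_matrix <- function(aln) {
  if (nrow(aln) < 2L) abort("Need at least two sequences.")
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(aln$seq, ""))
  counts <- matrix(0, 4, 4, dimnames = list(from = bases, to = bases))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% bases]
    if (length(col) < 2L) next
    tab <- table(factor(col, bases))
    top <- which(tab == max(tab))
    if (length(top) != 1L) next  # ambiguous polarity
    maj <- bases[top]
    minor <- col[col != maj]
    if (length(minor) == 0L) next
    mt <- table(factor(minor, bases))
    counts[maj, ] <- counts[maj, ] + as.numeric(mt)
  }
  n_events <- sum(counts)
  if (n_events == 0) abort("No variable columns; substitution matrix undefined.")
  out <- counts / n_events * 100
  structure(out, class = c("substitution_matrix", class(out)),
            n_events = n_events)
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("<substitution_matrix> off-diagonal sum =",
      format(sum(x), digits = 6), "|", attr(x, "n_events"), "events\n")
  print(round(unclass(x), 2))
  invisible(x)
}
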