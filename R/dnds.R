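.BASES <- c("A", "C", "G", "T")

# All 64 codons in fixed order; index arithmetic keys the lookup tables.
all_codons <- function() {
  as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0)) |> sort()
}

jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# Cache of per-genetic-code codon lookup tables.
.dnds_cache <- new.env(parent = emptyenv())

# Nei-Gojobori (1986) building blocks for one genetic code:
#  - s_sites / n_sites per codon: at each position the fraction of the
#    three possible changes that are synonymous (changes to stop codons
#    count as nonsynonymous), so s + n = 3 for every sense codon;
#  - SD / ND matrices: synonymous / nonsynonymous differences between two
#    codons, averaged over all minimal substitution paths; paths passing
#    through stop codons are excluded (all-stop path sets fall back to
#    the unrestricted average).
codon_tables <- function(code) {
  key <- as.character(code$table_id)
  if (!is.null(.dnds_cache[[key]])) return(.dnds_cache[[key]])
  codons <- all_codons()
  aa <- unname(code$codons[codons])
  n <- length(codons)
  s_sites <- numeric(n); n_sites <- numeric(n)
  for (i in seq_len(n)) {
    if (aa[i] == "*") { s_sites[i] <- NA; n_sites[i] <- NA; next }
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(.BASES, substr(codons[i], pos, pos))) {
        alt <- codons[i]
        substr(alt, pos, pos) <- b
        if (unname(code$codons[alt]) == aa[i]) syn <- syn + 1 / 3
      }
    }
    s_sites[i] <- syn
    n_sites[i] <- 3 - syn
  }
  step_counts <- function(c1, c2) {
    a1 <- unname(code$codons[c1]); a2 <- unname(code$codons[c2])
    if (a1 == a2) c(1, 0) else c(0, 1)
  }
  SD <- matrix(0, n, n, dimnames = list(codons, codons))
  ND <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (aa[i] == "*" || aa[j] == "*") { SD[i, j] <- NA; ND[i, j] <- NA; next }
      pos_diff <- which(strsplit(codons[i], "")[[1]] !=
                          strsplit(codons[j], "")[[1]])
      paths <- if (length(pos_diff) == 1L) list(pos_diff) else
        apply(gtools_permute(pos_diff), 1, identity, simplify = FALSE)
      tally <- function(order, allow_stop) {
        cur <- codons[i]; sd <- 0; nd <- 0
        for (p in order) {
          nxt <- cur
          substr(nxt, p, p) <- substr(codons[j], p, p)
          if (!allow_stop && unname(code$codons[nxt]) == "*") return(NULL)
          st <- step_counts(cur, nxt)
          sd <- sd + st[1]; nd <- nd + st[2]
          cur <- nxt
        }
        c(sd, nd)
      }
      res <- purrr::compact(map(paths, tally, allow_stop = FALSE))
      if (length(res) == 0L) res <- map(paths, tally, allow_stop = TRUE)
      mat <- do.call(rbind, res)
      SD[i, j] <- mean(mat[, 1]); ND[i, j] <- mean(mat[, 2])
    }
  }
  out <- list(codons = codons, aa = aa, s_sites = s_sites, n_sites = n_sites,
              SD = SD, ND = ND)
  .dnds_cache[[key]] <- out
  out
}

# All orderings of a small integer vector (2 or 3 elements).
gtools_permute <- function(v) {
  if (length(v) == 2L) return(rbind(v, rev(v)))
  perms <- list()
  for (i in seq_along(v)) {
    rest <- v[-i]
    perms <- c(perms, list(c(v[i], rest[1], rest[2]),
                           c(v[i], rest[2], rest[1])))
  }
  unique(do.call(rbind, perms))
}

codon_ok <- function(codon, tables) {
  idx <- match(codon, tables$codons)
  !is.na(idx) & tables$aa[idx] != "*"
}

#' Pairwise Nei-Gojobori dN and dS
#'
#' Counting estimator of synonymous (dS) and nonsynonymous (dN)
#' substitutions per site between two codon sequences: synonymous and
#' nonsynonymous site counts are averaged over the two sequences,
#' observed differences at multi-hit codons are averaged over all
#' minimal substitution paths (paths through stop codons excluded), and
#' the proportions are corrected for multiple hits with the
#' Jukes-Cantor transform d = -(3/4) ln(1 - 4p/3). The estimate is
#' symmetric in its arguments. Codon pairs where either codon is
#' gapped, ambiguous or a stop are skipped.
#'
#' @param codons_a,codons_b Character vectors of codons, equal length.
#' @param code A [genetic_code()].
#' @return A list with `dN`, `dS`, `N_sites`, `S_sites`, `N_subs`,
#'   `S_subs`, `n_codons_used`. `dN`/`dS` are `NA` when the corrected
#'   proportion is undefined (p >= 3/4) or no codons were comparable.
#' @examples
#' ng86_pairwise("TTT", "TTC", genetic_code(5))  # one synonymous change
#' @export
ng86_pairwise <- function(codons_a, codons_b, code = genetic_code(5)) {
  if (length(codons_a) != length(codons_b)) {
    abort("Codon vectors must have equal length.")
  }
  tb <- codon_tables(code)
  use <- codon_ok(codons_a, tb) & codon_ok(codons_b, tb)
  a <- match(codons_a[use], tb$codons)
  b <- match(codons_b[use], tb$codons)
  if (length(a) == 0L) {
    return(list(dN = NA_real_, dS = NA_real_, N_sites = 0, S_sites = 0,
                N_subs = 0, S_subs = 0, n_codons_used = 0L))
  }
  S <- sum((tb$s_sites[a] + tb$s_sites[b]) / 2)
  N <- sum((tb$n_sites[a] + tb$n_sites[b]) / 2)
  idx <- cbind(a, b)
  Sd <- sum(tb$SD[idx]); Nd <- sum(tb$ND[idx])
  list(dN = jc_correct(if (N > 0) Nd / N else NA_real_),
       dS = jc_correct(if (S > 0) Sd / S else NA_real_),
       N_sites = N, S_sites = S, N_subs = Nd, S_subs = Sd,
       n_codons_used = length(a))
}

sample_pairs <- function(n, max_pairs) {
  total <- n * (n - 1) / 2
  if (total <= max_pairs) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(cbind(idx[, 1], idx[, 2]))
  }
  seen <- new.env(parent = emptyenv())
  out <- matrix(0L, max_pairs, 2)
  k <- 0L
  while (k < max_pairs) {
    i <- sample.int(n, 1L); j <- sample.int(n, 1L)
    if (i == j) next
    lo <- min(i, j); hi <- max(i, j)
    key <- paste0(lo, "_", hi)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    k <- k + 1L
    out[k, ] <- c(lo, hi)
  }
  out
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Codon-wise dN/dS profile of an alignment
#'
#' For every codon column, Nei-Gojobori substitution and site counts are
#' accumulated over sequence pairs (all pairs, or a seeded random subset
#' capped at `max_pairs` for large alignments), and the per-site ratio
#' dN/dS = (N_subs/N_sites)/(S_subs/S_sites) is computed on the
#' Jukes-Cantor-corrected proportions. Values far below 1 indicate
#' purifying selection, the dominant regime for mitochondrial
#' protein-coding sequence.
#'
#' @param aln A `marker_alignment` of in-frame nucleotide sequences.
#' @param code A [genetic_code()].
#' @param frame_offset Reading-frame offset.
#' @param max_pairs Cap on sequence pairs per alignment (default 500).
#' @param seed Seed controlling pair subsampling (`NULL` = current RNG).
#' @return A tibble of class `codon_selection_profile`: one row per
#'   codon with `codon`, `n_pairs`, `N_sites`, `S_sites`, `N_subs`,
#'   `S_subs`, `dN`, `dS`, `dnds` (`NA` when dS is 0 or undefined).
#' @export
codon_site_dnds <- function(aln, code = genetic_code(5), frame_offset = 0L,
                            max_pairs = 500L, seed = NULL) {
  if (nrow(aln) < 2L) abort("Need at least two sequences.")
  tb <- codon_tables(code)
  len <- alignment_length(aln)
  n_codons <- (len - frame_offset) %/% 3L
  codon_mat <- do.call(rbind, map(aln$seq, split_codons,
                                  frame_offset = frame_offset,
                                  n_codons = n_codons))
  pairs <- with_seed(seed, sample_pairs(nrow(aln), max_pairs))
  rows <- map(seq_len(n_codons), function(j) {
    ca <- codon_mat[pairs[, 1], j]
    cb <- codon_mat[pairs[, 2], j]
    use <- codon_ok(ca, tb) & codon_ok(cb, tb)
    a <- match(ca[use], tb$codons); b <- match(cb[use], tb$codons)
    if (length(a) == 0L) {
      return(tibble(codon = j, n_pairs = 0L, N_sites = 0, S_sites = 0,
                    N_subs = 0, S_subs = 0, dN = NA_real_, dS = NA_real_,
                    dnds = NA_real_))
    }
    N <- sum((tb$n_sites[a] + tb$n_sites[b]) / 2)
    S <- sum((tb$s_sites[a] + tb$s_sites[b]) / 2)
    idx <- cbind(a, b)
    Nd <- sum(tb$ND[idx]); Sd <- sum(tb$SD[idx])
    dN <- jc_correct(Nd / N); dS <- jc_correct(Sd / S)
    tibble(codon = j, n_pairs = length(a), N_sites = N, S_sites = S,
           N_subs = Nd, S_subs = Sd, dN = dN, dS = dS,
           dnds = ifelse(!is.na(dS) && dS > 0 && !is.na(dN), dN / dS,
                         NA_real_))
  })
  out <- bind_rows(rows)
  structure(out, class = c("codon_selection_profile", class(out)))
}
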