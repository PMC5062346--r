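# Independent brute-force oracles and small fixture builders.

AA20 <- c("G", "A", "V", "L", "M", "I", "S", "T", "C", "P", "N", "Q",
          "F", "Y", "W", "K", "R", "H", "D", "E")
NT4 <- c("A", "C", "G", "T")

GROUP_OF <- local({
  g <- biochemical_groups()
  setNames(rep(names(g), lengths(g)), unlist(g, use.names = FALSE))
})

# Entropy straight from the definition, summing over an explicit table.
oracle_entropy <- function(column) {
  column <- column[!column %in% c("-", "X")]
  n <- length(column)
  h <- 0
  for (state in unique(column)) {
    p <- sum(column == state) / n
    h <- h - p * log(p)
  }
  h
}

# G statistic by direct cell-wise evaluation, margins computed by loops.
oracle_g <- function(m, williams = TRUE) {
  N <- sum(m)
  G <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] > 0) {
        e <- sum(m[i, ]) * sum(m[, j]) / N
        G <- G + 2 * m[i, j] * log(m[i, j] / e)
      }
    }
  }
  if (williams) {
    df <- (nrow(m) - 1) * (ncol(m) - 1)
    q <- 1 + ((N * sum(1 / rowSums(m)) - 1) *
                (N * sum(1 / colSums(m)) - 1)) / (6 * N * df)
    G <- G / q
  }
  G
}

# Mann-Whitney U of x by exhaustive pair comparison, 1/2 per tie.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Site classification by exhaustive case analysis.
oracle_classify <- function(column) {
  res <- unique(column[!column %in% c("-", "X")])
  if (length(res) == 0) return(NA_character_)
  if (length(res) == 1) return("conserved")
  if (length(unique(GROUP_OF[res])) == 1) return("nonvariable_within_group")
  if (oracle_entropy(column) < 0.5) return("nonvariable")
  "variable"
}

# NG86 pairwise counts by recursive path enumeration, independent of the
# package's precomputed lookup tables. Returns NULL when every
# substitution path passes through a stop codon.
oracle_ng86 <- function(a, b, code) {
  aa <- function(cd) unname(code$codons[cd])
  site_counts <- function(cd) {
    s <- 0
    for (pos in 1:3) {
      for (nb in setdiff(NT4, substr(cd, pos, pos))) {
        alt <- cd
        substr(alt, pos, pos) <- nb
        if (aa(alt) == aa(cd)) s <- s + 1 / 3
      }
    }
    c(s, 3 - s)
  }
  paths <- function(cur, target) {
    d <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (length(d) == 0) return(list(c(0, 0)))
    out <- list()
    for (p in d) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      if (aa(nxt) == "*") next
      syn <- aa(cur) == aa(nxt)
      for (sub in paths(nxt, target)) {
        out[[length(out) + 1]] <- sub + c(syn, !syn)
      }
    }
    out
  }
  pp <- paths(a, b)
  if (length(pp) == 0) return(NULL)
  mat <- do.call(rbind, pp)
  sa <- site_counts(a); sb <- site_counts(b)
  list(S_sites = (sa[1] + sb[1]) / 2, N_sites = (sa[2] + sb[2]) / 2,
       S_subs = mean(mat[, 1]), N_subs = mean(mat[, 2]))
}

random_sense_codon <- function(code) {
  repeat {
    cd <- paste(sample(NT4, 3, replace = TRUE), collapse = "")
    if (unname(code$codons[cd]) != "*") return(cd)
  }
}

# A 658-nt in-frame barcode-like sequence (219 Leu codons + 1 spare nt).
barcode_658 <- function() paste0(strrep("CTT", 219), "A")

# Residue alignment built directly from amino acid strings.
fake_raln <- function(aa, id = paste0("s", seq_along(aa))) {
  structure(tibble::tibble(id = id, aa = aa,
                           internal_stops = 0L),
            class = c("residue_alignment", "tbl_df", "tbl", "data.frame"),
            alignment_length = nchar(aa[[1]]), frame_offset = 0L,
            table_id = 5L)
}

# Minimal PDB writer: polymer ALA residues plus ligand heteroatoms.
write_toy_pdb <- function(path, polymer, ligands = NULL, chain = "A") {
  lines <- character(0)
  serial <- 0
  for (i in seq_len(nrow(polymer))) {
    serial <- serial + 1
    p <- polymer[i, ]
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, p$name, p$resid, chain, p$resno, p$x, p$y, p$z, 1, 0, p$elem))
  }
  if (!is.null(ligands)) {
    for (i in seq_len(nrow(ligands))) {
      serial <- serial + 1
      l <- ligands[i, ]
      lines <- c(lines, sprintf(
        "HETATM%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, l$name, l$resid, chain, l$resno, l$x, l$y, l$z, 1, 0, l$elem))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

toy_polymer <- function() {
  tibble::tibble(
    name = rep("CA", 3), resid = rep("ALA", 3), resno = 1:3,
    x = c(0, 10, 20), y = 0, z = 0, elem = "C")
}
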