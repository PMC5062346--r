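.AA20 <- c("G", "A", "V", "L", "M", "I",
           "S", "T", "C", "P", "N", "Q",
           "F", "Y", "W",
           "K", "R", "H",
           "D", "E")

#' The five biochemical residue groups
#'
#' The standard partition of the 20 amino acids used to discount
#' chemically conservative variation: a site whose residues all belong to
#' one group is treated as non-variable regardless of its entropy.
#'
#' @return A named list of five character vectors: `nonpolar_aliphatic`
#'   (G, A, V, L, M, I), `polar_uncharged` (S, T, C, P, N, Q), `aromatic`
#'   (F, Y, W), `positively_charged` (K, R, H), `negatively_charged`
#'   (D, E). The sets are disjoint and cover exactly the 20 standard
#'   residues.
#' @export
biochemical_groups <- function() {
  list(
    nonpolar_aliphatic = c("G", "A", "V", "L", "M", "I"),
    polar_uncharged    = c("S", "T", "C", "P", "N", "Q"),
    aromatic           = c("F", "Y", "W"),
    positively_charged = c("K", "R", "H"),
    negatively_charged = c("D", "E")
  )
}

#' Biochemical group of each residue
#'
#' @param residue Character vector of one-letter residue codes.
#' @return Character vector of group names; errors on a symbol outside
#'   the 20 standard residues.
#' @export
aa_group <- function(residue) {
  groups <- biochemical_groups()
  lookup <- setNames(rep(names(groups), lengths(groups)),
                     unlist(groups, use.names = FALSE))
  bad <- setdiff(unique(residue), names(lookup))
  if (length(bad) > 0L) {
    abort(paste0("Unknown residue symbol(s): ", paste(bad, collapse = " ")))
  }
  unname(lookup[residue])
}
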