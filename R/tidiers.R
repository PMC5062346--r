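#' Tidy a test result
#'
#' @param x A `g_test` or `wilcoxon_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `df`, `p.value`,
#'   `correction`, `method`.
#' @method tidy evo_test
#' @export
tidy.evo_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         correction = x$correction, method = x$method)
}

#' @rdname tidy.evo_test
#' @method glance evo_test
#' @export
glance.evo_test <- function(x, ...) tidy.evo_test(x)

#' Tidy a site profile
#'
#' Flattens the list columns (`groups` to a comma-joined string,
#' `freqs` dropped) for export or joining.
#'
#' @param x A `site_profile`.
#' @param ... Unused.
#' @return A tibble with one row per alignment column.
#' @method tidy site_profile
#' @export
tidy.site_profile <- function(x, ...) {
  flatten_profile(x) |> select(-"freqs")
}

#' Summarise a site profile
#'
#' @param x A `site_profile`.
#' @param ... Unused.
#' @return One-row tibble: column count, class counts, number of
#'   consensus-conserved columns and mean entropy.
#' @method glance site_profile
#' @export
glance.site_profile <- function(x, ...) {
  tibble(n_sites = nrow(x),
         n_conserved = sum(x$class == "conserved", na.rm = TRUE),
         n_nonvariable = sum(x$class == "nonvariable", na.rm = TRUE),
         n_within_group = sum(x$class == "nonvariable_within_group",
                              na.rm = TRUE),
         n_variable = sum(x$class == "variable", na.rm = TRUE),
         n_consensus_conserved = sum(x$consensus_conserved, na.rm = TRUE),
         mean_entropy = mean(x$entropy, na.rm = TRUE))
}

#' Summarise a codon selection profile
#'
#' @param x A `codon_selection_profile`.
#' @param ... Unused.
#' @return One-row tibble with codon count, number of codons with a
#'   defined ratio, and median dN, dS and dN/dS.
#' @method glance codon_selection_profile
#' @export
glance.codon_selection_profile <- function(x, ...) {
  tibble(n_codons = nrow(x),
         n_defined = sum(!is.na(x$dnds)),
         median_dn = median(x$dN, na.rm = TRUE),
         median_ds = median(x$dS, na.rm = TRUE),
         median_dnds = median(x$dnds, na.rm = TRUE))
}
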