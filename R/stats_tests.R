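#' Williams-corrected G-test of independence
#'
#' Log-likelihood-ratio test of independence for an r x c contingency
#' table: G_raw = 2 * sum O * ln(O/E) with expectations from the margins
#' (cells with O = 0 contribute nothing). By default the statistic is
#' divided by the Williams correction factor
#' q = 1 + (N * sum(1/R_i) - 1)(N * sum(1/C_j) - 1) / (6 N (r-1)(c-1)),
#' which improves the chi-square approximation at moderate sample sizes;
#' q > 1 always, so the corrected G is smaller than the raw G. The
#' p-value is the chi-square upper tail with df = (r-1)(c-1).
#'
#' @param table Matrix of nonnegative counts, at least 2 x 2, with no
#'   all-zero row or column.
#' @param williams Apply the Williams correction (default `TRUE`).
#' @return An object of classes `g_test`/`evo_test`: list with
#'   `statistic`, `df`, `p.value`, `correction`, `q`, `table`, `method`.
#' @examples
#' g_test(matrix(c(16, 143, 7, 53), 2, byrow = TRUE))
#' @export
g_test <- function(table, williams = TRUE) {
  m <- as.matrix(table)
  if (nrow(m) < 2L || ncol(m) < 2L) abort("Table must be at least 2x2.")
  if (any(m < 0) || any(m != round(m))) {
    abort("Table must contain nonnegative integer counts.")
  }
  R <- rowSums(m); C <- colSums(m); N <- sum(m)
  if (any(R == 0) || any(C == 0)) {
    abort("Zero row or column margin; collapse the degenerate categories.")
  }
  E <- outer(R, C) / N
  G_raw <- 2 * sum(ifelse(m > 0, m * log(m / E), 0))
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  q <- 1
  if (williams) {
    q <- 1 + ((N * sum(1 / R) - 1) * (N * sum(1 / C) - 1)) / (6 * N * df)
  }
  G <- G_raw / q
  structure(list(statistic = G, df = df,
                 p.value = chi2_upper_tail(G, df),
                 correction = if (williams) "williams" else "none",
                 q = q, table = m,
                 method = "G-test of independence"),
            class = c("g_test", "evo_test"))
}

#' Chi-square upper-tail probability
#'
#' Survival function of the chi-square distribution; for df = 1 it
#' equals 2 * (1 - Phi(sqrt(x))).
#'
#' @param x Nonnegative statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Upper-tail probability in [0, 1].
#' @export
chi2_upper_tail <- function(x, df) {
  stopifnot(all(x >= 0), all(df >= 1))
  pchisq(x, df, lower.tail = FALSE)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test with midranks for ties. The reported
#' statistic W is the Mann-Whitney U of the first sample, so
#' U_x + U_y = n_x * n_y. The default p-value uses the normal
#' approximation with tie and continuity corrections (appropriate for
#' the ~219-codon samples this package compares); an exact p-value (no
#' ties) is used when both samples have at most 10 values, or on
#' request.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param method `"auto"` (exact when n_x, n_y <= 10 and no ties),
#'   `"normal"` or `"exact"`.
#' @return An object of classes `wilcoxon_test`/`evo_test` with
#'   `statistic` (U of `x`), `p.value`, `n_x`, `n_y`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, method = c("auto", "normal", "exact")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) abort("Both samples must be non-empty.")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (method == "auto") {
    method <- if (nx <= 10 && ny <= 10 && !ties) "exact" else "normal"
  }
  if (all(c(x, y) == c(x, y)[1])) {
    warn("All values identical across both samples; p = 1.")
    p <- 1
  } else if (method == "exact") {
    if (ties) abort("Exact method requires untied data.")
    p <- min(1, 2 * min(stats::pwilcox(U, nx, ny),
                        stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)))
  } else {
    N <- nx + ny
    tie_counts <- table(c(x, y))
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 *
      ((N + 1) - sum(tie_counts^3 - tie_counts) / (N * (N - 1)))
    if (sigma2 <= 0) {
      warn("Zero rank variance; p = 1.")
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  structure(list(statistic = U, p.value = p, n_x = nx, n_y = ny,
                 df = NA_real_, correction = method,
                 method = "Wilcoxon rank-sum test"),
            class = c("wilcoxon_test", "evo_test"))
}

#' @export
print.evo_test <- function(x, ...) {
  cat("<", x$method, ">\n  statistic = ", format(x$statistic, digits = 6),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      ", p = ", format(x$p.value, digits = 4),
      " (", x$correction, ")\n", sep = "")
  invisible(x)
}
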