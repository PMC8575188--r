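#' Sidak-corrected per-comparison significance threshold
#'
#' For a family-wise error rate `family_alpha` over `m` independent
#' comparisons, the per-comparison threshold is
#' `1 - (1 - family_alpha)^(1/m)`. With family alpha 0.01 over the six
#' pairwise day comparisons this evaluates to 0.00167 (5 d.p.).
#'
#' @param family_alpha family-wise alpha in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return Per-comparison threshold.
#' @export
sidak_threshold <- function(family_alpha, m) {
  if (!is.finite(family_alpha) || family_alpha <= 0 || family_alpha >= 1)
    stop("family_alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  1 - (1 - family_alpha)^(1 / m)
}

#' Pairwise two-sided Mann-Whitney rank tests across groups
#'
#' One two-sided U-test per pair of groups. When both groups have at most
#' `exact_max` observations and the pooled data are tie-free, the exact
#' null distribution of U is used; otherwise the normal approximation with
#' tie correction and continuity correction. Returns a symmetric p-value
#' matrix with `NA` on the diagonal.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @param exact_max switch point for the exact test (default 8).
#' @return Symmetric matrix of p-values.
#' @export
ranktest_pairwise <- function(groups, exact_max = 8L) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(!vapply(groups, length, 1L)))
    stop("empty group")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs n >= 2")
  k <- length(groups)
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("g", seq_len(k))
  p <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- groups[[i]]; y <- groups[[j]]
    use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
      !anyDuplicated(c(x, y))
    pv <- if (use_exact)
      stats::wilcox.test(x, y, exact = TRUE)$p.value
    else
      suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    p[i, j] <- p[j, i] <- pv
  }
  p
}

#' Shapiro-Wilk normality screen per group
#'
#' Advisory only: groups are screened for normality but rank tests are run
#' regardless. Groups outside the testable size range (3 <= n <= 5000) are
#' flagged `NA` with `testable = FALSE`.
#'
#' @param groups named list of numeric vectors.
#' @return Data frame: `group`, `n`, `p`, `testable`.
#' @export
normality_screen <- function(groups) {
  nms <- names(groups)
  if (is.null(nms)) nms <- paste0("g", seq_along(groups))
  rows <- lapply(seq_along(groups), function(i) {
    x <- groups[[i]]
    ok <- length(x) >= 3L && length(x) <= 5000L && stats::sd(x) > 0
    data.frame(group = nms[i], n = length(x),
               p = if (ok) stats::shapiro.test(x)$p.value else NA_real_,
               testable = ok, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kruskal-Wallis omnibus test across groups
#'
#' Tie-corrected Kruskal-Wallis H with chi-square p-value; the omnibus
#' check that the day groups are drawn from distinct distributions.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return List: `statistic` (H), `p`, `df`.
#' @export
omnibus_independence <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1L)
    stop("degenerate input: all values identical")
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Full statistical comparison report for one quantity
#'
#' The comparison layer applied to each quantity: per-group normality
#' screen, all pairwise two-sided rank tests, Sidak per-comparison
#' threshold (family alpha over the `choose(k, 2)` pairs), significance
#' flags, and the omnibus Kruskal-Wallis p.
#'
#' @param groups named list of per-day numeric vectors.
#' @param quantity label carried into the report.
#' @param family_alpha family-wise alpha (default 0.01, giving the
#'   0.00167 threshold for 4 day groups).
#' @return A `comparison_report` list.
#' @export
comparison_report <- function(groups, quantity = "value",
                              family_alpha = 0.01) {
  m <- choose(length(groups), 2L)
  alpha <- sidak_threshold(family_alpha, m)
  p <- ranktest_pairwise(groups)
  structure(list(quantity = quantity,
                 normality = normality_screen(groups),
                 pairwise_p = p,
                 sidak_alpha = alpha,
                 significant = p < alpha,
                 omnibus_p = omnibus_independence(groups)$p,
                 family_alpha = family_alpha, m = m),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s: %d pairwise tests, Sidak alpha %.5f\n",
              x$quantity, x$m, x$sidak_alpha))
  print(signif(x$pairwise_p, 3))
  cat(sprintf("omnibus Kruskal-Wallis p = %.3g\n", x$omnibus_p))
  invisible(x)
}
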