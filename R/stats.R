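#' Kruskal-Wallis test with Dunn's multiple comparison
#'
#' Rank-based comparison of p-distance distributions across loci: the
#' tie-corrected Kruskal-Wallis H statistic with a chi-square p-value on
#' k - 1 degrees of freedom (via [stats::kruskal.test()]), followed by
#' Dunn's z-tests on pairwise differences of mean ranks, adjusted for
#' multiple comparisons (Bonferroni by default).
#'
#' @param groups Named list of numeric vectors (e.g. inter-specific
#'   p-distances per locus).
#' @param adjust P-value adjustment for the pairwise tests:
#'   `"bonferroni"` (default), `"holm"` or `"none"`.
#' @param alpha Significance level for flagging pairs (default 0.05).
#' @return A list of class `kw_dunn`: `statistic` (H), `df`, `p_value`,
#'   and `pairwise` (data frame: `pair`, `z`, `p_raw`, `p_adj`,
#'   `significant`).
#' @examples
#' kruskal_dunn(list(a = c(1, 2, 3), b = c(10, 20, 30)))$statistic
#' @export
kruskal_dunn <- function(groups, adjust = c("bonferroni", "holm", "none"),
                         alpha = 0.05) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2L) stop("need at least two groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)),
                   levels = names(groups))
  if (length(unique(values)) == 1L) {
    kt <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
               parameter = c(df = length(groups) - 1L), p.value = 1)
  } else {
    kt <- kruskal.test(values, labels)
  }
  # Dunn's z on mean ranks, with tie correction
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  rbar <- tapply(r, labels, mean)
  n <- tapply(r, labels, length)
  combs <- combn(names(groups), 2)
  pw <- apply(combs, 2, function(pr) {
    z <- (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(sigma2 * (1 / n[pr[1]] + 1 / n[pr[2]]))
    p <- 2 * pnorm(-abs(z))
    c(z = unname(z), p = unname(p))
  })
  p_adj <- p.adjust(pw["p", ], method = adjust)
  pairwise <- data.frame(pair = paste(combs[1, ], combs[2, ], sep = " vs "),
                         z = pw["z", ], p_raw = pw["p", ], p_adj = p_adj,
                         significant = p_adj < alpha,
                         stringsAsFactors = FALSE)
  rownames(pairwise) <- NULL
  structure(list(statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = kt$p.value,
                 pairwise = pairwise, adjust = adjust),
            class = "kw_dunn")
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("Dunn's pairwise comparisons (%s-adjusted):\n", x$adjust))
  print(x$pairwise, digits = 4)
  invisible(x)
}

# exact null distribution of the signed-rank statistic W+ by the shift
# algorithm over doubled mid-ranks (doubling makes tied mid-ranks integral)
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1:(total + 1L - r)]
    f <- g
  }
  f / sum(f)
}

#' Wilcoxon matched-pair signed-rank test
#'
#' Tests whether paired quantities differ systematically — in barcode-gap
#' evaluation, whether per-species minimum inter-specific distances exceed
#' the matched maximum intra-specific distances. Zero differences are
#' dropped and ties receive mid-ranks (Wilcoxon's original treatment).
#' For `n <= exact_limit` non-zero pairs the p-value is exact, computed
#' from the full permutation distribution of the positive-rank sum; above
#' that, a normal approximation with continuity correction and tie-corrected
#' variance is used.
#'
#' @param x Numeric vector (e.g. minimum inter-specific distances), or a
#'   two-column matrix/data frame of pairs.
#' @param y Numeric vector matched to `x` (e.g. maximum intra-specific
#'   distances); omit when `x` has two columns.
#' @param alternative `"two.sided"` (default), `"greater"` (x tends to
#'   exceed y) or `"less"`.
#' @param exact_limit Maximum number of non-zero pairs for the exact
#'   distribution (default 25).
#' @return A list of class `wilcoxon_matched`: `statistic` (W+, the
#'   positive-rank sum), `n_used` (non-zero pairs), `p_value`, `exact`,
#'   `direction` (`"x>y"`, `"x<y"` or `"none"`).
#' @examples
#' # all six pairs positive with distinct magnitudes: one-sided p = 1/64
#' wilcoxon_matched(2^(1:6), rep(0, 6), alternative = "greater")$p_value
#' @export
wilcoxon_matched <- function(x, y = NULL,
                             alternative = c("two.sided", "greater", "less"),
                             exact_limit = 25L) {
  alternative <- match.arg(alternative)
  if (is.null(y)) {
    if (NCOL(x) != 2L) stop("supply y, or a two-column x")
    y <- x[, 2]; x <- x[, 1]
  }
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) == 0L) stop("no pairs")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(statistic = 0, n_used = 0L, p_value = 1,
                          exact = TRUE, direction = "none",
                          alternative = alternative),
                     class = "wilcoxon_matched"))
  }
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  EW <- sum(rk) / 2
  direction <- if (W > EW) "x>y" else if (W < EW) "x<y" else "none"
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * rk))
    null <- signed_rank_null(r2)
    w2 <- as.integer(round(2 * W))
    p_ge <- sum(null[(w2 + 1L):length(null)])
    p_le <- sum(null[1:(w2 + 1L)])
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    exact <- TRUE
  } else {
    ties <- table(rk)
    varW <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z_g <- (W - EW - 0.5) / sqrt(varW)
    z_l <- (W - EW + 0.5) / sqrt(varW)
    p_ge <- pnorm(z_g, lower.tail = FALSE)
    p_le <- pnorm(z_l)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    exact <- FALSE
  }
  structure(list(statistic = W, n_used = n, p_value = p, exact = exact,
                 direction = direction, alternative = alternative),
            class = "wilcoxon_matched")
}

#' @export
print.wilcoxon_matched <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon matched-pair test: W+ = %g on %d non-zero pairs\n  p = %.4g (%s, %s), direction: %s\n",
    x$statistic, x$n_used, x$p_value,
    if (x$exact) "exact" else "normal approximation",
    x$alternative, x$direction))
  invisible(x)
}
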