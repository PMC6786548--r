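#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Computes the one-way ANOVA F statistic from group sums of squares and
#' two-sided Dunnett-adjusted p-values of each group against a designated
#' reference group. Adjusted p-values are evaluated on the multivariate t
#' distribution of the comparison statistics (correlation
#' `rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j + n0)))`) using the seeded
#' Genz-Bretz Monte-Carlo algorithm of \pkg{mvtnorm}; a single comparison
#' reduces to the closed-form two-sided t-test.
#'
#' @param values Numeric response vector.
#' @param group Group factor (or coercible).
#' @param reference Reference group label; default = first factor level.
#' @param seed Seed for the Monte-Carlo evaluation of multivariate-t
#'   probabilities.
#' @return Object of class `group_comparison`: list with `F`, `df`,
#'   `p_anova`, and a `comparisons` data frame (group, estimate, t,
#'   p_adjusted).
#' @export
compare_groups <- function(values, group, reference = NULL, seed = 1L) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("each group needs n >= 2")
  if (is.null(reference)) reference <- levels(group)[1]
  if (!reference %in% levels(group)) stop("unknown reference group")
  group <- stats::relevel(group, ref = reference)
  n <- tapply(values, group, length)
  m <- tapply(values, group, mean)
  N <- sum(n); k <- nlevels(group)
  grand <- mean(values)
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum((values - m[group])^2)
  df1 <- k - 1; df2 <- N - k
  if (ss_within == 0) {
    # exact ties within every group: F is 0/0 for identical groups, Inf for
    # separated ones; document the convention F = 0 when between-SS is 0 too
    Fstat <- if (ss_between == 0) 0 else Inf
  } else {
    Fstat <- (ss_between / df1) / (ss_within / df2)
  }
  p_anova <- if (is.finite(Fstat)) stats::pf(Fstat, df1, df2, lower.tail = FALSE)
             else 0
  s2 <- if (df2 > 0) ss_within / df2 else NA_real_
  others <- levels(group)[-1]
  est <- m[others] - m[[reference]]
  se <- sqrt(s2 * (1 / n[others] + 1 / n[[reference]]))
  tval <- est / se
  tval[!is.finite(tval)] <- sign(est[!is.finite(tval)]) * Inf
  lam <- sqrt(n[others] / (n[others] + n[[reference]]))
  Rho <- outer(lam, lam); diag(Rho) <- 1
  padj <- vapply(seq_along(tval), function(i) {
    ti <- abs(tval[i])
    if (!is.finite(ti)) return(0)
    if (length(tval) == 1) return(2 * stats::pt(-ti, df2))
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    pr <- mvtnorm::pmvt(lower = rep(-ti, length(tval)),
                        upper = rep(ti, length(tval)),
                        df = df2, corr = Rho,
                        algorithm = mvtnorm::GenzBretz(abseps = 1e-5))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    max(0, min(1, 1 - as.numeric(pr)))
  }, numeric(1))
  structure(list(F = Fstat, df = c(df1, df2), p_anova = p_anova,
                 reference = reference,
                 comparisons = data.frame(group = others, estimate = as.numeric(est),
                                          t = as.numeric(tval),
                                          p_adjusted = padj,
                                          row.names = NULL)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p_anova))
  cat(sprintf("Dunnett comparisons vs '%s':\n", x$reference))
  print(x$comparisons, digits = 4)
  invisible(x)
}
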