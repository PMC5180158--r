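# Group-comparison statistics: two-way ANOVA with sequential (Type-I)
# sums of squares and Tukey HSD post-hoc tests. Thin, validated surfaces
# over stats::aov / stats::TukeyHSD, which already implement the
# sequential decomposition and the numerically integrated studentized
# range distribution.

#' Two-way ANOVA with sequential sums of squares
#'
#' Fits `values ~ factor_a * factor_b` (or the additive model when the
#' interaction is inestimable or disabled) and reports the sequential
#' (Type-I) ANOVA table in declared term order. With unbalanced groups the
#' sequential decomposition depends on term order; swap `factor_a` and
#' `factor_b` to change it.
#'
#' @param values Numeric response (per-mil isotope values).
#' @param factor_a,factor_b Factor labels, same length as `values`; each
#'   needs >= 2 observed levels.
#' @param interaction Include the interaction term when estimable.
#' @return An object of class `anova_result`: data frame `table` with one
#'   row per term plus residuals (`term`, `df`, `ss`, `ms`, `F`, `p`), the
#'   fitted `aov` object, and `n`.
#' @export
two_way_anova <- function(values, factor_a, factor_b, interaction = TRUE) {
  if (length(values) != length(factor_a) ||
      length(values) != length(factor_b)) {
    stop_input("inputs must have equal length")
  }
  keep <- is.finite(values) & !is.na(factor_a) & !is.na(factor_b)
  values <- values[keep]
  a <- droplevels(factor(factor_a[keep]))
  b <- droplevels(factor(factor_b[keep]))
  if (nlevels(a) < 2L || nlevels(b) < 2L) {
    stop_input("each factor needs at least 2 observed levels")
  }
  dat <- data.frame(y = values, a = a, b = b)
  counts <- table(a, b)
  use_int <- interaction && all(counts > 0L)
  form <- if (use_int) y ~ a + b + a:b else y ~ a + b
  npar <- nlevels(a) + nlevels(b) - 1L +
    if (use_int) (nlevels(a) - 1L) * (nlevels(b) - 1L) else 0L
  if (nrow(dat) <= npar) {
    stop_input("design inestimable: n must exceed the parameter count")
  }
  fit <- aov(form, data = dat)
  tab <- withCallingHandlers(
    anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  out <- data.frame(term = rownames(tab), df = tab$Df, ss = tab$`Sum Sq`,
                    ms = tab$`Mean Sq`, F = tab$`F value`,
                    p = tab$`Pr(>F)`, row.names = NULL)
  # a zero-variance response gives 0/0 F statistics; report F = 0, p = 1
  # (detected relative to the response scale to absorb rounding noise)
  if (sum(out$ss) < 1e-10 * (1 + mean(values)^2)) {
    nt <- nrow(out) - 1L
    out$ss <- out$ms <- rep(0, nrow(out))
    out$F[seq_len(nt)] <- 0
    out$p[seq_len(nt)] <- 1
  }
  structure(list(table = out, fit = fit, n = nrow(dat)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (n = %d), sequential SS\n", x$n))
  print(x$table, digits = 4)
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' One-way group comparison with studentized-range-adjusted p-values and
#' simultaneous confidence intervals.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, >= 2 observations each).
#' @param alpha Family-wise error rate for the confidence level.
#' @return Data frame with `comparison`, `diff`, `lwr`, `upr`, `p_adj` and
#'   a `significant` flag at `alpha`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  g <- droplevels(factor(groups[keep]))
  if (nlevels(g) < 2L) stop_input("need at least 2 groups")
  if (any(table(g) < 2L)) {
    stop_input("every group needs at least 2 observations")
  }
  fit <- aov(values ~ g)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha, row.names = NULL)
}
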