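# Group comparisons from summary statistics, and small inferential helpers.

#' Welch's t-test and Cohen's d from summary statistics
#'
#' Computes the Welch (unequal-variance) two-sample t statistic, its
#' Welch-Satterthwaite degrees of freedom, the two-sided p value, and
#' pooled-SD Cohen's d from group means, SDs and sizes.  Needed because
#' published group characteristics tables print only summaries, never raw
#' scores.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return List with `t` (sign matches `m2 - m1`), `df`, `p` (two-sided),
#'   and `d` (Cohen's d, `(n-1)`-weighted pooled SD, reported unsigned).
#' @examples
#' welch_from_summary(10.29, 2.50, 33, 11.50, 2.83, 30)
#' @export
welch_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) .abort("each group needs n >= 2", "vm_bad_summary")
  if (s1 <= 0 || s2 <= 0) .abort("SDs must be > 0", "vm_bad_summary")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t <- (m2 - m1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  list(t = t, df = df, p = p, d = abs(m2 - m1) / sp)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Wrapper over [stats::p.adjust()] with `method = "holm"`: step-down
#' Bonferroni with enforced monotonicity, clipped at 1.
#'
#' @param p Vector of raw p values in \[0, 1\].
#' @return Adjusted p values, same order as the input.
#' @export
holm_bonferroni <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    .abort("p values must lie in [0, 1]", "vm_bad_p")
  }
  p.adjust(p, method = "holm")
}

#' Pearson correlation with p value
#'
#' Wrapper over [stats::cor.test()].
#'
#' @param x,y Equal-length numeric vectors (n >= 3 complete pairs).
#' @return List with `r`, `df`, and two-sided `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) .abort("x and y must have equal length", "vm_bad_input")
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) .abort("need at least 3 complete pairs", "vm_bad_input")
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}

#' Welch comparison table for a participant roster
#'
#' Runs [welch_from_summary()] for each background measure of a roster,
#' comparing autism vs non-autism groups.
#'
#' @param roster Tibble from [participant_roster()].
#' @param measures Character vector of roster columns to compare.
#' @return Tibble with one row per measure: group means/SDs, `t`, `df`,
#'   `p`, `d`.
#' @export
roster_welch_table <- function(roster,
                               measures = c("age_years", "musical_training_years",
                                            "rspm", "ppvt_r", "digit_span")) {
  g1 <- roster[roster$group == "autism", ]
  g2 <- roster[roster$group == "non_autism", ]
  dplyr::bind_rows(lapply(measures, function(m) {
    x1 <- g1[[m]]; x2 <- g2[[m]]
    w <- welch_from_summary(mean(x1), sd(x1), length(x1),
                            mean(x2), sd(x2), length(x2))
    tibble::tibble(measure = m,
                   autism_mean = mean(x1), autism_sd = sd(x1),
                   non_autism_mean = mean(x2), non_autism_sd = sd(x2),
                   t = abs(w$t), df = w$df, p = w$p, d = w$d)
  }))
}
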