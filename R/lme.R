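# Effect-coded linear mixed models over the trial table, with the
# deterministic random-structure reduction protocol and marginal-means
# contrasts.
#
# Fixed effects: Group (+1 autism / -1 non-autism), Condition (+1 music /
# -1 speech), their interaction, and mean-centered PPVT-R and age.  Random
# factors: participant and item, crossed.  Fixed-effect tests use
# Satterthwaite degrees of freedom (lmerTest).

ALL_RANEF_COMPONENTS <- c("subject_intercept", "subject_condition_slope",
                          "item_intercept", "item_condition_slope",
                          "item_group_slope")

#' Specify a mixed model for one imitation metric
#'
#' The default is the maximal random structure the design licenses:
#' by-participant intercepts and condition slopes, by-item intercepts,
#' condition slopes and (optionally) group slopes, all correlated.
#'
#' @param response Name of the metric column to model (e.g.
#'   `"abs_pitch_dev_cents"`).
#' @param components Character vector of random-effect components, a subset
#'   of `"subject_intercept"`, `"subject_condition_slope"`,
#'   `"item_intercept"`, `"item_condition_slope"`, `"item_group_slope"`.
#' @param correlated Estimate correlations among random effects that share a
#'   grouping factor.
#' @param include_item_group_slope Convenience switch removing
#'   `"item_group_slope"` from the default components (group is a
#'   between-participant factor, but items see both groups).
#' @param covariates Fixed covariate columns (already centered) to include.
#' @return An object of class `vm_lme_spec`.
#' @export
lme_spec <- function(response,
                     components = ALL_RANEF_COMPONENTS,
                     correlated = TRUE,
                     include_item_group_slope = TRUE,
                     covariates = c("ppvt_r_centered", "age_centered")) {
  components <- match.arg(components, ALL_RANEF_COMPONENTS, several.ok = TRUE)
  if (!include_item_group_slope) {
    components <- setdiff(components, "item_group_slope")
  }
  structure(list(response = response, components = unique(components),
                 correlated = correlated, covariates = covariates),
            class = "vm_lme_spec")
}

#' @export
print.vm_lme_spec <- function(x, ...) {
  cat(sprintf("<vm_lme_spec> %s ~ Group * Condition + %s\n  random: %s (%s)\n",
              x$response, paste(x$covariates, collapse = " + "),
              paste(x$components, collapse = ", "),
              if (x$correlated) "correlated" else "uncorrelated"))
  invisible(x)
}

# one lme4 random-effects term per grouping factor (or per component when
# uncorrelated), built from the component set
.ranef_terms <- function(components, correlated) {
  grp <- list(subject = list(id = "participant_id",
                             int = "subject_intercept",
                             slopes = c(condition_c = "subject_condition_slope")),
              item = list(id = "item_id",
                          int = "item_intercept",
                          slopes = c(condition_c = "item_condition_slope",
                                     group_c = "item_group_slope")))
  terms <- character(0)
  for (g in grp) {
    has_int <- g$int %in% components
    slopes <- names(g$slopes)[g$slopes %in% components]
    if (!has_int && !length(slopes)) next
    if (correlated) {
      lhs <- paste(c(if (has_int) "1" else "0", slopes), collapse = " + ")
      terms <- c(terms, sprintf("(%s | %s)", lhs, g$id))
    } else {
      if (has_int) terms <- c(terms, sprintf("(1 | %s)", g$id))
      for (s in slopes) terms <- c(terms, sprintf("(0 + %s | %s)", s, g$id))
    }
  }
  terms
}

.lme_formula <- function(spec) {
  fixed <- paste(c("group * condition", spec$covariates), collapse = " + ")
  rand <- .ranef_terms(spec$components, spec$correlated)
  if (!length(rand)) .abort("no random-effect components left", "vm_no_ranef")
  as.formula(paste(spec$response, "~", fixed, "+", paste(rand, collapse = " + ")))
}

.prepare_lme_data <- function(table, spec) {
  need <- c(spec$response, "group", "condition", "participant_id", "item_id",
            spec$covariates)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    .abort(paste0("trial table lacks columns: ", paste(miss, collapse = ", ")),
           "vm_bad_table")
  }
  dat <- as.data.frame(table)[, unique(c(need, "group_c", "condition_c")[
    unique(c(need, "group_c", "condition_c")) %in% names(table)])]
  dat <- dat[!is.na(dat[[spec$response]]), , drop = FALSE]
  # alphabetical level order puts autism and music first, so contr.sum
  # assigns +1 to autism and music, the documented orientation
  dat$group <- factor(dat$group, levels = GROUPS)
  dat$condition <- factor(dat$condition, levels = c("music", "speech"))
  stats::contrasts(dat$group) <- stats::contr.sum(2)
  stats::contrasts(dat$condition) <- stats::contr.sum(2)
  if (!"group_c" %in% names(dat)) dat$group_c <- ifelse(dat$group == "autism", 1, -1)
  if (!"condition_c" %in% names(dat)) dat$condition_c <- ifelse(dat$condition == "music", 1, -1)
  dat
}

.fit_once <- function(spec, dat) {
  fml <- .lme_formula(spec)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(fml, data = dat, REML = TRUE,
                     control = lme4::lmerControl(optimizer = "bobyqa",
                                                 calc.derivs = TRUE)))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(fit = NULL, ok = FALSE, singular = NA,
                reason = conditionMessage(fit)))
  }
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  conv_fail <- any(grepl("failed to converge|unable to evaluate|degenerate",
                         msgs %||% character(0)))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  list(fit = fit, ok = !conv_fail && !singular, singular = singular,
       reason = if (conv_fail) paste(msgs, collapse = "; ")
                else if (singular) "singular fit" else "converged")
}

# map VarCorr rows to component ids and return estimated variances
.component_variances <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  vc <- vc[is.na(vc$var2) & vc$grp != "Residual", , drop = FALSE]
  base <- sub("\\..*$", "", vc$grp)
  comp <- character(nrow(vc))
  comp[base == "participant_id" & vc$var1 == "(Intercept)"] <- "subject_intercept"
  comp[base == "participant_id" & vc$var1 == "condition_c"] <- "subject_condition_slope"
  comp[base == "item_id" & vc$var1 == "(Intercept)"] <- "item_intercept"
  comp[base == "item_id" & vc$var1 == "condition_c"] <- "item_condition_slope"
  comp[base == "item_id" & vc$var1 == "group_c"] <- "item_group_slope"
  setNames(vc$vcov, comp)
}

# deterministic order for dropping components: slopes before intercepts;
# among equal (or unknown) variances, item-side before subject-side
.drop_candidates <- function(components) {
  slopes <- intersect(c("item_group_slope", "item_condition_slope",
                        "subject_condition_slope"), components)
  if (length(slopes)) return(slopes)
  intersect(c("item_intercept", "subject_intercept"), components)
}

.pick_drop <- function(components, variances) {
  cand <- .drop_candidates(components)
  v <- variances[cand]
  v[is.na(v)] <- Inf
  # order() is stable, so the item-before-subject order in cand breaks ties
  cand[order(v)][1]
}

#' Reduce the random-effects structure until the model converges
#'
#' Implements the reduction protocol: fit the requested (maximal) model;
#' if it fails to converge (or is singular), first remove the random
#' correlations; if it still fails, iteratively remove the random-effect
#' component with the smallest estimated variance -- slopes before
#' intercepts, item-side before subject-side on ties -- refitting after each
#' removal, until a model converges.  The sequence is deterministic, and the
#' full trail of attempts is returned.
#'
#' @param table Trial table (from [build_trial_table()] or
#'   [simulate_study()]).
#' @param spec Starting [lme_spec()].
#' @return List with `spec` (the final, converged spec), `fit` (the fitted
#'   `lmerModLmerTest`), `trail` (character vector of attempted steps), and
#'   `data` (the model data).  Errors with class `vm_no_convergence` when
#'   nothing converges.
#' @export
reduce_random_structure <- function(table, spec) {
  dat <- .prepare_lme_data(table, spec)
  trail <- character(0)
  step <- function(s, label) {
    r <- .fit_once(s, dat)
    trail <<- c(trail, sprintf("%s: %s", label, r$reason))
    r
  }
  r <- step(spec, sprintf("fit [%s%s]", paste(spec$components, collapse = "+"),
                          if (spec$correlated) ", correlated" else ", uncorrelated"))
  if (r$ok) return(list(spec = spec, fit = r$fit, trail = trail, data = dat))
  if (spec$correlated && length(spec$components) > 1) {
    spec$correlated <- FALSE
    r <- step(spec, "drop correlations")
    if (r$ok) return(list(spec = spec, fit = r$fit, trail = trail, data = dat))
  }
  last_fit <- r$fit
  while (length(spec$components) > 1) {
    variances <- if (!is.null(last_fit)) .component_variances(last_fit) else numeric(0)
    drop <- .pick_drop(spec$components, variances)
    spec$components <- setdiff(spec$components, drop)
    r <- step(spec, sprintf("drop %s (var=%.4g)", drop,
                            variances[drop] %||% NA_real_))
    if (r$ok) return(list(spec = spec, fit = r$fit, trail = trail, data = dat))
    if (!is.null(r$fit)) last_fit <- r$fit
  }
  .abort(paste0("no random structure converged; trail:\n  ",
                paste(trail, collapse = "\n  ")), "vm_no_convergence")
}

EFFECT_LABELS <- c("(Intercept)" = "Intercept", "group1" = "Group",
                   "condition1" = "Condition",
                   "ppvt_r_centered" = "PPVT-R", "age_centered" = "Age",
                   "group1:condition1" = "Group x Condition")

#' Fit the effect-coded mixed model for one metric
#'
#' REML fit with crossed participant and item random factors and
#' Satterthwaite fixed-effect tests.  With `reduce = TRUE` (default) the
#' random structure is simplified by [reduce_random_structure()] until the
#' fit converges; with `reduce = FALSE` the requested structure is fit once
#' and the convergence state reported as-is.
#'
#' @param table Trial table.
#' @param spec An [lme_spec()], or a metric name (a default maximal spec is
#'   built).
#' @param reduce Apply the reduction protocol on convergence failure.
#' @return An object of class `vm_lme`: fixed-effect table (`coefficients`:
#'   effect, estimate, se, df, t, p), random-effect variances (`varcorr`),
#'   `converged`, `singular`, the reduction `trail`, the final `spec`, and
#'   the underlying `fit`.
#' @export
fit_lme <- function(table, spec, reduce = TRUE) {
  if (is.character(spec)) spec <- lme_spec(spec)
  stopifnot(inherits(spec, "vm_lme_spec"))
  if (reduce) {
    red <- reduce_random_structure(table, spec)
    fit <- red$fit; final_spec <- red$spec; trail <- red$trail; dat <- red$data
    converged <- TRUE
  } else {
    dat <- .prepare_lme_data(table, spec)
    r <- .fit_once(spec, dat)
    if (is.null(r$fit)) .abort(paste0("model could not be fit: ", r$reason),
                               "vm_fit_error")
    fit <- r$fit; final_spec <- spec
    trail <- sprintf("fit (no reduction): %s", r$reason)
    converged <- r$ok
  }
  ct <- coef(summary(fit))   # lmerTest: Satterthwaite df
  eff <- rownames(ct)
  coefs <- tibble::tibble(
    effect = unname(ifelse(eff %in% names(EFFECT_LABELS),
                           EFFECT_LABELS[eff], eff)),
    estimate = unname(ct[, "Estimate"]), se = unname(ct[, "Std. Error"]),
    df = unname(ct[, "df"]), t = unname(ct[, "t value"]),
    p = unname(ct[, "Pr(>|t|)"]))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(response = final_spec$response, coefficients = coefs,
                 varcorr = tibble::as_tibble(vc), converged = converged,
                 singular = lme4::isSingular(fit, tol = 1e-4),
                 trail = trail, spec = final_spec, fit = fit, data = dat,
                 n_obs = nrow(dat)),
            class = "vm_lme")
}

#' @export
print.vm_lme <- function(x, digits = 3, ...) {
  cat(sprintf("Linear mixed model for %s (n = %d trials)\n", x$response, x$n_obs))
  cat(sprintf("Random structure: %s (%s)%s\n",
              paste(x$spec$components, collapse = ", "),
              if (x$spec$correlated) "correlated" else "uncorrelated",
              if (x$singular) " [singular]" else ""))
  tab <- as.data.frame(x$coefficients)
  tab[, -1] <- lapply(tab[, -1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Extract one fixed effect from a fitted model
#'
#' @param fit A `vm_lme`.
#' @param effect Label, e.g. `"Group"` or `"Group x Condition"`.
#' @return One-row tibble (estimate, se, df, t, p).
#' @export
fixed_effect <- function(fit, effect) {
  row <- fit$coefficients[fit$coefficients$effect == effect, ]
  if (nrow(row) != 1) .abort(paste0("no such effect: ", effect), "vm_bad_effect")
  row
}

#' Simple-effect contrasts with Holm-Bonferroni correction
#'
#' Estimated marginal means of the Group x Condition cells on the
#' fixed-effect scale (covariates at their centered means), with pairwise
#' group-within-condition and condition-within-group contrasts.  Holm
#' correction is applied across the whole per-model family of four
#' contrasts.
#'
#' @param fit A `vm_lme`.
#' @return Tibble with `contrast`, `within`, `estimate`, `se`, `df`, `t`,
#'   `p_raw`, `p_holm`.
#' @export
marginal_means_contrasts <- function(fit) {
  stopifnot(inherits(fit, "vm_lme"))
  emm_g <- emmeans::emmeans(fit$fit, ~ group | condition, data = fit$data,
                            lmer.df = "satterthwaite")
  emm_c <- emmeans::emmeans(fit$fit, ~ condition | group, data = fit$data,
                            lmer.df = "satterthwaite")
  cg <- as.data.frame(emmeans::contrast(emm_g, "pairwise", adjust = "none"))
  cc <- as.data.frame(emmeans::contrast(emm_c, "pairwise", adjust = "none"))
  out <- tibble::tibble(
    contrast = c(as.character(cg$contrast), as.character(cc$contrast)),
    within = c(as.character(cg$condition), as.character(cc$group)),
    estimate = c(cg$estimate, cc$estimate),
    se = c(cg$SE, cc$SE),
    df = c(cg$df, cc$df),
    t = c(cg$t.ratio, cc$t.ratio),
    p_raw = c(cg$p.value, cc$p.value))
  out$p_holm <- holm_bonferroni(out$p_raw)
  out
}
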