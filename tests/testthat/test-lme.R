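# Mixed-model layer: formula construction, reduction protocol, effect
# coding, and marginal-means contrasts.

# simulate trial rows straight from the mixed-model equation, with explicit
# random-effect SDs, so the fitting layer is tested against known structure
make_lme_data <- function(n_subj = 30, n_item = 16,
                          beta = c(int = 100, group = 10, condition = -20,
                                   gxc = 5),
                          sd_subj_int = 15, sd_subj_slope = 6,
                          sd_item_int = 10, sd_item_slope = 4,
                          sd_item_group = 0, sigma = 20) {
  subj <- sprintf("p%02d", seq_len(n_subj))
  item <- sprintf("i%02d", seq_len(n_item))
  grp <- rep(c("autism", "non_autism"), length.out = n_subj)
  b0s <- rnorm(n_subj, 0, sd_subj_int); b1s <- rnorm(n_subj, 0, sd_subj_slope)
  b0i <- rnorm(n_item, 0, sd_item_int); b1i <- rnorm(n_item, 0, sd_item_slope)
  b2i <- rnorm(n_item, 0, sd_item_group)
  df <- expand.grid(s = seq_len(n_subj), i = seq_len(n_item),
                    condition = c("speech", "music"),
                    stringsAsFactors = FALSE)
  cc <- ifelse(df$condition == "music", 1, -1)
  gc <- ifelse(grp[df$s] == "autism", 1, -1)
  ppvt <- rnorm(n_subj, 0, 10); age <- rnorm(n_subj, 0, 2)
  y <- beta[["int"]] + beta[["group"]] * gc + beta[["condition"]] * cc +
    beta[["gxc"]] * gc * cc + b0s[df$s] + b1s[df$s] * cc +
    b0i[df$i] + b1i[df$i] * cc + b2i[df$i] * gc + rnorm(nrow(df), 0, sigma)
  tibble::tibble(participant_id = subj[df$s], item_id = item[df$i],
                 group = grp[df$s], condition = df$condition,
                 group_c = gc, condition_c = cc, metric = y,
                 ppvt_r_centered = ppvt[df$s] - mean(ppvt),
                 age_centered = age[df$s] - mean(age))
}

test_that("well-conditioned data keep the maximal random structure", {
  withr::with_seed(41, {
    dat <- make_lme_data(n_subj = 40, n_item = 20, sd_item_group = 3)
  })
  fit <- fit_lme(dat, "metric")
  expect_length(fit$trail, 1)
  expect_true(fit$spec$correlated)
  expect_setequal(fit$spec$components,
                  c("subject_intercept", "subject_condition_slope",
                    "item_intercept", "item_condition_slope",
                    "item_group_slope"))
})

test_that("near-zero variance components are dropped first, item side first", {
  withr::with_seed(42, {
    dat <- make_lme_data(n_subj = 24, n_item = 10, sd_item_slope = 0,
                         sd_item_group = 0)
  })
  fit <- fit_lme(dat, "metric")
  expect_gt(length(fit$trail), 1)
  expect_match(fit$trail[[2]], "drop correlations")
  if (length(fit$trail) > 2) {
    expect_match(fit$trail[[3]], "drop item_(group|condition)_slope")
  }
  # the zero-variance components are gone from the final spec
  expect_false("item_group_slope" %in% fit$spec$components)
})

test_that("the reduction trail is identical across repeated runs", {
  withr::with_seed(43, {
    dat <- make_lme_data(n_subj = 16, n_item = 8, sd_item_slope = 0,
                         sd_item_group = 0, sd_subj_slope = 0)
  })
  f1 <- fit_lme(dat, "metric")
  f2 <- fit_lme(dat, "metric")
  expect_identical(f1$trail, f2$trail)
  expect_identical(f1$spec$components, f2$spec$components)
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate)
})

test_that("fixed effects recover the generating coefficients", {
  withr::with_seed(44, {
    dat <- make_lme_data(n_subj = 60, n_item = 20)
  })
  fit <- fit_lme(dat, "metric")
  est <- function(e) fixed_effect(fit, e)$estimate
  se <- function(e) fixed_effect(fit, e)$se
  expect_lt(abs(est("Group") - 10), 3 * se("Group"))
  expect_lt(abs(est("Condition") - (-20)), 3 * se("Condition"))
  expect_lt(abs(est("Group x Condition") - 5), 3 * se("Group x Condition"))
})

test_that("scaling the response scales estimates and SEs, not t", {
  withr::with_seed(45, {
    dat <- make_lme_data(n_subj = 20, n_item = 8)
  })
  sp <- lme_spec("metric", components = c("subject_intercept", "item_intercept"))
  f1 <- fit_lme(dat, sp, reduce = FALSE)
  dat2 <- dat; dat2$metric <- dat2$metric * 3.5
  f2 <- fit_lme(dat2, sp, reduce = FALSE)
  expect_equal(f2$coefficients$estimate, 3.5 * f1$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(f2$coefficients$se, 3.5 * f1$coefficients$se, tolerance = 1e-6)
  expect_equal(f2$coefficients$t, f1$coefficients$t, tolerance = 1e-6)
})

test_that("with zero true random variance the fixed effects match OLS", {
  withr::with_seed(46, {
    dat <- make_lme_data(n_subj = 30, n_item = 10, sd_subj_int = 0,
                         sd_subj_slope = 0, sd_item_int = 0,
                         sd_item_slope = 0, sigma = 15)
  })
  sp <- lme_spec("metric", components = c("subject_intercept", "item_intercept"))
  fit <- fit_lme(dat, sp, reduce = FALSE)
  dd <- as.data.frame(dat)
  dd$group <- factor(dd$group, levels = c("autism", "non_autism"))
  dd$condition <- factor(dd$condition, levels = c("music", "speech"))
  contrasts(dd$group) <- contr.sum(2)
  contrasts(dd$condition) <- contr.sum(2)
  ols <- lm(metric ~ group * condition + ppvt_r_centered + age_centered, dd)
  ref <- coef(ols)[c("(Intercept)", "group1", "condition1", "ppvt_r_centered",
                     "age_centered", "group1:condition1")]
  expect_equal(fit$coefficients$estimate, unname(ref), tolerance = 1e-3)
})

test_that("effect coding orientation is +1 autism, +1 music", {
  withr::with_seed(47, {
    dat <- make_lme_data(n_subj = 40, n_item = 12,
                         beta = c(int = 0, group = 8, condition = -8, gxc = 0),
                         sigma = 5)
  })
  sp <- lme_spec("metric", components = c("subject_intercept", "item_intercept"))
  fit <- fit_lme(dat, sp, reduce = FALSE)
  # generating code used +1 autism / +1 music, so signs must carry through
  expect_gt(fixed_effect(fit, "Group")$estimate, 0)
  expect_lt(fixed_effect(fit, "Condition")$estimate, 0)
})

test_that("marginal-means contrasts form the four simple effects with Holm", {
  withr::with_seed(48, {
    dat <- make_lme_data(n_subj = 40, n_item = 12,
                         beta = c(int = 100, group = 0, condition = -15,
                                  gxc = 0))
  })
  fit <- fit_lme(dat, lme_spec("metric",
                               components = c("subject_intercept",
                                              "item_intercept")),
                 reduce = FALSE)
  mc <- marginal_means_contrasts(fit)
  expect_equal(nrow(mc), 4)
  expect_setequal(unique(mc$contrast),
                  c("autism - non_autism", "music - speech"))
  expect_equal(mc$p_holm, holm_bonferroni(mc$p_raw))
  expect_true(all(mc$p_holm >= mc$p_raw))
  # no true interaction: group contrasts similar across conditions
  gg <- mc[mc$contrast == "autism - non_autism", ]
  expect_lt(abs(diff(gg$estimate)), 4 * max(gg$se))
  # condition contrasts strongly significant in both groups
  ccon <- mc[mc$contrast == "music - speech", ]
  expect_true(all(ccon$p_holm < 0.001))
})

test_that("exhausting the reduction raises an error carrying the trail", {
  # iid noise with no true random variance keeps every structure singular
  withr::with_seed(49, {
    dat <- make_lme_data(n_subj = 30, n_item = 10, sd_subj_int = 0,
                         sd_subj_slope = 0, sd_item_int = 0, sd_item_slope = 0,
                         sigma = 1)
  })
  err <- tryCatch(reduce_random_structure(dat, lme_spec("metric")),
                  vm_no_convergence = function(e) e)
  expect_s3_class(err, "vm_no_convergence")
  expect_match(conditionMessage(err), "trail")
})
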