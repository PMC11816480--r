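# Synthetic-study generator: design arithmetic, determinism, and
# closed-form calibration of the injected noise.

test_that("the design yields 40 model utterances per voice", {
  cfg <- sim_config(seed = 51)
  models <- generate_models(cfg, "female")
  expect_length(models, 40)   # 10 sentences x 2 foci x 2 conditions
  expect_setequal(vapply(models, function(u) u$condition, ""), c("speech", "music"))
  counts <- vapply(models, n_syllables, integer(1))
  expect_true(all(counts >= 2 & counts <= 6))
})

test_that("song F0s sit on the equal-tempered semitone grid of the tonic", {
  cfg <- sim_config(seed = 52)
  music <- Filter(function(u) u$condition == "music",
                  generate_models(cfg, "female"))
  for (u in music) {
    cents <- 1200 * log2(u$events$median_f0_hz / cfg$base_f0_female_hz)
    expect_lt(max(abs(cents - round(cents / 100) * 100)), 0.5)
  }
})

test_that("the male model sits exactly one octave below the female model", {
  cfg <- sim_config(seed = 53)
  f <- generate_models(cfg, "female")
  m <- generate_models(cfg, "male")
  for (i in seq_along(f)) {
    expect_equal(m[[i]]$events$median_f0_hz, f[[i]]$events$median_f0_hz / 2,
                 tolerance = 1e-12)
    expect_equal(m[[i]]$events$duration_s, f[[i]]$events$duration_s)
  }
})

test_that("with no focus boost, early and late versions share their F0s", {
  cfg <- sim_config(seed = 54, focus_pitch_boost_cents = 0)
  models <- generate_models(cfg, "female")
  for (s in 1:10) {
    pick <- function(focus, cond) Filter(function(u)
      u$utterance_id == sprintf("s%02d_%s", s, focus) && u$condition == cond,
      models)[[1]]
    expect_equal(pick("early", "speech")$events$median_f0_hz,
                 pick("late", "speech")$events$median_f0_hz)
  }
})

test_that("a noise-free study is a perfect imitation end to end", {
  zero <- c(autism.speech = 0, autism.music = 0,
            non_autism.speech = 0, non_autism.music = 0)
  cfg <- sim_config(n_autism = 2, n_non_autism = 2,
                    syllable_counts = c(2, 4, 6),
                    pitch_noise_sd_cents = zero,
                    duration_noise_sd_ratio = zero,
                    subject_sd_log_pitch = 0, subject_sd_log_duration = 0,
                    octave_error_rate = 0, creak_missing_rate = 0,
                    imitation_gap_sd_s = 0, seed = 55)
  st <- simulate_study(cfg)
  for (m in c("abs_pitch_dev_cents", "rel_pitch_dev_cents", "abs_dur_diff_ms",
              "rel_dur_diff_ms")) {
    expect_equal(max(abs(st$trials[[m]])), 0, tolerance = 1e-9)
  }
  for (m in c("contour_errors", "interval_errors", "time_errors",
              "octave_flags")) {
    expect_identical(sum(st$trials[[m]]), 0L)
  }
})

test_that("the same seed reproduces the study exactly", {
  cfg <- sim_config(n_autism = 3, n_non_autism = 3,
                    syllable_counts = c(2, 3), seed = 56)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(as.data.frame(s1$trials), as.data.frame(s2$trials))
  expect_identical(s1$roster, s2$roster)
})

test_that("the default configuration produces the full design size", {
  cfg <- sim_config(seed = 57)
  st <- simulate_study(cfg)
  expect_equal(nrow(st$roster), 63)        # 33 + 30
  expect_equal(nrow(st$trials), 63 * 40)   # 2520 scored trials
  expect_equal(nrow(st$exclusions), 0)
})

test_that("octave-error injection is recovered by the correction flags", {
  q <- 0.08
  cfg <- sim_config(seed = 58, octave_error_rate = q, creak_missing_rate = 0,
                    pitch_noise_sd_cents = c(
                      autism.speech = 100, autism.music = 100,
                      non_autism.speech = 100, non_autism.music = 100))
  model <- Filter(function(u) n_syllables(u) == 6,
                  generate_models(cfg, "female"))[[1]]
  prt <- unit_participant()
  withr::with_seed(58, {
    flags <- replicate(400, {
      im <- generate_imitation(model, prt[1, ], cfg)
      score_pair(utterance_pair(model, im))$octave_flags
    })
  })
  n_syll <- 400 * 6
  rate <- sum(flags) / n_syll
  ci <- q + c(-1, 1) * 3 * sqrt(q * (1 - q) / n_syll)
  expect_gt(rate, ci[[1]])
  expect_lt(rate, ci[[2]])
})

test_that("time-error rate matches the Gaussian tail probability", {
  sd_ratio <- 0.25
  cfg <- sim_config(seed = 59, octave_error_rate = 0, creak_missing_rate = 0,
                    imitation_gap_sd_s = 0,
                    duration_noise_sd_ratio = c(
                      autism.speech = sd_ratio, autism.music = sd_ratio,
                      non_autism.speech = sd_ratio, non_autism.music = sd_ratio))
  model <- Filter(function(u) n_syllables(u) == 5,
                  generate_models(cfg, "female"))[[1]]
  prt <- unit_participant()
  withr::with_seed(59, {
    errs <- replicate(400, {
      im <- generate_imitation(model, prt[1, ], cfg)
      count_time_errors(utterance_pair(model, im))
    })
  })
  p_hat <- sum(errs) / (400 * 5)
  p_true <- 2 * pnorm(-0.25 / sd_ratio)   # 0.3173
  se <- sqrt(p_true * (1 - p_true) / (400 * 5))
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("ground truth stores the closed-form expected metric levels", {
  cfg <- sim_config(seed = 60)
  tr <- simulation_truth(cfg)
  expect_equal(nrow(tr$expected), 4)
  row <- tr$expected[tr$expected$group == "autism" &
                       tr$expected$condition == "speech", ]
  amp <- exp(cfg$subject_sd_log_pitch^2 / 2)
  expect_equal(row$exp_abs_pitch_dev_cents,
               260 * sqrt(2 / pi) * amp, tolerance = 1e-12)
  expect_equal(row$exp_time_error_prob, 2 * pnorm(-0.25 / 0.45))
  beta <- truth_effect_coefficients(tr, "exp_time_error_prob")
  e <- tr$expected
  cell <- function(g, c) e$exp_time_error_prob[e$group == g & e$condition == c]
  expect_equal(unname(beta[["group_x_condition"]]),
               (cell("autism", "music") - cell("autism", "speech") -
                  cell("non_autism", "music") + cell("non_autism", "speech")) / 4)
})

test_that("YAML configs round-trip into sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_autism: 5", "n_non_autism: 4", "seed: 99",
    "octave_error_rate: 0.02",
    "pitch_noise_sd_cents:",
    "  autism.speech: 100", "  autism.music: 90",
    "  non_autism.speech: 80", "  non_autism.music: 70"), path)
  cfg <- sim_config_from_yaml(path)
  expect_equal(cfg$n_autism, 5)
  expect_equal(unname(cfg$pitch_noise_sd_cents["non_autism.music"]), 70)
  expect_equal(cfg$octave_error_rate, 0.02)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_key: 1", bad)
  expect_error(sim_config_from_yaml(bad), class = "vm_bad_config")
})
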