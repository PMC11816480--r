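# Synthetic imitation studies.
#
# The generator reproduces the study design: two groups (33 autistic, 30
# non-autistic participants), two conditions (speech, song), 10 sentences of
# 2-6 syllables each spoken/sung with an early or a late focus (40 model
# utterances), a focused word carrying a pitch boost and lengthening, a male
# model voice one octave below the female voice, and imitation noise with
# group x condition specific dispersion plus octave-error and creak
# contamination.  Every simulated trial is scored through the real pipeline.

.gc_names <- c("autism.speech", "autism.music",
               "non_autism.speech", "non_autism.music")

.gc <- function(x, group, condition) unname(x[paste(group, condition, sep = ".")])

#' Simulation configuration
#'
#' Defaults reproduce the study design sizes and echo the published
#' group x condition accuracy pattern (see the methods vignette for how the
#' noise defaults were chosen): per-syllable pitch noise is Gaussian on the
#' cents scale, duration noise is a Gaussian multiplicative ratio, octave
#' errors hit ~4% of syllables and creak silences ~1%.
#'
#' @param n_autism,n_non_autism Group sizes.
#' @param syllable_counts Syllable count per sentence (length = number of
#'   sentences; each sentence yields early/late focus versions in both
#'   conditions).
#' @param base_f0_female_hz Female model register (Hz).
#' @param male_octave_shift_cents Male model shift (cents; -1200 = one
#'   octave down).
#' @param focus_pitch_boost_cents Pitch raising on the focused word.
#' @param focus_lengthening_ratio Duration multiplier on the focused word.
#' @param speech_syllable_dur_s,music_syllable_dur_s Mean rhyme durations.
#' @param contour_jitter_sd_cents,declination_cents_per_syllable Shape of
#'   the per-sentence pitch contour.
#' @param pitch_noise_sd_cents Named vector (`autism.speech`,
#'   `autism.music`, `non_autism.speech`, `non_autism.music`) of per-syllable
#'   imitation pitch noise SDs in cents.
#' @param duration_noise_sd_ratio Same structure; SD of the multiplicative
#'   duration error.
#' @param subject_sd_log_pitch,subject_sd_log_duration Between-participant
#'   ability spread: each participant's noise SDs are scaled by a
#'   lognormal(0, tau) factor.
#' @param octave_error_rate Per-syllable probability of a whole-octave
#'   displacement in the imitation.
#' @param octave_error_down_prob Probability that an octave error goes down
#'   (creak lowers F0, so most do).
#' @param creak_missing_rate Per-syllable probability that the imitated F0
#'   is unmeasurable (missing).
#' @param imitation_gap_sd_s Jitter on inter-rhyme gaps when rebuilding
#'   imitation onsets.
#' @param drop_syllable_rate Per-trial probability that the imitation drops
#'   one interior syllable (misalignment testing; default off).
#' @param seed Integer seed; all randomness derives from it.
#' @return A `vm_sim_config` (named list, validated).
#' @export
sim_config <- function(n_autism = 33, n_non_autism = 30,
                       syllable_counts = c(2, 2, 3, 3, 4, 4, 5, 5, 6, 6),
                       base_f0_female_hz = 220,
                       male_octave_shift_cents = -1200,
                       focus_pitch_boost_cents = 200,
                       focus_lengthening_ratio = 1.3,
                       speech_syllable_dur_s = 0.22,
                       music_syllable_dur_s = 0.5,
                       contour_jitter_sd_cents = 150,
                       declination_cents_per_syllable = -30,
                       pitch_noise_sd_cents = c(
                         autism.speech = 260, autism.music = 165,
                         non_autism.speech = 210, non_autism.music = 165),
                       duration_noise_sd_ratio = c(
                         autism.speech = 0.45, autism.music = 0.31,
                         non_autism.speech = 0.44, non_autism.music = 0.22),
                       subject_sd_log_pitch = 0.25,
                       subject_sd_log_duration = 0.30,
                       octave_error_rate = 0.04,
                       octave_error_down_prob = 0.8,
                       creak_missing_rate = 0.01,
                       imitation_gap_sd_s = 0.01,
                       drop_syllable_rate = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (any(cfg$syllable_counts < 2 | cfg$syllable_counts > 6)) {
    .abort("syllable counts must lie in [2, 6]", "vm_bad_config")
  }
  for (nm in c("pitch_noise_sd_cents", "duration_noise_sd_ratio")) {
    if (!all(.gc_names %in% names(cfg[[nm]]))) {
      .abort(paste0(nm, " must be named with: ", paste(.gc_names, collapse = ", ")),
             "vm_bad_config")
    }
    if (any(cfg[[nm]] < 0)) .abort(paste0(nm, " must be >= 0"), "vm_bad_config")
  }
  for (nm in c("octave_error_rate", "creak_missing_rate", "drop_syllable_rate",
               "octave_error_down_prob")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      .abort(paste0(nm, " must be a probability"), "vm_bad_config")
    }
  }
  structure(cfg, class = "vm_sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Flat keys matching the arguments of [sim_config()]; the group x condition
#' noise maps may be nested (`autism: {speech: 260, music: 165}`).
#'
#' @param path YAML file path.
#' @return A `vm_sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  flatten_gc <- function(x) {
    if (is.list(x)) {
      out <- unlist(x)
      names(out) <- sub("^(autism|non_autism)\\.", "\\1.", names(out))
      out
    } else x
  }
  for (nm in c("pitch_noise_sd_cents", "duration_noise_sd_ratio")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- flatten_gc(raw[[nm]])
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    .abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
           "vm_bad_config")
  }
  do.call(sim_config, raw)
}

# Per-sentence blueprints shared by every voice/focus/condition variant:
# the pitch contour (cents above the female register) and base rhyme
# durations are drawn once per sentence from the config seed, so the same
# config always yields the same stimuli.
.model_blueprints <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)
  lapply(seq_along(config$syllable_counts), function(s) {
    n <- config$syllable_counts[[s]]
    list(
      n = n,
      contour_cents = 150 + config$declination_cents_per_syllable * (seq_len(n) - 1) +
        rnorm(n, 0, config$contour_jitter_sd_cents),
      speech_dur_s = config$speech_syllable_dur_s * exp(rnorm(n, 0, 0.2)),
      music_dur_s = config$music_syllable_dur_s * exp(rnorm(n, 0, 0.05)))
  })
}

#' Generate the 40 model utterances for one voice
#'
#' Speech versions carry a smooth per-sentence contour with the focus boost
#' and lengthening on the focused word (first word for early focus, last for
#' late); song versions quantize the same contour to the nearest
#' equal-tempered semitone of the register tonic, with near-isochronous
#' durations.  The male voice is the female voice shifted down one octave.
#'
#' @param config A [sim_config()].
#' @param voice `"female"` or `"male"`.
#' @return List of `vm_utterance` (length `2 * 2 * length(syllable_counts)`).
#' @export
generate_models <- function(config, voice = c("female", "male")) {
  voice <- match.arg(voice)
  shift <- if (voice == "male") config$male_octave_shift_cents else 0
  bps <- .model_blueprints(config)
  out <- list()
  for (s in seq_along(bps)) {
    bp <- bps[[s]]
    for (focus in FOCI) {
      fpos <- if (focus == "early") 1L else bp$n
      boost <- rep(0, bp$n); boost[fpos] <- config$focus_pitch_boost_cents
      lengthen <- rep(1, bp$n); lengthen[fpos] <- config$focus_lengthening_ratio
      speech_cents <- bp$contour_cents + boost
      music_cents <- round(speech_cents / 100) * 100   # semitone grid
      for (condition in CONDITIONS) {
        cents <- if (condition == "speech") speech_cents else music_cents
        dur <- (if (condition == "speech") bp$speech_dur_s else bp$music_dur_s) * lengthen
        gap <- if (condition == "speech") 0.08 else 0.02
        onset <- 0.1 + c(0, cumsum(dur[-bp$n] + gap))
        f0 <- config$base_f0_female_hz * 2^((cents + shift) / CENTS_PER_OCTAVE)
        out[[length(out) + 1L]] <- utterance(
          utterance_id = sprintf("s%02d_%s", s, focus),
          role = "model", condition = condition, focus = focus,
          speaker_id = paste0("model_", voice),
          events = syllable_events(onset, dur, f0))
      }
    }
  }
  out
}

#' Generate a synthetic participant roster
#'
#' Group sizes, sex ratios, and the distributions of age, PPVT-R, RSPM,
#' musical training and digit span follow the published group
#' characteristics.  Two latent per-participant ability factors
#' (`pitch_ability`, `duration_ability`, lognormal around 1) scale the
#' imitation noise SDs and induce realistic between-participant variance.
#' Uses the current RNG state.
#'
#' @param config A [sim_config()].
#' @return Roster tibble with the [participant_roster()] columns plus
#'   `pitch_ability` and `duration_ability`.
#' @export
generate_roster <- function(config) {
  n1 <- config$n_autism; n2 <- config$n_non_autism
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  mk <- function(n, prefix, group, sex_m_frac, age_m, age_s, ppvt_m, ppvt_s,
                 rspm_m, rspm_s, mus_m, mus_s, ds_m, ds_s) {
    sex <- ifelse(runif(n) < sex_m_frac, "M", "F")
    participant_roster(
      participant_id = sprintf("%s%02d", prefix, seq_len(n)),
      group = rep(group, n), sex = sex,
      age_years = clip(rnorm(n, age_m, age_s), 7, 16),
      ppvt_r = rnorm(n, ppvt_m, ppvt_s),
      rspm = rnorm(n, rspm_m, rspm_s),
      musical_training_years = pmax(0, rnorm(n, mus_m, mus_s)),
      digit_span = rnorm(n, ds_m, ds_s))
  }
  roster <- dplyr::bind_rows(
    mk(n1, "A", "autism", 28 / 33, 10.29, 2.50, 124.33, 25.87,
       110.12, 15.77, 0.88, 1.32, 8.49, 0.91),
    mk(n2, "N", "non_autism", 26 / 30, 11.50, 2.83, 141.77, 12.80,
       112.72, 10.26, 0.50, 1.11, 8.07, 1.11))
  roster$pitch_ability <- exp(rnorm(n1 + n2, 0, config$subject_sd_log_pitch))
  roster$duration_ability <- exp(rnorm(n1 + n2, 0, config$subject_sd_log_duration))
  roster
}

#' Generate one imitation of a model utterance
#'
#' Imitated F0 is the model F0 scaled by `2^(eps/1200)` with `eps ~
#' N(0, sd)` for the participant's group x condition (times the
#' participant's ability factor); with probability `octave_error_rate` a
#' syllable is additionally displaced a whole octave (down with probability
#' `octave_error_down_prob`), and with probability `creak_missing_rate` its
#' F0 is missing.  Durations are the model's times `(1 + eta)`, `eta ~
#' N(0, sd_ratio)` (floored so durations stay positive); onsets are rebuilt
#' by accumulating imitated durations plus the model's inter-rhyme gaps with
#' small jitter.  Uses the current RNG state.
#'
#' @param model A model `vm_utterance`.
#' @param participant One roster row.
#' @param config A [sim_config()].
#' @return An imitation `vm_utterance` carrying a `model_speaker` attribute.
#' @export
generate_imitation <- function(model, participant, config) {
  n <- nrow(model$events)
  group <- participant$group
  sd_p <- .gc(config$pitch_noise_sd_cents, group, model$condition) *
    (participant$pitch_ability %||% 1)
  sd_d <- .gc(config$duration_noise_sd_ratio, group, model$condition) *
    (participant$duration_ability %||% 1)
  eps <- rnorm(n, 0, sd_p)
  oct_hit <- runif(n) < config$octave_error_rate
  oct_sign <- ifelse(runif(n) < config$octave_error_down_prob, -1, 1)
  cents_err <- eps + ifelse(oct_hit, oct_sign * CENTS_PER_OCTAVE, 0)
  f0 <- model$events$median_f0_hz * 2^(cents_err / CENTS_PER_OCTAVE)
  f0[runif(n) < config$creak_missing_rate] <- NA_real_
  dur <- model$events$duration_s * pmax(1 + rnorm(n, 0, sd_d), 0.05)
  gaps <- diff(model$events$onset_s) - model$events$duration_s[-n]
  if (config$imitation_gap_sd_s > 0) {
    gaps <- pmax(gaps + rnorm(length(gaps), 0, config$imitation_gap_sd_s), 0.005)
  }
  onset <- model$events$onset_s[[1]] + c(0, cumsum(dur[-n] + gaps))
  keep <- seq_len(n)
  if (config$drop_syllable_rate > 0 && n > 2 &&
      runif(1) < config$drop_syllable_rate) {
    keep <- keep[-sample(2:(n - 1), 1)]
  }
  im <- utterance(model$utterance_id, "imitation", model$condition,
                  model$focus, participant$participant_id,
                  syllable_events(onset[keep], dur[keep], f0[keep],
                                  index = seq_along(keep) - 1L))
  attr(im, "model_speaker") <- model$speaker_id
  im
}

#' Simulate a complete imitation study
#'
#' Generates models (both voices), a roster, and one imitation of each of
#' the 40 items per participant (female model voice for children under 12
#' and all female participants, male voice for male participants 12 and
#' over), then pairs and scores every trial through the real pipeline.
#' Deterministic under a fixed config seed.
#'
#' @param config A [sim_config()].
#' @return List of class `vm_study`: `trials` (the scored trial table),
#'   `roster`, `models`, `imitations`, `exclusions`, and `truth`
#'   ([simulation_truth()] of the generating parameters and the closed-form
#'   expected metric levels).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "vm_sim_config"))
  models <- c(generate_models(config, "female"), generate_models(config, "male"))
  set.seed(config$seed)
  roster <- generate_roster(config)
  voice_for <- ifelse(roster$sex == "M" & roster$age_years >= 12,
                      "model_male", "model_female")
  imitations <- list()
  for (i in seq_len(nrow(roster))) {
    prt <- roster[i, ]
    mods <- Filter(function(u) u$speaker_id == voice_for[[i]], models)
    imitations <- c(imitations, lapply(mods, generate_imitation,
                                       participant = prt, config = config))
  }
  paired <- pair_trials(models, imitations)
  trials <- build_trial_table(paired$pairs, roster)
  structure(list(trials = trials, roster = roster, models = models,
                 imitations = imitations, exclusions = paired$exclusions,
                 truth = simulation_truth(config, models)),
            class = "vm_study")
}

#' @export
print.vm_study <- function(x, ...) {
  cat(sprintf("<vm_study> %d participants, %d model utterances, %d scored trials (%d excluded)\n",
              nrow(x$roster), length(x$models), nrow(x$trials),
              nrow(x$exclusions)))
  invisible(x)
}

#' Configuration for the qualitative pattern-validation study
#'
#' A [sim_config()] whose injected noise reproduces the published
#' group x condition accuracy pattern with unambiguous effect sizes: the
#' autism group is noisier than the non-autism group on pitch in speech but
#' not in song, and noisier on duration in song but not in speech, while
#' both groups are less noisy on pitch (and more variable on duration) in
#' song than in speech.  Used to check that the fitted fixed-effect signs
#' and the Holm-corrected simple-effect significance pattern come out as in
#' the study; effect sizes are chosen for high power at the default study
#' size, not to reproduce any published coefficient magnitude.
#'
#' @param seed Integer seed.
#' @return A `vm_sim_config`.
#' @export
directional_pattern_config <- function(seed = 1L) {
  sim_config(
    seed = seed,
    pitch_noise_sd_cents = c(autism.speech = 280, autism.music = 110,
                             non_autism.speech = 190, non_autism.music = 110),
    duration_noise_sd_ratio = c(autism.speech = 0.42, autism.music = 0.40,
                                non_autism.speech = 0.42, non_autism.music = 0.28))
}

#' Closed-form expected metric levels under the generator
#'
#' For per-syllable pitch noise `eps ~ N(0, sigma)` the expected absolute
#' pitch deviation is the folded-normal mean `sigma * sqrt(2/pi)`; for a
#' duration ratio SD `s` the per-syllable time-error probability is
#' `P(|eta| > 0.25) = 2 * Phi(-0.25 / s)`; the expected absolute duration
#' difference is `dbar * s * sqrt(2/pi)` with `dbar` the mean model rhyme
#' duration of the condition.  Participant-ability scaling multiplies the
#' pitch/duration means by `exp(tau^2 / 2)`.  These ignore octave-error,
#' creak and duration-floor contamination, which the defaults keep rare.
#'
#' @param config A [sim_config()].
#' @param models Model utterances (for condition mean durations); defaults
#'   to regenerating them from the config.
#' @return List with the generating parameters and tibble
#'   `expected` (group, condition, expected absolute pitch deviation in
#'   cents, time-error probability, absolute duration difference in ms).
#' @export
simulation_truth <- function(config, models = NULL) {
  if (is.null(models)) models <- generate_models(config, "female")
  mean_dur <- vapply(CONDITIONS, function(cond) {
    mean(vapply(Filter(function(u) u$condition == cond, models),
                function(u) mean(u$events$duration_s), numeric(1)))
  }, numeric(1))
  amp_pitch <- exp(config$subject_sd_log_pitch^2 / 2)
  amp_dur <- exp(config$subject_sd_log_duration^2 / 2)
  grid <- expand.grid(group = GROUPS, condition = CONDITIONS,
                      stringsAsFactors = FALSE)
  expected <- tibble::tibble(
    group = grid$group, condition = grid$condition,
    pitch_sd_cents = vapply(seq_len(nrow(grid)), function(i)
      .gc(config$pitch_noise_sd_cents, grid$group[[i]], grid$condition[[i]]),
      numeric(1)),
    dur_sd_ratio = vapply(seq_len(nrow(grid)), function(i)
      .gc(config$duration_noise_sd_ratio, grid$group[[i]], grid$condition[[i]]),
      numeric(1)))
  expected$exp_abs_pitch_dev_cents <- expected$pitch_sd_cents * sqrt(2 / pi) * amp_pitch
  expected$exp_time_error_prob <- 2 * pnorm(-0.25 / expected$dur_sd_ratio)
  expected$exp_abs_dur_diff_ms <- 1000 * unname(mean_dur[expected$condition]) *
    expected$dur_sd_ratio * sqrt(2 / pi) * amp_dur
  list(config = config, mean_model_dur_s = mean_dur, expected = expected)
}

#' Analytic effect-coded coefficients implied by the generator
#'
#' Converts the four expected cell means of a metric into the grand mean,
#' Group, Condition and Group x Condition coefficients under the +/-1
#' effect coding (+1 autism, +1 music).
#'
#' @param truth Output of [simulation_truth()].
#' @param column One of the `exp_*` columns of `truth$expected`.
#' @return Named numeric vector: `intercept`, `group`, `condition`,
#'   `group_x_condition`.
#' @export
truth_effect_coefficients <- function(truth, column) {
  e <- truth$expected
  cell <- function(g, c) e[[column]][e$group == g & e$condition == c]
  mu_am <- cell("autism", "music"); mu_as <- cell("autism", "speech")
  mu_nm <- cell("non_autism", "music"); mu_ns <- cell("non_autism", "speech")
  c(intercept = (mu_am + mu_as + mu_nm + mu_ns) / 4,
    group = (mu_am + mu_as - mu_nm - mu_ns) / 4,
    condition = (mu_am - mu_as + mu_nm - mu_ns) / 4,
    group_x_condition = (mu_am - mu_as - mu_nm + mu_ns) / 4)
}
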