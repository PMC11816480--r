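# Independent brute-force oracles and fixture builders.  These deliberately
# avoid the package's vectorized code paths: scalar loops, explicit octave
# shifting, and manual medians.

oracle_cents <- function(f_imit, f_model) 1200 * log2(f_imit / f_model)

oracle_fold <- function(x) {
  while (!is.na(x) && x > 600) x <- x - 1200
  while (!is.na(x) && x <= -600) x <- x + 1200
  x
}

# octave-corrected per-syllable deviations from raw Hz
oracle_deviations <- function(f_model, f_imit) {
  vapply(seq_along(f_model), function(i) {
    if (is.na(f_model[[i]]) || is.na(f_imit[[i]])) return(NA_real_)
    oracle_fold(oracle_cents(f_imit[[i]], f_model[[i]]))
  }, numeric(1))
}

oracle_corrected_hz <- function(f_model, f_imit) {
  vapply(seq_along(f_model), function(i) {
    if (is.na(f_model[[i]]) || is.na(f_imit[[i]])) return(f_imit[[i]])
    f_model[[i]] * 2^(oracle_fold(oracle_cents(f_imit[[i]], f_model[[i]])) / 1200)
  }, numeric(1))
}

oracle_abs_pitch <- function(f_model, f_imit) {
  d <- abs(oracle_deviations(f_model, f_imit))
  if (all(is.na(d))) NA_real_ else mean(d[!is.na(d)])
}

oracle_intervals <- function(f0) {
  n <- length(f0)
  out <- numeric(0)
  for (i in seq_len(n - 1)) out <- c(out, oracle_cents(f0[[i + 1]], f0[[i]]))
  out
}

oracle_rel_pitch <- function(f_model, f_imit) {
  fi <- oracle_corrected_hz(f_model, f_imit)
  im <- oracle_intervals(f_model)
  ii <- oracle_intervals(fi)
  d <- abs(abs(ii) - abs(im))
  if (all(is.na(d))) NA_real_ else mean(d[!is.na(d)])
}

oracle_direction <- function(x) {
  if (is.na(x)) NA_character_
  else if (x >= 50) "up" else if (x <= -50) "down" else "level"
}

oracle_contour_errors <- function(f_model, f_imit) {
  fi <- oracle_corrected_hz(f_model, f_imit)
  im <- oracle_intervals(f_model)
  ii <- oracle_intervals(fi)
  n_err <- 0L
  for (i in seq_along(im)) {
    a <- oracle_direction(im[[i]]); b <- oracle_direction(ii[[i]])
    if (!is.na(a) && !is.na(b) && a != b) n_err <- n_err + 1L
  }
  n_err
}

oracle_interval_errors <- function(f_model, f_imit) {
  fi <- oracle_corrected_hz(f_model, f_imit)
  im <- oracle_intervals(f_model)
  ii <- oracle_intervals(fi)
  n_err <- 0L
  for (i in seq_along(im)) {
    d <- abs(abs(ii[[i]]) - abs(im[[i]]))
    if (!is.na(d) && d >= 100) n_err <- n_err + 1L
  }
  n_err
}

oracle_abs_dur_ms <- function(d_model, d_imit) {
  1000 * mean(vapply(seq_along(d_model),
                     function(i) abs(d_imit[[i]] - d_model[[i]]), numeric(1)))
}

oracle_rel_dur_ms <- function(on_model, on_imit) {
  im <- numeric(0); ii <- numeric(0)
  for (i in seq_len(length(on_model) - 1)) {
    im <- c(im, 1000 * (on_model[[i + 1]] - on_model[[i]]))
    ii <- c(ii, 1000 * (on_imit[[i + 1]] - on_imit[[i]]))
  }
  mean(abs(ii - im))
}

oracle_time_errors <- function(d_model, d_imit) {
  n_err <- 0L
  for (i in seq_along(d_model)) {
    if (abs(d_imit[[i]] - d_model[[i]]) / d_model[[i]] > 0.25) n_err <- n_err + 1L
  }
  n_err
}

oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[[(n + 1) / 2]] else (x[[n / 2]] + x[[n / 2 + 1]]) / 2
}

# --- fixture builders ------------------------------------------------------

make_utterance <- function(onset_s, duration_s, f0_hz, id = "u1",
                           role = "model", condition = "speech",
                           focus = "early", speaker = "spk") {
  utterance(id, role, condition, focus, speaker,
            syllable_events(onset_s, duration_s, f0_hz))
}

make_pair <- function(f_model, f_imit, d_model = NULL, d_imit = NULL,
                      on_model = NULL, on_imit = NULL, id = "u1",
                      condition = "speech") {
  n <- length(f_model)
  if (is.null(d_model)) d_model <- rep(0.2, n)
  if (is.null(d_imit)) d_imit <- rep(0.2, n)
  if (is.null(on_model)) on_model <- cumsum(c(0.1, d_model[-n] + 0.05))
  if (is.null(on_imit)) on_imit <- cumsum(c(0.1, d_imit[-n] + 0.05))
  utterance_pair(
    make_utterance(on_model, d_model, f_model, id, "model", condition),
    make_utterance(on_imit, d_imit, f_imit, id, "imitation", condition,
                   speaker = "p1"))
}

# random aligned pair with occasional octave errors and missing F0
random_pair <- function(n = NULL) {
  if (is.null(n)) n <- sample(2:6, 1)
  fm <- runif(n, 120, 400)
  cents_err <- rnorm(n, 0, 250) + sample(c(-1200, 0, 0, 0, 1200), n, replace = TRUE)
  fi <- fm * 2^(cents_err / 1200)
  if (runif(1) < 0.2) fi[sample(n, 1)] <- NA
  dm <- runif(n, 0.1, 0.5)
  di <- dm * (1 + rnorm(n, 0, 0.3))
  di <- pmax(di, 0.02)
  om <- cumsum(c(0.1, dm[-n] + runif(n - 1, 0.02, 0.1)))
  oi <- cumsum(c(0.1, di[-n] + runif(n - 1, 0.02, 0.1)))
  make_pair(fm, fi, dm, di, om, oi)
}

# minimal roster row for driving generate_imitation directly
unit_participant <- function(id = "p1", group = "autism") {
  r <- participant_roster(id, group, "F", 10, 120, 110, 1, 8)
  r$pitch_ability <- 1
  r$duration_ability <- 1
  r
}
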