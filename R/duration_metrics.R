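# Timing metrics: rhyme durations and interonset intervals (IOIs).
# Internal times are seconds; reported metrics are milliseconds.

#' Absolute duration difference (ms)
#'
#' Mean over syllables of the absolute difference between imitated and model
#' rhyme durations, in milliseconds.  Larger values mean less accurate
#' absolute duration matching.
#'
#' @param pair A `vm_pair` from [utterance_pair()].
#' @return Mean absolute duration difference in ms.
#' @export
absolute_duration_difference <- function(pair) {
  1000 * mean(abs(pair$imitation$events$duration_s -
                    pair$model$events$duration_s))
}

#' Interonset intervals of an utterance
#'
#' Differences between the onsets of consecutive syllable rhymes, in
#' milliseconds.  The final syllable's offset never enters (an utterance of
#' n syllables has n - 1 IOIs).
#'
#' @param u A `vm_utterance`.
#' @return Numeric vector of IOIs in ms (length `n_syllables - 1`).
#' @export
ioi_series <- function(u) {
  on <- u$events$onset_s
  if (length(on) > 1 && any(diff(on) <= 0)) {
    .abort("onsets must be strictly increasing", "vm_nonmonotone_onsets")
  }
  1000 * diff(on)
}

#' Relative duration difference (ms)
#'
#' Mean over IOI positions of the absolute difference between imitated and
#' model IOIs.  Invariant to a constant time shift of all imitation onsets,
#' so it isolates rhythm from overall latency.
#'
#' @inheritParams absolute_duration_difference
#' @return Mean absolute IOI difference in ms, or `NA` for < 2 syllables.
#' @export
relative_duration_difference <- function(pair) {
  im <- ioi_series(pair$model)
  ii <- ioi_series(pair$imitation)
  if (length(im) == 0) return(NA_real_)
  mean(abs(ii - im))
}

#' Number of time errors
#'
#' Counts imitated syllables more than 25% longer or shorter than the
#' corresponding model syllable (strictly greater than 25%, relative to the
#' model's rhyme duration).
#'
#' @inheritParams absolute_duration_difference
#' @return Integer count (0 to `n_syllables`).
#' @export
count_time_errors <- function(pair) {
  dm <- pair$model$events$duration_s
  di <- pair$imitation$events$duration_s
  sum(abs(di - dm) / dm > 0.25)
}

#' Score one model/imitation pair on all seven metrics
#'
#' Computes the four pitch metrics (with octave correction) and the three
#' timing metrics for an aligned pair, plus bookkeeping counts: syllable
#' count, number of pitch-scoreable syllables (both F0s present), and number
#' of octave-corrected syllables.
#'
#' @inheritParams pair_pitch_deviations
#' @return One-row tibble with columns `abs_pitch_dev_cents`,
#'   `rel_pitch_dev_cents`, `contour_errors`, `interval_errors`,
#'   `abs_dur_diff_ms`, `rel_dur_diff_ms`, `time_errors`, `n_syllables`,
#'   `n_scoreable_syllables`, `octave_flags`.
#' @export
score_pair <- function(pair, correct_octave = TRUE) {
  nm <- nrow(pair$model$events)
  ni <- nrow(pair$imitation$events)
  if (nm != ni) {
    .abort(sprintf("alignment error: model has %d syllables, imitation %d",
                   nm, ni), "vm_alignment_error")
  }
  # compute the pitch deviations and interval series once and derive all
  # four pitch metrics from them (the exported per-metric functions are the
  # reference path; equality is covered by tests)
  pd <- pair_pitch_deviations(pair, correct_octave)
  dev <- pd$deviation_cents
  im <- interval_series(pair$model$events$median_f0_hz)
  ii <- interval_series(pd$f0_imit_corrected)
  int_diff <- abs(ii$abs_cents - im$abs_cents)
  dm <- classify_direction(im$signed_cents)
  di <- classify_direction(ii$signed_cents)
  tibble::new_tibble(list(
    abs_pitch_dev_cents = if (all(is.na(dev))) NA_real_ else mean(abs(dev), na.rm = TRUE),
    rel_pitch_dev_cents = if (all(is.na(int_diff))) NA_real_ else mean(int_diff, na.rm = TRUE),
    contour_errors = sum(dm != di, na.rm = TRUE),
    interval_errors = sum(int_diff >= 100, na.rm = TRUE),
    abs_dur_diff_ms = absolute_duration_difference(pair),
    rel_dur_diff_ms = relative_duration_difference(pair),
    time_errors = count_time_errors(pair),
    n_syllables = nm,
    n_scoreable_syllables = sum(!is.na(dev)),
    octave_flags = sum(pd$octave_flagged)
  ), nrow = 1L)
}
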