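# Pitch-side imitation metrics.
#
# All pitch comparisons are made in cents (1200 * log2 of the Hz ratio;
# 100 cents = one equal-tempered semitone), the scale on which pitch
# production error is approximately symmetric.  Octave errors -- imitated
# pitches displaced by ~12 semitones, typically through creaky voice --
# are folded out before any metric is computed.

#' Signed pitch deviation in cents
#'
#' `1200 * log2(f_imit / f_model)`: positive when the imitation is sharp
#' relative to the model, negative when flat.
#'
#' @param f_imit,f_model Frequencies in Hz (> 0). Vectorized; `NA` propagates.
#' @return Signed deviation in cents.
#' @export
cents_deviation <- function(f_imit, f_model) {
  bad <- (!is.na(f_imit) & f_imit <= 0) | (!is.na(f_model) & f_model <= 0)
  if (any(bad)) .abort("frequencies must be positive", "vm_bad_frequency")
  CENTS_PER_OCTAVE * log2(f_imit / f_model)
}

#' Fold a pitch deviation into the nearest octave
#'
#' Shifts the deviation by whole octaves (1200 cents) until it lies in
#' `(-600, +600]`.  A deviation of more than half an octave is treated as an
#' octave error: e.g. a 700-cent (7-semitone) deviation folds to -500 cents,
#' i.e. magnitude 12 - 7 = 5 semitones.  Exactly 600 cents is not more than
#' half an octave and is left unadjusted.  Idempotent.
#'
#' @param deviation Signed deviation(s) in cents; `NA` propagates.
#' @return Folded deviation(s) in `(-600, +600]`.
#' @export
fold_octave <- function(deviation) {
  k <- ceiling((deviation - 600) / CENTS_PER_OCTAVE)
  out <- deviation - CENTS_PER_OCTAVE * k
  out[is.na(deviation)] <- NA_real_
  out
}

#' Octave-correct imitated F0 against the model
#'
#' Scales each imitated F0 by the integer power of 2 that brings its
#' deviation from the matched model F0 into `(-600, +600]` cents, and flags
#' the syllables that needed adjusting (the octave-error rate is a data
#' quality diagnostic).  Syllables with missing model or imitated F0 are
#' returned unchanged and unflagged.
#'
#' @param f_imit,f_model Parallel vectors of median F0s in Hz.
#' @return List with `f0` (corrected imitated F0s) and `flagged` (logical).
#' @export
octave_correct_f0 <- function(f_imit, f_model) {
  stopifnot(length(f_imit) == length(f_model))
  dev <- cents_deviation(f_imit, f_model)
  k <- ceiling((dev - 600) / CENTS_PER_OCTAVE)
  k[is.na(k)] <- 0L
  list(f0 = f_imit * 2^(-k), flagged = k != 0L)
}

#' Per-syllable pitch deviations for an aligned pair
#'
#' @param pair A `vm_pair` from [utterance_pair()].
#' @param correct_octave Fold octave errors out of the imitated F0 first
#'   (default; the metrics are then computed on corrected pitches).
#' @return List with `deviation_cents` (signed, per syllable, `NA` where
#'   either F0 is missing), `f0_imit_corrected`, and `octave_flagged`.
#' @export
pair_pitch_deviations <- function(pair, correct_octave = TRUE) {
  fm <- pair$model$events$median_f0_hz
  fi <- pair$imitation$events$median_f0_hz
  if (correct_octave) {
    oc <- octave_correct_f0(fi, fm)
  } else {
    oc <- list(f0 = fi, flagged = rep(FALSE, length(fi)))
  }
  list(deviation_cents = cents_deviation(oc$f0, fm),
       f0_imit_corrected = oc$f0,
       octave_flagged = oc$flagged & !is.na(fm) & !is.na(fi))
}

#' Absolute pitch deviation (cents)
#'
#' Mean over scoreable syllables of the absolute octave-corrected deviation
#' between imitated and model median F0.  Larger values mean less accurate
#' absolute pitch matching.  Syllables with missing F0 on either side are
#' skipped; with no scoreable syllable the metric is `NA`.
#'
#' @inheritParams pair_pitch_deviations
#' @return Mean absolute deviation in cents, or `NA`.
#' @export
absolute_pitch_deviation <- function(pair, correct_octave = TRUE) {
  dev <- pair_pitch_deviations(pair, correct_octave)$deviation_cents
  if (all(is.na(dev))) return(NA_real_)
  mean(abs(dev), na.rm = TRUE)
}

#' Pitch intervals between consecutive syllables
#'
#' @param f0_hz Vector of median F0s in Hz (>= 2 values for a non-empty
#'   series); `NA` F0 makes both touching intervals `NA`.
#' @return List with `signed_cents` and `abs_cents`, each of length
#'   `length(f0_hz) - 1` (empty for fewer than 2 syllables).
#' @export
interval_series <- function(f0_hz) {
  n <- length(f0_hz)
  if (n < 2) return(list(signed_cents = numeric(0), abs_cents = numeric(0)))
  signed <- cents_deviation(f0_hz[-1], f0_hz[-n])
  list(signed_cents = signed, abs_cents = abs(signed))
}

#' Relative pitch deviation (cents)
#'
#' Pitch intervals (absolute cents between consecutive syllables) are
#' compared between imitation and model; the metric is the mean absolute
#' difference of interval magnitudes.  Invariant under global transposition
#' of the imitation.  Intervals touching a missing F0 are skipped.
#'
#' @inheritParams pair_pitch_deviations
#' @return Mean absolute interval-magnitude difference in cents, or `NA`
#'   when no interval is scoreable.
#' @export
relative_pitch_deviation <- function(pair, correct_octave = TRUE) {
  iv <- .pair_intervals(pair, correct_octave)
  d <- abs(iv$imit_abs - iv$model_abs)
  if (all(is.na(d))) return(NA_real_)
  mean(d, na.rm = TRUE)
}

.pair_intervals <- function(pair, correct_octave = TRUE) {
  pd <- pair_pitch_deviations(pair, correct_octave)
  im <- interval_series(pair$model$events$median_f0_hz)
  ii <- interval_series(pd$f0_imit_corrected)
  list(model_signed = im$signed_cents, model_abs = im$abs_cents,
       imit_signed = ii$signed_cents, imit_abs = ii$abs_cents)
}

#' Classify the direction of a pitch interval
#'
#' `up` when the signed interval is +50 cents or more, `down` when -50 or
#' less, `level` when strictly within +/-50 cents.
#'
#' @param signed_cents Signed interval(s) in cents.
#' @return Factor with levels `up`, `down`, `level` (`NA` propagates).
#' @export
classify_direction <- function(signed_cents) {
  out <- rep(NA_character_, length(signed_cents))
  ok <- !is.na(signed_cents)
  out[ok & signed_cents >= 50] <- "up"
  out[ok & signed_cents <= -50] <- "down"
  out[ok & abs(signed_cents) < 50] <- "level"
  factor(out, levels = c("up", "down", "level"))
}

#' Number of pitch contour errors
#'
#' Counts interval positions where the imitated direction (up/down/level at
#' the 50-cent threshold) disagrees with the model direction.  Intervals
#' touching a missing F0 are skipped.
#'
#' @inheritParams pair_pitch_deviations
#' @return Integer count (0 to `n_syllables - 1`).
#' @export
count_contour_errors <- function(pair, correct_octave = TRUE) {
  iv <- .pair_intervals(pair, correct_octave)
  dm <- classify_direction(iv$model_signed)
  di <- classify_direction(iv$imit_signed)
  sum(dm != di, na.rm = TRUE)
}

#' Number of pitch interval errors
#'
#' Counts intervals whose imitated magnitude differs from the model's
#' magnitude by 100 cents or more, direction ignored (magnitudes are
#' compared as absolute values).
#'
#' @inheritParams pair_pitch_deviations
#' @return Integer count (0 to `n_syllables - 1`).
#' @export
count_interval_errors <- function(pair, correct_octave = TRUE) {
  iv <- .pair_intervals(pair, correct_octave)
  sum(abs(iv$imit_abs - iv$model_abs) >= 100, na.rm = TRUE)
}
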