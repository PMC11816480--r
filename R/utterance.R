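# Utterance containers and the flat syllable-table format.

UTTERANCE_ROLES <- c("model", "imitation")
CONDITIONS <- c("speech", "music")
FOCI <- c("early", "late")
GROUPS <- c("autism", "non_autism")

#' Construct a syllable-event table
#'
#' One row per syllable rhyme: 0-based position, rhyme onset and duration in
#' seconds, and median F0 in Hz (`NA` for a fully creaky/unvoiced rhyme).
#'
#' @param onset_s Numeric vector of rhyme onsets (seconds, strictly
#'   increasing, all >= 0).
#' @param duration_s Numeric vector of rhyme durations (seconds, all > 0).
#' @param median_f0_hz Numeric vector of median F0s (Hz, > 0 or `NA`).
#' @param index 0-based syllable positions; defaults to `0:(n-1)`.
#' @return Tibble with columns `index`, `onset_s`, `duration_s`,
#'   `median_f0_hz`.
#' @export
syllable_events <- function(onset_s, duration_s, median_f0_hz,
                            index = seq_along(onset_s) - 1L) {
  n <- length(onset_s)
  stopifnot(length(duration_s) == n, length(median_f0_hz) == n,
            length(index) == n)
  if (n == 0) .abort("an utterance needs at least one syllable", "vm_bad_events")
  if (any(onset_s < 0)) .abort("onsets must be >= 0", "vm_bad_events")
  if (any(duration_s <= 0)) .abort("durations must be > 0", "vm_bad_events")
  if (n > 1 && any(diff(onset_s) <= 0)) {
    .abort("onsets must be strictly increasing within an utterance",
           "vm_nonmonotone_onsets")
  }
  bad_f0 <- !is.na(median_f0_hz) & median_f0_hz <= 0
  if (any(bad_f0)) .abort("median F0 must be > 0 Hz when present", "vm_bad_events")
  tibble::new_tibble(list(index = as.integer(index),
                          onset_s = as.numeric(onset_s),
                          duration_s = as.numeric(duration_s),
                          median_f0_hz = as.numeric(median_f0_hz)),
                     nrow = n)
}

#' Construct an utterance
#'
#' Bundles a syllable-event table with trial metadata.  Utterances carry
#' two to six syllables, the lengths used in the imitation design.
#'
#' @param utterance_id Item identifier, shared between a model utterance and
#'   its imitations.
#' @param role `"model"` or `"imitation"`.
#' @param condition `"speech"` or `"music"`.
#' @param focus `"early"` or `"late"` (position of the focused word).
#' @param speaker_id Speaker (model voice or participant) identifier.
#' @param events Syllable-event tibble from [syllable_events()].
#' @return An object of class `vm_utterance`.
#' @export
utterance <- function(utterance_id, role, condition, focus, speaker_id, events) {
  role <- match.arg(role, UTTERANCE_ROLES)
  condition <- match.arg(condition, CONDITIONS)
  focus <- match.arg(focus, FOCI)
  if (!is.data.frame(events)) .abort("events must be a data frame", "vm_bad_events")
  n <- nrow(events)
  if (n < 2 || n > 6) {
    .abort(sprintf("utterance '%s' has %d syllables; the design uses 2-6",
                   utterance_id, n), "vm_bad_events")
  }
  structure(
    list(utterance_id = as.character(utterance_id), role = role,
         condition = condition, focus = focus,
         speaker_id = as.character(speaker_id),
         events = tibble::as_tibble(events)),
    class = "vm_utterance")
}

#' @export
print.vm_utterance <- function(x, ...) {
  cat(sprintf("<vm_utterance> %s [%s/%s/%s] speaker=%s, %d syllables\n",
              x$utterance_id, x$role, x$condition, x$focus, x$speaker_id,
              nrow(x$events)))
  print(x$events)
  invisible(x)
}

#' Number of syllables in an utterance
#' @param u A `vm_utterance`.
#' @return Integer count.
#' @export
n_syllables <- function(u) nrow(u$events)

SYLLABLE_TABLE_COLS <- c("utterance_id", "role", "condition", "focus",
                         "speaker_id", "index", "onset_s", "duration_s",
                         "median_f0_hz")

#' Read a flat syllable table into utterances
#'
#' The CSV has one row per syllable with columns `utterance_id, role,
#' condition, focus, speaker_id, index, onset_s, duration_s, median_f0_hz`
#' (missing F0 encoded as an empty field).  Rows are grouped into utterances
#' keyed by `(utterance_id, role, speaker_id)`.
#'
#' @param path CSV path.
#' @return List of `vm_utterance` objects, ordered by speaker, condition,
#'   utterance id.
#' @export
read_syllable_table <- function(path) {
  if (!file.exists(path)) .abort(paste0("file not found: ", path), "vm_io_error")
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(median_f0_hz = "numeric"))
  missing_cols <- setdiff(SYLLABLE_TABLE_COLS, names(df))
  if (length(missing_cols)) {
    .abort(paste0("syllable table missing columns: ",
                  paste(missing_cols, collapse = ", ")), "vm_parse_error")
  }
  key <- paste(df$speaker_id, df$role, df$condition, df$utterance_id, sep = "\r")
  utts <- lapply(split(df, key), function(g) {
    g <- g[order(g$index), , drop = FALSE]
    if (anyDuplicated(g$index)) {
      .abort(sprintf("duplicate syllable index in utterance '%s' (%s/%s)",
                     g$utterance_id[[1]], g$role[[1]], g$speaker_id[[1]]),
             "vm_duplicate_index")
    }
    utterance(g$utterance_id[[1]], g$role[[1]], g$condition[[1]],
              g$focus[[1]], g$speaker_id[[1]],
              syllable_events(g$onset_s, g$duration_s, g$median_f0_hz,
                              index = g$index))
  })
  names(utts) <- NULL
  utts
}

#' Flatten utterances to a syllable table
#'
#' @param utterances List of `vm_utterance`.
#' @return Tibble in the syllable-table column layout.
#' @export
utterances_to_table <- function(utterances) {
  dplyr::bind_rows(lapply(utterances, function(u) {
    n <- nrow(u$events)
    tibble::new_tibble(list(
      utterance_id = rep(u$utterance_id, n), role = rep(u$role, n),
      condition = rep(u$condition, n), focus = rep(u$focus, n),
      speaker_id = rep(u$speaker_id, n), index = u$events$index,
      onset_s = u$events$onset_s, duration_s = u$events$duration_s,
      median_f0_hz = u$events$median_f0_hz), nrow = n)
  }))
}

#' Write utterances to a syllable-table CSV
#'
#' Inverse of [read_syllable_table()]; the round trip is the identity on
#' valid inputs.
#'
#' @param utterances List of `vm_utterance`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_syllable_table <- function(utterances, path) {
  .write_csv_atomic(utterances_to_table(utterances), path)
}

#' Write a tidy table to CSV atomically
#'
#' Writes to a temporary file in the destination directory, then renames, so
#' readers never see a half-written file.
#'
#' @param df Data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(df, path) .write_csv_atomic(df, path)

.write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write.csv(df, tmp, row.names = FALSE, na = "")
  if (!file.rename(tmp, path)) .abort(paste0("could not write ", path), "vm_io_error")
  invisible(path)
}

#' Build a participant roster record table
#'
#' @param participant_id,group,sex,age_years,ppvt_r,rspm,musical_training_years,digit_span
#'   Parallel vectors, one entry per participant.
#' @return Tibble, one row per participant.
#' @export
participant_roster <- function(participant_id, group, sex, age_years, ppvt_r,
                               rspm, musical_training_years, digit_span) {
  if (!all(group %in% GROUPS)) {
    .abort(paste0("group must be one of: ", paste(GROUPS, collapse = ", ")),
           "vm_bad_roster")
  }
  if (any(age_years <= 0)) .abort("age_years must be > 0", "vm_bad_roster")
  if (anyDuplicated(participant_id)) {
    .abort("duplicate participant_id in roster", "vm_bad_roster")
  }
  tibble::tibble(participant_id = as.character(participant_id),
                 group = group, sex = sex, age_years = age_years,
                 ppvt_r = ppvt_r, rspm = rspm,
                 musical_training_years = musical_training_years,
                 digit_span = digit_span)
}
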