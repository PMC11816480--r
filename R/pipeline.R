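# Trial assembly: pair model and imitated utterances, score every trial,
# and build the long-format analysis table.

#' Construct a model/imitation pair
#'
#' @param model,imitation `vm_utterance` objects with roles `model` and
#'   `imitation`, the same condition, and equal syllable counts.
#' @return An object of class `vm_pair`.
#' @export
utterance_pair <- function(model, imitation) {
  stopifnot(inherits(model, "vm_utterance"), inherits(imitation, "vm_utterance"))
  if (model$role != "model" || imitation$role != "imitation") {
    .abort("pair needs one model and one imitation utterance", "vm_bad_pair")
  }
  if (model$condition != imitation$condition) {
    .abort("model and imitation must share a condition", "vm_bad_pair")
  }
  if (nrow(model$events) != nrow(imitation$events)) {
    .abort(sprintf(
      "alignment error for item '%s': model has %d syllables, imitation %d",
      model$utterance_id, nrow(model$events), nrow(imitation$events)),
      "vm_alignment_error")
  }
  structure(
    list(item_id = model$utterance_id, condition = model$condition,
         focus = model$focus, participant_id = imitation$speaker_id,
         model = model, imitation = imitation),
    class = "vm_pair")
}

#' @export
print.vm_pair <- function(x, ...) {
  cat(sprintf("<vm_pair> item=%s condition=%s participant=%s (%d syllables)\n",
              x$item_id, x$condition, x$participant_id, nrow(x$model$events)))
  invisible(x)
}

#' Pair imitations with their model utterances
#'
#' Matches each imitation to the model utterance with the same
#' `(utterance_id, condition)` key.  Imitations whose syllable count differs
#' from the model's (inserted/deleted syllables) are excluded and reported,
#' never silently dropped.  Output order is deterministic: participant,
#' condition, item.
#'
#' @param models,imitations Lists of `vm_utterance`.
#' @return List with `pairs` (list of `vm_pair`) and `exclusions` (tibble
#'   with `participant_id`, `item_id`, `condition`, `expected_n`,
#'   `observed_n`).
#' @export
pair_trials <- function(models, imitations) {
  # key on item+condition; with several model voices, prefer the voice named
  # by the imitation's "model_speaker" attribute (set by the simulator)
  mindex <- split(seq_along(models),
                  vapply(models, function(u) paste(u$utterance_id, u$condition,
                                                   sep = "\r"), ""))
  ord <- order(vapply(imitations, function(u) u$speaker_id, ""),
               vapply(imitations, function(u) u$condition, ""),
               vapply(imitations, function(u) u$utterance_id, ""))
  pairs <- list()
  excl <- list()
  for (i in ord) {
    im <- imitations[[i]]
    key <- paste(im$utterance_id, im$condition, sep = "\r")
    cand <- mindex[[key]]
    if (is.null(cand)) {
      .abort(sprintf("imitation references unknown item '%s' (%s)",
                     im$utterance_id, im$condition), "vm_unknown_item")
    }
    mi <- cand[[1]]
    want <- attr(im, "model_speaker")
    if (!is.null(want)) {
      hit <- cand[vapply(models[cand], function(u) u$speaker_id, "") == want]
      if (length(hit)) mi <- hit[[1]]
    }
    mod <- models[[mi]]
    if (nrow(mod$events) != nrow(im$events)) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        participant_id = im$speaker_id, item_id = im$utterance_id,
        condition = im$condition, expected_n = nrow(mod$events),
        observed_n = nrow(im$events))
      next
    }
    pairs[[length(pairs) + 1L]] <- utterance_pair(mod, im)
  }
  list(pairs = pairs,
       exclusions = if (length(excl)) dplyr::bind_rows(excl) else
         tibble::tibble(participant_id = character(), item_id = character(),
                        condition = character(), expected_n = integer(),
                        observed_n = integer()))
}

#' Score pairs and assemble the long-format trial table
#'
#' One row per participant x item x condition, holding the seven imitation
#' metrics joined to roster covariates.  PPVT-R and age are centered at the
#' mean over unique participants (not over rows), so unequal trial counts do
#' not bias the centers; the centering constants are stored as attributes
#' `ppvt_r_center` and `age_center`.  Effect codings (+1 autism / -1
#' non-autism; +1 music / -1 speech) are added as `group_c`, `condition_c`.
#'
#' @param pairs List of `vm_pair` (e.g. from [pair_trials()]).
#' @param roster Participant tibble from [participant_roster()], covering
#'   every participant appearing in `pairs`.
#' @param correct_octave Passed to [score_pair()].
#' @return Tibble of class `vm_trial_table`, ordered by participant,
#'   condition, item.
#' @export
build_trial_table <- function(pairs, roster, correct_octave = TRUE) {
  pid <- vapply(pairs, function(p) p$participant_id, "")
  missing_p <- setdiff(unique(pid), roster$participant_id)
  if (length(missing_p)) {
    .abort(paste0("participants missing from roster: ",
                  paste(missing_p, collapse = ", ")), "vm_missing_participant")
  }
  rows <- dplyr::bind_rows(lapply(pairs, function(p) {
    ms <- score_pair(p, correct_octave)
    meta <- tibble::new_tibble(list(participant_id = p$participant_id,
                                    condition = p$condition, focus = p$focus,
                                    item_id = p$item_id), nrow = 1L)
    tibble::new_tibble(c(meta, ms), nrow = 1L)
  }))
  rows <- dplyr::left_join(rows, roster, by = "participant_id")
  used <- roster[roster$participant_id %in% unique(pid), ]
  ppvt_center <- mean(used$ppvt_r)
  age_center <- mean(used$age_years)
  rows$ppvt_r_centered <- rows$ppvt_r - ppvt_center
  rows$age_centered <- rows$age_years - age_center
  rows$group_c <- ifelse(rows$group == "autism", 1, -1)
  rows$condition_c <- ifelse(rows$condition == "music", 1, -1)
  rows <- rows[order(rows$participant_id, rows$condition, rows$item_id), ]
  out <- tibble::as_tibble(rows)
  attr(out, "ppvt_r_center") <- ppvt_center
  attr(out, "age_center") <- age_center
  class(out) <- c("vm_trial_table", class(out))
  out
}
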