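#' Decide a selection from per-epoch hard labels
#'
#' Sums the classifier's 0/1 labels per stimulus (the blink vote) and picks
#' the stimulus with the highest vote. Ties break deterministically to the
#' lowest stimulus index.
#'
#' @param labels A tibble (or data frame) with columns `stimulus_id` and
#'   `label` (0/1), one row per epoch; every stimulus id in
#'   `0:(n_stimuli - 1)` must be present.
#' @param n_stimuli Number of selectable stimuli (default 6).
#' @param true_target Optional instructed target id, recorded for scoring.
#' @return A one-row `selection_result` tibble: `predicted`, `true_target`,
#'   `correct`, `n_blinks_used`, and a list-column `votes` with the
#'   per-stimulus vote vector.
#' @export
#' @examples
#' labs <- tibble::tibble(stimulus_id = rep(0:5, each = 4),
#'                        label = as.integer(rep(0:5, each = 4) == 2))
#' decide_selection(labs, true_target = 2)
decide_selection <- function(labels, n_stimuli = 6, true_target = NA_integer_) {
  labels <- tibble::as_tibble(labels)
  present <- sort(unique(labels$stimulus_id))
  expected <- seq_len(n_stimuli) - 1L
  if (!setequal(present, expected)) {
    rlang::abort(sprintf("labels must cover every stimulus id 0..%d (missing: %s).",
                         n_stimuli - 1L,
                         paste(setdiff(expected, present), collapse = ", ")))
  }
  votes <- vapply(expected, function(s) {
    sum(labels$label[labels$stimulus_id == s])
  }, numeric(1))
  predicted <- expected[which.max(votes)]  # first max = lowest index on ties
  n_blinks <- max(table(labels$stimulus_id))
  out <- tibble::tibble(
    predicted = as.integer(predicted),
    true_target = as.integer(true_target),
    correct = if (is.na(true_target)) NA else predicted == true_target,
    n_blinks_used = as.integer(n_blinks),
    votes = list(stats::setNames(votes, expected))
  )
  class(out) <- c("selection_result", class(out))
  out
}

#' Load the continent / destination catalogue
#'
#' The two-step game selects first a continent, then one of its six
#' destinations. The default catalogue ships with the package (6 continents
#' x 6 places, 36 destinations); a custom catalogue can be supplied as a JSON
#' file mapping each continent name to an ordered list of exactly 6 places.
#'
#' @param path Path to a catalogue JSON file, or `NULL` for the default.
#' @return Named list of 6 character vectors of length 6.
#' @export
#' @examples
#' cat6 <- load_catalogue()
#' cat6$Asia
load_catalogue <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "catalogue.json", package = "p300tour")
  }
  if (!file.exists(path)) rlang::abort(paste0("catalogue file not found: ", path))
  cat6 <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                   error = function(e) {
                     rlang::abort(paste0("malformed catalogue JSON: ",
                                         conditionMessage(e)))
                   })
  if (!is.list(cat6) || length(cat6) != 6) {
    rlang::abort("catalogue must define exactly 6 continents.")
  }
  bad <- names(cat6)[vapply(cat6, length, integer(1)) != 6]
  if (length(bad)) {
    rlang::abort(paste0("each continent needs exactly 6 places; invalid: ",
                        paste(bad, collapse = ", ")))
  }
  lapply(cat6, as.character)
}

#' Play one two-step trial (continent, then place)
#'
#' Runs the decoding chain on the two selection blocks of a trial: the
#' continent step's epochs are classified and voted, the predicted continent
#' opens its destination screen, and the place step repeats the procedure.
#' Each step is scored independently against its instructed target id, which
#' matches an online protocol that proceeds with the (possibly wrong)
#' selected continent's screen.
#'
#' @param model An `swlda_model`.
#' @param step_epochs List of two `epoch_set`s (continent step, place step),
#'   each from one 6-stimulus selection block.
#' @param instructed Integer length-2: instructed continent id and place id
#'   (0-based).
#' @param catalogue Catalogue list from [load_catalogue()].
#' @return A one-row tibble: predicted and instructed ids for both steps,
#'   per-step correctness, and the named continent/place strings.
#' @export
play_trial <- function(model, step_epochs, instructed,
                       catalogue = load_catalogue()) {
  stopifnot(length(step_epochs) == 2, length(instructed) == 2)
  score_step <- function(epochs, target) {
    fm <- to_features(epochs, feature_sfreq = model_feature_sfreq(model, epochs))
    labs <- tibble::tibble(stimulus_id = fm$info$stimulus_id,
                           label = predict_label(model, fm))
    decide_selection(labs, true_target = target)
  }
  s1 <- score_step(step_epochs[[1]], instructed[1])
  s2 <- score_step(step_epochs[[2]], instructed[2])
  continents <- names(catalogue)
  tibble::tibble(
    continent_pred = s1$predicted, continent_true = s1$true_target,
    continent_correct = s1$correct,
    place_pred = s2$predicted, place_true = s2$true_target,
    place_correct = s2$correct,
    continent = continents[s1$predicted + 1L],
    place = catalogue[[s1$predicted + 1L]][s2$predicted + 1L]
  )
}

# feature grid must match the training grid; infer it from the model map
model_feature_sfreq <- function(model, epochs, default = 128) {
  fm <- model$feature_map
  if (is.null(fm)) return(default)
  ts <- sort(unique(fm$time_ms))
  if (length(ts) < 2) return(default)
  round(1000 / (ts[2] - ts[1]))
}

#' Replay a whole online session through a trained model
#'
#' Preprocesses the session, splits its epochs by selection block, and runs
#' the blink vote for every selection. Each of the 12 selections (6 trials x
#' continent + place) is scored independently against its instructed target.
#'
#' @param model An `swlda_model`.
#' @param session An online `bci_session` (EEG + schedule + ground truth).
#' @param proc_sfreq,band,window Preprocessing parameters, see
#'   [preprocess_session()].
#' @return A `session_record` tibble, one row per selection: `block_id`,
#'   `trial`, `step`, `predicted`, `true_target`, `correct`, `votes`.
#' @export
replay_session <- function(model, session, proc_sfreq = 512,
                           band = c(0.5, 10), window = c(200, 600)) {
  epochs <- preprocess_session(session, proc_sfreq, band, window)
  fm <- to_features(epochs, feature_sfreq = model_feature_sfreq(model, epochs))
  labels <- tibble::tibble(
    block_id = fm$info$block_id,
    stimulus_id = fm$info$stimulus_id,
    label = predict_label(model, fm)
  )
  score_labels(labels, session$targets)
}

#' Score per-epoch labels into per-selection results
#'
#' @param labels Tibble with `block_id`, `stimulus_id`, `label`.
#' @param targets Tibble with `block_id`, `target_id` (and optionally
#'   `trial`, `step`).
#' @return A `session_record` tibble, one row per block.
#' @export
score_labels <- function(labels, targets) {
  out <- purrr::map_dfr(seq_len(nrow(targets)), function(i) {
    b <- targets$block_id[i]
    sel <- decide_selection(labels[labels$block_id == b, , drop = FALSE],
                            true_target = targets$target_id[i])
    dplyr::bind_cols(
      tibble::tibble(
        block_id = b,
        trial = if ("trial" %in% names(targets)) targets$trial[i] else NA_integer_,
        step = if ("step" %in% names(targets)) targets$step[i] else NA_integer_),
      tibble::as_tibble(sel)
    )
  })
  class(out) <- c("session_record", class(out))
  out
}
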