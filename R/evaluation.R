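#' Selection accuracy in percent
#'
#' Fraction of selections whose predicted stimulus equals the instructed
#' target, as an unrounded percentage. Published tables in this field often
#' truncate to whole percent for display (91.67 printed as 91);
#' [accuracy_display()] applies that convention without losing the full
#' precision kept here.
#'
#' @param results A `session_record` / `selection_result` tibble with a
#'   `correct` column, or a logical vector of per-selection correctness.
#' @return Accuracy in percent (0-100), full precision.
#' @export
#' @examples
#' selection_accuracy(c(rep(TRUE, 8), rep(FALSE, 4)))  # 66.67
selection_accuracy <- function(results) {
  correct <- if (is.logical(results)) results else results$correct
  if (!length(correct)) rlang::abort("no selections to score.")
  if (anyNA(correct)) rlang::abort("selections without a known target cannot be scored.")
  100 * mean(correct)
}

#' @rdname selection_accuracy
#' @param accuracy Accuracy in percent.
#' @export
accuracy_display <- function(accuracy) trunc(accuracy)

#' Wolpaw information transfer rate
#'
#' The standard Wolpaw bit rate for an M-class selection with accuracy P and
#' selection time T:
#' \deqn{B = \log_2 M + P \log_2 P + (1-P) \log_2\frac{1-P}{M-1}}
#' bits per selection (with \eqn{0 \log_2 0 := 0}), reported as
#' \eqn{B \cdot 60 / T} bits per minute. At chance accuracy `P = 1/M` the
#' rate is 0; below chance the formula's (positive) value is returned as is.
#'
#' @param n_classes Number of selectable classes M (>= 2; default 6).
#' @param accuracy Selection accuracy P as a fraction in `[0, 1]`; vectorized.
#' @param selection_time_s Time per selection T in seconds (> 0).
#' @param digits Rounding for display; `NULL` (default) returns full
#'   precision. Published ITR tables print 2 decimals.
#' @return ITR in bits per minute.
#' @export
#' @examples
#' wolpaw_itr(6, 1.0, 30.5, digits = 2)     # 5.09
#' wolpaw_itr(6, 0.9375, 11.37, digits = 2) # 11.10
wolpaw_itr <- function(n_classes = 6, accuracy, selection_time_s,
                       digits = NULL) {
  if (n_classes < 2) rlang::abort("`n_classes` must be >= 2.")
  if (any(selection_time_s <= 0)) rlang::abort("`selection_time_s` must be positive.")
  if (any(accuracy < 0 | accuracy > 1)) rlang::abort("`accuracy` must be in [0, 1].")
  p <- accuracy
  m <- n_classes
  xlog <- function(x) ifelse(x > 0, x * log2(x), 0)
  bits <- log2(m) + xlog(p) + ifelse(p < 1, (1 - p) * log2((1 - p) / (m - 1)), 0)
  out <- bits * 60 / selection_time_s
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Default per-N selection response times
#'
#' Empirical response time (stimulation plus system delay) of one 6-stimulus
#' selection for N flashes per stimulus, in seconds. These constants embed a
#' measured system delay and are configuration values, not derivable from
#' the ISI alone.
#'
#' @return Named numeric vector for N = 1, 5, 10, 15, 20.
#' @export
default_response_times <- function() {
  c(`1` = 6.62, `5` = 11.37, `10` = 17.75, `15` = 23.87, `20` = 30.5)
}

#' Offline accuracy with subsampled blinks
#'
#' Estimates the accuracy the system would have reached with only N flashes
#' per stimulus: in each repeat, N epochs per stimulus are drawn without
#' replacement within every selection block, the blink vote is re-run, and
#' the selection accuracy computed; the mean and SD over `repeats` draws are
#' returned. When N equals the available epochs per stimulus the draw is
#' exhaustive and every repeat is identical (SD 0).
#'
#' @param labels Tibble with per-epoch `block_id`, `stimulus_id`, `label`
#'   (e.g. the labelled epochs of [replay_session()]'s internals), or an
#'   object from [predict_session_labels()].
#' @param targets Tibble with `block_id`, `target_id`.
#' @param n_blinks N, epochs drawn per stimulus per selection.
#' @param repeats Number of random draws (default 10).
#' @param seed Optional integer seed.
#' @return One-row tibble: `n_blinks`, `mean_accuracy`, `sd_accuracy` (percent).
#' @export
subsample_accuracy <- function(labels, targets, n_blinks, repeats = 10,
                               seed = NULL) {
  counts <- dplyr::count(labels, .data$block_id, .data$stimulus_id)
  if (any(counts$n < n_blinks)) {
    rlang::abort(sprintf("`n_blinks` = %d exceeds the available epochs per stimulus (min %d).",
                         n_blinks, min(counts$n)))
  }
  accs <- with_opt_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      sub <- labels |>
        dplyr::group_by(.data$block_id, .data$stimulus_id) |>
        dplyr::slice_sample(n = n_blinks) |>
        dplyr::ungroup()
      selection_accuracy(score_labels(sub, targets))
    }, numeric(1))
  })
  tibble::tibble(n_blinks = as.integer(n_blinks),
                 mean_accuracy = mean(accs),
                 sd_accuracy = stats::sd(accs))
}

#' Predict per-epoch labels for one or more sessions
#'
#' Convenience wrapper: preprocess each online session, classify every epoch
#' with the model, and return the pooled label table plus the pooled target
#' table (block ids offset so they stay unique across sessions).
#'
#' @param model An `swlda_model`.
#' @param sessions A `bci_session` or list of them.
#' @param proc_sfreq,band,window See [preprocess_session()].
#' @return List with `labels` and `targets` tibbles.
#' @export
predict_session_labels <- function(model, sessions, proc_sfreq = 512,
                                   band = c(0.5, 10), window = c(200, 600)) {
  if (inherits(sessions, "bci_session")) sessions <- list(sessions)
  offset <- 0L
  labels <- list(); targets <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    epochs <- preprocess_session(s, proc_sfreq, band, window)
    fm <- to_features(epochs, feature_sfreq = model_feature_sfreq(model, epochs))
    labels[[i]] <- tibble::tibble(
      block_id = fm$info$block_id + offset,
      stimulus_id = fm$info$stimulus_id,
      label = predict_label(model, fm)
    )
    targets[[i]] <- dplyr::mutate(s$targets, block_id = .data$block_id + offset)
    offset <- offset + max(s$targets$block_id)
  }
  list(labels = dplyr::bind_rows(labels), targets = dplyr::bind_rows(targets))
}

#' Accuracy / ITR curve across blink counts
#'
#' Runs [subsample_accuracy()] for every N and attaches the Wolpaw ITR
#' computed from the mean accuracy and the per-N response time.
#'
#' @param labels,targets See [subsample_accuracy()].
#' @param n_blinks Vector of N values (default `c(1, 5, 10, 15, 20)`).
#' @param response_times Named per-N selection times in seconds (default
#'   [default_response_times()]); must cover every N.
#' @param repeats Draws per N (default 10).
#' @param seed Optional integer seed.
#' @param n_classes Number of stimuli (default 6).
#' @return A `blink_curve` tibble: `n_blinks`, `mean_accuracy`, `sd_accuracy`,
#'   `response_time_s`, `itr_bits_min`.
#' @export
blink_curve <- function(labels, targets, n_blinks = c(1, 5, 10, 15, 20),
                        response_times = default_response_times(),
                        repeats = 10, seed = NULL, n_classes = 6) {
  missing <- setdiff(as.character(n_blinks), names(response_times))
  if (length(missing)) {
    rlang::abort(paste0("no response time for N = ", paste(missing, collapse = ", ")))
  }
  n_blinks <- sort(n_blinks)
  seeds <- if (is.null(seed)) vector("list", length(n_blinks)) else
    as.list(seed + seq_along(n_blinks) - 1L)
  rows <- purrr::map2_dfr(n_blinks, seeds, function(nb, sd_i) {
    subsample_accuracy(labels, targets, nb, repeats = repeats, seed = sd_i)
  })
  out <- rows |>
    dplyr::mutate(
      response_time_s = unname(response_times[as.character(.data$n_blinks)]),
      itr_bits_min = wolpaw_itr(n_classes, .data$mean_accuracy / 100,
                                .data$response_time_s)
    )
  class(out) <- c("blink_curve", class(out))
  out
}

#' Count selected features per channel
#'
#' Histogram of stepwise-selected features per channel, summed across models
#' (e.g. across a cohort of subjects). Channels with no selected feature are
#' kept with a zero count.
#'
#' @param models An `swlda_model` or list of them.
#' @param feature_map Feature-map tibble (`feature`, `channel`, `time_ms`);
#'   defaults to the first model's own map. Must cover every selected index.
#' @return Tibble `channel`, `n_features`, ordered as in the feature map.
#' @export
channel_feature_counts <- function(models, feature_map = NULL) {
  if (inherits(models, "swlda_model")) models <- list(models)
  if (is.null(feature_map)) feature_map <- models[[1]]$feature_map
  if (is.null(feature_map)) rlang::abort("a feature map is required.")
  selected <- unlist(lapply(models, function(m) m$selected))
  unknown <- setdiff(selected, feature_map$feature)
  if (length(unknown)) {
    rlang::abort(paste0("selected index outside the feature map: ",
                        paste(utils::head(unknown), collapse = ", ")))
  }
  channels <- unique(feature_map$channel)
  hit <- feature_map$channel[match(selected, feature_map$feature)]
  tibble::tibble(
    channel = channels,
    n_features = as.integer(vapply(channels, function(ch) sum(hit == ch),
                                   numeric(1)))
  )
}

#' Summarize Likert-scale questionnaire scores
#'
#' Mean and population standard deviation (divide-by-n) of 1-5 Likert
#' responses — the convention used by questionnaire summary tables in this
#' field, e.g. scores 4,5,5,4,3,4,5,5,5,3 summarize to 4.3 +/- 0.78.
#'
#' @param scores Integer vector of responses in 1..5.
#' @return One-row tibble: `n`, `mean`, `sd` (population SD).
#' @export
#' @examples
#' summarize_likert(c(4, 5, 5, 4, 3, 4, 5, 5, 5, 3))
summarize_likert <- function(scores) {
  if (!length(scores)) rlang::abort("`scores` must be non-empty.")
  if (any(scores < 1 | scores > 5 | scores != round(scores))) {
    rlang::abort("`scores` must be integers in 1..5.")
  }
  n <- length(scores)
  mu <- mean(scores)
  tibble::tibble(n = n, mean = mu, sd = sqrt(sum((scores - mu)^2) / n))
}
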