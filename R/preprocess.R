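#' Resample a continuous EEG record
#'
#' Anti-alias low-pass filters (6th-order Butterworth at 0.8 x the new
#' Nyquist, applied forward-backward for zero phase) and then decimates when
#' the rate ratio is an integer, or linearly interpolates onto the new grid
#' otherwise. Duration is preserved to within one sample.
#'
#' @param eeg An [eeg_record()].
#' @param target_sfreq New sampling rate in Hz; must not exceed the current
#'   rate.
#' @return A resampled `eeg_record`.
#' @export
resample <- function(eeg, target_sfreq) {
  stopifnot(inherits(eeg, "eeg_record"))
  if (target_sfreq > eeg$sfreq) {
    rlang::abort("`target_sfreq` must not exceed the current sampling rate.")
  }
  if (target_sfreq == eeg$sfreq) return(eeg)
  cutoff <- 0.8 * (target_sfreq / 2)
  bf <- signal::butter(6, cutoff / (eeg$sfreq / 2), type = "low")
  filtered <- t(apply(eeg$data, 1, function(x) signal::filtfilt(bf, x)))
  ratio <- eeg$sfreq / target_sfreq
  n_new <- floor(n_samples(eeg) / ratio)
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1L, by = round(ratio), length.out = n_new)
    data <- filtered[, idx, drop = FALSE]
  } else {
    t_old <- (seq_len(n_samples(eeg)) - 1) / eeg$sfreq
    t_new <- (seq_len(n_new) - 1) / target_sfreq
    data <- t(apply(filtered, 1, function(x) {
      stats::approx(t_old, x, xout = t_new, rule = 2)$y
    }))
  }
  eeg_record(data, target_sfreq, eeg$channel_names)
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so the
#' per-sample channel mean of the output is zero.
#'
#' @param eeg An [eeg_record()] with at least two channels.
#' @return A re-referenced `eeg_record`.
#' @export
common_average_reference <- function(eeg) {
  stopifnot(inherits(eeg, "eeg_record"))
  if (n_channels(eeg) < 2) {
    rlang::abort("common average reference needs at least 2 channels.")
  }
  data <- sweep(eeg$data, 2, colMeans(eeg$data))
  eeg_record(data, eeg$sfreq, eeg$channel_names)
}

#' Zero-phase band-pass filter
#'
#' Cascade of a 2nd-order Butterworth high-pass at `low` Hz and a 4th-order
#' Butterworth low-pass at `high` Hz, each applied forward-backward
#' (zero-phase). The split realization keeps the recursion numerically stable
#' at the very low normalized corner frequency of the 0.5 Hz default.
#'
#' @param eeg An [eeg_record()].
#' @param low High-pass corner in Hz (default 0.5).
#' @param high Low-pass corner in Hz (default 10).
#' @return A filtered `eeg_record`.
#' @export
bandpass <- function(eeg, low = 0.5, high = 10) {
  stopifnot(inherits(eeg, "eeg_record"))
  nyq <- eeg$sfreq / 2
  if (!(low > 0 && low < high && high < nyq)) {
    rlang::abort("need 0 < low < high < sfreq / 2.")
  }
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(4, high / nyq, type = "low")
  data <- t(apply(eeg$data, 1, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  }))
  eeg_record(data, eeg$sfreq, eeg$channel_names)
}

#' Extract per-flash epochs
#'
#' Cuts one epoch per flash event over the half-open window
#' `[window[1], window[2])` ms relative to flash onset, labelling each epoch
#' with the event's target flag, stimulus id and block id. The epoch holds
#' `floor((window[2] - window[1]) / 1000 * sfreq)` samples per channel.
#'
#' @param eeg An [eeg_record()].
#' @param schedule A `stim_schedule`; every event window must lie inside the
#'   recording.
#' @param window Numeric length-2, epoch window in ms after onset
#'   (default `c(200, 600)`).
#' @return An `epoch_set`: list with `data` (epochs x channels x samples
#'   array), `info` (tibble: `epoch`, `label`, `stimulus_id`, `block_id`,
#'   `onset_s`), `window`, `sfreq`, `channel_names`.
#' @export
extract_epochs <- function(eeg, schedule, window = c(200, 600)) {
  stopifnot(inherits(eeg, "eeg_record"))
  if (window[1] >= window[2]) rlang::abort("window start must precede end.")
  n_ep <- nrow(schedule)
  nsamp <- floor((window[2] - window[1]) / 1000 * eeg$sfreq)
  data <- array(0, dim = c(n_ep, n_channels(eeg), nsamp))
  if (n_ep > 0) {
    i0 <- round(schedule$onset_s * eeg$sfreq) +
      floor(window[1] / 1000 * eeg$sfreq) + 1L
    bad <- which(i0 < 1 | i0 + nsamp - 1L > n_samples(eeg))
    if (length(bad)) {
      rlang::abort(sprintf(
        "event %d (onset %.3f s) has its epoch window outside the recording.",
        bad[1], schedule$onset_s[bad[1]]))
    }
    for (e in seq_len(n_ep)) {
      data[e, , ] <- eeg$data[, i0[e]:(i0[e] + nsamp - 1L)]
    }
  }
  info <- tibble::tibble(
    epoch = seq_len(n_ep),
    label = as.integer(schedule$is_target),
    stimulus_id = schedule$stimulus_id,
    block_id = schedule$block_id,
    onset_s = schedule$onset_s
  )
  structure(
    list(data = data, info = info, window = window, sfreq = eeg$sfreq,
         channel_names = eeg$channel_names),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples, window [%g, %g) ms @ %g Hz, %d target\n",
    d[1], d[2], d[3], x$window[1], x$window[2], x$sfreq, sum(x$info$label)))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts a per-epoch, per-channel baseline statistic. The epoch window
#' starts after stimulus onset, so no pre-stimulus segment is available; the
#' default statistic is therefore the whole-epoch mean of each channel.
#'
#' @param epochs An `epoch_set`.
#' @param statistic Baseline statistic, `"mean"` (default) or `"median"`.
#' @return A corrected `epoch_set`. Idempotent for the mean statistic.
#' @export
baseline_correct <- function(epochs, statistic = c("mean", "median")) {
  stopifnot(inherits(epochs, "epoch_set"))
  statistic <- rlang::arg_match(statistic)
  if (dim(epochs$data)[1] == 0) rlang::abort("no epochs to correct.")
  fn <- if (statistic == "mean") rowMeans else function(m) apply(m, 1, stats::median)
  for (e in seq_len(dim(epochs$data)[1])) {
    sl <- epochs$data[e, , , drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, nrow = dim(epochs$data)[2])
    epochs$data[e, , ] <- sl - fn(sl)
  }
  epochs
}

#' Flatten epochs into a feature matrix
#'
#' Resamples every epoch onto the `feature_sfreq` grid (plain decimation when
#' the rate ratio is an integer; the band-limited signal needs no further
#' anti-aliasing after the 0.5-10 Hz band-pass) and flattens channel-major
#' into one long feature vector per epoch. `feature_map` records the
#' (channel, time) identity of every column.
#'
#' @param epochs An `epoch_set`.
#' @param feature_sfreq Feature-grid rate in Hz (default 128; must not exceed
#'   the epoch rate).
#' @return A `feature_matrix`: list with `values` (epochs x features matrix),
#'   `feature_map` (tibble: `feature`, `channel`, `time_ms`), `info` (epoch
#'   label table), `feature_sfreq`.
#' @export
to_features <- function(epochs, feature_sfreq = 128) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (feature_sfreq > epochs$sfreq) {
    rlang::abort("`feature_sfreq` must not exceed the epoch sampling rate.")
  }
  d <- dim(epochs$data)
  win_ms <- epochs$window[2] - epochs$window[1]
  nf <- floor(win_ms / 1000 * feature_sfreq)
  ratio <- epochs$sfreq / feature_sfreq
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1L, by = round(ratio), length.out = nf)
    grid <- function(x) x[idx]
  } else {
    t_old <- (seq_len(d[3]) - 1) / epochs$sfreq
    t_new <- (seq_len(nf) - 1) / feature_sfreq
    grid <- function(x) stats::approx(t_old, x, xout = t_new, rule = 2)$y
  }
  values <- matrix(0, d[1], d[2] * nf)
  for (e in seq_len(d[1])) {
    sl <- matrix(epochs$data[e, , ], nrow = d[2])
    # channel-major: each channel's nf grid samples are contiguous
    values[e, ] <- as.numeric(vapply(seq_len(d[2]),
                                     function(ch) grid(sl[ch, ]), numeric(nf)))
  }
  feature_map <- tibble::tibble(
    feature = seq_len(d[2] * nf),
    channel = rep(epochs$channel_names, each = nf),
    time_ms = rep(epochs$window[1] + (seq_len(nf) - 1) * 1000 / feature_sfreq,
                  times = d[2])
  )
  structure(
    list(values = values, feature_map = feature_map, info = epochs$info,
         feature_sfreq = feature_sfreq),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d epochs x %d features (%d channels x %d time points)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$feature_map$channel)),
              length(unique(x$feature_map$time_ms))))
  invisible(x)
}

#' Run the full preprocessing chain on a session
#'
#' Composes the decoding front end: resample to `proc_sfreq`, common average
#' reference, 0.5-10 Hz band-pass, epoch the `[200, 600)` ms window, and
#' baseline-correct. Epoch counts and labels are exactly those of the
#' schedule.
#'
#' @param session A `bci_session` (or a list with `eeg` and `schedule`).
#' @param proc_sfreq Processing rate in Hz (default 512).
#' @param band Band-pass corners in Hz (default `c(0.5, 10)`).
#' @param window Epoch window in ms (default `c(200, 600)`).
#' @param car Apply the common average reference (default `TRUE`, the
#'   decoding chain's setting). ERP waveform summaries may prefer the
#'   recording reference (`FALSE`); see the methods vignette.
#' @return An `epoch_set`.
#' @export
preprocess_session <- function(session, proc_sfreq = 512, band = c(0.5, 10),
                               window = c(200, 600), car = TRUE) {
  eeg <- session$eeg
  if (eeg$sfreq > proc_sfreq) eeg <- resample(eeg, proc_sfreq)
  if (car) eeg <- common_average_reference(eeg)
  eeg <- bandpass(eeg, band[1], band[2])
  epochs <- extract_epochs(eeg, session$schedule, window)
  baseline_correct(epochs)
}
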