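#' Write a continuous EEG record and its event schedule to disk
#'
#' The signal goes to a minimal EDF file (16-bit quantization against each
#' channel's physical range, 1-second data records, zero-padded to a whole
#' record; the true sample count is stored in the recording-id header field
#' so the padding round-trips away). Events go to a plain CSV with columns
#' `onset_s`, `stimulus_id`, `block_id`, `is_target`.
#'
#' @param eeg An [eeg_record()] with an integer sampling rate.
#' @param schedule A `stim_schedule` (or `NULL` to skip the event file).
#' @param edf_path Output EDF path.
#' @param events_path Output events CSV path (default: `edf_path` with a
#'   `.events.csv` suffix).
#' @return Invisibly, the EDF path.
#' @export
write_eeg <- function(eeg, schedule, edf_path,
                      events_path = paste0(edf_path, ".events.csv")) {
  stopifnot(inherits(eeg, "eeg_record"))
  if (abs(eeg$sfreq - round(eeg$sfreq)) > 1e-9) {
    rlang::abort("EDF export requires an integer sampling rate.")
  }
  sfreq <- as.integer(round(eeg$sfreq))
  ns <- n_channels(eeg)
  n <- n_samples(eeg)
  n_rec <- ceiling(n / sfreq)

  pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")
  con <- file(edf_path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(pad("0", 8), con, eos = NULL)
  writeChar(pad("X", 80), con, eos = NULL)                       # patient id
  writeChar(pad(paste0("nsamples=", n), 80), con, eos = NULL)    # recording id
  writeChar(pad("01.01.00", 8), con, eos = NULL)
  writeChar(pad("00.00.00", 8), con, eos = NULL)
  writeChar(pad(256L * (ns + 1L), 8), con, eos = NULL)
  writeChar(pad("", 44), con, eos = NULL)
  writeChar(pad(n_rec, 8), con, eos = NULL)
  writeChar(pad("1", 8), con, eos = NULL)
  writeChar(pad(ns, 4), con, eos = NULL)

  # EDF numeric header fields are fixed 8-char ASCII; shrink precision until
  # the text fits, then use the *parsed-back* values for digitization so the
  # reader recovers amplitudes exactly up to the 16-bit quantization step
  fit8 <- function(v) {
    for (d in 7:1) {
      cand <- formatC(signif(v, d), format = "g", digits = d)
      if (nchar(cand) <= 8) return(cand)
    }
    stop("value does not fit an 8-char EDF field")
  }
  pmin_ <- apply(eeg$data, 1, min)
  pmax_ <- apply(eeg$data, 1, max)
  span <- pmax_ - pmin_
  flat <- span < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  span <- pmax_ - pmin_
  pmin_s <- vapply(pmin_ - 1e-4 * span, fit8, character(1))
  pmax_s <- vapply(pmax_ + 1e-4 * span, fit8, character(1))
  pmin_ <- as.numeric(pmin_s)
  pmax_ <- as.numeric(pmax_s)
  if (any(pmin_ >= pmax_)) rlang::abort("channel range collapsed in EDF header.")
  num8 <- function(s) pad(s, 8)
  for (x in list(pad(eeg$channel_names, 16), pad(rep("", ns), 80),
                 pad(rep("uV", ns), 8), num8(pmin_s), num8(pmax_s),
                 pad(rep(-32768L, ns), 8), pad(rep(32767L, ns), 8),
                 pad(rep("", ns), 80), pad(rep(sfreq, ns), 8),
                 pad(rep("", ns), 32))) {
    writeChar(paste(x, collapse = ""), con, eos = NULL)
  }

  scale <- (pmax_ - pmin_) / 65535
  dig <- round(sweep(sweep(eeg$data, 1, pmin_), 1, scale, "/")) - 32768
  dig <- pmin(pmax(dig, -32768), 32767)
  padded <- matrix(0L, ns, n_rec * sfreq)
  padded[, seq_len(n)] <- as.integer(dig)
  for (r in seq_len(n_rec)) {
    seg <- padded[, ((r - 1L) * sfreq + 1L):(r * sfreq), drop = FALSE]
    writeBin(as.integer(t(seg)), con, size = 2, endian = "little")
  }

  if (!is.null(schedule)) write_events(schedule, events_path)
  invisible(edf_path)
}

#' @rdname write_eeg
#' @export
write_events <- function(schedule, events_path) {
  readr::write_csv(
    tibble::tibble(onset_s = schedule$onset_s,
                   stimulus_id = schedule$stimulus_id,
                   block_id = schedule$block_id,
                   is_target = as.integer(schedule$is_target)),
    events_path)
  invisible(events_path)
}

#' Read a continuous EEG record and event schedule back from disk
#'
#' Counterpart of [write_eeg()]. Amplitudes are recovered to within the
#' 16-bit quantization step of each channel's physical range; channel labels
#' and event tables round-trip exactly. Events with onsets beyond the
#' recording end raise a validation error.
#'
#' @param edf_path EDF file written by [write_eeg()] (or any EDF with
#'   identical per-channel record layout).
#' @param events_path Companion events CSV, or `NULL` to skip events.
#' @return List with `eeg` ([eeg_record()]) and `schedule` (tibble or `NULL`).
#' @export
read_eeg <- function(edf_path, events_path = paste0(edf_path, ".events.csv")) {
  con <- file(edf_path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(nch) trimws(readChar(con, nch, useBytes = TRUE))
  version <- rd(8)
  rd(80)
  rec_id <- rd(80)
  rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) rlang::abort("corrupt EDF header: signal count.")
  rdv <- function(nch) vapply(seq_len(ns), function(i) rd(nch), character(1))
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (anyNA(c(pmin_, pmax_, dmin, dmax, spr))) {
    rlang::abort("corrupt EDF header: signal fields.")
  }
  if (length(unique(spr)) != 1) {
    rlang::abort("only uniform samples-per-record EDF files are supported.")
  }
  sfreq <- spr[1] / rec_dur

  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    data[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
      matrix(raw, ns, spr[1], byrow = TRUE)
  }
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  data <- sweep(sweep(data, 1, dmin), 1, scale, "*")
  data <- sweep(data, 1, pmin_, "+")

  n_true <- sub("^nsamples=", "", rec_id)
  if (grepl("^nsamples=", rec_id) && !is.na(as.integer(n_true))) {
    data <- data[, seq_len(as.integer(n_true)), drop = FALSE]
  }
  eeg <- eeg_record(data, sfreq, labels)

  schedule <- NULL
  if (!is.null(events_path) && file.exists(events_path)) {
    ev <- readr::read_csv(events_path, show_col_types = FALSE)
    need <- c("onset_s", "stimulus_id", "block_id", "is_target")
    missing <- setdiff(need, names(ev))
    if (length(missing)) {
      rlang::abort(paste0("event file lacks column(s): ",
                          paste(missing, collapse = ", ")))
    }
    if (any(ev$onset_s < 0 | ev$onset_s > eeg_duration(eeg))) {
      rlang::abort("event onset beyond the recording end.")
    }
    schedule <- tibble::tibble(onset_s = ev$onset_s,
                               stimulus_id = as.integer(ev$stimulus_id),
                               block_id = as.integer(ev$block_id),
                               is_target = as.logical(ev$is_target))
  }
  list(eeg = eeg, schedule = schedule)
}

#' Save / load an SWLDA model as JSON
#'
#' Serializes the selected indices, weights, intercept, threshold, training
#' metadata and feature map to a JSON document, so a trained decoder can be
#' replayed across runs.
#'
#' @param model An `swlda_model`.
#' @param path Output (input) JSON path.
#' @return `save_model()` the path, invisibly; `load_model()` an
#'   `swlda_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "swlda_model"))
  doc <- list(
    selected = model$selected, weights = model$weights,
    intercept = model$intercept, threshold = model$threshold,
    p_values = model$p_values, train_meta = model$train_meta,
    p_enter = model$p_enter, p_remove = model$p_remove,
    feature_map = model$feature_map
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  new_swlda_model(
    selected = as.integer(doc$selected),
    weights = as.numeric(doc$weights),
    intercept = as.numeric(doc$intercept),
    threshold = as.numeric(doc$threshold),
    p_values = as.numeric(doc$p_values),
    train_meta = as.list(doc$train_meta),
    feature_map = if (!is.null(doc$feature_map)) tibble::as_tibble(doc$feature_map),
    p_enter = doc$p_enter %||% 0.05,
    p_remove = doc$p_remove %||% 0.10
  )
}

#' Save / load an epoch set
#'
#' Single-file serialization of an `epoch_set` (data array, label table,
#' window, rates) via R's native RDS format.
#'
#' @param epochs An `epoch_set`.
#' @param path File path.
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname save_epochs
#' @export
load_epochs <- function(path) {
  out <- readRDS(path)
  if (!inherits(out, "epoch_set")) rlang::abort("file does not hold an epoch_set.")
  out
}
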