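#' Continuous multi-channel EEG record
#'
#' Lightweight container for a continuous EEG recording: a channels x samples
#' amplitude matrix in microvolts plus its sampling rate and ordered 10-20
#' channel labels.
#'
#' @param data Numeric matrix, channels x samples, amplitudes in uV.
#' @param sfreq Sampling rate in Hz (> 0).
#' @param channel_names Character vector of unique channel labels, one per row
#'   of `data`. Defaults to the 32-channel montage of [montage_32()].
#'
#' @return An object of class `eeg_record`: a list with elements `data`,
#'   `sfreq`, `channel_names`.
#' @export
#' @examples
#' eeg <- eeg_record(matrix(0, 2, 100), 100, c("Cz", "Pz"))
#' n_samples(eeg)
eeg_record <- function(data, sfreq, channel_names = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    rlang::abort("`data` must be a numeric channels x samples matrix.")
  }
  if (!is.numeric(sfreq) || length(sfreq) != 1 || sfreq <= 0) {
    rlang::abort("`sfreq` must be a single positive number (Hz).")
  }
  if (is.null(channel_names)) {
    if (nrow(data) == length(montage_32())) {
      channel_names <- montage_32()
    } else {
      channel_names <- paste0("ch", seq_len(nrow(data)))
    }
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data)) {
    rlang::abort("`channel_names` must have one label per channel (matrix row).")
  }
  if (anyDuplicated(channel_names)) {
    rlang::abort("`channel_names` must be unique.")
  }
  structure(
    list(data = data, sfreq = sfreq, channel_names = channel_names),
    class = "eeg_record"
  )
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "<eeg_record> %d channels x %d samples @ %g Hz (%.2f s)\n",
    nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq
  ))
  cat("channels:", paste(utils::head(x$channel_names, 8), collapse = " "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' @rdname eeg_record
#' @param eeg An `eeg_record`.
#' @export
n_samples <- function(eeg) ncol(eeg$data)

#' @rdname eeg_record
#' @export
n_channels <- function(eeg) nrow(eeg$data)

#' @rdname eeg_record
#' @export
eeg_duration <- function(eeg) ncol(eeg$data) / eeg$sfreq

#' Standard 32-channel 10-20 montage
#'
#' The ordered scalp labels of a 32-electrode 10-20 layout (BioSemi 32
#' ordering, FP1 ... O2), used as the default montage for simulation.
#'
#' @return Character vector of 32 channel labels.
#' @export
montage_32 <- function() {
  c("FP1", "AF3", "F7", "F3", "FC1", "FC5", "FC6", "FC2", "F4", "F8",
    "AF4", "FP2", "Fz", "C3", "CP1", "CP5", "CP6", "CP2", "C4", "Cz",
    "P7", "P3", "Pz", "PO3", "PO4", "P4", "P8", "T7", "T8", "O1",
    "Oz", "O2")
}

# anterior-posterior coordinate (0 = frontal pole, 1 = occipital) and
# laterality (0 = midline, 1 = most lateral) for the 32-channel montage;
# used to build scalp topographies for the synthetic ERP.
channel_geometry <- function(channels = montage_32()) {
  ap <- c(
    FP1 = 0.00, FP2 = 0.00, AF3 = 0.10, AF4 = 0.10,
    F7 = 0.25, F3 = 0.25, Fz = 0.25, F4 = 0.25, F8 = 0.25,
    FC5 = 0.40, FC1 = 0.40, FC2 = 0.40, FC6 = 0.40,
    T7 = 0.55, C3 = 0.55, Cz = 0.55, C4 = 0.55, T8 = 0.55,
    CP5 = 0.70, CP1 = 0.70, CP2 = 0.70, CP6 = 0.70,
    P7 = 0.85, P3 = 0.85, Pz = 0.85, P4 = 0.85, P8 = 0.85,
    PO3 = 0.92, PO4 = 0.92,
    O1 = 1.00, Oz = 1.00, O2 = 1.00
  )
  lat <- c(
    FP1 = 0.40, FP2 = 0.40, AF3 = 0.40, AF4 = 0.40,
    F7 = 1.00, F3 = 0.50, Fz = 0.00, F4 = 0.50, F8 = 1.00,
    FC5 = 0.80, FC1 = 0.30, FC2 = 0.30, FC6 = 0.80,
    T7 = 1.00, C3 = 0.50, Cz = 0.00, C4 = 0.50, T8 = 1.00,
    CP5 = 0.80, CP1 = 0.30, CP2 = 0.30, CP6 = 0.80,
    P7 = 1.00, P3 = 0.50, Pz = 0.00, P4 = 0.50, P8 = 1.00,
    PO3 = 0.30, PO4 = 0.30,
    O1 = 0.40, Oz = 0.00, O2 = 0.40
  )
  missing <- setdiff(channels, names(ap))
  if (length(missing)) {
    rlang::abort(paste0("no scalp geometry for channel(s): ",
                        paste(missing, collapse = ", ")))
  }
  tibble::tibble(channel = channels, ap = unname(ap[channels]),
                 lateral = unname(lat[channels]))
}
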