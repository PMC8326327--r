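#' Default run configuration
#'
#' All numeric constants of the pipeline in one validated list: sampling
#' rates, filter band, epoch window, stimulation timing, stepwise-selection
#' settings, blink-subsampling protocol, per-N response times and
#' permutation-test settings. The configuration serializes losslessly to
#' JSON via [save_config()] / [load_config()].
#'
#' @param ... Named overrides of any default field.
#' @return A validated named list of class `run_config`.
#' @export
#' @examples
#' cfg <- bci_config(noise_scale = 15)
#' cfg$epoch_window_ms
bci_config <- function(...) {
  cfg <- list(
    acq_sfreq = 2048, proc_sfreq = 512, feature_sfreq = 128,
    band_hz = c(0.5, 10), epoch_window_ms = c(200, 600),
    isi_ms = 187.5, n_stimuli = 6,
    blinks_training = 30, blinks_online = 20, n_trials = 6,
    p_enter = 0.05, p_remove = 0.10, max_features = 60, threshold = 0.5,
    subsample_ns = c(1, 5, 10, 15, 20), subsample_repeats = 10,
    response_times_s = default_response_times(),
    n_perm = 10000, alpha = 0.05, fdr_q = 0.05,
    sim_sfreq = 512, noise_scale = 6, gap_s = 2,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    rlang::abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$acq_sfreq >= cfg$proc_sfreq, cfg$proc_sfreq >= cfg$feature_sfreq,
    cfg$band_hz[1] > 0, cfg$band_hz[1] < cfg$band_hz[2],
    cfg$band_hz[2] < cfg$proc_sfreq / 2,
    cfg$epoch_window_ms[1] < cfg$epoch_window_ms[2],
    cfg$isi_ms > 0, cfg$n_stimuli >= 2,
    cfg$blinks_training >= 1, cfg$blinks_online >= 1,
    cfg$p_enter > 0, cfg$p_enter <= cfg$p_remove, cfg$p_remove < 1,
    cfg$max_features >= 0, cfg$subsample_repeats >= 1,
    all(cfg$subsample_ns >= 1), cfg$n_perm >= 0,
    cfg$noise_scale >= 0, cfg$gap_s >= 0,
    all(as.character(cfg$subsample_ns) %in% names(cfg$response_times_s))
  )
  invisible(cfg)
}

#' @rdname bci_config
#' @param cfg A `run_config`.
#' @param path JSON path.
#' @export
save_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  cfg$response_times_s <- as.list(cfg$response_times_s)  # keep the N names
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname bci_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  raw$response_times_s <- unlist(raw$response_times_s)
  do.call(bci_config, raw)
}
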