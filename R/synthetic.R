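#' ERP template for synthetic target responses
#'
#' Describes the P300-like bump added to the EEG at every target flash: a
#' Gaussian waveform scaled per channel by a scalp topography, with optional
#' trial-to-trial jitter in latency and amplitude. The default topography
#' rises from frontal to occipital sites (Fz < Cz < Pz < Oz along the
#' midline), the pattern typical of visual-oddball P300 responses.
#'
#' @param peak_amplitude Peak amplitude in uV (default 5).
#' @param peak_latency Latency of the peak after flash onset in ms (default 350).
#' @param width Temporal spread in ms, the Gaussian standard deviation
#'   (default 80; > 0).
#' @param topography Named numeric vector of per-channel weights in `[0, 1]`,
#'   or `NULL` for the default posterior-dominant gradient over `channels`.
#' @param latency_jitter_sd Per-event latency jitter SD in ms (>= 0, default 20).
#' @param amplitude_jitter_sd Per-event amplitude jitter SD in uV (>= 0, default 1).
#' @param channels Channel labels used to build the default topography.
#'
#' @return An object of class `erp_template`.
#' @export
#' @examples
#' tpl <- erp_template()
#' tpl$topography[c("Fz", "Cz", "Pz", "Oz")]  # increasing
erp_template <- function(peak_amplitude = 5, peak_latency = 350, width = 80,
                         topography = NULL, latency_jitter_sd = 20,
                         amplitude_jitter_sd = 1, channels = montage_32()) {
  if (width <= 0) rlang::abort("`width` must be positive.")
  if (latency_jitter_sd < 0 || amplitude_jitter_sd < 0) {
    rlang::abort("jitter SDs must be non-negative.")
  }
  if (is.null(topography)) {
    geo <- channel_geometry(channels)
    # midline-parietal dominance: posterior gradient with strong lateral
    # falloff, so the common-average reference leaves a clear midline contrast
    w <- (0.12 + 0.88 * geo$ap^1.5) * (1 - 0.7 * geo$lateral)
    topography <- stats::setNames(w / max(w), geo$channel)
  }
  if (is.null(names(topography))) {
    rlang::abort("`topography` must be a named per-channel vector.")
  }
  if (any(topography < 0 | topography > 1)) {
    rlang::abort("`topography` weights must lie in [0, 1].")
  }
  structure(
    list(peak_amplitude = peak_amplitude, peak_latency = peak_latency,
         width = width, topography = topography,
         latency_jitter_sd = latency_jitter_sd,
         amplitude_jitter_sd = amplitude_jitter_sd),
    class = "erp_template"
  )
}

#' @export
print.erp_template <- function(x, ...) {
  cat(sprintf(
    "<erp_template> peak %g uV @ %g ms, width %g ms, jitter (%g ms, %g uV), %d channels\n",
    x$peak_amplitude, x$peak_latency, x$width,
    x$latency_jitter_sd, x$amplitude_jitter_sd, length(x$topography)
  ))
  invisible(x)
}

#' Generate colored background EEG noise
#'
#' Zero-mean 1/f-weighted ("pink") Gaussian noise per channel, synthesized in
#' the frequency domain with random phases, then scaled so each channel has
#' the requested RMS amplitude. This mimics the broadband low-frequency
#' dominance of spontaneous scalp EEG.
#'
#' @param n_channels Number of channels.
#' @param sfreq Sampling rate in Hz.
#' @param duration Recording length in seconds (> 0).
#' @param noise_scale Per-channel RMS amplitude in uV; 0 gives an all-zero
#'   record.
#' @param seed Optional integer seed for reproducibility.
#' @param channel_names Optional channel labels.
#'
#' @return An [eeg_record()] of size `n_channels` x `round(duration * sfreq)`.
#' @export
generate_background <- function(n_channels, sfreq, duration, noise_scale = 6,
                                seed = NULL, channel_names = NULL) {
  if (duration <= 0) rlang::abort("`duration` must be positive.")
  if (noise_scale < 0) rlang::abort("`noise_scale` must be non-negative.")
  n <- round(duration * sfreq)
  if (noise_scale == 0) {
    return(eeg_record(matrix(0, n_channels, n), sfreq, channel_names))
  }
  data <- with_opt_seed(seed, {
    t(vapply(seq_len(n_channels), function(ch) pink_noise(n, sfreq),
             numeric(n)))
  })
  data <- data * noise_scale
  eeg_record(data, sfreq, channel_names)
}

# unit-RMS 1/f noise: spectral amplitude ~ f^(-1/2), flat below f0 = 0.1 Hz
pink_noise <- function(n, sfreq) {
  nf <- n %/% 2
  f <- seq_len(nf) * sfreq / n
  amp <- ifelse(f < 0.1, 0.1^-0.5, f^-0.5)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Re(spec[nf]), imaginary = 0)
    if (nf > 1) full[n:(n - nf + 2)] <- Conj(spec[1:(nf - 1)])
  } else {
    full[n:(n - nf + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x - mean(x)
  x / stats::sd(x)
}

#' Add template ERP responses at every target flash
#'
#' Adds a Gaussian bump, scaled by the template's scalp topography and
#' jittered per event in latency and amplitude, at each `is_target` event of
#' the schedule. Nontarget events are untouched and the input record is not
#' mutated.
#'
#' @param eeg An [eeg_record()].
#' @param schedule A `stim_schedule` whose events fall inside the recording.
#' @param template An [erp_template()]; its topography must cover the
#'   record's channels.
#' @param seed Optional integer seed controlling the per-event jitter.
#'
#' @return A new `eeg_record` with responses added.
#' @export
inject_erp <- function(eeg, schedule, template, seed = NULL) {
  stopifnot(inherits(eeg, "eeg_record"), inherits(template, "erp_template"))
  missing <- setdiff(eeg$channel_names, names(template$topography))
  if (length(missing)) {
    rlang::abort(paste0("template topography lacks channel(s): ",
                        paste(missing, collapse = ", ")))
  }
  targets <- schedule[schedule$is_target, , drop = FALSE]
  n <- n_samples(eeg)
  support_ms <- template$peak_latency + 4 * template$width +
    4 * template$latency_jitter_sd
  if (nrow(targets) > 0 &&
      max(targets$onset_s) + support_ms / 1000 > n / eeg$sfreq) {
    rlang::abort("target event response window exceeds the recording end.")
  }
  if (template$peak_amplitude == 0 || nrow(targets) == 0) return(eeg)

  topo <- template$topography[eeg$channel_names]
  data <- eeg$data
  jit <- with_opt_seed(seed, list(
    lat = stats::rnorm(nrow(targets), 0, template$latency_jitter_sd),
    amp = stats::rnorm(nrow(targets), 0, template$amplitude_jitter_sd)
  ))
  sigma_s <- template$width / 1000
  for (i in seq_len(nrow(targets))) {
    centre <- targets$onset_s[i] + (template$peak_latency + jit$lat[i]) / 1000
    amp <- template$peak_amplitude + jit$amp[i]
    i0 <- max(1L, floor((centre - 4 * sigma_s) * eeg$sfreq) + 1L)
    i1 <- min(n, ceiling((centre + 4 * sigma_s) * eeg$sfreq) + 1L)
    t <- (seq(i0, i1) - 1) / eeg$sfreq
    bump <- amp * exp(-0.5 * ((t - centre) / sigma_s)^2)
    data[, i0:i1] <- data[, i0:i1] + outer(topo, bump)
  }
  eeg_record(data, eeg$sfreq, eeg$channel_names)
}

#' Simulate a full oddball session
#'
#' Generates a ground-truthed session mirroring the two-step destination
#' game's protocol. A *training* session presents 6 sequential selection
#' blocks, one per stimulus as target, each with 30 flashes per stimulus
#' (180 target / 900 nontarget events). An *online* session plays 6 trials of
#' two selections each (continent then place), 20 flashes per stimulus, with
#' targets drawn uniformly at random; ground truth is returned alongside.
#'
#' @param kind `"training"` or `"online"`.
#' @param template An [erp_template()] describing the target response.
#' @param noise_scale Background RMS amplitude in uV (default 6, calibrated
#'   so the decoding chain reproduces the published accuracy-vs-blinks
#'   operating range; see the methods vignette).
#' @param seed Optional integer seed; fixed seed gives a bit-reproducible
#'   session.
#' @param sfreq Simulation sampling rate in Hz (default 512).
#' @param n_channels Number of channels (default 32, the standard montage).
#' @param isi_ms Inter-stimulus interval in ms (default 187.5).
#' @param gap_s Plain-background gap between selection blocks in seconds
#'   (instruction/video time; default 2).
#' @param n_trials Online trials per session (default 6).
#'
#' @return A list of class `bci_session`: `eeg` ([eeg_record()]), `schedule`
#'   (`stim_schedule`), `targets` (tibble with `block_id`, `trial`, `step`,
#'   `target_id`), and `kind`.
#' @export
#' @examples
#' sess <- simulate_session("training", noise_scale = 0, seed = 1)
#' sum(sess$schedule$is_target)   # 180
simulate_session <- function(kind = c("training", "online"),
                             template = erp_template(), noise_scale = 6,
                             seed = NULL, sfreq = 512, n_channels = 32,
                             isi_ms = 187.5, gap_s = 2, n_trials = 6) {
  kind <- rlang::arg_match(kind)
  n_stimuli <- 6L
  channel_names <- if (n_channels == 32) montage_32() else
    paste0("ch", seq_len(n_channels))

  with_opt_seed(seed, {
    if (kind == "training") {
      blinks <- 30L
      targets <- tibble::tibble(
        block_id = seq_len(n_stimuli), trial = seq_len(n_stimuli),
        step = 1L, target_id = seq_len(n_stimuli) - 1L
      )
    } else {
      blinks <- 20L
      targets <- tibble::tibble(
        block_id = seq_len(2L * n_trials),
        trial = rep(seq_len(n_trials), each = 2L),
        step = rep(1:2, n_trials),
        target_id = sample.int(n_stimuli, 2L * n_trials, replace = TRUE) - 1L
      )
    }
    block_dur <- n_stimuli * blinks * isi_ms / 1000
    t0 <- gap_s + (targets$block_id - 1L) * (block_dur + gap_s)
    blocks <- purrr::map(seq_len(nrow(targets)), function(b) {
      build_stimulus_schedule(n_stimuli, blinks, isi_ms,
                              target_id = targets$target_id[b],
                              t0_s = t0[b], block_id = targets$block_id[b])
    })
    schedule <- bind_schedules(blocks)
    duration <- max(t0) + block_dur + gap_s
    eeg <- generate_background(n_channels, sfreq, duration, noise_scale,
                               channel_names = channel_names)
    eeg <- inject_erp(eeg, schedule, template)
    structure(list(eeg = eeg, schedule = schedule, targets = targets,
                   kind = kind),
              class = "bci_session")
  })
}

#' @export
print.bci_session <- function(x, ...) {
  cat(sprintf("<bci_session> %s: %d flash events in %d blocks, %.1f s of EEG\n",
              x$kind, nrow(x$schedule), nrow(x$targets), eeg_duration(x$eeg)))
  invisible(x)
}
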