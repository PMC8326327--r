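# shared, lazily built fixtures; the cache lives for the whole test run so
# expensive simulations are computed once and reused across test files
.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

# default-condition subject (seed 1): training session, its epochs, its model
train_session_default <- function() {
  fx("train_default", simulate_session("training", seed = 1))
}
train_epochs_default <- function() {
  fx("ep_default", preprocess_session(train_session_default()))
}
model_default <- function() fx("model_default", train_swlda(train_epochs_default()))

# high-SNR subject for recovery-style checks
hisnr_train <- function() fx("hisnr_train", simulate_session("training", noise_scale = 1, seed = 3))
hisnr_model <- function() fx("hisnr_model", train_swlda(preprocess_session(hisnr_train())))
hisnr_online <- function() fx("hisnr_online", simulate_session("online", noise_scale = 1, seed = 103))

# one simulated subject under the default study conditions: train on the
# training session, replay two online sessions, keep the pooled epoch labels
simulate_subject <- function(seed, noise_scale = 6, template = erp_template()) {
  train <- simulate_session("training", template = template,
                            noise_scale = noise_scale, seed = seed)
  model <- train_swlda(preprocess_session(train))
  online <- list(
    simulate_session("online", template = template, noise_scale = noise_scale,
                     seed = seed * 1000L + 1L),
    simulate_session("online", template = template, noise_scale = noise_scale,
                     seed = seed * 1000L + 2L)
  )
  pooled <- predict_session_labels(model, online)
  rec <- score_labels(pooled$labels, pooled$targets)
  list(model = model, labels = pooled$labels, targets = pooled$targets,
       record = rec, accuracy = selection_accuracy(rec))
}

# the 10-subject default-template cohort (seeds 1-10)
cohort_default <- function() {
  fx("cohort_default", lapply(1:10, simulate_subject))
}

# the matched cohort with a flat (zero-amplitude) template
cohort_null <- function() {
  fx("cohort_null", {
    tpl <- erp_template(peak_amplitude = 0)
    lapply(1:10, simulate_subject, template = tpl)
  })
}

# a tiny hand-built epoch set: values fully controlled by the caller
make_epochs <- function(data, labels, stimulus_id = NULL, block_id = NULL,
                        window = c(200, 600), sfreq = NULL,
                        channel_names = NULL) {
  d <- dim(data)
  if (is.null(sfreq)) sfreq <- d[3] / ((window[2] - window[1]) / 1000)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(d[2]))
  if (is.null(stimulus_id)) stimulus_id <- rep(0L, d[1])
  if (is.null(block_id)) block_id <- rep(1L, d[1])
  structure(
    list(data = data,
         info = tibble::tibble(epoch = seq_len(d[1]),
                               label = as.integer(labels),
                               stimulus_id = as.integer(stimulus_id),
                               block_id = as.integer(block_id),
                               onset_s = seq_len(d[1])),
         window = window, sfreq = sfreq, channel_names = channel_names),
    class = "epoch_set"
  )
}

# sine-wave record for filter checks
sine_eeg <- function(freqs, sfreq, duration = 4, amplitude = 1) {
  t <- seq(0, duration - 1 / sfreq, by = 1 / sfreq)
  data <- do.call(rbind, lapply(freqs, function(f) amplitude * sin(2 * pi * f * t)))
  eeg_record(data, sfreq, paste0("s", seq_along(freqs)))
}
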