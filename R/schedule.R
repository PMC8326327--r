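#' Build a randomized flash schedule for one selection block
#'
#' One selection is made of `blinks_per_stimulus` rounds; in each round every
#' stimulus flashes exactly once, in a fresh random permutation. Consecutive
#' rounds avoid an immediate repeat of the same stimulus across the round
#' boundary whenever the permutation allows it, so every stimulus occurs
#' exactly `blinks_per_stimulus` times and the attended (target) stimulus
#' behaves like a rare oddball among the six.
#'
#' Onsets are spaced exactly `isi_ms` apart, starting at `t0_s`.
#'
#' @param n_stimuli Number of selectable stimuli (default 6).
#' @param blinks_per_stimulus Flashes per stimulus in this selection
#'   (30 in a training block, 20 in an online selection).
#' @param isi_ms Onset-to-onset inter-stimulus interval in ms (default 187.5).
#' @param target_id Attended stimulus id, 0-based (`0 <= target_id < n_stimuli`).
#' @param seed Optional integer seed; with a fixed seed the schedule is
#'   reproducible. `NULL` uses the current RNG state.
#' @param t0_s Onset of the first flash in seconds (default 0).
#' @param block_id Selection-block identifier stored on every event.
#'
#' @return A `stim_schedule`: a tibble with columns `onset_s`, `stimulus_id`,
#'   `block_id`, `is_target`, plus attributes `isi_ms`, `n_stimuli`,
#'   `blinks_per_stimulus`.
#' @export
#' @examples
#' sch <- build_stimulus_schedule(6, 30, 187.5, target_id = 0, seed = 1)
#' nrow(sch)        # 180 flashes
#' sum(sch$is_target)  # 30
build_stimulus_schedule <- function(n_stimuli = 6, blinks_per_stimulus = 20,
                                    isi_ms = 187.5, target_id = 0,
                                    seed = NULL, t0_s = 0, block_id = 1L) {
  if (n_stimuli < 2) rlang::abort("`n_stimuli` must be at least 2.")
  if (blinks_per_stimulus < 1) rlang::abort("`blinks_per_stimulus` must be >= 1.")
  if (isi_ms <= 0) rlang::abort("`isi_ms` must be positive.")
  if (target_id < 0 || target_id >= n_stimuli) {
    rlang::abort(sprintf("`target_id` must be in [0, %d).", n_stimuli))
  }
  order <- with_opt_seed(seed, draw_flash_order(n_stimuli, blinks_per_stimulus))
  n <- length(order)
  out <- tibble::tibble(
    onset_s = t0_s + (seq_len(n) - 1) * isi_ms / 1000,
    stimulus_id = order,
    block_id = as.integer(block_id),
    is_target = order == as.integer(target_id)
  )
  new_stim_schedule(out, isi_ms = isi_ms, n_stimuli = n_stimuli,
                    blinks_per_stimulus = blinks_per_stimulus)
}

new_stim_schedule <- function(tbl, isi_ms, n_stimuli, blinks_per_stimulus) {
  structure(tbl,
            isi_ms = isi_ms, n_stimuli = as.integer(n_stimuli),
            blinks_per_stimulus = as.integer(blinks_per_stimulus),
            class = c("stim_schedule", class(tibble::tibble())))
}

# one random permutation of 0:(k-1) per round; swap the head of a round away
# from the previous round's tail when another position can take it
draw_flash_order <- function(n_stimuli, rounds) {
  ids <- seq_len(n_stimuli) - 1L
  out <- integer(0)
  last <- NA_integer_
  for (r in seq_len(rounds)) {
    perm <- sample(ids)
    if (!is.na(last) && perm[1] == last && n_stimuli > 1) {
      j <- sample(2:n_stimuli, 1)
      perm[c(1, j)] <- perm[c(j, 1)]
    }
    out <- c(out, perm)
    last <- perm[n_stimuli]
  }
  out
}

# run expr under a temporary seed when one is given, leaving the caller's RNG
# stream untouched; NULL seed draws from the current stream
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Concatenate selection-block schedules into one session schedule
#'
#' @param blocks List of `stim_schedule` objects (already laid out in time).
#' @return A single `stim_schedule` with all events in onset order.
#' @keywords internal
bind_schedules <- function(blocks) {
  tbl <- dplyr::arrange(dplyr::bind_rows(lapply(blocks, tibble::as_tibble)),
                        .data$onset_s)
  first <- blocks[[1]]
  new_stim_schedule(tbl, attr(first, "isi_ms"), attr(first, "n_stimuli"),
                    attr(first, "blinks_per_stimulus"))
}
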