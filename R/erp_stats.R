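#' Condition-averaged ERP with standard error
#'
#' Pointwise mean and standard error (SD / sqrt(n); 0 when n = 1) of the
#' target and nontarget epochs at one channel.
#'
#' @param epochs An `epoch_set` containing both conditions.
#' @param channel Channel name (default `"Cz"`, a standard midline site for
#'   the P300).
#' @return Tibble: `time_ms`, `condition` (`"target"` / `"nontarget"`),
#'   `mean`, `se`, `n`.
#' @export
average_erp <- function(epochs, channel = "Cz") {
  stopifnot(inherits(epochs, "epoch_set"))
  ci <- match(channel, epochs$channel_names)
  if (is.na(ci)) rlang::abort(paste0("unknown channel: ", channel))
  d <- dim(epochs$data)
  time_ms <- epochs$window[1] + (seq_len(d[3]) - 1) * 1000 / epochs$sfreq
  one <- function(rows, cond) {
    x <- matrix(epochs$data[rows, ci, ], nrow = length(rows))
    n <- length(rows)
    se <- if (n > 1) apply(x, 2, stats::sd) / sqrt(n) else rep(0, d[3])
    tibble::tibble(time_ms = time_ms, condition = cond,
                   mean = colMeans(x), se = se, n = n)
  }
  tgt <- which(epochs$info$label == 1)
  non <- which(epochs$info$label == 0)
  if (!length(tgt) || !length(non)) {
    rlang::abort("both target and nontarget epochs are required.")
  }
  dplyr::bind_rows(one(tgt, "target"), one(non, "nontarget"))
}

#' Per-timepoint permutation test with a two-sample t statistic
#'
#' For every timepoint, the observed pooled-variance two-sample t statistic
#' between target and nontarget epochs is compared against its permutation
#' distribution under random condition-label shuffles. Two-sided p-values use
#' the add-one estimator `p = (1 + #(|t*| >= |t|)) / (1 + n_perm)`, which
#' never returns an exact zero. Timepoints with zero pooled variance get
#' p = 1 with a warning.
#'
#' @param target Numeric epochs x timepoints matrix of target epochs.
#' @param nontarget Matrix of nontarget epochs over the same timepoints.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return List with `t_values` and `p_values`, one per timepoint.
#' @export
permutation_ttest <- function(target, nontarget, n_perm = 10000, seed = NULL) {
  target <- as.matrix(target); nontarget <- as.matrix(nontarget)
  if (ncol(target) != ncol(nontarget)) {
    rlang::abort("conditions must share the time axis.")
  }
  n1 <- nrow(target); n2 <- nrow(nontarget)
  if (n1 < 2 || n2 < 2) rlang::abort("need >= 2 epochs per condition.")
  X <- rbind(target, nontarget)
  n <- n1 + n2
  nt <- ncol(X)

  # sufficient statistics: per-timepoint group-1 sums and sums of squares,
  # computed for many permutations at once via 0/1 assignment matrices
  S <- colSums(X)
  SS <- colSums(X^2)
  tstat_from_sums <- function(S1, Q1) {
    m1 <- S1 / n1
    m2 <- (S - S1) / n2
    v1 <- Q1 - S1^2 / n1
    v2 <- (SS - Q1) - (S - S1)^2 / n2
    sp2 <- (v1 + v2) / (n - 2)
    denom <- sqrt(pmax(sp2, 0) * (1 / n1 + 1 / n2))
    t_ <- (m1 - m2) / denom
    t_[denom <= 0] <- NA_real_
    t_
  }
  t_obs <- tstat_from_sums(colSums(X[seq_len(n1), , drop = FALSE]),
                           colSums(X[seq_len(n1), , drop = FALSE]^2))
  degenerate <- is.na(t_obs)
  if (any(degenerate)) {
    rlang::warn(sprintf("%d timepoint(s) with zero pooled variance; p set to 1.",
                        sum(degenerate)))
  }
  X2 <- X^2
  counts <- with_opt_seed(seed, {
    cnt <- numeric(nt)
    done <- 0L
    block <- 500L
    while (done < n_perm) {
      nb <- min(block, n_perm - done)
      P <- matrix(0, n, nb)
      for (b in seq_len(nb)) P[sample.int(n, n1), b] <- 1
      S1 <- crossprod(X, P)    # nt x nb group-1 sums
      Q1 <- crossprod(X2, P)
      for (b in seq_len(nb)) {
        tp <- tstat_from_sums(S1[, b], Q1[, b])
        cnt <- cnt + (!is.na(tp) & !degenerate & abs(tp) >= abs(t_obs) - 1e-12)
      }
      done <- done + nb
    }
    cnt
  })
  p <- (1 + counts) / (1 + n_perm)
  p[degenerate] <- 1
  t_obs[degenerate] <- 0
  list(t_values = t_obs, p_values = p)
}

#' Benjamini-Yekutieli FDR mask
#'
#' Step-up FDR control at level `q` with the harmonic-sum correction factor,
#' valid under arbitrary dependence between tests (the appropriate choice for
#' the strongly autocorrelated timepoints of an ERP). Returns the rejection
#' mask.
#'
#' @param p_values Numeric p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Logical mask, `TRUE` where the hypothesis is rejected.
#' @export
fdr_by <- function(p_values, q = 0.05) {
  if (!length(p_values)) rlang::abort("`p_values` must be non-empty.")
  if (any(p_values <= 0 | p_values > 1 | is.na(p_values))) {
    rlang::abort("`p_values` must lie in (0, 1].")
  }
  stats::p.adjust(p_values, method = "BY") <= q
}

#' Full ERP contrast analysis at one channel
#'
#' Composes [average_erp()], [permutation_ttest()] and [fdr_by()]: the
#' condition-averaged curves with standard error, a per-timepoint two-sided
#' permutation t-test (default 10,000 shuffles), and the Benjamini-Yekutieli
#' significance mask.
#'
#' @param epochs An `epoch_set`.
#' @param channel Channel name (default `"Cz"`).
#' @param n_perm Permutations (default 10000).
#' @param q FDR level (default 0.05).
#' @param seed Optional integer seed.
#' @param parametric If `TRUE`, use the parametric two-sample t-test p-values
#'   instead of the permutation distribution.
#' @return An `erp_stat` tibble: `time_ms`, `mean_target`, `se_target`,
#'   `mean_nontarget`, `se_nontarget`, `t`, `p`, `significant`; attributes
#'   `channel`, `n_perm`, `q`.
#' @export
erp_stat <- function(epochs, channel = "Cz", n_perm = 10000, q = 0.05,
                     seed = NULL, parametric = FALSE) {
  avg <- average_erp(epochs, channel)
  ci <- match(channel, epochs$channel_names)
  tgt <- matrix(epochs$data[epochs$info$label == 1, ci, ],
                nrow = sum(epochs$info$label == 1))
  non <- matrix(epochs$data[epochs$info$label == 0, ci, ],
                nrow = sum(epochs$info$label == 0))
  if (parametric) {
    n1 <- nrow(tgt); n2 <- nrow(non)
    tt <- permutation_ttest(tgt, non, n_perm = 0, seed = seed)
    p <- 2 * stats::pt(-abs(tt$t_values), df = n1 + n2 - 2)
    p[p == 0] <- .Machine$double.xmin
    tt$p_values <- p
  } else {
    tt <- permutation_ttest(tgt, non, n_perm = n_perm, seed = seed)
  }
  wide <- tidyr::pivot_wider(avg, names_from = "condition",
                             values_from = c("mean", "se", "n"))
  out <- tibble::tibble(
    time_ms = wide$time_ms,
    mean_target = wide$mean_target, se_target = wide$se_target,
    mean_nontarget = wide$mean_nontarget, se_nontarget = wide$se_nontarget,
    t = tt$t_values, p = tt$p_values,
    significant = fdr_by(tt$p_values, q)
  )
  attr(out, "channel") <- channel
  attr(out, "n_perm") <- n_perm
  attr(out, "q") <- q
  class(out) <- c("erp_stat", class(out))
  out
}
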