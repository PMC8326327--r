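#' Forward-backward stepwise feature selection by ordinary least squares
#'
#' Classic stepwise regression of the 0/1 epoch label on feature columns: at
#' each forward step the candidate with the smallest partial-F p-value enters
#' if that p-value is below `p_enter`; after every entry, included features
#' whose coefficient p-value has risen above `p_remove` are dropped (worst
#' first). Selection stops when no feature can enter or leave, or when
#' `max_features` are included. Ties on the minimal p-value break to the
#' lowest feature index, so the path is deterministic given the inputs.
#'
#' Candidates that are (numerically) linearly dependent on the included set
#' are skipped at entry with a log note.
#'
#' @param X A `feature_matrix`, or a plain numeric epochs x features matrix.
#' @param y Integer 0/1 labels, one per row of `X`. Taken from `X$info$label`
#'   when `X` is a `feature_matrix` and `y` is missing.
#' @param p_enter Entry threshold on the partial p-value (default 0.05).
#' @param p_remove Removal threshold (default 0.10; must be >= `p_enter`).
#' @param max_features Cap on the number of selected features (default 60).
#' @return Integer vector of selected feature indices, in entry order.
#' @export
stepwise_select <- function(X, y = NULL, p_enter = 0.05, p_remove = 0.10,
                            max_features = 60) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$info$label
    X <- X$values
  }
  y <- as.numeric(y)
  n <- nrow(X)
  m <- ncol(X)
  if (length(y) != n) rlang::abort("`y` must have one label per row of `X`.")
  if (!all(y %in% c(0, 1))) rlang::abort("`y` must be 0/1 labels.")
  if (length(unique(y)) < 2) rlang::abort("`y` must contain both classes.")
  if (p_remove < p_enter) rlang::abort("`p_remove` must be >= `p_enter`.")
  if (max_features <= 0) return(integer(0))

  # Gram-Schmidt state: Q is an orthonormal basis of the included design
  # (intercept first); R holds every candidate column residualized on Q,
  # ry the residualized response.
  Q <- matrix(1 / sqrt(n), n, 1)
  R <- X - matrix(colMeans(X), n, m, byrow = TRUE)
  ry <- y - mean(y)
  col_ss <- colSums(R^2)
  scale0 <- pmax(colSums(scale(X, scale = FALSE)^2), .Machine$double.eps)
  included <- integer(0)
  n_skipped <- 0L

  repeat {
    if (length(included) >= max_features) break
    avail <- setdiff(seq_len(m), included)
    rss_y <- sum(ry^2)
    df <- n - ncol(Q) - 1L
    if (df < 1 || rss_y < 1e-12) break

    ok <- avail[col_ss[avail] > 1e-9 * scale0[avail]]
    n_skipped <- n_skipped + (length(avail) - length(ok))
    if (!length(ok)) break
    num <- colSums(R[, ok, drop = FALSE] * ry)
    pc2 <- num^2 / (col_ss[ok] * rss_y)
    pc2 <- pmin(pc2, 1 - 1e-12)
    tval <- sqrt(pc2 * df / (1 - pc2))
    pval <- 2 * stats::pt(-tval, df)
    best <- which.min(pval)   # which.min takes the first (lowest index) on ties
    if (pval[best] >= p_enter) break
    j <- ok[best]

    qn <- R[, j] / sqrt(col_ss[j])
    Q <- cbind(Q, qn)
    included <- c(included, j)
    proj <- as.numeric(crossprod(R, qn))
    R <- R - outer(qn, proj)
    R[, j] <- 0
    ry <- ry - qn * sum(qn * ry)
    col_ss <- pmax(colSums(R^2), 0)

    # backward pass: drop included features whose coefficient p exceeds p_remove
    removed_any <- FALSE
    repeat {
      pv <- included_pvalues(X, y, included)
      worst <- which.max(pv)
      if (length(included) == 0 || pv[worst] <= p_remove) break
      included <- included[-worst]
      removed_any <- TRUE
    }
    if (removed_any) {
      # rebuild the orthogonal state from the surviving set
      design <- cbind(1, X[, included, drop = FALSE])
      qrd <- qr(design)
      Q <- qr.Q(qrd)
      R <- X - Q %*% crossprod(Q, X)
      R[, included] <- 0
      ry <- y - Q %*% crossprod(Q, y)
      ry <- as.numeric(ry)
      col_ss <- pmax(colSums(R^2), 0)
    }
  }
  if (n_skipped > 0) {
    rlang::inform(sprintf("stepwise_select: skipped %d degenerate candidate evaluation(s).",
                          n_skipped))
  }
  included
}

# two-sided coefficient p-values of the OLS fit on the included columns
included_pvalues <- function(X, y, included) {
  if (!length(included)) return(numeric(0))
  design <- cbind(1, X[, included, drop = FALSE])
  fit <- stats::lm.fit(design, y)
  df <- length(y) - fit$rank
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / max(df, 1)
  XtXinv <- chol2inv(chol(crossprod(design)))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- fit$coefficients / se
  2 * stats::pt(-abs(tval[-1]), df)
}

#' Fit the linear decision rule on selected features
#'
#' Ordinary least squares of the 0/1 label on the selected columns. The
#' linear score approximates the posterior target probability; an epoch is
#' labelled target (1) when the score is at or above `threshold`.
#'
#' @param X A `feature_matrix` or numeric matrix (all columns; selected
#'   columns are indexed by `selected`).
#' @param y 0/1 labels (defaults to `X$info$label` for a `feature_matrix`).
#' @param selected Integer feature indices from [stepwise_select()];
#'   must be non-empty.
#' @param threshold Decision cut on the linear score (default 0.5). Scores
#'   exactly at the threshold are labelled 1.
#' @param feature_map Optional feature-map tibble carried into the model.
#' @return An object of class `swlda_model`.
#' @export
fit_linear <- function(X, y = NULL, selected, threshold = 0.5,
                       feature_map = NULL) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$info$label
    if (is.null(feature_map)) feature_map <- X$feature_map
    X <- X$values
  }
  y <- as.numeric(y)
  if (!length(selected)) rlang::abort("`selected` must be non-empty; see new_swlda_model() for the degenerate case.")
  design <- cbind(1, X[, selected, drop = FALSE])
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) rlang::abort("singular design on the selected features.")
  coefs <- qr.coef(qrd, y)
  pv <- included_pvalues(X, y, selected)
  new_swlda_model(
    selected = as.integer(selected),
    weights = unname(coefs[-1]),
    intercept = unname(coefs[1]),
    threshold = threshold,
    p_values = unname(pv),
    train_meta = list(n_target = sum(y == 1), n_nontarget = sum(y == 0)),
    feature_map = feature_map
  )
}

#' @rdname fit_linear
#' @param selected,weights,intercept,threshold,p_values,train_meta,p_enter,p_remove
#'   Model components; see [fit_linear()] and [train_swlda()].
#' @export
new_swlda_model <- function(selected, weights, intercept, threshold = 0.5,
                            p_values = numeric(length(selected)),
                            train_meta = list(), feature_map = NULL,
                            p_enter = 0.05, p_remove = 0.10) {
  stopifnot(length(weights) == length(selected))
  structure(
    list(selected = as.integer(selected), weights = as.numeric(weights),
         intercept = as.numeric(intercept), threshold = threshold,
         p_values = p_values, train_meta = train_meta,
         feature_map = feature_map, p_enter = p_enter, p_remove = p_remove),
    class = "swlda_model"
  )
}

#' @export
print.swlda_model <- function(x, ...) {
  cat(sprintf(
    "<swlda_model> %d features selected (p_enter %g, p_remove %g), threshold %g\n",
    length(x$selected), x$p_enter, x$p_remove, x$threshold))
  if (length(x$train_meta)) {
    cat(sprintf("trained on %d target / %d nontarget epochs\n",
                x$train_meta$n_target, x$train_meta$n_nontarget))
  }
  invisible(x)
}

#' Linear score and hard 0/1 label for epochs
#'
#' `predict_score()` returns the linear score; `predict_label()` thresholds
#' it into the hard 0 (nontarget) / 1 (target) label used by the blink vote.
#' A model with an empty selection labels every epoch 0, with a warning.
#'
#' @param model An `swlda_model`.
#' @param features One epoch's full feature vector, or an epochs x features
#'   matrix / `feature_matrix`; must cover all selected indices.
#' @return Integer labels (or numeric scores), one per epoch.
#' @export
predict_label <- function(model, features) {
  scores <- predict_score(model, features)
  if (!length(model$selected)) {
    rlang::warn("model has an empty feature selection; labelling all epochs 0.")
    return(rep(0L, length(scores)))
  }
  as.integer(scores >= model$threshold)
}

#' @rdname predict_label
#' @export
predict_score <- function(model, features) {
  stopifnot(inherits(model, "swlda_model"))
  if (inherits(features, "feature_matrix")) features <- features$values
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (!length(model$selected)) return(rep(0, nrow(features)))
  if (ncol(features) < max(model$selected)) {
    rlang::abort("feature vector does not cover all selected indices.")
  }
  as.numeric(features[, model$selected, drop = FALSE] %*% model$weights +
               model$intercept)
}

#' Train an SWLDA model from a training epoch set
#'
#' Composes [to_features()], [stepwise_select()] and [fit_linear()]; this is
#' the full classifier-construction recipe applied to a training session's
#' epochs.
#'
#' @param epochs An `epoch_set` (typically from [preprocess_session()] on a
#'   training session).
#' @param feature_sfreq Feature-grid rate in Hz (default 128).
#' @param p_enter,p_remove Stepwise entry/removal p-value thresholds
#'   (defaults 0.05 / 0.10).
#' @param max_features Selection cap (default 60).
#' @param threshold Decision threshold on the linear score (default 0.5).
#' @return An `swlda_model` carrying the feature map and training counts.
#' @export
train_swlda <- function(epochs, feature_sfreq = 128, p_enter = 0.05,
                        p_remove = 0.10, max_features = 60, threshold = 0.5) {
  fm <- to_features(epochs, feature_sfreq)
  selected <- stepwise_select(fm, p_enter = p_enter, p_remove = p_remove,
                              max_features = max_features)
  if (!length(selected)) {
    return(new_swlda_model(integer(0), numeric(0), 0, threshold,
                           train_meta = list(n_target = sum(fm$info$label == 1),
                                             n_nontarget = sum(fm$info$label == 0)),
                           feature_map = fm$feature_map,
                           p_enter = p_enter, p_remove = p_remove))
  }
  model <- fit_linear(fm, selected = selected, threshold = threshold)
  model$p_enter <- p_enter
  model$p_remove <- p_remove
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SWLDA model into one row per selected feature
#'
#' @param x An `swlda_model`.
#' @param ... Unused.
#' @return Tibble with columns `feature`, `weight`, `p_value`, and (when a
#'   feature map is attached) `channel`, `time_ms`.
#' @exportS3Method generics::tidy
tidy.swlda_model <- function(x, ...) {
  out <- tibble::tibble(feature = x$selected, weight = x$weights,
                        p_value = x$p_values)
  if (!is.null(x$feature_map)) {
    out <- dplyr::left_join(out, x$feature_map, by = "feature") |>
      dplyr::select("feature", "channel", "time_ms", "weight", "p_value")
  }
  out
}

#' One-row model summary
#'
#' @param x An `swlda_model`.
#' @param ... Unused.
#' @return Tibble with `n_selected`, `n_target`, `n_nontarget`, `threshold`,
#'   `p_enter`, `p_remove`.
#' @exportS3Method generics::glance
glance.swlda_model <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    n_target = x$train_meta$n_target %||% NA_integer_,
    n_nontarget = x$train_meta$n_nontarget %||% NA_integer_,
    threshold = x$threshold, p_enter = x$p_enter, p_remove = x$p_remove
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
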