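#' Time-window scheme for HDCA
#'
#' Tiles the epoch into consecutive non-overlapping windows of `window_ms`
#' (default 100 ms, the method's temporal resolution). At 600 Hz over the
#' 0-1000 ms classification window this gives 10 windows of 60 samples.
#' Trailing samples that do not fill a window are ignored.
#'
#' @param n_time samples per epoch.
#' @param fs sampling rate, Hz.
#' @param window_ms window duration, ms.
#' @return An object of class `hdca_windows`: sample index ranges per window.
#' @export
hdca_windows <- function(n_time, fs, window_ms = 100) {
  spw <- round(window_ms * fs / 1000)
  if (spw < 1) stop("window shorter than one sample")
  n_win <- n_time %/% spw
  if (n_win < 1) stop("epoch shorter than one window")
  structure(list(window_ms = window_ms, n_windows = n_win,
                 samples_per_window = spw,
                 start = (seq_len(n_win) - 1L) * spw + 1L,
                 end = seq_len(n_win) * spw),
            class = "hdca_windows")
}

#' Per-window channel-mean features
#'
#' Reduces an epoch array to its within-window per-channel means: the feature
#' representation both levels of HDCA operate on.
#'
#' @param data trials x channels x time array (or an [eeg_epochs]).
#' @param windows an [hdca_windows].
#' @return trials x channels x n_windows array.
#' @export
window_features <- function(data, windows) {
  if (inherits(data, "eeg_epochs")) data <- data$data
  d <- dim(data)
  out <- array(0, c(d[1], d[2], windows$n_windows))
  for (k in seq_len(windows$n_windows)) {
    idx <- windows$start[k]:windows$end[k]
    out[, , k] <- rowMeans(data[, , idx, drop = FALSE], dims = 2)
  }
  out
}

# ---- Fisher linear discriminant with shrinkage -----------------------------

# Ledoit-Wolf shrinkage intensity toward the scaled identity, computed on
# class-centered rows (pooled within-class covariance)
lw_shrinkage <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2)
  if (d2 < .Machine$double.eps) return(list(gamma = 0, S = S, mu = mu))
  b2 <- 0
  for (i in seq_len(n)) b2 <- b2 + sum((tcrossprod(Xc[i, ]) - S)^2)
  b2 <- min(b2 / n^2, d2)
  list(gamma = b2 / d2, S = S, mu = mu)
}

#' Fisher linear discriminant spatial weights
#'
#' Computes the spatial weight vector `w` proportional to
#' `(S_w + lambda I)^{-1} (mu_1 - mu_0)`, where `S_w` is the pooled
#' within-class covariance of the trial features and `lambda` a shrinkage
#' ridge. With `shrinkage = "auto"` the Ledoit-Wolf intensity is estimated
#' from the data (shrinking toward the scaled identity); a numeric value in
#' `[0, 1]` fixes the intensity. The result has unit L2 norm and its sign is
#' fixed so the mean self-class projection is at least the mean non-self
#' projection.
#'
#' @param x trials x channels numeric matrix of features.
#' @param labels 0/1 per trial; both classes with >= 2 trials each.
#' @param shrinkage `"auto"` or a fixed intensity in `[0, 1]`.
#' @return Unit-norm weight vector with attribute `"gamma"` (the intensity
#'   used).
#' @export
fld_weights <- function(x, labels, shrinkage = "auto") {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (min(table(labels)) < 2) stop("need >= 2 trials per class")
  if (all(x == 0)) stop("all-zero feature matrix")
  m1 <- colMeans(x[labels == 1, , drop = FALSE])
  m0 <- colMeans(x[labels == 0, , drop = FALSE])
  Xc <- x
  Xc[labels == 1, ] <- sweep(x[labels == 1, , drop = FALSE], 2, m1)
  Xc[labels == 0, ] <- sweep(x[labels == 0, , drop = FALSE], 2, m0)
  lw <- lw_shrinkage(Xc)
  gamma <- if (identical(shrinkage, "auto")) lw$gamma else as.numeric(shrinkage)
  p <- ncol(x)
  Sw <- (1 - gamma) * lw$S + diag(gamma * lw$mu + 1e-12, p)
  w <- tryCatch(solve(Sw, m1 - m0),
                error = function(e) solve(Sw + diag(1e-8 * max(lw$mu, 1), p),
                                          m1 - m0))
  nrm <- sqrt(sum(w^2))
  if (nrm < .Machine$double.eps) w <- rep(0, p) else w <- w / nrm
  if (sum(w * (m1 - m0)) < 0) w <- -w
  attr(w, "gamma") <- gamma
  w
}

#' Project window features through spatial weights
#'
#' For each trial and window `n`, computes the compressed single-channel value
#' `y_n = sum_i w_{n,i} x_{i,n}` from the window-mean features.
#'
#' @param feats trials x channels x n_windows array ([window_features]).
#' @param spatial_weights n_windows x channels matrix.
#' @return trials x n_windows score matrix.
#' @export
spatial_project <- function(feats, spatial_weights) {
  d <- dim(feats)
  if (ncol(spatial_weights) != d[2])
    stop("spatial weights were trained on ", ncol(spatial_weights),
         " channels; data has ", d[2])
  if (nrow(spatial_weights) != d[3])
    stop("window count mismatch")
  y <- matrix(0, d[1], d[3])
  for (k in seq_len(d[3]))
    y[, k] <- matrix(feats[, , k], d[1], d[2]) %*% spatial_weights[k, ]
  y
}

# ---- ridge-penalised logistic regression (IRLS) ----------------------------

# Light L2 keeps the temporal fit finite on linearly separable folds; the
# penalty applies to the window weights, not the intercept.
ridge_logistic <- function(X, y, lambda = 1e-2, max_iter = 200,
                           tol = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  Xa <- cbind(1, X)
  beta <- numeric(p + 1)
  pen <- diag(c(0, rep(lambda, p)), p + 1)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xa %*% beta)
    mu <- plogis(eta)
    wts <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / wts
    XtW <- t(Xa * wts)
    beta_new <- solve(XtW %*% Xa + 2 * pen, XtW %*% z)
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) break
  }
  list(intercept = beta[1], coef = beta[-1], lambda = lambda, iters = it)
}

#' Fit temporal fusion weights
#'
#' Second level of HDCA: ridge-penalised logistic regression of the class
#' labels on the per-window spatial scores, yielding the temporal weights
#' `v_k` and intercept that make self-face scores exceed non-self scores.
#'
#' @param y trials x n_windows spatial score matrix.
#' @param labels 0/1 per trial.
#' @param lambda L2 penalty on the weights (default 1e-2).
#' @return List with `coef` (v_k), `intercept`, `lambda`.
#' @export
fit_temporal <- function(y, labels, lambda = 1e-2) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  ridge_logistic(y, labels, lambda = lambda)
}

# ---- the HDCA model --------------------------------------------------------

#' Hierarchical discriminant component analysis
#'
#' Fits the two-level HDCA classifier for self- vs non-self-face epochs. The
#' epoch is tiled into `window_ms` windows; in each window a Fisher linear
#' discriminant compresses the channels into one score
#' `y_n = sum_i w_{n,i} x_{i,n}` computed from window-mean features; the window
#' scores are fused by logistic-regression weights `v_k` into one interest
#' score `Y_S = logistic(sum_k v_k y_k + b)` per trial. A trial is accepted as
#' the legitimate user when `Y_S >= threshold`.
#'
#' @param epochs an [eeg_epochs] (typically the 0-1000 ms crop at 600 Hz), or
#'   a trials x channels x time array.
#' @param labels 0/1 per trial; defaults to `epochs$labels`.
#' @param window_ms temporal resolution (default 100 ms).
#' @param channels channel subset to train on: logical/0-1 mask, indices or
#'   names (default: all channels).
#' @param shrinkage FLD shrinkage, `"auto"` (Ledoit-Wolf) or fixed in
#'   `[0, 1]`.
#' @param lambda L2 penalty of the temporal logistic fit.
#' @param threshold decision cutoff on the calibrated probability
#'   (default 0.5), or `"eer"` to place it at the training-set equal-error
#'   point.
#' @param fs sampling rate in Hz; only needed when `epochs` is a plain array.
#' @return An object of class `hdca` with components `spatial_weights`
#'   (n_windows x channels), `temporal_weights`, `intercept`, `threshold`,
#'   `windows`, `channel_mask`, `channel_names`.
#' @seealso [predict.hdca()], [authenticate()], [ga_hdca()]
#' @export
hdca <- function(epochs, labels = NULL, window_ms = 100, channels = NULL,
                 shrinkage = "auto", lambda = 1e-2, threshold = 0.5,
                 fs = NULL) {
  if (inherits(epochs, "eeg_epochs")) {
    if (is.null(labels)) labels <- epochs$labels
    ch_names <- epochs$channel_names
    fs <- epochs$fs
    data <- epochs$data
  } else {
    data <- epochs
    ch_names <- paste0("ch", seq_len(dim(data)[2]))
    if (is.null(labels)) stop("labels required for array input")
    if (is.null(fs)) stop("fs required for array input")
  }
  mask <- resolve_channel_mask(channels, ch_names)
  windows <- hdca_windows(dim(data)[3], fs, window_ms)
  feats <- window_features(data, windows)[, mask, , drop = FALSE]
  fit <- hdca_fit_features(feats, labels, shrinkage, lambda)
  thr <- threshold
  if (identical(threshold, "eer")) {
    y <- spatial_project(feats, fit$spatial_weights)
    score <- plogis(drop(y %*% fit$temporal$coef) + fit$temporal$intercept)
    thr <- eer_threshold(score, labels)
  }
  structure(list(spatial_weights = fit$spatial_weights,
                 temporal_weights = fit$temporal$coef,
                 intercept = fit$temporal$intercept,
                 threshold = thr, windows = windows,
                 channel_mask = mask, channel_names = ch_names,
                 fs = fs, window_ms = window_ms,
                 shrinkage_gamma = fit$gamma, lambda = lambda,
                 n_train = length(labels), call = match.call()),
            class = "hdca")
}

# core fit on already-masked window features
hdca_fit_features <- function(feats, labels, shrinkage = "auto",
                              lambda = 1e-2) {
  d <- dim(feats)
  W <- matrix(0, d[3], d[2])
  gam <- numeric(d[3])
  for (k in seq_len(d[3])) {
    w <- fld_weights(feats[, , k, drop = TRUE], labels, shrinkage)
    W[k, ] <- w
    gam[k] <- attr(w, "gamma")
  }
  y <- spatial_project(feats, W)
  list(spatial_weights = W, temporal = fit_temporal(y, labels, lambda),
       gamma = mean(gam))
}

resolve_channel_mask <- function(channels, ch_names) {
  nc <- length(ch_names)
  if (is.null(channels)) return(rep(TRUE, nc))
  if (is.logical(channels)) {
    stopifnot(length(channels) == nc)
    mask <- channels
  } else if (is.character(channels)) {
    if (!all(channels %in% ch_names))
      stop("unknown channel name(s): ",
           paste(setdiff(channels, ch_names), collapse = ", "))
    mask <- ch_names %in% channels
  } else if (all(channels %in% c(0, 1)) && length(channels) == nc) {
    mask <- channels == 1                      # 0/1 chromosome-style mask
  } else {
    mask <- rep(FALSE, nc)
    mask[as.integer(channels)] <- TRUE
  }
  if (!any(mask)) stop("channel mask selects no channels")
  mask
}

#' Predict interest scores or decisions from a fitted HDCA model
#'
#' @param object an [hdca] model.
#' @param newdata an [eeg_epochs] or trials x channels x time array on the
#'   same montage and window the model was trained on (the model's channel
#'   mask is applied internally).
#' @param type `"score"` for the calibrated probability `Y_S`, `"decision"`
#'   for accept (1) / reject (0) at the model threshold, `"window"` for the
#'   trials x n_windows spatial score matrix `y_n`.
#' @param ... unused.
#' @return Numeric vector (or matrix for `type = "window"`).
#' @export
predict.hdca <- function(object, newdata, type = c("score", "decision",
                                                   "window"), ...) {
  type <- match.arg(type)
  data <- if (inherits(newdata, "eeg_epochs")) newdata$data else newdata
  if (dim(data)[2] != length(object$channel_mask))
    stop("newdata has ", dim(data)[2], " channels; model expects ",
         length(object$channel_mask))
  feats <- window_features(data, object$windows)[, object$channel_mask, ,
                                                 drop = FALSE]
  y <- spatial_project(feats, object$spatial_weights)
  if (type == "window") return(y)
  score <- plogis(drop(y %*% object$temporal_weights) + object$intercept)
  if (type == "score") score else as.integer(score >= object$threshold)
}

#' Authenticate login attempts from consecutive trials
#'
#' One authentication uses `trials_per_login` consecutive trials (default 2,
#' i.e. 6 s of RSVP at 10 images x 300 ms per trial) and accepts when the mean
#' interest score reaches the model threshold — which also serves as the tie
#' rule when individual trial decisions disagree.
#'
#' @param model an [hdca] model.
#' @param epochs an [eeg_epochs] holding the login trials in order.
#' @param trials_per_login trials pooled per attempt.
#' @return data.frame with one row per login: mean score and accept decision.
#' @export
authenticate <- function(model, epochs, trials_per_login = 2) {
  score <- predict(model, epochs, type = "score")
  n_login <- length(score) %/% trials_per_login
  if (n_login < 1) stop("fewer trials than one login attempt")
  grp <- rep(seq_len(n_login), each = trials_per_login)
  ms <- tapply(score[seq_along(grp)], grp, mean)
  data.frame(login = seq_len(n_login), score = as.numeric(ms),
             accept = as.numeric(ms) >= model$threshold)
}

#' Equal-error-rate threshold
#'
#' Score cutoff at which false acceptance and false rejection rates are
#' closest (candidates are midpoints between adjacent sorted scores).
#'
#' @param scores numeric scores, higher = more user-like.
#' @param labels 0/1 truth.
#' @return Threshold value.
#' @export
eer_threshold <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(s[1] - 1e-9, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1e-9)
  gap <- vapply(cand, function(th) {
    far <- mean(scores[labels == 0] >= th)
    frr <- mean(scores[labels == 1] < th)
    abs(far - frr)
  }, 0)
  cand[which.min(gap)]
}

#' @export
print.hdca <- function(x, ...) {
  cat("HDCA classifier: ", x$windows$n_windows, " windows x ",
      sum(x$channel_mask), " channels (", x$window_ms, " ms resolution)\n",
      sep = "")
  cat("  channels: ", paste(x$channel_names[x$channel_mask], collapse = " "),
      "\n  threshold ", signif(x$threshold, 4), ", trained on ", x$n_train,
      " trials\n", sep = "")
  invisible(x)
}

#' @export
summary.hdca <- function(object, ...) {
  v <- object$temporal_weights
  tab <- data.frame(
    window = seq_along(v),
    t_start_ms = (object$windows$start - 1) / object$fs * 1000,
    t_end_ms = object$windows$end / object$fs * 1000,
    v_k = v,
    top_channel = object$channel_names[object$channel_mask][
      apply(abs(object$spatial_weights), 1, which.max)])
  structure(list(windows = tab, model = object), class = "summary.hdca")
}

#' @export
print.summary.hdca <- function(x, ...) {
  print(x$model)
  cat("\nTemporal weights by window:\n")
  print(x$windows, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.hdca <- function(object, ...) {
  list(spatial = object$spatial_weights,
       temporal = object$temporal_weights,
       intercept = object$intercept)
}

#' Plot an HDCA model
#'
#' Left: absolute temporal weights per window. Right: spatial weight magnitude
#' by channel and window.
#'
#' @param x an [hdca] model.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.hdca <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(5, 4, 3, 1))
  on.exit(graphics::par(old))
  mids <- ((x$windows$start + x$windows$end) / 2 - 1) / x$fs * 1000
  graphics::barplot(abs(x$temporal_weights), names.arg = round(mids),
                    xlab = "window centre (ms)", ylab = "|v_k|",
                    main = "temporal weights", ...)
  graphics::image(seq_len(nrow(x$spatial_weights)),
                  seq_len(ncol(x$spatial_weights)),
                  abs(x$spatial_weights), xlab = "window",
                  ylab = "", axes = FALSE, main = "|spatial weights|")
  graphics::axis(1, at = seq_len(nrow(x$spatial_weights)))
  graphics::axis(2, at = seq_len(ncol(x$spatial_weights)),
                 labels = x$channel_names[x$channel_mask], las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

# ---- model serialisation ---------------------------------------------------

#' Save or load an HDCA model as JSON
#'
#' Weights, windowing scheme, channel mask, threshold and training provenance
#' in one human-readable JSON file; numeric arrays are stored at full
#' precision, so the round-trip reproduces identical decisions.
#'
#' @param model an [hdca] model.
#' @param path file path.
#' @return `write_hdca` returns `path` invisibly; `read_hdca` the model.
#' @export
write_hdca <- function(model, path) {
  stopifnot(inherits(model, "hdca"))
  obj <- unclass(model)
  obj$call <- NULL
  obj$ga_config <- NULL
  obj$ga <- if (!is.null(obj$ga))
    list(mask = obj$ga$mask, fitness = obj$ga$fitness)
  obj$windows <- unclass(obj$windows)
  obj$spatial_weights <- as.list(as.data.frame(t(obj$spatial_weights)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hdca
#' @export
read_hdca <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("spatial_weights", "temporal_weights", "intercept",
                "threshold", "windows", "channel_mask", "channel_names")
  missing <- setdiff(required, names(obj))
  if (length(missing))
    stop("not an HDCA model file; missing field(s): ",
         paste(missing, collapse = ", "))
  obj$spatial_weights <- t(as.matrix(as.data.frame(obj$spatial_weights)))
  dimnames(obj$spatial_weights) <- NULL
  obj$windows <- structure(obj$windows, class = "hdca_windows")
  structure(obj, class = "hdca")
}
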