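#' Biometric authentication metrics
#'
#' Builds the standard verification metrics from per-trial decisions and
#' ground truth: accuracy `ACC = 100 * (1 - (FA + FR) / n_test)`, false
#' acceptance rate `FAR = 100 * FA / n_imposter` and false rejection rate
#' `FRR = 100 * FR / n_user`, all in percent. When a class is absent from the
#' test set the corresponding rate is `NA` and flagged in `incomplete`.
#'
#' @param decisions 0/1 accept decisions (1 = accepted as the user).
#' @param labels 0/1 truth (1 = legitimate user trial).
#' @return An object of class `auth_metrics`: confusion counts and rates.
#' @export
auth_metrics <- function(decisions, labels) {
  decisions <- as.integer(decisions); labels <- as.integer(labels)
  if (length(decisions) != length(labels))
    stop("decisions and labels must be aligned")
  if (!length(labels)) stop("empty test set")
  n_user <- sum(labels == 1)
  n_imp <- sum(labels == 0)
  fa <- sum(decisions == 1 & labels == 0)
  fr <- sum(decisions == 0 & labels == 1)
  m <- structure(list(
    n_user_test = n_user, n_imposter_test = n_imp,
    false_accepts = fa, false_rejects = fr,
    acc = 100 * (1 - (fa + fr) / (n_user + n_imp)),
    far = if (n_imp > 0) 100 * fa / n_imp else NA_real_,
    frr = if (n_user > 0) 100 * fr / n_user else NA_real_,
    incomplete = c(if (n_imp == 0) "FAR", if (n_user == 0) "FRR")),
    class = "auth_metrics")
  check_metric_identity(m)
  m
}

# defining identities, asserted on every computation
check_metric_identity <- function(m) {
  stopifnot(isTRUE(all.equal(
    m$acc,
    100 * (1 - (m$false_accepts + m$false_rejects) /
             (m$n_user_test + m$n_imposter_test)))))
  if (m$n_imposter_test > 0)
    stopifnot(isTRUE(all.equal(m$far,
                               100 * m$false_accepts / m$n_imposter_test)))
  if (m$n_user_test > 0)
    stopifnot(isTRUE(all.equal(m$frr,
                               100 * m$false_rejects / m$n_user_test)))
  invisible(m)
}

#' @export
print.auth_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f%%", v)
  cat("Authentication metrics (", x$n_user_test, " user + ",
      x$n_imposter_test, " imposter test trials)\n", sep = "")
  cat("  ACC ", fmt(x$acc), "   FAR ", fmt(x$far), "   FRR ", fmt(x$frr),
      "\n", sep = "")
  if (length(x$incomplete))
    cat("  [", paste(x$incomplete, collapse = ", "),
        " undefined: class missing from test set]\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.auth_metrics <- function(x, ...) {
  data.frame(n_user = x$n_user_test, n_imposter = x$n_imposter_test,
             false_accepts = x$false_accepts, false_rejects = x$false_rejects,
             acc = x$acc, far = x$far, frr = x$frr)
}

#' Stratified cross-validated authentication performance
#'
#' Stratified `folds`-fold cross-validation of the HDCA classifier: fold
#' assignment is seeded and balanced per class, each fold's model is trained
#' on the remaining folds and its held-out decisions are pooled into one
#' confusion table, so every trial is tested exactly once.
#'
#' @param epochs an [eeg_epochs] (classification crop).
#' @param labels 0/1 per trial; defaults to `epochs$labels`.
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param channels optional channel subset (e.g. a GA-selected mask); default
#'   all channels.
#' @param window_ms,shrinkage,lambda,threshold passed to the per-fold
#'   [hdca()] fits.
#' @return An `auth_metrics` with extra fields `fold_assignment` and
#'   `fold_acc`.
#' @export
crossval <- function(epochs, labels = NULL, folds = 5, seed = 1,
                     channels = NULL, window_ms = 100, shrinkage = "auto",
                     lambda = 1e-2, threshold = 0.5) {
  if (is.null(labels)) labels <- epochs$labels
  labels <- as.integer(labels)
  fold_id <- stratified_folds(labels, folds, seed)
  mask <- resolve_channel_mask(channels, epochs$channel_names)
  windows <- hdca_windows(dim(epochs$data)[3], epochs$fs, window_ms)
  feats <- window_features(epochs$data, windows)[, mask, , drop = FALSE]
  decisions <- integer(length(labels))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- hdca_fit_features(feats[!test, , , drop = FALSE], labels[!test],
                             shrinkage, lambda)
    y <- spatial_project(feats[test, , , drop = FALSE], fit$spatial_weights)
    score <- plogis(drop(y %*% fit$temporal$coef) + fit$temporal$intercept)
    decisions[test] <- as.integer(score >= threshold)
    fold_acc[f] <- mean(decisions[test] == labels[test])
  }
  m <- auth_metrics(decisions, labels)
  m$fold_assignment <- fold_id
  m$fold_acc <- 100 * fold_acc
  m
}

#' Compare plain HDCA with GA-optimised HDCA under one CV protocol
#'
#' Reports pooled cross-validated metrics for the all-channel HDCA model and
#' for HDCA restricted to the GA-selected channels, using the same seeded
#' fold assignment for both (and for the GA's internal fitness), so the two
#' numbers differ only in the channel mask. Channel selection is part of
#' model identification and is run once on the full registration set, as in
#' the original protocol.
#'
#' @param epochs an [eeg_epochs].
#' @param labels 0/1 per trial; defaults to `epochs$labels`.
#' @param config a [ga_config]; its `seed`/`cv_folds` drive both evaluations.
#' @param ... passed to [hdca()] / [ga_hdca()].
#' @return List: `hdca` and `ga_hdca` (`auth_metrics`), `model` (the fitted
#'   [ga_hdca()] model), `mask`.
#' @export
compare_methods <- function(epochs, labels = NULL, config = ga_config(),
                            ...) {
  if (is.null(labels)) labels <- epochs$labels
  m_hdca <- crossval(epochs, labels, folds = config$cv_folds,
                     seed = config$seed, ...)
  model <- ga_hdca(epochs, labels, config, ...)
  m_ga <- crossval(epochs, labels, folds = config$cv_folds,
                   seed = config$seed, channels = model$ga$mask, ...)
  list(hdca = m_hdca, ga_hdca = m_ga, model = model, mask = model$ga$mask)
}

#' Permanence (retest) evaluation
#'
#' Applies a previously trained model to a later session's epochs without any
#' refitting, reporting the resulting metrics. With user-only retest data
#' (the usual permanence protocol) only ACC and FRR are defined.
#'
#' @param model an [hdca] (or `ga_hdca`) model trained on session-1 data.
#' @param epochs session-2 [eeg_epochs] on the same montage.
#' @param labels 0/1 per trial; defaults to `epochs$labels`.
#' @return An `auth_metrics`.
#' @export
permanence_test <- function(model, epochs, labels = NULL) {
  if (is.null(labels)) labels <- epochs$labels
  if (length(model$channel_mask) != dim(epochs$data)[2])
    stop("channel count mismatch between model and session-2 data")
  decisions <- predict(model, epochs, type = "decision")
  auth_metrics(decisions, labels)
}

#' Write a per-user metrics table as TSV
#'
#' @param metrics named list of `auth_metrics` (typically one per user).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  rows <- do.call(rbind, lapply(metrics, as.data.frame))
  rows <- cbind(user = names(metrics), rows)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
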