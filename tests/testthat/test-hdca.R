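test_that("FLD weights match the closed form on random instances", {
  set.seed(42)
  for (rep in 1:5) {
    p <- sample(2:6, 1); n <- 60
    x <- matrix(rnorm(2 * n * p), 2 * n, p) %*%
      matrix(rnorm(p * p, sd = 0.5) + diag(p), p, p)
    labels <- rep(c(1L, 0L), each = n)
    shift <- rnorm(p)
    x[labels == 1, ] <- sweep(x[labels == 1, , drop = FALSE], 2, shift, "+")
    w <- fld_weights(x, labels, shrinkage = 0)
    # independent closed form: pooled within-class MLE covariance
    m1 <- colMeans(x[labels == 1, ]); m0 <- colMeans(x[labels == 0, ])
    xc <- rbind(sweep(x[labels == 1, ], 2, m1),
                sweep(x[labels == 0, ], 2, m0))
    w_ref <- solve(crossprod(xc) / nrow(xc), m1 - m0)
    w_ref <- w_ref / sqrt(sum(w_ref^2))
    expect_gt(abs(sum(w * w_ref)), 0.999)
    expect_equal(sqrt(sum(w^2)), 1, tolerance = 1e-12)
    # sign convention: self projects higher
    expect_gte(sum(w * (m1 - m0)), 0)
  }
})

test_that("FLD handles identity covariance, null effect and duplicates", {
  # orthogonal-design classes with exact identity within-class scatter
  base <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)) * sqrt(2)
  x <- rbind(base, sweep(base, 2, c(1, 0), "+"))
  labels <- rep(c(0L, 1L), each = 4)
  w <- fld_weights(x, labels, shrinkage = 0)
  expect_equal(as.numeric(w), c(1, 0), tolerance = 1e-12)
  # equal class means: weights still defined (unit norm)
  set.seed(7)
  x2 <- matrix(rnorm(80), 40, 2)
  expect_equal(sqrt(sum(fld_weights(x2, rep(0:1, 20))^2)), 1,
               tolerance = 1e-9)
  # duplicated channel: singular scatter, shrinkage keeps it solvable
  x3 <- cbind(x2, x2[, 2])
  lab3 <- rep(c(0L, 1L), each = 20)
  x3[lab3 == 1, 1] <- x3[lab3 == 1, 1] + 1
  expect_silent(w3 <- fld_weights(x3, lab3))
  expect_true(all(is.finite(w3)))
  # error contracts
  expect_error(fld_weights(x2, rep(1L, 40)), "both classes")
  expect_error(fld_weights(matrix(0, 10, 2), rep(0:1, 5)), "all-zero")
})

test_that("spatial projection is the windowed linear compression", {
  ep <- gaussian_epochs(n_per_class = 5, n_channels = 3, n_time = 40,
                        fs = 40, effect = 0, seed = 2)
  win <- hdca_windows(40, 40, 250)            # 4 windows of 10 samples
  feats <- window_features(ep, win)
  # single-channel weight 1 returns that channel's window mean
  W <- matrix(0, 4, 3); W[, 2] <- 1
  y <- spatial_project(feats, W)
  expect_equal(y[, 1], apply(ep$data[, 2, 1:10], 1, mean))
  # zero weights give zero; doubling weights doubles y exactly
  expect_true(all(spatial_project(feats, W * 0) == 0))
  expect_equal(spatial_project(feats, 2 * W), 2 * y)
  expect_error(spatial_project(feats, W[, 1:2]), "channels")
})

test_that("temporal fusion separates separable scores and splits duplicates", {
  # perfectly separated one-dimensional scores
  y <- matrix(c(rnorm(20, 3), rnorm(20, -3)), ncol = 1)
  labels <- rep(c(1L, 0L), each = 20)
  fit <- fit_temporal(y, labels)
  pred <- plogis(y %*% fit$coef + fit$intercept) >= 0.5
  expect_equal(as.integer(pred), labels)
  # duplicated column at penalty 2*lambda equals single column at lambda,
  # with the coefficient mass split equally
  set.seed(11)
  y1 <- matrix(rnorm(80, rep(c(1, -1), each = 40)), ncol = 1)
  lab <- rep(c(1L, 0L), each = 40)
  f1 <- fit_temporal(y1, lab, lambda = 5e-3)
  f2 <- fit_temporal(cbind(y1, y1), lab, lambda = 1e-2)
  expect_equal(f2$coef[1], f2$coef[2], tolerance = 1e-8)
  expect_equal(2 * f2$coef[1], f1$coef[1], tolerance = 1e-6)
  p1 <- plogis(y1 %*% f1$coef + f1$intercept)
  p2 <- plogis(cbind(y1, y1) %*% f2$coef + f2$intercept)
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-8)
  expect_error(fit_temporal(y1, rep(1L, 80)), "both classes")
})

test_that("permuted labels give chance-level held-out accuracy", {
  set.seed(31)
  ep <- gaussian_epochs(n_per_class = 100, effect = 1.5, seed = 31)
  perm <- sample(ep$labels)
  m <- crossval(ep, labels = perm, folds = 5, seed = 31)
  half <- 1.96 * sqrt(0.25 / 200) * 100       # 95% binomial band around 50%
  expect_gt(m$acc, 50 - half - 5)
  expect_lt(m$acc, 50 + half + 5)
})

test_that("interest scores follow the logistic fusion contract", {
  ep <- gaussian_epochs(n_per_class = 20, n_channels = 2, n_time = 50,
                        fs = 50, effect = 2, seed = 5)
  model <- hdca(ep, window_ms = 200)
  # hand-crafted weights: v = (1, 0, ...), intercept 0 maps y1 = 0 to 0.5
  m2 <- model
  m2$temporal_weights <- c(1, rep(0, length(model$temporal_weights) - 1))
  m2$intercept <- 0
  y <- predict(m2, ep, type = "window")
  s <- predict(m2, ep, type = "score")
  expect_equal(s, plogis(y[, 1]))
  expect_equal(s[abs(y[, 1]) < 1e-12], rep(0.5, sum(abs(y[, 1]) < 1e-12)))
  # all-zero weights: constant logistic(intercept)
  m3 <- model; m3$temporal_weights[] <- 0; m3$intercept <- 0.7
  expect_true(all(abs(predict(m3, ep, type = "score") - plogis(0.7)) < 1e-12))
  # monotonicity in a positively weighted window
  k <- which(model$temporal_weights > 0)[1]
  ep2 <- ep
  idx <- ((k - 1) * 10 + 1):(k * 10)
  wch <- which(model$spatial_weights[k, ] > 0)[1]
  ep2$data[, wch, idx] <- ep2$data[, wch, idx] + 5
  expect_true(all(predict(model, ep2, type = "score") >=
                  predict(model, ep, type = "score") - 1e-12))
})

test_that("training is deterministic and refuses degenerate input", {
  ep <- gaussian_epochs(n_per_class = 15, seed = 3)
  m1 <- hdca(ep); m2 <- hdca(ep)
  expect_identical(m1$spatial_weights, m2$spatial_weights)
  expect_identical(m1$temporal_weights, m2$temporal_weights)
  expect_error(hdca(ep, labels = rep(1L, 30)), "both classes")
})

test_that("one full-epoch window reduces HDCA to plain FLD ranking", {
  ep <- gaussian_epochs(n_per_class = 25, n_channels = 5, n_time = 60,
                        fs = 60, effect = 0.8, seed = 13)
  test_ep <- gaussian_epochs(n_per_class = 25, n_channels = 5, n_time = 60,
                             fs = 60, effect = 0.8, seed = 14)
  model <- hdca(ep, window_ms = 1000)          # single window spans the epoch
  expect_equal(model$windows$n_windows, 1)
  s_hdca <- predict(model, test_ep, type = "score")
  # direct FLD on whole-epoch channel means
  xm <- apply(ep$data, c(1, 2), mean)
  w <- fld_weights(xm, ep$labels)
  s_fld <- apply(test_ep$data, c(1, 2), mean) %*% w
  expect_equal(order(s_hdca), order(s_fld))
})

test_that("decisions are invariant to positive rescaling of the input", {
  ep <- gaussian_epochs(n_per_class = 40, effect = 1.2, seed = 17)
  test_ep <- gaussian_epochs(n_per_class = 40, effect = 1.2, seed = 18)
  d1 <- predict(hdca(ep), test_ep, type = "decision")
  ep5 <- ep; ep5$data <- ep$data * 5
  t5 <- test_ep; t5$data <- test_ep$data * 5
  d5 <- predict(hdca(ep5), t5, type = "decision")
  expect_equal(d1, d5)
})

test_that("discriminative structure is recovered in weights", {
  # effect confined to windows 4-5 (300-500 ms) on channels P3, Pz, P4
  pool <- make_pool(n_blocks = 6, seed = 8, noise_rms = 3,
                    common_mode_rms = 0,
                    templates = list(effect_template(default_montage())))
  model <- hdca(pool)
  v <- abs(model$temporal_weights)
  expect_true(which.max(v) %in% 4:5)
  ch <- match(c("P3", "Pz", "P4"), model$channel_names)
  w45 <- model$spatial_weights[4:5, ]
  mass <- sum(w45[, ch]^2) / sum(w45^2)
  expect_gte(mass, 0.5)
})

test_that("classification and login decisions follow the threshold rule", {
  ep <- gaussian_epochs(n_per_class = 10, seed = 21)
  model <- hdca(ep)
  model$threshold <- 0.5
  # forced scores via hand-set weights
  expect_equal(as.integer(c(0.9, 0.2) >= model$threshold), c(1L, 0L))
  # threshold 0 accepts everything
  m0 <- model; m0$threshold <- 0
  expect_true(all(predict(m0, ep, type = "decision") == 1))
  # two-trial login decided by mean score vs threshold
  login <- authenticate(model, ep, trials_per_login = 2)
  s <- predict(model, ep, type = "score")
  expect_equal(login$score, as.numeric(tapply(s, rep(1:10, each = 2), mean)))
  expect_equal(login$accept, login$score >= model$threshold)
})

test_that("model JSON round-trip reproduces identical decisions", {
  ep <- gaussian_epochs(n_per_class = 15, seed = 9)
  model <- hdca(ep)
  path <- tempfile(fileext = ".json")
  write_hdca(model, path)
  back <- read_hdca(path)
  expect_equal(back$spatial_weights, model$spatial_weights)
  expect_equal(back$temporal_weights, model$temporal_weights)
  expect_identical(predict(back, ep, type = "decision"),
                   predict(model, ep, type = "decision"))
})

test_that("eer threshold balances the two error rates", {
  set.seed(25)
  scores <- c(rnorm(200, 0.7, 0.1), rnorm(200, 0.3, 0.1))
  labels <- rep(c(1L, 0L), each = 200)
  th <- eer_threshold(scores, labels)
  far <- mean(scores[labels == 0] >= th)
  frr <- mean(scores[labels == 1] < th)
  expect_lt(abs(far - frr), 0.05)
})
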