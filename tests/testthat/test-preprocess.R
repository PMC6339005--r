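test_that("common average reference zeroes channel means and common signal", {
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(400), 4, 100), fs = 100,
                       channel_names = paste0("c", 1:4))
  out <- rereference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  # identical channels are annihilated
  same <- eeg_recording(matrix(rep(rnorm(100), each = 4), 4, 100), fs = 100,
                        channel_names = paste0("c", 1:4))
  expect_lt(max(abs(rereference(same)$data)), 1e-12)
  # identity matrix leaves data untouched; wrong shape errors
  expect_equal(rereference(rec, diag(4))$data, rec$data)
  expect_error(rereference(rec, diag(3)), "matrix")
})

test_that("low-pass design meets the passband/stopband contract", {
  des <- design_lowpass(2400)
  f_pass <- seq(0.5, 40, by = 0.5)
  f_stop <- seq(49, 100, by = 1)
  h_pass <- 20 * log10(Mod(lowpass_response(des, f_pass)))
  h_stop <- 20 * log10(Mod(lowpass_response(des, f_stop)))
  expect_true(all(h_pass >= -1 & h_pass <= 0.01))   # <= 1 dB ripple
  expect_true(all(h_stop <= -40))                   # >= 40 dB attenuation
  expect_error(design_lowpass(80, 40, 49), "fs/2")
  expect_error(design_lowpass(2400, 49, 40), "passband")
})

test_that("zero-phase filtering passes 10 Hz, kills 100 Hz, keeps DC", {
  fs <- 2400
  t <- seq(0, 4, by = 1 / fs)
  mid <- seq(round(1.5 * fs), round(2.5 * fs))    # steady-state section
  mk <- function(x) eeg_recording(matrix(x, 1), fs, "ch1")
  y10 <- lowpass(mk(sin(2 * pi * 10 * t)))$data[1, mid]
  expect_gt(max(abs(y10)), 10^(-1 / 20))            # within 1 dB of unit
  expect_lt(max(abs(y10)), 1.01)
  y100 <- lowpass(mk(sin(2 * pi * 100 * t)))$data[1, mid]
  expect_lt(max(abs(y100)), 1e-4)                   # two-pass >= 80 dB
  # two-pass response itself is far below -80 dB at 100 Hz
  des <- design_lowpass(fs)
  expect_lt(40 * log10(Mod(lowpass_response(des, 100))), -80)
  ydc <- lowpass(mk(rep(5, length(t))))$data[1, ]
  expect_lt(max(abs(ydc - 5)) / 5, 1e-6)
})

test_that("block-average downsampling averages, maps events, drops remainder", {
  rec <- eeg_recording(matrix(1:8, 1), fs = 8, channel_names = "c",
                       events = data.frame(sample = c(1L, 6L),
                                           label = c("self", "nonself")))
  out <- downsample_avg(rec, 4)
  expect_equal(out$data[1, ], c(2.5, 6.5))
  expect_equal(out$fs, 2)
  expect_equal(out$events$sample, c(1L, 2L))
  # factor 1 is the identity
  expect_equal(downsample_avg(rec, 1)$data, rec$data)
  # constants are preserved; trailing remainder dropped
  rec2 <- eeg_recording(matrix(7, 2, 10), fs = 10, paste0("c", 1:2))
  out2 <- downsample_avg(rec2, 3)
  expect_equal(dim(out2$data), c(2L, 3L))
  expect_true(all(out2$data == 7))
  expect_error(downsample_avg(rec, 100), "factor")
})

test_that("epoch extraction matches the documented sample arithmetic", {
  n <- 600 * 10
  rec <- eeg_recording(matrix(rnorm(2 * n), 2, n), fs = 600,
                       channel_names = c("a", "b"),
                       events = data.frame(sample = c(1200L, 3000L),
                                           label = c("self", "nonself")))
  ep_full <- extract_epochs(rec, tmin = -200, tmax = 1000)
  expect_equal(dim(ep_full$data)[3], 720)
  ep_cls <- extract_epochs(rec, tmin = 0, tmax = 1000)
  expect_equal(dim(ep_cls$data)[3], 600)
  expect_equal(ep_cls$labels, c(1L, 0L))
  # epoch content is the raw slice
  expect_equal(ep_cls$data[1, , ], rec$data[, 1200:1799])
  # events too close to the edge are rejected with a warning
  rec$events <- data.frame(sample = c(50L, 3000L),
                           label = c("self", "nonself"))
  expect_warning(ep <- extract_epochs(rec, tmin = -200, tmax = 1000),
                 "dropped")
  expect_equal(dim(ep$data)[1], 1)
})

test_that("baseline correction zeroes the window mean and is idempotent", {
  set.seed(8)
  ep <- eeg_epochs(array(rnorm(5 * 3 * 720) + 4, c(5, 3, 720)),
                   labels = rep(0:1, length.out = 5), fs = 600, t0 = -200,
                   channel_names = paste0("c", 1:3))
  out <- baseline_correct(ep)
  tt <- -200 + (0:719) / 600 * 1000
  idx <- which(tt >= -200 & tt < 0)
  base <- apply(out$data[, , idx], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-9)
  expect_equal(baseline_correct(out)$data, out$data)
  # constant epochs become exactly zero
  epc <- eeg_epochs(array(5, c(2, 2, 720)), c(0L, 1L), 600, -200,
                    c("a", "b"))
  expect_true(all(baseline_correct(epc)$data == 0))
})

test_that("adjacent-pair averaging halves trials within class", {
  set.seed(3)
  n <- 200
  labels <- rep(c(1L, 0L), 100)
  ep <- eeg_epochs(array(rnorm(n * 2 * 30), c(n, 2, 30)), labels, 60, 0,
                   c("a", "b"))
  out <- average_adjacent_pairs(ep)
  expect_equal(dim(out$data)[1], 100)
  expect_equal(sum(out$labels == 1), 50)
  # first output trial is the mean of the first two same-class trials
  i12 <- which(labels == 1)[1:2]
  expect_equal(out$data[1, , ], (ep$data[i12[1], , ] + ep$data[i12[2], , ]) / 2)
  # identical pair reproduces the input; opposite pair cancels
  ep2 <- eeg_epochs(array(rep(c(1, -1), each = 2 * 12), c(4, 2, 12)) * 0 +
                      c(3, 3, 2, -2), rep(1L, 4), 60, 0, c("a", "b"))
  out2 <- average_adjacent_pairs(ep2)
  expect_true(all(out2$data[1, , ] == 3))
  expect_true(all(out2$data[2, , ] == 0))
  # odd trailing trial dropped
  ep3 <- eeg_epochs(array(1, c(5, 1, 4)), rep(1L, 5), 10, 0, "a")
  expect_equal(dim(average_adjacent_pairs(ep3)$data)[1], 2)
  expect_error(average_adjacent_pairs(
    eeg_epochs(array(1, c(1, 1, 4)), 1L, 10, 0, "a")), "2 trials")
})

test_that("pair averaging halves the variance of white noise", {
  set.seed(17)
  ep <- eeg_epochs(array(rnorm(400 * 1 * 50), c(400, 1, 50)),
                   labels = rep(1L, 400), fs = 50, t0 = 0, "a")
  v_in <- stats::var(as.vector(ep$data))
  v_out <- stats::var(as.vector(average_adjacent_pairs(ep)$data))
  expect_equal(v_out / v_in, 0.5, tolerance = 0.1)
})

test_that("downsampling commutes with epoching for aligned windows", {
  set.seed(23)
  fs <- 240; factor <- 4
  rec <- eeg_recording(matrix(rnorm(2 * fs * 10), 2, fs * 10), fs,
                       c("a", "b"),
                       events = data.frame(sample = c(241L, 1441L),
                                           label = c("self", "self")))
  a <- extract_epochs(downsample_avg(rec, factor), tmin = 0, tmax = 1000)
  b <- extract_epochs(rec, tmin = 0, tmax = 1000)
  # downsample the epoched data manually
  bd <- array(0, dim(a$data))
  for (j in seq_len(dim(a$data)[3]))
    bd[, , j] <- apply(b$data[, , ((j - 1) * factor + 1):(j * factor),
                              drop = FALSE], c(1, 2), mean)
  expect_equal(a$data, bd, tolerance = 1e-12)
})

test_that("preprocess() is the fixed-order composition of its stages", {
  cfg <- tiny_config(n_blocks = 1, fs = 1200, seed = 19)
  rec <- simulate_recording(cfg)
  des <- design_lowpass(1200)
  got <- preprocess(rec, ds_factor = 2, design = des)
  manual <- rereference(rec)
  manual <- lowpass(manual, design = des)
  manual <- downsample_avg(manual, 2)
  manual <- extract_epochs(manual, -200, 1000)
  manual <- baseline_correct(manual, c(-200, 0))
  manual <- crop_epochs(manual, 0, 1000)
  manual <- average_adjacent_pairs(manual)
  expect_equal(got$data, manual$data)
  expect_equal(got$labels, manual$labels)
  expect_equal(got$meta$pipeline$ds_factor, 2)
})

test_that("peak-to-peak rejection drops only above-threshold trials", {
  ep <- eeg_epochs(array(c(rep(1, 12), seq(-60, 61, length.out = 12)),
                         c(2, 1, 12))[c(1, 2), , , drop = FALSE],
                   c(1L, 1L), 12, 0, "a")
  ep$data[1, 1, ] <- 1
  ep$data[2, 1, ] <- seq(-60, 60, length.out = 12)
  out <- reject_peak_to_peak(ep, 100)
  expect_equal(dim(out$data)[1], 1)
  expect_equal(out$meta$p2p_rejected, 1)
})
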