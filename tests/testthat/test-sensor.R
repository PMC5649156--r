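# GFP, windowed contrasts, Morlet time-frequency, spectral permutation.

test_that("GFP equals the brute-force spatial SD and honors its invariances", {
  set.seed(2)
  sf <- 200
  avg <- matrix(rnorm(20 * 400), 20)
  g <- global_field_power(avg, sf, band = NULL)
  brute <- vapply(seq_len(400), function(i) {
    v <- avg[, i]
    sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  }, 0)
  expect_equal(g$values, brute, tolerance = 1e-12)
  expect_true(all(g$values >= 0))

  # channel-common time series leave GFP unchanged
  common <- sin(seq_len(400) / 10)
  avg2 <- avg + rep(common, each = 20)
  expect_lt(max(abs(global_field_power(avg2, sf, band = NULL)$values - g$values)), 1e-12)

  # identical channels: GFP is identically zero
  flat <- matrix(rep(rnorm(400), each = 5), 5, byrow = FALSE)
  expect_equal(max(global_field_power(flat, sf, band = NULL)$values), 0)

  # common drift plus scaled fixed pattern: closed form |s(t)| * SD(pattern)
  pat <- rnorm(20); scale_t <- cos(seq_len(400) / 40)
  avg3 <- rep(common, each = 20) + outer(pat, scale_t)
  expect_equal(global_field_power(avg3, sf, band = NULL)$values,
               abs(scale_t) * sd(pat), tolerance = 1e-12)
  expect_error(global_field_power(avg[1, , drop = FALSE], sf), "2 channels")
})

test_that("windowed GFP contrast uses its default windows and degenerates to t = 0", {
  times <- seq(-1.5, 1.5, by = 0.01)
  set.seed(4)
  g <- matrix(abs(rnorm(8 * length(times), 5)), 8)
  res <- gfp_window_contrast(list(blink = g, control = g), times)
  expect_identical(res$condition, c("blink", "control"))
  # identical windows values for both conditions of the same matrix
  expect_equal(res$t[1], res$t[2])
  g2 <- g; ip <- times >= 0.15 & times <= 0.35
  g2[, ip] <- g2[, ip] + 3
  res2 <- gfp_window_contrast(list(blink = g2), times)
  expect_gt(res2$t[1], 0)
  expect_lt(res2$p[1], 0.01)
  # pre == post exactly: zero t
  gc <- matrix(5, 4, length(times))
  res3 <- gfp_window_contrast(list(x = gc), times)
  expect_equal(res3$t[1], 0)
  expect_equal(res3$p[1], 1)
})

test_that("Morlet log power localizes a sinusoid and scales as log of squared amplitude", {
  sf <- 120
  tt <- seq(0, 5, by = 1 / sf)
  ep <- array(0, c(2, 2, length(tt)))
  ep[1, 1, ] <- sin(2 * pi * 3 * tt); ep[1, 2, ] <- sin(2 * pi * 3 * tt + 1)
  ep[2, , ] <- ep[1, , ]
  tf <- suppressWarnings(morlet_tf(ep, sfreq = sf, freqs = seq(1.5, 6, 0.25)))
  mid <- 150:450
  prof <- apply(tf$average[, , mid], 2, mean)
  expect_equal(tf$freqs[which.max(prof)], 3)
  expect_equal(tf$n_cycles, 6)

  tf2 <- suppressWarnings(morlet_tf(2 * ep, sfreq = sf, freqs = seq(1.5, 6, 0.25)))
  expect_equal(tf2$average - tf$average,
               array(log10(4), dim(tf$average)), tolerance = 1e-12)
})

test_that("frequencies without wavelet support inside the epoch are dropped", {
  ep <- array(rnorm(2 * 2 * 361), c(2, 2, 361))     # 3 s at 120 Hz
  expect_warning(tf <- morlet_tf(ep, sfreq = 120), "dropping frequencies")
  expect_true(all(tf$freqs >= 2))                   # 6 cycles / 3 s
  expect_error(suppressWarnings(morlet_tf(ep, sfreq = 120, freqs = c(0.5, 1))),
               "every requested frequency")
})

test_that("baseline correction zeroes the baseline and is idempotent up to the window mean", {
  sf <- 120
  times <- seq(-1.5, 1.5, by = 1 / sf)
  set.seed(8)
  ep <- array(0, c(10, 3, length(times)))
  for (tr in 1:10) ep[tr, , ] <- bromeg:::.pink_rows(3, length(times), sf)
  tf <- suppressWarnings(morlet_tf(ep, sfreq = sf, times = times, keep_trials = TRUE))
  tfb <- baseline_correct(tf, c(-1.5, -0.5))
  idx <- which(times >= -1.5 & times <= -0.5)
  base_means <- apply(tfb$power[, , , idx], 1:3, mean)
  expect_lt(max(abs(base_means)), 1e-12)
  # stationary input: corrected mean over any other window is near zero
  post <- apply(tfb$average[, , times >= 0 & times <= 1], 1:2, mean)
  expect_lt(max(abs(post)), 3 * sd(tfb$average))
  tfb2 <- baseline_correct(tfb, c(-1.5, -0.5))
  expect_equal(tfb2$power, tfb$power, tolerance = 1e-12)
})

test_that("spectral permutation is calibrated on exchangeable data and detects shifts", {
  # degenerate null: identical pre/post
  x <- rnorm(8)
  res <- spectral_permutation(x, x, n_perm = 400, seed = 1)
  expect_gt(res$p, 1 - 2 / sqrt(400))
  # a consistent positive shift is detected
  set.seed(2)
  pre <- rnorm(10); post <- pre + 1 + rnorm(10, sd = 0.2)
  expect_lt(spectral_permutation(pre, post, n_perm = 500, seed = 2)$p, 0.01)
  # p never exactly zero
  expect_gte(spectral_permutation(pre, post, n_perm = 500, seed = 3)$p, 1 / 501)
  expect_error(spectral_permutation(1:3, 2:4), "4 subjects")
  # alias kept for the bootstrap-styled name
  expect_identical(spectral_bootstrap, spectral_permutation)
})

test_that("spectral sign-flip test has nominal type-I error under the null", {
  set.seed(31)
  n_rep <- 400
  rej <- vapply(seq_len(n_rep), function(i) {
    pre <- rnorm(10); post <- rnorm(10)
    spectral_permutation(pre, post, n_perm = 300, seed = 1000 + i)$p < 0.05
  }, TRUE)
  ci <- 2.576 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), ci + 1e-9)
})
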