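# Template-matching detection, morphology features, normalized averaging,
# split-half reliability.

test_that("an embedded template is found exactly once at its peak", {
  sf <- 250
  tmpl <- blink_waveform(blink_params(), sf)
  x <- numeric(5000)
  i0 <- 2000
  x[i0 + seq_along(tmpl$trace) - tmpl$t0_index] <- tmpl$trace
  ev <- detect_blinks(x, sf)
  expect_length(ev$t0_samples, 1)
  expect_equal(ev$t0_samples, i0)
  expect_gt(ev$scores, 0.99)
})

test_that("blinks closer than the temporal threshold are both removed", {
  sf <- 250
  tmpl <- blink_waveform(blink_params(), sf)
  x <- numeric(10000)
  for (i0 in c(3000, 3000 + 2 * sf)) {      # 2 s apart
    idx <- i0 + seq_along(tmpl$trace) - tmpl$t0_index
    x[idx] <- x[idx] + tmpl$trace
  }
  ev <- detect_blinks(x, sf, min_gap = 3)
  expect_length(ev$t0_samples, 0)
  expect_equal(ev$n_excluded_close, 2L)
  # with a 1.5 s threshold both survive
  expect_length(detect_blinks(x, sf, min_gap = 1.5)$t0_samples, 2)
})

test_that("detection recovers planted blinks on synthetic vEOG", {
  r <- quick_recording()
  sf <- r$recording$sfreq
  veog <- bandpass(veog_data(r$recording), 0.1, 30, sf)
  ev <- detect_blinks(veog, sf)
  det <- (ev$t0_samples - 1) / sf
  planted <- r$truth$blink_times
  recall <- mean(vapply(planted, function(p) any(abs(det - p) <= 0.05), TRUE))
  precision <- mean(vapply(det, function(d) any(abs(planted - d) <= 0.05), TRUE))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("detection is translation-equivariant and scale-invariant", {
  r <- quick_recording()
  sf <- r$recording$sfreq
  veog <- bandpass(veog_data(r$recording), 0.1, 30, sf)[1:6000]
  ev <- detect_blinks(veog, sf)
  k <- 100
  ev_shift <- detect_blinks(c(numeric(k), veog), sf)
  expect_identical(ev_shift$t0_samples, ev$t0_samples + as.integer(k))
  tmpl <- blink_waveform(blink_params(), sf)
  ev_scaled <- detect_blinks(3.7 * veog, sf, template = 3.7 * tmpl$trace)
  expect_identical(ev_scaled$t0_samples, ev$t0_samples)
})

test_that("degenerate detector inputs raise informative errors", {
  expect_error(detect_blinks(numeric(0), 250), "empty")
  expect_error(detect_blinks(rnorm(100), 250, template = rep(1, 10)), "flat template")
  expect_error(detect_blinks(rnorm(10), 250, template = rnorm(50)), "shorter")
})

test_that("morphology features follow a closed-form two-lobe construction", {
  sf <- 1000
  t <- seq(0, 2, by = 1 / sf)
  y <- numeric(length(t))
  y[t < 0.3] <- 40 * sin(pi * t[t < 0.3] / 0.3)       # base width 0.3, peak 40
  peak_t <- t[which.max(y)]
  reg <- t >= peak_t + 0.4 - 0.15 & t <= peak_t + 0.4 + 0.15
  y[reg] <- -10 * sin(pi * (t[reg] - (peak_t + 0.4 - 0.15)) / 0.3)
  m <- extract_morphology(y, sf)
  expect_equal(m$M1, 40, tolerance = 0.01)
  expect_equal(m$M2, 0.3, tolerance = 1 / sf + 1e-9)
  expect_equal(m$M3, -10, tolerance = 0.01)
  expect_equal(m$M4, 0.4, tolerance = 1 / sf + 1e-9)

  # homogeneity: scaling the trace scales amplitudes, not latencies
  m2 <- extract_morphology(2 * y, sf)
  expect_equal(m2$M1, 2 * m$M1)
  expect_equal(m2$M3, 2 * m$M3)
  expect_equal(m2$M2, m$M2)
  expect_equal(m2$M4, m$M4)
})

test_that("missing zero crossings are flagged undefined", {
  m <- extract_morphology(dnorm(seq(-3, 3, 0.01)) + 1, 100)
  expect_true("M2" %in% attr(m, "undefined"))
})

test_that("normalized averaging removes per-subject amplitude scale", {
  shape <- sin(seq(0, pi, length.out = 50))
  subj <- lapply(c(1, 10, 0.3), function(a) {
    matrix(rep(a * shape, 4), nrow = 4, byrow = TRUE)
  })
  na <- normalized_average(subj)
  expect_equal(max(na$grand_average), 1)
  for (i in 1:3) expect_equal(na$subject_averages[i, ], shape / max(shape),
                              tolerance = 1e-12)
  # randomly scaled copies of one shape leave the grand average unchanged
  set.seed(1)
  subj2 <- lapply(runif(5, 0.1, 5), function(a)
    matrix(rep(a * shape, 3), nrow = 3, byrow = TRUE))
  expect_equal(normalized_average(subj2)$grand_average, shape / max(shape),
               tolerance = 1e-12)
  expect_error(normalized_average(list(matrix(0, 2, 10))), "zero-amplitude")
})

test_that("split-half reliability matches a brute-force duplicate and detects order structure", {
  set.seed(10)
  vals <- cbind(a = runif(36), b = runif(36))
  res <- split_half_reliability(vals, n_reps = 200, seed = 77)

  # duplicate implementation with the same RNG protocol
  oracle <- local({
    n <- 36; h <- 18
    sums <- c(0, 0); counts <- c(0L, 0L)
    set.seed(77)
    for (rep in 1:200) {
      perm <- sample.int(n)
      g1 <- perm[1:h]; g2 <- perm[(h + 1):(2 * h)]
      for (j in 1:2) {
        a <- sort(vals[g1, j]); b <- sort(vals[g2, j])
        if (sd(a) > 0 && sd(b) > 0) {
          sums[j] <- sums[j] + cor(a, b); counts[j] <- counts[j] + 1L
        }
      }
    }
    sums / counts
  })
  expect_equal(unname(res$mean_rho), oracle, tolerance = 1e-12)

  # shared value plus tiny order-preserving jitter: near-perfect reliability
  vals2 <- cbind(x = 5 + seq(0, 1e-3, length.out = 36))
  res2 <- split_half_reliability(vals2, n_reps = 100, seed = 3)
  expect_gt(res2$mean_rho[1], 0.95)
  expect_true(res2$consistent)

  expect_error(split_half_reliability(vals[1:3, , drop = FALSE]), "4 subjects")
})
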