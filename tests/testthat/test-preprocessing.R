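# Filters, epoching, ICA cleanup, power ratios.

test_that("band-pass keeps in-band amplitude, zero phase, and rejects bad bands", {
  sf <- 600
  t <- seq(0, 10, by = 1 / sf)
  s3 <- sin(2 * pi * 3 * t)
  y <- bandpass(s3, 0.5, 45, sf)
  mid <- 2000:4000
  expect_equal(sd(y[mid]) / sd(s3[mid]), 1, tolerance = 0.02)
  pulse <- exp(-(t - 5)^2 / (2 * 0.05^2))
  expect_equal(which.max(bandpass(pulse, 0.5, 45, sf)), which.max(pulse))
  expect_error(bandpass(s3, 50, 10, sf), "invalid band")
})

test_that("the notch filter suppresses line noise by at least 20 dB", {
  sf <- 600
  t <- seq(0, 5, by = 1 / sf)
  s60 <- sin(2 * pi * 60 * t)
  y <- notch_filter(s60, 60, 2, sf)
  mid <- 1000:2000
  expect_lt(20 * log10(sd(y[mid]) / sd(s60[mid])), -20)
})

test_that("blink epochs are centered on T0 and edge events are dropped", {
  r <- quick_recording()
  rec <- r$recording
  sf <- rec$sfreq
  events <- detect_blinks(bandpass(veog_data(rec), 0.1, 30, sf), sf)
  ep <- epoch_blink(rec, events)
  expect_equal(length(ep$times), 2 * round(1.5 * sf) + 1)
  expect_equal(ep$times[which(ep$times == 0)], 0)
  k <- 3
  t0 <- ep$centers[k]
  expect_equal(ep$data[k, , which(ep$times == 0)], rec$data[, t0])

  # events too close to the start are excluded and counted
  ev_bad <- structure(list(t0_samples = c(10L, events$t0_samples), scores = NULL,
                           sfreq = sf), class = "bro_events")
  ep2 <- epoch_blink(rec, ev_bad)
  expect_equal(ep2$n_dropped, 1L)
  expect_equal(dim(ep2$data)[1], dim(ep$data)[1])
})

test_that("control epochs form a contiguous non-overlapping block at the midpoint", {
  r <- quick_recording()
  rec <- r$recording
  ep <- epoch_control(rec, 10)
  expect_equal(dim(ep$data)[1], 10)
  len <- length(ep$times)
  expect_true(all(diff(ep$centers) == len))          # non-overlapping
  expect_equal(mean(ep$centers), ncol(rec$data) / 2, tolerance = len)
  expect_error(epoch_control(rec, 10000), "too short")

  # epoch zeros are not locked to blinks: offsets to the nearest T0 vary
  offs <- vapply(ep$centers / rec$sfreq, function(cz)
    min(abs(r$truth$blink_times - cz)), 0)
  expect_gt(length(unique(round(offs, 2))), 3)
})

test_that("ICA reconstructs its input and recovers a planted source", {
  set.seed(5)
  n <- 4000
  S <- rbind(sin(seq_len(n) / 20), sign(sin(seq_len(n) / 77)), rnorm(n))
  A0 <- matrix(rnorm(18), 6, 3)
  X <- A0 %*% S + matrix(rnorm(6 * n, sd = 0.01), 6)
  ic_full <- run_ica(X, n_components = 6, seed = 2)
  recon <- ic_full$mixing %*% ic_full$sources + ic_full$row_means
  expect_lt(norm(X - recon, "F") / norm(X, "F"), 1e-6)

  ic <- run_ica(X, n_components = 3, seed = 2)
  expect_gt(max(abs(cor(t(ic$sources), S[1, ]))), 0.95)
  # determinism with canonicalized order and sign
  expect_identical(run_ica(X, 3, seed = 2)$sources, ic$sources)
  expect_error(run_ica(X, n_components = 10), "exceeds")
})

test_that("ocular components are flagged by vEOG correlation and removed", {
  set.seed(6)
  n <- 4000
  veog <- bandpass(cumsum(rnorm(n)), 0.1, 30, 200)
  S <- rbind(veog, rnorm(n), sin(seq_len(n) / 15))
  A0 <- matrix(rnorm(24), 8, 3)
  X <- A0 %*% S
  ic <- run_ica(X, 3, seed = 1)
  flagged <- identify_ocular_components(ic, veog, corr_thresh = 0.8)
  expect_length(flagged, 1)
  # white noise component never flags at moderate thresholds
  expect_false(2 %in% identify_ocular_components(ic, rnorm(n), corr_thresh = 0.5))

  cleaned <- remove_components(ic, flagged)
  # removing no components reproduces the input
  expect_equal(remove_components(ic, integer(0)), X, tolerance = 1e-6)
  expect_error(remove_components(ic, 1:3), "all components")
  # cleaned data carry (almost) no vEOG signal
  expect_lt(max(abs(cor(t(cleaned), veog))), 0.2)
})

test_that("ICA cleanup collapses the blink-locked frontal response", {
  r <- quick_recording()
  rec_f <- bandpass(r$recording, 0.5, 45)
  sf <- rec_f$sfreq
  events <- detect_blinks(bandpass(veog_data(rec_f), 0.1, 30, sf), sf)
  ep_pre <- epoch_blink(rec_f, events)
  erf_pre <- average_epochs(ep_pre)
  cleaned <- clean_ocular(rec_f, seed = 4)
  expect_gte(attr(cleaned, "n_removed"), 1)
  erf_post <- average_epochs(epoch_blink(cleaned, events))
  frontal <- rec_f$array$regions == "frontal"
  i0 <- which(ep_pre$times == 0)
  amp_pre <- max(abs(erf_pre[frontal, i0]))
  amp_post <- max(abs(erf_post[frontal, i0]))
  expect_lt(amp_post, 0.1 * amp_pre)
})

test_that("the power ratio follows its defining formula and invariances", {
  times <- seq(-1.5, 1.5, by = 0.01)
  nchan <- 10
  erf <- matrix(rnorm(nchan * length(times)), nchan)
  iy <- which.min(abs(times - 0)); ix <- which.min(abs(times + 1))
  y <- erf[, iy]; x <- erf[, ix]

  expect_equal(power_ratio(erf, times),
               sum((y - mean(y))^2) / sum((x - mean(x))^2))
  # identical values at both latencies
  erf1 <- erf; erf1[, iy] <- erf1[, ix]
  expect_equal(power_ratio(erf1, times), 1)
  # doubled deviations quadruple the ratio
  erf2 <- erf; erf2[, iy] <- mean(x) + 2 * (x - mean(x))
  expect_equal(power_ratio(erf2, times), 4)
  # invariant to channel-common offsets at either latency
  erf3 <- erf; erf3[, iy] <- erf3[, iy] + 5; erf3[, ix] <- erf3[, ix] - 2
  expect_equal(power_ratio(erf3, times), power_ratio(erf, times))

  expect_error(power_ratio(erf[1, , drop = FALSE], times), "2 channels")
  expect_error(power_ratio(erf, times, t_base = -2), "outside")
  erf4 <- erf; erf4[, ix] <- 1
  expect_error(power_ratio(erf4, times), "zero baseline")
})

test_that("power-ratio group comparison applies Bonferroni and the ANOVA runs", {
  set.seed(3)
  regions <- c("frontal", "central", "parietal", "temporal", "occipital")
  tab <- expand.grid(subject = 1:8, region = regions, stage = c("pre", "post"),
                     stringsAsFactors = FALSE)
  tab$ratio <- ifelse(tab$stage == "pre", exp(rnorm(nrow(tab), 2, 0.3)),
                      exp(rnorm(nrow(tab), 0, 0.2)))
  res <- compare_power_ratios(tab)
  expect_equal(nrow(res$t_tests), 5)
  expect_equal(res$t_tests$p_bonf, pmin(1, 5 * res$t_tests$p))
  expect_true(all(res$t_tests$p < 0.05))
  expect_equal(nrow(res$anova), 2)
  expect_true(all(is.finite(res$anova$F)))

  # identical stages: t = 0, adjusted p = 1
  tab0 <- tab; tab0$ratio <- rep(tab0$ratio[tab0$stage == "pre"], 2)
  res0 <- compare_power_ratios(tab0)
  expect_true(all(res0$t_tests$t == 0))
  expect_true(all(res0$t_tests$p_bonf == 1))
})
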