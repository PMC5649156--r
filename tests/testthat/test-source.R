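# Minimum-norm inversion, contrast images, FWE permutation, virtual electrodes.

test_that("minimum norm is linear, zero on zero data, and exact at tiny lambda", {
  lf <- small_leadfield
  nt <- 50
  expect_equal(minimum_norm(matrix(0, 36, nt), lf)$moments,
               matrix(0, ncol(lf$gain), nt))

  g <- 12L
  x <- tcrossprod(lf$gain[, 2 * g - 1], sin(seq_len(nt) / 5)) * 1e-8
  y <- tcrossprod(lf$gain[, 7], cos(seq_len(nt) / 3)) * 1e-8
  e_sum <- minimum_norm(2 * x + 3 * y, lf)$moments
  e_parts <- 2 * minimum_norm(x, lf)$moments + 3 * minimum_norm(y, lf)$moments
  expect_lt(max(abs(e_sum - e_parts)) / max(abs(e_sum)), 1e-10)

  lam0 <- 1e-12 * mean(diag(tcrossprod(lf$gain)))
  est <- minimum_norm(x, lf, lambda = lam0)
  refit <- lf$gain %*% est$moments
  expect_lt(norm(refit - x, "F") / norm(x, "F"), 1e-6)
})

test_that("a planted dipole is localized within one grid spacing", {
  lf <- small_leadfield
  set.seed(11)
  for (g in sample.int(nrow(small_grid$coords), 4)) {
    x <- tcrossprod(lf$gain[, 2 * g - 1], rep(1, 10)) * 1e-8
    pw <- rowSums(bromeg:::.source_power(minimum_norm(x, lf)$moments))
    d <- sqrt(sum((small_grid$coords[which.max(pw), ] - small_grid$coords[g, ])^2))
    # nominal spacing slightly underestimates local neighbor distances on
    # the quasi-uniform shell; one grid step is up to ~1.5x nominal
    expect_lte(d, 1.5 * small_grid$spacing)
  }
})

test_that("solution norm is non-increasing in the regularization", {
  lf <- small_leadfield
  set.seed(12)
  x <- matrix(rnorm(36 * 20, sd = 1e-13), 36)
  scale0 <- mean(diag(tcrossprod(lf$gain)))
  norms <- vapply(c(1e-4, 1e-2, 1, 100) * scale0, function(l)
    sqrt(sum(minimum_norm(x, lf, lambda = l)$moments^2)), 0)
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("discrepancy-principle lambda matches the noise floor", {
  lf <- small_leadfield
  set.seed(13)
  x <- tcrossprod(lf$gain[, 5], sin(1:100 / 7)) * 1e-8 +
    matrix(rnorm(36 * 100, sd = 2e-14), 36)
  base <- matrix(rnorm(36 * 200, sd = 2e-14), 36)
  lam <- estimate_lambda(x, lf, base)
  est <- minimum_norm(x, lf, lambda = lam)
  resid2 <- sum((x - lf$gain %*% est$moments)^2)
  target <- sum(base^2) / ncol(base) * ncol(x)
  expect_equal(resid2 / target, 1, tolerance = 0.1)
})

test_that("shell smoothing preserves mass and follows the Gaussian profile", {
  K <- smoothing_kernel(small_grid, fwhm = 0.008)
  img <- numeric(nrow(small_grid$coords)); img[40] <- 3
  sm <- as.numeric(K %*% img)
  expect_equal(sum(sm), 3, tolerance = 1e-9)
  d <- sqrt(colSums((t(small_grid$coords) - small_grid$coords[40, ])^2))
  sigma <- 0.008 / (2 * sqrt(2 * log(2)))
  pred <- exp(-d^2 / (2 * sigma^2)); pred <- pred / sum(pred) * 3
  near <- d < 0.02
  expect_lt(max(abs(sm[near] - pred[near])) / max(pred), 0.05)
})

test_that("source contrast vanishes when post equals pre", {
  lf <- small_leadfield
  sf <- 120
  times <- seq(-1.5, 1.5, by = 1 / sf)
  set.seed(14)
  x <- matrix(rnorm(36 * length(times), sd = 1e-13), 36)
  # make the pre and post windows carry identical data
  ip <- bromeg:::.win_idx(times, c(0.15, 0.35))
  ib <- bromeg:::.win_idx(times, c(-1.3, -1.1))
  est <- minimum_norm(x, lf)
  est$moments[, ip[seq_along(ib)]] <- est$moments[, ib]
  img <- source_contrast(est, times, sf, post_win = c(0.15, 0.35),
                         pre_win = c(-1.3, -1.1), band = NULL)
  expect_lt(max(abs(img)), 1e-30)
})

test_that("group FWE controls the familywise error and respects direction", {
  set.seed(15)
  # all-zero images: nothing significant
  zero <- matrix(0, 8, 50)
  res0 <- group_fwe(zero + rnorm(400, sd = 1e-6), n_perm = 300, seed = 1)
  expect_equal(sum(res0$significant), 0)

  # null calibration over repetitions
  n_rep <- 200
  fp <- vapply(seq_len(n_rep), function(i) {
    img <- matrix(rnorm(8 * 40), 8)
    any(group_fwe(img, n_perm = 300, seed = 5000 + i)$significant)
  }, TRUE)
  ci <- 2.576 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(fp) - 0.05), ci + 0.01)

  # a strong localized positive effect is detected; its negation is not
  img <- matrix(rnorm(10 * 40), 10)
  img[, 5] <- img[, 5] + 4
  res <- group_fwe(img, n_perm = 500, seed = 2)
  expect_true(res$significant[5])
  res_neg <- group_fwe(-img, n_perm = 500, seed = 2)
  expect_false(res_neg$significant[5])

  expect_error(group_fwe(matrix(0, 4, 10)), "6 subjects")
})

test_that("group FWE enumerates sign flips exhaustively for small cohorts", {
  set.seed(16)
  img <- matrix(rnorm(7 * 20), 7)
  res <- group_fwe(img, n_perm = 10000, seed = 1)
  expect_equal(res$n_perm, 2^7)
  # exhaustive null: result independent of the seed
  res2 <- group_fwe(img, n_perm = 10000, seed = 99)
  expect_equal(unname(res$p_fwe), unname(res2$p_fwe))
})

test_that("covariate adjustment restores sensitivity under a blink-count confound", {
  set.seed(17)
  cov_ <- rnorm(10)
  # a real effect at one voxel, swamped everywhere by covariate-driven
  # between-subject variance
  img <- matrix(rnorm(10 * 30, sd = 0.3), 10)
  img[, 5] <- img[, 5] + 1
  img <- img + tcrossprod(cov_, rep(2, 30))
  res_raw <- group_fwe(img, n_perm = 400, seed = 3)
  res_adj <- group_fwe(img, n_perm = 400, seed = 3, covariate = cov_)
  expect_false(res_raw$significant[5])
  expect_true(res_adj$significant[5])
  expect_gt(res_adj$t[5], res_raw$t[5])
})

test_that("virtual electrode recovers the planted waveform timing and polarity", {
  r <- quick_recording()
  hm <- r$headmodel
  rec_f <- bandpass(r$recording, 0.5, 45)
  sf <- rec_f$sfreq
  events <- detect_blinks(bandpass(veog_data(rec_f), 0.1, 30, sf), sf)
  cleaned <- clean_ocular(rec_f, seed = 6)
  ep <- epoch_blink(cleaned, events)
  ve <- virtual_electrode(ep, hm$leadfield,
                          hm$grid$coords[hm$grid$precuneus_left, ])
  tms <- ep$times
  win <- tms >= 0 & tms <= 0.5
  peak_t <- tms[win][which.max(ve$average[win])]
  expect_lt(abs(peak_t - 0.25), 0.03 + 1e-9)
  # positive deflection first, then the trough
  trough_t <- tms[which.min(ve$average[tms >= 0.3 & tms <= 1.1]) + sum(tms < 0.3)]
  expect_gt(trough_t, peak_t)

  # reusing the orientation on other data keeps the projection fixed
  ep0 <- epoch_control(cleaned, dim(ep$data)[1])
  vc <- virtual_electrode(ep0, hm$leadfield,
                          hm$grid$coords[hm$grid$precuneus_left, ],
                          orientation = ve$orientation)
  expect_identical(vc$orientation, ve$orientation)
  expect_lt(max(abs(vc$average)), max(abs(ve$average)))

  # zero input gives a flat zero trace
  ep_zero <- ep; ep_zero$data[] <- 0
  vz <- virtual_electrode(ep_zero, hm$leadfield,
                          hm$grid$coords[hm$grid$precuneus_left, ],
                          orientation = ve$orientation)
  expect_equal(max(abs(vz$average)), 0)
  expect_error(virtual_electrode(ep, hm$leadfield, c(0, 0, 0.2)), "empty VOI")
})
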