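# End-to-end cohort pipeline: detection -> preprocessing -> sensor and
# source statistics, with a structured report object.

#' Process one subject through the single-subject stages
#'
#' Runs blink detection on the band-filtered vEOG, band-pass filters the
#' recording, measures pre-ICA regional power ratios, removes ocular ICA
#' components, re-measures post-ICA ratios, epochs both conditions, and
#' computes the subject's GFP, TF band powers, source contrast image, and
#' VOI time courses.
#'
#' @param recording a `bro_recording`.
#' @param leadfield the shared `bro_leadfield` for the cohort's array.
#' @param analysis a [bro_analysis_config()].
#' @param seed integer seed (ICA initialization).
#' @param kernel optional precomputed smoothing kernel.
#' @return list of per-subject results (see the report fields of
#'   [run_pipeline()]).
#' @export
process_subject <- function(recording, leadfield, analysis = bro_analysis_config(),
                            seed = 1L, kernel = NULL) {
  sfreq <- recording$sfreq
  regions <- recording$array$regions
  veog_f <- bandpass(veog_data(recording), analysis$blink_band_lo,
                     analysis$blink_band_hi, sfreq)
  events <- detect_blinks(veog_f, sfreq, match_thresh = analysis$match_thresh,
                          amp_frac = analysis$amp_frac, min_gap = analysis$min_gap)
  if (length(events$t0_samples) < 2) stop("fewer than 2 blinks detected")
  blink_rate <- length(events$t0_samples) / (ncol(recording$data) / sfreq) * 60

  # vEOG morphology from the raw (blink-band) blink average
  veog_rec <- structure(list(data = matrix(veog_f, 1), sfreq = sfreq,
                             types = "EOG", labels = "VEOG",
                             duration = recording$duration,
                             array = recording$array), class = "bro_recording")
  vep <- epoch_blink(veog_rec, events, analysis$epoch_half_width)
  veog_epochs <- vep$data[, 1, ]
  veog_avg <- colMeans(veog_epochs)
  morph <- extract_morphology(veog_avg, sfreq)

  if (!is.null(analysis$notch))
    recording <- notch_filter(recording, analysis$notch, sfreq = sfreq)
  rec_f <- bandpass(recording, analysis$band_lo, analysis$band_hi)

  ep_pre <- epoch_blink(rec_f, events, analysis$epoch_half_width)
  erf_pre <- average_epochs(ep_pre)
  ratios_pre <- regional_power_ratios(erf_pre, regions, ep_pre$times,
                                      analysis$ratio_t_blink, analysis$ratio_t_base)

  rec_clean <- clean_ocular(rec_f, n_components = min(analysis$ica_n_components,
                                                      sum(rec_f$types == "MEG")),
                            seed = seed, corr_thresh = analysis$ica_corr_thresh,
                            max_fit_samples = analysis$ica_fit_samples,
                            maxit = analysis$ica_maxit)

  ep_blink <- epoch_blink(rec_clean, events, analysis$epoch_half_width)
  ep_control <- epoch_control(rec_clean, dim(ep_blink$data)[1],
                              analysis$epoch_half_width)
  erf_blink <- average_epochs(ep_blink)
  erf_control <- average_epochs(ep_control)
  times <- ep_blink$times
  ratios_post <- regional_power_ratios(erf_blink, regions, times,
                                       analysis$ratio_t_blink, analysis$ratio_t_base)

  # delta-band filtering happens on the continuous recording, then epochs
  # are cut: no per-epoch filter transients near the window edges
  rec_delta <- bandpass(rec_clean, analysis$delta_band[1], analysis$delta_band[2])
  ep_blink_d <- epoch_blink(rec_delta, events, analysis$epoch_half_width)
  ep_control_d <- epoch_control(rec_delta, dim(ep_blink_d$data)[1],
                                analysis$epoch_half_width)
  erf_blink_d <- average_epochs(ep_blink_d)
  erf_control_d <- average_epochs(ep_control_d)

  gfp_blink <- global_field_power(erf_blink_d, sfreq, band = NULL, times = times)
  gfp_control <- global_field_power(erf_control_d, sfreq, band = NULL, times = times)

  tf_power <- if (!isTRUE(analysis$do_tf)) NULL else
    lapply(list(blink = ep_blink, control = ep_control), function(ep) {
    tf <- suppressWarnings(morlet_tf(ep, freqs = analysis$tf_freqs,
                                     n_cycles = analysis$tf_n_cycles,
                                     baseline = analysis$tf_baseline))
    c(pre = tf_band_power(tf, analysis$gfp_pre_win, analysis$delta_band),
      post = tf_band_power(tf, analysis$gfp_post_win, analysis$delta_band))
  })

  lam <- analysis$lambda_rel * mean(diag(tcrossprod(leadfield$gain)))
  if (is.null(kernel)) kernel <- smoothing_kernel(leadfield$grid, analysis$smooth_fwhm)
  contrast <- lapply(list(blink = erf_blink_d, control = erf_control_d), function(erf) {
    est <- minimum_norm(erf, leadfield, lambda = lam)
    source_contrast(est, times, sfreq, analysis$gfp_post_win, analysis$gfp_pre_win,
                    band = NULL, fwhm = analysis$smooth_fwhm, kernel = kernel)
  })

  grid <- leadfield$grid
  voi <- lapply(c(left = grid$precuneus_left, right = grid$precuneus_right),
                function(pi_) {
    vb <- virtual_electrode(ep_blink_d, leadfield, grid$coords[pi_, ],
                            radius = analysis$voi_radius, lambda = lam,
                            band = NULL, post_win = analysis$gfp_post_win)
    vc <- virtual_electrode(ep_control_d, leadfield, grid$coords[pi_, ],
                            radius = analysis$voi_radius, lambda = lam,
                            band = NULL, orientation = vb$orientation)
    list(blink = vb$average, control = vc$average)
  })

  list(events = events, blink_rate = blink_rate, morphology = morph,
       veog_average = veog_avg, n_trials = dim(ep_blink$data)[1],
       n_dropped = ep_blink$n_dropped,
       ratios = list(pre = ratios_pre, post = ratios_post),
       n_ica_removed = attr(rec_clean, "n_removed"),
       gfp = list(blink = gfp_blink$values, control = gfp_control$values),
       tf_power = tf_power, contrast = contrast, voi = voi, times = times)
}

#' Run the full cohort pipeline
#'
#' Orchestrates all stages over a cohort and assembles the group-level
#' statistics: blink behavior (rate, morphology, split-half reliability),
#' power-ratio comparisons before/after ICA, windowed GFP contrasts and
#' bootstrap confidence bands, the delta-band spectral permutation test,
#' the four source contrasts (Bpost>Bpre, Bpre>Bpost, Cpost>Cpre,
#' Cpre>Cpost) with max-statistic FWE control and blink-count covariate,
#' and VOI cluster permutation tests (blink vs control).
#'
#' @param cohort list of subjects as returned by [simulate_cohort()] (each
#'   element has `$recording`), or a list of `bro_recording` objects.
#' @param headmodel shared head model (list with `array`, `grid`,
#'   `leadfield`); taken from `attr(cohort, "headmodel")` if absent.
#' @param analysis a [bro_analysis_config()].
#' @param seed master integer seed for all stochastic stages.
#' @return object of class `bro_report`.
#' @export
run_pipeline <- function(cohort, headmodel = NULL,
                         analysis = bro_analysis_config(), seed = 1L) {
  if (is.null(headmodel)) headmodel <- attr(cohort, "headmodel")
  if (is.null(headmodel)) stop("headmodel is required (or attach it to the cohort)")
  lf <- headmodel$leadfield
  grid <- headmodel$grid
  kernel <- smoothing_kernel(grid, analysis$smooth_fwhm)

  subjects <- lapply(seq_along(cohort), function(k) {
    rec <- if (inherits(cohort[[k]], "bro_recording")) cohort[[k]] else cohort[[k]]$recording
    tryCatch(process_subject(rec, lf, analysis, seed = .substream_seed(seed, 2000L + k),
                             kernel = kernel),
             error = function(e) stop("subject ", k, ": ", conditionMessage(e)))
  })
  n_subj <- length(subjects)
  times <- subjects[[1]]$times

  # --- blink behavior
  morph <- t(vapply(subjects, function(s)
    unlist(s$morphology[c("M1", "M2", "M3", "M4")]), numeric(4)))
  colnames(morph) <- c("M1_uV", "M2_s", "M3_uV", "M4_s")
  rates <- vapply(subjects, `[[`, 0, "blink_rate")
  counts <- vapply(subjects, function(s) length(s$events$t0_samples), 0L)
  reliability <- if (n_subj >= 4)
    split_half_reliability(morph, analysis$split_half_reps,
                           seed = .substream_seed(seed, 31L)) else NULL

  # --- power ratios
  ratio_tab <- do.call(rbind, lapply(seq_len(n_subj), function(k) {
    do.call(rbind, lapply(c("pre", "post"), function(st) {
      d <- subjects[[k]]$ratios[[st]]
      data.frame(subject = k, region = d$region, stage = st, ratio = d$ratio)
    }))
  }))
  ratio_tests <- if (n_subj >= 2) compare_power_ratios(ratio_tab) else NULL

  # --- sensor space
  gfp_mat <- list(
    blink = t(vapply(subjects, function(s) s$gfp$blink, numeric(length(times)))),
    control = t(vapply(subjects, function(s) s$gfp$control, numeric(length(times)))))
  gfp_tests <- if (n_subj >= 2)
    gfp_window_contrast(gfp_mat, times, analysis$gfp_post_win, analysis$gfp_pre_win)
    else NULL
  gfp_grand <- lapply(gfp_mat, colMeans)
  gfp_peak_latency <- times[which.max(gfp_grand$blink)]
  gfp_ci <- if (n_subj >= 4) lapply(gfp_mat, bootstrap_ci, level = analysis$ci_level,
                                    seed = .substream_seed(seed, 32L)) else NULL

  spectral <- if (n_subj >= 4 && !is.null(subjects[[1]]$tf_power)) {
    pre <- vapply(subjects, function(s) s$tf_power$blink["pre"], 0)
    post <- vapply(subjects, function(s) s$tf_power$blink["post"], 0)
    pre_c <- vapply(subjects, function(s) s$tf_power$control["pre"], 0)
    post_c <- vapply(subjects, function(s) s$tf_power$control["post"], 0)
    list(blink = spectral_permutation(pre, post, analysis$n_perm_spectral,
                                      seed = .substream_seed(seed, 33L)),
         control = spectral_permutation(pre_c, post_c, analysis$n_perm_spectral,
                                        seed = .substream_seed(seed, 34L)))
  } else NULL

  # --- source space: four contrasts
  img_b <- t(vapply(subjects, function(s) s$contrast$blink, numeric(nrow(grid$coords))))
  img_c <- t(vapply(subjects, function(s) s$contrast$control, numeric(nrow(grid$coords))))
  fwe <- if (n_subj >= 6) {
    imgs <- list(Bpost_gt_Bpre = img_b, Bpre_gt_Bpost = -img_b,
                 Cpost_gt_Cpre = img_c, Cpre_gt_Cpost = -img_c)
    lapply(seq_along(imgs), function(i) {
      group_fwe(imgs[[i]], analysis$n_perm_fwe,
                seed = .substream_seed(seed, 40L + i),
                covariate = counts, alpha = analysis$fwe_alpha)
    }) |> stats::setNames(names(imgs))
  } else NULL

  # --- VOI cluster statistics
  voi_tests <- if (n_subj >= 4) {
    lapply(c(left = "left", right = "right"), function(side) {
      a <- t(vapply(subjects, function(s) s$voi[[side]]$blink, numeric(length(times))))
      b <- t(vapply(subjects, function(s) s$voi[[side]]$control, numeric(length(times))))
      cluster_permutation(a, b, times, analysis$cluster_alpha,
                          analysis$n_perm_cluster,
                          seed = .substream_seed(seed, if (side == "left") 51L else 52L))
    })
  } else NULL

  structure(list(
    n_subjects = n_subj, times = times, seed = seed,
    blink = list(counts = counts, rates = rates, morphology = morph,
                 reliability = reliability),
    ratios = list(table = ratio_tab, tests = ratio_tests),
    gfp = list(matrices = gfp_mat, grand = gfp_grand, tests = gfp_tests,
               peak_latency = gfp_peak_latency, ci = gfp_ci),
    spectral = spectral,
    source = list(fwe = fwe, grid = grid,
                  precuneus = c(grid$precuneus_left, grid$precuneus_right)),
    voi = voi_tests,
    subjects = subjects
  ), class = "bro_report")
}

#' @export
print.bro_report <- function(x, ...) {
  cat(sprintf("<bro_report> %d subjects, master seed %d\n", x$n_subjects, x$seed))
  cat(sprintf("  blinks: %.1f +- %.1f per subject (%.1f +- %.1f per minute)\n",
              mean(x$blink$counts), stats::sd(x$blink$counts),
              mean(x$blink$rates), stats::sd(x$blink$rates)))
  m <- x$blink$morphology
  cat(sprintf("  morphology: M1 %.2f uV, M2 %.3f s, M3 %.2f uV, M4 %.3f s (means)\n",
              mean(m[, 1]), mean(m[, 2]), mean(m[, 3]), mean(m[, 4])))
  if (!is.null(x$blink$reliability))
    cat(sprintf("  split-half reliability: %s (consistent: %s)\n",
                paste(sprintf("%.3f", x$blink$reliability$mean_rho), collapse = ", "),
                x$blink$reliability$consistent))
  if (!is.null(x$gfp$tests)) {
    for (i in seq_len(nrow(x$gfp$tests)))
      cat(sprintf("  GFP post vs pre [%s]: t = %.2f, p = %.2g\n",
                  x$gfp$tests$condition[i], x$gfp$tests$t[i], x$gfp$tests$p[i]))
    cat(sprintf("  blink GFP peak latency: %.0f ms\n", 1000 * x$gfp$peak_latency))
  }
  if (!is.null(x$spectral))
    cat(sprintf("  delta spectral permutation: blink p = %.3g, control p = %.3g\n",
                x$spectral$blink$p, x$spectral$control$p))
  if (!is.null(x$source$fwe)) {
    for (nm in names(x$source$fwe)) {
      f <- x$source$fwe[[nm]]
      cat(sprintf("  %s: %d suprathreshold voxels%s\n", nm, sum(f$significant),
                  if (sum(f$significant)) sprintf(" (precuneus proxies included: %s)",
                    all(x$source$precuneus %in% which(f$significant))) else ""))
    }
  }
  if (!is.null(x$voi)) {
    for (side in names(x$voi)) {
      cl <- x$voi[[side]]$clusters
      sig <- cl[cl$p < 0.05, , drop = FALSE]
      cat(sprintf("  VOI %s: %d significant cluster(s)%s\n", side, nrow(sig),
                  if (nrow(sig)) paste0(" at ",
                    paste(sprintf("%.0f-%.0f ms (%s)", 1000 * sig$start,
                                  1000 * sig$end, ifelse(sig$sign > 0, "+", "-")),
                          collapse = ", ")) else ""))
    }
  }
  invisible(x)
}
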