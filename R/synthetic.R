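# Synthetic MEG + vEOG recordings with planted ground truth.
#
# A recording is composed of: (i) background brain noise (1/f-spectrum
# dipole sources on the grid, plus a posterior 10 Hz alpha rhythm and white
# sensor noise), (ii) an ocular artifact dipole anterior-inferior to the
# source grid whose moment follows the clean vEOG blink train, and (iii) a
# blink-locked delta-band neural response planted at the precuneus-proxy
# grid points. The vEOG channel carries the blink train plus pink noise.

#' Blink waveform parameters (vEOG morphology)
#'
#' Container for the four morphology features used as generator parameters:
#' positive peak amplitude M1 (uV), positive peak width M2 (s), negative
#' peak amplitude M3 (uV), negative peak time M4 (s after the blink
#' maximum). Defaults are the group-level values of a healthy adult cohort.
#'
#' @param pos_amp positive peak amplitude (uV), > 0.
#' @param pos_width positive lobe base width (s), > 0.
#' @param neg_amp negative trough amplitude (uV), < 0.
#' @param neg_time trough latency after the positive peak (s); must lie
#'   beyond the positive lobe (`neg_time > pos_width / 2`).
#' @return list of class `bro_blink_params`.
#' @export
blink_params <- function(pos_amp = 43.70, pos_width = 0.329,
                         neg_amp = -10.07, neg_time = 0.399) {
  if (pos_amp <= 0 || pos_width <= 0) stop("invalid params: positive lobe must have positive amplitude and width")
  if (neg_amp >= 0) stop("invalid params: neg_amp must be negative")
  if (neg_time <= pos_width / 2)
    stop("invalid params: neg_time lies inside the positive lobe")
  structure(list(pos_amp = pos_amp, pos_width = pos_width,
                 neg_amp = neg_amp, neg_time = neg_time),
            class = "bro_blink_params")
}

#' Biphasic vEOG blink template
#'
#' Smooth biphasic waveform: a Hann-shaped positive lobe of base width
#' `pos_width` peaking at t = 0 (the blink maximum), followed by a
#' Hann-shaped negative lobe whose trough sits at `neg_time` and which
#' returns to zero symmetrically. The two lobes scale independently with
#' their amplitudes, and the morphology extractor recovers the four
#' parameters to within one sample period.
#'
#' @param params a `bro_blink_params`.
#' @param sfreq sampling rate (Hz).
#' @param margin zero-padding (s) on both sides of the waveform.
#' @return list of class `bro_blink_template` with `trace` (uV), `t` (s,
#'   0 at the positive peak), `t0_index`, `sfreq`.
#' @export
blink_waveform <- function(params, sfreq, margin = 0.2) {
  stopifnot(inherits(params, "bro_blink_params"))
  w2 <- params$pos_width / 2
  neg_half <- params$neg_time - w2
  t_end <- params$neg_time + neg_half
  t <- seq(-w2 - margin, t_end + margin, by = 1 / sfreq)
  y <- numeric(length(t))
  ip <- abs(t) < w2
  y[ip] <- params$pos_amp * cos(pi * t[ip] / params$pos_width)^2
  inn <- abs(t - params$neg_time) < neg_half
  y[inn] <- params$neg_amp * cos(pi * (t[inn] - params$neg_time) / (2 * neg_half))^2
  structure(list(trace = y, t = t, t0_index = which.min(abs(t)), sfreq = sfreq),
            class = "bro_blink_template")
}

#' Spontaneous blink times: thinned Poisson process
#'
#' Homogeneous Poisson process at `rate` per minute on
#' `(margin, duration - margin)`, thinned left-to-right so consecutive kept
#' events are at least `refractory` seconds apart.
#'
#' @param duration recording length (s).
#' @param rate blink rate per minute.
#' @param refractory minimum gap between blinks (s).
#' @param seed integer seed.
#' @param margin guard zone at both edges (s).
#' @return sorted numeric vector of blink-maximum times (s).
#' @export
generate_blink_times <- function(duration, rate = 11.3, refractory = 3,
                                 seed = 1L, margin = 1.7) {
  stopifnot(duration > 0, rate >= 0, refractory >= 0)
  if (rate == 0 || duration <= 2 * margin) return(numeric(0))
  tt <- .substream_eval(seed, 1L, {
    n <- stats::rpois(1, rate / 60 * (duration - 2 * margin))
    sort(stats::runif(n, margin, duration - margin))
  })
  if (!length(tt)) return(numeric(0))
  keep <- tt[1]
  for (x in tt[-1]) if (x - keep[length(keep)] >= refractory) keep <- c(keep, x)
  keep
}

# unit-RMS rows with power spectral density ~ 1/f^slope (flat below f_floor)
.pink_rows <- function(n_rows, n_samp, sfreq, slope = 1, f_floor = 0.5) {
  f <- seq(0, sfreq / 2, length.out = floor(n_samp / 2) + 1)
  amp <- pmax(f, f_floor)^(-slope / 2)
  amp[1] <- 0                                  # no DC
  out <- matrix(0, n_rows, n_samp)
  for (r in seq_len(n_rows)) {
    ph <- stats::runif(length(f)) * 2 * pi
    spec <- amp * exp(1i * ph)
    full <- c(spec, Conj(rev(spec[2:(n_samp - length(f) + 1)])))
    x <- Re(stats::fft(full, inverse = TRUE))
    out[r, ] <- x / stats::sd(x)
  }
  out
}

# Blink-locked neural source waveform: a Hann-windowed one-cycle wave.
# A positive Hann lobe (base width 0.4 s, amplitude 1) peaks at `latency`;
# the adjacent negative lobe (width 0.5 s, amplitude -0.8) troughs 450 ms
# later (at 700 ms for the default 250 ms latency). The lobe areas cancel,
# so the pulse has no DC content and is naturally concentrated in the
# delta band, with no energy outside its 0.9 s support; the shallower,
# longer negative lobe mirrors the smaller trailing deflection of the
# response this emulates.
bro_response_waveform <- function(sfreq, latency = 0.25) {
  t <- seq(-1.5, 2.0, by = 1 / sfreq)
  tc <- t - latency                      # 0 at the positive peak
  y <- numeric(length(t))
  ip <- abs(tc) < 0.2
  y[ip] <- cos(pi * tc[ip] / 0.4)^2
  inn <- abs(tc - 0.45) < 0.25
  y[inn] <- -0.8 * cos(pi * (tc[inn] - 0.45) / 0.5)^2
  y / max(y)
}

#' Simulation configuration
#'
#' Defaults emulate the acquisition this pipeline targets: 151 axial
#' gradiometers (5 cm baseline) sampled at 1200 Hz for 10 minutes, blinks at
#' 11.3/min with at least 3 s separation, and a blink-locked delta-band
#' response at the precuneus-proxy grid points peaking 250 ms after the
#' blink maximum. Amplitude constants are documented package choices
#' (see the methods vignette): background dipole noise is scaled so that
#' the single-trial blink-locked sensor SNR is about -10 dB, so that
#' trial-averaged effects emerge at about 60 blinks.
#'
#' @param n_chan,sfreq,duration array size, sampling rate (Hz), length (s).
#' @param blink_rate blinks per minute.
#' @param refractory minimum blink separation (s).
#' @param blink_params a [blink_params()] object (vEOG morphology).
#' @param blink_amp_jitter SD of the per-blink multiplicative amplitude
#'   jitter (lognormal-free gaussian, truncated at 0.5).
#' @param veog_noise_uv pink-noise RMS on the vEOG channel (uV).
#' @param ocular_pos equivalent ocular dipole position (m).
#' @param ocular_gain ocular dipole moment per uV of clean vEOG (A*m/uV).
#' @param neural_amplitude peak moment of the planted response (A*m) at
#'   each precuneus-proxy point; 0 plants nothing.
#' @param neural_latency response peak latency after blink maximum (s).
#' @param morph_sd across-subject SDs of the four morphology parameters
#'   (uV, s, uV, s); each subject's blink waveform uses parameters drawn
#'   once around `blink_params` with these SDs.
#' @param neural_amp_sd lognormal SD of the per-subject neural amplitude
#'   scale (inter-individual response variability).
#' @param bg_rms_sd lognormal SD of the per-subject background level scale.
#' @param bg_rms mean per-channel RMS of projected background brain noise (T).
#' @param alpha_rms mean per-channel RMS of the 10 Hz posterior rhythm (T).
#' @param sensor_noise_rms white sensor noise RMS (T).
#' @param n_bg number of background noise dipoles.
#' @param grid_spacing source grid spacing (m).
#' @param helmet_radius,conductor_radius,baseline array geometry (m).
#' @return list of class `bro_sim_config`.
#' @export
bro_sim_config <- function(n_chan = 151, sfreq = 1200, duration = 600,
                           blink_rate = 11.3, refractory = 3,
                           blink_params = NULL,
                           blink_amp_jitter = 0.1, veog_noise_uv = 2,
                           ocular_pos = c(0, 0.075, -0.025),
                           ocular_gain = 3e-9,
                           neural_amplitude = 8e-9,
                           neural_latency = 0.25,
                           morph_sd = c(3.10, 0.016, 1.13, 0.017),
                           neural_amp_sd = 0.3, bg_rms_sd = 0.2,
                           bg_rms = 120e-15, alpha_rms = 60e-15,
                           sensor_noise_rms = 60e-15, n_bg = 30,
                           grid_spacing = 0.01, helmet_radius = 0.11,
                           conductor_radius = 0.09, baseline = 0.05) {
  cfg <- as.list(environment())
  if (is.null(cfg$blink_params)) cfg$blink_params <- blink_params()
  structure(cfg, class = "bro_sim_config")
}

#' Build the shared head model for a simulation config
#'
#' The sensor array, source grid, and lead field are deterministic given the
#' config and seed, and can be shared across the subjects of a cohort.
#'
#' @param config a `bro_sim_config`.
#' @param seed seed for the array jitter.
#' @return list with `array`, `grid`, `leadfield`.
#' @export
build_headmodel <- function(config, seed = 1L) {
  array <- build_sensor_array(config$n_chan, config$helmet_radius,
                              config$baseline, config$conductor_radius,
                              seed = seed)
  grid <- build_source_grid(config$grid_spacing,
                            conductor_radius = config$conductor_radius)
  list(array = array, grid = grid, leadfield = compute_leadfield(array, grid))
}

#' Generate one synthetic recording with ground truth
#'
#' @param config a [bro_sim_config()].
#' @param seed master integer seed for this subject; all generator
#'   components draw from documented substreams of it.
#' @param headmodel optional precomputed [build_headmodel()] result (reused
#'   across a cohort); built on the fly if `NULL`.
#' @return list with `recording` (class `bro_recording`: `data` is
#'   (n_chan+1) x n_samp with MEG rows in tesla and the last row the vEOG
#'   in microvolt, plus `sfreq`, `array`, `labels`, `types`) and `truth`
#'   (class `bro_ground_truth`: `blink_times`, `ocular_mixing`,
#'   `neural_source_index`, `neural_latency`, `neural_amplitude`,
#'   `neural_waveform`).
#' @export
generate_recording <- function(config = bro_sim_config(), seed = 1L,
                               headmodel = NULL) {
  stopifnot(inherits(config, "bro_sim_config"))
  if (is.null(headmodel)) headmodel <- build_headmodel(config, seed)
  array <- headmodel$array; grid <- headmodel$grid; lf <- headmodel$leadfield
  n_chan <- nrow(array$positions)
  sfreq <- config$sfreq
  n_samp <- round(config$duration * sfreq)

  # --- per-subject draws: morphology parameters and amplitude scales
  # (streams 13-15); inter-individual variability of the cohort
  bp <- config$blink_params
  ms <- config$morph_sd
  dm <- .substream_norm(seed, 13L, 4L)
  bp_subj <- blink_params(
    pos_amp = max(5, bp$pos_amp + dm[1] * ms[1]),
    pos_width = max(0.05, bp$pos_width + dm[2] * ms[2]),
    neg_amp = min(-0.5, bp$neg_amp + dm[3] * ms[3]),
    neg_time = max(max(0.05, bp$pos_width + dm[2] * ms[2]) / 2 + 0.02,
                   bp$neg_time + dm[4] * ms[4]))
  neural_amp <- config$neural_amplitude *
    exp(.substream_norm(seed, 14L, 1L, sd = config$neural_amp_sd))
  bg_scale <- exp(.substream_norm(seed, 15L, 1L, sd = config$bg_rms_sd))

  # --- vEOG: blink train + pink noise (streams 1-3)
  blink_times <- generate_blink_times(config$duration, config$blink_rate,
                                      config$refractory, seed)
  tmpl <- blink_waveform(bp_subj, sfreq)
  amps <- pmax(0.5, 1 + .substream_norm(seed, 2L, length(blink_times),
                                        sd = config$blink_amp_jitter))
  veog_clean <- numeric(n_samp)
  for (k in seq_along(blink_times)) {
    i0 <- round(blink_times[k] * sfreq) + 1L
    idx <- i0 + seq_along(tmpl$trace) - tmpl$t0_index
    ok <- idx >= 1L & idx <= n_samp
    veog_clean[idx[ok]] <- veog_clean[idx[ok]] + amps[k] * tmpl$trace[ok]
  }
  veog <- veog_clean + config$veog_noise_uv *
    .substream_eval(seed, 3L, .pink_rows(1L, n_samp, sfreq))[1, ]

  meg <- matrix(0, n_chan, n_samp)

  # --- background brain noise: 1/f dipoles on the grid (stream 4)
  n_grid <- nrow(grid$coords)
  if (config$bg_rms > 0 && config$n_bg > 0) {
    bg <- .substream_eval(seed, 4L, {
      src <- sample.int(n_grid, config$n_bg, replace = config$n_bg > n_grid)
      ang <- stats::runif(config$n_bg, 0, 2 * pi)
      tcs <- .pink_rows(config$n_bg, n_samp, sfreq)
      list(src = src, ang = ang, tcs = tcs)
    })
    G <- lf$gain[, 2 * bg$src - 1, drop = FALSE] * rep(cos(bg$ang), each = n_chan) +
         lf$gain[, 2 * bg$src, drop = FALSE] * rep(sin(bg$ang), each = n_chan)
    X <- G %*% bg$tcs
    meg <- meg + X * (bg_scale * config$bg_rms / mean(sqrt(rowMeans(X^2))))
  }

  # --- posterior alpha rhythm (stream 5)
  if (config$alpha_rms > 0) {
    post <- which.min(colSums((t(grid$coords) - c(0, -0.05, 0.03))^2))
    al <- .substream_eval(seed, 5L, {
      ph <- stats::runif(1, 0, 2 * pi)
      env <- .pink_rows(1L, n_samp, sfreq, slope = 2, f_floor = 0.05)[1, ]
      list(ph = ph, env = 1 + 0.5 * env / max(abs(env)))
    })
    tt <- (seq_len(n_samp) - 1) / sfreq
    a_tc <- sin(2 * pi * 10 * tt + al$ph) * al$env
    Xa <- tcrossprod(lf$gain[, 2 * post - 1], a_tc)
    meg <- meg + Xa * (bg_scale * config$alpha_rms / mean(sqrt(rowMeans(Xa^2))))
  }

  # --- ocular artifact dipole driven by the clean vEOG
  oc_tb <- .tangent_basis(config$ocular_pos)
  oc_dir <- oc_tb$e1    # polar tangent: vertical-ish eyelid current
  inner <- array$positions
  outer <- inner + array$orientations * array$baseline
  g_oc <- sarvas_field(config$ocular_pos, oc_dir, inner) -
    sarvas_field(config$ocular_pos, oc_dir, outer)
  if (config$ocular_gain > 0)
    meg <- meg + tcrossprod(g_oc, veog_clean * config$ocular_gain)

  # --- blink-locked neural response at the precuneus proxies
  neural_idx <- c(grid$precuneus_left, grid$precuneus_right)
  w <- bro_response_waveform(sfreq, config$neural_latency)
  w_t0 <- which.min(abs(seq(-1.5, 2.0, by = 1 / sfreq)))
  neural_tc <- numeric(n_samp)
  if (neural_amp > 0 && length(blink_times)) {
    for (tk in blink_times) {
      i0 <- round(tk * sfreq) + 1L
      idx <- i0 + seq_along(w) - w_t0
      ok <- idx >= 1L & idx <= n_samp
      neural_tc[idx[ok]] <- neural_tc[idx[ok]] + w[ok]
    }
    g_n <- lf$gain[, 2 * neural_idx - 1, drop = FALSE]   # first tangent orientation
    meg <- meg + (g_n %*% rbind(neural_tc, neural_tc)) * neural_amp
  }

  # --- sensor noise (stream 6)
  if (config$sensor_noise_rms > 0)
    meg <- meg + matrix(.substream_norm(seed, 6L, n_chan * n_samp,
                                        sd = config$sensor_noise_rms),
                        n_chan, n_samp)

  data <- rbind(meg, veog)
  dimnames(data) <- NULL
  recording <- structure(list(
    data = data,
    sfreq = sfreq,
    duration = config$duration,
    labels = c(array$labels, "VEOG"),
    types = c(rep("MEG", n_chan), "EOG"),
    array = array
  ), class = "bro_recording")

  truth <- structure(list(
    blink_times = blink_times,
    ocular_mixing = g_oc * config$ocular_gain,
    neural_source_index = neural_idx,
    neural_latency = config$neural_latency,
    neural_amplitude = neural_amp,
    blink_params = bp_subj,
    neural_waveform = w,
    neural_tc = neural_tc
  ), class = "bro_ground_truth")

  list(recording = recording, truth = truth)
}

#' @export
print.bro_recording <- function(x, ...) {
  cat(sprintf("<bro_recording> %d channels (%d MEG + %d EOG), %.0f s @ %g Hz\n",
              nrow(x$data), sum(x$types == "MEG"), sum(x$types == "EOG"),
              x$duration, x$sfreq))
  invisible(x)
}

#' Simulate a cohort of subjects sharing one head model
#'
#' @param n_subjects number of subjects.
#' @param config a [bro_sim_config()].
#' @param seed master seed; subject k uses substream `1000 + k`.
#' @param headmodel optional shared head model.
#' @return list of per-subject `generate_recording()` results; the shared
#'   head model is attached as attribute `headmodel`.
#' @export
simulate_cohort <- function(n_subjects, config = bro_sim_config(), seed = 1L,
                            headmodel = NULL) {
  if (is.null(headmodel)) headmodel <- build_headmodel(config, seed)
  out <- lapply(seq_len(n_subjects), function(k) {
    generate_recording(config, .substream_seed(seed, 1000L + k), headmodel)
  })
  attr(out, "headmodel") <- headmodel
  out
}

#' Extract the MEG rows / vEOG trace of a recording
#'
#' @param recording a `bro_recording`.
#' @return `meg_data`: MEG channels x samples matrix (T). `veog_data`: the
#'   vEOG trace (uV).
#' @export
meg_data <- function(recording) recording$data[recording$types == "MEG", , drop = FALSE]

#' @rdname meg_data
#' @export
veog_data <- function(recording) recording$data[recording$types == "EOG", , drop = FALSE][1, ]
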