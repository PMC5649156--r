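# Sensor-space analysis: delta-band global field power, windowed GFP
# contrasts, Morlet time-frequency log power, and the spectral
# permutation (sign-flip) test.

#' Global field power of a trial-averaged ERF
#'
#' Band-filters the trial-averaged data and takes the spatial standard
#' deviation across channels at each time point (the classical GFP
#' convention; set `type = "variance"` for spatial variance). GFP is
#' invariant to channel-common offsets and is non-negative.
#'
#' @param avg channels x time trial-averaged matrix.
#' @param sfreq sampling rate (Hz).
#' @param band length-2 band (Hz) applied before the spatial statistic;
#'   `NULL` skips filtering. Default delta, 0.5-4 Hz.
#' @param times optional time axis to attach.
#' @param type `"sd"` (default) or `"variance"`.
#' @return object of class `bro_gfp`: `values`, `times`, `band`.
#' @export
global_field_power <- function(avg, sfreq, band = c(0.5, 4), times = NULL,
                               type = c("sd", "variance")) {
  type <- match.arg(type)
  avg <- as.matrix(avg)
  if (nrow(avg) < 2) stop("GFP needs at least 2 channels")
  if (!is.null(band)) avg <- bandpass(avg, band[1], band[2], sfreq)
  v <- apply(avg, 2, stats::sd)
  if (type == "variance") v <- v^2
  structure(list(values = v,
                 times = if (is.null(times)) seq_len(ncol(avg)) / sfreq else times,
                 band = band, type = type),
            class = "bro_gfp")
}

#' Windowed GFP contrast (post vs pre) across subjects
#'
#' Averages each subject's GFP over a post-stimulus window (default
#' 150-350 ms, spanning the blink-condition GFP peak) and a pre-blink
#' baseline window (default -1300 to -1100 ms), and compares them with a
#' paired t-test, separately per condition.
#'
#' @param gfp_by_condition named list (conditions) of subjects x time GFP
#'   matrices.
#' @param times epoch time axis (s).
#' @param post_win,pre_win length-2 windows (s).
#' @return data.frame: condition, mean_post, mean_pre, t, df, p.
#' @export
gfp_window_contrast <- function(gfp_by_condition, times,
                                post_win = c(0.150, 0.350),
                                pre_win = c(-1.300, -1.100)) {
  ip <- .win_idx(times, post_win)
  ib <- .win_idx(times, pre_win)
  do.call(rbind, lapply(names(gfp_by_condition), function(cond) {
    g <- as.matrix(gfp_by_condition[[cond]])
    if (nrow(g) < 2) stop("need >= 2 subjects")
    post <- rowMeans(g[, ip, drop = FALSE])
    pre <- rowMeans(g[, ib, drop = FALSE])
    res <- paired_t(post, pre)
    data.frame(condition = cond, mean_post = mean(post), mean_pre = mean(pre),
               t = res$t, df = res$df, p = res$p, row.names = NULL)
  }))
}

# complex Morlet wavelet at frequency f (Hz): Gaussian envelope with
# sigma_t = n_cycles / (2 pi f), trimmed at +-2.5 sigma_t
.morlet_wavelet <- function(f, sfreq, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  t <- seq(-2.5 * sigma_t, 2.5 * sigma_t, by = 1 / sfreq)
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
  w / sqrt(sum(Mod(w)^2))
}

#' Morlet continuous wavelet transform log power of epochs
#'
#' Convolves every trial and channel with complex Morlet wavelets
#' (`n_cycles` cycles, default 6) and returns the base-10 logarithm of the
#' squared coefficient magnitude. Frequencies whose full wavelet support
#' (`n_cycles / f` seconds) exceeds the epoch length cannot be estimated
#' and are dropped with a warning (an error if none remain).
#'
#' @param epochs a `bro_epochs`, or a trials x channels x time array.
#' @param sfreq sampling rate (Hz); taken from `bro_epochs` input.
#' @param freqs frequencies of interest (Hz); default 0.5-6 Hz in 0.25 Hz
#'   steps (delta-centered analysis range).
#' @param n_cycles wavelet cycles; default 6.
#' @param channels optional channel subset (indices into the epoch's
#'   channel dimension); default all MEG channels.
#' @param keep_trials keep the per-trial dimension (memory-heavy); if
#'   `FALSE` (default) trials are averaged after the per-trial transform
#'   (and after per-trial baseline correction when `baseline` is given).
#' @param baseline optional length-2 baseline window (s) subtracted
#'   per-trial, per-channel, per-frequency (mean log power).
#' @param times optional epoch time axis (s) for array input.
#' @return object of class `bro_tfr`: `power` (trials x channels x freqs x
#'   time if `keep_trials`, else channels x freqs x time), `freqs`,
#'   `times`, `n_cycles`, `baseline`.
#' @export
morlet_tf <- function(epochs, sfreq = NULL, freqs = seq(0.5, 6, by = 0.25),
                      n_cycles = 6, channels = NULL, keep_trials = FALSE,
                      baseline = NULL, times = NULL) {
  if (n_cycles < 3) stop("n_cycles must be >= 3")
  if (inherits(epochs, "bro_epochs")) {
    sfreq <- epochs$sfreq
    times <- epochs$times
    if (is.null(channels)) channels <- which(epochs$types == "MEG")
    data <- epochs$data[, channels, , drop = FALSE]
  } else {
    if (is.null(sfreq)) stop("sfreq required for array input")
    data <- epochs
    if (!is.null(channels)) data <- data[, channels, , drop = FALSE]
    if (is.null(times)) times <- seq_len(dim(data)[3]) / sfreq
  }
  nt <- dim(data)[3]
  dur <- nt / sfreq
  ok <- n_cycles / freqs <= dur
  if (!any(ok)) stop("epoch shorter than the wavelet support at every requested frequency")
  if (any(!ok)) warning("dropping frequencies with wavelet support longer than the epoch: ",
                        paste(freqs[!ok], collapse = ", "), " Hz")
  freqs <- freqs[ok]
  if (any(freqs >= sfreq / 2)) stop("frequencies must lie below Nyquist")

  wavelets <- lapply(freqs, .morlet_wavelet, sfreq = sfreq, n_cycles = n_cycles)
  n_trial <- dim(data)[1]; n_chan <- dim(data)[2]; n_freq <- length(freqs)
  base_idx <- if (!is.null(baseline)) .win_idx(times, baseline) else NULL

  # one big FFT over all trial-channel signals; coefficient power near the
  # epoch edges is renormalized by the fraction of wavelet energy that
  # overlaps the epoch, so stationary signals keep flat expected power
  X <- aperm(data, c(3, 1, 2))                 # time x trial x chan
  dim(X) <- c(nt, n_trial * n_chan)
  m_max <- max(vapply(wavelets, length, 0L))
  nfft <- stats::nextn(nt + m_max - 1L, c(2, 3, 5))
  X <- rbind(X, matrix(0, nfft - nt, ncol(X)))
  XF <- stats::mvfft(X)

  out_trials <- if (keep_trials) array(0, c(n_trial, n_chan, n_freq, nt)) else NULL
  acc <- array(0, c(n_chan, n_freq, nt))
  for (fi in seq_len(n_freq)) {
    w <- wavelets[[fi]]
    m <- length(w)
    WF <- stats::fft(c(w, complex(real = numeric(nfft - m))))
    co <- stats::mvfft(XF * WF, inverse = TRUE) / nfft
    half <- (m - 1L) %/% 2L
    co <- co[(half + 1L):(half + nt), , drop = FALSE]
    # in-epoch wavelet energy at each coefficient center (edge correction)
    ones <- stats::fft(c(rep(1, nt), numeric(nfft - nt)))
    wsq <- stats::fft(c(Mod(w)^2, numeric(nfft - m)))
    e_in <- Re(stats::fft(ones * wsq, inverse = TRUE))[(half + 1L):(half + nt)] / nfft
    e_in <- pmax(e_in, .Machine$double.eps)    # total wavelet energy is 1
    lp <- log10(pmax(Mod(co)^2, .Machine$double.xmin)) - log10(e_in)
    if (!is.null(base_idx))
      lp <- lp - rep(colMeans(lp[base_idx, , drop = FALSE]), each = nt)
    dim(lp) <- c(nt, n_trial, n_chan)
    if (keep_trials) out_trials[, , fi, ] <- aperm(lp, c(2, 3, 1))
    acc[, fi, ] <- t(colSums(aperm(lp, c(2, 1, 3))) / n_trial)
  }
  structure(list(power = if (keep_trials) out_trials else acc,
                 average = acc,
                 freqs = freqs, times = times, n_cycles = n_cycles,
                 baseline = baseline, keep_trials = keep_trials),
            class = "bro_tfr")
}

#' @export
print.bro_tfr <- function(x, ...) {
  cat(sprintf("<bro_tfr> %s, %d frequencies (%.2f-%.2f Hz), %d time points%s\n",
              if (x$keep_trials) "per-trial" else "trial-averaged",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              if (is.null(x$baseline)) "" else sprintf(", baseline (%g, %g) s",
                                                       x$baseline[1], x$baseline[2])))
  invisible(x)
}

#' Baseline-correct a time-frequency representation
#'
#' Subtracts the mean log power over `base_win` from every trial, channel,
#' and frequency (or from the average, for trial-averaged input).
#'
#' @param tf a `bro_tfr`.
#' @param base_win length-2 window (s); default -1500 to -500 ms.
#' @return the corrected `bro_tfr`.
#' @export
baseline_correct <- function(tf, base_win = c(-1.5, -0.5)) {
  idx <- .win_idx(tf$times, base_win)
  if (tf$keep_trials) {
    dm <- dim(tf$power)
    for (tr in seq_len(dm[1])) for (ch in seq_len(dm[2])) for (fi in seq_len(dm[3])) {
      tf$power[tr, ch, fi, ] <- tf$power[tr, ch, fi, ] -
        mean(tf$power[tr, ch, fi, idx])
    }
    tf$average <- apply(tf$power, c(2, 3, 4), mean)
  } else {
    dm <- dim(tf$power)
    for (ch in seq_len(dm[1])) for (fi in seq_len(dm[2])) {
      tf$power[ch, fi, ] <- tf$power[ch, fi, ] - mean(tf$power[ch, fi, idx])
      }
    tf$average <- tf$power
  }
  tf$baseline <- base_win
  tf
}

#' Mean band power of a TFR in a time window
#'
#' @param tf a trial-averaged `bro_tfr`.
#' @param win length-2 time window (s).
#' @param band length-2 frequency band (Hz); default delta 0.5-4 Hz
#'   (intersected with the frequencies present).
#' @return scalar mean log power over channels, band frequencies, window.
#' @export
tf_band_power <- function(tf, win, band = c(0.5, 4)) {
  it <- .win_idx(tf$times, win)
  fi <- which(tf$freqs >= band[1] - 1e-9 & tf$freqs <= band[2] + 1e-9)
  if (!length(fi)) stop("no frequencies inside the requested band")
  avg <- if (tf$keep_trials) tf$average else tf$power
  mean(avg[, fi, it])
}

#' Spectral permutation test of post- vs pre-interval band power
#'
#' Group statistic: mean over subjects of (post - pre) band power. The null
#' is built by randomly swapping each subject's pre/post labels (paired
#' sign flips); the p-value is the one-sided fraction of null statistics at
#' least as large as observed (post > pre; set `alternative = "two.sided"`
#' to compare magnitudes).
#'
#' @param pre,post per-subject band power values (same length, >= 4).
#' @param n_perm permutations; default 1000.
#' @param seed integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return list with `stat` (observed mean difference), `p`, `null`.
#' @export
spectral_permutation <- function(pre, post, n_perm = 1000, seed = 1L,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(pre) == length(post))
  n <- length(pre)
  if (n < 4) stop("need at least 4 subjects")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")
  d <- post - pre
  obs <- mean(d)
  flips <- .substream_eval(seed, 11L,
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
  null <- as.numeric(flips %*% d) / n
  p <- if (alternative == "greater") (1 + sum(null >= obs)) / (n_perm + 1)
       else (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  list(stat = obs, p = p, null = null)
}

#' @rdname spectral_permutation
#' @export
spectral_bootstrap <- spectral_permutation
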