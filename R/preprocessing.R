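# Epoching, ICA-based ocular artifact removal, and the blink-to-baseline
# power-ratio statistics that validate the removal.

.extract_epochs <- function(data, centers, half_len) {
  n_samp <- ncol(data)
  ok <- centers - half_len >= 1 & centers + half_len <= n_samp
  centers <- centers[ok]
  ep <- array(0, c(length(centers), nrow(data), 2 * half_len + 1))
  for (k in seq_along(centers)) {
    ep[k, , ] <- data[, (centers[k] - half_len):(centers[k] + half_len)]
  }
  list(epochs = ep, n_dropped = sum(!ok), centers = centers)
}

#' Segment blink-locked epochs
#'
#' Extracts 3-second trials centered on each blink maximum T0 (time axis
#' -1.5 ... +1.5 s, 0 at T0). Events within 1.5 s of a recording edge are
#' dropped and counted.
#'
#' @param recording a `bro_recording`.
#' @param events a `bro_events` (or integer vector of T0 samples).
#' @param half_width epoch half width (s); default 1.5.
#' @return object of class `bro_epochs`: `data` (trials x channels x time),
#'   `times` (s), `condition = "blink"`, `sfreq`, `types`, `n_dropped`.
#' @export
epoch_blink <- function(recording, events, half_width = 1.5) {
  t0 <- if (inherits(events, "bro_events")) events$t0_samples else as.integer(events)
  half_len <- round(half_width * recording$sfreq)
  ex <- .extract_epochs(recording$data, t0, half_len)
  structure(list(data = ex$epochs,
                 times = seq(-half_len, half_len) / recording$sfreq,
                 condition = "blink", sfreq = recording$sfreq,
                 types = recording$types, n_dropped = ex$n_dropped,
                 centers = ex$centers),
            class = "bro_epochs")
}

#' Segment control epochs (pseudo-random with respect to blinks)
#'
#' Extracts `n_trials` consecutive non-overlapping 3-second epochs forming a
#' contiguous block centered on the middle of the recording. Epoch zeros are
#' thereby pseudo-random in timing with respect to blink maxima; the trial
#' count is matched to the blink condition.
#'
#' @param recording a `bro_recording`.
#' @param n_trials number of control trials (match the blink epoch count).
#' @param half_width epoch half width (s); default 1.5.
#' @return `bro_epochs` with `condition = "control"`.
#' @export
epoch_control <- function(recording, n_trials, half_width = 1.5) {
  half_len <- round(half_width * recording$sfreq)
  len <- 2 * half_len + 1
  n_samp <- ncol(recording$data)
  need <- n_trials * len
  if (need > n_samp) stop("recording too short for ", n_trials, " control epochs")
  start <- floor((n_samp - need) / 2)
  centers <- start + half_len + 1L + (seq_len(n_trials) - 1L) * len
  ex <- .extract_epochs(recording$data, centers, half_len)
  structure(list(data = ex$epochs,
                 times = seq(-half_len, half_len) / recording$sfreq,
                 condition = "control", sfreq = recording$sfreq,
                 types = recording$types, n_dropped = ex$n_dropped,
                 centers = ex$centers),
            class = "bro_epochs")
}

#' @export
print.bro_epochs <- function(x, ...) {
  cat(sprintf("<bro_epochs> %s condition: %d trials x %d channels x %d samples (%.1f ... %.1f s)\n",
              x$condition, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Trial-averaged event-related field
#'
#' @param epochs a `bro_epochs`.
#' @param channels channel indices; default all MEG channels.
#' @return channels x time matrix with the epoch time axis as attribute.
#' @export
average_epochs <- function(epochs, channels = NULL) {
  d <- epochs$data
  if (is.null(channels)) channels <- which(epochs$types == "MEG")
  erf <- apply(d[, channels, , drop = FALSE], c(2, 3), mean)
  attr(erf, "times") <- epochs$times
  erf
}

#' FastICA unmixing of MEG channels
#'
#' Decomposes the MEG rows into statistically independent components
#' (FastICA with tanh contrast after PCA whitening), with a seeded random
#' orthonormal initialization so results are reproducible. Components are
#' canonicalized deterministically: ordered by decreasing explained
#' variance, source rows scaled to unit variance, sign fixed so the
#' largest-magnitude mixing weight is positive. Rank-deficient data lead to
#' a reduced component count with a warning.
#'
#' @param x MEG channels x samples matrix, or a `bro_recording` (its MEG
#'   rows are used).
#' @param n_components number of components; default `min(n_chan, 30)`.
#' @param seed integer seed for the initialization.
#' @param maxit,tol FastICA iteration controls.
#' @param max_fit_samples the unmixing matrix is estimated on an evenly
#'   strided time subsample of at most this many samples (the mixing is
#'   instantaneous, so any time subset identifies it); sources are then
#'   derived on the full data. `Inf` fits on everything.
#' @return object of class `bro_ica`: `mixing` (n_chan x k), `sources`
#'   (k x n_samp, unit variance), `row_means`, `n_components`.
#' @export
run_ica <- function(x, n_components = NULL, seed = 1L, maxit = 200, tol = 1e-6,
                    max_fit_samples = 20000) {
  if (inherits(x, "bro_recording")) x <- meg_data(x)
  n_chan <- nrow(x)
  if (is.null(n_components)) n_components <- min(n_chan, 30L)
  if (n_components > n_chan) stop("n_components exceeds channel count")
  rm_ <- rowMeans(x)
  xc <- x - rm_
  ev <- eigen(tcrossprod(xc) / ncol(xc), symmetric = TRUE)
  pos <- ev$values > max(ev$values) * 1e-10
  if (sum(pos) < n_components) {
    warning("rank-deficient data: reducing components to ", sum(pos))
    n_components <- sum(pos)
  }
  R0 <- .substream_eval(seed, 8L, {
    M <- matrix(stats::rnorm(n_components^2), n_components)
    qr.Q(qr(M))
  })
  fit_idx <- if (ncol(xc) > max_fit_samples)
    unique(round(seq(1, ncol(xc), length.out = max_fit_samples))) else seq_len(ncol(xc))
  fit <- ica::icafast(t(xc[, fit_idx, drop = FALSE]), nc = n_components,
                      center = FALSE, maxit = maxit, tol = tol,
                      Rmat = R0, alg = "par")
  A <- fit$M                       # n_chan x k mixing
  S <- solve(crossprod(A), crossprod(A, xc))   # least-squares sources, k x n_samp
  # canonicalize: unit-variance sources, variance-ordered, positive max weight
  sdv <- apply(S, 1, stats::sd)
  S <- S / sdv
  A <- A * rep(sdv, each = nrow(A))
  ord <- order(colSums(A^2), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]; A <- A[, ord, drop = FALSE]
  sgn <- vapply(seq_len(ncol(A)), function(j) {
    w <- A[which.max(abs(A[, j])), j]; if (w < 0) -1 else 1
  }, 0)
  A <- A * rep(sgn, each = nrow(A))
  S <- S * sgn
  structure(list(mixing = A, sources = S, row_means = rm_,
                 n_components = n_components),
            class = "bro_ica")
}

#' @export
print.bro_ica <- function(x, ...) {
  cat(sprintf("<bro_ica> %d components over %d channels\n",
              x$n_components, nrow(x$mixing)))
  invisible(x)
}

#' Flag independent components correlated with the vEOG
#'
#' Components whose absolute Pearson correlation with the (blink-band
#' filtered) vEOG reaches `corr_thresh` are flagged as ocular. An empty
#' result is allowed.
#'
#' @param ica a `bro_ica`.
#' @param veog time-aligned vEOG trace (filter to 0.1-30 Hz upstream).
#' @param corr_thresh absolute correlation threshold; default 0.8.
#' @return integer vector of flagged component indices (ordered by
#'   decreasing |r|), with the correlations as attribute `r`.
#' @export
identify_ocular_components <- function(ica, veog, corr_thresh = 0.8) {
  r <- as.numeric(stats::cor(t(ica$sources), veog))
  flagged <- which(abs(r) >= corr_thresh)
  flagged <- flagged[order(abs(r[flagged]), decreasing = TRUE)]
  attr(flagged, "r") <- r
  flagged
}

#' Reconstruct data with flagged components removed
#'
#' With the original `data` supplied, subtracts the flagged components'
#' contribution from it (`X - A_f S_f`), which keeps everything outside the
#' ICA subspace untouched; this is exact for `flagged = NULL`. Without
#' `data`, reconstructs from the non-flagged components alone (equivalent
#' when the decomposition has full channel rank).
#'
#' @param ica a `bro_ica`.
#' @param flagged integer indices of components to remove; empty removes
#'   nothing.
#' @param data optional original channels x samples matrix the ICA was run
#'   on.
#' @return cleaned channels x samples matrix.
#' @export
remove_components <- function(ica, flagged, data = NULL) {
  k <- ica$n_components
  flagged <- as.integer(flagged)
  if (length(flagged) >= k) stop("cannot remove all components")
  if (!is.null(data)) {
    if (!length(flagged)) return(data)
    return(data - ica$mixing[, flagged, drop = FALSE] %*%
             ica$sources[flagged, , drop = FALSE])
  }
  keep <- setdiff(seq_len(k), flagged)
  ica$mixing[, keep, drop = FALSE] %*% ica$sources[keep, , drop = FALSE] +
    ica$row_means
}

#' Remove ocular components from a recording
#'
#' Convenience wrapper: runs ICA on the MEG rows, flags components against
#' the blink-band-filtered vEOG, reconstructs without them, and returns the
#' cleaned recording.
#'
#' @param recording a `bro_recording` (band-pass filter it first).
#' @param n_components,seed,corr_thresh passed to [run_ica()] and
#'   [identify_ocular_components()].
#' @param max_fit_samples,maxit passed to [run_ica()].
#' @return the recording with cleaned MEG rows; attributes
#'   `n_removed` and `flagged` record what was removed.
#' @export
clean_ocular <- function(recording, n_components = NULL, seed = 1L,
                         corr_thresh = 0.8, max_fit_samples = 20000,
                         maxit = 200) {
  veog_f <- bandpass(veog_data(recording), 0.1, 30, recording$sfreq)
  meg <- meg_data(recording)
  ic <- run_ica(meg, n_components = n_components, seed = seed,
                max_fit_samples = max_fit_samples, maxit = maxit)
  flagged <- identify_ocular_components(ic, veog_f, corr_thresh)
  if (length(flagged)) {
    recording$data[recording$types == "MEG", ] <-
      remove_components(ic, flagged, data = meg)
  }
  attr(recording, "flagged") <- flagged
  attr(recording, "n_removed") <- length(flagged)
  recording
}

#' Blink-to-baseline power ratio for one channel region
#'
#' Ratio of the demeaned across-channel squared deviations of the
#' trial-averaged ERF at the blink latency versus a pre-blink baseline
#' latency: `sum_i (y_i - mean(y))^2 / sum_i (x_i - mean(x))^2`, where
#' `y_i`/`x_i` are the ERF values of the region's channels at `t_blink`
#' (default 0 ms) and `t_base` (default -1000 ms). Values above 1 indicate
#' extra blink-locked signal relative to baseline. Invariant to adding a
#' channel-common constant at either latency.
#'
#' @param erf region channels x time matrix of the trial-averaged ERF.
#' @param times epoch time axis (s).
#' @param t_blink,t_base latencies to compare (s).
#' @return the power ratio (positive scalar).
#' @export
power_ratio <- function(erf, times, t_blink = 0, t_base = -1) {
  if (nrow(erf) < 2) stop("region needs at least 2 channels")
  if (t_blink < min(times) - 1e-9 || t_blink > max(times) + 1e-9)
    stop("t_blink outside the epoch")
  if (t_base < min(times) - 1e-9 || t_base > max(times) + 1e-9)
    stop("t_base outside the epoch")
  iy <- which.min(abs(times - t_blink))
  ix <- which.min(abs(times - t_base))
  y <- erf[, iy]; x <- erf[, ix]
  den <- sum((x - mean(x))^2)
  if (den == 0) stop("zero baseline variance across channels: power ratio undefined")
  sum((y - mean(y))^2) / den
}

#' Regional power-ratio table for one subject
#'
#' @param erf full MEG ERF (channels x time).
#' @param regions factor of region labels per channel.
#' @param times epoch time axis (s).
#' @param t_blink,t_base latencies (s).
#' @return data.frame with columns region, ratio.
#' @export
regional_power_ratios <- function(erf, regions, times, t_blink = 0, t_base = -1) {
  lev <- levels(regions)
  data.frame(region = lev,
             ratio = vapply(lev, function(rg) {
               power_ratio(erf[regions == rg, , drop = FALSE], times, t_blink, t_base)
             }, 0),
             row.names = NULL)
}

#' Compare power ratios before and after artifact removal
#'
#' Paired t-tests (pre- vs post-ICA) per region with Bonferroni correction
#' across the five regions, plus a one-way repeated-measures ANOVA across
#' regions within each stage.
#'
#' @param table data.frame with columns `subject`, `region`, `stage`
#'   (`"pre"`/`"post"`), `ratio` (one condition at a time).
#' @return list with `t_tests` (data.frame: region, t, df, p, p_bonf) and
#'   `anova` (data.frame: stage, F, df1, df2, p).
#' @export
compare_power_ratios <- function(table) {
  stopifnot(all(c("subject", "region", "stage", "ratio") %in% names(table)))
  regions <- unique(as.character(table$region))
  n_regions <- length(regions)
  tt <- do.call(rbind, lapply(regions, function(rg) {
    pre <- table$ratio[table$region == rg & table$stage == "pre"]
    post <- table$ratio[table$region == rg & table$stage == "post"]
    pre <- pre[order(table$subject[table$region == rg & table$stage == "pre"])]
    post <- post[order(table$subject[table$region == rg & table$stage == "post"])]
    if (length(pre) < 2) stop("need >= 2 subjects")
    res <- paired_t(pre, post)
    data.frame(region = rg, t = res$t, df = res$df, p = res$p,
               p_bonf = min(1, n_regions * res$p))
  }))
  an <- do.call(rbind, lapply(unique(as.character(table$stage)), function(st) {
    d <- table[table$stage == st, ]
    d$subject <- factor(d$subject); d$region <- factor(d$region)
    fit <- stats::aov(ratio ~ region + Error(subject), data = d)
    s <- summary(fit)[["Error: Within"]][[1]]
    data.frame(stage = st, F = s["region", "F value"],
               df1 = s["region", "Df"], df2 = s["Residuals", "Df"],
               p = s["region", "Pr(>F)"])
  }))
  list(t_tests = tt, anova = an)
}
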