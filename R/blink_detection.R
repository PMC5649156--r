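# Template-matching blink detection on the vEOG channel, morphology
# features, normalized averaging, and split-half reliability.

#' Detect blinks in a vEOG trace by template matching
#'
#' Slides a normalized (Pearson) correlation between the trace and a blink
#' template. Correlation local maxima above `match_thresh` become
#' candidates; candidates within one template length are collapsed to the
#' best match; candidates whose windowed vEOG peak falls below
#' `amp_frac` times the template peak are dropped; then any two surviving
#' events closer than `min_gap` seconds are both removed (each is too close
#' to an adjacent blink). The blink maximum T0 is the vEOG maximum inside
#' the matched window.
#'
#' The match statistic is scale- and offset-invariant, so detection is
#' unchanged when trace and template are multiplied by a common positive
#' constant, and shifting the trace shifts all T0 accordingly.
#'
#' @param veog numeric vEOG trace (uV).
#' @param sfreq sampling rate (Hz).
#' @param template blink template trace (uV); default is the canonical
#'   [blink_waveform()] with default [blink_params()]. A
#'   `bro_blink_template` object is also accepted.
#' @param match_thresh correlation threshold in (0, 1).
#' @param amp_frac amplitude threshold as a fraction of the template peak.
#' @param min_gap temporal exclusion threshold (s); default 3.
#' @return object of class `bro_events`: list with `t0_samples` (sorted,
#'   1-based), `scores` (match correlation per event), `sfreq`, and
#'   `n_excluded_close` (events removed by the temporal rule).
#' @export
detect_blinks <- function(veog, sfreq, template = NULL, match_thresh = 0.7,
                          amp_frac = 0.5, min_gap = 3) {
  if (!length(veog)) stop("invalid input: empty vEOG trace")
  if (is.null(template)) template <- blink_waveform(blink_params(), sfreq)
  if (inherits(template, "bro_blink_template")) template <- template$trace
  if (stats::sd(template) == 0) stop("invalid input: flat template (zero variance)")
  if (!(match_thresh > 0 && match_thresh < 1)) stop("match_thresh must be in (0, 1)")
  m <- length(template)
  n <- length(veog)
  if (m >= n) stop("invalid input: template must be shorter than the trace")

  tc <- template - mean(template)
  denom_t <- sqrt(sum(tc^2))
  # sliding covariance via FFT cross-correlation
  num <- .sliding_dot(veog, tc)                        # length n - m + 1
  s1 <- .rolling_sum(veog, m)
  s2 <- .rolling_sum(veog^2, m)
  win_ss <- pmax(s2 - s1^2 / m, 0)
  r <- num / (sqrt(win_ss) * denom_t)
  r[!is.finite(r)] <- 0

  nw <- length(r)
  cand <- which(r > match_thresh)
  cand <- cand[cand > 1 & cand < nw]
  cand <- cand[r[cand] >= r[cand - 1] & r[cand] >= r[cand + 1]]
  if (length(cand) > 1) {                              # collapse within one template length
    keep <- logical(length(cand))
    for (i in order(r[cand], decreasing = TRUE)) {
      if (!any(keep & abs(cand - cand[i]) < m)) keep[i] <- TRUE
    }
    cand <- sort(cand[keep])
  }

  if (length(cand)) {
    peak_ok <- vapply(cand, function(i) max(veog[i:(i + m - 1)]), 0) >=
      amp_frac * max(template)
    cand <- cand[peak_ok]
  }

  t0 <- vapply(cand, function(i) i - 1L + which.max(veog[i:(i + m - 1)]), 0L)
  scores <- r[cand]
  o <- order(t0)
  t0 <- t0[o]; scores <- scores[o]
  dup <- duplicated(t0)
  t0 <- t0[!dup]; scores <- scores[!dup]

  n_excl <- 0L
  if (length(t0) > 1) {
    gaps <- diff(t0) / sfreq
    close_pair <- gaps < min_gap
    bad <- logical(length(t0))
    bad[which(close_pair)] <- TRUE
    bad[which(close_pair) + 1L] <- TRUE
    n_excl <- sum(bad)
    t0 <- t0[!bad]; scores <- scores[!bad]
  }

  structure(list(t0_samples = as.integer(t0), scores = scores, sfreq = sfreq,
                 n_excluded_close = n_excl),
            class = "bro_events")
}

#' @export
print.bro_events <- function(x, ...) {
  cat(sprintf("<bro_events> %d blinks (%d removed by %s)\n",
              length(x$t0_samples), x$n_excluded_close, "temporal exclusion"))
  invisible(x)
}

.sliding_dot <- function(x, tc) {
  n <- length(x); m <- length(tc)
  nfft <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  TT <- stats::fft(c(rev(tc), numeric(nfft - m)))
  full <- Re(stats::fft(X * TT, inverse = TRUE)) / nfft
  full[m:(n)]                                          # starts 1..n-m+1
}

.rolling_sum <- function(x, m) {
  cs <- cumsum(c(0, x))
  cs[(m + 1):length(cs)] - cs[1:(length(cs) - m)]
}

#' Extract blink morphology features M1-M4
#'
#' From a blink-locked trace whose positive maximum marks the blink maximum
#' T0: M1 is the positive peak amplitude; M2 the width of the positive lobe
#' between its surrounding zero crossings (sub-sample, linearly
#' interpolated); M3 the most negative value after the positive lobe; M4
#' the latency of that trough relative to T0. Features whose defining zero
#' crossing does not exist are returned as `NA` with the `undefined`
#' attribute naming them.
#'
#' @param trace blink-locked vEOG trace (uV).
#' @param sfreq sampling rate (Hz).
#' @param t0_index index of the blink maximum; defaults to the global
#'   maximum of the trace.
#' @return list of class `bro_morphology` with `M1` (uV), `M2` (s),
#'   `M3` (uV), `M4` (s).
#' @export
extract_morphology <- function(trace, sfreq, t0_index = which.max(trace)) {
  n <- length(trace)
  M1 <- trace[t0_index]
  if (!is.finite(M1) || M1 <= 0) stop("invalid input: no positive peak at t0_index")
  undefined <- character(0)

  left <- which(trace[seq_len(t0_index - 1)] <= 0)
  right <- which(trace[(t0_index + 1):n] <= 0) + t0_index
  if (!length(left) || !length(right)) {
    M2 <- NA_real_
    undefined <- c(undefined, "M2")
    zc_r <- if (length(right)) min(right) else NA_integer_
  } else {
    il <- max(left); ir <- min(right)
    # sub-sample crossings by linear interpolation on the flanking samples
    xl <- il + trace[il] / (trace[il] - trace[il + 1])
    xr <- (ir - 1) + trace[ir - 1] / (trace[ir - 1] - trace[ir])
    M2 <- (xr - xl) / sfreq
    zc_r <- ir
  }

  if (!is.na(zc_r) && zc_r < n) {
    post <- trace[zc_r:n]
    M3 <- min(post)
    M4 <- (zc_r + which.min(post) - 1 - t0_index) / sfreq
    if (M3 >= 0) { M3 <- NA_real_; M4 <- NA_real_; undefined <- c(undefined, "M3", "M4") }
  } else {
    M3 <- NA_real_; M4 <- NA_real_
    undefined <- c(undefined, "M3", "M4")
  }
  structure(list(M1 = M1, M2 = M2, M3 = M3, M4 = M4),
            class = "bro_morphology", undefined = undefined)
}

#' @export
print.bro_morphology <- function(x, ...) {
  cat(sprintf("<bro_morphology> M1 = %.2f uV, M2 = %.3f s, M3 = %.2f uV, M4 = %.3f s\n",
              x$M1, x$M2, x$M3, x$M4))
  invisible(x)
}

#' Per-subject normalized blink averages and grand average
#'
#' Averages each subject's blink epochs, normalizes the average by its own
#' maximum (removing between-subject amplitude scale), and averages the
#' normalized traces across subjects. The grand-average peak is therefore
#' at most 1.
#'
#' @param epochs_by_subject list; each element is a trials x time matrix of
#'   blink-locked vEOG epochs for one subject.
#' @return list with `subject_averages` (subjects x time, normalized) and
#'   `grand_average`.
#' @export
normalized_average <- function(epochs_by_subject) {
  stopifnot(length(epochs_by_subject) >= 1)
  norm <- t(vapply(epochs_by_subject, function(ep) {
    avg <- colMeans(ep)
    mx <- max(avg)
    if (mx <= 0) stop("zero-amplitude subject average")
    avg / mx
  }, numeric(ncol(epochs_by_subject[[1]]))))
  list(subject_averages = norm, grand_average = colMeans(norm))
}

#' Split-half reliability of per-subject features
#'
#' Repeatedly splits subjects at random into two equal halves, sorts the
#' feature values within each half, and correlates the sorted vectors
#' (Pearson). With an odd number of subjects one subject is dropped at
#' random in each repetition. Repetitions where either half is constant
#' (undefined correlation) are excluded from the mean and counted.
#'
#' @param values subjects x features numeric matrix (or data.frame).
#' @param n_reps number of random splits; default 1000.
#' @param seed integer seed.
#' @param consistency_thresh mean-correlation criterion for flagging the
#'   feature set as consistent across subjects; default 0.8.
#' @return list with `mean_rho` (named per feature), `n_dropped` (skipped
#'   repetitions per feature), and `consistent` (all mean rho above
#'   threshold).
#' @export
split_half_reliability <- function(values, n_reps = 1000, seed = 1L,
                                   consistency_thresh = 0.8) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 4) stop("need at least 4 subjects")
  h <- n %/% 2
  nf <- ncol(values)
  sums <- numeric(nf); counts <- integer(nf)
  .with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      perm <- sample.int(n)
      g1 <- perm[seq_len(h)]; g2 <- perm[(h + 1):(2 * h)]
      for (j in seq_len(nf)) {
        a <- sort(values[g1, j]); b <- sort(values[g2, j])
        if (stats::sd(a) == 0 || stats::sd(b) == 0) next
        sums[j] <- sums[j] + stats::cor(a, b)
        counts[j] <- counts[j] + 1L
      }
    }
  })
  mean_rho <- ifelse(counts > 0, sums / counts, NA_real_)
  names(mean_rho) <- colnames(values)
  list(mean_rho = mean_rho, n_dropped = n_reps - counts,
       consistent = all(mean_rho > consistency_thresh, na.rm = FALSE))
}
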