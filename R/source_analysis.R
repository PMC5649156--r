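# Source-space analysis: regularized minimum-norm inversion, delta-band
# post-vs-pre contrast images with max-statistic permutation FWE control,
# and virtual-electrode (VOI) time courses.

#' Minimum-norm inverse operator
#'
#' Tikhonov-regularized minimum-norm kernel `M = G' (G G' + lambda I)^-1`
#' for a gradiometer lead field. With `lambda = 0` and a rank-deficient
#' Gram matrix, a pseudo-inverse is used with a warning.
#'
#' @param leadfield a `bro_leadfield`.
#' @param lambda regularization (units of the Gram matrix, T^2); `NULL`
#'   sets `lambda = lambda_rel * mean(diag(G G'))`.
#' @param lambda_rel relative regularization used when `lambda` is `NULL`;
#'   default 0.01.
#' @return (2 n_src) x n_chan kernel matrix.
#' @export
mn_operator <- function(leadfield, lambda = NULL, lambda_rel = 0.01) {
  G <- leadfield$gain
  gram <- tcrossprod(G)
  if (is.null(lambda)) lambda <- lambda_rel * mean(diag(gram))
  if (lambda < 0) stop("lambda must be >= 0")
  A <- gram + diag(lambda, nrow(gram))
  ev <- eigen(A, symmetric = TRUE)
  tolv <- max(ev$values) * 1e-12
  if (any(ev$values < tolv)) {
    warning("rank-deficient sensor Gram matrix: using pseudo-inverse")
    inv_vals <- ifelse(ev$values > tolv, 1 / ev$values, 0)
  } else inv_vals <- 1 / ev$values
  Ainv <- ev$vectors %*% (inv_vals * t(ev$vectors))
  crossprod(G, Ainv)
}

#' Discrepancy-principle regularization from a baseline window
#'
#' Chooses `lambda` so the residual power of the minimum-norm fit to `data`
#' matches the sensor noise power estimated from a pre-blink baseline
#' segment (bisection on log lambda via the SVD filter factors).
#'
#' @param data channels x time matrix to be inverted.
#' @param leadfield a `bro_leadfield`.
#' @param baseline_data channels x time matrix of baseline-only activity
#'   whose variance estimates the noise floor.
#' @return positive scalar lambda.
#' @export
estimate_lambda <- function(data, leadfield, baseline_data) {
  sv <- svd(leadfield$gain, nu = nrow(data), nv = 0)
  d2 <- sv$d^2
  U <- sv$u
  target <- sum(baseline_data^2) / ncol(baseline_data) * ncol(data)
  proj <- crossprod(U, data)            # n_chan x n_time (coordinates in U)
  resid_for <- function(lam) {
    f <- lam / (d2 + lam)               # residual filter factors
    sum((f^2) * rowSums(proj^2))
  }
  lo <- 1e-8 * max(d2); hi <- 1e4 * max(d2)
  if (resid_for(lo) > target) return(lo)
  for (i in 1:80) {
    mid <- sqrt(lo * hi)
    if (resid_for(mid) < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Minimum-norm source estimate
#'
#' Applies the regularized minimum-norm kernel to sensor data: among all
#' source configurations reproducing the data (as `lambda` tends to 0),
#' the one with the smallest L2 norm. Estimates are linear in the data and
#' contain only the two tangential orientations per grid point (radial
#' sources are silent in a spherical conductor).
#'
#' @param data channels x time matrix (T).
#' @param leadfield a `bro_leadfield` consistent with the data rows.
#' @param lambda,lambda_rel see [mn_operator()].
#' @return object of class `bro_source_estimate`: `moments`
#'   ((2 n_src) x n_time, A*m), `grid`, `lambda`.
#' @export
minimum_norm <- function(data, leadfield, lambda = NULL, lambda_rel = 0.01) {
  data <- as.matrix(data)
  if (nrow(data) != nrow(leadfield$gain))
    stop("data channel count does not match the lead field")
  gram_scale <- mean(diag(tcrossprod(leadfield$gain)))
  if (is.null(lambda)) lambda <- lambda_rel * gram_scale
  M <- mn_operator(leadfield, lambda = lambda)
  structure(list(moments = M %*% data, grid = leadfield$grid, lambda = lambda),
            class = "bro_source_estimate")
}

#' @export
print.bro_source_estimate <- function(x, ...) {
  cat(sprintf("<bro_source_estimate> %d source points x 2 orientations x %d samples (lambda = %.3g)\n",
              nrow(x$grid$coords), ncol(x$moments), x$lambda))
  invisible(x)
}

# per-point power time series: sum of squared moments over both orientations
.source_power <- function(moments) {
  n_src <- nrow(moments) / 2
  moments[2 * seq_len(n_src) - 1, , drop = FALSE]^2 +
    moments[2 * seq_len(n_src), , drop = FALSE]^2
}

#' Gaussian smoothing kernel on the source shell
#'
#' Pairwise Euclidean-distance Gaussian weights between grid points with
#' `sigma = fwhm / 2.355`, column-normalized so each point distributes unit
#' mass: smoothing preserves the total image mass.
#'
#' @param grid a `bro_source_grid`.
#' @param fwhm kernel full-width at half-maximum (m); default 8 mm.
#' @return n_src x n_src smoothing matrix.
#' @export
smoothing_kernel <- function(grid, fwhm = 0.008) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  cc <- grid$coords
  d2 <- outer(rowSums(cc^2), rowSums(cc^2), "+") - 2 * tcrossprod(cc)
  W <- exp(-pmax(d2, 0) / (2 * sigma^2))
  sweep(W, 2, colSums(W), "/")
}

#' Per-subject source contrast image (post vs pre window band power)
#'
#' Band-filters the source moment time courses (delta by default), forms
#' per-point power (summed over the two orientations), takes the mean over
#' the post window minus the mean over the pre window, and smooths the
#' resulting image on the shell with a Gaussian kernel (8 mm FWHM default).
#'
#' @param est a `bro_source_estimate` from trial-averaged data.
#' @param times epoch time axis (s) matching the estimate's columns.
#' @param sfreq sampling rate (Hz).
#' @param post_win,pre_win length-2 windows (s).
#' @param band length-2 frequency band (Hz); `NULL` skips filtering.
#' @param fwhm smoothing kernel FWHM (m); 0 skips smoothing.
#' @param kernel optional precomputed [smoothing_kernel()].
#' @return numeric vector (n_src) contrast image.
#' @export
source_contrast <- function(est, times, sfreq, post_win = c(0.150, 0.350),
                            pre_win = c(-1.300, -1.100), band = c(0.5, 4),
                            fwhm = 0.008, kernel = NULL) {
  mom <- est$moments
  if (!is.null(band)) mom <- bandpass(mom, band[1], band[2], sfreq)
  pw <- .source_power(mom)
  ip <- .win_idx(times, post_win)
  ib <- .win_idx(times, pre_win)
  img <- rowMeans(pw[, ip, drop = FALSE]) - rowMeans(pw[, ib, drop = FALSE])
  if (fwhm > 0) {
    if (is.null(kernel)) kernel <- smoothing_kernel(est$grid, fwhm)
    img <- as.numeric(kernel %*% img)
  }
  img
}

#' Group familywise-error-corrected T map by max-statistic permutation
#'
#' One-sample T per voxel across subject contrast images (optionally after
#' regressing out a centered covariate such as the per-subject blink
#' count). The null distribution of the maximum absolute T over voxels is
#' built by random sign flips of whole subject images (exhaustive
#' enumeration when `2^n_subjects <= n_perm`); the FWE-corrected p-value of
#' a voxel is the fraction of permutations whose max |T| reaches that
#' voxel's observed (signed) T, so only the tested direction can reach
#' significance.
#'
#' @param images subjects x voxels matrix of contrast images.
#' @param n_perm permutations; default 1000.
#' @param seed integer seed.
#' @param covariate optional per-subject covariate (e.g. blink count).
#' @param alpha familywise significance level; default 0.05.
#' @return object of class `bro_fwe_result`: `t` (voxel T values), `p_fwe`,
#'   `null_max`, `significant` (logical at `alpha`), `alpha`.
#' @export
group_fwe <- function(images, n_perm = 1000, seed = 1L, covariate = NULL,
                      alpha = 0.05) {
  images <- as.matrix(images)
  n <- nrow(images)
  if (n < 6) stop("need at least 6 subjects for a meaningful permutation null")
  if (!is.null(covariate)) {
    cc <- covariate - mean(covariate)
    if (sum(cc^2) > 0) {
      beta <- crossprod(cc, images) / sum(cc^2)
      images <- images - tcrossprod(cc, as.numeric(beta))
    }
  }
  if (2^n <= n_perm) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_perm <- nrow(flips)
  } else {
    flips <- .substream_eval(seed, 12L,
      matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
  }
  t_obs <- .flip_t(images, matrix(1, 1, n))[1, ]
  t_perm <- .flip_t(images, flips)
  null_max <- apply(abs(t_perm), 1, max)
  p_fwe <- vapply(t_obs, function(tv) (1 + sum(null_max >= tv)) / (n_perm + 1), 0)
  structure(list(t = t_obs, p_fwe = p_fwe, null_max = null_max,
                 significant = p_fwe < alpha, alpha = alpha, n_perm = n_perm),
            class = "bro_fwe_result")
}

#' @export
print.bro_fwe_result <- function(x, ...) {
  cat(sprintf("<bro_fwe_result> %d / %d voxels significant at FWE alpha = %.2f (%d permutations)\n",
              sum(x$significant), length(x$t), x$alpha, x$n_perm))
  invisible(x)
}

#' Virtual-electrode time course from a spherical VOI
#'
#' Restricts the minimum-norm kernel to the grid points of a spherical
#' volume of interest, fixes one orientation (the first principal direction
#' of the VOI moments of the trial-averaged data, sign chosen so the
#' largest post-window deflection of the trial average is positive), and
#' returns the per-trial projected time courses, band-filtered and their
#' trial average.
#'
#' @param epochs trials x channels x time array of MEG epochs (or a
#'   `bro_epochs`, whose MEG channels are used).
#' @param leadfield a `bro_leadfield`.
#' @param center VOI center (m), typically a named grid point.
#' @param radius VOI radius (m); default 5 mm.
#' @param times epoch time axis (s); taken from `bro_epochs` input.
#' @param sfreq sampling rate (Hz); taken from `bro_epochs` input.
#' @param lambda,lambda_rel regularization, see [mn_operator()].
#' @param band band for the output time courses (Hz); default delta.
#' @param orientation optional fixed orientation/sign vector (length
#'   2 * n_voi) from a previous call — use the blink-condition orientation
#'   when extracting the control condition of the same subject.
#' @param post_win window used to fix the sign convention (s).
#' @return list with `trials` (trials x time), `average`, `orientation`,
#'   `voi` (grid indices), `times`.
#' @export
virtual_electrode <- function(epochs, leadfield, center, radius = 0.005,
                              times = NULL, sfreq = NULL, lambda = NULL,
                              lambda_rel = 0.01, band = c(0.5, 4),
                              orientation = NULL, post_win = c(0.150, 0.350)) {
  if (inherits(epochs, "bro_epochs")) {
    times <- epochs$times; sfreq <- epochs$sfreq
    data <- epochs$data[, epochs$types == "MEG", , drop = FALSE]
  } else data <- epochs
  if (is.null(times) || is.null(sfreq)) stop("times and sfreq are required")
  voi <- voi_indices(leadfield$grid, center, radius)
  if (!length(voi)) stop("empty VOI: no grid points within radius of center")
  M <- mn_operator(leadfield, lambda = lambda, lambda_rel = lambda_rel)
  rows <- as.numeric(rbind(2 * voi - 1, 2 * voi))
  Mv <- M[rows, , drop = FALSE]                      # (2 n_voi) x n_chan

  avg <- apply(data, c(2, 3), mean)                  # n_chan x n_time
  mom_avg <- Mv %*% avg
  if (is.null(orientation)) {
    u <- svd(mom_avg, nu = 1, nv = 0)$u[, 1]
    proj <- as.numeric(crossprod(u, mom_avg))
    proj_f <- if (is.null(band)) proj else bandpass(proj, band[1], band[2], sfreq)
    ip <- .win_idx(times, post_win)
    if (proj_f[ip[which.max(abs(proj_f[ip]))]] < 0) u <- -u
    orientation <- u
  }
  P <- crossprod(orientation, Mv)                    # 1 x n_chan
  n_trial <- dim(data)[1]
  tcs <- matrix(0, n_trial, dim(data)[3])
  for (tr in seq_len(n_trial)) tcs[tr, ] <- P %*% data[tr, , ]
  if (!is.null(band)) tcs <- bandpass(tcs, band[1], band[2], sfreq)
  list(trials = tcs, average = colMeans(tcs), orientation = orientation,
       voi = voi, times = times)
}
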