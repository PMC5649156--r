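# Shared statistical machinery: paired t, bootstrap CIs, and the
# max-suprathreshold-cluster permutation test for paired time courses.

#' Paired t-test
#'
#' Thin wrapper over the standard two-sided paired t-test. Zero-variance
#' differences are a flagged degenerate path: identical vectors give t = 0
#' and p = 1; a constant nonzero difference gives an undefined t (NA) with
#' p = 1 and `zero_variance = TRUE`.
#'
#' @param x,y paired numeric vectors (one value per subject).
#' @return list with `t`, `p`, `df`, `zero_variance`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (all(d == 0) || stats::sd(d) <= 1e-12 * max(abs(d))) {
    return(list(t = if (all(d == 0)) 0 else NA_real_, p = 1,
                df = length(d) - 1L, zero_variance = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), zero_variance = FALSE)
}

# pointwise paired t statistics for a subjects x time difference matrix,
# vectorized over sign-flip permutations: flips is n_perm x n_subj (+-1)
.flip_t <- function(D, flips) {
  n <- nrow(D)
  ss <- colSums(D^2)                      # invariant under sign flips
  M <- flips %*% D / n                    # n_perm x n_time means
  varn <- (rep(ss, each = nrow(flips)) - n * M^2) / (n - 1)
  dim(varn) <- dim(M)
  tv <- M / sqrt(pmax(varn, 0) / n)
  tv[is.nan(tv)] <- 0                     # all-zero differences
  tv
}

# maximum run length of TRUE in a logical vector
.max_run <- function(z) {
  if (!any(z)) return(0L)
  r <- rle(z)
  max(r$lengths[r$values])
}

# contiguous runs of TRUE as (start, end) index pairs
.runs <- function(z) {
  r <- rle(z)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Cluster-based permutation test for paired time courses
#'
#' Computes pointwise paired t statistics between two conditions across
#' subjects; samples beyond the two-sided critical value at
#' `t_thresh_alpha` form contiguous same-sign suprathreshold clusters whose
#' size (sample count) is the cluster statistic. The null distribution of
#' the maximum cluster size is built by randomly swapping the condition
#' labels within subjects (sign flips of the paired differences); each
#' observed cluster's p-value is the fraction of null maxima at least as
#' large (with the observed statistic included, so p >= 1/(n_perm+1)).
#'
#' @param ts_a,ts_b subjects x time matrices (paired rows).
#' @param times optional time axis (s) used to report cluster spans.
#' @param t_thresh_alpha two-sided alpha of the cluster-forming threshold;
#'   default 0.05.
#' @param n_perm number of permutations; default 5000.
#' @param seed integer seed.
#' @return object of class `bro_cluster_result`: data.frame `clusters`
#'   (start, end in s; start_idx, end_idx; size; sign; p), the pointwise
#'   `t` series, `t_crit`, and the `null_max_sizes` distribution.
#' @export
cluster_permutation <- function(ts_a, ts_b, times = NULL,
                                t_thresh_alpha = 0.05, n_perm = 5000,
                                seed = 1L) {
  ts_a <- as.matrix(ts_a); ts_b <- as.matrix(ts_b)
  stopifnot(all(dim(ts_a) == dim(ts_b)))
  n <- nrow(ts_a)
  if (n < 4) stop("need at least 4 subjects")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")
  nt <- ncol(ts_a)
  if (is.null(times)) times <- seq_len(nt)
  D <- ts_a - ts_b
  t_obs <- .flip_t(D, matrix(1, 1, n))[1, ]
  t_crit <- stats::qt(1 - t_thresh_alpha / 2, n - 1)

  pos <- .runs(t_obs > t_crit)
  neg <- .runs(t_obs < -t_crit)
  clusters <- rbind(
    if (nrow(pos)) data.frame(pos, sign = 1L) else NULL,
    if (nrow(neg)) data.frame(neg, sign = -1L) else NULL
  )

  flips <- .substream_eval(seed, 9L,
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n))
  t_perm <- .flip_t(D, flips)
  null_max <- vapply(seq_len(n_perm), function(i) {
    max(.max_run(t_perm[i, ] > t_crit), .max_run(t_perm[i, ] < -t_crit))
  }, 0L)

  if (is.null(clusters) || !nrow(clusters)) {
    cl <- data.frame(start = numeric(0), end = numeric(0),
                     start_idx = integer(0), end_idx = integer(0),
                     size = integer(0), sign = integer(0), p = numeric(0))
  } else {
    clusters <- clusters[order(clusters$start), , drop = FALSE]
    size <- clusters$end - clusters$start + 1L
    p <- vapply(size, function(s) (1 + sum(null_max >= s)) / (n_perm + 1), 0)
    cl <- data.frame(start = times[clusters$start], end = times[clusters$end],
                     start_idx = clusters$start, end_idx = clusters$end,
                     size = size, sign = clusters$sign, p = p)
  }
  structure(list(clusters = cl, t = t_obs, t_crit = t_crit, times = times,
                 null_max_sizes = null_max, n_perm = n_perm),
            class = "bro_cluster_result")
}

#' @export
print.bro_cluster_result <- function(x, ...) {
  cat(sprintf("<bro_cluster_result> %d cluster(s), forming |t| > %.2f, %d permutations\n",
              nrow(x$clusters), x$t_crit, x$n_perm))
  if (nrow(x$clusters)) print(x$clusters[, c("start", "end", "size", "sign", "p")])
  invisible(x)
}

#' Percentile bootstrap confidence band for a group-mean time course
#'
#' Resamples subjects with replacement and takes pointwise percentile
#' intervals of the resampled group means.
#'
#' @param series subjects x time matrix.
#' @param level confidence level; default 0.95.
#' @param n_boot bootstrap replicates; default 1000.
#' @param seed integer seed.
#' @return list with `mean`, `lower`, `upper` (time-point vectors).
#' @export
bootstrap_ci <- function(series, level = 0.95, n_boot = 1000, seed = 1L) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (n < 4) stop("need at least 4 subjects")
  idx <- .substream_eval(seed, 10L,
    matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n))
  means <- matrix(0, n_boot, ncol(series))
  for (b in seq_len(n_boot)) means[b, ] <- colMeans(series[idx[b, ], , drop = FALSE])
  alpha <- (1 - level) / 2
  list(mean = colMeans(series),
       lower = apply(means, 2, stats::quantile, probs = alpha),
       upper = apply(means, 2, stats::quantile, probs = 1 - alpha))
}
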