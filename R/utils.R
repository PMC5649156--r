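# Internal helpers: seeded random substreams and window indexing.
#
# All randomness in the package flows from one master seed through
# numbered substreams, so different model components draw from
# non-interacting streams and the global RNG state is left untouched.
# Documented stream ids: 1 blink times, 2 blink amplitudes, 3 vEOG noise,
# 4 background sources, 5 alpha rhythm, 6 sensor noise, 7 array jitter,
# 8 ICA init, 9+ caller-defined.

.substream_seed <- function(seed, stream) {
  as.integer((abs(as.double(seed)) * 48271 + as.double(stream) * 69621) %% 2147483629)
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.substream_norm <- function(seed, stream, n, sd = 1) {
  .with_seed(.substream_seed(seed, stream), stats::rnorm(n, sd = sd))
}

.substream_unif <- function(seed, stream, n) {
  .with_seed(.substream_seed(seed, stream), stats::runif(n))
}

.substream_eval <- function(seed, stream, expr) {
  .with_seed(.substream_seed(seed, stream), expr)
}

# index range of a closed time window [w1, w2] on a time axis
.win_idx <- function(times, win) {
  idx <- which(times >= win[1] - 1e-9 & times <= win[2] + 1e-9)
  if (!length(idx)) stop("window [", win[1], ", ", win[2], "] s is outside the epoch")
  idx
}
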