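# On-disk formats: HDF5 recording container, CSV event files, YAML
# configuration, and cohort manifests.
#
# HDF5 layout (all float64 unless noted):
#   /data                  n_chan x n_samp (MEG rows in T, EOG rows in uV)
#   /times                 n_samp, seconds
#   /sfreq                 scalar, Hz
#   /channels/labels       strings
#   /channels/types        strings ("MEG" / "EOG")
#   /channels/positions    n_meg x 3 (m)
#   /channels/orientations n_meg x 3 (unit radial)
#   /channels/regions      strings, one of the five scalp regions
#   /geometry/{helmet_radius,conductor_radius,baseline}  scalars (m)

#' Write a recording to an HDF5 container
#'
#' @param recording a `bro_recording`.
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "bro_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  n_samp <- ncol(recording$data)
  rhdf5::h5createDataset(path, "data", dims = dim(recording$data),
                         chunk = c(nrow(recording$data), min(n_samp, 60000L)),
                         level = 4)
  rhdf5::h5write(recording$data, path, "data")
  rhdf5::h5write(seq_len(n_samp) / recording$sfreq - 1 / recording$sfreq,
                 path, "times")
  rhdf5::h5write(recording$sfreq, path, "sfreq")
  rhdf5::h5createGroup(path, "channels")
  rhdf5::h5write(recording$labels, path, "channels/labels")
  rhdf5::h5write(recording$types, path, "channels/types")
  arr <- recording$array
  rhdf5::h5write(arr$positions, path, "channels/positions")
  rhdf5::h5write(arr$orientations, path, "channels/orientations")
  rhdf5::h5write(as.character(arr$regions), path, "channels/regions")
  rhdf5::h5createGroup(path, "geometry")
  rhdf5::h5write(arr$helmet_radius, path, "geometry/helmet_radius")
  rhdf5::h5write(arr$conductor_radius, path, "geometry/conductor_radius")
  rhdf5::h5write(arr$baseline, path, "geometry/baseline")
  rhdf5::h5closeAll()
  invisible(path)
}

.h5_read_required <- function(path, name, contents) {
  if (!name %in% contents) stop("recording file is missing dataset /", name)
  rhdf5::h5read(path, name)
}

#' Read a recording from an HDF5 container
#'
#' Validates the layout written by [write_recording()]; a missing dataset
#' raises an error naming its path.
#'
#' @param path HDF5 file path.
#' @return a `bro_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ls_ <- rhdf5::h5ls(path)
  contents <- sub("^/", "", file.path(ls_$group, ls_$name))
  contents <- sub("^/", "", contents)
  data <- .h5_read_required(path, "data", contents)
  sfreq <- as.numeric(.h5_read_required(path, "sfreq", contents))
  if (!is.finite(sfreq) || sfreq <= 0) stop("invalid /sfreq: must be positive")
  labels <- as.character(.h5_read_required(path, "channels/labels", contents))
  types <- as.character(.h5_read_required(path, "channels/types", contents))
  positions <- .h5_read_required(path, "channels/positions", contents)
  orientations <- .h5_read_required(path, "channels/orientations", contents)
  regions <- as.character(.h5_read_required(path, "channels/regions", contents))
  helmet <- as.numeric(.h5_read_required(path, "geometry/helmet_radius", contents))
  conductor <- as.numeric(.h5_read_required(path, "geometry/conductor_radius", contents))
  baseline <- as.numeric(.h5_read_required(path, "geometry/baseline", contents))
  rhdf5::h5closeAll()
  arr <- structure(list(
    positions = positions, orientations = orientations, baseline = baseline,
    helmet_radius = helmet, conductor_radius = conductor,
    labels = labels[types == "MEG"],
    regions = factor(regions, levels = c("frontal", "central", "parietal",
                                         "temporal", "occipital"))
  ), class = "bro_sensor_array")
  structure(list(data = data, sfreq = sfreq,
                 duration = ncol(data) / sfreq,
                 labels = labels, types = types, array = arr),
            class = "bro_recording")
}

#' Write blink events to CSV
#'
#' Columns `t0_sample,t0_seconds,score`, sorted ascending; an empty event
#' set writes a header-only file.
#'
#' @param events a `bro_events` (or list with `t0_samples`, `scores`,
#'   `sfreq`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- data.frame(t0_sample = as.integer(events$t0_samples),
                   t0_seconds = (events$t0_samples - 1) / events$sfreq,
                   score = if (length(events$scores)) events$scores else numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read blink events from CSV
#'
#' @param path CSV path with columns `t0_sample,t0_seconds,score`.
#' @param sfreq sampling rate (Hz) to attach; inferred from
#'   `t0_sample`/`t0_seconds` when omitted and events exist.
#' @return a `bro_events`.
#' @export
read_events <- function(path, sfreq = NULL) {
  df <- utils::read.csv(path)
  need <- c("t0_sample", "t0_seconds", "score")
  if (!all(need %in% names(df)))
    stop("events file must have columns ", paste(need, collapse = ","))
  if (is.unsorted(df$t0_sample, strictly = TRUE) && nrow(df) > 1)
    stop("invalid events: t0 must be strictly increasing (sorted, no duplicates)")
  if (is.null(sfreq)) {
    sfreq <- if (nrow(df)) round((df$t0_sample[1] - 1) / df$t0_seconds[1]) else NA_real_
  }
  structure(list(t0_samples = as.integer(df$t0_sample), scores = df$score,
                 sfreq = sfreq, n_excluded_close = NA_integer_),
            class = "bro_events")
}

#' Analysis configuration defaults
#'
#' All tunables of the sensor/source pipeline in one list. Defaults:
#' 3-s epochs, 3-s blink exclusion gap, 0.5-45 Hz analysis band,
#' 0.1-30 Hz blink-detection band, delta band 0.5-4 Hz, 6-cycle Morlet over
#' 0.5-6 Hz, GFP/contrast windows 150-350 ms and -1300 to -1100 ms,
#' TF baseline -1500 to -500 ms, power-ratio latencies 0 and -1000 ms,
#' 1000 split-half repetitions, 5000 cluster permutations, 8 mm smoothing
#' FWHM, 5 mm VOI radius.
#'
#' @param ... overrides for any default (unknown names are rejected).
#' @return list of class `bro_analysis_config`.
#' @export
bro_analysis_config <- function(...) {
  cfg <- list(
    band_lo = 0.5, band_hi = 45,        # analysis band (Hz)
    blink_band_lo = 0.1, blink_band_hi = 30,
    notch = NULL,                       # e.g. 60 for line noise
    match_thresh = 0.7, amp_frac = 0.5, min_gap = 3,
    epoch_half_width = 1.5,
    ica_n_components = 30, ica_corr_thresh = 0.8,
    ica_fit_samples = 20000, ica_maxit = 100,
    ratio_t_blink = 0, ratio_t_base = -1,
    delta_band = c(0.5, 4),
    gfp_post_win = c(0.150, 0.350), gfp_pre_win = c(-1.300, -1.100),
    tf_freqs = seq(0.5, 6, by = 0.25), tf_n_cycles = 6,
    tf_baseline = c(-1.5, -0.5),
    lambda_rel = 0.01, smooth_fwhm = 0.008, voi_radius = 0.005,
    n_perm_fwe = 1000, n_perm_cluster = 5000, n_perm_spectral = 1000,
    cluster_alpha = 0.01, fwe_alpha = 0.05,
    split_half_reps = 1000, ci_level = 0.95,
    do_tf = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "bro_analysis_config")
}

#' Read / write configuration as YAML
#'
#' Serializes a simulation and/or analysis configuration. Unknown keys in
#' either section are rejected on read.
#'
#' @param path YAML file path.
#' @param simulation a `bro_sim_config` (optional).
#' @param analysis a `bro_analysis_config` (optional).
#' @return `write_config`: `path` invisibly. `read_config`: list with
#'   `simulation` and `analysis` populated with defaults plus overrides.
#' @export
write_config <- function(path, simulation = NULL, analysis = NULL) {
  out <- list()
  if (!is.null(simulation)) {
    s <- unclass(simulation)
    s$blink_params <- unclass(s$blink_params)
    out$simulation <- s
  }
  if (!is.null(analysis)) out$analysis <- unclass(analysis)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), c("simulation", "analysis"))
  if (length(bad)) stop("unknown config sections: ", paste(bad, collapse = ", "))
  sim <- bro_sim_config()
  if (!is.null(raw$simulation)) {
    s <- raw$simulation
    bp <- s$blink_params; s$blink_params <- NULL
    unknown <- setdiff(names(s), names(sim))
    if (length(unknown)) stop("unknown simulation keys: ", paste(unknown, collapse = ", "))
    args <- s
    if (!is.null(bp)) args$blink_params <- do.call(blink_params, bp)
    sim <- do.call(bro_sim_config, args)
  }
  ana <- if (is.null(raw$analysis)) bro_analysis_config()
         else do.call(bro_analysis_config, raw$analysis)
  list(simulation = sim, analysis = ana)
}

#' Write / read a cohort manifest
#'
#' CSV with columns `subject,recording,events,seed`; subject ids must be
#' unique.
#'
#' @param manifest data.frame with those columns.
#' @param path CSV path.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: the
#'   validated data.frame.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("subject", "recording", "events", "seed") %in% names(manifest)))
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject", "recording", "events", "seed")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ","))
  if (anyDuplicated(df$subject)) stop("manifest subject ids must be unique")
  df
}
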