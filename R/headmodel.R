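# Spherical-conductor forward model and sensor/source geometry.
#
# Coordinate frame: conductor center at the origin, +x right, +y anterior,
# +z superior (an "MNI-like" nominal frame; no anatomy is attached).
# All lengths in meters, fields in tesla, dipole moments in A*m.

MU0_OVER_4PI <- 1e-7

#' Build a quasi-uniform axial gradiometer array on a spherical cap
#'
#' Places `n_chan` sensing coils on the upper cap of a helmet sphere using a
#' Fibonacci spiral (quasi-uniform areal coverage), with a small seeded
#' tangential jitter so distinct seeds give distinct but statistically
#' equivalent arrays. Each channel is an axial gradiometer: a radially
#' oriented coil at the helmet radius plus a second coil `baseline` further
#' out along the same radius.
#'
#' @param n_chan number of channels (>= 4).
#' @param helmet_radius radius of the sensing surface (m); must exceed
#'   `conductor_radius`.
#' @param baseline gradiometer baseline (m), distance between the two coils.
#' @param conductor_radius radius of the homogeneous conducting sphere (m).
#' @param el_min_deg lowest sensor elevation in degrees (cap cut).
#' @param jitter tangential jitter amplitude as a fraction of the mean
#'   inter-sensor spacing; 0 gives the bare spiral.
#' @param seed integer seed for the jitter stream.
#' @return An object of class `bro_sensor_array`: list with `positions`
#'   (n_chan x 3), `orientations` (unit radial vectors), `baseline`,
#'   `helmet_radius`, `conductor_radius`, `labels`, and `regions` (factor
#'   with levels frontal/central/parietal/temporal/occipital).
#' @export
build_sensor_array <- function(n_chan = 151, helmet_radius = 0.11,
                               baseline = 0.05, conductor_radius = 0.09,
                               el_min_deg = -10, jitter = 0.2, seed = 1L) {
  if (n_chan < 4) stop("n_chan must be >= 4")
  if (helmet_radius <= 0 || baseline <= 0 || conductor_radius <= 0)
    stop("invalid geometry: radii and baseline must be positive")
  if (helmet_radius <= conductor_radius)
    stop("invalid geometry: helmet_radius must exceed conductor_radius")

  z_lo <- sin(el_min_deg * pi / 180)
  i <- seq_len(n_chan)
  z <- z_lo + (i - 0.5) / n_chan * (1 - z_lo)          # uniform in z => uniform area
  golden <- pi * (3 - sqrt(5))
  az <- (i - 1) * golden
  r_xy <- sqrt(pmax(0, 1 - z^2))
  pos <- unname(cbind(r_xy * sin(az), r_xy * cos(az), z))  # az = 0 -> anterior (+y)

  if (jitter > 0) {
    spacing <- sqrt(2 * pi * (1 - z_lo) / n_chan)      # mean angular spacing (rad)
    pos <- pos + .substream_norm(seed, 7L, n_chan * 3L, sd = jitter * spacing / 3)
    pos <- pos / sqrt(rowSums(pos^2))
  }
  pos <- pos * helmet_radius
  orient <- pos / helmet_radius

  arr <- structure(list(
    positions = pos,
    orientations = orient,
    baseline = baseline,
    helmet_radius = helmet_radius,
    conductor_radius = conductor_radius,
    labels = sprintf("MEG%03d", i),
    regions = NULL
  ), class = "bro_sensor_array")
  arr$regions <- partition_regions(arr)
  arr
}

#' @export
print.bro_sensor_array <- function(x, ...) {
  cat(sprintf("<bro_sensor_array> %d axial gradiometers, helmet %.3f m, baseline %.3f m\n",
              nrow(x$positions), x$helmet_radius, x$baseline))
  print(table(x$regions))
  invisible(x)
}

#' Assign channels to scalp regions by fixed angular sectors
#'
#' Deterministic partition of the channel set into frontal, central,
#' parietal, temporal, and occipital groups. Low-elevation channels
#' (< 50 deg) are split by azimuth from the anterior axis: the anterior
#' 60-degree sector is frontal, the posterior 60-degree sector occipital,
#' and the lateral bands temporal. High-elevation channels are central
#' (anterior half) or parietal (posterior half).
#'
#' @param array a `bro_sensor_array`.
#' @return factor of length n_chan with the five region levels.
#' @export
partition_regions <- function(array) {
  p <- array$positions
  r <- sqrt(rowSums(p^2))
  el <- asin(p[, 3] / r) * 180 / pi
  az <- abs(atan2(p[, 1], p[, 2])) * 180 / pi   # 0 = anterior, 180 = posterior
  reg <- ifelse(el >= 50,
                ifelse(az <= 90, "central", "parietal"),
                ifelse(az <= 60, "frontal",
                       ifelse(az >= 120, "occipital", "temporal")))
  factor(reg, levels = c("frontal", "central", "parietal", "temporal", "occipital"))
}

#' Source grid on a spherical shell inside the conductor
#'
#' Quasi-uniform (Fibonacci) grid on a shell of radius `shell_radius`,
#' restricted to z > `z_min`, with two designated precuneus-proxy points
#' obtained by radially scaling the nominal coordinates (-8, -68, 49) and
#' (7, -68, 39) mm onto the shell. These two named points are appended as
#' exact grid points.
#'
#' @param spacing nominal inter-point distance (m); default 10 mm.
#' @param shell_radius shell radius (m); must be strictly inside the conductor.
#' @param conductor_radius conductor radius (m), for validation.
#' @param z_min lower z cut of the shell (m).
#' @return `bro_source_grid`: list with `coords` (n_src x 3), `spacing`,
#'   `names` (NA except for the named proxies), and the indices
#'   `precuneus_left`, `precuneus_right`.
#' @export
build_source_grid <- function(spacing = 0.01, shell_radius = 0.07,
                              conductor_radius = 0.09, z_min = -0.03) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (shell_radius >= conductor_radius)
    stop("invalid geometry: source shell must be strictly inside the conductor")
  h <- shell_radius - z_min
  area <- 2 * pi * shell_radius * h                 # spherical zone area
  n <- max(8L, as.integer(round(area / spacing^2)))
  i <- seq_len(n)
  z <- (z_min / shell_radius) + (i - 0.5) / n * (1 - z_min / shell_radius)
  golden <- pi * (3 - sqrt(5))
  az <- (i - 1) * golden
  r_xy <- sqrt(pmax(0, 1 - z^2))
  coords <- unname(cbind(r_xy * sin(az), r_xy * cos(az), z)) * shell_radius

  proxies <- rbind(c(-8, -68, 49), c(7, -68, 39)) / 1000
  proxies <- proxies / sqrt(rowSums(proxies^2)) * shell_radius
  coords <- rbind(coords, proxies)
  nm <- c(rep(NA_character_, n), "precuneus_left", "precuneus_right")

  structure(list(coords = coords, spacing = spacing,
                 shell_radius = shell_radius, names = nm,
                 precuneus_left = n + 1L, precuneus_right = n + 2L),
            class = "bro_source_grid")
}

#' @export
print.bro_source_grid <- function(x, ...) {
  cat(sprintf("<bro_source_grid> %d points on %.0f mm shell, spacing %.0f mm\n",
              nrow(x$coords), 1000 * x$shell_radius, 1000 * x$spacing))
  invisible(x)
}

#' Radial magnetic field of a current dipole in a spherical conductor
#'
#' Closed-form (Sarvas) magnetic field of a current dipole inside a
#' spherically symmetric conductor centered at the origin, projected on the
#' outward radial direction at each sensor. Radial dipoles are magnetically
#' silent; a dipole at the center gives exactly zero field.
#'
#' @param dipole_pos length-3 position of the dipole (m), strictly inside
#'   the conductor.
#' @param dipole_moment length-3 dipole moment (A*m).
#' @param sensor_pos n x 3 matrix (or length-3 vector) of sensor positions
#'   (m), strictly outside the conductor.
#' @return numeric vector of radial field values (T), one per sensor row.
#' @export
sarvas_field <- function(dipole_pos, dipole_moment, sensor_pos) {
  r0 <- as.numeric(dipole_pos)
  q <- as.numeric(dipole_moment)
  if (is.null(dim(sensor_pos))) sensor_pos <- matrix(sensor_pos, nrow = 1)
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  n_sens <- nrow(sensor_pos)
  if (sum(qxr0^2) == 0) return(rep(0, n_sens))   # radial (or central) dipole: silent

  rn <- sqrt(rowSums(sensor_pos^2))
  a_vec <- sweep(sensor_pos, 2, r0)              # r - r0
  an <- sqrt(rowSums(a_vec^2))
  adotr <- rowSums(a_vec * sensor_pos)
  r0dotr <- as.numeric(sensor_pos %*% r0)
  FF <- an * (rn * an + rn^2 - r0dotr)
  c1 <- an^2 / rn + adotr / an + 2 * an + 2 * rn
  c2 <- an + 2 * rn + adotr / an
  # gradF rows: c1 * r - c2 * r0
  gradF <- sensor_pos * c1 - tcrossprod(c2, r0)
  qxr0_dot_r <- as.numeric(sensor_pos %*% qxr0)
  B <- (tcrossprod(FF, qxr0) - gradF * qxr0_dot_r) * (MU0_OVER_4PI / FF^2)
  rowSums(B * sensor_pos) / rn                   # radial component
}

.tangent_basis <- function(p) {
  # local (e_theta, e_phi) at point p; falls back to (e_x, e_y) near origin
  r <- sqrt(sum(p^2))
  if (r < 1e-12) return(list(e1 = c(1, 0, 0), e2 = c(0, 1, 0)))
  rhat <- p / r
  up <- if (abs(rhat[3]) < 0.99) c(0, 0, 1) else c(1, 0, 0)
  e1 <- up - sum(up * rhat) * rhat
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(rhat[2] * e1[3] - rhat[3] * e1[2],
          rhat[3] * e1[1] - rhat[1] * e1[3],
          rhat[1] * e1[2] - rhat[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Gradiometer lead field for a source grid
#'
#' For every grid point and each of two local tangential orientations,
#' computes the axial gradiometer output: radial field at the inner coil
#' minus radial field at the outer coil (`baseline` further out along the
#' sensor radius), per unit dipole moment. Radial source orientations are
#' excluded by construction (silent in a sphere).
#'
#' @param array a `bro_sensor_array`.
#' @param grid a `bro_source_grid`; all points must be strictly inside the
#'   conductor.
#' @return `bro_leadfield`: list with `gain` (n_chan x 2*n_src; columns
#'   ordered point1-orient1, point1-orient2, point2-orient1, ...),
#'   `grid`, `array`, and `tangents` (n_src x 3 x 2).
#' @export
compute_leadfield <- function(array, grid) {
  coords <- grid$coords
  rad <- sqrt(rowSums(coords^2))
  if (any(rad >= array$conductor_radius))
    stop("invalid geometry: source grid point outside the conductor")
  inner <- array$positions
  outer <- inner + array$orientations * array$baseline
  n_src <- nrow(coords)
  n_chan <- nrow(inner)
  gain <- matrix(0, n_chan, 2L * n_src)
  tang <- array(0, c(n_src, 3, 2))
  for (s in seq_len(n_src)) {
    tb <- .tangent_basis(coords[s, ])
    tang[s, , 1] <- tb$e1
    tang[s, , 2] <- tb$e2
    gain[, 2 * s - 1] <- sarvas_field(coords[s, ], tb$e1, inner) -
      sarvas_field(coords[s, ], tb$e1, outer)
    gain[, 2 * s] <- sarvas_field(coords[s, ], tb$e2, inner) -
      sarvas_field(coords[s, ], tb$e2, outer)
  }
  structure(list(gain = gain, grid = grid, array = array, tangents = tang),
            class = "bro_leadfield")
}

#' @export
print.bro_leadfield <- function(x, ...) {
  cat(sprintf("<bro_leadfield> %d channels x %d source points x 2 orientations\n",
              nrow(x$gain), nrow(x$grid$coords)))
  invisible(x)
}

#' Grid indices inside a spherical volume of interest
#'
#' @param grid a `bro_source_grid`.
#' @param center length-3 VOI center (m).
#' @param radius VOI radius (m); default 5 mm.
#' @return integer vector of grid indices within `radius` of `center`
#'   (possibly empty).
#' @export
voi_indices <- function(grid, center, radius = 0.005) {
  if (radius <= 0) stop("radius must be > 0")
  d2 <- rowSums(sweep(grid$coords, 2, as.numeric(center))^2)
  which(d2 <= radius^2)
}
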