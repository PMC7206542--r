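# hc in keV * Angstrom; photon wavelength [A] = .hc / energy [keV]
.hc <- 12.3984

#' Convert photon energy to wavelength
#'
#' @param energy Photon energy in keV.
#' @return Wavelength in Angstroms (`12.3984 / energy`).
#' @examples
#' wavelength_from_energy(13.5)
#' @export
wavelength_from_energy <- function(energy) {
  if (!is.numeric(energy) || any(!is.finite(energy)) || any(energy <= 0))
    stop("`energy` must be positive and finite (keV)", call. = FALSE)
  .hc / energy
}

#' Convert wavelength to photon energy
#'
#' @param wavelength Wavelength in Angstroms.
#' @return Photon energy in keV.
#' @export
energy_from_wavelength <- function(wavelength) {
  if (!is.numeric(wavelength) || any(!is.finite(wavelength)) || any(wavelength <= 0))
    stop("`wavelength` must be positive and finite (Angstrom)", call. = FALSE)
  .hc / wavelength
}

#' Experiment geometry for a normal-incidence area detector
#'
#' Describes the geometry needed to map detector pixels to reciprocal space:
#' photon energy/wavelength, sample-to-detector distance, beam center, pixel
#' size and detector shape. Only normal-incidence detectors (face
#' perpendicular to the beam) are supported.
#'
#' Pixel indices are 0-based `(row, column)` with rows increasing downward.
#' The beam center may be fractional and may lie outside the detector.
#'
#' @param distance Sample-to-detector distance in mm.
#' @param beam_center Numeric length-2, `(row, column)` in pixels (0-based,
#'   fractional allowed).
#' @param pixel_size Pixel edge length in mm (square pixels).
#' @param shape Integer length-2, detector `(rows, columns)`.
#' @param energy Photon energy in keV. Give `energy` or `wavelength` (or both,
#'   in which case they must agree to 1e-6 relative).
#' @param wavelength X-ray wavelength in Angstroms.
#' @param normal_incidence Must be `TRUE`; tilted detectors are rejected.
#' @param label Optional detector label used when merging.
#' @return An object of class `"xs_geometry"`.
#' @examples
#' g <- xs_geometry(distance = 1000, beam_center = c(0, 0),
#'                  pixel_size = 0.172, shape = c(195, 487), energy = 13.5)
#' g$wavelength
#' @export
xs_geometry <- function(distance, beam_center, pixel_size, shape,
                        energy = NULL, wavelength = NULL,
                        normal_incidence = TRUE, label = "det") {
  if (is.null(energy) && is.null(wavelength))
    stop("give `energy` (keV) or `wavelength` (Angstrom)", call. = FALSE)
  if (is.null(wavelength)) wavelength <- wavelength_from_energy(energy)
  if (is.null(energy)) energy <- energy_from_wavelength(wavelength)
  if (abs(wavelength - .hc / energy) > 1e-6 * wavelength)
    stop("`energy` and `wavelength` are inconsistent (require lambda = 12.3984/E)",
         call. = FALSE)
  if (!isTRUE(normal_incidence))
    stop("only normal-incidence detectors are modelled; tilted geometry is not supported",
         call. = FALSE)
  stopifnot(length(beam_center) == 2L, length(shape) == 2L)
  if (!all(is.finite(c(distance, pixel_size))) || distance <= 0 || pixel_size <= 0)
    stop("`distance` and `pixel_size` must be positive", call. = FALSE)
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop("`shape` must be positive integers", call. = FALSE)
  structure(
    list(energy = energy, wavelength = wavelength, distance = distance,
         beam_center = as.numeric(beam_center), pixel_size = pixel_size,
         shape = shape, normal_incidence = TRUE, label = label),
    class = "xs_geometry")
}

#' @export
print.xs_geometry <- function(x, ...) {
  cat(sprintf("<xs_geometry '%s'>\n", x$label))
  cat(sprintf("  energy %.4f keV (lambda %.5f A), distance %.2f mm\n",
              x$energy, x$wavelength, x$distance))
  cat(sprintf("  beam center (%.2f, %.2f) px, pixel %.4g mm, shape %d x %d\n",
              x$beam_center[1], x$beam_center[2], x$pixel_size,
              x$shape[1], x$shape[2]))
  invisible(x)
}

#' Per-pixel reciprocal-space map
#'
#' Computes, for every pixel, the scattering-vector magnitude
#' q = (4 pi / lambda) sin(theta) with 2 theta = arctan(r / D), the scattering
#' angle 2 theta (degrees), and the azimuth (degrees in \[-180, 180), 0 along
#' the +column axis, counter-clockwise positive with rows increasing
#' downward).
#'
#' @param geom An [xs_geometry()].
#' @return An object of class `"xs_qmap"`: matrices `q` (1/A), `two_theta`
#'   (deg), `azimuth` (deg) and logical `mask` of finite entries, plus the
#'   generating geometry.
#' @export
qmap_from_geometry <- function(geom) {
  stopifnot(inherits(geom, "xs_geometry"))
  nr <- geom$shape[1]; nc <- geom$shape[2]
  dr <- (seq_len(nr) - 1) - geom$beam_center[1]   # rows, 0-based
  dc <- (seq_len(nc) - 1) - geom$beam_center[2]
  DR <- matrix(dr, nr, nc)
  DC <- matrix(dc, nr, nc, byrow = TRUE)
  r_mm <- geom$pixel_size * sqrt(DR^2 + DC^2)
  tth <- atan(r_mm / geom$distance)                # radians
  q <- (4 * pi / geom$wavelength) * sin(tth / 2)
  az <- atan2(-DR, DC) * 180 / pi
  az[az >= 180] <- az[az >= 180] - 360
  structure(list(q = q, two_theta = tth * 180 / pi, azimuth = az,
                 mask = is.finite(q), geometry = geom),
            class = "xs_qmap")
}

#' Powder scattering standard
#'
#' A named set of lamellar d-spacings (Angstrom, sorted descending) whose
#' diffraction rings appear at q_n = 2 pi / d_n.
#'
#' @param name Standard name.
#' @param d_spacings Positive d-spacings in Angstroms, descending.
#' @return An object of class `"xs_standard"` with a `$q` vector of ring
#'   positions.
#' @export
scattering_standard <- function(name, d_spacings) {
  d <- as.numeric(d_spacings)
  if (any(!is.finite(d)) || any(d <= 0)) stop("d-spacings must be positive", call. = FALSE)
  if (is.unsorted(rev(d), strictly = TRUE))
    stop("d-spacings must be sorted strictly descending", call. = FALSE)
  structure(list(name = name, d = d, q = 2 * pi / d), class = "xs_standard")
}

#' Silver behenate calibration standard
#'
#' Lamellar standard with fundamental spacing d = 58.38 A (Huang et al. 1993,
#' J. Appl. Cryst. 26, 180) and harmonics d/n; the first-order ring sits at
#' q = 2 pi / 58.38 = 0.10763 1/A.
#'
#' @param n_orders Number of diffraction orders to include.
#' @return An `"xs_standard"`.
#' @export
silver_behenate <- function(n_orders = 5) {
  scattering_standard("AgBh", 58.38 / seq_len(n_orders))
}

# Unweighted radial profile in pixel units, 1-px bins; used for calibration.
radial_profile <- function(counts, center, mask = NULL) {
  nr <- nrow(counts); nc <- ncol(counts)
  DR <- matrix((seq_len(nr) - 1) - center[1], nr, nc)
  DC <- matrix((seq_len(nc) - 1) - center[2], nr, nc, byrow = TRUE)
  rad <- sqrt(DR^2 + DC^2)
  use <- if (is.null(mask)) rep(TRUE, length(rad)) else as.vector(mask)
  b <- floor(as.vector(rad)[use]) + 1L
  x <- as.vector(counts)[use]
  nb <- max(b)
  n <- tabulate(b, nb)
  s <- numeric(nb)
  rs <- rowsum(x, b)
  s[as.integer(rownames(rs))] <- rs[, 1]
  keep <- n > 0L
  list(r = (which(keep) - 0.5), I = (s / pmax(n, 1L))[keep], n = n[keep])
}

# Quadratic sub-bin interpolation of a local maximum at index i of y.
.quad_peak <- function(x, y, i) {
  if (i <= 1L || i >= length(y)) return(list(x = x[i], y = y[i]))
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(list(x = x[i], y = y[i]))
  d <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  d <- max(min(d, 0.5), -0.5)
  h <- x[i + 1] - x[i]
  list(x = x[i] + d * h, y = y[i] - 0.25 * (y[i - 1] - y[i + 1]) * d)
}

#' Calibrate sample-to-detector distance from a powder standard
#'
#' Locates the standard's diffraction rings in the radial intensity profile of
#' `pattern` (peak positions refined by quadratic interpolation around each
#' ring maximum) and least-squares fits the distance so that predicted ring
#' radii `D * tan(2 theta_n)` match the observed radii.
#'
#' @param pattern An [xs_pattern()] showing at least one ring of the standard.
#' @param standard An [scattering_standard()].
#' @param initial_geom Geometry with a starting distance within about 20% of
#'   the truth.
#' @param window Fractional half-width of the radial search window around each
#'   predicted ring.
#' @param min_prominence Minimum (peak - window median) / MAD for a ring to be
#'   accepted.
#' @return The input geometry with calibrated `distance`; attributes
#'   `"rings"` (data frame of observed/predicted radii and residuals in mm)
#'   and `"rms_residual_mm"`.
#' @export
calibrate_distance <- function(pattern, standard, initial_geom,
                               window = 0.2, min_prominence = 5) {
  stopifnot(inherits(pattern, "xs_pattern"), inherits(standard, "xs_standard"),
            inherits(initial_geom, "xs_geometry"))
  g <- initial_geom
  rp <- radial_profile(pattern$counts, g$beam_center, pattern$mask)
  # light smoothing stabilises the max under counting noise
  sm <- .movavg(rp$I, 3L)
  obs_r <- pred_tan <- resid_ring <- order_n <- numeric(0)
  rmax <- max(rp$r)
  for (j in seq_along(standard$q)) {
    qn <- standard$q[j]
    s <- qn * g$wavelength / (4 * pi)
    if (abs(s) >= 1) next
    tth <- 2 * asin(s)
    r_pred_px <- g$distance * tan(tth) / g$pixel_size
    lo <- r_pred_px * (1 - window); hi <- r_pred_px * (1 + window)
    if (lo < 2 || hi > rmax) next
    idx <- which(rp$r >= lo & rp$r <= hi)
    if (length(idx) < 5L) next
    y <- sm[idx]
    med <- stats::median(y)
    scatter <- stats::mad(y)
    if (!is.finite(scatter) || scatter <= 0) scatter <- max(1e-12, 0.01 * abs(med))
    i <- idx[which.max(y)]
    if ((sm[i] - med) / scatter < min_prominence) next
    pk <- .quad_peak(rp$r, rp$I, i)
    obs_r <- c(obs_r, pk$x * g$pixel_size)         # mm
    pred_tan <- c(pred_tan, tan(tth))
    order_n <- c(order_n, j)
  }
  if (length(obs_r) == 0L)
    stop("calibration failure: no standard ring found in the search window",
         call. = FALSE)
  d_hat <- sum(obs_r * pred_tan) / sum(pred_tan^2)
  resid_ring <- obs_r - d_hat * pred_tan
  out <- g
  out$distance <- d_hat
  attr(out, "rings") <- data.frame(order = order_n, r_obs_mm = obs_r,
                                   r_pred_mm = d_hat * pred_tan,
                                   residual_mm = resid_ring)
  attr(out, "rms_residual_mm") <- sqrt(mean(resid_ring^2))
  out
}

#' Read / write a flat key-value geometry config
#'
#' Plain-text `key = value` format with keys `energy_keV` (or `wavelength_A`),
#' `distance_mm`, `beam_center` (two numbers), `pixel_size_mm`, `shape`
#' (two integers) and optional `label`.
#'
#' @param path File path.
#' @param geom An [xs_geometry()] (for writing).
#' @return `read_geometry()` returns an `xs_geometry`; `write_geometry()`
#'   returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed geometry config: ", path, call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  num <- function(k) if (k %in% keys) as.numeric(strsplit(vals[match(k, keys)], "[ ,]+")[[1]]) else NULL
  xs_geometry(
    distance = num("distance_mm"),
    beam_center = num("beam_center"),
    pixel_size = num("pixel_size_mm"),
    shape = num("shape"),
    energy = num("energy_keV"),
    wavelength = num("wavelength_A"),
    label = if ("label" %in% keys) vals[match("label", keys)] else "det")
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "xs_geometry"))
  writeLines(c(
    sprintf("label = %s", geom$label),
    sprintf("energy_keV = %.17g", geom$energy),
    sprintf("wavelength_A = %.17g", geom$wavelength),
    sprintf("distance_mm = %.17g", geom$distance),
    sprintf("beam_center = %.17g %.17g", geom$beam_center[1], geom$beam_center[2]),
    sprintf("pixel_size_mm = %.17g", geom$pixel_size),
    sprintf("shape = %d %d", geom$shape[1], geom$shape[2])), path)
  invisible(path)
}

# centered moving average with edge renormalisation
.movavg <- function(y, k = 5L) {
  if (k <= 1L || length(y) < 2L) return(y)
  h <- k %/% 2L
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
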