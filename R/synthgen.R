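# evaluate code with a temporarily fixed RNG state; NULL seed = use current
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Phenomenological water/buffer scattering profile
#'
#' Flat baseline plus a broad Gaussian peak centered at q0 = 2.0 1/A:
#' `I(q) = B + A exp(-(q - q0)^2 / (2 w^2))`. This is a stand-in that
#' reproduces the position and height behaviour of the liquid-water peak used
#' for buffer matching, not a physical water structure factor.
#'
#' @param q q grid (1/A).
#' @param amplitude Peak amplitude A above the baseline.
#' @param center Peak position q0, default 2.0 1/A.
#' @param width Gaussian sigma w, default 0.3 1/A.
#' @param baseline Flat level B, default `0.2 * amplitude`.
#' @return An [xs_profile()] (sigma 0; noise is added when rendering).
#' @export
water_profile <- function(q, amplitude = 1, center = 2.0, width = 0.3,
                          baseline = 0.2 * amplitude) {
  I <- water_intensity(q, amplitude, center, width, baseline)
  xs_profile(q, I, meta = list(label = "water", model = "water_background",
                               amplitude = amplitude, center = center,
                               width = width, baseline = baseline))
}

#' Dilute-sphere form-factor profile
#'
#' `I(q) = I0 [3 (sin(qR) - qR cos(qR)) / (qR)^3]^2`, with `I(0) = I0`; the
#' first zero falls at `qR = 4.4934` and the Guinier radius is
#' `Rg = R sqrt(3/5)`.
#'
#' @param q q grid (1/A).
#' @param radius Sphere radius R in Angstroms.
#' @param I0 Forward scattering.
#' @return An [xs_profile()].
#' @export
sphere_profile <- function(q, radius, I0 = 1) {
  xs_profile(q, sphere_intensity(q, radius, I0),
             meta = list(label = "sphere", model = "sphere", radius = radius,
                         I0 = I0))
}

#' Intensity functions at arbitrary q
#'
#' Plain vectorized intensity evaluators behind the profile constructors;
#' usable as `model` arguments of [render_detector_image()] and
#' [generate_sec_run()], which evaluate them at unsorted per-pixel q values.
#'
#' @inheritParams water_profile
#' @inheritParams sphere_profile
#' @return Numeric vector of intensities at `q`.
#' @export
water_intensity <- function(q, amplitude = 1, center = 2.0, width = 0.3,
                            baseline = 0.2 * amplitude) {
  baseline + amplitude * exp(-(q - center)^2 / (2 * width^2))
}

#' @rdname water_intensity
#' @export
sphere_intensity <- function(q, radius, I0 = 1) {
  stopifnot(radius > 0)
  x <- q * radius
  F <- ifelse(abs(x) < 1e-4, 1 - x^2 / 10, 3 * (sin(x) - x * cos(x)) / pmax(x, 1e-300)^3)
  I0 * F^2
}

#' Guinier-Porod model profile
#'
#' Hammouda's empirical form: Guinier law `G exp(-q^2 Rg^2 / 3)` below the
#' crossover `q1 = sqrt(3 d / 2) / Rg` and a Porod power law `D / q^d` above
#' it, with D fixed by continuity.
#'
#' @param q q grid (1/A).
#' @param rg Radius of gyration (A).
#' @param porod_exp Porod exponent d (4 for sharp interfaces).
#' @param G Guinier prefactor.
#' @return An [xs_profile()].
#' @export
guinier_porod_profile <- function(q, rg, porod_exp = 4, G = 1) {
  stopifnot(rg > 0, porod_exp > 0)
  q1 <- sqrt(3 * porod_exp / 2) / rg
  D <- G * exp(-q1^2 * rg^2 / 3) * q1^porod_exp
  I <- ifelse(q <= q1, G * exp(-q^2 * rg^2 / 3), D / pmax(q, 1e-12)^porod_exp)
  xs_profile(q, I, meta = list(label = "guinier_porod", model = "guinier_porod",
                               rg = rg, porod_exp = porod_exp, G = G))
}

#' Gaussian-ring intensity model for a powder standard
#'
#' Sum of Gaussian rings at the standard's q positions over a small flat
#' baseline; used to render synthetic calibration images.
#'
#' @param standard An [scattering_standard()].
#' @param amplitude Ring amplitude.
#' @param width Ring sigma in q (1/A).
#' @param baseline Flat background level.
#' @return A function `I(q)`.
#' @export
standard_rings_model <- function(standard, amplitude = 100, width = 0.004,
                                 baseline = 1) {
  stopifnot(inherits(standard, "xs_standard"))
  qs <- standard$q
  function(q) {
    I <- rep(baseline, length(q))
    for (q0 in qs) I <- I + amplitude * exp(-(q - q0)^2 / (2 * width^2))
    I
  }
}

# coerce a model (function or profile) to an intensity function of q
.model_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "xs_profile")) {
    ok <- !model$empty
    qf <- model$q[ok]; If <- model$I[ok]
    return(function(q) stats::approx(qf, If, xout = q, rule = 2)$y)
  }
  stop("`model` must be a function of q or an xs_profile", call. = FALSE)
}

#' Render a synthetic detector image from a 1D model
#'
#' Expected counts per pixel are the model intensity at the pixel's q times
#' the exposure; realized counts are Poisson-sampled (deterministically for a
#' fixed seed) unless `noise = FALSE`.
#'
#' @param model Function `I(q)` or an [xs_profile()] (interpolated).
#' @param geom An [xs_geometry()].
#' @param exposure Exposure time, s (scales expected counts).
#' @param seed Integer seed for the Poisson sampling; `NULL` uses the current
#'   RNG state.
#' @param noise Poisson-sample the counts (`TRUE`) or return expected counts.
#' @param mask Optional logical pixel mask.
#' @param ref_distance Optional reference distance, mm. When given, expected
#'   counts are additionally scaled by the per-pixel solid-angle ratio
#'   `(ref_distance / distance)^2`, so that images rendered from one model
#'   on detectors at different distances merge consistently under
#'   [merge_scale_factor()] scaling; when `NULL` the model intensity is
#'   taken as expected counts at this detector's own distance.
#' @return An [xs_pattern()].
#' @export
render_detector_image <- function(model, geom, exposure = 1, seed = NULL,
                                  noise = TRUE, mask = NULL,
                                  ref_distance = NULL) {
  stopifnot(inherits(geom, "xs_geometry"))
  f <- .model_fun(model)
  qm <- qmap_from_geometry(geom)
  mu <- f(as.vector(qm$q)) * exposure
  if (!is.null(ref_distance))
    mu <- mu * (ref_distance / geom$distance)^2
  if (any(mu < 0)) stop("model produced negative expected counts", call. = FALSE)
  counts <- if (noise) with_seed(seed, stats::rpois(length(mu), mu)) else mu
  xs_pattern(matrix(counts, nrow(qm$q), ncol(qm$q)), geom, mask = mask,
             exposure = exposure, label = "rendered")
}

#' Specification of a synthetic SEC-SAXS run
#'
#' Defines species eluting as Gaussian (optionally exponentially-modified)
#' peaks on a linearly drifting water background, with Poisson counting
#' noise and a split-flow UV offset.
#'
#' @param species List of species, each a list with `model` (an
#'   [xs_profile()] or function of q), `center` and `width` (elution peak, s),
#'   `conc` (peak concentration scale) and optionally `uv_eps` (UV response,
#'   default 1) and `tau` (exponential tailing constant, s; 0 = symmetric).
#' @param drift_alpha Fractional background drift per second; baseline
#'   `b(t) = 1 + drift_alpha * t` (must stay positive; sign free).
#' @param frame_interval,run_length Frame spacing and run duration, s.
#' @param counts_scale Expected counts at the water peak per frame; sets the
#'   Poisson noise level (default 500, realistic shot noise for a 1 s frame).
#' @param water Water model parameters passed to [water_profile()].
#' @param uv_offset Split-flow delay of the UV trace relative to the X-ray
#'   cell, s.
#' @param uv_noise_sd Gaussian noise sd on the UV trace.
#' @return An object of class `"sec_run_spec"`.
#' @export
sec_run_spec <- function(species = list(), drift_alpha = 0,
                         frame_interval = 2, run_length = 1200,
                         counts_scale = 500,
                         water = list(amplitude = 1),
                         uv_offset = 30, uv_noise_sd = 0) {
  tmax <- run_length
  if (1 + drift_alpha * tmax <= 0 || 1 + drift_alpha * 0 <= 0)
    stop("background drift makes b(t) non-positive within the run", call. = FALSE)
  for (s in species) {
    stopifnot(!is.null(s$model), !is.null(s$center), !is.null(s$width))
    if (s$center < 0 || s$center > tmax)
      stop("species elution peak outside the run", call. = FALSE)
  }
  structure(list(species = species, drift_alpha = drift_alpha,
                 frame_interval = frame_interval, run_length = run_length,
                 counts_scale = counts_scale, water = water,
                 uv_offset = uv_offset, uv_noise_sd = uv_noise_sd),
            class = "sec_run_spec")
}

#' Generate a synthetic SEC-SAXS run
#'
#' Expected frame intensity is
#' `b(t) * I_w(q) + sum_s c_s(t) * P_s(q)` with `b(t) = 1 + alpha t`,
#' Gaussian elution profiles `c_s(t)`, and Poisson noise realized at the
#' spec's counting scale. The UV trace is the species concentration sum
#' delayed by the split-flow offset. The generating truth (noise-free buffer
#' and species matrices) is stored in `meta$truth`.
#'
#' @param spec A [sec_run_spec()].
#' @param q q grid (1/A); default 500 linear bins over 0.005-2.5, fine
#'   enough at low q for Guinier analysis of typical protein sizes.
#' @param seed Integer seed; fixed seed gives bit-identical runs.
#' @return A [sec_series()].
#' @export
generate_sec_run <- function(spec, q = seq(0.005, 2.5, length.out = 500),
                             seed = NULL) {
  stopifnot(inherits(spec, "sec_run_spec"))
  tt <- seq(0, spec$run_length, by = spec$frame_interval)
  if (tt[1] == 0) tt <- tt + spec$frame_interval / 2  # frame mid-times
  nt <- length(tt); nq <- length(q)
  Iw <- do.call(water_profile, c(list(q = q), spec$water))$I
  b <- 1 + spec$drift_alpha * tt
  expected <- outer(Iw, b)
  conc <- matrix(0, nt, length(spec$species))
  for (i in seq_along(spec$species)) {
    s <- spec$species[[i]]
    P <- .model_fun(s$model)(q)
    ci <- s$conc * exp(-(tt - s$center)^2 / (2 * s$width^2))
    if (!is.null(s$tau) && s$tau > 0) {
      # exponentially modified Gaussian tailing via discrete convolution
      kern <- exp(-(0:ceiling(5 * s$tau / spec$frame_interval)) *
                    spec$frame_interval / s$tau)
      kern <- kern / sum(kern)
      ci <- stats::filter(c(ci, rep(0, length(kern))), kern,
                          sides = 1)[seq_len(nt)]
      ci[is.na(ci)] <- 0
    }
    conc[, i] <- ci
    expected <- expected + P %o% ci
  }
  scale <- spec$counts_scale / max(Iw)
  lambda <- expected * scale
  counts <- with_seed(seed, matrix(stats::rpois(length(lambda), lambda),
                                   nq, nt))
  frames <- counts / scale
  sigma <- sqrt(pmax(lambda, 1)) / scale
  uv_v <- rep(0, nt)
  for (s in spec$species) {
    eps <- if (is.null(s$uv_eps)) 1 else s$uv_eps
    uv_v <- uv_v + eps * s$conc *
      exp(-((tt - spec$uv_offset) - s$center)^2 / (2 * s$width^2))
  }
  if (spec$uv_noise_sd > 0)
    uv_v <- uv_v + with_seed(if (is.null(seed)) NULL else seed + 1L,
                             stats::rnorm(nt, 0, spec$uv_noise_sd))
  sec_series(frames, q, tt, sigma = sigma,
             uv = data.frame(time = tt, value = uv_v),
             meta = list(spec = spec,
                         truth = list(buffer_matrix = outer(Iw, b),
                                      water = Iw, drift = b, conc = conc,
                                      noise_scale = scale)))
}

#' Dilute protein solution profile with excluded-volume displacement
#'
#' Builds `solution = (1 - phi) * buffer + protein` where
#' `phi = concentration * partial specific volume` is the volume fraction of
#' solvent displaced by the protein. At 5 mg/ml and 0.73 ml/g,
#' `phi = 0.365%`, so the water-peak scale of the solution relative to its
#' buffer deviates from unity by under 0.5%.
#'
#' @param buffer Buffer [xs_profile()].
#' @param protein Protein term as an [xs_profile()] on the same grid (or
#'   function of q).
#' @param concentration Protein concentration, g/ml (default 0.005 = 5 mg/ml).
#' @param specific_volume Partial specific volume, ml/g (default 0.73).
#' @return An [xs_profile()] with `meta$phi`.
#' @export
solution_profile <- function(buffer, protein, concentration = 0.005,
                             specific_volume = 0.73) {
  stopifnot(inherits(buffer, "xs_profile"))
  phi <- concentration * specific_volume
  P <- .model_fun(protein)(buffer$q)
  xs_profile(buffer$q, (1 - phi) * buffer$I + P, buffer$sigma, buffer$n,
             meta = list(label = "solution", phi = phi,
                         concentration = concentration,
                         specific_volume = specific_volume))
}

#' Flow-cell peak broadening model
#'
#' Models the measurement cell as an ideal mixing volume: the injection is a
#' rectangular plug of duration `load_volume / flow_rate`, broadened by the
#' column (Gaussian kernel) and then convolved with an exponential kernel of
#' time constant `cell_volume / flow_rate`. Larger load volumes raise the
#' peak (more sample) and widen it (worse chromatographic resolution); the
#' height gain outruns the width growth over the practical load range.
#'
#' @param column_peak `c(center, width)` of the column's Gaussian broadening,
#'   seconds (width = Gaussian sigma).
#' @param load_volume Sample load volume, ul.
#' @param cell_volume Internal cell volume, ul (default 10).
#' @param flow_rate Flow rate, ul/s (default 5.83, i.e. 0.35 ml/min).
#' @param dt Time step of the numerical convolution, s.
#' @return List with `height_factor` (peak concentration relative to the
#'   injected plug, <= 1), `fwhm` (s), and the `time`/`profile` vectors.
#' @export
flowcell_broadening <- function(column_peak = c(center = 120, width = 5),
                                load_volume = 50, cell_volume = 10,
                                flow_rate = 5.83, dt = 0.01) {
  stopifnot(load_volume > 0, cell_volume >= 0, flow_rate > 0,
            column_peak[2] > 0)
  t_load <- load_volume / flow_rate
  tau <- cell_volume / flow_rate
  half <- column_peak[2] * 8 + t_load + 8 * max(tau, dt)
  tt <- seq(column_peak[1] - half, column_peak[1] + half, by = dt)
  # rect (unit concentration, duration t_load) (x) normalized Gaussian
  prof <- (stats::pnorm(tt, column_peak[1] - t_load / 2, column_peak[2]) -
             stats::pnorm(tt, column_peak[1] + t_load / 2, column_peak[2]))
  if (tau > dt / 10) {
    kern <- exp(-(seq(0, 8 * tau, by = dt)) / tau)
    kern <- kern / sum(kern)
    m <- length(kern)
    padded <- c(rep(0, m - 1), prof)
    y <- stats::filter(padded, kern, sides = 1)
    prof <- as.numeric(y[(m - 1) + seq_along(tt)])
  }
  pk <- max(prof)
  above <- which(prof >= pk / 2)
  list(height_factor = pk, fwhm = (max(above) - min(above)) * dt,
       time = tt, profile = prof)
}
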