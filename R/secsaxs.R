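#' SEC-SAXS frame series
#'
#' Container for an in-line size-exclusion-chromatography scattering run: a
#' time-ordered stack of 1D profiles on a common q grid, per-element
#' uncertainties, frame timestamps, and optional UV / refractive-index
#' detector traces from the split flow.
#'
#' @param frames Numeric matrix, `n_q x n_frames`, intensity.
#' @param q Bin centers (1/A), length `n_q`.
#' @param frame_times Seconds from injection, strictly increasing, length
#'   `n_frames`.
#' @param sigma Matrix of per-element uncertainties (same shape as `frames`);
#'   default 0.
#' @param uv,ri Optional two-column data frames `(time, value)`.
#' @param meta Named list (flow rate, split ratio, generator truth, ...).
#' @return An object of class `"sec_series"`.
#' @export
sec_series <- function(frames, q, frame_times, sigma = NULL, uv = NULL,
                       ri = NULL, meta = list()) {
  frames <- as.matrix(frames)
  if (nrow(frames) != length(q))
    stop("`frames` must have one row per q bin", call. = FALSE)
  if (ncol(frames) != length(frame_times))
    stop("`frames` must have one column per frame time", call. = FALSE)
  if (is.unsorted(frame_times, strictly = TRUE))
    stop("`frame_times` must be strictly increasing", call. = FALSE)
  if (is.null(sigma)) sigma <- matrix(0, nrow(frames), ncol(frames))
  stopifnot(identical(dim(sigma), dim(frames)))
  for (tr in list(uv, ri))
    if (!is.null(tr) && (!is.data.frame(tr) || ncol(tr) < 2L))
      stop("traces must be two-column data frames (time, value)", call. = FALSE)
  structure(list(frames = frames, q = as.numeric(q),
                 frame_times = as.numeric(frame_times), sigma = sigma,
                 uv = uv, ri = ri, meta = meta),
            class = "sec_series")
}

#' @export
print.sec_series <- function(x, ...) {
  cat(sprintf("<sec_series> %d frames x %d q-bins, t in [%.1f, %.1f] s%s%s\n",
              ncol(x$frames), nrow(x$frames), min(x$frame_times),
              max(x$frame_times),
              if (!is.null(x$uv)) ", UV" else "",
              if (!is.null(x$ri)) ", RI" else ""))
  invisible(x)
}

# rows of the q grid inside [lo, hi]
.q_rows <- function(series, rng) {
  rows <- which(series$q >= rng[1] & series$q <= rng[2])
  if (length(rows) == 0L)
    stop(sprintf("empty q-range [%g, %g]", rng[1], rng[2]), call. = FALSE)
  rows
}

#' X-ray chromatograms over user q-ranges
#'
#' For each q-interval, the per-frame mean intensity over bins in the
#' interval versus frame time. Chromatograms at different q-ranges
#' discriminate species with different q-dependences.
#'
#' @param series A [sec_series()].
#' @param q_ranges List of `c(lo, hi)` intervals (1/A), or a string like
#'   `"0.02:0.027,0.05:0.12"`.
#' @return Data frame with `time` and one intensity column per range.
#' @export
xray_chromatogram <- function(series, q_ranges) {
  stopifnot(inherits(series, "sec_series"))
  if (is.character(q_ranges))
    q_ranges <- lapply(strsplit(q_ranges, ",")[[1]], function(s)
      as.numeric(strsplit(trimws(s), ":")[[1]]))
  if (!is.list(q_ranges)) q_ranges <- list(q_ranges)
  out <- data.frame(time = series$frame_times)
  for (rg in q_ranges) {
    rows <- .q_rows(series, rg)
    v <- if (length(rows) == 1L) series$frames[rows, ] else
      colMeans(series$frames[rows, , drop = FALSE])
    out[[sprintf("q%g-%g", rg[1], rg[2])]] <- v
  }
  out
}

#' 2D intensity map (q x time)
#'
#' @param series A [sec_series()].
#' @param log_intensity Return `log10` of positive intensities (non-positive
#'   entries become `NA`).
#' @return An object of class `"sec_map"`: `z` (n_q x n_frames), `q`, `time`.
#'   Its `plot` method draws the map with [graphics::image()].
#' @export
intensity_map <- function(series, log_intensity = FALSE) {
  stopifnot(inherits(series, "sec_series"))
  z <- series$frames
  if (log_intensity) {
    z[z <= 0] <- NA
    z <- log10(z)
  }
  structure(list(z = z, q = series$q, time = series$frame_times,
                 log_intensity = log_intensity), class = "sec_map")
}

#' @export
plot.sec_map <- function(x, ...) {
  graphics::image(x$time, x$q, t(x$z), xlab = "time (s)",
                  ylab = expression(q ~ (ring(A)^-1)),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Time offset between UV trace and X-ray chromatogram
#'
#' The split flow sends the eluent to the UV/RI detectors and the X-ray cell
#' at different rates, so the UV chromatogram lags the X-ray one. The offset
#' is found by maximizing the cross-correlation between the UV trace
#' (resampled to frame times) and the low-q X-ray chromatogram over a grid of
#' lags at the frame interval. A positive offset means the UV peak arrives
#' later.
#'
#' @param series A [sec_series()] with a `uv` trace.
#' @param q_range q-interval for the X-ray chromatogram; default the lowest
#'   10% of the q range.
#' @param max_lag Largest |lag| searched, s; default a third of the run.
#' @param min_cor Minimum peak correlation to accept an alignment; below it a
#'   warning is raised and 0 returned.
#' @return Offset in seconds (UV relative to X-ray).
#' @export
align_uv_offset <- function(series, q_range = NULL, max_lag = NULL,
                            min_cor = 0.5) {
  stopifnot(inherits(series, "sec_series"))
  if (is.null(series$uv)) stop("series has no UV trace", call. = FALSE)
  if (is.null(q_range))
    q_range <- c(min(series$q), min(series$q) + 0.1 * diff(range(series$q)))
  tt <- series$frame_times
  x <- xray_chromatogram(series, list(q_range))[[2]]
  # remove any linear baseline drift so the elution peak drives the correlation
  x <- stats::residuals(stats::lm(x ~ tt))
  dt <- stats::median(diff(tt))
  if (is.null(max_lag)) max_lag <- (max(tt) - min(tt)) / 3
  lags <- seq(-max_lag, max_lag, by = dt)
  uvt <- series$uv[[1]]; uvv <- series$uv[[2]]
  detrend <- function(v, t) stats::.lm.fit(cbind(1, t), v)$residuals
  cors <- vapply(lags, function(L) {
    u <- stats::approx(uvt - L, uvv, xout = tt)$y
    okp <- is.finite(u) & is.finite(x)
    if (sum(okp) < 10L || stats::sd(u[okp]) == 0 || stats::sd(x[okp]) == 0)
      return(NA_real_)
    stats::cor(detrend(x[okp], tt[okp]), detrend(u[okp], tt[okp]))
  }, 0)
  if (all(!is.finite(cors)) || max(cors, na.rm = TRUE) < min_cor) {
    warning("alignment failure: featureless or uncorrelated traces; offset 0",
            call. = FALSE)
    return(0)
  }
  best <- which(cors == max(cors, na.rm = TRUE))
  lags[best[which.min(abs(lags[best]))]]
}

#' Buffer background from selected frames (normal mode)
#'
#' Inverse-variance average of the chosen (pre/post-elution) frames; the
#' conventional SEC-SAXS background when the baseline is stable.
#'
#' @param series A [sec_series()].
#' @param buffer_frames Integer frame indices, non-empty, chosen outside the
#'   elution peaks.
#' @return An [xs_profile()].
#' @export
normal_background <- function(series, buffer_frames) {
  stopifnot(inherits(series, "sec_series"))
  buffer_frames <- as.integer(buffer_frames)
  if (length(buffer_frames) == 0L)
    stop("`buffer_frames` must be non-empty", call. = FALSE)
  if (any(buffer_frames < 1L | buffer_frames > ncol(series$frames)))
    stop("`buffer_frames` out of range", call. = FALSE)
  Im <- series$frames[, buffer_frames, drop = FALSE]
  Sm <- series$sigma[, buffer_frames, drop = FALSE]
  W <- 1 / pmax(Sm, 1e-150)^2
  wsum <- rowSums(W)
  xs_profile(series$q, rowSums(Im * W) / wsum, sqrt(1 / wsum),
             n = rep(length(buffer_frames), length(series$q)),
             meta = list(label = "sec-buffer", mode = "normal",
                         buffer_frames = buffer_frames))
}

#' SVD model of a time-dependent SEC background
#'
#' The user declares a window of frames containing the eluting sample; the
#' remaining frames are decomposed by singular value decomposition, the k
#' most significant components are kept, and each component's time
#' coefficient series (singular value times right singular vector) is
#' interpolated across the excluded window, giving a background estimate
#' `bg(q, t) = sum_i u_i(q) c_i(t)` for every frame. Only frames outside the
#' window ever enter the model. Works identically for increasing and
#' decreasing drifts.
#'
#' @param series A [sec_series()].
#' @param sample_window `c(first, last)` frame indices of the excluded sample
#'   region; must be strictly inside the run with at least 5 frames on each
#'   side.
#' @param rank `"auto"` (components with singular value >= `sv_ratio` of the
#'   largest, capped at `max_rank`) or an integer k >= 1.
#' @param interp `"spline"` (cubic smoothing spline, GCV) or `"linear"`
#'   interpolation of the coefficient series; linear is the fallback for
#'   short runs.
#' @param sv_ratio,max_rank Auto-rank rule parameters.
#' @return An object of class `"sec_background"`: `mode = "svd"`, rank `k`,
#'   q-space basis `u` (n_q x k), full coefficient matrix `coef`
#'   (n_frames x k), the `background` matrix (n_q x n_frames), and the
#'   window.
#' @export
svd_background <- function(series, sample_window, rank = "auto",
                           interp = c("spline", "linear"),
                           sv_ratio = 0.01, max_rank = 5L) {
  stopifnot(inherits(series, "sec_series"), length(sample_window) == 2L)
  interp <- match.arg(interp)
  nt <- ncol(series$frames)
  w1 <- as.integer(sample_window[1]); w2 <- as.integer(sample_window[2])
  if (w1 > w2) stop("invalid sample window", call. = FALSE)
  if (w1 < 6L || w2 > nt - 5L)
    stop("sample window must leave at least 5 frames on each side of the run",
         call. = FALSE)
  win <- w1:w2
  keep <- setdiff(seq_len(nt), win)
  M <- series$frames[, keep, drop = FALSE]
  sv <- svd(M)
  if (identical(rank, "auto")) {
    k <- sum(sv$d >= sv_ratio * sv$d[1])
    k <- max(1L, min(k, max_rank))
  } else {
    k <- as.integer(rank)
    if (k < 1L || k > length(keep))
      stop("rank k must be in [1, number of non-window frames]", call. = FALSE)
  }
  t_all <- series$frame_times
  t_nw <- t_all[keep]
  coef_all <- matrix(0, nt, k)
  for (i in seq_len(k)) {
    ci <- sv$d[i] * sv$v[, i]
    fitted <- NULL
    if (interp == "spline" && length(keep) >= 10L) {
      fitted <- tryCatch(
        stats::predict(stats::smooth.spline(t_nw, ci), t_all)$y,
        error = function(e) NULL)
    }
    if (is.null(fitted))
      fitted <- stats::approx(t_nw, ci, xout = t_all, rule = 2)$y
    # outside the window the observed coefficients are exact projections
    coef_all[, i] <- fitted
    coef_all[keep, i] <- ci
  }
  bg <- sv$u[, seq_len(k), drop = FALSE] %*% t(coef_all)
  if (any(bg < -1e-8 * max(abs(series$frames))) && all(series$frames >= 0))
    warning("reconstructed background has negative entries where raw data are non-negative",
            call. = FALSE)
  structure(list(mode = "svd", k = k, u = sv$u[, seq_len(k), drop = FALSE],
                 d = sv$d[seq_len(k)], coef = coef_all, background = bg,
                 window = c(w1, w2), interp = interp,
                 frame_times = t_all, q = series$q),
            class = "sec_background")
}

#' @export
print.sec_background <- function(x, ...) {
  cat(sprintf("<sec_background> svd mode, rank %d, window frames %d-%d, %s interpolation\n",
              x$k, x$window[1], x$window[2], x$interp))
  invisible(x)
}

#' Subtract an SEC background from a frame series
#'
#' Frame-wise subtraction: in normal mode (background is an [xs_profile()])
#' the same averaged buffer profile is removed from every frame and its
#' uncertainty added in quadrature; in SVD mode the time-dependent background
#' matrix is removed (the smooth model contributes negligible variance, so
#' frame sigmas are kept).
#'
#' @param series A [sec_series()].
#' @param model An [xs_profile()] from [normal_background()] or an
#'   `"sec_background"` from [svd_background()] computed on this series.
#' @return A new [sec_series()] of subtracted frames.
#' @export
subtract_sec_background <- function(series, model) {
  stopifnot(inherits(series, "sec_series"))
  if (inherits(model, "xs_profile")) {
    if (!isTRUE(all.equal(model$q, series$q)))
      stop("background grid does not match the series", call. = FALSE)
    frames <- series$frames - model$I
    sigma <- sqrt(series$sigma^2 + model$sigma^2)
  } else if (inherits(model, "sec_background")) {
    if (!identical(dim(model$background), dim(series$frames)))
      stop("background matrix does not match the series", call. = FALSE)
    frames <- series$frames - model$background
    sigma <- series$sigma
  } else stop("unsupported background model", call. = FALSE)
  sec_series(frames, series$q, series$frame_times, sigma = sigma,
             uv = series$uv, ri = series$ri,
             meta = c(series$meta, list(background_subtracted = TRUE)))
}

#' Extract one frame of a series as a profile
#'
#' @param series A [sec_series()].
#' @param frame Frame index.
#' @return An [xs_profile()].
#' @export
sec_frame_profile <- function(series, frame) {
  stopifnot(inherits(series, "sec_series"))
  frame <- as.integer(frame)
  if (frame < 1L || frame > ncol(series$frames))
    stop("frame index out of range", call. = FALSE)
  xs_profile(series$q, series$frames[, frame], series$sigma[, frame],
             meta = list(label = sprintf("frame %d", frame),
                         time = series$frame_times[frame]))
}
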