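#' 2D detector pattern
#'
#' A detector image with its validity mask, geometry and exposure metadata.
#'
#' @param counts Numeric matrix of photon counts, dimensions equal to
#'   `geometry$shape`.
#' @param geometry An [xs_geometry()].
#' @param mask Logical matrix, `TRUE` = use pixel. Default all `TRUE`.
#' @param exposure Exposure time in seconds.
#' @param label Pattern label.
#' @return An object of class `"xs_pattern"`.
#' @export
xs_pattern <- function(counts, geometry, mask = NULL, exposure = 1,
                       label = "") {
  stopifnot(inherits(geometry, "xs_geometry"))
  counts <- as.matrix(counts)
  if (!identical(dim(counts), as.integer(geometry$shape)))
    stop("`counts` dimensions must equal the detector shape", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(counts), ncol(counts))
  if (!identical(dim(mask), dim(counts)))
    stop("`mask` dimensions must equal the detector shape", call. = FALSE)
  if (any(counts[mask] < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  mask <- mask & is.finite(counts)
  structure(list(counts = counts, mask = mask, geometry = geometry,
                 exposure = exposure, label = label),
            class = "xs_pattern")
}

#' @export
print.xs_pattern <- function(x, ...) {
  cat(sprintf("<xs_pattern '%s'> %d x %d px, %d masked, exposure %.3g s\n",
              x$label, nrow(x$counts), ncol(x$counts), sum(!x$mask), x$exposure))
  invisible(x)
}

#' Read a detector image from TIFF
#'
#' @param path TIFF file (greyscale counts).
#' @inheritParams xs_pattern
#' @return An [xs_pattern()].
#' @export
read_pattern_tiff <- function(path, geometry, mask = NULL, exposure = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF images requires the 'tiff' package", call. = FALSE)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  xs_pattern(img, geometry, mask = mask, exposure = exposure,
             label = basename(path))
}

#' Azimuthal average by q-histogramming
#'
#' Reduces a 2D pattern to a 1D profile: valid pixels are histogrammed on the
#' q grid and each bin takes the plain mean of its pixel counts. Raw counts
#' are treated as Poisson with per-pixel variance `max(counts, 1)`; the bin
#' variance is the summed pixel variance divided by `n^2`. Bins receiving no
#' pixels are flagged empty (never reported as zero).
#'
#' @param pattern An [xs_pattern()].
#' @param qmap Optional [qmap_from_geometry()] result matching the pattern;
#'   computed from the pattern's geometry when omitted.
#' @param q_edges Numeric vector of bin edges (see [q_bin_edges()]). Default:
#'   `n_bins` linear bins spanning the valid-pixel q range.
#' @param n_bins Number of linear bins when `q_edges` is not given.
#' @param normalize If `TRUE`, divide intensities (and sigmas) by the
#'   exposure time, yielding counts per pixel per second.
#' @return An [xs_profile()].
#' @export
azimuthal_average <- function(pattern, qmap = NULL, q_edges = NULL,
                              n_bins = 690L, normalize = FALSE) {
  stopifnot(inherits(pattern, "xs_pattern"))
  if (is.null(qmap)) qmap <- qmap_from_geometry(pattern$geometry)
  if (!identical(dim(qmap$q), dim(pattern$counts)))
    stop("q-map shape does not match the pattern", call. = FALSE)
  use <- as.vector(pattern$mask & qmap$mask)
  if (!any(use)) stop("fully masked pattern: empty profile", call. = FALSE)
  qv <- as.vector(qmap$q)[use]
  xv <- as.vector(pattern$counts)[use]
  if (is.null(q_edges)) q_edges <- q_bin_edges(min(qv), max(qv), n_bins)
  nb <- length(q_edges) - 1L
  bin <- findInterval(qv, q_edges, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= nb
  bin <- bin[keep]; xv <- xv[keep]
  n <- tabulate(bin, nb)
  s <- v <- numeric(nb)
  rs <- rowsum(cbind(xv, pmax(xv, 1)), bin)
  idx <- as.integer(rownames(rs))
  s[idx] <- rs[, 1]; v[idx] <- rs[, 2]
  I <- ifelse(n > 0, s / pmax(n, 1L), NA_real_)
  sig <- ifelse(n > 0, sqrt(v) / pmax(n, 1L), NA_real_)
  if (normalize) { I <- I / pattern$exposure; sig <- sig / pattern$exposure }
  xs_profile(q = (q_edges[-1] + q_edges[-(nb + 1L)]) / 2, I = I, sigma = sig,
             n = n,
             meta = list(label = pattern$geometry$label, scale = 1,
                         grid = "linear", exposure = pattern$exposure,
                         normalized = normalize))
}

#' Inter-detector merge scale factor
#'
#' Detectors built from identical modules share the same sensitivity, so
#' profiles are put on a common scale strictly by the per-pixel solid-angle
#' ratio `(distance / distance_ref)^2`.
#'
#' @param det_geom,ref_geom [xs_geometry()] of the detector and the reference
#'   detector (same pixel size).
#' @return Dimensionless scale; 1 for identical distances.
#' @export
merge_scale_factor <- function(det_geom, ref_geom) {
  stopifnot(inherits(det_geom, "xs_geometry"), inherits(ref_geom, "xs_geometry"))
  if (abs(det_geom$pixel_size - ref_geom$pixel_size) >
      1e-9 * ref_geom$pixel_size)
    stop("merge scaling assumes identical pixel size across detectors",
         call. = FALSE)
  (det_geom$distance / ref_geom$distance)^2
}

#' Multi-detector configuration
#'
#' @param geometries List of [xs_geometry()] with unique labels.
#' @param reference Label of the reference detector for merge scaling.
#' @return An object of class `"xs_detconfig"`.
#' @export
detector_config <- function(geometries, reference = geometries[[1]]$label) {
  labs <- vapply(geometries, function(g) g$label, "")
  if (anyDuplicated(labs)) stop("detector labels must be unique", call. = FALSE)
  if (!reference %in% labs) stop("unknown reference detector", call. = FALSE)
  structure(list(geometries = stats::setNames(geometries, labs),
                 reference = reference), class = "xs_detconfig")
}

#' Merge profiles from several detectors
#'
#' Each profile is multiplied by its [merge_scale_factor()] (when a
#' `config` is supplied and the profile's `meta$label` matches a detector),
#' interpolated onto a common output grid, and combined by
#' inverse-variance-weighted averaging where detectors overlap. The output
#' spans the union of the input q ranges; an overlap discrepancy statistic
#' (mean |dI|/sigma over overlap bins) is recorded per pair and a warning is
#' raised above 3. Disjoint inputs produce gap bins flagged empty plus a gap
#' note in the provenance.
#'
#' @param profiles List of [xs_profile()].
#' @param config Optional [detector_config()] providing distances for
#'   scaling.
#' @param q_out Output bin centers. Default: the common input grid if all
#'   inputs share one, otherwise a linear grid over the union of ranges with
#'   the finest input spacing.
#' @return An [xs_profile()]; `meta$overlap_discrepancy` holds the pairwise
#'   statistics and `meta$gaps` any gap note.
#' @export
merge_profiles <- function(profiles, config = NULL, q_out = NULL) {
  stopifnot(length(profiles) >= 2L,
            all(vapply(profiles, inherits, TRUE, "xs_profile")))
  scales <- rep(1, length(profiles))
  if (!is.null(config)) {
    stopifnot(inherits(config, "xs_detconfig"))
    ref <- config$geometries[[config$reference]]
    for (i in seq_along(profiles)) {
      lab <- profiles[[i]]$meta$label
      if (!is.null(lab) && lab %in% names(config$geometries))
        scales[i] <- merge_scale_factor(config$geometries[[lab]], ref)
    }
  }
  scaled <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    p$I <- p$I * scales[i]; p$sigma <- p$sigma * scales[i]
    p$meta$scale <- scales[i]
    p
  })
  if (is.null(q_out)) {
    grids <- lapply(scaled, `[[`, "q")
    if (all(vapply(grids[-1], function(g)
      length(g) == length(grids[[1]]) && isTRUE(all.equal(g, grids[[1]])),
      TRUE))) {
      q_out <- grids[[1]]
    } else {
      dq <- min(vapply(grids, function(g) stats::median(diff(g)), 0))
      lo <- min(vapply(grids, min, 0)); hi <- max(vapply(grids, max, 0))
      q_out <- seq(lo, hi, length.out = max(2L, ceiling((hi - lo) / dq) + 1L))
    }
  }
  k <- length(scaled); nb <- length(q_out)
  Im <- Sm <- Nm <- matrix(NA_real_, nb, k)
  for (i in seq_len(k)) {
    ip <- .interp_profile(scaled[[i]], q_out)
    Im[, i] <- ip$I; Sm[, i] <- ip$sigma; Nm[, i] <- ip$n
  }
  W <- 1 / pmax(Sm, 1e-150)^2
  W[!is.finite(Im)] <- 0
  Iz <- Im; Iz[!is.finite(Im)] <- 0
  wsum <- rowSums(W)
  I <- ifelse(wsum > 0, rowSums(Iz * W) / wsum, NA_real_)
  sig <- ifelse(wsum > 0, sqrt(1 / wsum), NA_real_)
  n <- rowSums(Nm, na.rm = TRUE)
  n[wsum == 0] <- 0
  disc <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    both <- is.finite(Im[, i]) & is.finite(Im[, j])
    if (any(both)) {
      d <- mean(abs(Im[both, i] - Im[both, j]) /
                  sqrt(Sm[both, i]^2 + Sm[both, j]^2 + 1e-300))
      disc[[sprintf("%d-%d", i, j)]] <- d
      if (is.finite(d) && d > 3)
        warning(sprintf("merge overlap discrepancy %.2f sigma between profiles %d and %d",
                        d, i, j), call. = FALSE)
    } else disc[[sprintf("%d-%d", i, j)]] <- NA_real_
  }
  gaps <- NULL
  if (any(wsum == 0)) {
    gaps <- sprintf("%d gap bins with no detector coverage", sum(wsum == 0))
    warning(gaps, call. = FALSE)
  }
  xs_profile(q_out, I, sig, n,
             meta = list(label = "merged", scales = scales,
                         overlap_discrepancy = disc, gaps = gaps))
}

#' Average repeated exposures with outlier exclusion
#'
#' Inverse-variance-weighted mean of frames sharing one q grid; frames listed
#' in `exclude` (e.g. a first exposure showing radiation-damage or mixing
#' artifacts) are dropped and recorded in the provenance.
#'
#' @param profiles List of [xs_profile()] on a common grid.
#' @param exclude Integer indices of frames to exclude.
#' @return An [xs_profile()] with `meta$excluded_frames`.
#' @export
average_profiles <- function(profiles, exclude = integer(0)) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "xs_profile")))
  keep <- setdiff(seq_along(profiles), exclude)
  if (length(keep) == 0L) stop("all frames excluded", call. = FALSE)
  q <- profiles[[1]]$q
  for (p in profiles)
    if (!isTRUE(all.equal(p$q, q)))
      stop("profiles must share a common q grid", call. = FALSE)
  Im <- sapply(profiles[keep], `[[`, "I")
  Sm <- sapply(profiles[keep], `[[`, "sigma")
  Nm <- sapply(profiles[keep], `[[`, "n")
  W <- 1 / pmax(Sm, 1e-150)^2
  W[!is.finite(Im)] <- 0
  Iz <- Im; Iz[!is.finite(Im)] <- 0
  wsum <- rowSums(W)
  I <- ifelse(wsum > 0, rowSums(Iz * W) / wsum, NA_real_)
  sig <- ifelse(wsum > 0, sqrt(1 / wsum), NA_real_)
  xs_profile(q, I, sig, rowSums(Nm, na.rm = TRUE),
             meta = list(label = profiles[[keep[1]]]$meta$label,
                         excluded_frames = exclude,
                         n_frames = length(keep)))
}
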