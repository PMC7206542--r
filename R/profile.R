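#' One-dimensional scattering profile I(q)
#'
#' The universal 1D record of the pipeline: a strictly increasing q grid of
#' bin centers, mean intensity per bin, propagated uncertainty, contributing
#' pixel (or frame) counts, and an explicit empty-bin flag. Empty bins carry
#' `NA` intensity and are never exported as zeros.
#'
#' @param q Bin centers in 1/Angstrom, strictly increasing.
#' @param I Mean intensity per bin (arbitrary units).
#' @param sigma Per-bin uncertainty (>= 0 where defined).
#' @param n Contributing pixel/frame count per bin.
#' @param meta Named list of provenance metadata (detector label, applied
#'   scale factor, grid type, ...).
#' @return An object of class `"xs_profile"`.
#' @export
xs_profile <- function(q, I, sigma = rep(0, length(q)), n = rep(1L, length(q)),
                       meta = list()) {
  q <- as.numeric(q); I <- as.numeric(I); sigma <- as.numeric(sigma)
  stopifnot(length(I) == length(q), length(sigma) == length(q),
            length(n) == length(q))
  if (length(q) < 1L || is.unsorted(q, strictly = TRUE))
    stop("`q` must be non-empty and strictly increasing", call. = FALSE)
  empty <- n <= 0 | !is.finite(I)
  I[empty] <- NA_real_; sigma[empty] <- NA_real_
  if (any(sigma[!empty] < 0)) stop("`sigma` must be >= 0", call. = FALSE)
  structure(list(q = q, I = I, sigma = sigma, n = as.numeric(n),
                 empty = empty, meta = meta),
            class = "xs_profile")
}

#' @export
print.xs_profile <- function(x, ...) {
  ok <- !x$empty
  cat(sprintf("<xs_profile> %d bins (%d empty), q in [%.4g, %.4g] 1/A\n",
              length(x$q), sum(x$empty), min(x$q), max(x$q)))
  if (any(ok))
    cat(sprintf("  I in [%.4g, %.4g]%s\n", min(x$I[ok]), max(x$I[ok]),
                if (length(x$meta$label)) paste0("  [", x$meta$label, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.xs_profile <- function(x, ...) {
  data.frame(q = x$q, I = x$I, sigma = x$sigma, n = x$n, empty = x$empty)
}

#' @export
plot.xs_profile <- function(x, log = "y", ...) {
  ok <- !x$empty & if (grepl("y", log)) x$I > 0 else TRUE
  graphics::plot(x$q[ok], x$I[ok], type = "l", log = log,
                 xlab = expression(q ~ (ring(A)^-1)), ylab = "I(q)", ...)
  invisible(x)
}

# linear interpolation of a profile onto new q values; NA outside its range
.interp_profile <- function(p, q_out) {
  ok <- !p$empty
  if (sum(ok) < 2L) stop("profile has fewer than 2 non-empty bins", call. = FALSE)
  I <- stats::approx(p$q[ok], p$I[ok], xout = q_out)$y
  s <- stats::approx(p$q[ok], p$sigma[ok], xout = q_out)$y
  n <- stats::approx(p$q[ok], p$n[ok], xout = q_out)$y
  list(I = I, sigma = s, n = n)
}

#' Linear q-bin edges
#'
#' @param qmin,qmax Range in 1/Angstrom.
#' @param n Number of bins (default 690).
#' @return Numeric vector of `n + 1` edges.
#' @export
q_bin_edges <- function(qmin, qmax, n = 690L) {
  stopifnot(qmax > qmin, n >= 1L)
  seq(qmin, qmax, length.out = n + 1L)
}

#' Export a profile as a three-column ASCII file
#'
#' Writes whitespace-delimited `q I sigma` rows preceded by `#` header lines
#' carrying the wavelength, per-detector distances and sample/buffer names, a
#' format readable by common SAXS analysis tools. Empty bins are omitted.
#'
#' @param profile An [xs_profile()].
#' @param path Output file.
#' @param sample,buffer Sample and buffer names for the header.
#' @param geometry An [xs_geometry()] or list of them, for wavelength and
#'   distance header lines.
#' @return `path`, invisibly.
#' @export
export_ascii <- function(profile, path, sample = "sample", buffer = NA,
                         geometry = NULL) {
  stopifnot(inherits(profile, "xs_profile"))
  ok <- !profile$empty
  if (!any(ok)) stop("profile has no non-empty bins", call. = FALSE)
  hdr <- c(sprintf("# sample: %s", sample),
           if (!is.na(buffer)) sprintf("# buffer: %s", buffer))
  geoms <- if (inherits(geometry, "xs_geometry")) list(geometry) else geometry
  for (g in geoms) {
    hdr <- c(hdr,
             sprintf("# wavelength_A: %.6f", g$wavelength),
             sprintf("# detector %s distance_mm: %.4f", g$label, g$distance))
  }
  hdr <- c(hdr, "# columns: q(1/A) I sigma")
  rows <- sprintf("%.6e %.6e %.6e", profile$q[ok], profile$I[ok], profile$sigma[ok])
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a three-column ASCII profile
#'
#' @param path File written by [export_ascii()] (or any `q I sigma` table
#'   with `#` comments).
#' @return An [xs_profile()]; header lines are kept in `meta$header`.
#' @export
read_ascii <- function(path) {
  ln <- readLines(path, warn = FALSE)
  hdr <- ln[startsWith(trimws(ln), "#")]
  dat <- ln[!startsWith(trimws(ln), "#") & nzchar(trimws(ln))]
  m <- do.call(rbind, lapply(strsplit(trimws(dat), "[ \t]+"), as.numeric))
  if (is.null(m) || ncol(m) < 2L) stop("no data rows in ", path, call. = FALSE)
  xs_profile(m[, 1], m[, 2],
             sigma = if (ncol(m) >= 3L) m[, 3] else rep(0, nrow(m)),
             meta = list(header = hdr))
}
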