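#' Pack processed records into a portable text bundle
#'
#' Writes a per-experiment bundle as a directory: `bundle.json` holds the
#' metadata tree (per-sample attributes including the matching buffer name,
#' holder and channel, plus the instrument group with each detector's
#' distance, wavelength, beam center and pixel size), and each sample's
#' arrays live under `samples/<name>/` as whitespace-delimited text written
#' at full double precision (`%.17g`), so read-back is bit-exact. SEC records
#' store the frame matrix, frame times and UV/RI traces under the sample's
#' `sec` group.
#'
#' @param records Named list; each element is a list with any of:
#'   `processed` (an [xs_profile()]), `buffer_name`, `holder`, `channel`,
#'   `sec` (a [sec_series()]).
#' @param path Bundle directory to create.
#' @param instrument Optional [detector_config()] stored in the instrument
#'   group.
#' @param overwrite Replace an existing bundle directory.
#' @return `path`, invisibly.
#' @export
pack_bundle <- function(records, path, instrument = NULL, overwrite = FALSE) {
  nm <- names(records)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("`records` must be a named list of sample records", call. = FALSE)
  if (anyDuplicated(nm)) stop("sample names must be unique", call. = FALSE)
  if (dir.exists(path)) {
    if (!overwrite) stop("bundle ", path, " exists (use overwrite = TRUE)",
                         call. = FALSE)
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  meta <- list(format = "saxsred-bundle", version = 1L, samples = list())
  if (!is.null(instrument)) {
    meta$instrument <- lapply(instrument$geometries, function(g)
      list(label = g$label, distance_mm = g$distance,
           wavelength_A = g$wavelength, energy_keV = g$energy,
           beam_center = g$beam_center, pixel_size_mm = g$pixel_size,
           shape = g$shape))
    meta$reference_detector <- instrument$reference
  }
  wtab <- function(m, file) {
    m <- as.matrix(m)
    writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                             collapse = " ")), file)
  }
  for (s in nm) {
    rec <- records[[s]]
    sdir <- file.path(path, "samples", s)
    dir.create(sdir, recursive = TRUE)
    attrs <- list(buffer_name = rec$buffer_name, holder = rec$holder,
                  channel = rec$channel)
    attrs <- attrs[!vapply(attrs, is.null, TRUE)]
    meta$samples[[s]] <- attrs
    if (!is.null(rec$processed)) {
      p <- rec$processed
      wtab(cbind(p$q, ifelse(p$empty, NaN, p$I), ifelse(p$empty, NaN, p$sigma),
                 p$n), file.path(sdir, "processed.dat"))
    }
    if (!is.null(rec$sec)) {
      sec <- rec$sec
      wtab(sec$frames, file.path(sdir, "sec_frames.dat"))
      wtab(sec$sigma, file.path(sdir, "sec_sigma.dat"))
      wtab(cbind(sec$frame_times), file.path(sdir, "sec_times.dat"))
      wtab(cbind(sec$q), file.path(sdir, "sec_q.dat"))
      if (!is.null(sec$uv)) wtab(as.matrix(sec$uv[, 1:2]),
                                 file.path(sdir, "sec_uv.dat"))
      if (!is.null(sec$ri)) wtab(as.matrix(sec$ri[, 1:2]),
                                 file.path(sdir, "sec_ri.dat"))
    }
  }
  jsonlite::write_json(meta, file.path(path, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a bundle written by [pack_bundle()]
#'
#' @param path Bundle directory.
#' @return List with `meta` (the metadata tree) and `samples`, a named list
#'   whose elements carry the stored attributes plus `processed`
#'   ([xs_profile()]) and/or `sec` ([sec_series()]).
#' @export
read_bundle <- function(path) {
  jf <- file.path(path, "bundle.json")
  if (!file.exists(jf)) stop("not a bundle: ", path, call. = FALSE)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  rtab <- function(file) {
    if (!file.exists(file)) return(NULL)
    m <- do.call(rbind, lapply(strsplit(readLines(file), " ", fixed = TRUE),
                               as.numeric))
    m
  }
  samples <- list()
  snames <- names(meta$samples)
  for (s in snames) {
    sdir <- file.path(path, "samples", s)
    rec <- as.list(meta$samples[[s]])
    pr <- rtab(file.path(sdir, "processed.dat"))
    if (!is.null(pr))
      rec$processed <- xs_profile(pr[, 1], pr[, 2], pr[, 3], pr[, 4],
                                  meta = list(label = s))
    fr <- rtab(file.path(sdir, "sec_frames.dat"))
    if (!is.null(fr)) {
      uv <- rtab(file.path(sdir, "sec_uv.dat"))
      ri <- rtab(file.path(sdir, "sec_ri.dat"))
      rec$sec <- sec_series(
        fr, rtab(file.path(sdir, "sec_q.dat"))[, 1],
        rtab(file.path(sdir, "sec_times.dat"))[, 1],
        sigma = rtab(file.path(sdir, "sec_sigma.dat")),
        uv = if (!is.null(uv)) data.frame(time = uv[, 1], value = uv[, 2]),
        ri = if (!is.null(ri)) data.frame(time = ri[, 1], value = ri[, 2]))
    }
    samples[[s]] <- rec
  }
  list(meta = meta, samples = samples)
}
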