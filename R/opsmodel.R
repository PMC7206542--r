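#' Beam and flow-cell conditions
#'
#' Defaults are the beamline's typical operating point: flux 2.3e12
#' photons/s at 13.5 keV, a 0.5 x 0.5 mm beam, a 1.5 mm water path, 1 s
#' exposure, 10 ul/s flow through a 1 mm^2 channel.
#'
#' @param flux Photon flux, photons/s.
#' @param energy Photon energy, keV.
#' @param beam_w,beam_h Beam width and height, mm.
#' @param path Sample path length along the beam, mm.
#' @param exposure Exposure time, s.
#' @param flow_rate Sample flow rate, ul/s.
#' @param cross_section Flow-channel cross-section, mm^2.
#' @return An object of class `"beam_conditions"`.
#' @export
beam_conditions <- function(flux = 2.3e12, energy = 13.5, beam_w = 0.5,
                            beam_h = 0.5, path = 1.5, exposure = 1,
                            flow_rate = 10, cross_section = 1) {
  vals <- c(flux, energy, beam_w, beam_h, path, exposure, flow_rate,
            cross_section)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all beam conditions must be positive", call. = FALSE)
  structure(list(flux = flux, energy = energy, beam_w = beam_w,
                 beam_h = beam_h, path = path, exposure = exposure,
                 flow_rate = flow_rate, cross_section = cross_section),
            class = "beam_conditions")
}

# NIST mass energy-absorption coefficients mu_en/rho for liquid water
# (Hubbell & Seltzer, NIST SRD 126), cm^2/g, log-log interpolated.
.mu_en_water_table <- data.frame(energy_keV = c(10, 15, 20),
                                 mu_en_rho = c(4.944, 1.374, 0.5503))

#' Water mass energy-absorption coefficient
#'
#' Log-log interpolation of the NIST (Hubbell & Seltzer) mu_en/rho
#' tabulation for liquid water at 10, 15 and 20 keV; extrapolation outside
#' that range raises a warning.
#'
#' @param energy Photon energy, keV.
#' @return mu_en/rho in cm^2/g.
#' @export
mu_en_water <- function(energy) {
  stopifnot(is.numeric(energy), all(energy > 0))
  tb <- .mu_en_water_table
  if (any(energy < min(tb$energy_keV) | energy > max(tb$energy_keV)))
    warning("energy outside the 10-20 keV tabulation; log-log extrapolation",
            call. = FALSE)
  exp(stats::approx(log(tb$energy_keV), log(tb$mu_en_rho), xout = log(energy),
                    rule = 2)$y)
}

.keV_J <- 1.602176634e-16  # J per keV

# absorbed beam energy in J over one exposure
.absorbed_energy_J <- function(b, mu) {
  frac <- 1 - exp(-mu * (b$path / 10))       # rho = 1 g/cm^3, path in cm
  b$flux * b$energy * .keV_J * frac * b$exposure
}

#' Absorbed dose for a static (non-flowing) sample
#'
#' Dose = absorbed beam energy / mass of the illuminated water column, with
#' the absorbed fraction `1 - exp(-mu_en rho t)` from the tabulated water
#' energy-absorption coefficient. At the default conditions this evaluates
#' to about 3.3 kGy per 1 s exposure.
#'
#' @param b A [beam_conditions()].
#' @param mu_en_over_rho Water mass energy-absorption coefficient, cm^2/g;
#'   default interpolated from the packaged NIST tabulation at `b$energy`.
#' @return Dose in kGy.
#' @export
dose_static <- function(b = beam_conditions(),
                        mu_en_over_rho = mu_en_water(b$energy)) {
  stopifnot(inherits(b, "beam_conditions"))
  E <- .absorbed_energy_J(b, mu_en_over_rho)
  vol_ul <- b$beam_w * b$beam_h * b$path      # mm^3 = ul
  mass_kg <- vol_ul * 1e-6                    # water, 1 g/ml
  E / mass_kg / 1000
}

#' Absorbed dose for a flowing sample
#'
#' The same absorbed energy is spread uniformly over the mass that traverses
#' the beam during the exposure plus the initially illuminated volume:
#' `dose = E_abs / (rho (flow_rate * exposure + V_illuminated))`. In the
#' zero-flow limit this equals [dose_static()]. The uniform-absorption
#' assumption is attached to the result as attribute `"assumption"`.
#'
#' @inheritParams dose_static
#' @return Dose in kGy, with an `"assumption"` attribute.
#' @export
dose_flowing <- function(b = beam_conditions(),
                         mu_en_over_rho = mu_en_water(b$energy)) {
  stopifnot(inherits(b, "beam_conditions"))
  E <- .absorbed_energy_J(b, mu_en_over_rho)
  vol_ul <- b$flow_rate * b$exposure + b$beam_w * b$beam_h * b$path
  structure(E / (vol_ul * 1e-6) / 1000,
            assumption = "uniform absorption over flowed + illuminated water volume")
}

#' PEEK tubing internal volume and transit time
#'
#' @param length_m Tubing length, m.
#' @param inner_diameter_in Inner diameter, inch.
#' @param flow_ml_min Flow rate, ml/min.
#' @return List with `volume_ul` (= pi (d/2)^2 L) and `transit_s`
#'   (= volume / flow).
#' @examples
#' tubing_metrics(1, 0.01, 0.5)  # ~50.7 ul, ~6.1 s
#' @export
tubing_metrics <- function(length_m = 1, inner_diameter_in = 0.01,
                           flow_ml_min = 0.5) {
  stopifnot(length_m >= 0, inner_diameter_in > 0, flow_ml_min > 0)
  d_mm <- inner_diameter_in * 25.4
  vol_ul <- pi * (d_mm / 2)^2 * length_m * 1000   # mm^3 = ul
  flow_ul_s <- flow_ml_min * 1000 / 60
  list(volume_ul = vol_ul, transit_s = vol_ul / flow_ul_s)
}

#' Dual-channel sample-handler schedule simulation
#'
#' Event-driven simulation of the static measurement cycle. Each sample
#' needs a clean flow channel for its load/measure/return block (duration
#' `measure`), which also occupies the beam; washing/drying (`wash`) then
#' frees the channel. With one channel the cycle is `measure + wash`; with
#' two channels (staggered rows, two injection needles) one channel washes
#' while the other measures, so the steady-state cycle is
#' `max(measure, wash)` - about 40% shorter at the typical 90 s / 60 s
#' timings. An optional holder-exchange overhead is inserted every
#' `holder_size` samples.
#'
#' @param measure Load + measure + return block per sample, s.
#' @param wash Wash + dry per channel, s.
#' @param n_samples Number of samples.
#' @param n_channels 1 (sequential) or 2 (concurrent).
#' @param exchange Robot holder-exchange time inserted every `holder_size`
#'   samples, s (default 0).
#' @param holder_size Samples per holder (default 18).
#' @return List with `makespan_s` (end of the last measurement),
#'   `makespan_h`, and `cycle_s` (steady-state per-sample cycle).
#' @export
schedule_sim <- function(measure = 90, wash = 60, n_samples = 360,
                         n_channels = 2, exchange = 0, holder_size = 18) {
  stopifnot(measure > 0, wash >= 0, n_samples >= 1, n_channels %in% 1:2)
  channel_ready <- rep(0, n_channels)
  beam_free <- 0
  starts <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    ch <- ((i - 1) %% n_channels) + 1
    st <- max(beam_free, channel_ready[ch])
    starts[i] <- st
    beam_free <- st + measure
    channel_ready[ch] <- st + measure + wash
    if (exchange > 0 && i %% holder_size == 0) beam_free <- beam_free + exchange
  }
  makespan <- starts[n_samples] + measure
  # steady-state per-sample cycle, averaged over one channel rotation (the
  # last-start difference alternates when wash exceeds measure)
  cycle <- if (n_samples > n_channels)
    (starts[n_samples] - starts[n_samples - n_channels]) / n_channels
  else makespan / n_samples
  list(makespan_s = makespan, makespan_h = makespan / 3600, cycle_s = cycle)
}

#' SEC run duration from column bed volume
#'
#' The run time corresponds to about twice the column bed volume, to avoid
#' interference between consecutive injections on a shared column.
#'
#' @param bed_volume_ml Column bed volume, ml.
#' @param flow_ml_min Flow rate, ml/min.
#' @return Duration in minutes (`2 * bed / flow`).
#' @export
sec_run_duration <- function(bed_volume_ml, flow_ml_min) {
  stopifnot(bed_volume_ml > 0, flow_ml_min > 0)
  2 * bed_volume_ml / flow_ml_min
}

#' Read a sample sheet from CSV
#'
#' Expects columns `holder, position, row, name, buffer, is_buffer,
#' concentration, volume` (holder positions 1-18, rows A/B; `buffer` names
#' the matching buffer tube for protein samples). An optional second CSV
#' maps holders to storage slots (columns `holder, slot`, slots 1-20).
#'
#' @param path Holders CSV.
#' @param config_path Optional storage-configuration CSV.
#' @return An object of class `"sample_sheet"`.
#' @export
read_sample_sheet <- function(path, config_path = NULL) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("unparseable sample sheet ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  need <- c("holder", "position", "row", "name", "buffer", "is_buffer")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  cfg <- NULL
  if (!is.null(config_path)) {
    cfg <- utils::read.csv(config_path, stringsAsFactors = FALSE)
    if (!all(c("holder", "slot") %in% names(cfg)))
      stop("storage configuration needs columns holder, slot", call. = FALSE)
  }
  sample_sheet(df, cfg)
}

#' Construct a sample sheet
#'
#' @param holders Data frame with columns `holder, position, row, name,
#'   buffer, is_buffer` (plus optional `concentration`, `volume`).
#' @param config Optional data frame `holder, slot` (storage slots, max 20).
#' @return An object of class `"sample_sheet"`.
#' @export
sample_sheet <- function(holders, config = NULL) {
  stopifnot(is.data.frame(holders))
  holders$is_buffer <- as.logical(holders$is_buffer)
  structure(list(holders = holders, config = config), class = "sample_sheet")
}

#' Validate a sample sheet
#'
#' Enumerates scheduling violations: duplicate tube names; protein samples
#' whose named buffer is absent; sample and matching buffer assigned to
#' different rows (each row feeds one flow channel, and a sample must be
#' measured in the same channel as its buffer); duplicate positions within a
#' holder, positions outside 1-18, invalid rows; and storage-slot conflicts
#' (duplicate slots, slots outside 1-20). An empty sheet passes trivially.
#' The violation set is independent of row order.
#'
#' @param sheet A [sample_sheet()].
#' @param n_positions Positions per holder (default 18).
#' @param n_slots Storage slots (default 20).
#' @return Data frame with columns `type` and `detail` (zero rows if valid),
#'   sorted canonically.
#' @export
validate_sample_sheet <- function(sheet, n_positions = 18, n_slots = 20) {
  stopifnot(inherits(sheet, "sample_sheet"))
  h <- sheet$holders
  v <- list()
  add <- function(type, detail) v[[length(v) + 1]] <<- data.frame(
    type = type, detail = detail, stringsAsFactors = FALSE)
  if (nrow(h) > 0) {
    dup <- unique(h$name[duplicated(h$name)])
    for (d in dup) add("duplicate_name", sprintf("tube name '%s' appears %d times",
                                                 d, sum(h$name == d)))
    for (hid in unique(h$holder)) {
      sub <- h[h$holder == hid, ]
      dp <- unique(sub$position[duplicated(sub$position)])
      for (p in dp) add("duplicate_position",
                        sprintf("holder %s position %s occupied more than once", hid, p))
      bad <- sub$position[sub$position < 1 | sub$position > n_positions]
      for (p in bad) add("invalid_position",
                         sprintf("holder %s position %s outside 1-%d", hid, p, n_positions))
    }
    badrow <- unique(h$row[!h$row %in% c("A", "B")])
    for (r in badrow) add("invalid_row", sprintf("row '%s' is not A or B", r))
    prot <- h[!h$is_buffer, , drop = FALSE]
    for (i in seq_len(nrow(prot))) {
      bn <- prot$buffer[i]
      if (is.na(bn) || !nzchar(bn)) {
        add("missing_buffer", sprintf("sample '%s' has no buffer assigned", prot$name[i]))
        next
      }
      j <- which(h$name == bn & h$is_buffer)
      if (length(j) == 0L) {
        add("missing_buffer", sprintf("buffer '%s' for sample '%s' not found",
                                      bn, prot$name[i]))
      } else if (!prot$row[i] %in% h$row[j]) {
        add("channel_mismatch",
            sprintf("sample '%s' (row %s) and buffer '%s' (row %s) use different channels",
                    prot$name[i], prot$row[i], bn,
                    paste(unique(h$row[j]), collapse = "/")))
      }
    }
  }
  cfg <- sheet$config
  if (!is.null(cfg) && nrow(cfg) > 0) {
    ds <- unique(cfg$slot[duplicated(cfg$slot)])
    for (s in ds) add("slot_conflict", sprintf("storage slot %s assigned more than once", s))
    bad <- cfg$slot[cfg$slot < 1 | cfg$slot > n_slots]
    for (s in bad) add("invalid_slot", sprintf("slot %s outside 1-%d", s, n_slots))
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(type = character(0), detail = character(0))
  out[order(out$type, out$detail), , drop = FALSE]
}

#' Detect sample arrival from a camera-statistic trace
#'
#' The liquid-air interface entering the cell scatters visible light and
#' produces a pulse in the camera's frame statistic. Arrival is the first
#' index where the trace exceeds `median + k * MAD` for at least `sustain`
#' consecutive points.
#'
#' @param trace Numeric time series of the image statistic (length >= 10).
#' @param k Threshold in robust sigmas (default 6).
#' @param sustain Required consecutive above-threshold points (default 2).
#' @return First arrival index, or `NA_integer_` if no sustained pulse.
#' @export
detect_sample_arrival <- function(trace, k = 6, sustain = 2L) {
  if (!is.numeric(trace) || length(trace) < 10L)
    stop("`trace` must be numeric with at least 10 points", call. = FALSE)
  med <- stats::median(trace)
  scatter <- stats::mad(trace)
  if (scatter <= 0) scatter <- 1e-12
  above <- trace > med + k * scatter
  run <- rle(above)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= sustain)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(ends[hit[1]] - run$lengths[hit[1]] + 1L)
}
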