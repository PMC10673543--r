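# Ratiometric calibration: the monotone map between the 4.2/5.5 ppm
# contrast-difference ratio and pH for iopamidol under a given protocol.
#
# The pH dependence enters through base-catalysed amide exchange, modeled as
# a log-linear rate law k(pH) = k_ref * 10^(eta * (pH - pH_ref)). The
# constants below are package defaults with the correct monotone structure,
# not measured values; they are regenerated into a calibration curve by the
# same forward physics that drives the phantom generator, so that pH
# recovery is an internally consistent, testable loop.

#' Iopamidol two-site exchange model
#'
#' Iopamidol carries two amide resonances, at 4.2 ppm (two protons) and
#' 5.5 ppm (one proton), whose exchange rates increase with pH. Each site
#' follows `rate = k_ref * 10^(eta * (pH - pH_ref))`.
#'
#' @param k_ref_42,k_ref_55 Exchange rates (1/s) at `ph_ref` for the 4.2 and
#'   5.5 ppm sites. Defaults 500 and 2000: package defaults, not measured
#'   values.
#' @param eta_42,eta_55 pH sensitivity exponents (default 1).
#' @param ph_ref Reference pH (default 7.0).
#' @param concentration_mM Agent concentration in tissue (default 10 mM).
#' @param protons Protons per molecule at each site, `c(site42, site55)`.
#' @param T1,T2 Relaxation times (s) of the amide protons.
#' @return Object of class `iopamidol_model`.
#' @export
iopamidol_model <- function(k_ref_42 = 500, k_ref_55 = 2000,
                            eta_42 = 1, eta_55 = 1, ph_ref = 7.0,
                            concentration_mM = 10, protons = c(2, 1),
                            T1 = 1.0, T2 = 0.01) {
  stopifnot(k_ref_42 > 0, k_ref_55 > 0, eta_42 > 0, eta_55 > 0,
            concentration_mM > 0, length(protons) == 2, all(protons > 0))
  structure(
    list(k_ref_42 = k_ref_42, k_ref_55 = k_ref_55,
         eta_42 = eta_42, eta_55 = eta_55, ph_ref = ph_ref,
         concentration_mM = concentration_mM, protons = protons,
         T1 = T1, T2 = T2, shifts = c(4.2, 5.5)),
    class = "iopamidol_model")
}

# water proton molarity, 2 * 55.6 mol/L
WATER_PROTON_M <- 111.2

#' Iopamidol pools at a given pH
#'
#' @param model An [iopamidol_model()].
#' @param ph pH value.
#' @param concentration_mM Optional concentration override (mM).
#' @return List of two `cest_pool` objects (4.2 and 5.5 ppm sites).
#' @export
iopamidol_pools <- function(model, ph, concentration_mM = NULL) {
  stopifnot(inherits(model, "iopamidol_model"))
  conc <- if (is.null(concentration_mM)) model$concentration_mM else concentration_mM
  f <- conc / 1000 * model$protons / WATER_PROTON_M
  k42 <- model$k_ref_42 * 10^(model$eta_42 * (ph - model$ph_ref))
  k55 <- model$k_ref_55 * 10^(model$eta_55 * (ph - model$ph_ref))
  list(
    cest_pool("iop42", model$shifts[1], model$T1, model$T2, f[1], k42),
    cest_pool("iop55", model$shifts[2], model$T1, model$T2, f[2], k55)
  )
}

# agent contrast at the two label offsets for one pH:
# delta-ST(x) = Z_without_agent(x) - Z_with_agent(x). With smoothing = NULL
# the forward model is evaluated exactly at the label offsets; with a
# smoothing penalty, full spectra on the protocol grid are passed through
# the same smoothing-spline readout that the processing pipeline applies,
# so calibration and measurement share one ST operator.
agent_delta_st <- function(model, ph, protocol, water = water_pool(),
                           background = list(), concentration_mM = NULL,
                           smoothing = NULL, z_base_cache = NULL) {
  offs <- model$shifts
  base_pools <- c(list(water), background)
  agent <- iopamidol_pools(model, ph, concentration_mM)
  if (is.null(smoothing)) {
    prot2 <- cest_protocol(protocol$b1_amplitude, protocol$saturation_duration,
                           protocol$field_strength, offsets = offs,
                           reference_included = protocol$reference_included)
    z_base <- if (is.null(z_base_cache)) simulate_zspectrum(base_pools, prot2)$z_values
              else z_base_cache
    z_ag <- simulate_zspectrum(c(base_pools, agent), prot2)$z_values
    st <- z_base - z_ag
  } else {
    zs_base <- if (is.null(z_base_cache)) simulate_zspectrum(base_pools, protocol)
               else z_base_cache
    zs_ag <- simulate_zspectrum(c(base_pools, agent), protocol)
    f_base <- smooth_zspectrum(zs_base, smoothing)
    f_ag <- smooth_zspectrum(zs_ag, smoothing)
    st <- st_at(f_ag, offs) - st_at(f_base, offs)
  }
  names(st) <- c("d42", "d55")
  st
}

# baseline (no-agent) simulation reused across the pH grid
agent_base_cache <- function(protocol, water, background, smoothing) {
  base_pools <- c(list(water), background)
  if (is.null(smoothing)) {
    prot2 <- cest_protocol(protocol$b1_amplitude, protocol$saturation_duration,
                           protocol$field_strength, offsets = c(4.2, 5.5),
                           reference_included = protocol$reference_included)
    simulate_zspectrum(base_pools, prot2)$z_values
  } else {
    simulate_zspectrum(base_pools, protocol)
  }
}

#' Build the ratiometric pH calibration curve
#'
#' For each pH on the grid, simulates the agent-specific contrast at 4.2 and
#' 5.5 ppm with the Bloch-McConnell forward model and stores the ratio
#' `delta-ST(4.2) / delta-ST(5.5)`. The curve must be strictly monotone to
#' be invertible; when monotonicity fails on part of the grid, the valid
#' range is truncated to the largest monotone window containing pH 6.9, and
#' the build fails if no such window exists.
#'
#' @param model An [iopamidol_model()].
#' @param protocol A [cest_protocol()].
#' @param ph_grid pH grid, default `seq(6.0, 7.4, by = 0.05)`.
#' @param water Water pool used for the tissue baseline.
#' @param background Endogenous pools included in both the with- and
#'   without-agent simulations (the additive part cancels in the
#'   difference, mirroring the post-minus-pre subtraction); default none
#'   (agent-only calibration).
#' @param smoothing `NULL` for exact readout at the label offsets, or a
#'   smoothing penalty to route the forward spectra through the same
#'   spline-based ST readout as the processing pipeline (see
#'   [smooth_zspectrum()]).
#' @return Object of class `calibration_curve` with `ph_grid`, `ratio_grid`,
#'   `valid_range`, `direction` and `fingerprint`.
#' @export
build_calibration <- function(model, protocol,
                              ph_grid = seq(6.0, 7.4, by = 0.05),
                              water = water_pool(), background = list(),
                              smoothing = NULL) {
  stopifnot(inherits(model, "iopamidol_model"),
            inherits(protocol, "cest_protocol"))
  ph_grid <- sort(unique(as.numeric(ph_grid)))
  if (length(ph_grid) < 2)
    stop("cannot define a calibration curve from fewer than 2 pH values")
  zb <- agent_base_cache(protocol, water, background, smoothing)
  st <- vapply(ph_grid, function(p)
    agent_delta_st(model, p, protocol, water, background,
                   smoothing = smoothing, z_base_cache = zb),
    c(d42 = 0, d55 = 0))
  ratio <- st["d42", ] / st["d55", ]
  d <- diff(ratio)
  if (all(d > 0)) {
    keep <- seq_along(ph_grid)
  } else if (all(d < 0)) {
    keep <- seq_along(ph_grid)
  } else {
    keep <- largest_monotone_window(ratio, anchor = which.min(abs(ph_grid - 6.9)))
    if (length(keep) < 2)
      stop("calibration ratio is not monotone anywhere near pH 6.9; ",
           "cannot build an invertible curve")
  }
  ph_keep <- ph_grid[keep]; ratio_keep <- ratio[keep]
  structure(
    list(ph_grid = ph_keep, ratio_grid = ratio_keep,
         valid_range = range(ph_keep),
         direction = if (ratio_keep[2] > ratio_keep[1]) "increasing" else "decreasing",
         fingerprint = calibration_fingerprint(model, protocol,
                                               background = background,
                                               smoothing = smoothing)),
    class = "calibration_curve")
}

# largest run of strictly monotone (single-direction) ratio values whose
# index range contains `anchor`
largest_monotone_window <- function(ratio, anchor) {
  n <- length(ratio)
  d <- sign(diff(ratio))
  best <- integer(0)
  i <- 1
  while (i < n) {
    if (d[i] == 0) { i <- i + 1; next }
    j <- i
    while (j < n - 1 && d[j + 1] == d[i]) j <- j + 1
    win <- i:(j + 1)
    if (anchor >= win[1] && anchor <= win[length(win)] &&
        length(win) > length(best)) best <- win
    i <- j + 1
  }
  best
}

#' Fingerprint of the model + protocol behind a calibration
#'
#' Hash over every numeric parameter of the acquisition protocol and agent
#' model; any change invalidates cached or stale curves.
#'
#' @param model An [iopamidol_model()].
#' @param protocol A [cest_protocol()].
#' @param ... Further curve-defining inputs (background pools, smoothing).
#' @return Character hash.
#' @export
calibration_fingerprint <- function(model, protocol, ...) {
  rlang::hash(list(unclass(model), unclass(protocol),
                   lapply(list(...), function(x)
                     if (is.list(x)) rapply(x, unclass, how = "replace") else x)))
}

#' Pipeline-default calibration curve
#'
#' The curve the imaging pipeline inverts: built with the endogenous
#' background pools present and with the forward spectra routed through the
#' same smoothing-spline ST readout applied to measured data, so that the
#' calibration operator equals the measurement operator. Curves are cached
#' per fingerprint.
#'
#' @param protocol A [cest_protocol()].
#' @param model An [iopamidol_model()].
#' @param smoothing Spline penalty (default [default_smoothing()]).
#' @param ph_grid Calibration grid.
#' @return A `calibration_curve`.
#' @export
default_calibration <- function(protocol = cest_protocol(),
                                model = iopamidol_model(),
                                smoothing = default_smoothing(),
                                ph_grid = seq(6.0, 7.4, by = 0.05)) {
  key <- calibration_fingerprint(model, protocol,
                                 background = background_pools(),
                                 smoothing = smoothing, ph_grid = ph_grid)
  if (!is.null(.lookup_cache[[key]])) return(.lookup_cache[[key]])
  cv <- build_calibration(model, protocol, ph_grid = ph_grid,
                          background = background_pools(),
                          smoothing = smoothing)
  .lookup_cache[[key]] <- cv
  cv
}

#' Invert a contrast ratio to pH
#'
#' Monotone linear interpolation of the calibration grid; grid nodes invert
#' exactly. Ratios outside the calibrated ratio range return `NA` (the
#' out-of-range marker; such voxels are excluded downstream, never an
#' error).
#'
#' @param curve A [build_calibration()] result.
#' @param ratio Numeric vector of delta-ST(4.2)/delta-ST(5.5) values.
#' @return pH values (NA where out of range).
#' @export
invert_ratio <- function(curve, ratio) {
  stopifnot(inherits(curve, "calibration_curve"))
  rg <- range(curve$ratio_grid)
  out <- rep(NA_real_, length(ratio))
  ok <- is.finite(ratio) & ratio >= rg[1] & ratio <= rg[2]
  if (any(ok))
    out[ok] <- stats::approx(curve$ratio_grid, curve$ph_grid,
                             xout = ratio[ok], ties = "ordered")$y
  out
}

#' Serialize a calibration curve (TSV + JSON metadata)
#'
#' @param curve A `calibration_curve`.
#' @param path_tsv Two-column TSV (pH, ratio) path.
#' @param path_json Metadata (valid range, direction, fingerprint) path.
#' @return `path_tsv`, invisibly.
#' @export
write_calibration <- function(curve, path_tsv, path_json) {
  utils::write.table(data.frame(pH = curve$ph_grid, ratio = curve$ratio_grid),
                     path_tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(valid_range = curve$valid_range, direction = curve$direction,
         fingerprint = curve$fingerprint),
    path_json, auto_unbox = TRUE, digits = NA)
  invisible(path_tsv)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path_tsv, path_json) {
  d <- utils::read.table(path_tsv, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  structure(list(ph_grid = d$pH, ratio_grid = d$ratio,
                 valid_range = meta$valid_range, direction = meta$direction,
                 fingerprint = meta$fingerprint),
            class = "calibration_curve")
}
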