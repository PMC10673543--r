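#' @keywords internal
"_PACKAGE"

# gyromagnetic ratio of 1H over 2*pi, in Hz/uT (equivalently MHz/T)
GAMMA_HZ_PER_UT <- 42.577478

#' Define an exchanging proton pool
#'
#' A pool is characterised by its chemical shift relative to water, its
#' longitudinal and transverse relaxation times, its proton fraction relative
#' to the water pool, and its exchange rate towards water. The water pool has
#' `chemical_shift = 0` and `fraction = 1` by convention.
#'
#' @param name Label for the pool.
#' @param chemical_shift Shift in ppm relative to water (water = 0).
#' @param T1,T2 Relaxation times in seconds; both must be positive.
#' @param fraction Proton-pool fraction relative to water, in `[0, 1)` for
#'   solute pools (1 for water).
#' @param exchange_rate Pool-to-water exchange rate in 1/s (0 for water).
#' @return An object of class `cest_pool`.
#' @examples
#' water_pool()
#' cest_pool("amide", 3.5, T1 = 1, T2 = 0.01, fraction = 9e-4, exchange_rate = 30)
#' @export
cest_pool <- function(name, chemical_shift, T1, T2, fraction, exchange_rate) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(T1) || T1 <= 0) stop("T1 must be positive, got ", T1)
  if (!is.finite(T2) || T2 <= 0) stop("T2 must be positive, got ", T2)
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1], got ", fraction)
  if (fraction >= 1 && chemical_shift != 0)
    stop("only the water pool may have fraction 1")
  if (!is.finite(exchange_rate) || exchange_rate < 0)
    stop("exchange_rate must be >= 0, got ", exchange_rate)
  structure(
    list(name = name, chemical_shift = chemical_shift, T1 = T1, T2 = T2,
         fraction = fraction, exchange_rate = exchange_rate),
    class = "cest_pool")
}

#' @rdname cest_pool
#' @details `water_pool()` returns the bulk water pool with tissue-like
#'   relaxation times at 7 T (T1 = 2 s, T2 = 50 ms by default).
#' @export
water_pool <- function(T1 = 2.0, T2 = 0.05) {
  cest_pool("water", 0, T1 = T1, T2 = T2, fraction = 1, exchange_rate = 0)
}

#' Default endogenous background pools
#'
#' Tissue contributes agent-independent CEST signal that the pre-contrast
#' acquisition captures and the post-minus-pre subtraction removes. The
#' default background is one broad, magnetization-transfer-like semisolid
#' pool and one 3.5 ppm amide pool; both are conventional tissue stand-ins,
#' not fitted values. The semisolid fraction (0.03) is tumor-like: tumors
#' carry markedly less magnetization-transfer background than normal
#' tissue.
#'
#' @return List of `cest_pool` objects (without water).
#' @export
background_pools <- function() {
  list(
    cest_pool("mt",    -2.4, T1 = 1.0, T2 = 1e-5, fraction = 0.03,  exchange_rate = 30),
    cest_pool("amide",  3.5, T1 = 1.0, T2 = 0.01, fraction = 9e-4, exchange_rate = 30)
  )
}

#' Continuous-wave CEST acquisition protocol
#'
#' Describes the saturation experiment: CW block pulse amplitude and
#' duration, static field strength, the ordered saturation-offset list, and
#' whether an unsaturated reference image (S0) is acquired. Defaults mirror a
#' 7 T preclinical acquisition with a 3 uT, 5 s CW pulse.
#'
#' @param b1_amplitude Saturation amplitude in uT (>= 0).
#' @param saturation_duration CW pulse duration in s (> 0).
#' @param field_strength Static field in T.
#' @param offsets Saturation offsets in ppm; canonicalised to strictly
#'   increasing order.
#' @param reference_included Logical; is an unsaturated S0 image acquired?
#' @return An object of class `cest_protocol`.
#' @export
cest_protocol <- function(b1_amplitude = 3, saturation_duration = 5,
                          field_strength = 7, offsets = default_offsets(),
                          reference_included = TRUE) {
  if (!is.finite(b1_amplitude) || b1_amplitude < 0)
    stop("b1_amplitude must be >= 0")
  if (!is.finite(saturation_duration) || saturation_duration <= 0)
    stop("saturation_duration must be > 0")
  if (length(offsets) == 0) stop("offsets must be non-empty")
  offsets <- sort(unique(as.numeric(offsets)))
  structure(
    list(b1_amplitude = b1_amplitude,
         saturation_duration = saturation_duration,
         field_strength = field_strength, offsets = offsets,
         reference_included = isTRUE(reference_included)),
    class = "cest_protocol")
}

#' Default saturation-offset grid
#'
#' Coarse +-10 ppm coverage at 0.25 ppm with 0.1 ppm refinement over the
#' iopamidol amide region (3.9 to 5.8 ppm) and around the water dip
#' (+-1 ppm), so that spline-based ST readout at 4.2 / 5.5 ppm and water-dip
#' localisation are well supported.
#'
#' @return Numeric vector of ppm offsets, strictly increasing.
#' @export
default_offsets <- function() {
  sort(unique(round(c(seq(-10, 10, by = 0.25),
                      seq(3.9, 5.8, by = 0.1),
                      seq(-1, 1, by = 0.1)), 6)))
}

#' Serialize pools and protocol to YAML
#'
#' @param pools List of `cest_pool` objects.
#' @param protocol A `cest_protocol`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocol_yaml <- function(pools, protocol, path) {
  obj <- list(
    pools = lapply(pools, unclass),
    protocol = unclass(protocol)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read pools and protocol back from YAML
#'
#' @param path File written by [write_protocol_yaml()].
#' @return List with elements `pools` and `protocol`.
#' @export
read_protocol_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  pools <- lapply(obj$pools, function(p)
    cest_pool(p$name, p$chemical_shift, p$T1, p$T2, p$fraction, p$exchange_rate))
  pr <- obj$protocol
  protocol <- cest_protocol(pr$b1_amplitude, pr$saturation_duration,
                            pr$field_strength, unlist(pr$offsets),
                            pr$reference_included)
  list(pools = pools, protocol = protocol)
}
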