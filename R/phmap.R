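# Pixel-wise extracellular pH (pHe) maps from the contrast-difference ratio
# and the acidity score summarising intratumoral pH heterogeneity.

#' Compute a pixel-wise pHe map
#'
#' On voxels that are reliable in both contrast-difference maps, the ratio
#' `delta-ST(4.2) / delta-ST(5.5)` is inverted through the calibration
#' curve. Ratios outside the calibrated range (and zero-denominator voxels)
#' are excluded and counted against coverage.
#'
#' @param d42,d55 [delta_st()] maps at 4.2 and 5.5 ppm, co-registered.
#' @param curve A [build_calibration()] curve.
#' @param mask Logical 3-D tumor mask (non-empty).
#' @return Object of class `phe_map`: `values` (3-D pH, NA where
#'   undefined), `mean_pHe` (NA when no voxel is defined), `coverage`
#'   (defined fraction of mask voxels), `n_defined`.
#' @export
compute_phe_map <- function(d42, d55, curve, mask) {
  stopifnot(inherits(d42, "delta_st_map"), inherits(d55, "delta_st_map"),
            inherits(curve, "calibration_curve"))
  if (!identical(dim(d42$values), dim(d55$values)) ||
      !identical(dim(d42$values), dim(mask)))
    stop("delta-ST maps and mask must share geometry")
  if (!any(mask)) stop("tumor mask is empty")
  ok <- mask & d42$reliability & d55$reliability &
    is.finite(d42$values) & is.finite(d55$values) & d55$values != 0
  ph <- array(NA_real_, dim(mask))
  if (any(ok)) ph[ok] <- invert_ratio(curve, d42$values[ok] / d55$values[ok])
  defined <- is.finite(ph) & mask
  n_def <- sum(defined)
  structure(list(
    values = ph,
    mean_pHe = if (n_def > 0) mean(ph[defined]) else NA_real_,
    coverage = n_def / sum(mask),
    n_defined = n_def), class = "phe_map")
}

#' Default acidity-score pH thresholds
#'
#' Class boundaries `t_low = 6.7`, `t_high = 6.9`, bracketing the typical
#' extracellular pH of solid tumors (about 6.5-6.8 versus about 7.4 in
#' normal tissue). These are a package reconstruction of an unpublished
#' scoring rule, overridable everywhere they are used.
#'
#' @return Named numeric vector `c(t_low =, t_high =)`.
#' @export
default_acidity_bins <- function() c(t_low = 6.7, t_high = 6.9)

# class 1 (least acidic) for pH >= t_high, 3 (most acidic) for pH < t_low
compute_acidity_classes <- function(ph, bins = default_acidity_bins()) {
  if (bins["t_high"] <= bins["t_low"])
    stop("acidity thresholds out of order: need t_high > t_low")
  ifelse(ph >= bins["t_high"], 1L, ifelse(ph >= bins["t_low"], 2L, 3L))
}

#' Acidity score map
#'
#' Classifies every defined pHe voxel into three acidosis levels (1 = least
#' acidic, 3 = most acidic) and summarises the animal by the mean class
#' over defined voxels, jointly across slices.
#'
#' @param phe A [compute_phe_map()] result.
#' @param bins Two thresholds, see [default_acidity_bins()].
#' @return Object of class `acidity_map`: `classes` (3-D, NA where pH
#'   undefined) and `acidity_score` in `[1, 3]`.
#' @export
compute_acidity <- function(phe, bins = default_acidity_bins()) {
  stopifnot(inherits(phe, "phe_map"))
  cl <- array(NA_integer_, dim(phe$values))
  def <- is.finite(phe$values)
  cl[def] <- compute_acidity_classes(phe$values[def], bins)
  structure(list(classes = cl,
                 acidity_score = if (any(def)) mean(cl[def]) else NA_real_),
            class = "acidity_map")
}

#' Run the full per-animal imaging pipeline
#'
#' Convenience wrapper: process the pre/post stacks
#' ([process_stacks()]), form the 4.2 and 5.5 ppm contrast-difference maps,
#' invert to pHe and score acidity.
#'
#' @param animal Output of [generate_animal()] (or a compatible list with
#'   `pre`, `post`, `truth$tumor_mask`, `body_mask`).
#' @param curve Calibration curve.
#' @param smoothing Spline penalty.
#' @param spatial_sd In-mask delta-ST smoothing SD in voxels
#'   (see [smooth_inmask()]).
#' @param bins Acidity thresholds.
#' @param b0_correct Apply water-shift correction (default TRUE).
#' @return List with `phe` (`phe_map`), `acidity` (`acidity_map`), `proc`
#'   (the [process_stacks()] output).
#' @export
animal_phe <- function(animal, curve, smoothing = default_smoothing(),
                       spatial_sd = 1.5, bins = default_acidity_bins(),
                       b0_correct = TRUE) {
  mask <- animal$truth$tumor_mask
  # a subsample of agent-free tissue suffices for the noise-floor estimate
  noise_mask <- animal$body_mask & !mask
  nidx <- which(noise_mask)
  if (length(nidx) > 80) {
    keep <- nidx[seq(1, length(nidx), length.out = 80)]
    noise_mask[] <- FALSE
    noise_mask[keep] <- TRUE
  }
  proc <- process_stacks(animal$pre, animal$post, mask,
                         smoothing = smoothing, noise_mask = noise_mask,
                         spatial_sd = spatial_sd, b0_correct = b0_correct)
  phe <- compute_phe_map(proc$delta[["4.2"]], proc$delta[["5.5"]], curve, mask)
  list(phe = phe, acidity = compute_acidity(phe, bins), proc = proc)
}
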