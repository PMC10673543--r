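# Digital mouse-tumor phantom generator: known ground-truth pH fields
# rendered into pre/post-contrast CEST stacks with B0 inhomogeneity and
# Rician noise, standing in for raw preclinical scans.
#
# Per-voxel physics goes through a Z-spectrum lookup table (one
# Bloch-McConnell simulation per pH level, spline-interpolated in offset and
# linearly interpolated in pH) rather than a per-voxel matrix exponential;
# a static B0 error rigidly translates the spectrum, so a shifted evaluation
# of the same spline is exact up to interpolation error.

#' Phantom specification
#'
#' @param matrix In-plane matrix size `c(nx, ny)`; default 128 x 128.
#' @param n_slices Number of slices; default 8.
#' @param tumor List: `center` (x, y, in voxels; default image centre),
#'   `radii` (in-plane semi-axes in voxels), `slice_profile` (per-slice
#'   scale factors, length `n_slices`, 0 excludes the slice).
#' @param ph_field List: `mean` (mask-average pH), `core_rim` (pH difference
#'   rim minus core; positive means an acidic core), `sd` (spatial
#'   heterogeneity SD in pH units).
#' @param agent_mM Post-contrast iopamidol concentration in the tumor (mM);
#'   zero pre-contrast everywhere.
#' @param b0_ppm Amplitude of the smooth B0 inhomogeneity field (ppm).
#' @param snr Rician signal-to-noise ratio at S0 in tissue; `Inf` disables
#'   noise.
#' @param s0 Reference signal level in tissue (arbitrary units).
#' @param seed Integer seed; identical seeds give identical phantoms.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix = c(128, 128), n_slices = 8,
                         tumor = list(), ph_field = list(),
                         agent_mM = 10, b0_ppm = 0.05, snr = 40,
                         s0 = 100, seed = 1) {
  stopifnot(length(matrix) == 2, all(matrix >= 8), n_slices >= 1, snr > 0)
  tum <- utils::modifyList(list(
    center = matrix / 2 + 0.5,
    radii = pmax(3, round(matrix * 0.12)),
    slice_profile = ellipsoid_profile(n_slices)), tumor)
  phf <- utils::modifyList(list(mean = 6.7, core_rim = 0.2, sd = 0.05),
                           ph_field)
  if (any(tum$center - tum$radii < 1) ||
      any(tum$center + tum$radii > matrix))
    stop("tumor geometry exceeds the image matrix")
  if (length(tum$slice_profile) != n_slices)
    stop("slice_profile must have one entry per slice")
  structure(list(matrix = as.integer(matrix), n_slices = as.integer(n_slices),
                 tumor = tum, ph_field = phf, agent_mM = agent_mM,
                 b0_ppm = b0_ppm, snr = snr, s0 = s0,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# elliptical cross-section scale per slice for an ellipsoidal tumor
ellipsoid_profile <- function(n_slices) {
  if (n_slices == 1) return(1)
  s <- seq_len(n_slices)
  mid <- (n_slices + 1) / 2
  half <- (n_slices - 1) / 2 + 0.5
  sqrt(pmax(0, 1 - ((s - mid) / half)^2))
}

#' CEST image stack
#'
#' @param voxels 4-D array (x, y, slice, offset) of signal.
#' @param s0 3-D unsaturated reference image.
#' @param protocol The [cest_protocol()] used.
#' @param phase `"pre"` or `"post"` contrast.
#' @return Object of class `cest_stack`.
#' @export
cest_stack <- function(voxels, s0, protocol, phase = c("pre", "post")) {
  phase <- match.arg(phase)
  stopifnot(length(dim(voxels)) == 4,
            dim(voxels)[4] == length(protocol$offsets),
            identical(dim(voxels)[1:3], dim(s0)))
  if (any(voxels < 0, na.rm = TRUE)) stop("signals must be non-negative")
  structure(list(voxels = voxels, s0 = s0, protocol = protocol,
                 phase = phase),
            class = "cest_stack")
}

# ---- Z-spectrum lookup ----------------------------------------------------

.lookup_cache <- new.env(parent = emptyenv())

# spline-interpolable Z spectra: one water+background baseline and one
# spectrum per pH level with agent pools added. Guard offsets extend the
# support so B0-shifted evaluation stays in range.
build_zlookup <- function(protocol, model, water = water_pool(),
                          background = background_pools(),
                          ph_levels = seq(6.0, 7.45, by = 0.025),
                          agent_mM = 10, guard_ppm = 0.6) {
  key <- rlang::hash(list(unclass(model), unclass(protocol),
                          lapply(c(list(water), background), unclass),
                          ph_levels, agent_mM, guard_ppm))
  if (!is.null(.lookup_cache[[key]])) return(.lookup_cache[[key]])
  offs <- protocol$offsets
  ext <- sort(unique(c(offs,
                       min(offs) - c(guard_ppm, guard_ppm / 2),
                       max(offs) + c(guard_ppm / 2, guard_ppm))))
  prot_ext <- cest_protocol(protocol$b1_amplitude,
                            protocol$saturation_duration,
                            protocol$field_strength, offsets = ext)
  base_pools <- c(list(water), background)
  z_pre <- simulate_zspectrum(base_pools, prot_ext)
  pre_fun <- stats::splinefun(z_pre$offsets, z_pre$z_values, method = "natural")
  post_funs <- lapply(ph_levels, function(p) {
    z <- simulate_zspectrum(
      c(base_pools, iopamidol_pools(model, p, concentration_mM = agent_mM)),
      prot_ext)
    stats::splinefun(z$offsets, z$z_values, method = "natural")
  })
  lk <- list(pre_fun = pre_fun, post_funs = post_funs,
             ph_levels = ph_levels, offsets = offs)
  .lookup_cache[[key]] <- lk
  lk
}

# evaluate post-contrast Z at given pH by linear interpolation between the
# two bracketing pH levels (pH clipped to the level range)
zlookup_post <- function(lk, ph, offsets) {
  lv <- lk$ph_levels
  ph <- min(max(ph, lv[1]), lv[length(lv)])
  j <- findInterval(ph, lv, all.inside = TRUE)
  w <- (ph - lv[j]) / (lv[j + 1] - lv[j])
  (1 - w) * lk$post_funs[[j]](offsets) + w * lk$post_funs[[j + 1]](offsets)
}

# ---- fields ---------------------------------------------------------------

# smooth B0 field: tilted plane plus one broad Gaussian bump, coefficients
# drawn once per animal
make_b0_field <- function(nx, ny, nz, amp) {
  if (amp == 0) return(array(0, c(nx, ny, nz)))
  cf <- stats::runif(5, -1, 1)
  x <- (seq_len(nx) - nx / 2) / nx
  y <- (seq_len(ny) - ny / 2) / ny
  g <- outer(x, y, function(a, b)
    cf[1] * a + cf[2] * b + cf[3] * exp(-((a - cf[4] / 2)^2 +
                                          (b - cf[5] / 2)^2) / 0.18))
  g <- g / max(abs(g), 1e-12) * amp
  array(rep(g, nz), c(nx, ny, nz))
}

# elliptical mask for one slice
slice_mask <- function(nx, ny, center, radii) {
  x <- seq_len(nx); y <- seq_len(ny)
  outer(x, y, function(a, b)
    ((a - center[1]) / radii[1])^2 + ((b - center[2]) / radii[2])^2 <= 1)
}

tumor_mask_of <- function(spec) {
  nx <- spec$matrix[1]; ny <- spec$matrix[2]
  msk <- array(FALSE, c(nx, ny, spec$n_slices))
  for (s in seq_len(spec$n_slices)) {
    sc <- spec$tumor$slice_profile[s]
    if (sc <= 0) next
    msk[, , s] <- slice_mask(nx, ny, spec$tumor$center,
                             pmax(spec$tumor$radii * sc, 1))
  }
  msk
}

body_mask_of <- function(spec) {
  nx <- spec$matrix[1]; ny <- spec$matrix[2]
  radii <- pmin(c(nx, ny) * 0.45, spec$tumor$radii * 2.2)
  msk <- array(FALSE, c(nx, ny, spec$n_slices))
  for (s in seq_len(spec$n_slices))
    msk[, , s] <- slice_mask(nx, ny, spec$tumor$center, radii)
  msk
}

# ground-truth pH field on the tumor mask: configured mean, a core-to-rim
# gradient, and mean-centred Gaussian heterogeneity, so the mask average
# equals the configured mean exactly (before clipping)
make_ph_field <- function(spec, mask) {
  nx <- spec$matrix[1]; ny <- spec$matrix[2]
  idx <- which(mask, arr.ind = TRUE)
  ctr <- spec$tumor$center; rad <- spec$tumor$radii
  u <- sqrt(((idx[, 1] - ctr[1]) / rad[1])^2 +
            ((idx[, 2] - ctr[2]) / rad[2])^2)
  u <- pmin(u, 1)
  g <- spec$ph_field$core_rim * (u - mean(u))
  e <- stats::rnorm(nrow(idx), 0, spec$ph_field$sd)
  if (nrow(idx) > 1) e <- e - mean(e)
  ph <- array(NA_real_, c(nx, ny, spec$n_slices))
  ph[mask] <- spec$ph_field$mean + g + e
  ph
}

add_rician <- function(signal, sigma) {
  if (sigma <= 0) return(signal)
  n1 <- stats::rnorm(length(signal), 0, sigma)
  n2 <- stats::rnorm(length(signal), 0, sigma)
  array(sqrt((signal + n1)^2 + n2^2), dim(signal))
}

# ---- animal ---------------------------------------------------------------

#' Generate one phantom animal
#'
#' Composes, per voxel, water plus endogenous background pools (both
#' phases) and iopamidol pools with pH-dependent exchange rates
#' (post-contrast, tumor only), simulates the Z-spectrum with the local B0
#' shift, scales by S0 and applies Rician noise. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param protocol A [cest_protocol()].
#' @param model An [iopamidol_model()]; its concentration is overridden by
#'   `spec$agent_mM`.
#' @param water,background Tissue pools, as in [build_zlookup()].
#' @return List with `pre` and `post` ([cest_stack()]), `truth` (list:
#'   `ph_map`, `tumor_mask`, `acidity_truth`), and `body_mask`.
#' @export
generate_animal <- function(spec, protocol = cest_protocol(),
                            model = iopamidol_model(),
                            water = water_pool(),
                            background = background_pools()) {
  stopifnot(inherits(spec, "phantom_spec"))
  lk <- build_zlookup(protocol, model, water, background,
                      agent_mM = spec$agent_mM)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  nx <- spec$matrix[1]; ny <- spec$matrix[2]; nz <- spec$n_slices
  offs <- protocol$offsets; noff <- length(offs)
  tmask <- tumor_mask_of(spec)
  bmask <- body_mask_of(spec)
  if (!any(tmask)) stop("tumor mask is empty for this geometry")
  ph <- make_ph_field(spec, tmask)
  b0 <- make_b0_field(nx, ny, nz, spec$b0_ppm)

  dims <- c(nx, ny, nz)
  pre_v <- array(0, c(dims, noff))
  post_v <- array(0, c(dims, noff))
  s0_img <- array(0, dims)
  s0_img[bmask] <- spec$s0

  body_idx <- which(bmask)
  nvox <- prod(dims)
  # vectorised over voxels: X[k, j] is the B0-shifted evaluation offset of
  # voxel j at protocol offset k
  X <- outer(offs, b0[body_idx], "-")
  Zp <- matrix(lk$pre_fun(X), nrow = noff)
  Zq <- Zp
  tum <- tmask[body_idx]
  if (any(tum)) {
    lv <- lk$ph_levels
    ph_t <- pmin(pmax(ph[body_idx[tum]], lv[1]), lv[length(lv)])
    jlev <- findInterval(ph_t, lv, all.inside = TRUE)
    w <- (ph_t - lv[jlev]) / (lv[jlev + 1] - lv[jlev])
    cols_t <- which(tum)
    for (j in unique(jlev)) {
      sel <- jlev == j
      cc <- cols_t[sel]
      xj <- X[, cc, drop = FALSE]
      zj <- matrix(lk$post_funs[[j]](xj), nrow = noff)
      zj1 <- matrix(lk$post_funs[[j + 1]](xj), nrow = noff)
      Zq[, cc] <- sweep(zj, 2, 1 - w[sel], "*") + sweep(zj1, 2, w[sel], "*")
    }
  }
  for (k in seq_len(noff)) {
    pre_v[body_idx + (k - 1L) * nvox] <- Zp[k, ] * spec$s0
    post_v[body_idx + (k - 1L) * nvox] <- Zq[k, ] * spec$s0
  }

  if (is.finite(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    pre_v <- add_rician(pre_v, sigma)
    post_v <- add_rician(post_v, sigma)
    s0_pre <- add_rician(s0_img, sigma)
    s0_post <- add_rician(s0_img, sigma)
  } else {
    s0_pre <- s0_post <- s0_img
  }

  truth_ph <- ph
  acid <- compute_acidity_classes(truth_ph[tmask])
  list(pre = cest_stack(pre_v, s0_pre, protocol, "pre"),
       post = cest_stack(post_v, s0_post, protocol, "post"),
       truth = list(ph_map = truth_ph, tumor_mask = tmask,
                    acidity_truth = mean(acid)),
       body_mask = bmask)
}

# ---- cohort ---------------------------------------------------------------

#' Generate a two-arm phantom cohort
#'
#' Builds `n_per_group` animals per group. Each group has a pH-mean offset
#' and a tumor-growth-rate factor; caliper diameters follow an exponential
#' volume growth model (prolate geometry, `A = 1.3 B`, `V = A B^2 / 2`) and
#' the survival event is the first measurement day on which the volume
#' exceeds `volume_threshold` (the size-threshold sacrifice rule; the
#' source protocol states this endpoint with ambiguous units, and it is
#' treated here as a volume).
#'
#' @param template A [phantom_spec()] shared by all animals (its seed is
#'   ignored; per-animal seeds derive from `seed`).
#' @param n_per_group Animals per group (>= 2 for downstream tests; 1 is
#'   allowed but the statistics stage will refuse tests).
#' @param group_effects Named list per group with elements `ph` (additive
#'   pH-mean offset) and `growth` (growth-rate multiplier).
#' @param between_sd Between-animal SD of the true mean pH (default 0:
#'   animal-to-animal spread then comes only from spatial sampling and
#'   measurement noise).
#' @param days Measurement days for the caliper table.
#' @param v0 Initial (palpable) tumor volume, mm^3.
#' @param growth_rate Baseline exponential growth rate, 1/day.
#' @param growth_cv Lognormal coefficient of variation of per-animal growth
#'   rates.
#' @param volume_threshold Sacrifice threshold, mm^3 (default 800).
#' @param seed Integer master seed.
#' @param imaging Generate image stacks per animal (set `FALSE` for
#'   table-only cohorts).
#' @param protocol,model Passed to [generate_animal()].
#' @return List with `animals` (per-animal list: `spec`, `group`, `truth`
#'   and, if `imaging`, the stacks) and `table` (the cohort `data.frame`).
#' @export
generate_cohort <- function(template, n_per_group = 6,
                            group_effects = list(
                              control = list(ph = 0, growth = 1),
                              treated = list(ph = 0.12, growth = 0.55)),
                            between_sd = 0,
                            days = seq(0, 27, by = 3), v0 = 5,
                            growth_rate = 0.24, growth_cv = 0.15,
                            volume_threshold = 800, seed = 1,
                            imaging = TRUE,
                            protocol = cest_protocol(),
                            model = iopamidol_model()) {
  stopifnot(inherits(template, "phantom_spec"), n_per_group >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  groups <- names(group_effects)
  animals <- list()
  rows <- list()
  aid <- 0
  for (g in groups) {
    eff <- group_effects[[g]]
    for (i in seq_len(n_per_group)) {
      aid <- aid + 1
      an_seed <- as.integer((as.numeric(seed) * 7919 + aid * 104729) %%
                              .Machine$integer.max)
      ph_mean <- template$ph_field$mean + eff$ph +
        (if (between_sd > 0) stats::rnorm(1, 0, between_sd) else 0)
      gr <- growth_rate * eff$growth *
        stats::rlnorm(1, -growth_cv^2 / 2, growth_cv)
      vol <- v0 * exp(gr * days)
      B <- (2 * vol / 1.3)^(1 / 3)
      A <- 1.3 * B
      bw <- 20 + cumsum(stats::rnorm(length(days), 0.02, 0.1))
      over <- which(vol > volume_threshold)
      ev_time <- if (length(over)) days[over[1]] else max(days)
      ev_flag <- as.integer(length(over) > 0)
      rows[[aid]] <- data.frame(
        animal_id = sprintf("m%02d", aid), group = g, day = days,
        diameter_A = A, diameter_B = B, body_weight = bw,
        event_time = ev_time, event_flag = ev_flag)
      spec_i <- phantom_spec(template$matrix, template$n_slices,
                             tumor = template$tumor,
                             ph_field = utils::modifyList(template$ph_field,
                                                          list(mean = ph_mean)),
                             agent_mM = template$agent_mM,
                             b0_ppm = template$b0_ppm, snr = template$snr,
                             s0 = template$s0, seed = an_seed)
      an <- list(id = sprintf("m%02d", aid), group = g, spec = spec_i,
                 ph_mean_truth = ph_mean)
      if (imaging) an <- c(an, generate_animal(spec_i, protocol, model))
      animals[[aid]] <- an
    }
  }
  list(animals = animals, table = do.call(rbind, rows))
}
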