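# Disk plumbing: NIfTI stacks with JSON sidecars, run manifests, and run
# configuration. NIfTI-1 is used as the interchange format (the scanner's
# native format is proprietary); the saturation-offset list and protocol
# live in a JSON sidecar because NIfTI carries no offset-axis metadata.

#' Write one phantom animal to disk
#'
#' Writes `pre.nii` / `post.nii` (4-D stacks), `pre_s0.nii` /
#' `post_s0.nii`, `mask.nii`, `ph_truth.nii`, a `sidecar.json` (protocol,
#' offsets, spec, seed) and returns the manifest of files written.
#'
#' @param animal Output of [generate_animal()] (plus optional `id`).
#' @param dir Output directory (created; refuses to overwrite unless
#'   `force`).
#' @param force Overwrite an existing directory.
#' @return Character vector of file paths, invisibly.
#' @export
write_animal <- function(animal, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop("output directory ", dir, " exists; use force = TRUE to overwrite")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  RNifti::writeNifti(animal$pre$voxels, fp("pre.nii"))
  RNifti::writeNifti(animal$post$voxels, fp("post.nii"))
  RNifti::writeNifti(animal$pre$s0, fp("pre_s0.nii"))
  RNifti::writeNifti(animal$post$s0, fp("post_s0.nii"))
  RNifti::writeNifti(animal$truth$tumor_mask * 1L, fp("mask.nii"))
  ph <- animal$truth$ph_map
  ph[!is.finite(ph)] <- 0
  RNifti::writeNifti(ph, fp("ph_truth.nii"))
  pr <- animal$pre$protocol
  jsonlite::write_json(list(
    protocol = unclass(pr),
    acidity_truth = animal$truth$acidity_truth,
    id = animal$id %||% NA,
    seed = animal$spec$seed %||% NA),
    fp("sidecar.json"), auto_unbox = TRUE, digits = NA)
  files <- fp(c("pre.nii", "post.nii", "pre_s0.nii", "post_s0.nii",
                "mask.nii", "ph_truth.nii", "sidecar.json"))
  jsonlite::write_json(list(files = basename(files)), fp("manifest.json"),
                       auto_unbox = TRUE)
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a phantom animal back from disk
#'
#' @param dir Directory written by [write_animal()].
#' @return List compatible with [animal_phe()] (`pre`, `post`, `truth`,
#'   `body_mask` is reconstructed as the S0 support).
#' @export
read_animal <- function(dir) {
  fp <- function(x) file.path(dir, x)
  if (!file.exists(fp("sidecar.json")))
    stop("missing sidecar.json in ", dir,
         ": cannot recover offsets and protocol")
  sc <- jsonlite::read_json(fp("sidecar.json"), simplifyVector = TRUE)
  pr <- sc$protocol
  if (is.null(pr$offsets)) stop("sidecar in ", dir, " lists no offsets")
  protocol <- cest_protocol(pr$b1_amplitude, pr$saturation_duration,
                            pr$field_strength, pr$offsets,
                            pr$reference_included)
  noff <- length(protocol$offsets)
  rd <- function(x, ndim) {
    arr <- RNifti::readNifti(fp(x))
    a <- array(as.numeric(arr), dim(arr))
    # NIfTI writers may drop trailing singleton dimensions; restore them
    if (ndim == 3 && length(dim(a)) == 2) dim(a) <- c(dim(a), 1)
    if (ndim == 4 && length(dim(a)) == 3 && dim(a)[3] == noff)
      dim(a) <- c(dim(a)[1:2], 1, noff)
    a
  }
  pre_v <- rd("pre.nii", 4); post_v <- rd("post.nii", 4)
  s0_pre <- rd("pre_s0.nii", 3); s0_post <- rd("post_s0.nii", 3)
  mask <- rd("mask.nii", 3) > 0
  ph <- rd("ph_truth.nii", 3); ph[ph == 0] <- NA_real_
  # body support: S0 well above the noise floor (noisy S0 is positive
  # everywhere, so a plain > 0 test would include pure-noise voxels)
  list(id = sc$id,
       pre = cest_stack(pre_v, s0_pre, protocol, "pre"),
       post = cest_stack(post_v, s0_post, protocol, "post"),
       truth = list(ph_map = ph, tumor_mask = mask,
                    acidity_truth = sc$acidity_truth),
       body_mask = s0_pre > 0.2 * max(s0_pre))
}

#' Default run configuration
#'
#' Every tunable of the pipeline in one serializable list. Provenance tags
#' mark which entries reproduce the acquisition protocol of the emulated
#' study (`"study"`) and which are package reconstructions (`"default"`).
#'
#' @param seed Integer seed.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    protocol = list(b1_amplitude = 3, saturation_duration = 5,
                    field_strength = 7, provenance = "study"),
    matrix = list(size = c(128, 128), n_slices = 8, provenance = "study"),
    iopamidol = list(k_ref_42 = 500, k_ref_55 = 2000, eta = 1,
                     ph_ref = 7.0, concentration_mM = 10,
                     provenance = "default"),
    calibration = list(ph_grid = c(6.0, 7.4, 0.05), provenance = "default"),
    processing = list(smoothing = default_smoothing(),
                      reliability_floor = 0.02, provenance = "default"),
    acidity_bins = list(t_low = 6.7, t_high = 6.9, provenance = "default"),
    survival = list(volume_threshold_mm3 = 800,
                    note = paste("the source protocol states this endpoint",
                                 "as a 'maximum diameter of 800 mm^3';",
                                 "treated as a volume threshold"),
                    provenance = "study")),
    class = "run_config")
}

#' Write / read the resolved run configuration
#'
#' @param config A `run_config` list.
#' @param path YAML file path.
#' @return `path` (write); the configuration list (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}
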