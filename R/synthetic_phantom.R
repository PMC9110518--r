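#' Specify a synthetic lesion
#'
#' Lesions are ellipsoids of elevated uptake on a uniform background, with an
#' optional concentric cold core (inner ellipsoid at background uptake)
#' emulating the cold-in-hot morphology of an avascular sequestrum surrounded
#' by a hypermetabolic rim.
#'
#' @param center_mm World centre (mm, length 3).
#' @param semi_axes_mm Ellipsoid semi-axes (mm); a scalar gives a sphere.
#' @param suv_mean_true Uptake of the hot shell (SUV%), must exceed the
#'   phantom background.
#' @param cold_core_fraction In `[0, 1)`: each semi-axis is scaled by this
#'   fraction to form the inner cold ellipsoid (0 = no core).
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, semi_axes_mm, suv_mean_true,
                        cold_core_fraction = 0) {
  semi_axes_mm <- rep(as.numeric(semi_axes_mm), length.out = 3)
  if (any(semi_axes_mm <= 0))
    stop_bonespectq("semi-axes must be > 0", "spec_error")
  if (cold_core_fraction < 0 || cold_core_fraction >= 1)
    stop_bonespectq("cold_core_fraction must lie in [0, 1)", "spec_error")
  structure(list(center_mm = as.numeric(center_mm),
                 semi_axes_mm = semi_axes_mm,
                 suv_mean_true = suv_mean_true,
                 cold_core_fraction = cold_core_fraction),
            class = "lesion_spec")
}

#' Specify a digital SPECT-like phantom
#'
#' Defaults mirror a clinical bone-SPECT reconstruction grid: 128 x 128
#' matrix at 3.90 mm isotropic voxels and 8 mm FWHM Gaussian smoothing
#' standing in for total system plus reconstruction blur. Phantoms are
#' generated directly in SUV units; no projection-domain physics is
#' simulated.
#'
#' @param shape Grid dimensions (default `c(128, 128, 64)`).
#' @param spacing_mm Voxel spacing (default 3.90 mm isotropic).
#' @param background_suv Uniform background uptake (SUV%).
#' @param lesions List of [lesion_spec()] objects.
#' @param control_region Optional [seed_region()] with role `control`.
#' @param blur_fwhm_mm Gaussian FWHM in mm (>= 0; 0 disables).
#' @param noise `list(type = "none")` or `list(type = "poisson", scale = s)`;
#'   Poisson noise maps each voxel v to `rpois(v * s) / s`.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 64),
                         spacing_mm = c(3.9, 3.9, 3.9),
                         background_suv = 5,
                         lesions = list(),
                         control_region = NULL,
                         blur_fwhm_mm = 8,
                         noise = list(type = "none"),
                         seed = 1L) {
  if (blur_fwhm_mm < 0)
    stop_bonespectq("blur_fwhm_mm must be >= 0", "spec_error")
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3)
  structure(list(shape = as.integer(shape), spacing_mm = spacing_mm,
                 background_suv = background_suv, lesions = lesions,
                 control_region = control_region,
                 blur_fwhm_mm = blur_fwhm_mm, noise = noise,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian blur in world units. Kernels are truncated at 4 sigma
# and row-renormalized, so a constant field is preserved exactly and total
# intensity is conserved away from the grid boundary.
gaussian_blur_3d <- function(arr, spacing, fwhm_mm) {
  if (fwhm_mm <= 0) return(arr)
  sigma <- fwhm_mm / 2.35482
  for (ax in 1:3) {
    n <- dim(arr)[ax]
    dx <- spacing[ax]
    half <- max(1L, ceiling(4 * sigma / dx))
    offs <- -half:half
    kern <- exp(-(offs * dx)^2 / (2 * sigma^2))
    K <- matrix(0, n, n)
    for (m in seq_along(offs)) {
      o <- offs[m]
      idx <- which(seq_len(n) + o >= 1L & seq_len(n) + o <= n)
      K[cbind(idx, idx + o)] <- kern[m]
    }
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    a2 <- aperm(arr, perm)
    d2 <- dim(a2)
    a2 <- array(K %*% matrix(a2, nrow = d2[1]), dim = d2)
    arr <- aperm(a2, order(perm))
  }
  arr
}

#' Generate a digital phantom with known ground truth
#'
#' Fills the grid at the background uptake, paints each lesion's ellipsoid at
#' its true uptake (cold core reset to background), applies the Gaussian
#' blur (`sigma = fwhm / 2.35482`, world units), then optional Poisson
#' noise. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `volume` (an [image_volume()] in `suv_percent`) and
#'   `truth` — per-lesion list of `mask` (pre-blur logical array, hot shell
#'   only), `true_volume_cm3`, `true_suv_mean`, plus `control_true_mean`.
#' @export
generate_phantom <- function(spec) {
  dm <- spec$shape
  sp <- spec$spacing_mm
  extent <- (dm - 1) * sp      # last voxel centre, world coords (origin 0)
  arr <- array(spec$background_suv, dim = dm)
  vol <- image_volume(arr, spacing = sp, units = "suv_percent")
  xyz <- voxel_center_coords(vol)
  truth <- vector("list", length(spec$lesions))
  for (li in seq_along(spec$lesions)) {
    L <- spec$lesions[[li]]
    if (any(L$center_mm - L$semi_axes_mm < -sp / 2) ||
        any(L$center_mm + L$semi_axes_mm > extent + sp / 2))
      stop_bonespectq("lesion extends outside the grid", "spec_error")
    d <- sweep(xyz, 2, L$center_mm, "-")
    inside <- (d[, 1] / L$semi_axes_mm[1])^2 +
      (d[, 2] / L$semi_axes_mm[2])^2 +
      (d[, 3] / L$semi_axes_mm[3])^2 <= 1
    core <- rep(FALSE, nrow(xyz))
    if (L$cold_core_fraction > 0) {
      ca <- L$semi_axes_mm * L$cold_core_fraction
      core <- (d[, 1] / ca[1])^2 + (d[, 2] / ca[2])^2 +
        (d[, 3] / ca[3])^2 <= 1
    }
    hot <- inside & !core
    arr[hot] <- L$suv_mean_true
    arr[inside & core] <- spec$background_suv
    truth[[li]] <- list(mask = array(hot, dim = dm),
                        true_volume_cm3 = sum(hot) * prod(sp) / 1000,
                        true_suv_mean = L$suv_mean_true)
  }
  arr <- gaussian_blur_3d(arr, sp, spec$blur_fwhm_mm)
  if (!is.null(spec$noise$type) && spec$noise$type == "poisson") {
    s <- spec$noise$scale
    arr <- with_seed(spec$seed, {
      array(stats::rpois(length(arr), pmax(arr, 0) * s) / s, dim = dm)
    })
  }
  list(volume = image_volume(arr, spacing = sp, units = "suv_percent"),
       truth = list(lesions = truth,
                    control_true_mean = spec$background_suv))
}

#' Specify a synthetic stage cohort
#'
#' The defaults encode the study conditions this package validates against: a
#' mandibular-osteonecrosis cohort with stage sizes (3, 16, 4) whose
#' metabolic bone volume is log-normal with per-stage medians 8.28, 15.28
#' and 34.61 cm^3 (log-scale sigma 0.4), and stage-independent
#' control-normalised uptake ratios (rSUVmean medians 4.93 / 5.03 / 4.89,
#' rSUVmax medians 2.65 / 4.34 / 4.30).
#'
#' @param counts Lesions per stage (default `c(3, 16, 4)`).
#' @param mbv_median_cm3 Per-stage MBV medians (cm^3).
#' @param mbv_sigma Log-scale sigma of the MBV log-normal.
#' @param rsuv_mean_median,rsuv_mean_sigma Per-stage rSUVmean medians and
#'   log-scale sigma.
#' @param rsuv_max_median,rsuv_max_sigma Per-stage rSUVmax medians and
#'   log-scale sigma.
#' @param background_suv Background uptake of generated phantoms (SUV%).
#' @param blur_fwhm_mm,noise Imaging model for generated phantoms.
#' @param spacing_mm Voxel spacing of generated phantoms.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(counts = c(3L, 16L, 4L),
                        mbv_median_cm3 = c(8.28, 15.28, 34.61),
                        mbv_sigma = 0.4,
                        rsuv_mean_median = c(4.93, 5.03, 4.89),
                        rsuv_mean_sigma = 0.3,
                        rsuv_max_median = c(2.65, 4.34, 4.30),
                        rsuv_max_sigma = 0.3,
                        background_suv = 5,
                        blur_fwhm_mm = 8,
                        noise = list(type = "none"),
                        spacing_mm = c(3.9, 3.9, 3.9),
                        seed = 1L) {
  if (any(counts < 1L))
    stop_bonespectq("per-stage counts must be >= 1", "spec_error")
  if (any(mbv_median_cm3 <= 0) || any(rsuv_mean_median <= 0) ||
      any(rsuv_max_median <= 0))
    stop_bonespectq("medians must be > 0", "spec_error")
  structure(list(counts = as.integer(counts),
                 mbv_median_cm3 = mbv_median_cm3, mbv_sigma = mbv_sigma,
                 rsuv_mean_median = rsuv_mean_median,
                 rsuv_mean_sigma = rsuv_mean_sigma,
                 rsuv_max_median = rsuv_max_median,
                 rsuv_max_sigma = rsuv_max_sigma,
                 background_suv = background_suv,
                 blur_fwhm_mm = blur_fwhm_mm, noise = noise,
                 spacing_mm = rep(as.numeric(spacing_mm), length.out = 3),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Sphere radius (mm) whose voxelized volume approximates a target MBV (cm^3).
mbv_to_radius_mm <- function(mbv_cm3) (3 * mbv_cm3 * 1000 / (4 * pi))^(1 / 3)

#' Generate a synthetic cohort of lesions (and optionally phantoms)
#'
#' Per stage, draws each lesion's true MBV and uptake ratios from log-normal
#' distributions around the per-stage medians, and emits a ground-truth
#' cohort table. With `make_phantoms = TRUE` it also emits one
#' [phantom_spec()] per lesion: a sphere of equivalent radius on a compact
#' grid sized to the lesion plus blur and seed margins, with an off-lesion
#' spherical control region — sufficient for image-level end-to-end recovery
#' since all metrics depend only on the lesion neighbourhood.
#'
#' @param spec A [cohort_spec()].
#' @param make_phantoms Also build per-lesion phantom specs (default FALSE).
#' @return A list: `truth` (a cohort `data.frame` with `patient_id`,
#'   `lesion_id`, `stage`, `suv_max`, `suv_mean`, `mbv_cm3`, `tbu`,
#'   `rsuv_max`, `rsuv_mean`, `rtbu`) and `phantoms` (list of `phantom_spec`
#'   or `NULL`).
#' @export
generate_cohort <- function(spec, make_phantoms = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  k <- length(spec$counts)
  draws <- with_seed(spec$seed, {
    do.call(rbind, lapply(seq_len(k), function(s) {
      n <- spec$counts[s]
      data.frame(
        stage = rep(s, n),
        mbv_cm3 = stats::rlnorm(n, log(spec$mbv_median_cm3[s]),
                                spec$mbv_sigma),
        rsuv_mean = stats::rlnorm(n, log(spec$rsuv_mean_median[s]),
                                  spec$rsuv_mean_sigma),
        rsuv_max = stats::rlnorm(n, log(spec$rsuv_max_median[s]),
                                 spec$rsuv_max_sigma))
    }))
  })
  n_tot <- nrow(draws)
  truth <- data.frame(
    patient_id = sprintf("SIM%02d", seq_len(n_tot)),
    lesion_id = sprintf("L%02d", seq_len(n_tot)),
    stage = draws$stage,
    suv_max = draws$rsuv_max * spec$background_suv,
    suv_mean = draws$rsuv_mean * spec$background_suv,
    mbv_cm3 = draws$mbv_cm3,
    tbu = draws$mbv_cm3 * draws$rsuv_mean * spec$background_suv,
    rsuv_max = draws$rsuv_max,
    rsuv_mean = draws$rsuv_mean,
    rtbu = draws$rsuv_mean * draws$mbv_cm3,
    stringsAsFactors = FALSE)
  phantoms <- NULL
  if (make_phantoms) {
    phantoms <- lapply(seq_len(n_tot), function(i) {
      r <- mbv_to_radius_mm(truth$mbv_cm3[i])
      sp <- spec$spacing_mm
      margin <- 18                      # > 4 sigma of an 8 mm FWHM blur
      ctrl_offset <- r + 28             # lesion centre to control centre
      ctrl_radius <- 10                 # default control-sphere size
      # lesion at world (r+margin) on each axis, origin at 0; grid long
      # enough along x to host the control sphere past the lesion
      center <- rep(r + margin, 3)
      extent <- c(center[1] + ctrl_offset + ctrl_radius + 6,
                  2 * (r + margin), 2 * (r + margin))
      n_vox <- ceiling(extent / sp) + 1L
      ph <- phantom_spec(
        shape = n_vox, spacing_mm = sp,
        background_suv = spec$background_suv,
        lesions = list(lesion_spec(center_mm = center, semi_axes_mm = r,
                                   suv_mean_true = truth$suv_mean[i])),
        control_region = seed_region(
          shape = "sphere", center_mm = center + c(ctrl_offset, 0, 0),
          radius_mm = ctrl_radius, role = "control"),
        blur_fwhm_mm = spec$blur_fwhm_mm, noise = spec$noise,
        seed = substream_seed(spec$seed, i))
      attr(ph, "lesion_id") <- truth$lesion_id[i]
      ph
    })
  }
  list(truth = truth, phantoms = phantoms)
}

#' Run segmentation and metrics on phantoms and score against truth
#'
#' For each phantom: generates the image, derives a lesion target-range box
#' from the (known) lesion geometry plus `seed_margin_mm`, segments the
#' lesion VOI by the histogram-threshold method, materialises the control
#' VOI, computes lesion/ratio metrics, and reports relative errors against
#' the generating truth.
#'
#' @param phantoms List of [phantom_spec()] objects (single-lesion, with a
#'   control region).
#' @param truth Cohort `data.frame` as returned by [generate_cohort()].
#' @param params A [threshold_params()].
#' @param seed_margin_mm Margin added to the lesion semi-axes to form the
#'   target-range box (mm).
#' @return A `data.frame` with one row per phantom: true and recovered MBV,
#'   SUVmean, rSUVmean, rSUVmax and their relative errors, plus the
#'   threshold used.
#' @export
recover_and_score <- function(phantoms, truth, params = threshold_params(),
                              seed_margin_mm = 4) {
  rows <- lapply(seq_along(phantoms), function(i) {
    ph <- phantoms[[i]]
    gen <- generate_phantom(ph)
    suv <- gen$volume
    L <- ph$lesions[[1]]
    seed_box <- seed_region(shape = "box", center_mm = L$center_mm,
                            half_extents_mm = L$semi_axes_mm + seed_margin_mm,
                            role = "lesion_target_range")
    voi <- segment_lesion_voi(suv, seed_box, params)
    lesion_m <- compute_voi_metrics(suv, voi)
    ctrl <- define_control_voi(suv, ph$control_region)
    ctrl_m <- compute_voi_metrics(suv, ctrl)
    ratios <- compute_ratio_metrics(lesion_m, ctrl_m)
    tr <- truth[i, ]
    data.frame(
      lesion_id = tr$lesion_id, stage = tr$stage,
      true_mbv = gen$truth$lesions[[1]]$true_volume_cm3,
      recovered_mbv = lesion_m$mbv,
      mbv_rel_error = lesion_m$mbv / gen$truth$lesions[[1]]$true_volume_cm3 - 1,
      true_suv_mean = tr$suv_mean, recovered_suv_mean = lesion_m$suv_mean,
      suv_mean_rel_error = lesion_m$suv_mean / tr$suv_mean - 1,
      true_rsuv_mean = tr$rsuv_mean, recovered_rsuv_mean = ratios$rsuv_mean,
      true_rsuv_max = tr$rsuv_max, recovered_rsuv_max = ratios$rsuv_max,
      recovered_rtbu = ratios$rtbu,
      threshold = voi$threshold_used$threshold,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
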