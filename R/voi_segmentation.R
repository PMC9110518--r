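#' Define a seed / control region in world coordinates
#'
#' Regions are axis-aligned boxes or spheres specified in world mm, so the
#' same region definition applies at any grid resolution. A
#' `lesion_target_range` region is the user-drawn target range from which the
#' segmentation threshold is derived; a `control` region materialises directly
#' into a control VOI without thresholding.
#'
#' @param shape `"box"` or `"sphere"`.
#' @param center_mm World centre, length-3 mm.
#' @param radius_mm Sphere radius (mm), for `shape = "sphere"`; control
#'   spheres default to 10 mm (only anatomical placement, not size, is
#'   prescribed for controls).
#' @param half_extents_mm Box half-extents (mm, length 3), for
#'   `shape = "box"`.
#' @param role `"lesion_target_range"` or `"control"`.
#' @return An object of class `seed_region`.
#' @export
seed_region <- function(shape = c("box", "sphere"), center_mm,
                        radius_mm = NULL, half_extents_mm = NULL,
                        role = c("lesion_target_range", "control")) {
  shape <- match.arg(shape)
  role <- match.arg(role)
  center_mm <- as.numeric(center_mm)
  if (length(center_mm) != 3L || any(!is.finite(center_mm)))
    stop_bonespectq("center_mm must be a finite length-3 vector",
                    "geometry_error")
  if (shape == "sphere") {
    if (is.null(radius_mm) && role == "control") radius_mm <- 10
    if (is.null(radius_mm) || radius_mm <= 0)
      stop_bonespectq("sphere needs radius_mm > 0", "geometry_error")
    radius_mm <- as.numeric(radius_mm)
  } else {
    half_extents_mm <- as.numeric(half_extents_mm)
    if (length(half_extents_mm) != 3L || any(half_extents_mm <= 0))
      stop_bonespectq("box needs half_extents_mm > 0 (length 3)",
                      "geometry_error")
  }
  structure(list(shape = shape, center_mm = center_mm, radius_mm = radius_mm,
                 half_extents_mm = half_extents_mm, role = role),
            class = "seed_region")
}

#' Read seed/control regions from JSON
#'
#' Accepts a single region object or a list of them, each with fields
#' `shape`, `center_mm`, `radius_mm` or `half_extents_mm`, and `role`.
#'
#' @param path JSON file.
#' @return A list of [seed_region()] objects.
#' @export
read_regions <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!is.null(raw$shape)) raw <- list(raw)
  lapply(raw, function(r)
    seed_region(shape = r$shape, center_mm = unlist(r$center_mm),
                radius_mm = r$radius_mm,
                half_extents_mm = unlist(r$half_extents_mm),
                role = r$role))
}

# Logical vector (in array order) of voxel centres falling inside a region.
region_membership <- function(volume, region) {
  xyz <- voxel_center_coords(volume)
  d <- sweep(xyz, 2, region$center_mm, "-")
  if (region$shape == "sphere") {
    rowSums(d^2) <= region$radius_mm^2
  } else {
    abs(d[, 1]) <= region$half_extents_mm[1] &
      abs(d[, 2]) <= region$half_extents_mm[2] &
      abs(d[, 3]) <= region$half_extents_mm[3]
  }
}

#' Threshold-estimation parameters
#'
#' Controls the histogram-based threshold rule used for lesion segmentation:
#' the threshold is the base value plus `sd_multiplier` standard deviations of
#' the target-range voxel values. The base value is taken from the histogram
#' of the target range; under the default `freq95` rule it is the centre of
#' the first bin, scanning upward from the modal bin, whose count has fallen
#' to at most 95% of the modal count; under `value95` it is 0.95 times the
#' modal pixel value. `sd_scope` selects which voxels the SD is computed over.
#'
#' @param n_bins Number of histogram bins (default 128, minimum 2).
#' @param sd_multiplier Non-negative SD multiplier (default 0.5).
#' @param base_rule `"freq95"` (default) or `"value95"`.
#' @param sd_scope `"target_range"` (default) or `"supra_base"`.
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(n_bins = 128L, sd_multiplier = 0.5,
                             base_rule = c("freq95", "value95"),
                             sd_scope = c("target_range", "supra_base")) {
  base_rule <- match.arg(base_rule)
  sd_scope <- match.arg(sd_scope)
  if (n_bins < 2L)
    stop_bonespectq("n_bins must be at least 2", "input_error")
  if (sd_multiplier < 0)
    stop_bonespectq("sd_multiplier must be >= 0", "input_error")
  structure(list(n_bins = as.integer(n_bins), sd_multiplier = sd_multiplier,
                 base_rule = base_rule, sd_scope = sd_scope),
            class = "threshold_params")
}

#' Estimate a segmentation threshold from target-range voxel values
#'
#' Builds a uniform histogram of the values with bin centres equally spaced
#' from `min(values)` to `max(values)` (bin width `(max - min)/(n_bins - 1)`),
#' takes the most frequent bin as the mode (ties broken toward the lower
#' value), derives the base value per `base_rule`, and returns
#' `threshold = base + sd_multiplier * SD`. Constant input yields
#' mode = base = threshold = that value with SD 0.
#'
#' @param values Numeric vector of voxel values from the target range.
#' @param params A [threshold_params()].
#' @return An object of class `threshold_estimate` with fields `mode_value`,
#'   `base_value`, `sd`, `threshold`, `histogram` (list of `breaks`, `mids`,
#'   `counts`, and per-value bin assignments `bins`).
#' @export
estimate_threshold <- function(values, params = threshold_params()) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) == 0L)
    stop_bonespectq("estimate_threshold: empty input", "input_error")
  rng <- range(values)
  if (length(values) == 1L || diff(rng) == 0) {
    v <- values[1]
    est <- list(mode_value = v, base_value = v, sd = 0, threshold = v,
                histogram = list(breaks = c(v, v), mids = v,
                                 counts = length(values),
                                 bins = rep(1L, length(values))))
    return(structure(est, class = "threshold_estimate"))
  }
  nb <- params$n_bins
  width <- diff(rng) / (nb - 1)
  mids <- rng[1] + (seq_len(nb) - 1) * width
  # bin b holds values in [mids[b] - w/2, mids[b] + w/2); assignment compares
  # against upper edges mids + w/2 so edge values resolve deterministically
  bin <- findInterval(values, mids + width / 2) + 1L
  counts <- tabulate(bin, nbins = nb)
  modal <- which.max(counts)             # which.max: first max = lower bin
  mode_value <- mids[modal]
  if (params$base_rule == "freq95") {
    drop <- which(counts[modal:nb] <= 0.95 * counts[modal])
    base_value <- if (length(drop)) mids[modal + drop[1] - 1] else mode_value
  } else {
    base_value <- 0.95 * mode_value
  }
  sd_vals <- if (params$sd_scope == "target_range") values
             else values[values >= base_value]
  s <- if (length(sd_vals) > 1L) stats::sd(sd_vals) else 0
  structure(list(mode_value = mode_value, base_value = base_value, sd = s,
                 threshold = base_value + params$sd_multiplier * s,
                 histogram = list(breaks = c(mids - width / 2,
                                             rng[2] + width / 2),
                                  mids = mids, counts = counts, bins = bin)),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> mode %.4g, base %.4g, sd %.4g -> threshold %.4g\n",
              x$mode_value, x$base_value, x$sd, x$threshold))
  invisible(x)
}

# 26-connected flood fill from a set of start voxels, restricted to `mask`
# (logical array). Returns a logical array of the reached component.
flood_fill_26 <- function(mask, start_linear) {
  dm <- dim(mask)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  visited <- array(FALSE, dim = dm)
  frontier <- start_linear[mask[start_linear]]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    ijk <- arrayInd(frontier, dm)
    nbr_i <- rep(ijk[, 1], times = nrow(offs)) + rep(offs[, 1], each = nrow(ijk))
    nbr_j <- rep(ijk[, 2], times = nrow(offs)) + rep(offs[, 2], each = nrow(ijk))
    nbr_k <- rep(ijk[, 3], times = nrow(offs)) + rep(offs[, 3], each = nrow(ijk))
    ok <- nbr_i >= 1L & nbr_i <= dm[1] & nbr_j >= 1L & nbr_j <= dm[2] &
      nbr_k >= 1L & nbr_k <= dm[3]
    lin <- (nbr_k[ok] - 1L) * (dm[1] * dm[2]) + (nbr_j[ok] - 1L) * dm[1] +
      nbr_i[ok]
    lin <- unique(lin[mask[lin] & !visited[lin]])
    visited[lin] <- TRUE
    frontier <- lin
  }
  visited
}

#' Segment a lesion VOI by the histogram-threshold method
#'
#' Reproduces the semi-automatic threshold segmentation of quantitative
#' bone-SPECT workstations: the threshold is estimated from the voxels inside
#' the user-drawn target range ([estimate_threshold()]), all voxels at or
#' above the threshold are labelled, and the lesion VOI is the single
#' 26-connected component containing the maximum-SUV voxel of the target
#' range. A target range with no uptake at all (maximum value <= 0) is
#' rejected as degenerate, as is a threshold exceeding every seed value.
#'
#' @param suv An [image_volume()] in `suv_percent` units (an SUV map).
#' @param seed A [seed_region()] with role `lesion_target_range`.
#' @param params A [threshold_params()].
#' @param frozen_threshold Optional `threshold_estimate` to reuse instead of
#'   re-estimating (makes re-segmentation idempotent).
#' @return An object of class `voi`: fields `mask` ([mask_volume()]), `role`
#'   (`"lesion"`), `threshold_used` and `seed`.
#' @export
segment_lesion_voi <- function(suv, seed, params = threshold_params(),
                               frozen_threshold = NULL) {
  if (seed$role != "lesion_target_range")
    stop_bonespectq("seed region must have role lesion_target_range",
                    "input_error")
  inside <- region_membership(suv, seed)
  if (!any(inside))
    stop_bonespectq("seed region does not intersect the volume grid",
                    "geometry_error")
  vals <- as.vector(suv$data)[inside]
  if (max(vals) <= 0)
    stop_bonespectq("empty VOI: no uptake in the seed region",
                    "segmentation_error")
  est <- frozen_threshold %||% estimate_threshold(vals, params)
  supra <- suv$data >= est$threshold
  in_lin <- which(inside)
  seed_supra <- in_lin[supra[in_lin]]
  if (length(seed_supra) == 0L)
    stop_bonespectq("empty VOI: no supra-threshold voxel in the seed region",
                    "segmentation_error")
  anchor <- in_lin[which.max(as.vector(suv$data)[in_lin])]
  comp <- flood_fill_26(supra, anchor)
  structure(list(mask = mask_volume(comp, suv), role = "lesion",
                 threshold_used = est, seed = seed),
            class = "voi")
}

#' Materialise a manually placed control VOI
#'
#' The control VOI is the set of voxels whose centres fall inside the given
#' region — no thresholding, mirroring a manually drawn VOI over unaffected
#' bone. It never carries a threshold estimate.
#'
#' @param suv An [image_volume()] (any units).
#' @param region A [seed_region()] with role `control`.
#' @return A `voi` with role `"control"` and `threshold_used = NULL`.
#' @export
define_control_voi <- function(suv, region) {
  if (region$role != "control")
    stop_bonespectq("region must have role control", "input_error")
  inside <- region_membership(suv, region)
  if (!any(inside))
    stop_bonespectq("control region lies outside the volume grid",
                    "geometry_error")
  m <- array(inside, dim = dim(suv$data))
  structure(list(mask = mask_volume(m, suv), role = "control",
                 threshold_used = NULL, seed = region),
            class = "voi")
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi> role %s, %d voxels%s\n", x$role, sum(x$mask$data),
              if (!is.null(x$threshold_used))
                sprintf(", threshold %.4g", x$threshold_used$threshold)
              else ""))
  invisible(x)
}
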