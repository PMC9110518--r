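#' Per-VOI quantitative uptake metrics
#'
#' Computes the standard quantitative bone-SPECT lesion values over a VOI:
#' \itemize{
#'   \item `suv_max`, `suv_mean` — maximum and mean voxel value in the VOI;
#'   \item `mbv` — metabolic bone volume, the total volume of VOI voxels,
#'     `voxel_count x voxel_volume` in cm^3 (whole voxels, no partial-volume
#'     weighting);
#'   \item `tbu` — total bone uptake, `mbv x suv_mean`.
#' }
#'
#' @param suv An [image_volume()] (typically an SUV map).
#' @param voi A `voi` whose mask geometry matches `suv`.
#' @return An object of class `voi_metrics` with fields `suv_max`,
#'   `suv_mean`, `mbv`, `tbu`, `voxel_count`.
#' @export
compute_voi_metrics <- function(suv, voi) {
  assert_same_geometry(suv, voi$mask)
  vals <- suv$data[voi$mask$data]
  if (length(vals) == 0L)
    stop_bonespectq("empty VOI: no voxels to measure", "input_error")
  mbv <- length(vals) * voxel_volume(suv, "cm3")
  suv_mean <- mean(vals)
  structure(list(suv_max = max(vals), suv_mean = suv_mean, mbv = mbv,
                 tbu = mbv * suv_mean, voxel_count = length(vals)),
            class = "voi_metrics")
}

#' Control-normalised ratio metrics
#'
#' Ratios calibrate for individual differences in bone metabolism by dividing
#' lesion values by values from an unaffected control region:
#' `rsuv_max = lesion SUVmax / control SUVmax`,
#' `rsuv_mean = lesion SUVmean / control SUVmean`, and
#' `rtbu = rsuv_mean x lesion MBV` (cm^3). Because the SUV normalisation
#' constant is shared by lesion and control, these ratios are identical
#' whether computed on the raw activity volume or the SUV map.
#'
#' @param lesion,control `voi_metrics` for the lesion and control VOIs.
#' @return An object of class `ratio_metrics` with fields `rsuv_max`,
#'   `rsuv_mean`, `rtbu`.
#' @export
compute_ratio_metrics <- function(lesion, control) {
  if (!is.finite(control$suv_max) || control$suv_max <= 0 ||
      !is.finite(control$suv_mean) || control$suv_mean <= 0)
    stop_bonespectq("invalid control VOI: non-positive control SUV",
                    "division_error")
  rsuv_mean <- lesion$suv_mean / control$suv_mean
  structure(list(rsuv_max = lesion$suv_max / control$suv_max,
                 rsuv_mean = rsuv_mean,
                 rtbu = rsuv_mean * lesion$mbv),
            class = "ratio_metrics")
}

#' @export
print.voi_metrics <- function(x, ...) {
  cat(sprintf("<voi_metrics> SUVmax %.4g, SUVmean %.4g, MBV %.4g cm3, TBU %.4g (%d voxels)\n",
              x$suv_max, x$suv_mean, x$mbv, x$tbu, x$voxel_count))
  invisible(x)
}

#' @export
print.ratio_metrics <- function(x, ...) {
  cat(sprintf("<ratio_metrics> rSUVmax %.4g, rSUVmean %.4g, rTBU %.4g cm3\n",
              x$rsuv_max, x$rsuv_mean, x$rtbu))
  invisible(x)
}

#' Assemble a per-lesion metrics row
#'
#' One CSV-ready record combining identifiers, stage and the lesion/ratio
#' metrics.
#'
#' @param patient_id,lesion_id Identifiers.
#' @param stage Clinical stage (1, 2 or 3), or `NA`.
#' @param lesion A `voi_metrics`.
#' @param ratios A `ratio_metrics`.
#' @return A one-row `data.frame` with columns `patient_id, lesion_id, stage,
#'   suv_max, suv_mean, mbv_cm3, tbu, rsuv_max, rsuv_mean, rtbu`.
#' @export
metrics_row <- function(patient_id, lesion_id, stage = NA_integer_,
                        lesion, ratios) {
  data.frame(patient_id = as.character(patient_id),
             lesion_id = as.character(lesion_id),
             stage = as.integer(stage),
             suv_max = lesion$suv_max, suv_mean = lesion$suv_mean,
             mbv_cm3 = lesion$mbv, tbu = lesion$tbu,
             rsuv_max = ratios$rsuv_max, rsuv_mean = ratios$rsuv_mean,
             rtbu = ratios$rtbu,
             stringsAsFactors = FALSE)
}
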