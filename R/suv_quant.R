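#' Convert an activity-concentration volume to an SUV map
#'
#' Computes the body-weight-normalised standardized uptake value voxelwise:
#'
#' \deqn{SUV = \frac{\mathrm{pixel\ value\ [Bq/mL]}}{\mathrm{administered\ activity\ [Bq]}/\mathrm{body\ weight\ [g]}} \times 100 [\%]}
#'
#' The result is expressed as a percentage (`suv_percent`), the convention of
#' the quantitative bone-SPECT workstations this mirrors; `percent = FALSE`
#' drops the factor 100 for a conventional g/mL-style SUV. The formula mixes
#' Bq/mL with Bq/g, i.e. it implicitly assumes a tissue density of 1 g/mL; no
#' decay correction is applied. Geometry is unchanged.
#'
#' @param volume An [image_volume()] with units `activity_Bq_per_mL`.
#' @param meta An [acquisition_meta()].
#' @param percent Keep the x100 percent scale (default `TRUE`).
#' @return An [image_volume()] with units `suv_percent` (or `dimensionless`
#'   when `percent = FALSE`); attribute `provenance` records the
#'   normalisation.
#' @export
compute_suv_map <- function(volume, meta, percent = TRUE) {
  if (!inherits(volume, "image_volume") || volume$units != "activity_Bq_per_mL")
    stop_bonespectq("compute_suv_map needs a volume in activity_Bq_per_mL",
                    "units_error")
  if (!inherits(meta, "acquisition_meta"))
    stop_bonespectq("meta must be an acquisition_meta", "metadata_error")
  scale <- meta$body_weight_g / meta$administered_activity_bq *
    (if (percent) 100 else 1)
  suv <- image_volume(volume$data * scale, spacing = volume$spacing,
                      origin = volume$origin, orientation = volume$orientation,
                      units = if (percent) "suv_percent" else "dimensionless")
  attr(suv, "provenance") <- list(
    administered_activity_bq = meta$administered_activity_bq,
    body_weight_g = meta$body_weight_g,
    patient_id = meta$patient_id,
    percent = percent)
  suv
}
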