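#' Construct an image volume
#'
#' An `image_volume` is a 3D scalar grid plus the geometry needed to place it
#' in world space: voxel spacing (mm), the world coordinate of the centre of
#' voxel (0,0,0), a 3x3 direction matrix, and a units label. Voxel indexing is
#' 0-based and world coordinates always refer to voxel centres, so regions can
#' be specified in mm independently of grid resolution.
#'
#' @param data 3D numeric array (one value per voxel).
#' @param spacing Numeric length-3, voxel spacing in mm; all components > 0.
#' @param origin Numeric length-3, world position (mm) of the centre of voxel
#'   (0,0,0).
#' @param orientation 3x3 direction matrix with non-zero determinant.
#' @param units One of `"activity_Bq_per_mL"`, `"suv_percent"`,
#'   `"dimensionless"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0),
                         orientation = diag(3),
                         units = c("activity_Bq_per_mL", "suv_percent",
                                   "dimensionless")) {
  units <- match.arg(units)
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop_bonespectq("image data must be a 3D array", "geometry_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_bonespectq("spacing components must all be > 0", "geometry_error")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_bonespectq("origin must be a finite length-3 vector", "geometry_error")
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) || abs(det(orientation)) < 1e-12)
    stop_bonespectq("orientation must be 3x3 with non-zero determinant",
                    "geometry_error")
  structure(list(data = data, spacing = spacing, origin = origin,
                 orientation = orientation, units = units),
            class = "image_volume")
}

#' Construct a mask volume
#'
#' A boolean grid sharing the exact geometry of a companion [image_volume()].
#'
#' @param data 3D logical array.
#' @param geometry An `image_volume` (or `mask_volume`) providing
#'   spacing/origin/orientation.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(data, geometry) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop_bonespectq("mask data must be a 3D array", "geometry_error")
  if (!all(dim(data) == dim(geometry$data)))
    stop_bonespectq("mask shape must match its companion volume",
                    "geometry_error")
  storage.mode(data) <- "logical"
  structure(list(data = data, spacing = geometry$spacing,
                 origin = geometry$origin, orientation = geometry$orientation,
                 units = "dimensionless"),
            class = "mask_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, spacing %s mm, units %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$units))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s, spacing %s mm, %d voxels set\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Voxel volume in mm^3 or cm^3
#'
#' @param volume An `image_volume` or `mask_volume`.
#' @param units `"mm3"` or `"cm3"`.
#' @return Scalar voxel volume.
#' @export
voxel_volume <- function(volume, units = c("mm3", "cm3")) {
  units <- match.arg(units)
  v <- prod(volume$spacing)
  if (units == "cm3") v / 1000 else v
}

# World coordinates (mm) of every voxel centre, as an n x 3 matrix in the
# array's column-major voxel order. 0-based indices; centres at
# origin + orientation %*% (spacing * index).
voxel_center_coords <- function(volume) {
  dm <- dim(volume$data)
  idx <- as.matrix(expand.grid(i = seq_len(dm[1]) - 1,
                               j = seq_len(dm[2]) - 1,
                               k = seq_len(dm[3]) - 1))
  xyz <- t(volume$orientation %*% (t(idx) * volume$spacing))
  sweep(xyz, 2, volume$origin, "+")
}

#' Read a volumetric image from NIfTI
#'
#' Reads a NIfTI-1/NIfTI-2 volume, populates geometry from the header
#' (spacing, origin and direction from the stored affine), and clamps any
#' negative voxels to zero: activity concentrations cannot be negative, so
#' negatives are treated as reconstruction artefacts. The number of clamped
#' voxels is recorded in `attr(, "clamped")` and reported via a message.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param expected_units Units label to attach (the file format does not carry
#'   one).
#' @return An [image_volume()]; attribute `clamped` holds the clamp count.
#' @export
read_volume <- function(path, expected_units = "activity_Bq_per_mL") {
  if (!file.exists(path))
    stop_bonespectq(sprintf("file not found: %s", path), "format_error")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop_bonespectq(sprintf("unreadable NIfTI header: %s",
                                            conditionMessage(e)),
                                    "format_error"))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L || any(dim(arr) == 0L))
    stop_bonespectq("expected a non-degenerate 3D volume", "geometry_error")
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  rot <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  if (any(spacing <= 0))
    stop_bonespectq("non-positive voxel spacing in header", "geometry_error")
  orientation <- sweep(rot, 2, spacing, "/")
  origin <- aff[1:3, 4]
  neg <- sum(arr < 0)
  if (neg > 0) {
    message(sprintf("read_volume: clamped %d negative voxel(s) to 0", neg))
    arr[arr < 0] <- 0
  }
  vol <- image_volume(arr, spacing = spacing, origin = origin,
                      orientation = orientation, units = expected_units)
  attr(vol, "clamped") <- neg
  vol
}

#' Write a volume (or mask) to NIfTI
#'
#' Stores the geometry as an sform affine (code 2). Masks are written as
#' 0/1 bytes.
#'
#' @param volume An [image_volume()] or [mask_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  arr <- volume$data
  if (inherits(volume, "mask_volume")) storage.mode(arr) <- "integer"
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing
  aff <- rbind(cbind(volume$orientation %*% diag(volume$spacing),
                     volume$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  # NIfTI-2 stores pixdim/affine as doubles, making geometry lossless
  RNifti::writeNifti(img, path, version = 2)
  invisible(path)
}

#' Load an acquisition-metadata sidecar
#'
#' The sidecar (JSON or YAML) carries what is needed to normalise activity to
#' SUV: administered activity in Bq and body weight in g. An optional scan
#' delay in minutes is recorded but plays no part in the SUV computation (no
#' decay correction is applied).
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` sidecar with keys
#'   `administered_activity_bq`, `body_weight_g`, `patient_id` and optionally
#'   `scan_delay_min`.
#' @return An object of class `acquisition_meta`.
#' @export
load_acquisition_meta <- function(path) {
  if (!file.exists(path))
    stop_bonespectq(sprintf("file not found: %s", path), "metadata_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  acquisition_meta(
    administered_activity_bq = raw$administered_activity_bq,
    body_weight_g = raw$body_weight_g,
    patient_id = raw$patient_id %||% NA_character_,
    scan_delay_min = raw$scan_delay_min
  )
}

#' Construct acquisition metadata
#'
#' @param administered_activity_bq Administered activity in Bq; must be > 0.
#' @param body_weight_g Body weight in g; must be > 0.
#' @param patient_id Optional patient identifier.
#' @param scan_delay_min Optional scan delay (minutes), recorded only.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(administered_activity_bq, body_weight_g,
                             patient_id = NA_character_,
                             scan_delay_min = NULL) {
  for (key in c("administered_activity_bq", "body_weight_g")) {
    val <- get(key)
    if (is.null(val) || length(val) != 1L || !is.numeric(val) || is.na(val))
      stop_bonespectq(sprintf("missing or non-numeric key: %s", key),
                      "metadata_error")
    if (val <= 0)
      stop_bonespectq(sprintf("key %s must be > 0 (got %g)", key, val),
                      "metadata_error")
  }
  structure(list(administered_activity_bq = as.numeric(administered_activity_bq),
                 body_weight_g = as.numeric(body_weight_g),
                 patient_id = as.character(patient_id),
                 scan_delay_min = scan_delay_min),
            class = "acquisition_meta")
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf("<acquisition_meta> %.3g MBq, %.4g kg, patient %s\n",
              x$administered_activity_bq / 1e6, x$body_weight_g / 1000,
              x$patient_id))
  invisible(x)
}

#' Assert that two grids share the same geometry
#'
#' Silent when shape, spacing, origin and orientation match (spacing/origin to
#' 1e-4 mm); otherwise raises a geometry error naming the differing field.
#'
#' @param a,b Two `image_volume` / `mask_volume` objects.
#' @param tol Absolute tolerance (mm) on spacing and origin.
#' @return `TRUE`, invisibly.
#' @export
assert_same_geometry <- function(a, b, tol = 1e-4) {
  if (!all(dim(a$data) == dim(b$data)))
    stop_bonespectq("geometry mismatch: shape", "geometry_error")
  if (any(abs(a$spacing - b$spacing) > tol))
    stop_bonespectq("geometry mismatch: spacing", "geometry_error")
  if (any(abs(a$origin - b$origin) > tol))
    stop_bonespectq("geometry mismatch: origin", "geometry_error")
  if (any(abs(a$orientation - b$orientation) > 1e-6))
    stop_bonespectq("geometry mismatch: orientation", "geometry_error")
  invisible(TRUE)
}
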