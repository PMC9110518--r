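# Independent oracles and fixture builders shared across the suite.

# Brute-force threshold oracle: explicit histogram arrays and linear scans,
# written independently of estimate_threshold(). Bin centres run from min to
# max; values are assigned by a linear sweep over bins.
brute_force_threshold <- function(values, n_bins = 128L, sd_multiplier = 0.5,
                                  base_rule = "freq95") {
  values <- as.numeric(values)
  lo <- min(values); hi <- max(values)
  if (length(values) == 1L || hi == lo) {
    return(list(bins = rep(1L, length(values)), mode_value = lo,
                base_value = lo, sd = 0, threshold = lo))
  }
  w <- (hi - lo) / (n_bins - 1)
  centers <- lo + (0:(n_bins - 1)) * w
  bins <- integer(length(values))
  counts <- integer(n_bins)
  for (i in seq_along(values)) {
    b <- 1L
    while (b < n_bins && values[i] >= centers[b] + w / 2) b <- b + 1L
    bins[i] <- b
    counts[b] <- counts[b] + 1L
  }
  modal <- 1L                      # strict > keeps the lower bin on ties
  for (b in 2:n_bins) if (counts[b] > counts[modal]) modal <- b
  mode_value <- centers[modal]
  if (base_rule == "freq95") {
    base_value <- mode_value
    for (b in modal:n_bins) {
      if (counts[b] <= 0.95 * counts[modal]) { base_value <- centers[b]; break }
    }
  } else {
    base_value <- 0.95 * mode_value
  }
  mu <- sum(values) / length(values)
  s <- sqrt(sum((values - mu)^2) / (length(values) - 1))
  list(bins = bins, mode_value = mode_value, base_value = base_value, sd = s,
       threshold = base_value + sd_multiplier * s)
}

# Monte-Carlo permutation oracle for the Kruskal-Wallis p-value.
perm_kw_p <- function(groups, B = 20000L, seed = 11L) {
  pooled <- unlist(groups)
  n <- lengths(groups)
  gi <- rep(seq_along(n), n)
  h_obs <- kruskal_wallis(groups)$H_corrected
  bonespectq:::with_seed(seed, {
    hs <- replicate(B, kruskal_wallis(split(sample(pooled), gi))$H_corrected)
    mean(hs >= h_obs - 1e-12)
  })
}

# Enumerate voxel centres inside a sphere by a plain triple loop (independent
# of voxel_center_coords / region_membership).
sphere_center_count <- function(dims, spacing, center, radius) {
  cnt <- 0L
  for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1))
    for (k in 0:(dims[3] - 1)) {
      d <- c(i, j, k) * spacing - center
      if (sum(d^2) <= radius^2) cnt <- cnt + 1L
    }
  cnt
}

# A small blur-free phantom: uniform hot sphere on a constant background.
make_sphere_volume <- function(dims = c(24, 24, 24), spacing = 3.9,
                               bg = 0, hot = 10, radius = 12,
                               center = (dims - 1) / 2 * spacing) {
  ph <- phantom_spec(shape = dims, spacing_mm = rep(spacing, 3),
                     background_suv = bg,
                     lesions = list(lesion_spec(center, radius, hot)),
                     blur_fwhm_mm = 0, seed = 1)
  generate_phantom(ph)
}

write_tmp_meta <- function(activity = 740e6, weight = 60000,
                           patient = "P01", format = "json") {
  path <- tempfile(fileext = paste0(".", format))
  obj <- list(administered_activity_bq = activity, body_weight_g = weight,
              patient_id = patient)
  if (format == "json") jsonlite::write_json(obj, path, auto_unbox = TRUE)
  else yaml::write_yaml(obj, path)
  path
}
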