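#' Spherical air cavity specification
#'
#' Describes an air-filled sphere (frontal sinus, ear canal) whose
#' susceptibility contrast with surrounding tissue perturbs the B0 field.
#'
#' @param center Numeric length-3, cavity center in world mm.
#' @param radius Sphere radius in mm, > 0.
#' @param delta_chi_ppm Susceptibility difference (air minus tissue) in ppm
#'   (SI volume susceptibility). The standard literature value is about 9.4.
#' @param label Optional label (`"frontal_sinus"`, `"ear_left"`, ...).
#' @return An object of class `cavity_spec`.
#' @export
cavity_spec <- function(center, radius, delta_chi_ppm = 9.4, label = "") {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center))) {
    stop("`center` must be 3 finite mm coordinates", call. = FALSE)
  }
  if (!is.numeric(radius) || radius <= 0) {
    stop("`radius` must be > 0", call. = FALSE)
  }
  structure(list(center = center, radius = as.numeric(radius),
                 delta_chi_ppm = as.numeric(delta_chi_ppm),
                 label = as.character(label)),
            class = "cavity_spec")
}

#' Default air cavities of the head phantom
#'
#' Extended air spaces modelled as sphere clusters, anchored where B0
#' inhomogeneity is worst in vivo: a three-lobe frontal sinus behind the
#' forehead, ear canal plus mastoid air cells on each side, and the skull
#' base row (sphenoid/nasal, oral, nasopharyngeal). All sources sit outside
#' or at the margin of the brain ellipsoid, as real air spaces are
#' extracranial; clusters of spheres give the broad, moderately steep far
#' fields that measured brain field maps show, rather than the sharp shell of
#' a single small sphere. Positions are in the centered world frame of the
#' default grid (+y anterior, +z superior).
#'
#' @return List of [cavity_spec()] objects.
#' @export
default_cavities <- function() {
  c(
    lapply(list(c(-16, 76, -32), c(0, 79, -32), c(16, 76, -32)), function(p)
      cavity_spec(p, radius = 15, label = "frontal_sinus")),
    lapply(list(c(-58, -8, -34), c(-56, -30, -38)), function(p)
      cavity_spec(p, radius = 15, label = "ear_left")),
    lapply(list(c(58, -8, -34), c(56, -30, -38)), function(p)
      cavity_spec(p, radius = 15, label = "ear_right")),
    list(cavity_spec(c(0, 45, -65), radius = 17, label = "sphenoid"),
         cavity_spec(c(0, 0, -78), radius = 21, label = "oral"),
         cavity_spec(c(0, -45, -70), radius = 15, label = "nasopharynx"))
  )
}

#' Synthetic subject configuration
#'
#' Bundles everything needed to generate one synthetic subject: grid geometry,
#' brain-ellipsoid semiaxes, air cavities, a smooth background field and a
#' per-voxel noise level. The default grid matches a whole-brain dual-echo GRE
#' field-map protocol at 3T: 2.4 x 2.4 x 2 mm voxels over a
#' 214 x 250 x 120 mm field of view.
#'
#' @param seed Integer RNG seed; all randomness in [generate_subject()] flows
#'   from it.
#' @param semiaxes Numeric length-3 ellipsoid semiaxes (a, b, c) in mm. The
#'   default (70, 85, 55) gives a ~1.4 L brain that fits the default FOV.
#' @param cavities List of [cavity_spec()] objects.
#' @param background_poly Named coefficients (Hz) of a degree-2 polynomial in
#'   the scaled coordinates (x, y, z)/100 mm: terms `const, x, y, z, x2, y2,
#'   z2, xy, xz, yz`. Models the smooth global inhomogeneity left after the
#'   magnet's own shimming.
#' @param background_sh_rms_hz Whole-brain RMS amplitudes (Hz) of the seeded
#'   random solid-harmonic background for degrees 3, 4 and 5. Measured brain
#'   field maps retain broad high-order structure that a second-order shim
#'   cannot address (distal susceptibility sources in the neck and torso,
#'   distributed tissue heterogeneity, scanner shim residuals); this term
#'   emulates it. Per-subject coefficients are drawn from the subject seed.
#'   Set `c(0, 0, 0)` to disable.
#' @param noise_sd_hz Per-voxel i.i.d. Gaussian noise SD in Hz, >= 0.
#' @param spacing Voxel spacing (mm).
#' @param fov Field of view (mm); grid dims are `round(fov / spacing)`.
#' @param b0_tesla Main field strength in tesla.
#' @param mask_margin_mm Extra exclusion margin (mm) carved around each
#'   cavity when building the brain mask. Air cavities are separated from
#'   brain tissue by bone and CSF, and brain extraction drops the signal-void
#'   interface zone, so field maps never sample the immediate sphere surface;
#'   the margin reproduces that. Set 0 for a bare geometric carve.
#' @return An object of class `subject_config`.
#' @export
subject_config <- function(seed = 1L,
                           semiaxes = c(70, 85, 55),
                           cavities = default_cavities(),
                           background_poly = default_background_poly(),
                           background_sh_rms_hz = c(10, 8, 6),
                           noise_sd_hz = 2,
                           spacing = c(2.4, 2.4, 2),
                           fov = c(214, 250, 120),
                           b0_tesla = 3,
                           mask_margin_mm = 6) {
  spacing <- as.numeric(spacing)
  fov <- as.numeric(fov)
  if (any(spacing <= 0) || any(fov <= 0)) {
    stop("`spacing` and `fov` must be positive", call. = FALSE)
  }
  if (!is.numeric(noise_sd_hz) || noise_sd_hz < 0) {
    stop("`noise_sd_hz` must be >= 0", call. = FALSE)
  }
  semiaxes <- as.numeric(semiaxes)
  if (length(semiaxes) != 3L || any(semiaxes <= 0)) {
    stop("`semiaxes` must be 3 positive values (mm)", call. = FALSE)
  }
  poly <- default_background_poly()
  if (!is.null(background_poly)) {
    background_poly <- unlist(background_poly)
    bad <- setdiff(names(background_poly), names(poly))
    if (length(bad)) stop("unknown polynomial terms: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    poly[names(background_poly)] <- background_poly
  }
  if (!is.numeric(mask_margin_mm) || mask_margin_mm < 0) {
    stop("`mask_margin_mm` must be >= 0", call. = FALSE)
  }
  background_sh_rms_hz <- rep_len(as.numeric(background_sh_rms_hz), 3L)
  if (any(background_sh_rms_hz < 0)) {
    stop("`background_sh_rms_hz` must be >= 0", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), semiaxes = semiaxes,
                 cavities = cavities, background_poly = poly,
                 background_sh_rms_hz = background_sh_rms_hz,
                 noise_sd_hz = as.numeric(noise_sd_hz), spacing = spacing,
                 fov = fov, b0_tesla = as.numeric(b0_tesla),
                 mask_margin_mm = as.numeric(mask_margin_mm)),
            class = "subject_config")
}

#' Default smooth background field coefficients
#'
#' Hz coefficients of the degree-2 polynomial in (x, y, z)/100 mm used as the
#' smooth residual inhomogeneity underneath the cavity dipole fields. Chosen
#' to contribute on the order of 10-15 Hz of whole-brain SD, a realistic
#' residual for a 3T magnet after its built-in shim.
#'
#' @return Named numeric vector of 10 coefficients.
#' @export
default_background_poly <- function() {
  c(const = 0, x = 6, y = -10, z = 14,
    x2 = -12, y2 = 8, z2 = 18, xy = 4, xz = -6, yz = 5)
}

# grid template (zero field_map) from spacing + fov, centered on the origin
grid_geometry <- function(spacing, fov) {
  dims <- pmax(1L, as.integer(round(fov / spacing)))
  origin <- -(dims - 1) * spacing / 2
  field_map(array(0, dims), spacing = spacing, origin = origin)
}

#' Ellipsoid-with-cavities brain mask
#'
#' A voxel is in the mask iff its center lies inside the brain ellipsoid
#' (centered on the world origin) and outside every cavity sphere.
#'
#' @param config A [subject_config()].
#' @return A [brain_mask()].
#' @export
make_brain_mask <- function(config) {
  geom <- grid_geometry(config$spacing, config$fov)
  half_fov <- (dim(geom$data) - 1) * config$spacing / 2
  if (any(config$semiaxes > half_fov)) {
    stop("brain ellipsoid does not fit inside the field of view",
         call. = FALSE)
  }
  p <- voxel_centers(geom)
  s <- config$semiaxes
  inside <- (p[, 1] / s[1])^2 + (p[, 2] / s[2])^2 + (p[, 3] / s[3])^2 <= 1
  margin <- if (is.null(config$mask_margin_mm)) 0 else config$mask_margin_mm
  for (cav in config$cavities) {
    d2 <- (p[, 1] - cav$center[1])^2 + (p[, 2] - cav$center[2])^2 +
      (p[, 3] - cav$center[3])^2
    inside <- inside & d2 > (cav$radius + margin)^2
  }
  brain_mask(array(inside, dim(geom$data)), spacing = geom$spacing,
             origin = geom$origin)
}

#' Dipole field of a spherical susceptibility cavity
#'
#' External field of a sphere of susceptibility contrast `delta_chi_ppm` in a
#' uniform B0 along +z (Lorentz-sphere form): for `r > radius`,
#' `df = f0 * (dchi / 3) * (radius / r)^3 * (3 cos^2(theta) - 1)` where
#' `theta` is the polar angle from the B0 axis and `f0 = 42.577 MHz/T * B0`.
#' Inside the sphere the returned field is 0 (those voxels are excluded by the
#' mask anyway).
#'
#' @param cavity A [cavity_spec()].
#' @param geom A [field_map()] or [brain_mask()] supplying the grid.
#' @param b0_tesla Main field strength in tesla, > 0.
#' @return A [field_map()] of the frequency perturbation in Hz.
#' @export
cavity_dipole_field <- function(cavity, geom, b0_tesla = 3) {
  if (!is.numeric(b0_tesla) || b0_tesla <= 0) {
    stop("`b0_tesla` must be > 0", call. = FALSE)
  }
  f0 <- GAMMA_HZ_PER_T * b0_tesla
  p <- voxel_centers(geom)
  dx <- p[, 1] - cavity$center[1]
  dy <- p[, 2] - cavity$center[2]
  dz <- p[, 3] - cavity$center[3]
  r2 <- dx^2 + dy^2 + dz^2
  a2 <- cavity$radius^2
  out <- numeric(nrow(p))
  ext <- r2 > a2
  cos2 <- dz[ext]^2 / r2[ext]
  out[ext] <- f0 * (cavity$delta_chi_ppm * 1e-6 / 3) *
    (a2 / r2[ext])^1.5 * (3 * cos2 - 1)
  field_map(array(out, dim(geom$data)), spacing = geom$spacing,
            origin = geom$origin)
}

# evaluate the degree-2 background polynomial (Hz) at world coords (mm)
eval_background_poly <- function(coef, p) {
  u <- p[, 1] / 100
  v <- p[, 2] / 100
  w <- p[, 3] / 100
  coef[["const"]] + coef[["x"]] * u + coef[["y"]] * v + coef[["z"]] * w +
    coef[["x2"]] * u^2 + coef[["y2"]] * v^2 + coef[["z2"]] * w^2 +
    coef[["xy"]] * u * v + coef[["xz"]] * u * w + coef[["yz"]] * v * w
}

#' Generate one synthetic subject
#'
#' Builds the brain mask, the off-resonance field (sum of cavity dipole
#' fields, smooth background polynomial, seeded high-order solid-harmonic
#' background and seeded i.i.d. Gaussian noise) and
#' two box ROIs: a prefrontal-cortex box anterior-inferior around the frontal
#' sinus and a medial-temporal box spanning both ear cavities, both
#' intersected with the brain mask.
#'
#' @param config A [subject_config()].
#' @param subject_id Optional id stored on the field map.
#' @return A list of class `shim_subject` with elements `field`, `mask`,
#'   `roi_pfc`, `roi_mtl`, `config`.
#' @examples
#' sub <- generate_subject(subject_config(seed = 7, spacing = c(6, 6, 5)))
#' masked_stats(sub$field, sub$mask)
#' @export
generate_subject <- function(config, subject_id = NULL) {
  mask <- make_brain_mask(config)
  geom <- grid_geometry(config$spacing, config$fov)
  p <- voxel_centers(geom)
  total <- eval_background_poly(config$background_poly, p)
  for (cav in config$cavities) {
    total <- total + as.vector(
      cavity_dipole_field(cav, geom, config$b0_tesla)$data)
  }
  sh_rms <- config$background_sh_rms_hz
  if (is.null(sh_rms)) sh_rms <- c(0, 0, 0)
  draws <- with_seed(config$seed, {
    list(sh_coef = rnorm(sum(2 * (3:5) + 1)),
         noise = if (config$noise_sd_hz > 0) {
           rnorm(nrow(p), sd = config$noise_sd_hz)
         } else 0)
  })
  if (any(sh_rms > 0)) {
    raw <- solid_harmonics(p, 5L, center = c(0, 0, 0))
    degs <- attr(raw, "degree")
    keep <- degs >= 3L
    cols <- raw[, keep, drop = FALSE]
    degs <- degs[keep]
    # unit RMS over the brain, then per-degree amplitude split evenly
    rms <- sqrt(colMeans(cols[as.vector(mask$data), , drop = FALSE]^2))
    amp <- sh_rms[degs - 2L] / sqrt(2 * degs + 1)
    total <- total + drop(cols %*% (draws$sh_coef * amp / rms))
  }
  total <- total + draws$noise
  field <- field_map(array(total, dim(geom$data)), spacing = geom$spacing,
                     origin = geom$origin, subject_id = subject_id)

  labels <- vapply(config$cavities, function(x) x$label, character(1))
  centers <- do.call(rbind, lapply(config$cavities, function(x) x$center))
  grp_center <- function(lab) colMeans(centers[labels == lab, , drop = FALSE])
  # ROI anchors fall back to canonical positions when cavities are absent
  fc <- if ("frontal_sinus" %in% labels) grp_center("frontal_sinus")
        else if (length(labels)) centers[which.max(centers[, 2]), ]
        else c(0, 77, -32)
  ears <- if (all(c("ear_left", "ear_right") %in% labels)) {
    rbind(grp_center("ear_left"), grp_center("ear_right"))
  } else if (length(labels) >= 2) {
    centers[order(centers[, 1])[c(1, nrow(centers))], , drop = FALSE]
  } else rbind(c(-57, -19, -36), c(57, -19, -36))

  in_box <- function(lo, hi) {
    p[, 1] >= lo[1] & p[, 1] <= hi[1] &
      p[, 2] >= lo[2] & p[, 2] <= hi[2] &
      p[, 3] >= lo[3] & p[, 3] <= hi[3]
  }
  pfc <- in_box(c(fc[1] - 40, fc[2] - 20, fc[3] - 25),
                c(fc[1] + 40, fc[2] + 30, fc[3] + 45))
  ey <- mean(ears[, 2]); ez <- mean(ears[, 3])
  mtl <- in_box(c(min(ears[, 1]) - 20, ey - 30, ez - 25),
                c(max(ears[, 1]) + 20, ey + 35, ez + 20))
  roi <- function(v) {
    brain_mask(array(v, dim(geom$data)) & mask$data,
               spacing = geom$spacing, origin = geom$origin)
  }
  structure(list(field = field, mask = mask, roi_pfc = roi(pfc),
                 roi_mtl = roi(mtl), config = config),
            class = "shim_subject")
}

#' Cohort jitter distributions
#'
#' Standard deviations of the seeded between-subject jitter applied by
#' [generate_cohort()]: cavity center position, cavity radius, brain-ellipsoid
#' semiaxes (all mm, Gaussian) and an additive Gaussian perturbation of each
#' background polynomial coefficient (Hz).
#'
#' @param center_sd_mm,radius_sd_mm,semiaxes_sd_mm,poly_sd_hz Jitter SDs.
#' @return A named list.
#' @export
cohort_jitter <- function(center_sd_mm = 3, radius_sd_mm = 0.8,
                          semiaxes_sd_mm = 3, poly_sd_hz = 3) {
  list(center_sd_mm = center_sd_mm, radius_sd_mm = radius_sd_mm,
       semiaxes_sd_mm = semiaxes_sd_mm, poly_sd_hz = poly_sd_hz)
}

#' Generate a seeded synthetic cohort
#'
#' Draws `n` subjects from a base configuration with jittered cavity
#' positions/radii, ellipsoid semiaxes and background-field coefficients. All
#' randomness flows from `master_seed`; the same seed reproduces the cohort
#' bit for bit.
#'
#' @param n Number of subjects (>= 2; cohort statistics need at least two).
#' @param base A [subject_config()] used as the template.
#' @param master_seed Integer master seed.
#' @param jitter A [cohort_jitter()] list; all-zero SDs give identical
#'   subjects.
#' @return A list of `n` `shim_subject` objects with ids `"S01"`, `"S02"`, ...
#' @export
generate_cohort <- function(n = 24, base = subject_config(),
                            master_seed = 42, jitter = cohort_jitter()) {
  if (!is.numeric(n) || n < 2) {
    stop("`n` must be >= 2 for cohort statistics", call. = FALSE)
  }
  n <- as.integer(n)
  configs <- with_seed(master_seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      cavs <- lapply(base$cavities, function(cav) {
        cavity_spec(
          center = cav$center + rnorm(3, sd = jitter$center_sd_mm),
          radius = max(1, cav$radius + rnorm(1, sd = jitter$radius_sd_mm)),
          delta_chi_ppm = cav$delta_chi_ppm, label = cav$label)
      })
      poly <- base$background_poly +
        rnorm(length(base$background_poly), sd = jitter$poly_sd_hz)
      # clamp jittered semiaxes so every subject's brain fits the grid
      dims <- pmax(1L, as.integer(round(base$fov / base$spacing)))
      half_fov <- (dims - 1) * base$spacing / 2
      semi <- pmax(10, pmin(base$semiaxes + rnorm(3, sd = jitter$semiaxes_sd_mm),
                            half_fov))
      subject_config(seed = seeds[i], semiaxes = semi, cavities = cavs,
                     background_poly = poly,
                     background_sh_rms_hz = base$background_sh_rms_hz,
                     noise_sd_hz = base$noise_sd_hz,
                     spacing = base$spacing, fov = base$fov,
                     b0_tesla = base$b0_tesla,
                     mask_margin_mm = base$mask_margin_mm)
    })
  })
  ids <- sprintf("S%02d", seq_len(n))
  purrr::map2(configs, ids, generate_subject)
}

#' Write a subject to disk
#'
#' Writes field, mask and ROI volumes as NIfTI plus a JSON sidecar recording
#' the full configuration.
#'
#' @param subject A `shim_subject` from [generate_subject()].
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return The directory, invisibly.
#' @export
write_subject <- function(subject, dir, prefix = "subject") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(subject$field, file.path(dir, paste0(prefix, "_field.nii.gz")))
  write_volume(subject$mask, file.path(dir, paste0(prefix, "_mask.nii.gz")))
  write_volume(subject$roi_pfc, file.path(dir, paste0(prefix, "_roi_pfc.nii.gz")))
  write_volume(subject$roi_mtl, file.path(dir, paste0(prefix, "_roi_mtl.nii.gz")))
  cfg <- subject$config
  cfg$cavities <- lapply(cfg$cavities, unclass)
  jsonlite::write_json(unclass(cfg),
                       file.path(dir, paste0(prefix, "_config.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
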