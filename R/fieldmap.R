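#' Off-resonance field map
#'
#' A `field_map` holds a 3D grid of off-resonance frequency offsets in Hz,
#' together with its voxel spacing and world origin in mm. World coordinates
#' follow `world = origin + index * spacing` with 0-based voxel indices, and
#' the third array axis is the main-field (B0) direction.
#'
#' @param data 3D numeric array of frequency offsets (Hz). All values must be
#'   finite.
#' @param spacing Numeric length-3, voxel spacing `(dx, dy, dz)` in mm;
#'   strictly positive.
#' @param origin Numeric length-3, world coordinate of voxel `(0, 0, 0)` in mm.
#' @param subject_id Optional subject identifier string.
#' @return An object of class `field_map`.
#' @seealso [brain_mask()], [masked_stats()], [read_volume()]
#' @export
field_map <- function(data, spacing, origin = c(0, 0, 0), subject_id = NULL) {
  data <- unclass(data)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (any(dim(data) < 1L)) stop("grid dims must be >= 1", call. = FALSE)
  if (!all(is.finite(data))) {
    stop("field map contains non-finite values", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, origin = origin,
         subject_id = subject_id),
    class = "field_map"
  )
}

#' Binary brain mask
#'
#' A `brain_mask` is a 3D logical array sharing the geometry of the
#' [field_map()] it is paired with. Masks are inputs here: brain extraction
#' itself (e.g. BET on magnitude images) is out of scope.
#'
#' @param data 3D logical (or coercible numeric, binarised at > 0.5) array.
#' @inheritParams field_map
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- unclass(data)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  if (!is.logical(data)) {
    storage.mode(data) <- "double"
    data <- data > 0.5
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "brain_mask"
  )
}

#' @export
dim.field_map <- function(x) dim(x$data)

#' @export
dim.brain_mask <- function(x) dim(x$data)

#' @export
print.field_map <- function(x, ...) {
  cat("<field_map> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      sep = "")
  cat("  range: [", signif(min(x$data), 4), ", ", signif(max(x$data), 4),
      "] Hz\n", sep = "")
  if (!is.null(x$subject_id)) cat("  subject:", x$subject_id, "\n")
  invisible(x)
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("<brain_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " in mask\n", sep = "")
  invisible(x)
}

# shared-geometry contract used throughout the pipeline
check_same_geometry <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data))) {
    stop(sprintf("%s have different shapes (%s vs %s)", what,
                 paste(dim(a$data), collapse = "x"),
                 paste(dim(b$data), collapse = "x")), call. = FALSE)
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-6 ||
      max(abs(a$origin - b$origin)) > 1e-6) {
    stop(sprintf("%s have different geometry (spacing/origin)", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

# world coordinates (mm) of voxel centers; `which` restricts to a logical array
voxel_centers <- function(geom, which = NULL) {
  d <- dim(geom$data)
  sp <- geom$spacing
  or <- geom$origin
  if (is.null(which)) {
    idx <- arrayInd(seq_len(prod(d)), d)
  } else {
    idx <- which(which, arr.ind = TRUE)
  }
  cbind(
    or[1] + (idx[, 1] - 1) * sp[1],
    or[2] + (idx[, 2] - 1) * sp[2],
    or[3] + (idx[, 3] - 1) * sp[3]
  )
}

# population SD (denominator n); convention used for every SD in the package
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  m <- mean(x)
  sqrt(sum((x - m)^2) / n)
}

#' Convert a dual-echo phase pair to an off-resonance field map
#'
#' Computes `f = wrap(phase2 - phase1) / (2 * pi * dTE)` with the phase
#' difference wrapped into `[-pi, pi]` (a difference of exactly +pi maps to
#' +pi, the positive edge of the band) and `dTE` in seconds. The alias-free
#' range is `+/- 1 / (2 * dTE)` Hz; phase unwrapping beyond the single wrap of
#' the echo difference is not performed, so inputs are assumed alias-free.
#'
#' @param phase1,phase2 3D arrays of phase in radians at the first and second
#'   echo.
#' @param te1_ms,te2_ms Echo times in ms; `te2_ms > te1_ms`. Defaults are the
#'   common 3T dual-echo GRE values 2.00 / 4.46 ms.
#' @inheritParams field_map
#' @return A [field_map()] in Hz with the supplied geometry.
#' @examples
#' ph <- array(0, c(4, 4, 4))
#' fm <- phase_diff_to_hz(ph, ph + pi / 2, spacing = c(2.4, 2.4, 2))
#' fm$data[1, 1, 1]  # 101.6 Hz for dTE = 2.46 ms
#' @export
phase_diff_to_hz <- function(phase1, phase2, te1_ms = 2.00, te2_ms = 4.46,
                             spacing, origin = c(0, 0, 0), subject_id = NULL) {
  if (!identical(dim(phase1), dim(phase2))) {
    stop("phase volumes have different shapes", call. = FALSE)
  }
  if (!is.numeric(te1_ms) || !is.numeric(te2_ms) || te2_ms <= te1_ms) {
    stop("echo times invalid: need te2_ms > te1_ms", call. = FALSE)
  }
  dte_s <- (te2_ms - te1_ms) / 1000
  dphi <- phase2 - phase1
  # round-half-even keeps exactly +pi on the positive side
  wrapped <- dphi - 2 * pi * round(dphi / (2 * pi))
  field_map(wrapped / (2 * pi * dte_s), spacing = spacing, origin = origin,
            subject_id = subject_id)
}

#' Read a NIfTI volume as a field map or mask
#'
#' Geometry (voxel spacing and world origin) is taken from the NIfTI header
#' (pixdim and the xform translation). Field maps are expected to be stored in
#' Hz; mask and ROI volumes are binarised at > 0.5.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param kind One of `"field"`, `"mask"`, `"roi"`.
#' @return A [field_map()] for `kind = "field"`, otherwise a [brain_mask()].
#' @export
read_volume <- function(path, kind = c("field", "mask", "roi")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  im <- tryCatch(RNifti::readNifti(path),
                 error = function(e) stop("unreadable NIfTI file: ", path,
                                          call. = FALSE))
  arr <- as.array(im)
  arr <- array(as.double(arr), dim(arr))  # plain array, no image attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- array(arr, dim(arr)[1:3])
  }
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D volume in ", path, call. = FALSE)
  }
  sp <- RNifti::pixdim(im)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    stop("missing or invalid voxel spacing in NIfTI header", call. = FALSE)
  }
  xf <- RNifti::xform(im)
  or <- xf[1:3, 4]
  if (kind == "field") {
    field_map(arr, spacing = sp, origin = or)
  } else {
    brain_mask(arr, spacing = sp, origin = or)
  }
}

#' Write a field map or mask as NIfTI
#'
#' Field data are written as float32; masks as uint8. Spacing and origin go
#' into pixdim and an sform with code 2.
#'
#' @param x A [field_map()] or [brain_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (!inherits(x, c("field_map", "brain_mask"))) {
    stop("`x` must be a field_map or brain_mask", call. = FALSE)
  }
  arr <- x$data
  dtype <- "float"
  if (is.logical(arr)) {
    arr <- array(as.integer(arr), dim(arr))
    dtype <- "uint8"
  }
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- x$spacing
  xf <- diag(c(x$spacing, 1))
  xf[1:3, 4] <- x$origin
  RNifti::qform(im) <- structure(xf, code = 2L)
  RNifti::sform(im) <- structure(xf, code = 2L)
  RNifti::writeNifti(im, path, datatype = dtype)
  invisible(path)
}

#' Masked field statistics
#'
#' Mean, population standard deviation (denominator `n`) and voxel count of a
#' field map over the in-mask voxels. The SD over the whole brain is the
#' homogeneity figure of merit used throughout: shimming aims to minimise it.
#'
#' @param field A [field_map()].
#' @param mask A [brain_mask()] with identical geometry.
#' @return A tibble with columns `mean_hz`, `sd_hz`, `n_voxels`.
#' @examples
#' fm <- field_map(array(7, c(3, 3, 3)), spacing = c(1, 1, 1))
#' mk <- brain_mask(array(TRUE, c(3, 3, 3)), spacing = c(1, 1, 1))
#' masked_stats(fm, mk)
#' @export
masked_stats <- function(field, mask) {
  check_same_geometry(field, mask, "field and mask")
  v <- field$data[mask$data]
  if (length(v) == 0L) stop("mask is empty", call. = FALSE)
  tibble::tibble(mean_hz = mean(v), sd_hz = sd_pop(v), n_voxels = length(v))
}
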