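#' Spectral linewidth model
#'
#' Models the per-voxel spectral linewidth as a constant baseline plus the
#' macroscopic intravoxel term: `linewidth = baseline_hz + SD` where SD is
#' the population standard deviation of the field-map frequencies inside the
#' MRSI voxel. The baseline lumps the T2 contribution `1 / (pi * T2)` and the
#' microscopic susceptibility broadening; 9 Hz is a standard assumption at
#' 3T. A voxel is usable when its linewidth is strictly below `threshold_hz`
#' (default 18 Hz, matching the water-linewidth criterion).
#'
#' @param baseline_hz Baseline linewidth in Hz, > 0.
#' @param threshold_hz Usability cutoff in Hz, > `baseline_hz`.
#' @return An object of class `linewidth_model`.
#' @export
linewidth_model <- function(baseline_hz = 9, threshold_hz = 18) {
  if (!is.numeric(baseline_hz) || baseline_hz <= 0) {
    stop("`baseline_hz` must be > 0", call. = FALSE)
  }
  if (!is.numeric(threshold_hz) || threshold_hz <= baseline_hz) {
    stop("`threshold_hz` must exceed `baseline_hz`", call. = FALSE)
  }
  structure(list(baseline_hz = as.numeric(baseline_hz),
                 threshold_hz = as.numeric(threshold_hz)),
            class = "linewidth_model")
}

#' Linewidth of one MRSI voxel
#'
#' `baseline + population SD` of the in-mask field-map pixels inside the
#' voxel. With the default model, a voxel whose pixel SD is exactly 9 Hz has
#' linewidth 18 Hz and is not usable (strict threshold).
#'
#' @param block_values Numeric vector of in-mask pixel frequencies (Hz);
#'   must be non-empty.
#' @param model A [linewidth_model()].
#' @return Linewidth in Hz.
#' @examples
#' voxel_linewidth(rep(c(6, -6), 10), linewidth_model())  # 9 + 6 = 15 Hz
#' @export
voxel_linewidth <- function(block_values, model = linewidth_model()) {
  if (length(block_values) < 1L) stop("empty block", call. = FALSE)
  model$baseline_hz + sd_pop(block_values)
}

#' MRSI voxel grid over a field map
#'
#' Partitions the field-map grid into MRSI voxels (blocks) of the requested
#' physical size: per-axis block dimension is `round(voxel / spacing)`,
#' floored at 1 pixel. For a 2.4 x 2.4 x 2 mm field map and a 12 x 12 x 10 mm
#' MRSI voxel this is a 5 x 5 x 5 block of 125 pixels (1.44 cc); a requested
#' 4.8 x 4.8 x 4 mm voxel gives a 2 x 2 x 2 block (0.092 cc). A warning (not
#' an error) is raised when the realised voxel volume deviates more than 15%
#' from the requested one.
#'
#' @param spacing Field-map voxel spacing (mm).
#' @param voxel_size_mm Requested MRSI voxel size (mm); scalars are treated
#'   as isotropic.
#' @return An object of class `mrsi_grid` with `block_dims`, `realized_mm`,
#'   `realized_cc`, `requested_mm`.
#' @export
block_partition <- function(spacing, voxel_size_mm = c(12, 12, 10)) {
  spacing <- as.numeric(spacing)
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(spacing <= 0) || any(voxel_size_mm <= 0)) {
    stop("sizes must be positive", call. = FALSE)
  }
  bd <- pmax(1L, as.integer(round(voxel_size_mm / spacing)))
  realized <- bd * spacing
  realized_cc <- prod(realized) / 1000
  requested_cc <- prod(voxel_size_mm) / 1000
  if (abs(realized_cc - requested_cc) > 0.15 * requested_cc) {
    warning(sprintf(
      "realized MRSI voxel %.3g cc deviates >15%% from requested %.3g cc",
      realized_cc, requested_cc), call. = FALSE)
  }
  structure(list(block_dims = bd, realized_mm = realized,
                 realized_cc = realized_cc, requested_mm = voxel_size_mm),
            class = "mrsi_grid")
}

#' @export
print.mrsi_grid <- function(x, ...) {
  cat("<mrsi_grid> blocks ", paste(x$block_dims, collapse = " x "),
      " pixels (", prod(x$block_dims), " per voxel), ",
      signif(x$realized_cc, 3), " cc\n", sep = "")
  invisible(x)
}

#' MRSI brain coverage of a field map
#'
#' Tiles the volume into MRSI voxels (anchored at the volume origin; trailing
#' partial blocks kept), computes each voxel's linewidth from the in-mask
#' pixels, and reports the percentage of brain voxels that are usable. A
#' block is a *brain voxel* iff more than 50% of its pixels are in-mask; its
#' SD uses in-mask pixels only; it is *usable* iff
#' `linewidth < threshold_hz` (strict).
#'
#' @param field A [field_map()] (typically a shimmed residual).
#' @param mask A [brain_mask()] with the same geometry.
#' @param grid An [block_partition()] result.
#' @param model A [linewidth_model()].
#' @param rois Optional named list of ROI [brain_mask()]s; per-ROI coverage
#'   is computed as in [region_coverage()].
#' @return An object of class `coverage_result`: `coverage_pct`,
#'   `n_brain_voxels`, `n_usable`, a per-block tibble `blocks`, and
#'   `roi_coverage` (tibble, possibly empty).
#' @export
compute_coverage <- function(field, mask, grid = block_partition(mask$spacing),
                             model = linewidth_model(), rois = NULL) {
  check_same_geometry(field, mask, "field and mask")
  dims <- dim(field$data)
  bd <- grid$block_dims
  nb <- as.integer(ceiling(dims / bd))
  bi <- (seq_len(dims[1]) - 1L) %/% bd[1]
  bj <- (seq_len(dims[2]) - 1L) %/% bd[2]
  bk <- (seq_len(dims[3]) - 1L) %/% bd[3]
  block_id <- array(0L, dims)
  block_id[] <- 1L + outer(outer(bi, bj * nb[1], "+"), bk * nb[1] * nb[2],
                           "+")
  n_blocks <- prod(nb)
  n_pixels <- tabulate(block_id, n_blocks)
  msk <- mask$data
  id_in <- block_id[msk]
  n_inmask <- tabulate(id_in, n_blocks)
  v <- field$data[msk]
  s1 <- as.vector(rowsum(v, id_in, reorder = TRUE))
  s2 <- as.vector(rowsum(v^2, id_in, reorder = TRUE))
  present <- sort(unique(id_in))
  sum1 <- numeric(n_blocks); sum1[present] <- s1
  sum2 <- numeric(n_blocks); sum2[present] <- s2
  mean_b <- ifelse(n_inmask > 0, sum1 / pmax(n_inmask, 1), NA_real_)
  var_b <- ifelse(n_inmask > 0,
                  pmax(0, sum2 / pmax(n_inmask, 1) - mean_b^2), NA_real_)
  sd_b <- sqrt(var_b)
  is_brain <- n_inmask > 0.5 * n_pixels
  linewidth <- model$baseline_hz + sd_b
  usable <- is_brain & !is.na(linewidth) & linewidth < model$threshold_hz
  n_brain <- sum(is_brain)
  if (n_brain == 0L) stop("no brain voxels at this MRSI resolution",
                          call. = FALSE)
  ijk <- arrayInd(seq_len(n_blocks), nb)
  blocks <- tibble::tibble(
    bi = ijk[, 1], bj = ijk[, 2], bk = ijk[, 3],
    n_pixels = n_pixels, n_inmask = n_inmask,
    sd_hz = sd_b, linewidth_hz = linewidth,
    is_brain = is_brain, usable = usable
  )
  out <- structure(list(
    coverage_pct = 100 * sum(usable) / n_brain,
    n_brain_voxels = n_brain,
    n_usable = sum(usable),
    blocks = blocks,
    grid = grid,
    model = model,
    block_id = block_id,
    mask = mask
  ), class = "coverage_result")
  if (!is.null(rois)) {
    roi_names <- names(rois)
    if (is.null(roi_names)) roi_names <- sprintf("roi%d", seq_along(rois))
    out$roi_coverage <- tibble::tibble(
      roi = roi_names,
      coverage_pct = vapply(rois, function(r) region_coverage(out, r),
                            numeric(1))
    )
  } else {
    out$roi_coverage <- tibble::tibble(roi = character(),
                                       coverage_pct = numeric())
  }
  out
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("<coverage_result> %.1f%% (%d / %d brain voxels usable at %.3g cc)\n",
              x$coverage_pct, x$n_usable, x$n_brain_voxels,
              x$grid$realized_cc))
  if (nrow(x$roi_coverage)) {
    for (i in seq_len(nrow(x$roi_coverage))) {
      cat(sprintf("  %s: %.1f%%\n", x$roi_coverage$roi[i],
                  x$roi_coverage$coverage_pct[i]))
    }
  }
  invisible(x)
}

#' Coverage restricted to a region of interest
#'
#' Both numerator and denominator are restricted to brain voxels whose
#' in-mask pixels are more than 50% inside the ROI; the usability rule is
#' unchanged.
#'
#' @param cov A [compute_coverage()] result.
#' @param roi A [brain_mask()] aligned with the field grid.
#' @return Coverage percentage within the ROI.
#' @export
region_coverage <- function(cov, roi) {
  check_same_geometry(cov$mask, roi, "mask and ROI")
  n_blocks <- nrow(cov$blocks)
  in_roi <- tabulate(cov$block_id[cov$mask$data & roi$data], n_blocks)
  sel <- cov$blocks$is_brain & in_roi > 0.5 * cov$blocks$n_inmask
  if (!any(sel)) stop("ROI intersects no brain voxels", call. = FALSE)
  100 * sum(cov$blocks$usable[sel]) / sum(sel)
}

#' @rdname tidy_coverage
#' @exportS3Method
tidy.coverage_result <- function(x, ...) x$blocks

#' Tidy and summarise a coverage result
#'
#' `tidy()` returns the per-MRSI-voxel table; `glance()` the one-row summary.
#'
#' @param x A `coverage_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_coverage
#' @exportS3Method
glance.coverage_result <- function(x, ...) {
  tibble::tibble(
    coverage_pct = x$coverage_pct,
    n_brain_voxels = x$n_brain_voxels,
    n_usable = x$n_usable,
    voxel_cc = x$grid$realized_cc,
    baseline_hz = x$model$baseline_hz,
    threshold_hz = x$model$threshold_hz
  )
}
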