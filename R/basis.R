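#' Per-channel shim basis matrix
#'
#' Columns are the off-resonance field of one shim channel over the in-mask
#' voxels: Hz per ampere for coil channels, Hz per unit coefficient for
#' spherical-harmonic channels.
#'
#' @param values Numeric matrix, `n_masked_voxels x n_channels`; all finite.
#' @param channel_labels Character vector of column labels.
#' @param units Unit string (`"Hz/A"` or `"Hz/unit"`).
#' @param voxel_index Integer `n x 3` matrix of 1-based voxel indices for each
#'   row.
#' @param meta Optional named list of extra metadata (e.g. SH degrees).
#' @return An object of class `basis_matrix`.
#' @export
basis_matrix <- function(values, channel_labels, units, voxel_index,
                         meta = list()) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("basis contains non-finite entries",
                                    call. = FALSE)
  if (ncol(values) < 1L) stop("basis needs >= 1 channel", call. = FALSE)
  if (length(channel_labels) != ncol(values)) {
    stop("one label per channel required", call. = FALSE)
  }
  if (nrow(voxel_index) != nrow(values)) {
    stop("voxel_index rows must match basis rows", call. = FALSE)
  }
  colnames(values) <- channel_labels
  structure(list(values = values, channel_labels = channel_labels,
                 units = units, voxel_index = voxel_index, meta = meta),
            class = "basis_matrix")
}

#' @export
print.basis_matrix <- function(x, ...) {
  cat("<basis_matrix> ", nrow(x$values), " voxels x ", ncol(x$values),
      " channels [", x$units, "]\n", sep = "")
  invisible(x)
}

#' @export
dim.basis_matrix <- function(x) dim(x$values)

#' Loop Bz by polygonal Biot-Savart integration
#'
#' z-component of the magnetic field of a circular loop discretised into
#' `n_segments` straight chords, evaluated by the Biot-Savart midpoint rule,
#' summed over turns and converted to Hz per ampere with the proton
#' gyromagnetic ratio (42.577 MHz/T). The discretisation error falls as
#' `n_segments^-2`; at the default 256 segments it is ~1e-4 relative.
#'
#' @param loop A [loop_spec()].
#' @param points Numeric `n x 3` matrix of world coordinates (mm).
#' @param n_segments Number of chords (>= 8).
#' @param min_dist_mm Points closer than this to the wire raise a singularity
#'   error.
#' @return Numeric vector of Hz per ampere values.
#' @examples
#' lp <- loop_spec(c(0, 0, 0), c(0, 0, 1), radius = 47.5)
#' loop_bz_numeric(lp, matrix(c(0, 0, 0), 1))  # ~563.2 Hz/A at the center
#' @export
loop_bz_numeric <- function(loop, points, n_segments = 256L,
                            min_dist_mm = 0.1) {
  if (!inherits(loop, "loop_spec")) stop("`loop` must be a loop_spec",
                                         call. = FALSE)
  points <- rbind(points)
  if (ncol(points) != 3L) stop("`points` must be n x 3 (mm)", call. = FALSE)
  n_segments <- as.integer(n_segments)
  if (n_segments < 8L) stop("`n_segments` must be >= 8", call. = FALSE)
  # exact distance to the wire ring (loop frame), not to the chord midpoints
  rel <- sweep(points, 2, loop$center)
  zu <- rel %*% loop$normal
  rho <- sqrt(pmax(0, rowSums(rel^2) - zu^2))
  if (any(sqrt((rho - loop$radius)^2 + zu^2) < min_dist_mm)) {
    stop("evaluation point on or within ", min_dist_mm,
         " mm of the loop wire", call. = FALSE)
  }
  out <- .loop_bz_cpp(points, loop$center, loop$normal, loop$radius,
                      loop$turns, n_segments, min_dist_mm * 0.5,
                      GAMMA_HZ_PER_T)
  if (anyNA(out)) {
    stop("evaluation point on or within ", min_dist_mm,
         " mm of the loop wire", call. = FALSE)
  }
  out
}

#' Loop Bz by the elliptic-integral closed form
#'
#' Exact field of an ideal circular current loop via complete elliptic
#' integrals K and E, in the same units and conventions as
#' [loop_bz_numeric()] (Hz per ampere, z-component in the lab frame, summed
#' over turns). Serves as the independent oracle for the polygonal
#' integration.
#'
#' @inheritParams loop_bz_numeric
#' @return Numeric vector of Hz per ampere values.
#' @export
loop_bz_analytic <- function(loop, points, min_dist_mm = 0.1) {
  points <- rbind(points)
  if (ncol(points) != 3L) stop("`points` must be n x 3 (mm)", call. = FALSE)
  mu0 <- 4e-7 * pi
  a <- loop$radius * 1e-3
  n <- loop$normal
  # loop frame: n plus two orthonormal in-plane axes
  u <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- u - sum(u * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  rel <- sweep(points, 2, loop$center) * 1e-3
  zu <- rel %*% n              # axial coordinate in loop frame (m)
  xu <- rel %*% u
  yu <- rel %*% v
  rho <- sqrt(xu^2 + yu^2)
  # distance to the wire ring
  dw <- sqrt((rho - a)^2 + zu^2)
  if (any(dw < min_dist_mm * 1e-3)) {
    stop("evaluation point on or within ", min_dist_mm,
         " mm of the loop wire", call. = FALSE)
  }
  q <- (a + rho)^2 + zu^2
  m <- 4 * a * rho / q
  ke <- pracma::ellipke(as.vector(m))
  kk <- ke$k
  ee <- ke$e
  denom <- (a - rho)^2 + zu^2
  b_ax <- mu0 / (2 * pi * sqrt(q)) *
    (kk + (a^2 - rho^2 - zu^2) / denom * ee)   # along loop normal
  b_rho <- ifelse(
    rho > 1e-12,
    mu0 * zu / (2 * pi * rho * sqrt(q)) *
      (-kk + (a^2 + rho^2 + zu^2) / denom * ee),
    0
  )
  # back to lab frame, keep z-component only
  rho_safe <- pmax(rho, 1e-300)
  ex <- xu / rho_safe
  ey <- yu / rho_safe
  bz_lab <- b_ax * n[3] + b_rho * (ex * u[3] + ey * v[3])
  as.vector(bz_lab) * loop$turns * GAMMA_HZ_PER_T
}

# real solid harmonics r^l P_l^m(cos theta) {cos, sin}(m phi) for degrees
# 0..max_degree about `center`; coordinates scaled by 1/100 mm so magnitudes
# stay O(1) over a head-sized volume. Returns unnormalised matrix with
# attributes degree/order.
solid_harmonics <- function(points, max_degree, center = c(0, 0, 0)) {
  max_degree <- as.integer(max_degree)
  if (max_degree < 0L || max_degree > 5L) {
    stop("`max_degree` must be in 0..5", call. = FALSE)
  }
  points <- rbind(points)
  x <- (points[, 1] - center[1]) / 100
  y <- (points[, 2] - center[2]) / 100
  z <- (points[, 3] - center[3]) / 100
  r <- sqrt(x^2 + y^2 + z^2)
  ct <- ifelse(r > 0, z / r, 1)
  phi <- atan2(y, x)
  n_terms <- (max_degree + 1L)^2
  out <- matrix(0, length(r), n_terms)
  degs <- integer(n_terms)
  ords <- integer(n_terms)
  col <- 0L
  for (l in 0:max_degree) {
    pl <- if (l == 0L) matrix(1, 1, length(r)) else pracma::legendre(l, ct)
    rl <- r^l
    for (m in -l:l) {
      col <- col + 1L
      am <- abs(m)
      ang <- if (m > 0) cos(m * phi) else if (m < 0) sin(am * phi) else 1
      val <- rl * pl[am + 1L, ] * ang
      val[r == 0] <- if (l == 0L) 1 else 0
      out[, col] <- val
      degs[col] <- l
      ords[col] <- m
    }
  }
  attr(out, "degree") <- degs
  attr(out, "order") <- ords
  out
}

#' Spherical-harmonic shim basis over a brain mask
#'
#' Builds the real solid-harmonic shim fields `r^l P_l^m(cos theta)
#' {cos, sin}(m phi)` for degrees 0 to `max_degree` (degree `l` contributes
#' `2l + 1` terms; degree 0 is the global frequency term), evaluated at the
#' in-mask voxel centers about the expansion center and scaled to unit RMS
#' over the mask. The RMS scaling is a conditioning device only: shim
#' solutions with unbounded SH coefficients are invariant to column scaling.
#'
#' @param mask A [brain_mask()] (supplies both the voxel geometry and the
#'   evaluation points).
#' @param max_degree Highest SH degree, 0..5.
#' @param center Expansion origin in world mm; default is the mask centroid.
#' @param normalize Scale each column to unit RMS over the mask.
#' @return A [basis_matrix()] with `(max_degree + 1)^2` columns, labelled
#'   `"Y<l>,<m>"`, and `meta$degree` / `meta$order` vectors.
#' @export
sh_basis <- function(mask, max_degree = 2L, center = NULL, normalize = TRUE) {
  if (!inherits(mask, "brain_mask")) stop("`mask` must be a brain_mask",
                                          call. = FALSE)
  if (sum(mask$data) < 1L) stop("mask is empty", call. = FALSE)
  pts <- voxel_centers(mask, mask$data)
  if (is.null(center)) center <- colMeans(pts)
  raw <- solid_harmonics(pts, max_degree, center)
  degs <- attr(raw, "degree")
  ords <- attr(raw, "order")
  if (normalize) {
    rms <- sqrt(colMeans(raw^2))
    if (any(rms < 1e-12)) {
      stop("degenerate mask: an SH column has zero RMS (all points at the ",
           "expansion center?)", call. = FALSE)
    }
    raw <- sweep(raw, 2, rms, "/")
  }
  basis_matrix(raw,
               channel_labels = sprintf("Y%d,%d", degs, ords),
               units = "Hz/unit",
               voxel_index = which(mask$data, arr.ind = TRUE),
               meta = list(degree = degs, order = ords, center = center,
                           max_degree = as.integer(max_degree)))
}

#' Coil shim basis over a brain mask
#'
#' One column per loop in the layout: the Biot-Savart field (Hz per ampere,
#' [loop_bz_numeric()]) at the in-mask voxel centers. Errors if any loop's
#' wire passes through the mask volume.
#'
#' @param layout A [coil_layout()].
#' @param mask A [brain_mask()].
#' @param n_segments Chord count for the Biot-Savart integration.
#' @return A [basis_matrix()] in Hz/A with the layout's labels and
#'   `meta$current_bound_a`.
#' @export
assemble_coil_basis <- function(layout, mask, n_segments = 256L) {
  if (!inherits(layout, "coil_layout")) stop("`layout` must be a coil_layout",
                                             call. = FALSE)
  if (sum(mask$data) < 1L) stop("mask is empty", call. = FALSE)
  pts <- voxel_centers(mask, mask$data)
  half_diag <- sqrt(sum(mask$spacing^2)) / 2
  cols <- matrix(0, nrow(pts), length(layout$loops))
  for (j in seq_along(layout$loops)) {
    lp <- layout$loops[[j]]
    # wire-in-brain check: distance from masked voxel centers to the wire ring
    rel <- sweep(pts, 2, lp$center)
    zu <- abs(rel %*% lp$normal)
    rho <- sqrt(pmax(0, rowSums(rel^2) - zu^2))
    dw <- sqrt((rho - lp$radius)^2 + zu^2)
    if (any(dw < half_diag)) {
      stop("loop '", lp$label, "' intersects the brain mask volume",
           call. = FALSE)
    }
    cols[, j] <- loop_bz_numeric(lp, pts, n_segments = n_segments)
  }
  basis_matrix(cols,
               channel_labels = vapply(layout$loops, function(l) l$label,
                                       character(1)),
               units = "Hz/A",
               voxel_index = which(mask$data, arr.ind = TRUE),
               meta = list(
                 layout = layout$name,
                 current_bound_a = vapply(layout$loops,
                                          function(l) l$current_bound_a,
                                          numeric(1))))
}
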