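#' Box-constrained least-squares shim problem
#'
#' The shim problem is `min_c || field + basis %*% c ||^2` subject to
#' `lower <= c <= upper` per channel. Zero current must be feasible
#' (`lower <= 0 <= upper`), so a shim can never be worse than no shim. When
#' `include_f0` is `TRUE` an unbounded constant column is appended, mirroring
#' the scanner's center-frequency adjustment.
#'
#' @param basis A [basis_matrix()] or plain numeric matrix.
#' @param field Masked voxel frequencies (Hz): a numeric vector matching the
#'   basis rows, or a [field_map()] (then `mask` is required to extract the
#'   in-mask values consistent with the basis rows).
#' @param mask Optional [brain_mask()] used when `field` is a `field_map`.
#' @param lower,upper Per-channel bounds; scalars are recycled. Defaults: the
#'   layout's current bounds for a coil basis (from `meta$current_bound_a`),
#'   unbounded for an SH basis.
#' @param include_f0 Append an unbounded global-frequency column.
#' @return An object of class `shim_problem`.
#' @export
shim_problem <- function(basis, field, mask = NULL, lower = NULL,
                         upper = NULL, include_f0 = TRUE) {
  if (inherits(basis, "basis_matrix")) {
    a <- basis$values
    labels <- basis$channel_labels
    default_bound <- basis$meta$current_bound_a
  } else {
    a <- as.matrix(basis)
    labels <- colnames(a)
    if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(ncol(a)))
    default_bound <- NULL
  }
  if (inherits(field, "field_map")) {
    if (is.null(mask)) stop("`mask` required when `field` is a field_map",
                            call. = FALSE)
    check_same_geometry(field, mask, "field and mask")
    f <- field$data[mask$data]
  } else {
    f <- as.numeric(field)
  }
  if (length(f) != nrow(a)) {
    stop("basis rows (", nrow(a), ") must match field length (", length(f),
         ")", call. = FALSE)
  }
  if (length(f) < 1L) stop("empty shim problem (no voxels)", call. = FALSE)
  if (!all(is.finite(f)) || !all(is.finite(a))) {
    stop("non-finite values in field or basis", call. = FALSE)
  }
  p <- ncol(a)
  if (is.null(lower)) {
    lower <- if (!is.null(default_bound)) -default_bound else -Inf
  }
  if (is.null(upper)) {
    upper <- if (!is.null(default_bound)) default_bound else Inf
  }
  lower <- rep_len(lower, p)
  upper <- rep_len(upper, p)
  if (any(lower > 0) || any(upper < 0)) {
    stop("bounds must satisfy lower <= 0 <= upper (zero current feasible)",
         call. = FALSE)
  }
  if (include_f0) {
    a <- cbind(a, f0 = 1)
    labels <- c(labels, "f0")
    lower <- c(lower, -Inf)
    upper <- c(upper, Inf)
  }
  structure(list(a = a, f = f, lower = lower, upper = upper,
                 labels = labels, include_f0 = include_f0),
            class = "shim_problem")
}

#' Solve a shim problem
#'
#' Minimises `|| field + basis %*% c ||^2` over the box `lower <= c <= upper`
#' using an exact dual active-set quadratic program on the normal equations
#' (with a relative ridge of 1e-10 on the Gram matrix to guard rank
#' deficiency; among exactly optimal coefficient sets this selects the one of
#' near-minimum norm). When no finite bounds are present the problem reduces
#' to ordinary least squares.
#'
#' @param problem A [shim_problem()], or a basis (see [shim_problem()]) when
#'   the remaining arguments are supplied.
#' @param ... Passed to [shim_problem()] when `problem` is not already one.
#' @return An object of class `shim_result`: `coefficients` (named),
#'   `residual` (Hz over masked voxels), `sd_before`, `sd_after` (population
#'   SD, Hz), `objective`, `active_bounds` (labels of channels at a bound),
#'   and the problem itself (for [kkt_check()]).
#' @examples
#' a <- cbind(ch1 = c(1, 1, 2, 0))
#' res <- solve_shim(a, field = c(-5, -5, -10, 0), lower = -3, upper = 3,
#'                   include_f0 = FALSE)
#' res$coefficients  # bound-limited at +3
#' @export
solve_shim <- function(problem, ...) {
  if (!inherits(problem, "shim_problem")) {
    problem <- shim_problem(problem, ...)
  }
  a <- problem$a
  f <- problem$f
  p <- ncol(a)
  gram <- crossprod(a)
  # per-column proportional ridge: commutes with column rescaling, so the
  # shim solution is scale-invariant; the absolute floor guards zero columns
  dg <- diag(gram)
  ridge <- 1e-10 * pmax(dg, 1e-12 * mean(dg) + 1e-300)
  d_mat <- gram + diag(ridge, nrow = p)
  d_vec <- -crossprod(a, f)
  finite_lo <- is.finite(problem$lower)
  finite_hi <- is.finite(problem$upper)
  if (!any(finite_lo) && !any(finite_hi)) {
    coef <- drop(solve(d_mat, d_vec))
  } else {
    # constraints: c_i >= lower_i and -c_i >= -upper_i
    cols <- list()
    bvec <- numeric(0)
    for (i in which(finite_lo)) {
      e <- numeric(p); e[i] <- 1
      cols[[length(cols) + 1L]] <- e
      bvec <- c(bvec, problem$lower[i])
    }
    for (i in which(finite_hi)) {
      e <- numeric(p); e[i] <- -1
      cols[[length(cols) + 1L]] <- e
      bvec <- c(bvec, -problem$upper[i])
    }
    amat <- do.call(cbind, cols)
    sol <- quadprog::solve.QP(Dmat = d_mat, dvec = d_vec, Amat = amat,
                              bvec = bvec)
    coef <- sol$solution
  }
  # snap to bounds within solver tolerance, then clip (feasibility is exact)
  tol_b <- 1e-9 * pmax(1, abs(problem$upper))
  coef <- ifelse(is.finite(problem$upper) & coef > problem$upper - tol_b,
                 pmin(coef, problem$upper), coef)
  coef <- ifelse(is.finite(problem$lower) & coef < problem$lower + tol_b,
                 pmax(coef, problem$lower), coef)
  names(coef) <- problem$labels
  residual <- drop(f + a %*% coef)
  at_hi <- is.finite(problem$upper) & coef >= problem$upper - tol_b
  at_lo <- is.finite(problem$lower) & coef <= problem$lower + tol_b
  structure(list(
    coefficients = coef,
    residual = residual,
    sd_before = sd_pop(f),
    sd_after = sd_pop(residual),
    objective = sum(residual^2),
    active_bounds = problem$labels[at_hi | at_lo],
    problem = problem
  ), class = "shim_result")
}

#' @export
print.shim_result <- function(x, ...) {
  cat("<shim_result> ", length(x$coefficients), " channels\n", sep = "")
  cat(sprintf("  SD before: %.2f Hz, after: %.2f Hz (%.1f%% reduction)\n",
              x$sd_before, x$sd_after,
              sd_reduction_pct(x$sd_before, x$sd_after)))
  if (length(x$active_bounds)) {
    cat("  at bound:", paste(x$active_bounds, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Percent reduction in field standard deviation
#'
#' `100 * (1 - sd_after / sd_before)`: e.g. 100 Hz to 73 Hz is a 27%
#' reduction.
#'
#' @param sd_before,sd_after Field SDs in Hz; `sd_before > 0`.
#' @return Percent reduction.
#' @export
sd_reduction_pct <- function(sd_before, sd_after) {
  if (any(sd_before <= 0)) stop("`sd_before` must be > 0", call. = FALSE)
  100 * (1 - sd_after / sd_before)
}

#' KKT optimality audit of a shim result
#'
#' Checks first-order optimality of the box-constrained least-squares
#' solution: interior channels must have (normalised) objective gradient of
#' magnitude below `tol`; a channel at its upper bound must have gradient
#' <= `tol` (relaxing the current cannot decrease the objective), and
#' symmetrically at the lower bound. Gradients are normalised by
#' `2 * ||a_j|| * ||residual||` so `tol` is dimensionless.
#'
#' @param result A [shim_result()] from [solve_shim()].
#' @param tol Dimensionless gradient tolerance.
#' @return A tibble with one row per channel (`channel`, `coefficient`,
#'   `status`, `gradient`, `pass`) carrying an attribute `pass` (overall
#'   logical), also reported by `all(x$pass)`.
#' @export
kkt_check <- function(result, tol = 1e-6) {
  pb <- result$problem
  if (is.null(pb)) stop("result does not carry its problem", call. = FALSE)
  a <- pb$a
  coef <- result$coefficients
  res <- drop(pb$f + a %*% coef)
  g <- drop(2 * crossprod(a, res))
  scale <- 2 * sqrt(colSums(a^2)) * max(sqrt(sum(res^2)), 1e-12)
  gn <- g / scale
  tol_b <- 1e-9 * pmax(1, abs(pb$upper))
  at_hi <- is.finite(pb$upper) & coef >= pb$upper - tol_b
  at_lo <- is.finite(pb$lower) & coef <= pb$lower + tol_b
  status <- unname(ifelse(at_hi, "upper", ifelse(at_lo, "lower",
                                                 "interior")))
  pass <- ifelse(status == "interior", abs(gn) < tol,
                 ifelse(status == "upper", gn <= tol, gn >= -tol))
  out <- tibble::tibble(channel = pb$labels, coefficient = unname(coef),
                        status = status, gradient = unname(gn),
                        pass = unname(pass))
  attr(out, "pass") <- all(pass)
  out
}

#' @rdname tidy_shim
#' @exportS3Method
tidy.shim_result <- function(x, ...) {
  pb <- x$problem
  tibble::tibble(
    channel = names(x$coefficients),
    coefficient = unname(x$coefficients),
    at_bound = names(x$coefficients) %in% x$active_bounds
  )
}

#' Tidy and summarise a shim result
#'
#' `tidy()` returns one row per channel with its coefficient and bound
#' status; `glance()` returns the one-row fit summary (before/after SD,
#' percent reduction, objective, active-bound count).
#'
#' @param x A `shim_result`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_shim
#' @exportS3Method
glance.shim_result <- function(x, ...) {
  tibble::tibble(
    n_channels = length(x$coefficients),
    n_voxels = length(x$residual),
    sd_before_hz = x$sd_before,
    sd_after_hz = x$sd_after,
    sd_reduction_pct = sd_reduction_pct(x$sd_before, x$sd_after),
    objective = x$objective,
    n_at_bound = length(x$active_bounds)
  )
}

# rebuild a full field_map whose in-mask voxels hold the shimmed residual
# (out-of-mask voxels are zeroed); used by the cohort pipeline for coverage
residual_field <- function(result, mask) {
  arr <- array(0, dim(mask$data))
  arr[mask$data] <- result$residual
  field_map(arr, spacing = mask$spacing, origin = mask$origin)
}
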