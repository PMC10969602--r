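#' Circular shim loop specification
#'
#' @param center Numeric length-3, loop center in world mm.
#' @param normal Unit normal of the loop plane (renormalised if within 1e-9 of
#'   unit length, otherwise an error).
#' @param radius Loop radius in mm, > 0.
#' @param turns Number of wire turns (integer >= 1); field per ampere scales
#'   linearly with turns.
#' @param current_bound_a Per-channel current bound in amperes, > 0.
#' @param label Channel label.
#' @return An object of class `loop_spec`.
#' @export
loop_spec <- function(center, normal, radius, turns = 1L,
                      current_bound_a = 3, label = "") {
  center <- as.numeric(center)
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (!is.finite(nn) || abs(nn - 1) > 1e-9) {
    if (abs(nn - 1) < 1e-6) normal <- normal / nn
    else stop("`normal` must be a unit vector", call. = FALSE)
  }
  if (!is.numeric(radius) || radius <= 0) stop("`radius` must be > 0",
                                               call. = FALSE)
  turns <- as.integer(turns)
  if (turns < 1L) stop("`turns` must be >= 1", call. = FALSE)
  if (!is.numeric(current_bound_a) || current_bound_a <= 0) {
    stop("`current_bound_a` must be > 0", call. = FALSE)
  }
  structure(list(center = center, normal = normal / sqrt(sum(normal^2)),
                 radius = as.numeric(radius), turns = turns,
                 current_bound_a = as.numeric(current_bound_a),
                 label = as.character(label)),
            class = "loop_spec")
}

#' Helmet surface model
#'
#' A spherical dome over a cylindrical skirt of the same radius, the surface
#' on which shim loops sit. The skirt spans `z` from
#' `dome_center[3] - cylinder_half_height` to `dome_center[3]`; the dome is
#' the upper hemisphere above it. The default (radius 115 mm, skirt 60 mm)
#' encloses the default brain ellipsoid and field of view with clearance.
#'
#' @param dome_radius Dome (and skirt) radius in mm.
#' @param dome_center Center of the dome sphere in world mm.
#' @param cylinder_half_height Skirt extent below the dome equator in mm.
#' @return An object of class `helmet_model`.
#' @export
helmet_model <- function(dome_radius = 115, dome_center = c(0, 0, 0),
                         cylinder_half_height = 60) {
  if (dome_radius <= 0 || cylinder_half_height < 0) {
    stop("invalid helmet dimensions", call. = FALSE)
  }
  structure(list(dome_radius = as.numeric(dome_radius),
                 dome_center = as.numeric(dome_center),
                 cylinder_half_height = as.numeric(cylinder_half_height)),
            class = "helmet_model")
}

# deterministic, approximately area-uniform points on the helmet surface:
# golden-angle azimuth, area-ordered from the skirt bottom to the dome pole.
# Returns centers (n x 3, mm) and outward normals (n x 3).
helmet_surface_points <- function(helmet, n) {
  r <- helmet$dome_radius
  h <- helmet$cylinder_half_height
  ctr <- helmet$dome_center
  a_cyl <- 2 * pi * r * h
  a_dome <- 2 * pi * r^2
  golden <- pi * (3 - sqrt(5))
  centers <- matrix(0, n, 3)
  normals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    s <- (i - 0.5) / n * (a_cyl + a_dome)
    phi <- (i - 1) * golden
    if (s < a_cyl) {            # on the skirt
      z <- -h + s / (2 * pi * r)
      centers[i, ] <- ctr + c(r * cos(phi), r * sin(phi), z)
      normals[i, ] <- c(cos(phi), sin(phi), 0)
    } else {                    # on the dome (Archimedes: area ~ z)
      z <- (s - a_cyl) / (2 * pi * r)
      rho <- sqrt(max(0, r^2 - z^2))
      centers[i, ] <- ctr + c(rho * cos(phi), rho * sin(phi), z)
      normals[i, ] <- c(rho * cos(phi), rho * sin(phi), z) / r
    }
  }
  list(centers = centers, normals = normals)
}

# point on the dome at azimuth phi (from +y, towards +x) and elevation elev
# above the equator; returns center + outward normal
dome_point <- function(helmet, phi, elev) {
  r <- helmet$dome_radius
  d <- c(sin(phi) * cos(elev), cos(phi) * cos(elev), sin(elev))
  list(center = helmet$dome_center + r * d, normal = d)
}

# point on the skirt at azimuth phi and height z (<= 0, relative to equator)
skirt_point <- function(helmet, phi, z) {
  r <- helmet$dome_radius
  d <- c(sin(phi), cos(phi), 0)
  list(center = helmet$dome_center + c(r * d[1], r * d[2], z), normal = d)
}

#' Coil layout container
#'
#' @param name Layout name.
#' @param loops Ordered list of [loop_spec()] objects; channel count is
#'   `length(loops)`.
#' @return An object of class `coil_layout`.
#' @export
coil_layout <- function(name, loops) {
  stopifnot(is.character(name), is.list(loops), length(loops) >= 1)
  for (lp in loops) {
    if (!inherits(lp, "loop_spec")) stop("all loops must be loop_spec",
                                         call. = FALSE)
  }
  structure(list(name = name, loops = loops), class = "coil_layout")
}

#' @export
print.coil_layout <- function(x, ...) {
  cat("<coil_layout> ", x$name, ": ", length(x$loops), " channels\n", sep = "")
  invisible(x)
}

#' @export
length.coil_layout <- function(x) length(x$loops)

#' Tabular view of a coil layout
#'
#' @param x A [coil_layout()].
#' @param ... Unused.
#' @return A tibble with one row per loop.
#' @importFrom tibble as_tibble
#' @exportS3Method
as_tibble.coil_layout <- function(x, ...) {
  tibble::tibble(
    channel = seq_along(x$loops),
    label = vapply(x$loops, function(l) l$label, character(1)),
    x_mm = vapply(x$loops, function(l) l$center[1], numeric(1)),
    y_mm = vapply(x$loops, function(l) l$center[2], numeric(1)),
    z_mm = vapply(x$loops, function(l) l$center[3], numeric(1)),
    radius_mm = vapply(x$loops, function(l) l$radius, numeric(1)),
    turns = vapply(x$loops, function(l) l$turns, integer(1)),
    current_bound_a = vapply(x$loops, function(l) l$current_bound_a,
                             numeric(1))
  )
}

#' 32-channel shared-loop helmet layout
#'
#' Thirty-two single-turn loops of 9.5 cm diameter (the size of shim-RF shared
#' receive loops in a standard 32-channel head coil) distributed evenly over
#' the helmet surface by a deterministic golden-angle placement, with normals
#' along the outward surface normal.
#'
#' @param helmet A [helmet_model()].
#' @param current_bound_a Per-channel current bound (A).
#' @return A [coil_layout()] with 32 channels.
#' @export
layout_ipres32 <- function(helmet = helmet_model(), current_bound_a = 3) {
  pts <- helmet_surface_points(helmet, 32L)
  loops <- lapply(seq_len(32L), function(i) {
    loop_spec(pts$centers[i, ], pts$normals[i, ], radius = 47.5, turns = 1L,
              current_bound_a = current_bound_a,
              label = sprintf("large%02d", i))
  })
  coil_layout("ipres32", loops)
}

#' 51-channel shim layout with size-matched small loops
#'
#' Twenty-seven large single-turn loops (9.5 cm diameter) distributed evenly
#' over the helmet, plus 24 small two-turn loops targeting the regions nearest
#' the air cavities: a 2 x 4 forehead grid of 5 cm loops on the helmet
#' surface and a ring of eight 4 cm loops around each ear canal, mounted on
#' earmuff insets that sit against the head (closer than the helmet shell, as
#' ear-cavity loops are in practice). Two turns double the shim field per
#' unit current, compensating for the smaller loop area.
#'
#' @inheritParams layout_ipres32
#' @param ear_anchor Ear-canal anchor point for the right ear in mm
#'   `(x, y, z)` (mirrored in x for the left); the ring of ear loops lies in
#'   the sagittal plane `x = ear_anchor[1]` with normals along x.
#' @param ear_ring_radius Radius (mm) of the circle on which the 8 ear-loop
#'   centers sit.
#' @return A [coil_layout()] with 51 channels (27 large + 8 frontal +
#'   8 per ear).
#' @export
layout_unic51 <- function(helmet = helmet_model(), current_bound_a = 3,
                          ear_anchor = c(82, -5, -32),
                          ear_ring_radius = 26) {
  pts <- helmet_surface_points(helmet, 27L)
  large <- lapply(seq_len(27L), function(i) {
    loop_spec(pts$centers[i, ], pts$normals[i, ], radius = 47.5, turns = 1L,
              current_bound_a = current_bound_a,
              label = sprintf("large%02d", i))
  })
  # forehead patch: 2 rows x 4 columns around the +y (anterior) direction
  frontal <- list()
  cols <- c(-40.5, -13.5, 13.5, 40.5) * pi / 180
  k <- 0L
  for (row in 1:2) {
    for (phi in cols) {
      k <- k + 1L
      pt <- if (row == 1L) skirt_point(helmet, phi, -35)
            else skirt_point(helmet, phi, -5)
      frontal[[k]] <- loop_spec(pt$center, pt$normal, radius = 25,
                                turns = 2L,
                                current_bound_a = current_bound_a,
                                label = sprintf("frontal%02d", k))
    }
  }
  # one ring of 8 small loops per ear on a sagittal earmuff inset
  ear_ring <- function(side) {
    sgn <- if (side == "left") -1 else 1
    lapply(1:8, function(j) {
      psi <- 2 * pi * (j - 1) / 8
      ctr <- helmet$dome_center +
        c(sgn * ear_anchor[1],
          ear_anchor[2] + ear_ring_radius * cos(psi),
          ear_anchor[3] + ear_ring_radius * sin(psi))
      loop_spec(ctr, c(sgn, 0, 0), radius = 20, turns = 2L,
                current_bound_a = current_bound_a,
                label = sprintf("ear_%s%02d", side, j))
    })
  }
  coil_layout("unic51", c(large, frontal, ear_ring("left"),
                          ear_ring("right")))
}

#' Save a coil layout as JSON
#'
#' @param layout A [coil_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_layout <- function(layout, path) {
  obj <- list(
    name = layout$name,
    loops = lapply(layout$loops, function(l) {
      list(center_mm = l$center, normal = l$normal, radius_mm = l$radius,
           turns = l$turns, current_bound_a = l$current_bound_a,
           label = l$label)
    })
  )
  # 17 significant digits: doubles survive the round trip bit for bit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a coil layout from JSON
#'
#' Normals within 1e-6 of unit length are renormalised; anything further off
#' is a format error, as is a missing field.
#'
#' @param path Path to a layout JSON written by [save_layout()].
#' @return A [coil_layout()].
#' @export
load_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (is.null(obj$name) || is.null(obj$loops)) {
    stop("layout file missing 'name' or 'loops'", call. = FALSE)
  }
  loops <- lapply(obj$loops, function(l) {
    req <- c("center_mm", "normal", "radius_mm", "turns", "current_bound_a")
    miss <- req[vapply(req, function(f) is.null(l[[f]]), logical(1))]
    if (length(miss)) {
      stop("layout loop missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    nrm <- as.numeric(l$normal)
    nn <- sqrt(sum(nrm^2))
    if (abs(nn - 1) >= 1e-6) {
      stop("loop normal is not unit length (|norm - 1| = ",
           format(abs(nn - 1)), ")", call. = FALSE)
    }
    loop_spec(as.numeric(l$center_mm), nrm / nn, as.numeric(l$radius_mm),
              turns = as.integer(l$turns),
              current_bound_a = as.numeric(l$current_bound_a),
              label = if (is.null(l$label)) "" else as.character(l$label))
  })
  coil_layout(as.character(obj$name), loops)
}
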