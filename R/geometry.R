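#' Blood fluid properties
#'
#' Container for the two fluid constants the resistive model needs. Defaults
#' are the standard Newtonian blood surrogate used in cerebral CFD: density
#' 1050 kg/m^3 and dynamic viscosity 4 mPa s. Blood is shear-thinning, but in
#' narrow cerebral vessels the shear rate is high enough that the Newtonian
#' approximation is conventional.
#'
#' @param density fluid density in kg/m^3; must be > 0.
#' @param viscosity dynamic viscosity in Pa s; must be > 0.
#' @return An object of class `fluid_properties`.
#' @examples
#' blood <- fluid_properties()
#' blood$viscosity   # 0.004 Pa s
#' @export
fluid_properties <- function(density = 1050, viscosity = 4e-3) {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("`density` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(viscosity) || length(viscosity) != 1L ||
      !is.finite(viscosity) || viscosity <= 0) {
    stop("`viscosity` must be a single positive number", call. = FALSE)
  }
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Radius profile along a vessel centerline
#'
#' A vessel's lumen radius sampled at increasing arc positions along its
#' centerline. A single sample denotes a uniform cylinder; multiple samples
#' describe a tapered vessel with linear radius interpolation between
#' samples. All quantities are in metres.
#'
#' @param arc_position numeric vector of arc positions (m), strictly
#'   increasing, all >= 0.
#' @param radius numeric vector of radii (m), same length, all > 0.
#' @return An object of class `radius_profile`.
#' @examples
#' radius_profile(0, 1.1e-3)                      # uniform 1.1 mm vessel
#' radius_profile(c(0, 0.01), c(1.5e-3, 1.0e-3))  # linear taper
#' @export
radius_profile <- function(arc_position, radius) {
  arc_position <- as.numeric(arc_position)
  radius <- as.numeric(radius)
  if (length(arc_position) < 1L || length(arc_position) != length(radius)) {
    stop("`arc_position` and `radius` must be non-empty and equal length",
         call. = FALSE)
  }
  if (anyNA(arc_position) || anyNA(radius)) {
    stop("radius profile must not contain missing values", call. = FALSE)
  }
  if (any(radius <= 0)) {
    stop("invalid geometry: all radii must be strictly positive",
         call. = FALSE)
  }
  if (any(arc_position < 0)) {
    stop("arc positions must be non-negative", call. = FALSE)
  }
  if (length(arc_position) > 1L && any(diff(arc_position) <= 0)) {
    stop("arc positions must be strictly increasing", call. = FALSE)
  }
  structure(list(arc_position = arc_position, radius = radius),
            class = "radius_profile")
}

#' Vessel segment
#'
#' One edge of the vascular network: an anatomically labelled vessel with a
#' length, a radius profile, and (optionally) a directly supplied resistance
#' that bypasses the geometric Poiseuille computation. The override exists
#' because angiographic workflows often report segment resistances on an
#' instrument-specific scale without the underlying length and radius; all
#' downstream ratio-based logic is invariant to that scale.
#'
#' @param id segment identifier (unique within a network).
#' @param from_node,to_node node identifiers; must differ. Positive flow is
#'   directed from `from_node` to `to_node`.
#' @param length centerline length in m; must be > 0.
#' @param radius either a single radius in m (uniform cylinder), a
#'   [radius_profile()], or a two-column matrix/list of `(arc_position,
#'   radius)` samples.
#' @param label anatomical name (e.g. `"left_A1"`, `"ACom"`); defaults to the
#'   id.
#' @param resistance_override optional resistance (pressure x time / volume)
#'   used verbatim instead of the geometric value; must be > 0 when given.
#' @return An object of class `vessel_segment`.
#' @examples
#' seg <- vessel_segment("a1", "ica_term", "acoma", length = 0.014,
#'                       radius = 1.1e-3, label = "left_A1")
#' segment_resistance(seg, fluid_properties())
#' @export
vessel_segment <- function(id, from_node, to_node, length = NULL,
                           radius = NULL, label = id,
                           resistance_override = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  from_node <- as.character(from_node)
  to_node <- as.character(to_node)
  if (identical(from_node, to_node)) {
    stop("segment '", id, "': from_node and to_node must differ",
         call. = FALSE)
  }
  if (!is.null(resistance_override)) {
    resistance_override <- as.numeric(resistance_override)
    if (length(resistance_override) != 1L || !is.finite(resistance_override) ||
        resistance_override <= 0) {
      stop("segment '", id, "': resistance_override must be a single ",
           "positive number", call. = FALSE)
    }
  }
  profile <- NULL
  if (!is.null(radius)) {
    if (inherits(radius, "radius_profile")) {
      profile <- radius
    } else if (is.numeric(radius) && length(radius) == 1L) {
      profile <- radius_profile(0, radius)
    } else {
      m <- as.matrix(radius)
      if (ncol(m) != 2L) {
        stop("segment '", id, "': radius must be a scalar, a ",
             "radius_profile, or a two-column (arc_position, radius) table",
             call. = FALSE)
      }
      profile <- radius_profile(m[, 1L], m[, 2L])
    }
  }
  if (!is.null(length)) {
    length <- as.numeric(length)
    if (base::length(length) != 1L || !is.finite(length) || length <= 0) {
      stop("segment '", id, "': length must be a single positive number",
           call. = FALSE)
    }
    if (!is.null(profile) &&
        max(profile$arc_position) > length * (1 + 1e-9)) {
      stop("segment '", id, "': radius profile extends beyond segment length",
           call. = FALSE)
    }
  }
  if (is.null(resistance_override) && (is.null(length) || is.null(profile))) {
    stop("segment '", id, "': needs either resistance_override or both ",
         "length and radius", call. = FALSE)
  }
  structure(list(id = id, label = as.character(label),
                 from_node = from_node, to_node = to_node,
                 length = length, radius_profile = profile,
                 resistance_override = resistance_override),
            class = "vessel_segment")
}

#' @export
print.vessel_segment <- function(x, ...) {
  r <- tryCatch(segment_resistance(x, fluid_properties()),
                error = function(e) NA_real_)
  cat(sprintf("<vessel_segment> %s (%s): %s -> %s", x$id, x$label,
              x$from_node, x$to_node), "\n")
  if (!is.null(x$resistance_override)) {
    cat(sprintf("  resistance override: %g\n", x$resistance_override))
  } else {
    cat(sprintf("  L = %g m, r = [%g, %g] m, R(blood) = %g Pa s/m^3\n",
                x$length, min(x$radius_profile$radius),
                max(x$radius_profile$radius), r))
  }
  invisible(x)
}

# integral of r(s)^-4 over one linear-taper piece; the algebraic form
# (r1^2 + r1 r2 + r2^2) / (3 r1^3 r2^3) * ds is exact and regular at r1 == r2
.taper_piece_integral <- function(ds, r1, r2) {
  ds * (r1 * r1 + r1 * r2 + r2 * r2) / (3 * r1^3 * r2^3)
}

#' Hagen-Poiseuille resistance of a vessel segment
#'
#' For a uniform cylinder the resistance is `8 mu L / (pi r^4)`. A tapered
#' vessel is treated as a series chain of infinitesimal Poiseuille slices,
#' `R = (8 mu / pi) * integral ds / r(s)^4`, evaluated exactly piecewise under
#' linear radius interpolation between profile samples; any part of the
#' segment outside the sampled range is extended at the nearest sampled
#' radius. A `resistance_override` on the segment takes precedence.
#'
#' @param segment a [vessel_segment()].
#' @param fluid a [fluid_properties()].
#' @return Resistance in Pa s/m^3 (or the override's own units); > 0.
#' @examples
#' s <- vessel_segment("s", "a", "b", length = 0.01, radius = 1e-3)
#' segment_resistance(s, fluid_properties())   # ~1.019e8 Pa s/m^3
#' @export
segment_resistance <- function(segment, fluid) {
  stopifnot(inherits(segment, "vessel_segment"),
            inherits(fluid, "fluid_properties"))
  if (!is.null(segment$resistance_override)) {
    return(segment$resistance_override)
  }
  p <- segment$radius_profile
  L <- segment$length
  mu <- fluid$viscosity
  n <- length(p$radius)
  if (n == 1L) {
    return(8 * mu * L / (pi * p$radius^4))
  }
  s <- p$arc_position
  r <- p$radius
  integral <- 0
  # flat extensions where the profile does not cover [0, L]
  if (s[1L] > 0) integral <- integral + s[1L] / r[1L]^4
  if (s[n] < L) integral <- integral + (L - s[n]) / r[n]^4
  for (i in seq_len(n - 1L)) {
    integral <- integral +
      .taper_piece_integral(s[i + 1L] - s[i], r[i], r[i + 1L])
  }
  8 * mu * integral / pi
}

#' Poiseuille flow through a segment for a given pressure drop
#'
#' The flow-rate form of the Poiseuille law, `Q = pi r^4 dP / (8 mu L)`,
#' expressed through the segment resistance as `Q = dP / R` so that tapered
#' segments and overrides are handled uniformly. The sign of the flow follows
#' the sign of the pressure difference.
#'
#' @param delta_p pressure difference from `from_node` to `to_node` (Pa).
#' @param segment a [vessel_segment()].
#' @param fluid a [fluid_properties()].
#' @return Flow rate in m^3/s, signed.
#' @export
poiseuille_flow <- function(delta_p, segment, fluid) {
  delta_p / segment_resistance(segment, fluid)
}

#' Reynolds number of a segment flow
#'
#' Diameter-based Reynolds number with the mean cross-section velocity
#' `Q / (pi r^2)`: `Re = rho * 2|Q| / (pi r mu)`. Cerebral arterial flow is
#' laminar at physiologic rates (a few hundred); a warning is emitted above
#' 2000, the conventional transition threshold, where the laminar resistive
#' model stops being meaningful.
#'
#' @param flow flow rate in m^3/s (sign ignored).
#' @param radius vessel radius in m; must be > 0.
#' @param fluid a [fluid_properties()].
#' @param warn logical; warn when Re exceeds 2000 (default TRUE).
#' @return Dimensionless Reynolds number, >= 0.
#' @examples
#' reynolds_number(4e-6, 2e-3, fluid_properties())   # ~334
#' @export
reynolds_number <- function(flow, radius, fluid, warn = TRUE) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (any(radius <= 0)) stop("`radius` must be positive", call. = FALSE)
  re <- fluid$density * 2 * abs(flow) / (pi * radius * fluid$viscosity)
  if (warn && any(re > 2000)) {
    warning("Reynolds number exceeds 2000: flow may be turbulent and the ",
            "laminar Poiseuille model unreliable", call. = FALSE)
  }
  re
}
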