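#' Viscous resistance of a circular or annular vessel segment
#'
#' `poiseuille_resistance` gives the fully developed laminar resistance of
#' a straight circular tube, `R = 8 mu L / (pi r^4)`, converted to
#' mmHg s/mL. `annular_resistance` is the corresponding closed form for
#' the annulus left when a concentric wire of radius `r_inner` occupies the
#' lumen,
#' `R = 8 mu L / (pi [r_o^4 - r_i^4 - (r_o^2 - r_i^2)^2 / ln(r_o/r_i)])`,
#' and reduces exactly to the Poiseuille value as `r_inner -> 0`.
#'
#' @param radius,r_outer lumen radius, cm.
#' @param r_inner wire radius, cm; `0 <= r_inner < r_outer`.
#' @param length segment length, cm.
#' @param fluid a [fluid_params()] object.
#' @return Resistance in mmHg s/mL.
#' @examples
#' poiseuille_resistance(0.15, 1)
#' annular_resistance(0.1, 0.018, 1)
#' @export
poiseuille_resistance <- function(radius, length, fluid = fluid_params()) {
  if (any(radius <= 0) || any(length <= 0))
    stop("radius and length must be positive")
  8 * fluid$viscosity * length / (pi * radius^4) / .DYN_PER_MMHG
}

#' @rdname poiseuille_resistance
#' @export
annular_resistance <- function(r_outer, r_inner, length, fluid = fluid_params()) {
  if (any(r_outer <= 0) || any(length <= 0))
    stop("radius and length must be positive")
  if (any(r_inner < 0) || any(r_inner >= r_outer))
    stop("r_inner must satisfy 0 <= r_inner < r_outer")
  if (all(r_inner == 0)) return(poiseuille_resistance(r_outer, length, fluid))
  geom <- ifelse(r_inner == 0, r_outer^4,
                 r_outer^4 - r_inner^4 -
                   (r_outer^2 - r_inner^2)^2 / log(r_outer / r_inner))
  8 * fluid$viscosity * length / (pi * geom) / .DYN_PER_MMHG
}

#' Pressure drop across a stenosis throat
#'
#' Reduced-order stenosis loss model of Young-Tsai type: the drop across
#' the throat is the sum of a viscous term, `R_v q`, with `R_v` the
#' Poiseuille (or annular, when a guidewire crosses the throat) resistance
#' of the narrowed lumen, and a turbulent expansion term
#' `K_t * rho / (2 A_0^2) * (A_0/A_s - 1)^2 * q |q|`,
#' odd in the flow so that reverse flow loses pressure symmetrically.
#' With a wire of radius `r_w`, both the reference area `A_0` and the
#' throat area `A_s` are reduced by the wire cross-section.
#'
#' @param q flow through the throat, mL/s (any sign).
#' @param degree fractional area reduction `1 - A_s/A_0` in `[0, 1)`.
#' @param stenosis_length throat length, cm.
#' @param radius healthy lumen radius of the segment, cm.
#' @param wire_diameter guidewire diameter, cm (0 for wire-absent).
#' @param fluid a [fluid_params()] object.
#' @param kt turbulent-loss coefficient (default 1.52).
#' @return Pressure drop in mmHg, same length as `q`.
#' @examples
#' stenosis_pressure_drop(2, degree = 0.7, stenosis_length = 0.3, radius = 0.12)
#' @export
stenosis_pressure_drop <- function(q, degree, stenosis_length, radius,
                                   wire_diameter = 0, fluid = fluid_params(),
                                   kt = 1.52) {
  co <- stenosis_coefficients(degree, stenosis_length, radius,
                              wire_diameter / 2, fluid, kt)
  co$R_v * q + co$K2 * q * abs(q)
}

# Linear (viscous) and quadratic (turbulent) throat coefficients.
# Units: R_v in mmHg s/mL, K2 in mmHg s^2/mL^2.
stenosis_coefficients <- function(degree, stenosis_length, radius, wire_radius,
                                  fluid, kt) {
  if (degree < 0 || degree >= 1) stop("stenosis degree must lie in [0, 1)")
  r_s <- radius * sqrt(1 - degree)
  if (wire_radius > 0 && wire_radius >= r_s)
    stop(sprintf(
      "wire does not fit: wire radius %.4f cm >= stenotic lumen radius %.4f cm",
      wire_radius, r_s))
  A0 <- pi * (radius^2 - wire_radius^2)
  As <- pi * (r_s^2 - wire_radius^2)
  R_v <- annular_resistance(r_s, wire_radius, stenosis_length, fluid)
  K2 <- kt * fluid$density / (2 * A0^2) * (A0 / As - 1)^2 / .DYN_PER_MMHG
  list(R_v = R_v, K2 = K2)
}

# Per-segment hydraulic coefficients for the whole tree.
# R_dist: distributed viscous resistance of the healthy portion (annular if
#   the wire is present in the segment), interpolable along the segment.
# R_lump/K2: stenosis throat coefficients lumped at fractional position pos.
segment_coefficients <- function(tree, fluid = fluid_params(), kt = 1.52) {
  s <- tree$segments
  n <- nrow(s)
  R_dist <- numeric(n); R_lump <- numeric(n); K2 <- numeric(n)
  pos <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rw <- if (s$wire[i]) tree$wire_diameter_cm / 2 else 0
    if (!is.na(s$sten_degree[i])) {
      Ls <- s$sten_length_cm[i]
      Lh <- s$length_cm[i] - Ls
      R_dist[i] <- if (Lh > 0)
        annular_resistance(s$radius_cm[i], rw, Lh, fluid) else 0
      co <- stenosis_coefficients(s$sten_degree[i], Ls, s$radius_cm[i], rw,
                                  fluid, kt)
      R_lump[i] <- co$R_v
      K2[i] <- co$K2
      pos[i] <- s$sten_pos[i]
    } else {
      R_dist[i] <- annular_resistance(s$radius_cm[i], rw, s$length_cm[i], fluid)
    }
  }
  list(R_dist = R_dist, R_lump = R_lump, K2 = K2, pos = pos)
}

# Drop over a full segment at flow q.
segment_drop <- function(co, i, q) {
  (co$R_dist[i] + co$R_lump[i]) * q + co$K2[i] * q * abs(q)
}

# Linear and quadratic coefficients of the drop from the proximal node of
# segment i to fractional position f within it (distributed resistance
# interpolated; lump included once past its position).
partial_drop_coefficients <- function(co, i, f) {
  include <- !is.na(co$pos[i]) && f >= co$pos[i]
  list(R = co$R_dist[i] * f + if (include) co$R_lump[i] else 0,
       K2 = if (include) co$K2[i] else 0)
}
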