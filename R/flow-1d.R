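# Reduced-order steady airway flow: Bernoulli dynamic-pressure exchange plus
# circular-equivalent Poiseuille viscous loss along the measured area profile.

#' Fluid properties
#'
#' Defaults are air at 20 degrees C: density 1.204 kg/m^3, dynamic viscosity
#' 1.825e-5 Pa s.
#'
#' @param density_kg_m3 fluid density, kg/m^3 (> 0).
#' @param viscosity_pa_s dynamic viscosity, Pa s (> 0).
#' @return a `fluid_properties` list.
#' @export
fluid_properties <- function(density_kg_m3 = 1.204, viscosity_pa_s = 1.825e-5) {
  stopifnot(density_kg_m3 > 0, viscosity_pa_s > 0)
  structure(list(density_kg_m3 = density_kg_m3, viscosity_pa_s = viscosity_pa_s),
            class = "fluid_properties")
}

#' Flow boundary conditions
#'
#' Inspiratory convention: a constant volumetric flow is drawn through the
#' airway (enforced at the outlet/epiglottis end) with the inlet (nostril)
#' pressure pinned at 0 Pa, so luminal pressures are negative under flow.
#'
#' @param inlet_pressure_pa nostril pressure, Pa (default 0).
#' @param flow_ml_s constant volumetric flow rate, ml/s (> 0; default 5.28,
#'   a typical mean peak inspiratory flow for an adult mouse).
#' @return a `flow_bc` list.
#' @export
flow_bc <- function(inlet_pressure_pa = 0, flow_ml_s = 5.28) {
  stopifnot(flow_ml_s > 0)
  structure(list(inlet_pressure_pa = inlet_pressure_pa, flow_ml_s = flow_ml_s),
            class = "flow_bc")
}

#' Quasi-1D steady incompressible flow along an area profile
#'
#' Solves the reduced-order model
#' \deqn{P(s) = P(0) - \tfrac{1}{2}\rho\left[(Q/A(s))^2 - (Q/A(0))^2\right]
#'   - 8\pi\mu Q \int_0^s \frac{du}{A(u)^2}}
#' i.e. inviscid Bernoulli pressure exchange plus the Hagen–Poiseuille
#' viscous loss of the circular tube with the same local area. The mean
#' velocity is `v(s) = Q/A(s)`. The viscous integral uses trapezoidal
#' quadrature on the supplied profile, so resolution of the profile bounds
#' the quadrature error. For a straight circular tube this reduces exactly to
#' `dP = 8 mu L Q / (pi R^4)`.
#'
#' @param area_profile data frame with `s_mm` (strictly increasing) and
#'   `area_mm2` (> 0), e.g. a [phantom_truth] profile or an [area_profile()]
#'   measurement.
#' @param bc a [flow_bc()].
#' @param fluid a [fluid_properties()].
#' @return a `flow_1d` tibble: `s_mm`, `area_mm2`, `velocity_m_s`,
#'   `pressure_pa`, with `bc` and `fluid` attached as attributes.
#' @examples
#' prof <- tibble::tibble(s_mm = seq(0, 10, 0.1), area_mm2 = pi * 0.5^2)
#' sol <- solve_flow_1d(prof, flow_bc(flow_ml_s = 5.28), fluid_properties())
#' range(sol$pressure_pa)
#' @export
solve_flow_1d <- function(area_profile, bc = flow_bc(), fluid = fluid_properties()) {
  ap <- tibble::as_tibble(area_profile)
  stopifnot(all(c("s_mm", "area_mm2") %in% names(ap)))
  ap <- ap[!is.na(ap$area_mm2), ]
  if (any(diff(ap$s_mm) <= 0)) {
    stop("area profile arclengths must be strictly increasing", call. = FALSE)
  }
  if (any(ap$area_mm2 <= 0)) {
    stop("singular geometry: non-positive cross-sectional area", call. = FALSE)
  }
  s_m <- ap$s_mm * 1e-3
  a_m2 <- ap$area_mm2 * 1e-6
  q_m3 <- bc$flow_ml_s * 1e-6
  rho <- fluid$density_kg_m3
  mu <- fluid$viscosity_pa_s

  v <- q_m3 / a_m2
  inv_a2 <- 1 / a_m2^2
  visc_int <- cumtrapz_vec(s_m, inv_a2)
  pressure <- bc$inlet_pressure_pa -
    0.5 * rho * (v^2 - v[1]^2) -
    8 * pi * mu * q_m3 * visc_int

  out <- tibble::tibble(
    s_mm = ap$s_mm, area_mm2 = ap$area_mm2,
    velocity_m_s = v, pressure_pa = pressure
  )
  attr(out, "bc") <- bc
  attr(out, "fluid") <- fluid
  class(out) <- c("flow_1d", class(out))
  out
}

#' Hagen–Poiseuille pressure drop of a straight circular tube
#'
#' Closed form `dP = 8 mu L Q / (pi R^4)`; the analytic oracle against which
#' both flow solvers are validated.
#'
#' @param radius_mm tube radius, mm.
#' @param length_mm tube length, mm.
#' @param flow_ml_s volumetric flow, ml/s.
#' @param fluid a [fluid_properties()].
#' @return pressure drop, Pa (positive).
#' @export
hagen_poiseuille_dp <- function(radius_mm, length_mm, flow_ml_s,
                                fluid = fluid_properties()) {
  8 * fluid$viscosity_pa_s * (length_mm * 1e-3) * (flow_ml_s * 1e-6) /
    (pi * (radius_mm * 1e-3)^4)
}
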