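#' Transmural pressure applied to the sac wall
#'
#' Reduced-order load model: the pressure loading the aneurysm wall is the
#' outlet (arterial) pressure plus the stagnation pressure of the catheter
#' jet, \eqn{P(t) = p_{out}(t) + \tfrac12 \rho v_{jet}(t)^2}, with
#' \eqn{v_{jet}} the stimulus flow rate converted to mean velocity through
#' the catheter's inner lumen. With the stimulus off the transmural pressure
#' equals the outlet pressure exactly.
#'
#' @param load A \code{\link{load_program}}.
#' @param fluid A \code{\link{fluid_properties}}.
#' @param t Times, s; must lie within the load program's time grid.
#' @return Transmural pressure in Pa at each time.
#' @export
transmural_pressure <- function(load, fluid = fluid_properties(), t) {
  stopifnot(inherits(load, "load_program"), inherits(fluid, "fluid_properties"))
  rng <- range(load$series$time_s)
  if (any(t < rng[1] - 1e-12 | t > rng[2] + 1e-12))
    stop(sprintf("time outside the load program grid [%g, %g] s", rng[1], rng[2]))
  p <- waveform_pressure(load$waveform, t)
  q <- if (is.null(load$stimulus)) rep(0, length(t)) else stimulus_flow(load$stimulus, t)
  a_lumen <- pi * (load$catheter_inner_diameter / 2 * 1e-3)^2  # m^2
  v_jet <- (q * 1e-6 / 60) / a_lumen                           # m/s
  p + 0.5 * fluid$density * v_jet^2
}

# first principal Cauchy stress (kPa) of an equibiaxially stretched
# incompressible Fung membrane: sigma = 2 W'(I1) (lambda^2 - lambda^-4),
# I1 = 2 lambda^2 + lambda^-4
.membrane_sigma1 <- function(lambda, material) {
  I1 <- 2 * lambda^2 + lambda^-4
  2 * strain_energy_dI1(I1, material) * (lambda^2 - lambda^-4)
}

# Laplace pressure (kPa) sustained by the membrane at equibiaxial stretch
# lambda: P = 2 sigma h / r with r = R0 lambda, h = H lambda^-2
.membrane_pressure <- function(lambda, R0_mm, H_mm, material) {
  2 * .membrane_sigma1(lambda, material) * H_mm / (R0_mm * lambda^3)
}

#' Inflate the idealized spherical sac membrane
#'
#' Solves the spherical thin-membrane equilibrium for the equibiaxial
#' stretch \eqn{\lambda}: Laplace's law \eqn{P = 2\sigma(\lambda)
#' h(\lambda) / r(\lambda)} with \eqn{r = R_0\lambda}, incompressible
#' thinning \eqn{h = H\lambda^{-2}}, and \eqn{\sigma(\lambda) =
#' (\lambda/2)\, d\hat W/d\lambda} for \eqn{\hat W(\lambda) = W(2\lambda^2 +
#' \lambda^{-4})}. The root is bracketed on the stable ascending branch
#' (first root above \eqn{\lambda = 1}); pressures beyond the limit point of
#' a non-monotone pressure-stretch curve raise an error naming the limit
#' pressure.
#'
#' @param R0 Reference inner radius, mm (the diastolic baseline geometry).
#' @param H Wall thickness, micrometres.
#' @param material A \code{\link{fung_material}} (constant \code{a} in kPa).
#' @param P Transmural pressure, Pa.
#' @param warn_thick Emit a warning when \code{H/R0 > 0.15} (thin-wall
#'   assumption stretched; at the default geometry this is expected).
#' @return A \code{sac_state} list: \code{stretch}, \code{radius} (mm),
#'   \code{volume} (mm^3), \code{sigma1} (kPa), \code{pressure} (kPa,
#'   transmural).
#' @export
inflate_membrane <- function(R0, H, material, P, warn_thick = TRUE) {
  stopifnot(inherits(material, "fung_material"))
  if (R0 <= 0) stop("reference radius R0 must be > 0 mm")
  if (H <= 0) stop("wall thickness H must be > 0 um")
  if (P < 0) stop("transmural pressure must be >= 0 Pa")
  H_mm <- H / 1000
  if (warn_thick && H_mm / R0 > 0.15)
    warning(sprintf("H/R0 = %.2f > 0.15: thin-wall membrane assumption is stretched",
                    H_mm / R0), call. = FALSE)
  p_kpa <- P / 1000
  if (p_kpa == 0) {
    lam <- 1
  } else {
    f <- function(l) .membrane_pressure(l, R0, H_mm, material) - p_kpa
    # march multiplicatively until the target is bracketed or a limit point
    # of the pressure-stretch curve is detected
    l_lo <- 1; p_lo <- 0
    l_hi <- NA
    l <- 1
    repeat {
      l_next <- l * 1.05
      p_next <- .membrane_pressure(l_next, R0, H_mm, material)
      if (!is.finite(p_next)) break
      if (p_next >= p_kpa) { l_hi <- l_next; break }
      if (p_next < p_lo) {  # past the limit point without reaching target
        opt <- stats::optimize(function(x) .membrane_pressure(x, R0, H_mm, material),
                               interval = c(1, l_next), maximum = TRUE)
        stop(sprintf("no equilibrium below the limit point: requested %.6g kPa exceeds the limit pressure %.6g kPa",
                     p_kpa, opt$objective))
      }
      l_lo <- l_next; p_lo <- p_next; l <- l_next
      if (l > 50) stop("membrane stretch exceeded bracketing bound without equilibrium")
    }
    if (is.na(l_hi))
      stop("membrane pressure overflowed before the target was bracketed")
    lam <- stats::uniroot(f, lower = l_lo, upper = l_hi,
                          tol = .Machine$double.eps)$root
  }
  structure(list(
    stretch = lam,
    radius = R0 * lam,
    volume = 4 / 3 * pi * (R0 * lam)^3,
    sigma1 = .membrane_sigma1(lam, material),
    pressure = p_kpa
  ), class = "sac_state")
}

#' @export
print.sac_state <- function(x, ...) {
  cat(sprintf("sac state: lambda = %.6f, r = %.4f mm, V = %.4f mm^3, sigma1 = %.3f kPa, P = %.3f kPa\n",
              x$stretch, x$radius, x$volume, x$sigma1, x$pressure))
  invisible(x)
}

#' Idealized sac geometry
#'
#' @param R0 Reference (diastolic) inner radius of the sac, mm.
#' @param wall_thickness Uniform wall thickness, micrometres.
#' @return A \code{sac_geometry} list.
#' @export
sac_geometry <- function(R0 = 2, wall_thickness = 430) {
  if (R0 <= 0 || wall_thickness <= 0) stop("R0 and wall_thickness must be > 0")
  structure(list(R0 = R0, wall_thickness = wall_thickness),
            class = "sac_geometry")
}

#' Numerical luminal volume change of the sac
#'
#' Forward-model prediction of the luminal volume variation between the
#' baseline acquisition (time \code{t1}, stimulus off) and the stimulated
#' acquisition (time \code{t2}, stimulus on):
#' \eqn{\Delta V_{num} = V(t_2) - V(t_1)}, each volume from
#' \code{\link{inflate_membrane}} at the corresponding transmural pressure.
#' Strictly decreasing in the stiffness constant \code{a} at fixed loading.
#'
#' @param geometry A \code{\link{sac_geometry}}.
#' @param material A \code{\link{fung_material}}.
#' @param load A \code{\link{load_program}} carrying the stimulus (the
#'   baseline pressure at \code{t1} is the cardiac waveform alone).
#' @param t1 Baseline sampling instant, s (stimulus forced off).
#' @param t2 Stimulated sampling instant, s.
#' @param fluid A \code{\link{fluid_properties}}.
#' @return Volume change in mm^3.
#' @export
delta_v_numeric <- function(geometry, material, load, t1, t2,
                            fluid = fluid_properties()) {
  stopifnot(inherits(geometry, "sac_geometry"))
  p1 <- waveform_pressure(load$waveform, t1)  # stimulus off at baseline
  p2 <- transmural_pressure(load, fluid, t2)
  s1 <- inflate_membrane(geometry$R0, geometry$wall_thickness, material, p1,
                         warn_thick = FALSE)
  s2 <- inflate_membrane(geometry$R0, geometry$wall_thickness, material, p2,
                         warn_thick = FALSE)
  s2$volume - s1$volume
}

#' Stress-state comparison between two sac states
#'
#' Percentage changes of the mean first principal Cauchy stress and mean
#' transmural pressure between the baseline (C1) and stimulated (C2)
#' states, both at their systole peaks. For the idealized sac the area mean
#' equals the uniform membrane value.
#'
#' @param state_c1,state_c2 \code{sac_state} objects.
#' @return A list: \code{sigma1_c1}, \code{sigma1_c2}, \code{p_c1},
#'   \code{p_c2} (kPa), \code{d_sigma1_pct}, \code{d_p_pct} (%).
#' @export
stress_metrics <- function(state_c1, state_c2) {
  stopifnot(inherits(state_c1, "sac_state"), inherits(state_c2, "sac_state"))
  if (state_c1$sigma1 == 0 && state_c2$sigma1 != 0)
    stop("undefined percentage: baseline stress is zero with nonzero stimulated stress")
  if (state_c1$pressure == 0 && state_c2$pressure != 0)
    stop("undefined percentage: baseline pressure is zero with nonzero stimulated pressure")
  d_sigma <- if (state_c1$sigma1 == 0) 0 else
    (state_c2$sigma1 - state_c1$sigma1) / state_c1$sigma1 * 100
  d_p <- if (state_c1$pressure == 0) 0 else
    (state_c2$pressure - state_c1$pressure) / state_c1$pressure * 100
  list(sigma1_c1 = state_c1$sigma1, sigma1_c2 = state_c2$sigma1,
       p_c1 = state_c1$pressure, p_c2 = state_c2$pressure,
       d_sigma1_pct = d_sigma, d_p_pct = d_p)
}
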