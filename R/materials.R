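#' Fung-type hyperelastic material
#'
#' Constructs the isotropic incompressible exponential (Fung-like) material
#' used for the aneurysm wall, with strain energy
#' \deqn{W(I_1) = \frac{a}{b}\left(e^{\frac{b}{2}(I_1 - 3)} - 1\right),}
#' where \eqn{I_1} is the first invariant of the right Cauchy-Green
#' deformation tensor, \code{a} (kPa) sets the stiffness scale and \code{b}
#' (dimensionless) the strain stiffening.
#'
#' @param a Stiffness-like constant, kPa. Literature anchor for unruptured
#'   intracranial aneurysms: 353.6 kPa.
#' @param b Dimensionless strain-stiffening exponent (anchor 16.7).
#' @param density Wall density, kg/m^3.
#' @return An object of class \code{fung_material}.
#' @examples
#' mat <- fung_material(a = 353.6, b = 16.7)
#' strain_energy(3.01, mat)
#' @export
fung_material <- function(a, b, density = 1050) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (a <= 0) stop("material constant 'a' must be > 0 (kPa)")
  if (b <= 0) stop("material constant 'b' must be > 0")
  if (density <= 0) stop("density must be > 0 (kg/m^3)")
  structure(list(a = a, b = b, density = density),
            class = "fung_material")
}

#' @export
print.fung_material <- function(x, ...) {
  cat(sprintf("Fung-type incompressible material: a = %.4g kPa, b = %.4g (rho = %g kg/m^3)\n",
              x$a, x$b, x$density))
  invisible(x)
}

#' Strain-energy density of the Fung-type law
#'
#' @param I1 First invariant of the right Cauchy-Green tensor. Must be
#'   \eqn{\ge 3} (attainable for an incompressible deformation).
#' @param material A \code{\link{fung_material}}.
#' @return Strain-energy density in kPa. Zero at the undeformed state
#'   (\code{I1 = 3}), strictly increasing and convex in \code{I1}.
#' @export
strain_energy <- function(I1, material) {
  stopifnot(inherits(material, "fung_material"), is.numeric(I1))
  if (any(I1 < 3 - 1e-12)) stop("I1 < 3 is not attainable for an incompressible deformation")
  (material$a / material$b) * expm1(material$b / 2 * (pmax(I1, 3) - 3))
}

#' Derivative of the strain energy with respect to I1
#'
#' Equals \code{a/2} at the undeformed state \code{I1 = 3}.
#'
#' @inheritParams strain_energy
#' @return dW/dI1 in kPa.
#' @export
strain_energy_dI1 <- function(I1, material) {
  stopifnot(inherits(material, "fung_material"), is.numeric(I1))
  if (any(I1 < 3 - 1e-12)) stop("I1 < 3 is not attainable for an incompressible deformation")
  (material$a / 2) * exp(material$b / 2 * (pmax(I1, 3) - 3))
}

#' Blood / injectate fluid properties
#'
#' Newtonian single-phase blood analogue used by the reduced-order load
#' model.
#'
#' @param density Fluid density, kg/m^3.
#' @param dynamic_viscosity Dynamic viscosity, Pa s.
#' @return An object of class \code{fluid_properties}.
#' @export
fluid_properties <- function(density = 1050, dynamic_viscosity = 0.0035) {
  if (density <= 0 || dynamic_viscosity <= 0)
    stop("fluid density and dynamic viscosity must be > 0")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}
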