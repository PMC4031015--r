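# Material models: single-branch Generalized Maxwell (standard linear
# solid) viscoelasticity acting on the deviatoric response, isotropic
# linear elasticity, the tension-only fiber force law, and the scalar field
# measures (Von Mises stress, principal strains).
#
# Tensor arguments accept either a symmetric 3x3 matrix or a length-6 Voigt
# vector. Strain Voigt vectors use ENGINEERING shear (g12, g13, g23) when
# flagged; the hereditary update works on tensor shear components.

as_sym3 <- function(x, engineering_shear = FALSE) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(3, 3)) || max(abs(x - t(x))) > 1e-8 * (1 + max(abs(x))))
      stopf("expected a symmetric 3x3 tensor")
    return(x)
  }
  if (length(x) != 6) stopf("expected a 3x3 matrix or length-6 Voigt vector")
  s <- if (engineering_shear) x[4:6] / 2 else x[4:6]
  matrix(c(x[1], s[1], s[2],
           s[1], x[2], s[3],
           s[2], s[3], x[3]), 3, 3)
}

#' Effective Poisson ratio for nearly incompressible materials
#'
#' The cell materials are nominally incompressible (nu = 0.5); a purely
#' displacement-based formulation requires nu < 0.5, so nominal 0.5 is
#' realized as 0.499 (quadratic tetrahedra with mean-dilatation volumetric
#' treatment mitigate locking at this value). Nominal values below 0.5 are
#' used unchanged.
#'
#' @param nominal Nominal Poisson ratio.
#' @return Effective Poisson ratio used by the solver.
#' @export
effective_poisson <- function(nominal) {
  if (nominal >= 0.5) 0.499 else nominal
}

#' Prony series from SLS moduli
#'
#' One-branch Prony representation of the relaxation modulus:
#' relative branch modulus \code{g1 = 1 - E_inf/E0}, long-term factor
#' \code{E_inf/E0}, relaxation time \code{tau}.
#'
#' @param mat A \code{\link{visco_material_spec}}.
#' @return List with \code{g1}, \code{tau1}, \code{long_term_factor}.
#' @export
prony_from_moduli <- function(mat) {
  if (mat$E_inf > mat$E0) stopf("E_inf must not exceed E0")
  g1 <- if (mat$mode == "linear_elastic") 0 else 1 - mat$E_inf / mat$E0
  list(g1 = g1, tau1 = mat$tau, long_term_factor = 1 - g1)
}

#' Relaxation modulus of the standard linear solid
#'
#' \eqn{E(t) = E_\infty + (E_0 - E_\infty) e^{-t/\tau}}.
#'
#' @param t Time(s) in seconds, non-negative.
#' @param mat A \code{\link{visco_material_spec}}.
#' @return Modulus in kPa.
#' @export
relaxation_modulus <- function(t, mat) {
  if (any(t < 0)) stopf("t must be non-negative")
  mat$E_inf + (mat$E0 - mat$E_inf) * exp(-t / mat$tau)
}

#' Complex (storage/loss) modulus of the standard linear solid
#'
#' With \eqn{\omega = 2\pi f}:
#' storage \eqn{E' = E_\infty + (E_0-E_\infty)(\omega\tau)^2/(1+(\omega\tau)^2)},
#' loss \eqn{E'' = (E_0-E_\infty)\,\omega\tau/(1+(\omega\tau)^2)}.
#'
#' @param f Frequency in Hz, positive.
#' @param mat A \code{\link{visco_material_spec}}.
#' @return List with \code{storage} and \code{loss} in kPa.
#' @export
complex_modulus <- function(f, mat) {
  if (any(f <= 0)) stopf("f must be positive")
  wt <- 2 * pi * f * mat$tau
  dE <- mat$E0 - mat$E_inf
  list(storage = mat$E_inf + dE * wt^2 / (1 + wt^2),
       loss = dE * wt / (1 + wt^2))
}

#' Fresh viscoelastic internal state
#' @param n Number of tensor components tracked (6 for one point).
#' @return A \code{visco_state}: zero internal tensor, time 0.
#' @export
new_visco_state <- function(n = 6) {
  structure(list(h = numeric(n), last_time = 0), class = "visco_state")
}

#' Recursive deviatoric viscoelastic update
#'
#' Exponential-integrator update of the hereditary integral for one Maxwell
#' branch, exact for strain varying linearly within the step. Writing
#' \eqn{a = e^{-dt/\tau}} and the internal (strain-like) tensor \eqn{h} with
#' \eqn{\sigma_{dev} = 2G_0 (e - h)}, the update is
#' \deqn{h_{n+1} = a\,h_n + g_1(1-a)\,e_n +
#'   g_1\left[1 - \tfrac{\tau}{dt}(1-a)\right](e_{n+1}-e_n).}
#' Under constant strain this relaxes \eqn{\sigma_{dev}} to
#' \eqn{(E_\infty/E_0)\,2G_0\,e}; for \eqn{dt \ll \tau} from a virgin state
#' it returns the glassy response \eqn{2G_0\,e}.
#'
#' @param dt Time step, seconds (> 0).
#' @param dev_strain_new,dev_strain_old Deviatoric strain tensors (tensor
#'   shear components) as length-6 vectors, at the end/start of the step.
#' @param state A \code{\link{new_visco_state}} object.
#' @param prony A \code{\link{prony_from_moduli}} list.
#' @param shear_modulus_0 Instantaneous shear modulus, Pa.
#' @return List with \code{dev_stress} (Pa, Voigt tensor components) and
#'   \code{state} (updated).
#' @export
visco_deviatoric_update <- function(dt, dev_strain_new, dev_strain_old,
                                    state, prony, shear_modulus_0) {
  if (dt <= 0) stopf("dt must be positive")
  a <- exp(-dt / prony$tau1)
  bc <- prony$g1 * (1 - (prony$tau1 / dt) * (1 - a))
  h_new <- a * state$h + prony$g1 * (1 - a) * dev_strain_old +
    bc * (dev_strain_new - dev_strain_old)
  list(dev_stress = 2 * shear_modulus_0 * (dev_strain_new - h_new),
       state = structure(list(h = h_new, last_time = state$last_time + dt),
                         class = "visco_state"))
}

#' Isotropic linear elastic stress
#'
#' Small-strain Hooke law \eqn{\sigma = \lambda\,\mathrm{tr}(\varepsilon) I
#' + 2\mu\,\varepsilon}. Exactly incompressible input (nu = 0.5) is
#' rejected; use \code{\link{effective_poisson}} first.
#'
#' @param strain Symmetric 3x3 strain tensor (or Voigt-6 with tensor shears).
#' @param E Young's modulus, Pa.
#' @param nu_eff Effective Poisson ratio in (0, 0.5).
#' @return Stress tensor (3x3), Pa.
#' @export
isotropic_elastic_stress <- function(strain, E, nu_eff) {
  if (!(nu_eff > 0 && nu_eff < 0.5))
    stopf("nu_eff must lie strictly inside (0, 0.5); map nominal 0.5 with effective_poisson()")
  eps <- as_sym3(strain)
  lam <- E * nu_eff / ((1 + nu_eff) * (1 - 2 * nu_eff))
  mu <- E / (2 * (1 + nu_eff))
  lam * sum(diag(eps)) * diag(3) + 2 * mu * eps
}

#' Tension-only fiber force
#'
#' Linearly elastic cable law: \eqn{F = \max(0, E_{sf} A_{sf}
#' \varepsilon_{tot})} where the total axial strain includes the pre-strain
#' offset. Compression is not transmitted (slack fiber).
#'
#' @param total_axial_strain Total axial strain including pre-strain.
#' @param fibers A \code{\link{fiber_network_spec}}.
#' @param state Optional previous fiber state (unused by the law itself;
#'   carried for bookkeeping).
#' @return List with \code{force} (N) and \code{state}
#'   (\code{taut_flag}, \code{axial_force}).
#' @export
truss_axial_force <- function(total_axial_strain, fibers, state = NULL) {
  f <- pmax(0, fiber_axial_stiffness(fibers) * total_axial_strain)
  list(force = f,
       state = list(taut_flag = f > 0, axial_force = f))
}

#' Von Mises stress
#'
#' \eqn{\sqrt{3/2\; s\!:\!s}} with \eqn{s} the stress deviator.
#'
#' @param stress Symmetric 3x3 stress tensor or Voigt-6
#'   (s11,s22,s33,s12,s13,s23), Pa.
#' @return Scalar Von Mises stress, Pa.
#' @export
von_mises <- function(stress) {
  s <- as_sym3(stress)
  dev <- s - sum(diag(s)) / 3 * diag(3)
  sqrt(1.5 * sum(dev * dev))
}

#' Principal strains
#'
#' Eigenvalues of the small-strain tensor, sorted descending. The scalar
#' "strain" reported in field maps is the largest-magnitude principal
#' value, \code{max(abs(range(principal_strains(e))))}.
#'
#' @param strain Symmetric 3x3 strain tensor or Voigt-6; engineering shear
#'   if \code{engineering_shear = TRUE}.
#' @param engineering_shear Whether Voigt shears are engineering values.
#' @return Numeric length-3, principal strains in decreasing order.
#' @export
principal_strains <- function(strain, engineering_shear = FALSE) {
  e <- as_sym3(strain, engineering_shear = engineering_shear)
  sort(eigen(e, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' Largest-magnitude principal strain
#' @inheritParams principal_strains
#' @return Scalar, the reported strain magnitude (dimensionless).
#' @export
principal_strain_magnitude <- function(strain, engineering_shear = FALSE) {
  p <- principal_strains(strain, engineering_shear = engineering_shear)
  max(abs(p))
}
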