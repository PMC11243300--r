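# Neo-Hookean hyperelasticity with Simo-Taylor volumetric part ---------------
#
# Free energy  Psi(C) = U(J) + W(Cbar)
#   U(J)    = (1/4) kappa (J^2 - 1) - (1/2) kappa ln J
#   W(Cbar) = (1/2) mu_s (tr Cbar - 3),   Cbar = J^(-2/3) C
# Stress split (Cauchy):
#   p_s     = U'(J) = (1/2) kappa (J - 1/J)
#   dev s_s = mu_s J^(-5/3) dev(F F^T)
# The volumetric derivative uses the sign consistent with differentiating U
# (U'(1) = 0); see the methods vignette for the discussion of this choice.

#' Material constants for the vessel wall
#'
#' Defaults: E = 0.75 MPa, nu = 0.45, reference density 1200 kg/m^3; derived
#' shear modulus mu_s = E/(2(1+nu)) and bulk modulus kappa = E/(3(1-2 nu)).
#' The artery segment is ten times stiffer than the bulge (factor applied to E
#' by [assign_regions()]).
#'
#' @param E Young modulus of the bulge (Pa)
#' @param nu Poisson ratio (< 0.5)
#' @param rho_s0 reference density (kg/m^3)
#' @param artery_factor stiffness multiplier for the artery region
#' @return object of class `solid_properties`
#' @export
solid_properties <- function(E = 0.75e6, nu = 0.45, rho_s0 = 1200,
                             artery_factor = 10) {
  stopifnot(E > 0, nu < 0.5, nu > -1, rho_s0 > 0)
  structure(list(E = E, nu = nu, rho_s0 = rho_s0,
                 artery_factor = artery_factor,
                 mu_s = E / (2 * (1 + nu)),
                 kappa = E / (3 * (1 - 2 * nu))),
            class = "solid_properties")
}

# embed a 2x2 plane-strain deformation gradient as 3x3 (F33 = 1)
embed_F <- function(F) {
  if (all(dim(F) == c(3, 3))) return(F)
  stopifnot(all(dim(F) == c(2, 2)))
  F3 <- diag(3); F3[1:2, 1:2] <- F; F3
}

#' Strain-energy density of the wall material
#'
#' @param F deformation gradient, 2x2 (plane strain) or 3x3
#' @param props [solid_properties()]
#' @return energy density (J/m^3)
#' @export
strain_energy <- function(F, props = solid_properties()) {
  F <- embed_F(F)
  J <- det(F)
  if (J <= 0) abort_sf("inverted element: det F <= 0", "sacflow_inversion_error")
  C <- crossprod(F)                      # F^T F
  trCbar <- J^(-2 / 3) * sum(diag(C))
  0.25 * props$kappa * (J^2 - 1) - 0.5 * props$kappa * log(J) +
    0.5 * props$mu_s * (trCbar - 3)
}

#' Volumetric/deviatoric Cauchy stress split
#'
#' @inheritParams strain_energy
#' @return list with `p_s` (hydrostatic part, Pa), `dev` (deviatoric Cauchy
#'   stress, 3x3), and `sigma` (total Cauchy stress p_s I + dev)
#' @export
cauchy_stress <- function(F, props = solid_properties()) {
  F <- embed_F(F)
  J <- det(F)
  if (J <= 0) abort_sf("inverted element: det F <= 0", "sacflow_inversion_error")
  B <- tcrossprod(F)                     # F F^T
  p_s <- 0.5 * props$kappa * (J - 1 / J)
  devB <- B - diag(3) * sum(diag(B)) / 3
  dev <- props$mu_s * J^(-5 / 3) * devB
  list(p_s = p_s, dev = dev, sigma = p_s * diag(3) + dev)
}

#' First Piola-Kirchhoff stress (for reference-configuration assembly)
#' @inheritParams strain_energy
#' @return 3x3 matrix P = J sigma F^{-T}
#' @export
piola_stress <- function(F, props = solid_properties()) {
  F <- embed_F(F)
  s <- cauchy_stress(F, props)
  det(F) * s$sigma %*% t(solve(F))
}

#' Regional stiffness map for a wall mesh
#'
#' Elements whose centroid lies above the sac cut plane (y > plane_height)
#' belong to the bulge and keep factor 1; the remaining (artery) elements get
#' the artery stiffness factor (default 10).
#'
#' @param mesh a mesh with `nodes` (coordinates, mm) and `tri` (element indices)
#' @param plane_height_mm cut plane height (mm), default 8
#' @param artery_factor stiffness multiplier below the plane
#' @return numeric per-element factor vector
#' @export
assign_regions <- function(mesh, plane_height_mm = 8, artery_factor = 10) {
  # nodes in mm by convention; centroid y per element
  cy <- colMeans(matrix(mesh$nodes[as.vector(t(mesh$tri)), 2], nrow = 3))
  ifelse(cy > plane_height_mm, 1, artery_factor)
}
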