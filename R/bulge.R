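# Synthetic labelled bulge surfaces -----------------------------------------
#
# A bulge is a spherical-cap dome through a circular neck ring, radially
# modulated by low-order real spherical harmonics (degrees 2-4, amplitude
# `lobulation_amp`, tapered to zero at the neck so the ring stays circular
# and planar), sheared by the tilt angle and uniformly rescaled about the
# neck barycenter to match the target volume-equivalent diameter.  The local
# frame has the neck in the z = 0 plane with the dome along +z.

#' Bulge generation parameters
#'
#' @param seed integer RNG seed (shape of the harmonic perturbation)
#' @param target_diameter volume-equivalent diameter (mm); cohort sampler
#'   draws from [3, 9]
#' @param height_ratio dome height over neck diameter (hemisphere: 0.5)
#' @param tilt dome-axis tilt from the neck normal (degrees)
#' @param lobulation_amp relative radial perturbation amplitude (0 = smooth)
#' @param neck_radius neck ring radius before volume rescaling (mm)
#' @return `bulge_spec`
#' @export
bulge_spec <- function(seed = 1, target_diameter = 6, height_ratio = 0.5,
                       tilt = 0, lobulation_amp = 0, neck_radius = 1.2) {
  if (neck_radius <= 0 || height_ratio <= 0 || lobulation_amp < 0 ||
      target_diameter <= 0)
    abort_sf("invalid bulge spec: need positive sizes and amplitude >= 0",
             "sacflow_parameter_error")
  h <- 2 * neck_radius * height_ratio
  if (h <= 0.1 * neck_radius)
    abort_sf("degenerate bulge spec: neck radius exceeds the dome extent",
             "sacflow_parameter_error")
  if (lobulation_amp >= 0.8)
    abort_sf("lobulation amplitude too large (self-intersection risk)",
             "sacflow_parameter_error")
  structure(list(seed = as.integer(seed), target_diameter = target_diameter,
                 height_ratio = height_ratio, tilt = tilt,
                 lobulation_amp = lobulation_amp, neck_radius = neck_radius),
            class = "bulge_spec")
}

# associated Legendre P_l^m for l = 2..4 (unnormalized; random coefficients
# absorb constants)
assoc_legendre <- function(l, m, x) {
  s <- sqrt(pmax(1 - x^2, 0))
  switch(paste(l, m),
    "2 0" = (3 * x^2 - 1) / 2, "2 1" = 3 * x * s, "2 2" = 3 * s^2,
    "3 0" = (5 * x^3 - 3 * x) / 2, "3 1" = 1.5 * (5 * x^2 - 1) * s,
    "3 2" = 15 * x * s^2, "3 3" = 15 * s^3,
    "4 0" = (35 * x^4 - 30 * x^2 + 3) / 8,
    "4 1" = 2.5 * (7 * x^3 - 3 * x) * s,
    "4 2" = 7.5 * (7 * x^2 - 1) * s^2,
    "4 3" = 105 * x * s^3, "4 4" = 105 * s^4,
    stop("unsupported degree/order"))
}

#' Generate a labelled bulge surface
#'
#' @param spec [bulge_spec()]
#' @param segments azimuthal resolution of the rings
#' @param rings number of latitude rings from neck to apex
#' @return `labeled_bulge`: a [surface_mesh()] plus `neck_ring` (ordered
#'   boundary vertex indices), `dome_apex` (vertex index) and the realized
#'   `spec`
#' @export
generate_bulge <- function(spec, segments = 64, rings = 32) {
  stopifnot(inherits(spec, "bulge_spec"), segments >= 8, rings >= 4)
  rn <- spec$neck_radius
  h <- 2 * rn * spec$height_ratio
  z0 <- (h^2 - rn^2) / (2 * h)          # sphere center on the axis
  R <- (h^2 + rn^2) / (2 * h)
  if (rn >= R + 1e-12)
    abort_sf("degenerate bulge spec: neck radius exceeds the dome radius",
             "sacflow_parameter_error")
  psi_max <- acos(-z0 / R)

  phi <- seq(0, 2 * pi, length.out = segments + 1)[-(segments + 1)]
  psi <- psi_max * (1 - seq(0, 1, length.out = rings + 1))  # neck -> apex

  # random harmonic coefficients, deterministic per seed
  lm <- do.call(rbind, lapply(2:4, function(l) cbind(l, 0:l)))
  cf <- with_seed(spec$seed, {
    a <- rnorm(nrow(lm)) / (2 * lm[, 1] + 1)
    b <- rnorm(nrow(lm)) / (2 * lm[, 1] + 1)
    cbind(a, b)
  })
  pert_field <- function(cpsi, phiv) {
    f <- 0
    for (k in seq_len(nrow(lm))) {
      l <- lm[k, 1]; mo <- lm[k, 2]
      P <- assoc_legendre(l, mo, cpsi)
      f <- f + P * (cf[k, 1] * cos(mo * phiv) + cf[k, 2] * sin(mo * phiv))
    }
    f
  }
  # normalize perturbation to unit max over the cap
  gs <- expand.grid(cp = cos(seq(0, psi_max, length.out = 40)),
                    ph = seq(0, 2 * pi, length.out = 60))
  fmax <- max(abs(pert_field(gs$cp, gs$ph)), 1e-12)
  taper <- function(cpsi) (cpsi - cos(psi_max)) / (1 - cos(psi_max))

  verts <- matrix(0, 0, 3)
  ring_ids <- list()
  for (i in seq_len(rings)) {            # i = 1 is the neck ring
    ps <- psi[i]
    mult <- 1 + spec$lobulation_amp * taper(cos(ps)) *
      pert_field(rep(cos(ps), length(phi)), phi) / fmax
    r_eff <- R * mult
    ring <- cbind(r_eff * sin(ps) * cos(phi), r_eff * sin(ps) * sin(phi),
                  z0 + r_eff * cos(ps))
    ring_ids[[i]] <- nrow(verts) + seq_along(phi)
    verts <- rbind(verts, ring)
  }
  apex_mult <- 1 + spec$lobulation_amp * taper(1) * pert_field(1, 0) / fmax
  verts <- rbind(verts, c(0, 0, z0 + R * apex_mult))
  apex <- nrow(verts)

  tri <- matrix(0L, 0, 3)
  m <- length(phi)
  for (i in seq_len(rings - 1)) {
    a <- ring_ids[[i]]; b <- ring_ids[[i + 1]]
    j2 <- c(2:m, 1)
    tri <- rbind(tri,
                 cbind(a, a[j2], b[j2]),
                 cbind(a, b[j2], b))
  }
  top <- ring_ids[[rings]]
  tri <- rbind(tri, cbind(top, top[c(2:m, 1)], rep(apex, m)))

  # tilt: shear the dome keeping the neck plane fixed
  if (spec$tilt != 0)
    verts[, 1] <- verts[, 1] + tan(spec$tilt * pi / 180) * verts[, 3]

  msh <- surface_mesh(verts, tri)
  # outward orientation (positive capped volume)
  if (surf_volume(msh) < 0) msh$tri <- msh$tri[, c(1, 3, 2)]
  # uniform rescale about the neck barycenter (origin) to the target volume
  V <- surf_volume(msh)
  d_eq <- (6 * V / pi)^(1 / 3)
  s <- spec$target_diameter / d_eq
  msh$vertices <- msh$vertices * s

  structure(list(vertices = msh$vertices, tri = msh$tri,
                 neck_ring = ring_ids[[1]], dome_apex = apex, spec = spec,
                 scale_applied = s),
            class = c("labeled_bulge", "surface_mesh"))
}

#' @export
print.labeled_bulge <- function(x, ...) {
  d <- compute_descriptors(x)
  cat(sprintf(
    "labeled_bulge: %d vertices; D_eq %.2f mm, AR %.2f, NSI %.3f, tilt %.1f deg\n",
    nrow(x$vertices), d$D_eq, d$aspect_ratio, d$NSI, x$spec$tilt))
  invisible(x)
}

#' Generate a synthetic bulge cohort
#'
#' Volume-equivalent diameters are stratified over [3, 9] mm (one draw per
#' stratum, shuffled), guaranteeing the cohort spans the full size range;
#' height ratio, tilt, lobulation and neck radius are drawn uniformly over
#' ranges representative of sidewall-aneurysm morphologies.
#'
#' @param n number of cases (>= 1)
#' @param seed master seed
#' @param segments,rings mesh resolution per bulge
#' @return list of `list(spec, mesh)` entries
#' @export
generate_cohort <- function(n, seed = 0, segments = 64, rings = 32) {
  if (n < 1) abort_sf("cohort size must be >= 1", "sacflow_parameter_error")
  pars <- with_seed(seed, {
    list(d = 3 + 6 * (sample.int(n) - 1 + runif(n)) / n,
         hr = runif(n, 0.35, 1.1),
         tilt = runif(n, 0, 35),
         amp = runif(n, 0, 0.25),
         rn = runif(n, 0.8, 1.6),
         child = sample.int(2147483646L, n))
  })
  lapply(seq_len(n), function(i) {
    sp <- bulge_spec(seed = pars$child[i], target_diameter = pars$d[i],
                     height_ratio = pars$hr[i], tilt = pars$tilt[i],
                     lobulation_amp = pars$amp[i], neck_radius = pars$rn[i])
    list(spec = sp, mesh = generate_bulge(sp, segments, rings))
  })
}
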