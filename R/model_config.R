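# Scenario configuration: parametric cell/nucleus/membrane geometry, material
# parameter sets, stress-fiber network layout and the cyclic loading schedule.
# Everything downstream (meshing, solving, post-processing) consumes these
# specs; every test input in the package is generated from here.
#
# Unit conventions at this boundary: lengths in micrometres, moduli in kPa
# (cell materials) or MPa (membrane, stress fibers), times in seconds.
# The solver converts to SI (m, Pa, s) exactly once.

SCENARIO_SCHEMA <- "cellstrain-scenario/1"

#' Cell geometry specification
#'
#' Rotationally symmetric flattened ("fried-egg") cell shape: a cosine-power
#' dome of maximum height \code{max_height} sitting on a flat foot of
#' thickness \code{foot_thickness}, with profile
#' \deqn{h(r) = f + (H - f)\,\cos(\pi r / 2R)^p,}
#' where the single exponent \eqn{p} is calibrated so that the revolved
#' volume matches \code{target_volume}.
#'
#' @param radius Cell radius in micrometres (half the 20 um plan diameter).
#' @param max_height Apex height in micrometres.
#' @param foot_thickness Thickness of the flattened rim in micrometres.
#' @param target_volume Total cell volume in cubic micrometres.
#' @param profile_exponent Dome shape exponent; calibrated automatically
#'   when \code{NULL}.
#' @return An object of class \code{cell_geometry_spec}.
#' @export
cell_geometry_spec <- function(radius = 10, max_height = 5, foot_thickness = 1,
                               target_volume = 490, profile_exponent = NULL) {
  radius <- as.numeric(radius); max_height <- as.numeric(max_height)
  foot_thickness <- as.numeric(foot_thickness)
  target_volume <- as.numeric(target_volume)
  if (!(foot_thickness > 0 && foot_thickness < max_height &&
        max_height <= radius))
    stopf("cell geometry requires 0 < foot_thickness < max_height <= radius")
  if (target_volume <= pi * radius^2 * foot_thickness)
    stopf("target_volume (%g um^3) must exceed the foot slab volume (%g um^3)",
          target_volume, pi * radius^2 * foot_thickness)
  geom <- structure(list(radius = radius, max_height = max_height,
                         foot_thickness = foot_thickness,
                         target_volume = target_volume,
                         profile_exponent = NA_real_),
                    class = "cell_geometry_spec")
  geom$profile_exponent <- if (is.null(profile_exponent))
    calibrate_profile_exponent(geom) else as.numeric(profile_exponent)
  geom
}

#' Cell dome height profile
#'
#' Height of the cell surface above the substrate at radial position
#' \code{r}, smooth and monotone non-increasing from the apex to the foot.
#'
#' @param r Radial position(s) in micrometres, within \code{[0, radius]}.
#' @param geom A \code{\link{cell_geometry_spec}}.
#' @return Height(s) in micrometres.
#' @export
profile_height <- function(r, geom) {
  if (any(r < -1e-12 | r > geom$radius + 1e-12))
    stopf("r must lie in [0, %g]", geom$radius)
  r <- pmin(pmax(r, 0), geom$radius)
  geom$foot_thickness + (geom$max_height - geom$foot_thickness) *
    cos(pi * r / (2 * geom$radius))^geom$profile_exponent
}

revolved_profile_volume <- function(geom, exponent = geom$profile_exponent) {
  g <- geom; g$profile_exponent <- exponent
  2 * pi * integrate(function(r) r * profile_height(r, g),
                     0, geom$radius, rel.tol = 1e-12)$value
}

#' Calibrate the dome exponent to the target cell volume
#'
#' Finds the profile exponent such that the revolved profile volume equals
#' \code{geom$target_volume} to within 0.1 cubic micrometres, by adaptive
#' quadrature and root bracketing over the exponent range \code{[0.5, 50]}.
#' Deterministic.
#'
#' @param geom A \code{\link{cell_geometry_spec}}.
#' @return The calibrated exponent (dimensionless).
#' @export
calibrate_profile_exponent <- function(geom) {
  f <- function(p) revolved_profile_volume(geom, p) - geom$target_volume
  lo <- 0.5; hi <- 50
  if (f(lo) < 0 || f(hi) > 0)
    stopf("target volume %g um^3 not attainable for exponent in [%g, %g]",
          geom$target_volume, lo, hi)
  p <- uniroot(f, c(lo, hi), tol = 1e-10)$root
  if (abs(f(p)) > 0.1)
    stopf("profile calibration did not reach 0.1 um^3 (residual %g)", f(p))
  p
}

#' Nucleus specification
#'
#' Oblate spheroidal nucleus centred on the symmetry axis. Note: with the
#' default diameters (5 x 5 x 2 um) the analytic volume is
#' \eqn{(4/3)\pi\,2.5^2\,1 \approx 26.18} um^3; nominal nuclear volumes of
#' ~46 um^3 sometimes quoted for these diameters are inconsistent with an
#' ellipsoid and the diameters are taken as authoritative here.
#'
#' @param equatorial_diameter,polar_diameter Diameters in micrometres.
#' @param center_height Height of the nucleus centre above the substrate, um.
#' @return An object of class \code{nucleus_spec}.
#' @export
nucleus_spec <- function(equatorial_diameter = 5, polar_diameter = 2,
                         center_height = 2.25) {
  out <- structure(list(equatorial_diameter = as.numeric(equatorial_diameter),
                        polar_diameter = as.numeric(polar_diameter),
                        center_height = as.numeric(center_height)),
                   class = "nucleus_spec")
  if (out$equatorial_diameter <= 0 || out$polar_diameter <= 0)
    stopf("nucleus diameters must be positive")
  out
}

nucleus_volume <- function(nucleus) {
  4 / 3 * pi * (nucleus$equatorial_diameter / 2)^2 *
    (nucleus$polar_diameter / 2)
}

# minimum clearance between the nucleus surface and cytoplasm boundary (um),
# checked on a dense angular sampling of the ellipsoid surface
nucleus_clearance <- function(geom, nucleus) {
  a <- nucleus$equatorial_diameter / 2
  c_ <- nucleus$polar_diameter / 2
  zc <- nucleus$center_height
  psi <- seq(-pi / 2, pi / 2, length.out = 721)
  r <- a * cos(psi); z <- zc + c_ * sin(psi)
  if (any(r > geom$radius)) return(-Inf)
  top <- profile_height(r, geom) - z      # distance below dome (vertical)
  bot <- z                                 # distance above substrate
  min(c(top, bot))
}

#' Point on the nucleus surface
#'
#' Parametric point on the nuclear ellipsoid at the given azimuth and
#' latitude, used to place stress-fiber attachment sites.
#'
#' @param azimuth Azimuth in degrees about the symmetry axis.
#' @param latitude Latitude in degrees, -90 (south pole) to +90 (north pole).
#' @param nucleus A \code{\link{nucleus_spec}}.
#' @return Numeric xyz coordinates in micrometres.
#' @export
nucleus_surface_point <- function(azimuth, latitude, nucleus) {
  if (latitude < -90 || latitude > 90)
    stopf("latitude must lie in [-90, 90]")
  a <- nucleus$equatorial_diameter / 2
  c_ <- nucleus$polar_diameter / 2
  al <- azimuth * pi / 180; la <- latitude * pi / 180
  c(a * cos(la) * cos(al), a * cos(la) * sin(al),
    nucleus$center_height + c_ * sin(la))
}

#' Stress-fiber network specification
#'
#' Pre-tensioned actin stress-fiber bundle layout: \code{n_azimuths} radial
#' groups of \code{fibers_per_azimuth} fibers each, running from basal
#' anchor radii to prescribed latitudes on the nuclear surface. Defaults
#' give the 24-fiber network (8 groups of 3 at 45-degree intervals).
#'
#' @param n_azimuths Number of radial groups.
#' @param fibers_per_azimuth Fibers per group.
#' @param azimuth_spacing Angular spacing between groups, degrees.
#' @param foot_anchor_radii Basal anchor radii, micrometres (one per fiber
#'   in a group).
#' @param nucleus_latitudes Nuclear attachment latitudes, degrees.
#' @param diameter Fiber diameter, micrometres.
#' @param elastic_modulus Fiber modulus, MPa.
#' @param pre_strain Pre-tension expressed as fiber strain (dimensionless).
#' @return An object of class \code{fiber_network_spec}.
#' @export
fiber_network_spec <- function(n_azimuths = 8, fibers_per_azimuth = 3,
                               azimuth_spacing = 45,
                               foot_anchor_radii = c(6, 7.5, 9),
                               nucleus_latitudes = c(-45, 0, 45),
                               diameter = 0.3, elastic_modulus = 1.45,
                               pre_strain = 0.001) {
  out <- structure(list(n_azimuths = as.numeric(n_azimuths),
                        fibers_per_azimuth = as.numeric(fibers_per_azimuth),
                        azimuth_spacing = as.numeric(azimuth_spacing),
                        foot_anchor_radii = as.numeric(foot_anchor_radii),
                        nucleus_latitudes = as.numeric(nucleus_latitudes),
                        diameter = as.numeric(diameter),
                        elastic_modulus = as.numeric(elastic_modulus),
                        pre_strain = as.numeric(pre_strain)),
                   class = "fiber_network_spec")
  if (length(out$foot_anchor_radii) != out$fibers_per_azimuth ||
      length(out$nucleus_latitudes) != out$fibers_per_azimuth)
    stopf("foot_anchor_radii and nucleus_latitudes need one entry per fiber")
  if (out$pre_strain < 0) stopf("pre_strain must be >= 0")
  if (out$diameter <= 0) stopf("fiber diameter must be positive")
  out
}

#' Membrane (substrate) specification
#'
#' The elastomeric PDMS sheet the cell adheres to. In the default
#' \code{prescribed_basal_displacement} coupling the membrane is not meshed:
#' it is two orders of magnitude stiffer than the cell (modulus ratio
#' ~277), so the imposed equibiaxial strain field is transferred to the
#' basal cell surface as a prescribed displacement.
#'
#' @param thickness Sheet thickness, millimetres.
#' @param elastic_modulus Sheet modulus, MPa.
#' @param poisson_ratio Sheet Poisson ratio (must be < 0.5).
#' @param coupling_mode \code{"prescribed_basal_displacement"} (supported) or
#'   \code{"explicit_shell"} (reserved; rejected by the solver).
#' @param model_radius Modelled membrane radius, micrometres
#'   (\code{explicit_shell} only).
#' @return An object of class \code{membrane_spec}.
#' @export
membrane_spec <- function(thickness = 0.25, elastic_modulus = 1.8,
                          poisson_ratio = 0.49,
                          coupling_mode = "prescribed_basal_displacement",
                          model_radius = 40) {
  coupling_mode <- match.arg(coupling_mode,
                             c("prescribed_basal_displacement",
                               "explicit_shell"))
  if (!(poisson_ratio > 0 && poisson_ratio < 0.5))
    stopf("membrane poisson_ratio must lie in (0, 0.5)")
  structure(list(thickness = as.numeric(thickness),
                 elastic_modulus = as.numeric(elastic_modulus),
                 poisson_ratio = as.numeric(poisson_ratio),
                 coupling_mode = coupling_mode,
                 model_radius = as.numeric(model_radius)),
            class = "membrane_spec")
}

#' Cytoplasm material specification (standard linear solid)
#'
#' Single-branch Generalized Maxwell viscoelasticity with instantaneous
#' modulus \code{E0}, equilibrium modulus \code{E_inf} and relaxation time
#' \code{tau}. The nominal Poisson ratio of 0.5 (incompressible) is realized
#' numerically as an effective value of 0.499 (see
#' \code{\link{effective_poisson}}).
#'
#' @param E0 Instantaneous modulus, kPa.
#' @param E_inf Equilibrium modulus, kPa.
#' @param tau Relaxation time, seconds.
#' @param poisson_ratio Nominal Poisson ratio.
#' @param mode \code{"viscoelastic"} or \code{"linear_elastic"} (the latter
#'   uses \code{E0} and ignores \code{E_inf}/\code{tau}).
#' @return An object of class \code{visco_material_spec}.
#' @export
visco_material_spec <- function(E0 = 6.5, E_inf = 4.3, tau = 15.4,
                                poisson_ratio = 0.5,
                                mode = "viscoelastic") {
  mode <- match.arg(mode, c("viscoelastic", "linear_elastic"))
  E0 <- as.numeric(E0); E_inf <- as.numeric(E_inf); tau <- as.numeric(tau)
  if (!(E0 >= E_inf && E_inf > 0)) stopf("need E0 >= E_inf > 0")
  if (tau <= 0) stopf("tau must be positive")
  structure(list(E0 = E0, E_inf = E_inf, tau = tau,
                 poisson_ratio = as.numeric(poisson_ratio), mode = mode),
            class = "visco_material_spec")
}

#' Nucleus material specification
#'
#' Isotropic linear elastic nucleus; default modulus is four times the
#' instantaneous cytoplasmic modulus. With \code{iso_elastic_flag = TRUE}
#' the modulus is forced to the cytoplasmic value (6.5 kPa), the
#' "iso-elastic nucleus" variant.
#'
#' @param elastic_modulus Modulus, kPa.
#' @param poisson_ratio Nominal Poisson ratio.
#' @param iso_elastic_flag Use the cytoplasm modulus instead.
#' @return An object of class \code{nucleus_material_spec}.
#' @export
nucleus_material_spec <- function(elastic_modulus = 26, poisson_ratio = 0.5,
                                  iso_elastic_flag = FALSE) {
  elastic_modulus <- as.numeric(elastic_modulus)
  if (isTRUE(iso_elastic_flag)) elastic_modulus <- 6.5
  if (elastic_modulus <= 0) stopf("nucleus modulus must be positive")
  structure(list(elastic_modulus = elastic_modulus,
                 poisson_ratio = as.numeric(poisson_ratio),
                 iso_elastic_flag = isTRUE(iso_elastic_flag)),
            class = "nucleus_material_spec")
}

#' Loading specification
#'
#' Sinusoidal equibiaxial (radially isotropic) substrate strain.
#'
#' @param strain_amplitude Peak radial strain (default 1e-3, i.e. 1,000
#'   microstrain).
#' @param frequency Stimulation frequency, Hz.
#' @param n_cycles Number of complete strain cycles simulated.
#' @param frames_per_cycle Recorded output frames per cycle.
#' @param waveform Only \code{"sinusoid"} is defined.
#' @return An object of class \code{loading_spec}.
#' @export
loading_spec <- function(strain_amplitude = 1e-3, frequency = 1,
                         n_cycles = 10, frames_per_cycle = 12,
                         waveform = "sinusoid") {
  waveform <- match.arg(waveform, "sinusoid")
  out <- structure(list(strain_amplitude = as.numeric(strain_amplitude),
                        frequency = as.numeric(frequency),
                        n_cycles = as.numeric(n_cycles),
                        frames_per_cycle = as.numeric(frames_per_cycle),
                        waveform = waveform),
                   class = "loading_spec")
  if (out$frequency <= 0) stopf("frequency must be positive")
  if (out$n_cycles < 1) stopf("n_cycles must be >= 1")
  if (out$frames_per_cycle < 2) stopf("frames_per_cycle must be >= 2")
  out
}

#' Full scenario specification
#'
#' Bundles geometry, materials, fiber network (or \code{NULL}), loading and
#' solver options into one serializable description of a simulation.
#'
#' @param geometry,nucleus,membrane,cytoplasm_material,nucleus_material,fibers,loading
#'   Component specs (see the respective constructors); \code{fibers} may be
#'   \code{NULL} for the fiber-free model.
#' @param solver_options A \code{\link{solver_options}} object.
#' @param label Free-text scenario label.
#' @return An object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(geometry = cell_geometry_spec(),
                          nucleus = nucleus_spec(),
                          membrane = membrane_spec(),
                          cytoplasm_material = visco_material_spec(),
                          nucleus_material = nucleus_material_spec(),
                          fibers = NULL,
                          loading = loading_spec(),
                          solver_options = cellstrain::solver_options(),
                          label = "scenario") {
  if (nucleus_clearance(geometry, nucleus) < 0.25)
    stopf("nucleus must clear the cytoplasm boundary by >= 0.25 um")
  if (!is.null(fibers)) {
    if (any(fibers$foot_anchor_radii >= geometry$radius))
      stopf("fiber anchor radii must be smaller than the cell radius")
  }
  structure(list(schema = SCENARIO_SCHEMA,
                 label = as.character(label), geometry = geometry,
                 nucleus = nucleus, membrane = membrane,
                 cytoplasm_material = cytoplasm_material,
                 nucleus_material = nucleus_material, fibers = fibers,
                 loading = loading, solver_options = solver_options),
            class = "scenario_spec")
}

#' Named study scenarios
#'
#' Returns the fully populated \code{\link{scenario_spec}} for one of the
#' canonical study runs. Families: \code{baseline_*} (viscoelastic
#' cytoplasm, 26 kPa nucleus, no fibers), \code{tau0.1_*}/\code{tau1_*}/
#' \code{tau10_*} (relaxation-time sweep), \code{elastic_*} (linear elastic
#' cytoplasm), \code{isoelastic_nucleus_*} (both regions linear elastic at
#' 6.5 kPa) and \code{cytoskeleton_*} (baseline plus the 24-fiber
#' pre-tensioned network), each at \code{1Hz}, \code{20Hz} or \code{45Hz}.
#'
#' @param name Scenario name, e.g. \code{"baseline_45Hz"}.
#' @return A \code{\link{scenario_spec}}.
#' @export
#' @examples
#' spec <- paper_scenario("baseline_45Hz")
#' spec$loading$frequency
paper_scenario <- function(name) {
  valid <- scenario_names()
  if (!is.character(name) || length(name) != 1 || !(name %in% valid))
    stopf("unknown scenario '%s'; valid names are: %s",
          paste(name, collapse = ","), paste(valid, collapse = ", "))
  parts <- regmatches(name, regexec("^(.*)_([0-9]+)Hz$", name))[[1]]
  family <- parts[2]; freq <- as.numeric(parts[3])
  cyt <- visco_material_spec()
  nuc <- nucleus_material_spec()
  fib <- NULL
  if (family %in% c("tau0.1", "tau1", "tau10")) {
    tau <- c("tau0.1" = 0.1, "tau1" = 1, "tau10" = 10)[[family]]
    cyt <- visco_material_spec(tau = tau)
  } else if (family == "elastic") {
    cyt <- visco_material_spec(mode = "linear_elastic")
  } else if (family == "isoelastic_nucleus") {
    cyt <- visco_material_spec(mode = "linear_elastic")
    nuc <- nucleus_material_spec(iso_elastic_flag = TRUE)
  } else if (family == "cytoskeleton") {
    fib <- fiber_network_spec()
  }
  scenario_spec(cytoplasm_material = cyt, nucleus_material = nuc,
                fibers = fib, loading = loading_spec(frequency = freq),
                label = name)
}

#' All canonical scenario names
#' @return Character vector of the 21 study scenario names.
#' @export
scenario_names <- function() {
  fams <- c("baseline", "tau0.1", "tau1", "tau10", "elastic",
            "isoelastic_nucleus", "cytoskeleton")
  as.vector(t(outer(fams, c("1Hz", "20Hz", "45Hz"), paste, sep = "_")))
}

#' Build the stress-fiber segment set
#'
#' Lays out the fiber network: fiber \code{k} of azimuth group \code{j} runs
#' from the basal point at radius \code{foot_anchor_radii[k]} (z = 0) to the
#' nuclear surface point at the group's azimuth and
#' \code{nucleus_latitudes[k]}. The default network has exact 45-degree
#' rotational symmetry.
#'
#' @param fibers A \code{\link{fiber_network_spec}}.
#' @param geom A \code{\link{cell_geometry_spec}}.
#' @param nucleus A \code{\link{nucleus_spec}}.
#' @return A \code{fiber_network}: data frame of segments (one row per
#'   fiber) with endpoint coordinates, plus the material attributes.
#' @export
build_fiber_network <- function(fibers, geom, nucleus) {
  segs <- do.call(rbind, lapply(seq_len(fibers$n_azimuths) - 1, function(j) {
    az <- j * fibers$azimuth_spacing
    do.call(rbind, lapply(seq_len(fibers$fibers_per_azimuth), function(k) {
      r0 <- fibers$foot_anchor_radii[k]
      p0 <- c(r0 * cos(az * pi / 180), r0 * sin(az * pi / 180), 0)
      p1 <- nucleus_surface_point(az, fibers$nucleus_latitudes[k], nucleus)
      data.frame(group = j + 1, fiber = k, azimuth_deg = az,
                 x0 = p0[1], y0 = p0[2], z0 = p0[3],
                 x1 = p1[1], y1 = p1[2], z1 = p1[3],
                 length = sqrt(sum((p1 - p0)^2)))
    }))
  }))
  if (any(segs$length < 1e-9)) stopf("zero-length fiber segment")
  # segments must stay inside the cytoplasm (between substrate, dome and
  # outside the nucleus) strictly between their endpoints
  a <- nucleus$equatorial_diameter / 2; c_ <- nucleus$polar_diameter / 2
  zc <- nucleus$center_height
  for (i in seq_len(nrow(segs))) {
    tt <- seq(0.02, 0.98, length.out = 25)
    px <- segs$x0[i] + tt * (segs$x1[i] - segs$x0[i])
    py <- segs$y0[i] + tt * (segs$y1[i] - segs$y0[i])
    pz <- segs$z0[i] + tt * (segs$z1[i] - segs$z0[i])
    rr <- sqrt(px^2 + py^2)
    if (any(rr > geom$radius + 1e-9) || any(pz < -1e-9) ||
        any(pz > profile_height(pmin(rr, geom$radius), geom) + 1e-9))
      stopf("fiber %d leaves the cell volume", i)
    inside_nuc <- (rr / a)^2 + ((pz - zc) / c_)^2 < 1 - 1e-9
    if (any(inside_nuc)) stopf("fiber %d crosses the nucleus interior", i)
  }
  structure(segs, class = c("fiber_network", "data.frame"),
            spec = fibers)
}

#' Nominal fiber pre-tension force
#'
#' Force-prescription equivalent of the fiber pre-strain:
#' \eqn{N = E_{sf} \,\varepsilon_{pre}\, \pi (d/2)^2}. With defaults
#' (1.45 MPa, 0.3 um, 0.1\% strain) this is about 102.5 pN.
#'
#' @param fibers A \code{\link{fiber_network_spec}}.
#' @return Force in newtons.
#' @export
pretension_force <- function(fibers) {
  area <- pi * (fibers$diameter / 2 * 1e-6)^2            # m^2
  fibers$elastic_modulus * 1e6 * fibers$pre_strain * area # Pa * strain * m^2
}

fiber_axial_stiffness <- function(fibers) {
  # EA in newtons (per unit strain)
  fibers$elastic_modulus * 1e6 * pi * (fibers$diameter / 2 * 1e-6)^2
}

# ---- serialization -------------------------------------------------------

#' Serialize a scenario to JSON
#'
#' Writes (or returns) a lossless JSON form of a \code{\link{scenario_spec}}
#' with a versioned schema string; \code{\link{scenario_from_json}} restores
#' an identical object.
#'
#' @param spec A \code{\link{scenario_spec}}.
#' @param path Optional file path; when omitted the JSON string is returned.
#' @return Invisibly, the JSON string.
#' @export
scenario_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  payload <- lapply(unclass(spec), function(comp) {
    if (is.list(comp)) c(lapply(unclass(comp), identity),
                         list(.class = class(comp)[1]))
    else comp
  })
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                         null = "null", pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(as.character(js))
}

#' Restore a scenario from JSON
#' @param x A JSON string or file path produced by
#'   \code{\link{scenario_to_json}}.
#' @return A \code{\link{scenario_spec}} identical to the serialized one.
#' @export
scenario_from_json <- function(x) {
  txt <- if (file.exists(x)) paste(readLines(x), collapse = "\n") else x
  raw <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  if (!identical(raw$schema, SCENARIO_SCHEMA))
    stopf("unrecognized scenario schema: %s", raw$schema)
  restore <- function(comp) {
    if (!is.list(comp)) return(comp)
    cls <- comp$.class
    comp$.class <- NULL
    comp <- lapply(comp, function(v) if (is.numeric(v)) as.numeric(v) else v)
    structure(comp, class = cls)
  }
  spec <- raw
  for (nm in c("geometry", "nucleus", "membrane", "cytoplasm_material",
               "nucleus_material", "fibers", "loading", "solver_options"))
    if (!is.null(spec[[nm]])) spec[[nm]] <- restore(spec[[nm]])
  structure(spec, class = "scenario_spec")
}
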