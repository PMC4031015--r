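test_that("named scenarios are populated as specified", {
  b45 <- paper_scenario("baseline_45Hz")
  expect_equal(b45$loading$frequency, 45)
  expect_equal(b45$cytoplasm_material$E0, 6.5)
  expect_equal(b45$cytoplasm_material$E_inf, 4.3)
  expect_equal(b45$cytoplasm_material$tau, 15.4)
  expect_equal(b45$nucleus_material$elastic_modulus, 26)
  expect_null(b45$fibers)

  iso <- paper_scenario("isoelastic_nucleus_1Hz")
  expect_equal(iso$nucleus_material$elastic_modulus, 6.5)
  expect_identical(iso$cytoplasm_material$mode, "linear_elastic")
  expect_true(iso$nucleus_material$iso_elastic_flag)

  cyto <- paper_scenario("cytoskeleton_20Hz")
  expect_s3_class(cyto$fibers, "fiber_network_spec")

  # frequency is the only difference between baseline variants
  b1 <- paper_scenario("baseline_1Hz")
  b1mod <- b1
  b1mod$loading$frequency <- 45
  b1mod$label <- "baseline_45Hz"
  expect_identical(b1mod, b45)

  expect_error(paper_scenario("nonsense"), "valid names")
  expect_length(scenario_names(), 21L)
})

test_that("cell profile hits its endpoints and rejects out-of-domain radii", {
  g <- test_geom()
  expect_equal(profile_height(0, g), 5)
  expect_equal(profile_height(10, g), 1)
  expect_error(profile_height(10.5, g), "must lie")
  expect_error(profile_height(-0.1, g), "must lie")
  # monotone non-increasing
  h <- profile_height(seq(0, 10, length.out = 200), g)
  expect_true(all(diff(h) <= 1e-12))
})

test_that("profile exponent calibration matches an independent quadrature oracle", {
  g <- test_geom()
  p_pkg <- g$profile_exponent
  p_oracle <- bisect_profile_exponent(g)
  expect_lt(abs(p_pkg - p_oracle), 1e-3)
  expect_lt(abs(trapz_profile_volume(g, p_pkg) - 490), 0.1)
  # h(R/2) from the calibrated exponent, via direct formula evaluation
  h_half <- 1 + 4 * cos(pi / 4)^p_oracle
  expect_equal(profile_height(5, g), h_half, tolerance = 1e-3)
  # unattainable targets are rejected (dome cannot shrink to ~0)
  expect_error(cell_geometry_spec(target_volume = pi * 100 * 1 + 1),
               "not attainable")
})

test_that("nucleus surface points sit at the parametric locations", {
  n <- test_nucleus()
  expect_equal(nucleus_surface_point(0, 0, n), c(2.5, 0, 2.25))
  expect_equal(nucleus_surface_point(0, 90, n), c(0, 0, 3.25))
  expect_equal(nucleus_surface_point(45, 0, n),
               c(2.5 / sqrt(2), 2.5 / sqrt(2), 2.25))
  expect_error(nucleus_surface_point(0, 95, n), "latitude")
})

test_that("fiber network has 24 segments in 8 groups with 45-degree symmetry", {
  net <- build_fiber_network(fiber_network_spec(), test_geom(),
                             test_nucleus())
  expect_equal(nrow(net), 24L)
  expect_equal(length(unique(net$group)), 8L)
  # rotating every azimuth by 45 degrees reproduces the same segment set
  rot <- function(x, y, ang) cbind(x * cos(ang) - y * sin(ang),
                                   x * sin(ang) + y * cos(ang))
  p0r <- rot(net$x0, net$y0, pi / 4)
  key <- function(m) sort(apply(round(m, 9), 1, paste, collapse = "/"))
  expect_identical(key(cbind(p0r, net$z0)),
                   key(cbind(net$x0, net$y0, net$z0)))
  # segment lengths agree with the Euclidean distance of their endpoints
  lens <- sqrt((net$x1 - net$x0)^2 + (net$y1 - net$y0)^2 +
                 (net$z1 - net$z0)^2)
  expect_equal(net$length, lens)
  # spot-check one endpoint against nucleus_surface_point
  expect_equal(unlist(net[1, c("x1", "y1", "z1")], use.names = FALSE),
               nucleus_surface_point(0, -45, test_nucleus()))
})

test_that("pre-tension force follows E * eps * A", {
  fib <- fiber_network_spec()
  expect_equal(pretension_force(fib), 1.45e6 * 1e-3 * pi * 0.15e-6^2)
  expect_equal(pretension_force(fib), 1.025e-10, tolerance = 1e-3)
  expect_equal(pretension_force(fiber_network_spec(pre_strain = 0)), 0)
  f2 <- fiber_network_spec(diameter = 0.6)
  expect_equal(pretension_force(f2) / pretension_force(fib), 4)
})

test_that("scenario specs round-trip losslessly through JSON", {
  for (nm in c("baseline_45Hz", "cytoskeleton_1Hz", "tau0.1_20Hz")) {
    spec <- paper_scenario(nm)
    js <- scenario_to_json(spec)
    back <- scenario_from_json(js)
    expect_identical(back, spec, label = nm)
  }
  tmp <- tempfile(fileext = ".json")
  scenario_to_json(paper_scenario("elastic_1Hz"), tmp)
  expect_identical(scenario_from_json(tmp), paper_scenario("elastic_1Hz"))
})

test_that("spec invariants are enforced", {
  expect_error(cell_geometry_spec(foot_thickness = 6), "foot_thickness")
  expect_error(visco_material_spec(E0 = 4, E_inf = 5), "E0 >= E_inf")
  expect_error(loading_spec(frequency = 0), "frequency")
  expect_error(membrane_spec(poisson_ratio = 0.5), "poisson_ratio")
  # nucleus clearance check at the scenario level
  expect_error(scenario_spec(nucleus = nucleus_spec(center_height = 4.5)),
               "clear")
})
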