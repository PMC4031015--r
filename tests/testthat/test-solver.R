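quiet_quasi <- function(steps = 12) {
  solver_options(mode = "quasi_static", steps_per_cycle = steps)
}

test_that("substrate displacement is radial, isotropic and zero at the centre", {
  ld <- loading_spec(frequency = 2)
  expect_equal(substrate_displacement(0, ld, c(5, 3, 0)), c(0, 0, 0))
  # peak phase: u_r = eps * r
  tpk <- 1 / 8 # quarter period at 2 Hz
  u <- substrate_displacement(tpk, ld, c(10, 0, 0))
  expect_equal(u, c(1e-2, 0, 0), tolerance = 1e-12)
  p <- rbind(c(7, 0, 0), c(0, 7, 0), c(7 / sqrt(2), 7 / sqrt(2), 0))
  um <- substrate_displacement(tpk, ld, p)
  expect_equal(sqrt(rowSums(um^2)), rep(7e-3, 3), tolerance = 1e-12)
})

test_that("constant-strain patch test is exact", {
  slab <- make_slab_fixture(4, 1, 1)
  nd <- slab$nodes
  bnd <- which(abs(abs(nd[, 1]) - 2) < 1e-9 | abs(abs(nd[, 2]) - 2) < 1e-9 |
                 abs(nd[, 3]) < 1e-9 | abs(nd[, 3] - 1) < 1e-9)
  e <- 1e-3; nu <- 0.499; ez <- -2 * nu / (1 - nu) * e
  spec <- scenario_spec(
    cytoplasm_material = visco_material_spec(mode = "linear_elastic"),
    loading = loading_spec(frequency = 1, n_cycles = 1),
    solver_options = quiet_quasi(), label = "patch")
  model <- build_discrete_model(spec, slab, prescribed_nodes = bnd,
                                prescribed_fun = function(t, xs)
                                  cbind(e * xs[, 1], e * xs[, 2],
                                        ez * xs[, 3]))
  st <- advance(model, cellstrain:::new_solver_state(model), 0.25)
  orc <- slab_oracle()
  expect_lt(max(abs(st$E6[1, ] - e)) / e, 1e-10)
  expect_lt(max(abs(st$E6[3, ] - ez)) / abs(ez), 1e-10)
  gs <- cellstrain:::gp_stress(model, st$E6, st$h)
  vm <- cellstrain:::von_mises_gp(gs$S)
  expect_lt(max(abs(vm - orc$von_mises)) / orc$von_mises, 1e-10)
})

test_that("rigid translation stores no strain energy", {
  model <- cached("tiny_model_elastic", {
    spec <- scenario_spec(
      cytoplasm_material = visco_material_spec(mode = "linear_elastic"),
      loading = loading_spec(frequency = 1, n_cycles = 1),
      solver_options = quiet_quasi(), label = "k")
    build_discrete_model(spec, tiny_cell_mesh())
  })
  K <- system_matrices(model)$K
  ndof <- ncol(K)
  rigid <- rep(c(1e-6, -2e-6, 3e-6), ndof / 3)
  e_rigid <- as.numeric(rigid %*% (K %*% rigid))
  # reference: a stretch field of the same displacement magnitude
  xn <- model$coords[rep(1:(ndof / 3), each = 3), 1]
  stretch <- rep(c(1e-6, 0, 0), ndof / 3) * xn / max(abs(xn))
  e_ref <- as.numeric(stretch %*% (K %*% stretch))
  expect_lt(abs(e_rigid), 1e-9 * e_ref)
})

test_that("quasi-static elastic response is proportional to amplitude and phase", {
  base <- paper_scenario("elastic_1Hz")
  base$loading$n_cycles <- 1
  base$solver_options <- quiet_quasi()
  m <- tiny_cell_mesh()
  s1 <- run_transient(build_discrete_model(base, m))
  base2 <- base
  base2$loading$strain_amplitude <- 2e-3
  s2 <- run_transient(build_discrete_model(base2, m))
  # superposition: doubling the load amplitude doubles every field
  expect_lt(max(abs(s2$vm - 2 * s1$vm)) / max(s2$vm), 1e-8)
  # linearity in phase: fields follow |sin(2 pi f t)| exactly
  k30 <- 2L   # t = T/12, sin = 0.5
  kpk <- 4L   # t = T/4,  sin = 1
  expect_lt(max(abs(s1$vm[, k30] - 0.5 * s1$vm[, kpk])) / max(s1$vm), 1e-8)
})

test_that("single-element viscoelastic step matches the hereditary oracle", {
  one <- make_single_element_fixture()
  spec <- scenario_spec(cytoplasm_material = visco_material_spec(tau = 0.8),
                        loading = loading_spec(frequency = 1, n_cycles = 3),
                        solver_options = quiet_quasi(24), label = "one")
  # prescribe a pure deviatoric simple-extension history on all nodes:
  # ux = e(t) x, uy = -e(t)/2 y, uz = -e(t)/2 z
  ef <- function(t) 1e-3 * sin(2 * pi * t)
  model <- build_discrete_model(spec, one,
                                prescribed_nodes = seq_len(10),
                                prescribed_fun = function(t, xs)
                                  cbind(ef(t) * xs[, 1],
                                        -ef(t) / 2 * xs[, 2],
                                        -ef(t) / 2 * xs[, 3]))
  st <- cellstrain:::new_solver_state(model)
  dt <- 1 / 24
  times <- seq(0, 3, by = dt)
  s11 <- numeric(length(times))
  for (k in 2:length(times)) {
    st <- advance(model, st, dt)
    gs <- cellstrain:::gp_stress(model, st$E6, st$h)
    s11[k] <- mean(gs$S[1, ]) - mean((gs$S[1, ] + gs$S[2, ] + gs$S[3, ]) / 3)
  }
  G0 <- 6500 / (2 * 1.499)
  ref <- convolution_stress(times, ef(times), 1 - 4.3 / 6.5, 0.8, G0)
  expect_lt(max(abs(s11 - ref)) / max(abs(ref)), 1e-8)
})

test_that("fiber-free cell fields are axisymmetric; fibered fields are 45-degree symmetric", {
  s <- tiny_run("baseline_1Hz", n_cycles = 2)
  kpk <- which.max(apply(s$vm, 2, max))
  expect_lt(orbit_scatter(s$mesh, s$vm[, kpk]), 0.02)
  sc <- tiny_run("cytoskeleton_1Hz", n_cycles = 2)
  kpk <- which.max(apply(sc$vm, 2, max))
  expect_lt(orbit_scatter(sc$mesh, sc$vm[, kpk]), 0.02)
})

test_that("pre-tension equilibrium carries the nominal fiber force", {
  spec <- paper_scenario("cytoskeleton_1Hz")
  spec$solver_options <- quiet_quasi(24)
  model <- build_discrete_model(spec, tiny_fiber_mesh())
  st <- static_pretension_solve(model)
  expect_true(all(st$taut))
  expect_equal(st$fiber_force,
               rep(pretension_force(spec$fibers), 24), tolerance = 1e-9)
  # fiber-free model: zero state
  m0 <- build_discrete_model(paper_scenario("baseline_1Hz"),
                             tiny_cell_mesh())
  expect_equal(max(abs(static_pretension_solve(m0)$u)), 0)
})

test_that("transient bookkeeping: frame counts, rest at zero amplitude", {
  s <- tiny_run("baseline_1Hz", n_cycles = 2)
  expect_equal(n_cycle_frames(s), 2L * 12L)
  expect_equal(length(s$times), 25L)
  expect_true(all(diff(s$times) > 0))
  spec <- paper_scenario("baseline_1Hz")
  spec$loading$strain_amplitude <- 0
  spec$loading$n_cycles <- 1
  spec$solver_options <- quiet_quasi()
  s0 <- run_transient(build_discrete_model(spec, tiny_cell_mesh()))
  expect_equal(max(abs(s0$vm)), 0)
  # steps/frames mismatch is rejected
  spec$solver_options$steps_per_cycle <- 25
  expect_error(run_transient(build_discrete_model(spec, tiny_cell_mesh())),
               "multiple")
})

test_that("dynamic solution converges to the quasi-static one at low density", {
  spec <- paper_scenario("baseline_45Hz")
  spec$loading$n_cycles <- 2
  spec$solver_options$steps_per_cycle <- 24
  m <- tiny_cell_mesh()
  sq <- local({ s <- spec; s$solver_options$mode <- "quasi_static"
                run_transient(build_discrete_model(s, m)) })
  for (dens in c(1050, 1050 / 1000)) {
    sd_ <- local({ s <- spec; s$solver_options$mode <- "dynamic_newmark"
                   s$solver_options$density <- dens
                   run_transient(build_discrete_model(s, m)) })
    expect_lt(max(abs(sd_$vm - sq$vm)) / max(sq$vm), 0.01)
  }
})

test_that("boundary work balances strain plus kinetic energy in dynamic mode", {
  slab <- make_slab_fixture(6, 1, 1)
  # density scaled so inertia genuinely participates at 1 Hz
  spec <- scenario_spec(
    cytoplasm_material = visco_material_spec(mode = "linear_elastic"),
    loading = loading_spec(frequency = 1, n_cycles = 3),
    solver_options = solver_options(mode = "dynamic_newmark", density = 2e12,
                                    steps_per_cycle = 96,
                                    track_energy = TRUE),
    label = "energy")
  se <- run_transient(build_discrete_model(spec, slab))
  en <- se$energy
  expect_gt(tail(en$kinetic, 1) / tail(en$strain, 1), 0.1) # truly dynamic
  err <- abs(en$work - (en$strain + en$kinetic)) /
    pmax(abs(en$work), max(abs(en$work)) * 1e-3)
  expect_lt(max(err), 0.01)
})

test_that("explicit shell membrane coupling is rejected with a clear error", {
  spec <- paper_scenario("baseline_1Hz")
  spec$membrane <- membrane_spec(coupling_mode = "explicit_shell")
  expect_error(build_discrete_model(spec, tiny_cell_mesh()),
               "explicit_shell")
})
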