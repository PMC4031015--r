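test_that("Prony conversion and its invariant hold", {
  pr <- prony_from_moduli(visco_material_spec())
  expect_equal(pr$g1, 1 - 4.3 / 6.5)
  expect_equal(pr$tau1, 15.4)
  expect_equal(pr$g1 + pr$long_term_factor, 1)
  expect_equal(prony_from_moduli(visco_material_spec(E_inf = 6.5))$g1, 0)
  # the invariant g1 + E_inf/E0 = 1 across a sweep of moduli
  set.seed(7)
  for (i in 1:20) {
    E0 <- runif(1, 1, 20); Ei <- runif(1, 0.05, 1) * E0
    pr <- prony_from_moduli(visco_material_spec(E0 = E0, E_inf = Ei))
    expect_equal(pr$g1 + pr$long_term_factor, 1)
  }
})

test_that("relaxation and complex moduli match the closed forms", {
  m <- visco_material_spec()
  expect_equal(relaxation_modulus(0, m), 6.5)
  expect_equal(relaxation_modulus(1e6, m), 4.3, tolerance = 1e-12)
  expect_equal(relaxation_modulus(15.4, m), 4.3 + 2.2 * exp(-1))
  expect_error(relaxation_modulus(-1, m), "non-negative")

  # loss peak at omega*tau = 1
  f_peak <- 1 / (2 * pi * 15.4)
  cm <- complex_modulus(f_peak, m)
  expect_equal(cm$loss, 2.2 / 2)
  # 1 Hz values (omega*tau = 96.76): nearly glassy storage, small loss
  wt <- 2 * pi * 15.4
  cm1 <- complex_modulus(1, m)
  expect_equal(cm1$storage, 4.3 + 2.2 * wt^2 / (1 + wt^2))
  expect_equal(cm1$loss, 2.2 * wt / (1 + wt^2))
  expect_lt(abs(cm1$storage - 6.5) / 6.5, 1e-3)
})

test_that("recursive update reaches the equilibrium and glassy limits", {
  m <- visco_material_spec()
  pr <- prony_from_moduli(m)
  G0 <- 1000
  e <- c(1e-3, -5e-4, -5e-4, 0, 0, 0)
  # constant strain held for >> tau relaxes to (E_inf/E0) * 2 G0 * e
  st <- new_visco_state()
  for (i in 1:400) {
    up <- visco_deviatoric_update(1, e, e, st, pr, G0)
    st <- up$state
  }
  expect_equal(up$dev_stress, (4.3 / 6.5) * 2 * G0 * e, tolerance = 1e-6)
  # tiny first step from virgin state gives the glassy response
  up0 <- visco_deviatoric_update(1e-6, e, 0 * e, new_visco_state(), pr, G0)
  expect_equal(up0$dev_stress, 2 * G0 * e, tolerance = 1e-6)
  expect_error(visco_deviatoric_update(0, e, e, st, pr, G0), "dt")
})

test_that("recursive update reproduces the brute-force convolution integral", {
  G0 <- 2168
  set.seed(42)
  for (tau in c(0.5, 5, 15.4)) {
    pr <- list(g1 = 1 - 4.3 / 6.5, tau1 = tau, long_term_factor = 4.3 / 6.5)
    times <- cumsum(runif(101, 0.01, 0.2)); times <- c(0, times[-101])
    e <- cumsum(rnorm(101, sd = 1e-4)); e[1] <- 0
    st <- new_visco_state(1)
    sig <- numeric(101)
    for (k in 2:101) {
      up <- visco_deviatoric_update(times[k] - times[k - 1], e[k], e[k - 1],
                                    st, pr, G0)
      st <- up$state
      sig[k] <- up$dev_stress
    }
    ref <- convolution_stress(times, e, pr$g1, tau, G0)
    expect_lt(max(abs(sig[-1] - ref[-1])) / max(abs(ref)), 1e-6)
  }
})

test_that("steady-state sinusoidal response matches the complex modulus", {
  m <- visco_material_spec()
  pr <- prony_from_moduli(m)
  G0 <- 1 # amplitude scales out
  for (f in c(0.01, 0.1, 1)) {
    Tp <- 1 / f
    dt <- Tp / 1000
    eps0 <- 1e-3
    st <- new_visco_state(1)
    nstep <- 10 * 1000
    tgrid <- (0:nstep) * dt
    e <- eps0 * sin(2 * pi * f * tgrid)
    sig <- numeric(nstep + 1)
    for (k in 2:(nstep + 1)) {
      up <- visco_deviatoric_update(dt, e[k], e[k - 1], st, pr, G0)
      st <- up$state
      sig[k] <- up$dev_stress
    }
    # fit the last two periods to A sin + B cos
    idx <- tgrid > (10 - 2) * Tp
    X <- cbind(sin(2 * pi * f * tgrid[idx]), cos(2 * pi * f * tgrid[idx]))
    ab <- qr.solve(X, sig[idx])
    cm <- complex_modulus(f, m)
    # shear ratios equal tensile ratios: G'(f)/G0 = E'(f)/E0
    expect_equal(ab[1], 2 * G0 * eps0 * cm$storage / 6.5, tolerance = 5e-3)
    expect_equal(ab[2], 2 * G0 * eps0 * cm$loss / 6.5, tolerance = 5e-3)
  }
})

test_that("linear-elastic mode equals viscoelastic with g1 = 0", {
  mel <- visco_material_spec(mode = "linear_elastic")
  prel <- prony_from_moduli(mel)
  expect_equal(prel$g1, 0)
  pr0 <- list(g1 = 0, tau1 = 15.4, long_term_factor = 1)
  set.seed(1)
  e <- rnorm(6, sd = 1e-3)
  st1 <- new_visco_state(); st2 <- new_visco_state()
  for (k in 1:20) {
    en <- e * sin(k / 3)
    eo <- e * sin((k - 1) / 3)
    u1 <- visco_deviatoric_update(0.05, en, eo, st1, prel, 999)
    u2 <- visco_deviatoric_update(0.05, en, eo, st2, pr0, 999)
    expect_identical(u1$dev_stress, u2$dev_stress)
    expect_identical(u1$dev_stress, 2 * 999 * en)
    st1 <- u1$state; st2 <- u2$state
  }
})

test_that("elastic stress, fiber law and scalar measures behave", {
  expect_equal(isotropic_elastic_stress(diag(0, 3), 6500, 0.499),
               diag(0, 3))
  s <- isotropic_elastic_stress(diag(c(1e-3, 0, 0)), 6500, 1e-8)
  expect_equal(s[1, 1], 6.5, tolerance = 1e-6)
  expect_error(isotropic_elastic_stress(diag(3), 6500, 0.5), "nu_eff")
  # equibiaxial plane-stress state
  nu <- 0.499; e <- 1e-3; ez <- -2 * nu * e / (1 - nu)
  sb <- isotropic_elastic_stress(diag(c(e, e, ez)), 6500, nu)
  expect_equal(sb[3, 3], 0, tolerance = 1e-10)
  expect_equal(sb[1, 1], 6500 * e / (1 - nu))

  fib <- fiber_network_spec()
  expect_equal(truss_axial_force(0.001, fib)$force, pretension_force(fib))
  slack <- truss_axial_force(-0.002, fib)
  expect_equal(slack$force, 0)
  expect_false(slack$state$taut_flag)
  expect_equal(truss_axial_force(0.002, fib)$force,
               2 * pretension_force(fib))
  # continuity at zero force
  expect_lt(truss_axial_force(1e-12, fib)$force, 1e-15)

  expect_equal(von_mises(diag(c(100, 0, 0))), 100)
  expect_equal(von_mises(diag(c(7, 7, 7))), 0)
  expect_equal(von_mises(diag(c(13, 13, 0))), 13)
  expect_equal(principal_strains(diag(c(2e-3, -1e-3, -1e-3))),
               c(2e-3, -1e-3, -1e-3))
  expect_equal(principal_strains(matrix(0, 3, 3)), c(0, 0, 0))
  # incompressible equibiaxial: reported scalar is the out-of-plane value
  expect_equal(principal_strain_magnitude(diag(c(1e-3, 1e-3, -1.992e-3))),
               1.992e-3)
})
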