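# Discrete model assembly and time integration.
#
# The strain-displacement operator B (from the compiled tet10 kernel) is the
# single consistency anchor: stiffness K = B' W D B, internal forces
# B' W sigma and post-processed fields all use the same operator and
# quadrature, so patch tests are exact to solver precision.
#
# Viscoelasticity enters through the per-quadrature-point recursive update
# (see visco_deviatoric_update); for a fixed step size the update makes the
# step equation linear with an effective shear modulus, so one sparse
# Cholesky factorization serves an entire run.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solver options
#'
#' @param mode \code{"dynamic_newmark"} (implicit average-acceleration
#'   Newmark with consistent mass) or \code{"quasi_static"} (inertia-free).
#'   At cell scale the two agree to high precision: the elastic wavelength
#'   at 45 Hz is centimetres against a 20 um cell.
#' @param density Tissue mass density, kg/m^3 (dynamic mode).
#' @param newmark_beta,newmark_gamma Newmark parameters (defaults are the
#'   unconditionally stable average-acceleration values).
#' @param steps_per_cycle Implicit steps per strain cycle; must be a
#'   multiple of the loading's \code{frames_per_cycle}.
#' @param linear_solver_tolerance Relative tolerance bookkeeping for the
#'   linear solver (direct sparse Cholesky is used; the value is recorded
#'   and used for residual checks).
#' @param max_state_iterations Fixed-point iterations allowed per step for
#'   resolving fiber taut/slack states.
#' @param ramp_cycles Optional cosine start-up ramp length in cycles
#'   (0 = loading starts at full amplitude, the default).
#' @param track_energy Record boundary work / strain / kinetic energy
#'   (dynamic mode).
#' @param record_displacement Store nodal displacements in recorded frames.
#' @param bbar Use the mean-dilatation (B-bar) volumetric treatment
#'   (recommended for the nearly incompressible cell materials).
#' @return An object of class \code{solver_options}.
#' @export
solver_options <- function(mode = "dynamic_newmark", density = 1050,
                           newmark_beta = 0.25, newmark_gamma = 0.5,
                           steps_per_cycle = 96,
                           linear_solver_tolerance = 1e-9,
                           max_state_iterations = 20,
                           ramp_cycles = 0, track_energy = FALSE,
                           record_displacement = TRUE, bbar = TRUE) {
  mode <- match.arg(mode, c("dynamic_newmark", "quasi_static"))
  structure(list(mode = mode, density = as.numeric(density),
                 newmark_beta = as.numeric(newmark_beta),
                 newmark_gamma = as.numeric(newmark_gamma),
                 steps_per_cycle = as.numeric(steps_per_cycle),
                 linear_solver_tolerance = as.numeric(linear_solver_tolerance),
                 max_state_iterations = as.numeric(max_state_iterations),
                 ramp_cycles = as.numeric(ramp_cycles),
                 track_energy = isTRUE(track_energy),
                 record_displacement = isTRUE(record_displacement),
                 bbar = isTRUE(bbar)),
            class = "solver_options")
}

#' Substrate displacement field
#'
#' Equibiaxial (radially isotropic) sinusoidal displacement imposed by the
#' stretched membrane on the basal cell surface:
#' \eqn{u_r = \varepsilon_a \sin(2\pi f t)\, r}, \eqn{u_z = 0}; zero at the
#' strain-field centre.
#'
#' @param t Time, seconds.
#' @param loading A \code{\link{loading_spec}}.
#' @param point Point coordinates (xyz, micrometres): vector or n x 3 matrix.
#' @return Displacement(s) in micrometres, same shape as \code{point}.
#' @export
substrate_displacement <- function(t, loading, point) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  s <- loading$strain_amplitude * sin(2 * pi * loading$frequency * t)
  out <- cbind(s * p[, 1], s * p[, 2], 0)
  if (is.matrix(point)) out else drop(out)
}

ramp_factor <- function(t, loading, ramp_cycles) {
  if (ramp_cycles <= 0) return(list(r = 1, dr = 0, ddr = 0))
  Tr <- ramp_cycles / loading$frequency
  if (t >= Tr) return(list(r = 1, dr = 0, ddr = 0))
  w <- pi / Tr
  list(r = 0.5 * (1 - cos(w * t)), dr = 0.5 * w * sin(w * t),
       ddr = 0.5 * w^2 * cos(w * t))
}

#' Build the discrete model
#'
#' Binds mesh regions to materials, sets up the strain-displacement
#' operator, boundary conditions (prescribed basal motion from the
#' substrate strain field) and fiber data.
#'
#' @param spec A \code{\link{scenario_spec}}.
#' @param mesh A \code{cs_mesh} (with fibers attached for cytoskeletal
#'   scenarios).
#' @param prescribed_nodes,prescribed_fun Optional Dirichlet override for
#'   fixture tests: node indices and a function \code{(t, coords_si)}
#'   returning an n x 3 displacement matrix in metres.
#' @return A \code{discrete_model}.
#' @export
build_discrete_model <- function(spec, mesh, prescribed_nodes = NULL,
                                 prescribed_fun = NULL) {
  opts <- spec$solver_options
  if (spec$membrane$coupling_mode == "explicit_shell")
    stopf("explicit_shell membrane coupling is not supported; use prescribed_basal_displacement")
  if (!is.null(spec$fibers) && is.null(mesh$tru3))
    stopf("scenario has a fiber network but the mesh has no truss elements; call attach_fiber_elements()")
  coords <- mesh$nodes * 1e-6                       # um -> m
  nel <- nrow(mesh$tet10)
  reg <- mesh$region
  cyt <- spec$cytoplasm_material
  nuc <- spec$nucleus_material
  if (any(reg == 2L) && is.null(nuc))
    stopf("mesh has a nucleus region but no nucleus material is bound")
  nu_c <- effective_poisson(cyt$poisson_ratio)
  nu_n <- effective_poisson(nuc$poisson_ratio)
  E_c <- cyt$E0 * 1e3; E_n <- nuc$elastic_modulus * 1e3
  pr <- prony_from_moduli(cyt)
  el <- list(G0 = ifelse(reg == 1L, E_c / (2 * (1 + nu_c)),
                         E_n / (2 * (1 + nu_n))),
             Kb = ifelse(reg == 1L, E_c / (3 * (1 - 2 * nu_c)),
                         E_n / (3 * (1 - 2 * nu_n))),
             g1 = ifelse(reg == 1L, pr$g1, 0),
             tau = ifelse(reg == 1L, pr$tau1, Inf))
  so <- .cs_tet10_strainop(coords, mesh$tet10, opts$bbar)
  B <- Matrix::sparseMatrix(i = so$i, j = so$j, x = so$x,
                            dims = c(so$nrow, 3L * nrow(coords)))
  ngp <- nel * 4L
  gp <- lapply(el, function(v) rep(v, each = 4L))
  nfib <- if (is.null(mesh$tru3)) 0L else nrow(mesh$tru3)
  fibers <- NULL
  if (nfib > 0) {
    n1 <- mesh$tru3[, 1]; n2 <- mesh$tru3[, 3]
    dvec <- coords[n2, , drop = FALSE] - coords[n1, , drop = FALSE]
    L0 <- sqrt(rowSums(dvec^2))
    fibers <- list(n1 = n1, n2 = n2, nvec = dvec / L0, L0 = L0,
                   EA = fiber_axial_stiffness(mesh$fiber_spec),
                   F0 = pretension_force(mesh$fiber_spec),
                   pre_strain = mesh$fiber_spec$pre_strain)
  }
  if (is.null(prescribed_nodes)) {
    pnodes <- mesh$node_sets$basal
    amp <- spec$loading$strain_amplitude
    om <- 2 * pi * spec$loading$frequency
    px <- coords[pnodes, 1]; py <- coords[pnodes, 2]
    rc <- opts$ramp_cycles
    ld <- spec$loading
    bc_fun <- function(t) {
      rf <- ramp_factor(t, ld, rc)
      s <- sin(om * t); cphase <- cos(om * t)
      f <- amp * rf$r * s
      df <- amp * (rf$dr * s + rf$r * om * cphase)
      ddf <- amp * (rf$ddr * s + 2 * rf$dr * om * cphase - rf$r * om^2 * s)
      list(u = cbind(f * px, f * py, 0),
           v = cbind(df * px, df * py, 0),
           a = cbind(ddf * px, ddf * py, 0))
    }
  } else {
    pnodes <- prescribed_nodes
    bc_fun <- function(t) {
      u <- prescribed_fun(t, coords[pnodes, , drop = FALSE])
      eps <- 1e-7 / max(spec$loading$frequency, 1)
      up <- prescribed_fun(t + eps, coords[pnodes, , drop = FALSE])
      um <- prescribed_fun(max(t - eps, 0), coords[pnodes, , drop = FALSE])
      list(u = u, v = (up - um) / (2 * eps), a = (up - 2 * u + um) / eps^2)
    }
  }
  ndof <- 3L * nrow(coords)
  pdofs <- as.vector(t(cbind(3 * pnodes - 2, 3 * pnodes - 1, 3 * pnodes)))
  sdofs <- if (length(mesh$slaved_nodes))
    as.vector(rbind(3 * mesh$slaved_nodes - 2, 3 * mesh$slaved_nodes - 1,
                    3 * mesh$slaved_nodes)) else integer(0)
  free <- setdiff(seq_len(ndof), c(pdofs, sdofs))
  M <- NULL
  if (opts$mode == "dynamic_newmark") {
    mm <- .cs_tet10_mass(coords, mesh$tet10, rep(opts$density, nel))
    M <- Matrix::sparseMatrix(i = mm$i, j = mm$j, x = mm$x,
                              dims = c(ndof, ndof))
  }
  structure(list(mesh = mesh, spec = spec, coords = coords, B = B,
                 Bt = Matrix::t(B), w = so$w, el_volume = so$volume,
                 nel = nel, ngp = ngp, gp = gp, fibers = fibers,
                 pnodes = pnodes, pdofs = pdofs, sdofs = sdofs, free = free,
                 bc_fun = bc_fun, M = M, options = opts),
            class = "discrete_model")
}

#' Instantaneous system matrices
#'
#' Stiffness assembled with the instantaneous moduli (and fiber taut
#' stiffness when present) plus the consistent mass matrix (dynamic mode),
#' mainly for diagnostics and verification tests.
#'
#' @param model A \code{discrete_model}.
#' @return List with sparse \code{K} and \code{M} (or \code{NULL}).
#' @export
system_matrices <- function(model) {
  K <- assemble_stiffness(model, model$gp$G0)
  if (!is.null(model$fibers)) K <- K + fiber_stiffness(model)
  list(K = K, M = model$M)
}

assemble_stiffness <- function(model, Ggp) {
  ngp <- model$ngp
  w <- model$w
  Kb <- model$gp$Kb
  base <- (seq_len(ngp) - 1L) * 6L
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (r in 1:3) for (cc in 1:3) {
    ii <- c(ii, base + r); jj <- c(jj, base + cc)
    xx <- c(xx, w * (Kb + ifelse(r == cc, 4, -2) * Ggp / 3))
  }
  for (r in 4:6) {
    ii <- c(ii, base + r); jj <- c(jj, base + r)
    xx <- c(xx, w * Ggp)
  }
  WD <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                             dims = c(6L * ngp, 6L * ngp))
  Matrix::forceSymmetric(Matrix::crossprod(model$B, WD %*% model$B))
}

fiber_stiffness <- function(model) {
  fb <- model$fibers
  ndof <- ncol(model$B)
  if (is.null(fb)) return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                               x = numeric(0),
                                               dims = c(ndof, ndof)))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (f in seq_along(fb$L0)) {
    kf <- fb$EA / fb$L0[f]
    n <- fb$nvec[f, ]
    blk <- kf * (n %o% n)
    d1 <- 3 * fb$n1[f] - 2:0; d2 <- 3 * fb$n2[f] - 2:0
    for (a in 1:3) for (b in 1:3) {
      ii <- c(ii, d1[a], d1[a], d2[a], d2[a])
      jj <- c(jj, d1[b], d2[b], d1[b], d2[b])
      xx <- c(xx, blk[a, b], -blk[a, b], -blk[a, b], blk[a, b])
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
}

# fiber elongation delta = (u2 - u1) . n for all fibers
fiber_delta <- function(model, u) {
  fb <- model$fibers
  d1 <- cbind(3 * fb$n1 - 2, 3 * fb$n1 - 1, 3 * fb$n1)
  d2 <- cbind(3 * fb$n2 - 2, 3 * fb$n2 - 1, 3 * fb$n2)
  rowSums((matrix(u[d2], ncol = 3) - matrix(u[d1], ncol = 3)) * fb$nvec)
}

# current fiber forces given elongations and the pretension reference
fiber_forces <- function(model, delta, ref_delta) {
  fb <- model$fibers
  pmax(0, fb$EA * (fb$pre_strain + (delta - ref_delta) / fb$L0))
}

# assembled nodal load from fiber tensions F (positive toward the partner)
fiber_load <- function(model, Fax) {
  fb <- model$fibers
  ndof <- ncol(model$B)
  g <- numeric(ndof)
  for (f in seq_along(Fax)) {
    pf <- Fax[f] * fb$nvec[f, ]
    d1 <- 3 * fb$n1[f] - 2:0; d2 <- 3 * fb$n2[f] - 2:0
    g[d1] <- g[d1] + pf
    g[d2] <- g[d2] - pf
  }
  g
}

gp_matrix <- function(v, ngp) matrix(v, nrow = 6, ncol = ngp)

# deviatoric split of a 6 x ngp engineering-strain matrix: returns tensor
# shear components in rows 4:6 and the mean strain
strain_split <- function(E6) {
  em <- (E6[1, ] + E6[2, ] + E6[3, ]) / 3
  D <- E6
  D[1, ] <- E6[1, ] - em; D[2, ] <- E6[2, ] - em; D[3, ] <- E6[3, ] - em
  D[4:6, ] <- E6[4:6, ] / 2
  list(dev = D, mean = em)
}

# vectorized largest-magnitude eigenvalue of symmetric 3x3 tensors stored
# as 6 x n (tensor shear components)
max_abs_principal <- function(T6) {
  q <- (T6[1, ] + T6[2, ] + T6[3, ]) / 3
  a <- T6[1, ] - q; b <- T6[2, ] - q; c_ <- T6[3, ] - q
  d <- T6[4, ]; e <- T6[5, ]; f <- T6[6, ]
  p2 <- a^2 + b^2 + c_^2 + 2 * (d^2 + e^2 + f^2)
  p <- sqrt(pmax(p2 / 6, 0))
  detB <- a * (b * c_ - f^2) - d * (d * c_ - f * e) + e * (d * f - b * e)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  lam1 <- q + 2 * p * cos(phi)
  lam3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  pmax(abs(lam1), abs(lam3))
}

von_mises_gp <- function(S6) {
  sm <- (S6[1, ] + S6[2, ] + S6[3, ]) / 3
  sqrt(1.5 * ((S6[1, ] - sm)^2 + (S6[2, ] - sm)^2 + (S6[3, ] - sm)^2 +
                2 * (S6[4, ]^2 + S6[5, ]^2 + S6[6, ]^2)))
}

# volume-weighted per-element average of a per-gauss-point scalar
el_average <- function(x, w, nel) {
  xm <- matrix(x * w, nrow = 4, ncol = nel)
  wm <- matrix(w, nrow = 4, ncol = nel)
  colSums(xm) / colSums(wm)
}

# gp stresses for a given displacement/history (returns list of gp arrays)
gp_stress <- function(model, E6, h) {
  ss <- strain_split(E6)
  S <- 2 * rep(model$gp$G0, each = 6) * (ss$dev - h)
  vol <- 3 * model$gp$Kb * ss$mean
  S[1, ] <- S[1, ] + vol; S[2, ] <- S[2, ] + vol; S[3, ] <- S[3, ] + vol
  list(S = S, dev = ss$dev, mean = ss$mean)
}

new_solver_state <- function(model) {
  ndof <- ncol(model$B)
  nfib <- if (is.null(model$fibers)) 0L else length(model$fibers$L0)
  list(t = 0, u = numeric(ndof), v = numeric(ndof), a = numeric(ndof),
       h = matrix(0, 6, model$ngp), edev = matrix(0, 6, model$ngp),
       fiber_force = numeric(nfib), fiber_ref_delta = numeric(nfib),
       taut = rep(TRUE, nfib))
}

#' Static pre-tension solve
#'
#' Applies the nominal fiber pre-tension (force prescription, ~102.5 pN per
#' fiber with defaults) with the basal surface held fixed and solves for
#' static equilibrium with the instantaneous moduli. The solved state is
#' the reference configuration for the subsequent cyclic run, so every
#' fiber starts taut at exactly the nominal pre-tension. For a fiber-free
#' model this returns the zero state.
#'
#' @param model A \code{discrete_model}.
#' @return A solver state (internal structure).
#' @export
static_pretension_solve <- function(model) {
  st <- new_solver_state(model)
  if (is.null(model$fibers)) return(st)
  K <- assemble_stiffness(model, model$gp$G0)
  free <- model$free
  Ch <- Matrix::Cholesky(K[free, free], LDL = FALSE)
  f0 <- fiber_load(model, rep(model$fibers$F0, length(model$fibers$L0)))
  uf <- Matrix::solve(Ch, f0[free])
  st$u[free] <- as.numeric(uf)
  st$u[model$sdofs] <- slave_displacement(model, st$u)
  res <- K[free, free] %*% st$u[free] - f0[free]
  if (max(abs(res)) > max(model$options$linear_solver_tolerance, 1e-9) *
        max(abs(f0[free])))
    stopf("pre-tension solve did not reach equilibrium")
  st$fiber_ref_delta <- fiber_delta(model, st$u)
  st$fiber_force <- rep(model$fibers$F0, length(model$fibers$L0))
  st$taut <- st$fiber_force > 0
  st$edev <- strain_split(gp_matrix(as.numeric(model$B %*% st$u),
                                    model$ngp))$dev
  st
}

slave_displacement <- function(model, u) {
  # fiber mid nodes follow the mean of their end nodes
  fb <- model$fibers
  if (is.null(fb)) return(numeric(0))
  d1 <- cbind(3 * fb$n1 - 2, 3 * fb$n1 - 1, 3 * fb$n1)
  d2 <- cbind(3 * fb$n2 - 2, 3 * fb$n2 - 1, 3 * fb$n2)
  as.vector(t((matrix(u[d1], ncol = 3) + matrix(u[d2], ncol = 3)) / 2))
}

make_stepper <- function(model, dt) {
  opts <- model$options
  dyn <- opts$mode == "dynamic_newmark"
  ngp <- model$ngp
  g1 <- model$gp$g1; tau <- model$gp$tau; G0 <- model$gp$G0
  afac <- ifelse(is.finite(tau), exp(-dt / tau), 1)
  bcf <- ifelse(g1 > 0, g1 * (1 - (tau / dt) * (1 - afac)), 0)
  Geff <- G0 * (1 - bcf)
  K <- assemble_stiffness(model, Geff)
  Kf <- if (!is.null(model$fibers)) fiber_stiffness(model) else NULL
  A <- if (is.null(Kf)) K else K + Kf
  beta <- opts$newmark_beta; gam <- opts$newmark_gamma
  if (dyn) A <- A + model$M * (1 / (beta * dt^2))
  free <- model$free; pdofs <- model$pdofs
  Ch <- Matrix::Cholesky(Matrix::forceSymmetric(A[free, free]), LDL = FALSE)
  Afp <- A[free, pdofs]
  # history-stress coefficient: sigma_hist = chist * e_dev_old - 2 G0 a * h
  chist6 <- rep(2 * G0 * (bcf - g1 * (1 - afac)), each = 6)
  ah6 <- rep(2 * G0 * afac, each = 6)
  a6 <- rep(afac, each = 6); g1a6 <- rep(g1 * (1 - afac), each = 6)
  bcf6 <- rep(bcf, each = 6)
  wS <- rep(model$w, each = 6)
  maxit <- opts$max_state_iterations

  function(state) {
    tn <- state$t + dt
    bc <- model$bc_fun(tn)
    u_new <- state$u
    u_new[pdofs] <- as.vector(t(bc$u))
    shist <- chist6 * state$edev - ah6 * state$h
    f_hist <- as.numeric(model$Bt %*% (wS * as.vector(shist)))
    rhs0 <- -f_hist[free] - as.numeric(Afp %*% u_new[pdofs])
    if (dyn) {
      pred <- state$u / (beta * dt^2) + state$v / (beta * dt) +
        (1 / (2 * beta) - 1) * state$a
      rhs0 <- rhs0 + as.numeric((model$M %*% pred)[free])
    }
    nfib <- if (is.null(model$fibers)) 0L else length(model$fibers$L0)
    taut <- state$taut
    Fax <- state$fiber_force
    for (it in seq_len(max(1L, if (nfib) maxit else 1L))) {
      rhs <- rhs0
      if (nfib) {
        delta <- fiber_delta(model, u_new)
        Fax <- fiber_forces(model, delta, state$fiber_ref_delta)
        g <- fiber_load(model, Fax) + as.numeric(Kf %*% u_new)
        rhs <- rhs + g[free]
      }
      uf <- if (length(free)) as.numeric(Matrix::solve(Ch, rhs)) else numeric(0)
      moved <- if (length(free)) max(abs(uf - u_new[free])) else 0
      u_new[free] <- uf
      if (nfib == 0) break
      delta <- fiber_delta(model, u_new)
      Fax <- fiber_forces(model, delta, state$fiber_ref_delta)
      taut_new <- Fax > 0
      # with all fibers taut the assembled fiber load is constant (the taut
      # stiffness sits in A), so an unchanged taut pattern means converged;
      # slack fibers couple the load to u and need the displacement test
      if (all(taut_new == taut) &&
          (all(taut_new) || moved <= 1e-10 * max(abs(uf), 1e-30))) {
        taut <- taut_new
        break
      }
      taut <- taut_new
      if (it == maxit) warnf("fiber taut/slack iteration hit max_state_iterations")
    }
    if (length(model$sdofs)) u_new[model$sdofs] <- slave_displacement(model, u_new)
    E6 <- gp_matrix(as.numeric(model$B %*% u_new), ngp)
    ss <- strain_split(E6)
    h_new <- a6 * state$h + g1a6 * state$edev + bcf6 * (ss$dev - state$edev)
    state_new <- state
    if (dyn) {
      # Newmark kinematic update on every dof (prescribed ones included, so
      # the discrete work-energy identity holds exactly; boundary velocity
      # and acceleration converge to the analytic ones at O(dt^2))
      a_new <- (u_new - state$u) / (beta * dt^2) -
        state$v / (beta * dt) - (1 / (2 * beta) - 1) * state$a
      v_new <- state$v + dt * ((1 - gam) * state$a + gam * a_new)
      state_new$v <- v_new; state_new$a <- a_new
    }
    state_new$t <- tn
    state_new$u <- u_new
    state_new$h <- h_new
    state_new$edev <- ss$dev
    state_new$E6 <- E6
    if (nfib) { state_new$fiber_force <- Fax; state_new$taut <- taut }
    state_new
  }
}

#' Advance the model by one implicit step
#'
#' One Newmark (average acceleration) or quasi-static step of size
#' \code{dt}, updating viscoelastic internal variables with the recursive
#' deviatoric update and resolving fiber taut/slack states by fixed-point
#' iteration.
#'
#' @param model A \code{discrete_model}.
#' @param state A solver state (from \code{\link{static_pretension_solve}}
#'   or a previous step).
#' @param dt Step size, seconds.
#' @return The updated state.
#' @export
advance <- function(model, state, dt) {
  if (dt <= 0) stopf("dt must be positive")
  make_stepper(model, dt)(state)
}

frame_fields <- function(model, state) {
  E6 <- state$E6 %||% gp_matrix(as.numeric(model$B %*% state$u), model$ngp)
  gs <- gp_stress(model, E6, state$h)
  # convert deviator + mean back to tensor strain for principal values
  Et <- gs$dev
  Et[1, ] <- Et[1, ] + gs$mean; Et[2, ] <- Et[2, ] + gs$mean
  Et[3, ] <- Et[3, ] + gs$mean
  list(vm = el_average(von_mises_gp(gs$S), model$w, model$nel),
       ps = el_average(max_abs_principal(Et), model$w, model$nel),
       stress_gp = gs$S)
}

#' Run the transient (cyclic) simulation
#'
#' Executes the static pre-tension step (when fibers are present) and then
#' \code{n_cycles x steps_per_cycle} implicit steps from rest, recording
#' every \code{steps_per_cycle / frames_per_cycle}-th step plus the initial
#' state. Deterministic.
#'
#' @param model A \code{discrete_model}.
#' @return A \code{solution_series} with frame times, per-element Von Mises
#'   stress and principal-strain magnitude, nodal displacements (optional)
#'   and fiber forces.
#' @export
run_transient <- function(model) {
  ld <- model$spec$loading
  opts <- model$options
  spc <- opts$steps_per_cycle
  fpc <- ld$frames_per_cycle
  if (spc %% fpc != 0)
    stopf("steps_per_cycle (%g) must be a multiple of frames_per_cycle (%g)",
          spc, fpc)
  stride <- spc %/% fpc
  dt <- 1 / (ld$frequency * spc)
  nstep <- as.integer(ld$n_cycles * spc)
  nframe <- as.integer(ld$n_cycles * fpc) + 1L
  state <- static_pretension_solve(model)
  step <- make_stepper(model, dt)
  nel <- model$nel
  nfib <- if (is.null(model$fibers)) 0L else length(model$fibers$L0)
  times <- numeric(nframe)
  vm <- matrix(0, nel, nframe); ps <- matrix(0, nel, nframe)
  ff <- if (nfib) matrix(0, nfib, nframe) else NULL
  U <- if (opts$record_displacement)
    matrix(0, length(state$u), nframe) else NULL
  energy <- if (opts$track_energy && opts$mode == "dynamic_newmark")
    data.frame(time = numeric(0), work = numeric(0), strain = numeric(0),
               kinetic = numeric(0)) else NULL
  rec <- function(k, st) {
    fl <- frame_fields(model, st)
    times[k] <<- st$t
    vm[, k] <<- fl$vm; ps[, k] <<- fl$ps
    if (nfib) ff[, k] <<- st$fiber_force
    if (!is.null(U)) U[, k] <<- st$u
  }
  rec(1L, state)
  kframe <- 1L
  if (!is.null(energy)) {
    Ksys <- assemble_stiffness(model, model$gp$G0)
    work <- 0
    Rp_prev <- numeric(length(model$pdofs))
  }
  for (n in seq_len(nstep)) {
    state_new <- step(state)
    if (!is.null(energy)) {
      R <- as.numeric(Ksys %*% state_new$u) +
        as.numeric(model$M %*% state_new$a)
      Rp <- R[model$pdofs]
      dup <- state_new$u[model$pdofs] - state$u[model$pdofs]
      work <- work + 0.5 * sum((Rp + Rp_prev) * dup)
      Rp_prev <- Rp
      energy <- rbind(energy, data.frame(
        time = state_new$t, work = work,
        strain = 0.5 * sum(state_new$u * as.numeric(Ksys %*% state_new$u)),
        kinetic = 0.5 * sum(state_new$v *
                              as.numeric(model$M %*% state_new$v))))
    }
    state <- state_new
    if (n %% stride == 0L) {
      kframe <- kframe + 1L
      rec(kframe, state)
    }
  }
  structure(list(times = times, vm = vm, ps = ps, fiber_force = ff, U = U,
                 energy = energy, spec = model$spec, mesh = model$mesh,
                 region = model$mesh$region, mode = opts$mode, dt = dt),
            class = "solution_series")
}

#' @method print solution_series
#' @export
print.solution_series <- function(x, ...) {
  cat(sprintf("solution_series: %d frames (t = 0 .. %.4g s), %d elements, mode %s\n",
              length(x$times), max(x$times), nrow(x$vm), x$mode))
  invisible(x)
}

#' Number of cyclic frames in a series (excluding the initial state)
#' @param series A \code{solution_series}.
#' @return Integer frame count.
#' @export
n_cycle_frames <- function(series) length(series$times) - 1L

#' Convenience wrapper: mesh, bind and run one scenario
#'
#' @param spec A \code{\link{scenario_spec}} (e.g. from
#'   \code{\link{paper_scenario}}).
#' @param target_edge Mesh resolution, micrometres.
#' @param mesh Optional pre-built mesh (fibers are attached here if the
#'   scenario needs them and the mesh has none).
#' @param ... Passed to \code{\link{generate_cell_mesh}}.
#' @return A \code{solution_series}.
#' @export
run_scenario <- function(spec, target_edge = 0.8, mesh = NULL, ...) {
  if (is.null(mesh))
    mesh <- generate_cell_mesh(spec$geometry, spec$nucleus,
                               target_edge = target_edge, ...)
  if (!is.null(spec$fibers) && is.null(mesh$tru3)) {
    net <- build_fiber_network(spec$fibers, spec$geometry, spec$nucleus)
    mesh <- attach_fiber_elements(mesh, net)
  }
  model <- build_discrete_model(spec, mesh)
  run_transient(model)
}
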