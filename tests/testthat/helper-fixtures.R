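# Shared fixtures, built once per test run and cached. Cell runs use a
# deliberately coarse mesh (8 sectors) so the whole suite stays fast; the
# scientific conditions (1,000 ustrain, 10 cycles, 12 frames/cycle) are the
# study conditions unless a property test only needs fewer cycles.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

test_geom <- function() cached("geom", cell_geometry_spec())
test_nucleus <- function() cached("nucleus", nucleus_spec())

# ~1300-element cell mesh with 45-degree sector symmetry
tiny_cell_mesh <- function() cached("tiny_mesh",
  generate_cell_mesh(test_geom(), test_nucleus(), target_edge = 1.4,
                     sectors = 8, rays = 8, layers = 2, rings = 2))

tiny_fiber_mesh <- function() cached("tiny_fiber_mesh", {
  net <- build_fiber_network(fiber_network_spec(), test_geom(),
                             test_nucleus())
  attach_fiber_elements(tiny_cell_mesh(), net)
})

# quasi-static coarse-mesh scenario run under the full study loading
tiny_run <- function(name, n_cycles = 10, steps_per_cycle = 24,
                     mode = "quasi_static") {
  key <- sprintf("run_%s_%d_%d_%s", name, n_cycles, steps_per_cycle, mode)
  cached(key, {
    spec <- paper_scenario(name)
    spec$loading$n_cycles <- n_cycles
    spec$solver_options$mode <- mode
    spec$solver_options$steps_per_cycle <- steps_per_cycle
    spec$solver_options$record_displacement <- FALSE
    mesh <- if (is.null(spec$fibers)) tiny_cell_mesh() else tiny_fiber_mesh()
    run_transient(build_discrete_model(spec, mesh))
  })
}

peak_of <- function(series, region, quantity, policy = "none") {
  region_peak(series, region, quantity, policy)$peak_value
}

# reference reduced mesh (~5,400 elements), the scale the published-value
# comparisons are run at
medium_cell_mesh <- function() cached("mesh_08",
  generate_cell_mesh(test_geom(), test_nucleus(), target_edge = 0.8))

medium_fiber_mesh <- function() cached("fiber_mesh_08", {
  net <- build_fiber_network(fiber_network_spec(), test_geom(),
                             test_nucleus())
  attach_fiber_elements(medium_cell_mesh(), net)
})

medium_run <- function(name, mode = "quasi_static") {
  key <- sprintf("mrun_%s_%s", name, mode)
  cached(key, {
    spec <- paper_scenario(name)
    spec$solver_options$mode <- mode
    spec$solver_options$steps_per_cycle <- 24
    spec$solver_options$record_displacement <- FALSE
    mesh <- if (is.null(spec$fibers)) medium_cell_mesh()
            else medium_fiber_mesh()
    run_transient(build_discrete_model(spec, mesh))
  })
}

# small elastic quasi-static slab scenario (shared by slab-oracle tests)
slab_series <- function() cached("slab_series", {
  slab <- make_slab_fixture(side = 16, thickness = 1, target_edge = 0.8)
  spec <- scenario_spec(
    cytoplasm_material = visco_material_spec(mode = "linear_elastic"),
    loading = loading_spec(frequency = 1, n_cycles = 1),
    solver_options = solver_options(mode = "quasi_static",
                                    steps_per_cycle = 12),
    label = "slab_oracle")
  run_transient(build_discrete_model(spec, slab))
})

slab_interior <- function(mesh, margin = 6) {
  cen <- t(vapply(seq_len(nrow(mesh$tet10)), function(e)
    colMeans(mesh$nodes[mesh$tet10[e, 1:4], ]), numeric(3)))
  half <- max(abs(mesh$nodes[, 1]))
  which(pmax(abs(cen[, 1]), abs(cen[, 2])) < half - margin)
}

# azimuthal scatter of an element field over the mesh's rotational orbits:
# max over orbits of (max - min) / mean within the orbit
orbit_scatter <- function(mesh, field) {
  meta <- mesh$element_meta
  orbit <- paste(meta$tri2d, meta$sub)
  vals <- split(field, orbit)
  vals <- vals[vapply(vals, function(v) mean(abs(v)) > 1e-3 * max(abs(field)),
                      TRUE)]
  max(vapply(vals, function(v) (max(v) - min(v)) / mean(v), 0))
}
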