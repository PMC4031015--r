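test_that("slab and single-element fixtures are exact", {
  slab <- make_slab_fixture(10, 1, 1)
  mm <- mesh_metrics(slab)
  expect_equal(mm$total_volume, 100, tolerance = 1e-9)
  expect_equal(mm$min_scaled_jacobian, 1)
  # basal set contains every z = 0 node and nothing else
  expect_setequal(slab$node_sets$basal, which(abs(slab$nodes[, 3]) < 1e-12))

  one <- make_single_element_fixture()
  expect_equal(nrow(one$nodes), 10L)
  expect_equal(nrow(one$tet10), 1L)
  mm1 <- mesh_metrics(one)
  expect_equal(mm1$total_volume, 1 / 6, tolerance = 1e-12)
  expect_gt(mm1$min_scaled_jacobian, 0)
})

test_that("cell mesh volumes match the analytic geometry within 2%", {
  m <- cached("mesh_16", generate_cell_mesh(test_geom(), test_nucleus(),
                                            target_edge = 1.6))
  mm <- mesh_metrics(m)
  expect_lt(abs(mm$total_volume - 490) / 490, 0.02)
  v_nuc <- 4 / 3 * pi * 2.5^2 * 1
  expect_lt(abs(mm$region_volumes[["nucleus"]] - v_nuc) / v_nuc, 0.02)
  expect_gt(mm$min_scaled_jacobian, 0)
  # basal surface exactly planar
  expect_true(all(abs(m$nodes[m$node_sets$basal, 3]) < 1e-9))
})

test_that("region volumes converge under refinement", {
  m1 <- cached("mesh_16", generate_cell_mesh(test_geom(), test_nucleus(),
                                             target_edge = 1.6))
  m2 <- cached("mesh_08", generate_cell_mesh(test_geom(), test_nucleus(),
                                             target_edge = 0.8))
  v1 <- mesh_metrics(m1)$total_volume
  v2 <- mesh_metrics(m2)$total_volume
  expect_lt(abs(v2 - v1) / v1, 0.005)
  expect_lt(abs(v2 - 490) / 490, abs(v1 - 490) / 490 + 1e-9)
})

test_that("meshes are conforming with a paired cytoplasm/nucleus interface", {
  m <- tiny_cell_mesh()
  cf <- check_mesh_conformity(m)
  expect_true(cf$conforming)
  expect_gt(cf$n_interface_faces, 0)
})

test_that("mesh generation is deterministic and validates its inputs", {
  a <- generate_cell_mesh(test_geom(), test_nucleus(), target_edge = 1.4,
                          sectors = 8, rays = 8, layers = 2, rings = 2)
  b <- generate_cell_mesh(test_geom(), test_nucleus(), target_edge = 1.4,
                          sectors = 8, rays = 8, layers = 2, rings = 2)
  expect_identical(a, b)
  expect_error(generate_cell_mesh(test_geom(), test_nucleus(),
                                  target_edge = 0.05), "target_edge")
  expect_error(generate_cell_mesh(test_geom(), test_nucleus(),
                                  target_edge = 1, sectors = 12),
               "multiple of 8")
})

test_that("fiber attachment creates 24 chains with 48 node ties", {
  m <- tiny_fiber_mesh()
  expect_equal(nrow(m$tru3), 24L)
  expect_equal(nrow(m$ties), 48L)
  # anchors live on their target surfaces
  expect_true(all(abs(m$nodes[m$node_sets$sf_foot_anchors, 3]) < 1e-9))
  expect_true(all(m$node_sets$sf_nucleus_anchors %in%
                    m$node_sets$interface))
  # mid nodes are bookkeeping only (slaved)
  expect_setequal(m$slaved_nodes, m$tru3[, 2])
  # attaching an empty network is a no-op
  m0 <- tiny_cell_mesh()
  expect_identical(attach_fiber_elements(m0, NULL), m0)
})
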