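test_that("element fields vanish for the zero state and match the slab oracle", {
  spec <- paper_scenario("baseline_1Hz")
  spec$solver_options$mode <- "quasi_static"
  model <- build_discrete_model(spec, tiny_cell_mesh())
  st <- cellstrain:::new_solver_state(model)
  fl <- element_fields(model, st)
  expect_equal(max(abs(fl$von_mises)), 0)
  expect_equal(max(abs(fl$principal_strain_magnitude)), 0)

  s <- slab_series()
  orc <- slab_oracle()
  kpk <- which.min(abs(s$times - 0.25))
  interior <- slab_interior(s$mesh)
  expect_lt(max(abs(s$vm[interior, kpk] - orc$von_mises)) / orc$von_mises,
            0.03)
  expect_lt(max(abs(s$ps[interior, kpk] -
                      abs(orc$out_of_plane_strain))) /
              abs(orc$out_of_plane_strain), 0.03)
})

test_that("attachment exclusion is local, non-empty and never raises a peak", {
  expect_identical(attachment_exclusion_set(tiny_cell_mesh()), integer(0))
  mf <- tiny_fiber_mesh()
  excl <- attachment_exclusion_set(mf)
  expect_gte(length(excl), 48L)
  # every excluded element touches an anchor; stay within 2 um of one
  anchors <- c(mf$node_sets$sf_foot_anchors, mf$node_sets$sf_nucleus_anchors)
  apos <- mf$nodes[anchors, , drop = FALSE]
  for (e in excl[seq(1, length(excl), length.out = 25)]) {
    cen <- colMeans(mf$nodes[mf$tet10[e, 1:4], ])
    expect_lt(min(sqrt(colSums((t(apos) - cen)^2))), 2.5)
  }
  s <- tiny_run("cytoskeleton_1Hz", n_cycles = 2)
  for (r in c("cytoplasm", "nucleus")) for (q in c("stress", "strain")) {
    expect_lte(peak_of(s, r, q, "exclude_attachment_ring"),
               peak_of(s, r, q, "none"))
  }
})

test_that("region peaks are frame-order invariant and region-checked", {
  s <- tiny_run("baseline_1Hz", n_cycles = 2)
  pk <- region_peak(s, "cytoplasm", "stress")
  perm <- sample(length(s$times))
  s2 <- s
  s2$vm <- s$vm[, perm]; s2$ps <- s$ps[, perm]; s2$times <- s$times[perm]
  pk2 <- region_peak(s2, "cytoplasm", "stress")
  expect_equal(pk2$peak_value, pk$peak_value)
  expect_equal(pk$region, "cytoplasm")
  expect_true(pk$frame_time %in% s$times)
})

test_that("summary table has the scenario x region x quantity layout", {
  s1 <- tiny_run("baseline_1Hz", n_cycles = 2)
  s45 <- tiny_run("baseline_45Hz", n_cycles = 2)
  tab <- summary_table(list(s1, s45))
  expect_equal(nrow(tab), 2L * 2L * 2L)
  expect_named(tab, c("scenario", "frequency_hz", "region", "quantity",
                      "peak", "frame_time_s", "excluded_policy",
                      "ratio_vs_1hz"))
  expect_true(all(tab$ratio_vs_1hz[tab$frequency_hz == 1] == 1))
  # strain rows are reported in microstrain
  expect_gt(min(tab$peak[tab$quantity == "strain"]), 100)
})

test_that("VTU export round-trips fields and rejects empty series", {
  s <- tiny_run("baseline_1Hz", n_cycles = 2)
  small <- s
  keep <- 1:3
  small$times <- s$times[keep]; small$vm <- s$vm[, keep]
  small$ps <- s$ps[, keep]
  td <- file.path(tempdir(), "vtk_test", "series")
  files <- export_vtk(small, td)
  expect_equal(sum(grepl("\\.vtu$", files)), 3L)
  expect_true(file.exists(paste0(td, ".pvd")))
  back <- read_vtu(files[2])
  expect_equal(back$points, unname(small$mesh$nodes), tolerance = 1e-12)
  expect_equal(back$cell_data$VonMises_Pa, small$vm[, 2], tolerance = 1e-12)
  expect_equal(back$cell_data$PrincStrain, small$ps[, 2], tolerance = 1e-12)
  expect_true(all(back$types == 24))
  empty <- small; empty$times <- numeric(0)
  expect_error(export_vtk(empty, td), "non-empty")
})

test_that("series persist and restore identically", {
  s <- tiny_run("baseline_1Hz", n_cycles = 2)
  p <- file.path(tempdir(), "series_store", "run.rds")
  save_series(s, p)
  expect_identical(load_series(p), s)
})
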