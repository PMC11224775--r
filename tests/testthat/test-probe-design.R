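test_that("channel enumeration filters by the SDS threshold", {
  solo <- discover_topology(modules = "1")
  lay <- fold_out_2d(solo)
  ch35 <- enumerate_channels(lay, 35)
  expect_equal(nrow(ch35), 6)
  expect_true(all(ch35$kind == "intra"))
  expect_equal(sort(ch35$sds_mm), c(8, 24.5, 24.5, 24.5, 24.5, 30),
               tolerance = 1e-6)
  ch20 <- enumerate_channels(lay, 20)
  expect_equal(nrow(ch20), 1)
  expect_equal(ch20$sds_mm, 8, tolerance = 1e-9)

  # two modules far apart: intra channels only
  far <- discover_topology(wiring_list(a = "1", port_a = 1, b = "2",
                                       port_b = 3, distance_mm = 500))
  chf <- enumerate_channels(fold_out_2d(far), 35)
  expect_equal(nrow(chf), 12)
  expect_true(all(chf$kind == "intra"))
})

test_that("adjacent modules contribute inter-module channels", {
  two <- discover_topology(wiring_list(a = "1", port_a = 1, b = "2",
                                       port_b = 3))
  ch <- enumerate_channels(fold_out_2d(two), 35)
  expect_true(any(ch$kind == "inter"))
  expect_true(all(ch$sds_mm <= 35))
})

test_that("conflict graph follows the shared-detector rule", {
  solo <- discover_topology(modules = "1")
  g <- build_conflict_graph(enumerate_channels(fold_out_2d(solo), 35))
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)  # complete on 3 sources

  far <- discover_topology(wiring_list(a = "1", port_a = 1, b = "2",
                                       port_b = 3, distance_mm = 500))
  g2 <- build_conflict_graph(enumerate_channels(fold_out_2d(far), 35))
  expect_equal(igraph::vcount(g2), 6)
  expect_equal(igraph::ecount(g2), 6)  # two disjoint triangles
  comp <- igraph::components(g2)
  expect_equal(comp$no, 2)

  # single source probe: one node, no edges
  single <- discover_topology(
    modules = "1",
    specs = module_spec(optodes = list(optode("S1", "source", 0, 0),
                                       optode("D1", "detector", 0, 10))))
  g3 <- build_conflict_graph(enumerate_channels(fold_out_2d(single), 35))
  expect_equal(igraph::vcount(g3), 1)
  expect_equal(igraph::ecount(g3), 0)
})

test_that("greedy SMG assignment colors canonical graphs", {
  solo <- discover_topology(modules = "1")
  plan <- assign_smgs(build_conflict_graph(
    enumerate_channels(fold_out_2d(solo), 35)))
  expect_equal(plan$n_groups, 3)
  expect_equal(plan$smr, 1.0)

  far <- discover_topology(wiring_list(a = "1", port_a = 1, b = "2",
                                       port_b = 3, distance_mm = 500))
  plan2 <- assign_smgs(build_conflict_graph(
    enumerate_channels(fold_out_2d(far), 35)))
  expect_equal(plan2$n_groups, 3)  # triangles colored in parallel
  expect_equal(plan2$smr, 2.0)

  edgeless <- igraph::make_empty_graph(5, directed = FALSE)
  edgeless <- igraph::set_vertex_attr(edgeless, "name",
                                      value = paste0("s", 1:5))
  plan3 <- assign_smgs(edgeless)
  expect_equal(plan3$n_groups, 1)
  expect_equal(plan3$smr, 5.0)
})

test_that("SMG coloring is proper and bounded by clique and source counts", {
  for (seed in 1:30) {
    topo <- random_topology(seed)
    lay <- suppressWarnings(fold_out_2d(topo))
    g <- build_conflict_graph(enumerate_channels(lay, 35))
    plan <- assign_smgs(g)
    # proper coloring: no conflict edge within a group
    ends <- igraph::as_edgelist(g)
    if (nrow(ends))
      expect_true(all(plan$group_of[ends[, 1]] != plan$group_of[ends[, 2]]))
    expect_lte(plan$n_groups, plan$n_sources)
    expect_gte(plan$n_groups, igraph::clique_num(g))
  }
})

test_that("greedy coloring is exact on interval-like chain probes", {
  for (n in 2:5) {
    topo <- chain_topology(n)
    g <- build_conflict_graph(enumerate_channels(fold_out_2d(topo), 35))
    plan <- assign_smgs(g)
    expect_equal(plan$n_groups, exact_chromatic_number(g))
    expect_equal(plan$n_groups, igraph::clique_num(g))
  }
})

test_that("timing model and frame rates reproduce the printed rates", {
  tm <- timing_model()
  expect_equal(tm$t_slot_ms, 30)  # 7.5 ms x 2 wavelengths x (signal + dark)
  expect_equal(timing_model(include_dark = FALSE)$t_slot_ms, 15)
  expect_equal(signif(frame_rate(3, tm), 2), 11)
  expect_equal(signif(frame_rate(15, tm), 2), 2.2)
  expect_equal(signif(frame_rate(14, tm), 2), 2.4)
  expect_equal(signif(frame_rate(7, tm), 2), 4.8)
  expect_error(frame_rate(0, tm), "positive")
  # exact identity before rounding
  for (n in c(1, 3, 14, 15))
    expect_equal(frame_rate(n, tm) * n * tm$t_slot_ms, 1000)
})

test_that("multiplexed/sequential rate ratio equals the SMR exactly", {
  tm <- timing_model()
  for (seed in 1:10) {
    topo <- random_topology(seed)
    lay <- suppressWarnings(fold_out_2d(topo))
    plan <- assign_smgs(build_conflict_graph(enumerate_channels(lay, 35)))
    expect_equal(frame_rate(plan$n_groups, tm) /
                   frame_rate(plan$n_sources, tm),
                 plan$smr)
  }
})

test_that("probe_report composes the pipeline", {
  r1 <- probe_report(discover_topology(modules = "1"))
  expect_equal(r1$n_modules, 1)
  expect_equal(r1$n_channels, 6)
  expect_equal(r1$n_groups, 3)
  expect_equal(r1$rate_sequential_hz_display, 11)

  rv <- probe_report(v_probe_topology())
  expect_equal(rv$n_sources, 15)
  expect_equal(rv$improvement_ratio, rv$n_sources / rv$n_groups)
  expect_equal(rv$rate_multiplexed_hz / rv$rate_sequential_hz, rv$smr)

  expect_error(probe_report(discover_topology(
    modules = "1",
    specs = module_spec(optodes = list(optode("D1", "detector", 0, 0))))),
    "no valid channels|no sources")
})

test_that("source-distance conflict rule is available as an alternative", {
  topo <- v_probe_topology()
  ch <- enumerate_channels(fold_out_2d(topo), 35)
  g_sd <- build_conflict_graph(ch, rule = "source_distance")
  plan <- assign_smgs(g_sd)
  ends <- igraph::as_edgelist(g_sd)
  expect_true(all(plan$group_of[ends[, 1]] != plan$group_of[ends[, 2]]))
})
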