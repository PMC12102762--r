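test_that("the ER lipid recipe sums to 100 with net charge -10 per leaflet", {
  comp <- er_membrane_composition()
  expect_equal(sum(comp$count), 100)
  expect_equal(sum(comp$count * comp$charge), -10)
  mem <- build_membrane_slab(scale = 1)
  expect_equal(attr(mem, "lipids_per_leaflet"), 100)
  expect_equal(attr(mem, "net_charge_per_leaflet"), -10)
  # the full-size leaflet of the reference model
  mem19 <- build_membrane_slab(scale = 1.9)
  expect_equal(attr(mem19, "lipids_per_leaflet"), 190)
})

test_that("largest-remainder rounding conserves totals and table-order ties", {
  comp <- er_membrane_composition()
  for (scale in c(0.37, 0.5, 1.13, 1.9)) {
    counts <- peripose:::largest_remainder(comp$count * scale,
                                           round(100 * scale))
    expect_equal(sum(counts), round(100 * scale))
    expect_true(all(counts >= 0))
  }
  # deterministic tie-break by position
  expect_equal(peripose:::largest_remainder(c(1, 1, 1), 2), c(1L, 1L, 0L))
})

test_that("slab geometry: phosphate planes, tails toward centre, box checks", {
  mem <- build_membrane_slab(scale = 0.3, half_thickness = 16)
  top <- mem$topology
  z <- mem$frame$coords[, 3]
  p <- top$atom_name == "P"
  expect_equal(sort(unique(z[p])), c(-16, 16))
  expect_true(all(abs(z[!p]) < 16))
  expect_true(all(top$segment == "membrane"))
  # two leaflets of equal size
  expect_equal(sum(z[p] > 0), sum(z[p] < 0))
  expect_error(build_membrane_slab(scale = 1, box = c(20, 20, 120)),
               "too small")
})

test_that("binding trajectories are bit-reproducible under a fixed seed", {
  mem <- build_membrane_slab(scale = 0.2)
  prot <- build_protein_template(n_res = 5)
  scen <- binding_scenario(phases = c(approach = 5, bound = 20), seed = 42)
  s1 <- simulate_binding_trajectory(scen, mem, prot)
  s2 <- simulate_binding_trajectory(scen, mem, prot)
  expect_identical(s1$trajectory$coords, s2$trajectory$coords)
  scen2 <- binding_scenario(phases = c(approach = 5, bound = 20), seed = 43)
  s3 <- simulate_binding_trajectory(scen2, mem, prot)
  expect_false(identical(s1$trajectory$coords, s3$trajectory$coords))
})

test_that("a never-binding scenario stays out of contact", {
  mem <- build_membrane_slab(scale = 0.2)
  prot <- build_protein_template(n_res = 5)
  scen <- binding_scenario(phases = c(diffuse = 30), seed = 8)
  sim <- simulate_binding_trajectory(scen, mem, prot)
  top <- sim$trajectory$topology
  ser <- contact_series(sim$trajectory,
                        make_selection(top, "protein and heavy"),
                        make_selection(top, "membrane and heavy"))
  expect_true(all(total_contact_series(ser)$total < 0.5))
})

test_that("planted anchor depths are recovered within the noise budget", {
  mem <- build_membrane_slab(scale = 0.3)
  prot <- build_protein_template(n_res = 8)
  scen <- binding_scenario(phases = c(bound = 300), anchor_depth = 9, seed = 5)
  sim <- simulate_binding_trajectory(scen, mem, prot)
  top <- sim$trajectory$topology
  dep <- residue_depth_series(sim$trajectory,
                              make_selection(top, "protein and heavy"),
                              make_selection(top, "membrane and heavy"))
  anchor <- dep |> dplyr::filter(chain == "A", residue_id == 1)
  expect_lt(abs(mean(anchor$depth) - 9), 0.5)
})

test_that("scenario validation rejects bad scripts", {
  expect_error(binding_scenario(phases = c(flying = 10)), "phases must be")
  expect_error(binding_scenario(phases = c(bound = 0)), ">= 1 frame")
  expect_error(binding_scenario(tilt_mode = 200), "0, 180")
})

test_that("Crooks generator: degenerate limit, determinism and recovery", {
  sch <- lambda_schedule(c(0, 0.5, 1))
  # sigma = 0: every forward sample equals the window free energy exactly
  s0 <- fep_scenario(sch, dg_per_window = c(1.5, -0.5), sigma = 0, n_per_direction = 4)
  leg0 <- simulate_fep_leg(s0)
  fwd <- leg0$work |> dplyr::filter(direction == "forward", lambda_start == 0)
  expect_true(all(fwd$delta_u == 1.5))
  expect_equal(leg0$true_total, 1.0)
  # same seed, same samples
  s1 <- fep_scenario(dg_per_window = 0.3, sigma = 1, seed = 12)
  expect_identical(simulate_fep_leg(s1)$work$delta_u,
                   simulate_fep_leg(s1)$work$delta_u)
  # estimator recovery across the default 14-window leg
  s2 <- fep_scenario(dg_per_window = 5 / 14, sigma = 1.5, seed = 21)
  leg <- simulate_fep_leg(s2)
  est <- leg_free_energy(leg$work)
  expect_lt(abs(est$total - leg$true_total), 3 * est$error)
})

test_that("fixtures round trip through the package readers", {
  mem <- build_membrane_slab(scale = 0.2)
  prot <- build_protein_template(n_res = 5)
  scen <- binding_scenario(phases = c(bound = 8), seed = 2)
  sim <- simulate_binding_trajectory(scen, mem, prot)
  dir <- tempfile(); dir.create(dir)
  files <- write_fixture(trajectory = sim$trajectory, truth = sim$truth,
                         dir = dir, prefix = "fx")
  expect_true(all(file.exists(files)))
  back_top <- read_structure(files[["topology"]])
  expect_equal(nrow(back_top$topology), nrow(sim$trajectory$topology))
  back <- read_trajectory(back_top$topology, files[["trajectory"]])
  expect_equal(n_frames(back), 8)
  expect_lt(max(abs(back$coords - sim$trajectory$coords)), 1e-3)

  # fep fixtures too
  leg <- simulate_fep_leg(fep_scenario(lambda_schedule(c(0, 0.5, 1)),
                                       n_per_direction = 5))
  f2 <- write_fixture(work = leg$work, dir = dir, prefix = "leg")
  reparsed <- parse_fepout(f2[["fepout"]])
  expect_equal(nrow(reparsed), nrow(leg$work))
  expect_equal(sort(reparsed$delta_u), sort(leg$work$delta_u), tolerance = 1e-6)
})
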