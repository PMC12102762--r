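test_that("membrane centre and leaflet surfaces follow their definitions", {
  top <- topology(
    atom_name = c("P", "P", "P", "P", "C1"),
    residue_id = 1:5, residue_name = "PC", chain = "M"
  )
  coords <- rbind(c(0, 0, 15), c(0, 0, 17), c(0, 0, -15), c(0, 0, -17),
                  c(0, 0, 0))
  all_mem <- make_selection(top, "membrane")
  p_sel <- make_selection(top, "name P")
  expect_equal(membrane_center_z(coords, p_sel), 0)
  expect_equal(membrane_center_z(rbind(c(0,0,0), c(0,0,3), c(0,0,6)),
                                 structure(1:3, class = "pp_selection")), 3)
  s <- leaflet_surfaces(coords, top, p_sel, 0)
  expect_equal(unname(s), c(16, -16))
  # equivariance under z translation
  shifted <- coords; shifted[, 3] <- shifted[, 3] + 5
  expect_equal(membrane_center_z(shifted, p_sel), 5)
  s2 <- leaflet_surfaces(shifted, top, p_sel, 5)
  expect_equal(unname(s2), c(21, -11))
  # name filter rejects non-phosphate atoms
  expect_error(leaflet_surfaces(coords, top, all_mem, 0), "name filter")
  # one-sided selections are rejected
  expect_error(leaflet_surfaces(coords, top, structure(1:2, class = "pp_selection"), 0),
               "both sides")
  expect_error(membrane_center_z(coords, integer()), "empty")
})

test_that("residue depths pick the heavy atom nearest the centre, signed", {
  top <- topology(
    atom_name = c("CA", "CB", "CA", "P", "C1"),
    residue_id = c(1, 1, 2, 3, 3),
    residue_name = c("ALA", "ALA", "GLY", "PC", "PC"),
    chain = c("A", "A", "A", "M", "M")
  )
  coords <- rbind(c(0, 0, 18), c(0, 0, 9), c(0, 0, -3), c(0, 0, 2), c(0, 0, -2))
  traj <- trajectory(top, list(coords), box = c(60, 60, 200))
  prot <- make_selection(top, "protein and heavy")
  mem <- make_selection(top, "membrane and heavy")
  dep <- residue_depth_series(traj, prot, mem)
  expect_equal(dep$depth[dep$residue_id == 1], 9)   # nearest-to-centre rule
  expect_equal(dep$depth[dep$residue_id == 2], -3)  # sign convention
  # brute-force oracle on every residue
  cz <- mean(coords[mem, 3])
  for (r in 1:2) {
    idx <- which(top$residue_id == r)
    expect_lt(abs(dep$depth[dep$residue_id == r] - brute_depth(coords, idx, cz)),
              1e-10)
  }
})

test_that("depth pipeline is equivariant under whole-system z shifts", {
  sys <- tiny_system(n_res = 3, n_lipids = 6, protein_z = 12)
  traj1 <- trajectory(sys$topology, list(sys$coords), box = sys$box)
  shifted <- sweep(sys$coords, 2, c(0, 0, 11), "+")
  traj2 <- trajectory(sys$topology, list(shifted), box = sys$box)
  prot <- make_selection(sys$topology, "protein and heavy")
  mem <- make_selection(sys$topology, "membrane and heavy")
  d1 <- residue_depth_series(traj1, prot, mem)
  d2 <- residue_depth_series(traj2, prot, mem)
  expect_equal(d1$depth, d2$depth, tolerance = 1e-10)
})

test_that("depth histograms normalise per residue and split mass correctly", {
  ser <- tibble::tibble(
    frame = rep(1:4, 2), time = rep(1:4, 2),
    chain = "A", residue_id = rep(1:2, each = 4),
    global_index = rep(1:2, each = 4),
    depth = c(9, 9, 9, 9, 4, 4, 12, 12)
  )
  class(ser) <- c("pp_depth_series", class(ser))
  h <- depth_histogram(ser, bin_width = 0.5, window_fraction = 1)
  h1 <- h[h$residue_id == 1, ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$probability, 1)
  h2 <- h[h$residue_id == 2, ]
  expect_equal(sort(h2$probability), c(0.5, 0.5))
  sums <- h |>
    dplyr::group_by(residue_id) |>
    dplyr::summarise(p = sum(probability))
  expect_true(all(abs(sums$p - 1) < 1e-9))
  expect_error(depth_histogram(ser, bin_width = 0), "bin_width")
})

test_that("breach classification compares depth mass with the surface plane", {
  h <- tibble::tibble(
    chain = "A", residue_id = c(1, 2), global_index = c(1, 2),
    bin_left = c(19.75, 8.75), bin_right = c(20.25, 9.25),
    probability = c(1, 1)
  )
  br <- breach_residues(h, geometry = 16)
  expect_equal(br$breach, c(FALSE, TRUE))
  # the same via a geometry table
  geom <- tibble::tibble(upper_surface_z = c(16, 16), lower_surface_z = c(-16, -16))
  br2 <- breach_residues(h, geom)
  expect_equal(br2$breach, br$breach)
})
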