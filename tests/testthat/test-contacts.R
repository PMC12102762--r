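test_that("contact kernel matches its closed form and limits", {
  expect_identical(contact_weight(4), 0.5)
  expect_equal(contact_weight(3), 1 / (1 + exp(-5)), tolerance = 1e-6)
  expect_equal(contact_weight(3), 0.993307, tolerance = 1e-5)
  expect_equal(contact_weight(5), 1 / (1 + exp(5)), tolerance = 1e-12)
  expect_equal(contact_weight(5), 0.0066929, tolerance = 1e-4)
  grid <- seq(0, 30, by = 0.1)
  expect_true(all(diff(contact_weight(grid)) < 0))
  expect_lt(1 - contact_weight(0), 1e-8)
  expect_lt(contact_weight(30), 1e-8)
  expect_error(contact_weight(-1), "finite")
  expect_error(contact_weight(Inf), "finite")
})

test_that("residue contact counts follow the kernel and are additive", {
  top <- topology(
    atom_name = c("CA", "CB", "P", "P"),
    residue_id = c(1, 1, 2, 3),
    residue_name = c("ALA", "ALA", "PC", "PC"),
    chain = c("A", "A", "M", "M")
  )
  coords <- rbind(c(0, 0, 0), c(0, 0, 50), c(4, 0, 0), c(0, 0, 46))
  frame <- list(coords = coords, box = c(100, 100, 100))
  res <- make_selection(top, "protein")
  m1 <- make_selection(top, "membrane and resid 2")
  m2 <- make_selection(top, "membrane and resid 3")
  mem <- make_selection(top, "membrane")
  # single atom pair at the midpoint distance
  expect_equal(residue_contacts(frame, top, structure(1L, class = "pp_selection"), m1), 0.5)
  # two residue atoms each 4 A from one membrane atom
  coords2 <- rbind(c(0, 0, 0), c(8, 0, 0), c(4, 0, 0), c(0, 0, 46))
  expect_equal(residue_contacts(list(coords = coords2, box = c(100, 100, 100)),
                                top, res, m1), 1.0)
  # additivity over disjoint membrane subsets
  c_all <- residue_contacts(frame, top, res, mem)
  expect_equal(c_all,
               residue_contacts(frame, top, res, m1) +
                 residue_contacts(frame, top, res, m2))
  # empty membrane selection warns and returns 0
  suppressWarnings(empty <- make_selection(top, "resid 99"))
  expect_warning(z <- residue_contacts(frame, top, res, empty), "empty")
  expect_equal(z, 0)
  # overlap is an error
  expect_error(residue_contacts(frame, top, res, res), "overlap")
  # hydrogen-containing selections are rejected
  toph <- topology(c("CA", "HA", "P"), c(1, 1, 2), c("ALA", "ALA", "PC"),
                   c("A", "A", "M"))
  expect_error(
    residue_contacts(list(coords = coords[1:3, ], box = rep(100, 3)), toph,
                     structure(1:2, class = "pp_selection"),
                     structure(3L, class = "pp_selection")),
    "heavy"
  )
})

test_that("contact series matches the brute-force oracle and is rigid-motion invariant", {
  sys <- tiny_system(n_res = 4, n_lipids = 6, protein_z = 17)
  top <- sys$topology
  frames <- list(sys$coords, sweep(sys$coords, 2, c(10, 10, 0), "+"))
  traj <- trajectory(top, frames, box = sys$box)
  prot <- make_selection(top, "protein and heavy")
  mem <- make_selection(top, "membrane and heavy")
  ser <- contact_series(traj, prot, mem)

  for (r in unique(top$residue_id[prot])) {
    idx <- which(top$chain == "A" & top$residue_id == r & top$is_heavy)
    want <- brute_contacts(sys$coords, idx, mem, box_z = sys$box[3])
    got <- ser$contact[ser$frame == 1 & ser$residue_id == r]
    expect_lt(abs(got - want), 1e-10)
  }
  # rigid in-plane translation of the full system changes nothing
  f1 <- ser$contact[ser$frame == 1]
  f2 <- ser$contact[ser$frame == 2]
  expect_lt(max(abs(f1 - f2)), 1e-10)
  # rotation about z changes nothing either
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  traj_rot <- trajectory(top, list(sys$coords %*% t(rot)), box = sys$box)
  ser_rot <- contact_series(traj_rot, prot, mem)
  expect_lt(max(abs(ser_rot$contact - f1)), 1e-9)
})

test_that("a distant protein registers essentially zero contacts", {
  sys <- tiny_system(protein_z = 50)
  traj <- trajectory(sys$topology, list(sys$coords), box = sys$box)
  ser <- contact_series(traj,
                        make_selection(sys$topology, "protein and heavy"),
                        make_selection(sys$topology, "membrane and heavy"))
  expect_true(all(ser$contact < 1e-9))
})

test_that("totals, window means and cumulative sums obey their arithmetic", {
  ser <- tibble::tibble(
    frame = rep(1:4, each = 3), time = rep(1:4, each = 3),
    chain = "A", residue_id = rep(1:3, 4), global_index = rep(1:3, 4),
    contact = c(1, 2, 0.5, 1, 2, 0.5, 4, 4, 4, 4, 4, 4)
  )
  class(ser) <- c("pp_contact_series", class(ser))
  tot <- total_contact_series(ser)
  expect_equal(tot$total, c(3.5, 3.5, 12, 12))

  # trailing half of [a, a, 4, 4] per residue is 4
  prof <- window_mean_profile(ser, 0.5)
  expect_equal(prof$mean_contact, c(4, 4, 4))
  # full window equals the plain mean
  prof_all <- window_mean_profile(ser, 1.0)
  expect_equal(prof_all$mean_contact, c(2.5, 3, 2.25))

  cum <- cumulative_profile(
    tibble::tibble(chain = "A", residue_id = 1:3, global_index = 1:3,
                   mean_contact = c(0.5, 0, 1.5))
  )
  expect_equal(cum$cumulative, c(0.5, 0.5, 2.0))
  expect_true(all(diff(cum$cumulative) >= 0))
  expect_equal(dplyr::last(cum$cumulative), sum(cum$mean_contact))

  expect_error(window_mean_profile(ser, 0), "window_fraction")
  expect_error(window_mean_profile(ser, 1.5), "window_fraction")
})

test_that("dissociation detection follows the persistence state machine", {
  rep1 <- detect_dissociation(c(0, 0, 3, 2, 0, 0, 4), threshold = 0.5,
                              min_persistence = 2)
  expect_equal(rep1$association_frame, 3L)
  expect_equal(rep1$events, 5L)
  expect_true(rep1$ever_dissociated)

  # always bound: no dissociation
  rep2 <- detect_dissociation(rep(2, 10), threshold = 0.5, min_persistence = 2)
  expect_equal(rep2$association_frame, 1L)
  expect_false(rep2$ever_dissociated)

  # never associated
  rep3 <- detect_dissociation(rep(0, 10), threshold = 0.5)
  expect_true(is.na(rep3$association_frame))
  expect_false(rep3$ever_dissociated)

  # single-frame flickers shorter than the persistence are ignored
  rep4 <- detect_dissociation(c(0, 2, 2, 0, 2, 2, 0, 0), threshold = 0.5,
                              min_persistence = 2)
  expect_equal(rep4$association_frame, 2L)
  expect_equal(rep4$events, 7L)

  # repeated unbind/rebind cycles all count
  rep5 <- detect_dissociation(c(2, 2, 0, 0, 2, 2, 0, 0), threshold = 0.5,
                              min_persistence = 2)
  expect_equal(rep5$events, c(3L, 7L))
})
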