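kT310 <- 0.0019872041 * 310

test_that("exponential estimator matches hand-evaluated closed forms", {
  # degenerate distribution: dG equals the constant sample
  expect_equal(exp_free_energy(rep(2, 10))$dg, 2, tolerance = 1e-12)
  # hand evaluation of -kT ln mean exp(-dU/kT) for {1, 3} at kT = 0.6
  expect_equal(exp_free_energy(c(1, 3), kT = 0.6)$dg,
               -0.6 * log(mean(exp(-c(1, 3) / 0.6))), tolerance = 1e-12)
  expect_equal(exp_free_energy(c(1, 3), kT = 0.6)$dg, 1.3948, tolerance = 1e-4)
  # Jensen: the estimate never exceeds the sample mean
  set.seed(2)
  for (i in 1:20) {
    du <- rnorm(50, runif(1, -3, 3), runif(1, 0.1, 3))
    expect_lte(exp_free_energy(du)$dg, mean(du) + 1e-12)
  }
  expect_error(exp_free_energy(numeric()), "no samples")
  expect_error(exp_free_energy(c(1, NA)), "non-finite")
  # overflow-safe at extreme energies
  expect_equal(exp_free_energy(c(1000, 1002))$dg, 1000, tolerance = 0.1)
})

test_that("BAR is exact in the zero-variance limit and antisymmetric", {
  r <- bar_free_energy(rep(2.5, 20), rep(-2.5, 20))
  expect_equal(r$dg, 2.5, tolerance = 1e-8)
  expect_equal(r$se, 0)
  set.seed(3)
  p <- crooks_pair(200, 1.2, 1.0, kT310)
  a <- bar_free_energy(p$forward, p$backward)
  b <- bar_free_energy(p$backward, p$forward)
  expect_equal(a$dg, -b$dg, tolerance = 1e-8)
  # in the zero-variance limit BAR and EXP agree exactly with dU
  expect_equal(exp_free_energy(rep(2.5, 20))$dg, 2.5, tolerance = 1e-12)
})

test_that("BAR recovers planted Gaussian free energies within 3 SE", {
  set.seed(17)
  for (dg_true in c(-2, 0.5, 3)) {
    p <- crooks_pair(500, dg_true, 1.5, kT310)
    r <- bar_free_energy(p$forward, p$backward)
    expect_lt(abs(r$dg - dg_true), 3 * r$se)
    expect_gt(r$se, 0)
  }
  # unequal sample sizes stay unbiased (the M = kT ln nF/nR term)
  set.seed(18)
  errs <- replicate(40, {
    sh <- 1.5^2 / (2 * kT310)
    wf <- rnorm(1600, 1 + sh, 1.5)
    wr <- rnorm(400, -1 + sh, 1.5)
    bar_free_energy(wf, wr)$dg - 1
  })
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(length(errs)))
})

test_that("the default lambda schedule carries the published protocol arithmetic", {
  sch <- lambda_schedule()
  g <- glance(sch)
  expect_equal(g$n_values, 15)
  expect_equal(g$n_pairs, 14)
  expect_equal(g$transition_ns, 45)
  expect_equal(g$reaction_ns, 90)
  expect_equal(sch$values[2], 0.02)
  expect_error(lambda_schedule(c(0, 0.5, 0.4, 1)), "increasing")
  expect_error(lambda_schedule(c(0.1, 0.5, 1)), "increasing from 0 to 1")
})

test_that("leg totals, quadrature errors and coverage checking behave", {
  # simple arithmetic on a 4-value schedule
  sch <- lambda_schedule(c(0, 0.3, 0.7, 1))
  work <- dplyr::bind_rows(
    tibble::tibble(lambda_start = 0, lambda_end = 0.3, direction = "forward", delta_u = 1),
    tibble::tibble(lambda_start = 0.3, lambda_end = 0, direction = "backward", delta_u = -1),
    tibble::tibble(lambda_start = 0.3, lambda_end = 0.7, direction = "forward", delta_u = -1),
    tibble::tibble(lambda_start = 0.7, lambda_end = 0.3, direction = "backward", delta_u = 1),
    tibble::tibble(lambda_start = 0.7, lambda_end = 1, direction = "forward", delta_u = 0.5),
    tibble::tibble(lambda_start = 1, lambda_end = 0.7, direction = "backward", delta_u = -0.5)
  )
  leg <- leg_free_energy(work, sch, mutation = "toy")
  expect_equal(leg$total, 0.5, tolerance = 1e-8)
  expect_equal(leg$total, sum(leg$windows$dg))
  expect_equal(leg$error, sqrt(sum(leg$windows$se^2)))

  # missing window is a coverage error naming the gap
  expect_error(leg_free_energy(work[1:4, ], sch), "missing windows.*0.7")
  # the default schedule demands exactly 14 adjacent pairs
  expect_error(leg_free_energy(work, lambda_schedule()), "missing windows")
  # windows outside the schedule are rejected
  extra <- dplyr::bind_rows(work, tibble::tibble(
    lambda_start = 0, lambda_end = 0.5, direction = "forward", delta_u = 1))
  expect_error(leg_free_energy(extra, sch), "outside the schedule")
})

test_that("quadrature and sign conventions of the thermodynamic cycle hold", {
  fake_leg <- function(total, error, leg, mutation = "F99A") {
    structure(list(leg = leg, mutation = mutation, total = total,
                   error = error, estimator = "BAR",
                   windows = tibble::tibble(dg = total, se = error)),
              class = "pp_leg")
  }
  cyc <- ddg_cycle(fake_leg(10, 0.4, "bound"), fake_leg(7.3, 0.3, "solution"))
  expect_equal(cyc$ddg, 2.7)
  expect_equal(cyc$error, 0.5)
  # identical legs cancel
  expect_equal(ddg_cycle(fake_leg(4, 0.1, "bound"),
                         fake_leg(4, 0.1, "solution"))$ddg, 0)
  # reversed mutation direction negates the cycle
  rev <- ddg_cycle(fake_leg(-10, 0.4, "bound"), fake_leg(-7.3, 0.3, "solution"))
  expect_equal(rev$ddg, -cyc$ddg)
  expect_error(ddg_cycle(fake_leg(1, 0.1, "bound", "A"),
                         fake_leg(1, 0.1, "solution", "B")), "labels differ")
  g <- glance(cyc)
  expect_equal(g$ddg, 2.7)
  expect_equal(g$dg_bound, 10)
})

test_that("restraint energies follow U = k |x - xref|^2 without the half factor", {
  ref <- rbind(c(0, 0, 0), c(1, 1, 1))
  spec <- restraint_spec(1:2, ref, k = 1)
  # one atom displaced 2 A: U = 1 * 2^2 = 4 (no half factor)
  coords <- rbind(c(2, 0, 0), c(1, 1, 1))
  expect_equal(restraint_energy(coords, spec), 4)
  expect_equal(restraint_energy(ref, spec), 0)
  # two atoms displaced 1 A each add to 2
  coords2 <- rbind(c(1, 0, 0), c(1, 1, 2))
  expect_equal(restraint_energy(coords2, spec), 2)
  # the conventional half factor is available as a flag
  spec_half <- restraint_spec(1:2, ref, k = 1, half_factor = TRUE)
  expect_equal(restraint_energy(coords, spec_half), 2)

  # linear drift produces a quadratically increasing series
  top <- topology(c("CA", "CA"), 1:2, "ALA", "A")
  drift <- seq(0, 2, length.out = 5)
  frames <- lapply(drift, function(d) sweep(ref, 2, c(d, 0, 0), "+"))
  traj <- trajectory(top, frames, box = c(50, 50, 50))
  ser <- restraint_energy_series(traj, spec)
  expect_equal(ser$energy, 2 * drift^2, tolerance = 1e-10)
  # brute-force oracle per frame
  for (f in seq_along(frames)) {
    want <- sum(1 * rowSums((frames[[f]] - ref)^2))
    expect_lt(abs(ser$energy[f] - want), 1e-10)
  }
  # lambda-consistency audit
  audit <- restraint_audit(ser, lambda = c(0, 0, 0.5, 0.5, 1))
  expect_equal(nrow(audit), 3)
  expect_equal(audit$n, c(2, 2, 1))
})

test_that("leg antisymmetry: reversing every window negates the total", {
  set.seed(23)
  sch <- lambda_schedule(c(0, 0.5, 1))
  p1 <- crooks_pair(300, 1.0, 1.0, kT310)
  p2 <- crooks_pair(300, -0.4, 1.0, kT310)
  mk <- function(l0, l1, p) dplyr::bind_rows(
    tibble::tibble(lambda_start = l0, lambda_end = l1, direction = "forward",
                   delta_u = p$forward),
    tibble::tibble(lambda_start = l1, lambda_end = l0, direction = "backward",
                   delta_u = p$backward)
  )
  work <- dplyr::bind_rows(mk(0, 0.5, p1), mk(0.5, 1, p2))
  # mirror the schedule: forward samples become backward of the reversed leg
  rev_work <- work |>
    dplyr::mutate(
      lambda_start = 1 - lambda_start, lambda_end = 1 - lambda_end,
      direction = ifelse(direction == "forward", "backward", "forward")
    )
  a <- leg_free_energy(work, sch)
  b <- leg_free_energy(rev_work, sch)
  expect_equal(a$total, -b$total, tolerance = 1e-8)
})
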