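# Free-energy-perturbation bookkeeping: lambda schedules, per-window
# free-energy estimators (exponential/Zwanzig and Bennett acceptance ratio),
# leg sums with quadrature errors, the thermodynamic-cycle ddG of a mutation
# (bound leg minus solution leg; positive values mean weakened membrane
# binding), and the harmonic positional-restraint energy audit.

DEFAULT_LAMBDA <- c(0, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5,
                    0.6, 0.7, 0.8, 0.9, 0.95, 0.98, 1)

#' Alchemical lambda schedule
#'
#' The default is the 15-value schedule 0, 0.02, 0.05, 0.1, 0.2, ..., 0.9,
#' 0.95, 0.98, 1 with 3 ns of sampling per window: 45 ns per transition and
#' 90 ns per bidirectional reaction.
#'
#' @param values Strictly increasing lambda values from 0 to 1.
#' @param ns_per_window Sampling time per lambda value, ns.
#' @return A list of class `pp_lambda_schedule` with `values`,
#'   `ns_per_window`.
#' @export
lambda_schedule <- function(values = DEFAULT_LAMBDA, ns_per_window = 3) {
  values <- as.numeric(values)
  if (length(values) < 2 || any(diff(values) <= 0) ||
      values[1] != 0 || values[length(values)] != 1) {
    abort("lambda values must be strictly increasing from 0 to 1")
  }
  assert_scalar_number(ns_per_window, "ns_per_window", positive = TRUE)
  structure(list(values = values, ns_per_window = ns_per_window),
            class = "pp_lambda_schedule")
}

#' @export
glance.pp_lambda_schedule <- function(x, ...) {
  tibble(
    n_values = length(x$values),
    n_pairs = length(x$values) - 1L,
    ns_per_window = x$ns_per_window,
    transition_ns = length(x$values) * x$ns_per_window,
    reaction_ns = 2 * length(x$values) * x$ns_per_window
  )
}

#' @export
print.pp_lambda_schedule <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pp_lambda_schedule> %d values (%d adjacent pairs), %g ns/window: %g ns per transition, %g ns per bidirectional reaction\n",
              g$n_values, g$n_pairs, g$ns_per_window, g$transition_ns, g$reaction_ns))
  invisible(x)
}

# Adjacent (start, end) lambda pairs of a schedule.
lambda_pairs <- function(schedule) {
  v <- schedule$values
  tibble(lambda_start = v[-length(v)], lambda_end = v[-1])
}

resolve_kT <- function(temperature, kT) {
  if (!is.null(kT)) {
    assert_scalar_number(kT, "kT", positive = TRUE)
    kT
  } else {
    kT_kcal(temperature)
  }
}

window_result <- function(dg, se, estimator, n_forward, n_backward = NA_integer_) {
  tibble(dg = dg, se = se, estimator = estimator,
         n_forward = as.integer(n_forward), n_backward = as.integer(n_backward))
}

#' Exponential (Zwanzig) free-energy estimate of one window
#'
#' `dG = -kT log mean(exp(-dU/kT))`, evaluated overflow-safely.  The standard
#' error comes from block averaging (`n_blocks` contiguous blocks).
#'
#' @param delta_u Energy-difference samples, kcal/mol.
#' @param temperature Temperature in K (default 310).
#' @param kT Optional explicit thermal energy (kcal/mol), overriding
#'   `temperature`.
#' @param n_blocks Blocks for the block-averaged error (default 5).
#' @return One-row tibble: `dg`, `se`, `estimator`, `n_forward`,
#'   `n_backward`.
#' @export
exp_free_energy <- function(delta_u, temperature = 310, kT = NULL,
                            n_blocks = 5) {
  delta_u <- as.numeric(delta_u)
  if (!length(delta_u)) abort("no samples")
  if (any(!is.finite(delta_u))) abort("non-finite energy samples")
  kT <- resolve_kT(temperature, kT)
  dg <- -kT * log_mean_exp(-delta_u / kT)
  n <- length(delta_u)
  se <- 0
  if (n >= 2 * n_blocks) {
    blocks <- split(delta_u, cut(seq_len(n), n_blocks, labels = FALSE))
    bdg <- vapply(blocks, function(b) -kT * log_mean_exp(-b / kT), numeric(1))
    se <- sd(bdg) / sqrt(n_blocks)
  } else if (n >= 2) {
    se <- kT * sd(exp(-(delta_u - min(delta_u)) / kT)) /
      (mean(exp(-(delta_u - min(delta_u)) / kT)) * sqrt(n))
  }
  window_result(dg, se, "EXP", n)
}

#' Bennett acceptance ratio estimate of one window
#'
#' Solves the Bennett self-consistency equation for the forward/backward
#' work samples of one lambda pair: with `M = kT log(nF/nR)` and the Fermi
#' function `f(x) = 1/(1 + exp(x))`,
#' `sum_i f((M + wF_i - dG)/kT) = sum_j f((-M + wR_j + dG)/kT)`.
#' The root is found by Brent bracketing on the (monotone) residual; the
#' standard error is the asymptotic (delta-method) variance of the implicit
#' equation.
#'
#' @param forward Forward energy differences (work of the forward
#'   transformation), kcal/mol.
#' @param backward Backward energy differences (work of the reverse
#'   transformation), kcal/mol.
#' @param temperature Temperature in K (default 310).
#' @param kT Optional explicit thermal energy (kcal/mol).
#' @param tol Convergence tolerance on dG, kcal/mol (default 1e-8).
#' @param max_iter Maximum bracket expansions (default 100).
#' @return One-row tibble: `dg`, `se`, `estimator`, `n_forward`,
#'   `n_backward`.
#' @export
bar_free_energy <- function(forward, backward, temperature = 310, kT = NULL,
                            tol = 1e-8, max_iter = 100) {
  wf <- as.numeric(forward)
  wr <- as.numeric(backward)
  if (!length(wf) || !length(wr)) abort("both directions need samples")
  if (any(!is.finite(wf)) || any(!is.finite(wr))) abort("non-finite energy samples")
  kT <- resolve_kT(temperature, kT)
  nf <- length(wf); nr <- length(wr)
  M <- kT * log(nf / nr)
  fermi <- function(x) plogis(-x)
  g <- function(x) {
    sum(fermi((M + wf - x) / kT)) - sum(fermi((-M + wr + x) / kT))
  }
  # g is strictly increasing in x; bracket the root around the
  # work-mean-based initial guess, expanding if needed.
  init <- (mean(wf) - mean(-wr)) / 2
  spread <- sd(c(wf, -wr))
  if (!is.finite(spread)) spread <- 1
  half <- max(1, 2 * spread, abs(init)) + 1
  lo <- init - half; hi <- init + half
  it <- 0
  while (g(lo) > 0 && it < max_iter) { lo <- lo - half; it <- it + 1 }
  while (g(hi) < 0 && it < max_iter) { hi <- hi + half; it <- it + 1 }
  if (g(lo) > 0 || g(hi) < 0) {
    abort(sprintf("BAR failed to bracket a root after %d expansions (last interval [%g, %g])",
                  it, lo, hi))
  }
  root <- uniroot(g, c(lo, hi), tol = min(tol, 1e-10))$root
  if (abs(g(root)) > max(1e-6, tol) * (nf + nr)) {
    abort(sprintf("BAR did not converge: residual %.3g at dG = %.6g", g(root), root))
  }
  # delta-method standard error of the implicit estimator
  fF <- fermi((M + wf - root) / kT)
  fR <- fermi((-M + wr + root) / kT)
  var_g <- nf * stats::var(fF) + nr * stats::var(fR)
  if (!is.finite(var_g)) var_g <- 0
  slope <- (sum(fF * (1 - fF)) + sum(fR * (1 - fR))) / kT
  se <- if (slope > 0) sqrt(var_g) / slope else 0
  if (isTRUE(all(wf == wf[1])) && isTRUE(all(wr == wr[1]))) se <- 0
  if (se > 0 && (mean(fF) < 1e-12 || mean(fR) < 1e-12)) {
    warn("negligible forward/backward overlap; BAR variance estimate may diverge")
  }
  window_result(root, se, "BAR", nf, nr)
}

normalise_work <- function(work) {
  work <- as_tibble(work)
  required <- c("lambda_start", "lambda_end", "delta_u")
  missing <- setdiff(required, names(work))
  if (length(missing)) {
    abort(paste0("work table is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (!"direction" %in% names(work)) {
    work$direction <- ifelse(work$lambda_end >= work$lambda_start,
                             "forward", "backward")
  }
  work
}

#' Free energy of one alchemical leg
#'
#' Sums per-window estimates over every adjacent lambda pair of the
#' schedule; the leg error is the quadrature sum of window errors.  With
#' `estimator = "BAR"` each pair needs forward and backward samples; with
#' `"EXP"` forward samples suffice.
#'
#' @param work A work table: one row per sample with `lambda_start`,
#'   `lambda_end`, `delta_u` (kcal/mol) and optionally `direction`
#'   (`"forward"`/`"backward"`, inferred from the lambda ordering when
#'   absent).
#' @param schedule A [lambda_schedule()].
#' @param estimator `"BAR"` (default) or `"EXP"`.
#' @param temperature Temperature in K.
#' @param kT Optional explicit thermal energy (kcal/mol).
#' @param leg Leg tag, `"bound"` or `"solution"`.
#' @param mutation Mutation label carried into the cycle.
#' @return A list of class `pp_leg`: `leg`, `mutation`, `total` (kcal/mol),
#'   `error`, `estimator`, `windows` (per-pair tibble).
#' @export
leg_free_energy <- function(work, schedule = lambda_schedule(),
                            estimator = c("BAR", "EXP"),
                            temperature = 310, kT = NULL,
                            leg = "bound", mutation = "mutation") {
  estimator <- match.arg(estimator)
  work <- normalise_work(work)
  pairs <- lambda_pairs(schedule)
  eps <- 1e-9
  rows <- vector("list", nrow(pairs))
  gaps <- character()
  for (i in seq_len(nrow(pairs))) {
    l0 <- pairs$lambda_start[i]; l1 <- pairs$lambda_end[i]
    fwd <- work |> filter(abs(.data$lambda_start - l0) < eps,
                          abs(.data$lambda_end - l1) < eps,
                          .data$direction == "forward")
    bwd <- work |> filter(abs(.data$lambda_start - l1) < eps,
                          abs(.data$lambda_end - l0) < eps,
                          .data$direction == "backward")
    if (!nrow(fwd)) {
      gaps <- c(gaps, sprintf("forward %g->%g", l0, l1))
      next
    }
    if (estimator == "BAR" && !nrow(bwd)) {
      gaps <- c(gaps, sprintf("backward %g->%g", l1, l0))
      next
    }
    est <- if (estimator == "BAR") {
      bar_free_energy(fwd$delta_u, bwd$delta_u,
                      temperature = temperature, kT = kT)
    } else {
      exp_free_energy(fwd$delta_u, temperature = temperature, kT = kT)
    }
    rows[[i]] <- mutate(est, lambda_start = l0, lambda_end = l1,
                        .before = 1)
  }
  if (length(gaps)) {
    abort(paste0("work table does not cover the schedule; missing windows: ",
                 paste(gaps, collapse = ", ")))
  }
  # duplicated windows (same pair supplied twice) are a coverage error too
  fwd_counts <- work |>
    filter(.data$direction == "forward") |>
    dplyr::count(.data$lambda_start, .data$lambda_end)
  extra <- dplyr::anti_join(
    fwd_counts |> select("lambda_start", "lambda_end"),
    pairs, by = c("lambda_start", "lambda_end")
  )
  if (nrow(extra)) {
    abort(paste0("work table has windows outside the schedule: ",
                 paste(sprintf("%g->%g", extra$lambda_start, extra$lambda_end),
                       collapse = ", ")))
  }
  windows <- bind_rows(rows)
  structure(
    list(leg = leg, mutation = mutation,
         total = sum(windows$dg),
         error = sqrt(sum(windows$se^2)),
         estimator = estimator, windows = windows),
    class = "pp_leg"
  )
}

#' @export
print.pp_leg <- function(x, ...) {
  cat(sprintf("<pp_leg> %s leg of %s (%s): dG = %.3f +/- %.3f kcal/mol over %d windows\n",
              x$leg, x$mutation, x$estimator, x$total, x$error, nrow(x$windows)))
  invisible(x)
}

#' @export
tidy.pp_leg <- function(x, ...) x$windows

#' @export
glance.pp_leg <- function(x, ...) {
  tibble(leg = x$leg, mutation = x$mutation, dg = x$total, se = x$error,
         estimator = x$estimator, n_windows = nrow(x$windows))
}

#' Thermodynamic-cycle relative binding free energy
#'
#' `ddG = dG_bound - dG_solution` for one mutation, with quadrature error.
#' Positive values mean the mutation weakens membrane binding.
#'
#' @param bound,solution [leg_free_energy()] results for the membrane-bound
#'   and solution legs of the same mutation.
#' @return A list of class `pp_cycle`: `mutation`, `ddg`, `error`,
#'   `bound`, `solution`.
#' @export
ddg_cycle <- function(bound, solution) {
  if (!identical(bound$mutation, solution$mutation)) {
    abort(sprintf("leg mutation labels differ: '%s' vs '%s'",
                  bound$mutation, solution$mutation))
  }
  structure(
    list(mutation = bound$mutation,
         ddg = bound$total - solution$total,
         error = sqrt(bound$error^2 + solution$error^2),
         bound = bound, solution = solution),
    class = "pp_cycle"
  )
}

#' @export
print.pp_cycle <- function(x, ...) {
  cat(sprintf("<pp_cycle> %s: ddG = %.3f +/- %.3f kcal/mol (bound %.3f, solution %.3f)\n",
              x$mutation, x$ddg, x$error, x$bound$total, x$solution$total))
  invisible(x)
}

#' @export
glance.pp_cycle <- function(x, ...) {
  tibble(mutation = x$mutation, dg_bound = x$bound$total,
         dg_solution = x$solution$total, ddg = x$ddg, se = x$error)
}

#' @export
tidy.pp_cycle <- function(x, ...) {
  bind_rows(glance(x$bound), glance(x$solution))
}

# ---------------------------------------------------------------------------
# Harmonic positional restraints: U = k |x - xref|^2 with k in
# kcal/(mol A^2).  The published form carries no 1/2 factor; half_factor
# applies the conventional k/2 instead.

#' Harmonic positional restraint specification
#'
#' @param atoms Selection of restrained atoms (alpha-carbons and membrane
#'   phosphates in the membrane-bound protocol).
#' @param reference `length(atoms) x 3` matrix of reference coordinates,
#'   Angstrom.
#' @param k Force constant, kcal/(mol Angstrom^2); default 1.
#' @param half_factor Apply the conventional 1/2 prefactor (default FALSE:
#'   `U = k |x - xref|^2` as stated).
#' @return A list of class `pp_restraint_spec`.
#' @export
restraint_spec <- function(atoms, reference, k = 1, half_factor = FALSE) {
  reference <- as.matrix(reference)
  if (nrow(reference) != length(atoms) || ncol(reference) != 3) {
    abort("`reference` must be a length(atoms) x 3 matrix")
  }
  assert_scalar_number(k, "k", positive = TRUE)
  structure(list(atoms = as.integer(atoms), reference = reference,
                 k = k, half_factor = isTRUE(half_factor)),
            class = "pp_restraint_spec")
}

#' Restraint energy of one frame
#'
#' @param frame A frame or coordinate matrix.
#' @param spec A [restraint_spec()].
#' @return Total restraint energy, kcal/mol.
#' @export
restraint_energy <- function(frame, spec) {
  coords <- if (is.list(frame)) frame$coords else frame
  if (max(spec$atoms) > nrow(coords)) abort("restrained atoms missing from frame")
  d <- coords[spec$atoms, , drop = FALSE] - spec$reference
  pref <- if (spec$half_factor) spec$k / 2 else spec$k
  pref * sum(d * d)
}

#' Per-frame restraint energy series
#'
#' @param traj A `pp_trajectory`.
#' @param spec A [restraint_spec()].
#' @return A tibble with `frame`, `time`, `energy` (kcal/mol).
#' @export
restraint_energy_series <- function(traj, spec) {
  nf <- n_frames(traj)
  e <- vapply(seq_len(nf), function(f) {
    restraint_energy(frame_coords(traj, f), spec)
  }, numeric(1))
  tibble(frame = seq_len(nf), time = traj$time, energy = e)
}

#' Restraint-consistency audit across lambda windows
#'
#' Summarises a restraint energy series per lambda window (mean and SD), the
#' check that applied restraints stay consistent across the alchemical
#' schedule.
#'
#' @param series A [restraint_energy_series()] tibble.
#' @param lambda Per-frame lambda labels (same length as the series).
#' @return A tibble with `lambda`, `n`, `mean_energy`, `sd_energy`.
#' @export
restraint_audit <- function(series, lambda) {
  if (length(lambda) != nrow(series)) {
    abort("`lambda` must label every frame of the series")
  }
  series |>
    mutate(lambda = lambda) |>
    group_by(.data$lambda) |>
    summarise(n = n(), mean_energy = mean(.data$energy),
              sd_energy = sd(.data$energy), .groups = "drop")
}
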