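# Synthetic ground-truth generators: a slab pseudo-bilayer with the ER lipid
# recipe, scripted rigid-body peripheral-binding trajectories with planted
# contact/depth/tilt behaviour, and Crooks-consistent alchemical work
# samples with known free energies.  Pseudo-lipids are geometric stand-ins
# (one phosphorus-named surface atom plus four tail atoms), sufficient for
# every estimator under test while keeping fixtures tiny.

#' ER membrane lipid recipe
#'
#' Reference composition of the ER model bilayer: counts per 100 lipids and
#' the formal charge per lipid for each species.
#'
#' @return A tibble with `head`, `tail`, `count`, `charge`.
#' @export
er_membrane_composition <- function() {
  tibble(
    head = c("PC", "PC", "PC", "PE", "PE", "PE",
             "PI", "PI", "PS", "SM", "PA", "CHL"),
    tail = c("16:0/18:0", "16:0/18:2", "18:0/20:4", "16:0/18:1",
             "16:0/18:0", "18:0/20:4", "18:0/20:4", "18:0/18:2",
             "18:1/18:2", "18:1/16:0", "16:0/18:1", ""),
    count = c(16L, 18L, 27L, 5L, 8L, 7L, 3L, 3L, 3L, 4L, 1L, 5L),
    charge = c(0L, 0L, 0L, 0L, 0L, 0L, -1L, -1L, -1L, 0L, -1L, 0L)
  )
}

#' Build a slab pseudo-bilayer
#'
#' Places two leaflets of pseudo-lipids on square grids.  Each lipid is one
#' "P"-named surface atom at the phosphate plane plus `n_tail` carbon atoms
#' stepping toward the membrane centre.  Species counts per leaflet are the
#' largest-remainder rounding of `count * scale` over the composition table
#' (ties broken in table order).
#'
#' @param composition A composition tibble (default
#'   [er_membrane_composition()], 100 lipids per leaflet at `scale = 1`).
#' @param scale Positive scale factor on the per-100 counts (1.9 gives the
#'   190-lipid leaflets of the full-size model).
#' @param box Optional box lengths (Angstrom); defaults to the grid extent
#'   in x/y and 120 in z.  Too small a box for the lipid count at the 8
#'   Angstrom grid spacing is an error.
#' @param half_thickness Phosphate-plane height above the centre, Angstrom
#'   (default 16).
#' @param spacing Lipid grid spacing, Angstrom (default 8).
#' @param n_tail Tail atoms per lipid (default 4, at 2 Angstrom steps).
#' @param seed Optional seed shuffling species over grid sites
#'   (deterministic given the seed; without it, species fill in table
#'   order).
#' @return A list `membrane` with `topology`, `frame` (coords, box, time)
#'   and attributes `lipids_per_leaflet` and `net_charge_per_leaflet`.
#' @export
build_membrane_slab <- function(composition = er_membrane_composition(),
                                scale = 1, box = NULL, half_thickness = 16,
                                spacing = 8, n_tail = 4, seed = NULL) {
  assert_scalar_number(scale, "scale", positive = TRUE)
  counts <- largest_remainder(composition$count * scale,
                              round(sum(composition$count) * scale))
  n_lip <- sum(counts)
  if (n_lip < 1) abort("scaled composition rounds to zero lipids")
  nx <- ceiling(sqrt(n_lip))
  ny <- ceiling(n_lip / nx)
  if (is.null(box)) box <- c(nx * spacing, ny * spacing, 120)
  if (box[1] * box[2] < n_lip * spacing^2) {
    abort(sprintf("box %g x %g too small for %d lipids at %g Angstrom spacing",
                  box[1], box[2], n_lip, spacing))
  }
  species <- rep(composition$head, counts)
  if (!is.null(seed)) {
    species <- withr::with_seed(seed, sample(species))
  }
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))[seq_len(n_lip), ]
  x <- (grid$ix - 0.5) * spacing - box[1] / 2
  y <- (grid$iy - 0.5) * spacing - box[2] / 2

  atoms_per_lipid <- 1L + n_tail
  rows <- list(); coords <- list()
  resid <- 0L
  for (leaflet in c(1, -1)) {
    for (i in seq_len(n_lip)) {
      resid <- resid + 1L
      zs <- leaflet * (half_thickness - c(0, seq_len(n_tail) * 2))
      rows[[resid]] <- tibble(
        atom_name = c("P", paste0("C", seq_len(n_tail))),
        residue_id = resid,
        residue_name = species[i],
        chain = "M",
        element = c("P", rep("C", n_tail))
      )
      coords[[resid]] <- cbind(rep(x[i], atoms_per_lipid),
                               rep(y[i], atoms_per_lipid), zs)
    }
  }
  at <- bind_rows(rows)
  top <- topology(at$atom_name, at$residue_id, at$residue_name, at$chain,
                  element = at$element)
  frame <- new_frame(do.call(rbind, coords), box = box, time = 0)
  net_charge <- sum(counts * composition$charge)
  structure(list(topology = top, frame = frame),
            lipids_per_leaflet = n_lip,
            net_charge_per_leaflet = net_charge,
            species_counts = setNames(counts, paste(composition$head,
                                                    composition$tail)),
            class = "pp_membrane")
}

#' Rigid rod-like protein template
#'
#' A multi-residue rigid pseudo-protein whose residues sit along a straight
#' axis: residue 1 is the deep membrane anchor, residue `n_res` the distal
#' anchor.  Each residue has three tightly clustered heavy atoms (CA, CB,
#' CG) plus one hydrogen, so heavy-atom filters are exercised.
#'
#' @param n_res Residues (default 12).
#' @param length_A End-to-end anchor distance, Angstrom (default 30).
#' @param chain Chain id (default "A").
#' @param first_resid Source number of the first residue (default 1).
#' @return A list with `topology` and `local` (atom coordinates with the
#'   anchor-A centre at the origin and the rod along +z).
#' @export
build_protein_template <- function(n_res = 12, length_A = 30, chain = "A",
                                   first_resid = 1) {
  stopifnot(n_res >= 2)
  rise <- length_A / (n_res - 1)
  rows <- list(); coords <- list()
  # heavy-atom offsets sum to zero so the residue centre sits on the axis
  off <- rbind(c(0.3, 0, 0), c(-0.15, 0.26, 0), c(-0.15, -0.26, 0))
  for (r in seq_len(n_res)) {
    z <- (r - 1) * rise
    rows[[r]] <- tibble(
      atom_name = c("CA", "CB", "CG", "HA"),
      residue_id = first_resid + r - 1L,
      residue_name = "ALA",
      chain = chain,
      element = c("C", "C", "C", "H")
    )
    coords[[r]] <- rbind(cbind(off[, 1], off[, 2], off[, 3] + z),
                         c(0, 0.1, z))
  }
  at <- bind_rows(rows)
  list(
    topology = topology(at$atom_name, at$residue_id, at$residue_name,
                        at$chain, element = at$element),
    local = do.call(rbind, coords)
  )
}

#' Scripted binding scenario
#'
#' Describes the rigid-body motion of the synthetic protein: an ordered
#' phase script (`diffuse`, `approach`, `bound`, `dissociated` with frame
#' durations), the planted anchor depth, and the planted tilt distribution
#' of the bound phase.
#'
#' @param phases A data frame with columns `phase` and `n_frames`, or a
#'   named integer vector like `c(approach = 50, bound = 500)`.
#' @param anchor_depth Planted signed depth of the deep anchor (residue 1)
#'   during the bound phase, Angstrom from the membrane centre (default 9).
#' @param tilt_mode Planted most-favoured tilt, degrees (default 42).
#' @param tilt_sd Tilt spread, degrees (default 8).
#' @param noise_sd Per-atom Gaussian positional noise, Angstrom
#'   (default 0.25).
#' @param approach_height Height of the diffuse/dissociated protein above
#'   the upper surface, Angstrom (default 30).
#' @param dt_ns Frame spacing, ns (default 1).
#' @param seed Seed making the trajectory bit-reproducible (default 1).
#' @return A list of class `pp_binding_scenario`.
#' @export
binding_scenario <- function(phases = c(approach = 50, bound = 450),
                             anchor_depth = 9, tilt_mode = 42, tilt_sd = 8,
                             noise_sd = 0.25, approach_height = 30,
                             dt_ns = 1, seed = 1) {
  if (!is.data.frame(phases)) {
    phases <- tibble(phase = names(phases), n_frames = as.integer(phases))
  }
  phases <- as_tibble(phases)
  valid <- c("diffuse", "approach", "bound", "dissociated")
  if (!all(phases$phase %in% valid)) {
    abort(paste0("phases must be one of: ", paste(valid, collapse = ", ")))
  }
  if (any(phases$n_frames < 1)) abort("phase durations must be >= 1 frame")
  if (tilt_mode < 0 || tilt_mode > 180) abort("tilt_mode must be in [0, 180]")
  assert_scalar_number(tilt_sd, "tilt_sd", positive = TRUE)
  structure(
    list(phases = phases, anchor_depth = anchor_depth, tilt_mode = tilt_mode,
         tilt_sd = tilt_sd, noise_sd = noise_sd,
         approach_height = approach_height, dt_ns = dt_ns, seed = seed),
    class = "pp_binding_scenario"
  )
}

# N(mode, sd) wrapped mod 360 and folded onto [0, 180] -- the distribution
# of an axis angle; preserves the planted mode.
sample_wrapped_tilt <- function(n, mode, sd) {
  th <- rnorm(n, mode, sd) %% 360
  ifelse(th > 180, 360 - th, th)
}

rotation_tilt <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  ry <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  rz <- rbind(c(cos(ph), -sin(ph), 0), c(sin(ph), cos(ph), 0), c(0, 0, 1))
  rz %*% ry
}

#' Simulate a scripted peripheral-binding trajectory
#'
#' Moves the rigid protein template over the membrane per the scenario's
#' phase script: `diffuse` (held ~`approach_height` above the surface),
#' `approach` (linear descent), `bound` (anchor residue held at the planted
#' depth, tilt drawn per frame from the planted wrapped-normal
#' distribution), `dissociated` (lift-off).  Gaussian positional noise is
#' added to every atom.  Bit-reproducible under the scenario seed.
#'
#' @param scenario A [binding_scenario()].
#' @param membrane A [build_membrane_slab()] result.
#' @param protein A [build_protein_template()] result.
#' @return A list with `trajectory` (protein atoms first, then membrane)
#'   and `truth` (planted tilt mode/sd, anchor depth, and a phase table
#'   with 1-based `start_frame`/`end_frame`).
#' @export
simulate_binding_trajectory <- function(scenario, membrane,
                                        protein = build_protein_template()) {
  stopifnot(inherits(scenario, "pp_binding_scenario"))
  ptop <- protein$topology
  anchors <- range(ptop$residue_id)
  mtop <- membrane$topology
  mcoords <- membrane$frame$coords
  box <- membrane$frame$box
  surface <- max(mcoords[, 3])
  center_z <- mean(mcoords[mtop$is_heavy, 3])

  combined <- topology(
    atom_name = c(ptop$atom_name, mtop$atom_name),
    residue_id = c(ptop$residue_id, mtop$residue_id),
    residue_name = c(ptop$residue_name, mtop$residue_name),
    chain = c(ptop$chain, mtop$chain),
    element = c(ptop$element, mtop$element)
  )

  phases <- scenario$phases
  nf <- sum(phases$n_frames)
  high_z <- surface + scenario$approach_height
  bound_z <- center_z + scenario$anchor_depth

  frames <- vector("list", nf)
  f <- 0L
  withr::with_seed(scenario$seed, {
    for (p in seq_len(nrow(phases))) {
      ph <- phases$phase[p]
      np <- phases$n_frames[p]
      for (i in seq_len(np)) {
        f <- f + 1L
        bound_like <- ph == "bound"
        theta <- if (bound_like) {
          sample_wrapped_tilt(1, scenario$tilt_mode, scenario$tilt_sd)
        } else {
          runif(1, 0, 180)
        }
        phi <- runif(1, 0, 360)
        rot <- rotation_tilt(theta, phi)
        # the anchor-A centre sits at the local origin, so rotation leaves it
        # in place and a pure translation sets the height
        xyz <- protein$local %*% t(rot)
        # detached phases keep the protein's lowest atom at the scripted
        # height above the surface, whatever its orientation
        lift <- high_z - min(xyz[, 3])
        za <- switch(ph,
          bound = bound_z,
          diffuse = lift + rnorm(1, 0, 1),
          dissociated = lift + rnorm(1, 0, 1),
          approach = lift + (bound_z - lift) * (i - 1) / max(1, np - 1)
        )
        shift <- c(rnorm(1, 0, 0.5), rnorm(1, 0, 0.5), za)
        xyz <- sweep(xyz, 2, shift, "+")
        noise <- matrix(rnorm(length(xyz), 0, scenario$noise_sd), ncol = 3)
        frames[[f]] <- rbind(xyz + noise, mcoords)
      }
    }
  })
  traj <- trajectory(combined, frames, box = box, dt_ns = scenario$dt_ns)
  bounds <- cumsum(phases$n_frames)
  truth <- list(
    tilt_mode = scenario$tilt_mode,
    tilt_sd = scenario$tilt_sd,
    anchor_depth = scenario$anchor_depth,
    anchor_residues = anchors,
    phases = phases |>
      mutate(start_frame = c(1L, head(bounds, -1L) + 1L),
             end_frame = bounds),
    seed = scenario$seed
  )
  list(trajectory = traj, truth = truth)
}

#' Alchemical leg scenario with known free energies
#'
#' @param schedule A [lambda_schedule()].
#' @param dg_per_window Planted per-window free energies, one per adjacent
#'   lambda pair (recycled if scalar).
#' @param sigma Work standard deviation per window, kcal/mol.
#' @param n_per_direction Samples per direction per window (default 500).
#' @param temperature K (default 310).
#' @param seed Seed (default 1).
#' @return A list of class `pp_fep_scenario`.
#' @export
fep_scenario <- function(schedule = lambda_schedule(), dg_per_window = 0.5,
                         sigma = 1.5, n_per_direction = 500,
                         temperature = 310, seed = 1) {
  n_pairs <- length(schedule$values) - 1L
  dg <- rep_len(as.numeric(dg_per_window), n_pairs)
  if (sigma < 0) abort("sigma must be >= 0")
  if (n_per_direction < 1) abort("n_per_direction must be >= 1")
  structure(
    list(schedule = schedule, dg_per_window = dg, sigma = sigma,
         n_per_direction = as.integer(n_per_direction),
         temperature = temperature, seed = seed),
    class = "pp_fep_scenario"
  )
}

#' Simulate Crooks-consistent work samples for one leg
#'
#' For each window with planted free energy `dG_w` and work SD `sigma`,
#' draws forward samples from `N(dG_w + sigma^2/(2 kT), sigma^2)` and
#' backward samples from `N(-dG_w + sigma^2/(2 kT), sigma^2)` -- the
#' Gaussian work pair satisfying the Crooks fluctuation relation with free
#' energy `dG_w`.
#'
#' @param scenario A [fep_scenario()].
#' @return A list with `work` (a work table with both directions for every
#'   adjacent pair) and `true_total` (the planted leg free energy,
#'   kcal/mol).
#' @export
simulate_fep_leg <- function(scenario) {
  stopifnot(inherits(scenario, "pp_fep_scenario"))
  pairs <- lambda_pairs(scenario$schedule)
  kT <- kT_kcal(scenario$temperature)
  shift <- scenario$sigma^2 / (2 * kT)
  n <- scenario$n_per_direction
  out <- withr::with_seed(scenario$seed, {
    purrr::map(seq_len(nrow(pairs)), function(i) {
      dgw <- scenario$dg_per_window[i]
      bind_rows(
        tibble(lambda_start = pairs$lambda_start[i],
               lambda_end = pairs$lambda_end[i],
               direction = "forward",
               delta_u = rnorm(n, dgw + shift, scenario$sigma),
               temperature = scenario$temperature),
        tibble(lambda_start = pairs$lambda_end[i],
               lambda_end = pairs$lambda_start[i],
               direction = "backward",
               delta_u = rnorm(n, -dgw + shift, scenario$sigma),
               temperature = scenario$temperature)
      )
    })
  })
  list(work = bind_rows(out), true_total = sum(scenario$dg_per_window))
}

#' Write synthetic objects as on-disk fixtures
#'
#' Writes a trajectory as PDB (topology + first frame) plus DCD, a work
#' table as both fepout dialect and TSV, and a truth record as TSV.
#' Re-reading through the package readers reproduces values to format
#' precision.
#'
#' @param trajectory Optional `pp_trajectory`.
#' @param work Optional work table.
#' @param truth Optional truth record (a list; flattened scalars are
#'   written).
#' @param dir Output directory (created if missing).
#' @param prefix Filename prefix (default "fixture").
#' @return Named character vector of the files written.
#' @export
write_fixture <- function(trajectory = NULL, work = NULL, truth = NULL,
                          dir = ".", prefix = "fixture") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  if (!is.null(trajectory)) {
    pdb <- file.path(dir, paste0(prefix, ".pdb"))
    dcd <- file.path(dir, paste0(prefix, ".dcd"))
    write_structure(trajectory$topology,
                    list(coords = frame_coords(trajectory, 1),
                         box = trajectory$box[1, ]),
                    pdb)
    write_dcd(trajectory, dcd)
    files <- c(files, topology = pdb, trajectory = dcd)
  }
  if (!is.null(work)) {
    fo <- file.path(dir, paste0(prefix, ".fepout"))
    tsv <- file.path(dir, paste0(prefix, "_work.tsv"))
    write_fepout(work, fo)
    write_work_table(work, tsv)
    files <- c(files, fepout = fo, work_tsv = tsv)
  }
  if (!is.null(truth)) {
    tr <- file.path(dir, paste0(prefix, "_truth.tsv"))
    scalars <- truth[vapply(truth, function(x) is.atomic(x) && length(x) <= 2,
                            logical(1))]
    flat <- tibble(key = names(scalars),
                   value = vapply(scalars, function(x) paste(x, collapse = ","),
                                  character(1)))
    readr::write_tsv(flat, tr, progress = FALSE)
    files <- c(files, truth = tr)
  }
  files
}
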