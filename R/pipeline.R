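# Pipeline stages: validated configs in, TSV outputs plus a manifest out.
# Each stage is a pure function of (inputs, config); deterministic stages
# rerun byte-identically.

config_field <- function(type, default = NULL, required = FALSE) {
  list(type = type, default = default, required = required)
}

check_type <- function(value, type) {
  switch(type,
    number = is.numeric(value) && length(value) == 1 && is.finite(value),
    string = is.character(value) && length(value) == 1,
    strings = is.character(value) && length(value) >= 1,
    numbers = is.numeric(value) && length(value) >= 1,
    logical = is.logical(value) && length(value) == 1,
    list = is.list(value),
    TRUE
  )
}

validate_config <- function(config, schema, stage) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort(sprintf("%s: config must be a list or YAML path", stage))
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    abort(sprintf("%s: unknown config field(s): %s", stage,
                  paste(unknown, collapse = ", ")))
  }
  for (f in names(schema)) {
    sp <- schema[[f]]
    if (is.null(config[[f]])) {
      if (sp$required) abort(sprintf("%s: config field '%s' is required", stage, f))
      config[[f]] <- sp$default
    } else if (!check_type(config[[f]], sp$type)) {
      abort(sprintf("%s: config field '%s' must be of type %s", stage, f, sp$type))
    }
  }
  config
}

write_manifest <- function(out_dir, stage, config, inputs = character()) {
  checksums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    stage = stage,
    package = "peripose",
    version = as.character(utils::packageVersion("peripose")),
    seed = config$seed,
    config = config,
    input_md5 = checksums
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

tsv_out <- function(tbl, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_tsv(tbl, path, progress = FALSE)
  path
}

load_stage_inputs <- function(config) {
  s <- read_structure(config$topology)
  traj <- read_trajectory(s$topology, config$trajectory, dt_ns = config$dt_ns,
                          box = s$frame$box)
  if (isTRUE(config$rewrap_z)) {
    mem <- make_selection(s$topology, config$membrane_selection)
    traj <- rewrap_z(traj, mem)
  }
  traj
}

common_schema <- function() {
  list(
    topology = config_field("string", required = TRUE),
    trajectory = config_field("strings", required = TRUE),
    out_dir = config_field("string", required = TRUE),
    protein_selection = config_field("string", "protein and heavy"),
    membrane_selection = config_field("string", "membrane and heavy"),
    window_fraction = config_field("number", 0.5),
    dt_ns = config_field("number", 1),
    rewrap_z = config_field("logical", FALSE),
    seed = config_field("number", 1)
  )
}

#' Run the contact-analysis stage
#'
#' Computes the per-residue contact series, per-frame totals, the
#' window-mean cumulative profile and the dissociation report, and writes
#' them as TSV with a manifest.
#'
#' @param config A named list or YAML path.  Required: `topology`,
#'   `trajectory` (one or more paths), `out_dir`.  Optional:
#'   `protein_selection`, `membrane_selection`, `window_fraction`,
#'   `steepness`, `midpoint`, `threshold`, `persistence_ns`, `dt_ns`,
#'   `rewrap_z`, `seed`.
#' @return Invisibly, a list with `totals`, `profile`, `dissociation` and
#'   the output paths.
#' @export
run_contacts <- function(config) {
  schema <- c(common_schema(), list(
    steepness = config_field("number", 5),
    midpoint = config_field("number", 4),
    threshold = config_field("number", 0.5),
    persistence_ns = config_field("number", 10)
  ))
  config <- validate_config(config, schema, "contacts")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  traj <- load_stage_inputs(config)
  top <- traj$topology
  protein <- make_selection(top, config$protein_selection)
  membrane <- make_selection(top, config$membrane_selection)
  params <- contact_params(config$steepness, config$midpoint)

  series <- contact_series(traj, protein, membrane, params)
  totals <- total_contact_series(series)
  profile <- cumulative_profile(window_mean_profile(series, config$window_fraction))
  report <- detect_dissociation(totals, config$threshold,
                                persistence_frames(traj, config$persistence_ns))
  paths <- c(
    tsv_out(totals, config$out_dir, "contact_totals.tsv"),
    tsv_out(profile, config$out_dir, "contact_profile.tsv"),
    tsv_out(tibble(
      association_frame = report$association_frame,
      ever_dissociated = report$ever_dissociated,
      events = paste(report$events, collapse = ",")
    ), config$out_dir, "dissociation.tsv")
  )
  write_manifest(config$out_dir, "contacts", config,
                 c(config$topology, config$trajectory))
  invisible(list(totals = totals, profile = profile, dissociation = report,
                 paths = paths))
}

#' Run the depth-analysis stage
#'
#' Per-residue signed insertion depths, per-residue histograms (pooled over
#' replicas), a summary with breach flags, written as TSV.
#'
#' @param config As [run_contacts()] plus `bin_width` (default 0.5),
#'   `min_breach_probability` (default 0.05), `phosphate_selection`
#'   (default `"name P and membrane"`), `absolute` (default FALSE).
#'   Multiple `trajectory` paths are treated as replicas and pooled.
#' @return Invisibly, a list with `summary`, `histogram`, `geometry`, paths.
#' @export
run_depth <- function(config) {
  schema <- c(common_schema(), list(
    bin_width = config_field("number", 0.5),
    min_breach_probability = config_field("number", 0.05),
    phosphate_selection = config_field("string", "name P and membrane"),
    absolute = config_field("logical", FALSE)
  ))
  config <- validate_config(config, schema, "depth")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  s <- read_structure(config$topology)
  top <- s$topology
  protein <- make_selection(top, config$protein_selection)
  membrane <- make_selection(top, config$membrane_selection)
  phosphate <- make_selection(top, config$phosphate_selection)

  all_series <- list(); all_geom <- list()
  for (r in seq_along(config$trajectory)) {
    traj <- read_trajectory(top, config$trajectory[r], dt_ns = config$dt_ns,
                            box = s$frame$box)
    if (isTRUE(config$rewrap_z)) traj <- rewrap_z(traj, membrane)
    ser <- residue_depth_series(traj, protein, membrane)
    geom <- membrane_geometry(traj, membrane, phosphate)
    ser$replica <- r; geom$replica <- r
    all_series[[r]] <- ser; all_geom[[r]] <- geom
  }
  series <- bind_rows(all_series)
  geometry <- bind_rows(all_geom)
  hist <- depth_histogram(series, config$bin_width, config$window_fraction,
                          absolute = config$absolute)
  breach <- breach_residues(hist, geometry, config$min_breach_probability)
  summary <- series |>
    group_by(.data$chain, .data$residue_id, .data$global_index) |>
    summarise(mean_depth = mean(.data$depth),
              min_abs_depth = min(abs(.data$depth)), .groups = "drop") |>
    left_join(breach, by = c("chain", "residue_id", "global_index")) |>
    arrange(.data$global_index)
  paths <- c(
    tsv_out(summary, config$out_dir, "depth_summary.tsv"),
    tsv_out(hist, config$out_dir, "depth_histogram.tsv"),
    tsv_out(geometry, config$out_dir, "membrane_geometry.tsv")
  )
  write_manifest(config$out_dir, "depth", config,
                 c(config$topology, config$trajectory))
  invisible(list(summary = summary, histogram = hist, geometry = geometry,
                 paths = paths))
}

#' Run the tilt/pose stage
#'
#' Pools tilt-angle samples across replica trajectories, Boltzmann-inverts
#' the pooled histogram and reports the most favoured tilt.
#'
#' @param config As [run_contacts()] plus `residue_a`/`residue_b`
#'   (`"chain:resid"` strings, required), `bin_width` (default 2 degrees)
#'   and `kT` (default 1).
#' @return Invisibly, a list with `series`, `profile`, `favored_tilt`,
#'   paths.
#' @export
run_tilt <- function(config) {
  schema <- c(common_schema(), list(
    residue_a = config_field("string", required = TRUE),
    residue_b = config_field("string", required = TRUE),
    bin_width = config_field("number", 2),
    kT = config_field("number", 1)
  ))
  config <- validate_config(config, schema, "tilt")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  parse_res <- function(x) {
    parts <- strsplit(x, ":")[[1]]
    if (length(parts) != 2) abort("residues must be 'chain:resid' strings")
    c(parts[1], parts[2])
  }
  spec <- tilt_spec(parse_res(config$residue_a), parse_res(config$residue_b))
  s <- read_structure(config$topology)
  all_series <- list()
  for (r in seq_along(config$trajectory)) {
    traj <- read_trajectory(s$topology, config$trajectory[r],
                            dt_ns = config$dt_ns, box = s$frame$box)
    ser <- tilt_series(traj, spec, config$window_fraction)
    ser$replica <- r
    all_series[[r]] <- ser
  }
  series <- bind_rows(all_series)
  profile <- pose_free_energy(series, config$bin_width, config$kT)
  favored <- most_favored_tilt(profile)
  paths <- c(
    tsv_out(series, config$out_dir, "tilt_series.tsv"),
    tsv_out(profile, config$out_dir, "pose_profile.tsv"),
    tsv_out(tibble(favored_tilt_deg = favored), config$out_dir,
            "favored_tilt.tsv")
  )
  write_manifest(config$out_dir, "tilt", config,
                 c(config$topology, config$trajectory))
  invisible(list(series = series, profile = profile, favored_tilt = favored,
                 paths = paths))
}

#' Run the FEP-cycle stage
#'
#' For each mutation, reads bound- and solution-leg work files (fepout or
#' TSV, by extension), estimates per-window and leg free energies and the
#' cycle ddG, and writes per-window and per-cycle tables.
#'
#' @param config A named list or YAML path with `out_dir`, `mutations` (a
#'   list of lists with `label`, `bound`, `solution` file paths), and
#'   optionally `estimator` ("BAR"/"EXP"), `temperature` (default 310),
#'   `lambda` (schedule values), `ns_per_window` (default 3), `seed`.
#' @return Invisibly, a list with `cycles` (tibble mirroring the mutation
#'   table: mutation, dg_bound, dg_solution, ddg, se), `windows`, paths.
#' @export
run_fep <- function(config) {
  schema <- list(
    out_dir = config_field("string", required = TRUE),
    mutations = config_field("list", required = TRUE),
    estimator = config_field("string", "BAR"),
    temperature = config_field("number", 310),
    lambda = config_field("numbers", DEFAULT_LAMBDA),
    ns_per_window = config_field("number", 3),
    seed = config_field("number", 1)
  )
  config <- validate_config(config, schema, "fep")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- lambda_schedule(config$lambda, config$ns_per_window)
  read_work <- function(paths) {
    bind_rows(lapply(paths, function(p) {
      if (grepl("\\.fepout$", p)) parse_fepout(p) else read_work_table(p)
    }))
  }
  cycles <- list(); windows <- list(); inputs <- character()
  for (m in config$mutations) {
    if (is.null(m$label) || is.null(m$bound) || is.null(m$solution)) {
      abort("each mutation needs 'label', 'bound' and 'solution' entries")
    }
    inputs <- c(inputs, unlist(m$bound), unlist(m$solution))
    bound <- leg_free_energy(read_work(unlist(m$bound)), schedule,
                             estimator = config$estimator,
                             temperature = config$temperature,
                             leg = "bound", mutation = m$label)
    solution <- leg_free_energy(read_work(unlist(m$solution)), schedule,
                                estimator = config$estimator,
                                temperature = config$temperature,
                                leg = "solution", mutation = m$label)
    cyc <- ddg_cycle(bound, solution)
    cycles[[m$label]] <- glance(cyc)
    windows[[m$label]] <- bind_rows(
      tidy(bound) |> mutate(mutation = m$label, leg = "bound"),
      tidy(solution) |> mutate(mutation = m$label, leg = "solution")
    )
  }
  cycles <- bind_rows(cycles)
  windows <- bind_rows(windows)
  paths <- c(
    tsv_out(windows, config$out_dir, "fep_windows.tsv"),
    tsv_out(cycles, config$out_dir, "fep_cycles.tsv")
  )
  write_manifest(config$out_dir, "fep", config, inputs)
  invisible(list(cycles = cycles, windows = windows, paths = paths))
}

#' Run the synthetic-data stage
#'
#' Builds the slab membrane and scripted binding replicas, writes PDB/DCD
#' fixtures with their ground-truth records, and simulates a
#' Crooks-consistent FEP leg pair.
#'
#' @param config A named list or YAML path with `out_dir` and optionally
#'   `seed`, `scale` (membrane scale, default 0.5), `n_res`,
#'   `replicas` (a list of scenario field lists overriding
#'   [binding_scenario()] defaults; one fixture per entry).
#' @return Invisibly, a list of written files per replica.
#' @export
run_simulate <- function(config) {
  schema <- list(
    out_dir = config_field("string", required = TRUE),
    seed = config_field("number", 1),
    scale = config_field("number", 0.5),
    n_res = config_field("number", 12),
    replicas = config_field("list", list(list()))
  )
  config <- validate_config(config, schema, "simulate")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  membrane <- build_membrane_slab(scale = config$scale)
  protein <- build_protein_template(n_res = config$n_res)
  out <- list()
  for (r in seq_along(config$replicas)) {
    over <- config$replicas[[r]]
    if (!is.null(over$phases) && is.list(over$phases)) {
      over$phases <- unlist(over$phases)
    }
    args <- utils::modifyList(list(seed = config$seed + r - 1), over)
    scen <- do.call(binding_scenario, args)
    sim <- simulate_binding_trajectory(scen, membrane, protein)
    files <- write_fixture(trajectory = sim$trajectory, truth = sim$truth,
                           dir = config$out_dir,
                           prefix = sprintf("replica%02d", r))
    out[[r]] <- files
  }
  write_manifest(config$out_dir, "simulate", config)
  invisible(out)
}
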