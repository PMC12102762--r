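# Membrane geometry and per-residue insertion depths.
#
# Depth of a residue in a frame: the signed z-distance between the geometric
# centre of the membrane and the residue heavy atom nearest (along z) to that
# centre.  Negative depths are below the centre; the membrane normal is z.

#' Geometric centre of the membrane along z
#'
#' @param frame A frame (list with `coords`) or `n x 3` matrix.
#' @param membrane Heavy-atom membrane selection.
#' @return Mean z of the membrane atoms, Angstrom.
#' @export
membrane_center_z <- function(frame, membrane) {
  if (!length(membrane)) abort("membrane selection is empty")
  coords <- if (is.list(frame)) frame$coords else frame
  mean(coords[membrane, 3])
}

#' Leaflet surface planes from phosphate positions
#'
#' Operationalises the membrane surface as the mean phosphorus z per leaflet
#' (atoms above vs. below the membrane centre).
#'
#' @param frame A frame or coordinate matrix.
#' @param topology The topology the selection indexes into.
#' @param phosphate Selection of phosphate atoms (names must begin with "P").
#' @param center_z Membrane centre from [membrane_center_z()].
#' @return Named numeric vector `c(upper = ..., lower = ...)`, Angstrom.
#' @export
leaflet_surfaces <- function(frame, topology, phosphate, center_z) {
  if (!length(phosphate)) abort("phosphate selection is empty")
  bad <- !grepl("^P", toupper(topology$atom_name[phosphate]))
  if (any(bad)) {
    abort("phosphate selection contains non-phosphate atoms (name filter)")
  }
  coords <- if (is.list(frame)) frame$coords else frame
  z <- coords[phosphate, 3]
  up <- z > center_z
  if (!any(up) || all(up)) {
    abort("phosphate selection must have atoms on both sides of the membrane centre")
  }
  c(upper = mean(z[up]), lower = mean(z[!up]))
}

#' Per-frame membrane geometry
#'
#' @param traj A `pp_trajectory`.
#' @param membrane Heavy-atom membrane selection.
#' @param phosphate Phosphate selection (see [leaflet_surfaces()]).
#' @return A tibble with `frame`, `time`, `center_z`, `upper_surface_z`,
#'   `lower_surface_z`.
#' @export
membrane_geometry <- function(traj, membrane, phosphate) {
  nf <- n_frames(traj)
  out <- tibble(frame = seq_len(nf), time = traj$time,
                center_z = NA_real_, upper_surface_z = NA_real_,
                lower_surface_z = NA_real_)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    cz <- membrane_center_z(xyz, membrane)
    s <- leaflet_surfaces(xyz, traj$topology, phosphate, cz)
    out$center_z[f] <- cz
    out$upper_surface_z[f] <- s[["upper"]]
    out$lower_surface_z[f] <- s[["lower"]]
  }
  out
}

#' Signed per-residue insertion depth series
#'
#' For every protein residue and frame, reports `z - center_z` of the residue
#' heavy atom minimising `|z - center_z|` (z minimum image applied).
#'
#' @param traj A `pp_trajectory`.
#' @param protein Heavy-atom protein selection.
#' @param membrane Heavy-atom membrane selection (defines the centre).
#' @param index_map Optional [residue_index_map()].
#' @return A tibble of class `pp_depth_series`: `frame`, `time`, `chain`,
#'   `residue_id`, `global_index`, `depth` (Angstrom, signed).
#' @export
residue_depth_series <- function(traj, protein, membrane, index_map = NULL) {
  top <- traj$topology
  if (any(!top$is_heavy[protein])) {
    abort("protein selection must contain heavy atoms only")
  }
  if (is.null(index_map)) index_map <- residue_index_map(top)
  key <- paste(top$chain[protein], top$residue_id[protein])
  res_tbl <- tibble(chain = top$chain[protein],
                    residue_id = top$residue_id[protein]) |>
    distinct() |>
    left_join(index_map, by = c("chain", "residue_id")) |>
    arrange(.data$global_index)
  group <- match(key, paste(res_tbl$chain, res_tbl$residue_id))

  nf <- n_frames(traj)
  nres <- nrow(res_tbl)
  vals <- matrix(NA_real_, nrow = nres, ncol = nf)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)
    cz <- membrane_center_z(xyz, membrane)
    dz <- min_image(xyz[protein, 3] - cz, traj$box[f, 3])
    # per residue: signed dz of the atom with minimal |dz|
    for (r in seq_len(nres)) {
      dzr <- dz[group == r]
      vals[r, f] <- dzr[which.min(abs(dzr))]
    }
  }
  out <- tibble(
    frame = rep(seq_len(nf), each = nres),
    time = rep(traj$time, each = nres),
    chain = rep(res_tbl$chain, nf),
    residue_id = rep(res_tbl$residue_id, nf),
    global_index = rep(res_tbl$global_index, nf),
    depth = as.numeric(vals)
  )
  class(out) <- c("pp_depth_series", class(out))
  out
}

#' Per-residue depth histograms over the trailing window
#'
#' @param series A [residue_depth_series()] tibble.
#' @param bin_width Bin width in Angstrom (default 0.5).
#' @param window_fraction Trailing fraction of frames (default 0.5).
#' @param absolute Histogram `|depth|` instead of signed depth.
#' @return A tibble of class `pp_depth_histogram`: `chain`, `residue_id`,
#'   `global_index`, `bin_left`, `bin_right`, `probability`; probabilities
#'   sum to 1 per residue.
#' @export
depth_histogram <- function(series, bin_width = 0.5, window_fraction = 0.5,
                            absolute = FALSE) {
  assert_scalar_number(bin_width, "bin_width", positive = TRUE)
  keep <- trailing_window_frames(unique(series$frame), window_fraction)
  win <- series |> filter(.data$frame %in% keep)
  if (!nrow(win)) abort("analysis window is empty")
  d <- if (absolute) abs(win$depth) else win$depth
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  win$bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  out <- win |>
    group_by(.data$chain, .data$residue_id, .data$global_index, .data$bin) |>
    summarise(count = n(), .groups = "drop_last") |>
    mutate(probability = .data$count / sum(.data$count)) |>
    ungroup() |>
    mutate(bin_left = breaks[.data$bin],
           bin_right = breaks[.data$bin] + bin_width) |>
    select("chain", "residue_id", "global_index",
           "bin_left", "bin_right", "probability") |>
    arrange(.data$global_index, .data$bin_left)
  class(out) <- c("pp_depth_histogram", class(out))
  out
}

#' Residues found beneath the membrane surface
#'
#' Flags residues whose depth distribution places more than `min_probability`
#' of its mass inside the surface planes (`|depth| <` the mean upper-surface
#' height), i.e. residues that breach the membrane surface.
#'
#' @param hist A [depth_histogram()] tibble (signed or absolute).
#' @param geometry A [membrane_geometry()] tibble for the same window (its
#'   surfaces are averaged), or a single numeric surface height.
#' @param min_probability Minimum breach probability (default 0.05).
#' @return A tibble with one row per residue: `chain`, `residue_id`,
#'   `global_index`, `breach_probability`, `breach`.
#' @export
breach_residues <- function(hist, geometry, min_probability = 0.05) {
  surface <- if (is.numeric(geometry) && length(geometry) == 1L) {
    abs(geometry)
  } else {
    mean(abs(c(geometry$upper_surface_z, geometry$lower_surface_z)))
  }
  hist |>
    mutate(mid = (.data$bin_left + .data$bin_right) / 2) |>
    group_by(.data$chain, .data$residue_id, .data$global_index) |>
    summarise(
      breach_probability = sum(.data$probability[abs(.data$mid) < surface]),
      .groups = "drop"
    ) |>
    mutate(breach = .data$breach_probability > min_probability) |>
    arrange(.data$global_index)
}
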