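# Tilt-angle pose analysis: the angle between the vector joining two anchor
# residues and the membrane normal (+z), and its Boltzmann inversion
# dG = -kT ln(P1/P2) into a pose free-energy profile in kT units, where P1
# counts frames inside a tilt bin and P2 frames outside it.

#' Specify the tilt-angle vector
#'
#' @param residue_a,residue_b Anchor residues as `c(chain, residue_id)`
#'   (e.g. `c("A", 15)`); must be distinct.
#' @param center_rule `"heavy"` (geometric centre of heavy atoms, default) or
#'   `"CA"` (alpha-carbon only).
#' @return A list of class `pp_tilt_spec`.
#' @export
tilt_spec <- function(residue_a, residue_b, center_rule = c("heavy", "CA")) {
  center_rule <- match.arg(center_rule)
  ra <- list(chain = as.character(residue_a[1]), residue_id = as.integer(residue_a[2]))
  rb <- list(chain = as.character(residue_b[1]), residue_id = as.integer(residue_b[2]))
  if (identical(ra, rb)) abort("tilt residues must be distinct")
  structure(list(residue_a = ra, residue_b = rb, center_rule = center_rule),
            class = "pp_tilt_spec")
}

residue_center <- function(coords, topology, chain, residue_id, center_rule) {
  sel <- topology$chain == chain & topology$residue_id == residue_id &
    topology$is_heavy
  if (center_rule == "CA") {
    sel <- sel & toupper(topology$atom_name) == "CA"
  }
  if (!any(sel)) {
    abort(sprintf("residue %s:%d has no atoms for centre rule '%s'",
                  chain, residue_id, center_rule))
  }
  colMeans(coords[sel, , drop = FALSE])
}

#' Tilt angle of one frame
#'
#' Angle between the vector from residue A's centre to residue B's centre
#' and the +z axis, in degrees on `[0, 180]`.
#'
#' @param frame A frame or coordinate matrix.
#' @param topology The matching [topology()].
#' @param spec A [tilt_spec()].
#' @return Angle in degrees.
#' @export
tilt_angle <- function(frame, topology, spec) {
  coords <- if (is.list(frame)) frame$coords else frame
  ca <- residue_center(coords, topology, spec$residue_a$chain,
                       spec$residue_a$residue_id, spec$center_rule)
  cb <- residue_center(coords, topology, spec$residue_b$chain,
                       spec$residue_b$residue_id, spec$center_rule)
  v <- cb - ca
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) abort("tilt residue centres coincide")
  acos(pmin(1, pmax(-1, v[3] / nv))) * 180 / pi
}

#' Tilt-angle time series over the trailing window
#'
#' @param traj A `pp_trajectory`.
#' @param spec A [tilt_spec()].
#' @param window_fraction Trailing fraction of frames (default 0.5, the last
#'   half of the run).
#' @return A tibble of class `pp_tilt_series` with `frame`, `time`,
#'   `angle_deg`.
#' @export
tilt_series <- function(traj, spec, window_fraction = 0.5) {
  keep <- trailing_window_frames(seq_len(n_frames(traj)), window_fraction)
  ang <- vapply(keep, function(f) {
    tilt_angle(frame_coords(traj, f), traj$topology, spec)
  }, numeric(1))
  out <- tibble(frame = keep, time = traj$time[keep], angle_deg = ang)
  class(out) <- c("pp_tilt_series", class(out))
  out
}

#' Boltzmann-inverted pose free-energy profile
#'
#' Bins the tilt angles on `[0, 180]` and converts occupancies to free
#' energies with `dG = -kT ln(P1 / P2)`, `P1` the frames inside a bin and
#' `P2` the frames outside it.  Empty bins get `+Inf`; a bin holding every
#' frame gets `-Inf`.
#'
#' @param series A [tilt_series()] tibble, or a numeric vector of angles in
#'   degrees.
#' @param bin_width Bin width in degrees (default 2).
#' @param kT Thermal energy unit (default 1: free energies are reported in
#'   kT units).
#' @return A tibble of class `pp_pose_profile` with `bin_left`, `bin_right`,
#'   `bin_mid`, `p1`, `p2`, `dg`; attributes `kT`, `n_frames`, `bin_width`.
#' @export
pose_free_energy <- function(series, bin_width = 2, kT = 1) {
  assert_scalar_number(bin_width, "bin_width", positive = TRUE)
  assert_scalar_number(kT, "kT", positive = TRUE)
  ang <- if (is.data.frame(series)) series$angle_deg else as.numeric(series)
  if (length(ang) < 2) abort("at least 2 frames are required")
  if (any(ang < 0 | ang > 180)) abort("angles must lie in [0, 180] degrees")
  breaks <- seq(0, 180 + bin_width, by = bin_width)
  bin <- findInterval(pmin(ang, 180 - 1e-12), breaks)
  nb <- length(breaks) - 1L
  p1 <- tabulate(bin, nbins = nb)
  total <- length(ang)
  p2 <- total - p1
  dg <- -kT * log(p1 / p2)  # 0/n -> Inf, n/0 -> -Inf as specified
  out <- tibble(
    bin_left = breaks[seq_len(nb)],
    bin_right = breaks[seq_len(nb) + 1L],
    bin_mid = breaks[seq_len(nb)] + bin_width / 2,
    p1 = as.integer(p1),
    p2 = as.integer(p2),
    dg = dg
  ) |> filter(.data$bin_left < 180)
  attr(out, "kT") <- kT
  attr(out, "n_frames") <- total
  attr(out, "bin_width") <- bin_width
  class(out) <- c("pp_pose_profile", class(out))
  out
}

#' Most favoured tilt angle
#'
#' Midpoint of the bin with minimal free energy (equivalently maximal
#' occupancy); ties break toward the smaller angle.  Infinite bins are
#' excluded.
#'
#' @param profile A [pose_free_energy()] tibble.
#' @return Angle in degrees.
#' @export
most_favored_tilt <- function(profile) {
  finite <- profile |> filter(is.finite(.data$dg) | .data$dg == -Inf)
  finite <- finite |> filter(.data$p1 > 0)
  if (!nrow(finite)) abort("no occupied tilt bins")
  finite <- finite |> arrange(.data$dg, .data$bin_mid)
  finite$bin_mid[1]
}
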