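# Logistic-weighted protein-membrane contact statistic.
#
# A heavy-atom pair at distance d contributes 1 / (1 + exp(s (d - d0))) of a
# contact, with steepness s = 5 per Angstrom and midpoint d0 = 4 Angstrom, so
# counts are fractional near the cutoff instead of jumping at a hard
# threshold.  Per-residue counts sum the kernel over all heavy-atom pairs
# between the residue and the membrane.

#' Contact kernel parameters
#'
#' @param steepness Logistic steepness in 1/Angstrom (default 5).
#' @param midpoint Distance at which a pair counts as half a contact,
#'   Angstrom (default 4).
#' @return A list of class `pp_contact_params`.
#' @export
contact_params <- function(steepness = 5, midpoint = 4) {
  assert_scalar_number(steepness, "steepness", positive = TRUE)
  assert_scalar_number(midpoint, "midpoint", positive = TRUE)
  structure(list(steepness = steepness, midpoint = midpoint),
            class = "pp_contact_params")
}

#' Logistic contact weight of one heavy-atom pair
#'
#' `1 / (1 + exp(steepness * (d - midpoint)))`: 0.5 at the midpoint, tending
#' to 1 at contact and 0 at long range.
#'
#' @param d Distance(s) in Angstrom, finite and non-negative.
#' @param params A [contact_params()] object.
#' @return Weight(s) strictly in (0, 1).
#' @export
contact_weight <- function(d, params = contact_params()) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0)) {
    abort("`d` must be finite and >= 0")
  }
  plogis(-params$steepness * (d - params$midpoint))
}

# Pairwise weight sum between two coordinate blocks, with z minimum image.
pair_contact_sum_by_group <- function(xyz_a, group_a, xyz_b, box_z, params) {
  dx <- outer(xyz_a[, 1], xyz_b[, 1], "-")
  dy <- outer(xyz_a[, 2], xyz_b[, 2], "-")
  dz <- min_image(outer(xyz_a[, 3], xyz_b[, 3], "-"), box_z)
  w <- plogis(-params$steepness *
                (sqrt(dx * dx + dy * dy + dz * dz) - params$midpoint))
  per_atom <- rowSums(w)
  as.numeric(rowsum(per_atom, group_a, reorder = FALSE))
}

check_contact_selections <- function(topology, residue_atoms, membrane_atoms) {
  if (any(!topology$is_heavy[residue_atoms]) ||
      any(!topology$is_heavy[membrane_atoms])) {
    abort("contact selections must contain heavy atoms only")
  }
  if (length(intersect(residue_atoms, membrane_atoms))) {
    abort("residue and membrane selections overlap")
  }
}

#' Weighted contact count of one residue in one frame
#'
#' Sums [contact_weight()] over every (residue heavy atom, membrane heavy
#' atom) pair.  Distances use the minimum image along z (membranes are
#' z-normal by convention).
#'
#' @param frame A frame (list with `coords`, `box`) or `n x 3` matrix.
#' @param topology The [topology()] the selections index into.
#' @param residue_atoms,membrane_atoms Heavy-atom selections
#'   ([make_selection()]); must be disjoint.
#' @param params A [contact_params()] object.
#' @return The dimensionless contact count `C_i >= 0`.
#' @export
residue_contacts <- function(frame, topology, residue_atoms, membrane_atoms,
                             params = contact_params()) {
  check_contact_selections(topology, residue_atoms, membrane_atoms)
  if (!length(membrane_atoms)) {
    warn("membrane selection is empty; contact count is 0")
    return(0)
  }
  coords <- if (is.list(frame)) frame$coords else frame
  box_z <- if (is.list(frame)) frame$box[3] else NA_real_
  sum(pair_contact_sum_by_group(
    coords[residue_atoms, , drop = FALSE],
    rep(1L, length(residue_atoms)),
    coords[membrane_atoms, , drop = FALSE],
    box_z, params
  ))
}

#' Per-residue, per-frame weighted contact series
#'
#' Computes the contact count of every protein residue against the membrane
#' in every frame.
#'
#' @param traj A `pp_trajectory`.
#' @param protein,membrane Heavy-atom selections ([make_selection()]).
#' @param params A [contact_params()] object.
#' @param index_map Optional [residue_index_map()]; computed from the
#'   topology when omitted.
#' @return A tibble of class `pp_contact_series` with columns `frame`, `time`,
#'   `chain`, `residue_id`, `global_index`, `contact`, ordered by frame then
#'   global index.
#' @export
contact_series <- function(traj, protein, membrane,
                           params = contact_params(), index_map = NULL) {
  top <- traj$topology
  check_contact_selections(top, protein, membrane)
  if (is.null(index_map)) index_map <- residue_index_map(top)
  key <- paste(top$chain[protein], top$residue_id[protein])
  res_tbl <- tibble(chain = top$chain[protein],
                    residue_id = top$residue_id[protein]) |>
    distinct() |>
    left_join(index_map, by = c("chain", "residue_id")) |>
    arrange(.data$global_index)
  group <- match(key, paste(res_tbl$chain, res_tbl$residue_id))
  # reorder protein atoms so rowsum groups appear in global-index order
  ord <- order(group)
  protein <- protein[ord]
  group <- group[ord]

  nf <- n_frames(traj)
  nres <- nrow(res_tbl)
  vals <- matrix(NA_real_, nrow = nres, ncol = nf)
  empty_membrane <- !length(membrane)
  if (empty_membrane) warn("membrane selection is empty; all contacts are 0")
  for (f in seq_len(nf)) {
    if (empty_membrane) {
      vals[, f] <- 0
      next
    }
    xyz <- frame_coords(traj, f)
    vals[, f] <- pair_contact_sum_by_group(
      xyz[protein, , drop = FALSE], group,
      xyz[membrane, , drop = FALSE],
      traj$box[f, 3], params
    )
  }
  out <- tibble(
    frame = rep(seq_len(nf), each = nres),
    time = rep(traj$time, each = nres),
    chain = rep(res_tbl$chain, nf),
    residue_id = rep(res_tbl$residue_id, nf),
    global_index = rep(res_tbl$global_index, nf),
    contact = as.numeric(vals)
  )
  class(out) <- c("pp_contact_series", class(out))
  out
}

#' Per-frame total protein-membrane contacts
#'
#' @param series A [contact_series()] tibble.
#' @return A tibble with `frame`, `time`, `total`.
#' @export
total_contact_series <- function(series) {
  series |>
    group_by(.data$frame, .data$time) |>
    summarise(total = sum(.data$contact), .groups = "drop") |>
    arrange(.data$frame)
}

# frames belonging to the trailing analysis window
trailing_window_frames <- function(frames, window_fraction) {
  assert_scalar_number(window_fraction, "window_fraction", positive = TRUE)
  if (window_fraction > 1) abort("`window_fraction` must be in (0, 1]")
  nf <- length(frames)
  n_keep <- max(1L, ceiling(window_fraction * nf))
  sort(frames)[(nf - n_keep + 1L):nf]
}

#' Window-averaged per-residue contact profile
#'
#' Arithmetic mean of each residue's contact count over the trailing window
#' of the trajectory (default: the last half, mirroring an analysis of the
#' final 500 ns of a 1 microsecond run).
#'
#' @param series A [contact_series()] tibble.
#' @param window_fraction Trailing fraction of frames in (0, 1].
#' @return A tibble of class `pp_contact_profile` with `chain`, `residue_id`,
#'   `global_index`, `mean_contact`; window times are stored in attributes
#'   `window_start`/`window_end`.
#' @export
window_mean_profile <- function(series, window_fraction = 0.5) {
  keep <- trailing_window_frames(unique(series$frame), window_fraction)
  if (!length(keep)) abort("analysis window is empty")
  win <- series |> filter(.data$frame %in% keep)
  prof <- win |>
    group_by(.data$chain, .data$residue_id, .data$global_index) |>
    summarise(mean_contact = mean(.data$contact), .groups = "drop") |>
    arrange(.data$global_index)
  attr(prof, "window_start") <- min(win$time)
  attr(prof, "window_end") <- max(win$time)
  class(prof) <- c("pp_contact_profile", class(prof))
  prof
}

#' Cumulative contact profile across the residue axis
#'
#' Running sum of the window-mean profile in global-index order, the
#' "cumulative contacts" presentation of per-residue binding footprints.
#'
#' @param profile A [window_mean_profile()] tibble.
#' @return The profile with an added monotone `cumulative` column.
#' @export
cumulative_profile <- function(profile) {
  profile |>
    arrange(.data$global_index) |>
    mutate(cumulative = cumsum(.data$mean_contact))
}

#' Detect association and dissociation events from total contacts
#'
#' The protein counts as associated from the first frame where the total
#' contact count holds at or above `threshold` for `min_persistence`
#' consecutive frames; a dissociation event is the first subsequent frame
#' where it holds below the threshold equally persistently.  Re-association
#' and repeated events are allowed.
#'
#' @param totals A [total_contact_series()] tibble, or a numeric vector of
#'   per-frame totals.
#' @param threshold Contact threshold (> 0, default 0.5 contacts).
#' @param min_persistence Frames a state must persist (default 1).
#' @return A list of class `pp_dissociation`: `association_frame` (1-based,
#'   `NA` if never associated), `events` (1-based dissociation frames) and
#'   `ever_dissociated`.
#' @export
detect_dissociation <- function(totals, threshold = 0.5, min_persistence = 1L) {
  assert_scalar_number(threshold, "threshold", positive = TRUE)
  if (min_persistence < 1) abort("`min_persistence` must be >= 1")
  x <- if (is.data.frame(totals)) totals$total else as.numeric(totals)
  above <- x >= threshold
  r <- rle(above)
  starts <- cumsum(c(1L, head(r$lengths, -1L)))
  association <- NA_integer_
  events <- integer()
  bound <- FALSE
  for (k in seq_along(r$lengths)) {
    if (r$lengths[k] < min_persistence) next
    if (r$values[k] && !bound) {
      bound <- TRUE
      if (is.na(association)) association <- starts[k]
    } else if (!r$values[k] && bound) {
      bound <- FALSE
      events <- c(events, starts[k])
    }
  }
  structure(
    list(association_frame = association, events = events,
         ever_dissociated = length(events) > 0),
    class = "pp_dissociation"
  )
}

#' @export
print.pp_dissociation <- function(x, ...) {
  if (is.na(x$association_frame)) {
    cat("<pp_dissociation> never associated\n")
  } else {
    cat(sprintf("<pp_dissociation> associated at frame %d; %d dissociation event(s)%s\n",
                x$association_frame, length(x$events),
                if (length(x$events)) paste0(" at ", paste(x$events, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Frames spanning a persistence time
#'
#' Converts a persistence requirement in ns into frames, given the
#' trajectory's frame spacing.  Used for the default dissociation
#' persistence of 10 ns.
#'
#' @param traj A `pp_trajectory`.
#' @param ns Persistence time in ns.
#' @return At least 1 frame.
#' @export
persistence_frames <- function(traj, ns = 10) {
  dt <- if (n_frames(traj) > 1) mean(diff(traj$time)) else ns
  max(1L, as.integer(round(ns / dt)))
}
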