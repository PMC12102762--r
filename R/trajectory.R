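# Trajectory container and DCD I/O.  Coordinates are Angstrom, times ns.

new_trajectory <- function(topology, coords, box, time) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(topology)) {
    abort(sprintf("coordinate array has %d atoms but topology has %d",
                  dim(coords)[1], nrow(topology)))
  }
  if (any(diff(time) <= 0)) abort("frame times must be strictly increasing")
  structure(
    list(topology = topology, coords = coords,
         box = box, time = as.numeric(time)),
    class = "pp_trajectory"
  )
}

#' Assemble a trajectory from in-memory frames
#'
#' @param topology A [topology()] tibble.
#' @param frames List of `n_atom x 3` coordinate matrices (Angstrom).
#' @param box Either a length-3 vector (constant box) or an
#'   `n_frame x 3` matrix of box lengths.
#' @param dt_ns Time between frames in ns (frame times are
#'   `0, dt_ns, 2 dt_ns, ...`), ignored when `time` is given.
#' @param time Optional explicit frame times (ns), strictly increasing.
#' @return A `pp_trajectory` object.
#' @export
trajectory <- function(topology, frames, box = c(NA, NA, NA), dt_ns = 1,
                       time = NULL) {
  nf <- length(frames)
  stopifnot(nf >= 1)
  coords <- array(NA_real_, dim = c(nrow(frames[[1]]), 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- as.matrix(frames[[f]])
  if (is.null(dim(box))) box <- matrix(rep(as.numeric(box), nf), ncol = 3, byrow = TRUE)
  if (is.null(time)) time <- (seq_len(nf) - 1) * dt_ns
  new_trajectory(topology, coords, box, time)
}

#' @export
print.pp_trajectory <- function(x, ...) {
  cat(sprintf("<pp_trajectory> %d atoms x %d frames (%.3g-%.3g ns)\n",
              dim(x$coords)[1], n_frames(x), min(x$time), max(x$time)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `pp_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

# n_atom x 3 coordinates of frame f
frame_coords <- function(traj, f) traj$coords[, , f, drop = TRUE]

#' Read coordinate files into a trajectory
#'
#' Reads one or more CHARMM/NAMD DCD files (or single-frame PDB files) and
#' concatenates their frames in the given order.  Frame times are assigned as
#' a uniform stride (`dt_ns`) across the concatenated frames unless the first
#' frame times are supplied explicitly.
#'
#' @param topology A [topology()] tibble the frames must match.
#' @param paths Character vector of DCD (or PDB) paths, concatenated in order.
#' @param dt_ns Uniform frame spacing in ns.
#' @param box Fallback box lengths when the files carry no unit cell.
#' @return A `pp_trajectory`.
#' @export
read_trajectory <- function(topology, paths, dt_ns = 1, box = c(NA, NA, NA)) {
  frames <- list()
  boxes <- list()
  for (p in paths) {
    if (!file.exists(p)) abort(sprintf("trajectory file '%s' does not exist", p))
    if (grepl("\\.pdb$", p, ignore.case = TRUE)) {
      s <- read_structure(p)
      if (nrow(s$topology) != nrow(topology)) {
        abort(sprintf("atom-count mismatch: '%s' has %d atoms, topology has %d",
                      p, nrow(s$topology), nrow(topology)))
      }
      frames <- c(frames, list(s$frame$coords))
      boxes <- c(boxes, list(if (all(is.finite(s$frame$box))) s$frame$box else box))
    } else if (grepl("\\.dcd$", p, ignore.case = TRUE)) {
      mat <- tryCatch(
        bio3d::read.dcd(p, verbose = FALSE),
        error = function(e) abort(sprintf("failed to read DCD '%s': %s", p, conditionMessage(e)))
      )
      cell <- tryCatch(bio3d::read.dcd(p, cell = TRUE, verbose = FALSE),
                       error = function(e) NULL)
      natom_file <- ncol(mat) / 3
      if (natom_file != nrow(topology)) {
        abort(sprintf("atom-count mismatch: '%s' has %d atoms, topology has %d",
                      natom_file, natom_file, nrow(topology)))
      }
      for (f in seq_len(nrow(mat))) {
        frames <- c(frames, list(matrix(mat[f, ], ncol = 3, byrow = TRUE)))
        b <- if (!is.null(cell)) as.numeric(cell[f, 1:3]) else as.numeric(box)
        boxes <- c(boxes, list(b))
      }
    } else {
      abort(sprintf("unsupported trajectory format: '%s' (PDB and DCD are supported)", p))
    }
  }
  if (!length(frames)) abort("no frames read")
  bx <- do.call(rbind, boxes)
  trajectory(topology, frames, box = bx, dt_ns = dt_ns)
}

#' Write a trajectory to a CHARMM-format DCD file
#'
#' Writes single-precision coordinates with per-frame unit-cell records, the
#' layout read back by `bio3d::read.dcd()` and by the common MD analysis
#' stacks.
#'
#' @param traj A `pp_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  natom <- dim(traj$coords)[1]
  nf <- n_frames(traj)
  has_cell <- all(is.finite(traj$box))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wfloat <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wdouble <- function(x) writeBin(as.numeric(x), con, size = 8, endian = "little")

  wint(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24L
  wint(icntrl[1:9]); wfloat(0); wint(icntrl[11:20])
  wint(84)

  title <- sprintf("%-80s", "written by peripose")
  wint(4 + 80); wint(1); writeChar(title, con, nchars = 80, eos = NULL); wint(4 + 80)
  wint(4); wint(natom); wint(4)

  for (f in seq_len(nf)) {
    if (has_cell) {
      b <- traj$box[f, ]
      wint(48); wdouble(c(b[1], 0, b[2], 0, 0, b[3])); wint(48)
    }
    xyz <- frame_coords(traj, f)
    for (d in 1:3) {
      wint(4 * natom); wfloat(xyz[, d]); wint(4 * natom)
    }
  }
  invisible(path)
}

#' Recentre the membrane at z = 0 in every frame
#'
#' Applies a per-frame z shift so the geometric centre of the membrane
#' selection sits at z = 0, the convention the depth and contact analyses
#' assume for pre-wrapped trajectories that drifted along the normal.
#'
#' @param traj A `pp_trajectory`.
#' @param membrane A membrane atom selection from [make_selection()].
#' @return The shifted `pp_trajectory`.
#' @export
rewrap_z <- function(traj, membrane) {
  for (f in seq_len(n_frames(traj))) {
    shift <- mean(traj$coords[membrane, 3, f])
    traj$coords[, 3, f] <- traj$coords[, 3, f] - shift
  }
  traj
}
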