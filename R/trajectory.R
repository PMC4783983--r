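# ---------------------------------------------------------------------------
# Trajectory container and the TRJF v1 text fixture format
# ---------------------------------------------------------------------------

#' Construct a trajectory
#'
#' Coordinates are stored bio3d-style as an F x 3N matrix whose rows are
#' frames in the flat layout (x1, y1, z1, x2, ...), all in Angstrom.
#'
#' @param system An [sd_system()].
#' @param xyz F x 3N coordinate matrix (or a single flat vector for one
#'   frame).
#' @param times Frame times in ps, strictly increasing.
#' @param box Optional orthorhombic box: a length-3 vector (constant box)
#'   or an F x 3 matrix.
#' @return Object of class `sd_trajectory` with elements `system`, `xyz`,
#'   `times`, `box`.
#' @export
sd_trajectory <- function(system, xyz, times = NULL, box = NULL) {
  stopifnot(inherits(system, "sd_system"))
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  n <- n_atoms(system)
  if (ncol(xyz) != 3L * n) {
    stop(sprintf("xyz has %d columns but the system has %d atoms (need %d)",
                 ncol(xyz), n, 3L * n))
  }
  f <- nrow(xyz)
  if (f < 1L) stop("a trajectory needs at least one frame")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  if (is.null(times)) times <- as.numeric(seq_len(f))
  if (length(times) != f) stop("times length must equal the frame count")
  if (f > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = f, ncol = 3L, byrow = TRUE)
    box <- as.matrix(box)
    stopifnot(nrow(box) == f, ncol(box) == 3L, all(box > 0))
  }
  structure(list(system = system, xyz = xyz, times = as.numeric(times),
                 box = box),
            class = "sd_trajectory")
}

#' @export
print.sd_trajectory <- function(x, ...) {
  cat(sprintf("sd_trajectory: %d frames x %d atoms, t = %g..%g ps%s\n",
              n_frames(x), n_atoms(x$system), x$times[1],
              x$times[n_frames(x)],
              if (is.null(x$box)) "" else ", periodic box"))
  invisible(x)
}

#' Number of frames
#' @param traj An `sd_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame as an N x 3 matrix
#' @param traj An `sd_trajectory`.
#' @param i Frame index (1-based).
#' @return N x 3 matrix in Angstrom.
#' @export
frame_coords <- function(traj, i) xyz_to_mat(traj$xyz[i, ])

#' Read / write the TRJF v1 text trajectory format
#'
#' TRJF v1 is a deliberately simple, inspectable fixture format: a header
#' (`natoms`, `nframes`, `dt_ps`, `box bx by bz` or `box none`) followed by
#' per-frame blocks, each a `frame <i> time <t>` line and N coordinate
#' lines `x y z` in Angstrom written with 6 decimal places.
#'
#' @param path File path.
#' @param system System the coordinates belong to (checked against the
#'   header atom count).
#' @return [read_trjf()] returns an [sd_trajectory()]; [write_trjf()]
#'   returns `path` invisibly.
#' @export
read_trjf <- function(path, system) {
  lines <- readLines(path, warn = FALSE)
  hdr <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (!length(ln)) stop(sprintf("TRJF format error: missing header '%s'", key))
    sub(paste0("^", key, " +"), "", ln[1])
  }
  natoms <- as.integer(hdr("natoms"))
  nframes <- as.integer(hdr("nframes"))
  boxspec <- hdr("box")
  box <- if (identical(boxspec, "none")) NULL else {
    v <- as.numeric(strsplit(trimws(boxspec), " +")[[1]])
    if (length(v) != 3L || anyNA(v)) stop("TRJF format error: bad box line")
    v
  }
  if (natoms != n_atoms(system)) {
    stop(sprintf("TRJF atom count %d does not match system atom count %d",
                 natoms, n_atoms(system)))
  }
  frame_at <- grep("^frame ", lines)
  if (length(frame_at) != nframes) {
    stop(sprintf("TRJF format error: header promises %d frames, found %d",
                 nframes, length(frame_at)))
  }
  times <- numeric(nframes)
  xyz <- matrix(NA_real_, nframes, 3L * natoms)
  block_end <- c(frame_at[-1] - 1L, length(lines))
  for (k in seq_len(nframes)) {
    fl <- strsplit(trimws(lines[frame_at[k]]), " +")[[1]]
    times[k] <- as.numeric(fl[4])
    body <- lines[(frame_at[k] + 1L):block_end[k]]
    body <- body[nzchar(trimws(body))]
    if (length(body) != natoms) {
      stop(sprintf("TRJF format error: frame %d has %d coordinate lines, expected %d",
                   k, length(body), natoms))
    }
    co <- matrix(scan(text = body, quiet = TRUE), ncol = 3L, byrow = TRUE)
    xyz[k, ] <- mat_to_xyz(co)
  }
  if (nframes > 1L && any(diff(times) <= 0)) {
    stop("TRJF validation error: frame times not strictly increasing")
  }
  sd_trajectory(system, xyz, times = times, box = box)
}

#' @param traj Trajectory to write.
#' @rdname read_trjf
#' @export
write_trjf <- function(traj, path) {
  n <- n_atoms(traj$system)
  f <- n_frames(traj)
  dt <- if (f > 1L) traj$times[2] - traj$times[1] else 0
  boxline <- if (is.null(traj$box)) "box none" else
    sprintf("box %.6f %.6f %.6f", traj$box[1, 1], traj$box[1, 2],
            traj$box[1, 3])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("natoms %d", n), sprintf("nframes %d", f),
               sprintf("dt_ps %.6f", dt), boxline), con)
  for (k in seq_len(f)) {
    writeLines(sprintf("frame %d time %.6f", k, traj$times[k]), con)
    m <- frame_coords(traj, k)
    writeLines(sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Extract a subset of frames
#' @param traj An `sd_trajectory`.
#' @param idx Frame indices to keep (in order).
#' @return A new `sd_trajectory`.
#' @export
subset_frames <- function(traj, idx) {
  sd_trajectory(traj$system, traj$xyz[idx, , drop = FALSE],
                times = traj$times[idx],
                box = if (is.null(traj$box)) NULL else
                  traj$box[idx, , drop = FALSE])
}
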