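# ---------------------------------------------------------------------------
# Least-squares rigid-body superposition (Kabsch, via SVD)
# ---------------------------------------------------------------------------

#' Optimal rigid superposition and RMSD
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' the selected atoms of `mobile` and `reference` (Kabsch algorithm via
#' singular value decomposition; the reflection branch is corrected so the
#' returned rotation always has determinant +1).
#'
#' @param mobile N x 3 coordinate matrix to fit.
#' @param reference N x 3 target coordinates.
#' @param selection Atom indices the fit (and the RMSD) is computed over;
#'   default all rows.
#' @return List with `rotation` (3 x 3), `translation` (length 3), `rmsd`
#'   (Angstrom) and `coords`, the fully transformed `mobile` matrix. The
#'   transform is `x %*% rotation + translation`.
#' @export
kabsch_superpose_rmsd <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L) stop("superposition needs at least 3 selected atoms")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  comA <- colMeans(A); comB <- colMeans(B)
  Ac <- sweep(A, 2, comA); Bc <- sweep(B, 2, comB)
  if (qr(Bc)$rank < 2L || qr(Ac)$rank < 2L) {
    stop("degenerate (collinear) selection: rank < 2 after centering")
  }
  C <- crossprod(Ac, Bc)              # 3x3
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  translation <- comB - as.vector(comA %*% R)
  fitted_sel <- Ac %*% R
  rmsd <- sqrt(mean(rowSums((fitted_sel - Bc)^2)))
  coords <- sweep(mobile %*% R, 2, translation, "+")
  list(rotation = R, translation = translation, rmsd = rmsd, coords = coords)
}

#' RMSD between two coordinate sets without fitting
#' @param a,b N x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
rmsd_raw <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))

#' Least-squares fit every frame of a trajectory to a reference
#'
#' @param traj An [sd_trajectory()].
#' @param reference N x 3 reference coordinates (default: the system's
#'   starting structure).
#' @param selection Atom indices used for the fit (default: solute CA
#'   atoms when present, else all atoms).
#' @return F x 3N matrix of fitted coordinates (same layout as `traj$xyz`).
#' @export
fit_frames <- function(traj, reference = NULL, selection = NULL) {
  if (is.null(reference)) reference <- traj$system$reference
  if (is.null(selection)) selection <- default_fit_selection(traj$system)
  out <- traj$xyz
  for (k in seq_len(n_frames(traj))) {
    out[k, ] <- mat_to_xyz(
      kabsch_superpose_rmsd(frame_coords(traj, k), reference,
                            selection)$coords)
  }
  out
}

default_fit_selection <- function(sys) {
  ca <- which(sys$atoms$name == "CA" & sys$atoms$is_solute &
              !sys$atoms$is_hydrogen)
  if (length(ca) >= 3L) ca else seq_len(n_atoms(sys))
}

#' Per-frame RMSD time series after superposition
#'
#' @inheritParams fit_frames
#' @param selection Atoms the fit and RMSD are computed over; default the
#'   backbone heavy atoms (N, CA, C, O).
#' @return Numeric vector of per-frame RMSD values (Angstrom).
#' @export
rmsd_series <- function(traj, reference = NULL, selection = NULL) {
  if (is.null(reference)) reference <- traj$system$reference
  if (is.null(selection)) {
    at <- traj$system$atoms
    selection <- which(at$is_solute & at$name %in% c("N", "CA", "C", "O"))
  }
  vapply(seq_len(n_frames(traj)), function(k) {
    kabsch_superpose_rmsd(frame_coords(traj, k), reference, selection)$rmsd
  }, numeric(1))
}
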