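# ---------------------------------------------------------------------------
# Essential dynamics: covariance PCA of atomic fluctuations, projections,
# cosine-content convergence diagnostic, combined two-trajectory ED
# ---------------------------------------------------------------------------

# Fit frames to a reference on `selection`, return the F x 3n matrix of the
# selected atoms' fitted coordinates.
fitted_selection_matrix <- function(traj, selection, fit_reference) {
  f <- n_frames(traj)
  cols <- as.vector(rbind(3L * (selection - 1L) + 1L,
                          3L * (selection - 1L) + 2L,
                          3L * selection))
  out <- matrix(NA_real_, f, 3L * length(selection))
  for (k in seq_len(f)) {
    fit <- kabsch_superpose_rmsd(frame_coords(traj, k), fit_reference,
                                 selection)
    out[k, ] <- mat_to_xyz(fit$coords[selection, , drop = FALSE])
  }
  out
}

# Eigendecomposition of the population covariance of a frames x 3n matrix.
ed_from_matrix <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nrow(X)
  eg <- eigen(C, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  # sign convention: largest-magnitude component positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(mean = mu, eigenvalues = vals, eigenvectors = vecs,
       tmsf = sum(vals))
}

#' Essential dynamics decomposition
#'
#' Least-squares fits every frame to `fit_reference` on the selection,
#' accumulates the 3n x 3n Cartesian covariance of the selected atoms
#' (unweighted, population normalisation 1/F) and diagonalises it.
#' Eigenvalues are variances along collective modes, sorted descending;
#' their sum is the total mean square fluctuation (TMSF). Each
#' eigenvector's sign is fixed so its largest-magnitude component is
#' positive.
#'
#' @param traj An [sd_trajectory()].
#' @param selection Atom indices to analyse; default solute CA atoms.
#' @param fit_reference N x 3 reference coordinates; default the system's
#'   starting structure.
#' @param fit Superpose frames before accumulating the covariance
#'   (default `TRUE`; disable for pre-aligned synthetic data).
#' @return Object of class `sd_ed`: `selection`, `mean_structure` (n x 3,
#'   Angstrom), `eigenvectors` (3n x 3n, orthonormal columns),
#'   `eigenvalues` (Angstrom^2), `eigenvalues_nm2`, `tmsf` (Angstrom^2),
#'   `tmsf_nm2`, `fit_reference`, `fit`.
#' @export
ed_decompose <- function(traj, selection = NULL, fit_reference = NULL,
                         fit = TRUE) {
  if (n_frames(traj) < 2L) stop("essential dynamics needs at least 2 frames")
  sys <- traj$system
  if (is.null(selection)) selection <- default_fit_selection(sys)
  if (length(selection) < 3L) stop("selection must contain at least 3 atoms")
  if (is.null(fit_reference)) fit_reference <- sys$reference
  X <- if (fit) {
    fitted_selection_matrix(traj, selection, fit_reference)
  } else {
    cols <- as.vector(rbind(3L * (selection - 1L) + 1L,
                            3L * (selection - 1L) + 2L,
                            3L * selection))
    traj$xyz[, cols, drop = FALSE]
  }
  dec <- ed_from_matrix(X)
  structure(list(selection = selection,
                 mean_structure = xyz_to_mat(dec$mean),
                 eigenvectors = dec$eigenvectors,
                 eigenvalues = dec$eigenvalues,
                 eigenvalues_nm2 = dec$eigenvalues / 100,
                 tmsf = dec$tmsf, tmsf_nm2 = dec$tmsf / 100,
                 fit_reference = fit_reference, fit = fit),
            class = "sd_ed")
}

#' @export
print.sd_ed <- function(x, ...) {
  cat(sprintf("sd_ed: %d atoms, TMSF %.4g A^2 (%.4g nm^2); top eigenvalues (A^2): %s\n",
              length(x$selection), x$tmsf, x$tmsf_nm2,
              paste(signif(head(x$eigenvalues, 5), 4), collapse = ", ")))
  invisible(x)
}

#' Project a trajectory onto essential-dynamics eigenvectors
#'
#' `p_k(t) = v_k . (x_fit(t) - <x>)`, with frames fitted the same way the
#' decomposition was built.
#'
#' @param traj An [sd_trajectory()].
#' @param ed An [ed_decompose()] result.
#' @param k Eigenvector index (may be a vector).
#' @return Numeric vector (or F x length(k) matrix) of projections in
#'   Angstrom.
#' @export
project <- function(traj, ed, k = 1L) {
  if (any(k > ncol(ed$eigenvectors))) {
    stop("eigenvector index beyond available eigenvectors")
  }
  X <- if (ed$fit) {
    fitted_selection_matrix(traj, ed$selection, ed$fit_reference)
  } else {
    cols <- as.vector(rbind(3L * (ed$selection - 1L) + 1L,
                            3L * (ed$selection - 1L) + 2L,
                            3L * ed$selection))
    traj$xyz[, cols, drop = FALSE]
  }
  p <- sweep(X, 2, mat_to_xyz(ed$mean_structure)) %*%
    ed$eigenvectors[, k, drop = FALSE]
  if (length(k) == 1L) as.vector(p) else p
}

#' Extreme projections along an eigenvector
#'
#' Returns the frames attaining the minimum and maximum projection on
#' eigenvector `k`, plus linear Cartesian interpolations between the two
#' fitted extreme structures (these emphasise the conformational
#' difference; they are not a transition pathway).
#'
#' @inheritParams project
#' @param n_interpolants Total number of structures returned, including
#'   both extremes (minimum 2).
#' @return List with `frame_min`, `frame_max`, `p_min`, `p_max`, and
#'   `structures`, a list of n x 3 matrices from the minimum to the
#'   maximum extreme.
#' @export
projection_extremes <- function(traj, ed, k = 1L, n_interpolants = 2L) {
  stopifnot(length(k) == 1L, n_interpolants >= 2L)
  p <- project(traj, ed, k)
  imin <- which.min(p); imax <- which.max(p)
  a <- kabsch_superpose_rmsd(frame_coords(traj, imin), ed$fit_reference,
                             ed$selection)$coords[ed$selection, , drop = FALSE]
  b <- kabsch_superpose_rmsd(frame_coords(traj, imax), ed$fit_reference,
                             ed$selection)$coords[ed$selection, , drop = FALSE]
  lam <- seq(0, 1, length.out = n_interpolants)
  structures <- lapply(lam, function(w) (1 - w) * a + w * b)
  list(frame_min = imin, frame_max = imax, p_min = p[imin], p_max = p[imax],
       structures = structures)
}

#' Cosine content of a projection time series
#'
#' `c_k = (2/T) * (integral cos(k pi t / T) p(t) dt)^2 / integral p(t)^2
#' dt`, trapezoid-discretised over frames with the series mean-centred
#' first. Values near 1 mean the mode resembles random diffusion
#' (unconverged sampling); values near 0 indicate converged sampling.
#'
#' @param p Numeric series (projection on one eigenvector), length >= 4.
#' @param k Cosine index (default 1, the half-period cosine).
#' @param center Mean-centre the series first (default `TRUE`).
#' @return Cosine content in [0, 1].
#' @export
cosine_content <- function(p, k = 1L, center = TRUE) {
  n <- length(p)
  if (n < 4L) stop("series too short for cosine content (need >= 4 points)")
  if (center) p <- p - mean(p)
  if (all(p == 0)) stop("cosine content undefined for an all-zero series")
  tt <- seq(0, 1, length.out = n)   # time scale cancels
  ck <- cos(k * pi * tt)
  num <- 2 * pracma::trapz(tt, ck * p)^2
  den <- pracma::trapz(tt, p^2)
  num / den
}

#' Combined essential dynamics of two trajectories
#'
#' Concatenates two trajectories (fitted to a common reference on a shared
#' selection), performs ED on the joint covariance, and reports per-half
#' projection statistics: the mean and the mean square displacement
#' `msd_h(k) = mean(p_k^2)` of each half, with projections centred on the
#' combined mean so the MSD captures both the conformational shift between
#' the simulations and the fluctuation within each. Histograms of each
#' half share common bin edges.
#'
#' @param trajA,trajB Trajectories over the same atoms.
#' @param selection Atom indices (default solute CA of `trajA`'s system).
#' @param fit_reference Common fit reference (default `trajA`'s starting
#'   structure).
#' @param n_vectors Number of leading eigenvectors to report statistics
#'   for (default `min(30, 3n)`).
#' @param n_bins Histogram bins per eigenvector (default 40).
#' @return Object of class `sd_combined_ed`: `ed` (the joint [sd_ed]),
#'   `stats` (data frame `k`, `mean_A`, `mean_B`, `msd_A`, `msd_B`),
#'   `histograms` (per k: `breaks`, `density_A`, `density_B`), and
#'   `n_frames` per half.
#' @export
combined_ed <- function(trajA, trajB, selection = NULL,
                        fit_reference = NULL, n_vectors = NULL,
                        n_bins = 40L) {
  if (n_atoms(trajA$system) != n_atoms(trajB$system)) {
    stop("trajectories have different atom counts")
  }
  sys <- trajA$system
  if (is.null(selection)) selection <- default_fit_selection(sys)
  if (is.null(fit_reference)) fit_reference <- sys$reference
  XA <- fitted_selection_matrix(trajA, selection, fit_reference)
  XB <- fitted_selection_matrix(trajB, selection, fit_reference)
  X <- rbind(XA, XB)
  dec <- ed_from_matrix(X)
  ed <- structure(list(selection = selection,
                       mean_structure = xyz_to_mat(dec$mean),
                       eigenvectors = dec$eigenvectors,
                       eigenvalues = dec$eigenvalues,
                       eigenvalues_nm2 = dec$eigenvalues / 100,
                       tmsf = dec$tmsf, tmsf_nm2 = dec$tmsf / 100,
                       fit_reference = fit_reference, fit = TRUE),
                  class = "sd_ed")
  nA <- nrow(XA)
  if (is.null(n_vectors)) n_vectors <- min(30L, ncol(dec$eigenvectors))
  P <- sweep(X, 2, dec$mean) %*% dec$eigenvectors[, seq_len(n_vectors),
                                                  drop = FALSE]
  pA <- P[seq_len(nA), , drop = FALSE]
  pB <- P[-seq_len(nA), , drop = FALSE]
  stats <- data.frame(k = seq_len(n_vectors),
                      mean_A = colMeans(pA), mean_B = colMeans(pB),
                      msd_A = colMeans(pA^2), msd_B = colMeans(pB^2))
  histograms <- lapply(seq_len(n_vectors), function(j) {
    rng <- range(P[, j])
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    hA <- graphics::hist(pA[, j], breaks = breaks, plot = FALSE)
    hB <- graphics::hist(pB[, j], breaks = breaks, plot = FALSE)
    list(breaks = breaks, density_A = hA$density, density_B = hB$density)
  })
  structure(list(ed = ed, stats = stats, histograms = histograms,
                 n_frames = c(A = nA, B = nrow(XB))),
            class = "sd_combined_ed")
}

#' @export
print.sd_combined_ed <- function(x, ...) {
  cat(sprintf("sd_combined_ed: halves of %d + %d frames, joint TMSF %.4g A^2\n",
              x$n_frames[1], x$n_frames[2], x$ed$tmsf))
  cat(sprintf("  eigenvector 1: mean_A %.3g, mean_B %.3g, msd_A %.3g, msd_B %.3g\n",
              x$stats$mean_A[1], x$stats$mean_B[1], x$stats$msd_A[1],
              x$stats$msd_B[1]))
  invisible(x)
}
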