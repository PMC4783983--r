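# ---------------------------------------------------------------------------
# Per-residue RMSF and burial-depth flexibility profiles
# ---------------------------------------------------------------------------

#' Per-residue RMSF
#'
#' `RMSF_i = sqrt(< |r_i(t) - <r_i>|^2 >)` over frames, after
#' least-squares fitting every frame to the reference on the selection.
#'
#' @param traj An [sd_trajectory()].
#' @param selection Atom indices, one per residue (default solute CA).
#' @param fit_reference N x 3 reference (default the starting structure).
#' @param fit Superpose frames first (default `TRUE`).
#' @return Named numeric vector of RMSF values (Angstrom), names = residue
#'   indices.
#' @export
per_residue_rmsf <- function(traj, selection = NULL, fit_reference = NULL,
                             fit = TRUE) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  sys <- traj$system
  if (is.null(selection)) selection <- default_fit_selection(sys)
  if (is.null(fit_reference)) fit_reference <- sys$reference
  X <- if (fit) fitted_selection_matrix(traj, selection, fit_reference)
       else {
         cols <- as.vector(rbind(3L * (selection - 1L) + 1L,
                                 3L * (selection - 1L) + 2L,
                                 3L * selection))
         traj$xyz[, cols, drop = FALSE]
       }
  Xc <- sweep(X, 2, colMeans(X))
  msf_percoord <- colMeans(Xc^2)
  msf_atom <- msf_percoord[seq(1, length(msf_percoord), 3)] +
    msf_percoord[seq(2, length(msf_percoord), 3)] +
    msf_percoord[seq(3, length(msf_percoord), 3)]
  setNames(sqrt(msf_atom), sys$atoms$resid[selection])
}

#' RMSF as a function of burial depth
#'
#' Surface atoms are the heavy solute atoms with per-atom SASA above
#' `surface_threshold` on the trajectory mean structure (probe radius from
#' `config`). The burial depth of a residue is the distance from its CA to
#' the nearest surface atom (0 when its own CA is a surface atom).
#' Residues are binned into `n_bins` equal-width depth bins; the profile
#' is the mean RMSF per bin. Empty bins are reported as `NA`, never zero.
#'
#' @param traj An [sd_trajectory()].
#' @param config An [analysis_config()].
#' @param n_bins Number of depth bins (default 6).
#' @param surface_threshold Per-atom SASA above which an atom counts as
#'   surface (Angstrom^2, default 0.5).
#' @return Object of class `sd_flex_profile`: per-residue `rmsf` and
#'   `depth`, `bin` assignment, `edges`, `profile` (mean RMSF per bin) and
#'   `counts`.
#' @export
rmsf_depth_profile <- function(traj, config = analysis_config(),
                               n_bins = 6L, surface_threshold = 0.5) {
  sys <- traj$system
  at <- sys$atoms
  ca <- which(at$name == "CA" & at$is_solute & !at$is_hydrogen)
  if (!length(ca)) stop("no CA atoms found")
  rmsf <- per_residue_rmsf(traj, selection = ca)
  X <- fit_frames(traj, selection = ca)
  mean_struct <- xyz_to_mat(colMeans(X))
  heavy <- which(at$is_solute & !at$is_hydrogen)
  sasa <- shrake_rupley_sasa(mean_struct[heavy, , drop = FALSE],
                             at$vdw_radius[heavy],
                             config$sasa_probe_radius,
                             config$sasa_points_per_atom)
  surf <- heavy[sasa > surface_threshold]
  if (!length(surf)) stop("no surface atoms found (all atoms buried?)")
  depth <- vapply(ca, function(i) {
    if (i %in% surf) return(0)
    sqrt(min(dist2_point(mean_struct[i, ], mean_struct[surf, , drop = FALSE])))
  }, numeric(1))
  dmax <- max(depth)
  if (dmax == 0) {
    edges <- c(0, 1)
    bin <- rep(1L, length(depth))
    n_bins <- 1L
  } else {
    edges <- seq(0, dmax, length.out = n_bins + 1L)
    bin <- findInterval(depth, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
  }
  profile <- vapply(seq_len(n_bins), function(b)
    if (any(bin == b)) mean(rmsf[bin == b]) else NA_real_, numeric(1))
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(rmsf = rmsf, depth = setNames(depth, names(rmsf)),
                 bin = bin, edges = edges, profile = profile,
                 counts = counts),
            class = "sd_flex_profile")
}

#' @export
print.sd_flex_profile <- function(x, ...) {
  cat(sprintf("sd_flex_profile: %d residues, depth 0..%.2f A in %d bins\n",
              length(x$rmsf), max(x$depth), length(x$profile)))
  invisible(x)
}

#' Write a flexibility profile as TSV
#' @param prof An `sd_flex_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_flex_profile <- function(prof, path) {
  df <- data.frame(residue = names(prof$rmsf), rmsf = unname(prof$rmsf),
                   depth = unname(prof$depth), bin = prof$bin)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
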