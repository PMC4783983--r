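# ---------------------------------------------------------------------------
# Solvent mean-square displacement and hydration-shell classification
# ---------------------------------------------------------------------------

#' Mean-square displacement with periodic unwrapping
#'
#' Coordinates are unwrapped by accumulating minimum-image frame-to-frame
#' displacements (orthorhombic box; skipped when the trajectory has no
#' box), then `MSD(tau) = < |r(t + tau) - r(t)|^2 >` averaged over the
#' selected atoms and all sliding time origins. The diffusion coefficient
#' is `slope / (2 * 3)` from a linear fit of MSD over `fit_window`.
#'
#' @param traj An [sd_trajectory()].
#' @param selection Atom indices to track (e.g. water oxygens).
#' @param max_lag Maximum lag in frames (must be < number of frames).
#' @param fit_window Lag-index range (2-vector) for the diffusion fit;
#'   default the second half of the lag range.
#' @param subset Label stored on the curve (`"all"`, `"hydration"`,
#'   `"bulk"`, ...).
#' @return Object of class `sd_msd`: `lag_ps`, `msd` (Angstrom^2),
#'   `diffusion_coefficient` (Angstrom^2/ps), `subset`.
#' @export
unwrap_msd <- function(traj, selection, max_lag, fit_window = NULL,
                       subset = "all") {
  f <- n_frames(traj)
  if (max_lag >= f) stop("max_lag must be smaller than the trajectory length")
  if (!length(selection)) stop("empty selection")
  n <- length(selection)
  cols <- as.vector(rbind(3L * (selection - 1L) + 1L,
                          3L * (selection - 1L) + 2L,
                          3L * selection))
  U <- traj$xyz[, cols, drop = FALSE]
  if (!is.null(traj$box) && f > 1L) {
    for (k in 2:f) {
      d <- U[k, ] - U[k - 1L, ]
      b <- rep(traj$box[k, ], times = n)   # matches (x1,y1,z1,x2,...) layout
      d <- d - b * round(d / b)
      U[k, ] <- U[k - 1L, ] + d
    }
  }
  lags <- 0:max_lag
  msd <- numeric(length(lags))
  for (m in seq_along(lags)) {
    lag <- lags[m]
    if (lag == 0L) next
    D <- U[(1L + lag):f, , drop = FALSE] - U[1:(f - lag), , drop = FALSE]
    msd[m] <- sum(D^2) / ((f - lag) * n)
  }
  dt <- if (f > 1L) traj$times[2] - traj$times[1] else 1
  lag_ps <- lags * dt
  if (is.null(fit_window)) {
    fit_window <- c(max(2L, floor(max_lag / 2)), max_lag)
  }
  sel_fit <- which(lags >= fit_window[1] & lags <= fit_window[2])
  D_coef <- if (length(sel_fit) >= 2L) {
    unname(stats::coef(stats::lm(msd[sel_fit] ~ lag_ps[sel_fit]))[2] / 6)
  } else NA_real_
  structure(list(lag_ps = lag_ps, msd = msd,
                 diffusion_coefficient = D_coef, subset = subset),
            class = "sd_msd")
}

#' @export
print.sd_msd <- function(x, ...) {
  cat(sprintf("sd_msd (%s): %d lags, MSD(max) %.4g A^2, D = %.4g A^2/ps\n",
              x$subset, length(x$lag_ps), max(x$msd),
              x$diffusion_coefficient))
  invisible(x)
}

#' Write an MSD curve as TSV
#' @param msd An `sd_msd`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_msd <- function(msd, path) {
  utils::write.table(data.frame(lag_ps = msd$lag_ps, msd_A2 = msd$msd,
                                subset = msd$subset),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Partition water molecules into hydration shell and bulk
#'
#' A water is "hydration" iff its oxygen lies within `cutoff` of any
#' protein (solute) heavy atom, minimum-image when a box is given;
#' otherwise "bulk". The partition is exhaustive and exclusive.
#'
#' @param coords N x 3 frame coordinates.
#' @param sys An [sd_system()].
#' @param cutoff Shell cutoff in Angstrom (default 4.5).
#' @param box Optional length-3 box.
#' @return Data frame with one row per water molecule: `resid`, `o_atom`
#'   (oxygen atom index), `class` (`"hydration"`/`"bulk"`).
#' @export
classify_hydration <- function(coords, sys, cutoff = 4.5, box = NULL) {
  at <- sys$atoms
  wat_o <- which(!at$is_solute & at$resname %in% .solvent_resnames &
                 at$name %in% c("OW", "O"))
  if (!length(wat_o)) stop("no solvent (water oxygen) atoms in the system")
  prot <- which(at$is_solute & !at$is_hydrogen)
  if (!length(prot)) stop("no protein heavy atoms in the system")
  pm <- coords[prot, , drop = FALSE]
  cls <- vapply(wat_o, function(i) {
    d2 <- dist2_point(coords[i, ], pm, box)
    if (min(d2) <= cutoff^2) "hydration" else "bulk"
  }, character(1))
  data.frame(resid = at$resid[wat_o], o_atom = wat_o, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}
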