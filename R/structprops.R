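# ---------------------------------------------------------------------------
# Structural property calculators: Rg, native contacts, Shrake-Rupley SASA,
# per-trajectory property tables and delta arithmetic
# ---------------------------------------------------------------------------

#' Radius of gyration
#'
#' `Rg = sqrt(sum m_i |r_i - r_com|^2 / sum m_i)`; mass-weighted by
#' default, set `masses = NULL` explicitly for the geometric variant via
#' `mass_weighted = FALSE`.
#'
#' @param coords N x 3 coordinates (Angstrom).
#' @param selection Row indices to include (default all).
#' @param masses Per-atom masses (amu) aligned with `coords` rows; ignored
#'   when `mass_weighted` is `FALSE`.
#' @param mass_weighted Use mass weighting (default `TRUE`).
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(coords, selection = NULL, masses = NULL,
                               mass_weighted = TRUE) {
  coords <- as.matrix(coords)
  if (is.null(selection)) selection <- seq_len(nrow(coords))
  if (!length(selection)) stop("empty selection for radius of gyration")
  x <- coords[selection, , drop = FALSE]
  w <- if (mass_weighted && !is.null(masses)) masses[selection]
       else rep(1, length(selection))
  if (sum(w) <= 0) stop("total mass must be positive")
  com <- colSums(x * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(x, 2, com)^2)) / sum(w))
}

#' Build the native-contact pair list from the reference structure
#'
#' All solute heavy-atom pairs in different residues closer than the cutoff
#' (strict `<`) in the reference coordinates.
#'
#' @param sys An [sd_system()].
#' @param cutoff Distance cutoff in Angstrom (default 6).
#' @return The system with `native_pairs` (2-column index matrix) set.
#' @export
build_native_pairs <- function(sys, cutoff = 6.0) {
  at <- sys$atoms
  idx <- which(at$is_solute & !at$is_hydrogen)
  x <- sys$reference[idx, , drop = FALSE]
  m <- length(idx)
  pairs <- NULL
  cut2 <- cutoff^2
  for (i in seq_len(m - 1L)) {
    j <- (i + 1L):m
    j <- j[at$resid[idx[j]] != at$resid[idx[i]]]
    if (!length(j)) next
    d2 <- dist2_point(x[i, ], x[j, , drop = FALSE])
    hit <- j[d2 < cut2]
    if (length(hit)) pairs <- rbind(pairs, cbind(idx[i], idx[hit]))
  }
  sys$native_pairs <- pairs
  sys
}

#' Count surviving native contacts in a frame
#'
#' @param coords N x 3 frame coordinates.
#' @param sys System whose `native_pairs` have been built with
#'   [build_native_pairs()].
#' @param cutoff Distance cutoff in Angstrom (strict `<`, default 6).
#' @return Integer count.
#' @export
native_contact_count <- function(coords, sys, cutoff = 6.0) {
  if (is.null(sys$native_pairs)) {
    stop("native_pairs not set; call build_native_pairs() on the reference first")
  }
  p <- sys$native_pairs
  d2 <- rowSums((coords[p[, 1], , drop = FALSE] -
                 coords[p[, 2], , drop = FALSE])^2)
  sum(d2 < cutoff^2)
}

# Deterministic golden-spiral point set on the unit sphere.
golden_spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Places a deterministic golden-spiral point set on each atom's solvent-
#' expanded sphere (radius `r_i + probe`) and counts points not buried in
#' any neighbour's expanded sphere. Per-atom area is the exposed fraction
#' times `4 pi (r_i + probe)^2`.
#'
#' @param coords N x 3 coordinates (Angstrom).
#' @param radii Per-atom van der Waals radii (Angstrom).
#' @param probe Probe radius (default 1.4).
#' @param n_points Quadrature points per atom (default 960, minimum 60).
#' @return Numeric vector of per-atom areas in Angstrom^2 (sum for the
#'   total SASA).
#' @export
shrake_rupley_sasa <- function(coords, radii, probe = 1.4, n_points = 960L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(radii) == n, all(radii > 0), n_points >= 60)
  pts <- golden_spiral_points(n_points)
  rr <- radii + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- dist2_point(coords[i, ], coords)
    nb <- which(d2 < (rr[i] + rr)^2 & seq_len(n) != i)
    sphere <- sweep(pts * rr[i], 2, coords[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- dist2_point(coords[j, ], sphere[exposed, , drop = FALSE])
      exposed[exposed] <- dj >= rr[j]^2
    }
    area[i] <- sum(exposed) / n_points * 4 * pi * rr[i]^2
  }
  area
}

# ---------------------------------------------------------------------------
# Property tables and delta arithmetic
# ---------------------------------------------------------------------------

#' Per-trajectory structural property table
#'
#' Computes, frame by frame, the backbone RMSD to the starting structure,
#' total solute SASA, native-contact count, radius of gyration and
#' secondary-structure residue counts (helix = H+G, sheet = E, turn = T),
#' then reports their means and standard deviations. The layout mirrors
#' the conventional "average structural properties" table of
#' protein-solvent temperature studies.
#'
#' @param traj An [sd_trajectory()].
#' @param config An [analysis_config()].
#' @param label Condition label, e.g. `"P300/S180"` (protein temperature /
#'   solvent temperature).
#' @param sasa_stride Compute SASA every `sasa_stride`-th frame (it is by
#'   far the most expensive property; default 1 = every frame).
#' @param with_sse Include secondary-structure counts (default `TRUE`).
#' @return A one-row data frame of class `sd_property_table` with
#'   `<prop>_mean` / `<prop>_sd` columns.
#' @export
property_table <- function(traj, config = analysis_config(),
                           label = "traj", sasa_stride = 1L,
                           with_sse = TRUE) {
  sys <- traj$system
  at <- sys$atoms
  f <- n_frames(traj)
  if (is.null(sys$native_pairs)) {
    sys <- build_native_pairs(sys, config$native_contact_cutoff)
  }
  solute_idx <- which(at$is_solute)
  heavy_solute <- which(at$is_solute & !at$is_hydrogen)
  rmsd <- rmsd_series(traj)
  rg <- numeric(f); nnc <- integer(f)
  sasa <- rep(NA_real_, f)
  sse_h <- sse_e <- sse_t <- rep(NA_real_, f)
  sasa_frames <- seq(1L, f, by = sasa_stride)
  for (k in seq_len(f)) {
    m <- frame_coords(traj, k)
    rg[k] <- radius_of_gyration(m, solute_idx, at$mass)
    nnc[k] <- native_contact_count(m, sys, config$native_contact_cutoff)
    if (k %in% sasa_frames) {
      sasa[k] <- sum(shrake_rupley_sasa(m[heavy_solute, , drop = FALSE],
                                        at$vdw_radius[heavy_solute],
                                        config$sasa_probe_radius,
                                        config$sasa_points_per_atom))
    }
    if (with_sse) {
      lab <- assign_secondary_structure(m, sys)
      sse_h[k] <- sum(lab %in% c("H", "G"))
      sse_e[k] <- sum(lab == "E")
      sse_t[k] <- sum(lab == "T")
    }
  }
  ms <- function(v) c(mean(v, na.rm = TRUE),
                      if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0)
  vals <- c(rmsd = ms(rmsd), sasa = ms(sasa), nnc = ms(nnc), rg = ms(rg),
            sse_helix = ms(sse_h), sse_sheet = ms(sse_e), sse_turn = ms(sse_t))
  out <- as.data.frame(as.list(vals))
  names(out) <- as.vector(outer(c("mean", "sd"),
    c("rmsd", "sasa", "nnc", "rg", "sse_helix", "sse_sheet", "sse_turn"),
    function(s, p) paste0(p, "_", s)))
  out <- cbind(data.frame(label = label, stringsAsFactors = FALSE), out)
  class(out) <- c("sd_property_table", class(out))
  out
}

#' Assemble a property table row from known averages
#'
#' Useful for delta arithmetic on published tables where only the printed
#' means/SDs are available.
#'
#' @param label Condition label.
#' @param ... Named values among `rmsd`, `sasa`, `nnc`, `rg`, `sse_helix`,
#'   `sse_sheet`, `sse_turn` (means) and optional `<prop>_sd` entries.
#' @return An `sd_property_table` row.
#' @export
property_table_from_values <- function(label, ...) {
  v <- list(...)
  props <- c("rmsd", "sasa", "nnc", "rg", "sse_helix", "sse_sheet",
             "sse_turn")
  out <- data.frame(label = label, stringsAsFactors = FALSE)
  for (p in props) {
    out[[paste0(p, "_mean")]] <- if (!is.null(v[[p]])) v[[p]] else NA_real_
    out[[paste0(p, "_sd")]] <- if (!is.null(v[[paste0(p, "_sd")]]))
      v[[paste0(p, "_sd")]] else NA_real_
  }
  class(out) <- c("sd_property_table", class(out))
  out
}

#' Percent- and fold-change between two property tables
#'
#' For each property with a finite mean in both tables reports
#' `percent_change = 100 (b - a) / a` and `fold_change = (b - a) / a`
#' (a 3.64-fold increase means b is 4.64 times a). Secondary-structure
#' residue counts are compared on the helix + sheet + turn sum (`sse`).
#'
#' @param a,b `sd_property_table` rows (from -> to).
#' @return Data frame with one row per property: `property`, `from_label`,
#'   `to_label`, `from`, `to`, `percent_change`, `fold_change`.
#' @export
compare_tables <- function(a, b) {
  props <- c("rmsd", "sasa", "nnc", "rg")
  va <- vapply(props, function(p) a[[paste0(p, "_mean")]], numeric(1))
  vb <- vapply(props, function(p) b[[paste0(p, "_mean")]], numeric(1))
  sse_a <- a$sse_helix_mean + a$sse_sheet_mean + a$sse_turn_mean
  sse_b <- b$sse_helix_mean + b$sse_sheet_mean + b$sse_turn_mean
  props <- c(props, "sse")
  va <- c(va, sse = sse_a); vb <- c(vb, sse = sse_b)
  keep <- is.finite(va) & is.finite(vb)
  va <- va[keep]; vb <- vb[keep]; props <- props[keep]
  if (any(va == 0 & vb != 0)) {
    stop("undefined percent change: baseline value is zero")
  }
  data.frame(property = props, from_label = a$label, to_label = b$label,
             from = unname(va), to = unname(vb),
             percent_change = 100 * (vb - va) / va,
             fold_change = (vb - va) / va,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percent/fold change between two scalar values
#'
#' The elementary arithmetic behind [compare_tables()], exposed for
#' quantities that do not live in a property table (e.g. total mean square
#' fluctuations).
#'
#' @param a,b Scalars (from -> to).
#' @return List with `percent_change` and `fold_change`.
#' @export
value_delta <- function(a, b) {
  if (a == 0 && b != 0) stop("undefined percent change: baseline is zero")
  list(percent_change = 100 * (b - a) / a, fold_change = (b - a) / a)
}
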