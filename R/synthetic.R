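# ---------------------------------------------------------------------------
# Synthetic systems and trajectories with planted ground truth
# ---------------------------------------------------------------------------

# Place atom D bonded to C given bond length, angle B-C-D (deg) and
# torsion A-B-C-D (deg); natural extension reference frame construction.
nerf_place <- function(A, B, C, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + bond * (-cos(ang) * bc + sin(ang) * (cos(tor) * m + sin(tor) * n))
}

# Ideal peptide geometry constants (Angstrom / degrees)
.pep <- list(b_nca = 1.46, b_cac = 1.52, b_cn = 1.33, b_co = 1.23,
             b_nh = 1.00, b_cacb = 1.53, b_cbog = 1.42, b_ogh = 0.96,
             a_ncac = 111.0, a_cacn = 117.0, a_cnca = 121.7,
             a_caco = 120.5, a_cacb = 110.5, a_cbog = 110.5,
             a_ogh = 109.5, omega = 180)

#' Build an ideal peptide system
#'
#' Constructs a poly-peptide backbone from ideal internal coordinates
#' (N-CA 1.46, CA-C 1.52, C-N 1.33 Angstrom, omega = 180) at template
#' dihedrals: helix phi = -57, psi = -47; extended phi = -120, psi = 120.
#' Backbone atoms are N, H (from residue 2 on), CA, C, O; `sidechain`
#' entries add a serine-like CB-OG-HG arm ("ser") or an aspartate-like
#' CB-CG-OD1 arm ("asp") to the named residues.
#'
#' @param n_residues Number of residues (>= 2).
#' @param geometry `"helix"` or `"extended"`.
#' @param sidechain Optional named character vector, e.g.
#'   `c("3" = "ser", "7" = "asp")`, keyed by residue index.
#' @return An [sd_system()] whose reference coordinates hold the template.
#' @export
gen_peptide_system <- function(n_residues, geometry = c("helix", "extended"),
                               sidechain = NULL) {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 2)
  phi <- if (geometry == "helix") -57 else -120
  psi <- if (geometry == "helix") -47 else 120
  p <- .pep
  # backbone trace first: N, CA, C per residue
  Nx <- CAx <- Cx <- vector("list", n_residues)
  Nx[[1]] <- c(0, 0, 0)
  CAx[[1]] <- c(p$b_nca, 0, 0)
  Cx[[1]] <- nerf_place(c(0, 0, 1), Nx[[1]], CAx[[1]], p$b_cac, p$a_ncac, 0)
  for (i in 2:n_residues) {
    Nx[[i]] <- nerf_place(Nx[[i - 1]], CAx[[i - 1]], Cx[[i - 1]],
                          p$b_cn, p$a_cacn, psi)
    CAx[[i]] <- nerf_place(CAx[[i - 1]], Cx[[i - 1]], Nx[[i]],
                           p$b_nca, p$a_cnca, p$omega)
    Cx[[i]] <- nerf_place(Cx[[i - 1]], Nx[[i]], CAx[[i]],
                          p$b_cac, p$a_ncac, phi)
  }
  atoms <- list(); coords <- list()
  add <- function(name, resid, pos, resname) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, resname = resname, resid = resid, chain = "A",
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <<- pos
  }
  for (i in seq_len(n_residues)) {
    sc <- if (!is.null(sidechain)) sidechain[as.character(i)] else NA
    resname <- if (is.na(sc)) "GLY" else if (sc == "ser") "SER" else "ASP"
    add("N", i, Nx[[i]], resname)
    if (i > 1L) {
      # amide H on the bisector extension of C(prev)-N and CA-N
      u1 <- Nx[[i]] - Cx[[i - 1]]; u1 <- u1 / sqrt(sum(u1^2))
      u2 <- Nx[[i]] - CAx[[i]]; u2 <- u2 / sqrt(sum(u2^2))
      b <- u1 + u2; b <- b / sqrt(sum(b^2))
      add("H", i, Nx[[i]] + p$b_nh * b, resname)
    }
    add("CA", i, CAx[[i]], resname)
    if (!is.na(sc)) {
      cb <- nerf_place(Nx[[i]], Cx[[i]], CAx[[i]], p$b_cacb, p$a_cacb, -122)
      add("CB", i, cb, resname)
      if (sc == "ser") {
        og <- nerf_place(Nx[[i]], CAx[[i]], cb, p$b_cbog, p$a_cbog, 180)
        add("OG", i, og, resname)
        add("HG", i, nerf_place(CAx[[i]], cb, og, p$b_ogh, p$a_ogh, 180),
            resname)
      } else {
        cg <- nerf_place(Nx[[i]], CAx[[i]], cb, 1.52, 112.6, 180)
        add("CG", i, cg, resname)
        add("OD1", i, nerf_place(CAx[[i]], cb, cg, 1.25, 118.4, 180),
            resname)
      }
    }
    add("C", i, Cx[[i]], resname)
    # carbonyl O anti to the next amide nitrogen (psi + 180)
    add("O", i, nerf_place(Nx[[i]], CAx[[i]], Cx[[i]], p$b_co, p$a_caco,
                           psi + 180), resname)
  }
  at <- do.call(rbind, atoms)
  sd_system(at, do.call(rbind, coords))
}

#' Two-strand antiparallel beta-hairpin template
#'
#' Two extended strands, the second rotated 180 degrees about the z axis
#' and offset so the Kabsch-Sander antiparallel bridge registry forms
#' between the strand interiors. Residues are numbered 1..n on strand 1
#' and n+1..2n on strand 2 (no covalent connector is modelled).
#'
#' @param n_per_strand Residues per strand.
#' @param offset Translation (length 3) applied to the rotated strand;
#'   the default was calibrated so interior residues pair.
#' @return An [sd_system()].
#' @export
gen_beta_hairpin <- function(n_per_strand = 6L, offset = NULL) {
  s1 <- gen_peptide_system(n_per_strand, "extended")
  n1 <- n_atoms(s1)
  xy1 <- s1$reference
  rot <- cbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, 1))
  xy2 <- xy1 %*% rot
  if (is.null(offset)) offset <- .hairpin_offset(n_per_strand)
  xy2 <- sweep(xy2, 2, offset, "+")
  at2 <- s1$atoms[, c("name", "resname", "resid", "chain")]
  at2$resid <- at2$resid + n_per_strand
  at1 <- s1$atoms[, c("name", "resname", "resid", "chain")]
  sd_system(rbind(at1, at2), rbind(xy1, xy2))
}

# Offset placing the rotated strand for antiparallel pairing; calibrated
# once by least-squares placement of the N-H...O=C rungs for residues
# 3<->4' and 5<->2' on the extended template.
.hairpin_offset <- function(n_per_strand) c(15.859, -1.522, 3.365)

# --- planted covariance modes ----------------------------------------------

#' Planted covariance mode
#'
#' @param eigenvector Unit-length numeric vector of length 3N.
#' @param eigenvalue Variance along the mode (Angstrom^2, >= 0).
#' @return List of class `sd_planted_mode`.
#' @export
planted_mode <- function(eigenvector, eigenvalue) {
  nrm <- sqrt(sum(eigenvector^2))
  if (abs(nrm - 1) > 1e-8) stop("mode eigenvector must have unit norm")
  if (eigenvalue < 0) stop("mode eigenvalue must be >= 0")
  structure(list(eigenvector = eigenvector, eigenvalue = eigenvalue),
            class = "sd_planted_mode")
}

#' Random planted modes orthogonal to rigid-body motion
#'
#' Draws random directions in the 3N configuration space of the selected
#' atoms, projects out the six rigid-body modes (translations and
#' rotations about the selection centroid) and orthonormalises, so that
#' least-squares fitting before covariance analysis does not drain
#' variance from the planted modes.
#'
#' @param sys An [sd_system()].
#' @param eigenvalues Variances (Angstrom^2), one per requested mode,
#'   descending.
#' @param seed Integer seed.
#' @param selection Atoms the modes act on (default all).
#' @return List of [planted_mode()] objects.
#' @export
make_planted_modes <- function(sys, eigenvalues, seed = 1L,
                               selection = NULL) {
  set.seed(seed)
  n <- n_atoms(sys)
  if (is.null(selection)) selection <- seq_len(n)
  x <- sweep(sys$reference[selection, , drop = FALSE], 2,
             colMeans(sys$reference[selection, , drop = FALSE]))
  ns <- length(selection)
  rigid <- matrix(0, 3L * ns, 6L)
  for (k in 1:3) rigid[seq(k, 3L * ns, by = 3L), k] <- 1
  # infinitesimal rotations about the three axes
  axes <- diag(3)
  for (k in 1:3) {
    w <- axes[, k]
    rxw <- cbind(w[2] * x[, 3] - w[3] * x[, 2],
                 w[3] * x[, 1] - w[1] * x[, 3],
                 w[1] * x[, 2] - w[2] * x[, 1])
    rigid[, 3L + k] <- mat_to_xyz(rxw)
  }
  basis <- qr.Q(qr(rigid))
  modes <- vector("list", length(eigenvalues))
  kept <- NULL
  for (m in seq_along(eigenvalues)) {
    v <- stats::rnorm(3L * ns)
    v <- v - basis %*% crossprod(basis, v)
    if (!is.null(kept)) v <- v - kept %*% crossprod(kept, v)
    v <- v / sqrt(sum(v^2))
    kept <- cbind(kept, v)
    full <- numeric(3L * n)
    cols <- as.vector(rbind(3L * (selection - 1L) + 1L,
                            3L * (selection - 1L) + 2L, 3L * selection))
    full[cols] <- v
    modes[[m]] <- planted_mode(full, eigenvalues[m])
  }
  modes
}

#' Trajectory with planted Gaussian covariance modes
#'
#' Frames are `reference + sum_k z_k(t) v_k` with independent
#' `z_k ~ N(0, lambda_k)` per frame, so the population covariance is
#' exactly `sum_k lambda_k v_k v_k^T`.
#'
#' @param sys An [sd_system()].
#' @param modes List of [planted_mode()] objects, mutually orthogonal.
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed.
#' @param dt_ps Frame spacing (ps).
#' @return An [sd_trajectory()].
#' @export
gen_gaussian_mode_trajectory <- function(sys, modes, n_frames, seed = 1L,
                                         dt_ps = 10) {
  stopifnot(n_frames >= 2)
  ref <- mat_to_xyz(sys$reference)
  if (length(modes)) {
    V <- vapply(modes, function(m) m$eigenvector, numeric(length(ref)))
    V <- matrix(V, ncol = length(modes))
    G <- crossprod(V)
    if (max(abs(G - diag(ncol(V)))) > 1e-8) {
      stop("planted modes must be mutually orthogonal unit vectors")
    }
    lam <- vapply(modes, function(m) m$eigenvalue, numeric(1))
    set.seed(seed)
    Z <- matrix(stats::rnorm(n_frames * length(modes)), n_frames) %*%
      diag(sqrt(lam), nrow = length(lam))
    xyz <- matrix(rep(ref, each = n_frames), n_frames) + tcrossprod(Z, V)
  } else {
    xyz <- matrix(rep(ref, each = n_frames), n_frames)
  }
  sd_trajectory(sys, xyz, times = dt_ps * seq_len(n_frames))
}

# --- simple stochastic series ----------------------------------------------

#' Gaussian random walk
#'
#' Cumulative sum of i.i.d. `N(0, step_sd^2)` steps per dimension; the toy
#' model for the unconverged, diffusion-like regime of the leading
#' essential-dynamics projections.
#'
#' @param n_dims Number of dimensions.
#' @param step_sd Step standard deviation (0 gives a constant series).
#' @param n_frames Series length (>= 2).
#' @param seed Integer seed.
#' @return Numeric vector (`n_dims = 1`) or `n_frames x n_dims` matrix.
#' @export
gen_random_walk <- function(n_dims = 1L, step_sd = 1, n_frames = 1000L,
                            seed = 1L) {
  if (n_frames < 2L) stop("random walk needs at least 2 frames")
  if (step_sd < 0) stop("step_sd must be >= 0")
  set.seed(seed)
  steps <- matrix(stats::rnorm(n_frames * n_dims, sd = step_sd), n_frames)
  w <- apply(steps, 2, cumsum)
  if (n_dims == 1L) as.vector(w) else w
}

#' Two-state Markov hopping series
#'
#' A two-state chain with stationary ratio `p_B / p_A = exp(-delta_F)`
#' (detailed balance: hop probabilities `hop_prob * min(1, exp(-+delta_F))`),
#' emitting the state centre plus Gaussian jitter of standard deviation
#' 0.05 x the state separation.
#'
#' @param delta_F Free-energy difference F_B - F_A in kT units.
#' @param hop_prob Base hop attempt probability per step (0 < p < 1).
#' @param n_frames Series length.
#' @param seed Integer seed.
#' @param centers State centres (length 2).
#' @return List with `series`, `states` (1 = A, 2 = B) and `centers`.
#' @export
gen_two_state <- function(delta_F, hop_prob = 0.1, n_frames = 10000L,
                          seed = 1L, centers = c(-1, 1)) {
  if (hop_prob <= 0 || hop_prob >= 1) stop("hop_prob must be in (0, 1)")
  set.seed(seed)
  p_ab <- hop_prob * min(1, exp(-delta_F))
  p_ba <- hop_prob * min(1, exp(delta_F))
  states <- integer(n_frames)
  u <- stats::runif(n_frames)
  s <- 1L
  for (i in seq_len(n_frames)) {
    if (s == 1L) { if (u[i] < p_ab) s <- 2L } else if (u[i] < p_ba) s <- 1L
    states[i] <- s
  }
  jitter_sd <- 0.05 * abs(diff(centers))
  series <- centers[states] + stats::rnorm(n_frames, sd = jitter_sd)
  list(series = series, states = states, centers = centers)
}

#' Box of diffusing or arrested solvent particles
#'
#' Single-site waters in a cubic periodic box: `"diffusive"` particles
#' follow independent Gaussian random walks (wrapped into the box),
#' `"arrested"` particles follow an Ornstein-Uhlenbeck process around
#' fixed cage centres (glass-like, plateauing MSD).
#'
#' @param n_particles Number of waters.
#' @param box_length Cubic box edge (Angstrom).
#' @param n_frames Number of frames.
#' @param mode `"diffusive"` or `"arrested"`.
#' @param step_sd Per-coordinate step SD for diffusive mode (Angstrom).
#' @param cage_sd Stationary per-coordinate SD for arrested mode.
#' @param relax Per-step OU memory factor (arrested mode, in [0,1)).
#' @param dt_ps Frame spacing (ps).
#' @param seed Integer seed.
#' @return An [sd_trajectory()] with a periodic box.
#' @export
gen_solvent_box <- function(n_particles, box_length, n_frames,
                            mode = c("diffusive", "arrested"),
                            step_sd = 0.5, cage_sd = 0.5, relax = 0.9,
                            dt_ps = 1, seed = 1L) {
  mode <- match.arg(mode)
  set.seed(seed)
  at <- data.frame(name = "OW", resname = "SOL",
                   resid = seq_len(n_particles), chain = "W",
                   stringsAsFactors = FALSE)
  start <- matrix(stats::runif(3 * n_particles, 0, box_length),
                  n_particles)
  xyz <- matrix(NA_real_, n_frames, 3L * n_particles)
  pos <- start
  for (k in seq_len(n_frames)) {
    if (k > 1L) {
      if (mode == "diffusive") {
        pos <- pos + matrix(stats::rnorm(3 * n_particles, sd = step_sd),
                            n_particles)
      } else {
        noise_sd <- cage_sd * sqrt(1 - relax^2)
        pos <- start + relax * (pos - start) +
          matrix(stats::rnorm(3 * n_particles, sd = noise_sd), n_particles)
      }
    }
    xyz[k, ] <- mat_to_xyz(pos %% box_length)
  }
  sys <- sd_system(at, xyz_to_mat(xyz[1, ]))
  sd_trajectory(sys, xyz, times = dt_ps * seq_len(n_frames),
                box = rep(box_length, 3))
}

# --- toy protein-solvent system with a hydrogen-bond schedule ---------------

#' Toy protein-solvent system with a scripted hydrogen-bond schedule
#'
#' Builds an ideal peptide plus water box in which selected
#' donor-hydrogen-acceptor triples are switched on and off per frame by
#' construction: on-frames place the acceptor collinear with the
#' donor-hydrogen bond at 3.0 Angstrom (satisfying both detection
#' criteria), off-frames at 3.8 Angstrom (violating the 3.5 Angstrom
#' distance cutoff by exactly 0.3). The schedule is therefore an exact
#' oracle for [detect_hbonds_frame()] and [hbond_statistics()].
#'
#' Scheduled bond classes cycle through M-M, M-S, S-S, M-solv, S-solv
#' ("M"/"S" = mainchain/side chain, "solv" = water). Donor residues are
#' spaced four apart on an extended chain so scheduled sites do not
#' interact; moved acceptors are always acceptor-only atoms (backbone O,
#' aspartate OD1, or a water whose hydrogens point away from the
#' protein).
#'
#' @param n_residues Chain length; needs `>= 4 * n_bonds + 2` residues
#'   for `n_bonds` scheduled bonds.
#' @param geometry `"extended"` (required for scheduling) or `"helix"`.
#' @param n_waters Unscheduled waters placed around the protein.
#' @param schedule `"auto"` (random on/off masks), `"none"`, or a list
#'   with `classes` (character vector) and `mask`
#'   (`n_bonds x n_frames` 0/1 matrix).
#' @param n_frames Number of frames (ignored when an explicit mask is
#'   given).
#' @param n_bonds Number of scheduled bonds for `"auto"`.
#' @param shell_fraction Fraction of unscheduled waters placed in the
#'   hydration shell at 4.0 Angstrom from the protein surface (beyond
#'   hydrogen-bond range); the rest sit in the far field, at least 8
#'   Angstrom away.
#' @param seed Integer seed.
#' @param dt_ps Frame spacing (ps).
#' @return List with `system`, `trajectory` and `schedule` (data frame
#'   `donor`, `hydrogen`, `acceptor`, `class` plus the 0/1 `mask` matrix
#'   as an attribute; `NULL` for `schedule = "none"`).
#' @export
gen_toy_protein_solvent <- function(n_residues = 22L,
                                    geometry = c("extended", "helix"),
                                    n_waters = 6L, schedule = "auto",
                                    n_frames = 20L, n_bonds = 5L,
                                    shell_fraction = 0.5, seed = 1L,
                                    dt_ps = 10) {
  geometry <- match.arg(geometry)
  set.seed(seed)
  classes_all <- c("M-M", "M-S", "S-S", "M-solv", "S-solv")
  if (identical(schedule, "none")) {
    cls <- character(0)
  } else if (identical(schedule, "auto")) {
    cls <- classes_all[(seq_len(n_bonds) - 1L) %% 5L + 1L]
  } else {
    cls <- schedule$classes
    if (!all(cls %in% classes_all)) {
      stop("schedule classes must be among ", paste(classes_all,
                                                    collapse = ", "))
    }
    n_frames <- ncol(schedule$mask)
  }
  nb <- length(cls)
  if (nb && geometry != "extended") {
    stop("hydrogen-bond scheduling requires the extended geometry")
  }
  if (nb && n_residues < 4L * nb) {
    stop(sprintf("need at least %d residues for %d scheduled bonds",
                 4L * nb, nb))
  }
  # donor residues every 4 from residue 2; each bond's acceptor atom comes
  # from the residue two past its donor (the atom is relocated per frame,
  # so only distinctness matters)
  don_res <- 2L + 4L * (seq_len(nb) - 1L)
  acc_res <- don_res + 2L
  sidechain <- character(0)
  for (b in seq_len(nb)) {
    if (cls[b] %in% c("M-S", "S-S", "S-solv")) {
      sidechain[as.character(don_res[b])] <- "ser"
    }
    if (cls[b] == "S-S") sidechain[as.character(acc_res[b])] <- "asp"
  }
  sys_p <- gen_peptide_system(n_residues, geometry,
                              sidechain = if (length(sidechain)) sidechain
                                          else NULL)
  at_p <- sys_p$atoms
  xyz_p <- sys_p$reference
  find_atom <- function(resid, name) {
    i <- which(at_p$resid == resid & at_p$name == name)
    if (!length(i)) stop(sprintf("template lacks atom %s in residue %d",
                                 name, resid))
    i[1]
  }
  # resolve scheduled triples and the count of scheduled waters
  sched <- NULL
  n_sched_wat <- sum(cls %in% c("M-solv", "S-solv"))
  wat_counter <- 0L
  if (nb) {
    don_at <- hyd_at <- acc_at <- integer(nb)
    acc_is_water <- logical(nb)
    for (b in seq_len(nb)) {
      if (cls[b] %in% c("M-M", "M-solv")) {
        don_at[b] <- find_atom(don_res[b], "N")
        hyd_at[b] <- find_atom(don_res[b], "H")
      } else {
        don_at[b] <- find_atom(don_res[b], "OG")
        hyd_at[b] <- find_atom(don_res[b], "HG")
      }
      if (cls[b] %in% c("M-M", "M-S")) {
        acc_at[b] <- find_atom(acc_res[b], "O")
      } else if (cls[b] == "S-S") {
        acc_at[b] <- find_atom(acc_res[b], "OD1")
      } else {
        acc_is_water[b] <- TRUE
      }
    }
  }
  # water block: scheduled waters first, then shell, then bulk
  prot_heavy <- which(!at_p$is_hydrogen)
  centroid <- colMeans(xyz_p)
  wat_rows <- list(); wat_xyz <- list()
  add_water <- function(opos, udir) {
    udir <- udir / sqrt(sum(udir^2))
    v <- if (abs(udir[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v <- v - sum(v * udir) * udir; v <- v / sqrt(sum(v^2))
    half <- 104.52 / 2 * pi / 180
    h1 <- opos + 0.9572 * (cos(half) * udir + sin(half) * v)
    h2 <- opos + 0.9572 * (cos(half) * udir - sin(half) * v)
    rbind(opos, h1, h2)
  }
  n_total_wat <- n_sched_wat + n_waters
  wat_base_o <- matrix(NA_real_, max(n_total_wat, 1L), 3L)
  wat_dir <- matrix(NA_real_, max(n_total_wat, 1L), 3L)
  w <- 0L
  if (nb) {
    for (b in seq_len(nb)) {
      if (!acc_is_water[b]) next
      w <- w + 1L
      u <- xyz_p[hyd_at[b], ] - xyz_p[don_at[b], ]
      u <- u / sqrt(sum(u^2))
      wat_base_o[w, ] <- xyz_p[don_at[b], ] + 3.8 * u
      wat_dir[w, ] <- u
      acc_at[b] <- -w   # marker: scheduled water index
    }
  }
  # shell + bulk waters
  n_shell <- round(shell_fraction * n_waters)
  surf_cand <- prot_heavy[order(xyz_p[prot_heavy, 3])]
  for (j in seq_len(n_waters)) {
    w <- w + 1L
    if (j <= n_shell) {
      anchor <- prot_heavy[1L + ((j - 1L) * 7L) %% length(prot_heavy)]
      u <- xyz_p[anchor, ] - centroid
      u[3] <- u[3] + 2 * j   # spread shell waters out of plane
      u <- u / sqrt(sum(u^2))
      wat_base_o[w, ] <- xyz_p[anchor, ] + 4.0 * u
    } else {
      wat_base_o[w, ] <- c(max(xyz_p[, 1]) + 10 + 4 * j,
                           max(xyz_p[, 2]) + 10, 5 * (j %% 3))
      u <- c(0, 1, 0)
    }
    wat_dir[w, ] <- u
  }
  for (k in seq_len(n_total_wat)) {
    wb <- add_water(wat_base_o[k, ], wat_dir[k, ])
    wat_rows[[k]] <- data.frame(name = c("OW", "HW1", "HW2"),
                                resname = "SOL",
                                resid = n_residues + k, chain = "W",
                                stringsAsFactors = FALSE)
    wat_xyz[[k]] <- wb
  }
  atoms <- rbind(at_p[, c("name", "resname", "resid", "chain")],
                 if (n_total_wat) do.call(rbind, wat_rows))
  ref <- rbind(xyz_p, if (n_total_wat) do.call(rbind, wat_xyz))
  sys <- sd_system(atoms, ref)
  n_prot_atoms <- nrow(at_p)
  wat_o_idx <- function(k) n_prot_atoms + 3L * (k - 1L) + 1L
  # schedule mask
  if (nb) {
    mask <- if (is.list(schedule)) {
      m <- as.matrix(schedule$mask)
      storage.mode(m) <- "integer"
      m
    } else {
      matrix(stats::rbinom(nb * n_frames, 1L, 0.5), nb, n_frames)
    }
    stopifnot(nrow(mask) == nb)
    acc_resolved <- ifelse(acc_at < 0L, wat_o_idx(-acc_at), acc_at)
    sched <- data.frame(donor = don_at, hydrogen = hyd_at,
                        acceptor = acc_resolved, class = cls,
                        stringsAsFactors = FALSE)
    if (!all(sys$atoms$donor[sched$donor])) {
      stop("schedule references a non-donor atom")
    }
    if (!all(sys$atoms$acceptor[sched$acceptor])) {
      stop("schedule references a non-acceptor atom")
    }
    attr(sched, "mask") <- mask
  }
  # frames
  xyz <- matrix(rep(mat_to_xyz(ref), each = n_frames), n_frames)
  if (nb) {
    for (b in seq_len(nb)) {
      u <- ref[sched$hydrogen[b], ] - ref[sched$donor[b], ]
      u <- u / sqrt(sum(u^2))
      dpos <- ref[sched$donor[b], ]
      for (f in seq_len(n_frames)) {
        dist <- if (mask[b, f] == 1L) 3.0 else 3.8
        target <- dpos + dist * u
        a <- sched$acceptor[b]
        if (acc_at[b] < 0L) {
          wb <- add_water(target, u)
          for (q in 0:2) xyz[f, (3L * (a - 1L + q) + 1L):(3L * (a + q))] <-
            wb[q + 1L, ]
        } else {
          xyz[f, (3L * (a - 1L) + 1L):(3L * a)] <- target
        }
      }
    }
  }
  traj <- sd_trajectory(sys, xyz, times = dt_ps * seq_len(n_frames))
  list(system = sys, trajectory = traj, schedule = sched)
}
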