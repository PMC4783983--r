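# ---------------------------------------------------------------------------
# Secondary structure by Kabsch-Sander backbone hydrogen-bond energies
# (reduced alphabet H/G/E/T/C; no pi-helix, bend or isolated-bridge class)
# ---------------------------------------------------------------------------

# Kabsch-Sander electrostatic HB energy prefactor, kcal/mol * Angstrom:
# q1*q2*f = 0.42 * 0.20 * 332
.ks_prefactor <- 27.888
.ks_cutoff <- -0.5

# Backbone geometry per residue: indices of N, CA, C, O (+ amide H if
# present). Returns NULL rows for incomplete residues.
backbone_index <- function(sys) {
  at <- sys$atoms
  res <- sort(unique(at$resid[at$is_solute]))
  pick <- function(r, nm) {
    i <- which(at$resid == r & at$name == nm & at$is_solute)
    if (length(i)) i[1] else NA_integer_
  }
  data.frame(resid = res,
             N = vapply(res, pick, integer(1), nm = "N"),
             H = vapply(res, pick, integer(1), nm = "H"),
             CA = vapply(res, pick, integer(1), nm = "CA"),
             C = vapply(res, pick, integer(1), nm = "C"),
             O = vapply(res, pick, integer(1), nm = "O"))
}

# Ideal amide H position: 1.0 A from N along the bisector extension of the
# C(prev)-N and CA-N bonds (in-plane, trans to the carbonyl side).
infer_amide_h <- function(coords, n_i, ca_i, cprev_i) {
  n <- coords[n_i, ]
  u1 <- n - coords[cprev_i, ]; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- n - coords[ca_i, ]; u2 <- u2 / sqrt(sum(u2^2))
  b <- u1 + u2
  nb <- sqrt(sum(b^2))
  if (nb < 1e-8) return(n + c(1, 0, 0))
  n + b / nb
}

# Backbone hydrogen-bond matrix: hb[d, a] is TRUE when the N-H of residue
# d donates to the C=O of residue a with Kabsch-Sander energy < -0.5
# kcal/mol. Residues d == a and |d - a| == 1 are excluded.
ks_hbond_matrix <- function(coords, sys, bb = NULL) {
  if (is.null(bb)) bb <- backbone_index(sys)
  nres <- nrow(bb)
  hb <- matrix(FALSE, nres, nres)
  if (nres < 3L) return(hb)
  hpos <- matrix(NA_real_, nres, 3L)
  for (d in seq_len(nres)) {
    if (!is.na(bb$H[d])) {
      hpos[d, ] <- coords[bb$H[d], ]
    } else if (d > 1L && !anyNA(c(bb$N[d], bb$CA[d], bb$C[d - 1L]))) {
      hpos[d, ] <- infer_amide_h(coords, bb$N[d], bb$CA[d], bb$C[d - 1L])
    }
  }
  for (d in seq_len(nres)) {
    if (is.na(bb$N[d]) || anyNA(hpos[d, ])) next
    npos <- coords[bb$N[d], ]
    for (a in seq_len(nres)) {
      if (abs(d - a) < 2L) next
      if (is.na(bb$C[a]) || is.na(bb$O[a])) next
      opos <- coords[bb$O[a], ]; cpos <- coords[bb$C[a], ]
      r_on <- sqrt(sum((opos - npos)^2))
      if (r_on > 5.2) next   # energy cannot reach -0.5 beyond this
      r_ch <- sqrt(sum((cpos - hpos[d, ])^2))
      r_oh <- sqrt(sum((opos - hpos[d, ])^2))
      r_cn <- sqrt(sum((cpos - npos)^2))
      e <- .ks_prefactor * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
      hb[d, a] <- e < .ks_cutoff
    }
  }
  hb
}

#' Assign secondary structure (reduced DSSP alphabet)
#'
#' Backbone hydrogen bonds are scored with the Kabsch-Sander electrostatic
#' energy `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol
#' (bond if `E < -0.5`); amide hydrogens are taken from the structure or
#' placed geometrically when absent. Labels: `H` (alpha helix, two or more
#' consecutive i->i+4 turns), `G` (3/10 helix from i->i+3 runs), `E`
#' (parallel/antiparallel bridge patterns), `T` (isolated 3- or 4-turns),
#' `C` otherwise, with priority `H > E > G > T`.
#'
#' @param coords N x 3 frame coordinates.
#' @param sys An [sd_system()].
#' @return Character vector of per-residue labels (solute residues, in
#'   residue order).
#' @export
assign_secondary_structure <- function(coords, sys) {
  bb <- backbone_index(sys)
  nres <- nrow(bb)
  if (nres < 3L) {
    warning("chain shorter than 3 residues: all coil")
    return(rep("C", nres))
  }
  hb <- ks_hbond_matrix(coords, sys, bb)
  turn4 <- vapply(seq_len(nres), function(i)
    i + 4L <= nres && hb[i + 4L, i], logical(1))
  turn3 <- vapply(seq_len(nres), function(i)
    i + 3L <= nres && hb[i + 3L, i], logical(1))
  isH <- isG <- isE <- isT <- rep(FALSE, nres)
  for (i in seq_len(nres - 1L)) {
    if (turn4[i] && i > 1L && turn4[i - 1L]) isH[i:(i + 3L)] <- TRUE
    if (turn3[i] && i > 1L && turn3[i - 1L]) isG[i:(i + 2L)] <- TRUE
  }
  # bridge patterns; hb[d, a]: N-H of d to C=O of a
  for (i in 2:(nres - 1L)) {
    for (j in 2:(nres - 1L)) {
      if (abs(i - j) < 3L) next
      par <- (hb[i, j - 1L] && hb[j, i + 1L]) ||
             (hb[j - 1L, i] && hb[i + 1L, j])
      anti <- (hb[i, j] && hb[j, i]) ||
              (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (par || anti) { isE[i] <- TRUE; isE[j] <- TRUE }
    }
  }
  for (i in seq_len(nres)) {
    if (turn4[i] && i + 3L <= nres) isT[(i + 1L):(i + 3L)] <- TRUE
    if (turn3[i] && i + 2L <= nres) isT[(i + 1L):(i + 2L)] <- TRUE
  }
  lab <- rep("C", nres)
  lab[isT] <- "T"
  lab[isG] <- "G"
  lab[isE] <- "E"
  lab[isH] <- "H"
  lab
}
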