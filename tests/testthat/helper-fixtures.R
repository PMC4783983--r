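# Shared fixture builders. Everything is generated in code; nothing is
# read from disk.

# Random cloud of isolated donors (N with one attached H) and acceptors
# (carbonyl O), one residue per group, inside a cube. Used to compare the
# hydrogen-bond detector against brute-force enumeration.
make_hb_cloud <- function(n_donors, n_acceptors, seed, side = 12) {
  set.seed(seed)
  rows <- list(); xyz <- list()
  rid <- 0L
  for (i in seq_len(n_donors)) {
    rid <- rid + 1L
    p <- runif(3, 0, side)
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    rows[[length(rows) + 1L]] <- data.frame(
      name = c("N", "H"), resname = "ALA", resid = rid, chain = "A",
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- rbind(p, p + u)
  }
  for (i in seq_len(n_acceptors)) {
    rid <- rid + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      name = "O", resname = "ALA", resid = rid, chain = "A",
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- matrix(runif(3, 0, side), 1)
  }
  sd_system(do.call(rbind, rows), do.call(rbind, xyz))
}

# Brute-force hydrogen-bond enumeration over every donor/H/acceptor
# triple; deliberately naive (plain loops, no shared code with the
# detector's candidate pruning).
brute_force_hbonds <- function(coords, sys, dcut = 3.5, acut = 120) {
  at <- sys$atoms
  out <- NULL
  for (d in which(at$donor)) {
    for (h in sys$h_attached[[d]]) {
      for (a in which(at$acceptor)) {
        if (a == d) next
        dda <- sqrt(sum((coords[d, ] - coords[a, ])^2))
        if (dda > dcut || dda <= 1.8) next
        v1 <- coords[d, ] - coords[h, ]
        v2 <- coords[a, ] - coords[h, ]
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= acut) out <- rbind(out, c(d, h, a))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0)))
  }
  out <- data.frame(donor = out[, 1], hydrogen = out[, 2],
                    acceptor = out[, 3])
  out[order(out$donor, out$hydrogen, out$acceptor), , drop = FALSE]
}

# Densely packed pseudo-residue ball (one CA per residue on a cubic grid
# clipped to a sphere) whose jitter grows from core to surface, so the
# burial-depth/RMSF relation is planted by construction. The 3 A grid
# keeps interior atoms solvent-inaccessible to a 1.4 A probe.
two_shell_trajectory <- function(radius = 9, spacing = 3,
                                 sd_core = 0.05, sd_surface = 0.35,
                                 n_frames = 40, seed = 1) {
  set.seed(seed)
  g <- seq(-radius, radius, by = spacing)
  ref <- as.matrix(expand.grid(x = g, y = g, z = g))
  r <- sqrt(rowSums(ref^2))
  keep <- r <= radius
  ref <- ref[keep, , drop = FALSE]
  r <- r[keep]
  n <- nrow(ref)
  at <- data.frame(name = "CA", resname = "GLY", resid = seq_len(n),
                   chain = "A", stringsAsFactors = FALSE)
  sys <- sd_system(at, ref)
  sds <- sd_core + (sd_surface - sd_core) * r / radius
  xyz <- matrix(NA_real_, n_frames, 3 * n)
  base <- as.vector(t(ref))
  for (k in seq_len(n_frames)) {
    xyz[k, ] <- base + rnorm(3 * n, sd = rep(sds, each = 3))
  }
  sd_trajectory(sys, xyz, times = 10 * seq_len(n_frames))
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
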