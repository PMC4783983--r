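# ---------------------------------------------------------------------------
# Free-energy landscapes: Boltzmann histogram inversion, an overdamped
# Langevin sampler on analytic 1D potentials, well-tempered metadynamics
# ---------------------------------------------------------------------------

#' Free-energy surface from a histogram of collective-variable samples
#'
#' Boltzmann inversion `F_b = -kT ln(n_b / n_max)` over occupied bins; the
#' most populated bin sits at 0 and empty bins are masked (`NA`), never
#' reported as zero. Accepts a 1D series or a 2-column matrix (2D CV).
#'
#' @param samples Numeric vector (1D) or 2-column matrix (2D).
#' @param bins Number of bins per dimension (default 50).
#' @param kT Thermal energy in kJ/mol (see [kT_kJmol()]).
#' @param edges Optional explicit bin edges (vector, or list of two for
#'   2D); default: equal-width bins over the data range.
#' @return Object of class `sd_fel`: `centers` (vector or list of two),
#'   `free_energy` (vector or matrix, kJ/mol, `NA` = unvisited), `counts`,
#'   `kT`, `ndim`.
#' @export
histogram_fel <- function(samples, bins = 50L, kT, edges = NULL) {
  if (is.matrix(samples) && ncol(samples) == 2L) {
    if (nrow(samples) == 0L) stop("no samples for free-energy histogram")
    if (is.null(edges)) {
      edges <- list(seq(min(samples[, 1]), max(samples[, 1]),
                        length.out = bins + 1L),
                    seq(min(samples[, 2]), max(samples[, 2]),
                        length.out = bins + 1L))
    }
    b1 <- findInterval(samples[, 1], edges[[1]], rightmost.closed = TRUE,
                       all.inside = TRUE)
    b2 <- findInterval(samples[, 2], edges[[2]], rightmost.closed = TRUE,
                       all.inside = TRUE)
    counts <- matrix(0L, length(edges[[1]]) - 1L, length(edges[[2]]) - 1L)
    for (i in seq_along(b1)) counts[b1[i], b2[i]] <- counts[b1[i], b2[i]] + 1L
    fe <- -kT * log(counts / max(counts))
    fe[counts == 0L] <- NA_real_
    centers <- list((head(edges[[1]], -1) + tail(edges[[1]], -1)) / 2,
                    (head(edges[[2]], -1) + tail(edges[[2]], -1)) / 2)
    ndim <- 2L
  } else {
    samples <- as.numeric(samples)
    if (!length(samples)) stop("no samples for free-energy histogram")
    if (is.null(edges)) {
      rng <- range(samples)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      edges <- seq(rng[1], rng[2], length.out = bins + 1L)
    }
    b <- findInterval(samples, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    counts <- tabulate(b, nbins = length(edges) - 1L)
    fe <- -kT * log(counts / max(counts))
    fe[counts == 0L] <- NA_real_
    centers <- (head(edges, -1) + tail(edges, -1)) / 2
    ndim <- 1L
  }
  structure(list(centers = centers, free_energy = fe, counts = counts,
                 kT = kT, ndim = ndim),
            class = "sd_fel")
}

#' @export
print.sd_fel <- function(x, ...) {
  occ <- sum(!is.na(x$free_energy))
  cat(sprintf("sd_fel: %dD, %d occupied bins, range 0..%.3g kJ/mol (kT = %.4g)\n",
              x$ndim, occ, max(x$free_energy, na.rm = TRUE), x$kT))
  invisible(x)
}

# --- analytic 1D potentials -------------------------------------------------

#' Analytic collective-variable potentials
#'
#' Builders for the 1D potentials used by [langevin_sample()] and
#' [wt_metadynamics()]: each returns a list with `f(s)` (kJ/mol) and
#' `grad(s)` (kJ/mol per CV unit).
#'
#' `double_well_potential(barrier, half_sep)` is
#' `U(s) = barrier * ((s/half_sep)^2 - 1)^2`: minima at +/- `half_sep`,
#' barrier height `barrier` at s = 0.
#'
#' @param kappa Harmonic force constant (kJ/mol per CV unit^2).
#' @param center Harmonic minimum position.
#' @return Potential object (list of `f`, `grad`).
#' @export
harmonic_potential <- function(kappa, center = 0) {
  list(f = function(s) 0.5 * kappa * (s - center)^2,
       grad = function(s) kappa * (s - center))
}

#' @param barrier Barrier height at s = 0 (kJ/mol).
#' @param half_sep Half the well separation (minima at +/- half_sep).
#' @rdname harmonic_potential
#' @export
double_well_potential <- function(barrier, half_sep = 2) {
  list(f = function(s) barrier * ((s / half_sep)^2 - 1)^2,
       grad = function(s) 4 * barrier * s * ((s / half_sep)^2 - 1) /
         half_sep^2)
}

#' @rdname harmonic_potential
#' @export
flat_potential <- function() {
  list(f = function(s) rep(0, length(s)), grad = function(s) rep(0, length(s)))
}

#' Overdamped Langevin sampling of a 1D potential
#'
#' Euler-Maruyama update `s <- s - grad U(s)/friction dt +
#' sqrt(2 kT dt / friction) xi`, `xi ~ N(0,1)`. The integration is stable
#' for `dt` well below `friction / max|U''|`.
#'
#' @param potential Potential object (see [harmonic_potential()]).
#' @param kT Thermal energy (kJ/mol); 0 gives deterministic relaxation.
#' @param friction Friction coefficient (kJ/mol ps per CV unit^2).
#' @param dt Time step (ps).
#' @param n_steps Number of steps.
#' @param seed Integer seed.
#' @param s0 Starting point (default 0).
#' @param guard Abort when |s| exceeds this bound (integration divergence).
#' @return Numeric vector of length `n_steps + 1` (including `s0`).
#' @export
langevin_sample <- function(potential, kT, friction = 1, dt = 0.01,
                            n_steps = 10000L, seed = 1L, s0 = 0,
                            guard = 1e3) {
  set.seed(seed)
  s <- numeric(n_steps + 1L)
  s[1] <- s0
  noise_amp <- sqrt(2 * kT * dt / friction)
  xi <- if (kT > 0) stats::rnorm(n_steps) else numeric(n_steps)
  g <- potential$grad
  cur <- s0
  for (i in seq_len(n_steps)) {
    cur <- cur - g(cur) / friction * dt + noise_amp * xi[i]
    if (abs(cur) > guard) {
      stop(sprintf("Langevin integration diverged at step %d (|s| > %g); reduce dt = %g",
                   i, guard, dt))
    }
    s[i + 1L] <- cur
  }
  s
}

#' Well-tempered metadynamics parameters
#'
#' Defaults follow common practice for eigenvector-projection collective
#' variables: Gaussian hills of initial height 0.4 kJ/mol and width 0.35
#' (CV units, nm for projection CVs) deposited every 2 ps with bias factor
#' 10.
#'
#' @param hill_height Initial Gaussian hill height w0 (kJ/mol).
#' @param hill_width Gaussian width sigma (CV units).
#' @param stride_ps Deposition period tau (ps).
#' @param bias_factor Bias factor gamma (> 1).
#' @param temperature Temperature (K).
#' @param run_length_ns Run length (ns).
#' @param dt_ps Integration time step (ps). The default keeps the
#'   per-step random displacement (`sqrt(2 kT dt / friction)`, here ~0.1
#'   CV units) well below the hill width, so the walker resolves the bias
#'   it deposits; enlarge with care.
#' @param friction Langevin friction (kJ/mol ps per CV unit^2).
#' @return List of class `sd_metad_params`.
#' @export
metadynamics_params <- function(hill_height = 0.4, hill_width = 0.35,
                                stride_ps = 2, bias_factor = 10,
                                temperature = 300, run_length_ns = 1,
                                dt_ps = 0.01, friction = 5) {
  if (bias_factor <= 1) stop("bias factor must exceed 1")
  stopifnot(hill_height > 0, hill_width > 0, stride_ps > 0, dt_ps > 0,
            run_length_ns > 0, friction > 0)
  structure(list(hill_height = hill_height, hill_width = hill_width,
                 stride_ps = stride_ps, bias_factor = bias_factor,
                 temperature = temperature, run_length_ns = run_length_ns,
                 dt_ps = dt_ps, friction = friction),
            class = "sd_metad_params")
}

#' Well-tempered metadynamics on an analytic 1D potential
#'
#' Overdamped Langevin dynamics with a history-dependent bias: every
#' `stride_ps` a Gaussian hill of height
#' `w = w0 exp(-V_bias(s) / ((gamma - 1) kT))` is deposited at the current
#' CV value. The bias (and its gradient) is kept on a grid of spacing at
#' most `hill_width / 5`, so each step costs O(1). The free-energy
#' estimate is `F_hat = -(gamma / (gamma - 1)) V_bias`, shifted so its
#' minimum is 0.
#'
#' @param potential Potential object (list of `f`, `grad`), kJ/mol.
#' @param params An [metadynamics_params()].
#' @param seed Integer seed.
#' @param grid_min,grid_max CV-space guard bounds; the walker is reflected
#'   at the bounds and the bias grid spans them.
#' @param s0 Starting CV value.
#' @return Object of class `sd_metad`: `hills` (data frame `time_ps`,
#'   `center`, `height`), `centers`, `bias` (final V_bias on the grid),
#'   `fes` (instantaneous estimate from the final bias, min 0), `fes_avg`
#'   (shot-noise-reduced estimate from the bias shape time-averaged over
#'   the second half of the run, min 0), `series` (subsampled CV
#'   trajectory), `params`, `kT`.
#' @export
wt_metadynamics <- function(potential, params = metadynamics_params(),
                            seed = 1L, grid_min = -4, grid_max = 4,
                            s0 = NULL) {
  kT <- kT_kJmol(params$temperature)
  gamma <- params$bias_factor
  w0 <- params$hill_height
  sig <- params$hill_width
  dt <- params$dt_ps
  friction <- params$friction
  n_steps <- round(params$run_length_ns * 1000 / dt)
  stride <- max(1L, round(params$stride_ps / dt))
  ds <- sig / 5
  centers <- seq(grid_min, grid_max, by = ds)
  ng <- length(centers)
  V <- numeric(ng)
  dV <- numeric(ng)
  set.seed(seed)
  if (is.null(s0)) s0 <- (grid_min + grid_max) / 2
  cur <- s0
  noise_amp <- sqrt(2 * kT * dt / friction)
  xi <- stats::rnorm(n_steps)
  g <- potential$grad
  n_hills <- n_steps %/% stride
  hill_t <- numeric(n_hills); hill_c <- numeric(n_hills)
  hill_w <- numeric(n_hills)
  nh <- 0L
  Vsum <- numeric(ng); n_avg <- 0L
  avg_from <- n_hills %/% 2L
  keep_every <- max(1L, stride %/% 2L)
  series <- numeric(n_steps %/% keep_every)
  denom_wt <- (gamma - 1) * kT
  inv_ds <- 1 / ds
  for (i in seq_len(n_steps)) {
    # linear interpolation of the bias gradient on the grid
    u <- (cur - grid_min) * inv_ds
    j <- floor(u)
    if (j < 0) j <- 0 else if (j >= ng - 1L) j <- ng - 2L
    w <- u - j
    fbias <- (1 - w) * dV[j + 1L] + w * dV[j + 2L]
    cur <- cur - (g(cur) + fbias) / friction * dt + noise_amp * xi[i]
    # reflective guard bounds
    if (cur < grid_min) cur <- 2 * grid_min - cur
    if (cur > grid_max) cur <- 2 * grid_max - cur
    if (i %% stride == 0L) {
      u <- (cur - grid_min) * inv_ds
      j <- floor(u); if (j < 0) j <- 0 else if (j >= ng - 1L) j <- ng - 2L
      w <- u - j
      vb <- (1 - w) * V[j + 1L] + w * V[j + 2L]
      h <- w0 * exp(-vb / denom_wt)
      dd <- centers - cur
      gaus <- h * exp(-dd^2 / (2 * sig^2))
      V <- V + gaus
      dV <- dV - dd / sig^2 * gaus   # d/ds of the hill, evaluated on grid
      nh <- nh + 1L
      hill_t[nh] <- i * dt; hill_c[nh] <- cur; hill_w[nh] <- h
      if (nh > avg_from) {
        Vsum <- Vsum + V
        n_avg <- n_avg + 1L
      }
    }
    if (i %% keep_every == 0L) series[i %/% keep_every] <- cur
  }
  fes <- -gamma / (gamma - 1) * V
  fes <- fes - min(fes)
  fes_avg <- if (n_avg > 0L) {
    fa <- -gamma / (gamma - 1) * (Vsum / n_avg)
    fa - min(fa)
  } else fes
  structure(list(hills = data.frame(time_ps = hill_t[seq_len(nh)],
                                    center = hill_c[seq_len(nh)],
                                    height = hill_w[seq_len(nh)]),
                 centers = centers, bias = V, fes = fes,
                 fes_avg = fes_avg, series = series,
                 params = params, kT = kT),
            class = "sd_metad")
}

#' @export
print.sd_metad <- function(x, ...) {
  cat(sprintf("sd_metad: %d hills, FES range 0..%.3g kJ/mol on [%g, %g]\n",
              nrow(x$hills), max(x$fes), min(x$centers), max(x$centers)))
  invisible(x)
}

#' Write a metadynamics hill log in PLUMED-style HILLS layout
#' @param metad An `sd_metad` result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hills <- function(metad, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! FIELDS time cv sigma height biasf", con)
  with(metad$hills, writeLines(sprintf("%.4f %.6f %.6f %.6f %.1f",
                                       time_ps, center,
                                       metad$params$hill_width, height,
                                       metad$params$bias_factor), con))
  invisible(path)
}

#' Reweighted free-energy estimate from a biased CV series
#'
#' Histogram of the visited CV values weighted by `exp(V_bias(s)/kT)`
#' under the final bias (a standard umbrella-style reweighting that
#' ignores the early time-dependence of the bias).
#'
#' @param metad An `sd_metad` result.
#' @param bins Number of bins.
#' @return An `sd_fel`.
#' @export
reweighted_fel <- function(metad, bins = 50L) {
  s <- metad$series
  vb <- stats::approx(metad$centers, metad$bias, xout = s, rule = 2)$y
  w <- exp((vb - max(vb)) / metad$kT)
  edges <- seq(min(metad$centers), max(metad$centers), length.out = bins + 1L)
  b <- findInterval(s, edges, rightmost.closed = TRUE, all.inside = TRUE)
  wsum <- vapply(seq_len(bins), function(i) sum(w[b == i]), numeric(1))
  fe <- -metad$kT * log(wsum / max(wsum))
  fe[wsum == 0] <- NA_real_
  structure(list(centers = (head(edges, -1) + tail(edges, -1)) / 2,
                 free_energy = fe, counts = tabulate(b, bins),
                 kT = metad$kT, ndim = 1L),
            class = "sd_fel")
}
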