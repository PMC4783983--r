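# Essential dynamics, projections, cosine content, combined ED

ed_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sys <- gen_peptide_system(60, "helix")
      ca <- which(sys$atoms$name == "CA")
      modes <- make_planted_modes(sys, c(4, 1), seed = 7, selection = ca)
      tr <- gen_gaussian_mode_trajectory(sys, modes, n_frames = 10000,
                                         seed = 11)
      cache <<- list(sys = sys, ca = ca, modes = modes, tr = tr,
                     ed = ed_decompose(tr, selection = ca))
    }
    cache
  }
})

sel_cols <- function(sel) as.vector(rbind(3 * (sel - 1) + 1,
                                          3 * (sel - 1) + 2, 3 * sel))

test_that("ED recovers planted eigenvalues and eigenvectors", {
  fx <- ed_fixture()
  expect_rel(fx$ed$eigenvalues[1], 4, 0.10)
  expect_rel(fx$ed$eigenvalues[2], 1, 0.10)
  expect_lt(fx$ed$eigenvalues[3], 0.05)
  cols <- sel_cols(fx$ca)
  for (k in 1:2) {
    ov <- abs(sum(fx$ed$eigenvectors[, k] *
                  fx$modes[[k]]$eigenvector[cols]))
    expect_gt(ov, 0.99)
  }
  # eigenvalue ordering and orthonormality
  expect_true(all(diff(fx$ed$eigenvalues) <= 1e-12))
  G <- crossprod(fx$ed$eigenvectors[, 1:10])
  expect_lt(max(abs(G - diag(10))), 1e-8)
  # nm^2 reporting: 1 nm^2 = 100 A^2
  expect_equal(fx$ed$eigenvalues_nm2, fx$ed$eigenvalues / 100)
})

test_that("static trajectories give zero eigenvalues and zero TMSF", {
  sys <- gen_peptide_system(10, "helix")
  tr <- gen_gaussian_mode_trajectory(sys, list(), 5, seed = 1)
  ed <- ed_decompose(tr)
  expect_lt(max(ed$eigenvalues), 1e-12)
  expect_lt(ed$tmsf, 1e-12)
  expect_error(ed_decompose(subset_frames(tr, 1)), "2 frames")
})

test_that("TMSF equals the covariance trace (sum of per-atom MSF)", {
  fx <- ed_fixture()
  X <- solvdyn:::fitted_selection_matrix(fx$tr, fx$ca,
                                         fx$sys$reference)
  Xc <- sweep(X, 2, colMeans(X))
  trace <- sum(colMeans(Xc^2))
  expect_rel(fx$ed$tmsf, trace, 1e-6)
  # consistency with per-residue RMSF
  rmsf <- per_residue_rmsf(fx$tr, selection = fx$ca)
  expect_rel(sum(rmsf^2), fx$ed$tmsf, 1e-6)
})

test_that("projection variances equal eigenvalues and are uncorrelated", {
  fx <- ed_fixture()
  p <- project(fx$tr, fx$ed, k = 1:3)
  f <- nrow(p)
  pv <- colMeans(sweep(p, 2, colMeans(p))^2)   # population variance
  expect_rel(pv[1], fx$ed$eigenvalues[1], 1e-6)
  expect_rel(pv[2], fx$ed$eigenvalues[2], 1e-6)
  cv <- mean((p[, 1] - mean(p[, 1])) * (p[, 2] - mean(p[, 2])))
  expect_lt(abs(cv) / sqrt(pv[1] * pv[2]), 1e-6)
  expect_error(project(fx$tr, fx$ed, k = 10000), "beyond")
})

test_that("PCA reconstruction reproduces fitted frames", {
  sys <- gen_peptide_system(12, "helix")
  ca <- which(sys$atoms$name == "CA")
  tr <- gen_gaussian_mode_trajectory(
    sys, make_planted_modes(sys, c(0.5, 0.2, 0.1), seed = 2,
                            selection = ca), 50, seed = 3)
  ed <- ed_decompose(tr, selection = ca)
  X <- solvdyn:::fitted_selection_matrix(tr, ca, sys$reference)
  Xc <- sweep(X, 2, colMeans(X))
  recon <- (Xc %*% ed$eigenvectors) %*% t(ed$eigenvectors)
  expect_lt(max(abs(recon - Xc)), 1e-6)
})

test_that("projection extremes bracket planted two-state centres", {
  sys <- gen_peptide_system(20, "helix")
  ca <- which(sys$atoms$name == "CA")
  modes <- make_planted_modes(sys, 1, seed = 5, selection = ca)
  v <- modes[[1]]$eigenvector
  ts <- gen_two_state(0, hop_prob = 0.2, n_frames = 300, seed = 6,
                      centers = c(-2, 2))
  ref_flat <- as.vector(t(sys$reference))
  xyz <- matrix(rep(ref_flat, each = 300), 300) + outer(ts$series, v)
  tr <- sd_trajectory(sys, xyz, times = seq_len(300))
  ed <- ed_decompose(tr, selection = ca)
  ex <- projection_extremes(tr, ed, 1, n_interpolants = 5)
  expect_length(ex$structures, 5)
  expect_lt(ex$p_min, -1.5)
  expect_gt(ex$p_max, 1.5)
  # interpolants are linear: midpoint equals the average of the extremes
  mid <- (ex$structures[[1]] + ex$structures[[5]]) / 2
  expect_equal(ex$structures[[3]], mid, tolerance = 1e-10)
})

test_that("cosine content: defining cases and [0, 1] bounds", {
  n <- 1000
  tt <- seq(0, 1, length.out = n)
  expect_equal(cosine_content(cos(pi * tt), 1), 1, tolerance = 1e-3)
  expect_equal(cosine_content(cos(2 * pi * tt), 1), 0, tolerance = 1e-3)
  expect_equal(cosine_content(cos(2 * pi * tt), 2), 1, tolerance = 1e-3)
  set.seed(8)
  for (i in 1:20) {
    p <- rnorm(50 + i)
    ck <- cosine_content(p, sample(1:3, 1))
    expect_gte(ck, 0)
    expect_lte(ck, 1)
  }
  expect_error(cosine_content(rnorm(3)), "too short")
})

test_that("random walks have high first-PC cosine content vs white noise", {
  # ensemble comparison plus agreement with an independent Riemann-sum
  # evaluation of the same integral
  cc_riemann <- function(p, k = 1) {
    p <- p - mean(p)
    Tn <- length(p)
    tt <- seq(0, 1, length.out = Tn)
    w <- rep(1, Tn); w[c(1, Tn)] <- 0.5   # trapezoid weights
    num <- 2 * (sum(w * cos(k * pi * tt) * p) / (Tn - 1))^2
    den <- sum(w * p^2) / (Tn - 1)
    num / den
  }
  walks <- vapply(1:200, function(s)
    cosine_content(gen_random_walk(1, 1, 1000, seed = s)), numeric(1))
  noise <- vapply(1:200, function(s) {
    set.seed(10000 + s)
    cosine_content(rnorm(1000))
  }, numeric(1))
  expect_gt(median(walks), median(noise))
  expect_gt(mean(walks), 0.4)   # diffusion-like series look cosine-like
  ref <- vapply(1:200, function(s)
    cc_riemann(gen_random_walk(1, 1, 1000, seed = s)), numeric(1))
  expect_equal(mean(walks), mean(ref), tolerance = 0.005)
})

test_that("combined ED: identical halves give identical statistics", {
  sys <- gen_peptide_system(15, "helix")
  ca <- which(sys$atoms$name == "CA")
  tr <- gen_gaussian_mode_trajectory(
    sys, make_planted_modes(sys, 0.5, seed = 2, selection = ca),
    100, seed = 3)
  ce <- combined_ed(tr, tr, selection = ca)
  expect_equal(ce$stats$mean_A, ce$stats$mean_B, tolerance = 1e-10)
  expect_equal(ce$stats$msd_A, ce$stats$msd_B, tolerance = 1e-10)
})

test_that("combined ED separates displaced halves along the shift", {
  sys <- gen_peptide_system(40, "helix")
  ca <- which(sys$atoms$name == "CA")
  modes <- make_planted_modes(sys, 0.5, seed = 3, selection = ca)
  shift <- 3
  trA <- gen_gaussian_mode_trajectory(sys, modes, 500, seed = 4)
  trB <- gen_gaussian_mode_trajectory(sys, modes, 500, seed = 5)
  trB$xyz <- sweep(trB$xyz, 2, -shift * modes[[1]]$eigenvector)
  ce <- combined_ed(trA, trB, selection = ca)
  cols <- sel_cols(ca)
  align <- abs(sum(ce$ed$eigenvectors[, 1] *
                   modes[[1]]$eigenvector[cols]))
  expect_gt(align, 0.99)
  expect_rel(abs(ce$stats$mean_A[1] - ce$stats$mean_B[1]), shift, 0.02)
  # histograms of the first eigenvector barely overlap
  h <- ce$histograms[[1]]
  overlap <- sum(pmin(h$density_A, h$density_B)) * diff(h$breaks[1:2])
  expect_lt(overlap, 0.2)
})

test_that("half with larger planted variance has the larger projection MSD", {
  sys <- gen_peptide_system(20, "helix")
  ca <- which(sys$atoms$name == "CA")
  modes <- make_planted_modes(sys, 0.4, seed = 6, selection = ca)
  modes3 <- list(planted_mode(modes[[1]]$eigenvector, 1.2))
  wins <- 0L
  for (s in 1:50) {
    trA <- gen_gaussian_mode_trajectory(sys, modes, 150, seed = 100 + s)
    trB <- gen_gaussian_mode_trajectory(sys, modes3, 150, seed = 200 + s)
    ce <- combined_ed(trA, trB, selection = ca, n_vectors = 1L)
    if (ce$stats$msd_B[1] > ce$stats$msd_A[1]) wins <- wins + 1L
  }
  expect_gte(wins, 48)
})

test_that("joined-spectrum is invariant to concatenation order", {
  sys <- gen_peptide_system(15, "helix")
  ca <- which(sys$atoms$name == "CA")
  modes <- make_planted_modes(sys, c(0.6, 0.3), seed = 8, selection = ca)
  trA <- gen_gaussian_mode_trajectory(sys, modes, 80, seed = 9)
  trB <- gen_gaussian_mode_trajectory(sys, modes, 80, seed = 10)
  edAB <- combined_ed(trA, trB, selection = ca)$ed
  edBA <- combined_ed(trB, trA, selection = ca)$ed
  expect_equal(edAB$eigenvalues, edBA$eigenvalues, tolerance = 1e-10)
})
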