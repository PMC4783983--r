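# Structural property calculators

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10)
  fit0 <- kabsch_superpose_rmsd(ref, ref)
  expect_lt(fit0$rmsd, 1e-12)
  expect_equal(det(fit0$rotation), 1, tolerance = 1e-10)
  th <- 37 * pi / 180
  R <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(ref %*% R, 2, c(1, 2, 3), "+")
  fit <- kabsch_superpose_rmsd(moved, ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_equal(fit$coords, ref, tolerance = 1e-8)
})

test_that("Kabsch RMSD is the global minimum (rotation-grid oracle)", {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  mob <- tet
  mob[1, ] <- mob[1, ] + c(1, 0, 0)
  got <- kabsch_superpose_rmsd(mob, tet)$rmsd
  # independent oracle: exhaustive Euler-angle grid + local refinement
  rot_mat <- function(a, b, c) {
    Rz <- function(t) cbind(c(cos(t), sin(t), 0), c(-sin(t), cos(t), 0),
                            c(0, 0, 1))
    Ry <- function(t) cbind(c(cos(t), 0, -sin(t)), c(0, 1, 0),
                            c(sin(t), 0, cos(t)))
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  obj <- function(p) {
    M <- sweep(mob, 2, colMeans(mob)) %*% rot_mat(p[1], p[2], p[3])
    sqrt(mean(rowSums((M - sweep(tet, 2, colMeans(tet)))^2)))
  }
  best <- Inf; best_p <- NULL
  gr <- seq(0, 2 * pi, length.out = 13)[-13]
  for (a in gr) for (b in seq(0, pi, length.out = 7)) for (c in gr) {
    v <- obj(c(a, b, c))
    if (v < best) { best <- v; best_p <- c(a, b, c) }
  }
  best <- stats::optim(best_p, obj)$value
  expect_equal(got, best, tolerance = 1e-3)
  expect_lte(got, best + 1e-6)  # never worse than the grid search
})

test_that("degenerate (collinear) selections are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose_rmsd(line, line), "collinear")
  expect_error(kabsch_superpose_rmsd(line[1:2, ], line[1:2, ]), "3 selected")
})

test_that("fitted RMSD never exceeds unfitted RMSD", {
  sys <- gen_peptide_system(15, "helix")
  ca <- which(sys$atoms$name == "CA")
  tr <- gen_gaussian_mode_trajectory(
    sys, make_planted_modes(sys, c(0.8, 0.2), seed = 3, selection = ca),
    20, seed = 4)
  for (k in c(2, 10, 20)) {
    m <- frame_coords(tr, k)
    fitted <- kabsch_superpose_rmsd(m, sys$reference, ca)$rmsd
    raw <- rmsd_raw(m[ca, ], sys$reference[ca, ])
    expect_lte(fitted, raw + 1e-12)
  }
})

test_that("radius of gyration matches closed forms and a direct oracle", {
  two <- rbind(c(-1, 0, 0), c(1, 0, 0))
  expect_equal(radius_of_gyration(two), 1.0)
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  circ <- cbind(3 * cos(th), 3 * sin(th), 0)
  expect_equal(radius_of_gyration(circ), 3.0)
  set.seed(7)
  pts <- matrix(rnorm(300), 100)
  m <- runif(100, 0.5, 20)
  com <- colSums(pts * m) / sum(m)
  oracle <- sqrt(sum(m * rowSums(sweep(pts, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(pts, masses = m), oracle,
               tolerance = 1e-10)
  expect_error(radius_of_gyration(pts, selection = integer(0)), "empty")
})

test_that("native contacts: reference count, blow-up, brute-force oracle", {
  toy <- gen_toy_protein_solvent(n_residues = 20, n_waters = 0,
                                 schedule = "none", n_frames = 2, seed = 5)
  sys <- build_native_pairs(toy$system, 6.0)
  expect_gt(nrow(sys$native_pairs), 0)
  expect_equal(native_contact_count(sys$reference, sys, 6.0),
               nrow(sys$native_pairs))
  centroid <- colMeans(sys$reference)
  blown <- sweep(sweep(sys$reference, 2, centroid), 1, 10, "*")
  blown <- sweep(blown, 2, centroid, "+")
  expect_equal(native_contact_count(blown, sys, 6.0), 0)
  # rotation/translation invariance
  th <- 0.7
  R <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(sys$reference %*% R, 2, c(5, -3, 2), "+")
  expect_equal(native_contact_count(moved, sys, 6.0),
               nrow(sys$native_pairs))
  # brute-force pair oracle on a perturbed frame
  set.seed(8)
  frame <- sys$reference + matrix(rnorm(length(sys$reference), sd = 1.5),
                                  ncol = 3)
  cnt <- 0L
  for (r in seq_len(nrow(sys$native_pairs))) {
    i <- sys$native_pairs[r, 1]; j <- sys$native_pairs[r, 2]
    if (sqrt(sum((frame[i, ] - frame[j, ])^2)) < 6.0) cnt <- cnt + 1L
  }
  expect_equal(native_contact_count(frame, sys, 6.0), cnt)
  sys2 <- toy$system
  expect_error(native_contact_count(frame, sys2), "build_native_pairs")
})

test_that("Shrake-Rupley SASA matches analytic and Monte-Carlo oracles", {
  # isolated sphere r = 1.5: 4 pi (1.5 + 1.4)^2
  a1 <- shrake_rupley_sasa(matrix(0, 1, 3), 1.5)
  expect_rel(a1, 4 * pi * 2.9^2, 0.01)
  # distant spheres: additivity
  far <- rbind(c(0, 0, 0), c(20, 0, 0))
  a2 <- shrake_rupley_sasa(far, c(1.5, 1.7))
  expect_rel(sum(a2), 4 * pi * 2.9^2 + 4 * pi * 3.1^2, 0.01)
  # fused spheres at 2.0 A vs a random-point Monte-Carlo surface oracle
  fused <- rbind(c(0, 0, 0), c(2, 0, 0))
  radii <- c(1.5, 1.5)
  got <- sum(shrake_rupley_sasa(fused, radii))
  set.seed(10)
  mc_one <- function(center, r_exp, other, r_other, n = 2e5) {
    u <- matrix(rnorm(3 * n), n)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * r_exp, 2, center, "+")
    keep <- rowSums(sweep(pts, 2, other)^2) >= r_other^2
    mean(keep) * 4 * pi * r_exp^2
  }
  oracle <- mc_one(fused[1, ], 2.9, fused[2, ], 2.9) +
    mc_one(fused[2, ], 2.9, fused[1, ], 2.9)
  expect_rel(got, oracle, 0.02)
})

test_that("SASA is monotone non-increasing as two spheres approach", {
  prev <- Inf
  for (d in seq(6, 1, by = -0.5)) {
    tot <- sum(shrake_rupley_sasa(rbind(c(0, 0, 0), c(d, 0, 0)),
                                  c(1.5, 1.5), n_points = 240))
    expect_lte(tot, prev + 1e-9)
    prev <- tot
  }
})

test_that("secondary structure: helix H runs, extended coil, hairpin E", {
  helix <- gen_peptide_system(15, "helix")
  lab <- assign_secondary_structure(helix$reference, helix)
  # i -> i+4 backbone bond oracle
  hb <- solvdyn:::ks_hbond_matrix(helix$reference, helix)
  turns <- vapply(1:11, function(i) hb[i + 4, i], logical(1))
  expect_true(all(turns))
  expect_equal(lab, c("C", rep("H", 13), "C"))
  ext <- gen_peptide_system(12, "extended")
  expect_equal(assign_secondary_structure(ext$reference, ext),
               rep("C", 12))
  hp <- gen_beta_hairpin(6)
  lab_hp <- assign_secondary_structure(hp$reference, hp)
  expect_equal(which(lab_hp == "E"), c(4, 5, 8, 9))
  short <- gen_peptide_system(2, "helix")
  expect_warning(lab_s <- assign_secondary_structure(short$reference, short),
                 "coil")
  expect_equal(lab_s, c("C", "C"))
})

test_that("SSE labels partition the residue set", {
  for (geo in c("helix", "extended")) {
    sys <- gen_peptide_system(10, geo)
    lab <- assign_secondary_structure(sys$reference, sys)
    expect_length(lab, 10)
    expect_true(all(lab %in% c("H", "G", "E", "T", "C")))
  }
})

test_that("property deltas follow the percent/fold definitions", {
  a <- property_table_from_values("low", rmsd = 0.62, sasa = 10574,
                                  nnc = 137766, rg = 16.6,
                                  sse_helix = 69.9, sse_sheet = 62.0,
                                  sse_turn = 42.7)
  d0 <- compare_tables(a, a)
  expect_true(all(abs(d0$percent_change) < 1e-12))
  expect_true(all(abs(d0$fold_change) < 1e-12))
  dl <- value_delta(0.64, 2.97)
  expect_equal(dl$fold_change, 3.640625, tolerance = 1e-6)
  expect_equal(dl$percent_change, 364.0625, tolerance = 1e-6)
  expect_error(value_delta(0, 1), "zero")
})

test_that("property_table means match per-frame recomputation", {
  toy <- gen_toy_protein_solvent(n_residues = 8, n_waters = 0,
                                 schedule = "none", n_frames = 4, seed = 9)
  tr <- toy$trajectory
  tr$xyz <- tr$xyz + matrix(rnorm(length(tr$xyz), sd = 0.05),
                            nrow = nrow(tr$xyz))
  pt <- property_table(tr, label = "jit")
  rg <- vapply(1:4, function(k)
    radius_of_gyration(frame_coords(tr, k),
                       which(tr$system$atoms$is_solute),
                       tr$system$atoms$mass), numeric(1))
  expect_equal(pt$rg_mean, mean(rg), tolerance = 1e-10)
  expect_equal(pt$rg_sd, sd(rg), tolerance = 1e-10)
  expect_equal(pt$label, "jit")
})
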