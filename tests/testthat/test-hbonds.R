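# Hydrogen-bond detection and bookkeeping

make_dha_system <- function(d_pos, h_pos, a_pos) {
  at <- data.frame(name = c("N", "H", "O"), resname = "ALA",
                   resid = c(1, 1, 2), chain = "A",
                   stringsAsFactors = FALSE)
  sd_system(at, rbind(d_pos, h_pos, a_pos))
}

test_that("inclusive distance and angle cutoffs behave as documented", {
  cfg <- analysis_config()
  # collinear D-H...A at 2.9 A: detected
  sys <- make_dha_system(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))
  hb <- detect_hbonds_frame(sys$reference, sys, cfg)
  expect_equal(nrow(hb), 1)
  expect_equal(unlist(hb[1, 1:3]), c(donor = 1, hydrogen = 2, acceptor = 3))
  expect_equal(hb$class, "M-M")
  # 3.6 A: distance fail
  sys2 <- make_dha_system(c(0, 0, 0), c(1, 0, 0), c(3.6, 0, 0))
  expect_equal(nrow(detect_hbonds_frame(sys2$reference, sys2, cfg)), 0)
  # exactly 3.5 A is inclusive
  sys3 <- make_dha_system(c(0, 0, 0), c(1, 0, 0), c(3.5, 0, 0))
  expect_equal(nrow(detect_hbonds_frame(sys3$reference, sys3, cfg)), 1)
  # angle below 120 fails; 120 passes (acceptor placed to set the angle)
  ang_sys <- function(theta_deg) {
    th <- theta_deg * pi / 180
    a <- c(1, 0, 0) + 2.0 * c(cos(pi - th), sin(pi - th), 0)
    make_dha_system(c(0, 0, 0), c(1, 0, 0), a)
  }
  s110 <- ang_sys(110)
  expect_equal(nrow(detect_hbonds_frame(s110$reference, s110, cfg)), 0)
  s120 <- ang_sys(120)
  expect_equal(nrow(detect_hbonds_frame(s120$reference, s120, cfg)), 1)
})

test_that("detector equals brute-force enumeration on random clouds", {
  cfg <- analysis_config()
  for (seed in 1:100) {
    sys <- make_hb_cloud(8, 8, seed = seed, side = 10)
    got <- detect_hbonds_frame(sys$reference, sys, cfg)
    want <- brute_force_hbonds(sys$reference, sys)
    expect_equal(got[, c("donor", "hydrogen", "acceptor")], want,
                 ignore_attr = TRUE, info = paste("seed", seed))
  }
})

test_that("minimum-image convention finds bonds across the box boundary", {
  # D-H points +x at the box edge; the acceptor sits 1.9 A past H but
  # wrapped to the other side of the 10 A box
  sys <- make_dha_system(c(8.5, 5, 5), c(9.5, 5, 5), c(1.4, 5, 5))
  cfg <- analysis_config()
  # without a box, D-A distance is 7.1: nothing
  expect_equal(nrow(detect_hbonds_frame(sys$reference, sys, cfg)), 0)
  # with the box, the image distance is 2.9 at angle 180
  hb <- detect_hbonds_frame(sys$reference, sys, cfg, box = c(10, 10, 10))
  expect_equal(nrow(hb), 1)
})

test_that("persistency bookkeeping matches a scripted schedule", {
  mask <- rbind(rep(1L, 10),
                c(rep(1L, 5), rep(0L, 5)),
                c(1L, rep(0L, 9)))
  toy <- gen_toy_protein_solvent(
    n_residues = 14, n_waters = 2,
    schedule = list(classes = c("M-M", "S-S", "M-solv"), mask = mask),
    seed = 21)
  st <- hbond_statistics(toy$trajectory, scope = "intra-protein")
  expect_equal(st$static_mean, 1.5)
  expect_equal(st$dynamic_count, 2)
  expect_equal(sort(st$bonds$persistency), c(50, 100))
  expect_equal(st$mean_persistency, 75)
  sv <- hbond_statistics(toy$trajectory, scope = "protein-solvent")
  expect_equal(sv$dynamic_count, 1)
  expect_equal(sv$static_mean, 0.1)
  expect_equal(sv$bonds$persistency, 10)
  expect_equal(sv$bonds$class, "M-solv")
})

test_that("single always-present bond gives persistency 100", {
  mask <- matrix(1L, 1, 8)
  toy <- gen_toy_protein_solvent(
    n_residues = 6, n_waters = 1,
    schedule = list(classes = "M-solv", mask = mask), seed = 22)
  st <- hbond_statistics(toy$trajectory, scope = "protein-solvent")
  expect_equal(st$static_mean, 1.0)
  expect_equal(st$dynamic_count, 1)
  expect_equal(st$bonds$persistency, 100)
})

test_that("sum of persistencies / 100 equals the static mean exactly", {
  set.seed(31)
  for (seed in c(31, 32, 33)) {
    toy <- gen_toy_protein_solvent(n_residues = 22, n_waters = 3,
                                   schedule = "auto", n_frames = 25,
                                   n_bonds = 5, seed = seed)
    for (scope in c("intra-protein", "protein-solvent")) {
      st <- hbond_statistics(toy$trajectory, scope = scope)
      expect_equal(sum(st$bonds$persistency) / 100, st$static_mean,
                   tolerance = 1e-12)
    }
  }
})

test_that("dynamic count is monotone in trajectory length (prefix property)", {
  toy <- gen_toy_protein_solvent(n_residues = 22, n_waters = 3,
                                 schedule = "auto", n_frames = 30,
                                 n_bonds = 5, seed = 41)
  prev <- 0L
  for (f in c(5, 10, 20, 30)) {
    st <- hbond_statistics(subset_frames(toy$trajectory, 1:f),
                           scope = "intra-protein")
    expect_gte(st$dynamic_count, prev)
    prev <- st$dynamic_count
  }
})

test_that("class counts and class static means sum to the totals", {
  toy <- gen_toy_protein_solvent(n_residues = 22, n_waters = 4,
                                 schedule = "auto", n_frames = 20,
                                 n_bonds = 5, seed = 51)
  for (scope in c("intra-protein", "protein-solvent")) {
    st <- hbond_statistics(toy$trajectory, scope = scope)
    expect_equal(sum(st$class_counts), st$dynamic_count)
    expect_equal(sum(st$class_static_mean), st$static_mean,
                 tolerance = 1e-12)
  }
  expect_equal(sort(unique(st$bonds$class)),
               sort(names(st$class_counts)))
})

test_that("protein-solvent scope on a solvent-free system errors", {
  sys <- gen_peptide_system(5, "helix")
  tr <- gen_gaussian_mode_trajectory(sys, list(), 3, seed = 1)
  expect_error(hbond_statistics(tr, scope = "protein-solvent"),
               "no solvent")
})
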