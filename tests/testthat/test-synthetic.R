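test_that("ideal helix geometry matches canonical alpha-helix parameters", {
  helix <- make_ideal_helix(20)
  ca <- frame_coords(helix, 1)[helix$atoms$name == "CA", ]
  # rise per residue along the helix axis (z by construction)
  expect_equal(mean(diff(ca[, 3])), 1.562, tolerance = 0.01)
  # twist per residue about the axis
  ang <- atan2(ca[, 2], ca[, 1])
  tw <- diff(ang) %% (2 * pi)
  expect_equal(mean(tw) * 180 / pi, 99.67, tolerance = 0.1)
  # every (i, i+4) backbone pair is hydrogen bonded: n - 4 pairs
  expect_warning(occ <- occupancy_map(helix, "H", 1:20), "skipped")
  expect_equal(nrow(occ), 16L)
  expect_equal(occ$occupancy, rep(1, 16))
})

test_that("perturbing one carbonyl oxygen breaks exactly that pair", {
  helix <- make_ideal_helix(12)
  at <- helix$atoms
  iO <- which(at$resid == 4 & at$name == "O")
  helix$coords[1, iO, ] <- helix$coords[1, iO, ] + c(3, 0, 0)
  occ <- occupancy_map(helix, "H", 1:8)
  expect_equal(occ$occupancy[occ$resid == 4], 0)
  expect_equal(occ$occupancy[occ$resid != 4], rep(1, 7))
})

test_that("helix hydrogen bonding is invariant under rigid rotation", {
  helix <- make_ideal_helix(12)
  set.seed(61)
  rot <- helix
  rot$coords[1, , ] <- sweep(frame_coords(helix, 1) %*% random_rotation(),
                             2, c(10, -4, 2), "+")
  expect_equal(occupancy_map(rot, "H", 1:8)$occupancy,
               occupancy_map(helix, "H", 1:8)$occupancy)
})

test_that("hinged trajectories follow the planted separation signal", {
  # amplitude 0, no noise: constant separation at base
  flat <- make_hinged_trajectory(hinged_config(
    separation_amplitude = 0, thermal_sigma = 0, n_frames = 10, seed = 1))
  e <- flat$ensemble
  d <- com_distance_trace(e, resolve_selection(e, "chain A"),
                          resolve_selection(e, "chain B"))$d
  expect_equal(d, rep(40, 10), tolerance = 1e-8)

  # with thermal noise the CoM error is bounded by noise propagation:
  # each domain CoM jitters ~ sigma/sqrt(n) per coordinate
  cfg <- hinged_config(n_frames = 50, thermal_sigma = 0.5,
                       n_atoms_per_domain = 60, seed = 3)
  gen <- make_hinged_trajectory(cfg)
  e2 <- gen$ensemble
  d2 <- com_distance_trace(e2, resolve_selection(e2, "chain A"),
                           resolve_selection(e2, "chain B"))$d
  bound <- 3 * cfg$thermal_sigma * sqrt(2 / cfg$n_atoms_per_domain) * 3
  expect_lt(max(abs(d2 - gen$manifest$planted_distance)), bound)
})

test_that("hinged trajectories are bit-identical for a fixed seed", {
  g1 <- make_hinged_trajectory(hinged_config(n_frames = 6, seed = 99))
  g2 <- make_hinged_trajectory(hinged_config(n_frames = 6, seed = 99))
  expect_identical(g1$ensemble$coords, g2$ensemble$coords)
  expect_identical(g1$manifest$planted_distance, g2$manifest$planted_distance)
})

test_that("manifest break fractions equal the realized frame counts", {
  bp <- data.frame(resid = c(2, 5, 8), fraction = c(0.2, 0.4, 0.8))
  gen <- make_hinged_trajectory(hinged_config(
    n_frames = 10, thermal_sigma = 0, broken_pairs = bp, seed = 37))
  expect_equal(gen$manifest$broken_pairs$realized_fraction, bp$fraction)
  expect_equal(vapply(gen$manifest$break_frames, length, 0L), c(2L, 4L, 8L))
})

test_that("synthetic DEER traces match the closed-form forward model", {
  g <- r_grid(n = 128)
  cfg <- deer_sim_config(components = data.frame(mean = 4.5, sd = 0.4, weight = 1),
                         noise_sigma = 0, grid = g, seed = 1, n_t = 80)
  sim <- make_synthetic_deer(cfg)
  kern <- build_kernel(sim$trace$t, g)
  expected <- (1 - cfg$lambda + cfg$lambda *
                 as.vector(kern$K %*% sim$truth$p) * g$dr) *
    exp(-cfg$bg_k * sim$trace$t)
  expect_equal(sim$trace$v, expected / expected[1], tolerance = 1e-10)

  s1 <- make_synthetic_deer(deer_sim_config(seed = 5, n_t = 60))
  s2 <- make_synthetic_deer(deer_sim_config(seed = 5, n_t = 60))
  expect_identical(s1$trace$v, s2$trace$v)
})

test_that("the configured SNR matches the empirical noise level", {
  g <- r_grid(n = 64)
  sds <- vapply(1:50, function(s) {
    cfg <- deer_sim_config(noise_sigma = 0.01, grid = g, seed = s, n_t = 120)
    clean <- make_synthetic_deer(deer_sim_config(noise_sigma = 0, grid = g,
                                                 seed = s, n_t = 120))
    noisy <- make_synthetic_deer(cfg)
    sd(noisy$trace$v - clean$trace$v)
  }, numeric(1))
  expect_lt(abs(mean(sds) - 0.01) / 0.01, 0.1)
})

test_that("sequence sets honor degenerate and typical frequencies", {
  all_g <- make_sequence_set(seq_set_config(n_sequences = 3, length = 20,
                                            gly_freq = 1, pro_freq = 0, seed = 2))
  expect_true(all(all_g$block$rows == strrep("G", 20)))

  cfg <- seq_set_config(n_sequences = 100, length = 150, gly_freq = 0.1, seed = 11)
  gen <- make_sequence_set(cfg)
  chars <- unlist(strsplit(gen$block$rows, ""))
  phat <- mean(chars == "G")
  se <- sqrt(0.1 * 0.9 / length(chars))
  expect_lt(abs(phat - 0.1), 3 * se)

  r1 <- make_sequence_set(cfg)$block$rows
  expect_identical(r1, gen$block$rows)
})

test_that("crystal stand-ins embed their published target geometry", {
  ls <- synthetic_label_site_structure()
  expect_equal(pair_distance(ls, "resid 613 and name CB", "resid 1258 and name CB"),
               48.0, tolerance = 1e-9)
  dimer <- synthetic_closed_nbd_dimer()
  d <- com_distance_trace(dimer, resolve_selection(dimer, "chain A"),
                          resolve_selection(dimer, "chain B"))$d
  expect_equal(d, 26.2, tolerance = 1e-9)
})
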