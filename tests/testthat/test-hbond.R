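replicate_frames <- function(ens, f) {
  coords <- array(0, c(f, n_atoms(ens), 3))
  for (i in seq_len(f)) coords[i, , ] <- frame_coords(ens, 1)
  structure_ensemble(ens$atoms, coords)
}

test_that("hbond_present follows the geometric criterion with inclusive boundary", {
  helix <- make_ideal_helix(12)
  expect_true(all(vapply(1:8, function(i)
    hbond_present(helix, 1, "H", i), logical(1))))

  pair <- tiny_ensemble(rbind(c(0, 0, 0), c(5, 0, 0)),
                        names = c("O", "N"), elements = c("O", "N"),
                        resids = c(1L, 5L))
  expect_false(hbond_present(pair, 1, "A", 1))

  on_edge <- tiny_ensemble(rbind(c(0, 0, 0), c(3.5, 0, 0)),
                           names = c("O", "N"), elements = c("O", "N"),
                           resids = c(1L, 5L))
  expect_true(hbond_present(on_edge, 1, "A", 1))   # d == d_NO_max is bonded
})

test_that("the angle condition applies when hydrogens are present", {
  helix <- make_ideal_helix(12, with_hydrogens = TRUE)
  crit <- hbond_criterion(use_hydrogens = TRUE)
  expect_true(all(vapply(1:8, function(i)
    hbond_present(helix, 1, "H", i, crit), logical(1))))
  # demanding near-perfect linearity breaks the ~165 degree helical geometry
  strict <- hbond_criterion(use_hydrogens = TRUE, angle_min = 175)
  expect_false(hbond_present(helix, 1, "H", 1, strict))
})

test_that("missing backbone atoms yield NA and a warning, not an error", {
  helix <- make_ideal_helix(12)
  expect_true(is.na(hbond_present(helix, 1, "H", 9)))  # i+4 = 13 absent
  expect_warning(occ <- occupancy_map(helix, "H", 1:9), "skipped")
  expect_equal(nrow(occ), 8L)
})

test_that("occupancy is exact on static helices and planted breaks", {
  helix10 <- replicate_frames(make_ideal_helix(12), 10)
  occ <- occupancy_map(helix10, "H", 1:8)
  expect_equal(occ$occupancy, rep(1, 8))

  gen <- make_hinged_trajectory(hinged_config(
    n_frames = 10, thermal_sigma = 0, seed = 13,
    broken_pairs = data.frame(resid = 3, fraction = 0.4)))
  occ2 <- occupancy_map(gen$ensemble, "L", 1:11)
  expect_equal(occ2$occupancy[occ2$resid == 3], 0.6)
  expect_equal(occ2$occupancy[occ2$resid != 3], rep(1, 10))
})

test_that("occupancy is invariant to frame order", {
  gen <- make_hinged_trajectory(hinged_config(
    n_frames = 10, thermal_sigma = 0, seed = 17,
    broken_pairs = data.frame(resid = c(2, 7), fraction = c(0.3, 0.6))))
  ens <- gen$ensemble
  perm <- ens
  set.seed(1)
  perm$coords <- ens$coords[sample(10), , , drop = FALSE]
  expect_equal(occupancy_map(perm, "L", 1:11)$occupancy,
               occupancy_map(ens, "L", 1:11)$occupancy)
})

test_that("defect calls use a strict >30% absence rule", {
  map <- data.frame(chain = "L", resid = 1:4,
                    occupancy = c(0.6, 0.70, 1.0, 0.69))
  class(map) <- c("HBondOccupancyMap", "data.frame")
  def <- call_defects(map)
  expect_equal(def$defect, c(TRUE, FALSE, FALSE, TRUE))
  # alternative persistence reading: occupancy < threshold itself
  alt <- call_defects(map, strict_persistence = TRUE)
  expect_equal(alt$defect, rep(FALSE, 4))
})

test_that("tightening d_NO_max can only reduce occupancy", {
  gen <- make_hinged_trajectory(hinged_config(
    n_frames = 12, thermal_sigma = 0, seed = 23,
    broken_pairs = data.frame(resid = c(3, 8), fraction = c(0.25, 0.5))))
  ens <- gen$ensemble
  # jitter linker O/N slightly so the criterion boundary actually bites
  set.seed(2)
  ens$coords <- ens$coords + array(rnorm(length(ens$coords), 0, 0.25),
                                   dim(ens$coords))
  loose <- occupancy_map(ens, "L", 1:11, hbond_criterion(d_NO_max = 3.5))
  tight <- occupancy_map(ens, "L", 1:11, hbond_criterion(d_NO_max = 3.0))
  expect_true(all(tight$occupancy <= loose$occupancy + 1e-12))
})

test_that("defect calls are stable under frame subsampling by 2", {
  gen <- make_hinged_trajectory(hinged_config(
    n_frames = 40, thermal_sigma = 0, seed = 29,
    broken_pairs = data.frame(resid = c(2, 6), fraction = c(0.1, 0.6))))
  ens <- gen$ensemble
  sub <- ens
  sub$coords <- ens$coords[seq(1, 40, by = 2), , , drop = FALSE]
  sub$frame_times <- ens$frame_times[seq(1, 40, by = 2)]
  occ_full <- occupancy_map(ens, "L", 1:11)
  occ_sub <- occupancy_map(sub, "L", 1:11)
  # break frames are placed at random, so halving the frames perturbs the
  # occupancy by sampling noise on top of the 1/20 quantization
  expect_true(all(abs(occ_full$occupancy - occ_sub$occupancy) <= 0.15))
  expect_equal(call_defects(occ_sub)$defect, call_defects(occ_full)$defect)
})

test_that("the per-residue view marks every residue spanned by a defect", {
  map <- data.frame(chain = "L", resid = c(1, 6), occupancy = c(0.5, 1.0))
  class(map) <- c("HBondOccupancyMap", "data.frame")
  view <- residue_defect_view(call_defects(map))
  expect_true(all(view$defect[view$resid %in% 1:5]))
  expect_false(any(view$defect[view$resid %in% 6:10]))
})
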