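# Superposition, RMSD, fluctuation profiles, flexible regions,
# displacement.

random_coords <- function(n) matrix(stats::rnorm(n * 3, sd = 5), ncol = 3)

random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_rot(q)
}

test_that("superposition is exact for identical and rigidly moved copies", {
  set.seed(2)
  x <- random_coords(12)
  fit <- superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  moved <- sweep(x %*% t(random_rotation()), 2, c(5, -3, 11), "+")
  fit2 <- superpose(x, moved)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-10)
})

test_that("superposition rejects degenerate point sets", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(superpose(line, line + 1), "degenerate")
})

test_that("superposition RMSD matches the quaternion-optimisation oracle", {
  set.seed(31)
  for (rep in 1:10) {
    ref <- random_coords(10)
    mob <- random_coords(10)
    expect_equal(superpose(ref, mob)$rmsd, oracle_min_rmsd(ref, mob),
                 tolerance = 1e-4)
  }
})

test_that("superposition agrees with bio3d least-squares fitting", {
  set.seed(17)
  ref <- random_coords(20)
  mob <- random_coords(20)
  ours <- superpose(ref, mob)$rmsd
  theirs <- bio3d::rmsd(as.vector(t(ref)), as.vector(t(mob)),
                        fit = TRUE)
  expect_equal(ours, theirs, tolerance = 1e-4)
})

test_that("RMSD series is zero for static input and trends under drift", {
  s <- trajectory_scenario(n_residues = 10L, n_frames = 6L,
                           core_sigma = 0, loop_sigma = 0)
  expect_equal(rmsd_series(simulate_trajectory(s)), rep(0, 6),
               tolerance = 1e-10)
  # marker drift: RMSD from the starting structure grows with the drift
  sd_ <- trajectory_scenario(n_residues = 40L, n_frames = 60L,
                             core_sigma = 0, loop_sigma = 0,
                             loop_interval = c(10L, 20L),
                             marker_residue = 15L,
                             marker_displacement = 20, seed = 3L)
  series <- rmsd_series(simulate_trajectory(sd_))
  expect_equal(series[1], 0, tolerance = 1e-10)
  expect_true(all(diff(series) > -1e-9))
  expect_gt(series[60], series[2])
})

test_that("single-frame trajectory gives a single zero RMSD", {
  tr <- trajectory(array(random_coords(8), c(1, 8, 3)))
  expect_equal(rmsd_series(tr), 0, tolerance = 1e-10)
  expect_error(fluctuation_profile(tr), "2 frames")
})

test_that("fluctuations recover the isotropic Gaussian identity", {
  # sigma = 1 A per axis: <dr^2> = 3 A^2, B = 8 pi^2 ~ 78.96 A^2
  s <- trajectory_scenario(n_residues = 60L, n_frames = 2000L,
                           core_sigma = 1, loop_sigma = 1,
                           loop_interval = c(30L, 31L), seed = 8L)
  prof <- fluctuation_profile(simulate_trajectory(s))
  expect_equal(mean(prof$msf_A2), 3, tolerance = 0.05)
  expect_equal(mean(prof$bfactor_A2), 8 * pi^2, tolerance = 0.05 * 8 * pi^2)
})

test_that("B equals (8 pi^2 / 3) msf elementwise to machine precision", {
  s <- trajectory_scenario(n_residues = 20L, n_frames = 50L, seed = 2L,
                           loop_interval = c(8L, 12L))
  prof <- fluctuation_profile(simulate_trajectory(s))
  expect_equal(prof$bfactor_A2, 8 * pi^2 / 3 * prof$msf_A2,
               tolerance = 1e-14)
  expect_true(all(prof$msf_A2 >= 0))
})

test_that("per-region sigma is recovered from B within 5% at 2000 frames", {
  s <- trajectory_scenario(n_residues = 120L, n_frames = 2000L,
                           core_sigma = 0.5, loop_sigma = 2,
                           loop_interval = c(55L, 95L), seed = 12L)
  prof <- fluctuation_profile(simulate_trajectory(s))
  loop <- prof$residue >= 55 & prof$residue <= 95
  # <dr^2> = 3 sigma^2: 12 A^2 in the loop, 0.75 A^2 in the core
  expect_equal(mean(prof$msf_A2[loop]), 12, tolerance = 0.05)
  expect_equal(mean(prof$msf_A2[!loop]), 0.75, tolerance = 0.05)
  expect_gt(min(prof$bfactor_A2[loop]), max(prof$bfactor_A2[!loop]))
})

test_that("fluctuations are invariant to a global rigid-body motion", {
  s <- trajectory_scenario(n_residues = 30L, n_frames = 100L, seed = 5L,
                           loop_interval = c(10L, 20L))
  traj <- simulate_trajectory(s)
  rot <- random_rotation()
  moved <- traj
  for (f in seq_len(dim(traj$coords)[1])) {
    moved$coords[f, , ] <- sweep(traj$coords[f, , ] %*% t(rot), 2,
                                 c(10, 20, -5), "+")
  }
  expect_equal(fluctuation_profile(moved)$msf_A2,
               fluctuation_profile(traj)$msf_A2, tolerance = 1e-8)
  expect_equal(rmsd_series(moved), rmsd_series(traj), tolerance = 1e-8)
})

test_that("equal masses make the residue average a plain mean", {
  set.seed(4)
  coords <- array(stats::rnorm(20 * 6 * 3), c(20, 6, 3))
  residue <- c(1L, 1L, 2L, 2L, 3L, 3L)
  tr_eq <- trajectory(coords, residue = residue, mass = rep(12, 6))
  tr_any <- trajectory(coords, residue = residue, mass = rep(99, 6))
  expect_equal(fluctuation_profile(tr_eq)$msf_A2,
               fluctuation_profile(tr_any)$msf_A2, tolerance = 1e-12)
})

test_that("flexible region calling localises the high-sigma loop", {
  # flat profile: nothing called
  s_flat <- trajectory_scenario(n_residues = 50L, n_frames = 200L,
                                core_sigma = 1, loop_sigma = 1,
                                loop_interval = c(20L, 25L), seed = 6L)
  expect_equal(nrow(flexible_regions(
    fluctuation_profile(simulate_trajectory(s_flat)))), 0L)

  # one loop at 40-100 in a 150-residue chain
  s1 <- trajectory_scenario(n_residues = 150L, n_frames = 400L,
                            core_sigma = 0.5, loop_sigma = 2,
                            loop_interval = c(40L, 100L), seed = 7L)
  reg <- flexible_regions(fluctuation_profile(simulate_trajectory(s1)))
  expect_equal(nrow(reg), 1L)
  expect_gte(reg$from, 38)
  expect_lte(reg$to, 102)
  expect_true(reg$peak_residue >= 40 && reg$peak_residue <= 100)
})

test_that("two separated loops give two intervals", {
  s <- trajectory_scenario(n_residues = 120L, n_frames = 400L,
                           core_sigma = 0.4, loop_sigma = 2.5,
                           loop_interval = c(20L, 35L), seed = 9L)
  traj <- simulate_trajectory(s)
  # add a second loop by re-simulating and splicing coordinates
  s2 <- trajectory_scenario(n_residues = 120L, n_frames = 400L,
                            core_sigma = 0.4, loop_sigma = 2.5,
                            loop_interval = c(80L, 95L), seed = 10L)
  traj2 <- simulate_trajectory(s2)
  traj$coords[, 80:95, ] <- traj2$coords[, 80:95, ]
  reg <- flexible_regions(fluctuation_profile(traj))
  expect_equal(nrow(reg), 2L)
  expect_true(reg$from[1] >= 18 && reg$to[1] <= 37)
  expect_true(reg$from[2] >= 78 && reg$to[2] <= 97)
})

test_that("marker displacement is recovered after core superposition", {
  s <- trajectory_scenario(n_residues = 100L, n_frames = 200L,
                           core_sigma = 0.1, loop_sigma = 0.5,
                           loop_interval = c(60L, 90L),
                           marker_residue = 75L, marker_displacement = 30,
                           seed = 14L)
  traj <- simulate_trajectory(s)
  core <- setdiff(1:100, 60:90)
  d <- displacement(traj, 1L, 200L, marker = 75L, core = core)
  # per-frame positional noise (sd sqrt(2) * 0.5 along the drift axis)
  # bounds the recovery error well inside 10%
  expect_equal(d, 30, tolerance = 0.1)
  # identical frames: zero displacement
  expect_equal(displacement(traj, 5L, 5L, marker = 75L, core = core), 0,
               tolerance = 1e-10)
  # a core residue barely moves under the same superposition
  expect_lt(displacement(traj, 1L, 200L, marker = 10L, core = core), 1)
  expect_error(displacement(traj, 1L, 200L, marker = 999L), "marker")
})
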