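# Generators: promoter construction, sensorgrams, isotherms, melt curves,
# trajectories.

test_that("F-architecture promoter embeds the five motifs at the printed layout", {
  prom <- build_promoter_sequence(f_promoter_architecture(), seed = 11L)
  truth <- prom$truth
  expect_equal(nrow(truth), 5L)
  # three consensus copies on +, consensus #4 and degenerate #2' on -
  expect_equal(sum(truth$strand == "+"), 3L)
  expect_equal(sum(truth$strand == "-"), 2L)
  hits <- scan_motifs(prom$sequence, "CTTTGC", 2L)
  exact <- hits[hits$mismatches == 0L, ]
  expect_equal(nrow(exact), 4L)
  expect_equal(sum(exact$strand == "+"), 3L)
  expect_equal(sum(exact$strand == "-"), 1L)
  two_mm_minus <- hits[hits$mismatches == 2L & hits$strand == "-" &
                         hits$start %in% truth$start, ]
  expect_equal(nrow(two_mm_minus), 1L)
  expect_equal(two_mm_minus$observed, "TCTTGC")
  # direct-orientation gaps of 13 bp between #1/#2 and #2/#3
  plus <- truth[truth$strand == "+", ]
  expect_equal(diff(plus$start), c(19L, 19L)) # 6-bp motif + 13-bp gap
})

test_that("promoter truth table is self-consistent under rescanning", {
  for (seed in c(1L, 5L, 23L)) {
    prom <- build_promoter_sequence(f_promoter_architecture(), seed = seed)
    hits <- scan_motifs(prom$sequence, "CTTTGC", 2L)
    for (i in seq_len(nrow(prom$truth))) {
      match <- hits$start == prom$truth$start[i] &
        hits$strand == prom$truth$strand[i] &
        hits$observed == prom$truth$seq[i]
      expect_true(any(match))
    }
  }
})

test_that("degenerate promoter constructions behave as built", {
  # single element, no flanks, AT fraction 1: sequence equals the element
  arch <- promoter_architecture(
    data.frame(seq = "CTTTGC", strand = "+", gap = 0L),
    at_fraction = 1, flank_left = 0L, flank_right = 0L)
  prom <- build_promoter_sequence(arch, seed = 1L)
  expect_equal(prom$sequence, "CTTTGC")
  # two + elements with a 13-bp gap: start difference is motif + gap
  arch2 <- promoter_architecture(
    data.frame(seq = c("CTTTGC", "CTTTGC"), strand = c("+", "+"),
               gap = c(0L, 13L)))
  prom2 <- build_promoter_sequence(arch2, seed = 2L)
  expect_equal(prom2$truth$start[2] - (prom2$truth$start[1] + 6L), 13L)
  # overlapping elements are rejected naming the colliding pair
  arch3 <- promoter_architecture(
    data.frame(seq = c("CTTTGC", "CTTTGC"), strand = c("+", "+"),
               gap = c(0L, 0L)))
  arch3$elements$gap[2] <- -3L # force a collision past the validator
  expect_error(build_promoter_sequence(arch3, seed = 1L), "overlapping")
})

test_that("generators are bit-deterministic under equal scenario and seed", {
  a <- build_promoter_sequence(f_promoter_architecture(), seed = 3L)
  b <- build_promoter_sequence(f_promoter_architecture(), seed = 3L)
  expect_identical(a$sequence, b$sequence)
  s <- spr_scenario(seed = 3L)
  expect_identical(simulate_sensorgrams(s), simulate_sensorgrams(s))
  ts <- default_emsa_scenario(3L)
  expect_identical(simulate_isotherm(ts), simulate_isotherm(ts))
  ms <- melt_scenario(noise_sd = 0.01, seed = 3L)
  expect_identical(simulate_melt_curve(ms), simulate_melt_curve(ms))
  js <- trajectory_scenario(n_residues = 10L, n_frames = 4L, seed = 3L)
  expect_identical(simulate_trajectory(js)$coords,
                   simulate_trajectory(js)$coords)
})

test_that("noiseless sensorgrams plateau at the scenario's true Rmax", {
  s <- spr_scenario(noise_sd = 0, concentrations = c(1e-6, 1e-4),
                    t_assoc = 5000)
  expect_equal(s$rmax_true, 6 * (44000 / 89760) * 300, tolerance = 1e-12)
  sg <- simulate_sensorgrams(s)
  plateau <- max(sg[[2]]$response)
  # at 100 uM >> KD the equilibrium response is essentially Rmax
  expect_equal(plateau, s$rmax_true, tolerance = 1e-3)
})

test_that("zero bound dimers give flat zero sensorgrams", {
  s <- spr_scenario(true_dimers_bound = 0, noise_sd = 0)
  sg <- simulate_sensorgrams(s)
  expect_true(all(vapply(sg, function(x) all(x$response == 0), logical(1))))
})

test_that("sensorgram scenario validates durations and concentrations", {
  expect_error(spr_scenario(t_assoc = -1), "durations")
  expect_error(spr_scenario(concentrations = c(1e-6, 1e-6)),
               "strictly increasing")
})

test_that("noiseless isotherms match their forward models exactly", {
  hs <- titration_scenario("hill", kd_true = 85, hill_h_true = 3,
                           protein_concs = c(10, 85, 170), noise_sd = 0)
  iso <- simulate_isotherm(hs)
  expect_equal(iso$fraction_bound[2], 0.5)
  expect_equal(iso$fraction_bound,
               hill_model(hs$protein_concs, 85, 3))
  ds <- titration_scenario("depletion", kd_true = 10, probe_conc = 15,
                           protein_concs = c(25), noise_sd = 0)
  expect_equal(simulate_isotherm(ds)$fraction_bound,
               (50 - sqrt(1000)) / 30, tolerance = 1e-12)
})

test_that("noisy isotherms stay clipped to [0, 1]", {
  s <- titration_scenario("hill", kd_true = 10,
                          protein_concs = 10^seq(0, 4, length.out = 30),
                          noise_sd = 0.5, seed = 4L)
  iso <- simulate_isotherm(s)
  expect_true(all(iso$fraction_bound >= 0 & iso$fraction_bound <= 1))
})

test_that("melt scenario rejects a midpoint outside the grid", {
  expect_error(melt_scenario(tm_true = 80, t_range = c(25, 65)),
               "inside t_range")
})

test_that("melt curves share shape across conditions, shifted by Tm", {
  apo <- simulate_melt_curve(melt_scenario(44.5))
  adp <- simulate_melt_curve(melt_scenario(46.1))
  r_apo <- apo$f350 / apo$f330
  r_adp <- adp$f350 / adp$f330
  # transitions differ only by position: the ADP curve at T matches the
  # apo curve at T - 1.6 away from the (slightly sloped) baselines
  shift_idx <- round(1.6 / 0.1)
  mid <- which.min(abs(apo$temp_C - 44.5))
  win <- (mid - 30):(mid + 30)
  expect_equal(r_adp[win + shift_idx], r_apo[win], tolerance = 5e-3)
})

test_that("static trajectory is exactly the reference in every frame", {
  s <- trajectory_scenario(n_residues = 8L, n_frames = 5L, core_sigma = 0,
                           loop_sigma = 0)
  traj <- simulate_trajectory(s)
  expect_true(all(rmsd_series(traj) < 1e-12))
})

test_that("marker drift moves the marker by the prescribed distance", {
  s <- trajectory_scenario(n_residues = 30L, n_frames = 50L,
                           core_sigma = 0, loop_sigma = 0,
                           loop_interval = c(10L, 20L),
                           marker_residue = 15L, marker_displacement = 30,
                           seed = 9L)
  traj <- simulate_trajectory(s)
  d <- sqrt(sum((traj$coords[50, 15, ] - traj$coords[1, 15, ])^2))
  expect_equal(d, 30, tolerance = 1e-9)
})

test_that("trajectory scenario validates the marker and loop ranges", {
  expect_error(trajectory_scenario(n_residues = 10L, marker_residue = 11L),
               "marker")
  expect_error(trajectory_scenario(n_residues = 10L,
                                   loop_interval = c(5L, 12L)),
               "loop_interval")
})
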