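# Synthetic coordinate trajectories: a rigid core with a high-fluctuation
# loop, standing in for molecular-dynamics output. Frames are a fixed
# non-collinear reference structure plus per-residue isotropic Gaussian
# perturbations, optionally with a linear drift that carries a marker
# residue a prescribed distance between the first and last frames
# (emulating a loop residue swinging away while the core stays put).

#' Describe a trajectory scenario
#'
#' @param n_residues residues (CA-only, one atom per residue).
#' @param n_frames frames (>= 2).
#' @param core_sigma per-axis Gaussian sigma outside the loop, Angstrom.
#' @param loop_interval `c(from, to)` residue range of the flexible loop
#'   (default: the middle 45-80% stretch of the chain).
#' @param loop_sigma per-axis sigma inside the loop, Angstrom.
#' @param marker_residue residue carrying the drift (NA for none).
#' @param marker_displacement total drift between first and last frame,
#'   Angstrom.
#' @param masses per-residue masses, Da (default 110, an average residue).
#' @param seed integer seed.
#' @return list of class `trajectory_scenario`.
#' @export
trajectory_scenario <- function(n_residues = 120L, n_frames = 2000L,
                                core_sigma = 0.5,
                                loop_interval = NULL,
                                loop_sigma = 2,
                                marker_residue = NA_integer_,
                                marker_displacement = 30,
                                masses = NULL, seed = 1L) {
  stopifnot(n_frames >= 2L, core_sigma >= 0, loop_sigma >= 0)
  loop_interval <- loop_interval %||%
    c(max(1L, round(n_residues * 0.45)), max(1L, round(n_residues * 0.8)))
  if (loop_interval[1] < 1L || loop_interval[2] > n_residues ||
      loop_interval[1] > loop_interval[2]) {
    stop("loop_interval must lie within [1, n_residues]")
  }
  if (!is.na(marker_residue) &&
      (marker_residue < 1L || marker_residue > n_residues)) {
    stop("marker residue outside range")
  }
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 core_sigma = core_sigma,
                 loop_interval = as.integer(loop_interval),
                 loop_sigma = loop_sigma,
                 marker_residue = marker_residue,
                 marker_displacement = marker_displacement,
                 masses = masses %||% rep(110, n_residues),
                 seed = as.integer(seed)),
            class = "trajectory_scenario")
}

# helical CA reference trace: non-collinear by construction
reference_structure <- function(n_residues) {
  i <- seq_len(n_residues)
  cbind(x = 1.5 * i, y = 2.3 * cos(i * 100 * pi / 180),
        z = 2.3 * sin(i * 100 * pi / 180))
}

#' Simulate a CA-only trajectory
#'
#' @param s a `trajectory_scenario`.
#' @return list of class `trajectory`: `coords` (frames x atoms x 3
#'   array, Angstrom), `residue` (atom-to-residue map), `mass` (Da),
#'   `times` (frame index as pseudo-time).
#' @export
simulate_trajectory <- function(s) {
  stopifnot(inherits(s, "trajectory_scenario"))
  ref <- reference_structure(s$n_residues)
  sig <- rep(s$core_sigma, s$n_residues)
  loop <- s$loop_interval[1]:s$loop_interval[2]
  sig[loop] <- s$loop_sigma
  nf <- s$n_frames
  coords <- with_seed(derive_seed(s$seed, "trajectory"), {
    arr <- array(NA_real_, c(nf, s$n_residues, 3))
    for (f in seq_len(nf)) {
      noise <- matrix(stats::rnorm(s$n_residues * 3), ncol = 3) * sig
      arr[f, , ] <- ref + noise
    }
    arr
  })
  if (!is.na(s$marker_residue)) {
    drift_dir <- c(0, 1, 0)
    for (f in seq_len(nf)) {
      frac <- (f - 1) / (nf - 1)
      coords[f, s$marker_residue, ] <- coords[f, s$marker_residue, ] +
        frac * s$marker_displacement * drift_dir
    }
  }
  structure(list(coords = coords, residue = seq_len(s$n_residues),
                 mass = s$masses, times = seq_len(nf)),
            class = "trajectory")
}

#' Construct a trajectory object from a coordinate array
#'
#' @param coords frames x atoms x 3 array (Angstrom).
#' @param residue atom-to-residue map (default one residue per atom).
#' @param mass per-atom masses, Da (default 110).
#' @param times optional frame times.
#' @return a `trajectory`.
#' @export
trajectory <- function(coords, residue = NULL, mass = NULL, times = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  na <- dim(coords)[2]
  residue <- residue %||% seq_len(na)
  mass <- mass %||% rep(110, na)
  stopifnot(length(residue) == na, length(mass) == na, all(mass > 0))
  structure(list(coords = coords, residue = residue, mass = mass,
                 times = times %||% seq_len(dim(coords)[1])),
            class = "trajectory")
}
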