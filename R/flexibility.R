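# Trajectory analytics: least-squares superposition, RMSD series,
# per-residue positional fluctuations and simulated B-factors, flexible
# region calling and marker displacement.
#
# These reproduce standard molecular-dynamics post-processing: frames are
# rigid-body superposed (Kabsch algorithm, proper rotations only), the
# mean-square positional fluctuation per residue is converted to a
# crystallographic-style temperature factor through B = (8 pi^2 / 3) <dr^2>,
# and contiguous stretches of unusually high B are reported as flexible
# regions (for the partition ATPase, the winged-HTH).

B_FACTOR_CONST <- 8 * pi^2 / 3

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the weighted RMSD
#' between `mobile` and `reference`; reflections are rejected by
#' sign-correcting the smallest singular vector.
#'
#' @param reference,mobile n x 3 coordinate matrices (Angstrom), equal
#'   rows, at least 3 non-collinear points.
#' @param weights per-atom weights (default equal).
#' @return list: `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (weighted, Angstrom), `transformed` (mobile after the fit).
#' @export
superpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  stopifnot(ncol(reference) == 3L, ncol(mobile) == 3L,
            nrow(reference) == nrow(mobile), nrow(reference) >= 3L)
  n <- nrow(reference)
  w <- weights %||% rep(1, n)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  cref <- colSums(reference * w)
  cmob <- colSums(mobile * w)
  x <- sweep(mobile, 2, cmob)
  y <- sweep(reference, 2, cref)
  # degenerate input: all points (weighted) collinear or coincident
  sv_chk <- svd(x * sqrt(w))$d
  if (sv_chk[2] < 1e-10 * max(sv_chk[1], 1e-30)) {
    stop("degenerate coordinates: points are collinear or coincident")
  }
  h <- t(x * w) %*% y
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  transformed <- x %*% t(rot)
  transformed <- sweep(transformed, 2, cref, "+")
  dev2 <- rowSums((transformed - reference)^2)
  list(rotation = rot, translation = cref - as.vector(rot %*% cmob),
       rmsd = sqrt(sum(w * dev2)), transformed = transformed)
}

#' Per-frame RMSD series against a reference structure
#'
#' Each frame is superposed onto the reference (first frame by default,
#' i.e. RMSD from the starting structure) and the post-fit RMSD recorded
#' in frame order.
#'
#' @param traj a `trajectory` (see [simulate_trajectory()] /
#'   [read_trajectory_csv()]).
#' @param reference `"first"` or an n x 3 coordinate matrix.
#' @param weights per-atom weights (default the trajectory masses).
#' @return numeric vector of RMSD (Angstrom), one per frame.
#' @export
rmsd_series <- function(traj, reference = "first", weights = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  ref <- if (is.character(reference) && reference == "first") {
    traj$coords[1, , ]
  } else {
    as.matrix(reference)
  }
  w <- weights %||% traj$mass
  n_frames <- dim(traj$coords)[1]
  vapply(seq_len(n_frames), function(f) {
    superpose(ref, traj$coords[f, , ], w)$rmsd
  }, numeric(1))
}

#' Per-residue fluctuation profile and simulated B-factors
#'
#' Frames are superposed onto an iteratively computed mean structure (two
#' passes: fit to the first frame, average, re-fit to the average,
#' re-average), then the time-averaged squared deviation from the mean is
#' computed per atom, mass-weight-averaged per residue, and converted to
#' B-factors through `B = (8 pi^2 / 3) * <dr^2>`.
#'
#' @param traj a `trajectory` with at least 2 frames.
#' @return list of class `fluctuation_profile`: `residue`, `msf_A2`
#'   (`<dr^2>`, Angstrom^2), `bfactor_A2`, `reference = "mean structure"`.
#' @export
fluctuation_profile <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]
  if (nf < 2L) stop("fluctuation profile requires at least 2 frames")
  w <- traj$mass
  fit_all <- function(ref) {
    fitted <- array(NA_real_, dim(traj$coords))
    for (f in seq_len(nf)) {
      fitted[f, , ] <- superpose(ref, traj$coords[f, , ], w)$transformed
    }
    fitted
  }
  mean_of <- function(arr) apply(arr, c(2, 3), mean)
  fitted <- fit_all(traj$coords[1, , ])
  mref <- mean_of(fitted)
  fitted <- fit_all(mref)
  mref <- mean_of(fitted)
  dev2 <- matrix(0, nrow = dim(traj$coords)[2], ncol = nf)
  for (f in seq_len(nf)) {
    dev2[, f] <- rowSums((fitted[f, , ] - mref)^2)
  }
  msf_atom <- rowMeans(dev2)
  res_ids <- sort(unique(traj$residue))
  msf_res <- vapply(res_ids, function(r) {
    idx <- traj$residue == r
    sum(msf_atom[idx] * w[idx]) / sum(w[idx])
  }, numeric(1))
  structure(list(residue = res_ids, msf_A2 = msf_res,
                 bfactor_A2 = B_FACTOR_CONST * msf_res,
                 reference = "mean structure"),
            class = "fluctuation_profile")
}

#' Call flexible regions from a B-factor profile
#'
#' Residues with `B > median(B) + k * mad(B)` are merged into maximal
#' contiguous intervals (bridging gaps up to `gap` residues); intervals
#' narrower than `min_width` residues are discarded as isolated outliers.
#' Each interval reports its peak residue. The robust median/MAD baseline
#' keeps the threshold anchored to the rigid core even when the flexible
#' region spans a large fraction of the chain (a mean/SD threshold is
#' dragged above the loop values in that regime).
#'
#' @param profile a `fluctuation_profile`.
#' @param k threshold in scaled-MAD units above the median (default 3).
#' @param gap residue gap tolerance when merging (default 2).
#' @param min_width minimum residues per reported region (default 3).
#' @return data.frame with `from`, `to`, `peak_residue`, `peak_bfactor`;
#'   zero rows for a flat profile.
#' @export
flexible_regions <- function(profile, k = 3, gap = 2L, min_width = 3L) {
  stopifnot(inherits(profile, "fluctuation_profile"))
  b <- profile$bfactor_A2
  res <- profile$residue
  thr <- stats::median(b) + k * stats::mad(b)
  flagged <- which(b > thr)
  empty <- data.frame(from = integer(), to = integer(),
                      peak_residue = integer(), peak_bfactor = numeric())
  if (length(flagged) == 0L || !is.finite(thr)) return(empty)
  runs <- split(flagged, cumsum(c(1, diff(res[flagged]) > gap + 1L)))
  out <- do.call(rbind, lapply(runs, function(idx) {
    peak <- idx[which.max(b[idx])]
    data.frame(from = res[min(idx)], to = res[max(idx)],
               peak_residue = res[peak], peak_bfactor = b[peak])
  }))
  out <- out[out$to - out$from + 1L >= min_width, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) empty else out
}

#' Marker displacement between two frames after core superposition
#'
#' Superposes frame `b` onto frame `a` using only the core selection (the
#' rigid part of the molecule), then measures the Euclidean distance
#' between the marker atom's positions. This is how a loop-residue
#' excursion is quantified while the core stays fixed.
#'
#' @param traj a `trajectory`.
#' @param frame_a,frame_b frame indices.
#' @param marker residue id of the marker.
#' @param core residue ids defining the superposition core (default: all
#'   residues except the marker).
#' @return displacement in Angstrom.
#' @export
displacement <- function(traj, frame_a, frame_b, marker, core = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  res <- traj$residue
  if (!marker %in% res) stop("marker residue not present in trajectory")
  core <- core %||% setdiff(unique(res), marker)
  core_idx <- which(res %in% core)
  a <- traj$coords[frame_a, , ]
  b <- traj$coords[frame_b, , ]
  fit <- superpose(a[core_idx, , drop = FALSE], b[core_idx, , drop = FALSE],
                   traj$mass[core_idx])
  b_fit <- sweep(b %*% t(fit$rotation), 2, fit$translation, "+")
  m_idx <- which(res == marker)
  sqrt(sum((colMeans(b_fit[m_idx, , drop = FALSE]) -
              colMeans(a[m_idx, , drop = FALSE]))^2))
}
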