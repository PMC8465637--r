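# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# motif_hits as a bare data.frame (drops scan metadata attributes) for
# comparison against oracle output
plain_hits <- function(h) {
  d <- data.frame(start = h$start, strand = h$strand,
                  observed = h$observed, mismatches = h$mismatches,
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  d
}

# brute-force window-by-window motif scan (both strands, Hamming distance)
brute_scan <- function(seq, consensus, max_mismatch) {
  s <- toupper(seq)
  consensus <- toupper(consensus)
  L <- nchar(consensus)
  cv <- strsplit(consensus, "", fixed = TRUE)[[1]]
  out <- list()
  n <- nchar(s)
  if (n >= L) {
    for (i in seq_len(n - L + 1L)) {
      win <- substr(s, i, i + L - 1L)
      wv <- strsplit(win, "", fixed = TRUE)[[1]]
      d_fwd <- sum(wv != cv)
      if (d_fwd <= max_mismatch) {
        out[[length(out) + 1L]] <- data.frame(
          start = i - 1L, strand = "+", observed = win,
          mismatches = d_fwd, stringsAsFactors = FALSE)
      }
      rc <- revcomp(win)
      d_rev <- sum(strsplit(rc, "", fixed = TRUE)[[1]] != cv)
      if (d_rev <= max_mismatch) {
        out[[length(out) + 1L]] <- data.frame(
          start = i - 1L, strand = "-", observed = rc,
          mismatches = d_rev, stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), strand = character(),
               observed = character(), mismatches = integer(),
               stringsAsFactors = FALSE)
  df <- df[order(df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_dna <- function(n, at = 0.5) {
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# quaternion rotation matrix (always proper)
quat_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# minimum RMSD over proper rotations by numerical optimisation of a
# quaternion parameterisation, multi-started from a coarse grid
oracle_min_rmsd <- function(ref, mobile, n_starts = 24L) {
  ref_c <- sweep(ref, 2, colMeans(ref))
  mob_c <- sweep(mobile, 2, colMeans(mobile))
  obj <- function(q) {
    r <- quat_rot(q)
    sqrt(mean(rowSums((mob_c %*% t(r) - ref_c)^2)))
  }
  best <- Inf
  starts <- rbind(diag(4), matrix(stats::rnorm(4 * (n_starts - 4L)),
                                  ncol = 4))
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(starts[k, ], obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
    if (o$value < best) best <- o$value
  }
  best
}
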