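# Readers and writers for the plain-text interchange formats used by the
# analysis: FASTA promoters, CSV sensorgrams / isotherms / melt curves,
# CA-only multi-model PDB or long-CSV trajectories, BED-like motif tables
# and PFM matrices. All formats round-trip with their counterparts here.

#' Write promoter sequences as FASTA (60-column wrap)
#'
#' @param seqs named character vector of DNA sequences, or a single
#'   `synthetic_promoter`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(seqs, path) {
  if (inherits(seqs, "synthetic_promoter")) {
    seqs <- stats::setNames(seqs$sequence, "synthetic_promoter")
  }
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_promoter_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sensorgrams to CSV
#'
#' Long format: `time_s`, `response_RU`, `conc_M`, `phase`
#' (`association`/`dissociation`).
#' @param sensorgrams list of `sensorgram` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sensorgram_csv <- function(sensorgrams, path) {
  if (inherits(sensorgrams, "sensorgram")) sensorgrams <- list(sensorgrams)
  df <- do.call(rbind, lapply(sensorgrams, function(s) {
    data.frame(time_s = s$times, response_RU = s$response, conc_M = s$conc,
               phase = ifelse(s$times <= s$t_off, "association",
                              "dissociation"))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read sensorgrams from CSV
#'
#' @param path CSV written by [write_sensorgram_csv()].
#' @return list of `sensorgram` objects (one per concentration).
#' @export
read_sensorgram_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$conc_M), function(d) {
    d <- d[order(d$time_s), ]
    t_off <- max(d$time_s[d$phase == "association"])
    structure(list(times = d$time_s, response = d$response_RU,
                   conc = d$conc_M[1], t_on = min(d$time_s),
                   t_off = t_off),
              class = "sensorgram")
  })
}

#' Write / read a titration isotherm CSV (`conc_nM`, `fraction_bound`)
#'
#' @param iso a `binding_isotherm`.
#' @param path CSV file.
#' @return `path` invisibly (writer); a `binding_isotherm` (reader; probe
#'   concentration is carried in a `# probe_nM:` header comment).
#' @export
write_isotherm_csv <- function(iso, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# probe_nM: %g", iso$probe_nM %||% NA), con)
  utils::write.csv(data.frame(conc_nM = iso$conc_nM,
                              fraction_bound = iso$fraction_bound),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_isotherm_csv
#' @export
read_isotherm_csv <- function(path) {
  first <- readLines(path, n = 1L)
  probe <- if (grepl("^# probe_nM:", first)) {
    as.numeric(sub("^# probe_nM:", "", first))
  } else NA_real_
  df <- utils::read.csv(path, comment.char = "#")
  structure(list(conc_nM = df$conc_nM, fraction_bound = df$fraction_bound,
                 probe_nM = probe, model_kind = NA_character_),
            class = "binding_isotherm")
}

#' Write / read a melt curve CSV (`temp_C`, `f330`, `f350`)
#'
#' @param curve a `melt_curve`.
#' @param path CSV file.
#' @return `path` invisibly (writer); a `melt_curve` (reader).
#' @export
write_melt_csv <- function(curve, path) {
  utils::write.csv(data.frame(temp_C = curve$temp_C, f330 = curve$f330,
                              f350 = curve$f350),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_melt_csv
#' @export
read_melt_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(temp_C = df$temp_C, f330 = df$f330, f350 = df$f350,
                 condition = NA_character_),
            class = "melt_curve")
}

#' Write a trajectory as a CA-only multi-model PDB subset
#'
#' Emits MODEL / ATOM / ENDMDL records only, one CA atom per residue,
#' chain A. A minimal but standard-conformant subset sufficient for
#' trajectory exchange.
#'
#' @param traj a `trajectory`.
#' @param path output PDB file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  nf <- dim(traj$coords)[1]
  na <- dim(traj$coords)[2]
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL %8d", f), con)
    for (a in seq_len(na)) {
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        a, traj$residue[a],
        traj$coords[f, a, 1], traj$coords[f, a, 2], traj$coords[f, a, 3],
        1.00, 0.00), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a CA-only multi-model PDB trajectory
#'
#' Parses MODEL/ATOM/ENDMDL records; only CA atoms are kept. Masses
#' default to 110 Da per residue.
#'
#' @param path PDB file.
#' @return a `trajectory`.
#' @export
read_trajectory_pdb <- function(path) {
  lines <- readLines(path)
  atom <- grepl("^ATOM ", lines) &
    trimws(substr(lines, 13, 16)) == "CA"
  model_id <- cumsum(grepl("^MODEL", lines))
  al <- lines[atom]
  am <- model_id[atom]
  res <- as.integer(substr(al, 23, 26))
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  frames <- sort(unique(am))
  na <- sum(am == frames[1])
  coords <- array(NA_real_, c(length(frames), na, 3))
  for (k in seq_along(frames)) {
    idx <- which(am == frames[k])
    if (length(idx) != na) stop("inconsistent atom count across models")
    coords[k, , 1] <- x[idx]; coords[k, , 2] <- y[idx]
    coords[k, , 3] <- z[idx]
  }
  trajectory(coords, residue = res[am == frames[1]])
}

#' Write / read a trajectory as long CSV
#'
#' Columns `frame`, `residue`, `x`, `y`, `z`, `mass` (Angstrom, Da).
#'
#' @param traj a `trajectory`.
#' @param path CSV file.
#' @return `path` invisibly (writer); a `trajectory` (reader).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- dim(traj$coords)[1]
  na <- dim(traj$coords)[2]
  df <- data.frame(
    frame = rep(seq_len(nf), each = na),
    residue = rep(traj$residue, nf),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3])),
    mass = rep(traj$mass, nf)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  frames <- sort(unique(df$frame))
  first <- df[df$frame == frames[1], ]
  na <- nrow(first)
  coords <- array(NA_real_, c(length(frames), na, 3))
  for (k in seq_along(frames)) {
    d <- df[df$frame == frames[k], ]
    if (nrow(d) != na) stop("inconsistent atom count across frames")
    coords[k, , ] <- as.matrix(d[, c("x", "y", "z")])
  }
  trajectory(coords, residue = first$residue, mass = first$mass)
}

#' Write motif hits or IR pairs as BED-like 6-column TSV
#'
#' Columns: seq_id, start (0-based), end (half-open), name, mismatches,
#' strand. IR pairs are written as two rows per pair (left/right
#' half-site), named `pairK_left` / `pairK_right`.
#'
#' @param x `motif_hits` or `ir_pairs`.
#' @param path output TSV.
#' @param seq_id sequence identifier (default "promoter").
#' @return `path`, invisibly.
#' @export
write_motifs_bed <- function(x, path, seq_id = "promoter") {
  L <- attr(x, "motif_len") %||% 6L
  if (inherits(x, "ir_pairs")) {
    df <- do.call(rbind, lapply(seq_len(nrow(x)), function(k) {
      rbind(
        data.frame(seq_id = seq_id, start = x$left_start[k],
                   end = x$left_start[k] + L,
                   name = sprintf("pair%d_left", k),
                   mismatches = x$left_mismatches[k], strand = "+"),
        data.frame(seq_id = seq_id, start = x$right_start[k],
                   end = x$right_start[k] + L,
                   name = sprintf("pair%d_right", k),
                   mismatches = x$right_mismatches[k], strand = "-")
      )
    }))
  } else {
    df <- data.frame(seq_id = seq_id, start = x$start, end = x$start + L,
                     name = x$observed, mismatches = x$mismatches,
                     strand = x$strand)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a position frequency matrix as 4 x L TSV
#'
#' Rows A, C, G, T with row names in the first column.
#'
#' @param pfm 4 x L count matrix.
#' @param path TSV file.
#' @return `path` invisibly (writer); the matrix (reader).
#' @export
write_pfm_tsv <- function(pfm, path) {
  utils::write.table(pfm, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pfm_tsv
#' @export
read_pfm_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", row.names = 1)
  m <- as.matrix(df)
  colnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Write a fluctuation profile as CSV (`residue`, `msf_A2`, `bfactor_A2`)
#'
#' @param profile a `fluctuation_profile`.
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(data.frame(residue = profile$residue,
                              msf_A2 = profile$msf_A2,
                              bfactor_A2 = profile$bfactor_A2),
                   path, row.names = FALSE)
  invisible(path)
}
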