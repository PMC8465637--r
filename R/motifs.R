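# Hexamer motif scanning, inverted-repeat pairing and promoter architecture
# classification.
#
# Type Ia partition ATPases autoregulate their operon through an N-terminal
# winged-HTH that contacts short hexamer motifs (consensus 5'-CTTTGC for the
# F plasmid) in the promoter region. A dimer presents two wHTH motifs and
# reads an inverted repeat (IR): two half-sites on opposite strands
# separated by a large spacer (26-29 bp observed across F/P1/P7-type
# promoters). These functions detect half-sites, pair them into IRs under
# spacer constraints, and summarise the overlapping-IR architecture.

#' Scan a sequence for motif occurrences on both strands
#'
#' Every window of `nchar(consensus)` bases is compared to the consensus by
#' Hamming distance: plus-strand windows as written, minus-strand windows
#' after reverse complement (i.e. the motif as read 5'->3' on the minus
#' strand). Case-insensitive; any non-ACGT character in the sequence counts
#' as a mismatch at its position.
#'
#' @param seq single DNA string.
#' @param consensus motif consensus over A/C/G/T (default the F-plasmid
#'   ParA half-site `CTTTGC`).
#' @param max_mismatch maximum Hamming distance reported (must be smaller
#'   than the motif length).
#' @return a data.frame of hits with columns `start` (0-based, plus-strand
#'   coordinates), `strand` (`+`/`-`), `observed` (the window as read
#'   5'->3' on its strand), and `mismatches`; sorted by start then strand.
#' @examples
#' scan_motifs("AACTTTGCAA", "CTTTGC", 0)
#' @export
scan_motifs <- function(seq, consensus = "CTTTGC", max_mismatch = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  consensus <- toupper(consensus)
  if (!grepl("^[ACGT]+$", consensus)) {
    stop("consensus must contain only A, C, G, T: got ", consensus)
  }
  L <- nchar(consensus)
  if (max_mismatch >= L) stop("max_mismatch must be < motif length")
  s <- toupper(seq)
  n <- nchar(s)
  hits <- list()
  if (n >= L) {
    sv <- strsplit(s, "", fixed = TRUE)[[1]]
    cv <- strsplit(consensus, "", fixed = TRUE)[[1]]
    rv <- strsplit(revcomp(consensus), "", fixed = TRUE)[[1]]
    # mismatch count per window via one pass per motif position
    mm_fwd <- integer(n - L + 1L)
    mm_rev <- integer(n - L + 1L)
    for (j in seq_len(L)) {
      win <- sv[j:(n - L + j)]
      mm_fwd <- mm_fwd + (win != cv[j])
      mm_rev <- mm_rev + (win != rv[j])
    }
    starts <- which(mm_fwd <= max_mismatch)
    for (i in starts) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = i - 1L, strand = "+",
        observed = substr(s, i, i + L - 1L),
        mismatches = mm_fwd[i], stringsAsFactors = FALSE
      )
    }
    starts <- which(mm_rev <= max_mismatch)
    for (i in starts) {
      hits[[length(hits) + 1L]] <- data.frame(
        start = i - 1L, strand = "-",
        observed = revcomp(substr(s, i, i + L - 1L)),
        mismatches = mm_rev[i], stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(), strand = character(),
               observed = character(), mismatches = integer(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "motif_len") <- L
  attr(out, "consensus") <- consensus
  class(out) <- c("motif_hits", "data.frame")
  out
}

#' Pair motif hits into inverted repeats under a spacer window
#'
#' An IR pair is a plus-strand hit followed downstream by a minus-strand
#' hit with `spacer = right.start - (left.start + motif_len)` inside
#' `[spacer_min, spacer_max]`. A pair is `perfect` when both half-sites
#' match the consensus exactly, `degenerate` otherwise. The default
#' degeneracy tolerance admits at most `max_pair_mismatch` mismatches
#' summed over the pair with at least one perfect half-site.
#'
#' @param hits a `motif_hits` data.frame from [scan_motifs()].
#' @param spacer_min,spacer_max inclusive spacer window in bp (defaults 26
#'   and 29, the observed range across F/P1/P7-type promoters).
#' @param max_pair_mismatch maximum total mismatches across both half-sites
#'   (default 2).
#' @param require_perfect_half require one exact half-site per pair
#'   (default TRUE; the degenerate F-promoter IR pairs a 2-mismatch
#'   half-site with a perfect one).
#' @return data.frame with one row per pair: left/right starts, strands,
#'   observed sequences, `spacer`, `center_distance` (= spacer +
#'   motif_len), total mismatches and `irclass`.
#' @export
find_inverted_repeats <- function(hits, spacer_min = 26L, spacer_max = 29L,
                                  max_pair_mismatch = 2L,
                                  require_perfect_half = TRUE) {
  stopifnot(spacer_min <= spacer_max)
  L <- attr(hits, "motif_len") %||% 6L
  lefts <- hits[hits$strand == "+", , drop = FALSE]
  rights <- hits[hits$strand == "-", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(lefts))) for (j in seq_len(nrow(rights))) {
    spacer <- rights$start[j] - (lefts$start[i] + L)
    if (spacer < spacer_min || spacer > spacer_max) next
    mm <- lefts$mismatches[i] + rights$mismatches[j]
    if (mm > max_pair_mismatch) next
    if (require_perfect_half &&
        lefts$mismatches[i] > 0L && rights$mismatches[j] > 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      left_start = lefts$start[i], right_start = rights$start[j],
      left_observed = lefts$observed[i], right_observed = rights$observed[j],
      left_mismatches = lefts$mismatches[i],
      right_mismatches = rights$mismatches[j],
      spacer = spacer, center_distance = spacer + L,
      mismatches = mm,
      irclass = if (mm == 0L) "perfect" else "degenerate",
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(left_start = integer(), right_start = integer(),
               left_observed = character(), right_observed = character(),
               left_mismatches = integer(), right_mismatches = integer(),
               spacer = integer(), center_distance = integer(),
               mismatches = integer(), irclass = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$left_start, out$right_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "motif_len") <- L
  class(out) <- c("ir_pairs", "data.frame")
  out
}

#' Classify the overlapping-IR architecture of a promoter
#'
#' Summarises IR pairs, singleton motifs (hits in no pair; candidate
#' half-site anchors for a dimer binding through one wHTH, like motif #1 of
#' the F promoter), which pair footprints `[left_start, right_start +
#' motif_len)` intersect, and the 5' margin upstream of the first paired
#' motif. The margin is flagged as insufficient below `margin_threshold`:
#' nucleation of the three-dimer complex needs enough DNA on the left of
#' the IR (an IR placed mid-fragment does not shift in gel assays).
#'
#' @param hits `motif_hits` from [scan_motifs()].
#' @param ir_pairs `ir_pairs` from [find_inverted_repeats()].
#' @param seq_len promoter length in bp.
#' @param margin_threshold minimum acceptable 5' margin in bp (default 40,
#'   a heuristic from the ~85-bp minimal binding fragment minus the IR
#'   footprint).
#' @return a list of class `architecture_report` with elements `ir_pairs`,
#'   `singletons`, `overlaps` (data.frame of intersecting pair index
#'   pairs, symmetric), `min_left_margin_bp` and `left_margin_ok`.
#' @export
classify_architecture <- function(hits, ir_pairs, seq_len,
                                  margin_threshold = 40L) {
  L <- attr(hits, "motif_len") %||% 6L
  paired <- logical(nrow(hits))
  for (k in seq_len(nrow(ir_pairs))) {
    paired <- paired |
      (hits$start == ir_pairs$left_start[k] & hits$strand == "+") |
      (hits$start == ir_pairs$right_start[k] & hits$strand == "-")
  }
  singletons <- hits[!paired, , drop = FALSE]
  ov <- list()
  n <- nrow(ir_pairs)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      a <- c(ir_pairs$left_start[i], ir_pairs$right_start[i] + L)
      b <- c(ir_pairs$left_start[j], ir_pairs$right_start[j] + L)
      if (a[1] < b[2] && b[1] < a[2]) {
        ov[[length(ov) + 1L]] <- data.frame(i = i, j = j)
        ov[[length(ov) + 1L]] <- data.frame(i = j, j = i)
      }
    }
  }
  overlaps <- if (length(ov)) do.call(rbind, ov) else
    data.frame(i = integer(), j = integer())
  margin <- if (n > 0L) min(ir_pairs$left_start) else NA_integer_
  structure(list(
    ir_pairs = ir_pairs,
    singletons = singletons,
    overlaps = overlaps,
    min_left_margin_bp = margin,
    left_margin_ok = if (is.na(margin)) NA else margin >= margin_threshold,
    margin_threshold = margin_threshold,
    seq_len = seq_len
  ), class = "architecture_report")
}

#' @export
print.architecture_report <- function(x, ...) {
  cat("Promoter architecture report (", x$seq_len, " bp)\n", sep = "")
  cat("  IR pairs:", nrow(x$ir_pairs), "(",
      sum(x$ir_pairs$irclass == "perfect"), "perfect )\n")
  cat("  singleton motifs:", nrow(x$singletons), "\n")
  cat("  overlapping pair couples:", nrow(x$overlaps) / 2, "\n")
  cat("  5' margin before first paired motif:", x$min_left_margin_bp,
      "bp -", if (isTRUE(x$left_margin_ok)) "sufficient" else "INSUFFICIENT",
      "\n")
  invisible(x)
}

#' Position frequency matrix of aligned motifs
#'
#' @param motifs character vector of equal-length DNA strings.
#' @return 4 x L integer matrix of base counts (rows A, C, G, T); each
#'   column sums to the number of motifs.
#' @export
build_pfm <- function(motifs) {
  stopifnot(length(motifs) >= 1L)
  motifs <- toupper(motifs)
  L <- unique(nchar(motifs))
  if (length(L) != 1L) stop("motifs must have equal lengths")
  pfm <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
  for (m in motifs) {
    v <- strsplit(m, "", fixed = TRUE)[[1]]
    for (j in seq_len(L)) {
      if (!v[j] %in% BASES) stop("non-ACGT character in motif: ", m)
      pfm[v[j], j] <- pfm[v[j], j] + 1L
    }
  }
  pfm
}

#' Per-column information content and logo letter heights
#'
#' IC_j = 2 + sum_b p_bj log2 p_bj with p = counts/n and 0*log(0) = 0;
#' no small-sample correction by default (sets as small as 3 motifs are
#' analysed), optionally the e_n correction can be applied.
#'
#' @param pfm a 4 x L count matrix from [build_pfm()].
#' @param small_sample apply the e_n = 3/(2 ln 2 n) correction
#'   (default FALSE).
#' @return list with `ic` (bits per column, in `[0, 2]`) and `heights`
#'   (4 x L matrix, p_bj * IC_j).
#' @export
information_content <- function(pfm, small_sample = FALSE) {
  n <- unique(colSums(pfm))
  if (length(n) != 1L) stop("PFM columns must all sum to the same n")
  p <- sweep(pfm, 2, colSums(pfm), "/")
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + colSums(plogp)
  if (small_sample) ic <- pmax(0, ic - 3 / (2 * log(2) * n))
  list(ic = ic, heights = sweep(p, 2, ic, "*"))
}
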