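# Synthetic promoter construction.
#
# The generator emulates an AT-rich partition promoter with hexamer binding
# motifs embedded at prescribed positions and orientations, together with a
# truth table of every embedded motif. It does not transcribe any natural
# sequence: the background is random, only the motif architecture (element
# sequences, strands, gaps) is specified.

#' Describe a promoter architecture
#'
#' @param elements data.frame with columns `seq` (motif as read 5'->3' on
#'   its strand), `strand` (`+`/`-`) and `gap` (bp from the end of the
#'   previous element to the start of this one; ignored for the first
#'   element). All sequences must share `motif_length`.
#' @param motif_length bp (default 6).
#' @param at_fraction background AT fraction in `[0, 1]` (default 0.73, the
#'   AT-richness of the F-plasmid partition promoter over 100 bp).
#' @param flank_left,flank_right background bp before the first and after
#'   the last element.
#' @return list of class `promoter_architecture`.
#' @export
promoter_architecture <- function(elements, motif_length = 6L,
                                  at_fraction = 0.73,
                                  flank_left = 30L, flank_right = 30L) {
  stopifnot(is.data.frame(elements),
            all(c("seq", "strand", "gap") %in% names(elements)))
  if (any(nchar(elements$seq) != motif_length)) {
    stop("all element sequences must have length motif_length")
  }
  if (any(elements$gap[-1] < 0)) stop("gaps must be >= 0")
  if (!all(elements$strand %in% c("+", "-"))) stop("strand must be + or -")
  if (at_fraction < 0 || at_fraction > 1) stop("at_fraction must be in [0,1]")
  structure(list(elements = elements, motif_length = as.integer(motif_length),
                 at_fraction = at_fraction,
                 flank_left = as.integer(flank_left),
                 flank_right = as.integer(flank_right)),
            class = "promoter_architecture")
}

#' The F-plasmid promoter architecture
#'
#' Default architecture of the F partition promoter: three consensus
#' hexamers (#1, #2, #3) in direct orientation with 13-bp intervals, a
#' degenerate half-site #2' (`tcTTGC`) in inverted orientation 27 bp
#' downstream of #2, and the consensus #4 in inverted orientation 28 bp
#' downstream of #3. Motifs #3/#4 form the perfect IR (spacer 28,
#' center-to-center 34 bp); #2/#2' form the overlapping degenerate IR
#' (spacer 27). Positions along the sequence are #1, #2, #3, #2', #4, so
#' the element gaps are 13, 13, 8 (end of #3 to start of #2') and 14 (end
#' of #2' to start of #4).
#'
#' @param at_fraction background AT fraction (default 0.73).
#' @param flank_left,flank_right flank lengths in bp (defaults 30 and 30;
#'   with the 84-bp motif span this yields a 144-bp promoter, comparable to
#'   the 136-bp fragment used on the sensor surface).
#' @return a `promoter_architecture`.
#' @export
f_promoter_architecture <- function(at_fraction = 0.73,
                                    flank_left = 30L, flank_right = 30L) {
  promoter_architecture(
    elements = data.frame(
      name = c("#1", "#2", "#3", "#2'", "#4"),
      seq = c("CTTTGC", "CTTTGC", "CTTTGC", "TCTTGC", "CTTTGC"),
      strand = c("+", "+", "+", "-", "-"),
      gap = c(0L, 13L, 13L, 8L, 14L),
      stringsAsFactors = FALSE
    ),
    motif_length = 6L, at_fraction = at_fraction,
    flank_left = flank_left, flank_right = flank_right
  )
}

#' Build a synthetic promoter sequence with motif truth table
#'
#' Embeds each architecture element at its implied coordinate (minus-strand
#' elements as their reverse complement on the plus strand) in an i.i.d.
#' background with `P(A) = P(T) = at_fraction/2`. The background is
#' resampled (deterministically, from seeds derived from `seed`) until a
#' rescan of the built sequence finds no spurious exact-consensus window
#' and no IR pair beyond those implied by the embedded elements, so motif
#' counts and IR detection on generated promoters depend only on the
#' architecture, not on background luck.
#'
#' @param arch a `promoter_architecture`.
#' @param seed integer seed (explicit; generators never use global RNG
#'   state).
#' @param consensus consensus used for the spurious-hit screen (default
#'   `CTTTGC`).
#' @param max_screen_tries background resampling budget (default 100).
#' @return list of class `synthetic_promoter`: `sequence` (DNA string) and
#'   `truth` (data.frame: `name`, `start` 0-based, `strand`, `seq` as read
#'   on its strand, `embedded` as it appears on the plus strand).
#' @export
build_promoter_sequence <- function(arch, seed, consensus = "CTTTGC",
                                    max_screen_tries = 100L) {
  stopifnot(inherits(arch, "promoter_architecture"))
  L <- arch$motif_length
  el <- arch$elements
  starts <- integer(nrow(el))
  pos <- arch$flank_left
  for (i in seq_len(nrow(el))) {
    if (i > 1L) pos <- pos + el$gap[i]
    starts[i] <- pos
    pos <- pos + L
  }
  # collision check on [start, start+L)
  if (nrow(el) > 1L) {
    for (i in seq_len(nrow(el) - 1L)) for (j in (i + 1L):nrow(el)) {
      if (starts[i] < starts[j] + L && starts[j] < starts[i] + L) {
        stop("overlapping embedded elements: ",
             el$name[i] %||% i, " and ", el$name[j] %||% j)
      }
    }
  }
  total_len <- pos + arch$flank_right
  embedded <- ifelse(el$strand == "+", toupper(el$seq),
                     vapply(el$seq, revcomp, ""))
  truth <- data.frame(
    name = el$name %||% paste0("m", seq_len(nrow(el))),
    start = starts, strand = el$strand, seq = toupper(el$seq),
    embedded = embedded, stringsAsFactors = FALSE
  )

  p <- c(A = arch$at_fraction / 2, C = (1 - arch$at_fraction) / 2,
         G = (1 - arch$at_fraction) / 2, T = arch$at_fraction / 2)
  exact_expected <- sum(truth$seq == toupper(consensus))

  for (try in seq_len(max_screen_tries)) {
    sv <- with_seed(derive_seed(seed, paste0("promoter-bg-", try)), {
      sample(BASES, total_len, replace = TRUE, prob = p)
    })
    for (i in seq_len(nrow(truth))) {
      sv[(truth$start[i] + 1L):(truth$start[i] + L)] <-
        strsplit(truth$embedded[i], "", fixed = TRUE)[[1]]
    }
    seqstr <- paste(sv, collapse = "")
    # screen: exact hits must be exactly the embedded consensus copies, and
    # IR pairing at the degenerate tolerance must find only embedded pairs
    hits0 <- scan_motifs(seqstr, consensus, 0L)
    if (nrow(hits0) != exact_expected) next
    hits2 <- scan_motifs(seqstr, consensus, 2L)
    prs <- find_inverted_repeats(hits2)
    emb_ok <- all(prs$left_start %in% truth$start &
                    prs$right_start %in% truth$start)
    n_expected <- nrow(find_inverted_repeats(
      scan_truth_hits(truth, consensus)))
    if (emb_ok && nrow(prs) == n_expected) {
      out <- structure(list(sequence = seqstr, truth = truth,
                            arch = arch, seed = seed),
                       class = "synthetic_promoter")
      return(out)
    }
  }
  stop("could not draw a background free of spurious motifs in ",
       max_screen_tries, " tries")
}

# motif_hits-shaped table built from the truth table alone (no sequence),
# used to count the IR pairs the architecture itself implies.
scan_truth_hits <- function(truth, consensus) {
  L <- nchar(truth$seq[1])
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  mm <- vapply(truth$seq, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1]] != cons)
  }, integer(1))
  out <- data.frame(start = truth$start, strand = truth$strand,
                    observed = truth$seq, mismatches = mm,
                    stringsAsFactors = FALSE)
  attr(out, "motif_len") <- L
  class(out) <- c("motif_hits", "data.frame")
  out
}
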