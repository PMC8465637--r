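# Motif scanning, IR pairing, architecture classification, PFM / logo.

test_that("scanner finds plus- and minus-strand consensus sites", {
  h <- scan_motifs("AACTTTGCAA", "CTTTGC", 0L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 2L)
  expect_equal(h$strand, "+")
  # GCAAAG on the plus strand is CTTTGC read on the minus strand
  h2 <- scan_motifs("TTGCAAAGTT", "CTTTGC", 0L)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$observed, "CTTTGC")
})

test_that("mismatch counting matches the promoter variants", {
  # the plus-strand window GTAAAG is one variation away from GCAAAG (the
  # consensus read on the opposite strand), so it scores as a
  # single-mismatch minus-strand half-site
  h <- scan_motifs("AAGTAAAGAA", "CTTTGC", 1L)
  minus <- h[h$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$observed, "CTTTAC")
  expect_equal(minus$mismatches, 1L)
  # the degenerate half-site tcTTGC carries two variations
  h2 <- scan_motifs(revcomp("TCTTGC"), "CTTTGC", 2L)
  minus2 <- h2[h2$strand == "-", ]
  expect_equal(minus2$observed, "TCTTGC")
  expect_equal(minus2$mismatches, 2L)
})

test_that("scanner validates consensus and treats ambiguity as mismatch", {
  expect_error(scan_motifs("ACGT", "CTNTGC", 0L), "A, C, G, T")
  h <- scan_motifs("AACTNTGCAA", "CTTTGC", 1L)
  plus <- h[h$strand == "+", ]
  expect_equal(plus$mismatches, 1L)
})

test_that("scanner agrees with the brute-force window oracle", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(20:300, 1)
    seq <- random_dna(n, at = stats::runif(1, 0.3, 0.8))
    mm <- sample(0:2, 1)
    got <- scan_motifs(seq, "CTTTGC", mm)
    want <- brute_scan(seq, "CTTTGC", mm)
    expect_equal(plain_hits(got), want)
  }
})

test_that("scanner agrees with Biostrings::matchPattern per strand", {
  set.seed(7)
  seq <- random_dna(400, at = 0.6)
  for (mm in 0:2) {
    got <- scan_motifs(seq, "CTTTGC", mm)
    bs_plus <- Biostrings::start(Biostrings::matchPattern(
      "CTTTGC", Biostrings::DNAString(seq), max.mismatch = mm)) - 1L
    bs_minus <- Biostrings::start(Biostrings::matchPattern(
      revcomp("CTTTGC"), Biostrings::DNAString(seq),
      max.mismatch = mm)) - 1L
    expect_equal(got$start[got$strand == "+"], bs_plus)
    expect_equal(got$start[got$strand == "-"], bs_minus)
  }
})

test_that("strand closure: the reverse complement yields the mirror hit set", {
  set.seed(13)
  seq <- random_dna(200, at = 0.7)
  n <- nchar(seq)
  fwd <- scan_motifs(seq, "CTTTGC", 2L)
  rev <- scan_motifs(revcomp(seq), "CTTTGC", 2L)
  mirrored <- data.frame(
    start = n - 6L - rev$start,
    strand = ifelse(rev$strand == "+", "-", "+"),
    observed = rev$observed, mismatches = rev$mismatches,
    stringsAsFactors = FALSE)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  rownames(mirrored) <- NULL
  expect_equal(plain_hits(fwd), mirrored)
})

test_that("hit sets are monotone in the mismatch threshold", {
  set.seed(99)
  seq <- random_dna(300, at = 0.6)
  key <- function(h) paste(h$start, h$strand)
  for (m in 0:1) {
    a <- key(scan_motifs(seq, "CTTTGC", m))
    b <- key(scan_motifs(seq, "CTTTGC", m + 1L))
    expect_true(all(a %in% b))
  }
})

test_that("IR pairing finds the two F-promoter pairs with correct arithmetic", {
  prom <- build_promoter_sequence(f_promoter_architecture(), seed = 11L)
  hits <- scan_motifs(prom$sequence, "CTTTGC", 2L)
  prs <- find_inverted_repeats(hits, 26L, 29L)
  expect_equal(nrow(prs), 2L)
  perfect <- prs[prs$irclass == "perfect", ]
  degen <- prs[prs$irclass == "degenerate", ]
  expect_equal(perfect$spacer, 28L)
  expect_equal(perfect$center_distance, 34L)
  expect_equal(degen$spacer, 27L)
  expect_equal(degen$right_observed, "TCTTGC")
  # pair arithmetic invariant
  expect_equal(prs$right_start - prs$left_start, prs$center_distance)
  expect_equal(prs$center_distance, prs$spacer + 6L)
})

test_that("orientation is required for pairing", {
  hits <- scan_motifs(paste0("AA", "CTTTGC", strrep("A", 28), "CTTTGC",
                             "AA"), "CTTTGC", 0L)
  expect_equal(nrow(hits), 2L)
  expect_equal(nrow(find_inverted_repeats(hits, 26L, 29L)), 0L)
})

test_that("architecture report flags overlaps, singletons and margins", {
  prom <- build_promoter_sequence(f_promoter_architecture(), seed = 11L)
  hits <- scan_motifs(prom$sequence, "CTTTGC", 2L)
  prs <- find_inverted_repeats(hits)
  rep_ <- classify_architecture(hits, prs, nchar(prom$sequence))
  # the degenerate and perfect IR footprints intersect
  expect_equal(nrow(rep_$overlaps), 2L) # symmetric listing of one couple
  expect_equal(rep_$overlaps$i, rev(rep_$overlaps$j))
  # motif #1 is paired to nothing
  expect_true(prom$truth$start[1] %in% rep_$singletons$start)
  expect_false(prom$truth$start[1] %in%
                 c(prs$left_start, prs$right_start))

  # a lone perfect IR with ample margin: one pair, no overlap, no flag
  seq2 <- paste0(strrep("A", 50), "CTTTGC", strrep("A", 28),
                 revcomp("CTTTGC"), strrep("A", 20))
  h2 <- scan_motifs(seq2, "CTTTGC", 0L)
  p2 <- find_inverted_repeats(h2)
  r2 <- classify_architecture(h2, p2, nchar(seq2))
  expect_equal(nrow(r2$ir_pairs), 1L)
  expect_equal(nrow(r2$overlaps), 0L)
  expect_true(r2$left_margin_ok)

  # an IR too close to the 5' end is flagged (mid-fragment probes do not
  # shift: the three-dimer complex needs DNA on the left)
  seq3 <- paste0(strrep("A", 10), "CTTTGC", strrep("A", 28),
                 revcomp("CTTTGC"), strrep("A", 60))
  h3 <- scan_motifs(seq3, "CTTTGC", 0L)
  r3 <- classify_architecture(h3, find_inverted_repeats(h3), nchar(seq3))
  expect_false(r3$left_margin_ok)
})

test_that("PFM columns count bases and information content is bounded", {
  motifs <- c("CTTTGC", "CTTTGC", "CTTTGC", "CTTTGC")
  pfm <- build_pfm(motifs)
  expect_true(all(colSums(pfm) == 4L))
  ic <- information_content(pfm)
  expect_equal(unname(ic$ic), rep(2, 6)) # perfectly conserved columns

  # uniform column has zero information
  pfm_u <- build_pfm(c("A", "C", "G", "T"))
  expect_equal(unname(information_content(pfm_u)$ic), 0)

  # 3:1 column: 2 - H(0.75, 0.25) = 1.1887 bits
  pfm_31 <- build_pfm(c("A", "A", "A", "C"))
  expect_equal(unname(information_content(pfm_31)$ic), 1.18872,
               tolerance = 1e-5)

  expect_error(build_pfm(c("ACGT", "ACG")), "equal lengths")
})

test_that("IC stays in [0, 2] and columns sum to n on random motif sets", {
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(3:16, 1)
    motifs <- replicate(n, random_dna(6, at = runif(1, 0.2, 0.8)))
    pfm <- build_pfm(motifs)
    expect_true(all(colSums(pfm) == n))
    ic <- information_content(pfm)$ic
    expect_true(all(ic >= 0 - 1e-12 & ic <= 2 + 1e-12))
    # letter heights sum to the column IC
    expect_equal(unname(colSums(information_content(pfm)$heights)),
                 unname(ic))
  }
})
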