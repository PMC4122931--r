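test_that("find_gaps reports exactly the maximal N-runs", {
  sc <- make_scaffolds(s1 = "ACGTNNNNNACGT")
  g <- find_gaps(sc, min_run = 5L)
  expect_equal(nrow(g), 1L)
  expect_equal(c(g$start, g$end, g$estimated_size), c(4L, 9L, 5L))

  expect_equal(nrow(find_gaps(make_scaffolds(s1 = "ACGTACGT"))), 0L)

  # runs at sequence ends count; min_run filters short runs
  sc2 <- make_scaffolds(s1 = "NNACGTNN")
  g2 <- find_gaps(sc2, min_run = 2L)
  expect_equal(g2$start, c(0L, 6L))
  expect_equal(g2$end, c(2L, 8L))
  expect_equal(nrow(find_gaps(sc2, min_run = 3L)), 0L)
})

test_that("repeat detection recovers planted copies, forward and rc", {
  set.seed(401)
  core <- endoerode:::random_dna(400)
  bg <- function(n) endoerode:::random_dna(n)
  seq <- paste0(bg(3000), core, bg(2500), core, bg(2000),
                endoerode:::revcomp(core), bg(1500))
  sc <- make_scaffolds(chr = seq)
  rep_ <- detect_repeats(sc, k = 24L, min_copies = 2L)
  truth <- data.frame(start = c(3000L, 3000L + 400L + 2500L,
                                3000L + 400L + 2500L + 400L + 2000L))
  truth$end <- truth$start + 400L
  covered <- sum(vapply(seq_len(nrow(truth)), function(i) {
    interval_overlap_bp(truth$start[i], truth$end[i], rep_)
  }, numeric(1)))
  expect_gte(covered / 1200, 0.95)
  # all three copies are one family (shared seeds, strand-aware)
  expect_equal(length(unique(rep_$family_id)), 1L)
  # false-positive masking on the background stays tiny
  fp <- sum(rep_$end - rep_$start) - covered
  expect_lte(fp / (nchar(seq) - 1200), 0.01)

  # unique-k-mer genome: nothing detected
  expect_equal(nrow(detect_repeats(make_scaffolds(u = bg(5000)), 24L, 2L)),
               0L)

  # iterated masking reaches its fixed point and agrees with one round
  expect_equal(repeat_mask_iterative(sc), rep_)
})

test_that("melting temperature matches a hand-summed NN computation", {
  # independent table sum for AGCGTCGACCTAGGATCAAC at 50 mM Na+, 500 nM:
  # dinucleotides AG GC CG GT TC CG GA AC CC CT TA AG GG GA AT TC CA AA AC
  dh <- c(-7.8, -9.8, -10.6, -8.4, -8.2, -10.6, -8.2, -8.4, -8.0, -7.8,
          -7.2, -7.8, -8.0, -8.2, -7.2, -8.2, -8.5, -7.9, -8.4)
  ds <- c(-21.0, -24.4, -27.2, -22.4, -22.2, -27.2, -22.2, -22.4, -19.9,
          -21.0, -21.3, -21.0, -19.9, -22.2, -20.4, -22.2, -22.7, -22.2,
          -22.4)
  dH <- sum(dh) + 2.3 + 0.1          # terminal A and terminal C initiations
  dS <- sum(ds) + 4.1 - 2.8
  dS <- dS + 0.368 * 19 * log(0.05)
  tm_oracle <- 1000 * dH / (dS + 1.9872 * log(500e-9 / 4)) - 273.15
  tm <- melting_temperature("AGCGTCGACCTAGGATCAAC", na_mM = 50,
                            primer_nM = 500)
  expect_equal(tm, tm_oracle, tolerance = 1e-6)
  # frozen cross-check value from an independent NN implementation
  expect_lt(abs(tm - 56.657), 0.1)
})

test_that("melting temperature is duplex-symmetric and GC-monotone", {
  set.seed(77)
  for (i in 1:20) {
    s <- endoerode:::random_dna(sample(18:27, 1))
    expect_equal(melting_temperature(s),
                 melting_temperature(endoerode:::revcomp(s)),
                 tolerance = 1e-9)
    expect_gte(melting_temperature(paste0(s, "GC")), melting_temperature(s))
  }
  expect_error(melting_temperature("ACGTNACGT"), "N")
  expect_error(melting_temperature("ACGT"), "shorter")
})

test_that("candidate gates reject the documented pathologies", {
  expect_equal(score_candidate("GATCAAAAAGCGTCGACCTAGG")$reason,
               "homopolymer")
  expect_equal(score_candidate(strrep("GC", 10))$reason, "gc")
  expect_equal(score_candidate(paste0(strrep("AT", 9), "GC"))$reason, "gc")
  ok <- score_candidate("AGCGTCGACCTAGGATCAAC", tm_range = c(50, 70))
  expect_true(ok$ok)
  expect_true(is.finite(ok$penalty) && ok$penalty >= 0)
})

test_that("designed pairs span the gap, avoid masks, and sit in the window", {
  set.seed(402)
  core <- endoerode:::random_dna(400)
  seq <- paste0(endoerode:::random_dna(1500), core,
                endoerode:::random_dna(800), strrep("N", 200),
                endoerode:::random_dna(900), core,
                endoerode:::random_dna(1400))
  sc <- make_scaffolds(chr = seq)
  gaps <- find_gaps(sc, min_run = 10L)
  reps <- detect_repeats(sc)
  res <- design_gap_primers(gaps[1, ], sc, reps)
  expect_s3_class(res, "primer_pair")
  expect_true(res$product_size >= 100 && res$product_size <= 1000)
  expect_true(res$left$end <= gaps$start[1])
  expect_true(res$right$start >= gaps$end[1])
  for (side in c("left", "right")) {
    pc <- res[[side]]
    expect_equal(interval_overlap_bp(pc$start, pc$end, reps), 0L)
    expect_false(grepl("N", substr(seq, pc$start + 1, pc$end)))
  }
  # right primer sequence is the reverse complement of its window
  expect_equal(res$right$sequence,
               endoerode:::revcomp(substr(seq, res$right$start + 1,
                                          res$right$end)))

  # a gap larger than the product window is a typed arithmetic failure
  big <- data.frame(scaffold_id = "chr", start = 100L, end = 2100L)
  fail <- design_gap_primers(big, make_scaffolds(
    chr = paste0(endoerode:::random_dna(100), strrep("N", 2000),
                 endoerode:::random_dna(100))), reps[0, ])
  expect_s3_class(fail, "primer_failure")
  expect_equal(fail$reason, "product_range_unsatisfiable")
})

test_that("fully masked flanks give the flanks_masked failure", {
  set.seed(403)
  core <- endoerode:::random_dna(1200)
  seq <- paste0(endoerode:::random_dna(300), core, strrep("N", 150), core,
                endoerode:::random_dna(300))
  sc <- make_scaffolds(chr = seq)
  gaps <- find_gaps(sc, min_run = 10L)
  reps <- detect_repeats(sc)
  res <- design_gap_primers(gaps[1, ], sc, reps, flank = 1000L)
  expect_s3_class(res, "primer_failure")
  expect_equal(res$reason, "flanks_masked")

  expect_error(design_gap_primers(
    data.frame(scaffold_id = "nope", start = 0L, end = 10L), sc, reps),
    "unknown scaffold")
})

test_that("coverage arithmetic matches its definition", {
  expect_equal(coverage_report(68, 96)$percent, 70.83)
  expect_equal(coverage_report(0, 7)$percent, 0)
  expect_equal(coverage_report(5, 10)$percent, 50)
})
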