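test_that("genome generation is deterministic and respects constraints", {
  cfg <- sim_config(seed = 1, genome_length = 50000L, n_genes = 40L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$features), 40L)
  # non-overlapping, in order
  f <- g1$features
  expect_true(all(f$start[-1] >= f$end[-nrow(f)]))
  expect_true(all(f$start >= 0 & f$end <= 50000))

  g0 <- generate_genome(sim_config(seed = 1, n_genes = 0L))
  expect_equal(nrow(g0$features), 0L)

  expect_error(
    generate_genome(sim_config(seed = 1, genome_length = 5000L,
                               n_genes = 40L,
                               gene_length_range = c(300L, 400L))),
    "exceeds genome_length")
})

test_that("generated artifacts are parseable by the io layer", {
  g <- generate_genome(sim_config(seed = 5, genome_length = 20000L,
                                  n_genes = 15L))
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(g$scaffolds, fa)
  write_feature_table(g$features, tsv)
  expect_equal(read_fasta(fa)$records, g$scaffolds$records)
  back <- read_feature_table(tsv, dialect = "tsv")
  expect_equal(back$start, g$features$start)
  expect_equal(back$end, g$features$end)
})

test_that("inversions flip the signed permutation block by block", {
  # hand-checkable case: force the block spanning genes 2..3 of 4
  g <- generate_genome(sim_config(seed = 2, genome_length = 8000L,
                                  n_genes = 4L,
                                  gene_length_range = c(300L, 500L)))
  inv0 <- apply_inversions(g$scaffolds, g$features, 0L, seed = 9)
  expect_equal(inv0$truth$perm, 1:4)

  set.seed(99)
  found <- FALSE
  for (s in 1:200) {
    inv <- apply_inversions(g$scaffolds, g$features, 1L, seed = s)
    if (identical(inv$truth$blocks[[1]], c(2L, 3L))) {
      expect_equal(inv$truth$perm, c(1L, -3L, -2L, 4L))
      found <- TRUE
      break
    }
  }
  expect_true(found)
  expect_error(apply_inversions(g$scaffolds, g$features, -1L, seed = 1),
               ">= 0")
})

test_that("inversion scars are planted as IS features at breakpoints", {
  g <- generate_genome(sim_config(seed = 3, genome_length = 60000L,
                                  n_genes = 30L))
  inv <- apply_inversions(g$scaffolds, g$features, 4L, seed = 11,
                          plant_is = TRUE)
  n_is <- sum(inv$features$klass == "IS")
  expect_equal(n_is, length(inv$truth$breakpoints))
  expect_lte(n_is, 8L)     # 2 per inversion minus merges
  expect_gt(n_is, 0L)
})

test_that("scaffoldize plants recoverable gaps and rejects impossible asks", {
  g <- generate_genome(sim_config(seed = 4))
  sg <- scaffoldize(g$scaffolds, g$features, 5L, c(100L, 500L), seed = 4)
  found <- find_gaps(sg$scaffolds, min_run = 10L)
  expect_equal(found$start, sg$truth$start)
  expect_equal(found$end, sg$truth$end)
  # restoring the recorded original content undoes the gapping exactly
  seq <- sg$scaffolds$records[[1]]
  for (i in seq_len(nrow(sg$truth))) {
    substr(seq, sg$truth$start[i] + 1, sg$truth$end[i]) <- sg$truth$original[i]
  }
  expect_identical(seq, g$scaffolds$records[[1]])

  sg0 <- scaffoldize(g$scaffolds, g$features, 0L, c(100L, 500L), seed = 4)
  expect_identical(sg0$scaffolds$records, g$scaffolds$records)

  expect_error(
    scaffoldize(g$scaffolds, g$features, 500L, c(400L, 500L), seed = 4),
    "exceeds available")
})

test_that("planted repeats overwrite only intergenic space, forward or rc", {
  g <- generate_genome(sim_config(seed = 6))
  sg <- scaffoldize(g$scaffolds, g$features, 4L, c(100L, 300L), seed = 6)
  pr <- plant_repeats(sg$scaffolds, g$features, 2L, 3L, 400L, seed = 6,
                      gaps = sg$truth)
  expect_equal(nrow(pr$truth), 6L)
  expect_setequal(unique(pr$truth$family_id), c("truefam_01", "truefam_02"))
  # no planted copy intersects a gene or a gap
  for (i in seq_len(nrow(pr$truth))) {
    expect_equal(interval_overlap_bp(pr$truth$start[i], pr$truth$end[i],
                                     g$features), 0L)
    expect_equal(interval_overlap_bp(pr$truth$start[i], pr$truth$end[i],
                                     sg$truth), 0L)
  }
  # copies of one family are identical up to reverse complement
  fam <- pr$truth[pr$truth$family_id == "truefam_01", ]
  seqs <- substring(pr$scaffolds$records[[1]], fam$start + 1, fam$end)
  canon <- ifelse(fam$strand == "+", seqs,
                  vapply(seqs, function(s) endoerode:::revcomp(s),
                         character(1)))
  expect_equal(length(unique(canon)), 1L)

  p0 <- plant_repeats(sg$scaffolds, g$features, 0L, 3L, 400L, seed = 6)
  expect_identical(p0$scaffolds$records, sg$scaffolds$records)
})

test_that("pseudogenize records truth states and leaves intacts alone", {
  prots <- stats::setNames(
    vapply(rep(200, 30), function(n) endoerode:::random_protein(n),
           character(1)),
    sprintf("p%02d", 1:30))
  p0 <- pseudogenize(prots, fraction = 0, seed = 8)
  expect_true(all(p0$truth$state == "intact"))
  expect_identical(p0$proteins, prots)

  ps <- pseudogenize(prots, fraction = 0.4, seed = 8)
  expect_equal(sum(ps$truth$state == "pseudo"), 12L)
  expect_true(all(ps$truth$retained[ps$truth$state == "pseudo"] < 1))
  # gray zone around the downstream cutoff is excluded by construction
  r <- ps$truth$retained[ps$truth$state == "pseudo"]
  expect_true(all(r < 0.25 | r > 0.35))
  # untouched proteins are unchanged
  keep <- ps$truth$state == "intact"
  expect_identical(ps$proteins[keep], prots[keep])
})

test_that("simulated mate-pair libraries match their planted mixture", {
  lens <- c(ctg1 = 300000L, ctg2 = 300000L)
  cfg <- sim_config(seed = 12, matepair = list(n_pairs = 12000L))
  mp <- simulate_matepairs(lens, cfg, seed = 12)
  expect_equal(nrow(mp), 12000L)
  # per-class fractions within 3 binomial SE of the planted mixture
  fr <- cfg$matepair$fractions
  for (k in names(fr)) {
    p <- fr[[k]]
    se <- sqrt(p * (1 - p) / nrow(mp))
    expect_lt(abs(mean(mp$truth_class == k) - p), 3 * se + 1e-12)
  }
  # every record lies within contig bounds, mates on the same contig
  expect_true(all(mp$start1 >= 0 & mp$end1 <= lens[mp$contig1]))
  expect_true(all(mp$start2 >= 0 & mp$end2 <= lens[mp$contig2]))

  mp0 <- simulate_matepairs(lens, sim_config(seed = 1,
                                             matepair = list(n_pairs = 0L)),
                            seed = 1)
  expect_equal(nrow(mp0), 0L)

  expect_error(simulate_matepairs(c(short = 4000L), cfg, seed = 1),
               "shorter than")
})

test_that("a pure concordant library is classified 100% concordant", {
  cfg <- sim_config(seed = 13, matepair = list(
    n_pairs = 2000L,
    fractions = c(concordant_RF = 1, FR_contam = 0, RF_discordant = 0,
                  FF_err = 0, RR_err = 0)))
  mp <- simulate_matepairs(c(ctg = 200000L), cfg, seed = 13)
  cl <- filter_cascade(mp)
  expect_true(all(cl$disposition == "concordant_discarded"))
})

test_that("the seed fan-out rule is deterministic and stage-separating", {
  expect_identical(sim_child_seed(42, "genome"), sim_child_seed(42, "genome"))
  expect_false(sim_child_seed(42, "genome") == sim_child_seed(42, "repeats"))
  expect_true(sim_child_seed(2147483646, "x") < 2147483647)
})
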