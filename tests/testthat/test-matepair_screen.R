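mk_pairs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(pair_id = paste0("p", i),
               contig1 = r$c1, start1 = r$s1, end1 = r$e1, strand1 = r$st1,
               contig2 = r$c2, start2 = r$s2, end2 = r$e2, strand2 = r$st2,
               stringsAsFactors = FALSE)
  }))
}
pp <- function(c1, s1, e1, st1, c2 = c1, s2, e2, st2) {
  list(c1 = c1, s1 = s1, e1 = e1, st1 = st1,
       c2 = c2, s2 = s2, e2 = e2, st2 = st2)
}

test_that("orientation and insert size follow the leftmost-mate convention", {
  recs <- mk_pairs(
    pp("c", 100, 200, "+", s2 = 3000, e2 = 3100, st2 = "-"),   # FR
    pp("c", 100, 200, "-", s2 = 3000, e2 = 3100, st2 = "+"),   # RF
    pp("c", 100, 200, "+", s2 = 3000, e2 = 3100, st2 = "+"),   # FF
    pp("c", 100, 200, "-", s2 = 3000, e2 = 3100, st2 = "-"))   # RR
  cl <- classify_orientation(recs)
  expect_equal(cl$orientation, c("FR", "RF", "FF", "RR"))
  expect_equal(cl$insert_size, rep(3000L, 4))

  # swapping the mate labels changes nothing
  swapped <- recs[, c("pair_id", "contig2", "start2", "end2", "strand2",
                      "contig1", "start1", "end1", "strand1")]
  names(swapped) <- names(recs)
  cl2 <- classify_orientation(swapped)
  expect_equal(cl2$orientation, cl$orientation)
  expect_equal(cl2$insert_size, cl$insert_size)

  # different contigs: no orientation, no insert
  inter <- mk_pairs(pp("c1", 100, 200, "+", c2 = "c2", s2 = 50, e2 = 150,
                       st2 = "-"))
  cli <- classify_orientation(inter)
  expect_false(cli$same_contig)
  expect_true(is.na(cli$orientation) && is.na(cli$insert_size))
})

test_that("the filter cascade applies the published rules in order", {
  mobile <- data.frame(contig = "c", start = 50000L, end = 51000L)
  recs <- mk_pairs(
    pp("c", 100, 200, "-", s2 = 3000, e2 = 3100, st2 = "+"),   # concordant
    pp("c", 100, 200, "-", s2 = 4000, e2 = 4100, st2 = "+"),   # RF kept
    pp("c", 50500, 50600, "+", s2 = 53000, e2 = 53100, st2 = "-"), # mobile
    pp("c", 100, 200, "+", c2 = "d", s2 = 100, e2 = 200, st2 = "-"),
    pp("c", 100, 250, "+", s2 = 249, e2 = 400, st2 = "-"),     # 1 bp overlap
    pp("c", 100, 200, "+", s2 = 400, e2 = 500, st2 = "-"))     # FR kept
  cl <- filter_cascade(recs, mobile_regions = mobile)
  expect_equal(cl$disposition,
               c("concordant_discarded", "retained", "mobile_discarded",
                 "intercontig", "overlap_discarded", "retained"))
  # conservation: dispositions partition the input
  expect_equal(sum(table(cl$disposition)), nrow(recs))
  # a concordant-looking pair in a mobile region is caught by the
  # concordant filter first (cascade order)
  rec2 <- mk_pairs(pp("c", 50100, 50200, "-", s2 = 53000, e2 = 53100,
                      st2 = "+"))
  expect_equal(filter_cascade(rec2, mobile_regions = mobile)$disposition,
               "concordant_discarded")
})

test_that("orientation summary fractions are percentages of retained", {
  s <- orientation_summary(c(FF = 10, RR = 10, RF = 30, FR = 50))
  expect_equal(s$retained_total, 100)
  expect_equal(unname(s$orientation_percent["FR"]), 50)

  # empty retained set: NA percentages, zero total
  empty <- filter_cascade(mk_pairs(
    pp("c", 100, 200, "-", s2 = 3000, e2 = 3100, st2 = "+")))
  s0 <- orientation_summary(empty)
  expect_equal(s0$retained_total, 0)
  expect_true(all(is.na(s0$orientation_percent)))

  # one-class library: 100% that class
  s1 <- orientation_summary(c(FF = 0, RR = 0, RF = 0, FR = 7))
  expect_equal(unname(s1$orientation_percent["FR"]), 100)
})

test_that("recovered class fractions track the planted mixture", {
  cfg <- sim_config(seed = 14, matepair = list(n_pairs = 15000L))
  mp <- simulate_matepairs(c(ctg1 = 400000L, ctg2 = 400000L), cfg, seed = 14)
  cl <- filter_cascade(mp)
  # truth classes map onto recovered dispositions/orientations exactly
  expect_true(all(cl$disposition[cl$truth_class == "concordant_RF"] ==
                    "concordant_discarded"))
  ret <- cl[cl$disposition == "retained", ]
  expect_true(all(ret$orientation[ret$truth_class == "FR_contam"] == "FR"))
  expect_true(all(ret$orientation[ret$truth_class == "FF_err"] == "FF"))
  expect_true(all(ret$orientation[ret$truth_class == "RR_err"] == "RR"))
  expect_true(all(ret$orientation[ret$truth_class == "RF_discordant"] ==
                    "RF"))
})

test_that("junction clustering finds planted junctions, not scatter", {
  set.seed(901)
  # 15 RF pairs at a common junction on a simulated inverted allele
  junc <- do.call(rbind, lapply(1:15, function(i) {
    off1 <- sample(0:400, 1); off2 <- sample(0:400, 1)
    data.frame(pair_id = paste0("j", i), contig1 = "c",
               start1 = 20000L + off1, end1 = 20100L + off1, strand1 = "-",
               contig2 = "c", start2 = 60000L + off2, end2 = 60100L + off2,
               strand2 = "+", stringsAsFactors = FALSE)
  }))
  cl <- filter_cascade(junc)
  j <- junction_evidence(cl)
  expect_equal(nrow(j), 1L)
  expect_equal(j$support, 15L)
  expect_equal(j$orientation, "RF")

  # scattered FF/RR singletons never reach min_support
  scatter <- do.call(rbind, lapply(1:30, function(i) {
    s1 <- i * 30000L
    data.frame(pair_id = paste0("s", i), contig1 = "c",
               start1 = s1, end1 = s1 + 100L, strand1 = "+",
               contig2 = "c", start2 = s1 + 5000L, end2 = s1 + 5100L,
               strand2 = "+", stringsAsFactors = FALSE)
  }))
  expect_equal(nrow(junction_evidence(filter_cascade(scatter))), 0L)
  # min_support 1 degenerates to counting single-linkage components
  expect_equal(nrow(junction_evidence(filter_cascade(scatter),
                                      min_support = 1L)), 30L)
})

test_that("mate-pair tables round-trip through the TSV reader", {
  path <- withr::local_tempfile(fileext = ".tsv")
  mp <- simulate_matepairs(c(ctg = 100000L),
                           sim_config(seed = 2,
                                      matepair = list(n_pairs = 50L)),
                           seed = 2)
  utils::write.table(mp[, 1:9], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  back <- read_matepair_table(path)
  expect_equal(back, mp[, 1:9])
  writeLines(c("pair_id\tcontig1\tstart1\tend1\tstrand1\tcontig2\tstart2\tend2\tstrand2",
               "p1\tc\t200\t100\t+\tc\t300\t400\t-"), path)
  expect_error(read_matepair_table(path), "start >= end")
})
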