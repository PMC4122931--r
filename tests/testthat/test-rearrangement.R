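feat_from_order <- function(order, scaffold = "chr", prefix = "og") {
  n <- length(order)
  data.frame(feature_id = sprintf("g%02d", seq_len(n)),
             scaffold_id = scaffold,
             start = seq(0L, by = 1000L, length.out = n),
             end = seq(600L, by = 1000L, length.out = n),
             strand = ifelse(order > 0, "+", "-"),
             klass = "CDS", family = NA_character_,
             cog_category = NA_character_,
             ortho_group = sprintf("%s_%02d", prefix, abs(order)),
             stringsAsFactors = FALSE)
}

test_that("shared signed orders exclude mobiles, multicopies, privates", {
  fa <- feat_from_order(1:4)
  fb <- feat_from_order(c(1L, -3L, -2L, 4L))
  so <- shared_signed_orders(fa, fb)
  expect_equal(so$a$order, 1:4)
  expect_equal(so$b$order, c(1L, -3L, -2L, 4L))

  # identical genomes give the identity
  so_id <- shared_signed_orders(fa, fa)
  expect_equal(so_id$b$order, 1:4)

  # a gene private to A disappears from both orders
  fb2 <- fb[fb$ortho_group != "og_02", ]
  so2 <- shared_signed_orders(fa, fb2)
  expect_equal(length(so2$a$order), 3L)
  expect_false("og_02" %in% names(so2$a$index_map))

  # mobile-class features never enter the index
  fa_is <- rbind(fa, within(fa[1, ], {
    feature_id <- "isX"; klass <- "IS"; ortho_group <- "og_99"
    start <- 9000L; end <- 9100L
  }))
  fb_is <- rbind(fb, within(fb[1, ], {
    feature_id <- "isY"; klass <- "IS"; ortho_group <- "og_99"
    start <- 9000L; end <- 9100L
  }))
  expect_false("og_99" %in%
                 names(shared_signed_orders(fa_is, fb_is)$a$index_map))

  # multicopy groups are excluded with a count
  fa_dup <- rbind(fa, within(fa[1, ], {
    feature_id <- "dup"; start <- 9000L; end <- 9600L
  }))
  so3 <- shared_signed_orders(fa_dup, fb)
  expect_equal(so3$n_excluded_multicopy, 1L)
  expect_false("og_01" %in% names(so3$a$index_map))
})

test_that("synteny clusters equal exhaustive maximal-run search", {
  # identity: one cluster covering everything
  id <- list(a = list(order = 1:6), b = list(order = 1:6))
  expect_equal(nrow(synteny_clusters(id)), 1L)

  # the worked inversion example splits into {1,2,3} and {4,5}
  ex <- list(a = list(order = 1:5), b = list(order = c(1L, 2L, 3L, -5L, -4L)))
  cl <- synteny_clusters(ex)
  expect_equal(cl$n_genes, c(3L, 2L))

  # exhaustive check against the brute-force oracle: all signed
  # permutations for n <= 5, seeded samples for n = 6, 7
  for (n in 2:5) {
    for (p in all_signed_perms(n)) {
      got <- synteny_clusters(list(a = list(order = seq_len(n)),
                                   b = list(order = p)))
      want <- oracle_colinear_runs(p)
      expect_equal(got$n_genes, lengths(want), info = paste(p, collapse = ","))
    }
  }
  set.seed(701)
  for (n in 6:7) {
    for (rep_ in 1:200) {
      p <- sample(seq_len(n)) * sample(c(-1L, 1L), n, replace = TRUE)
      got <- synteny_clusters(list(a = list(order = seq_len(n)),
                                   b = list(order = p)))
      want <- oracle_colinear_runs(p)
      expect_equal(got$n_genes, lengths(want), info = paste(p, collapse = ","))
    }
  }
})

test_that("clusters partition the shared gene set in A order", {
  set.seed(702)
  g <- generate_genome(sim_config(seed = 31, genome_length = 60000L,
                                  n_genes = 40L))
  inv <- apply_inversions(g$scaffolds, g$features, 5L, seed = 31)
  so <- shared_signed_orders(g$features, inv$features)
  cl <- synteny_clusters(so)
  members <- unlist(strsplit(cl$members, ","))
  expect_identical(members, names(so$a$index_map))
  expect_equal(sum(cl$n_genes), length(so$a$order))
})

test_that("breakpoint distance matches hand counts and bounds", {
  expect_equal(breakpoint_distance(1:8), 0L)
  expect_equal(breakpoint_distance(c(1L, -3L, -2L, 4L)), 2L)
  # every single inversion of the identity costs 2 breakpoints, or 1 when a
  # frame edge absorbs one (brute force over all i <= j, n <= 8)
  for (n in c(4L, 6L, 8L)) {
    for (i in seq_len(n)) {
      for (j in i:n) {
        p <- seq_len(n)
        p[i:j] <- -rev(p[i:j])
        expect_true(breakpoint_distance(p) %in% c(1L, 2L),
                    info = paste(n, i, j))
      }
    }
  }
  expect_error(breakpoint_distance(c(1L, 1L, 2L)), "signed permutation")
})

test_that("circular framing is invariant under whole-genome reversal", {
  expect_equal(breakpoint_distance(c(-4L, -3L, -2L, -1L), circular = TRUE),
               0L)
  set.seed(703)
  for (rep_ in 1:25) {
    n <- sample(3:9, 1)
    p <- sample(seq_len(n)) * sample(c(-1L, 1L), n, replace = TRUE)
    flipped <- -rev(p)
    expect_equal(breakpoint_distance(p, circular = TRUE),
                 breakpoint_distance(flipped, circular = TRUE),
                 info = paste(p, collapse = ","))
  }
})

test_that("planted inversions respect the distance/2 lower bound and trend", {
  set.seed(704)
  dists <- integer(0); ninvs <- integer(0)
  for (rep_ in 1:20) {
    k <- sample(0:12, 1)
    g <- generate_genome(sim_config(seed = 7000 + rep_,
                                    genome_length = 120000L,
                                    n_genes = 100L))
    inv <- apply_inversions(g$scaffolds, g$features, k, seed = 7000 + rep_,
                            plant_is = FALSE)
    d <- breakpoint_distance(inv$truth$perm)
    expect_gte(k, d / 2)
    dists <- c(dists, d); ninvs <- c(ninvs, k)
  }
  expect_gt(suppressWarnings(cor(ninvs, dists, method = "spearman")), 0.9)
})

test_that("pairwise distance matrices are symmetric with zero diagonal", {
  g <- generate_genome(sim_config(seed = 32, genome_length = 50000L,
                                  n_genes = 30L))
  inv1 <- apply_inversions(g$scaffolds, g$features, 3L, seed = 41)
  inv2 <- apply_inversions(g$scaffolds, g$features, 6L, seed = 42)
  m <- pairwise_distance_matrix(list(A = g$features, B = inv1$features,
                                     C = inv2$features))
  expect_equal(diag(m), c(A = 0L, B = 0L, C = 0L))
  expect_identical(m, t(m))
  expect_equal(pairwise_distance_matrix(list(A = g$features,
                                             A2 = g$features))["A", "A2"],
               0L)
})

test_that("greedy reversal sort is an upper bound that reaches identity", {
  set.seed(705)
  for (rep_ in 1:10) {
    n <- sample(4:8, 1)
    p <- sample(seq_len(n)) * sample(c(-1L, 1L), n, replace = TRUE)
    cnt <- greedy_reversal_count(p)
    expect_gte(cnt, breakpoint_distance(p) / 2)
  }
  expect_equal(greedy_reversal_count(1:5), 0L)
})

test_that("flanking tally finds mobiles within the window on either side", {
  g <- generate_genome(sim_config(seed = 33, genome_length = 80000L,
                                  n_genes = 50L))
  inv <- apply_inversions(g$scaffolds, g$features, 4L, seed = 51,
                          plant_is = TRUE)
  # tally in the derived genome's coordinates, where the scars live
  so <- shared_signed_orders(inv$features, g$features)
  cl <- synteny_clusters(so)
  tally <- flanking_element_tally(cl, inv$features, window = 3000L)
  # IS scars sit at inversion breakpoints, i.e. at cluster boundaries in
  # the derived genome: with spans taken from strain A some terminal
  # clusters may be unflanked, but breakpoint-adjacent ones must be hit
  expect_gte(tally$counts[["IS"]], nrow(cl) - 2L)
  expect_equal(sum(tally$per_cluster$none),
               tally$counts[["none"]])

  # an element 1.5 kb past a boundary counts; 4 kb away does not
  cl1 <- data.frame(cluster_id = "c1", a_scaffold = "chr",
                    a_start = 10000L, a_end = 20000L,
                    stringsAsFactors = FALSE)
  near <- data.frame(feature_id = "e1", scaffold_id = "chr",
                     start = 21500L, end = 21600L, strand = "+",
                     klass = "IS", family = NA, cog_category = NA,
                     ortho_group = NA, stringsAsFactors = FALSE)
  far <- within(near, { start <- 24000L; end <- 24100L })
  expect_equal(flanking_element_tally(cl1, near)$counts[["IS"]], 1L)
  t2 <- flanking_element_tally(cl1, far)
  expect_equal(t2$counts[["IS"]], 0L)
  expect_equal(t2$counts[["none"]], 1L)
})
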