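## Synthetic genomes, scaffolds, protein sets and mate-pair libraries with
## known ground truth, so every analysis stage is testable without any
## external download. One global seed fans out to per-stage child seeds by a
## fixed multiplicative rule, keeping stages reproducible yet independent.

#' Derive a deterministic per-stage child seed
#'
#' `child = (seed * 48271 + hash(stage)) mod (2^31 - 1)`, where `hash` is the
#' sum of the UTF-8 codes of the stage name. Keeps all derived seeds inside
#' 32-bit integer range.
#'
#' @param seed Integer master seed.
#' @param stage Stage name (character scalar).
#' @return Integer child seed in `[1, 2^31 - 2]`.
#' @export
sim_child_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage))
  x <- (as.numeric(seed) %% 2147483647) * 48271 + h
  s <- as.integer(x %% 2147483647)
  if (s == 0L) s <- 1L
  s
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-genome generator. Defaults emulate
#' the assembly state of a mobile-element-rich facultative endosymbiont
#' draft: a ~100 kb chromosome slice, N-gapped scaffolds, planted repeat
#' families near gap flanks, inversions with insertion-sequence scars at
#' breakpoints, and a ~3 kb-insert mate-pair library dominated by concordant
#' RF pairs with paired-end (FR) contamination and rare FF/RR errors.
#'
#' @param seed Integer master seed (mandatory).
#' @param genome_length Chromosome length in bp.
#' @param n_genes Number of genes.
#' @param gene_length_range Gene length interval in bp.
#' @param n_repeat_families,repeat_length,repeat_copies Planted repeat
#'   families: count, core length (bp), copies per family.
#' @param n_gaps,gap_size_range Assembly gaps: count and size interval (bp).
#' @param n_inversions Number of planted inversions.
#' @param pseudogenize_fraction Fraction of proteins to inactivate.
#' @param gc G+C fraction of the background (default 0.5).
#' @param matepair List with `n_pairs`, `insert_mu`, `insert_sd`, `read_len`
#'   and `fractions`, a named vector over classes `concordant_RF`,
#'   `FR_contam`, `RF_discordant`, `FF_err`, `RR_err` summing to 1.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_length = 100000L,
                       n_genes = 80L,
                       gene_length_range = c(300L, 1500L),
                       n_repeat_families = 2L,
                       repeat_length = 400L,
                       repeat_copies = 3L,
                       n_gaps = 5L,
                       gap_size_range = c(100L, 500L),
                       n_inversions = 3L,
                       pseudogenize_fraction = 0.3,
                       gc = 0.5,
                       matepair = list()) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  mp <- utils::modifyList(list(
    n_pairs = 10000L, insert_mu = 2931, insert_sd = 240, read_len = 100L,
    ## overall mixture emulating the study library: ~77.7% concordant pairs,
    ## the remainder split as in the retained discordant classes
    fractions = c(concordant_RF = 0.7769,
                  FR_contam = 0.21257,
                  RF_discordant = 0.00759,
                  FF_err = 0.00096,
                  RR_err = 0.00198)), matepair)
  mp$fractions <- mp$fractions / sum(mp$fractions)
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              n_genes = n_genes, gene_length_range = gene_length_range,
              n_repeat_families = n_repeat_families,
              repeat_length = repeat_length, repeat_copies = repeat_copies,
              n_gaps = n_gaps, gap_size_range = gap_size_range,
              n_inversions = n_inversions,
              pseudogenize_fraction = pseudogenize_fraction,
              gc = gc, matepair = mp)
  counts <- c(cfg$genome_length, cfg$n_genes, cfg$n_repeat_families,
              cfg$repeat_copies, cfg$n_gaps, cfg$n_inversions, mp$n_pairs)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (abs(sum(mp$fractions) - 1) > 1e-9) {
    stop("mate-pair class fractions must sum to 1", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

## sample() guard for possibly length-1 vectors
resample <- function(x, size = 1, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic genome with non-overlapping genes
#'
#' Background bases are i.i.d. with the configured G+C; genes are placed
#' without overlap by distributing the leftover space multinomially between
#' them, so placement always succeeds when the summed gene lengths fit.
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `scaffolds` (a single-chromosome [scaffold_set()]),
#'   `features` (gene table, klass `CDS`, ortho groups in genomic order) and
#'   `truth` (the same gene table).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_child_seed(config$seed, "genome"))
  L <- config$genome_length
  n <- config$n_genes
  seq <- random_dna(L, config$gc)
  if (n == 0) {
    sc <- scaffold_set(stats::setNames(seq, "chr1"))
    return(list(scaffolds = sc, features = empty_features(),
                truth = empty_features()))
  }
  lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 n, replace = TRUE)
  slack <- L - sum(lens)
  if (slack < 0) {
    stop("total gene span exceeds genome_length; reduce n_genes or ",
         "gene lengths", call. = FALSE)
  }
  ## broken-stick intergenic spacing: exponential-like, so a realistic share
  ## of intergenic segments is long enough to host gaps and repeat copies
  cuts <- sort(resample(0:slack, n))
  spacers <- as.integer(diff(c(0L, cuts, slack)))
  starts <- cumsum(c(0L, lens[-n])) + cumsum(spacers[-(n + 1)])
  strand <- sample(c("+", "-"), n, replace = TRUE)
  features <- data.frame(
    feature_id = sprintf("gene_%03d", seq_len(n)),
    scaffold_id = "chr1",
    start = starts, end = starts + lens,
    strand = strand, klass = "CDS", family = NA_character_,
    cog_category = NA_character_,
    ortho_group = sprintf("og_%03d", seq_len(n)),
    stringsAsFactors = FALSE)
  sc <- scaffold_set(stats::setNames(seq, "chr1"))
  list(scaffolds = sc, features = features, truth = features)
}

reverse_complement_region <- function(seq, start, end) {
  ## 0-based half-open region
  paste0(substr(seq, 1, start),
         revcomp(substr(seq, start + 1, end)),
         substr(seq, end + 1, nchar(seq)))
}

#' Apply random inversions between genes
#'
#' Each inversion picks a contiguous block of genes (in the current order)
#' and two breakpoints in the flanking intergenic space, reverse-complements
#' the enclosed sequence, updates the gene coordinates and strands, and
#' flips the corresponding block of the signed gene-order truth permutation.
#' Optionally a short insertion-sequence scar is annotated at each
#' breakpoint.
#'
#' @param scaffolds Single-chromosome [scaffold_set()].
#' @param features Gene table from [generate_genome()].
#' @param n_inversions Number of inversions (>= 0).
#' @param seed Integer seed.
#' @param plant_is Annotate an `IS` feature at each breakpoint (default
#'   TRUE).
#' @param is_width Width in bp of the annotated IS scar (default 30).
#' @return List with `scaffolds`, `features` (genes plus any IS scars),
#'   `truth` = list(`perm` signed permutation of original gene indices,
#'   `blocks` inverted gene-position blocks, `breakpoints` bp coordinates).
#' @export
apply_inversions <- function(scaffolds, features, n_inversions, seed,
                             plant_is = TRUE, is_width = 30L) {
  if (n_inversions < 0) stop("n_inversions must be >= 0", call. = FALSE)
  stopifnot(inherits(scaffolds, "scaffold_set"))
  set.seed(sim_child_seed(seed, "inversions"))
  sid <- names(scaffolds$records)[1]
  seq <- scaffolds$records[[sid]]
  L <- nchar(seq)
  genes <- features[features$klass == "CDS", , drop = FALSE]
  genes <- genes[order(genes$start), , drop = FALSE]
  n <- nrow(genes)
  perm <- seq_len(n)                       # signed original indices
  blocks <- list(); bps <- integer(0)
  if (n_inversions > 0 && n >= 1) {
    for (it in seq_len(n_inversions)) {
      ij <- sort(sample.int(n, 2, replace = TRUE))
      i <- ij[1]; j <- ij[2]
      left_lo <- if (i == 1) 0L else genes$end[i - 1]
      left_hi <- genes$start[i]
      right_lo <- genes$end[j]
      right_hi <- if (j == n) L else genes$start[j + 1]
      bp1 <- resample(left_lo:left_hi)
      bp2 <- resample(right_lo:right_hi)
      ## earlier scars inside the inverted region move with it
      inside <- bps >= bp1 & bps < bp2
      bps[inside] <- bp1 + (bp2 - bps[inside])
      seq <- reverse_complement_region(seq, bp1, bp2)
      ## remap genes i..j
      blk <- i:j
      ns <- bp1 + (bp2 - genes$end[blk])
      ne <- bp1 + (bp2 - genes$start[blk])
      genes$start[blk] <- ns
      genes$end[blk] <- ne
      genes$strand[blk] <- ifelse(genes$strand[blk] == "+", "-", "+")
      genes[blk, ] <- genes[rev(blk), ]
      perm[blk] <- -rev(perm[blk])
      blocks[[it]] <- c(i, j)
      bps <- c(bps, bp1, bp2)
    }
  }
  out_feats <- genes
  if (plant_is && length(bps)) {
    ub <- unique(bps)
    is_df <- data.frame(
      feature_id = sprintf("is_%03d", seq_along(ub)),
      scaffold_id = sid,
      start = pmax(0L, as.integer(ub) - is_width %/% 2L),
      end = pmin(L, as.integer(ub) + is_width %/% 2L),
      strand = "+", klass = "IS", family = "IS481",
      cog_category = NA_character_, ortho_group = NA_character_,
      stringsAsFactors = FALSE)
    out_feats <- rbind(out_feats, is_df)
  }
  out_feats <- out_feats[order(out_feats$start), , drop = FALSE]
  rownames(out_feats) <- NULL
  sc <- scaffold_set(stats::setNames(seq, sid))
  list(scaffolds = sc, features = out_feats,
       truth = list(perm = perm, blocks = blocks, breakpoints = sort(unique(bps))))
}

## Intervals on one scaffold not covered by any feature: candidates for
## planting gaps and repeats.
free_intervals <- function(L, features, extra = NULL) {
  occ <- rbind(
    if (nrow(features)) features[, c("start", "end")] else NULL,
    if (!is.null(extra) && nrow(extra)) extra[, c("start", "end")] else NULL)
  if (is.null(occ) || nrow(occ) == 0) {
    return(data.frame(start = 0L, end = L))
  }
  ir <- IRanges::reduce(IRanges::IRanges(occ$start + 1L, occ$end))
  gaps <- IRanges::gaps(ir, start = 1L, end = L)
  data.frame(start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps))
}

#' Replace intergenic segments with assembly gaps (N-runs)
#'
#' Picks `n_gaps` distinct intergenic segments that can hold a sampled gap
#' size (plus a 1 bp non-N margin on each side), and overwrites a centered
#' slice with Ns. Coordinates are untouched (replacement, not insertion), so
#' all feature annotations stay valid.
#'
#' @param scaffolds Single-chromosome [scaffold_set()].
#' @param features Feature table (used to find intergenic space).
#' @param n_gaps Number of gaps.
#' @param gap_size_range Gap size interval in bp.
#' @param seed Integer seed.
#' @return List with `scaffolds` (N-gapped), `truth` data frame
#'   (`scaffold_id, start, end, original`).
#' @export
scaffoldize <- function(scaffolds, features, n_gaps, gap_size_range, seed) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  set.seed(sim_child_seed(seed, "scaffoldize"))
  sid <- names(scaffolds$records)[1]
  seq <- scaffolds$records[[sid]]
  L <- nchar(seq)
  truth <- data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), original = character(),
                      stringsAsFactors = FALSE)
  if (n_gaps == 0) {
    return(list(scaffolds = scaffolds, truth = truth))
  }
  free <- free_intervals(L, features[features$scaffold_id == sid, ])
  sizes <- sample(seq(gap_size_range[1], gap_size_range[2]), n_gaps,
                  replace = TRUE)
  ## match the largest gaps to intervals first so every sampled size finds
  ## a host segment whenever one exists
  taken <- rep(FALSE, nrow(free))
  picks <- integer(n_gaps)
  for (t in order(sizes, decreasing = TRUE)) {
    ok <- which(!taken & free$end - free$start >= sizes[t] + 2L)
    if (!length(ok)) {
      stop("n_gaps exceeds available intergenic sites large enough to ",
           "hold the sampled gap sizes", call. = FALSE)
    }
    picks[t] <- resample(ok)
    taken[picks[t]] <- TRUE
  }
  for (t in seq_len(n_gaps)) {
    iv <- free[picks[t], ]
    gsz <- sizes[t]
    mid <- (iv$start + iv$end) %/% 2L
    s <- mid - gsz %/% 2L
    e <- s + gsz
    truth <- rbind(truth, data.frame(
      scaffold_id = sid, start = s, end = e,
      original = substr(seq, s + 1L, e), stringsAsFactors = FALSE))
    substr(seq, s + 1L, e) <- strrep("N", gsz)
  }
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(scaffolds = scaffold_set(stats::setNames(seq, sid)), truth = truth)
}

#' Plant repeat families into intergenic space
#'
#' Each family is one random core sequence copied `copies` times (forward or
#' reverse-complement) into intergenic positions, overwriting the background.
#' A configurable fraction of copies is placed immediately adjacent to gap
#' flanks, emulating an assembly whose gaps are bordered by repetitive
#' sequence.
#'
#' @param scaffolds Single-chromosome [scaffold_set()] (possibly N-gapped).
#' @param features Feature table (intergenic space is kept gene-free).
#' @param n_families,copies,length Family count, copies per family, core
#'   length (bp).
#' @param seed Integer seed.
#' @param gaps Optional gap truth/interval table (`start`, `end`); required
#'   for gap-adjacent placement.
#' @param near_gap_fraction Fraction of copies placed flush against a gap
#'   flank (default 0.5 when gaps are given, else 0).
#' @return List with `scaffolds` and `truth` data frame (`scaffold_id,
#'   start, end, family_id, strand`).
#' @export
plant_repeats <- function(scaffolds, features, n_families, copies, length,
                          seed, gaps = NULL, near_gap_fraction = 0.5) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  set.seed(sim_child_seed(seed, "repeats"))
  sid <- names(scaffolds$records)[1]
  seq <- scaffolds$records[[sid]]
  L <- nchar(seq)
  truth <- data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), family_id = character(),
                      strand = character(), stringsAsFactors = FALSE)
  if (n_families == 0 || copies == 0) {
    return(list(scaffolds = scaffolds, truth = truth))
  }
  occupied <- rbind(
    features[features$scaffold_id == sid, c("start", "end")],
    if (!is.null(gaps) && nrow(gaps)) gaps[, c("start", "end")] else NULL)
  gap_flanks <- if (!is.null(gaps) && nrow(gaps)) {
    c(rbind(gaps$start, gaps$end))   # interleaved left/right flank anchors
  } else integer(0)
  if (!length(gap_flanks)) near_gap_fraction <- 0
  for (f in seq_len(n_families)) {
    core <- random_dna(length, gc = 0.5)
    for (cp in seq_len(copies)) {
      free <- free_intervals(L, data.frame(start = occupied$start,
                                           end = occupied$end))
      ## a planted copy must not contain N (gaps are excluded via occupied)
      near <- length(gap_flanks) > 0 && stats::runif(1) < near_gap_fraction
      placed <- FALSE
      if (near) {
        anch <- sample(gap_flanks, 1)
        ## try flush-left of a gap (copy ends at gap start) or flush-right
        cand <- free[(free$end == anch & free$end - free$start >= length) |
                       (free$start == anch & free$end - free$start >= length),
                     , drop = FALSE]
        if (nrow(cand)) {
          iv <- cand[1, ]
          s <- if (iv$end == anch) iv$end - length else iv$start
          placed <- TRUE
        }
      }
      if (!placed) {
        fits <- free[free$end - free$start >= length, , drop = FALSE]
        if (!nrow(fits)) {
          stop("no intergenic space left to plant repeat copies; reduce ",
               "copies or repeat length", call. = FALSE)
        }
        iv <- fits[sample.int(nrow(fits), 1), ]
        s <- iv$start + sample.int(iv$end - iv$start - length + 1L, 1) - 1L
      }
      strand <- sample(c("+", "-"), 1)
      ins <- if (strand == "+") core else revcomp(core)
      substr(seq, s + 1L, s + length) <- ins
      occupied <- rbind(occupied, data.frame(start = s, end = s + length))
      truth <- rbind(truth, data.frame(
        scaffold_id = sid, start = s, end = s + length,
        family_id = sprintf("truefam_%02d", f), strand = strand,
        stringsAsFactors = FALSE))
    }
  }
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(scaffolds = scaffold_set(stats::setNames(seq, sid)), truth = truth)
}

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) {
  paste(c("M", sample(.aa20, n - 1, replace = TRUE)), collapse = "")
}

mutate_protein <- function(s, rate = 0.02) {
  b <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  if (length(hit)) b[hit] <- sample(.aa20, length(hit), replace = TRUE)
  paste(b, collapse = "")
}

#' Inactivate a fraction of proteins with known truth
#'
#' Selected proteins are truncated to a sampled retained fraction
#' (`truncate`), cut at a premature stop (`internal_stop`, equivalent
#' outcome on the protein level, recorded as its own mode) or retain a
#' prefix followed by a garbled tail (`frameshift`). Retained fractions are
#' sampled outside the `gray_zone` around the downstream 30%-of-self score
#' cutoff so planted states are unambiguous.
#'
#' @param proteins Named character vector of protein sequences.
#' @param fraction Fraction of proteins to inactivate.
#' @param seed Integer seed.
#' @param modes Modes to sample from.
#' @param retained_range Interval the retained fraction is drawn from.
#' @param gray_zone Excluded interval around the score cutoff.
#' @return List with `proteins` (mutated set) and `truth` data frame
#'   (`id, state, mode, retained`).
#' @export
pseudogenize <- function(proteins, fraction, seed,
                         modes = c("truncate", "internal_stop", "frameshift"),
                         retained_range = c(0.05, 0.90),
                         gray_zone = c(0.25, 0.35)) {
  set.seed(sim_child_seed(seed, "pseudogenize"))
  n <- length(proteins)
  truth <- data.frame(id = names(proteins), state = "intact",
                      mode = NA_character_, retained = 1,
                      stringsAsFactors = FALSE)
  k <- round(fraction * n)
  if (k == 0) return(list(proteins = proteins, truth = truth))
  sel <- sample.int(n, k)
  draw_retained <- function() {
    repeat {
      r <- stats::runif(1, retained_range[1], retained_range[2])
      if (r < gray_zone[1] || r > gray_zone[2]) return(r)
    }
  }
  for (i in sel) {
    m <- sample(modes, 1)
    r <- draw_retained()
    len <- nchar(proteins[i])
    keep <- max(3L, round(r * len))
    frag <- substr(proteins[i], 1, keep)
    if (m == "frameshift" && keep < len) {
      frag <- paste0(frag, paste(sample(.aa20, len - keep, replace = TRUE),
                                 collapse = ""))
    }
    proteins[i] <- frag
    truth$state[i] <- "pseudo"
    truth$mode[i] <- m
    truth$retained[i] <- keep / len
  }
  list(proteins = proteins, truth = truth)
}

#' Simulate a mapped mate-pair library
#'
#' Generates mapped read-pair records over the given contigs as a mixture of
#' concordant RF mate-pairs (insert drawn from a normal truncated to the
#' concordant window), discordant RF pairs (insert outside the window),
#' short-insert FR paired-end contamination, and rare FF/RR orientation
#' errors. Insert size is the outer distance (leftmost start to rightmost
#' end). Mate labels 1/2 are randomly swapped, so downstream classification
#' must derive left/right from coordinates.
#'
#' @param contigs A [scaffold_set()] or named integer vector of contig
#'   lengths.
#' @param config A [sim_config()] (its `matepair` element is used) or a
#'   bare list with the same fields.
#' @param seed Integer seed.
#' @param concordant_window Insert-size window defining concordance
#'   (default `c(2211, 3651)`).
#' @return Data frame `pair_id, contig1, start1, end1, strand1, contig2,
#'   start2, end2, strand2, truth_class` (0-based half-open mate
#'   coordinates).
#' @export
simulate_matepairs <- function(contigs, config, seed,
                               concordant_window = c(2211, 3651)) {
  mp <- if (inherits(config, "sim_config")) config$matepair else config
  set.seed(sim_child_seed(seed, "matepairs"))
  lens <- if (inherits(contigs, "scaffold_set")) scaffold_lengths(contigs)
          else contigs
  rl <- mp$read_len
  max_insert <- max(6000, concordant_window[2] + 500)
  if (any(lens < max_insert)) {
    stop("contig shorter than the maximum simulated insert (", max_insert,
         " bp)", call. = FALSE)
  }
  n <- mp$n_pairs
  cols <- c("pair_id", "contig1", "start1", "end1", "strand1",
            "contig2", "start2", "end2", "strand2", "truth_class")
  if (n == 0) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(cols)), cols),
      stringsAsFactors = FALSE)
    return(out)
  }
  fr <- mp$fractions
  cls <- sample(names(fr), n, replace = TRUE, prob = fr)
  contig <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  insert <- integer(n)
  is_cc <- cls == "concordant_RF"
  if (any(is_cc)) {
    ## normal insert, rejection-sampled into the concordant window
    lo <- max(concordant_window[1], 2 * rl + 1)
    x <- round(stats::rnorm(sum(is_cc), mp$insert_mu, mp$insert_sd))
    while (any(bad <- x < lo | x > concordant_window[2])) {
      x[bad] <- round(stats::rnorm(sum(bad), mp$insert_mu, mp$insert_sd))
    }
    insert[is_cc] <- as.integer(x)
  }
  is_rd <- cls == "RF_discordant"
  if (any(is_rd)) {
    k <- sum(is_rd)
    lo_max <- concordant_window[1] - 1
    below <- stats::runif(k) < 0.5 & lo_max > 2 * rl + 1
    x <- integer(k)
    if (any(below)) x[below] <- resample((2 * rl + 1):lo_max, sum(below),
                                         replace = TRUE)
    if (any(!below)) x[!below] <- resample((concordant_window[2] + 1):
                                             max_insert, sum(!below),
                                           replace = TRUE)
    insert[is_rd] <- x
  }
  is_fc <- cls == "FR_contam"
  if (any(is_fc)) {
    insert[is_fc] <- resample(max(200, 2 * rl):500, sum(is_fc),
                              replace = TRUE)
  }
  is_err <- cls %in% c("FF_err", "RR_err")
  if (any(is_err)) {
    insert[is_err] <- resample((2 * rl + 1):max_insert, sum(is_err),
                               replace = TRUE)
  }
  ls <- as.integer(floor(stats::runif(n) *
                           (lens[contig] - insert + 1L)))
  left_strand <- ifelse(cls %in% c("concordant_RF", "RF_discordant"), "-",
                 ifelse(cls == "FR_contam", "+",
                 ifelse(cls == "FF_err", "+", "-")))
  right_strand <- ifelse(cls %in% c("concordant_RF", "RF_discordant"), "+",
                  ifelse(cls == "FR_contam", "-",
                  ifelse(cls == "FF_err", "+", "-")))
  l1 <- ls; l2 <- ls + rl
  r1 <- ls + insert - rl; r2 <- ls + insert
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  out <- data.frame(
    pair_id = sprintf("pair_%06d", seq_len(n)),
    contig1 = contig,
    start1 = ifelse(swap, r1, l1), end1 = ifelse(swap, r2, l2),
    strand1 = ifelse(swap, right_strand, left_strand),
    contig2 = contig,
    start2 = ifelse(swap, l1, r1), end2 = ifelse(swap, l2, r2),
    strand2 = ifelse(swap, left_strand, right_strand),
    truth_class = cls, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a scaffold set for the gap-primer benchmark
#'
#' Builds `n_scaffolds` N-gapped scaffolds with planted repeats: most carry
#' a gap with clean 1.6 kb flanks and two copies of a shared repeat family
#' placed outside the primer search flanks (so pairs are designable and the
#' repeat family is detectable genome-wide), while `n_masked_flank`
#' scaffolds bury the gap between two copies of a repeat core longer than
#' the search flank, so primer design must return a typed
#' `flanks_masked` failure.
#'
#' @param n_scaffolds Total scaffold count (default 50).
#' @param n_masked_flank How many scaffolds get fully repeat-masked flanks
#'   (default 5).
#' @param seed Integer seed.
#' @param gap_size_range Planted gap sizes in bp.
#' @param repeat_length Length of the shared repeat core in bp.
#' @return List with `scaffolds` (a [scaffold_set()]) and `truth` (data
#'   frame `scaffold_id, masked_flank`).
#' @export
simulate_gap_primer_set <- function(n_scaffolds = 50L, n_masked_flank = 5L,
                                    seed, gap_size_range = c(150L, 250L),
                                    repeat_length = 400L) {
  set.seed(sim_child_seed(seed, "gap_primer_set"))
  core <- random_dna(repeat_length)
  wall <- random_dna(1100L)      # longer than the 1 kb primer search flank
  recs <- character(0)
  masked <- logical(0)
  for (i in seq_len(n_scaffolds)) {
    gsz <- resample(gap_size_range[1]:gap_size_range[2])
    if (i <= n_scaffolds - n_masked_flank) {
      ori <- function(x) if (stats::runif(1) < 0.5) x else revcomp(x)
      s <- paste0(random_dna(500), ori(core), random_dna(1600),
                  strrep("N", gsz), random_dna(1600), ori(core),
                  random_dna(500))
      masked <- c(masked, FALSE)
    } else {
      s <- paste0(random_dna(300), wall, strrep("N", gsz), wall,
                  random_dna(300))
      masked <- c(masked, TRUE)
    }
    recs[sprintf("scf_%02d", i)] <- s
  }
  list(scaffolds = scaffold_set(recs),
       truth = data.frame(scaffold_id = names(recs), masked_flank = masked,
                          stringsAsFactors = FALSE))
}

#' Simulate a three-strain ortholog erosion data set
#'
#' Builds per-strain protein sets, feature tables and an ortholog membership
#' table with planted per-cell states. Every group keeps at least one intact
#' member (the alignment reference) and at least two non-absent members, so
#' the planted truth survives the matrix filters; extra groups carrying a
#' mobile-element member or present in a single strain are added to exercise
#' the filters. Absent states are realized either as no annotated feature or
#' as a severely truncated fragment scoring below the cutoff.
#'
#' @param n_groups Number of clean ortholog groups.
#' @param seed Integer seed.
#' @param strains Strain ids (default `c("SAp", "SCt", "SCc")`).
#' @param len_range Protein length interval (aa).
#' @param state_probs Sampling weights for intact/pseudo/absent.
#' @param n_mobile_groups,n_single_groups Counts of planted filter-fodder
#'   groups.
#' @param gray_zone Retained-fraction interval excluded around the cutoff.
#' @return List with `features` (named list of per-strain feature tables),
#'   `proteins` (named list of per-strain named character vectors),
#'   `ortho_table` (`group_id, strain, feature_id`) and `truth` (data frame
#'   of planted states for the clean groups, one column per strain).
#' @export
simulate_erosion_dataset <- function(n_groups = 300L, seed,
                                     strains = c("SAp", "SCt", "SCc"),
                                     len_range = c(120L, 400L),
                                     state_probs = c(intact = 0.6,
                                                     pseudo = 0.25,
                                                     absent = 0.15),
                                     n_mobile_groups = 10L,
                                     n_single_groups = 10L,
                                     gray_zone = c(0.25, 0.35)) {
  set.seed(sim_child_seed(seed, "erosion"))
  feats <- stats::setNames(vector("list", length(strains)), strains)
  prots <- stats::setNames(vector("list", length(strains)), strains)
  for (s in strains) {
    feats[[s]] <- list()
    prots[[s]] <- character(0)
  }
  ortho <- list()
  truth <- list()
  add_feature <- function(s, fid, klass, prot = NULL) {
    k <- length(feats[[s]]) + 1L
    feats[[s]][[k]] <<- data.frame(
      feature_id = fid, scaffold_id = paste0(s, "_chr"),
      start = (k - 1L) * 2000L, end = (k - 1L) * 2000L + 1200L,
      strand = "+", klass = klass, family = NA_character_,
      cog_category = NA_character_, ortho_group = NA_character_,
      stringsAsFactors = FALSE)
    if (!is.null(prot)) prots[[s]][fid] <<- prot
  }
  for (g in seq_len(n_groups)) {
    gid <- sprintf("grp_%04d", g)
    ref <- random_protein(sample(seq(len_range[1], len_range[2]), 1))
    repeat {
      st <- sample(names(state_probs), length(strains), replace = TRUE,
                   prob = state_probs)
      if (sum(st != "absent") >= 2 && any(st == "intact")) break
    }
    names(st) <- strains
    ## intact copies first: the state-matrix reference is the first intact
    ## member in strain order, and planted fragments are checked against it
    intact_prot <- stats::setNames(rep(NA_character_, length(strains)),
                                   strains)
    for (s in strains[st == "intact"]) {
      intact_prot[s] <- mutate_protein(ref, 0.02)
    }
    representative <- intact_prot[which(!is.na(intact_prot))[1]]
    ## planted fragments must land outside the cutoff gray zone on the
    ## *realized* score ratio, so truth states are unambiguous by design
    draw_fragment <- function(lo_ratio, hi_ratio, lo_ret, hi_ret) {
      repeat {
        r <- stats::runif(1, lo_ret, hi_ret)
        frag <- substr(ref, 1, max(3L, round(r * nchar(ref))))
        ratio <- relative_score(frag, representative)
        if (ratio > lo_ratio && ratio < hi_ratio) return(frag)
      }
    }
    for (s in strains) {
      fid <- paste0(s, "_", gid)
      if (st[s] == "intact") {
        add_feature(s, fid, "CDS", intact_prot[s])
        ortho[[length(ortho) + 1L]] <- data.frame(
          group_id = gid, strain = s, feature_id = fid,
          stringsAsFactors = FALSE)
      } else if (st[s] == "pseudo") {
        frag <- draw_fragment(gray_zone[2], 0.95, gray_zone[2] + 0.03, 0.90)
        add_feature(s, fid, "pseudogene", frag)
        ortho[[length(ortho) + 1L]] <- data.frame(
          group_id = gid, strain = s, feature_id = fid,
          stringsAsFactors = FALSE)
      } else {
        ## absent: half the time no feature at all, otherwise a fragment
        ## far below the cutoff
        if (stats::runif(1) < 0.5) {
          frag <- draw_fragment(0, gray_zone[1], 0.05, gray_zone[1])
          add_feature(s, fid, "pseudogene", frag)
          ortho[[length(ortho) + 1L]] <- data.frame(
            group_id = gid, strain = s, feature_id = fid,
            stringsAsFactors = FALSE)
        }
      }
    }
    truth[[g]] <- data.frame(group_id = gid, t(st), stringsAsFactors = FALSE)
  }
  ## groups carrying a mobile member: must be dropped by the matrix builder
  for (m in seq_len(n_mobile_groups)) {
    gid <- sprintf("mob_%03d", m)
    ref <- random_protein(200)
    for (s in strains[1:2]) {
      fid <- paste0(s, "_", gid)
      add_feature(s, fid, if (s == strains[1]) "IS" else "CDS", ref)
      ortho[[length(ortho) + 1L]] <- data.frame(
        group_id = gid, strain = s, feature_id = fid,
        stringsAsFactors = FALSE)
    }
  }
  ## single-strain groups: dropped by the >= 2 strain rule
  for (m in seq_len(n_single_groups)) {
    gid <- sprintf("one_%03d", m)
    s <- strains[1]
    fid <- paste0(s, "_", gid)
    add_feature(s, fid, "CDS", random_protein(150))
    ortho[[length(ortho) + 1L]] <- data.frame(
      group_id = gid, strain = s, feature_id = fid, stringsAsFactors = FALSE)
  }
  features <- lapply(feats, function(x) {
    out <- do.call(rbind, x); rownames(out) <- NULL; out
  })
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(features = features, proteins = prots,
       ortho_table = do.call(rbind, ortho), truth = truth)
}
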