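## Gap-closure primer design over N-gapped scaffolds: enumerate assembly
## gaps, de novo detect and mask repeats by exact k-mer seeding, then pick a
## minimum-penalty primer pair spanning each gap, with the product size
## counting the N-run at its estimated (run) length.

#' Find assembly gaps (maximal N-runs)
#'
#' @param scaffolds A [scaffold_set()].
#' @param min_run Minimum N-run length to report (default 1).
#' @return Data frame `scaffold_id, start, end, estimated_size` (0-based
#'   half-open), sorted by (scaffold, start). The estimated gap size is the
#'   run length.
#' @export
find_gaps <- function(scaffolds, min_run = 1L) {
  stopifnot(inherits(scaffolds, "scaffold_set"), min_run >= 1)
  out <- lapply(names(scaffolds$records), function(id) {
    m <- gregexpr("N+", scaffolds$records[[id]])[[1]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "match.length")
    keep <- len >= min_run
    if (!any(keep)) return(NULL)
    data.frame(scaffold_id = id, start = as.integer(m[keep]) - 1L,
               end = as.integer(m[keep]) + len[keep] - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$scaffold_id, out$start), , drop = FALSE]
  out$estimated_size <- out$end - out$start
  rownames(out) <- NULL
  out
}

## Union-find used to link repeat intervals into families via shared seeds.
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' De novo repeat detection by exact k-mer seeding
#'
#' Stand-in for an iterative de novo repeat finder: every position covered by
#' an exact k-mer (forward or reverse-complement, i.e. canonical form)
#' occurring at least `min_copies` times genome-wide is repeat-masked;
#' overlapping seed hits merge into maximal intervals, and intervals sharing
#' any seed k-mer are linked into one family.
#'
#' @param scaffolds A [scaffold_set()].
#' @param k Seed length (>= 12, default 24).
#' @param min_copies Minimum genome-wide copy number of a seed (default 2).
#' @return Data frame `scaffold_id, start, end, family_id` (0-based
#'   half-open), sorted by (scaffold, start).
#' @export
detect_repeats <- function(scaffolds, k = 24L, min_copies = 2L) {
  stopifnot(inherits(scaffolds, "scaffold_set"), k >= 12)
  ids <- names(scaffolds$records)
  kmers <- character(0); scaf <- character(0); pos <- integer(0)
  for (id in ids) {
    s <- scaffolds$records[[id]]
    L <- nchar(s)
    if (L < k) next
    st <- seq_len(L - k + 1L)
    km <- substring(s, st, st + k - 1L)
    ok <- !grepl("N", km, fixed = TRUE)
    kmers <- c(kmers, km[ok])
    scaf <- c(scaf, rep(id, sum(ok)))
    pos <- c(pos, st[ok] - 1L)           # 0-based start
  }
  empty <- data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), family_id = character(),
                      stringsAsFactors = FALSE)
  if (!length(kmers)) return(empty)
  canon <- pmin(kmers, revcomp(kmers))
  uc <- unique(canon)
  ci <- match(canon, uc)
  cnt <- tabulate(ci, nbins = length(uc))
  seed <- cnt[ci] >= min_copies
  if (!any(seed)) return(empty)
  sdf <- data.frame(scaffold_id = scaf[seed], start = pos[seed],
                    kmer = ci[seed], stringsAsFactors = FALSE)
  ## merge overlapping seed hits into maximal intervals per scaffold
  iv <- list(); hit_interval <- integer(nrow(sdf)); n_iv <- 0L
  for (id in unique(sdf$scaffold_id)) {
    sel <- which(sdf$scaffold_id == id)
    ir <- IRanges::IRanges(start = sdf$start[sel] + 1L, width = k)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red, select = "first")
    hit_interval[sel] <- n_iv + ov
    iv[[id]] <- data.frame(scaffold_id = id,
                           start = IRanges::start(red) - 1L,
                           end = IRanges::end(red),
                           stringsAsFactors = FALSE)
    n_iv <- n_iv + length(red)
  }
  ivdf <- do.call(rbind, iv)
  ## family linkage: union intervals sharing a seed k-mer
  parent <- seq_len(n_iv)
  links <- unique(data.frame(kmer = sdf$kmer, iv = hit_interval))
  sp <- split(links$iv, links$kmer)
  for (g in sp) {
    if (length(g) < 2) next
    r <- uf_find(parent, g[1])
    for (j in g[-1]) {
      rj <- uf_find(parent, j)
      if (rj != r) parent[rj] <- r
    }
  }
  roots <- vapply(seq_len(n_iv), function(i) uf_find(parent, i), integer(1))
  fam <- match(roots, unique(roots))
  ivdf$family_id <- sprintf("repfam_%03d", fam)
  ivdf <- ivdf[order(ivdf$scaffold_id, ivdf$start), , drop = FALSE]
  rownames(ivdf) <- NULL
  ivdf
}

#' Iterated repeat masking to a fixed point
#'
#' Runs [detect_repeats()] in detect-and-mask rounds until the masked
#' interval set stops changing or `max_iter` rounds have run. Exact k-mer
#' detection is independent of previous masking, so the fixed point is
#' normally reached after one round; the loop keeps the stage faithful to an
#' iterative masking design and guards any future detector change.
#'
#' @inheritParams detect_repeats
#' @param max_iter Maximum detect-mask rounds (default 5).
#' @return As [detect_repeats()].
#' @export
repeat_mask_iterative <- function(scaffolds, k = 24L, min_copies = 2L,
                                  max_iter = 5L) {
  prev <- NULL
  for (i in seq_len(max_iter)) {
    cur <- detect_repeats(scaffolds, k = k, min_copies = min_copies)
    if (!is.null(prev) && identical(prev[c("scaffold_id", "start", "end")],
                                    cur[c("scaffold_id", "start", "end")])) {
      break
    }
    prev <- cur
  }
  prev
}

## ---------------------------------------------------------------------------
## Nearest-neighbor melting temperature (unified dinucleotide parameter set).
## dH in kcal/mol, dS in cal/(mol K). Entropic salt correction
## 0.368 * (N-1) * ln[Na+]; duplex initiation split per terminal base.

.nn_dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
.init_dH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.init_dS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
.gas_R <- 1.9872   # cal/(mol K)

is_selfcomp <- function(s) identical(s, revcomp(s))

#' Nearest-neighbor primer melting temperature
#'
#' Thermodynamic two-state melting temperature from unified dinucleotide
#' enthalpy/entropy parameters with per-terminal initiation terms, an
#' entropic monovalent-salt correction of `0.368 (N-1) ln[Na+]`, and the
#' symmetry correction for self-complementary sequences. Divalent-cation
#' corrections are not supported.
#'
#' @param sequence Primer sequence, 5'->3', alphabet `A,C,G,T`, length >= 8.
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @param primer_nM Primer concentration in nM (default 500).
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(sequence, na_mM = 50, primer_nM = 500) {
  s <- toupper(sequence)
  if (nchar(s) < 8) stop("sequence shorter than 8 nt", call. = FALSE)
  if (grepl("[^ACGT]", s)) {
    stop("sequence contains a character outside A,C,G,T (N not allowed)",
         call. = FALSE)
  }
  n <- nchar(s)
  b <- strsplit(s, "")[[1]]
  di <- paste0(b[-n], b[-1])
  dH <- sum(.nn_dH[di]) + .init_dH[b[1]] + .init_dH[b[n]]
  dS <- sum(.nn_dS[di]) + .init_dS[b[1]] + .init_dS[b[n]]
  ct <- primer_nM * 1e-9
  if (is_selfcomp(s)) {
    dS <- dS - 1.4
    x <- 1
  } else {
    x <- 4
  }
  dS <- dS + 0.368 * (n - 1) * log(na_mM / 1000)
  unname(1000 * dH / (dS + .gas_R * log(ct / x)) - 273.15)
}

## Longest run k such that the reverse complement of the 3'-terminal k bases
## occurs elsewhere in the sequence (self-annealing 3' end). The reverse
## complement of the terminal k-mer is the leading k bases of revcomp(s).
three_prime_selfcomp_run <- function(s, rc = revcomp(s)) {
  n <- nchar(s)
  best <- 0L
  for (k in seq_len(min(8L, n - 1L))) {
    if (grepl(substr(rc, 1L, k), substr(s, 1L, n - 1L), fixed = TRUE)) {
      best <- k
    } else break
  }
  best
}

## Longest hairpin stem with loop >= min_loop: positions i<j with
## s[i..i+m) reverse-complementary to s[j..j+m). The m-mer of revcomp(s)
## starting at a is the reverse complement of the s m-mer starting at
## j = n - a - m + 2 (1-based), so one revcomp plus substring comparisons
## cover all stems.
hairpin_stem_length <- function(s, min_loop = 3L, rc = revcomp(s)) {
  n <- nchar(s)
  best <- 0L
  for (m in seq(2L, max(2L, n %/% 2L))) {
    if (m > n %/% 2L) break
    st <- seq_len(n - m + 1L)
    subs_s <- substring(s, st, st + m - 1L)
    subs_rc <- substring(rc, st, st + m - 1L)
    j_of_a <- n - st - m + 2L
    hit <- outer(subs_s, subs_rc, "==") &
      outer(st + m + min_loop, j_of_a, "<=")
    if (any(hit)) best <- m else break
  }
  best
}

#' Score or reject one primer candidate window
#'
#' Rejection gates: GC fraction outside [0.20, 0.80]; Tm outside [57, 63]
#' degrees C; homopolymer run >= 5; 3'-terminal self-complementary run >= 4;
#' hairpin stem >= 6 bp with loop >= 3. Surviving windows get penalty
#' `|Tm - 60| + 2|GC - 0.5| + 0.25 * (3' self-complementary run) +
#' 0.25 * (longest sub-threshold hairpin stem)`.
#'
#' @param sequence Candidate sequence 5'->3' (no N, length 18-27).
#' @param na_mM,primer_nM Salt and primer concentrations for the Tm model.
#' @param tm_range,gc_range Acceptance windows.
#' @return List with `ok` (logical), and either `reason` (character) or
#'   `tm`, `gc`, `penalty`.
#' @export
score_candidate <- function(sequence, na_mM = 50, primer_nM = 500,
                            tm_range = c(57, 63), gc_range = c(0.20, 0.80)) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < 18 || n > 27) return(list(ok = FALSE, reason = "length"))
  if (grepl("[^ACGT]", s)) return(list(ok = FALSE, reason = "ambiguous_base"))
  if (grepl("AAAAA|CCCCC|GGGGG|TTTTT", s)) {
    return(list(ok = FALSE, reason = "homopolymer"))
  }
  gc <- (nchar(gsub("[AT]", "", s))) / n
  if (gc < gc_range[1] || gc > gc_range[2]) {
    return(list(ok = FALSE, reason = "gc"))
  }
  tm <- melting_temperature(s, na_mM = na_mM, primer_nM = primer_nM)
  if (tm < tm_range[1] || tm > tm_range[2]) {
    return(list(ok = FALSE, reason = "tm"))
  }
  rc <- revcomp(s)
  run3 <- three_prime_selfcomp_run(s, rc = rc)
  if (run3 >= 4) return(list(ok = FALSE, reason = "self_complementary_3prime"))
  stem <- hairpin_stem_length(s, rc = rc)
  if (stem >= 6) return(list(ok = FALSE, reason = "hairpin"))
  pen <- abs(tm - 60) + 2 * abs(gc - 0.5) + 0.25 * run3 + 0.25 * stem
  list(ok = TRUE, tm = tm, gc = gc, penalty = pen)
}

## Vectorized pre-screen of all windows of the given lengths inside a region.
## Computes rolling Tm (non-symmetric formula; palindromic windows are
## re-evaluated exactly later) and GC, and excludes windows touching an
## invalid (N or masked) base. Returns 0-based window starts/ends with
## approximate tm for ranking; definitive scoring is score_candidate().
scan_primer_windows <- function(seq, invalid, region_start, region_end,
                                lengths = 18:27, na_mM = 50, primer_nM = 500,
                                tm_range = c(57, 63),
                                gc_range = c(0.20, 0.80), max_windows = 300L) {
  if (region_end - region_start < min(lengths)) return(NULL)
  sub <- substr(seq, region_start + 1L, region_end)
  L <- nchar(sub)
  b <- strsplit(sub, "")[[1]]
  bad <- invalid[(region_start + 1L):region_end]
  dH <- .nn_dH[paste0(b[-L], b[-1])]
  dS <- .nn_dS[paste0(b[-L], b[-1])]
  dH[is.na(dH)] <- 0; dS[is.na(dS)] <- 0
  cH <- cumsum(c(0, dH)); cS <- cumsum(c(0, dS))
  cBad <- cumsum(c(0, as.integer(bad)))
  isGC <- as.integer(b %in% c("G", "C"))
  cGC <- cumsum(c(0, isGC))
  ct <- primer_nM * 1e-9
  res <- list()
  for (w in lengths) {
    if (L < w) next
    st <- seq_len(L - w + 1L)           # 1-based within sub
    en <- st + w - 1L
    okb <- (cBad[en + 1L] - cBad[st]) == 0
    if (!any(okb)) next
    st <- st[okb]; en <- en[okb]
    dHs <- cH[en] - cH[st] + .init_dH[b[st]] + .init_dH[b[en]]
    dSs <- cS[en] - cS[st] + .init_dS[b[st]] + .init_dS[b[en]] +
      0.368 * (w - 1) * log(na_mM / 1000)
    tm <- 1000 * dHs / (dSs + .gas_R * log(ct / 4)) - 273.15
    gc <- (cGC[en + 1L] - cGC[st]) / w
    keep <- tm >= tm_range[1] & tm <= tm_range[2] &
      gc >= gc_range[1] & gc <= gc_range[2]
    if (!any(keep)) next
    res[[length(res) + 1L]] <- data.frame(
      start = region_start + st[keep] - 1L,     # 0-based
      end = region_start + en[keep],
      tm_approx = tm[keep], stringsAsFactors = FALSE)
  }
  if (!length(res)) return(NULL)
  out <- do.call(rbind, res)
  ## deterministic pre-ranking before expensive structure checks
  out <- out[order(abs(out$tm_approx - 60), out$start, out$end), , drop = FALSE]
  utils::head(out, max_windows)
}

primer_candidate <- function(scaffold_id, start, end, strand, sequence, sc) {
  list(scaffold_id = scaffold_id, start = start, end = end, strand = strand,
       sequence = sequence, tm = sc$tm, gc_fraction = sc$gc,
       penalty = sc$penalty)
}

primer_failure <- function(gap, reason) {
  structure(list(gap = gap, reason = reason), class = "primer_failure")
}

#' Design a gap-spanning primer pair
#'
#' Enumerates candidate windows in the unmasked, N-free flanks of a gap (left
#' primer on the + strand upstream, right primer on the - strand downstream),
#' scores them with [score_candidate()], and returns the minimum-penalty pair
#' whose product spans the gap and lies in `product_range`. The product size
#' is measured in scaffold coordinates (`right.end - left.start`), counting
#' the N-run at its estimated length. A primer overlapping even one masked or
#' N base is rejected outright. Ties break by smaller product, then leftmost
#' left primer.
#'
#' @param gap One row of a [find_gaps()] table (or a list with
#'   `scaffold_id, start, end`).
#' @param scaffolds A [scaffold_set()].
#' @param repeats Repeat intervals from [detect_repeats()] (may have 0 rows).
#' @param product_range Allowed product size window in bp (default
#'   `c(100, 1000)`; a second-round preset would be `c(100, 3000)`).
#' @param flank Flank length searched on each side of the gap (default 1000).
#' @param max_tm_diff Maximum left/right Tm difference in degrees C
#'   (default 3).
#' @param na_mM,primer_nM Passed to the Tm model.
#' @return An object of class `primer_pair` (elements `gap`, `left`, `right`,
#'   `product_size`, `pair_penalty`) or of class `primer_failure` with
#'   `reason` in `flanks_masked`, `no_candidate_window`,
#'   `product_range_unsatisfiable`.
#' @export
design_gap_primers <- function(gap, scaffolds, repeats,
                               product_range = c(100, 1000), flank = 1000L,
                               max_tm_diff = 3, na_mM = 50, primer_nM = 500) {
  stopifnot(inherits(scaffolds, "scaffold_set"))
  sid <- as.character(gap$scaffold_id)
  if (!sid %in% names(scaffolds$records)) {
    stop("gap references unknown scaffold: ", sid, call. = FALSE)
  }
  seq <- scaffolds$records[[sid]]
  L <- nchar(seq)
  gs <- as.integer(gap$start); ge <- as.integer(gap$end)
  gap_size <- ge - gs
  min_len <- 18L
  if (gap_size + 2L * min_len > product_range[2]) {
    return(primer_failure(gap, "product_range_unsatisfiable"))
  }
  ## invalid positions: N or repeat-masked
  invalid <- rep(FALSE, L)
  nhit <- gregexpr("N", seq, fixed = TRUE)[[1]]
  if (nhit[1] != -1) invalid[as.integer(nhit)] <- TRUE
  if (!is.null(repeats) && nrow(repeats) > 0) {
    rsel <- repeats[repeats$scaffold_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(rsel))) {
      invalid[(rsel$start[i] + 1L):rsel$end[i]] <- TRUE
    }
  }
  left_lo <- max(0L, gs - as.integer(flank)); left_hi <- gs
  right_lo <- ge; right_hi <- min(L, ge + as.integer(flank))
  has_window <- function(lo, hi) {
    if (hi - lo < min_len) return(FALSE)
    runs <- rle(invalid[(lo + 1L):hi])
    any(!runs$values & runs$lengths >= min_len)
  }
  if (!has_window(left_lo, left_hi) || !has_window(right_lo, right_hi)) {
    return(primer_failure(gap, "flanks_masked"))
  }
  lw <- scan_primer_windows(seq, invalid, left_lo, left_hi,
                            na_mM = na_mM, primer_nM = primer_nM)
  rw <- scan_primer_windows(seq, invalid, right_lo, right_hi,
                            na_mM = na_mM, primer_nM = primer_nM)
  if (is.null(lw) || is.null(rw)) {
    return(primer_failure(gap, "no_candidate_window"))
  }
  score_side <- function(win, minus_strand) {
    out <- vector("list", nrow(win))
    for (i in seq_len(nrow(win))) {
      sq <- substr(seq, win$start[i] + 1L, win$end[i])
      if (minus_strand) sq <- revcomp(sq)
      sc <- score_candidate(sq, na_mM = na_mM, primer_nM = primer_nM)
      if (isTRUE(sc$ok)) {
        out[[i]] <- data.frame(start = win$start[i], end = win$end[i],
                               tm = sc$tm, gc = sc$gc, penalty = sc$penalty,
                               sequence = sq, stringsAsFactors = FALSE)
      }
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  lc <- score_side(lw, minus_strand = FALSE)
  rc <- score_side(rw, minus_strand = TRUE)
  if (is.null(lc) || is.null(rc)) {
    return(primer_failure(gap, "no_candidate_window"))
  }
  ## minimum pair penalty subject to product window and Tm compatibility
  best <- NULL
  ord <- order(rc$end)
  rc <- rc[ord, , drop = FALSE]
  for (i in seq_len(nrow(lc))) {
    pmin_end <- lc$start[i] + product_range[1]
    pmax_end <- lc$start[i] + product_range[2]
    sel <- which(rc$end >= pmin_end & rc$end <= pmax_end &
                   abs(rc$tm - lc$tm[i]) <= max_tm_diff)
    if (!length(sel)) next
    pen <- lc$penalty[i] + rc$penalty[sel]
    prod <- rc$end[sel] - lc$start[i]
    o <- order(pen, prod, rc$start[sel])
    j <- sel[o[1]]
    cand <- list(pen = lc$penalty[i] + rc$penalty[j],
                 prod = rc$end[j] - lc$start[i],
                 lstart = lc$start[i], li = i, rj = j)
    if (is.null(best) ||
        cand$pen < best$pen - 1e-12 ||
        (abs(cand$pen - best$pen) <= 1e-12 && cand$prod < best$prod) ||
        (abs(cand$pen - best$pen) <= 1e-12 && cand$prod == best$prod &&
         cand$lstart < best$lstart)) {
      best <- cand
    }
  }
  if (is.null(best)) return(primer_failure(gap, "no_candidate_window"))
  li <- best$li; rj <- best$rj
  left <- primer_candidate(sid, lc$start[li], lc$end[li], "+",
                           lc$sequence[li],
                           list(tm = lc$tm[li], gc = lc$gc[li],
                                penalty = lc$penalty[li]))
  right <- primer_candidate(sid, rc$start[rj], rc$end[rj], "-",
                            rc$sequence[rj],
                            list(tm = rc$tm[rj], gc = rc$gc[rj],
                                 penalty = rc$penalty[rj]))
  structure(list(gap = gap, left = left, right = right,
                 product_size = best$prod, pair_penalty = best$pen),
            class = "primer_pair")
}

#' Design primers for every gap in a scaffold set
#'
#' Convenience driver: finds gaps, masks repeats (iterated to a fixed point)
#' and runs [design_gap_primers()] on each gap.
#'
#' @inheritParams design_gap_primers
#' @param min_gap_run Minimum N-run length treated as a gap.
#' @param k,min_copies Repeat-detection parameters.
#' @return List with `gaps`, `repeats`, and `results` (one `primer_pair` or
#'   `primer_failure` per gap).
#' @export
design_all_gap_primers <- function(scaffolds, product_range = c(100, 1000),
                                   flank = 1000L, min_gap_run = 1L,
                                   k = 24L, min_copies = 2L, ...) {
  gaps <- find_gaps(scaffolds, min_run = min_gap_run)
  repeats <- repeat_mask_iterative(scaffolds, k = k, min_copies = min_copies)
  results <- lapply(seq_len(nrow(gaps)), function(i) {
    design_gap_primers(gaps[i, ], scaffolds, repeats,
                       product_range = product_range, flank = flank, ...)
  })
  list(gaps = gaps, repeats = repeats, results = results)
}

#' Gap primer coverage report
#'
#' Either pass the gap table and the per-gap result list, or two numbers
#' (`gaps_with_primers`, `gaps_total`).
#'
#' @param gaps Gap table, or the number of gaps with a designed pair.
#' @param results List of per-gap results, or the total gap count.
#' @return List `gaps_total`, `gaps_with_primers`, `percent` (percent rounded
#'   to 2 decimals).
#' @export
coverage_report <- function(gaps, results) {
  if (is.numeric(gaps) && length(gaps) == 1 &&
      is.numeric(results) && length(results) == 1) {
    with_p <- gaps
    total <- results
  } else {
    total <- nrow(gaps)
    with_p <- sum(vapply(results, inherits, logical(1), what = "primer_pair"))
  }
  pct <- if (total > 0) round(100 * with_p / total, 2) else 0
  list(gaps_total = total, gaps_with_primers = with_p, percent = pct)
}
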