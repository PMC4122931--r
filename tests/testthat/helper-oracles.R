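# Independent oracles used across the suite. Each is a deliberately naive
# implementation (exhaustive or direct dynamic programming) kept free of any
# code path it is used to check.

# Affine-gap local alignment (Gotoh) scored like BLAST: a gap of length L
# costs open + L * extend. Direct O(nm) DP over three matrices.
oracle_local_align <- function(a, b, submat, open = 11, extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0,
                             M[i, j] + s, Ix[i, j] + s, Iy[i, j] + s)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                              Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                              Iy[i + 1, j] - extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

blosum62_oracle <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      env$m <- as.matrix(env$BLOSUM62)
    }
    env$m
  }
})

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Maximum total score over all mutually non-overlapping subsets of hit
# intervals (half-open), by exhaustive bitmask enumeration.
oracle_max_nonoverlap_score <- function(start, end, score) {
  n <- length(start)
  if (n == 0) return(0)
  conflict <- outer(seq_len(n), seq_len(n), function(i, j) {
    start[i] < end[j] & start[j] < end[i] & i != j
  })
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) > 1 && any(conflict[sel, sel])) next
    best <- max(best, sum(score[sel]))
  }
  best
}

# Maximal colinear runs of a signed permutation, by exhaustive interval
# testing: an interval i..j of A (identity order) is colinear when the same
# genes occupy consecutive positions of B in identical order/signs or fully
# reversed with flipped signs.
oracle_colinear_runs <- function(ord_b) {
  n <- length(ord_b)
  pos <- integer(n); sgn <- integer(n)
  pos[abs(ord_b)] <- seq_len(n)
  sgn[abs(ord_b)] <- sign(ord_b)
  is_colinear <- function(i, j) {
    g <- i:j
    p <- pos[g]
    if (max(p) - min(p) != j - i) return(FALSE)
    fwd <- all(p == seq(min(p), max(p))) && all(sgn[g] == 1)
    rev_ <- all(p == seq(max(p), min(p))) && all(sgn[g] == -1)
    fwd || rev_
  }
  runs <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && is_colinear(i, j + 1L)) j <- j + 1L
    runs[[length(runs) + 1L]] <- i:j
    i <- j + 1L
  }
  runs
}

# All signed permutations of 1..n.
all_signed_perms <- function(n) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      rest <- perms(v[-k])
      out <- c(out, lapply(rest, function(r) c(v[k], r)))
    }
    out
  }
  base <- perms(seq_len(n))
  out <- list()
  for (p in base) {
    for (mask in 0:(2^n - 1)) {
      sg <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, -1L, 1L)
      out[[length(out) + 1L]] <- p * sg
    }
  }
  out
}

# Minimum Dollo event count for one 3-leaf pattern by enumerating the
# internal node state (root fixed intact = level 0). Transition from level
# u to level v >= u along a branch contributes v - u events; degradation
# only, so labelings with any v < u on a path are invalid.
oracle_dollo_min_events <- function(lv_a, lv_b, lv_out) {
  best <- Inf
  for (internal in 0:2) {
    if (internal > lv_a || internal > lv_b) next
    ev <- internal + (lv_a - internal) + (lv_b - internal) + lv_out
    best <- min(best, ev)
  }
  best
}

# Small helper: overlap in bp between one interval and a set of intervals.
interval_overlap_bp <- function(start, end, tab) {
  if (nrow(tab) == 0) return(0L)
  sum(pmax(0L, pmin(end, tab$end) - pmax(start, tab$start)))
}

make_scaffolds <- function(...) scaffold_set(c(...))
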