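## Signed gene orders of shared single-copy nonmobile orthologs, syntenic
## clusters (maximal colinear runs), breakpoint distances as a desk-scale
## rearrangement statistic, and mobile elements flanking clusters within a
## +/- 3 kb window.

#' Extract shared signed gene orders for two strains
#'
#' Mobile-class features are excluded, then only ortholog groups that are
#' single-copy in each strain and present in both are kept. Strain A's order
#' is 1..n by construction (all positive); strain B's order is the signed
#' permutation of A's indices, the sign being + where the gene lies on the
#' same strand in both strains and - otherwise. Genes are ordered by
#' (scaffold, start) within each strain.
#'
#' @param features_a,features_b Feature tables (internal convention) with an
#'   `ortho_group` column, or joined against `ortho_table`.
#' @param ortho_table Optional data frame `group_id, strain, feature_id`
#'   with exactly two strains; if `NULL`, the `ortho_group` column of the
#'   feature tables is used.
#' @return List of class `signed_orders`: `a` and `b` (each with
#'   `strain_id`, `order`, `index_map` from ortholog id to index) and
#'   `n_excluded_multicopy`.
#' @export
shared_signed_orders <- function(features_a, features_b, ortho_table = NULL) {
  prep <- function(f) {
    f <- f[!(f$klass %in% MOBILE_CLASSES), , drop = FALSE]
    f <- f[!is.na(f$ortho_group), , drop = FALSE]
    f[order(f$scaffold_id, f$start), , drop = FALSE]
  }
  if (!is.null(ortho_table)) {
    strains <- unique(ortho_table$strain)
    stopifnot(length(strains) == 2)
    join <- function(f, s) {
      m <- ortho_table[ortho_table$strain == s, , drop = FALSE]
      f$ortho_group <- m$group_id[match(f$feature_id, m$feature_id)]
      f
    }
    features_a <- join(features_a, strains[1])
    features_b <- join(features_b, strains[2])
  }
  fa <- prep(features_a)
  fb <- prep(features_b)
  multi_a <- names(which(table(fa$ortho_group) > 1))
  multi_b <- names(which(table(fb$ortho_group) > 1))
  multi <- union(multi_a, multi_b)
  shared <- setdiff(intersect(fa$ortho_group, fb$ortho_group), multi)
  fa <- fa[fa$ortho_group %in% shared, , drop = FALSE]
  fb <- fb[fb$ortho_group %in% shared, , drop = FALSE]
  n <- nrow(fa)
  index_map <- stats::setNames(seq_len(n), fa$ortho_group)
  idx_b <- index_map[fb$ortho_group]
  sign_b <- ifelse(fb$strand == fa$strand[idx_b], 1L, -1L)
  structure(list(
    a = list(strain_id = "A", order = seq_len(n), index_map = index_map,
             features = fa),
    b = list(strain_id = "B", order = as.integer(idx_b * sign_b),
             index_map = index_map, features = fb),
    n_excluded_multicopy = length(multi)), class = "signed_orders")
}

#' Syntenic clusters: maximal colinear runs of shared genes
#'
#' Partitions strain A's gene order into maximal runs i..j such that the
#' same orthologs are consecutive in strain B, either in identical order
#' with identical signs or fully reversed with flipped signs. Adjacency
#' (k, k+1) in A is conserved when B places the two genes next to each other
#' in the orientation-consistent direction.
#'
#' @param orders A `signed_orders` object (or a list with elements `a$order`
#'   and `b$order` over indices 1..n).
#' @param features_a,features_b Optional feature tables (rows aligned with
#'   the orders, as produced by [shared_signed_orders()]) used to attach
#'   per-strain genomic spans.
#' @return Data frame, one row per cluster: `cluster_id, members
#'   (comma-separated ortholog ids or indices), n_genes`, plus per-strain
#'   span columns when features are given.
#' @export
synteny_clusters <- function(orders, features_a = NULL, features_b = NULL) {
  ord_b <- if (inherits(orders, "signed_orders")) orders$b$order else
    orders$b$order
  n <- length(ord_b)
  ids <- if (inherits(orders, "signed_orders"))
    names(orders$a$index_map) else as.character(seq_len(n))
  if (inherits(orders, "signed_orders")) {
    if (is.null(features_a)) features_a <- orders$a$features
    if (is.null(features_b)) features_b <- orders$b$features
  }
  if (n == 0) {
    return(data.frame(cluster_id = character(), members = character(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  }
  pos_b <- integer(n); sign_b <- integer(n)
  pos_b[abs(ord_b)] <- seq_len(n)
  sign_b[abs(ord_b)] <- sign(ord_b)
  breaks <- logical(n - 1L)
  if (n > 1) {
    for (k in seq_len(n - 1L)) {
      conserved <-
        (sign_b[k] == 1L && sign_b[k + 1L] == 1L &&
           pos_b[k + 1L] == pos_b[k] + 1L) ||
        (sign_b[k] == -1L && sign_b[k + 1L] == -1L &&
           pos_b[k + 1L] == pos_b[k] - 1L)
      breaks[k] <- !conserved
    }
  }
  cluster_of <- cumsum(c(1L, as.integer(breaks)))
  out <- lapply(split(seq_len(n), cluster_of), function(run) {
    data.frame(members = paste(ids[run], collapse = ","),
               n_genes = length(run),
               first_index = run[1], last_index = run[length(run)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- cbind(cluster_id = sprintf("cluster_%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  span_cols <- function(f, tag) {
    if (is.null(f)) return(NULL)
    a <- vapply(seq_len(nrow(out)), function(i) {
      run <- out$first_index[i]:out$last_index[i]
      rows <- if (identical(tag, "a")) run else {
        ## B rows: the same orthologs, located via B positions
        pos_b[run]
      }
      c(min(f$start[rows]), max(f$end[rows]))
    }, numeric(2))
    df <- data.frame(scaffold = f$scaffold_id[1], start = a[1, ],
                     end = a[2, ], stringsAsFactors = FALSE)
    names(df) <- paste0(tag, "_", names(df))
    df
  }
  sa <- span_cols(features_a, "a")
  sb <- span_cols(features_b, "b")
  if (!is.null(sa)) out <- cbind(out, sa, stringsAsFactors = FALSE)
  if (!is.null(sb)) out <- cbind(out, sb, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Breakpoint distance of a signed permutation
#'
#' Frames the permutation with 0 and n+1 (linear mode) and counts adjacent
#' pairs (a, b) with `b - a != 1`; a conserved adjacency is exactly a pair
#' of genes that are neighbors in the same relative orientation in both
#' genomes. In circular mode the frame wraps around and an adjacency is
#' conserved when `(b - a) mod n == 1`.
#'
#' @param perm Integer vector: signed permutation of 1..n relative to the
#'   identity.
#' @param circular Treat the gene order as circular (default FALSE).
#' @return Integer breakpoint count.
#' @export
breakpoint_distance <- function(perm, circular = FALSE) {
  n <- length(perm)
  if (n == 0) return(0L)
  if (!setequal(abs(perm), seq_len(n))) {
    stop("not a signed permutation of 1..n", call. = FALSE)
  }
  if (circular) {
    a <- perm
    b <- c(perm[-1], perm[1])
    return(sum((b - a) %% n != 1L))
  }
  ext <- c(0L, perm, n + 1L)
  sum(diff(ext) != 1L)
}

#' Pairwise breakpoint-distance matrix over several strains
#'
#' For every strain pair, extracts the shared signed orders and computes the
#' breakpoint distance of strain B's order relative to strain A's. The
#' matrix is symmetric with a zero diagonal; the triangle inequality is not
#' asserted (breakpoint distance does not guarantee it in general).
#'
#' @param features_list Named list of per-strain feature tables carrying
#'   `ortho_group`.
#' @param circular Passed to [breakpoint_distance()].
#' @return Symmetric integer matrix of breakpoint distances.
#' @export
pairwise_distance_matrix <- function(features_list, circular = FALSE) {
  ids <- names(features_list)
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (length(ids) < 2) return(m)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      so <- shared_signed_orders(features_list[[i]], features_list[[j]])
      d <- breakpoint_distance(so$b$order, circular = circular)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  m
}

#' Greedy sorting-by-reversals count (heuristic upper bound)
#'
#' Repeatedly applies the reversal that removes the most breakpoints
#' (leftmost on ties); when no reversal removes any, applies the reversal
#' that places the next out-of-position element. The returned count is an
#' upper bound on the true reversal distance and is labeled heuristic.
#'
#' @param perm Signed permutation of 1..n.
#' @return Integer number of reversals applied.
#' @export
greedy_reversal_count <- function(perm) {
  n <- length(perm)
  if (n == 0) return(0L)
  count <- 0L
  apply_rev <- function(p, i, j) {
    p[i:j] <- -rev(p[i:j])
    p
  }
  guard <- 0L
  while (breakpoint_distance(perm) > 0 && guard < 10L * n + 20L) {
    guard <- guard + 1L
    base <- breakpoint_distance(perm)
    best <- NULL
    for (i in seq_len(n)) {
      for (j in i:n) {
        d <- breakpoint_distance(apply_rev(perm, i, j))
        if (d < base && (is.null(best) || d < best$d)) {
          best <- list(i = i, j = j, d = d)
        }
      }
      if (!is.null(best) && best$d <= base - 2L) break
    }
    if (is.null(best)) {
      ## no breakpoint-reducing reversal: put the next misplaced element home
      k <- which(perm != seq_len(n))[1]
      pos <- which(abs(perm) == k)
      perm <- apply_rev(perm, k, pos)
      if (perm[k] != k) perm <- apply_rev(perm, k, k)
    } else {
      perm <- apply_rev(perm, best$i, best$j)
    }
    count <- count + 1L
  }
  count
}

#' Tally mobile elements flanking syntenic clusters
#'
#' A cluster counts for mobile class c when any feature of class c starts or
#' ends within `window` bp of either cluster boundary on the same scaffold;
#' one cluster can count in several categories, and clusters with no mobile
#' element in reach count as `none`.
#'
#' @param clusters Cluster table from [synteny_clusters()] (span columns
#'   `a_scaffold, a_start, a_end` are used).
#' @param features Feature table to scan for mobile-class elements.
#' @param window Flank window in bp (default 3000).
#' @return List with `per_cluster` (logical data frame, one column per
#'   category plus `none`) and `counts` (named integer vector over
#'   IS/phage/GIIME/TnTIR/none).
#' @export
flanking_element_tally <- function(clusters, features, window = 3000L) {
  mob <- features[features$klass %in% MOBILE_CLASSES, , drop = FALSE]
  cats <- MOBILE_CLASSES
  flag <- matrix(FALSE, nrow = nrow(clusters), ncol = length(cats),
                 dimnames = list(clusters$cluster_id, cats))
  for (i in seq_len(nrow(clusters))) {
    sc <- clusters$a_scaffold[i]
    bnds <- c(clusters$a_start[i], clusters$a_end[i])
    ms <- mob[mob$scaffold_id == sc, , drop = FALSE]
    if (!nrow(ms)) next
    near <- rep(FALSE, nrow(ms))
    for (b in bnds) {
      near <- near | abs(ms$start - b) <= window | abs(ms$end - b) <= window
    }
    for (cat in cats) {
      flag[i, cat] <- any(near & ms$klass == cat)
    }
  }
  none <- !apply(flag, 1, any)
  per_cluster <- data.frame(cluster_id = clusters$cluster_id, flag,
                            none = none, stringsAsFactors = FALSE)
  counts <- c(colSums(flag), none = sum(none))
  storage.mode(counts) <- "integer"
  list(per_cluster = per_cluster, counts = counts)
}
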