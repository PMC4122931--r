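## COG functional-category frequency profiles and the degradation divergence
## of endosymbiont strains from the mean of their free-living relatives.
## Hit tables are precomputed (synthetic in tests); no homology search is
## run here.

#' Select non-overlapping COG hits per CDS
#'
#' Removes hits above the e-value cutoff, then keeps, per CDS, the
#' maximum-total-score set of mutually non-overlapping hit intervals
#' (weighted interval scheduling; intervals are 0-based half-open on the
#' CDS, so abutting hits do not conflict). Ties between equal-score optima
#' break deterministically toward lower e-value, then leftmost start.
#'
#' @param hits Data frame with columns `cds_id, start, end, category,
#'   score, evalue` (and optionally `strain`).
#' @param evalue_cutoff Maximum e-value retained (default 1e-3).
#' @return The accepted subset of `hits`, ordered by (cds_id, start).
#' @export
select_nonoverlapping_hits <- function(hits, evalue_cutoff = 1e-3) {
  keep <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(keep) == 0) return(keep[0, , drop = FALSE])
  picked <- lapply(split(seq_len(nrow(keep)), keep$cds_id), function(idx) {
    h <- keep[idx, , drop = FALSE]
    o <- order(h$end, h$evalue, h$start)
    h <- h[o, , drop = FALSE]; idx <- idx[o]
    n <- nrow(h)
    ## p[i]: last j < i with end[j] <= start[i]
    p <- vapply(seq_len(n), function(i) {
      ok <- which(h$end[seq_len(i - 1)] <= h$start[i])
      if (length(ok)) max(ok) else 0L
    }, integer(1))
    opt <- numeric(n + 1)        # opt[i+1] = best score of first i hits
    take <- logical(n)
    for (i in seq_len(n)) {
      with_i <- h$score[i] + opt[p[i] + 1]
      ## on equal score prefer taking hit i (lower evalue/leftmost wins via
      ## the pre-sort within equal ends)
      if (with_i >= opt[i]) {
        opt[i + 1] <- with_i
        take[i] <- TRUE
      } else {
        opt[i + 1] <- opt[i]
      }
    }
    sel <- logical(n)
    i <- n
    while (i >= 1) {
      if (take[i] && h$score[i] + opt[p[i] + 1] >= opt[i]) {
        sel[i] <- TRUE
        i <- p[i]
      } else {
        i <- i - 1L
      }
    }
    idx[sel]
  })
  out <- keep[sort(unlist(picked, use.names = FALSE)), , drop = FALSE]
  out <- out[order(out$cds_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-strain COG category frequencies
#'
#' Absolute category frequencies divided by the strain's total number of
#' COG-assigned CDSs. A CDS whose accepted hits fall in m distinct
#' categories contributes 1/m to each, keeping the profile on the simplex.
#'
#' @param accepted Accepted hits (from [select_nonoverlapping_hits()]) for
#'   one strain.
#' @param strain_id Strain label to attach.
#' @return List of class `category_profile`: `strain_id`, `freq` (named
#'   numeric, sums to 1 when nonempty) and `n_assigned`.
#' @export
category_frequencies <- function(accepted, strain_id) {
  if (nrow(accepted) == 0) {
    return(structure(list(strain_id = strain_id, freq = numeric(0),
                          n_assigned = 0L), class = "category_profile"))
  }
  per_cds <- lapply(split(accepted$category, accepted$cds_id), unique)
  n_assigned <- length(per_cds)
  contrib <- unlist(lapply(per_cds, function(cats) {
    rep(1 / length(cats), length(cats))
  }), use.names = FALSE)
  cat_of <- unlist(per_cds, use.names = FALSE)
  freq <- tapply(contrib, cat_of, sum) / n_assigned
  freq <- stats::setNames(as.numeric(freq), names(freq))
  freq <- freq[order(names(freq))]
  structure(list(strain_id = strain_id, freq = freq,
                 n_assigned = n_assigned), class = "category_profile")
}

#' Degradation divergence from the free-living mean
#'
#' Per category, `delta(strain) = freq(strain) - mean(freq over free-living
#' strains)`, computed on the union category set with zero-fill (mean
#' subtraction is otherwise undefined when strains miss categories).
#' Divergences are returned for every strain, including the free-living
#' ones, whose per-category deltas average to zero by construction.
#'
#' @param profiles List of `category_profile` objects.
#' @param free_living_ids Nonempty character vector of free-living strain
#'   ids (must be a subset of the profiles).
#' @return Named list of divergence profiles: each has `strain_id` and
#'   `delta` (named numeric over the union category set).
#' @export
degradation_divergence <- function(profiles, free_living_ids) {
  ids <- vapply(profiles, function(p) p$strain_id, character(1))
  names(profiles) <- ids
  if (length(free_living_ids) == 0) {
    stop("free-living strain set is empty", call. = FALSE)
  }
  if (!all(free_living_ids %in% ids)) {
    stop("free-living id(s) not among profiles: ",
         paste(setdiff(free_living_ids, ids), collapse = ", "),
         call. = FALSE)
  }
  cats <- sort(unique(unlist(lapply(profiles, function(p) names(p$freq)))))
  mat <- vapply(profiles, function(p) {
    v <- stats::setNames(numeric(length(cats)), cats)
    v[names(p$freq)] <- p$freq
    v
  }, numeric(length(cats)))
  if (length(cats) == 1) mat <- matrix(mat, nrow = 1,
                                       dimnames = list(cats, ids))
  fl_mean <- rowMeans(mat[, free_living_ids, drop = FALSE])
  lapply(stats::setNames(ids, ids), function(s) {
    list(strain_id = s, delta = mat[, s] - fl_mean)
  })
}

#' Write profiles or divergences as a TSV matrix
#'
#' @param x List of `category_profile` objects or of divergence profiles.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cog_table <- function(x, path) {
  ids <- vapply(x, function(p) p$strain_id, character(1))
  vals <- lapply(x, function(p) if (!is.null(p$freq)) p$freq else p$delta)
  cats <- sort(unique(unlist(lapply(vals, names))))
  mat <- vapply(vals, function(v) {
    out <- stats::setNames(numeric(length(cats)), cats)
    out[names(v)] <- v
    out
  }, numeric(length(cats)))
  df <- data.frame(category = cats, mat, check.names = FALSE)
  colnames(df) <- c("category", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
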