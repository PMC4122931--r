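## Intrapopulation rearrangement screen on a mapped mate-pair library:
## orientation/insert classification, the published filter cascade
## (concordant -> mobile-region -> same-contig -> mate-overlap), class
## fraction summaries and single-linkage clustering of discordant evidence.
##
## Conventions (declared, the source data defines neither): insert size is
## the outer distance right.end - left.start; orientation is read off the
## coordinate-leftmost mate, so RF (leftmost mate reverse) is the canonical
## large-insert mate-pair orientation and FR the short-insert "innie"
## contamination.

#' Classify mate-pair orientation and insert size
#'
#' Vectorized over a record table. The mate with the smaller start is
#' "left"; orientation is FR if left is + and right is -, RF if left is -
#' and right is +, FF/RR if both strands agree. Insert size is the outer
#' distance. Pairs on different contigs get `NA` orientation and insert.
#'
#' @param records Data frame `pair_id, contig1, start1, end1, strand1,
#'   contig2, start2, end2, strand2` (0-based half-open mates).
#' @return `records` with added columns `same_contig, orientation,
#'   insert_size, left_start, left_end, right_start, right_end`.
#' @export
classify_orientation <- function(records) {
  same <- records$contig1 == records$contig2
  swap <- same & (records$start2 < records$start1)
  ls <- ifelse(swap, records$start2, records$start1)
  le <- ifelse(swap, records$end2, records$end1)
  lstr <- ifelse(swap, records$strand2, records$strand1)
  rs <- ifelse(swap, records$start1, records$start2)
  re <- ifelse(swap, records$end1, records$end2)
  rstr <- ifelse(swap, records$strand1, records$strand2)
  orientation <- ifelse(!same, NA_character_,
                 ifelse(lstr == "+" & rstr == "-", "FR",
                 ifelse(lstr == "-" & rstr == "+", "RF",
                 ifelse(lstr == "+" & rstr == "+", "FF", "RR"))))
  insert <- ifelse(same, re - ls, NA_integer_)
  out <- records
  out$same_contig <- same
  out$orientation <- orientation
  out$insert_size <- as.integer(insert)
  out$left_start <- as.integer(ifelse(same, ls, NA))
  out$left_end <- as.integer(ifelse(same, le, NA))
  out$right_start <- as.integer(ifelse(same, rs, NA))
  out$right_end <- as.integer(ifelse(same, re, NA))
  out
}

overlaps_any_region <- function(contig, start, end, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(rep(FALSE, length(start)))
  hit <- rep(FALSE, length(start))
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (contig == regions$contig[i] &
                    start < regions$end[i] & end > regions$start[i])
  }
  hit
}

#' Apply the discordant mate-pair filter cascade
#'
#' Filters in the published order: (1) concordant pairs (same contig, RF
#' orientation, insert inside `concordant_window`) are discarded; (2) pairs
#' with at least one mate overlapping a putative mobile region are
#' discarded; (3) pairs whose mates map to different contigs are set aside
#' (`intercontig`, no orientation analysis); (4) pairs whose mates partly or
#' entirely overlap each other are discarded. Everything else is retained
#' with a defined orientation.
#'
#' @param records Mate-pair record table (see [classify_orientation()]).
#' @param concordant_window Concordant insert-size window in bp (default
#'   `c(2211, 3651)`).
#' @param mobile_regions Optional data frame `contig, start, end` (0-based
#'   half-open) of mobile-element regions.
#' @return The classified table with a `disposition` column over
#'   `concordant_discarded, mobile_discarded, intercontig,
#'   overlap_discarded, retained`.
#' @export
filter_cascade <- function(records, concordant_window = c(2211, 3651),
                           mobile_regions = NULL) {
  cl <- classify_orientation(records)
  n <- nrow(cl)
  disposition <- rep(NA_character_, n)
  concord <- !is.na(cl$orientation) & cl$orientation == "RF" &
    cl$insert_size >= concordant_window[1] &
    cl$insert_size <= concordant_window[2]
  disposition[concord] <- "concordant_discarded"
  mob <- overlaps_any_region(cl$contig1, cl$start1, cl$end1, mobile_regions) |
    overlaps_any_region(cl$contig2, cl$start2, cl$end2, mobile_regions)
  set_mob <- is.na(disposition) & mob
  disposition[set_mob] <- "mobile_discarded"
  inter <- is.na(disposition) & !cl$same_contig
  disposition[inter] <- "intercontig"
  ovl <- is.na(disposition) & cl$same_contig &
    (cl$right_start < cl$left_end)        # partly or entirely overlapping
  disposition[ovl] <- "overlap_discarded"
  disposition[is.na(disposition)] <- "retained"
  cl$disposition <- disposition
  stopifnot(sum(table(disposition)) == n)
  cl
}

#' Summarize orientation classes among retained pairs
#'
#' Counts and percentages (`100 * count / retained_total`, rounded to two
#' decimals) per orientation among retained pairs, plus disposition counts.
#' With an empty retained set the percentages are `NA`.
#'
#' @param classified Output of [filter_cascade()], or a named numeric vector
#'   of retained counts per orientation (`FF, RR, RF, FR`).
#' @return List of class `screen_summary`: `disposition_counts`,
#'   `orientation_counts`, `orientation_percent`, `retained_total`.
#' @export
orientation_summary <- function(classified) {
  orient_levels <- c("FF", "RR", "RF", "FR")
  if (is.numeric(classified)) {
    oc <- stats::setNames(rep(0, length(orient_levels)), orient_levels)
    oc[names(classified)] <- classified
    disp <- c(retained = sum(oc))
  } else {
    ret <- classified[classified$disposition == "retained", , drop = FALSE]
    oc <- table(factor(ret$orientation, levels = orient_levels))
    oc <- stats::setNames(as.numeric(oc), orient_levels)
    disp <- table(classified$disposition)
    disp <- stats::setNames(as.numeric(disp), names(disp))
    stopifnot(sum(oc) == sum(classified$disposition == "retained"))
  }
  total <- sum(oc)
  pct <- if (total > 0) round(100 * oc / total, 2) else
    stats::setNames(rep(NA_real_, length(orient_levels)), orient_levels)
  structure(list(disposition_counts = disp, orientation_counts = oc,
                 orientation_percent = pct, retained_total = total),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("mate-pair screen:", x$retained_total, "retained pairs\n")
  for (o in names(x$orientation_counts)) {
    cat(sprintf("  %s: %d (%.2f%%)\n", o, as.integer(x$orientation_counts[o]),
                x$orientation_percent[o]))
  }
  invisible(x)
}

#' Cluster discordant mate-pair evidence into candidate junctions
#'
#' Greedy single-linkage clustering of retained non-FR pairs: two pairs link
#' when they sit on the same contig and both their left and right mate
#' starts lie within `window` bp of each other. Clusters reaching
#' `min_support` pairs are reported as candidate rearrangement junctions; a
#' rearrangement-free library yields none at the defaults.
#'
#' @param classified Output of [filter_cascade()].
#' @param min_support Minimum supporting pairs per reported cluster
#'   (default 10).
#' @param window Linkage window in bp (default 1000).
#' @return Data frame `junction_id, contig, left_lo, left_hi, right_lo,
#'   right_hi, orientation, support` (0 rows when no cluster qualifies).
#' @export
junction_evidence <- function(classified, min_support = 10L, window = 1000L) {
  cand <- classified[classified$disposition == "retained" &
                       classified$orientation != "FR", , drop = FALSE]
  empty <- data.frame(junction_id = character(), contig = character(),
                      left_lo = integer(), left_hi = integer(),
                      right_lo = integer(), right_hi = integer(),
                      orientation = character(), support = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(cand$contig1, cand$left_start), , drop = FALSE]
  n <- nrow(cand)
  parent <- seq_len(n)
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && cand$contig1[j] == cand$contig1[i] &&
           cand$left_start[j] - cand$left_start[i] <= window) {
      if (abs(cand$right_start[j] - cand$right_start[i]) <= window) {
        ri <- uf_find(parent, i)
        rj <- uf_find(parent, j)
        if (ri != rj) parent[rj] <- ri
      }
      j <- j + 1L
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  comp <- split(seq_len(n), roots)
  out <- lapply(comp, function(idx) {
    if (length(idx) < min_support) return(NULL)
    data.frame(contig = cand$contig1[idx[1]],
               left_lo = min(cand$left_start[idx]),
               left_hi = max(cand$left_start[idx]),
               right_lo = min(cand$right_start[idx]),
               right_hi = max(cand$right_start[idx]),
               orientation = paste(sort(unique(cand$orientation[idx])),
                                   collapse = "/"),
               support = length(idx), stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  out <- do.call(rbind, out)
  out <- out[order(-out$support, out$contig, out$left_lo), , drop = FALSE]
  out <- cbind(junction_id = sprintf("junction_%03d", seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a mate-pair record TSV
#'
#' The tab-delimited subset used by the screen: `pair_id, contig1, start1,
#' end1, strand1, contig2, start2, end2, strand2`, coordinates 0-based
#' half-open (they never touch the GFF boundary convention).
#'
#' @param path Input path.
#' @return Record data frame.
#' @export
read_matepair_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "contig1", "start1", "end1", "strand1",
            "contig2", "start2", "end2", "strand2")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("mate-pair table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- tb$start1 >= tb$end1 | tb$start2 >= tb$end2
  if (any(bad)) stop("mate with start >= end: ", tb$pair_id[which(bad)[1]],
                     call. = FALSE)
  if (any(!c(tb$strand1, tb$strand2) %in% c("+", "-"))) {
    stop("mate strand must be + or -", call. = FALSE)
  }
  tb
}
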