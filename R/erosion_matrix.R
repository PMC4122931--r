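## Per-strain gene-state matrices (intact / pseudogene / absent) for shared
## nonmobile ortholog groups, using a 30%-of-self local alignment score rule,
## and Dollo assignment of inactivation events to the branches of a fixed
## three-strain topology ((SAp,SCt),SCc) rooted with an intact outgroup
## state.

## BLOSUM62 with X scored 0 against everything, so fragments with ambiguous
## residues neither gain nor lose score from them.
erosion_matrix_env <- new.env(parent = emptyenv())

blosum62_x0 <- function() {
  if (is.null(erosion_matrix_env$mat)) {
    utils::data("BLOSUM62", package = "Biostrings",
                envir = erosion_matrix_env)
    mat <- as.matrix(erosion_matrix_env$BLOSUM62)
    if ("X" %in% rownames(mat)) {
      mat["X", ] <- 0L
      mat[, "X"] <- 0L
    }
    erosion_matrix_env$mat <- mat
  }
  erosion_matrix_env$mat
}

#' Optimal local protein alignment score
#'
#' Smith-Waterman local alignment raw score under BLOSUM62 with affine gaps
#' (gap open 11, gap extend 1; a gap of length L costs 11 + L). `X` residues
#' score 0 against everything. The score is symmetric in its arguments.
#'
#' @param a,b Protein sequences (standard 20-letter alphabet, `X`
#'   tolerated).
#' @param gap_open,gap_extend Affine gap parameters.
#' @return Nonnegative numeric alignment score.
#' @export
local_align_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = blosum62_x0(),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
}

#' Alignment score relative to the reference self-score
#'
#' `local_align_score(query, ref) / local_align_score(ref, ref)`: the
#' fraction of the reference's self-alignment score that the query attains.
#' Under BLOSUM62 the diagonal dominates every row, so the ratio lies in
#' [0, 1]. Pseudogene fragments scoring below 0.30 of self are treated as
#' beyond recognition downstream.
#'
#' @param query,ref Protein sequences; `ref` must be nonempty with positive
#'   self-score.
#' @return Ratio in [0, 1].
#' @export
relative_score <- function(query, ref) {
  self <- local_align_score(ref, ref)
  if (self <= 0) stop("reference self-score is not positive", call. = FALSE)
  local_align_score(query, ref) / self
}

#' Assign a gene state from strain evidence
#'
#' A strain is `intact` for a group if it has an annotated intact CDS
#' member; `pseudo` if it lacks one but some translated fragment reaches
#' `relative_score >= cutoff` against the intact reference; `absent`
#' otherwise.
#'
#' @param has_intact_cds Logical: does the strain have an intact CDS member?
#' @param fragments Character vector of fragment protein sequences (possibly
#'   empty).
#' @param ref Intact reference protein.
#' @param cutoff Relative-score cutoff (default 0.30).
#' @return List with `state` in `intact/pseudo/absent` and `rel_score` (best
#'   fragment ratio, NA if no fragment).
#' @export
assign_state <- function(has_intact_cds, fragments, ref, cutoff = 0.30) {
  if (isTRUE(has_intact_cds)) {
    return(list(state = "intact", rel_score = NA_real_))
  }
  fragments <- fragments[nzchar(fragments)]
  if (!length(fragments)) {
    return(list(state = "absent", rel_score = NA_real_))
  }
  rs <- vapply(fragments, relative_score, numeric(1), ref = ref)
  best <- max(rs)
  list(state = if (best >= cutoff) "pseudo" else "absent", rel_score = best)
}

## Elementwise batched local alignment scores: score(queries[i], refs[i]).
## One vectorized call amortizes the per-alignment setup cost.
batch_local_scores <- function(queries, refs, gap_open = 11, gap_extend = 1) {
  if (!length(queries)) return(numeric(0))
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAStringSet(refs),
    type = "local", substitutionMatrix = blosum62_x0(),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
}

#' Translate a nucleotide fragment in all six frames
#'
#' Helper for pseudogene loci with only nucleotide evidence: returns the six
#' conceptual translations (stops as `*` are cut at the first stop of each
#' frame is NOT done here; downstream scoring tolerates `*` as `X`).
#'
#' @param nt Nucleotide sequence.
#' @return Character vector of six protein sequences.
#' @export
translate_six_frames <- function(nt) {
  nt <- toupper(nt)
  rc <- revcomp(nt)
  out <- character(0)
  for (s in c(nt, rc)) {
    for (off in 0:2) {
      sub <- substr(s, off + 1, nchar(s) - ((nchar(s) - off) %% 3))
      if (nchar(sub) < 3) next
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                               if.fuzzy.codon = "X"))
      out <- c(out, gsub("\\*", "X", aa))
    }
  }
  out
}

#' Build the ortholog state matrix
#'
#' For every ortholog group: drop it if any member is a mobile-class
#' feature; otherwise score each strain with [assign_state()] against the
#' group's intact reference (first intact CDS member in strain-input order,
#' ties by feature id). Groups with fewer than two non-absent strains are
#' dropped. Rows are ordered lexicographically by group id.
#'
#' @param features_by_strain Named list of per-strain feature tables.
#' @param proteins_by_strain Named list of per-strain named protein vectors.
#' @param ortho_table Data frame `group_id, strain, feature_id`.
#' @param cutoff Relative-score cutoff (default 0.30).
#' @return Object of class `ortho_state_matrix`: list with `states`
#'   (character matrix groups x strains over `intact/pseudo/absent`) and
#'   `provenance` (per-cell evidence data frame).
#' @export
build_state_matrix <- function(features_by_strain, proteins_by_strain,
                               ortho_table, cutoff = 0.30) {
  strains <- unique(ortho_table$strain)
  missing_strains <- setdiff(strains, names(features_by_strain))
  if (length(missing_strains)) {
    stop("strain(s) in ortholog table but not in inputs: ",
         paste(missing_strains, collapse = ", "), call. = FALSE)
  }
  strains <- names(features_by_strain)[names(features_by_strain) %in% strains]
  feat_all <- do.call(rbind, lapply(strains, function(s) {
    f <- features_by_strain[[s]]
    f$strain <- s
    f
  }))
  key <- paste(feat_all$strain, feat_all$feature_id)
  groups <- sort(unique(ortho_table$group_id))
  states <- matrix(NA_character_, nrow = length(groups),
                   ncol = length(strains),
                   dimnames = list(groups, strains))
  mem_by_group <- split(ortho_table, ortho_table$group_id)
  ## pass 1: references, intact calls, and the fragment-scoring task list
  prov <- list()
  tasks <- list()          # one row per fragment to score
  refs <- stats::setNames(rep(NA_character_, length(groups)), groups)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    mem <- mem_by_group[[g]]
    idx <- match(paste(mem$strain, mem$feature_id), key)
    if (anyNA(idx)) {
      stop("ortholog table references unknown feature for group ", g,
           call. = FALSE)
    }
    mf <- feat_all[idx, , drop = FALSE]
    if (any(mf$klass %in% MOBILE_CLASSES)) next   # mobile member: drop row
    ## intact reference: first intact CDS member, strain-input order then id
    cds <- mf[mf$klass == "CDS", , drop = FALSE]
    if (nrow(cds)) {
      cds <- cds[order(match(cds$strain, strains), cds$feature_id), ,
                 drop = FALSE]
      refs[g] <- proteins_by_strain[[cds$strain[1]]][[cds$feature_id[1]]]
    }
    row_states <- stats::setNames(rep("absent", length(strains)), strains)
    for (s in strains) {
      ms <- mf[mf$strain == s, , drop = FALSE]
      if (!nrow(ms)) next
      if (any(ms$klass == "CDS")) {
        row_states[s] <- "intact"
        prov[[length(prov) + 1L]] <- data.frame(
          group_id = g, strain = s, state = "intact",
          n_members = nrow(ms), rel_score = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      frags <- unlist(lapply(ms$feature_id, function(fid) {
        p <- proteins_by_strain[[s]][[fid]]
        if (is.null(p)) character(0) else p
      }))
      frags <- frags[nzchar(frags)]
      if (!length(frags) || is.na(refs[g])) {
        ## no fragment evidence, or no intact member anywhere to score
        ## against: absent
        prov[[length(prov) + 1L]] <- data.frame(
          group_id = g, strain = s, state = "absent",
          n_members = nrow(ms), rel_score = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      row_states[s] <- "pending"
      tasks[[length(tasks) + 1L]] <- data.frame(
        group_id = g, strain = s, query = frags,
        n_members = nrow(ms), stringsAsFactors = FALSE)
    }
    states[gi, ] <- row_states
  }
  ## pass 2: batch all fragment alignments plus reference self-scores
  if (length(tasks)) {
    td <- do.call(rbind, tasks)
    uref <- refs[!is.na(refs)]
    uref <- uref[unique(td$group_id)]
    self <- batch_local_scores(unname(uref), unname(uref))
    names(self) <- names(uref)
    if (any(self <= 0)) {
      stop("reference self-score is not positive", call. = FALSE)
    }
    td$score <- batch_local_scores(td$query, unname(refs[td$group_id]))
    td$ratio <- td$score / self[td$group_id]
    cellkey <- paste(td$group_id, td$strain)
    for (ck in unique(cellkey)) {
      rows <- td[cellkey == ck, , drop = FALSE]
      best <- max(rows$ratio)
      st <- if (best >= cutoff) "pseudo" else "absent"
      states[rows$group_id[1], rows$strain[1]] <- st
      prov[[length(prov) + 1L]] <- data.frame(
        group_id = rows$group_id[1], strain = rows$strain[1], state = st,
        n_members = rows$n_members[1], rel_score = best,
        stringsAsFactors = FALSE)
    }
  }
  ## shared-by->=2 rule, applied after all cells are resolved
  keep <- !is.na(states[, 1]) &
    rowSums(states != "absent", na.rm = TRUE) >= 2
  states <- states[keep, , drop = FALSE]
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(group_id = character(), strain = character(),
               state = character(), n_members = integer(),
               rel_score = numeric(), stringsAsFactors = FALSE)
  prov <- prov[prov$group_id %in% rownames(states), , drop = FALSE]
  rownames(prov) <- NULL
  structure(list(states = states, provenance = prov),
            class = "ortho_state_matrix")
}

#' @export
print.ortho_state_matrix <- function(x, ...) {
  cat("ortho_state_matrix:", nrow(x$states), "groups x",
      ncol(x$states), "strains\n")
  tab <- table(factor(x$states, levels = c("intact", "pseudo", "absent")))
  print(tab)
  invisible(x)
}

.state_level <- c(intact = 0L, pseudo = 1L, absent = 2L)

## Events implied by moving from parent state to child state along one
## branch under the Dollo order intact -> pseudo -> absent (no regain).
branch_events <- function(from, to) {
  c(pseudogenization = as.integer(from < 1 & to >= 1),
    loss = as.integer(from < 2 & to >= 2))
}

#' Assign inactivation events to branches of a fixed 3-strain topology
#'
#' Dollo parsimony on the rooted topology `((ingroup1, ingroup2), outgroup)`
#' with the root fixed `intact`: along any root-to-leaf path the state may
#' only degrade (intact to pseudogene to absent, never back). The internal
#' (ingroup ancestor) state is set to the least-degraded state compatible
#' with both ingroup leaves, which uniquely minimizes the total number of
#' events. Rows where both ingroup leaves are non-intact are flagged
#' `ambiguous`: the shared event on the internal branch could instead be two
#' independent terminal events (one extra event).
#'
#' @param x An `ortho_state_matrix` (or a bare character matrix of states).
#' @param ingroup Two sister strain ids (default `c("SAp", "SCt")`).
#' @param outgroup Outgroup strain id (default `"SCc"`).
#' @return List with `per_group` (data frame: internal state, per-branch
#'   events, ambiguity flag) and `branch_counts` (data frame: branch,
#'   pseudogenization and loss event totals). Branches are named `internal`
#'   (root to ingroup ancestor), the two ingroup terminal branches, and the
#'   outgroup terminal branch.
#' @export
assign_loss_branches <- function(x, ingroup = c("SAp", "SCt"),
                                 outgroup = "SCc") {
  states <- if (inherits(x, "ortho_state_matrix")) x$states else x
  need <- c(ingroup, outgroup)
  if (!all(need %in% colnames(states))) {
    stop("state matrix lacks strain column(s): ",
         paste(setdiff(need, colnames(states)), collapse = ", "),
         call. = FALSE)
  }
  branches <- c("internal", ingroup, outgroup)
  counts <- matrix(0L, nrow = length(branches), ncol = 2,
                   dimnames = list(branches, c("pseudogenization", "loss")))
  per <- vector("list", nrow(states))
  for (i in seq_len(nrow(states))) {
    lv <- .state_level[states[i, need]]
    names(lv) <- need
    internal <- min(lv[ingroup])      # maximizing retention minimizes events
    ev_int <- branch_events(0L, internal)
    ev_a <- branch_events(internal, lv[[ingroup[1]]])
    ev_b <- branch_events(internal, lv[[ingroup[2]]])
    ev_o <- branch_events(0L, lv[[outgroup]])
    counts["internal", ] <- counts["internal", ] + ev_int
    counts[ingroup[1], ] <- counts[ingroup[1], ] + ev_a
    counts[ingroup[2], ] <- counts[ingroup[2], ] + ev_b
    counts[outgroup, ] <- counts[outgroup, ] + ev_o
    per[[i]] <- data.frame(
      group_id = rownames(states)[i],
      internal_state = names(.state_level)[internal + 1L],
      events_total = sum(ev_int, ev_a, ev_b, ev_o),
      ambiguous = all(lv[ingroup] > 0L),
      stringsAsFactors = FALSE)
  }
  per_group <- if (length(per)) do.call(rbind, per) else
    data.frame(group_id = character(), internal_state = character(),
               events_total = integer(), ambiguous = logical(),
               stringsAsFactors = FALSE)
  branch_counts <- data.frame(branch = branches,
                              pseudogenization = counts[, 1],
                              loss = counts[, 2], row.names = NULL,
                              stringsAsFactors = FALSE)
  list(per_group = per_group, branch_counts = branch_counts)
}

#' Write an ortholog state matrix as TSV
#' @param x An `ortho_state_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_state_matrix <- function(x, path) {
  stopifnot(inherits(x, "ortho_state_matrix"))
  df <- data.frame(group_id = rownames(x$states), x$states,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
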