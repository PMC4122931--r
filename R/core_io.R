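## Shared coordinate convention: every in-memory coordinate in this package is
## 0-based half-open [start, end). On-disk GFF3/TSV coordinates are 1-based
## inclusive and are converted exactly once, at read/write time.

#' Feature class vocabulary
#'
#' Closed set of feature classes used throughout the package. The four mobile
#' classes are insertion sequences (IS), prophage-derived genes (phage),
#' group II intron mobile elements (GIIME) and the TnTIR transposon-like
#' quorum-sensing element. `gap`, `repeat_region` and `primer` are structural
#' annotation types emitted by the primer-design stage.
#'
#' @format Character vectors.
#' @name feature-classes
NULL

#' @rdname feature-classes
#' @export
MOBILE_CLASSES <- c("IS", "phage", "GIIME", "TnTIR")

#' @rdname feature-classes
#' @export
FEATURE_CLASSES <- c("CDS", "pseudogene", "IS", "phage", "GIIME", "TnTIR",
                     "RNA", "gap", "repeat_region", "primer")

.rna_tokens <- c("RNA", "tRNA", "rRNA", "ncRNA", "tmRNA", "misc_RNA")

## Map a raw class token from an annotation file onto the controlled
## vocabulary. IS family names (IS481, IS3, ...) collapse to "IS" with the
## family retained; assorted RNA types collapse to "RNA".
map_klass <- function(token) {
  token <- as.character(token)
  out <- character(length(token))
  fam <- rep(NA_character_, length(token))
  for (i in seq_along(token)) {
    tk <- token[i]
    if (tk %in% FEATURE_CLASSES) {
      out[i] <- tk
    } else if (tk %in% .rna_tokens) {
      out[i] <- "RNA"
    } else if (grepl("^IS[0-9]", tk)) {
      out[i] <- "IS"
      fam[i] <- tk
    } else if (tk %in% c("prophage", "phage_element")) {
      out[i] <- "phage"
    } else if (tk %in% c("group_II_intron", "group_II_intron_mobile_element")) {
      out[i] <- "GIIME"
    } else {
      stop("unknown feature class token '", tk, "'; accepted tokens: ",
           paste(FEATURE_CLASSES, collapse = ", "),
           ", RNA types (", paste(.rna_tokens, collapse = ", "),
           "), IS family names (IS<digits>...), prophage, group_II_intron",
           call. = FALSE)
    }
  }
  list(klass = out, family = fam)
}

#' Construct a scaffold set
#'
#' A scaffold set holds named nucleotide sequences (uppercase `A,C,G,T,N`)
#' together with a separate soft-mask interval table. Masking never edits the
#' sequence itself, so it stays reversible and auditable.
#'
#' @param seqs Named character vector of sequences.
#' @param softmask Data frame with columns `scaffold_id`, `start`, `end`
#'   (0-based half-open) marking soft-masked intervals, or `NULL`.
#' @return An object of class `scaffold_set`: a list with elements `records`
#'   (named uppercase character vector) and `softmask`.
#' @export
scaffold_set <- function(seqs, softmask = NULL) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every scaffold must have a nonempty id", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate scaffold id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for scaffold ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  bad <- regexpr("[^ACGTNacgtn]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("illegal character '", substr(seqs[i], bad[i], bad[i]),
         "' in scaffold ", ids[i], " at position ", bad[i], call. = FALSE)
  }
  if (is.null(softmask)) {
    softmask <- data.frame(scaffold_id = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  }
  rec <- toupper(seqs)
  names(rec) <- ids
  structure(list(records = rec, softmask = softmask), class = "scaffold_set")
}

#' @export
print.scaffold_set <- function(x, ...) {
  cat("scaffold_set with", length(x$records), "scaffold(s),",
      sum(nchar(x$records)), "bp total,",
      nrow(x$softmask), "soft-masked interval(s)\n")
  invisible(x)
}

#' Scaffold lengths
#' @param x A `scaffold_set`.
#' @return Named integer vector of sequence lengths.
#' @export
scaffold_lengths <- function(x) {
  stopifnot(inherits(x, "scaffold_set"))
  nchar(x$records)
}

#' Read a FASTA file into a scaffold set
#'
#' Sequences are uppercased on read; lowercase runs in the input are recorded
#' as soft-mask intervals rather than kept in the sequence. Duplicate ids,
#' empty records and characters outside `A,C,G,T,N` (either case) are hard
#' errors, the latter reporting the offending position.
#'
#' @param path Path to a FASTA file.
#' @return A [scaffold_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  names(seqs) <- ids
  ## lowercase runs -> soft-mask intervals (0-based half-open)
  mk <- lapply(seq_along(seqs), function(i) {
    m <- gregexpr("[acgtn]+", seqs[i])[[1]]
    if (m[1] == -1) return(NULL)
    data.frame(scaffold_id = ids[i], start = as.integer(m) - 1L,
               end = as.integer(m) + attr(m, "match.length") - 1L,
               stringsAsFactors = FALSE)
  })
  mk <- do.call(rbind, mk[!vapply(mk, is.null, logical(1))])
  scaffold_set(seqs, softmask = mk)
}

#' Write a scaffold set to FASTA
#'
#' Soft-masked intervals are written in lowercase; everything else uppercase.
#' Sequences are wrapped at 70 columns.
#'
#' @param x A `scaffold_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "scaffold_set"))
  seqs <- x$records
  if (nrow(x$softmask) > 0) {
    for (i in seq_len(nrow(x$softmask))) {
      id <- x$softmask$scaffold_id[i]
      s <- x$softmask$start[i]; e <- x$softmask$end[i]
      substr(seqs[id], s + 1L, e) <- tolower(substr(seqs[id], s + 1L, e))
    }
  }
  out <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(out, path, width = 70L)
  invisible(path)
}

## Canonical empty feature table.
empty_features <- function() {
  data.frame(feature_id = character(), scaffold_id = character(),
             start = integer(), end = integer(), strand = character(),
             klass = character(), family = character(),
             cog_category = character(), ortho_group = character(),
             stringsAsFactors = FALSE)
}

#' Read a gene feature table
#'
#' Supports two on-disk dialects: GFF3 (via `rtracklayer`) and a plain TSV
#' with columns `feature_id, scaffold_id, start, end, strand, klass` and
#' optional `cog_category, ortho_group`. On-disk coordinates are 1-based
#' inclusive and converted to the internal 0-based half-open convention.
#' Class tokens are mapped through the controlled vocabulary (see
#' [FEATURE_CLASSES]); IS family names such as `IS481` map to class `IS` with
#' the family kept in the `family` column.
#'
#' @param path Path to the file.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return Data frame with columns `feature_id, scaffold_id, start, end,
#'   strand, klass, family, cog_category, ortho_group` (internal
#'   coordinates).
#' @export
read_feature_table <- function(path, dialect = c("gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) == 0) return(empty_features())
    mc <- S4Vectors::mcols(gr)
    fid <- if ("ID" %in% names(mc)) as.character(mc$ID) else
      paste0("feature_", seq_along(gr))
    fid[is.na(fid)] <- paste0("feature_", which(is.na(fid)))
    raw_klass <- as.character(mc$type)
    km <- map_klass(raw_klass)
    fam <- km$family
    if ("family" %in% names(mc)) {
      f2 <- as.character(mc$family)
      fam[!is.na(f2)] <- f2[!is.na(f2)]
    }
    out <- data.frame(
      feature_id = fid,
      scaffold_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
      klass = km$klass,
      family = fam,
      cog_category = if ("cog_category" %in% names(mc))
        as.character(mc$cog_category) else NA_character_,
      ortho_group = if ("ortho_group" %in% names(mc))
        as.character(mc$ortho_group) else NA_character_,
      stringsAsFactors = FALSE)
  } else {
    tb <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("feature_id", "scaffold_id", "start", "end", "strand", "klass")
    miss <- setdiff(need, names(tb))
    if (length(miss)) stop("TSV feature table missing column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    if (nrow(tb) == 0) return(empty_features())
    if (any(tb$end < tb$start)) {
      stop("feature with end < start: ",
           tb$feature_id[which(tb$end < tb$start)[1]], call. = FALSE)
    }
    km <- map_klass(tb$klass)
    out <- data.frame(
      feature_id = as.character(tb$feature_id),
      scaffold_id = as.character(tb$scaffold_id),
      start = as.integer(tb$start) - 1L,
      end = as.integer(tb$end),
      strand = as.character(tb$strand),
      klass = km$klass,
      family = km$family,
      cog_category = if ("cog_category" %in% names(tb))
        as.character(tb$cog_category) else NA_character_,
      ortho_group = if ("ortho_group" %in% names(tb))
        as.character(tb$ortho_group) else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (any(out$end < out$start)) {
    stop("feature with end < start: ",
         out$feature_id[which(out$end < out$start)[1]], call. = FALSE)
  }
  if (any(!out$strand %in% c("+", "-", "."))) {
    stop("strand must be one of +, -, .", call. = FALSE)
  }
  out
}

#' Write a gene feature table as TSV
#'
#' Inverse of [read_feature_table()] with `dialect = "tsv"`; coordinates are
#' emitted 1-based inclusive.
#'
#' @param features Internal feature data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  out$start <- out$start + 1L
  ## emit the family token back into klass for IS elements so the table
  ## round-trips the family information without an extra column dependency
  keep_family <- !is.na(out$family) & out$klass == "IS"
  out$klass[keep_family] <- out$family[keep_family]
  out$family <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write gap, repeat and primer annotations
#'
#' Emits one GFF3 file with feature types `gap`, `repeat_region` and `primer`
#' (1-based inclusive coordinates) and, optionally, a FASTA of the primer
#' sequences. The GFF3 round-trips through [read_feature_table()].
#'
#' @param gaps Data frame of gap intervals (`scaffold_id, start, end`,
#'   internal coordinates), e.g. from [find_gaps()].
#' @param repeats Data frame of repeat intervals (`scaffold_id, start, end,
#'   family_id`), e.g. from [detect_repeats()].
#' @param pairs List of `primer_pair` objects (see [design_gap_primers()]);
#'   failures are skipped.
#' @param path Output GFF3 path.
#' @param fasta_path Optional output path for the primer FASTA.
#' @param scaffolds Optional `scaffold_set`; if given, features are checked
#'   against scaffold bounds and sequence lengths are declared in the GFF3.
#' @return Invisibly, `path`.
#' @export
write_primer_gff <- function(gaps, repeats, pairs, path,
                             fasta_path = NULL, scaffolds = NULL) {
  rows <- list()
  if (!is.null(gaps) && nrow(gaps) > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold_id = gaps$scaffold_id, start = gaps$start, end = gaps$end,
      strand = ".", type = "gap",
      ID = paste0("gap_", seq_len(nrow(gaps))),
      estimated_size = gaps$end - gaps$start,
      family = NA_character_, stringsAsFactors = FALSE)
  }
  if (!is.null(repeats) && nrow(repeats) > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      scaffold_id = repeats$scaffold_id, start = repeats$start,
      end = repeats$end, strand = ".", type = "repeat_region",
      ID = paste0("repeat_", seq_len(nrow(repeats))),
      estimated_size = NA_integer_,
      family = as.character(repeats$family_id), stringsAsFactors = FALSE)
  }
  primer_seqs <- character()
  if (length(pairs)) {
    k <- 0L
    for (p in pairs) {
      if (!inherits(p, "primer_pair")) next
      k <- k + 1L
      for (side in c("left", "right")) {
        pc <- p[[side]]
        rows[[length(rows) + 1L]] <- data.frame(
          scaffold_id = pc$scaffold_id, start = pc$start, end = pc$end,
          strand = pc$strand, type = "primer",
          ID = paste0("primer_", k, "_", side),
          estimated_size = NA_integer_, family = NA_character_,
          stringsAsFactors = FALSE)
        primer_seqs[paste0("primer_", k, "_", side)] <- pc$sequence
      }
    }
  }
  if (length(rows)) {
    tb <- do.call(rbind, rows)
    if (!is.null(scaffolds)) {
      lens <- scaffold_lengths(scaffolds)
      unk <- setdiff(tb$scaffold_id, names(lens))
      if (length(unk)) stop("feature references unknown scaffold: ",
                            paste(unk, collapse = ", "), call. = FALSE)
      if (any(tb$end > lens[tb$scaffold_id]) || any(tb$start < 0)) {
        stop("feature outside scaffold bounds", call. = FALSE)
      }
    }
    gr <- GenomicRanges::GRanges(
      seqnames = tb$scaffold_id,
      ranges = IRanges::IRanges(start = tb$start + 1L, end = tb$end),
      strand = ifelse(tb$strand == ".", "*", tb$strand))
    S4Vectors::mcols(gr)$type <- tb$type
    S4Vectors::mcols(gr)$ID <- tb$ID
    S4Vectors::mcols(gr)$estimated_size <- tb$estimated_size
    S4Vectors::mcols(gr)$family <- tb$family
    S4Vectors::mcols(gr)$source <- "endoerode"
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    writeLines("##gff-version 3", path)
  }
  if (!is.null(fasta_path)) {
    if (length(primer_seqs)) {
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(primer_seqs),
                                  fasta_path, width = 70L)
    } else {
      file.create(fasta_path)
    }
  }
  invisible(path)
}

## Reverse complement for plain character vectors. Biostrings handles the
## batch case; short scalars go through a cheap chartr path (the primer
## scorer calls this in tight loops).
revcomp <- function(x) {
  if (length(x) == 1 && nchar(x) <= 64) {
    return(paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", x),
                              "")[[1]]), collapse = ""))
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
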