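# Genome input, rRNA feature extraction, pre-rRNA region derivation.

#' Construct a genome record
#'
#' @param replicon_id replicon identifier.
#' @param sequence plus-strand DNA sequence (A/C/G/T/N and IUPAC codes).
#' @param features data.frame with columns `kind`, `start`, `end` (1-based
#'   inclusive), `strand` ("+"/"-") and `product`.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(replicon_id, sequence,
                          features = NULL) {
  if (is.null(features)) features <- empty_feature_table()
  stopifnot(is.character(replicon_id), length(replicon_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  check_dna_alphabet(sequence, sprintf("record '%s' sequence", replicon_id))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features)) {
    if (any(features$start > features$end)) {
      abort_validation("genome_record '%s': feature with start > end", replicon_id)
    }
    if (any(features$start < 1L) || any(features$end > nchar(sequence))) {
      abort_validation("genome_record '%s': feature outside [1, %d]",
                       replicon_id, nchar(sequence))
    }
    if (!all(features$strand %in% c("+", "-"))) {
      abort_validation("genome_record '%s': feature strand must be '+' or '-'",
                       replicon_id)
    }
  }
  structure(list(replicon_id = replicon_id, sequence = sequence,
                 features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %d features\n",
              x$replicon_id, nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

#' Read an annotated genome or plain rRNA FASTA
#'
#' GenBank input yields one record per replicon with its annotated features;
#' FASTA input yields one record per sequence with zero features (the
#' sequences are then treated directly as rRNA templates downstream).
#'
#' @param path input file path.
#' @param format `"genbank"` or `"fasta"`.
#' @return list of `genome_record`.
#' @export
read_annotated_genome <- function(path, format = c("genbank", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_io("input file does not exist: %s", path)
  if (format == "genbank") {
    return(read_genbank_file(path))
  }
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) abort_parse("malformed FASTA '%s': %s",
                                                  path, conditionMessage(e)))
  if (length(set) == 0L) abort_parse("FASTA file contains no sequences: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]))
  })
}

# Length bins used when the product qualifier does not name the rRNA type.
.RRNA_LENGTH_BINS <- list(`5S` = c(80L, 150L), `16S` = c(1300L, 1800L),
                          `23S` = c(2500L, 3400L))

classify_rrna_type <- function(product, width) {
  hit <- regmatches(product, regexpr("(5S|16S|23S)", product))
  if (length(hit) && nzchar(hit)) return(hit)
  for (ty in names(.RRNA_LENGTH_BINS)) {
    b <- .RRNA_LENGTH_BINS[[ty]]
    if (width >= b[1] && width <= b[2]) return(ty)
  }
  NA_character_
}

rrna_features_frame <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  class(df) <- c("rrna_features", "data.frame")
  df
}

#' Extract rRNA gene features from annotated genome records
#'
#' One feature per annotated rRNA gene of a requested type; minus-strand
#' genes are reverse complemented to the sense (as-transcribed) strand.
#' Same-strand genes on a replicon within `linking_nt` of each other share
#' an `operon_id`. Records carrying no annotation at all (plain FASTA input)
#' are treated as bare rRNA templates, one feature per record, classified by
#' sequence length (or header text naming 5S/16S/23S).
#'
#' @param records list of `genome_record`.
#' @param types subset of `c("5S","16S","23S")` to extract.
#' @param linking_nt maximum same-strand gap between rRNA genes of one operon.
#' @return an `rrna_features` data.frame with columns `feature_id`,
#'   `rna_type`, `sequence`, `replicon_id`, `start`, `end`, `strand`,
#'   `operon_id`.
#' @export
extract_rrna_features <- function(records, types = c("5S", "16S", "23S"),
                                  linking_nt = 1500L) {
  if (inherits(records, "genome_record")) records <- list(records)
  types <- match.arg(types, several.ok = TRUE)
  annotated <- any(vapply(records, function(r) nrow(r$features) > 0L, logical(1)))

  rows <- list()
  if (!annotated) {
    # bare templates: whole sequences are rRNAs
    for (r in records) {
      ty <- classify_rrna_type(r$replicon_id, nchar(r$sequence))
      if (is.na(ty)) {
        warning(sprintf("sequence '%s' (%d nt) not classifiable as 5S/16S/23S; skipped",
                        r$replicon_id, nchar(r$sequence)))
        next
      }
      if (!(ty %in% types)) next
      rows[[length(rows) + 1L]] <- rrna_features_frame(
        feature_id = r$replicon_id, rna_type = ty, sequence = r$sequence,
        replicon_id = r$replicon_id, start = 1L, end = nchar(r$sequence),
        strand = "+", operon_id = "")
    }
    if (!length(rows)) abort_validation("no rRNA sequences of the requested types found")
    out <- do.call(rbind, rows)
    class(out) <- c("rrna_features", "data.frame")
    return(out)
  }

  for (r in records) {
    f <- r$features
    f <- f[grepl("rRNA", f$kind, ignore.case = TRUE), , drop = FALSE]
    if (!nrow(f)) next
    for (i in seq_len(nrow(f))) {
      ty <- classify_rrna_type(f$product[i], f$end[i] - f$start[i] + 1L)
      if (is.na(ty)) {
        warning(sprintf("rRNA feature at %s:%d-%d not classifiable; skipped",
                        r$replicon_id, f$start[i], f$end[i]))
        next
      }
      slice <- substr(r$sequence, f$start[i], f$end[i])
      if (f$strand[i] == "-") slice <- revcomp(slice)
      rows[[length(rows) + 1L]] <- rrna_features_frame(
        feature_id = sprintf("%s_%s_%d", r$replicon_id, ty, f$start[i]),
        rna_type = ty, sequence = slice, replicon_id = r$replicon_id,
        start = f$start[i], end = f$end[i], strand = f$strand[i],
        operon_id = "")
    }
  }
  if (!length(rows)) {
    abort_validation("no rRNA features found in the annotated genome")
  }
  out <- do.call(rbind, rows)
  out <- assign_operons(out, linking_nt)
  out <- out[out$rna_type %in% types, , drop = FALSE]
  if (!nrow(out)) {
    abort_validation("no rRNA features of the requested types (%s) found",
                     paste(types, collapse = ","))
  }
  rownames(out) <- NULL
  class(out) <- c("rrna_features", "data.frame")
  out
}

# Group same-strand neighbouring rRNA genes into operons.
assign_operons <- function(feats, linking_nt) {
  feats$operon_id <- ""
  ord <- order(feats$replicon_id, feats$start)
  feats <- feats[ord, , drop = FALSE]
  op <- 0L
  last <- NULL
  ids <- character(nrow(feats))
  for (i in seq_len(nrow(feats))) {
    new_op <- is.null(last) ||
      feats$replicon_id[i] != last$replicon_id ||
      feats$strand[i] != last$strand ||
      (feats$start[i] - last$end - 1L) > linking_nt
    if (new_op) op <- op + 1L
    ids[i] <- sprintf("operon_%02d", op)
    last <- list(replicon_id = feats$replicon_id[i], end = feats$end[i],
                 strand = feats$strand[i])
  }
  feats$operon_id <- ids
  rownames(feats) <- NULL
  feats
}

#' Derive pre-rRNA operon regions
#'
#' For each operon: the internal spacers between consecutive rRNA genes,
#' plus `leader_nt` transcriptionally upstream of the first gene and
#' `trailer_nt` downstream of the last (strand-aware), clipped to the
#' replicon and with zero-length regions dropped. These regions carry the
#' precursor-only sequence that mature-rRNA probes cannot reach.
#'
#' @param records list of `genome_record` (sequence source for the regions).
#' @param features `rrna_features` with assigned `operon_id`.
#' @param leader_nt,trailer_nt flank lengths in nt (>= 0).
#' @return an `rrna_features` data.frame with `rna_type == "pre-rRNA"`.
#' @export
derive_pre_rrna_regions <- function(records, features,
                                    leader_nt = 150L, trailer_nt = 150L) {
  if (inherits(records, "genome_record")) records <- list(records)
  if (leader_nt < 0 || trailer_nt < 0) {
    abort_validation("leader_nt and trailer_nt must be >= 0")
  }
  if (!nrow(features)) abort_validation("no rRNA features supplied")
  if (any(!nzchar(features$operon_id))) {
    abort_validation("features must carry operon_id (see extract_rrna_features)")
  }
  seqs <- setNames(lapply(records, `[[`, "sequence"),
                   vapply(records, `[[`, "", "replicon_id"))
  rows <- list()
  for (op in unique(features$operon_id)) {
    g <- features[features$operon_id == op, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    strand <- g$strand[1]
    rep_id <- g$replicon_id[1]
    rep_len <- nchar(seqs[[rep_id]])
    # genomic-coordinate intervals: upstream flank, spacers, downstream flank
    iv <- list()
    five_nt <- if (strand == "+") leader_nt else trailer_nt
    three_nt <- if (strand == "+") trailer_nt else leader_nt
    if (five_nt > 0) {
      iv[[length(iv) + 1L]] <- c(g$start[1] - five_nt, g$start[1] - 1L)
    }
    if (nrow(g) > 1L) {
      for (i in seq_len(nrow(g) - 1L)) {
        iv[[length(iv) + 1L]] <- c(g$end[i] + 1L, g$start[i + 1L] - 1L)
      }
    }
    if (three_nt > 0) {
      iv[[length(iv) + 1L]] <- c(g$end[nrow(g)] + 1L, g$end[nrow(g)] + three_nt)
    }
    k <- 0L
    for (span in iv) {
      s <- max(span[1], 1L); e <- min(span[2], rep_len)
      if (e < s) next
      k <- k + 1L
      slice <- substr(seqs[[rep_id]], s, e)
      if (strand == "-") slice <- revcomp(slice)
      rows[[length(rows) + 1L]] <- rrna_features_frame(
        feature_id = sprintf("%s_pre%d", op, k), rna_type = "pre-rRNA",
        sequence = slice, replicon_id = rep_id, start = as.integer(s),
        end = as.integer(e), strand = strand, operon_id = op)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    rrna_features_frame(feature_id = character(0), rna_type = character(0),
                        sequence = character(0), replicon_id = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), operon_id = character(0))
  rownames(out) <- NULL
  class(out) <- c("rrna_features", "data.frame")
  out
}
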