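# Read classification against rRNA annotations and the mapped-read
# percentage accounting used to quality-control depletion experiments.

.READ_CLASSES <- c("5S", "16S", "23S", "pre-rRNA", "other")

#' Construct depletion counts directly
#'
#' For feeding published accounting rows (mapped totals and per-class rRNA
#' counts) straight into [rrna_fraction()] without read-level data.
#'
#' @param per_class named counts for any of
#'   `5S`, `16S`, `23S`, `pre-rRNA`; missing classes count 0. `other` is
#'   inferred as the remainder to `mapped_total`.
#' @param mapped_total total reads mapped on the genome.
#' @return an object of class `depletion_counts`.
#' @export
#' @examples
#' depletion_counts(c(`5S` = 119, `16S` = 1744649, `23S` = 1507768),
#'                  mapped_total = 3310864)
depletion_counts <- function(per_class, mapped_total) {
  pc <- setNames(numeric(length(.READ_CLASSES)), .READ_CLASSES)
  if (length(per_class)) {
    bad <- setdiff(names(per_class), .READ_CLASSES)
    if (length(bad)) abort_validation("unknown read class: %s", paste(bad, collapse = ","))
    pc[names(per_class)] <- as.numeric(per_class)
  }
  if (any(pc < 0) || mapped_total < 0) {
    abort_validation("depletion_counts: counts must be >= 0")
  }
  assigned <- sum(pc[setdiff(.READ_CLASSES, "other")]) + pc["other"]
  if (pc["other"] == 0) {
    rest <- mapped_total - sum(pc[setdiff(.READ_CLASSES, "other")])
    if (rest < 0) abort_validation("depletion_counts: class counts exceed mapped_total")
    pc["other"] <- rest
  } else if (abs(assigned - mapped_total) > 0.5) {
    abort_validation("depletion_counts: class counts do not sum to mapped_total")
  }
  structure(list(mapped_total = mapped_total, per_class = pc,
                 subtotal_rrna = unname(pc["5S"] + pc["16S"] + pc["23S"])),
            class = "depletion_counts")
}

#' @export
print.depletion_counts <- function(x, ...) {
  cat(sprintf("<depletion_counts> %s mapped; rRNA subtotal %s\n",
              format(x$mapped_total, big.mark = ","),
              format(x$subtotal_rrna, big.mark = ",")))
  invisible(x)
}

#' Classify mapped reads against rRNA annotations
#'
#' Each read is assigned to the labelled class interval with which it shares
#' the largest overlap (at least 1 nt; ties go to the class interval with
#' the smaller start); reads overlapping no class interval are `other`.
#' Strand is ignored.
#'
#' @param reads data.frame of read intervals (`read_id`, `replicon_id`,
#'   `start`, `end`), e.g. from [read_sam_intervals()] or
#'   [read_bed_intervals()].
#' @param classes labelled intervals: an `rrna_features` data.frame or any
#'   data.frame with `replicon_id`, `start`, `end` and a class label column
#'   (`rna_type` or `class`).
#' @return an object of class `depletion_counts`.
#' @export
classify_reads <- function(reads, classes) {
  if (is.null(reads) || nrow(reads) == 0L) {
    abort_validation("classify_reads: empty read set")
  }
  lab <- if ("rna_type" %in% names(classes)) classes$rna_type else classes$class
  if (is.null(lab)) abort_validation("classify_reads: class intervals need rna_type/class labels")
  if (!all(lab %in% setdiff(.READ_CLASSES, "other"))) {
    abort_validation("classify_reads: class labels must be 5S/16S/23S/pre-rRNA")
  }
  if (any(reads$start > reads$end)) abort_validation("classify_reads: read with start > end")

  rgr <- GenomicRanges::GRanges(reads$replicon_id,
                                IRanges::IRanges(reads$start, reads$end))
  cgr <- GenomicRanges::GRanges(classes$replicon_id,
                                IRanges::IRanges(classes$start, classes$end))
  ov <- GenomicRanges::findOverlaps(rgr, cgr, minoverlap = 1L)
  assigned <- rep("other", nrow(reads))
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    w <- BiocGenerics::width(IRanges::pintersect(IRanges::ranges(rgr)[qh],
                                                 IRanges::ranges(cgr)[sh]))
    # per read: widest overlap, tie -> interval with smaller start
    ord <- order(qh, -w, classes$start[sh], sh)
    first <- !duplicated(qh[ord])
    assigned[qh[ord][first]] <- lab[sh[ord][first]]
  }
  tab <- table(factor(assigned, levels = .READ_CLASSES))
  depletion_counts(as.numeric(tab[setdiff(.READ_CLASSES, "other")]) |>
                     setNames(setdiff(.READ_CLASSES, "other")),
                   mapped_total = nrow(reads))
}

#' rRNA fraction report
#'
#' The mapped-read accounting used for depletion quality control:
#' `pct_rrna = 100 * (5S + 16S + 23S) / mapped_total` (pre-rRNA reported as
#' its own category, outside the rRNA subtotal). Reported percentages are
#' rounded to 2 decimals, half away from zero; unrounded values are
#' retained.
#'
#' @param counts a `depletion_counts` object.
#' @return list with `mapped_total`, `per_class`, `subtotal_rrna`,
#'   `pct_rrna`, `pct_per_class` (rounded) and `pct_rrna_raw`,
#'   `pct_per_class_raw`.
#' @export
#' @examples
#' rrna_fraction(depletion_counts(
#'   c(`5S` = 119, `16S` = 1744649, `23S` = 1507768), 3310864))$pct_rrna
rrna_fraction <- function(counts) {
  stopifnot(inherits(counts, "depletion_counts"))
  if (counts$mapped_total <= 0) {
    abort_validation("rrna_fraction: mapped_total must be > 0")
  }
  raw <- 100 * counts$subtotal_rrna / counts$mapped_total
  raw_pc <- 100 * counts$per_class / counts$mapped_total
  list(mapped_total = counts$mapped_total,
       per_class = counts$per_class,
       subtotal_rrna = counts$subtotal_rrna,
       pct_rrna = round_half_away(raw, 2L),
       pct_per_class = round_half_away(raw_pc, 2L),
       pct_rrna_raw = raw,
       pct_per_class_raw = raw_pc)
}

#' Read mapped-read intervals from a SAM file
#'
#' Parses alignment lines of a text SAM file; only primary, mapped
#' alignments are kept (FLAG bits 0x4, 0x100, 0x800 excluded) so each read
#' is counted once. The reference footprint is POS plus the
#' reference-consuming CIGAR length (M/D/N/=/X).
#'
#' @param path SAM file path.
#' @return data.frame `read_id`, `replicon_id`, `start`, `end`, `strand`.
#' @export
read_sam_intervals <- function(path) {
  if (!file.exists(path)) abort_io("cannot read SAM file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) abort_parse("SAM file has no alignment lines: %s", path)
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(f) < 11L
  if (any(bad)) abort_parse("malformed SAM line %d in %s", which(bad)[1], path)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  keep <- bitwAnd(flag, 0x4L) == 0L & bitwAnd(flag, 0x100L) == 0L &
    bitwAnd(flag, 0x800L) == 0L & rname != "*"
  if (!any(keep)) abort_validation("SAM file contains no primary mapped reads: %s", path)
  ref_len <- vapply(cigar[keep], cigar_reference_width, integer(1), USE.NAMES = FALSE)
  data.frame(read_id = vapply(f, `[[`, "", 1L)[keep],
             replicon_id = rname[keep],
             start = pos[keep],
             end = pos[keep] + ref_len - 1L,
             strand = ifelse(bitwAnd(flag[keep], 0x10L) != 0L, "-", "+"),
             stringsAsFactors = FALSE)
}

cigar_reference_width <- function(cigar) {
  if (cigar == "*") return(1L)
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cigar)) {
    abort_parse("malformed CIGAR string: %s", cigar)
  }
  n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^\\d+", "", ops)
  w <- sum(n[op %in% c("M", "D", "N", "=", "X")])
  max(w, 1L)
}

#' Read read intervals from a BED file
#'
#' @param path BED file path (0-based half-open; converted to 1-based
#'   inclusive).
#' @return data.frame `read_id`, `replicon_id`, `start`, `end`, `strand`.
#' @export
read_bed_intervals <- function(path) {
  if (!file.exists(path)) abort_io("cannot read BED file: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) abort_parse("malformed BED '%s': %s",
                                                 path, conditionMessage(e)))
  if (!length(gr)) abort_parse("BED file has no intervals: %s", path)
  nm <- if (!is.null(gr$name)) gr$name else sprintf("read_%06d", seq_along(gr))
  data.frame(read_id = nm,
             replicon_id = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             strand = as.character(BiocGenerics::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Published depletion accounting rows
#'
#' Mapped-read accounting rows (total mapped reads and per-class rRNA read
#' counts with the percentage as printed) from published bacterial
#' rRNA-depletion experiments across seven species and three library types,
#' bundled as a plain-text fixture. `known_discrepancy` flags rows whose
#' printed percentage is arithmetically inconsistent with its own count
#' columns (by exactly +0.01).
#'
#' @return data.frame with columns `organism`, `method`, `note`,
#'   `mapped_reads`, `s5`, `s16`, `s23`, `subtotal`, `pct_printed`,
#'   `known_discrepancy`.
#' @export
depletion_table_examples <- function() {
  path <- system.file("extdata", "depletion_read_accounting.csv",
                      package = "ribodesign")
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
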