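# Probe set serialization: FASTA + CSV (+ optional BED of binding sites).

#' Write probe design outputs
#'
#' FASTA (70-column wrapped) carries the synthesized oligo sequences; the
#' CSV carries per-probe metadata (`name, rna_type, template_id, start, end,
#' length, tm_C, below_threshold, length_adjusted, three_prime_block`, Tm
#' rounded to 0.01 C). Optionally a BED6 file of probe binding sites lifted
#' to genomic coordinates (0-based half-open; score = Tm x 100 clipped to
#' 0-1000; strand = strand of the targeted gene copy) is written when
#' `features` supplies genomic provenance — one BED line per gene copy a
#' probe's template derives from.
#'
#' @param probes a non-empty `probe_set`.
#' @param fasta_path,csv_path output paths.
#' @param bed_path optional BED output path.
#' @param features optional `rrna_features` giving genomic provenance for
#'   the BED lift (matched to probes via `template_id`/`rna_type` or
#'   `feature_id`).
#' @param config optional named character/list echoed as `# key=value`
#'   comment lines at the top of the CSV.
#' @return invisibly, the paths written.
#' @export
write_probe_outputs <- function(probes, fasta_path, csv_path, bed_path = NULL,
                                features = NULL, config = NULL) {
  if (!inherits(probes, "probe_set") || nrow(probes) == 0L) {
    abort_validation("write_probe_outputs: probe set is empty")
  }
  dna <- Biostrings::DNAStringSet(probes$sequence)
  names(dna) <- probes$name
  ok <- tryCatch({
    Biostrings::writeXStringSet(dna, fasta_path, width = 70L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io("cannot write FASTA: %s", fasta_path)

  meta <- data.frame(name = probes$name, rna_type = probes$rna_type,
                     template_id = probes$template_id, start = probes$start,
                     end = probes$end, length = probes$length,
                     tm_C = round_half_away(probes$tm_C, 2L),
                     below_threshold = probes$below_threshold,
                     length_adjusted = probes$length_adjusted,
                     three_prime_block = probes$three_prime_block,
                     stringsAsFactors = FALSE)
  con <- tryCatch(file(csv_path, "w"), error = function(e)
    abort_io("cannot write CSV: %s", csv_path))
  if (!is.null(config) && length(config)) {
    writeLines(sprintf("# %s=%s", names(config),
                       vapply(config, function(v) paste(format(v), collapse = ","), "")),
               con)
  }
  write.csv(meta, con, row.names = FALSE, quote = FALSE)
  close(con)

  if (!is.null(bed_path)) {
    gr <- probe_binding_sites(probes, features)
    if (length(gr)) rtracklayer::export(gr, bed_path, format = "BED")
  }
  invisible(c(fasta = fasta_path, csv = csv_path,
              bed = if (is.null(bed_path)) NA_character_ else bed_path))
}

#' Genomic binding sites of a probe set
#'
#' Lifts template coordinates of each probe onto every gene copy its
#' template derives from: position p of a plus-strand copy starting at
#' genomic g maps to g + p - 1; on minus-strand copies the footprint is
#' mirrored from the copy's end.
#'
#' @param probes a `probe_set`.
#' @param features `rrna_features` with genomic coordinates.
#' @return a `GRanges` with `name` and `score` (Tm x 100, clipped to
#'   0-1000) columns.
#' @export
probe_binding_sites <- function(probes, features) {
  if (is.null(features) || nrow(features) == 0L) {
    abort_validation("probe_binding_sites: genomic provenance (features) required")
  }
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    fid <- probes$template_id[i]
    hit <- features[features$feature_id == fid |
                      features$rna_type == probes$rna_type[i], , drop = FALSE]
    for (j in seq_len(nrow(hit))) {
      if (probes$end[i] > nchar(hit$sequence[j])) next
      if (hit$strand[j] == "+") {
        gs <- hit$start[j] + probes$start[i] - 1L
        ge <- hit$start[j] + probes$end[i] - 1L
      } else {
        ge <- hit$end[j] - probes$start[i] + 1L
        gs <- hit$end[j] - probes$end[i] + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = hit$replicon_id[j], start = gs, end = ge,
        strand = hit$strand[j], name = probes$name[i],
        score = min(max(as.integer(round(probes$tm_C[i] * 100)), 0L), 1000L),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(GenomicRanges::GRanges())
  }
  df <- do.call(rbind, rows)
  GenomicRanges::GRanges(df$seqnames,
                         IRanges::IRanges(df$start, df$end),
                         strand = df$strand, name = df$name, score = df$score)
}

#' Read a probe set back from FASTA + CSV
#'
#' Inverse of [write_probe_outputs()]: sequences come from the FASTA,
#' metadata from the CSV (comment lines starting with `#` are ignored).
#'
#' @param fasta_path,csv_path paths written by [write_probe_outputs()].
#' @return a `probe_set`.
#' @export
read_probe_set <- function(fasta_path, csv_path) {
  if (!file.exists(fasta_path)) abort_io("missing FASTA: %s", fasta_path)
  if (!file.exists(csv_path)) abort_io("missing CSV: %s", csv_path)
  dna <- Biostrings::readDNAStringSet(fasta_path)
  meta <- read.csv(csv_path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "rna_type", "template_id", "start", "end", "length",
            "tm_C", "below_threshold", "length_adjusted", "three_prime_block")
  if (!all(need %in% names(meta))) {
    abort_parse("probe CSV '%s' lacks required columns", csv_path)
  }
  idx <- match(meta$name, sub("\\s.*$", "", names(dna)))
  if (anyNA(idx)) abort_parse("probe CSV/FASTA name mismatch in %s", csv_path)
  meta$sequence <- as.character(dna)[idx]
  meta$three_prime_block <- as.character(meta$three_prime_block)
  meta <- meta[, c("name", "sequence", "rna_type", "template_id", "start",
                   "end", "length", "tm_C", "below_threshold",
                   "length_adjusted", "three_prime_block")]
  meta <- meta[, c(1, 2, 4, 3, 5:11)]  # name, sequence, template_id, rna_type, ...
  new_probe_set(meta, NULL, list(source = csv_path))
}
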