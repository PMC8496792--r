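# Minimal GenBank flat-file reader/writer.
#
# Supports what annotated bacterial replicons need here: LOCUS, FEATURES with
# plain or complement() spans and quoted/unquoted qualifiers (possibly
# continued over lines), and the ORIGIN sequence block. join() and remote
# locations are rejected as unsupported rather than misread.

read_genbank_file <- function(path) {
  if (!file.exists(path)) abort_io("cannot read GenBank file: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort_parse("empty GenBank file: %s", path)
  ends <- grep("^//\\s*$", lines)
  if (length(ends) == 0L) {
    abort_parse("truncated GenBank file (no record terminator '//'): %s", path)
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  records <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    chunk <- lines[starts[i]:(ends[i] - 1L)]
    chunk <- chunk[nzchar(trimws(chunk)) | seq_along(chunk) > 1L]
    records[[i]] <- parse_genbank_record(chunk, path)
  }
  records
}

parse_genbank_record <- function(lines, path) {
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1L) {
    abort_parse("GenBank record without a single LOCUS line in %s", path)
  }
  locus_fields <- strsplit(trimws(lines[locus_i]), "\\s+")[[1]]
  if (length(locus_fields) < 2L) abort_parse("malformed LOCUS line in %s", path)
  replicon_id <- locus_fields[2]

  # ACCESSION/VERSION override LOCUS name when present (matches common usage).
  ver_i <- grep("^VERSION\\s+\\S", lines)
  if (length(ver_i) >= 1L) {
    vf <- strsplit(trimws(lines[ver_i[1]]), "\\s+")[[1]]
    if (length(vf) >= 2L) replicon_id <- vf[2]
  }

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) != 1L) {
    abort_parse("GenBank record '%s' has no ORIGIN block (%s)", replicon_id, path)
  }
  sequence <- parse_origin_block(lines[(orig_i + 1L):length(lines)], replicon_id)

  features <- empty_feature_table()
  if (length(feat_i) == 1L && feat_i + 1L < orig_i) {
    features <- parse_feature_block(lines[(feat_i + 1L):(orig_i - 1L)], replicon_id)
  }
  bad <- features$start < 1L | features$end > nchar(sequence) | features$start > features$end
  if (any(bad)) {
    abort_parse("feature interval outside sequence bounds in record '%s'", replicon_id)
  }
  genome_record(replicon_id, sequence, features)
}

parse_origin_block <- function(lines, replicon_id) {
  seq <- gsub("[^A-Za-z]", "", paste(lines, collapse = ""))
  if (!nzchar(seq)) abort_parse("empty ORIGIN block in record '%s'", replicon_id)
  seq <- toupper(seq)
  check_dna_alphabet(seq, sprintf("record '%s' sequence", replicon_id))
  seq
}

empty_feature_table <- function() {
  data.frame(kind = character(0), start = integer(0), end = integer(0),
             strand = character(0), product = character(0),
             stringsAsFactors = FALSE)
}

parse_feature_block <- function(lines, replicon_id) {
  # A feature header has its key at column 6; qualifiers are indented further.
  is_key <- grepl("^\\s{5}\\S", lines)
  key_idx <- which(is_key)
  feats <- list()
  for (j in seq_along(key_idx)) {
    from <- key_idx[j]
    to <- if (j < length(key_idx)) key_idx[j + 1L] - 1L else length(lines)
    header <- trimws(lines[from])
    parts <- strsplit(header, "\\s+")[[1]]
    kind <- parts[1]
    loc <- paste(parts[-1], collapse = "")
    body <- lines[seq(from, to)]
    # location may continue onto lines before the first qualifier
    qual_start <- grep("^\\s+/", body)
    loc_extra <- if (length(qual_start)) {
      body[setdiff(seq_along(body)[-1], seq(min(qual_start), length(body)))]
    } else body[-1]
    if (length(loc_extra)) loc <- paste0(loc, paste(trimws(loc_extra), collapse = ""))
    span <- parse_genbank_location(loc, replicon_id, kind)
    product <- parse_qualifier(body, "product")
    feats[[length(feats) + 1L]] <- data.frame(
      kind = kind, start = span$start, end = span$end, strand = span$strand,
      product = product, stringsAsFactors = FALSE)
  }
  if (!length(feats)) return(empty_feature_table())
  do.call(rbind, feats)
}

parse_genbank_location <- function(loc, replicon_id, kind) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("join|order|:", loc)) {
    abort_parse("unsupported compound location '%s' (%s feature in record '%s')",
                loc, kind, replicon_id)
  }
  loc <- gsub("[<>]", "", loc)
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) == 3L) {
    return(list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand))
  }
  if (grepl("^\\d+$", loc)) {
    p <- as.integer(loc)
    return(list(start = p, end = p, strand = strand))
  }
  abort_parse("malformed location '%s' (%s feature in record '%s')",
              loc, kind, replicon_id)
}

parse_qualifier <- function(body, name) {
  pat <- sprintf("^\\s+/%s=", name)
  i <- grep(pat, body)
  if (!length(i)) return("")
  val <- sub(pat, "", body[i[1]])
  if (startsWith(val, "\"")) {
    # collect continuation lines until the closing quote
    buf <- val
    k <- i[1]
    while (!grepl("\"\\s*$", buf) && k < length(body)) {
      k <- k + 1L
      if (grepl("^\\s+/", body[k])) break
      buf <- paste(buf, trimws(body[k]))
    }
    val <- gsub("^\"|\"$", "", trimws(buf))
  }
  val
}

#' Write a genome record as a GenBank flat file
#'
#' Emits LOCUS, a FEATURES table (source plus any annotated features with
#' their product qualifiers) and the ORIGIN sequence block. Round-trips
#' through [read_annotated_genome()].
#'
#' @param record a `genome_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "genome_record"))
  con <- tryCatch(file(path, "w"), error = function(e)
    abort_io("cannot write GenBank file: %s", path))
  on.exit(close(con))
  n <- nchar(record$sequence)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT",
                     record$replicon_id, n), con)
  writeLines(sprintf("DEFINITION  synthetic record %s.", record$replicon_id), con)
  writeLines(sprintf("VERSION     %s", record$replicon_id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  f <- record$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      loc <- sprintf("%d..%d", f$start[i], f$end[i])
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", f$kind[i], loc), con)
      if (nzchar(f$product[i])) {
        writeLines(sprintf("                     /product=\"%s\"", f$product[i]), con)
      }
    }
  }
  writeLines("ORIGIN", con)
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    block <- substr(record$sequence, s, min(s + 59L, n))
    tens <- substring(block, seq(1, nchar(block), 10), pmin(seq(10, nchar(block) + 9, 10), nchar(block)))
    writeLines(sprintf("%9d %s", s, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}
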