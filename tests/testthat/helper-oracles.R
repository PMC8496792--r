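# Independent oracles and small fixture builders used across the suite.

# Character vectors as integer codes for fast comparison.
dna_int <- function(s) utf8ToInt(s)

# Naive diagonal scan: every maximal exact shared run (>= min_run) between a
# query string and a subject string, independent of the seed-and-extend
# implementation. Runs are maximal along each alignment diagonal by
# construction of rle().
naive_shared_runs <- function(qry, subj, min_run) {
  q <- dna_int(qry); s <- dna_int(subj)
  m <- length(q); n <- length(s)
  out <- list()
  for (d in (1L - m):(n - 1L)) {           # d = subject_pos - query_pos
    qlo <- max(1L, 1L - d); qhi <- min(m, n - d)
    if (qhi - qlo + 1L < min_run) next
    eq <- q[qlo:qhi] == s[(qlo + d):(qhi + d)]
    r <- rle(eq)
    ends_q <- qlo - 1L + cumsum(r$lengths)
    starts_q <- ends_q - r$lengths + 1L
    keep <- r$values & r$lengths >= min_run
    for (i in which(keep)) {
      out[[length(out) + 1L]] <- c(starts_q[i] + d, ends_q[i] + d)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  u <- unique(do.call(rbind, out))
  data.frame(start = u[, 1], end = u[, 2])
}

# Full naive counterpart of offtarget_scan (same exclusion / strand /
# containment semantics, quadratic core).
naive_offtarget_scan <- function(probes, record, exclude = NULL, min_run = 15L) {
  hits <- list()
  for (p in seq_len(nrow(probes))) {
    for (strand in c("+", "-")) {
      qry <- if (strand == "+") revcomp(probes$sequence[p]) else probes$sequence[p]
      runs <- naive_shared_runs(qry, record$sequence, min_run)
      if (!nrow(runs)) next
      if (!is.null(exclude) && nrow(exclude)) {
        ex <- exclude[exclude$replicon_id == record$replicon_id, , drop = FALSE]
        if (nrow(ex)) {
          ov <- vapply(seq_len(nrow(runs)), function(i) {
            any(runs$start[i] <= ex$end & runs$end[i] >= ex$start)
          }, logical(1))
          runs <- runs[!ov, , drop = FALSE]
        }
      }
      if (!nrow(runs)) next
      hits[[length(hits) + 1L]] <- data.frame(
        probe_name = probes$name[p], subject_id = record$replicon_id,
        subject_strand = strand, run_start = runs$start, run_end = runs$end,
        run_length = runs$end - runs$start + 1L, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(probe_name = character(0), subject_id = character(0),
               subject_strand = character(0), run_start = integer(0),
               run_end = integer(0), run_length = integer(0),
               stringsAsFactors = FALSE)
  # same containment rule as the implementation
  out <- ribodesign:::drop_contained_runs(out)
  rownames(out) <- NULL
  out
}

# Brute-force full-length mapping with <= max_mm substitutions (no indels).
naive_best_placement <- function(probe_seq, target_seq, max_mm) {
  pat <- dna_int(revcomp(probe_seq))
  tgt <- dna_int(target_seq)
  m <- length(pat); n <- length(tgt)
  if (m > n) return(NULL)
  best <- NULL
  for (s in seq_len(n - m + 1L)) {
    mm <- sum(pat != tgt[s:(s + m - 1L)])
    if (mm <= max_mm && (is.null(best) || mm < best$mm)) {
      best <- list(start = s, mm = mm)
      if (mm == 0L) break
    }
  }
  best
}

# rrna_features frame from bare sequences (templates with no genomic context)
features_from_seqs <- function(seqs, rna_type = "16S", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("%s_%d", rna_type, seq_along(seqs))
  rna_type <- rep_len(rna_type, length(seqs))
  ids <- rep_len(ids, length(seqs))
  df <- data.frame(feature_id = ids, rna_type = rna_type, sequence = seqs,
                   replicon_id = ids, start = rep(1L, length(seqs)),
                   end = nchar(seqs), strand = rep("+", length(seqs)),
                   operon_id = rep("", length(seqs)), stringsAsFactors = FALSE)
  class(df) <- c("rrna_features", "data.frame")
  df
}

# a probe_set directly from oligo sequences (reverse complements of windows)
probe_set_from_seqs <- function(seqs, template_id = "T") {
  df <- data.frame(name = sprintf("p%03d", seq_along(seqs)), sequence = seqs,
                   template_id = template_id, rna_type = "16S",
                   start = NA_integer_, end = NA_integer_,
                   length = nchar(seqs), tm_C = NA_real_,
                   below_threshold = FALSE, length_adjusted = FALSE,
                   three_prime_block = "none", stringsAsFactors = FALSE)
  ribodesign:::new_probe_set(df, NULL, list())
}

random_dna_seed <- function(n, gc = 0.5, seed = 1L) {
  ribodesign:::with_seed(seed, ribodesign:::random_dna(n, gc))
}

# deterministic high-GC template on which every 32-mer melts above threshold
hot_template <- function(len = 1000L, seed = 42L) {
  random_dna_seed(len, gc = 0.62, seed = seed)
}
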