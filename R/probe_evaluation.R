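# Probe set evaluation: placement on targets, coverage gaps, cross-species
# transfer, and off-target consecutive-match screening.

#' Map probes onto rRNA targets
#'
#' Full-length, indel-free alignment of each probe's reverse complement
#' against the sense strand of each target, allowing up to `max_mismatches`
#' substitutions. One best placement (fewest mismatches; ties to the
#' smallest start) is reported per (probe, target) pair.
#'
#' @param probes a `probe_set`.
#' @param targets an `rrna_features` data.frame.
#' @param max_mismatches maximum substitutions allowed (>= 0).
#' @return data.frame with columns `probe_name`, `target_id`, `start`,
#'   `end`, `mismatches`.
#' @export
map_probes <- function(probes, targets, max_mismatches = 0L) {
  if (is.null(targets) || nrow(targets) == 0L) {
    abort_validation("map_probes: no targets supplied")
  }
  if (max_mismatches < 0L) abort_validation("map_probes: max_mismatches must be >= 0")
  pat <- revcomp(probes$sequence)
  rows <- list()
  for (t in seq_len(nrow(targets))) {
    subj <- Biostrings::DNAString(targets$sequence[t])
    for (p in seq_along(pat)) {
      if (nchar(pat[p]) > length(subj)) next
      m <- Biostrings::matchPattern(pat[p], subj,
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE)
      if (length(m) == 0L) next
      starts <- BiocGenerics::start(m)
      mm <- vapply(seq_along(m), function(k) {
        sum(strsplit(as.character(m[[k]]), "")[[1]] !=
              strsplit(pat[p], "")[[1]])
      }, numeric(1))
      best <- order(mm, starts)[1]
      rows[[length(rows) + 1L]] <- data.frame(
        probe_name = probes$name[p], target_id = targets$feature_id[t],
        start = starts[best], end = starts[best] + nchar(pat[p]) - 1L,
        mismatches = as.integer(mm[best]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(probe_name = character(0), target_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coverage report for one target
#'
#' Gap structure of a target under a set of probe placements: maximal
#' disjoint uncovered intervals over the full template (head and tail
#' included), covered nucleotide count, probe density per kb, and how many
#' placed probes were designed below the Tm threshold.
#'
#' @param placements data.frame from [map_probes()], restricted to one target.
#' @param target one row of an `rrna_features` data.frame (or a list with
#'   `feature_id` and `sequence`).
#' @param probes optional `probe_set` used to count below-threshold probes
#'   among those placed.
#' @return an object of class `coverage_report`.
#' @export
coverage_report <- function(placements, target, probes = NULL) {
  target_id <- target$feature_id[1]
  tlen <- nchar(target$sequence[1])
  placements <- placements[placements$target_id == target_id, , drop = FALSE]
  ir <- IRanges::IRanges(placements$start, placements$end)
  red <- IRanges::reduce(ir)
  gap_ir <- IRanges::gaps(red, start = 1L, end = tlen)
  gaps <- data.frame(start = BiocGenerics::start(gap_ir),
                     end = BiocGenerics::end(gap_ir),
                     length = BiocGenerics::width(gap_ir))
  n_below <- if (!is.null(probes)) {
    sum(probes$below_threshold[probes$name %in% placements$probe_name])
  } else NA_integer_
  structure(list(target_id = target_id,
                 covered_nt = sum(BiocGenerics::width(red)),
                 gaps = gaps,
                 max_gap_nt = if (nrow(gaps)) max(gaps$length) else 0L,
                 probes_per_kb = 1000 * nrow(placements) / tlen,
                 n_below_threshold = n_below,
                 target_length = tlen),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %s: %d/%d nt covered, max gap %d nt, %.1f probes/kb\n",
              x$target_id, x$covered_nt, x$target_length, x$max_gap_nt,
              x$probes_per_kb))
  invisible(x)
}

#' Cross-species probe transfer assessment
#'
#' A probe transfers ("matches") when it has at least one full-length
#' placement at `max_mismatches` or fewer on any target rRNA. Coverage of
#' each target is then computed from matched placements only.
#'
#' @param probes a `probe_set`.
#' @param target_features `rrna_features` of the other species.
#' @param max_mismatches transfer criterion (default 1 substitution).
#' @return an object of class `transfer_report` with `n_probes`, `matched`
#'   (data.frame probe_name/best_mismatches), `unmatched` (names), and
#'   `coverage` (list of `coverage_report`).
#' @export
transfer_assessment <- function(probes, target_features, max_mismatches = 1L) {
  if (is.null(target_features) || nrow(target_features) == 0L) {
    abort_validation("transfer_assessment: no target rRNAs supplied")
  }
  pl <- map_probes(probes, target_features, max_mismatches)
  best <- if (nrow(pl)) {
    agg <- stats::aggregate(mismatches ~ probe_name, data = pl, FUN = min)
    names(agg) <- c("probe_name", "best_mismatches")
    agg
  } else data.frame(probe_name = character(0), best_mismatches = integer(0))
  unmatched <- setdiff(probes$name, best$probe_name)
  cov <- lapply(seq_len(nrow(target_features)), function(t) {
    coverage_report(pl, target_features[t, , drop = FALSE], probes)
  })
  names(cov) <- target_features$feature_id
  structure(list(n_probes = nrow(probes), matched = best,
                 unmatched = unmatched, coverage = cov,
                 max_mismatches = max_mismatches),
            class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat(sprintf("<transfer_report> %d of %d probes matched (<= %d mismatches)\n",
              nrow(x$matched), x$n_probes, x$max_mismatches))
  mg <- max(vapply(x$coverage, `[[`, numeric(1), "max_gap_nt"))
  cat(sprintf("  maximum coverage gap across targets: %d nt\n", as.integer(mg)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# off-target consecutive-match scan

#' Scan probes for off-target consecutive matches
#'
#' Finds every maximal exact shared run of `min_run` nt or longer between a
#' probe and the non-rRNA portion of subject genomes, on both subject
#' strands: a run on the `+` strand is a stretch where the probe's reverse
#' complement equals the plus-strand sequence (the probe would hybridize a
#' plus-strand transcript), and vice versa for `-`. Runs overlapping an
#' excluded interval (the rRNA loci themselves) are suppressed; runs whose
#' subject interval is contained in a longer reported run of the same probe
#' are dropped. Behaves as exact seed lookup of length `min_run` with
#' maximal extension.
#'
#' @param probes a `probe_set`.
#' @param subjects list of `genome_record` (or a single one).
#' @param exclude optional data.frame (`replicon_id`, `start`, `end`) or
#'   `rrna_features` of intervals to mask (1-based inclusive).
#' @param min_run minimum run length, nt (>= 8).
#' @param annotations optional data.frame (`replicon_id`, `start`, `end`,
#'   `gene`) used to fill `overlapping_gene`.
#' @return data.frame of hits: `probe_name`, `subject_id`, `subject_strand`,
#'   `run_start`, `run_end`, `run_length`, `overlapping_gene`.
#' @export
offtarget_scan <- function(probes, subjects, exclude = NULL, min_run = 15L,
                           annotations = NULL) {
  if (inherits(subjects, "genome_record")) subjects <- list(subjects)
  min_run <- as.integer(min_run)
  if (min_run < 8L) abort_validation("offtarget_scan: min_run must be >= 8")
  if (min_run > max(nchar(probes$sequence))) {
    abort_validation("offtarget_scan: min_run exceeds probe length")
  }
  hits <- list()
  for (s in subjects) {
    subj_chr <- s$sequence
    subj <- Biostrings::DNAString(subj_chr)
    excl <- NULL
    if (!is.null(exclude) && nrow(exclude) > 0L) {
      ex <- exclude[exclude$replicon_id == s$replicon_id, , drop = FALSE]
      if (nrow(ex)) excl <- IRanges::IRanges(ex$start, ex$end)
    }
    for (p in seq_len(nrow(probes))) {
      pseq <- probes$sequence[p]
      if (nchar(pseq) < min_run) next
      for (strand in c("+", "-")) {
        qry <- if (strand == "+") revcomp(pseq) else pseq
        runs <- shared_runs(qry, subj, subj_chr, min_run)
        if (!nrow(runs)) next
        if (!is.null(excl)) {
          rr <- IRanges::IRanges(runs$start, runs$end)
          keep <- IRanges::countOverlaps(rr, excl) == 0L
          runs <- runs[keep, , drop = FALSE]
          if (!nrow(runs)) next
        }
        hits[[length(hits) + 1L]] <- data.frame(
          probe_name = probes$name[p], subject_id = s$replicon_id,
          subject_strand = strand, run_start = runs$start,
          run_end = runs$end, run_length = runs$end - runs$start + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(probe_name = character(0), subject_id = character(0),
               subject_strand = character(0), run_start = integer(0),
               run_end = integer(0), run_length = integer(0),
               stringsAsFactors = FALSE)
  out <- drop_contained_runs(out)
  out$overlapping_gene <- character(nrow(out))
  if (!is.null(annotations) && nrow(out)) {
    for (i in seq_len(nrow(out))) {
      g <- annotations[annotations$replicon_id == out$subject_id[i] &
                         annotations$start <= out$run_end[i] &
                         annotations$end >= out$run_start[i], , drop = FALSE]
      if (nrow(g)) out$overlapping_gene[i] <- g$gene[order(g$start)][1]
    }
  }
  rownames(out) <- NULL
  out
}

# Maximal exact shared runs between query string and subject, as subject
# coordinates. Seeds of length min_run are located with matchPattern and
# extended maximally; duplicates collapse to unique maximal runs.
shared_runs <- function(qry, subj, subj_chr, min_run) {
  qlen <- nchar(qry)
  slen <- length(subj)
  if (qlen < min_run || slen < min_run) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  qb <- strsplit(qry, "", fixed = TRUE)[[1]]
  seeds <- substring(qry, seq_len(qlen - min_run + 1L),
                     seq_len(qlen - min_run + 1L) + min_run - 1L)
  found <- list()
  for (qpos in seq_along(seeds)) {
    seed <- seeds[qpos]
    if (!is_acgt(seed)) next
    m <- Biostrings::matchPattern(seed, subj)
    if (length(m) == 0L) next
    for (spos in BiocGenerics::start(m)) {
      # extend left
      qi <- qpos - 1L; si <- spos - 1L
      while (qi >= 1L && si >= 1L &&
             qb[qi] == substr(subj_chr, si, si)) {
        qi <- qi - 1L; si <- si - 1L
      }
      run_s <- si + 1L
      # extend right
      qj <- qpos + min_run; sj <- spos + min_run
      while (qj <= qlen && sj <= slen &&
             qb[qj] == substr(subj_chr, sj, sj)) {
        qj <- qj + 1L; sj <- sj + 1L
      }
      run_e <- sj - 1L
      found[[length(found) + 1L]] <- c(run_s, run_e)
    }
  }
  if (!length(found)) return(data.frame(start = integer(0), end = integer(0)))
  u <- unique(do.call(rbind, found))
  data.frame(start = u[, 1], end = u[, 2])
}

# Drop runs whose subject interval is strictly contained in another run of
# the same (probe, subject, strand); exact duplicates collapse to one.
drop_contained_runs <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- unique(hits)
  keep <- rep(TRUE, nrow(hits))
  key <- paste(hits$probe_name, hits$subject_id, hits$subject_strand)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    for (a in idx) {
      contained <- any(hits$run_start[idx] <= hits$run_start[a] &
                         hits$run_end[idx] >= hits$run_end[a] &
                         (hits$run_start[idx] < hits$run_start[a] |
                            hits$run_end[idx] > hits$run_end[a]))
      if (contained) keep[a] <- FALSE
    }
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$probe_name, out$subject_id, out$subject_strand, out$run_start), ,
      drop = FALSE]
}
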