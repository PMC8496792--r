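# Consensus templates and the Tm-thresholded tiled probe placement.

#' Probe design parameters
#'
#' Defaults follow the published tiling rule: 32-nt probes, first window at
#' template position 50, at most 50 uncovered nt between probes, an upstream
#' search space of 10 nt when a window melts below threshold, and a 68 C
#' melting-temperature threshold (3 C above the 65 C digestion reaction).
#'
#' @param probe_len default probe length, nt.
#' @param min_len,max_len bounds for length adjustment, nt.
#' @param tm_threshold_C melting-temperature threshold, degrees C.
#' @param max_gap_nt maximum number of template nt covered by no probe
#'   between consecutive probes.
#' @param search_space_nt how far upstream of a failing start to search.
#' @param head_offset template position of the first candidate window
#'   (1-based).
#' @param allow_length_adjust extend a below-threshold probe at its 3'
#'   (template-downstream) edge up to `max_len` until it passes.
#' @param thermo a [thermo_params()] object.
#' @return an object of class `design_params`.
#' @export
#' @examples
#' design_params(max_gap_nt = 8)  # dense tiling, ~one probe per 40 nt
design_params <- function(probe_len = 32L, min_len = 28L, max_len = 43L,
                          tm_threshold_C = 68, max_gap_nt = 50L,
                          search_space_nt = 10L, head_offset = 50L,
                          allow_length_adjust = FALSE,
                          thermo = thermo_params()) {
  probe_len <- as.integer(probe_len); min_len <- as.integer(min_len)
  max_len <- as.integer(max_len); max_gap_nt <- as.integer(max_gap_nt)
  search_space_nt <- as.integer(search_space_nt)
  head_offset <- as.integer(head_offset)
  if (!(min_len <= probe_len && probe_len <= max_len)) {
    abort_validation("design_params: need min_len <= probe_len <= max_len")
  }
  if (max_gap_nt < 0L || search_space_nt < 0L || head_offset < 1L) {
    abort_validation("design_params: max_gap_nt/search_space_nt >= 0 and head_offset >= 1 required")
  }
  if (!is.finite(tm_threshold_C) || tm_threshold_C <= 0) {
    abort_validation("design_params: tm_threshold_C must be > 0")
  }
  if (!inherits(thermo, "thermo_params")) thermo <- do.call(thermo_params, thermo)
  structure(list(probe_len = probe_len, min_len = min_len, max_len = max_len,
                 tm_threshold_C = tm_threshold_C, max_gap_nt = max_gap_nt,
                 search_space_nt = search_space_nt, head_offset = head_offset,
                 allow_length_adjust = isTRUE(allow_length_adjust),
                 thermo = thermo),
            class = "design_params")
}

new_probe_set <- function(probes, params, provenance = list()) {
  if (nrow(probes)) {
    probes <- probes[order(probes$template_id, probes$start), , drop = FALSE]
    rownames(probes) <- NULL
  }
  structure(probes, params = params, provenance = provenance,
            class = c("probe_set", "data.frame"))
}

probe_columns <- function() {
  data.frame(name = character(0), sequence = character(0),
             template_id = character(0), rna_type = character(0),
             start = integer(0), end = integer(0), length = integer(0),
             tm_C = numeric(0), below_threshold = logical(0),
             length_adjusted = logical(0), three_prime_block = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("<probe_set> %d probes on %d template(s)\n",
              nrow(x), length(unique(x$template_id))))
  if (nrow(x)) {
    cat(sprintf("  Tm %.2f-%.2f C, %d below threshold\n",
                min(x$tm_C), max(x$tm_C), sum(x$below_threshold)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# consensus

# Set-based k-mer distance (size of the symmetric difference of k-mer sets).
kmer_distance <- function(a, b, k = 8L) {
  ka <- unique(substring(a, seq_len(nchar(a) - k + 1L), seq_len(nchar(a) - k + 1L) + k - 1L))
  kb <- unique(substring(b, seq_len(nchar(b) - k + 1L), seq_len(nchar(b) - k + 1L) + k - 1L))
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Build a consensus template from rRNA gene copies
#'
#' Equal-length copies give a column-wise majority consensus with
#' per-position agreement (majority count over copy count); majority ties
#' are broken by the base of the lowest-index source copy. When lengths
#' differ, the medoid copy (minimal summed 8-mer distance to the others) is
#' used as the consensus backbone and agreement is computed over the
#' equal-length members only.
#'
#' @param features an `rrna_features` data.frame, all of one `rna_type`.
#' @param template_id identifier for the template (defaults to the rna_type).
#' @return an object of class `consensus_template` with fields
#'   `template_id`, `rna_type`, `sequence`, `agreement`, `n_copies`,
#'   `source_ids`, `note`.
#' @export
build_consensus <- function(features, template_id = NULL) {
  if (is.null(features) || nrow(features) == 0L) {
    abort_validation("build_consensus: no input sequences")
  }
  if (length(unique(features$rna_type)) != 1L) {
    abort_validation("build_consensus: mixed rna_type in input")
  }
  rna_type <- features$rna_type[1]
  if (is.null(template_id)) template_id <- rna_type
  seqs <- toupper(features$sequence)
  n <- length(seqs)
  lens <- nchar(seqs)
  note <- ""
  if (length(unique(lens)) == 1L) {
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    cons <- character(ncol(mat))
    agree <- numeric(ncol(mat))
    for (j in seq_len(ncol(mat))) {
      tab <- table(mat[, j])
      best <- max(tab)
      winners <- names(tab)[tab == best]
      if (length(winners) > 1L) {
        # tie: base of the lowest-index source sequence among the winners
        first_hit <- which(mat[, j] %in% winners)[1]
        cons[j] <- mat[first_hit, j]
      } else cons[j] <- winners
      agree[j] <- best / n
    }
    sequence <- paste(cons, collapse = "")
  } else {
    dist_sum <- vapply(seq_len(n), function(i) {
      sum(vapply(seq_len(n)[-i], function(j) kmer_distance(seqs[i], seqs[j]), numeric(1)))
    }, numeric(1))
    med <- which.min(dist_sum)  # ties: lowest index
    sequence <- seqs[med]
    same <- which(lens == lens[med])
    mat <- do.call(rbind, strsplit(seqs[same], "", fixed = TRUE))
    agree <- vapply(seq_len(ncol(mat)), function(j) {
      sum(mat[, j] == substr(sequence, j, j)) / length(same)
    }, numeric(1))
    note <- "medoid"
  }
  structure(list(template_id = template_id, rna_type = rna_type,
                 sequence = sequence, agreement = agree, n_copies = n,
                 source_ids = features$feature_id, note = note),
            class = "consensus_template")
}

#' @export
print.consensus_template <- function(x, ...) {
  cat(sprintf("<consensus_template> %s (%s): %d nt from %d copies%s\n",
              x$template_id, x$rna_type, nchar(x$sequence), x$n_copies,
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# stepwise tiling

#' Design probes on one template
#'
#' Stepwise Tm-thresholded tiling. The first candidate window starts at
#' `head_offset`; each subsequent candidate start is
#' `previous_end + max_gap_nt + 1`. Candidate positions are evaluated from
#' the nominal start upstream (at most `search_space_nt` positions, never
#' into the previous probe) and the first position melting at or above the
#' threshold is accepted; if none passes, the evaluated position with the
#' highest Tm is recorded with `below_threshold = TRUE` (ties to the most
#' downstream position). With `allow_length_adjust`, a below-threshold
#' winner is extended 1 nt at a time at its template-downstream edge up to
#' `max_len`; if the threshold is never reached the unextended window is
#' kept. Windows overrunning the template are clamped to its end, and design
#' stops when a clamped window would overlap the previous probe.
#'
#' @param template a `consensus_template` (or a single DNA string).
#' @param params a [design_params()] object.
#' @return a `probe_set` (possibly empty, with a warning, when the template
#'   is shorter than the first window).
#' @export
#' @examples
#' tpl <- build_consensus(data.frame(feature_id = "x", rna_type = "16S",
#'   sequence = paste(rep("ACGGCGCATGCGGAAGCTTGCCAGGTCCGGCAT", 40), collapse = "")))
#' design_probes(tpl)
design_probes <- function(template, params = design_params()) {
  if (is.character(template)) {
    template <- structure(list(template_id = "template", rna_type = "16S",
                               sequence = toupper(template),
                               agreement = rep(1, nchar(template)),
                               n_copies = 1L, source_ids = "template",
                               note = ""),
                          class = "consensus_template")
  }
  stopifnot(inherits(template, "consensus_template"),
            inherits(params, "design_params"))
  tseq <- template$sequence
  tlen <- nchar(tseq)
  L <- params$probe_len
  if (tlen < params$head_offset + L - 1L) {
    warning(sprintf("template '%s' (%d nt) shorter than the first probe window (%d); no probes designed",
                    template$template_id, tlen, params$head_offset + L - 1L))
    return(new_probe_set(probe_columns(), params,
                         list(template_id = template$template_id)))
  }

  probes <- list()
  prev_end <- 0L
  s0 <- params$head_offset
  first <- TRUE
  repeat {
    clamped <- FALSE
    start_nominal <- s0
    if (start_nominal + L - 1L > tlen) {
      start_nominal <- tlen - L + 1L
      clamped <- TRUE
    }
    if (clamped && start_nominal <= prev_end) break
    floor_pos <- max(start_nominal - params$search_space_nt,
                     if (first) 1L else prev_end + 1L)
    cand_starts <- seq(start_nominal, floor_pos, by = -1L)
    windows <- substring(tseq, cand_starts, cand_starts + L - 1L)
    valid <- is_acgt(windows)
    if (any(!valid)) {
      warning(sprintf("template '%s': %d candidate window(s) near position %d skipped (ambiguous base)",
                      template$template_id, sum(!valid), start_nominal))
    }
    if (!any(valid)) {
      # no evaluable window here; step past the region without placing
      prev_end <- start_nominal + L - 1L
      s0 <- prev_end + params$max_gap_nt + 1L
      first <- FALSE
      if (prev_end >= tlen) break
      next
    }
    cand_starts <- cand_starts[valid]
    windows <- windows[valid]
    tms <- melting_temperature(windows, params$thermo)
    pass <- which(tms >= params$tm_threshold_C)
    below <- FALSE
    adjusted <- FALSE
    if (length(pass)) {
      pick <- pass[1]  # first passing position scanning downstream -> upstream
    } else {
      pick <- which.max(tms)  # ties resolve to most downstream (scan order)
      below <- TRUE
    }
    start <- cand_starts[pick]
    end <- start + L - 1L
    tm <- tms[pick]
    if (below && params$allow_length_adjust) {
      ext_end <- end
      while (ext_end < min(start + params$max_len - 1L, tlen)) {
        ext_end <- ext_end + 1L
        w <- substr(tseq, start, ext_end)
        if (!is_acgt(w)) break
        tm_ext <- melting_temperature(w, params$thermo)
        if (tm_ext >= params$tm_threshold_C) {
          end <- ext_end; tm <- tm_ext
          below <- FALSE; adjusted <- TRUE
          break
        }
      }
    }
    probes[[length(probes) + 1L]] <- data.frame(
      name = "", sequence = revcomp(substr(tseq, start, end)),
      template_id = template$template_id, rna_type = template$rna_type,
      start = start, end = end, length = end - start + 1L, tm_C = tm,
      below_threshold = below, length_adjusted = adjusted,
      three_prime_block = "none", stringsAsFactors = FALSE)
    prev_end <- end
    first <- FALSE
    if (prev_end >= tlen) break
    s0 <- prev_end + params$max_gap_nt + 1L
  }
  out <- if (length(probes)) do.call(rbind, probes) else probe_columns()
  if (nrow(out)) {
    out$name <- sprintf("%s_%03d", template$template_id, seq_len(nrow(out)))
  }
  new_probe_set(out, params, list(template_id = template$template_id,
                                  n_copies = template$n_copies))
}

#' Design a genome-wide probe panel
#'
#' Extracts rRNA genes, builds one consensus per requested rRNA type and
#' tiles each with [design_probes()]. With `include_pre_rrna`, every derived
#' pre-rRNA operon region (leader, spacers, trailer) is additionally tiled
#' as its own template with length adjustment forced on (these regions are
#' typically AT-rich, so fixed-length windows often melt below threshold).
#'
#' @param records list of `genome_record` (or a single one).
#' @param params a [design_params()] object.
#' @param types rRNA types to target.
#' @param include_pre_rrna also design probes over pre-rRNA operon regions.
#' @param leader_nt,trailer_nt pre-rRNA flank extents (see
#'   [derive_pre_rrna_regions()]).
#' @return a `probe_set`.
#' @export
design_probe_panel <- function(records, params = design_params(),
                               types = c("5S", "16S", "23S"),
                               include_pre_rrna = FALSE,
                               leader_nt = 150L, trailer_nt = 150L) {
  feats <- extract_rrna_features(records, types = types)
  sets <- list()
  for (ty in intersect(c("16S", "23S", "5S"), unique(feats$rna_type))) {
    tpl <- build_consensus(feats[feats$rna_type == ty, , drop = FALSE])
    sets[[length(sets) + 1L]] <- design_probes(tpl, params)
  }
  if (include_pre_rrna) {
    pre <- derive_pre_rrna_regions(records, feats, leader_nt, trailer_nt)
    pre_params <- params
    pre_params$allow_length_adjust <- TRUE
    for (i in seq_len(nrow(pre))) {
      tpl <- structure(list(template_id = pre$feature_id[i],
                            rna_type = "pre-rRNA",
                            sequence = pre$sequence[i],
                            agreement = rep(1, nchar(pre$sequence[i])),
                            n_copies = 1L, source_ids = pre$feature_id[i],
                            note = ""),
                       class = "consensus_template")
      sets[[length(sets) + 1L]] <- withCallingHandlers(
        design_probes(tpl, pre_params),
        warning = function(w) {
          if (grepl("shorter than the first probe window", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    }
  }
  probes <- do.call(rbind, lapply(sets, function(s) as.data.frame(s)))
  if (is.null(probes)) probes <- probe_columns()
  reps <- if (inherits(records, "genome_record")) records$replicon_id else
    vapply(records, `[[`, "", "replicon_id")
  new_probe_set(probes, params,
                list(replicons = reps,
                     tool = sprintf("ribodesign %s",
                                    as.character(utils::packageVersion("ribodesign"))),
                     include_pre_rrna = include_pre_rrna))
}
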