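# Deterministic synthetic data: annotated rRNA-operon genomes, diverged
# rRNAs, classified read fixtures, and an idealized depletion simulation.

#' Specification for a synthetic rRNA-operon genome
#'
#' Defaults emulate an E. coli-like chromosome fragment: multi-copy
#' 16S-spacer-23S-spacer-5S operons whose copies are nearly identical
#' (substitution-only divergence), rRNA at slightly higher GC than the
#' background.
#'
#' @param n_operons number of operon copies.
#' @param gene_lengths named lengths for `16S`, `23S`, `5S` (nt).
#' @param spacer_lengths lengths of the 16S-23S and 23S-5S spacers (nt).
#' @param intercopy_substitution_rate per-base substitution probability
#'   applied to copies 2..n relative to the master cassette.
#' @param gc_content background GC fraction.
#' @param rrna_gc GC fraction of rRNA genes.
#' @param intergenic_nt background separation between operons and at the
#'   margins.
#' @param seed integer RNG seed; identical seeds give byte-identical output.
#' @return an object of class `operon_spec`.
#' @export
operon_spec <- function(n_operons = 2L,
                        gene_lengths = c(`16S` = 1542L, `23S` = 2904L, `5S` = 120L),
                        spacer_lengths = c(440L, 90L),
                        intercopy_substitution_rate = 0.002,
                        gc_content = 0.50, rrna_gc = 0.54,
                        intergenic_nt = 2000L,
                        seed = 1009821L) {
  if (intercopy_substitution_rate < 0 || intercopy_substitution_rate > 1 ||
      gc_content < 0 || gc_content > 1 || rrna_gc < 0 || rrna_gc > 1) {
    abort_validation("operon_spec: rates and GC fractions must lie in [0,1]")
  }
  if (any(gene_lengths <= 0) || any(spacer_lengths <= 0) || n_operons < 1L ||
      intergenic_nt < 0L) {
    abort_validation("operon_spec: lengths must be positive and n_operons >= 1")
  }
  if (!all(c("16S", "23S", "5S") %in% names(gene_lengths))) {
    abort_validation("operon_spec: gene_lengths must name 16S, 23S and 5S")
  }
  structure(list(n_operons = as.integer(n_operons),
                 gene_lengths = gene_lengths,
                 spacer_lengths = as.integer(spacer_lengths),
                 intercopy_substitution_rate = intercopy_substitution_rate,
                 gc_content = gc_content, rrna_gc = rrna_gc,
                 intergenic_nt = as.integer(intergenic_nt),
                 seed = as.integer(seed)),
            class = "operon_spec")
}

substitute_bases <- function(seq, positions) {
  if (!length(positions)) return(list(seq = seq, ref = character(0), alt = character(0)))
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  ref <- b[positions]
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                "", USE.NAMES = FALSE)
  b[positions] <- alt
  list(seq = paste(b, collapse = ""), ref = ref, alt = alt)
}

#' Generate an annotated synthetic rRNA-operon genome
#'
#' Builds `n_operons` copies of a 16S-spacer-23S-spacer-5S cassette mutated
#' from a shared master at the intercopy substitution rate, embeds them in
#' random background sequence, and places every second operon on the minus
#' strand. Returns the annotated record plus a truth table of feature
#' coordinates and planted intercopy variants.
#'
#' @param spec an [operon_spec()].
#' @return list with `record` (a `genome_record`, GenBank-writable via
#'   [write_genbank()]) and `truth` (list with `features` and `variants`
#'   data.frames; variant positions are 1-based within the sense-strand
#'   gene/cassette sequence).
#' @export
generate_operon_genome <- function(spec = operon_spec()) {
  stopifnot(inherits(spec, "operon_spec"))
  gl <- spec$gene_lengths
  cassette_len <- sum(gl) + sum(spec$spacer_lengths)
  with_seed(spec$seed, {
    master <- list(
      `16S` = random_dna(gl[["16S"]], spec$rrna_gc),
      spacer1 = random_dna(spec$spacer_lengths[1], spec$gc_content * 0.9),
      `23S` = random_dna(gl[["23S"]], spec$rrna_gc),
      spacer2 = random_dna(spec$spacer_lengths[2], spec$gc_content * 0.9),
      `5S` = random_dna(gl[["5S"]], spec$rrna_gc))
    part_names <- names(master)
    gene_parts <- c("16S", "23S", "5S")

    seq_chunks <- character(0)
    pos <- 0L
    feats <- list()
    truth_feats <- list()
    variants <- list()
    add_chunk <- function(s) {
      seq_chunks[[length(seq_chunks) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    add_chunk(random_dna(spec$intergenic_nt, spec$gc_content))
    for (k in seq_len(spec$n_operons)) {
      minus <- (k %% 2L == 0L)  # every second operon on the minus strand
      parts <- master
      if (k > 1L && spec$intercopy_substitution_rate > 0) {
        for (pn in part_names) {
          n <- nchar(parts[[pn]])
          hit <- which(runif(n) < spec$intercopy_substitution_rate)
          if (length(hit)) {
            mut <- substitute_bases(parts[[pn]], hit)
            parts[[pn]] <- mut$seq
            if (pn %in% gene_parts) {
              variants[[length(variants) + 1L]] <- data.frame(
                operon = k, part = pn, pos = hit, ref = mut$ref, alt = mut$alt,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
      cassette <- paste(unlist(parts[part_names]), collapse = "")
      # sense-strand part offsets within the cassette
      offs <- cumsum(c(0L, nchar(unlist(parts[part_names]))))
      cass_start <- pos + 1L
      if (minus) {
        add_chunk(revcomp(cassette))
      } else {
        add_chunk(cassette)
      }
      for (gi in seq_along(part_names)) {
        pn <- part_names[gi]
        if (!(pn %in% gene_parts)) next
        ps <- offs[gi] + 1L; pe <- offs[gi + 1L]
        if (minus) {
          gs <- cass_start + (cassette_len - pe)
          ge <- cass_start + (cassette_len - ps)
        } else {
          gs <- cass_start + ps - 1L
          ge <- cass_start + pe - 1L
        }
        feats[[length(feats) + 1L]] <- data.frame(
          kind = "rRNA", start = gs, end = ge,
          strand = if (minus) "-" else "+",
          product = sprintf("%s ribosomal RNA", pn), stringsAsFactors = FALSE)
        truth_feats[[length(truth_feats) + 1L]] <- data.frame(
          operon = k, rna_type = pn, start = gs, end = ge,
          strand = if (minus) "-" else "+",
          sequence = parts[[pn]], stringsAsFactors = FALSE)
      }
      add_chunk(random_dna(spec$intergenic_nt, spec$gc_content))
    }
    record <- genome_record("synthetic_chr", paste(seq_chunks, collapse = ""),
                            do.call(rbind, feats))
    truth <- list(
      features = do.call(rbind, truth_feats),
      variants = if (length(variants)) do.call(rbind, variants) else
        data.frame(operon = integer(0), part = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   stringsAsFactors = FALSE),
      master = master, spec = spec)
    list(record = record, truth = truth)
  })
}

#' Mutate rRNA features into a diverged "species"
#'
#' Substitution-only mutation of each feature sequence at the given
#' per-base divergence, with a per-position truth table so per-probe
#' mismatch footprints are computable.
#'
#' @param features an `rrna_features` data.frame.
#' @param divergence per-base substitution probability, in \[0, 0.25\].
#' @param seed integer RNG seed.
#' @return list with `features` (mutated copy) and `truth` (data.frame
#'   `feature_id`, `pos`, `ref`, `alt`).
#' @export
generate_diverged_rrnas <- function(features, divergence, seed = 1009821L) {
  if (divergence < 0 || divergence > 0.25) {
    abort_validation("generate_diverged_rrnas: divergence must lie in [0, 0.25]")
  }
  with_seed(seed, {
    out <- features
    truth <- list()
    for (i in seq_len(nrow(out))) {
      n <- nchar(out$sequence[i])
      hit <- which(runif(n) < divergence)
      if (!length(hit)) next
      mut <- substitute_bases(out$sequence[i], hit)
      out$sequence[i] <- mut$seq
      truth[[length(truth) + 1L]] <- data.frame(
        feature_id = out$feature_id[i], pos = hit, ref = mut$ref,
        alt = mut$alt, stringsAsFactors = FALSE)
    }
    list(features = out,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(feature_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE))
  })
}

#' Generate a classified read fixture
#'
#' Places reads uniformly inside intervals of their assigned class so that
#' [classify_reads()] recovers the class composition. `class_fractions`
#' given as exact per-class counts (summing to `n_reads`) are honoured
#' exactly; fractional specifications are converted to counts by largest
#' remainder.
#'
#' @param classes labelled intervals (`rrna_features` or data.frame with
#'   `replicon_id`, `start`, `end`, `rna_type`), the non-`other` classes.
#' @param genome_length replicon length, used to place `other` reads in the
#'   complement of the class intervals.
#' @param replicon_id replicon name for the reads.
#' @param n_reads total reads.
#' @param class_fractions named fractions (or counts) over
#'   `5S`/`16S`/`23S`/`pre-rRNA`/`other`.
#' @param read_len read length, nt.
#' @param seed integer RNG seed.
#' @return list with `reads` (data.frame `read_id`, `replicon_id`, `start`,
#'   `end`, `strand`) and `truth` (per-read class labels).
#' @export
generate_read_fixture <- function(classes, genome_length, replicon_id,
                                  n_reads, class_fractions,
                                  read_len = 75L, seed = 1009821L) {
  if (!length(class_fractions) || is.null(names(class_fractions))) {
    abort_validation("class_fractions must be a named vector")
  }
  counts <- if (sum(class_fractions) == n_reads && all(class_fractions == round(class_fractions))) {
    as.integer(class_fractions)
  } else {
    if (abs(sum(class_fractions) - 1) > 1e-9) {
      abort_validation("class_fractions must sum to 1 (or be exact counts summing to n_reads)")
    }
    exact <- class_fractions * n_reads
    base <- floor(exact)
    rem <- n_reads - sum(base)
    if (rem > 0) {
      extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    as.integer(base)
  }
  names(counts) <- names(class_fractions)

  lab <- if ("rna_type" %in% names(classes)) classes$rna_type else classes$class
  class_iv <- split(data.frame(start = classes$start, end = classes$end), lab)
  # complement intervals for "other"
  all_ir <- IRanges::reduce(IRanges::IRanges(classes$start, classes$end))
  other_ir <- IRanges::gaps(all_ir, start = 1L, end = genome_length)
  other_iv <- data.frame(start = BiocGenerics::start(other_ir),
                         end = BiocGenerics::end(other_ir))

  with_seed(seed, {
    rows <- list()
    labels <- character(0)
    for (cl in names(counts)) {
      k <- counts[[cl]]
      if (k == 0L) next
      iv <- if (cl == "other") other_iv else class_iv[[cl]]
      if (is.null(iv) || !nrow(iv)) {
        abort_validation("class '%s' has no interval to place reads in", cl)
      }
      iv <- iv[iv$end - iv$start + 1L >= read_len, , drop = FALSE]
      if (!nrow(iv)) {
        abort_validation("class '%s' has no interval of at least read_len", cl)
      }
      pick <- sample.int(nrow(iv), k, replace = TRUE)
      smax <- iv$end[pick] - read_len + 1L
      starts <- iv$start[pick] +
        floor(runif(k) * (smax - iv$start[pick] + 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("%s_read_%05d", cl, seq_len(k)),
        replicon_id = replicon_id, start = as.integer(starts),
        end = as.integer(starts) + read_len - 1L, strand = "+",
        stringsAsFactors = FALSE)
      labels <- c(labels, rep(cl, k))
    }
    reads <- do.call(rbind, rows)
    list(reads = reads,
         truth = data.frame(read_id = reads$read_id, class = labels,
                            stringsAsFactors = FALSE))
  })
}

#' Idealized depletion of a molecule pool
#'
#' Deterministic model of the enzymatic reaction: a molecule is removed iff
#' at least one probe hybridizes perfectly, i.e. the probe's reverse
#' complement occurs as an exact full-length substring of the molecule.
#' Survivors are returned unchanged.
#'
#' @param probes a `probe_set`.
#' @param molecules data.frame with columns `sequence` and `class` (and
#'   optionally `molecule_id`).
#' @return the surviving subset of `molecules`, with a logical `removed`
#'   attribute-free accounting left to the caller.
#' @export
simulate_depletion <- function(probes, molecules) {
  if (is.null(molecules) || nrow(molecules) == 0L) {
    abort_validation("simulate_depletion: empty molecule pool")
  }
  binders <- revcomp(probes$sequence)
  removed <- vapply(molecules$sequence, function(m) {
    any(vapply(binders, function(b) grepl(b, m, fixed = TRUE), logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  molecules[!removed, , drop = FALSE]
}

#' Transcript pool of a synthetic genome
#'
#' One molecule per rRNA gene copy (classes 5S/16S/23S), one per derived
#' pre-rRNA region, plus optional background mRNAs drawn from non-rRNA
#' intervals.
#'
#' @param generated output of [generate_operon_genome()].
#' @param leader_nt,trailer_nt pre-rRNA flank extents.
#' @param n_mrna number of background mRNA molecules.
#' @param mrna_len mRNA length, nt.
#' @param seed RNG seed for mRNA placement.
#' @return data.frame `molecule_id`, `class`, `sequence`.
#' @export
transcript_pool <- function(generated, leader_nt = 150L, trailer_nt = 150L,
                            n_mrna = 0L, mrna_len = 600L, seed = 1L) {
  feats <- extract_rrna_features(generated$record)
  pre <- derive_pre_rrna_regions(generated$record, feats, leader_nt, trailer_nt)
  mol <- data.frame(molecule_id = c(feats$feature_id, pre$feature_id),
                    class = c(feats$rna_type, pre$rna_type),
                    sequence = c(feats$sequence, pre$sequence),
                    stringsAsFactors = FALSE)
  if (n_mrna > 0L) {
    glen <- nchar(generated$record$sequence)
    occ <- IRanges::reduce(IRanges::IRanges(c(feats$start, pre$start),
                                            c(feats$end, pre$end)))
    free <- IRanges::gaps(occ, start = 1L, end = glen)
    free <- free[BiocGenerics::width(free) >= mrna_len]
    mol_m <- with_seed(seed, {
      pick <- sample.int(length(free), n_mrna, replace = TRUE)
      smax <- BiocGenerics::end(free)[pick] - mrna_len + 1L
      starts <- BiocGenerics::start(free)[pick] +
        floor(runif(n_mrna) * (smax - BiocGenerics::start(free)[pick] + 1L))
      data.frame(molecule_id = sprintf("mRNA_%04d", seq_len(n_mrna)),
                 class = "mRNA",
                 sequence = substring(generated$record$sequence, starts,
                                      starts + mrna_len - 1L),
                 stringsAsFactors = FALSE)
    })
    mol <- rbind(mol, mol_m)
  }
  mol
}
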