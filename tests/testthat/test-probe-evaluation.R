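# Placement, coverage gaps, cross-species transfer, off-target scanning.

test_that("probes map back onto their design template at their design coordinates", {
  tpl <- hot_template(1000)
  probes <- design_probes(tpl)
  pl <- map_probes(probes, features_from_seqs(tpl, ids = "tpl"), 0L)
  pl <- pl[match(probes$name, pl$probe_name), ]
  expect_equal(pl$start, probes$start)
  expect_equal(pl$end, probes$end)
  expect_true(all(pl$mismatches == 0))
})

test_that("mismatch counts on a diverged target equal the truth footprint counts", {
  tpl <- hot_template(1500, seed = 21)
  probes <- design_probes(tpl)
  div <- generate_diverged_rrnas(features_from_seqs(tpl, ids = "t1"),
                                 divergence = 0.02, seed = 77)
  pl <- map_probes(probes, div$features, max_mismatches = 3L)
  for (i in seq_len(nrow(probes))) {
    truth_mm <- sum(div$truth$pos >= probes$start[i] &
                      div$truth$pos <= probes$end[i])
    got <- pl[pl$probe_name == probes$name[i], ]
    if (truth_mm <= 3) {
      expect_equal(got$mismatches, truth_mm,
                   info = sprintf("probe %s", probes$name[i]))
    } else {
      expect_equal(nrow(got), 0)
    }
  }
})

test_that("probes exceeding the mismatch allowance yield no placement", {
  tpl <- hot_template(300, seed = 3)
  probes <- design_probes(tpl)
  mutated <- tpl
  # plant 2 substitutions inside the first probe footprint
  for (pos in c(55L, 70L)) {
    cur <- substr(mutated, pos, pos)
    substr(mutated, pos, pos) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  pl <- map_probes(probes[1, ], features_from_seqs(mutated, ids = "m"), 1L)
  expect_equal(nrow(pl), 0)
})

test_that("coverage gap arithmetic matches the worked example", {
  target <- features_from_seqs(strrep("A", 120), ids = "t")
  pl <- data.frame(probe_name = c("a", "b"), target_id = "t",
                   start = c(10L, 60L), end = c(41L, 91L), mismatches = 0L)
  cv <- coverage_report(pl, target)
  expect_equal(cv$gaps$start, c(1L, 42L, 92L))
  expect_equal(cv$gaps$end, c(9L, 59L, 120L))
  expect_equal(cv$gaps$length, c(9L, 18L, 29L))
  expect_equal(cv$max_gap_nt, 29L)
  expect_equal(cv$covered_nt + sum(cv$gaps$length), 120L)
  # no placements: one gap spanning everything
  cv0 <- coverage_report(pl[0, ], target)
  expect_equal(cv0$gaps$length, 120L)
})

test_that("self-coverage of a designed template never exceeds the design gap bound", {
  tpl <- hot_template(2000, seed = 14)
  probes <- design_probes(tpl)
  target <- features_from_seqs(tpl, ids = "tpl")
  cv <- coverage_report(map_probes(probes, target, 0L), target)
  expect_true(all(cv$gaps$length <= attr(probes, "params")$max_gap_nt))
})

test_that("identity transfer matches every probe with zero mismatches", {
  tpl <- hot_template(1200, seed = 4)
  probes <- design_probes(tpl)
  rep <- transfer_assessment(probes, features_from_seqs(tpl, ids = "tpl"), 1L)
  expect_equal(nrow(rep$matched), nrow(probes))
  expect_length(rep$unmatched, 0)
  expect_true(all(rep$matched$best_mismatches == 0))
})

test_that("transfer counts equal a brute-force full-length scan on a diverged species", {
  tpl <- hot_template(1500, seed = 22)
  probes <- design_probes(tpl)
  div <- generate_diverged_rrnas(features_from_seqs(tpl, ids = "sp2"),
                                 divergence = 0.04, seed = 55)
  rep <- transfer_assessment(probes, div$features, max_mismatches = 1L)
  brute <- vapply(probes$sequence, function(s)
    !is.null(naive_best_placement(s, div$features$sequence[1], 1L)),
    logical(1))
  expect_equal(nrow(rep$matched), sum(brute))
  expect_equal(nrow(rep$matched) + length(rep$unmatched), rep$n_probes)
})

test_that("planted exact reverse complement is recovered as a full-length hit", {
  subj <- random_dna_seed(3000, 0.5, 91)
  probes <- probe_set_from_seqs(
    ribodesign:::with_seed(92, ribodesign:::random_dna(32, 0.5)))
  substr(subj, 1200, 1231) <- revcomp(probes$sequence[1])
  hits <- offtarget_scan(probes, genome_record("chr", subj), min_run = 15L)
  full <- hits[hits$run_length == 32L, ]
  expect_equal(nrow(full), 1)
  expect_equal(full$run_start, 1200L)
  expect_equal(full$subject_strand, "+")
})

test_that("a planted 16-nt shared substring in a 10-kb subject is found exactly once", {
  subj <- random_dna_seed(10000, 0.5, 93)
  probe <- ribodesign:::with_seed(94, ribodesign:::random_dna(32, 0.5))
  probes <- probe_set_from_seqs(probe)
  frag <- substr(revcomp(probe), 9, 24)
  substr(subj, 5000, 5015) <- frag
  # force the flanks to break the run at exactly 16 nt
  left_next <- substr(revcomp(probe), 8, 8)
  right_next <- substr(revcomp(probe), 25, 25)
  substr(subj, 4999, 4999) <- setdiff(c("A", "C", "G", "T"), left_next)[1]
  substr(subj, 5016, 5016) <- setdiff(c("A", "C", "G", "T"), right_next)[1]
  hits <- offtarget_scan(probes, genome_record("chr", subj), min_run = 16L)
  planted <- hits[hits$subject_strand == "+", ]
  expect_equal(nrow(planted), 1)
  expect_equal(planted$run_start, 5000L)
  expect_equal(planted$run_end, 5015L)
  expect_equal(planted$run_length, 16L)
  # oracle agrees on the complete hit set
  nv <- naive_offtarget_scan(probes, genome_record("chr", subj), min_run = 16L)
  expect_equal(nrow(nv), nrow(hits))
})

test_that("rRNA loci listed in exclude produce no hits", {
  tpl <- hot_template(800, seed = 17)
  probes <- design_probes(tpl)
  background <- random_dna_seed(2000, 0.5, 18)
  subj <- paste0(background, tpl, substr(background, 1, 500))
  rec <- genome_record("chr", subj)
  excl <- data.frame(replicon_id = "chr", start = 2001L, end = 2000L + nchar(tpl))
  hits_all <- offtarget_scan(probes, rec, min_run = 15L)
  expect_true(any(hits_all$run_length == 32L))  # locus visible unmasked
  hits <- offtarget_scan(probes, rec, exclude = excl, min_run = 15L)
  expect_false(any(hits$run_start >= 2001L & hits$run_end <= 2000L + nchar(tpl)))
})

test_that("off-target scan equals the naive quadratic oracle, with strand symmetry", {
  subj <- random_dna_seed(5000, 0.55, 71)
  set.seed(72)
  probes <- probe_set_from_seqs(replicate(10, ribodesign:::random_dna(32, 0.55)))
  substr(subj, 800, 831) <- revcomp(probes$sequence[2])
  substr(subj, 2500, 2517) <- substr(probes$sequence[5], 7, 24)
  substr(subj, 4400, 4412) <- substr(revcomp(probes$sequence[8]), 11, 23)
  rec <- genome_record("chr", subj)
  key <- function(d) paste(d$probe_name, d$subject_strand, d$run_start, d$run_end)
  for (k in c(12L, 13L)) {
    im <- offtarget_scan(probes, rec, min_run = k)
    nv <- naive_offtarget_scan(probes, rec, min_run = k)
    expect_setequal(key(im), key(nv))
  }
  # monotonicity: hits at k+1 are the length-filtered subset of hits at k
  h12 <- offtarget_scan(probes, rec, min_run = 12L)
  h13 <- offtarget_scan(probes, rec, min_run = 13L)
  expect_true(all(key(h13) %in% key(h12[h12$run_length >= 13L, ])))
  # symmetry: reverse-complemented subject gives mirrored hits
  rec_rc <- genome_record("chr", revcomp(subj))
  h_rc <- offtarget_scan(probes, rec_rc, min_run = 13L)
  n <- nchar(subj)
  mirrored <- paste(h_rc$probe_name,
                    ifelse(h_rc$subject_strand == "+", "-", "+"),
                    n - h_rc$run_end + 1L, n - h_rc$run_start + 1L)
  expect_setequal(mirrored, key(h13))
})

test_that("off-target scan validates its inputs", {
  probes <- probe_set_from_seqs(strrep("ACGT", 8))
  rec <- genome_record("chr", strrep("ACGT", 100))
  expect_error(offtarget_scan(probes, rec, min_run = 40L),
               class = "ribodesign_validation")
  expect_error(offtarget_scan(probes, rec, min_run = 6L),
               class = "ribodesign_validation")
  expect_error(map_probes(probes, features_from_seqs(character(0)), 0L),
               class = "ribodesign_validation")
})
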