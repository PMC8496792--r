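# Genome reading, rRNA extraction, pre-rRNA regions, probe serialization.

make_fixture <- function(seed = 1009821L, n_operons = 2L) {
  generate_operon_genome(operon_spec(n_operons = n_operons, seed = seed))
}

test_that("GenBank fixture round-trips with all rRNA features at truth coordinates", {
  gen <- make_fixture()
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(gen$record, gb)
  recs <- read_annotated_genome(gb, "genbank")
  expect_length(recs, 1)
  expect_identical(recs[[1]]$sequence, gen$record$sequence)
  feats <- extract_rrna_features(recs)
  expect_equal(nrow(feats), 6)
  truth <- gen$truth$features[order(gen$truth$features$start), ]
  got <- feats[order(feats$start), ]
  expect_equal(got$start, truth$start)
  expect_equal(got$end, truth$end)
  expect_equal(got$strand, truth$strand)
  expect_equal(got$rna_type, truth$rna_type)
  # sense-strand sequences equal the generator's cassette parts
  expect_equal(got$sequence, truth$sequence)
})

test_that("FASTA input yields records with zero features", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seqA", "ACGTACGTACGTAC", ">seqB", "GGGCCCAAATTTGG"), fa)
  recs <- read_annotated_genome(fa, "fasta")
  expect_length(recs, 2)
  expect_equal(vapply(recs, function(r) nrow(r$features), integer(1)), c(0L, 0L))
  expect_equal(recs[[1]]$replicon_id, "seqA")
})

test_that("truncated or malformed GenBank input raises a parse error", {
  gb <- withr::local_tempfile(fileext = ".gb")
  gen <- make_fixture()
  write_genbank(gen$record, gb)
  lines <- readLines(gb)
  writeLines(head(lines, length(lines) %/% 2), gb)  # drop terminator + tail
  expect_error(read_annotated_genome(gb, "genbank"),
               class = "ribodesign_parse")
  expect_error(read_annotated_genome(tempfile(), "genbank"),
               class = "ribodesign_io")
})

test_that("minus-strand rRNA genes are extracted as transcribed", {
  gen <- make_fixture()
  feats <- extract_rrna_features(gen$record)
  minus <- feats[feats$strand == "-" & feats$rna_type == "16S", ][1, ]
  genomic_slice <- substr(gen$record$sequence, minus$start, minus$end)
  expect_identical(minus$sequence, revcomp(genomic_slice))
})

test_that("type filtering and operon grouping behave", {
  gen <- make_fixture()
  f16 <- extract_rrna_features(gen$record, types = "16S")
  expect_equal(nrow(f16), 2)
  expect_true(all(f16$rna_type == "16S"))
  all_f <- extract_rrna_features(gen$record)
  expect_equal(length(unique(all_f$operon_id)), 2)
  expect_equal(unname(table(all_f$operon_id)), c(3L, 3L), ignore_attr = TRUE)
})

test_that("annotated genome without rRNA raises an explicit error", {
  rec <- genome_record("chr", strrep("ACGT", 300),
                       data.frame(kind = "CDS", start = 10L, end = 300L,
                                  strand = "+", product = "hypothetical"))
  expect_error(extract_rrna_features(rec), "no rRNA",
               class = "ribodesign_validation")
})

test_that("strand mirror: extracting from the reverse-complemented genome gives the same sequences", {
  gen <- make_fixture()
  feats <- extract_rrna_features(gen$record)
  n <- nchar(gen$record$sequence)
  flipped <- gen$record$features
  flipped$start2 <- n - gen$record$features$end + 1L
  flipped$end <- n - gen$record$features$start + 1L
  flipped$start <- flipped$start2
  flipped$start2 <- NULL
  flipped$strand <- ifelse(gen$record$features$strand == "+", "-", "+")
  rec2 <- genome_record("chr_rc", revcomp(gen$record$sequence), flipped)
  feats2 <- extract_rrna_features(rec2)
  expect_setequal(feats2$sequence, feats$sequence)
})

test_that("pre-rRNA regions follow the interval arithmetic contract", {
  seq <- strrep("ACGT", 2000)
  rec <- genome_record("chr", seq,
                       data.frame(kind = "rRNA", start = c(1001L, 2801L),
                                  end = c(2500L, 5600L), strand = "+",
                                  product = c("16S ribosomal RNA",
                                              "23S ribosomal RNA")))
  feats <- extract_rrna_features(rec)
  pre <- derive_pre_rrna_regions(rec, feats, leader_nt = 100, trailer_nt = 100)
  expect_equal(pre$start, c(901L, 2501L, 5601L))
  expect_equal(pre$end, c(1000L, 2800L, 5700L))
  expect_true(all(pre$rna_type == "pre-rRNA"))
  # single-gene operon, no flanks -> nothing
  rec1 <- genome_record("chr", seq,
                        data.frame(kind = "rRNA", start = 1001L, end = 2500L,
                                   strand = "+", product = "16S ribosomal RNA"))
  pre0 <- derive_pre_rrna_regions(rec1, extract_rrna_features(rec1), 0, 0)
  expect_equal(nrow(pre0), 0)
})

test_that("pre-rRNA regions tile the operon complement without touching gene bodies", {
  gen <- make_fixture()
  feats <- extract_rrna_features(gen$record)
  pre <- derive_pre_rrna_regions(gen$record, feats)
  expect_equal(nrow(pre), 2 * (2 + 2))  # per operon: 2 spacers + leader + trailer
  gene_ir <- IRanges::IRanges(feats$start, feats$end)
  pre_ir <- IRanges::IRanges(pre$start, pre$end)
  expect_equal(sum(IRanges::countOverlaps(pre_ir, gene_ir)), 0)
  # spacers + genes tile each operon span exactly
  for (op in unique(feats$operon_id)) {
    g <- feats[feats$operon_id == op, ]
    p <- pre[pre$operon_id == op, ]
    span <- IRanges::reduce(IRanges::IRanges(c(g$start, p$start), c(g$end, p$end)))
    expect_equal(length(span), 1)
    expect_equal(BiocGenerics::width(span), sum(g$end - g$start + 1) +
                   sum(p$end - p$start + 1))
  }
})

test_that("probe outputs round-trip through FASTA + CSV", {
  probes <- design_probes(hot_template(600))
  fa <- withr::local_tempfile(fileext = ".fasta")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_probe_outputs(probes, fa, csv, config = c(run = "roundtrip"))
  back <- read_probe_set(fa, csv)
  expect_equal(back$name, probes$name)
  expect_equal(back$sequence, probes$sequence)
  expect_equal(back$start, probes$start)
  expect_equal(back$end, probes$end)
  expect_equal(back$tm_C, round(probes$tm_C, 2), tolerance = 1e-9)
  expect_equal(back$below_threshold, probes$below_threshold)
})

test_that("BED export lifts template coordinates through genomic provenance", {
  probes <- design_probes(hot_template(600))
  one <- probes[1, , drop = FALSE]  # template positions 50..81
  class(one) <- class(probes)
  feats <- features_from_seqs(hot_template(600), ids = "16S")
  feats$replicon_id <- "chr"
  feats$start <- 1001L
  feats$end <- 1600L
  gr <- probe_binding_sites(one, feats)
  # 1-based genomic 1050..1081 -> BED half-open [1049, 1081)
  expect_equal(BiocGenerics::start(gr), 1050)
  expect_equal(BiocGenerics::end(gr), 1081)
  bed <- withr::local_tempfile(fileext = ".bed")
  rtracklayer::export(gr, bed, format = "BED")
  line1 <- strsplit(readLines(bed)[1], "\t")[[1]]
  expect_equal(as.integer(line1[2]), 1049L)
  expect_equal(as.integer(line1[3]), 1081L)
  expect_true(as.integer(line1[5]) >= 0 && as.integer(line1[5]) <= 1000)
})

test_that("empty probe sets are rejected at write time", {
  empty <- suppressWarnings(design_probes(hot_template(60)))
  expect_equal(nrow(empty), 0)
  expect_error(write_probe_outputs(empty, tempfile(), tempfile()),
               class = "ribodesign_validation")
})
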