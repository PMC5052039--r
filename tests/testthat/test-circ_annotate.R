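test_that("realign_and_snap matches exact and jittered junctions", {
  m <- toy_models()
  idx <- build_splice_site_index(m)
  # identity: exon1 start / exon3 end of GA.2, tolerance 0
  hit <- realign_and_snap("chr1", 100, 900, "+", idx, tolerance = 0)
  expect_true(all(c("GA.1", "GA.2") %in% hit$isoform_name))
  expect_true(all(hit$offset == 0))
  # displaced +2 / -1 with tolerance 2: total offset 3 (brute-force checked)
  hit2 <- realign_and_snap("chr1", 102, 899, "+", idx, tolerance = 2)
  expect_equal(unique(hit2$offset), 3)
  expect_equal(unique(hit2$snapped_start), 100)
  expect_equal(unique(hit2$snapped_end), 900)
  oracle <- brute_force_matches(m, "chr1", 102, 899, "+", 2)
  expect_equal(hit2$isoform_name, oracle$isoform_name)
  expect_equal(hit2$snapped_start, oracle$snapped_start)
  expect_equal(hit2$snapped_end, oracle$snapped_end)
  # intergenic
  expect_equal(nrow(realign_and_snap("chr1", 9000, 9500, "+", idx, 2)), 0L)
})

test_that("annotate resolves blocks, tie-breaks and fallbacks", {
  m <- toy_models()
  samples <- toy_samples()
  # junction over exons 2..4 of the 5-exon isoform GA.1
  j <- toy_junctions("chr1", 300, 1300, 7)
  recs <- annotate_circ(j, m, samples)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$read_count, 7)
  expect_equal(recs$rpm, 7)
  expect_equal(length(recs$block_starts[[1]]), 3L)
  expect_equal(recs$block_starts[[1]], c(300, 700, 1200))
  expect_equal(recs$block_sizes[[1]], c(100, 200, 100))
  expect_equal(recs$circ_type, "exonic")
  expect_equal(c(recs$start_status, recs$end_status), c("annotated", "annotated"))
  # two isoforms match equally (GA.1 vs GA.2 for exons 1..3): same offset,
  # same exon count in span -> lexicographically smaller isoform wins
  j2 <- toy_junctions("chr1", 100, 900, 5)
  r2 <- annotate_circ(j2, m, samples)
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$isoform_name, "GA.1")
  # junction within a single intron -> ciRNA-like single block
  j3 <- toy_junctions("chr1", 420, 650, 3)
  r3 <- annotate_circ(j3, m, samples)
  expect_equal(r3$circ_type, "ciRNA-like")
  expect_equal(r3$gene_name, "GA")
  expect_equal(length(r3$block_starts[[1]]), 1L)
  # intergenic fallback
  j4 <- toy_junctions("chr1", 9000, 9500, 2)
  r4 <- annotate_circ(j4, m, samples)
  expect_equal(r4$circ_type, "intergenic")
  # minus-strand gene annotates with its own strand
  j5 <- toy_junctions("chr1", 3400, 4000, 4, strand = ".")
  r5 <- annotate_circ(j5, m, samples)
  expect_equal(r5$strand, "-")
  expect_equal(length(r5$block_starts[[1]]), 2L)
})

test_that("annotate equals the exhaustive boundary-pair matcher", {
  for (seed in c(11, 12, 13)) {
    m <- random_models(15, seed = seed)
    idx <- build_splice_site_index(m)
    set.seed(seed + 100)
    bounds_s <- unlist(m$exon_starts); bounds_e <- unlist(m$exon_ends)
    for (rep in 1:15) {
      s <- sample(bounds_s, 1) + sample(-3:3, 1)
      e <- sample(bounds_e[bounds_e > s + 3], 1) + sample(-3:3, 1)
      got <- realign_and_snap("chrR", s, e, ".", idx, tolerance = 2)
      want <- brute_force_matches(m, "chrR", s, e, ".", 2)
      if (is.null(want)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(got$isoform_name, want$isoform_name)
        expect_equal(got$snapped_start, want$snapped_start)
        expect_equal(got$snapped_end, want$snapped_end)
        expect_equal(got$offset, want$offset)
      }
    }
  }
})

test_that("circ BED12+6 writes and reads back identically", {
  sim <- tiny_sim(401, n_genes = 10)
  samples <- read_sample_sheet(sim$paths$samples)
  jn <- parse_junction_bed(sim$paths[["CL1_pAminus.backsplice"]],
                           "backsplice", samples[1, ])
  models <- read_genepred(sim$paths$annotation)
  recs <- annotate_circ(jn, models, samples)
  f <- withr::local_tempfile()
  write_circ_bed(recs, f)
  back <- read_circ_bed(f, library_id = recs$library_id[1])
  for (col in c("chrom", "start", "end", "name", "strand", "gene_name",
                "isoform_name", "read_count", "rpm", "circ_type",
                "start_status", "end_status", "block_starts", "block_sizes")) {
    expect_equal(back[[col]], recs[[col]], info = col)
  }
  # a second write of the re-read records is byte-identical
  f2 <- withr::local_tempfile()
  write_circ_bed(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed circ BED block structure errors on read", {
  f <- withr::local_tempfile()
  ok <- paste("chr1", 100, 900, "c1", 5, "+", 100, 900, "0,0,0", 2,
              "100,200,", "0,600,", 5, "5", "exonic", "G", "G.1",
              "annotated/annotated", sep = "\t")
  writeLines(ok, f)
  expect_silent(read_circ_bed(f))
  # last block does not reach end
  bad <- sub("100,200,", "100,100,", ok, fixed = TRUE)
  writeLines(bad, f)
  expect_error(read_circ_bed(f), "block structure")
  bad2 <- sub("\t2\t", "\t3\t", ok, fixed = TRUE)
  writeLines(bad2, f)
  expect_error(read_circ_bed(f), "blockCount")
})

test_that("planted junctions are recovered exactly, with and without jitter", {
  sim <- tiny_sim(402, n_genes = 15, jitter = 0)
  samples <- read_sample_sheet(sim$paths$samples)
  models <- read_genepred(sim$paths$annotation)
  jn <- parse_junction_bed(sim$paths[["CL1_pAminus.backsplice"]],
                           "backsplice", samples[1, ])
  recs <- annotate_circ(jn, models, samples)
  rep0 <- evaluate_recovery(sim$truth, recs)
  expect_equal(rep0$circ$precision, 1)
  expect_equal(rep0$circ$recall, 1)
  # jittered by <= 2 nt, tolerance 2: snapped coordinates equal planted ones
  simj <- tiny_sim(402, n_genes = 15, jitter = 2)
  jnj <- parse_junction_bed(simj$paths[["CL1_pAminus.backsplice"]],
                            "backsplice", samples[1, ])
  recsj <- annotate_circ(jnj, read_genepred(simj$paths$annotation), samples,
                         tolerance = 2)
  repj <- evaluate_recovery(simj$truth, recsj)
  expect_equal(repj$circ$recall, 1)
})
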