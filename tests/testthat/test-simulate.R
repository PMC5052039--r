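test_that("a degenerate one-locus config emits the expected evidence", {
  sim <- tiny_sim(701, n_genes = 1, exons_per_gene = c(4, 4),
                  p_circ_locus = 1, p_alt_backsplice = 0,
                  p_cassette = 0, p_retention = 0, p_alt_ss = 0,
                  p_control_pair = 0, depth_backsplice = 100)
  expect_equal(length(sim$truth$circ), 1L)
  cl <- sim$truth$circ[[1]]
  lines <- readLines(sim$paths[["CL1_pAminus.backsplice"]])
  expect_equal(length(lines), 1L)
  f <- strsplit(lines, "\t")[[1]]
  expect_equal(as.numeric(f[2]), cl$start)
  expect_equal(as.numeric(f[3]), cl$ends[1])
  expect_equal(as.numeric(f[5]), 100)
  # GT/AG context at the planted back-splice sites (strand-appropriate)
  g <- sim$genome
  if (cl$strand == "+") {
    expect_equal(genome_slice(g, cl$chrom, cl$ends[1], cl$ends[1] + 2), "GT")
    expect_equal(genome_slice(g, cl$chrom, cl$start - 2, cl$start), "AG")
  } else {
    expect_equal(genome_slice(g, cl$chrom, cl$start - 2, cl$start), "AC")
    expect_equal(genome_slice(g, cl$chrom, cl$ends[1], cl$ends[1] + 2), "CT")
  }
})

test_that("identical seeds give byte-identical outputs", {
  d1 <- file.path(tempfile("det"), "a")
  d2 <- file.path(tempfile("det"), "b")
  cfg <- sim_config(seed = 77, n_genes = 10, novel_frac = 0.2, jitter = 1)
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2, info = f)
  }
  # a different seed changes the outputs
  simulate_dataset(sim_config(seed = 78, n_genes = 10, novel_frac = 0.2,
                              jitter = 1), d2)
  expect_false(identical(
    readBin(file.path(d1, "genome.fa"), "raw", file.size(file.path(d1, "genome.fa"))),
    readBin(file.path(d2, "genome.fa"), "raw", file.size(file.path(d2, "genome.fa")))))
})

test_that("library types honor their RNA-fraction semantics", {
  libs <- data.frame(
    library_id = c("m", "p", "r", "rr"),
    rna_fraction = c("pA_minus", "pA_plus", "ribo_minus", "pA_minus_RNaseR"),
    cell_line = "CL1", total_mapped_reads = 1e6, stringsAsFactors = FALSE)
  sim <- tiny_sim(702, n_genes = 8, libraries = libs)
  # p(A)+ emits no back-splice junctions at all
  expect_equal(length(readLines(sim$paths[["p.backsplice"]])), 0L)
  expect_gt(length(readLines(sim$paths[["m.backsplice"]])), 0L)
  expect_gt(length(readLines(sim$paths[["rr.backsplice"]])), 0L)
  # RNase R: no linear-only junctions outside circ spans
  spans <- do.call(rbind, lapply(sim$truth$circ, function(cl)
    data.frame(start = cl$start, end = max(cl$ends))))
  rr <- utils::read.table(sim$paths[["rr.linear"]], sep = "\t")
  inside <- vapply(seq_len(nrow(rr)), function(i)
    any(spans$start <= rr$V2[i] & rr$V3[i] <= spans$end), logical(1))
  expect_true(all(inside))
  # ribo- carries linear junctions outside spans too
  rb <- utils::read.table(sim$paths[["r.linear"]], sep = "\t")
  expect_gt(nrow(rb), nrow(rr))
})

test_that("junction totals equal configured depths exactly", {
  sim <- tiny_sim(703, n_genes = 12, p_alt_backsplice = 1, p_circ_locus = 1,
                  exons_per_gene = c(5, 7), depth_backsplice = 250)
  bs <- utils::read.table(sim$paths[["CL1_pAminus.backsplice"]], sep = "\t")
  # per alternative locus, proximal + distal counts sum to the depth
  totals <- tapply(bs$V5, sub("_bs.$", "", bs$V4), sum)
  expect_true(all(totals == 250))
})

test_that("emitted junction coordinates stay within the configured jitter", {
  sim <- tiny_sim(704, n_genes = 12, jitter = 2)
  bs <- utils::read.table(sim$paths[["CL1_pAminus.backsplice"]], sep = "\t")
  planted <- unlist(lapply(sim$truth$circ, function(cl) c(cl$start, cl$ends)))
  for (x in c(bs$V2, bs$V3)) {
    expect_lte(min(abs(planted - x)), 2)
  }
})

test_that("p(A)+-only input yields zero circRNA calls", {
  sim <- tiny_sim(705, n_genes = 10)
  samples <- read_sample_sheet(sim$paths$samples)
  plib <- samples[samples$rna_fraction == "pA_plus", ]
  jn <- parse_junction_bed(sim$paths[["CL1_pAplus.backsplice"]],
                           "backsplice", plib)
  expect_equal(nrow(jn), 0L)
  recs <- annotate_circ(jn, read_genepred(sim$paths$annotation), samples)
  expect_equal(nrow(recs), 0L)
})

test_that("impossible geometry is rejected before writing", {
  expect_error(sim_config(intron_len = c(50, 80)), "impossible geometry")
  expect_error(sim_config(p_circ_locus = 1.2), "probabilities")
})

test_that("the manifest agrees with the written reference annotation", {
  sim <- tiny_sim(706, n_genes = 15, exons_per_gene = c(5, 8),
                  novel_frac = 0.3, p_cassette = 0, p_retention = 0,
                  p_alt_ss = 0, p_alt_backsplice = 0)
  ref <- read_genepred(sim$paths$annotation)
  ref_keys <- unlist(lapply(seq_len(nrow(ref)), function(i)
    paste(ref$chrom[i], ref$exon_starts[[i]], ref$exon_ends[[i]])))
  for (w in sim$truth$withheld) {
    expect_false(paste(w$chrom, w$start, w$end) %in% ref_keys)
  }
  full <- read_genepred(sim$paths$annotation_full)
  full_keys <- unlist(lapply(seq_len(nrow(full)), function(i)
    paste(full$chrom[i], full$exon_starts[[i]], full$exon_ends[[i]])))
  for (w in sim$truth$withheld) {
    expect_true(paste(w$chrom, w$start, w$end) %in% full_keys)
  }
})
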