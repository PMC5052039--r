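test_that("withheld exons are rediscovered from junction evidence", {
  sim <- tiny_sim(501, n_genes = 20, exons_per_gene = c(5, 8),
                  p_alt_backsplice = 0, novel_frac = 0.5,
                  p_cassette = 0, p_retention = 0, p_alt_ss = 0)
  expect_gt(length(sim$truth$withheld), 0)
  samples <- read_sample_sheet(sim$paths$samples)
  clib <- samples[samples$rna_fraction == "pA_minus", ]
  models <- read_genepred(sim$paths$annotation)
  recs <- annotate_circ(parse_junction_bed(
    sim$paths[["CL1_pAminus.backsplice"]], "backsplice", clib),
    models, samples)
  jn <- parse_junction_bed(sim$paths[["CL1_pAminus.linear"]], "linear", clib)
  genome <- read_genome_fasta(sim$paths$genome)
  nov <- discover_novel_exons(recs, jn, models, genome)
  rep <- evaluate_recovery(sim$truth, recs, novel = nov)
  expect_equal(rep$novel$recall, 1)
  expect_equal(rep$novel$precision, 1)
  # nothing withheld: zero novel calls
  sim0 <- tiny_sim(501, n_genes = 20, exons_per_gene = c(5, 8),
                   p_alt_backsplice = 0, novel_frac = 0,
                   p_cassette = 0, p_retention = 0, p_alt_ss = 0)
  models0 <- read_genepred(sim0$paths$annotation)
  recs0 <- annotate_circ(parse_junction_bed(
    sim0$paths[["CL1_pAminus.backsplice"]], "backsplice", clib),
    models0, samples)
  jn0 <- parse_junction_bed(sim0$paths[["CL1_pAminus.linear"]], "linear", clib)
  nov0 <- discover_novel_exons(recs0, jn0, models0,
                               read_genome_fasta(sim0$paths$genome))
  expect_equal(nrow(nov0), 0L)
})

test_that("novelty is tested against the union of reference sources", {
  sim <- tiny_sim(502, n_genes = 12, exons_per_gene = c(5, 7),
                  p_alt_backsplice = 0, novel_frac = 0.5,
                  p_cassette = 0, p_retention = 0, p_alt_ss = 0)
  samples <- read_sample_sheet(sim$paths$samples)
  clib <- samples[samples$rna_fraction == "pA_minus", ]
  models <- read_genepred(sim$paths$annotation)
  recs <- annotate_circ(parse_junction_bed(
    sim$paths[["CL1_pAminus.backsplice"]], "backsplice", clib),
    models, samples)
  jn <- parse_junction_bed(sim$paths[["CL1_pAminus.linear"]], "linear", clib)
  genome <- read_genome_fasta(sim$paths$genome)
  nov <- discover_novel_exons(recs, jn, models, genome)
  expect_gt(nrow(nov), 0)
  # add the withheld exons back as an "ensembl" source: union test makes
  # them non-novel even though refseq still lacks them
  wh <- sim$truth$withheld
  ens <- gene_models(
    vapply(wh, `[[`, character(1), "gene"),
    paste0(vapply(wh, `[[`, character(1), "gene"), ".ens"),
    vapply(wh, `[[`, character(1), "chrom"),
    vapply(wh, `[[`, character(1), "strand"),
    lapply(wh, `[[`, "start"), lapply(wh, `[[`, "end"),
    source_tag = "ensembl")
  union_models <- rbind(as.data.frame(models), as.data.frame(ens))
  class(union_models) <- c("gene_models", "data.frame")
  nov2 <- discover_novel_exons(recs, jn, union_models, genome)
  expect_equal(nrow(nov2), 0L)
  # monotone: enlarging the reference can only shrink the novel set
  expect_lte(nrow(nov2), nrow(nov))
})

test_that("candidates without canonical motifs are rejected", {
  sim <- tiny_sim(503, n_genes = 12, exons_per_gene = c(5, 7),
                  p_alt_backsplice = 0, novel_frac = 0.5,
                  p_cassette = 0, p_retention = 0, p_alt_ss = 0)
  samples <- read_sample_sheet(sim$paths$samples)
  clib <- samples[samples$rna_fraction == "pA_minus", ]
  models <- read_genepred(sim$paths$annotation)
  recs <- annotate_circ(parse_junction_bed(
    sim$paths[["CL1_pAminus.backsplice"]], "backsplice", clib),
    models, samples)
  jn <- parse_junction_bed(sim$paths[["CL1_pAminus.linear"]], "linear", clib)
  genome <- read_genome_fasta(sim$paths$genome)
  nov <- discover_novel_exons(recs, jn, models, genome)
  expect_gt(nrow(nov), 0)
  # destroy the acceptor AG (plus strand) / donor AC (minus strand)
  # upstream of every discovered exon; rediscovery must drop them
  seqstr <- genome[["chr1"]]
  for (i in seq_len(nrow(nov))) {
    substr(seqstr, nov$start[i] - 1, nov$start[i]) <- "NN"
  }
  genome2 <- structure(stats::setNames(seqstr, "chr1"), class = "genome_seq")
  nov2 <- discover_novel_exons(recs, jn, models, genome2)
  expect_equal(nrow(nov2), 0L)
  # but with the motif gate off they come back
  nov3 <- discover_novel_exons(recs, jn, models, genome2,
                               require_motif = FALSE)
  expect_gte(nrow(nov3), nrow(nov))
})

test_that("splice-strength PWM scores behave like a log-odds model", {
  sim <- tiny_sim(504, n_genes = 20)
  model <- train_splice_strength(sim$models_full, sim$genome, min_sites = 20)
  expect_s3_class(model, "splice_strength_model")
  # GT / AG are fixed in the simulated genome, so the consensus carries them
  expect_equal(substr(model$donor_consensus, 4, 5), "GT")
  expect_equal(substr(model$acceptor_consensus, 19, 20), "AG")
  cons <- score_splice_site(model, model$donor_consensus, "donor")
  # consensus is the argmax of the matrix: nothing scores higher
  set.seed(8)
  rnd <- replicate(500, score_splice_site(
    model, rand_dna(9), "donor"))
  expect_true(all(rnd <= cons))
  expect_lt(mean(rnd), cons)
  # a non-GT donor window is penalized but finite
  w <- model$donor_consensus
  substr(w, 4, 5) <- "CC"
  expect_true(is.finite(score_splice_site(model, w, "donor")))
  expect_lt(score_splice_site(model, w, "donor"), cons)
  expect_error(score_splice_site(model, "ACGT", "donor"), "9 nt")
  expect_error(train_splice_strength(sim$models_full, sim$genome,
                                     min_sites = 1e5), "insufficient")
})

test_that("strand-correct window extraction makes scores strand-invariant", {
  sim <- tiny_sim(505, n_genes = 16)
  g <- sim$genome
  m <- sim$models_full
  model <- train_splice_strength(m, g, min_sites = 20)
  minus <- m[m$strand == "-", ][1, ]
  s <- minus$exon_starts[[1]]; e <- minus$exon_ends[[1]]
  # a minus-strand internal donor is the genomic start of a non-first
  # (transcript sense) exon; its window equals the revcomp construction
  d <- s[2]
  w_minus <- circkit:::donor_window(g, minus$chrom, d, "-")
  manual <- revcomp(genome_slice(g, minus$chrom, d - 6, d + 3))
  expect_identical(w_minus, manual)
  expect_equal(substr(w_minus, 4, 5), "GT")
  a <- e[2]
  wa <- circkit:::acceptor_window(g, minus$chrom, a, "-")
  expect_equal(substr(wa, 19, 20), "AG")
})

test_that("exon characterization: GC, ESE density", {
  g <- structure(stats::setNames(
    paste0("GGCC", "ATAT", paste(rep("A", 992), collapse = "")), "chrT"),
    class = "genome_seq")
  ex <- data.frame(chrom = "chrT", start = c(0, 4), end = c(4, 8),
                   strand = "+", stringsAsFactors = FALSE)
  ch <- characterize_exons(ex, g)
  expect_equal(ch$gc_fraction, c(1, 0))
  # 1000-nt exon with 5 planted motif hits: density 5/kb; count checked
  # against an independent sliding-window scan
  set.seed(31)
  motif <- "GAAGAA"
  body <- strsplit(paste(sample(c("C", "T"), 1000, TRUE), collapse = ""), "")[[1]]
  for (pos in c(10, 200, 400, 600, 800)) {
    body[pos:(pos + 5)] <- strsplit(motif, "")[[1]]
  }
  seqstr <- paste(body, collapse = "")
  sliding <- sum(vapply(1:995, function(i)
    substr(seqstr, i, i + 5) == motif, logical(1)))
  expect_equal(sliding, 5L)
  g2 <- structure(stats::setNames(seqstr, "chrT"), class = "genome_seq")
  ex2 <- data.frame(chrom = "chrT", start = 0, end = 1000, strand = "+")
  ch2 <- characterize_exons(ex2, g2, ese_motifs = motif)
  expect_equal(ch2$ese_per_kb, 5)
  # all-N exon: undefined GC, not an error
  gN <- structure(stats::setNames("NNNNNNNN", "chrT"), class = "genome_seq")
  chN <- characterize_exons(data.frame(chrom = "chrT", start = 0, end = 8,
                                       strand = "+"), gN)
  expect_true(is.na(chN$gc_fraction))
})
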