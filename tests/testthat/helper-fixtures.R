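# Shared fixture builders. Everything is generated in code; nothing binary.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# a small hand-built annotation: two genes on opposite strands
toy_models <- function() {
  gene_models(
    gene_name = c("GA", "GA", "GB"),
    isoform_name = c("GA.1", "GA.2", "GB.1"),
    chrom = "chr1",
    strand = c("+", "+", "-"),
    exon_starts = list(c(100, 300, 700, 1200, 1600),
                       c(100, 300, 700, 1200),
                       c(3000, 3400, 3800, 4200)),
    exon_ends = list(c(200, 400, 900, 1300, 1700),
                     c(200, 400, 900, 1300),
                     c(3200, 3600, 4000, 4400)),
    source_tag = c("refseq", "refseq", "refseq"))
}

toy_samples <- function() {
  validate_sample_sheet(data.frame(
    library_id = c("L1", "L2", "L3"),
    rna_fraction = c("pA_minus", "pA_plus", "ribo_minus"),
    total_mapped_reads = c(1e6, 1e6, 1e6),
    cell_line = "CL1", stringsAsFactors = FALSE))
}

toy_junctions <- function(chrom, start, end, read_count, strand = "+",
                          library_id = "L1") {
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = paste0("j", seq_along(start)),
                   read_count = read_count, strand = strand,
                   library_id = library_id, stringsAsFactors = FALSE)
  class(df) <- c("junctions", "data.frame")
  df
}

# independent brute-force matcher: every (exon start, exon end) boundary
# pair of every isoform, naive loops -- the oracle for realign_and_snap and
# annotate
brute_force_matches <- function(models, chrom, start, end, strand, tolerance) {
  hits <- list()
  for (i in seq_len(nrow(models))) {
    if (models$chrom[i] != chrom) next
    if (strand != "." && models$strand[i] != strand) next
    es <- models$exon_starts[[i]]; ee <- models$exon_ends[[i]]
    best <- NULL
    for (s in es) for (e in ee) {
      if (abs(s - start) <= tolerance && abs(e - end) <= tolerance && s < e) {
        off <- abs(s - start) + abs(e - end)
        cand <- c(s = s, e = e, off = off)
        if (is.null(best) || off < best["off"] ||
            (off == best["off"] &&
             (abs(s - start) < abs(best["s"] - start) ||
              (abs(s - start) == abs(best["s"] - start) && s < best["s"]) ||
              (s == best["s"] &&
               (abs(e - end) < abs(best["e"] - end) ||
                (abs(e - end) == abs(best["e"] - end) && e < best["e"])))))) {
          best <- cand
        }
      }
    }
    if (!is.null(best)) {
      hits[[length(hits) + 1L]] <- data.frame(
        model = i, isoform_name = models$isoform_name[i],
        snapped_start = best[["s"]], snapped_end = best[["e"]],
        offset = best[["off"]], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(NULL)
  out <- do.call(rbind, hits)
  out[order(out$offset, out$isoform_name), , drop = FALSE]
}

# a random small annotation for oracle-equivalence tests
random_models <- function(n_genes, seed) {
  set.seed(seed)
  starts <- list(); ends <- list(); strands <- character(n_genes)
  pos <- 0
  for (g in seq_len(n_genes)) {
    pos <- pos + sample(200:500, 1)
    n_ex <- sample(2:6, 1)
    s <- numeric(n_ex); e <- numeric(n_ex)
    for (k in seq_len(n_ex)) {
      s[k] <- pos; pos <- pos + sample(50:150, 1); e[k] <- pos
      pos <- pos + sample(100:300, 1)
    }
    starts[[g]] <- s; ends[[g]] <- e
    strands[g] <- sample(c("+", "-"), 1)
  }
  gene_models(sprintf("G%d", seq_len(n_genes)),
              sprintf("G%d.1", seq_len(n_genes)),
              "chrR", strands, starts, ends, "refseq")
}

# two 2-kb "introns" with an optional planted complementary element pair
plant_rc_pair <- function(seed, len_a = 2000, len_b = 2000, arm = 60,
                          pos_a = 500, pos_b = 1000, same_orientation = FALSE) {
  set.seed(seed)
  a <- rand_dna(len_a); b <- rand_dna(len_b)
  e <- rand_dna(arm)
  substr(a, pos_a + 1, pos_a + arm) <- e
  substr(b, pos_b + 1, pos_b + arm) <- if (same_orientation) e else revcomp(e)
  list(a = a, b = b, elem = e)
}

tiny_sim <- function(seed, ...) {
  cfg <- sim_config(seed = seed, ...)
  simulate_dataset(cfg, file.path(tempfile("sim"), "out"))
}
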