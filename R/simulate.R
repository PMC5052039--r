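#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: a genome with GT/AG-motif splice sites, multi-exon genes on both
#' strands, circRNA loci with single or alternative back-splice sites,
#' intra-circRNA splicing designs (cassette exon, intron retention,
#' alternative splice site) with separate circular and linear inclusion
#' fractions, orientation-opposite complementary elements planted in
#' flanking introns, and per-library junction evidence drawn multinomially
#' at configured depth. One integer seed determines all outputs.
#'
#' @param seed integer seed; all stochastic draws flow from it.
#' @param n_genes number of genes.
#' @param exons_per_gene inclusive range of exon counts per gene.
#' @param exon_len,intron_len,intergenic inclusive length ranges (nt).
#' @param minus_strand_frac fraction of genes on the minus strand.
#' @param p_circ_locus probability a (>= 4 exon) gene hosts a circRNA locus.
#' @param p_alt_backsplice probability a circ locus (>= 5 exon gene) uses two
#'   alternative back-splice sites.
#' @param p_proximal range (or single value) of the true proximal-site
#'   fraction of alternative loci.
#' @param p_cassette,p_retention,p_alt_ss probabilities of the three
#'   intra-circRNA splicing designs on single-site loci (applied in that
#'   order, mutually exclusive).
#' @param psi_circ,psi_lin,pir_circ,pir_lin,psu_circ,psu_lin ranges (or
#'   single values) for the circular/linear inclusion, retention and
#'   splice-site usage fractions.
#' @param element_len length of planted complementary elements (nt).
#' @param element_placement named probabilities for alternative loci:
#'   `both`, `proximal`, `distal`, `none`.
#' @param p_control_pair probability a single-site locus carries one
#'   flanking complementary pair (the background rate).
#' @param libraries data frame (library_id, rna_fraction, cell_line,
#'   total_mapped_reads).
#' @param depth_backsplice back-splice junction reads per circ locus.
#' @param depth_linear reads per constitutive linear junction.
#' @param depth_splice informative reads per designed splicing event.
#' @param jitter max +/- nt of coordinate noise on emitted back-splice
#'   junctions (default 0).
#' @param novel_frac fraction of eligible internal exons withheld from the
#'   reference annotation to create "novel" exons (default 0).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, exons_per_gene = c(4L, 7L),
                       exon_len = c(80L, 200L), intron_len = c(300L, 800L),
                       intergenic = c(300L, 800L), minus_strand_frac = 0.5,
                       p_circ_locus = 0.8, p_alt_backsplice = 0.4,
                       p_proximal = c(0.2, 0.8),
                       p_cassette = 0.25, p_retention = 0.2, p_alt_ss = 0.15,
                       psi_circ = c(0.6, 0.95), psi_lin = c(0.05, 0.4),
                       pir_circ = c(0.3, 0.8), pir_lin = c(0.0, 0.1),
                       psu_circ = c(0.55, 0.9), psu_lin = c(0.9, 0.98),
                       element_len = 60L,
                       element_placement = c(both = 0.5, proximal = 0.15,
                                             distal = 0.15, none = 0.2),
                       p_control_pair = 0.2,
                       libraries = NULL,
                       depth_backsplice = 200L, depth_linear = 100L,
                       depth_splice = 200L, jitter = 0L, novel_frac = 0) {
  if (is.null(libraries)) {
    libraries <- data.frame(
      library_id = c("CL1_pAminus", "CL1_pAplus"),
      rna_fraction = c("pA_minus", "pA_plus"),
      cell_line = "CL1", total_mapped_reads = 1e6,
      stringsAsFactors = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = exons_per_gene, exon_len = exon_len,
              intron_len = intron_len, intergenic = intergenic,
              minus_strand_frac = minus_strand_frac,
              p_circ_locus = p_circ_locus,
              p_alt_backsplice = p_alt_backsplice, p_proximal = p_proximal,
              p_cassette = p_cassette, p_retention = p_retention,
              p_alt_ss = p_alt_ss, psi_circ = psi_circ, psi_lin = psi_lin,
              pir_circ = pir_circ, pir_lin = pir_lin,
              psu_circ = psu_circ, psu_lin = psu_lin,
              element_len = as.integer(element_len),
              element_placement = element_placement,
              p_control_pair = p_control_pair, libraries = libraries,
              depth_backsplice = as.integer(depth_backsplice),
              depth_linear = as.integer(depth_linear),
              depth_splice = as.integer(depth_splice),
              jitter = as.integer(jitter), novel_frac = novel_frac)
  probs <- c(cfg$p_circ_locus, cfg$p_alt_backsplice, cfg$p_cassette,
             cfg$p_retention, cfg$p_alt_ss, cfg$p_control_pair,
             cfg$novel_frac, cfg$element_placement)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]", call. = FALSE)
  need <- if (sum(cfg$element_placement[c("both")]) > 0) 2L * cfg$element_len + 90L
          else cfg$element_len + 50L
  if (min(cfg$intron_len) < need) {
    stop(sprintf("impossible geometry: introns (min %d nt) cannot host %d-nt elements",
                 min(cfg$intron_len), cfg$element_len), call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

rand_len <- function(range) {
  if (length(range) == 1L || range[1] == range[2]) return(as.integer(range[1]))
  sample(seq(range[1], range[2]), 1L)
}

rand_frac <- function(range) {
  if (length(range) == 1L) return(range)
  stats::runif(1, range[1], range[2])
}

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Generate a complete synthetic fixture set with ground truth
#'
#' Writes, under `outdir`: `genome.fa`, `annotation.genepred` (the
#' reference annotation, with any withheld exons removed),
#' `annotation_full.genepred` (the complete truth models, labelled
#' synthetic), `samples.tsv`, `manifest.json`, and per library
#' `<id>.backsplice.bed`, `<id>.linear.bed`, `<id>.boundaries.tsv`.
#' p(A)+ libraries emit no back-splice junctions; p(A)-/RNase R libraries
#' emit no linear-only junctions outside circRNA spans; junction read
#' totals equal the configured depths exactly (multinomial draws with fixed
#' totals). Identical seeds produce byte-identical outputs.
#'
#' @param config a `sim_config`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the truth manifest, the full and
#'   reference models, the genome and the written paths.
#' @export
simulate_dataset <- function(config, outdir) {
  set.seed(config$seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  chrom <- "chr1"
  pieces <- character(0)
  cursor <- 0L
  genes <- list()
  for (g in seq_len(config$n_genes)) {
    gap <- rand_len(config$intergenic)
    pieces <- c(pieces, rand_seq(gap)); cursor <- cursor + gap
    n_ex <- rand_len(config$exons_per_gene)
    strand <- if (stats::runif(1) < config$minus_strand_frac) "-" else "+"
    ex_lens <- vapply(seq_len(n_ex), function(i) rand_len(config$exon_len),
                      integer(1))
    in_lens <- if (n_ex > 1)
      vapply(seq_len(n_ex - 1L), function(i) rand_len(config$intron_len),
             integer(1)) else integer(0)
    starts <- numeric(n_ex); ends <- numeric(n_ex)
    pos <- cursor
    for (k in seq_len(n_ex)) {
      starts[k] <- pos; ends[k] <- pos + ex_lens[k]
      pieces <- c(pieces, rand_seq(ex_lens[k]))
      pos <- ends[k]
      if (k < n_ex) {
        intron <- rand_seq(in_lens[k])
        if (strand == "+") {
          substr(intron, 1, 2) <- "GT"
          substr(intron, in_lens[k] - 1L, in_lens[k]) <- "AG"
        } else {
          substr(intron, 1, 2) <- "CT"
          substr(intron, in_lens[k] - 1L, in_lens[k]) <- "AC"
        }
        pieces <- c(pieces, intron)
        pos <- pos + in_lens[k]
      }
    }
    cursor <- pos
    genes[[g]] <- list(gene = sprintf("GENE%03d", g),
                       iso = sprintf("GENE%03d.1", g),
                       chrom = chrom, strand = strand,
                       starts = starts, ends = ends)
  }
  tail_gap <- rand_len(config$intergenic)
  pieces <- c(pieces, rand_seq(tail_gap))
  genome <- structure(stats::setNames(paste(pieces, collapse = ""), chrom),
                      class = "genome_seq")

  # --- circRNA locus designs ------------------------------------------------
  circ <- list(); splice <- list(); elements <- list()
  for (g in seq_along(genes)) {
    gn <- genes[[g]]
    n_ex <- length(gn$starts)
    if (n_ex < 4L || stats::runif(1) >= config$p_circ_locus) next
    alt <- n_ex >= 5L && stats::runif(1) < config$p_alt_backsplice
    if (alt) {
      first <- 2L; prox_last <- 3L; dist_last <- 4L
      p <- rand_frac(config$p_proximal)
      circ[[length(circ) + 1L]] <- list(
        gene = gn$gene, chrom = gn$chrom, strand = gn$strand, design = "alt",
        start = gn$starts[first],
        ends = c(gn$ends[prox_last], gn$ends[dist_last]),
        first = first, lasts = c(prox_last, dist_last), p_proximal = p)
      placement <- sample(names(config$element_placement), 1L,
                          prob = config$element_placement)
      if (placement != "none") {
        elements[[length(elements) + 1L]] <- plant_elements(
          genome, gn, first, prox_last, dist_last, placement,
          config$element_len)
        genome <- elements[[length(elements)]]$genome
        elements[[length(elements)]]$genome <- NULL
      }
    } else {
      first <- 2L; last <- min(4L, n_ex - 1L)
      circ[[length(circ) + 1L]] <- list(
        gene = gn$gene, chrom = gn$chrom, strand = gn$strand,
        design = "single", start = gn$starts[first], ends = gn$ends[last],
        first = first, lasts = last, p_proximal = NA_real_)
      if (stats::runif(1) < config$p_control_pair) {
        elements[[length(elements) + 1L]] <- plant_elements(
          genome, gn, first, last, NA, "control", config$element_len)
        genome <- elements[[length(elements)]]$genome
        elements[[length(elements)]]$genome <- NULL
      }
      # intra-circRNA splicing design (needs an internal exon in the span)
      if (last - first >= 2L) {
        mid <- first + 1L
        u <- stats::runif(1)
        if (u < config$p_cassette) {
          splice[[length(splice) + 1L]] <- list(
            type = "cassette_exon", gene = gn$gene, chrom = gn$chrom,
            strand = gn$strand, region_start = gn$starts[mid],
            region_end = gn$ends[mid], exon = mid,
            p_circ = rand_frac(config$psi_circ),
            p_lin = rand_frac(config$psi_lin))
        } else if (u < config$p_cassette + config$p_retention) {
          splice[[length(splice) + 1L]] <- list(
            type = "intron_retention", gene = gn$gene, chrom = gn$chrom,
            strand = gn$strand, region_start = gn$ends[first],
            region_end = gn$starts[first + 1L], intron_after = first,
            p_circ = rand_frac(config$pir_circ),
            p_lin = rand_frac(config$pir_lin))
        } else if (u < config$p_cassette + config$p_retention + config$p_alt_ss) {
          splice[[length(splice) + 1L]] <- list(
            type = "alt_ss", gene = gn$gene, chrom = gn$chrom,
            strand = gn$strand, region_start = gn$starts[mid],
            region_end = gn$starts[mid] + 6L, exon = mid,
            p_circ = rand_frac(config$psu_circ),
            p_lin = rand_frac(config$psu_lin))
        }
      }
    }
  }

  # --- withheld ("novel") exons --------------------------------------------
  design_exons <- vapply(splice, function(s)
    paste(s$gene, if (!is.null(s$exon)) s$exon else -1L), character(1))
  eligible <- list()
  for (cl in circ) {
    g <- which(vapply(genes, `[[`, character(1), "gene") == cl$gene)
    span_last <- max(cl$lasts)
    inner <- setdiff(seq(cl$first, span_last), c(cl$first, cl$lasts))
    for (k in inner) {
      if (paste(cl$gene, k) %in% design_exons) next
      eligible[[length(eligible) + 1L]] <- list(gene_idx = g, exon = k)
    }
  }
  withheld <- list()
  if (config$novel_frac > 0 && length(eligible) > 0) {
    n_wh <- max(1L, round(config$novel_frac * length(eligible)))
    pick <- sample(seq_along(eligible), min(n_wh, length(eligible)))
    withheld <- eligible[pick]
  }

  models_full <- gene_models(
    vapply(genes, `[[`, character(1), "gene"),
    vapply(genes, `[[`, character(1), "iso"),
    vapply(genes, `[[`, character(1), "chrom"),
    vapply(genes, `[[`, character(1), "strand"),
    lapply(genes, `[[`, "starts"), lapply(genes, `[[`, "ends"),
    source_tag = "synthetic")
  ref_starts <- lapply(genes, `[[`, "starts")
  ref_ends <- lapply(genes, `[[`, "ends")
  for (w in withheld) {
    ref_starts[[w$gene_idx]] <- ref_starts[[w$gene_idx]][-w$exon]
    ref_ends[[w$gene_idx]] <- ref_ends[[w$gene_idx]][-w$exon]
  }
  models_ref <- gene_models(
    vapply(genes, `[[`, character(1), "gene"),
    vapply(genes, `[[`, character(1), "iso"),
    vapply(genes, `[[`, character(1), "chrom"),
    vapply(genes, `[[`, character(1), "strand"),
    ref_starts, ref_ends, source_tag = "refseq")

  # --- per-library evidence -------------------------------------------------
  libs <- config$libraries
  paths <- list(genome = file.path(outdir, "genome.fa"),
                annotation = file.path(outdir, "annotation.genepred"),
                annotation_full = file.path(outdir, "annotation_full.genepred"),
                samples = file.path(outdir, "samples.tsv"),
                manifest = file.path(outdir, "manifest.json"))
  write_genome_fasta(genome, paths$genome)
  write_genepred(models_ref, paths$annotation)
  write_genepred(models_full, paths$annotation_full)
  write_sample_sheet(validate_sample_sheet(libs), paths$samples)

  gene_by_name <- stats::setNames(genes, vapply(genes, `[[`, character(1), "gene"))
  splice_by_gene <- stats::setNames(splice, vapply(splice, `[[`, character(1), "gene"))
  for (li in seq_len(nrow(libs))) {
    lib <- libs[li, ]
    bs_rows <- character(0)
    lin <- list()  # accumulated junction counts keyed by start/end
    bnd <- list()
    add_lin <- function(start, end, n) {
      if (n <= 0) return(invisible())
      key <- paste(start, end)
      lin[[key]] <<- (if (is.null(lin[[key]])) 0 else lin[[key]]) + n
    }
    circ_side <- lib$rna_fraction %in% c("pA_minus", "pA_minus_RNaseR", "ribo_minus")
    linear_side <- lib$rna_fraction %in% c("pA_plus", "ribo_minus")
    if (circ_side) {
      for (ci in seq_along(circ)) {
        cl <- circ[[ci]]
        if (cl$design == "alt") {
          counts <- as.vector(stats::rmultinom(1, config$depth_backsplice,
                                               c(cl$p_proximal, 1 - cl$p_proximal)))
        } else {
          counts <- config$depth_backsplice
        }
        for (s in seq_along(cl$ends)) {
          js <- cl$start; je <- cl$ends[s]
          if (config$jitter > 0) {
            js <- js + sample(seq(-config$jitter, config$jitter), 1L)
            je <- je + sample(seq(-config$jitter, config$jitter), 1L)
          }
          bs_rows <- c(bs_rows, sprintf("%s\t%d\t%d\t%s_bs%d\t%d\t%s",
                                        cl$chrom, as.integer(js), as.integer(je),
                                        cl$gene, s, counts[s], cl$strand))
        }
        # circRNA-internal linear junctions over the full (truth) model
        gn <- gene_by_name[[cl$gene]]
        span_last <- max(cl$lasts)
        des <- splice_by_gene[[cl$gene]]
        for (k in seq(cl$first, span_last - 1L)) {
          istart <- gn$ends[k]; iend <- gn$starts[k + 1L]
          if (!is.null(des) && des$type == "intron_retention" &&
              des$intron_after == k) {
            r <- stats::rbinom(1, config$depth_splice, des$p_circ)
            bnd[[length(bnd) + 1L]] <- data.frame(
              chrom = cl$chrom, pos = c(istart, iend), kind = c("ei", "ie"),
              read_count = r, library_id = lib$library_id,
              stringsAsFactors = FALSE)
            add_lin(istart, iend, config$depth_splice - r)
          } else if (!is.null(des) && des$type == "cassette_exon" &&
                     des$exon == k + 1L) {
            incl <- stats::rbinom(1, config$depth_splice, des$p_circ)
            add_lin(gn$ends[k], gn$starts[k + 1L], incl)
            add_lin(gn$ends[k + 1L], gn$starts[k + 2L], incl)
            add_lin(gn$ends[k], gn$starts[k + 2L], config$depth_splice - incl)
          } else if (!is.null(des) && des$type == "cassette_exon" &&
                     des$exon == k) {
            # downstream inclusion junction already emitted with the exon
          } else if (!is.null(des) && des$type == "alt_ss" && des$exon == k + 1L) {
            cts <- as.vector(stats::rmultinom(1, config$depth_splice,
                                              c(des$p_circ, 1 - des$p_circ)))
            add_lin(gn$ends[k], gn$starts[k + 1L], cts[1])
            add_lin(gn$ends[k], gn$starts[k + 1L] + 6L, cts[2])
          } else {
            add_lin(istart, iend, config$depth_splice)
          }
        }
      }
    }
    if (linear_side) {
      for (gn in genes) {
        n_ex <- length(gn$starts)
        if (n_ex < 2L) next
        gi <- which(vapply(genes, `[[`, character(1), "gene") == gn$gene)
        wh_exons <- vapply(withheld, function(w)
          if (w$gene_idx == gi) w$exon else -1L, numeric(1))
        des <- splice_by_gene[[gn$gene]]
        k <- 1L
        while (k < n_ex) {
          nxt <- k + 1L
          while (nxt <= n_ex && nxt %in% wh_exons) nxt <- nxt + 1L
          if (nxt > n_ex) break
          istart <- gn$ends[k]; iend <- gn$starts[nxt]
          if (!is.null(des) && des$type == "intron_retention" &&
              des$intron_after == k) {
            r <- stats::rbinom(1, config$depth_splice, des$p_lin)
            bnd[[length(bnd) + 1L]] <- data.frame(
              chrom = gn$chrom, pos = c(istart, iend), kind = c("ei", "ie"),
              read_count = r, library_id = lib$library_id,
              stringsAsFactors = FALSE)
            add_lin(istart, iend, config$depth_splice - r)
          } else if (!is.null(des) && des$type == "cassette_exon" &&
                     des$exon == nxt) {
            incl <- stats::rbinom(1, config$depth_splice, des$p_lin)
            add_lin(gn$ends[k], gn$starts[nxt], incl)
            add_lin(gn$ends[nxt], gn$starts[nxt + 1L], incl)
            add_lin(gn$ends[k], gn$starts[nxt + 1L], config$depth_splice - incl)
            nxt <- nxt + 1L  # downstream junction handled
          } else if (!is.null(des) && des$type == "alt_ss" && des$exon == nxt) {
            cts <- as.vector(stats::rmultinom(1, config$depth_splice,
                                              c(des$p_lin, 1 - des$p_lin)))
            add_lin(gn$ends[k], gn$starts[nxt], cts[1])
            add_lin(gn$ends[k], gn$starts[nxt] + 6L, cts[2])
          } else {
            add_lin(istart, iend, config$depth_linear)
          }
          k <- nxt
        }
      }
    }
    bs_path <- file.path(outdir, paste0(lib$library_id, ".backsplice.bed"))
    writeLines(bs_rows, bs_path)
    lin_path <- file.path(outdir, paste0(lib$library_id, ".linear.bed"))
    keys <- names(lin)
    if (length(keys)) {
      parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
      ord <- order(as.numeric(parts[, 1]), as.numeric(parts[, 2]))
      writeLines(sprintf("%s\t%s\t%s\tlj%d\t%d\t.", chrom,
                         parts[ord, 1], parts[ord, 2], seq_along(keys),
                         as.integer(unlist(lin))[ord]), lin_path)
    } else writeLines(character(0), lin_path)
    bnd_path <- file.path(outdir, paste0(lib$library_id, ".boundaries.tsv"))
    bnd_df <- if (length(bnd)) do.call(rbind, bnd) else
      data.frame(chrom = character(0), pos = numeric(0), kind = character(0),
                 read_count = numeric(0), library_id = character(0),
                 stringsAsFactors = FALSE)
    if (nrow(bnd_df)) bnd_df <- bnd_df[order(bnd_df$pos, bnd_df$kind), ]
    write_boundary_counts(bnd_df, bnd_path)
    paths[[paste0(lib$library_id, ".backsplice")]] <- bs_path
    paths[[paste0(lib$library_id, ".linear")]] <- lin_path
    paths[[paste0(lib$library_id, ".boundaries")]] <- bnd_path
  }

  truth <- list(
    chrom = chrom,
    circ = lapply(circ, function(cl) cl[c("gene", "chrom", "strand", "design",
                                          "start", "ends", "first", "lasts",
                                          "p_proximal")]),
    splicing = splice,
    elements = lapply(elements, function(e) e[names(e) != "genome"]),
    withheld = lapply(withheld, function(w) {
      gn <- genes[[w$gene_idx]]
      list(gene = gn$gene, chrom = gn$chrom, strand = gn$strand,
           start = gn$starts[w$exon], end = gn$ends[w$exon])
    }),
    seed = config$seed)
  jsonlite::write_json(truth, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(truth = truth, models_full = models_full,
                 models_ref = models_ref, genome = genome, paths = paths,
                 config = config))
}

# overwrite intron interiors with complementary elements; returns modified
# genome plus a record of what was planted
plant_elements <- function(genome, gn, first, prox_last, dist_last, placement,
                           elem_len) {
  m <- list(exon_starts = list(gn$starts), exon_ends = list(gn$ends),
            strand = gn$strand)
  n_ex <- length(gn$starts)
  upstream_iv <- if (first > 1) c(gn$ends[first - 1L], gn$starts[first]) else NULL
  prox_iv <- if (prox_last < n_ex) c(gn$ends[prox_last], gn$starts[prox_last + 1L]) else NULL
  dist_iv <- if (!is.na(dist_last) && dist_last < n_ex)
    c(gn$ends[dist_last], gn$starts[dist_last + 1L]) else NULL
  seqstr <- genome[[gn$chrom]]
  planted <- list()
  put <- function(iv, offset, s) {
    pos <- iv[1] + offset
    stopifnot(pos + nchar(s) <= iv[2] - 2)
    substr(seqstr, pos + 1L, pos + nchar(s)) <<- s
    c(pos, pos + nchar(s))
  }
  plant_pair <- function(common_iv, var_iv, up_off) {
    e <- rand_seq(elem_len)
    arm1 <- put(common_iv, up_off, e)
    arm2 <- put(var_iv, 20L, revcomp(e))
    list(arm1 = arm1, arm2 = arm2)
  }
  if (placement %in% c("both", "proximal") && !is.null(upstream_iv) &&
      !is.null(prox_iv)) {
    planted$proximal <- plant_pair(upstream_iv, prox_iv, 20L)
  }
  if (placement %in% c("both", "distal") && !is.null(upstream_iv) &&
      !is.null(dist_iv)) {
    planted$distal <- plant_pair(upstream_iv, dist_iv, 20L + elem_len + 10L)
  }
  if (placement == "control" && !is.null(upstream_iv) && !is.null(prox_iv)) {
    planted$control <- plant_pair(upstream_iv, prox_iv, 20L)
  }
  genome[[gn$chrom]] <- seqstr
  out <- list(gene = gn$gene, placement = placement, genome = genome)
  for (nm in names(planted)) out[[nm]] <- planted[[nm]]
  out
}

#' Compare pipeline output against a simulation's ground truth
#'
#' Coordinates are compared exactly; metrics numerically.
#'
#' @param truth the `truth` element returned by [simulate_dataset()].
#' @param records `circ_records` called from the simulated evidence.
#' @param events optional `altbs_events` (one library) for PCU error
#'   assessment.
#' @param novel optional `novel_exons` for novel-exon recovery.
#' @param competition optional row-bound [classify_competition()] calls.
#' @return a list of recovery statistics.
#' @export
evaluate_recovery <- function(truth, records, events = NULL, novel = NULL,
                              competition = NULL) {
  true_keys <- unlist(lapply(truth$circ, function(cl) {
    paste(cl$chrom, cl$start, cl$ends, sep = "\r")
  }))
  called_keys <- unique(paste(records$chrom, records$start, records$end,
                              sep = "\r"))
  tp <- sum(called_keys %in% true_keys)
  out <- list(circ = list(
    precision = if (length(called_keys)) tp / length(called_keys) else NA_real_,
    recall = if (length(true_keys)) sum(true_keys %in% called_keys) / length(true_keys)
             else NA_real_,
    n_called = length(called_keys), n_true = length(true_keys)))
  if (!is.null(events)) {
    errs <- numeric(0)
    for (cl in truth$circ) {
      if (cl$design != "alt") next
      sel <- which(events$chrom == cl$chrom & events$common_site == cl$start &
                     events$common_side == "start")
      if (length(sel) != 1L) next
      pcu <- events$pcu[[sel]]
      spans <- events$spans[[sel]]
      errs <- c(errs, abs(pcu[which.min(spans)] / 100 - cl$p_proximal))
    }
    out$pcu <- list(n_events = length(errs), mean_abs_error = mean(errs),
                    max_abs_error = if (length(errs)) max(errs) else NA_real_)
  }
  if (!is.null(novel)) {
    true_nov <- vapply(truth$withheld, function(w)
      paste(w$chrom, w$start, w$end, w$strand, sep = "\r"), character(1))
    got <- paste(novel$chrom, novel$start, novel$end, novel$strand, sep = "\r")
    out$novel <- list(
      recall = if (length(true_nov)) mean(true_nov %in% got) else NA_real_,
      precision = if (length(got)) mean(got %in% true_nov) else NA_real_,
      n_true = length(true_nov), n_called = length(got))
  }
  if (!is.null(competition)) {
    place <- vapply(truth$elements, `[[`, character(1), "placement")
    names(place) <- vapply(truth$elements, `[[`, character(1), "gene")
    alt_gene <- stats::setNames(
      vapply(truth$circ, `[[`, character(1), "gene"),
      vapply(truth$circ, function(cl) as.character(cl$start), character(1)))
    expected <- c(both = "competing", proximal = "proximal_only",
                  distal = "distal_only", none = "none")
    ev_gene <- alt_gene[as.character(competition$common_site)]
    ev_place <- place[ev_gene]
    ev_place[is.na(ev_place)] <- "none"
    out$competition <- table(truth = expected[ev_place],
                             called = competition$verdict)
  }
  out
}
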