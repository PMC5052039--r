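#' Discover previously unannotated exons inside circRNA spans
#'
#' Candidate exons come from two evidence routes: (a) exons of assembled
#' transcript models overlapping a circRNA span, and (b) intervals bounded
#' by the ends of two linear junctions inside a circRNA span whose implied
#' splice sites carry strand-appropriate GT/AG motifs in the genome. A
#' junction-bounded candidate is rejected when another junction lies
#' strictly inside it (a real exon has no spliced-out intron within it).
#' Candidates fully contained in (including equal to) a same-strand exon of
#' the reference union are not novel and are dropped; the reference union
#' is every model tagged refseq, known_genes or ensembl, so presence in any
#' one of the three sources disqualifies a candidate.
#'
#' @param records `circ_records` delimiting the search spans.
#' @param junctions linear `junctions` (circular-fraction evidence).
#' @param reference_models `gene_models` of the reference union.
#' @param genome a `genome_seq`; required for the motif gate.
#' @param assembled_models optional `gene_models` from de novo assembly.
#' @param require_motif require canonical GT/AG at the implied splice sites
#'   of junction-bounded candidates (default TRUE).
#' @return data frame of class `novel_exons`: chrom, start, end, strand,
#'   gene_name, evidence, basis.
#' @export
discover_novel_exons <- function(records, junctions, reference_models, genome,
                                 assembled_models = NULL, require_motif = TRUE) {
  if (require_motif && is.null(genome)) {
    stop("a genome is required for the GT/AG motif check", call. = FALSE)
  }
  cands <- list()
  add <- function(chrom, start, end, strand, gene, evidence, basis) {
    cands[[length(cands) + 1L]] <<- data.frame(
      chrom = chrom, start = start, end = end, strand = strand,
      gene_name = gene, evidence = evidence, basis = basis,
      stringsAsFactors = FALSE)
  }
  spans <- records[records$circ_type == "exonic" | records$circ_type == "intergenic", ,
                   drop = FALSE]
  if (!is.null(assembled_models) && nrow(assembled_models) > 0L) {
    for (i in seq_len(nrow(assembled_models))) {
      s <- assembled_models$exon_starts[[i]]; e <- assembled_models$exon_ends[[i]]
      for (k in seq_along(s)) {
        hit <- spans$chrom == assembled_models$chrom[i] &
          spans$start < e[k] & spans$end > s[k] &
          (spans$strand == assembled_models$strand[i] | spans$strand == ".")
        if (any(hit)) {
          add(assembled_models$chrom[i], s[k], e[k], assembled_models$strand[i],
              spans$gene_name[which(hit)[1]],
              assembled_models$isoform_name[i], "assembled")
        }
      }
    }
  }
  for (r in seq_len(nrow(spans))) {
    rec <- spans[r, ]
    jn <- junctions[junctions$chrom == rec$chrom &
                      junctions$start >= rec$start &
                      junctions$end <= rec$end &
                      (junctions$strand == rec$strand |
                         junctions$strand == "." | rec$strand == "."), ,
                    drop = FALSE]
    if (nrow(jn) < 2L) next
    strand <- if (rec$strand %in% c("+", "-")) rec$strand else "+"
    for (i in seq_len(nrow(jn))) {
      for (k in seq_len(nrow(jn))) {
        x <- jn$end[i]; y <- jn$start[k]
        if (x >= y) next
        inner <- jn$start > x & jn$end < y
        inner[c(i, k)] <- FALSE
        if (any(inner)) next
        if (require_motif && !splice_motifs_ok(genome, rec$chrom, x, y, strand)) next
        add(rec$chrom, x, y, strand, rec$gene_name,
            paste(jn$name[i], jn$name[k], sep = ";"), "junction")
      }
    }
  }
  out <- if (length(cands)) do.call(rbind, cands) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), gene_name = character(0),
               evidence = character(0), basis = character(0),
               stringsAsFactors = FALSE)
  out <- out[!duplicated(paste(out$chrom, out$start, out$end, out$strand)), ,
             drop = FALSE]
  novel <- !vapply(seq_len(nrow(out)), function(i) {
    contained_in_reference(reference_models, out$chrom[i], out$start[i],
                           out$end[i], out$strand[i])
  }, logical(1))
  out <- out[novel, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("novel_exons", "data.frame")
  out
}

# candidate fully contained in (or equal to) a same-strand reference exon?
contained_in_reference <- function(models, chrom, start, end, strand) {
  sel <- which(models$chrom == chrom & models$strand == strand)
  for (i in sel) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    if (any(s <= start & end <= e)) return(TRUE)
  }
  FALSE
}

# GT at the donor side and AG at the acceptor side of a putative exon
# [x, y) on the given strand (genomic-motif equivalents on minus strand)
splice_motifs_ok <- function(genome, chrom, x, y, strand) {
  len <- genome_lengths(genome)[[chrom]]
  if (x < 2 || y + 2 > len) return(FALSE)
  left <- genome_slice(genome, chrom, x - 2, x)
  right <- genome_slice(genome, chrom, y, y + 2)
  if (strand == "+") {
    left == "AG" && right == "GT"
  } else {
    left == "AC" && right == "CT"
  }
}

#' Train a position-weight-matrix splice-strength model
#'
#' Donor sites are scored over a 9-nt window (3 exonic + 6 intronic bases)
#' and acceptor sites over a 23-nt window (20 intronic + 3 exonic),
#' extracted strand-correctly from internal exon boundaries of the supplied
#' models. Position weights use a pseudocount of 1 per base per position;
#' the background is the overall base composition of the training windows.
#'
#' @param models `gene_models` used for training.
#' @param genome a `genome_seq`.
#' @param min_sites minimum number of training donors and acceptors
#'   (default 200; configurable for small synthetic genomes).
#' @return an object of class `splice_strength_model` with donor/acceptor
#'   probability matrices, background frequencies and consensus strings.
#' @export
train_splice_strength <- function(models, genome, min_sites = 200) {
  dw <- character(0); aw <- character(0)
  seen_d <- character(0); seen_a <- character(0)
  for (i in seq_len(nrow(models))) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    n <- length(s)
    if (n < 2L) next
    chrom <- models$chrom[i]; strand <- models$strand[i]
    if (strand == "+") {
      dco <- e[-n]; aco <- s[-1L]
    } else {
      dco <- s[-1L]; aco <- e[-n]
    }
    for (d in dco) {
      key <- paste(chrom, strand, d)
      if (key %in% seen_d) next
      w <- donor_window(genome, chrom, d, strand)
      if (!is.na(w)) { dw <- c(dw, w); seen_d <- c(seen_d, key) }
    }
    for (a in aco) {
      key <- paste(chrom, strand, a)
      if (key %in% seen_a) next
      w <- acceptor_window(genome, chrom, a, strand)
      if (!is.na(w)) { aw <- c(aw, w); seen_a <- c(seen_a, key) }
    }
  }
  if (length(dw) < min_sites || length(aw) < min_sites) {
    stop(sprintf("insufficient training sites (%d donors, %d acceptors; need %d)",
                 length(dw), length(aw), min_sites), call. = FALSE)
  }
  donor <- pwm_from_windows(dw, 9L)
  acceptor <- pwm_from_windows(aw, 23L)
  bg <- base_composition(c(dw, aw))
  structure(list(donor = donor, acceptor = acceptor, background = bg,
                 n_donor = length(dw), n_acceptor = length(aw),
                 donor_consensus = pwm_consensus(donor),
                 acceptor_consensus = pwm_consensus(acceptor)),
            class = "splice_strength_model")
}

# donor boundary coordinate -> 9-nt window (3 exonic + 6 intronic),
# transcript sense; NA if out of genome bounds
donor_window <- function(genome, chrom, coord, strand) {
  len <- genome_lengths(genome)[[chrom]]
  if (strand == "+") {
    if (coord < 3 || coord + 6 > len) return(NA_character_)
    genome_slice(genome, chrom, coord - 3, coord + 6)
  } else {
    if (coord < 6 || coord + 3 > len) return(NA_character_)
    revcomp(genome_slice(genome, chrom, coord - 6, coord + 3))
  }
}

# acceptor boundary coordinate -> 23-nt window (20 intronic + 3 exonic)
acceptor_window <- function(genome, chrom, coord, strand) {
  len <- genome_lengths(genome)[[chrom]]
  if (strand == "+") {
    if (coord < 20 || coord + 3 > len) return(NA_character_)
    genome_slice(genome, chrom, coord - 20, coord + 3)
  } else {
    if (coord < 3 || coord + 20 > len) return(NA_character_)
    revcomp(genome_slice(genome, chrom, coord - 3, coord + 20))
  }
}

BASES <- c("A", "C", "G", "T")

pwm_from_windows <- function(windows, width) {
  mat <- matrix(1, nrow = 4, ncol = width, dimnames = list(BASES, NULL))
  chars <- strsplit(windows, "", fixed = TRUE)
  for (w in chars) {
    for (p in seq_len(width)) {
      b <- w[p]
      if (b %in% BASES) mat[b, p] <- mat[b, p] + 1
    }
  }
  sweep(mat, 2, colSums(mat), "/")
}

base_composition <- function(windows) {
  tab <- table(factor(unlist(strsplit(windows, "", fixed = TRUE)), levels = BASES))
  tab <- tab + 1
  as.numeric(tab) / sum(tab) -> p
  names(p) <- BASES
  p
}

pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm, 2, which.max)], collapse = "")
}

#' Score a splice-site sequence window
#'
#' Log-odds in bits: `sum_p log2(weight[base, p] / background[base])`.
#' Positions with non-ACGT bases contribute 0. There is no hard rejection
#' of non-GT/AG windows; they simply score poorly.
#'
#' @param model a `splice_strength_model`.
#' @param window sequence window (9 nt for donors, 23 nt for acceptors).
#' @param type `"donor"` or `"acceptor"`.
#' @return log-odds score in bits.
#' @export
score_splice_site <- function(model, window, type = c("donor", "acceptor")) {
  type <- match.arg(type)
  pwm <- model[[type]]
  window <- toupper(window)
  if (nchar(window) != ncol(pwm)) {
    stop(sprintf("%s window must be %d nt, got %d", type, ncol(pwm),
                 nchar(window)), call. = FALSE)
  }
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  score <- 0
  for (p in seq_along(chars)) {
    b <- chars[p]
    if (b %in% BASES) {
      score <- score + log2(pwm[b, p] / model$background[[b]])
    }
  }
  score
}

#' Characterize exons: GC content, splice-site strength, ESE density
#'
#' GC fraction is (G+C)/(A+C+G+T) over the exon (NA when the exon has no
#' unambiguous base). ESE density counts overlapping matches of the
#' supplied hexamer motifs on the exon's sense sequence, per kilobase.
#' Splice-site scores are computed at the exon's own boundaries when a
#' strength model is given.
#'
#' @param exons data frame with chrom, start, end, strand.
#' @param genome a `genome_seq`.
#' @param ese_motifs optional character vector of hexamer motifs.
#' @param strength_model optional `splice_strength_model`.
#' @return data frame with gc_fraction, donor_score, acceptor_score,
#'   ese_per_kb.
#' @export
characterize_exons <- function(exons, genome, ese_motifs = NULL,
                               strength_model = NULL) {
  n <- nrow(exons)
  out <- data.frame(chrom = exons$chrom, start = exons$start, end = exons$end,
                    strand = exons$strand, gc_fraction = NA_real_,
                    donor_score = NA_real_, acceptor_score = NA_real_,
                    ese_per_kb = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    seq <- genome_slice(genome, exons$chrom[i], exons$start[i], exons$end[i])
    if (exons$strand[i] == "-") seq <- revcomp(seq)
    counts <- table(factor(strsplit(seq, "", fixed = TRUE)[[1]], levels = BASES))
    denom <- sum(counts)
    out$gc_fraction[i] <- if (denom > 0) (counts[["G"]] + counts[["C"]]) / denom
                          else NA_real_
    if (!is.null(ese_motifs)) {
      hits <- sum(vapply(ese_motifs, function(m) {
        g <- gregexpr(paste0("(?=", m, ")"), seq, perl = TRUE)[[1]]
        if (g[1] == -1) 0L else length(g)
      }, integer(1)))
      out$ese_per_kb[i] <- hits * 1000 / nchar(seq)
    }
    if (!is.null(strength_model)) {
      strand <- exons$strand[i]
      dcoord <- if (strand == "+") exons$end[i] else exons$start[i]
      acoord <- if (strand == "+") exons$start[i] else exons$end[i]
      dw <- donor_window(genome, exons$chrom[i], dcoord, strand)
      aw <- acceptor_window(genome, exons$chrom[i], acoord, strand)
      if (!is.na(dw)) out$donor_score[i] <- score_splice_site(strength_model, dw, "donor")
      if (!is.na(aw)) out$acceptor_score[i] <- score_splice_site(strength_model, aw, "acceptor")
    }
  }
  out
}

#' Write novel exons as BED6 plus evidence columns
#' @param exons a `novel_exons` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_novel_bed <- function(exons, path) {
  lines <- sprintf("%s\t%d\t%d\tnovel_%d\t0\t%s\t%s\t%s",
                   exons$chrom, as.integer(exons$start), as.integer(exons$end),
                   seq_len(nrow(exons)), exons$strand, exons$evidence,
                   exons$basis)
  writeLines(lines, path)
  invisible(path)
}
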