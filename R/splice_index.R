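#' Build a splice-site index over transcript models
#'
#' Classifies every exon boundary as donor or acceptor respecting strand
#' (plus strand: exon end = donor, exon start = acceptor; minus strand
#' mirrored) and records which models carry it. A boundary is flagged
#' terminal only if it is transcript-terminal in every model carrying it.
#'
#' @param models a `gene_models` object (non-empty).
#' @return an object of class `splice_site_index`: a data frame with columns
#'   chrom, strand, coord, kind (`"donor"`/`"acceptor"`), terminal, and a
#'   list column `models` of integer row indices into `models` (also stored
#'   as attribute `models`).
#' @export
build_splice_site_index <- function(models) {
  if (nrow(models) == 0L) stop("no models supplied", call. = FALSE)
  rows <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    n <- length(s)
    if (models$strand[i] == "+") {
      kind_s <- "acceptor"; kind_e <- "donor"
      term_s <- seq_len(n) == 1L; term_e <- seq_len(n) == n
    } else {
      # minus strand: the transcript-last exon (genomic first) has the
      # non-functional donor; the transcript-first exon (genomic last) the
      # non-functional acceptor
      kind_s <- "donor"; kind_e <- "acceptor"
      term_s <- seq_len(n) == 1L; term_e <- seq_len(n) == n
    }
    rows[[i]] <- data.frame(
      chrom = models$chrom[i], strand = models$strand[i],
      coord = c(s, e), kind = c(rep(kind_s, n), rep(kind_e, n)),
      terminal = c(term_s, term_e), model = i, stringsAsFactors = FALSE
    )
  }
  all <- do.call(rbind, rows)
  key <- paste(all$chrom, all$strand, all$coord, all$kind, sep = "\r")
  grp <- split(seq_len(nrow(all)), key)
  idx <- do.call(rbind, lapply(grp, function(ix) {
    data.frame(chrom = all$chrom[ix[1]], strand = all$strand[ix[1]],
               coord = all$coord[ix[1]], kind = all$kind[ix[1]],
               terminal = all(all$terminal[ix]), stringsAsFactors = FALSE)
  }))
  idx$models <- lapply(grp, function(ix) sort(unique(all$model[ix])))
  idx <- idx[order(idx$chrom, idx$strand, idx$coord, idx$kind), ]
  rownames(idx) <- NULL
  attr(idx, "models") <- models
  class(idx) <- c("splice_site_index", "data.frame")
  idx
}

#' Look up splice-site boundaries near a coordinate
#'
#' @param index a `splice_site_index`.
#' @param chrom chromosome.
#' @param pos query coordinate (0-based).
#' @param tolerance maximum |offset| in nucleotides (default 0).
#' @param strand optional strand filter.
#' @param kind optional `"donor"`/`"acceptor"` filter.
#' @return the matching index rows with an `offset` column
#'   (`coord - pos`), sorted by |offset| then coordinate.
#' @export
splice_site_lookup <- function(index, chrom, pos, tolerance = 0,
                               strand = NULL, kind = NULL) {
  sel <- index$chrom == chrom & abs(index$coord - pos) <= tolerance
  if (!is.null(strand)) sel <- sel & index$strand == strand
  if (!is.null(kind)) sel <- sel & index$kind == kind
  out <- index[sel, , drop = FALSE]
  out$offset <- out$coord - pos
  out <- out[order(abs(out$offset), out$coord), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Introns flanking a run of exons, in transcript sense
#'
#' For a circRNA spanning exons `first..last` (1-based genomic ordinals of
#' the host model), returns the intron immediately 5' (transcript sense) of
#' the first circRNA exon and the intron immediately 3' of the last. On the
#' minus strand, transcript-sense upstream/downstream are swapped relative
#' to genomic order. A terminal exon with no flanking intron yields `NULL`
#' on that side.
#'
#' @param model one row of a `gene_models` object.
#' @param first,last genomic exon ordinals (1-based), `first <= last`.
#' @return `list(upstream =, downstream =)`, each `c(start, end)` in
#'   genomic 0-based half-open coordinates, or `NULL` when absent.
#' @export
flanking_introns <- function(model, first, last) {
  s <- model$exon_starts[[1]]; e <- model$exon_ends[[1]]
  n <- length(s)
  if (first < 1 || last > n || first > last) {
    stop(sprintf("exon range %d..%d out of bounds for %d-exon model",
                 first, last, n), call. = FALSE)
  }
  left <- if (first > 1) c(e[first - 1], s[first]) else NULL
  right <- if (last < n) c(e[last], s[last + 1]) else NULL
  if (model$strand == "+") {
    list(upstream = left, downstream = right)
  } else {
    list(upstream = right, downstream = left)
  }
}
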