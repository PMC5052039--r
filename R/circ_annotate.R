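#' Realign a back-splice junction to annotated exon boundaries
#'
#' Returns every isoform for which an acceptor-side boundary lies within
#' `tolerance` of the junction start AND a donor-side boundary of the same
#' isoform lies within `tolerance` of the junction end (in genomic terms,
#' the start side always snaps to an exon start and the end side to an exon
#' end; which is donor and which acceptor follows the model strand).
#' Within one isoform, ties between equally distant boundaries are broken
#' toward the smaller coordinate.
#'
#' @param chrom,start,end,strand junction fields (back-splice convention;
#'   `strand` may be `"."` for unknown, in which case both strands are
#'   considered).
#' @param index a `splice_site_index`.
#' @param tolerance maximum per-side snap distance in nt (default 2).
#' @return data frame with columns model (row index into the index's
#'   models), isoform_name, strand, snapped_start, snapped_end, off_start,
#'   off_end, offset (total |offset|), sorted by offset then isoform_name;
#'   zero rows when unannotatable.
#' @export
realign_and_snap <- function(chrom, start, end, strand = ".", index,
                             tolerance = 2) {
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  models <- attr(index, "models")
  cand_models <- which(models$chrom == chrom &
                         (strand == "." | models$strand == strand) &
                         models$tx_start - tolerance <= start &
                         models$tx_end + tolerance >= end)
  if (length(cand_models) == 0L) return(empty_snap())
  rows <- lapply(cand_models, function(i) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    snap_s <- snap_to(s, start, tolerance)
    snap_e <- snap_to(e, end, tolerance)
    if (is.na(snap_s) || is.na(snap_e) || snap_s >= snap_e) return(NULL)
    data.frame(model = i, isoform_name = models$isoform_name[i],
               strand = models$strand[i],
               snapped_start = snap_s, snapped_end = snap_e,
               off_start = snap_s - start, off_end = snap_e - end,
               offset = abs(snap_s - start) + abs(snap_e - end),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty_snap())
  out <- do.call(rbind, rows)
  out <- out[order(out$offset, out$isoform_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_snap <- function() {
  data.frame(model = integer(0), isoform_name = character(0),
             strand = character(0), snapped_start = numeric(0),
             snapped_end = numeric(0), off_start = numeric(0),
             off_end = numeric(0), offset = numeric(0),
             stringsAsFactors = FALSE)
}

# nearest boundary within tolerance; ties toward the smaller coordinate
snap_to <- function(coords, pos, tolerance) {
  d <- abs(coords - pos)
  ok <- d <= tolerance
  if (!any(ok)) return(NA_real_)
  coords <- coords[ok]; d <- d[ok]
  coords[order(d, coords)][1]
}

#' Annotate back-splice junctions into exon-resolved circRNA records
#'
#' The pipeline core: each junction's two back-splice sites are matched to
#' exon boundaries of the supplied models (within `tolerance` nt), the best
#' isoform is chosen (minimal total offset, then most exons inside the
#' span, then lexicographic isoform name), and the circRNA's exon blocks
#' are taken from that isoform. Each back-splice site is marked
#' `"annotated"` if the snapped boundary exists in any model from the
#' reference union (RefSeq / UCSC Known Genes / Ensembl source tags) and
#' `"novel"` otherwise. Junctions matching no isoform fall back to
#' `ciRNA-like` (contained in a single annotated intron), exonic-novel
#' (inside a gene span) or `intergenic`, each as a single block.
#'
#' When the best match is tied exactly across strands, both records are
#' emitted flagged `ambiguous`.
#'
#' @param junctions a back-splice `junctions` data frame.
#' @param models a `gene_models` object (known plus optionally assembled).
#' @param samples a `sample_sheet` providing the RPM denominator per
#'   library.
#' @param tolerance snap tolerance in nt (default 2).
#' @return a data frame of class `circ_records` with BED12-like list
#'   columns `block_starts` (absolute) and `block_sizes`.
#' @export
annotate_circ <- function(junctions, models, samples, tolerance = 2) {
  index <- build_splice_site_index(models)
  ref <- models[models$source_tag %in% ANNOTATION_SOURCES, , drop = FALSE]
  ref_starts <- boundary_key_set(ref, "start")
  ref_ends <- boundary_key_set(ref, "end")
  out <- vector("list", nrow(junctions))
  for (r in seq_len(nrow(junctions))) {
    j <- junctions[r, ]
    lib <- sample_info(samples, j$library_id)
    rpm <- compute_rpm(j$read_count, lib)
    cands <- realign_and_snap(j$chrom, j$start, j$end, j$strand, index,
                              tolerance)
    if (nrow(cands) > 0L) {
      cands$n_exons <- vapply(seq_len(nrow(cands)), function(k) {
        m <- models[cands$model[k], ]
        sum(m$exon_starts[[1]] >= cands$snapped_start[k] &
              m$exon_ends[[1]] <= cands$snapped_end[k])
      }, numeric(1))
      ord <- order(cands$offset, -cands$n_exons, cands$isoform_name)
      cands <- cands[ord, , drop = FALSE]
      top <- cands[1, ]
      picks <- 1L
      if (nrow(cands) > 1L) {
        tie <- which(cands$offset == top$offset & cands$n_exons == top$n_exons &
                       cands$strand != top$strand &
                       cands$snapped_start == top$snapped_start &
                       cands$snapped_end == top$snapped_end)
        tie <- tie[tie != 1L]
        if (length(tie)) picks <- c(1L, tie[1])
      }
      recs <- lapply(picks, function(k) {
        cc <- cands[k, ]
        m <- models[cc$model, ]
        keep <- m$exon_starts[[1]] >= cc$snapped_start &
          m$exon_ends[[1]] <= cc$snapped_end
        bs <- m$exon_starts[[1]][keep]; be <- m$exon_ends[[1]][keep]
        circ_record(j$chrom, cc$snapped_start, cc$snapped_end, cc$strand,
                    m$gene_name, m$isoform_name, bs, be - bs,
                    j$read_count, rpm, "exonic",
                    site_ann(ref_starts, j$chrom, cc$strand, cc$snapped_start),
                    site_ann(ref_ends, j$chrom, cc$strand, cc$snapped_end),
                    ambiguous = length(picks) > 1L, library_id = j$library_id)
      })
      out[[r]] <- do.call(rbind, recs)
    } else {
      out[[r]] <- annotate_fallback(j, models, rpm)
    }
  }
  if (nrow(junctions) == 0L) return(empty_circ_records())
  recs <- do.call(rbind, out)
  recs <- recs[order(recs$chrom, recs$start, recs$end, recs$strand), ]
  recs$name <- sprintf("circ_%s_%d_%d_%s", recs$chrom, as.integer(recs$start),
                       as.integer(recs$end), recs$strand)
  rownames(recs) <- NULL
  class(recs) <- c("circ_records", "data.frame")
  recs
}

boundary_key_set <- function(models, side) {
  if (nrow(models) == 0L) return(character(0))
  keys <- unlist(lapply(seq_len(nrow(models)), function(i) {
    coords <- if (side == "start") models$exon_starts[[i]] else models$exon_ends[[i]]
    paste(models$chrom[i], models$strand[i], coords, sep = "\r")
  }))
  unique(keys)
}

site_ann <- function(key_set, chrom, strand, coord) {
  if (paste(chrom, strand, coord, sep = "\r") %in% key_set) "annotated" else "novel"
}

empty_circ_records <- function() {
  recs <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), name = character(0),
                     strand = character(0), gene_name = character(0),
                     isoform_name = character(0), read_count = numeric(0),
                     rpm = numeric(0), circ_type = character(0),
                     start_status = character(0), end_status = character(0),
                     ambiguous = logical(0), library_id = character(0),
                     stringsAsFactors = FALSE)
  recs$block_starts <- list()
  recs$block_sizes <- list()
  class(recs) <- c("circ_records", "data.frame")
  recs
}

circ_record <- function(chrom, start, end, strand, gene, iso, block_starts,
                        block_sizes, read_count, rpm, circ_type,
                        start_status, end_status, ambiguous, library_id) {
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = NA_character_, strand = strand,
                   gene_name = gene, isoform_name = iso,
                   read_count = read_count, rpm = rpm, circ_type = circ_type,
                   start_status = start_status, end_status = end_status,
                   ambiguous = ambiguous, library_id = library_id,
                   stringsAsFactors = FALSE)
  df$block_starts <- list(as.numeric(block_starts))
  df$block_sizes <- list(as.numeric(block_sizes))
  df
}

annotate_fallback <- function(j, models, rpm) {
  same_chr <- which(models$chrom == j$chrom)
  # within a single intron of some model -> ciRNA-like
  for (i in same_chr) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    if (length(s) < 2L) next
    istart <- e[-length(e)]; iend <- s[-1L]
    hit <- which(istart <= j$start & j$end <= iend)
    if (length(hit)) {
      return(circ_record(j$chrom, j$start, j$end, models$strand[i],
                         models$gene_name[i], NA_character_,
                         j$start, j$end - j$start, j$read_count, rpm,
                         "ciRNA-like", "novel", "novel", FALSE, j$library_id))
    }
  }
  # inside a gene span -> exonic with novel sites (novel-discovery candidate)
  host <- same_chr[models$tx_start[same_chr] <= j$start &
                     models$tx_end[same_chr] >= j$end]
  if (length(host)) {
    i <- host[1]
    return(circ_record(j$chrom, j$start, j$end, models$strand[i],
                       models$gene_name[i], NA_character_,
                       j$start, j$end - j$start, j$read_count, rpm,
                       "exonic", "novel", "novel", FALSE, j$library_id))
  }
  circ_record(j$chrom, j$start, j$end, ".", NA_character_, NA_character_,
              j$start, j$end - j$start, j$read_count, rpm,
              "intergenic", "novel", "novel", FALSE, j$library_id)
}

#' Write circRNA records as BED12 plus 6 annotation columns
#'
#' Columns 1-12 are standard BED12 (score = read count, blockStarts
#' relative to `start`); the extras are read_count, rpm (full double
#' precision), circ_type, gene_name, isoform_name and site_status
#' (`start/end`, each `annotated` or `novel`).
#'
#' @param records a `circ_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_circ_bed <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    bs <- records$block_starts[[i]]; bz <- records$block_sizes[[i]]
    paste(records$chrom[i], fmt0(records$start[i]), fmt0(records$end[i]),
          records$name[i], fmt0(records$read_count[i]), records$strand[i],
          fmt0(records$start[i]), fmt0(records$end[i]), "0,0,0", length(bs),
          paste0(paste(fmt0(bz), collapse = ","), ","),
          paste0(paste(fmt0(bs - records$start[i]), collapse = ","), ","),
          fmt0(records$read_count[i]), sprintf("%.17g", records$rpm[i]),
          records$circ_type[i],
          records$gene_name[i] %|NA|% ".",
          records$isoform_name[i] %|NA|% ".",
          paste0(records$start_status[i], "/", records$end_status[i]),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

fmt0 <- function(x) format(x, scientific = FALSE, trim = TRUE)

`%|NA|%` <- function(x, default) ifelse(is.na(x), default, x)

#' Read circRNA records from BED12+6 written by [write_circ_bed()]
#'
#' Validates the block structure: the first block must start at `start`,
#' the last must end at `end`, and blocks must be increasing and
#' non-overlapping.
#'
#' @param path input path.
#' @param library_id library to attribute the records to (default taken
#'   from the file name is not attempted; use `"unknown"`).
#' @return a `circ_records` data frame.
#' @export
read_circ_bed <- function(path, library_id = "unknown") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 18L) {
      stop(sprintf("circ BED line %d: expected 18 columns, got %d", i, length(f)),
           call. = FALSE)
    }
    start <- as.numeric(f[2]); end <- as.numeric(f[3])
    nb <- as.integer(f[10])
    sizes <- as.numeric(strsplit(f[11], ",", fixed = TRUE)[[1]])
    rel <- as.numeric(strsplit(f[12], ",", fixed = TRUE)[[1]])
    if (length(sizes) != nb || length(rel) != nb) {
      stop(sprintf("circ BED line %d: blockCount does not match block lists", i),
           call. = FALSE)
    }
    bs <- start + rel; be <- bs + sizes
    ok <- rel[1] == 0 && be[nb] == end && all(sizes > 0) &&
      (nb == 1L || (all(diff(bs) > 0) && all(be[-nb] <= bs[-1L])))
    if (!ok) {
      stop(sprintf("circ BED line %d: block structure does not tile [start,end)", i),
           call. = FALSE)
    }
    status <- strsplit(f[18], "/", fixed = TRUE)[[1]]
    rows[[i]] <- circ_record(f[1], start, end, f[6],
                             if (f[16] == ".") NA_character_ else f[16],
                             if (f[17] == ".") NA_character_ else f[17],
                             bs, sizes, as.numeric(f[13]), as.numeric(f[14]),
                             f[15], status[1], status[2], FALSE, library_id)
    rows[[i]]$name <- f[4]
  }
  recs <- do.call(rbind, rows)
  class(recs) <- c("circ_records", "data.frame")
  recs
}
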