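#' Percent Spliced In (PSI) of a cassette exon
#'
#' Junction-read estimator: `PSI = 100 * ((a+b)/2) / ((a+b)/2 + c)` where
#' `a` and `b` are the reads supporting the two inclusion junctions and `c`
#' the reads supporting the skipping junction. Below `min_reads` total
#' informative reads the event is not quantifiable and `NA` is returned.
#'
#' @param a,b,c junction read counts.
#' @param min_reads minimum `a+b+c` (default 5).
#' @return PSI in [0, 100], or `NA` when under-covered.
#' @export
compute_psi <- function(a, b, c, min_reads = 5) {
  if (any(c(a, b, c) < 0)) stop("read counts must be non-negative", call. = FALSE)
  if (a + b + c < min_reads) return(NA_real_)
  inc <- (a + b) / 2
  100 * inc / (inc + c)
}

#' Percent Intron Retention (PIR)
#'
#' `PIR = 100 * ((e5+e3)/2) / ((e5+e3)/2 + s)` where `e5`/`e3` are reads
#' spanning the two exon-intron boundaries of the intron and `s` the reads
#' of the spliced junction removing it.
#'
#' @param e5,e3 boundary-spanning read counts.
#' @param s spliced junction read count.
#' @param min_reads minimum `(e5+e3)/2 + s` (default 5).
#' @return PIR in [0, 100], or `NA` when under-covered.
#' @export
compute_pir <- function(e5, e3, s, min_reads = 5) {
  if (any(c(e5, e3, s) < 0)) stop("read counts must be non-negative", call. = FALSE)
  ret <- (e5 + e3) / 2
  if (ret + s < min_reads) return(NA_real_)
  100 * ret / (ret + s)
}

#' Percent Splice-site Usage (PSU)
#'
#' Per-site usage among alternative 5'/3' splice sites sharing the other
#' junction end; identical arithmetic to [compute_pcu()] applied to
#' canonical junction reads. Sums to 100.
#'
#' @param counts per-site junction read counts.
#' @return numeric vector of PSUs.
#' @export
compute_psu <- function(counts) compute_pcu(counts)

junction_count <- function(junctions, chrom, start, end) {
  sel <- junctions$chrom == chrom & junctions$start == start &
    junctions$end == end
  sum(junctions$read_count[sel])
}

boundary_count <- function(boundaries, chrom, pos, kind) {
  sel <- boundaries$chrom == chrom & boundaries$pos == pos &
    boundaries$kind == kind
  sum(boundaries$read_count[sel])
}

#' Detect alternative splicing events inside circRNA spans
#'
#' Searches each expressed circRNA span for the four basic alternative
#' splicing patterns using only junction/boundary reads whose ends both
#' fall inside the span:
#' \itemize{
#'   \item cassette exon: an internal exon block with reads on both
#'     inclusion junctions and on the skipping junction;
#'   \item intron retention: an intron between consecutive blocks with
#'     exon-intron boundary read support;
#'   \item alternative 5'/3' splice site: two or more junctions sharing one
#'     end and differing at the other, where at least one variable
#'     coordinate is not an exon boundary of the host isoform (pure
#'     exon-boundary groups are the cassette/skipping pattern and are
#'     reported as such).
#' }
#' Duplicate events across circRNAs are merged by coordinates.
#'
#' @param records `circ_records` (one library).
#' @param junctions linear `junctions` from the same library.
#' @param boundaries boundary counts (see [read_boundary_counts()]) from
#'   the same library; may be an empty data frame.
#' @param models the `gene_models` used for annotation.
#' @param rpm_threshold expression filter on the host circRNA (default 0.1).
#' @return a data frame of class `splice_events` with per-type count
#'   columns (a, b, c for cassette; e5, e3, s for retention; list columns
#'   `sites`/`site_counts` for alternative splice sites) and unfilled
#'   metrics.
#' @export
detect_splice_events <- function(records, junctions, boundaries, models,
                                 rpm_threshold = 0.1) {
  if (nrow(boundaries) == 0L) {
    boundaries <- data.frame(chrom = character(0), pos = numeric(0),
                             kind = character(0), read_count = numeric(0),
                             library_id = character(0), stringsAsFactors = FALSE)
  }
  keep <- records$rpm >= rpm_threshold & records$circ_type == "exonic" &
    !is.na(records$isoform_name)
  records <- records[keep, , drop = FALSE]
  rows <- list()
  lib <- if (nrow(junctions)) junctions$library_id[1] else
    if (nrow(records)) records$library_id[1] else "unknown"
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    bs <- rec$block_starts[[1]]; be <- bs + rec$block_sizes[[1]]
    nb <- length(bs)
    jn <- junctions[junctions$chrom == rec$chrom &
                      junctions$start >= rec$start &
                      junctions$end <= rec$end &
                      (junctions$strand == rec$strand |
                         junctions$strand == "." | rec$strand == "."), ,
                    drop = FALSE]
    if (nb >= 3L) {
      for (k in 2:(nb - 1L)) {
        a <- junction_count(jn, rec$chrom, be[k - 1L], bs[k])
        b <- junction_count(jn, rec$chrom, be[k], bs[k + 1L])
        cc <- junction_count(jn, rec$chrom, be[k - 1L], bs[k + 1L])
        if (a > 0 && b > 0 && cc > 0) {
          rows[[length(rows) + 1L]] <- splice_event_row(
            "cassette_exon", rec, bs[k], be[k], a = a, b = b, c = cc,
            library_id = lib)
        }
      }
    }
    if (nb >= 2L) {
      for (k in seq_len(nb - 1L)) {
        istart <- be[k]; iend <- bs[k + 1L]
        e5 <- boundary_count(boundaries, rec$chrom, istart, "ei")
        e3 <- boundary_count(boundaries, rec$chrom, iend, "ie")
        s <- junction_count(jn, rec$chrom, istart, iend)
        if (e5 + e3 > 0) {
          rows[[length(rows) + 1L]] <- splice_event_row(
            "intron_retention", rec, istart, iend, e5 = e5, e3 = e3, s = s,
            library_id = lib)
        }
      }
    }
    host_bounds <- c(bs, be)
    for (side in c("start", "end")) {
      varside <- if (side == "start") "end" else "start"
      for (g in split(seq_len(nrow(jn)), jn[[side]])) {
        vs <- sort(unique(jn[[varside]][g]))
        if (length(vs) < 2L) next
        if (all(vs %in% host_bounds)) next  # exon-skipping pattern, not alt SS
        counts <- vapply(vs, function(x) sum(jn$read_count[g][jn[[varside]][g] == x]),
                         numeric(1))
        plus_like <- rec$strand != "-"
        # shared genomic-left end = shared donor on +, shared acceptor on -
        type <- if (side == "start") {
          if (plus_like) "alt_3ss" else "alt_5ss"
        } else {
          if (plus_like) "alt_5ss" else "alt_3ss"
        }
        row <- splice_event_row(type, rec, min(vs), max(vs),
                                library_id = lib)
        row$shared_site <- jn[[side]][g[1]]
        row$sites <- list(vs)
        row$site_counts <- list(counts)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else splice_event_row()[0, ]
  # merge duplicates across host circRNAs
  key <- paste(out$event_type, out$chrom, out$region_start, out$region_end,
               if (nrow(out)) vapply(out$sites, paste, character(1), collapse = ","), sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$chrom, out$region_start, out$event_type), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("splice_events", "data.frame")
  out
}

splice_event_row <- function(event_type = character(0), rec = NULL,
                             region_start = numeric(0), region_end = numeric(0),
                             a = NA_real_, b = NA_real_, c = NA_real_,
                             e5 = NA_real_, e3 = NA_real_, s = NA_real_,
                             library_id = character(0)) {
  if (length(event_type) == 0L) {
    df <- data.frame(event_type = character(0), circ_id = character(0),
                     chrom = character(0), strand = character(0),
                     region_start = numeric(0), region_end = numeric(0),
                     a = numeric(0), b = numeric(0), c = numeric(0),
                     e5 = numeric(0), e3 = numeric(0), s = numeric(0),
                     shared_site = numeric(0), metric = numeric(0),
                     library_id = character(0), stringsAsFactors = FALSE)
    df$sites <- list(); df$site_counts <- list()
    return(df)
  }
  df <- data.frame(event_type = event_type, circ_id = rec$name,
                   chrom = rec$chrom, strand = rec$strand,
                   region_start = region_start, region_end = region_end,
                   a = a, b = b, c = c, e5 = e5, e3 = e3, s = s,
                   shared_site = NA_real_, metric = NA_real_,
                   library_id = library_id, stringsAsFactors = FALSE)
  df$sites <- list(numeric(0)); df$site_counts <- list(numeric(0))
  df
}

#' Fill PSI/PIR/PSU metrics on detected splice events
#'
#' For alternative splice-site events the scalar `metric` column is the PSU
#' of the site with the smallest coordinate (the full per-site vector stays
#' in the `psu` list column).
#'
#' @param events a `splice_events` data frame.
#' @param min_reads minimum informative reads per event (default 5);
#'   under-covered events get `NA` metrics and `insufficient = TRUE`.
#' @return the events with `metric`, `psu` and `insufficient` filled.
#' @export
quantify_splice_events <- function(events, min_reads = 5) {
  n <- nrow(events)
  events$psu <- rep(list(numeric(0)), length.out = n)
  events$insufficient <- rep(FALSE, n)
  for (i in seq_len(n)) {
    t <- events$event_type[i]
    m <- NA_real_
    if (t == "cassette_exon") {
      m <- compute_psi(events$a[i], events$b[i], events$c[i], min_reads)
    } else if (t == "intron_retention") {
      m <- compute_pir(events$e5[i], events$e3[i], events$s[i], min_reads)
    } else {
      cts <- events$site_counts[[i]]
      if (sum(cts) >= min_reads) {
        psu <- compute_psu(cts)
        events$psu[[i]] <- psu
        m <- psu[1]
      }
    }
    events$metric[i] <- m
    events$insufficient[i] <- is.na(m)
  }
  events
}

#' Informative read total of one splice event
#' @keywords internal
event_read_support <- function(event) {
  switch(event$event_type,
         cassette_exon = event$a + event$b + event$c,
         intron_retention = (event$e5 + event$e3) / 2 + event$s,
         sum(event$site_counts[[1]]))
}

#' Call circRNA-predominant splicing events
#'
#' Contrasts event metrics measured in circular-fraction evidence (p(A)- or
#' p(A)-/RNase R libraries) against the parallel polyadenylated (p(A)+)
#' library of the same cell line. ribo- libraries are rejected on the
#' circular side: they contain both polyadenylated and nonpolyadenylated
#' transcripts, so splicing events cannot be attributed to circRNAs.
#' An event is predominant iff `circ_metric - linear_metric >= delta`, the
#' circular side has at least `min_reads` informative reads, and the linear
#' side was measurable; events whose linear side cannot be measured are
#' `"unassessable"`.
#'
#' @param circ_events quantified `splice_events` from the circular-fraction
#'   library.
#' @param linear_events quantified `splice_events` from the p(A)+ library.
#' @param circ_library,linear_library sample-sheet rows for the two
#'   libraries.
#' @param delta predominance margin in metric points (default 20).
#' @param min_reads minimum circular-side informative reads (default 5).
#' @return a data frame of calls with circ_metric, linear_metric, verdict
#'   (`predominant`, `not_predominant`, `unassessable`) and cell_line.
#' @export
call_circ_predominant <- function(circ_events, linear_events, circ_library,
                                  linear_library, delta = 20, min_reads = 5) {
  if (!circ_library$rna_fraction %in% c("pA_minus", "pA_minus_RNaseR")) {
    stop("circular-side library '", circ_library$library_id,
         "' has rna_fraction '", circ_library$rna_fraction,
         "'; only pA_minus or pA_minus_RNaseR libraries can attribute ",
         "splicing events to circRNAs (ribo- contains linear transcripts)",
         call. = FALSE)
  }
  if (linear_library$rna_fraction != "pA_plus") {
    stop("linear-side library must be pA_plus", call. = FALSE)
  }
  if (circ_library$cell_line != linear_library$cell_line) {
    stop("circular and linear libraries are from different cell lines (",
         circ_library$cell_line, " vs ", linear_library$cell_line, ")",
         call. = FALSE)
  }
  lkey <- paste(linear_events$event_type, linear_events$chrom,
                linear_events$region_start, linear_events$region_end, sep = "\r")
  calls <- circ_events
  calls$linear_metric <- NA_real_
  calls$verdict <- "unassessable"
  for (i in seq_len(nrow(calls))) {
    ck <- paste(calls$event_type[i], calls$chrom[i], calls$region_start[i],
                calls$region_end[i], sep = "\r")
    li <- match(ck, lkey)
    circ_m <- calls$metric[i]
    circ_n <- event_read_support(calls[i, ])
    lin_m <- if (!is.na(li)) linear_events$metric[li] else NA_real_
    if (calls$event_type[i] %in% c("alt_5ss", "alt_3ss") && !is.na(li) &&
        length(calls$psu[[i]]) > 0 && length(linear_events$psu[[li]]) > 0) {
      # site-wise contrast: the circRNA-predominant site is whichever
      # alternative site gains the most usage in the circular fraction
      shared <- intersect(calls$sites[[i]], linear_events$sites[[li]])
      if (length(shared) >= 2L) {
        cs <- calls$site_counts[[i]][match(shared, calls$sites[[i]])]
        ls <- linear_events$site_counts[[li]][match(shared, linear_events$sites[[li]])]
        cp <- 100 * cs / sum(cs); lp <- 100 * ls / sum(ls)
        best <- which.max(cp - lp)
        circ_m <- cp[best]; lin_m <- lp[best]
        calls$metric[i] <- circ_m
      }
    }
    calls$linear_metric[i] <- lin_m
    if (is.na(circ_m) || is.na(lin_m) || circ_n < min_reads) {
      calls$verdict[i] <- "unassessable"
    } else if (circ_m - lin_m >= delta) {
      calls$verdict[i] <- "predominant"
    } else {
      calls$verdict[i] <- "not_predominant"
    }
  }
  calls$cell_line <- circ_library$cell_line
  names(calls)[names(calls) == "metric"] <- "circ_metric"
  calls
}

#' High-confidence calls: predominant in multiple cell lines
#'
#' @param calls row-bound output of [call_circ_predominant()] across cell
#'   lines.
#' @param min_lines minimum number of distinct cell lines in which the
#'   event is called predominant (default 2).
#' @return the predominant calls belonging to events passing the filter.
#' @export
high_confidence_across_lines <- function(calls, min_lines = 2) {
  key <- paste(calls$event_type, calls$chrom, calls$region_start,
               calls$region_end, sep = "\r")
  pred <- calls$verdict == "predominant"
  nlines <- tapply(calls$cell_line[pred], key[pred],
                   function(x) length(unique(x)))
  good <- names(nlines)[nlines >= min_lines]
  out <- calls[pred & key %in% good, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize splice-event calls to TSV
#' @param events a `splice_events` or calls data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_splice_tsv <- function(events, path) {
  flat <- events
  for (col in c("sites", "site_counts", "psu")) {
    if (col %in% names(flat)) {
      flat[[col]] <- vapply(flat[[col]],
                            function(x) paste(sprintf("%.6g", x), collapse = ","),
                            character(1))
    }
  }
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
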