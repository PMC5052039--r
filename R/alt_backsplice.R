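#' Percent Circularized-site Usage (PCU)
#'
#' Usage of each alternative back-splice site among sites sharing a common
#' site: `100 * r_m / sum(r_n)` over the back-splice junction read counts
#' of the alternative sites. PCUs are in [0, 100] and sum to 100.
#'
#' @param counts non-negative junction read counts, at least one positive.
#' @return numeric vector of PCUs.
#' @export
compute_pcu <- function(counts) {
  if (length(counts) == 0L || any(counts < 0)) {
    stop("counts must be non-negative and non-empty", call. = FALSE)
  }
  total <- sum(counts)
  if (total < 1) stop("all-zero counts: no observed back-splice reads", call. = FALSE)
  100 * counts / total
}

#' Cluster circRNAs of one library by shared back-splice sites
#'
#' circRNAs sharing a 3' back-splice (acceptor) site with two or more
#' distinct 5' (donor) sites form one alternative 5' back-splicing event
#' (`alt5BS`); circRNAs sharing a donor with two or more acceptors form an
#' `alt3BS` event. In genomic terms the shared `start` coordinate is the
#' acceptor on the plus strand and the donor on the minus strand (records
#' of unknown strand are treated as plus). Alternative sites are ordered
#' proximal to distal, proximal being the site with the smallest
#' back-splice span (ties by coordinate).
#'
#' @param records `circ_records` from a single library.
#' @return a data frame of class `altbs_events` with list columns `sites`,
#'   `counts`, `pcu`, `rpm`, `spans`, `members`.
#' @export
cluster_backsplice <- function(records) {
  if (nrow(records) > 0L && length(unique(records$library_id)) != 1L) {
    stop("cluster_backsplice expects records from a single library", call. = FALSE)
  }
  ev <- list()
  for (side in c("start", "end")) {
    common <- records[[side]]
    varside <- if (side == "start") "end" else "start"
    key <- paste(records$chrom, records$strand, common, sep = "\r")
    for (g in split(seq_len(nrow(records)), key)) {
      vs <- records[[varside]][g]
      if (length(unique(vs)) < 2L) next
      agg <- rowsum(data.frame(rc = records$read_count[g]), group = vs)
      sites <- as.numeric(rownames(agg))
      counts <- agg$rc
      rpm <- vapply(sites, function(x) max(records$rpm[g][vs == x]), numeric(1))
      cm <- common[g[1]]
      spans <- abs(sites - cm)
      ord <- order(spans, sites)
      strand <- records$strand[g[1]]
      plus_like <- strand != "-"
      type <- if (side == "start") {
        if (plus_like) "alt5BS" else "alt3BS"
      } else {
        if (plus_like) "alt3BS" else "alt5BS"
      }
      row <- data.frame(
        event_id = sprintf("%s_%s_%s_%d", type, records$chrom[g[1]], strand,
                           as.integer(cm)),
        event_type = type, chrom = records$chrom[g[1]], strand = strand,
        common_side = side, common_site = cm,
        n_sites = length(sites), library_id = records$library_id[g[1]],
        stringsAsFactors = FALSE
      )
      row$sites <- list(sites[ord])
      row$counts <- list(counts[ord])
      row$pcu <- list(compute_pcu(counts[ord]))
      row$rpm <- list(rpm[ord])
      row$spans <- list(spans[ord])
      row$members <- list(records$name[g][order(match(vs, sites[ord]))])
      ev[[length(ev) + 1L]] <- row
    }
  }
  if (length(ev) == 0L) {
    out <- data.frame(event_id = character(0), event_type = character(0),
                      chrom = character(0), strand = character(0),
                      common_side = character(0), common_site = numeric(0),
                      n_sites = integer(0), library_id = character(0),
                      stringsAsFactors = FALSE)
    out$sites <- list(); out$counts <- list(); out$pcu <- list()
    out$rpm <- list(); out$spans <- list(); out$members <- list()
  } else {
    out <- do.call(rbind, ev)
    out <- out[order(out$chrom, out$common_site, out$event_type), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("altbs_events", "data.frame")
  out
}

#' Keep alternative back-splicing events with highly expressed sites
#'
#' An event is kept iff at least one member circRNA reaches the RPM
#' threshold (inclusive; default 0.1).
#'
#' @param events an `altbs_events` data frame.
#' @param rpm_threshold expression threshold (default 0.1 RPM).
#' @return the filtered events.
#' @export
filter_high_confidence <- function(events, rpm_threshold = 0.1) {
  keep <- vapply(events$rpm, function(x) any(x >= rpm_threshold), logical(1))
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-library variation of proximal back-splice-site usage
#'
#' Events are matched across libraries by (event type, chromosome, strand,
#' common site); the alternative-site set is intersected across the
#' libraries carrying the event and PCU is renormalized over the
#' intersection so the proximal-site usages are comparable. Events present
#' in fewer than `min_libraries` libraries, or whose site intersection
#' retains fewer than two sites, are excluded. Quartiles use linear
#' interpolation (R quantile type 7).
#'
#' @param events_by_library list of `altbs_events`, one element per library
#'   (already expression-filtered as desired).
#' @param min_libraries minimum number of libraries (default 3).
#' @return data frame with per-event n_libraries, proximal site, min, q1,
#'   median, q3, max of the proximal-site PCU.
#' @export
pcu_across_samples <- function(events_by_library, min_libraries = 3) {
  if (length(events_by_library) < min_libraries) {
    stop("need at least min_libraries event sets", call. = FALSE)
  }
  flat <- do.call(rbind, events_by_library)
  if (is.null(flat) || nrow(flat) == 0L) return(empty_pcu_summary())
  key <- paste(flat$event_type, flat$chrom, flat$strand, flat$common_side,
               flat$common_site, sep = "\r")
  rows <- list()
  for (g in split(seq_len(nrow(flat)), key)) {
    if (length(unique(flat$library_id[g])) < min_libraries) next
    shared <- Reduce(intersect, flat$sites[g])
    if (length(shared) < 2L) next
    spans <- abs(shared - flat$common_site[g[1]])
    prox <- shared[order(spans, shared)][1]
    pcus <- vapply(g, function(i) {
      sel <- match(shared, flat$sites[[i]])
      cts <- flat$counts[[i]][sel]
      100 * cts[match(prox, shared)] / sum(cts)
    }, numeric(1))
    q <- stats::quantile(pcus, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7,
                         names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      event_id = flat$event_id[g[1]], event_type = flat$event_type[g[1]],
      chrom = flat$chrom[g[1]], strand = flat$strand[g[1]],
      common_site = flat$common_site[g[1]], proximal_site = prox,
      n_libraries = length(unique(flat$library_id[g])),
      min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(empty_pcu_summary())
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$common_site, out$event_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_pcu_summary <- function() {
  data.frame(event_id = character(0), event_type = character(0),
             chrom = character(0), strand = character(0),
             common_site = numeric(0), proximal_site = numeric(0),
             n_libraries = integer(0), min = numeric(0), q1 = numeric(0),
             median = numeric(0), q3 = numeric(0), max = numeric(0),
             stringsAsFactors = FALSE)
}

#' Serialize alternative back-splicing events to TSV
#'
#' List columns (sites, counts, PCUs, RPMs) are comma-joined.
#'
#' @param events an `altbs_events` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_altbs_tsv <- function(events, path) {
  flat <- data.frame(
    event_id = events$event_id, event_type = events$event_type,
    chrom = events$chrom, strand = events$strand,
    common_side = events$common_side, common_site = events$common_site,
    n_sites = events$n_sites,
    sites = vapply(events$sites, function(x) paste(fmt0(x), collapse = ","), character(1)),
    counts = vapply(events$counts, function(x) paste(fmt0(x), collapse = ","), character(1)),
    pcu = vapply(events$pcu, function(x) paste(sprintf("%.6g", x), collapse = ","), character(1)),
    rpm = vapply(events$rpm, function(x) paste(sprintf("%.6g", x), collapse = ","), character(1)),
    library_id = events$library_id, stringsAsFactors = FALSE
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
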