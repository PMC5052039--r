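#' Find orientation-opposite complementary sequence pairs between two introns
#'
#' Seed-and-extend alignment of `seq_a` against the reverse complement of
#' `seq_b`: exact k-mer seeds, ungapped X-drop extension (match +1,
#' mismatch -2, drop 15 by default), overlapping hits merged keeping the
#' best score. A reported pair means a subsequence of intron A is
#' (approximately) the reverse complement of a subsequence of intron B --
#' the geometry required for an across-intron RNA duplex.
#'
#' Arm coordinates are local to each input sequence (0-based half-open, on
#' the forward genomic strand of each intron); add the introns' genomic
#' offsets via `a_offset`/`b_offset` to get genomic coordinates.
#'
#' @param seq_a,seq_b intron sequences (forward genomic strand).
#' @param k seed length (default 11).
#' @param min_len minimum alignment length (default 30).
#' @param min_identity minimum identity fraction (default 0.8).
#' @param match,mismatch,xdrop ungapped extension scores (defaults +1, -2,
#'   15).
#' @param max_pairs cap on reported pairs (default 100).
#' @param a_offset,b_offset genomic start coordinates of the two introns
#'   (default 0 = local coordinates).
#' @return data frame of class `complementary_pairs` with arm coordinates,
#'   length, n_match, identity and score; zero rows when either intron is
#'   empty or nothing aligns.
#' @export
find_complementary_pairs <- function(seq_a, seq_b, k = 11, min_len = 30,
                                     min_identity = 0.8, match = 1,
                                     mismatch = -2, xdrop = 15,
                                     max_pairs = 100, a_offset = 0,
                                     b_offset = 0) {
  empty <- data.frame(a_start = numeric(0), a_end = numeric(0),
                      b_start = numeric(0), b_end = numeric(0),
                      length = numeric(0), n_match = numeric(0),
                      identity = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("complementary_pairs", "data.frame")
  la <- nchar(seq_a); lb <- nchar(seq_b)
  if (la < max(k, min_len) || lb < max(k, min_len)) return(empty)
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  brc_str <- revcomp(seq_b)
  b <- strsplit(brc_str, "", fixed = TRUE)[[1]]
  kmers_a <- substring(toupper(seq_a), seq_len(la - k + 1), k:la)
  kmers_b <- substring(brc_str, seq_len(lb - k + 1), k:lb)
  pos_a <- split(seq_len(la - k + 1), kmers_a)
  shared <- intersect(names(pos_a), unique(kmers_b))
  shared <- shared[!grepl("N", shared, fixed = TRUE)]
  if (length(shared) == 0L) return(empty)
  pos_b <- split(seq_len(lb - k + 1), kmers_b)
  seeds <- do.call(rbind, lapply(shared, function(km) {
    expand.grid(i = pos_a[[km]], j = pos_b[[km]])
  }))
  seeds$diag <- seeds$i - seeds$j
  seeds <- seeds[order(seeds$diag, seeds$i), , drop = FALSE]
  hits <- list()
  covered_to <- -Inf; covered_diag <- NA
  for (r in seq_len(nrow(seeds))) {
    i <- seeds$i[r]; j <- seeds$j[r]; d <- seeds$diag[r]
    if (!is.na(covered_diag) && d == covered_diag && i <= covered_to) next
    ext <- xdrop_extend(a, b, i, j, k, match, mismatch, xdrop)
    covered_diag <- d; covered_to <- ext$a_end  # 1-based inclusive end in a
    len <- ext$a_end - ext$a_start + 1L
    ident <- ext$n_match / len
    if (len >= min_len && ident >= min_identity) {
      hits[[length(hits) + 1L]] <- data.frame(
        a_start = ext$a_start - 1L, a_end = ext$a_end,
        rc_start = ext$b_start - 1L, rc_end = ext$b_end,
        length = len, n_match = ext$n_match, identity = ident,
        score = ext$n_match * match + (len - ext$n_match) * mismatch,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) return(empty)
  hits <- do.call(rbind, hits)
  hits <- hits[order(-hits$score, hits$a_start), , drop = FALSE]
  keep <- logical(nrow(hits))
  for (r in seq_len(nrow(hits))) {
    ov <- keep & ((hits$a_start < hits$a_end[r] & hits$a_end > hits$a_start[r]) |
                    (hits$rc_start < hits$rc_end[r] & hits$rc_end > hits$rc_start[r]))
    if (!any(ov[seq_len(r - 1L)])) keep[r] <- TRUE
  }
  hits <- hits[keep, , drop = FALSE][seq_len(min(sum(keep), max_pairs)), ,
                                     drop = FALSE]
  out <- data.frame(
    a_start = a_offset + hits$a_start, a_end = a_offset + hits$a_end,
    b_start = b_offset + (lb - hits$rc_end),
    b_end = b_offset + (lb - hits$rc_start),
    length = hits$length, n_match = hits$n_match,
    identity = hits$identity, score = hits$score, stringsAsFactors = FALSE)
  out <- out[order(out$a_start, out$b_start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("complementary_pairs", "data.frame")
  out
}

# ungapped X-drop extension from an exact k-mer seed at 1-based (i, j)
xdrop_extend <- function(a, b, i, j, k, match, mismatch, xdrop) {
  n_match <- k
  # right
  best <- 0; cur <- 0; best_off <- 0L
  p <- i + k; q <- j + k; off <- 0L; gained <- 0L
  while (p <= length(a) && q <= length(b)) {
    hit <- a[p] == b[q] && a[p] %in% BASES
    cur <- cur + if (hit) match else mismatch
    off <- off + 1L
    if (cur > best) { best <- cur; best_off <- off; gained <- gained + 0L }
    if (best - cur >= xdrop) break
    p <- p + 1L; q <- q + 1L
  }
  right <- best_off
  if (right > 0) {
    seg <- seq_len(right)
    n_match <- n_match + sum(a[i + k - 1L + seg] == b[j + k - 1L + seg] &
                               a[i + k - 1L + seg] %in% BASES)
  }
  # left
  best <- 0; cur <- 0; best_off <- 0L
  p <- i - 1L; q <- j - 1L; off <- 0L
  while (p >= 1L && q >= 1L) {
    hit <- a[p] == b[q] && a[p] %in% BASES
    cur <- cur + if (hit) match else mismatch
    off <- off + 1L
    if (cur > best) { best <- cur; best_off <- off }
    if (best - cur >= xdrop) break
    p <- p - 1L; q <- q - 1L
  }
  left <- best_off
  if (left > 0) {
    seg <- seq_len(left)
    n_match <- n_match + sum(a[i - seg] == b[j - seg] & a[i - seg] %in% BASES)
  }
  list(a_start = i - left, a_end = i + k - 1L + right,
       b_start = j - left, b_end = j + k - 1L + right,
       n_match = n_match)
}

#' Classify an alternative back-splicing event by RNA-pair competition
#'
#' For an alternative 5' back-splicing event (shared acceptor), a proximal
#' pair is a complementary pair between the intron transcript-upstream of
#' the common-acceptor exon and the intron transcript-downstream of the
#' proximal donor exon; the distal pair uses the distal donor's downstream
#' intron. Alternative 3' events are mirrored. The verdict is `competing`
#' when both pairs exist, otherwise `proximal_only`, `distal_only` or
#' `none`. A member circRNA ending at a transcript-terminal exon has no
#' flanking intron on that side; the side is reported unsearchable (the
#' corresponding `*_searchable` flag is FALSE) rather than erroring.
#'
#' @param event one row of an `altbs_events` data frame.
#' @param records the `circ_records` the event was clustered from.
#' @param models the `gene_models` used for annotation.
#' @param genome a `genome_seq`.
#' @param k,min_len,min_identity pairing parameters (see
#'   [find_complementary_pairs()]).
#' @param max_intron introns are truncated to this many bases nearest the
#'   back-splice site (default 50000).
#' @return one-row data frame: event_id, has_proximal_pair,
#'   has_distal_pair, proximal_searchable, distal_searchable, n pair
#'   counts, verdict.
#' @export
classify_competition <- function(event, records, models, genome, k = 11,
                                 min_len = 30, min_identity = 0.8,
                                 max_intron = 50000) {
  sites <- event$sites[[1]]
  prox_site <- sites[1]; dist_site <- sites[length(sites)]
  member_introns <- function(site) {
    if (event$common_side == "start") {
      mstart <- event$common_site; mend <- site
    } else {
      mstart <- site; mend <- event$common_site
    }
    rec <- records[records$chrom == event$chrom & records$start == mstart &
                     records$end == mend & records$strand == event$strand, ,
                   drop = FALSE]
    if (nrow(rec) == 0L || is.na(rec$isoform_name[1])) return(NULL)
    mi <- match(rec$isoform_name[1], models$isoform_name)
    if (is.na(mi)) return(NULL)
    m <- models[mi, ]
    es <- m$exon_starts[[1]]; ee <- m$exon_ends[[1]]
    inside <- which(es >= mstart & ee <= mend)
    if (length(inside) == 0L) return(NULL)
    fl <- flanking_introns(m, min(inside), max(inside))
    fl
  }
  fl_prox <- member_introns(prox_site)
  fl_dist <- member_introns(dist_site)
  # the common-site side intron: upstream for alt5BS, downstream for alt3BS
  common_key <- if (event$event_type == "alt5BS") "upstream" else "downstream"
  var_key <- if (event$event_type == "alt5BS") "downstream" else "upstream"
  common_iv <- if (!is.null(fl_prox)) fl_prox[[common_key]] else NULL
  slice_iv <- function(iv, near_left) {
    if (is.null(iv) || iv[2] <= iv[1]) return(NULL)
    if (iv[2] - iv[1] > max_intron) {
      if (near_left) iv <- c(iv[1], iv[1] + max_intron)
      else iv <- c(iv[2] - max_intron, iv[2])
    }
    iv
  }
  # truncate toward the back-splice span: the common intron abuts the span
  # on one side, the variable introns on the other
  span_left <- event$common_side == "start"
  common_iv <- slice_iv(common_iv, near_left = !span_left)
  search <- function(fl) {
    if (is.null(fl) || is.null(fl[[var_key]]) || is.null(common_iv)) {
      return(list(searchable = FALSE, n = 0L))
    }
    var_iv <- slice_iv(fl[[var_key]], near_left = span_left)
    if (is.null(var_iv)) return(list(searchable = FALSE, n = 0L))
    pairs <- find_complementary_pairs(
      genome_slice(genome, event$chrom, common_iv[1], common_iv[2]),
      genome_slice(genome, event$chrom, var_iv[1], var_iv[2]),
      k = k, min_len = min_len, min_identity = min_identity,
      a_offset = common_iv[1], b_offset = var_iv[1])
    list(searchable = TRUE, n = nrow(pairs))
  }
  sp <- search(fl_prox)
  sd <- search(fl_dist)
  has_p <- sp$searchable && sp$n > 0
  has_d <- sd$searchable && sd$n > 0
  verdict <- if (has_p && has_d) "competing"
  else if (has_p) "proximal_only"
  else if (has_d) "distal_only"
  else "none"
  data.frame(event_id = event$event_id, event_type = event$event_type,
             chrom = event$chrom, strand = event$strand,
             common_site = event$common_site,
             has_proximal_pair = has_p, has_distal_pair = has_d,
             proximal_searchable = sp$searchable,
             distal_searchable = sd$searchable,
             n_proximal_pairs = sp$n, n_distal_pairs = sd$n,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Summarize RNA-pair competition over events and a control set
#'
#' @param calls row-bound output of [classify_competition()] for the
#'   high-confidence alternative back-splicing events.
#' @param control_records non-alternative circRNAs sampled by the caller
#'   (seeded) as a background set.
#' @param models,genome as in [classify_competition()].
#' @param ... pairing parameters forwarded to [find_complementary_pairs()].
#' @return a list with `fraction_competing` among searchable alternative
#'   events, `fraction_control_paired` among searchable controls, and the
#'   underlying counts.
#' @export
pairing_summary <- function(calls, control_records, models, genome, ...) {
  searchable <- calls$proximal_searchable & calls$distal_searchable
  n_alt <- sum(searchable)
  n_comp <- sum(calls$verdict == "competing" & searchable)
  n_ctrl <- 0L; n_ctrl_paired <- 0L
  for (r in seq_len(nrow(control_records))) {
    rec <- control_records[r, ]
    if (is.na(rec$isoform_name)) next
    mi <- match(rec$isoform_name, models$isoform_name)
    if (is.na(mi)) next
    m <- models[mi, ]
    es <- m$exon_starts[[1]]; ee <- m$exon_ends[[1]]
    inside <- which(es >= rec$start & ee <= rec$end)
    if (length(inside) == 0L) next
    fl <- flanking_introns(m, min(inside), max(inside))
    if (is.null(fl$upstream) || is.null(fl$downstream)) next
    n_ctrl <- n_ctrl + 1L
    pairs <- find_complementary_pairs(
      genome_slice(genome, rec$chrom, fl$upstream[1], fl$upstream[2]),
      genome_slice(genome, rec$chrom, fl$downstream[1], fl$downstream[2]),
      ...)
    if (nrow(pairs) > 0) n_ctrl_paired <- n_ctrl_paired + 1L
  }
  if (n_ctrl == 0L) warning("empty control set; control fraction unavailable")
  list(fraction_competing = if (n_alt > 0) n_comp / n_alt else NA_real_,
       n_alternative = n_alt, n_competing = n_comp,
       fraction_control_paired = if (n_ctrl > 0) n_ctrl_paired / n_ctrl else NA_real_,
       n_control = n_ctrl, n_control_paired = n_ctrl_paired)
}

#' Write complementary pairs as BEDPE
#'
#' @param pairs a `complementary_pairs` data frame (genomic coordinates).
#' @param chrom chromosome name for both arms.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs_bedpe <- function(pairs, chrom, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\tpair_%d\t%d\t+\t-\t%.6g\t%d",
                   chrom, as.integer(pairs$a_start), as.integer(pairs$a_end),
                   chrom, as.integer(pairs$b_start), as.integer(pairs$b_end),
                   seq_len(nrow(pairs)), as.integer(pairs$score),
                   pairs$identity, as.integer(pairs$length))
  writeLines(lines, path)
  invisible(path)
}

#' Read complementary pairs from BEDPE written by [write_pairs_bedpe()]
#' @param path input path.
#' @return a `complementary_pairs` data frame plus chrom columns.
#' @export
read_pairs_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- do.call(rbind, lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 12L) {
      stop(sprintf("BEDPE line %d: expected 12 columns", i), call. = FALSE)
    }
    data.frame(chrom_a = f[1], a_start = as.numeric(f[2]), a_end = as.numeric(f[3]),
               chrom_b = f[4], b_start = as.numeric(f[5]), b_end = as.numeric(f[6]),
               score = as.numeric(f[8]), identity = as.numeric(f[11]),
               length = as.numeric(f[12]), stringsAsFactors = FALSE)
  }))
  out
}
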