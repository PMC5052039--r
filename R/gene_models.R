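#' Construct a set of transcript models
#'
#' A `gene_models` object is a data frame with one row per transcript
#' isoform and list columns for exon coordinates, following genePred
#' semantics: 0-based half-open exons, sorted in genomic order.
#'
#' @param gene_name,isoform_name,chrom,strand character vectors.
#' @param exon_starts,exon_ends lists of numeric vectors (0-based starts,
#'   end-exclusive ends), one vector per isoform.
#' @param source_tag provenance of each model: one of `"refseq"`,
#'   `"known_genes"`, `"ensembl"`, `"assembled"`, `"synthetic"`.
#' @return a data frame of class `gene_models`.
#' @export
gene_models <- function(gene_name, isoform_name, chrom, strand,
                        exon_starts, exon_ends, source_tag = "refseq") {
  n <- length(isoform_name)
  df <- data.frame(
    gene_name = as.character(gene_name),
    isoform_name = as.character(isoform_name),
    chrom = as.character(chrom),
    strand = as.character(strand),
    source_tag = rep_len(as.character(source_tag), n),
    stringsAsFactors = FALSE
  )
  df$exon_starts <- lapply(exon_starts, as.numeric)
  df$exon_ends <- lapply(exon_ends, as.numeric)
  df$tx_start <- vapply(df$exon_starts, function(x) x[1], numeric(1))
  df$tx_end <- vapply(df$exon_ends, function(x) x[length(x)], numeric(1))
  class(df) <- c("gene_models", "data.frame")
  validate_gene_models(df)
  df
}

ANNOTATION_SOURCES <- c("refseq", "known_genes", "ensembl")

validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    s <- models$exon_starts[[i]]
    e <- models$exon_ends[[i]]
    id <- models$isoform_name[i]
    if (length(s) != length(e) || length(s) < 1L) {
      stop("model '", id, "': exon start/end lists must be equal length >= 1",
           call. = FALSE)
    }
    if (length(s) > 1L && any(diff(s) <= 0)) {
      stop("model '", id, "': exon starts not strictly increasing", call. = FALSE)
    }
    ok <- all(s < e) && (length(s) == 1L || all(e[-length(e)] <= s[-1L]))
    if (!ok) {
      stop("model '", id, "': exons overlap or are malformed", call. = FALSE)
    }
    if (!models$strand[i] %in% c("+", "-")) {
      stop("model '", id, "': strand must be '+' or '-'", call. = FALSE)
    }
  }
  invisible(models)
}

#' Read transcript models from a genePred/refFlat file
#'
#' Expects the 11-column refFlat layout (geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds) with
#' 0-based half-open coordinates and comma-separated exon lists (trailing
#' commas tolerated).
#'
#' @param path input file.
#' @param source_tag provenance tag applied to all models (default
#'   `"refseq"`).
#' @return a `gene_models` object.
#' @export
read_genepred <- function(path, source_tag = "refseq") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(gene_models(character(0), character(0), character(0), character(0),
                       list(), list(), source_tag)[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  parse_int <- function(x, ln, col) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v))) {
      stop(sprintf("genePred line %d: column '%s' is not numeric", ln, col),
           call. = FALSE)
    }
    v
  }
  parse_list <- function(x, ln, col) {
    parts <- strsplit(x, ",", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    parse_int(parts, ln, col)
  }
  n <- length(fields)
  gene <- iso <- chrom <- strand <- character(n)
  starts <- ends <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 11L) {
      stop(sprintf("genePred line %d: expected 11 tab-separated columns, got %d",
                   i, length(f)), call. = FALSE)
    }
    gene[i] <- f[1]; iso[i] <- f[2]; chrom[i] <- f[3]; strand[i] <- f[4]
    cnt <- parse_int(f[9], i, "exonCount")
    s <- parse_list(f[10], i, "exonStarts")
    e <- parse_list(f[11], i, "exonEnds")
    if (length(s) != cnt || length(e) != cnt) {
      stop(sprintf("genePred line %d: exonCount (%d) does not match exon list lengths (%d/%d)",
                   i, cnt, length(s), length(e)), call. = FALSE)
    }
    starts[[i]] <- s; ends[[i]] <- e
  }
  models <- tryCatch(
    gene_models(gene, iso, chrom, strand, starts, ends, source_tag),
    error = function(err) stop("genePred '", path, "': ", conditionMessage(err),
                               call. = FALSE)
  )
  models
}

#' Write transcript models to a genePred/refFlat file
#'
#' Inverse of [read_genepred()]; exon lists get the canonical trailing comma.
#'
#' @param models a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genepred <- function(models, path) {
  fmt_list <- function(x) paste0(paste(format(x, scientific = FALSE, trim = TRUE),
                                       collapse = ","), ",")
  lines <- vapply(seq_len(nrow(models)), function(i) {
    s <- models$exon_starts[[i]]; e <- models$exon_ends[[i]]
    paste(models$gene_name[i], models$isoform_name[i], models$chrom[i],
          models$strand[i],
          format(s[1], scientific = FALSE), format(e[length(e)], scientific = FALSE),
          format(s[1], scientific = FALSE), format(e[length(e)], scientific = FALSE),
          length(s), fmt_list(s), fmt_list(e), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Only `exon` features are used; they are grouped by `transcript_id` and
#' converted from GTF's 1-based inclusive coordinates to the internal
#' 0-based half-open convention. Exons may appear in any order in the file.
#'
#' @param path input GTF.
#' @param source_tag provenance tag (default `"assembled"`, the usual origin
#'   of GTF input here).
#' @return a `gene_models` object.
#' @export
read_gtf <- function(path, source_tag = "assembled") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "exon", logical(1))
  fields <- fields[keep]
  if (length(fields) == 0L) {
    return(gene_models(character(0), character(0), character(0), character(0),
                       list(), list(), source_tag)[0, ])
  }
  attr_value <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, "\\s+\"?([^\";]+)\"?"), attrs))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  rec <- lapply(fields, function(f) {
    tid <- attr_value(f[9], "transcript_id")
    gid <- attr_value(f[9], "gene_id")
    if (is.na(tid)) stop("GTF exon feature without transcript_id", call. = FALSE)
    list(chrom = f[1], start = as.numeric(f[4]) - 1, end = as.numeric(f[5]),
         strand = f[7], tid = tid, gid = if (is.na(gid)) tid else gid)
  })
  tids <- vapply(rec, `[[`, character(1), "tid")
  groups <- split(rec, factor(tids, levels = unique(tids)))
  gene <- iso <- chrom <- strand <- character(length(groups))
  starts <- ends <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    ord <- order(vapply(g, `[[`, numeric(1), "start"))
    g <- g[ord]
    s <- vapply(g, `[[`, numeric(1), "start")
    e <- vapply(g, `[[`, numeric(1), "end")
    if (length(s) > 1L && any(s[-1L] < e[-length(e)])) {
      stop("GTF transcript '", g[[1]]$tid, "' has overlapping exons", call. = FALSE)
    }
    gene[i] <- g[[1]]$gid; iso[i] <- g[[1]]$tid
    chrom[i] <- g[[1]]$chrom; strand[i] <- g[[1]]$strand
    starts[[i]] <- s; ends[[i]] <- e
  }
  gene_models(gene, iso, chrom, strand, starts, ends, source_tag)
}

#' Spliced transcript sequence of a model
#'
#' Concatenates exon slices and reverse-complements on the minus strand,
#' yielding the mRNA-sense sequence.
#'
#' @param model one row of a `gene_models` object.
#' @param genome a `genome_seq` object.
#' @return a character string.
#' @export
transcript_sequence <- function(model, genome) {
  s <- model$exon_starts[[1]]; e <- model$exon_ends[[1]]
  parts <- mapply(function(a, b) genome_slice(genome, model$chrom, a, b), s, e)
  seq <- paste(parts, collapse = "")
  if (model$strand == "-") revcomp(seq) else seq
}
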