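#' Read a sample sheet describing sequencing libraries
#'
#' Tab-separated with header columns `library_id`, `rna_fraction`,
#' `total_mapped_reads`, `cell_line`. `rna_fraction` encodes the RNA
#' isolation strategy: `pA_plus` (polyadenylated), `pA_minus`
#' (nonpolyadenylated), `pA_minus_RNaseR` (nonpolyadenylated plus
#' exonuclease digestion of linear RNAs), or `ribo_minus` (rRNA-depleted
#' total RNA).
#'
#' @param path TSV path.
#' @return a data frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("library_id", "rna_fraction", "total_mapped_reads", "cell_line")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_sample_sheet(df)
}

RNA_FRACTIONS <- c("pA_plus", "pA_minus", "pA_minus_RNaseR", "ribo_minus")

validate_sample_sheet <- function(df) {
  bad <- setdiff(unique(df$rna_fraction), RNA_FRACTIONS)
  if (length(bad)) {
    stop("unknown rna_fraction value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$total_mapped_reads)) || any(df$total_mapped_reads <= 0)) {
    stop("total_mapped_reads must be positive", call. = FALSE)
  }
  if (anyDuplicated(df$library_id)) {
    stop("duplicate library_id in sample sheet", call. = FALSE)
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet
#' @param samples a `sample_sheet` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

sample_info <- function(samples, library_id) {
  i <- match(library_id, samples$library_id)
  if (is.na(i)) {
    stop("library '", library_id, "' not found in sample sheet", call. = FALSE)
  }
  samples[i, , drop = FALSE]
}

new_junctions <- function(chrom = character(0), start = numeric(0),
                          end = numeric(0), name = character(0),
                          read_count = numeric(0), strand = character(0),
                          library_id = character(0),
                          kind = "backsplice") {
  df <- data.frame(chrom = chrom, start = start, end = end, name = name,
                   read_count = read_count, strand = strand,
                   library_id = library_id, stringsAsFactors = FALSE)
  attr(df, "kind") <- kind
  class(df) <- c("junctions", "data.frame")
  df
}

#' Parse STAR-style chimeric junction output into back-splice junctions
#'
#' Consumes the tab-separated `Chimeric.out.junction` dialect: columns
#' chrA, coordA (1-based first intronic base on the donor side), strandA,
#' chrB, coordB (1-based last intronic base on the acceptor side), strandB,
#' junction_type, repeatL, repeatR, read_name, ... Only same-chromosome,
#' same-strand chimeras whose segment order implies a downstream-donor to
#' upstream-acceptor join (i.e. back-splicing) are kept; identical junctions
#' are collapsed with `read_count` = number of distinct supporting read
#' names.
#'
#' The resulting convention: `start` = 0-based first base of the most
#' upstream circRNA exon (acceptor side), `end` = one past the last base of
#' the most downstream exon (donor side).
#'
#' @param path input file.
#' @param library one row of a `sample_sheet` (or a list with
#'   `library_id`).
#' @param keep_noncanonical keep records with junction_type < 0 (no
#'   canonical splice motif at the chimeric breakpoint); dropped by default.
#' @return a `junctions` data frame (kind `"backsplice"`).
#' @export
parse_star_chimeric <- function(path, library, keep_noncanonical = FALSE) {
  lib_id <- as.character(library$library_id)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(new_junctions(library_id = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  chrA <- chrB <- sA <- sB <- reads <- character(n)
  cA <- cB <- jtype <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 10L) {
      stop(sprintf("chimeric junction line %d: expected >= 10 columns, got %d",
                   i, length(f)), call. = FALSE)
    }
    ca <- suppressWarnings(as.numeric(f[2]))
    cb <- suppressWarnings(as.numeric(f[5]))
    jt <- suppressWarnings(as.numeric(f[7]))
    if (is.na(ca) || is.na(cb) || is.na(jt)) {
      stop(sprintf("chimeric junction line %d: non-numeric coordinate or junction type", i),
           call. = FALSE)
    }
    chrA[i] <- f[1]; cA[i] <- ca; sA[i] <- f[3]
    chrB[i] <- f[4]; cB[i] <- cb; sB[i] <- f[6]
    jtype[i] <- jt; reads[i] <- f[10]
  }
  same <- chrA == chrB & sA == sB & sA %in% c("+", "-")
  if (!any(same)) {
    warning("no same-chromosome same-strand chimeras found in '", path, "'")
    return(new_junctions(library_id = character(0)))
  }
  if (!keep_noncanonical) same <- same & jtype >= 0
  # segment A carries the donor breakpoint, segment B the acceptor breakpoint
  start <- ifelse(sA == "+", cB, cA)          # 0-based acceptor-side exon start
  end <- ifelse(sA == "+", cA - 1, cB - 1)    # end-exclusive donor-side exon end
  keep <- same & start < end
  if (!any(keep)) return(new_junctions(library_id = character(0)))
  key <- paste(chrA[keep], start[keep], end[keep], sA[keep], sep = "\r")
  grp <- split(reads[keep], key)
  parts <- strsplit(names(grp), "\r", fixed = TRUE)
  out <- new_junctions(
    chrom = vapply(parts, `[`, character(1), 1),
    start = as.numeric(vapply(parts, `[`, character(1), 2)),
    end = as.numeric(vapply(parts, `[`, character(1), 3)),
    name = paste0("bsj", seq_along(grp)),
    read_count = vapply(grp, function(r) length(unique(r)), numeric(1)),
    strand = vapply(parts, `[`, character(1), 4),
    library_id = lib_id
  )
  out <- out[order(out$chrom, out$start, out$end), ]
  out$name <- paste0("bsj", seq_len(nrow(out)))
  rownames(out) <- NULL
  class(out) <- c("junctions", "data.frame")
  attr(out, "kind") <- "backsplice"
  out
}

#' Parse junction evidence from BED6
#'
#' The score column holds the junction read count. For `kind =
#' "backsplice"`, (start, end) follow the back-splice convention (start =
#' acceptor-side exon start, end = donor-side exon end). For `kind =
#' "linear"`, (start, end) delimit the spliced-out intron (donor-side exon
#' end, acceptor-side exon start in genomic order). Duplicate
#' (chrom, start, end, strand) lines are summed.
#'
#' @param path BED6 path.
#' @param kind `"backsplice"` or `"linear"`.
#' @param library one row of a `sample_sheet` (or list with `library_id`).
#' @return a `junctions` data frame.
#' @export
parse_junction_bed <- function(path, kind = c("backsplice", "linear"), library) {
  kind <- match.arg(kind)
  lib_id <- as.character(library$library_id)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_junctions(library_id = character(0), kind = kind))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  chrom <- name <- strand <- character(n)
  start <- end <- score <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 6L) {
      stop(sprintf("junction BED line %d: expected 6 columns, got %d", i, length(f)),
           call. = FALSE)
    }
    sc <- suppressWarnings(as.numeric(f[5]))
    if (is.na(sc) || sc != round(sc)) {
      stop(sprintf("junction BED line %d: score (read count) must be an integer", i),
           call. = FALSE)
    }
    st <- as.numeric(f[2]); en <- as.numeric(f[3])
    if (is.na(st) || is.na(en) || st >= en) {
      stop(sprintf("junction BED line %d: start must be < end", i), call. = FALSE)
    }
    chrom[i] <- f[1]; start[i] <- st; end[i] <- en
    name[i] <- f[4]; score[i] <- sc; strand[i] <- f[6]
  }
  key <- paste(chrom, start, end, strand, sep = "\r")
  grp <- split(seq_len(n), factor(key, levels = unique(key)))
  out <- new_junctions(
    chrom = vapply(grp, function(ix) chrom[ix[1]], character(1)),
    start = vapply(grp, function(ix) start[ix[1]], numeric(1)),
    end = vapply(grp, function(ix) end[ix[1]], numeric(1)),
    name = vapply(grp, function(ix) name[ix[1]], character(1)),
    read_count = vapply(grp, function(ix) sum(score[ix]), numeric(1)),
    strand = vapply(grp, function(ix) strand[ix[1]], character(1)),
    library_id = lib_id, kind = kind
  )
  rownames(out) <- NULL
  out
}

#' Write junctions to BED6
#' @param junctions a `junctions` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junctions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   junctions$chrom, as.integer(junctions$start),
                   as.integer(junctions$end), junctions$name,
                   as.integer(junctions$read_count), junctions$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Back-splice junction reads per million mapped reads (RPM)
#'
#' The expression unit for circRNAs: `1e6 * read_count /
#' total_mapped_reads`. The high-confidence expression filter used
#' throughout is RPM >= 0.1 (inclusive).
#'
#' @param read_count non-negative read count(s).
#' @param library one row of a `sample_sheet`, a list with
#'   `total_mapped_reads`, or a bare positive number of mapped reads.
#' @return numeric RPM value(s).
#' @export
compute_rpm <- function(read_count, library) {
  total <- if (is.numeric(library)) library else library$total_mapped_reads
  if (length(total) != 1L || !is.finite(total) || total <= 0) {
    stop("total_mapped_reads must be a single positive number", call. = FALSE)
  }
  if (any(read_count < 0)) stop("read_count must be non-negative", call. = FALSE)
  1e6 * read_count / total
}

#' Read exon-intron boundary read counts
#'
#' TSV with header columns `chrom`, `pos`, `kind`, `read_count`,
#' `library_id`. `kind` is `"ei"` for reads spanning an exon|intron
#' boundary at the intron start coordinate and `"ie"` for reads spanning an
#' intron|exon boundary at the intron end coordinate (genomic orientation).
#' These supply the e5/e3 counts of the intron-retention metric.
#'
#' @param path TSV path.
#' @return a data frame of boundary counts.
#' @export
read_boundary_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         library_id = "character"))
  required <- c("chrom", "pos", "kind", "read_count", "library_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("boundary counts missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!df$kind %in% c("ei", "ie"))) {
    stop("boundary count kind must be 'ei' or 'ie'", call. = FALSE)
  }
  df
}

#' Write exon-intron boundary read counts
#' @param counts boundary count data frame (see [read_boundary_counts()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_boundary_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
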