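test_that("PSI, PIR and PSU formulas and gates", {
  expect_equal(compute_psi(10, 10, 10), 50)
  expect_equal(compute_psi(8, 4, 0), 100)
  expect_equal(compute_psi(6, 10, 8), 50)   # (6+10)/2 = 8; 8/(8+8)
  expect_true(is.na(compute_psi(1, 1, 1, min_reads = 5)))
  expect_error(compute_psi(-1, 0, 0), "non-negative")

  expect_equal(compute_pir(0, 0, 10), 0)
  expect_equal(compute_pir(6, 6, 6), 50)
  expect_equal(compute_pir(4, 8, 6), 50)    # (4+8)/2 = 6; 6/12
  expect_true(is.na(compute_pir(1, 1, 0, min_reads = 5)))

  expect_equal(compute_psu(c(1, 1)), c(50, 50))
  expect_equal(compute_psu(c(9, 1)), c(90, 10))
  expect_equal(compute_psu(c(1, 1, 2)), c(25, 25, 50))
  expect_equal(sum(compute_psu(c(3, 9, 17))), 100)
  expect_error(compute_psu(c(0, 0)))
})

toy_span_record <- function() {
  # circRNA over three 100-nt exons at 100-200, 300-400, 500-600
  df <- data.frame(chrom = "chr1", start = 100, end = 600, name = "c1",
                   strand = "+", gene_name = "G", isoform_name = "G.1",
                   read_count = 50, rpm = 1, circ_type = "exonic",
                   start_status = "annotated", end_status = "annotated",
                   ambiguous = FALSE, library_id = "L1",
                   stringsAsFactors = FALSE)
  df$block_starts <- list(c(100, 300, 500))
  df$block_sizes <- list(c(100, 100, 100))
  class(df) <- c("circ_records", "data.frame")
  df
}

toy_linear <- function(start, end, reads) {
  df <- data.frame(chrom = "chr1", start = start, end = end,
                   name = paste0("lj", seq_along(start)), read_count = reads,
                   strand = ".", library_id = "L1", stringsAsFactors = FALSE)
  class(df) <- c("junctions", "data.frame")
  df
}

no_boundaries <- function() data.frame(chrom = character(0), pos = numeric(0),
                                       kind = character(0),
                                       read_count = numeric(0),
                                       library_id = character(0))

test_that("event detection finds the four basic patterns inside spans", {
  rec <- toy_span_record()
  models <- gene_models("G", "G.1", "chr1", "+",
                        list(c(100, 300, 500)), list(c(200, 400, 600)))
  # inclusion junctions e1-e2 and e2-e3 plus the skip e1-e3: cassette exon
  jn <- toy_linear(c(200, 400, 200), c(300, 500, 500), c(12, 10, 6))
  ev <- detect_splice_events(rec, jn, no_boundaries(), models)
  expect_equal(ev$event_type, "cassette_exon")
  expect_equal(c(ev$region_start, ev$region_end), c(300, 400))
  expect_equal(c(ev$a, ev$b, ev$c), c(12, 10, 6))
  q <- quantify_splice_events(ev)
  expect_equal(q$metric, 100 * 11 / (11 + 6))

  # inclusion only: no event
  jn2 <- toy_linear(c(200, 400), c(300, 500), c(12, 10))
  expect_equal(nrow(detect_splice_events(rec, jn2, no_boundaries(), models)), 0L)

  # two junctions sharing a donor, acceptors 10 nt apart: alt 3'SS on +
  jn3 <- toy_linear(c(200, 200), c(300, 310), c(9, 3))
  ev3 <- detect_splice_events(rec, jn3, no_boundaries(), models)
  expect_equal(ev3$event_type, "alt_3ss")
  expect_equal(ev3$sites[[1]], c(300, 310))
  q3 <- quantify_splice_events(ev3)
  expect_equal(q3$psu[[1]], c(75, 25))

  # intron retention from boundary reads
  bnd <- data.frame(chrom = "chr1", pos = c(200, 300), kind = c("ei", "ie"),
                    read_count = c(6, 6), library_id = "L1")
  ev4 <- detect_splice_events(rec, toy_linear(200, 300, 18), bnd, models)
  ret <- ev4[ev4$event_type == "intron_retention", ]
  expect_equal(nrow(ret), 1L)
  q4 <- quantify_splice_events(ret)
  expect_equal(q4$metric, 100 * 6 / 24)

  # under the expression filter nothing is searched
  expect_equal(nrow(detect_splice_events(rec, jn, no_boundaries(), models,
                                         rpm_threshold = 2)), 0L)
})

test_that("predominance calls respect delta, coverage and library types", {
  rec <- toy_span_record()
  models <- gene_models("G", "G.1", "chr1", "+",
                        list(c(100, 300, 500)), list(c(200, 400, 600)))
  samples <- toy_samples()
  clib <- samples[1, ]; llib <- samples[2, ]; rlib <- samples[3, ]
  mk_events <- function(incl, skip) {
    quantify_splice_events(detect_splice_events(
      rec, toy_linear(c(200, 400, 200), c(300, 500, 500),
                      c(incl, incl, skip)),
      no_boundaries(), models))
  }
  # circ PSI 90 vs linear PSI 5: predominant
  calls <- call_circ_predominant(mk_events(90, 10), mk_events(5, 95),
                                 clib, llib)
  expect_equal(calls$verdict, "predominant")
  # equal metrics: not predominant
  expect_equal(call_circ_predominant(mk_events(50, 50), mk_events(50, 50),
                                     clib, llib)$verdict, "not_predominant")
  # threshold sweep: 65 vs 50 fails delta 20, passes delta 10
  c65 <- mk_events(65, 35); c50 <- mk_events(50, 50)
  expect_equal(call_circ_predominant(c65, c50, clib, llib,
                                     delta = 20)$verdict, "not_predominant")
  expect_equal(call_circ_predominant(c65, c50, clib, llib,
                                     delta = 10)$verdict, "predominant")
  # no matching linear event: unassessable
  empty <- quantify_splice_events(detect_splice_events(
    rec, toy_linear(200, 300, 5), no_boundaries(), models))
  expect_equal(call_circ_predominant(mk_events(90, 10), empty,
                                     clib, llib)$verdict, "unassessable")
  # ribo- on the circular side is a hard error naming the library type
  expect_error(call_circ_predominant(mk_events(90, 10), mk_events(5, 95),
                                     rlib, llib), "ribo")
  # mismatched cell lines error
  llib2 <- llib; llib2$cell_line <- "OTHER"
  expect_error(call_circ_predominant(mk_events(90, 10), mk_events(5, 95),
                                     clib, llib2), "cell lines")
})

test_that("multi-cell-line confirmation filters predominant calls", {
  base <- data.frame(event_type = "cassette_exon", chrom = "chr1",
                     region_start = 300, region_end = 400,
                     verdict = "predominant", stringsAsFactors = FALSE)
  calls <- rbind(cbind(base, cell_line = "A"), cbind(base, cell_line = "B"),
                 cbind(base[0, ], cell_line = character(0)))
  other <- cbind(data.frame(event_type = "cassette_exon", chrom = "chr1",
                            region_start = 700, region_end = 800,
                            verdict = "predominant", stringsAsFactors = FALSE),
                 cell_line = "A")
  all_calls <- rbind(calls, other)
  kept <- high_confidence_across_lines(all_calls, min_lines = 2)
  expect_equal(unique(kept$region_start), 300)
  expect_equal(nrow(high_confidence_across_lines(all_calls, min_lines = 1)),
               nrow(all_calls))
  expect_equal(nrow(high_confidence_across_lines(other, min_lines = 2)), 0L)
})

test_that("PSI recovery and predominance error rates behave binomially", {
  set.seed(2024)
  n <- 200; reps <- 200
  # parameter recovery at p = 0.7
  p <- 0.7; ok <- 0L
  for (i in seq_len(reps)) {
    incl <- stats::rbinom(1, n, p)
    psi <- compute_psi(incl, incl, n - incl)
    if (abs(psi / 100 - p) <= 3 * sqrt(p * (1 - p) / n)) ok <- ok + 1L
  }
  expect_gte(ok / reps, 0.99)
  # specificity: identical circ/linear fractions, delta 20
  false_calls <- 0L
  for (i in seq_len(reps)) {
    ic <- stats::rbinom(1, n, 0.5); il <- stats::rbinom(1, n, 0.5)
    dpsi <- compute_psi(ic, ic, n - ic) - compute_psi(il, il, n - il)
    if (dpsi >= 20) false_calls <- false_calls + 1L
  }
  expect_lt(false_calls / reps, 0.01)
})
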