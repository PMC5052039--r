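---
title: "circkit: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circkit: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circkit)
```

# The model

## Back-splice junctions and their annotation

A back-splice junction is represented by the genomic interval
`[start, end)` of the resulting circRNA: `start` is the first base of the
most upstream circularized exon (the 3′ acceptor side) and `end` is one
past the last base of the most downstream exon (the 5′ donor side). On the
plus strand `start` is therefore an exon start and `end` an exon end; on
the minus strand the donor/acceptor roles swap but the genomic convention
is unchanged, which keeps all coordinate arithmetic strand-free. All
internal coordinates are 0-based half-open; GTF input is converted at the
boundary. Chromosome naming mismatches between inputs are errors, never
silently repaired.

Annotation (`annotate_circ()`) snaps each side of a junction to the nearest
exon boundary of each candidate isoform within a tolerance (default
**2 nt**, covering small aligner imprecision at chimeric breakpoints).
Among isoforms matching both sides, the winner minimizes total |offset|,
then maximizes the number of exons inside the span, then takes the
lexicographically smallest isoform name. These tie-breaks are package
conventions: the original pipeline's choice among equally good isoforms is
not documented anywhere we can consult, and determinism matters more than
any particular choice. An exact cross-strand tie emits both records flagged
`ambiguous`. Equidistant boundaries within one isoform resolve toward the
smaller coordinate. Junctions matching no isoform fall back to
`ciRNA-like` (contained in one annotated intron), exonic-with-novel-sites
(inside a gene span — the input queue for novel-exon discovery), or
`intergenic`.

The test suite pins this whole procedure to an independent brute-force
matcher that enumerates every (exon start, exon end) boundary pair of every
isoform.

## Expression unit and filters

circRNA expression is **RPM**: back-splice junction reads per million
mapped reads of the library, computed per library — multi-library runs
never pool denominators, since cross-cell-line comparisons require
per-library normalization. The high-confidence filter is **RPM ≥ 0.1,
inclusive**: a record at exactly 0.1 passes. Downstream, an alternative
back-splicing event is kept when *at least one* member circRNA passes.

## Alternative back-splicing and PCU

circRNAs from one library sharing a 3′ acceptor with ≥ 2 distinct donors
form an alternative 5′ back-splicing event; sharing a donor with ≥ 2
acceptors, an alternative 3′ event. Usage of each alternative site is

$$\mathrm{PCU}_m = 100 \cdot \frac{r_m}{\sum_n r_n}$$

over the junction read counts of the sites. *Proximal* means the site with
the smallest back-splice span (ties by coordinate) — the paper-style
figures depict proximal/distal genomically but never define them formally,
so span length is our operational definition. Cross-library variation
summaries match events by (type, chromosome, strand, common site), keep
events seen in ≥ 3 libraries (configurable), intersect the alternative-site
sets, renormalize PCU over the intersection (so libraries missing a
low-count site remain comparable and Σ = 100 holds), and report
min/Q1/median/Q3/max of the proximal-site PCU using linear interpolation
(R quantile type 7).

## Alternative splicing inside circRNAs

Only junction and boundary reads whose ends both fall inside the circRNA
span contribute to circular-fraction metrics. The estimators are the
standard junction-based ones; the exact formulas used by the original
study are in supplemental material unavailable here, so these are frozen,
documented conventions:

* cassette exon: $\mathrm{PSI} = 100\,\frac{(a+b)/2}{(a+b)/2 + c}$ with
  $a, b$ the two inclusion-junction counts and $c$ the skip count;
* intron retention: $\mathrm{PIR} = 100\,\frac{(e_5+e_3)/2}{(e_5+e_3)/2 + s}$
  with $e_5, e_3$ exon–intron boundary counts and $s$ the spliced-junction
  count;
* alternative 5′/3′ splice sites: PSU, arithmetically identical to PCU on
  canonical junction counts.

Events with fewer than **5** informative reads (configurable) are flagged
insufficient rather than quantified. A junction group sharing one end whose
variable ends are *all* exon boundaries of the host isoform is the
cassette/skipping pattern, not an alternative splice site, and is only
reported as a cassette event — without this rule every skip junction would
double-report.

**circRNA predominance.** Circular-side metrics must come from p(A)− or
p(A)−/RNase R libraries; ribo− libraries are rejected with an error because
they contain polyadenylated transcripts and cannot attribute a splicing
event to the circle. The linear side is the parallel p(A)+ library of the
same cell line. An event is predominant when circ − linear ≥ **Δ = 20
points** (convention, not from the source study's main text) with adequate
coverage on both sides; high-confidence events are those predominant in
≥ **2** cell lines. For alternative splice-site events the contrast is
site-wise: usage is renormalized over the sites shared by both libraries
and the site with the largest circ − linear gain is scored, since the
circRNA-predominant site is generally the alternative one, not a fixed
ordinal.

## Novel exons

A candidate exon is an interval inside a circRNA span bounded by the
acceptor end of one linear junction and the donor start of another, with
strand-appropriate GT/AG motifs at the implied splice sites (back-splicing
is spliceosomal, so canonical motifs are required by default;
`require_motif = FALSE` disables the gate). A candidate containing another
junction strictly inside it is rejected — a real exon has no spliced-out
intron within it; without this rule, junction pairs two exons apart
manufacture false multi-exon "exons". Exons of assembled (GTF) transcripts
overlapping circ spans are a second candidate route. Novelty is tested
against the *union* of reference sources (RefSeq, UCSC Known Genes,
Ensembl): presence in any one disqualifies, implemented as containment in
any same-strand reference exon. This makes the novel set monotonically
non-increasing in the reference.

Splice-site strength is an annotation-trained position-weight-matrix
log-odds in bits: donor windows of 9 nt (3 exonic + 6 intronic), acceptor
windows of 23 nt (20 intronic + 3 exonic) — community-conventional window
sizes — with pseudocount 1 per base per position and the training windows'
own base composition as background. The original study does not name its
scorer in the main text, so absolute scales are not comparable across
tools; only within-run contrasts (novel vs annotated) are meaningful.
ESE motifs are a user-supplied hexamer list (published sets differ in
licensing); density counts overlapping matches per kilobase.

## Flanking-intron RNA pairing

Orientation-opposite complementary sequences in the introns bracketing
back-splice sites can pair across the circle-forming region; competition
between a pair flanking the proximal sites and one flanking the distal
sites is the proposed driver of alternative site choice. The search aligns
intron A against the reverse complement of intron B by exact **k = 11**-mer
seeding and ungapped X-drop extension (match +1, mismatch −2, drop 15),
keeping alignments of length ≥ **30** at identity ≥ **0.8** and merging
overlaps by best score. The thresholds are documented conventions (the
study's exact criteria are supplemental); they comfortably capture the
planted 60-nt perfect repeats used in testing and Alu-scale real repeats,
while random 2-kb intron pairs yield an expected
$(L-k+1)^2/4^k \approx 0.94$ seeds and essentially zero surviving pairs —
a property the acceptance suite checks against that closed form. Introns
are truncated to 50 kb nearest the back-splice site to bound the quadratic
search. Gapped alignment is deliberately omitted at default: ungapped is
deterministic, fast, and adequate for high-identity repeats.

For an alternative event, the proximal pair is searched between the intron
transcript-upstream of the common-site exon and the intron downstream of
the proximal variable exon (mirrored for alternative 3′ events); the
distal pair uses the most distal variable exon. Events with more than two
sites are classified on their extremes. A member circRNA ending at a
transcript-terminal exon has no flanking intron; that side is reported
unsearchable rather than erroring, and excluded from summary denominators.

# The simulator: what it emulates, what it does not

`simulate_dataset()` generates a single-chromosome genome of multi-exon
genes on both strands with GT/AG (strand-appropriate) motifs at every
splice site, then plants: circRNA loci over internal exon runs; two-donor
alternative loci with a true proximal fraction *p*; cassette / retention /
alternative-splice-site designs with separate circular and linear
fractions; 60-nt perfect complementary element pairs in flanking introns
(placements `both`/`proximal`/`distal`/`none`, plus a background pair rate
of 0.2 on single-site loci — chosen to mirror the ~20 % pairing rate the
field reports for non-alternative circRNAs); and optionally withholds a
fraction of internal exons from the written reference annotation to create
ground-truth "novel" exons.

Evidence is emitted at junction-count level, not as reads: back-splice
counts are multinomial over alternative sites at fixed per-locus depth
(default 200), so totals equal depths exactly. For internal splicing, each
included molecule contributes **one read to each of its two inclusion
junctions** and each skipped molecule one skip read; retention likewise
yields equal boundary counts at both intron edges. Under this read model
the PSI/PIR estimators above are exactly binomial proportions, which is
what makes the 3-standard-error recovery criteria sharp. Library semantics:
p(A)+ emits no back-splice junctions and excludes withheld (novel) exons;
p(A)− and p(A)−/RNase R emit circRNA-derived junctions (the RNase R
fraction emits nothing outside circ spans); ribo− emits both. Default
depths (200 back-splice reads/locus, 100–200 per junction) and gene
geometry (4–7 exons of 80–200 nt, 300–800 nt introns) are small-genome
stand-ins chosen so a locus clears the RPM ≥ 0.1 filter at the default
1 M-read library size while keeping test genomes ~100 kb.

What the generator does **not** emulate — and hence what a green test does
not establish: sequencing error and mapping ambiguity (junction counts are
taken as given); linear nonpolyadenylated residue in p(A)− fractions (real
p(A)− libraries are contaminated; the p(A)+ contrast mitigates but the
simulator idealizes it away); expression-level biology (depths are uniform
across loci, not drawn from an expression model); imperfect or nested
repeat elements; multi-isoform host genes (one isoform per gene is
simulated, though the annotation code handles many); PCR duplicates.
Recovery of 100 % on simulated data therefore validates the bookkeeping and
the estimators, not robustness to alignment noise.

# Numerical and degenerate-input choices

* The RPM filter boundary is inclusive (`>=`), pinned by a test at exactly
  0.1 and at 0.0999….
* PCU/PSU of an all-zero count vector is an error (such an event cannot
  have been observed); zero-count sites are simply absent from events.
* Under-covered splicing events get `NA` metrics and an `insufficient`
  flag; they are never silently dropped before reporting.
* Exons consisting only of N have undefined GC (NA), not an error.
* Quantiles use R type 7 (linear interpolation), stated because Q1/Q3 of
  3–13 cell lines differ visibly across quantile definitions.
* Jittered junction coordinates are snapped per side independently;
  per-side nearest-boundary choice also minimizes total offset because the
  two sides are independent.
* `rpm` survives BED round trips exactly because it is serialized with
  `%.17g`.
* Seeds: one integer seed drives each simulation; every stochastic test
  fixes its own seed.

# Known limitations

* Mutually exclusive exons are out of scope (not among the four basic
  types handled).
* No statistical testing of PCU or PSI differences between cell lines;
  cross-line diversity is reported descriptively.
* The PWM splice-strength scale is not comparable to MaxEnt or other
  published scorers.
* circRNA abundance is junction-read based only; internal coverage is not
  used, and full-length circRNA isoform reconstruction beyond annotated
  blocks is not attempted.
* BAM input is not parsed; chimeric evidence must be exported to the STAR
  text dialect or junction BED first.
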