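---
title: "Methods: curated genome-wide ncRNA annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curated genome-wide ncRNA annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncRNAcurator)
```

## The problem

Plant genomes carry thousands of non-coding RNA loci across at least six
classes with very different discovery signatures. Similarity searches find
conserved family members but also fragments and paralogous noise;
covariance-model searches find structurally conserved loci the similarity
search misses; class-specific scanners (tRNA, snoRNA, rRNA) have their own
false-positive modes. The published evidence for plant miRNAs is especially
noisy — a majority of previously reported precursors in well-studied crops
fail current annotation criteria. This package implements the curation layer
between those upstream searches and a final locus catalogue: filtering,
strand-aware overlap resolution, class-specific validation, and
expression-evidence flagging, all deterministic and logged.

## Evidence model and overlap resolution

Every upstream hit is reduced to a common record: a 1-based inclusive,
stranded genomic interval plus query coverage, percent identity, e-value,
bit score, a source tag (`similarity`, `structural`, `specialist`) and
claimed class/family. Coordinates are GFF3-convention internally; BED I/O
converts to 0-based half-open at the file boundary. All sequences are
normalized to the uppercase T alphabet on ingestion, so U/T never matters
downstream.

Similarity hits are kept when coverage and identity are *strictly* greater
than 90% — the filter is worded as "over 90%", so 90.0 fails — and at least
60 nt long (59 nt fails, 60 passes: "smaller than 60" is removed).
Structural hits are kept at >= 60 nt and restricted to the five small
classes. Hits without a coverage value (a 12-column BLAST table and no query
lengths) fail the coverage filter closed, with a logged count: guessing
coverage would inflate false positives.

Overlap means >= 1 shared bp on the same contig and strand; cross-strand
overlaps coexist. Conflicts are resolved by an ordered tie-break cascade —
for similarity merges: highest coverage, highest identity, lowest e-value,
highest bit score; for structural and cross-source merges: score and
e-value. Chains of more than two mutually overlapping hits are resolved by
*repeated tournament*: the best remaining hit is kept, all its overlappers
are removed, and the process repeats. The upstream description of the
procedure is pairwise, so the multi-way rule is this package's own
construction; it is logged per removal (kept id, removed id, deciding
criterion) and checked in the tests against an independent exhaustive
tournament on every input of up to eight mutually overlapping hits. After
cascade exhaustion, ties break lexicographically on
(contig, start, end, query id), which makes the output independent of input
order — determinism replaces the "manual analysis" such overlaps would
historically get.

## Class-specific stages

**snRNA.** The accepted family vocabulary is the full set of nine
spliceosomal U snRNAs (U1, U2, U4, U4atac, U5, U6, U6atac, U11, U12), even
though U4atac is rarely observed in plants — the filter defines the family
universe, not any one species' outcome. Length bounds 60–220 nt, inclusive
on both sides (derived from exclusion wording).

**tRNA.** Bounds 70–95 nt, inclusive (again from the exclusion wording:
"smaller than 70" and "more than 95" are excluded, so 70 and 95 survive).
tRNA-SeC predictions are kept but flagged `is_putative_false_positive`,
since dedicated scanners are known to call spurious selenocysteine tRNAs in
plants and higher plants lack the selenocysteine insertion machinery;
confirming them is out of scope. An anticodon whose reverse complement does
not translate to the claimed isotype under the standard code is flagged, not
dropped. The isoacceptor table reports distinct anticodons per isotype; the
standard code bounds the total at 61.

**rRNA.** Unit labels (5S, 5.8S, LSU-fragment, SSU-fragment, indeterminate)
come from family-label string rules, with 5.8S tested before 5S so the
substring does not shadow it. No upper length bound is imposed: observed
rRNA fragments range far above the small-RNA sizes and no bound is stated
for them.

**snoRNA.** C/D box validation demands the leftmost RUGAUGA starting within
the first 10 nt and the rightmost CUGA ending within the last 10 nt, C box
before D box; H/ACA validation demands an ANANNA H box starting within the
central 35–75% of the sequence and an ACA starting within the last 6 nt.
The terminal windows, hinge span and ACA window quantify "near the ends",
"hinge region" and "next to the 3' end", which canonical snoRNA literature
places in these regions without exact offsets; all three are configurable
and the defaults are recorded here deliberately. Candidates within 60–300 nt
that fail both motif sets keep evidence-only status (not high-confidence)
rather than being discarded. When both motif sets match, the evidence family
label decides, defaulting to C/D. Clusters are single-linkage chains of
snoRNA genes whose facing-end gaps are strictly below 500 nt (a 500-nt gap
does not chain); strand is ignored because plant snoRNA clusters are
polycistronic.

## miRNA curation

The curation engine applies eight rules per candidate: R1 non-redundancy
(exact or reverse-complement precursor duplicates collapse to one
representative, chosen by source priority then id), R2 precursor <= 300 nt
(301 fails), R3 a single qualifying hairpin, R4 two mature sequences, R5
exact location of both matures in the precursor, R6 mature length in
[21, 22] nt (a [20, 24] relaxation is configurable), R7 expression support
(each mature with >= 1 read in >= 1 library; configurable), and R8 duplex
geometry: matures on opposite arms, <= 5 mismatched positions, <= 3-nt
asymmetric bulge. A candidate failing only R4/R7 can be force-included via
an allowlist, mirroring the rescue of qPCR-validated loci.

The hairpin test is deliberately not a trained classifier: folding is
base-pair maximisation (Nussinov-style dynamic programming; allowed pairs
AU/GC/GU, minimum loop 3 nt) with a deterministic traceback (pairing
preferred over leaving the 5' base unpaired; 5'-most partner on ties). A
qualifying hairpin is a stem-loop of >= 15 pairs; with known matures,
exactly one terminal loop may lie between them. This keeps the test
dependency-free, configurable and provable against an exhaustive
structure-enumeration oracle (every sequence up to 15 nt in the tests).
Maximum-pairing is not thermodynamic folding: it over-pairs relative to
minimum-free-energy structures, which is acceptable here because the test is
a coarse "is there one real hairpin covering the duplex" gate, not a
structure prediction.

Mature-length exclusions and "failed in more than one criterion" reporting
are ambiguous in the upstream literature (published failure categories can
overlap); the engine therefore reports both a per-candidate failed-rule set
and bucketed summary counts that partition the input: redundant first, then
pass, then one bucket per single-failed rule, then a multi-failure bucket.

Target sites are scored 5'→3' along the mature with an additive expectation
penalty: +1 per mismatch, +0.5 per G:U pair, +2 per gap opened, +0.5 per
extended gap position, all doubled at mature positions 2–13 (the seed).
Scanning is antisense-only with ungapped windows; the gapped score is
available through the pairwise scorer. A perfect reverse-complement site
scores 0; hits below the cutoff (default 2, the conventional
high-confidence bound) are reported.

## lncRNA identification and classification

Stage order is fixed: length (>= 200 nt) → redundancy (80% identity) →
coding filter → genome anchoring (>= 95% coverage and identity, inclusive)
→ exclusion of candidates overlapping any other ncRNA locus (>= 1 bp,
strand-agnostic) → positional classification with precedence
sense > antisense > gene_overlap > no_overlap. The "more than 200 nt" and
"ranging from 200 nt" wordings conflict upstream; the inclusive reading
(>= 200) was adopted since the observed ranges include 200 exactly.
Redundancy removal does not re-implement CD-HIT-EST: a deterministic
greedy longest-first clustering (ties by name) joins a transcript to the
first representative whose best ungapped k-mer-anchored diagonal reaches
80% identity of the shorter sequence — same intent, documented and
deterministic. The coding filter is pluggable: external classifier labels
plus a protein-hit list take precedence (ids missing from the label table
are conservatively treated as coding); the self-contained fallback is an
ORF heuristic (noncoding iff the longest ORF across all six frames is
under 100 codons), clearly a stand-in with a different operating point than
a trained coding-potential classifier. Antisense calls use the candidate's
anchored strand (a minus-strand anchor makes the candidate a minus-strand
locus); whether upstream analyses did the same is not documented, so this
choice is stated here.

## Expression evidence

Reads are counted per locus and library with strand-aware overlap
(>= 1 bp); a read spanning several loci counts once for each. A locus is
`expressed` when reads from at least two independent studies support it and
`high_support` when its total read count across all libraries is strictly
greater than 10 ("more than 10"; a total of exactly 10 fails, 11 passes).
The total is summed across libraries because no per-library qualifier is
stated; both the threshold and the per-library alternative are
configurable. The two flags are deliberately independent — upstream usage
of "high-confidence" mixes structural and read-count senses — and the
composite `expressed_or_high_support` is reported alongside. Differential
expression itself is out of scope; the package exports count matrices and
contrast files for external count-based DE tools.

## Phylogeny

For miRNA family analyses the package computes p-distances (proportion of
differing sites; gapped sites removed pairwise by default, with complete
deletion available since the upstream software's gap handling is not
documented), builds neighbor-joining trees (via ape; Q-criterion NJ with
standard branch-length formulas, negative branch lengths reported as
computed unless clamped) and attaches bootstrap supports as percentages of
column-resampled replicates containing each internal bipartition. The
conventional full-scale replicate count (5000) is the config default; the
tests and acceptance script use 100–200 replicates, which is ample to
saturate an invariant cherry at 100%.

## The synthetic-data generator

`simulate_ncrna()` emulates the inputs the pipeline consumes in a real
genome project: two assembled chromosomes plus an unplaced scaffold
("chr0", carrying only background reads and sub-threshold decoy hits,
mirroring the pseudomolecule bookkeeping of draft assemblies), planted loci
of all six classes, gene models with exons, candidate transcripts, miRNA
candidate records, emulated blast6/Infernal-tblout/tRNAscan hit tables and
three small-RNA libraries mapped to three independent studies.

Every filter has planted boundary fixtures: snoRNA cluster gaps of 100, 499
and exactly 500 nt; tRNA lengths 69/70/95/96 nt; a 230-nt U-family locus; a
301-nt miRNA precursor, a single-mature candidate, a hairpin-less candidate,
23-nt matures, an unexpressed candidate and a redundant duplicate; 199-nt,
coding and duplicated lncRNA transcripts, one candidate of each positional
class and one overlapping a tRNA locus; read totals of exactly 10 and 11 and
single-study-only support around the expression rules. Planted motif loci
are rejection-sampled so that accidental motifs in the random background can
never flip an intended verdict, and miRNA constructions are verified against
the rule engine at generation time — intended outcomes are achievable by
construction. All randomness flows from one seed; a rerun is byte-identical.

What the generator does *not* emulate: sequencing error, adapter artefacts
and quality scores (trimming is upstream and out of scope), paralogous
families with partially diverged copies, compositional biases (background is
uniform by default, with a GC knob), and realistic read-depth distributions
(per-locus counts are planted exactly). Passing the closed loop therefore
demonstrates that the decision logic implements its rules faithfully — not
that the thresholds themselves are optimal for any particular real genome.

## Numerical and design choices

* Degenerate inputs: empty hit tables and locus tables flow through every
  stage; zero-read libraries warn and contribute zero columns; a gene
  without exon features is treated as all non-exonic gene region (logged).
* All writers emit stable sort orders and no timestamps, so equal inputs
  give byte-identical files.
* Folding traceback, overlap-resolution tie-breaks, redundancy clustering
  order and dedup representative choice are all explicitly deterministic;
  there is no hidden dependence on input order.
* Problem sizes in the tests: the default simulation plants roughly 100
  loci across ~100 kb, the folding oracle enumerates all structures for
  sequences up to 15 nt, the resolution oracle covers up to 8 mutually
  overlapping hits, and NJ recovery uses random additive trees of up to 10
  taxa — sizes chosen so the whole suite and the acceptance script each run
  in a couple of minutes on one core while still exercising every rule and
  boundary.

## Known limitations

The coding-potential heuristic and the greedy redundancy clustering are
documented stand-ins for trained/optimised external tools and will not
reproduce their exact outputs on real data. Base-pair-maximisation folding
over-pairs relative to thermodynamic models. The snoRNA box windows encode
canonical descriptions, not fitted values. Chromosome-scale statistics in
the report are only as meaningful as the upstream evidence supplied. None of
these affect the package's core contract: given the same evidence and
configuration, the curation decisions are exact, reproducible and fully
logged.
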