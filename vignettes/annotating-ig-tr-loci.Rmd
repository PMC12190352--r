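---
title: "Annotating IG and TR loci by reference transfer: methods and design"
author: "vdjloci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating IG and TR loci by reference transfer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjloci)
```

# The problem and the approach

Antigen-receptor loci (IGH, IGK, IGL, TRA, TRB, TRG, TRD) encode many
short, mutually similar V, D and J gene segments and multi-exon C genes.
Annotating a newly assembled contig means locating every segment,
deciding whether it could function in V(D)J recombination, and emitting
coordinates in standard formats. `vdjloci` treats this as *annotation
transfer*: a curated reference annotation (an IMGT/LIGM-DB-style flat
file, or a previous run's output) provides full-length gene sequences,
exon structure and conserved-residue positions; the novel contig is
searched by homology; candidates are then vetted against the biology
of recombination and splicing.

Using the *full genomic span* of each reference gene as the search query
— introns included — is a deliberate choice. It allows multi-exon C
genes and V leader exons to be carried into the target in one step, and
it makes the homology signal robust to the short lengths of J (~50 nt)
and D (~10–35 nt) segments, which would be hard to anchor from coding
sequence alone.

# RSS scanning with RIC models

A candidate segment is only credible if a recombination signal sequence
(RSS) abuts its coding end: a conserved heptamer (consensus `CACAGTG`),
a 12 or 23 nt spacer, and a nonamer (consensus `ACAAAAACC`). RSS are too
variable for alignment-based detection, so the scanner uses a
statistical model of recombination information content (RIC).

**Model form.** For a window of length 16 + spacer (28 nt for the
12-class, 39 nt for the 23-class), position $i$ carries a table of
conditional probabilities $P(b_i \mid b_{i-k..i-1})$ estimated from
aligned training windows with an additive pseudocount, where $k$ =
`min(order, i - 1)`. The score of a window is
$\sum_i \log P(b_i \mid \text{context}_i)$ in nats; the consensus of a
noise-free model scores exactly 0 and everything else is negative. Order
0 reduces to a position weight matrix; the default order 1 captures
nearest-neighbour dependence, the simplest structure beyond
independence. The dependence depth is a constructor argument, so richer
structures can be explored without touching the scan code.

**Threshold.** There is no universal RIC cutoff; the default reporting
threshold is the *minimum training-window score minus a 5-nat margin*.
This guarantees that every window the model was trained on would be
recovered by a scan, while keeping random background (which scores tens
of nats lower, because ~12 of the 16 conserved core positions mismatch
in expectation) far below threshold. The margin and the threshold are
user-settable per model: transfer across species with a foreign model is
exactly the situation where a laxer threshold may be needed.

**N handling.** Any `N` in a window makes its likelihood undefined; such
windows score $-\infty$ and are never reported. Assembly gaps are
handled downstream by the completeness/gap rules, not by the scanner.

**Interchange.** Candidates are exchanged as BED6 with the RIC score
rescaled affinely from `[threshold, 0]` onto `[0, 1000]`, so any
external RSS predictor whose output can be reformatted as BED can slot
into the pipeline in place of the built-in scanner. The integer BED
score quantizes the RIC value; intervals, strands and spacer classes
round-trip exactly.

**Limitation.** Spacer lengths are fixed at 12 and 23 nt; the ±1 nt
spacer polymorphism seen in nature is not modelled, and a window
containing it will score as if misaligned.

# Homology search and chaining

The default engine is a self-contained seed-and-extend aligner: exact
k-mer seeds (word size 11 for V/J/C, 7 for D) are grouped by diagonal,
and each cluster is refined by Smith–Waterman with affine gaps
(match +1, mismatch −2, gap open 5, extend 2) via
`Biostrings::pairwiseAlignment`, restricted to the cluster's
neighbourhood so stray seeds stay cheap. Significance is reported as an
approximate Karlin–Altschul e-value so the gates mean the same thing
whichever engine runs; `blastn` (tabular output) is supported as an
external engine and is cross-checked against the built-in one in the
test suite.

Per-type gates reflect segment biology: V/J/C hits must pass e-value
≤ 1e-10 and 60% identity; D genes are so short that significance is
meaningless, so they instead require 80% identity over ≥ 90% of the
reference D length at a relaxed e-value (≤ 10), and the raw-score floor
is lowered to 8 so a perfect 10 nt D match is never discarded by the
aligner itself. The e-value ceiling is the primary sensitivity knob when
transferring between distant species.

**Chaining.** A multi-exon gene whose introns have diverged produces one
local hit per conserved exon. `chainHits()` assembles hits for one gene
and strand into gene models by exact dynamic programming: maximize the
summed bit score over strictly co-linear hit chains whose consecutive
target gaps are ≤ `max_intron` (default 16 kb, sized for the
kilobase-scale introns of IGH/TRA/TRB C genes) and query gaps are
≤ 50 nt. Chains are peeled off best-first so each hit belongs to at most
one candidate; the test suite checks the DP against exhaustive subset
enumeration. Candidate selection is greedy per segment type, ranked by
(bit score, completeness, name), rejecting a candidate whose coding
projection overlaps an accepted one by more than half its length — so
two alleles of one gene yield a single call, with the name as the
deterministic tie-break.

**Exon projection.** Reference exon boundaries are mapped onto the
target through the chain's gap-free aligned blocks. A boundary that
falls in an unaligned gap is first placed by nearest-aligned-position
interpolation and then snapped to the nearest plausible GT (donor) or AG
(acceptor) within ±6 nt, since splice verification is about to judge
exactly those dinucleotides. Boundaries inside aligned blocks are taken
as aligned, without adjustment.

# Verification and classification

Each selected candidate passes through four checks:

* **RSS matching** — required flanks by segment type (V: 3' of the
  coding end; J: 5' of the coding start; D: both), with spacer classes
  from a per-locus 12/23-rule table (`locusRules()`; IGH V/23–D/12,12–
  J/23, IGK V/12–J/23, IGL V/23–J/12, TRA V/23–J/12, TRB and TRD
  V/23–D/12,23–J/12, TRG V/23–J/12 — data, not code, and overridable).
  The heptamer edge must lie within 3 nt of the gene boundary (the
  heptamer abuts the coding end biologically; the small tolerance
  absorbs projection error). Among eligible RSS the best RIC score wins,
  ties to the smaller coordinate.
* **Splice verification** — every intron implied by the exon map must
  begin `GT` and end `AG` (read on the gene strand); observed
  dinucleotides are recorded, so a GC donor is visible in the report.
  Single-exon genes pass vacuously.
* **Coding checks** — the spliced coding sequence must start with ATG
  (V genes), contain no stop codon, and differ from the reference coding
  length by a multiple of 3. Conserved residues (V: both cysteines, J:
  the tryptophan/phenylalanine) are checked at positions projected from
  the reference through the alignment. D segments have no intrinsic
  reading frame — it is set during rearrangement — so stop and
  frameshift checks do not apply to them.
* **Classification** — defects are accumulated as machine-readable
  codes. `INTERNAL_STOP`, `FRAMESHIFT` and `NO_START` are
  pseudogene-class; `RSS_MISSING`, `NONCANONICAL_SPLICE`,
  `MISSING_CONSERVED_CYS` and `MISSING_CONSERVED_WF` are ORF-class. Any
  pseudogene-class code makes the call "pseudogene"; otherwise any
  ORF-class code makes it "ORF"; otherwise "functional". The function is
  pure: the same report always yields the same call.

Candidates whose aligned coverage of the reference coding region falls
below `completeness_min` (default 0.95) or whose projected coding region
contains any `N` are withheld from the output entirely and logged with
coordinates and cause — an assembly gap inside a coding exon is not
evidence of a pseudogene, and reporting a half-gene would poison
downstream use.

**D segments and false positives.** A 10–15 nt D reference matches
i.i.d. background by chance every few hundred kilobases even at 80%
identity and 90% coverage, and such a match carries no RSS. Because a D
segment is biologically defined by its flanking 12/23 RSS pair, a D
candidate with *no* matched RSS on either flank is withheld (logged as
`D_WITHOUT_RSS`) rather than reported as an ORF. A D with at least one
matched flank is still reported, so a single scrambled RSS downgrades it
to ORF rather than deleting it.

**Naming.** A candidate whose coding (or full-span) sequence exactly
matches the reference allele index inherits that `gene*allele` name.
Novel sequences are named `gene*xxxx` where `xxxx` is the first four
lowercase hex characters of the SHA-1 digest of the uppercase, ungapped
coding nucleotide sequence (exons concatenated, introns excluded) — the
coding sequence is the allele-defining unit, and hashing it makes names
reproducible across runs and machines. Prefix collisions between
distinct sequences are logged and disambiguated with `_2`, `_3`, …
suffixes.

# Coordinates and formats

Internally every feature is a `GenomicInterval`: 0-based, half-open,
contig-forward, with explicit strand; minus-strand features are stored
in contig-forward coordinates and reverse-complemented only at sequence
extraction. Conversion to 1-based inclusive coordinates happens at
exactly one place, the GFF3 writer. The GFF3 dialect is strict: version
pragma first, one `##sequence-region` per contig, nine tab-separated
columns, percent-encoding of `; = & ,` tab and newline in attribute
values, CDS features always phased, parents before children, and a
deterministic (contig, start, ID) ordering that makes re-emission
byte-identical. The reader enforces the pragma and column count with
line numbers and resolves `Parent` references. BED is BED6, 0-based
half-open, scores clamped to [0, 1000]. Sequences outside `{A,C,G,T,N}`
are rejected on ingest by default (`ambig_to_n = TRUE` maps IUPAC
ambiguity codes to N), because the RIC model and the translation
contracts are defined over that alphabet.

The flat-file parser accepts the EMBL feature-table grammar (`n..m`,
`complement`, `join`/`order`, nesting, `<`/`>` fuzzy bounds recorded as
a partial flag) and a documented label lexicon (V genes from L-PART1 /
L-PART2 / V-EXON / V-REGION; D-REGION; J-REGION; C genes from C-REGION,
CH1–CH4, H, H1, H2, CH-S, M, M1, M2, EX1–EX4, with EX4UTR as
non-coding). LIGM-DB formatting is not fully standardized, so unknown
labels are preserved as passthrough notes and a gene with no locatable
exon is skipped with a log entry — parsing is total on tolerated input.
When explicit `1st-CYST`/`2nd-CYST`/`J-TRP`/`J-PHE` labels are absent,
conserved positions are borrowed from the closest same-type gene that
has them, via translated pairwise alignment; if none exists the residue
check is simply skipped and the gene can still be classified on the
other criteria.

# The synthetic-locus generator

The generator is the package's validation instrument, and its defaults
are the study conditions of the test suite: loci of 8 V + 4 D + 6 J +
2 C genes (D only for loci that have D), V coding 270–309 nt with a
45–60 nt ATG-initiated leader exon and an 80–150 nt GT/AG intron,
cysteine codons at fixed projected positions, D of 10–35 nt, J of
45–63 nt with a TGG codon ten codons from the end, C genes of 2–4 exons
of 102–330 nt separated by 100–2000 nt introns, intergenic spacing
uniform on 500–5000 nt, and i.i.d. uniform-ACGT background
(GC-content configurable). Genes are planted on random strands with
their required RSS abutting the coding boundaries, and the same
structures are rendered as an IMGT-style flat file so the parser is
exercised against known truth. Identical spec and seed give
byte-identical output.

Planted RSS are resampled from the same window pool the scan models
were trained on. This makes the generator's detectability guarantee
literal: a planted window scores at least the minimum training score,
which is above the default threshold by construction of the margin
rule. Sampling fresh windows from the consensus-noise distribution
instead (the `rss_noise` path) occasionally produces a window in the
distribution's lower tail that a default-threshold scan would miss —
useful as a harder, more realistic regime, but not as ground truth for
an exactness test.

Mutation operators apply exactly one change per gene, so the expected
call is unambiguous: `introduce_stop`, `delete_start` and
`frameshift_del1` are pseudogene-class; `scramble_rss` (one flank only,
for D) and `gc_donor` are ORF-class; `insert_n_gap` (200 N into a coding
exon) must lead to the candidate being withheld as gap-broken.

The divergence series (`divergeReferenceSet()`) emulates cross-species
transfer by substituting the *reference* sequences i.i.d. at rates 0,
5, 10 and 20% before the search, while the target stays fixed. Each
position carries one uniform draw compared against the rate, so the
mutation sets are nested across rates: the recall curve then measures
the effect of divergence itself rather than the sampling noise of
independent mutation draws, and monotone degradation is the meaningful
expectation to test.

What the generator does *not* emulate: real loci have paralogous gene
families with high mutual similarity (the generator's genes are
independent random sequences, so cross-gene confusion is untested),
indel-rich evolutionary divergence, segmental duplications, haplotype
variation, and non-uniform base composition. Passing the synthetic
suite therefore demonstrates correctness of the machinery — coordinate
arithmetic, chaining, verification logic, classification, naming — not
performance on any particular genome.

# Problem sizes and numerical choices

The default validation runs ten ~20-gene loci (~70–90 kb each) for
plant-and-recover, three replicate loci for the mutation matrix, two
loci across four divergence rates, 200 random windows per model order
for the RIC oracle (agreement to 1e-12 absolute, the double-precision
summation budget), and 30 random hit sets of up to 10 hits for the
chaining oracle (exhaustive enumeration is 2^10 subsets). RIC training
uses 400 windows at spacer noise 0.1 (heptamer/nonamer noise 0.02);
`trainRic` uses pseudocount 1 by default so unseen contexts stay finite.
Ties are broken deterministically everywhere (score, then completeness,
then name, then coordinate), which is what makes re-runs and re-emitted
GFF3 byte-identical.

# Known limitations

* Fixed-length spacers; no flexible-spacer RSS scoring.
* The RIC dependence structure is a within-window order-k chain; no
  claim of score parity with any published RSS scanner is made.
* C-gene reading frames are assumed to begin in frame 0 at the first
  coding exon, as IMGT constant-region annotations conventionally do.
* Cross-type overlaps are not resolved (a V and a D may in principle be
  reported on overlapping coordinates; overlap resolution is
  within-type).
* IMGT unique numbering (gapped V alignment) is out of scope; conserved
  residues are located by projection, not by numbering.
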