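---
title: "Models and methods behind the retrozyme pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the retrozyme pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrozyme)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and the limits of what the synthetic benchmarks demonstrate.

## The HHR descriptor and its linearization

A hammerhead ribozyme is modelled as a grammar of sequence elements: two
conserved core boxes (`box1 = CUGANGA` between helices I and II, `box2 =
GAAAC` between helices II and III), the cleavage triplet `NUH` (H = A, C or
U; scission 3′ of the H), three helices with per-helix base-pair ranges, and
the loops closing them. Counting every box and triplet position — including
the degenerate N and H slots, which are structurally required even though
their identity is free — the default descriptor constrains exactly 15 core
positions, the canonical size of the motif's catalytic core.

The three HHR topologies are the circular permutations of one element
cycle, named for the open-ended helix. The grammar drawing fixes adjacency
but not a unique linearization, so the package fixes one and uses it
consistently in both the matcher and the generator:

```
type I   : h1a il1a box1 h2a loop2 h2b box2 h3a loop3 h3b NUH il1b h1b
type II  : h2b box2 h3a loop3 h3b NUH il1b h1b l1t h1a il1a box1 h2a
type III : h3b NUH il1b h1b l1t h1a il1a box1 h2a loop2 h2b box2 h3a
```

`il1a`/`il1b` are the two strands of the internal loop of helix I — the
"loop 1" region that makes tertiary contacts with loop 2 of helix II in
canonical type I motifs. When helix I is not the open helix (types II and
III), a terminal loop `l1t` closes it. Type II motifs have no terminal
loop 2 (helix II is the open helix), so their tertiary-contact count can
only draw on loop 1; with the default threshold they classify as minimal.
This is a deliberate simplification: the canonical/minimal distinction in
this package is about the type I loop–loop contact.

Default element ranges: helix I 3–11 bp, helix II 3–6 bp, helix III 1–6 bp
(down to the single base pair seen in amphibian motifs), internal loop 0–4
nt per strand, loop 2 4–10 nt, loop 3 3–8 nt. G·U wobble pairs are allowed
inside helices (standard for RNA), and the core is matched exactly
(`max_core_mismatches = 0`) so that the synthetic false-positive rate stays
near zero; both are configurable.

Two further grammar decisions deserve explanation:

* **Helix II base mismatch.** One of the two axolotl ribozyme families
  carries a U·U mismatch at the core-proximal position of helix II. A
  strict complementarity rule could never match such a motif, so the
  descriptor admits (by default) exactly one non-complementary pair at that
  position; the feature is recorded per hit and feeds the cleavage-mode
  prediction.
* **Tertiary rule identities.** The loop 1/loop 2 nucleotides that form the
  tertiary contact are depicted structurally in the field's figures rather
  than printed as a linear consensus. The shipped defaults (`UG` anchored at
  the start of loop 1, `GUGA` at the start of loop 2, ≥ 3 of the 6
  constrained positions required) are configurable placeholders: they make
  "canonical" a well-defined, testable label without claiming to reproduce
  the exact published identities.

## Matching, scanning and determinism

`match_at()` enumerates *every* assignment of element lengths at a given
offset — no heuristics, no scoring shortcuts — accepting an assignment iff
the boxes match within the mismatch budget and every helix is complementary
under the pairing alphabet. Windows containing N never match (conservative
and reproducible). `scan_genome()` accelerates this only by anchoring: with
exact cores, any match must place `box1` on an exact occurrence, so only
offsets compatible with an occurrence are enumerated; with a non-zero
mismatch budget it falls back to all offsets. `brute_force_scan()` *is* the
reference semantics — enumeration from every offset — and the test suite
asserts `scan_genome ≡ brute_force_scan` on random sequences, so the
anchoring is an optimization with a proof obligation, not a behavioural
choice.

One genomic window can admit several foldings (e.g. a shorter helix II plus
a longer loop). The pipeline reports a single hit per overlapping cluster:
the assignment with the most total base pairs, ties broken by leftmost
start then shortest span. Output is sorted by (contig, start, strand);
re-running any command with the same inputs and seed is byte-identical.

Hit variant labels derive from the tertiary-contact count: `canonical` iff
the count reaches the canonical threshold, otherwise `minimal`. The
predicted cleavage mode is a pure function of features: helix III ≤ 1 bp →
`dimer_required` (such motifs barely self-cleave as monomers and pair up in
dimeric arrangements); helix III = 2 bp or missing tertiary contacts →
`weak`; helix III ≥ 3 bp with contacts → `monomer_competent`. The
thresholds are arguments with these defaults.

## Locus annotation

Hits on one contig and strand whose start-to-start spacing is ≤ `max_gap`
(default 900 nt = 2 × the largest monomer considered) form a tandem
cluster. The monomer period is the **median** spacing — robust to a single
aberrant gap — and the copy number is the hit count, which assumes one HHR
per monomer (the repeat architecture modelled here; the assumption is
recorded rather than verified). Locus spans cover whole arrays, anchored at
the strand-5′ HHR: `copy_number × period` nucleotides. Three quality
measures follow:

* `validate_repeat`: the fraction of positions matching one period ahead
  (1.0 for exact arrays, ≈ 0.25 for unrelated sequence); it decreases
  monotonically with substitution rate — with per-copy i.i.d. mutations at
  rate μ the expectation is (1 − μ)² + μ²/3.
* `locus_gc`: percent G+C of the span.
* `detect_tsd`: the longest k ≤ 20 for which the k-mer immediately 5′ of
  the locus equals the k-mer immediately 3′ of it — the duplicated target
  site brackets the insertion. Only exact duplications of ≥ 5 nt are
  reported, because metazoan retrozyme TSDs are described as larger than
  the typical 4 bp of plant elements.

Classification: `retrozyme` iff ≥ 2 copies, period within 150–450 nt and
GC < 45% (the printed bounds for metazoan retrozyme repeats; all three are
config values), `isolated_hhr` for singletons, `ambiguous` otherwise.

Monomer sequences of retrozyme loci are clustered into families by greedy
centroid clustering: each sequence joins the first family whose centroid
identity reaches the threshold (default 0.80), else founds a new family.
Identity is global-alignment matches over alignment columns under unit
scoring (match +1, mismatch 0, gap −1), computed with
`Biostrings::pairwiseAlignment`. The 0.80 default is a design choice — no
threshold is printed for the published family counts — chosen so that
indel-separated length variants of one element (identity ≈ 225/245 ≈ 0.92)
stay in one family while unrelated monomers (identity ≈ 0.55) split. Being
greedy and order-dependent, the clustering is deterministic in input order,
which the pipeline fixes to genomic order.

## Cleavage kinetics

The co-transcriptional self-cleavage model is first-order:
F_t = F_inf (1 − exp(−k t)), t in minutes, k = k_obs in min⁻¹. Fitting
exploits the model's structure: for fixed k the optimal F_inf is the
closed-form least-squares slope through the origin of F_t on
(1 − e^(−kt)), so the fit is a 1-D minimization over log k — bracketed on a
coarse 80-point grid, then golden-section to a relative tolerance of 1e−6,
within k ∈ [1e−5, 10] min⁻¹. The `converged` flag additionally requires the
optimum to sit away from the search bounds. F_inf is capped at 1.05 to
absorb small gel-quantification overshoot; fitted values above 1 warn.
t = 0 points are excluded from the residual (the model passes through the
origin exactly); at least three positive-time points are required, and
all-zero data is refused as degenerate. The test suite pins the fitter to
an independent dense 2-D grid-search oracle to three significant figures.

Simulated time courses (eight points on 0.5–30 min by default, Gaussian
noise sd 0.02 — a realistic gel-quantification error, clipped to [0, 1])
recover the generating rate to within a few percent in the median over 50
seeds at both rate regimes studied (0.8 and 0.1 min⁻¹).

## Maximum base-pairing fold

Free-energy folding is out of scope; all structure statements are restated
as **maximum base-pairing** properties and labelled as such. The fold is
the classic O(n³) nested-structure dynamic program (min_loop = 3 unpaired
nt enclosed per pair; G·U counted by default), with deterministic traceback
(skip-i preferred, then smallest pairing partner). Circular RNAs are folded
as the best linear cut over all rotations, which multiplies cost by n —
fine for the monomer-scale sequences it is intended for.

Two honest caveats, both verified by simulation during development:

* Pair *count* is reverse-complement invariant only under strict
  Watson–Crick pairing: a G·U pair maps to A·C under reverse
  complementation. With wobble on, counts can differ between a sequence
  and its reverse complement.
* The maximum-pairing score of random RNA is high (~0.8 of positions at
  these lengths), so `self_pairedness` does **not** discriminate generator
  monomers from dinucleotide-shuffled controls: the generator fills
  monomers with i.i.d. sequence, and the guaranteed HHR helices are too
  small a fraction to shift the saturated score. Designed hairpins do
  out-pair their shuffles, and that is what the tests assert. Statements
  about real retrozyme circRNAs being "highly self-paired" rest on
  thermodynamic folding of real sequences and are not reproduced by this
  heuristic on synthetic data.

## The synthetic-genome generator

The generator defines the study conditions. Species profiles fix monomer
lengths and HHR features to the published repeat landscapes: coral 225/245
nt (the shorter variant derived from the longer master by deleting a 20-nt
block — the "typical indel"; copies 2–62), mussel 350–390 nt (uniform;
tertiary contacts actively absent), axolotl 330 nt (1-bp helix III,
palindromic tetraloop) and 350 nt (2-bp helix III, U·U at the helix II
base). Values the sources do not state were fixed once at realistic
levels: background GC 0.42 and monomer GC 0.38 (comfortably below the 45%
cutoff; the monomer filler is re-drawn until within ±2 points of target so
classification does not ride on composition noise), TSD length 6 nt
(satisfying "larger than 4 bp"), substitution noise 0 by default (exact
arrays; a mutation-rate parameter exists for robustness tests).

Each locus is one master monomer per profile (so family structure reflects
descent), tandem-duplicated, flanked by a duplicated 6-mer target site, and
inserted at a random non-overlapping background position on a random
strand. The HHR sits at the monomer start, i.e. tandem copies abut at
cleavage positions, mirroring monomer excision at repeat junctions. Three
boundary constraints make the planted truth *exactly* recoverable rather
than merely approximately: loop ends are rewritten so no helix can extend
inward by an accidental loop-end pair (otherwise an alternative folding
with one more base pair would outrank the planted one), clamp bases prevent
helix I from extending outward across monomer junctions or into the TSD,
and TSDs avoid short internal periodicities so the detected duplication
length equals the planted one. These guards remove measure-zero-in-spirit
but seed-visible artefacts; they do not change the statistical character of
the background.

What passing tests show — and what they do not: perfect recall/precision,
exact periods and byte-identical reruns on this generator demonstrate the
*pipeline logic* under noiseless, composition-simple conditions. Real
genomes bring diverged copies, nested repeats, N-runs and compositional
structure that the i.i.d. background does not emulate; the mutation-rate
parameter probes the first of these only.

## Problem sizes

The shipped test suite and acceptance script run at desk scale, chosen to
exercise every code path while keeping the whole suite under a minute:
genomes of 20–150 kb with 1–8 loci for unit and pipeline tests, a 500-kb
12-locus coral genome for the monomer-class measurement (scanning ~20 s),
50 × 300-nt sequences for the scanner-vs-oracle equivalence, folds to 40 nt
against the enumeration oracle, and 50-seed kinetic recovery batches.
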