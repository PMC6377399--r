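---
title: "Measuring LTR retrotransposon birth and death with ltrdyn"
author: "ltrdyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring LTR retrotransposon birth and death with ltrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The biological model

An LTR retrotransposon inserts as a unit: target-site cleavage duplicates a
short motif (the TSD, typically 5 bp) on both sides, and reverse
transcription guarantees that the two long terminal repeats are identical at
the moment of integration. Two clocks start ticking at that moment.

First, the two LTRs diverge neutrally and independently, so the pairwise
distance between them grows at twice the per-lineage substitution rate. We
estimate that distance with Kimura's two-parameter model, which corrects
transitions (proportion $P$) and transversions ($Q$) separately:

$$K = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q),
\qquad T = \frac{K}{2\mu}.$$

The default rate is $\mu = 1.3\times10^{-8}$ substitutions per site per
year, the conventional value for plant nuclear DNA. When $1-2P-Q \le 0$ or
$1-2Q \le 0$ the logarithms have no real value; the element is reported
*saturated* and never receives a numeric age.

Second, the element starts decaying. Unequal homologous recombination
between the two LTRs excises the internal region and one LTR, leaving a
solo-LTR still flanked by the original TSD; accumulated deletions instead
chew elements into truncated remnants (one LTR plus partial internal
sequence) and eventually into unrecognizable fragments, without preserving
the TSD. The genome-wide ratios of solo (S) and truncated (T) copies to
intact (I) elements therefore measure the removal rate, and TSD retention
separates the two removal mechanisms.

## Pipeline stages and their parameters

**Detection.** Candidates are pairs of direct repeats satisfying structural
constraints: LTR length 100–3,000 bp, element span 1–15 kb, LTR–LTR global
identity >80% (`detection_params()`). The search finds exact 20-bp seeds
shared between two positions, groups them by diagonal, and extends each
seed cluster with an ungapped X-drop scan (match +1, mismatch −3, X-drop
24). Identity is then scored by global alignment under a fixed scheme
(match +2, mismatch −3, gap open 5, gap extend 2) used for every nucleotide
alignment in the package, so thresholds are reproducible. Candidates whose
LTR has fewer than three distinct residues are discarded (homopolymer runs
otherwise satisfy every structural rule). Overlapping candidates are
resolved by higher identity, then longer span, then leftmost position.

**Boundary refinement.** The X-drop boundary is accurate only to a few bp:
a chance flank match extends it (one in four per side), and a mismatch
cluster at the LTR edge can stop it short. Since the parse of an insertion
site is ambiguous at single-base scale — next to a genuine 5-bp TSD, one
matching base always creates a 6-bp anchored repeat one base over, and an
overshot boundary always leaves a 4-bp suffix of the real TSD anchored —
the detector scans boundary shifts of up to ±4 bp for anchored direct
repeats and prefers the parse whose TSD length is closest to the canonical
5 bp, then the smallest displacement. A lenient re-extension (mismatch −1)
is tried when no anchored repeat is found, and adopted only if it exposes
one. TSD presence is recorded but never required: whether the original
analyses filtered on TSDs is not documented, so we keep detection purely
structural.

**Intactness.** The internal region is translated in six frames and each
frame locally aligned (BLOSUM62, gaps 11/1) against every library protein.
Hits must cover ≥50% of the library protein, exceed 30% identity and reach
E ≤ 1e-8; E-values follow Karlin–Altschul statistics with the standard
gapped BLOSUM62 constants ($\lambda = 0.267$, $K = 0.041$) over a search
space of translated length × library length. An element is intact when all
five domains GAG, PR, RT, RH, INT have qualifying hits (configurable via
`required_domains`); the same thresholds serve the flank scans of the
remnant classifier, since the source analyses state them only once. The
bundled library (`synthetic_domain_library()`) contains *synthetic*
exemplar proteins — deterministic random sequences of realistic lengths,
one per domain per clade (Del, Tat, Galadriel, Reina; Sire, Tork, Oryco,
Retrofit) — because real GyDB entries cannot be redistributed here. They
make planted-domain recovery exactly testable; production runs should point
`domains` at a real GyDB-style FASTA.

**Remnant classification.** Each intact element's 5′ LTR (the clustering
exemplar, so the same sequence drives both stages) is searched genome-wide:
16-mer seeds propose windows, a local alignment scores each window
(E ≤ 1e-10, ≥90% of the query aligned, ≥90% identity; the overlap
denominator is the *query* length, the less ambiguous reading), and a
query-global alignment fixes the reported boundaries so terminal
substitutions cannot erode them. Hits overlapping intact loci are masked
out; overlapping hits from different queries merge, with the best-scoring
source winning. Flanks of 3 kb decide the category: Gag-Pol evidence on
neither side → SOLO, exactly one side → TRUNCATED, both sides → AMBIGUOUS.
The two-sided rule in the source analyses is silent about the both-sides
case; we report such loci separately and exclude them from ratios. TSDs
around remnants are recorded descriptively and never reclassify a call.

**Clustering.** Following Silix semantics, families are connected
components of the graph whose edges are local alignments mutually covering
≥70% of both sequences at ≥60% identity (superfamily level) or ≥80%
(family level). Remnants join the cluster of their best-scoring intact LTR,
provided that alignment itself satisfies the thresholds — the "most
similar" rule leaves the cutoff open, and requiring the same thresholds
keeps assignment and clustering consistent; remnants failing it are
reported unassigned and excluded from ratios.

**Statistics.** Genome-wide ratios are quotients of summed counts, not
means of per-cluster ratios, matching the single genome-wide figures the
analysis is built to produce. Clusters without intact members appear in the
report but are excluded from ratio denominators and from the proportion of
clusters with S:I > 3. Age histograms use half-open 1-Mya bins over
[0, 20) Mya with an overflow bin, and saturated elements are counted
separately so histogram mass is conserved. Gene distances are bp strictly
between element and gene (0 for overlap); the summary bins
{overlap, 0–1, 1–3, 3–5, 5–10, >10 kb} resolve the 3–5 kb band where
non-overlapping elements concentrate.

## The simulator: what it emulates, and what it does not

`simulate_genome()` plants loci with full ground truth in an order-0
Markov background at 35.8% GC (a typical value for the plant genomes this
analysis targets). Each family descends from a random ancestral exemplar:
a 500-bp LTR and a 5,000-bp internal region consisting of a 150-bp leader,
the clade's GAG–PR–RT–RH–INT coding block in one frame, and a short
trailer. The layout is deliberate: with coding sequence occupying almost
the whole internal region, even a 20% truncation remnant retains more than
half of its outermost domain, so planted truncations are classifiable under
the 50%-coverage flank rule. Ages are drawn per element from a mixture
defaulting to 70% Uniform(2, 10) + 30% Uniform(0, 1) Mya — an ancient
amplification peak plus recent activity, the regime the statistics are
designed to resolve. Both LTR copies then accumulate substitutions
independently via the analytic K2P transition probabilities at rate μ and
transition/transversion ratio κ = 2, which makes the dating estimator
exactly calibrated against the generator. Intact loci get TSDs;
recombination solos keep a single LTR between the original TSD copies;
fragmentation solos and truncations (random 20–80% prefix or suffix of the
internal region) carry none.

Default per-family counts (6 intact, 1 recombination solo, 13 fragmentation
solos, 2 truncated) put the planted genome-wide ratios at S:I = 2.33 and
T:I = 0.33 — the removal-rate regime of a large, slowly-deleting plant
genome, with recombination solos a small minority, consistent with the very
low TSD retention observed among real solo-LTRs. Loci are spaced ≥16 kb
apart so that no two planted loci can jointly satisfy the 15-kb span
constraint: every locus is independently resolvable, the
no-overlapping-insertions regime the validation targets. Real genomes
violate several of these simplifications — nested insertions, indels
between LTRs, gene conversion homogenizing LTR pairs, segmental
duplications, diverged and fragmented background repeats. Passing the
planted-truth tests therefore demonstrates correctness of the measurement
machinery under clean insertion histories, not detector completeness on
real chromosomes.

## Numerical choices and degenerate inputs

- All coordinates are 1-based closed intervals (the Bioconductor/GFF3
  convention), so GFF3 output needs no conversion.
- IUPAC ambiguity codes are collapsed to N on input; alignment columns
  containing gaps or N are excluded from P/Q counts.
- K2P saturation yields a flag, never an age; zero informative sites is an
  error.
- Pairwise LTR alignment for dating is a deterministic global alignment; a
  general multiple-alignment engine adds nothing for two sequences and
  would cost reproducibility.
- Nucleotide E-values use a λ solved from the +2/−3 score distribution at
  uniform base composition and a fixed K = 0.3; with 1e-10 cutoffs against
  multi-hundred-bp alignments the decision is insensitive to K over many
  orders of magnitude.
- Ties are fixed everywhere: overlapping candidates (identity, span,
  leftmost), merged homolog sources (score, identity, length, id), clade
  calls (lexicographic), remnant assignment (score, identity, lowest id),
  nearest gene (lower coordinate).
- Determinism is part of the contract: identical configs and seeds give
  byte-identical simulator output and pipeline manifests (content hashes of
  every artefact plus the config hash).

## Validation problem sizes

The shipped checks run at sizes chosen to keep the full suite comfortably
reproducible on a laptop: dating recovery with 200 LTR pairs of 1 kb at 1,
5 and 10 Mya (mean recovered age within 10%); detection on a 2-Mb genome
with 30 planted elements at ≤10% LTR divergence (≥95% recall within
±5 bp, no detection outside planted loci); classification on a planted
10 I / 20 recombination-S / 10 fragmentation-S / 10 T genome at ≤5%
divergence (≥95% category accuracy, perfect at zero divergence, TSD
retention ≥95% for intact + recombination solos and ≤5% for
fragmentation products); clustering against an independent
connected-components oracle on 150 sequences; and an end-to-end run whose
planted S:I of 2.0 is recovered within 10% with ≥95% of remnants placed in
their true family.

## Known limitations

Nested and overlapping insertions are not resolved (and the simulator does
not plant them); non-LTR transposon classes are out of scope; the clade
label of an element is whatever the domain library provides, not a
phylogenetic placement; gene conversion between LTRs biases ages downward
and is not corrected; homolog search sensitivity decays for remnants beyond
the 90%-identity threshold, so very old solo populations are undercounted —
a property shared with the thresholds it implements, not a bug of the
implementation.
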