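---
title: "Methods: deconstructing a paleopolyploid genome from NBS-R gene organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deconstructing a paleopolyploid genome from NBS-R gene organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the approach

An ancient hexaploid genome such as grapevine's is a fusion of component
genomes that may have evolved independently for tens of millions of
years. `nbsdecon` reconstructs that history from a single, dense marker
system: the NBS-R disease-resistance genes. The logic is that tandem
duplication builds NBS-R clusters *in situ*, so clusters carry a local
record of their ancestry; if two sets of chromosomes evolved apart before
fusing, between-cluster similarity should sort chromosomes into two
groups, rare single-gene transpositions between the groups should be
young (post-fusion), and a molecular clock on synonymous divergence can
date both the transpositions and cluster growth.

This vignette documents the models, parameter choices, numerical
decisions and limitations of each stage. Empirical statements about
estimator behaviour refer to properties the test suite computes on
simulated data; nothing here asserts a result the code does not produce.

# Gene model and classification

A gene record carries 0-based half-open coordinates (converted to and
from 1-based inclusive GFF3 on I/O), a CDS whose literal translation must
equal the stated protein (terminal stop stripped; no initiator-codon
special-casing), a 3' genomic flank in transcription orientation, and a
domain composition over {TIR, CC, NB-ARC, LRR}. The NB-ARC domain is
diagnostic: records lacking it are rejected at load time. Class
assignment is the deterministic map

| domains              | class       |
|----------------------|-------------|
| CC, NB-ARC, LRR      | CC-NBS-LRR  |
| CC, NB-ARC           | CC-NBS      |
| TIR, NB-ARC, LRR     | TIR-NBS-LRR |
| TIR, NB-ARC          | TIR-NBS     |
| NB-ARC, LRR          | NBS-LRR     |
| NB-ARC               | NBS-tr      |

TIR and CC are structurally alternative N-terminal domains, so their
co-occurrence is a data error, not a seventh class. Domain discovery
itself (profile-HMM scanning of proteomes) is out of scope; domain flags
are inputs. Genes not anchored to a chromosome are loadable but excluded
from every chromosome-dependent stage, so all positional analyses operate
on the anchored subset only.

# Cluster calling

Two or more NBS-R genes form a cluster when every *consecutive* pair
satisfies both thresholds: gap at most `max_gap_kb` (default 244 kb,
measured start-of-downstream minus end-of-upstream) and at most
`max_intervening_orfs` (default 21) non-NBS open reading frames lying
strictly between their spans. The consecutive-pair reading — rather than
a cluster-level mean distance — is the only order-independent
interpretation and agrees with the established 200-kb
consecutive-gene-distance convention for resistance-gene clusters. The
partition is therefore a union of maximal compliant chains, and relaxing
either threshold can only grow clusters (a monotonicity the tests check
against an exhaustive chain-merge oracle). Cluster ids are assigned
CL1..CLn in genome order unless ids are supplied.

# Synonymous divergence

## Alignment

Protein pairs are aligned globally (Needleman–Wunsch) under BLOSUM62 with
affine gaps; a gap of length L costs `gap_open + L * gap_extend`
(defaults 11/1, the BLAST convention — the analysis this package
re-implements fixes the scoring matrix but not the gap costs, so the
community default is used).
Alignment is implemented in C++ (Gotoh's algorithm) with a deterministic
traceback preferring diagonal, then a gap in the second sequence, then in
the first; scores are verified in the tests against both a plain-R
dynamic-programming reference and an independent library implementation.
Pairs aligned over fewer than 150 ungapped residues or below 30% identity
are flagged and excluded from Ks estimation and cluster scoring — partial
or highly diverged pairs would otherwise contribute unstable estimates.

## Codon alignment and NG86

The codon alignment is obtained by back-translating the protein
alignment (each residue column becomes its codon, each gap a codon gap),
which is reading-frame-safe by construction and replaces the nucleotide
realignment used historically. Ks is the Nei–Gojobori (1986) estimator:

- *Sites.* Per codon position, the synonymous fraction is the number of
  synonymous single-nucleotide changes divided by the number of changes
  that do not create a stop codon; changes to stops are excluded from
  numerator and denominator. Sites are averaged between the two
  sequences. (Met and Trp codons contribute zero synonymous sites; a
  sequence pair with no synonymous sites at all is an error, not a zero.)
- *Differences.* For each codon pair, synonymous and nonsynonymous
  differences are averaged over all minimal mutation pathways, excluding
  pathways through stop codons (falling back to all pathways in the rare
  case every one is blocked).
- *Correction.* `Ks = -3/4 ln(1 - 4/3 ps)`. When `ps >= 3/4` the
  correction is undefined and the value is flagged saturated rather than
  raised as an error; saturated values are excluded from means and from
  dating, and their count is reported.

Site and pathway counts are precomputed once over the 61 sense codons and
cached. The tests compare the estimator against an exhaustive
pathway-enumeration oracle on every sense-codon pair and on random short
sequences. Because the estimator named by the original analysis is not
specified to the formula level, NG86 was adopted as the standard
codon-counting estimator; absolute Ks values may differ systematically
from other estimators, which matters for none of the within-study
comparisons (all stages use the same estimator) but should be remembered
when comparing dates across studies.

Ks-w denotes values between members of one cluster, Ks-bg every other
pair. On data where clusters grow by tandem duplication, Ks-w is expected
to sit well below Ks-bg, and the simulation tests confirm the estimator
reproduces this.

# Between-cluster similarity and genome grouping

Gene pairs are scored either as Smith–Waterman bit scores
(`(λS - ln K)/ln 2`, with the standard gapped BLOSUM62 constants λ =
0.267, K = 0.041 — any monotone transform leaves percentile selection
unchanged, so the constants set only the reported units) or as global
alignment identities. The quality filter is evaluated on the local
alignment in bit mode (a BLAST-style screen) and on the global alignment
in identity mode. The similarity of two clusters with n and k members is
the arithmetic mean of the n×k member-pair scores; pairs failing the
filter contribute zero rather than being dropped, because dropping them
would bias means upward exactly for the most dissimilar cluster pairs.

Cluster pairs at or above the nearest-rank percentile threshold (default
93; 90 and 96 as companions) become graph edges. The nearest-rank method
with ≥-inclusion means ties can push the selected count above the nominal
7%, which is the desired behaviour for degenerate score distributions.
Raising the percentile always yields a subset of the selection at a lower
one.

Connected components are projected onto chromosomes; components sharing a
chromosome are merged; the two largest resulting chromosome groups become
the candidate component genomes, the larger labelled Va and the smaller
Vc. One degenerate case gets special handling: if merging collapses
everything into a single group although two substantive multi-chromosome
components existed, the two largest original components are retained as
candidates and the bridging chromosomes — those carrying clusters of
both — are labelled `conflict`, making mixed signals explicit instead of
silently collapsing the grouping.

A structural limitation follows directly from the selection rule: at the
93rd percentile only ~7% of cluster pairs become edges, so a chromosome
whose few clusters draw no selected edge cannot be assigned. This is not
an implementation artefact — in the grapevine case, 5 of 19 chromosomes
could not be assigned for exactly this reason. On simulated genomes
the tests therefore require that no chromosome is assigned to the wrong
genome, that unassignable (grey) chromosomes are never assigned, and that
a majority of each planted genome's chromosomes is recovered; exact
recovery of every chromosome is additionally verified for the grouping
machinery on constructed similarity matrices in which every chromosome is
guaranteed a selected edge. Grouping concordance between the bit-score
and identity pipelines is reported per chromosome, excluding chromosomes
unassigned by either.

# Helitron footprint scanning

Helitron excision leaves a compact signature in the 3' region of a
mobilized gene: an inverted repeat able to form a stem-loop, plus a CTAG
tetranucleotide nearby. The scanner enumerates stem-loops with arms
scored +3 per paired position and −1 per mismatch (no gaps), reporting
arms whose score reaches `min_stem_score` (default 28, so a perfect 10-bp
arm at score 30 passes and a 10-bp arm with one mismatch at 26 does not).
`max_repeat_len` (default 30) bounds the *total extent* of the structure
from left-arm start to right-arm end — the einverted "maxrepeat"
convention — which restricts default hits to near-perfect 10–13-bp arms
with short loops. The alternative reading (28 as a minimum arm length) is
available as `stem_rule = "length"`. Under the extent reading the scan is
selective — the validation suite verifies a false-positive rate below 5%
per kilobase on dinucleotide-shuffled flanks — and fast; under the
arm-length reading with mismatch −1, 30-bp arms at 50% identity would
qualify and random sequence would trigger constantly, which is
incompatible with the sparse footprint catalogues this method produces
in practice.

For each loop placement the arm is grown outwards and the best-scoring
arm kept (ties to the shorter arm); overlapping stem-loops are pruned
greedily by score, then leftmost position, then shorter loop, for
determinism. Non-ACGT characters are masked and scored as mismatches. The
CTAG is sought downstream of the stem-loop within `max_ctag_distance`
(default 100 bp: documented helitron footprints show spacings of a few
tens of nucleotides between stem-loop and CTAG, and the analysis imposes
proximity without fixing a published value). A
footprint call is the highest-scoring stem-loop that has a compliant
CTAG. Scanning covers the first `scan_window` (1000) bases of the flank.

# Dating and cross-genome transpositions

The clock is linear: `mya = round(Ks × 41/0.82)` with half-away-from-zero
integer rounding, reproducing the calibration point exactly (0.82 → 41).
Rounding half away from zero was chosen because it reproduces the
published event dates; residual ±1-mya discrepancies in cluster dates are
attributable to Ks values being rounded before publication, so the test
tolerance for the full published tables is ±1 mya.

A single gene is a cross-genome transposition candidate when its clade's
clustered genes all lie in the other component genome; its progenitor is
the clustered candidate with the lowest non-saturated, filter-passing Ks
(ties broken lexicographically for determinism), and the event age is the
progenitor Ks converted by the clock. Cluster formation is dated from the
maximal within-cluster Ks — the two most diverged members bound the
cluster's expansion period. Clade definitions (gene-to-clade maps) are
inputs; phylogenetic tree inference is out of scope.

Chromosome triplets (inputs, from collinearity analysis) are coloured
g/r/y for Va/Vc/unassigned. Exactly 10 colour multisets of size 3 exist;
a combination is compatible with the two-Va-plus-one-Vc hypothesis iff it
shows at most two g and at most one r (grey slots can be filled to reach
exactly 2+1), giving 6 compatible and 4 incompatible combinations.
Conflict chromosomes are treated as grey with a warning.

# The synthetic-genome generator

`simulate_nbs_genome()` is first-class, tested code: it generates the
structures the pipeline assumes so every stage can be validated against
planted truth.

**Study conditions (defaults).** 9 Va + 5 Vc + 5 grey chromosomes;
1–4 clusters per Va/Vc chromosome of 2–15 genes; 0–3 non-transposed
singles per chromosome; cluster founding ages 20–138 mya; 8 post-fusion
cross-genome transpositions at ages up to the fusion age (65 mya), 30% of
them carrying a planted helitron footprint; ω = 0.15; 300-codon genes
with 1-kb 3' flanks; 5 non-NBS filler ORFs per 100 kb; clock 50 mya per
Ks unit. These mirror the organism-scale facts the analysis targets
(chromosome counts, cluster size range, published event-age range, fusion
age) and standard values where no source number exists (ω typical of
conserved plant gene families; gene and flank lengths sized to the
NB-ARC region and the footprint search window).

**Ancestry.** Each component genome has an independent random ancestral
coding sequence, so between-genome protein identity is at chance level
and far below within-genome identity — the condition the grouping method
requires. Within a genome, families (used as clades, with fixed
family-specific domain profiles) radiate at 160 mya and cluster founder
lineages separate at 140 mya; cluster roots (20–138 mya) therefore
postdate their founder's divergence, keeping the simulated history
time-consistent. Clusters grow by tandem duplication: duplication times
are uniform over the cluster's age and each event copies a random extant
lineage, so planted pairwise divergence ages are the tree's coalescence
times.

**Sequence evolution.** Substitutions are applied as discrete events at
per-lineage synonymous rate 1/(2 × 50) per synonymous site per million
years (so a pair separated T my accumulates T/50 expected synonymous
substitutions per site) and nonsynonymous rate ω times that, with events
landing on random codons among sense-preserving single-nucleotide
changes. This approximates a Jukes–Cantor-like process with multiple
hits; the contract is not exact NG86 recovery (which would be circular)
but the tested regression property: estimated Ks tracks planted age with
Spearman correlation above 0.9 and a slope within 20% of 1/50.

**Transpositions and footprints.** Each event copies a random clustered
gene into a random chromosome of the other genome; the copy's branch is
evolved for twice the event age so its pairwise divergence from the
progenitor equals the event age on the generator's clock (collapsing the
progenitor's own post-event evolution onto the copy's branch — pairwise
divergence, which is all the estimator sees, is unaffected).
Helitron-flagged copies receive a planted footprint (perfect 10–13-bp
inverted-repeat arms within the 30-bp extent bound, CTAG 4–40 nt
downstream), and the planting is rejection-sampled until the scanner
locates it at exactly the planted coordinates. All other single-type
genes get flanks rejection-sampled to be footprint-free at default scan
settings, so scanner specificity is measurable; clustered genes (whose
flanks the pipeline does not scan) get plain random flanks.

**Geometry.** Within chromosomes, clusters and singles are separated by
300–600 kb (beyond the 244-kb rule) and cluster members by 2–15 kb
(mean near the published 8.3 kb), so the planted cluster partition is
recoverable exactly by construction; filler ORF density keeps
within-cluster interruptions far below the 21-ORF limit.

**What the generator does not emulate.** Real intergenic sequence and
repeat content; heterogeneous clusters mixing distant lineages;
pseudogenes and partial CDS; lineage-specific rate variation;
chromosome-scale rearrangement. Passing tests therefore demonstrate
correctness of the estimators and procedures under the model's
assumptions, not robustness to every idiosyncrasy of real annotations.

# Problem sizes and determinism

All randomness flows from a single mandatory seed; a repeated run is
bit-identical. The validation suite exercises default-condition genomes
(roughly 200–360 genes, 27–39 clusters) for five seeds in the
full-recovery checks and three seeds for the bit-versus-identity
concordance property, with Ks estimated on all within-cluster pairs, all
progenitor-candidate pairs and a 1,500-pair sample of between pairs per
genome (the between mean is a mean over a large homogeneous set, so
sampling affects only its precision). Unit tests use smaller genomes
(tens of genes, 60–150-codon sequences) chosen to exercise every code
path rather than to emulate the organism.

# Known limitations

- NG86 underestimates Ks near saturation; values at ps ≥ 3/4 are flagged
  and excluded rather than extrapolated, so dates near and beyond
  ~150 mya are censored.
- The percentile-threshold grouping cannot assign chromosomes with
  little clustered content (by design, matching the original analysis).
- The footprint scanner detects the excision signature only; it does not
  classify autonomous elements or validate candidate footprints against
  helitron termini beyond the CTAG/stem-loop pair.
- Clade maps and chromosome triplets are taken as given; errors in those
  inputs propagate into transposition candidacy and compatibility calls.
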