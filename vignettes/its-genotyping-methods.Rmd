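---
title: "Methods: multi-genotype ITS profiling of Ophiocordyceps sinensis"
author: "OphioITS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-genotype ITS profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OphioITS)
```

## The biological problem

The nuclear ribosomal internal transcribed spacer region
(ITS1–5.8S–ITS2, ~630 bp when amplified with the universal ITS5/ITS4
primers) is the marker by which the multiple genotypes of
*Ophiocordyceps sinensis* are told apart inside natural
*Cordyceps sinensis*. Three features of this system drive every design
decision in the package:

1. **Compositional bias.** Relative to Genotype #1 (*Hirsutella
   sinensis*), a family of variants differs by numerous *transition*
   point mutations that predominantly replace G/C with A/T. These
   AT-biased genotypes (#4–6, #15–17) have also lost the EcoRI site
   GAATTC through the single transition GAATTC→GAATTT, so an EcoRI
   digest separates the two classes on a gel — a qualitative,
   locus-specific assay.
2. **Recombinant genotypes.** Genotypes #13 and #14 look like reciprocal
   splices of two parents: one shares its entire ITS1 with Genotype #1
   while the 5.8S–ITS2 matches the AB067719-type fungus, the other the
   converse. Their signature is segment-wise: 100% identity to one
   parent in one segment, far less elsewhere.
3. **Compartment structure.** Clone libraries from five compartments
   (immature stroma, mature stroma, stromal fertile portion, fully and
   semiejected ascospores) have different genotype complements; the
   analysis output is a presence/absence table over taxa ×
   compartments.

## Alignment model

All comparisons rest on global pairwise alignment with affine gaps
(`globalAlign`). A gap of length $k$ costs $g_o + k\,g_e$; defaults are
match $+1$, mismatch $-1$, $g_o=-5$, $g_e=-1$ with **free terminal
gaps**. Strong gap penalties fit an rDNA marker where indels are rare
and short; free end gaps make partial clones (several deposited
sequences are incomplete) comparable to full-length references without
penalty. All parameters are exposed through `alignParams()` because the
identity conventions behind published percent-homology figures are
rarely stated; values may shift by up to about a percentage point
between conventions.

Numerical choices: the dynamic program is exact (no banding); among
co-optimal alignments the one with the most identical columns is
returned, which makes percent identity invariant under swapping the two
sequences; remaining ties are broken in a fixed order (substitution,
then gap in the first sequence, then gap in the second), so outputs are
bit-reproducible. An exhaustive path-enumeration oracle
(`bruteForceScore`, independent of the dynamic program) verifies score
optimality for short sequences in the test suite, and scores are
cross-checked against a second aligner implementation on random pairs.

**Percent identity** defaults to the exclude-terminal-gaps convention:
leading/trailing gap columns are not counted, internal gap columns count
as non-identical, ambiguity codes match only themselves. This mirrors
common GenBank "% homology" usage. `percentIdentity` also offers the
all-columns convention.

**Segment projection** maps ITS1/5.8S/ITS2 boundaries of an annotated
reference through the alignment onto a query; boundaries landing in
query gaps snap to the nearest query residue inside the segment, and
segments with no query residues are dropped (partial-coverage queries
are profiled only where they overlap). Projection is refused when
identity falls below 50% or fewer than 50 residue columns align —
both conditions are needed because with free end gaps a short random
fragment can reach deceptively high identity over a tiny chance
overlap.

## In-silico PCR

Primer binding is modelled as ungapped, position-wise comparison over
the primer length, on both strands, with IUPAC-aware matching and a
configurable identity floor (default 60%, roughly the weakest sites
still reported as amplifiable for this primer panel). The touch-down
thermocycling of the wet-lab protocol is represented *only* by this
threshold; no melting-temperature or polymerase model is attempted.
Mismatch positions are reported in primer coordinates with a flag for
the 3'-terminal three bases — informational, not disqualifying, since no
extension model is claimed. The per-pair output uses the conventional
"fwd%/rev%" notation so published specificity figures can be audited
either over the full primer or a trimmed core.

## EcoRI discrimination

`ecoriDiscriminate` anchors the assay at the reference's GAATTC locus
(positions 294–299 in the Genotype #1 representative), projects that
locus onto the query and calls "cut" only when the homologous positions
read GAATTC. A motif hit elsewhere cannot flip the call, and queries
whose locus cannot be projected are "ambiguous" rather than guessed.
Star activity and methylation are out of scope; the published assay is
qualitative present/absent.

## Bias classification and genotype calling

The mutation profile classifies each substitution column as transition
(A↔G, C↔T) or transversion and counts the *AT shift*: transitions with
reference base G/C and query base A/T. The decision rule —
AT-biased iff at least 5 transitions and an AT-shift fraction of at
least 0.6 — separates the two classes by a wide margin: real AT-biased
genotypes differ from Genotype #1 by dozens of almost purely AT-shifted
transitions, while near-#1 variants carry only a handful of mutations.
Alignments under 100 residue columns are "unclassified" rather than
risked.

Genotype calls take the library reference with the highest full-region
(ITS1-through-ITS2) identity, requiring 97% to assign. The threshold
sits between clone-error levels (≤1% error leaves a true clone above
99%) and the closest distinct genotype pair in the published similarity
table (94.9%), and is configurable. Ties break to the lower genotype
number, then lexicographic accession, so calls are deterministic.

## Chimera detection

Windowed parental voting: the query is aligned to both candidate
parents, each 60 bp query window (step 10) is assigned to the parent
with the higher windowed identity if the margin reaches 2 identity
points (else "tie"), and a breakpoint is declared between two runs of
opposite winners of at least 3 windows each. The reported interval
spans the query region between the flanking runs. This is a
deterministic, auditable rule rather than a likelihood model — adequate
because the recombination evidence in this system is descriptive
segment identity, and because planted-truth simulations (parents at 10%
divergence, the observed parental distance scale) recover ≥95% of
single breakpoints within one window width. With window 60 and margin
2, parents must disagree at ≥2 sites per window on average, which 8–10%
divergence comfortably provides; more similar parents require a larger
window or smaller margin, at the cost of localization. Multi-breakpoint
parsimony phasing and >2 parents are out of scope.

## Distances, trees and clusters

Pairwise distances are either the p-distance (1 − identity fraction,
exclude-terminal-gaps convention) or the Kimura two-parameter distance
$d = -\tfrac12\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big)$ from transition and
transversion proportions over residue-aligned columns. Saturated pairs
(non-positive logarithm argument) are flagged and fall back to the
p-distance instead of disappearing.

Trees are neighbor-joining (`ape::nj`) — a deliberate, documented
stand-in for the Bayesian MCMC consensus used in the original analysis,
because everything downstream consumes only topology-level cluster
membership, which NJ reproduces. NJ can emit slightly negative branch
lengths on non-additive input; these are clamped to zero (the excess is
not redistributed, as only topology feeds the cluster extraction).
Bootstrap support resamples columns of a *master alignment* built by
aligning every sequence to a designated reference (the Genotype #1
representative), which preserves column-resampling semantics without a
multiple-alignment dependency; insertions relative to the reference are
dropped, a known simplification.

Cluster extraction roots at the outgroup, finds the maximal clade
containing all AT-biased seeds and none of the GC-biased seeds, labels
its two basal subclades A and B by the location of the designated
Cluster-A seed (#5), and labels everything else in the ingroup GC. If
the seeds are not monophyletic under the rooting the affected tips are
"unplaced" with a warning — never silently guessed.

## Occurrence profiling

Presence is clone-count thresholded (default: one clone suffices),
never abundance-modelled — gel-intensity evidence in this system is
qualitative, so relative clone counts are reported but not tested.
Unassigned clones are tallied per compartment, empty samples yield
"unassessed" columns, and sub-threshold counts are kept as near-miss
notes. `compareToExpected` diffs presence cell-by-cell against the
bundled expected table and fails loudly on label mismatches.

## What the synthetic generator emulates — and what it does not

`buildReferenceFamily` reproduces the *structure* of the real panel on
a 650 bp marker: planted ITS5/ITS4 sites at the ends, segment tiling
(40 bp 18S flank, 230 bp ITS1, 160 bp 5.8S, 190 bp ITS2, 30 bp 28S
flank), a unique EcoRI site inside 5.8S, an AT-biased lineage (25
shared root transitions including the diagnostic site loss, 10 per
cluster, 6 private per leaf), a 10%-diverged outgroup, 20%-diverged
species control, and reciprocal chimeras switching at the ITS1/5.8S
boundary. Clone libraries draw 30 clones per compartment — the
colony-picking depth of the emulated study — with independent uniform
substitution errors (default 0, capped at 5%).

Deliberately **not** emulated: non-uniform mutation hotspots, length
variation and indel polymorphism between genotypes (generator variants
are substitution-only, so chimera parents share coordinates), secondary
structure that suppresses amplification of some genotypes, PCR bias,
primer competition and chimeric-amplicon artefacts. Passing tests
therefore demonstrate correctness of the algorithms under known truth,
not performance on every pathology of real clone libraries; the
accession-based checks (enabled once the GenBank records are fetched,
see `scripts/fetch_references.R`) are the bridge to real sequence data.

## Problem sizes and reproducibility

The validation suite uses 500 random pairs (length ≤ 8) for the
alignment oracle, 1000 random templates for digestion conservation, 200
single-breakpoint chimeras, 100 planted AT-biased mutants, 20 random
additive trees of 4–8 taxa, 100 bootstrap replicates in the bootstrap
check, and the full five-compartment scenario (150 clones against a
12-member library) end-to-end. Every stochastic step takes an explicit
seed, and all generators are deterministic given it; identical seeds
yield byte-identical FASTA output and identical pipeline manifests.

## Known limitations

* Percent identities depend on alignment parameters; published values
  derived from unstated conventions are only reproducible to about
  ±1 percentage point.
* The master-alignment bootstrap ignores insertions relative to the
  chosen reference.
* Chimera localization is limited to one window width; breakpoints
  falling exactly at segment boundaries cannot be placed more finely
  than the windows allow.
* `extractClusters` assumes the AT clade is bifurcating at its base
  (true for binary NJ trees); multifurcations would need manual
  resolution.
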