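# OphioITS

Multi-genotype ITS profiling of *Ophiocordyceps sinensis*.

Natural *Cordyceps sinensis* — the insect–fungal complex of the
Qinghai-Tibetan Plateau — harbours not one fungus but a community: up to 17
ITS1-5.8S-ITS2 sequence variants ("genotypes") attributed to
*O. sinensis*, together with *Samsoniella hepiali* and an unidentified
AB067719-type fungus, distributed unevenly across the stroma, the stromal
fertile portion (SFP, densely covered with ascocarps) and the two kinds of
ascospores (fully and semiejected). `OphioITS` implements the molecular
side of that profiling workflow as reusable, tested R functions, for
mycologists and molecular ecologists working with clone-library ITS data:

* **In-silico PCR** — mismatch-tolerant, ungapped scanning of the published
  universal (ITS5/ITS4), genotype-specific (Hsprp1–3, HsATp1–3) and
  species-specific primer panels against templates, with amplicon
  prediction and a primer-by-reference specificity matrix in the
  "fwd%/rev%" notation.
* **EcoRI discrimination** — the GC-biased genotypes carry a GAATTC site
  that AT-biased genotypes have lost through a single transition
  (GAATTC → GAATTT); `ecoriDiscriminate()` projects the site locus through
  a global alignment so the call is locus-specific, not motif-grep.
* **Segment-wise identity profiling** — affine-gap Needleman–Wunsch
  alignment (`globalAlign`), segment projection and per-segment percent
  identity for ITS1, 5.8S, ITS2 and the full in-scope region
  (`segmentIdentityProfile`).
* **Genotype calling and compositional-bias classification** — per-column
  transition/transversion profiles against the Genotype #1 reference; a
  query is AT-biased when ≥ 5 transitions shift G/C→A/T at a fraction
  ≥ 0.6 (`classifyBias`); nearest-reference assignment at a 97%
  full-region identity threshold (`callGenotype`).
* **Chimera detection** — the recombinant Genotypes #13/#14 descend from
  two parents (Genotype #1 and the AB067719-type fungus) by large-segment
  exchange; `detectChimera()` recovers breakpoints by windowed parental
  identity voting (window 60 bp, step 10, margin 2 identity points,
  support 3 windows).
* **Phylogenetic clustering** — p-distance / Kimura-2-parameter distances
  from pairwise alignments, neighbor-joining with column-resampling
  bootstrap, and extraction of the GC clade and the AT Cluster-A
  (#5, #6, #16, #17) / Cluster-B (#4, #15) memberships relative to the
  AB067719-type outgroup (`extractClusters`).
* **Occurrence profiling** — clone libraries per compartment in, a
  presence/absence table with clone counts out (`profileSamples`), plus a
  cell-by-cell diff against an expected table (`compareToExpected`).
* **Synthetic data with known truth** — `randomMarker`, `mutateSeq`,
  `makeChimera`, `simulateCloneLibrary` and `buildTable2Scenario` generate
  ITS-like markers with planted primer sites, EcoRI locus, AT-biased
  mutations, chimeric breakpoints and five-compartment clone libraries,
  recording every planted edit for validation.

## Worked example

```r
library(OphioITS)

# simulate the five-compartment study design (30 clones per compartment)
sc  <- buildTable2Scenario(seed = 1)
tab <- profileSamples(sc$samples, sc$library)
presenceMatrix(tab)[c("#13", "#14", "#4", "#15"), 4:5]
#>      ascospores_fully_ejected ascospores_semiejected
#> #13                     FALSE                   TRUE
#> #14                      TRUE                  FALSE
#> #4                      FALSE                  FALSE
#> #15                     FALSE                  FALSE
compareToExpected(tab, sc$expected)$n_disagree
#> [1] 0
```

The recombinant genotype #13 appears only in semiejected and #14 only in
fully ejected ascospores, Cluster-B genotypes are confined to the
stroma/SFP, and the whole table matches the expected pattern with zero
diffs.

```r
s <- as.character(refSeqs(sc$library))
segmentIdentityProfile(s[["#13"]], sc$library["#1"])[, 3:6]
#>   its1  r58s     its2     full
#> 1  100 86.25 89.47368 92.75862
ecoriDiscriminate(s[["#5"]], sc$library["#1"])$call
#> [1] "uncut"
```

The chimera shares its complete ITS1 with Genotype #1 but diverges beyond
it, and an AT-biased genotype is scored "uncut" (EcoRI site lost).

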