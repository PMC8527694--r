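---
title: "Sequence-based biomarkers: model, choices and validation"
author: "SBBtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based biomarkers: model, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

16S rRNA amplicon studies quantify a community as counts of amplicon
sequence variants (ASVs) per sample.  Before testing for differential
abundance between a case and a control cohort, ASVs are conventionally
aggregated -- by taxonomic annotation, by OTU clustering at a similarity
threshold, or not at all.  Each choice fixes one aggregation scale, and a
differentially abundant clade that straddles that scale can be missed:
too fine and the signal is diluted across sparse ASV columns, too coarse
and it is averaged away inside a large group.

Sequence-based biomarkers (SBBs) sidestep the choice of scale.  After a
multiple sequence alignment of all ASV sequences, a *variant* is the
presence of a base (A, C, G or T) at an alignment column, and an order-N
biomarker is a combination of N variants at distinct columns (N = 1, 2
or 3).  Each biomarker defines a microbial group: the set of ASVs
carrying all of its loci.  Because 16S variants accumulate along
ancestry, carrier sets approximate clades at every granularity at once,
and testing all realized biomarkers tests all these scales jointly.

The pipeline is:

1. **Encoding.** The alignment becomes a sparse binary ASV x variant
   matrix (`oneHotEncode()`).  Gaps assert nothing; ambiguity codes are
   mapped to the gap state on input because a biomarker is defined only
   over the four bases.  The alignment itself is delegated to external
   tools (e.g. the RDP aligner); this package consumes aligned FASTA.
2. **Enumeration.** For each ASV, every size-N combination of its
   variants is emitted (`enumerateBiomarkers()`).  The universe is the
   union of *realized* combinations -- never the full
   $\binom{L}{N} 4^N$ space -- which is what keeps order 2 and 3
   tractable (a gap-free ASV of width $L$ carries exactly
   $\binom{L}{N}$ memberships).
3. **Filtering.** Biomarkers carried by every ASV aggregate to a
   constant 1 and are dropped (`filterUninformative()`).  No prevalence
   filter is applied: a rare but abundant ASV is informative, and its
   signal survives aggregation.
4. **LD pruning.** Biomarkers carried by exactly the same ASVs are in
   complete linkage disequilibrium and aggregate identically;
   `ldPrune()` keeps one representative per identical-column class
   (lowest order, then lexicographically smallest label).
5. **Aggregation.** Counts are normalized to within-sample relative
   abundance $R_{a,p} = C_{a,p} / \sum_a C_{a,p}$ and summed over each
   group, $R'_{G,p} = \sum_{a \in G} R_{a,p}$ (`relAbundance()`,
   `aggregateByGroup()`).  Groups overlap, so columns of the group table
   do not sum to one and no cross-group renormalization is attempted.
6. **Testing.** Per group, a centered Wilcoxon signed-rank statistic on
   within-pair differences (paired designs) or a centered Mann-Whitney U
   (unpaired designs), with a permutation null that preserves the design
   structure, yields a false discovery rate per group
   (`sbbDiffAbundance()`).
7. **Reporting.** Significant biomarkers are clustered against their
   carrier ASVs with a Hamming-fraction distance to reveal conserved
   groups (`clusterBiomarkers()`), and any group table can be
   benchmarked as phenotype-prediction features under a repeated-split
   random-forest protocol (`evaluatePrediction()`).

## Why permutation FDR

Relative abundances are compositional and SBB groups share ASVs, so
per-group statistics are strongly dependent; Bonferroni-style corrections
over $10^5$ groups would be both miscalibrated and hopelessly
conservative.  The permutation null recomputes all group statistics under
relabelled designs, so it carries the full dependence structure --
including compositional coupling and duplicated (perfectly correlated)
groups -- into the null.

Permutations preserve the design: in paired mode each case-control pair
keeps or swaps both labels with probability 1/2; in unpaired mode
phenotype label vectors are exchanged between families of equal size
(samples without a family are singleton families), which preserves both
within-family concordance and the exact case/control counts.  Exchanging
only within equal-size strata is slightly more conservative than any
scheme that mixes family sizes, but it guarantees exact label counts
without rejection sampling.

The estimator is the plug-in
$\widehat{FDR}(t) = \min\!\left(1, \frac{\mathbb{E}_{perm}\,\#\{|stat| \ge t\}}{\#\{\,|stat_{obs}| \ge t\}}\right)$
evaluated at each observed $|statistic|$, then monotonized step-up so
estimates never increase with the statistic.  Its resolution is
1/`nIterations` per group: a group exceeding every null statistic is
reported as 0.

Two implementation facts are worth knowing.  Ranks are invariant under
relabelling, so the permuted statistics are exact matrix products of a
fixed (signed-)rank matrix with sign or indicator vectors; and both
statistics live on a lattice of quarter-integers, so the null is stored
as exceedance counts over that lattice.  Together these make 100,000
iterations cheap and keep memory independent of the iteration count.
For paired designs with at most 20 pairs and $2^k \le$ `nIterations`,
all $2^k$ sign patterns are enumerated and the null is exact.

## The paired test, named precisely

The source method describes its paired statistic as a rank-sum test "for
paired data"; a rank-sum (Mann-Whitney) test is by definition unpaired,
so this package implements the standard paired analogue, the Wilcoxon
signed-rank statistic: within-pair differences, zero differences
dropped, midranks for ties, centered at its null mean.  Two-sided
discovery on $|statistic|$ with the sign reported separately as the
enrichment direction.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `orders` | 1, 2 | biomarker locus counts; order 2 is the recommended working point -- order 3 multiplies the universe several-hundred-fold for little granularity gain |
| `nIterations` | 100,000 | permutation count; tests and examples in this package use 1,000 for speed, which bounds the FDR resolution at 1/1,000 |
| `fdrCutoff` | 0.1 | reporting threshold |
| `acrossOrders` | TRUE | LD-prune jointly across orders (the scope of pruning is not dictated by the method; both scopes are exposed) |
| `linkage` | average | clustering linkage; the distance (Hamming) is part of the method, the linkage is not, and the cut (`k`/`h`) is deliberately user-chosen |
| `nRepeats`, `testFraction` | 100, 0.2 | prediction protocol: 100 repeats of 80/20 splits, median AUC +/- 1 SD |
| `nTrees` | 100 | trees per random forest, otherwise default parameters |

In paired designs the prediction splits keep both members of a pair on
one side by default (`respectPairs`); this is a leakage guard the
original protocol does not state, and it can be disabled.

## The synthetic-data generator

`simulateDataset()` exists so that every stage is testable without real
data.  It emulates: clade structure (sequences evolve from a random root
down a balanced binary tree, i.i.d. per-position substitutions, optional
inherited deletions); a planted differential clade (the subtree of the
first `cladeSize` leaves receives private bases at masked diagnostic
loci, so the clade is exactly the carrier set of one diagnostic
biomarker); compositional counts (per-sample proportions are Dirichlet
draws with concentration `theta` around a baseline composition; case
samples have the clade multiplied by `effectSize` and renormalized;
multinomial counts at fixed depth); and sparsity (background baseline
means are log-normal with spread calibrated so the expected zero
fraction matches `sparsityTarget`).

Defaults are the study conditions used throughout validation: 32 ASVs x
64 columns, clade of 4 with a 2-locus diagnostic biomarker, 60
case-control pairs, effect size 4, 10,000 reads per sample.
`sparsityTarget = 0.5` rather than the ~80-97% of real ASV tables:
with tens of ASVs instead of thousands, 50% zeros already reproduces the
realistic regime of roughly a dozen taxa present per sample.
`cladeBaseline = 0.05` makes the planted clade a moderately abundant
family-level group, and `theta = 50` gives overdispersion in the range
of Dirichlet-multinomial fits to real 16S data.  An earlier symmetric-
Dirichlet design was discarded: calibrated to the same sparsity it makes
single ASVs dominate whole samples, saturating group abundances at 0/1
-- an artefact of small ASV counts, not a property of gut communities.

What it does **not** emulate: sequencing error, chimeras, PCR bias,
varying library sizes (an option exists in spirit -- depth cancels in
Eq.-style normalization), uneven tree shapes, or correlated phenotype
effects across multiple clades.  Green tests therefore demonstrate the
machinery and its calibration, not performance on real data.

## Numerical choices and degenerate inputs

- Positions are 1-based on the post-alignment coordinate system; labels
  render as `"12A"` / `"1A/2C/3G"` with positions ascending.
- Column order of every matrix is deterministic (position then base
  A<C<G<T; biomarkers by variant-index tuples), so identical inputs give
  bitwise-identical outputs.
- Within-pair differences of float abundances are compared exactly; zero
  differences are dropped, tied magnitudes get midranks.  Both
  statistics then live on an exact quarter-integer lattice, which is
  what the null's exceedance grid indexes.
- All-zero (or all-constant) groups receive the null-center statistic 0.
- Zero-total samples are rejected at read time: relative abundance is
  undefined for them.
- Aggregation tolerates membership matrices covering a subset of the
  counted ASVs (the rest contribute to no group) but refuses unknown
  ASVs.
- A split that leaves a one-class test set is redrawn with a warning.
- Validation sizes: oracle-equivalence runs on 25 random gapped
  alignments up to 20 x 30 at orders 1-3 against exhaustive
  enumeration; calibration on 50 null datasets (40 pairs, 500 groups,
  1,000 permutations each); recovery on 20 replicates at the default
  study conditions; prediction sanity on 200-sample feature tables under
  the full 100-repeat protocol.

## Known limitations

- The method consumes a *given* alignment; alignment errors propagate
  into variant coordinates and are invisible to it.
- Ambiguity codes are treated as gaps, i.e. as missing evidence; an
  alternative (expanding them to candidate bases) would create
  biomarkers the read does not actually support.
- FDR estimates are plug-in, not provably conservative for every
  dependence structure; the calibration test covers the exchangeable
  null the permutations assume.
- Order-3 extraction is supported but costly in universe size; the
  recommended working point is orders 1-2.

## A minimal session

```{r example}
library(SBBtools)

sim <- simulateDataset(sbbSimSpec(seed = 1))
ext <- extractBiomarkers(sim$seqs, orders = c(1, 2))
ga  <- aggregateByGroup(relAbundance(sim$counts), ext$biomarkers)
res <- sbbDiffAbundance(ga, sim$design, nIterations = 1000, seed = 2)
res

sm <- significantBiomarkers(res, ext$biomarkers, fdrCutoff = 0.1)
clusterBiomarkers(sm, k = 4)
evaluatePrediction(ga, sim$design, nRepeats = 100, seed = 3)
```
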