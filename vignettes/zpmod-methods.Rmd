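---
title: "Methods: replicate-alignment support, MAD rooting, domain-loss scanning and disulfide connectivity typing"
author: "zpmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate-alignment support, MAD rooting, domain-loss scanning and disulfide connectivity typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zpmod)
```

## The problem

Zona pellucida (ZP) modules are two-domain extracellular protein units
(ZP-N + ZP-C) that polymerize into matrices such as the nematode cuticle.
Family-wide evolutionary analysis of ZP modules faces three linked
difficulties that this package addresses:

1. **Alignment uncertainty.** The module is short and the family is
   ancient, so stochastic aligners produce visibly different replicate
   alignments of the same sequences. Branch support must therefore be
   measured across *replicate alignments*, not bootstrap pseudo-replicates.
2. **Domain-architecture change.** Some subfamilies have lost the entire
   ZP-N domain. Loss shows up as a domain-restricted block of missing
   data, which must be separated from sporadic, single-sequence
   truncation artifacts.
3. **Disulfide rewiring.** The cysteine complement of the ZP-C domain
   varies among subfamilies; classifying each module's connectivity type
   and mapping type changes on the phylogeny requires both sequence
   (cysteine presence at homologous columns) and structure (spatial
   plausibility of candidate bonds).

## Branch support under alignment uncertainty

For `k` replicate trees on one tip set, `majorityRuleConsensus()` keeps
exactly the bipartitions occurring in strictly more than half of the
trees (such splits are always mutually compatible) and collapses the
rest into polytomies. Each retained branch carries:

* **BRP** (branch recovery proportion): the fraction of replicate trees
  containing the bipartition. Splits at exactly 50% are excluded —
  they may be mutually incompatible, and "majority" is read strictly.
* **TBE** (transfer bootstrap expectation): for a branch with
  smaller-side size $p$, the mean over replicate trees of
  $1 - \delta/(p-1)$, where the transfer index $\delta$ is the minimum
  number of tips that must be moved to recover the branch in that tree.
  $\delta$ is minimized over *all* branches of the replicate tree,
  trivial tip branches included, which gives the score its floor at 0
  and guarantees $\delta \le p-1$. For $p=2$ the score degenerates to
  presence/absence. TBE is never below BRP on the same inputs, which
  the test suite asserts over hundreds of random replicate sets.

Tip-set mismatches between replicate trees are hard errors, never
silently pruned.

Tree disagreement is quantified two ways. `rfNormalized()` divides the
symmetric-difference count of the two bipartition sets by its maximum
attainable value given each tree's resolution (the total number of
bipartitions in the two trees), so 0 means topologically identical and
1 completely contradictory, for polytomous trees too. `rfWeighted()`
sums $|l_1 - l_2|$ over the union of bipartitions (an absent split
contributes length 0) and divides by $\sum(l_1 + l_2)$; it reduces to
the unweighted version when all internal lengths are equal, and
de-emphasizes conflicts among near-zero branches. No single standard
normalization exists for the weighted form; the one above is chosen
because it reproduces both boundary behaviours and is recorded in
output metadata. `branchLengthConcordance()` reports plain Pearson
correlations between replicate branch-length vectors on a fixed
topology, with zero-variance vectors reported as missing (`NA`), never
as 0.

`njTree()` (neighbor joining on missing-aware p-distances, negative
lengths clamped to 0) is deliberately plain plumbing: it exists so the
pipeline can run end to end when externally estimated
maximum-likelihood trees are not supplied, and is not a substitute for
proper ML inference on real data.

## Rooting

`madRoot()` implements minimal ancestor deviation rooting. For a
candidate root at relative position $\rho$ on a branch, every tip pair
$(b, c)$ contributes the relative deviation
$|2\,d(\mathrm{anc}, b)/d(b, c) - 1|$, where the ancestor is the
candidate root itself for pairs spanning the branch and the ordinary
path ancestor otherwise; the branch score is the root-mean-square over
all pairs and the root is the global minimizer. Because the spanning
terms are affine in $\rho$, the per-branch optimum is the closed-form
minimizer of a quadratic, clamped to $[0,1]$; the test suite checks it
against a $10^{-3}$-step grid search that evaluates the definition
directly. Numerical decisions:

* Tip pairs at zero distance have undefined relative deviation; they
  are skipped and counted in a warning.
* Ties within $10^{-12}$ of the minimal deviation are all reported; the
  winner is the branch whose canonical smaller-side tip set is
  lexicographically smallest, making the output deterministic.
* The deviation of an exactly clocklike tree is zero only up to the
  double-precision floor of a root-mean-square ($\sqrt{\varepsilon}
  \approx 10^{-8}$); "zero" is asserted at $10^{-7}$.

`midpointRoot()` places the root halfway along the tree diameter.
Rate-accelerated lineages drag the midpoint but barely move the MAD
root; `rootComparison()` reports both so root ambiguity stays visible.
On 16-tip clocklike trees with 5% multiplicative branch-length noise,
MAD recovers the true root branch in at least 95 of 100 simulations
(recomputed by the acceptance script).

## Cysteine registry and domain demarcation

Homologous cysteine columns are carried in a `CysteineRegistry`
(trimmed-alignment coordinates): ZP-N Cys1–Cys4 at columns 1, 29, 48,
80; ZP-C Cys5 (146), Cys6 (164), Cys7 (201), Cys8 (218 or 215 — two
alternative columns, as replicate alignments place it at either), CysA
(206), CysB (210); and the novel sites — the IHP pair (105, 134), the
Type-3 partner in the βC strand (140), the AB-loop pair (117/129) and
the FBN-1 partner (203). A site counts as present if a cysteine occurs
within ±2 columns of one of its registry columns; the window absorbs
replicate jitter.

Domains are demarcated by cysteine anchors: ZP-N = \[1, 80\]
(Cys1–Cys4), ZP-C = \[105, 218\] (βA-strand cysteine to Cys8), closed
1-based intervals. Because replicate trimming shifts columns, anchors
are re-located per replicate to the nearest column within ±3 whose
cysteine frequency is at least 0.5, falling back to the nominal
position.

## Domain-loss scanning

Gap proportions (fraction of gap or ambiguous characters, with X and ?
counted as missing and B/Z/U as residues) are computed per sequence and
domain in every replicate, averaged, and mapped onto a rooted tree.
`detectLossClades()` flags maximal clades with

* target-domain tip-median ≥ `tau_high` (default 0.70),
* every other domain's tip-median ≤ `tau_low` (default 0.30),
* at least `min_tips` tips (default 4),

and reports high-gap tips outside every flagged clade as outliers
(isolated truncation artifacts, not loss clades). The thresholds are an
explicit operationalization — published loss signatures sit at 74–99%
gap against a 6–8% background, so the defaults split the two regimes
with wide margin — and are configurable and recorded in every report.

One refinement beyond the plain median rule proved necessary: a clade
qualifies only if it is *loss-conforming throughout*, i.e. every child
subtree with more than one tip recursively has a target-median ≥
`tau_high`. Without this, a clade containing two loss subfamilies and
one clean subfamily can clear the median threshold on the strength of
its loss members alone and swallow the clean subfamily. Single tips are
exempt from the child condition, preserving the median's resistance to
isolated aberrant tips. A corollary: two *sister* loss subfamilies are
reported as one clade — the appropriate evolutionary reading, since a
single loss event on their shared stem explains both.

## Connectivity typing and parsimony mapping

`classifyType()` works from the presence vector alone: modules lacking
the IHP pair are Type 1; modules with both IHP cysteines are Type 2,
unless CysA is absent while the βC partner (140) is present, which is
the reshuffled CysA–CysB bond diagnostic of Type 3. Exactly one IHP
cysteine fits no rule and is `atypical`. Flags record Cys5–Cys7 loss
(either member absent) and full CysA–CysB loss.

`callDisulfides()` judges spatial plausibility from side-chain
centroids (mean of CB and SG; CA fallback with a warning) via greedy
non-overlapping pairing: repeatedly call the closest remaining pair
within `call_thresh`, consuming both cysteines, then report remaining
pairs within `proximal_thresh` as proximal. Defaults are
`call_thresh = 8.0` Å and `proximal_thresh = 10.0` Å: observed
plausible bonds in homology models sit at roughly 5.6–7.3 Å centroid
distance, so 8 Å covers them with margin while 10 Å marks the gray
zone. Greedy matching was chosen over optimal weighted matching for
transparency; the tests compare it against enumeration on the planted
geometry, where the two coincide.

`fitchParsimony()` maps type changes on a rooted binary tree with the
standard two-pass algorithm; ties in the top-down pass prefer the
parent's state, then the lexicographically smallest, so labelings are
deterministic. Exhaustive enumeration over all internal labelings is
the test oracle.

## The synthetic-data generator

`syntheticSpec()` fixes the study conditions; `makeFixtureBundle()`
writes a complete bundle (replicate FASTAs, true tree, per-tip PDB +
residue-column maps, feature table, truth JSON) that is byte-identical
for identical (spec, seed). Defaults, chosen once to mirror the regime
the method targets at desk scale:

| parameter | default | rationale |
|---|---|---|
| subfamilies × species | 6 × 5 | ancient paralogous clades across species; 30 tips keeps a full recovery sweep fast |
| `seq_length` | 240 columns | within the trimmed-alignment range (233–269) |
| `subs_rate` | 1.0 subs/site root-to-tip | deep divergence: most background columns variable, registry cysteines invariant |
| backbone vs within-subfamily branches | ~5× longer | pre-radiation origins of the subfamilies |
| `n_replicates` | 10 | the analysis design uses 100 replicates; 10 exercises every replicate-aware code path at a fraction of the cost, and the replicate count is a parameter, not a constant |
| `gap_jitter_sd` | 1.0 column | reproduces the reported replicate ranges (length 233–269, gaps ~7–9%) without embedding an aligner |
| background gaps | ~5–9% per sequence | matches the reported 6.7–8.6% overall gap fraction |
| planted ZP-N loss | 2 subfamilies, gap ∈ \[0.80, 0.99\] | the observed 74–99% loss regime; one Type 2 and one Type 3 subfamily, mirroring the standalone ZP-C subfamilies |
| type assignments | 2× Type 1, 2× Type 2, 2× Type 3 | all three connectivity classes present |
| planted disulfide SG–SG centroid distance | U\[2, 6\] Å | below the 8 Å call threshold with margin |
| decoy cysteine separation | ≥ 10 Å | above the proximal threshold |

Design notes and deliberate simplifications:

* Substitutions follow a uniform-frequency Poisson process (no
  WAG/VT-style exchangeabilities): downstream stages consume alignments
  and trees, never model fits.
* Replicate perturbation jitters gap blocks and trims 0–3 columns per
  flank of the true alignment rather than re-aligning; this emulates
  the *effect* of replicate alignment (column jitter, length variation)
  without embedding an aligner.
* Background columns never carry cysteine, so presence calls are a pure
  function of the planted layout; real alignments contain incidental
  cysteines that would make recovery probabilistic rather than exact.
* Retention noise inside a lost domain spares only non-cysteine
  residues: a lost domain loses its disulfide network, and stray
  retained cysteines at adjacent positions would also make the decoy
  geometry (≥ 10 Å) unconstructible on a chain.
* Coordinates are a smooth curve with planted geometry, not protein
  biophysics; only centroid distances are meaningful.
* The truth record includes the minimum number of type changes on the
  true tree, computed at generation time by exhaustive enumeration over
  the subfamily backbone — independent of the package's Fitch
  implementation, so the parsimony check is dual-route.
* All randomness derives from one master seed via a counter-based
  splitter; every generator output is a pure function of (spec, seed).

What passing recovery tests on these bundles shows: the detection and
classification machinery is correct under the stated regime (clean
separation of loss and background, cysteine layouts exactly at registry
columns, planted geometry). What it does not show: robustness to
misalignment of cysteine columns beyond ±2, incidental background
cysteines, partial domain loss, or model-based tree estimation error on
real data.

## Problem sizes used by the test and acceptance suites

Oracle-equivalence checks run on 50 random ≤10-tip instances (transfer
index), 50 random 8-tip pairs (both RF variants), 20 random 8-tip
labelings (Fitch) and 20 random 6-tip trees (MAD vs grid). Rooting
recovery uses 100 16-tip clocklike trees with 5% length noise.
Loss/type recovery sweeps 20 default bundles (30 tips, 10 replicates
each), with coordinate files for six representative tips on two of
them. The full suite and the acceptance script each complete in well
under a minute of compute per stage on one CPU.

## Known limitations

* Consensus construction assumes the >50% splits of the replicate set
  are the interesting ones; no effort is made to recover compatible
  sub-majority splits (greedy consensus is out of scope).
* `fitchParsimony()` requires a binary rooted tree; consensus trees
  with polytomies must be resolved (`ape::multi2di`) first, which adds
  zero-length branches but can affect the change count's
  interpretation.
* The NJ fallback is distance-based and missing-data-sensitive; with
  ~90% of a domain gapped, its placements within loss clades rest on
  the remaining domain only.
* The registry is module-centric: positions are meaningful only in the
  trimmed module alignment's coordinate system, and mapping back to
  full-length sequences is the caller's responsibility (the bundle's
  sidecar TSVs do exactly this for synthetic structures).
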