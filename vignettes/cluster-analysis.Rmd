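---
title: "Exact combinatorial analysis of synaptic input clusters on dendrites"
author: "SpineClusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact combinatorial analysis of synaptic input clusters on dendrites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpineClusters)
```

## The question the package answers

Modern mapping experiments (optogenetics with calcium imaging, GRASP,
array tomography, dense electron microscopy) tell us, spine by spine,
which dendritic spines of a neuron receive input from a defined
presynaptic population. A central question about such maps is whether the
labeled inputs are arranged *randomly* along the dendrite or form
*clusters* — local accumulations that matter for dendritic integration
and for theories of plasticity.

SpineClusters answers this with exact combinatorics. Under the null
hypothesis, the $n$ labeled inputs are a uniform random draw of $n$ of
the $N$ spines, so every arrangement has probability $1/\binom{N}{n}$.
Any spatial pattern can therefore be assigned an exact likelihood by
counting arrangements. The package counts them with arbitrary-precision
integer arithmetic, so the likelihoods are exact rational numbers rather
than estimates — the alternative, estimating likelihoods by random
reshuffling, needs on the order of $10^6$ rounds for a 1% relative error
on a probability of 0.01 (see the error model below), and only yields an
estimate.

## Ensembles, gaps and ensemble types

An **ensemble** is a candidate cluster: a stretch of spines delimited by
labeled spines at both ends whose labeled members satisfy a spatial
criterion. Three criteria are supported by `detectEnsembles()`:

1. *continuous* — directly neighbouring labeled spines (mostly of
   theoretical interest);
2. *nearest-neighbour distance* — every labeled member is within
   $\Delta_{crit}$ of its nearest labeled neighbour (the working
   criterion; $\Delta_{crit}$ can be justified by the length constants of
   dendritic interactions);
3. *packing ratio* — the fraction of labeled spines in the stretch is at
   least $PR_{crit}$. The two thresholds are related by
   `packingRatioThreshold()`: $PR_{crit} = m/(m\,\Delta_{crit}+1) \approx
   1/\Delta_{crit}$ for large $m$; the packing ratio is the weaker
   criterion because it does not constrain the internal arrangement.

In the **order-based** treatment spines are counted by rank (the special
case of uniform spacing) and an ensemble type is a triple $(M, m, g)$:
$M$ spines in total, $m \ge 2$ of them labeled (both ends must be
labeled), flanked on each side by a **gap** of $g$ spines free of the
specific input. The gap equals the nearest-neighbour criterion expressed
in spines. In the **distance-based** treatment the type is
$(\ell_M, m, \ell_g)$ with the ensemble length and gap length in µm.

## The specific ensemble likelihood

For one segment, the probability of an ensemble with exactly $m$ inputs
is a product of three exact counts divided by the total
$\binom{N}{n}$:

* internal arrangements: $\binom{M-2}{m-2}$ ways to place the inner
  $m-2$ inputs, both ensemble ends being labeled
  (`internalArrangements()`);
* external arrangements: for every admissible position of the $M$-spine
  window along the segment, $\binom{f}{n-m}$ ways to place the remaining
  inputs on the $f$ spines outside window and gaps
  (`externalArrangements()`). Near the segment ends the gaps are
  truncated by the border, which adds the spines of the missing gap back
  to $f$. The implementation sums over window positions directly; for
  $N - M \ge 2g$ this equals the familiar two-term closed form
  $2\sum_{i=0}^{g-1}\binom{N-M-g-i}{n-m} +
  (N-M-2g+1)\binom{N-M-2g}{n-m}$, and it remains correct on segments too
  short for two full gaps (where the closed form's vanishing-coefficient
  convention undercounts — e.g. an ensemble occupying the entire segment
  has exactly one arrangement).

The **specific ensemble likelihood** (SEL) of the type "$M$ spines with
*at least* $m$ inputs" sums the exact probabilities over
$i = m, \dots, \min(n, M)$ (`specificEnsembleLikelihood()`). It is
non-increasing in $m$. The "at least" convention reflects the biological
reading that a mechanism requiring some number of clustered inputs stays
operational with more of them.

Two deliberate properties of this counting are worth knowing:

* **Arrangements with two disjoint same-type ensembles are counted once
  per ensemble.** The counting enumerates qualifying windows, not
  arrangements; `enumerateAssignmentsOracle()` quantifies the excess
  (window count minus arrangement count) for any configuration that can
  be enumerated. Two disjoint ensembles of one type need $2m$ labels
  plus separating gaps, so the excess vanishes whenever $2m > n$.
* **The internal nearest-neighbour criterion is not enforced inside the
  window**: $\binom{M-2}{m-2}$ includes arrangements whose inner inputs
  sit further than the criterion apart, which a detector would split
  into smaller ensembles. This is the published counting convention; a
  `strict = TRUE` switch restricts the internal arrangements to those
  satisfying the criterion (bounded-composition counts) for users who
  want window and detector semantics to coincide.

## The six analysis steps

1. **Detection** (`detectEnsembles()`) — maximal, non-overlapping
   ensembles under the chosen criterion. Under the packing-ratio
   criterion, where two maximal stretches can share a boundary input,
   the proximal stretch claims it (detection scans proximal to distal).
2. **SEL** (`ensembleLikelihoods()`) — each detected ensemble's type
   receives its exact likelihood.
3. **Classification** (`classifyClusters()`) — an ensemble is a
   **cluster** if its SEL is at or below a threshold (default 1%, with
   2.5% in use elsewhere in the literature), subject to a minimum input
   count (default 2; 3 is a common stricter choice) and to the
   *whole-segment exclusion*: ensembles with $N \ge M \ge N - 2g$ and
   $m = n$ (or the distance analogue) span the entire segment, carry no
   positional information, and are excluded by default. SELs exactly at
   the threshold classify as clusters (the "at or below" rule) and are
   flagged `atThreshold` so the boundary case is visible.
4. **Overall cluster likelihood** (`overallClusterLikelihood()` and
   variants) — the probability of observing *any* ensemble type at
   least as unlikely as the reference cluster: over ensemble sizes
   $M = 2, \dots, (n-1)g+1$ (`maxEnsembleSize()`), the SEL of the
   smallest $m$ whose SEL is at or below the reference SEL is added.
   Keeping only the smallest qualifying $m$ per size avoids counting an
   arrangement twice within a size, because the "at least $m$" events
   are nested in $m$.
5. **Dataset test** (`datasetClusterTest()`) — with $S$ analyzed
   segments/trees of which $c$ contain a cluster, the binomial tail
   $P = \sum_{x=c}^{S}\binom{S}{x}\,OCL_{max}^x(1-OCL_{max})^{S-x}$ is
   the P value against the random-arrangement hypothesis, computed with
   the dataset's maximum OCL (conservative). When single high OCL values
   mask significance, `rankedClusterTest()` sorts the OCL values
   ascending and reports the tail probability for every $c$ using the
   $c$-th value as the bound.
6. **Characterization** (`characterizeClusters()`) — input count, total
   spines, span between the outermost inputs, distance of the cluster
   midpoint from the soma, spine density inside versus outside, packing
   ratio.

`analyzeClusters()` chains steps 1–4 for one segment or tree.

## Branched trees

On a tree, the remaining inputs distribute over all $N_{tot}$ spines
(exact sums over segments, `treeTotals()`), and two placement families
contribute (`treeEnsembleProbability()`):

* **Within-segment placements** with end-aware gaps. A segment end with
  no spines beyond it (the soma end of the root, distal tips) is
  *closed*: gaps truncate there exactly as at segment borders. An end at
  a branch point is *open*: spines exist beyond it on **both** adjacent
  segments, so when only $i < g$ gap spines fit on the segment itself,
  the residual $g - i$ must be present on *each* adjacent segment —
  $2g - i$ gap spines in total at that end. The count of free spines in
  the end-correction sum is therefore $N_{tot} - M - 3g + i$ (full gap
  $g$ on the far side plus $2g-i$ on the open side). We derived this
  from the gap bookkeeping and confirmed it by exhaustive enumeration on
  small trees; a version of the end sum with $N_{tot}-M-2g+i$, which
  treats the open end like a truncated closed end, fails that
  enumeration. Likewise the interior-placement multiplier is
  $(N_x - M - 2g + 1)$, by the same bookkeeping as the single-segment
  case.
* **Branch-point placements**: ensembles spanning two or three of the
  segments meeting at a bifurcation. An $M$-spine ensemble can split
  over two segments in $3(M-1)$ ways
  (`branchpointTwoSegmentPlacements()`) and over three segments in
  $(M-1)(M-2)/2$ ways — the compositions of $M$ into three positive
  parts (`branchpointThreeSegmentPlacements()`). Two-arm spans have two
  labeled ends ($\binom{M-2}{m-2}$ internal arrangements), three-arm
  spans three ($\binom{M-3}{m-3}$, vanishing for $m = 2$). Every one of
  the three segments carries a gap of $g$ spines beyond its arm (also
  the unoccupied one, which abuts the ensemble across the branch
  point), so $3g$ spines are deducted when everything fits.

Rather than evaluating those closed forms blindly, the implementation
enumerates the placements explicitly and counts gap spines per
placement. This matters when segments are short: a gap (or an arm) that
does not fit is handled by **recursive extension** — the residual
continues past the next segment end, splitting again at further branch
points (`gapExtension = "recursive"`, the default, which matches
exhaustive enumeration) — or by **truncation at the adjacent segments**
(`gapExtension = "upper_bound"`), which reproduces the behaviour of the
printed closed forms and yields an upper estimate of the likelihood; the
result is then flagged (`isUpperBound()`). Trees are restricted to
bifurcations; a segment with a single child is treated as a
continuation, and branchings of higher degree are rejected. The root's
proximal end is the soma and is closed; since no spines exist beyond it,
an alternative classification would not change any count, so this is
fixed rather than configurable.

The tree SEL (`treeSpecificEnsembleLikelihood()`) and tree OCL
(`overallClusterLikelihoodTree()`) then follow exactly as on segments.

## The distance-based treatment

Real spine spacing is irregular. The distance engine slides a window of
length $\ell_M$ from spine to spine: the window starting at spine $i$
(position $d_i$) covers $[d_i,\, d_i + \ell_M]$ and contributes
$\binom{M_i - 2}{m - 2}\binom{N - M_i - g_i - h_i}{n - m}$ arrangements,
where $M_i$ is the number of spines in the window (zero contribution
when below $m$), and $g_i, h_i$ count the spines in the trailing gap
interval before $d_i$ and the leading gap interval after the window end,
truncated at the segment borders. Every qualifying spine set has a
unique leftmost labeled spine, so the sum over start spines does not
double-count it. The SEL and OCL definitions carry over
(`specificEnsembleLikelihoodDistance()`,
`overallClusterLikelihoodDistance()`); since any realizable ensemble
length is a span between two spines, the OCL's outer sum runs over the
pairwise spine spans up to $(n-1)\ell_g$, de-duplicated by the window
sets they generate so that a set of spines satisfying several lengths is
counted once.

### Interval conventions

Endpoint handling at the window and gap boundaries is consequential and
is therefore explicit:

* `convention = "exclusive"` (default): windows are closed intervals
  (a spine exactly at the window end is inside), both gap intervals
  exclude the window's own boundary spines, and a window must fit the
  segment ($d_i + \ell_M \le d_N$) — a truncated window at the distal
  border is an ensemble of a *shorter* length and is counted under its
  own type, which keeps types disjoint in the spirit of the OCL's
  count-once rule. Under this convention the distance treatment on a
  unit-spacing layout with $\ell_M = M - 1$, $\ell_g = g$ coincides
  *exactly*, cell by cell, with the order-based treatment, and the
  geometric enumeration oracle (`enumerateDistanceOracle()`) reproduces
  every value.
* `convention = "published"`: the leading-gap interval is the closed
  interval $[d_i + \ell_M,\, d_i + \ell_M + \ell_g]$ — taken literally
  from the printed piecewise definitions, it contains the window-end
  spine itself, which is then subtracted from the free spines a second
  time — and the window slides across *every* start spine, clipped at
  the distal segment end. This convention exists because it is the one
  that reproduces the published table of the 30-spine worked example
  (below); it is a reproduction mode, not a recommended analysis mode.

On trees, the same window logic applies within segments, with gap
*lengths* spilling across open ends: the part of $\ell_g$ that does not
fit on the segment continues onto both adjacent segments (and further,
recursively, when those are short). Branch-point ensembles choose an arm
end spine on two or all three adjacent segments with summed
branch-point distances within $\ell_M$; occupied arms must end in a
labeled spine (two or three labeled ends), and each segment carries a
gap of length $\ell_g$ beyond its arm
(`branchpointProbabilityDistance()`, `treeSELDistance()`).

For reporting, a detected cluster's length is the span between its
outermost labeled spines, and that span is also the $\ell_M$ used for
its likelihood.

## The worked example and its published table

The package ships a fully specified worked example
(`publishedWorkedExample()`): one segment, $N = 30$, $n = 5$, gap 2.
Its published SEL table is reproduced by the distance engine in the
`"published"` convention on the unit-spacing layout:

```{r worked}
ex <- publishedWorkedExample()
ex$display
signif(likelihoodValue(ex$ocl), 3)
```

Eleven of the fourteen cells agree with the published figures to half a
unit of the last printed digit. Three sit within about one unit:
SEL(4,3) computes to 0.08750 (printed 0.088 — one arrangement count away
from the rounding boundary), SEL(6,4) to 0.0216 (printed 0.021) and
SEL(6,5) to 0.000709 (printed 0.0007); the latter two equal the printed
figures under truncation instead of rounding. The order-based closed
form (`engine = "order"`, or `specificEnsembleLikelihood()`) gives
slightly different values in the cells affected by the interval overlap
and the clipped distal windows — e.g. SEL(2,2) = 0.424 rather than 0.37,
and SEL(9,5) = 0.0054 rather than 0.0056 — which is precisely the
difference between the two conventions; exhaustive enumeration over all
142506 assignments confirms the order-based closed form exactly.

The published overall cluster likelihood of this example, 0.0253, equals
the sum of the *displayed* (rounded) table entries; summing the same
cells at full precision gives `r signif(likelihoodValue(publishedWorkedExample()$ocl), 4)`
(published convention) or 0.02703 (order-based). The package reports
full-precision OCLs and additionally carries 2-significant-figure
display fields in its outputs, matching the table style.

## The reshuffling baseline and its error model

`reshuffleLikelihoodEstimate()` re-assigns the $n$ labels uniformly for
a chosen number of rounds and counts the rounds containing the target
type (size with $\ge m$ labels and clean gaps — the SEL event). The hit
count is binomial, so $\mathrm{Var} = \text{rounds}\cdot p(1-p)$
(`reshuffleVariance()`) and the estimate's coefficient of variation is
$\sqrt{(1-p)/(\text{rounds}\cdot p)}$ (`reshuffleCV()`): $10^6$ rounds
for a 1% error at $p = 0.01$, and four times the rounds for half the
error. The baseline exists to cross-validate the exact values and to
make the cost of estimate-based analysis explicit.

## Synthetic data: what it does and does not emulate

`generateRandomLayout()` places spines on a grid or as a Poisson process
and draws labels uniformly — exactly the null model, for calibration.
`generatePlantedClusterLayout()` plants an $(M, m, g)$ cluster (ends
labeled, internal spacings within the criterion, clean flanking gaps)
and scatters the remaining labels outside cluster and gaps, recording
the members as ground truth; `generateRandomTree()` does the random case
on a tree. The generators do **not** emulate measurement realities:
undetected spines or inputs, spatially varying spine density along real
dendrites, uncertainty in path-length measurements, or biologically
correlated input placement. Green tests on synthetic data therefore
demonstrate internal correctness of the counting and the workflow — not
that a particular biological data set is clustered.

## Numerical and design choices

* All arrangement counts are exact big integers (base-$10^6$ limb
  arithmetic; binomials by exact multiply/divide); division to a float
  happens once per likelihood. Doubles would lose exactness near
  $\binom{57}{28}$ already. `LikelihoodValue` objects expose the exact
  fraction (`numeratorCount()`, `denominatorCount()`).
* Distance comparisons use an absolute tolerance of $10^{-9}$ µm; ties
  at a window boundary count as inside the window. Duplicate positions
  are legal and counted individually.
* Probabilities are displayed at 2 significant figures next to their
  full-precision values.
* The calibration event for null layouts is the SEL event (a qualifying
  window type present), matching what the OCL sums; a maximal-ensemble
  detector flags strictly fewer layouts because the window counting
  does not enforce the internal criterion (see above).
* Test problem sizes are chosen for exact enumerability at desk scale:
  segment sweeps up to $N = 14$, tree sweeps up to $N_{tot} \le 12$,
  calibration on 2000 null layouts, reshuffling checks at $10^4$ rounds
  across 100 seeds and one $10^6$-round run.

## Limitations

* Only bifurcating trees; ensembles wrapping around more than one
  branch point are not modelled (their likelihood contributions are
  covered by the branch-point terms only insofar as arms stay on the
  adjacent segments; gaps do recurse further).
* One input category; co-clustering of several input types is outside
  the current model.
* The window counting's disclosed overcounts (multiple same-type
  ensembles; internal criterion) make SEL/OCL slightly conservative
  upper counts in regimes where those arrangements exist; the oracles
  quantify this exactly at small scale.
* Path-length distances only; no Euclidean shortcuts, no electrotonic
  metrics.
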