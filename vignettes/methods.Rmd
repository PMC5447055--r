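---
title: "Connectivity-based parcellation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-based parcellation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractparc)
```

## The problem

Anatomically defined brain regions are rarely functionally homogeneous. A
seed region (say, the precentral gyrus) can be subdivided by asking which of
its voxels *connect to the rest of the brain in the same way*: probabilistic
tractography draws thousands of streamlines from every seed voxel, the
visitation counts over the brain form that voxel's connectivity profile, and
voxels with similar profiles are grouped into subregions. tractparc
implements this workflow from raw per-voxel streamline counts to
group-level subregion atlases, together with the machinery needed to answer
the awkward question every such study faces: *how many subregions?*

Tractography itself (and the registration that puts all subjects into a
common grid) is performed by external tools; tractparc ingests
streamline-count matrices already expressed on one voxel grid, or simulates
them (see "The phantom cohort" below).

## From counts to a clustering problem

For seed voxel $i$ with $N_s$ samples (default 5,000), the connection
probability to target voxel $j$ is $p_{ij} = c_{ij} / N_s$. Three
preprocessing steps turn raw counts into the **native connectivity matrix**:

1. **Thresholding.** Entries with $p_{ij} \le 0.04\%$ — i.e. counts of 2 or
   fewer out of 5,000 — are zeroed. The inequality is strict: a count of 3
   survives. This suppresses spurious single-streamline visits while keeping
   genuine weak pathways.
2. **Path-length correction.** Streamline counts decay with distance from
   the seed, so each retained entry is multiplied by the Euclidean distance
   (mm) between target and seed voxel centers. The seed's own voxel sits at
   distance zero and drops out.
3. **Down-sampling.** The corrected profile is summed over axis-aligned
   blocks (default 5 mm); summing (not averaging) conserves total
   streamline mass exactly.

The order — threshold on raw counts first, then correct, then down-sample —
is a deliberate package choice: the cutoff is defined in raw samples, so it
must see raw counts. Applying the correction first and thresholding the
corrected values would make the cutoff distance-dependent.

The entry $(i,j)$ of the **cross-correlation matrix** is the Pearson
correlation between rows $i$ and $j$ of the native matrix. Rows with zero
variance (a fully thresholded voxel) get correlation 0 with everything and
1 with themselves, which keeps the matrix well-defined without special
cases downstream.

## Normalized-cut spectral clustering

Clustering follows the symmetric-normalization spectral procedure: clip
negative correlations to zero to obtain affinities $W$ (anti-correlated
profiles carry *no* affinity — clipping preserves that semantics where an
additive shift would not), zero the diagonal, form
$L = D^{-1/2} W D^{-1/2}$ with $D$ the degree matrix (zero degrees replaced
by $10^{-12}$), take the top-$k$ eigenvectors, normalize their rows to unit
length, and run k-means on the embedded rows. k-means uses k-means++
seeding with 100 restarts under a fixed derived seed; if every restart
yields an empty cluster the procedure re-derives the seed (at most 10
times) before giving up. Eigenvectors are sign-canonicalized (largest
absolute entry made positive) so results do not depend on the eigen
solver's arbitrary sign choices. No spatial constraint is applied: spatial
contiguity of the result is an empirical finding, not an input, and the
continuity index below measures it.

Cluster labels from any clustering run are arbitrary names. Immediately
after clustering they are renumbered canonically — decreasing cluster size,
ties by smallest contained voxel index — which makes runs reproducible,
but carries no meaning across subjects. Because the preferred $k$ is not
known in advance, `cluster_solutions()` computes one independent solution
per $k$ in a range (default 2–12); the per-$k$ runs share nothing and can
execute on parallel workers with bit-identical results.

## Group consensus and maps

Cross-subject correspondence is established in three steps. First the
per-subject solutions at a given $k$ are pooled into a **coincidence
matrix**: entry $(i,j)$ is the fraction of subjects in which voxels $i$ and
$j$ share a label, zeroed below 0.5 (a majority). The source text names
this pooled matrix but not its formula; same-label co-occurrence is this
package's reading, and the majority threshold is a documented default, not
an inference. Second, spectral clustering of that matrix yields a
group-level labeling scheme. Third, each subject's labels are matched to
the scheme by maximizing total spatial overlap over all $k!$ bijections —
solved exactly by a dynamic program over label subsets, with the
lexicographically smallest optimal mapping returned for determinism. The
partition of every subject is untouched; only names change. When paired
left/right seed regions are analyzed, the right hemisphere is mirrored
across the grid midplane and matched the same way before propagation.

The **probabilistic map** of cluster $c$ holds, at each voxel, the fraction
of *all* subjects assigning that voxel to $c$ (subjects not covering the
voxel count in the denominator — the literal "relative number of subjects").
The **maximum probability map** assigns each voxel with any nonzero
probability to the argmax cluster; exact ties are broken by averaging each
tied cluster's probability over the 26 adjacent voxels (dividing by 26
regardless of how many neighbors fall inside the volume — a documented
choice for boundary voxels), residual ties go to the smallest label, and no
minimum-probability floor is applied. A final cleanup flips any labeled
voxel whose label disagrees with the strict majority of its labeled
6-connected neighbors, synchronously, for up to 10 passes; ties and
neighborless voxels are left alone and background never gains labels. The
pass cap matters: adversarial configurations (a two-label checkerboard)
oscillate under synchronous majority updates and must be cut off.

## The validity suite

Indices are grouped by what they measure.

**Consistency across parcellations** — Cramer's V, Dice, NMI, VI — compare
two parcellations through their overlap frequency table $T$
($T_{ij}$ = voxels with label $i$ in A and $j$ in B, over voxels labeled in
both):

* $V = \sqrt{\chi^2 / (N \min(m-1, n-1))}$, with zero-expectation cells
  skipped in $\chi^2$;
* $\mathrm{Dice} = \frac{1}{k}\sum_i 2|A_i \cap B_i| / (|A_i| + |B_i|)$,
  which *requires matched labels* (clusters empty in both contribute 1,
  empty in exactly one contribute 0);
* $\mathrm{NMI} = 2I(A;B) / (H(A) + H(B))$, and
  $\mathrm{VI} = H(A) + H(B) - 2I(A;B)$. All entropies use the natural
  logarithm: NMI is base-invariant and VI is reported in nats. The identity
  $VI = (H_A + H_B)(1 - \mathrm{NMI})$ is exploited as a cross-check in the
  tests.

They are evaluated under three resampling schemes: **split-half** (random
equal halves, default 100 repetitions, odd cohorts give the first half the
extra subject; the two half-cohort MPMs are compared after label alignment
by assignment), **pairwise** (all $n(n-1)/2$ subject pairs directly), and
**leave-one-out** (each subject against the MPM of the rest). Half-cohort
MPMs are built without the noise-correction pass; the correction is a
final-map cleanup, and applying it inside every replicate would smooth the
very variability the schemes are meant to measure.

**Consistency within parcellation** — the mean **silhouette** under the
cosine distance between native-matrix rows (all-zero rows sit at distance 1
from everything; singleton-cluster voxels score 0), and the **continuity
index**: per cluster, largest connected component over cluster size,
averaged, under 6-, 18- and 26-connectivity.

**Consistency of topology** — the **hierarchy index**
$HI_k = \frac{1}{k}\sum_i \max_j(x_{ij}) / \bar{x}_i$, where $x_{ij}$
counts voxels of cluster $i$ (at $k$) stemming from cluster $j$ (at
$k-1$); and the **topological distance**, the cosine distance between
vectorized row-normalized contact matrices (voxels of region $i$ touching
region $j$ under 26-connectivity; diagonal excluded; an all-zero contact
pattern gives distance 1 by convention).

### Choosing k

`suggest_k()` lets each index series nominate its local extrema in the
favorable direction (maxima for CV/Dice/NMI/silhouette/continuity/HI,
minima for TpD). "Local extremum" is operationalized as: interior points
must be at least as good as both neighbors and strictly better than one;
endpoints must strictly beat their single neighbor — so flat plateaus do
not flood the vote. VI instead uses a stability rule: $k$ is nominated when
the VI increment from $k$ to $k+1$ exceeds the mean increment by one
standard deviation while the increment into $k$ does not exceed the mean.
"Considerable increase" is not quantified in the source description; the
mean + 1 sd rule is this package's parameterization (`vi_rule_sd`).
Each (index, resampling scheme) pair is one voter; continuity votes only
through its default 26-connectivity series (the 6- and 18-connectivity
series are reported but non-voting) so one index does not carry triple
weight. The suggestion is the mode of all nominations, ties to the smallest
$k$ — and it is advisory: the full vote table is returned and nothing
downstream applies it silently.

## The phantom cohort

Real inputs require diffusion MRI, tractography and registration, so the
package ships a generator whose output exercises every downstream stage.
Each planted subregion $c$ owns a prototype probability pattern over the
target grid: disjoint supports (pairwise cosine similarity 0, against a
design bound of 0.2), covering a random 40% of the subregion's block of the
grid with Gamma(1.5)-distributed weights — sparse, uneven patterns loosely
mimicking the footprint of a corrected, thresholded tract distribution. A
subject's seed voxel with planted label $c$ draws its profile as one
multinomial sample of $N_s$ streamlines from
$(1-\alpha)\,\mathrm{proto}_c + \alpha\,\mathrm{uniform}$, where the noise
mixture $\alpha$ defaults to 0.15. Optional boundary jitter reassigns
voxels within a radius of a planted boundary to a neighboring cluster with
probability 0.5, and each subject's labels pass through a stored random
permutation, emulating the arbitrary label names the group stage must
undo. Default geometry: a 6×6×8 seed block (288 voxels) at 2 mm on a 16³
target grid, 20 subjects, planted $k=4$ as near-equal slabs along the
longest axis. Per-subject RNG substreams are derived from the master seed
by a multiplicative-congruential mix, so cohorts are bit-reproducible and
independent of generation order. A bilateral variant mirrors the planted
arrangement across the first axis with independent noise, giving a ground
truth with topological distance exactly 0.

What the phantom does *not* emulate: spatially correlated noise between
neighboring seed voxels, distance-dependent count decay (profiles are
drawn from distance-free prototypes; the pipeline's correction step is
exercised but cannot be validated against a planted bias), partial-volume
effects, registration error, and anatomically curved subregion shapes.
Passing recovery tests therefore show the machinery is correct under the
stated generative model, not that real cohorts will behave as cleanly.

## Numerical and scale choices

* Coordinates are 0-based voxel indices, ordered lexicographically by
  (x, y, z); this ordering is the row order of every matrix and is
  re-derived identically on every read.
* Matrix text files carry a "rows cols" header and full double precision
  (round-trips below $10^{-12}$); label images are stored as 32-bit integer
  NIfTI (bit-exact round-trips), probability maps as 32-bit float.
* The assignment dynamic program is exact for $k \le 16$; the pipeline's
  $k \le 12$ default sits comfortably inside.
* Tests and examples run at reduced scale chosen for seconds-to-minutes
  turnaround: phantom recovery uses the default 288-voxel seed block with
  20 subjects and $k = 2..8$, split-half repetitions are cut to 20 inside
  the 10-seed recovery loop (100 remains the production default), and the
  oracle comparison for normalized cuts enumerates all bipartitions of 8
  voxels. These sizes are the package's own simulation design.
* Degenerate inputs: empty seed masks, single-row native matrices,
  single-cluster overlap tables (Cramer's V defined as 1 only when both
  sides are single-cluster), and disjoint supports all raise informative
  errors rather than returning misleading scores.

## Limitations

The pipeline assumes all subjects share one voxel grid; registration
quality is outside its control and outside its error model. The group
coincidence matrix is a label-co-occurrence construction — other readings
of "connectional similarity" (e.g. pooling subject-level correlation
matrices) would yield different group schemes. The VI stability rule and
the local-extremum definition are reasonable but not unique
operationalizations; both are parameterized and reported rather than
hidden. Finally, `suggest_k()` aggregates heterogeneous evidence by
unweighted majority — with few voters the mode can be fragile, which is
why the vote table, not just the winner, is always returned.
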