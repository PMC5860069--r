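---
title: "Gating and Poisson quantification of two-channel ddPCR data"
author: "dropgate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gating and Poisson quantification of two-channel ddPCR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropgate)
```

## The problem

Droplet digital PCR partitions a reaction into roughly 20 000 droplets of
volume $V$ (nominally 0.85 nl), each of which amplifies independently. With
two fluorescence channels — say a mutant-specific probe on Channel 1 and a
wild-type probe on Channel 2 — every droplet lands in one of four classes:
negative in both channels (NN), positive only in Channel 1 (PN), positive
only in Channel 2 (NP), or positive in both (PP). Counting positives per
channel and applying Poisson statistics yields absolute concentrations
without a standard curve, which is what makes the platform attractive for
rare-variant work such as circulating free tumour DNA, where mutant
molecules may be a few percent (or far less) of the total.

Two practical obstacles stand between raw amplitudes and counts. First, the
four clusters are not always separable by one horizontal and one vertical
gate: the single-positive clusters commonly *lean* (PN) or *lift* (NP),
tilting diagonally in amplitude space. Second, a fringe of droplets of
intermediate fluorescence — *rain* — sits between the clusters and should
not be counted on either side.

## The model

### Classification

`droplet_gate()` supports three gating rules, each also exported on its own:

* **Thresholds** (`threshold_classify`): a droplet is Channel-$j$-positive
  iff its amplitude is $\ge$ the channel threshold. The boundary is closed
  (equality counts as positive) because a closed decision is needed and the
  choice is immaterial at fluorescence noise scales.
* **Four-centre k-means** (`kmeans_classify`): standard Lloyd iteration on
  the raw two-channel amplitudes — assign each droplet to the nearest
  centre by Euclidean distance, recompute centres as cluster means, stop
  when the largest centre movement falls below `tol` (default $10^{-6}$
  amplitude units, far below fluorescence noise) or after `max_iter`
  (default 100) iterations. Distances use raw amplitudes by default; the
  two channels of these instruments share a scale, and raw distances match
  the visual geometry of an amplitude plot. `standardize = TRUE` divides
  each channel by its standard deviation first, for assays where the
  scales differ materially. Seeding is deterministic: the four corner
  points of the per-channel 10th/90th percentiles, so repeated runs agree
  without a random-number stream; centres are user-overridable. An emptied
  cluster is an error naming the offending starting centre rather than a
  silent 3-cluster result.
* **k-nearest neighbours** (`knn_classify`): each droplet takes the
  majority label of its $k$ nearest training droplets; distance ties break
  by training-row order (deterministic), and a winning vote fraction below
  `min_vote_fraction` (default 0.51) leaves the droplet `Unclassified`.
  Because the minimum fraction exceeds one half, split votes never assign
  a class.

Cluster centres found by k-means are *named* by geometry
(`assign_centres_to_classes`): NN has the smallest sum of per-channel
ranks, PP the largest, and of the remaining two the one with the larger
Channel 1 coordinate is PN. The assignment is invariant under permutation
of the input and refuses genuinely ambiguous geometries instead of
guessing.

### Rain refinement

Both refinements compute each cluster's statistics **once** from the
incoming labels, then test every droplet — a single refinement pass, with
no re-estimation after removal. Labels only ever move from the four
classes *to* `Rain`, never back and never across classes.

* `sd_rain(table, n_sd = 5)` relabels a droplet `Rain` when it lies more
  than `n_sd` sample standard deviations from its cluster mean in either
  channel. The bounds are axis-aligned rectangles.
* `mahalanobis_rain(table, max_distance = 30)` computes each cluster's
  sample mean $\vec\mu_c$ and covariance $\Sigma_c$ and relabels droplets
  whose squared Mahalanobis distance
  $d^2_c(\vec x) = (\vec x - \vec\mu_c)^\top \Sigma_c^{-1} (\vec x - \vec\mu_c)$
  exceeds the class radius $m_c$. The iso-distance contours are ellipses
  aligned with the cluster, so leaning and lifting clusters are trimmed
  along their own axes — the property the axis-aligned methods lack.

Two conventions deserve explicit statement. The distance is the standard
*inverse*-covariance quadratic form; quadratic forms in the covariance
itself (without the inverse) sometimes appear in print but are not a
distance in the cluster's own units, and this package does not offer that
form. And $m_c$ bounds the **squared** distance: under an approximately
Gaussian cluster $d^2$ is roughly $\chi^2_2$, so $m_c = 30$ keeps
essentially all genuine members ($P(\chi^2_2 > 30) \approx 3\times10^{-7}$)
and is deliberately permissive. Radii generally need manual adjustment per
assay — large enough to keep real members, small enough to cut the rain —
and the per-class `max_distance` argument exists for exactly that.

A robustness limit worth knowing: because the ellipse is built from
moments of the *current* members, contamination inflates the covariance
along the contamination direction and thereby hides itself. If a fraction
$f$ of a cluster's members are actually rain at distance $D \gg \sigma$,
the inflated variance along that axis is about $(1-f)\sigma^2 + fD^2$, and
removal at radius $m_c$ is only possible when roughly $f < 1/m_c$. Tighter
radii are therefore *more* robust to contamination, at the cost of
trimming more genuine droplets; with rain excluded from the accepted total
(the default, below) uniform trimming does not bias the concentration.

### Quantification

With $P_T$ positive droplets for target $T$ among $R$ accepted droplets,
the concentration per microlitre is

$$\hat c_T = \frac{-\log\left(1 - P_T/R\right)}{V},$$

the inversion of the Poisson zero-class: a droplet is empty of $T$ with
probability $e^{-c_T V}$. `Rain` and `Unclassified` droplets are excluded
from both $P_T$ and $R$ by default — they are ambiguous, not negative —
with `exclude_rain = FALSE` providing the alternative reading (rain counted
as accepted negatives). Exclusion has a useful side effect: any refinement
that removes the same *fraction* of every class leaves $P_T/R$, and hence
the estimate, unchanged. A saturated channel ($P_T = R$) is an error, not
an infinite estimate, and a well that saturates inside a plate summary is
flagged in its `Status` column rather than aborting the plate.

Fractional abundance is reported as
$\hat c_{\text{ch1}} / (\hat c_{\text{ch1}} + \hat c_{\text{ch2}})$, with
Channel 1 the mutant channel *by convention*: the ratio-of-concentrations
definition is a documented package choice, since "allelic fraction" admits
several formulas (ratios of copies, of positives, of concentrations) that
differ at high occupancy.

### Plate-level gating

When `droplet_gate()` receives a plate, classification and rain refinement
run on the droplets of **all wells pooled**, and quantification is per
well. This matters for dilution series: a low-input well may contain no
double-positive droplets at all, so per-well 4-means would fail (an empty
cluster), while the pooled plate anchors every cluster with the wells
where it is abundant. The cost is the assumption that cluster positions
are stable across the plate — true for a single assay on one plate, and
the reason per-well gating remains available by fitting wells one at a
time.

## The synthetic-data generator

`simulate_well()` draws each droplet's true class from the independent
per-channel occupancy probabilities $p_j = 1 - e^{-c_j V}$, then draws its
amplitudes from the class's bivariate Gaussian. `simulate_kras_series()`
arranges wells the way rare-mutant validation experiments are run:
replicate wells at a fixed mutant fraction over increasing input amounts.
Defaults, chosen once and documented here:

* **Geometry**: NN at (2000, 1500), NP (2500, 7500), PN (9000, 1800), PP
  (9500, 8000), per-channel sd 300 — resembling real amplitude plots.
  A `shear` parameter (series default 0.3) tilts the PN and NP covariances
  to emulate lean and lift; it is a phenomenological stand-in for probe
  cross-hybridisation, not a chemistry model.
* **Series**: totals of 15, 60, 240 and 960 copies/µl, i.e. roughly 1, 4,
  16 and 64 ng of human genomic DNA in a 20 µl reaction at ~303 haploid
  genome copies per ng. The mass-to-concentration mapping is a convenience
  default; the argument takes any concentrations.
* **Rain**: a `rain_fraction` share of droplets (series default 0.002,
  ~40 per 20 000-droplet well — a clean assay with a visible fringe) is
  placed uniformly on the *interior* of the segment between two randomly
  chosen cluster means (relative position $u \sim U(0.3, 0.7)$, Gaussian
  jitter orthogonal to the segment). Rain is kept off the cluster cores
  deliberately: a droplet inside a cluster's own spread is phenotypically
  a member of that cluster, and no classifier could (or should) call it
  rain; rain is defined by *intermediate* fluorescence between clusters.
* **Reproducibility**: each well uses its own stream seeded
  `seed + well index`, so plates are bit-reproducible and wells
  independent.

What the generator does **not** emulate: PCR kinetics, probe
cross-hybridisation chemistry, droplet-volume variability, baseline drift
between wells, or heavy-tailed amplitude noise. Passing tests on this
generator therefore show that the pipeline inverts its own statistical
model correctly — not that it is robust to every artefact of real plates,
which is why the rain radii remain a manual, per-assay judgement.

## A worked series

The study-scale check the package ships (see `scripts/acceptance.R`) gates
a simulated 5% series — 3 replicates at each of the four input levels,
20 000 droplets per well — with pooled k-means seeded at the true cluster
means, Mahalanobis rain at $m_c = 9$, and per-well quantification:

```{r series}
plate <- simulate_kras_series(mutant_fraction = 0.05,
                              total_copies_series = c(15, 60, 240, 960),
                              replicates = 3, seed = 1)
centres <- do.call(rbind, plate_metadata(plate)$cluster_means[
  droplet_classes(core_only = TRUE)])
fit <- droplet_gate(plate, method = "kmeans", centres = centres,
                    rain = "mahalanobis", max_distance = 9)
mean(coef(fit)[, "fractional_abundance"])
```

The radius $m_c = 9$ (3-sigma ellipses) is the manually adjusted value for
this geometry, per the discussion above: at the default 30 the rare PN
cluster's ellipse, inflated by the rain it attracted during k-means
assignment, would keep part of that rain; at 9 it sheds it while retaining
98.9% of genuine members of every class — and, rain being excluded from
$R$, that uniform trimming cancels out of the concentration estimate.

## Numerical choices and edge cases

* Covariance inversion is guarded by an exact condition-number threshold
  of $10^{10}$; beyond it the operation errors naming the cluster rather
  than silently regularising.
* Sample covariances use the $n-1$ denominator; a singleton cluster gets a
  zero covariance and a `singleton` flag; classes with fewer than 3
  droplets refuse Mahalanobis refinement.
* k-means assignment ties break to the lowest centre index; k-NN distance
  ties break by training-row order. Both rules are deterministic and
  mirrored exactly by the brute-force oracles in the test suite.
* Amplitude CSVs are written with a shortest-exact numeric rendering, so
  write-then-parse reproduces every double bit-for-bit and seeded
  pipeline re-runs are byte-identical.
* Degenerate wells — fewer than 4 droplets, or all amplitudes identical —
  refuse k-means with a clear error instead of guessing.

## Scale of the shipped checks

The test suite and acceptance script run entirely on generated data: the
dilution series at its full design (12 wells × 20 000 droplets),
concentration recovery over 200 simulated wells of 20 000 droplets, and
oracle-equivalence sweeps on 20 random instances of up to 500 droplets —
sizes chosen to match the study design while keeping a full run in the
order of seconds.

## Known limitations

* Four clusters only: multi-target experiments with more clusters, and
  one-channel extreme-value thresholding pipelines, are out of scope.
* Point estimates only: no confidence intervals or error propagation on
  concentrations.
* The Mahalanobis ellipse is moment-based and single-pass, with the
  self-masking contamination limit described above; radii are a manual,
  per-assay setting, not an automated optimum.
* Pooled plate gating assumes cluster positions are stable across wells.
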