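---
title: "Automated resting-state network selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated resting-state network selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Spontaneous BOLD fluctuations in the 0.01–0.05 Hz range are temporally
coherent across the regions of a resting-state network. Spatial independent
component analysis (ICA) separates a 4D resting run into spatial maps with
paired time courses, but leaves two practical problems: components arrive in
arbitrary order and sign, and many of them are artifactual (scanner drift,
motion transients, physiological oscillations, and a global component
expressed everywhere). `rsnica` implements an automated selection of the
component carrying a target network — here modelled on the auditory
resting-state network — together with the group-level machinery needed to
compare two cohorts, and a phantom generator that makes the whole chain
testable against known ground truth.

## The selection model

For a decomposition into $n$ components (default 30), each of 14 target ROIs
and 6 anticorrelated ROIs contributes a mean time course, which is regressed
on an intercept plus all $n$ component courses, giving per-ROI, per-component
betas and $T$ statistics with $\nu = t - n - 1$ degrees of freedom. For each
component $c$ and sign $s \in \{+,-\}$ a connectivity graph is built on the
target ROIs: its nodes are the ROIs with $T > T_{th}$ (positive family,
graphs $1..n$) or $T < -T_{th}$ (negative family, graphs $n+1..2n$), and
every pair of nodes is joined (clique rule), so a graph with $k$ nodes has
$E = k(k-1)/2$ edges. The threshold $T_{th}$ is the upper-tail $t$ quantile
at $1 - \alpha/\binom{14}{2} = 1 - 0.05/91$, a Bonferroni correction over
all 91 possible edges. Each graph is scored

$$\mathrm{score} = E \times w \times w_F$$

where $w \in [0,1]$ is the fraction of the 6 anticorrelated ROIs whose $T$
has the sign *opposite* to the graph's condition — near zero for the global
component, which expresses every ROI with the same sign — and $w_F \in
(0,1]$ is a fingerprint weight measuring closeness to a reference "neuronal"
fingerprint. The graph with the maximal score selects the network component;
ties break toward higher $E$, then lower graph index; if every score is zero
the result is flagged rather than resolved arbitrarily. Because the two sign
families mirror each other, the selection is invariant under flipping any
component's (map, course) pair.

Design choices made here where the method description left latitude:

* **Clique rule.** Each ROI has one $T$ per component, so "an edge between
  each pair of suprathreshold targets" is the only consistent reading.
* **$w$ as a sign-count fraction.** Only the behavioural contract is fixed
  (≈0 for the global component); a count of opposite-signed anti ROIs over 6
  satisfies it and is scale-free.
* **$w_F = \exp(-d/k)$** with $d$ the Euclidean distance of
  scale-standardized features and $k = 11$ the number of features: smooth,
  parameter-free, 1 at the reference mean, 0 in the far limit.
* **Degrees of freedom are computed from the design** ($t - n - 1$; 269 for
  300 volumes and 30 components), never hard-coded.

## Fingerprints

Each component's fingerprint has 11 features: spatial skewness and excess
kurtosis of the map, 64-bin histogram entropy of map values, "clusterness"
(the fraction of $|z|>2$ voxels lying in 26-connected clusters of ≥10
voxels), one-lag autocorrelation and 64-bin entropy of the time course, and
periodogram band-power fractions in 0–0.008, 0.008–0.02, 0.02–0.05,
0.05–0.1 and 0.1–Nyquist Hz. The exact feature list is a design decision
(versioned as `rsnica-fp-1` in the output metadata): the fingerprint concept
constrains the feature *families* (spatial, temporal, spectral), not an
exact list. Skewness enters distances as its absolute value so that $w_F$ is
invariant to the ICA sign indeterminacy. The reference fingerprint is the
per-feature mean over the network components of a reference cohort with a
robust spread (MAD × 1.4826). The spread is floored at 10 % of the
feature's absolute mean (and $10^{-3}$ absolute): with a homogeneous
reference cohort the raw MAD of a feature can collapse toward zero, and a
hard near-zero floor would turn any deviation — for instance the extra
regions legitimately present in a patient's network component — into an
astronomical standardized distance that vetoes the component outright. The
relative floor caps the confidence any single feature can carry.

## Preprocessing

Temporal filtering is projection on the orthogonal complement of an
intercept, a linear trend, and discrete-cosine regressors covering all
frequencies below the 0.005 Hz cutoff — the standard fMRI drift model.
Projection is exactly idempotent and has no wraparound artifacts; a pure
linear ramp is annihilated and a 0.002 Hz oscillation loses >99 % of its
power while the 0.01–0.05 Hz band of interest is preserved. Smoothing is a
separable Gaussian of 8 mm FWHM ($\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$,
converted to voxels per axis), replicate-padded at the mask bounding box.
The order is fixed as filter → smooth. Motion correction, slice-timing and
template normalization are out of scope: the phantoms are generated on a
common grid, and the package expects real data to arrive already aligned.

## Group analysis

Per subject, the time courses of all components *except* the selected one
are regressed out of the preprocessed data, and the residual is regressed on
the selected component's course. The predictor is itself partialled against
the same nuisance set, which makes the voxelwise slope equal to the
full-model partial regression coefficient (Frisch–Waugh); without this the
slope would be shrunk by $1-R^2$ of the selected course on its 29
colleagues — a factor that varies by subject and would corrupt group
statistics. Because maps are z-scored, betas are in comparable units across
subjects; the course is sign-flipped when the negative-sign graph won, so
the network always loads positively. Group inference is a voxelwise
one-sample $t$ (random effects, $\nu = n-1$) per group with
Benjamini–Hochberg FDR at $q = 0.05$, and a pooled-variance two-sample
contrast ($\nu = n_1+n_2-2$; 26 for 15 vs 13 subjects).

Cluster-extent correction simulates null maps — white Gaussian noise
smoothed to the estimated map smoothness, standardized exactly per voxel
using the separable kernel's row sums of squares, and mapped monotonically
to a $t$ field — thresholds them two-sided at the voxel threshold (default
$p = 0.01$, $t$ from the actual dof; $t = 2.772$ survives as a regression
constant for 26–27 dof), and returns the smallest cluster size whose
exceedance fraction over (default) 1000 iterations is ≤ 5 %. Thresholding is
performed in $z$ space, which is equivalent because the $z \mapsto t$ map is
monotone, and 26-connectivity is used throughout. Null smoothness is
estimated from group-demeaned beta maps via the Gaussian autocorrelation
model $\rho(\Delta)=\exp(-\Delta^2/4\sigma^2)$; demeaning removes the shared
network structure that would otherwise inflate the estimate. Residual
inter-subject misalignment still inflates it mildly (typically 10–11 mm for
8 mm smoothing), making the cluster threshold conservative rather than
liberal.

## The phantom generator

Each phantom run is a linear mixture over a 24×24×24 grid of 3 mm voxels
(300 volumes, TR 2 s by default — a desk-sized version of a 10-minute
resting acquisition):

* **network** — 14 disjoint spherical blobs (radius 2.5 voxels) with a
  band-limited 0.01–0.05 Hz Gaussian course (all Fourier mass inside the
  band by construction);
* **anti_network** — 6 blobs (radius 2.5) expressed with the exact
  sign-flipped network course. Because the tie makes the two sources one
  temporal dimension, spatial ICA recovers them as a single component whose
  map is positive on the targets and negative on the anti blobs — exactly
  the pattern the anticorrelation weight keys on;
* **global** — strictly positive everywhere ($0.3 + 0.5 g^2$ for a smooth
  Gaussian field $g$: right-skewed, hence separable by ICA), sharing the
  0.01–0.05 Hz band so that it competes with the network on edge count and
  must be rejected by $w$;
* **drift** — a spatial gradient with a monotone linear course (removed
  almost entirely by the high-pass filter, as scanner drift should be);
* **spike** — a motion-like transient (3 volumes) expressed on opposite
  face slabs of the volume;
* **physio** — a 0.15 Hz sinusoid on a handful of blobs.

Artifact maps are deliberately spatially non-Gaussian (skewed, sparse or
slab-like): spatial ICA separates sources by map non-Gaussianity, and real
artifact topographies are structured. Source amplitudes (network 1.0, global
0.7, drift 0.45, spike 0.5, physio 0.6 in course-SD units) were calibrated
once so that ordinary least squares on the ground-truth maps recovers the
mixing matrix to within 5 % relative error at SNR 1 while artifacts stay
comparable in power to the network; `snr` is the ratio of noiseless-mixture
RMS to the i.i.d. Gaussian noise SD. Noise is drawn after fixing its scale
from the base mixture, so a patient and control run with the same seed share
the identical noise realization and differ only inside the extra regions.

The **patient condition** injects the network course into `n_extra_regions`
(default 3) additional blobs at gain 1.0 × network amplitude. The gain is a
calibration choice (no effect size is available to copy). It is set by the
geometry of cluster-extent inference: at 8 mm smoothing and a voxel
threshold of $t \approx 2.78$, the minimum cluster size on this grid is
50–80 voxels, and a weaker coupling (e.g. 0.6) yields suprathreshold
extents of 35–200 voxels across the seeded regions — peak $t$ of 6–7 but
detection of *every* region becomes a coin flip on the jitter realization.
Gain 1.0 pushes each region's extent safely past the cluster threshold
while remaining of the same order as the network's own expression. The
extra blobs use radius 2.8 voxels — the largest that keeps the blob lattice
disjoint — for the same reason: effects smaller than the smoothing kernel
are invisible to cluster-extent inference by construction. Per-subject
anatomy is emulated by a rigid integer translation of all blob maps, uniform
on {−2..2} voxels per axis, which preserves blob disjointness while
degrading voxelwise group overlap, as residual normalization error does.

What the phantoms do **not** model: head motion fields, slice timing, EPI
distortion, autocorrelated or Rician noise, and any hemodynamic model. The
analysis chain never exploits noise structure, so Gaussian i.i.d. noise
keeps every oracle closed-form; passing tests demonstrate the pipeline's
internal correctness and statistical calibration, not robustness to
real-scanner artifacts.

## Numerical choices and degenerate inputs

* Fixed-point ICA: logcosh contrast, symmetric decorrelation, tolerance
  $10^{-4}$, 1000 iterations; non-convergence returns the current estimate
  with a warning flag. PCA uses the $t \times t$ Gram matrix
  (deterministic); the random orthogonal initialization is seeded, so a
  decomposition is bit-reproducible given its seed.
* Cross-subject clustering: deterministic reference matching on |spatial
  correlation|. Constrained agglomerative merging was tried first and
  deadlocks — once the surviving clusters pairwise share subjects no legal
  merge remains, stranding more clusters than requested — so the seeding
  subject's components initialize the clusters and every other subject's
  components are assigned by repeatedly taking the globally best remaining
  correlation with the running sign-aligned cluster means. The seed and the
  assignment order are data-driven (cohort similarity, ties by subject id),
  which makes the result independent of input order.
* ROI cubes use voxel-center-in-cube membership with half-open upper
  bounds, so counts are grid-independent; an empty intersection is an error
  naming the offending ROI. The map threshold default (1.0 in z units)
  keeps roughly the upper sixth of a z-scored map.
* Zero-variance voxels in group maps get $t = 0$ and are counted, not
  propagated as NaN. Rank-deficient designs abort with the collinear
  columns named.
* The cluster-size estimator requires ≥100 iterations; the held-out
  false-positive check (`cluster_fpr`) uses fresh seeds so calibration and
  validation never share noise.

## Problem sizes used by the test-suite

The bundled tests exercise the chain at the scale the phantom defaults
define: a 12-subject reference cohort for ROI and reference-fingerprint
derivation; 50 single-subject phantoms at SNR 2 for selection accuracy; a
15 + 13 cohort (300 volumes) for contrast recovery; 20 pure-null cohorts
(120 volumes, ground-truth courses) for cluster-level specificity, compared
against the 5 % nominal rate with a two-binomial-SE sampling margin — the
same margin convention used for the 1000-iteration calibration check.

## Known limitations

* The two-step beta maps inherit variance from ICA estimation: when a
  subject's network pattern is partially split across components, the
  partial coefficient remains unbiased but noisier.
* Smoothness estimation from demeaned beta maps still absorbs
  misalignment-induced structure, so cluster thresholds err conservative.
* The fingerprint feature list is fixed and versioned; it is a reasonable
  instantiation of the concept, not a reconstruction of any particular
  published list.
* With fewer than ~6 reference subjects the MAD scales of the reference
  fingerprint are unstable; `run_reference` therefore wants a dozen
  subjects, mirroring common practice for reference cohorts.
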