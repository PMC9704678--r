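---
title: "Linking meta-analytic grey-matter alteration to spatial gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking meta-analytic grey-matter alteration to spatial gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alexpr)
```

## The analysis

`alexpr` implements a four-stage imaging-transcriptomics pipeline that
asks whether the spatial pattern of grey-matter (GM) alteration found by
coordinate-based meta-analysis of voxel-based morphometry (VBM) studies
co-varies with the cortical expression of candidate genes, and whether
that co-variation concentrates in particular resting-state networks
(RSNs).

### Stage 1 — ALE meta-analysis

Each VBM experiment contributes a set of peak coordinates (foci) in
Talairach space; MNI coordinates are first converted with the pooled
icbm2tal affine (Lancaster et al., 2007, *Hum. Brain Mapp.* 28:1194).
Around every focus a three-dimensional Gaussian is placed,

$$p(X_i) = \frac{1}{\sigma^3 (2\pi)^{3/2}} \, e^{-d_i^2 / 2\sigma^2},
\qquad \sigma = \frac{\mathrm{FWHM}}{\sqrt{8\ln 2}},$$

where $d_i$ is the Euclidean distance (mm) between a voxel centre and
focus $i$.  Per voxel we store probability mass (density × voxel
volume).  An experiment's modelled-activation (MA) map combines its
focus kernels — by voxel-wise maximum by default, or as a probabilistic
union — and the ALE map is the union across experiments,
$\mathrm{ALE}(v) = 1 - \prod_e (1 - \mathrm{MA}_e(v))$.

Significance comes from a random-foci Monte Carlo null: each iteration
redraws the observed number of foci uniformly within the analysis mask
(keeping the observed foci-per-experiment structure) and evaluates the
resulting ALE value at randomly sampled in-mask voxels.  Voxel p-values
use the add-one rank rule $p = (1 + \#\{\mathrm{null} \ge
\mathrm{ALE}\}) / (1 + N)$, clamped to $[1/(N{+}1),\, N/(N{+}1)]$ so the
Z map ($z = \Phi^{-1}(1-p)$) is finite everywhere.  The map is
thresholded at $p < 0.05$ uncorrected with a minimum cluster extent of
150 mm³ — a deliberately liberal screen, because network-level inference
happens downstream with its own null model.  Surviving
connected components (26-connectivity by default) are labelled in
decreasing size order.

### Stage 2 — gene expression maps

Expression enters as donor-level point samples (coordinate + value),
emulating Allen Human Brain Atlas microarray samples: six donors, of
which four cover the left hemisphere only.  Per donor we (i) z-score the
sample values across that donor's samples (population SD; the choice of
divisor cannot affect the downstream Pearson correlations), (ii) mirror
left-only donors across the midsagittal plane under a left–right
symmetry assumption (samples within 1 mm of the midline are not
duplicated), and (iii) propagate values to voxels by Voronoi
tessellation: every in-mask voxel takes the value of its nearest sample
in world mm.  The six donor volumes are averaged voxel-wise into one map
per gene.  Z-scoring before tessellation removes donor-level scale
differences before averaging; a `zscore_stage = "post_average"` switch
standardizes the averaged volume instead, for sensitivity analysis.

### Stage 3 — cluster-wise correlation

For every GM-alteration cluster (decrease and increase analysed
separately) and every gene, we compute the Pearson correlation between
the ALE Z values and the gene map values over the cluster's voxels
(pairwise-complete; clusters with fewer than 3 usable voxels or zero
variance are flagged and excluded).  Both the Fisher transform
$\operatorname{atanh}(r)$ and the Student statistic $t = r\sqrt{n-2} /
\sqrt{1-r^2}$ are recorded; neither drives inference — they are
descriptive, and the ambiguity between the two conventions is therefore
quarantined here.  Each cluster's $r$ is painted back over the cluster's
voxels, giving genes × directions piecewise-constant correlation
volumes (16 maps for the canonical 8-gene panel).

### Stage 4 — network projection and permutation test

Correlation volumes are projected onto an RSN atlas (e.g. the Yeo-7
cortical networks plus basal ganglia/thalamus and cerebellum; any
integer-label NIfTI can be supplied and is regridded by
nearest-neighbour).  A network's observed statistic is the mean of the
non-zero correlation values over its voxels.  Significance uses a
cluster-permutation Monte Carlo null: holding cluster geometry fixed,
the vector of cluster $r$ values is permuted uniformly at random
(identity permitted; N = 10,000 by default) and every network's mean is
recomputed, yielding a per-network null distribution.  A network is
significant when its observed mean exceeds the one-sided 95% quantile
(the order statistic of rank $\lceil 0.95\,n\rceil$); `p_perm` uses the
add-one rank rule.  Decrease and increase clusters are permuted
separately, matching their separate reporting.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `fwhm_mm` | 10 mm | kernel FWHM; or `"sample_size_rule"`, FWHM $= 10\sqrt{10/n}$ mm, shrinking with sample size |
| `alpha` | 0.05 | uncorrected voxel threshold |
| `min_cluster_mm3` | 150 | minimum cluster extent |
| `n_null` | 10,000 | random-foci null iterations |
| `connectivity` | 26 | cluster connectivity (6/18/26) |
| `within_experiment_combine` | `max` | focus-kernel combination within an experiment |
| `n_perm` | 10,000 | cluster permutations |
| `ci` | 0.95 | one-sided significance quantile |
| midline tolerance | 1 mm | mirroring band |

The kernel width deserves comment: widely used ALE software derives
FWHM from an empirical between-subject variance model per sample size.
That per-study table is not re-derived here; the default is a fixed
10 mm FWHM (a typical effective value for VBM meta-analysis), with the
square-root sample-size rule available, and every run records the FWHM
actually used per experiment in its manifest.

Other deliberately fixed conventions: uniform null foci are drawn over
the supplied analysis mask (whole-brain if no grey-matter mask is
given); cluster size is `n_voxels × voxel_volume` with retention at
`>= min_cluster_mm3`; equal-sized clusters are ordered by lexicographic
peak coordinate; nearest-neighbour ties in the tessellation go to the
lowest sample index; the empirical ALE null is stored as the full
sorted sample vector, so tail p-values are exact ranks rather than
binned approximations.

## The synthetic-data generators

Because the original BrainMap and AHBA inputs cannot be redistributed,
every stage is validated against generated data with known ground
truth:

* **Foci**: experiments draw a focus from each planted alteration
  centre of their direction with a per-centre hit probability and
  Gaussian spatial jitter (default: four decrease and four increase
  centres, 6 mm jitter, 80% hit rate), plus Poisson-distributed
  background foci uniform in the mask (rate 2 per experiment), with
  subject counts uniform on 10–30.
* **Expression**: per-donor sample locations uniform in the mask (left
  hemisphere only for left-only donors); values are smooth fields built
  by Gaussian-kernel mixing of white noise on random knots (length
  scale 15 mm by default).  A planted gene adds
  $\rho \cdot z_{\mathrm{ref}}$ (with the noise scaled by
  $\sqrt{1-\rho^2}$) to samples inside a designated target region.
* **Atlas**: Voronoi parcels of k random in-mask seeds; with
  `symmetric = TRUE`, seeds come in x-mirrored pairs sharing one label,
  giving bilateral parcels like real RSN atlases.

What the generators do *not* emulate: anatomically realistic grey-matter
geometry, spatially varying sampling density of the AHBA (which is
denser cortically), probe-level microarray noise, and inter-donor
registration error.  Passing tests therefore demonstrate the
correctness and statistical calibration of the pipeline's machinery,
not the biological validity of any particular real-data result.

## Self-calibration of the permutation test

`simulate_network_calibration()` measures the network test's operating
characteristics against a fixed geometry: a 4 mm grid over an 88 mm
cube, a bilateral 9-parcel atlas, 64-voxel block clusters separated by
at least 8 mm (eight in a target parcel, up to eight per other parcel;
the separation keeps individual Voronoi cells from straddling two
clusters, which would couple their r values), 1,200 samples per donor,
a 6 mm expression field length scale, and a smooth x-even reference
pattern standing in for the ALE Z map (correlation length ~15 mm —
above the nearest-sample spacing so tessellation preserves
sample-level correlation, below the domain size so within-cluster
correlation is well defined).  Each replicate draws a fresh donor
panel, rebuilds the gene map, and runs the full correlation +
permutation stack with 1,000 permutations.

* With `rho = 0` and bilateral donors the rejection rate estimates the
  test's type-I error; the package's acceptance suite checks 0.05 ±
  0.02 over 500 replicates.
* With `rho = 0.5` planted across the (bilateral) target parcel and the
  full 4-left-only donor panel, the target network's rejection rate
  estimates power; the acceptance suite requires at least 80% over 200
  replicates.

The planted region is the whole target parcel rather than the cluster
voxels alone because the Voronoi cells that cover a cluster are fed by
samples throughout its neighbourhood; planting only inside cluster
voxels would dilute the realized voxel-level correlation far below the
nominal $\rho$.

One behaviour surfaced by this harness is worth knowing about: when
left-only donors are mirrored *and* networks are bilateral, a cluster
and its mirror-image counterpart carry strongly correlated $r$ values
(four of six donors contribute identical values to both hemispheres).
The cluster-permutation null assumes exchangeable clusters, so under
these conditions the test runs anticonservatively (empirically roughly
twice the nominal rate at this harness's scale).  The null calibration
above therefore uses bilateral donors, which satisfy exchangeability;
the mirroring-induced dependence is a limitation of the hemispheric
symmetry assumption itself and applies equally to any analysis built on
mirrored donor data.

## Numerical and degenerate-input conventions

* Empty suprathreshold sets are valid ALE results (all-zero label map,
  logged); a single defined cluster makes the permutation null
  degenerate and is warned about (significance impossible).
* Networks without non-zero correlation voxels are reported with
  missing means and never significant; `p_perm` is left undefined.
* Undefined cluster correlations (zero variance / too few voxels)
  paint 0 and are excluded from network means and permutations.
* All stochastic stages derive named sub-seeds from one master seed, so
  every artifact is bit-reproducible and stages are independently
  reproducible.

## Verification scales

The shipped verification runs use desk-scale problems chosen to
exercise every code path with comfortable margins: 20³ grids for the
brute-force ALE oracle, 16³ grids for tessellation oracles, a 23³ 4 mm
grid for the calibration harness (500 null and 200 power replicates at
1,000 permutations), and the 4 mm fixture pipeline with 8 genes, 40
experiments and 10,000-sample nulls for structure and determinism
checks.

## Known limitations

* The test is one-sided by construction: only means above the upper
  quantile are flagged, matching the reporting convention the pipeline
  mirrors; negative gene–alteration associations are reported but never
  marked significant.
* No multiple-testing correction across the networks × genes grid by
  default (a `p_adjust` option exists, off by default).
* Cluster-permutation exchangeability is approximate when clusters
  differ greatly in size or when mirrored donor data meet bilateral
  networks (see above).
* The Voronoi propagation makes expression maps piecewise constant;
  within-cluster correlations are therefore step-function
  approximations whose effective degrees of freedom are the number of
  Voronoi cells intersecting the cluster, not its voxel count.
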