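---
title: "Joint image segmentation with MRF-regularized Dirichlet processes"
author: "hdpseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint image segmentation with MRF-regularized Dirichlet processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdpseg)
```

## The problem

Segmenting a grayscale medical image — the motivating case is an axial lung
CT slice — means assigning every pixel to one of an unknown number of
tissue classes (lung field, soft-tissue background, vertebral bone, tumor).
Two features of the clinical setting shape the model:

* the number of classes is not known in advance, and pathological
  structures (a tumor) may be present in some patients and absent in
  others;
* slices from different patients, or neighboring slices of one patient,
  are composed of essentially the same set of tissue classes in similar
  spatial arrangements, so segmenting them *jointly* should stabilize each
  individual segmentation.

`hdpseg` implements a nonparametric Bayesian treatment of both points: a
Dirichlet process (DP) mixture per image, spatially regularized by a
Potts-type Markov random field (MRF), with a hierarchical Dirichlet
process (HDP) on top that makes the mixture components — "atoms", i.e.
intensity classes — shared across images.

## The model

**Observation model.** Pixel intensities are standardized (mean 0,
standard deviation 1, population convention; pooled across the image set
in joint mode, see below) and modelled within class $k$ as
$x \sim \mathcal N(\mu_k, \sigma_k^2)$. Class parameters
$(\mu_k, \sigma_k^2)$ carry a conjugate normal–inverse-gamma (NIG) base
measure with parameters $(\mu_0, \kappa_0, a_0, b_0)$, and are integrated
out analytically: an atom is represented only by the sufficient statistics
$(n, \sum x, \sum x^2)$ of the pixels currently assigned to it, and the
predictive density of a new value given an atom is a scaled, shifted
Student-$t$ (`logPredictive()`). Defaults
$\mu_0 = 0, \kappa_0 = 0.1, a_0 = 2, b_0 = 1$ are weakly informative on
standardized intensities (prior variance centered near 1, prior mean
worth one tenth of an observation).

**Single-image model.** The label field of one image follows a DP mixture
with concentration $\alpha_0$, multiplied by a Potts interaction: for
pixel $i$ with neighborhood $\partial(i)$ and edge weights $w_{il}$, a
candidate label $S$ receives the factor
$\exp\{\lambda \sum_{l \in \partial(i)} w_{il}\,\delta_{S, S_l}\}$.
Neighbor *agreement is favored* — written as a raw energy term inside
$\exp(-H)$ the same expression would penalize agreement, so the sign is
fixed to match the interaction's purpose of smoothing the label field.
The lattice neighborhood is 4-connected by default (8 available), with
uniform unit edge weights and no wraparound.

**Joint model.** Each image $j$ has its own mixing measure $G_j \sim
DP(\alpha_0, G_0)$, and the shared base measure is itself a draw
$G_0 \sim DP(\gamma, H)$. Because $G_0$ is discrete, the images share a
common set of atoms, each image using its own subset — exactly the
"common set of organs, patient-specific subset" assumption. The MRF
factor lives inside every image's label field, with agreement evaluated
at the level of *global atoms* (two pixels agree when they carry the same
atom, even if they sit at different local clusters).

**Defaults.** $\alpha_0 = 0.01$ and $\lambda = 0.001$ are the package
defaults (the values used in the CT experiments the model originates
from); $\gamma = 1$ is a design choice as no value is given for the
top-level concentration. Note one empirical caveat documented rather than
resolved: in the standard Chinese restaurant process a *larger*
$\alpha_0$ opens more clusters a priori, while the source experiments
report the opposite tendency; `hdpseg` follows the standard CRP
predictive, and `crpWeights()` has a unit test asserting the standard
monotonicity.

## Inference

Inference is collapsed Gibbs sampling in the Chinese restaurant franchise
representation: within each image, pixels ("customers") sit at local
clusters ("tables"), and each table serves one global atom ("dish").
A sweep has two stages per image:

1. **Pixel stage.** Every pixel, in fixed column-major scan order, is
   detached and reseated: an existing table $t$ with size $n_t$ and atom
   $k_t$ has weight $n_t \cdot p(x \mid k_t) \cdot
   e^{\lambda a(k_t)}$, where $p(x \mid k)$ is the collapsed predictive
   and $a(k)$ the neighbor agreement with atom $k$; a new table has
   weight $\alpha_0$ times the franchise mixture
   $\sum_k \frac{m_k}{m+\gamma} p(x \mid k) e^{\lambda a(k)} +
   \frac{\gamma}{m+\gamma} p(x \mid \varnothing)$, marginalized in a
   single categorical draw ($m_k$ = tables serving atom $k$, $m$ = all
   tables).
2. **Table stage.** Every table is detached and its dish resampled:
   existing atom $k$ has weight $m_k$ times the marginal likelihood ratio
   of absorbing the table's data, times the Potts factor of the table's
   boundary pixels; a fresh atom has weight $\gamma$ times the prior
   marginal. These whole-cluster moves are what lets atoms merge across
   images; without them the MRF-coupled pixel stage alone mixes far too
   slowly.

Emptied tables and unserved atoms are deleted immediately. The
single-image sampler is the same construction without the franchise
layer. Both samplers are implemented in C++ (Rcpp) and draw exclusively
from R's RNG stream, so a run is bit-reproducible given
`samplerConfig(seed = )`.

**Validation against exact enumeration.** On instances of at most six
pixels the posterior can be computed exactly by enumerating all set
partitions (and, in joint mode, all assignments of local clusters to
atoms), scoring each by partition prior x marginal likelihood x Potts
factor (`bruteForcePosterior()`, implemented in plain R with the
Student-$t$ density from `stats::dt`). The test suite requires the
empirical distribution of long Gibbs chains to match this oracle within
total variation 0.02 for both samplers, with and without smoothing.

### Initialization

At $\alpha_0 = 0.01$, a collapsed sampler started from a single cluster
essentially never nucleates a new atom (the new-atom weight is
$\sim \alpha_0 \cdot$ prior predictive against $n_k \cdot$ predictive
with $n_k$ in the thousands), and the franchise sampler cannot split a
table (split–merge moves are out of scope). The sampler therefore starts
from a deterministic over-segmentation: pooled intensities are cut into
`nInitBins = 8` **equal-width** bins, each bin an initial atom, each image
one table per bin it contains. Equal-width (not quantile) bins matter:
with a dominant background class, quantile bins lump all minority
high-intensity classes into one top bin, and that merged table is
metastable. From the binned start, excess atoms drain quickly through the
rich-get-richer pixel stage and whole-table dish moves.

### Mode-based label extraction

After `burnIn` sweeps, every `thin`-th label field is retained. "The
mode" of a label posterior is ambiguous (joint MAP configuration vs
per-pixel marginal mode), and raw label ids are not comparable across
sweeps. `modeEstimate()` aligns every retained sample to the last one by
maximum-overlap injective matching (an exact bitmask dynamic program up
to 12 labels, greedy beyond) and then takes the per-pixel majority label,
ties to the smallest id. The retained sample with the highest log joint
is stored alongside (`@mapLabels`) as the joint-MAP alternative. The
log-joint trace over all sweeps is kept for convergence inspection.

### Standardization in joint mode

Images are standardized with the *pooled* mean and standard deviation of
the whole image set rather than per image. Per-image standardization
would shift the intensity of one physical class between images whose
class compositions differ (an image without a tumor has a different mean
than one with), which breaks the premise that a global atom describes the
same tissue everywhere. Single-image runs standardize per image.
Standardization itself uses the population-sd convention and is exactly
affine-invariant, so 8-bit and 16-bit encodings of the same pattern give
identical standardized inputs.

## The phantom generator

No clinical data ship with the package; the generator
(`generatePhantoms()`) produces image sets with precisely the structure
the model assumes, plus exact ground truth:

* a fixed set of global Gaussian intensity classes shared by all images,
  with a declared per-image subset (the canonical fixture
  `defaultLungSpec(4)` gives image 2 no tumor);
* spatially coherent regions: by default a geometric, CT-slice-like
  layout — soft-tissue background, two dark lung ellipses, a bright
  vertebra rectangle, a tumor disk inside the right lung — with a ±2 px
  per-image jitter of shape centers emulating similar-but-not-identical
  positioning across patients; alternatively a Potts-sampled mosaic for
  irregular, pathology-like shapes;
* independent Gaussian pixel noise at a declared sd. The canonical
  fixture uses class means (lung −3, background −1, tumor +1,
  vertebra +3) and sd 0.5, i.e. at least 4 sd between any two classes.

What the phantom deliberately does **not** emulate: CT physics (beam
hardening, partial-volume mixtures at boundaries), intensity
inhomogeneity, correlated noise, anatomical shape variability beyond
rigid jitter. Passing the recovery tests therefore demonstrates that the
inference machinery works when the model's assumptions hold; it does not
certify performance on clinical scans, where class overlap and
non-Gaussian structure are the dominant difficulties.

## Evaluation

`jaccardIndex()` implements $|A \cap B| / |A \cup B|$. Because predicted
atom ids carry no semantics, `matchLabels()` first finds the injective
predicted-to-truth mapping maximizing total pixel overlap (exact
assignment, as above) and then reports the per-truth-object Jaccard
index; truth objects left unmatched — for instance when a segmentation
merges vertebra into background — score 0, so omissions always show up in
the table produced by `scoreRun()`.

## Numerical choices and degenerate inputs

* Collapsed predictive and marginal likelihoods are evaluated in log
  space; conditionals are normalized by max-subtraction. The
  within-cluster sum of squares is clamped at 0 against cancellation.
* Categorical draws use inverse-CDF sampling on R's uniform stream; ties
  in per-pixel majority voting go to the smallest label id.
* A constant image standardizes to all zeros; a 1 x 1 image has an empty
  neighborhood and degenerates to a plain DP draw; both-empty pixel sets
  make the Jaccard index an error (0/0), not a value.
* Problem sizes in the shipped tests are chosen to keep the default
  suite in the minutes range: oracle comparisons use 10^5 sweeps on 4-6
  pixel instances; recovery uses the 64 x 64 x 4-image fixture at the
  default 600-sweep schedule, ten seeds.

## Known limitations

* Scalar intensity is the only feature; the observation model is
  univariate Gaussian. Texture features or multivariate likelihoods
  would require a different base measure.
* No split–merge or reversible-jump moves; mixing across well-separated
  modes relies on the binned initialization and whole-table dish moves.
* The MRF weight acts multiplicatively on an unnormalized conditional;
  $\lambda$ beyond ~0.01 visibly over-smooths (the test suite checks that
  the estimated label count is non-increasing in $\lambda$), and the
  partition function of the field is never needed or computed.
* Superpixels, 3-D volumes, DICOM series, variational or GPU inference
  are out of scope.

## A worked run

```{r, eval = FALSE}
ph <- generatePhantoms(defaultLungSpec(4, seed = 1))
res <- runSampler(ph, hyperParameters(), samplerConfig(seed = 1))
scoreRun(res, ph)
```
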