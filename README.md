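# hdpseg

Joint Bayesian segmentation of 2-D grayscale images — lung CT slices being
the motivating application — with an unknown, data-inferred number of
tissue classes.

## For whom, and why

Segmenting CT slices into lung field, soft tissue, bone and tumor usually
requires either a preset number of regions or manually placed seeds. Both
are fragile when pathology is present: tumors appear in some patients and
not in others, and their intensity can sit close to that of surrounding
tissue. `hdpseg` targets users who want

* the number of intensity classes inferred from the data (nonparametric),
* spatial coherence of the label field (MRF smoothing), and
* *joint* segmentation of several images that share the same set of
  tissue classes, so each image borrows strength from the others.

## The model

Each image is a Dirichlet process (DP) mixture of Gaussian intensity
classes: pixel intensities within class *k* are
N(μ<sub>k</sub>, σ<sub>k</sub>²), with a conjugate normal–inverse-gamma
base measure over (μ<sub>k</sub>, σ<sub>k</sub>²) that is integrated out
(collapsed representation). The label field is regularized by a
Potts-type Markov random field: a candidate label *S* for pixel *i* is
boosted by exp{λ Σ<sub>l∈∂(i)</sub> w<sub>il</sub> δ(S, S<sub>l</sub>)},
favoring agreement with neighbors. For a set of images, a hierarchical
Dirichlet process (HDP) ties the image-specific DPs together: G<sub>j</sub>
∼ DP(α₀, G₀) per image with G₀ ∼ DP(γ, H) shared, so intensity classes
(atoms) are global and each image uses its own subset.

Inference is collapsed Gibbs sampling in the Chinese restaurant franchise
representation (pixel reseating + whole-cluster dish moves, implemented in
C++), with the final labeling taken as the label-aligned per-pixel
majority over retained samples. Accuracy is scored with the Jaccard index
JI = |A∩B| / |A∪B| after an optimal injective matching of predicted to
ground-truth labels. An exact brute-force posterior over all label
configurations of tiny (≤ 6 pixel) instances serves as the correctness
oracle for both samplers. Defaults: α₀ = 0.01, λ = 0.001, γ = 1.

## Worked example

Generate the canonical 4-image lung-like phantom (64 × 64, four classes;
image 2 has no tumor), segment all four images jointly, and score against
the known truth:

```r
library(hdpseg)
ph <- generatePhantoms(defaultLungSpec(4, seed = 1))
ph
#> PhantomSet: 4 image(s) 64 x 64, 4 global classes, min separation 4.00 sd

res <- runSampler(ph, hyperParameters(), samplerConfig(seed = 1))
res
#> SegmentationResult: 4 image(s), 4 label(s) in final estimate
#>   mode: joint_hdp  seed: 1
#>   final log-joint: -23872.686

round(atomMeans(res), 3)
#>      1      2      3      4
#>  3.304 -1.359  1.831  0.207

tab <- scoreRun(res, ph)
head(tab, 4)
#>   image     object jaccard
#> 1     1 background   0.963
#> 2     1       lung   0.891
#> 3     1   vertebra   0.973
#> 4     1      tumor   0.816
mean(tab$jaccard)
#> [1] 0.92
```

The sampler recovers exactly the four generating classes. The four atom
means are the class means on the pooled-standardized scale (vertebra ≈
3.3, lung ≈ −1.4, tumor ≈ 1.8, background ≈ 0.2), and the per-object
Jaccard table has one row per (image, object) — note image 2 contributes
no tumor row. The mean matched Jaccard of 0.92 means 92% overlap between
estimated and true regions averaged over all objects; small regions
(tumor ≈ 80 px) score lower because the size-proportional CRP prior
shifts their decision boundary toward the large background class.

A thin command-line front end with `segment`, `joint`, `phantom` and
`score` subcommands is installed at `inst/scripts/hdpseg`; see
`vignettes/hdpseg-methods.Rmd` for the full model description, design
choices and limitations.

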