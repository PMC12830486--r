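# synaptau

Nanoscale analysis of tau aggregates in single synaptosomes.

In Alzheimer's disease, small (sub-diffraction) tau aggregates accumulate
inside synapses long before tangles appear. Quantifying them requires a
chain of image-analysis and inference steps: clustering single-molecule
localisations into aggregates and measuring their shape, segmenting
synaptosomes from a membrane stain to decide which aggregates are synaptic,
co-localising marker puncta across channels, and fitting mechanistic models
to what was measured. `synaptau` implements that chain as a tested,
reusable R package for researchers working with single-molecule
localisation microscopy (dSTORM), diffraction-limited multi-channel
imaging, or STED of synapses.

## What it computes

**Aggregate detection and morphometry.** DBSCAN over localisation tables
(ε = 75 nm, minimum 2 points, where clustering reduces to connected
components of the ε-graph), principal-axis morphometry per cluster —
length = major-axis extent, eccentricity = √(1 − λ_min/λ_max) — and the
fibril-like classification (length > 150 nm and eccentricity > 0.9).

**Compartment assignment.** Synaptosome segmentation by mean + 2 SD
thresholding with morphological opening and size filtering; an aggregate is
synaptic when its centroid falls inside a region mask. Includes the
mask-based spatial filtering of 3D-projected localisations with
centroid-to-centroid distance summaries.

**Length-distribution inference.** A truncated geometric model for monomer
counts n on [n_min, n_max] = [500, 1200] (lengths × 4 monomers/nm),

    P(n) = (1 − α) / (α^n_min − α^(n_max+1)) · α^n,

fitted by Bayesian inference with a uniform prior on α (adaptive grid
posterior, MAP + central 68% credible interval), and the relative
removal-rate ratio between compartments,

    r̃_intra / r̃_extra = (α_intra⁻¹ − 1) / (α_extra⁻¹ − 1),

with uncertainty propagated by posterior sampling.

**Marker co-occurrence.** The four per-FoV co-occurrence parameters
(total, marginal %, conditional % given AT8, joint %), the conjugate Beta
posterior for Bernoulli frequencies, and a closed-form Bayes factor
comparing "shared frequency" against "independent frequencies", reported
as the probability B/(1+B).

**Co-localisation and STED.** Nearest-neighbour-distance co-localisation
with an inclusive 50 nm threshold; à-trous B3-spline wavelet spot
detection, anisotropic 2D Gaussian fitting (length = 2.3 σ_long), synapse
candidate filters (> 200 ADU, σ in 80–800 nm) and the inclusive 90 nm
presynaptic proximity rule.

**Group statistics.** Bootstrap/Welch 95% confidence intervals for
differences of group means with the zero-exclusion significance rule.

**Synthetic scenes.** A fully seeded generator for every input the
pipeline consumes — localisation clouds with planted length/eccentricity,
synaptosome discs with a membrane-stain image, background localisations,
bead pairs under a planted affine distortion, truncated-geometric length
samples, and Bernoulli presence/absence tables — so the whole chain is
testable without any raw data.

## Worked example

```r
library(synaptau)

# a synthetic field of view with planted ground truth
spec <- scene_spec(n_synaptosomes = 150, fov_size_nm = c(60000, 60000),
                   occupancy_fraction = 0.3,
                   aggregates_per_occupied = list(type = "constant", value = 1),
                   extra_synaptic_aggregate_count = 20, seed = 82)
res <- run_pipeline(spec)

round(res$occupancy_fraction, 3)        # 0.284  (planted 0.3)
nrow(res$aggregates)                    # 68 detected aggregates
res$fibril_fraction_synaptic            # 0.125
print(res$length_fit)
#> Truncated geometric length fit
#>   alpha (MAP): 0.994919  [68% CI 0.993775, 0.995868]
#>   support: [500, 1200] monomers; n = 38 observations
```

The occupancy is the fraction of segmented synaptosome regions containing
at least one detected aggregate; the fit's α is the decay parameter of the
synaptic length distribution (planted here at 0.995) with its 68% credible
interval. Comparing two compartments:

```r
intra <- generate_length_sample(0.9972, count = 3000, seed = 2)
extra <- generate_length_sample(0.9949, count = 3000, seed = 3)
rr <- removal_ratio(fit_alpha(intra$length_nm), fit_alpha(extra$length_nm),
                    seed = 4)
print(rr)
#> Relative removal ratio (synaptic / extra-synaptic): 0.5367 [68% 0.5137, 0.5601]
#>   reduction in synaptic relative removal: 46.3%
```

A ratio below 1 means removal (relative to elongation) is slower inside
synapses — here recovered within uncertainty of the planted 45.2%
reduction.

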