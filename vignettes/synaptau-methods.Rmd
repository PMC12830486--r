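---
title: "Methods: nanoscale tau aggregate analysis in single synaptosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoscale tau aggregate analysis in single synaptosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptau)
```

## Overview

`synaptau` implements a quantitative pipeline for nanoscopic tau aggregates
imaged in individual synaptosomes: super-resolution localisation tables are
clustered into aggregates and measured (length, eccentricity), synaptosomes
are segmented from a membrane-stain channel so that each aggregate can be
assigned to the synaptic or extra-synaptic compartment, diffraction-limited
marker puncta are co-localised by nearest-neighbour distance, and two
Bayesian analyses extract the biology: a truncated-geometric length model
whose decay parameter measures the balance of aggregate elongation and
removal, and a Beta--Bernoulli model comparison that asks whether a marker's
frequency differs between AT8-positive and other synaptosomes.

Because raw human-brain imaging data of this kind are not publicly
deposited, every stage is exercised against synthetic scenes with planted
ground truth. The generator is first-class, tested code: it defines the
study conditions under which the package's claims are validated.

## The length model

Aggregate lengths are converted to monomer counts with a factor of 4
monomers per nm (a double-stranded aggregate with 0.5 nm beta-sheet
spacing; results are insensitive to this conversion, which we verify by
refitting with a doubled factor and scaled support). On the support
$n_{\min} \le n \le n_{\max}$ the steady-state distribution arising from a
balance of elongation and removal is truncated geometric:

$$P(n) = \frac{1-\alpha}{\alpha^{n_{\min}} - \alpha^{n_{\max}+1}}\,\alpha^{n},$$

with decay parameter $\alpha \in (0,1)$. The defaults $n_{\min} = 500$ and
$n_{\max} = 1200$ monomers (125--300 nm) restrict the fit to lengths well
above the nucleation size and below the under-sampled tail. The support
filter is inclusive at $n_{\min}$, matching the normalisation above; a
strict variant is available via `inclusive_min = FALSE`.

Inference uses a uniform prior on $\alpha$. The posterior is evaluated on a
grid, but a single uniform grid over $(0,1)$ cannot resolve it: at
realistic sample sizes (thousands of aggregates) the posterior standard
deviation is of order $10^{-4}$, smaller than the spacing of a 4001-point
uniform grid. `fit_alpha()` therefore refines recursively: each pass keeps
the region whose log-posterior lies within 30 nats of the maximum and
re-grids it with the same number of points, until the high-mass region is
well resolved. The MAP is polished by golden-section search inside the
bracketing grid interval, and the quoted uncertainty is the central 68%
credible interval (16th--84th posterior percentiles), interpolated linearly
on the final grid. Calibration is verified by simulation: over 200
replicates at $n = 5000$ the MAP bias is below one posterior SD and the
68% interval covers the truth at its nominal rate.

The relative removal rate $\tilde r$ (removal/elongation) enters through

$$\frac{\tilde r_{\mathrm{intra}}}{\tilde r_{\mathrm{extra}}}
 = \frac{\alpha_{\mathrm{intra}}^{-1} - 1}{\alpha_{\mathrm{extra}}^{-1} - 1},$$

computed from the two MAP values. Uncertainty is propagated by drawing
$\alpha$ pairs independently from the two grid posteriors (the compartments
are disjoint datasets) and taking the central 68% interval of the ratio.

## Co-occurrence: Beta posterior and Bayes factor

Marker presence per synaptosome is Bernoulli with unknown frequency $f$;
with a Beta$(a,b)$ prior the posterior is Beta$(a+n,\, b+N-n)$ for $n$
positives out of $N$. The priors default to $a = b = 1$ (uniform) and are
exposed as parameters.

To ask whether AT8-positive tau changes the probability of seeing a marker,
`bayes_factor_shared_vs_independent()` compares M1 ("one shared $f$
generated both count pairs") with M2 ("each pair has its own independent
$f$"). Treating the data as ordered Bernoulli sequences makes the binomial
coefficients cancel, leaving closed Beta-function marginals evaluated in
log space. The Bayes factor is reported together with
$P(M_1) = B/(1+B)$ and its complement, so both the "has an effect" and
"has no effect" readings are always available. `derive_count_pairs()`
supports the literal comparison (all synaptosomes vs the AT8-positive
subset, which overlap) and a `disjoint` mode (AT8-negative vs AT8-positive)
for users who prefer statistically independent groups; the literal mode is
the default.

## Localisation clustering and morphometry

Aggregates are DBSCAN clusters of localisations at $\varepsilon$ = 75 nm
with a minimum of 2 points, where the count includes the point itself: any
localisation with one neighbour within 75 nm is core, so clustering reduces
to connected components of the 75 nm neighbourhood graph and isolated
localisations are noise. The implementation is a generic DBSCAN
(grid-binned fixed-radius neighbour search plus union-find over core
points); border points, which can only arise at `min_points` > 2, are
assigned to the cluster of their nearest core point with ties broken by the
lower cluster id. Cluster ids are canonicalised by the lexicographically
smallest member coordinate, making the output invariant under row
permutation. Tests verify exact agreement with an independent
connected-components oracle.

Morphometry uses the member-coordinate covariance: eccentricity is
$\sqrt{1 - \lambda_{\min}/\lambda_{\max}}$ (0 = circle, 1 = line; defined
as 0 for a degenerate cluster), and length is the full extent of member
projections on the major eigenvector. Monomer counts round half-up.
An aggregate is *fibril-like* when length > 150 nm **and** eccentricity
> 0.9, both strict.

Two estimator properties matter when interpreting recovery tests. First,
the extent under-estimates the planted length at modest localisation
counts (the sample maximum sits below the support edge); at 150
localisations the bias is about 5%, which propagates to a decay-parameter
bias well inside the $\pm 0.005$ tolerance band used below. Second, the
eccentricity of near-circular clusters is noisy (the eigenvalue ratio
fluctuates most when the axes are nearly equal): at planted eccentricity
0.3 and 1000 localisations the estimator is unbiased but has SD
$\approx 0.09$, so per-cluster $\pm 0.05$ recovery is only guaranteed for
elongated clusters (eccentricity $\ge$ 0.7); for rounder clusters the
recovery claim holds for the mean over replicates.

## Segmentation, assignment and co-localisation

The membrane-stain image is thresholded at the FoV mean plus
`k_sd` (default 2) standard deviations, cleaned by morphological opening
(disc radii default 1 px), labelled, and size-filtered; a constant image
yields zero regions by construction. An aggregate is synaptic when the
pixel containing its centroid lies in a region mask — a rule that is robust
to single stray localisations. Pixel convention throughout: continuous nm
coordinates with origin at the image top-left corner; pixel $(i,j)$ spans
the half-open square $[(j{-}1)p, jp) \times [(i{-}1)p, ip)$.

Puncta co-localisation is object-based: for each punctum the
nearest-neighbour distance to the other channel is computed, and 50 nm is
an inclusive threshold. The four co-occurrence parameters (total signal,
marginal %, conditional % given AT8, joint %) are exact rational
percentages; the conditional metric is reported as undefined — never 0 —
when no AT8-positive synaptosome exists.

Channel registration fits a least-squares affine transform to matched bead
coordinates (the same beads imaged in both channels, so no correspondence
search); images are resampled with bilinear interpolation. Rendering
super-resolved images places one unit-mass pixel-integrated Gaussian
(default $\sigma$ = 20 nm) per localisation, truncated at $4\sigma$
(≤ 1.3e-4 mass loss); the rendering pixel size is a parameter with a 10 nm
default, since reconstruction pixel sizes vary between set-ups.

## STED morphometry

Spot detection uses the à-trous B3-spline wavelet transform; by
construction the wavelet planes plus residual reconstruct the input
exactly. The default detection plane is 2 of 3 with a threshold of 3 plane
SDs, the convention of the single-molecule tools this mirrors. That scale
targets near-diffraction-limited spots; for the broad synapse-scale spots
in our synthetic scenes ($\sigma$ = 150 nm at 20 nm pixels) plane 2 rides
the noise ripples on top of the spot and jitters by 1--2 px, so the
validation scenes detect on plane 3, which matches the spot scale and
localises every planted spot within one pixel. The plane is an exposed
parameter and should be matched to the expected spot size.

Each candidate is fitted with an anisotropic 2D Gaussian
(Levenberg--Marquardt, moment-based initialisation, short-axis sigma
parameterised on the log scale to stay positive); non-convergent fits are
discarded. Spot length is defined as $2.3\,\sigma_{\mathrm{long}}$.
Synapse candidates require amplitude > 200 ADU (strict) and a sigma between
80 and 800 nm inclusive; because the fit is anisotropic while the filter
names a single sigma, the rotation-invariant geometric mean of the two
sigmas is used. An aggregate is presynaptic when its centroid lies within
90 nm (inclusive) of a synapse centroid. Orientation is identifiable only
modulo $\pi$ and reported in $[0, \pi)$.

## Group differences

Differences between stage groups are summarised by the difference of group
means with a 95% interval — bootstrap percentile by default (resampling
each group independently; distribution-free and suited to few replicates),
Welch's t-interval as an alternative — and a difference is significant
exactly when the interval excludes zero.

## The synthetic-scene generator

`scene_spec()` + `generate_localisation_scene()` emulate one field of view:

- **Synaptosomes**: discs with Gaussian-distributed radii (default
  500 ± 50 nm) placed by rejection sampling with a no-overlap constraint
  (at most 10,000 retries, then an error); each is occupied with the
  planted probability (default 0.2).
- **Aggregates**: anisotropic Gaussian localisation clouds. The major-axis
  coordinate is hard-truncated at $\pm$length/2 (with
  $\sigma_{\mathrm{maj}}$ = length/4), so the planted length *is* the full
  extent of the noise-free support — the same definition the measurement
  uses. The minor-axis variance is scaled from the realised truncated-major
  variance so that the planted eccentricity matches the covariance
  definition. The nominal localisation precision (default 20 nm) is
  recorded in the table's `sigma` column as metadata; it is not added as
  extra jitter on top of the cloud, because the cloud covariance already
  represents the observed scatter and extra jitter would make high planted
  eccentricities unreachable at aggregate scale (at 150 nm length and
  20 nm precision no minor-axis variance could yield eccentricity 0.9).
- **Lengths/eccentricities**: either explicit pairs or lengths drawn from
  the truncated geometric law by inverse-CDF on the finite support, with
  eccentricities from a two-component uniform mixture (defaults: 25%
  elongated in [0.93, 0.99], the rest in [0.2, 0.8] — chosen so that the
  planted fibril-like fraction is ≈ 0.15 under the default length law).
- **Background**: uniform localisations at a density of 0.05 per µm², and
  a membrane-stain image of one Gaussian blob per synaptosome
  (peak 300 counts over a 100-count baseline) under Poisson shot noise.
  Background density and localisations per aggregate (Poisson, mean 150,
  floor 20) are fixture parameters — the source studies do not report
  them — and are documented, not estimated.
- **Determinism**: all randomness derives from one master seed through
  named sub-streams, so identical specs give byte-identical scenes.

What the generator does *not* emulate: blinking photophysics and emitter
re-activation, stage drift, chromatic aberration beyond the affine model,
3D structure, and non-disc synaptosome shapes. Passing recovery tests
therefore demonstrate the correctness of the computational chain under the
stated noise models, not robustness to every artefact of real acquisitions.

## Validation conditions and tolerance bands

The repeated-scene recovery test uses 500 synaptosomes at occupancy 0.2,
one aggregate per occupied synaptosome (so every detected cluster traces
to exactly one planted aggregate; multi-aggregate synaptosomes whose
clouds overlap within 75 nm would merge and confound shape recovery — a
genuine resolution limit of the clustering step, visible also on real
data), lengths at $\alpha = 0.995$, and 50 extra-synaptic aggregates.
Tolerance bands versus the *realised* planted truth were fixed from the
estimator analysis above at roughly three standard errors: occupancy
within $\pm 0.05$, fibril-like fraction within $\pm 0.10$ (binomial noise
at ~100 synaptic aggregates plus threshold-boundary misclassification),
and $\alpha$ within $\pm 0.005$ (posterior width plus the extent-bias
term). Problem sizes throughout the test-suite simulations (5000 draws and
200 replicates for calibration, 3000 per compartment for the ratio, 20
repeated scenes) were chosen so the whole suite completes in a few minutes
on one CPU while keeping Monte-Carlo error well inside each band.

## Known limitations

- The Bayes-factor comparison in its literal mode uses overlapping
  datasets (all synaptosomes vs the AT8-positive subset); the `disjoint`
  mode is provided because the overlap makes the comparison non-standard.
- No hierarchical modelling of between-sample variation in $f$; pooling
  repeats assumes a constant frequency within a stage, and the posterior
  would otherwise be wider.
- Touching synaptosomes are not split (no watershed); the generator's
  no-overlap placement sidesteps this, real data may not.
- DBSCAN at minPts 2 cannot separate aggregates closer than 75 nm.
- Near-circular eccentricity estimates are noisy at realistic
  localisation counts (see above); downstream fibril-like classification
  is dominated by the elongated tail where the estimator is precise.
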