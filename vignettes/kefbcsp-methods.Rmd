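---
title: "Spectral-spatial EEG features: the KEFB-CSP pipeline and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-spatial EEG features: the KEFB-CSP pipeline and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kefbcsp)
```

## The problem

Resting-state EEG differs between clinical groups (for example patients
with major depressive disorder and healthy controls) in ways that are
distributed across both frequency and scalp location. Classical features
capture one axis at a time: band power describes the spectrum channel by
channel, coherence describes pairwise synchrony, and nonlinear indices
such as the correlation dimension summarize signal complexity. The common
spatial pattern (CSP) family instead learns *spatial* filters that
contrast the two groups' covariance structure, and doing so separately
within narrow frequency bands (a filter bank) captures the joint
spectral-spatial structure.

This package implements that pipeline end to end for two-class,
participant-independent discrimination, together with the baseline
features and the evaluation procedures appropriate for cohort data.

## The model

### Stage 1 — filter bank

The 4-44 Hz range (theta through gamma) is tiled by contiguous Butterworth
band-passes of equal width; the default 4-Hz width gives ten sub-bands
(4-8, 8-12, ..., 40-44 Hz), a 2-Hz width gives twenty. Filters are
3rd-order designs applied forward and backward, so the net phase is zero
and the effective magnitude response is the squared design response.
Zero-phase filtering matters here because the next stage works on epoch
covariances: a phase-distorting causal pass would smear energy across
samples without changing total band energy, but it complicates any later
inspection of the surrogate time courses. Each end of the 6-s epoch is
reflect-padded (point symmetric, three times the effective filter order)
before filtering to suppress the startup transient. Adjacent sub-bands
share edges by construction; no guard bands are inserted.

### Stage 2 — common spatial patterns per sub-band

For each sub-band, the two classes' average spatial covariances are
computed with per-epoch trace normalization,
\[
\bar C_k = \frac{1}{n_k}\sum_i \frac{E_{ki}E_{ki}^{\mathsf T}}
  {\mathrm{tr}(E_{ki}E_{ki}^{\mathsf T})},
\]
so that epochs contribute equally regardless of overall amplitude. The
composite covariance \(\bar C_1 + \bar C_2\) is whitened, and the whitened
class-1 covariance is diagonalized; the resulting transform \(W\)
simultaneously diagonalizes both classes, with class-1 eigenvalues
\(\lambda\) descending in \([0,1]\) and class-2 eigenvalues equal to
\(1-\lambda\). The first and last \(p\) rows of \(W\) are the most
discriminative spatial filters; an epoch's features are the normalized
log energies of the corresponding surrogate signals,
\(\log\big(\mathrm{var}(z_i)/\sum_{j=1}^{2p}\mathrm{var}(z_j)\big)\),
where "var" is the plain sum of squared samples (band-passed signals are
effectively zero-mean, and the energy reading keeps the feature an exact
function of the epoch's scatter matrix). Concatenating over the bank gives
the filter-bank CSP (FBCSP) vector of length \(q = 2p \times N_{sb}\).

One consequence of the per-epoch trace normalization is worth knowing:
CSP is exactly invariant to a channel mixing only when the mixing
preserves epoch traces (scaled rotations). A general invertible mixing
reweights epochs inside the class averages and perturbs the features
slightly; the tests pin both behaviors. Relatedly, with \(N\) unit
sources and one source's in-band variance scaled by \(e\) in class 1,
the normalized problem's top eigenvalue is
\(s_1/(s_1 + 1/N)\) with \(s_1 = e/(e+N-1)\) — e.g. 0.744 at \(e=4\),
\(N=8\) — not the \(e/(1+e)\) of the unnormalized two-source problem;
the synthetic tests assert this closed form.

Numerical choices: a relative ridge of \(10^{-10}\,\mathrm{tr}/N\) is
added before whitening and eigenvalues below \(10^{-12}\) of the maximum
are floored, so narrowband rank deficiencies fail loudly only when truly
degenerate; eigenvector signs are fixed by making each filter's
largest-magnitude coefficient positive (features are sign-invariant, but
the fitted \(W\) becomes reproducible); exact eigenvalue ties keep the
symmetric eigensolver's ordering. Only two-class CSP is provided.

### Stage 3 — kernel PCA

The FBCSP vectors of the training set are mapped through a Gaussian
kernel \(K(x,y)=\exp(-\lVert x-y\rVert^2/2\sigma^2)\) and the centered
kernel matrix is eigendecomposed; the \(d\) leading positive eigenpairs
define the projection, and a test vector's features are its centered
kernel row against the training set times the expansion coefficients.
With a degree-1 polynomial kernel the feature space is the input space
and the stage reduces exactly to ordinary PCA — the package's
`fbcsp_pca` feature and the `kernel = "polynomial"` model are this
special case, which the tests pin against `prcomp()`.

Two conventions in the printed derivation of this method are internally
inconsistent with its own centering equation: projecting a test point
with the *uncentered* kernel vector, and normalizing expansion
coefficients by \(1/\lambda\) rather than \(1/\sqrt\lambda\). The package
defaults to the mathematically consistent choices (centered test rows;
unit-norm feature-space directions, under which the variance of training
projections on component \(i\) is exactly \(\lambda_i/n\)), and exposes
`literal_eq14` and `paper_literal_scaling` flags that reproduce the
printed formulas; the literal scaling changes only per-component scale,
never direction, so classifier rankings based on Euclidean geometry are
affected only through the implicit component weighting.

## Baseline features

* **Band power** — one periodogram of the full epoch (rectangular window,
  single DFT), power summed over bins with \(lo \le f < hi\). A single
  DFT rather than an averaged spectrum is used because the feature is a
  coarse band aggregate; the half-open bin rule makes contiguous bands
  partition the spectrum exactly (the tests assert this Parseval
  consistency).
* **Coherence** — Welch magnitude-squared coherence with 1-s Hann
  segments at 50% overlap, averaged over the band's bins, for all
  \((N^2-N)/2\) channel pairs. Welch averaging is necessary: a
  single-segment estimate is identically 1 for every pair.
* **Correlation dimension (GPFD)** — delay embedding at delay \(\tau\)
  (candidates 50-100 samples at 500 Hz), correlation integral over 30
  log-spaced radii between the 1st and 99th percentiles of the pairwise
  distances, slope fitted by least squares over the 10-radius window with
  the most constant local slope, and the estimate taken at the smallest
  embedding dimension \(M \le 30\) whose relative increase falls below
  0.05 (the saturation value). Two guards keep the window search on the
  scaling region: radii whose correlation integral has saturated
  (\(C \ge 0.975\)) are excluded, since the large-\(r\) plateau is
  constant by construction, and distances at floating-point-noise scale
  (below \(10^{-6}\) of the 99th percentile) are ignored when placing the
  radius grid, since periodic signals sampled commensurately produce
  near-duplicate embedded points. The correlation-integral normalizer is
  the number of embedded-vector pairs, so \(C(r)\to 1\); a flag restores
  the printed series-length normalizer, which only shifts the curve by a
  constant on the log scale and leaves the slope unchanged. On the
  oracles used in the tests the estimator recovers a sinusoid's limit
  cycle at \(1.06\) and a two-tone torus at \(1.82\).

## Evaluation

Participant-independent accuracy is estimated by leave-one-participant-out
cross-validation (LOPO-CV): all of one participant's epochs form the test
fold and every data-dependent stage — CSP transforms, kernel PCA, and the
classifier — is refitted on the remaining participants. Band-pass
filtering is a fixed per-epoch operation, so per-epoch band scatter
matrices are cached across folds; this is what makes a full-protocol run
(24 participants x 54 epochs, ten sub-bands) complete in a few minutes on
one core, and it cannot leak test data into training.

The voting variant restricts every participant to their first \(n_t\)
epochs in acquisition order, classifies the held-out participant's epochs
one at a time, and scores the participant correct iff *strictly* more
than half are correct; sensitivity, specificity and the individual
classification accuracy are exact fractions over the cohort. A ratio of
exactly 0.5 is therefore a miss.

Classifiers are k-NN (Euclidean, \(k=3\) by default), LDA, and a
Gaussian-kernel SVM whose kernel matches the KPCA convention
(\(\gamma = 1/2\sigma_s^2\)). Grid search enumerates the Cartesian
product of candidate values in a deterministic order (sorted parameter
names, ascending values; ties to the first cell). Because the search
selects parameters by the same cross-validation whose accuracy it
reports, the selected accuracy is optimistically biased; the function
says so at run time, and a nested mode (`nested = TRUE`) re-runs the
search inside each training fold to produce an unbiased outer estimate.
"Trial" in the voting procedure is interpreted as one 6-s epoch in
acquisition order, which is the only reading under which
\(1 \le n_t \le 54\) is satisfiable.

## The synthetic study

The generator emulates the recording geometry of a resting-state
protocol — 500 Hz sampling, 6-s epochs, 54 epochs per participant, 12
participants per class, an 8-channel temporal-montage layout by default —
with a fully known ground truth. Each source is a sum of independent
band-limited Gaussian processes, one per sub-band, produced by spectral
masking of white noise (an exact band-limiting filter, chosen over
per-band IIR filtering of noise purely for speed at cohort scale). One
designated source's variance in one designated sub-band (8-12 Hz by
default) is multiplied by the effect size in class 1; channels mix the
sources through a fixed full-rank matrix plus white sensor noise
(sd 0.1 of the unit source scale); and each participant receives
log-normal per-channel gains (log-sd 0.1), which makes held-out
participants genuinely harder than held-out epochs and keeps LOPO-CV
honest. Default effect size 4 represents a strong, clearly recoverable
contrast; effect size 1 is the exact null.

What passing tests on this data do show: the pipeline recovers planted
spatial patterns (alignment > 0.95 at low noise), its accuracy grows with
the planted effect, and the whole evaluation is leakage-free and
deterministic. What they cannot show: performance on real EEG, which has
1/f spectra, artifacts, nonstationarity, and class differences that are
neither confined to one band nor rank-one in space. The generator is a
correctness instrument, not a realism claim.

## Worked example

```{r example, eval = FALSE}
sim <- generate_dataset(synth_config(participants_per_class = 3,
                                     epochs_per_participant = 6,
                                     epoch_seconds = 2, seed = 1))
fit <- kefbcsp(sim$set, p = 1, d = 2, sigma = 10)
summary(fit)
res <- lopo_cv(sim$set, feature_spec("kefbcsp", p = 1, d = 2, sigma = 10))
res
```

The problem sizes used in the package's own test suite are scaled to the
question each test asks: algebraic identities run on 2-4 channel toy
data, cohort behavior on 6-participant cohorts of 2-s epochs, and one
full-protocol run (24 x 54 six-second epochs, ten sub-bands, a 20-cell
parameter grid) exercises the cached evaluation path at scale.

## Known limitations

* Two classes only; no multi-class CSP extension.
* No artifact handling, resampling, or notch filtering; inputs are
  assumed preprocessed.
* The EDF reader covers the plain continuous 16-bit layout with a
  uniform sampling rate; EDF+ annotations and variable-rate signals are
  out of scope.
* Kernel PCA stores the training vectors; memory grows with the training
  set, and no approximate or incremental variant is provided.
* The grid search's non-nested default reproduces the optimistic
  protocol it models; for honest generalization estimates use
  `nested = TRUE`.
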