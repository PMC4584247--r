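---
title: "Methods: hyperspectral TSS calibration and mapping in hsitss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral TSS calibration and mapping in hsitss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsitss)
```

# The problem

Total soluble solids (TSS, °Brix) — the dissolved sugars, acids and
minerals of fruit juice — are the standard internal-quality measure for
fresh fruit, conventionally obtained by juicing the fruit and reading a
refractometer. A visible/near-infrared hyperspectral camera offers a
non-destructive alternative: it records a reflectance spectrum at every
pixel, and the –OH and –CH overtone bands of water and carbohydrates
(most prominently the absorption valley near 960–980 nm) co-vary with
sugar content. Calibrating a regression from sample-mean spectra to
refractometer TSS, then applying it pixel by pixel, yields a spatial map
of TSS across each fruit.

`hsitss` implements this workflow end to end. Because no public
hyperspectral fruit dataset with reference TSS accompanies it, the
package ships a first-class synthetic generator whose physics are simple
but whose statistical structure matches what the calibration methods
assume, so that every stage can be validated against known ground truth.

# The synthetic acquisition model

## Fruit spectra

The noise-free reflectance of a fruit with soluble-solids content $t$ is
a sum of Gaussian shape components,

$$R(\lambda; t) = \sum_j \left(a_j + s_j\,t\right)
  \exp\!\left(-\left(\frac{\lambda - c_j}{w_j}\right)^2\right),$$

with defaults (see `spectral_model_params()`):

| component | centre $c_j$ | width $w_j$ | amplitude $a_j$ | TSS coupling $s_j$ |
|---|---|---|---|---|
| flat baseline | — | $\infty$ | 0.05 | 0 |
| NIR hump | 850 nm | 120 nm | 0.55 | 0 |
| absorption valley | 970 nm | 20 nm | −0.06 | −0.012 /°Brix |

These values were chosen once so the model reproduces the qualitative
signature of ripe dark fruit: visible reflectance below 10% over
420–650 nm (anthocyanin-dark skin), a broad reflectance peak at 850 nm,
and a water/carbohydrate valley whose interior minimum stays within
960–980 nm and deepens linearly with TSS over the full generated °Brix
range. Linearity of the TSS coupling is deliberate: it is exactly the
structure a linear calibration (PLSR) assumes, so parameter-recovery
tests have a well-defined truth. Reference TSS values are drawn from a
normal distribution with mean 6.75 and SD 1.55 °Brix, truncated by
rejection to [3.21, 10.99] — the summary statistics of a realistic
harvest of ripe fruit spanning unripe-tart to fully sweet.

## Scene and sensor

A capture renders non-overlapping circular fruit blobs (default radius
7 px in a 96 × 96 scene, six blobs per capture) on a spectrally flat
background of reflectance 0.25. The background level is a free choice —
real conveyor or stage materials vary — made so that the band-difference
masking statistic (below) is ~0 on background and ~0.48 on fruit,
cleanly separated by the 0.4 threshold. Digital counts follow

$$I_\text{raw} = I_\text{dark} + (I_\text{white} - I_\text{dark})\,
  R \cdot s \cdot \varepsilon,$$

with dark level 0.02 and white level 0.95 in full-scale-normalized
counts, a per-pixel scaling factor $s \sim N(1, 0.03^2)$ shared across
bands (bumpy-surface scatter), multiplicative per-pixel-per-band sensor
noise $\varepsilon \sim N(1, 0.01^2)$, clipping to the sensor full scale
of 1.0, and a small fraction (0.2%) of fruit pixels forced to full scale
to emulate specular saturation. With noise, scatter and saturation set
to zero, reflectance calibration inverts the generator exactly — the
round-trip identity the test suite pins at machine precision.

## What the generator does *not* emulate

Radiometric realism (halogen illuminant spectra, camera PSF, dark-current
drift), pigment chemistry (anthocyanin/chlorophyll absorption features
beyond a generic dark-visible plateau), spatial TSS gradients within one
fruit, and wavelength-dependent scatter. Consequently, passing tests
demonstrate the *algorithms* are correct and the pipeline recovers known
structure; they do not certify the accuracy attainable on real fruit,
where surface geometry and chemistry make spectra far richer.

# Preprocessing

Reflectance calibration is the element-wise ratio
$(I_\text{raw} - I_\text{dark})/(I_\text{white} - I_\text{dark})$;
values are deliberately *not* clipped to [0, 1] (specular pixels exceed
1), and saturation is flagged rather than altered. Band cropping keeps
the closed interval 420–1000 nm; on the linear 512-band 380–1030 nm grid
this retains 456 bands. (Published work on an instrument grid reports
460 bands for the same window — instrument band centres are not exactly
linear, so the count is instrument-specific; the closed-interval rule is
the portable definition.)

Masking subtracts the 569 nm band image from the 893 nm image and flags
pixels with difference ≥ 0.4 as foreground; band lookup is
nearest-neighbour on the grid since named wavelengths rarely coincide
with band centres. The ≥ comparison (rather than >) is a tie-break
convention. Per-sample spectra are arithmetic means over the fruit's
foreground pixels; multi-fruit masks are split into per-sample regions
with a 4-connectivity flood fill (`label_mask`).

The denoising filter is a true median filter (each pixel replaced by the
median of its 5 × 5 window) with reflection padding at the edges.
Descriptions of this step sometimes say "average gray value", but the
method named is median filtering and the median is what removes impulse
noise without blurring edges; the package implements the median, and the
window and edge policy are tested against brute-force medians.

# SPXY partitioning

Calibration/prediction splitting uses sample-set partitioning on joint
x–y distances: with $d_x$ Euclidean on spectra and $d_y = |y_i - y_j|$,
the joint distance is $d = d_x/\max d_x + d_y/\max d_y$, and selection
is Kennard–Stone: seed with the pair of maximal $d$, then repeatedly add
the sample whose minimum distance to the selected set is largest, until
the requested calibration size is reached. Ties break to the smallest
original sample index, which makes the split invariant to input
permutation. If all spectra (or all responses) are identical the
non-degenerate distance is used alone. The procedure is deterministic —
no seed involved — and by construction places the extreme samples in the
calibration set, so the calibration response range contains the
prediction range.

# Random Frog

The search keeps a current subset $V_0$ of $Q_0$ wavelengths and
iterates $T$ times:

1. draw a candidate size
   $Q^* \sim \mathrm{round}\,N(Q_0,\ (\theta Q_0)^2)$, clamped to
   $[1, p]$;
2. if $Q^* > Q_0$, draw $\omega\,(Q^* - Q_0)$ bands at random from the
   complement, fit a PLS sub-model on the union, and keep the $Q^*$
   bands with the largest absolute regression coefficients; if
   $Q^* < Q_0$, fit PLS on $V_0$ and keep the top $Q^*$; if equal, the
   candidate is $V_0$ itself;
3. score the candidate by 5-fold cross-validated RMSE of a PLS
   sub-model (latent variables $= \min(n_\text{lv,max}, |V|,
   n_\text{train} - 1)$); accept outright if not worse, else accept with
   probability $\min(\eta,\ \eta\,f(V_0)/f(V^*))$;
4. record membership of the retained subset.

A band's selection probability is its inclusion count divided by $T$.
Defaults are $T = 10{,}000$, $Q = 50$, $\theta = 0.3$, $\omega = 3$,
$\eta = 0.1$; tests and the demo pipeline run reduced $T$ (a few
hundred), which suffices for the rank structure to emerge on synthetic
data. Several details are open in the literature and fixed here as
package choices: the coefficient-magnitude add/delete scheme in step 2;
the 5-fold (not leave-one-out) sub-model fitness, since $T$ fits of a
leave-one-out loop would be prohibitive and fold noise averages out over
thousands of iterations; $\eta$ read as a ceiling on the acceptance
probability of worse candidates; the subset size evolving with the
retained subset (transdimensional moves); and a single seeded generator
driving all randomness, making runs bit-reproducible.

One property sometimes expected of selection probabilities does **not**
hold and is intentionally not asserted: under a pure-noise response, SPs
are *not* Binomial$(T, \text{rate})$ samples, because retained subsets
persist across iterations — the chain is strongly autocorrelated, and a
lucky subset can hold the chain for hundreds of iterations, pushing
individual SPs toward 1 even with no signal. The exchangeability that
does hold — no band is *systematically* favoured — is tested across
independent seeds: over eight pure-noise runs, no band attains the
maximal SP in more than half of them.

# Calibration models

## PLS1 (NIPALS)

X and y are mean-centred, never variance-scaled (reflectance bands share
units). Each component takes the weight vector
$w \propto X_c^\top y_c$, scores $t = X_c w$, loadings
$p = X_c^\top t / t^\top t$, $q = y_c^\top t / t^\top t$, then deflates
both blocks. The $k$-component model collapses to one regression vector
$B_k = W_k (P_k^\top W_k)^{-1} q_{1:k}$ plus intercept, and the full
coefficient path is kept so any component count predicts without
refitting. With as many components as the data's rank, PLS1 reproduces
ordinary least squares — the oracle identity the tests assert at
$10^{-8}$ relative tolerance. Training RMSE is non-increasing in the
component count (also tested). The component count is chosen by minimum
cross-validated RMSE under leave-one-out (each fold fitted once, scored
at all counts).

## LS-SVM

Training solves the $(n+1) \times (n+1)$ KKT system
$\begin{bmatrix} 0 & \mathbf 1^\top \\ \mathbf 1 & K + \gamma^{-1} I
\end{bmatrix} \begin{bmatrix} b \\ \alpha \end{bmatrix} =
\begin{bmatrix} 0 \\ y \end{bmatrix}$
by dense LU with a reciprocal-condition guard; $\sum_k \alpha_k = 0$
follows from the first row and is verified after every fit. The RBF
kernel uses $K(x, z) = \exp(-\|x - z\|^2 / \sigma^2)$ — $\sigma^2$ the
bandwidth, in the denominator with **no factor 2**. The alternative
convention $\exp(-\|x-z\|^2 / 2\sigma^2)$ is common; tuned bandwidths
are not portable across the two, so the convention is stated on the
model object's documentation.

Hyperparameters are tuned by exhaustive grid search under leave-one-out
CV over $\gamma \in 10^{0..9}$ (13 log-spaced points) and $\sigma^2 \in
10^{-2..6}$ (17 points); the linear kernel has no bandwidth and ignores
the $\sigma^2$ grid. Ties break to the smallest $\gamma$, then smallest
$\sigma^2$. The LOO residuals come from the closed-form identity
$e_i^{(-i)} = \alpha_i / (A^{-1})_{ii}$ (one factorization per grid
point instead of $n$ refits); the identity is verified against literal
refitting in the test suite. The generic `loo_cv()` operation, by
contrast, performs the literal $n$ fits its contract promises. Very
large $\gamma$ with many training samples can drive full-band LS-SVM fits
to near-zero training error — an overfitting symptom, not a virtue; the
prediction-set metrics are what matter.

# Chemical imaging

Mapping unfolds the cube to a pixels × bands matrix (row-major pixel
order, pixel (1,1) first), restricts columns to the model's wavelengths
by nearest-band lookup (erroring if the nearest band is more than half a
grid step away), predicts the foreground pixels, and folds back to an
image. Background pixels carry `NA` — never a fake 0 °Brix. Two
different mapping diagrams are sometimes drawn for linear and kernel
models; both reduce to this same unfold–predict–fold contract, so one
implementation serves both.

For any *linear* model the footprint mean of the per-pixel map equals
the model applied to the footprint's mean spectrum — the algebraic
bridge between sample-level calibration and pixel-level maps, asserted
at $10^{-8}$. Median denoising is applied per band image *before*
prediction (whether denoising historically preceded prediction or was
applied to the final map is ambiguous; the per-band option is the
default and both are reachable — run the filter on `map$values` for the
other order). Saturated pixels are defined as raw counts at sensor
full-scale in any model wavelength; they remain visible in the image but
are excluded from all statistics. Pseudo-colour rendering interpolates a
documented blue→red ramp linearly between user-chosen °Brix endpoints
(no specific published ramp exists to match); background renders neutral
gray and the endpoints/ramp are attached as colour-bar metadata.

The bundled published model (`inst/extdata/eq12.json`) is a 23-term
multilinear equation: intercept 16.207 °Brix plus signed coefficients on
the reflectance at 960, 929, 814, 849, 432, 500, 877, 995, 903, 915,
831, 956, 967, 954, 923, 511, 454, 840, 835, 527, 509, 850 and 883 nm,
in that fixed order. It was fitted to spectra that are not publicly
deposited, so applying it to this package's synthetic cubes gives
structurally sensible but numerically meaningless maps; it is shipped as
a worked, testable artifact (its zero-input, single-coefficient and
all-ones probes are pinned in the tests) and as a template for
serializing models fitted here.

# The pipeline and reproducibility

`run_pipeline()` derives one seed per stage from a master seed (via a
seeded draw, so stage seeds stay independent and below $2^{31}$),
executes generate → preprocess → partition → frog → fit → map, and
writes every artifact plus a manifest (package version, R version,
seeds, full config) to the run directory. Identical config + seed
reproduce all numeric artifacts byte for byte. The metrics table has one
row per model × band set — model family, wavelength count, latent
variables or $(\gamma, \sigma^2)$, then R/RMSE for calibration,
cross-validation and prediction — the standard layout for side-by-side
model comparison.

# Problem sizes and runtime choices

The packaged tests and the acceptance script run at sizes chosen to keep
a complete check of every stage within a few minutes on one CPU: 310
samples × 456 bands for the full parameter-recovery path (the canonical
study scale), Random Frog at $T = 500$ with 10 planted bands among 460
over 10 seeds for the power check, $T \le 300$ elsewhere, and captures
of six blobs in 96 × 96 scenes. Production-scale selection
($T = 10{,}000$) is a configuration change, not a code path change.

# Known limitations

- The generator's fruit are spectrally homogeneous discs; no
  within-fruit TSS gradients, shading or specular geometry beyond the
  scalar scatter factor.
- PLS1 supports a single response; multi-response PLS2 is out of scope.
- The Random Frog candidate scheme is one reasonable reconstruction of a
  loosely specified algorithm; rankings are stable on clear signals but
  exact SP values depend on these choices (and on $T$).
- ENVI I/O covers BIL/BSQ float cubes with a `wavelength` header list —
  the common case for reflectance work — not the full ENVI type zoo.
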