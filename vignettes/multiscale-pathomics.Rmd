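---
title: "Multi-scale wavelet pathomics: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale wavelet pathomics: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pathowave` quantifies tissue texture at multiple spatial scales and asks
how the scale representation — the mother wavelet and the decomposition
level — affects the discrimination of histology tile classes. This
vignette records the model as implemented, every convention the
implementation had to fix where a convention was genuinely open, and what
the bundled synthetic study set can and cannot demonstrate.

## The decomposition model

A tile is an 8-bit single-channel intensity matrix. The wavelet-packet
engine applies the separable low-pass analysis step of a discrete mother
wavelet along rows and columns and keeps every second sample, recursively
`level` times; only the repeated low-low ("approximation") packet node is
retained. Boundary handling is symmetric half-point extension
(`... x2 x1 | x1 x2 ... xn | xn xn-1 ...`), under which a side of length
$n$ becomes $\lfloor (n + m - 1)/2 \rfloor$ for filter length $m$. This
extension was chosen because it yields exactly the size ladder
75/38/19/10/5/3 for a 150-px tile under a length-2 filter, the geometry the
rest of the pipeline is calibrated to. The transform is linear and
deterministic; for the Haar filter on dyadic sides it reduces to scaled
block sums, which the tests exploit as an independent oracle.

Filter coefficients for the six discrete families (haar; db1–db20;
sym2–sym20; coif1–coif17; all 15 bior and 15 rbio pairs — 87 wavelets)
ship as a plain-text table and are validated in the tests by the
quadrature-mirror conditions (coefficients sum to $\sqrt 2$, unit norm
and shift-orthogonality for the orthogonal families). Daubechies filters
above order 20 are longer than a level-2 approximation of a 150-px tile
is wide and are deliberately not rostered. Continuous families (Morlet,
Mexican hat, Gaussian, Shannon, ...) have no finite filter bank and are
excluded by construction. A feasibility guard
(`max_feasible_level()`) refuses decompositions whose current side is
shorter than the filter or whose output would drop below 2 samples.

## The 532-feature signature

The feature ledger (`default_ledger()`) fixes, per tile and wavelet
setting, 26 derived maps and the descriptor applied to each:

* **First-order statistics** (max, min, mean, population SD) on 25 maps:
  the approximation at full floating precision, the 20 Gabor magnitude
  maps of the quantised approximation, the 3 LBP maps, and the pixelwise
  mean of the 20 Gabor maps ("Gabor aggregate") — $25 \times 4 = 100$
  features.
* **GLCM statistics** — contrast, dissimilarity, homogeneity,
  correlation, angular second moment, energy $= \sqrt{\mathrm{ASM}}$ — at
  4 angles $\times$ 3 distances on 6 quantised maps: the approximation,
  the 3 LBP maps, the Gabor aggregate, and the aggregate of a
  rotation-angle Gabor bank applied to the *original* undecomposed tile —
  $6 \times 72 = 432$ features.

The total, 532, is a structural contract: the acceptance tests assert it
for every rostered wavelet at levels 1–2. The composition itself is this
package's reconstruction: it uses exactly the descriptor counts above (20 Gabor
kernels; 3 LBP variants; 6 co-occurrence statistics at 4 angles and 3
distances) and the multi-level map combinations, and totals exactly 532;
the ledger is the single place where the composition is pinned down.

### Descriptor parameters

* **Gabor.** Even/odd kernels
  $K e^{-(i^2+j^2)/2\sigma^2} \cos / \sin\!\big(2\pi f (i\cos\theta + j\sin\theta)\big)$.
  The bank uses five equally spaced orientations
  $\{0^\circ, 36^\circ, 72^\circ, 108^\circ, 144^\circ\}$ and four
  equally spaced wavelengths $\{4, 28/3, 44/3, 20\}$ px/cycle
  ($f = 1/\lambda$), spanning the 4–20 px/cycle range at five evenly
  spaced directions. The rotation bank on the original tile uses
  $\{70^\circ, 100^\circ, 130^\circ, 160^\circ, 190^\circ\}$, five even
  steps across 70°–190°. The envelope width $\sigma = 0.56\,\lambda$
  (≈ one-octave bandwidth), $K = 1$, kernel half-width
  $\lceil 3\sigma \rceil$: these are this package's conventions, chosen
  once and fixed. Responses are same-size
  convolutions with reflective padding; magnitude
  $\sqrt{\text{even}^2 + \text{odd}^2}$.
* **LBP.** $P = 8$ neighbors at radius $R = 1$, bilinear interpolation of
  the diagonal neighbors, code $\sum_p s(i_p - i_c)\,2^p$ with
  $s(x) = 1$ for $x \ge 0$. The three variants: gray-scale/rotation-invariant → minimum over circular bit
  rotations; variance of local texture → population variance of the
  interpolated ring; uniform patterns with finer angular set points →
  non-rotation-invariant uniform codes (59 bins at $P = 8$).
* **GLCM.** 256 gray levels on 8-bit input, angles
  $\{0^\circ, 45^\circ, 90^\circ, 135^\circ\}$, distances
  $\{1, 3, 5\}$ px (angles span 0°–135° and distances span 1–5 px; the
  interior distance value 3 is this package's choice). Matrices are symmetrised and normalised to
  sum 1.

### Quantisation and degeneracy conventions

Descriptors that need 8-bit input (LBP, GLCM) receive maps min–max
rescaled to 0–255 with half-up rounding. Three conventions keep the
532-vector finite everywhere, including 3×3 level-6 approximations:

* a map whose range is below $10^{-8}$ of its magnitude is treated as
  constant and rescaled to all zeros — otherwise FFT rounding noise on a
  flat map would be amplified to full 8-bit scale;
* a GLCM whose offset does not fit inside the map is flagged empty and
  contributes six zeros (features are zeroed, never dropped, so the
  vector length is level-invariant);
* GLCM correlation is 1 when a marginal variance is zero (a perfectly
  predictable image), and interpolated LBP neighbor intensities are
  rounded to $10^{-6}$ so exact ties with the centre pixel are not broken
  by floating rounding of the bilinear weights.

Convolutions are computed by FFT on a 5-smooth padded size with a
reflected margin wide enough for the kernel support, so circular
wrap-around never reaches the retained window; the tests verify
equivalence with direct sliding-window sums to $10^{-9}$.

## Feature selection

One-way ANOVA per feature across the classes of the held-out validation
rows only: $F = \mathrm{MS}_{\text{between}} / \mathrm{MS}_{\text{within}}$,
with the dual criterion $p < \alpha$ **and** $F > F_{\text{crit}}$, where
$F_{\text{crit}}$ is the $1 - \alpha$ quantile (percent point function)
of $F(k - 1, N - k)$ and $\alpha = 0.05$. The mask is then applied
unchanged to training and testing rows, which remain unseen by the
selection. Conventions: a feature constant everywhere gets $F = 0$,
$p = 1$ (never selected, rather than an error, so batch selection always
completes); zero within-class variance with differing means gets
$F = \infty$, $p = 0$ (always selected). Features are not standardised
before ANOVA — the statistic is scale-invariant per feature — and no
multiple-testing correction is applied: the dual criterion is itself the
selection rule.

## Classifiers

Both model families standardise features to z-scores using training-row
statistics only (constant features pass through as zeros).

* **SVM**: one-vs-one multiclass RBF SVM via `e1071`. Defaults — fixed here for reproducibility — are $C = 1$ and
  $\gamma = 1 / (p \cdot \mathrm{var}(X))$ on the standardised training
  matrix.
* **ANN**: 532 inputs → 1 or 2 sigmoid hidden layers (canonical width
  grid {64, 128, 256, 512, 1024, 2048}) → softmax over the classes,
  cross-entropy loss, Adam (learning rate $10^{-3}$, batch 32), inverted
  dropout 0.2 on hidden activations, at most 500 epochs with patience 25
  on the validation loss; the weights of the best validation epoch are
  kept. The optimiser, learning rate, dropout rate and batch size are
  this package's choices. The network
  is implemented in the package (plain matrix arithmetic) and is
  seed-reproducible.

## Evaluation protocol

`make_splits()` reserves `round(0.1 n)` rows by largest-remainder
per-class apportionment (500 of 5000 is not divisible by 8, so "class
balance preserved" is interpreted as within ±1 of exact proportionality —
the best achievable), then deals the remainder into 10 stratified folds
with a rotating assignment of per-class remainders so fold totals are
exactly balanced (450/4050 per fold on the 5000-tile geometry). Accuracy
is the fraction of correct predictions on each unseen fold, reported as
fold-mean ± SD across folds, not as pooled predictions. The validation split serves feature selection
(`svm_selected`) or early stopping (`ann_full`) and is never tested on.
`run_sweep()` walks the wavelet × level × strategy grid, extracting
features once per (wavelet, level), skipping infeasible pairs with a
message, and rewriting its output CSV after every row so partial results
survive interruption. `summarize_sweep()` bins model accuracies per
family or per level into shares per accuracy band plus group means.

## The synthetic study set

The generator emulates the *shape* of the public colorectal collection —
8 balanced classes, 625 tiles each by default, 150×150 px, 8-bit — with
eight parametric texture families chosen so that the classes differ in
characteristic scale and orientation (the axes this pipeline probes):
flat noise; a 2-px checkerboard; gratings of wavelength 12 px at 0° and
6 px at 45°; smoothed-noise blob fields of correlation length ≈3 px and
≈10 px; salt-and-pepper speckle; and a grating-plus-blob superposition.
Per-tile phase, offsets and noise come from a stream seeded by
(seed, class, tile index), so datasets are bit-reproducible and
independent of generation order.

What it does **not** emulate: H&E stain colour and its variability,
cell-level morphology, within-class heterogeneity of real tissue, or
label noise. Passing the end-to-end checks therefore demonstrates that
the pipeline's machinery — decomposition, descriptors, selection,
training, stratification — is correct and discriminative on textures
with known scale structure; it does not certify any particular accuracy
on real histology. Benchmark accuracies reported in the literature for
real tile collections are correspondingly *not* asserted anywhere;
approaching them requires the real tiles (supported via `read_tile_folder()`).

### Problem sizes used by the tests and the acceptance script

Test-time and acceptance runs use a reduced study set of 40 tiles per
class (320 tiles) at full 150-px tile size, 10% hold-out and 10 folds,
with the ANN at width 64 — the smallest member of the canonical grid.
These sizes were chosen as the smallest at which every protocol element
(stratification granularity, selection degrees of freedom
$df_2 = N_{\text{val}} - 8$, per-fold class balance) still operates
non-trivially; descriptor-level checks run on small random images
against brute-force oracles. The acceptance script reports, among other
quantities, the three strategies' 10-fold accuracies on this set, a
label-permutation null for the network (which should sit in the binomial
3σ band around chance, 1/8), and the level-6 vs level-1 comparison
(deep approximations of 3×3 px are expected to discriminate worse than
level 1, mirroring the scale-degradation effect).

## Known limitations

* The 532-feature composition is a constrained reconstruction (see
  above); other compositions matching the same descriptor counts exist.
* Grayscale conversion of RGB tiles uses ITU-R 601 luminance — a
  convention of this package, not a property of any tile collection.
* The wavelet roster (87 wavelets) deliberately omits db21–db38; counts
  of "all variations" therefore differ from rosters of other libraries.
* The SVM's `svm_selected` path requires at least 2 validation rows per
  class beyond the class count ($df_2 \ge 1$); very small validation
  splits are rejected rather than silently degraded.
* GLCMs are dense 256×256 matrices; extraction cost is dominated by the
  72 co-occurrence computations per tile (about a quarter of a second
  per tile on one CPU core, as reported by the acceptance script).
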