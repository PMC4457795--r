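---
title: "Gray-voting and Gaussian-mixture vessel segmentation: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-voting and Gaussian-mixture vessel segmentation: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `retivote`, the parameters that
matter, the synthetic phantom the tests rely on, and the design decisions
taken where the method's published description leaves room — in the spirit of
a methods section, not a tutorial.

## The segmentation model

The pipeline is unsupervised and works on the green channel of an RGB fundus
photograph, the channel with the best vessel/background contrast. Vessels
are darker than the background there; internally every enhancement stage
sees the *inverted* green channel (vessels bright), for reasons discussed
under *Fusion polarity* below.

### Orientation-maximum Gabor wavelet

The analysing wavelet is an anisotropic complex Gabor function
\[
\psi(\mathbf{x}) = \exp(i\,\mathbf{k}_0\!\cdot\!\mathbf{u})\,
                   \exp(-\tfrac12 |A\mathbf{u}|^2),
\qquad \mathbf{u} = a^{-1} r_{-\theta}\mathbf{x},
\quad A = \mathrm{diag}(\varepsilon^{-1/2}, 1),
\]
correlated densely with the image via FFT. The anisotropy
\(\varepsilon = 4\) elongates the envelope along the rotated first axis
while the modulation \(\mathbf{k}_0 = (0, 3)\) oscillates across it, so the
modulus responds to ridge-like structures aligned with the elongated axis.
The scale is fixed at \(a = 3\) (pixels), the value at which vessels of the
typical DRIVE calibre respond best. Taking the per-pixel maximum modulus
over \(\theta \in \{0, 10, \dots, 170\}\) degrees makes the response
orientation-free. \(\varepsilon\) and \(\mathbf{k}_0\) are not dictated by
the method itself; the defaults follow the established supervised Gabor
parameterisation for this problem and are exposed in the configuration.

Numerical choices: the kernel is sampled on an odd grid whose half-width is
\(a\sqrt{\varepsilon}\sqrt{2\ln 10^5}\), so the envelope falls below
\(10^{-5}\) at the border. The image is reflect-padded by that half-width
(suppressing wrap-around) and then zero-padded to the next 5-smooth FFT
length; the cropped centre equals direct spatial correlation exactly, which
the test suite verifies to \(10^{-8}\) relative error. The continuous
transform's normalising constant is folded into a final rescaling of the
orientation maximum to \([0,1]\) by its in-FOV maximum, since only relative
magnitudes feed the downstream fusion.

### Gray-voting

For each pixel, within its \(m \times m\) window (\(m = 11\)), with window
extremes \(M_{\max}, M_{\min}\) (centre included):
\[
L = \frac{M_{\max}}{m^2-1},\qquad
N = -\frac{M_{\min}}{m^2-1}\ \text{(main pass)}\quad\text{or}\quad
    -\frac{M_{\max}}{m^2-1}\ \text{(complement pass)},
\]
\(\mathit{Num}_1\) counts neighbours \(\ge \mathit{Center} - k\),
\(\mathit{Num}_2\) the remaining \(m^2-1-\mathit{Num}_1\), and
\(P_{vote} = \mathit{Num}_1 L + \mathit{Num}_2 N\). The gray transition
scale \(k\) is quoted on the 0–255 scale (3 for the main pass, −5 for the
complement pass) and divided by 255 internally. A constant image is a fixed
point for \(k > 0\). Because `Comparison = Center − k`, *raising* \(k\)
admits more neighbours into \(\mathit{Num}_1\) and drives the response
pointwise toward \(M_{\max}\): structures appear as *dips*, and fewer pixels
fall below any threshold as \(k\) grows — the formal counterpart of "larger
\(k\), less detected noise".

Window borders are reflect-padded. In FOV-restricted mode, out-of-FOV
neighbours are excluded from both the counts and the window extremes, and
\(L, N\) are renormalised by the actual neighbour count; isolated in-FOV
pixels return 0.

### Fusion polarity

The fusion rule is the product \(I_{gv} = I_{Gabor}\,(1 - I_{vessel})\).
On a *dark-vessel* input the main gray-vote pass assigns vessels the local
maximum (every neighbour exceeds `Center − k` when the centre is the darkest
pixel of its window), so \(1 - I_{vessel}\) would *suppress* vessels and
boost the non-vessel halo — we measured exactly that during development
(fused images separated vessel from halo worse than the Gabor response
alone). The combination is internally consistent only when the vote runs on
the same bright-vessel working image as the Gabor stage: vessels are then
penalised in \(P_{vote}\), and the complement \(1 - I_{vessel}\)
re-brightens them in the product. `retivote` therefore runs *both*
enhancement stages on the inverted green channel (`invertGreen = TRUE`,
exposed). The vote response is min–max rescaled to \([0,1]\) over the FOV
before fusion, which the product requires to be meaningful.

### Mixture clustering

In-FOV fused intensities are modelled as a K-component univariate Gaussian
mixture \(p(x) = \sum_i \omega_i\, \mathcal{N}(x;\mu_i,\sigma_i^2)\),
initialised by kmeans++-seeded Lloyd iterations (per-cluster means, ML
variances and relative sizes) and fitted by standard EM until the relative
log-likelihood change drops below `tol = 1e-6` or 500 iterations. Variances
are floored at \(10^{-6}\) (with a warning) to survive the quantised,
sometimes constant-valued backgrounds of noise-free images. K = 4 follows
the four-layer decomposition of the fused image into two background layers,
a faint-structure layer and a vessel layer; K is configurable.

Hard assignment uses posterior (weight-aware) probabilities by default;
`weighted = FALSE` reproduces the unweighted comparison of plain component
densities. Ties break toward the lower index, so the layers always
partition the data.

**Vessel-layer selection.** The published description does not state how the
vessel cluster is chosen. On real fundus images one might expect the
brightest fused cluster to be dominated by the optic-disc rim, making the
second-brightest the vessel layer. On the phantom (and, we argue, whenever
the multiplicative vote factor suppresses the disc rim, which it does by
construction — the rim is a strong *edge*, not a ridge, and its
neighbourhood votes against it), the brightest layer *is* the vessel layer:
selecting the second-brightest yielded masks dominated by the Gabor skirt
with Jaccard overlap an order of magnitude below the brightest-layer choice.
The default is therefore `vesselRule = "highest"`, with
`"second_highest"` and `"index:i"` available for images where the disc or
bright lesions dominate the top cluster.

### Complementation

A second gray-vote (\(k = -5\), both weights from \(M_{\max}\)) runs on the
*dark-vessel rendering* of the fused image (\(1 - I_{gv}\)): with a negative
\(k\) the comparison sits *above* the centre, so flat background (where no
neighbour clears `Center + |k|`) is driven to \(-M_{\max}\) while vessel
pixels — surrounded by brighter background — rise toward \(+M_{\max}\).
This matches the reported behaviour that more negative \(k\) yields more
small-vessel fragments. Binarisation keeps strictly positive responses
(`binarize = "zero"`, i.e. the natural decision boundary of the voting
operator: a window majority brighter by \(|k|\)). An Otsu alternative is
exposed but measured poorly here: on the phantom it kept roughly 40% of the
FOV, which percolates into one giant 8-connected component, leaving no
fragment small enough to adopt — the complementation stage then never
fires.

Adoption follows the marker/complement pseudocode: every marker component
with at most `tSeed = 30` pixels looks up the complement component under its
first pixel (column-major scan order, the `find` convention of the
pseudocode's original environment) and, if that component has at most
`tFragment = 100` pixels, unions it into the output. Seeds landing on
complement background are skipped; one fragment may be adopted by several
seeds (idempotent union). The output is always a superset of the marker.

### Fragment elimination

Components with fewer than 14000 pixels *and* squareness rate
\(S = 100F/(1+mx^2) > 0.2\) are removed. `mx` is interpreted as the larger
bounding-box extent (position-independent; the alternative reading — the
absolute maximum coordinate — would make shape scoring depend on where the
fragment sits, and is available as `mxMode = "coordinate"`). As defined,
the constants are aggressive: any component smaller than 14000 px survives
only if its extent exceeds ~500 px, so in practice the stage keeps the main
connected vascular network and removes every unlinked small blob, noise or
vessel alike. This makes the *adoption* stage load-bearing: a recovered
small-vessel fragment survives only when it bridges into the main network
(the published account indeed describes the fragments as *linking* broken
vessels). The constants are exposed in the configuration.

### Evaluation

Pixel confusion counts restricted to the FOV; sensitivity
\(TP/(TP+FN)\), specificity \(TN/(TN+FP)\), accuracy \((TP+TN)/total\). The
TN-only accuracy numerator that appears in some accounts of this method family would score
a perfect segmentation below 1 and is inconsistent with published result
tables; it is available as `accuracyAsPrinted = TRUE` for literal
comparison. Overlays colour TP green, FP blue, FN red over a grayscale
background, and their class counts equal the confusion counts exactly.

## The synthetic phantom

The generator emulates the features of DRIVE/STARE-style fundus photographs
that this pipeline actually exercises:

- branching vessel trees rooted at the optic-disc rim, darker than the
  background, with widths tapering from ~6 px (main arcades; square-root
  taper so proximal segments keep their calibre) to 1 px at the tips;
- thin vessels are *fainter*: stamp amplitude scales from 100% of the
  nominal contrast at main width down to 40% at 1 px;
- visibility varies smoothly along each vessel (AR(1) process, correlation
  length ≈ 50 px, floor 0.08, attenuated for wide vessels), reproducing the
  broken-small-vessel appearance that motivates the complementation stage;
- a textured background: broad illumination bumps plus band-limited granular
  texture (Gaussian white noise blurred at σ = 3 px, amplitude 0.012) — the
  choroidal mottling visible in real green channels even at negligible
  sensor noise;
- a bright optic disc, a darker fovea, a circular FOV, additive Gaussian
  sensor noise (σ = 0.01 by default), and 8-bit quantisation so files
  round-trip exactly.

Ground truth marks pixels whose intensity dip exceeds half its local
amplitude (i.e. within half the local FWHM of a centreline), and a width map
records the nominal width there, so small-vessel (≤ 2 px) sensitivity can be
scored separately. Default tree count and branching probability were chosen
so the in-FOV vessel fraction falls in the 10–15% range reported for manual
segmentations of real images.

What the phantom does **not** emulate: pathology (exudates, haemorrhages),
colour constancy problems, compression artefacts, inter-image illumination
variation, and the full width spectrum of real vasculature. Passing the
end-to-end tests therefore demonstrates that the pipeline's stages interact
as designed on fundus-like geometry — not clinical-grade performance on real
data, which requires the DRIVE/STARE archives.

Problem sizes used by the test-suite: unit tests run on 192×192 phantoms and
32–64 px images; the end-to-end regression and the acceptance script use the
full 584×565 size.

## Degenerate inputs and tie-breaks

- Constant images: Otsu binarisation warns and returns all-FALSE; the
  gray-vote returns the constant itself (k > 0).
- Mixture fitting requires at least K distinct values; component collapse is
  handled by the variance floor.
- Equal posterior ties in assignment go to the lower component index.
- Seeds on complement background are skipped (adopting the background label
  would flood the image).
- An even gray-vote window, mismatched shapes, or a kernel larger than the
  image are rejected with informative errors.

## Known limitations

- The method is unsupervised and intensity-based; it cannot use the
  vessel-profile priors a trained classifier would.
- The elimination constants, taken verbatim from the method, remove all unlinked small components
  (see above); sensitivity to genuinely isolated small vessels therefore
  rests entirely on the adoption stage bridging them into the network.
- Those constants also presuppose full-size (DRIVE/STARE-scale) images: on
  rasters much smaller than ~500 px the entire vascular network falls below
  the 14000-px size cut and is eliminated, leaving an empty final mask.
  Lower `post.sizeCut` accordingly when segmenting crops or thumbnails.
- Pixel metrics do not reflect topology: a mask thinner than the gold
  standard everywhere scores poorly even if the vascular tree is complete.
- GIF input is unsupported (no reader in the dependency set); DICOM is out
  of scope.
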