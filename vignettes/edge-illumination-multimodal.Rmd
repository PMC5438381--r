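---
title: "Asymmetric edge-illumination XPCI: model, retrieval and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetric edge-illumination XPCI: model, retrieval and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eixpci)
```

## The imaging model

Edge illumination (EI) is an x-ray phase-contrast technique in which a
pre-sample mask (M1) splits the beam into fan-shaped beamlets, each paired
with an aperture of a detector mask (M2) in front of one detector column.
Scanning M1 laterally traces out the **illumination curve** (IC): a
bell-shaped response $R(\varphi)$ of detected intensity versus mask
displacement, maximal when the apertures are aligned. An object placed
between the masks acts on the IC in three ways:

* **attenuation** scales it by the transmission $I_R \in (0, 1]$;
* **refraction** shifts it by the refraction angle $\Delta\varphi_R$
  (differential phase contrast, DPC);
* **sub-pixel scattering** broadens it; the broadening is parametrized by
  the variance $\sigma^2_{\Delta\varphi_S}$ of a stochastic scattering
  angle (dark field, DF).

In the *asymmetric* EI configuration the M1 apertures are grouped in
repeating blocks of four, each block member laterally shifted by
$\{-s, 0, s, 2s\}$ (with $s = 10\,\mu$m in the modelled system). Each
detector column therefore works at a fixed, known point of the IC, and a
single lateral scan of the object — no optics motion — yields four full
object images $I_1 \ldots I_4$ at four IC points. To second order around
the working point $\bar\varphi_j$,

$$ I_j \;=\; I_R\!\left[ R_j + \dot R_j\, \Delta\varphi_R +
   \tfrac12 \ddot R_j\,\Delta\varphi_R^2 +
   \tfrac12 \ddot R_j\, \sigma^2_{\Delta\varphi_S} \right],
   \qquad j \in [1,4], $$

where $R_j,\dot R_j,\ddot R_j$ are the IC value and derivatives at
$\bar\varphi_j$. This expansion is the forward model of the simulator
(`expected_intensity()`) and the system inverted by the retrieval.

With pair-symmetric sampling ($\bar\varphi_1 = -\bar\varphi_4$,
$\bar\varphi_2 = -\bar\varphi_3$, hence $R_4 = R_1$, $\dot R_4 = -\dot
R_1$, etc.) and the outer pair at 50% of the IC maximum, the system admits
the closed-form solution implemented in `retrieve_multimodal()`:

$$ I_R = \frac{1}{2}\,\frac{I_1+I_2+I_3+I_4}{R_1+R_2}, \qquad
   \Delta\varphi_R = \frac{(I_1+I_2)-(I_3+I_4)}{I_1+I_2+I_3+I_4}\,
   \frac{R_1+R_2}{\dot R_1+\dot R_2}, $$

$$ \sigma^2_{\Delta\varphi_S} =
   2\,\frac{R_1 (I_2+I_3) - R_2 (I_1+I_4)}{\ddot R_2\,(I_1+I_4)}
   - \Delta\varphi_R^2 . $$

The third formula uses only the *inner*-point curvature $\ddot R_2$ and
the pairings exactly as printed in the source method; no re-symmetrization
is applied.

## The illumination-curve model and its parameters

The functional form of the IC is not prescribed by the method, only its
bell shape and symmetry. The package models it parametrically
(`make_ic()`):

| parameter | units | default | rationale |
|---|---|---|---|
| `peak_amplitude` | — | 0.9 | fraction of the aligned-aperture flux reaching the detector; < 1 for realistic aperture/septa losses |
| `width` | µm (M1 plane) | $15/\sqrt{2\ln 2} \approx 12.74$ | chosen so the outer sampling pair at ±15 µm sits exactly at 50% of the IC maximum (see below) |
| `baseline` | — | 0.01 | pedestal from transmission through the thick gold septa; close-to-zero minima are a design goal of such masks at high energy |
| `center` | µm | 0 | IC maximum position; offsets are always taken relative to it |
| `shape` | — | `"gaussian"` | standard laboratory-source approximation: smooth, symmetric, analytically differentiable |

Two shapes are provided behind the same evaluation contract
(`ic_eval()` returns $R, \dot R, \ddot R$ analytically; tests verify the
derivatives against central finite differences to $10^{-6}$ relative):

* **Gaussian on a pedestal** (default): $R = b + (p-b)
  e^{-u^2/2w^2}$.
* **Raised cosine** (`"cos2"`): $R = b + (p-b)\cos^2(\pi u / 2U)$ on
  $|u| < U$, with $U = 2\sqrt{2\ln 2}\,w$ so the FWHM matches the
  Gaussian of equal `width`. Its inflection sits exactly at half maximum,
  i.e. the flanks are curvature-free where the outer points sample them —
  the regime the closed-form retrieval implicitly assumes.

Focal-spot blurring is folded into the effective IC width rather than
modelled by explicit source convolution: the retrieval only ever sees the
local value and derivatives of the IC, so a wider effective curve captures
everything the algorithm can respond to.

### Sampling-point placement

The printed subgroup shifts $\{-s, 0, s, 2s\}$ are not symmetric about
zero, while the acquisition is described as symmetric ("two on one side
and two on the other") with the outer images at ±50% of the IC. The only
placement consistent with both facts is a rigid alignment offset of
$-s/2$ (equivalently, an IC center at $+s/2$), giving offsets
$\{\pm s/2, \pm 3s/2\} = \{\pm 5, \pm 15\}\,\mu$m
(`scheme_from_shifts()`), with the IC width then fixed so that ±15 µm is
the half-maximum point. The position of the *inner* pair on the IC is not
stated anywhere; `place_half_max_scheme()` therefore exposes it as
`inner_fraction` (inner offset as a fraction of the outer offset), with
default 1/3 — the value implied by the printed shift pattern.

### Exactness of the closed form, and a deliberate red test

The closed form is not an exact inverse of the second-order forward
model. Writing $q = \Delta\varphi_R^2 + \sigma^2$, the pair sums are
$I_1+I_4 = I_R(2R_1 + \ddot R_1 q)$ and $I_2+I_3 = I_R(2R_2 + \ddot R_2
q)$; eliminating $I_R$ exactly gives
$q = 2(R_2 - r R_1)/(r\ddot R_1 - \ddot R_2)$ with $r =
(I_2+I_3)/(I_1+I_4)$, whereas the printed formula is this expression with
$\ddot R_1 \equiv 0$. Consequently, in the small-signal limit the
retrieved dark field carries a constant multiplicative bias

$$ \frac{\hat\sigma^2}{\sigma^2} \;\to\; 1 -
   \frac{R_2 \ddot R_1}{R_1 \ddot R_2}, $$

which equals **1.452** for the default Gaussian scheme (the 50% point of
a Gaussian is *not* its inflection), and exactly **1** for the
raised-cosine IC. Both predictions are verified by tests against the
package's independent least-squares inversion
(`retrieve_multimodal_ls()`, which solves the forward model — linear in
$(I_R,\ I_R\Delta\varphi,\ I_R q)$ — exactly). The absorption and DPC
channels are exact at $q = 0$ and carry relative errors of order
$q\,\ddot R/R \sim 10^{-3}$–$10^{-2}$ over $|\Delta\varphi_R| \le 0.1\,w$.

For this reason one acceptance test (closed form vs numerical inversion
agreeing to $10^{-3}$ on all channels over that input range) is
**knowingly red**: the requested tolerance is unattainable for any smooth
IC with this closed form, and the package asserts it as stated rather
than weakening it. The sharp, correct statements — exact LS inversion,
the 1.452 Gaussian DF bias, bias-free DF on the flank-linear IC, and
error orders under signal scaling — are all asserted green elsewhere in
the suite. In practice the multiplicative DF bias is benign (dark field
is routinely interpreted on a relative scale), but quantitative DF work
should either calibrate it out or use the least-squares mode.

## What the synthetic generator emulates — and what it does not

`simulate_scan()` emulates: the column-to-IC-point assignment of the
asymmetric mask (repeating 1–4 pattern, 128 columns → 32 columns per
subgroup); the object translation at one scan step per frame with vacuum
padding outside the field of view; Poisson counting statistics at a
configurable flux; and flat stacks recorded before and after the scan
with independent noise. Each beamlet samples the phantom at a single x
position (delta-aperture model) — the forward model is pointwise, so
aperture-width integration is a separable blur that can be applied to the
phantom if desired. Phantoms are projections of simple solids with
additive $\delta t$, $\beta t$ and scatter$\cdot t$ maps; refraction is
the central finite difference of $\delta t$ along x.

Not modelled: polychromatic spectra and beam hardening; source-size ray
tracing (folded into the IC width); mask-panel stitching and blind areas;
detector charge sharing and dual-energy thresholds; gain drift (flats
differ only by noise); explicit sub-pixel speckle (scattering enters only
through the variance term, i.e. Gaussian scattering). A green
full-pipeline test therefore establishes the *algorithmic* chain —
normalization conventions, subgroup bookkeeping, unit conversions,
inversion formulas, noise propagation — on data that satisfy the forward
model by construction; it does not establish robustness to the
instrumental effects listed above.

The acquisition defaults mirror the modelled system: 32 Hz frame rate,
128 columns, flux $10^4$ photons/column/frame, 100-frame flat stacks.
The published speed/rate pair (2.5 mm/s at 32 Hz) gives an exact scan
step of 78.125 µm while the effective pixel is quoted as 75 µm; the
package keeps `scan_step()` as the exact quotient, and the simulator's
default grid uses the 75 µm effective pixel (= the demagnified detector
pitch, keeping column offsets commensurate with the scan grid, i.e.
default speed 2.4 mm/s).

## Numerical choices

* **Half-maximum root finding**: bisection (`uniroot`, tolerance
  $10^{-13} w$) followed by three Newton steps, so the outer points hit
  the 50% level to well below the $10^{-9}$ contract.
* **Degenerate inputs**: `inner_fraction` ∈ {0, 1} rejected (coincident
  points); all-equal subgroup shifts rejected (no asymmetry);
  non-pair-symmetric placements rejected at construction, because every
  retrieval identity assumes the symmetry.
* **Missing values**: dead flat columns and zero-denominator pixels
  ($\sum_j I_j = 0$ or $I_1 + I_4 = 0$) propagate as `NA` with a count
  (`n_bad`), never as silent zeros; dark-field values are reported
  unclipped (negative under noise) so downstream statistics stay
  unbiased.
* **Subgroup assembly**: exact integer shifts when column offsets are
  commensurate with the scan step; linear interpolation between adjacent
  frames only on explicit request (`interpolate = TRUE`), otherwise an
  error.
* **Gradient edges**: refraction maps use one-sided differences at the
  first/last column.
* **Clipping**: forward intensities driven negative (expansion outside
  its validity) clip to zero with a count; single-shot attenuation
  factors clip at a positive floor before the logarithm.
* **RNG**: one top-level seed; every frame (scan, before-flats,
  after-flats) draws from a deterministically derived substream, so
  implementation order cannot change results.

## The single-shot phase map

The ultra-low-dose mode uses only the image of beamlet 1 (on the IC
slope). The algorithm it references is published elsewhere, so this
package documents its own defined variant with the same interface and
contract: for a quasi-homogeneous object with fixed $\delta/\beta$,
linearizing the IC about $\bar\varphi_1$ gives
$m = u - a\,\partial_x u$ with $u = e^{-\mu t}$, $\mu = 2k\beta$ and
$a = (\dot R_1/R_1)\, g\, (\delta/\beta)\, \lambda/4\pi$ ($g$ the
geometry lever arm converting refraction angles to M1 displacement).
This first-order filter is inverted row-wise in Fourier space
($\hat u = \hat m / (1 - i a \kappa)$, mirror-padded), after which the
phase map is $\Phi = \tfrac12 (\delta/\beta) \ln u \le 0$ — only the
ratio $\delta/\beta$ is needed, as in Paganin-type retrieval. Vacuum maps
to zero phase; thickness maps monotonically to phase; a homogeneous wedge
yields a linear ramp (all tested).

## Known limitations

* The closed-form DF bias discussed above (use `"multimodal_ls"` for
  bias-free inversion of simulated data).
* The linearized single-shot variant assumes weak refraction contrast on
  the IC slope; strongly refracting edges violate it.
* Retrieval quality figures quoted anywhere in this package are computed
  on synthetic data satisfying the forward model; no claim is made about
  measured-data performance.
* Frame and channel files are plain-text bundles (TSV + JSON); TIFF/HDF5
  backends would slot behind the same read/write functions where those
  libraries are available.
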