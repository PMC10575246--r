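---
title: "Underwater seabed mosaicking: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Underwater seabed mosaicking: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

uwmosaic builds large-field-of-view photomosaics of shallow seabed imagery
collected by a downward-facing underwater camera. This vignette documents
the science the package implements, the parameters that matter, what the
synthetic-survey generator does and does not emulate, and the design
decisions taken where several reasonable choices existed.

## 1. The image-formation model and its inversion

A pixel observed through water is modelled as

$$ I_c(x) = J_c(x)\,t_c(x) + A_c\,(1 - t_c(x)), \qquad c \in \{R, G, B\}, $$

where $J_c$ is the scene radiance, $A_c$ the background (veiling) light and
$t_c(x) = e^{-\beta_c d(x)}$ the transmission along the viewing path of
length $d(x)$ (Beer–Lambert). Water attenuates red much faster than green
and blue, which is why raw frames show the familiar blue-green cast and why
a restoration that treats the three channels identically fails underwater.

The enhancement stage (`enhance()`) inverts this model per channel:

1. **Dark channel over G and B only** (`underwater_dark_channel()`): the
   dark-channel prior says that haze-free scenes contain near-zero minima in
   small patches; underwater, the red channel is too attenuated to carry
   that signal, so the patch minimum is taken over green and blue.
2. **Background light** (`estimate_background_light()`): per channel, the
   mean of the top 0.1% brightest pixels. This estimator assumes the veiling
   light dominates the brightest pixels — true in turbid water where targets
   have low target-to-background contrast.
3. **Attenuation ratios** (`attenuation_ratios()`): the scattering
   coefficient of seawater is close to linear in wavelength,
   $b(\lambda) \propto -0.00113\,\lambda + 1.62517$, and the background
   light satisfies $A_c \propto b_c / c_c$, giving the attenuation ratios
   $c_G/c_R = (b_G A_R)/(b_R A_G)$ (and analogously for blue) at the
   representative wavelengths 620, 540 and 450 nm. These ratios link the
   per-channel transmissions as power laws:
   $t_G = t_R^{\,c_G/c_R}$, $t_B = t_R^{\,c_B/c_R}$.
4. **Rough transmissions** for G and B from the per-channel dark-channel
   estimate, $t_{0c} = 1 - \omega\,\min_{\Omega}(I_c / A_c)$; **joint red
   transmission** as the mean of the two power-law conversions; **guided
   filtering** of $t_R$ against the luminance to remove patch blockiness;
   re-expansion to all channels; and recovery
   $J_c = (I_c - A_c)/\max(t_c, t_0) + A_c$.

With the true $t$ and $A$, recovery is an exact algebraic inverse (up to
clipping into $[0,1]$); the test suite asserts this to $10^{-9}$ and the
validation script to machine precision.

### Enhancement parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `patch_size` | 15 px | dark-channel patch; the classic window size, large enough to hit a shadow pixel, small enough to track depth changes |
| `omega` | 0.95 | haze retention; keeps a sliver of veil so the result looks natural (1.0 gives the pure estimate) |
| `top_fraction` | 0.001 | fraction of brightest pixels averaged into $A$ |
| `t0` | 0.1 | lower clamp in the recovery division; prevents noise blow-up where the medium is nearly opaque |
| `t_floor` | 0.05 | floor applied to transmissions before power/refinement steps, keeps exponentials and logs stable |
| `guided_radius`, `guided_eps` | 40 px, $10^{-3}$ | guided filter window and regularization, standard refinement practice |
| `a_floor` | $10^{-3}$ | floor on $A_c$ (the recovery divides by it) |

Whether refinement happens on $t_R$ before the power-law expansion or on
each channel after is a genuinely open choice; refining $t_R$ once is the
default (one filter pass instead of three, and the expansion preserves
smoothness), with `refine_before_amend = FALSE` as the alternative.

## 2. Registration

Frames are aligned to the middle frame of the sequence (minimizing
accumulated distortion) with global similarity warps by default — a
downward-looking camera over a near-planar seabed is well approximated by
4 degrees of freedom, and the seam and fusion stages absorb the residual
parallax. Projective warps are available via `registration$warp`.

Feature matching runs on the *enhanced* frames: restoring contrast is what
makes underwater feature matching work at all, and the package's validation
script quantifies the gain in RANSAC inliers on degraded synthetic pairs.
The detector is a Harris corner detector with sub-pixel (quadratic)
localization and an *absolute* cornerness threshold ($3\times10^{-7}$), so
its yield genuinely reflects image contrast; a floor of 50 corners keeps
very low-contrast frames registrable. Descriptors are 8×8 patches of
blurred luminance sampled 2 px apart, normalized to zero mean and unit norm
— invariant to the gain/bias compression that attenuation causes, tolerant
of the few degrees of roll a hand-guided sweep produces, and cheap.
Matching uses the 2-NN ratio test (0.75) with a cross-check, followed by
RANSAC (3 px reprojection threshold, up to 2000 adaptive iterations, seeded
from the pipeline configuration so runs are reproducible) and a final
least-squares fit on the inliers (closed form for similarity, normalized
DLT for projective). Degenerate configurations (under-determined systems,
collinear points) raise typed errors rather than returning garbage.

## 3. Superpixel-restricted optimal seam

In the overlap of the mosaic and an incoming frame, a row-monotone,
rV-connected seam is sought that minimizes the cumulative energy

$$ E(u,v) = \alpha\,E_{hue} + \beta\,E_{int}^2 + \gamma\,E_{str}, $$

with the hue difference taken in HSV, the intensity difference averaged
over a 3×3 neighborhood under a center-weighted kernel (center 8, surround
1, normalizer 16 — so a constant difference yields exactly that constant),
and the gradient difference as the sum of squared Scharr-response
differences. The three terms live on very different scales, so each is
min–max normalized over the overlap before weighting; the default weights
are 1/3 each. The seam is restricted to the 5×5-dilated boundaries of SLIC
superpixels computed on the pixel mean of the two aligned overlaps —
boundaries trace image structure, which is where a cut hides best. When the
boundary network admits no connected monotone path (common when superpixel
boundaries run perpendicular to the seam direction), the restriction is
lifted with a warning and the seam is found over the whole overlap; the
restriction is a shape prior, not a hard requirement. Overlaps wider than
tall are transposed so the seam always crosses the short direction.

The dynamic program accumulates
$E_{acc}(u,v) = \min_{|k-v|\le rV} E_{acc}(u-1,k) + E(u,v)$, picks the
terminal argmin and traces back through window argmins, breaking ties to
the smallest column. Its optimality is verified against exhaustive path
enumeration on 100 random grids.

Two subtleties worth recording: the neighborhood intensity term is *not*
zero for two identical textured images (it measures local roughness by
construction); only the hue and gradient terms vanish there. And the
squared intensity term is squared *after* the neighborhood averaging.

## 4. Stripe-confined Laplacian fusion

Blending the whole overlap would re-introduce decomposition loss
everywhere, so fusion is confined to a stripe of half-width
$\alpha = 30$ px centered on the seam. Both overlap crops are decomposed
into 3-level Laplacian pyramids (5-tap Burt–Adelson kernel; inputs padded
by edge replication to multiples of $2^{levels}$; zero-insertion
upsampling pads the coarse samples by replication first so constants are
reproduced exactly), the residuals and tops are mixed under the Gaussian
pyramid of the binary seam-side mask, and the reconstruction replaces the
stripe in the composite. Every pixel outside the stripe is left
bit-identical — asserted exactly in the tests. `reconstruct(build(x))`
equals `x` to float precision by construction.

The stripe that is *replaced* is the full $2\alpha$ band by default; a
narrower central band (half the width) is available as
`fusion$replace_half_stripe`, since either reading of "an α-pixel stripe"
is defensible.

### What fusion does and does not improve

The validation script scores fused and unfused composites of misaligned
synthetic pairs against the known ground-truth panorama inside the stripe.
Stripe fusion consistently improves PSNR over the hard seam composite
(10/10 seeds at the default settings), because blending two oppositely
shifted observations is closer to the truth in the L2 sense. Histogram
mutual information moves the other way by a few hundredths of a bit
(0/10 seeds improved): the continuum of blend weights spreads the joint
gray-level histogram, which MI penalizes even as the MSE falls. Against a
ghosted average-overlay baseline the ranking flips exactly (MI improves
10/10, PSNR 0/10 — an average of two symmetrically shifted sources is the
L2-optimal composite). No composite wins both metrics against a hard-cut
baseline under symmetric residual misalignment; treat the pair of metrics
as complementary, not redundant. Both contrasts are reported by
`scripts/acceptance.R`.

## 5. The synthetic survey generator

`generate_survey()` is the package's oracle: it draws a seabed texture,
a smooth depth field, and a sweep of overlapping views with known warps,
degrades each view through the exact image-formation model above, and
stores the clean views, true transmissions and warps.

What it emulates, and why:

* **Texture** (`generate_seabed_texture()`): multi-octave value noise
  (sand/rubble), elliptical high-frequency blobs in contrasting hues
  (coral heads), clumped dark crevices *plus scattered per-pixel grain
  shadows* — the near-black minima in every local patch that the
  dark-channel prior requires — and fine speckle so corner detectors and
  superpixels have structure to grip.
* **Illumination**: the texture is the scene radiance at zero viewing
  distance, which underwater is already dim and blue-green shifted because
  the illumination has been filtered by the water column above the seabed.
  The defaults (`illumination = c(0.40, 0.85, 0.90)`, `brightness = 0.75`)
  encode this low target-to-background contrast; they also place the
  brightest pixels in the haze-dominated regime that the background-light
  estimator assumes. With an unfiltered bright texture that estimator reads
  texture instead of haze and its bias dominates the transmission error.
* **Degradation**: `betaR = 1` with depth in `[0.2, 2.0]` spans optical
  thicknesses from nearly clear to heavily veiled
  ($t_R \in [0.14, 0.82]$). Background light defaults to the bluish-green
  `A = (0.25, 0.55, 0.70)`.
* **Geometry**: views of 192×256 px spaced for 50% overlap, with similarity
  jitter of ±2° roll, ±3% scale and ±3 px translation — the scale of
  hand-guided sweep variation; zero-jitter and projective options exist.
  `generate_misaligned_pair()` additionally perturbs the two placements by
  ±misalignment/2 in opposite directions so the true geometry lies between
  them, which is how residual error presents around an estimated
  registration.

What it deliberately does **not** emulate: forward-scatter blur, caustics
and surface flicker, vignetting and lens distortion, sensor noise, moving
fauna, and non-planar relief (parallax). Passing the synthetic validation
therefore demonstrates that the pipeline inverts its own image-formation
model, registers and composites correctly under known geometry — not that
it is robust to every optical effect in real footage. The quantization
option (`quantize = TRUE`) exercises the 8-bit I/O path, which is where
real degraded frames genuinely lose information.

## 6. Numerical choices and problem sizes

* All arithmetic is double-precision on `[0, 1]`; 8-bit I/O converts at the
  boundary by `/255` and `round(* 255)`.
* Window operations (dark channel, box sums for the guided filter) use
  border truncation (replicate semantics); separable passes make them
  linear in pixel count.
* Canvas extents round outward with a $10^{-6}$ guard so an exactly
  identity warp does not shift the canvas by a pixel.
* DP ties break to the smallest column; RANSAC is seeded per pair from the
  pipeline seed (`seed + 7919 * pair`), keeping mosaics byte-identical
  across reruns.
* Validation problem sizes were chosen to finish in minutes on one core:
  512×512 transmission-recovery scenes (10 seeds), 100 seam-oracle grids up
  to 8×8, ten 2-view match-gain and fusion fixtures, and 5- and 20-view
  end-to-end surveys at 192×256 px per view.

## 7. Known limitations

* Sequential pairwise chaining accumulates drift along very long sweeps;
  there is no bundle adjustment or loop closure. Sub-pixel corner
  localization keeps 20-view drift well under a pixel on synthetic sweeps.
* The background-light estimator needs haze-dominated bright pixels;
  on high-contrast scenes in clear water it overestimates $A$ and the
  power-law conversion degrades accordingly.
* The superpixel restriction frequently has no feasible monotone path and
  falls back to the unrestricted seam; it is an accelerator/shape prior,
  not a guarantee.
* No gain compensation or color constancy across frames: exposure steps
  between frames will survive outside the blended stripe.
* Histogram MI slightly decreases under stripe blending (see §4); use PSNR
  and MI together when comparing composites.
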