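---
title: "Methods: automated breast and fibroglandular volumetry from T1-weighted MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated breast and fibroglandular volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Breast density — the fraction of fibroglandular (parenchymal) tissue in the
breast — is an established breast-cancer risk factor. On non-fat-suppressed
T1-weighted breast MRI, fat is bright, parenchyma and muscle are darker, and
air is near zero, so density can in principle be measured volumetrically by
counting voxels. Two obstacles stand in the way of simple thresholding:

1. **Intensity inhomogeneity (bias field).** Surface receiver coils produce a
   strong smooth multiplicative intensity gradient — fat near the nipple can
   be several times brighter than the same tissue near the chest wall, with an
   additional left–right modulation from B1 effects. Region- and
   threshold-based segmentation fails without correcting it.
2. **Anatomy.** The bright-tissue segmentation includes everything fatty or
   bright in the field of view; the breast must be separated from the
   pectoral muscle and body, holes (parenchyma) must be filled to obtain the
   total breast volume, and the mask must be cut at the posterior sternum
   boundary, which is the standard landmark for the breast–body cut in
   manual protocols.

`breastdens` implements a three-stage pipeline: (1) per-slice joint
segmentation and bias-field estimation with a two-phase level set, (2)
geometric refinement of the breast mask, (3) parenchyma extraction and
density computation, plus the agreement statistics used to compare automatic
and reference volumetry.

# Stage 1: joint segmentation and bias-field estimation

## Model

Each axial slice is modeled as

$$U(x) = J(x)\, b(x) + n(x),$$

where $J$ is piecewise constant over $K$ tissue classes with intensities
$c_1 < \dots < c_K$, $b$ is a smooth, slowly varying multiplicative bias, and
$n$ is zero-mean Gaussian noise. The stage minimizes the clustering energy

$$E(\phi, c, w) \;=\; \sum_{k=1}^{K} \int_\Omega |U(x) - b(x)\,c_k|^2\, m_k(x)\,dx
\;+\; \nu\,\mathrm{Length}(\phi = 0) \;+\; \mu\,\mathcal{R}(\phi),$$

with memberships $m_k$ induced by a two-phase level-set embedding $\phi$:
the region $\phi > 0$ is the brightest class (fat on this contrast), and the
remaining classes partition $\phi \le 0$ by nearest (bias-scaled) centroid.
The bias is expanded in a tensor Legendre polynomial basis,
$b(x) = w^\top G(x)$, of order 4 per axis by default — smooth by
construction, with no separate smoothing kernel.

## Minimization

Alternating minimization per sweep, each step in closed form or provably
non-increasing:

* **Class reassignment** of the non-fat phase (pointwise argmin).
* **Centroids:** $c_k = \sum U b\, m_k / \sum b^2 m_k$ — the weighted
  least-squares optimum; with $b \equiv 1$ this is a k-means step. Classes
  that lose all members are frozen and flagged.
* **Bias coefficients:** normal equations of the weighted least-squares
  problem $\min_w \sum_x (U - c_{l(x)} w^\top G(x))^2$.
* **Level-set evolution:** a monotone region-competition sweep in
  checkerboard order. A pixel changes phase when the change lowers the sum
  of its data cost and $\nu$ times the local interface length (4-neighbor
  disagreement count). The embedding is then re-initialized to the signed
  distance of the region, which keeps the distance-regularity term
  $\mathcal{R}$ at its minimum; this "regularization by re-initialization"
  is why $\mu$ defaults to 0. The discrete scheme makes the full energy
  trace non-increasing by construction, which the test suite asserts on
  seeded phantoms.

Slices are normalized to $[0,1]$ internally so that $\nu$ (default $10^{-3}$)
is comparable across inputs. Iteration stops when the relative energy change
drops below $10^{-4}$ or after 200 sweeps. Initialization is an Otsu
threshold for the fat phase and intensity quantiles for the remaining
centroids. Per-ACR parameter profiles (`acr1`–`acr4`) are exposed as named
presets; they currently share these defaults, so that per-group tuning is a
configuration change.

Three result images are produced per slice — the fat segmentation, the
bias-corrected image $U/b$, and the bias field itself — and composed back
into 3D volumes. After correction the intensity histogram becomes clearly
multimodal; `histogram_valley_depth()` quantifies this and the tests require
the corrected volume to have deeper inter-mode valleys than the input.

## Numerical choices

* **Identifiability.** A multiplicative bias is only determined up to a
  scale, so the emitted field is normalized to slice mean 1; it is only
  determined at all where there is signal, so strict positivity is enforced
  on the tissue classes, while in pure-air regions the polynomial
  extrapolates freely and is floored at $\varepsilon = 10^{-6}$ before
  division. Accordingly, bias-recovery accuracy is evaluated over tissue
  voxels.
* **Slice ordering.** `segment_volume()` processes slices from the middle of
  the selected range outward and warm-starts each slice from its
  already-solved neighbour (centroids and bias coefficients; labels are
  re-derived by pointwise classification). The per-slice functional is
  unchanged. The cold start is unreliable only on end-cap slices with a few
  hundred fat voxels, where a histogram threshold cannot tell fat from body
  — there the warm start anchors the class structure and roughly halves the
  iteration count elsewhere.
* **Degenerate inputs.** Constant slices are rejected; failed slices are
  zero-filled and reported in the convergence log rather than aborting a
  volume run.

# Stage 2: breast-mask refinement

The raw fat segmentation is turned into a solid breast mask:

1. **Largest 3D component** (26-connectivity; ties broken deterministically
   by label order, with a warning).
2. **Reference slice.** Starting from the component's centroid slice and
   moving outward, the first slice whose set differences against both
   neighbours contain no connected component larger than $T$ (default 5%) of
   the slice's area is taken as reference. If no slice qualifies the
   centroid slice is used, with a warning — processing must not abort on
   pathological stacks.
3. **Boundary propagation.** Sweeping from the reference slice toward both
   ends, each slice is split into catchment components by a watershed on the
   inverted Euclidean distance map of its foreground (regional maxima merged
   below a depth of one voxel to prevent over-fragmentation); components
   whose overlap with the already-refined neighbour is below 50% of their
   area are discarded. This removes bright tissue that "leaked" into the
   pectoral muscle through thin connections. Watershed boundary pixels
   between two kept components are restored, so regions split only by the
   watershed are merged back; only pixels of the slice's original foreground
   are eligible, so propagation never adds tissue. A lobe present on the
   reference slice itself is, by construction, not removed — the reference
   is assumed clean.
4. **Hole filling and posterior exclusion.** In-plane holes (enclosed
   parenchyma) are filled per slice; the posterior 15% of the image rows,
   which contains lung and body structures irrelevant to the breast, is
   excluded. The exclusion is relative to the image, not to the component
   box: a clean breast component's box ends at the chest wall, and cutting a
   fraction of it would remove true posterior breast tissue.
5. **Region-dependent rolling-ball closing.** Surface concavities are closed
   with metric balls of three radii: 12 mm in the anterior band
   (nipple/areola), 8 mm in the pectoral-adjacent posterior band, 3 mm
   elsewhere (sides, skin folds). Radii are in mm and honour anisotropic
   voxel spacing; the distance-transform implementation pads with background
   so closing is exact (idempotent on convex sets) at the domain boundary.
6. **Sternum cut.** The posterior-most breast-tissue row within a narrow
   window around the component's x-centroid approximates the posterior
   sternum boundary — the same landmark used by manual protocols — and
   everything posterior to it is removed.

All constants live in `refinement_params()` and none are hard-coded. The
defaults are anatomy-scaled values for adult breast MRI at clinical
resolution; the 24-slice test phantom samples the breast more coarsely than
a clinical stack, so the refinement unit tests open the triple-similarity
threshold to 10% for it.

# Stage 3: parenchyma and density

The refined breast mask $B$ masks the segmentation $S$; the parenchyma is
$P = B \wedge \neg(S \wedge B)$ — the breast voxels not classified as bright
fat. $P$ and $S \wedge B$ partition $B$ exactly, which the tests assert on
every pipeline run. (Taken literally, "masked segmentation minus breast"
would be empty, since the masked segmentation is a subset of the breast;
the implemented direction matches the manual protocol, where parenchyma is
the non-fatty tissue inside the breast region.) BV and PV are voxel counts
converted to liters through the voxel volume; percent density is
$100\,\mathrm{PV}/\mathrm{BV}$.

# Agreement statistics

`agreement_stats()` computes Dice's similarity coefficient
$2|A \cap M|/(|A| + |M|)$, delineation sensitivity (true-positive volume
fraction $|A \cap M|/|M|$) and specificity ($1 -$ false-positive volume
fraction $|A \setminus M| / |\Omega \setminus M|$) against a reference mask.
Specificity is reported for parity but flagged: it is close to 1 whenever
the background dwarfs any plausible oversegmentation.

`bland_altman()` uses the difference convention automatic − manual.
`regression_loa()` implements regression-based limits of agreement for the
case where the difference varies with the magnitude: the difference is
regressed on the average, $\hat D(a)$; the absolute residuals are regressed
on the average, $\hat R(a)$; and the limits are
$\hat D(a) \pm 1.96\sqrt{\pi/2}\,\hat R(a)$, where $\sqrt{\pi/2} \approx
1.2533$ converts the mean absolute deviation of a Gaussian into its SD.
Whether the slope is significant enough to warrant the regression-based
limits is a decision left to the caller. SDs use the $n-1$ denominator.

# The phantom generator

Because clinical breast MRI cannot be redistributed, the package ships a
synthetic prone-breast phantom with known ground truth; all recovery claims
in the test suite are statements about this phantom, not about clinical
data.

The phantom emulates, in a $40 \times 128 \times 128$ grid at
$3 \times 1.7 \times 1.7$ mm by default:

* two pendant half-ellipsoidal breasts of bright fat (intensity 400)
  attached to a posterior body band (muscle-like, 140), with air (10)
  elsewhere; the breast footprints overlap slightly at the midline so the
  inter-mammary cleft reaches the chest wall, as in prone positioning;
* a connected, blobby parenchymal structure (150) inside each breast —
  thresholded Gaussian blobs, closed, with the threshold bisected until the
  parenchyma occupies the target fraction (default 20%, an ACR-2-like
  density) of the breast volume;
* a multiplicative bias field: a strictly decreasing logistic along the
  anterior→posterior axis times a low-frequency cosine that brightens the
  lateral edges, normalized to mean 1. The default amplitude (0.5) gives
  roughly a 3:1 fat-intensity ratio across the breast, matching the
  magnitude of coil-profile artefacts on non-fat-suppressed T1 images;
* additive Gaussian noise, default SD 8 = 2% of the fat intensity, clipped
  at zero.

All randomness flows from a single integer seed. The leakage fixture
injects a fat-bright lobe into the body band, connected to a breast by a
thin neck on selected slices only, with the injected disk and neck voxels
recorded for exact bookkeeping.

**What the phantom does not model:** partial-volume voxels, skin, coil
elements and aliasing, motion, lesions or implants, Rician noise, and
through-plane bias variation. Passing recovery tests on the phantom shows
the algorithmic machinery is correct and self-consistent at clinical-like
contrast and artefact strength; it does not certify clinical accuracy.

# Problem sizes and test design

The recovery checks run end-to-end on twenty $128 \times 128 \times 40$
phantoms (mean breast-mask Dice ≥ 0.95, parenchyma Dice ≥ 0.80 against
truth), bias recovery requires per-slice correlation > 0.99 against the
analytic field over tissue voxels at 2% noise, and leakage repair requires
≥ 99% of the injected lobe removed with < 0.5% of true breast voxels lost
at the propagation stage (the sternum cut later removes neck remnants).
Unit tests use $24 \times 64 \times 64$ phantoms. Two pipeline runs from
the same configuration and seed must be byte-identical, including the JSON
report.

# Known limitations

* Per-slice 2D processing: no 3D coupling of the level set across slices
  (the warm start shares initialization, not the functional).
* The reference slice is assumed clean; leakage present on it propagates.
* The sternum landmark assumes medial breast tissue reaches the chest wall;
  on stacks without midline tissue the cut is skipped with a warning.
* Specificity against a whole-volume background is uninformative (reported
  but flagged).
* The per-ACR parameter profiles are placeholders sharing one default until
  tuned on real cohorts.
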