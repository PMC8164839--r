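---
title: "CShin morphometrics, motif conservation and mask-based colocalization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CShin morphometrics, motif conservation and mask-based colocalization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cshin)
```

## The Cell Shape Index

Epithelial cells under junctional tension have taut, nearly straight
borders; mesenchymal or mesenchymal-like cells have serrated, wavy
outlines decorated with protrusions. Two classical particle-analysis
descriptors each capture half of this picture:

* **Circularity** $= 4\pi A / P^2$, with $A$ the area and $P$ the
  perimeter of the outline. It equals 1 for a circle (isoperimetric
  inequality) and collapses quickly when the border becomes wavy,
  because undulation inflates $P$ at nearly constant $A$. It barely
  reacts to elongation.
* **Roundness** $= 4A / (\pi M^2)$, with $M$ the full major axis of the
  moment-equivalent ellipse. For an ellipse with semi-axes $a \ge b$ it
  equals $b/a$, so it tracks gross elongation — but it is blind to
  border texture, since small-amplitude waviness hardly moves the
  second moments.

The Cell Shape Index divides one by the other,

$$\mathrm{CShin} = \frac{\mathrm{Roundness}}{\mathrm{Circularity}},$$

so that a perfect circle scores exactly 1, smooth elongated outlines
score below 1 (the numerator falls faster than the denominator), and
border waviness pushes the score above 1 (the denominator collapses
while the numerator stands still). The package computes all three on
exact polygon geometry:

```{r circle}
theta <- 2 * pi * (0:4095) / 4096
shape_metrics(contour(100 * cos(theta), 100 * sin(theta)))
```

### Geometry conventions and numerics

* Area is the shoelace sum; perimeter includes the closing edge; both
  are exact for the polygon as given.
* The major axis comes from the closed-form second central moments of
  the *filled* polygon (Green's theorem), normalised by area:
  $M = 4\sqrt{\lambda_{\max}}$ of the moment tensor. This reproduces
  the exact axis for true ellipses and gives $2s/\sqrt{3}$ for a square
  of side $s$; no rasterisation is involved.
* Contours are normalised to counter-clockwise orientation; duplicate
  consecutive vertices are dropped; zero-area and self-intersecting
  polygons are rejected. Generator outlines that are star-shaped with
  strictly positive radius are provably simple and skip the
  $O(n^2)$ crossing check.
* `cshin` is computed literally as `roundness / circularity`, so the
  definitional identity holds bit for bit.
* Raster inputs are not measured natively: a 0.5-level marching-squares
  contour is traced per connected component (`mask_to_contours`),
  because pixel-count perimeters are biased. The raw traced polygon
  still overestimates the perimeter of smooth shapes by several
  percent (45-degree staircase cuts), so a circular moving average of
  window 5 over the traced vertices is applied by default; on a smooth
  blob this brings the round-trip CShin within about 1 % of the
  exact-polygon value. Set `smooth = 1` to disable.
* Components below `min_area = 50` px² are discarded as segmentation
  specks; the threshold is configurable.

## The synthetic outline generator

The study conditions the package reproduces are microscopy-free:
populations of outlines with controlled border texture stand in for
cell cultures. The radial model is

$$r(\theta) = R(\theta)\,\bigl(1 + \varepsilon\, w(k\theta)\bigr),$$

where $R(\theta)$ is the base figure (circle, ellipse, or a low-order
"blob"), $\varepsilon$ the dimensionless wave amplitude, $k$ the wave
count, and $w$ either a sinusoid or a triangle wave ("serrated"). For
cornered figures (square, rectangle, triangle) the same perturbation is
applied along the outward normal, parameterised by arc length, with the
true corners always included among the sampled vertices so that the
base geometry stays exact. $\varepsilon < 1$ keeps radial shapes simple
by construction; cornered shapes are checked and an over-aggressive
$(\varepsilon, k)$ combination is rejected by name.

Two presets define the morphology dichotomy by its CShin signature, not
by any biological claim:

| preset | aspect | $\varepsilon$ | $k$ | expected CShin |
|---|---|---|---|---|
| epithelial | U(1.2, 2.0) | 0 | — | below 1 |
| mesenchymal | U(1.2, 2.0) | U(0.08, 0.18) | U{10..20} | above 1 |

Cell size is U(45, 75) px in radius and rotation is uniform in both
presets; 512 vertices per outline resolve up to 20 waves comfortably.
The amplitude and count ranges were chosen once as visually plausible
for serrated cell borders (protrusion-scale undulation, not noise);
population medians then land near 0.68 and 1.8, an unambiguous split
around 1. The monotone response of CShin to $\varepsilon$ — the
property that makes the index useful — is asserted over a grid of
amplitudes in the tests. The printed index of any *particular* wavy
figure depends on the unpublished $(\varepsilon, k)$ of that figure, so
only ordering and threshold properties are meaningful targets.

All generators are pure functions of their spec and an explicit seed
(`withr::with_seed`); no global RNG state is consumed or leaked.

What the generator does **not** emulate: optics (PSF, defocus,
chromatic shift), segmentation error, protrusion anisotropy, contact
between neighbouring cells, or any correlation between size and
border texture. Passing tests therefore validate the estimator and its
statistics, not the microscopy or the manual outlining step of real
experiments.

## Group statistics

CShin distributions are not normal, so comparisons are rank-based
throughout, two-sided:

* **Two groups** — Mann-Whitney on the medians. The exact enumeration
  p-value is used when $n_a n_b \le 400$ and there are no ties
  (at which size exactness is cheap), otherwise the normal
  approximation with tie and continuity corrections. The reported U is
  $\min(U_a, U_b)$.
* **Three or more** — Kruskal-Wallis (tie-corrected H, $\chi^2_{k-1}$
  p-value) followed by Conover-Iman post hoc t-statistics on the pooled
  ranks,
  $t_{ij} = (\bar R_i - \bar R_j)\big/\sqrt{S^2\,\tfrac{N-1-H}{N-k}\,(\tfrac1{n_i}+\tfrac1{n_j})}$,
  with $S^2 = \bigl(\sum R^2 - N(N+1)^2/4\bigr)/(N-1)$ and $N-k$
  degrees of freedom.
* **Multiplicity** — Benjamini-Hochberg step-up across all pairs of one
  experiment (one family per experiment, never across experiments).

With two groups the Conover step falls back to Mann-Whitney with a
warning rather than fabricating a one-pair "post hoc".

```{r stats}
epi <- preset_population_metrics("epithelial", 50, seed = 1)
mes <- preset_population_metrics("mesenchymal", 50, seed = 1)
compare_groups(list(epithelial = epi$cshin, mesenchymal = mes$cshin))
```

## Motif scanning and conservation

The tankyrase-binding motif scanner matches the canonical hexamer
`R-X-X-O-X-G` and the non-canonical heptamer `R-X-X-X-O-X-G`, with
`O` one of G/P/A/C and `X` any residue. Coordinates are 1-based
inclusive; every overlapping or nested window is reported (no
suppression rule exists for these motifs); `X` (unknown) satisfies only
the unconstrained positions, never an anchor, because the anchors *are*
the motif definition.

Conservation is assessed against a *precomputed* multiple alignment
(aligned FASTA or Clustal; alignment computation is out of scope). Each
reference motif locus is projected onto its alignment-column window and
every other row is classified there: **conserved** if the ungapped
residues under the window match the same class pattern; **degenerate**
if the motif length and the R/G anchors survive but the O-position
fails; **absent** otherwise (including indel-shifted windows). The
third class exists so that near-misses — the interesting evolutionary
cases — are inspectable rather than silently binned as absent.

The RefSeq proteins themselves are not redistributed. A deterministic
**synthetic surrogate** (`synthetic_vcl_record()`, and the
`synthetic_*` files under `inst/extdata/`) embeds the three vinculin
motifs at their published coordinates (339, 449, 520) in a background
scrubbed of spurious matches, so the scanner's positional behaviour is
exercised end to end; the conservation demo alignment is likewise
synthetic and labelled as such.

## Colocalization suite

The mask-based workflow, in order:

1. **Masking** — foreground iff intensity **strictly** exceeds the
   threshold (dialects differ on the boundary pixel; the strict rule is
   stated rather than assumed), either fixed or Otsu. A control image
   (no primary antibody) can be checked: more than 0.1 % foreground at
   the same threshold raises a warning, since a valid threshold must
   empty the control.
2. **Mask product** — pixelwise AND; the product outlines the overlap
   region exactly.
3. **Manders M1/M2** — *count-based*: $M_1 = |A \wedge B| / |A|$,
   $M_2 = |A \wedge B| / |B|$, the fraction of one channel's positive
   pixels that are also positive in the other. This is deliberately not
   the classical intensity-weighted variant, which is available behind
   `weighted = TRUE` for comparison. An empty mask makes the
   coefficient undefined and is an explicit error, never a silent 0.
4. **Pearson r** — over *all* ROI pixels, not only mask-positive ones;
   invariant under positive affine rescaling of either channel.
5. **Li's ICA** — $\mathrm{PDM}_i = (A_i - \bar A)(B_i - \bar B)$;
   $\mathrm{ICQ} = \#\{\mathrm{PDM} > 0\}/\#\{\mathrm{PDM} \ne 0\} - 0.5
   \in [-0.5, 0.5]$. Zero-PDM pixels are excluded from the denominator
   (their sign is undefined, and the exclusion is what makes the
   degenerate identities ICQ $= \pm 0.5$ exactly attainable). The
   ++PDM mask flags pixels with both channels above their means.

ROIs are logical masks or polygons; a polygon selects pixels whose
centres fall inside (even-odd rule). Swapping channels swaps
$M_1 \leftrightarrow M_2$ and leaves $r$ and ICQ unchanged.

### The belt-pair generator

Synthetic two-channel images emulate junction-belt micrographs: channel
A stains a full annulus (radius 90 px, width 14 px on a 256-px canvas),
channel B a contiguous-arc subset covering a known fraction $\rho$ of
A's foreground, plus optional off-belt B-only signal; both channels get
additive Gaussian noise (foreground 200, background 20, sd 10 by
default, thresholds at 110 separating them). Because $\rho$ is defined
on A's foreground, it *is* the expected count-based $M_1$, which is
what makes recovery testable: mean $M_1$ over seeds must sit within
±0.05 of $\rho$. The tests also assert the agreement the mask-product
and ++PDM routes show on such images (Jaccard overlap ≥ 0.5 at the
generator defaults) — a regression property of this generator and
suite, not a theorem about arbitrary images.

## Problem sizes

The shipped analyses and tests use 4096-gon circles for the identity
checks, populations of 50–100 outlines (512 vertices each), 256-px belt
images with 10–20 seeds per condition, 1,000 random sequences for the
scanner-vs-oracle equality, full enumeration (12,870 splits) for the
exact Mann-Whitney oracle at $n = 8,8$, and 10,000 simulated null pairs
for the type-I-error calibration. These sizes give sub-minute runs
while leaving every statistical margin several standard errors wide.

## Known limitations

* Contours with holes are not modelled; `mask_to_contours` keeps the
  longest loop per component.
* The raster route's smoothing window trades staircase bias for a
  sub-pixel boundary displacement; at extreme undulation (wavelength
  comparable to the window) it will clip genuine texture.
* The Mann-Whitney exact/approximate switchover is a stated convention;
  near the boundary the two p-values differ in the third decimal.
* Otsu assumes a bimodal histogram; belts occupying a few percent of
  the canvas can defeat it, which is why fixed thresholds validated on
  controls are the default analysis path.
* The colocalization coefficients of real micrographs depend on
  acquisition choices (threshold placement, ROI drawing) that no
  simulation reproduces; the synthetic belt pairs validate the
  estimators, not any biological effect size.
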