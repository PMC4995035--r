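---
title: "Models, parameters and design choices in fibertrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in fibertrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

fibertrace extracts individual actin stress fibers from fluorescence
micrographs in three stages: source separation, enhancement plus
multi-scale line detection, and segment extraction with merging. This
vignette explains the models behind each stage, every tunable parameter
with its default and rationale, what the synthetic-scene generator does and
does not emulate, and the numerical and design choices made where more than
one reasonable construction existed.

## 1. The source model and its separation

A micrograph is modeled as `f = u_f + v_a + eta`: filamentous content,
smooth background artifacts (out-of-focus haze, staining deposits), and
additive noise. The separation assumes each content type is sparse in its
own dictionary and diffuse in the other's:

* **Fiber dictionary (`curvelet_dictionary()`).** A tight frame of
  FFT-domain windows: Meyer-type radial rings split into overlapping
  raised-cosine orientation wedges, opposite wedges fused so coefficients
  describe an undirected orientation, plus one isotropic lowpass band. The
  squared windows sum to one at every frequency, so analysis followed by
  synthesis is exact to machine precision. Elongated, orientation-selective
  atoms represent smooth curvilinear ridges with few large coefficients —
  the defining property needed from a curvelet-type transform. Defaults:
  3 scales, 12 and 8 wedges on the two directional scales. More wedges
  sharpen orientation selectivity at proportional cost; the default
  resolves 15 degrees at the finest scale, matching the line detector's
  orientation step.
* **Artifact dictionary (`udwt_dictionary()`).** The isotropic undecimated
  B3-spline ("starlet") wavelet transform, 4 levels. Detail bands are
  differences of successive smoothings, so the plain sum of bands
  reconstructs exactly. Smooth blobs concentrate in its coarse bands.

The solver (`mca_decompose()`) is block-coordinate iterative thresholding:
each iteration re-estimates each component from its marginal residual,
thresholds its coefficients at the current `gamma`, re-synthesizes, and
optionally applies a small total-variation-diminishing correction. Key
choices:

* `p = 0` — hard thresholding (an l0-type penalty); `p = 1` gives soft.
* `delta = 3` — weight of the TV correction, implemented as soft shrinkage
  of first-difference (undecimated Haar) details with amount
  `delta * gamma_t / gamma_init_k`, i.e. proportional to the current
  threshold so the correction anneals with the sweep. It is applied to the
  artifacts component by default (`tv_target = "artifacts"`, as the
  objective is written); the cartoon-component convention of the MCA
  literature is available via `tv_target = "fibers"`.
* `gamma` schedule — linear from `30 x sigma_MAD` down to `3 x sigma_MAD`
  over `n_iter = 100` iterations, where `sigma_MAD` is the robust noise
  estimate of the input. The start is floored at the smaller of the two
  dictionaries' maximal coefficient magnitudes: on a noiseless image
  `sigma_MAD` is ~0 and without the floor the very first update would
  absorb the whole image into one component. On noisy images the floor is
  inactive.
* The artifacts dictionary's lowpass band is never thresholded while every
  curvelet band is: exactly one component must own the smooth lowpass
  content for the separation to be well-posed, and assigning it to the
  artifacts side matches what the artifacts are (smooth background).
* All transforms run on a mirror-padded copy (`pad = 16` px) to suppress
  periodic-boundary artifacts of the FFT; components are cropped back and
  the residual is defined as `f - u_f - v_a` after cropping, so additivity
  is exact by construction.

`estimate_noise_sigma()` reads the noise level off the finest starlet
detail band: MAD / 0.6745, divided by the band's noise gain (the L2 norm of
its equivalent filter, about 0.89), so pure Gaussian noise of known sigma
is recovered unbiased.

## 2. Enhancement

`enhance()` chains three filters and rescales the result to [0, 1]:

* Gaussian smoothing, `gaussian_sigma = 1` px — suppresses pixel noise at a
  scale below the narrowest fibers of interest.
* Laplace sharpening: the 3x3 kernel `beta * [[0,-1,0],[-1,c,-1],[0,-1,0]]`
  with `beta = 10` and center `c = -4` as printed in the source method.
  With that center the scaled kernel is an all-negative smoother whose
  response to a bright ridge is strongly negative; the chain therefore
  takes the magnitude after this step by default (`laplace_abs = TRUE`),
  which restores ridges as bright structures. The center is configurable
  (`laplace_center = 4` gives a conventional sharpening kernel) — the
  printed value is kept as the default rather than silently corrected.
* A directional Gaussian bank: anisotropic Gaussians with long-axis
  `dg_sigma = 10` px and short-axis 1 px (preserving width while
  reinforcing along the fiber), at 12 evenly spaced orientations, combined
  by per-pixel maximum. The support parameter is `r = 2*ceil(3*sigma_dg)`;
  since `r` is even, the kernel is sampled on an `(r+1) x (r+1)` grid (one
  zero ring) so the convolution is exactly centered.

A limitation stated plainly: on our synthetic fixtures the chain does not
increase simple on/off contrast measures — the directional bank flattens
the background but also spreads a halo around strokes, and downstream
detection quality with and without the chain is comparable on clean scenes.
Its role in the full method is reinforcing faint, broken, defocused
filaments so they survive binarization as connected chains; the tested
property is the weaker, robust one (filament pixels come out clearly
brighter than background).

## 3. Multi-scale line response and binarization

The line response at a pixel is the mean of the enhanced image along a
length-`s` oriented line element centered there, minus the mean over the
surrounding `(2W+1) x (2W+1)` window (mirror boundary; integer-rounded
sample offsets). `multiscale_response()` maximizes over 12 orientations
(15-degree steps), averages over element lengths `s = 1..W` plus the raw
pixel intensity as the `(W+1)`-th term (`include_pixel_term = TRUE`, which
is what the `1/(W+1)` normalization implies), and rescales to [0, 1].
`W = 4` is the expected fiber width in pixels and should be set to match
the material's magnification. The window side `2W+1` follows the standard
multi-scale line-detector convention; responses are raw means, without
local standardization (a standardized variant would couple the response to
background variance estimates; the raw form keeps the detector linear in
the image).

`wellner_binarize()` estimates a local threshold as the median over a
`median_window = 15` neighborhood and keeps pixels that clear it by the
fraction `b` of the remaining normalized response range:
`u_G > med + b*(1 - med)`, then removes connected components smaller than
`min_component_px = 5`. The headroom form is a deliberate reading of
Wellner-style percentage thresholding: on a [0, 1]-rescaled response a
threshold *proportional* to the local median is scale-free and cannot
separate ridges from any non-zero background (it floods the mask), whereas
the percentage-of-headroom form reproduces, at the stated working value
`b = 0.1`, the sparse masks and near-unit specificity this detector is
documented to operate at. Decreasing `b` monotonically retains more
candidates; a constant image yields an empty mask for every `b > 0`.

## 4. Segment extraction and merging

The mask is thinned to a one-pixel skeleton (Zhang-Suen). Branch points are
detected by crossing number (the number of 0-to-1 transitions around the
8-neighborhood; plain neighbor counts misfire on diagonal staircases), and
diagonal adjacencies that shortcut through a removed junction cell are
severed so crossing filaments stay separate chains. Each remaining branch
is walked into an ordered chain with a direction-momentum preference that
carries the walk straight through spur attachment points; every skeleton
pixel lands in exactly one chain.

`fit_segments()` grows a total-least-squares line along each chain while
the *maximal* perpendicular distance of chain pixels from the line stays
within 1 px (TLS, because the error criterion is perpendicular: ordinary
regression on x would bias steep orientations), closes the segment at the
first violation, restarts at the violating pixel, and keeps segments whose
endpoint distance is at least `L = 30` px.

`merge_fibers()` runs the increasing-tolerance sweep: for each integer
tolerance `xi = 0..T_theta` (default `T_theta = 2`), each surviving segment
merges into the first later segment whose orientation differs by at most
`xi` degrees — circularly on the 180-degree axis, so 1 and 179 degrees are
2 degrees apart — and whose endpoints overlap within `overlap_tol_px = 2`
(minimum distance from an endpoint of one to the pixel set of the other,
boundary inclusive). The merged orientation is the length-weighted mean
`(d_k θ_k + d_i θ_i)/(d_k + d_i)`; pixels beyond the intersection point of
the two fitted lines are discarded (for near-parallel lines, under half a
degree apart, the midpoint of the closest endpoint pair stands in for the
intersection). The sweep is single-pass per tolerance value, in stable
index order.

## 5. The synthetic-scene generator

`compose_scene()` builds `clip(u + v + eta, 0, 1)`:

* `u`: anti-aliased strokes with a flat intensity profile across the width
  (the line detector assumes near-uniform brightness over the stroke),
  optional gentle curvature (bounded so total angular drift stays within 20
  degrees), optional global Gaussian blur emulating defocus. Default
  material: lengths 60-100 px, widths 2-6 px — centered on the detector's
  expected width `W = 4`, since `W` is by definition matched to the
  material — intensities 0.6-1, centerline separation at least 10 px.
* `v`: isotropic Gaussian blobs (sigma 5-20 px, amplitudes 0.1-0.4),
  rejection-sampled so centers stay at least 1.5 times the summed sigmas
  apart — overlapping Gaussians would merge into elongated ridges,
  violating the defining non-fiber-like geometry of these artifacts — plus
  a constant background level of 0.1 (camera offset / diffuse
  fluorescence) which keeps the additive noise clear of the zero clip so
  the stated noise sigma is actually present in the composite.
* `eta`: i.i.d. Gaussian noise, default sigma 0.04.

What the generator does **not** emulate: a physically accurate microscope
PSF, photobleaching, intensity falloff along fibers, curvilinear bundles
beyond gentle drift, fiber crossings in the recovery benchmarks, or 3D
structure. Passing tests on these scenes therefore demonstrates the
pipeline's geometric and statistical correctness on its stated model — not
robustness to every real-microscopy nuisance.

## 6. Evaluation conventions

Pixel metrics are `Acc = (TP+TN)/total`, `Sn = TP/(TP+FN)`,
`Sp = TN/(TN+FP)`; undefined ratios return `NA` with a warning, never a
silent zero. `confusion_counts()` is strict pixelwise by default; the
tolerant mode (`match_tol_px = 1`) exists because rendered strokes have a
half-pixel ambiguity ring (anti-aliased partial-coverage pixels), and the
package's own recovery checks use 1 px — measured false positives on
fixtures are predominantly within 1 px of the truth outline, i.e. width
ambiguity rather than spurious detection. Both strict and tolerant values
are reported by the acceptance script.

Orientation summaries are linear statistics of angles on [0, 180) with the
population (divide-by-n) variance, optionally length-weighted; an axial
circular alternative (`circular = TRUE`) is provided but non-default, since
the linear convention is what orientation summaries in this literature
report. Angular histograms are normalized by their maximum bin count.

## 7. Problem sizes and runtime

The shipped test and acceptance runs use, as the package's own choices:
128-160 px fixtures for unit properties; 192 px scenes with 10 fibers
(ten seeds) for pixel-level recovery; one 256 px scene for decomposition
quality and noise recovery; and three 384 px scenes of 20 long
(80-140 px), well-separated (16 px) fibers for one-to-one fiber recovery.
Separation of 16 px embodies "well separated": it exceeds the detector's
spatial support (the W-window plus the directional-Gaussian cross
profile), below which masks of collinear neighbors fuse and produce the
method's characteristic too-long fibers. Lengths of 80-140 px make the
15%-length criterion meaningful against the fixed end-localization scale
(a few pixels to ~sigma_dg) that the directional bank imposes on ridge
ends.

## 8. Known limitations

* End localization: extracted fibers systematically over- or under-run
  stroke ends by up to ~10 px at `sigma_dg = 10`; relative length accuracy
  is poor for fibers shorter than ~2L.
* Fibers much wider than `W` are invisible to the detector interior (a
  ribbon wider than the window has no line contrast); choose `W` to match
  the material.
* The merging sweep is single-pass per tolerance as specified; contrived
  configurations can leave mergeable pairs after one run, though fixture
  networks converge in one pass (idempotence is asserted on them).
* Linear orientation statistics are sensible for populations away from the
  0/180 wrap; use the circular option near the wrap.
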