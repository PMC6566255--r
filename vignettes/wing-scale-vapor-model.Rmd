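---
title: "Modelling vapour-induced reflectance changes in pepper-pot wing scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vapour-induced reflectance changes in pepper-pot wing scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepperpot)
```

## The system and the model

Many lycaenid butterflies colour their wing scales with a *pepper-pot*
photonic nanoarchitecture: a stack of a few chitin layer pairs in which the
thick "A" layers carry a quasi-random lateral arrangement of large air
voids, and the thin "B" layers are crossed only by narrow vertical air
channels.  The stack behaves as a one-dimensional photonic cluster whose
stop band sets the visible colour.  In *Albulina metallica* both wing sides
carry the same architecture at two length scales -- the dorsal (blue) side
with a 200 nm vertical period and the ventral (gold-green) side with
260 nm -- which makes the species a natural laboratory for studying how
geometry controls the optical response to vapours.

When the wing is exposed to a solvent vapour, three things happen at once:

1. **capillary condensation** fills the smallest air spaces (the "B"-layer
   channels) with liquid first,
2. at higher concentrations liquid also reaches the large "A"-layer voids,
3. the chitin skeleton **swells** by a fraction of a percent, red-shifting
   every spectral feature.

`pepperpot` implements this picture as a fully parametric, deterministic
pipeline: geometry → effective-medium indices → multilayer reflectance →
whole-wing corrections → relative spectra → least-squares parameter
recovery, together with a direct-space-averaging (DSA) tool for the
cross-sectional TEM images from which the geometry is measured, and seeded
synthetic generators so that every stage can be tested without external
data.

## Geometry and effective media

`scale_geometry()` holds the cuboid model of one unit cell: lateral period
`p_xy`, layer thicknesses `d_a`, `d_b`, channel widths `w_a`, `w_b`, and
the channel length `c_len`, from which the void size follows as
`v_xy = p_xy - c_len`, `v_z = d_a`.  `dorsal_geometry()` and
`ventral_geometry()` are the measured presets (the ventral values are the
dorsal ones scaled by 1.3).

Each layer is collapsed to its *perforation factor* P -- the air volume
fraction of the unit cell -- and an effective index

$$n_\mathrm{eff} = P\,n_\mathrm{void} + (1-P)\,n_\mathrm{chitin},$$

with $n_\mathrm{chitin} = 1.56 + 0.033i$ (the imaginary part standing in
for pigment absorption) and $n_\mathrm{ethanol} = 1.36$.  The "A"-layer air
volume is the union of the central void and the horizontal channels that
cross the walls along both lateral axes; overlaps are counted once.  The
channels' contribution is computed analytically (the three cuboid families
only overlap inside the void), and the test suite checks it against an
independent 1 nm voxel count.  The Bragg predictor of the main peak is

$$\lambda_\mathrm{main} = 2\,p_\mathrm{eff}, \qquad
  p_\mathrm{eff} = \mathrm{Re}(n_a)\,d_a + \mathrm{Re}(n_b)\,d_b .$$

```{r}
geom <- dorsal_geometry()
media <- optical_media()
effective_stack(geom, media)
```

`calibrate_channel_width()` inverts this map: it finds the common channel
width that reproduces a measured peak position, mirroring how the channel
diameter -- the one dimension that cannot be read directly off a TEM
image -- is determined in practice.

## Reflectance solver

`multilayer_reflectance()` is a standard normal-incidence
characteristic-matrix (transfer-matrix) solver for planar stacks; it is
exact for the 1D effective-medium reduction used here and is verified in
the tests against closed-form Fresnel and Airy formulas at 1e-10 relative
accuracy.  A deliberate design decision replaces a full 3D
finite-element treatment of the lateral structure: for normal
backscattering the lateral disorder does not affect the spectrum to first
order, so the lateral structure enters only through the perforation
factors.  The consequences are that oblique incidence, polarisation and
angle-resolved quantities are out of scope, and that UV-range details
sensitive to void shape are not reproduced.

Two numerical points deserve mention:

* the solver follows the thin-film convention $N = n - ik$ internally and
  conjugates the supplied $n + ik$ indices, so absorbing layers attenuate
  (a sign slip here turns absorption into gain, which the
  absorption-vs-lossless test would catch);
* the Bragg identity $\lambda_\mathrm{peak} = 2 p_\mathrm{eff}$ is an
  infinite-crystal statement.  At the biological four stories the finite
  stack pulls the peak a few nm to the blue; the consistency test is
  therefore run at 32 stories, where the stop band is fully developed and
  the agreement is within one 2 nm grid step.  The four-story blue pull is
  itself asserted as a property (peak reflectance grows monotonically with
  the number of stories).

## Filling, swelling, and mixing

Because condensation is spatially patchy on scales larger than the
coherence length of white light, a partially filled scale reflects as an
*incoherent* mixture of end states, never as an intermediate effective
index.  With `R0`, `RB`, `RAB` the spectra of the empty, B-filled and
fully filled structure, the model spectrum at filling weights
$(c_B, c_{AB})$ and swelling $s$ is

$$R(\lambda) = (1 - c_B - c_{AB})\,R_0(\lambda') + c_B R_B(\lambda')
             + c_{AB} R_{AB}(\lambda'), \qquad
  \lambda' = \lambda / (1 + s).$$

The layer filling factors follow as $f_A = c_{AB}$ and
$f_B = c_{AB} + c_B$; an "A-only" process is excluded because the small
"B" channels always fill first.  The swelling parameter is a fractional
enlargement ($s = 0.008$ means 0.8 % linear swelling), implemented as the
spectral rescale $\lambda \mapsto \lambda/(1+s)$ with linear interpolation
and clamped grid edges; edge effects sit inside the background windows and
never reach the fitted region.

## Whole-wing corrections

A wing is not one scale: ground scales loaded with melanin add a smooth
background, and the random angular distribution of scales broadens every
feature.  `whole_wing_spectrum()` applies a Gaussian broadening (default
`sigma` = 15 nm, unit-area kernel, replicate padding) and adds a linear
background.  Neither the broadening width nor the background line is
printed with the study this models, so both are package defaults chosen
once on physical grounds: 15 nm is a typical orientation-disorder width
for lycaenid wings, and the default synthetic background
(`background_line(0.05, 5e-5)`) is a weak, mildly red-rising ground-scale
reflectance.  `fit_background()` recovers a background line from
measured spectra using the 200–250 nm and 750–800 nm flanks, where the
photonic peak contributes nothing.  Relative spectra are ratios of two
whole-wing spectra with the denominator floored at 1e-4 to keep the
strongly absorbed UV region finite.

## Parameter recovery

`fit_state()` inverts the forward model at a single concentration by
minimising the integrated squared residual

$$\Delta = \int_{200\,\mathrm{nm}}^{800\,\mathrm{nm}}
  \left[R_\mathrm{meas}(\lambda) - R_\mathrm{model}(\lambda)\right]^2
  d\lambda$$

(trapezoidal quadrature).  The residual is affine in $(c_B, c_{AB})$ --
rescaling, broadening and the background are all linear -- but nonlinear
in $s$, so the search splits into an outer deterministic 1D search over
$s$ (51-point grid on $[0, 0.05]$ plus golden-section refinement) and, for
each $s$, an exact constrained 2-parameter linear solve
($c_B, c_{AB} \ge 0$, $c_B + c_{AB} \le 1$; the candidate set is the
unconstrained stationary point, the clamped edges and the vertices).  The
whole fit is deterministic and takes well under a second on the default
301-point grid.  A forward model in which filling does not change the
spectrum at all (for instance if the condensate had the index of air) is
refused as non-identifiable rather than silently returning zeros.

The fit is performed at the largest measured concentration
(`x_fit = 0.5`) and extrapolated downward with `linearize_in_x()`, which
assumes each parameter is proportional to the vapour concentration;
fitting each concentration separately is equally possible by calling
`fit_state()` per spectrum.

Peak positions are read with 3-point parabolic interpolation
(`peak_wavelength()`), since the 2 nm grid is coarse against the few-nm
vapour-induced shifts; `peak_shift()` flags maxima on the search-window
edge instead of returning a meaningless value.

```{r}
model <- relative_spectrum_model(dorsal_geometry(), media,
                                 background_line(0.05, 5e-5), sigma = 15)
truth <- state_at_x(fit_coefficients(0.08, 0.08, 0.016), 0.5)
measured <- model$predict(truth)        # noise-free synthetic spectrum
fitted <- fit_state(measured, model, x_fit = 0.5)
fitted
```

## The DSA module

`dsa_average()` implements direct-space averaging for cross-sectional
images: for every interior void of the analysed "A" layer the image is
shifted so the void sits at the window centre, rotated so the line through
its left and right neighbours is horizontal, rescaled so the neighbour
distance maps to a common reference (the median distance, robust to
outliers), and the transforms are accumulated pixel by pixel with bilinear
resampling in the order shift → rotate → scale.  Layer waviness and
spacing jitter are thereby transformed out of the average.  Gray values
are averaged raw, without per-sub-image normalisation; the leftmost and
rightmost voids never contribute as centres because the transform needs
both neighbours.  The window defaults to 1.5 × the reference distance wide
and 0.75 × tall, enough to show both neighbouring voids and the adjacent
"B" bands.  Source pixels falling outside the image contribute their
clamped edge value and are flagged in a coverage mask rather than silently
mixed in.

`detect_void_centers()` is deliberately simple plumbing (real analyses may
supply hand-marked centres): band-restricted column profiles, heavier
smoothing for peak finding, lighter smoothing with an iterated
narrow-window centroid for sub-pixel refinement.  Inverted images (dark
voids) are flagged via a band-mean heuristic, not silently corrected.
`dsa_linecut()` rescales a row of the average to [0, 1]; constant rows are
returned as zeros with an explicit flag.

## The synthetic generators

`generate_tem_image()` renders the morphology a sectioning TEM would show:
alternating bands, bright elliptical voids at jittered spacings, mid-gray
channel marks (the projection of partial-thickness air through a thin
slice), a shared sinusoidal waviness, and additive Gaussian noise -- three
gray levels plus noise, which is sufficient to exercise every DSA
contract.  It does **not** emulate electron-optical contrast formation,
focus gradients or staining artefacts, so passing DSA tests demonstrate
correctness of the registration/averaging machinery, not robustness to
every real TEM pathology.  Channel placement is either correlated
(`above_wall`, channels above the chitin walls, as observed in real
scales) or `random`, giving the null case against which the correlation
statistic is validated.

`generate_spectra_series()` runs the forward chain for a series of
concentrations and applies mean-one multiplicative lognormal noise
(reflectance ratios are positive, so lognormal is the natural choice; the
study this emulates reports no noise model).  Both generators are pure
functions of their parameters and seed, and leave the caller's RNG stream
untouched.

## Problem sizes and determinism

All spectra live on the 200–800 nm grid in 2 nm steps (301 points).  The
test suite uses synthetic images of roughly 1500–3000 × 330 px with 15–30
voids per layer -- comparable to the ~36 voids available in a real
cross-sectional micrograph -- and 20–50 seeded replicates for the
stochastic properties.  Every random draw in the package and its tests is
seeded; the acceptance script's quantities are deterministic (noise-free
forward generation), so its output is identical for every seed.

## Known limitations

* The 1D effective-medium reduction ignores lateral scattering entirely;
  it is adequate for normal backscattering in the visible but not for the
  UV or for angle-resolved questions.
* The melanin background is linear in wavelength; real eumelanin and
  pheomelanin absorption curves are not, and matching measured whole-wing
  line shapes exactly would require fitting those curves and the
  broadening width.
* Swelling rescales the spectrum rather than re-solving the enlarged
  structure; for sub-percent swelling the two are equivalent to first
  order.
* The filling model has three global parameters; it cannot express
  void-size-dependent filling within one layer.
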