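---
title: "Quantifying two-channel puncta proximity and junction morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-channel puncta proximity and junction morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(punctaprox)
```

## The problem

Super-resolution (STED-class) imaging of two immunolabelled proteins — here
motivated by the mechanosensitive channel PIEZO1 and the junctional adhesion
molecule PECAM1 in endothelium — produces two punctate channels at roughly
50 nm resolution. The biological question is whether the two proteins sit
close enough to interact, and the measurable quantity is the distribution of
distances between puncta of one channel and their nearest neighbours in the
other. Because each localisation carries error, even truly coincident
molecules produce a spread of non-zero distances; the analysis therefore
fits an explicit localisation-error distance model rather than reading
distances off directly.

`punctaprox` implements that analysis end to end: puncta detection in the
style of ImageJ's Analyze Particles, windowed nearest-neighbour distance
collection, and the mixture distance-distribution fit with confidence
intervals and a degeneracy diagnostic. A second, independent track provides
junction morphometry: junction width as a Gaussian full width at half
maximum (FWHM), staining organisation as the coefficient of variance (CoV)
of line profiles, background-normalised junctional intensity, and the
Boltzmann sigmoid used for pressure–response curves. A synthetic-data
module generates point patterns and rendered images with known ground
truth, so every stage is testable without raw data.

## The distance model

The distance $r$ between two points whose coordinates carry isotropic 2D
Gaussian error follows the Rice-type density

$$DD(r) = \sum_{k=1}^{2} A_k \frac{r}{\sigma_k^2}
  \exp\!\left(-\frac{\mu_k^2 + r^2}{2\sigma_k^2}\right)
  I_0\!\left(\frac{r\,\mu_k}{\sigma_k^2}\right),$$

where $\mu_k$ is the characteristic true separation of component $k$,
$\sigma_k$ the combined two-channel localisation dispersion, $A_k$ the
component amplitude, and $I_0$ the modified Bessel function of integer
order zero. For $\mu \to 0$ a component reduces to the Rayleigh density
$(r/\sigma^2)\exp(-r^2/2\sigma^2)$; the density integrates to $A_1 + A_2$,
so on a density-normalised histogram the amplitudes play the role of
mixture proportions. Two components capture the empirically observed
structure of junctional data: a frequent short-range mode and an
occasional longer-range one.

```{r density}
p <- mixture_params()   # a1 0.7, a2 0.3, mu 34/169 nm, sigma 10/40 nm
r <- seq(0, 0.4, length.out = 400)
plot(r, dd_density(r, p), type = "l", xlab = "distance (µm)",
     ylab = "density (1/µm)")
```

Numerically, the product of the exponential and $I_0$ overflows for large
$r\mu/\sigma^2$; the implementation always evaluates
$\exp(-(r-\mu)^2/2\sigma^2)\,\tilde I_0(r\mu/\sigma^2)$ with the
exponentially scaled Bessel function $\tilde I_0(x) = e^{-x}I_0(x)$, which
is stable across the whole parameter range.

## From images to distances

The detection chain mirrors the established ImageJ workflow, in physical
units throughout:

1. **Gaussian blur**, sigma 0.015 µm by default (0.75 px on the 0.02 µm/px
   raster the defaults assume).
2. **Rolling-ball background subtraction**, radius 3 px (0.06 µm),
   implemented as grayscale opening with a non-flat ball structuring
   element whose depth is scaled to the image intensity range. This is the
   morphological reading of the sliding-paraboloid operation; the
   paraboloid refinement is approximated by the ball.
3. **Thresholding** with Otsu's method on the preprocessed image by
   default. The classical particle-analysis workflow presupposes a
   threshold without fixing one; Otsu is the standard parameter-free
   choice, and an explicit numeric threshold can be supplied instead.
4. **Connected components** with 8-connectivity, filtered by area
   (default 0–0.02 µm², i.e. up to 50 px) and circularity
   ($4\pi A / P^2$, clipped to 1 because discrete perimeters of tiny
   objects can push the ratio above 1). The perimeter is the length of the
   component's marching-squares boundary polygon.
5. **Centres of mass on the raw image** — preprocessing decides *which*
   pixels form a particle, but positions are measured on unmanipulated
   intensities.

Pixel (row $i$, col $j$), 1-based, maps to physical
$x = (j-\tfrac12)\,\Delta$, $y = (i-\tfrac12)\,\Delta$ with $\Delta$ the
pixel size; all exported coordinates are in µm.

Nearest-neighbour distances use a **square, per-axis window** (default
0.5 µm in X and in Y): for each query particle, references within the
window are candidates and the minimum Euclidean distance is kept. A square
window means recorded distances can reach $0.5\sqrt2$ µm, and the fit
range covers that support. Queries with no candidate are counted as
excluded, not silently dropped. Matching is many-to-one; no deduplication
is applied. Distances from multiple images are pooled before fitting by
default (per-image fitting remains available by running the pipeline per
image): pooling matches the single-histogram formulation of the analysis.

```{r nn}
pat <- generate_point_pattern(
  synth_truth(mixture_params(), n_pairs = 800, clutter_density = 0.05,
              field_size = c(10, 10), seed = 2))
a <- subset(pat$points, channel == "A")
b <- subset(pat$points, channel == "B")
nn <- nearest_neighbour_distances(a, b, window_um = 0.5)
glance(nn)
```

## Fitting, confidence intervals, degeneracy

The model is fitted to the density-normalised histogram (default bin
width 10 nm, chosen to resolve a ~34 nm mode with at least three bins) by
bounded Levenberg–Marquardt least squares at the bin midpoints.
Initialisation takes the two most prominent maxima of a lightly smoothed
histogram as starting $\mu$ values (mode and 3× mode if only one peak is
found), $\sigma$ at twice the bin width, and solves the amplitudes
linearly; up to five perturbed restarts are tried on non-convergence, and
the convergence flag is reported honestly. Components are reported with
$\mu_1 \le \mu_2$.

Bins are **Poisson-weighted by default**: the density estimate of a bin
with count $c$ has standard error $\sqrt{c}/(n\,\Delta r)$, and weighting
residuals by its reciprocal makes the covariance-derived intervals
approximately calibrated. This was a measured choice: on simulated fits at
$n = 10{,}000$, unweighted least squares — the default behaviour of
generic curve-fitting routines — produced 95% intervals for $\mu_1$ about
3.6× narrower than bootstrap intervals, with 30% empirical coverage,
whereas Poisson weighting achieves ~85% coverage. Unweighted fitting
remains available as an option.

95% confidence half-widths are $1.96\sqrt{\mathrm{diag}(\Sigma)}$ with
$\Sigma$ the covariance of the least-squares solution (no
degrees-of-freedom t-correction; with dozens of bins the difference is
negligible). A fit is flagged **degenerate** when any active parameter's
half-width exceeds the magnitude of its estimate — the model is then
uninformative, which is exactly what unpaired scatter produces:

```{r degenerate}
tr <- synth_truth(mixture_params(), n_pairs = 0, clutter_density = 5,
                  field_size = c(10, 10), seed = 3)
pat <- generate_point_pattern(tr)
nn0 <- nearest_neighbour_distances(subset(pat$points, channel == "A"),
                                   subset(pat$points, channel == "B"))
fit0 <- fit_distance_model(build_histogram(nn0), n_components = 2)
glance(fit0)
```

```{r fitplot}
s <- sample_displacement_distances(mixture_params(), n = 10000, seed = 4)
fit <- fit_distance_model(build_histogram(s$distance_um), n_components = 2)
tidy(fit)
autoplot(fit)
```

## What the synthetic generator does and does not emulate

The generator is the package's study-condition definition, not a
convenience fixture. Channel-A points are placed uniformly (or along a
junction polyline with 0.05 µm transverse jitter); each paired channel-B
point is displaced by a draw from the mixture law — component chosen by
amplitude, true offset of length $\mu$ in a uniform direction, isotropic
Gaussian noise of per-axis $\sigma$. The full two-channel dispersion is
applied to the B point only; only the relative displacement matters
downstream, so this is mathematically equivalent to splitting the error
between channels. Unpaired clutter is homogeneous Poisson in each channel
(default 0.05 µm⁻²; 5 µm⁻² emulates dense unpaired scatter). Rendering
integrates a Gaussian PSF (default $\sigma$ 0.02 µm, matching ~50 nm
optical FWHM) exactly over pixel areas, adds a constant background rate,
and applies per-pixel Poisson noise; defaults are 500 expected photons per
punctum over a background of 1 count/pixel on a 20 × 20 µm field at
0.02 µm/px. The default mixture truth reuses the characteristic distances
a junctional two-protein analysis reports (34 and 169 nm); the
dispersions (10 and 40 nm) and proportions (0.7/0.3) are this package's
own choices of a realistic regime, since only the characteristic
distances are published.

Not emulated: 3D structure, drift, chromatic aberration, depletion-beam
physics, spatially varying background, and label-specific blinking.
Passing tests on synthetic data therefore validate the *estimator chain*,
not the acquisition physics of any particular microscope.

One property of the estimator deserves emphasis. At high puncta density,
windowed nearest-neighbour distances are **biased towards short range**:
a query's true long-range partner is occasionally pre-empted by an
unrelated nearer punctum. At 5 pairs/µm² (2,000 pairs on a 20 × 20 µm
field) this depresses the fitted $\mu_2$ by roughly 10–15% while leaving
$\mu_1$ essentially unbiased — short-range partners are rarely pre-empted
(the probability that unrelated scatter of density $\rho$ intrudes within
$r$ is $1-e^{-\rho\pi r^2}$, about 2% at 34 nm but about 36% at 169 nm at
this density). The end-to-end recovery checks run at exactly these
conditions and their 15% tolerance absorbs, barely, a bias that is a
property of the windowed-NN measurement itself, not of the fitting. Users
comparing $\mu_2$ across conditions with different puncta densities
should keep this in mind.

## Junction morphometry

Line profiles are sampled by bilinear interpolation at pixel-size spacing,
averaged over the line width. Junction width is the FWHM,
$2\sqrt{2\ln 2}\,\sigma$, of a Gaussian fitted **with a constant offset
term**: junction profiles sit on non-zero background, and omitting the
offset inflates the width; the convention is recorded in the output.
Organisation is the coefficient of variance of the trace after division
by its minimum ("normalised to minimum" read as division — an additive
reading would make the statistic depend on an arbitrary zero), using the
sample ($n-1$) standard deviation, the spreadsheet convention; both
choices are surfaced in the documentation because the originating
workflows leave them unstated. Junctional intensity is the mean inside a
junction mask (derived from the marker channel by smooth → Otsu →
dilate) divided by the mean background, invariant under global gain.
Pressure–response curves use the Boltzmann sigmoid
$y = A_2 + (A_1 - A_2)/(1 + e^{(x - x_0)/dx})$; since swapping
$A_1 \leftrightarrow A_2$ while negating $dx$ leaves the curve unchanged,
fits are canonicalised to $A_1 \le A_2$ so that the sign of $dx$ encodes
orientation.

```{r morpho}
spec <- render_spec(pixel_size_um = 0.05, seed = 6)
jr <- generate_junction_image(ridge_sigma_um = 0.35 / (2 * sqrt(2 * log(2))),
                              amplitude = 100, baseline = 10, noise_sd = 10,
                              spec = spec, field_size = c(4, 4))
prof <- extract_line_profile(jr$image, c(0, 2), c(4, 2))
gaussian_fwhm(prof)
profile_cov(prof)
```

## Numerical and design notes

* **Degenerate inputs.** Empty images segment to empty particle tables
  (not errors); queries without neighbours are tallied in `n_excluded`;
  an empty distance sample refuses histogramming with a pointer to that
  diagnostic; flat profiles refuse Gaussian and Boltzmann fits rather
  than returning junk.
* **Edge conventions.** Particles exactly on a polygon edge count as
  inside (even-odd rule); histogram bins are right-open; area and
  circularity filters are inclusive on both ends, so widening a filter
  can never drop a particle.
* **Connectivity.** Components are 8-connected, the particle-analysis
  default.
* **Determinism.** Every generator is a pure function of (parameters,
  seed); pipeline reports embed the configuration hash, seed, stage
  parameters and package version, and existing outputs are not
  overwritten unless forced.
* **Problem sizes.** The validation suite runs its recovery studies at
  2,000 rendered pairs per field, 10,000 sampled distances per fit and
  20-seed ensembles — sizes at which Monte-Carlo error is well below the
  tolerances being checked while the whole suite stays desk-scale.

## Known limitations

* Centre-of-mass localisation only; no sub-pixel PSF-model fitting, no
  single-molecule reconstruction.
* The binned least-squares fit is not a maximum-likelihood fit of the raw
  distances; for very small samples the binning choice matters.
* The windowed-NN density bias described above; no correction is applied
  because the established workflow applies none.
* No cross-correlation or Ripley-K colocalisation statistics; no 3D.
* Junction scan lines are user-supplied or generated at fixed spacing;
  there is no automatic junction tracing.
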