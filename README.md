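# punctaprox

Quantifies how close two punctate protein channels sit in two-colour
super-resolution (STED-class) fluorescence images, and measures junction
morphometry from the same kind of data. The package was built around the
question of whether the mechanosensitive channel PIEZO1 localises with the
adhesion molecule PECAM1 at endothelial cell–cell junctions, but every
operator is generic two-channel image analysis.

## What it computes

**Proximity track.** Puncta are segmented per channel (Gaussian blur →
rolling-ball background subtraction → threshold → connected components
with area and circularity filters), centres of mass are measured on the
raw images, and for each query punctum the nearest reference-channel
punctum within a square per-axis window (default 0.5 µm in X and Y) gives
one distance. The distance histogram is then fitted with a two-component
localisation-error distance law:

    DD(r) = A1 (r/σ1²) exp(−(µ1² + r²)/(2σ1²)) I0(r µ1/σ1²)
          + A2 (r/σ2²) exp(−(µ2² + r²)/(2σ2²)) I0(r µ2/σ2²)

where µk are characteristic separations, σk the combined two-channel
localisation dispersions and I0 the modified Bessel function of order
zero. Fits carry a covariance matrix, 95% confidence intervals
(1.96·SE), and a *degenerate* flag raised when any parameter's confidence
half-width exceeds its estimate — the signature of data without paired
structure.

**Morphometry track.** Junction width as the full width at half maximum
(2√(2 ln 2)·σ) of a Gaussian fitted to perpendicular line profiles;
staining organisation as the coefficient of variance of min-normalised
traces; junctional intensity normalised to background via masks derived
from a marker channel; and Boltzmann sigmoid fits
y = A2 + (A1 − A2)/(1 + exp((x − x0)/dx)) for pressure–response curves.

**Synthetic data.** A generator produces paired two-channel point
patterns from a known mixture truth, renders them with an integrated
Gaussian PSF and Poisson noise, and builds straight-ridge junction images
of known width — so every stage of the analysis can be validated against
ground truth without any raw data.

## Worked example

Simulate a junctional field whose ground-truth mixture has characteristic
distances 34 nm (70%) and 169 nm (30%), render and analyse it end to end:

```r
library(punctaprox)

truth <- synth_truth(mixture_params(), n_pairs = 2000,
                     clutter_density = 0.05, field_size = c(20, 20),
                     seed = 42)
report <- run_proximity_pipeline(proximity_config(truth = truth, seed = 42))
report
#> <proximity_report> 3872 particles, 1 region(s), seed 42
#>   all: mu1 = 33.8 nm, mu2 = 145.5 nm

fit <- report$regions$all$fit
fit
#> <dd_fit> 2-component distance-distribution fit (n = 1936)
#>   mu1 = 0.03384 um (+/- 0.000581), sigma1 = 0.01217 um, a1 = 0.698
#>   mu2 = 0.1455 um (+/- 0.00413), sigma2 = 0.04469 um, a2 = 0.284
#>   residual SS 34.21; converged: TRUE; degenerate: FALSE

tidy(fit)
#> # A tibble: 6 × 5
#>   term   estimate std.error conf.low conf.high
#> 1 a1       0.698   0.0156     0.668     0.729
#> 2 a2       0.284   0.0101     0.264     0.304
#> 3 mu1      0.0338  0.000296   0.0333    0.0344
#> 4 mu2      0.146   0.00211    0.141     0.150
#> 5 sigma1   0.0122  0.000234   0.0117    0.0126
#> 6 sigma2   0.0447  0.00149    0.0418    0.0476
```

The short mode is recovered essentially exactly (33.8 nm against a 34 nm
truth). The long mode reads ~146 nm against a 169 nm truth: at this puncta
density (5 pairs/µm²) the windowed nearest-neighbour measurement itself
biases long separations downward, because a distant true partner is
sometimes pre-empted by an unrelated nearer punctum — see the methods
vignette (`vignettes/proximity-methods.Rmd`) for the quantitative
discussion. `autoplot(fit)` overlays the fitted curve and its components
on the distance histogram.

Unpaired scatter, by contrast, produces a degenerate fit:

```r
glance(fit_distance_model(build_histogram(nn0), n_components = 2))
#> ... converged: TRUE, degenerate: TRUE
```

where `nn0` holds nearest-neighbour distances between two clutter-only
channels (see the vignette for the full snippet).

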