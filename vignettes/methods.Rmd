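---
title: "Models and methods: multi-method cave-site geochronology, dental morphometrics and enamel-proteome screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavechron)
```

`cavechron` integrates the quantitative methods used to date and analyse
hominin fossils recovered from karstic breccias: closed-form U-series
carbonate ages with detrital-thorium correction, coupled US-ESR dating of
dental tissues with an open-system uranium-uptake model, luminescence
central/minimum age models with anomalous-fading correction, a Bayesian
ordered-sequence model for stratigraphic boundaries, crown metric and
tissue-proportion comparisons, enamel-dentine junction (EDJ) semilandmark
morphometrics, and downstream screening of ancient-enamel
peptide-spectrum matches. This vignette records the models, their
assumptions, the numerical choices, and what the synthetic-data
generators do and do not establish.

## 1. U-series carbonate ages

The age of a carbonate sub-sample solves the standard single-stage
ingrowth equation in activity-ratio form,

$$\left(\tfrac{^{230}\mathrm{Th}}{^{238}\mathrm{U}}\right) =
1 - e^{-\lambda_{230} t} +
\left(\tfrac{^{234}\mathrm{U}}{^{238}\mathrm{U}} - 1\right)
\frac{\lambda_{230}}{\lambda_{230}-\lambda_{234}}
\left(1 - e^{-(\lambda_{230}-\lambda_{234})t}\right),$$

with half-lives 75,690 yr (230Th) and 245,250 yr (234U) by default
(`decay_constants()`). The root is found by bisection on t in (0, 10 Myr]
to 1 yr; the near-equilibrium flat region is guarded analytically (ratios
at or above the asymptote raise a "non-finite age" error rather than
returning an arbitrarily old age). Uncertainties come from seeded
Monte-Carlo resampling of the measured ratios (default 10,000 draws);
draws beyond equilibrium are counted and reported, not silently dropped.

**Detrital thorium.** `detrital_correct()` subtracts non-radiogenic 230Th
assuming a detrital (230Th/232Th) ratio `r0`. Two conventions ship and
the choice matters at ages where 230Th decay is appreciable:

* `r0_at = "initial"` (default): `r0` is the ratio the detritus carried
  at deposition; the subtracted term decays as
  $e^{-\lambda_{230} t}$. Because the corrected age feeds back into the
  decay factor, the correction is solved as a single monotone-bracketed
  root of the combined equation (the naive fixed-point iteration
  converges too slowly under heavy contamination). Under very heavy
  contamination the combined root function can lose its upper crossing;
  this is flagged as over-correction rather than reported as an age.
* `r0_at = "present"`: `r0` is the present-day detrital ratio and is
  subtracted without a decay factor. This is the quantity an isochron of
  *measured* ratios estimates: plotting (230Th/232Th) against
  (234U/232Th) across coeval sub-samples sharing one detrital component
  gives a line whose intercept on the (230Th/232Th) axis is the
  present-day detrital ratio (`fit_detrital_intercept()`, ordinary least
  squares by default, a weighted variant behind a flag; the regression
  direction is y = (230Th/232Th) on x = (234U/232Th), matching the
  intercept-on-the-230Th/232Th-axis convention).

The package deliberately exposes both because the two quantities are
related by $e^{-\lambda_{230}t}$ and conflating them biases corrected
ages; the synthetic generator `gen_useries_set()` takes the same switch
so round-trip tests are convention-consistent. Over-correction (the
corrected ratio driven negative, or no positive root) is a flagged
result, mirroring the diagnostic behaviour of bulk-Earth corrections on
dirty carbonates; a 50% uncertainty on `r0` propagates into the large
error magnification that motivates isochron-based site values.

Weighted means (`weighted_mean_age()`) are inverse-variance with the
internal error $1/\sqrt{\sum \sigma_i^{-2}}$, the MSWD over n-1 degrees
of freedom, and an MSWD-inflated error (multiplied by the square root of
MSWD when MSWD > 1). Both errors are reported because published weighted
means do not always state which convention their uncertainty follows.

## 2. Coupled US-ESR dating

The ESR equivalent dose comes from a single saturating exponential
(SSE), $I(D) = I_{max}(1 - e^{-(D+D_e)/D_0})$, fit to the additive-dose
curve below a cut-off `d_max` (`fit_sse()`). The nonlinear fit is seeded
by a coarse grid over $(D_0, D_e)$ with the amplitude solved in closed
form (it enters linearly), which makes convergence robust on noisy
curves; errors are by Monte-Carlo refitting, and a `mode = "bayesian"`
random-walk MCMC with flat positive priors returns a full posterior on
$(I_{max}, D_0, D_e)$ for users who prefer the probabilistic framing.

**Uranium uptake.** Dental tissues take up uranium post mortem following
the power-law family $U(t) = U_{final}(t/T)^{p+1}$: p = -1 is early
uptake (closed system), p = 0 linear, large p recent uptake. Two
consequences are implemented exactly:

* the time-integrated dose from tissue uranium is the closed form
  $1/(p+2)$ of the closed-system value (`uptake_fraction_integral()`);
* the present-day U-series ratios of a tissue are uptake-weighted
  averages of parcel-wise ingrowth (`uptake_useries_ratios()`),
  integrated by trapezoid quadrature in the cumulative-uptake variable.
  That substitution makes the integrand uniform in parcel mass, so the
  p -> -1 limit is exact rather than numerically singular.

`us_esr_age()` couples the two: per Monte-Carlo draw, the uptake
exponent of each tissue is solved from its measured (234U/238U) and
(230Th/238U) at the trial age (the initial 234U activity of incoming
uranium is eliminated by back-projecting the tissue's measured value, a
flagged approximation), uranium-borne dose-rate components are scaled by
$1/(p+2)$, and the age is the bisection root of accumulated dose =
equivalent dose. Draws with no root in (0, 3 Myr] are rejected and
counted; more than 20% rejections aborts with diagnostics. The rest of
the 238U chain is assumed in equilibrium, so dose-rate conversion uses
full-chain infinite-matrix constants (`dose_conversion_factors()`), and
beta attenuation for enamel thickness is a configured factor per layer,
not computed from first principles. `external_gamma_geometry()` scales
the infinite-matrix gamma rate by a solid-angle fraction: 1 for a full
sphere of sediment, and a configured fraction (default 0.5, a half-space
after erosion of the covering deposit) for the "current burial" scenario
whose published counterpart shifts ages older by tens of kyr.

## 3. Luminescence ages

`central_age_model()` and `minimum_age_model()` implement the standard
log-dose likelihoods: CAM models log-doses as Gaussian around a central
log-dose with variance (relative error)^2 + OD^2; MAM-3 is the
three-parameter minimum-age mixture (a proportion at the minimum dose,
the remainder a truncated log-normal above it), with `sigma_b` added in
quadrature to grain errors (default 0.2, standing in for the
overdispersion of a well-bleached control when none is available; the
published context reports 23-38% overdispersion but no explicit
sigma_b). MAM maximisation uses multiple starts; the uncertainty on the
minimum dose is a profile-likelihood interval (drop of 1/2 unit), and
optimizer-at-bound fits are flagged. A brute-force grid-search oracle in
the test suite guards the likelihood implementation at small n. MAM-4 is
not implemented; the 3-parameter form is the default for the small
single-grain samples this workflow targets.

`g_value()` regresses the remnant-signal ratio on log10(delay/tc);
`fading_correct()` solves the Huntley-Lamothe relation
$T_{meas} = T\,[1 - \kappa(\ln(T/t_c) - 1)]$, $\kappa = g/(100\ln 10)$,
by fixed-point iteration to 0.01 kyr with Monte-Carlo errors over (age,
g); a correction factor reaching zero (fading too strong for the age) is
outside the method's validity and errors. The correction is applied to
the age, not per grain, and tc defaults to 48 h. Residual doses measured
in bleaching tests are *not* subtracted, following the conservative
published practice.

`assemble_dose_rate()` applies the conventional water-attenuation
factors 1.25 (beta) and 1.14 (gamma) per unit water mass fraction, adds
the internal (40K + 87Rb) component (default 0.84 Gy/kyr for coarse
K-feldspar) and cosmic dose, and propagates first-order errors in
quadrature including the water term. `cosmic_dose_rate()` is a
configured hard + soft parameterization: hard (muon) component 0.21
exp(-0.070 x + 0.0005 x^2) Gy/kyr with x in hg/cm^2, a soft surface
component of 0.11 Gy/kyr absorbed in the uppermost decimetres, an
exponential altitude factor (scale 4.4 km) and a few-percent dipole
geomagnetic-latitude modulation. The constants live in
`cosmic_config()`; tests pin the configured surface value and
monotonicity rather than any published site rate, since at cave-interior
depths the cosmic term is a minor component. The single-grain
acceptance/rejection cascade is upstream of this package: De tables are
taken as already screened.

## 4. Bayesian stratigraphic model

`build_model()` encodes an ordered sequence of units (0 = oldest) on a
calendar scale in kyr before present (larger = older). Latent boundary
ages close every unit from both sides (including outer boundaries, so no
fixed support limit acts as an artificial phase edge); within a unit,
true event ages are uniform between its boundaries, giving the
uniform-phase likelihood $(span)^{-N}$ per unit. The span prior is
p(span) proportional to 1/span on the overall depositional span (the
standard end-effect correction), with `uniform_span` as the alternative;
this freedom moves boundary posteriors by a few kyr, well inside the
tolerance used for the published comparison. Each dated event enters as
a Gaussian centred on its latent true age; minimum/maximum-age estimates
enter through a Gaussian auxiliary variable constrained to lie below/
above the true age. No outlier down-weighting is performed.

Sampling is Metropolis-within-Gibbs over (true ages, auxiliaries,
boundaries), with single-site random-walk proposals scaled by the event
sigmas. Defaults are 4 chains x 50,000 iterations, 20% burn-in, thinning
5; convergence is monitored by split-Rhat per boundary (flagged above
1.05). Events are put in a canonical internal order at model building,
so posteriors are invariant to the input row order under a fixed seed.
The sampler is validated against an independent grid-integration oracle
on a two-event model (posterior mean agreement below 1 kyr) and a
frequentist calibration study (68% intervals over synthetic sequences).

For the bundled three-unit cave sequence (silty clay below, fossiliferous
breccia with five direct ages, capping flowstone as a minimum age), the
luminescence dates are entered as Gaussian direct ages - matching how
they were published - although single-grain sediment ages in a karst
flood deposit are arguably maxima; a `role = "maximum"` entry reproduces
that reading if wanted. The defaults reproduce the published boundary
posteriors within their stated tolerance.

## 5. Dental crown metrics and tissue proportions

`adjusted_z()` is the t-based tolerance-band score
$[(x-m)/(s\sqrt{1+1/n})]/t_{crit}(n-1)$ for comparing one specimen with
a small reference sample; the critical value is two-tailed at alpha =
0.05 (the spreadsheet convention of the printed formula, under which
|score| > 1 means outside the 95% band), with a one-tailed option behind
a flag. `tissue_proportions()` computes the percent crown dentine
Vcdp/Vc, 3D average enamel thickness AET = Ve/SEDJ, and scale-free RET =
100 AET / Vcdp^(1/3). `thickness_map()` measures, for every outer-enamel
vertex, the minimum point-to-triangle distance to the EDJ: nearest-point
distance rather than normal-ray casting, which is robust on wrinkled
crowns but a documented convention difference from some commercial
tools. `hmh_threshold()` is the half-maximum-height midpoint between two
material grey-value peaks, with a batch variant over repeated slices.
The crown-cervix cropping plane of real AET/RET protocols is not printed
anywhere usable; the synthetic crown generator therefore defines its own
closed surfaces end to end, so volume/area tests are self-consistent.

## 6. EDJ semilandmark morphometrics

The 94-point configuration is 4 dentine-horn landmarks (protoconid,
metaconid, entoconid, hypoconid), 60 marginal-ridge semilandmarks in
segments of 12/12/24/12 between consecutive horns, and 30 cervix
semilandmarks. Shared cusp points belong to the anatomical set and are
not double-counted - that is the only reading under which the published
counts total 94. Curves are cubic splines reparameterised by arc length
(`resample_curve()`); semilandmarks are equally spaced along each
segment. No bending-energy or minimum-Procrustes sliding is applied: the
source protocol projects resampled points without stating sliding, so
equal arc-length spacing is adopted and flagged as a convention.

`gpa()` removes translation, scale (unit centroid size) and rotation by
iterative alignment to the evolving mean (rotations only - mirrored
specimens must be reflected explicitly via `build_template(mirror =
TRUE)`, which records chirality). Tangent-space coordinates are the
aligned configurations; Procrustes distance is Euclidean there.
`shape_pca()`, `bgpca()` (PCA of equally weighted group means, with
strict a-posteriori projection of unknowns) and `cva()` (canonical axes
of between- over pooled-within covariance, whitened so Mahalanobis
classification is Euclidean in canonical space, equal priors) follow the
standard morphometric conventions; `select_pcs()` implements the
"first PCs explaining ~90% of variance" rule. Classification priors are
equal because the published analysis does not state sample-size priors.
`cross_validate()` refits the ordination without each held-out specimen
before projecting it, so reported rates are honest. Missing cervix
regions are not imputed; complete curves are required.
`allometry_regression()` regresses each ordination axis on centroid size
with permutation p-values (classical F as fallback at `n_perm = 0`).

## 7. Enamel-proteome screening

All sequence matching treats I and L as equivalent
(mass-indistinguishable). `ptm_rate()` is relative spectral counting:
PSMs carrying the modification on a target residue over PSMs containing
any target residue, blanks excluded; a zero denominator is reported as
undefined, not zero. `phospho_motif()` tallies residues at offsets -5..+5
around phospho-serines and the fraction of sites with E at +2 (the S-x-E
motif); sites whose +2 position falls outside the peptide leave the
denominator. `diagnostic_coverage()` applies the fragmentation-support
gate (spectra without site support are excluded), flags conflicting
supported residues, and intersects per-site compatible lineage sets into
the most exclusive call; when only hominin-versus-ape sites resolve, the
call is "genus Homo, within-Homo indeterminate". `amely_screen()` reports
"male" on an AMELY-specific match and otherwise "female or degraded
beyond detection" - never a bare female call, because absence of
evidence is degradation-confounded in ancient enamel. Proteins with a
single distinct peptide and listed contaminants are removed by
`filter_psms()` before statistics; the diagnostic panel is data, not
hard-coded biology, and the bundled panel (`synth_protein_set()`) is
synthetic and labelled as such. Site support is the sole
high-confidence gate; a score column is read but unused.

## 8. Synthetic data: what a green test establishes

Every generator is seeded, bit-reproducible, and emits its ground truth.
Defaults are chosen to match the published setting where one is stated
(SSE D0 600 Gy and De 500 Gy inside the reported 400-2000 Gy / 600-1000
Gy ranges; overdispersion 0.25 inside 23-38%; burial dose 500 Gy;
partial bleaching 70/30 up to 1500 Gy; g-value series built around 2.0
%/decade; the three-unit event table uses the printed ages verbatim) and
to a field-plausible value where none is (10% single-grain measurement
error; 2% isotope-ratio noise; a 4-cusp crown of 8 mm width, 0.5 mm
enamel). The crown generator builds the EDJ as a smooth superellipsoidal
dome with planform-Gaussian cusp bumps - the bump width is fixed in mm,
not in angle, so surface curvature stays bounded at the apex - and the
outer enamel surface as a positive normal offset; offsets that would
self-intersect (thickness exceeding local curvature radius) error
instead of producing a broken mesh. Truth volumes and areas are measured
on a 4x-refined mesh of the same surfaces.

The generators emulate the *statistical structure* each method assumes:
coeval sub-samples with one shared detrital component, SSE curves with
multiplicative noise, log-normal plus inflated De mixtures, uniform
within-unit event ages, isotropic landmark noise, Bernoulli PTM
assignment. They do not emulate instrument drift, spatial U-series
heterogeneity within tissues, non-isotropic shape covariance, or real
spectral quality - so green tests establish correctness of the
estimators under their own assumptions, not robustness to every field
pathology. The bundled event table is the one place real published
numbers enter the tests.

## 9. Numerical choices and limitations

* Bisection everywhere a root is needed (age equations, dose balance):
  robust against the flat near-equilibrium region, tolerance 1 yr (ages)
  or 0.01 kyr (corrections).
* The detrital correction solves a bracketed upper root; genuinely
  ambiguous (beyond-equilibrium) inputs are flagged, not guessed.
* MCMC is plain R Metropolis-within-Gibbs; the default 4 x 50k run takes
  about a minute on one CPU for the bundled sequence. Heavier models
  would warrant a compiled sampler.
* Mesh operations are exact point-to-triangle distances at O(vertices x
  faces); adequate for the test-scale meshes, not for scan-resolution
  surfaces.
* The US-ESR coupling assumes the power-law uptake family and full-chain
  equilibrium; open-system leaching (measured 230Th/234U above 1) must
  be handled upstream, as in the published workflow where a dentine
  ratio was substituted.
* Uncertainties are 1-sigma throughout; readers accept a `sigma_level`
  column for 2-sigma tables.
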