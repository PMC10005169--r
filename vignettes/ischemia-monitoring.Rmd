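---
title: "Out-of-distribution ischemia monitoring from multispectral laparoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Out-of-distribution ischemia monitoring from multispectral laparoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During laparoscopic partial nephrectomy the renal artery is clamped before
tumor resection, and the surgeon must verify that the kidney has actually
become ischemic. The clinical standard uses an injected fluorescent contrast
agent with a washout period of roughly half an hour, so a failed clamping
attempt cannot be re-checked promptly. A snapshot-mosaic multispectral camera
(16 bands in a repeating 4x4 filter pattern on a 272x512 sensor) mounted on a
standard laparoscope offers a contrast-agent-free alternative: hemoglobin
dominates visible-light absorption in internal organs, and ischemia lowers
both tissue oxygenation and blood volume, so the per-pixel 16-band
reflectance spectrum carries the perfusion signal.

The statistical obstacle is inter-patient heterogeneity. In spectral
measurements of diseased kidneys, most variance is attributable to the
patient rather than to the perfusion state, so a supervised classifier
trained across patients generalizes poorly. `msimon` instead treats ischemia
detection as a **per-patient out-of-distribution (OoD) problem**: a density
model of *perfused* spectra is trained on a short video sequence from the
patient on the table, and later spectra are scored by how atypical they are
under that model. No other patient's data enter the decision.

## The ischemia index

The density estimator is an ensemble (default n = 5) of RealNVP-style
**affine coupling flows**, invertible maps $f_\Theta : \mathbb{R}^{16} \to
\mathbb{R}^{16}$ trained so that the latent variable $z = f_\Theta(x)$ is
standard normal. The exact log likelihood follows from the change of
variables,

$$\log P(x \mid \Theta) = -\tfrac12 \lVert f_\Theta(x)\rVert_2^2
  - \tfrac{n}{2}\log(2\pi) + \log\left|\det J_{f_\Theta}(x)\right|,$$

and ensemble members differing only in their random seed supply the moments
of the **widely applicable information criterion**

$$\mathrm{WAIC}(x) = \mathrm{Var}_\Theta[\log P(x \mid \Theta)]
  - \mathrm{E}_\Theta[\log P(x \mid \Theta)].$$

A spectrum is flagged as OoD either because its estimated density is low or
because the members disagree about it — the latter matters in regions the
training data never populated. Per frame, WAIC values of all valid pixels in
each of two tracked 30x30 regions of interest (ROIs) are aggregated by the
median, and the two ROI medians are averaged into the frame-level **ischemia
index**; higher means more ischemic. For presentation, the index is min-max
normalized per patient over all evaluated frames (a strictly monotone map,
so ranking metrics are unchanged). Separation between the perfused and
ischemic test sequences is quantified by the AU-ROC with ischemic as the
positive class, computed by the exact rank (Mann-Whitney) statistic with
ties counted one half.

Two conventions were open and are fixed here as follows. The WAIC variance
is the *population* variance over the members (the criterion is a moment of
the parameter distribution, not a sample estimate; `var_type = "sample"` is
available). Min-max normalization pools both test sequences of a patient,
since the index is compared across them.

## Flow architecture and training

Each coupling block applies a fixed random channel permutation, splits the
vector into halves, and transforms one half affinely with scale and shift
produced by a 3-layer fully connected ReLU subnetwork conditioned on the
other half. Log-scales are soft-clamped, $s = c \tanh(s_{\mathrm{raw}}/c)$
with $c = 2$, for numerical stability. Defaults follow the full-scale
profile (20 blocks, 256 hidden units); cohort studies use a reduced profile
(8 blocks, 64 hidden units, at most 2000 training spectra per patient) that
preserves behavior at a fraction of the cost, with `paper_scale = TRUE`
restoring the full setting.

Training minimizes the negative log likelihood with Adam (learning rate
1e-3, weight decay 1e-4, batch size 512), with additive Gaussian noise
augmentation (SD 0.05 in normalized units). Training data are z-score
normalized; the statistics are frozen into each flow and their Jacobian is
included in the likelihood. The ensemble is optionally pretrained on
simulated tissue spectra (100 epochs) and then fine-tuned on the patient's
perfused pixel spectra (10 epochs); the z-score statistics are re-estimated
from the patient data at fine-tune time so that inference is calibrated to
the patient's own distribution. All stochastic elements — initialization,
permutations, batch order, noise — derive from a per-member seed, so any
training run is exactly reproducible. Gradients are computed by an explicit
reverse pass through the coupling algebra; the test suite checks them
against finite differences, and the log-determinant against a numerical
Jacobian.

The final subnetwork layer is initialized near zero, so an untrained flow
starts close to the identity map on z-scored data — a well-calibrated
Gaussian initial density that makes the short intraoperative fine-tuning
schedule stable.

## Preprocessing

Raw mosaic frames are collapsed into 16-band cubes by 4x4 tile collapse
without spatial interpolation (the cube is 68x128 for the full sensor);
interpolation is cosmetic and irrelevant for density estimation. The
band-to-offset assignment of the mosaic is a configurable field of the
camera model (default row-major), since correctness is layout-conditional.
Counts are normalized per pixel and band with white/dark Spectralon
references, $(I - D)/(W - D)$, references being averaged over their repeats
first; pixels where $W = D$ are flagged invalid rather than raising. An
$\ell_2$ normalization across bands then removes the dependence on
illumination intensity and working distance. A pixel is valid when all its
bands lie strictly between the under- and oversaturation thresholds
(defaults 5% and 98% of full scale — the rule is from the acquisition
protocol, the thresholds are package choices), and a tracked sequence is
accepted when at least 95% of tracked pixels are valid. Per-pixel normalized
spectra feed flow training and WAIC scoring; per-ROI median spectra feed the
heterogeneity and Beer-Lambert analyses. The median is taken after the
$\ell_2$ normalization (the plausible reading of the processing order; the
alternative ordering differs negligibly for homogeneous ROIs). ROI tracks
are inputs here: the deep-feature tracker used on real recordings depends on
pretrained weights and is out of scope.

## Simulated tissue spectra

Pretraining data come from Monte-Carlo photon transport through three
infinitely wide slabs. Per layer, absorption follows the hemoglobin mixing
rule
$\mu_a = v_{hb}\,[s\,\epsilon_{HbO_2} + (1-s)\,\epsilon_{Hb}]\,
\ln(10) \cdot 150\,\mathrm{g\,l^{-1}} / 6.45\cdot 10^4\,\mathrm{g\,mol^{-1}}$
and scattering the Mie power law
$\mu_s = a_{mie}/(1-g) \cdot (\lambda/500\,\mathrm{nm})^{-b_{mie}}$.
Layer parameters are sampled uniformly: blood volume fraction 0-30%,
oxygenation 0-100%, reduced scattering at 500 nm 5-50 cm$^{-1}$, scattering
power 0.3-3, anisotropy 0.80-0.95, refractive index 1.33-1.54, thickness
0.002-0.2 cm. The transport kernel (Rcpp) launches photons at normal
incidence from an ambient medium (n = 1, also below the last layer), applies
specular loss at entry, exponential steps with carried optical depth across
boundaries, Henyey-Greenstein scattering, unpolarized Fresnel
reflection/refraction, and Russian roulette below weight 1e-4 with survival
probability 0.1 (standard transport defaults; anisotropy is held constant
per layer across wavelength, the simplest reading of the scalar sampling
ranges). Reported reflectance is the total fraction of launched weight
escaping upward; the suite verifies energy conservation, the Beer
attenuation limit, the zero-absorption limit, monotonicity in absorption,
and agreement with an independent plain-R photon loop.

Simulated spectra are integrated into camera bands as

$$r_k = \frac{\int T(\lambda) I(\lambda) f_k(\lambda) r(\lambda)\,
  d\lambda}{\int T(\lambda) I(\lambda) f_k(\lambda)\, d\lambda},$$

by trapezoidal quadrature on the 2 nm camera grid, where $T$ is the combined
optics transmission, $I$ the illuminant (default flat — the band integral
normalizes a flat illuminant out, and the xenon spectrum is not tabulated
here; a measured curve can be supplied), and $f_k$ the filter responses. The
default synthetic filters are Gaussians with secondary ("second-order")
peaks on bands 6-13, mimicking Fabry-Perot mosaic sensors; amplitudes are
configurable. The hemoglobin extinction table shipped with the package is an
approximate compilation with the standard landmarks (Soret and alpha/beta
bands, isosbestic points near 500/569/800 nm) intended for simulation, not
metrology.

**Problem sizes.** The package's default corpus is 192 samples at 400
photons per wavelength on a 10 nm grid (interpolated back to 2 nm before
band integration), and synthetic sessions use 1500 photons on an 8 nm grid.
These sizes were chosen so a full cohort study runs on a single CPU core in
minutes; the Monte-Carlo noise they leave (well under 1% at band level after
integration) is far below the spectral contrasts of interest. All sizes
scale up by configuration.

## The synthetic session generator

Patient recordings are not publicly deposited, so the package ships a
generator that emulates the acquisition protocol end to end: three sequences
per patient (perfused_1 for training; perfused_2 and ischemic for testing,
both recorded after simulated laparoscope reinsertion), white/dark
references, two drifting non-overlapping ROI tracks per sequence (at most 2
px/frame), saturation defects, and 10-bit quantization. The ischemic state
lowers each layer's oxygenation by 0.30 (absolute) and halves the blood
volume fraction — the direction is ischemia physiology; the magnitudes are
package choices for a "clearly separated" profile. Per-patient variability
comes from the tissue parameter draws plus a smoothed multiplicative
per-band offset (SD 0.08) shared by all of a patient's sequences, which by
construction makes the patient, not the state, the dominant variance
component across a cohort — the regime that motivates the per-patient
approach. A "hard" profile adds one near-null patient; a "null" profile
removes the state difference entirely.

Design choices worth knowing:

* **Common random numbers across states.** The perfused and ischemic
  Monte-Carlo runs of a patient share one seed, so a null profile yields
  bit-identical state spectra and any residual separation measured there
  comes from the downstream noise processes, not from Monte-Carlo noise
  between two runs of the same tissue.
* **Shot-noise-dominated sensor.** Sensor noise is applied proportionally to
  the signal (default SD 1% of signal, SNR 100), matching the high-SNR
  regime of the real device. With a fixed additive noise floor, the noise
  level *relative to reflectance* would depend on the illumination scale,
  and a between-sequence illumination change would by itself be detectable
  as OoD — an artifact, not physiology.
* **Reinsertion is modeled as an illumination intensity rescale (0.85-1.0)
  plus ROI relocation**, not as a spectral tilt. Real pose changes can tilt
  spectra; a systematic per-sequence tilt would make even a null cohort
  separable and is deliberately excluded, which is a limitation to keep in
  mind when reading the null-profile calibration.
* **Static texture is not modeled**: pixel jitter (lognormal, SD 2%) is
  independent across frames and pixels. Real tissue has persistent spatial
  structure; the flows here only need the marginal pixel distribution, so
  this simplification is immaterial for the index but makes the synthetic
  frames unsuitable for testing spatial trackers.

Consequently, a passing synthetic study shows that the pipeline detects
physiological spectral change against realistic per-patient variation,
illumination changes and sensor noise; it does not certify performance
against surface contamination (blood, fat, smoke), specular highlights,
tracking drift, or pathologies that suppress spectral contrast — the
failure modes the real study observed in one patient.

## Beer-Lambert baseline

The model-based comparator regresses band absorbance $a_k = -\log r_k$ on
band-averaged extinction coefficients,
$a_k = \epsilon_{HbO_2,k}\, v_{HbO_2} l + \epsilon_{Hb,k}\, v_{Hb} l + g$,
by ordinary least squares, where the fitted intercept $g$ absorbs scattering
losses (fitting it, rather than fixing it, is the package's choice; the
symbol clashes with the scattering anisotropy only in name). Oxygenation
$s$ and the total product $v_{HbT} l$ follow from the coefficients and are
reported **unclipped** — implausible values such as $s > 1$ are diagnostic
output, not errors. Inputs are ROI-median reflectances *before* $\ell_2$
normalization (absorbance needs physical reflectance; a positive rescaling
only shifts the intercept). On simulated cohorts the oxygenation score
separates states well, while the total-hemoglobin score flips sign from
patient to patient: multiple scattering makes the effective path length grow
as absorption falls, so halving the blood volume does not reliably lower the
fitted product. This mirrors the known unreliability of the linearized model
on such data and is exactly the weakness the WAIC index avoids by learning
the density of measured spectra directly.

## Heterogeneity analysis

Cohort rows are per-frame averages (across ROIs) of median normalized
spectra. `pca_project()` reports centered principal-component scores and
explained-variance fractions; `fit_mixed_model()` fits, per band, the
random-intercept model $r_{ij} = \alpha + \beta S_{ij} + \delta_i +
\epsilon_{ij}$ by REML (`lme4`), with patient effect $\delta_i$ and state
indicator $S_{ij}$. Explained-variability proportions are computed as
$\hat\beta^2 \mathrm{Var}(S)$ (population variance over the design) versus
$\hat\sigma_\delta^2$ versus $\hat\sigma_\epsilon^2$, normalized to sum to
one — a documented default for the fixed-effect contribution, since the
published decompositions differ in detail. Boundary (singular) fits with a
zero variance component are treated as converged; genuine optimizer
failures are flagged and their proportions withheld. State-density overlap
for single patients uses a Gaussian product-kernel KDE with normal-reference
bandwidths on a shared, padded grid.

## Numerical notes and degenerate inputs

* Quadrature is trapezoidal on the camera grid; bands whose weighted
  response integrates to zero raise an error naming the band.
* Mosaic/demosaic are exact inverses; any frame with dimensions divisible
  by 4 round-trips bit for bit.
* Zero pixel spectra, $W = D$ pixels, and saturated pixels become invalid
  pixels, not exceptions; an ROI with no valid pixels raises.
* A frame with only one available ROI falls back to that ROI's WAIC with a
  warning — live monitoring should not halt on a lost track.
* A constant index series cannot be min-max normalized and raises.
* Flow training aborts with advice if the loss turns non-finite.
* `evaluate_auroc()` uses midranks, hence exact tie handling at any size.

## Limitations

The flows, transport kernel, generator and statistics are validated against
analytic limits, independent oracles and property checks, but the synthetic
cohort remains a simulation twin: absolute clinical performance figures
cannot be reproduced without the original recordings. The extinction table
is approximate; users with calibrated tables or measured filter curves
should load them via the CSV interfaces. Sessions are held in memory
(roughly 130 MB per full-sensor patient), which is comfortable for cohort
studies of tens of patients but not for hour-long recordings.
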