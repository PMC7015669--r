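---
title: "Mapping effective axon radii from high b-value diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping effective axon radii from high b-value diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Axon radii in white matter are mostly 0.5–1.5 µm, far below MRI resolution,
and the diffusion-MRI signal of water restricted in a cylinder of radius $r$
attenuates only as $\ln S \sim -r^4$ in the long-pulse regime. Two confounds
have historically dominated attempts to measure radii anyway: orientation
dispersion of the axons, and extra-axonal water whose signal swamps the
intra-axonal contribution at moderate diffusion weighting. This package
implements an analysis that removes both: spherical (powder) averaging of
each b-shell factors out the fiber orientation distribution, and restricting
the fit to high b-values ($b > 6$ ms/µm² in vivo, $b \ge 20$ ms/µm² ex vivo)
suppresses the exponentially decaying extra-axonal signal.

For impermeable zero-radius "sticks" the powder-averaged signal follows the
scale-invariant power law

$$\bar S(b) \simeq \beta\, b^{-1/2} + \gamma, \qquad
  \beta = \sqrt{\pi/4}\, \frac{f}{\sqrt{D_a^\parallel}},$$

with $f$ the T2-weighted axonal water fraction and $D_a^\parallel$ the
parallel intra-axonal diffusivity. A finite radius truncates the power law,

$$\bar S(b) \simeq \beta\, e^{-b D_a^\perp} b^{-1/2} + f_{\rm im},$$

where $f_{\rm im}$ is the fraction of fully restricted ("dot") water and
$D_a^\perp$ the radial intra-axonal diffusivity. Written as a function of
$\xi = 1/\sqrt b$, this curve is concave up to its inflection point
$\xi_* = \sqrt{2 D_a^\perp}$, so a straight-line (pure power law)
extrapolation to $\xi \to 0$ acquires a negative offset
$\epsilon = \gamma - f_{\rm im} \le 0$ with maximal magnitude
$|\epsilon_{\max}| = \beta\sqrt{2 D_a^\perp / e}$: a *negative intercept* is
the hallmark of sensitivity to the inner axon diameter
(`tangent_intercept()` computes these diagnostics). Water exchange instead
produces a *convex* decay $\bar S \simeq \beta(b^{-1/2} + c\,b^{-3/2}) +
f_{\rm im}$, which is how gray matter distinguishes itself in the model
comparison.

## From diffusivity to radius

Inside a cylinder the Gaussian-phase-approximation attenuation is the van
Gelderen series (`vangelderen_lnS()`), which for pulse durations long
compared to the correlation time $t_c = r^2/D_0$ reduces to the Neuman limit
$\ln S = -\tfrac{7}{48} g^2 \delta r^4 / D_0$ (`neuman_lnS()`). Writing the
latter as $e^{-b D_a^\perp}$ gives the bidirectional maps

$$D_a^\perp = \frac{7\, r^4}{48\, D_0\, \delta (\Delta - \delta/3)}
  \quad\Longleftrightarrow\quad
  r_{\rm MR} = \Big(\tfrac{48}{7}\, \delta(\Delta - \delta/3)\, D_0\,
  D_a^\perp\Big)^{1/4}$$

(`daperp_from_radius()`, `radius_from_daperp()`). For a distribution $h(r)$
of radii the volume-weighted signal average is dominated by the tail, and the
single quantity MRI can report is the *effective radius*

$$r_{\rm eff} = \big(\langle r^6\rangle / \langle r^2\rangle\big)^{1/4},$$

always larger than the arithmetic mean $\bar r$ (`effective_radius()`,
`mean_radius()`; the narrow-pulse variant
$(\langle r^4\rangle/\langle r^2\rangle)^{1/2}$ sits between the two). The
exponent convention for the narrow-pulse variant is chosen so the statistic
keeps units of length.

## The pipeline

```{r pipeline}
library(axonradius)

protocol <- protocol_preset("connectom")
truth <- phantom_ground_truth(protocol, dims = c(8, 8, 1),
                              radius_range = c(1, 3), seed = 1)
dir <- tempfile()
generate_dwi_phantom(truth, dir)

ds <- read_dwi(file.path(dir, "dwi.nii.gz"), file.path(dir, "dwi.bval"),
               file.path(dir, "dwi.bvec"),
               mask_path = file.path(dir, "mask.nii.gz"),
               sigma_path = file.path(dir, "sigma.nii.gz"))
pa <- powder_average_dataset(ds)                  # Rician-ML spherical means
decay <- spherical_mean_decay(pa$b, pa$S_bar[1, ])
fit <- fit_decay_model(decay, "vii", b_min = 6)   # truncated power law
rmr <- rmr_map(array(fit$params[["Da_perp"]], c(1, 1, 1)), D0 = 2.4, protocol)
```

Stage by stage:

1. **Spherical means** (`spherical_mean_sh()`): each shell's directional
   signals are fit with real, orthonormal, even-order spherical harmonics up
   to degree 6 (28 coefficients for 60 directions) by maximizing the Rician
   likelihood with a known noise level; the spherical mean is
   $c_{00}/\sqrt{4\pi}$. The noise level comes from a noise map or a scalar
   SNR — it is never estimated inside this step.
2. **Dot correction** (`estimate_dot_fraction()`, `dot_correct()`): in fixed
   tissue the immobile-water fraction is estimated from repeated
   parallel-direction measurements at the maximal b-value, normalized by the
   non-diffusion-weighted signal, and subtracted from the decay. Skipping
   this step when $f_{\rm im}$ is genuinely nonzero flattens the decay and
   drives the fitted $D_a^\perp$ down — typically negative, i.e. a severe
   radius underestimate.
3. **Model fitting** (`fit_decay_model()`, `compare_decay_models()`): eight
   candidate decays (power laws with/without intercept and free exponent,
   truncated power law, exchange expansion) are fit by unweighted nonlinear
   least squares and ranked by AICc, with $\Delta\mathrm{AICc} \ge 2$ as the
   evidence threshold.
4. **Radius conversion** (`rmr_map()`): voxelwise $D_a^\perp \to r_{\rm MR}$
   using the supplied axoplasm diffusivity $D_0$; following common practice
   the estimated $D_a^\parallel$ serves as a proxy for $D_0$ (an explicit
   override is available). Negative $D_a^\perp$ voxels are biophysically
   implausible but expected at finite SNR; they propagate as flagged `NA`s
   and their fraction is itself a reported outcome, never an exception.
5. **Feasibility** (`crlb_daperp()`, `minimal_detectable_radius()`): before
   any scan, the Fisher information of the two-parameter truncated power law
   gives a lower bound on the SD of $\hat D_a^\perp$, and a radius grid scan
   returns the smallest radius whose $D_a^\perp$ exceeds $1.96\times$ that
   bound — the protocol's detection floor.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `b_min` | 6 (in vivo), 20 (ex vivo) [ms/µm²] | fit-range lower bound; high enough that extra-axonal signal is negligible |
| `lmax` | 6 | even spherical-harmonic order of the powder average |
| `M` | 20 | van Gelderen series terms; residual checked against 1e-9 |
| `f`, `Da_par` | 0.6, 2.4 µm²/ms (in vivo); 0.8 µm²/ms ex vivo | nominal tissue values entering the CRLB feasibility analysis only |
| `D0` | = `Da_par` | axoplasm diffusivity proxy in the radius conversion |
| `z` | 1.96 | Wald threshold of the detection criterion |
| `k_c` | 1 | proportionality constant of the exchange coefficient; only its product with the residence time is identified |

The multi-start grid of the nonlinear fits is deterministic (β from the
data-implied scale ×{0.5, 1, 1.5}; $D_a^\perp \in$ {0, 1e-4, 1e-3, 1e-2};
$\alpha \in$ {0.3, 0.5, 0.7}; $c \in$ {0, 1, 5}; intercept ∈ {0, min(data)}),
because the objective has a notoriously shallow valley and reproducibility
matters more than speed here.

## The synthetic phantom

`phantom_ground_truth()` + `generate_dwi_phantom()` emulate the two study
acquisitions: the in vivo human protocol (δ/Δ = 13/30 ms, 13 shells at
b = 1–25 ms/µm², 60 directions each, SNR 52 at b = 0) and the ex vivo
protocol (δ/Δ = 7.1/20 ms, 18 shells to b = 100 ms/µm², SNR 195). The exact
18 ex vivo shell positions were never published; the default is a uniform
grid from 2.5 to 100 ms/µm², overridable via `protocol_preset("aeon",
aeon_bvals = ...)`. Voxels are arranged in homogeneous stripes spanning
radii 0.5–3 µm (the histologically plausible range); each voxel mixes an
intra-axonal compartment with radial diffusivity given by the long-pulse
map, a Gaussian extra-axonal compartment, and an optional dot fraction
(ex vivo values run ~8–17%), under a Watson orientation distribution
(default concentration 8, i.e. moderate dispersion). Noise is two-channel
Rician, $|S + n_1 + i n_2|$, so the Rician-ML machinery is exercised against
the true likelihood. Ground truth is written alongside the NIfTI volumes as
a JSON sidecar.

What the phantom deliberately does **not** contain: time-dependent
extra-axonal diffusion, axonal undulation and caliber variation, cell bodies
and astrocytic processes, anatomy, or imaging artifacts (motion, eddy
currents, Gibbs ringing — preprocessing is outside the package's scope).
Passing recovery tests therefore demonstrates that the estimator chain is
correct and efficient under the model's own assumptions, not that those
assumptions hold in tissue. The phantom's radial kernel is the factorized
$e^{-b D_a^\perp}$ form the fitted models assume; the van Gelderen/Neuman
agreement is established separately by the cylinder-model tests.

## Numerical choices

- **Bessel-derivative roots** are bracketed on a fine grid and polished with
  `uniroot` to ~1e-12, then cached; the identity
  $4\sum_m [\alpha_m^4(\alpha_m^2-1)]^{-1} = 7/48$ ties the series to the
  Neuman limit and is verified in the tests.
- **Rician ML fits** use exponentially scaled Bessel functions with
  asymptotic expansions beyond $z = 700$, where R's scaled `besselI`
  underflows.
- **The spherical-harmonic ML estimate** is computed by a damped fixed-point
  iteration that least-squares-fits the Gaussianized pseudo-data
  $y \cdot I_1/I_0(y\nu/\sigma^2)$, starting from the least-squares solution.
  At high SNR the Bessel ratio is 1 and the estimate *is* the least-squares
  fit; at low SNR floor-dominated directions are shrunk toward zero, removing
  the Rician bias of the shell mean. One caveat is inherent to maximum
  likelihood on magnitude data: for very sharply peaked signals whose
  band-limited reconstruction dips negative (a noiseless stick at
  $b D_a^\parallel \gtrsim 10$ fit at degree 6), the even likelihood tolerates
  sign flips and the estimate can sit ~3% below the sphere average of the
  true signal. At the study SNRs and shells the Monte-Carlo bias of the
  estimator is at the 1e-3 level, an order of magnitude below the naive
  directional mean.
- **Watson ODF quadrature** uses a Gauss–Legendre × uniform-azimuth product
  rule (32 × 24 nodes on the hemisphere) rather than a quasi-uniform point
  set: the phantom integrates kernels as sharp as $e^{-80\cos^2\psi}$, where
  a 300-node quasi-uniform set leaves a b-dependent quadrature error of up
  to 0.5% that masquerades as a radius bias. The product rule is spectrally
  accurate for these smooth integrands.
- **AICc** floors a vanishing residual sum of squares at machine epsilon
  (with a flag) instead of returning $-\infty$.
- **Degenerate inputs**: zero radius and zero gradient short-circuit the
  cylinder series exactly; all-zero radius distributions and empty fit
  ranges raise errors; negative fitted diffusivities are flagged, not
  thrown.

## Design decisions that were genuinely open

- **Noise of a shell's spherical mean** in the feasibility analysis is
  Gaussian with SD $\sigma_0/\sqrt{n_{\rm dirs}}$: averaging 60 directions
  makes the mean's distribution near-Gaussian, and no published value pins
  down the alternative. With this model and the documented nominal tissue
  values, the detection floor for the in vivo preset computes to ~2.1 µm —
  noticeably above the 1.41 µm quoted for comparable hardware elsewhere;
  reproducing that figure would require an assumed b = 0 SNR of ~250 rather
  than 52. The package reports what its stated assumptions imply.
- **ROI decays** average voxelwise spherical means (mean, not median) after
  normalization; configurable.
- **The ex vivo nominal axonal fraction** for the feasibility analysis
  defaults to the in vivo value (0.6), there being no published number.
- **Simultaneous (f_im, D_a^⊥) estimation** (model iii) is exposed but the
  two parameters are nearly unidentifiable from linear multi-shell data
  alone; the supported workflow is the dedicated parallel-direction dot
  measurement.
- **Histogram moments** use bin centers, so histology CSVs are unambiguous.

## Problem sizes used by the tests

The test-suite phantoms are 6×6×1 to 12×12×4 voxel grids with the full
shell complement of each preset, and the Monte-Carlo loops use 200–500
realizations; these sizes give stable pass/fail behavior at desk scale while
keeping a full run in the minutes range. The phantom generator's defaults
(20×20×3) are what a user exploring parameter maps would start from.

## Known limitations

- Accuracy degrades for large radii where the Gaussian phase approximation
  itself loses higher-order terms; the package stays at GPA level.
- The radius conversion inherits the fourth-root sensitivity to the assumed
  $D_0$; errors in $D_0$ are damped but not removed.
- Reconstructing the full distribution $h(r)$ from $r_{\rm eff}$ alone is
  ill-posed and deliberately out of scope.
- The exchange coefficient is reported as-is; only $c \propto
  \mathcal{R}\,T_E/D_e^\perp$ is identified, so residence times require an
  assumed $D_e^\perp$ and $k_c$.
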