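# axonradius

Noninvasive mapping of effective axon radii from strongly diffusion-weighted
MRI, for researchers working with multi-shell acquisitions on high-gradient
systems (human Connectom-class scanners in vivo, preclinical systems ex
vivo) and for methodologists validating radius estimation against histology.

## The method

Axons are micrometre-thin, so at ordinary diffusion weightings they behave
as zero-radius "sticks" whose powder-averaged (spherically averaged) signal
follows the scale-invariant power law

    S̄(b) ≃ β b^(−1/2) + γ,      β = √(π/4) · f / √(Da∥),

once the b-range is high enough (b > 6 ms/µm² in vivo, b ≥ 20 ms/µm² ex
vivo) that extra-axonal water is suppressed and powder averaging has
factored out orientation dispersion. A finite axon radius breaks the power
law by truncating it,

    S̄(b) ≃ β e^(−b·Da⊥) b^(−1/2) + f_im,

where Da⊥ is the radial intra-axonal diffusivity and f_im the immobile
("dot") water fraction. Two consequences carry all the information:

- **Negative intercept.** Extrapolating a straight power-law fit of the
  concave truncated decay to 1/√b → 0 yields an intercept γ < f_im, with
  maximal offset |ε_max| = β√(2·Da⊥/e) at the inflection point
  ξ* = √(2·Da⊥). A negative γ is the hallmark of radius sensitivity.
- **Effective radius.** Converting the fitted Da⊥ through the long-pulse
  (Neuman) limit of restricted diffusion in a cylinder,
  r_MR = (48/7 · δ(Δ−δ/3) · D0 · Da⊥)^(1/4), estimates the tail-weighted
  effective radius r_eff = (⟨r⁶⟩/⟨r²⟩)^(1/4) of the underlying axon radius
  distribution — not its mean; dMRI sees the thickest axons.

The package implements the complete chain: Rician maximum-likelihood
spherical means from even-order spherical harmonics; dot-fraction estimation
from dedicated parallel-direction measurements and its subtraction; eight
candidate decay models (power laws, truncated power law, exchange expansion
for gray matter) fit by multi-start nonlinear least squares and ranked by
AICc; the van Gelderen / Neuman cylinder model with bidirectional
radius ↔ diffusivity maps; Cramér–Rao protocol feasibility (minimal
detectable radius); histology-side radius statistics with a Poisson
mesoscopic-fluctuation bootstrap; and a ground-truthed synthetic phantom
generator so the whole pipeline is testable without scanner data.

## Worked example

```r
library(axonradius)

protocol <- protocol_preset("connectom")
protocol
#> Acquisition protocol 'connectom'
#>   delta/Delta = 13/30 ms, TE = 62 ms, SNR(b=0) = 52
#>   13 shells, b = 1, 3, 5, 7, 9, 11, 12.1, 13.5, 15, 16.9, 19.1, 21.7, 25 ms/um^2

# feasibility: which radii can this protocol detect at all?
minimal_detectable_radius(protocol, f = 0.6, Da_par = 2.4, b_min = 6)
#> CRLB feasibility (connectom, b >= 6, f = 0.6, Da_par = 2.4, D0 = 2.4):
#>   minimal detectable radius r_min = 2.10 um (z = 1.96)

# a synthetic voxel population with 2.5 um effective radius at scanner SNR
truth <- phantom_ground_truth(protocol, dims = c(6, 6, 1),
                              radius_range = c(2.5, 2.5), dot_nrep = 0,
                              seed = 7)
rec <- end_to_end_recovery(truth, dir = tempfile(), b_min = 6)
rec
#> End-to-end recovery: median rel. error 2.3%, bias 2.7%, RMSE 8.0%, implausible 0.0%
median(rec$r_hat, na.rm = TRUE)
#> [1] 2.56

# histology-side statistics from a per-axon radius sample
h <- generate_radius_sample("gev", list(mu = 0.5, sigma = 0.15, xi = 0.1),
                            n = 1e5, seed = 7)
round(c(r_bar = mean_radius(h), r_eff = effective_radius(h)), 2)
#> r_bar r_eff
#>  0.60  1.07
```

Reading the numbers: the feasibility analysis says this acquisition can
statistically resolve Da⊥ > 0 only for effective radii above ~2.1 µm, so a
2.5 µm population sits in the detectable regime — and the full pipeline
(powder averaging of the noisy directional volumes, truncated-power-law fit
over b > 6, radius conversion) recovers a median 2.56 µm against the 2.5 µm
truth, with no biophysically implausible (negative-Da⊥) voxels. The
histology sample illustrates the tail weighting: a distribution whose mean
radius is 0.60 µm has an effective (MR-visible) radius of 1.07 µm.

A thin command-line front end with `simulate`, `powder-average`, `dotfrac`,
`fit`, `select-model`, `map-radius`, `crlb` and `hist-stats` subcommands is
installed under `inst/cli/axonradius`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/axonradius", package="axonradius"))')" \
    crlb --preset connectom --f 0.6 --dapar 2.4 --bmin 6
```

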