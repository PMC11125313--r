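---
title: "Methods: colorimetric PLS calibration and adsorption analytics for MIP plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colorimetric PLS calibration and adsorption analytics for MIP plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipsense)
```

## The measurement problem

A molecularly imprinted polymer (MIP) grafted on a PET plate captures
tartrazine (E102), a yellow azo dye, from solution. The loaded plate is
photographed with a smartphone under controlled geometry, and the dye is
quantified from the plate's color alone: a cheap, instrument-free
alternative to spectrophotometry. `mipsense` implements the two halves of
that workflow — the chemometric calibration that maps plate color to
concentration, and the batch-adsorption analytics that characterize the
plate as a sorbent (kinetics, isotherms, selectivity, reuse).

Because the raw laboratory images and adsorption tables behind such studies
are rarely published, the package ships a seeded synthetic generator that
emulates their statistical structure, so every stage of the pipeline is
exercised end to end by code alone.

## Color features

Each plate photograph is reduced to the mean RGB of one or two 16 × 16
pixel regions of interest (two ROIs describe the same plate and are pooled,
not treated as replicates). The mean triplet is expanded to ten channels:

* CMYK by plain subtraction: \(C = 1 - R/255\), \(M = 1 - G/255\),
  \(Y = 1 - B/255\), \(K = \min(C, M, Y)\). Note that C, M, Y are *not*
  rescaled by \(1 - K\), so K always equals the minimum of the other three.
* HSV with the piecewise hue: \(V = \max(R, G, B)\) kept on the 0–255
  count scale, \(S = 1 - \min/V\) (a ratio, 0 when \(V = 0\)), and H in
  degrees from the six-case formula over the dominant channel.

Two conventions deserve emphasis. First, the feature set deliberately mixes
scales (V in counts, S a ratio); standardization before the regression makes
this immaterial for calibration, and exports keep the raw scales. Second,
the hue is undefined when \(\max = \min\); the package fixes \(H = 0\)
there so blank (gray/white) plates still produce a complete feature vector.
Ties in the maximum resolve in case order — R first, then G, then B.
Pixel coordinates are 0-based, row-major, origin top-left, with ROIs
covering half-open blocks.

## PLS calibration

Features and concentration are autoscaled (mean 0, SD 1, \(n-1\)
denominator; constant columns are dropped and recorded), and a partial
least squares regression is fitted with the classical NIPALS sequence for a
univariate response: per component, weight \(w \propto X^\top y\) (unit
norm), score \(t = Xw\), loadings \(p = X^\top t / t^\top t\) and
\(q = y^\top t / t^\top t\), then rank-one deflation of both \(X\) and
\(y\). Coefficients are \(B = W (P^\top W)^{-1} q\). Successive scores are
orthogonal, and at full rank the fit coincides with ordinary least squares
— both properties are asserted in the test suite. Weight signs follow a
fixed convention (first non-negligible element positive) so serialized
models are reproducible. Four latent components are the default for the
ten-channel feature set; requests beyond the rank of \(X\) raise an error
rather than being silently reduced.

Validation is leave-one-out cross-validation — the standard choice for
calibration sets of a few dozen plates — with the standardization
re-estimated inside every fold so the held-out sample never leaks into the
preprocessing.

### Working range

The decadic color response saturates at high loading, so the full 0–20
mg/L series is deliberately curved and a truncated range calibrates better.
`select_working_range()` refits and cross-validates the model on each
candidate upper bound and picks the winner by a deterministic lexicographic
rule: slope of predicted-vs-measured closest to 1, then highest \(R^2\),
then lowest RMSECV. A visual inspection of metric curves cannot be
reproduced by software; this rule can. The scan table for every candidate
is always reported, so the choice is auditable.

### LOD and LOQ

No formula is universal here; the package uses the residual-SD rule
\(LOD = 3.3\,s/|m|\) and \(LOQ = 10\,s/|m|\), with \(s\) the SD of
out-of-fold residuals in the working range and \(m\) the cross-validated
slope. The LOQ is additionally floored at the lowest non-zero calibration
standard — a method should not claim quantification below the lowest level
it was shown — and reports carry both the floored and unfloored values plus
a flag. The working range is likewise reported twice: as scanned, and with
its low end replaced by the floored LOQ.

## Adsorption analytics

Removal and areal capacity follow the standard definitions
\(100 (C_o - C_e)/C_o\) and \(Q = (C_o - C_e)V/A\) (mg cm⁻²). A variant
removal convention with \(C_e\) in the denominator is available behind an
explicit flag for fidelity with sources that print it that way; it exceeds
100% for removals above one half, which is why it is not the default, and
every report names the convention used.

Kinetic and isotherm constants are estimated from the classical
linearizations, because that is what tabulated constants in this field
describe:

| model | linear axes | constants |
|---|---|---|
| pseudo-first order | \(\log_{10}(Q_e - Q_t)\) vs \(t\) | \(k_1 = -2.303 \cdot\) slope, \(Q_{cal} = 10^{\text{intercept}}\) |
| pseudo-second order | \(t/Q_t\) vs \(t\) | \(Q_e = 1/\)slope, \(k_2 = \)slope²/intercept |
| intraparticle diffusion | \(Q_t\) vs \(\sqrt{t}\), 10–60 min | \(k_{id} = \) slope, boundary-layer \(C\) |
| Langmuir | \(C_e/Q_e\) vs \(C_e\) | \(Q_m = 1/\)slope, \(b = \)slope/intercept |
| Freundlich | \(\log_{10} Q_e\) vs \(\log_{10} C_e\) | \(n = 1/\)slope, \(K_f = 10^{\text{intercept}}\) |

Numerical conventions: logarithms are base 10 with the conventional 2.303
factor in the PFO rate constant (which is why a PFO round trip recovers
\(k_1\) to about 2 × 10⁻⁴ relative rather than machine precision — the
factor is a rounded \(\ln 10\)); the PFO equilibrium capacity defaults to
the last (plateau) observation, and points whose log argument
\(Q_e - Q_t \le 0\) (at least that plateau point) are dropped with a
message; the intraparticle fit is windowed to 10–60 min by default, the
diffusion-controlled stage. \(R^2\) is computed on the linearized axes —
that is what published kinetic/isotherm \(R^2\) values describe — and an
optional nonlinear least-squares refit (`minpack.lm`) is reported alongside
with its own \(R^2\) as a secondary diagnostic. In the pipeline's kinetics
report the winning model is chosen by \(R^2\) with every model fitted over
the *full* time window (the windowed intraparticle fit is kept as the
mechanistic analysis); comparing a six-point windowed fit against full-run
fits would bias the comparison.

Selectivity uses the imprinting factor \(\alpha = \)removal(MIP)/removal(NIP)
and selectivity factor \(\beta = \alpha_{template}/\alpha_{interferent}\)
(\(\beta = 1\) for the template by construction). Reusability reports
removal per regeneration cycle and the first cycle falling below
\((1-\delta)\) of the first-cycle removal, \(\delta = 0.10\) by default.

## The synthetic generator

The generator defines the study conditions under which the pipeline is
exercised:

* **Calibration plates.** 21 standards, 0–20 mg/L in 1 mg/L steps, two
  replicates (42 images), 3 mL aliquots on 1 cm² plates, with complete
  uptake assumed, so the areal loading is \(q = CV/A\) (up to 0.06
  mg cm⁻²). Each 64 × 64 image applies a per-channel decadic response
  \(ch(q) = ch_0 \cdot 10^{-a_{ch} q}\) — a reflectance analogue of the
  Beer–Lambert law that keeps channels in [0, 255] at any loading — then a
  2% linear illumination gradient with per-image random orientation, then
  i.i.d. Gaussian pixel noise, clipping and rounding to 8 bits.
* **Frozen response constants.** Blank plate (235, 230, 225); attenuations
  \(a_B = 25\), \(a_G = a_R = 8\) per mg cm⁻²; pixel noise SD 8 counts.
  These were chosen once and frozen: the strong blue attenuation yellows
  the plate and saturates the response toward 20 mg/L so that the range
  scan genuinely has a truncation to find; the equal red/green tails (the
  dye absorbs blue light, with only weak, similar tails elsewhere) keep the
  hue's march toward yellow monotone, giving the expected correlation signs
  (concentration rising with H, S, Y and falling with V, R, G); and the
  noise level places the detection limit in the few-tenths mg/L region,
  below the 1 mg/L lowest standard. They are conventions of the artifact —
  the channel-versus-loading law of a real plate is not published — and are
  not claims about any physical device.
* **Batch experiments.** Kinetics, isotherms and selectivity records are
  generated from the same closed forms the fitters assume (PFO/PSO/IPD,
  Langmuir/Freundlich), with multiplicative Gaussian noise and mandatory
  seeds. The default kinetic fixture samples t = 10–120 min in 10 min
  steps plus 180 and 240 min, through the slow approach to equilibrium:
  ending the run mid-rise would make the plateau default of the PFO
  linearization ill-conditioned, as it would for a real experiment ended
  too early.

What passing tests on these data do and do not show: they verify the
algebra, the estimators, the determinism and the end-to-end plumbing under
a known generating model. They do not certify performance on real plate
photographs, which add JPEG compression, specular highlights, white-balance
drift, plate heterogeneity and matrix effects that the generator
deliberately omits.

## Problem sizes and runtime

The shipped configuration — 42 images of 64 × 64 pixels, leave-one-out
cross-validation over candidate ranges, and 10–14-point adsorption tables —
was chosen so a full simulate → calibrate → quantify cycle plus all
adsorption suites completes in seconds on a single core while still
exercising every code path at realistic calibration sizes.

## Known limitations

* The PLS is univariate in the response (one analyte); no PLS2, variable
  selection or nonlinear calibration.
* The camera model is statistical, not radiometric: no device color
  profiles, white-balance correction or color-checker calibration.
* The printed-form removal convention (\(C_e\) denominator) and the
  mixed-scale HSV are kept verbatim by design; both are flagged in
  reports rather than silently normalized.
* Linearized estimators are the primary route; for heteroscedastic data the
  secondary nonlinear refits may disagree, and both are reported so the
  discrepancy is visible.
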