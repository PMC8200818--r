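---
title: "Methods: from plate counts to projected human organ doses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from plate counts to projected human organ doses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radioknot)
```

radioknot implements the quantitative chain of a preclinical evaluation of a
^177^Lu-DOTA integrin αvβ6 cystine knot peptide (knottin) in pancreatic
cancer models: in-vitro radioligand pharmacology, radiosensitivity,
ex-vivo biodistribution in Capan-2 xenograft mice, and a projection of
human organ absorbed doses. This vignette explains each model, its
assumptions and tunable parameters, the design decisions where the
methodology was genuinely open, and what the synthetic-data generators do
and do not emulate.

## Radioligand binding pharmacology

**Saturation.** Total and nonspecific wells are fitted *simultaneously* by
least squares to

$$\mathrm{Total}(c) = \frac{B_{max}\,c}{K_d + c} + m\,c + b, \qquad
  \mathrm{Nonspecific}(c) = m\,c + b,$$

with $c$ the radioligand concentration (nM), $B_{max}$ in cpm, $m$ the
linear nonspecific slope (cpm/nM) and $b$ a background (cpm). Sharing
$(m, b)$ across both conditions is what the classic "one site — total and
non-specific" analysis does; the specific curve is the difference of the
two fitted curves and is nonnegative by construction whenever the fit
converges. All replicate wells enter the objective (not their means), the
fit is unweighted by default (matching common plate-fitting software), and
1/Y weighting is available behind a flag. Initialisation is deterministic:
$K_d$ starts at the mid-range concentration, $B_{max}$ at the largest mean
specific signal, $(m, b)$ at the nonspecific regression line; there are no
random restarts. Non-convergence returns a flagged result with the
optimizer's diagnostics; all-zero plates are rejected as degenerate.

**cpm to sites per cell.** The counter conversion is

$$\mathrm{cpm/fmol} = \frac{SA\,(\mathrm{Ci/mmol}) \times 2.22\times10^{12}
  \times \varepsilon}{10^{12}}, \qquad
  \mathrm{sites/cell} = \frac{B_{max}(\mathrm{cpm})}{\mathrm{cpm/fmol}}
  \times \frac{6.02\times10^{8}}{N_{cells}}.$$

At the default specific activity of 2175 Ci/mmol (carrier-free ^125^I) and
counter efficiency $\varepsilon = 0.65$, one fmol of bound ligand counts as
3138.525 cpm, so 3138.525 cpm of $B_{max}$ with 50,000 seeded cells is
12,040 sites/cell. The efficiency default is 0.65 because that is the value
the conversion formula actually uses in practice; configuring the
alternative narrative value of 0.5 is allowed but warns. The same
conversion, divided by the assay volume, turns the radioligand input of a
competition well into a concentration (1 fmol/µL = 1 nM); the assay volume
is rarely reported, so it is a configuration parameter with default 100 µL
that is flagged in every report.

**Competition.** Displacement is the unit-slope log-logistic

$$Y(c) = Bottom + \frac{Top - Bottom}{1 + c/IC_{50}},$$

fitted on $\log_{10} IC_{50}$ with the zero-competitor wells pinning
$Top$. A curve whose total displacement is under 10% of the top is flagged
as non-converged ("no displacement") rather than reported. Because the
radioligand occupies part of the receptor pool, the inhibitory constant is
obtained by the Cheng–Prusoff correction
$K_i = IC_{50} / (1 + [hot]/K_d)$; the package reports the fitted IC50 and
the corrected $K_i$ side by side and labelled, since published "Ki" values
do not always state which of the two fits produced them.

## Radiation dose–response and ΔΔCt

Nuclei counts (or tabulated colony-area fractions; image segmentation is
upstream of this package) against dose follow a four-parameter logistic
with variable Hill slope bounded to $[0.2, 10]$; the IC50 is the dose of
half-maximal growth inhibition in Gy. Both published dose ladders (the
nine-dose design and the ten-dose variant with the extra 0.05 Gy point)
are accepted. A response that *rises* with dose is flagged as "no
inhibition" instead of being forced through the model.

ΔΔCt normalisation averages replicate Ct values per (sample, gene), takes
the reference level as the arithmetic mean of the reference-gene mean Cts
(equivalent to the geometric mean of the corresponding expression
quantities, e.g. of UBC and GAPDH), and reports $2^{-\Delta\Delta Ct}$
against a calibrator sample. The calibrator's fold is exactly 1 and the
result is invariant to any common Ct shift within a sample — both are
tested properties.

## Biodistribution reduction

Each dissected sample is counted together with a standard representing a
known fraction $f_{std}$ of the injected activity, so

$$\%IA/g = \frac{cpm_{sample}}{cpm_{std}/f_{std}} \times
  \frac{100}{mass\,(g)}.$$

Samples and standard counted in the same session share the decay factor,
which cancels; when session offsets differ, both are decay-corrected to
injection time with $T_{1/2}(^{177}\mathrm{Lu}) = 6.647$ d (159.528 h, a
configurable constant). Negative net counts are clamped to zero with a
warning. Organ names are validated against the fixed fourteen-organ
dissection vocabulary (tumor, small intestine, colon, liver, spleen,
kidney, heart, blood, lung, muscle, femur, stomach, pancreas, tail), with
case-insensitive aliases.

Tumor-to-organ ratios are reported under *both* conventions —
ratio-of-means across animals and mean of per-animal ratios with its SD —
because published tables rarely state which one they use. On the packaged
reference means the ratio-of-means reproduces the published ratio cells at
72–192 h to within 2%, while the 24 h cells deviate by 4–8%, a pattern
consistent with a mean-of-per-animal-ratios convention in the original
table; the raw per-animal data are not public, so this remains an
observation, not a target.

## Mouse-to-human extrapolation and residence times

Assuming equal organ-to-whole-body activity concentration ratios across
species, uptake and time are scaled by

$$(\%IA/organ)_{human} = (\%IA/g)_{mouse}\, M_{mouse}(kg)\,
  \left[\frac{m(g)}{M(kg)}\right]_{human}, \qquad
  t_{human} = t_{animal}\left[\frac{M_{human}}{M_{animal}}\right]^{0.25}.$$

The mouse body mass is not part of the published record; the default is
0.025 kg (a typical adult NMRI nude mouse), with the human reference adult
at 73.7 kg and a packaged, user-replaceable organ-mass CSV (reference
adult male values; the package's own compilation). Amplitudes and times
are scaled *first*, then the human-time curve is fitted and integrated —
consistent with extrapolating uptake data before organ-level dose
assessment.

Organ curves are fitted mono- or bi-exponentially on the per-time-point
means; `auto` keeps mono for four or fewer points and otherwise selects by
AICc. Residuals are linear by default with a log-residual option (for the
mono model the log option is the exact log-linear regression). The fitted
curve is back-extrapolated to $t = 0$ at its fitted amplitude (no
absorption phase is modelled — with a first sample at 24 h mouse time
there is no information about one). The time-integrated activity
coefficient is

$$\tau = \int_0^{\infty} A(t)\,dt = \sum_i A_i/\lambda_i \;\; (h),$$

with $A$ in fraction of injected activity. A numeric trapezoid-plus-
analytic-tail integrator cross-checks the closed form to better than
10^-6^ relative. After time dilation an apparent organ clearance can come
out *slower* than ^177^Lu physical decay, which is unphysical for a
nuclide-bound tracer; each rate is floored at the physical decay constant
(the adjustment is reported on the returned object), which also enforces
the bound $\tau \le f_0\,T_{1/2,phys}/\ln 2$.

A consequence worth knowing: because the mass scaling multiplies by the
human organ mass, the 28 kg reference muscle acquires a larger
*whole-organ* fraction than kidney even though its concentration is ~70×
lower, so whole-organ residence times do not simply follow per-gram
uptake. Absorbed dose divides by the target mass again, which is why the
kidney still ranks first in dose (below).

## MIRD-style dosimetry

The dose engine is deliberately open and minimal. ^177^Lu emits a mean
electron (β + conversion + Auger) energy of 0.1479 MeV per decay, i.e.
$\Delta_e = 2.370\times10^{-8}$ Gy·kg/(MBq·s). Electron range in tissue is
a few mm, so in the default `electron_self_only` mode the S matrix is
diagonal with $S_{self} = \Delta_e/m$ and photon cross-fire is omitted;
the ~11% photon energy fraction can be added by supplying specific
absorbed fractions, which are phantom-specific and not part of this
package. Organ doses are $D_T = \sum_S \tau_S \cdot 3600 \cdot S(T\!\leftarrow\!S)$
in mGy/MBq (numerically mSv/MBq for electrons/photons), and the effective
dose applies the ICRP-60 tissue-weight generation (the one contemporary
with classic organ-level dosimetry codes; ICRP-103 is available behind a
flag), with the remainder weight spread mass-proportionally over dosed
organs without an explicit weight. Organs without a phantom entry (tumor,
tail, blood, femur) are excluded from the phantom report and listed
separately; a tumor dose can be obtained with a user-supplied sphere mass
via $\Delta_e/m$.

The published organ-dose table for this tracer cannot be reproduced
numerically from the published uptake alone: the residence-time
derivation, mouse masses and the closed dosimetry software's internals are
unreported, and several printed entries are far below what the printed
uptake implies under standard assumptions. The engine therefore reports
its own values with full provenance, and the validation asserts structure
instead: linearity of dose in τ and S, uniform-dose invariance of the
effective dose, the physical-decay bound on τ, analytic-vs-quadrature
agreement, and the kidney ranking first in absorbed dose among phantom
organs — which it does:

```{r dose}
report <- project_human_doses(reference_biodistribution())
report
```

## Synthetic data: what it emulates, and what it does not

Every generator takes an explicit integer seed (the global RNG state is
saved and restored) and is exact at zero noise. Defaults are the study
conditions: the 12-point saturation and competition ladders, triplicate
wells, 5% CV Gaussian counter noise (counter statistics at 10^3^–10^5^
cpm); the BxPC-3 generating parameters $K_d = 0.30$ nM, $B_{max} =$
11,874 sites/cell, $K_i = 1.69$ nM (Capan-2: 0.75 nM, 11,545, 9.46 nM);
the nine-dose nuclei-count ladder with 5 replicates and a radiation IC50
of 4.3 Gy; and the published organ means at 24/48/72/192 h with 4–5
animals per time point and ~1 MBq injected. Competition curves generated
from a $K_i$ are placed at $IC_{50} = K_i(1 + [hot]/K_d)$ so the
Cheng–Prusoff-corrected fit recovers the generating value. Generator
nuisance parameters the study does not report (nonspecific slope
20 cpm/nM, background 50 cpm, bound top ~20,000 cpm, dose-response top
15,000 nuclei with bottom 500, organ sample masses) were fixed once at
values typical for these assays.

Inter-animal biodistribution scatter is lognormal with σ = 0.25 (chosen to
match the magnitude of the published SDs), parameterised mean-preserving
($\mu_{log} = \log m - \sigma^2/2$) so reduced per-time means are unbiased
estimates of the generating means. Counts are derived from %IA/g through
the sample mass and the co-counted standard, with physical decay applied
identically within a counting session.

What the generators do *not* emulate: plate edge effects and pipetting
gradients, counter dead-time and spillover, receptor internalisation or
ligand depletion at high occupancy, correlated organ uptake within an
animal, partial-volume effects of SPECT-derived curves, and any absorption
phase before the first sampling time. Passing parameter-recovery tests on
this synthetic surface therefore demonstrates correctness of the
estimators under the stated noise models, not robustness to every
real-world artefact.

## Numerical choices and problem sizes

Nonlinear fits use Levenberg–Marquardt (minpack.lm) with bounded
parameters and deterministic starts; grid searches with the conditionally
linear parameters profiled out serve as independent oracles in the test
suite. Validation runs 200 seeded plates per binding/dose-response
recovery study and 100 seeded biodistribution experiments — enough for
medians with ~0.5% Monte-Carlo error at 5% CV noise — and completes in a
few seconds. Ties in initialisation grids resolve to the smallest index;
zero organ means propagate as zero uptake and are excluded from
exponential fitting; ratios against a zero denominator are reported as
undefined (`NA`), never infinite.

## Known limitations

Two-site and cooperative binding, kinetic (k~on~/k~off~) assays,
linear-quadratic survival models, plating-efficiency correction,
compartmental PK, bladder voiding, photon cross-dose and voxel/Monte-Carlo
transport are all out of scope. The human projection inherits every caveat
of allometric scaling from a single mouse strain, and its absolute organ
doses should be read as order-of-magnitude planning numbers with stated
provenance, not as a reproduction of any specific closed-software output.
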