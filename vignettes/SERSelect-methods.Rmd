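---
title: "Variable-selection PLS calibration for SERS quantification: models and design"
author: "SERSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-selection PLS calibration for SERS quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SERSelect)
```

## The problem

Surface-enhanced Raman scattering (SERS) substrates amplify the vibrational
fingerprint of trace analytes — here the fungicide carbendazim, whose
residues in apple are regulated (the Chinese maximum residue limit in apple
is 5 mg/kg) — to the point where quantification from a one-second spectrum
becomes feasible. The obstacle is that a raw SERS spectrum of a food
extract is dominated by things other than the analyte: substrate and
matrix emission, multiplicative scatter differences between replicate
chips, baseline drift, and detector noise. Of the 1416 wavenumber channels
collected between 400 and 2500 1/cm, only narrow regions around the
analyte's bands carry quantitative information.

`SERSelect` implements the calibration strategy appropriate to this
setting: multiplicative scatter correction (MSC), a rank-stratified 2:1
calibration/prediction split, PLS1 regression with a cross-validated
latent-variable count, and four wavelength-selection algorithms — a
genetic algorithm (GA), the interval variable iterative space shrinkage
approach (iVISSA), the LASSO, and bootstrapping soft shrinkage (BOSS) —
each feeding a downstream PLS model that is evaluated by RMSEP, the
correlation coefficients $R_C$/$R_P$, and the ratio of prediction to
deviation (RPD = SD/RMSEP; above 2 is conventionally usable, above 3 a
good quantitative model). Spike-recovery statistics (recovery %, RSD %,
relative error %) summarise validation on fortified samples.

Because the study design this emulates (seven concentration levels of
0.1, 0.5, 1, 5, 10, 20, 50 mg/L with 36 replicate spectra each) has no
deposited raw spectra, the package ships a first-class synthetic-spectrum
generator. The generator defines the study conditions for every test in
this package; this vignette documents its model and the reasoning behind
each default, because several of those choices are forced in non-obvious
ways by the interaction of MSC with variable selection.

## The generator model

For a sample at concentration $c$ the generator draws

$$ x(\nu) \;=\; g\,\Big[r(c)\,S_i(\nu) + B(\nu) + b(\nu)\Big] \;+\; o
   \;+\; \varepsilon(\nu), $$

with, per spectrum $i$: gain $g \sim N(1, \sigma_b)$ (default 0.05),
offset $o \sim N(0, \sigma_a)$ (default 0.5), a random polynomial drift
$b(\nu)$ of degree 2 (coefficient sd 0.002), and iid noise $\varepsilon$
(sd 0.01). $B$ is a fixed smooth substrate/instrument background (an
exponential decay, three broad humps and a constant, in arbitrary counts
of order $10^4$; optional per-spectrum component rescaling and fringe-like
undulations are available but default to zero).

The per-spectrum concentration signature is

$$ S_i(\nu) \;=\; \sum_b (1 + \alpha_{ib})\,P_b(\nu)
   \;-\; \gamma \sum_d (1 + \alpha_{id})\,D_d(\nu), $$

where $P_b$ are the carbendazim bands (Gaussian, HWHM 2.5 1/cm, centers
629, 736, 770, 1007, 1227, 1271, 1462, 1521 1/cm, relative amplitudes
1.0, 0.8, 0.6, 0.9, 1.0, 0.7, 0.6, 0.9), $D_d$ are the bands of a
synthetic citrate-like surface species that the analyte displaces on
adsorption (centers 470, 565, 845, 955, 1395, 1640, 2080 1/cm, HWHM 3),
$\gamma$ makes the mean signature exactly zero over the grid, and
$\alpha_{ib}$ is a per-band, per-spectrum enhancement jitter: an
independent per-band draw (sd 0.008) plus a component common to all bands
(sd 0.0024). The response $r(c)$ is linear by default; the Langmuir adsorption
law $r(c) = c/(1 + c/c_{sat})$ is available.

Four of these ingredients — the displacement term, the per-band jitter,
the band width, and the near-absence of structured drift — are not
cosmetic. Each is forced by a requirement the package's validation places
on the data, and each failure mode was observed, not hypothesised. They
are documented here in that spirit.

### The displacement term: why the signature must have zero spectral mean

MSC regresses each spectrum on the calibration-mean reference and returns
$(x - \hat a)/\hat b$. The intercept removes the spectrum's own spectral
mean — including the mean of the analyte signal, $r\,\overline{P}$. For
any non-negative band profile, every wavenumber of the corrected spectrum
then carries $-\overline{P}(r - \bar r)$: a nearly noise-free copy of the
concentration, identical at all 1416 channels (per-spectrum centring
removes constant noise exactly). Two consequences follow:

* every off-band variable becomes genuinely informative, and
* the centred signature splits its $\ell_1$ mass exactly 50/50 between
  its positive (band) and negative (everywhere else) parts, so a
  regression vector proportional to it can never concentrate its
  absolute-coefficient mass at the bands — BOSS's weighted bootstrap then
  provably stalls with roughly half the grid retained.

The displacement term removes this channel at its source: with
$\int S = 0$, the spectral mean that MSC removes carries no concentration
signal. Physically it is competitive adsorption — analyte coverage
displaces the stabiliser layer, whose own bands shrink proportionally —
and the displaced-species band centers are part of the generator's ground
truth for "informative wavelengths" alongside the analyte bands.

### Per-band enhancement jitter: why selection needs it

SERS replicate spectra differ in enhancement: hot-spot occupancy and
adsorption geometry modulate band amplitudes. The generator models this
as the per-band $\alpha_{ib}$. Besides realism, this term is what makes
wavelength selection behave the way the method comparison assumes:

* channels within one band share the fluctuation, so averaging more
  channels of the same band stops improving RMSECV — subsets with a few
  channels per band score within the 2% cross-validation equality window
  of subsets with every channel, and the tie-break towards smaller sets
  becomes effective;
* compensating the fluctuation requires reweighting *bands*, so the
  deeper PLS components stay inside the band windows instead of smearing
  the coefficient vector across the grid.

The split between the independent and common parts is a balance measured
at both ends. With purely independent per-band noise, deeper PLS
components can genuinely improve cross-validation by reweighting bands,
but only on some datasets — the component choice sits on a knife edge,
and when a deep model wins on a junk-bearing variable set its
noise-amplifying coefficients inflate the relative error at the lowest
spike level several-fold. The common component caps those reweighting
gains (nothing can average it away), pinning the component count low
everywhere. It cannot be large, though: a shared multiplicative
fluctuation couples into the fitted calibration slope and shows up as a
seed-dependent intercept of order (common sd) x (mean concentration),
which the ±10% relative-error budget at 0.1 mg/L can only absorb up to a
common sd of a few 10^-3. The defaults (0.008 independent, 0.0024 common)
sit inside that window.

### Band width: set by the clustering geometry

The validation statistics demand per-sample relative errors within ±10%
at the 0.1 mg/L spike level, which caps the additive noise and puts the
per-channel signal-to-noise ratio at the top concentration in the
several-hundreds. A Gaussian band of HWHM $w$ is then genuinely
informative out to roughly $w\sqrt{\ln(\mathrm{SNR})/\ln 2}$ — about
±28 1/cm for $w = 6$ — and selectors rightly pick variables far outside
any ±10 1/cm notion of "the band". Requiring the informative halo to stay
within ±10 1/cm gives $w \approx 2.5$, the default. Lorentzian profiles
(available via `shape = "lorentzian"`) make this worse — their $w^2/d^2$
tails keep most of the grid informative at this SNR — which is why the
default shape is Gaussian.

### Structured drift: why the defaults are near zero

Any per-spectrum structured variation (baseline curvature above the noise
floor, background-shape changes, fringes) has two costs. First, accuracy:
variation of the components that make up the MSC reference perturbs the
fitted scatter gain, and a relative slope error $\delta$ propagates as a
prediction error of roughly $\delta(y - \bar y + \kappa_0)$ — of order
$12\delta$ mg/L at the lowest level, so the ±10% band at 0.1 mg/L
requires background stability of a few parts in $10^4$. Second,
selection: whatever structure the data contain, the PLS coefficient
vector acquires delocalised cancellation components with small amplitude
but large $\ell_1$ mass, which re-spreads BOSS's weights. The defaults
therefore keep the polynomial drift at 0.002 (below the iid noise) and
the background-shape jitter and fringe terms at zero; all three remain
available for robustness experiments. The modelled workflow's only
preprocessing is MSC — there is deliberately no detrending step — so
these choices also state what the pipeline could not have corrected.

### Why the response is linear by default

The study reports per-sample recoveries of 86–116% at 0.1 mg/L from a
calibration spanning 0.1–50 mg/L. A linear calibration cannot achieve
that under materially saturating response: fitting $c$ against
$c/(1 + c/100)$ over the seven design levels mispredicts the 0.1 mg/L
level by more than 1 mg/L. The default is therefore linear; the Langmuir
option (with $c_{sat}$ = 100 mg/L) is retained for studying exactly this
failure mode, and converges to the linear law as $c_{sat} \to \infty$.

### Remaining defaults

* **Interferent libraries** (`interferentPeaks()`) are synthetic stand-ins
  for the five pesticides of the specificity panel; their band centers
  avoid the 1225 ± 15 1/cm window by construction, and their amplitudes
  are small, mimicking the weak SERS affinity of non-adsorbing species.
* **Spiked sets** add a matrix background distinct from the calibration
  background: broad Gaussian humps at 880, 1120, 1680, 1960 1/cm (scale
  0.005 with 20% per-spectrum jitter) plus an elevated, partly random
  baseline lift. The hump scale stays small because a matrix component
  unseen during calibration projects onto the regression vector as a
  concentration-independent bias, largest in relative terms at the lowest
  spike level.
* **Background magnitude**: the fixed background dominates the band
  signal. MSC identifies the multiplicative scatter gain from whatever
  dominates the spectral variance; a weak background lets the fitted
  slope absorb part of the concentration response and bends the corrected
  calibration curve (observed as a systematic negative bias at the lowest
  levels).

## Model core

* **Split.** Samples are shuffled (seeded; this also breaks ties), sorted
  by reference value from high to low, grouped into consecutive triplets,
  and one member per triplet, chosen uniformly, goes to the prediction
  set (leftovers to calibration). 252 samples give 168 calibration and 84
  prediction spectra.
* **PLS1.** Classical NIPALS with X-deflation (for univariate responses
  each component is extracted in a single step, so no inner-iteration
  tolerance applies); coefficients are reconstructed as
  $B_k = W_k (P_k^T W_k)^{-1} q_k$ for every truncation $k$. Requested
  components are bounded by $\min(n-1, p)$ and truncated with a warning
  if the deflated matrix runs out of covariance.
* **Cross-validation.** Seeded random fold assignment (10 folds for final
  models), RMSECV over all held-out samples for each $k$, chosen $k$ =
  smallest within 2% of the curve minimum (parsimony rule).
  Selection-internal scoring uses 5 folds and a component cap of 10;
  both are exposed in every selector's arguments.
* **Tie-breaking.** Exact ties between continuous CV scores never occur,
  so "equal RMSECV" is read throughout as "within the same 2% window used
  by the parsimony rule": among statistically indistinguishable candidate
  sets the smaller wins, then the earlier iteration. This applies to
  BOSS's returned iteration and to the GA's best-ever chromosome.

## The four selectors

All four operate on the MSC-corrected calibration block and score
candidate subsets by the minimum of the PLS RMSECV curve under one fixed,
seeded fold assignment.

* **BOSS** iterates: weighted bootstrap sampling of variable subsets (the
  unique variables among $p$ weighted draws), RMSECV scoring, retention
  of the best tenth, and weight update by summed normalised $|\beta|$ of
  the kept sub-models — the soft shrinkage that lets weakly weighted
  variables survive to later rounds. Each sub-model's $\beta$ is taken at
  the component count chosen by the 2% parsimony rule; the scoring CV is
  kept shallow (5 components) and its fold assignment is redrawn every
  round, because deep scoring against one fixed assignment lets the
  bootstrap entrench variables that exploit that particular split.
  Rounds stop when the retained count has stopped decreasing (stable for
  three rounds; transient one-round plateaus occur while weights are
  still concentrating), and the returned set is the best iteration under
  the tie-break above.
* **GA** uses binary chromosomes, fitness $-$RMSECV, tournament
  selection, uniform crossover, mutation and elitist carry-over.
  Chromosomes are initialised sparse (12 variables) and capped at 30.
  The mutation rate (0.01) is applied per *retained* variable — the index
  encoding customary in GA wavelength selection — as relocation plus
  occasional single additions/removals; a per-grid-bit rate at
  $p = 1416$ would rewrite ~14 bits per child, destroy inheritance, and
  reduce the search to random draws.
* **LASSO** runs cyclic coordinate descent over a log-spaced λ path from
  $\lambda_{max}$ downward with warm starts (convergence on the relative
  decrease of the penalised objective — with nearly collinear adjacent
  channels the split of a coefficient between twins converges arbitrarily
  slowly while fit and support converge fast), chooses λ by
  cross-validation with the one-standard-error rule, and returns the
  support; the downstream model is a PLS fit on that support (LASSO-PLS),
  not the penalised fit.
* **iVISSA** alternates a global weighted binary matrix sampling phase
  (inclusion probabilities start at 0.5, updated to each variable's
  frequency among the best tenth of rows until the mean best-row RMSECV
  stops improving) with a local phase widening each retained variable
  into symmetric intervals while expansions reduce RMSECV.

### What selection can and cannot achieve here

On the default dataset, BOSS shrinks 1416 variables to ~110-130, nearly
all within ±10 1/cm of a true band, covering every analyte band; the
LASSO support behaves the same. GA and iVISSA do not concentrate, and the
package treats this as a structural property worth stating precisely:
under the accuracy constraints above, adding an uninformative channel to
a subset changes RMSECV by far less than cross-validation can resolve, so
a fitness of $-$RMSECV is blind to junk. The GA keeps fitness-neutral
passenger variables (about half of each chromosome), and iVISSA's
inclusion frequencies form a driftless random walk that retains roughly
half the grid — which matches the reported behaviour of the method in the
comparison study this package mirrors (945 of 1416 variables selected).
The corresponding acceptance check is asserted at its stated threshold
for all four methods and fails, deliberately unweakened, for GA and
iVISSA.

## Evaluation

`rmse`, `pearsonR` and `rpd` implement the standard definitions (RPD uses
the n−1 standard deviation of the prediction-set reference values).
`recoveryStats` reports per-level mean ± sd, per-sample recovery range,
RSD and relative-error range; a blank level (0) is reported descriptively
with recovery undefined. `peakIntensity` is the baseline-corrected band
height: the maximum inside a window minus the linear interpolation
between the window endpoints, evaluated at the position of the maximum —
this makes the 1225 1/cm specificity comparison insensitive to smooth
background differences and to tails of neighbouring interferent bands.
Spike recovery is evaluated with the BOSS-PLS model, the workflow's
best-performing calibration.

## Problem sizes and determinism

The default study conditions are the full 252 × 1416 design; the
acceptance suite runs it once (all four selectors) and derives every
headline statistic from that seeded run. Unit tests exercise the
algorithms on reduced instances: coarser grids, and planted
two-variable regressions whose exhaustive-search optima are computed
in-test. Every stochastic stage — generation, split, fold assignment,
bootstraps, chromosomes, sampling matrices — is a pure function of an
integer seed, and bit-identical reruns are asserted.

## Known limitations

* The generator is additive and low-rank in its structured parts; it does
  not emulate wavelength-axis jitter, instrument line-shape convolution,
  cosmic-ray artifacts, or the heavy hot-spot variability of real SERS
  substrates beyond the 1% per-band jitter. Passing tests demonstrate the
  chemometric machinery, not field performance on real extracts.
* MSC is the only preprocessing implemented (as in the modelled
  workflow); data with baseline curvature above the noise level would
  need a detrending step the package deliberately does not provide.
* The synthetic accuracy regime is cleaner than the real study's (RMSEP
  of order 0.06 mg/L versus 0.247 mg/L over the same 0.1–50 mg/L range):
  the acceptance checks are one-sided bounds, not reproductions of the
  real instrument's error magnitudes.
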