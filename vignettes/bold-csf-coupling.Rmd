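---
title: "Quantifying BOLD-CSF coupling: models, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying BOLD-CSF coupling: models, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfcoupling)
```

## The measurement

During drowsiness and light sleep the brain produces widespread,
high-amplitude activity excursions that appear as slow (< 0.1 Hz)
fluctuations of the *global BOLD signal* — the mean resting-state fMRI
signal over gray matter. Each such excursion is followed by a pulse of
cerebrospinal fluid flowing into the imaging volume. Fresh spins entering
the bottom slice of the acquisition have not been saturated by previous
radio-frequency pulses, so CSF influx registers as an intensity increase in
bottom-slice CSF voxels — the *inflow effect*. Because CSF movement through
perivascular spaces is the carrier of glymphatic waste clearance (including
amyloid-beta), the strength of the coupling between global activity and CSF
inflow is a candidate imaging marker for clearance integrity.

The package measures this coupling as a lagged cross-correlation function

$$CC(\tau) = \mathrm{cor}\big(G(t),\, F(t - \tau)\big), \qquad \tau = k
\cdot \mathrm{TR},\ k = -K..K,$$

between the global signal $G$ and the bottom-slice CSF signal $F$ of a
session, and summarises it by the value at $\tau = +1\,\mathrm{TR}$
(+3 s at the conventional TR of 3 s), the negative peak of the canonical
cross-correlation shape. **More negative values mean stronger coupling**:
CSF flows in while the global signal falls. The sign convention is anchored
so that a *negative* lag shifts the CSF series ahead of time; the canonical
shape then has a positive peak at a negative lag (around $-6$ s) and the
negative peak at $+3$ s.

Mechanistically, inflow tracks the *negative derivative* of the global
signal (flow follows the fall of the BOLD curve), so the package also
provides the cross-correlation of $-dG/dt$ with $F$, whose positive peak
sits near lag $-d$ for a physiological delay $d$.

## Signal extraction

`extract_session_signals()` applies, in a fixed and logged order:

1. **Spatial smoothing** (Gaussian, FWHM 4 mm, converted to voxels through
   the stored voxel size).
2. **Zero-phase band-pass**, 0.01-0.1 Hz. The filter is an FFT-domain mask
   with a real transfer function. Zero phase is non-negotiable here: any
   group delay would displace the cross-correlation peaks that *are* the
   measurement. The DC component is removed exactly.
3. **Polynomial detrending** (linear + quadratic).
4. **Edge discard**: the first and last 5 volumes are dropped *after*
   filtering, so pre-steady-state volumes and filter edge effects (the FFT
   filter wraps around) are discarded together. A 140-volume session
   yields 130 analysed samples; a 200-volume session yields 190.
5. **Extraction.** The global signal z-scores every gray-matter voxel and
   averages the z-scores; each voxel then contributes unit variance, so the
   SD of the average measures *inter-voxel synchrony* (it is $\le 1$ by
   construction) and is reused as the session's global-signal amplitude, an
   arousal proxy. The CSF signal averages the mask voxels first and
   z-scores the average once — the paper-trail normalisation does not
   matter for any correlation downstream (Pearson is affine-invariant,
   which a property test asserts), but the amplitude convention for the
   global signal does, which is why the two differ.

Whether z-scoring happens before or after the band-pass is not fixed by
the source conventions; the package filters first and normalises last.

The derivative stencil is the forward difference $-(x_{t+1}-x_t)/TR$
assigned to the leading timepoint. A one-sample shift in this convention
moves the derivative cross-correlation peak by a full TR, so the stencil
is pinned by an analytic cosine oracle in the test suite.

## The permutation null

Session-level significance of the mean cross-correlation uses a
session-shuffling null: each of $B$ iterations applies one uniform random
permutation to the session labels of the global signals, re-pairs each CSF
series with the permuted global series, and recomputes the session-mean
cross-correlation function. Two-sided empirical p-values use the add-one
convention, $p = (1 + \#\{|\bar r_{null}| \ge |\bar r_{obs}|\})/(1 + B)$,
so the smallest attainable p at the default $B = 10{,}000$ is just below
$10^{-4}$. Design details:

* Sessions of unequal length (130 vs 190 samples) are truncated to the
  common shortest length before pairing — the source procedure is silent
  on this point.
* Random permutations may contain fixed points (true uniform shuffles).
  With dozens of sessions the expected number of self-pairings is 1 per
  draw; their effect is conservative.
* Uniform validity of the p-values on uncoupled cohorts is verified by a
  600-replicate calibration simulation in the acceptance suite, and the
  sampled null is checked against exhaustive enumeration on 3-session
  toys, where all $3! = 6$ permutation values can be listed.

## Covariate-adjusted statistics

Because subjects contribute multiple sessions, session-level associations
use a linear mixed model with a subject random intercept. The package
reports two quantities per analysis cell, computed separately on purpose:

* `spearman_rho` — the Spearman correlation between the *adjusted* outcome
  (outcome minus the nuisance fixed-effect contributions, intercept
  retained) and the predictor; a robust effect-size descriptor for
  non-Gaussian quantities such as MMSE.
* `lmm_p` — the Satterthwaite-df p-value for the predictor from the full
  mixed model (predictor + nuisance + random intercept).

No Satterthwaite implementation was available in the toolchain, so
`lmm_ri()` implements it directly on top of lme4 REML fits: with variance
components $v = (\sigma^2_{subj}, \sigma^2_{res})$, the df for coefficient
$j$ is $2 C_{jj}^2 / (g_j^\top A\, g_j)$ where $C(v) = (X^\top V^{-1}
X)^{-1}$, $g_j = \partial C_{jj}/\partial v$ (central differences) and $A$
is the inverse numeric Hessian of the REML criterion. Two boundary rules
keep the machinery honest: if every subject contributes one session, or the
subject variance collapses to (numerical) zero, the fit reduces to ordinary
least squares with $df = n - p$ — so mixed-model p-values provably coincide
with simple-regression p-values in that limit, which the acceptance suite
asserts at $|\Delta p| < 10^{-4}$. On balanced designs with a
between-subject predictor the Satterthwaite df has the closed form
$m - p$ (subjects minus fixed-effect rank); the numeric machinery
reproduces it to two decimals in the tests.

Other conventions, each validated against the published
cohort-characteristics table:

* Group comparisons of summary statistics use the **pooled-variance**
  Student t (df $= n_1 + n_2 - 2$), not Welch — the pooled form reproduces
  the printed age p-value (0.02) where Welch gives about 0.006.
* The Fisher exact test is two-sided by the standard convention: the sum
  of hypergeometric probabilities of all tables no more probable than the
  observed one. It matches full enumeration and the reference
  implementation on random tables.
* The diagnostic-group dose-response trend scores the ordered conditions
  HC < SMC < MCI < AD as 0-3 and tests the linear term; the exact contrast
  behind the published trend p is unstated, and a linear score is the
  conventional reading of a monotone dose-response claim. Pairwise group
  contrasts are reported alongside.
* Missing values propagate; every analysis row reports its effective n.
  Nominal p-values are reported without multiplicity correction, with the
  total test count attached to the results object.

## The synthetic cohort: what it emulates, what it does not

Raw sessions from the source study are access-restricted, so
`simulate_cohort()` generates a stand-in world in which every downstream
stage can be tested against known ground truth:

* **Global activity** $G_0$: Gaussian event kernels (SD 5 s, so events
  span roughly 10-20 s) at Poisson onsets, 3 events/min by default (one
  every ~20 s, as in drowsy-state recordings), plus band-limited (< 0.08
  Hz) background noise (SD 0.1). Generation happens at dt = 0.5 s and is
  block-averaged to TR = 3 s, so sub-TR delays are representable even
  though analysis lags are TR multiples.
* **CSF inflow** $F(t) = \kappa \cdot r(-G_0'(t - d)) + \varepsilon$, with
  delay $d = 3$ s and a per-session gain $\kappa \ge 0$. The linear drive
  ($r = $ identity) is the analytically tractable default; half-wave
  rectification is available since physical inflow cannot be negative.
* **Session state**: a per-session arousal level drawn from [0.3, 1.7]
  scales event amplitudes, emulating alert-to-light-sleep variation. The
  event rate and arousal range were fixed once so that the estimated
  global amplitude tracks the injected arousal level with rank correlation
  at least 0.9 — the generator's own fidelity requirement.
* **Covariate linkage**: $\kappa_i = \max(0,\ \kappa_0 - \text{deficit}_i
  - \epsilon_i)$ where the deficit rises with age (0.02 per year above
  74), female gender (0.15), diagnostic severity (0.08 per ordinal step)
  and baseline amyloid SUVR (1.2 per unit above 0.88), so *weaker coupling
  accompanies higher risk* — the direction of every published association.
  Follow-up MMSE declines by 2.5 points per unit of systematic deficit.
  The source provides no quantitative gain-covariate model; all effect
  sizes are configuration, not claims. The age effect was set so that the
  emergent session-level coupling-age correlation is of the published
  order (about 0.2) and every injected sign is recoverable at 200
  sessions — both are generator-calibration requirements, fixed before the
  acceptance suite existed.
* **Volume assembly** (volume mode): gray-matter voxels carry positive
  log-normal loadings times $G_0$ plus voxel noise (SD 0.5); bottom-slice
  CSF voxels carry $F$ plus voxel noise; the loading map doubles as a
  synthetic arousal template, since the real template is not
  redistributable. The default 12 x 12 x 8 grid keeps full-volume tests
  fast. The fast signal-only mode skips assembly but simulates a small set
  of pseudo-voxels (24 gray-matter, 8 CSF) so that the
  z-score-then-average amplitude convention behaves identically in both
  modes.
* Covariate distributions (age N(74, 6), group frequencies, group-specific
  SUVR and MMSE means/SDs, APOE carrier rates rising with severity) mirror
  the published cohort-characteristics table.

Not emulated: cardiac- and respiratory-band signals (unsampleable at TR =
3 s), spatial registration and anatomy, scanner/site effects beyond a
batch label, motion-signal coupling (motion parameters are an independent
random walk), and any claim that the injected gain-covariate coefficients
match real physiology. A green recovery test therefore establishes that
the *pipeline* recovers injected structure of realistic magnitude — not
that the biological effect sizes are correct.

## Numerical choices and degenerate inputs

* Brick-wall FFT band-pass: exact zero phase and exact DC removal; the
  pass/stop behaviour (gain >= 0.8 mid-band, <= 0.2 at 0.002 and 0.15 Hz)
  is probed with on-grid sinusoids. Wrap-around edge artefacts are
  handled by the post-filter edge discard.
* Gaussian smoothing uses a separable truncated kernel (radius 3 sigma,
  renormalised once); an interior impulse preserves total intensity to
  1e-6, signal within the truncation radius of the grid edge is slightly
  attenuated (zero padding).
* Per-lag correlations are recomputed on the overlapping samples with
  per-lag re-standardisation, so every value is a true Pearson r with
  |r| <= 1; the implementation is pinned to a brute-force
  shift-trim-correlate oracle at 1e-12.
* Constant series make correlations undefined and raise errors naming the
  offending input; zero-variance voxels inside a mask are named by index.
* Empirical p-values use add-one corrections and can never be 0; an exact
  linear fit can still produce p = 0 in the OLS limit.
* All randomness flows from explicit seeds; library code saves and
  restores the caller's RNG state.

## Limitations

* The Satterthwaite Hessian is numeric; on boundary fits (subject variance
  near zero) the implementation deliberately falls back to OLS df rather
  than report unstable df.
* The synthetic world links covariates to the coupling gain linearly; it
  cannot probe nonlinear or interaction structure.
* Recomputing the published summary-table p-values from printed (rounded)
  means and SDs reproduces the printed values at printed precision for
  age, gender and APOE cells; a few SUVR/MMSE cells are sensitive to the
  2-decimal input rounding and can only be matched to the significant /
  nonsignificant side.
* `read_nifti()`/`write_nifti()` implement the single-file NIfTI-1 subset
  this package needs (no extensions, no two-file pairs, no quaternion
  geometry) — they are not a general NIfTI library.
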