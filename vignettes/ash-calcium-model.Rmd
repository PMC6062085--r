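---
title: "Modelling stimulus-evoked Ca2+ transients in the ASH neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stimulus-evoked Ca2+ transients in the ASH neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ashca)
```

## The system and the model

The ASH neuron of *C. elegans* is a polymodal nociceptor whose response to
aversive stimuli (e.g. hyperosmotic solution at the nose) is read out
experimentally as a percent change of a FRET sensor ratio, a proxy for
cytosolic Ca²⁺. Two features dominate the transient: an **"on" peak** at
stimulus delivery and a second **"off" peak** at withdrawal. `ashca`
implements a ten-state ODE model of this transient.

States: cytosolic Ca²⁺ `c` (µM), ER Ca²⁺ `c_ER` (µM), TRPV activation and
inactivation gates `O`, `I`, three coarse-grained cascade players `P0`,
`P1`, `P2`, the fraction of inhibited IP₃ receptors `y`, IP₃ concentration
`p` (µM), and membrane potential `V` (mV).

The two mass balances are

$$\frac{dc}{dt} = J_{IPR} + J_{Leak,ER} - J_{PMCA} - J_{SERCA} + J_{TRPV} + J_{VGCC} + J_{Leak},$$
$$\frac{dc_{ER}}{dt} = \gamma\,(J_{SERCA} - (J_{IPR} + J_{Leak,ER})),$$

where $\gamma$ is the cytosol:ER volume ratio (default 5.4, also absorbing
fast linear ER buffering). Pumps follow Hill-squared kinetics; TRPV entry is
$G_{TRPV}\,O\,I\,(c_{ES}-c)$ against a fixed extracellular concentration
$c_{ES} = 2000$ µM; ER release uses the reduced De Young–Keizer open
probability (cubed single-subunit probability) with the original 1992
constants; VGCC influx is a Goldman–Hodgkin–Katz flux with quasi-steady
L-type activation $m_\infty(V)^2$; the membrane potential is a
phenomenological graded (non-spiking) response driven by cytosolic Ca²⁺,
resting at −70 mV with ceiling $V_{max}$ (+20 mV by default — the value is
not constrained by available data and is exposed as a fixed constant).

Assumptions worth keeping in mind: the cell is well mixed (no spatial
gradients), the sensor equilibrates instantaneously and does not buffer
Ca²⁺, TRPV channels carry no voltage dependence, there is no
Na⁺/Ca²⁺ exchanger, and all non-Ca²⁺ currents are absorbed into the graded
voltage phenomenology.

### Sign conventions

Release and entry fluxes ($J_{TRPV}$, $J_{IPR}$, $J_{VGCC}$, both leaks)
are positive **into the cytosol**; pump fluxes ($J_{PMCA}$, $J_{SERCA}$)
are positive **out of** it. $J_{IPR}$ is proportional to $(c_{ER}-c)$ and
the GHK flux is oriented to be a positive influx at physiological negative
potentials with $c \ll c_{ES}$; both orientations are forced by the mass
balances (a release flux must raise cytosolic Ca²⁺) and are unit-tested.
The graded-voltage relation is integrated as a differential equation,
$dV/dt = \alpha'(c)(V_{max}-V) - \beta'(c)(V-V_{rest})$, since a static
reading would make the response instantaneous rather than graded in time.

### Leak calibration

Both leaks are derived, not free: at the analytic rest state
($c = c_0 = 0.1$ µM, $p = 0$, $O = 0$, $I = 1$, $y = c_0/(c_0+K_4)$, $V$ at
the graded-voltage fixed point) the IP₃ receptor is closed, so
$J_{Leak,ER} = J_{SERCA}(c_0)$ and
$J_{Leak} = J_{PMCA}(c_0) - J_{VGCC}(rest)$. After `calibrate_leaks()` the
rest state is a fixed point of the full right-hand side to numerical
precision; a knockout that removes a pump collapses the corresponding leak
(PMCA removal makes the membrane leak essentially zero). A calibrated leak
more negative than 1e-3 µM/s triggers a warning, signalling pump/channel
strengths that are inconsistent with a 100 nM rest.

## Why the "off" peak needs a timescale split

IP₃ is produced by `P1` and suppressed by `P2` (an incoherent feed-forward
motif with a fourth-power suppression term), gated by cytosolic Ca²⁺ through
$c^2/(c^2+K_c^2)$ (Ca²⁺-induced Ca²⁺ release, CICR). For the surge of `p` to
occur only at withdrawal, the suppressing branch must both **arrive before**
the activating branch at onset and **leave before** it at offset. The
reference set therefore makes `P0` and `P2` fast (sub-second to ~1 s) and
`P1` slow (~4 s). At stimulus onset, suppression is in place before `P1`
rises; at withdrawal, suppression collapses within a second while `P1` —
and hence IP₃ production — persists for several seconds, producing the IP₃
surge that dumps the ER store. CICR makes this release regenerative: the
released Ca²⁺ strengthens both IP₃ production and receptor opening, so the
off response behaves like a thresholded ignition. This is also what keeps a
TRPV knockout silent at onset (cytosolic Ca²⁺ never rises, so CICR never
ignites during the pulse) while its off response is *amplified* — the ER
was never drained, and ignition at withdrawal starts from a full store.

## The reference parameter fixture

No reference table of fitted values is shipped with the available source
material, so the package provides its own versioned 23-parameter reference
set (`make_reference_params()`), designed against four anchors: rest at
100 nM, an on-peak of 8–12 % FRET under the standard 30 s unit-magnitude
square pulse, a stable plateau over the 30–40 s window, and a distinct
off-peak after withdrawal. It is a synthetic fixture — a concrete,
reproducible operating point for tests and examples — not a fitted or
published parameter set. Its values live in `R/synthetic.R` with unit
annotations; the knockout phenotype matrix and the complex-stimulus suite
in the test directory document the behaviours it guarantees.

The stimulus is dimensionless, expressed relative to a reference magnitude
$\alpha \equiv 1$; the transduction stage `S/(S + K_P0)` uses a large
`K_P0` (400) so that responses stay approximately linear in stimulus area
up to ~10× the reference magnitude while still saturating for very strong
stimuli.

## Units, fixed constants, and numerical conventions

* Time s; concentrations µM; voltage mV; fluxes µM/s.
* Temperature 293.15 K (≈20 °C, standard worm culture), giving
  $RT/zF \approx 12.63$ mV for $z = 2$.
* De Young–Keizer constants: $K_1 = 0.13$, $K_2 = 1.049$, $K_3 = 0.9434$,
  $K_4 = 0.1445$, $K_5 = 0.08234$ µM; $k_2^- = 0.2098$, $k_4^- = 0.0289$ /s
  (the original 1992 values). With these, $\phi_1$ reduces exactly to
  $0.2\,c$ — a convenient independent check.
* ER initial content $c_{ER,0} = 10$ µM and $\gamma = 5.4$ are package
  defaults (configurable), chosen as a plausible store size for a small
  neuron; they are not literature-fitted values.
* Removable singularities (the L-type $\beta$ rate at $V = 1.31$ mV, the
  graded-voltage rates, the GHK flux at $V = 0$) are evaluated by a guarded
  series branch within $10^{-4}$ of the singular point; the GHK value at
  $V = \pm 10^{-6}$ mV matches the analytic limit to $10^{-6}$ relative.
* Integration: `deSolve::lsoda` (stiff-capable, adaptive) at `rtol = 1e-8`,
  `atol = 1e-10`, restarted at every stimulus-segment boundary so square
  edges are never smeared; stimulus segments are half-open `[start, end)`
  and evaluation at a discontinuity takes the right-side value.
* Divergence flag: solver failure, cytosolic Ca²⁺ above $100\,c_{ES}$, or
  failure to return towards baseline (final $c > 10\,c_0$). The last
  criterion is what detects the PMCA knockout, whose bounded dynamics settle
  at a far-from-rest plateau rather than overflowing numerically.

## Transient features

`extract_features()` computes the eight summary statistics of a transient:
on-peak and its time, plateau level (mean FRET over the 30–40 s window of
the response clock for pulses of ≥40 s; for shorter pulses, the final third
of the pulse), the on decay slope
$(on_{max}-A_{plateau})/(T_{minplateau}-T_{max})$, off-peak and its time,
the off rising slope measured from stimulus offset, and the off decay slope
$off_{max}/|T_{offmax}-T_{min}|$. Two conventions are deliberate choices:
$T_{minplateau}$ is the first time after the on-peak at which the trace
enters within 2 % of the plateau level, and the off decay interval is taken
as an absolute value. When "off-peak magnitude" is used as a criterion
(knockouts), it means the **rise above the FRET level at stimulus offset**,
since the raw post-offset maximum of any trace with a plateau is just the
plateau itself.

## Synthetic cohorts and what passing tests mean

`generate_dataset()` emulates the structure of cohort recordings: four
cohorts (young/aged × unstressed/stressed) as multiplicative
parameter-modification maps on the reference set, ~17–35 replicates, a 30 s
square stimulus, and i.i.d. Gaussian replicate noise on the percent-FRET
scale, summarised as per-time mean and standard deviation. The presets
encode the qualitative aging/stress phenotypes (stronger peaks, altered IP₃
turnover) and are labelled synthetic. What the generator does **not**
emulate: correlated (worm-level) noise, baseline drift, photobleaching,
sensor saturation artefacts, or variable stimulus delivery. Estimation
tests passing on this generator therefore demonstrate correctness of the
pipeline (identifiable parameters are recovered at realistic noise), not
performance on real recordings.

## Estimation

The objective is the standardized residual
$(FRET_{model}(t_i) - \mu_i)/\sigma_i$; both optimizer stages minimize the
identical sum of squares ("sum of residuals" is implemented as the sum of
squared residuals so the global and local stages share one functional). The
global stage is a real-coded genetic algorithm over log-parameters
(positivity is structural): tournament selection, simulated binary
crossover, polynomial mutation, (µ+λ) survivors; defaults 48 individuals ×
40 generations within a ±1 decade box. Its best individual seeds a
Levenberg–Marquardt refinement (`minpack.lm::nls.lm`) — a damped
Gauss–Newton least-squares step of the same family as trust-region
reflective methods, with bounds made unnecessary by the log transform. The
covariance diagonal is $s^2\,\mathrm{diag}((J^\top J)^{-1})$ from a
forward-difference Jacobian with respect to the **raw** parameters at the
optimum, so sensitivities carry parameter units; `covariance_select()`
picks the candidate with the smallest covariance-diagonal sum and excludes
rank-deficient candidates.

`multiobjective_seed()` runs an NSGA-II-style non-dominated-sorting GA with
one objective per cohort and returns, from the non-dominated set, the
individual with the smallest total residual, plus the final population as a
warm start for the single-cohort GA.

`enumerate_plausible()` re-fits every combination (default: sizes ≤ 2 — a
desk-scale reduction of the full $2^{13}-1$ sweep, which remains available
via `max_size = 13`) of the 13-parameter selectable subset
({G_PMCA, K_PMCA, G_SERCA, K_SERCA, G_IPR, k_p, k_p⁻, k_O, k_O⁻, k_I, k_I⁻,
k_P0, k_P0⁻}), pools the results per cohort, and flags a combination
plausible when (1) its residual lies in the best 1 % of the pool
(ceiling-rounded, so at least one combination always survives) and (2)
every re-fitted parameter moved by more than its covariance-derived
sensitivity (the square root of the reference covariance diagonal). The
percentile is applied per cohort pool; applying it jointly across cohorts
would mix incommensurable residual scales.

`sensitivity_scan()` perturbs all 23 parameters multiplicatively and
uniformly within ±25 % (100 samples per set by default), recalibrates the
leaks for each sample, and records on/off peak FRET; diverged samples are
retained with a flag.

Problem sizes used throughout the examples and tests — 30 replicates at
0.2–2 % FRET noise, 0.5 s data grids over 80 s, GA budgets of a few
thousand model evaluations — were chosen as representative desk-scale
settings; a single 90 s simulation costs a few milliseconds, so all
pipelines run interactively.

## Known limitations

* The reference fixture is synthetic; absolute parameter values should not
  be interpreted biologically, only the mechanism structure and the
  qualitative phenotypes.
* The IP₃-surge mechanism relies on the P1/P2 timescale split; stimuli with
  strong power below ~1 s interact with the P2 timescale, which is why the
  default flicker protocol is 2 Hz (slower equal-area flicker pairs
  progressively diverge).
* The gate named "inactivation probability" `I` multiplies the TRPV flux
  yet rests at 1 and *decreases* under stimulation; the equations are
  implemented exactly as specified and the naming oddity is left as-is.
* Identifiability is assessed only through the covariance diagonal; no
  profile likelihoods or Bayesian posteriors are computed.
* Knockout mode `"updated"` re-fits the remaining selectable parameters
  against a target dataset; with the default budgets this is a demonstration
  of the workflow rather than an exhaustive compensation search.
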