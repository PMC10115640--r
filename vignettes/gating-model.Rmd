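---
title: "A kinetic model of CFTR gating and its single-molecule analysis chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A kinetic model of CFTR gating and its single-molecule analysis chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cftrgate)
```

## The model

CFTR is an ATP-gated anion channel of the ABC-transporter family. Its two
nucleotide-binding domains (NBDs) dimerize when ATP occupies the two
composite interfacial sites, and pore opening is driven by conformational
changes downstream of dimerization. Single-molecule FRET on labelled NBDs
and single-channel recording probe two different reaction coordinates of
the same machine: inter-NBD distance (low-FRET separated vs. high-FRET
dimerized) and pore conductance. The central quantitative facts the model
has to reconcile are that at saturating ATP the channel is NBD-dimerized
about 85% of the time but open only about 22% of the time, that dimerized
sojourns outlast open bursts roughly twenty-fold, and that both dose
responses share a common midpoint near 50 µM ATP. NBD dimerization and
pore opening are therefore allosterically, not rigidly, coupled.

`cftrgate` encodes this picture as a nine-state continuous-time Markov
chain (`build_topology()`):

| state | meaning | FRET class | conducting |
|---|---|---|---|
| `SEP_apo` | NBDs separated, no nucleotide | low | no |
| `SEP_atp` | NBDs separated, ATP bound | low | no |
| `DIM_closed` | NBD dimer, pre-open | high | no |
| `OPEN_pre` | open burst, pre-hydrolytic | high | yes |
| `FLICKER` | brief closure inside the burst | high | no |
| `OPEN_post` | open, post-hydrolytic | high | yes |
| `DIM_ADP` | non-conductive ADP-bound dimer | high | no |
| `INT_dimer` | nucleotide-exchange intermediate, interface engaged | high | no |
| `INT_sep` | exchange intermediate, partially separated | low | no |

Thirteen directed transitions connect them: ATP association/dissociation
to the separated channel (`k_bind`·[ATP], `k_unbind`), dimerization
(`k1`, blocked in dephosphorylated channels), the rate-limiting opening
step (`k2`), flicker entry/exit (`k_flick_on`, `k_flick_off`),
hydrolysis at the consensus site (`k3`), post-hydrolytic closure (`k4`),
ADP release (`k5`), ATP rebinding at the dimer interface (`k6`·[ATP]),
isomerization of the exchange intermediate (`k7_fwd`, `k7_rev`) and
complete separation (`k8`). Only `k_bind` and `k6` are ATP-proportional
(pseudo-first-order). The cycle is driven: hydrolysis breaks detailed
balance, and the net flux through the `k3` edge is the ATP turnover.

This topology is a deliberate concretization. The structural evidence is
a cartoon of eight mechanistic steps, not a state list; we chose the
minimal graph that realizes those steps plus the flicker substate, and
version it as the package's canonical topology so alternatives can be
added alongside. Three simplifications matter most:

* **Lumped nucleotide occupancy.** Binding at the degenerate and
  consensus sites is collapsed into a single ATP-bound separated state
  plus the rebinding path through the exchange intermediate. Evidence
  from site-directed binding variants is qualitative, and site-resolved
  occupancy is not identifiable from the printed observables; the
  multimodality of dwell-time distributions attributed to single-site
  occupancy is explicitly outside this model's scope.
* **Irreversible opening.** `DIM_closed -> OPEN_pre` has no reverse
  edge; closure proceeds through the flicker or the hydrolytic path.
  Pre-hydrolytic full closure is rare, and omitting it keeps the cycle
  identifiable. A corollary worth stating plainly: the only way out of
  an open burst is the `k3` edge, so in variant presets that shorten
  bursts without hydrolyzing ATP (G551D, L927P), `k3` functions as the
  burst-terminating relaxation rather than literal hydrolysis, and the
  near-zero `k3` firings those presets produce are consistent with their
  near-abolished ATPase activity.
* **Return path after separation.** Whether complete separation leaves
  ATP bound is not directly observable; because the degenerate site
  retains nucleotide for minutes, `INT_sep` resolves to `SEP_atp`
  rather than to the apo state.

## Exact computations

`stationary_distribution()` solves the global balance equations by
replacing one balance row with the normalization constraint (dense
`solve`; the graphs are small and well-conditioned in the physiological
rate range). Occupancies are clipped at zero and renormalized, and a
residual beyond 1e-8 is an error, never silently accepted.
`occupancy_relaxation()` propagates the master equation with a single
matrix exponential of the generator times the grid step, applied
iteratively - exact for a time-homogeneous chain, with cost independent
of stiffness. Mean sojourn times of aggregate classes (the dimerized
class, the open burst) are computed by linear algebra: entry weights are
stationary probability fluxes into the class, and mean absorption times
come from the negated sub-generator. The deterministic burst definition
aggregates `OPEN_pre`, `FLICKER` and `OPEN_post`, i.e. it treats all
flickers as bridged; with the calibrated flicker dwell of ~1.4 ms the
discrepancy against the stochastic 10-ms-bridged definition is below one
percent.

`simulate_ssa()` is an exact Gillespie sampler. Under piecewise-constant
ATP protocols the pending waiting time is redrawn at each schedule
breakpoint, which is valid because the chain is memoryless. One
`set.seed()` per simulation (R's default Mersenne-Twister) makes paths
bit-reproducible; ensemble members derive per-trace seeds from the
master seed by a fixed affine map.

## Calibration

The thirteen rate constants are not printed anywhere; they are estimated
by `calibrate_rates()` from the printed observables, and the shipped
wild-type rate set is the frozen output of that optimization (the target
file ships with the package, `extdata/wt_targets.json`). The objective
is a weighted sum of squared scaled residuals over: Po = 0.22 and
Pdim = 0.85 at 3 mM ATP, dwell ratio 20 (25% tolerance in the shipped
file: the measurement is itself an "approximately"), activation
τ = 490 ms, separation τ = 1.6 s and 20 s, EC50s of 53 µM and 55 µM,
and a *window* (not a point) of 0.3-1 s⁻¹ on hydrolysis turnover,
because a minimal cycle model is expected to sit high in - or above -
the measured range. Optimization runs in log-rate space (rates span five
decades) under box bounds of 1e-3 to 1e3 s⁻¹ for first-order and 1e3 to
1e8 M⁻¹s⁻¹ for second-order constants, by multi-start L-BFGS-B; the
objective uses only the deterministic quantities above, never stochastic
simulation, so it is noise-free. Equal-objective restarts resolve to the
lowest restart index.

Two residuals deserve comment. The model cannot split the two
dose-response midpoints: opening and dimerization are gated by the same
binding-limited entry into the cycle - which is precisely the
experimental observation - so both fitted EC50s converge to ~54 µM,
inside the measured uncertainties (53 ± 4 and 55 ± 8 µM) but never
exactly 53 *and* 55. And the calibrated turnover (0.33 s⁻¹) sits at the
low end of its window; pushing it higher trades away the separation time
constants. Individual rates are not claimed to be identifiable from
these targets (the round-trip property tests check recovery of
*observables*, not rates).

Relaxation constants are defined operationally, exactly as measured:
`tau_opening_s` is a mono-exponential fit to the rise of open occupancy
after an instantaneous jump from the phosphorylated apo state to 3 mM
ATP, and the separation constants are a bi-exponential fit to the decay
of dimerized occupancy after setting ATP to zero from the saturating
stationary state. The fast phase is the drainage of the cycle in
progress; the slow phase arises from re-dimerization of channels that
still hold nucleotide, and ends with full dissociation. Solvent-exchange
kinetics of perfusion systems (~115-150 ms) are *not* convolved into
these model relaxations: the 490 ms activation is treated as intrinsic,
being ~3-fold slower than exchange. The fits use `fit_relaxation()`
(Levenberg-Marquardt with exponential-peeling start values); grids are
10 ms over 6 s for activation and 50 ms over 90 s for withdrawal, wide
enough that the 20 s component is constrained by a 4.5-fold horizon.

## The synthetic-trace generator

`generate_ensemble()` exists so that every downstream analysis stage can
be tested against known truth without any external data. It emulates,
per trace: exponential start-state draws from the condition's stationary
law; camera frame integration at 10 or 100 ms computed as the exact
dwell-weighted average of state emission means within each frame (so
sub-frame excursions appear at intermediate apparent efficiencies - the
time-averaging artifact that corrupts naive rate estimates); Gaussian
noise on the two detection channels (not on the efficiency), default
total intensity 500 counts with per-channel sd 25, giving a
signal-to-noise ratio of ~14 and a per-frame FRET sd of ~0.05;
single-step donor photobleaching (exponential, mean 30 s against a 60 s
record - values chosen to give realistic pre-bleach record lengths of a
few hundred frames); and donor blinking (Poisson arrivals at 0.05 s⁻¹,
exponential 0.3 s durations). A blink silences *both* channels: without
an excited donor there is no sensitized acceptor emission, so modelling
blinks as donor-only dark states would create spurious efficiency-one
frames instead of dark frames.

Emission means are 0.25 for the separated state in the dephosphorylated
apo condition, shifting to 0.28 whenever ATP is bound or the channel is
phosphorylated (a local rearrangement around the labels, not NBD
approach), 0.49 for the dimerized state, and intermediate values for the
partial-approach variants (0.37 for G551D, 0.31 for L927P). In those
variants the non-conducting dimer-class states carry the intermediate
(`mid`) FRET class while the rare conducting excursions remain fully
dimerized at 0.49 - which reproduces the observed rare excursions from
the intermediate level.

Current traces are a boxcar conduction signal plus Gaussian noise passed
through a causal 4-pole low-pass Butterworth filter (`signal::butter`
coefficients at the stated corner over half the sampling rate), the
digital stand-in for the analogue filtering conventional in
electrophysiology; 2 ms flickers at 100 Hz filtering are attenuated by
more than half, as in real filtered records.

What the generator does *not* emulate - spectral crosstalk, gamma
correction, acceptor photophysics, baseline drift, multi-channel
records, the heavy-tailed intensity distributions of real cameras -
bounds what passing round-trip tests show: they validate the analysis
chain's correctness and its statistical behaviour under the stated noise
model, not its robustness to every artifact of real data.

## Quality control and idealization

`qc_select()` replaces manual trace curation with deterministic filters,
applied in a fixed order so every rejection has a single attributable
reason: single-step photobleaching, then blink count, signal-to-noise,
frames above baseline, and the maximum-FRET exclusion. Numerical
choices the underlying reports do not specify, fixed here as package
definitions: SNR is mean total pre-bleach intensity over its standard
deviation (threshold 8); bleaching is detected as the change point
maximizing the one-step SSE reduction on total intensity, requires at
least 80% depletion, and the trace is rejected if the pre-bleach segment
(excluding dark frames) contains another sustained step of at least 30%
of the initial level; dark frames are those below 30% of the 98th
intensity percentile - several noise standard deviations away from both
levels of the bimodal intensity distribution; the FRET baseline is 0.1
(at least 50 frames above it); and traces with more than 2% of frames
above 0.8 efficiency are excluded as the nucleotide-insensitive
subpopulation. With the default generator settings these criteria accept
roughly 70% of traces, rejecting mostly records that never bleach within
the observation window or bleach too early to analyze - the same
attrition pattern seen in real screens.

`skm_idealize()` implements segmental k-means with the standard
two-state model (means 0.25 and 0.48, sds 0.1): iterated most-likely
Gaussian segmentation with a uniform switch penalty, followed by
re-estimation of the state means from the assigned frames. The penalty
(3 nats per switch) is the segmentation prior the original analysis
does not state; it is exposed as a parameter. The path log-likelihood
is non-decreasing across iterations, and the loop stops when the
assignment is stable. Two post-rules handle degenerate geometry: states
with fewer than two assigned frames keep their initial means, and
states whose re-estimated means fall within one model standard
deviation (0.1) of each other are merged, because two Gaussians closer
than one sd are not separable at the single-trace level - this is what
lets a unimodal intermediate-FRET variant distribution re-estimate to a
single state at its true center instead of being split artificially.
Dark frames are excluded from segmentation and re-estimation, and
sojourns interrupted by blinks are censored in dwell extraction.

Ensemble summaries (`ensemble_state_means()`) pool per-trace
re-estimated means with frame weights, keeping only states occupying at
least 10% of a trace's usable frames; the `principal` (highest
qualifying), `principal_low` and `modal` (most occupied) reporters
correspond to the high-FRET state mean, low-FRET state mean, and the
center of the predominant conformation respectively.

## Dwell times, dose responses, transition frequency

`extract_dwells()` produces maximal sojourns per aggregate class;
first/last sojourns per trace are censored, and burst analysis bridges
non-conducting gaps shorter than 10 ms into the surrounding open sojourn
(`bridge_class` names the absorbing class, so gap time is counted once
and the partition still tiles the record). `fit_survival()` fits
exponential mixtures by maximum likelihood with right-censored sojourns
contributing survival terms - discarding them would bias rates upward in
short records - and reports BIC for one- versus two-component
comparison. It warns whenever a fitted mean dwell falls below three
camera frames, the regime where time averaging corrupts apparent rates.
`fit_hill()` fixes the Hill coefficient to 1 by default, matching the
convention for these dose responses. `transition_frequency()` counts
low/high class switches per analyzable second; on idealized traces,
switches across dark gaps are not counted.

The model reproduces the bell-shaped dependence of that frequency on
ATP: at low ATP, entries into the dimerized state are binding-limited
and rare; at saturating ATP, rebinding at the dimer interface outruns
complete separation, so the channel idles through many hydrolytic
cycles per FRET excursion; exchange dynamics are maximal in between
(around 30-100 µM in the calibrated model).

## Validation scale and reproducibility

The shipped checks run at sizes chosen to keep statistical power without
waste: stochastic-versus-exact equivalence on random graphs uses
4000-second runs with block-bootstrap standard errors; dwell-ratio
validation pools eight 2000-second simulations (~1000 dimerized
sojourns, ~3.5% standard error); the trace round trip uses 300 traces of
60 s at 100 ms frames per condition, recovering condition centers to
within ±0.005 of the emission truth; mixture-recovery and Hill-recovery
studies use 5000 dwells and 500 replicates respectively. Every
stochastic result in the package is a pure function of an integer seed.

## Known limitations

* Rates are effective, not microscopic: the lumped binding path makes
  `k_bind` a composite of association and commitment, and individual
  rates are only constrained jointly.
* At zero ATP the re-dimerization loop implies some hydrolytic cycling
  during the slow separation phase; the model is calibrated to the
  FRET decay, and its post-withdrawal *current* decay inherits the slow
  component rather than the faster hydrolysis-limited decay seen
  experimentally.
* Dwell-time distributions are single-mode per aggregate by
  construction; the experimentally observed multimodality (attributed
  to single-site occupancy states) needs a site-resolved extension.
* ADP competition, divalent withdrawal, phosphate-analog trapping,
  graded phosphorylation and potentiator pharmacology are out of scope;
  phosphorylation is a binary switch on `k1`.
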