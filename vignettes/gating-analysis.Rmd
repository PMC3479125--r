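---
title: "Methods: single-channel VDAC gating analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-channel VDAC gating analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, algorithms and numerical choices behind
`vdacgate`: what the gating simulator assumes, how traces are idealized and
decomposed into conductance states, which parameters matter, and what the
synthetic-data tests do and do not demonstrate about real recordings.

## 1. The gating model

A reconstituted VDAC channel is modelled as a **semi-Markov process** over a
small set of conductance states: the open state S0 and the low-conductance
states S1, S2A and S2B. The channel stays in state $s$ for an exponentially
distributed sojourn with mean $\tau_s$ (seconds) and then jumps to a
successor drawn from a categorical distribution $w_{s\cdot}$ over the other
states. This is the weakest model consistent with what single-channel BLM
studies typically report — per-state **mean** dwell times and state
identities, but no rate matrix. Two consequences:

* The per-state successor weights are not identifiable from published means
  alone; the defaults route all closures through S0
  (`S0 -> {S1: 0.50, S2A: 0.35, S2B: 0.15}`, every closed state back to S0
  with weight 1), matching the observation that closed states are entered
  from the open level. Direct S1–S2 transitions can be configured but are
  off by default.
* S2A and S2B share one dwell mean, because only a single S2 dwell is
  reported.

Rendering is **Ohmic**: $I(t) = g_{s(t)}\,V(t) + \varepsilon(t)$ with $g$ in
nS and $V$ in mV, so currents are in pA, plus Gaussian acquisition noise
$\varepsilon \sim \mathcal N(0, \sigma^2)$ with $\sigma = 2$ pA at the 5 kHz
acquisition rate. The noise default is a design choice (acquisition noise of
painted-bilayer rigs is not usually printed); it is set so that the smallest
state separation used in classification (~0.4 nS, i.e. 16 pA at 40 mV)
exceeds five standard deviations of the decimated noise
($2/\sqrt{25} = 0.4$ pA at 200 Hz).

Each sojourn additionally receives a **per-event conductance scatter**
(`conductance_sd_nS`, default 0.12 nS) around its state mean. Measured
closed-state amplitude histograms are roughly 0.1–0.15 nS wide per
component — far wider than per-sample noise alone can explain — reflecting
membrane-to-membrane and event-to-event variability. Without this term the
simulator's amplitude histograms would be needle-thin and the Gaussian
decomposition trivially easy; 0.12 nS reproduces the widths that the
published two-Gaussian fits imply. Set it to 0 for exactly reproducible
levels (used by the zero-noise oracle tests).

**Polarity asymmetry.** For cross-linked variants that close under one field
orientation only, the preset carries `asymmetric = TRUE` and an
`orientation` of +1 or −1. During simulation, any transition out of S0 is
suppressed (the S0 sojourn simply continues — valid by memorylessness)
whenever `sign(V) != orientation`, and a closed sojourn is forced back to S0
the instant the voltage leaves the closing polarity. The convention that
`orientation = +1` means "closure permitted at positive voltages" is
arbitrary (the orientation a channel adopts on insertion is random); it is
documented and configurable.

**Seeding.** One master seed drives everything; the state path, the
conductance scatter and the recording noise use independent streams derived
by `derive_seed()`, so the same gating path can be re-rendered with a
different noise realization. Identical seeds give bit-identical traces.

### Preset parameter sources

`build_preset()` ships the variants studied in the wet-lab characterization
this package models: `native` (S0 3.94, S1 2.61, S2A 2.03, S2B 1.48 nS;
dwells 27.40 / 2.92 / 2.45 s), `cysteinless`, the N-terminal truncation
`delta21` (single constitutively open state, 4.00 nS), and the oxidized and
reduced forms of the two double-cysteine variants (`A14C-S193C_ox`
S0-dominated with a mean S0 dwell of 1836.6 s; `V3C-K119C_ox` asymmetric).
Where the text and the summary table of the source measurements disagree on
the reduced variants' conductances, the table values are used. The closed
state of `A14C-S193C_ox` is made effectively absorbing (mean dwell $10^6$ s)
because that channel does not reopen once closed; a semi-Markov chain has no
literal absorbing sojourn.

The printed per-state native dwell means imply a visit-weighted mean sojourn
of ≈15.0 s, whereas the overall "any state before switching" statistic is
reported as 10.34 s — the two were evidently measured on different event
sets. The presets keep the printed per-state means;
`rescale_dwell_means(preset, 10.34)` multiplies all dwell means by a common
factor so the theoretical overall mean (visit frequencies of the embedded
jump chain × dwell means, `theoretical_mean_sojourn()`) matches the overall
statistic. The dwell-recovery analyses in the acceptance material use that
rescaled preset, since the overall mean is the quantity they target.

## 2. Idealization

**Baseline.** Conductance levels are defined relative to the zero-channel
baseline. `estimate_baseline()` histograms per-sample $|I|/|V|$ (0.05 nS
bins), takes the lowest occupied cluster, and returns the mean current of
its samples — which equals any additive current offset. A trace with no
baseline-level samples yields the lowest-conductance *state* cluster instead
and a warning; simulated pipelines therefore prepend a 2 s channel-free
lead (`baseline_lead_s`). An all-zero-voltage trace has no conductance
axis; the median current is returned, flagged.

**Segmentation.** Each constant-voltage region is split by recursive binary
change-point detection: the CUSUM of mean-centred samples locates the best
single split; a split is accepted when the two sides' means differ by more
than `jump_threshold_pA` (default 4× a robust noise estimate,
$1.4826\,\mathrm{med}|\Delta x|/\sqrt2$), and the procedure recurses. Runs
shorter than `min_duration_s` (default 25 ms = 5 samples at 200 Hz, the
shortest run with a stable mean) are merged into the neighbour with the
closer mean. A final pass removes **transition artifacts**: block
decimation blends the one sample spanning each level change, which can pull
the detected change point a few samples off the true boundary and leave a
brief run whose mean lies strictly *between* its two neighbours' means.
Such between-level runs shorter than twice the minimum duration are merged
into the closer neighbour — a genuine brief state visit lies outside the
band spanned by its flanking levels (closures depart from and return to the
open level), so real events are not absorbed. Without this pass the
artifact fragments break open-state sojourns and bias dwell means several
percent low. The algorithm is deterministic, parameter-light and exactly
recovers change points on zero-noise traces (to one analysis sample, the
resolution limit after block decimation), which the property tests exploit
as an oracle against the simulator's own state path. There is no
sub-sample interpolation and no missed-event correction: sojourns briefer
than 25 ms are absorbed into their neighbours, which thins fast events
(~1 % of closed sojourns at the native time scales) and slightly lengthens
apparent open dwells.

**Classification.** An event of conductance $g$ is assigned to reference
state $r$ when $|g-r| \le 0.05\,r$ (the ±5 % convention used for state
identification in this field); overlapping windows are resolved by the
smallest relative distance. Values matching no window are `INTERMEDIATE` —
deliberately retained, because transitions of the base-cross-linked variant
pass through intermediate conductances — unless they fall below the
smallest reference by more than a further window width (`BASELINE`).
Windows are applied to conductance, not current; at constant voltage the
two are equivalent.

## 3. Conductance analysis

**Ohm fits.** Per-state conductances are the slopes of through-origin
weighted least-squares fits of per-voltage mean ΔI against V (weights = the
number of events per voltage). The channel responds linearly at both
polarities, so an intercept-free fit is appropriate; a free-intercept
diagnostic is available. With events at a single voltage only, the mean
per-event conductance is returned and flagged. The SEM is the per-event
conductance SD over $\sqrt n$.

**Mixture decomposition.** The closed-state sample (all events that are not
S0 or baseline, including intermediates below the S1–S0 midpoint) is binned
at 0.05 nS — about the resolution of published amplitude histograms — and a
sum of $k$ Gaussians is fitted to the binned counts by Levenberg–Marquardt
least squares. This mirrors the Origin-style histogram workflow whose
$R^2$ values are reported in the literature; a likelihood-based EM fit
would weight the data differently, so the binned fit defines the reported
numbers, and EM (via mclust) serves only as an independent cross-check in
the test suite. Starting values come deterministically from histogram
peaks, with quantile-based fallbacks; for $k=2$ the $k=1$ solution with a
zero-amplitude twin is included among the candidates, so
$R^2_{k=2} \ge R^2_{k=1}$ holds structurally. Components are reported
sorted by descending mean with weights proportional to component area
($A_i\sigma_i$); fitted SDs are bounded below by a quarter bin width.

`decompose_closed_states()` runs the nested two-stage procedure: stage 1
splits all closed conductances into S1 (upper) and S2 (lower) components;
stage 2 refits two Gaussians inside the 0.80–2.20 nS S2 window, resolving
S2A (upper) and S2B (lower). Events are assigned to the nearest component
mean in SD units — the assignment rule behind the reported sub-state
counts, chosen because no explicit rule is published. Both the closed-state
sample mean and the single-Gaussian fitted mean are reported (it is not
documented which one a printed "mean closed state" refers to), and the
S2A:S2B ratio is given both as a count ratio and as a component-area ratio,
since the two need not agree and the published figures are ambiguous on
this point.

## 4. Dwell times and asymmetry

Sojourns are maximal runs of same-state segments within one
constant-voltage region; adjacent same-label segments are merged only when
their conductances agree within 0.05 nS, which heals spurious splits
without collapsing genuine switches between like-labelled events. The first
and last sojourn of every region are censored (their true extent is
unknown) and excluded. `dwell_summary()` reports per-state mean ± SEM and
n, the overall any-state-before-switching statistic, and an S2 union row
(S2A + S2B + in-window intermediates). Dwell times are pooled across
voltages by default and treated as voltage-independent, as the single
published numbers per variant imply. Exponential-mixture dwell fitting and
kinetic rate estimation are out of scope.

`fold_change()` reproduces the reporting conventions (half-up rounding to
integers, tens, or one decimal — e.g. 1836.60/10.34 → 180 with nearest-ten
rounding).

`detect_asymmetry()` computes closed-time fractions separately at positive
and negative voltages. A channel is called asymmetric when one polarity
closes less than 0.5 % of the analyzable time while the other exceeds 2 %;
the defaults classify the simulated presets correctly from ≥60 s per
polarity and are configurable. The waiting-for-reversal dwell of an
asymmetric channel under a given protocol conflates protocol timing with
intrinsic kinetics; the simulator reproduces such numbers only under a
matching protocol.

## 5. Statistics

Values are reported as mean ± SEM ($\mathrm{sd}/\sqrt n$, $n-1$
denominator). Two-sample comparisons use Welch's t from summary triplets:
$t = (\bar a - \bar b)/\sqrt{\mathrm{sem}_a^2 + \mathrm{sem}_b^2}$ with
Welch–Satterthwaite degrees of freedom. Welch's form is the defensible
default for the very unequal group sizes and variances in this material
(published "Student t-tests" from summary calculators are reproduced to
order of magnitude, not digit-for-digit); the pooled-variance form is
available via `pooled = TRUE`. Under the null, the test's type-I error at
$\alpha = 0.05$ is calibrated to [0.04, 0.06] in 10,000-rep simulation. No
multiple-testing correction is applied (none is used in this workflow).

## 6. Problem sizes, determinism, degenerate inputs

* The acceptance material simulates 50 × 64 s recordings for the Ohm-fit
  target, draws the closed-state sample at the reported counts
  (386/224/70, scatter 0.12 nS) for the decomposition targets, and
  simulates until ≥300 uncensored sojourns for the dwell target; the
  20-replicate recovery check analyzes three ~64 min recordings per
  replicate. These sizes give estimator precision comfortably inside the
  stated tolerances (±0.08 nS, 3 SEM) at desk scale.
* All pipelines are deterministic given (config, seed): reports are
  byte-identical across reruns, with timestamps confined to the run log.
* Degenerate inputs fail loudly and early: unknown presets and unknown
  config keys are rejected before any computation; empty traces,
  single-polarity asymmetry queries, all-censored dwell sets and
  sub-minimum mixture samples raise informative errors; single-bin
  amplitude histograms return a flagged single component.

## 7. What the synthetic tests do and do not show

The simulator reproduces the statistical structure the analysis assumes:
Ohmic piecewise-constant levels, exponential sojourns, Gaussian noise and
event scatter, polarity-gated closure, ≤5 summed channels. Passing the
recovery tests therefore demonstrates that the estimators are correct and
calibrated *under these assumptions*. Real BLM records additionally contain
capacitance transients at voltage steps (an `edge_trim_s` parameter exists
for them), 1/f and flicker noise, baseline drift, non-exponential and
voltage-dependent dwells, and occasional antiparallel insertions — none of
which are modelled, and all of which can degrade segmentation and
classification in ways these tests do not measure. The package's claims
about real data are therefore methodological (reproducibility,
determinism, explicit parameters), not a validation against wet-lab
recordings, which are not publicly deposited for this system.
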