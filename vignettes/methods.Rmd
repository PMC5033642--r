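---
title: "Modelling tDCS-modulated effective connectivity in the frontal naming network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tDCS-modulated effective connectivity in the frontal naming network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcsdcm)
```

## The scientific question

Anodal transcranial direct current stimulation (tDCS) applied over left
frontal cortex during overt picture naming speeds naming and reduces the
BOLD response in the left inferior frontal sulcus (IFS) and left ventral
premotor cortex (VPM). `tdcsdcm` implements the effective-connectivity
analysis that asks *how* stimulation changes the coupling within this
two-region network, and whether individual variability in the coupling
change predicts individual behavioural facilitation.

The pipeline has five stages, each exposed as ordinary R functions:

1. a generative model of the data (bilinear neural dynamics plus a
   balloon-Windkessel haemodynamic model),
2. a crossed space of six candidate network architectures,
3. variational-Laplace inversion of each model against each subject's
   two-session region-of-interest (ROI) time series,
4. fixed-effects Bayesian model selection (BMS) and sampling-based
   Bayesian model averaging (BMA) with a two-distribution test for
   condition differences, and
5. a behavioural stage: reaction-time (RT) cleaning, one-tailed paired
   tests, and the Pearson correlation between per-subject connectivity
   change and naming facilitation.

Because no imaging data are distributed with the package, a synthetic
cohort generator reproduces the study design end to end, and every stage
is tested against it.

## The generative model

Neuronal activity $x \in \mathbb{R}^2$ follows the bilinear state equation

$$\dot x = (A + B_{c})\,x + C\,u(t),$$

where $A$ (Hz) is the intrinsic coupling, $B_c$ the modulation by
stimulation condition $c \in \{\text{anodal}, \text{sham}\}$, $C$ the gain
of the driving input, and $u(t)$ a train of unit-mass sticks at picture
onsets. Rows index the target region, so `A[2,1]` is the backward
IFS-to-VPM influence. Self-connections (the diagonal) are inhibitory;
their magnitude is the decay rate of regional activity, and
`halfLife(a) = log(0.5)/a` converts one to the time for activity to halve
(2.67 s at $-0.26$ Hz, 7.70 s at $-0.09$ Hz).

Each region's activity drives the standard balloon-Windkessel cascade
(vasodilatory signal $s$, inflow $f$, volume $v$, deoxyhaemoglobin $q$)
and the usual BOLD observation equation with $k_1 = 7E_0$, $k_2 = 2$,
$k_3 = 2E_0 - 0.2$. The haemodynamic constants are fixed at the canonical
literature set ($\kappa = 0.64\,\mathrm{s^{-1}}$,
$\gamma = 0.32\,\mathrm{s^{-1}}$, $\tau = 2$ s, $\alpha = 0.32$,
$E_0 = 0.4$, $V_0 = 4\%$): a two-region inversion is far better
conditioned with them fixed, and nothing in the analysis depends on their
subject-level values. A per-region observation gain can be estimated
instead (`settings$estimateGain`).

Since only one connection value per condition is ever reported, the
package reports **effective connectivity** $A + B_c$ per condition; the
split between $A$ and $B$ is a parameterization detail that the shrinkage
priors resolve, not an identified quantity (see *Identifiability*, below).

### Numerical integration

The coupled 10-state system is integrated by fixed-step classical RK4
(compiled code), default `dt = 0.1` s, and read out at the TR grid
(TR = 3.36 s) by linear interpolation. Stick inputs are represented as
fixed-width (0.1 s) unit-mass pulses averaged over each integration step,
so the injected mass is independent of `dt`; halving `dt` changes sampled
output by less than $10^{-3}$ of the signal range (a tested property).
Simulation refuses any effective matrix with a non-negative real
eigenvalue. The replicate-heavy test and acceptance harnesses use
`dt = 0.2` s for both generation and inversion; at that step the
discretization deviation (about 1.5% of signal range) is far below the
SNR-1 noise floor, and using the same step on both sides removes any
model-mismatch bias.

## The model space

All six candidate models share a fully connected $A$ and modulable
self-connections; they differ in which between-region connections the
condition may modulate (forward VPM-to-IFS, backward IFS-to-VPM, or both)
crossed with the input site (IFS or VPM). `buildModelSpace()` constructs
them deterministically; `validateModel()` enforces the shared structural
contracts.

## Inversion

`invertVL()` fits one model to one subject's two sessions *jointly*: one
$B$ per condition carries the stimulation difference while $A$ captures
coupling common to both sessions (a per-session separate mode clamps $B$
and fits each session alone). Session means are removed from data and
prediction, matching the percent-change baseline convention.

The optimizer is Gauss-Newton on the conditional mode with
Levenberg-style damping. Priors are weakly informative shrinkage priors:
$A$ off-diagonal $\mathcal N(0, 0.25)$, $A$ diagonal
$\mathcal N(-0.5, 0.0625)$ (kept negative by the stability gate rather
than a hard truncation), $B$ entries $\mathcal N(0, 0.25)$, $C$
$\mathcal N(0, 1)$. The observation noise is white and Gaussian with a
single precision $\lambda$ shared across regions and sessions, updated
each iteration by a Gamma-regularized EM point estimate; white noise
matches the synthetic generator and is a deliberate simplification
relative to autoregressive noise models used elsewhere. Jacobians are
central finite differences (step $10^{-4}$), exploiting the session-block
structure ($B$ parameters of one condition cannot affect the other
session).

The objective is the variational free energy
$F = \text{accuracy} - \mathrm{KL}(q \,\|\, \text{prior})$, the standard
lower bound on log model evidence. A candidate step is accepted only if
its fully recomputed $F$ (own Jacobian, refreshed $\lambda$ and
covariance) improves, so the recorded $F$ trace is monotone by
construction; convergence is declared when the accepted improvement falls
below `tol` (default 0.01 nats, our own choice — the original analyses do
not state theirs). A two-start option (`multistart`) guards against
slow-decay/fast-decay local optima of the self-connections; the default
single start is used by the replicate harnesses, where it proved
sufficient once the generator respected its planted means.

### Identifiability

With one $B$ per condition, only the sums $A + B_c$ (and $C$) are
data-identified; the $A$-vs-$B$ split is resolved by the priors. All
reporting, recovery scoring and BMA therefore work on the per-condition
effective values. Parameter-recovery tests score the correlation between
posterior-mean effective values (plus $C$) and ground truth, not the raw
$A$/$B$ decomposition, which would punish an arbitrary convention.

## BMS, BMA and the two-distribution test

Fixed-effects BMS sums free energies over subjects and softmaxes them
(max-subtracted for overflow safety). BMA is realized by sampling:
each of 10,000 samples draws a subject uniformly, a model from that
subject's posterior model probabilities, and a parameter vector from that
model's Gaussian posterior; a connection absent from the drawn model
contributes exactly zero. Per-subject average connection strengths (for
the correlation stage) come from subject-restricted sampling.

The two-distribution test compares the anodal and sham sample
distributions of one connection: samples are randomly paired across
conditions (independent index draws under a fixed seed, each drawn pair
used in both orders, which makes the test exactly antisymmetric), and the
exceedance proportion is the fraction of paired differences sharing the
majority sign. The null of equal condition strength is rejected at a 95%
exceedance. Reports print the proportion as the percentage pair
$100p$ / $100(1-p)$; we interpret the published percentage pairs this
way — the only reading consistent with a 95% threshold on two
distributions — and record that definition in the report metadata.

## The behavioural stage

Trials with an incorrect response or invalid voice-key activation are
excluded first; then, in a single pass, trials more than two sample
standard deviations from their subject-by-condition mean. By-subject and
by-item condition means feed one-tailed paired t-tests, facilitation is
$100(\text{sham} - \text{anodal})/\text{sham}$, and the brain-behaviour
stage is a two-tailed Pearson correlation between per-subject effective
connectivity change (anodal $-$ sham BMA means) and facilitation, with a
leave-one-out refit that removes the subject with the lowest connectivity
change. Degrees of freedom are reported both as $n-2$ (the Pearson
convention, used for the p-value) and as the printed convention $n$,
because published reports in this literature sometimes print the latter.
If the paired differences are all exactly zero the t-test reports
$t = 0$, $p = 0.5$ rather than failing on zero variance.

## The synthetic cohort generator

`cohortSpec()` defines the population; its defaults *are* the study
conditions:

* design: 107 naming events per session in blocks of 6 with 7 s rests,
  ITI 3.92 s, 1 s fixation lead, 2.5 s pictures, TR 3.36 s, 344 volumes,
  two sessions (anodal, sham);
* population mean effective connectivity per condition: the reported
  values (sham: IFS self $-0.60$, VPM self $-0.26$, forward $0.96$,
  backward $-0.26$; anodal: $-0.57$, $-0.09$, $0.87$, $-0.67$ Hz), so the
  planted effects are a more negative backward connection and a less
  negative VPM self-connection under anodal stimulation;
* input to VPM (the winning architecture) with gain
  $\mathcal N(0.5, 0.1)$ truncated above 0.1 — the publication reports no
  input gain, so this is our choice of a value producing realistic 1-3%
  BOLD responses;
* between-subject variability: additive Gaussian SD 0.15 Hz on
  between-region couplings and on their condition differences
  (within-subject correlated, as in real crossover data). Self-connections
  are decay-rate constants, so they vary *multiplicatively*
  (mean-corrected log-normal, log-SD 0.35 between subjects and 0.15 per
  condition): an additive Gaussian on the anodal VPM self-connection
  ($-0.09 \pm 0.15$) would collide with the stability boundary and any
  truncation would silently shrink the planted condition effect;
* noise: white Gaussian at SNR 1 (noise SD = each subject's own
  noise-free signal SD);
* behaviour: sham mean RT 839.5 ms (between-subject SD 94.2), mean
  facilitation 3.35% with SD 10% (chosen so the by-subject paired t is
  near the reported non-significant value), within-subject trial SD
  120 ms, shared item effects SD 60 ms, accuracy 97%, voice-key validity
  99% — together yielding a single-digit trial-exclusion percentage of the
  same order as real naming studies report; and
* a plantable correlation $\rho$ (default 0.7) between the
  forward-connection (VPM-to-IFS) change and facilitation, constructed by
  the standard linear-correlation decomposition.

All randomness flows from one master seed; regeneration is bit-identical.

### What the generator does *not* emulate

No image-level confounds (motion, physiological noise, drift), no
autocorrelated noise, no session-order effects (the counterbalancing is
metadata only), no auditory-cue structure, and haemodynamics are identical
across subjects and regions. Passing recovery tests therefore demonstrate
that the estimator is correct and well calibrated *under its own
assumptions* at the study's size and SNR — not that real fMRI data meet
those assumptions.

## Problem sizes used by the test and acceptance harnesses

These are the package's own choices of replicate design:

* parameter recovery: one default cohort (10 subjects, full 344-volume
  sessions, SNR 1), generating model inverted per subject, correlation
  over the 90 identified quantities;
* BMS model recovery: 10 replicate 2-subject cohorts generated from the
  `backward-inVPM` architecture. The default cohort's forward modulation
  ($0.87$ vs $0.96$, a difference that is itself not significant) is too
  small to distinguish the bidirectional model from its nested
  backward-only neighbour — the sparser model then *correctly* wins by
  Occam's razor — so architecture recovery is scored on a generating
  architecture whose distinguishing effects are actually present
  (forward coupling set condition-independent at its average, and no
  subject-level forward condition noise, via `condNoiseMask`);
* condition-effect sign recovery: 50 replicate 4-subject cohorts, full
  session length, two-model space, 2,000 BMA samples;
* null calibration: 200 trials-only cohorts with $\rho = 0$; the
  correlation stage consumes the generator's planted connectivity deltas,
  since estimation noise could only attenuate an already-null correlation.
* inversions in these harnesses use `maxIter = 12` and `dt = 0.2` s.

## Known limitations

* Self-connection deltas are weakly identified at SNR 1: their
  posterior is nearly flat over a few tenths of a Hz per subject, so
  group-level direction calls need several subjects.
* The A-vs-B split is prior-determined; only per-condition sums should be
  interpreted.
* White-noise likelihood; real fMRI noise is autocorrelated.
* The two-region network ignores polysynaptic routes through regions
  outside the model, as deterministic DCM always does.
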