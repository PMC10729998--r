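---
title: "A motoneuron-driven motor-unit pool model of isometric muscle force"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A motoneuron-driven motor-unit pool model of isometric muscle force}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(mupool)
```

## The model in one paragraph

`mupool` predicts the isometric force of a skeletal muscle from the
discharge activity of its motoneurons. The muscle is a population of
motor units (MUs) acting in parallel: each MU receives a binary spike
train, transforms it through a cascade of excitation–contraction
coupling stages into an *active state* $a(t) \in [0,1]$, scales that
state by its own maximum force and by a force–length factor, and the
whole-muscle force is the sum

$$F^M(t) = F_0^M \sum_k \bar{f}^{MU}_{0,k}\, a_k(t)\, f_{FL}(\bar l, a_k(t)),$$

optionally low-pass filtered per MU by the *twitch dispersion* of its
fibres. The parameterisation ships for the human tibialis anterior (TA):
a pool of $N = 400$ MUs innervating 200,000 fibres, working at the fixed
normalized length $\bar l = 1.16$ of the dorsiflexed ankle, with
$F_0^M = 1046$ N.

## The generic MU pool

Four continuous distributions describe the pool across the MU index $j$
ranked by recruitment threshold, each of the linear–exponential form
$s\,(c_1 j/N + b^{(j/N)^e})$:

* recruitment thresholds $T^{th}(j)$ (%MVC), spanning 0.53–89.1 %MVC —
  most of the pool is recruited at low force (about 58% below 20 %MVC);
* normalized twitch forces, spanning a 16.3-fold range;
* normalized maximum (tetanic) forces $\bar f^{MU}_0(j)$, spanning an
  11-fold range and summing to 1 over the pool, so they tile the
  muscle's maximum force;
* innervation ratios, the twitch distribution rescaled so fibre counts
  sum to the muscle total.

The exponential term is a *base* raised to the power $(j/N)^e$. This
parse is forced by the printed checkpoints of the distributions (fold
ranges, recruitment counts, the unit sum): reading it as a product
$b \cdot (j/N)^e$ fails all of them. MUs are labelled slow-type up to
the smallest index whose cumulative innervation ratio reaches 72% of the
fibres (index 359 for the TA defaults) and fast-type above.

```{r pool}
pool <- mu_pool(mu_pool_spec(), F0M = 1046)
autoplot(pool)
```

Experimentally identified MUs are located in this pool by inverting
$T^{th}(\cdot)$ at their measured thresholds (bisection on the
continuous index, tolerance `1e-6`, rounding half up). A sample of
$N_r$ identified MUs stands in for all $N_a$ recruited MUs by giving
each identified MU the summed maximum force of a window of neighbours:
interior window bounds follow the floor-midpoint rule
$[\lfloor (N_{i-1}+N_i)/2 \rfloor + 1,\ \lfloor (N_i+N_{i+1})/2 \rfloor]$.
The first window is anchored at MU 1 and the last at $N_a$ so the
windows *partition* the recruited range and the representative forces
conserve the total recruited force exactly — the natural completion of
the floor-midpoint rule, whose boundary behaviour is otherwise
undefined, and one that reproduces both published worked examples.

## Excitation and activation dynamics

Each MU's spike train drives five cascaded states:

1. **Motoneuron action potentials** $e(t)$: a half-sine wave of
   amplitude $V_e = 90$ mV and duration $T/2 = 0.7$ ms at each
   discharge. Overlapping waves (discharges closer than $T/2$) are
   summed, with a warning — the physiological regime never reaches such
   rates.
2. **Fibre action potential** $u(t)$:
   $\ddot u = a_1 e - a_2 u - a_3 \dot u$, an overdamped second-order
   response (characteristic rates 2929 and 17071 s$^{-1}$) with
   time-to-peak 0.6 ms.
3. **Free calcium** $c(t)$:
   $\ddot c = b_1 u - \frac{1}{f_1(\bar l)}(b_2 f_2(\bar l)\, c + b_3 \dot c)$,
   with piecewise-linear length scalings $f_1, f_2$ of the twitch
   amplitude and decay.
4. **Calcium–troponin binding** $P(t)$:
   $\dot P = c_1 f_3 (P_0 f_4 - P)\, c^2 - c_2 f_5 P$ — second order in
   calcium (the forward rate has units M$^{-2}$s$^{-1}$), saturating at
   the total troponin concentration. The hooks $f_3$–$f_5$ default to 1
   (exact at optimal length) and are injectable.
5. **Active state** $a(t)$:
   $\dot a = (d_1 P - a)/(d_2 + d_3 P)$, clamped to $[0, 1]$.

Two genuinely open parses were decided as follows. The active-state
equation is read as the *ratio* form above because it relaxes with time
constant $d_2 = 24$ ms at low calcium–troponin levels — physiological
for human TA twitches — whereas the alternative product form
$d_1 P - a(d_2 + d_3 P)$ would relax over ~40 s, incompatible with any
single-twitch trace. The clamp at 1 is required because the unclamped
equilibrium $d_1 P$ exceeds 1 under fused stimulation; clamped samples
are counted and reported as an attribute.

### The drive-unit convention

The published coefficient set is not dimensionally closed across the
chain: feeding the calcium equation with $u$ in volts leaves the whole
cascade about three orders of magnitude below any useful regime (the
active state would peak near $3\times10^{-4}$). Some implicit unit
rescaling must be restored, and the package treats its magnitude as the
one genuinely free constant of the chain. We express the fibre
depolarisation in units of 10 mV (`u_to_drive = 100`): this is the
single scale at which the simulated chain reproduces the model's
documented calibration — slow and fast twitch-to-tetanus ratios of
about 0.30 and 0.19 (we compute 0.332 and 0.173) with tetanic
saturation at exactly 1.0 at 50 Hz for the slow MU. A millivolt
convention would instead reproduce the documented tens-of-micromolar
calcium transients but saturates *both* ratios at 1.0, contradicting
the documented twitch calibration; no scale satisfies both facts
simultaneously. We prefer the active-state calibration because the
active state, not the calcium amplitude, determines force. With the
adopted convention calcium transients sit in the low-micromolar range;
their *timing* (which the scale cannot affect — the stage is linear) is
reproduced: ~2.0 ms time-to-peak for an isolated fast twitch.

```{r twitch, eval = FALSE}
# single slow twitch and a fused 50 Hz train (a few seconds of RK4)
tw <- simulate_ne(0.01, "slow", duration = 1)
tet <- simulate_ne(seq(0.01, 3, by = 1/50), "slow", duration = 3)
autoplot(tw)
```

### What does not reproduce

Three documented chain properties are not reproducible by forward
evaluation of the published coefficients, under any convention we
found; the acceptance tests assert them anyway and fail honestly,
printing the computed values:

* the fibre-AP peak-to-peak of 77 mV — the coefficients yield 100.4 mV
  (confirmed by an analytic convolution oracle and an independent
  adaptive solver; the chain is linear in $V_e$, so no parse rescues
  it, and the documented time-to-peak of 0.6 ms *does* reproduce);
* the fast calcium twitch decay constant of 6.6 ms — the printed
  $b_2, b_3, f_1$ values fix the slow characteristic mode at 5.2 ms;
* the 0-to-0.8 activation rise-rate pair (3.5/s at 15 Hz, 5.8/s at
  50 Hz) — under the adopted calibration the 15 Hz steady state is
  ~0.51, so the active state never crosses 0.8 at that rate.

## Contraction dynamics and force assembly

In isometric conditions the contraction dynamics reduce to a Gaussian
force–length factor
$f_{FL} = \exp(-((\bar l - \bar l_0(a))/0.45)^2)$ whose apparent
optimum $\bar l_0(a) = 0.15(1-a) + 1$ sits up to 15% longer at rest.
Force–velocity properties are deliberately absent (fixed length).
Note the direction of the activation effect: the shift is *leftward*
with increasing activation, so activation raises relative force near
the true optimum but lowers it well beyond the resting optimum.

Because a MU's fibres receive the motoneuron command with small random
delays, the MU force is a dispersion-filtered version of its idealized
force. The window $\Delta t$ of these delays is not documented; we
default to 4 ms (a small fraction of a twitch, clearly below any
physiological conduction-delay spread that would alter force) and
implement the many-fibre limit as a centred boxcar convolution, which
is deterministic and preserves the force–time integral to machine
precision. A seeded Monte-Carlo mode with one explicit delay per fibre
(`ir` delays) is available and converges to the boxcar.

For spike trains obtained by reconstruction rather than measurement, a
MU recruited *during* the constant-force plateau but discharging below
7 Hz on average over it carries mostly noise; `plateau_rate_rule()`
zeroes such MUs' forces. MUs recruited on the ramps are never touched.

## Neural drive and validation metrics

The effective neural drive is the low-frequency content of the
cumulative spike train: per-sample binary sum, low-pass filtered at
4 Hz with a 2nd-order Butterworth applied forward–backward (zero phase,
so onsets are not delayed by filtering), then normalized to the plateau
mean — mirroring the normalization of the reference force, which is
deliberately not max-normalized to resist decomposition artefacts.

`trace_metrics()` computes the full validation set: onset error
$\Delta_1$ (first crossing of 2% of each trace's own maximum),
the reference force $\Delta_1^F$ developed at the predicted onset, the
maximum error, $r^2$, and the normalized RMS error over the whole trace
and over the ascending ramp / plateau / descending ramp. The nRMSE
normalizer is not documented in the source material; the default is the
reference range over the analysed interval, with plateau-mean and max
alternatives selectable. Segment boundaries can be auto-detected from a
trapezoidal reference: the plateau is the longest run within ±5% of the
plateau level, ramps run from/to the 2% onset crossings.

## The synthetic task generator

Real inputs to this model are decomposition results from high-density
surface EMG. To make the pipeline testable without recordings,
`generate_spikes()` emulates a trapezoidal isometric task: the common
input ramps at 5 %MVC/s to a plateau and back; MU $j$ discharges while
the input exceeds its pool threshold $T^{th}(j)$; its instantaneous
rate is `min_rate` at recruitment, grows with the excess drive
(`gain`, default 3 Hz per %MVC), and saturates at a peak rate that
*decreases* with threshold (onion-skin organisation: default 35 Hz
minus 0.3 Hz per %MVC of threshold, floored at `min_rate`). Discharge
times come from integrating the rate to a unit threshold with lognormal
jitter (ISI coefficient of variation 0.15, in the range reported for
voluntary contractions). All randomness flows through one explicit
seed; a fixed seed is bit-reproducible.

The generator emulates recruitment order, rate coding and trapezoid
structure. It does **not** emulate decomposition errors (missed or
merged discharges), common oscillatory drive, rate adaptation,
derecruitment hysteresis, or motoneuron intrinsic dynamics — so a
passing end-to-end test shows the *pipeline* is coherent (simulated
force tracks the smoothed drive of its own input, $r^2 \ge 0.9$ at a
30 %MVC analogue), not that the model fits any particular subject.

## Numerical choices

* All five ODE stages are integrated together by fixed-step RK4 at
  `dt_solver = 5e-6` s (the fastest mode, 17071 s$^{-1}$, needs steps
  well below the 2048 Hz spike grid; steps above `0.1/max_root` are
  refused with guidance rather than silently under-resolved), with the
  motoneuron potential evaluated analytically inside the step. Output
  is sampled at the spike-train rate.
* Stage-by-stage entry points (`fibre_ap_ode()`, `calcium_ode()`, ...)
  integrate the same equations with linear interpolation of their
  sampled inputs — convenient for testing single stages, at the cost of
  interpolation error if the input is coarsely sampled.
* Pool-index rounding: half up. Innervation ratios are kept real-valued
  internally; integer export uses largest-remainder rounding so the
  fibre total is preserved exactly.
* Duplicate pool indices after threshold mapping are kept, with a
  warning (the degenerate case of two identified MUs mapping to one
  index).
* Steady states are measured as the mean over the final second of a 3 s
  train; a plateau slope above $10^{-3}$/s triggers a non-convergence
  warning that reports the slope.

## Problem sizes

The shipped tests run the chain at `dt = 5e-6` s throughout; the
end-to-end self-test uses 50 MUs sampled across the recruited pool, a
40 s task at 2048 Hz and the full per-MU force pipeline. The whole
suite completes in a few minutes on one core.

## Known limitations

* Rigid tendon only: normalized length is $(l^{MT} - l_s^T)/l_0^M$ and
  constant; muscles with compliant tendons need an elastic-equilibrium
  extension that is out of scope here.
* All MUs share the muscle's optimal length and working length.
* The length hooks $f_3$–$f_5$ of the calcium–troponin stage default to
  1; away from optimal length their true forms (not publicly
  documented) would modulate the CaTn transients.
* Force summation is linear; no mechanical interaction between MUs.
* The co-contraction correction $\Delta T(T)$ for estimating an
  experimental muscle force from joint torque is subject-specific and
  must be supplied; the default applies none and warns.
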