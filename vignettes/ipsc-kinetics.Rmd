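---
title: "Kinetic modelling of gephyrin-dependent IPSCs: methods and design"
author: "ipscfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of gephyrin-dependent IPSCs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipscfit)
```

## The model and its assumptions

GABA-A receptor mediated synaptic currents are recorded under whole-cell
voltage clamp as inward deflections (high-chloride internal solutions put
the chloride reversal potential near 0 mV; holding at −60 or −70 mV makes
the driving force negative). `ipscfit` models each spontaneous event with
a small kinetic scheme of the transsynaptic signalling pathway organised
around gephyrin:

* a double-exponential conductance transient
  $g(t) = w\,(e^{-t/\tau_d} - e^{-t/\tau_r})$ stands in for all
  presynaptic release machinery; $w$ scales the amount of
  neurotransmitter released;
* neurotransmitter $N$ is generated at rate $\beta\,\alpha_f\,g(t)$,
  modulated by the neuroligin-2/neurexin cluster level $NLG2$, and cleared
  at rate $\alpha_b$;
* $NLG2$ follows a Michaelis–Menten scheme saturating in the gephyrin
  level $GEPH$ and turning over at rate $\varphi$
  (steady state $GEPH\,(2-\varphi)/(2\varphi)$, positive only for
  $0 < \varphi < 2$ — the constructor enforces this);
* postsynaptic receptors $R_y$ are scaffolded at rate $h\,GEPH$ and
  removed at rate $h_1$ (steady state $h\,GEPH/h_1$);
* the current is $I = c_1\,N\,R_y\,(v - e_{rev})$.

Assumptions inherited from this design: a single compartment under
perfect voltage and space clamp (membrane passive properties do not
affect the modelled current, so they are not modelled); isolated events
on an equilibrated synapse ($N(0)=0$, $NLG2$ and $R_y$ at steady state),
which excludes short-term plasticity by construction; linear
superposition when events are summed into trains (no receptor
saturation).

Units: time in ms, voltage in mV, current in pA. $w$ and $c_1$ are
effective scale factors; $c_1$ is fixed to 1 and all scale is absorbed by
$w$, so exactly ten parameters are fittable. $e_{rev} = 0$ mV throughout.

## The closed-form solution and its calibration

With $NLG2$ and $R_y$ at steady state, the neurotransmitter equation is
linear with a double-exponential drive and solves exactly. Writing
$D_1 = 1-\alpha_b\tau_d$, $D_2 = 1-\alpha_b\tau_r$:

$$
I(t) = I_{FACT}\,
\frac{(\tau_d-\tau_r)\,e^{-\alpha_b t}
      - \tau_d D_2\, e^{-t/\tau_d}
      + \tau_r D_1\, e^{-t/\tau_r}}{D_1 D_2}\,(v - e_{rev}),
\qquad
I_{FACT} = c_1 \frac{h}{h_1}
\frac{(2-\varphi)\,GEPH^2}{2\varphi}\,\beta\,\alpha_f\,w .
$$

The three exponentials cancel at $t=0$. We derived this bracket directly
from the ODE (the $\tau_d$, $\tau_r$ factors on the two fast exponentials
are required for the cancellation); validated against the numerical
integrator it agrees to the integration tolerance with **no extra scale
factor** — the calibration constant between the closed form and the ODE
solution is exactly 1, and `analytic_current()` therefore serves as the
fast path everywhere. When $\alpha_b$ is within tolerance of $1/\tau_d$
or $1/\tau_r$ the denominator is singular and the function falls back to
`simulate_ode()`.

```{r closed-form}
p <- reference_params("benchmark")
tg <- seq(0, 300, by = 0.1)
max(abs(simulate_ode(p, tg)$current - analytic_current(p, tg))) /
  max(abs(analytic_current(p, tg)))
```

### Rate-relabelling degeneracy

$I(t)$ is a sum of three exponentials with rates
$\{\alpha_b, 1/\tau_d, 1/\tau_r\}$ and coefficients fixed by the rates.
Writing $a=\alpha_b$, $b=1/\tau_d$, $r=1/\tau_r$, the bracket is
proportional to
$(r-b)e^{-at} - (r-a)e^{-bt} + (b-a)e^{-rt}$ over $(b-a)(r-a)$, and under
the exchange $a \leftrightarrow b$ it maps to itself times the constant
$(r-a)/(r(r-b))$ — a constant the fitted $w$ absorbs. The same holds for
any permutation of the three rates. Consequently **the three rates are
identifiable only as an unordered set**, and the individual symbols
$\tau_d$, $\tau_r$, $\alpha_b$ are labels. `fit_event()` canonicalizes
the returned labelling to the permutation log-closest to the centre of
the search bounds, accepting a relabelling only when its recomputed RMSE
confirms exact equivalence. Beyond the rates, $I_{FACT}$ collapses seven
parameters into one scale: parameter-recovery claims in the tests are
restricted to $\tau_d$, $\tau_r$, $\alpha_b$ (canonical labelling) and
$I_{FACT}$, and the test suite demonstrates that multiple accepted
parameter vectors more than a decade apart coexist for a single event.

### Units of $\alpha_b$

All rate constants are treated as 1/ms. The literature-calibrated control
references carry $\alpha_b \sim 10^{-5}$/ms; at that value clearance is
negligible within a 300 ms window and the current is effectively the
integral of $g$, so $\alpha_b$ barely shapes the trace. The package
therefore also ships a `benchmark` reference with $\alpha_b = 0.5$/ms
(quasi-static clearance: time-to-peak ≈ 7 ms, decay to 10% of peak within
≈ 80 ms, an IPSC-like shape) whose rates are well separated
(0.8, 2, 30 ms) and hence identifiable. Detection and parameter-recovery
benchmarks use this reference; distribution-level emulation of the three
experiments uses the literature references. The benchmark $w$ (0.18) is
chosen so the mean event peak lands near 50 pA, the experimental mIPSC
amplitude scale.

## The synthetic-data generator

The generator emulates: 10 kHz sampling low-pass filtered at 2 kHz
(4th-order zero-phase Butterworth — the published cutoff without claiming
the hardware filter type); additive white Gaussian noise added **before**
filtering, default SD 2 pA so synthetic SNR (peak / baseline SD ≈ 10–25)
brackets typical miniature-IPSC recordings; spontaneous events as a
homogeneous Poisson process at the per-condition frequencies (1.5, 1.8,
1.1, 1.4, 0.6, 0.91, 0.42 Hz for the built-in condition references); peak
amplitudes drawn from the published 4-parameter pseudo-Voigt profiles by
exact mixture sampling (Cauchy and Gaussian branches with weights
$c\pi b$ and $(1-c)\sqrt{2\pi}\,b$) with non-positive draws rejected;
per-event ground-truth parameters from truncated normals around a
reference mean/SD table (validity enforced by resampling:
$\varphi \in (0,2)$, $\tau_r < \tau_d$); blocked conditions built by
scaling GEPH (quadratic effect on amplitudes) and optional multiplicative
perturbations of other reference means; and per-cell / per-day labels so
the day-screening stage is exercisable. A JSON manifest plus the recorded
seed regenerates every trace bit-for-bit.

It does **not** emulate: series-resistance and dendritic-filtering
artifacts, tonic currents, receptor saturation between events, or any
nonstationarity within a recording. Tests passing on synthetic data
therefore validate the computational pipeline — detection geometry,
optimizer behaviour, statistical calibration — not the biological
fidelity of real recordings.

## Event detection

`sliding_template_detect()` slides an event-shaped kernel one sample at a
time; at each offset the scale and baseline offset minimizing the SSE are
computed in closed form, and the detection criterion is the scale divided
by the standard error of the fit (threshold 4 by default; the criterion
is a design decision, the published analysis having delegated it to an
acquisition program). Three design points worth recording:

* **Template length.** The default template is a negative double
  exponential ($\tau_r$ 1 ms, $\tau_d$ 30 ms) of length $2\tau_d$
  (60 ms). With a longer window (e.g. $5\tau_d$) a neighbouring event
  60–150 ms away sits inside the matching window, inflates the fit SSE
  and pushes the criterion below threshold: in that configuration a
  60 pA event 62 ms before its neighbour measured criterion 3.8 and was
  lost. The 60 ms template restores recall ≥ 0.99 for events ≥ 50 ms
  apart at precision 1.0.
* **Arming.** Criterion maxima are scanned in time order; a maximum is
  accepted only beyond the refractory gap (20 ms) of the last *accepted*
  detection, and rejected maxima do not reset the clock — otherwise
  decay-tail re-triggers mask following true events.
* **Vetoes.** A detection must show a template-like fast rise
  (20–80% rise time ≤ 10 ms, measured at the refined onset), an extremum
  within 50 ms of onset, and a peak above 4× a robust noise estimate
  (median template-fit SE). These kill threshold grazes on noise and
  decay-tail bumps; on 300 s of pure noise the false-positive count is 0.

Onsets are refined by extrapolating the 20–80% rise line back to
baseline (the criterion maximum lags the true onset by a shape-dependent
~2 ms); on the benchmark shape the refined onset is within 0.25 ms of
ground truth. The fit window runs from 2 ms before onset to the first
sample after the current decays to 10% of peak, capped at 300 ms and
truncated at the next event's onset.

Event selection before fitting: overlap exclusion removes both members of
any pair of onsets closer than 20 ms (the neighbour structure can be
pinned to the raw event list so the overlap predicate commutes with
row-wise screens), and the amplitude-consistency screen keeps events
within $k = 2$ reference SDs of the reference mean (≈ 95% normal
coverage; $k$ is exposed).

## Fitting

Per event, the RMSE between the closed-form model and the
baseline-subtracted data is minimized over the ten parameters in log10
space (positivity for free, and the published initialization spans 5
orders of magnitude — ±2.5 decades around the reference means, which also
serve as bounds). The local minimizer is Nelder–Mead under a
clip/swap-repair of the constraints ($\varphi < 2$; $\tau_r < \tau_d$ by
swap-and-nudge), multi-started from log-uniform draws (default 100
starts, capped at 3000 iterations each; the tests use 6–20 starts). The
overall scale $w$ is profiled out by linear least squares at every cost
evaluation — the model current is exactly linear in $w$, so the search
effectively explores shape space (separable least squares). Ties among
equal-RMSE starts resolve to the lowest start index. A fit is accepted
when RMSE < 10% of the event peak, strictly.

Fixed parameters are never moved; the frequency-proportional GEPH rule
(`geph_from_frequency()`) fixes the blocked condition's GEPH to the
control mean times the ratio of spontaneous-event frequencies, frequency
being taken as proportional to the number of gephyrin molecules. In the
pipeline this runs as two passes: control events are fitted
unconstrained, then blocked events are fitted with GEPH fixed.

Because of the degeneracy, the *absolute* values of the scaffold-pathway
parameters ($h$, $h_1$, $GEPH$, $\beta$, $\alpha_f$, $\varphi$, $w$) in a
fit table are not individually interpretable; comparisons across
conditions remain meaningful because both groups are fitted in the same
bounds with the same procedure, and the GEPH constraint anchors the
blocked condition's scale relative to control.

## Statistics

* **Pseudo-Voigt amplitude profiles.** Histograms use 30 equal-width bins
  over $[0, q_{0.99}]$ — a robust upper edge, since sampled Lorentzian
  tails produce extreme outliers that would collapse an equal-width
  histogram over $[0, \max]$ (real recordings are bounded, so this
  matches the published binning in practice). The least-squares fit runs
  from a small grid of $(b, c)$ starts because the $(b, c)$ surface has a
  boundary local optimum at $c = 1$ that a single narrow start can fall
  into; the correlation $r$ between fitted and observed bin heights is
  reported.
* **Day-wise control screening.** For each parameter the day centres
  under control conditions are compared pairwise and the maximum absolute
  relative difference (%) is kept; a condition effect smaller than this
  physiological fluctuation is never attributed to the intervention.
  Centres are medians; with `center = "mean-if-normal"` the mean is used
  for a pair when Shapiro–Wilk accepts normality in both days at
  $\alpha = 0.05$ (the normality test is a design choice).
* **Condition comparison.** Kruskal–Wallis omnibus plus Dunn's pairwise
  z-comparisons on the pooled ranks with tie correction, implemented
  in-package (no installed package provides the procedure); p-values are
  reported raw by default (significance read at $p < 0.05$, as in the
  source figures), with any `p.adjust` method exposed. Relative changes
  are $100\,(\mathrm{med}_{blocked} -
  \mathrm{med}_{control})/\mathrm{med}_{control}$ on raw parameters
  (not log-parameters).
* **Effect labels.** Four-way rule: not significant → `no-difference`;
  significant but within the control day-to-day range →
  `within-control-range`; otherwise `significant-increase` /
  `significant-decrease` by the sign of the median difference.

Calibration: under the null the comparison's type-I error is 0.046
(500 replicates, n = 200/group, fixed seed), and an unperturbed
two-condition pipeline labels all ten parameters `no-difference` or
`within-control-range` in 20/20 seeded replicates (n = 100/group, 5
control days — sizes chosen as a desk-scale standard for the null check).

## Classification

`cross_validated_classify()` reproduces the held-out classification of
events into conditions from their ten fitted parameters: stratified
10-fold CV (each model trains on 90% of the data; after the 10 folds
every sample has been left out exactly once), features log10-transformed
(fitted values span decades) and standardized with training-fold
statistics only — the test suite verifies fold predictions against an
independent re-computation to rule out leakage. Presets: "medium KNN"
as k = 10 nearest neighbours on standardized Euclidean distance, and
"quadratic SVM" as a degree-2 polynomial kernel with `coef0 = 1`
(the inhomogeneous quadratic kernel; the homogeneous one loses the
linear term and fails even on separable clusters). On GEPH-scaled
synthetic conditions with one perturbed release parameter, accuracy lands
well above chance and below ceiling, consistent with the published
50–78% regime; exact accuracies depend on the recordings and are not
asserted.

## Numerical choices

* ODE integration: `deSolve::lsoda`, rtol 1e-8, atol 1e-10; NLG2 floored
  at 1e-12 inside the derivative (its equation is singular at 0);
  $\tau_r = \tau_d$ is rejected at construction (the double-exponential
  difference degenerates) rather than replaced by the alpha-function
  limit.
* Closed-form singular denominators ($\alpha_b \to 1/\tau_d$ or
  $1/\tau_r$) are detected at relative tolerance 1e-8 and routed to the
  integrator.
* Cross-correlation for detection runs on a power-of-two padded FFT
  (arbitrary-length FFTs can hit slow prime factorizations on
  minute-long traces).
* Optimizer: `optim` Nelder–Mead, reltol 1e-10; out-of-bound proposals
  are clipped (projection), the $\tau$ ordering repaired by
  swap-and-nudge in log space.
* Problem sizes in the shipped tests: 50 random parameter sets for the
  closed-form/ODE check, 10 noiseless events × 20 starts for recovery,
  120 s trains for detection benchmarks, 500 replicates for type-I
  calibration, 50 000 draws for distribution round trips, 20 replicates
  for the end-to-end null — sizes chosen to make each property
  measurable with comfortable margins on a laptop-scale machine.

## Known limitations

* The kinetic scheme is deliberately minimal: no multicompartment
  morphology, no receptor desensitization or saturation, no short-term
  plasticity, no tonic current. It is a lens for attributing changes to
  pre- vs post-synaptic pathways, not a biophysically complete synapse.
* Absolute fitted values of the non-identifiable parameters depend on
  the search bounds; only the canonical rate set and $I_{FACT}$ transfer
  across studies.
* The detection vetoes assume template-like events (fast rise, extremum
  near onset); pathologically slow-rising events would need a matched
  template and relaxed vetoes.
* Reproducing the published per-condition parameter tables requires the
  original recordings; the package reproduces their *computation* on
  synthetic data and the published in-text arithmetic
  (frequency-proportional GEPH fixings, selection percentages).
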