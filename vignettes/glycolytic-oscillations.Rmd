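---
title: "Modelling and measuring yeast glycolytic oscillations with glycosc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring yeast glycolytic oscillations with glycosc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycosc)
```

## The phenomenon and the model

When glucose-starved *Saccharomyces cerevisiae* cells are fed glucose in
the presence of cyanide, the concentrations of glycolytic intermediates —
most visibly NADH, whose autofluorescence can be followed non-invasively —
oscillate with a period of tens of seconds for about twenty minutes.
`glycosc` provides the computational side of studying this phenomenon:
a kinetic model of anaerobic glycolysis, feature extraction on its limit
cycle, parameter sensitivity analysis, in-silico enzyme-titration
experiments, and Fourier analysis of fluorescence traces, together with a
synthetic trace generator that stands in for the fluorimeter.

The model is the nine-state Wolf formulation of anaerobic glycolysis.
Its state variables (mM) are glucose $S_1$, fructose-1,6-bisphosphate
$S_2$, the triose-phosphate pool $S_3$, the 3-phosphoglycerate pool
$S_4$, pyruvate $S_5$, intracellular and extracellular acetaldehyde
$S_6$, $S_{6x}$, NADH $N_2$ and ATP $A_3$. NAD$^+$ and ADP are not
integrated: the nicotinamide and adenine pools are conserved moieties,
$N_1 = N_{tot} - N_2$ and $A_2 = A_{tot} - A_3$. The reactions:

* **HK-PFK** (lumped hexokinase + phosphofructokinase), with allosteric
  ATP inhibition:
  $v_1 = k_1 S_1 A_3 / \bigl(1 + (A_3/K_i)^q\bigr)$.
  The negative feedback of ATP on this step is what destabilises the
  steady state and produces the limit cycle.
* **ALD** $v_2 = k_2 S_2$, producing two triose phosphates
  ($dS_3$ gains $2 v_2$).
* **GAPDH-PGK**, lumped and reversible. 1,3-bisphosphoglycerate is a
  fast intermediate eliminated by a quasi-steady-state assumption,
  giving
  $v_3 = \dfrac{k_{g1} k_{p1} S_3 N_1 A_2 - k_{g2} k_{p2} S_4 N_2 A_3}
               {k_{g2} N_2 + k_{p1} A_2}$.
  $v_3$ may be negative; no flux clipping is applied.
* **PK** (lumped PGM + ENO + pyruvate kinase) $v_4 = k_4 S_4 A_2$;
  **PDC** $v_5 = k_5 S_5$; **ADH** $v_6 = k_6 S_6 N_2$;
  **ATPase** $v_7 = k_7 A_3$; the glycerol branch $v_8 = k_8 S_3 N_2$;
  degradation of extracellular acetaldehyde (the cyanide sink)
  $v_9 = k_9 S_{6x}$; and membrane exchange
  $J_{ex} = \kappa (S_6 - S_{6x})$, entering the extracellular balance
  scaled by the volume ratio $\varphi$.

Glucose enters at a constant influx $J_0$. Model time is in minutes —
every rate constant is per minute — and all reported periods are
converted to seconds.

### Parameters

`wolf_params()` carries the published rate constants of the model as
defaults ($k_1 = 550$, $K_i = 1$ mM, $k_2 = 9.8$, $k_{g1} = 323.8$,
$k_{g2} = 57823.1$, $k_{p1} = 76411.1$, $k_{p2} = 23.7$, $k_4 = 80$,
$k_5 = 9.7$, $k_6 = 2000$, $k_7 = 28$, $k_8 = 85.7$, $k_9 = 80$,
$\kappa = 375$, in mM and minutes) plus the reference conditions
$J_0 = 50$ mM/min, $N_{tot} = 1$ mM, $A_{tot} = 4$ mM. Two structural
constants are not part of that printed set: the inhibition
cooperativity $q = 4$ and the volume ratio $\varphi = 0.1$ come from
the original model formulation. We validated this pairing by a scan:
over $q \in \{2, 3, 4, 6, 8\}$ and $\varphi \in [0.05, 1]$, only
$q = 4, \varphi = 0.1$ reproduces the reference NADH amplitude of the
GAPDH experiment suite (for $q < 4$ the limit cycle does not exist at
all). Both are ordinary config fields, never hard-coded. One unit note:
the PDC constant is listed in some sources with second-order units
although the reaction is modelled first order ($v_5 = k_5 S_5$); we
treat it as a first-order constant of 9.7 min$^{-1}$, which matches the
reaction scheme.

Config files use the reaction-indexed symbols of the published model
(`r1k1`, `r1ki1`, ..., `r11v`, `jKappa`) via `read_wolf_params()` /
`write_wolf_params()`, in JSON or YAML.

### Numerics

Integration uses `deSolve::lsoda` (stiff-capable) with relative
tolerance `1e-8`, absolute tolerance `1e-10`, and a default output grid
of 0.001 min — fine enough that parabolic interpolation of peaks
resolves sub-second period differences. Trajectories are checked
against non-negativity and the pool bounds to within a 1e-6 mM solver
round-off allowance. Initial concentrations are not part of the model
specification; `default_initial_state()` is an arbitrary fixed positive
state, and all reported features are computed after transient discard,
which makes them initial-condition independent (verified in the tests:
a 10% perturbation of every initial concentration changes the
limit-cycle period by under 0.1%).

## Limit-cycle features

`oscillation_features()` discards the first 10 model minutes (extending
the discard stepwise, up to half the horizon, if the inter-peak
intervals still vary by more than 1%), then:

* **Amplitude** is the peak-to-trough range of the retained window.
  Both a `"range"` (max − min) and a `"half_range"` convention are
  implemented; the package default is `"range"`, the convention
  calibrated against the reference value 0.1239 mM for NADH at default
  parameters (the half-range convention misses it by a factor two).
* **Period** comes from strict local maxima refined by fitting a
  parabola through the three bracketing samples, then a least-squares
  regression of interpolated peak times on cycle index. The regression
  averages interpolation error over all cycles; with it, per-species
  period estimates on the same trajectory agree to a few parts in
  $10^5$, which is what makes the species-invariance check on period
  sensitivities meaningful.
* **Oscillation death** is declared when the range falls below
  $10^{-4}$ mM (model trajectories) or when fewer than four peaks
  remain. A dead series carries no period; `period_of()` errors rather
  than returning a number.

At the default parameters the model settles on a limit cycle with NADH
amplitude 0.1237 mM and period 8.44 s. The amplitude matches the
reference table of the GAPDH experiment suite to 0.2%; the period scale
is discussed below.

### A note on the period scale

Published tabulations of this parameterisation quote periods around
25–30 s, matching experimental traces. With the printed per-minute rate
constants, however, the integrated model's NADH period is 8.44 s
(0.1406 min × 60). The discrepancy is a uniform scale factor: the
*relative* periods across the GAPDH titration suite reproduce the
published ratios to about 1% (e.g. the 50/50 scaling changes the period
by −7.9% here against −7.9% in the published ratios), and the published
absolute values are exact Fourier-bin periods, which points to a
frequency-axis labelling artifact in their extraction rather than a
kinetic difference. We report what the equations produce: periods in
model minutes times sixty. Users comparing against literature tables
should compare period *ratios*, which are unit-free, or the amplitudes,
which carry no time unit.

## Sensitivity analysis

For a feature $F$ (amplitude of one species, or the period) and a
parameter $p$, the non-normalised sensitivity is the forward finite
difference $s = (F(p + \delta p) - F(p))/\delta p$ and its
dimensionless normalisation is $s_n = (p/F(p))\, s$. The default
perturbation is $+1\%$ of the nominal value, matching the granularity
of the incremental scans; central differences and other step sizes are
available. Each sensitivity costs exactly two integrations (verified by
call counting in the tests), and `sensitivity_table()` shares one
reference simulation and one perturbed simulation per parameter across
all nine species — 16 integrations for the full 15-parameter table.
If a perturbed model has lost its limit cycle the record is flagged and
the sensitivity reported as missing, never as zero or infinity.

Parameters are ranked by the mean of $|s_n|$ across the nine state
variables. Two robust qualitative outcomes at the reference conditions:
the HK-PFK ATP-inhibition constant `r1ki1` dominates the amplitude
ranking (normalized sensitivity ≈ 6, twice the runner-up), confirming
the ATP feedback on PFK as the main controller; and period
sensitivities are identical across species (relative spread < $10^{-3}$)
because the period is a global property of the orbit, not of one
variable — a useful internal consistency check, since any disagreement
would indicate feature-extraction noise rather than dynamics.

`perturbation_scan()` runs the 0–10% incremental scan of one parameter,
and `run_scan_pair()` contrasts the most sensitive parameter with the
glycerol-branch constant `r8k`: the `r1ki1` scan spreads the period
over tens of percent while the `r8k` scan moves it by under 2%.

## The GAPDH titration suite

GAPDH activity enters the lumped reversible rate law through the
forward ($k_{g1}$) and reverse ($k_{g2}$) constants, so enzyme-level
changes are modelled by scaling them (`scale_gapdh()`). The suite
(`run_gapdh_suite()`) integrates six members for 30 minutes each:
wild type, 100/50, 100/0, 50/100, 50/50 and 30/100 percent
forward/reverse. The asymmetry is the scientific point: eliminating the
reverse reaction entirely changes the NADH amplitude by under 10%,
while halving the forward constant halves the amplitude and scaling it
to 30% collapses the oscillation by about 80% — near the Hopf
bifurcation, where the amplitude shrinks like the square root of the
distance to the bifurcation and becomes exquisitely sensitive to the
exact kinetics. For that near-death member the features are measured
over the final third of the run, and if fewer than four peaks remain a
flagged spectral estimate replaces the peak-based period.

## Fourier analysis of fluorescence traces

Experimental-style traces (`nadh_trace`) follow the induction protocol:
10 Hz sampling, glucose at 60 s, KCN at 140 s, intensities within 10–30
arbitrary units. The discrete Fourier transform of a series
$x_1, \dots, x_N$ uses the standard convention with 1-based bins,
$X_k = \sum_{n=1}^{N} x_n e^{-j 2\pi (k-1)(n-1)/N}$; the implementation
calls the fast transform and is tested against the direct
$O(N^2)$ sum at every length up to 64 and against Parseval's identity.
The dominant frequency is the maximum-power bin among the one-sided
non-DC bins, ties broken toward the lower frequency; the spectral
amplitude is the one-sided, sinusoid-calibrated $2|X_{k^*}|/N$.

The analysis pipeline (`trace_features()`) is: select the oscillating
window, detrend, transform, read off the dominant bin. Window selection
is this package's own definition (only "the oscillating part" is a
standard notion, not an algorithm):

1. noise SD from the pre-glucose baseline (residuals of a line);
2. linear detrend of the post-KCN segment and light smoothing (a
   running mean of a tenth of the nominal period);
3. candidate peaks above three noise SDs, with a minimum separation of
   half a nominal period (smoothed noise can split one crest into
   several local maxima);
4. the window starts at the *second* such peak — the first sits on the
   induction transient — and ends where the rolling peak-to-trough
   range over three nominal periods falls below three noise SDs, or at
   the trace end;
5. the verdict is *oscillatory* only if the window spans at least three
   nominal periods, holds at least four peaks, and its dominant
   spectral component completes at least two cycles — the last rule
   rejects the monotone post-KCN spike relaxation, whose power sits
   below one cycle per window.

Linear (rather than moving-average) detrending was chosen for exact
reproducibility; on a protocol-length window it removes an injected
drift to 0.2% and recovers a superposed sine to 0.6% pointwise. A
non-oscillatory verdict is a flag, never an exception, and such a trace
is never assigned a period. `replicate_summary()` reduces replicate
features to sample means and SDs (n−1), the form in which analytical
replicates are usually reported.

## The synthetic trace generator

No public fluorescence traces accompany this analysis, so
`generate_trace()` emulates the measurement protocol with a
phenomenological signal model: baseline plus slow linear drift, a
post-glucose NADH spike relaxing exponentially (or, for the `pfk2`
phenotype, a post-glucose *drop*), an oscillation switching on a
configurable delay after KCN with a plateau-then-exponential-taper
envelope, and i.i.d. Gaussian measurement noise. Every shape parameter
lives in `synthetic_trace_spec()`; nothing is hard-coded.

The presets encode the documented strain phenotypes: wild types
`by4743` (period 26.05 s) and `x2180` (27.67 s); `hxk1`/`hxk2` with
reduced amplitude and extended duration, `hxk2` more extreme and
slower; near-wild-type `pfk1`, `tdh1`, `tdh2`; and non-oscillatory
`pfk2` (no spike, with the drop), `tdh3`, `pde2`, `ira2`. Wild-type
periods are published values; mutant amplitude and duration numbers
are qualitative encodings of reported orderings, chosen once
(wild type 12% of baseline, `hxk1` 6%, `hxk2` 3%; durations 17/25/35
min) and documented as non-quantitative — no acceptance property
depends on them beyond the oscillatory/non-oscillatory class and the
ordering. Default noise is 2% of the wild-type oscillation amplitude,
a realistic floor for a stirred-cuvette fluorimeter at these settings.

What the generator deliberately does **not** emulate: it is not driven
by the kinetic model (fluorescence units, cell-density effects and
inner-filter artifacts sit outside the model's scope); the noise is
white, whereas real detector noise has low-frequency structure; the
oscillation frequency is constant within a trace, whereas real traces
drift slightly as substrate depletes. Passing the closed-loop tests
therefore demonstrates that the analysis pipeline recovers known
ground truth under protocol-faithful conditions — not that it is
validated on real fluorimetry.

Determinism is guaranteed at both levels: a trace is a pure function of
(spec, seed), and cohorts derive disjoint per-trace sub-seeds from one
master seed (`generate_cohort()`), so every figure and statistic is
exactly reproducible.

## Problem sizes and runtime

The defaults used throughout the package and its tests are 20–30 model
minutes per integration at a 0.001-min output grid (the 30-minute
GAPDH suite is six integrations), one reference plus 15 perturbed
integrations for the sensitivity table, 11-point incremental scans,
and 20 seeds per preset for the closed-loop recovery properties.
These sizes give sub-percent feature reproducibility while keeping a
full run of the suite in the minutes range on a single core.

## Known limitations

* The model lumps HK with PFK and cannot distinguish enzyme subunits or
  isoforms; mutant-specific mechanisms are outside its reach, which is
  precisely why the GAPDH titration works through rate-constant scaling.
* Absolute periods at the printed rate constants are ~3.4× shorter than
  published tabulations (see the period-scale note); ratios and
  amplitudes are the comparable quantities.
* No bifurcation continuation, stochastic simulation, or SBML import;
  the parameter config format is a flat key-value file.
* The window-selection algorithm assumes the standard induction
  protocol (baseline, glucose, KCN); traces without a pre-event
  baseline have no noise estimate and are rejected.
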