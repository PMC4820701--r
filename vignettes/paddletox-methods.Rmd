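---
title: "Models and methods behind paddletox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paddletox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paddletox)
```

paddletox analyses three measurements that together characterize how
amphipathic gating-modifier toxins act on voltage-gated channels: Boltzmann
voltage activation, resting-state toxin occupancy, and lipid partitioning.
This vignette explains each model, its assumptions, the tunable parameters,
the synthetic-data generator used to validate the pipeline, and the
numerical and design choices a maintainer should know about.

## Voltage activation

A channel's open probability at equilibrium is modelled as a two-state
Boltzmann, $P_o(V) = [1 + e^{-zF(V - V_{1/2})/RT}]^{-1}$, with
half-activation voltage $V_{1/2}$ (mV) and effective valence $z$
(elementary charges). The thermal voltage $RT/F$ is computed from the
temperature in `channel_constants()` (default 295.15 K, i.e. room
temperature; ≈25.43 mV), never hard-coded — the source experiments report
only "room temperature (~22 °C)", so the exact value is an assumption, and
it is configurable.

Two fit forms are exposed by `fit_boltzmann()`:

* **Kv form** for normalized tail-current curves (tail current immediately
  after repolarization is proportional to the open probability at the end
  of the step);
* **Cav form**, $(V - V_{rev}) G_{max} P_o(V)$, for peak Ba²⁺ current–voltage
  relations, where the ohmic driving force must be divided out.

Estimation is Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with
deterministic, data-driven starting values: $V_{1/2}$ from the
half-maximum crossing by linear interpolation, $z$ from the 10–90% voltage
width ($z_0 = \ln 81 \cdot (RT/F)/\Delta V_{10-90}$), and for the Cav form
$V_{rev}$, $G_{max}$ from a line through the most depolarized points.
Points are unweighted. $z$ is bounded to $(0.1, 10]$; a fit that lands on a
bound or fails to converge is flagged and a warning raised, never silently
returned. Curves with no transition (response span < 10⁻³) are rejected.
Each curve is fitted individually; per-cell fits can be pooled downstream
(the alternative — fitting pooled means — is not implemented).

## Trace processing

`subtract_leak()` estimates the linear (ohmic) leak by regressing the
steady-state current at user-chosen subthreshold test voltages on voltage,
and subtracts the extrapolated line from every sample using the known
command voltage. At least two fit voltages are required; with three or
more, systematic curvature of the regression (root-mean-square residual
above 5% of the fitted span) flags likely overlap with the activation
range. The operation is idempotent up to the channel current remaining at
the fit voltages — which is why those voltages must really be
subthreshold.

`extract_activation_curve()` reduces each sweep to one amplitude. In Kv
mode a mono-exponential $A e^{-t/\tau} + C$ is fitted to the tail after
blanking the first 2 ms (where real recordings carry the capacitive
transient), and the **relaxing component $A$** extrapolated to tail onset
is taken as the amplitude. Using $A$ rather than $A + C$ is deliberate:
constant tail offsets — residual leak, the steady-state current at the
tail voltage — land in $C$ and cancel exactly from toxin/control
amplitude ratios, and a fast-deactivating subpopulation (toxin-bound
channels, see below) decays inside the blanking window and is likewise
excluded. The price is that the normalized curve is offset by the open
probability at the tail voltage; with the tail placed well below
activation this is ≤10⁻³ and the Boltzmann fit is unaffected. Degenerate
tails (no measurable relaxation) fall back to an early-minus-late mean
difference and are flagged per point. Normalization divides by the signed
amplitude of the largest-magnitude point, so curves saturate at +1 even
when the tail driving force is inward (e.g. a tail at −120 mV, below the
K⁺ reversal). In Cav mode the amplitude is the signed extremum within the
step: the figure legends of the source study describe "peak current
amplitude" even though its methods text says steady-state currents, and
peak is the convention we follow (for the simulator's kinetics the two
coincide at the end of a 500 ms step).

## Toxin occupancy

The occupancy model assumes $n$ equal and independent toxin-binding sites
per channel and that a single bound toxin suffices to prevent opening at
weak depolarizations. The fraction of channels with no bound toxin is then
$F_u = (K_d/(K_d + [T]))^n$, and inverting gives
$K_d = (1/(1 - F_u^{1/n}) - 1)[T]$ (`kd_from_fu()`, the exact algebraic
inverse of `unbound_probability()` — a property the tests verify to 10⁻⁹).

$F_u$ is measured from the current ratio $I/I_0$ (`ratio_curve()`, on raw
amplitudes; points where the control amplitude is below 2% of its maximum
are dropped as quotient noise). `estimate_fu()` locates the plateau as the
longest contiguous run (≥3 points) of consecutive points whose local slope
stays below 0.002 per mV, ties resolved toward more negative voltages; the
source experiments never quantify "plateau", so both thresholds are
package choices, exposed as arguments. A curve without a qualifying run is
an error — experimentally one would adjust the voltage protocol until a
well-defined plateau exists. A single-voltage mode
(`estimate_fu(mode = "voltage")`) supports studies that read $F_u$ at one
stated voltage (e.g. −40 mV for wild type, −30 mV for a mutant); the
plateau mean is the default because it uses more data.

For K⁺-conducting homotetramers $n$ is fixed at 4; for Cav channels
`fit_stoichiometry()` fits $(K_d, n)$ freely to a dose-response table and
also reports companions with $n$ constrained to 1, 2 and 3 for model
comparison. The constrained models are nested in the free one, so the free
residual can never exceed theirs; if the optimizer lands worse, the free
fit is restarted from the best constrained solution. $K_d$ estimates above
a censoring limit (default 50 µM, matching summary tables that print
">50") are flagged censored rather than reported as precise numbers.
`alanine_scan_ratio()` expresses a mutant's sensitivity change as
$F_u^{mut}/F_u^{control}$ at matched dose (>1 = weaker inhibition).

## Lipid partitioning

Toxin insertion into vesicles is quantified from intrinsic tryptophan
fluorescence. Two observables are used: the blue shift of the emission
peak (≈355 nm in water, ≈8 nm shift at saturating lipid), located by
argmax after a 3 nm moving average (`spectral_shift()`; argmax rather than
centroid because the generator's asymmetric bands would bias a centroid,
and the shift is read on a 1 nm grid anyway); and the intensity at 320 nm
across a lipid titration, normalized to the zero-lipid intensity
(`build_partition_curve()`), fitted with the mole-fraction partition
function
$F/F_0([L]) = 1 + (F/F_0^{max} - 1)\,K_x[L]/([W] + K_x[L])$
(`fit_partition()`), where $[W] = 55.3$ M is the molarity of water and
$[L]$ the *available* lipid — 60% of total, a fixed convention of the
assay (roughly the outer-leaflet fraction accessible to an external
peptide); both constants are configurable but should not normally be
touched. Because $K_x$ spans 10⁵–10⁷ across toxins, it is fitted on a
log₁₀ scale internally for conditioning and reported on the linear scale
with a delta-method standard error. The fitted curve's half-saturation
sits at $[L] = [W]/K_x$ — a closed-form identity the tests check. Flat
titrations (span < 0.02) are rejected as "no partitioning detectable".
If the spectra include vesicle-only blanks, each blank is subtracted from
its matched toxin spectrum first; this is the package's concrete reading
of "corrected for vesicle scattering", whose original procedure is not
specified.

## The synthetic-data generator

`simulate_activation_family()` is a forward model of a two-electrode
voltage-clamp activation experiment. Channels split into an unbound
subpopulation (probability $p_0$ from the occupancy model) and a
toxin-bound one; each gates as a single first-order gate relaxing toward
its own Boltzmann steady state with
$\tau(V) = \tau_{V_{1/2}}\,\mathrm{sech}((V - V_{1/2})/w)$ (default 10 ms
at the midpoint, width 30 mV). The sech profile is a package choice: the
source data are described by single-exponential fits per voltage but no
kinetic model is given, and any smooth unimodal $\tau(V)$ that vanishes
far from the midpoint serves, this one being simple and testable. Currents
are ohmic, $g_{max}(V - V_{rev})$, with an additive ohmic leak through
0 mV and Gaussian sample noise.

Toxin-bound channels have their activation midpoint shifted by
`bound_vhalf_shift` (default **+100 mV**) and kinetics slowed 3-fold. The
shift's magnitude is not a measured quantity — the experiments only
require that bound channels fail to open at weak depolarizations — and
the default is chosen so that this defining assumption actually holds in
the simulator: at +100 mV a bound channel's open probability in the
plateau region is below $e^{-z \cdot 100/(RT/F)} \approx 10^{-4}$, so the
$I/I_0$ plateau equals $F_u$ to the accuracy the downstream 5% $K_d$
tolerance requires. (At a +50 mV shift, bound channels would still carry
$\approx e^{-2.6 \cdot 50/25.4} \approx 0.6\%$ of the control current,
biasing strongly-inhibited conditions by >5% in $K_d$ — measurable in the
simulator and at odds with the assumption the estimator encodes.)

Noise defaults to 1% of the maximum amplitude *in the measurement phase*
(tail currents for Kv mode, step currents for Cav mode). Anchoring noise
to the measured quantity rather than to the largest step current keeps
plateau-region tail currents measurable, mirroring real experiments where
protocols and gains are adjusted until the plateau is well defined; oocyte
recordings resolve currents at far better than 1% of maximum.

`simulate_dose_response()` applies fractional Gaussian noise (default 1%)
to the closed-form $F_u$, clipped to (0, 1]. `simulate_emission_spectra()`
builds each spectrum as a weighted sum of two log-normal bands (free peak
355 nm, bound peak 347 nm, FWHM 60 nm — the band shape is arbitrary but
fixed, since only the 320 nm ratio and the argmax carry information), with
the bound-band amplitude chosen so the 320 nm intensity ratio reproduces
the partition function *exactly* at every lipid concentration; optional
vesicle blanks add a smooth scattering background to exercise the
correction stage. All generators are bit-reproducible given a seed.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: capacitive transients and series
resistance; channel inactivation (the relevant study reports no toxin
effect on steady-state availability); multi-state Markov gating and gating
currents; surface-charge screening by divalents; vesicle light-scattering
physics beyond a smooth background; cell-to-cell parameter variability
(noise enters only as additive/fractional Gaussian). Recovery of a
parameter from data generated by the matching model is a necessary check
of the estimator, not evidence about model adequacy for any real channel.

## The screen

`run_screen()` ties the stages together for a construct × toxin table:
simulate (or average `n_cells = 6` simulated cells, matching the n = 6
means reported in this kind of study), leak-subtract, extract, fit gating,
ratio, plateau $F_u$, $K_d$. Failures in any cell are caught and recorded
in a `note` column while the screen continues, so a batch resembles a real
summary table with its censored and "ND" entries. Every intermediate can
be written to disk (`out_dir`) so each summary number traces to an
artifact. With a fixed seed the whole screen is reproducible; per-family
sub-seeds are derived arithmetically from the base seed.
`correlate_inhibition_partitioning()` reports a Spearman rank correlation
between per-toxin inhibition and log $K_x$ — with four toxins this is a
sign summary, not an inference, and the tests only assert its sign for the
study-like configuration.

There is no shell entry point: the exported functions and YAML
configuration (`read_study_config()`) are the interface, which suits an
analysis package used from R scripts and notebooks.

## Problem sizes and defaults used in validation

The package's own validation (test suite and `scripts/acceptance.R`) uses:
activation curves on 5 mV grids spanning the transition (29–33 points);
simulated families with the standard protocol (holding −100 mV, 500 ms
steps every 10 mV, 100 ms tails, 10 kHz sampling); dose-response tables of
8 log-spaced concentrations over 0.1–30 µM; lipid titrations of 10
log-spaced totals over 0.1–100 µM plus the zero-lipid reference; and 100
noisy replicate screens for the bias check of the end-to-end $K_d$
estimator. These sizes resolve all parameters comfortably while keeping
the full validation run in the low minutes on one core.

## Known limitations

* The plateau detector assumes the weak-depolarization plateau is the
  longest flat run; pathological ratio curves with a longer flat segment
  at saturating voltages would need the `v_max` argument.
* Asymptotic standard errors from `nlsLM` understate uncertainty for
  strongly censored or near-flat data; bootstrap intervals are not built
  in.
* The Cav peak-current reading ignores inactivation by construction; for
  channels with fast inactivation the simulator's "peak" is not the
  physiological peak.
* Units are fixed package-wide (mV, ms, µS/nA, µM for toxin, M for lipid
  and water); any conversion happens at the I/O boundary, not inside the
  models.
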