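---
title: "Raman soft sensors for CHO fed-batch cultures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raman soft sensors for CHO fed-batch cultures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softsense)
```

# The problem

Industrial CHO (Chinese hamster ovary) cultivations are monitored with
off-line analysers that measure glucose, glutamine, glutamate, lactate,
ammonium and cell counts once or twice a day. An in-line Raman probe,
by contrast, delivers a spectrum every half hour — but a spectrum is
3000 numbers, not a glucose concentration. A *soft sensor* closes that
gap: a calibration model maps each spectrum to the process variables,
turning the sparse daily record into a dense time course that feeding
controllers can act on.

`softsense` implements the full calibration workflow (preprocessing,
partial least squares, variable selection, outlier removal), a
mechanistic cell-cycle simulator of the fed-batch process, particle
swarm parameter estimation, and a synthetic-data generator that stands
in for proprietary plant data.

# Spectrum preprocessing

**Savitzky–Golay filtering.** A local polynomial least-squares filter:
around every channel $j$ a polynomial of order $p$ is fitted over a
window of $2k+1$ channels, and the smoothed value (or the first or
second derivative) is the fitted polynomial evaluated at the centre:
$x_j^* = \frac{1}{N}\sum_{h=-k}^{k} c_h\, x_{j+h}$.
`savgol_coefficients()` derives the weights $c_h$ and normalisation $N$
by exact integer arithmetic (Gram determinant and adjugate of the
window design matrix), so the classical integer tables are reproduced
bit-exactly — for the 5-point quadratic window: smoothing
$(-3,12,17,12,-3)/35$, first derivative $(-2,-1,0,1,2)/10$, second
derivative $(2,-1,-2,-1,2)/7$:

```{r}
savgol_coefficients(savgol_spec(half_window = 2, poly_order = 2, "smooth"))
```

The window edges are handled by asymmetric least-squares fits of the
same polynomial order over the available channels, preserving the
spectrum length; discarding $2k$ channels of a 3000-channel spectrum
would be wasteful and shift the wavenumber grid. Derivative weights
assume unit channel spacing — physical cm$^{-1}$ scaling would only
multiply every derivative spectrum by a constant, which the subsequent
standardisation removes anyway. The calibration default is a 15-sample
window ($k=7$) with a quadratic polynomial, smoothing only; derivative
targets are available for baseline-heavy data.

**SNV normalisation.** Laser power and probe alignment drift between
acquisitions, scaling and offsetting whole spectra. The standard normal
variate transform centres each spectrum to mean zero and scales it to
unit *population* standard deviation (divisor $N$, not $N-1$). A
zero-variance spectrum is a degenerate input and raises an error rather
than emitting NaN.

# NIPALS partial least squares

With ~100 calibration pairs against ~3000 collinear wavenumbers,
ordinary regression is hopeless; PLS extracts a few latent variables
that maximise predictor–response covariance. The NIPALS implementation
follows the textbook iteration: initialise the response surrogate $u$
from the first response column; compute weights $w = X^\top u / u^\top
u$, normalise $\lVert w\rVert = 1$, scores $t = Xw$, update
$u = Y^\top t/t^\top t$; iterate until the relative score change is
below $10^{-10}$ (at most 500 iterations; a single-column response
converges in one pass per component). $X$ and $Y$ are then deflated by
their rank-one score/loading contributions, and regression coefficients
assemble as $B = W(P^\top W)^{-1}Q^\top$. Both $X$ and $y$ are
standardised before fitting (the data do not say whether scaling the
response is essential, so the symmetric choice is made and recorded in
the model); $B$ lives on the standardised scale and predictions are
back-transformed.

**How many latent variables?** `cross_validate()` computes RMSECV for
each candidate count with standardisation refitted inside every fold
(no leakage). Two fold schemes are provided: contiguous blocks
(default — spectra are a time series, and blocks reduce leakage between
temporally adjacent spectra, giving a conservative, between-batch
flavour of error) and seeded random folds (matching a random
train/validation split, as used in the end-to-end benchmark).
`select_components()` formalises the usual elbow reading — "no drastic
drop beyond here" — as the smallest count within 5% of the curve
minimum; the tolerance is configurable and 0 recovers the strict
minimiser.

# Variable selection

**VIP.** The variable-importance-in-projection score
$\mathrm{VIP}_j = \sqrt{m \sum_a \mathrm{SSY}_a w_{ja}^2 / \sum_a
\mathrm{SSY}_a}$, with $\mathrm{SSY}_a = q_a^2\, t_a^\top t_a$ the
response variance captured by component $a$. Squared scores average to
exactly 1, so the conventional threshold of 1 selects variables
carrying more than an average share of the signal. VIP is cheap but
known to over-select under collinearity and to be unstable on small
calibration sets.

**CARS.** Competitive adaptive reweighted sampling is described in the
chemometrics literature as a Monte-Carlo loop; the concrete recipe
implemented here is the canonical one: at iteration $i$ of $N$, (i) fit
a PLS model on a random 80% row subsample of the currently retained
variables; (ii) weight every variable by $|b_j|$, its standardised
coefficient magnitude (standardised so units cannot bias selection);
(iii) enforce an exponentially decreasing retained count
$r(i) = m e^{-\lambda (i-1)}$ calibrated so $r(1)=m$ and $r(N)=2$;
(iv) resample the survivors with probability proportional to weight
(adaptive reweighted sampling, $m$ draws with replacement); (v) score
the candidate subset by RMSECV on the full calibration set. The subset
with the smallest RMSECV wins. The default budget is 100 iterations
with 5-fold CV scoring — enough for the retained count to anneal from
3000 to 2 — and every run is bit-reproducible per seed.

# Monte-Carlo outlier removal

Bubbles, fluorescence bursts and unmixed sample volumes produce spectra
that no calibration should be asked to fit. The screening procedure is
prediction-based: repeatedly split the calibration pairs 4:1, fit the
full PLS pipeline on the 80%, and record each held-out spectrum's
absolute prediction error; over many repeats every spectrum accumulates
a mean error and an error standard deviation. Spectra with consistently
high errors are outlier candidates.

The flagging threshold is deliberately robust: a spectrum is flagged
when its mean error exceeds `median + 3.5 * MAD`, or when mean + sd
exceeds the analogous combined threshold — median/MAD because the error
population is itself contaminated by the outliers being hunted, and
absolute (not squared) errors for the same reason. Removal then refits;
by default a single round is performed, and never more than 20% of the
rows are removed in total, a guard against pruning the model into
overfitting on "typical" spectra.

# The fed-batch cell-cycle model

The simulator's core is a mechanistic model with four cell-cycle
compartments — quiescent G0, growth G1, DNA-synthesis S and mitosis
G2/M — plus volume, glutamine, ammonium, glucose, lactate and antibody
balances. All states are *amounts* (concentration × volume): the
balances are naturally written as $d(CV)/dt$, so amount form is the
literal transcription and avoids quotient-rule bookkeeping;
concentrations are derived views (`observables()`).

Key structure: mitosis returns cells from G2/M to G1 with a factor 2
(one net new cell per division); the G1 efflux splits between S
(fraction `m_stress`) and G0; an additional G1→G0 transition
`k_G1G0` represents temperature stress. Transition rates default to
$\ln 2 / t_{\text{phase}}$, consistent with the doubling-time growth
rate $\mu = \ln 2/(t_{G1}+t_S+t_{G2M})$ that also scales the
phase-specific antibody productivities. Glutamine is consumed by all
viable cells and degrades chemically to ammonia (`K_deg`); glucose is
consumed at `Q_Glc` by cycling cells and at the maintenance rate
`m_Glc` by G0 cells, with lactate coupled through the yield `Y_Lac`.
As written, the maintenance term carries a negative sign in the lactate
balance, so lactate + `Y_Lac`·glucose is conserved exactly only while
the G0 pathway is idle; the conservation tests exercise exactly that
regime. The outflow `F_OUT` removes every species at its current
concentration.

Three dependencies are named by the model but have no closed form in
it: the temperature dependence of `k_G1G0`, lactate inhibition of
`Q_Glc`, and the glutamine uptake-limiting function. They are exposed
as multiplicative hooks (`f_temp(t)`, `f_inh(lac)`, `f_upt(gln)`)
defaulting to a constant 1, so the bare model is exactly the printed
balance set. The antibody production term uses the constant
doubling-time $\mu$; a state-dependent growth rate can be injected
through the same hook mechanism if needed.

Integration uses `deSolve::lsoda` between discontinuities:
piecewise-constant feed rates and instantaneous bolus/sampling events
split the horizon into smooth segments, so the stiff-capable adaptive
integrator never steps across a jump. Boluses add volume and
feed-concentration × volume of analyte; samples scale all amounts by
$(V-v)/V$. Default tolerances are `rtol = 1e-8`, `atol = 1e-10`;
halving them moves a 3-day endpoint by less than $10^{-6}$ relative.
Tiny negative excursions (beyond $-10^{-9}$ of the state scale the run
aborts) are clamped to zero with a warning.

# Particle swarm parameter estimation

Kinetic parameters are estimated by global-best PSO with the
constriction-equivalent defaults $w = 0.729$, $c_1 = c_2 = 1.494$, 30
particles, 300 iterations, positions reflected at the (mandatory) box
bounds and velocities clamped to half the box width. The criterion is a
combined RMSE: each observed series is interpolated from the simulated
trajectory at its observation times, its RMSE normalised by the series'
standard deviation (so g/L, mmol/L and cell counts combine on one
scale — the data alone do not dictate a unit reconciliation, so this
explicit, overridable normalisation is used), and the weighted mean
taken. A parameter vector whose simulation fails scores a large finite
penalty instead of raising, keeping the swarm moving.

# The synthetic world

The study's plant data are proprietary, so the package ships a
generator whose defaults define the benchmark conditions once:

* **Process**: four 14-day fed-batches in an 8 L working volume,
  inoculated at 0.5·10⁶ cells/mL, growing to a 12–18·10⁶ cells/mL
  plateau after a day-7 temperature downshift (hook `f_temp`, factor 4
  on `k_G1G0`) with Monod-limited glutamine uptake (K = 0.1 g/L).
  Glucose starts at 10 g/L; once it falls below the 6 g/L setpoint an
  operator doses concentrated feed (400 g/L) once a day to top it back
  up — dosing *from the measurement*, which is what produces the
  characteristic sawtooth. Batches differ by ±10% in inoculum, start
  glucose and uptake rates.
* **References**: 2 per day with 2% relative measurement noise
  (typical analyser repeatability), ~112 usable pairs over 4 batches.
  Glutamate and total cell count are synthetic bookkeeping views
  (accumulated degraded glutamine; viable + accumulated dead cells).
* **Spectra**: every 1800 s, ~672 per batch, on a 3000-channel
  100–3400 cm$^{-1}$ axis. Each spectrum is a linear mixture of
  random pure-component profiles (glutamine and glutamate share 80% of
  their peaks — they are nearly indistinguishable by Raman, which is
  why the glutamine sensor is the weak one), sitting on a large
  constant aqueous-medium background. That background matters: it is
  what makes per-spectrum SNV normalisation approximately affine, as
  it is on real bioreactor spectra where water and media dominate.
* **Nuisances**: random cubic baselines (amplitude 30), a growing
  broad fluorescence background (30), 5% lognormal gain,
  additive channel noise (0.5), ten unmodelled interferent species
  with smooth random time courses (amplitude 5), and slow per-channel
  random-walk drift (amplitude 10, probe fouling/detector aging).
  The interferents and drift are what give wavelength selection its
  advantage over full-spectrum PLS — exactly the regime the method
  ladder (plain PLS → CARS → CARS + outlier removal) is designed for.
  These magnitudes were set so that the ladder's validation metrics
  land near the reported behaviour of such pipelines on real
  cultivations (plain PLS R² ≈ 0.95, improving with selection and
  outlier removal), and are not revisited per experiment.
* **Outliers**: 2% of all spectra, plus 3% of the reference-matched
  spectra (the ones that become calibration pairs), corrupted as
  cosmic-ray spikes, fluorescence bursts, or inhomogeneity events
  (the spectrum blends in the content of a different process state).
  Gain-type corruptions are deliberately *not* planted: SNV removes
  them exactly, so they are harmless by construction. Ground-truth
  labels are returned for benchmarking recall and false-alarm rates.

What passing tests on this world do *not* show: real spectra have
nonlinear detector response, temperature-dependent peak shifts, and
water-band interactions that a linear mixture cannot produce; the
generator's linearity is the assumption under which PLS is the right
model, so end-to-end results validate the workflow, not the physics.

**Evaluation convention**: validation metrics are computed on
uncorrupted validation spectra (using the ground-truth labels). A soft
sensor cannot be asked to read a bubble; the value of outlier removal
is measured through the model it trains, not by scoring predictions on
spectra known to be garbage.

# Problem sizes used in the test suite

The shipped tests run the canonical fixture at its full scale (4
batches × 672 spectra × 3000 channels) once for the headline accuracy
check, and use reduced scales elsewhere — 300–600 channels, hourly
spectra, 2 batches — chosen so the whole suite exercises every code
path at statistically meaningful sizes. The 10-seed method-ordering
study uses hourly spectra with 50 CARS iterations and 40 Monte-Carlo
outlier repeats per seed.

# Known limitations

* The model has no dead-cell state: total cell count exists only as a
  generator-side bookkeeping view, and `F_OUT` removes cells at the
  viable-cell concentration.
* One documented CSV dialect (comma, decimal point, UTF-8); no vendor
  binary formats.
* CARS's subset scoring inherits the winner's-curse bias of choosing
  the minimum over many cross-validated candidates; its RMSECV is an
  optimistic estimate and validation on held-out data remains the
  arbiter.
* PSO offers no identifiability analysis: a flat criterion valley
  yields an arbitrary point inside it.
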