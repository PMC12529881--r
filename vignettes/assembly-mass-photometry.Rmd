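---
title: "Quantifying protein assembly equilibria and their inhibition from mass photometry events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein assembly equilibria and their inhibition from mass photometry events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

assemblyMP analyzes single-particle mass photometry (MP) data for a protein
that self-associates in two steps, monomer to dimer to tetramer, and whose
assembly state is shifted by a substrate and by small-molecule inhibitors.
The motivating system is the UDP-GlcNAc 2-epimerase subunit (GNE, 46.4 kDa
as the His-tagged construct) of the bifunctional GNE/MNK enzyme: only the
tetramer is catalytically active, substrate binding stabilizes tetramers,
and orthosteric inhibitors that displace the substrate disassemble them.
This vignette is the package's account of its models, estimators, numerical
choices and limitations. Every empirical statement here is computed by the
test suite or by the `analysis/` drivers; nothing is quoted from elsewhere.

## The assembly model

The stepwise equilibria are

$$2\,\mathrm{M} \rightleftharpoons \mathrm{D}, \qquad K_1 = \frac{[M]^2}{[D]},
\qquad\qquad 2\,\mathrm{D} \rightleftharpoons \mathrm{T}, \qquad
K_2 = \frac{[D]^2}{[T]},$$

with both dissociation constants in molar particle units. Mass conservation
in monomer equivalents,

$$[M] + 2\frac{[M]^2}{K_1} + 4\frac{[M]^4}{K_1^2 K_2} = C_\mathrm{tot},$$

is strictly increasing in $[M]$, so `solve_equilibrium()` brackets the unique
root on $[0, C_\mathrm{tot}]$ and bisects for 200 iterations. Bisection was
chosen over Newton-type schemes because it converges unconditionally over
the full parameter range (constants from nanomolar to molar), needs no
starting guess, and makes the solver bit-reproducible. The conservation
residual is below $10^{-9}$ relative; the test suite checks this against an
independent `uniroot()` oracle over 1000 random parameter draws.

No trimeric intermediate is modeled: MP histograms of this system show
three well-separated populations at roughly 1x/2x/4x the monomer mass, so
assembly is treated as strictly stepwise. Assembly kinetics are out of
scope; all conditions are assumed equilibrated (the emulated protocol
incubates 30 min and measures within 60 s of dilution, inside the window in
which the distribution is known to be stable, so the generator evaluates
the equilibrium at the incubation concentration, not at the diluted
measurement concentration).

## Substrate and inhibitor linkage

The study system is characterized by four interface constants: without
substrate $K_1^0$ = 12.6 nM and $K_2^0$ = 9.6 uM; with saturating substrate
$K_1^S$ = 37.2 nM and $K_2^S$ = 98.1 nM. How interface energies move between
these endpoints as a function of substrate occupancy is not observable from
endpoint experiments, so the package makes the simplest monotone choice,
log-linear interpolation weighted by a Hill-shaped occupancy:

$$\theta = \frac{s}{1 + s + b + \alpha s b}, \quad
s = (S/K_S)^{n_\mathrm{link}}, \; b = B/K_B,$$
$$\log K_2^\mathrm{eff} = (1-\theta)\log K_2^0 + \theta \log K_2^S,$$

and analogously for $K_1$, with one extra term $\phi_B \log \gamma_D$ on
$K_1$, where $\phi_B$ is the fractional inhibitor occupancy. The occupancy
denominator is the allosteric ternary-complex form: an inhibitor competes
with substrate through $b$, and $\alpha$ < 1 encodes negative binding
cooperativity. Defaults: $K_S$ = 34.6 uM and $n_\mathrm{link}$ = 1.3 (the
measured substrate affinity and tetramer-curve cooperativity of the study
system).

`gamma_D` is a deliberate phenomenological addition: the pyrimidinone
inhibitors destabilize dimers as well as tetramers, which pure competition
at the substrate site cannot produce in this model. $\gamma_D$ is the
fold-weakening of $K_1$ at full inhibitor occupancy; $\gamma_D = 1$ gives a
clean tetramer-only inhibitor (the xanthine-scaffold compound), and the
default 8 for the two pyrimidinone-like profiles produces the observed
sequential pattern - tetramers collapse first (low inhibitor), dimers
second (high inhibitor) - without affecting the tetramer IC50 materially.

### Inhibitor profiles are calibrated to measured potencies

The measured tetramer-destabilization potencies of the three study
compounds are IC50 = 19.7, 19.4 and 3.1 uM, while the operational-model
estimate of the most potent compound's affinity is $K_B$ = 25.2 nM. These
two numbers are not mutually consistent under the ternary-complex linkage
above: $K_B$ = 25.2 nM would predict a tetramer IC50 near 0.1 uM under the
standard assay (800 nM protein, 100 uM substrate). The package treats the
measured IC50s as the defining property of each synthetic inhibitor:
`calibrate_inhibitor_kb()` root-finds the $K_B$ at which the model's
noise-free tetramer IC50 (half-drop of the tetramer fraction, located by
interpolation on a fine log grid) equals the target. `inhibitor_profiles()`
applies this with $\alpha$ = 0.02 shared by all three profiles and
$\gamma_D$ = 1 / 8 / 8. The affinity gap between Schild/OMAM estimates and
IC50-implied affinities is thereby carried into the synthetic data as a
property of the emulated study rather than silently reconciled.

## The synthetic-data generator

`simulate_events()` draws one acquisition: species are drawn multinomially
with probabilities proportional to the *particle* concentrations
$([M], [D], [T])$ - MP counts landings, so counts are particle-based, not
mass-weighted. Each event mass is Gaussian around $k \cdot 46.4$ kDa
($k = 1, 2, 4$) with standard deviation `peak_cv` times the species mass;
events under the 40 kDa detection floor are redrawn. A `background_rate`
fraction of events is uniform over [40, 300] kDa, mimicking non-specific
landings. Defaults `peak_cv = 0.08` and `background_rate = 0.02` are
judgment calls - the instrument's true peak widths are not published - and
both are exposed in `noise_model()`. Histograms default to 8000 events, the
per-histogram count floor of the emulated experiments; titrations default
to the study's grids (`titration_design()`): 11 two-fold protein steps
50 nM-50 uM, 7 two-fold substrate or inhibitor steps 7.81-500 uM at 800 nM
protein, and a Schild grid of 14 substrate steps (~0.1-800 uM) crossed
with inhibitor concentrations from 2 nM to 200 uM.

What the generator does *not* emulate: interferometric contrast physics,
frame-level movie structure, focus drift, mass-dependent detection
efficiency (the monomer sits near the 40 kDa floor, but the emulated
analysis quantifies it without correction, so the generator omits the
effect by default), and day-to-day calibration drift. Passing tests
therefore demonstrate that the estimators are consistent for data with the
assumed statistical structure - multinomial counting noise on equilibrium
proportions plus Gaussian peak broadening - not that they are robust to
every instrumental artifact of real acquisitions.

`simulate_calibration_standard()` provides the glycinin mass standard (160,
320, 480, 640 kDa species) used by `calibrate_masses()`, which k-means-locates
one peak per known species (deterministic quantile initialization) and fits
the linear raw-to-kDa map by least squares.

## From events to oligomer fractions

`fit_peaks()` fits a three-component Gaussian mixture (plus optional
uniform background) by EM, initialized at the nominal species masses with
8% relative widths, and hard-assigns events by maximum posterior. Degenerate
outcomes - zero-width components (noise-free input), non-convergence within
500 iterations, or reordered component means - are flagged and counting
falls back to fixed windows at mean +/- 2.5 initial sigmas, with ties
assigned to the lower-mass species. For well-separated peaks
(`peak_cv` <= 0.1) posterior and window counts agree within 2%.

`fractions_from_counts()` reports both conventions, always: *count
fractions* $c_k/\sum c$ (the frequency-distribution view of the histogram)
and *concentration fractions* $(c_M, 2c_D, 4c_T)/\sum$ (the share of total
protein in each species). Downstream fits use concentration fractions;
count fractions are retained because the two conventions differ
substantially whenever oligomers are abundant, and published figures do not
always state which is shown.

## Interface affinities: the estimator and its factor of two

The binding-plot convention plots a species fraction against the free
partner concentration ($M_\mathrm{free} = f_M C_\mathrm{tot}$,
$D_\mathrm{free} = f_D C_\mathrm{tot}/2$) and reads the dissociation
constant off a Hill-logistic midpoint. Under the stepwise model the total
fractions are imperfect probes: the monomer fraction of *all* protein is
depressed by tetramer at high concentration, and the tetramer fraction of
all protein is contaminated by monomer at low $K_2^\mathrm{eff}$, which
biases midpoints by up to ~30% in the with-substrate design. The package
therefore fits the conversion fraction *local to each interface*:

$$y_{MM} = \frac{f_D}{f_M + f_D} = \frac{[M]/K_1 \cdot [M]}{[M] + 2[M]^2/K_1}
\cdot 2 = \frac{M_\mathrm{free}}{K_1/2 + M_\mathrm{free}}, \qquad
y_{DD} = \frac{f_T}{f_D + f_T} = \frac{D_\mathrm{free}}{K_2/2 + D_\mathrm{free}}.$$

Each is an exact rectangular hyperbola in the free partner with midpoint
$K/2$: the half-conversion point of a 2-into-1 association sits at half the
mass-action constant. `fit_assembly_affinities()` fits these with plateaus
fixed at 0 and 100% and reports $K_d = 2 \times$ midpoint, which recovers
the generating constants exactly on noise-free fractions and within 15% at
8000 events x 3 replicates. This stoichiometric factor is also the likely
origin of the familiar observation that law-of-mass-action constants
computed from species concentrations run about two-fold above
midpoint-read constants: `mass_action_kd()` on this package's generator
reproduces the generating constants exactly, while the naive total-fraction
midpoint sits at half of them.

Measurements with substrate are made at a fixed 100 uM, not at saturation
(occupancy $\theta \approx 0.80$ at the defaults), so the fitted constants
are effective constants at that occupancy. When given the linkage
parameters, `fit_assembly_affinities()` inverts the log-linear linkage to
report saturation constants; the inversion is exact on noise-free data and
amplifies relative noise by $1/\theta \approx 1.25$.

## Dose-response conventions

`fit_hill()` fits $y = \mathrm{bottom} + (\mathrm{top} -
\mathrm{bottom})\, x^n/(K^n + x^n)$ by Levenberg-Marquardt with the
midpoint on a log scale, inverse-variance weights when replicate standard
deviations exist, plateau constraints as hard boxes (+/- 5 response
percentage points around a supplied asymptote, or fixed exactly), and an
optionally fixed Hill coefficient. Fits are flagged - never silently
reported - when the optimizer fails, the midpoint leaves the data range by
more than 100x, or the observed response spans under 5 percentage points
(no transition to fit).

Tetramer curves use $n$ fixed at 1.3, the cooperativity measured for this
system; other curves leave $n$ free. This matters for the substrate
titration: the tetramer-fraction midpoint under the generator linkage is
intrinsically right-shifted from the linkage $K_S$ (the fraction responds
convexly to occupancy), about +22% with free $n$ and +15% with $n$ fixed
at 1.3. The package adopts the fixed-$n$ convention for the $K_S$ readout
and treats the residual shift as a property of reading a linkage constant
off a response midpoint.

The inhibitor stage of the pipeline extends the two-fold titration below
the 7.81 uM protocol floor (down to 61 nM) because a 3.1 uM midpoint is not
identifiable from a grid that starts above it; the emulated study likewise
extended its most potent compound down to 2 nM.

## Pharmacology

**IC50 to Ki.** The exact algebra behind the study's modified Cheng-Prusoff
conversion is supplementary-only, and no standard closed form ( $1 + S/K_S$
= 3.9, its Hill-power = 5.9, $1 + (S/K_S)^n$ = 5.0 ) reproduces the
printed IC50/Ki ratios of ~38. Rather than guess one closed form,
`ic50_to_ki()` exposes three explicit modes - `classical`, `hill`, and
`empirical_lambda` - and `calibrate_lambda()` back-derives the factor as
the geometric mean of matched IC50/Ki pairs, flagging inconsistency above
10%. On the three study pairs the per-pair ratios agree within 2%
($\lambda \approx 37.9$), so the empirical mode reproduces every printed Ki
from its printed IC50; the mode used is recorded in every output.

**Schild.** `schild_analysis()` regresses $\log_{10}(CR - 1)$ on
$\log_{10} B$ with $CR = EC_{50}(B)/EC_{50}(0)$, reporting slope,
$K_{B,\mathrm{app}} = 10^{x\text{-intercept}}$ and $R^2$. The linear region
defaults to all points with $CR - 1 > 0.2$, a deterministic mirror of the
empirical no-effect/linear split; per-curve EC50s use free Hill slopes. On
competitive input $CR = 1 + B/K_B$ the slope is exactly 1 and the intercept
exactly $K_B$ for any $K_B$ (a test property over three decades).
`schild_nonlinear()` fits the allosteric ternary-complex relation
$CR = (1 + B/K_B)/(1 + \alpha B/K_B)$ on log CR, flagging the
unidentifiable $\alpha = 1$ case.

**OMAM.** `omam_response()` implements the Hill-modified operational model
of allosterically modulated agonism,

$$E = E_\mathrm{max} \frac{A^n}{C^n + A^n}, \quad
A = \tau_S S (K_B + \alpha\beta B) + \tau_I B K_S, \quad
C = S K_B + K_S K_B + K_S B + \alpha S B,$$

which reduces at $B = 0$ to the operational Hill curve
$E_\mathrm{max} (\tau_S S)^n / ((S + K_S)^n + (\tau_S S)^n)$.
`omam_global_fit()` fixes $E_\mathrm{max}$ and $K_S$, shares the six free
parameters across all curves, and minimizes weighted SSE from 12
log-uniform multi-starts (seed 12345, fixed for reproducibility) with box
bounds $\alpha, \beta \in [0, 100]$, $\tau \geq 0$ on log scales, picking
the best final SSE. Noise-free curves generated from the model refit to
within 5% of truth, and refitting the fit's own predictions returns the
same parameters (idempotence); a missing $B = 0$ control raises an
identifiability error, and a $B = 0$-only input returns $\tau_S$ with the
inhibitor-side parameters flagged unidentifiable.

Two caveats are retained deliberately. First, the printed operational
parameters imply a $B = 0$ midpoint near $K_S/(\tau_S - 1) \approx 2$ uM,
in tension with a response that plateaus only near 100 uM; the package
implements the stated functional form and does not force consistency.
Second, when the OMAM is fitted to data from the *thermodynamic* generator
(stage 4 of the analysis), the two model families disagree: the fit
compensates through parameters pinned at bounds (reported in `at_bounds`).
Schild and OMAM estimates are treated as independent analyses, exactly
because each is model-based.

## Problem sizes and reproducibility

Every stochastic component takes an explicit integer seed; per-condition
seeds are derived deterministically, event simulation restores the caller's
RNG state, and rerunning any driver or `run_pipeline()` with the same
configuration yields byte-identical outputs. The analysis drivers run the
full study scale (8000 events, triplicates, all designs: ~500 histograms)
in well under a minute; the test suite uses the same scale for the headline
recovery checks and smaller sizes (500-2000 events) for interface and
smoke tests. Recovery tolerances asserted in the tests are 15% for the
substrate-free constants and 20% for the saturated dimer-dimer constant
and the tetramer IC50, at study scale.

## Known limitations

- The linkage between substrate occupancy and interface energies is a
  modeling choice; only its endpoints are empirically anchored.
- Interface-local conversion fractions assume strictly stepwise assembly;
  off-pathway species would bias both axes.
- The EM peak model assumes Gaussian, unimodal, well-separated species
  peaks; heavily overlapping peaks (peak_cv well above 0.1) degrade
  assignment before they are flagged.
- `empirical_lambda` reproduces a conversion, not a mechanism: it should be
  recalibrated for any other assay.
- Curves are fitted independently (plus one global OMAM fit); a joint
  thermodynamic fit of all species and conditions is out of scope.
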