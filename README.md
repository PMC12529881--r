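# assemblyMP

Quantitative analysis of protein oligomerization — and its inhibition by
small molecules — from single-particle mass photometry (MP) data.

MP measures the mass of individual particles landing on a glass surface, so
one acquisition is simply a list of per-particle masses (kDa). For a protein
that assembles stepwise, monomer ⇌ dimer ⇌ tetramer, those event lists
carry the full assembly thermodynamics: the histogram peaks at 1×/2×/4× the
monomer mass, and the peak populations across a titration encode the
interface dissociation constants and how ligands shift them. The package is
written for biophysicists and drug-discovery scientists who want to turn MP
event lists into interface affinities, substrate-linkage parameters, and
inhibitor potencies. Its motivating system is the UDP-GlcNAc 2-epimerase
subunit (GNE, 46.4 kDa) of the sialic-acid pathway enzyme GNE/MNK, whose
active species is the tetramer, but every component is parameterized and
reusable.

## What it computes

* **Equilibrium core** — for 2M ⇌ D (K₁ = [M]²/[D]) and 2D ⇌ T
  (K₂ = [D]²/[T]), `solve_equilibrium()` finds the unique species
  distribution at any total concentration (bisection on the conservation
  equation, residual < 10⁻⁹). `effective_constants()` maps substrate and
  inhibitor concentrations onto effective K₁/K₂ through an allosteric
  ternary-complex occupancy with Hill exponent; `mass_action_kd()` inverts
  species concentrations back to constants.
* **Synthetic data** — `simulate_events()` / `simulate_titration()` generate
  seeded event lists with multinomial particle counting, Gaussian peak
  broadening, uniform background and a 40 kDa detection floor, for the
  study's designs (protein dilution 50 nM–50 µM, substrate/inhibitor
  titrations 7.81–500 µM at 800 nM protein, substrate × inhibitor Schild
  grids) plus a glycinin calibration standard (160/320/480/640 kDa).
* **Histogram analysis** — `fit_peaks()` (3-Gaussian mixture + background,
  EM with a deterministic fixed-window fallback), `fractions_from_counts()`
  (count and monomer-equivalent concentration conventions, always both),
  `mass_accuracy()`, and linear mass calibration against the standard.
* **Binding fits** — `fit_hill()` (4-parameter Hill-logistic,
  y = bottom + (top − bottom)·xⁿ/(Kⁿ + xⁿ), weighted, with plateau boxes
  and fixable n) and `fit_assembly_affinities()`, which reads K₁ and K₂
  from interface-local conversion fractions against free monomer/dimer
  concentrations and extrapolates fixed-substrate measurements to
  saturation.
* **Pharmacology** — `ic50_to_ki()` (classical, Hill and empirically
  calibrated Cheng–Prusoff modes; `calibrate_lambda()` derives the factor
  from matched IC50/Ki pairs), `schild_analysis()` (log(CR−1) vs log B,
  slope and K_B,app), `schild_nonlinear()` (allosteric ternary-complex CR),
  and `omam_global_fit()` (Hill-modified operational model of allosterically
  modulated agonism; multi-start global fit of τ_S, τ_I, α, β, K_B, n).
* **Pipeline** — `run_pipeline()` chains simulate → quantify → fit →
  pharmacology from a `run_config()` (or YAML file) into CSV/JSON outputs;
  the `analysis/` scripts run the same stages as a narrated workflow.

## Worked example

```r
library(assemblyMP)
p <- equilibrium_params()   # study-system constants: K1 = 12.6 nM, K2 = 9.6 uM, ...

# species distribution at 50 nM total protein, no substrate
sp <- solve_equilibrium(p$K1_0, p$K2_0, 50e-9)
#> M = 14.9 nM, D = 17.5 nM, T = 0.032 nM

# simulate one acquisition at the standard assay point and quantify it
ev <- simulate_events(p, NULL, assay_condition(800e-9, S = 100e-6),
                      n_events = 8000, seed = 1)
quantify_events(ev)
#> fractions (conc): M 8.5%, D 40.3%, T 51.2%  [method: mixture]

p$K2_0 / p$K2_S        # substrate stabilization of the dimer-dimer interface
#> 98
mass_accuracy(50, 46.4) # observed monomer peak vs known monomer mass
#> 92.8
```

At 50 nM the protein is mostly monomer and dimer with a trace of tetramer;
at 800 nM with 100 µM substrate, half the protein mass sits in tetramers —
the substrate strengthens the dimer–dimer interface 98-fold (9.6 µM →
98.1 nM). The monomer peak appears near 50 kDa against a true 46.4 kDa,
i.e. 93% mass accuracy.

The full narrated analysis — simulate and quantify all designs, fit the
interface affinities, rank inhibitor potencies, run Schild and OMAM — is:

```sh
Rscript analysis/01_simulate_quantify.R
Rscript analysis/02_assembly_affinities.R
Rscript analysis/03_inhibition.R
Rscript analysis/04_schild_omam.R
```

Each script states what it found and writes tables under `results/`.

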