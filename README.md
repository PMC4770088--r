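# modflex

Cytosine carries a family of chemical marks — 5-methylcytosine (5mC) and
its oxidation products 5-hydroxymethyl- (5hmC), 5-formyl- (5fC) and
5-carboxylcytosine (5caC) — that sit at the heart of DNA methylation and
demethylation. Beyond their signalling roles, these marks change the
*mechanics* of the double helix: how easily it bends, how fast a short
fragment cyclizes into a loop, and how stably it stays wrapped around a
histone core under tension. modflex is an R package for analysing exactly
these questions, aimed at single-molecule biophysicists and simulators who
need a tested, reproducible pipeline from conformational ensembles and
single-molecule recordings to flexibility and stability statistics.

## What it computes

* **Rigid base-pair geometry.** Reference frames fitted to base ring atoms,
  and the twelve parameters of the rigid base-pair description — shift,
  slide, rise, tilt, roll, twist between stacked pairs and shear, stretch,
  stagger, buckle, propeller, opening within a pair — via the mid-frame
  decomposition $R_1^{\top}R_2 = R_z(\tfrac{\omega}{2}-\phi)\,R_y(\Gamma)\,
  R_z(\tfrac{\omega}{2}+\phi)$, with an exact inverse (`rebuild_frames()`)
  for building chains back from parameters.
* **Fluctuation statistics.** Per-position Gaussian summaries with
  block-averaged standard errors, change-in-mean / change-in-s.d. profiles
  versus distance from a CpG step, 3-bp window averages, and condition
  ranking with "greater-or-similar" tie notation.
* **Cyclization kinetics.** Two-state looping simulation of a molecule
  population after a salt jump, exponential fits of the looped fraction
  $f(t) = f_\mathrm{eq}(1-e^{-t/\tau})$ with molecule-bootstrap errors, and
  fold-changes of the apparent looping time $\tau$.
* **Loop-closure propensity.** A seeded Monte Carlo over fluctuating
  90-step base-pair chains (compiled core) linking fluctuation amplitudes
  to loop-closure probability, with exact binomial intervals.
* **Force spectroscopy.** Ratiometric FRET efficiencies, Gaussian histogram
  peaks, simulation and change-point classification of nucleosome
  stretching traces (high-force drop / gradual-then-drop / low-force drop),
  trace averaging and class percentages.
* **Synthetic data.** Generators for MD-like parameter ensembles (Gaussian
  fluctuations with CpG-localized modification effects), looping time
  courses and stretching traces, so the whole pipeline is testable end to
  end with no external data.

## Worked example

Build the cyclization construct, simulate looping for unmodified DNA and a
four-copy 5fC construct, and compare looping times:

```r
library(modflex)

loop_circumference(cyclization_construct(80, 10))
#> [1] 90

seq70 <- cyclization_core_70mer()
interior_cpg_steps(seq70)
#> [1] 22 28 34 46

tc_un <- simulate_looping(500, 0.8 / 600, 0.2 / 600,
                          default_sample_times(600), seed = 1)
tc_fc <- simulate_looping(500, 0.8 / 200, 0.2 / 200,
                          default_sample_times(200), seed = 2)
fit_un <- fit_looping(tc_un)
fit_fc <- fit_looping(tc_fc)
fit_un
#> looping_fit: tau = 575.4 +/- 46 s, f_eq = 0.804 +/- 0.016
fold_change(fit_un, fit_fc)$ratio
#> [1] 2.63957
```

The loop closes at a circumference of 90 bp; the central 70-mer carries
four interior CpG steps; and the fitted looping times recover the
generative threefold contrast (600 s vs 200 s) within the bootstrap
errors, with equilibrium looped fractions near 0.8.

The numbered scripts under `analysis/` run the full workflow —
constructs, looping kinetics for all five conditions, fluctuation
profiles and ranking, end-to-end geometry recovery, closure-propensity
comparison, and force-spectroscopy analysis — writing their tables under
`results/`. For instance, `Rscript analysis/03_fluctuation_profiles.R`
ends with the flexibility ranking by the window-averaged change in roll
s.d.:

```
Flexibility ranking by roll s.d. change:
   5-fC>5-hmC>5-caC>unmodified C>5-mC
```

and `Rscript analysis/05_loop_propensity.R` shows closure propensities
ordered the same way (5fC ~2.6× the unmodified chain, 5mC ~0.3×).

## Documentation

The methods vignette (`vignettes/modflex-methods.Rmd`) documents the
models, parameter conventions, what the synthetic generators do and do not
emulate, numerical tolerances, and known limitations.
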