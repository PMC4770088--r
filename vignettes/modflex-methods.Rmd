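---
title: "Models and methods behind modflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind modflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modflex)
```

modflex analyses how cytosine modifications — 5-methylcytosine (5mC) and
its TET-oxidation products 5-hydroxymethyl- (5hmC), 5-formyl- (5fC) and
5-carboxylcytosine (5caC) — change the mechanical behaviour of DNA and of
nucleosomes. The package joins four quantitative layers: (i) the rigid
base-pair description of duplex geometry and its fluctuation statistics,
(ii) two-state cyclization (looping) kinetics as the operational readout of
flexibility, (iii) a Monte Carlo loop-closure model connecting the two, and
(iv) FRET force-spectroscopy trace analysis for nucleosome unwrapping.
Because the raw inputs of such a study (atomistic trajectories, single-
molecule recordings) are far beyond desk scale, modflex ships generators
that emulate their statistical structure, so every estimator can be
validated end to end against known ground truth. This vignette documents
the models, the choices behind them, and what passing tests do and do not
demonstrate.

## The rigid base-pair description

A duplex conformation is reduced to one reference frame per base, fitted by
least-squares superposition (`fit_base_frame()`) of the standard ring-atom
geometry onto the observed ring atoms. Only ring atoms enter the fit —
C1′ and all exocyclic substituents are excluded — so frames of modified and
unmodified cytosines are directly comparable and parameter statistics
reflect base motion rather than substituent placement. The two frames of a
pair are combined into a base-pair frame and six intra-base-pair parameters
(shear, stretch, stagger in Å; buckle, propeller, opening in degrees), and
consecutive base-pair frames yield the six step parameters (shift, slide,
rise; tilt, roll, twist).

Both decompositions use the mid-frame convention: the relative rotation
between frames is factored as

$$ R_1^{\top} R_2 \;=\; R_z\!\left(\tfrac{\omega}{2}-\phi\right)\,
   R_y(\Gamma)\, R_z\!\left(\tfrac{\omega}{2}+\phi\right), $$

with twist $\omega$ about the mid-frame z axis and a bend $\Gamma$ about a
hinge at phase $\phi$ in the mid-frame xy plane, giving
$\mathrm{roll} = \Gamma\cos\phi$ and $\mathrm{tilt} = \Gamma\sin\phi$;
translations are the origin displacement expressed in the mid frame. The
mid-frame scheme (rather than a global-helical-axis scheme) was chosen
because it is the convention of the standard trajectory-analysis tools in
this field, it is exactly invertible, and it needs no axis fitting.
`rebuild_frames()` implements the exact inverse, which the synthetic
trajectory generator and the closure Monte Carlo both rely on.

Numerical choices: frames must be orthonormal within $10^{-9}$; the
rebuild–extract round trip is tested to $10^{-8}$ (degrees/Å) and in
practice agrees to $\sim 10^{-12}$; extraction is cross-checked against an
independent numerical-minimization oracle to $10^{-6}$. The degenerate
$\Gamma = 180^\circ$ bend (twist undefined) raises an error rather than
returning an arbitrary branch; twist is reported in $(-180, 180]$ with the
compensating sign flip of $\Gamma$ applied so the factorization stays
exact at the branch cut. Frame fitting requires at least three matched
ring atoms and rejects collinear sets (second singular value below
$10^{-8}$ of the first).

## The synthetic conformational ensemble

`generate_parameter_ensemble()` emulates the statistical structure of a
long room-temperature trajectory of a B-DNA duplex: every
(position, parameter) series is Gaussian, fluctuating about B-DNA means
(twist 36°, rise 3.38 Å, all other means zero) with baseline spreads of
4.5–5° for angles and 0.25–0.5 Å for translations. These baselines are
calibration constants typical of B-DNA simulations, exposed in
`default_baseline()`, not fitted values.

Modifications perturb the moments locally: each fully modified CpG step
contributes a shift of mean and of s.d. at the step centre, tapered by a
neighbour kernel (default: linear decay to zero at ±3 bp, so up to six
neighbouring base pairs are affected). The roll mean shifts at the CpG
centre are +5, +2, −1 and +1° for 5fC, 5hmC, 5caC and 5mC. The s.d.
effects follow the flexibility ordering
5fC > 5hmC > 5caC > unmodified > 5mC for ten of the twelve parameters,
with tilt and shift slightly damped by every modification (unmodified
largest); their magnitudes (`default_modification_effects()`) are a
synthetic calibration chosen once to realize that ordering at a realistic
fraction of the baseline spread, and are not measured values.

Distances from a CpG step centre are binned as follows: the centre sits
midway between the step's two base pairs, so step parameters take integer
offsets from the central step while base-pair parameters map their
half-integer offsets toward zero — the two central pairs share the d = 0
bin. This convention is applied identically in the generator and in
`delta_profile()`, and is recorded in output headers.

Frames are independent across time by default; the optional AR(1) mode
(`ar1_tau`, in ps) exists to give block averaging something real to
estimate. The default ensemble size is 52,083 frames — 250 ns at the
4.8-ps frame interval; tests and the bundled analyses use 1,000–6,000
frames (4.8–28.8 ns equivalent) with proportionally shorter blocks, sizes
chosen so the whole suite runs on a single desktop core while every
statistical bound retains its power. Negative effect-adjusted s.d. values
are floored at $10^{-6}$ native units with a warning.

`realize_coordinates()` maps an ensemble to 3-D ring-atom coordinates
(frames chained from step parameters, pairs split via intra-base-pair
parameters, standard geometries placed through each base frame) and
`extract_parameters()` is its exact inverse, so generation, realization,
file I/O and extraction can be validated as a closed loop. What passing
these tests shows: the estimators recover exactly the statistical
structure they assume. What they cannot show: real trajectories have
autocorrelation, anharmonicity, sequence-dependent baselines and
correlated parameters, none of which the generator emulates (beyond the
optional AR(1) mode); agreement on synthetic data is a necessary, not a
sufficient, condition for correctness on molecular-dynamics output.

## Fluctuation statistics and ranking

The "Gaussian fit" of a parameter series is its sample mean and s.d. —
the maximum-likelihood Gaussian fit, bin-free and unbiased; histogram
fitting is reserved for the FRET module where binned counts are the
natural data. Standard errors treat fixed-length block averages as
independent measurements (default block 20 ns; `gaussian_summary()`
refuses series shorter than two complete blocks rather than silently
shrinking them, and discards the incomplete trailing block). Errors of
differences propagate in quadrature; profile values pool the four CpG
steps of the construct; window averages pool ±1 bp around the centre.
No multiplicity correction is applied to the descriptive profiles.

`rank_modifications()` orders conditions by point estimate and renders an
adjacent pair with "≳" when its difference is below `tie_threshold`
(default 1.0) times the propagated standard error of the difference.
Note an intrinsic statistical tension: a pair rendered "≳" has a
difference within one standard error, which is exactly the regime in
which its *order* is not reproducible across replicates. Stochastic
replicate tests therefore assert recovery of the generative ordering,
while the rendering rule itself is tested deterministically.

## Cyclization kinetics

Looping is a two-state Markov process per molecule with rates
$k_\mathrm{loop}$ and $k_\mathrm{unloop}$; starting all-unlooped (a salt
jump), the expected looped fraction is
$f(t) = f_\mathrm{eq}\,(1 - e^{-t/\tau})$ with
$f_\mathrm{eq} = k_\mathrm{loop}/(k_\mathrm{loop}+k_\mathrm{unloop})$ and
$\tau = 1/(k_\mathrm{loop}+k_\mathrm{unloop})$. The apparent looping time
$\tau$ is the flexibility readout. The default sampling grid is dense
early and log-spaced, as in a salt-jump measurement; molecules are
independent and photobleaching-free by default (a dropout rate exists for
stress-testing and defaults to zero).

`fit_looping()` fits the exponential by unweighted least squares with the
plateau floating (bounded to [0, 1]); a fixed-plateau mode and a
binomially weighted mode are provided. Standard errors deserve a note:
a time course tracks the *same* molecules across time points, so its
residuals are strongly correlated and asymptotic regression errors
understate the uncertainty several-fold. When per-molecule trajectories
are available the package therefore reports molecule-level bootstrap
errors (resample molecules, recompute the fraction curve, refit; 200
resamples by default), which are valid under exactly this correlation
structure; for bare time-course tables it falls back to the asymptotic
errors and says so in the fit object.

## Loop-closure propensity

The Monte Carlo estimator draws all step parameters independently
Gaussian, rebuilds the 90-step chain, and counts a conformation closed
when the end origin is within a capture radius $r_c$ of the start, the
terminal z axes are within $\theta_c$, and (optionally) the summed twist
is within $\phi_c$ of a full number of turns. Intra-base-pair parameters
are excluded: the chain is the rigid base-pair abstraction. Propensities
carry exact Clopper–Pearson intervals and are reproducible under a seed;
the compiled sampler is pinned draw-for-draw to a plain-R reference in
the tests, and its unbiasedness is checked against exhaustive enumeration
on a discretized three-step toy chain.

Closure of a 90-step chain at near-physical stiffness is a genuinely rare
event. At bend (roll and tilt) s.d. values of 4–6° per step, the closure
probability under capture criteria of $r_c = 50$ Å and
$\theta_c = 60^\circ$ lies far below $10^{-6}$ — a coherent ~3.2°-per-step
mean bend is required, with a Gaussian cost of roughly
$\exp\{-(3.2/\sigma)^2 \cdot 90/4\}$ — and only becomes countable at
desk-scale sample sizes around 8° or under more generous capture. The
bundled comparison analysis therefore uses $r_c = 220$ Å,
$\theta_c = 120^\circ$ and $2\times10^5$ samples per condition, where all
five conditions yield hundreds of closures and cleanly ordered ratios.
Results are comparative propensities, never absolute J-factors; no
importance sampling or half-chain convolution is attempted in this
version, which is the main documented extension point.

## Force-spectroscopy traces

FRET efficiency is the ratiometric
$E = I_A/(I_A + \gamma I_D)$ with $\gamma = 1$ by default (no detection
correction is assumed). Histogram peaks are Gaussian fits to binned
counts, reported with the standard error of the fitted mean.

Synthetic stretching traces realize the three observed unwrapping
behaviours: a stable high-FRET plateau with a sigmoidal drop at ~15 pN;
the same with an additional linear pre-drop decline (0.02 FRET/pN by
default); and a drop already at ~5 pN. Per-point Gaussian noise defaults
to 0.05. The classifier locates the largest FRET decrease over a sliding
±1.5 pN force window; a drop below the 8-pN boundary (midway between the
two landmark forces) is the low-force class, otherwise the pre-drop
segment's fitted slope (threshold −0.01 FRET/pN) separates the gradual
from the stable class. The source observations do not define a
classification rule, so this procedure is this package's
operationalization, with every threshold exposed as an argument; it is
invariant to constant FRET offsets, flags flat traces as unclassifiable
instead of guessing, and only the stretch segment is analysed. Trace
averages pool per-trace bin means and flag (never drop) bins covered by
fewer than two traces. Percentages are rounded half away from zero, with
a whole-percent display option.

## Problem sizes and determinism

All stochastic components take explicit seeds, and every simulation in
the tests and bundled analyses is seeded. Sizes used: 5,000-frame
ensembles (2.4-ns blocks) for the end-to-end recovery checks; 100
replicates of 3,000-frame, roll-only suites for ordering recovery
(coordinate realization is an exact deterministic pass-through, verified
separately, so replicating it a hundred times would add runtime and no
information); 500 molecules per looping time course over 100 seeds; $10^6$
Monte Carlo samples per closure condition; 300 traces per classification
batch. Statistical assertions over many positions use family-wise
(Bonferroni-style) z bounds so that the suite's pass/fail behaviour is
calibrated as a whole.

## Known limitations

* The generator samples parameters independently across positions and
  parameters; real DNA fluctuations are correlated along the helix and
  between parameters (e.g. twist–roll coupling).
* Modification effects enter as additive Gaussian moment shifts; real
  effects need not be Gaussian-preserving.
* The closure model has no excluded volume, electrostatics or
  twist–bend coupling, and its capture criteria are tunable conventions.
* The trace classifier is a heuristic matched to the simulated trace
  families; traces with multiple comparable drops resolve to the largest
  one only.
* Standard base geometries are embedded constants (v1); swapping in a
  different reference geometry changes absolute frames but not round-trip
  consistency.
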