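---
title: "Modelling mismatch-elimination strand displacement with tmsd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mismatch-elimination strand displacement with tmsd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsd)
```

## The system and the question

In toehold-mediated strand displacement (TMSD) an invading strand `I`
nucleates at a short single-stranded toehold on a target `T` and then
replaces the incumbent strand `O` by branch migration. When the initial
duplex `O.T` carries an internal base-pair mismatch that the invader
corrects, the elimination contributes several kcal/mol of extra driving
free energy to the reaction. The interesting design fact is that the
*kinetic* consequence of that free energy depends almost entirely on
*where* the mismatch sits: eliminated early (but not immediately) during
branch migration it accelerates displacement by orders of magnitude, while
eliminated late it leaves the forward rate nearly untouched — a *hidden*
thermodynamic drive, ideal for catalytic circuits that must resist leak
reactions.

`tmsd` implements the full modelling chain for this motif:

1. nearest-neighbour (NN) duplex thermodynamics with internal-mismatch
   parameters and duplex-end fraying (`nn_params()`,
   `duplex_free_energy()`, `reaction_delta_g()`,
   `displacement_profile()`);
2. a discrete-state Markov-chain landscape of toehold binding and branch
   migration with exact absorption solves (`build_chain()`,
   `splitting_probability_exact()`, `conditional_probabilities()`,
   `relative_rate()`, `mean_first_passage_time()`);
3. stochastic counterparts — kinetic Monte Carlo and forward flux
   sampling — validated against the exact solves (`kmc_splitting()`,
   `run_ffs()`);
4. mass-action ODE models of the three experimental circuits (rate assay,
   catalytic toehold exchange, two-toehold pulse generator) with trace
   normalization and least-squares fitting (`build_*_model()`,
   `simulate_network()`, `normalize_trace()`, `fit_rate_constant()`);
5. a synthetic spectrofluorimeter-trace generator and the
   mismatch-position sequence construction, so every stage is testable
   without laboratory data (`generate_trace()`,
   `generate_mismatch_series()`, `trace_fixture_suite()`).

## Thermodynamic layer

Duplex free energies are sums of dinucleotide stack terms, per-end
initiation terms and a salt correction. The Watson-Crick stacks are the
unified oligonucleotide parameters (SantaLucia 1998); internal single
mismatches use the published mismatch tables (Allawi & SantaLucia 1997-98;
Peyret et al. 1999). All entries are stored as (dH, dS), so free energies
at the working temperature (25 °C by default, the fluorimeter set point)
are reconstructed as `dH - T*dS` rather than being pinned to the 37 °C
tabulation. The 50 mM Na+ / 10 mM Mg2+ assay buffer enters through a
monovalent-equivalent entropy correction
(`[Na+]eq = [Na+] + 120*sqrt([Mg2+ mM]) mM`, applied as
`0.368 * (n_bp - 1) * ln [Na+]eq` cal/(mol K)); the correction is a
configurable model choice, since no particular correction is prescribed
for the quoted mismatch free-energy estimates. It cancels in every
mismatch-vs-reference difference the package reports.

With the default C.C mismatch motif (target `5'-TCT-3'` opposite an
incumbent C) the two mismatch-containing stacks replace two Watson-Crick
stacks, and the reaction free-energy difference between a
mismatch-carrying system and its mismatch-free reference is −5.64
kcal/mol at 25 °C — the "three to four extra base pairs" scale of hidden
drive, and C.C is indeed the most destabilising of the twelve mismatch
pairings under these tables.

### Free-energy profiles and fraying

`displacement_profile()` assigns macrostates by the number `n` of
invader-target base pairs (toehold pairs included; `G(1) = 0`). Each
macrostate is a small partition sum over microstates with `f = 0..f_max`
frayed `O.T` base pairs immediately ahead of the branch point. Microstate
energies are NN duplex energies of the intact `I.T` and `O.T` segments;
the mismatch enters as a lumped destabilisation `ddG_mm` that is charged
only while the mismatch is enclosed in intact `O.T` (it is dropped once
the branch point passes it, once it is inside the frayed window, or when
it sits at an open duplex end). This lumped accounting makes the
mismatch-free and mismatch profiles exactly superimposable up to the
enclosure coordinate when fraying is off, which is also how the package
tests pin down where the drop begins.

Two profile parameters describe branch migration itself, in the tradition
of intuitive-energy-landscape models of displacement:

* `dg_plateau` (kB*T) — the penalty for holding the three-stranded
  junction; raises every branch-migration macrostate.
* `dg_sawtooth` (kB*T) — the per-step barrier between branch-migration
  macrostates; it never shifts macrostate free energies, only the hopping
  rate (`k_hop = k_bm * exp(-dg_sawtooth)`).

**Fraying depth.** The default is `f_max = 1`: only the terminal `O.T`
base pair ahead of the branch point frays. Opening that single pair is
what makes a position-2 mismatch cheap to accommodate — the duplex trades
the full enclosure cost for the loss of one terminal stack — and it is
the mechanism visible in coarse-grained simulations of this motif. We
deliberately do not use a deeper fray window: because each additional
frayed pair only costs one stack term in a nearest-neighbour description,
a window of depth `f >= 2` lets the relief reach *through* mismatches at
positions up to `f + 1`, which flattens (and for `f_max = 3` inverts) the
position-3 maximum of the rate-vs-position curve. Single-pair fraying
reproduces both the reduced position-2 thermodynamic bias and the
non-monotonic kinetics; `f_max` remains a function argument for
sensitivity analysis.

## Kinetic layer: the landscape chain

`build_chain()` converts a profile into an absorbing Markov chain

```
DETACHED <- TOEHOLD_BOUND <-> BRANCH(h+1) <-> ... <-> BRANCH(n_max) -> DISPLACED
```

with hop rates `k_hop * exp(-(G_j - G_i)/2)`, which satisfies detailed
balance on the profile exactly (a constructed invariant, tested to
1e-12). Toehold binding is a single bimolecular step with rate constant
`k_toehold`; detachment follows from detailed balance at the 1 M standard
state, `k_off = k_toehold * exp(dG_toehold / kBT)`, with the toehold
attachment free energy taken from the toehold subduplex NN energy.
Per-base-pair toehold zipping is deliberately not resolved: the
second-order decomposition `k = k_toehold * p(disp | toehold)` needs only
the bound state and its lifetime, and the toehold is common to all
systems compared.

Splitting probabilities, the conditional decomposition
`p(disp|toehold) = p(bp x reached | toehold) * p(disp | bp x reached)`
and first-order-limit mean first-passage times are all exact linear
solves on this chain; because the chain is a linear ladder the
decomposition product is independent of the reference position `x` to
solver precision. Relative rates between systems sharing a toehold are
ratios of splitting probabilities, from which `k_toehold` cancels.

### Parameter values and calibration

| parameter | default | units | origin |
|---|---|---|---|
| `k_toehold` | 3e6 | 1/(M s) | literature-typical toehold binding; cancels from all ratios |
| `k_bm` | 1e7 | 1/s | bare branch-migration attempt frequency |
| `dg_sawtooth` | 7.3 | kB*T | literature-scale branch-migration barrier |
| `dg_plateau` | 2.96 | kB*T | calibrated (see below) |
| `f_max` | 1 | bp | single terminal-pair fraying (above) |
| temperature | 25 | °C | fluorimeter set point; configurable |

Only one number was calibrated: with the other defaults fixed,
`dg_plateau` was solved (once) so that the mismatch-free 4-nt-toehold
reference system reproduces the measured mismatch-free rate constant
`k0 = 2.6e3 M^-1 s^-1`; the calibrated value, 2.96 kB*T, sits squarely in
the range expected for the junction penalty. Nothing else was tuned: the
non-monotonic rate-vs-position curve (slow at position 2, maximal at 3,
decaying back to the mismatch-free rate by position ~13), the saturation
of all ratios to 1 for strongly binding toeholds, and the
first-order-limit speed-ups all follow from the thermodynamics.

The model's maximal acceleration (factor ~3.5e2 at position 3 with the
default stand-in sequences) is larger than the experimentally fitted
factor ~69 and the coarse-grained simulation factor ~23; absolute
acceleration factors are sensitive to the exact mismatch context and to
toehold strength, and no published factor is enforced — only the shape of
the position dependence is asserted by the tests.

### A known limitation of the first-order limit

In the instant-rebinding (first-order) limit the chain predicts
mean-first-passage-time reductions of up to a factor ~3 for early
mismatches, with the optimum at positions 4-5 for the default sequences.
The specific ordering "position 2 is slower than position 3" is *not*
robust here: position 2 and position 3 speed-ups differ by under 10% and
their order can flip with sequence roughness (position 3 of the default
series sits next to a local landscape barrier). The tests therefore
assert the robust statement — the optimal speed-up is early but not at
the earliest position — rather than the specific 2-vs-3 ordering.

## Stochastic estimators

`kmc_splitting()` samples the embedded jump chain (holding times do not
affect splitting probabilities) with a single seeded stream over a
vectorised simulation, so results are bit-reproducible.
`kmc_trajectory()` is a full Gillespie simulation with sojourn times,
used for stationary-occupancy checks against `exp(-G)` on closed chains.

`run_ffs()` implements direct forward flux sampling on the same
dynamics: interfaces are thresholds on the invader base-pair coordinate
(default: every 2 coordinate units from `h+1` to `n_max`, plus the
committed coordinate), trials launch from configurations stored at the
previous interface, and the displacement probability is the product of
per-interface crossing probabilities with propagated binomial errors.
Because the chain is memoryless, storing the state label at an interface
restarts the dynamics exactly in distribution — a simplification relative
to rare-event sampling of a molecular model, where stored configurations
carry microscopic detail. An interface with zero successful crossings
aborts with an "interface starved" error naming the interface. Both
estimators are validated against the exact absorption solves to within
three standard errors in the test-suite.

## Reaction-kinetics layer

The three experimental circuits are ideal second-order mass-action
networks (`deSolve::lsoda`, tight tolerances; strand-conservation totals
are checked to 1e-9 relative):

* **Rate assay** — `I + O.T -> I.T + O` with a reporter for released
  `O`. The reporter is treated as an instantaneous sink by default (its
  toehold is 7 nt, making it far faster than the assayed reaction); an
  explicit `O + Rep -> F + W` step with `k_rep` is available and agrees
  with the instantaneous limit within 2% when `k_rep` dominates. Default
  concentrations follow the cuvette mixing arithmetic: 2.4 µL of 10 µM
  substrate and invader into 1.92 mL gives 12.5 nM each; 2.4 µL of 20 µM
  reporter gives 25 nM. Injection dilution (~0.13% per addition) is
  ignored.
* **Catalytic toehold exchange** — `A + B.D <-> B + A.D`,
  `C + A.D <-> A + C.D`, the direct leak `C + B.D <-> B + C.D`, and a
  reporter sink for `B`; presets 40 nM `B.D`, 200 nM `C`, 5 nM `A`,
  250 nM reporter. The reverse leak constant defaults to thermodynamic
  cycle closure `K_leak = K1*K2`, so catalysis changes only the route to
  equilibrium. Raising `k2/k2r` emulates mismatch elimination in `C.D`
  (hidden drive: faster catalysed conversion at a fixed leak); raising
  `k_leak` emulates the extended fuel strand with extra toehold base
  pairs (strong leak).
* **Pulse generator** — two invaders attack `O.T` from opposite
  toeholds (`I3` kinetically favoured by an early mismatch, ~20-fold in
  the forward constant by default), plus the toehold-exchange relaxation
  `I5 + I3.T <-> I5.T + I3`; concentrations `[I5]:[I3]:[O.T] = 4:2:1`.
  Reverse constants left unspecified are filled in from the equilibrium
  constants with cycle closure; a supplied inconsistent set triggers a
  warning carrying the cycle residual. The Cy3/Cy5 channels map to
  `[I3.T]`/`[I5.T]`, and the inferred output curve is their sum.

A note on catalysis neutrality: with 5 nM catalyst against 40 nM
substrate, the literal equilibrium species concentrations with and
without catalyst differ by ~2%, because the intermediate `A.D`
stoichiometrically sequesters part of `D`. What catalysis cannot change
is the *position* of the exchange equilibrium: the equilibrium yield
`[C.D]/([B.D]+[C.D])` agrees to ~4e-5 and the reaction quotient equals
`K_leak` in both cases, and that is what the acceptance test asserts.

`fit_rate_constant()` fits free rate constants by trust-region
Levenberg-Marquardt least squares in log10-parameter space (positivity
for free), with five log-spaced starts per free constant and standard
errors from the Jacobian at the optimum; fits are deterministic for
identical inputs and non-convergence is flagged on the result rather
than thrown. Traces are normalized, when needed, by the fractional
fluorescence recovery `(F - Fmin)/(Fmax - Fmin)` over user-chosen
baseline and maximum windows, which is invariant to affine detector
maps.

## Synthetic data

`generate_trace()` emulates the spectrofluorimeter acquisition: the ODE
system is solved piecewise across a schedule of reagent injections
(baseline → substrate → invader), sampled every 60 s (the measurement
interval), passed through an affine gain/baseline map, optionally
bleached exponentially, and given seeded additive Gaussian noise. The
default noise level in the fixture suite is 0-2% of full scale; no noise
magnitude is reported for the real instrument, so this is a package
choice. The generator does not emulate instrument drift, lamp flicker,
inner-filter effects or cross-talk — passing tests therefore demonstrate
correctness of the modelling chain, not robustness to every artefact of
real fluorimetry.

`generate_mismatch_series()` reproduces the sequence-design rules of the
mismatch-position series: for positions 2-13 the 3-bp mismatch motif
slides along the domain by moving the base pair after the motif to just
before it, so all targets are identical once the motif window is deleted
and base content is conserved (both tested); positions 15 and 17 fall in
the region that doubles as the reporter toehold, where the output strand
may not change, so they are built by a single point mutation of a target
G inside the motif environment. The experimental motif and flanking
sequences live in supplementary material that is not shipped here; the
package defaults are a documented synthetic stand-in with the same
architecture (4-nt toehold, 20-bp domain, C.C mismatch in a conserved
`TCT` motif, G at domain positions 15 and 17 in the correct
environment), and every motif-dependent computation takes the sequences
as inputs so the real ones can be dropped in.

## Numerical choices and problem sizes

* Exact probabilities come from dense LAPACK solves on chains of ~22
  states; the decomposition identity holds to well below the 1e-10
  assertion.
* Partition sums over fraying use log-sum-exp.
* ODE integration uses `lsoda` with `rtol = 1e-10`, `atol = 1e-16`
  (concentrations are 1e-9-1e-7 M).
* The test-suite uses 1e4 KMC trajectories and 1e3 FFS trials per
  interface for the sampling-vs-exact comparisons, 50 replicates for the
  noise-bias check, and 500-min/60-s traces for parameter recovery; the
  whole suite runs in about a minute on one core.
* Degenerate inputs are rejected eagerly: domains shorter than 2 bp,
  mismatch positions outside the domain, terminal mismatches in
  `duplex_free_energy()` (position 1/N mismatches are scored with the
  terminal pair open — an extrapolation, as the study never places them
  there), non-increasing trace times, starved FFS interfaces, and
  configs with unknown keys.

## Limitations

* The landscape model is a surrogate at macrostate resolution: no
  nucleotide-level structure, no sequential toehold zipping, no
  three-way intermediates beyond the single branch point, and no second
  toehold at landscape level (the exchange circuits are modelled at the
  network level instead).
* Absolute rate constants inherit the uncertainty of `k_toehold` and the
  landscape calibration; ratios are the trustworthy output.
* NN parameters are equilibrium duplex parameters; using them for
  intermediate microstates (and coaxial junction stacking) is the
  standard but uncontrolled approximation of landscape models.
* The position-2 vs position-3 ordering of *first-order-limit* passage
  times is sequence-sensitive (see above); the second-order behaviour,
  which is what the experiments measure, is robust.
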