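# tmsd

Kinetics and thermodynamics of mismatch-elimination DNA strand
displacement.

## The problem

Toehold-mediated strand displacement (TMSD) is the workhorse reaction of
dynamic DNA nanotechnology: an invader strand *I* binds a short
single-stranded toehold on a target *T* and replaces the incumbent *O* by
branch migration. Catalytic DNA circuits need a thermodynamic drive
toward products, but the usual source of drive — extra base pairs in the
product — also accelerates uncatalysed *leak* reactions. Placing an
internal base-pair mismatch in the substrate duplex `O·T` that the
invader eliminates provides several kcal/mol of drive whose kinetic
footprint depends almost entirely on the mismatch *position*: eliminated
early (but not immediately) it speeds displacement by orders of
magnitude; eliminated late it is a *hidden* drive that leaves forward
and leak kinetics nearly untouched.

`tmsd` is an R package for designing and analysing this motif. It is
aimed at people building strand-displacement circuits (rate assays,
catalytic toehold-exchange motifs, pulse generators) and at modellers who
want a transparent, testable surrogate for coarse-grained simulations of
displacement.

## The models

**Thermodynamics.** Duplex free energies are nearest-neighbour sums
(unified Watson–Crick parameters plus the published internal-mismatch
tables, as ΔH/ΔS so any temperature is supported, with a
monovalent-equivalent salt correction). `displacement_profile()` builds
the free-energy profile *G(n)* over macrostates labelled by the number
*n* of invader–target base pairs, as a partition sum over duplex-end
fraying microstates; a mismatch enters as a lumped destabilisation while
it is enclosed in `O·T`.

**Kinetics.** `build_chain()` turns a profile into an absorbing Markov
chain (detached ← toehold-bound ↔ branch states → displaced) obeying
detailed balance. In the second-order regime the rate constant
factorises as

    k = k_toehold · p(disp | toehold)
    p(disp | toehold) = p(bp x reached | toehold) · p(disp | bp x reached)

and all three probabilities are exact linear absorption solves (the
product is independent of the reference position *x*). Relative rates
between systems sharing a toehold are ratios of splitting probabilities.
Kinetic Monte Carlo (`kmc_splitting()`) and forward flux sampling
(`run_ffs()`) provide stochastic estimators validated against the exact
solves. Mean first-passage times cover the first-order
(high-concentration) limit.

**Circuits.** Mass-action ODE models of the rate assay, the catalytic
toehold-exchange motif (with leak channel and reporter sink) and the
two-toehold pulse generator, plus fractional-fluorescence normalization
`(F − Fmin)/(Fmax − Fmin)` and Levenberg–Marquardt fitting of rate
constants from traces (`fit_rate_constant()`, with broom-style `tidy()`
and `glance()` methods). A synthetic spectrofluorimeter-trace generator
(60-s sampling, injection protocol, affine gain, seeded Gaussian noise)
and the mismatch-position sequence constructions make the whole pipeline
testable without laboratory data.

See `vignettes/tmsd-methods.Rmd` for the model assumptions, parameter
defaults and their calibration, and known limitations.

## Worked example

```r
library(tmsd)

ref  <- design_system(NULL) # mismatch-free reference (4-nt toehold, 20-bp domain)
sys3 <- design_system(3)    # C·C mismatch at domain position 3

# hidden drive contributed by the mismatch
reaction_delta_g(sys3) - reaction_delta_g(ref)
#> [1] -5.64 (kcal/mol)

# relative displacement rate from the landscape model
relative_rate(sys3, ref)
#>          k       k0    ratio       regime
#> 1 907955.7 2599.127 349.3311 second-order

# the probability decomposition: the product is independent of x
conditional_probabilities(tmsd:::.system_chain(sys3, landscape_params()),
                          c(3, 10, 17))
#>    x   p_reach p_disp_given_reach   product
#> 1  3 0.3097045          0.9772281 0.3026519
#> 2 10 0.3068914          0.9861856 0.3026519
#> 3 17 0.3032366          0.9980718 0.3026519

# recover a rate constant from a synthetic fluorescence trace
net   <- build_rate_assay_model(2.6e3)        # 12.5 nM substrate + invader
trace <- generate_trace(net, t_end = 500 * 60, noise = noise_model())
trace$signal <- trace$noiseless
fit <- fit_rate_constant(trace, build_rate_assay_model,
                         free_parameters = c(k_disp = 1e4))
tidy(fit)
#>   term   estimate std.error
#> 1 k_disp    2600.  1.57e-13
```

Reading the numbers: the position-3 mismatch adds −5.64 kcal/mol of
driving free energy and accelerates displacement ~350-fold over the
mismatch-free reference (whose absolute rate constant, 2.6 × 10³
M⁻¹s⁻¹, is the calibration anchor of the landscape defaults). The
decomposition shows why: a mismatch at position 3 is reached with
probability ~0.31 per toehold-binding event and commits the reaction
once reached. The fitter recovers the generating rate constant of a
noiseless synthetic rate-assay trace essentially exactly.

`autoplot()` methods exist for profiles, traces and decompositions, and
`plot_relative_rates()` draws rate-vs-position curves.

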