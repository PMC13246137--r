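# neoscf

Multicomponent nuclear-electronic orbital Hartree-Fock (NEO-HF) in R, for
studying how the *representation of the quantum nuclei* shapes SCF
convergence.

## The problem

In the NEO framework selected nuclei — in practice protons — are treated
quantum mechanically alongside the electrons, so zero-point motion and
proton delocalization enter the wavefunction directly instead of through a
Born-Oppenheimer correction. The price is a coupled two-subsystem SCF that
is notoriously harder to converge than ordinary Hartree-Fock. The quantum
protons can be described by a nuclear **Slater determinant** (SD: one Fock
operator shared by all protons, including self-Coulomb/self-exchange terms
that cancel in the energy but not in the operator) or as a **Hartree
product** of distinguishable protons (HP: one Fock operator per proton,
no self terms, no proton-proton exchange). Because inter-proton exchange for
localized protons is many orders of magnitude below any convergence
threshold, both representations give the same energy

```
f^p(SD)  = h^p + sum_{j'} (J_{j'} - K_{j'}) - 2 sum_i J_i^e
f^p_(i') = h^p + sum_{j' != i'} J_{j'}      - 2 sum_i J_i^e     (HP)
```

— but they do not optimize equally well. This package exists to make that
comparison quantitative on desk-scale molecules: it implements SD, HP, and
HP\* (HP with the self terms added back, which isolates them as the cause of
slow convergence), plus three simultaneous optimizers over the stacked
electronic+nuclear orbital rotations — coupled **DIIS** (one shared
extrapolation coefficient set for both subsystems), a **GDM-style**
preconditioned limited-memory BFGS with line search, and **TRAH**
(trust-radius augmented Hessian: Davidson on the level-shifted augmented
eigenproblem using exact coupled Hessian-vector products).

Everything below the solvers is a complete Gaussian integral engine
(McMurchie-Davidson, Cartesian shells up to d, mass-scaled kinetic,
particle-agnostic 1/r12 kernel) written in C++ via Rcpp, with core and
SAD-style initial guesses for both particle types and built-in molecular
fixtures (H2, water, hydronium, acetylene, water dimer, Zundel and Eigen
cations) with all protons quantum.

Who is it for: method developers and students who want a transparent,
fully-tested multicomponent SCF they can read end to end, instrument per
iteration, and extend.

## Worked example

```r
library(neoscf)

r_sd <- neo_run("h3o+", config = neo_config("SD",  "diis"), quiet = TRUE)
r_hp <- neo_run("h3o+", config = neo_config("HP",  "diis"), quiet = TRUE)
r_hps <- neo_run("h3o+", config = neo_config("HPstar", "diis"), quiet = TRUE)
r_sd; r_hp; r_hps
#> <neo_convergence_report: SD/diis, converged in 29 iterations, E = -75.2345770096>
#> <neo_convergence_report: HP/diis, converged in 10 iterations, E = -75.2345770096>
#> <neo_convergence_report: HPstar/diis, converged in 38 iterations, E = -75.2345770096>
```

All three nuclear representations reach the same total energy (hydronium,
minimal electronic basis, 4s3p even-tempered protonic basis, thresholds
1e-8): the proton self-interaction terms cancel exactly in the energy. But
the Hartree product converges in a third of the iterations, and HP\* —
which differs from HP *only* by those self terms — is back to SD-like
counts: the self terms, not proton indistinguishability, are what slows the
optimization. Each proton's HP Fock equation is linear in its orbital given
the mean field, so the nuclear subsystem needs no inner iteration.

The energy decomposition and per-iteration trace are part of every report:

```r
r_hp$energy_report
#> NEO-HF energy decomposition (HP representation)
#>   kinetic_e                 73.778819355374
#>   external_e              -184.141324572268
#>   coulomb_ee                46.641193035603
#>   exchange_ee               -8.986938110836
#>   kinetic_p                  0.050502656493
#>   external_p                12.492376192141
#>   coulomb_pp                 0.940618222215
#>   exchange_pp                0.000000000000
#>   coulomb_ep               -16.009823788346
#>   classical_repulsion       0.000000000000
#>   total                   -75.234577009625 Hartree
head(trace_plot_data(list(SD = r_sd, HP = r_hp)))   # log10(E_i - E0) table
```

Robustness sweeps reproduce the guess-sensitivity experiment:

```r
sw <- neo_sweep(c("h2", "water", "h3o+", "acetylene", "water_dimer"),
                representations = c("SD", "HP"), solvers = "diis",
                guesses = list(c("core", "core")))
table(sw$cells$representation, sw$cells$classification)
#>      converged converged_higher_energy failed
#>   HP         5                       0      0
#>   SD         1                       2      2
```

With deliberately poor core,core guesses the Slater-determinant runs strand
on higher-energy solutions or fail outright; the Hartree product converges
to the lowest energy every time.

There is also a thin command-line interface over the same functions:

```sh
Rscript inst/cli/neoscf.R run --fixture h3o+ --repr HP --solver diis \
    --guess sad,sad --output report.json
Rscript inst/cli/neoscf.R fixtures
```

## Further reading

The methods vignette (`vignettes/neoscf-methods.Rmd`) documents the model,
the three representations and their energy bookkeeping, every solver's
internals and tunable constants, the guess constructions, what the fixtures
do and do not emulate, and the package's numerical-edge-case policies.
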