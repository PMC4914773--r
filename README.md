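# erknoise

Dissecting the origins of cell-to-cell variability in MEK-ERK signaling from
cross-sectional single-cell snapshots.

## The problem

Quantitative image cytometry measures total phosphorylated MEK (ppMEK) and
ERK (ppERK) in thousands of single cells every 2 minutes after growth-factor
stimulation — but in a *different* cohort of cells at every time point, so
no cell is ever tracked. Given such data, which source of noise explains the
observed heterogeneity?

* **Intrinsic noise**: stochastic reaction timing within each cell. Modeled
  by the chemical master equation of a distributive dual-phosphorylation
  MEK-ERK module (9 species, 14 mass-action reactions, 20 free parameters),
  simulated exactly with the Gillespie SSA and approximated by the linear
  noise approximation (LNA), which yields a Gaussian likelihood with means
  m_t(θ) and variances v_t(θ) from a system of moment ODEs.
* **Extrinsic noise**: per-cell parameter values θ_i drawn from independent
  log-normal population laws with means μ_θ and variances σ²_θ. Observable
  moments are propagated through the ODE model by the unscented transform
  (UT), giving a log-normal likelihood
  ∏_t ∏_i ψ(x*_{i,t}; m_t^x(μ_θ,σ²_θ), v_t^x(μ_θ,σ²_θ)) ·
  ψ(y*_{i,t}; m_t^y, v_t^y).

Posteriors and model evidences p(x*|M) come from a likelihood-tempered
sequential Monte Carlo sampler; models are ranked by the Bayes factor
BF = p(x*|M1)/p(x*|M2), with BF > 30 read as "very strong" evidence.
Downstream analyses: variance decomposition by parameter group
(upstream / initial conditions / reaction rates / driving parameters k1,
k10), posterior ranking of contributing parameters by population CV, the
λ(σ_k1, σ_k10, t) input-variability scan, and KDE mutual information between
ppMEK and ppERK (Gaussian kernels, bandwidth 1.06·σ·N^(−1/5)).

Everything runs end-to-end on synthetic snapshot data with a documented
ground truth; the study's own dataset and inferred values were never
deposited, so the fixtures are explicitly synthetic.

## Worked example

```r
library(erknoise)

model <- build_distributive_model()        # 9 species, 14 reactions, 20 parameters
fixture <- reference_hyperparameters("extrinsic")
snap <- generate_qic_dataset(model, fixture,
                             default_design(cells_per_time = 500), seed = 11)

center <- reference_parameters()
free <- c("k1", "k2", "k10", "M0", "Epp0")  # the five varying factors
fe <- fit_extrinsic(snap, model, center, free, n_particles = 256,
                    move_count = 5, seed = 4)
fi <- fit_intrinsic(snap, model, center, free, n_particles = 256,
                    move_count = 5, seed = 5)

fe$log_evidence            # 16876.52
fi$log_evidence            # -298890.5
bayes_factor(fe, fi)$label # "very strong"
round(posterior_quantiles(fe), 3)["mean_k1", ]
#  0.487 0.500 0.512      (generating value: 0.5)
```

The evidence gap (≈ 3.2·10⁵ nats for 500 cells × 26 time points) says the
snapshot heterogeneity cannot be explained by reaction stochasticity at any
system size: the extrinsic-noise model wins "very strong" support, and the
posterior 90% credible intervals recover the generating population means.
`rank_contributors(fe)` then flags exactly the five generative factors
(k1, k2, k10, M0, Epp0) as significant contributors, and

```r
mi_series(population_simulate(model, fixture$hyper, 3000, c(10, 20, 40), seed = 21))
```

shows the post-transient (t = 20, 40 min) mutual information between ppMEK
and ppERK dropping under full extrinsic noise relative to a population in
which only the driving inputs k1, k10 vary — heterogeneity inside the
module degrades information transfer even though it barely changes the
marginal variances. (At the response peak, t = 10, the comparison reverses
on this fixture because ppERK saturates; see the methods vignette.)

## Command line

`inst/cli/erknoise.R` exposes subcommands
`simulate | stats | mi | fit | evidence-compare | decompose | lambda-scan | run-all`,
e.g.

```sh
Rscript inst/cli/erknoise.R simulate --scenario extrinsic --cells 500 --seed 7 --out snap.csv
Rscript inst/cli/erknoise.R mi --data snap.csv --out mi.csv
```

## Layout

* `R/model.R` — mechanistic models, parameterization, ODE solutions
* `R/stochastic.R` — SSA and LNA engines
* `R/population.R` — log-normal populations, UT propagation, total variance
* `R/inference.R`, `R/smc.R`, `R/fits.R` — likelihoods, SMC, evidence
* `R/variability.R` — variance decomposition, contributor ranking, λ scans
* `R/information.R` — summary statistics and KDE mutual information
* `R/synthetic.R` — acquisition designs and synthetic ground truths
* `R/io.R`, `R/cli.R` — CSV/JSON I/O, pipeline, CLI
* `src/engines.cpp` — RK45, LNA, SSA, KDE kernels (RcppArmadillo)
* `vignettes/noise-dissection-methods.Rmd` — models, assumptions, numerical
  choices, limitations
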