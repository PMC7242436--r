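# mixehr

Multi-view Bayesian topic modelling of heterogeneous electronic health
record (EHR) data with informative (non-missing-at-random) lab results.

EHR data mix several discrete modalities — clinical-note words, ICD
diagnosis codes, prescriptions, procedures — plus lab tests whose results
are categorical and, crucially, often *absent for a reason*: whether a
test is ordered depends on the patient's (latent) disease state.
`mixehr` is for biostatisticians and clinical informaticians who want an
unsupervised, interpretable low-dimensional representation of such
records that uses all modalities jointly and treats lab missingness as
signal rather than noise.

## The model

Each patient `j` has a disease-topic mixture `θ_j ~ Dir(α)` over `K`
topics.  Topic `k` holds one multinomial `φ_k^(t) ~ Dir(β_t)` per data
type `t`, and tokens arise as `z ~ Mul(θ_j)`, `x ~ Mul(φ_z^(t))`.  For
every patient-lab pair a latent topic `h ~ Mul(θ_j)` concurrently drives
the observation indicator `r ~ Ber(ψ_{l,h})`, `ψ_{lk} ~ Beta(a_l, b_l)`,
and the result state `y ~ Mul(η_{l,h})`, `η_{lk} ~ Dir(ζ_l)` — so result
and missingness are conditionally independent given the topic, and
missingness is non-missing-at-random through `ψ`.

Inference is collapsed variational Bayes with a zero-order approximation
(CVB0): the Dirichlet/Beta parameters are integrated out and only
per-record topic-assignment distributions are maintained, updated in
compiled code, with empirical-Bayes digamma fixed-point updates for all
hyperparameters.  A stochastic variant (`fit_scvb()`) trains on
minibatches with natural-gradient interpolation of the global statistics
and constant memory.  On top of the fitted embedding the package provides
held-out predictive likelihood and cross-validated choice of `K`,
k-nearest-neighbour code prediction and lab-result imputation, and
topic-embedding comorbidity correlation networks with permutation
significance.  A generative simulator reproduces the full data-generating
process so everything is testable without clinical data.  Loop-literal
reference oracles (`oracle_*`) validate the fast path in the test suite.

## Worked example

```r
library(mixehr)

bm  <- simulate_benchmark("recovery", D = 500, seed = 21)
bm$corpus
#> <mixehr_corpus> 500 patients, 2 data type(s) [W = 60,40], 10 lab(s)
#>   12551 count records (40000 tokens), 2749 lab records, 2749 observed lab-patient pairs

fit <- fit_jcvb(bm$corpus, K = 3,
                jcvb_control(max_iter = 80, min_iter = 15), seed = 23)
fit
#> <mixehr_fit> K=3, 22 sweep(s), final loglik -98560.2

round(head(fit$estimates$theta, 3), 3)   # patient topic mixtures
#>       [,1]  [,2]  [,3]
#> [1,] 0.674 0.068 0.258
#> [2,] 0.533 0.032 0.435
#> [3,] 0.551 0.092 0.357

round(fit$estimates$psi[1:3, ], 3)       # P(lab observed | topic)
#>       [,1]  [,2]  [,3]
#> [1,] 0.804 0.390 0.441
#> [2,] 0.423 0.499 0.174
#> [3,] 0.720 0.711 0.421
```

Each `theta` row is a patient's disease mixture (rows sum to 1); each
`psi` row says how strongly a lab's *being ordered at all* depends on the
topic — the NMAR mechanism.  Fold-in of a new (or held-out) patient
against the frozen model reproduces the training mixture:

```r
th <- infer_patient_mixture(fit$estimates, patient_record(bm$corpus, 7))
round(th, 3)                        #> 0.410 0.171 0.418
round(fit$estimates$theta[7, ], 3)  #> 0.410 0.172 0.418
```

From here, `cross_validate_K()` picks `K` by held-out predictive
likelihood, `knn_neighbors()` + `predict_code()` score masked EHR codes
(k = 100, threshold 1/k), `impute_lab_result()` imputes a masked lab
result from the 25 nearest patients in topic space, and
`code_embedding()` + `permutation_significance()` build comorbidity
networks around a target code.  A thin command-line wrapper with
subcommands `simulate`, `train`, `infer`, `predict-code`, `impute-lab`,
`correlate`, `cv-k` and `selftest` is installed at
`system.file("exec", "mixehr", package = "mixehr")`.

See the methods vignette (`vignettes/mixehr-methods.Rmd`) for the model,
the update equations, the open design choices and the limitations of the
synthetic benchmarks.

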