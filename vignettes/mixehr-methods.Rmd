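---
title: "Multi-view EHR topic modelling with informative lab missingness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view EHR topic modelling with informative lab missingness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixehr)
```

## The model

`mixehr` models a patient's electronic health record as a mixture of `K`
latent *disease topics* shared across heterogeneous data types.  Patient
`j` carries a mixture `theta_j ~ Dirichlet(alpha)`.  Each topic `k`
prescribes, for every data type `t` (notes words, diagnosis codes,
prescriptions, ...), a multinomial distribution `phi_k^(t) ~
Dirichlet(beta_t)` over that type's vocabulary of `W[t]` features.  A
token is generated by drawing a topic `z ~ Multinomial(theta_j)` and then
a feature `x ~ Multinomial(phi_z^(t))` — multi-view latent Dirichlet
allocation.

Lab tests get a richer treatment because *whether a lab is taken at all is
informative*.  For every patient-lab pair `(l, j)` a latent topic
`h_lj ~ Multinomial(theta_j)` is drawn; conditioned on it the model
*concurrently* samples

* the observation indicator `r_lj ~ Bernoulli(psi_{l,h})`, with
  topic-dependent observation probability `psi_lk ~ Beta(a_l, b_l)`, and
* the result state `y_lj ~ Multinomial(eta_{l,h})`, with
  `eta_lk ~ Dirichlet(zeta_l)` over the lab's `V[l]` states.

Result and missingness are conditionally independent given the topic, so
missingness depends on the latent disease state but never directly on the
unseen value — a non-missing-at-random (NMAR) mechanism.  When `r = 0`
nothing is recorded, and the model treats the pair as carrying a latent
joint distribution over (topic, result).

All hyperparameters (`alpha`, `beta`, `zeta`, `a`, `b`) are unknown and
given Gamma hyper-priors (default shape 1, rate 1 — weakly informative).

## Collapsed variational inference

Conjugacy lets us integrate out `theta`, `phi`, `eta`, `psi` analytically,
leaving a marginal over the discrete assignments only, expressed through
Gamma-function ratios of smoothed counts (`oracle_collapsed_loglik()`
evaluates it literally).  Inference maintains, per record, an assignment
distribution: `gamma` for each distinct token record (identical tokens
share one distribution, weighted by their count — memory scales with
distinct records, not tokens), `lambda` for each observed lab record, and
a joint `K x V[l]` table `pi` for each unobserved pair.

Updates follow collapsed variational Bayes with a zero-order Taylor
approximation (CVB0): each record's new distribution is proportional to a
product of ratios of *expected* counts, with the record's own
count-weighted contribution excluded (and clipped at zero against
floating-point drift).  The three update rules are exposed one record at a
time as `update_gamma()`, `update_lambda()`, `update_pi()`; the compiled
sweep (`e_step()`) applies exactly the same arithmetic to every record in
a fixed deterministic order — patients ascending; within a patient,
tokens, then observed labs, then unobserved pairs.  The order is a
reproducibility choice, not a mathematical one.  All products are formed
in linear space: every factor is a ratio of smoothed counts, bounded well
away from overflow; only the likelihood monitor works in log space.

Exclusion statistics are maintained incrementally (subtract, update, add
back); a full `refresh_statistics()` pass after every sweep recomputes the
caches from scratch so drift cannot accumulate.  The test suite pins the
compiled sweep against a pure-R, loop-literal reference implementation
(`oracle_e_step()`) to 1e-10 on a frozen 6-patient fixture, and the
per-record rules against `oracle_update()` at every fixture record.

Two readings of the collapsed likelihood are genuinely open and are kept
configurable:

* **Patient mixture mass.** The collapsed patient term couples token mass
  `n_jk` and lab-topic mass `m_jk`; the predictive-likelihood estimator
  for `theta` can be read as using token mass only.  `estimate_parameters()`
  includes the lab mass by default (`include_lab_mass = FALSE` gives the
  token-only reading); the coupling in the collapsed joint is our reason
  for the default.
* **Lab term of the predictive likelihood.** The generative process
  implies the product `psi_lk * eta_lkv` for an observed result; an
  additive combination `psi_lk + eta_lkv` is also available
  (`lab_mode = "sum"`) since either convention appears in applied use.
  The product is the default because it is the probability the generative
  model actually assigns.

### Empirical-Bayes hyperparameters

Every 5 sweeps (configurable) each hyperparameter family is moved by a
digamma-ratio fixed point that maximizes the collapsed marginal likelihood
with its Gamma prior, e.g. for a feature concentration:

```
beta* = (shape - 1 + beta * sum_k [psi(beta + n_wk) - psi(beta)]) /
        (rate  + sum_k [psi(sum_w beta + n_.k) - psi(sum_w beta)])
```

with analogous updates for `alpha` (on `n_jk + m_jk`), `zeta` (on
`m_lkv`), and the Beta shapes `a`, `b` (on the observed/unobserved masses
`p`, `q`).  At zero counts the digamma terms cancel and the update returns
the prior mode `(shape - 1)/rate` exactly; the test suite also verifies
that the converged coordinate agrees with a 1-D grid-search argmax of the
collapsed objective to 1e-3.  Updates are floored at 1e-6 to keep every
concentration strictly positive.

### Convergence

`fit_jcvb()` monitors the training predictive log-likelihood under the
current posterior means and stops when its relative change over a sweep
falls below `tol` (default 1e-4), with a `min_iter` floor (default 10)
because the first sweeps break the near-uniform initial symmetry slowly
and the monitor can be transiently flat.  CVB0 is not provably monotone,
so the tests assert start-to-end improvement, not per-sweep monotonicity.
Initialization is perturbed-uniform: entries uniform in
`[1/K - 0.1/K, 1/K + 0.1/K]`, then normalized; unobserved-pair tables
start exactly uniform.  Each patient draws from its own seeded RNG stream
so batch-local and full initializations coincide at equal seeds.

## Stochastic inference

`fit_scvb()` trains with constant memory: per epoch the patients are
shuffled into minibatches of `D'`; each batch's local assignments are
freshly initialized and updated by the same compiled sweep against the
current global statistics; the batch sums are scaled by `D/D'` so they
estimate full-corpus statistics; and the global feature/lab statistics
move by natural-gradient interpolation `(1 - rho) old + rho new`.  The
Beta observation masses `p`, `q` are interpolated with the same rate —
they are global statistics of the same kind, and leaving them stale would
desynchronize the missingness mechanism from the topics.  Scaling before
interpolation is the default because without it the stationary point
would depend on the batch size.  The learning rate is a fixed `rho`
(default 0.5) or an opt-in Robbins-Monro schedule `(s + tau)^(-kappa)`.

With `D' = D`, `rho = 1` and one local sweep, an epoch reduces exactly to
one batch sweep — the suite asserts this to 1e-10 — and out-of-batch
assignments are never materialized (the returned object records the
largest local table used).

## Prediction, imputation, model choice

* `infer_patient_mixture()` folds a new patient in against the frozen
  trained parameters: local CVB0 sweeps (default 10) updating only the
  patient's own masses.  Unobserved labs participate through the
  `1 - psi` mechanism by default, matching training.  A record with no
  observations of any kind returns the prior mean `alpha/sum(alpha)` —
  the degenerate contract; note that under a strict NMAR reading even an
  all-missing lab pattern carries some information, which this convention
  deliberately ignores for patients about whom nothing was recorded.
* `predictive_log_likelihood()` scores held-out records;
  `cross_validate_K()` combines patient-level folds with a 50/50 feature
  completion split (stratified per data type so no modality vanishes from
  the fold-in half; observed labs split as whole patient-lab pairs) to
  choose `K` by mean held-out likelihood.
* `knn_neighbors()` / `predict_code()` implement retrospective EHR code
  prediction: Euclidean distance between topic mixtures (ties broken by
  patient index), prediction = average binary presence of the code among
  the `k = 100` nearest training patients, classification threshold
  `1/k`.  Presence is binarized because the task is classification, not
  count regression.
* `impute_lab_result()` masks the target lab, folds the patient in, finds
  the `k = 25` nearest training patients *with that lab observed*, and
  averages their per-patient normalized state distributions —
  normalization keeps heavy-utilization patients from dominating the
  vote.
* `code_embedding()` / `code_correlation_matrix()` /
  `permutation_significance()` build comorbidity networks: a code's
  embedding is its row of `phi` (probability of the code under each
  topic, not renormalized by default; a `renormalize` flag exists because
  either convention is defensible), correlations are Pearson across
  topics, and significance comes from shuffling the target code's topic
  probabilities with the add-one permutation estimator
  `p = (1 + #{|r_null| >= |r_obs|}) / (1 + n_perm)` (two-sided by
  default; the null construction is sign-agnostic).

## The synthetic generator

`sample_truth()` / `sample_corpus()` sample the generative process
exactly as written above, so every downstream stage is testable without
any clinical dataset.  One observed pair records one result draw by
default (the 0/1 use of the indicator implies a single trial); a
`Poisson(lambda) + 1` option emulates repeated measurements within an
admission.  `simulate_benchmark()` freezes the two study conditions used
by the tests and the acceptance script:

* **recovery** — `D = 500` (or as stated), `K = 3`, vocabularies
  `(60, 40)`, 80 tokens/patient, 10 binary labs, sparse topics
  (`beta = 0.05`, hence well separated), `alpha = 0.5`, `zeta = 0.5`,
  uniform `Beta(1,1)` observation probabilities.
* **nmar** — as above with 60 tokens/patient, near-deterministic result
  preferences (`eta = 0.9` on a topic-alternating preferred state) and
  topic-dependent observation (`psi = 0.7` under one designated topic per
  lab, `0.3` otherwise), `alpha = 0.3`.  The softer `psi` contrast keeps
  the marginal result distribution mixed, so the patient-specific signal
  is visible over a global majority-state baseline while missingness
  remains clearly topic-dependent.

What the generator does *not* emulate: longitudinal visit structure and
admission time stamps, vocabulary burstiness and stop-word structure of
real notes, code hierarchies, and patient-level confounders of lab
ordering (utilization, care setting).  Passing the synthetic benchmarks
therefore demonstrates correctness of the inference machinery and the
directional value of modelling informative missingness — not clinical
performance on real EHR data.

## Problem sizes and numerical choices

The test suite and `scripts/acceptance.R` use sizes chosen to exercise
the claims while keeping a full run in minutes on one core: the frozen
6-patient fixture for all oracle equivalences (1e-10), `D = 500` / 3
seeds for parameter recovery (best-permutation mean cosine of `phi`
against truth >= 0.90; mean absolute error of `psi` <= 0.10), `D = 240`
with 2 folds for `K`-selection over `{1, 3, 8}`, `D = 1000` with an
800/200 split for imputation (>= 5 percentage points over the majority
baseline) and masked-code prediction (AUROC >= 0.6), and `n_perm = 999`
over 200 independent codes for permutation calibration
(Kolmogorov-Smirnov statistic < 0.1).  The minibatch recovery check runs
at `D = 300` with `D' = 50` and the `(tau = 10, kappa = 0.7)` schedule.

Known limitations worth keeping in mind:

* Topic labels are not identifiable; all recovery metrics align by the
  best permutation, and comparisons across runs must do the same.
* Fold-in and training mixtures agree closely only when one patient's
  contribution to the global statistics is negligible; on corpora of a
  handful of patients the two fixed points visibly differ for ambiguous
  patients.
* CVB0's zero-order approximation trades a small bias for speed; the
  monitored likelihood can wiggle, which is why convergence uses a
  relative-change window plus a minimum sweep count.
* The AUPRC reported by `evaluate_binary_predictions()` is average
  precision with tied scores grouped; AUROC comes from `pROC`.
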