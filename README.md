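# protomix

Prototype, exemplar and mixture models for single-category dot-pattern
learning.

`protomix` is for researchers studying how people learn a perceptual
category from distorted variants of an unseen prototype: whether
endorsement decisions ("this belongs to category A") rest on similarity
to an abstracted prototype, on summed similarity to stored training
exemplars, or on a weighted mixture of both strategies. The package
provides the complete modelling chain on simulated data: Posner-style
9-dot stimulus generation under distance constraints, the observation
models, per-subject Bayesian fitting, DIC model comparison,
participant-level quality control, and parameter/model-recovery
experiments.

## The models

Perceptual similarity decays exponentially with distance *d* at
sensitivity *c*:

- prototype route: `s_iP = exp(-c * d_iP)`
- exemplar route: `s_iE = Σ_j exp(-c * d_ij)` over the 12 training
  exemplars

Endorsement probability follows a ratio rule with criterion *k*,
optionally sharpened by a response-scaling exponent *γ*:

```
r = s^γ / (s^γ + k^γ)
```

and the mixture family weights the two routes with *β*:

```
r_mix = β * r_proto + (1 − β) * r_ex
```

Eight variants are implemented: `PROTO`, `EX`, `EX_G`, `MIX`, `MIX_2C`
(separate sensitivities per route), `MIX_G`, `MIX_2C_G`, and the
parameter-free `GUESS` model (`r = 0.5` for every item), which anchors
model comparison. Fitting is MCMC under uniform priors (`c ~ U(0,5)`,
`k ~ U(0,1)`, `β ~ U(0,1)`, `γ ~ U(0,20)`) with a two-stage
initialization protocol (short exploratory chains, then final chains
started from the stage-1 posterior quantiles), split-chain Rhat
convergence checks, and DIC (`pD = Dbar − Dhat`) for model comparison.
See the methods vignette (`vignettes/protomix-methods.Rmd`) for the
full account.

## Worked example

Generate a stimulus set, simulate one agent's transfer-phase
endorsements from a known mixture truth, and ask which model explains
them:

```r
library(protomix)

set_ <- build_stimulus_set(2026)
set_
#> <stimulus_set seed=2026: prototype + 12/12 training members/nonmembers
#>  + 8/8 novel members/nonmembers>

dists <- stimulus_distances(set_, "all")
r <- model_predict("MIX", c(c = 0.8, k = 0.3, beta = 0.6), dists)
set.seed(11)
ed <- endorsement_data(names(r), count = rbinom(length(r), 8, r),
                       n_rounds = 8, phase = "transfer")

fits <- lapply(c(MIX = "MIX", PROTO = "PROTO", EX = "EX"), function(m)
  fit_model(m, ed, dists, chains = quick_chain_config(seed = 2026)))
guess <- fit_model("GUESS", ed, dists)

fits$MIX
#> <fit_result MIX: DIC = 172.74 (pD = -0.58), converged = TRUE>
#> posterior means:
#>      c      k   beta
#> 1.4461 0.0853 0.6720
fits$PROTO$dic$DIC   # 192.99
fits$EX$dic$DIC      # 203.19
guess$dic$DIC        # 454.70  (= 2 * 328 * log(2), analytic)

sel <- select_model(fits, guess)
sel$best_model       # "MIX"
sel$guess_level      # FALSE
```

The generating mixture model wins by ~20 DIC over either single-route
account and by ~280 over guessing, so this simulated subject would be
classified as a genuine mixture-strategy user, not a guesser. The
posterior mean of the strategy weight (`beta = 0.672`) recovers the
generating truth 0.6 within its 95% credible interval (0.53–0.79);
sensitivity and criterion trade off along a ridge and are individually
less sharp, which is a property of the design, not the sampler. The
parsimony guard matters in such comparisons: near-ties in DIC (within
2) are resolved toward the model with fewer free parameters.

Cohort-level simulation mirrors the full task protocol (feedback
training to a 75% stop criterion, then 8 transfer rounds over all 41
items):

```r
ds <- simulate_cohort(cohort_config(n_per_group = 10, stimulus_seed = 2,
                                    agent_seed = 3))
accuracy_summary(ds, by = c("membership", "group", "phase"))
qc <- participant_qc(ds, trait_scores = setNames(ds$agents$trait_score,
                                                 ds$agents$subject_id))
```

A thin CLI covering generation, simulation and reporting is installed
at `inst/exec/protomix`.

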