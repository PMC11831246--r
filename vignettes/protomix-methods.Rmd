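---
title: "Models and methods in protomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in protomix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In a single-category ("A / not-A") dot-pattern learning task, observers
study distorted variants of an unseen 9-dot prototype, receive
trial-by-trial feedback during training, and are then probed without
feedback on a transfer set containing old items, the prototype itself,
novel distortions and novel random patterns. The central question is
*what representation supports endorsement decisions*: similarity to an
abstracted prototype, summed similarity to stored training exemplars, or
a weighted mixture of the two. `protomix` implements the full modelling
chain — stimulus construction, observation models, Bayesian per-subject
fitting, model comparison and quality control — together with a
synthetic-agent simulator so that every stage can be exercised and
validated without human data.

## Stimulus generation

Prototypes are 9 distinct dots drawn uniformly from the integer grid
points of the central 30×30 window of a 50×50 grid-unit canvas. This
grid convention follows the classical dot-pattern construction; the
canvas is configurable but must be at least 30×30.

Members are made by displacing each prototype dot independently in a
uniformly random direction by a radius drawn uniformly on
`[0, magnitude(DL)]`, with per-level magnitudes `1.5, 2.1, 2.7, 3.3`
grid units for distortion levels (DL) 4–7. Classical distortion schemes
use area-indexed displacement probability tables; those tables are not
reproduced here, so the level-to-magnitude mapping is an explicit,
configurable approximation whose only load-bearing property — expected
displacement strictly increasing in level — is property-tested. Dot
order is preserved under distortion, so prototype-relative distances
need no correspondence solving.

Pattern distance is the Euclidean norm in the 18-dimensional stacked
coordinate space, `sqrt(sum_dots(dx^2 + dy^2))`. The distance
constraints — members within 6.22 of the prototype, nonmembers at least
12.93 away — are interpreted as bounds on this 18-D norm (a per-dot
average is the other possible reading; the 18-D norm is adopted and
exposed in configuration). They are enforced *by construction* through
rejection sampling with a hard cap of 10,000 attempts per item; hitting
the cap is an error naming the violated constraint, never a silent
relaxation. The default magnitudes give high acceptance rates (the DL7
mean distance sits near 5.7, comfortably inside the member bound), and
random nonmembers on this canvas land far beyond the nonmember bound
essentially always.

The inventory is 41 patterns: 1 prototype, 12 training members (4 each
at DL5, DL6, DL7 — i.e. 8 medium plus 4 high distortions), 12 training
nonmembers, 8 novel members (2 each at DL4–DL7) and 8 novel nonmembers.
Training presents the 24 training items (prototype withheld); transfer
presents all 41.

## Observation models

All variants share an exponential similarity gradient with sensitivity
`c` (grid-unit⁻¹):

- prototype similarity of item *i*: `s_iP = exp(-c d_iP)`
- exemplar similarity: `s_iE = sum_j exp(-c d_ij)` over the 12 training
  members (a training item's self-term contributes exactly 1)

Endorsement probability uses a criterion constant `k` via the ratio rule
`r = s/(s + k)`; response scaling `gamma` sharpens (`gamma > 1`) or
flattens (`gamma < 1`) choices via `r = s^gamma/(s^gamma + k^gamma)`.
The mixture family combines the two routes with weight `beta`:
`r = beta r_proto + (1 - beta) r_ex`. Eight variants are available:
`PROTO`, `EX`, `EX_G`, `MIX`, `MIX_2C` (separate `c_proto`, `c_ex`),
`MIX_G`, `MIX_2C_G`, and the parameter-free `GUESS` model (`r = 0.5`
everywhere), which anchors model comparison.

Two conventions required a decision:

- **Gamma scope.** The printed scaling rule covers the exemplar route
  only. For the gamma mixture variants we scale *both* routes by default
  (`gamma_scope = "both"`), because an asymmetric rule makes `beta`
  partially confounded with `gamma`; `"exemplar_only"` is available as a
  switch and covered by tests.
- **Likelihood family.** Training rounds contribute Bernoulli terms per
  binary response; transfer data are endorsement counts over the
  observed rounds and contribute binomial *kernels* — the binomial
  normalizing constant is deliberately omitted so that a transfer item
  seen over `n` rounds contributes exactly as `n` Bernoulli trials
  would. The constant is parameter-free, so posteriors and DIC
  differences are unaffected, while deviances stay comparable across
  phases and the guessing deviance takes the clean closed form
  `2 N log 2` for `N` Bernoulli-equivalent trials (454.70 for 41 items
  × 8 rounds). Timeout trials are dropped from likelihoods, mirroring
  their exclusion from accuracy. Probabilities are clipped to
  `[1e-12, 1 - 1e-12]` inside likelihoods only, never in reported `r`.

Hard parameter domains: `c >= 0`, `k` in `(0, 1]` (zero would make
`r = 1` singular), `beta` in `[0, 1]`, `gamma > 0`.

## Bayesian fitting

Priors are uniform: `c ~ U(0,5)` (likewise `c_proto`, `c_ex`),
`k ~ U(0,1)`, `beta ~ U(0,1)`, `gamma ~ U(0,20)`. Because priors are
flat on a box, the posterior is the likelihood restricted to the box,
and any sampler respecting the box is admissible; the chain protocol,
not the engine, is the contract. `protomix` uses random-walk Metropolis
with Gaussian proposals *reflected* at the box boundaries (reflection
keeps the proposal symmetric, so the acceptance ratio is the likelihood
ratio). Proposal scales start at a tenth of each prior range and adapt
toward ~30% acceptance during burn-in only, so the retained chain is a
fixed-kernel Markov chain.

The two-stage protocol: stage 1 runs 4 chains × 4000 iterations
(burn-in 500) from random prior draws; the pooled stage-1 posterior
quantiles at 2.5, 25, 50, 75 and 97.5% are computed, and the four outer
quantiles initialize the four final chains (the median is recorded in
the fit metadata but unused when exactly four chains are run — five
quantiles onto four chains forces a choice, and dropping the median
keeps the most dispersed starts, which is what overdispersed
initialization is for). The final run is 4 chains × 20,000 iterations,
burn-in 2500, thinning 5. Convergence is assessed by split-chain
Gelman–Rubin Rhat with threshold 1.1 (a conventional cutoff; the
statistic itself is standard but no numeric cutoff is canonical, so it
is configurable). If any parameter exceeds the threshold the final
stage is repeated once at 100,000 iterations; persistent
non-convergence is *reported* (`converged = FALSE`), never an error, so
hard-to-fit variants (e.g. the gamma mixtures on transfer data) surface
as flagged results rather than crashes.

Model fit is the deviance information criterion with
`pD = Dbar - Dhat` (the classic mean-deviance penalty, rather than the
half-variance variant) and `DIC = Dbar + pD`. The guessing model's DIC
is computed analytically, with `pD = 0`. Model selection ranks
converged fits by DIC, breaks near-ties (within 2) toward fewer free
parameters, and flags a subject as guess-level when the best model is
not at least `delta_guess = 2` below the guessing DIC — a conventional
weak-evidence threshold adopted because "meaningful difference" has no
canonical value; both constants are arguments.

For a well-identified check of the whole chain, the test suite also
fits the prototype model through an independent general-purpose Gibbs
engine (JAGS) under identical priors and compares posterior means.

## Synthetic cohorts

Agents respond from a generating model whose parameters follow linear
per-round trajectories between start and end values (linearity is the
simplest shape consistent with monotone trends; the trajectory is a
template, not a claim). The default scenario encodes the qualitative
group dynamics of interest:

| parameter | AQ_low start → end | AQ_high start → end |
|---|---|---|
| beta | 0.474 → 0.15 | 0.474 → 0.30 |
| c | 0.05 → 0.8 | 0.05 → 0.8 |
| k | 0.22 → 0.08 | 0.32 → 0.18 |
| gamma | 1 → 3 | 1 → 3 |

Both groups start at the same near-even strategy mixture (0.474);
reliance on the prototype route declines in both but more slowly in the
high-trait group; sensitivity rises identically; the criterion relaxes
over training but stays uniformly stricter in the high-trait group; and
transfer parameters (`beta = 0.38, c = 0.5, k = 0.12, gamma = 2`) do
not differ by group. The numeric start/end values are calibration
constants — chosen once so that default cohorts learn to the 75%
criterion within the protocol while preserving those orderings — not
estimates of anything. Trait scores are drawn as integers around 11
(low group, range 4–14) and 18 (high group, range 15–28), mimicking a
subclinical sample split at its median of 14.

The training protocol engine stops after at least eight rounds of which
four reached 75% accuracy, or at round 14; round accuracy for the stop
rule is computed over non-timeout trials. Timeouts are independent
coin-flips per trial (default rate 0.02, capped at 0.1) — no timeout
model is claimed.

What the simulator does *not* emulate: reaction times, within-round
order effects, attention lapses correlated with difficulty, learning
between (rather than across) rounds, and any neural signal. Passing
recovery tests therefore demonstrates that the inference machinery is
correct and well-calibrated *when the observation model is true*; they
cannot certify behaviour on real data, where all models are
approximations.

## Recovery experiments and problem sizes

Parameter recovery simulates transfer datasets (41 items × 8 binomial
rounds) from `MIX` at `beta` in {0.2, 0.5, 0.8} with the anchor values
`c = 0.8`, `k = 0.3`, 20 replicates per truth. The anchor was chosen so
that both routes contribute discriminable item profiles: at much lower
sensitivity the two similarity vectors become nearly collinear across
the inventory, and at much higher sensitivity the prototype route
carries signal only at the prototype itself; in both regimes `beta` is
weakly identified *in any implementation* — a property of the design,
not the sampler. The suite asserts the recovered `beta` rank order
across the three truths and ≥85% coverage of 95% credible intervals.
Model recovery simulates from `EX` (`c = 1.0, k = 0.3`) and `PROTO`
(`c = 1.5, k = 0.3`) and checks that DIC prefers the generating model.

Tests run these experiments with a reduced chain protocol
(`quick_chain_config()`: 4 chains × 4000, burn-in 500, stage-1
4 × 1000), which the calibration checks show is sufficient at this data
size; the full protocol remains the default for analyses. The default
demonstration pipeline uses 2 agents per group; the packaged cohort
fixtures use 10 per group.

## Numerical choices and degenerate inputs

- Sampling is confined to the open box (bounds nudged inward by 1e-9 of
  the range) so `k = 0` and other boundary singularities are
  unreachable.
- Rhat of identically constant chains is defined as 1 (zero variance in
  a parameter that never moves is a point posterior, not divergence);
  zero within-chain variance with nonzero between-chain variance yields
  infinity.
- Effective sample size uses a truncated autocorrelation sum (first lag
  below 0.05, capped at 50) — a coarse diagnostic, not an estimator of
  record.
- Deviance draws that are non-finite are excluded with a warning; more
  than 10% non-finite aborts the DIC computation.
- All stochastic entry points take explicit integer seeds; per-chain
  and per-agent seeds derive deterministically from them, and every
  derived seed stays within the 32-bit integer range.
- JSON stimulus files store 17 significant digits so coordinates
  round-trip bit-exactly.

## Known limitations

- The distortion scheme approximates the classical area-displacement
  tables with a radial-jitter family; absolute distortion magnitudes
  are conventions, and only their ordering is asserted.
- Generated nonmembers sit far beyond the minimum-distance bound
  (typically 30+ grid units from the prototype), which makes simulated
  rejection decisions easier than for hand-tuned stimulus sets whose
  nonmembers hug the bound.
- The random-walk sampler is serviceable for these 2–5 parameter
  posteriors but makes no claim of efficiency on multimodal targets;
  the escalation path and the convergence flag exist precisely because
  some variants (notably gamma mixtures on transfer data) may not mix.
- DIC is the only fit index implemented; WAIC/LOO and hierarchical
  pooling across subjects are out of scope.
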