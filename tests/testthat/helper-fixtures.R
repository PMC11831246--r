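# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A default stimulus set (seed 42) and its distance structures.
test_stimuli <- function() {
  if (is.null(.fixtures$set)) .fixtures$set <- build_stimulus_set(42)
  .fixtures$set
}

test_distances <- function(phase = "all") {
  key <- paste0("dist_", phase)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- stimulus_distances(test_stimuli(), phase)
  .fixtures[[key]]
}

# A small simulated cohort under the default scenario.
test_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- simulate_cohort(
      cohort_config(n_per_group = 10L, stimulus_seed = 2L,
                    agent_seed = 3L))
  }
  .fixtures$cohort
}

# Hand-made tiny distance structure: 3 items, 2 exemplars.
toy_distances <- function() {
  d_ex <- rbind(c(0, 2, 10), c(1, 0, 12))
  colnames(d_ex) <- c("i1", "i2", "i3")
  rownames(d_ex) <- c("e1", "e2")
  list(d_proto = c(i1 = 1, i2 = 3, i3 = 11),
       d_ex = d_ex,
       role = c(i1 = "member", i2 = "member", i3 = "nonmember"),
       dl = c(i1 = 5L, i2 = 6L, i3 = NA_integer_))
}

# Simulate one transfer dataset (endorsement counts over n_rounds) from a
# model truth.
simulate_transfer_counts <- function(model, params, dists, seed,
                                     n_rounds = 8) {
  r <- model_predict(model, params, dists)
  set.seed(seed)
  endorsement_data(item_id = names(r),
                   count = rbinom(length(r), n_rounds, r),
                   n_rounds = n_rounds, phase = "transfer")
}

# Reduced chain settings used when many fits are run in a test.
test_chains <- function(seed) quick_chain_config(seed = seed)

# Random admissible parameter draw for a model.
random_params <- function(model) {
  vals <- c(c = runif(1, 0.01, 5), c_proto = runif(1, 0.01, 5),
            c_ex = runif(1, 0.01, 5), k = runif(1, 0.01, 1),
            beta = runif(1), gamma = runif(1, 0.05, 20))
  vals[model_parameters(model)]
}
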