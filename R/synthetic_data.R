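# Simulated cohorts of category learners.
#
# Agents respond according to one of the observation models. Over
# training their parameters follow a linear trajectory between start and
# end values: the mixture weight beta declines (reliance on the prototype
# strategy fades), sensitivity c rises (sharper generalization
# gradients), the criterion k relaxes, and response scaling gamma grows
# (more deterministic choices). The high-trait group starts with the same
# strategy mixture but moves away from the prototype strategy more slowly
# and keeps a stricter criterion throughout.

#' Default per-group parameter trajectory templates
#'
#' Start/end values for the training-phase trajectory (linearly
#' interpolated over 14 rounds) and a constant transfer-phase parameter
#' set per group. The values are calibration constants chosen so that
#' simulated cohorts learn to criterion while reproducing the qualitative
#' group dynamics: a slower decline of the prototype weight and a
#' stricter criterion in the high-trait group, identical sensitivity
#' growth in both groups, and no group differences in the transfer
#' parameters.
#'
#' @return Named list with one template per group (`AQ_low`, `AQ_high`);
#'   each template has `start`, `end` (named parameter vectors) and
#'   `transfer` (a constant parameter set).
#' @export
default_group_templates <- function() {
  shared_start <- c(beta = 0.474, c = 0.05, gamma = 1)
  shared_end <- c(c = 0.8, gamma = 3)
  transfer <- c(beta = 0.38, c = 0.5, k = 0.12, gamma = 2)
  list(
    AQ_low = list(
      start = c(shared_start, k = 0.22),
      end = c(shared_end, beta = 0.15, k = 0.08),
      transfer = transfer),
    AQ_high = list(
      start = c(shared_start, k = 0.32),
      end = c(shared_end, beta = 0.30, k = 0.18),
      transfer = transfer)
  )
}

#' Linearly interpolated per-round parameter trajectory
#'
#' @param start,end Named parameter vectors (same names).
#' @param n_rounds Number of training rounds covered (default 14).
#' @return Data frame with one row per round and one column per
#'   parameter.
#' @export
make_trajectory <- function(start, end, n_rounds = 14L) {
  stopifnot(setequal(names(start), names(end)), n_rounds >= 8)
  frac <- if (n_rounds == 1) 0 else (seq_len(n_rounds) - 1) / (n_rounds - 1)
  out <- as.data.frame(lapply(names(start), function(nm)
    start[[nm]] + frac * (end[[nm]] - start[[nm]])))
  names(out) <- names(start)
  out$round <- seq_len(n_rounds)
  out
}

#' Configuration of one simulated agent
#'
#' @param agent_id Identifier.
#' @param group Trait group label, `"AQ_low"` or `"AQ_high"`.
#' @param generating_model Observation model used to generate responses
#'   (default `"MIX"`).
#' @param trajectory Data frame from [make_trajectory()] (per-round
#'   training parameters).
#' @param transfer_params Named parameter vector for the transfer phase.
#' @param timeout_rate Probability of a timeout (`NA` response) per
#'   trial, in `[0, 0.1]`.
#' @param trait_score Simulated trait sum score (optional).
#' @return An `agent_config`.
#' @export
agent_config <- function(agent_id, group = c("AQ_low", "AQ_high"),
                         generating_model = "MIX", trajectory,
                         transfer_params, timeout_rate = 0.02,
                         trait_score = NA_real_) {
  group <- match.arg(group)
  if (timeout_rate < 0 || timeout_rate > 0.1)
    stop("timeout_rate must lie in [0, 0.1]", call. = FALSE)
  if (nrow(trajectory) < 8)
    stop("trajectory must cover at least 8 rounds", call. = FALSE)
  for (i in seq_len(nrow(trajectory)))
    check_params(generating_model,
                 trajectory[i, setdiff(names(trajectory), "round")])
  check_params(generating_model, transfer_params)
  structure(list(agent_id = as.character(agent_id), group = group,
                 generating_model = generating_model,
                 trajectory = trajectory,
                 transfer_params = transfer_params,
                 timeout_rate = timeout_rate,
                 trait_score = trait_score),
            class = "agent_config")
}

#' Simulate one round of responses from an agent
#'
#' Each item is endorsed with its model-implied probability `r`; with
#' probability `timeout_rate` the response is `NA` (timeout). Correctness
#' is derived from the item role: endorsing a member or rejecting a
#' nonmember is correct (the prototype counts as a member).
#'
#' @param agent An [agent_config()].
#' @param round_index Training round (indexes the trajectory), or any
#'   value for transfer.
#' @param distances Distance structure of the items presented this round.
#' @param phase `"training"` or `"transfer"`.
#' @return Data frame `item_id, role, dl, response, correct` (one row per
#'   item; uses the current RNG stream).
#' @export
simulate_round <- function(agent, round_index, distances,
                           phase = c("training", "transfer")) {
  phase <- match.arg(phase)
  params <- if (phase == "training") {
    if (round_index > nrow(agent$trajectory))
      stop("round_index beyond trajectory", call. = FALSE)
    unlist(agent$trajectory[round_index,
                            setdiff(names(agent$trajectory), "round")])
  } else {
    agent$transfer_params
  }
  r <- model_predict(agent$generating_model, params, distances)
  n <- length(r)
  response <- as.numeric(stats::runif(n) < r)
  response[stats::runif(n) < agent$timeout_rate] <- NA
  is_member <- distances$role %in% c("member", "prototype")
  data.frame(item_id = names(r), role = distances$role,
             dl = distances$dl, response = response,
             correct = ifelse(is.na(response), NA,
                              as.numeric(response == as.numeric(is_member))),
             row.names = NULL)
}

#' Cohort simulation configuration
#'
#' @param n_per_group Agents per trait group (>= 1).
#' @param stimulus_seed Seed for [build_stimulus_set()].
#' @param agent_seed Base seed from which per-agent seeds derive.
#' @param templates Per-group trajectory templates, see
#'   [default_group_templates()].
#' @param generating_model Model generating the responses.
#' @param timeout_rate Per-trial timeout probability.
#' @param n_transfer_rounds Transfer rounds (default 8).
#' @param max_training_rounds Training round cap (default 14).
#' @return A `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 10L, stimulus_seed = 1L,
                          agent_seed = 100L,
                          templates = default_group_templates(),
                          generating_model = "MIX", timeout_rate = 0.02,
                          n_transfer_rounds = 8L,
                          max_training_rounds = 14L) {
  stopifnot(n_per_group >= 1)
  structure(list(n_per_group = as.integer(n_per_group),
                 stimulus_seed = as.integer(stimulus_seed),
                 agent_seed = as.integer(agent_seed),
                 templates = templates,
                 generating_model = generating_model,
                 timeout_rate = timeout_rate,
                 n_transfer_rounds = as.integer(n_transfer_rounds),
                 max_training_rounds = as.integer(max_training_rounds)),
            class = "cohort_config")
}

# Simulated trait sum scores: low group centred at 11 (range 4-14), high
# group centred at 18 (range 15-28), mimicking a subclinical sample split
# at the median.
draw_trait_score <- function(group) {
  if (group == "AQ_low") {
    min(max(round(stats::rnorm(1, 11, 3)), 4), 14)
  } else {
    min(max(round(stats::rnorm(1, 18, 3)), 15), 28)
  }
}

#' Simulate a full cohort through training and transfer
#'
#' Each agent runs the training protocol (stop rule: at least eight
#' rounds with four rounds at 75% accuracy or more, cap at 14 rounds)
#' followed by the transfer rounds over the full 41-item inventory.
#' Round-level accuracy for the stop rule is computed over non-timeout
#' trials. Deterministic given the config seeds.
#'
#' @param config A [cohort_config()].
#' @return A `behavioural_dataset`: the `stimulus_set`, a tidy `trials`
#'   data frame (`subject_id, group, phase, round, item_id, role, dl,
#'   response, correct`), per-agent metadata (`agents`), and a provenance
#'   block.
#' @export
simulate_cohort <- function(config) {
  set_ <- build_stimulus_set(config$stimulus_seed)
  dist_train <- stimulus_distances(set_, "training")
  dist_transfer <- stimulus_distances(set_, "all")
  groups <- rep(names(config$templates), each = config$n_per_group)
  trials <- vector("list", length(groups))
  agents <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    set.seed(derive_seed(config$agent_seed, i))
    tmpl <- config$templates[[g]]
    agent <- agent_config(
      agent_id = sprintf("s%03d", i), group = g,
      generating_model = config$generating_model,
      trajectory = make_trajectory(tmpl$start, tmpl$end,
                                   config$max_training_rounds),
      transfer_params = tmpl$transfer,
      timeout_rate = config$timeout_rate,
      trait_score = draw_trait_score(g))
    state <- protocol_state()
    rows <- list()
    while (!state$terminated) {
      rnd <- state$round_index + 1L
      resp <- simulate_round(agent, rnd, dist_train, "training")
      resp <- resp[sample.int(nrow(resp)), ]  # pseudorandomized order
      acc <- mean(resp$correct, na.rm = TRUE)
      state <- advance_protocol(state, acc)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject_id = agent$agent_id, group = g,
                   phase = "training", round = rnd), resp)
    }
    for (tr in seq_len(config$n_transfer_rounds)) {
      resp <- simulate_round(agent, tr, dist_transfer, "transfer")
      resp <- resp[sample.int(nrow(resp)), ]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject_id = agent$agent_id, group = g,
                   phase = "transfer", round = tr), resp)
    }
    trials[[i]] <- do.call(rbind, rows)
    agents[[i]] <- data.frame(
      subject_id = agent$agent_id, group = g,
      trait_score = agent$trait_score,
      n_training_rounds = state$round_index,
      termination_reason = state$termination_reason)
  }
  structure(list(
    stimuli = set_,
    trials = do.call(rbind, trials),
    agents = do.call(rbind, agents),
    provenance = list(config = unclass(config), package = "protomix")),
    class = "behavioural_dataset")
}

#' @export
print.behavioural_dataset <- function(x, ...) {
  cat(sprintf("<behavioural_dataset: %d agents, %d trials>\n",
              nrow(x$agents), nrow(x$trials)))
  invisible(x)
}

#' Aggregate a subject's transfer trials into endorsement counts
#'
#' @param trials Tidy trial data frame (one subject's transfer rows, or a
#'   larger frame filtered by `subject_id`).
#' @param subject_id Subject to aggregate (optional if already filtered).
#' @return An [endorsement_data()] object (`phase = "transfer"`);
#'   timeout rounds are excluded from each item's denominator.
#' @export
aggregate_transfer <- function(trials, subject_id = NULL) {
  d <- trials[trials$phase == "transfer", ]
  if (!is.null(subject_id)) d <- d[d$subject_id == subject_id, ]
  if (nrow(d) == 0) stop("no transfer trials", call. = FALSE)
  counts <- tapply(d$response, d$item_id, function(x) sum(x, na.rm = TRUE))
  denoms <- tapply(d$response, d$item_id, function(x) sum(!is.na(x)))
  endorsement_data(item_id = names(counts), count = as.numeric(counts),
                   n_rounds = as.numeric(denoms), phase = "transfer")
}

#' Extract one training round as binary endorsement data
#'
#' @param trials Tidy trial data frame.
#' @param round Training round number.
#' @param subject_id Subject to extract (optional if already filtered).
#' @return An [endorsement_data()] object (`phase = "training"`).
#' @export
training_round_data <- function(trials, round, subject_id = NULL) {
  d <- trials[trials$phase == "training" & trials$round == round, ]
  if (!is.null(subject_id)) d <- d[d$subject_id == subject_id, ]
  if (nrow(d) == 0) stop("no training trials for round ", round,
                         call. = FALSE)
  endorsement_data(item_id = d$item_id, response = d$response,
                   phase = "training")
}

#' Generate labelled datasets for parameter/model recovery
#'
#' For each row of the parameter grid, simulates `n_datasets`
#' transfer-phase datasets (endorsement counts over
#' `n_rounds` rounds of the full inventory) from an agent holding those
#' parameters fixed, and labels each dataset with its generating truth.
#'
#' @param model Generating model name.
#' @param grid Data frame of true parameter values (one column per free
#'   parameter).
#' @param n_datasets Replicate datasets per grid point.
#' @param seed Base seed.
#' @param stimulus_seed Seed of the shared stimulus set.
#' @param n_rounds Transfer rounds per dataset (default 8).
#' @param priors A [prior_spec()]; grid points outside the prior bounds
#'   are a configuration error.
#' @return List with `stimuli`, `distances` and `datasets` (each dataset:
#'   `truth`, `data`, `seed`, `grid_row`, `replicate`).
#' @export
make_recovery_suite <- function(model, grid, n_datasets = 1L, seed = 1L,
                                stimulus_seed = 1L, n_rounds = 8L,
                                priors = prior_spec()) {
  for (i in seq_len(nrow(grid))) {
    p <- check_params(model, grid[i, , drop = FALSE])
    for (nm in names(p)) {
      b <- priors[[nm]]
      if (p[[nm]] < b[1] || p[[nm]] > b[2])
        stop("grid value for ", nm, " lies outside the prior bounds",
             call. = FALSE)
    }
  }
  set_ <- build_stimulus_set(stimulus_seed)
  dists <- stimulus_distances(set_, "all")
  datasets <- list()
  for (i in seq_len(nrow(grid))) {
    truth <- unlist(grid[i, , drop = TRUE])
    r <- model_predict(model, truth, dists)
    for (rep_ in seq_len(n_datasets)) {
      ds_seed <- derive_seed(seed, i * 1000L + rep_)
      set.seed(ds_seed)
      counts <- stats::rbinom(length(r), n_rounds, r)
      datasets[[length(datasets) + 1L]] <- list(
        truth = truth, grid_row = i, replicate = rep_, seed = ds_seed,
        data = endorsement_data(item_id = names(r), count = counts,
                                n_rounds = n_rounds, phase = "transfer"))
    }
  }
  list(model = model, stimuli = set_, distances = dists,
       datasets = datasets)
}
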