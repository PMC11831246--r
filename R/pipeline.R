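# Orchestration: training protocol engine, accuracy summaries,
# participant-level QC, recovery experiments, similarity-vector export
# and reporting.

#' Fresh training-protocol state
#'
#' @return A `protocol_state` with zeroed counters.
#' @export
protocol_state <- function() {
  structure(list(round_index = 0L, accuracy_history = numeric(0),
                 rounds_at_criterion = 0L, terminated = FALSE,
                 termination_reason = NA_character_),
            class = "protocol_state")
}

#' Advance the training protocol by one completed round
#'
#' Training continues until at least eight rounds are completed of which
#' at least four reached 75% accuracy, or until round 14.
#'
#' @param state A `protocol_state` (not yet terminated).
#' @param round_accuracy Accuracy of the round just completed, in
#'   `[0, 1]`.
#' @param criterion Accuracy criterion (default 0.75).
#' @param min_rounds,rounds_at_criterion,max_rounds Stop-rule constants
#'   (defaults 8, 4, 14).
#' @return The updated `protocol_state`.
#' @export
advance_protocol <- function(state, round_accuracy, criterion = 0.75,
                             min_rounds = 8L, rounds_at_criterion = 4L,
                             max_rounds = 14L) {
  if (state$terminated)
    stop("cannot advance a terminated protocol", call. = FALSE)
  if (is.na(round_accuracy) || round_accuracy < 0 || round_accuracy > 1)
    stop("round accuracy must lie in [0, 1]", call. = FALSE)
  state$round_index <- state$round_index + 1L
  state$accuracy_history <- c(state$accuracy_history, round_accuracy)
  state$rounds_at_criterion <- sum(state$accuracy_history >= criterion)
  if (state$round_index >= min_rounds &&
      state$rounds_at_criterion >= rounds_at_criterion) {
    state$terminated <- TRUE
    state$termination_reason <- "criterion"
  } else if (state$round_index >= max_rounds) {
    state$terminated <- TRUE
    state$termination_reason <- "round_cap"
  }
  state
}

#' Mean accuracy summarized over grouping cells
#'
#' Timeout trials are excluded from denominators. Distortion-level
#' summaries are restricted to category members; novelty contrasts are
#' restricted to DL5-DL7 items (the levels present in both training and
#' novel item pools).
#'
#' @param dataset A `behavioural_dataset` or a tidy trials data frame.
#' @param by Grouping variables among `"membership"`, `"round"`, `"dl"`,
#'   `"group"`, `"novelty"`, `"phase"`, `"subject"`.
#' @return Data frame of cell means with an `n_trials` column; empty
#'   cells are dropped with a warning if a requested level is absent.
#' @export
accuracy_summary <- function(dataset, by = c("membership", "group")) {
  d <- if (inherits(dataset, "behavioural_dataset")) dataset$trials else
    dataset
  if (nrow(d) == 0) stop("empty dataset", call. = FALSE)
  by <- match.arg(by, c("membership", "round", "dl", "group", "novelty",
                        "phase", "subject"), several.ok = TRUE)
  d$membership <- ifelse(d$role %in% c("member", "prototype"),
                         "member", "nonmember")
  if ("dl" %in% by) d <- d[d$membership == "member" & !is.na(d$dl), ]
  if ("novelty" %in% by) {
    d$novelty <- ifelse(grepl("^t", d$item_id), "training", "novel")
    d <- d[!is.na(d$dl) & d$dl %in% 5:7 |
             (d$role == "nonmember"), ]
  }
  d <- d[!is.na(d$correct), ]
  if (nrow(d) == 0) {
    warning("no observed trials in the requested cells")
    return(data.frame())
  }
  cols <- c(membership = "membership", round = "round", dl = "dl",
            group = "group", novelty = "novelty", phase = "phase",
            subject = "subject_id")[by]
  agg <- stats::aggregate(d$correct, by = lapply(cols, function(cc) d[[cc]]),
                          FUN = mean)
  names(agg) <- c(names(cols), "accuracy")
  cnt <- stats::aggregate(d$correct, by = lapply(cols, function(cc) d[[cc]]),
                          FUN = length)
  agg$n_trials <- cnt$x
  agg
}

#' Median split of trait scores into low/high groups
#'
#' Scores at or below the median go to the low group; utility for
#' pipeline parity with median-split designs (simulated agents carry
#' their group by construction).
#'
#' @param scores Numeric trait scores.
#' @return Factor with levels `"low"`, `"high"`.
#' @export
median_split <- function(scores) {
  med <- stats::median(scores, na.rm = TRUE)
  factor(ifelse(scores <= med, "low", "high"), levels = c("low", "high"))
}

#' Participant-level quality-control filters
#'
#' Flags: `low_performance` when the last-training-round accuracy is
#' below the criterion AND the transfer-phase mean accuracy is also below
#' it; `guess_level` when no model fit beats the guessing model
#' meaningfully (from [select_model()]); `trait_outlier` when the trait
#' score exceeds the cohort mean by more than 3 SD or exceeds the
#' clinical cutoff. A subject is included iff no flag is set.
#'
#' @param dataset A `behavioural_dataset` or tidy trials data frame.
#' @param selections Named list (by subject) of [select_model()] results,
#'   or `NULL` to skip the guess-level flag.
#' @param trait_scores Named vector of trait scores by subject, or
#'   `NULL`.
#' @param criterion Accuracy criterion (default 0.75).
#' @param trait_cutoff Clinical trait cutoff (default 32).
#' @param last_window Number of final training rounds forming the "last
#'   block" (default 1).
#' @return A `qc_report` data frame: one row per subject with the three
#'   flags, `included` and `reasons`.
#' @export
participant_qc <- function(dataset, selections = NULL, trait_scores = NULL,
                           criterion = 0.75, trait_cutoff = 32,
                           last_window = 1L) {
  d <- if (inherits(dataset, "behavioural_dataset")) dataset$trials else
    dataset
  subjects <- unique(d$subject_id)
  if (!all(c("training", "transfer") %in% d$phase))
    stop("QC needs both training and transfer phase data", call. = FALSE)
  t_mean <- if (!is.null(trait_scores))
    mean(trait_scores, na.rm = TRUE) else NA
  t_sd <- if (!is.null(trait_scores))
    stats::sd(trait_scores, na.rm = TRUE) else NA
  rows <- lapply(subjects, function(s) {
    ds <- d[d$subject_id == s, ]
    tr <- ds[ds$phase == "training", ]
    last_rounds <- sort(unique(tr$round), decreasing = TRUE)[
      seq_len(min(last_window, length(unique(tr$round))))]
    last_acc <- mean(tr$correct[tr$round %in% last_rounds], na.rm = TRUE)
    transfer_acc <- mean(ds$correct[ds$phase == "transfer"], na.rm = TRUE)
    low_perf <- (last_acc < criterion) && (transfer_acc < criterion)
    guess <- if (!is.null(selections) && !is.null(selections[[s]]))
      isTRUE(selections[[s]]$guess_level) else FALSE
    trait <- if (!is.null(trait_scores) && !is.na(trait_scores[s])) {
      trait_scores[s] > trait_cutoff ||
        (!is.na(t_sd) && t_sd > 0 && trait_scores[s] > t_mean + 3 * t_sd)
    } else FALSE
    reasons <- c(if (low_perf) "low_performance",
                 if (guess) "guess_level",
                 if (trait) "trait_outlier")
    data.frame(subject_id = s, last_training_accuracy = last_acc,
               transfer_accuracy = transfer_acc,
               low_performance = low_perf, guess_level = guess,
               trait_outlier = trait,
               included = !(low_perf || guess || trait),
               reasons = paste(reasons, collapse = ";"))
  })
  structure(do.call(rbind, rows), class = c("qc_report", "data.frame"))
}

#' Run a parameter- and model-recovery experiment
#'
#' Fits `fit_models` to every labelled dataset of a recovery suite and
#' summarizes per-parameter bias, RMSE and 95% credible-interval
#' coverage for the generating model, plus a model-recovery confusion
#' matrix (which fitted model wins by DIC per dataset).
#'
#' @param suite Output of [make_recovery_suite()].
#' @param fit_models Models to fit to each dataset (default: the
#'   generating model only).
#' @param chains A [chain_config()]; seeds per dataset derive from it.
#' @param priors A [prior_spec()].
#' @return List with `fits` (per-dataset summaries), `parameter_recovery`
#'   (bias/RMSE/coverage per parameter), `confusion` (generating model x
#'   winning model table), `errors` (non-fatal failures).
#' @export
run_recovery <- function(suite, fit_models = suite$model,
                         chains = quick_chain_config(),
                         priors = prior_spec()) {
  results <- list()
  errors <- list()
  for (i in seq_along(suite$datasets)) {
    ds <- suite$datasets[[i]]
    per_model <- list()
    for (m in fit_models) {
      cfg <- chains
      cfg$seed <- derive_seed(chains$seed, i * 37L + match(m, fit_models))
      fit <- tryCatch(
        fit_model(m, ds$data, suite$distances, priors = priors,
                  chains = cfg),
        error = function(e) e)
      if (inherits(fit, "error")) {
        errors[[length(errors) + 1L]] <-
          list(dataset = i, model = m, message = conditionMessage(fit))
      } else per_model[[m]] <- fit
    }
    if (length(per_model) == 0) next
    dics <- vapply(per_model, function(f) f$dic$DIC, numeric(1))
    gen_fit <- per_model[[suite$model]]
    rec <- NULL
    if (!is.null(gen_fit)) {
      q <- gen_fit$quantiles
      rec <- data.frame(
        parameter = names(ds$truth),
        truth = as.numeric(ds$truth),
        estimate = as.numeric(gen_fit$posterior_mean[names(ds$truth)]),
        ci_lower = as.numeric(q["2.5%", names(ds$truth)]),
        ci_upper = as.numeric(q["97.5%", names(ds$truth)]))
      rec$covered <- rec$truth >= rec$ci_lower & rec$truth <= rec$ci_upper
    }
    results[[length(results) + 1L]] <- list(
      dataset = i, truth = ds$truth, grid_row = ds$grid_row,
      replicate = ds$replicate, dic = dics,
      winner = names(dics)[which.min(dics)], recovery = rec)
  }
  rec_all <- do.call(rbind, lapply(results, `[[`, "recovery"))
  param_summary <- if (!is.null(rec_all)) {
    do.call(rbind, lapply(split(rec_all, rec_all$parameter), function(g)
      data.frame(parameter = g$parameter[1],
                 bias = mean(g$estimate - g$truth),
                 rmse = sqrt(mean((g$estimate - g$truth)^2)),
                 coverage = mean(g$covered), n = nrow(g))))
  } else NULL
  winners <- vapply(results, `[[`, character(1), "winner")
  confusion <- table(generating = rep(suite$model, length(winners)),
                     winner = factor(winners, levels = fit_models))
  list(fits = results, parameter_recovery = param_summary,
       confusion = confusion, errors = errors)
}

#' Export trial-wise similarity vectors from a converged fit
#'
#' For each correctly categorized member trial, computes the prototype
#' and exemplar similarities at the posterior-mean parameters, and (for
#' mixture fits) the beta-weighted mixture similarity used as a single
#' parametric modulator.
#'
#' @param fit A converged `fit_result` for a mixture-family or
#'   single-route model.
#' @param set A `stimulus_set`.
#' @param trials Tidy trial data frame of the subject (any phase subset).
#' @param phase `"training"` or `"transfer"`.
#' @return Data frame `round, item_id, dl, s_proto, s_ex` plus `s_mix`
#'   when the fit has a mixture weight.
#' @export
export_similarity_vectors <- function(fit, set, trials,
                                      phase = c("training", "transfer")) {
  phase <- match.arg(phase)
  if (!isTRUE(fit$converged))
    stop("refusing to export similarity vectors from a non-converged fit",
         call. = FALSE)
  p <- as.list(fit$posterior_mean)
  dists <- stimulus_distances(set, if (phase == "training") "training"
                              else "all")
  d <- trials[trials$phase == phase & trials$role == "member" &
                !is.na(trials$correct) & trials$correct == 1, ]
  idx <- match(d$item_id, names(dists$d_proto))
  c_p <- if (!is.null(p$c_proto)) p$c_proto else p$c
  c_e <- if (!is.null(p$c_ex)) p$c_ex else p$c
  out <- data.frame(round = d$round, item_id = d$item_id, dl = d$dl,
                    s_proto = similarity_to_prototype(dists$d_proto[idx],
                                                      c_p),
                    s_ex = similarity_to_exemplars(
                      dists$d_ex[, idx, drop = FALSE], c_e))
  if (!is.null(p$beta))
    out$s_mix <- mixture_similarity_vector(out$s_proto, out$s_ex, p$beta)
  rownames(out) <- NULL
  out
}

#' Run a small end-to-end demonstration pipeline
#'
#' Generates stimuli, simulates a cohort, fits a model family to each
#' subject's transfer data, selects models, applies QC and writes all
#' tables (CSV) and metadata (JSON) to a run directory.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param n_per_group Agents per group (default 2, to keep the demo
#'   small).
#' @param models Models fitted per subject (always includes `GUESS`).
#' @param chains A [chain_config()] (default [quick_chain_config()]).
#' @return Invisibly, a list with the dataset, fits, selections and QC
#'   report.
#' @export
run_demo_pipeline <- function(out_dir, seed = 1L, n_per_group = 2L,
                              models = c("MIX", "PROTO", "EX"),
                              chains = quick_chain_config(seed = seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- cohort_config(n_per_group = n_per_group,
                       stimulus_seed = derive_seed(seed, 1L),
                       agent_seed = derive_seed(seed, 2L))
  dataset <- simulate_cohort(cfg)
  write_stimuli(dataset$stimuli, file.path(out_dir, "stimuli.json"))
  utils::write.csv(stimuli_to_df(dataset$stimuli),
                   file.path(out_dir, "stimuli.csv"), row.names = FALSE)
  utils::write.csv(dataset$trials, file.path(out_dir, "trials.csv"),
                   row.names = FALSE)
  dists <- stimulus_distances(dataset$stimuli, "all")
  subjects <- dataset$agents$subject_id
  fits <- list()
  selections <- list()
  for (s in subjects) {
    ed <- aggregate_transfer(dataset$trials, s)
    # fitting order randomized per subject (logged via the seed)
    set.seed(derive_seed(seed, 50L + match(s, subjects)))
    order_models <- sample(models)
    sfits <- lapply(order_models, function(m) {
      cfg_m <- chains
      cfg_m$seed <- derive_seed(seed, 100L * match(s, subjects) +
                                  match(m, models))
      fit_model(m, ed, dists, chains = cfg_m)
    })
    names(sfits) <- order_models
    gfit <- fit_model("GUESS", ed, dists, chains = chains)
    fits[[s]] <- c(sfits, list(GUESS = gfit))
    selections[[s]] <- select_model(sfits, gfit)
  }
  dic_tab <- do.call(rbind, lapply(subjects, function(s)
    do.call(rbind, lapply(fits[[s]], function(f) data.frame(
      subject_id = s, model = f$model, DIC = f$dic$DIC, pD = f$dic$pD,
      converged = f$converged)))))
  utils::write.csv(dic_tab, file.path(out_dir, "dic.csv"),
                   row.names = FALSE)
  trait <- stats::setNames(dataset$agents$trait_score, subjects)
  qc <- participant_qc(dataset, selections, trait)
  utils::write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
  acc <- accuracy_summary(dataset, by = c("membership", "group", "phase"))
  utils::write.csv(acc, file.path(out_dir, "accuracy.csv"),
                   row.names = FALSE)
  meta <- list(seed = seed, models = models,
               best_model = lapply(selections, `[[`, "best_model"),
               package_version = as.character(
                 utils::packageVersion("protomix")))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "run.json"))
  invisible(list(dataset = dataset, fits = fits, selections = selections,
                 qc = qc, accuracy = acc))
}

#' Summarize a completed run directory as a markdown report
#'
#' Sections: stimulus constraint check, accuracy summary, QC table, DIC
#' model-comparison table, and run provenance. Partial runs are
#' summarized with warnings for missing pieces.
#'
#' @param run_dir Directory written by [run_demo_pipeline()].
#' @param file Output file (default `report.md` inside `run_dir`).
#' @return Path to the report, invisibly.
#' @export
report <- function(run_dir, file = file.path(run_dir, "report.md")) {
  needed <- c("stimuli.json", "trials.csv", "dic.csv", "qc.csv",
              "accuracy.csv", "run.json")
  present <- file.exists(file.path(run_dir, needed))
  if (!any(present))
    stop("no run outputs found in '", run_dir, "'", call. = FALSE)
  if (!all(present))
    warning("partial run: missing ", paste(needed[!present],
                                           collapse = ", "))
  lines <- c("# Category-learning run report", "")
  fmt_table <- function(df) {
    df[] <- lapply(df, function(x) if (is.numeric(x)) round(x, 3) else x)
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                      " |")))
  }
  if (present[1]) {
    set_ <- read_stimuli(file.path(run_dir, "stimuli.json"))
    dp <- stimulus_distances(set_, "all")$d_proto
    role <- stimulus_distances(set_, "all")$role
    lines <- c(lines, "## Stimulus constraints", "",
               sprintf("- inventory size: %d patterns", length(dp)),
               sprintf("- max member distance to prototype: %.3f (limit %.2f)",
                       max(dp[role == "member"]), set_$config$member_dmax),
               sprintf("- min nonmember distance to prototype: %.3f (limit %.2f)",
                       min(dp[role == "nonmember"]),
                       set_$config$nonmember_dmin), "")
  }
  if (present[5]) {
    acc <- utils::read.csv(file.path(run_dir, "accuracy.csv"))
    lines <- c(lines, "## Accuracy summary", "", fmt_table(acc), "")
  }
  if (present[4]) {
    qc <- utils::read.csv(file.path(run_dir, "qc.csv"))
    lines <- c(lines, "## Participant QC", "", fmt_table(qc), "")
  }
  if (present[3]) {
    dic <- utils::read.csv(file.path(run_dir, "dic.csv"))
    lines <- c(lines, "## Model comparison (DIC)", "", fmt_table(dic), "")
  }
  if (present[6]) {
    meta <- jsonlite::fromJSON(file.path(run_dir, "run.json"))
    lines <- c(lines, "## Provenance", "",
               sprintf("- seed: %s", meta$seed),
               sprintf("- models fitted: %s",
                       paste(meta$models, collapse = ", ")),
               sprintf("- package version: %s", meta$package_version), "")
  }
  writeLines(lines, file)
  invisible(file)
}
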