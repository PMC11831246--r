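# Bayesian fitting of the observation models.
#
# Parameters have bounded supports with uniform priors, so the posterior
# is proportional to the likelihood on the prior box. Sampling uses a
# random-walk Metropolis algorithm with reflection at the box boundaries
# (a symmetric proposal on the box, so the acceptance ratio is the
# likelihood ratio). The chain protocol is two-stage: a short run without
# explicit initial values, whose pooled posterior quantiles seed the
# chains of the final run.

#' Uniform prior bounds for the model parameters
#'
#' Defaults: `c ~ U(0,5)` (also `c_proto`, `c_ex`), `k ~ U(0,1)`,
#' `beta ~ U(0,1)`, `gamma ~ U(0,20)`.
#'
#' @param ... Named length-2 vectors overriding individual bounds,
#'   e.g. `c = c(0, 10)`.
#' @return A `prior_spec`: named list of `c(lower, upper)` bounds.
#' @export
prior_spec <- function(...) {
  bounds <- list(c = c(0, 5), c_proto = c(0, 5), c_ex = c(0, 5),
                 k = c(0, 1), beta = c(0, 1), gamma = c(0, 20))
  over <- list(...)
  for (nm in names(over)) {
    b <- over[[nm]]
    if (length(b) != 2 || !is.finite(b[1]) || !is.finite(b[2]) || b[1] >= b[2])
      stop("prior bounds must be finite with lower < upper", call. = FALSE)
    bounds[[nm]] <- b
  }
  structure(bounds, class = "prior_spec")
}

#' MCMC chain configuration
#'
#' Defaults follow the two-stage protocol: a first stage of 4 chains x
#' 4000 iterations (burn-in 500) without explicit initial values, then a
#' final stage of 4 chains x 20000 iterations, burn-in 2500, thinning 5,
#' with chain starts taken from stage-1 posterior quantiles. If any
#' parameter's Rhat exceeds the threshold after the final stage, the fit
#' is repeated once with `escalation_iter` iterations.
#'
#' @param n_chains Number of chains (final stage).
#' @param n_iter Iterations per chain (final stage).
#' @param burn_in Burn-in iterations discarded per chain.
#' @param thin Thinning factor (keep every `thin`-th draw).
#' @param init_n_iter,init_burn_in,init_n_chains Stage-1 settings.
#' @param escalation_iter Iterations for the one-shot escalation refit.
#' @param rhat_threshold Convergence cutoff on the potential scale
#'   reduction factor.
#' @param seed Integer seed; every random step derives from it.
#' @return A `chain_config`.
#' @export
chain_config <- function(n_chains = 4L, n_iter = 20000L, burn_in = 2500L,
                         thin = 5L, init_n_iter = 4000L, init_burn_in = 500L,
                         init_n_chains = 4L, escalation_iter = 100000L,
                         rhat_threshold = 1.1, seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1,
            init_burn_in < init_n_iter)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 init_n_iter = as.integer(init_n_iter),
                 init_burn_in = as.integer(init_burn_in),
                 init_n_chains = as.integer(init_n_chains),
                 escalation_iter = as.integer(escalation_iter),
                 rhat_threshold = rhat_threshold, seed = as.integer(seed)),
            class = "chain_config")
}

#' A quick chain configuration for small problems
#'
#' Reduced iteration counts (4 chains x 4000, burn-in 500, stage-1
#' 4 x 1000) for simulation studies and examples where many fits are run.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [chain_config()].
#' @return A `chain_config`.
#' @export
quick_chain_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_chains = 4L, n_iter = 4000L, burn_in = 500L, thin = 5L,
         init_n_iter = 1000L, init_burn_in = 200L, escalation_iter = 12000L,
         seed = seed),
    list(...))
  do.call(chain_config, args)
}

# Lean log-likelihood closure for the sampler: distances aligned and
# missing trials dropped once, parameters positional, no per-call
# validation (bounds are enforced by the sampler's prior box). Must agree
# with log_likelihood() to machine precision; tested against it.
make_fast_loglik <- function(model, data, distances, gamma_scope = "both") {
  dd <- align_distances(data, distances)
  ok <- !is.na(data$y)
  dp <- unname(dd$d_proto[ok])
  De <- dd$d_ex[, ok, drop = FALSE]
  dimnames(De) <- NULL
  y <- unname(data$y[ok])
  ny <- unname(data$n[ok]) - y
  both <- identical(gamma_scope, "both")
  bern <- function(r) {
    r[r < 1e-12] <- 1e-12
    r[r > 1 - 1e-12] <- 1 - 1e-12
    sum(y * log(r) + ny * log(1 - r))
  }
  switch(model,
    PROTO = function(th) {
      sp <- exp(-th[1] * dp)
      bern(sp / (sp + th[2]))
    },
    EX = function(th) {
      s <- colSums(exp(-th[1] * De))
      bern(s / (s + th[2]))
    },
    EX_G = function(th) {
      s <- colSums(exp(-th[1] * De))^th[3]
      bern(s / (s + th[2]^th[3]))
    },
    MIX = function(th) {
      sp <- exp(-th[1] * dp)
      se <- colSums(exp(-th[1] * De))
      bern(th[3] * sp / (sp + th[2]) + (1 - th[3]) * se / (se + th[2]))
    },
    MIX_2C = function(th) {
      sp <- exp(-th[1] * dp)
      se <- colSums(exp(-th[2] * De))
      bern(th[4] * sp / (sp + th[3]) + (1 - th[4]) * se / (se + th[3]))
    },
    MIX_G = function(th) {
      g <- th[4]
      kg <- th[2]^g
      sp <- if (both) exp(-th[1] * dp)^g else exp(-th[1] * dp)
      se <- colSums(exp(-th[1] * De))^g
      rp <- if (both) sp / (sp + kg) else sp / (sp + th[2])
      bern(th[3] * rp + (1 - th[3]) * se / (se + kg))
    },
    MIX_2C_G = function(th) {
      g <- th[5]
      kg <- th[3]^g
      sp <- if (both) exp(-th[1] * dp)^g else exp(-th[1] * dp)
      se <- colSums(exp(-th[2] * De))^g
      rp <- if (both) sp / (sp + kg) else sp / (sp + th[3])
      bern(th[4] * rp + (1 - th[4]) * se / (se + kg))
    },
    stop("no fast likelihood for model ", model, call. = FALSE))
}

# Deterministic per-chain seed derivation, kept inside 32-bit range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 1009 + 7) %% 2147483629)
}

# One random-walk Metropolis chain on the prior box. Reflection at the
# bounds keeps the proposal symmetric. Proposal scales adapt toward an
# acceptance rate of ~0.3 during burn-in only.
run_chain <- function(loglik, lower, upper, init, n_iter, burn_in, thin,
                      seed) {
  set.seed(seed)
  npar <- length(lower)
  width <- upper - lower
  scale <- width / 10
  theta <- init
  ll <- loglik(theta)
  if (!is.finite(ll)) {
    # fall back to prior draws until the likelihood is finite
    for (try in 1:100) {
      theta <- lower + stats::runif(npar) * width
      ll <- loglik(theta)
      if (is.finite(ll)) break
    }
    if (!is.finite(ll))
      stop("non-finite likelihood at all initialization points",
           call. = FALSE)
  }
  kept <- matrix(NA_real_, nrow = floor((n_iter - burn_in) / thin),
                 ncol = npar)
  accepted <- 0L
  window_acc <- 0L
  k_row <- 0L
  for (it in seq_len(n_iter)) {
    prop <- theta + stats::rnorm(npar, 0, scale)
    # reflect into [lower, upper]
    p <- (prop - lower) %% (2 * width)
    prop <- lower + width - abs(p - width)
    ll_prop <- loglik(prop)
    if (is.finite(ll_prop) && log(stats::runif(1)) < ll_prop - ll) {
      theta <- prop
      ll <- ll_prop
      accepted <- accepted + 1L
      window_acc <- window_acc + 1L
    }
    if (it <= burn_in && it %% 50L == 0L) {
      rate <- window_acc / 50
      scale <- scale * exp(0.5 * (rate - 0.3))
      scale <- pmin(pmax(scale, width * 1e-4), width)
      window_acc <- 0L
    }
    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      k_row <- k_row + 1L
      kept[k_row, ] <- theta
    }
  }
  list(draws = kept, acceptance = accepted / n_iter)
}

#' Split-chain potential scale reduction factor (Rhat)
#'
#' Gelman-Rubin diagnostic computed after splitting each chain in half.
#' Degenerate chains with zero variance everywhere return exactly 1.
#'
#' @param chains List of numeric vectors (one per chain, same parameter)
#'   or of matrices (draws x parameters).
#' @return Rhat per parameter (scalar for vector input).
#' @export
compute_rhat <- function(chains) {
  if (length(chains) < 2) stop("need at least 2 chains", call. = FALSE)
  if (is.matrix(chains[[1]])) {
    npar <- ncol(chains[[1]])
    return(vapply(seq_len(npar), function(j)
      compute_rhat(lapply(chains, function(m) m[, j])), numeric(1)))
  }
  n <- min(lengths(chains))
  if (n < 10) stop("need at least 10 draws per chain", call. = FALSE)
  half <- floor(n / 2)
  splits <- unlist(lapply(chains, function(x)
    list(x[seq_len(half)], x[(half + 1):(2 * half)])), recursive = FALSE)
  m <- length(splits)
  means <- vapply(splits, mean, numeric(1))
  vars <- vapply(splits, stats::var, numeric(1))
  W <- mean(vars)
  B <- half * stats::var(means)
  if (!is.finite(W) || W <= 0) {
    if (is.finite(B) && B > 0) return(Inf)
    return(1)
  }
  var_plus <- (half - 1) / half * W + B / half
  sqrt(var_plus / W)
}

#' Deviance information criterion from posterior draws
#'
#' `Dbar` is the posterior mean deviance (`-2 log L` averaged over
#' draws), `Dhat` the deviance at the posterior parameter means,
#' `pD = Dbar - Dhat` the effective number of parameters and
#' `DIC = Dbar + pD`. Non-finite deviance draws are excluded with a
#' warning; more than 10% non-finite is an error.
#'
#' @param model Model name.
#' @param data An [endorsement_data()] object.
#' @param distances Distance structure.
#' @param draws Matrix of posterior draws (draws x parameters, named
#'   columns); ignored for `GUESS`.
#' @param gamma_scope See [endorsement_probability()].
#' @return List with `Dbar`, `Dhat`, `pD`, `DIC`.
#' @export
compute_dic <- function(model, data, distances, draws = NULL,
                        gamma_scope = "both") {
  if (model == "GUESS") {
    n_trials <- sum(data$n[!is.na(data$y)])
    D <- 2 * n_trials * log(2)
    return(list(Dbar = D, Dhat = D, pD = 0, DIC = D))
  }
  stopifnot(is.matrix(draws), nrow(draws) >= 1)
  draws <- draws[, model_parameters(model), drop = FALSE]
  fl <- make_fast_loglik(model, data, distances, gamma_scope = gamma_scope)
  dev <- -2 * apply(draws, 1, fl)
  bad <- !is.finite(dev)
  if (any(bad)) {
    if (mean(bad) > 0.1)
      stop("more than 10% of deviance draws are non-finite", call. = FALSE)
    warning(sum(bad), " non-finite deviance draws excluded")
    dev <- dev[!bad]
    draws <- draws[!bad, , drop = FALSE]
  }
  Dbar <- mean(dev)
  Dhat <- -2 * log_likelihood(model, colMeans(draws), data, distances,
                              gamma_scope = gamma_scope)
  pD <- Dbar - Dhat
  list(Dbar = Dbar, Dhat = Dhat, pD = pD, DIC = Dbar + pD)
}

#' Fit one model to one subject's endorsement data
#'
#' Two-stage MCMC under uniform priors. Stage 1 runs short chains started
#' from random prior draws; the pooled stage-1 posterior quantiles at
#' 2.5%, 25%, 75% and 97.5% provide the initial values of the final
#' chains (the 50% quantile is computed but not used as a start when four
#' chains are run; extra chains recycle the quantile list including the
#' median). After the final run, split-chain Rhat is checked per
#' parameter; if any exceeds the threshold the final stage is repeated
#' once with `escalation_iter` iterations. Non-convergence after
#' escalation is reported via `converged = FALSE`, never an error.
#'
#' The parameterless guessing model is not sampled: its deviance is
#' computed analytically.
#'
#' @param model Model name, see [model_names()].
#' @param data An [endorsement_data()] object with at least one observed
#'   trial.
#' @param distances Distance structure from [stimulus_distances()].
#' @param priors A [prior_spec()].
#' @param chains A [chain_config()].
#' @param gamma_scope See [endorsement_probability()].
#' @return A `fit_result`: posterior draw matrix, per-parameter means and
#'   `{2.5, 25, 50, 75, 97.5}%` quantiles, Rhat, effective sample size,
#'   DIC components, and a `converged` flag.
#' @export
fit_model <- function(model, data, distances, priors = prior_spec(),
                      chains = chain_config(), gamma_scope = "both") {
  model <- match.arg(model, model_names())
  if (all(is.na(data$y))) stop("all responses are missing", call. = FALSE)

  if (model == "GUESS") {
    dic <- compute_dic("GUESS", data, distances)
    return(structure(list(
      model = model, draws = NULL, posterior_mean = numeric(0),
      quantiles = NULL, rhat = numeric(0), ess = numeric(0), dic = dic,
      converged = TRUE, escalated = FALSE, n_iter_used = 0L,
      seed = chains$seed), class = "fit_result"))
  }

  par_names <- model_parameters(model)
  lower <- vapply(par_names, function(nm) priors[[nm]][1], numeric(1))
  upper <- vapply(par_names, function(nm) priors[[nm]][2], numeric(1))
  # k = 0 makes r = s/(s+k) degenerate; keep the sampler strictly inside
  eps <- 1e-9 * (upper - lower)
  lower_s <- lower + eps
  upper_s <- upper - eps
  loglik <- make_fast_loglik(model, data, distances,
                             gamma_scope = gamma_scope)

  run_stage <- function(n_iter, burn_in, n_chains, inits, seed_off) {
    out <- lapply(seq_len(n_chains), function(ch) {
      run_chain(loglik, lower_s, upper_s, inits[[ch]],
                n_iter = n_iter, burn_in = burn_in, thin = chains$thin,
                seed = derive_seed(chains$seed, seed_off + ch))
    })
    lapply(out, function(o) {
      colnames(o$draws) <- par_names
      o$draws
    })
  }

  # stage 1: no explicit inits (random prior draws)
  stage1_inits <- lapply(seq_len(chains$init_n_chains), function(ch) {
    set.seed(derive_seed(chains$seed, 900 + ch))
    lower_s + stats::runif(length(par_names)) * (upper_s - lower_s)
  })
  stage1 <- run_stage(chains$init_n_iter, chains$init_burn_in,
                      chains$init_n_chains, stage1_inits, seed_off = 0L)
  pooled <- do.call(rbind, stage1)
  qprobs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  qmat <- apply(pooled, 2, stats::quantile, probs = qprobs)
  # quantile rows -> chain inits; with 4 chains the median row is unused
  init_rows <- if (chains$n_chains == 4L) c(1L, 2L, 4L, 5L) else
    rep_len(seq_len(5L), chains$n_chains)
  final_inits <- lapply(init_rows, function(i)
    pmin(pmax(qmat[i, ], lower_s), upper_s))

  run_final <- function(n_iter, seed_off) {
    draws_by_chain <- run_stage(n_iter, chains$burn_in, chains$n_chains,
                                final_inits, seed_off = seed_off)
    rhat <- compute_rhat(draws_by_chain)
    names(rhat) <- par_names
    list(chains = draws_by_chain, rhat = rhat)
  }
  fin <- run_final(chains$n_iter, seed_off = 100L)
  escalated <- FALSE
  if (any(fin$rhat > chains$rhat_threshold)) {
    fin <- run_final(chains$escalation_iter, seed_off = 200L)
    escalated <- TRUE
  }
  draws <- do.call(rbind, fin$chains)
  converged <- all(fin$rhat <= chains$rhat_threshold)
  ess <- vapply(par_names, function(nm)
    ess_basic(lapply(fin$chains, function(m) m[, nm])), numeric(1))
  dic <- compute_dic(model, data, distances, draws,
                     gamma_scope = gamma_scope)
  structure(list(
    model = model, draws = draws,
    posterior_mean = colMeans(draws),
    quantiles = apply(draws, 2, stats::quantile, probs = qprobs),
    rhat = fin$rhat, ess = ess, dic = dic, converged = converged,
    escalated = escalated,
    n_iter_used = if (escalated) chains$escalation_iter else chains$n_iter,
    init_quantiles = qmat, seed = chains$seed), class = "fit_result")
}

# Crude effective sample size from lag-autocorrelations (Geyer initial
# positive sequence, capped at lag 50).
ess_basic <- function(chains) {
  x <- unlist(chains)
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(50, n - 1), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  cutoff <- if (length(pos)) pos[1] - 1 else length(ac)
  n / (1 + 2 * sum(ac[seq_len(cutoff)]))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s: DIC = %.2f (pD = %.2f), converged = %s>\n",
              x$model, x$dic$DIC, x$dic$pD, x$converged))
  if (length(x$posterior_mean)) {
    cat("posterior means:\n")
    print(round(x$posterior_mean, 4))
  }
  invisible(x)
}

#' Rank model fits by DIC and flag guess-level subjects
#'
#' Converged fits are ranked by DIC (ascending). Near-ties (DIC within
#' `tie_epsilon`) are broken toward the model with fewer free parameters.
#' A subject is flagged `guess_level` when the best model's DIC is not at
#' least `delta_guess` below the guessing model's DIC. Non-converged fits
#' are excluded from ranking but reported.
#'
#' @param fits List of `fit_result` objects (the substantive models).
#' @param guessing_fit The guessing-model `fit_result`.
#' @param delta_guess Minimum DIC advantage over guessing (default 2).
#' @param tie_epsilon DIC difference treated as a tie (default 2).
#' @return List with `table` (model, DIC, pD, converged, n_params, rank),
#'   `best_model`, `guess_level`, `excluded`.
#' @export
select_model <- function(fits, guessing_fit, delta_guess = 2,
                         tie_epsilon = 2) {
  stopifnot(length(fits) >= 1)
  tab <- do.call(rbind, lapply(fits, function(f) data.frame(
    model = f$model, DIC = f$dic$DIC, pD = f$dic$pD,
    converged = f$converged,
    n_params = length(model_parameters(f$model)))))
  tab <- rbind(tab, data.frame(
    model = "GUESS", DIC = guessing_fit$dic$DIC, pD = guessing_fit$dic$pD,
    converged = TRUE, n_params = 0L))
  cand <- tab[tab$converged & tab$model != "GUESS", , drop = FALSE]
  if (nrow(cand) == 0)
    stop("no converged model fits to rank", call. = FALSE)
  # tie-break toward fewer parameters: sort by DIC coarsened to tie groups
  ord <- order(cand$DIC, cand$n_params)
  cand <- cand[ord, , drop = FALSE]
  for (i in seq_len(nrow(cand) - 1)) {
    if (i >= nrow(cand)) break
    j <- i + 1
    if (abs(cand$DIC[j] - cand$DIC[i]) < tie_epsilon &&
        cand$n_params[j] < cand$n_params[i]) {
      cand[c(i, j), ] <- cand[c(j, i), ]
    }
  }
  cand$rank <- seq_len(nrow(cand))
  best <- cand$model[1]
  guess_level <- !(cand$DIC[1] <= guessing_fit$dic$DIC - delta_guess)
  list(table = merge(tab, cand[, c("model", "rank")], all.x = TRUE,
                     sort = FALSE),
       best_model = best, guess_level = guess_level,
       excluded = tab$model[!tab$converged])
}
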