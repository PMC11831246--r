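# Observation models for single-category endorsement decisions.
#
# Perceptual similarity decays exponentially with distance, s = exp(-c d).
# The prototype model carries similarity to the prototype only; the
# exemplar model sums similarity over the training exemplars; mixture
# models weight the two endorsement routes by beta. Endorsement
# probability follows r = s / (s + k) with criterion k, optionally
# sharpened by a response-scaling exponent gamma.

.MODEL_PARAMS <- list(
  PROTO    = c("c", "k"),
  EX       = c("c", "k"),
  EX_G     = c("c", "k", "gamma"),
  MIX      = c("c", "k", "beta"),
  MIX_2C   = c("c_proto", "c_ex", "k", "beta"),
  MIX_G    = c("c", "k", "beta", "gamma"),
  MIX_2C_G = c("c_proto", "c_ex", "k", "beta", "gamma"),
  GUESS    = character(0)
)

#' Names of the available model variants
#' @return Character vector of model names.
#' @export
model_names <- function() names(.MODEL_PARAMS)

#' Free parameters of a model variant
#'
#' @param model One of `"PROTO"`, `"EX"`, `"EX_G"`, `"MIX"`, `"MIX_2C"`,
#'   `"MIX_G"`, `"MIX_2C_G"`, `"GUESS"`.
#' @return Character vector of free parameter names (empty for `GUESS`).
#' @export
model_parameters <- function(model) {
  model <- match.arg(model, model_names())
  .MODEL_PARAMS[[model]]
}

# Validate a named parameter vector/list against a model's free parameters
# and the hard domains: c >= 0, k in (0,1], beta in [0,1], gamma > 0.
check_params <- function(model, params) {
  need <- model_parameters(model)
  params <- unlist(params)
  missing <- setdiff(need, names(params))
  if (length(missing))
    stop("model ", model, " needs parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  p <- as.list(params[need])
  for (nm in intersect(c("c", "c_proto", "c_ex"), need))
    if (p[[nm]] < 0) stop("sensitivity must be non-negative", call. = FALSE)
  if ("k" %in% need && (p$k <= 0 || p$k > 1))
    stop("criterion k must lie in (0, 1]", call. = FALSE)
  if ("beta" %in% need && (p$beta < 0 || p$beta > 1))
    stop("mixture weight beta must lie in [0, 1]", call. = FALSE)
  if ("gamma" %in% need && p$gamma <= 0)
    stop("response scaling gamma must be positive", call. = FALSE)
  p
}

#' Similarity of an item to the prototype
#'
#' `s = exp(-c d)`: exponential decay of perceptual similarity with
#' distance, strictly decreasing in `d` for `c > 0`.
#'
#' @param d Distance(s) to the prototype, non-negative.
#' @param c Sensitivity parameter, non-negative.
#' @return Similarity in `(0, 1]`, vectorized over `d`.
#' @export
similarity_to_prototype <- function(d, c) {
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  if (c < 0) stop("sensitivity must be non-negative", call. = FALSE)
  exp(-c * d)
}

#' Summed similarity of an item to the training exemplars
#'
#' `s = sum_j exp(-c d_j)` over the exemplar set. For a training item
#' evaluated against a set containing itself the self-term contributes
#' exactly 1.
#'
#' @param d Distances to the exemplars: a vector (one item) or a matrix
#'   with one column per item and one row per exemplar.
#' @param c Sensitivity parameter, non-negative.
#' @return Non-negative summed similarity (may exceed 1), one value per
#'   item.
#' @export
similarity_to_exemplars <- function(d, c) {
  if (length(d) == 0) stop("exemplar set must be non-empty", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  if (c < 0) stop("sensitivity must be non-negative", call. = FALSE)
  if (is.matrix(d)) colSums(exp(-c * d)) else sum(exp(-c * d))
}

# One endorsement route r = s^gamma / (s^gamma + k^gamma).
route_probability <- function(s, k, gamma = 1) {
  sg <- s^gamma
  sg / (sg + k^gamma)
}

#' Endorsement probability under a model variant
#'
#' Computes `r` from precomputed similarity components. For `PROTO`
#' `r = s_p/(s_p+k)`; for `EX` `r = s_e/(s_e+k)`; gamma variants raise the
#' similarity component(s) and `k` to the power gamma; mixture variants
#' return `beta * r_proto + (1-beta) * r_ex`; `GUESS` returns 0.5
#' everywhere.
#'
#' For the two-sensitivity variants the caller must supply `s_proto` and
#' `s_ex` already computed with `c_proto` and `c_ex` (see
#' [model_predict()], which handles this from distances).
#'
#' @param model Model name, see [model_names()].
#' @param params Named parameter vector or list (see
#'   [model_parameters()]).
#' @param s_proto Similarity to the prototype, in `(0, 1]`.
#' @param s_ex Summed similarity to the exemplars, non-negative.
#' @param gamma_scope Whether gamma scales only the exemplar route
#'   (`"exemplar_only"`) or both routes (`"both"`, the default) in the
#'   gamma mixture variants.
#' @return Endorsement probabilities in `(0, 1)`, vectorized over items.
#' @export
endorsement_probability <- function(model, params, s_proto = NULL,
                                    s_ex = NULL,
                                    gamma_scope = c("both", "exemplar_only")) {
  model <- match.arg(model, model_names())
  gamma_scope <- match.arg(gamma_scope)
  if (model == "GUESS") {
    n <- max(length(s_proto), length(s_ex), 1L)
    return(rep(0.5, n))
  }
  p <- check_params(model, params)
  gamma <- if ("gamma" %in% names(p)) p$gamma else 1
  switch(model,
    PROTO = route_probability(s_proto, p$k),
    EX = route_probability(s_ex, p$k),
    EX_G = route_probability(s_ex, p$k, gamma),
    MIX = , MIX_2C = , MIX_G = , MIX_2C_G = {
      g_proto <- if (gamma_scope == "both") gamma else 1
      r_p <- route_probability(s_proto, p$k, g_proto)
      r_e <- route_probability(s_ex, p$k, gamma)
      p$beta * r_p + (1 - p$beta) * r_e
    })
}

#' Per-item endorsement probabilities from a distance structure
#'
#' Computes the similarity components with the model's own sensitivity
#' parameter(s) (`c`, or `c_proto`/`c_ex` for the two-sensitivity
#' variants) and applies [endorsement_probability()].
#'
#' @param model Model name.
#' @param params Named parameters.
#' @param distances A distance structure from [stimulus_distances()], or
#'   any list with `d_proto` (named vector) and `d_ex` (exemplar x item
#'   matrix).
#' @param gamma_scope See [endorsement_probability()].
#' @return Named vector of endorsement probabilities over the items.
#' @export
model_predict <- function(model, params, distances,
                          gamma_scope = c("both", "exemplar_only")) {
  model <- match.arg(model, model_names())
  if (model == "GUESS")
    return(stats::setNames(rep(0.5, length(distances$d_proto)),
                           names(distances$d_proto)))
  p <- check_params(model, params)
  c_p <- if (!is.null(p$c_proto)) p$c_proto else p$c
  c_e <- if (!is.null(p$c_ex)) p$c_ex else p$c
  s_p <- similarity_to_prototype(distances$d_proto, c_p)
  s_e <- similarity_to_exemplars(distances$d_ex, c_e)
  r <- endorsement_probability(model, params, s_proto = s_p, s_ex = s_e,
                               gamma_scope = gamma_scope)
  stats::setNames(r, names(distances$d_proto))
}

#' Endorsement data for one subject and phase
#'
#' Training-phase data are binary per-item responses from a single round;
#' transfer-phase data are per-item endorsement counts over the observed
#' transfer rounds. Timeout trials are recorded as `NA` and dropped from
#' likelihoods.
#'
#' @param item_id Item identifiers (no duplicates).
#' @param response Binary responses in `{0, 1, NA}` (training phase).
#' @param count Endorsement counts (transfer phase).
#' @param n_rounds Rounds-observed denominators, scalar or per item
#'   (transfer phase).
#' @param phase `"training"` or `"transfer"`.
#' @return An `endorsement_data` object.
#' @export
endorsement_data <- function(item_id, response = NULL, count = NULL,
                             n_rounds = NULL,
                             phase = c("training", "transfer")) {
  phase <- match.arg(phase)
  item_id <- as.character(item_id)
  if (anyDuplicated(item_id)) stop("duplicated item ids", call. = FALSE)
  if (phase == "training") {
    if (is.null(response) || length(response) != length(item_id))
      stop("training data need one binary response per item", call. = FALSE)
    if (!all(response %in% c(0, 1) | is.na(response)))
      stop("responses must be 0, 1 or NA", call. = FALSE)
    obj <- list(phase = phase, item_id = item_id,
                y = as.numeric(response), n = rep(1, length(item_id)))
  } else {
    if (is.null(count) || is.null(n_rounds))
      stop("transfer data need counts and round denominators", call. = FALSE)
    n <- rep_len(n_rounds, length(item_id))
    if (any(count < 0 | count > n, na.rm = TRUE))
      stop("counts must lie in [0, n_rounds]", call. = FALSE)
    obj <- list(phase = phase, item_id = item_id,
                y = as.numeric(count), n = as.numeric(n))
  }
  structure(obj, class = "endorsement_data")
}

#' @export
print.endorsement_data <- function(x, ...) {
  cat(sprintf("<endorsement_data: %s phase, %d items, %d observed trials>\n",
              x$phase, length(x$item_id), sum(x$n[!is.na(x$y)])))
  invisible(x)
}

# Align a distance structure to the items of an endorsement_data object.
align_distances <- function(data, distances) {
  idx <- match(data$item_id, names(distances$d_proto))
  if (anyNA(idx))
    stop("items missing from distance table: ",
         paste(data$item_id[is.na(idx)], collapse = ", "), call. = FALSE)
  list(d_proto = distances$d_proto[idx],
       d_ex = distances$d_ex[, idx, drop = FALSE])
}

#' Log-likelihood of endorsement data under a model
#'
#' Bernoulli log-likelihood of binary responses (training phase) or
#' binomial-kernel log-likelihood of endorsement counts over the round
#' denominators (transfer phase). The binomial normalizing constant is
#' omitted so that a transfer item observed over `n` rounds contributes
#' exactly as `n` Bernoulli trials would; deviances are then directly
#' comparable across phases and the guessing model's deviance is
#' `2 N log 2` for `N` Bernoulli-equivalent trials. Missing (timeout)
#' responses are dropped. Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` inside the likelihood only.
#'
#' @param model Model name.
#' @param params Named parameters (ignored for `GUESS`).
#' @param data An [endorsement_data()] object.
#' @param distances Distance structure containing all items of `data`.
#' @param gamma_scope See [endorsement_probability()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(model, params, data, distances,
                           gamma_scope = c("both", "exemplar_only")) {
  dd <- align_distances(data, distances)
  r <- model_predict(model, params, dd, gamma_scope = gamma_scope)
  ok <- !is.na(data$y)
  r <- pmin(pmax(r[ok], 1e-12), 1 - 1e-12)
  sum(data$y[ok] * log(r) + (data$n[ok] - data$y[ok]) * log(1 - r))
}

#' Beta-weighted mixture similarity vector
#'
#' `s_mix = beta * s_proto + (1 - beta) * s_ex`, the single parametric
#' modulator used when the two similarity vectors are too correlated to
#' separate.
#'
#' @param s_proto,s_ex Similarity vectors of equal length.
#' @param beta Mixture weight in `[0, 1]`.
#' @return Numeric vector `s_mix`.
#' @export
mixture_similarity_vector <- function(s_proto, s_ex, beta) {
  if (length(s_proto) != length(s_ex))
    stop("similarity vectors must have equal length", call. = FALSE)
  if (beta < 0 || beta > 1)
    stop("mixture weight beta must lie in [0, 1]", call. = FALSE)
  beta * s_proto + (1 - beta) * s_ex
}

#' Correlation between prototype and exemplar similarity vectors
#'
#' Pearson correlation over an item subset; used to decide whether the two
#' vectors are separable enough to serve as distinct trial-wise
#' modulators.
#'
#' @param s_proto,s_ex Similarity vectors of equal length.
#' @param subset Indices or logical mask selecting at least 3 items
#'   (default: all).
#' @return Pearson correlation coefficient.
#' @export
similarity_correlation <- function(s_proto, s_ex, subset = NULL) {
  if (length(s_proto) != length(s_ex))
    stop("similarity vectors must have equal length", call. = FALSE)
  if (!is.null(subset)) {
    s_proto <- s_proto[subset]
    s_ex <- s_ex[subset]
  }
  if (length(s_proto) < 3)
    stop("need at least 3 items to correlate", call. = FALSE)
  if (stats::sd(s_proto) == 0 || stats::sd(s_ex) == 0)
    stop("similarity vector has zero variance; correlation undefined",
         call. = FALSE)
  stats::cor(s_proto, s_ex)
}

#' Distance structure of a stimulus set
#'
#' Prototype-relative distances and the exemplar distance matrix (training
#' members are the exemplar set) for the items of a phase.
#'
#' @param set A `stimulus_set`.
#' @param phase `"all"` (transfer inventory) or `"training"`.
#' @return List with `d_proto` (named vector), `d_ex` (12 exemplars x
#'   items matrix), `role` and `dl` per item.
#' @export
stimulus_distances <- function(set, phase = "all") {
  pats <- stimulus_patterns(set, phase)
  ex_ids <- vapply(set$training_members, `[[`, character(1), "id")
  d_proto <- vapply(pats, pattern_distance, numeric(1), b = set$prototype)
  d_ex <- vapply(pats, function(p)
    vapply(set$training_members, pattern_distance, numeric(1), b = p),
    numeric(length(ex_ids)))
  rownames(d_ex) <- ex_ids
  list(d_proto = d_proto, d_ex = d_ex,
       role = vapply(pats, `[[`, character(1), "role"),
       dl = vapply(pats, `[[`, integer(1), "distortion_level"))
}
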