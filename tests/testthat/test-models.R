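test_that("similarity functions match their closed forms", {
  expect_identical(similarity_to_prototype(0, 2), 1)
  expect_identical(similarity_to_prototype(3.7, 0), 1)
  expect_equal(similarity_to_prototype(2, 0.5), exp(-1))
  expect_error(similarity_to_prototype(-1, 1), "non-negative")
  expect_error(similarity_to_prototype(1, -0.1), "non-negative")

  expect_identical(similarity_to_exemplars(rep(3, 12), 0), 12)
  expect_identical(similarity_to_exemplars(0, 1), 1)
  expect_equal(similarity_to_exemplars(c(1, 2), 1), exp(-1) + exp(-2))
  expect_error(similarity_to_exemplars(numeric(0), 1), "non-empty")
  # matrix form: one value per item column
  m <- cbind(a = c(1, 2), b = c(0, 0))
  expect_equal(similarity_to_exemplars(m, 1),
               c(a = exp(-1) + exp(-2), b = 2))
})

test_that("endorsement probabilities follow the similarity-criterion rule", {
  expect_equal(endorsement_probability("GUESS", NULL,
                                       s_proto = runif(10)),
               rep(0.5, 10))
  # balance point: s equal to k gives one half
  expect_equal(endorsement_probability("PROTO", c(c = 1, k = 0.4),
                                       s_proto = 0.4), 0.5)
  # monotone in s, antitone in k
  s <- seq(0.05, 0.95, by = 0.1)
  r <- endorsement_probability("PROTO", c(c = 1, k = 0.3), s_proto = s)
  expect_true(all(diff(r) > 0))
  r2 <- endorsement_probability("PROTO", c(c = 1, k = 0.6), s_proto = s)
  expect_true(all(r2 < r))
  # mixture moves monotonically toward the larger component with beta
  for (b in seq(0, 1, by = 0.25)) {
    r_m <- endorsement_probability("MIX", c(c = 1, k = 0.3, beta = b),
                                   s_proto = 0.8, s_ex = 0.1)
    r_p <- endorsement_probability("PROTO", c(c = 1, k = 0.3),
                                   s_proto = 0.8)
    r_e <- endorsement_probability("EX", c(c = 1, k = 0.3), s_ex = 0.1)
    expect_equal(r_m, b * r_p + (1 - b) * r_e)
  }
  expect_error(endorsement_probability("PROTO", c(c = 1, k = 0),
                                       s_proto = 0.5), "criterion")
  expect_error(endorsement_probability("MIX", c(c = 1, k = 0.5, beta = 1.2),
                                       s_proto = 0.5, s_ex = 0.5), "beta")
})

test_that("model variants reduce to their restricted versions at boundary parameters", {
  dists <- test_distances()
  set.seed(11)
  for (i in 1:25) {
    c_ <- runif(1, 0.01, 5); k_ <- runif(1, 0.01, 1); g_ <- runif(1, 0.1, 20)
    expect_equal(model_predict("MIX", c(c = c_, k = k_, beta = 1), dists),
                 model_predict("PROTO", c(c = c_, k = k_), dists))
    expect_equal(model_predict("MIX", c(c = c_, k = k_, beta = 0), dists),
                 model_predict("EX", c(c = c_, k = k_), dists))
    b_ <- runif(1)
    expect_equal(model_predict("MIX_2C",
                               c(c_proto = c_, c_ex = c_, k = k_, beta = b_),
                               dists),
                 model_predict("MIX", c(c = c_, k = k_, beta = b_), dists))
    expect_equal(model_predict("EX_G", c(c = c_, k = k_, gamma = 1), dists),
                 model_predict("EX", c(c = c_, k = k_), dists))
    expect_equal(model_predict("MIX_G",
                               c(c = c_, k = k_, beta = b_, gamma = 1),
                               dists),
                 model_predict("MIX", c(c = c_, k = k_, beta = b_), dists))
  }
})

test_that("all endorsement probabilities stay inside (0,1) for admissible parameters", {
  dists <- test_distances()
  set.seed(12)
  for (m in setdiff(model_names(), "GUESS")) {
    for (i in 1:20) {
      # full admissible box: probabilities are finite and in [0, 1]
      # (extreme gamma on far items can underflow a route to exactly 0
      # in double precision)
      r <- model_predict(m, random_params(m), dists)
      expect_true(all(is.finite(r) & r >= 0 & r <= 1))
      # moderate parameters: strictly inside the open interval
      p <- random_params(m)
      p[names(p) %in% c("c", "c_proto", "c_ex")] <- runif(1, 0.01, 2)
      if ("gamma" %in% names(p)) p["gamma"] <- runif(1, 0.1, 4)
      r <- model_predict(m, p, dists)
      expect_true(all(r > 0 & r < 1))
    }
  }
})

test_that("log-likelihood has the guessing closed form and is order-invariant", {
  dists <- toy_distances()
  ed <- endorsement_data(c("i1", "i2", "i3"), response = c(1, 0, 1),
                         phase = "training")
  expect_equal(log_likelihood("GUESS", NULL, ed, dists), 3 * log(0.5))
  # 24 binary trials at chance
  d24 <- list(d_proto = setNames(runif(24, 1, 5), paste0("x", 1:24)),
              d_ex = matrix(runif(48, 1, 5), nrow = 2,
                            dimnames = list(NULL, paste0("x", 1:24))))
  ed24 <- endorsement_data(paste0("x", 1:24),
                           response = rep(c(0, 1), 12), phase = "training")
  expect_equal(log_likelihood("GUESS", NULL, ed24, d24), 24 * log(0.5),
               tolerance = 1e-12)
  # permutation invariance
  perm <- c(2, 3, 1)
  ed_p <- endorsement_data(c("i2", "i3", "i1"),
                           response = c(0, 1, 1), phase = "training")
  p <- c(c = 0.7, k = 0.3, beta = 0.4)
  expect_equal(log_likelihood("MIX", p, ed, dists),
               log_likelihood("MIX", p, ed_p, dists))
})

test_that("timeout responses are dropped from the likelihood", {
  dists <- toy_distances()
  p <- c(c = 0.7, k = 0.3)
  with_na <- endorsement_data(c("i1", "i2", "i3"),
                              response = c(1, NA, 0), phase = "training")
  without <- endorsement_data(c("i1", "i3"), response = c(1, 0),
                              phase = "training")
  expect_equal(log_likelihood("PROTO", p, with_na, dists),
               log_likelihood("PROTO", p, without, dists))
})

test_that("likelihood approaches zero from below for near-deterministic agreement", {
  dists <- toy_distances()
  # strong sensitivity: members endorsed, nonmember rejected, data agree
  ed <- endorsement_data(c("i1", "i2", "i3"), count = c(8, 8, 0),
                         n_rounds = 8, phase = "transfer")
  ll <- log_likelihood("PROTO", c(c = 4, k = 0.001), ed,
                       list(d_proto = c(i1 = 0, i2 = 0, i3 = 11),
                            d_ex = dists$d_ex))
  expect_true(ll < 0 && ll > -0.1)
})

test_that("endorsement data constructors validate their invariants", {
  expect_error(endorsement_data(c("a", "a"), response = c(1, 0),
                                phase = "training"), "duplicated")
  expect_error(endorsement_data("a", response = 2, phase = "training"),
               "0, 1 or NA")
  expect_error(endorsement_data("a", count = 9, n_rounds = 8,
                                phase = "transfer"), "lie in")
  ed <- endorsement_data(c("a", "b"), count = c(3, 8), n_rounds = 8,
                         phase = "transfer")
  expect_identical(ed$n, c(8, 8))
  expect_error(log_likelihood("PROTO", c(c = 1, k = 0.5), ed,
                              toy_distances()), "missing from distance")
})

test_that("mixture similarity vectors are the beta-weighted combination", {
  sp <- c(0.4, 0.9, 0.1)
  se <- c(0.8, 0.2, 0.5)
  expect_identical(mixture_similarity_vector(sp, se, 1), sp)
  expect_identical(mixture_similarity_vector(sp, se, 0), se)
  expect_equal(mixture_similarity_vector(0.4, 0.8, 0.5), 0.6)
  expect_error(mixture_similarity_vector(sp, se[1:2], 0.5), "equal length")
  expect_error(mixture_similarity_vector(sp, se, 1.5), "beta")
})

test_that("similarity correlation flags degenerate inputs and recovers known signs", {
  sp <- c(0.1, 0.4, 0.7, 0.9)
  expect_equal(similarity_correlation(sp, 2 * sp), 1)
  expect_equal(similarity_correlation(sp, -sp), -1)
  expect_error(similarity_correlation(sp, rep(0.5, 4)), "zero variance")
  expect_error(similarity_correlation(sp[1:2], sp[1:2] * 2), "at least 3")
  # on generated training members with a typical sensitivity the two
  # similarity vectors are positively correlated
  dists <- test_distances("training")
  members <- dists$role == "member"
  sp_m <- similarity_to_prototype(dists$d_proto[members], 0.5)
  se_m <- similarity_to_exemplars(dists$d_ex[, members], 0.5)
  expect_gt(similarity_correlation(sp_m, se_m), 0)
})

test_that("gamma scope switch restricts scaling to the exemplar route", {
  dists <- test_distances()
  p <- c(c = 0.8, k = 0.3, beta = 0.5, gamma = 3)
  r_both <- model_predict("MIX_G", p, dists, gamma_scope = "both")
  r_exo <- model_predict("MIX_G", p, dists, gamma_scope = "exemplar_only")
  sp <- similarity_to_prototype(dists$d_proto, 0.8)
  se <- similarity_to_exemplars(dists$d_ex, 0.8)
  manual_exo <- 0.5 * sp / (sp + 0.3) +
    0.5 * se^3 / (se^3 + 0.3^3)
  expect_equal(unname(r_exo), unname(manual_exo))
  expect_false(isTRUE(all.equal(r_both, r_exo)))
})
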