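h <- function(...) hypnogram(c(...))

test_that("the smoothing rules rewrite the documented patterns", {
  expect_equal(stage_names(apply_rules(h("W", "REM", "N2"))),
               c("W", "N1", "N2"))
  expect_equal(stage_names(apply_rules(h("N1", "REM", "N2"))),
               c("N1", "N1", "N2"))
  expect_equal(stage_names(apply_rules(h("N2", "W", "N2"))),
               c("N2", "N2", "N2"))
  expect_equal(stage_names(apply_rules(h("REM", "W", "REM"))),
               c("REM", "REM", "REM"))
  # no pattern matches
  expect_equal(stage_names(apply_rules(h("W", "W", "W", "W"))),
               rep("W", 4))
  # rule 1: leading REM before the first N2 becomes N1 (then no-ops)
  expect_equal(stage_names(apply_rules(h("REM", "N1", "N2"))),
               c("N1", "N1", "N2"))
  # without any N2 there is no "first appearance", so rule 1 is inert and
  # isolated REM before wake survives
  expect_equal(stage_names(apply_rules(h("W", "REM", "W"))),
               c("W", "REM", "W"))
  expect_length(apply_rules(hypnogram(integer(0))), 0L)
})

test_that("the rule engine matches the naive rewriting oracle on random hypnograms", {
  set.seed(77)
  for (i in 1:300) {
    n <- sample(1:50, 1)
    x <- hypnogram(sample(0:4, n, replace = TRUE))
    expect_identical(as.integer(apply_rules(x)),
                     as.integer(rules_oracle(x)))
  }
})

test_that("rules 2-5 are idempotent on their own output (logged check)", {
  set.seed(88)
  viol <- 0L
  for (i in 1:100) {
    x <- hypnogram(sample(0:4, 30, replace = TRUE))
    once <- apply_rules(x)
    twice <- apply_rules(once)
    if (!identical(as.integer(once), as.integer(twice))) viol <- viol + 1L
  }
  # cascading rewrites can in principle interact; report, require rarity
  if (viol > 0) message(viol, "/100 random hypnograms were not idempotent")
  expect_lte(viol, 5L)
})

test_that("fit_hmm reproduces hand-tabulated counts", {
  truth <- h("W", "W", "N1", "N2", "N2", "N2", "N3", "N3", "N2", "REM")
  obs   <- h("W", "N1", "N1", "N2", "N2", "W", "N3", "N3", "N2", "REM")
  fit <- fit_hmm(truth, obs, smoothing = 0)
  # transitions from N2 in truth: N2->N2 (x2), N2->N3, N2->REM; 4 total
  expect_equal(unname(fit$A["N2", ]), c(0, 0, 2, 1, 1) / 4)
  # emissions from truth W: observed W once, N1 once
  expect_equal(unname(fit$B["W", ]), c(1, 1, 0, 0, 0) / 2)
  expect_equal(unname(fit$pi), c(2, 1, 4, 2, 1) / 10)
  # perfect observer limit: B -> identity as smoothing -> 0
  long <- hypnogram(sample(0:4, 500, replace = TRUE))
  expect_equal(unname(fit_hmm(long, long, smoothing = 0)$B), diag(5))
  # constant truth: the diagonal transition entry -> 1
  const <- hypnogram(rep(2L, 50))
  expect_equal(fit_hmm(const, const, smoothing = 0)$A["N2", "N2"], 1)
  # smoothing keeps everything positive and rows stochastic
  sm <- fit_hmm(truth, obs, smoothing = 1)
  expect_true(all(sm$A > 0) && all(sm$B > 0) && all(sm$pi > 0))
  expect_equal(rowSums(sm$A), rep(1, 5), ignore_attr = TRUE)
  expect_error(fit_hmm(truth, obs[1:5]), "length")
  # recording boundaries are excluded from transition counts
  two <- fit_hmm(list(h("W", "W"), h("N2", "N2")),
                 list(h("W", "W"), h("N2", "N2")), smoothing = 0)
  expect_equal(two$A["W", "N2"], 0)
})

test_that("viterbi decoding matches identity-emission and brute-force oracles", {
  # identity emission + continuity-dominant transitions: decode = observe
  ident <- structure(list(A = matrix(0.04, 5, 5) + diag(5) * 0.8,
                          B = diag(5) * 0.96 + 0.01,
                          pi = rep(0.2, 5)), class = "hmm_params")
  ident$A <- ident$A / rowSums(ident$A)
  ident$B <- ident$B / rowSums(ident$B)
  obs <- hypnogram(c(0, 0, 1, 2, 2, 3, 4, 4, 0))
  expect_equal(as.integer(viterbi_decode(obs, ident)), as.integer(obs))

  # brute force over all 5^L paths on random instances
  set.seed(55)
  for (i in 1:60) {
    L <- sample(2:6, 1)
    params <- random_hmm(seed = 1000 + i)
    obs <- hypnogram(sample(0:4, L, replace = TRUE))
    got <- viterbi_decode(obs, params)
    oracle <- viterbi_oracle(obs, params)
    expect_equal(path_log_prob(got, obs, params), oracle$score,
                 tolerance = 1e-10)
    expect_identical(as.integer(got), as.integer(oracle$path))
  }

  # uniform emission: decoding depends only on A and pi
  unif <- random_hmm(3)
  unif$B <- matrix(0.2, 5, 5)
  obs1 <- hypnogram(sample(0:4, 6, replace = TRUE))
  obs2 <- hypnogram(sample(0:4, 6, replace = TRUE))
  expect_identical(as.integer(viterbi_decode(obs1, unif)),
                   as.integer(viterbi_decode(obs2, unif)))
  expect_identical(as.integer(viterbi_decode(obs1, unif)),
                   as.integer(viterbi_oracle(obs1, unif)$path))
})

test_that("HMM refinement raises nontransition accuracy on noisy predictions", {
  tm <- default_transition_model()
  truth_val <- simulate_hypnogram(tm, 2000, seed = 61)
  truth_test <- simulate_hypnogram(tm, 2000, seed = 62)
  corrupt <- function(hyp, rate, seed) {
    set.seed(seed)
    s <- as.integer(hyp)
    flip <- which(runif(length(s)) < rate)
    s[flip] <- vapply(s[flip], function(v)
      sample(setdiff(0:4, v), 1), integer(1))
    hypnogram(s)
  }
  pred_val <- corrupt(truth_val, 0.25, 63)
  pred_test <- corrupt(truth_test, 0.25, 64)
  params <- fit_hmm(truth_val, pred_val)
  refined <- viterbi_decode(pred_test, params)
  nt <- !mark_transitions(truth_test)
  acc_before <- compute_metrics(truth_test, pred_test, nt)$accuracy
  acc_after <- compute_metrics(truth_test, refined, nt)$accuracy
  expect_gt(acc_after, acc_before)
})
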