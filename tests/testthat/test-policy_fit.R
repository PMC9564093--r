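test_that("purely random data prefer the single-stage random model by BIC", {
  co <- simulate_cohort(3, seed = 21, model = "random", sigma = 20)
  for (id in co$manifest$id) {
    tt <- co$trials[co$trials$id == id & co$trials$phase == "test", ]
    fits <- fit_all_policies(tt, co$mapping)
    expect_equal(best_policy_model(fits), "random")
    # the rnd-bi fit cannot beat rnd after the switch-point penalty
    expect_gte(fits[["random-bilateral"]]$loglik, fits[["random"]]$loglik)
    expect_lt(fits[["random-bilateral"]]$evidence - fits[["random"]]$evidence, 0)
  }
})

test_that("true switch blocks and unilateral dimension are recovered", {
  hits <- 0
  for (s in 1:10) {
    spec <- participant_spec(
      id = "p1",
      stage_per_block = rep(c("random", "unilateral", "bilateral"),
                            c(3, 5, 6)),
      unilateral_dim = 1, sigma = 10, seed = s)
    m <- make_mapping("grid", seed = 1000 + s)
    tt <- simulate_participant(spec, mapping = m)
    tt <- tt[tt$phase == "test", ]
    fit <- fit_policy_sequence(tt, m, "random-unilateral-bilateral",
                               sigma = 10)
    if (all(abs(fit$switch_blocks - c(4, 9)) <= 1) &&
        fit$unilateral_dim == 1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("the correct single-stage model dominates on its own data", {
  co <- simulate_cohort(2, seed = 31, model = "bilateral", sigma = 15)
  for (id in co$manifest$id) {
    tt <- co$trials[co$trials$id == id & co$trials$phase == "test", ]
    fits <- fit_all_policies(tt, co$mapping, sigma = 15)
    expect_gte(fits[["bilateral"]]$loglik, fits[["random"]]$loglik)
    expect_equal(best_policy_model(fits), "bilateral")
  }
})

test_that("adding a stage never decreases the maximised log likelihood", {
  co <- simulate_cohort(2, seed = 41, model = "random-bilateral")
  tt <- co$trials[co$trials$id == co$manifest$id[1] &
                    co$trials$phase == "test", ]
  fits <- fit_all_policies(tt, co$mapping)
  expect_gte(fits[["random-bilateral"]]$loglik, fits[["random"]]$loglik)
  expect_gte(fits[["random-bilateral"]]$loglik, fits[["bilateral"]]$loglik)
  expect_gte(fits[["random-unilateral-bilateral"]]$loglik,
             fits[["random-bilateral"]]$loglik)
})

test_that("inadmissible stage sets are rejected", {
  co <- simulate_cohort(1, seed = 5)
  tt <- co$trials[co$trials$phase == "test", ]
  expect_error(fit_policy_sequence(tt, co$mapping, c("bilateral", "random")),
               "inadmissible")
})

test_that("RFX-BMS obeys symmetry, decisive limits and exchangeability", {
  b <- rfx_bms(matrix(0, 12, 2))
  expect_equal(b$expected_frequencies, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(b$expected_frequencies), 1)
  expect_equal(rowSums(b$posterior_probabilities), rep(1, 12))

  n <- 15
  b2 <- rfx_bms(cbind(rep(100, n), 0), alpha0 = 1)
  expect_equal(b2$expected_frequencies[1], (n + 1) / (n + 2),
               tolerance = 1e-6)

  set.seed(4)
  ev <- matrix(rnorm(30), 10, 3)
  b3 <- rfx_bms(ev)
  b4 <- rfx_bms(ev[sample(10), ])
  expect_equal(b3$expected_frequencies, b4$expected_frequencies,
               tolerance = 1e-6)
  expect_error(rfx_bms(matrix(c(1, NA, 0, 0), 2, 2)), "non-finite")
})

test_that("unilateral attribution separates generating policies", {
  attr_rate <- function(co, sigma) {
    mean(vapply(unique(co$manifest$id), function(id) {
      tt <- co$trials[co$trials$id == id & co$trials$phase == "test", ]
      unilateral_attribution(fit_all_policies(tt, co$mapping, sigma = sigma))
    }, logical(1)))
  }
  co_rb <- simulate_cohort(12, seed = 7, model = "random-bilateral",
                           sigma = 15)
  co_ru <- simulate_cohort(12, seed = 8,
                           model = "random-unilateral-bilateral", sigma = 15)
  expect_lt(attr_rate(co_rb, 15), 0.35)
  expect_gt(attr_rate(co_ru, 15), 0.65)
})

test_that("matched cohorts reproduce the target block LLR profile", {
  co <- simulate_cohort(4, seed = 13, model = "random-bilateral", sigma = 15)
  mc <- build_matched_cohort(co$trials, co$mapping, sigma = 15, seed = 3)
  expect_true(all(mc$weights$w >= 0 & mc$weights$w <= 1))
  for (id in unique(co$manifest$id)) {
    orig <- llr(co$trials[co$trials$id == id & co$trials$phase == "test", ],
                co$mapping, 15)
    sim <- llr(mc$trials[mc$trials$id == paste0(id, "_sim"), ],
               co$mapping, 15)
    expect_gt(cor(orig$per_block, sim$per_block), 0.8)
  }
})

test_that("inflection analysis recovers a constructed two-step error profile", {
  set.seed(1)
  m <- make_mapping("grid", randomize = FALSE)
  n <- 224
  tt <- data.frame(block = rep(1:14, each = 16), truth_x = 90, truth_y = 90,
                   resp_x = ifelse(seq_len(n) > 50, 90, 0) + rnorm(n, 0, 2),
                   resp_y = ifelse(seq_len(n) > 120, 90, 0) + rnorm(n, 0, 2))
  r <- crossval_inflection(tt, m)
  expect_equal(r$cv_difference, 70, tolerance = 5)
  expect_false(r$degenerate)
})

test_that("identical error trajectories give near-zero CV differences", {
  m <- make_mapping("grid", randomize = FALSE)
  diffs <- vapply(1:6, function(s) {
    set.seed(s)
    n <- 224
    drop_at <- 80
    tt <- data.frame(block = rep(1:14, each = 16), truth_x = 90, truth_y = 90,
                     resp_x = ifelse(seq_len(n) > drop_at, 90, 0) + rnorm(n, 0, 8),
                     resp_y = ifelse(seq_len(n) > drop_at, 90, 0) + rnorm(n, 0, 8))
    crossval_inflection(tt, m)$cv_difference
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 10)
})

test_that("flat error trajectories are flagged degenerate at the midpoint", {
  m <- make_mapping("grid", randomize = FALSE)
  tt <- data.frame(block = rep(1:14, each = 16), truth_x = 90, truth_y = 90,
                   resp_x = 90, resp_y = 90)
  r <- crossval_inflection(tt, m)
  expect_true(r$degenerate)
  expect_equal(r$cv_difference, 0)
})

test_that("delta LLR is the telescoping first difference", {
  d <- delta_llr(rep(2, 14), seq(0, 26, by = 2))
  expect_equal(d$train, rep(0, 13))
  expect_equal(d$test, rep(2, 13))
  x <- cumsum(rnorm(14))
  expect_equal(sum(delta_llr(x, x)$train), x[14] - x[1])
})
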