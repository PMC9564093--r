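test_that("sampled responses always lie inside the arena disk", {
  m <- make_mapping("polar", seed = 1)
  R <- m$arena$radius
  set.seed(3)
  for (kind in c("random", "bilateral")) {
    p <- sample_policy_response(500, kind, m, truth = c(150, 80), sigma = 25)
    expect_true(all(p[, 1]^2 + p[, 2]^2 <= R^2))
  }
  for (dim in 1:2) {
    p <- sample_policy_response(500, "unilateral", m, truth = c(150, 80),
                                dim = dim, sigma = 25)
    expect_true(all(p[, 1]^2 + p[, 2]^2 <= R^2))
  }
})

test_that("large samples match the generating density on a coarse grid", {
  # chi-square goodness of fit of sampled bilateral responses against the
  # lattice density, on 40 px cells
  m <- make_mapping("grid", randomize = FALSE)
  truth <- c(90, -90)
  set.seed(11)
  n <- 50000
  p <- sample_policy_response(n, "bilateral", m, truth = truth, sigma = 30)
  cell <- 40
  cx <- floor((p[, 1] + 280) / cell); cy <- floor((p[, 2] + 280) / cell)
  obs <- table(paste(cx, cy))
  # expected probabilities from a fine half-offset grid so no grid point
  # sits on a cell edge
  d <- density_bilateral(m, truth, 30)
  ax <- seq(-264.5, 264.5, by = 1)
  g <- expand.grid(x = ax, y = ax)
  g <- g[g$x^2 + g$y^2 <= 265^2, ]
  w <- exp(hebbgate:::log_unnorm(d, g$x, g$y))
  w <- w / sum(w)
  lcx <- floor((g$x + 280) / cell); lcy <- floor((g$y + 280) / cell)
  expd <- tapply(w, paste(lcx, lcy), sum) * n
  keep <- names(expd)[expd >= 20]
  o <- as.numeric(obs[keep]); o[is.na(o)] <- 0
  e <- as.numeric(expd[keep])
  stat <- sum((o - e)^2 / e)
  pval <- pchisq(stat, df = length(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("polar bilateral sampling follows the product-form density", {
  # radial and angular marginals centre on the truth with the right spread
  m <- make_mapping("polar", randomize = FALSE)
  truth <- c(159, 0)
  set.seed(5)
  p <- sample_policy_response(20000, "bilateral", m, truth = truth,
                              sigma = 20)
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  phi <- atan2(p[, 2], p[, 1])
  expect_equal(mean(rho), 159, tolerance = 2)
  expect_equal(sd(rho), 20, tolerance = 1)
  expect_equal(mean(phi), 0, tolerance = 0.01)
  expect_equal(sd(phi), hebbgate:::sigma_phi_for(20, 159), tolerance = 0.01)
})

test_that("all-bilateral participants classify as generalizers, random ones do not", {
  gens <- c(); rand_llr <- c()
  for (s in 1:6) {
    m <- make_mapping("grid", seed = 100 + s)
    good <- simulate_participant(
      participant_spec("g", stage_per_block = rep("bilateral", 14),
                       sigma = 10, seed = s), m)
    bad <- simulate_participant(
      participant_spec("b", stage_per_block = rep("random", 14),
                       sigma = 10, seed = s), m)
    gens <- c(gens, classify_generalizer(
      llr(good[good$phase == "test", ], m, 20)))
    rand_llr <- c(rand_llr, llr(bad[bad$phase == "test", ], m, 20)$total)
  }
  expect_true(all(gens))
  expect_lt(mean(rand_llr), 0)     # expected log ratio under uniform < 0
})

test_that("non-monotone stage schedules are rejected", {
  expect_error(participant_spec("p", stage_per_block =
    rep(c("bilateral", "random"), c(7, 7))), "monotone")
})

test_that("cohorts carry a faithful manifest and disjoint response streams", {
  co <- simulate_cohort(5, seed = 17, model = "random-unilateral-bilateral")
  expect_equal(nrow(co$manifest), 5)
  expect_equal(length(unique(co$trials$id)), 5)
  expect_true(all(!is.na(co$manifest$switch1)))
  expect_true(all(co$manifest$switch1 < co$manifest$switch2))
  # no duplicated response rows across participants
  key <- paste(co$trials$resp_x, co$trials$resp_y)
  tkey <- key[co$trials$phase == "test"]
  expect_lt(max(table(tkey)), 3)
  # structural counts
  expect_equal(nrow(co$trials), 5 * 350)
  expect_equal(sum(co$trials$phase == "test"), 5 * 224)
})

test_that("a 478-participant cohort would yield 107,072 test responses", {
  co <- simulate_cohort(2, seed = 1)
  per_participant <- sum(co$trials$phase == "test") / 2
  expect_equal(478 * per_participant, 107072)
})
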