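test_that("cue encoding is two-hot with one slot per dimension", {
  x <- encode_cue(0, 0)
  expect_equal(which(x == 1), c(1, 6))
  expect_equal(sum(encode_cue(3, 4)), 2)
  # two cues sharing a color share exactly one active slot
  shared <- encode_cue(2, 0) * encode_cue(2, 4)
  expect_equal(sum(shared), 1)
})

test_that("effector composition matches the rotation-translation geometry", {
  expect_equal(effector_to_point(c(0, 0, 0, 0)), c(0, 0))
  expect_equal(effector_to_point(c(100, 50, 0, 0)), c(100, 50))
  expect_equal(effector_to_point(c(0, 0, 212, pi / 2)), c(0, 212),
               tolerance = 1e-9)
})

test_that("effector targets are the redundant 4-coordinate description", {
  expect_equal(point_to_effector_targets(c(0, 0)), c(0, 0, 0, 0))
  expect_equal(point_to_effector_targets(c(212, 0)), c(212, 0, 212, 0))
  expect_equal(point_to_effector_targets(c(-90, 0)), c(-90, 0, 90, pi))
})

test_that("forward pass respects gating", {
  hyper <- agent_hyperparams(w_init_sd = 0, rho_init = 0)
  st <- init_agent("vanilla", hyper, seed = 1)
  expect_equal(agent_forward(st, encode_cue(1, 1)), rep(0, 4))   # W = 0

  # fully closed gates silence any W
  sth <- init_agent("hebbian", agent_hyperparams(), seed = 2)
  sth$W <- matrix(5, 4, 10)
  expect_equal(agent_forward(sth, encode_cue(0, 3)), rep(0, 4))

  # all gates open reproduces the vanilla forward pass exactly
  stv <- init_agent("vanilla", agent_hyperparams(), seed = 3)
  sth2 <- init_agent("hebbian", agent_hyperparams(tau = 0.3), seed = 3)
  sth2$U <- matrix(1, 4, 10)
  for (c in 0:4) for (s in c(0, 2, 4))
    expect_identical(agent_forward(sth2, encode_cue(c, s)),
                     agent_forward(stv, encode_cue(c, s)))
})

test_that("sgd respects the learning rate and the gating contract", {
  x <- encode_cue(1, 2)
  st0 <- init_agent("vanilla", agent_hyperparams(sgd_rate = 0), seed = 1)
  expect_identical(sgd_step(st0, x, c(50, 50))$W, st0$W)

  # weights behind closed gates are never touched
  sth <- init_agent("hebbian", agent_hyperparams(), seed = 1)
  sth$U <- matrix(0, 4, 10)
  sth$U[1, 2] <- 0.9                       # one open gate
  W_before <- sth$W
  sth2 <- sgd_step(sth, x, c(80, -40))
  moved <- sth2$W != W_before
  expect_true(moved[1, 2])
  expect_equal(sum(moved), 1)

  # repeated steps on one trial do not increase the loss (small rate)
  st <- init_agent("vanilla", agent_hyperparams(sgd_rate = 0.005,
                                                steps_per_trial = 1), seed = 4)
  f <- c(120, -60)
  loss <- function(s) sum((effector_to_point(agent_forward(s, x)) - f)^2)
  prev <- loss(st)
  for (k in 1:30) {
    st <- sgd_step(st, x, f)
    cur <- loss(st)
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("hebbian update follows the surprise rules", {
  hyper <- agent_hyperparams(alpha_U = 0.1, lambda = 0.5)
  st <- init_agent("hebbian", hyper, seed = 1)
  # first trial of a block: no update, history grows
  st <- hebb_update(st, encode_cue(0, 0),
                    point_to_effector_targets(c(-180, 0)))
  expect_equal(st$U, matrix(0, 4, 10))
  expect_length(st$history, 1)

  # one prior trial, input feature and output dimension both changed:
  # entry rises by alpha_U * 1 (from U = 0)
  st <- hebb_update(st, encode_cue(1, 0),
                    point_to_effector_targets(c(-90, 0)))
  # color slots 1 and 2 changed; trans_x and rho changed, trans_y did not
  expect_equal(st$U[1, 1], 0.1)
  expect_equal(st$U[1, 2], 0.1)
  expect_equal(st$U[3, 1], 0.1)
  expect_equal(st$U[2, 1], 0)

  # identical consecutive inputs leave U unchanged
  st2 <- init_agent("hebbian", hyper, seed = 1)
  z <- point_to_effector_targets(c(100, 50))
  st2 <- hebb_update(st2, encode_cue(2, 2), z)
  U_before <- st2$U
  st2 <- hebb_update(st2, encode_cue(2, 2), z)
  expect_identical(st2$U, U_before)
})

test_that("a pair whose input and output always change converges to 0.5", {
  hyper <- agent_hyperparams(alpha_U = 0.3, lambda = 0.5)
  st <- init_agent("hebbian", hyper, seed = 1)
  xs <- list(encode_cue(0, 0), encode_cue(1, 1), encode_cue(2, 2),
             encode_cue(3, 3), encode_cue(4, 4))
  pts <- list(c(-180, -180), c(-90, -90), c(10, 10), c(90, 90), c(180, 180))
  for (rep in 1:40) {
    i <- (rep - 1) %% 5 + 1
    st <- hebb_update(st, xs[[i]], point_to_effector_targets(pts[[i]]))
  }
  active <- st$U[1, 1:5]                 # color -> trans_x gates
  expect_true(all(abs(active - 0.5) < 0.1))
})

test_that("U stays in [0, 1] under arbitrary update streams", {
  hyper <- agent_hyperparams(alpha_U = 1, lambda = 0.9)   # most extreme rate
  st <- init_agent("hebbian", hyper, seed = 1)
  set.seed(42)
  for (k in 1:60) {
    if (k %% 9 == 1) st$history <- list()
    cue <- sample(0:4, 2, replace = TRUE)
    p <- sample_policy_response(1, "random", fixture_mapping("grid", 1))
    st <- hebb_update(st, encode_cue(cue[1], cue[2]),
                      point_to_effector_targets(as.numeric(p)))
    expect_true(all(st$U >= 0 & st$U <= 1))
  }
})

test_that("raising tau never opens a gate that was closed", {
  st <- init_agent("hebbian", agent_hyperparams(tau = 0.2), seed = 5)
  set.seed(7)
  st$U <- matrix(runif(40), 4, 10)
  open_low <- hebbgate:::gate_matrix(st)
  st$hyper$tau <- 0.45
  open_high <- hebbgate:::gate_matrix(st)
  expect_true(all(open_high <= open_low))
})

test_that("agent runs are deterministic and respect block structure", {
  m <- make_mapping("grid", seed = 3)
  cur <- make_curriculum(1, m, "aligned", 3)
  sch <- make_schedule(cur, m, 3)
  r1 <- run_agent("hebbian", sch, m, seed = 11)
  r2 <- run_agent("hebbian", sch, m, seed = 11)
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$state$W, r2$state$W)
})

test_that("a hebbian agent with alpha_U = 0 stays fully gated at the centre", {
  m <- make_mapping("grid", seed = 3)
  cur <- make_curriculum(1, m, "aligned", 3)
  sch <- make_schedule(cur, m, 3, n_blocks = 3)
  run <- run_agent("hebbian", sch, m, agent_hyperparams(alpha_U = 0), seed = 2)
  expect_true(all(run$trials$resp_x == 0 & run$trials$resp_y == 0))
})
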