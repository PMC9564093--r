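test_that("grid and polar truth locations follow the mapping geometry", {
  m <- make_mapping("grid", randomize = FALSE)
  expect_equal(unlist(truth_location(m, 2, 2)), c(x = 0, y = 0))
  corner <- truth_location(m, 0, 0)
  expect_equal(unlist(corner), c(x = -180, y = -180))
  expect_lt(sqrt(sum(corner^2)), 265)           # corner fits inside the wall
  expect_equal(sqrt(sum(corner^2)), 180 * sqrt(2))

  mp <- make_mapping("polar", randomize = FALSE)
  p <- truth_location(mp, 3, 0)                  # ring level 3 -> 212 px, spoke 0
  expect_equal(unlist(p), c(x = 212, y = 0))
})

test_that("every mapping places 25 distinct points strictly inside the arena", {
  for (seed in 1:10) for (kind in c("grid", "polar")) {
    m <- make_mapping(kind, seed = seed)
    pts <- truth_location(m, cue_set()$color, cue_set()$shape)
    expect_equal(anyDuplicated(round(cbind(pts$x, pts$y), 9)), 0)
    expect_true(all(pts$x^2 + pts$y^2 < m$arena$radius^2))
  }
})

test_that("curricula partition the 25 cues into 9 train and 16 test", {
  for (seed in 1:8) {
    for (cfg in list(list(1, "grid", "aligned"), list(1, "grid", "misaligned"),
                     list(1, "polar", "aligned"), list(1, "polar", "misaligned"),
                     list(2, "grid", "blocked"), list(2, "polar", "interleaved"))) {
      m <- make_mapping(cfg[[2]], seed = seed)
      cur <- make_curriculum(cfg[[1]], m, cfg[[3]], seed)
      key <- function(d) paste(d$color, d$shape)
      expect_equal(nrow(cur$train), 9)
      expect_equal(nrow(cur$test), 16)
      expect_length(intersect(key(cur$train), key(cur$test)), 0)
      expect_setequal(c(key(cur$train), key(cur$test)), key(cue_set()))
    }
  }
})

test_that("exp 1 aligned training cues are one full level of each dimension", {
  m <- make_mapping("grid", seed = 3)
  cur <- make_curriculum(1, m, "aligned", seed = 5)
  # one fixed color crossed with all shapes, one fixed shape with all colors
  n_per_color <- table(cur$train$color)
  n_per_shape <- table(cur$train$shape)
  expect_equal(max(n_per_color), 5)
  expect_equal(max(n_per_shape), 5)
  expect_equal(nrow(cur$overlap), 1)
})

test_that("misaligned training cues are the two cue-lattice diagonals", {
  m <- make_mapping("grid", seed = 3)
  cur <- make_curriculum(1, m, "misaligned", seed = 5)
  key <- paste(cur$train$color, cur$train$shape)
  diag_keys <- c(paste(0:4, 0:4), paste(0:4, 4:0))
  expect_setequal(key, unique(diag_keys))
  expect_equal(unlist(cur$overlap), c(color = 2, shape = 2))
})

test_that("invalid experiment/condition combinations are rejected", {
  m <- make_mapping("grid", seed = 1)
  expect_error(make_curriculum(1, m, "blocked", 1), "not valid")
  expect_error(make_curriculum(2, m, "aligned", 1), "not valid")
})

test_that("blocked training order puts the overlap cue at position 5 and alternates axes", {
  m <- make_mapping("grid", seed = 2)
  cur <- make_curriculum(1, m, "aligned", seed = 2)
  key <- function(d) paste(d$color, d$shape)
  first_axis_dim <- function(ord) {
    # which axis do trials 1-4 come from?
    if (all(key(ord[1:4, ]) %in% key(cur$axis1))) 1 else 2
  }
  for (b in 1:6) {
    ord <- order_training_trials(cur, b, seed = 11)
    expect_equal(key(ord[5, , drop = FALSE]), key(cur$overlap))
    expect_true(all(key(ord[1:4, ]) %in% key(cur$axis1)) ||
                  all(key(ord[1:4, ]) %in% key(cur$axis2)))
  }
  a1 <- first_axis_dim(order_training_trials(cur, 1, seed = 11))
  a2 <- first_axis_dim(order_training_trials(cur, 2, seed = 11))
  a3 <- first_axis_dim(order_training_trials(cur, 3, seed = 11))
  expect_false(a1 == a2)
  expect_equal(a1, a3)
})

test_that("interleaved order is a permutation of the 9 training cues", {
  m <- make_mapping("grid", seed = 2)
  cur <- make_curriculum(2, m, "interleaved", seed = 2)
  key <- function(d) paste(d$color, d$shape)
  o1 <- order_training_trials(cur, 1, seed = 1)
  o2 <- order_training_trials(cur, 1, seed = 99)
  expect_setequal(key(o1), key(cur$train))
  expect_setequal(key(o2), key(cur$train))
  expect_false(identical(key(o1), key(o2)))
})

test_that("points follow the half-open distance bands", {
  expect_equal(score_points(c(10, 19.99, 20, 39.9, 40, 45, 59.9, 60, 300)),
               c(5L, 5L, 2L, 2L, 1L, 1L, 1L, 0L, 0L))
  expect_error(score_points(-1), "non-negative")
})

test_that("schedules have 14 blocks of 9 train + 16 test with all 25 cues", {
  m <- make_mapping("polar", seed = 4)
  cur <- make_curriculum(2, m, "blocked", seed = 4)
  sch <- make_schedule(cur, m, seed = 9)
  expect_equal(sum(sch$phase == "train"), 126)
  expect_equal(sum(sch$phase == "test"), 224)
  for (b in 1:14) {
    blk <- sch[sch$block == b, ]
    expect_equal(nrow(blk), 25)
    expect_equal(anyDuplicated(paste(blk$color, blk$shape)), 0)
    expect_equal(blk$phase, rep(c("train", "test"), c(9, 16)))
  }
})

test_that("identical seeds reproduce identical curricula and schedules", {
  m1 <- make_mapping("grid", seed = 7)
  m2 <- make_mapping("grid", seed = 7)
  expect_identical(m1[setdiff(names(m1), "arena")],
                   m2[setdiff(names(m2), "arena")])
  cur <- make_curriculum(2, m1, "interleaved", seed = 7)
  expect_identical(make_schedule(cur, m1, seed = 5),
                   make_schedule(cur, m1, seed = 5))
})
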