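# Fully synthetic participant cohorts with known ground-truth policies, so
# every analysis stage can be exercised and validated without external data.

#' Sample responses from a policy density
#'
#' Exact rejection sampling of the disk-truncated policy densities used by
#' the response models. Random: uniform on the disk. Bilateral grid:
#' Gaussian around the truth, rejected outside the disk. Bilateral polar and
#' the polar unilaterals: the radial/angular factors are sampled directly and
#' accepted with probability rho/R, which exactly cancels the polar Jacobian
#' so draws follow the Cartesian product-form density the models define.
#'
#' @param n Number of responses.
#' @param kind `"random"`, `"unilateral"` or `"bilateral"`.
#' @param mapping A [make_mapping()] object.
#' @param truth Ground-truth point `(x, y)` in px.
#' @param dim Learned dimension for unilateral sampling (1 or 2).
#' @param sigma Dispersion in px.
#' @return An n x 2 matrix of response points (px). Assumes the caller has
#'   seeded the RNG.
#' @export
sample_policy_response <- function(n, kind, mapping, truth = c(0, 0),
                                   dim = 1, sigma = 20) {
  R <- mapping$arena$radius
  draw_uniform <- function(m) {
    out <- matrix(NA_real_, 0, 2)
    while (nrow(out) < m) {
      x <- stats::runif(2 * m, -R, R); y <- stats::runif(2 * m, -R, R)
      ok <- x^2 + y^2 <= R^2
      out <- rbind(out, cbind(x[ok], y[ok]))
    }
    out[seq_len(m), , drop = FALSE]
  }
  draw_radial <- function(m, rho_fn, phi_fn) {
    # accept w.p. rho/R to convert the (rho, phi) proposal into the
    # Cartesian product-form density
    out <- matrix(NA_real_, 0, 2)
    while (nrow(out) < m) {
      k <- 3 * m
      rho <- rho_fn(k); phi <- phi_fn(k)
      ok <- rho > 0 & rho <= R & stats::runif(k) < rho / R
      out <- rbind(out, cbind(rho[ok] * cos(phi[ok]),
                              rho[ok] * sin(phi[ok])))
    }
    out[seq_len(m), , drop = FALSE]
  }
  rho0 <- sqrt(sum(truth^2)); phi0 <- atan2(truth[2], truth[1])
  sphi <- sigma_phi_for(sigma, rho0)

  if (kind == "random") return(draw_uniform(n))

  if (kind == "bilateral") {
    if (mapping$kind == "grid") {
      out <- matrix(NA_real_, 0, 2)
      while (nrow(out) < n) {
        k <- 2 * n
        x <- stats::rnorm(k, truth[1], sigma); y <- stats::rnorm(k, truth[2], sigma)
        ok <- x^2 + y^2 <= R^2
        out <- rbind(out, cbind(x[ok], y[ok]))
      }
      return(out[seq_len(n), , drop = FALSE])
    }
    return(draw_radial(n,
                       function(k) stats::rnorm(k, rho0, sigma),
                       function(k) phi0 + wrap_angle(stats::rnorm(k, 0, sphi))))
  }

  # unilateral
  if (mapping$kind == "grid") {
    out <- matrix(NA_real_, 0, 2)
    while (nrow(out) < n) {
      k <- 3 * n
      g <- stats::rnorm(k, if (dim == 1) truth[1] else truth[2], sigma)
      u <- stats::runif(k, -R, R)
      x <- if (dim == 1) g else u
      y <- if (dim == 1) u else g
      ok <- x^2 + y^2 <= R^2
      out <- rbind(out, cbind(x[ok], y[ok]))
    }
    return(out[seq_len(n), , drop = FALSE])
  }
  if (dim == 1) {
    draw_radial(n, function(k) stats::rnorm(k, rho0, sigma),
                function(k) stats::runif(k, -pi, pi))
  } else {
    draw_radial(n, function(k) stats::runif(k, 0, R),
                function(k) phi0 + wrap_angle(stats::rnorm(k, 0, sphi)))
  }
}

#' Specification of one synthetic participant
#'
#' @param id Participant identifier.
#' @param stage_per_block Character vector (length `n_blocks`) of test-trial
#'   policies per block, monotone in the order random < unilateral <
#'   bilateral.
#' @param unilateral_dim Learned dimension during unilateral blocks.
#' @param sigma Response dispersion in px.
#' @param seed Participant seed (drives the schedule and all responses).
#' @param experiment,condition Curriculum settings (see
#'   [make_curriculum()]).
#' @param train_policy `"ramp"` (random in block 1, bilateral afterwards --
#'   realistic learning of the 9 training locations), `"bilateral"` (accurate
#'   from the start) or `"random"` (a non-learner, for exercising the
#'   exclusion rule).
#' @param train_sigma Dispersion of training-trial responses in px.
#' @return A list of class `participant_spec`.
#' @export
participant_spec <- function(id, stage_per_block = rep("bilateral", 14),
                             unilateral_dim = 1, sigma = 20, seed = 1L,
                             experiment = 1, condition = "aligned",
                             train_policy = c("ramp", "bilateral", "random"),
                             train_sigma = sigma) {
  train_policy <- match.arg(train_policy)
  stopifnot(all(stage_per_block %in% c("random", "unilateral", "bilateral")))
  ord <- match(stage_per_block, c("random", "unilateral", "bilateral"))
  if (any(diff(ord) < 0))
    stop("stage_per_block must be monotone in stage order")
  structure(list(id = id, stage_per_block = stage_per_block,
                 unilateral_dim = unilateral_dim, sigma = sigma, seed = seed,
                 experiment = experiment, condition = condition,
                 train_policy = train_policy, train_sigma = train_sigma),
            class = "participant_spec")
}

#' Simulate one participant's trial log
#'
#' Builds the participant's schedule and samples every response: test trials
#' from the block's assigned policy density, training trials according to the
#' spec's training policy.
#'
#' @param spec A [participant_spec()].
#' @param mapping A [make_mapping()] object (if `NULL`, a participant-specific
#'   mapping is drawn from the spec seed).
#' @param mapping_kind Used when `mapping` is `NULL`.
#' @return A trial-log data frame (schedule columns plus `id`, `resp_x`,
#'   `resp_y`, `points`).
#' @export
simulate_participant <- function(spec, mapping = NULL,
                                 mapping_kind = "grid") {
  seeds <- derive_seeds(spec$seed, 4)
  if (is.null(mapping))
    mapping <- make_mapping(mapping_kind, seed = seeds[1])
  curr <- make_curriculum(spec$experiment, mapping, spec$condition, seeds[2])
  n_blocks <- length(spec$stage_per_block)
  sched <- make_schedule(curr, mapping, seeds[3], n_blocks = n_blocks)
  n <- nrow(sched)
  resp <- matrix(NA_real_, n, 2)
  with_seed(seeds[4], {
    for (i in seq_len(n)) {
      b <- sched$block[i]
      truth <- c(sched$truth_x[i], sched$truth_y[i])
      if (sched$phase[i] == "test") {
        resp[i, ] <- sample_policy_response(1, spec$stage_per_block[b],
                                            mapping, truth,
                                            spec$unilateral_dim, spec$sigma)
      } else {
        kind <- switch(spec$train_policy,
                       bilateral = "bilateral",
                       random = "random",
                       ramp = if (b == 1) "random" else "bilateral")
        resp[i, ] <- sample_policy_response(1, kind, mapping, truth,
                                            sigma = spec$train_sigma)
      }
    }
  })
  d <- sqrt((resp[, 1] - sched$truth_x)^2 + (resp[, 2] - sched$truth_y)^2)
  cbind(id = spec$id, sched,
        data.frame(resp_x = resp[, 1], resp_y = resp[, 2],
                   points = score_points(d)))
}

# Draw a monotone stage schedule for a given model, with switch blocks
# uniform in the given ranges. Assumes a seeded RNG.
draw_stage_schedule <- function(model, n_blocks = 14,
                                switch_range = c(2, 13)) {
  stages <- POLICY_MODELS[[model]]
  k <- length(stages)
  if (k == 1) return(list(stages = rep(stages, n_blocks),
                          switches = integer(0)))
  sw <- sort(sample(seq(switch_range[1], switch_range[2]), k - 1))
  starts <- c(1, sw)
  lens <- diff(c(starts, n_blocks + 1))
  list(stages = rep(stages, lens), switches = sw)
}

#' Simulate a cohort with known ground-truth policies
#'
#' Generates `n` participants whose test-trial policies follow the given
#' stagewise model(s), together with a manifest recording every true policy
#' parameter for recovery scoring.
#'
#' @param n Number of participants.
#' @param seed Master seed; per-participant streams are disjoint.
#' @param mapping_kind `"grid"` or `"polar"`.
#' @param model Policy model name(s), recycled over participants (see
#'   [fit_policy_sequence()] for the admissible seven).
#' @param sigma Response dispersion in px.
#' @param experiment,condition Curriculum settings.
#' @param switch_range Inclusive block range in which switch points are
#'   drawn.
#' @param share_mapping If `TRUE` (default) all participants share one
#'   mapping (cheaper density caching); otherwise each gets their own.
#' @param train_policy Training response policy (see [participant_spec()]).
#' @param n_blocks Number of blocks.
#' @return A list of class `synthetic_cohort`: `trials` (row-bound logs),
#'   `manifest` (id, model, switch blocks, unilateral dim, sigma, seed),
#'   `mapping` (the shared mapping, or a list).
#' @export
simulate_cohort <- function(n, seed = 1L, mapping_kind = "grid",
                            model = "random-bilateral", sigma = 20,
                            experiment = 1, condition = "aligned",
                            switch_range = c(2, 13), share_mapping = TRUE,
                            train_policy = "ramp", n_blocks = 14) {
  seeds <- derive_seeds(seed, n + 2L)
  shared_map <- if (share_mapping)
    make_mapping(mapping_kind, seed = seeds[n + 1]) else NULL
  model <- rep_len(model, n)
  logs <- vector("list", n)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    drawn <- with_seed(seeds[i], list(
      sched = draw_stage_schedule(model[i], n_blocks, switch_range),
      dim = sample(1:2, 1)))
    spec <- participant_spec(
      id = sprintf("p%03d", i), stage_per_block = drawn$sched$stages,
      unilateral_dim = drawn$dim, sigma = sigma, seed = seeds[i],
      experiment = experiment, condition = condition,
      train_policy = train_policy)
    logs[[i]] <- simulate_participant(spec, mapping = shared_map,
                                      mapping_kind = mapping_kind)
    man[[i]] <- data.frame(
      id = spec$id, model = model[i],
      switch1 = drawn$sched$switches[1] %||% NA_integer_,
      switch2 = drawn$sched$switches[2] %||% NA_integer_,
      unilateral_dim = drawn$dim, sigma = sigma, seed = seeds[i])
  }
  structure(list(trials = do.call(rbind, logs),
                 manifest = do.call(rbind, man),
                 mapping = shared_map),
            class = "synthetic_cohort")
}
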