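# Stagewise policy-sequence models: each block of test responses is assigned
# one of the random / unilateral / bilateral policies, with transitions
# allowed only in ascending order of number of dimensions learned and only at
# block boundaries.

POLICY_MODELS <- list(
  "random"                      = "random",
  "unilateral"                  = "unilateral",
  "bilateral"                   = "bilateral",
  "random-unilateral"           = c("random", "unilateral"),
  "random-bilateral"            = c("random", "bilateral"),
  "unilateral-bilateral"        = c("unilateral", "bilateral"),
  "random-unilateral-bilateral" = c("random", "unilateral", "bilateral")
)

# Per-block log likelihood of one participant's test responses under each
# stage density: a blocks x 4 matrix (random, unilateral dim 1, unilateral
# dim 2, bilateral).
block_stage_loglik <- function(responses, mapping, sigma = 20, step = 2,
                               n_blocks = 14) {
  cl <- clamp_to_disk(responses$resp_x, responses$resp_y,
                      mapping$arena$radius)
  n <- nrow(responses)
  ll <- matrix(0, n, 4,
               dimnames = list(NULL, c("random", "uni1", "uni2", "bilateral")))
  ll[, "random"] <- log_density(density_random(mapping$arena, step),
                                cl$x, cl$y)
  tkey <- paste(signif(responses$truth_x, 10), signif(responses$truth_y, 10))
  for (k in unique(tkey)) {
    idx <- which(tkey == k)
    truth <- c(responses$truth_x[idx[1]], responses$truth_y[idx[1]])
    ll[idx, "bilateral"] <-
      log_density(density_bilateral(mapping, truth, sigma, step),
                  cl$x[idx], cl$y[idx])
    ll[idx, "uni1"] <-
      log_density(density_unilateral(mapping, truth, 1, sigma, step),
                  cl$x[idx], cl$y[idx])
    ll[idx, "uni2"] <-
      log_density(density_unilateral(mapping, truth, 2, sigma, step),
                  cl$x[idx], cl$y[idx])
  }
  out <- matrix(0, n_blocks, 4, dimnames = list(NULL, colnames(ll)))
  for (b in seq_len(n_blocks))
    out[b, ] <- colSums(ll[responses$block == b, , drop = FALSE])
  out
}

# All compositions of n_blocks into k consecutive runs (runs may be empty,
# so every smaller stage set is nested inside every larger one), as a matrix
# of run lengths, one row per assignment.
stage_compositions <- function(n_blocks, k) {
  if (k == 1) return(matrix(n_blocks, 1, 1))
  if (k == 2) {
    b <- 0:n_blocks
    return(cbind(b, n_blocks - b))
  }
  out <- list()
  for (b1 in 0:n_blocks)
    for (b2 in 0:(n_blocks - b1))
      out[[length(out) + 1]] <- c(b1, b2, n_blocks - b1 - b2)
  do.call(rbind, out)
}

#' Fit one stagewise policy-sequence model
#'
#' Exhaustively searches all monotone assignments of blocks to the model's
#' stages (consecutive runs in the fixed order random < unilateral <
#' bilateral; a stage may occupy zero blocks, so every smaller stage set is
#' nested within every larger one and adding a stage can never decrease the
#' maximised likelihood) and, where a unilateral stage exists, both choices
#' of the learned dimension. BIC separates nested ties in favour of fewer
#' switch points. Each block's
#' likelihood is the product over its test trials of the assigned stage's
#' density at the response. Model evidence is approximated by -BIC/2 with the
#' number of free parameters equal to the number of switch points plus one if
#' the unilateral dimension is fitted.
#'
#' @param responses One participant's test-trial data frame (`block`,
#'   `truth_x`, `truth_y`, `resp_x`, `resp_y`).
#' @param mapping A [make_mapping()] object.
#' @param stage_set One of the seven admissible models, e.g.
#'   `"random-bilateral"` (see `names(hebbgate:::POLICY_MODELS)`), or a
#'   character vector of stages in ascending order.
#' @param sigma Stage-density dispersion in px.
#' @param block_ll Optional precomputed [block_stage_loglik] matrix (skips
#'   density evaluation; used when fitting many models to one participant).
#' @param n_blocks Number of blocks (default 14).
#' @param step Lattice step in px.
#' @return A list of class `policy_fit`: `model`, `stages`, `switch_blocks`
#'   (first block of each stage after the first), `unilateral_dim` (NA if no
#'   unilateral stage), `block_assignment`, `loglik`, `n_free_params`,
#'   `evidence`.
#' @export
fit_policy_sequence <- function(responses, mapping, stage_set, sigma = 20,
                                block_ll = NULL, n_blocks = 14, step = 2) {
  stages <- if (length(stage_set) == 1 && stage_set %in% names(POLICY_MODELS))
    POLICY_MODELS[[stage_set]] else stage_set
  model_name <- paste(stages, collapse = "-")
  if (!model_name %in% names(POLICY_MODELS))
    stop(sprintf("inadmissible stage set: %s", model_name))
  if (is.null(block_ll))
    block_ll <- block_stage_loglik(responses, mapping, sigma, step, n_blocks)
  n_trials <- if (!is.null(responses)) nrow(responses) else 16 * n_blocks
  has_uni <- "unilateral" %in% stages
  dims <- if (has_uni) 1:2 else 1
  k <- length(stages)
  comp <- stage_compositions(n_blocks, k)

  best <- list(loglik = -Inf)
  for (dim in dims) {
    cols <- vapply(stages, function(s) switch(s,
      random = "random", bilateral = "bilateral",
      unilateral = paste0("uni", dim)), character(1))
    cum <- apply(rbind(0, block_ll[, cols, drop = FALSE]), 2, cumsum)
    for (r in seq_len(nrow(comp))) {
      ends <- cumsum(comp[r, ])
      starts <- c(1, ends[-k] + 1)
      ll <- sum(cum[cbind(ends + 1, seq_len(k))] -
                  cum[cbind(starts, seq_len(k))])
      if (ll > best$loglik)
        best <- list(loglik = ll, starts = starts, dim = dim)
    }
  }
  n_free <- (k - 1) + as.integer(has_uni)
  assignment <- rep(stages, diff(c(best$starts, n_blocks + 1)))
  structure(list(
    model = model_name, stages = stages,
    switch_blocks = if (k > 1) best$starts[-1] else integer(0),
    unilateral_dim = if (has_uni) best$dim else NA_integer_,
    block_assignment = assignment,
    loglik = best$loglik, n_free_params = n_free,
    evidence = best$loglik - 0.5 * n_free * log(n_trials)
  ), class = "policy_fit")
}

#' Fit all seven policy-sequence models to one participant
#'
#' @inheritParams fit_policy_sequence
#' @param models Character vector of model names (default: all seven).
#' @return A named list of [fit_policy_sequence()] results.
#' @export
fit_all_policies <- function(responses, mapping, sigma = 20,
                             models = names(POLICY_MODELS), n_blocks = 14,
                             step = 2) {
  block_ll <- block_stage_loglik(responses, mapping, sigma, step, n_blocks)
  fits <- lapply(models, function(m)
    fit_policy_sequence(responses, mapping, m, sigma, block_ll = block_ll,
                        n_blocks = n_blocks, step = step))
  names(fits) <- models
  fits
}

#' Best model for a participant, with principled tie-breaking
#'
#' Ties in evidence are broken toward the model with fewer free parameters,
#' then lexicographically by model name.
#'
#' @param fits A [fit_all_policies()] list.
#' @return The name of the winning model.
#' @export
best_policy_model <- function(fits) {
  ev <- vapply(fits, `[[`, numeric(1), "evidence")
  np <- vapply(fits, `[[`, numeric(1), "n_free_params")
  ord <- order(-ev, np, names(fits))
  names(fits)[ord[1]]
}

#' Does the best model include a unilateral stage?
#'
#' @param fits A [fit_all_policies()] list covering all seven models.
#' @return Logical scalar.
#' @export
unilateral_attribution <- function(fits) {
  grepl("unilateral", best_policy_model(fits))
}

#' Random-effects Bayesian model selection
#'
#' Variational Dirichlet scheme for estimating population model frequencies
#' from per-participant log model evidences: starting from the uniform prior
#' concentration, iterate participant responsibilities
#' `u_nk = exp(evidence_nk + digamma(alpha_k) - digamma(sum(alpha)))`
#' (normalised over models) and concentration updates
#' `alpha = alpha0 + colSums(responsibilities)` to convergence.
#'
#' @param evidences Participants x models matrix of log evidences.
#' @param alpha0 Prior concentration per model (default 1).
#' @param tol Convergence tolerance on the concentration (default 1e-6).
#' @param max_iter Iteration cap.
#' @return A list of class `bms_result`: `dirichlet_alpha`,
#'   `expected_frequencies` (sums to 1), `posterior_probabilities`
#'   (rows sum to 1), `iterations`.
#' @export
rfx_bms <- function(evidences, alpha0 = 1, tol = 1e-6, max_iter = 10000) {
  evidences <- as.matrix(evidences)
  if (any(!is.finite(evidences))) {
    bad <- which(!is.finite(evidences), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite evidence for participant %d, model %d",
                 bad[1], bad[2]))
  }
  n <- nrow(evidences); k <- ncol(evidences)
  alpha <- rep(alpha0, k)
  for (it in seq_len(max_iter)) {
    lu <- sweep(evidences, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    g <- exp(lu - apply(lu, 1, logsumexp))
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  structure(list(dirichlet_alpha = alpha,
                 expected_frequencies = alpha / sum(alpha),
                 posterior_probabilities = g,
                 iterations = it),
            class = "bms_result")
}

# Lattice expectations of the per-trial LLR (bilateral vs random) when the
# response is drawn from the bilateral resp. random density for one truth.
expected_llr_components <- function(mapping, truth, sigma = 20, step = 2) {
  key <- paste0("ellr_", mapping$kind, "|", signif(truth[1], 10), "|",
                signif(truth[2], 10), "|", sigma, "|",
                mapping$arena$radius, "|", step)
  if (!is.null(.hg_cache[[key]])) return(.hg_cache[[key]])
  lat <- disk_lattice(mapping$arena$radius, step)
  lb <- log_density(density_bilateral(mapping, truth, sigma, step),
                    lat$x, lat$y)
  lr <- log_density(density_random(mapping$arena, step), lat$x, lat$y)
  val <- lb - lr
  res <- c(bilateral = sum(exp(lb) * val) * step^2,
           random = sum(exp(lr) * val) * step^2)
  .hg_cache[[key]] <- res
  res
}

#' Performance-matched random-bilateral simulated cohort
#'
#' For every participant and block, finds the mixture weight `w` in [0, 1]
#' such that responses drawn from `w * bilateral + (1 - w) * random` have the
#' observed per-block LLR in expectation (the expected block LLR is linear in
#' `w`, so the matching weight is solved in closed form and clamped), then
#' samples one synthetic response per original test trial from the fitted
#' mixture. The simulated cohort is thus matched block by block in
#' performance but constrained to the random-to-bilateral policy axis.
#'
#' @param trials Cohort test-trial data frame (`id`, `block`, `truth_x`,
#'   `truth_y`, `resp_x`, `resp_y`).
#' @param mapping A single [make_mapping()] shared by the cohort, or a named
#'   list of mappings keyed by participant id.
#' @param sigma Bilateral dispersion in px.
#' @param seed Master seed for the response sampling.
#' @param step Lattice step in px.
#' @return A list: `trials` (synthetic logs, ids suffixed `"_sim"`),
#'   `weights` (data frame id, block, w, clamped).
#' @export
build_matched_cohort <- function(trials, mapping, sigma = 20, seed = 1L,
                                 step = 2) {
  if ("phase" %in% names(trials)) trials <- trials[trials$phase == "test", ]
  ids <- unique(trials$id)
  seeds <- derive_seeds(seed, length(ids))
  out <- vector("list", length(ids))
  wts <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    tt <- trials[trials$id == ids[j], ]
    map_j <- if (inherits(mapping, "cue_mapping")) mapping
             else mapping[[as.character(ids[j])]]
    obs <- llr(tt, map_j, sigma, step = step)
    rx <- numeric(nrow(tt)); ry <- numeric(nrow(tt))
    wrow <- data.frame(id = ids[j], block = sort(unique(tt$block)), w = NA,
                       clamped = FALSE)
    sub_seeds <- derive_seeds(seeds[j], nrow(wrow))
    for (bi in seq_len(nrow(wrow))) {
      b <- wrow$block[bi]
      idx <- which(tt$block == b)
      comp <- vapply(idx, function(i)
        expected_llr_components(map_j, c(tt$truth_x[i], tt$truth_y[i]),
                                sigma, step), numeric(2))
      e_bi <- sum(comp["bilateral", ]); e_rnd <- sum(comp["random", ])
      w <- (obs$per_block[b] - e_rnd) / (e_bi - e_rnd)
      if (w > 1 || w < 0) wrow$clamped[bi] <- TRUE
      w <- min(max(w, 0), 1)
      wrow$w[bi] <- w
      samp <- with_seed(sub_seeds[bi], {
        use_bi <- stats::runif(length(idx)) < w
        t(vapply(seq_along(idx), function(q) {
          i <- idx[q]
          kind <- if (use_bi[q]) "bilateral" else "random"
          sample_policy_response(1, kind, map_j,
                                 c(tt$truth_x[i], tt$truth_y[i]),
                                 sigma = sigma)
        }, numeric(2)))
      })
      rx[idx] <- samp[, 1]; ry[idx] <- samp[, 2]
    }
    sim <- tt
    sim$id <- paste0(ids[j], "_sim")
    sim$resp_x <- rx; sim$resp_y <- ry
    if ("points" %in% names(sim))
      sim$points <- score_points(sqrt((rx - sim$truth_x)^2 +
                                        (ry - sim$truth_y)^2))
    out[[j]] <- sim
    wts[[j]] <- wrow
  }
  if (any(vapply(wts, function(w) any(w$clamped), logical(1))))
    message("some block LLRs lay outside the pure random..bilateral range; ",
            "mixture weights clamped to [0, 1]")
  list(trials = do.call(rbind, out), weights = do.call(rbind, wts))
}

# Descending 4-parameter sigmoid err(t) = lo + (hi - lo)/(1 + exp((t - t0)/k))
# fitted by multi-start bounded least squares. Returns t0 and a degeneracy
# flag (flat error trajectories get t0 at the trial-range midpoint).
fit_sigmoid_inflection <- function(t, err, n_starts = 5) {
  rng <- range(t)
  mid <- mean(rng)
  if (stats::sd(err) < 1e-12)
    return(list(t0 = mid, degenerate = TRUE, sse = 0))
  sse <- function(par) {
    pred <- par[1] + (par[2] - par[1]) / (1 + exp((t - par[3]) / par[4]))
    sum((err - pred)^2)
  }
  lo0 <- stats::quantile(err, 0.1); hi0 <- stats::quantile(err, 0.9)
  starts <- stats::quantile(t, seq(0.1, 0.9, length.out = n_starts))
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(c(lo0, hi0, s, diff(rng) / 8), sse,
                            method = "L-BFGS-B",
                            lower = c(-Inf, -Inf, rng[1], 1e-2),
                            upper = c(Inf, Inf, rng[2], Inf)),
               silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    return(list(t0 = mid, degenerate = TRUE, sse = NA))
  list(t0 = best$par[3], degenerate = abs(best$par[2] - best$par[1]) < 1e-8,
       sse = best$value)
}

#' Cross-validated per-dimension inflection-point difference
#'
#' Splits one participant's test trials into odd and even folds by
#' chronological index. On one fold, fits a descending sigmoid to the error
#' magnitude over time separately for each spatial dimension (grid: |dx|,
#' |dy|; polar: |drho|, wrapped |dphi|) and labels the dimensions earlier /
#' later by fitted inflection point; on the other fold, measures
#' `t0(later) - t0(earlier)` under the first fold's labels. The procedure is
#' repeated with the folds swapped and the two outcomes averaged. Parallel
#' (bilateral-only) learning predicts differences centred on zero; a
#' unilateral interim stage predicts consistently positive differences.
#'
#' @param responses One participant's test trials in chronological order.
#' @param mapping A [make_mapping()] object.
#' @return A list of class `inflection_result`: `cv_difference` (trials),
#'   `per_fold` (data frame of per-fold per-dimension t0), `degenerate`.
#' @export
crossval_inflection <- function(responses, mapping) {
  n <- nrow(responses)
  t_idx <- seq_len(n)
  if (mapping$kind == "grid") {
    e1 <- abs(responses$resp_x - responses$truth_x)
    e2 <- abs(responses$resp_y - responses$truth_y)
  } else {
    e1 <- abs(sqrt(responses$resp_x^2 + responses$resp_y^2) -
                sqrt(responses$truth_x^2 + responses$truth_y^2))
    e2 <- abs(wrap_angle(atan2(responses$resp_y, responses$resp_x) -
                           atan2(responses$truth_y, responses$truth_x)))
  }
  folds <- list(odd = t_idx %% 2 == 1, even = t_idx %% 2 == 0)
  fits <- lapply(folds, function(f) list(
    d1 = fit_sigmoid_inflection(t_idx[f], e1[f]),
    d2 = fit_sigmoid_inflection(t_idx[f], e2[f])))
  one_direction <- function(label_fold, measure_fold) {
    lab <- fits[[label_fold]]
    early_is_d1 <- lab$d1$t0 <= lab$d2$t0
    mea <- fits[[measure_fold]]
    if (early_is_d1) mea$d2$t0 - mea$d1$t0 else mea$d1$t0 - mea$d2$t0
  }
  cv <- mean(c(one_direction("odd", "even"), one_direction("even", "odd")))
  per_fold <- data.frame(
    fold = rep(c("odd", "even"), each = 2),
    dimension = rep(1:2, 2),
    t0 = c(fits$odd$d1$t0, fits$odd$d2$t0, fits$even$d1$t0, fits$even$d2$t0),
    degenerate = c(fits$odd$d1$degenerate, fits$odd$d2$degenerate,
                   fits$even$d1$degenerate, fits$even$d2$degenerate))
  structure(list(cv_difference = cv, per_fold = per_fold,
                 degenerate = any(per_fold$degenerate)),
            class = "inflection_result")
}

#' Block-to-block LLR changes
#'
#' First differences of the per-block LLR series for training and test
#' trials (13 values each for 14 blocks).
#'
#' @param train_llr,test_llr Numeric per-block LLR vectors (length 14).
#' @return A list with `train` and `test` difference vectors.
#' @export
delta_llr <- function(train_llr, test_llr) {
  stopifnot(length(train_llr) == length(test_llr))
  list(train = diff(train_llr), test = diff(test_llr))
}
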