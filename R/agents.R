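#' Agent hyperparameters
#'
#' One shared hyperparameter set is used for all curricula and mappings.
#' Internally the network produces translations and expansion in units of the
#' arena radius and rotation in half-turns (scaled by pi on output), and SGD
#' minimises squared error in the task's native geometry normalised by the
#' squared radius, so all four effector channels share a curvature scale and
#' a single learning rate.
#'
#' @param sgd_rate SGD learning rate on the normalised loss.
#' @param steps_per_trial Gradient steps taken on each feedback trial.
#' @param tau Gating threshold in (0, 0.5): a gate is open when its Hebbian
#'   weight exceeds `tau`. The Hebbian dynamics drive a gate whose input and
#'   output always change together to the fixed point 0.5, and gates whose
#'   output also co-varies with the other cue dimension to about 0.44 under
#'   ambiguous (interleaved) trial orderings and lower under blocked ones.
#'   The default 0.43 therefore opens cleanly coupled gates under any
#'   ordering, admits ambiguous couplings under interleaving (degrading its
#'   gate selectivity, as observed behaviourally), and keeps incidental
#'   couplings shut.
#' @param alpha_U Hebbian learning rate in (0, 1].
#' @param lambda Discount factor in (0, 1] weighting comparisons with more
#'   recent trials of the current block more heavily.
#' @param w_init_sd Standard deviation of the Normal(0, sd^2) initialisation
#'   of the feedforward weights (normalised units).
#' @param rho_init Positive initial bias of the expansion channel, in units
#'   of the arena radius (split over the two active input slots). An outward
#'   reach prior: it keeps the expansion channel in its positive basin, so
#'   rotation learning is not deadlocked between the two sign-symmetric
#'   solutions of the composed effector map.
#' @param eps_z Tolerance below which two output coordinates count as equal
#'   when computing output surprise (guards float noise only).
#' @return A list of class `agent_hyperparams`.
#' @export
agent_hyperparams <- function(sgd_rate = 0.025, steps_per_trial = 3,
                              tau = 0.43, alpha_U = 0.25, lambda = 0.5,
                              w_init_sd = 0.01, rho_init = 0.4,
                              eps_z = 1e-6) {
  stopifnot(sgd_rate >= 0, steps_per_trial >= 1,
            tau > 0, tau < 0.5, alpha_U >= 0, alpha_U <= 1,
            lambda > 0, lambda <= 1)
  structure(list(sgd_rate = sgd_rate, steps_per_trial = steps_per_trial,
                 tau = tau, alpha_U = alpha_U, lambda = lambda,
                 w_init_sd = w_init_sd, rho_init = rho_init, eps_z = eps_z),
            class = "agent_hyperparams")
}

#' Two-hot cue encoding
#'
#' @param color,shape Integer vectors in 0..4.
#' @return A 10-vector (or 10-column matrix for vector input): positions 1-5
#'   one-hot in color, positions 6-10 one-hot in shape.
#' @export
encode_cue <- function(color, shape) {
  stopifnot(all(color %in% 0:4), all(shape %in% 0:4))
  n <- max(length(color), length(shape))
  color <- rep_len(color, n); shape <- rep_len(shape, n)
  x <- matrix(0, n, 10)
  x[cbind(seq_len(n), color + 1)] <- 1
  x[cbind(seq_len(n), shape + 6)] <- 1
  if (n == 1) drop(x) else x
}

#' Compose the four effectors into an arena point
#'
#' The output effectors are horizontal translation, vertical translation,
#' expansion rho and rotation phi. The cursor lands at
#' p = R(phi) (trans_x + rho, trans_y), rotation about the arena centre, so a
#' pure grid solution uses the translations (rho = phi = 0) and a pure polar
#' solution uses expansion and rotation (trans = 0).
#'
#' @param e Numeric 4-vector `(trans_x, trans_y, rho, phi)`; translations and
#'   rho in pixels, phi in radians.
#' @return Numeric `(x, y)` in pixels.
#' @export
effector_to_point <- function(e) {
  stopifnot(length(e) == 4, all(is.finite(e)))
  v <- c(e[1] + e[3], e[2])
  c(cos(e[4]) * v[1] - sin(e[4]) * v[2],
    sin(e[4]) * v[1] + cos(e[4]) * v[2])
}

#' Redundant effector description of a feedback point
#'
#' Expresses a feedback (ground-truth) location in all four effector
#' coordinates; these are the output signals whose trial-to-trial changes
#' drive the Hebbian update. phi at the exact arena centre is defined as 0.
#'
#' @param p Numeric `(x, y)` in pixels.
#' @return Numeric 4-vector `(trans_x, trans_y, rho, phi)`.
#' @export
point_to_effector_targets <- function(p) {
  stopifnot(length(p) == 2, all(is.finite(p)))
  rho <- sqrt(sum(p^2))
  phi <- if (rho == 0) 0 else atan2(p[2], p[1])
  c(p[1], p[2], rho, phi)
}

#' Initialise an agent
#'
#' @param agent_kind `"vanilla"` (plain linear effector network trained by
#'   SGD) or `"hebbian"` (the same network whose feedforward weights are
#'   binarily gated by separately learned Hebbian weights U; U starts at 0 so
#'   the network begins fully gated).
#' @param hyper An [agent_hyperparams()] object.
#' @param arena An [make_arena()] object (fixes the output scale).
#' @param seed Seed for the weight initialisation.
#' @return An agent state list with feedforward weights `W` (4 x 10,
#'   normalised units) and, for the Hebbian agent, gate weights `U` (4 x 10 in
#'   [0, 1]) and the within-block comparison `history`.
#' @export
init_agent <- function(agent_kind = c("vanilla", "hebbian"),
                       hyper = agent_hyperparams(), arena = make_arena(),
                       seed = 1L) {
  agent_kind <- match.arg(agent_kind)
  W <- with_seed(seed, matrix(stats::rnorm(40, 0, hyper$w_init_sd), 4, 10))
  W[3, ] <- W[3, ] + hyper$rho_init / 2    # two-hot input: initial expansion = rho_init
  st <- list(kind = agent_kind, W = W, hyper = hyper, scale = arena$radius)
  if (agent_kind == "hebbian") {
    st$U <- matrix(0, 4, 10)
    st$history <- list()
  }
  structure(st, class = "hg_agent")
}

# Binary gate matrix: 1 where U > tau. Vanilla agents are fully open.
gate_matrix <- function(state) {
  if (state$kind == "hebbian") (state$U > state$hyper$tau) * 1
  else matrix(1, 4, 10)
}

#' Forward pass
#'
#' Computes `z = (W o g_tau(U)) x` (elementwise gating; vanilla agents have
#' all gates open) and scales the translation/expansion channels back to
#' pixels.
#'
#' @param state An [init_agent()] state.
#' @param x Two-hot 10-vector input.
#' @return Effector 4-vector `(trans_x, trans_y, rho, phi)` in pixel/radian
#'   units, suitable for [effector_to_point()].
#' @export
agent_forward <- function(state, x) {
  z <- drop((state$W * gate_matrix(state)) %*% x)
  c(z[1:3] * state$scale, z[4] * pi)
}

#' One trial of SGD on the feedforward weights
#'
#' Takes `steps_per_trial` gradient steps on the squared error between the
#' composed response point and the feedback point, measured in the task's
#' native geometry (normalised by the squared arena radius): for the grid
#' mapping the plain squared Euclidean distance; for the polar mapping the
#' squared radial error plus the squared arc-length error at the feedback
#' radius, with the angular residual wrapped to (-pi, pi]. The two losses
#' agree to second order near the feedback point; the polar form unrolls the
#' circle so rotation errors near half a turn still produce a useful
#' gradient. For the Hebbian agent gradients flow only through open gates;
#' weights behind closed gates are untouched.
#'
#' @param state Agent state.
#' @param x Two-hot input vector.
#' @param feedback Feedback point `(x, y)` in pixels.
#' @param geometry `"cartesian"` or `"polar"` error geometry (use the
#'   mapping's kind; [run_agent()] does this automatically).
#' @return The updated state.
#' @export
sgd_step <- function(state, x, feedback, geometry = c("cartesian", "polar")) {
  geometry <- match.arg(geometry)
  G <- gate_matrix(state)
  f <- feedback / state$scale
  lr <- state$hyper$sgd_rate
  rho_f <- sqrt(sum(f^2))
  phi_f <- if (rho_f == 0) 0 else atan2(f[2], f[1])
  for (i in seq_len(state$hyper$steps_per_trial)) {
    z <- drop((state$W * G) %*% x)
    phi <- z[4] * pi
    cs <- cos(phi); sn <- sin(phi)
    v <- c(z[1] + z[3], z[2])
    p <- c(cs * v[1] - sn * v[2], sn * v[1] + cs * v[2])
    if (geometry == "cartesian") {
      gp <- 2 * (p - f)
    } else {
      rho_p <- sqrt(sum(p^2))
      if (rho_p < 1e-8) {
        gp <- 2 * (p - f)          # at the centre the geometries coincide
      } else {
        u_hat <- p / rho_p
        t_hat <- c(-u_hat[2], u_hat[1])
        dphi_res <- wrap_angle(atan2(p[2], p[1]) - phi_f)
        # radial pull plus a tangential pull of one arc length at the
        # feedback radius; agrees with the Euclidean gradient to first
        # order and stays bounded at the centre
        gp <- 2 * (rho_p - rho_f) * u_hat + 2 * rho_f * dphi_res * t_hat
      }
    }
    gv <- c(cs * gp[1] + sn * gp[2], -sn * gp[1] + cs * gp[2])
    dphi <- gp[1] * (-sn * v[1] - cs * v[2]) + gp[2] * (cs * v[1] - sn * v[2])
    gz <- c(gv[1], gv[2], gv[1], pi * dphi)
    state$W <- state$W - lr * (outer(gz, x) * G)
  }
  state
}

#' Hebbian gate update with preactivated depression
#'
#' Compares the current feedback trial with every earlier feedback trial of
#' the same block. For each pair, input surprise is the elementwise absolute
#' input difference and output surprise the indicator of an output-coordinate
#' change. Gating implements symmetric coincidence detection. A gate is
#' excited when its input and output change together
#' (`(dz outer dx) (1 - U)`) and depressed whenever its input changes,
#' whatever the output does (`(1 outer dx) U`, preactivated depression); a
#' pair whose output always follows its input is thereby driven to the fixed
#' point 0.5 of `(1 - U) - U`. A gate is additionally depressed when its
#' output changes while its entire input dimension is static -- the converse
#' failure of co-variation -- which drives gates from promiscuous outputs
#' (those that also follow the other cue dimension) below the gate threshold.
#' Pairs are combined with normalised
#' discount weights lambda^(t-i) so recent comparisons dominate, scaled by
#' `alpha_U` and added to U. With these convex weights U stays in [0, 1]
#' without clipping. Finally the trial is appended to the block history.
#'
#' @param state Hebbian agent state.
#' @param x_t Two-hot input of the current feedback trial.
#' @param z_t Effector 4-vector of the feedback point, from
#'   [point_to_effector_targets()].
#' @return The updated state.
#' @export
hebb_update <- function(state, x_t, z_t) {
  stopifnot(state$kind == "hebbian")
  n_prev <- length(state$history)
  if (n_prev > 0) {
    lam <- state$hyper$lambda
    wts <- lam^(n_prev:1)           # weight for trials i = 1..n_prev
    wts <- wts / sum(wts)
    M <- matrix(0, 4, 10)
    for (i in seq_len(n_prev)) {
      hi <- state$history[[i]]
      dx <- abs(x_t - hi$x)
      dz <- as.numeric(abs(z_t - hi$z) > state$hyper$eps_z)
      # slots of an input dimension (color: 1-5, shape: 6-10) that did not
      # change between the two trials
      static_slots <- c(rep(all(dx[1:5] == 0), 5), rep(all(dx[6:10] == 0), 5))
      M <- M + wts[i] * (outer(dz, dx) * (1 - state$U) -
                           outer(rep(1, 4), dx) * state$U -
                           outer(dz, as.numeric(static_slots)) * state$U)
    }
    state$U <- state$U + state$hyper$alpha_U * M
  }
  state$history <- c(state$history, list(list(x = x_t, z = z_t)))
  state
}

#' Run an agent through a full schedule
#'
#' Iterates the schedule in trial order. On every trial the composed
#' response is confined to the arena disk (radial clamp), as the task
#' display confines the cursor. On training trials the agent responds, then
#' (Hebbian only) updates its gates from the feedback point, then takes SGD
#' steps on the feedforward weights. On test trials it responds
#' with no updates. The Hebbian comparison history is cleared at every block
#' boundary; U persists across blocks. Identical seeds give identical runs.
#'
#' @param agent_kind `"vanilla"` or `"hebbian"`.
#' @param schedule A [make_schedule()] data frame.
#' @param mapping The [make_mapping()] object the schedule was built with.
#' @param hyper An [agent_hyperparams()] object.
#' @param seed Seed for weight initialisation.
#' @param id Identifier recorded in the trial log.
#' @return A list of class `agent_run`: `trials` (the schedule plus `id`,
#'   `resp_x`, `resp_y`, `points`), and the final `state`.
#' @export
run_agent <- function(agent_kind, schedule, mapping,
                      hyper = agent_hyperparams(), seed = 1L,
                      id = paste0(agent_kind, "_", seed)) {
  state <- init_agent(agent_kind, hyper, mapping$arena, seed)
  radius <- mapping$arena$radius
  n <- nrow(schedule)
  rx <- numeric(n); ry <- numeric(n)
  cur_block <- 0L
  for (i in seq_len(n)) {
    if (schedule$block[i] != cur_block) {
      cur_block <- schedule$block[i]
      if (state$kind == "hebbian") state$history <- list()
    }
    x <- encode_cue(schedule$color[i], schedule$shape[i])
    p <- effector_to_point(agent_forward(state, x))
    # the display confines the cursor to the arena
    r <- sqrt(sum(p^2))
    if (r > radius) p <- p * ((radius - 1e-6) / r)
    rx[i] <- p[1]; ry[i] <- p[2]
    if (schedule$phase[i] == "train") {
      truth <- c(schedule$truth_x[i], schedule$truth_y[i])
      if (state$kind == "hebbian")
        state <- hebb_update(state, x, point_to_effector_targets(truth))
      state <- sgd_step(state, x, truth,
                        geometry = if (mapping$kind == "polar") "polar"
                                   else "cartesian")
    }
  }
  d <- sqrt((rx - schedule$truth_x)^2 + (ry - schedule$truth_y)^2)
  trials <- cbind(id = id, schedule,
                  data.frame(resp_x = rx, resp_y = ry,
                             points = score_points(pmin(d, Inf))))
  structure(list(trials = trials, state = state, agent_kind = agent_kind,
                 hyper = hyper, seed = seed),
            class = "agent_run")
}

#' Does the open-gate set match the ground-truth factorisation?
#'
#' For a grid mapping the ground truth routes the color-driving cue dimension
#' to one translation effector and the shape-driving dimension to the other;
#' for a polar mapping, to expansion and rotation respectively. The check
#' passes when every gate of the two ground-truth input-effector groups is
#' open and every other gate (the swapped groups and the two effectors the
#' mapping does not use) is closed.
#'
#' @param state Final Hebbian agent state.
#' @param mapping The mapping the agent was trained on.
#' @return Logical scalar.
#' @export
gates_match_truth <- function(state, mapping) {
  G <- gate_matrix(state) > 0
  rows <- if (mapping$kind == "grid") c(1, 2) else c(3, 4)
  dim1_cols <- if (mapping$color_dim == 1) 1:5 else 6:10
  dim2_cols <- setdiff(1:10, dim1_cols)
  want <- matrix(FALSE, 4, 10)
  want[rows[1], dim1_cols] <- TRUE
  want[rows[2], dim2_cols] <- TRUE
  all(G == want)
}
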