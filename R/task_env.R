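#' Arena geometry
#'
#' The response area is a disk centred at the origin. Responses and ground
#' truth locations live in arena-centred pixel coordinates with y increasing
#' upward.
#'
#' @param radius Arena radius in pixels (default 265, the task's value).
#' @return An object of class `arena`.
#' @export
make_arena <- function(radius = 265) {
  stopifnot(is.numeric(radius), length(radius) == 1, radius > 0)
  structure(list(radius = radius), class = "arena")
}

#' The 25-cue set
#'
#' Cues are colored shapes: five color levels crossed with five shape levels.
#'
#' @return A data frame with columns `color` and `shape`, each in 0..4,
#'   one row per cue (25 rows).
#' @export
cue_set <- function() {
  expand.grid(color = 0:4, shape = 0:4, KEEP.OUT.ATTRS = FALSE)
}

#' Ground-truth cue-to-location mapping
#'
#' Builds a grid or polar mapping from cues to arena points. In the grid
#' mapping one cue dimension drives the horizontal and the other the vertical
#' coordinate of a 5x5 lattice; in the polar mapping one dimension drives the
#' ring (radius) and the other the spoke (angle). Per-participant
#' randomisations -- which cue dimension drives which spatial rule, the ordinal
#' mapping of levels to magnitudes, and (polar only) a global rotation -- are
#' drawn from `seed` when `randomize = TRUE`.
#'
#' Defaults place the grid lattice at offsets {-2,...,2} * 90 px (corners at
#' ~254.6 px, inside the 265 px wall) and the rings at
#' {53, 106, 159, 212, 245} px with spokes 72 degrees apart.
#'
#' @param kind `"grid"` or `"polar"`.
#' @param seed Integer seed for the per-participant randomisations.
#' @param arena An [make_arena()] object.
#' @param grid_spacing Pixels between adjacent grid levels.
#' @param ring_radii Five ring radii in pixels (all < arena radius).
#' @param spoke_angles Five spoke angles in radians.
#' @param randomize If `FALSE`, use identity level orders, color driving
#'   dimension 1, and zero rotation (useful for deterministic examples).
#' @return An object of class `cue_mapping`.
#' @export
make_mapping <- function(kind = c("grid", "polar"), seed = 1L,
                         arena = make_arena(),
                         grid_spacing = 90,
                         ring_radii = c(53, 106, 159, 212, 245),
                         spoke_angles = 2 * pi * (0:4) / 5,
                         randomize = TRUE) {
  kind <- match.arg(kind)
  stopifnot(length(ring_radii) == 5, length(spoke_angles) == 5,
            all(ring_radii > 0), all(ring_radii < arena$radius))
  if (randomize) {
    draws <- with_seed(seed, list(
      color_dim = sample(1:2, 1),
      order1 = sample(0:4),
      order2 = sample(0:4),
      rotation = stats::runif(1, 0, 2 * pi)
    ))
  } else {
    draws <- list(color_dim = 1L, order1 = 0:4, order2 = 0:4, rotation = 0)
  }
  m <- structure(list(
    kind = kind,
    arena = arena,
    color_dim = draws$color_dim,
    level_order = list(dim1 = draws$order1, dim2 = draws$order2),
    polar_rotation = if (kind == "polar") draws$rotation else 0,
    grid_spacing = grid_spacing,
    ring_radii = ring_radii,
    spoke_angles = spoke_angles,
    seed = seed
  ), class = "cue_mapping")
  pts <- truth_location(m, cue_set()$color, cue_set()$shape)
  if (anyDuplicated(round(cbind(pts$x, pts$y), 9)))
    stop("mapping produces duplicate ground-truth points")
  if (any(pts$x^2 + pts$y^2 >= arena$radius^2))
    stop("mapping places ground-truth points outside the arena")
  m
}

# Spatial levels (0..4) along dim1/dim2 for given cues under a mapping.
cue_levels <- function(mapping, color, shape) {
  lev_c <- if (mapping$color_dim == 1) mapping$level_order$dim1[color + 1] else
    mapping$level_order$dim2[color + 1]
  lev_s <- if (mapping$color_dim == 1) mapping$level_order$dim2[shape + 1] else
    mapping$level_order$dim1[shape + 1]
  if (mapping$color_dim == 1) list(dim1 = lev_c, dim2 = lev_s)
  else list(dim1 = lev_s, dim2 = lev_c)
}

#' Ground-truth location of a cue
#'
#' Deterministically maps cues to arena points. Grid: dimension-1 level sets
#' x and dimension-2 level sets y, centred on the arena (level 2 at 0). Polar:
#' dimension-1 level picks the ring radius and dimension-2 level the spoke
#' angle (plus the participant rotation), converted to Cartesian.
#'
#' @param mapping A [make_mapping()] object.
#' @param color,shape Integer vectors in 0..4 (recycled to common length).
#' @return A data frame with columns `x` and `y` in pixels.
#' @export
truth_location <- function(mapping, color, shape) {
  stopifnot(all(color %in% 0:4), all(shape %in% 0:4))
  n <- max(length(color), length(shape))
  color <- rep_len(color, n); shape <- rep_len(shape, n)
  lev <- cue_levels(mapping, color, shape)
  if (mapping$kind == "grid") {
    data.frame(x = (lev$dim1 - 2) * mapping$grid_spacing,
               y = (lev$dim2 - 2) * mapping$grid_spacing)
  } else {
    rho <- mapping$ring_radii[lev$dim1 + 1]
    phi <- mapping$spoke_angles[lev$dim2 + 1] + mapping$polar_rotation
    data.frame(x = rho * cos(phi), y = rho * sin(phi))
  }
}

#' Training curriculum
#'
#' Partitions the 25 cues into 9 training and 16 test cues and fixes the
#' presentation regime. Experiment 1 manipulates axis alignment: `"aligned"`
#' training cues are one full level of each cue dimension (the central spatial
#' row + column in the grid mapping; the central ring + one spoke in the polar
#' mapping), sharing one overlap cue; `"misaligned"` training cues are the two
#' diagonals of the 5x5 cue lattice, sharing the central cue. Experiment 2
#' always uses axis-aligned cues from a uniformly random row + column
#' (ring + spoke) and manipulates ordering: `"blocked"` or `"interleaved"`.
#' Experiment 1 curricula are always blocked.
#'
#' @param experiment 1 or 2.
#' @param mapping A [make_mapping()] object (fixes the cue-to-space geometry
#'   the alignment refers to).
#' @param condition `"aligned"`/`"misaligned"` (Exp. 1) or
#'   `"blocked"`/`"interleaved"` (Exp. 2).
#' @param seed Participant-level seed driving the random axis choice (Exp. 2),
#'   the Exp. 1 polar spoke choice, and which axis is queried first in block 1.
#' @return An object of class `curriculum` with elements `train`, `test`
#'   (cue data frames), `axis1`, `axis2` (training cues by axis, overlap cue
#'   excluded), `overlap`, `ordering`, `first_axis`.
#' @export
make_curriculum <- function(experiment, mapping, condition, seed = 1L) {
  stopifnot(experiment %in% c(1, 2))
  ok <- if (experiment == 1) c("aligned", "misaligned") else
    c("blocked", "interleaved")
  if (!condition %in% ok)
    stop(sprintf("condition '%s' is not valid for experiment %d", condition,
                 experiment))
  cues <- cue_set()
  draws <- with_seed(seed, list(
    lev1 = sample(0:4, 1), lev2 = sample(0:4, 1),
    spoke = sample(0:4, 1), first_axis = sample(1:2, 1)
  ))

  if (experiment == 1 && condition == "misaligned") {
    ax1 <- data.frame(color = c(0, 1, 3, 4), shape = c(0, 1, 3, 4))  # main diagonal
    ax2 <- data.frame(color = c(0, 1, 3, 4), shape = c(4, 3, 1, 0))  # anti-diagonal
    overlap <- data.frame(color = 2, shape = 2)
  } else {
    # Axis-aligned cue cross: all cues at one dim1 spatial level plus all cues
    # at one dim2 spatial level. Exp. 1 uses the central row/column (grid) or
    # central ring + a random spoke (polar); Exp. 2 draws both at random.
    if (experiment == 1) {
      lev1 <- 2L
      lev2 <- if (mapping$kind == "polar") draws$spoke else 2L
    } else {
      lev1 <- draws$lev1
      lev2 <- draws$lev2
    }
    lev <- cue_levels(mapping, cues$color, cues$shape)
    on_ax1 <- lev$dim1 == lev1   # dim1 held at lev1, dim2 varying
    on_ax2 <- lev$dim2 == lev2
    ax1 <- cues[on_ax1 & !on_ax2, ]
    ax2 <- cues[on_ax2 & !on_ax1, ]
    overlap <- cues[on_ax1 & on_ax2, ]
  }
  train <- rbind(ax1, overlap, ax2)
  key <- function(d) paste(d$color, d$shape)
  test <- cues[!key(cues) %in% key(train), ]
  stopifnot(nrow(train) == 9, nrow(test) == 16)
  structure(list(
    experiment = experiment,
    mapping_kind = mapping$kind,
    condition = condition,
    ordering = if (experiment == 2 && condition == "interleaved")
      "interleaved" else "blocked",
    train = train, test = test,
    axis1 = ax1, axis2 = ax2, overlap = overlap,
    first_axis = draws$first_axis,
    seed = seed
  ), class = "curriculum")
}

#' Training-trial order within one block
#'
#' Blocked curricula query trials 1-4 from one axis, trial 5 the overlap cue
#' shared between the axes, and trials 6-9 the other axis; the axis queried
#' first alternates between blocks (the block-1 axis is a participant-level
#' randomisation held in the curriculum). Interleaved curricula present the
#' nine training cues in a uniformly random order.
#'
#' @param curriculum A [make_curriculum()] object.
#' @param block Block index in 1..14.
#' @param seed Seed for the within-axis (or full) shuffles.
#' @return A 9-row cue data frame in presentation order.
#' @export
order_training_trials <- function(curriculum, block, seed = 1L) {
  stopifnot(block %in% 1:14)
  shuffle <- function(d) d[with_seed(seed + block, sample(nrow(d))), ]
  if (curriculum$ordering == "interleaved") {
    return(shuffle(curriculum$train))
  }
  perms <- with_seed(seed + block, list(a = sample(4), b = sample(4)))
  first <- if ((block + curriculum$first_axis) %% 2 == 0) 1L else 2L
  axA <- if (first == 1) curriculum$axis1 else curriculum$axis2
  axB <- if (first == 1) curriculum$axis2 else curriculum$axis1
  rbind(axA[perms$a, ], curriculum$overlap, axB[perms$b, ])
}

#' Points awarded for a response
#'
#' 5 points for a distance under 20 px, 2 under 40 px, 1 under 60 px, else 0.
#' Intervals are half-open, so exactly 60 px scores 0. A response is "correct"
#' (for the training-accuracy criterion) when the distance is under 60 px.
#'
#' @param distance Non-negative distances in pixels.
#' @return Integer points, same length as `distance`.
#' @export
score_points <- function(distance) {
  if (any(is.na(distance)) || any(distance < 0))
    stop("distance must be non-negative")
  ifelse(distance < 20, 5L,
         ifelse(distance < 40, 2L,
                ifelse(distance < 60, 1L, 0L)))
}

#' Full 14-block trial schedule
#'
#' Each of 14 blocks queries all 25 cues exactly once: trials 1-9 are training
#' trials ordered by [order_training_trials()], trials 10-25 are test trials
#' in an independent uniform random order per block. 14 x 9 = 126 training
#' and 14 x 16 = 224 test trials in total.
#'
#' @param curriculum A [make_curriculum()] object.
#' @param mapping A [make_mapping()] object.
#' @param seed Seed for all trial-order randomisation.
#' @param n_blocks Number of blocks (default 14).
#' @return A data frame with columns `experiment`, `mapping`, `curriculum`,
#'   `block`, `trial`, `phase`, `color`, `shape`, `truth_x`, `truth_y`.
#' @export
make_schedule <- function(curriculum, mapping, seed = 1L, n_blocks = 14) {
  seeds <- derive_seeds(seed, 2L * n_blocks)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    tr <- order_training_trials(curriculum, b, seeds[b])
    te <- curriculum$test[with_seed(seeds[n_blocks + b],
                                    sample(nrow(curriculum$test))), ]
    cues <- rbind(tr, te)
    data.frame(block = b, trial = seq_len(nrow(cues)),
               phase = rep(c("train", "test"), c(nrow(tr), nrow(te))),
               color = cues$color, shape = cues$shape)
  })
  sched <- do.call(rbind, blocks)
  pts <- truth_location(mapping, sched$color, sched$shape)
  cbind(data.frame(experiment = curriculum$experiment,
                   mapping = mapping$kind,
                   curriculum = curriculum$condition),
        sched, truth_x = pts$x, truth_y = pts$y)
}
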