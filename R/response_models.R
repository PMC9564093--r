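# Proper probability densities over the arena disk for the random,
# unilateral and bilateral response policies, and LLR scoring.
#
# All densities share one Cartesian lattice over the disk and are normalised
# numerically on it, so truncation at the wall and the polar product form are
# handled uniformly and LLR comparisons are fair (identical support and
# discretisation for every model).

disk_lattice <- function(radius, step = 2) {
  key <- sprintf("lat_%g_%g", radius, step)
  if (!is.null(.hg_cache[[key]])) return(.hg_cache[[key]])
  ax <- seq(-radius + step / 2, radius - step / 2, by = step)
  g <- expand.grid(x = ax, y = ax, KEEP.OUT.ATTRS = FALSE)
  inside <- g$x^2 + g$y^2 <= radius^2
  lat <- list(x = g$x[inside], y = g$y[inside], step = step,
              n = sum(inside), radius = radius)
  .hg_cache[[key]] <- lat
  lat
}

# Angular dispersion for polar densities: sigma px of arc at the truth
# radius, capped at 0.3 rad.
sigma_phi_for <- function(sigma, rho_truth) {
  if (rho_truth <= 0) return(0.3)
  min(sigma / rho_truth, 0.3)
}

# Unnormalised log density of a DiskDensity at (x, y); -Inf outside the disk.
log_unnorm <- function(dens, x, y) {
  u <- switch(dens$kind,
    random = rep(0, length(x)),
    bilateral = if (dens$mapping_kind == "grid") {
      -((x - dens$truth[1])^2 + (y - dens$truth[2])^2) / (2 * dens$sigma^2)
    } else {
      rho <- sqrt(x^2 + y^2)
      phi <- atan2(y, x)
      -(rho - dens$rho0)^2 / (2 * dens$sigma^2) -
        wrap_angle(phi - dens$phi0)^2 / (2 * dens$sigma_phi^2)
    },
    unilateral = if (dens$mapping_kind == "grid") {
      if (dens$dim == 1) -(x - dens$truth[1])^2 / (2 * dens$sigma^2)
      else               -(y - dens$truth[2])^2 / (2 * dens$sigma^2)
    } else {
      if (dens$dim == 1) {
        rho <- sqrt(x^2 + y^2)
        -(rho - dens$rho0)^2 / (2 * dens$sigma^2)
      } else {
        phi <- atan2(y, x)
        -wrap_angle(phi - dens$phi0)^2 / (2 * dens$sigma_phi^2)
      }
    },
    stop("unknown density kind"))
  u[x^2 + y^2 > dens$radius^2] <- -Inf
  u
}

finish_density <- function(dens) {
  key <- paste0("norm_", paste(dens$kind, dens$mapping_kind,
                               dens$dim %||% "", dens$sigma %||% "",
                               signif(dens$truth[1] %||% 0, 10),
                               signif(dens$truth[2] %||% 0, 10),
                               dens$radius, dens$step, sep = "|"))
  if (is.null(.hg_cache[[key]])) {
    lat <- disk_lattice(dens$radius, dens$step)
    .hg_cache[[key]] <- logsumexp(log_unnorm(dens, lat$x, lat$y)) +
      2 * log(lat$step)
  }
  dens$log_norm <- .hg_cache[[key]]
  structure(dens, class = "disk_density")
}

#' Uniform (random-policy) density over the arena
#'
#' Constant inside the disk, zero outside, normalised on the shared lattice
#' (so its log density is within discretisation error of -ln(pi R^2)).
#'
#' @param arena An [make_arena()] object.
#' @param step Lattice step in pixels (default 2).
#' @return A `disk_density` object.
#' @export
density_random <- function(arena, step = 2) {
  finish_density(list(kind = "random", mapping_kind = "grid",
                      truth = c(0, 0), sigma = NA, dim = NA,
                      radius = arena$radius, step = step))
}

#' Bilateral (full generalisation) density
#'
#' A narrow distribution centred on the ground-truth point: an isotropic
#' Cartesian Gaussian for the grid mapping, and the product of a Gaussian in
#' radius and a wrapped Gaussian in angle (residuals wrapped to (-pi, pi],
#' evaluated pointwise with no Jacobian correction) for the polar mapping;
#' both truncated to the disk and renormalised on the lattice.
#'
#' @param mapping A [make_mapping()] object (fixes the coordinate system).
#' @param truth Ground-truth point `(x, y)` in pixels, inside the arena.
#' @param sigma Dispersion in px (Cartesian and radial components); the
#'   angular dispersion is `sigma` px of arc at the truth radius, capped at
#'   0.3 rad.
#' @param step Lattice step in pixels.
#' @return A `disk_density` object.
#' @export
density_bilateral <- function(mapping, truth, sigma = 20, step = 2) {
  if (sigma <= 0) stop("sigma must be positive")
  rho0 <- sqrt(sum(truth^2))
  finish_density(list(kind = "bilateral", mapping_kind = mapping$kind,
                      truth = truth, sigma = sigma, dim = NA,
                      rho0 = rho0, phi0 = atan2(truth[2], truth[1]),
                      sigma_phi = sigma_phi_for(sigma, rho0),
                      radius = mapping$arena$radius, step = step))
}

#' Unilateral (one-dimension) density
#'
#' Consistent with the ground truth on one spatial dimension and uniform over
#' the other: a Gaussian ridge along the truth column/row (grid), ring
#' (polar, `dim = 1`) or spoke (polar, `dim = 2`), truncated to the disk and
#' renormalised on the lattice.
#'
#' @inheritParams density_bilateral
#' @param dim Which spatial dimension is learned: 1 (x / radius) or
#'   2 (y / angle).
#' @return A `disk_density` object.
#' @export
density_unilateral <- function(mapping, truth, dim, sigma = 20, step = 2) {
  if (sigma <= 0) stop("sigma must be positive")
  stopifnot(dim %in% 1:2)
  rho0 <- sqrt(sum(truth^2))
  finish_density(list(kind = "unilateral", mapping_kind = mapping$kind,
                      truth = truth, sigma = sigma, dim = dim,
                      rho0 = rho0, phi0 = atan2(truth[2], truth[1]),
                      sigma_phi = sigma_phi_for(sigma, rho0),
                      radius = mapping$arena$radius, step = step))
}

#' Log density of a disk density at given points
#'
#' @param dens A `disk_density` object.
#' @param x,y Point coordinates in pixels.
#' @return Log densities (per px^2); `-Inf` outside the disk.
#' @export
log_density <- function(dens, x, y) {
  log_unnorm(dens, x, y) - dens$log_norm
}

#' Lattice integral of a disk density
#'
#' Diagnostic: should equal 1 up to floating point, by construction.
#'
#' @param dens A `disk_density` object.
#' @return Numeric scalar.
#' @export
density_lattice_integral <- function(dens) {
  lat <- disk_lattice(dens$radius, dens$step)
  sum(exp(log_density(dens, lat$x, lat$y))) * lat$step^2
}

# Clamp out-of-disk responses to just inside the boundary (real-data
# robustness); warns with the offending count.
clamp_to_disk <- function(x, y, radius) {
  r <- sqrt(x^2 + y^2)
  out <- r > radius
  if (any(out)) {
    warning(sprintf("%d response(s) outside the arena clamped to boundary",
                    sum(out)))
    f <- (radius - 1e-6) / r[out]
    x[out] <- x[out] * f
    y[out] <- y[out] * f
  }
  list(x = x, y = y)
}

#' Log-likelihood ratio of responses: bilateral vs random
#'
#' The main dependent measure. Each response contributes
#' `log d_bilateral(response) - log d_random(response)`; per-block LLRs sum
#' the trial log ratios of that block, and the participant LLR sums the block
#' LLRs. Positive values signal evidence for generalisation. The second-half
#' mean averages the per-block LLRs of blocks 8-14.
#'
#' @param responses Data frame with columns `block`, `truth_x`, `truth_y`,
#'   `resp_x`, `resp_y` (typically the test trials of one participant).
#' @param mapping A [make_mapping()] object.
#' @param sigma Bilateral dispersion in px (default 20).
#' @param n_blocks Number of blocks the experiment had (default 14); blocks
#'   with no responses contribute a per-block LLR of 0.
#' @param step Lattice step in pixels.
#' @return A list of class `llr_summary`: `per_trial`, `per_block`
#'   (length `n_blocks`), `total`, `mean_second_half`, `is_generalizer`.
#' @export
llr <- function(responses, mapping, sigma = 20, n_blocks = 14, step = 2) {
  if (nrow(responses) == 0) {
    return(structure(list(per_trial = numeric(0),
                          per_block = rep(0, n_blocks), total = 0,
                          mean_second_half = 0, is_generalizer = FALSE),
                     class = "llr_summary"))
  }
  cl <- clamp_to_disk(responses$resp_x, responses$resp_y,
                      mapping$arena$radius)
  d_rnd <- density_random(mapping$arena, step)
  lr_rnd <- log_density(d_rnd, cl$x, cl$y)
  lr_bil <- numeric(nrow(responses))
  tkey <- paste(signif(responses$truth_x, 10), signif(responses$truth_y, 10))
  for (k in unique(tkey)) {
    idx <- which(tkey == k)
    d_bil <- density_bilateral(mapping,
                               c(responses$truth_x[idx[1]],
                                 responses$truth_y[idx[1]]), sigma, step)
    lr_bil[idx] <- log_density(d_bil, cl$x[idx], cl$y[idx])
  }
  per_trial <- lr_bil - lr_rnd
  per_block <- vapply(seq_len(n_blocks), function(b)
    sum(per_trial[responses$block == b]), numeric(1))
  msh <- if (n_blocks >= 8) mean(per_block[8:min(14, n_blocks)]) else 0
  structure(list(per_trial = per_trial, per_block = per_block,
                 total = sum(per_trial), mean_second_half = msh,
                 is_generalizer = msh > 0),
            class = "llr_summary")
}

#' Classify a participant or network as a generalizer
#'
#' A generalizer is on average better fit by the bilateral than the random
#' model across the second half of the experiment: mean per-block LLR over
#' blocks 8-14 strictly positive.
#'
#' @param summary An [llr()] summary (needs all 14 blocks).
#' @return Logical scalar.
#' @export
classify_generalizer <- function(summary) {
  if (length(summary$per_block) < 14)
    stop("generalizer classification requires 14 blocks")
  mean(summary$per_block[8:14]) > 0
}

#' Maximum-likelihood bilateral dispersion for one participant
#'
#' Optional alternative to the fixed default sigma: maximises the summed
#' bilateral log likelihood of the responses over a single sigma shared
#' across trials.
#'
#' @inheritParams llr
#' @param interval Search interval for sigma in px.
#' @return The fitted sigma (px).
#' @export
fit_sigma_ml <- function(responses, mapping, interval = c(2, 150), step = 2) {
  cl <- clamp_to_disk(responses$resp_x, responses$resp_y,
                      mapping$arena$radius)
  tkey <- paste(signif(responses$truth_x, 10), signif(responses$truth_y, 10))
  negll <- function(sig) {
    tot <- 0
    for (k in unique(tkey)) {
      idx <- which(tkey == k)
      d <- density_bilateral(mapping, c(responses$truth_x[idx[1]],
                                        responses$truth_y[idx[1]]), sig, step)
      tot <- tot - sum(log_density(d, cl$x[idx], cl$y[idx]))
    }
    tot
  }
  stats::optimize(negll, interval)$minimum
}
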