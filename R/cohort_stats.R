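#' Uncorrected 2x2 Pearson chi-square
#'
#' Compares the proportion of "successes" (e.g. generalizers) between two
#' groups with the Pearson chi-square statistic on the 2x2 contingency table,
#' with df = 1 and no continuity correction (the study's printed statistics
#' are the uncorrected ones).
#'
#' @param x1,n1 Successes and total in group 1.
#' @param x2,n2 Successes and total in group 2.
#' @return A list with `statistic`, `p_value`, and the input `table`.
#' @export
chi_square_2x2 <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2, n1 > 0, n2 > 0)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, 2, byrow = TRUE,
                dimnames = list(group = c("g1", "g2"),
                                outcome = c("yes", "no")))
  if (any(colSums(tab) == 0))
    stop("chi-square undefined: a column total is zero")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       table = tab)
}

#' One-sided bootstrap test on a difference in group means
#'
#' Resamples each group with replacement `n_resamples` times and reports the
#' proportion of resampled mean differences `mean(a*) - mean(b*)` that are
#' at or below zero, i.e. a one-sided p-value for the hypothesis
#' `mean(a) > mean(b)`.
#'
#' @param group_a,group_b Numeric vectors (e.g. per-participant test LLRs).
#' @param n_resamples Number of bootstrap resamples (default 10000).
#' @param seed RNG seed; results are reproducible given the seed.
#' @return A list with `p_value`, `observed_diff`, `n_resamples`.
#' @export
bootstrap_mean_diff <- function(group_a, group_b, n_resamples = 10000,
                                seed = 1L) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  diffs <- with_seed(seed, {
    a <- matrix(sample(group_a, length(group_a) * n_resamples,
                       replace = TRUE), nrow = n_resamples)
    b <- matrix(sample(group_b, length(group_b) * n_resamples,
                       replace = TRUE), nrow = n_resamples)
    rowMeans(a) - rowMeans(b)
  })
  list(p_value = mean(diffs <= 0),
       observed_diff = mean(group_a) - mean(group_b),
       n_resamples = n_resamples)
}

#' Second-half training accuracy per participant
#'
#' Fraction of training trials in blocks 8-14 whose response lies within
#' 60 px of the ground truth (the "correct" criterion).
#'
#' @param trials Trial-log data frame (needs `id`, `block`, `phase`,
#'   `truth_x`, `truth_y`, `resp_x`, `resp_y`).
#' @return A data frame with columns `id` and `accuracy`.
#' @export
training_accuracy <- function(trials) {
  tt <- trials[trials$phase == "train" & trials$block >= 8 &
                 trials$block <= 14, ]
  d <- sqrt((tt$resp_x - tt$truth_x)^2 + (tt$resp_y - tt$truth_y)^2)
  ok <- !is.na(d) & d < 60
  agg <- stats::aggregate(ok, by = list(id = tt$id), FUN = mean)
  names(agg)[2] <- "accuracy"
  agg
}

#' MAD-based exclusion of low training performers
#'
#' Within each condition, computes the median training accuracy and the
#' median absolute deviation (scale constant 1.4826) and excludes
#' participants whose accuracy falls more than 3 MADs below the median.
#' Exclusion is one-sided: nobody at or above the condition median is ever
#' excluded. If the MAD is exactly zero the rule degenerates; in that case a
#' participant is excluded only if strictly below the median AND below an
#' absolute accuracy floor of 0.5, and the condition is flagged.
#'
#' @param accuracies Data frame with columns `id`, `condition`, `accuracy`
#'   (accuracy in [0, 1], e.g. from [training_accuracy()]).
#' @param n_mad Rejection threshold in MADs (default 3).
#' @return A list of class `exclusion_report`: `per_condition` (median, MAD,
#'   threshold, degenerate flag), `excluded` (ids), `kept` (ids).
#' @export
mad_exclusion <- function(accuracies, n_mad = 3) {
  stopifnot(all(accuracies$accuracy >= 0), all(accuracies$accuracy <= 1))
  conds <- unique(accuracies$condition)
  per <- data.frame(condition = conds, median = NA_real_, mad = NA_real_,
                    threshold = NA_real_, degenerate = FALSE,
                    n = NA_integer_, n_excluded = NA_integer_)
  excluded <- character(0)
  for (i in seq_along(conds)) {
    sub <- accuracies[accuracies$condition == conds[i], ]
    m <- stats::median(sub$accuracy)
    s <- stats::mad(sub$accuracy)    # constant = 1.4826
    per$median[i] <- m; per$mad[i] <- s; per$n[i] <- nrow(sub)
    if (s == 0) {
      per$degenerate[i] <- TRUE
      per$threshold[i] <- m
      drop <- sub$accuracy < m & sub$accuracy < 0.5
      if (any(drop))
        warning(sprintf(
          "condition '%s': MAD is zero; %d participant(s) excluded by the
 degenerate below-median, below-0.5 rule", conds[i], sum(drop)))
    } else {
      per$threshold[i] <- m - n_mad * s
      drop <- sub$accuracy < per$threshold[i]
    }
    per$n_excluded[i] <- sum(drop)
    excluded <- c(excluded, as.character(sub$id[drop]))
  }
  structure(list(per_condition = per, excluded = excluded,
                 kept = setdiff(as.character(accuracies$id), excluded)),
            class = "exclusion_report")
}
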