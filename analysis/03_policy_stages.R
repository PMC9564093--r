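#!/usr/bin/env Rscript
# Stagewise policy analysis on a synthetic cohort with known ground truth:
# fits the seven admissible policy-sequence models per participant, runs
# random-effects Bayesian model selection on the three-model comparison set
# (random, random-bilateral, random-unilateral-bilateral), compares
# unilateral attribution against a performance-matched random-bilateral
# cohort, and computes the cross-validated per-dimension inflection-point
# differences.

library(hebbgate)

master <- 7
sigma <- 15
n_per_group <- 25
dir.create("results", showWarnings = FALSE)

# half the cohort passes through a genuine unilateral stage, half does not
co_uni <- simulate_cohort(n_per_group, seed = master,
                          model = "random-unilateral-bilateral",
                          sigma = sigma)
co_rb <- simulate_cohort(n_per_group, seed = master + 1,
                         model = "random-bilateral", sigma = sigma)

fit_cohort <- function(co, label) {
  out <- lapply(co$manifest$id, function(id) {
    tt <- co$trials[co$trials$id == id & co$trials$phase == "test", ]
    fits <- fit_all_policies(tt, co$mapping, sigma = sigma)
    ev <- vapply(fits, `[[`, numeric(1), "evidence")
    data.frame(cohort = label, id = id, best = best_policy_model(fits),
               unilateral = unilateral_attribution(fits),
               t(ev), check.names = FALSE)
  })
  do.call(rbind, out)
}
fits_uni <- fit_cohort(co_uni, "unilateral_truth")
fits_rb <- fit_cohort(co_rb, "random_bilateral_truth")
fits <- rbind(fits_uni, fits_rb)
write.csv(fits, "results/policy_fits.csv", row.names = FALSE)

# RFX-BMS on the three-model set, over the combined cohort
three <- c("random", "random-bilateral", "random-unilateral-bilateral")
bms <- rfx_bms(as.matrix(fits[, three]))
cat("Expected model frequencies (rnd, rnd-bi, rnd-uni-bi):\n")
print(round(bms$expected_frequencies, 3))

# attribution specificity against the performance-matched cohort
mc <- build_matched_cohort(co_uni$trials, co_uni$mapping, sigma = sigma,
                           seed = master + 2)
attr_matched <- vapply(unique(mc$trials$id), function(id) {
  tt <- mc$trials[mc$trials$id == id, ]
  unilateral_attribution(fit_all_policies(tt, co_uni$mapping, sigma = sigma))
}, logical(1))
chi <- chi_square_2x2(sum(fits_uni$unilateral), nrow(fits_uni),
                      sum(attr_matched), length(attr_matched))
cat(sprintf(
  "\nUnilateral attribution: %d/%d with a true unilateral stage vs %d/%d in
 the matched random-bilateral cohort (chi2 = %.1f, p = %.3g)\n",
  sum(fits_uni$unilateral), nrow(fits_uni), sum(attr_matched),
  length(attr_matched), chi$statistic, chi$p_value))

# cross-validated inflection differences: positive for staged learners,
# centred on zero for the matched controls
cv_diff <- function(trials, ids, mapping) {
  vapply(ids, function(id) {
    tt <- trials[trials$id == id & trials$phase == "test", ]
    crossval_inflection(tt, mapping)$cv_difference
  }, numeric(1))
}
cv_uni <- cv_diff(co_uni$trials, co_uni$manifest$id, co_uni$mapping)
cv_mc <- cv_diff(mc$trials, unique(mc$trials$id), co_uni$mapping)
cat(sprintf("\nCV inflection difference (trials): staged median %.1f, matched
 control median %.1f\n", median(cv_uni), median(cv_mc)))

report <- list(
  bms_expected_frequencies = as.list(setNames(bms$expected_frequencies, three)),
  attribution = list(unilateral_cohort = mean(fits_uni$unilateral),
                     matched_cohort = mean(attr_matched),
                     chi2 = chi$statistic, p = chi$p_value),
  cv_inflection_median = list(staged = median(cv_uni),
                              matched = median(cv_mc)))
jsonlite::write_json(report, "results/policy_stage_report.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
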