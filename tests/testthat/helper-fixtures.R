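# Shared fixtures: everything is generated in code at test time.

fixture_mapping <- function(kind = "grid", seed = 1, randomize = TRUE) {
  make_mapping(kind, seed = seed, randomize = randomize)
}

# Run one agent under one condition and return summary measures.
run_condition <- function(agent, experiment, mapping_kind, condition, seed,
                          hyper = agent_hyperparams()) {
  ss <- hebbgate:::derive_seeds(seed, 3)
  m <- make_mapping(mapping_kind, seed = ss[1])
  cur <- make_curriculum(experiment, m, condition, ss[2])
  sch <- make_schedule(cur, m, ss[3])
  run <- run_agent(agent, sch, m, hyper, seed = seed)
  te <- run$trials[run$trials$phase == "test", ]
  tr <- run$trials[run$trials$phase == "train", ]
  s_te <- llr(te, m)
  s_tr <- llr(tr, m)
  list(test_total = s_te$total,
       test_late = mean(s_te$per_block[8:14]),
       train_late = mean(s_tr$per_block[8:14]),
       generalizer = classify_generalizer(s_te),
       gates_ok = if (agent == "hebbian") gates_match_truth(run$state, m)
                  else NA,
       run = run, mapping = m)
}

# Test-trial data frame at fixed truths, for density/LLR checks.
fixture_responses <- function(resp_x, resp_y, truth_x = 0, truth_y = 0,
                              block = 1) {
  n <- length(resp_x)
  data.frame(block = rep_len(block, n),
             truth_x = rep_len(truth_x, n), truth_y = rep_len(truth_y, n),
             resp_x = resp_x, resp_y = resp_y)
}
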