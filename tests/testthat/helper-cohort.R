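# 48-animal study composition (8/16/8 animals at 22/24/26-h T-cycles plus
# 16 in DD, 7 recorded days each), built once per test run and reused by
# the slower suites.
study_cohorts <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      conds <- c("LD22", "LD24", "LD26", "DD")
      cache <<- lapply(seq_along(conds), function(i)
        simulate_cohort(conds[i], record_days = 7, seed = 1000 + i))
      names(cache) <<- conds
    }
    cache
  }
})
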