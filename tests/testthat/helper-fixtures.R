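# Shared fixtures for the suite. TOY1's scan artifacts are computed once
# and reused; everything is generated in code, nothing is read from disk.

toy1_artifacts <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- build_toy1()
      init <- initialize_scan(m, "R2", "EX_P")
      sch <- build_step_schedule(init$target_max)
      tab <- run_scan(m, "R2", "EX_P", sch)
      tabf <- filter_valid_profiles(tab)
      cls <- classify_reactions(tabf)
      swf <- suppressMessages(score_scan(tabf))
      cache <<- list(model = m, init = init, schedule = sch,
                     table = tab, filtered = tabf,
                     classifications = cls, swf = swf)
    }
    cache
  }
})

# the seeded fixture matrix used wherever scan and oracle are compared
random_toy_for_seed <- function(seed) {
  build_random_toy(n_branch_reactions = seed %% 4,
                   uptake_bound = 5 + (seed %% 3) * 2.5,
                   include_maintenance = seed %% 2 == 0,
                   seed = seed)
}

sorted_classes <- function(df) {
  df <- df[order(df$reaction_id), c("reaction_id", "reaction_type")]
  rownames(df) <- NULL
  df
}
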