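# Shared fixtures, built once per test run. Everything is generated in code
# under fixed seeds; nothing is read from disk.

# small structured cohort: scanner session only, 4 subjects
fix_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- simulate_cohort(4, seed = 101)
    memo
  }
})

# one structured agent on a scanner session, known generating parameters
fix_agent <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      sched <- generate_schedule(session_specs("scanner"), seed = 11)
      pars <- list(`+1` = learner_params(0.4, 5, h_ab = 1),
                   `-1` = learner_params(0.4, 5, h_ab = -1))
      memo <<- list(behavior = simulate_agent(sched, pars, seed = 12),
                    params = pars)
    }
    memo
  }
})

# small phantom cohort on a reduced grid (fast enough for repeated use)
fix_phantom <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      spec <- phantom_spec(grid_dim = c(12, 12, 8), region_size = c(4, 4, 3),
                           n_subjects = 6)
      beh <- simulate_cohort(6, seed = 301)
      memo <<- list(spec = spec,
                    cohort = generate_cohort_fmri(spec, seed = 302,
                                                  behavior = beh))
    }
    memo
  }
})

# independent R-level oracle for the belief recursion (never calls the C++
# path); returns the pre-update estimate of the presented stimulus per trial
oracle_beliefs <- function(behavior, params) {
  g <- c(A = 0, B = 0, C = 0)
  out <- numeric(nrow(behavior))
  cur_block <- NULL
  for (t in seq_len(nrow(behavior))) {
    if (is.null(cur_block) || behavior$block[t] != cur_block) {
      g <- c(A = 0, B = 0, C = 0)
      cur_block <- behavior$block[t]
    }
    out[t] <- g[[behavior$stimulus[t]]]
    if (behavior$feedback[t]) {
      g <- update_beliefs(g, behavior$stimulus[t], behavior$outcome[t],
                          params)
    }
  }
  out
}

# brute-force paired t and p (formula implementation, no stats::t.test)
oracle_paired_t <- function(d, tail = "two") {
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  p <- switch(tail,
              two = 2 * pt(-abs(tstat), n - 1),
              greater = 1 - pt(tstat, n - 1),
              less = pt(tstat, n - 1))
  list(statistic = tstat, p = p)
}

# exhaustive sign-flip enumeration oracle for n <= 12 subjects
oracle_sign_flip_p <- function(maps) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  stopifnot(n <= 12)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  M <- (flips %*% maps) / n
  obs <- colMeans(maps)
  colMeans(sweep(M, 2, obs, ">="))
}
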