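#' Specify one block of the correlated-bandit task
#'
#' A block presents three one-armed bandits (stimuli A, B, C) whose latent
#' good-outcome probabilities switch between 0.9 and 0.1. Bandits A and B are
#' related: in `+Corr` blocks they share one latent process, in `-Corr` blocks
#' their probabilities are mirrored (they always sum to 1) and switch
#' together. Bandit C follows its own independent process.
#'
#' @param structure_sign `+1` (A and B identical) or `-1` (A and B mirrored).
#' @param stimulus_set Stimulus-set label, 1 or 2 (which visual triplet cues
#'   the bandits).
#' @param trials_per_stimulus Presentations of each stimulus; 10 in scanner
#'   blocks, 14 pre-scan, 20 in online training. Block length is three times
#'   this value.
#' @param switch_prob Per-trial probability that a latent process flips
#'   between 0.9 and 0.1; 0.15 in the scanner, 0.05 in training.
#' @param no_feedback_tail Number of trials at the end of the block on which
#'   the outcome is withheld if the trial is rejected (15 on training days
#'   3-4, otherwise 0).
#' @param background_color Categorical label cueing the structure (the cue
#'   subjects learn to map to the correlation sign).
#' @return A one-row tibble describing the block.
#' @export
#' @examples
#' block_spec(+1, 1)                     # scanner defaults: 30-trial block
#' block_spec(-1, 2, trials_per_stimulus = 20, switch_prob = 0.05)
block_spec <- function(structure_sign, stimulus_set,
                       trials_per_stimulus = 10, switch_prob = 0.15,
                       no_feedback_tail = 0, background_color = NULL) {
  stopifnot(structure_sign %in% c(-1L, 1L), stimulus_set %in% c(1L, 2L))
  if (!is.numeric(trials_per_stimulus) ||
      trials_per_stimulus != round(trials_per_stimulus) ||
      trials_per_stimulus < 1) {
    stop("`trials_per_stimulus` must be a positive integer", call. = FALSE)
  }
  if (switch_prob <= 0 || switch_prob >= 1) {
    stop("`switch_prob` must lie in (0, 1)", call. = FALSE)
  }
  if (no_feedback_tail < 0 || no_feedback_tail != round(no_feedback_tail)) {
    stop("`no_feedback_tail` must be a non-negative integer", call. = FALSE)
  }
  if (is.null(background_color)) {
    background_color <- if (structure_sign > 0) "blue" else "orange"
  }
  tibble::tibble(
    structure_sign = as.integer(structure_sign),
    stimulus_set = as.integer(stimulus_set),
    trials_per_stimulus = as.integer(trials_per_stimulus),
    switch_prob = switch_prob,
    no_feedback_tail = as.integer(no_feedback_tail),
    background_color = background_color,
    block_type = sprintf("%sCorr_set%d",
                         if (structure_sign > 0) "+" else "-", stimulus_set)
  )
}

#' Block specifications for a full session
#'
#' Builds the ordered block list of one session of the 2x2 (stimulus set x
#' relational structure) design. The scanner session has 2 runs of 4 blocks
#' (one of each block type per run, 10 trials per stimulus, switch
#' probability 0.15); the pre-scan reminder has 1 run of 4 block types at 14
#' trials per stimulus and the slower training switch rate 0.05; online
#' training sessions have 8 blocks of 60 trials, with the 15-trial
#' no-feedback tail on days 3-4. Block order within a run is counterbalanced
#' across subjects by a Latin square (cyclic shift of the 4 block types by
#' subject and run).
#'
#' @param session One of `"scanner"`, `"prescan"`, `"training"`.
#' @param subject Subject index used for counterbalancing.
#' @param training_day Training day 1-4 (only used for `session =
#'   "training"`); days 3-4 mix both structures and withhold feedback on
#'   rejected tail trials.
#' @return A tibble of block specs in presentation order with `run` and
#'   `block` columns.
#' @export
session_specs <- function(session = c("scanner", "prescan", "training"),
                          subject = 1L, training_day = 4L) {
  session <- match.arg(session)
  types <- tibble::tibble(
    structure_sign = c(1L, 1L, -1L, -1L),
    stimulus_set = c(1L, 2L, 1L, 2L)
  )
  latin <- function(shift) types[((seq_len(4) - 1 + shift) %% 4) + 1, ]
  mk <- function(run, ord, tps, sp, tail) {
    dplyr::bind_rows(purrr::pmap(ord, function(structure_sign, stimulus_set) {
      block_spec(structure_sign, stimulus_set, trials_per_stimulus = tps,
                 switch_prob = sp, no_feedback_tail = tail)
    })) |>
      dplyr::mutate(run = as.integer(run), .before = 1)
  }
  out <- switch(session,
    scanner = dplyr::bind_rows(
      mk(1, latin(subject), 10, 0.15, 0),
      mk(2, latin(subject + 1), 10, 0.15, 0)
    ),
    prescan = mk(1, latin(subject), 14, 0.05, 0),
    training = {
      tail <- if (training_day >= 3) 15 else 0
      if (training_day <= 2) {
        # one structure per day, two sessions collapsed into 8 same-sign blocks
        sgn <- if ((subject + training_day) %% 2 == 0) 1L else -1L
        ord <- tibble::tibble(structure_sign = rep(sgn, 4),
                              stimulus_set = rep(c(1L, 2L), 2))
        dplyr::bind_rows(mk(1, ord, 20, 0.05, tail), mk(2, ord, 20, 0.05, tail))
      } else {
        dplyr::bind_rows(mk(1, latin(subject), 20, 0.05, tail),
                         mk(2, latin(subject + 1), 20, 0.05, tail))
      }
    }
  )
  dplyr::mutate(out, block = dplyr::row_number(), .before = 1)
}

# one latent 0.9/0.1 process over n trials; returns the probability sequence
latent_process <- function(n, switch_prob) {
  state <- sample(c(0.9, 0.1), 1)
  if (n == 1) return(state)
  flips <- rbinom(n - 1, 1, switch_prob)
  parity <- cumsum(flips) %% 2
  other <- if (state == 0.9) 0.1 else 0.9
  c(state, ifelse(parity == 1, other, state))
}

# truncated draws by rejection sampling
rtrunc_exp <- function(n, mean, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rexp(2 * n + 10, rate = 1 / mean)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# trial timing: 1.5 s pre-choice window + RT + 0.5 s highlight +
# choice-outcome delay + 1 s outcome + ITI
trial_onsets <- function(n) {
  rt <- rlnorm(n, meanlog = 0, sdlog = 0.3)          # median 1 s
  delay <- rtrunc_exp(n, 4.5, 3.5, 5.5)
  iti <- rtrunc_exp(n, 3, 2.5, 4)
  dur <- 1.5 + rt + 0.5 + delay + 1 + iti
  onset_stim <- cumsum(c(0, head(dur, -1)))
  onset_press <- onset_stim + 1.5 + rt
  onset_outcome <- onset_press + 0.5 + delay
  list(stim = onset_stim, press = onset_press, outcome = onset_outcome,
       duration = sum(dur))
}

#' Generate a reward schedule for a sequence of blocks
#'
#' For each block, three latent good-outcome probability processes are
#' simulated: A and B share one process (`+Corr`) or mirrored processes
#' (`-Corr`, probabilities summing to 1 and switching together), and C flips
#' independently, each with the block's per-trial switch probability. Stimuli
#' are interleaved in a seeded random order with exactly
#' `trials_per_stimulus` presentations each, binary outcomes are drawn from
#' the presented stimulus's latent probability, and event onset times follow
#' the trial timing model (pre-choice window, lognormal RT, jittered
#' choice-outcome delay and inter-trial interval).
#'
#' @param specs Tibble of block specs in order (see [block_spec()],
#'   [session_specs()]); may carry `run`/`block` columns.
#' @param seed Integer seed; schedules are bit-identical given the same seed.
#' @return A tibble with one row per trial: block indices, block type,
#'   presented `stimulus`, latent `p_good_A/B/C`, outcome `y` coded -1/+1,
#'   the no-feedback-tail marker `tail`, and onset times (seconds, within
#'   block). `block_duration_s` carries the scan length of each block.
#' @export
#' @examples
#' sched <- generate_schedule(session_specs("scanner"), seed = 1)
#' dplyr::count(sched, block)   # 8 blocks of 30 trials
generate_schedule <- function(specs, seed) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1, !missing(seed))
  if (!"block" %in% names(specs)) specs$block <- seq_len(nrow(specs))
  if (!"run" %in% names(specs)) specs$run <- 1L
  with_seed(seed, {
    purrr::pmap(as.list(specs), function(...) {
      b <- list(...)
      n <- 3L * b$trials_per_stimulus
      pA <- latent_process(n, b$switch_prob)
      pB <- if (b$structure_sign > 0) pA else ifelse(pA == 0.9, 0.1, 0.9)
      pC <- latent_process(n, b$switch_prob)
      stim <- sample(rep(c("A", "B", "C"), b$trials_per_stimulus))
      p_pres <- dplyr::case_when(stim == "A" ~ pA, stim == "B" ~ pB,
                                 TRUE ~ pC)
      y <- ifelse(runif(n) < p_pres, 1L, -1L)
      tm <- trial_onsets(n)
      tibble::tibble(
        run = b$run, block = b$block, block_type = b$block_type,
        structure_sign = b$structure_sign, stimulus_set = b$stimulus_set,
        switch_prob = b$switch_prob, trial = seq_len(n), stimulus = stim,
        p_good_A = pA, p_good_B = pB, p_good_C = pC, outcome = y,
        tail = seq_len(n) > n - b$no_feedback_tail,
        onset_stim_s = tm$stim, onset_press_s = tm$press,
        onset_outcome_s = tm$outcome,
        block_duration_s = tm$duration + 12  # post-block washout
      )
    }) |> dplyr::bind_rows()
  })
}

#' Parameters of the cross-term delta-rule learner
#'
#' The learner tracks one outcome-probability estimate per stimulus on the
#' `[-1, 1]` scale. After an outcome `y` on stimulus X, the presented
#' stimulus updates by the classic delta rule with learning rate `alpha`, and
#' every other stimulus Y updates through the cross-term `H_XY`: `g_Y' = (1 -
#' alpha*|H_XY|) g_Y + alpha * H_XY * y`. `H = +1` treats two stimuli as the
#' same bandit, `H = -1` as opposite bandits, `H = 0` as unrelated. Choices
#' are sigmoidal in `beta * g`. The structure-naive learner (`NAIVE`) is the
#' nested special case with all cross-terms fixed at 0.
#'
#' @param alpha Learning rate in `[0, 1]`.
#' @param beta Inverse temperature in `[0, 8]`.
#' @param h_ab,h_ac,h_bc Cross-terms in `[-1, 1]`.
#' @param model `"STRUCT"` or `"NAIVE"`; `NAIVE` forces all cross-terms to 0.
#' @return A `learner_params` object (named list).
#' @export
#' @examples
#' learner_params(0.4, 5, h_ab = 1)    # knows A and B are the same bandit
learner_params <- function(alpha, beta, h_ab = 0, h_ac = 0, h_bc = 0,
                           model = c("STRUCT", "NAIVE")) {
  model <- match.arg(model)
  if (model == "NAIVE") h_ab <- h_ac <- h_bc <- 0
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 8,
            abs(h_ab) <= 1, abs(h_ac) <= 1, abs(h_bc) <= 1)
  structure(list(alpha = alpha, beta = beta,
                 h = c(AB = h_ab, AC = h_ac, BC = h_bc), model = model),
            class = "learner_params")
}

#' @export
print.learner_params <- function(x, ...) {
  cat(sprintf("<%s learner>  alpha=%.3f beta=%.3f H_AB=%+.3f H_AC=%+.3f H_BC=%+.3f\n",
              x$model, x$alpha, x$beta, x$h[1], x$h[2], x$h[3]))
  invisible(x)
}

stim_index <- function(stimulus) match(stimulus, c("A", "B", "C"))

# pick the params for each block's structure: either a single learner_params
# or list(`+1` = ..., `-1` = ...)
params_for_sign <- function(params, sign) {
  if (inherits(params, "learner_params")) return(params)
  key <- if (sign > 0) "+1" else "-1"
  p <- params[[key]]
  if (is.null(p)) stop("no learner_params supplied for structure ", key,
                       call. = FALSE)
  p
}

#' Simulate an agent's choices on a schedule
#'
#' Runs the cross-term learner over the schedule: beliefs reset to 0 at every
#' block start, the agent accepts with probability `1 / (1 + exp(-beta * g))`
#' for the presented stimulus's current estimate, and beliefs are updated
#' only on trials where feedback is seen. On no-feedback-tail trials the
#' outcome is withheld when the agent rejects, so `feedback` is resolved
#' here. Accepting a good outcome gains a point, accepting a bad one loses a
#' point, rejections leave the score unchanged.
#'
#' @param schedule Tibble from [generate_schedule()].
#' @param params A [learner_params()] object, or a list keyed `"+1"` / `"-1"`
#'   giving per-structure parameters (as in per-structure pooled fits).
#' @param seed Integer seed; identical seeds give identical choice sequences.
#' @return The schedule with `choice` (`"accept"`/`"reject"`), `correct`,
#'   `points`, resolved `feedback`, and the pre-choice belief `g_stim`.
#' @export
#' @examples
#' sched <- generate_schedule(session_specs("scanner"), seed = 1)
#' beh <- simulate_agent(sched, learner_params(0.4, 5, h_ab = 1), seed = 2)
#' mean(beh$correct)
simulate_agent <- function(schedule, params, seed) {
  stopifnot(is.data.frame(schedule), nrow(schedule) >= 1)
  out <- with_seed(seed, {
    u <- runif(nrow(schedule))
    schedule |>
      dplyr::mutate(.u = u) |>
      dplyr::group_by(.data$structure_sign) |>
      dplyr::group_modify(function(d, key) {
        p <- params_for_sign(params, key$structure_sign)
        sim <- cpp_simulate_agent(stim_index(d$stimulus), as.double(d$outcome),
                                  d$tail, as.integer(d$block),
                                  p$alpha, p$beta, as.double(p$h), d$.u)
        d$choice <- ifelse(sim$choice == 1, "accept", "reject")
        d$feedback <- sim$feedback
        d$g_stim <- sim$g_stim
        d
      }) |>
      dplyr::ungroup()
  })
  out |>
    dplyr::select(-".u") |>
    dplyr::mutate(
      correct = (.data$choice == "accept") == (.data$outcome == 1),
      points = dplyr::case_when(
        choice == "accept" & outcome == 1 ~ 1L,
        choice == "accept" & outcome == -1 ~ -1L,
        TRUE ~ 0L
      )
    ) |>
    dplyr::arrange(.data$run, .data$block, .data$trial)
}

# default heterogeneous "structured" agent population: learned the correct
# coupling for the block's structure, with realistic spread
default_agent_params <- function(subject_seed, structured = TRUE) {
  with_seed(subject_seed, {
    alpha <- runif(1, 0.25, 0.55)
    beta <- runif(1, 3, 6)
    hmag <- if (structured) runif(1, 0.6, 1) else 0
    list(`+1` = learner_params(alpha, beta, h_ab = hmag),
         `-1` = learner_params(alpha, beta, h_ab = -hmag))
  })
}

#' Simulate a multi-subject behavioral cohort
#'
#' Generates schedules and choices for `n_subjects` simulated subjects, each
#' with its own counterbalanced block order (Latin square over the 4 block
#' types) and a per-subject child seed derived from the master seed. The
#' default agents have learned the correct relational structure
#' (cross-terms of the related pair near the true sign, other cross-terms 0)
#' with moderate heterogeneity in learning rate and inverse temperature;
#' `structured = FALSE` yields structure-naive agents for null cohorts.
#'
#' @param n_subjects Number of subjects.
#' @param session Session layout passed to [session_specs()].
#' @param seed Master seed.
#' @param structured Whether agents exploit the relational structure.
#' @param params Optional function `(subject) -> params` overriding the
#'   default agent population.
#' @param sessions Character vector of sessions to concatenate (e.g.
#'   `c("prescan", "scanner")` for the pooled 42+30-trial-block fits).
#' @return A tibble of trials for all subjects, with a `subject` column and
#'   a `session` column.
#' @export
simulate_cohort <- function(n_subjects, seed, sessions = "scanner",
                            structured = TRUE, params = NULL) {
  purrr::map(seq_len(n_subjects), function(s) {
    pars <- if (is.null(params)) {
      default_agent_params(derive_seed(seed, s, 1000), structured)
    } else {
      params(s)
    }
    purrr::imap(sessions, function(sess, si) {
      sched <- generate_schedule(session_specs(sess, subject = s),
                                 seed = derive_seed(seed, s, si))
      simulate_agent(sched, pars, seed = derive_seed(seed, s, si, 7)) |>
        dplyr::mutate(session = sess, .before = 1)
    }) |>
      dplyr::bind_rows() |>
      dplyr::mutate(subject = s, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Write / read behavioral trial tables
#'
#' Trial tables are exchanged as plain tab-separated text, one row per trial.
#'
#' @param behavior Trial tibble (from [simulate_agent()] /
#'   [simulate_cohort()]).
#' @param path File path.
#' @return `write_behavior_tsv()` returns `path` invisibly;
#'   `read_behavior_tsv()` returns the trial tibble.
#' @export
write_behavior_tsv <- function(behavior, path) {
  utils::write.table(behavior, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_tsv
#' @export
read_behavior_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}
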