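#' Sigmoidal accept probability
#'
#' The selector maps the current outcome-probability estimate of the
#' presented stimulus to an accept probability through a logistic function
#' with inverse temperature `beta`; `beta = 0` chooses at random, large
#' `beta` accepts deterministically when the estimate is positive.
#'
#' @param g Outcome-probability estimate(s) in `[-1, 1]`.
#' @param beta Inverse temperature, `>= 0`.
#' @return Accept probability in `(0, 1)`.
#' @export
#' @examples
#' p_accept(0, 5)      # 0.5
#' p_accept(1, 8)      # near 1
p_accept <- function(g, beta) {
  stopifnot(all(abs(g) <= 1 + 1e-12), beta >= 0)
  1 / (1 + exp(-beta * g))
}

#' One cross-term delta-rule belief update
#'
#' Applies the update following outcome `y` on the presented stimulus: the
#' presented estimate moves toward `y` by `alpha`; each other stimulus Y
#' moves toward `H_XY * y` at rate `alpha * |H_XY|`. Estimates therefore stay
#' in `[-1, 1]` for any sequence (each update is a convex combination of the
#' previous estimate and a value in `[-1, 1]`).
#'
#' @param g Named numeric vector `c(A =, B =, C =)` of current estimates.
#' @param presented Presented stimulus, `"A"`, `"B"` or `"C"`.
#' @param y Outcome, `-1` or `+1`.
#' @param params [learner_params()].
#' @return Updated named estimate vector; the input is not modified.
#' @export
#' @examples
#' update_beliefs(c(A = 0, B = 0.4, C = 0.2), "A", +1,
#'                learner_params(0.25, 4, h_ab = -1))
update_beliefs <- function(g, presented, y, params) {
  stopifnot(y %in% c(-1, 1), presented %in% c("A", "B", "C"))
  s <- stim_index(presented)
  h <- params$h
  pair_h <- function(a, b) {
    key <- paste0(sort(c("A", "B", "C")[c(a, b)]), collapse = "")
    h[[key]]
  }
  out <- g
  for (k in 1:3) {
    if (k == s) {
      out[k] <- (1 - params$alpha) * g[k] + params$alpha * y
    } else {
      hx <- pair_h(s, k)
      out[k] <- (1 - params$alpha * abs(hx)) * g[k] + params$alpha * hx * y
    }
  }
  out
}

# columns every likelihood-facing function needs, in canonical order
prep_trials <- function(behavior) {
  stopifnot(all(c("stimulus", "outcome", "feedback", "choice") %in%
                  names(behavior)))
  b <- dplyr::arrange(behavior,
                      dplyr::across(dplyr::any_of(c("subject", "session",
                                                    "run", "block", "trial"))))
  key <- paste(b[["subject"]] %||% 1, b[["session"]] %||% 1,
               b[["run"]] %||% 1, b$block)
  list(stim = stim_index(b$stimulus), y = as.double(b$outcome),
       feedback = as.logical(b$feedback),
       block = as.integer(factor(key, levels = unique(key))),
       choice = as.integer(b$choice == "accept"), data = b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Negative log likelihood of observed choices
#'
#' Runs the learner forward over the trials (beliefs reset to 0 at every
#' block start; updates skipped on trials without feedback, though the choice
#' on such trials still contributes to the likelihood) and accumulates
#' `-sum(log P(choice))` under the sigmoidal selector. Probabilities are
#' floored at 1e-12 inside the log so a boundary `beta` cannot produce
#' infinities.
#'
#' @param behavior Trial tibble with `stimulus`, `outcome`, `feedback`,
#'   `choice` and block identifiers.
#' @param params [learner_params()].
#' @return The scalar negative log likelihood.
#' @export
#' @examples
#' sched <- generate_schedule(session_specs("scanner"), seed = 1)
#' beh <- simulate_agent(sched, learner_params(0.4, 5, h_ab = 1), seed = 2)
#' negative_log_likelihood(beh, learner_params(0.4, 5, h_ab = 1))
negative_log_likelihood <- function(behavior, params) {
  tr <- prep_trials(behavior)
  cpp_nll(tr$stim, tr$y, tr$feedback, tr$block, tr$choice,
          params$alpha, params$beta, as.double(params$h))
}

param_bounds <- function(model) {
  if (model == "STRUCT") {
    list(lower = c(0, 0, -1, -1, -1), upper = c(1, 8, 1, 1, 1),
         names = c("alpha", "beta", "h_ab", "h_ac", "h_bc"))
  } else {
    list(lower = c(0, 0), upper = c(1, 8), names = c("alpha", "beta"))
  }
}

vec_to_params <- function(theta, model) {
  if (model == "STRUCT") {
    learner_params(theta[1], theta[2], theta[3], theta[4], theta[5],
                   model = "STRUCT")
  } else {
    learner_params(theta[1], theta[2], model = "NAIVE")
  }
}

# single bound-constrained ML fit on one dataset
fit_single <- function(behavior, model, n_starts = 10, seed = 1,
                       reltol = 1e-6) {
  tr <- prep_trials(behavior)
  if (nrow(behavior) == 0) stop("no trials to fit", call. = FALSE)
  if (!any(tr$feedback)) stop("all trials lack feedback; parameters are not identifiable",
                              call. = FALSE)
  bd <- param_bounds(model)
  k <- length(bd$lower)
  obj <- function(theta) {
    h <- if (model == "STRUCT") theta[3:5] else c(0, 0, 0)
    cpp_nll(tr$stim, tr$y, tr$feedback, tr$block, tr$choice,
            theta[1], theta[2], h)
  }
  starts <- with_seed(seed, lhs::randomLHS(n_starts, k))
  starts <- sweep(sweep(starts, 2, bd$upper - bd$lower, "*"), 2, bd$lower, "+")
  fits <- purrr::map(seq_len(n_starts), function(i) {
    optim(starts[i, ], obj, method = "L-BFGS-B",
          lower = bd$lower, upper = bd$upper,
          control = list(factr = reltol / .Machine$double.eps / 1e3))
  })
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]
  theta <- stats::setNames(best$par, bd$names)
  tibble::tibble(
    model = model, alpha = theta[["alpha"]], beta = theta[["beta"]],
    h_ab = theta["h_ab"] %|na|% 0, h_ac = theta["h_ac"] %|na|% 0,
    h_bc = theta["h_bc"] %|na|% 0,
    nll = best$value, n_trials = nrow(behavior), n_free_params = k,
    converged = best$convergence == 0, starts_used = n_starts
  )
}

`%|na|%` <- function(a, b) if (is.na(a)) b else unname(a)

#' Fit the learner to choice data by constrained maximum likelihood
#'
#' Minimizes the negative log likelihood under box constraints (learning rate
#' in `[0, 1]`, cross-terms in `[-1, 1]`, inverse temperature in `[0, 8]`)
#' with L-BFGS-B from seeded Latin-hypercube multi-starts, keeping the best
#' optimum. `STRUCT` has 5 free parameters per dataset, `NAIVE` 2. Fits are
#' grouped per subject and either pooled over all blocks of one relational
#' structure (`pool = "structure"`, the default used downstream) or fitted
#' per block type (`pool = "blocktype"`, the cross-validation granularity).
#'
#' @param behavior Trial tibble (may hold many subjects).
#' @param model `"STRUCT"` or `"NAIVE"`.
#' @param pool `"structure"`, `"blocktype"` or `"all"`.
#' @param n_starts Number of Latin-hypercube starting points.
#' @param seed Seed for the starting points.
#' @return A tibble of fits, one row per subject x pooling unit, of class
#'   `banditrsa_fit`; see [tidy.banditrsa_fit()].
#' @export
#' @examples
#' beh <- simulate_cohort(2, seed = 1)
#' fit_learner(beh, "NAIVE", n_starts = 4)
fit_learner <- function(behavior, model = c("STRUCT", "NAIVE"),
                        pool = c("structure", "blocktype", "all"),
                        n_starts = 10, seed = 1) {
  model <- match.arg(model)
  pool <- match.arg(pool)
  if (!"subject" %in% names(behavior)) behavior$subject <- 1L
  grp <- switch(pool, structure = "structure_sign", blocktype = "block_type",
                all = character(0))
  out <- behavior |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject", grp)))) |>
    dplyr::group_modify(function(d, key) {
      fit_single(d, model, n_starts = n_starts,
                 seed = derive_seed(seed, key$subject[1],
                                    sum(utf8ToInt(paste(key, collapse = "")))))
    }) |>
    dplyr::ungroup()
  class(out) <- c("banditrsa_fit", class(out))
  out
}

fit_row_params <- function(row) {
  learner_params(row$alpha, row$beta, row$h_ab, row$h_ac, row$h_bc,
                 model = row$model)
}

#' Per-trial model-derived quantities for GLM regressors
#'
#' Replays the fitted learner over the trials and returns, per trial, the
#' pre-update estimate of the presented stimulus (`stimulus_value`), the
#' outcome prediction error `pe = y - g`, the chosen-action value (equal to
#' the stimulus value on accept trials and its negation on reject trials —
#' a confident rejection is a high-value action), and the "correctness"
#' prediction error, whose magnitude is `|pe|` with a positive sign exactly
#' when the outcome matches the choice (good outcome accepted or bad outcome
#' rejected).
#'
#' @param behavior Trial tibble for one parameter set (one subject, blocks of
#'   one structure — or any set of blocks the params should replay).
#' @param params [learner_params()] (typically from a fit row).
#' @return The input tibble with `stimulus_value`, `pe`,
#'   `chosen_action_value` and `correctness_pe` columns appended.
#' @export
trial_derivatives <- function(behavior, params) {
  tr <- prep_trials(behavior)
  pass <- cpp_belief_pass(tr$stim, tr$y, tr$feedback, tr$block,
                          params$alpha, params$beta, as.double(params$h))
  d <- tr$data
  d$stimulus_value <- pass$g_stim
  d$pe <- tr$y - pass$g_stim
  accept <- tr$choice == 1
  d$chosen_action_value <- ifelse(accept, d$stimulus_value, -d$stimulus_value)
  congruent <- (accept & tr$y == 1) | (!accept & tr$y == -1)
  d$correctness_pe <- ifelse(congruent, abs(d$pe), -abs(d$pe))
  d
}

#' @export
#' @rdname tidy.banditrsa_fit
glance.banditrsa_fit <- function(x, ...) {
  tibble::tibble(
    n_fits = nrow(x), models = paste(unique(x$model), collapse = ","),
    total_nll = sum(x$nll), all_converged = all(x$converged)
  )
}

#' Tidy and summarize learner fits
#'
#' `tidy()` returns one row per fitted parameter; `glance()` a one-row fit
#' summary, following the broom convention.
#'
#' @param x A `banditrsa_fit` tibble from [fit_learner()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.banditrsa_fit <- function(x, ...) {
  id <- intersect(c("subject", "structure_sign", "block_type", "model"),
                  names(x))
  x |>
    tidyr::pivot_longer(dplyr::any_of(c("alpha", "beta", "h_ab", "h_ac",
                                        "h_bc")),
                        names_to = "term", values_to = "estimate") |>
    dplyr::select(dplyr::all_of(id), "term", "estimate", "nll")
}

#' Serialize fitted parameters to JSON
#'
#' @param fits `banditrsa_fit` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  jsonlite::write_json(as.data.frame(fits), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# generic hooks so broom-style verbs work without depending on broom
#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")
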