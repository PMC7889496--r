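# a small structured cohort with pooled pre-scan + scanner data (the
# granularity the cross-validation uses), cached across tests
cv_fixture <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      beh <- simulate_cohort(5, seed = 501, sessions = c("prescan",
                                                         "scanner"))
      memo <<- list(behavior = beh,
                    cv = crossval_matrix(beh, n_starts = 4, seed = 502))
    }
    memo
  }
})

test_that("cross-validation diagonal equals the training fit, and entries
          match direct likelihood recomputation", {
  fx <- cv_fixture()
  cv <- fx$cv
  expect_equal(nrow(cv), 5 * 2 * 16)
  expect_true(all(cv$nll >= 0))
  # oracle identity: recompute a sample of cells straight from the NLL
  some <- dplyr::slice_sample(cv, n = 20)
  redo <- purrr::pmap_dbl(
    list(some$subject, some$test, some$alpha, some$beta, some$h_ab,
         some$h_ac, some$h_bc, some$model),
    function(su, te, a, b, hab, hac, hbc, mo) {
      d <- dplyr::filter(fx$behavior, subject == su, block_type == te)
      negative_log_likelihood(d, learner_params(a, b, hab, hac, hbc,
                                                model = mo))
    })
  expect_equal(some$nll, redo, tolerance = 1e-12)
  # masks partition off-diagonal + diagonal correctly
  expect_true(all(cv$same_data + cv$within_structure + cv$across_structure
                  == 1))
  expect_equal(sum(cv$within_structure[cv$model == "STRUCT" &
                                         cv$subject == 1]), 4)
})

test_that("structured cohorts show the within < across structure pattern", {
  fx <- cv_fixture()
  res <- within_across_test(fx$cv, "within_structure", "across_structure",
                            "STRUCT", tail = "less")
  expect_lt(res$mean_diff, 0)
  expect_lt(res$p, 0.05)
  expect_equal(res$dof, 4)
})

test_that("the paired test matches the brute-force formula and handles
          degenerate input", {
  set.seed(61)
  for (i in 1:5) {
    d <- rnorm(9)
    got <- within_across_test  # access internal via identical masks trick
    res <- banditrsa:::paired_t(d, "two")
    orc <- oracle_paired_t(d, "two")
    expect_equal(res$statistic, orc$statistic, tolerance = 1e-10)
    expect_equal(res$p, orc$p, tolerance = 1e-10)
  }
  # identical masks: zero contrast
  fx <- cv_fixture()
  res0 <- within_across_test(fx$cv, "within_structure", "within_structure")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # zero-variance nonzero contrast: flagged, limit p
  resd <- banditrsa:::paired_t(rep(-2, 6), "two")
  expect_true(resd$degenerate)
  expect_equal(resd$p, 0)
})

test_that("type-I error of the mask comparison is nominal under the
          exchangeable null", {
  # For structure-naive agents the NAIVE model's generalization depends only
  # on how well (alpha, beta) transfer, never on the structure labels, so
  # its within- vs across-structure cells are exchangeable: a true null.
  # (The STRUCT cells are NOT null even for naive agents - the fitted
  # cross-terms exploit the schedule's own outcome correlations; see the
  # methods vignette.)
  n_cohorts <- 60
  pvals <- purrr::map_dbl(seq_len(n_cohorts), function(i) {
    beh <- simulate_cohort(4, seed = 7000 + i, structured = FALSE)
    cv <- crossval_matrix(beh, models = "NAIVE", n_starts = 2,
                          seed = 7100 + i)
    within_across_test(cv, "within_structure", "across_structure",
                       "NAIVE")$p
  })
  rej <- mean(pvals < 0.05)
  ci <- qbinom(c(0.005, 0.995), n_cohorts, 0.05) / n_cohorts
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2] + 1e-12)
})

test_that("the NAIVE matrix is blind to the structure labels", {
  # relabeling which blocks are +Corr / -Corr permutes the NAIVE matrix's
  # rows and columns but cannot change any entry: the model never reads the
  # structure. (Fits are matched by relabeling the per-blocktype datasets.)
  sched <- generate_schedule(session_specs("scanner"), seed = 811)
  b1 <- simulate_agent(sched, learner_params(0.4, 5), seed = 812)
  relabel <- function(x) ifelse(startsWith(x, "+"),
                                sub("^\\+", "-", x), sub("^-", "+", x))
  b2 <- dplyr::mutate(b1, structure_sign = -structure_sign,
                      block_type = relabel(block_type))
  cv1 <- crossval_matrix(b1, models = "NAIVE", n_starts = 3, seed = 813)
  cv2 <- crossval_matrix(b2, models = "NAIVE", n_starts = 3, seed = 813)
  j <- dplyr::inner_join(
    cv1, dplyr::mutate(cv2, train = relabel(train), test = relabel(test)),
    by = c("subject", "model", "train", "test"), suffix = c("_1", "_2"))
  expect_equal(nrow(j), 16)
  expect_equal(j$nll_1, j$nll_2, tolerance = 1e-5)
})

test_that("divergent-trial selection respects sign disagreement and ties", {
  # +Corr blocks of an agent that learned H_AB = +1, against the matching
  # STRUCT parameterization
  beh <- dplyr::filter(fix_agent()$behavior, structure_sign == 1)
  p_struct <- learner_params(0.4, 5, h_ab = 1)
  p_naive <- learner_params(0.4, 5, model = "NAIVE")
  # identical models never diverge
  expect_equal(nrow(divergent_trials(beh, p_struct, p_struct)), 0)
  div <- divergent_trials(beh, p_struct, p_naive)
  expect_true(nrow(div) > 0)
  # block starts have g = 0 under both models (p_accept exactly 0.5): always
  # excluded by the tie rule
  firsts <- dplyr::filter(beh, trial == 1)
  expect_false(any(div$g == 0))
  # structured agents follow the structured model on divergent trials
  div1 <- dplyr::filter(div, model == "STRUCT")
  frac <- mean((div1$g > 0) == (div1$choice == "accept"))
  expect_gt(frac, 0.5)
})

test_that("the cross-term test separates structured from naive cohorts", {
  # all-identical cross-terms: zero contrast, one-tailed p at its midpoint
  flat <- tibble::tibble(subject = rep(1:6, each = 2), model = "STRUCT",
                         h_ab = 0.5, h_ac = 0.5, h_bc = 0.5)
  res <- cross_term_test(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.5)

  # correct-structure cohort: |H_AB| -> 1, others -> 0
  beh <- cv_fixture()$behavior
  fits <- fit_learner(beh, "STRUCT", pool = "structure", n_starts = 4,
                      seed = 503)
  res2 <- cross_term_test(fits)
  expect_gt(res2$statistic, 3)
  expect_lt(res2$p, 0.01)

  # antisymmetry under swapping the mask roles
  swapped <- dplyr::mutate(fits, h_ab2 = (abs(h_ac) + abs(h_bc)) / 2)
  d1 <- fits |>
    dplyr::group_by(subject) |>
    dplyr::summarise(d = mean(abs(h_ab)) - mean((abs(h_ac) + abs(h_bc)) / 2))
  expect_equal(banditrsa:::paired_t(-d1$d, "greater")$statistic,
               -res2$statistic)
})

test_that("information criteria penalize the extra cross-terms correctly", {
  mk_fit <- function(model, nll, k) {
    structure(tibble::tibble(subject = 1:3, model = model,
                             nll = nll, n_free_params = k, n_trials = 400),
              class = c("banditrsa_fit", "tbl_df", "tbl", "data.frame"))
  }
  # equal likelihood: the smaller model wins both criteria
  ic <- information_criteria(mk_fit("STRUCT", 100, 5L),
                             mk_fit("NAIVE", 100, 2L))
  expect_equal(ic$group$preferred_aic[1], "NAIVE")
  expect_equal(ic$group$preferred_bic[1], "NAIVE")

  # BIC algebra: STRUCT preferred iff dNLL > (k_s - k_n) ln(n) / 2
  dk <- 3
  n <- 400
  edge <- dk * log(n) / 2
  ic2 <- information_criteria(mk_fit("STRUCT", 100 - edge - 1, 5L),
                              mk_fit("NAIVE", 100, 2L))
  expect_equal(ic2$group$preferred_bic[1], "STRUCT")
  ic3 <- information_criteria(mk_fit("STRUCT", 100 - edge + 1, 5L),
                              mk_fit("NAIVE", 100, 2L))
  expect_equal(ic3$group$preferred_bic[1], "NAIVE")

  # mismatched data refuse to compare
  bad <- mk_fit("NAIVE", 100, 2L)
  bad$n_trials <- 200
  expect_error(information_criteria(mk_fit("STRUCT", 90, 5L), bad),
               "identical data")

  # structured agents at ~600 trials: STRUCT wins the group-summed BIC
  beh <- cv_fixture()$behavior
  fs <- fit_learner(beh, "STRUCT", pool = "structure", n_starts = 4,
                    seed = 504)
  fn <- fit_learner(beh, "NAIVE", pool = "structure", n_starts = 4,
                    seed = 504)
  ic4 <- information_criteria(fs, fn)
  g <- ic4$group
  expect_equal(g$preferred_bic[1], "STRUCT")
  expect_lt(g$bic[g$model == "STRUCT"], g$bic[g$model == "NAIVE"])
})

test_that("crossval and divergent plots build", {
  fx <- cv_fixture()
  p1 <- autoplot(fx$cv)
  expect_s3_class(p1, "ggplot")
  div <- divergent_trials(fix_agent()$behavior,
                          learner_params(0.4, 5, h_ab = 1),
                          learner_params(0.4, 5, model = "NAIVE"))
  p2 <- plot_divergent_histograms(div)
  expect_s3_class(p2, "ggplot")
})
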