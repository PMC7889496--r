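#' Cross-validated likelihood matrix over block types
#'
#' Fits each model separately to each of the four block types (2 structures
#' x 2 stimulus sets) and evaluates every fitted model on every block type's
#' choices, giving a 4x4 matrix of test negative log likelihoods per model
#' per subject (beliefs reset at each block as always). Cell masks classify
#' the entries for the within/across-structure comparison: `within_structure`
#' ("pink") — off-diagonal cells whose train and test block types share the
#' structure sign; `across_structure` ("green") — cells whose structures
#' differ; `same_data` ("gray") — train == test diagonal cells.
#'
#' @param behavior Cohort trial tibble.
#' @param models Models to include.
#' @param n_starts,seed Passed to [fit_learner()].
#' @return A tibble of class `banditrsa_crossval` with one row per subject x
#'   model x train x test block type: `nll`, and logical mask columns
#'   `within_structure`, `across_structure`, `same_data`.
#' @export
crossval_matrix <- function(behavior, models = c("STRUCT", "NAIVE"),
                            n_starts = 10, seed = 1) {
  if (!"subject" %in% names(behavior)) behavior$subject <- 1L
  types <- sort(unique(behavior$block_type))
  if (length(types) != 4) {
    stop("need all 4 block types; found: ", paste(types, collapse = ", "),
         call. = FALSE)
  }
  type_sign <- behavior |>
    dplyr::distinct(.data$block_type, .data$structure_sign)
  fits <- purrr::map(models, function(m) {
    fit_learner(behavior, m, pool = "blocktype", n_starts = n_starts,
                seed = seed) |>
      dplyr::rename(train = "block_type")
  }) |> dplyr::bind_rows()
  grid <- tidyr::expand_grid(
    subject = unique(behavior$subject),
    model = models, train = types, test = types
  )
  out <- grid |>
    dplyr::left_join(fits, by = c("subject", "model", "train")) |>
    dplyr::mutate(nll = purrr::pmap_dbl(
      list(.data$subject, .data$test, .data$alpha, .data$beta,
           .data$h_ab, .data$h_ac, .data$h_bc, .data$model),
      function(su, te, a, b, hab, hac, hbc, mo) {
        d <- dplyr::filter(behavior, .data$subject == su,
                           .data$block_type == te)
        negative_log_likelihood(d, learner_params(a, b, hab, hac, hbc,
                                                  model = mo))
      })) |>
    dplyr::left_join(dplyr::rename(type_sign, train_sign = "structure_sign"),
                     by = c(train = "block_type")) |>
    dplyr::left_join(dplyr::rename(type_sign, test_sign = "structure_sign"),
                     by = c(test = "block_type")) |>
    dplyr::mutate(
      same_data = .data$train == .data$test,
      within_structure = !.data$same_data &
        .data$train_sign == .data$test_sign,
      across_structure = .data$train_sign != .data$test_sign
    ) |>
    dplyr::select("subject", "model", "train", "test", "nll", "alpha",
                  "beta", "h_ab", "h_ac", "h_bc", "same_data",
                  "within_structure", "across_structure")
  class(out) <- c("banditrsa_crossval", class(out))
  out
}

#' Paired group test between two cross-validation cell masks
#'
#' For each subject, averages the test NLL over the cells selected by
#' `mask_a` and by `mask_b` (per-cell means, since the masks select
#' different numbers of cells) and runs a paired t-test on the per-subject
#' difference `mean(a) - mean(b)` (e.g. within-structure STRUCT cells against
#' across-structure STRUCT cells, or within-structure STRUCT against
#' same-data NAIVE). A zero-variance difference is degenerate: the result is
#' flagged and the p value reported as the limit (0 for a nonzero mean
#' difference in the tested direction, 1 otherwise).
#'
#' @param cv `banditrsa_crossval` tibble.
#' @param mask_a,mask_b One-sided formulas or strings naming mask columns
#'   (optionally with a model), e.g. `"within_structure"`; see
#'   `cv_cell_sum()`.
#' @param model_a,model_b Model whose cells each mask selects.
#' @param tail `"two"`, `"less"` or `"greater"` (direction of `a - b`).
#' @return A one-row tibble: `statistic`, `dof`, `p`, `tail`, `mean_diff`,
#'   `degenerate`, plus the per-subject contrast in a list column.
#' @export
within_across_test <- function(cv, mask_a = "within_structure",
                               mask_b = "across_structure",
                               model_a = "STRUCT", model_b = model_a,
                               tail = c("two", "less", "greater")) {
  tail <- match.arg(tail)
  a <- cv_cell_sum(cv, mask_a, model_a)
  b <- cv_cell_sum(cv, mask_b, model_b)
  ab <- dplyr::inner_join(a, b, by = "subject", suffix = c("_a", "_b"))
  paired_t(ab$sum_a - ab$sum_b, tail)
}

# per-subject per-cell mean NLL over one mask's cells for one model (the
# masks have different cell counts - 4 within-structure vs 8
# across-structure - so raw sums are not comparable)
cv_cell_sum <- function(cv, mask, model) {
  stopifnot(mask %in% c("within_structure", "across_structure", "same_data"))
  cv |>
    dplyr::filter(.data$model == !!model, .data[[mask]]) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(sum = mean(.data$nll), .groups = "drop")
}

# paired/one-sample t with explicit degenerate handling
paired_t <- function(d, tail = c("two", "less", "greater")) {
  tail <- match.arg(tail)
  n <- length(d)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  m <- mean(d)
  s <- sd(d)
  dof <- n - 1
  degenerate <- s < .Machine$double.eps * max(1, abs(m)) * 100
  if (degenerate) {
    stat <- if (m == 0) 0 else sign(m) * Inf
    p <- switch(tail,
      two = if (m == 0) 1 else 0,
      greater = if (m > 0) 0 else if (m == 0) 0.5 else 1,
      less = if (m < 0) 0 else if (m == 0) 0.5 else 1
    )
    if (m == 0 && tail == "two") p <- 1
  } else {
    stat <- m / (s / sqrt(n))
    p <- switch(tail,
      two = 2 * pt(-abs(stat), dof),
      greater = pt(stat, dof, lower.tail = FALSE),
      less = pt(stat, dof)
    )
  }
  tibble::tibble(statistic = stat, dof = dof, p = p, tail = tail,
                 mean_diff = m, degenerate = degenerate,
                 contrasts = list(d))
}

#' Trials where two fitted models predict different choices
#'
#' A model predicts accept when its accept probability exceeds 0.5 (i.e. its
#' current estimate is positive); trials where either model's probability is
#' exactly 0.5 are excluded. Returns the retained trials with both models'
#' estimates and the actual choice, ready for the model-estimate histograms
#' split by choice.
#'
#' @param behavior Trial tibble for one subject (or any trial set).
#' @param params1,params2 Two [learner_params()] to replay.
#' @param labels Names for the two models in the output.
#' @return A tibble with one row per divergent trial per model: `model`,
#'   `g` (the model's estimate), `choice`.
#' @export
divergent_trials <- function(behavior, params1, params2,
                             labels = c(params1$model, params2$model)) {
  d1 <- trial_derivatives(behavior, params1)
  d2 <- trial_derivatives(behavior, params2)
  g1 <- d1$stimulus_value
  g2 <- d2$stimulus_value
  keep <- sign(g1) != sign(g2) & g1 != 0 & g2 != 0
  dplyr::bind_rows(
    tibble::tibble(model = labels[1], g = g1[keep],
                   choice = d1$choice[keep]),
    tibble::tibble(model = labels[2], g = g2[keep],
                   choice = d2$choice[keep])
  )
}

#' Cross-term hypothesis test
#'
#' Tests whether the related pair's cross-term is larger in magnitude than
#' the unrelated ones: per subject, the mean over fitted structures of
#' `|H_AB|` minus the mean of `(|H_AC| + |H_BC|) / 2`, followed by a
#' one-tailed paired t-test across subjects.
#'
#' @param struct_fits `banditrsa_fit` tibble of STRUCT fits (one row per
#'   subject x structure).
#' @return One-row tibble as in [within_across_test()].
#' @export
cross_term_test <- function(struct_fits) {
  stopifnot(all(struct_fits$model == "STRUCT"))
  d <- struct_fits |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      related = mean(abs(.data$h_ab)),
      unrelated = mean((abs(.data$h_ac) + abs(.data$h_bc)) / 2),
      .groups = "drop"
    )
  paired_t(d$related - d$unrelated, tail = "greater")
}

#' Information-criterion model comparison
#'
#' Computes `AIC = 2k + 2 NLL` and `BIC = k log(n) + 2 NLL` per subject for
#' two sets of fits on the same data (summing NLL, trial counts and free
#' parameters over a subject's fits, e.g. the two per-structure fits), plus
#' group sums. Lower is better for both criteria.
#'
#' @param fit_struct,fit_naive `banditrsa_fit` tibbles on identical data.
#' @return A list with `per_subject` (tibble) and `group` (tibble with
#'   summed criteria and the preferred model per criterion).
#' @export
information_criteria <- function(fit_struct, fit_naive) {
  per_model <- function(f) {
    f |>
      dplyr::group_by(.data$subject) |>
      dplyr::summarise(model = .data$model[1], nll = sum(.data$nll),
                       k = sum(.data$n_free_params),
                       n = sum(.data$n_trials), .groups = "drop")
  }
  both <- dplyr::bind_rows(per_model(fit_struct), per_model(fit_naive))
  # same subjects, same trial counts within subject
  chk <- both |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(ok = dplyr::n() == 2 && length(unique(.data$n)) == 1,
                     .groups = "drop")
  if (!all(chk$ok)) stop("fits are not on identical data", call. = FALSE)
  per_subject <- both |>
    dplyr::mutate(aic = 2 * .data$k + 2 * .data$nll,
                  bic = .data$k * log(.data$n) + 2 * .data$nll)
  group <- per_subject |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(nll = sum(.data$nll), aic = sum(.data$aic),
                     bic = sum(.data$bic), .groups = "drop")
  list(
    per_subject = per_subject,
    group = group |>
      dplyr::mutate(
        preferred_aic = .data$model[which.min(.data$aic)],
        preferred_bic = .data$model[which.min(.data$bic)]
      )
  )
}

#' Heatmap of a cross-validation matrix
#'
#' @param object `banditrsa_crossval` tibble.
#' @param ... Unused.
#' @return A ggplot: mean test NLL per train/test cell, one facet per model.
#' @export
autoplot.banditrsa_crossval <- function(object, ...) {
  cellmean <- object |>
    dplyr::group_by(.data$model, .data$train, .data$test) |>
    dplyr::summarise(nll = mean(.data$nll), .groups = "drop")
  ggplot2::ggplot(cellmean, ggplot2::aes(.data$test, .data$train,
                                         fill = .data$nll)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~model) +
    ggplot2::scale_fill_viridis_c(name = "test NLL") +
    ggplot2::labs(x = "test block type", y = "training block type")
}

#' Histograms of model estimates on divergent trials
#'
#' @param divergent Output of [divergent_trials()].
#' @return A ggplot of estimate histograms split by actual choice, one facet
#'   per model.
#' @export
plot_divergent_histograms <- function(divergent) {
  ggplot2::ggplot(divergent, ggplot2::aes(.data$g, fill = .data$choice)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.6, bins = 20) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "outcome probability estimate g", y = "trials")
}
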