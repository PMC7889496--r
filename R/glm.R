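#' Double-gamma hemodynamic response kernel
#'
#' The canonical HRF: a gamma response peaking at `peak_delay` seconds minus
#' a gamma undershoot, with the undershoot delay scaled proportionally when
#' the peak delay is changed (so the 8.5 s variant keeps the same shape,
#' stretched). Normalized to unit peak.
#'
#' @param peak_delay Response peak delay in seconds (6 by default; 8.5 for
#'   regions with a slower hemodynamic response).
#' @param sampling Sampling interval of the returned series in seconds.
#' @param duration Kernel length in seconds.
#' @param undershoot_ratio Amplitude ratio of undershoot to response (1/6).
#' @return Numeric vector of kernel values sampled at `sampling` intervals
#'   starting at t = 0.
#' @export
#' @examples
#' k <- hrf_kernel(6, sampling = 0.1)
#' (which.max(k) - 1) * 0.1    # peaks near 6 s
hrf_kernel <- function(peak_delay = 6, sampling = 0.1, duration = 32,
                       undershoot_ratio = 1 / 6) {
  if (peak_delay <= 0) stop("`peak_delay` must be positive", call. = FALSE)
  t <- seq(0, duration, by = sampling)
  under_delay <- 16 * peak_delay / 6     # scale undershoot with the peak
  disp <- 1
  # gamma with unit scale has its mode at (shape - 1): put the mode at the
  # requested delay
  h <- stats::dgamma(t, shape = peak_delay / disp + 1, scale = disp) -
    undershoot_ratio * stats::dgamma(t, shape = under_delay / disp + 1,
                                     scale = disp)
  h / max(h)
}

#' Build an event-based design matrix
#'
#' Events are modeled as delta functions ("sticks") on a fine time grid,
#' scaled by their (block-mean-centered) parametric modulator where one is
#' given, convolved with the double-gamma HRF and resampled at the TR.
#' Per-block intercept columns are appended, and optional nuisance series
#' (e.g. motion parameters) are passed through unconvolved.
#'
#' @param events Tibble with columns `onset` (s), `regressor` (name),
#'   optional `modulator` (parametric value; `NA`/absent means a unit main
#'   effect), optional `block` (for per-block centering and intercepts) and
#'   `role` (`"main"`, `"parametric"`, `"nuisance"`).
#' @param duration Run duration in seconds (scalar, or per-block named
#'   vector when `blockwise`).
#' @param tr Repetition time in seconds.
#' @param hrf_delay HRF peak delay in seconds.
#' @param nuisance Optional numeric matrix (time x series) appended as-is.
#' @param drift_cutoff_s If non-`NULL`, adds a discrete-cosine drift basis
#'   implementing a high-pass at this cutoff (seconds); `NULL` disables.
#' @param oversample Fine-grid resolution in seconds.
#' @return A `banditrsa_design` list: `X` (time x columns matrix), `frame_times`,
#'   `columns` (tibble of column metadata), `tr`.
#' @export
build_design <- function(events, duration, tr = 1.235, hrf_delay = 6,
                         nuisance = NULL, drift_cutoff_s = NULL,
                         oversample = 0.1) {
  stopifnot(is.data.frame(events), all(c("onset", "regressor") %in%
                                         names(events)))
  if (!"block" %in% names(events)) events$block <- 1L
  if (!"modulator" %in% names(events)) events$modulator <- NA_real_
  if (any(events$onset < 0 | events$onset > duration)) {
    stop("event onsets outside [0, duration]", call. = FALSE)
  }
  # mean-center parametric modulators within block
  events <- events |>
    dplyr::group_by(.data$regressor, .data$block) |>
    dplyr::mutate(weight = ifelse(is.na(.data$modulator), 1,
                                  .data$modulator -
                                    mean(.data$modulator))) |>
    dplyr::ungroup()

  n_scans <- floor(duration / tr)
  frame_times <- (seq_len(n_scans) - 1) * tr
  fine_t <- seq(0, duration + tr, by = oversample)
  kern <- hrf_kernel(hrf_delay, sampling = oversample)
  regs <- unique(events$regressor)

  cols <- purrr::map(regs, function(r) {
    ev <- dplyr::filter(events, .data$regressor == r)
    stick <- numeric(length(fine_t))
    idx <- pmin(length(fine_t), floor(ev$onset / oversample) + 1)
    for (i in seq_along(idx)) stick[idx[i]] <- stick[idx[i]] + ev$weight[i]
    conv <- stats::convolve(stick, rev(kern), type = "open")[
      seq_along(fine_t)]
    stats::approx(fine_t, conv, xout = frame_times, rule = 2)$y
  })
  X <- do.call(cbind, cols)
  colnames(X) <- regs
  meta <- tibble::tibble(column = regs, role = "task")

  if (!is.null(drift_cutoff_s)) {
    n_basis <- max(0, floor(2 * duration / drift_cutoff_s))
    if (n_basis > 0) {
      dct <- sapply(seq_len(n_basis), function(k) {
        cos(pi * k * (frame_times + tr / 2) / duration)
      })
      colnames(dct) <- paste0("drift_", seq_len(n_basis))
      X <- cbind(X, dct)
      meta <- dplyr::bind_rows(meta, tibble::tibble(column = colnames(dct),
                                                    role = "drift"))
    }
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == n_scans)
    if (is.null(colnames(nuisance))) {
      colnames(nuisance) <- paste0("nuisance_", seq_len(ncol(nuisance)))
    }
    X <- cbind(X, nuisance)
    meta <- dplyr::bind_rows(meta, tibble::tibble(column = colnames(nuisance),
                                                  role = "nuisance"))
  }
  X <- cbind(X, intercept = 1)
  meta <- dplyr::bind_rows(meta, tibble::tibble(column = "intercept",
                                                role = "intercept"))
  structure(list(X = X, frame_times = frame_times, columns = meta, tr = tr),
            class = "banditrsa_design")
}

#' Voxelwise ordinary least squares
#'
#' @param bold Voxel x time matrix (or time x voxel with `time_first`).
#' @param design `banditrsa_design` from [build_design()], or a plain matrix.
#' @param time_first Set `TRUE` if `bold` is time x voxel.
#' @return A `banditrsa_glmfit` list: `beta` (coefficient x voxel),
#'   `residuals` (time x voxel), `sigma2` (residual variance per voxel),
#'   `design`.
#' @export
fit_glm <- function(bold, design, time_first = FALSE) {
  X <- if (inherits(design, "banditrsa_design")) design$X else as.matrix(design)
  Y <- if (time_first) as.matrix(bold) else t(as.matrix(bold))
  if (nrow(Y) != nrow(X)) stop("time dimensions differ", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  dof <- nrow(X) - ncol(X)
  structure(list(beta = beta, residuals = res,
                 sigma2 = colSums(res^2) / max(dof, 1), design = design),
            class = "banditrsa_glmfit")
}

#' Linear contrast of GLM coefficients
#'
#' @param fit `banditrsa_glmfit`.
#' @param weights Numeric weight vector over coefficients (length = number
#'   of design columns) or a named vector over a subset of columns (others
#'   0).
#' @return Numeric vector: the weighted coefficient sum per voxel.
#' @export
contrast_map <- function(fit, weights) {
  p <- nrow(fit$beta)
  if (!is.null(names(weights))) {
    w <- stats::setNames(numeric(p), rownames(fit$beta))
    missing_w <- setdiff(names(weights), names(w))
    if (length(missing_w)) stop("unknown columns: ",
                                paste(missing_w, collapse = ", "),
                                call. = FALSE)
    w[names(weights)] <- weights
  } else {
    if (length(weights) != p) stop("weight length != coefficient length",
                                   call. = FALSE)
    w <- weights
  }
  drop(crossprod(fit$beta, w))
}

# event helper: one regressor's stick set
ev <- function(onset, regressor, block, modulator = NA_real_,
               role = "main") {
  if (length(onset) == 0) return(NULL)
  tibble::tibble(onset = onset, regressor = regressor, block = block,
                 modulator = modulator, role = role)
}

#' Event sets for the four task GLM layouts
#'
#' Builds the per-block regressor lists of the analysis GLMs from one
#' subject's trial table (all regressors stick functions at stimulus or
#' outcome onsets; parametric sticks carry the learner-derived modulators):
#'
#' * `glm1` — related-pair (`AB`) stimulus and outcome main effects; two
#'   parametric regressors at `AB` stimulus time carrying the STRUCT and
#'   NAIVE chosen-action values, pitted against each other without
#'   orthogonalization; `C` stimulus/outcome mains; accept and reject
#'   button-press regressors.
#' * `glm2` — per-stimulus (`A`,`B`,`C`) mains at stimulus and outcome
#'   times; buttons. The per-stimulus patterns feed the 8- and 12-condition
#'   RDMs.
#' * `glm2a` — the related pair collapsed onto one regressor: `AB` and `C`
#'   mains at stimulus and outcome times; buttons (4-condition RDMs).
#' * `glm3` — `AB`/`C` outcome and stimulus mains plus one parametric
#'   regressor of the STRUCT "correctness" prediction error locked to `AB`
#'   outcome time; buttons.
#'
#' Regressor names are suffixed `_b<block>` so each block contributes its
#' own columns; motion nuisances and intercepts are added by
#' [build_design()].
#'
#' @param layout `"glm1"`, `"glm2"`, `"glm2a"` or `"glm3"`.
#' @param behavior One subject's trial tibble for a single run.
#' @param derivatives Matching [trial_derivatives()] output (needed for
#'   `glm1` and `glm3`); for `glm1` supply the STRUCT derivatives in
#'   `derivatives` and NAIVE in `derivatives_naive`.
#' @param derivatives_naive NAIVE-model derivatives for `glm1`.
#' @return An events tibble for [build_design()].
#' @export
build_task_glm <- function(layout = c("glm1", "glm2", "glm2a", "glm3"),
                           behavior, derivatives = NULL,
                           derivatives_naive = NULL) {
  layout <- match.arg(layout)
  b <- behavior
  ab <- b$stimulus %in% c("A", "B")
  blk <- b$block
  base_buttons <- dplyr::bind_rows(
    ev(b$onset_press_s[b$choice == "accept"], "button_accept",
       blk[b$choice == "accept"]),
    ev(b$onset_press_s[b$choice == "reject"], "button_reject",
       blk[b$choice == "reject"])
  )
  per_block <- function(events) {
    # suffix regressor names by block so every block gets its own columns
    dplyr::mutate(events,
                  regressor = paste0(.data$regressor, "_b", .data$block))
  }
  core <- switch(layout,
    glm1 = {
      stopifnot(!is.null(derivatives), !is.null(derivatives_naive))
      dplyr::bind_rows(
        ev(b$onset_stim_s[ab], "AB_stim", blk[ab]),
        ev(b$onset_outcome_s[ab], "AB_outcome", blk[ab]),
        ev(b$onset_stim_s[ab], "chosen_value_struct", blk[ab],
           modulator = derivatives$chosen_action_value[ab],
           role = "parametric"),
        ev(b$onset_stim_s[ab], "chosen_value_naive", blk[ab],
           modulator = derivatives_naive$chosen_action_value[ab],
           role = "parametric"),
        ev(b$onset_stim_s[!ab], "C_stim", blk[!ab]),
        ev(b$onset_outcome_s[!ab], "C_outcome", blk[!ab])
      )
    },
    glm2 = dplyr::bind_rows(purrr::map(c("A", "B", "C"), function(s) {
      i <- b$stimulus == s
      dplyr::bind_rows(
        ev(b$onset_stim_s[i], paste0(s, "_stim"), blk[i]),
        ev(b$onset_outcome_s[i], paste0(s, "_outcome"), blk[i])
      )
    })),
    glm2a = dplyr::bind_rows(
      ev(b$onset_stim_s[ab], "AB_stim", blk[ab]),
      ev(b$onset_outcome_s[ab], "AB_outcome", blk[ab]),
      ev(b$onset_stim_s[!ab], "C_stim", blk[!ab]),
      ev(b$onset_outcome_s[!ab], "C_outcome", blk[!ab])
    ),
    glm3 = {
      stopifnot(!is.null(derivatives))
      dplyr::bind_rows(
        ev(b$onset_outcome_s[ab], "AB_outcome", blk[ab]),
        ev(b$onset_outcome_s[!ab], "C_outcome", blk[!ab]),
        ev(b$onset_outcome_s[ab], "correctness_pe", blk[ab],
           modulator = derivatives$correctness_pe[ab],
           role = "parametric"),
        ev(b$onset_stim_s[ab], "AB_stim", blk[ab]),
        ev(b$onset_stim_s[!ab], "C_stim", blk[!ab])
      )
    }
  )
  per_block(dplyr::bind_rows(core, base_buttons))
}

#' Assemble the design of one run from per-block acquisitions
#'
#' Each block is acquired (and simulated) as its own scan segment with
#' onsets starting at zero, so the run design is block-diagonal: every
#' block's task columns and intercept occupy only that block's scans.
#' Optional per-block nuisance matrices (e.g. 6 motion series) are appended
#' the same way.
#'
#' @param behavior_run One subject's trials for one run.
#' @param layout,derivatives,derivatives_naive See [build_task_glm()].
#' @param tr,hrf_delay,drift_cutoff_s See [build_design()].
#' @param nuisance Optional named list `block -> matrix(scans x series)`.
#' @return A `banditrsa_design` covering the whole run; `columns$block`
#'   records each column's block.
#' @export
build_run_design <- function(behavior_run, layout = "glm2",
                             derivatives = NULL, derivatives_naive = NULL,
                             tr = 1.235, hrf_delay = 6,
                             drift_cutoff_s = NULL, nuisance = NULL) {
  blocks <- unique(behavior_run$block)
  parts <- purrr::map(blocks, function(bk) {
    i <- behavior_run$block == bk
    evs <- build_task_glm(layout, behavior_run[i, ],
                          derivatives = if (!is.null(derivatives))
                            derivatives[i, ],
                          derivatives_naive = if (!is.null(derivatives_naive))
                            derivatives_naive[i, ])
    des <- build_design(evs, duration = behavior_run$block_duration_s[i][1],
                        tr = tr, hrf_delay = hrf_delay,
                        nuisance = nuisance[[as.character(bk)]],
                        drift_cutoff_s = drift_cutoff_s)
    nm <- colnames(des$X)
    nm[nm == "intercept"] <- paste0("intercept_b", bk)
    ren <- !grepl("_b[0-9]+$", nm)
    nm[ren] <- paste0(nm[ren], "_b", bk)
    colnames(des$X) <- nm
    des$columns$column <- nm
    des$columns$block <- bk
    des
  })
  ncols <- sum(purrr::map_int(parts, ~ncol(.x$X)))
  nrows <- sum(purrr::map_int(parts, ~nrow(.x$X)))
  X <- matrix(0, nrows, ncols)
  cn <- character(ncols)
  r0 <- 0; c0 <- 0
  ft <- numeric(0)
  for (p in parts) {
    nr <- nrow(p$X); nc <- ncol(p$X)
    X[r0 + seq_len(nr), c0 + seq_len(nc)] <- p$X
    cn[c0 + seq_len(nc)] <- colnames(p$X)
    ft <- c(ft, p$frame_times + if (length(ft)) max(ft) + tr else 0)
    r0 <- r0 + nr; c0 <- c0 + nc
  }
  colnames(X) <- cn
  structure(list(X = X, frame_times = ft,
                 columns = dplyr::bind_rows(purrr::map(parts, "columns")),
                 tr = tr),
            class = "banditrsa_design")
}
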