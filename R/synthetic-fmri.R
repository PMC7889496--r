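# cuboid of voxel coordinates
cuboid <- function(origin, size) {
  as.matrix(expand.grid(origin[1] + seq_len(size[1]) - 1,
                        origin[2] + seq_len(size[2]) - 1,
                        origin[3] + seq_len(size[3]) - 1))
}

#' Specification of the synthetic BOLD phantom
#'
#' Defines a voxel grid with four disjoint planted regions: `structure`
#' (condition patterns shared by all conditions of the same relational
#' structure), `stimulus` (patterns keyed by visual stimulus identity),
#' `pe_by_structure` (prediction-error parametric patterns keyed by
#' structure), and `null` (no signal). The analysis mask is the union of the
#' regions — the volumetric-searchlight-within-anatomical-mask setting.
#'
#' @param grid_dim Grid dimensions (default 20 x 20 x 20).
#' @param region_size Region dimensions (default `c(5, 5, 6)`, 150 voxels).
#' @param effect Named effect sizes (prototype SD) per signal region.
#' @param noise_sd BOLD noise standard deviation (marginal).
#' @param ar Lag-1 autocorrelation of the BOLD noise; 0 (white) by default.
#' @param n_subjects Cohort size.
#' @param tr Repetition time in seconds (1.235, matching acquisition).
#' @param hrf_delay HRF peak delay for generation (6 s).
#' @return A `phantom_spec` list with `regions` (named list of coordinate
#'   matrices), `coords` (mask voxels x 3), `region_index` (named list of
#'   row indices into the mask), and the scalar settings.
#' @export
phantom_spec <- function(grid_dim = c(20, 20, 20), region_size = c(5, 5, 6),
                         effect = c(structure = 0.5, stimulus = 0.5,
                                    pe_by_structure = 0.5),
                         noise_sd = 1, n_subjects = 20, tr = 1.235,
                         hrf_delay = 6, ar = 0) {
  stopifnot(noise_sd > 0, all(unlist(effect) >= 0), all(region_size >= 1),
            ar >= 0, ar < 1)
  effect <- as.list(effect)
  origins <- list(structure = c(2, 2, 2),
                  stimulus = c(grid_dim[1] - region_size[1], 2, 2),
                  pe_by_structure = c(2, grid_dim[2] - region_size[2],
                                      grid_dim[3] - region_size[3]),
                  null = c(grid_dim[1] - region_size[1],
                           grid_dim[2] - region_size[2], 2))
  regions <- purrr::map(origins, cuboid, size = region_size)
  coords <- do.call(rbind, regions)
  sizes <- purrr::map_int(regions, nrow)
  ends <- cumsum(sizes)
  region_index <- purrr::map2(ends - sizes + 1, ends, seq)
  names(region_index) <- names(regions)
  structure(list(grid_dim = grid_dim, regions = regions, coords = coords,
                 region_index = region_index, effect = effect,
                 noise_sd = noise_sd, ar = ar,
                 n_subjects = n_subjects, tr = tr,
                 hrf_delay = hrf_delay),
            class = "phantom_spec")
}

# smooth per-block motion series (6 parameters), scans x 6
motion_series <- function(n_scans) {
  m <- matrix(rnorm(n_scans * 6, sd = 0.05), n_scans, 6)
  apply(m, 2, function(x) stats::filter(cumsum(x), rep(1 / 15, 15),
                                        sides = 1)) |>
    (\(x) {x[is.na(x)] <- 0; x})()
}

# union generating design of one run: per-stimulus mains + PE parametric +
# buttons, per block, with motion nuisances
phantom_run_design <- function(beh_run, deriv_run, spec, nuisance) {
  ev2 <- build_task_glm("glm2", beh_run)
  pe <- beh_run$stimulus %in% c("A", "B")
  ev_pe <- ev(beh_run$onset_outcome_s[pe], "correctness_pe",
              beh_run$block[pe], modulator = deriv_run$correctness_pe[pe],
              role = "parametric") |>
    dplyr::mutate(regressor = paste0(.data$regressor, "_b", .data$block))
  events <- dplyr::bind_rows(ev2, ev_pe)
  blocks <- unique(beh_run$block)
  parts <- purrr::map(blocks, function(bk) {
    i <- beh_run$block == bk
    build_design(dplyr::filter(events, .data$block == bk),
                 duration = beh_run$block_duration_s[i][1], tr = spec$tr,
                 hrf_delay = spec$hrf_delay,
                 nuisance = nuisance[[as.character(bk)]])
  })
  # block-diagonal assembly (as in build_run_design)
  ncols <- sum(purrr::map_int(parts, ~ncol(.x$X)))
  nrows <- sum(purrr::map_int(parts, ~nrow(.x$X)))
  X <- matrix(0, nrows, ncols)
  cn <- character(ncols)
  blk_of <- integer(0)
  r0 <- 0; c0 <- 0
  for (pi in seq_along(parts)) {
    p <- parts[[pi]]
    nm <- colnames(p$X)
    nm[nm == "intercept"] <- paste0("intercept_b", blocks[pi])
    ren <- !grepl("_b[0-9]+$", nm)
    nm[ren] <- paste0(nm[ren], "_b", blocks[pi])
    nr <- nrow(p$X); nc <- ncol(p$X)
    X[r0 + seq_len(nr), c0 + seq_len(nc)] <- p$X
    cn[c0 + seq_len(nc)] <- nm
    blk_of <- c(blk_of, rep(blocks[pi], nc))
    r0 <- r0 + nr; c0 <- c0 + nc
  }
  colnames(X) <- cn
  list(X = X, block_of = stats::setNames(blk_of, cn))
}

#' Generate one subject's phantom BOLD session
#'
#' Builds the generating design from the subject's behavior (per-stimulus
#' stick mains, the correctness-PE parametric regressor, buttons, motion),
#' plants the region geometries in the true coefficient maps, and simulates
#' `BOLD = X B + noise` per run over the mask voxels.
#'
#' Planted geometry: in the `structure` region every stimulus-presentation
#' pattern of a block equals a per-structure prototype; in the `stimulus`
#' region it equals a per-(stimulus set, stimulus) prototype; in the
#' `pe_by_structure` region the PE parametric pattern equals a
#' per-structure prototype. Prototypes are drawn once per subject per
#' region from a seeded standard normal times the region's effect size.
#'
#' @param spec [phantom_spec()].
#' @param behavior One subject's scanner-session trials.
#' @param params The agent's generating [learner_params()] (list by
#'   structure), used for the PE modulator.
#' @param seed Subject-level seed.
#' @return List with per-run `bold` (voxel x time), `design` (generating
#'   design), `motion` (per-block nuisance list), `behavior`, and the true
#'   coefficient matrices.
#' @export
generate_phantom_subject <- function(spec, behavior, params, seed) {
  with_seed(seed, {
    n_vox <- nrow(spec$coords)
    proto <- function(n) rnorm(n)
    # prototypes: structure keyed by sign; stimulus keyed by set x stimulus
    ri <- spec$region_index
    p_struct <- list(`+1` = proto(length(ri$structure)),
                     `-1` = proto(length(ri$structure)))
    p_stim <- purrr::map(stats::setNames(1:2, 1:2), function(s)
      purrr::map(stats::setNames(c("A", "B", "C"), c("A", "B", "C")),
                 ~proto(length(ri$stimulus))))
    p_pe <- list(`+1` = proto(length(ri$pe_by_structure)),
                 `-1` = proto(length(ri$pe_by_structure)))

    runs <- sort(unique(behavior$run))
    out <- purrr::map(runs, function(r) {
      beh <- dplyr::filter(behavior, .data$run == r)
      deriv <- behavior |>
        dplyr::group_by(.data$structure_sign) |>
        dplyr::group_modify(~trial_derivatives(
          .x, params_for_sign(params, .y$structure_sign))) |>
        dplyr::ungroup() |>
        dplyr::filter(.data$run == r) |>
        dplyr::arrange(.data$block, .data$trial)
      nuis <- purrr::map(stats::setNames(unique(beh$block),
                                         unique(beh$block)), function(bk) {
        n_sc <- floor(beh$block_duration_s[beh$block == bk][1] / spec$tr)
        motion_series(n_sc)
      })
      des <- phantom_run_design(beh, deriv, spec, nuis)
      B <- matrix(0, ncol(des$X), n_vox, dimnames = list(colnames(des$X)))
      blockinfo <- dplyr::distinct(beh, .data$block, .data$structure_sign,
                                   .data$stimulus_set)
      for (bi in seq_len(nrow(blockinfo))) {
        bk <- blockinfo$block[bi]
        sgn <- if (blockinfo$structure_sign[bi] > 0) "+1" else "-1"
        set <- as.character(blockinfo$stimulus_set[bi])
        eff <- spec$effect
        # the structure code is a block-context signal: present at every
        # stimulus presentation, C included (this also keeps the planted
        # geometry orthogonal to the stimulus-identity contrast)
        for (s in c("A", "B", "C")) {
          cn <- paste0(s, "_stim_b", bk)
          if (cn %in% rownames(B)) {
            B[cn, ri$structure] <- eff[["structure"]] * p_struct[[sgn]]
          }
        }
        for (s in c("A", "B", "C")) {
          cn <- paste0(s, "_stim_b", bk)
          if (cn %in% rownames(B)) {
            B[cn, ri$stimulus] <- B[cn, ri$stimulus] +
              eff[["stimulus"]] * p_stim[[set]][[s]]
          }
        }
        cn <- paste0("correctness_pe_b", bk)
        if (cn %in% rownames(B)) {
          B[cn, ri$pe_by_structure] <- eff[["pe_by_structure"]] *
            p_pe[[sgn]]
        }
      }
      noise <- matrix(rnorm(nrow(des$X) * n_vox, sd = spec$noise_sd),
                      nrow(des$X), n_vox)
      if (spec$ar > 0) {
        # stationary AR(1): innovations scaled to keep the marginal sd
        noise <- apply(noise * sqrt(1 - spec$ar^2), 2, function(x)
          as.numeric(stats::filter(x, spec$ar, method = "recursive")))
      }
      bold <- t(des$X %*% B + noise)
      list(bold = bold, design = des, motion = nuis, behavior = beh,
           deriv = deriv, tr = spec$tr, hrf_delay = spec$hrf_delay,
           truth_beta = B)
    })
    names(out) <- paste0("run", runs)
    out
  })
}

#' Generate a multi-subject phantom cohort
#'
#' Couples a behavioral cohort (scanner sessions) with per-subject phantom
#' BOLD. Each subject receives a derived child seed; the same master seed
#' reproduces the cohort bit-identically.
#'
#' @param spec [phantom_spec()].
#' @param seed Master seed.
#' @param behavior Optional pre-simulated cohort (scanner session); default
#'   simulates `spec$n_subjects` structured agents.
#' @return A list: `subjects` (list of [generate_phantom_subject()]
#'   outputs), `behavior`, `spec`, `truth` (region indices into the mask).
#' @export
generate_cohort_fmri <- function(spec, seed, behavior = NULL) {
  if (is.null(behavior)) {
    behavior <- simulate_cohort(spec$n_subjects, seed = derive_seed(seed, 1))
  }
  subjects <- purrr::map(sort(unique(behavior$subject)), function(s) {
    pars <- default_agent_params(derive_seed(seed, s, 1000))
    generate_phantom_subject(spec, dplyr::filter(behavior,
                                                 .data$subject == s),
                             pars, seed = derive_seed(seed, s, 2))
  })
  list(subjects = subjects, behavior = behavior, spec = spec,
       truth = spec$region_index)
}

# condition labels of a scanner session's block types
blocktype_labels <- function(behavior) {
  behavior |>
    dplyr::distinct(.data$block_type, .data$structure_sign,
                    .data$stimulus_set) |>
    dplyr::arrange(.data$block_type)
}

#' Extract labeled condition patterns from a phantom subject
#'
#' Refits the analysis GLM per run on the synthetic BOLD and returns the
#' per-condition coefficient patterns feeding the RDMs:
#' `"ab8"` — A and B stimulus-presentation patterns of each block type
#' (8 conditions, the relational-structure analysis); `"abc12"` — all three
#' stimuli (12 conditions, the stimulus-identity analysis); `"pe4"` — the
#' correctness-PE parametric pattern per block type (4 conditions);
#' `"ab4"` — the collapsed related-pair pattern per block type (4
#' conditions).
#'
#' @param subject Output of [generate_phantom_subject()].
#' @param conditions `"ab8"`, `"abc12"`, `"pe4"` or `"ab4"`.
#' @return List: `run1`, `run2` (condition x voxel), `labels` tibble,
#'   `residuals` (time x voxel, runs concatenated).
#' @export
extract_patterns <- function(subject,
                             conditions = c("ab8", "abc12", "pe4", "ab4")) {
  conditions <- match.arg(conditions)
  per_run <- purrr::map(subject, function(rn) {
    beh <- rn$behavior
    layout <- switch(conditions, pe4 = "glm3", ab4 = "glm2a", "glm2")
    des <- build_run_design(beh, layout = layout,
                            derivatives = if (layout == "glm3") rn$deriv,
                            tr = rn$tr, hrf_delay = rn$hrf_delay,
                            nuisance = rn$motion)
    fit <- fit_glm(rn$bold, des)
    stims <- switch(conditions, ab8 = c("A", "B"), abc12 = c("A", "B", "C"),
                    ab4 = "AB", pe4 = "pe")
    blockinfo <- dplyr::distinct(beh, .data$block, .data$block_type,
                                 .data$structure_sign, .data$stimulus_set)
    rows <- tidyr::expand_grid(stimulus = stims,
                               block = blockinfo$block) |>
      dplyr::left_join(blockinfo, by = "block") |>
      dplyr::mutate(column = dplyr::case_when(
        stimulus == "pe" ~ paste0("correctness_pe_b", .data$block),
        stimulus == "AB" ~ paste0("AB_stim_b", .data$block),
        TRUE ~ paste0(.data$stimulus, "_stim_b", .data$block)
      ),
      condition = paste0(.data$stimulus, ".", .data$block_type))
    list(patterns = fit$beta[rows$column, , drop = FALSE], labels = rows,
         residuals = fit$residuals)
  })
  l1 <- per_run[[1]]$labels |> dplyr::arrange(.data$condition)
  l2 <- per_run[[2]]$labels |> dplyr::arrange(.data$condition)
  stopifnot(identical(l1$condition, l2$condition))
  r1 <- per_run[[1]]$patterns[match(l1$column,
                                    per_run[[1]]$labels$column), ,
                              drop = FALSE]
  r2 <- per_run[[2]]$patterns[match(l2$column,
                                    per_run[[2]]$labels$column), ,
                              drop = FALSE]
  rownames(r1) <- rownames(r2) <- l1$condition
  labels <- dplyr::select(l1, "condition", "stimulus", "block_type",
                          "structure_sign", "stimulus_set")
  list(run1 = r1, run2 = r2, labels = labels,
       residuals = rbind(per_run[[1]]$residuals, per_run[[2]]$residuals))
}

#' Write a voxel map (or mask) on the phantom grid as NIfTI
#'
#' Off-mask voxels are written as zero.
#'
#' @param values Numeric vector over the mask voxels.
#' @param spec [phantom_spec()] carrying grid and mask coordinates.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path` invisibly.
#' @export
write_map_nifti <- function(values, spec, path) {
  vol <- array(0, spec$grid_dim)
  vol[spec$coords] <- values
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @param path NIfTI file to read.
#' @return `read_map_nifti()` returns the values over the mask voxels.
#' @export
read_map_nifti <- function(spec, path) {
  vol <- RNifti::readNifti(path)
  vol[spec$coords]
}
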