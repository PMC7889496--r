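#' Pipeline configuration
#'
#' Collects every stage parameter with defaults mirroring the task and
#' analysis settings (scanner switch probability 0.15, parameter bounds
#' alpha in `[0,1]`, cross-terms in `[-1,1]`, beta in `[0,8]` — fixed in the
#' fitter — 100-voxel searchlights, 10000 sign-flip permutations,
#' cluster-forming p 0.001, HRF delay 6 s). Unknown keys are rejected;
#' every stochastic stage receives a child seed derived from the master
#' seed. The config round-trips through JSON.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A `banditrsa_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    n_subjects = 20,
    sessions = c("prescan", "scanner"),
    switch_prob_scanner = 0.15,
    switch_prob_training = 0.05,
    n_starts = 10,
    searchlight_k = 100,
    n_perm = 10000,
    cluster_p = 0.001,
    hrf_delay = 6,
    tr = 1.235,
    grid_dim = c(20, 20, 20),
    region_size = c(5, 5, 6),
    effect = list(structure = 0.5, stimulus = 0.5, pe_by_structure = 0.5),
    noise_sd = 1,
    seed = 1,
    out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(modifyList(defaults, over), class = "banditrsa_config")
}

pipeline_log <- function(stage, msg, t0 = NULL) {
  el <- if (!is.null(t0)) sprintf(" [%.1fs]", as.numeric(Sys.time()) - t0)
  else ""
  message(sprintf("[%s] %s%s", stage, msg, el))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the stages in order — simulate behavior, fit both learners
#' (pooled per structure and per block type), cross-validated model
#' comparison and cross-term test, simulate the BOLD phantom, per-subject
#' GLMs and searchlight contrast maps, group sign-flip + cluster-mass FWE
#' inference, detection scoring against the planted truth — and returns a
#' report bundle. When `config$out_dir` is set, every intermediate artifact
#' is written there (TSV/JSON tables, NIfTI maps) together with a manifest
#' of seeds and stage timings.
#'
#' @param config [pipeline_config()].
#' @return A list: `behavior`, `fits` (STRUCT + NAIVE, pooled), `crossval`,
#'   `tests` (within/across, vs-NAIVE, cross-term), `ic` (information
#'   criteria), `phantom_truth`, `maps` (per-contrast subject x voxel
#'   matrices), `inference` (per-contrast cluster tables), `detection`
#'   (per-contrast sensitivity/specificity), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "banditrsa_config"))
  seed <- config$seed
  t0 <- as.numeric(Sys.time())
  manifest <- list(seed = seed, started = format(Sys.time()),
                   config = unclass(config))

  pipeline_log("simulate-behavior", "generating cohort")
  behavior <- simulate_cohort(config$n_subjects, seed = derive_seed(seed, 1),
                              sessions = config$sessions)
  if (config$n_subjects < 3) {
    warning("very small cohort: group tests run with dof = ",
            config$n_subjects - 1, call. = FALSE)
  }

  pipeline_log("fit", "pooled per-structure fits", t0)
  fits_struct <- fit_learner(behavior, "STRUCT", pool = "structure",
                             n_starts = config$n_starts,
                             seed = derive_seed(seed, 2))
  fits_naive <- fit_learner(behavior, "NAIVE", pool = "structure",
                            n_starts = config$n_starts,
                            seed = derive_seed(seed, 2))

  pipeline_log("crossval", "cross-validated model comparison", t0)
  cv <- crossval_matrix(behavior, n_starts = config$n_starts,
                        seed = derive_seed(seed, 3))
  tests <- list(
    within_vs_across = within_across_test(cv, "within_structure",
                                          "across_structure", "STRUCT"),
    within_vs_naive = within_across_test(cv, "within_structure",
                                         "same_data", "STRUCT", "NAIVE"),
    cross_term = cross_term_test(fits_struct)
  )
  ic <- information_criteria(fits_struct, fits_naive)

  pipeline_log("simulate-fmri", "generating phantom cohort", t0)
  spec <- phantom_spec(grid_dim = config$grid_dim,
                       region_size = config$region_size,
                       effect = config$effect, noise_sd = config$noise_sd,
                       n_subjects = config$n_subjects, tr = config$tr,
                       hrf_delay = config$hrf_delay)
  scanner_beh <- dplyr::filter(behavior, .data$session == "scanner")
  cohort <- generate_cohort_fmri(spec, seed = derive_seed(seed, 4),
                                 behavior = scanner_beh)

  pipeline_log("rsa-searchlight", "per-subject searchlight maps", t0)
  neighbors <- knn_searchlights(spec$coords, k = config$searchlight_k)
  contrasts <- list(
    structure = list(conditions = "ab8", contrast = "structure"),
    stimulus = list(conditions = "abc12", contrast = "stimulus"),
    pe_by_structure = list(conditions = "pe4", contrast = "structure")
  )
  maps <- purrr::imap(contrasts, function(ct, nm) {
    m <- purrr::map(cohort$subjects, function(su) {
      pat <- extract_patterns(su, ct$conditions)
      spec_c <- rdm_contrast_spec(pat$labels, contrast = ct$contrast)
      searchlight_map(pat$run1, pat$run2, pat$residuals, spec$coords,
                      spec_c, k = config$searchlight_k,
                      neighbors = neighbors)
    })
    do.call(rbind, m)
  })

  pipeline_log("inference", "sign-flip + cluster-mass FWE", t0)
  inference <- purrr::imap(maps, function(m, nm) {
    cluster_mass_fwe(m, spec$coords, threshold_p = config$cluster_p,
                     n_perm = config$n_perm, seed = derive_seed(seed, 5))
  })
  detection <- purrr::imap(inference, function(fw, nm) {
    sig <- fw$clusters |> dplyr::filter(.data$p_fwe < 0.05)
    detected <- unlist(sig$voxels)
    truth <- cohort$truth[[if (nm == "stimulus") "stimulus" else
      if (nm == "pe_by_structure") "pe_by_structure" else "structure"]]
    score_detection(detected, truth, nrow(spec$coords)) |>
      dplyr::mutate(contrast = nm, .before = 1)
  }) |> dplyr::bind_rows()

  manifest$finished <- format(Sys.time())
  manifest$elapsed_s <- as.numeric(Sys.time()) - t0
  out <- list(behavior = behavior,
              fits = list(struct = fits_struct, naive = fits_naive),
              crossval = cv, tests = tests, ic = ic,
              phantom_truth = cohort$truth, spec = spec, maps = maps,
              inference = inference, detection = detection,
              manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

# write the report bundle as plain-text artifacts + NIfTI maps
write_pipeline_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$out_dir, ...)
  write_behavior_tsv(out$behavior, p("behavior.tsv"))
  write_fits_json(out$fits$struct, p("fits_struct.json"))
  write_fits_json(out$fits$naive, p("fits_naive.json"))
  utils::write.table(out$crossval[, !sapply(out$crossval, is.list)],
                     p("crossval.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    purrr::map(out$tests, ~as.list(dplyr::select(.x, -"contrasts"))),
    p("group_tests.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(out$ic$per_subject, p("information_criteria.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(out$inference)) {
    cl <- out$inference[[nm]]$clusters
    utils::write.table(cl[, setdiff(names(cl), "voxels")],
                       p(paste0("clusters_", nm, ".tsv")), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_map_nifti(out$inference[[nm]]$t, out$spec,
                    p(paste0("tmap_", nm, ".nii.gz")))
    write_map_nifti(-log10(out$inference[[nm]]$p_uncorrected), out$spec,
                    p(paste0("neglog10p_", nm, ".nii.gz")))
  }
  utils::write.table(out$detection, p("detection.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(out$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(config$out_dir)
}
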