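# Shared sign-flip stream: one +/-1 matrix (permutation x subject) per seed,
# so the voxelwise test and the cluster-mass correction see identical flips.
sign_flip_matrix <- function(n_subjects, n_perm, seed) {
  with_seed(seed, {
    matrix(sample(c(-1, 1), n_perm * n_subjects, replace = TRUE),
           n_perm, n_subjects)
  })
}

# permutation group means and t statistics for all flips at once;
# sum(x^2) is flip-invariant, so t needs only the flipped means
flip_stats <- function(maps, flips) {
  n <- nrow(maps)
  M <- (flips %*% maps) / n                       # perm x voxel means
  ss <- colSums(maps^2)
  var_b <- sweep(-M^2 * n, 2, ss, "+") / (n - 1)  # flip-invariant SS
  Tm <- M / sqrt(pmax(var_b, 0) / n)
  Tm[!is.finite(Tm)] <- 0
  list(mean = M, t = Tm)
}

#' Sign-flip permutation test on subject contrast maps
#'
#' Under the null that per-subject contrasts are symmetric around 0, each
#' subject's map may be multiplied by +/-1. The statistic is the
#' cross-subject mean per voxel; `n_perm` random flip patterns (shared
#' across voxels within a permutation) build the null distribution, and the
#' one-tailed p value is `(1 + #{permuted mean >= observed mean}) / (1 +
#' n_perm)`, so the smallest achievable p is `1/(1 + n_perm)`.
#'
#' @param maps Subject x voxel matrix of contrast values.
#' @param n_perm Number of permutations (10000 in the full analysis).
#' @param seed Seed for the flip stream.
#' @return A list: `p` (voxelwise one-tailed p), `mean`, `t` (mean/SE),
#'   `n_perm`, `seed`.
#' @export
sign_flip_test <- function(maps, n_perm = 10000, seed = 1) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  flips <- sign_flip_matrix(n, n_perm, seed)
  st <- flip_stats(maps, flips)
  obs_mean <- colMeans(maps)
  exceed <- colSums(sweep(st$mean, 2, obs_mean, ">="))
  obs_sd <- apply(maps, 2, sd)
  obs_t <- ifelse(obs_sd > 0, obs_mean / (obs_sd / sqrt(n)), 0)
  list(p = (1 + exceed) / (1 + n_perm), mean = obs_mean, t = obs_t,
       n_perm = n_perm, seed = seed)
}

# face-connectivity clusters among suprathreshold voxels; returns a list of
# integer index vectors (into the mask), using igraph components
find_clusters <- function(supra_idx, coords) {
  if (length(supra_idx) == 0) return(list())
  if (length(supra_idx) == 1) return(list(supra_idx))
  xy <- coords[supra_idx, , drop = FALSE]
  # face neighbors differ by 1 in exactly one coordinate
  edges <- NULL
  key <- xy[, 1] * 4e6 + xy[, 2] * 2e3 + xy[, 3]
  lookup <- stats::setNames(seq_along(supra_idx), key)
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (o in 1:3) {
    nb_key <- (xy[, 1] + offs[o, 1]) * 4e6 + (xy[, 2] + offs[o, 2]) * 2e3 +
      (xy[, 3] + offs[o, 3])
    hit <- lookup[as.character(nb_key)]
    src <- which(!is.na(hit))
    if (length(src)) edges <- rbind(edges, cbind(src, unname(hit[src])))
  }
  if (is.null(edges)) {
    return(purrr::map(seq_along(supra_idx), ~supra_idx[.x]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(supra_idx) -
                                     igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  split(supra_idx, comp)
}

cluster_masses <- function(p_vec, t_vec, threshold_p, coords) {
  supra <- which(p_vec < threshold_p)
  cl <- find_clusters(supra, coords)
  purrr::map_dbl(cl, function(ix) sum(t_vec[ix]))
}

#' Max-cluster-mass family-wise error correction
#'
#' Thresholds the uncorrected sign-flip p map at `threshold_p` and scores
#' each surviving face-connected cluster by its mass — the sum over member
#' voxels of the t-like statistic (group mean / SE). The same flip stream is
#' then replayed: in every permutation the flipped maps are thresholded by
#' their within-permutation-distribution p values and the mass of the
#' largest cluster is recorded, giving the null distribution against which
#' each observed cluster's corrected p is computed.
#'
#' @param maps Subject x voxel contrast matrix.
#' @param coords Mask voxel coordinates (voxel x 3 integer matrix).
#' @param threshold_p Cluster-forming threshold on the uncorrected p map
#'   (0.001 in the full analysis). Must lie in (0, 1); note thresholds below
#'   `1/n_perm` cannot be crossed by any permutation.
#' @param n_perm,seed Flip stream, shared with [sign_flip_test()].
#' @return A list: `clusters` (tibble: cluster id, n_voxels, mass,
#'   `p_fwe`, list column of member voxel indices), `p_uncorrected`
#'   (voxel p map), `null_max_mass` (the permutation null), `threshold_p`.
#' @export
cluster_mass_fwe <- function(maps, coords, threshold_p = 0.001,
                             n_perm = 10000, seed = 1) {
  if (threshold_p <= 0 || threshold_p >= 1) {
    stop("`threshold_p` must be in (0, 1)", call. = FALSE)
  }
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  coords <- as.matrix(coords)
  flips <- sign_flip_matrix(n, n_perm, seed)
  st <- flip_stats(maps, flips)
  obs_mean <- colMeans(maps)
  obs_sd <- apply(maps, 2, sd)
  obs_t <- ifelse(obs_sd > 0, obs_mean / (obs_sd / sqrt(n)), 0)
  p_unc <- (1 + colSums(sweep(st$mean, 2, obs_mean, ">="))) / (1 + n_perm)

  # within-permutation p of each permuted mean among all permuted means
  # (counts >= itself, so the smallest permuted p is 1/n_perm)
  ranks <- apply(st$mean, 2, rank, ties.method = "min")
  p_perm <- (n_perm - ranks + 1) / n_perm

  null_max <- vapply(seq_len(n_perm), function(b) {
    m <- cluster_masses(p_perm[b, ], st$t[b, ], threshold_p, coords)
    if (length(m)) max(m) else 0
  }, numeric(1))

  supra <- which(p_unc < threshold_p)
  cl <- find_clusters(supra, coords)
  clusters <- tibble::tibble(
    cluster = seq_along(cl),
    n_voxels = purrr::map_int(cl, length),
    mass = purrr::map_dbl(cl, function(ix) sum(obs_t[ix])),
    voxels = cl
  ) |>
    dplyr::mutate(p_fwe = purrr::map_dbl(.data$mass, function(m) {
      (1 + sum(null_max >= m)) / (1 + n_perm)
    })) |>
    dplyr::arrange(dplyr::desc(.data$mass))
  list(clusters = clusters, p_uncorrected = p_unc, t = obs_t,
       null_max_mass = null_max, threshold_p = threshold_p,
       n_perm = n_perm, seed = seed)
}

#' ROI-averaged RDM test
#'
#' Averages each subject's searchlight RDMs over the ROI voxels, evaluates
#' the hypothesis contrast on the averaged RDM, and runs a one-tailed t-test
#' on the per-subject contrasts.
#'
#' @param rdms Per-subject RDMs: a list over subjects, each element either a
#'   single RDM or a list of RDMs (one per ROI voxel) to average.
#' @param spec Contrast spec from [rdm_contrast_spec()].
#' @return One-row tibble as in [within_across_test()].
#' @export
roi_test <- function(rdms, spec) {
  if (length(rdms) == 0) stop("empty ROI / no subjects", call. = FALSE)
  vals <- purrr::map_dbl(rdms, function(r) {
    if (is.list(r) && !is.matrix(r)) {
      if (length(r) == 0) stop("empty ROI", call. = FALSE)
      r <- Reduce(`+`, purrr::map(r, unclass)) / length(r)
    }
    contrast_value(r, spec)
  })
  paired_t(vals, tail = "greater")
}

#' Leave-one-out robustness of the cluster-level result
#'
#' Reruns the group stage (sign-flip test and max-cluster-mass FWE) once per
#' held-out subject on the remaining subjects' contrast maps, and reports
#' the corrected p value of the largest cluster in each rerun (`NA` when no
#' cluster forms). Per-subject searchlight maps do not depend on other
#' subjects, so this is the full leave-one-out of everything downstream of
#' the held-out subject.
#'
#' @param maps Subject x voxel contrast matrix.
#' @param coords Mask voxel coordinates.
#' @param threshold_p,n_perm,seed As in [cluster_mass_fwe()].
#' @return Tibble with `left_out` and `p_fwe` (best cluster per rerun).
#' @export
leave_one_out <- function(maps, coords, threshold_p = 0.001,
                          n_perm = 1000, seed = 1) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  purrr::map_dfr(seq_len(n), function(s) {
    fw <- cluster_mass_fwe(maps[-s, , drop = FALSE], coords,
                           threshold_p = threshold_p, n_perm = n_perm,
                           seed = seed)
    tibble::tibble(
      left_out = s,
      p_fwe = if (nrow(fw$clusters)) min(fw$clusters$p_fwe) else NA_real_
    )
  })
}

#' Detection scores against planted ground truth
#'
#' Voxelwise sensitivity (fraction of truly positive voxels detected) and
#' specificity (fraction of null voxels not detected) of a suprathreshold
#' voxel set against the planted-positive set of a phantom.
#'
#' @param detected Integer indices (into the mask) of detected voxels.
#' @param truth Integer indices of truly positive voxels.
#' @param n_voxels Total number of mask voxels.
#' @return One-row tibble: `sensitivity`, `specificity`, `n_detected`,
#'   `n_true`.
#' @export
score_detection <- function(detected, truth, n_voxels) {
  stopifnot(all(detected <= n_voxels), all(truth <= n_voxels))
  tp <- length(intersect(detected, truth))
  fp <- length(setdiff(detected, truth))
  n_neg <- n_voxels - length(truth)
  tibble::tibble(
    sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
    specificity = if (n_neg) 1 - fp / n_neg else NA_real_,
    n_detected = length(detected), n_true = length(truth)
  )
}
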