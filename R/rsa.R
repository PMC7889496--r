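#' Multivariate noise normalization (spatial prewhitening)
#'
#' Estimates the spatial covariance of the GLM residuals over the voxels at
#' hand, shrinks it toward its diagonal (Ledoit-Wolf-style intensity
#' estimated from the data unless given), and multiplies the coefficient
#' patterns by the inverse matrix square root. Correlated noise between
#' nearby voxels otherwise masquerades as shared signal in
#' correlation-distance RDMs.
#'
#' @param betas Condition x voxel coefficient matrix.
#' @param residuals Time x voxel residual matrix from the same GLM (runs may
#'   be concatenated).
#' @param shrink Shrinkage intensity in `[0, 1]`; `NULL` estimates it.
#' @return Whitened condition x voxel matrix.
#' @export
prewhiten <- function(betas, residuals, shrink = NULL) {
  betas <- as.matrix(betas)
  residuals <- as.matrix(residuals)
  v <- ncol(residuals)
  if (v < 2) stop("need at least 2 voxels", call. = FALSE)
  if (nrow(residuals) < 2) stop("need at least 2 residual timepoints",
                                call. = FALSE)
  stopifnot(ncol(betas) == v)
  S <- stats::cov(residuals)
  if (is.null(shrink)) shrink <- shrinkage_intensity(residuals, S)
  Ssh <- (1 - shrink) * S + shrink * diag(diag(S), v)
  e <- eigen(Ssh, symmetric = TRUE)
  vals <- pmax(e$values, max(e$values) * 1e-10)
  W <- e$vectors %*% diag(1 / sqrt(vals), v) %*% t(e$vectors)
  betas %*% W
}

# Schafer-Strimmer estimate of the optimal shrinkage toward the diagonal
shrinkage_intensity <- function(residuals, S) {
  n <- nrow(residuals)
  Xc <- scale(residuals, center = TRUE, scale = FALSE)
  # var of each covariance entry
  W2 <- (crossprod(Xc^2) - n * (S * (n - 1) / n)^2) * n / ((n - 1)^3)
  off <- !diag(ncol(S))
  num <- sum(W2[off])
  den <- sum(S[off]^2)
  if (den <= 0) return(1)
  min(1, max(0, num / den))
}

#' Cross-run correlation-distance RDM
#'
#' Dissimilarity between conditions i and j is the mean of the two
#' between-run correlation distances, `d_ij = ((1 - cor(r1_i, r2_j)) + (1 -
#' cor(r1_j, r2_i))) / 2`, which makes the matrix symmetric by construction
#' and — because run 1 and run 2 patterns carry independent noise — leaves a
#' meaningful diagonal: `d_ii` is the distance of a condition to itself
#' across runs, not 0. Entries lie in `[0, 2]`. Conditions with a
#' zero-variance pattern get `NA` entries with a warning.
#'
#' @param run1,run2 Condition x voxel pattern matrices with matching rows
#'   (conditions) and columns (voxels).
#' @param labels Optional condition metadata tibble (carried as an
#'   attribute), with columns such as `condition`, `structure_sign`,
#'   `stimulus_set`, `stimulus`.
#' @return A symmetric condition x condition matrix of class
#'   `banditrsa_rdm`.
#' @export
cross_run_rdm <- function(run1, run2, labels = NULL) {
  run1 <- as.matrix(run1); run2 <- as.matrix(run2)
  stopifnot(identical(dim(run1), dim(run2)), nrow(run1) >= 2,
            ncol(run1) >= 2)
  s1 <- apply(run1, 1, sd); s2 <- apply(run2, 1, sd)
  bad <- s1 == 0 | s2 == 0
  if (any(bad)) {
    warning("zero-variance pattern(s); RDM entries set to NA for: ",
            paste(which(bad), collapse = ", "), call. = FALSE)
  }
  C <- suppressWarnings(cor(t(run1), t(run2)))   # C[i, j] = cor(r1_i, r2_j)
  C[bad, ] <- NA; C[, bad] <- NA
  D <- 1 - C
  rdm <- (D + t(D)) / 2
  if (!is.null(rownames(run1))) dimnames(rdm) <- list(rownames(run1),
                                                      rownames(run1))
  structure(rdm, class = c("banditrsa_rdm", "matrix"),
            labels = labels)
}

#' Hypothesis contrasts over RDM elements
#'
#' Formalizes a representational hypothesis as two disjoint element sets of
#' the (cross-run) RDM — including the diagonal, which is meaningful here —
#' plus an optional exclusion mask. `"structure"`: pairs of conditions with
#' the same relational structure sign are hypothesized similar, pairs with
#' different signs dissimilar. `"stimulus"`: pairs showing the same visual
#' stimulus (same stimulus set and same stimulus) are similar, others
#' dissimilar. Control exclusions drop same-stimulus (`"same_stim"`) or
#' same-stimulus-set (`"same_set"`) pairs from both sets, so a structure
#' effect cannot be carried by visual identity.
#'
#' @param labels Condition metadata tibble with `structure_sign` and (for
#'   stimulus contrasts / exclusions) `stimulus_set`, `stimulus`.
#' @param contrast `"structure"` or `"stimulus"`.
#' @param exclude `"none"`, `"same_stim"` or `"same_set"`.
#' @return A list with logical matrices `similar`, `dissimilar`, `excluded`.
#' @export
rdm_contrast_spec <- function(labels, contrast = c("structure", "stimulus"),
                              exclude = c("none", "same_stim", "same_set")) {
  contrast <- match.arg(contrast)
  exclude <- match.arg(exclude)
  n <- nrow(labels)
  same <- function(col) {
    outer(labels[[col]], labels[[col]], "==")
  }
  sim <- switch(contrast,
    structure = same("structure_sign"),
    stimulus = same("stimulus_set") & same("stimulus")
  )
  excl <- switch(exclude,
    none = matrix(FALSE, n, n),
    same_stim = same("stimulus_set") & same("stimulus"),
    same_set = same("stimulus_set")
  )
  spec <- list(similar = sim & !excl, dissimilar = !sim & !excl,
               excluded = excl, contrast = contrast, exclude = exclude)
  if (!any(spec$similar) || !any(spec$dissimilar)) {
    stop("contrast spec has an empty element set after masking",
         call. = FALSE)
  }
  spec
}

#' Contrast value of an RDM under a hypothesis spec
#'
#' Mean over hypothesized-dissimilar elements minus mean over
#' hypothesized-similar elements; excluded and `NA` entries are dropped from
#' both (with a warning when `NA`s are present). Positive values mean the
#' measured geometry matches the hypothesis.
#'
#' @param rdm `banditrsa_rdm` (or plain symmetric matrix).
#' @param spec From [rdm_contrast_spec()] (or any list with logical
#'   `similar`/`dissimilar` matrices).
#' @return Scalar contrast.
#' @export
contrast_value <- function(rdm, spec) {
  d <- unclass(rdm)
  stopifnot(identical(dim(spec$similar), dim(d)))
  if (anyNA(d[spec$similar | spec$dissimilar])) {
    warning("NA RDM entries excluded from contrast", call. = FALSE)
  }
  m_dis <- mean(d[spec$dissimilar], na.rm = TRUE)
  m_sim <- mean(d[spec$similar], na.rm = TRUE)
  if (is.nan(m_dis) || is.nan(m_sim)) {
    stop("contrast element set empty after NA removal", call. = FALSE)
  }
  m_dis - m_sim
}

#' k-nearest-voxel volumetric searchlights
#'
#' For every in-mask voxel, the searchlight is the `k` in-mask voxels
#' nearest in 3-D Euclidean distance (including the center). When the mask
#' holds fewer than `k` voxels the searchlight is truncated with a warning.
#'
#' @param coords Integer voxel coordinates (n x 3 matrix) of the mask.
#' @param k Searchlight size in voxels (100 by default).
#' @param chunk Centers processed per distance block (memory knob).
#' @return Integer matrix (n x k') of neighbor row indices per center.
#' @export
knn_searchlights <- function(coords, k = 100, chunk = 512) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(k >= 2)
  if (n < k) {
    warning("mask smaller than searchlight; truncating to ", n, " voxels",
            call. = FALSE)
    k <- n
  }
  sq <- rowSums(coords^2)
  out <- matrix(0L, n, k)
  for (i0 in seq(1, n, by = chunk)) {
    idx <- i0:min(n, i0 + chunk - 1)
    D2 <- outer(sq[idx], sq, "+") - 2 * coords[idx, , drop = FALSE] %*%
      t(coords)
    for (r in seq_along(idx)) {
      out[idx[r], ] <- order(D2[r, ])[seq_len(k)]
    }
  }
  out
}

#' Searchlight map of an RDM contrast
#'
#' Runs the full per-searchlight stack at every in-mask voxel: prewhiten the
#' condition patterns with the local residual covariance, compute the
#' cross-run correlation-distance RDM, and evaluate the hypothesis contrast,
#' assigning the value to the center voxel. The result is one contrast map
#' per subject, the unit that enters group sign-flip inference.
#'
#' @param run1,run2 Condition x voxel pattern matrices over the mask voxels.
#' @param residuals Time x voxel residual matrix (runs concatenated) for
#'   prewhitening; `NULL` skips whitening.
#' @param coords Mask voxel coordinates (n x 3).
#' @param spec Contrast spec from [rdm_contrast_spec()].
#' @param k Searchlight size in voxels.
#' @param neighbors Optional precomputed [knn_searchlights()] result (reuse
#'   across subjects).
#' @return Numeric vector of contrast values, one per mask voxel.
#' @export
searchlight_map <- function(run1, run2, residuals, coords, spec, k = 100,
                            neighbors = NULL) {
  if (is.null(neighbors)) neighbors <- knn_searchlights(coords, k)
  n <- nrow(coords)
  # the residual covariance and the entry-variance matrix needed by the
  # shrinkage estimator are sliceable, so compute them once over the mask
  if (!is.null(residuals)) {
    nt <- nrow(residuals)
    Xc <- scale(residuals, center = TRUE, scale = FALSE)
    Sfull <- crossprod(Xc) / (nt - 1)
    W2full <- (crossprod(Xc^2) - nt * (Sfull * (nt - 1) / nt)^2) *
      nt / ((nt - 1)^3)
  }
  nc <- nrow(run1)
  vapply(seq_len(n), function(v) {
    idx <- neighbors[v, ]
    r1 <- run1[, idx, drop = FALSE]
    r2 <- run2[, idx, drop = FALSE]
    if (!is.null(residuals)) {
      S <- Sfull[idx, idx]
      off <- !diag(length(idx))
      den <- sum(S[off]^2)
      shrink <- if (den <= 0) 1 else
        min(1, max(0, sum(W2full[idx, idx][off]) / den))
      Ssh <- (1 - shrink) * S + shrink * diag(diag(S))
      e <- eigen(Ssh, symmetric = TRUE)
      vals <- pmax(e$values, max(e$values) * 1e-10)
      W <- e$vectors %*% (t(e$vectors) / sqrt(vals))
      r1 <- r1 %*% W
      r2 <- r2 %*% W
    }
    contrast_value(cross_run_rdm(r1, r2), spec)
  }, numeric(1))
}

#' Average-linkage dendrogram of an RDM
#'
#' Agglomerative clustering of the conditions using the off-diagonal
#' dissimilarities (the diagonal is not used by the linkage). With a planted
#' structure geometry, conditions should merge by relational structure
#' before stimulus set.
#'
#' @param rdm `banditrsa_rdm` or symmetric dissimilarity matrix.
#' @return An [stats::hclust] tree.
#' @export
rdm_dendrogram <- function(rdm) {
  d <- unclass(rdm)
  if (nrow(d) < 2) stop("need at least 2 conditions", call. = FALSE)
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Heatmap of an RDM
#'
#' @param object `banditrsa_rdm`.
#' @param ... Unused.
#' @return A ggplot tile plot of the dissimilarity matrix.
#' @export
autoplot.banditrsa_rdm <- function(object, ...) {
  d <- unclass(object)
  if (is.null(rownames(d))) rownames(d) <- seq_len(nrow(d))
  if (is.null(colnames(d))) colnames(d) <- rownames(d)
  df <- tibble::as_tibble(d, rownames = "row") |>
    tidyr::pivot_longer(-"row", names_to = "col", values_to = "distance") |>
    dplyr::mutate(row = factor(.data$row, rev(rownames(d))),
                  col = factor(.data$col, colnames(d)))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 2)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "cross-run\ndistance")
}

#' Write an RDM as tab-separated text
#'
#' @param rdm `banditrsa_rdm`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_rdm_tsv <- function(rdm, path) {
  utils::write.table(unclass(rdm), path, sep = "\t", quote = FALSE,
                     row.names = !is.null(rownames(rdm)),
                     col.names = !is.null(colnames(rdm)))
  invisible(path)
}
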