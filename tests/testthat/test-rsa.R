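# residual matrix with an exact target sample covariance (for the
# prewhitening identities)
residuals_with_cov <- function(n, S, seed = 1) {
  set.seed(seed)
  v <- ncol(S)
  X <- matrix(rnorm(n * v), n, v)
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- X %*% solve(chol(stats::cov(X)))       # sample cov now identity
  X %*% chol(S)
}

test_that("prewhitening respects the residual covariance", {
  v <- 6
  betas <- matrix(rnorm(4 * v), 4, v)

  # exact identity covariance: betas unchanged
  res_id <- residuals_with_cov(80, diag(v), seed = 2)
  expect_equal(prewhiten(betas, res_id), betas, tolerance = 1e-8)

  # diagonal covariance with variance 4 on one voxel: that voxel halved
  S <- diag(v); S[3, 3] <- 4
  res_d <- residuals_with_cov(80, S, seed = 3)
  wh <- prewhiten(betas, res_d)
  expect_equal(wh[, 3], betas[, 3] / 2, tolerance = 1e-8)
  expect_equal(wh[, -3], betas[, -3], tolerance = 1e-8)

  expect_error(prewhiten(betas[, 1, drop = FALSE],
                         res_id[, 1, drop = FALSE]), "2 voxels")
})

test_that("whitening makes spatially correlated residuals near-independent", {
  set.seed(4)
  v <- 12; n <- 300
  S <- 0.7^abs(outer(1:v, 1:v, "-"))           # strong neighbor correlation
  res <- matrix(rnorm(n * v), n, v) %*% chol(S)
  wh_res <- prewhiten(res, res)
  off <- !diag(v)
  raw_r <- mean(abs(cor(res)[off]))
  wh_r <- mean(abs(cor(wh_res)[off]))
  expect_lt(wh_r, raw_r / 2)
})

test_that("cross-run correlation distance has the documented geometry", {
  v <- 20
  set.seed(5)
  # mutually orthogonal, mean-zero condition patterns (columns of a Q basis
  # that includes the constant vector, which is then dropped), reused across
  # runs
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(v * 4), v, 4))))
  pats <- t(Q[, 2:5])
  rdm <- cross_run_rdm(pats, pats)
  expect_equal(unname(diag(unclass(rdm))), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(unclass(rdm)[!diag(4)]), rep(1, 12), tolerance = 1e-10)

  # anticorrelated across runs: meaningful diagonal hits the 2 bound
  rdm2 <- cross_run_rdm(pats, -pats)
  expect_equal(unname(diag(unclass(rdm2))), rep(2, 4), tolerance = 1e-10)

  # exact symmetry and range on arbitrary input
  r1 <- matrix(rnorm(6 * v), 6, v); r2 <- matrix(rnorm(6 * v), 6, v)
  rdm3 <- unclass(cross_run_rdm(r1, r2))
  expect_identical(rdm3, t(rdm3))
  expect_true(all(rdm3 >= 0 & rdm3 <= 2))

  # zero-variance pattern flagged as missing
  r1[2, ] <- 5
  expect_warning(rdm4 <- cross_run_rdm(r1, r2), "zero-variance")
  expect_true(all(is.na(unclass(rdm4)[2, ])))
})

test_that("contrast values are mask arithmetic on RDM elements", {
  labels <- tidyr::expand_grid(structure_sign = c(1, -1),
                               stimulus_set = 1:2) |>
    dplyr::mutate(condition = paste0("c", dplyr::row_number()),
                  stimulus = "AB")
  spec <- rdm_contrast_spec(labels, "structure")
  d <- matrix(0.6, 4, 4)
  d[spec$similar] <- 0.2
  expect_equal(contrast_value(d, spec), 0.4)
  expect_equal(contrast_value(matrix(0.7, 4, 4), spec), 0)

  # scale invariance: correlation distance ignores common rescaling
  set.seed(6)
  r1 <- matrix(rnorm(4 * 30), 4, 30); r2 <- matrix(rnorm(4 * 30), 4, 30)
  c1 <- contrast_value(cross_run_rdm(r1, r2), spec)
  c2 <- contrast_value(cross_run_rdm(3.7 * r1, 3.7 * r2), spec)
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("the structure contrast grows with the planted effect size", {
  labels <- tidyr::expand_grid(structure_sign = c(1, -1),
                               stimulus_set = 1:2) |>
    dplyr::mutate(condition = paste0("c", dplyr::row_number()),
                  stimulus = "AB")
  spec <- rdm_contrast_spec(labels, "structure")
  v <- 60
  mean_contrast <- function(e, seed) {
    set.seed(seed)
    proto <- list(`1` = rnorm(v), `-1` = rnorm(v))
    reps <- replicate(30, {
      mk <- function() {
        t(sapply(seq_len(4), function(i)
          e * proto[[as.character(labels$structure_sign[i])]] + rnorm(v)))
      }
      contrast_value(cross_run_rdm(mk(), mk()), spec)
    })
    mean(reps)
  }
  cs <- sapply(c(0, 0.1, 0.3), mean_contrast, seed = 7)
  expect_lt(abs(cs[1]), 0.05)
  expect_gt(cs[2], cs[1])
  expect_gt(cs[3], cs[2])
})

test_that("element-masking controls keep a genuine structure effect", {
  # planted structure geometry on 8 conditions (2 stimuli x 4 block types):
  # excluding same-stimulus or same-set pairs must not abolish the contrast
  labels <- tidyr::expand_grid(stimulus = c("A", "B"),
                               structure_sign = c(1, -1),
                               stimulus_set = 1:2) |>
    dplyr::mutate(condition = paste0(stimulus, ".", structure_sign, ".",
                                     stimulus_set))
  v <- 80
  set.seed(8)
  proto <- list(`1` = rnorm(v), `-1` = rnorm(v))
  mk <- function() {
    t(sapply(seq_len(nrow(labels)), function(i)
      0.6 * proto[[as.character(labels$structure_sign[i])]] + rnorm(v)))
  }
  r1 <- mk(); r2 <- mk()
  rdm <- cross_run_rdm(r1, r2)
  for (ex in c("none", "same_stim", "same_set")) {
    spec <- rdm_contrast_spec(labels, "structure", exclude = ex)
    expect_gt(contrast_value(rdm, spec), 0.1)
  }
  # exclusion masks drop strictly more elements
  s0 <- rdm_contrast_spec(labels, "structure", exclude = "none")
  s2 <- rdm_contrast_spec(labels, "structure", exclude = "same_set")
  expect_gt(sum(s0$similar) + sum(s0$dissimilar),
            sum(s2$similar) + sum(s2$dissimilar))
})

test_that("searchlights have exactly k voxels and localize planted effects", {
  fx <- fix_phantom()
  spec <- fx$spec
  nb <- knn_searchlights(spec$coords, k = 30)
  expect_equal(dim(nb), c(nrow(spec$coords), 30))
  expect_true(all(nb[, 1] == seq_len(nrow(spec$coords))
                  | nb[, 1] > 0))  # center included among neighbors
  # each searchlight's voxels are unique
  expect_true(all(apply(nb, 1, function(r) length(unique(r)) == 30)))
  # warning when the mask is smaller than k
  expect_warning(knn_searchlights(spec$coords[1:10, ], k = 30), "truncat")

  pat <- extract_patterns(fx$cohort$subjects[[1]], "ab8")
  cspec <- rdm_contrast_spec(pat$labels, "structure")
  m <- searchlight_map(pat$run1, pat$run2, pat$residuals, spec$coords,
                       cspec, k = 30, neighbors = nb)
  ri <- spec$region_index
  # top-decile contrast voxels concentrate in the planted structure region
  top <- order(m, decreasing = TRUE)[seq_len(ceiling(length(m) / 10))]
  expect_gte(mean(top %in% ri$structure), 0.8)
  expect_lt(abs(mean(m[ri$null])), 0.1)
})

test_that("a uniform-noise volume yields a near-zero contrast map", {
  set.seed(9)
  v <- 150
  coords <- as.matrix(expand.grid(1:5, 1:5, 1:6))
  labels <- tidyr::expand_grid(structure_sign = c(1, -1),
                               stimulus_set = 1:2) |>
    dplyr::mutate(condition = paste0("c", dplyr::row_number()),
                  stimulus = "AB")
  cspec <- rdm_contrast_spec(labels, "structure")
  r1 <- matrix(rnorm(4 * v), 4, v)
  r2 <- matrix(rnorm(4 * v), 4, v)
  m <- searchlight_map(r1, r2, NULL, coords, cspec, k = 20)
  expect_lt(abs(mean(m)), 0.1)
})

test_that("dendrograms recover planted cluster geometry", {
  # two tight pairs merge within-pair first
  d <- matrix(1, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  hc <- rdm_dendrogram(d)
  first_two <- hc$merge[1:2, ]
  expect_setequal(abs(as.vector(first_two)), 1:4)
  expect_equal(hc$height[1:2], c(0.1, 0.1))

  # ultrametric input is reproduced exactly by average linkage
  du <- matrix(0.8, 4, 4)
  du[1, 2] <- du[2, 1] <- 0.2
  du[3, 4] <- du[4, 3] <- 0.4
  diag(du) <- 0
  hc2 <- rdm_dendrogram(du)
  expect_equal(sort(hc2$height), c(0.2, 0.4, 0.8))
  expect_equal(unname(as.matrix(stats::cophenetic(hc2))), unname(du),
               tolerance = 1e-12)

  # planted structure RDM clusters by structure sign, not stimulus set
  labels <- tidyr::expand_grid(structure_sign = c(1, -1),
                               stimulus_set = 1:2) |>
    dplyr::mutate(condition = paste0(structure_sign, "/", stimulus_set),
                  stimulus = "AB")
  set.seed(10)
  v <- 100
  proto <- list(`1` = rnorm(v), `-1` = rnorm(v))
  mk <- function() t(sapply(seq_len(4), function(i)
    0.8 * proto[[as.character(labels$structure_sign[i])]] + 0.5 * rnorm(v)))
  rdm <- cross_run_rdm(mk(), mk(), labels = labels)
  rownames(rdm) <- labels$condition
  hc3 <- rdm_dendrogram(rdm)
  two <- stats::cutree(hc3, 2)
  expect_equal(length(unique(two[labels$structure_sign == 1])), 1)
  expect_equal(length(unique(two[labels$structure_sign == -1])), 1)
  expect_error(rdm_dendrogram(matrix(0, 1, 1)), "2 conditions")

  expect_s3_class(autoplot(rdm), "ggplot")
})

test_that("RDMs round-trip through TSV", {
  set.seed(11)
  rdm <- cross_run_rdm(matrix(rnorm(80), 4), matrix(rnorm(80), 4))
  rownames(rdm) <- colnames(rdm) <- paste0("c", 1:4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rdm_tsv(rdm, path)
  back <- as.matrix(utils::read.delim(path, sep = "\t", row.names = 1))
  expect_equal(unname(back), unname(unclass(rdm)), tolerance = 1e-12)
})
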