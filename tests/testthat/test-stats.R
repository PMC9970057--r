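test_that("pca_scores selects components by cumulative variance", {
  set.seed(1)
  # rank-1 matrix: one component at any threshold
  u <- rnorm(20); v <- rnorm(7)
  X1 <- outer(u, v)
  expect_equal(pca_scores(X1, 0.5)$n_components, 1L)
  expect_equal(pca_scores(X1, 1.0)$n_components, 1L)
  # isotropic 3-feature Gaussian: all 3 needed at 95%
  X2 <- matrix(rnorm(900), 300, 3)
  expect_equal(pca_scores(X2, 0.95)$n_components, 3L)
  # with all components kept, scores are an isometry of centred X
  pc <- pca_scores(X2, 1.0)
  expect_equal(as.matrix(stats::dist(pc$scores)),
               as.matrix(stats::dist(scale(X2, scale = FALSE))), tolerance = 1e-9)
  expect_error(pca_scores(X2, 0), "var_threshold")
  expect_error(pca_scores(X2, 1.2), "var_threshold")
})

test_that("representation correlation matches a hand-rolled oracle", {
  set.seed(2)
  X1 <- matrix(rnorm(30 * 4), 30, 4)
  X2 <- matrix(rnorm(30 * 6), 30, 6)
  res <- representation_correlation(X1, X2)
  # independent implementation: explicit distance loops + cor formula
  n <- 30
  d1 <- d2 <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d1 <- c(d1, sqrt(sum((X1[i, ] - X1[j, ])^2)))
    d2 <- c(d2, sqrt(sum((X2[i, ] - X2[j, ])^2)))
  }
  r_or <- sum((d1 - mean(d1)) * (d2 - mean(d2))) /
    sqrt(sum((d1 - mean(d1))^2) * sum((d2 - mean(d2))^2))
  expect_equal(res$r, r_or, tolerance = 1e-12)
  expect_equal(res$df, length(d1) - 2)
  t_or <- r_or * sqrt(res$df / (1 - r_or^2))
  expect_equal(res$p, 2 * stats::pt(-abs(t_or), res$df), tolerance = 1e-12)
})

test_that("representation correlation is invariant to rotation and scale", {
  set.seed(3)
  X <- matrix(rnorm(25 * 5), 25, 5)
  expect_equal(representation_correlation(X, X)$r, 1)
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  expect_equal(representation_correlation(X, 3.7 * X %*% Q)$r, 1, tolerance = 1e-12)
  # symmetry in the arguments
  Y <- matrix(rnorm(25 * 3), 25, 3)
  expect_equal(representation_correlation(X, Y)$r,
               representation_correlation(Y, X)$r)
  rownames(X) <- paste0("s", 1:25)
  Y2 <- Y; rownames(Y2) <- paste0("t", 1:25)
  expect_error(representation_correlation(X, Y2), "ids")
  # Mantel permutation p-value is available and seeded
  rm1 <- representation_correlation(X, Y, mantel_permutations = 99, seed = 1)
  rm2 <- representation_correlation(X, Y, mantel_permutations = 99, seed = 1)
  expect_equal(rm1$p_mantel, rm2$p_mantel)
})

test_that("classifiers recover well-separated clusters perfectly", {
  set.seed(4)
  centers <- rbind(c(0, 0), c(12, 0), c(0, 12))
  X <- centers[rep(1:3, each = 15), ] + matrix(rnorm(90, 0, 0.5), 45, 2)
  y <- rep(c("A", "B", "C"), each = 15)
  for (meth in c("kmeans", "logistic", "naive_bayes", "lda")) {
    res <- classify_groups(X, y, meth, folds = 5, seed = 1)
    expect_equal(res$mean, 1, info = meth)
    if (meth != "kmeans") expect_equal(res$sd, 0, info = meth)  # every fold perfect
  }
})

test_that("shuffled labels drop accuracy to chance and results are seeded", {
  set.seed(5)
  X <- matrix(rnorm(60 * 3), 60, 3)
  y <- sample(rep(c("A", "B", "C"), each = 20))
  accs <- vapply(1:8, function(s) {
    classify_groups(X, sample(y), "lda", folds = 5, seed = s)$mean
  }, 0)
  expect_lt(abs(mean(accs) - 1 / 3), 0.12)  # permutation baseline ~ 1/K
  r1 <- classify_groups(X, y, "logistic", folds = 5, seed = 7)
  r2 <- classify_groups(X, y, "logistic", folds = 5, seed = 7)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_true(all(r1$per_fold >= 0 & r1$per_fold <= 1))
})

test_that("11-fold stratification of a 102-shape collection gives folds of 9-10", {
  set.seed(6)
  y <- factor(rep(paste0("G", 1:5), c(30, 25, 20, 15, 12)))  # 102 shapes
  folds <- fmorph:::stratified_folds(y, 11)
  sizes <- tabulate(folds, 11)
  expect_true(all(sizes %in% c(9L, 10L)))
  expect_equal(sum(sizes), 102L)
  # a training fold missing a class raises a stratification error
  X <- matrix(rnorm(8 * 2), 8, 2)
  ytiny <- factor(c("A", rep("B", 7)))
  expect_error(classify_groups(X, ytiny, "lda", folds = 4, seed = 1),
               "stratification error")
})

test_that("landmark transfer error is zero for identity maps and bounded by snapping", {
  coll <- tf_coll6()
  meshes <- coll$meshes[1:3]
  ids <- names(meshes)
  n <- nrow(meshes[[1]]$vertices)
  p2p <- list()
  for (i in ids) for (j in setdiff(ids, i))
    p2p[[paste0(i, "->", j)]] <- fmorph:::point_map(seq_len(n), n, i, j)
  lte <- landmark_transfer_error(p2p, meshes, coll$landmarks[ids])
  expect_equal(nrow(lte), 5L)  # one row per landmark
  # landmarks sit exactly on vertices and maps are the exact ground truth
  expect_equal(lte$mean, rep(0, 5))
  expect_equal(lte$sd, rep(0, 5))
  # perturbed landmarks: error bounded by the snapping distance
  lmk <- coll$landmarks[ids]
  set.seed(7)
  for (id in ids) lmk[[id]] <- lmk[[id]] + matrix(rnorm(15, 0, 1e-3), 5, 3)
  lte2 <- landmark_transfer_error(p2p, meshes, lmk)
  snap_bound <- max(vapply(ids, function(id) {
    max(sqrt(rowSums((lmk[[id]] -
      meshes[[id]]$vertices[fmorph:::nn_index(lmk[[id]], meshes[[id]]$vertices), ])^2)))
  }, 0))
  expect_lte(max(lte2$mean), 2 * snap_bound + 1e-12)
  # missing pair -> warning, pair skipped
  expect_warning(landmark_transfer_error(p2p[-1], meshes, coll$landmarks[ids]),
                 "missing maps")
})

test_that("group covariance traces partition total variance sensibly", {
  set.seed(8)
  X <- rbind(matrix(rnorm(40, 0, 1), 20, 2), matrix(rnorm(40, 5, 3), 20, 2))
  tr <- group_covariance_traces(X, rep(c("a", "b"), each = 20))
  expect_gt(tr[["b"]], tr[["a"]])
  expect_gt(attr(tr, "total"), 0)
})
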