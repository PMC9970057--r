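iso_ops <- function(k = 20) {
  iso <- tf_iso_pair(2)
  maps <- list("a->b" = gt_fmap(iso$map, iso$b1, iso$b2, k, "a", "b"),
               "b->a" = gt_fmap(iso$map, iso$b2, iso$b1, k, "b", "a"))
  fmn <- fmap_network(maps, list(a = iso$b1$evals, b = iso$b2$evals))
  ls <- compute_limit_shape(fmn, k)
  list(iso = iso, fmn = fmn, ls = ls, ops = latent_shape_differences(ls, fmn$evals))
}

test_that("shape differences are the identity on exactly isometric shapes", {
  k <- 20
  res <- iso_ops(k)
  for (id in c("a", "b")) {
    expect_lt(norm(res$ops[[id]]$D_area - diag(k), "F"), 1e-3)
    expect_lt(norm(res$ops[[id]]$D_conf - diag(k), "F"), 1e-3)
  }
})

test_that("unit-area normalisation removes pure scale differences", {
  iso <- tf_iso_pair(2)
  big <- iso$m1; big$vertices <- 2.7 * big$vertices
  pair <- list(a = iso$m1, b = normalize_unit_area(big))
  bases <- lapply(pair, spectral_basis, k = 25)
  k <- 15
  n <- nrow(iso$m1$vertices)
  maps <- list("a->b" = gt_fmap(seq_len(n), bases$a, bases$b, k, "a", "b"),
               "b->a" = gt_fmap(seq_len(n), bases$b, bases$a, k, "b", "a"))
  fmn <- fmap_network(maps, lapply(bases, function(b) b$evals))
  ops <- latent_shape_differences(compute_limit_shape(fmn, k), fmn$evals)
  expect_lt(norm(ops[["b"]]$D_area - diag(k), "F"), 1e-3)
})

test_that("operators are symmetric PSD and rigid-motion invariant", {
  res <- iso_ops(20)
  Da <- res$ops[["a"]]$D_area
  expect_true(isSymmetric(Da, tol = 1e-6))
  expect_gte(min(eigen(Da, symmetric = TRUE, only.values = TRUE)$values), -1e-6)
  expect_true(isSymmetric(res$ops[["a"]]$D_conf, tol = 1e-10))
  # shapes a and b differ by a rigid motion only: their operators agree
  expect_lt(norm(res$ops[["a"]]$D_area - res$ops[["b"]]$D_area, "F"), 1e-6)
  expect_lt(norm(res$ops[["a"]]$D_conf - res$ops[["b"]]$D_conf, "F"), 1e-6)
})

test_that("shape-difference operators match dense explicit-matrix oracles", {
  # bumped 642-vertex pair with exact bijection; oracles build the latent
  # functions and integrate the mass / Dirichlet inner products densely
  fx <- bumped_pair_fixture()
  k <- fx$k
  bumped <- fx$ids[2]
  ops <- fx$ops
  # the bump changes local area: trace deviates measurably from k_latent
  expect_gt(abs(sum(diag(ops[[bumped]]$D_area)) - k), 5e-3)
  lap <- build_laplacian(fx$meshes[[bumped]])
  # (i) dense Gram of the latent functions realised on the bumped shape
  Lb <- fx$bases[[bumped]]$Phi[, 1:k] %*% fx$ls$Y[[bumped]]
  G_area <- t(Lb) %*% (Matrix::diag(lap$mass) * Lb)
  expect_lt(norm(ops[[bumped]]$D_area - G_area, "F") / norm(G_area, "F"), 0.02)
  G_dir <- as.matrix(t(Lb) %*% (lap$stiffness %*% Lb))
  lam0 <- fx$ls$evals0
  D_conf_or <- ifelse(lam0 < 1e-12, 0, 1 / pmax(lam0, 1e-12)) * G_dir
  D_conf_or[lam0 < 1e-12, ] <- 0
  diag(D_conf_or)[lam0 < 1e-12] <- 1
  D_conf_or <- (D_conf_or + t(D_conf_or)) / 2
  expect_lt(norm(ops[[bumped]]$D_conf - D_conf_or, "F") / norm(D_conf_or, "F"), 0.02)
  # (ii) pullback oracle: latent functions carried from the unbumped shape
  # through the exact bijection, then integrated with the bumped shape's
  # mass; traces agree within 2%
  La_on_b <- (fx$bases[[1]]$Phi[, 1:k] %*% fx$ls$Y[[fx$ids[1]]])[seq_len(fx$n), , drop = FALSE]
  G_pull <- t(La_on_b) %*% (Matrix::diag(lap$mass) * La_on_b)
  expect_lt(abs(sum(diag(ops[[bumped]]$D_area)) - sum(diag(G_pull))) / sum(diag(G_pull)),
            0.02)
})

test_that("LSSD matrices have the documented shape and scaling", {
  res <- iso_ops(20)
  Xa <- lssd_matrix(res$ops, "area")
  expect_equal(dim(Xa), c(2, 400))
  # isometric shapes: (numerically) identical rows, zero variance
  expect_lt(max(apply(Xa, 2, stats::sd)), 1e-6)
  Xc <- lssd_matrix(res$ops, "combined")
  expect_equal(ncol(Xc), 800)
  # standardisation contract: each non-constant column has mean 0
  expect_lt(max(abs(colMeans(Xc))), 1e-9)
})

test_that("LSSD distances are invariant to collection order", {
  coll <- tf_coll6()
  ids <- names(coll$meshes)[c(1, 2, 4)]
  meshes <- coll$meshes[ids]
  bases <- lapply(meshes, spectral_basis, k = 20)
  k <- 10
  n <- nrow(meshes[[1]]$vertices)
  build <- function(order_ids) {
    maps <- list()
    for (i in order_ids) for (j in setdiff(order_ids, i))
      maps[[paste0(i, "->", j)]] <- gt_fmap(seq_len(n), bases[[i]], bases[[j]], k, i, j)
    fmn <- fmap_network(maps, lapply(bases[order_ids], function(b) b$evals))
    ops <- latent_shape_differences(compute_limit_shape(fmn, k), fmn$evals)
    lssd_matrix(ops[order_ids], "area")  # fixed row order for comparison
  }
  X1 <- build(ids)
  X2 <- build(rev(ids))[ids, ]
  d1 <- unname(as.matrix(stats::dist(X1)))
  d2 <- unname(as.matrix(stats::dist(X2)))
  expect_equal(d1, d2, tolerance = 1e-4)
})

test_that("distinctive functions vanish for identical groups and localise bumps", {
  res <- iso_ops(15)
  iso <- res$iso
  # four rigid copies in two groups: groups are identical, field must be flat 0
  ids <- c("a", "b")
  bases <- list(a = iso$b1, b = iso$b2)
  ops4 <- c(res$ops, res$ops)
  names(ops4) <- c("a", "b", "c", "d")
  ops4 <- lapply(names(ops4), function(id) {
    o <- ops4[[id]]; o$shape_id <- id; o
  })
  names(ops4) <- c("a", "b", "c", "d")
  emb <- res$ls
  emb$Y <- c(emb$Y, stats::setNames(emb$Y, c("c", "d")))
  groups <- stats::setNames(c("G1", "G2", "G1", "G2"), names(ops4))
  df <- distinctive_functions(ops4, emb, c(bases, stats::setNames(bases, c("c", "d"))),
                              "a", groups, c("G1", "G2"), kind = "area")
  expect_lt(max(df$field), 1e-6)
  expect_error(distinctive_functions(ops4, emb, bases, "a",
                                     stats::setNames(c("G1", "G2", "G2", "G2"), names(ops4)),
                                     c("G1", "G2")), "at least 2")
})
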