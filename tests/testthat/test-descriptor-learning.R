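test_that("fm_layer agrees with estimate_fmap and handles the self map", {
  set.seed(1)
  k <- 6; d <- 10
  Fc <- matrix(rnorm(k * d), k, d)
  Gc <- matrix(rnorm(k * d), k, d)
  ev1 <- sort(runif(k, 0, 5)); ev2 <- sort(runif(k, 0, 5))
  lay <- fm_layer(Fc, Gc, ev1, ev2, alpha = 1e-2)
  expect_equal(lay$C12, estimate_fmap(Fc, Gc, ev1, ev2, alpha = 1e-2)$C,
               tolerance = 1e-12)
  expect_equal(lay$C21, estimate_fmap(Gc, Fc, ev2, ev1, alpha = 1e-2)$C,
               tolerance = 1e-12)
  self <- fm_layer(Fc, Fc, ev1, ev1, alpha = 1e-2)
  expect_equal(self$C12, diag(k), tolerance = 1e-8)
  expect_equal(self$C21, diag(k), tolerance = 1e-8)
})

test_that("fm_layer gradients match central finite differences", {
  set.seed(2)
  k <- 5; d <- 8
  Fc <- matrix(rnorm(k * d), k, d); Gc <- matrix(rnorm(k * d), k, d)
  ev1 <- sort(runif(k, 0, 10)); ev2 <- sort(runif(k, 0, 10))
  D1 <- lapply(1:2, function(i) matrix(rnorm(k * k), k, k))
  D2 <- lapply(1:2, function(i) matrix(rnorm(k * k), k, k))
  w <- c(1.3, 0.7, 2.1, 0.9)
  loss_of <- function(Fm, Gm) {
    lay <- fm_layer(Fm, Gm, ev1, ev2, alpha = 1e-2)
    surfmnet_loss(lay$C12, lay$C21, ev1, ev2, D1, D2, w)$total
  }
  lay <- fm_layer(Fc, Gc, ev1, ev2, alpha = 1e-2)
  ls <- surfmnet_loss(lay$C12, lay$C21, ev1, ev2, D1, D2, w)
  gb <- lay$backward(ls$dC12, ls$dC21)
  h <- 1e-6
  for (probe in list(c(1, 1), c(3, 5), c(5, 8))) {
    i <- probe[1]; j <- probe[2]
    Fp <- Fc; Fp[i, j] <- Fp[i, j] + h
    Fm2 <- Fc; Fm2[i, j] <- Fm2[i, j] - h
    num <- (loss_of(Fp, Gc) - loss_of(Fm2, Gc)) / (2 * h)
    expect_equal(gb$dF[i, j], num, tolerance = 1e-4)
    Gp <- Gc; Gp[i, j] <- Gp[i, j] + h
    Gm2 <- Gc; Gm2[i, j] <- Gm2[i, j] - h
    num2 <- (loss_of(Fc, Gp) - loss_of(Fc, Gm2)) / (2 * h)
    expect_equal(gb$dG[i, j], num2, tolerance = 1e-4)
  }
})

test_that("loss terms match a symbolic element-wise expansion on a 3x3 case", {
  set.seed(3)
  k <- 3
  C12 <- matrix(rnorm(9), 3); C21 <- matrix(rnorm(9), 3)
  ev1 <- c(0, 1.5, 4); ev2 <- c(0, 2, 3)
  D1 <- list(matrix(rnorm(9), 3)); D2 <- list(matrix(rnorm(9), 3))
  ls <- surfmnet_loss(C12, C21, ev1, ev2, D1, D2, weights = c(1, 1, 1, 1))
  # independent element-wise oracle with explicit loops
  fro2 <- function(M) sum(M^2)
  I3 <- diag(3)
  E1 <- fro2(C12 %*% C21 - I3) + fro2(C21 %*% C12 - I3)
  E2 <- fro2(t(C12) %*% C12 - I3) + fro2(t(C21) %*% C21 - I3)
  L1 <- diag(ev1); L2 <- diag(ev2)
  E3 <- fro2(C12 %*% L1 - L2 %*% C12) + fro2(C21 %*% L2 - L1 %*% C21)
  E4 <- fro2(C12 %*% D1[[1]] - D2[[1]] %*% C12) +
        fro2(C21 %*% D2[[1]] - D1[[1]] %*% C21)
  expect_equal(unname(ls$terms), c(E1, E2, E3, E4), tolerance = 1e-12)
  expect_equal(ls$total, E1 + E2 + E3 + E4, tolerance = 1e-12)
})

test_that("loss structure: identity maps are the global zero, orthogonal maps kill E1/E2", {
  k <- 6
  ev <- seq(0, 5, length.out = k)
  ls0 <- surfmnet_loss(diag(k), diag(k), ev, ev)
  expect_equal(unname(ls0$terms), rep(0, 4))
  set.seed(4)
  Q <- qr.Q(qr(matrix(rnorm(k * k), k)))
  ev2 <- sort(runif(k, 0, 5))
  lsq <- surfmnet_loss(Q, t(Q), ev, ev2)
  expect_lt(lsq$terms["E1"], 1e-20)
  expect_lt(lsq$terms["E2"], 1e-20)
  expect_gt(lsq$terms["E3"], 1e-6)
  expect_true(all(unname(lsq$terms) >= 0))
})

test_that("pair_sampler enumerates every ordered pair once per epoch, seeded", {
  s <- pair_sampler(c("x", "y", "z"), seed = 5)
  ep <- s(1)
  expect_equal(nrow(ep), 6)
  expect_equal(sort(paste(ep[, 1], ep[, 2])),
               sort(c("x y", "x z", "y x", "y z", "z x", "z y")))
  expect_identical(pair_sampler(c("x", "y", "z"), seed = 5)(1), ep)
  expect_false(identical(s(2), ep) && identical(s(3), ep))
  # n(n-1) pairs for a large collection
  expect_equal(nrow(pair_sampler(sprintf("s%03d", 1:102), seed = 0)(1)), 10302)
  expect_error(pair_sampler("one"), "at least 2")
})

test_that("training configuration validates its inputs", {
  expect_error(training_config(learning_rate = 0), "learning_rate")
  expect_error(training_config(weights = c(-1, 1, 1, 1)), "weights")
  expect_equal(training_config()$learning_rate, 1e-3)
  expect_equal(training_config()$batch_size, 1)
})

test_that("seeded training decreases the loss; zero learning rate freezes it", {
  coll <- make_collection(n_groups = 2, n_per_group = 3, level = 2, seed = 21)
  bases <- lapply(coll$meshes, spectral_basis, k = 30)
  ext <- extractor_spectral_mlp(n_wks = 16, hidden = 32, out_dim = 300)
  cfg <- training_config(epochs = 20, seed = 4, k = 20, conv_tol = 0)
  tr <- train_descriptors(bases, coll$meshes, ext, cfg)
  expect_gte(1 - tr$loss_trace[length(tr$loss_trace)] / tr$loss_trace[1], 0.5)
  # reproducibility
  tr2 <- train_descriptors(bases, coll$meshes, ext,
                           training_config(epochs = 2, seed = 4, k = 20, conv_tol = 0))
  expect_equal(tr2$loss_trace, tr$loss_trace[1:2], tolerance = 1e-12)
  # zero learning rate: loss trace is constant
  cfg0 <- training_config(epochs = 3, seed = 4, k = 20, learning_rate = 1e-30,
                          conv_tol = 0)
  tr0 <- train_descriptors(bases, coll$meshes, ext, cfg0)
  expect_lt(diff(range(tr0$loss_trace)) / tr0$loss_trace[1], 1e-12)
  assign("train20", tr, envir = .fix_cache)
  assign("train_bases", bases, envir = .fix_cache)
  assign("train_coll", coll, envir = .fix_cache)
})

test_that("training on identical-shape pairs keeps bijectivity and orthogonality at zero", {
  # the Siamese pair of an identical shape yields C12 = C21 = I at every
  # step, so the bijectivity and orthogonality terms sit at the loss floor
  m <- warped_ellipsoid(2)
  meshes <- list(a = m, b = m)
  bases <- lapply(meshes, spectral_basis, k = 15)
  ext <- extractor_spectral_mlp(n_wks = 12, hidden = 16, out_dim = 60)
  cfg <- training_config(epochs = 5, seed = 1, k = 10, conv_tol = 0, n_desc_e4 = 5)
  tr <- train_descriptors(bases, meshes, ext, cfg)
  e12 <- rowSums(tr$term_trace[, c("E1", "E2"), drop = FALSE])
  expect_lt(max(e12), 1e-10)
  expect_true(all(is.finite(tr$loss_trace)))
})

test_that("a frozen WKS extractor reduces the learned path to the axiomatic one", {
  coll <- tf_coll6()
  meshes <- coll$meshes[1:2]
  bases <- lapply(meshes, spectral_basis, k = 25)
  ext <- extractor_spectral_mlp(n_wks = 40, frozen_wks = TRUE)
  expect_equal(ext$n_params, 0L)
  tr <- train_descriptors(bases, meshes, ext,
                          training_config(epochs = 1, seed = 0, k = 15, conv_tol = 0))
  # descriptors are exactly the WKS values
  for (id in names(meshes))
    expect_equal(tr$descriptors[[id]], wks(bases[[id]], n_energies = 40)$values)
  # and the maps they induce equal the axiomatic estimate
  fmn_learned <- fmap_network_from_descriptors(bases, tr$descriptors, k = 15)
  fmn_axiomatic <- fmap_network_from_descriptors(
    bases, lapply(bases, wks, n_energies = 40), k = 15)
  for (key in names(fmn_learned$maps))
    expect_equal(fmn_learned$maps[[key]]$C, fmn_axiomatic$maps[[key]]$C,
                 tolerance = 1e-12)
})

test_that("extractor contract holds for the reference extractor", {
  fx <- tf_basis70()
  ext <- extractor_spectral_mlp(n_wks = 12, hidden = 8, out_dim = 20)
  params <- ext$init(3)
  X <- ext$features(fx$mesh, fx$basis)
  out <- ext$forward(X, params)$out
  expect_equal(nrow(out), nrow(fx$mesh$vertices))
  expect_true(all(is.finite(out)))
  expect_true(ext$rigid_invariant)
  # rotated copy: identical features (WKS inputs are intrinsic)
  rep <- descriptor_contract_check(out, fx$mesh, recompute = function(mm) {
    b2 <- spectral_basis(mm, k = 70)
    ext$forward(ext$features(mm, b2), params)$out
  })
  expect_true(rep$pass)
  expect_true(rep$rigid_invariant)
})
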