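#' Reference feature extractor: pointwise MLP over spectral inputs
#'
#' The learnable descriptor extractor used for unsupervised descriptor
#' learning. It is a small pointwise network (one tanh hidden layer, linear
#' output) applied to rigid-motion-invariant spectral inputs — the Wave
#' Kernel Signature channels of each vertex — so its output satisfies the
#' descriptor contract by construction. Any extractor honouring the same
#' interface (`features`, `forward`, `backward`, `init`) can be dropped in;
#' a richer surface-convolution network is one such replacement. Setting
#' `frozen_wks = TRUE` returns a parameter-free extractor that passes the
#' WKS channels through unchanged, reducing the learned pipeline exactly to
#' the axiomatic one.
#'
#' @param n_wks number of WKS input channels per vertex.
#' @param hidden hidden-layer width.
#' @param out_dim output descriptor dimension (contract default 300).
#' @param frozen_wks if `TRUE`, the extractor has no parameters and outputs
#'   its WKS inputs unchanged.
#' @return object of class `extractor_contract` with elements
#'   `features(mesh, basis)`, `forward(X, params)` (returns `out` and a
#'   backprop `cache`), `backward(cache, d_out)` (returns the parameter
#'   gradient), `init(seed)`, `n_params`, `out_dim`, `rigid_invariant`.
#' @export
extractor_spectral_mlp <- function(n_wks = 16, hidden = 32, out_dim = 300,
                                   frozen_wks = FALSE) {
  if (frozen_wks) {
    return(structure(list(
      features = function(mesh, basis) wks(basis, n_energies = n_wks)$values,
      forward = function(X, params) list(out = X, cache = NULL),
      backward = function(cache, d_out) numeric(0),
      init = function(seed = 0) numeric(0),
      n_params = 0L, out_dim = n_wks, rigid_invariant = TRUE),
      class = "extractor_contract"))
  }
  n1 <- n_wks * hidden; n2 <- hidden; n3 <- hidden * out_dim; n4 <- out_dim
  unpack <- function(params) {
    list(W1 = matrix(params[seq_len(n1)], n_wks, hidden),
         b1 = params[n1 + seq_len(n2)],
         W2 = matrix(params[n1 + n2 + seq_len(n3)], hidden, out_dim),
         b2 = params[n1 + n2 + n3 + seq_len(n4)])
  }
  structure(list(
    features = function(mesh, basis) wks(basis, n_energies = n_wks)$values,
    forward = function(X, params) {
      p <- unpack(params)
      H <- tanh(sweep(X %*% p$W1, 2, p$b1, `+`))
      out <- sweep(H %*% p$W2, 2, p$b2, `+`)
      list(out = out, cache = list(X = X, H = H, p = p))
    },
    backward = function(cache, d_out) {
      H <- cache$H; X <- cache$X; p <- cache$p
      dW2 <- crossprod(H, d_out)
      db2 <- colSums(d_out)
      dH <- tcrossprod(d_out, p$W2) * (1 - H^2)
      dW1 <- crossprod(X, dH)
      db1 <- colSums(dH)
      c(as.vector(dW1), db1, as.vector(dW2), db2)
    },
    init = function(seed = 0) {
      old <- get0(".Random.seed", envir = globalenv())
      set.seed(as.integer(seed))
      out <- c(stats::rnorm(n1, 0, 1 / sqrt(n_wks)), numeric(n2),
               stats::rnorm(n3, 0, 1 / sqrt(hidden)), numeric(n4))
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      out
    },
    n_params = n1 + n2 + n3 + n4, out_dim = out_dim, rigid_invariant = TRUE),
    class = "extractor_contract")
}

#' Differentiable functional-map layer
#'
#' Computes the functional maps in both directions between a source and a
#' target shape from their descriptor coefficient matrices, with the same
#' closed-form minimiser as [estimate_fmap()], and exposes the exact
#' adjoint (backward) pass through the row-wise linear solves so that
#' gradients of any loss on `C12`/`C21` propagate to the descriptors.
#'
#' @param Fc,Gc `k x d` descriptor coefficient matrices of source and
#'   target.
#' @param evals1,evals2 length-`k` eigenvalue vectors.
#' @param alpha Laplacian-commutativity regularisation weight.
#' @return list with `C12`, `C21` (`k x k` matrices) and `backward`, a
#'   function mapping gradients `(dC12, dC21)` to `list(dF, dG)`.
#' @export
fm_layer <- function(Fc, Gc, evals1, evals2, alpha = 1e-2) {
  s12 <- fm_solve(Fc, Gc, evals1, evals2, alpha)
  s21 <- fm_solve(Gc, Fc, evals2, evals1, alpha)
  list(C12 = s12$C, C21 = s21$C,
       backward = function(dC12, dC21) {
         g12 <- fm_solve_backward(s12, dC12)
         g21 <- fm_solve_backward(s21, dC21)
         list(dF = g12$dA + g21$dB, dG = g12$dB + g21$dA)
       })
}

# forward of one direction; caches factors for the adjoint pass
fm_solve <- function(A, B, evals1, evals2, alpha) {
  k1 <- nrow(A); k2 <- nrow(B)
  AAt <- tcrossprod(A)
  ABt <- tcrossprod(A, B)
  C <- matrix(0, k2, k1)
  Minv <- vector("list", k2)
  es <- max(evals1, evals2, 1e-300)
  ev1 <- evals1 / es; ev2 <- evals2 / es
  for (i in seq_len(k2)) {
    M <- AAt + diag(alpha * (ev1 - ev2[i])^2, k1)
    Mi <- tryCatch(solve(M), error = function(e) {
      message("fm_layer: ill-conditioned normal equations, adding ridge jitter")
      solve(M + diag(1e-9 * max(1, mean(diag(M))), k1))
    })
    Minv[[i]] <- Mi
    C[i, ] <- Mi %*% ABt[, i]
  }
  list(C = C, A = A, B = B, Minv = Minv)
}

# adjoint of fm_solve: gradients w.r.t. A and B given dL/dC
fm_solve_backward <- function(s, dC) {
  k2 <- nrow(s$C); k1 <- ncol(s$C)
  U <- matrix(0, k2, k1)
  for (i in seq_len(k2)) U[i, ] <- s$Minv[[i]] %*% dC[i, ]
  dA <- crossprod(U, s$B) - (crossprod(U, s$C) + crossprod(s$C, U)) %*% s$A
  dB <- U %*% s$A
  list(dA = dA, dB = dB)
}

#' Unsupervised structural loss on a pair of functional maps
#'
#' The four-term penalty driving descriptor learning, each assessing a
#' structural property an ideal map pair has: `E1` bijectivity (the two
#' maps invert each other), `E2` orthogonality (local area preservation),
#' `E3` commutativity with the Laplacian (near-isometry), and `E4`
#' commutativity with descriptor multiplication operators (the maps arise
#' from an underlying point map). All terms are nonnegative and vanish
#' exactly at bijective, orthogonal, commuting maps. Analytic gradients
#' with respect to the maps (and the descriptor operators, for `E4`) are
#' returned alongside the values.
#'
#' @param C12,C21 `k x k` functional maps.
#' @param evals1,evals2 length-`k` eigenvalue vectors.
#' @param D1,D2 optional lists of `k x k` descriptor multiplication
#'   operators (one per channel; see [descriptor_operators()]).
#' @param weights length-4 nonnegative loss weights `(w1, w2, w3, w4)`.
#' @return list with `total`, `terms` (named E1-E4), `dC12`, `dC21`, and
#'   (when operators are supplied) `dD1`, `dD2`.
#' @export
surfmnet_loss <- function(C12, C21, evals1, evals2, D1 = NULL, D2 = NULL,
                          weights = c(1e3, 1e3, 1, 1e5)) {
  if (any(weights < 0)) stop("loss weights must be >= 0")
  k <- nrow(C12)
  I <- diag(k)
  R1 <- C12 %*% C21 - I; R2 <- C21 %*% C12 - I
  E1 <- sum(R1^2) + sum(R2^2)
  dC12 <- weights[1] * 2 * (R1 %*% t(C21) + t(C21) %*% R2)
  dC21 <- weights[1] * 2 * (t(C12) %*% R1 + R2 %*% t(C12))
  O1 <- crossprod(C12) - I; O2 <- crossprod(C21) - I
  E2 <- sum(O1^2) + sum(O2^2)
  dC12 <- dC12 + weights[2] * 4 * C12 %*% O1
  dC21 <- dC21 + weights[2] * 4 * C21 %*% O2
  L1 <- evals1[seq_len(k)]; L2 <- evals2[seq_len(k)]
  Q1 <- sweep(C12, 2, L1, `*`) - L2 * C12   # C12 Lam1 - Lam2 C12
  Q2 <- sweep(C21, 2, L2, `*`) - L1 * C21
  E3 <- sum(Q1^2) + sum(Q2^2)
  dC12 <- dC12 + weights[3] * 2 * (sweep(Q1, 2, L1, `*`) - L2 * Q1)
  dC21 <- dC21 + weights[3] * 2 * (sweep(Q2, 2, L2, `*`) - L1 * Q2)
  E4 <- 0
  dD1 <- dD2 <- NULL
  if (!is.null(D1)) {
    nc <- length(D1)
    dD1 <- vector("list", nc); dD2 <- vector("list", nc)
    for (cix in seq_len(nc)) {
      M1 <- D1[[cix]]; M2 <- D2[[cix]]
      Rc <- C12 %*% M1 - M2 %*% C12
      Sc <- C21 %*% M2 - M1 %*% C21
      E4 <- E4 + sum(Rc^2) + sum(Sc^2)
      dC12 <- dC12 + weights[4] * 2 * (Rc %*% t(M1) - t(M2) %*% Rc)
      dC21 <- dC21 + weights[4] * 2 * (Sc %*% t(M2) - t(M1) %*% Sc)
      dD1[[cix]] <- weights[4] * 2 * (t(C12) %*% Rc - Sc %*% t(C21))
      dD2[[cix]] <- weights[4] * 2 * (t(C21) %*% Sc - Rc %*% t(C12))
    }
  }
  terms <- c(E1 = E1, E2 = E2, E3 = E3, E4 = E4)
  list(total = sum(weights * terms), terms = terms,
       dC12 = dC12, dC21 = dC21, dD1 = dD1, dD2 = dD2)
}

#' Descriptor multiplication operators in the reduced basis
#'
#' For each selected descriptor channel `f`, the operator
#' `M = t(Phi_k) %*% A %*% diag(f) %*% Phi_k` expressing pointwise
#' multiplication by `f` in the truncated eigenbasis.
#'
#' @param values `n x d` descriptor matrix.
#' @param basis a `spectral_basis`.
#' @param k truncation order.
#' @param channels integer vector of channel indices (default all).
#' @return list of `k x k` matrices.
#' @export
descriptor_operators <- function(values, basis, k, channels = seq_len(ncol(values))) {
  Phi <- basis$Phi[, seq_len(k), drop = FALSE]
  aPhi <- Phi * basis$a
  lapply(channels, function(cix) crossprod(aPhi, values[, cix] * Phi))
}

#' Epoch iterator over ordered shape pairs
#'
#' One training epoch visits every ordered pair `(i, j)`, `i != j`, exactly
#' once, in a seeded random order; an epoch is complete when each pair has
#' been seen once.
#'
#' @param ids character vector of shape ids (>= 2).
#' @param seed integer seed.
#' @return function `(epoch)` returning the epoch's pair sequence as a
#'   2-column character matrix.
#' @export
pair_sampler <- function(ids, seed = 0) {
  if (length(ids) < 2) stop("need at least 2 shapes")
  all_pairs <- do.call(rbind, lapply(ids, function(i) cbind(i, setdiff(ids, i))))
  function(epoch) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed) + as.integer(epoch) * 1000003L)
    ord <- sample.int(nrow(all_pairs))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    all_pairs[ord, , drop = FALSE]
  }
}

#' Training configuration
#'
#' @param learning_rate ADAM learning rate (default 1e-3).
#' @param batch_size pairs per gradient step (default 1).
#' @param epochs maximum number of epochs.
#' @param seed master seed for initialisation and pair order.
#' @param weights length-4 loss weights.
#' @param k truncation order of the FM layer.
#' @param alpha FM-layer regularisation weight.
#' @param n_desc_e4 number of descriptor channels subsampled per step for
#'   the `E4` term (seeded; keeps the operator cost proportional to a fixed
#'   channel budget).
#' @param conv_tol,conv_window convergence: stop when the relative change of
#'   the epoch loss over `conv_window` epochs falls below `conv_tol`.
#' @return list of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-3, batch_size = 1, epochs = 20,
                            seed = 0, weights = c(1e3, 1e3, 1, 1e5), k = 20,
                            alpha = 1e-2, n_desc_e4 = 15,
                            conv_tol = 1e-3, conv_window = 5) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (any(weights < 0)) stop("loss weights must be >= 0")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, seed = seed, weights = weights, k = k,
                 alpha = alpha, n_desc_e4 = n_desc_e4, conv_tol = conv_tol,
                 conv_window = conv_window),
            class = "training_config")
}

#' Unsupervised descriptor training over a collection
#'
#' Siamese training: per step one ordered pair of shapes is drawn, the
#' extractor produces per-vertex descriptors on both, these are projected
#' to spectral coefficients, the FM layer estimates the map pair, and the
#' structural loss ([surfmnet_loss()]) is backpropagated through the layer
#' and extractor; parameters are updated with ADAM (batch size 1). Training
#' stops at the epoch cap or when the epoch loss plateaus. Entirely seeded:
#' the loss trace is reproducible.
#'
#' @param bases named list of `spectral_basis` (>= `config$k` eigenpairs).
#' @param meshes named list of `surface_mesh` aligned with `bases`.
#' @param extractor an `extractor_contract`.
#' @param config a [training_config()].
#' @return list with `params` (trained parameter vector), `loss_trace`
#'   (per-epoch mean total loss), `term_trace` (epoch x 4 matrix),
#'   `descriptors` (named list of final per-shape descriptor matrices),
#'   `config`.
#' @export
train_descriptors <- function(bases, meshes, extractor, config = training_config()) {
  ids <- names(bases)
  k <- config$k
  feats <- lapply(ids, function(i) extractor$features(meshes[[i]], bases[[i]]))
  names(feats) <- ids
  Phi_k <- lapply(bases, function(b) b$Phi[, seq_len(k), drop = FALSE])
  aPhi_k <- lapply(ids, function(i) Phi_k[[i]] * bases[[i]]$a)
  names(aPhi_k) <- ids
  params <- extractor$init(config$seed)
  adam <- adam_state(length(params))
  sampler <- pair_sampler(ids, seed = config$seed)
  loss_trace <- numeric(0)
  term_trace <- NULL
  best_params <- params
  rng_seed <- as.integer(config$seed) + 777L
  for (epoch in seq_len(config$epochs)) {
    pairs <- sampler(epoch)
    ep_loss <- 0
    ep_terms <- c(E1 = 0, E2 = 0, E3 = 0, E4 = 0)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      fw1 <- extractor$forward(feats[[i]], params)
      fw2 <- extractor$forward(feats[[j]], params)
      A <- crossprod(aPhi_k[[i]], fw1$out)
      B <- crossprod(aPhi_k[[j]], fw2$out)
      lay <- fm_layer(A, B, bases[[i]]$evals[seq_len(k)], bases[[j]]$evals[seq_len(k)],
                      alpha = config$alpha)
      use_e4 <- config$weights[4] > 0 && config$n_desc_e4 > 0
      ch <- NULL; D1 <- D2 <- NULL
      if (use_e4) {
        # channels are a seeded function of the pair so that the epoch loss
        # is a deterministic function of the parameters
        old <- get0(".Random.seed", envir = globalenv())
        set.seed(rng_seed + match(i, ids) * 131071L + match(j, ids))
        ch <- sample.int(ncol(fw1$out), min(config$n_desc_e4, ncol(fw1$out)))
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        D1 <- descriptor_operators(fw1$out, bases[[i]], k, ch)
        D2 <- descriptor_operators(fw2$out, bases[[j]], k, ch)
      }
      ls <- surfmnet_loss(lay$C12, lay$C21, bases[[i]]$evals, bases[[j]]$evals,
                          D1 = D1, D2 = D2, weights = config$weights)
      if (!is.finite(ls$total)) {
        warning("NaN/Inf loss at epoch ", epoch, "; aborting with last-good parameters")
        return(finish_training(best_params, loss_trace, term_trace, feats,
                               extractor, config, ids))
      }
      gb <- lay$backward(ls$dC12, ls$dC21)
      dF1 <- aPhi_k[[i]] %*% gb$dF
      dF2 <- aPhi_k[[j]] %*% gb$dG
      if (use_e4) {
        for (ci in seq_along(ch)) {
          G1 <- Phi_k[[i]] %*% ls$dD1[[ci]]
          dF1[, ch[ci]] <- dF1[, ch[ci]] + bases[[i]]$a * rowSums(G1 * Phi_k[[i]])
          G2 <- Phi_k[[j]] %*% ls$dD2[[ci]]
          dF2[, ch[ci]] <- dF2[, ch[ci]] + bases[[j]]$a * rowSums(G2 * Phi_k[[j]])
        }
      }
      grad <- extractor$backward(fw1$cache, dF1) + extractor$backward(fw2$cache, dF2)
      if (length(params) > 0) {
        upd <- adam_step(adam, grad, config$learning_rate)
        adam <- upd$state
        params <- params - upd$delta
      }
      ep_loss <- ep_loss + ls$total
      ep_terms <- ep_terms + ls$terms
    }
    loss_trace <- c(loss_trace, ep_loss / nrow(pairs))
    term_trace <- rbind(term_trace, ep_terms / nrow(pairs))
    best_params <- params
    w <- config$conv_window
    if (length(loss_trace) > w) {
      recent <- loss_trace[(length(loss_trace) - w):length(loss_trace)]
      if (abs(recent[1] - recent[w + 1]) < config$conv_tol * abs(recent[1])) break
    }
  }
  finish_training(params, loss_trace, term_trace, feats, extractor, config, ids)
}

finish_training <- function(params, loss_trace, term_trace, feats, extractor,
                            config, ids) {
  descs <- lapply(ids, function(i) extractor$forward(feats[[i]], params)$out)
  names(descs) <- ids
  list(params = params, loss_trace = loss_trace, term_trace = term_trace,
       descriptors = descs, config = config)
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(state = state, delta = lr * mhat / (sqrt(vhat) + eps))
}
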