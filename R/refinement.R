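#' Functional map network over a shape collection
#'
#' A directed graph whose nodes are shapes and whose edges carry pairwise
#' functional maps; both directions of every pair are stored. The network
#' also keeps each shape's (truncated) Laplace-Beltrami eigenvalues, which
#' the Limit Shape construction needs.
#'
#' @param maps named list of `functional_map` objects, names `"i->j"` using
#'   shape ids.
#' @param evals named list of eigenvalue vectors, one per shape id.
#' @return object of class `fmap_network` with `ids`, `maps`, `evals`,
#'   `edges` (2-column character matrix).
#' @export
fmap_network <- function(maps, evals) {
  edges <- do.call(rbind, strsplit(names(maps), "->", fixed = TRUE))
  ids <- names(evals)
  if (!all(edges %in% ids)) stop("map endpoints must be named in evals")
  # require both directions
  rev_keys <- paste0(edges[, 2], "->", edges[, 1])
  if (!all(rev_keys %in% names(maps))) stop("every stored edge needs its reverse edge")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (length(setdiff(ids, igraph::V(g)$name)) > 0 || igraph::components(g)$no > 1)
    stop("functional map network must be connected over all shapes")
  structure(list(ids = ids, maps = maps, evals = evals, edges = edges),
            class = "fmap_network")
}

#' @export
print.fmap_network <- function(x, ...) {
  cat(sprintf("<fmap_network: %d shapes, %d directed maps, k = %d>\n",
              length(x$ids), length(x$maps), x$maps[[1]]$k1))
  invisible(x)
}

#' Build a functional map network from descriptors
#'
#' Estimates both directions of every (ordered) pair with [estimate_fmap()]
#' from per-shape descriptor coefficient matrices.
#'
#' @param bases named list of `spectral_basis` (one per shape).
#' @param descs named list of `descriptor_field` (or matrices) aligned with
#'   `bases`.
#' @param k truncation order of the estimated maps.
#' @param alpha regularisation weight passed to [estimate_fmap()].
#' @param pairs `"all"` for all ordered pairs, or `"star"` for a star graph
#'   rooted at the first shape (both directions).
#' @return an `fmap_network`.
#' @export
fmap_network_from_descriptors <- function(bases, descs, k = 20, alpha = 1e-2,
                                          pairs = c("all", "star")) {
  pairs <- match.arg(pairs)
  ids <- names(bases)
  coef <- lapply(ids, function(id) {
    d <- descs[[id]]
    vals <- if (inherits(d, "descriptor_field")) d$values else as.matrix(d)
    project(vals, bases[[id]])[seq_len(k), , drop = FALSE]
  })
  names(coef) <- ids
  pair_list <- if (pairs == "all") {
    do.call(rbind, lapply(ids, function(i) cbind(i, setdiff(ids, i))))
  } else {
    root <- ids[1]
    rbind(cbind(root, ids[-1]), cbind(ids[-1], root))
  }
  maps <- list()
  for (r in seq_len(nrow(pair_list))) {
    i <- pair_list[r, 1]; j <- pair_list[r, 2]
    maps[[paste0(i, "->", j)]] <- estimate_fmap(
      coef[[i]], coef[[j]],
      bases[[i]]$evals[seq_len(k)], bases[[j]]$evals[seq_len(k)],
      alpha = alpha, source_id = i, target_id = j)
  }
  evals <- lapply(bases, function(b) b$evals)
  fmap_network(maps, evals)
}

#' Limit shape: canonical consistent latent basis of a collection
#'
#' Computes latent maps `Y_i` (one per shape) into a shared "limit shape"
#' functional space, such that every stored map is approximately realised
#' through the latent space: `C_ij ~ Y_j pinv(Y_i)`. The `Y_i` are the
#' smallest eigenvectors of the map-consistency matrix (blocks
#' `H_ii += t(C_ij) C_ij`, `H_jj += I`, `H_ij -= t(C_ij)`, `H_ji -= C_ij`
#' over directed edges), stacked and normalised so that
#' `sum_i t(Y_i) Y_i = N I`. They are then canonicalised by diagonalising
#' the average pulled-back Laplacian `(1/N) sum_i t(Y_i) L_i Y_i`, whose
#' ascending eigenvalues are the latent spectrum `Lambda0` — for a
#' collection of copies of one shape this reproduces that shape's own
#' eigenvalues and all `Y_i` coincide.
#'
#' @param fmn an `fmap_network`.
#' @param k map order at which to read the stored maps (rows/cols truncated
#'   to `k`).
#' @param k_latent latent dimension (default `k`; reduced automatically with
#'   a warning on rank collapse).
#' @return object of class `limit_shape`: list with `Y` (named list of
#'   `k x k_latent` matrices), `evals0` (latent eigenvalues), `k`,
#'   `k_latent`, `residuals` (named per-edge relative consistency
#'   residuals).
#' @export
compute_limit_shape <- function(fmn, k, k_latent = k) {
  ids <- fmn$ids
  N <- length(ids)
  pos <- stats::setNames(seq_along(ids), ids)
  H <- matrix(0, N * k, N * k)
  blk <- function(i) ((pos[[i]] - 1) * k + 1):(pos[[i]] * k)
  for (key in names(fmn$maps)) {
    m <- fmn$maps[[key]]
    Cij <- m$C[seq_len(k), seq_len(k), drop = FALSE]
    bi <- blk(m$source_id); bj <- blk(m$target_id)
    H[bi, bi] <- H[bi, bi] + crossprod(Cij)
    H[bj, bj] <- H[bj, bj] + diag(k)
    H[bi, bj] <- H[bi, bj] - t(Cij)
    H[bj, bi] <- H[bj, bi] - Cij
  }
  H <- (H + t(H)) / 2
  es <- eigen(H, symmetric = TRUE)
  idx <- order(es$values)[seq_len(k_latent)]
  Yst <- es$vectors[, idx, drop = FALSE]
  # deterministic signs
  sgn <- apply(Yst, 2, function(col) sign(col[which.max(abs(col))]))
  Yst <- sweep(Yst, 2, sgn, `*`) * sqrt(N)   # sum_i t(Y_i) Y_i = N I
  Y <- lapply(ids, function(i) Yst[blk(i), , drop = FALSE])
  names(Y) <- ids
  # rank check
  minsv <- min(vapply(Y, function(Yi) min(svd(Yi, nu = 0, nv = 0)$d), 0))
  if (minsv < 1e-8) {
    warning("latent basis rank collapse; reducing k_latent")
    keep <- seq_len(max(1L, k_latent - 1L))
    Y <- lapply(Y, function(Yi) Yi[, keep, drop = FALSE])
    k_latent <- length(keep)
  }
  # canonicalisation: diagonalise the average pulled-back Laplacian
  E <- matrix(0, k_latent, k_latent)
  for (i in ids) {
    li <- fmn$evals[[i]][seq_len(k)]
    E <- E + crossprod(Y[[i]], li * Y[[i]])
  }
  E <- (E + t(E)) / (2 * N)
  ce <- eigen(E, symmetric = TRUE)
  ord <- order(ce$values)
  U <- ce$vectors[, ord, drop = FALSE]
  usgn <- apply(U, 2, function(col) sign(col[which.max(abs(col))]))
  U <- sweep(U, 2, usgn, `*`)
  evals0 <- pmax(ce$values[ord], 0)
  Y <- lapply(Y, function(Yi) Yi %*% U)
  residuals <- vapply(names(fmn$maps), function(key) {
    m <- fmn$maps[[key]]
    Cij <- m$C[seq_len(k), seq_len(k), drop = FALSE]
    Yi <- Y[[m$source_id]]; Yj <- Y[[m$target_id]]
    pred <- Yj %*% MASS::ginv(Yi)
    norm(Cij - pred, "F") / max(norm(Cij, "F"), 1e-12)
  }, 0)
  structure(list(Y = Y, evals0 = evals0, k = k, k_latent = k_latent,
                 residuals = residuals),
            class = "limit_shape")
}

#' @export
print.limit_shape <- function(x, ...) {
  cat(sprintf("<limit_shape: %d shapes, k = %d, k_latent = %d, mean residual %.4f>\n",
              length(x$Y), x$k, x$k_latent, mean(x$residuals)))
  invisible(x)
}

#' Consistent ZoomOut refinement of a map collection
#'
#' Iteratively refines all maps in the network jointly, from spectral
#' resolution `k_init` up to `k_final`: at each scale (1) the limit shape is
#' recomputed from the current maps, (2) every shape's vertices are embedded
#' in the shared latent coordinates (`Phi_i %*% Y_i`) and new point-to-point
#' maps are recovered by exact nearest neighbours in that common space, and
#' (3) the maps are re-expressed as functional maps at the next, larger
#' truncation via [p2p_to_fmap()]. Unlike pairwise refinement this treats
#' the whole collection symmetrically — no source/target bias — and tends
#' to increase bijective coverage.
#'
#' @param fmn an `fmap_network` (maps at order >= `k_init`).
#' @param bases named list of `spectral_basis` computed to >= `k_final`.
#' @param k_init,k_final,step refinement schedule (defaults 20, 70, 5).
#' @return list with `fmn` (refined network at `k_final`), `p2p` (named list
#'   of `point_map` at the final scale), `limit_shape` (final
#'   `limit_shape`), `coverage_before`, `coverage_after` (named vectors),
#'   `residual_trace` (mean latent consistency residual per scale).
#' @export
consistent_zoomout <- function(fmn, bases, k_init = 20, k_final = 70, step = 5) {
  if (k_final > min(vapply(bases, function(b) as.integer(b$k), 0L)))
    stop("bases must be computed to at least k_final")
  if (k_init > k_final) stop("k_init must be <= k_final")
  keys <- names(fmn$maps)
  ends <- do.call(rbind, strsplit(keys, "->", fixed = TRUE))
  coverage_before <- vapply(keys, function(key) {
    m <- fmn$maps[[key]]
    pm <- fmap_to_p2p(functional_map(m$C[seq_len(k_init), seq_len(k_init), drop = FALSE],
                                     m$source_id, m$target_id),
                      bases[[m$source_id]], bases[[m$target_id]])
    as.numeric(pm$coverage)
  }, 0)
  residual_trace <- numeric(0)
  k <- k_init
  cur <- fmn
  repeat {
    ls <- compute_limit_shape(cur, k = k)
    residual_trace <- c(residual_trace, mean(ls$residuals))
    emb <- lapply(cur$ids, function(i)
      bases[[i]]$Phi[, seq_len(k), drop = FALSE] %*% ls$Y[[i]])
    names(emb) <- cur$ids
    k_next <- min(k + step, k_final)
    p2p <- list()
    maps <- list()
    for (r in seq_len(nrow(ends))) {
      i <- ends[r, 1]; j <- ends[r, 2]
      Tvec <- nn_index(emb[[i]], emb[[j]])
      pm <- point_map(Tvec, n_target = nrow(emb[[j]]), source_id = i, target_id = j)
      p2p[[keys[r]]] <- pm
      maps[[keys[r]]] <- p2p_to_fmap(pm, bases[[i]], bases[[j]], k = k_next)
    }
    cur <- fmap_network(maps, fmn$evals)
    if (k >= k_final) break
    k <- k_next
  }
  coverage_after <- vapply(keys, function(key) as.numeric(p2p[[key]]$coverage), 0)
  ls_final <- compute_limit_shape(cur, k = k_final)
  residual_trace <- c(residual_trace, mean(ls_final$residuals))
  reg <- coverage_after < coverage_before - 0.2
  if (any(reg))
    warning("coverage regression > 20% on pairs: ", paste(keys[reg], collapse = ", "))
  list(fmn = cur, p2p = p2p, limit_shape = ls_final,
       coverage_before = coverage_before, coverage_after = coverage_after,
       residual_trace = residual_trace)
}
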