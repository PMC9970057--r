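#' Rigidly prealign a mesh collection to a common frame
#'
#' A lightweight rigid aligner for collections whose specimens arrive in
#' arbitrary poses: each mesh is centred and rotated onto its principal
#' axes (signs disambiguated by the third central moment along each axis,
#' determinant fixed to +1), then polished by point-to-plane ICP against the
#' first specimen. Only rotations and translations are applied, so
#' intrinsic geometry — every pairwise vertex distance — is untouched.
#' Collections aligned upstream by an external Procrustes tool can skip
#' this step entirely.
#'
#' @param collection list of unit-area `surface_mesh` objects (>= 2).
#' @param seed integer seed (kept for interface stability; the procedure is
#'   deterministic).
#' @param max_iter maximum ICP iterations per mesh.
#' @param tol RMS-change convergence tolerance.
#' @return list of aligned `surface_mesh` objects, same order and ids.
#' @export
rigid_prealign <- function(collection, seed = 0, max_iter = 30, tol = 1e-8) {
  if (length(collection) < 2) stop("need at least 2 meshes to prealign")
  areas <- vapply(collection, mesh_area, 0)
  if (any(abs(areas - 1) > 1e-3))
    stop("meshes must be unit-area before prealignment (see normalize_unit_area)")
  aligned <- lapply(collection, principal_axes_align)
  ref <- aligned[[1]]
  ref_nrm <- vertex_normals(ref)
  for (i in seq_along(aligned)[-1]) {
    res <- icp_point_to_plane(aligned[[i]], ref, ref_nrm, max_iter = max_iter, tol = tol)
    if (!res$converged)
      warning(sprintf("ICP did not converge for mesh %d ('%s'); returning principal-axes alignment",
                      i, aligned[[i]]$id))
    aligned[[i]] <- res$mesh
  }
  aligned
}

principal_axes_align <- function(mesh) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  ev <- eigen(crossprod(vc) / nrow(vc), symmetric = TRUE)
  R <- ev$vectors[, order(ev$values, decreasing = TRUE)]
  x <- vc %*% R
  # sign disambiguation: positive third central moment along each axis
  s <- sign(colSums(x^3)); s[s == 0] <- 1
  R <- R %*% diag(s)
  if (det(R) < 0) R[, 3] <- -R[, 3]
  mesh$vertices <- vc %*% R
  mesh
}

icp_point_to_plane <- function(mesh, ref, ref_nrm, max_iter = 30, tol = 1e-8) {
  v <- mesh$vertices
  prev_rms <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    nn <- nn_index(v, ref$vertices)
    q <- ref$vertices[nn, , drop = FALSE]
    nq <- ref_nrm[nn, , drop = FALSE]
    b <- -rowSums((v - q) * nq)
    a <- cbind(v[, 2] * nq[, 3] - v[, 3] * nq[, 2],
               v[, 3] * nq[, 1] - v[, 1] * nq[, 3],
               v[, 1] * nq[, 2] - v[, 2] * nq[, 1],
               nq)
    x <- tryCatch(solve(crossprod(a), crossprod(a, b)),
                  error = function(e) rep(0, 6))
    R <- rodrigues(x[1:3])
    v <- v %*% t(R) + matrix(x[4:6], nrow(v), 3, byrow = TRUE)
    rms <- sqrt(mean(b^2))
    if (abs(prev_rms - rms) < tol) { converged <- TRUE; break }
    prev_rms <- rms
  }
  mesh$vertices <- v
  list(mesh = mesh, converged = converged)
}

rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  ax <- w / th
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Exact nearest-neighbour indices between point sets
#'
#' For each row of `x`, the index of the closest row of `y` in Euclidean
#' distance, computed exactly by blocked dense distance evaluation (ties
#' broken by lowest index). Exactness matters here: point-to-point map
#' recovery is defined as an exact nearest-neighbour assignment and is
#' tested against brute-force enumeration.
#'
#' @param x query matrix (rows = points).
#' @param y reference matrix with the same number of columns.
#' @param block rows of `x` processed per dense block.
#' @return integer vector of `nrow(x)` indices into rows of `y`.
#' @export
nn_index <- function(x, y, block = 2048L) {
  x <- as.matrix(x); y <- as.matrix(y)
  ny2 <- rowSums(y^2)
  out <- integer(nrow(x))
  for (s in seq(1L, nrow(x), by = block)) {
    e <- min(s + block - 1L, nrow(x))
    xb <- x[s:e, , drop = FALSE]
    d2 <- outer(rowSums(xb^2), ny2, `+`) - 2 * tcrossprod(xb, y)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}
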