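#' Estimate a functional map from descriptor coefficients
#'
#' Solves the regularised least-squares problem
#' `C = argmin ||C A - B||_F^2 + alpha ||C L1 - L2 C||_F^2`
#' where `A`/`B` are the spectral coefficients of corresponding descriptors
#' on source and target and `L1`/`L2` are the diagonal eigenvalue matrices.
#' The Laplacian-commutativity term decouples row-wise, so each row `i` of
#' `C` has the closed form solution of
#' `(A A^T + alpha diag((l1_j - l2_i)^2)) c_i = A B_i^T`.
#' Eigenvalues are normalised by their joint maximum inside the regulariser
#' so that `alpha` is independent of mesh scale and truncation.
#'
#' @param A `k1 x d` source coefficient matrix (see [project()]).
#' @param B `k2 x d` target coefficient matrix.
#' @param evals1,evals2 eigenvalues of the source/target bases (lengths
#'   `k1`, `k2`).
#' @param alpha nonnegative commutativity-regularisation weight.
#' @param source_id,target_id optional ids stored on the result.
#' @return object of class `functional_map`: list with `C` (`k2 x k1`),
#'   `source_id`, `target_id`, `k1`, `k2`.
#' @export
estimate_fmap <- function(A, B, evals1, evals2, alpha = 1e-2,
                          source_id = NULL, target_id = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  k1 <- nrow(A); k2 <- nrow(B)
  if (ncol(A) != ncol(B)) stop("A and B must have the same number of descriptor channels")
  if (alpha < 0) stop("alpha must be >= 0")
  if (ncol(A) < k1) warning("fewer descriptor channels than basis functions; system may be underdetermined")
  AAt <- tcrossprod(A)
  ABt <- tcrossprod(A, B)  # k1 x k2; column i is A B_i^T
  C <- matrix(0, k2, k1)
  # eigenvalues normalised by their joint maximum so that alpha is scale-free
  es <- max(evals1, evals2, 1e-300)
  ev1 <- evals1 / es; ev2 <- evals2 / es
  for (i in seq_len(k2)) {
    M <- AAt
    if (alpha > 0) {
      dg <- alpha * (ev1 - ev2[i])^2
      M <- M + diag(dg, k1)
    }
    ci <- tryCatch(solve(M, ABt[, i]), error = function(e) {
      warning("singular normal equations; using least-norm solution")
      as.numeric(MASS::ginv(M) %*% ABt[, i])
    })
    C[i, ] <- ci
  }
  functional_map(C, source_id = source_id, target_id = target_id)
}

functional_map <- function(C, source_id = NULL, target_id = NULL) {
  structure(list(C = C, source_id = source_id, target_id = target_id,
                 k1 = ncol(C), k2 = nrow(C)),
            class = "functional_map")
}

#' @export
print.functional_map <- function(x, ...) {
  cat(sprintf("<functional_map %s -> %s: %d x %d, C[1,1] = %.4f>\n",
              x$source_id %||% "?", x$target_id %||% "?", x$k2, x$k1, x$C[1, 1]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Recover a point-to-point map from a functional map
#'
#' Each source vertex is embedded as the corresponding row of
#' `Phi_src %*% t(C)` (its delta function expressed in the target spectral
#' coordinates) and assigned the exact nearest row of `Phi_tgt`; ties break
#' to the lowest index. Also records both readings of bijective coverage
#' (see [coverage()]).
#'
#' @param C a `functional_map` (or bare `k2 x k1` matrix).
#' @param basis_src,basis_tgt the `spectral_basis` of source and target.
#' @return object of class `point_map`: list with `T` (length `n1` integer
#'   vector of target vertex indices), `coverage`, `source_id`, `target_id`.
#' @export
fmap_to_p2p <- function(C, basis_src, basis_tgt) {
  Cm <- if (inherits(C, "functional_map")) C$C else C
  k1 <- ncol(Cm); k2 <- nrow(Cm)
  if (k1 > basis_src$k || k2 > basis_tgt$k) stop("C dimensions exceed basis truncations")
  src_emb <- basis_src$Phi[, seq_len(k1), drop = FALSE] %*% t(Cm)
  tgt_emb <- basis_tgt$Phi[, seq_len(k2), drop = FALSE]
  Tvec <- nn_index(src_emb, tgt_emb)
  point_map(Tvec, n_target = nrow(tgt_emb),
            source_id = if (inherits(C, "functional_map")) C$source_id else NULL,
            target_id = if (inherits(C, "functional_map")) C$target_id else NULL)
}

point_map <- function(Tvec, n_target, source_id = NULL, target_id = NULL) {
  cov <- coverage(Tvec, n_target)
  structure(list(T = as.integer(Tvec), n_target = as.integer(n_target),
                 coverage = cov, source_id = source_id, target_id = target_id),
            class = "point_map")
}

#' @export
print.point_map <- function(x, ...) {
  cat(sprintf("<point_map %s -> %s: n = %d, coverage = %.3f (image reading %.3f)>\n",
              x$source_id %||% "?", x$target_id %||% "?", length(x$T),
              x$coverage, attr(x$coverage, "image_coverage")))
  invisible(x)
}

#' Bijective coverage of a point-to-point map
#'
#' The implemented reading is the fraction of source points whose target
#' vertex is not claimed by any other source point (unique-preimage
#' fraction): 1 for a bijection, 0 when everything collapses to one vertex.
#' The alternative image reading `|unique(T)| / n_target` is returned as
#' attribute `"image_coverage"`.
#'
#' @param T integer vector of target indices (or a `point_map`).
#' @param n_target number of target vertices.
#' @return scalar coverage in `[0, 1]` with attribute `image_coverage`.
#' @export
coverage <- function(T, n_target = NULL) {
  if (inherits(T, "point_map")) { n_target <- T$n_target; T <- T$T }
  dup <- duplicated(T) | duplicated(T, fromLast = TRUE)
  out <- mean(!dup)
  attr(out, "image_coverage") <- length(unique(T)) / n_target
  out
}

#' Convert a point-to-point map to a functional map
#'
#' Given `T` mapping source vertices to target vertices, forms the 0/1
#' matrix `Pi` with `Pi[q, p] = 1` iff `T(p) = q` and returns
#' `C = t(Phi_tgt) %*% A_tgt %*% Pi %*% Phi_src` truncated to `k x k` — the
#' spectral expression of the pointwise correspondence, used to lift refined
#' point maps back to functional maps at a higher truncation.
#'
#' @param T a `point_map` (or integer vector of target indices).
#' @param basis_src,basis_tgt source and target `spectral_basis`.
#' @param k output truncation (<= both basis truncations).
#' @param source_id,target_id ids stored on the result (taken from `T` when
#'   it is a `point_map`).
#' @return a `functional_map` with `C` of size `k x k`.
#' @export
p2p_to_fmap <- function(T, basis_src, basis_tgt, k, source_id = NULL,
                        target_id = NULL) {
  sid <- source_id; tid <- target_id
  if (inherits(T, "point_map")) { sid <- T$source_id; tid <- T$target_id; T <- T$T }
  if (k > basis_src$k || k > basis_tgt$k) stop("k exceeds basis truncation")
  M <- basis_tgt$Phi[, seq_len(k), drop = FALSE] * basis_tgt$a  # A_tgt Phi_tgt
  C <- crossprod(M[T, , drop = FALSE], basis_src$Phi[, seq_len(k), drop = FALSE])
  functional_map(C, source_id = sid, target_id = tid)
}

#' Construct the exact functional map of a known vertex bijection
#'
#' For ground-truth correspondences on fixtures: the least-squares spectral
#' representation `C = Phi_tgt^+ Pi Phi_src` of the permutation `T`,
#' computed with the mass-weighted pseudoinverse (equals [p2p_to_fmap()] for
#' A-orthonormal bases; kept separate for clarity in tests).
#'
#' @inheritParams p2p_to_fmap
#' @return a `functional_map`.
#' @export
gt_fmap <- function(T, basis_src, basis_tgt, k, source_id = NULL,
                    target_id = NULL)
  p2p_to_fmap(T, basis_src, basis_tgt, k, source_id, target_id)
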