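#' Cotangent Laplace-Beltrami discretisation
#'
#' Builds the standard first-order finite-element discretisation of the
#' Laplace-Beltrami operator on a triangular mesh: the symmetric cotangent
#' stiffness matrix `W` (off-diagonal entry `-(cot a + cot b)/2` per edge,
#' zero row sums) and the lumped barycentric mass matrix `A` (one third of
#' the incident triangle area per vertex, so `sum(diag(A))` equals the total
#' surface area). Cotangents of near-degenerate triangles are clamped to
#' `|cot| <= clamp` since scanned surfaces routinely contain slivers.
#'
#' @param mesh a `surface_mesh`.
#' @param clamp cotangent magnitude clamp (default `1e4`).
#' @return list with sparse matrices `stiffness` (`dgCMatrix`) and `mass`
#'   (diagonal `ddiMatrix`).
#' @export
build_laplacian <- function(mesh, clamp = 1e4) {
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(v)
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  e1 <- v[i3, , drop = FALSE] - v[i2, , drop = FALSE]  # opposite vertex 1
  e2 <- v[i1, , drop = FALSE] - v[i3, , drop = FALSE]
  e3 <- v[i2, , drop = FALSE] - v[i1, , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  dbl_area <- sqrt(rowSums(cr(e3, -e2)^2))  # 2 * triangle area
  cot1 <- rowSums(-e2 * e3) / dbl_area      # angle at vertex 1, opposite edge e1
  cot2 <- rowSums(-e3 * e1) / dbl_area
  cot3 <- rowSums(-e1 * e2) / dbl_area
  nclamped <- sum(abs(c(cot1, cot2, cot3)) > clamp)
  if (nclamped > 0) message(sprintf("build_laplacian: clamped %d cotangent(s)", nclamped))
  cl <- function(x) pmin(pmax(x, -clamp), clamp)
  cot1 <- cl(cot1); cot2 <- cl(cot2); cot3 <- cl(cot3)
  # off-diagonal contributions: half-cotangent of the opposite angle
  ii <- c(i2, i3, i3, i1, i1, i2)
  jj <- c(i3, i2, i1, i3, i2, i1)
  xx <- 0.5 * c(cot1, cot1, cot2, cot2, cot3, cot3)
  Wo <- Matrix::sparseMatrix(i = ii, j = jj, x = -xx, dims = c(n, n))
  W <- Wo - Matrix::Diagonal(n, x = Matrix::rowSums(Wo))
  areas <- dbl_area / 2
  a_diag <- (tapply_sum(areas, i1, n) + tapply_sum(areas, i2, n) +
             tapply_sum(areas, i3, n)) / 3
  list(stiffness = methods::as(W, "CsparseMatrix"),
       mass = Matrix::Diagonal(n, x = a_diag))
}

#' Truncated Laplace-Beltrami eigenbasis
#'
#' Solves the generalised symmetric eigenproblem `W phi = lambda A phi` for
#' the `k` smallest eigenpairs and packages them as a `spectral_basis`:
#' eigenfunctions `Phi` (A-orthonormal columns, first one constant
#' `1/sqrt(area)`), ascending eigenvalues, and the mass/stiffness matrices.
#' Small problems use a dense solver on the mass-normalised operator; larger
#' ones use ARPACK (via [igraph::arpack()]) in shift-invert mode, retried
#' with a larger Krylov subspace on non-convergence. Eigenfunction signs are
#' fixed by making each column's largest-magnitude entry positive.
#'
#' @param stiffness,mass matrices from [build_laplacian()].
#' @param k truncation order (number of eigenpairs, `k < n`).
#' @param dense_cutoff use the dense path when `n` is at most this.
#' @return object of class `spectral_basis` with elements `Phi` (n x k),
#'   `evals` (length k), `mass`, `stiffness`, `k`, `a` (mass diagonal).
#' @export
eigendecompose <- function(stiffness, mass, k, dense_cutoff = 900L) {
  n <- nrow(stiffness)
  if (k >= n) stop("k must be < number of vertices")
  a <- Matrix::diag(mass)
  inv_sqrt_a <- 1 / sqrt(a)
  if (n <= dense_cutoff) {
    B <- as.matrix(stiffness) * outer(inv_sqrt_a, inv_sqrt_a)
    B <- (B + t(B)) / 2
    es <- eigen(B, symmetric = TRUE)
    idx <- order(es$values)[seq_len(k)]
    evals <- es$values[idx]
    Phi <- es$vectors[, idx, drop = FALSE] * inv_sqrt_a
  } else {
    scale_ref <- mean(Matrix::diag(stiffness)) / mean(a)
    eps <- 1e-8 * scale_ref
    K <- stiffness + eps * mass
    ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(K), "CsparseMatrix"),
                           LDL = FALSE, perm = TRUE)
    sqrt_a <- sqrt(a)
    matvec <- function(x, extra = NULL) {
      z <- sqrt_a * x
      u <- as.numeric(Matrix::solve(ch, z, system = "A"))
      sqrt_a * u
    }
    res <- arpack_try(matvec, n, k)
    theta <- res$values
    evals <- 1 / theta - eps
    ordi <- order(evals)
    evals <- evals[ordi]
    Phi <- (res$vectors[, ordi, drop = FALSE]) * inv_sqrt_a
  }
  evals[evals < 0 & evals > -1e-8 * max(abs(evals))] <- 0
  # A-orthonormalise exactly and fix signs
  nrm <- sqrt(colSums(Phi^2 * a))
  Phi <- sweep(Phi, 2, nrm, `/`)
  sgn <- apply(Phi, 2, function(col) sign(col[which.max(abs(col))]))
  Phi <- sweep(Phi, 2, sgn, `*`)
  structure(list(Phi = Phi, evals = evals, mass = mass, stiffness = stiffness,
                 k = k, a = a),
            class = "spectral_basis")
}

arpack_try <- function(matvec, n, k) {
  for (ncv in unique(pmin(n, c(max(2 * k + 10, 40), max(4 * k + 20, 80))))) {
    res <- tryCatch(
      igraph::arpack(matvec, sym = TRUE,
                     options = list(n = n, nev = k, ncv = ncv, which = "LA",
                                    maxiter = 3000)),
      error = function(e) e)
    if (!inherits(res, "error")) return(res)
  }
  stop("eigensolver failed to converge: ", conditionMessage(res))
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis: n = %d, k = %d, eigenvalue range [%.4g, %.4g]>\n",
              nrow(x$Phi), x$k, min(x$evals), max(x$evals)))
  invisible(x)
}

#' Compute the spectral basis of a mesh
#'
#' Convenience wrapper: [build_laplacian()] followed by [eigendecompose()].
#'
#' @param mesh a `surface_mesh`.
#' @param k truncation order.
#' @param ... passed to [eigendecompose()].
#' @return a `spectral_basis`.
#' @export
spectral_basis <- function(mesh, k = 70, ...) {
  lap <- build_laplacian(mesh)
  eigendecompose(lap$stiffness, lap$mass, k = k, ...)
}

#' Project a vertex function onto a spectral basis
#'
#' Mass-weighted projection `t(Phi) %*% A %*% field`, giving the
#' coefficients of the function in the truncated eigenbasis; `reconstruct()`
#' maps coefficients back to vertex values (`Phi %*% coeffs`), and the
#' composition is the A-orthogonal projector onto the basis span.
#'
#' @param field `n x d` matrix (or length-n vector) of function values.
#' @param basis a `spectral_basis`.
#' @return `project()`: `k x d` coefficient matrix; `reconstruct()`:
#'   `n x d` vertex-value matrix.
#' @export
project <- function(field, basis) {
  field <- as.matrix(field)
  if (nrow(field) != nrow(basis$Phi)) stop("field row count must equal vertex count")
  crossprod(basis$Phi, field * basis$a)
}

#' @rdname project
#' @param coeffs `k x d` coefficient matrix.
#' @export
reconstruct <- function(coeffs, basis) basis$Phi %*% as.matrix(coeffs)
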