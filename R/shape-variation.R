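#' Latent shape-space difference operators
#'
#' For each shape `i` with latent map `Y_i` (see [compute_limit_shape()]),
#' computes the two shape-difference operators relative to the limit shape,
#' expressed in the canonical consistent latent basis:
#' the area-based operator `D_area = t(Y_i) Y_i` (the Gram matrix of the
#' latent functions under shape `i`'s mass inner product — how local area
#' distorts), and the conformal operator
#' `D_conf = pinv(Lambda0) t(Y_i) Lambda_i Y_i` (the Dirichlet-energy Gram
#' whitened by the latent spectrum — how angles distort, independent of
#' area). Latent modes with `Lambda0` below `tol` (the constant mode) carry
#' no Dirichlet energy and their distortion ratio is defined as 1, so the
#' corresponding `D_conf` rows are identity rows. `D_conf` is returned
#' symmetrised; for an exactly isometric collection both operators equal
#' the identity.
#'
#' @param emb a `limit_shape`.
#' @param evals named list of per-shape eigenvalue vectors (e.g.
#'   `fmn$evals`); truncated to `emb$k`.
#' @param tol threshold below which latent eigenvalues count as zero.
#' @return named list of `shape_difference` objects, each with `D_area`,
#'   `D_conf`, `shape_id`.
#' @export
latent_shape_differences <- function(emb, evals, tol = 1e-12) {
  k <- emb$k
  lam0 <- emb$evals0
  zero <- lam0 < tol
  inv0 <- ifelse(zero, 0, 1 / pmax(lam0, tol))
  out <- lapply(names(emb$Y), function(id) {
    Yi <- emb$Y[[id]]
    D_area <- crossprod(Yi)
    D_area <- (D_area + t(D_area)) / 2
    li <- evals[[id]][seq_len(k)]
    M <- inv0 * crossprod(Yi, li * Yi)
    M[zero, ] <- 0
    M[cbind(which(zero), which(zero))] <- 1
    D_conf <- (M + t(M)) / 2
    structure(list(D_area = D_area, D_conf = D_conf, shape_id = id),
              class = "shape_difference")
  })
  names(out) <- names(emb$Y)
  out
}

#' @export
print.shape_difference <- function(x, ...) {
  k <- nrow(x$D_area)
  cat(sprintf("<shape_difference '%s': k_latent = %d, tr(D_area) = %.3f, tr(D_conf) = %.3f>\n",
              x$shape_id, k, sum(diag(x$D_area)), sum(diag(x$D_conf))))
  invisible(x)
}

#' LSSD feature matrix
#'
#' Flattens each shape's difference operator(s) into one row of shape
#' variables: `k_latent^2` features per kind. For `kind = "combined"` the
#' two kinds are standardised per feature (zero-variance columns left at 0)
#' and concatenated.
#'
#' @param ops list of `shape_difference` objects (uniform `k_latent`).
#' @param kind `"area"`, `"conformal"` or `"combined"`.
#' @return numeric matrix, shapes x features, row names = shape ids.
#' @export
lssd_matrix <- function(ops, kind = c("area", "conformal", "combined")) {
  kind <- match.arg(kind)
  ks <- vapply(ops, function(o) nrow(o$D_area), 0L)
  if (length(unique(ks)) != 1) stop("mixed k_latent across shapes")
  flat <- function(field) t(vapply(ops, function(o) as.vector(o[[field]]),
                                   numeric(ks[1]^2)))
  out <- switch(kind,
    area = flat("D_area"),
    conformal = flat("D_conf"),
    combined = cbind(std_cols(flat("D_area")), std_cols(flat("D_conf"))))
  rownames(out) <- vapply(ops, function(o) o$shape_id, "")
  out
}

std_cols <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  # (numerically) constant columns map to 0 rather than amplified noise
  const <- !is.finite(sd) | sd <= 1e-10 * pmax(abs(mu), 1)
  sd[const] <- Inf
  sweep(sweep(X, 2, mu), 2, sd, `/`)
}

#' Weighted distinctive functions between two groups
#'
#' Localises where intrinsic distortion differs most between two groups of
#' shapes, directly on a display surface: the group-mean difference
#' operators are subtracted (`V = Dbar_G1 - Dbar_G2`), `V` is
#' eigen-decomposed, the top-`m` latent eigenfunctions are realised on the
#' display shape via `Phi_display %*% Y_display`, and the field is the
#' eigenvalue-magnitude-weighted sum of their squares, max-normalised to
#' `[0, 1]`. The field is symmetric in the group order by construction.
#'
#' @param ops named list of `shape_difference` (all shapes).
#' @param emb the `limit_shape` used to compute `ops`.
#' @param bases named list of `spectral_basis`.
#' @param display_shape_id id of the shape to display the field on.
#' @param groups named group labels (factor or character, names = shape
#'   ids); exactly the two labels in `group_pair` are used.
#' @param group_pair length-2 vector of group labels to contrast.
#' @param kind `"area"` or `"conformal"`.
#' @param m number of eigencomponents (default 10).
#' @return object of class `distinctive_function`: list with `field`
#'   (per-vertex values in `[0,1]`), `kind`, `group_pair`, `display_shape_id`,
#'   `eigenvalues`.
#' @export
distinctive_functions <- function(ops, emb, bases, display_shape_id, groups,
                                  group_pair = NULL, kind = c("area", "conformal"),
                                  m = 10) {
  kind <- match.arg(kind)
  groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(group_pair)) group_pair <- unique(groups)[1:2]
  g1 <- names(groups)[groups == group_pair[1]]
  g2 <- names(groups)[groups == group_pair[2]]
  if (length(g1) < 2 || length(g2) < 2) stop("each group needs at least 2 shapes")
  field_name <- if (kind == "area") "D_area" else "D_conf"
  mean_op <- function(idv) Reduce(`+`, lapply(ops[idv], `[[`, field_name)) / length(idv)
  V <- mean_op(g1) - mean_op(g2)
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  ord <- order(abs(ev$values), decreasing = TRUE)[seq_len(min(m, ncol(V)))]
  mu <- ev$values[ord]
  vecs <- ev$vectors[, ord, drop = FALSE]
  Yd <- emb$Y[[display_shape_id]]
  Phi <- bases[[display_shape_id]]$Phi[, seq_len(emb$k), drop = FALSE]
  funcs <- Phi %*% (Yd %*% vecs)          # n x m transferred latent functions
  field <- as.numeric(funcs^2 %*% abs(mu))
  # numerically-zero fields (identical groups) stay exactly zero rather than
  # being max-normalised into noise
  if (max(field) > 1e-10) field <- field / max(field) else field[] <- 0
  structure(list(field = field, kind = kind, group_pair = group_pair,
                 display_shape_id = display_shape_id, eigenvalues = mu),
            class = "distinctive_function")
}

#' @export
print.distinctive_function <- function(x, ...) {
  cat(sprintf("<distinctive_function (%s) %s vs %s on '%s': %d vertices>\n",
              x$kind, x$group_pair[1], x$group_pair[2], x$display_shape_id,
              length(x$field)))
  invisible(x)
}
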