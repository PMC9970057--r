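#' Run the full landmark-free shape-analysis pipeline on a collection
#'
#' Convenience wrapper chaining the pipeline stages: unit-area
#' normalisation, spectral bases, point descriptors (axiomatic WKS by
#' default, or descriptors learned unsupervised when `learn = TRUE`),
#' pairwise functional-map estimation, collection-wide Consistent ZoomOut
#' refinement, and latent shape-space difference (LSSD) extraction.
#'
#' @param meshes named list of `surface_mesh` objects (a collection).
#' @param groups optional named group labels (for downstream analyses;
#'   stored on the result).
#' @param k_init,k_final,step refinement schedule (defaults 20, 70, 5).
#' @param n_wks number of WKS energy channels used to seed the maps.
#' @param alpha functional-map regularisation weight.
#' @param learn run unsupervised descriptor learning instead of raw WKS.
#' @param config a [training_config()] (used when `learn = TRUE`).
#' @param pairs `"all"` ordered pairs or a `"star"` graph.
#' @param seed master seed.
#' @return object of class `fmorph_pipeline`: list with `bases`, `fmn`
#'   (refined network), `p2p`, `limit_shape`, `shape_differences`,
#'   `lssd_area`, `lssd_conformal`, `coverage_before`, `coverage_after`,
#'   `groups`, `meshes`, and (if learned) `training`.
#' @examples
#' \donttest{
#' coll <- make_collection(n_groups = 2, n_per_group = 3, level = 1, seed = 1)
#' fit <- fmorph_pipeline(coll$meshes, coll$groups, k_init = 10, k_final = 20,
#'                        step = 5, n_wks = 40)
#' summary(fit)
#' }
#' @export
fmorph_pipeline <- function(meshes, groups = NULL, k_init = 20, k_final = 70,
                            step = 5, n_wks = 100, alpha = 1e-2, learn = FALSE,
                            config = NULL, pairs = "all", seed = 0) {
  meshes <- lapply(meshes, normalize_unit_area)
  bases <- lapply(meshes, spectral_basis, k = k_final)
  if (learn) {
    if (is.null(config)) config <- training_config(k = k_init, seed = seed)
    training <- train_descriptors(bases, meshes, extractor_spectral_mlp(),
                                  config = config)
    descs <- training$descriptors
  } else {
    training <- NULL
    descs <- lapply(bases, wks, n_energies = n_wks)
  }
  fmn0 <- fmap_network_from_descriptors(bases, descs, k = k_init, alpha = alpha,
                                        pairs = pairs)
  ref <- consistent_zoomout(fmn0, bases, k_init = k_init, k_final = k_final,
                            step = step)
  ops <- latent_shape_differences(ref$limit_shape, ref$fmn$evals)
  structure(list(bases = bases, fmn = ref$fmn, p2p = ref$p2p,
                 limit_shape = ref$limit_shape, shape_differences = ops,
                 lssd_area = lssd_matrix(ops, "area"),
                 lssd_conformal = lssd_matrix(ops, "conformal"),
                 coverage_before = ref$coverage_before,
                 coverage_after = ref$coverage_after,
                 residual_trace = ref$residual_trace,
                 groups = groups, meshes = meshes, training = training),
            class = "fmorph_pipeline")
}

#' @export
print.fmorph_pipeline <- function(x, ...) {
  cat(sprintf("<fmorph_pipeline: %d shapes, maps %d x %d, mean coverage %.3f -> %.3f>\n",
              length(x$meshes), x$limit_shape$k, x$limit_shape$k,
              mean(x$coverage_before), mean(x$coverage_after)))
  invisible(x)
}

#' @export
summary.fmorph_pipeline <- function(object, ...) {
  cat("Landmark-free functional-map shape analysis\n")
  cat(sprintf("  shapes: %d (%s)\n", length(object$meshes),
              paste(utils::head(names(object$meshes), 5), collapse = ", ")))
  cat(sprintf("  refined maps: %d directed pairs at k = %d\n",
              length(object$fmn$maps), object$limit_shape$k))
  cat(sprintf("  bijective coverage: %.3f before -> %.3f after refinement\n",
              mean(object$coverage_before), mean(object$coverage_after)))
  cat(sprintf("  latent consistency residual: %.4f\n",
              mean(object$limit_shape$residuals)))
  cat(sprintf("  LSSD features: %d (area) + %d (conformal) per shape\n",
              ncol(object$lssd_area), ncol(object$lssd_conformal)))
  if (!is.null(object$groups)) {
    tab <- table(object$groups)
    cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(object)
}
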