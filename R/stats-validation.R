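#' PCA scores covering a variance threshold
#'
#' Centred (unscaled) principal component analysis of a shapes-by-features
#' representation matrix; the retained component count is the smallest
#' number whose cumulative variance ratio reaches `var_threshold`.
#'
#' @param X shapes x features numeric matrix.
#' @param var_threshold cumulative variance ratio in (0, 1] (default 0.95).
#' @return list with `scores` (all components), `selected` (scores truncated
#'   to `n_components`), `eigenvalues`, `n_components`,
#'   `variance_ratio`.
#' @export
pca_scores <- function(X, var_threshold = 0.95) {
  if (var_threshold <= 0 || var_threshold > 1) stop("var_threshold must be in (0, 1]")
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 shapes")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  vr <- ev / sum(ev)
  ncomp <- which(cumsum(vr) >= var_threshold - 1e-12)[1]
  list(scores = pc$x, selected = pc$x[, seq_len(ncomp), drop = FALSE],
       eigenvalues = ev, n_components = ncomp, variance_ratio = vr)
}

#' Correlation between two shape-space representations
#'
#' Pearson's r between the upper-triangle entries of the Euclidean
#' distance matrices of two representations of the same specimens, with the
#' two-sided p-value from the t transform (`df = n_pairs - 2`). Since
#' distances are invariant to rotation and translate only with global
#' scale, r is unaffected by rigid motion or uniform scaling of either
#' representation. An optional Mantel permutation p-value accounts for the
#' non-independence of distance-matrix entries.
#'
#' @param X1,X2 shapes x features matrices with identical row ids/order
#'   (row names compared when present).
#' @param mantel_permutations if > 0, also compute a Mantel permutation
#'   p-value with this many permutations.
#' @param seed seed for the Mantel permutations.
#' @return list with `r`, `p`, `df`, and optionally `p_mantel`.
#' @export
representation_correlation <- function(X1, X2, mantel_permutations = 0, seed = 0) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (nrow(X1) != nrow(X2)) stop("representations must cover the same shapes")
  if (!is.null(rownames(X1)) && !is.null(rownames(X2)) &&
      !identical(rownames(X1), rownames(X2)))
    stop("shape ids of the two representations do not match")
  d1 <- as.matrix(stats::dist(X1)); d2 <- as.matrix(stats::dist(X2))
  ut <- upper.tri(d1)
  v1 <- d1[ut]; v2 <- d2[ut]
  r <- stats::cor(v1, v2)
  df <- length(v1) - 2
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  out <- list(r = r, p = p, df = df)
  if (mantel_permutations > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    n <- nrow(d1)
    perm_r <- replicate(mantel_permutations, {
      pidx <- sample.int(n)
      stats::cor(v1, d2[pidx, pidx][ut])
    })
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    out$p_mantel <- (sum(perm_r >= r) + 1) / (mantel_permutations + 1)
  }
  out
}

#' Cross-validated group classification of shape variables
#'
#' Reproduces the standard group-recovery harness on a shape
#' representation: the supervised methods (multinomial logistic regression,
#' naive Bayes, linear discriminant analysis) are scored by stratified
#' k-fold cross-validation (mean accuracy and between-fold sd); K-means is
#' unsupervised and scored once on all data with `K =` number of groups,
#' matching clusters to labels by the best assignment before computing a
#' single accuracy.
#'
#' @param X shapes x features matrix (typically PCA scores from
#'   [pca_scores()]).
#' @param labels group labels (factor/character, length `nrow(X)`).
#' @param method one of `"kmeans"`, `"logistic"`, `"naive_bayes"`, `"lda"`.
#' @param folds number of CV folds (default 11).
#' @param seed seed controlling fold assignment and K-means starts.
#' @return list with `mean` accuracy, `sd` (NA for kmeans), `per_fold`
#'   (NULL for kmeans), `method`.
#' @export
classify_groups <- function(X, labels, method = c("kmeans", "logistic",
                                                  "naive_bayes", "lda"),
                            folds = 11, seed = 0) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- factor(labels)
  if (nrow(X) != length(y)) stop("labels must match rows of X")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  if (method == "kmeans") {
    km <- stats::kmeans(X, centers = nlevels(y), nstart = 25)
    acc <- cluster_label_accuracy(km$cluster, y)
    return(list(mean = acc, sd = NA_real_, per_fold = NULL, method = method))
  }
  fold_id <- stratified_folds(y, folds)
  # every training fold must still contain every class
  for (f in seq_len(folds))
    if (nlevels(droplevels(y[fold_id != f])) < nlevels(y))
      stop("stratification error: a class is absent from a training fold")
  per_fold <- vapply(seq_len(folds), function(f) {
    tr <- fold_id != f; te <- !tr
    df_tr <- data.frame(y = y[tr], X[tr, , drop = FALSE])
    df_te <- data.frame(X[te, , drop = FALSE])
    pred <- switch(method,
      logistic = {
        fit <- nnet::multinom(y ~ ., data = df_tr, trace = FALSE,
                              maxit = 200, MaxNWts = 1e5)
        stats::predict(fit, newdata = df_te)
      },
      naive_bayes = {
        fit <- e1071::naiveBayes(y ~ ., data = df_tr)
        stats::predict(fit, newdata = df_te)
      },
      lda = {
        fit <- MASS::lda(y ~ ., data = df_tr)
        stats::predict(fit, newdata = df_te)$class
      })
    mean(as.character(pred) == as.character(y[te]))
  }, 0)
  list(mean = mean(per_fold), sd = stats::sd(per_fold), per_fold = per_fold,
       method = method)
}

# stratified fold assignment: shuffled within class, classes dealt onto the
# currently least-loaded folds so fold sizes stay balanced overall
stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  load <- integer(folds)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    ord <- order(load, sample.int(folds))  # ties broken randomly
    take <- rep_len(ord, length(idx))
    fold_id[idx] <- take
    load <- load + tabulate(take, folds)
  }
  fold_id
}

# best cluster->label assignment accuracy (exhaustive for small K, greedy otherwise)
cluster_label_accuracy <- function(cluster, y) {
  K <- nlevels(y)
  tab <- table(factor(cluster, levels = seq_len(K)), y)
  if (K <= 7) {
    perms <- permutations_of(K)
    best <- 0
    for (r in seq_len(nrow(perms)))
      best <- max(best, sum(tab[cbind(seq_len(K), perms[r, ])]))
  } else {
    best <- 0; used <- logical(K); tb <- tab
    for (i in seq_len(K)) {
      w <- which(tb == max(tb), arr.ind = TRUE)[1, ]
      best <- best + tb[w[1], w[2]]
      tb[w[1], ] <- -1; tb[, w[2]] <- -1
    }
  }
  best / length(y)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))))
}

#' Landmark-transfer error of a refined map collection
#'
#' Replays the landmark-position-estimation protocol against ground truth:
#' each shape's landmarks are snapped to their nearest vertices, pushed
#' through the point-to-point map to every other shape, and compared (in
#' Euclidean distance, unit-area mesh units) to that shape's own
#' ground-truth landmark positions. Errors are aggregated per landmark over
#' all ordered pairs.
#'
#' @param p2p named list of `point_map` objects (names `"i->j"`).
#' @param meshes named list of `surface_mesh` (unit-area).
#' @param landmarks named list of per-shape `L x 3` landmark coordinate
#'   matrices (same landmark order across shapes).
#' @return data.frame with columns `landmark`, `mean`, `sd`, `n_pairs`, plus
#'   attribute `"per_pair"` (list of per-pair error matrices).
#' @export
landmark_transfer_error <- function(p2p, meshes, landmarks) {
  ids <- names(meshes)
  L <- nrow(landmarks[[1]])
  # snap landmarks to nearest vertices per shape
  snap <- lapply(ids, function(i) nn_index(landmarks[[i]], meshes[[i]]$vertices))
  names(snap) <- ids
  errs <- vector("list", 0)
  for (key in names(p2p)) {
    pm <- p2p[[key]]
    i <- pm$source_id; j <- pm$target_id
    if (is.null(i) || !i %in% ids || !j %in% ids) next
    est <- meshes[[j]]$vertices[pm$T[snap[[i]]], , drop = FALSE]
    gt <- landmarks[[j]]
    errs[[key]] <- sqrt(rowSums((est - gt)^2))
  }
  if (length(errs) == 0) stop("no usable maps: point_map ids do not match meshes")
  expected <- length(ids) * (length(ids) - 1)
  if (length(errs) < expected)
    warning(sprintf("missing maps for %d ordered pair(s); skipped", expected - length(errs)))
  M <- do.call(rbind, errs)  # pairs x L
  data.frame(landmark = seq_len(L),
             mean = colMeans(M),
             sd = apply(M, 2, stats::sd),
             n_pairs = nrow(M)) -> out
  attr(out, "per_pair") <- errs
  out
}

#' Per-group covariance traces
#'
#' Utility reporting the trace of each group's variance-covariance matrix —
#' a scalar spread measure used to compare variance partitioning across
#' representations.
#'
#' @param X shapes x features matrix.
#' @param labels group labels.
#' @return named numeric vector of traces, plus total trace as attribute.
#' @export
group_covariance_traces <- function(X, labels) {
  y <- factor(labels)
  out <- vapply(levels(y), function(lev) {
    sub <- X[y == lev, , drop = FALSE]
    sum(apply(sub, 2, stats::var))
  }, 0)
  attr(out, "total") <- sum(apply(X, 2, stats::var))
  out
}
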