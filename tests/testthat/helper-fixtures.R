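# Shared, memoised test fixtures. Everything is generated in code with fixed
# seeds; heavier objects (spectral bases, refined pipelines) are built once
# and reused across test files.

.fix_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fix_cache)) assign(key, builder(), envir = .fix_cache)
  get(key, envir = .fix_cache)
}

# closed cube surface (12 triangles, area 6 for unit edge length)
cube_mesh <- function(edge = 1) {
  v <- as.matrix(expand.grid(c(0, edge), c(0, edge), c(0, edge)))
  colnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),  # z = 0
    c(5, 6, 7), c(6, 8, 7),  # z = edge
    c(1, 2, 5), c(2, 6, 5),  # y = 0
    c(3, 7, 4), c(4, 7, 8),  # y = edge
    c(1, 5, 3), c(3, 5, 7),  # x = 0
    c(2, 4, 6), c(4, 8, 6))  # x = edge
  surface_mesh(v, f, id = "cube")
}

# asymmetric single mesh: warped + bumped ellipsoid (no symmetry left)
warped_ellipsoid <- function(level = 3, seed = 11) {
  m <- deform_with_known_map(ellipsoid(level), params = list(
    warp = list(n_centers = 6, amplitude = 0.05),
    bump = list(center = 100, amplitude = 0.15, radius = 0.3),
    rigid = FALSE), seed = seed)$mesh
  normalize_unit_area(m)
}

tf_basis70 <- function() memo("basis70", function() {
  m <- warped_ellipsoid(3)
  list(mesh = m, basis = spectral_basis(m, k = 70))
})

# two-group, six-shape collection at full fixture resolution, plus its
# spectral bases and the refined pipeline (used by several test files)
tf_coll6 <- function() memo("coll6", function() {
  coll <- make_collection(n_groups = 2, n_per_group = 3, level = 3, seed = 7)
  coll
})

tf_fit6 <- function() memo("fit6", function() {
  coll <- tf_coll6()
  fmorph_pipeline(coll$meshes, coll$groups, k_init = 20, k_final = 70, step = 5)
})

# exact isometric pair (rigid copy) with spectral bases
tf_iso_pair <- function(level = 2) memo(paste0("iso", level), function() {
  m1 <- warped_ellipsoid(level, seed = 4)
  m2 <- deform_with_known_map(m1, params = list(rigid = TRUE), seed = 9)$mesh
  list(m1 = m1, m2 = m2,
       b1 = spectral_basis(m1, k = 30), b2 = spectral_basis(m2, k = 30),
       map = seq_len(nrow(m1$vertices)))
})

mean_gt_error <- function(p2p, meshes) {
  mean(vapply(p2p, function(pm) {
    V <- meshes[[pm$target_id]]$vertices
    mean(sqrt(rowSums((V[pm$T, , drop = FALSE] - V)^2)))
  }, 0))
}

bumped_pair_fixture <- function() memo("bumped_pair", function() {
  # canonical bumped fixture: two specimens differing exactly by one
  # group bump (no warp, no noise), exact identity bijection
  coll <- make_collection(n_groups = 2, n_per_group = 1, level = 3,
                          bump_amplitude = c(0, 0.18), group_warp_amplitude = 0,
                          indiv_warp_amplitude = 0, noise_sd = 0, seed = 13)
  meshes <- coll$meshes
  bases <- lapply(meshes, spectral_basis, k = 30)
  ids <- names(meshes)
  k <- 20
  n <- nrow(meshes[[1]]$vertices)
  maps <- list()
  maps[[paste0(ids[1], "->", ids[2])]] <-
    gt_fmap(seq_len(n), bases[[1]], bases[[2]], k, ids[1], ids[2])
  maps[[paste0(ids[2], "->", ids[1])]] <-
    gt_fmap(seq_len(n), bases[[2]], bases[[1]], k, ids[2], ids[1])
  fmn <- fmap_network(maps, lapply(bases, function(b) b$evals))
  ls <- compute_limit_shape(fmn, k)
  list(meshes = meshes, bases = bases, ids = ids, k = k, n = n,
       fmn = fmn, ls = ls, ops = latent_shape_differences(ls, fmn$evals))
})
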