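#' Synthetic base meshes
#'
#' Seeded, deterministic generators for the closed test surfaces used
#' throughout the package: recursively subdivided icospheres (genus 0,
#' `10 * 4^level + 2` vertices), ellipsoids (an icosphere scaled by three
#' distinct semi-axes, which breaks the sphere's continuous symmetry), and a
#' parametric torus (genus 1).
#'
#' @param level icosphere subdivision level (0 = icosahedron, 12 vertices).
#' @param id specimen identifier.
#' @return a [surface_mesh()].
#' @examples
#' nrow(icosphere(2)$vertices)  # 162
#' @export
icosphere <- function(level = 3, id = sprintf("icosphere%d", level)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- surface_mesh(v, f, id = id)
  for (i in seq_len(level)) {
    mesh <- subdivide_midpoint(mesh)
    mesh$vertices <- mesh$vertices / sqrt(rowSums(mesh$vertices^2))
  }
  mesh$id <- id
  mesh
}

#' @rdname icosphere
#' @param axes length-3 positive semi-axes of the ellipsoid.
#' @export
ellipsoid <- function(level = 3, axes = c(1, 0.8, 0.65), id = "ellipsoid") {
  mesh <- icosphere(level, id = id)
  mesh$vertices <- sweep(mesh$vertices, 2, axes, `*`)
  mesh
}

#' @rdname icosphere
#' @param nu,nv number of grid steps around the major and minor circles.
#' @param R,r major and minor torus radii.
#' @export
torus_mesh <- function(nu = 24, nv = 16, R = 1, r = 0.4, id = "torus") {
  iu <- rep(seq_len(nu), each = nv); iv <- rep(seq_len(nv), times = nu)
  u <- 2 * pi * (iu - 1) / nu; v <- 2 * pi * (iv - 1) / nv
  verts <- cbind((R + r * cos(v)) * cos(u), (R + r * cos(v)) * sin(u), r * sin(v))
  idx <- function(i, j) ((i - 1) %% nu) * nv + ((j - 1) %% nv) + 1
  f <- NULL
  for (i in seq_len(nu)) for (j in seq_len(nv)) {
    a <- idx(i, j); b <- idx(i + 1, j); c2 <- idx(i + 1, j + 1); d <- idx(i, j + 1)
    f <- rbind(f, c(a, b, c2), c(a, c2, d))
  }
  surface_mesh(verts, f, id = id)
}

# one round of midpoint (1:4) subdivision
subdivide_midpoint <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  uk <- unique(key)
  mid_id <- nrow(v) + match(key, uk)            # new vertex id per half-edge
  ue <- e[!duplicated(key), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]; m23 <- mid_id[nf + seq_len(nf)]; m31 <- mid_id[2 * nf + seq_len(nf)]
  newf <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
                cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  surface_mesh(rbind(v, mids), newf, id = mesh$id, validate = FALSE)
}

#' Deform a mesh while keeping the exact vertex correspondence
#'
#' Applies a smooth low-frequency warp (a sum of wide Gaussian displacement
#' kernels), an optional localized Gaussian bump displacing vertices along
#' their normals, iid vertex noise, and finally a rigid motion. Connectivity
#' is untouched, so the ground-truth bijection between input and output is
#' the identity on vertex indices — every downstream correspondence error
#' can be measured exactly.
#'
#' @param mesh a `surface_mesh`.
#' @param params list with optional components:
#'   `warp = list(n_centers, amplitude, scale)` smooth warp field;
#'   `bump = list(center, amplitude, radius)` where `center` is a vertex
#'   index (or xyz vector) and displacement is along vertex normals
#'   (`bumps` may give a list of several such bumps);
#'   `noise_sd` iid Gaussian coordinate noise; `rigid` logical, append a
#'   random rotation + translation (default `TRUE`).
#' @param seed integer seed; the generator is a pure function of
#'   `(mesh, params, seed)`.
#' @return list with `mesh` (deformed `surface_mesh`) and `map` (integer
#'   ground-truth bijection, here the identity permutation).
#' @export
deform_with_known_map <- function(mesh, params = list(), seed = 0) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  v <- mesh$vertices
  n <- nrow(v)
  disp <- matrix(0, n, 3)
  w <- params$warp
  if (!is.null(w) && w$amplitude > 0) {
    nc <- if (is.null(w$n_centers)) 8L else w$n_centers
    sc <- if (is.null(w$scale)) 0.5 * diff(range(v)) else w$scale
    centers <- v[sample.int(n, nc), , drop = FALSE]
    for (j in seq_len(nc)) {
      a <- stats::rnorm(1, 0, w$amplitude)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      d2 <- rowSums(sweep(v, 2, centers[j, ])^2)
      disp <- disp + outer(a * exp(-d2 / (2 * sc^2)), u)
    }
  }
  bumps <- params[["bumps"]]
  if (!is.null(params[["bump"]])) bumps <- c(bumps, list(params[["bump"]]))
  if (length(bumps) > 0) {
    nrm <- vertex_normals(mesh)
    for (b in bumps) {
      if (b$amplitude == 0) next
      ctr <- if (length(b$center) == 1) v[b$center, ] else b$center
      d2 <- rowSums(sweep(v, 2, ctr)^2)
      disp <- disp + nrm * (b$amplitude * exp(-d2 / (2 * b$radius^2)))
    }
  }
  if (!is.null(params$noise_sd) && params$noise_sd > 0)
    disp <- disp + matrix(stats::rnorm(3 * n, 0, params$noise_sd), n, 3)
  newv <- v + disp
  out <- surface_mesh(newv, mesh$faces, id = mesh$id, validate = FALSE)
  # reject deformations that flip triangles (proxy for self-intersection)
  dots <- rowSums(face_normals_raw(mesh) * face_normals_raw(out))
  if (any(dots <= 0))
    stop("amplitude error: deformation flips ", sum(dots <= 0), " triangle(s)")
  if (is.null(params$rigid) || isTRUE(params$rigid)) {
    Rm <- random_rotation(max_angle = if (is.null(params$max_angle)) pi / 6 else params$max_angle)
    out$vertices <- out$vertices %*% t(Rm) +
      matrix(stats::rnorm(3, 0, 0.1), n, 3, byrow = TRUE)
  }
  list(mesh = out, map = seq_len(n))
}

# uniform-axis random rotation with bounded angle (draws from current RNG)
random_rotation <- function(max_angle = pi) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, max_angle)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a synthetic mesh collection with known ground truth
#'
#' Builds a seeded collection standing in for a real bone dataset: every
#' specimen is a deformation of one shared template. The template is a base
#' surface (default an ellipsoid with distinct semi-axes) carrying a fixed,
#' asymmetric "anatomy" — two bumps of different sign and size at fixed
#' locations — so that, like homologous features on real bones, every
#' specimen presents the same symmetry-breaking landmarks to the
#' correspondence machinery. Each group then adds a shared deformation mode
#' (a group bump at a group-specific surface patch plus a shared smooth
#' warp) and each specimen a small idiosyncratic warp and vertex noise.
#' Group structure mirrors real comparative samples: a set of homologous
#' surface patches (one per group, well separated) carries a weak bump on
#' every specimen, and each group additionally enlarges the bump at its own
#' patch — so features are present in all groups and differ in size, never
#' in existence. Because connectivity is shared, the ground-truth bijection
#' between any two specimens is the identity, and five landmarks placed at
#' fixed template vertices away from the group patches correspond exactly
#' across shapes.
#'
#' @param n_groups number of groups.
#' @param n_per_group specimens per group (scalar or length `n_groups`).
#' @param level icosphere subdivision level of the base mesh.
#' @param base one of `"ellipsoid"`, `"icosphere"`, `"torus"`.
#' @param bump_amplitude,bump_radius group-specific bump enlargement
#'   (normal displacement height added at the group's own patch) and the
#'   Gaussian patch radius, in template units; either may be a vector
#'   recycled across groups, e.g. `bump_amplitude = c(0, 0.18)` gives a
#'   two-group collection whose second group carries an area bump the
#'   first lacks. The default staggers amplitudes (0.12, 0.19, 0.26, ...)
#'   so that no two groups' enlarged patches are interchangeable.
#' @param bump_weak amplitude of the weak homologous bump every specimen
#'   carries at every group patch.
#' @param group_warp_amplitude,indiv_warp_amplitude smooth-warp scales of
#'   the shared group mode and the per-specimen idiosyncrasy.
#' @param noise_sd iid vertex coordinate noise.
#' @param rigid apply a random rigid motion to each specimen.
#' @param seed integer seed; the collection is a pure function of its
#'   arguments.
#' @return list with `meshes` (named list of unit-area `surface_mesh`),
#'   `groups` (named factor), `gt_maps` (`function(i, j)` returning the
#'   ground-truth bijection as integer vector), `landmarks` (list per shape:
#'   5 x 3 coordinate matrix with attribute `"vertex"` of vertex ids),
#'   `bump_centers` (per-group base vertex index of the group bump), and
#'   `manifest` (data.frame id/group).
#' @export
make_collection <- function(n_groups = 3, n_per_group = 8, level = 2,
                            base = "ellipsoid",
                            bump_amplitude = NULL, bump_radius = 0.3,
                            bump_weak = 0.06,
                            group_warp_amplitude = 0.05,
                            indiv_warp_amplitude = 0.02,
                            noise_sd = 0.001, rigid = TRUE, seed = 0) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  raw_base <- switch(base,
    ellipsoid = ellipsoid(level),
    icosphere = icosphere(level),
    torus = torus_mesh(),
    stop("unknown base mesh: ", base))
  n <- nrow(raw_base$vertices)
  if (is.null(bump_amplitude))
    bump_amplitude <- seq(0.12, by = 0.07, length.out = n_groups)
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, n_groups)
  stopifnot(all(n_per_group >= 1))
  # fixed asymmetric anatomy shared by all specimens: two unequal bumps at
  # well-separated template locations (breaks every residual symmetry)
  anat <- farthest_point_sample(raw_base$vertices, 2L, start = 17L)
  base_mesh <- deform_with_known_map(raw_base, params = list(
    bump = list(center = anat[1], amplitude = 0.25, radius = 0.3),
    rigid = FALSE), seed = 1)$mesh
  base_mesh <- deform_with_known_map(base_mesh, params = list(
    bump = list(center = anat[2], amplitude = -0.15, radius = 0.22),
    rigid = FALSE), seed = 2)$mesh
  # well-separated group bump centers by farthest-point sampling
  fps <- farthest_point_sample(base_mesh$vertices, n_groups, start = 1L)
  bump_centers <- fps[seq_len(n_groups)]
  bump_amplitude <- rep_len(bump_amplitude, n_groups)
  bump_radius <- rep_len(bump_radius, n_groups)
  # landmarks go on anatomy shared by every specimen: well-separated vertices
  # away from all group-difference patches (as an expert would place them)
  dmin <- rep(Inf, n)
  for (g in seq_len(n_groups)) {
    dg <- sqrt(rowSums(sweep(base_mesh$vertices, 2, base_mesh$vertices[bump_centers[g], ])^2))
    dmin <- pmin(dmin, dg)
  }
  candidates <- which(dmin > 3.5 * max(bump_radius))
  if (length(candidates) < 5) candidates <- order(dmin, decreasing = TRUE)[1:max(5, n %/% 4)]
  lm_local <- farthest_point_sample(base_mesh$vertices[candidates, , drop = FALSE],
                                    5L, start = 1L)
  lm_vertices <- candidates[lm_local]
  meshes <- list(); groups <- character(); landmarks <- list()
  shape_seeds <- sample.int(2^30, sum(n_per_group) + n_groups)
  s_ix <- 0L
  for (g in seq_len(n_groups)) {
    # shared group mode: bump location + a group warp (same seed for the group)
    s_ix <- s_ix + 1L
    group_seed <- shape_seeds[s_ix]
    for (m in seq_len(n_per_group[g])) {
      s_ix <- s_ix + 1L
      id <- sprintf("g%d_s%d", g, m)
      group_bumps <- lapply(seq_len(n_groups), function(p) list(
        center = bump_centers[p],
        amplitude = bump_weak + if (p == g) bump_amplitude[g] else 0,
        radius = bump_radius[p]))
      shared <- deform_with_known_map(base_mesh, params = list(
        warp = list(n_centers = 6, amplitude = group_warp_amplitude),
        bumps = group_bumps,
        rigid = FALSE), seed = group_seed)$mesh
      indiv <- deform_with_known_map(shared, params = list(
        warp = list(n_centers = 6, amplitude = indiv_warp_amplitude),
        noise_sd = noise_sd, rigid = rigid), seed = shape_seeds[s_ix])$mesh
      indiv$id <- id
      indiv <- normalize_unit_area(indiv)
      meshes[[id]] <- indiv
      groups[id] <- sprintf("G%d", g)
      lmk <- indiv$vertices[lm_vertices, , drop = FALSE]
      attr(lmk, "vertex") <- lm_vertices
      landmarks[[id]] <- lmk
    }
  }
  list(meshes = meshes,
       groups = factor(groups),
       gt_maps = function(i, j) seq_len(n),
       landmarks = landmarks,
       bump_centers = bump_centers,
       manifest = data.frame(id = names(meshes), group = unname(groups),
                             stringsAsFactors = FALSE))
}

# deterministic Euclidean farthest-point sampling of vertex indices
farthest_point_sample <- function(v, k, start = 1L) {
  idx <- integer(k)
  idx[1] <- start
  d <- rowSums(sweep(v, 2, v[start, ])^2)
  for (i in seq_len(k - 1L)) {
    idx[i + 1] <- which.max(d)
    d <- pmin(d, rowSums(sweep(v, 2, v[idx[i + 1], ])^2))
  }
  idx
}

#' Write a fixture collection to disk
#'
#' Emits the meshes (binary PLY), a manifest CSV (`id,path,group`) and a
#' landmarks CSV (`id,landmark,x,y,z,vertex`) into `dir`.
#'
#' @param collection result of [make_collection()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(collection$meshes))
    write_mesh(collection$meshes[[id]], file.path(dir, paste0(id, ".ply")))
  manifest <- collection$manifest
  manifest$path <- paste0(manifest$id, ".ply")
  utils::write.csv(manifest[, c("id", "path", "group")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  lmk <- do.call(rbind, lapply(names(collection$landmarks), function(id) {
    L <- collection$landmarks[[id]]
    data.frame(id = id, landmark = seq_len(nrow(L)), x = L[, 1], y = L[, 2],
               z = L[, 3], vertex = attr(L, "vertex"))
  }))
  utils::write.csv(lmk, file.path(dir, "landmarks.csv"), row.names = FALSE)
  invisible(dir)
}
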