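#' Surface mesh objects
#'
#' A `surface_mesh` represents one specimen's bone surface as a closed
#' triangular mesh: an `n x 3` matrix of vertex coordinates and an `m x 3`
#' matrix of 1-based vertex indices (counter-clockwise orientation). All
#' meshes in a collection are assumed to share physical units until
#' [normalize_unit_area()] makes coordinates dimensionless.
#'
#' @param vertices numeric `n x 3` matrix of vertex coordinates.
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @param id specimen identifier string.
#' @param validate run [validate_mesh()] on the result (default `TRUE`).
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces`, `id`.
#' @examples
#' m <- icosphere(1)
#' mesh_area(m)
#' @export
surface_mesh <- function(vertices, faces, id = "mesh", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces, id = as.character(id)),
                    class = "surface_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh '%s': %d vertices, %d faces, area %.6g>\n",
              x$id, nrow(x$vertices), nrow(x$faces), mesh_area(x)))
  invisible(x)
}

#' Validate surface-mesh invariants
#'
#' Checks the structural invariants every mesh in the pipeline must satisfy:
#' 3-column coordinate and face arrays, all face indices within range,
#' no degenerate faces (three distinct vertices), positive total area, and
#' edge-manifoldness (every undirected edge shared by at most two faces).
#'
#' @param mesh a `surface_mesh`.
#' @param require_closed additionally require every edge to border exactly
#'   two faces (watertight surface). Default `FALSE`.
#' @return `mesh`, invisibly. Errors describe the violated invariant.
#' @export
validate_mesh <- function(mesh, require_closed = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3L) stop("vertices must be an n x 3 matrix")
  if (!is.matrix(f) || ncol(f) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(f) == 0L) stop("validation error: mesh has no faces")
  if (anyNA(v) || any(!is.finite(v))) stop("vertices contain non-finite values")
  if (min(f) < 1L || max(f) > nrow(v)) stop("face indices out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("degenerate faces present (repeated vertex index)")
  if (mesh_area(mesh) <= 0) stop("validation error: total surface area is not positive")
  ek <- edge_keys(f)
  tab <- tabulate(match(ek, unique(ek)))
  if (any(tab > 2L)) stop("mesh is not edge-manifold (an edge borders > 2 faces)")
  if (require_closed && any(tab != 2L)) stop("mesh is not closed (boundary edges present)")
  invisible(mesh)
}

# undirected edge keys, one per half-edge (3 per face)
edge_keys <- function(f) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

# m x 3 matrix of per-face corner coordinates differences -> face normals (unnormalized)
face_normals_raw <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Per-face areas and total surface area
#'
#' @param mesh a `surface_mesh`.
#' @return `face_areas()`: numeric vector of triangle areas. `mesh_area()`:
#'   total surface area (their sum).
#' @export
face_areas <- function(mesh) {
  nrm <- face_normals_raw(mesh)
  0.5 * sqrt(rowSums(nrm^2))
}

#' @rdname face_areas
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

#' Area-weighted per-vertex normals (unit length)
#'
#' @param mesh a `surface_mesh`.
#' @return `n x 3` matrix of unit vertex normals.
#' @export
vertex_normals <- function(mesh) {
  nrm <- face_normals_raw(mesh)
  n <- nrow(mesh$vertices)
  vn <- matrix(0, n, 3)
  for (j in 1:3) {
    idx <- mesh$faces[, j]
    vn[, 1] <- vn[, 1] + unname(tapply_sum(nrm[, 1], idx, n))
    vn[, 2] <- vn[, 2] + unname(tapply_sum(nrm[, 2], idx, n))
    vn[, 3] <- vn[, 3] + unname(tapply_sum(nrm[, 3], idx, n))
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

# fast grouped sum into a fixed-length vector
tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Rescale a mesh to unit surface area
#'
#' Multiplies all coordinates by the single scalar `1/sqrt(area)` so that the
#' total triangle area becomes exactly 1. Size is thereby removed before any
#' spectral computation, mirroring the standard practice of standardising
#' each specimen to unit surface area so that correspondence estimation is
#' not confounded by scale.
#'
#' @param mesh a `surface_mesh` with positive area.
#' @return the rescaled `surface_mesh` (returned unchanged if already unit
#'   area to within 1e-12).
#' @export
normalize_unit_area <- function(mesh) {
  a <- mesh_area(mesh)
  if (a <= 0) stop("validation error: zero-area mesh")
  if (abs(a - 1) < 1e-12) return(mesh)
  mesh$vertices <- mesh$vertices / sqrt(a)
  mesh
}

#' Mean edge length of a mesh
#'
#' Average length over unique undirected edges; the natural resolution scale
#' against which correspondence errors are judged.
#' @param mesh a `surface_mesh`.
#' @return scalar mean edge length.
#' @export
mean_edge_length <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(e), , drop = FALSE]
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Euler characteristic of a mesh
#'
#' V - E + F; 2 for genus-0 closed surfaces, 0 for a torus.
#' @param mesh a `surface_mesh`.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  ne <- length(unique(edge_keys(f)))
  nrow(mesh$vertices) - ne + nrow(f)
}

# Merge duplicate vertices and drop unreferenced ones; reindexes faces.
clean_mesh_arrays <- function(vertices, faces, tol = 0) {
  key <- apply(round(vertices / max(tol, .Machine$double.eps)) * max(tol, .Machine$double.eps), 1, paste, collapse = ",")
  if (tol == 0) key <- apply(vertices, 1, paste, collapse = ",")
  first <- match(key, key)                  # representative index per vertex
  remap <- match(first, sort(unique(first)))# compress to 1..n'
  vertices <- vertices[sort(unique(first)), , drop = FALSE]
  faces <- matrix(remap[faces], ncol = 3)
  # drop faces that became degenerate by merging
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  faces <- faces[keep, , drop = FALSE]
  # drop unreferenced vertices
  used <- sort(unique(as.vector(faces)))
  faces <- matrix(match(faces, used), ncol = 3)
  vertices <- vertices[used, , drop = FALSE]
  list(vertices = vertices, faces = faces)
}
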