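test_that("mesh I/O round-trips geometry in every supported format", {
  m <- icosphere(2)
  td <- withr::local_tempdir()
  for (fmt in c("ply", "off", "obj")) {
    p <- file.path(td, paste0("mesh.", fmt))
    write_mesh(m, p)
    m2 <- read_mesh(p)
    expect_equal(nrow(m2$vertices), nrow(m$vertices), info = fmt)
    expect_equal(nrow(m2$faces), nrow(m$faces), info = fmt)
    # geometry preserved up to vertex reindexing
    expect_equal(sort(as.vector(m2$vertices)), sort(as.vector(m$vertices)),
                 tolerance = 1e-12, info = fmt)
    expect_equal(mesh_area(m2), mesh_area(m), tolerance = 1e-9, info = fmt)
  }
  # ascii STL stores full doubles; binary STL is float32 by format
  write_mesh(m, file.path(td, "mesh.stl"), binary = FALSE)
  ma_stl <- read_mesh(file.path(td, "mesh.stl"))
  expect_equal(nrow(ma_stl$vertices), nrow(m$vertices))
  expect_equal(mesh_area(ma_stl), mesh_area(m), tolerance = 1e-7)
  # binary PLY round trip is bit-exact for double coordinates
  p <- file.path(td, "exact.ply")
  write_mesh(m, p, binary = TRUE)
  m3 <- read_mesh(p)
  expect_identical(m3$vertices, m$vertices)
  expect_identical(m3$faces, m$faces)
  # ascii PLY also supported
  write_mesh(m, file.path(td, "a.ply"), binary = FALSE)
  expect_equal(read_mesh(file.path(td, "a.ply"))$vertices, m$vertices,
               tolerance = 1e-12)
  # binary STL parses (float32 precision)
  write_mesh(m, file.path(td, "b.stl"), binary = TRUE)
  expect_equal(mesh_area(read_mesh(file.path(td, "b.stl"))), mesh_area(m),
               tolerance = 1e-5)
})

test_that("read_mesh merges duplicate vertices and rejects degenerate files", {
  td <- withr::local_tempdir()
  # OFF file with one duplicated vertex: n decreases by 1, faces reindexed
  m <- icosphere(1)
  v <- rbind(m$vertices, m$vertices[5, ])
  f <- m$faces
  f[f[, 1] == 5L, 1] <- nrow(v)  # some faces reference the duplicate
  p <- file.path(td, "dup.off")
  writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f)),
               apply(v, 1, function(r) paste(format(r, digits = 17), collapse = " ")),
               apply(f - 1L, 1, function(r) paste(c(3, r), collapse = " "))), p)
  m2 <- read_mesh(p)
  expect_equal(nrow(m2$vertices), nrow(m$vertices))  # brute-force duplicate scan
  expect_equal(mesh_area(m2), mesh_area(m), tolerance = 1e-12)
  validate_mesh(m2, require_closed = TRUE)
  # zero faces -> validation error
  p0 <- file.path(td, "empty.off")
  writeLines(c("OFF", "3 0 0", "0 0 0", "1 0 0", "0 1 0"), p0)
  expect_error(read_mesh(p0), "validation error")
  # unparseable file -> format error
  pf <- file.path(td, "garbage.ply")
  writeLines("not a mesh at all", pf)
  expect_error(read_mesh(pf), "format error")
})

test_that("unit-area normalisation scales exactly and is idempotent", {
  cube <- cube_mesh(1)
  expect_equal(mesh_area(cube), 6)
  n1 <- normalize_unit_area(cube)
  # all coordinates multiplied by the single scalar 1/sqrt(6)
  expect_equal(n1$vertices, cube$vertices / sqrt(6))
  expect_equal(mesh_area(n1), 1, tolerance = 1e-12)
  # idempotence
  expect_identical(normalize_unit_area(n1), n1)
  # sphere of radius 2: area recomputed after scaling is exactly 1
  s <- icosphere(2); s$vertices <- 2 * s$vertices
  expect_equal(mesh_area(normalize_unit_area(s)), 1, tolerance = 1e-12)
  # commutes with rigid motion: the scale factor is rotation-invariant
  set.seed(3)
  R <- fmorph:::random_rotation()
  rot <- cube; rot$vertices <- cube$vertices %*% t(R)
  expect_equal(mesh_area(normalize_unit_area(rot)), 1, tolerance = 1e-12)
  expect_equal(normalize_unit_area(rot)$vertices,
               normalize_unit_area(cube)$vertices %*% t(R), tolerance = 1e-12)
  # zero-area mesh (all vertices collinear) errors
  flat <- cube; flat$vertices[, 2:3] <- 0
  expect_error(normalize_unit_area(flat), "zero-area")
})

test_that("resampling hits the target count and preserves area and topology", {
  # no-op when already at target
  m <- icosphere(3)
  expect_identical(resample_to_vertex_count(m, 642L), m)
  # upsampling path: 162 -> 642 by one subdivision
  up <- resample_to_vertex_count(icosphere(2), 642L)
  expect_equal(nrow(up$vertices), 642L)
  expect_equal(euler_characteristic(up), 2L)
  # decimation path: 2562 -> 642, exact count, area within 5%, genus kept
  big <- icosphere(4)
  dec <- resample_to_vertex_count(big, 642L)
  expect_lte(abs(nrow(dec$vertices) - 642) / 642, 0.02)
  expect_lt(abs(mesh_area(dec) - mesh_area(big)) / mesh_area(big), 0.05)
  expect_equal(euler_characteristic(dec), 2L)
  validate_mesh(dec, require_closed = TRUE)
  # mixed path: subdivide then decimate to a non-lattice target
  mid <- resample_to_vertex_count(icosphere(2), 400L)
  expect_lte(abs(nrow(mid$vertices) - 400) / 400, 0.02)
  validate_mesh(mid, require_closed = TRUE)
  expect_error(resample_to_vertex_count(m, 3), "target_n")
})

test_that("rigid prealignment recovers pose without touching intrinsic geometry", {
  m1 <- warped_ellipsoid(2)
  # rotated + translated copy
  set.seed(5)
  R <- fmorph:::random_rotation(pi / 2)
  m2 <- m1
  m2$vertices <- m1$vertices %*% t(R) +
    matrix(c(0.2, 0.1, -0.3), nrow(m1$vertices), 3, byrow = TRUE)
  al <- rigid_prealign(list(m1, m2), seed = 0)
  rms <- sqrt(mean(rowSums((al[[1]]$vertices - al[[2]]$vertices)^2)))
  expect_lt(rms, 1e-6)
  # edge-length multiset preserved to 1e-9 (rigid motions only)
  d_before <- sort(as.vector(stats::dist(m2$vertices)))
  d_after <- sort(as.vector(stats::dist(al[[2]]$vertices)))
  expect_lt(max(abs(d_before - d_after)), 1e-9)
  # already-aligned collection: near-identity transforms
  al2 <- rigid_prealign(al, seed = 0)
  expect_lt(max(abs(al2[[2]]$vertices - al[[2]]$vertices)), 1e-4)
  # degenerate input
  expect_error(rigid_prealign(list(m1), seed = 0), "at least 2")
  raw <- icosphere(1)  # not unit area
  expect_error(rigid_prealign(list(raw, raw), seed = 0), "unit-area")
})

test_that("mesh validation flags broken invariants", {
  m <- icosphere(1)
  bad <- m; bad$faces[1, ] <- c(1L, 1L, 2L)
  expect_error(validate_mesh(bad), "degenerate")
  bad2 <- m; bad2$faces <- rbind(bad2$faces, bad2$faces[1, ])
  expect_error(validate_mesh(bad2), "manifold")
  bad3 <- m; bad3$faces[2, ] <- c(14L, 3L, 7L)
  expect_error(surface_mesh(m$vertices, matrix(c(1, 2, 99), 1), validate = TRUE),
               "out of range")
})
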