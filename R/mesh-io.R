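#' Read a triangular surface mesh from file
#'
#' Supports PLY (ascii and binary little-endian), OFF, OBJ and STL (ascii
#' and binary). Quads are triangulated by fan splitting; duplicate vertices
#' are merged and unreferenced vertices dropped, so the returned mesh always
#' satisfies the `surface_mesh` invariants.
#'
#' @param path file path.
#' @param fmt one of `"ply"`, `"off"`, `"obj"`, `"stl"`; default guesses from
#'   the file extension.
#' @param id specimen identifier; defaults to the file name without extension.
#' @return a [surface_mesh()].
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, fmt = NULL, id = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(fmt)) fmt <- tolower(tools::file_ext(path))
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  raw <- switch(tolower(fmt),
    off = read_off(path),
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path),
    stop("unsupported mesh format: ", fmt))
  if (nrow(raw$faces) == 0L) stop("validation error: mesh file contains no faces")
  cl <- clean_mesh_arrays(raw$vertices, raw$faces)
  surface_mesh(cl$vertices, cl$faces, id = id)
}

#' Write a triangular surface mesh to file
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path.
#' @param fmt one of `"ply"`, `"off"`, `"obj"`, `"stl"`; default from the
#'   extension.
#' @param binary for PLY/STL, write the binary little-endian flavour
#'   (default `TRUE` for PLY; STL ascii unless `binary = TRUE`). Binary PLY
#'   stores double-precision coordinates, so a write/read round trip is
#'   bit-exact.
#' @param quality optional per-vertex scalar written as a PLY `quality`
#'   property (used to export distinctive functions for external viewers).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, fmt = NULL, binary = TRUE, quality = NULL) {
  if (is.null(fmt)) fmt <- tolower(tools::file_ext(path))
  switch(tolower(fmt),
    off = write_off(mesh, path),
    ply = write_ply(mesh, path, binary = binary, quality = quality),
    obj = write_obj(mesh, path),
    stl = write_stl(mesh, path, binary = binary),
    stop("unsupported mesh format: ", fmt))
  invisible(path)
}

read_off <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  if (!grepl("OFF", txt[1])) stop("format error: not an OFF file")
  header <- txt[1]
  body <- if (grepl("^\\s*OFF\\s*$", header)) txt[-1] else c(sub(".*OFF", "", header), txt[-1])
  body <- body[nzchar(trimws(body))]
  counts <- scan(text = body[1], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  if (is.na(nv) || is.na(nf)) stop("format error: bad OFF header")
  vals <- scan(text = body[2:(1 + nv)], quiet = TRUE)
  vertices <- matrix(vals, ncol = 3, byrow = TRUE)
  faces <- list()
  if (nf > 0) {
    flines <- body[(2 + nv):(1 + nv + nf)]
    faces <- parse_poly_lines(flines)
  }
  list(vertices = vertices, faces = to_face_matrix(faces))
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
}

# parse polygon lines "k i1 i2 ... ik" (0-based) -> list of triangle fans
parse_poly_lines <- function(lines) {
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    x <- scan(text = lines[i], quiet = TRUE)
    k <- x[1]
    idx <- x[2:(1 + k)] + 1L
    if (k == 3) out[[i]] <- matrix(idx, 1, 3)
    else out[[i]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])
  }
  out
}

to_face_matrix <- function(faces) {
  if (length(faces) == 0) return(matrix(integer(), 0, 3))
  f <- do.call(rbind, faces)
  storage.mode(f) <- "integer"
  f
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii lines terminated by "end_header"
  header <- character()
  repeat {
    line <- read_bin_line(con)
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 1000) stop("format error: PLY header not terminated")
  }
  if (!identical(trimws(header[1]), "ply")) stop("format error: not a PLY file")
  fmt_line <- grep("^format", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  ascii <- grepl("ascii", fmt_line)
  if (!binary && !ascii) stop("format error: unsupported PLY encoding (big-endian)")
  # parse element/property structure
  elems <- list(); cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        elems[[cur]]$props[[tok[5]]] <- list(list = TRUE, ctype = tok[3], vtype = tok[4])
      else
        elems[[cur]]$props[[tok[3]]] <- list(list = FALSE, vtype = tok[2])
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face)) stop("format error: PLY missing vertex/face elements")
  if (ascii) {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    nv <- elems$vertex$count; nf <- elems$face$count
    pv <- names(elems$vertex$props)
    vdat <- matrix(scan(text = rest[seq_len(nv)], quiet = TRUE), ncol = length(pv), byrow = TRUE)
    colnames(vdat) <- pv
    vertices <- vdat[, c("x", "y", "z"), drop = FALSE]
    faces <- parse_poly_lines(rest[nv + seq_len(nf)])
    return(list(vertices = vertices, faces = to_face_matrix(faces)))
  }
  # binary little-endian
  nv <- elems$vertex$count
  pv <- elems$vertex$props
  sizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2, ushort = 2,
             int16 = 2, uint16 = 2, int = 4, uint = 4, int32 = 4, uint32 = 4,
             float = 4, float32 = 4, double = 8, float64 = 8)
  vrow <- sum(sizes[vapply(pv, function(p) p$vtype, "")])
  vraw <- readBin(con, "raw", n = nv * vrow)
  vertices <- matrix(0, nv, 3)
  offset <- 0
  for (nm in names(pv)) {
    sz <- sizes[[pv[[nm]]$vtype]]
    if (nm %in% c("x", "y", "z")) {
      idx <- as.vector(outer(seq_len(sz) + offset, (seq_len(nv) - 1L) * vrow, "+"))
      col <- readBin(vraw[idx], what = if (sz == 8) "double" else "numeric",
                     size = sz, n = nv, endian = "little")
      vertices[, match(nm, c("x", "y", "z"))] <- col
    }
    offset <- offset + sz
  }
  fp <- elems$face$props[[1]]
  csz <- sizes[[fp$ctype]]; isz <- sizes[[fp$vtype]]
  faces <- vector("list", elems$face$count)
  for (i in seq_len(elems$face$count)) {
    k <- readBin(con, "integer", size = csz, n = 1, endian = "little", signed = csz > 1)
    idx <- readBin(con, "integer", size = isz, n = k, endian = "little") + 1L
    faces[[i]] <- if (k == 3) matrix(idx, 1, 3) else cbind(idx[1], idx[2:(k - 1)], idx[3:k])
  }
  list(vertices = vertices, faces = to_face_matrix(faces))
}

read_bin_line <- function(con) {
  out <- raw()
  repeat {
    ch <- readBin(con, "raw", n = 1)
    if (length(ch) == 0 || ch == as.raw(10)) break
    out <- c(out, ch)
  }
  rawToChar(out)
}

write_ply <- function(mesh, path, binary = TRUE, quality = NULL) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nv),
           sprintf("property double x"), "property double y", "property double z",
           if (!is.null(quality)) "property double quality",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (binary) {
    vdat <- mesh$vertices
    if (!is.null(quality)) vdat <- cbind(vdat, as.numeric(quality))
    writeBin(as.vector(t(vdat)), con, size = 8, endian = "little")
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    vdat <- mesh$vertices
    if (!is.null(quality)) vdat <- cbind(vdat, as.numeric(quality))
    writeBin(charToRaw(paste0(paste(apply(vdat, 1, function(r)
      paste(format(r, digits = 17), collapse = " ")), collapse = "\n"), "\n")), con)
    writeBin(charToRaw(paste0(paste(apply(mesh$faces - 1L, 1, function(r)
      paste(c(3L, r), collapse = " ")), collapse = "\n"), "\n")), con)
  }
}

read_obj <- function(path) {
  txt <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", txt, value = TRUE)
  flines <- grep("^f\\s", txt, value = TRUE)
  if (length(vlines) == 0) stop("format error: OBJ has no vertices")
  vertices <- matrix(scan(text = gsub("^v\\s+", "", vlines), quiet = TRUE), ncol = 3, byrow = TRUE)
  faces <- lapply(flines, function(l) {
    tok <- strsplit(trimws(sub("^f\\s+", "", l)), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[`, "", 1))
    k <- length(idx)
    if (k == 3) matrix(idx, 1, 3) else cbind(idx[1], idx[2:(k - 1)], idx[3:k])
  })
  list(vertices = vertices, faces = to_face_matrix(faces))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(c("v", format(r, digits = 17)), collapse = " ")), con)
  writeLines(apply(mesh$faces, 1, function(r) paste(c("f", r), collapse = " ")), con)
}

read_stl <- function(path) {
  hdr <- readBin(path, "raw", n = 80)
  is_ascii <- grepl("^solid", rawToChar(hdr[1:5]))
  # ascii guess can be wrong for binary files starting with "solid"; verify size
  sz <- file.size(path)
  if (!is_ascii || is_binary_stl(path, sz)) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", size = 4, endian = "little")
    dat <- readBin(con, "raw", n = nf * 50)
    tri <- matrix(0, nf * 3, 3)
    for (i in seq_len(nf)) {
      block <- dat[(i - 1) * 50 + seq_len(48)]
      vals <- readBin(block, "numeric", size = 4, n = 12, endian = "little")
      tri[(i - 1) * 3 + 1:3, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    txt <- readLines(path, warn = FALSE)
    vlines <- grep("vertex", txt, value = TRUE)
    tri <- matrix(scan(text = gsub(".*vertex", "", vlines), quiet = TRUE), ncol = 3, byrow = TRUE)
  }
  nf <- nrow(tri) / 3
  faces <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
  list(vertices = tri, faces = faces)  # duplicates merged by read_mesh
}

is_binary_stl <- function(path, sz) {
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", size = 4, endian = "little")
  isTRUE(sz == 84 + nf * 50)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  nrm <- face_normals_raw(mesh)
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], t(v[f[i, ], ]))), con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid fmorph", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("  outer loop", con)
      for (j in 1:3) {
        p <- v[f[i, j], ]
        writeLines(sprintf("    vertex %.17g %.17g %.17g", p[1], p[2], p[3]), con)
      }
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid fmorph", con)
  }
}

#' Read a collection manifest
#'
#' A manifest is a CSV with columns `id`, `path` and optionally `group`;
#' paths are resolved relative to the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return list with `meshes` (named list of `surface_mesh`) and `groups`
#'   (named character vector or `NULL`).
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "path") %in% names(df))) stop("manifest needs columns id, path")
  dir <- dirname(path)
  meshes <- lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(dir, df$path[i])
    read_mesh(p, id = df$id[i])
  })
  names(meshes) <- df$id
  groups <- if ("group" %in% names(df)) stats::setNames(df$group, df$id) else NULL
  list(meshes = meshes, groups = groups)
}
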