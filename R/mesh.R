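#' Triangulated surface mesh
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented (outward normals by the right-hand rule).
#' @return A `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3 || ncol(faces) != 3)
    stop("vertices and faces must have 3 columns")
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh>", nrow(x$vertices), "vertices,", nrow(x$faces),
      "triangles\n")
  invisible(x)
}

# Directed-edge bookkeeping: a closed, consistently oriented triangulation
# has every undirected edge shared by exactly two triangles with opposite
# direction.
check_closed_oriented <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(edges[, 1], edges[, 2])
  rkey <- paste(edges[, 2], edges[, 1])
  if (any(duplicated(key)))
    stop("mesh is not consistently oriented (repeated directed edge)")
  if (!all(key %in% rkey))
    stop("mesh is not closed (boundary edge found)")
  invisible(TRUE)
}

#' Icosphere fixture
#'
#' Recursively subdivided icosahedron projected onto a sphere: a closed,
#' consistently oriented (outward) triangulation.
#'
#' @param refinement Subdivision level (0 = icosahedron, 20 triangles).
#' @param radius Sphere radius (mm).
#' @return A `surface_mesh`.
#' @export
#' @examples
#' nrow(make_icosphere(0)$faces) # 20
make_icosphere <- function(refinement = 3, radius = 1) {
  if (refinement < 0) stop("refinement must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(refinement)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                    c(ab, bc, ca))
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  surface_mesh(v, f)
}

#' Cavity volume by the divergence theorem
#'
#' Volume of the region enclosed by a closed, consistently outward-oriented
#' triangulated surface under a deformation `phi`, computed as the surface
#' integral `(1/3) \\int x . n ds` (Ostrogradsky formula) over the deformed
#' surface. The reference (identity) volume must be positive, i.e. normals
#' outward.
#'
#' @param mesh A [surface_mesh()].
#' @param deformation A function mapping an n x 3 coordinate matrix to
#'   deformed coordinates, or `NULL` for the reference configuration.
#' @return Enclosed volume (mm^3).
#' @export
#' @examples
#' abs(enclosed_volume(make_icosphere(3)) - 4 * pi / 3) < 0.01 * 4 * pi / 3
enclosed_volume <- function(mesh, deformation = NULL) {
  check_closed_oriented(mesh)
  v <- mesh$vertices
  ref <- signed_volume(v, mesh$faces)
  if (ref <= 0)
    stop("reference volume is non-positive: mesh normals must point ",
         "outward from the enclosed cavity")
  if (is.null(deformation)) return(ref)
  vd <- deformation(v)
  if (!is.matrix(vd) || !all(dim(vd) == dim(v)))
    stop("deformation must return a matrix of the same shape")
  signed_volume(vd, mesh$faces)
}

signed_volume <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Read / write OFF surface meshes
#'
#' Minimal ASCII OFF support for triangle meshes.
#'
#' @param path File path.
#' @return [read_off()] returns a `surface_mesh`; [write_off()] returns the
#'   path invisibly.
#' @export
read_off <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (toupper(ln[1]) != "OFF") stop("not an OFF file")
  hdr <- as.integer(strsplit(ln[2], "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  vtx <- do.call(rbind, lapply(ln[3:(2 + nv)], function(s)
    as.numeric(strsplit(s, "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(ln[(3 + nv):(2 + nv + nf)], function(s) {
    x <- as.integer(strsplit(s, "\\s+")[[1]])
    if (x[1] != 3) stop("only triangle meshes are supported")
    x[2:4] + 1L
  }))
  surface_mesh(vtx, fc)
}

#' @rdname read_off
#' @param mesh A `surface_mesh`.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$faces), 0), con)
  writeLines(apply(mesh$vertices, 1, paste, collapse = " "), con)
  writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                   mesh$faces[, 3] - 1), con)
  invisible(path)
}
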