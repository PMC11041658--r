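#' Triangulated surface mesh
#'
#' Constructs and validates a triangulated surface: vertex coordinates in mm
#' and triangle connectivity. This is the geometric substrate every map metric
#' operates on; validation is strict so downstream code can assume a sane mesh.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in mm, n >= 3.
#' @param triangles integer matrix (m x 3) of 1-based vertex indices, m >= 1.
#'   Each row is one triangle; no row may repeat a vertex and every triangle
#'   must have strictly positive area.
#' @return An object of class \code{tri_mesh}: a list with elements
#'   \code{vertices} and \code{triangles}.
#' @examples
#' m <- tri_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)),
#'               rbind(c(1, 2, 3), c(1, 3, 4)))
#' n_vertices(m)
#' @export
tri_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  if (!is.numeric(vertices) || ncol(vertices) != 3)
    stop("`vertices` must be a numeric n x 3 matrix (mm)")
  if (nrow(vertices) < 3)
    stop("a mesh needs at least 3 vertices, got ", nrow(vertices))
  if (anyNA(vertices) || any(!is.finite(vertices)))
    stop("vertex coordinates must be finite; offending vertex ",
         which(apply(!is.finite(vertices), 1, any))[1])
  if (ncol(triangles) != 3 || nrow(triangles) < 1)
    stop("`triangles` must be an m x 3 index matrix with m >= 1")
  storage.mode(triangles) <- "integer"
  bad <- which(apply(triangles, 1, function(tr)
    anyNA(tr) || any(tr < 1L) || any(tr > nrow(vertices))))
  if (length(bad))
    stop("triangle ", bad[1], " references a vertex outside 1..",
         nrow(vertices))
  bad <- which(apply(triangles, 1, anyDuplicated) > 0)
  if (length(bad))
    stop("triangle ", bad[1], " repeats a vertex")
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  mesh <- structure(list(vertices = vertices, triangles = triangles),
                    class = "tri_mesh")
  areas <- triangle_areas(mesh, check = FALSE)
  if (any(areas <= 0))
    stop("triangle ", which(areas <= 0)[1], " is degenerate (zero area)")
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat("tri_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  ext <- apply(x$vertices, 2, range)
  cat(sprintf("  extent: x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  invisible(x)
}

#' Number of vertices of a mesh or map
#' @param x a \code{tri_mesh} or \code{surface_map}.
#' @return integer vertex count.
#' @export
n_vertices <- function(x) {
  if (inherits(x, "surface_map")) x <- x$mesh
  nrow(x$vertices)
}

#' Per-triangle areas
#'
#' Areas from the cross-product formula, in mm^2.
#'
#' @param mesh a \code{tri_mesh}.
#' @param check internal; skip class checks during construction.
#' @return numeric vector of triangle areas (mm^2), all > 0 for a valid mesh.
#' @export
triangle_areas <- function(mesh, check = TRUE) {
  if (check) mesh <- as_tri_mesh(mesh)
  v <- mesh$vertices
  tr <- mesh$triangles
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

as_tri_mesh <- function(x) {
  if (inherits(x, "tri_mesh")) return(x)
  if (inherits(x, "surface_map")) return(x$mesh)
  stop("expected a tri_mesh or surface_map")
}

#' Unique undirected edges of a mesh
#'
#' @param mesh a \code{tri_mesh} or \code{surface_map}.
#' @return integer matrix (k x 2), each row one undirected edge, smaller index
#'   first, no duplicates.
#' @export
mesh_edges <- function(mesh) {
  mesh <- as_tri_mesh(mesh)
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2), drop = FALSE],
             tr[, c(2, 3), drop = FALSE],
             tr[, c(1, 3), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Euclidean radius neighborhood of a vertex
#'
#' All vertices within a straight-line (3D Euclidean) distance of the given
#' vertex, the neighborhood used by the reentry vulnerability index. The bound
#' is inclusive and the center vertex is excluded.
#'
#' @param map a \code{surface_map} or \code{tri_mesh}.
#' @param vertex vertex index (1-based).
#' @param radius search radius in mm, > 0.
#' @return sorted integer vector of neighbor indices (possibly empty).
#' @export
neighborhood <- function(map, vertex, radius) {
  mesh <- as_tri_mesh(map)
  n <- nrow(mesh$vertices)
  if (length(vertex) != 1 || is.na(vertex) || vertex < 1 || vertex > n)
    stop("vertex index ", vertex, " outside 1..", n)
  if (!is.numeric(radius) || radius <= 0) stop("`radius` must be > 0")
  d2 <- colSums((t(mesh$vertices) - mesh$vertices[vertex, ])^2)
  out <- which(d2 <= radius^2)
  sort(setdiff(out, vertex))
}

#' Project points onto the nearest mesh vertex
#'
#' Assigns each query point to its nearest mesh vertex, rejecting points
#' farther than \code{max_distance} — the external-point filter applied when
#' collating catheter recording sites onto the surface (default cut 7 mm).
#'
#' @param points numeric matrix (k x 3) of query coordinates (mm); k may be 0.
#' @param mesh a \code{tri_mesh}.
#' @param max_distance rejection distance in mm (> 0); \code{Inf} accepts all.
#' @return data.frame with one row per point: \code{point}, \code{vertex}
#'   (NA if rejected), \code{distance} (mm), \code{accepted}.
#' @export
project_points <- function(points, mesh, max_distance = 7) {
  mesh <- as_tri_mesh(mesh)
  points <- matrix(as.numeric(points), ncol = 3)
  if (!is.numeric(max_distance) || max_distance <= 0)
    stop("`max_distance` must be > 0")
  k <- nrow(points)
  if (k == 0)
    return(data.frame(point = integer(0), vertex = integer(0),
                      distance = numeric(0), accepted = logical(0)))
  vt <- t(mesh$vertices)
  vertex <- integer(k)
  distance <- numeric(k)
  for (i in seq_len(k)) {
    d2 <- colSums((vt - points[i, ])^2)
    vertex[i] <- which.min(d2)
    distance[i] <- sqrt(d2[vertex[i]])
  }
  accepted <- distance <= max_distance
  vertex[!accepted] <- NA_integer_
  data.frame(point = seq_len(k), vertex = vertex,
             distance = distance, accepted = accepted)
}
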