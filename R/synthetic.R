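#' Regular triangulated sheet mesh
#'
#' Planar nx x ny grid in the z = 0 plane with each grid cell split into two
#' triangles: (nx ny) vertices and 2 (nx-1)(ny-1) triangles. Vertex (ix, iy)
#' has index (iy-1) nx + ix and coordinates ((ix-1) s, (iy-1) s, 0).
#'
#' @param nx,ny grid dimensions, both >= 2.
#' @param spacing grid spacing in mm, > 0.
#' @return a \code{tri_mesh}.
#' @export
make_sheet_mesh <- function(nx, ny, spacing) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 2 || ny < 2)
    stop("`nx` and `ny` must both be >= 2")
  if (!is.numeric(spacing) || spacing <= 0) stop("`spacing` must be > 0")
  nx <- as.integer(nx); ny <- as.integer(ny)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  vertices <- cbind((g$ix - 1) * spacing, (g$iy - 1) * spacing, 0)
  id <- function(ix, iy) (iy - 1L) * nx + ix
  tris <- vector("list", (nx - 1L) * (ny - 1L))
  k <- 0L
  for (iy in seq_len(ny - 1L)) {
    for (ix in seq_len(nx - 1L)) {
      v00 <- id(ix, iy); v10 <- id(ix + 1L, iy)
      v01 <- id(ix, iy + 1L); v11 <- id(ix + 1L, iy + 1L)
      k <- k + 1L
      tris[[k]] <- rbind(c(v00, v10, v11), c(v00, v11, v01))
    }
  }
  tri_mesh(vertices, do.call(rbind, tris))
}

#' Icosphere mesh
#'
#' Unit icosahedron subdivided \code{subdivisions} times (each triangle into
#' four, midpoints projected back to the sphere), scaled to \code{radius} —
#' a closed-surface stand-in for a cardiac chamber.
#'
#' @param radius sphere radius in mm, > 0.
#' @param subdivisions number of subdivision rounds, >= 0 (0 = icosahedron).
#' @return a \code{tri_mesh}.
#' @export
make_icosphere <- function(radius = 25, subdivisions = 3) {
  if (radius <= 0) stop("`radius` must be > 0")
  if (subdivisions < 0) stop("`subdivisions` must be >= 0")
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
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(midcache[[key]])) return(midcache[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      midcache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- vector("list", nrow(f))
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[[k]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                       c(ab, bc, ca))
    }
    f <- do.call(rbind, nf)
  }
  tri_mesh(v * radius, f)
}

#' Analytic planar-wave activation times
#'
#' LAT(p) = t0 + (n . p) / v for a unit direction n — the exact case the
#' triangulation CV method assumes, used wherever exactness is needed.
#'
#' @param mesh a \code{tri_mesh}.
#' @param direction 3D propagation direction (any nonzero vector; normalized).
#' @param speed wavefront speed in m/s (= mm/ms), > 0.
#' @param t0 activation time offset (ms).
#' @return numeric per-vertex LAT (ms).
#' @export
planar_wave_lat <- function(mesh, direction, speed, t0 = 0) {
  mesh <- as_tri_mesh(mesh)
  direction <- as.numeric(direction)
  nn <- sqrt(sum(direction^2))
  if (!is.finite(nn) || nn == 0) stop("`direction` must be a nonzero vector")
  if (!is.numeric(speed) || speed <= 0) stop("`speed` must be > 0")
  t0 + as.numeric(mesh$vertices %*% (direction / nn)) / speed
}

#' Graph-eikonal activation times on a mesh
#'
#' Shortest arrival time from a set of source vertices by Dijkstra relaxation
#' over the mesh edges. An edge (p, q) costs its length divided by the
#' harmonic mean of the endpoint speeds — i.e. length times the mean slowness
#' — so heterogeneous speed fields (slow patches) are honored. Arrival times
#' slightly exceed the continuum eikonal solution because paths are confined
#' to mesh edges (about <= 8 percent on a diagonal-rich grid).
#'
#' @param mesh a \code{tri_mesh}.
#' @param speeds per-vertex speed field (m/s), all > 0.
#' @param sources integer vector of source vertex indices (LAT 0 there).
#' @return numeric per-vertex LAT (ms); NA at vertices unreachable from every
#'   source.
#' @export
eikonal_lat <- function(mesh, speeds, sources) {
  mesh <- as_tri_mesh(mesh)
  n <- nrow(mesh$vertices)
  speeds <- as.numeric(speeds)
  if (length(speeds) == 1) speeds <- rep(speeds, n)
  if (length(speeds) != n) stop("`speeds` must have one value per vertex")
  if (any(!is.finite(speeds)) || any(speeds <= 0))
    stop("all speeds must be positive and finite")
  sources <- unique(as.integer(sources))
  if (!length(sources) || any(sources < 1 | sources > n))
    stop("`sources` must be a non-empty set of valid vertex indices")
  e <- mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  w <- len * (1 / speeds[e[, 1]] + 1 / speeds[e[, 2]]) / 2
  g <- igraph::make_graph(as.vector(t(e)), n = n, directed = FALSE)
  d <- igraph::distances(g, v = sources, weights = w, algorithm = "dijkstra")
  lat <- apply(d, 2, min)
  lat[!is.finite(lat)] <- NA_real_
  unname(lat)
}

#' Action-potential-duration field with gradient and patches
#'
#' APD(p) = base + gradient . p + sum of patch deltas, where each patch
#' contributes delta cos^2(pi r / (2 R)) inside its radius R (smooth radial
#' falloff, zero at the rim) — the mechanism for repolarization heterogeneity
#' and steep local APD shortening/prolongation.
#'
#' @param mesh a \code{tri_mesh}.
#' @param base baseline APD (ms), > 0.
#' @param gradient 3D linear APD gradient vector (ms/mm), default zero.
#' @param patches list of patches, each \code{list(center, radius, delta)}
#'   (mm, mm, ms).
#' @return numeric per-vertex APD (ms), all > 0 (error otherwise).
#' @export
make_apd_field <- function(mesh, base, gradient = c(0, 0, 0),
                           patches = list()) {
  mesh <- as_tri_mesh(mesh)
  if (!is.numeric(base) || base <= 0) stop("`base` APD must be > 0")
  apd <- base + as.numeric(mesh$vertices %*% as.numeric(gradient))
  for (p in patches) {
    r <- sqrt(colSums((t(mesh$vertices) - as.numeric(p$center))^2))
    inside <- r < p$radius
    apd[inside] <- apd[inside] +
      p$delta * cos(pi * r[inside] / (2 * p$radius))^2
  }
  if (any(apd <= 0))
    stop("APD parameters drive APD <= 0 at vertex ", which(apd <= 0)[1])
  apd
}

# Per-vertex speed field from a base speed plus hard-assignment slow patches.
speed_field <- function(mesh, base_speed, patches = list()) {
  mesh <- as_tri_mesh(mesh)
  if (!is.numeric(base_speed) || base_speed <= 0)
    stop("`base_speed` must be > 0")
  sp <- rep(base_speed, nrow(mesh$vertices))
  for (p in patches) {
    if (!is.numeric(p$speed) || p$speed <= 0)
      stop("patch speeds must be > 0")
    r <- sqrt(colSums((t(mesh$vertices) - as.numeric(p$center))^2))
    sp[r <= p$radius] <- p$speed
  }
  sp
}

# Evaluate an expression with a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
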