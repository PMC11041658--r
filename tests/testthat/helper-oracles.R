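# Shared fixtures and independent oracles used across the suite.

# Two-triangle square sheet, 10 mm side.
square_sheet <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)),
           rbind(c(1, 2, 3), c(1, 3, 4)))
}

# Four collinear vertices spaced 15 mm plus one distant helper vertex so the
# mesh is valid; the helper carries no fields.
collinear_map <- function(lat = c(0, 5, 50, 55), lrt = c(200, 210, 260, 270)) {
  mesh <- tri_mesh(
    rbind(c(0, 0, 0), c(15, 0, 0), c(30, 0, 0), c(45, 0, 0),
          c(22.5, 500, 0)),
    rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5)))
  suppressWarnings(build_surface_map(mesh, lat = c(lat, NA),
                                     lrt = c(lrt, NA)))
}

# Independent all-pairs RVI oracle: full distance matrix via stats::dist and
# a literal min over (LRT' - LAT_D) differences.
rvi_brute <- function(map, radius = 20) {
  ok <- map$valid & !is.na(map$lat) & !is.na(map$lrt)
  lrtc <- map$lrt - stats::median(map$lrt[ok])
  D <- as.matrix(stats::dist(map$mesh$vertices))
  n <- n_vertices(map)
  vals <- rep(NA_real_, n)
  for (p in which(ok)) {
    cand <- which(ok & D[p, ] <= radius)
    cand <- setdiff(cand, p)
    if (length(cand)) vals[p] <- min(lrtc[p] - map$lat[cand])
  }
  vals
}

# Independent edge-max gradient oracle: loops raw triangle rows.
grad_brute <- function(map, field) {
  f <- map[[field]]
  ok <- map$valid & !is.na(f)
  V <- map$mesh$vertices
  tr <- map$mesh$triangles
  n <- n_vertices(map)
  g <- rep(NA_real_, n)
  for (k in seq_len(nrow(tr))) {
    for (pair in list(tr[k, 1:2], tr[k, 2:3], tr[k, c(1, 3)])) {
      i <- pair[1]; j <- pair[2]
      if (!ok[i] || !ok[j]) next
      q <- abs(f[i] - f[j]) / sqrt(sum((V[i, ] - V[j, ])^2))
      if (is.na(g[i]) || q > g[i]) g[i] <- q
      if (is.na(g[j]) || q > g[j]) g[j] <- q
    }
  }
  g
}

# Random triangle with pairwise distances in [d_lo, d_hi], as a 3x3 matrix.
random_triangle <- function(d_lo = 3, d_hi = 20) {
  repeat {
    P <- matrix(stats::runif(9, 0, d_hi), 3, 3)
    d <- as.numeric(stats::dist(P))
    cr <- crossprod3(P[2, ] - P[1, ], P[3, ] - P[1, ])
    if (all(d >= d_lo) && all(d <= d_hi) &&
        0.5 * sqrt(sum(cr^2)) > 2) return(P)
  }
}

# Unit propagation direction inside the triangle's own plane: the wavefront
# travels in the tissue surface, so only tangential directions are physical.
random_inplane_direction <- function(P) {
  e1 <- P[2, ] - P[1, ]
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- P[3, ] - P[1, ]
  e2 <- e2 - sum(e2 * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  phi <- stats::runif(1, 0, 2 * pi)
  cos(phi) * e1 + sin(phi) * e2
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Random map on a jittered sheet with plausible LAT/LRT fields.
random_map <- function(nx, ny, spacing = 6, invalid_frac = 0.05) {
  mesh <- make_sheet_mesh(nx, ny, spacing)
  v <- mesh$vertices
  v <- v + matrix(stats::rnorm(length(v), 0, spacing / 10), ncol = 3)
  mesh <- tri_mesh(v, mesh$triangles)
  n <- nrow(v)
  lat <- as.numeric(v %*% c(1.2, 0.4, 0.1)) + stats::rnorm(n, 0, 4)
  lrt <- lat + stats::runif(n, 150, 320)
  valid <- stats::runif(n) > invalid_frac
  suppressWarnings(build_surface_map(mesh, lat, lrt, valid))
}

# Random 3D rigid transformation (rotation + translation).
random_rigid <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = stats::rnorm(3, 0, 40))
}

apply_rigid <- function(V, tf) {
  sweep(V %*% t(tf$R), 2, -tf$t)
}
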