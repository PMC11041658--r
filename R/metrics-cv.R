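#' Triangulation-based conduction velocity
#'
#' Estimates wavefront speed per mesh triangle from the activation times at
#' its three vertices, assuming a locally planar wavefront. With A the
#' earliest-activated vertex and edges a = AB, b = AC, c = BC:
#' \deqn{\theta = \arccos\left(\frac{|a|^2+|b|^2-|c|^2}{2|a||b|}\right)}
#' \deqn{\tan\alpha = \frac{t_b|a| - t_a|b|\cos\theta}{t_a|b|\sin\theta}}
#' \deqn{v = \frac{|a|\cos\alpha}{t_a}}
#' with \eqn{t_a = LAT(B)-LAT(A)}, \eqn{t_b = LAT(C)-LAT(A)} (ms), lengths in
#' mm, so v is in mm/ms = m/s. \eqn{\alpha} is evaluated with the two-argument
#' arctangent; \eqn{|\alpha| \ge 90°} (wavefront not exiting through edge a)
#' makes the triangle inadmissible.
#'
#' To limit the impact of annotation error, a triangle is admissible only when
#' all three pairwise vertex distances lie in \code{[d_min, d_max]} mm and all
#' three pairwise activation-time differences are at least \code{dt_min} ms.
#'
#' @param map a \code{surface_map} with a \code{lat} field.
#' @param d_min,d_max pairwise distance bounds (mm), defaults 3 and 20.
#' @param dt_min minimum pairwise |LAT difference| (ms), default 3.
#' @return data.frame of class \code{triangle_cv} with one row per triangle:
#'   vertex roles \code{A,B,C}, edge lengths \code{a_len,b_len,c_len} (mm),
#'   \code{t_a,t_b} (ms), angles \code{theta,alpha} (rad), speed \code{v}
#'   (m/s), \code{admissible}, and \code{reason} (one of \code{ok},
#'   \code{invalid_lat}, \code{distance_bound}, \code{dt_bound},
#'   \code{angle_bound}).
#' @export
triangle_cv <- function(map, d_min = 3, d_max = 20, dt_min = 3) {
  stopifnot(inherits(map, "surface_map"))
  if (is.null(map$lat)) stop("conduction velocity needs a `lat` field")
  mesh <- map$mesh
  lat <- map$lat
  latok <- map$valid & !is.na(lat)
  tr <- mesh$triangles
  m <- nrow(tr)
  out <- data.frame(
    triangle = seq_len(m),
    A = NA_integer_, B = NA_integer_, C = NA_integer_,
    a_len = NA_real_, b_len = NA_real_, c_len = NA_real_,
    t_a = NA_real_, t_b = NA_real_,
    theta = NA_real_, alpha = NA_real_, v = NA_real_,
    admissible = FALSE, reason = "ok",
    stringsAsFactors = FALSE)
  V <- mesh$vertices
  for (i in seq_len(m)) {
    idx <- tr[i, ]
    if (!all(latok[idx])) { out$reason[i] <- "invalid_lat"; next }
    # A = earliest activation, ties broken by vertex index order
    ord <- order(lat[idx], idx)
    A <- idx[ord[1]]; rest <- sort(idx[ord[-1]])
    B <- rest[1]; C <- rest[2]
    a_len <- sqrt(sum((V[B, ] - V[A, ])^2))
    b_len <- sqrt(sum((V[C, ] - V[A, ])^2))
    c_len <- sqrt(sum((V[C, ] - V[B, ])^2))
    t_a <- lat[B] - lat[A]
    t_b <- lat[C] - lat[A]
    out[i, c("A", "B", "C")] <- c(A, B, C)
    out[i, c("a_len", "b_len", "c_len")] <- c(a_len, b_len, c_len)
    out[i, c("t_a", "t_b")] <- c(t_a, t_b)
    d <- c(a_len, b_len, c_len)
    if (any(d < d_min) || any(d > d_max)) {
      out$reason[i] <- "distance_bound"; next
    }
    dts <- abs(c(t_a, t_b, lat[C] - lat[B]))
    if (any(dts < dt_min)) { out$reason[i] <- "dt_bound"; next }
    cth <- (a_len^2 + b_len^2 - c_len^2) / (2 * a_len * b_len)
    cth <- min(1, max(-1, cth))
    theta <- acos(cth)
    alpha <- atan2(t_b * a_len - t_a * b_len * cos(theta),
                   t_a * b_len * sin(theta))
    out$theta[i] <- theta
    out$alpha[i] <- alpha
    if (abs(alpha) >= pi / 2) { out$reason[i] <- "angle_bound"; next }
    out$v[i] <- a_len * cos(alpha) / t_a
    out$admissible[i] <- TRUE
  }
  class(out) <- c("triangle_cv", "data.frame")
  out
}

#' Per-vertex conduction velocity
#'
#' Projects triangle speed estimates onto vertices as the arithmetic mean of
#' the admissible triangles incident to each vertex (for display parity with
#' clinical CV maps).
#'
#' @param estimates result of \code{\link{triangle_cv}}.
#' @param mesh the \code{tri_mesh} the estimates were computed on.
#' @return A \code{scalar_field} in m/s; vertices with no admissible incident
#'   triangle are invalid.
#' @export
vertex_cv <- function(estimates, mesh) {
  mesh <- as_tri_mesh(mesh)
  n <- nrow(mesh$vertices)
  acc <- numeric(n)
  cnt <- integer(n)
  adm <- which(estimates$admissible)
  for (i in adm) {
    idx <- mesh$triangles[estimates$triangle[i], ]
    acc[idx] <- acc[idx] + estimates$v[i]
    cnt[idx] <- cnt[idx] + 1L
  }
  v <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  scalar_field(v, cnt > 0, "m/s", list(metric = "vertex_cv"))
}

#' Functional conduction-block regions
#'
#' Marks admissible triangles whose estimated speed falls below the threshold
#' (default 0.2 m/s, the conventional cut for functional block), measures the
#' total blocked area and labels connected components (triangles sharing an
#' edge).
#'
#' @param estimates result of \code{\link{triangle_cv}}.
#' @param mesh the \code{tri_mesh} the estimates were computed on.
#' @param threshold block threshold in m/s, default 0.2.
#' @return A \code{block_region}: list with per-triangle logical \code{mask},
#'   \code{threshold}, \code{area_cm2}, \code{component} (integer label per
#'   triangle, NA outside the mask) and \code{n_components}.
#' @export
detect_block <- function(estimates, mesh, threshold = 0.2) {
  mesh <- as_tri_mesh(mesh)
  m <- nrow(mesh$triangles)
  mask <- rep(FALSE, m)
  mask[estimates$triangle[estimates$admissible & !is.na(estimates$v) &
                            estimates$v < threshold]] <- TRUE
  areas <- triangle_areas(mesh)
  component <- rep(NA_integer_, m)
  ncomp <- 0L
  sel <- which(mask)
  if (length(sel)) {
    # adjacency: blocked triangles sharing an undirected edge
    tr <- mesh$triangles[sel, , drop = FALSE]
    ekey <- function(i, j) paste(pmin(i, j), pmax(i, j))
    keys <- c(ekey(tr[, 1], tr[, 2]), ekey(tr[, 2], tr[, 3]),
              ekey(tr[, 1], tr[, 3]))
    owner <- rep(seq_along(sel), 3)
    dup <- split(owner, keys)
    pairs <- do.call(rbind, lapply(dup[lengths(dup) > 1], function(o)
      t(utils::combn(o, 2))))
    g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
    if (!is.null(pairs) && nrow(pairs))
      g <- igraph::add_edges(g, t(pairs))
    comp <- igraph::components(g)
    component[sel] <- comp$membership
    ncomp <- comp$no
  }
  structure(list(mask = mask, threshold = threshold,
                 area_cm2 = sum(areas[mask]) / 100,
                 component = component, n_components = ncomp),
            class = "block_region")
}

#' @export
print.block_region <- function(x, ...) {
  cat(sprintf(
    "block_region: %d triangles < %.2f m/s, area %.2f cm^2, %d component(s)\n",
    sum(x$mask), x$threshold, x$area_cm2, x$n_components))
  invisible(x)
}
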