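#' Activation-recovery interval (ARI)
#'
#' ARI = LRT - LAT at each vertex, the electrogram surrogate for local action
#' potential duration. Vertices where either time is missing or invalid get an
#' invalid ARI, never a fabricated number.
#'
#' @param map a \code{surface_map} with both \code{lat} and \code{lrt}.
#' @return A \code{scalar_field}: list with \code{values} (ms; NA where
#'   invalid), \code{valid}, \code{units}, \code{provenance}.
#' @export
compute_ari <- function(map) {
  stopifnot(inherits(map, "surface_map"))
  if (is.null(map$lat) || is.null(map$lrt))
    stop("ARI needs both `lat` and `lrt` fields")
  valid <- map$valid & !is.na(map$lat) & !is.na(map$lrt)
  values <- ifelse(valid, map$lrt - map$lat, NA_real_)
  scalar_field(values, valid, "ms", list(metric = "ari"))
}

scalar_field <- function(values, valid, units, provenance = list()) {
  structure(list(values = values, valid = valid, units = units,
                 provenance = provenance),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat("scalar_field (", x$units, "): ", length(x$values), " vertices, ",
      sum(x$valid), " valid\n", sep = "")
  if (any(x$valid))
    cat("  range:", paste(signif(range(x$values[x$valid]), 5),
                          collapse = " .. "), x$units, "\n")
  invisible(x)
}

#' Edge-based spatial gradient of a map field
#'
#' For each vertex p the absolute difference quotient |f(p) - f(q)| / |p - q|
#' is evaluated over every mesh edge meeting p (with q valid), and the
#' gradient at p is the maximum of those quotients. This is the per-vertex
#' dispersion measure used for activation and repolarization gradient maps.
#'
#' @param map a \code{surface_map}.
#' @param field one of \code{"lat"}, \code{"lrt"}, \code{"ari"}.
#' @return A \code{scalar_field} in ms/mm; vertices with no valid neighbor are
#'   invalid.
#' @export
spatial_gradient <- function(map, field = c("lat", "lrt", "ari")) {
  stopifnot(inherits(map, "surface_map"))
  field <- match.arg(field)
  f <- map_field(map, field)
  mesh <- map$mesh
  e <- mesh_edges(mesh)
  ok <- f$valid[e[, 1]] & f$valid[e[, 2]]
  e <- e[ok, , drop = FALSE]
  n <- n_vertices(map)
  g <- rep(NA_real_, n)
  if (nrow(e)) {
    len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
    q <- abs(f$values[e[, 1]] - f$values[e[, 2]]) / len
    for (k in seq_along(q)) {
      i <- e[k, 1]; j <- e[k, 2]
      if (is.na(g[i]) || q[k] > g[i]) g[i] <- q[k]
      if (is.na(g[j]) || q[k] > g[j]) g[j] <- q[k]
    }
  }
  scalar_field(g, !is.na(g), "ms/mm",
               list(metric = "spatial_gradient", field = field))
}

#' Map-level summary of activation and repolarization
#'
#' Ranges (max - min over valid vertices) of LAT and LRT — the activation
#' delay and the dispersion of repolarization — plus the ARI median and range.
#'
#' @param map a \code{surface_map} with at least one field.
#' @return list with \code{lat_range_ms}, \code{lrt_range_ms},
#'   \code{ari_median_ms}, \code{ari_range_ms}, \code{n_valid}; entries are NA
#'   where the underlying field is absent.
#' @export
summarize_map <- function(map) {
  stopifnot(inherits(map, "surface_map"))
  if (is.null(map$lat) && is.null(map$lrt))
    stop("map has neither `lat` nor `lrt`")
  if (!any(map$valid)) stop("map has no valid vertices")
  rng <- function(field) {
    f <- map[[field]]
    if (is.null(f)) return(NA_real_)
    v <- f[map$valid & !is.na(f)]
    if (!length(v)) return(NA_real_)
    diff(range(v))
  }
  ari_median <- ari_range <- NA_real_
  if (!is.null(map$lat) && !is.null(map$lrt)) {
    ari <- compute_ari(map)
    if (any(ari$valid)) {
      ari_median <- stats::median(ari$values[ari$valid])
      ari_range <- diff(range(ari$values[ari$valid]))
    }
  }
  list(lat_range_ms = rng("lat"), lrt_range_ms = rng("lrt"),
       ari_median_ms = ari_median, ari_range_ms = ari_range,
       n_valid = sum(map$valid))
}

#' Bazett-corrected QT interval
#'
#' QTc = QT / sqrt(RR) with RR expressed in seconds; inputs in ms.
#'
#' @param qt_ms QT interval (ms), > 0. Vectorized.
#' @param rr_ms RR interval (ms), > 0. Vectorized.
#' @return QTc in ms.
#' @examples
#' qtc_bazett(440, 640)  # 550 ms
#' @export
qtc_bazett <- function(qt_ms, rr_ms) {
  if (any(!is.finite(qt_ms)) || any(qt_ms <= 0))
    stop("`qt_ms` must be positive and finite")
  if (any(!is.finite(rr_ms)) || any(rr_ms <= 0))
    stop("`rr_ms` must be positive and finite")
  qt_ms / sqrt(rr_ms / 1000)
}
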