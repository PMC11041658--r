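#' Reentry vulnerability index (RVI)
#'
#' Per-vertex RVI with cycle-length correction: after subtracting the median
#' LRT from all LRTs (LRT' = LRT - median LRT),
#' \deqn{RVI_P = \min_{D} (LRT'_P - LAT_D)}
#' over all sites D within a Euclidean \code{radius} of P (default 20 mm,
#' excluding P itself). Low RVI marks sites where a wavefront can find
#' recovered tissue close to still-late-repolarizing tissue — the substrate
#' for reentry. LAT stays in the map's declared time reference; only LRT is
#' median-centered.
#'
#' @param map a \code{surface_map} with valid \code{lat} and \code{lrt} at two
#'   or more vertices.
#' @param radius neighborhood radius in mm, default 20.
#' @param percentile fraction for the global summary, default 0.10.
#' @return An \code{rvi_result}: list with per-vertex \code{values} (ms, NA
#'   where undefined), \code{valid}, \code{global_ms} (the
#'   \code{percentile}-quantile of the valid values, linear interpolation
#'   between order statistics) and \code{params}.
#' @export
compute_rvi <- function(map, radius = 20, percentile = 0.10) {
  stopifnot(inherits(map, "surface_map"))
  if (is.null(map$lat) || is.null(map$lrt))
    stop("RVI needs both `lat` and `lrt` fields")
  if (!is.numeric(radius) || radius <= 0) stop("`radius` must be > 0")
  ok <- map$valid & !is.na(map$lat) & !is.na(map$lrt)
  if (sum(ok) < 2) stop("RVI needs at least 2 valid vertices")
  n <- n_vertices(map)
  lrt_med <- stats::median(map$lrt[ok])
  lrtc <- map$lrt - lrt_med
  V <- map$mesh$vertices
  values <- rep(NA_real_, n)
  # RVI_P = LRT'_P - max_D LAT_D over valid D within radius; chunked distance
  # computation keeps memory flat on large maps.
  donors <- which(ok)
  Vd <- V[donors, , drop = FALSE]
  latd <- map$lat[donors]
  r2 <- radius^2
  for (p in which(ok)) {
    d2 <- (Vd[, 1] - V[p, 1])^2 + (Vd[, 2] - V[p, 2])^2 +
      (Vd[, 3] - V[p, 3])^2
    inside <- d2 <= r2 & donors != p
    if (any(inside)) values[p] <- lrtc[p] - max(latd[inside])
  }
  valid <- !is.na(values)
  structure(list(values = values, valid = valid,
                 global_ms = if (any(valid))
                   rvi_percentile(values[valid], percentile) else NA_real_,
                 params = list(radius_mm = radius, percentile = percentile,
                               lrt_median_offset_ms = lrt_med)),
            class = "rvi_result")
}

rvi_percentile <- function(x, q) {
  # linear interpolation between order statistics, h = (n-1) q
  stats::quantile(x, probs = q, type = 7, names = FALSE)
}

#' Global RVI summary
#'
#' The global RVI is a low quantile (default the 10th percentile) of the
#' per-vertex RVI distribution — a robust stand-in for the map's minimum RVI.
#' Quantiles interpolate linearly between order statistics (h = (n-1)q).
#'
#' @param result an \code{rvi_result} from \code{\link{compute_rvi}}.
#' @param percentile quantile fraction, default 0.10.
#' @return global RVI in ms.
#' @export
global_rvi <- function(result, percentile = 0.10) {
  stopifnot(inherits(result, "rvi_result"))
  x <- result$values[result$valid]
  if (!length(x)) stop("no valid RVI values")
  rvi_percentile(x, percentile)
}

#' @export
print.rvi_result <- function(x, ...) {
  cat(sprintf(
    "rvi_result: %d valid vertices, global RVI %.1f ms (radius %g mm, q=%g)\n",
    sum(x$valid), x$global_ms, x$params$radius_mm, x$params$percentile))
  invisible(x)
}

#' Full substrate metric record for one map
#'
#' Runs the whole metric pipeline (ARI, gradients, conduction velocity, block
#' area, RVI) with the standard parameter set and collects the map-level
#' quantities into one machine-readable record — the unit the before/after
#' drug comparison operates on.
#'
#' @param map a \code{surface_map}.
#' @param rvi_radius RVI neighborhood radius (mm), default 20.
#' @param block_threshold block speed threshold (m/s), default 0.2.
#' @param percentile global-RVI quantile, default 0.10.
#' @param cv_bounds list with \code{d_min}, \code{d_max} (mm) and
#'   \code{dt_min} (ms) admissibility bounds.
#' @return A \code{map_metrics} list: \code{global_rvi_ms},
#'   \code{block_area_cm2}, \code{block_components}, \code{lat_range_ms},
#'   \code{lrt_range_ms}, \code{ari_median_ms}, gradient maxima
#'   (\code{grad_lat_max}, \code{grad_lrt_max}, ms/mm), \code{n_valid},
#'   \code{params}. Metrics whose inputs are absent are NA, never fabricated.
#' @export
analyze_map <- function(map, rvi_radius = 20, block_threshold = 0.2,
                        percentile = 0.10,
                        cv_bounds = list(d_min = 3, d_max = 20, dt_min = 3)) {
  stopifnot(inherits(map, "surface_map"))
  smry <- summarize_map(map)
  has_lat <- !is.null(map$lat)
  has_lrt <- !is.null(map$lrt)
  grad_max <- function(field) {
    g <- spatial_gradient(map, field)
    if (any(g$valid)) max(g$values[g$valid]) else NA_real_
  }
  block_area <- block_comp <- global <- NA_real_
  grad_lat <- grad_lrt <- NA_real_
  if (has_lat) {
    est <- triangle_cv(map, cv_bounds$d_min, cv_bounds$d_max, cv_bounds$dt_min)
    blk <- detect_block(est, map$mesh, block_threshold)
    block_area <- blk$area_cm2
    block_comp <- blk$n_components
    grad_lat <- grad_max("lat")
  }
  if (has_lrt) grad_lrt <- grad_max("lrt")
  if (has_lat && has_lrt)
    global <- compute_rvi(map, rvi_radius, percentile)$global_ms
  structure(list(
    global_rvi_ms = global,
    block_area_cm2 = block_area,
    block_components = block_comp,
    lat_range_ms = smry$lat_range_ms,
    lrt_range_ms = smry$lrt_range_ms,
    ari_median_ms = smry$ari_median_ms,
    grad_lat_max = grad_lat,
    grad_lrt_max = grad_lrt,
    n_valid = smry$n_valid,
    params = list(rvi_radius_mm = rvi_radius,
                  block_threshold_m_s = block_threshold,
                  percentile = percentile, cv_bounds = cv_bounds)),
    class = "map_metrics")
}

#' @export
print.map_metrics <- function(x, ...) {
  cat(sprintf(paste0(
    "map_metrics: global RVI %.1f ms | block %.2f cm^2 (%s comp) | ",
    "LAT range %.1f ms | LRT range %.1f ms\n"),
    x$global_rvi_ms, x$block_area_cm2, format(x$block_components),
    x$lat_range_ms, x$lrt_range_ms))
  invisible(x)
}

#' Before/after map comparison
#'
#' Absolute and percent change of the headline substrate metrics between two
#' analyses of the same heart (e.g. baseline vs. after drug). Percent change
#' is 100 (post - pre) / |pre|. For global RVI an algebraic increase (toward
#' less negative values) means a less vulnerable substrate and is reported as
#' improvement; a decrease as worsening.
#'
#' @param pre,post \code{map_metrics} records from \code{\link{analyze_map}}.
#' @return list with, per metric (\code{global_rvi_ms}, \code{lat_range_ms},
#'   \code{lrt_range_ms}, \code{block_area_cm2}): \code{pre}, \code{post},
#'   \code{change}, \code{percent} (NA when pre is 0); plus \code{verdict}
#'   ("improvement", "worsening" or "unchanged") driven by the global RVI.
#' @export
compare_maps <- function(pre, post) {
  stopifnot(inherits(pre, "map_metrics"), inherits(post, "map_metrics"))
  if (is.na(pre$global_rvi_ms) || is.na(post$global_rvi_ms))
    stop("both maps must have a computable global RVI")
  one <- function(name) {
    a <- pre[[name]]; b <- post[[name]]
    list(pre = a, post = b, change = b - a,
         percent = if (!is.na(a) && a != 0) 100 * (b - a) / abs(a)
                   else NA_real_)
  }
  delta <- one("global_rvi_ms")
  verdict <- if (delta$change > 0) "improvement"
             else if (delta$change < 0) "worsening" else "unchanged"
  list(global_rvi_ms = delta,
       lat_range_ms = one("lat_range_ms"),
       lrt_range_ms = one("lrt_range_ms"),
       block_area_cm2 = one("block_area_cm2"),
       verdict = verdict)
}
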