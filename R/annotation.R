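#' Unipolar electrogram
#'
#' A uniformly sampled unipolar signal at one mapped site.
#'
#' @param samples_mv numeric vector of sample values (mV), at least 3, finite.
#' @param fs_hz sampling rate (Hz), > 0.
#' @param site_id site identifier (character or integer).
#' @param t_start_ms time of the first sample in the map's time reference
#'   (ms), default 0.
#' @param position optional 3D coordinates of the recording site (mm).
#' @return An \code{electrogram} object.
#' @export
electrogram <- function(samples_mv, fs_hz, site_id = NA, t_start_ms = 0,
                        position = NULL) {
  samples_mv <- as.numeric(samples_mv)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0)
    stop("`fs_hz` must be a single positive number")
  if (length(samples_mv) < 3) stop("an electrogram needs at least 3 samples")
  if (any(!is.finite(samples_mv)))
    stop("sample values must be finite (sample ",
         which(!is.finite(samples_mv))[1], ")")
  if (!is.null(position)) position <- as.numeric(position)[1:3]
  structure(list(samples_mv = samples_mv, fs_hz = fs_hz, site_id = site_id,
                 t_start_ms = t_start_ms, position = position),
            class = "electrogram")
}

#' @export
print.electrogram <- function(x, ...) {
  cat(sprintf("electrogram site %s: %d samples @ %g Hz, t = [%g, %g] ms\n",
              format(x$site_id), length(x$samples_mv), x$fs_hz,
              x$t_start_ms, x$t_start_ms +
                (length(x$samples_mv) - 1) * 1000 / x$fs_hz))
  invisible(x)
}

egm_times <- function(egm) {
  egm$t_start_ms + (seq_along(egm$samples_mv) - 1) * 1000 / egm$fs_hz
}

#' Annotation windows
#'
#' Global activation and repolarization search windows (ms, map time
#' reference). The repolarization window should span the whole T wave so the
#' maximum-upslope rule works regardless of T polarity; windows must not
#' overlap.
#'
#' @param activation numeric length-2, activation window (ms).
#' @param repolarization numeric length-2, repolarization window (ms).
#' @return An \code{annotation_windows} object.
#' @export
annotation_windows <- function(activation, repolarization) {
  chk <- function(w, name) {
    w <- as.numeric(w)
    if (length(w) != 2 || any(!is.finite(w)) || w[2] <= w[1])
      stop("`", name, "` must be c(start, end) with end > start")
    w
  }
  activation <- chk(activation, "activation")
  repolarization <- chk(repolarization, "repolarization")
  if (max(activation[1], repolarization[1]) <
      min(activation[2], repolarization[2]))
    stop("activation and repolarization windows may not overlap")
  structure(list(activation = activation, repolarization = repolarization),
            class = "annotation_windows")
}

# Shared slope-extremum annotator. sign = -1: most negative dV/dt (LAT);
# sign = +1: most positive dV/dt (LRT, Wyatt rule). Ties -> earliest sample.
annotate_extremum <- function(egm, window, sign, smooth_ms = 0) {
  stopifnot(inherits(egm, "electrogram"))
  window <- as.numeric(window)
  t <- egm_times(egm)
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1e-9)
    stop("window [", window[1], ", ", window[2],
         "] is outside the trace span [", t[1], ", ", t[length(t)], "]")
  s <- egm$samples_mv
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms * egm$fs_hz / 1000))
    if (w %% 2 == 0) w <- w + 1L
    if (w > 1) {
      sm <- stats::filter(s, rep(1 / w, w), sides = 2)
      keep <- !is.na(sm)
      s[keep] <- sm[keep]
    }
  }
  n <- length(s)
  dt <- 1000 / egm$fs_hz
  d <- rep(NA_real_, n)
  d[2:(n - 1)] <- (s[3:n] - s[1:(n - 2)]) / (2 * dt)
  cand <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9 & !is.na(d))
  flags <- character(0)
  if (!length(cand))
    return(list(time_ms = NA_real_, flags = "empty_window"))
  dv <- sign * d[cand]
  if (max(dv) - min(dv) < 1e-12 && abs(max(dv)) < 1e-12)
    return(list(time_ms = NA_real_, flags = "flat"))
  best <- cand[which.max(dv)]          # which.max: earliest on ties
  if (best == cand[1] || best == cand[length(cand)])
    flags <- c(flags, "edge")
  list(time_ms = t[best], flags = flags)
}

#' Annotate local activation time (LAT)
#'
#' LAT is the time of the most negative first time-derivative (-dV/dt
#' extremum) of the unipolar electrogram within the activation window,
#' evaluated with central finite differences on the raw trace (an optional
#' moving-average pre-smoothing is off by default). Ties go to the earliest
#' sample; an extremum on the window edge is flagged; a flat signal yields no
#' annotation.
#'
#' @param egm an \code{electrogram}.
#' @param window numeric length-2 activation window (ms) or an
#'   \code{annotation_windows} object.
#' @param smooth_ms moving-average width in ms applied before
#'   differentiation; 0 (default) disables smoothing.
#' @return list with \code{time_ms} (NA if not annotatable) and \code{flags}
#'   (character vector; may include \code{"edge"}, \code{"flat"},
#'   \code{"empty_window"}).
#' @export
annotate_lat <- function(egm, window, smooth_ms = 0) {
  if (inherits(window, "annotation_windows")) window <- window$activation
  annotate_extremum(egm, window, sign = -1, smooth_ms = smooth_ms)
}

#' Annotate local recovery time (LRT, Wyatt rule)
#'
#' LRT is the time of the most positive first time-derivative (+dV/dt
#' extremum) within the repolarization window. Because the maximum upslope is
#' taken over the whole T-wave window, the rule is independent of T-wave
#' polarity. Same tie-break, edge and flat handling as
#' \code{\link{annotate_lat}}.
#'
#' @inheritParams annotate_lat
#' @param window numeric length-2 repolarization window (ms) or an
#'   \code{annotation_windows} object.
#' @return list with \code{time_ms} and \code{flags}.
#' @export
annotate_lrt <- function(egm, window, smooth_ms = 0) {
  if (inherits(window, "annotation_windows")) window <- window$repolarization
  annotate_extremum(egm, window, sign = +1, smooth_ms = smooth_ms)
}

#' Annotate a whole map of electrograms
#'
#' Runs LAT and LRT annotation on every electrogram, assigns each site to a
#' mesh vertex (by the electrogram's recorded position through
#' \code{\link{project_points}} with the external-point cut, or by explicit
#' vertex ids) and assembles a \code{surface_map}. Sites whose annotation
#' raised a flag, whose projection was rejected, or where LRT <= LAT are kept
#' but marked invalid, mirroring manual review that discards equivocal sites.
#'
#' @param egms list of \code{electrogram} objects.
#' @param windows an \code{annotation_windows} object.
#' @param mesh a \code{tri_mesh}.
#' @param vertex_ids optional integer vector assigning each electrogram to a
#'   vertex; when NULL, electrogram positions are projected onto the mesh.
#' @param max_distance projection rejection distance (mm), default 7.
#' @param smooth_ms optional pre-smoothing width (ms) for both annotations.
#' @param meta metadata list for the resulting map.
#' @return A \code{surface_map} with \code{lat}, \code{lrt} and validity.
#' @export
annotate_map <- function(egms, windows, mesh, vertex_ids = NULL,
                         max_distance = 7, smooth_ms = 0, meta = list()) {
  stopifnot(inherits(windows, "annotation_windows"))
  mesh <- as_tri_mesh(mesh)
  n <- nrow(mesh$vertices)
  if (!length(egms)) stop("no electrograms supplied")
  if (is.null(vertex_ids)) {
    pos <- t(vapply(egms, function(e) {
      if (is.null(e$position))
        stop("electrogram ", format(e$site_id),
             " has no position and no explicit vertex id")
      e$position
    }, numeric(3)))
    proj <- project_points(pos, mesh, max_distance)
    vertex_ids <- proj$vertex
  } else if (length(vertex_ids) != length(egms)) {
    stop("`vertex_ids` must match the number of electrograms")
  }
  lat <- rep(NA_real_, n)
  lrt <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  n_annotated <- 0L
  for (i in seq_along(egms)) {
    vid <- vertex_ids[i]
    if (is.na(vid)) next  # projection rejected
    a <- annotate_lat(egms[[i]], windows, smooth_ms = smooth_ms)
    r <- annotate_lrt(egms[[i]], windows, smooth_ms = smooth_ms)
    lat[vid] <- a$time_ms
    lrt[vid] <- r$time_ms
    clean <- !length(a$flags) && !length(r$flags) &&
      !is.na(a$time_ms) && !is.na(r$time_ms)
    valid[vid] <- clean
    if (clean) n_annotated <- n_annotated + 1L
  }
  if (n_annotated == 0L)
    stop("no electrogram produced a clean annotation; map would be empty")
  suppressWarnings(
    build_surface_map(mesh, lat = lat, lrt = lrt, valid = valid, meta = meta))
}

#' Flag isolated outlier annotations
#'
#' A local, scale-free screen for isolated annotation outliers: a vertex is
#' flagged when its field value deviates from the median of its ring-1 mesh
#' neighbors by more than \code{k} times the map-wide median absolute
#' edge-difference of that field. Vertices with fewer than 3 valid ring-1
#' neighbors are never flagged (insufficient evidence). Flagged vertices
#' become invalid.
#'
#' @param map a \code{surface_map}.
#' @param field \code{"lat"} or \code{"lrt"}.
#' @param k threshold multiplier, default 5.
#' @return list with \code{map} (updated validity) and \code{flagged}
#'   (indices of newly invalidated vertices).
#' @export
flag_outliers <- function(map, field = c("lat", "lrt"), k = 5) {
  stopifnot(inherits(map, "surface_map"))
  field <- match.arg(field)
  f <- map[[field]]
  if (is.null(f)) stop("map has no `", field, "` field")
  ok <- map$valid & !is.na(f)
  e <- mesh_edges(map$mesh)
  e <- e[ok[e[, 1]] & ok[e[, 2]], , drop = FALSE]
  flagged <- integer(0)
  if (nrow(e)) {
    scale <- stats::median(abs(f[e[, 1]] - f[e[, 2]]))
    nb <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
    for (v in which(ok)) {
      ns <- nb[[as.character(v)]]
      if (is.null(ns) || length(ns) < 3) next
      if (abs(f[v] - stats::median(f[ns])) > k * scale)
        flagged <- c(flagged, v)
    }
  }
  map$valid[flagged] <- FALSE
  list(map = map, flagged = flagged)
}
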