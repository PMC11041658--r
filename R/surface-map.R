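#' Surface map: mesh plus per-vertex activation/recovery fields
#'
#' Bundles a triangulated surface with per-vertex local activation time (LAT,
#' ms) and local recovery time (LRT, ms) and a validity mask, the structure of
#' a clinical electroanatomical map export. Times are in the map's declared
#' reference (e.g. the pacing spike at 0 ms). A vertex where both times are
#' present but LRT <= LAT is physiologically impossible and is marked invalid
#' rather than kept.
#'
#' @param mesh a \code{tri_mesh}.
#' @param lat per-vertex activation times (ms); NA where missing. NULL if the
#'   field was not acquired.
#' @param lrt per-vertex recovery times (ms); NA where missing. NULL if absent.
#' @param valid optional logical mask of a-priori usable vertices (e.g. sites
#'   that survived manual review); combined with internal consistency checks.
#' @param meta list of acquisition metadata: \code{chamber}, \code{protocol}
#'   (e.g. "S4"), \code{time_ref}, \code{cycle_length_ms}.
#' @return A \code{surface_map}: list with \code{mesh}, \code{lat}, \code{lrt},
#'   \code{valid}, \code{meta}.
#' @examples
#' m <- tri_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)),
#'               rbind(c(1, 2, 3), c(1, 3, 4)))
#' sm <- build_surface_map(m, lat = c(0, 5, 10, 15),
#'                         lrt = c(200, 205, 210, 215))
#' sum(sm$valid)
#' @export
build_surface_map <- function(mesh, lat = NULL, lrt = NULL, valid = NULL,
                              meta = list()) {
  mesh <- as_tri_mesh(mesh)
  n <- nrow(mesh$vertices)
  check_field <- function(f, name) {
    if (is.null(f)) return(NULL)
    f <- as.numeric(f)
    if (length(f) != n)
      stop("`", name, "` has length ", length(f),
           " but the mesh has ", n, " vertices")
    if (any(is.infinite(f)))
      stop("`", name, "` must be finite; offending vertex ",
           which(is.infinite(f))[1])
    f
  }
  lat <- check_field(lat, "lat")
  lrt <- check_field(lrt, "lrt")
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (length(valid) != n)
    stop("`valid` has length ", length(valid), " but the mesh has ",
         n, " vertices")
  valid <- as.logical(valid) & !is.na(valid)
  if (!is.null(lat)) valid <- valid & !is.na(lat)
  if (!is.null(lrt)) valid <- valid & !is.na(lrt)
  if (!is.null(lat) && !is.null(lrt)) {
    bad <- valid & !is.na(lat) & !is.na(lrt) & (lrt <= lat)
    if (any(bad)) {
      warning(sum(bad), " vertex/vertices with LRT <= LAT marked invalid ",
              "(first: vertex ", which(bad)[1], ")")
      valid[bad] <- FALSE
    }
  }
  structure(list(mesh = mesh, lat = lat, lrt = lrt, valid = valid,
                 meta = meta),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat("surface_map:", n_vertices(x), "vertices (",
      sum(x$valid), "valid ),", nrow(x$mesh$triangles), "triangles\n")
  fields <- c(if (!is.null(x$lat)) "lat", if (!is.null(x$lrt)) "lrt")
  cat("  fields:", if (length(fields)) paste(fields, collapse = ", ")
      else "(none)", "\n")
  if (length(x$meta)) {
    tags <- vapply(x$meta, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  meta:", paste(names(tags), tags, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

# Extract a named per-vertex field, computing ARI on demand.
map_field <- function(map, field = c("lat", "lrt", "ari")) {
  field <- match.arg(field)
  if (field == "ari") {
    ari <- compute_ari(map)
    return(list(values = ari$values, valid = ari$valid))
  }
  f <- map[[field]]
  if (is.null(f)) stop("map has no `", field, "` field")
  list(values = f, valid = map$valid & !is.na(f))
}
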