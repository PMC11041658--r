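#' Write a surface map to the interchange format
#'
#' Canonical interchange is a single JSON document carrying a mandatory units
#' declaration, the mesh (with its declared triangle index base), the
#' per-vertex fields and the acquisition metadata. A CSV dialect for
#' spreadsheet workflows writes \code{<base>_vertices.csv},
#' \code{<base>_triangles.csv} (1-based indices), \code{<base>_fields.csv}
#' and \code{<base>_meta.json} (units, index base, metadata). Missing field
#' values are written as JSON null / empty CSV cells, never sentinel numbers.
#' Numeric values are written at full precision so write -> read round-trips
#' bit-for-bit.
#'
#' @param map a \code{surface_map}.
#' @param path output path: a \code{.json} file (JSON format) or a base path
#'   without suffix (CSV format).
#' @param format \code{"json"} or \code{"csv"}; default guessed from
#'   \code{path} extension.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_map}}
#' @export
write_map <- function(map, path, format = NULL) {
  stopifnot(inherits(map, "surface_map"))
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") write_map_json(map, path) else write_map_csv(map, path)
  invisible(path)
}

MAP_SCHEMA_VERSION <- 1L

write_map_json <- function(map, path) {
  doc <- list(
    schema = "eam-map",
    version = MAP_SCHEMA_VERSION,
    units = list(length = "mm", time = "ms"),
    index_base = 0L,
    vertices = unname(split(map$mesh$vertices,
                            row(map$mesh$vertices))),
    triangles = unname(split(map$mesh$triangles - 1L,
                             row(map$mesh$triangles))),
    fields = Filter(Negate(is.null), list(
      lat = map$lat, lrt = map$lrt, valid = map$valid)),
    meta = map$meta)
  # digits = I(17): decimal text that reparses to the identical double
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       null = "null", na = "null", pretty = FALSE)
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

write_map_csv <- function(map, base) {
  v <- map$mesh$vertices
  utils::write.csv(
    data.frame(id = seq_len(nrow(v)), x = fmt_num(v[, 1]),
               y = fmt_num(v[, 2]), z = fmt_num(v[, 3])),
    paste0(base, "_vertices.csv"), row.names = FALSE, quote = FALSE)
  tr <- map$mesh$triangles
  utils::write.csv(
    data.frame(id = seq_len(nrow(tr)), v1 = tr[, 1], v2 = tr[, 2],
               v3 = tr[, 3]),
    paste0(base, "_triangles.csv"), row.names = FALSE, quote = FALSE)
  fields <- data.frame(id = seq_len(nrow(v)))
  if (!is.null(map$lat)) fields$lat <- fmt_num(map$lat)
  if (!is.null(map$lrt)) fields$lrt <- fmt_num(map$lrt)
  fields$valid <- as.integer(map$valid)
  utils::write.csv(fields, paste0(base, "_fields.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(schema = "eam-map", version = MAP_SCHEMA_VERSION,
         units = list(length = "mm", time = "ms"), index_base = 1L,
         meta = map$meta),
    paste0(base, "_meta.json"), digits = NA, auto_unbox = TRUE)
  invisible(base)
}

#' Read a surface map from the interchange format
#'
#' Reads the JSON document or CSV dialect written by \code{\link{write_map}}.
#' The units declaration is mandatory — a document without one is rejected,
#' never silently assumed. Triangle indices are normalized from the file's
#' declared base to the internal 1-based convention; vertices are never
#' reordered.
#'
#' @param path a \code{.json} file or a CSV base path.
#' @param format \code{"json"} or \code{"csv"}; default guessed from
#'   \code{path}.
#' @return a \code{surface_map}.
#' @export
read_map <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") read_map_json(path) else read_map_csv(path)
}

check_units <- function(units, where) {
  if (is.null(units) || is.null(units$length) || is.null(units$time))
    stop(where, ": missing mandatory `units` declaration")
  if (!identical(units$length, "mm") || !identical(units$time, "ms"))
    stop(where, ": unsupported units (need length=mm, time=ms), got ",
         units$length, "/", units$time)
}

num_or_na <- function(x) {
  vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
         numeric(1))
}

read_map_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::read_json(path)
  check_units(doc$units, path)
  vertices <- do.call(rbind, lapply(doc$vertices, num_or_na))
  if (is.null(vertices)) stop(path, ": no vertices")
  if (anyNA(vertices))
    stop(path, ": non-finite vertex coordinate at vertex ",
         which(apply(is.na(vertices), 1, any))[1])
  base <- if (is.null(doc$index_base)) 0L else as.integer(doc$index_base)
  triangles <- do.call(rbind, lapply(doc$triangles, function(tr)
    as.integer(unlist(tr)))) - base + 1L
  mesh <- tri_mesh(vertices, triangles)
  f <- doc$fields
  lat <- if (!is.null(f$lat)) num_or_na(f$lat)
  lrt <- if (!is.null(f$lrt)) num_or_na(f$lrt)
  valid <- if (!is.null(f$valid))
    vapply(f$valid, function(v) isTRUE(v) || identical(v, 1L) ||
             identical(v, 1), logical(1))
  meta <- if (is.null(doc$meta)) list() else doc$meta
  suppressWarnings(
    build_surface_map(mesh, lat = lat, lrt = lrt, valid = valid, meta = meta))
}

read_map_csv <- function(base) {
  meta_path <- paste0(base, "_meta.json")
  if (!file.exists(meta_path))
    stop("no such file: ", meta_path,
         " (the CSV dialect requires the meta sidecar with units)")
  metadoc <- jsonlite::read_json(meta_path)
  check_units(metadoc$units, meta_path)
  idx_base <- if (is.null(metadoc$index_base)) 1L
              else as.integer(metadoc$index_base)
  vdf <- utils::read.csv(paste0(base, "_vertices.csv"))
  if (anyNA(vdf$x) || anyNA(vdf$y) || anyNA(vdf$z))
    stop(base, "_vertices.csv: non-finite coordinate at record ",
         which(is.na(vdf$x) | is.na(vdf$y) | is.na(vdf$z))[1])
  tdf <- utils::read.csv(paste0(base, "_triangles.csv"))
  mesh <- tri_mesh(cbind(vdf$x, vdf$y, vdf$z),
                   cbind(tdf$v1, tdf$v2, tdf$v3) - idx_base + 1L)
  fdf <- utils::read.csv(paste0(base, "_fields.csv"))
  lat <- if ("lat" %in% names(fdf)) as.numeric(fdf$lat)
  lrt <- if ("lrt" %in% names(fdf)) as.numeric(fdf$lrt)
  valid <- if ("valid" %in% names(fdf)) fdf$valid == 1
  meta <- if (is.null(metadoc$meta)) list() else metadoc$meta
  suppressWarnings(
    build_surface_map(mesh, lat = lat, lrt = lrt, valid = valid, meta = meta))
}

#' Export a map to VTK or PLY with per-vertex scalars
#'
#' Writes the mesh with selected per-vertex fields attached, for inspection
#' in standard 3D viewers (ParaView and friends). VTK is legacy ASCII
#' POLYDATA with one SCALARS array per field; PLY is ASCII with one float
#' vertex property per field. Field values at invalid vertices are written as
#' -1e30 (VTK has no null).
#'
#' @param map a \code{surface_map}.
#' @param path output file path.
#' @param format \code{"vtk"} or \code{"ply"}; default guessed from
#'   extension.
#' @param fields character vector of fields to attach: any of \code{"lat"},
#'   \code{"lrt"}, \code{"ari"} or the name of an extra per-vertex numeric
#'   vector passed via \code{extra}.
#' @param extra named list of additional per-vertex numeric vectors (e.g. a
#'   computed \code{rvi} field).
#' @return \code{path}, invisibly.
#' @export
export_mesh <- function(map, path, format = NULL,
                        fields = character(0), extra = list()) {
  stopifnot(inherits(map, "surface_map"))
  if (is.null(format))
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "vtk"
  format <- match.arg(format, c("vtk", "ply"))
  n <- n_vertices(map)
  get_field <- function(name) {
    if (name %in% names(extra)) {
      v <- as.numeric(extra[[name]])
      if (length(v) != n) stop("extra field `", name, "` has wrong length")
      return(v)
    }
    if (name %in% c("lat", "lrt", "ari")) {
      f <- map_field(map, name)
      v <- f$values
      v[!f$valid] <- NA_real_
      return(v)
    }
    stop("unknown field: ", name)
  }
  vals <- lapply(fields, get_field)
  names(vals) <- fields
  sentinel <- -1e30
  vals <- lapply(vals, function(v) ifelse(is.na(v), sentinel, v))
  if (format == "vtk") write_vtk(map$mesh, vals, path)
  else write_ply(map$mesh, vals, path)
  invisible(path)
}

write_vtk <- function(mesh, vals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  tr <- mesh$triangles
  writeLines(c("# vtk DataFile Version 3.0",
               "electroanatomical surface map", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4 * nrow(tr)), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L,
                     tr[, 3] - 1L), con)
  if (length(vals)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(vals)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", vals[[nm]]), con)
    }
  }
}

write_ply <- function(mesh, vals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices
  tr <- mesh$triangles
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("property float %s", names(vals)),
               sprintf("element face %d", nrow(tr)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  cols <- cbind(v, do.call(cbind, c(vals, list(deparse.level = 0))))
  writeLines(apply(cols, 1, function(r) paste(sprintf("%.9g", r),
                                              collapse = " ")), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L,
                     tr[, 3] - 1L), con)
}

#' Read a table of unipolar electrograms
#'
#' CSV with a leading time column (\code{time_ms}) and one column per site.
#' Sampling must be uniform; the sampling rate is inferred from the time
#' step. Non-monotonic or gapped time axes are rejected.
#'
#' @param path CSV file path.
#' @return list of \code{electrogram} objects, one per site column.
#' @export
read_egm_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop(path, ": need a time column plus >= 1 site column")
  t <- as.numeric(df[[1]])
  if (length(t) < 3) stop(path, ": fewer than 3 samples")
  dt <- diff(t)
  if (any(dt <= 0)) stop(path, ": time column is not strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop(path, ": non-uniform sampling (gap near row ",
         which.max(abs(dt - stats::median(dt))) + 1, ")")
  fs <- 1000 / stats::median(dt)
  lapply(names(df)[-1], function(nm)
    electrogram(df[[nm]], fs_hz = fs, site_id = nm, t_start_ms = t[1]))
}

#' Write a metric record to JSON
#'
#' Serializes an \code{analyze_map} record or \code{compare_maps} result to a
#' machine-readable JSON report with units embedded in the field names.
#'
#' @param x a \code{map_metrics} record or comparison list.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, digits = NA, auto_unbox = TRUE,
                       na = "null", pretty = TRUE)
  invisible(path)
}
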