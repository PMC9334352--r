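#' Read a localization table
#'
#' Reads a delimited text table (comma or tab, auto-detected) with a header
#' row and returns a [loc_set()]. Columns other than the coordinate columns
#' (frame numbers, intensities, ...) are ignored. Rows with non-finite
#' coordinates are dropped and their count reported.
#'
#' @param path Path to the delimited file.
#' @param columns Named character vector mapping `x`, `y` (and optionally `z`)
#'   to column names in the file. If `z` is not mapped but a `z` column
#'   exists, it is used automatically.
#' @param unit_scale Factor applied to coordinates on ingest so that the
#'   result is in nm (e.g. 1000 for a table recorded in micrometres).
#' @param channel,image_id Labels stored on the returned set; `image_id`
#'   defaults to the file name.
#' @return A [loc_set()] in nm. The number of dropped rows is attached as
#'   attribute `"n_dropped"`.
#' @export
read_localizations <- function(path, columns = c(x = "x", y = "y"),
                               unit_scale = 1, channel = "",
                               image_id = basename(path)) {
  if (!file.exists(path))
    stop("localization file not found: ", path, call. = FALSE)
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("x", "y") %in% names(columns)))
    stop("`columns` must map at least x and y", call. = FALSE)
  if (!"z" %in% names(columns) && "z" %in% names(tab))
    columns <- c(columns, z = "z")
  missing_cols <- setdiff(unname(columns), names(tab))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  coords <- as.matrix(tab[, unname(columns[c("x", "y", "z")[
    c("x", "y", "z") %in% names(columns)]]), drop = FALSE])
  storage.mode(coords) <- "double"
  keep <- stats::complete.cases(coords) & apply(is.finite(coords), 1L, all)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with non-finite coordinates dropped from ",
            basename(path))
  coords <- coords[keep, , drop = FALSE]
  if (nrow(coords) == 0L)
    stop("no valid localizations in ", path, call. = FALSE)
  out <- loc_set(coords * unit_scale, channel = channel, image_id = image_id)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a localization table
#'
#' Writes the coordinates of a [loc_set()] as a CSV with `x,y(,z)` header,
#' in nm, at full double precision.
#'
#' @param points A [loc_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(points, path) {
  stopifnot(inherits(points, "loc_set"))
  data.table::fwrite(as.data.frame(points$coords), path)
  invisible(path)
}

#' Polygonal region of interest (2D)
#'
#' @param vertices An n x 2 matrix of polygon vertices in nm, in order, not
#'   closed (the last vertex connects back to the first). The polygon must be
#'   simple (non-self-intersecting) with positive area.
#' @return An object of class `roi` (subtype polygon).
#' @export
roi_polygon <- function(vertices) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("a polygon ROI needs an n x 2 vertex matrix with n >= 3", call. = FALSE)
  if (!all(is.finite(vertices))) stop("ROI vertices must be finite", call. = FALSE)
  if (self_intersects(vertices))
    stop("ROI polygon is self-intersecting", call. = FALSE)
  measure <- abs(pracma::polyarea(vertices[, 1], vertices[, 2]))
  if (measure <= 0) stop("ROI polygon has zero area", call. = FALSE)
  structure(list(type = "polygon", vertices = vertices, measure = measure,
                 dim = 2L), class = "roi")
}

#' Axis-aligned box region of interest
#'
#' @param lo,hi Numeric vectors of length 2 or 3 with the lower and upper
#'   corner in nm; `hi` must exceed `lo` on every axis.
#' @return An object of class `roi` (subtype box).
#' @export
roi_box <- function(lo, hi) {
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  d <- length(lo)
  if (length(hi) != d || !d %in% c(2L, 3L))
    stop("lo and hi must both have length 2 or 3", call. = FALSE)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi <= lo))
    stop("box ROI must have finite positive extent on every axis", call. = FALSE)
  structure(list(type = "box", lo = lo, hi = hi, measure = prod(hi - lo),
                 dim = as.integer(d)), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  unit <- if (x$dim == 2L) "nm^2" else "nm^3"
  cat(sprintf("<roi> %s, %dD, measure %.6g %s\n", x$type, x$dim, x$measure, unit))
  invisible(x)
}

#' Measure (area or volume) of an ROI
#' @param roi An [roi_polygon()] or [roi_box()].
#' @return Area in nm^2 (2D) or volume in nm^3 (3D).
#' @export
roi_measure <- function(roi) {
  stopifnot(inherits(roi, "roi"))
  roi$measure
}

#' Read an ROI from file
#'
#' A `.json` file is read as a box spec (`{"lo": [...], "hi": [...]}`); any
#' other delimited file is read as a table of polygon vertices with `x,y`
#' columns.
#'
#' @param path Path to the ROI file.
#' @return An `roi` object.
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!all(c("lo", "hi") %in% names(spec)))
      stop("JSON ROI must contain 'lo' and 'hi'", call. = FALSE)
    return(roi_box(spec$lo, spec$hi))
  }
  tab <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("x", "y") %in% names(tab)))
    stop("polygon ROI file must have x and y columns", call. = FALSE)
  roi_polygon(cbind(tab$x, tab$y))
}

#' Clip localizations to a region of interest
#'
#' Retains points inside the ROI; points exactly on the boundary count as
#' inside.
#'
#' @param points A [loc_set()].
#' @param roi An `roi` of matching dimensionality.
#' @return A `loc_set` of the retained points, with attribute `"n_clipped"`
#'   giving the number removed.
#' @export
clip_to_roi <- function(points, roi) {
  stopifnot(inherits(points, "loc_set"), inherits(roi, "roi"))
  d <- loc_dim(points)
  if (d != roi$dim)
    stop("ROI dimensionality (", roi$dim, ") does not match points (", d, ")",
         call. = FALSE)
  xy <- points$coords
  if (roi$type == "polygon") {
    inside <- sp::point.in.polygon(xy[, 1], xy[, 2],
                                   roi$vertices[, 1], roi$vertices[, 2]) > 0
  } else {
    inside <- rep(TRUE, nrow(xy))
    for (k in seq_len(d))
      inside <- inside & xy[, k] >= roi$lo[k] & xy[, k] <= roi$hi[k]
  }
  if (!any(inside))
    stop("no localizations inside the ROI", call. = FALSE)
  out <- loc_set(xy[inside, , drop = FALSE],
                 channel = points$channel, image_id = points$image_id)
  attr(out, "n_clipped") <- sum(!inside)
  out
}

# O(n^2) proper-intersection test between non-adjacent polygon edges
self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i || j == i %% n + 1L || i == j %% n + 1L) next
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross2(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross2(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross2(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross2(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}
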