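#' Voronoi tessellation of a reference channel
#'
#' Partitions the plane (2D) or space (3D) into one Voronoi region per
#' reference localization: the set of points closer to that localization than
#' to any other. Regions extending to infinity (edge regions) are flagged
#' unbounded and carry no measure; bounded regions get their exact polygon
#' area (nm^2) or convex polytope volume (nm^3). Region adjacency (shared
#' Voronoi facets, equivalently Delaunay edges) and the mean distance from
#' each seed to its adjacent seeds (the NND density proxy) are computed at the
#' same time.
#'
#' Edge regions are excluded from enrichment analysis on two grounds, both
#' artifacts of the finite field of view: cells of infinite measure
#' (`finite = FALSE`), and finite cells that protrude beyond the observation
#' window (minus sampling). The second matters because seeds just inside the
#' convex hull can own finite cells whose vertices - circumcentres of sliver
#' simplices - lie far outside the imaged region; their measures are real
#' but reflect unobserved space, and a handful of them can dominate the
#' total measure and bias every enrichment score upwards. The working flag
#' `bounded` marks regions that pass both checks and enter the analysis.
#'
#' @param reference A [loc_set()] (or bare coordinate matrix) of the reference
#'   species. At least d + 2 non-degenerate seeds are required and exact
#'   duplicate seeds are an error unless `dedupe = TRUE` (duplicates usually
#'   indicate uncorrected multi-blinking, which should be fixed upstream).
#' @param total_measure Optional override of the total analysed measure used
#'   in the expected-count calculation, e.g. an ROI area from
#'   [roi_measure()]. Defaults to the sum of included region measures.
#' @param dedupe Merge exact duplicate seeds instead of failing.
#' @param window Observation window for the minus-sampling edge exclusion:
#'   a 2 x d matrix (rows: lower and upper corner, in nm), an [roi_box()],
#'   or `NULL` (default) for the bounding box of the seeds. Cells with any
#'   vertex outside the window are flagged as edge regions.
#' @param margin_factor Half-width of the working bounding box used for cell
#'   construction, in multiples of the seed extent (enlarged automatically
#'   for far-reaching cells).
#' @return An object of class `voronoi_tessellation`: a list with `seeds`,
#'   per-region `bounded` (included in analysis), `finite` (cell of finite
#'   measure), `measure`, `neighbors`, `nnd`, the cell `polygons`, and
#'   `total_measure`.
#' @examples
#' seeds <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
#' tess <- tessellate(loc_set(seeds))
#' tess$measure   # only the central region is bounded, area 0.5
#' @export
tessellate <- function(reference, total_measure = NULL, dedupe = FALSE,
                       window = NULL, margin_factor = 10) {
  reference <- as_loc_set(reference)
  coords <- reference$coords
  d <- ncol(coords)
  dup <- duplicated(coords)
  if (any(dup)) {
    if (!dedupe)
      stop(sum(dup), " duplicate seed(s); duplicated localizations usually ",
           "mean uncorrected multi-blinking (fix upstream) - or pass ",
           "dedupe = TRUE to merge them", call. = FALSE)
    coords <- coords[!dup, , drop = FALSE]
    reference <- loc_set(coords, channel = reference$channel,
                         image_id = reference$image_id)
  }
  n <- nrow(coords)
  if (n < d + 2L)
    stop("need at least ", d + 2L, " distinct seeds for a ", d,
         "D tessellation", call. = FALSE)
  sv <- svd(scale(coords, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[d] < 1e-9 * sv[1])
    stop("degenerate seed geometry: points are ",
         if (d == 2L) "collinear" else "coplanar", call. = FALSE)

  res <- cpp_voronoi(coords, margin_factor = margin_factor,
                     return_vertices = TRUE)
  # minus-sampling window: cells poking outside it are edge regions
  if (inherits(window, "roi")) {
    if (window$type != "box")
      stop("only box windows are supported for edge exclusion", call. = FALSE)
    window <- rbind(window$lo, window$hi)
  }
  if (is.null(window)) {
    window <- apply(coords, 2L, range)
  } else {
    window <- as.matrix(window)
    if (!all(dim(window) == c(2L, d)) || any(window[2L, ] <= window[1L, ]))
      stop("window must be a 2 x ", d, " matrix of finite corners with ",
           "positive extent", call. = FALSE)
  }
  wtol <- 1e-9 * max(window[2L, ] - window[1L, ])
  in_window <- vapply(seq_len(n), function(i) {
    if (!res$bounded[i]) return(FALSE)
    v <- res$vertices[[i]]
    all(v >= rep(window[1L, ] - wtol, each = nrow(v)) &
        v <= rep(window[2L, ] + wtol, each = nrow(v)))
  }, logical(1))
  included <- res$bounded & in_window
  # symmetrize adjacency (facet detection is per-cell; take the union)
  nb <- res$neighbors
  for (i in seq_len(n))
    for (j in nb[[i]])
      if (!i %in% nb[[j]]) nb[[j]] <- sort(c(nb[[j]], i))
  nnd <- vapply(seq_len(n), function(i) {
    js <- nb[[i]]
    if (!length(js)) return(NA_real_)
    mean(sqrt(colSums((t(coords[js, , drop = FALSE]) - coords[i, ])^2)))
  }, numeric(1))

  if (!is.null(total_measure) && (!is.finite(total_measure) || total_measure <= 0))
    stop("total_measure override must be a positive number", call. = FALSE)
  structure(list(seeds = reference,
                 bounded = included,
                 finite = res$bounded,
                 measure = res$measure,
                 neighbors = nb,
                 nnd = nnd,
                 polygons = res$vertices,
                 window = window,
                 dim = d,
                 total_measure = total_measure %||%
                   sum(res$measure[included]),
                 roi_override = !is.null(total_measure)),
            class = "voronoi_tessellation")
}

#' @export
print.voronoi_tessellation <- function(x, ...) {
  unit <- if (x$dim == 2L) "nm^2" else "nm^3"
  cat(sprintf(paste0("<voronoi_tessellation> %dD, %d regions ",
                     "(%d bounded, %d edge), total measure %.6g %s%s\n"),
              x$dim, length(x$bounded), sum(x$bounded), sum(!x$bounded),
              x$total_measure, unit,
              if (x$roi_override) " (ROI override)" else ""))
  invisible(x)
}

#' Mean distance to Voronoi-adjacent seeds
#'
#' For each region, the arithmetic mean of Euclidean distances from its seed
#' to all Voronoi-adjacent seeds (natural neighbours, including seeds of edge
#' regions). This one-dimensional local-density proxy scales as
#' measure^(1/d) and is the recommended binning axis for enrichment profiles.
#'
#' @param tess A [tessellate()] result.
#' @return Numeric vector of per-region NND in nm.
#' @export
mean_neighbor_distance <- function(tess) {
  stopifnot(inherits(tess, "voronoi_tessellation"))
  tess$nnd
}

#' Indices of regions included in the analysis
#'
#' Edge regions (unbounded cells, and finite cells protruding beyond the
#' observation window) are discarded from all enrichment calculations,
#' together with the primary localizations they contain; this returns the
#' region indices that remain.
#'
#' @param tess A [tessellate()] result.
#' @return Integer vector of region indices.
#' @export
included_regions <- function(tess) {
  stopifnot(inherits(tess, "voronoi_tessellation"))
  idx <- which(tess$bounded)
  if (!length(idx))
    stop("no bounded regions: every Voronoi cell is an edge region, ",
         "nothing to analyse", call. = FALSE)
  idx
}

#' Per-region table of a tessellation
#'
#' @param x A [tessellate()] result.
#' @param ... Unused.
#' @return A data frame with one row per region: seed index and coordinates,
#'   boundedness, measure (NA for edge regions) and NND.
#' @export
as.data.frame.voronoi_tessellation <- function(x, ...) {
  coords <- x$seeds$coords
  df <- data.frame(region = seq_len(nrow(coords)), coords,
                   bounded = x$bounded, measure = x$measure, nnd = x$nnd)
  rownames(df) <- NULL
  df
}
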