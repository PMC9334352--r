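#' Localization set
#'
#' A set of molecular localizations from one SMLM channel: an n x d coordinate
#' matrix in nanometres (d = 2 or 3) plus a channel label and an image
#' identifier used for per-image statistics.
#'
#' @param coords Numeric matrix or data frame with 2 or 3 columns (x, y\[, z\])
#'   in nm.
#' @param channel Channel label, e.g. the fluorophore or protein name.
#' @param image_id Identifier of the image the localizations came from.
#' @return An object of class `loc_set`.
#' @examples
#' ls <- loc_set(cbind(runif(10), runif(10)), channel = "ch1")
#' n_localizations(ls)
#' @export
loc_set <- function(coords, channel = "", image_id = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  d <- ncol(coords)
  if (!d %in% c(2L, 3L))
    stop("coordinates must have 2 or 3 columns (x, y[, z])", call. = FALSE)
  if (nrow(coords) < 1L)
    stop("a localization set needs at least one point", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("coordinates must all be finite", call. = FALSE)
  colnames(coords) <- c("x", "y", "z")[seq_len(d)]
  structure(list(coords = coords,
                 channel = as.character(channel),
                 image_id = as.character(image_id)),
            class = "loc_set")
}

#' @export
print.loc_set <- function(x, ...) {
  cat(sprintf("<loc_set> %d localizations, %dD%s%s\n",
              nrow(x$coords), ncol(x$coords),
              if (nzchar(x$channel)) paste0(", channel '", x$channel, "'") else "",
              if (nzchar(x$image_id)) paste0(", image '", x$image_id, "'") else ""))
  invisible(x)
}

#' Number of localizations in a set
#' @param x A [loc_set()].
#' @return Integer count.
#' @export
n_localizations <- function(x) {
  stopifnot(inherits(x, "loc_set"))
  nrow(x$coords)
}

#' Dimensionality of a localization set
#' @param x A [loc_set()].
#' @return 2 or 3.
#' @export
loc_dim <- function(x) {
  stopifnot(inherits(x, "loc_set"))
  ncol(x$coords)
}

#' Project a 3D localization set onto the xy plane
#'
#' Drops the z coordinate, mimicking what a 2D acquisition of the same sample
#' would record. x and y are unchanged and the point count is preserved.
#'
#' @param points A 3D [loc_set()].
#' @return A 2D `loc_set`.
#' @export
project_to_2d <- function(points) {
  stopifnot(inherits(points, "loc_set"))
  if (loc_dim(points) != 3L)
    stop("project_to_2d() requires a 3D localization set", call. = FALSE)
  loc_set(points$coords[, 1:2, drop = FALSE],
          channel = points$channel, image_id = points$image_id)
}

as_loc_set <- function(x, channel = "", image_id = "") {
  if (inherits(x, "loc_set")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(read_localizations(x, channel = channel, image_id = image_id))
  loc_set(x, channel = channel, image_id = image_id)
}
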