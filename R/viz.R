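# RE colour mapping: symmetric in log2 around RE = 1, so a two-fold
# enrichment and a two-fold depletion sit at equal distance from the centre
# colour. Limits default to the 2nd-98th percentile of |log2 RE|, clipped.
re_limits <- function(re) {
  lre <- log2(re[is.finite(re) & re > 0])
  if (!length(lre)) return(1)
  lim <- as.numeric(quantile(abs(lre), 0.98))
  if (!is.finite(lim) || lim <= 0) lim <- 1
  lim
}

re_fill_scale <- function(lim, aesthetics = "fill") {
  ggplot2::scale_fill_gradient2(
    low = "#2166AC", mid = "#F7F7F7", high = "#B2182B", midpoint = 0,
    limits = c(-lim, lim), oob = scales::squish,
    name = expression(log[2] ~ RE),
    aesthetics = aesthetics)
}

save_or_return <- function(p, path, width = 6, height = 5) {
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}

#' Map of Voronoi regions colour-coded by RE
#'
#' Draws the bounded reference regions as filled polygons coloured by their
#' RE score on a diverging scale centred at RE = 1 (log2-symmetric).
#' Unbounded edge regions are omitted. 2D only; use [render_point_map()] for
#' 3D data.
#'
#' @param tess A 2D [tessellate()] result.
#' @param re Per-region RE scores, e.g. `region_enrichment(...)$re`.
#' @param path Optional output file (png/pdf/svg); when `NULL` the ggplot
#'   object is returned.
#' @param limit Optional symmetric limit for `|log2 RE|`.
#' @return The ggplot object (invisibly when written to `path`).
#' @export
render_region_map <- function(tess, re, path = NULL, limit = NULL) {
  stopifnot(inherits(tess, "voronoi_tessellation"))
  if (tess$dim != 2L)
    stop("region maps are 2D only; use render_point_map() for 3D data",
         call. = FALSE)
  if (length(re) != length(tess$bounded))
    stop("re must have one value per region", call. = FALSE)
  idx <- which(tess$bounded & is.finite(re))
  polys <- do.call(rbind, lapply(idx, function(i) {
    v <- tess$polygons[[i]]
    data.frame(region = i, x = v[, 1], y = v[, 2],
               lre = log2(max(re[i], .Machine$double.xmin)))
  }))
  lim <- limit %||% re_limits(re)
  p <- ggplot2::ggplot(polys, ggplot2::aes(x = .data$x, y = .data$y,
                                           group = .data$region,
                                           fill = .data$lre)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.1) +
    re_fill_scale(lim) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
  save_or_return(p, path)
}

#' Scatter map of reference localizations colour-coded by RE
#'
#' Plots each reference localization coloured by its region's RE score,
#' avoiding the visual domination of large sparse regions that polygon maps
#' suffer from. For 3D data a projection plane can be chosen (`"xz"`/`"yz"`
#' give side views with z on the vertical axis).
#'
#' @param points The reference [loc_set()] (the tessellation seeds).
#' @param re Per-localization (= per-region) RE scores.
#' @param path Optional output file.
#' @param view `"xy"` (default), `"xz"` or `"yz"`; side views need 3D data.
#' @param limit Optional symmetric limit for `|log2 RE|`.
#' @param point_size Dot size.
#' @return The ggplot object (invisibly when written to `path`).
#' @export
render_point_map <- function(points, re, path = NULL,
                             view = c("xy", "xz", "yz"), limit = NULL,
                             point_size = 0.6) {
  points <- as_loc_set(points)
  view <- match.arg(view)
  if (length(re) != n_localizations(points))
    stop("re must have one value per localization", call. = FALSE)
  if (view != "xy" && loc_dim(points) != 3L)
    stop("side views require 3D data", call. = FALSE)
  ax <- switch(view, xy = c("x", "y"), xz = c("x", "z"), yz = c("y", "z"))
  keep <- is.finite(re)
  df <- data.frame(h = points$coords[keep, ax[1]],
                   v = points$coords[keep, ax[2]],
                   lre = log2(pmax(re[keep], .Machine$double.xmin)))
  lim <- limit %||% re_limits(re)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$h, y = .data$v,
                                        colour = .data$lre)) +
    ggplot2::geom_point(size = point_size) +
    re_fill_scale(lim, aesthetics = "colour") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(ax[1], "(nm)"), y = paste(ax[2], "(nm)")) +
    ggplot2::theme_minimal()
  save_or_return(p, path)
}

#' Enrichment profile plot with density histogram
#'
#' The standard presentation of an enrichment analysis: mean RE per bin as a
#' line (with SEM ribbon for condition profiles) on the left axis, the
#' relative bin occupancy of the reference species as a histogram on the
#' right axis, and a dashed guide at RE = 1. Optionally marks bins that
#' differ significantly between two conditions.
#'
#' @param profiles A single [build_profile()] / [aggregate_profiles()] result
#'   or a (optionally named) list of condition profiles sharing bin edges.
#' @param path Optional output file.
#' @param significance Optional [compare_conditions()] result; significant
#'   bins are marked along the top of the panel.
#' @param require_shared_edges Insist that all profiles share bin edges
#'   (the default; set `FALSE` when overlaying the two directions of a swap
#'   analysis, whose NND axes legitimately differ).
#' @return The ggplot object (invisibly when written to `path`).
#' @export
plot_profile <- function(profiles, path = NULL, significance = NULL,
                         require_shared_edges = TRUE) {
  if (inherits(profiles, c("enrichment_profile", "condition_profile")))
    profiles <- list(profiles)
  if (!length(profiles)) stop("empty profile list", call. = FALSE)
  nms <- names(profiles) %||% paste0("profile ", seq_along(profiles))
  nms[nms == ""] <- paste0("profile ", which(nms == ""))
  edges <- attr(profiles[[1L]], "bin_edges")
  if (require_shared_edges)
    for (p in profiles[-1L])
      if (!isTRUE(all.equal(attr(p, "bin_edges"), edges)))
        stop("profiles do not share bin edges", call. = FALSE)
  df <- do.call(rbind, lapply(seq_along(profiles), function(k) {
    p <- profiles[[k]]
    data.frame(condition = nms[k], bin_mid = p$bin_mid, mean_re = p$mean_re,
               sem = if ("sem" %in% names(p)) p$sem else NA_real_,
               region_fraction = p$region_fraction)
  }))
  if (all(is.na(df$mean_re))) stop("profile has no occupied bins", call. = FALSE)
  ymax <- max(df$mean_re + ifelse(is.na(df$sem), 0, df$sem), 1, na.rm = TRUE)
  fmax <- max(df$region_fraction, na.rm = TRUE)
  k <- if (is.finite(fmax) && fmax > 0) ymax / fmax else 1
  hist_df <- df[df$condition == nms[1L], ]
  width <- diff(edges[1:2]) * 0.9
  xlab <- if (identical(attr(profiles[[1L]], "bin_mode"), "log_area"))
    expression(log[10] ~ "region measure") else "mean neighbour distance (nm)"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid)) +
    ggplot2::geom_col(data = hist_df,
                      ggplot2::aes(y = .data$region_fraction * k),
                      width = width, fill = "grey80", colour = NA) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40")
  has_sem <- any(is.finite(df$sem))
  if (has_sem)
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_re - .data$sem,
                   ymax = .data$mean_re + .data$sem,
                   group = .data$condition, fill = .data$condition),
      alpha = 0.25, colour = NA, na.rm = TRUE)
  p <- p + ggplot2::geom_line(
    ggplot2::aes(y = .data$mean_re, colour = .data$condition), na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_re,
                                     colour = .data$condition),
                        size = 0.8, na.rm = TRUE)
  if (!is.null(significance)) {
    sig <- significance[significance$significant, , drop = FALSE]
    if (nrow(sig))
      p <- p + ggplot2::geom_point(data = data.frame(bin_mid = sig$bin_mid),
                                   ggplot2::aes(x = .data$bin_mid,
                                                y = ymax * 1.05),
                                   shape = 15, size = 1.5, colour = "black")
  }
  p <- p +
    ggplot2::scale_y_continuous(
      name = "mean RE",
      sec.axis = ggplot2::sec_axis(~ . / k, name = "relative bin occupancy")) +
    ggplot2::labs(x = xlab, colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
  if (length(profiles) == 1L)
    p <- p + ggplot2::theme(legend.position = "none")
  save_or_return(p, path)
}

#' Depth (z) distribution of 3D species
#'
#' Kernel-smoothed z-density of each species, with the z axis shifted so the
#' reference species' modal depth sits at 0 (e.g. depth normalised to the
#' peak transporter position).
#'
#' @param sets A named list of 3D [loc_set()]s.
#' @param normalization Index or name of the reference set whose modal depth
#'   defines z = 0.
#' @param path Optional output file.
#' @return The ggplot object (invisibly when written to `path`); the applied
#'   shift is attached as attribute `"z_shift"`.
#' @export
depth_profile <- function(sets, normalization = 1L, path = NULL) {
  if (inherits(sets, "loc_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1L)
  if (any(vapply(sets, loc_dim, integer(1)) != 3L))
    stop("depth profiles require 3D localization sets", call. = FALSE)
  nms <- names(sets) %||% vapply(sets, function(s) s$channel, character(1))
  nms[!nzchar(nms)] <- paste0("species ", which(!nzchar(nms)))
  ref <- sets[[normalization]]
  dref <- density(ref$coords[, 3])
  shift <- dref$x[which.max(dref$y)]
  df <- do.call(rbind, lapply(seq_along(sets), function(k) {
    d <- density(sets[[k]]$coords[, 3] - shift)
    data.frame(species = nms[k], z = d$x, dens = d$y)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$dens,
                                        colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "depth relative to reference mode (nm)", y = "density",
                  colour = NULL) +
    ggplot2::theme_minimal()
  attr(p, "z_shift") <- shift
  save_or_return(p, path)
}
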