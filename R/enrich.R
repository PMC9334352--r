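#' Assign primary localizations to reference regions
#'
#' Each primary localization belongs to the Voronoi cell of its nearest
#' reference seed. Primaries falling in unbounded (edge) regions are
#' discarded from all totals; exact ties between seeds are broken towards the
#' lowest seed index so the assignment is deterministic.
#'
#' @param tess A [tessellate()] result for the reference species.
#' @param primary A [loc_set()] of the primary species, same dimensionality.
#' @return A list of class `primary_assignment`: `observed` (per-region
#'   counts; only bounded regions enter any total), `region_of` (per-primary
#'   region index), `retained` (logical, primary not discarded),
#'   `n_retained`, `n_discarded`.
#' @export
assign_primaries <- function(tess, primary) {
  stopifnot(inherits(tess, "voronoi_tessellation"))
  primary <- as_loc_set(primary)
  if (loc_dim(primary) != tess$dim)
    stop("primary dimensionality (", loc_dim(primary),
         ") does not match tessellation (", tess$dim, ")", call. = FALSE)
  ref <- tess$seeds$coords
  k <- min(nrow(ref), 4L)
  nn <- RANN::nn2(ref, primary$coords, k = k)
  assigned <- nn$nn.idx[, 1L]
  if (k > 1L) {
    d1 <- nn$nn.dists[, 1L]
    tol <- 1e-9 * pmax(d1, 1) # ties at floating-point resolution
    tied <- nn$nn.dists <= d1 + tol
    idx <- nn$nn.idx
    idx[!tied] <- NA_integer_
    assigned <- do.call(pmin, c(lapply(seq_len(k), function(j) idx[, j]),
                                list(na.rm = TRUE)))
  }
  retained <- tess$bounded[assigned]
  observed <- tabulate(assigned[retained], nbins = length(tess$bounded))
  structure(list(observed = observed, region_of = assigned,
                 retained = retained,
                 n_retained = sum(retained),
                 n_discarded = sum(!retained)),
            class = "primary_assignment")
}

#' Expected primary count per region
#'
#' The count expected under complete spatial randomness of the primary
#' species over the analysed area: the region's share of the total measure
#' times the total number of (retained) primary localizations.
#'
#' @param measure Per-region measure (nm^2 or nm^3), or a
#'   [tessellate()] result (in which case its measures and total are used).
#' @param total_measure Total analysed measure; ignored when `measure` is a
#'   tessellation (its `total_measure`, possibly an ROI override, is used).
#' @param n_primary_total Total number of primary localizations surviving the
#'   edge-region discard.
#' @return Numeric vector of expected counts.
#' @examples
#' # region of 0.24 um^2 in 1.3 um^2 total with 20 primaries:
#' expected_counts(0.24, 1.3, 20)  # 3.7 localizations
#' @export
expected_counts <- function(measure, total_measure = NULL, n_primary_total) {
  if (inherits(measure, "voronoi_tessellation")) {
    total_measure <- total_measure %||% measure$total_measure
    measure <- measure$measure
  }
  if (is.null(total_measure) || !is.finite(total_measure) || total_measure <= 0)
    stop("total_measure must be a positive number", call. = FALSE)
  if (n_primary_total < 0) stop("n_primary_total must be >= 0", call. = FALSE)
  measure / total_measure * n_primary_total
}

#' Relative enrichment score
#'
#' The ratio of observed to expected primary counts in a region. RE = 1 is
#' the random expectation; values below 1 indicate depletion and values above
#' 1 enrichment of the primary species near reference localizations of that
#' density.
#'
#' @param observed Observed primary count(s), non-negative.
#' @param expected Expected count(s) from [expected_counts()], strictly
#'   positive.
#' @return Numeric vector of RE scores (dimensionless).
#' @examples
#' relative_enrichment(1, expected_counts(0.24, 1.3, 20))  # 0.27
#' @export
relative_enrichment <- function(observed, expected) {
  if (any(observed < 0, na.rm = TRUE))
    stop("observed counts must be >= 0", call. = FALSE)
  if (any(expected <= 0, na.rm = TRUE))
    stop("expected counts must be > 0", call. = FALSE)
  observed / expected
}

#' Per-region enrichment of a primary species on a reference tessellation
#'
#' Runs the full per-region calculation: assigns primaries to regions,
#' discards edge regions and the primaries they contain, computes expected
#' counts from region measures (or an ROI-overridden total) and scores each
#' included region by relative enrichment.
#'
#' @param tess A [tessellate()] result for the reference species.
#' @param primary A [loc_set()] of the primary species.
#' @return A data frame of class `region_enrichment` with one row per region:
#'   `region`, `bounded`, `measure`, `nnd`, `observed`, `expected`, `re`
#'   (NA for edge regions). Attributes: `n_retained`, `n_discarded`,
#'   `total_measure`, `image_id`.
#' @examples
#' sc <- simulate_scene(scene_config("uniform", n_points = 200, rng_seed = 1))
#' enr <- region_enrichment(tessellate(sc$reference), sc$primary)
#' mean(enr$re, na.rm = TRUE)
#' @export
region_enrichment <- function(tess, primary) {
  asg <- assign_primaries(tess, primary)
  expected <- expected_counts(tess, n_primary_total = asg$n_retained)
  re <- ifelse(tess$bounded, asg$observed / expected, NA_real_)
  df <- data.frame(region = seq_along(tess$bounded), bounded = tess$bounded,
                   measure = tess$measure, nnd = tess$nnd,
                   observed = ifelse(tess$bounded, asg$observed, NA_integer_),
                   expected = expected, re = re)
  structure(df,
            class = c("region_enrichment", "data.frame"),
            n_retained = asg$n_retained, n_discarded = asg$n_discarded,
            total_measure = tess$total_measure,
            roi_override = tess$roi_override,
            dimensionality = tess$dim,
            image_id = primary$image_id %||% "")
}

#' Common profile bin edges for a set of images
#'
#' Computes a shared set of bin edges (uniform on NND, or uniform in log10 of
#' the region measure) from pooled per-region values, so that profiles from
#' several images of a condition are binned comparably.
#'
#' @param enrichments A [region_enrichment()] result or a list of them.
#' @param bin_mode `"nnd"` (default) or `"log_area"`.
#' @param n_bins Number of bins (default 40).
#' @param max_quantile For `"nnd"`, the pooled quantile used as the upper
#'   edge (default 0.99); the lower edge is 0.
#' @return Numeric vector of `n_bins + 1` strictly increasing edges, in nm
#'   (`nnd`) or log10 nm^2 / nm^3 (`log_area`).
#' @export
common_edges <- function(enrichments, bin_mode = c("nnd", "log_area"),
                         n_bins = 40, max_quantile = 0.99) {
  bin_mode <- match.arg(bin_mode)
  if (inherits(enrichments, "region_enrichment"))
    enrichments <- list(enrichments)
  vals <- unlist(lapply(enrichments, function(e) {
    e <- e[e$bounded, ]
    if (bin_mode == "nnd") e$nnd else log10(e$measure)
  }))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no finite binning values", call. = FALSE)
  if (bin_mode == "nnd") {
    upper <- as.numeric(quantile(vals, max_quantile))
    if (upper <= 0) upper <- max(vals)
    seq(0, upper, length.out = n_bins + 1L)
  } else {
    rng <- range(vals)
    if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
    seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
}

#' Binned enrichment profile across the reference density distribution
#'
#' Bins included regions by NND (or log10 measure) and reports the unweighted
#' mean RE per bin together with the relative bin occupancy (the density
#' histogram of the reference species). Empty bins carry `NA` means, not
#' zeros. Regions outside the edge range are left out of the profile.
#'
#' @param enrichment A [region_enrichment()] result.
#' @param bin_mode `"nnd"` (default) or `"log_area"`.
#' @param bin_edges Strictly increasing numeric edges; default
#'   [common_edges()] of this image.
#' @param n_bins Number of bins when `bin_edges` is not supplied.
#' @param max_quantile Upper NND quantile for default edges.
#' @return A data frame of class `enrichment_profile` with columns `bin`,
#'   `bin_left`, `bin_right`, `bin_mid`, `mean_re`, `region_count`,
#'   `region_fraction`; attributes `bin_mode`, `bin_edges`, `image_id`.
#' @export
build_profile <- function(enrichment, bin_mode = c("nnd", "log_area"),
                          bin_edges = NULL, n_bins = 40,
                          max_quantile = 0.99) {
  stopifnot(inherits(enrichment, "region_enrichment"))
  bin_mode <- match.arg(bin_mode)
  if (is.null(bin_edges))
    bin_edges <- common_edges(enrichment, bin_mode, n_bins, max_quantile)
  if (any(diff(bin_edges) <= 0))
    stop("bin_edges must be strictly increasing", call. = FALSE)
  nb <- length(bin_edges) - 1L
  e <- enrichment[enrichment$bounded, ]
  x <- if (bin_mode == "nnd") e$nnd else log10(e$measure)
  bin <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  keep <- bin >= 1L & bin <= nb
  bin <- bin[keep]
  re <- e$re[keep]
  count <- tabulate(bin, nbins = nb)
  mean_re <- rep(NA_real_, nb)
  if (length(bin)) {
    sums <- vapply(split(re, factor(bin, levels = seq_len(nb))), sum,
                   numeric(1))
    mean_re[count > 0L] <- sums[count > 0L] / count[count > 0L]
  }
  total <- sum(count)
  df <- data.frame(bin = seq_len(nb),
                   bin_left = bin_edges[-length(bin_edges)],
                   bin_right = bin_edges[-1L],
                   bin_mid = (bin_edges[-1L] + bin_edges[-length(bin_edges)]) / 2,
                   mean_re = mean_re,
                   region_count = count,
                   region_fraction = if (total > 0) count / total else
                     rep(NA_real_, nb))
  structure(df, class = c("enrichment_profile", "data.frame"),
            bin_mode = bin_mode, bin_edges = bin_edges,
            image_id = attr(enrichment, "image_id"))
}

#' Mean enrichment of the densest regions
#'
#' Summarises colocalization at the highest reference densities: the
#' unweighted mean RE over included regions whose mean neighbour distance is
#' at or below a threshold (10 nm by default, i.e. localizations with less
#' than 10 nm on average to adjacent molecules of the same species).
#'
#' @param enrichment A [region_enrichment()] result.
#' @param nnd_threshold NND cut-off in nm.
#' @return A list with `mean_re` (NA with a warning when no region
#'   qualifies) and `n_regions`.
#' @export
dense_region_summary <- function(enrichment, nnd_threshold = 10) {
  stopifnot(inherits(enrichment, "region_enrichment"))
  e <- enrichment[enrichment$bounded, ]
  qual <- is.finite(e$nnd) & e$nnd <= nnd_threshold
  if (!any(qual)) {
    warning("no regions with NND <= ", nnd_threshold, " nm")
    return(list(mean_re = NA_real_, n_regions = 0L))
  }
  list(mean_re = mean(e$re[qual]), n_regions = sum(qual))
}
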