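#' Run the full enrichment pipeline and write an output bundle
#'
#' Wires the whole analysis together: read (or take) the two channels,
#' optionally clip them to an ROI (whose measure then overrides the total in
#' the expected-count calculation), tessellate the reference, score every
#' region, build the binned profile, summarise the densest regions, and
#' write a region CSV, profile CSV, JSON summary and plots to `out_dir`.
#'
#' @param reference,primary [loc_set()]s, coordinate matrices, or file paths
#'   accepted by [read_localizations()].
#' @param out_dir Output directory, created if needed.
#' @param bin_mode,bin_edges,n_bins,max_quantile Passed to [build_profile()].
#' @param nnd_threshold NND cut-off (nm) for [dense_region_summary()].
#' @param roi Optional `roi` object or ROI file path; clips both channels and
#'   supplies the total measure.
#' @param total_measure Optional explicit total-measure override (takes
#'   precedence over the ROI measure).
#' @param seed Optional integer seed (for reproducibility of any downstream
#'   randomness; the pipeline itself is deterministic).
#' @param dedupe Passed to [tessellate()].
#' @param make_plots Write region/point map and profile plot.
#' @param unit_scale Passed to [read_localizations()] for path inputs.
#' @return (Invisibly) a list with `tess`, `enrichment`, `profile`,
#'   `summary` and the written `paths`.
#' @export
run_enrichment <- function(reference, primary, out_dir,
                           bin_mode = c("nnd", "log_area"), bin_edges = NULL,
                           n_bins = 40, max_quantile = 0.99,
                           nnd_threshold = 10, roi = NULL,
                           total_measure = NULL, seed = NULL, dedupe = FALSE,
                           make_plots = TRUE, unit_scale = 1) {
  bin_mode <- match.arg(bin_mode)
  if (!is.null(seed)) set.seed(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  ref <- stage("io", if (is.character(reference))
    read_localizations(reference, unit_scale = unit_scale)
    else as_loc_set(reference))
  prim <- stage("io", if (is.character(primary))
    read_localizations(primary, unit_scale = unit_scale)
    else as_loc_set(primary))
  if (!is.null(roi)) {
    roi <- stage("io", if (is.character(roi)) read_roi(roi) else roi)
    stopifnot(inherits(roi, "roi"))
    ref <- stage("roi", clip_to_roi(ref, roi))
    prim <- stage("roi", clip_to_roi(prim, roi))
    total_measure <- total_measure %||% roi_measure(roi)
  }
  tess <- stage("tess", tessellate(ref, total_measure = total_measure,
                                   dedupe = dedupe))
  enr <- stage("enrich", region_enrichment(tess, prim))
  prof <- stage("enrich", build_profile(enr, bin_mode = bin_mode,
                                        bin_edges = bin_edges,
                                        n_bins = n_bins,
                                        max_quantile = max_quantile))
  dense <- stage("enrich", suppressWarnings(
    dense_region_summary(enr, nnd_threshold = nnd_threshold)))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(regions = file.path(out_dir, "regions.csv"),
                profile = file.path(out_dir, "profile.csv"),
                summary = file.path(out_dir, "summary.json"))
  region_tab <- cbind(as.data.frame(tess),
                      observed = enr$observed, expected = enr$expected,
                      re = enr$re)
  data.table::fwrite(region_tab, paths$regions)
  prof_tab <- data.frame(bin_left = prof$bin_left, bin_right = prof$bin_right,
                         mean_re = prof$mean_re,
                         region_fraction = prof$region_fraction,
                         region_count = prof$region_count,
                         image_id = attr(prof, "image_id"))
  data.table::fwrite(prof_tab, paths$profile)
  summary <- list(
    n_reference = n_localizations(ref),
    n_primary = n_localizations(prim),
    n_regions = length(tess$bounded),
    n_edge_regions = sum(!tess$bounded),
    n_primaries_retained = attr(enr, "n_retained"),
    n_primaries_discarded = attr(enr, "n_discarded"),
    total_measure = tess$total_measure,
    roi_override = tess$roi_override,
    grand_mean_re = mean(enr$re[enr$bounded]),
    dense_mean_re = dense$mean_re,
    dense_n_regions = dense$n_regions,
    nnd_threshold = nnd_threshold,
    bin_mode = bin_mode)
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (make_plots) {
    re_full <- enr$re
    if (tess$dim == 2L) {
      paths$region_map <- file.path(out_dir, "region_map.png")
      stage("viz", render_region_map(tess, re_full, path = paths$region_map))
    }
    paths$point_map <- file.path(out_dir, "point_map.png")
    stage("viz", render_point_map(tess$seeds, re_full,
                                  path = paths$point_map))
    paths$profile_plot <- file.path(out_dir, "profile.png")
    stage("viz", plot_profile(prof, path = paths$profile_plot))
  }
  invisible(list(tess = tess, enrichment = enr, profile = prof,
                 summary = summary, paths = paths))
}

#' Run the enrichment pipeline in both directions
#'
#' Relative enrichment is deliberately asymmetric: tessellating species A and
#' counting B generally differs from the reverse. This runs both
#' directionalities into `fwd/` and `rev/` subdirectories and writes a
#' side-by-side profile plot.
#'
#' @inheritParams run_enrichment
#' @param ... Further arguments passed to [run_enrichment()].
#' @return (Invisibly) a list with elements `fwd`, `rev` and the comparison
#'   plot path.
#' @export
run_swap <- function(reference, primary, out_dir, ...) {
  fwd <- run_enrichment(reference, primary, file.path(out_dir, "fwd"), ...)
  rev <- run_enrichment(primary, reference, file.path(out_dir, "rev"), ...)
  cmp_path <- file.path(out_dir, "profiles_both_directions.png")
  plot_profile(list(`reference -> primary` = fwd$profile,
                    `primary -> reference` = rev$profile),
               path = cmp_path, require_shared_edges = FALSE)
  invisible(list(fwd = fwd, rev = rev, comparison_plot = cmp_path))
}
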