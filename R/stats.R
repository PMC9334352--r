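#' Aggregate per-image profiles into a condition-level curve
#'
#' Averages per-image bin means (unweighted over images) and attaches the
#' standard error of the mean over images, per bin. All profiles must share
#' identical bin edges (use [common_edges()]); a bin's mean and SEM use only
#' the images in which the bin is non-empty, and the SEM is defined only for
#' bins present in at least two images.
#'
#' @param profiles A list of [build_profile()] results (one per image), or a
#'   single profile.
#' @param condition Condition label stored on the result.
#' @return A data frame of class `condition_profile` with columns `bin`,
#'   `bin_left`, `bin_right`, `bin_mid`, `mean_re`, `sem`, `n_images`,
#'   `region_fraction` (mean over images); attributes `bin_mode`,
#'   `bin_edges`, `condition`.
#' @export
aggregate_profiles <- function(profiles, condition = "") {
  if (inherits(profiles, "enrichment_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "enrichment_profile")))
  edges <- attr(profiles[[1L]], "bin_edges")
  for (p in profiles[-1L])
    if (!isTRUE(all.equal(attr(p, "bin_edges"), edges)))
      stop("profiles do not share identical bin edges; rebuild them with ",
           "common_edges()", call. = FALSE)
  m <- do.call(rbind, lapply(profiles, `[[`, "mean_re"))
  fr <- do.call(rbind, lapply(profiles, `[[`, "region_fraction"))
  n_img <- colSums(!is.na(m))
  mean_re <- ifelse(n_img > 0L, colMeans(m, na.rm = TRUE), NA_real_)
  sem <- rep(NA_real_, ncol(m))
  ok <- n_img >= 2L
  sem[ok] <- apply(m[, ok, drop = FALSE], 2L, sd, na.rm = TRUE) /
    sqrt(n_img[ok])
  df <- data.frame(bin = profiles[[1L]]$bin,
                   bin_left = profiles[[1L]]$bin_left,
                   bin_right = profiles[[1L]]$bin_right,
                   bin_mid = profiles[[1L]]$bin_mid,
                   mean_re = mean_re, sem = sem, n_images = n_img,
                   region_fraction = colMeans(fr, na.rm = TRUE))
  structure(df, class = c("condition_profile", "data.frame"),
            bin_mode = attr(profiles[[1L]], "bin_mode"),
            bin_edges = edges, condition = condition)
}

profile_matrix <- function(profiles) {
  if (inherits(profiles, "enrichment_profile")) profiles <- list(profiles)
  do.call(rbind, lapply(profiles, `[[`, "mean_re"))
}

#' Compare two conditions by unpaired t-tests with Holm correction
#'
#' Per-bin (or single-summary) unpaired Student's t-tests between two sets of
#' per-image values, with Bonferroni-Holm step-down adjustment across the
#' tested family to control the familywise error rate. One-sided tests
#' require an explicit direction and are never inferred from the data.
#'
#' @param a,b Either lists of [build_profile()] results (one per image,
#'   shared bin edges; tested per bin), numeric matrices of per-image values
#'   (rows: images, columns: bins), or plain numeric vectors of per-image
#'   summary values (a single test).
#' @param sided `"two.sided"` (default), `"less"` (alternative: a < b) or
#'   `"greater"` (a > b).
#' @param alpha Familywise significance level for the `significant` flag.
#' @return A data frame of class `profile_comparison` with one row per tested
#'   bin: `bin`, `bin_mid`, `n_a`, `n_b`, `t`, `p_raw`, `p_holm`,
#'   `significant`. Bins with fewer than two images in either condition are
#'   skipped with a warning. Attributes: `alpha`, `sided`.
#' @export
compare_conditions <- function(a, b,
                               sided = c("two.sided", "less", "greater"),
                               alpha = 0.05) {
  sided <- match.arg(sided)
  if (is.matrix(a) && is.matrix(b)) {
    am <- a; bm <- b
    if (ncol(am) != ncol(bm))
      stop("conditions were binned differently", call. = FALSE)
    mids <- rep(NA_real_, ncol(am))
  } else if (is.numeric(a) && is.numeric(b)) {
    am <- matrix(a, ncol = 1L); bm <- matrix(b, ncol = 1L)
    mids <- NA_real_
  } else {
    am <- profile_matrix(a); bm <- profile_matrix(b)
    if (ncol(am) != ncol(bm))
      stop("conditions were binned differently", call. = FALSE)
    ea <- attr(if (inherits(a, "enrichment_profile")) a else a[[1L]], "bin_edges")
    eb <- attr(if (inherits(b, "enrichment_profile")) b else b[[1L]], "bin_edges")
    if (!isTRUE(all.equal(ea, eb)))
      stop("conditions do not share bin edges", call. = FALSE)
    mids <- (ea[-1L] + ea[-length(ea)]) / 2
  }
  nb <- ncol(am)
  n_a <- colSums(!is.na(am)); n_b <- colSums(!is.na(bm))
  testable <- n_a >= 2L & n_b >= 2L
  if (!any(testable))
    stop("no bin has at least two images per condition", call. = FALSE)
  if (any(!testable))
    warning(sum(!testable), " bin(s) skipped: fewer than two images in a ",
            "condition")
  tstat <- p_raw <- rep(NA_real_, nb)
  for (j in which(testable)) {
    tt <- t.test(am[, j], bm[, j], alternative = sided, var.equal = TRUE)
    tstat[j] <- unname(tt$statistic)
    p_raw[j] <- tt$p.value
  }
  p_holm <- rep(NA_real_, nb)
  p_holm[testable] <- p.adjust(p_raw[testable], method = "holm")
  df <- data.frame(bin = seq_len(nb), bin_mid = mids, n_a = n_a, n_b = n_b,
                   t = tstat, p_raw = p_raw, p_holm = p_holm,
                   significant = !is.na(p_holm) & p_holm < alpha)
  df <- df[testable, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("profile_comparison", "data.frame"),
            alpha = alpha, sided = sided)
}

#' Tessellation-based Spearman and Mander's comparison coefficients
#'
#' Single-value colocalization coefficients computed from the two channels'
#' tessellations, provided for benchmarking against coefficient-based
#' approaches; they are approximations of externally defined measures and are
#' not part of the enrichment analysis itself. The local density of a cell is
#' the inverse of its measure. For direction A->B, the Spearman coefficient
#' rank-correlates each A localization's own cell density with the density of
#' the B cell containing it, and the Mander's-style coefficient is the
#' fraction of A localizations lying in B cells of above-threshold density.
#' Localizations in unbounded cells (their own or the containing one) are
#' excluded, consistent with the edge-region discard.
#'
#' @param tess_a,tess_b [tessellate()] results for the two channels.
#' @param threshold_a,threshold_b Density thresholds (1/nm^2 or 1/nm^3) for
#'   the Mander's fractions; each defaults to the mean bounded-cell density
#'   of the *opposing* channel (i.e. `threshold_b`, applied to B cells when
#'   scoring A localizations, defaults to B's mean density).
#' @return A list with `spearman` (named vector: `a_on_b`, `b_on_a`),
#'   `manders` (`a_on_b`, `b_on_a`) and the thresholds used.
#' @export
coloc_coefficients <- function(tess_a, tess_b, threshold_a = NULL,
                               threshold_b = NULL) {
  stopifnot(inherits(tess_a, "voronoi_tessellation"),
            inherits(tess_b, "voronoi_tessellation"))
  if (tess_a$dim != tess_b$dim)
    stop("tessellations have different dimensionality", call. = FALSE)
  dens_a <- 1 / tess_a$measure
  dens_b <- 1 / tess_b$measure
  thr_b <- threshold_b %||% mean(dens_b[tess_b$bounded])
  thr_a <- threshold_a %||% mean(dens_a[tess_a$bounded])
  one_way <- function(from, dens_from, to, dens_to, thr_to) {
    cell <- RANN::nn2(to$seeds$coords, from$seeds$coords, k = 1L)$nn.idx[, 1L]
    own <- dens_from
    other <- dens_to[cell]
    ok <- is.finite(own) & is.finite(other)
    if (sum(ok) < 3L)
      stop("too few localizations in bounded cells for rank correlation",
           call. = FALSE)
    list(spearman = suppressWarnings(cor(own[ok], other[ok],
                                         method = "spearman")),
         manders = mean(other[ok] > thr_to))
  }
  ab <- one_way(tess_a, dens_a, tess_b, dens_b, thr_b)
  ba <- one_way(tess_b, dens_b, tess_a, dens_a, thr_a)
  list(spearman = c(a_on_b = ab$spearman, b_on_a = ba$spearman),
       manders = c(a_on_b = ab$manders, b_on_a = ba$manders),
       thresholds = c(a = thr_a, b = thr_b))
}
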