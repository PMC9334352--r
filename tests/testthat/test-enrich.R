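test_that("the worked-example region scores as published", {
  # region of 0.24 um^2 in a 1.3 um^2 total with 20 primaries and 1 observed
  exp_count <- expected_counts(0.24, 1.3, 20)
  expect_equal(round(0.24 / 1.3 * 100, 1), 18.5)   # area share
  expect_equal(round(exp_count, 1), 3.7)           # expected occurrences
  expect_equal(round(relative_enrichment(1, exp_count), 2), 0.27)
})

test_that("expected counts split evenly across equal regions and validate", {
  expect_equal(expected_counts(rep(2, 5), 10, 20), rep(4, 5))
  expect_error(expected_counts(1, 0, 10), "positive")
  expect_error(relative_enrichment(-1, 2), ">= 0")
  expect_error(relative_enrichment(1, 0), "> 0")
})

test_that("primaries go to their nearest seed with low-index tie-breaks", {
  tt <- tessellate(square_centre_seeds())
  # primary coincident with a seed lands in that region
  asg <- assign_primaries(tt, loc_set(rbind(c(0.5, 0.5), c(0.49, 0.5))))
  expect_equal(asg$region_of, c(5L, 5L))
  expect_equal(asg$observed[5], 2L)
  expect_equal(asg$n_retained, 2L)
  # a primary exactly equidistant from seeds 1 and 2 goes to seed 1
  asg2 <- assign_primaries(tt, loc_set(rbind(c(0.5, -5))))
  expect_equal(asg2$region_of, 1L)
  expect_equal(asg2$n_discarded, 1L)  # corner regions are edge regions
  expect_error(assign_primaries(tt, loc_set(cbind(1, 1, 1))), "dimensionality")
})

test_that("nearest-seed assignment equals polygon membership on random scenes", {
  for (seed in c(3, 4)) {
    set.seed(seed)
    ref <- rand_points(30, 2, 100)
    prim <- rand_points(200, 2, 100)
    tt <- tessellate(ref)
    asg <- assign_primaries(tt, loc_set(prim))
    for (i in included_regions(tt)) {
      v <- tt$polygons[[i]]
      inside <- sp::point.in.polygon(prim[, 1], prim[, 2], v[, 1], v[, 2]) > 0
      expect_identical(which(asg$region_of == i), which(inside))
    }
  }
})

test_that("identical point sets give the closed-form RE and exact conservation", {
  sc <- simulate_scene(scene_config("identical", n_points = 300, rng_seed = 6))
  tt <- tessellate(sc$reference)
  enr <- region_enrichment(tt, sc$primary)
  b <- enr$bounded
  P <- attr(enr, "n_retained")
  expect_equal(P, sum(b))  # each included region holds exactly its twin
  closed <- attr(enr, "total_measure") / (P * enr$measure[b])
  expect_equal(enr$re[b], closed, tolerance = 1e-9)
  # conservation: observed and expected totals match, weighted mean RE is 1
  expect_equal(sum(enr$observed[b]), P)
  expect_equal(sum(enr$expected[b]), P, tolerance = 1e-9)
  expect_equal(sum(enr$measure[b] / attr(enr, "total_measure") * enr$re[b]), 1,
               tolerance = 1e-12)
})

test_that("swapping reference and primary changes the result", {
  sc <- simulate_scene(scene_config("offset_clusters", n_clusters = 6,
                                    points_per_cluster = 80, rng_seed = 12))
  fwd <- region_enrichment(tessellate(sc$reference), sc$primary)
  rev <- region_enrichment(tessellate(sc$primary), sc$reference)
  gf <- mean(fwd$re[fwd$bounded])
  gr <- mean(rev$re[rev$bounded])
  expect_false(isTRUE(all.equal(gf, gr, tolerance = 1e-6)))
})

test_that("RE is invariant under uniform coordinate scaling", {
  sc <- simulate_scene(scene_config("offset_clusters", n_clusters = 4,
                                    points_per_cluster = 60, rng_seed = 14))
  e1 <- region_enrichment(tessellate(sc$reference), sc$primary)
  s <- 7.3
  e2 <- region_enrichment(
    tessellate(loc_set(sc$reference$coords * s)),
    loc_set(sc$primary$coords * s))
  expect_identical(e1$bounded, e2$bounded)
  expect_equal(e1$re, e2$re, tolerance = 1e-9)
  expect_equal(e2$nnd, s * e1$nnd, tolerance = 1e-9)
})

test_that("profiles bin regions with absent (not zero) empty bins", {
  sc <- simulate_scene(scene_config("uniform", n_points = 500, rng_seed = 8))
  enr <- region_enrichment(tessellate(sc$reference), sc$primary)
  b <- enr$bounded
  # a single bin spanning everything reproduces the grand mean
  p1 <- build_profile(enr, bin_edges = c(0, max(enr$nnd[b]) + 1))
  expect_equal(p1$mean_re, mean(enr$re[b]))
  expect_equal(p1$region_count, sum(b))
  expect_equal(p1$region_fraction, 1)
  # default binning: fractions sum to 1, empty bins carry NA means
  p <- build_profile(enr, n_bins = 30)
  expect_equal(sum(p$region_fraction), 1)
  expect_true(all(is.na(p$mean_re[p$region_count == 0])))
  expect_true(all(diff(attr(p, "bin_edges")) > 0))
  expect_error(build_profile(enr, bin_edges = c(0, 2, 1)), "increasing")
})

test_that("log-area binning uses log10 of the region measure", {
  sc <- simulate_scene(scene_config("uniform", n_points = 500, rng_seed = 8))
  enr <- region_enrichment(tessellate(sc$reference), sc$primary)
  p <- build_profile(enr, bin_mode = "log_area", n_bins = 25)
  expect_identical(attr(p, "bin_mode"), "log_area")
  b <- enr$bounded
  expect_gte(min(attr(p, "bin_edges")), min(log10(enr$measure[b])) - 1e-9)
  expect_equal(sum(p$region_count), sum(b))
})

test_that("the dense-region summary averages qualifying regions", {
  # construct a minimal enrichment table with known REs below threshold
  df <- data.frame(region = 1:5, bounded = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                   measure = 1, nnd = c(5, 8, 9, 20, 2),
                   observed = 1, expected = 1, re = c(2, 2, 4, 9, 100))
  class(df) <- c("region_enrichment", "data.frame")
  out <- dense_region_summary(df, nnd_threshold = 10)
  expect_equal(out$mean_re, 8 / 3)  # {2,2,4}; the unbounded row is ignored
  expect_equal(out$n_regions, 3L)
  # an infinite threshold reproduces the grand mean over included regions
  expect_equal(dense_region_summary(df, Inf)$mean_re, mean(c(2, 2, 4, 9)))
  expect_warning(out0 <- dense_region_summary(df, 1), "no regions")
  expect_true(is.na(out0$mean_re))
})

test_that("uniform scenes give flat unit profiles in every bin", {
  reps <- lapply(1:6, function(s) {
    sc <- simulate_scene(scene_config("uniform", n_points = 2000,
                                      rng_seed = 100 + s))
    region_enrichment(tessellate(sc$reference), sc$primary)
  })
  edges <- common_edges(reps, n_bins = 15)
  profs <- lapply(reps, build_profile, bin_edges = edges)
  m <- do.call(rbind, lapply(profs, `[[`, "mean_re"))
  n_img <- colSums(!is.na(m))
  mu <- colMeans(m, na.rm = TRUE)
  se <- apply(m, 2, sd, na.rm = TRUE) / sqrt(n_img)
  ok <- n_img >= 2 & se > 0
  expect_true(all(abs(mu[ok] - 1) <= 3 * se[ok]))
})
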