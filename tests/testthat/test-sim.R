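test_that("identical-kind scenes copy coordinates exactly and seeds reproduce", {
  sc <- simulate_scene(scene_config("identical", n_points = 100, rng_seed = 3))
  expect_identical(sc$reference$coords, sc$primary$coords)

  a <- simulate_scene(scene_config("uniform", n_points = 200, rng_seed = 9))
  b <- simulate_scene(scene_config("uniform", n_points = 200, rng_seed = 9))
  expect_identical(a$reference$coords, b$reference$coords)
  expect_identical(a$primary$coords, b$primary$coords)

  v1 <- simulate_vesicle_scene(vesicle_scene_config(rng_seed = 4))
  v2 <- simulate_vesicle_scene(vesicle_scene_config(rng_seed = 4))
  expect_identical(v1$cargo$coords, v2$cargo$coords)
})

test_that("offset clusters recover the configured displacement", {
  cfg <- scene_config("offset_clusters", offset = c(50, 0), rng_seed = 7)
  sc <- simulate_scene(cfg)
  gt <- sc$ground_truth
  expect_equal(gt$primary_centers - gt$ref_centers,
               matrix(rep(c(50, 0), each = cfg$n_clusters), ncol = 2),
               ignore_attr = TRUE)
  # per-cluster sample centroids displace by ~the offset
  centroid <- function(coords, of) {
    keep <- !is.na(of)
    rowsum(coords[keep, ], of[keep]) / tabulate(of[keep])
  }
  disp <- colMeans(centroid(sc$primary$coords, gt$primary_cluster_of) -
                     centroid(sc$reference$coords, gt$ref_cluster_of))
  tol <- 3 * cfg$cluster_sd / sqrt(cfg$points_per_cluster)
  expect_lt(abs(disp[1] - 50), tol)
  expect_lt(abs(disp[2]), tol)
})

test_that("anti-colocalized primary centres respect the exclusion distance", {
  cfg <- scene_config("anticolocalized_clusters", rng_seed = 2)
  sc <- simulate_scene(cfg)
  gt <- sc$ground_truth
  dmat <- as.matrix(dist(rbind(gt$ref_centers, gt$primary_centers)))
  k <- nrow(gt$ref_centers)
  cross <- dmat[seq_len(k), k + seq_len(nrow(gt$primary_centers))]
  expect_true(all(cross >= cfg$exclusion))
  expect_equal(cfg$exclusion, 4 * cfg$cluster_sd)

  # infeasible exclusion reports a generation error
  bad <- scene_config("anticolocalized_clusters", extent = c(300, 300),
                      exclusion = 5000, rng_seed = 1)
  expect_error(simulate_scene(bad), "exclusion")
})

test_that("scene configs validate their parameters", {
  expect_error(scene_config("uniform", extent = c(-1, 10)), "positive")
  expect_error(scene_config("uniform", n_points = 0), "n_points")
  expect_error(scene_config("offset_clusters", cluster_sd = 0), "cluster_sd")
  expect_error(scene_config("offset_clusters", background_fraction = 1.2),
               "background_fraction")
  expect_error(vesicle_scene_config(fraction_docked = -0.1), "fraction_docked")
  expect_error(vesicle_scene_config(vesicle_radius = 0), "radius")
})

test_that("vesicle scenes have the documented composition", {
  cfg <- vesicle_scene_config(rng_seed = 5)
  vs <- simulate_vesicle_scene(cfg)
  gt <- vs$ground_truth
  expect_equal(nrow(gt$centers), 20L)
  expect_equal(sum(gt$docked), 10L)  # half docked, each with an AZ cluster
  expect_equal(n_localizations(vs$az), 10L * cfg$az_cluster_size)
  expect_equal(n_localizations(vs$vesicle_membrane),
               20L * cfg$points_per_vesicle_membrane)
  # docked vesicles touch the membrane plane, undocked centres lie above it
  expect_equal(gt$centers[gt$docked, 3],
               rep(cfg$membrane_plane_z + cfg$vesicle_radius, 10))
  expect_true(all(gt$centers[!gt$docked, 3] >
                    cfg$membrane_plane_z + cfg$vesicle_radius))
  # true AZ positions sit exactly on the membrane plane
  expect_true(all(gt$true_az[, 3] == cfg$membrane_plane_z))
})

test_that("without jitter all cargo lies strictly inside its vesicle", {
  cfg <- vesicle_scene_config(jitter_sd_xy = 0, jitter_sd_z = 0, rng_seed = 8)
  vs <- simulate_vesicle_scene(cfg)
  gt <- vs$ground_truth
  r <- sqrt(rowSums((vs$cargo$coords -
                       gt$centers[gt$cargo_vesicle, , drop = FALSE])^2))
  expect_true(all(r < cfg$vesicle_radius))
  # membrane points lie exactly on the sphere
  rm_ <- sqrt(rowSums((vs$vesicle_membrane$coords -
                         gt$centers[gt$membrane_vesicle, , drop = FALSE])^2))
  expect_equal(rm_, rep(cfg$vesicle_radius, length(rm_)), tolerance = 1e-12)
})

test_that("axial jitter is twice the lateral jitter", {
  cfg <- vesicle_scene_config(rng_seed = 10)
  expect_equal(cfg$jitter_sd_z, 2 * cfg$jitter_sd_xy)
  vs <- simulate_vesicle_scene(cfg)
  d <- vs$vesicle_membrane$coords - vs$ground_truth$true_membrane
  ratio <- sd(d[, 3]) / sd(d[, 1])
  # 1600 points: the sd ratio estimate is within ~10% of 2
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("scenes serialize to CSV plus a JSON sidecar", {
  dir <- withr::local_tempdir()
  sc <- simulate_scene(scene_config("uniform", n_points = 50, rng_seed = 1))
  write_scene(sc, dir)
  expect_true(file.exists(file.path(dir, "reference.csv")))
  expect_true(file.exists(file.path(dir, "scene.json")))
  side <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  expect_equal(side$config$n_points, 50)
  back <- read_localizations(file.path(dir, "reference.csv"))
  expect_equal(back$coords, sc$reference$coords, tolerance = 1e-9,
               ignore_attr = TRUE)
})
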