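#' Configure a simulated two-species scene
#'
#' Describes the synthetic point patterns used throughout for validation:
#' independent uniform fields, offset Gaussian clusters over uniform
#' background, anti-colocalized clusters, exact duplicate point sets, and a
#' clustered-versus-uniform pair. All lengths are nm. Cluster point counts
#' are fixed by default so that fixtures are exactly reproducible; set
#' `poisson = TRUE` for Poisson-distributed counts.
#'
#' @param kind One of `"uniform"`, `"offset_clusters"`,
#'   `"anticolocalized_clusters"`, `"identical"`, `"clustered_vs_uniform"`,
#'   `"vesicle_scene"`.
#' @param extent Numeric vector of box side lengths per axis (2 or 3 values),
#'   strictly positive.
#' @param n_points Number of points per uniform species.
#' @param n_clusters Number of Gaussian clusters per clustered species.
#' @param points_per_cluster Localizations per cluster.
#' @param cluster_sd Isotropic cluster standard deviation, nm.
#' @param offset Offset vector added to the primary cluster centres
#'   (`offset_clusters` only); recycled to the scene dimensionality.
#' @param background_fraction Fraction of a clustered species' points drawn
#'   uniformly over the extent, in \[0, 1\].
#' @param exclusion Minimum distance between a primary cluster centre and
#'   every reference centre for `anticolocalized_clusters`; defaults to
#'   `4 * cluster_sd`.
#' @param poisson If `TRUE`, per-cluster counts are Poisson with mean
#'   `points_per_cluster`.
#' @param rng_seed Integer seed; identical seeds and configs give
#'   bit-identical scenes.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(kind = c("uniform", "offset_clusters",
                                  "anticolocalized_clusters", "identical",
                                  "clustered_vs_uniform", "vesicle_scene"),
                         extent = c(2000, 2000), n_points = 5000,
                         n_clusters = 12, points_per_cluster = 150,
                         cluster_sd = 40, offset = c(50, 0),
                         background_fraction = 0.25, exclusion = NULL,
                         poisson = FALSE, rng_seed = NULL) {
  kind <- match.arg(kind)
  extent <- as.numeric(extent)
  if (!length(extent) %in% c(2L, 3L) || any(!is.finite(extent)) ||
      any(extent <= 0))
    stop("extent must be 2 or 3 strictly positive lengths", call. = FALSE)
  if (!is.finite(n_points) || n_points < 1)
    stop("n_points must be a positive count", call. = FALSE)
  if (!is.finite(cluster_sd) || cluster_sd <= 0)
    stop("cluster_sd must be > 0", call. = FALSE)
  if (!is.finite(background_fraction) || background_fraction < 0 ||
      background_fraction > 1)
    stop("background_fraction must lie in [0, 1]", call. = FALSE)
  if (n_clusters < 1 || points_per_cluster < 1)
    stop("cluster counts must be positive", call. = FALSE)
  structure(list(kind = kind, extent = extent,
                 n_points = as.integer(n_points),
                 n_clusters = as.integer(n_clusters),
                 points_per_cluster = as.integer(points_per_cluster),
                 cluster_sd = cluster_sd,
                 offset = as.numeric(offset),
                 background_fraction = background_fraction,
                 exclusion = exclusion %||% (4 * cluster_sd),
                 poisson = isTRUE(poisson),
                 rng_seed = rng_seed),
            class = "scene_config")
}

runif_box <- function(n, extent) {
  d <- length(extent)
  matrix(runif(n * d), ncol = d) %*% diag(extent, d)
}

# Gaussian clusters + uniform background; returns coords and ground truth
sample_clustered <- function(config, centers = NULL) {
  extent <- config$extent
  d <- length(extent)
  sd <- config$cluster_sd
  if (is.null(centers)) {
    margin <- pmin(3 * sd, extent / 4)
    centers <- sweep(matrix(runif(config$n_clusters * d), ncol = d), 2L,
                     extent - 2 * margin, `*`)
    centers <- sweep(centers, 2L, margin, `+`)
  }
  counts <- if (config$poisson)
    stats::rpois(nrow(centers), config$points_per_cluster)
  else rep(config$points_per_cluster, nrow(centers))
  counts[counts == 0L] <- 1L
  idx <- rep(seq_len(nrow(centers)), counts)
  pts <- centers[idx, , drop = FALSE] +
    matrix(rnorm(length(idx) * d, sd = sd), ncol = d)
  bf <- config$background_fraction
  n_bg <- if (bf >= 1) config$n_points else round(bf / (1 - bf) * nrow(pts))
  if (n_bg > 0) pts <- rbind(pts, runif_box(n_bg, extent))
  list(coords = pts, centers = centers, cluster_of = c(idx, rep(NA, n_bg)),
       n_background = n_bg)
}

#' Simulate a two-species validation scene
#'
#' Draws the reference and primary point patterns described by a
#' [scene_config()]. Generating ground truth (cluster centres, cluster
#' membership) is returned alongside the coordinates for use as a test
#' oracle. Identical seeds and configs give bit-identical output.
#'
#' @param config A [scene_config()].
#' @return A list of class `sim_scene` with elements `reference` and
#'   `primary` ([loc_set()]s), `ground_truth`, and `config`. For
#'   `kind = "vesicle_scene"` the result of [simulate_vesicle_scene()] is
#'   returned instead.
#' @examples
#' sc <- simulate_scene(scene_config("uniform", n_points = 100, rng_seed = 1))
#' n_localizations(sc$reference)
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (config$kind == "vesicle_scene")
    return(simulate_vesicle_scene(vesicle_scene_config(rng_seed = config$rng_seed)))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  extent <- config$extent
  d <- length(extent)
  gt <- list()
  if (config$kind == "uniform") {
    ref <- runif_box(config$n_points, extent)
    prim <- runif_box(config$n_points, extent)
  } else if (config$kind == "identical") {
    ref <- runif_box(config$n_points, extent)
    prim <- ref
  } else if (config$kind == "clustered_vs_uniform") {
    rs <- sample_clustered(config)
    ref <- rs$coords
    prim <- runif_box(config$n_points, extent)
    gt <- list(ref_centers = rs$centers, ref_cluster_of = rs$cluster_of)
  } else if (config$kind == "offset_clusters") {
    rs <- sample_clustered(config)
    offset <- rep_len(config$offset, d)
    ps <- sample_clustered(config,
                           centers = sweep(rs$centers, 2L, offset, `+`))
    ref <- rs$coords; prim <- ps$coords
    gt <- list(ref_centers = rs$centers, primary_centers = ps$centers,
               ref_cluster_of = rs$cluster_of,
               primary_cluster_of = ps$cluster_of, offset = offset)
  } else if (config$kind == "anticolocalized_clusters") {
    rs <- sample_clustered(config)
    pcenters <- matrix(NA_real_, config$n_clusters, d)
    margin <- pmin(3 * config$cluster_sd, extent / 4)
    tries <- 0L
    for (i in seq_len(config$n_clusters)) {
      repeat {
        tries <- tries + 1L
        if (tries > 10000L * config$n_clusters)
          stop("could not place anti-colocalized cluster centres: exclusion ",
               "distance ", config$exclusion, " nm is infeasible in this extent",
               call. = FALSE)
        cand <- runif(d) * (extent - 2 * margin) + margin
        dmin <- sqrt(min(colSums((t(rs$centers) - cand)^2)))
        if (dmin >= config$exclusion) break
      }
      pcenters[i, ] <- cand
    }
    ps <- sample_clustered(config, centers = pcenters)
    ref <- rs$coords; prim <- ps$coords
    gt <- list(ref_centers = rs$centers, primary_centers = pcenters,
               ref_cluster_of = rs$cluster_of,
               primary_cluster_of = ps$cluster_of,
               exclusion = config$exclusion)
  }
  structure(list(reference = loc_set(ref, channel = "reference",
                                     image_id = paste0("sim_", config$kind)),
                 primary = loc_set(prim, channel = "primary",
                                   image_id = paste0("sim_", config$kind)),
                 ground_truth = gt, config = config),
            class = "sim_scene")
}

#' Configure the simulated docked-vesicle scene
#'
#' Parameters of a 3D scene with three molecular species around synaptic-like
#' vesicles: a vesicle-membrane species sampled uniformly on each vesicle
#' sphere, a lumenal cargo species sampled uniformly inside each vesicle, and
#' an active-zone (AZ) species clustered on the membrane plane beneath docked
#' vesicles only. Docked vesicles touch the membrane plane; undocked vesicle
#' centres lie strictly above it. Anisotropic Gaussian jitter emulates
#' localization uncertainty, with the axial (z) standard deviation twice the
#' lateral one by default, as is typical for astigmatic 3D SMLM.
#'
#' @param n_vesicles Number of vesicles (default 20).
#' @param fraction_docked Fraction of vesicles docked at the membrane plane
#'   (default 0.5).
#' @param vesicle_radius Vesicle radius in nm (default 20, a small synaptic
#'   vesicle).
#' @param points_per_vesicle_membrane Membrane localizations per vesicle.
#' @param points_per_lumen Cargo localizations per vesicle.
#' @param az_cluster_size AZ localizations per docked vesicle.
#' @param az_cluster_sd Lateral spread of each AZ cluster, nm.
#' @param membrane_plane_z z position of the plasma membrane plane, nm.
#' @param extent_xy Lateral scene extent, nm.
#' @param z_max Upper z bound for undocked vesicle centres, nm.
#' @param jitter_sd_xy Lateral localization jitter sd, nm.
#' @param jitter_sd_z Axial jitter sd, nm; defaults to `2 * jitter_sd_xy`.
#' @param rng_seed Integer seed.
#' @return An object of class `vesicle_scene_config`.
#' @export
vesicle_scene_config <- function(n_vesicles = 20, fraction_docked = 0.5,
                                 vesicle_radius = 20,
                                 points_per_vesicle_membrane = 80,
                                 points_per_lumen = 40,
                                 az_cluster_size = 60, az_cluster_sd = 10,
                                 membrane_plane_z = 0,
                                 extent_xy = c(500, 500), z_max = 250,
                                 jitter_sd_xy = 10,
                                 jitter_sd_z = 2 * jitter_sd_xy,
                                 rng_seed = NULL) {
  if (!is.finite(fraction_docked) || fraction_docked < 0 || fraction_docked > 1)
    stop("fraction_docked must lie in [0, 1]", call. = FALSE)
  if (vesicle_radius <= 0) stop("vesicle_radius must be > 0", call. = FALSE)
  if (n_vesicles < 1) stop("n_vesicles must be positive", call. = FALSE)
  if (jitter_sd_xy < 0 || jitter_sd_z < 0)
    stop("jitter sds must be non-negative", call. = FALSE)
  if (z_max <= membrane_plane_z + 3 * vesicle_radius)
    stop("z_max leaves no room for undocked vesicles", call. = FALSE)
  structure(list(n_vesicles = as.integer(n_vesicles),
                 fraction_docked = fraction_docked,
                 vesicle_radius = vesicle_radius,
                 points_per_vesicle_membrane = as.integer(points_per_vesicle_membrane),
                 points_per_lumen = as.integer(points_per_lumen),
                 az_cluster_size = as.integer(az_cluster_size),
                 az_cluster_sd = az_cluster_sd,
                 membrane_plane_z = membrane_plane_z,
                 extent_xy = as.numeric(extent_xy), z_max = z_max,
                 jitter_sd_xy = jitter_sd_xy, jitter_sd_z = jitter_sd_z,
                 rng_seed = rng_seed),
            class = "vesicle_scene_config")
}

# uniform directions on the unit sphere (normalized Gaussians)
unit_sphere <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Simulate the 3D docked-vesicle scene
#'
#' Generates the three-species vesicle scene described by
#' [vesicle_scene_config()]: with the defaults, 20 vesicles of which half are
#' docked at the membrane plane and associated with an AZ cluster. True
#' (pre-jitter) positions, vesicle centres and docked flags are returned as
#' ground truth.
#'
#' @param config A [vesicle_scene_config()].
#' @return A list of class `vesicle_scene` with 3D [loc_set()]s
#'   `vesicle_membrane`, `az` and `cargo`, plus `ground_truth` and `config`.
#' @export
simulate_vesicle_scene <- function(config = vesicle_scene_config()) {
  stopifnot(inherits(config, "vesicle_scene_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  r <- config$vesicle_radius
  nv <- config$n_vesicles
  n_docked <- round(nv * config$fraction_docked)
  docked <- rep(c(TRUE, FALSE), c(n_docked, nv - n_docked))

  # vesicle centres: rejection-sample xy for a minimum separation
  centers <- matrix(NA_real_, nv, 3)
  tries <- 0L
  for (i in seq_len(nv)) {
    repeat {
      tries <- tries + 1L
      if (tries > 10000L * nv)
        stop("could not place ", nv, " non-overlapping vesicles in the extent",
             call. = FALSE)
      xy <- runif(2) * (config$extent_xy - 2 * r) + r
      if (i == 1L ||
          min(colSums((t(centers[seq_len(i - 1L), 1:2, drop = FALSE]) - xy)^2)) >=
            (2.2 * r)^2) break
    }
    z <- if (docked[i]) config$membrane_plane_z + r
         else runif(1, config$membrane_plane_z + 2 * r, config$z_max - r)
    centers[i, ] <- c(xy, z)
  }

  # membrane: uniform on each sphere surface
  mem_v <- rep(seq_len(nv), each = config$points_per_vesicle_membrane)
  mem <- centers[mem_v, , drop = FALSE] + r * unit_sphere(length(mem_v))
  # cargo: uniform in each ball
  car_v <- rep(seq_len(nv), each = config$points_per_lumen)
  car <- centers[car_v, , drop = FALSE] +
    (r * runif(length(car_v))^(1 / 3)) * unit_sphere(length(car_v))
  # AZ: lateral Gaussian clusters on the membrane plane under docked vesicles
  az_v <- rep(which(docked), each = config$az_cluster_size)
  az <- cbind(centers[az_v, 1:2, drop = FALSE] +
                matrix(rnorm(2 * length(az_v), sd = config$az_cluster_sd),
                       ncol = 2),
              config$membrane_plane_z)

  jitter3 <- function(x)
    x + cbind(matrix(rnorm(2 * nrow(x), sd = config$jitter_sd_xy), ncol = 2),
              rnorm(nrow(x), sd = config$jitter_sd_z))
  mem_j <- jitter3(mem); az_j <- jitter3(az); car_j <- jitter3(car)

  structure(list(
    vesicle_membrane = loc_set(mem_j, channel = "vesicle_membrane",
                               image_id = "sim_vesicle"),
    az = loc_set(az_j, channel = "az", image_id = "sim_vesicle"),
    cargo = loc_set(car_j, channel = "cargo", image_id = "sim_vesicle"),
    ground_truth = list(centers = centers, docked = docked,
                        true_membrane = mem, true_az = az, true_cargo = car,
                        membrane_vesicle = mem_v, cargo_vesicle = car_v,
                        az_vesicle = az_v),
    config = config), class = "vesicle_scene")
}

#' Write a simulated scene to disk
#'
#' Writes each species as a localization CSV plus a JSON sidecar holding the
#' configuration and generating ground truth.
#'
#' @param scene A `sim_scene` or `vesicle_scene`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, c("sim_scene", "vesicle_scene")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sets <- Filter(function(x) inherits(x, "loc_set"), scene)
  for (nm in names(sets))
    write_localizations(sets[[nm]], file.path(dir, paste0(nm, ".csv")))
  side <- list(config = unclass(scene$config),
               ground_truth = scene$ground_truth)
  jsonlite::write_json(side, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
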