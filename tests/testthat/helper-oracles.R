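# Analytic fixtures and brute-force oracles used across the test files.

square_centre_seeds <- function() {
  rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
}

cube_centre_seeds <- function() {
  rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)), c(0.5, 0.5, 0.5))
}

rand_points <- function(n, d = 2, extent = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(n * d, 0, extent), ncol = d)
}

# undirected edge keys "i-j" with i < j, for adjacency set comparisons
edge_keys <- function(neighbors) {
  unique(sort(unlist(lapply(seq_along(neighbors), function(i) {
    js <- neighbors[[i]]
    if (!length(js)) return(character(0))
    paste(pmin(i, js), pmax(i, js), sep = "-")
  }))))
}

# brute-force Delaunay edges on <= ~30 2D points via the empty-circumcircle
# test: an edge belongs to the Delaunay graph iff it is part of a triangle
# whose circumcircle contains no other point.
brute_delaunay_edges <- function(xy) {
  n <- nrow(xy)
  keys <- character(0)
  for (i in seq_len(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        ax <- xy[i, 1]; ay <- xy[i, 2]
        bx <- xy[j, 1]; by <- xy[j, 2]
        cx <- xy[k, 1]; cy <- xy[k, 2]
        dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
        if (abs(dd) < 1e-12) next  # collinear
        ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
                 (cx^2 + cy^2) * (ay - by)) / dd
        uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
                 (cx^2 + cy^2) * (bx - ax)) / dd
        r2 <- (ax - ux)^2 + (ay - uy)^2
        others <- setdiff(seq_len(n), c(i, j, k))
        din <- (xy[others, 1] - ux)^2 + (xy[others, 2] - uy)^2
        if (all(din > r2 * (1 - 1e-12))) {
          keys <- c(keys, paste(c(i, i, j), c(j, k, k), sep = "-"))
        }
      }
    }
  }
  unique(sort(keys))
}

# even-odd ray-casting point-in-polygon test (boundary treated separately
# by the caller when it matters)
ray_cast_inside <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# per-image enrichment profiles of a vesicle scene with common edges
vesicle_profiles <- function(seed, edges) {
  vs <- simulate_vesicle_scene(vesicle_scene_config(rng_seed = seed))
  t3 <- tessellate(vs$vesicle_membrane)
  t2 <- tessellate(project_to_2d(vs$vesicle_membrane))
  list(az3 = build_profile(region_enrichment(t3, vs$az), bin_edges = edges),
       ca3 = build_profile(region_enrichment(t3, vs$cargo), bin_edges = edges),
       az2 = build_profile(region_enrichment(t2, project_to_2d(vs$az)),
                           bin_edges = edges),
       ca2 = build_profile(region_enrichment(t2, project_to_2d(vs$cargo)),
                           bin_edges = edges))
}
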