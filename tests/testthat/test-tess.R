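test_that("hull seeds own unbounded cells; the square-centre cell is exact", {
  # 4 seeds at unit-square corners: every cell is unbounded
  t4 <- tessellate(square_centre_seeds()[1:4, ])
  expect_true(all(!t4$finite))
  expect_true(all(!t4$bounded))
  expect_error(included_regions(t4), "no bounded")

  # adding the centre: exactly one included region, the bisector square
  # with vertices (0.5,0),(1,0.5),(0.5,1),(0,0.5), area 0.5
  t5 <- tessellate(square_centre_seeds())
  expect_identical(included_regions(t5), 5L)
  expect_equal(t5$measure[5], 0.5, tolerance = 1e-12)
  expect_equal(t5$total_measure, 0.5, tolerance = 1e-12)
  expect_equal(mean_neighbor_distance(t5)[5], sqrt(2) / 2, tolerance = 1e-12)
  expect_setequal(t5$neighbors[[5]], 1:4)
})

test_that("the cube-centre cell is the L1 ball with volume 0.5625", {
  t9 <- tessellate(cube_centre_seeds())
  expect_true(t9$finite[9])
  expect_equal(t9$measure[9], 0.5625, tolerance = 1e-9)
  expect_setequal(t9$neighbors[[9]], 1:8)
  expect_equal(t9$nnd[9], sqrt(3) / 2, tolerance = 1e-12)
})

test_that("measures are invariant under rigid motion to 1e-9 relative", {
  xy <- rand_points(120, 2, 1000, seed = 21)
  t0 <- tessellate(xy)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  t1 <- tessellate(xy %*% rot + matrix(rep(c(300, -150), each = 120), ncol = 2))
  # rotation changes the axis-aligned window, so compare the infinite-cell
  # geometry: measures of cells finite in both
  both <- t0$finite & t1$finite
  expect_gt(sum(both), 50)
  expect_equal(t0$measure[both], t1$measure[both], tolerance = 1e-9)

  xyz <- rand_points(100, 3, 500, seed = 22)
  s0 <- tessellate(xyz)
  s1 <- tessellate(xyz + matrix(rep(c(100, 200, -50), each = 100), ncol = 3))
  expect_equal(s0$measure, s1$measure, tolerance = 1e-9)
  expect_identical(s0$bounded, s1$bounded)
})

test_that("included cells are positive, contain their seed, adjacency is symmetric", {
  for (d in 2:3) {
    pts <- rand_points(150, d, 800, seed = 30 + d)
    tt <- tessellate(pts)
    idx <- included_regions(tt)
    expect_true(all(tt$measure[idx] > 0))
    # every seed lies inside its own (convex) cell: the seed is closer to
    # itself than to any other seed by construction, so check via the
    # polygon for 2D and via nearest-seed for both
    expect_identical(RANN::nn2(pts, pts, k = 1)$nn.idx[, 1], seq_len(150))
    if (d == 2) {
      for (i in idx[1:20]) {
        v <- tt$polygons[[i]]
        expect_gte(sp::point.in.polygon(pts[i, 1], pts[i, 2], v[, 1], v[, 2]), 1)
      }
    }
    for (i in seq_along(tt$neighbors))
      for (j in tt$neighbors[[i]])
        expect_true(i %in% tt$neighbors[[j]])
  }
})

test_that("adjacency equals the brute-force empty-circumcircle Delaunay graph", {
  for (seed in c(11, 12, 13)) {
    xy <- rand_points(25, 2, 50, seed = seed)
    tt <- tessellate(xy)
    expect_setequal(edge_keys(tt$neighbors), brute_delaunay_edges(xy))
  }
})

test_that("2D areas and adjacency match deldir on random fields", {
  skip_if_not_installed("deldir")
  for (seed in c(5, 6)) {
    xy <- rand_points(180, 2, 100, seed = seed)
    tt <- tessellate(xy)
    dd <- deldir::deldir(xy[, 1], xy[, 2],
                         rw = c(-1e5, 1e5 + 100, -1e5, 1e5 + 100))
    del <- unique(paste(pmin(dd$delsgs$ind1, dd$delsgs$ind2),
                        pmax(dd$delsgs$ind1, dd$delsgs$ind2), sep = "-"))
    expect_setequal(edge_keys(tt$neighbors), del)
    hull <- chull(xy)
    interior <- setdiff(seq_len(180), hull)
    expect_setequal(which(tt$finite), interior)
    fin <- which(tt$finite)
    # compare areas of cells that fit in deldir's window
    comparable <- fin[vapply(fin, function(i)
      all(abs(tt$polygons[[i]]) < 9e4), logical(1))]
    expect_equal(tt$measure[comparable], dd$summary$dir.area[comparable],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("nnd scales homogeneously and grows like measure^(1/d)", {
  xy <- rand_points(400, 2, 1000, seed = 40)
  t1 <- tessellate(xy)
  t2 <- tessellate(xy * 3.5)
  expect_equal(t2$nnd, 3.5 * t1$nnd, tolerance = 1e-9)
  b <- t1$bounded
  expect_gt(cor(t1$nnd[b], t1$measure[b], method = "spearman"), 0.5)
  # concave relationship: nnd ~ sqrt(area), so nnd/sqrt(area) is flat
  # while nnd/area decreases with area
  expect_gt(cor(t1$nnd[b], sqrt(t1$measure[b])), cor(t1$nnd[b], t1$measure[b]))
})

test_that("degenerate and duplicate seed sets are rejected", {
  line <- cbind(1:10, 2 * (1:10) + 1)
  expect_error(tessellate(line), "collinear")
  plane <- cbind(rand_points(10, 2, 10, seed = 1), 0)
  expect_error(tessellate(plane), "coplanar")
  expect_error(tessellate(rand_points(3, 2, 10, seed = 2)), "at least 4")
  dup <- rbind(square_centre_seeds(), c(0.5, 0.5))
  expect_error(tessellate(dup), "duplicate")
  td <- tessellate(dup, dedupe = TRUE)
  expect_equal(length(td$bounded), 5L)
  expect_equal(td$measure[5], 0.5, tolerance = 1e-12)
})

test_that("an ROI override replaces the total measure only", {
  tt <- tessellate(square_centre_seeds(), total_measure = 2.6)
  expect_equal(tt$total_measure, 2.6)
  expect_equal(tt$measure[5], 0.5, tolerance = 1e-12)
  expect_true(tt$roi_override)
  expect_error(tessellate(square_centre_seeds(), total_measure = -1),
               "positive")
})

test_that("the per-region table export carries geometry and density", {
  tt <- tessellate(square_centre_seeds())
  df <- as.data.frame(tt)
  expect_named(df, c("region", "x", "y", "bounded", "measure", "nnd"))
  expect_equal(nrow(df), 5L)
  expect_equal(df$measure[5], 0.5, tolerance = 1e-12)
})
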