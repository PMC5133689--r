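ft <- 0.3048

test_that("ignition clustering honours the 20-ft link distance and 3-point minimum", {
  # chain of 3 points with consecutive 15-ft gaps: one cluster
  chain <- tibble::tibble(x = c(0, 15, 30) * ft, y = 0)
  cl <- cluster_ignition_points(chain)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$n, 3L)
  # two points 5 ft apart: below the minimum size, no cluster
  pair <- tibble::tibble(x = c(0, 5) * ft, y = 0)
  expect_equal(nrow(cluster_ignition_points(pair)$clusters), 0)
  # empty input warns
  expect_warning(cluster_ignition_points(tibble::tibble(x = double(), y = double())),
                 "no ignition-on points")
})

test_that("cluster partition matches brute-force union-find on random points", {
  set.seed(17)
  pts <- tibble::tibble(x = runif(200, 0, 60), y = runif(200, 0, 60))
  cl <- cluster_ignition_points(pts, link_distance_m = 20 * ft, min_size = 1)
  ref <- oracle_components(pts$x, pts$y, 20 * ft)
  got <- cl$points$cluster_id
  expect_true(all(tapply(ref, got, function(v) length(unique(v))) == 1))
  expect_equal(length(unique(got)), length(unique(ref)))
  # order independence
  perm <- sample(200)
  cl2 <- cluster_ignition_points(pts[perm, ], link_distance_m = 20 * ft, min_size = 1)
  g2 <- cl2$points$cluster_id[order(perm)]
  expect_true(all(tapply(got, g2, function(v) length(unique(v))) == 1))
})

test_that("primary locations require a 10% ignition-on share", {
  one_spot <- tibble::tibble(x = rnorm(40, 0, 0.5), y = rnorm(40, 0, 0.5))
  pl <- detect_primary_locations(cluster_ignition_points(one_spot))
  expect_equal(nrow(pl), 1)
  expect_equal(pl$share, 1.0)

  # clusters at 60% and 20% of 50 ignition-ons: both primary
  pts <- dplyr::bind_rows(
    tibble::tibble(x = rnorm(30, 0, 0.5), y = rnorm(30, 0, 0.5)),
    tibble::tibble(x = rnorm(10, 500, 0.5), y = rnorm(10, 0, 0.5)),
    tibble::tibble(x = 1000 + (1:10) * 50, y = 500)   # scattered singletons
  )
  pl2 <- detect_primary_locations(cluster_ignition_points(pts))
  expect_equal(nrow(pl2), 2)
  expect_equal(pl2$share, c(0.6, 0.2))
  expect_lt(abs(pl2$centroid_x[1]), 1)
  expect_lt(abs(pl2$centroid_x[2] - 500), 1)

  # a 9.9%-share cluster is not primary (threshold boundary)
  total <- 1000L
  small <- cluster_ignition_points(
    tibble::tibble(x = rnorm(99, 0, 0.3), y = rnorm(99, 0, 0.3))
  )
  expect_equal(nrow(detect_primary_locations(small, total_ignition_on = total)), 0)
  at_thr <- cluster_ignition_points(
    tibble::tibble(x = rnorm(100, 0, 0.3), y = rnorm(100, 0, 0.3))
  )
  expect_equal(nrow(detect_primary_locations(at_thr, total_ignition_on = total)), 1)
})

test_that("destination counts follow the disc-dissolve geometry", {
  # a single ignition-on point is one destination at every radius
  single <- tibble::tibble(x = 0, y = 0)
  expect_equal(count_unique_destinations(single)$n_destinations, c(1L, 1L, 1L))

  # two points 250 ft apart: circles of r=100 don't meet, r=250 do
  two <- tibble::tibble(x = c(0, 250 * ft), y = 0)
  cnt <- count_unique_destinations(two)
  expect_equal(cnt$n_destinations[cnt$radius_ft == 100], 2L)
  expect_equal(cnt$n_destinations[cnt$radius_ft == 250], 1L)
  expect_equal(cnt$n_destinations[cnt$radius_ft == 500], 1L)

  # tangent discs (distance exactly 2r) stay separate: strict merge rule
  tangent <- tibble::tibble(x = c(0, 200 * ft), y = 0)
  expect_equal(
    count_unique_destinations(tangent, radii_ft = 100)$n_destinations, 2L
  )
})

test_that("random destination counts equal brute-force disc-union oracles and decrease with radius", {
  # 100-point set vs all-pairs disc-overlap components (strict: d < 2r)
  set.seed(23)
  pts <- tibble::tibble(x = runif(100, 0, 900), y = runif(100, 0, 900))
  cnt <- count_unique_destinations(pts)
  for (r_ft in c(100, 250, 500)) {
    ref <- max(oracle_components(pts$x, pts$y, 2 * r_ft * ft, strict = TRUE))
    expect_equal(cnt$n_destinations[cnt$radius_ft == r_ft], ref)
  }
  expect_true(all(diff(cnt$n_destinations) <= 0))

  # explicit geometric union (rasterised disc union) on a small fixture whose
  # pairwise distances stay clear of tangency at every radius, so the raster
  # resolves every gap and overlap unambiguously
  set.seed(52)
  sx <- runif(20, 0, 400); sy <- runif(20, 0, 400)
  d <- as.matrix(dist(cbind(sx, sy))); diag(d) <- Inf
  small <- tibble::tibble(x = sx, y = sy)
  cnt2 <- count_unique_destinations(small)
  for (r_ft in c(100, 250, 500)) {
    stopifnot(min(abs(d - 2 * r_ft * ft)) > 1.8)   # oracle validity margin
    geo <- oracle_disc_union_count(sx, sy, r_ft * ft, h = 0.7)
    expect_equal(cnt2$n_destinations[cnt2$radius_ft == r_ft], geo)
  }
})

test_that("synthetic anchors are recovered within 100 ft with exact shares", {
  scn <- small_scenario()
  crumbs <- project_local(scn$crumbs, center = scn$config$center)
  ign <- dplyr::filter(crumbs, event_type == "ignition_on")
  cl <- cluster_ignition_points(ign)
  pl <- detect_primary_locations(cl)
  anchors <- scn$manifest$anchors
  expect_gte(nrow(pl), nrow(anchors))
  for (a in seq_len(nrow(anchors))) {
    d <- sqrt((pl$centroid_x - anchors$x[a])^2 + (pl$centroid_y - anchors$y[a])^2)
    expect_lt(min(d), 100 * ft)
  }
  # emitted ignition-on rows near the anchor match the manifest share exactly
  share <- scn$manifest$expected$anchor_ignition_share[["anchor1"]]
  near <- sqrt((ign$x - anchors$x[1])^2 + (ign$y - anchors$y[1])^2) < 50
  expect_equal(sum(near) / nrow(scn$manifest$trips), share, tolerance = 1e-9)
})
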