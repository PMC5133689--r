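test_that("local projection is exact on round-trip and metric at kilometre scale", {
  center <- c(38.63, -90.20)
  # the centre maps to the origin
  at_center <- project_local(tibble::tibble(latitude = 38.63, longitude = -90.20),
                             center = center)
  expect_equal(c(at_center$x, at_center$y), c(0, 0), tolerance = 1e-9)

  set.seed(42)
  pts <- tibble::tibble(
    latitude = 38.63 + runif(1000, -0.5, 0.5),
    longitude = -90.20 + runif(1000, -0.5, 0.5)
  )
  proj <- project_local(pts, center = center)
  back <- unproject_local(proj$x, proj$y, center)
  err_m <- sqrt(((back$latitude - pts$latitude) * 111e3)^2 +
                  ((back$longitude - pts$longitude) * 111e3 * cos(38.63 * pi / 180))^2)
  expect_lt(max(err_m), 0.1)

  skip_if_not_installed("geosphere")
  # two points ~1 km apart: planar distance within 0.5% of the haversine
  a <- c(-90.20, 38.63); b <- c(-90.195, 38.637)
  hav <- geosphere::distHaversine(a, b)
  pp <- project_local(tibble::tibble(latitude = c(a[2], b[2]),
                                     longitude = c(a[1], b[1])), center = center)
  plan <- sqrt(diff(pp$x)^2 + diff(pp$y)^2)
  expect_lt(abs(plan - hav) / hav, 0.005)
})

test_that("convex hulls match a gift-wrapping oracle and contain their points", {
  set.seed(7)
  x <- rnorm(500); y <- rnorm(500)
  areas <- compute_driving_area(
    tibble::tibble(vehicle_id = "v", local_month = "2016-07", x = x, y = y)
  )
  hull <- areas$hull[[1]]
  oracle <- oracle_gift_wrap(x, y)
  key <- function(m) sort(paste(round(m[, 1], 9), round(m[, 2], 9)))
  expect_equal(key(hull), key(oracle))
  expect_true(all(point_in_ring(x, y, hull)))
})

test_that("a one-kilometre square has unit hull area and central mean center", {
  sq <- tibble::tibble(
    vehicle_id = "v", local_month = "2016-07",
    x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000)
  )
  area <- compute_driving_area(sq)
  expect_equal(area$area_km2, 1.0, tolerance = 1e-12)
  expect_false(area$degenerate)
  mc <- compute_mean_center(sq)
  expect_equal(c(mc$x, mc$y), c(500, 500))

  # fewer than 3 distinct points, or collinear: degenerate, zero area
  line <- tibble::tibble(vehicle_id = "v", local_month = "2016-07",
                         x = c(0, 1, 2), y = c(0, 1, 2))
  expect_true(compute_driving_area(line)$degenerate)
  expect_equal(compute_driving_area(line)$area_km2, 0)
})

test_that("mean centers lie inside their convex hulls", {
  set.seed(11)
  for (rep in 1:20) {
    df <- tibble::tibble(vehicle_id = "v", local_month = "2016-07",
                         x = rnorm(50, sd = 500), y = rnorm(50, sd = 500))
    hull <- compute_driving_area(df)$hull[[1]]
    mc <- compute_mean_center(df)
    expect_true(point_in_ring(mc$x, mc$y, hull))
  }
})

test_that("adding a point never shrinks the driving area", {
  set.seed(3)
  x <- runif(40, 0, 1000); y <- runif(40, 0, 1000)
  base <- compute_driving_area(tibble::tibble(vehicle_id = "v",
                                              local_month = "m", x = x, y = y))
  for (rep in 1:20) {
    nx <- runif(1, -500, 1500); ny <- runif(1, -500, 1500)
    grown <- compute_driving_area(tibble::tibble(
      vehicle_id = "v", local_month = "m", x = c(x, nx), y = c(y, ny)
    ))
    expect_gte(grown$area_km2, base$area_km2 - 1e-12)
  }
})

test_that("overlap metrics: identical, disjoint and half-overlapping months", {
  sq <- function(x0, y0, s = 1000) {
    cbind(c(x0, x0 + s, x0 + s, x0), c(y0, y0, y0 + s, y0 + s))
  }
  mk_area <- function(hulls, months) {
    tibble::tibble(
      vehicle_id = "v", local_month = months,
      n_crumbs = 4L, hull = hulls,
      area_km2 = vapply(hulls, function(h) abs(pracma_shoelace(h)) / 1e6, 0),
      degenerate = FALSE
    )
  }
  pracma_shoelace <- function(h) {
    x <- h[, 1]; y <- h[, 2]
    sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  }

  same <- mk_area(list(sq(0, 0), sq(0, 0), sq(0, 0)), c("m1", "m2", "m3"))
  om <- overlap_metrics(same)
  expect_equal(om$overall$ratio, 1.0, tolerance = 1e-12)

  apart <- mk_area(list(sq(0, 0), sq(5000, 0)), c("m1", "m2"))
  om2 <- overlap_metrics(apart)
  expect_equal(om2$overall$ratio, 0.0)
  expect_equal(om2$pairwise$overlap_km2, 0)

  # unit square and its half-overlapping translate:
  # intersection 0.5 km2, union 1.5 km2, ratio 1/3
  shift <- mk_area(list(sq(0, 0), sq(500, 0)), c("m1", "m2"))
  om3 <- overlap_metrics(shift)
  expect_equal(om3$pairwise$overlap_km2, 0.5, tolerance = 1e-12)
  expect_equal(om3$overall$common_all_km2, 0.5, tolerance = 1e-12)
  expect_equal(om3$overall$total_km2, 1.5, tolerance = 1e-12)
  expect_equal(om3$overall$ratio, 0.5 / 1.5, tolerance = 1e-12)

  # pairwise overlap can never exceed the smaller month, ratio stays in [0,1]
  set.seed(5)
  rand_hull <- function() {
    x <- runif(30, 0, 2000); y <- runif(30, 0, 2000)
    compute_driving_area(tibble::tibble(vehicle_id = "v", local_month = "m",
                                        x = x, y = y))$hull[[1]]
  }
  hs <- list(rand_hull(), rand_hull(), rand_hull())
  ra <- mk_area(hs, c("m1", "m2", "m3"))
  om4 <- overlap_metrics(ra)
  expect_true(om4$overall$ratio >= 0 && om4$overall$ratio <= 1)
  for (i in seq_len(nrow(om4$pairwise))) {
    a1 <- ra$area_km2[ra$local_month == om4$pairwise$period_a[i]]
    a2 <- ra$area_km2[ra$local_month == om4$pairwise$period_b[i]]
    expect_lte(om4$pairwise$overlap_km2[i], min(a1, a2) + 1e-12)
  }
})

test_that("threshold components equal brute-force union-find and ignore input order", {
  set.seed(13)
  x <- runif(200, 0, 100); y <- runif(200, 0, 100)
  for (thr in c(3, 8, 15)) {
    got <- threshold_components(x, y, thr)
    ref <- oracle_components(x, y, thr)
    # same partition (labels may differ)
    expect_equal(got[order(x, y)], got[order(x, y)])
    expect_true(all(tapply(ref, got, function(v) length(unique(v))) == 1))
    expect_equal(length(unique(got)), length(unique(ref)))
  }
  # permutation invariance of the partition
  perm <- sample(200)
  g1 <- threshold_components(x, y, 8)
  g2 <- threshold_components(x[perm], y[perm], 8)[order(perm)]
  expect_true(all(tapply(g1, g2, function(v) length(unique(v))) == 1))
  expect_equal(length(unique(g1)), length(unique(g2)))
})
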