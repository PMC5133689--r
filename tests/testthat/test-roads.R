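mk_random_segments <- function(n, span = 5000) {
  tibble::tibble(
    segment_id = seq_len(n),
    name = sprintf("seg %d", seq_len(n)),
    cfcc = "A41",
    avg_speed = sample(c(25, 35, 55), n, replace = TRUE),
    polyline = purrr::map(seq_len(n), function(i) {
      a <- runif(2, 0, span)
      ang <- runif(1, 0, 2 * pi)
      len <- runif(1, 50, 600)
      rbind(a, a + len * c(cos(ang), sin(ang)))
    })
  )
}

test_that("nearest-segment queries: on-segment hits, deterministic tie-breaks", {
  segs <- tibble::tibble(
    segment_id = c(5L, 9L),
    name = c("a", "b"), cfcc = "A41", avg_speed = 30,
    polyline = list(cbind(c(0, 100), c(0, 0)), cbind(c(0, 100), c(20, 20)))
  )
  idx <- build_segment_index(segs)
  on_seg <- nearest_segment(50, 0, idx)
  expect_equal(on_seg$near_fid, 5L)
  expect_equal(on_seg$near_dist, 0)
  # equidistant from both: the lower segment_id wins
  tie <- nearest_segment(50, 10, idx)
  expect_equal(tie$near_fid, 5L)
  expect_equal(tie$near_dist, 10)
  expect_error(build_segment_index(segs[0, ]))
})

test_that("indexed nearest equals exhaustive search on 1000 points x 200 segments", {
  set.seed(31)
  segs <- mk_random_segments(200)
  idx <- build_segment_index(segs)
  px <- runif(1000, -200, 5200); py <- runif(1000, -200, 5200)
  got <- nearest_segment(px, py, idx)
  for (q in seq_len(1000)) {
    ref <- oracle_nearest_segment(px[q], py[q], segs)
    expect_equal(got$near_fid[q], ref$id)
    expect_equal(got$near_dist[q], ref$dist, tolerance = 1e-9)
  }
})

test_that("near distance is invariant under joint rigid motion", {
  set.seed(33)
  segs <- mk_random_segments(40, span = 2000)
  px <- runif(50, 0, 2000); py <- runif(50, 0, 2000)
  d0 <- nearest_segment(px, py, build_segment_index(segs))$near_dist
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(1234, -567)
  segs_r <- dplyr::mutate(segs, polyline = purrr::map(polyline, function(pl) {
    sweep(pl %*% t(R), 2, -shift)
  }))
  p_r <- cbind(px, py) %*% t(R)
  d1 <- nearest_segment(p_r[, 1] + shift[1], p_r[, 2] + shift[2],
                        build_segment_index(segs_r))$near_dist
  expect_equal(d1, d0, tolerance = 1e-6)
})

test_that("breadcrumb annotation inherits road attributes and flags off-network fixes", {
  segs <- tibble::tibble(
    segment_id = 1L, name = "Main St", cfcc = "A31", avg_speed = 35,
    polyline = list(cbind(c(0, 1000), c(0, 0)))
  )
  crumbs <- tibble::tibble(x = c(500, 500), y = c(5, 2000))
  ann <- annotate_breadcrumbs(crumbs, segs)
  expect_equal(ann$road_name[1], "Main St")
  expect_equal(ann$road_avg_speed[1], 35)
  expect_false(ann$off_network[1])
  expect_true(ann$off_network[2])
  expect_true(is.na(ann$road_name[2]))
})

test_that("a synthetic drive is annotated with its scheduled route's streets", {
  scn <- small_scenario()
  crumbs <- project_local(scn$crumbs, center = scn$config$center)
  moving <- dplyr::filter(crumbs, event_type == "regular")
  ann <- annotate_breadcrumbs(moving, scn$segments)
  # moving crumbs sit on the grid up to GPS noise: nearly all on-network and
  # within a few metres of their street
  expect_gte(mean(!ann$off_network), 0.99)
  expect_lt(median(ann$near_dist), 15 * 0.3048 * 2)
})

test_that("segments round-trip through GeoJSON", {
  segs <- mk_random_segments(5, span = 2000)
  center <- c(38.63, -90.20)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_segments_geojson(segs, path, center)
  back <- read_segments_geojson(path, center)
  expect_equal(back$segment_id, segs$segment_id)
  expect_equal(back$avg_speed, segs$avg_speed)
  for (i in seq_len(5)) {
    expect_equal(back$polyline[[i]], segs$polyline[[i]], tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})
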