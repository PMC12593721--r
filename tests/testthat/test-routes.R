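mk_routes <- function(xy) {
  route_table(data.frame(route_id = seq_len(nrow(xy)), x_km = xy[, 1],
                         y_km = xy[, 2], richness = 50))
}

test_that("human-cover filter applies a strict threshold on the buffer fraction", {
  # 100% natural landscape: retained
  forest <- grid_raster(matrix(10, 40, 40), res_km = 1)
  r <- human_cover_filter(mk_routes(cbind(20, 20)), forest,
                          human_classes = c(1, 2, 3), radius_km = 10)
  expect_true(r$retained[1])
  expect_equal(r$human_frac[1], 0)
  # exactly 50% cropland: dropped (boundary exclusive)
  half <- grid_raster(cbind(matrix(1, 40, 20), matrix(10, 40, 20)),
                      res_km = 1)
  # build a buffer that covers an exact half-half split: use the full raster
  r2 <- human_cover_filter(mk_routes(cbind(20, 20)), half,
                           human_classes = 1, radius_km = 100,
                           threshold = 0.5)
  expect_false(r2$retained[1])
  expect_equal(r2$human_frac[1], 0.5)
  expect_equal(r2$drop_reason[1], "human_cover")
  # just under the threshold: retained; fraction checked by brute force
  set.seed(11)
  m <- matrix(10, 30, 30)
  idx <- sample(900, 440)  # 48.9% urban
  m[idx] <- 2
  lc <- grid_raster(m, res_km = 1)
  r3 <- human_cover_filter(mk_routes(cbind(15, 15)), lc, human_classes = 2,
                           radius_km = 50)
  expect_true(r3$retained[1])
  expect_equal(r3$human_frac[1], mean(m == 2))
  # brute-force fraction inside a smaller buffer
  cc <- cell_centers(lc)
  inside <- outer((cc$y - 15)^2, (cc$x - 15)^2, "+") <= 8^2
  r4 <- human_cover_filter(mk_routes(cbind(15, 15)), lc, human_classes = 2,
                           radius_km = 8)
  expect_equal(r4$human_frac[1], mean(m[inside] == 2))
  # empty buffer: dropped with its own reason
  hole <- grid_raster(matrix(NA_real_, 40, 40), res_km = 1)
  r5 <- human_cover_filter(mk_routes(cbind(20, 20)), hole, 1,
                           radius_km = 5)
  expect_false(r5$retained[1])
  expect_equal(r5$drop_reason[1], "no_valid_landcover")
})

test_that("containment filter requires the whole buffer inside the boundary", {
  box <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  pts <- rbind(c(50, 50),     # deep interior
               c(50, 10.5),   # 10.5 km from the edge
               c(50, 9.9),    # closer than the radius
               c(150, 50))    # outside entirely
  r <- containment_filter(mk_routes(pts), box, radius_km = 10)
  expect_equal(r$retained, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$drop_reason[3], "buffer_outside_boundary")
  expect_error(containment_filter(mk_routes(pts), cbind(0, 0)), "invalid")
})

test_that("containment decisions agree with dense circle-point sampling", {
  # convex pentagon
  ang <- seq(0, 2 * pi, length.out = 6)[-6]
  poly <- cbind(50 + 40 * cos(ang), 50 + 40 * sin(ang))
  set.seed(21)
  pts <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  r <- containment_filter(mk_routes(pts), poly, radius_km = 12)
  circ <- seq(0, 2 * pi, length.out = 361)[-361]
  for (i in seq_len(nrow(pts))) {
    samples <- cbind(pts[i, 1] + 12 * cos(circ), pts[i, 2] + 12 * sin(circ))
    all_in <- all(vapply(seq_len(360), function(k)
      svcspde:::point_in_rings(samples[k, ], list(poly)), logical(1))) &&
      svcspde:::point_in_rings(pts[i, ], list(poly))
    expect_equal(r$retained[i], all_in,
                 label = paste("route", i, "containment"))
  }
})

test_that("retention filters commute", {
  set.seed(31)
  lc <- grid_raster(matrix(sample(c(1, 10), 3600, replace = TRUE,
                                  prob = c(0.45, 0.55)), 60, 60), res_km = 1)
  box <- cbind(c(5, 55, 55, 5), c(5, 5, 55, 55))
  pts <- cbind(runif(30, 0, 60), runif(30, 0, 60))
  a <- containment_filter(human_cover_filter(mk_routes(pts), lc, 1,
                                             radius_km = 6), box,
                          radius_km = 6)
  b <- human_cover_filter(containment_filter(mk_routes(pts), box,
                                             radius_km = 6), lc, 1,
                          radius_km = 6)
  expect_equal(a$retained, b$retained)
})

test_that("route tables validate and round-trip through CSV", {
  expect_error(route_table(data.frame(route_id = c(1, 1), x_km = 0,
                                      y_km = 0, richness = 1)), "unique")
  expect_error(route_table(data.frame(x_km = 0)), "missing columns")
  r <- mk_routes(cbind(1:3, 4:6))
  r$retained[2] <- FALSE
  r$drop_reason[2] <- "human_cover"
  f <- tempfile(fileext = ".csv")
  write_route_csv(r, f)
  r2 <- read_route_csv(f)
  expect_equal(r2$retained, r$retained)
  expect_equal(r2$drop_reason, r$drop_reason)
  unlink(f)
})
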