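disk_image <- function(r, pad = 10, value = 0.8) {
  n <- 2 * r + 2 * pad
  img <- matrix(0, n, n)
  yy <- row(img) - n / 2
  xx <- col(img) - n / 2
  img[yy^2 + xx^2 <= r^2] <- value
  img
}

test_that("segmentation finds disjoint components, merges overlaps, fills holes", {
  img <- matrix(0, 120, 200)
  for (cx in c(40, 100, 160)) {
    yy <- row(img) - 60; xx <- col(img) - cx
    img[yy^2 + xx^2 <= 15^2] <- 0.8
  }
  expect_length(segment_colonies(img, 0.3, 50), 3L)

  # two overlapping disks form one component
  img2 <- matrix(0, 100, 100)
  for (cx in c(40, 60)) {
    yy <- row(img2) - 50; xx <- col(img2) - cx
    img2[yy^2 + xx^2 <= 15^2] <- 0.8
  }
  expect_length(segment_colonies(img2, 0.3, 50), 1L)

  # interior hole is filled into the colony area
  img3 <- matrix(0, 100, 100)
  yy <- row(img3) - 50; xx <- col(img3) - 50
  img3[yy^2 + xx^2 <= 30^2] <- 0.8
  img3[yy^2 + xx^2 <= 10^2] <- 0
  m <- segment_colonies(img3, 0.3, 50)
  expect_length(m, 1L)
  expect_equal(nrow(m[[1]]), sum(yy^2 + xx^2 <= 30^2))

  # all-background image: empty list, not an error
  expect_length(segment_colonies(matrix(0, 50, 50)), 0L)

  # diagonal contact merges under 8-connectivity
  img4 <- matrix(0, 10, 10)
  img4[2:4, 2:4] <- 0.9
  img4[5:7, 5:7] <- 0.9
  expect_length(segment_colonies(img4, 0.3, 5), 1L)
})

test_that("isoperimetric geometry: disk, square, ellipse within tolerance", {
  g <- measure_colony(segment_colonies(disk_image(50), 0.3, 50)[[1]])
  expect_gte(g$circularity, 0.93)
  expect_lte(g$circularity, 1.02)

  sq <- matrix(0, 120, 120); sq[11:110, 11:110] <- 0.9
  gs <- measure_colony(segment_colonies(sq, 0.3, 50)[[1]])
  expect_equal(gs$area_px, 10000L)
  expect_equal(gs$circularity, pi / 4, tolerance = 0.03 / (pi / 4))

  e <- matrix(0, 200, 200)
  yy <- row(e) - 100; xx <- col(e) - 100
  e[(xx / 60)^2 + (yy / 30)^2 <= 1] <- 0.8
  ge <- measure_colony(segment_colonies(e, 0.3, 50)[[1]])
  # Ramanujan perimeter of the ideal 2:1 ellipse gives 0.841
  h <- (60 - 30)^2 / (60 + 30)^2
  per <- pi * 90 * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  ideal <- 4 * pi * (pi * 60 * 30) / per^2
  expect_equal(ge$circularity, ideal, tolerance = 0.03 / ideal)

  # disk maximizes the isoperimetric quotient at matched area
  expect_gt(g$circularity, gs$circularity)
  expect_gt(g$circularity, ge$circularity)

  # physical units
  gu <- measure_colony(segment_colonies(disk_image(20), 0.3, 50)[[1]],
                       pixel_size = 2)
  expect_equal(gu$area_um2, gu$area_px * 4)
  expect_error(measure_colony(matrix(numeric(), 0, 2)), "empty mask")
})

test_that("colony classification follows the 14-cell and countability rules", {
  expect_equal(classify_colony(14, TRUE), "not_colony")   # strict threshold
  expect_equal(classify_colony(15, TRUE), "sparse")
  expect_equal(classify_colony(40, FALSE), "dense")
  expect_equal(classify_colony(0, FALSE), "not_colony")
  expect_error(classify_colony(-1, TRUE), ">= 0")
})

test_that("CFE is the per-1e5 seeding rate and is jointly scale-invariant", {
  expect_equal(colony_forming_efficiency(44, 1e6), 4.4)
  expect_equal(colony_forming_efficiency(0, 123), 0)
  expect_equal(colony_forming_efficiency(30, 2e5),
               colony_forming_efficiency(300, 2e6))
  expect_error(colony_forming_efficiency(10, 0), "n_seeded")
  # the control/differentiated comparison is a plain ratio of CFEs
  expect_equal(colony_forming_efficiency(111, 1e6) /
                 colony_forming_efficiency(44, 1e6),
               11.1 / 4.4)
})

test_that("grid proportions pool correctly and match the binomial oracle", {
  expect_equal(grid_proportion(cbind(c(5, 5), c(10, 10)))$fraction, 0.5)
  expect_equal(grid_proportion(cbind(rep(0, 20), rep(10, 20)))$fraction, 0)
  expect_error(grid_proportion(cbind(0, 0)), "empty")
  expect_error(grid_proportion(cbind(5, 4)), "positive")

  set.seed(2)
  pos <- stats::rbinom(20, 30, 0.35)
  gp <- grid_proportion(cbind(pos, rep(30, 20)))
  se <- sqrt(0.35 * 0.65 / (20 * 30))
  expect_lt(abs(gp$fraction - 0.35), 3 * se)
  expect_equal(gp$percent, 100 * gp$fraction)
  expect_length(gp$per_field, 20L)
})

test_that("ordinal staining score covers [0,1] monotonically with no gaps", {
  expect_equal(semiquant_score(0.10), "-")
  expect_equal(semiquant_score(0.25), "+")
  expect_equal(semiquant_score(0.50), "+")     # boundary closed at '+'
  expect_equal(semiquant_score(0.60), "++")
  expect_equal(semiquant_score(0.75), "++")
  expect_equal(semiquant_score(1.00), "+++")
  expect_error(semiquant_score(1.2), "\\[0,1\\]")
  # monotone over a fine grid
  grid <- seq(0, 1, by = 0.001)
  lv <- match(semiquant_score(grid), c("-", "+", "++", "+++"))
  expect_true(all(diff(lv) >= 0))
})

test_that("quadrant counts conserve totals and use half-open boundaries", {
  pos <- cbind(c(10, 10, 90, 90, 10, 10, 90, 90),
               c(10, 20, 10, 20, 90, 80, 90, 80))
  qs <- quadrant_summary(pos, c(100, 100))
  expect_equal(qs$counts, rep(2L, 4))
  expect_equal(qs$mean_per_quadrant, 2)

  # exactly on the vertical midline: left quadrant, counted once
  qs2 <- quadrant_summary(cbind(50, 10), c(100, 100))
  expect_equal(qs2$counts, c(1L, 0L, 0L, 0L))
  expect_equal(sum(qs2$counts), 1L)

  set.seed(9)
  pos3 <- cbind(stats::runif(200, 0, 100), stats::runif(200, 0, 100))
  expect_equal(sum(quadrant_summary(pos3, c(100, 100))$counts), 200L)
  expect_error(quadrant_summary(pos, c(0, 100)), "zero-area")
})

test_that("segmentation + measurement recover generator ground truth", {
  f <- gen_colony_field(n_colonies = 6, seed = 5)
  masks <- segment_colonies(f$image, 0.3, 50)
  expect_length(masks, nrow(f$truth))
  tab <- analyze_colony_image(f$image, field_id = "t")
  # match measured colonies to truth by nearest centroid
  m <- vapply(seq_len(nrow(tab)), function(i) {
    which.min((f$truth$cx - tab$cx[i])^2 + (f$truth$cy - tab$cy[i])^2)
  }, integer(1))
  expect_equal(sort(m), 1:6)
  expect_equal(tab$area_px, f$truth$area_px[m])         # exact recovery
  expect_true(all(abs(tab$area_px / f$truth$area_px[m] - 1) <= 0.05))
})
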