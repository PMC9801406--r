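test_that("crop_lane does shape arithmetic and back-maps exactly", {
  cam <- camera_model()
  fr <- render_frame(cam, lane_model(), list(), 0)
  full <- crop_lane(fr, NULL)
  expect_identical(full$depth, fr$depth)

  cr <- crop_lane(fr, c(101, 620, 1, 1280))
  expect_equal(dim(cr$depth), c(520, 1280))

  px <- cbind(c(1, 10, 520), c(1, 7, 1280))
  back <- back_map_pixels(px, cr)
  expect_equal(back[, 1], px[, 1] + 100)
  expect_equal(back[, 2], px[, 2])

  expect_error(crop_lane(fr, c(10, 5, 1, 10)), "empty or outside")
})

test_that("the colorization ramp is monotone, well-defined and invertible", {
  range <- c(400, 2750)
  expect_equal(hue_of_depth(400, range), 0)
  expect_equal(hue_of_depth(2750, range), 240)
  d <- 400:2750
  h <- hue_of_depth(d, range)
  expect_true(all(diff(h) > 0))
  # brute-force inversion over every integer depth in range
  expect_lt(max(abs(depth_of_hue(h, range) - d)), 1e-9)
  # equal depths map to equal hue
  expect_equal(hue_of_depth(1234, range), hue_of_depth(1234, range))

  fr <- depth_frame(matrix(c(400L, 2750L, 1500L, NA), 2, 2))
  hsv <- colorize_depth(fr, range)
  expect_equal(hsv$v[2, 2], 0)       # sentinel has zero value
  expect_equal(hsv$v[1, 1], 1)
  expect_equal(hsv$h[1, 1], 0)
  expect_equal(hsv$h[2, 1], 240)
})

test_that("hue thresholding equals direct depth thresholding on valid pixels", {
  set.seed(13)
  range <- c(400, 2750)
  for (i in 1:25) {
    d <- matrix(as.integer(sample(400:2750, 300, replace = TRUE)), 15, 20)
    d[sample(300, 30)] <- NA
    fr <- depth_frame(d)
    hsv <- colorize_depth(fr, range)
    a <- sort(sample(400:2750, 2))
    got <- threshold_hue(hsv, hue_of_depth(a, range))
    want <- !is.na(d) & d >= a[1] & d <= a[2]
    expect_identical(got, want)
  }
})

test_that("empty and full hue bands behave as bounds", {
  d <- matrix(as.integer(seq(500, 2700, length.out = 12)), 3, 4)
  d[1, 1] <- NA
  hsv <- colorize_depth(depth_frame(d), c(400, 2750))
  expect_false(any(threshold_hue(hsv, c(10, 10 - 1e-9))))
  full <- threshold_hue(hsv, c(0, 240))
  expect_identical(full, !is.na(d))
})

test_that("largest_contour keeps the biggest blob and matches the BFS oracle", {
  m <- matrix(FALSE, 40, 40)
  m[2:21, 2:21] <- TRUE    # 400 px
  m[30:38, 30:39] <- TRUE  # 90 px
  lc <- largest_contour(m)
  expect_equal(lc$area, 400L)
  expect_equal(sort(lc$component_areas), c(90L, 400L))
  expect_true(all(which(lc$mask) %in% which(m)))

  single <- matrix(FALSE, 10, 10); single[3:6, 4:8] <- TRUE
  expect_identical(largest_contour(single)$mask, single)

  empty <- matrix(FALSE, 5, 5)
  expect_true(largest_contour(empty)$empty)

  set.seed(17)
  for (i in 1:100) {
    g <- matrix(runif(2500) < runif(1, 0.15, 0.6), 50, 50)
    lc <- largest_contour(g)
    lab <- oracle_label8(g)
    if (max(lab) == 0) {
      expect_true(lc$empty)
    } else {
      areas <- tabulate(lab[lab > 0])
      expect_equal(lc$area, max(areas))
      expect_equal(sort(lc$component_areas), sort(areas))
      # the retained component is one of the oracle's maximal components
      labs_in_mask <- unique(lab[lc$mask])
      expect_length(labs_in_mask, 1)
      expect_equal(areas[labs_in_mask], max(areas))
    }
  }
})

test_that("the traced contour is the boundary of the retained component", {
  m <- matrix(FALSE, 30, 30)
  m[5:20, 8:25] <- TRUE
  lc <- largest_contour(m)
  ct <- lc$contour
  expect_true(all(m[ct]))
  # boundary pixels have at least one 4-neighbor outside the component
  pad <- matrix(FALSE, 32, 32); pad[2:31, 2:31] <- lc$mask
  is_boundary <- function(r, c) {
    !all(pad[cbind(r + 1 + c(-1, 1, 0, 0), c + 1 + c(0, 0, -1, 1))])
  }
  expect_true(all(mapply(is_boundary, ct[, 1], ct[, 2])))
  # every true boundary pixel appears in the trace
  bnd <- which(lc$mask & !(rbind(FALSE, lc$mask[-30, ]) &
                             rbind(lc$mask[-1, ], FALSE) &
                             cbind(FALSE, lc$mask[, -30]) &
                             cbind(lc$mask[, -1], FALSE)))
  expect_setequal(bnd, (ct[, 2] - 1) * 30 + ct[, 1])
})

test_that("closing matches the brute-force oracle and fills only small holes", {
  solid <- matrix(TRUE, 40, 40)
  holed <- solid; holed[18:22, 18:22] <- FALSE  # 5x5 hole
  closed <- close_mask(holed, 10)
  expect_identical(closed, oracle_close(holed, 10))
  expect_true(all(closed))  # 5x5 hole filled by a 10x10 element

  big <- matrix(TRUE, 60, 60); big[16:45, 16:45] <- FALSE  # 30x30 hole
  closed_big <- close_mask(big, 10)
  expect_identical(closed_big, oracle_close(big, 10))
  expect_false(all(closed_big))  # not fully filled

  expect_identical(close_mask(solid, 10), solid)  # idempotent on closed sets

  set.seed(19)
  for (i in 1:20) {
    g <- matrix(runif(900) < 0.4, 30, 30)
    k <- sample(c(2L, 3L, 7L, 10L), 1)
    got <- close_mask(g, k)
    expect_identical(got, oracle_close(g, k))
    expect_true(all(got[g]))  # extensivity: output contains input
  }
})

test_that("the full chain segments a clean synthetic cow with IoU >= 0.9", {
  cam <- test_camera(320, 180)
  lane <- lane_model()
  params <- seg_params(cam, crop = lane_crop(cam, lane))
  for (t in c(1.0, 1.5, 2.2)) {
    fr <- render_frame(cam, lane, cow_model(speed = 1), t)
    sm <- segment_frame(fr, params)
    expect_false(sm$empty)
    truth <- crop_truth(fr, params$crop)
    iou <- sum(sm$mask & truth) / sum(sm$mask | truth)
    expect_gte(iou, 0.9)
    # final mask is a single 8-connected component
    expect_equal(max(oracle_label8(sm$mask)), 1)
  }
})

test_that("dropout holes smaller than the closing element vanish", {
  cam <- test_camera(320, 180)
  lane <- lane_model()
  params <- seg_params(cam, crop = lane_crop(cam, lane))
  fr <- render_frame(cam, lane, cow_model(speed = 1, coat_lightness = 1), 1.5)
  nz <- noise_model(dropout_base_rate = 0.02, dropout_blob_radius_px = 3,
                    seed = 23)
  noisy <- apply_noise(fr, attr(fr, "truth")$mask, nz, coat_lightness = 1)
  sm <- segment_frame(noisy, params)
  # interior dropout blobs (radius 3 < closing size 10) leave no holes:
  # every interior truth pixel is foreground in the final mask
  truth <- crop_truth(fr, params$crop)
  # brute-force erosion of the truth mask by 4 px: interior pixels
  interior <- truth
  nr <- nrow(truth); nc <- ncol(truth)
  for (di in -4:4) for (dj in -4:4) {
    sh <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 - di):min(nr, nr - di)
    cs <- max(1, 1 - dj):min(nc, nc - dj)
    sh[rs, cs] <- truth[rs + di, cs + dj]
    interior <- interior & sh
  }
  expect_true(all(sm$mask[interior]))
})

test_that("a floor-only frame yields the empty-result flag", {
  cam <- test_camera()
  lane <- lane_model()
  params <- seg_params(cam, crop = lane_crop(cam, lane))
  sm <- segment_frame(render_frame(cam, lane, list(), 0), params)
  expect_true(sm$empty)
  expect_equal(sum(sm$mask), 0)
})

test_that("segmentation is deterministic and stages are retrievable", {
  cam <- test_camera()
  fr <- render_frame(cam, lane_model(), cow_model(speed = 1), 1.5)
  params <- seg_params(cam, crop = lane_crop(cam, lane_model()))
  a <- segment_frame(fr, params)
  b <- segment_frame(fr, params)
  expect_identical(a$mask, b$mask)
  expect_named(a$stages, c("cropped", "hsv", "binary", "largest"))
  # largest-contour retention never grows the threshold foreground
  expect_lte(a$stages$largest$area, sum(a$stages$binary))
})
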