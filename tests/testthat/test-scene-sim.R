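test_that("an empty lane renders floor depth everywhere except the rails", {
  cam <- camera_model()
  lane <- lane_model()
  fr <- render_frame(cam, lane, list(), t = 0)
  expect_s3_class(fr, "depth_frame")
  rail_mm <- floor_depth_mm(cam) - 1000 * lane$rail_height
  expect_setequal(unique(as.vector(fr$depth)), c(2750L, rail_mm))
  # away from the rails every pixel is the floor
  crop <- lane_crop(cam, lane)
  expect_true(all(fr$depth[crop[1]:crop[2], ] == 2750L))
  expect_equal(attr(fr, "truth")$n_cows_visible, 0L)
})

test_that("a centered cow peaks at floor minus its body height", {
  cam <- camera_model()
  lane <- lane_model()
  cow <- cow_model(body_height = 1.45, speed = 1.0, entry_time = 0)
  t_mid <- (lane$exit_x - lane$entrance_x) / 2  # center under the camera
  fr <- render_frame(cam, lane, cow, t = t_mid)
  truth <- attr(fr, "truth")
  expect_equal(min(fr$depth[truth$mask]), 2750L - 1450L)
  # brute-force check of the half-ellipsoid profile over the bounding box:
  # every in-mask depth must equal floor - 1000 * h(x, y) from geometry
  plane_mm <- floor_depth_mm(cam) - 1000 * (2 / 3) * cow$body_height
  xs <- lanecam:::world_x_of_cols(cam, lane, plane_mm)
  ys <- lanecam:::world_y_of_rows(cam, lane, plane_mm)
  idx <- which(truth$mask, arr.ind = TRUE)
  set.seed(1)
  sel <- idx[sample.int(nrow(idx), 500), , drop = FALSE]
  u <- (xs[sel[, 2]] - t_mid) / (cow$body_length / 2)
  v <- ys[sel[, 1]] / (cow$body_width / 2)
  h <- cow$body_height * sqrt(pmax(0, 1 - u^2 - v^2))
  expect_equal(fr$depth[sel], as.integer(round(2750 - 1000 * h)))
})

test_that("a cow that has not yet entered leaves the frame untouched", {
  cam <- test_camera()
  lane <- lane_model()
  cow <- cow_model(entry_time = 2.0, speed = 1.0)
  expect_identical(render_frame(cam, lane, cow, t = 0)$depth,
                   render_frame(cam, lane, list(), t = 0)$depth)
})

test_that("noiseless rendering is a pure function", {
  cam <- test_camera()
  lane <- lane_model()
  cow <- cow_model(speed = 1.3)
  a <- render_frame(cam, lane, cow, t = 1.1)
  b <- render_frame(cam, lane, cow, t = 1.1)
  expect_identical(a$depth, b$depth)
  expect_identical(attr(a, "truth")$mask, attr(b, "truth")$mask)
})

test_that("increasing body height strictly decreases the minimum depth", {
  cam <- test_camera()
  lane <- lane_model()
  t_mid <- (lane$exit_x - lane$entrance_x) / 2
  mins <- vapply(seq(1.2, 1.7, by = 0.1), function(h) {
    fr <- render_frame(cam, lane, cow_model(body_height = h, speed = 1), t_mid)
    min(fr$depth[attr(fr, "truth")$mask])
  }, 0L)
  expect_true(all(diff(mins) < 0))
})

test_that("a body at floor level spans length / (m-per-px at floor) pixels", {
  cam <- camera_model()
  lane <- lane_model()
  for (len in c(1.2, 1.6, 2.0)) {
    flat <- cow_model(body_length = len, body_height = 0.002, speed = 1)
    bb <- attr(render_frame(cam, lane, flat,
                            (lane$exit_x - lane$entrance_x) / 2), "truth")$bbox
    got <- bb[["col_max"]] - bb[["col_min"]] + 1
    want <- len / meters_per_pixel(cam, floor_depth_mm(cam), "x")
    expect_lt(abs(got - want), 1.5)
  }
})

test_that("a cow wider than the lane is a configuration error", {
  expect_error(
    render_frame(test_camera(), lane_model(lane_width = 0.6),
                 cow_model(body_width = 0.65, speed = 1), t = 1),
    "does not fit the lane"
  )
})

test_that("overlapping cows render as the nearest surface", {
  cam <- test_camera()
  lane <- lane_model()
  tall <- cow_model(body_height = 1.6, speed = 1, entry_time = 0)
  short <- cow_model(body_height = 1.2, speed = 1, entry_time = 0)
  t_mid <- 1.5
  fr_both <- render_frame(cam, lane, list(tall, short), t_mid)
  fr_tall <- render_frame(cam, lane, tall, t_mid)
  expect_identical(fr_both$depth, pmin(fr_tall$depth,
    render_frame(cam, lane, short, t_mid)$depth))
  expect_equal(attr(fr_both, "truth")$n_cows_visible, 2L)
})

test_that("a pass spans roughly lane-length / speed worth of frames", {
  cam <- test_camera()
  lane <- lane_model()  # 3 m lane
  cow <- cow_model(speed = 1.5)
  st <- simulate_pass(cam, lane, cow)
  n_in <- sum(vapply(st, function(f) any(attr(f, "truth")$mask), TRUE))
  expect_lt(abs(n_in - 3 / 1.5 * cam$fps), 2)
})

test_that("stationary or reversed cows are rejected", {
  cow <- cow_model(speed = 1)
  cow$speed <- 0
  expect_error(simulate_stream(test_camera(), lane_model(), list(cow)),
               "speed must be positive")
})

test_that("simulation is deterministic and noiseless streams equal renders", {
  cam <- test_camera()
  lane <- lane_model()
  cow <- cow_model(speed = 1.4, coat_lightness = 0.8)
  nz <- noise_model(gaussian_sigma = 6, dropout_base_rate = 0.3, seed = 11)
  a <- simulate_pass(cam, lane, cow, noise = nz)
  b <- simulate_pass(cam, lane, cow, noise = nz)
  expect_identical(lapply(a, `[[`, "depth"), lapply(b, `[[`, "depth"))
  # zero noise reproduces the pure render exactly
  quiet <- simulate_pass(cam, lane, cow,
                         noise = noise_model(gaussian_sigma = 0,
                                             dropout_base_rate = 0))
  pure <- simulate_pass(cam, lane, cow)
  expect_identical(lapply(quiet, `[[`, "depth"), lapply(pure, `[[`, "depth"))
})

test_that("dropout hits the configured fraction of the mask and spares the floor", {
  cam <- test_camera()
  lane <- lane_model()
  cow <- cow_model(speed = 1, coat_lightness = 1)
  fr <- render_frame(cam, lane, cow, t = 1.5)
  mask <- attr(fr, "truth")$mask
  blob_area <- sum(outer((-3):3, (-3):3,
                         function(a, b) a^2 + b^2 <= 9))
  for (rate in c(0.2, 0.5, 1.0)) {
    fracs <- vapply(1:100, function(s) {
      nz <- noise_model(dropout_base_rate = rate, dropout_blob_radius_px = 3,
                        seed = s)
      out <- apply_noise(fr, mask, nz, coat_lightness = 1)
      mean(is.na(out$depth[mask]))
    }, 0)
    # coverage targeted to within one blob of the configured fraction
    expect_true(all(abs(fracs - rate) <= blob_area / sum(mask) + 1e-9))
    if (rate == 1) expect_true(all(fracs == 1))
  }
  nz <- noise_model(dropout_base_rate = 1, seed = 1)
  out <- apply_noise(fr, mask, nz, coat_lightness = 1)
  expect_true(all(!is.na(out$depth[!mask])))  # floor never dropped
})

test_that("zero dropout leaves only Gaussian jitter", {
  cam <- test_camera()
  lane <- lane_model()
  fr <- render_frame(cam, lane, cow_model(speed = 1), t = 1.5)
  nz <- noise_model(gaussian_sigma = 4, dropout_base_rate = 0, seed = 5)
  out <- apply_noise(fr, attr(fr, "truth")$mask, nz)
  expect_true(all(!is.na(out$depth)))
  expect_lt(max(abs(out$depth - fr$depth)), 6 * 4)
})

test_that("the infrared cut lens halves the expected dropout", {
  cam <- test_camera()
  lane <- lane_model()
  fr <- render_frame(cam, lane, cow_model(speed = 1, coat_lightness = 1),
                     t = 1.5)
  mask <- attr(fr, "truth")$mask
  counts <- vapply(1:100, function(s) {
    off <- apply_noise(fr, mask, noise_model(dropout_base_rate = 0.4,
                                             seed = s), 1)
    on <- apply_noise(fr, mask, noise_model(dropout_base_rate = 0.4,
                                            ir_cut_lens = TRUE,
                                            ir_cut_factor = 0.5,
                                            seed = s), 1)
    c(off = sum(is.na(off$depth)), on = sum(is.na(on$depth)))
  }, c(off = 0, on = 0))
  ratio <- mean(counts["on", ]) / mean(counts["off", ])
  expect_lt(abs(ratio - 0.5), 0.05)
  # paired coupling: the lens-on dropout set is a subset of lens-off
  off1 <- apply_noise(fr, mask, noise_model(dropout_base_rate = 0.4,
                                            seed = 3), 1)
  on1 <- apply_noise(fr, mask, noise_model(dropout_base_rate = 0.4,
                                           ir_cut_lens = TRUE, seed = 3), 1)
  expect_true(all(which(is.na(on1$depth)) %in% which(is.na(off1$depth))))
})
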