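# Small scene fixtures and independent brute-force oracles used across the
# suite.  The oracles deliberately use naive algorithms (BFS labeling,
# offset-loop morphology, closed-form geometry) so they share no code with
# the implementations they check.

test_camera <- function(width_px = 160L, height_px = 90L, fps = 30) {
  camera_model(width_px = width_px, height_px = height_px, fps = fps)
}

test_lane <- function() lane_model()

# crop ground-truth mask to a seg crop rectangle
crop_truth <- function(frame, crop) {
  attr(frame, "truth")$mask[crop[1]:crop[2], crop[3]:crop[4], drop = FALSE]
}

# --- oracle: 8-connected component labeling by breadth-first search -------
oracle_label8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        qi <- p[1] + di; qj <- p[2] + dj
        if (qi < 1 || qi > nr || qj < 1 || qj > nc) next
        if (m[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- cur
          queue[[length(queue) + 1L]] <- c(qi, qj)
        }
      }
    }
  }
  lab
}

# --- oracle: closing = dilate then erode with a k x k square --------------
# computed on a padded domain by explicit offset loops; closing is
# independent of the structuring-element origin, so any fixed origin works
oracle_close <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(FALSE, nr + 2 * k, nc + 2 * k)
  p[k + seq_len(nr), k + seq_len(nc)] <- m
  dil <- matrix(FALSE, nrow(p), ncol(p))
  for (di in 0:(k - 1)) for (dj in 0:(k - 1)) {
    sh <- matrix(FALSE, nrow(p), ncol(p))
    rows <- seq_len(nrow(p) - di); cols <- seq_len(ncol(p) - dj)
    sh[rows + di, cols + dj] <- p[rows, cols]
    dil <- dil | sh
  }
  ero <- matrix(TRUE, nrow(p), ncol(p))
  for (di in 0:(k - 1)) for (dj in 0:(k - 1)) {
    sh <- matrix(FALSE, nrow(p), ncol(p))
    rows <- seq_len(nrow(p) - di); cols <- seq_len(ncol(p) - dj)
    sh[rows, cols] <- dil[rows + di, cols + dj]
    ero <- ero & sh
  }
  ero[k + seq_len(nr), k + seq_len(nc)]
}

# --- oracle: closed-form POI depth of a half-ellipsoid body ---------------
# depth the renderer should produce at the POI column while a cow passes,
# from geometry alone (no pixel grid)
oracle_poi_depth <- function(camera, lane, cow, t, poi_world_x) {
  floor_mm <- floor_depth_mm(camera)
  if (t < cow$entry_time) return(floor_mm)
  x_c <- lane$entrance_x + cow$speed * (t - cow$entry_time)
  if (x_c < lane$entrance_x || x_c > lane$exit_x) return(floor_mm)
  u <- (lane$entrance_x + poi_world_x - x_c) / (cow$body_length / 2)
  if (abs(u) >= 1) return(floor_mm)
  floor_mm - round(1000 * cow$body_height * sqrt(1 - u^2))
}

# a stream of bare floor-depth frames with a cow-shaped depth dip painted
# at one pixel: handy for exercising the trigger in isolation
poi_trace_stream <- function(depths, poi_px = c(2L, 2L), floor_mm = 2750L,
                             fps = 30) {
  lapply(seq_along(depths), function(i) {
    d <- matrix(floor_mm, 4L, 4L)
    d[poi_px[1], poi_px[2]] <- depths[i]
    depth_frame(d, timestamp = (i - 1) / fps, frame_index = i - 1L)
  })
}

# minimal stub objects for grading-cascade tests
seg_stub <- function(mask, component_areas = sum(mask),
                     invalid_frac = 0, empty = !any(mask)) {
  structure(list(mask = mask, contour = matrix(integer(0), 0, 2),
                 empty = empty, area = sum(mask),
                 n_components = length(component_areas),
                 component_areas = component_areas,
                 invalid_frac = invalid_frac, crop = NULL, params = NULL,
                 stages = NULL),
            class = "seg_mask")
}

metrics_stub <- function(determinable = TRUE) {
  structure(list(height = 1.4, length = 1.6, width = 0.6,
                 apex_pixel = c(1L, 1L), scale_depth_mm = 1800,
                 determinable = c(height = determinable,
                                  length = determinable,
                                  width = determinable)),
            class = "body_metrics")
}
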