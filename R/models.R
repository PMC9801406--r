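#' Overhead depth camera model
#'
#' Describes a downward-facing RGB-D sensor mounted above a walk-through
#' lane.  The defaults match a sensor with an 87 degree horizontal and
#' 58 degree vertical field of view, mounted 2.75 m above the ground and
#' streaming 1280 x 720 depth frames at 30 frames per second.  The image
#' x-axis (the 1280-pixel dimension) is the travel axis of the lane, so the
#' head-to-tail extent of an animal falls along image columns.
#'
#' @param height_above_ground Camera height above the lane floor, meters.
#' @param h_fov,v_fov Horizontal and vertical field of view, degrees.
#' @param width_px,height_px Frame resolution in pixels.
#' @param fps Frame rate, frames per second.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model()
#' meters_per_pixel(cam, 2750) # footprint of one pixel at floor level
#' @export
camera_model <- function(height_above_ground = 2.75, h_fov = 87, v_fov = 58,
                         width_px = 1280L, height_px = 720L, fps = 30) {
  stopifnot(
    height_above_ground > 0,
    h_fov > 0, h_fov < 180, v_fov > 0, v_fov < 180,
    width_px >= 1, height_px >= 1, fps > 0
  )
  structure(
    list(
      height_above_ground = height_above_ground,
      h_fov = h_fov, v_fov = v_fov,
      width_px = as.integer(width_px), height_px = as.integer(height_px),
      fps = fps
    ),
    class = "camera_model"
  )
}

#' Walk-through lane model
#'
#' The lane is a straight corridor along the world x-axis; the camera sits
#' above its midpoint.  The world origin is the lane entrance projected onto
#' the floor, and the lane centerline is `y = 0`.  Fence rails run along the
#' lane edges at a fixed height above the floor; their centerlines are given
#' as lateral offsets from the centerline.
#'
#' @param entrance_x,exit_x Lane entrance and exit positions along the travel
#'   axis, meters (`entrance_x` is 0 by convention).
#' @param lane_width Usable lane width, meters.  Walk-through lanes for single
#'   cows are typically 0.9-1.2 m wide.
#' @param rail_left_y,rail_right_y Rail centerlines, meters from the lane
#'   centerline (default: the lane edges).
#' @param rail_height Rail height above the floor, meters.
#' @param rail_width Rendered rail thickness, meters.
#' @return An object of class `lane_model`.
#' @export
lane_model <- function(entrance_x = 0, exit_x = 3, lane_width = 1.0,
                       rail_left_y = -lane_width / 2,
                       rail_right_y = lane_width / 2,
                       rail_height = 1.2, rail_width = 0.05) {
  stopifnot(
    exit_x > entrance_x, lane_width > 0,
    rail_height > 0, rail_width > 0,
    rail_left_y < rail_right_y
  )
  structure(
    list(
      entrance_x = entrance_x, exit_x = exit_x, lane_width = lane_width,
      rail_left_y = rail_left_y, rail_right_y = rail_right_y,
      rail_height = rail_height, rail_width = rail_width
    ),
    class = "lane_model"
  )
}

#' Camera-to-floor distance in millimeters
#'
#' @param camera A [camera_model()].
#' @return Floor depth in integer millimeters.
#' @export
floor_depth_mm <- function(camera) {
  as.integer(round(1000 * camera$height_above_ground))
}

#' Synthetic cow body model
#'
#' The body is modeled as a half-ellipsoid standing on the floor (legs are
#' abstracted away; the ground-truth mask is the body footprint).  The animal
#' walks along the lane centerline at constant speed, its nose crossing the
#' entrance at `entry_time`.  `coat_lightness` drives the probability of
#' depth dropout under the sensor noise model: light (overexposed) coats lose
#' more depth readings than dark ones.
#'
#' @param body_length Head-to-tail length, meters.
#' @param body_width Lateral width, meters; must be smaller than the lane.
#' @param body_height Topline height above the floor, meters.
#' @param speed Walking speed, meters/second; cows walk between a slow walk
#'   and a mild trot, roughly 0.8-2.0 m/s.
#' @param coat_lightness Fraction in `[0, 1]` scaling the dropout rate.
#' @param entry_time Time at which the body center crosses the entrance,
#'   seconds.
#' @return An object of class `cow_model`.
#' @export
cow_model <- function(body_length = 1.6, body_width = 0.65,
                      body_height = 1.45, speed = 1.2,
                      coat_lightness = 0.5, entry_time = 0) {
  stopifnot(
    body_length > 0, body_width > 0, body_height > 0,
    speed > 0,
    coat_lightness >= 0, coat_lightness <= 1
  )
  structure(
    list(
      body_length = body_length, body_width = body_width,
      body_height = body_height, speed = speed,
      coat_lightness = coat_lightness, entry_time = entry_time
    ),
    class = "cow_model"
  )
}

#' Depth-sensor noise model
#'
#' Two noise processes are emulated: per-pixel Gaussian jitter on valid depth
#' readings, and dropout blobs (patches with no reading) planted inside the
#' animal mask.  Dropout emulates overexposure on light coat regions: the
#' expected fraction of in-mask pixels lost is
#' `dropout_base_rate * coat_lightness`, scaled by `ir_cut_factor` when an
#' infrared cut lens is fitted (the lens blocks ambient infrared and so
#' reduces overexposure).
#'
#' @param gaussian_sigma Jitter standard deviation, millimeters.
#' @param dropout_base_rate Base fraction of in-mask pixels lost to dropout.
#' @param dropout_blob_radius_px Radius of each circular dropout patch,
#'   pixels.
#' @param ir_cut_lens Logical; is an infrared cut lens fitted?
#' @param ir_cut_factor Multiplier (< 1) applied to the dropout rate when the
#'   lens is fitted.
#' @param seed Integer seed; all stochastic operations derive per-frame
#'   sub-seeds from it deterministically.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sigma = 0, dropout_base_rate = 0,
                        dropout_blob_radius_px = 4L, ir_cut_lens = FALSE,
                        ir_cut_factor = 0.5, seed = 1L) {
  stopifnot(
    gaussian_sigma >= 0,
    dropout_base_rate >= 0, dropout_base_rate <= 1,
    dropout_blob_radius_px >= 1,
    ir_cut_factor > 0, ir_cut_factor < 1
  )
  structure(
    list(
      gaussian_sigma = gaussian_sigma,
      dropout_base_rate = dropout_base_rate,
      dropout_blob_radius_px = as.integer(dropout_blob_radius_px),
      ir_cut_lens = isTRUE(ir_cut_lens),
      ir_cut_factor = ir_cut_factor,
      seed = as.integer(seed)
    ),
    class = "noise_model"
  )
}

#' Construct a depth frame
#'
#' A depth frame is a `height_px x width_px` integer matrix of
#' camera-to-surface distances in millimeters, with `NA` marking pixels
#' without a valid reading (sensor dropout).  On disk the sentinel is 0, but
#' in memory it is always an explicit `NA` so that no computation can
#' mistake "no reading" for a zero distance.
#'
#' @param depth Integer matrix of depths in millimeters (`NA` = no reading).
#' @param timestamp Frame timestamp, seconds from the stream start.
#' @param frame_index Zero-based frame counter within the stream.
#' @return An object of class `depth_frame`.
#' @export
depth_frame <- function(depth, timestamp = 0, frame_index = 0L) {
  stopifnot(is.matrix(depth))
  storage.mode(depth) <- "integer"
  if (any(depth <= 0L, na.rm = TRUE))
    stop("valid depths must be positive millimeters; use NA for no reading")
  structure(
    list(depth = depth, timestamp = timestamp,
         frame_index = as.integer(frame_index)),
    class = "depth_frame"
  )
}

#' @export
print.depth_frame <- function(x, ...) {
  d <- x$depth
  cat(sprintf(
    "<depth_frame> %d x %d px, t = %.3f s, index %d, %.1f%% valid, range [%s, %s] mm\n",
    nrow(d), ncol(d), x$timestamp, x$frame_index,
    100 * mean(!is.na(d)),
    if (all(is.na(d))) "-" else min(d, na.rm = TRUE),
    if (all(is.na(d))) "-" else max(d, na.rm = TRUE)
  ))
  invisible(x)
}

# focal lengths in pixels for the pinhole model
focal_px <- function(camera) {
  c(
    fx = camera$width_px / 2 / tan(camera$h_fov * pi / 360),
    fy = camera$height_px / 2 / tan(camera$v_fov * pi / 360)
  )
}

#' Metric footprint of one pixel at a given depth
#'
#' Under the pinhole model a plane at distance `d` from the camera is imaged
#' at `2 * d * tan(fov/2) / axis_px` meters per pixel; the footprint grows
#' linearly (hence strictly monotonically) with distance.
#'
#' @param camera A [camera_model()].
#' @param depth_mm Plane distance from the camera, millimeters.
#' @param axis `"x"` (travel axis, image columns) or `"y"` (lateral axis,
#'   image rows).
#' @return Meters per pixel at that plane.
#' @export
meters_per_pixel <- function(camera, depth_mm, axis = c("x", "y")) {
  axis <- match.arg(axis)
  f <- focal_px(camera)
  (depth_mm / 1000) / unname(if (axis == "x") f["fx"] else f["fy"])
}

# world x (meters) of pixel-column centers at a plane `depth_mm` from the
# camera; the camera is above the lane midpoint
world_x_of_cols <- function(camera, lane, depth_mm,
                            cols = seq_len(camera$width_px)) {
  cam_x <- (lane$entrance_x + lane$exit_x) / 2
  mpp <- meters_per_pixel(camera, depth_mm, "x")
  cam_x + (cols - (camera$width_px + 1) / 2) * mpp
}

# world y (meters, 0 = lane centerline) of pixel-row centers at a plane
world_y_of_rows <- function(camera, lane, depth_mm,
                            rows = seq_len(camera$height_px)) {
  mpp <- meters_per_pixel(camera, depth_mm, "y")
  (rows - (camera$height_px + 1) / 2) * mpp
}

# nearest pixel column imaging world x at a plane `depth_mm`
col_of_world_x <- function(camera, lane, x, depth_mm) {
  cam_x <- (lane$entrance_x + lane$exit_x) / 2
  mpp <- meters_per_pixel(camera, depth_mm, "x")
  as.integer(round((x - cam_x) / mpp + (camera$width_px + 1) / 2))
}

# run the RNG at a derived sub-seed without disturbing the caller's RNG state
with_sub_seed <- function(seed, index, code) {
  sub <- (as.double(seed) * 48271 + 7919 * (as.double(index) + 1)) %%
    2147483647
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(sub))
  code
}
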