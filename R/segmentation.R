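#' Segmentation parameters
#'
#' Parameters for the depth-image segmentation chain: crop to the
#' walk-through area, colorize depth to a hue/saturation/value image,
#' threshold on hue, keep the largest contour, morphologically close.  The
#' hue band is normally derived from a physically meaningful *height band*
#' (objects between `height_band[1]` and `height_band[2]` meters above the
#' floor) through the documented colorization ramp; it can also be supplied
#' directly.
#'
#' @param camera A [camera_model()] (fixes the floor distance the ramp and
#'   height band refer to).
#' @param crop Crop rectangle `c(row_min, row_max, col_min, col_max)`
#'   (1-based, inclusive), or `NULL` for the full frame.  The crop is the
#'   primary rail exclusion: choose it to cut away the fence rails while
#'   leaving the walk-through area intact.
#' @param height_band Heights above the floor (meters) considered
#'   foreground when `hue_band` is not given.
#' @param depth_range Near/far depth limits of the colorization ramp,
#'   millimeters (defaults to 400 mm through the floor distance).
#' @param hue_band Hue interval (degrees) kept by the threshold; derived
#'   from `height_band` when `NULL`.
#' @param closing_size Side of the square structuring element used for
#'   morphological closing, pixels.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(camera = camera_model(), crop = NULL,
                       height_band = c(0.35, 2.0), depth_range = NULL,
                       hue_band = NULL, closing_size = 10L) {
  floor_mm <- floor_depth_mm(camera)
  if (is.null(depth_range)) depth_range <- c(400, floor_mm)
  stopifnot(length(depth_range) == 2, depth_range[1] < depth_range[2],
            closing_size >= 1)
  if (!is.null(crop)) {
    stopifnot(length(crop) == 4, crop[1] <= crop[2], crop[3] <= crop[4],
              crop[1] >= 1, crop[3] >= 1)
  }
  if (is.null(hue_band)) {
    stopifnot(length(height_band) == 2, height_band[1] < height_band[2])
    d_hi <- floor_mm - 1000 * height_band[1]  # lowest object of interest
    d_lo <- floor_mm - 1000 * height_band[2]  # tallest object of interest
    hue_band <- c(hue_of_depth(d_lo, depth_range),
                  hue_of_depth(d_hi, depth_range))
  }
  stopifnot(length(hue_band) == 2, hue_band[1] <= hue_band[2])
  structure(
    list(camera = camera, crop = crop, depth_range = depth_range,
         hue_band = hue_band, height_band = height_band,
         closing_size = as.integer(closing_size)),
    class = "seg_params"
  )
}

#' Crop a depth frame to the walk-through area
#'
#' @param frame A [depth_frame()].
#' @param rect `c(row_min, row_max, col_min, col_max)`, 1-based inclusive,
#'   or `NULL` for no crop.
#' @return A [depth_frame()] of the sub-grid; the rectangle is recorded in
#'   attribute `"crop"` so cropped pixel coordinates can be mapped back via
#'   [back_map_pixels()].
#' @export
crop_lane <- function(frame, rect) {
  if (is.null(rect)) rect <- c(1L, nrow(frame$depth), 1L, ncol(frame$depth))
  rect <- as.integer(rect)
  d <- frame$depth
  if (rect[1] < 1 || rect[3] < 1 || rect[2] > nrow(d) || rect[4] > ncol(d) ||
      rect[1] > rect[2] || rect[3] > rect[4])
    stop("crop rectangle ", paste(rect, collapse = ":"),
         " is empty or outside the frame")
  out <- depth_frame(d[rect[1]:rect[2], rect[3]:rect[4], drop = FALSE],
                     timestamp = frame$timestamp,
                     frame_index = frame$frame_index)
  attr(out, "crop") <- rect
  out
}

#' Map cropped pixel coordinates back to the full frame
#'
#' @param px Two-column matrix of `(row, col)` pixels in cropped
#'   coordinates.
#' @param cropped A frame returned by [crop_lane()] (or its `"crop"`
#'   attribute).
#' @return Matrix of `(row, col)` pixels in original frame coordinates.
#' @export
back_map_pixels <- function(px, cropped) {
  rect <- if (is.numeric(cropped)) cropped else attr(cropped, "crop")
  stopifnot(!is.null(rect))
  px <- rbind(px)
  cbind(px[, 1] + rect[1] - 1L, px[, 2] + rect[3] - 1L)
}

#' Hue of a depth value under the colorization ramp
#'
#' The ramp maps depth linearly onto hue: `near` maps to 0 degrees and
#' `far` to 240 degrees, at full saturation and value; depths outside the
#' range are clamped.  The mapping is strictly monotone on `[near, far]`,
#' hence invertible there (see [depth_of_hue()]).
#'
#' @param d Depth(s), millimeters.
#' @param range `c(near, far)` millimeters.
#' @return Hue in degrees.
#' @export
hue_of_depth <- function(d, range) {
  240 * (pmin(pmax(d, range[1]), range[2]) - range[1]) /
    (range[2] - range[1])
}

#' Invert the colorization ramp
#'
#' @param h Hue(s), degrees.
#' @inheritParams hue_of_depth
#' @return Depth in millimeters.
#' @export
depth_of_hue <- function(h, range) {
  range[1] + h / 240 * (range[2] - range[1])
}

#' Colorize a depth frame into a hue/saturation/value image
#'
#' Valid depths map onto the documented hue ramp over `range` at full
#' saturation and value; sentinel (no-reading) pixels get value 0.
#'
#' @param frame A [depth_frame()].
#' @param range `c(near, far)` depth limits of the ramp, millimeters.
#' @return An object of class `hsv_image`: matrices `h` (degrees), `s`,
#'   `v`, plus the `range` used.
#' @export
colorize_depth <- function(frame, range) {
  stopifnot(range[1] < range[2])
  d <- frame$depth
  valid <- !is.na(d)
  h <- matrix(0, nrow(d), ncol(d))
  h[valid] <- hue_of_depth(d[valid], range)
  v <- matrix(0, nrow(d), ncol(d))
  v[valid] <- 1
  s <- v
  structure(list(h = h, s = s, v = v, range = range), class = "hsv_image")
}

#' Threshold an HSV image on hue
#'
#' A pixel is foreground iff its hue lies within `band` and it has a valid
#' reading (value > 0).
#'
#' @param hsv An `hsv_image` from [colorize_depth()].
#' @param band `c(low, high)` hue bounds, degrees.
#' @return Logical foreground matrix.
#' @export
threshold_hue <- function(hsv, band) {
  stopifnot(inherits(hsv, "hsv_image"), length(band) == 2)
  hsv$h >= band[1] & hsv$h <= band[2] & hsv$v > 0
}

#' Keep the largest connected foreground component
#'
#' Components are 8-connected; ties in area are broken toward the component
#' whose first pixel comes earliest in column-major scan order.  The
#' retained component's boundary is traced clockwise.
#'
#' @param binary Logical foreground matrix.
#' @return List with `mask` (logical matrix of the retained component),
#'   `contour` (ordered n x 2 matrix of boundary `(row, col)` pixels),
#'   `area`, `n_components`, `component_areas`, and `empty` (`TRUE` when
#'   the input had no foreground).
#' @export
largest_contour <- function(binary) {
  stopifnot(is.logical(binary), is.matrix(binary))
  lab <- .cc_label8(binary)
  k <- max(lab)
  if (k == 0L)
    return(list(mask = binary & FALSE, contour = matrix(integer(0), 0, 2),
                area = 0L, n_components = 0L,
                component_areas = integer(0), empty = TRUE))
  areas <- tabulate(lab[lab > 0L], nbins = k)
  best <- which.max(areas)  # first maximum = earliest in scan order
  mask <- lab == best
  list(mask = mask, contour = .trace_boundary(mask),
       area = areas[best], n_components = k, component_areas = areas,
       empty = FALSE)
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by the paired erosion with a `size x size` square
#' structuring element, computed on a background-padded domain so the
#' operation is exact at the borders.  Closing is extensive (output
#' contains the input) and fills interior holes smaller than the element.
#'
#' @param mask Logical matrix.
#' @param size Side of the square structuring element, pixels.
#' @return Logical matrix containing `mask`.
#' @export
close_mask <- function(mask, size = 10L) {
  stopifnot(is.logical(mask), is.matrix(mask), size >= 1)
  out <- .binary_close(mask, as.integer(size))
  dimnames(out) <- NULL
  out
}

#' Segment an animal from a depth frame
#'
#' Runs the full chain crop -> colorize -> hue threshold -> largest
#' contour -> morphological closing and returns the final mask with all
#' per-stage intermediates retrievable for debugging.  Because the
#' colorization ramp is monotone in depth, thresholding on hue band
#' `[hue(a), hue(b)]` is equivalent to thresholding depth directly on
#' `[a, b]` for valid pixels.
#'
#' @param frame A [depth_frame()].
#' @param params A [seg_params()].
#' @return An object of class `seg_mask`: `mask` (logical, in cropped
#'   coordinates), `contour`, `empty` flag, `area`, `n_components` and
#'   `component_areas` of the pre-retention threshold image,
#'   `invalid_frac` (fraction of in-mask pixels without a depth reading),
#'   `crop` rectangle, `params`, and `stages` (cropped frame, HSV image,
#'   threshold image, retained component).
#' @export
segment_frame <- function(frame, params) {
  stopifnot(inherits(params, "seg_params"))
  cropped <- crop_lane(frame, params$crop)
  hsv <- colorize_depth(cropped, params$depth_range)
  binary <- threshold_hue(hsv, params$hue_band)
  lc <- largest_contour(binary)
  if (lc$empty) {
    mask <- lc$mask
    contour <- lc$contour
  } else {
    closed <- close_mask(lc$mask, params$closing_size)
    # closing is extensive but need not preserve connectedness in exotic
    # cases; re-keep the largest component so the mask contract holds
    final <- largest_contour(closed)
    mask <- final$mask
    contour <- final$contour
  }
  invalid_frac <- if (any(mask)) mean(is.na(cropped$depth[mask])) else NA_real_
  structure(
    list(mask = mask, contour = contour, empty = lc$empty,
         area = sum(mask), n_components = lc$n_components,
         component_areas = lc$component_areas,
         invalid_frac = invalid_frac,
         crop = attr(cropped, "crop"), params = params,
         stages = list(cropped = cropped, hsv = hsv, binary = binary,
                       largest = lc)),
    class = "seg_mask"
  )
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf(
    "<seg_mask> %s, area %d px, %d threshold component(s), invalid frac %s\n",
    if (x$empty) "empty" else "non-empty", x$area, x$n_components,
    if (is.na(x$invalid_frac)) "-" else sprintf("%.3f", x$invalid_frac)
  ))
  invisible(x)
}
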