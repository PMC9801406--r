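#' Animal height from a depth frame and mask
#'
#' The topline height is the camera height minus the minimum valid in-mask
#' depth: `height = height_above_ground - min(depth[mask]) / 1000`.  The
#' apex pixel is the argmin (ties broken by column-major scan order).  The
#' result is flagged not determinable when the mask is empty or when fewer
#' than `min_valid_frac` of the mask pixels carry a valid reading.
#'
#' @param frame A [depth_frame()] (typically the cropped frame a mask was
#'   segmented from).
#' @param mask Logical matrix aligned with `frame`.
#' @param camera A [camera_model()].
#' @param min_valid_frac Minimum fraction of valid in-mask depths for the
#'   measurement to count as determinable.
#' @return List with `height` (meters or `NA`), `apex_pixel`
#'   (`(row, col)` or `NULL`) and `determinable`.
#' @export
cow_height <- function(frame, mask, camera, min_valid_frac = 0.5) {
  stopifnot(is.logical(mask), all(dim(mask) == dim(frame$depth)))
  d <- frame$depth
  in_mask <- d[mask]
  n_valid <- sum(!is.na(in_mask))
  if (!any(mask) || n_valid == 0 || n_valid / sum(mask) < min_valid_frac)
    return(list(height = NA_real_, apex_pixel = NULL, determinable = FALSE))
  dmin <- min(in_mask, na.rm = TRUE)
  idx <- which(mask & !is.na(d) & d == dmin)[1]
  apex <- c(row = (idx - 1L) %% nrow(d) + 1L,
            col = (idx - 1L) %/% nrow(d) + 1L)
  list(height = camera$height_above_ground - dmin / 1000,
       apex_pixel = apex, determinable = TRUE)
}

#' Animal length and width from a mask
#'
#' Pixel extents of the mask's axis-aligned bounding box converted to
#' meters with the pinhole scale at the animal's *mean back depth* (the
#' mean valid in-mask depth) — the animal's surface, not the floor, is the
#' measured plane.  Length runs along the travel axis (image columns),
#' width along the lateral axis (rows).  An extent is flagged not
#' determinable when the mask touches the crop boundary on that axis (the
#' animal is partly out of view), or when the mask is empty or has no
#' valid depths.
#'
#' @inheritParams cow_height
#' @return List with `length`, `width` (meters or `NA`),
#'   `length_determinable`, `width_determinable`, `scale_depth_mm` (the
#'   mean back depth used).
#' @export
cow_length_width <- function(mask, frame, camera) {
  stopifnot(is.logical(mask), all(dim(mask) == dim(frame$depth)))
  nd <- list(length = NA_real_, width = NA_real_,
             length_determinable = FALSE, width_determinable = FALSE,
             scale_depth_mm = NA_real_)
  if (!any(mask)) return(nd)
  d_in <- frame$depth[mask]
  if (all(is.na(d_in))) return(nd)
  d_mean <- mean(d_in, na.rm = TRUE)
  rc <- which(mask, arr.ind = TRUE)
  rows <- range(rc[, 1])
  cols <- range(rc[, 2])
  len_px <- cols[2] - cols[1] + 1L
  wid_px <- rows[2] - rows[1] + 1L
  len_ok <- cols[1] > 1L && cols[2] < ncol(mask)
  wid_ok <- rows[1] > 1L && rows[2] < nrow(mask)
  list(
    length = if (len_ok) len_px * meters_per_pixel(camera, d_mean, "x")
             else NA_real_,
    width = if (wid_ok) wid_px * meters_per_pixel(camera, d_mean, "y")
            else NA_real_,
    length_determinable = len_ok,
    width_determinable = wid_ok,
    scale_depth_mm = d_mean
  )
}

#' Measure height, width and length of an animal
#'
#' Composition of [cow_height()] and [cow_length_width()].  An image is
#' only usable downstream when all three dimensions are determinable; the
#' per-metric flags propagate into image grading.
#'
#' @inheritParams cow_height
#' @return An object of class `body_metrics` with fields `height`,
#'   `length`, `width` (meters), `apex_pixel`, `scale_depth_mm` and a
#'   logical `determinable` vector over the three metrics.
#' @export
measure_body <- function(frame, mask, camera, min_valid_frac = 0.5) {
  h <- cow_height(frame, mask, camera, min_valid_frac)
  lw <- cow_length_width(mask, frame, camera)
  structure(
    list(
      height = h$height, length = lw$length, width = lw$width,
      apex_pixel = h$apex_pixel, scale_depth_mm = lw$scale_depth_mm,
      determinable = c(height = h$determinable,
                       length = lw$length_determinable && h$determinable,
                       width = lw$width_determinable && h$determinable)
    ),
    class = "body_metrics"
  )
}

#' @export
print.body_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.3f m", v)
  cat(sprintf(
    "<body_metrics> height %s, length %s, width %s (determinable: %s)\n",
    fmt(x$height), fmt(x$length), fmt(x$width),
    paste(names(x$determinable)[x$determinable], collapse = ", ")
  ))
  invisible(x)
}
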