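#' Render one synthetic top-view depth frame
#'
#' Produces the depth image an overhead sensor would record at time `t`:
#' floor pixels read the camera-to-floor distance, rail pixels read
#' `floor - 1000 * rail_height`, and pixels over a cow body read
#' `floor - 1000 * local_body_height(x, y)` with a half-ellipsoid height
#' profile peaking at `body_height`.  The body silhouette is projected with
#' the pinhole model at the body's mean back plane (camera height minus two
#' thirds of the body height, the mean surface height of a half-ellipsoid
#' over its footprint), so that pixel extents and the mean in-mask depth are
#' mutually consistent; a body at floor level occupies
#' `length / meters_per_pixel(floor)` pixels along the travel axis.
#'
#' A cow is rendered while its body center lies between the lane entrance
#' and exit, clipped to the lane window; where two cows overlap, the nearest
#' surface wins (pixelwise minimum depth).
#'
#' @param camera A [camera_model()].
#' @param lane A [lane_model()].
#' @param cows List of [cow_model()] objects (possibly empty).
#' @param t Scene time, seconds.
#' @param timestamp,frame_index Metadata stored on the returned frame
#'   (`timestamp` defaults to `t`).
#' @return A [depth_frame()] carrying a `truth` attribute: a list with the
#'   ground-truth cow `mask` (logical matrix), its bounding `bbox`
#'   (`row_min, row_max, col_min, col_max`, or `NULL` when empty) and
#'   `n_cows_visible`.
#' @export
render_frame <- function(camera, lane, cows = list(), t = 0,
                         timestamp = t, frame_index = 0L) {
  stopifnot(t >= 0)
  if (inherits(cows, "cow_model")) cows <- list(cows)
  floor_mm <- floor_depth_mm(camera)
  nr <- camera$height_px
  nc <- camera$width_px
  depth <- matrix(floor_mm, nr, nc)

  # rails: horizontal bands (constant image rows) at the rail plane
  rail_mm <- as.integer(round(floor_mm - 1000 * lane$rail_height))
  if (rail_mm <= 0L) stop("rail_height places the rail above the camera")
  y_rail_plane <- world_y_of_rows(camera, lane, rail_mm)
  for (ry in c(lane$rail_left_y, lane$rail_right_y)) {
    rows <- which(abs(y_rail_plane - ry) <= lane$rail_width / 2)
    if (length(rows) == 0)
      stop("rail centerline at y = ", ry,
           " m falls outside the image footprint")
    depth[rows, ] <- pmin(depth[rows, ], rail_mm)
  }

  mask <- matrix(FALSE, nr, nc)
  n_visible <- 0L
  light_vis <- 0
  for (cow in cows) {
    if (cow$body_width >= lane$lane_width)
      stop("cow body_width (", cow$body_width,
           " m) does not fit the lane (", lane$lane_width, " m)")
    if (t < cow$entry_time) next
    x_c <- lane$entrance_x + cow$speed * (t - cow$entry_time)
    if (x_c < lane$entrance_x || x_c > lane$exit_x) next
    n_visible <- n_visible + 1L
    light_vis <- max(light_vis, cow$coat_lightness)
    plane_mm <- floor_mm - 1000 * (2 / 3) * cow$body_height
    xs <- world_x_of_cols(camera, lane, plane_mm)
    ys <- world_y_of_rows(camera, lane, plane_mm)
    u2 <- ((xs - x_c) / (cow$body_length / 2))^2
    v2 <- (ys / (cow$body_width / 2))^2
    in_lane <- xs >= lane$entrance_x & xs <= lane$exit_x
    r2 <- outer(v2, ifelse(in_lane, u2, Inf), `+`)
    inside <- r2 < 1
    if (!any(inside)) next
    h <- sqrt(pmax(0, 1 - r2[inside])) * cow$body_height
    d_cow <- as.integer(round(floor_mm - 1000 * h))
    d_cow <- pmax(d_cow, 1L)
    idx <- which(inside)
    nearer <- d_cow < depth[idx]
    depth[idx[nearer]] <- d_cow[nearer]
    # the truth mask is the full geometric footprint (a sub-millimeter rim
    # can round onto the floor depth yet still belongs to the body)
    mask[idx] <- TRUE
  }

  fr <- depth_frame(depth, timestamp = timestamp, frame_index = frame_index)
  bbox <- if (any(mask)) {
    rc <- which(mask, arr.ind = TRUE)
    c(row_min = min(rc[, 1]), row_max = max(rc[, 1]),
      col_min = min(rc[, 2]), col_max = max(rc[, 2]))
  } else NULL
  attr(fr, "truth") <- list(mask = mask, bbox = bbox,
                            n_cows_visible = n_visible,
                            coat_lightness = light_vis)
  fr
}

#' Simulate a depth stream of one or more lane passes
#'
#' Renders frames at the camera frame rate from `t_start` to `t_end`
#' (defaulting to a short lead-in before the first entry and lead-out after
#' the last exit), then applies the sensor noise model frame by frame.
#' Given equal seeds the output is bit-identical across calls.
#'
#' @inheritParams render_frame
#' @param noise A [noise_model()], or `NULL` for a noiseless stream.
#' @param t_start,t_end Stream time window, seconds.
#' @param pad Lead-in/out around the passes when `t_start`/`t_end` are not
#'   given, seconds.
#' @return A list of [depth_frame()] objects, each carrying its ground-truth
#'   `truth` attribute (computed before noise is applied).
#' @export
simulate_stream <- function(camera, lane, cows = list(), noise = NULL,
                            t_start = NULL, t_end = NULL, pad = 0.5) {
  if (inherits(cows, "cow_model")) cows <- list(cows)
  for (cow in cows) if (cow$speed <= 0)
    stop("cow speed must be positive; compose speed schedules in the caller")
  lane_len <- lane$exit_x - lane$entrance_x
  if (is.null(t_start)) {
    t_start <- if (length(cows))
      max(0, min(vapply(cows, `[[`, 0, "entry_time")) - pad) else 0
  }
  if (is.null(t_end)) {
    t_end <- if (length(cows))
      max(vapply(cows, function(cw) cw$entry_time + lane_len / cw$speed, 0)) +
        pad
    else t_start + pad
  }
  stopifnot(t_end >= t_start)
  times <- seq(t_start, t_end, by = 1 / camera$fps)
  frames <- vector("list", length(times))
  for (i in seq_along(times)) {
    fr <- render_frame(camera, lane, cows, times[i],
                       timestamp = times[i], frame_index = i - 1L)
    if (!is.null(noise)) {
      truth <- attr(fr, "truth")
      noisy <- apply_noise(fr, truth$mask, noise,
                           coat_lightness = truth$coat_lightness)
      attr(noisy, "truth") <- truth
      fr <- noisy
    }
    frames[[i]] <- fr
  }
  frames
}

#' Simulate a single cow pass
#'
#' Convenience wrapper around [simulate_stream()] for one animal traversing
#' the lane entrance to exit at its own speed.
#'
#' @inheritParams simulate_stream
#' @param cow A single [cow_model()].
#' @return A list of [depth_frame()] objects with ground-truth attributes.
#' @export
simulate_pass <- function(camera, lane, cow, noise = NULL, pad = 0.5) {
  stopifnot(inherits(cow, "cow_model"))
  simulate_stream(camera, lane, list(cow), noise = noise, pad = pad)
}

#' Apply sensor noise to a depth frame
#'
#' Adds integer-rounded Gaussian jitter to every valid depth reading, then
#' plants circular dropout blobs (readings replaced by the no-reading
#' sentinel) inside the animal mask until the lost fraction reaches
#' `dropout_base_rate * coat_lightness`, scaled by `ir_cut_factor` when the
#' infrared cut lens is fitted.  Blob seed pixels are drawn as one random
#' permutation of the mask, so for a fixed seed the dropout pattern at a
#' lower effective rate is a subset of the pattern at a higher rate.  Floor
#' pixels are never dropped.
#'
#' @param frame A [depth_frame()].
#' @param cow_mask Logical matrix aligned with the frame marking animal
#'   pixels (dropout is confined to it).
#' @param noise A [noise_model()].
#' @param coat_lightness Dropout multiplier in `[0, 1]` for the animal in
#'   the frame.
#' @return A new [depth_frame()] with jittered depths and `NA` dropout.
#' @export
apply_noise <- function(frame, cow_mask, noise, coat_lightness = 1) {
  stopifnot(inherits(frame, "depth_frame"), inherits(noise, "noise_model"))
  d <- frame$depth
  if (!is.null(cow_mask))
    stopifnot(is.logical(cow_mask), all(dim(cow_mask) == dim(d)))
  with_sub_seed(noise$seed, frame$frame_index, {
    valid <- which(!is.na(d))
    if (noise$gaussian_sigma > 0 && length(valid)) {
      d[valid] <- pmax(
        1L,
        as.integer(round(d[valid] +
          stats::rnorm(length(valid), 0, noise$gaussian_sigma)))
      )
    }
    rate <- noise$dropout_base_rate * min(max(coat_lightness, 0), 1)
    if (noise$ir_cut_lens) rate <- rate * noise$ir_cut_factor
    rate <- min(max(rate, 0), 1)
    if (rate > 0 && !is.null(cow_mask) && any(cow_mask)) {
      idx <- which(cow_mask)
      target <- round(rate * length(idx))
      if (target > 0) {
        seeds <- sample(idx)
        r <- noise$dropout_blob_radius_px
        off <- expand.grid(dr = -r:r, dc = -r:r)
        off <- off[off$dr^2 + off$dc^2 <= r^2, ]
        nr <- nrow(d)
        dropped <- 0L
        for (s in seeds) {
          if (dropped >= target) break
          sr <- (s - 1L) %% nr + 1L
          sc <- (s - 1L) %/% nr + 1L
          rr <- sr + off$dr
          cc <- sc + off$dc
          ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol(d)
          blob <- (cc[ok] - 1L) * nr + rr[ok]
          blob <- blob[cow_mask[blob] & !is.na(d[blob])]
          d[blob] <- NA_integer_
          dropped <- dropped + length(blob)
        }
      }
    }
  })
  out <- depth_frame(d, timestamp = frame$timestamp,
                     frame_index = frame$frame_index)
  attr(out, "truth") <- attr(frame, "truth")
  out
}
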