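#' Point-of-interest configuration
#'
#' A POI is a fixed pixel whose depth reading is monitored to detect an
#' animal entering and leaving the lane.  Starting from the camera-to-floor
#' distance at that pixel, a valid reading that drops by at least
#' `trigger_delta` (default 600 mm, i.e. an object at least 0.6 m tall over
#' the POI) fires the trigger; a valid reading back within
#' `release_tolerance` of the floor releases it.  Readings with no depth
#' (sensor dropout) never change the trigger state; a consecutive-missing
#' watchdog force-releases after `watchdog` seconds so a dead pixel cannot
#' deadlock the system.
#'
#' @param pixel Integer `(row, col)` of the monitored pixel.
#' @param floor_depth Camera-to-floor distance at the POI, millimeters; when
#'   `NULL` it is calibrated from the stream prefix with
#'   [estimate_floor_depth()].
#' @param trigger_delta Depth decrease that fires the trigger, millimeters.
#' @param release_tolerance Maximum deviation from the floor still counted
#'   as "returned to the floor", millimeters.
#' @param watchdog Consecutive-missing span that force-releases an active
#'   trigger, seconds.
#' @param world_x Optional lane position the pixel was derived from, meters
#'   (metadata only).
#' @return An object of class `poi_config`.
#' @export
poi_config <- function(pixel, floor_depth = NULL, trigger_delta = 600,
                       release_tolerance = 50, watchdog = 2,
                       world_x = NULL) {
  pixel <- as.integer(pixel)
  stopifnot(length(pixel) == 2, all(pixel >= 1),
            trigger_delta > 0, release_tolerance >= 0, watchdog > 0)
  if (!is.null(floor_depth))
    stopifnot(floor_depth > trigger_delta)
  structure(
    list(pixel = pixel, floor_depth = floor_depth,
         trigger_delta = trigger_delta,
         release_tolerance = release_tolerance,
         watchdog = watchdog, world_x = world_x),
    class = "poi_config"
  )
}

#' Place a POI pixel at a lane position
#'
#' Converts a distance from the lane entrance into the pixel that images
#' that floor position (center row, floor-plane projection).  Typical
#' placements are 1.52 m from the entrance for picture capture and roughly
#' 0.61 m for video capture, which gives the recorder time to start before
#' the animal is fully in view.
#'
#' @inheritParams render_frame
#' @param world_x Distance from the lane entrance, meters.
#' @param ... Passed on to [poi_config()].
#' @return A `poi_config` with `pixel` and `floor_depth` filled in.
#' @export
poi_at <- function(camera, lane, world_x = 1.52, ...) {
  floor_mm <- floor_depth_mm(camera)
  col <- col_of_world_x(camera, lane, lane$entrance_x + world_x, floor_mm)
  if (col < 1 || col > camera$width_px)
    stop("POI position ", world_x, " m maps outside the image")
  poi_config(pixel = c(as.integer(round((camera$height_px + 1) / 2)), col),
             floor_depth = floor_mm, world_x = world_x, ...)
}

#' Depth reading at the POI
#'
#' @param frame A [depth_frame()].
#' @param poi A [poi_config()].
#' @return Depth in millimeters, or `NA` when the pixel has no valid
#'   reading (never 0).
#' @export
poi_depth <- function(frame, poi) {
  d <- frame$depth
  px <- poi$pixel
  if (px[1] > nrow(d) || px[2] > ncol(d))
    stop("POI pixel (", px[1], ", ", px[2], ") outside the frame")
  d[px[1], px[2]]
}

#' Calibrate the floor depth at the POI
#'
#' Median of the valid POI readings over a stream prefix; used as the
#' trigger baseline when the floor distance is not configured explicitly.
#'
#' @param frames List of [depth_frame()] objects (a stream prefix).
#' @param poi A [poi_config()].
#' @return Floor depth in millimeters.
#' @export
estimate_floor_depth <- function(frames, poi) {
  vals <- vapply(frames, poi_depth, integer(1), poi = poi)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0)
    stop("floor calibration error: no valid POI reading in the prefix")
  stats::median(vals)
}

#' One step of the trigger state machine
#'
#' The trigger is `ARMED` until a valid POI depth drops to
#' `floor_depth - trigger_delta` or below (onset: an object has entered the
#' frame), then `ACTIVE` until a valid depth returns to within
#' `release_tolerance` of the floor (release).  Missing readings leave the
#' state unchanged.
#'
#' @param state `"ARMED"` or `"ACTIVE"`.
#' @param depth POI depth in millimeters, or `NA` for no reading.
#' @param poi A [poi_config()] with `floor_depth` set.
#' @return List with elements `state`, `onset`, `release`.
#' @export
trigger_state_step <- function(state, depth, poi) {
  stopifnot(state %in% c("ARMED", "ACTIVE"), !is.null(poi$floor_depth))
  onset <- FALSE
  release <- FALSE
  if (!is.na(depth)) {
    if (state == "ARMED" && depth <= poi$floor_depth - poi$trigger_delta) {
      state <- "ACTIVE"
      onset <- TRUE
    } else if (state == "ACTIVE" &&
               depth >= poi$floor_depth - poi$release_tolerance) {
      state <- "ARMED"
      release <- TRUE
    }
  }
  list(state = state, onset = onset, release = release)
}

#' Picture-capture configuration
#'
#' A fixed number of pictures per trigger, spaced at a fixed interval.
#' The two standard settings are 3 pictures at 0.75 s and 10 pictures at
#' 0.15 s.
#'
#' @param n_pictures Pictures per capture event.
#' @param interval Spacing between scheduled pictures, seconds.
#' @param bytes_per_frame Storage estimate per persisted picture, bytes
#'   (used for reporting when frames are not actually written to disk).
#' @return An object of class `picture_mode_config`.
#' @export
picture_mode_config <- function(n_pictures = 3L, interval = 0.75,
                                bytes_per_frame = 670000) {
  stopifnot(n_pictures >= 1, interval > 0, bytes_per_frame >= 0)
  structure(list(n_pictures = as.integer(n_pictures), interval = interval,
                 bytes_per_frame = bytes_per_frame),
            class = "picture_mode_config")
}

#' Video-capture configuration
#'
#' Records every stream frame from trigger onset to release, optionally
#' capped at `max_duration` seconds (a 5 s cap bounds recordings of
#' stationary animals).
#'
#' @param fps Recording frame rate (normally the stream rate), frames/second.
#' @param max_duration Maximum recording length, seconds (`Inf` = no cap).
#' @param bytes_per_frame Storage estimate per recorded frame, bytes.
#' @return An object of class `video_mode_config`.
#' @export
video_mode_config <- function(fps = 30, max_duration = Inf,
                              bytes_per_frame = 670000) {
  stopifnot(fps > 0, max_duration > 0, bytes_per_frame >= 0)
  structure(list(fps = fps, max_duration = max_duration,
                 bytes_per_frame = bytes_per_frame),
            class = "video_mode_config")
}

new_capture_event <- function(event_id, trigger_timestamp, mode,
                              frame_indices, timestamps, frames,
                              bytes_per_frame, truncated) {
  structure(
    list(event_id = event_id, trigger_timestamp = trigger_timestamp,
         mode = mode, frame_indices = frame_indices,
         timestamps = timestamps, frames = frames,
         n_frames = length(frame_indices),
         stored_bytes = length(frame_indices) * bytes_per_frame,
         truncated = truncated),
    class = "capture_event"
  )
}

#' @export
print.capture_event <- function(x, ...) {
  cat(sprintf(
    "<capture_event #%d> %s mode, onset t = %.3f s, %d frame(s)%s, %.2f MB\n",
    x$event_id, x$mode, x$trigger_timestamp, x$n_frames,
    if (x$truncated) " [truncated]" else "", x$stored_bytes / 1e6
  ))
  invisible(x)
}

# shared driver over a stream: calls mode-specific hooks at onset/per-frame/
# release and enforces one event per onset-release cycle plus the
# consecutive-missing watchdog
resolve_floor <- function(stream, poi, calib_frames = 30L) {
  if (!is.null(poi$floor_depth)) return(poi)
  n <- min(length(stream), calib_frames)
  poi$floor_depth <- estimate_floor_depth(stream[seq_len(n)], poi)
  poi
}

#' Run the picture-based capture mode over a stream
#'
#' Monitors the POI frame by frame.  At trigger onset the onset frame is
#' captured and the remaining `n_pictures - 1` pictures are scheduled at the
#' configured interval, each taken as the stream frame nearest its scheduled
#' time (ties broken toward the earlier frame).  After the set is captured
#' no further pictures are taken until the animal leaves the POI (release)
#' and a new onset occurs, so there is exactly one event per onset-release
#' cycle.  If the stream ends mid-capture the event keeps the frames
#' obtained so far and is flagged truncated.
#'
#' @param stream List of [depth_frame()] objects ordered by timestamp.
#' @param poi A [poi_config()].
#' @param cfg A [picture_mode_config()].
#' @param keep_frames Keep the captured [depth_frame()] objects in each
#'   event (set `FALSE` to retain only indices/timestamps for large runs).
#' @return List of `capture_event` objects.
#' @export
run_picture_mode <- function(stream, poi, cfg = picture_mode_config(),
                             keep_frames = TRUE) {
  stopifnot(inherits(cfg, "picture_mode_config"))
  poi <- resolve_floor(stream, poi)
  times <- vapply(stream, `[[`, 0, "timestamp")
  stopifnot(!is.unsorted(times))
  events <- list()
  state <- "ARMED"
  pending <- NULL  # scheduled capture times not yet taken
  taken <- integer(0)
  onset_t <- NA_real_
  miss_since <- NA_real_

  close_event <- function(truncated) {
    idx <- taken
    events[[length(events) + 1L]] <<- new_capture_event(
      event_id = length(events) + 1L, trigger_timestamp = onset_t,
      mode = "picture", frame_indices = idx, timestamps = times[idx],
      frames = if (keep_frames) stream[idx] else NULL,
      bytes_per_frame = cfg$bytes_per_frame, truncated = truncated
    )
    pending <<- NULL
    taken <<- integer(0)
  }

  for (i in seq_along(stream)) {
    d <- poi_depth(stream[[i]], poi)
    if (state == "ACTIVE") {
      if (is.na(d)) {
        if (is.na(miss_since)) miss_since <- times[i]
        if (times[i] - miss_since >= poi$watchdog) {
          state <- "ARMED"  # watchdog force-release
          if (!is.null(pending)) close_event(truncated = TRUE)
          miss_since <- NA_real_
          next
        }
      } else miss_since <- NA_real_
    }
    st <- trigger_state_step(state, d, poi)
    state <- st$state
    if (st$onset) {
      # a new animal while the previous schedule is still open closes the
      # previous event with the pictures obtained so far
      if (!is.null(pending)) close_event(truncated = TRUE)
      onset_t <- times[i]
      pending <- onset_t + cfg$interval * (seq_len(cfg$n_pictures) - 1)
      miss_since <- NA_real_
    }
    # take every pending picture whose nearest stream frame is this one:
    # frame i is nearest to a scheduled time s iff |t_i - s| is minimal,
    # ties toward the earlier frame, i.e. once t_i + half-period passes s
    while (!is.null(pending) && length(pending) > length(taken)) {
      s <- pending[length(taken) + 1L]
      if (i < length(stream)) {
        # is frame i at least as close to s as the next frame?
        if (abs(times[i] - s) <= abs(times[i + 1L] - s)) taken <- c(taken, i)
        else break
      } else if (times[i] >= s) {
        taken <- c(taken, i)  # last frame, schedule already due
      } else break  # schedule beyond stream end: leave pending (truncated)
    }
    if (!is.null(pending) && length(taken) == length(pending))
      close_event(truncated = FALSE)
    if (st$release) miss_since <- NA_real_
  }
  if (!is.null(pending)) close_event(truncated = TRUE)
  events
}

#' Run the video-based capture mode over a stream
#'
#' Records every frame from trigger onset until release — a valid POI depth
#' back at the floor distance (within the release tolerance) — or until the
#' optional maximum duration, whichever comes first.  One event is emitted
#' per onset-release cycle; frames within an event are contiguous at the
#' stream frame rate.  A stream ending while the trigger is active closes
#' the event flagged truncated.
#'
#' @inheritParams run_picture_mode
#' @param cfg A [video_mode_config()].
#' @return List of `capture_event` objects.
#' @export
run_video_mode <- function(stream, poi, cfg = video_mode_config(),
                           keep_frames = TRUE) {
  stopifnot(inherits(cfg, "video_mode_config"))
  poi <- resolve_floor(stream, poi)
  times <- vapply(stream, `[[`, 0, "timestamp")
  stopifnot(!is.unsorted(times))
  events <- list()
  state <- "ARMED"
  rec <- integer(0)
  onset_t <- NA_real_
  miss_since <- NA_real_

  close_event <- function(truncated) {
    events[[length(events) + 1L]] <<- new_capture_event(
      event_id = length(events) + 1L, trigger_timestamp = onset_t,
      mode = "video", frame_indices = rec, timestamps = times[rec],
      frames = if (keep_frames) stream[rec] else NULL,
      bytes_per_frame = cfg$bytes_per_frame, truncated = truncated
    )
    rec <<- integer(0)
  }

  # duration cap in whole frames: a 5 s cap at 30 fps is exactly 150 frames
  n_cap <- if (is.finite(cfg$max_duration))
    floor(cfg$max_duration * cfg$fps + 0.5) else Inf

  for (i in seq_along(stream)) {
    d <- poi_depth(stream[[i]], poi)
    if (state == "ACTIVE") {
      if (is.na(d)) {
        if (is.na(miss_since)) miss_since <- times[i]
        if (times[i] - miss_since >= poi$watchdog) {
          state <- "ARMED"
          close_event(truncated = TRUE)
          miss_since <- NA_real_
          next
        }
      } else miss_since <- NA_real_
    }
    st <- trigger_state_step(state, d, poi)
    if (st$onset) {
      onset_t <- times[i]
      miss_since <- NA_real_
    }
    state <- st$state
    # record every frame while active (onset frame included, release frame
    # excluded: at release the POI reads the floor again)
    if (state == "ACTIVE" && length(rec) < n_cap) rec <- c(rec, i)
    if (st$release) close_event(truncated = FALSE)
  }
  if (state == "ACTIVE" && length(rec)) close_event(truncated = TRUE)
  events
}
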