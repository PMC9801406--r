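#' Image grade categories
#'
#' Every post-segmentation image falls into exactly one of six categories:
#' successful, unsuccessful due to quality, unsuccessful due to the animal
#' not being fully in the field of vision, unsuccessful due to rail
#' separation, unsuccessful due to quality and rail separation, and
#' unsuccessful due to multiple animals in the same image.
#'
#' @format Character vector of the six category labels.
#' @export
GRADE_LEVELS <- c("SUCCESS", "QUALITY", "OUT_OF_VIEW", "RAIL",
                  "QUALITY_AND_RAIL", "MULTIPLE_COWS")

#' Grading thresholds
#'
#' @param component_area_floor Minimum area (pixels) for a threshold-image
#'   component to count as a separate animal in the multiple-animal check.
#' @param rail_rows Rows of the cropped image treated as rail bands (where
#'   residual rail pixels may contaminate the mask), or `NULL` for none.
#' @param rail_overlap_floor Minimum mask pixels inside the rail bands for
#'   a rail-separation failure.
#' @param quality_floor Maximum tolerated fraction of in-mask pixels with
#'   no depth reading before the image fails on quality.
#' @param min_mask_area Minimum retained-mask area (pixels) for the
#'   dimensions to count as measurable; heavy dropout fragments the
#'   threshold image, leaving a clean-looking but partial component whose
#'   extents are far from the animal's.  `0` disables the check.
#' @return An object of class `grade_config`.
#' @export
grade_config <- function(component_area_floor = 500L, rail_rows = NULL,
                         rail_overlap_floor = 200L, quality_floor = 0.25,
                         min_mask_area = 0L) {
  stopifnot(component_area_floor >= 1, rail_overlap_floor >= 1,
            quality_floor >= 0, quality_floor <= 1, min_mask_area >= 0)
  structure(
    list(component_area_floor = as.integer(component_area_floor),
         rail_rows = rail_rows,
         rail_overlap_floor = as.integer(rail_overlap_floor),
         quality_floor = quality_floor,
         min_mask_area = as.integer(min_mask_area)),
    class = "grade_config"
  )
}

#' Grade one segmented image into the six categories
#'
#' Deterministic rule cascade, evaluated in order:
#' \enumerate{
#'   \item two or more threshold-image components above the area floor:
#'     `MULTIPLE_COWS` (the retained mask deliberately keeps one component,
#'     so this looks at the pre-retention component statistics);
#'   \item mask touches the crop boundary on the travel axis:
#'     `OUT_OF_VIEW`;
#'   \item mask overlaps the rail bands above the overlap floor *and* the
#'     in-mask invalid fraction exceeds the quality floor:
#'     `QUALITY_AND_RAIL`;
#'   \item rail overlap alone: `RAIL`;
#'   \item quality floor breached, any metric not determinable, the
#'     retained mask smaller than `min_mask_area`, or an empty mask:
#'     `QUALITY`;
#'   \item otherwise `SUCCESS`.
#' }
#'
#' @param seg A `seg_mask` from [segment_frame()].
#' @param metrics A `body_metrics` from [measure_body()].
#' @param cfg A [grade_config()].
#' @return One of [GRADE_LEVELS].
#' @export
grade_image <- function(seg, metrics, cfg = grade_config()) {
  stopifnot(inherits(seg, "seg_mask"), inherits(metrics, "body_metrics"))
  n_big <- sum(seg$component_areas >= cfg$component_area_floor)
  if (n_big >= 2) return("MULTIPLE_COWS")
  if (seg$empty) return("QUALITY")
  rc <- which(seg$mask, arr.ind = TRUE)
  cols <- range(rc[, 2])
  if (cols[1] <= 1L || cols[2] >= ncol(seg$mask)) return("OUT_OF_VIEW")
  rail_overlap <- if (is.null(cfg$rail_rows)) 0L else
    sum(seg$mask[cfg$rail_rows, , drop = FALSE])
  rail_bad <- rail_overlap >= cfg$rail_overlap_floor
  quality_bad <- (!is.na(seg$invalid_frac) &&
                    seg$invalid_frac > cfg$quality_floor) ||
    !all(metrics$determinable) ||
    seg$area < cfg$min_mask_area
  if (rail_bad && quality_bad) return("QUALITY_AND_RAIL")
  if (rail_bad) return("RAIL")
  if (quality_bad) return("QUALITY")
  "SUCCESS"
}

#' Per-animal success from its image grades
#'
#' The default, conjunctive rule declares a pass successful when at least
#' two images were captured *and* at least one image graded `SUCCESS`.
#' Alternative readings are available as documented switches:
#' `"two_captured"` (any two images captured), `"two_success"` (two
#' successful images), `"one_success"` (one successful image).
#'
#' @param grades Character vector of [GRADE_LEVELS] entries, one per image.
#' @param rule Success rule; see Details.
#' @return Logical flag.
#' @export
cow_success <- function(grades,
                        rule = c("two_and_one_success", "two_captured",
                                 "two_success", "one_success")) {
  rule <- match.arg(rule)
  stopifnot(all(grades %in% GRADE_LEVELS))
  n <- length(grades)
  ns <- sum(grades == "SUCCESS")
  switch(rule,
    two_and_one_success = n >= 2 && ns >= 1,
    two_captured = n >= 2,
    two_success = ns >= 2,
    one_success = ns >= 1
  )
}

# round half up (away from zero for positives), the convention used by the
# printed success-rate tables; base round() rounds half to even
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Per-group success rate in percent
#'
#' `100 * n_success / n_tested`, half-up rounded to two decimals.
#'
#' @param n_success,n_tested Counts, `0 <= n_success <= n_tested`.
#' @return Percentage, rounded to 2 decimals.
#' @examples
#' success_rate(165, 237) # 69.62
#' @export
success_rate <- function(n_success, n_tested) {
  if (any(n_tested <= 0)) stop("n_tested must be positive")
  stopifnot(all(n_success >= 0), all(n_success <= n_tested))
  round_half_up(100 * n_success / n_tested, 2)
}

#' Storage totals and per-animal average
#'
#' @param events List of `capture_event` objects, or a numeric vector of
#'   per-event stored bytes.
#' @return List with `total_mb` (sum of stored bytes / 1e6) and
#'   `avg_mb_per_cow`, the latter rendered at two decimals below 5 MB and
#'   one decimal at or above (matching the mixed precision storage
#'   figures are conventionally reported at).
#' @examples
#' storage_summary(rep(476.47e6 / 237, 237)) # avg 2.01 MB over 237 cows
#' @export
storage_summary <- function(events) {
  if (is.list(events))
    events <- vapply(events, `[[`, 0, "stored_bytes")
  if (length(events) == 0) stop("no capture events")
  total_mb <- sum(events) / 1e6
  avg <- total_mb / length(events)
  avg <- round_half_up(avg, if (avg >= 5) 1 else 2)
  list(total_mb = total_mb, avg_mb_per_cow = avg)
}

#' Summarize per-animal results by lens and method
#'
#' Rolls per-animal capture results up into one row per
#' `lens x method` group with the columns of a success-rate table — cows
#' tested, number successful/unsuccessful, percent successful — plus
#' per-image success counts and storage accounting.
#'
#' @param results Data frame with one row per animal pass and columns
#'   `lens` (`"with"`/`"without"`), `method` (`"picture3"`, `"picture10"`,
#'   `"video"`), `success` (logical), `images_total`, `images_success`
#'   (integer counts; optional), `stored_bytes` (optional).
#' @return Data frame with one row per group and columns `lens`, `method`,
#'   `cows_tested`, `n_success`, `n_fail`, `pct_success`, and when
#'   available `images_total`, `images_success`, `pct_images_success`,
#'   `total_mb`, `avg_mb_per_cow`.
#' @export
summarize_results <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("lens", "method", "success") %in% names(results)))
  bad <- setdiff(unique(results$method), c("picture3", "picture10", "video"))
  if (length(bad))
    stop("unknown method tag(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(results$lens), c("with", "without"))
  if (length(bad))
    stop("unknown lens tag(s): ", paste(bad, collapse = ", "))
  groups <- unique(results[c("lens", "method")])
  groups <- groups[order(match(groups$lens, c("without", "with")),
                         match(groups$method,
                               c("picture3", "picture10", "video"))), ]
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- results$lens == groups$lens[g] & results$method == groups$method[g]
    r <- results[sel, ]
    n <- nrow(r)
    ns <- sum(r$success)
    out <- data.frame(
      lens = groups$lens[g], method = groups$method[g],
      cows_tested = n, n_success = ns, n_fail = n - ns,
      pct_success = success_rate(ns, n)
    )
    if (all(c("images_total", "images_success") %in% names(r))) {
      it <- sum(r$images_total)
      is_ <- sum(r$images_success)
      out$images_total <- it
      out$images_success <- is_
      out$pct_images_success <- if (it > 0) success_rate(is_, it) else NA
    }
    if ("stored_bytes" %in% names(r)) {
      st <- storage_summary(r$stored_bytes)
      out$total_mb <- st$total_mb
      out$avg_mb_per_cow <- st$avg_mb_per_cow
    }
    out
  })
  do.call(rbind, rows)
}

#' Render a summary table as Markdown
#'
#' @param summary A data frame from [summarize_results()].
#' @return Character scalar containing a Markdown table.
#' @export
format_summary_markdown <- function(summary) {
  hdr <- names(summary)
  fmt_cell <- function(x) {
    if (is.numeric(x) && !is.integer(x)) format(x, nsmall = 0) else
      as.character(x)
  }
  lines <- c(
    paste0("| ", paste(hdr, collapse = " | "), " |"),
    paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"),
    vapply(seq_len(nrow(summary)), function(i) {
      paste0("| ", paste(vapply(summary[i, ], fmt_cell, ""),
                         collapse = " | "), " |")
    }, "")
  )
  paste(lines, collapse = "\n")
}
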