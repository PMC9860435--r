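#' Evaluate a trigger-evaluation image
#'
#' Runs one cycle of the motion-detection pipeline on a 320 x 240
#' trigger-evaluation image (TEI): Gaussian blur (5 x 5), crop to the
#' configured trigger ROI, foreground classification against the
#' background model at the configured greyscale sensitivity (the model is
#' updated in place), morphological closing to merge fragmented
#' detections, and trigger evaluation by either connected-component size
#' or total pixel count. The returned decision carries full diagnostics
#' (foreground count, component sizes, largest bounding box) so it can be
#' re-derived offline from the stored TEI.
#'
#' @param model an `octo_mog` model built over the blurred, cropped TEI
#'   geometry (see [mog_init()]).
#' @param tei a 320 x 240 `octo_frame`.
#' @param s an `octo_settings` configuration.
#' @return an `octo_trigger_decision` list: `triggered`, `method`,
#'   `fg_pixels`, `component_sizes`, `largest_bbox`, `mask`, `timestamp`.
#' @export
evaluate_tei <- function(model, tei, s) {
  assert_tei(tei)
  f <- gaussian_blur(tei, 5L)
  f <- crop_roi(f, s$motion$trigger_roi)
  mask <- mog_update_classify(model, f, s$motion$foreground_threshold)
  mask <- morph_close(mask, 3L)
  comps <- if (identical(s$motion$trigger_eval_method, "object_size")) {
    connected_components(mask)
  } else NULL
  d <- decide_trigger(mask, comps, s)
  d$timestamp <- frame_timestamp(tei)
  d$mask <- mask
  d
}

#' Trigger decision from a foreground mask
#'
#' Applies the configured evaluation rule to the post-closing foreground
#' mask. Under `pixel_total` the trigger fires when the number of
#' foreground pixels strictly exceeds `min_pixel_count`; under
#' `object_size` it fires when any connected component strictly exceeds
#' `min_object_size` pixels.
#'
#' @param mask the post-closing foreground `octo_mask`.
#' @param comps the `octo_components` of `mask` (required for
#'   `object_size`; may be `NULL` for `pixel_total`).
#' @param s an `octo_settings` configuration.
#' @return an `octo_trigger_decision`.
#' @export
decide_trigger <- function(mask, comps, s) {
  method <- s$motion$trigger_eval_method
  fg <- sum(unclass(mask))
  if (identical(method, "pixel_total")) {
    triggered <- fg > s$motion$min_pixel_count
    sizes <- integer()
    bbox <- NULL
  } else if (identical(method, "object_size")) {
    if (is.null(comps)) comps <- connected_components(mask)
    sizes <- comps$sizes
    triggered <- any(sizes > s$motion$min_object_size)
    bbox <- if (length(sizes)) {
      comps$bboxes[which.max(comps$bboxes$size), ]
    } else NULL
  } else {
    stop(sprintf("unknown trigger_eval_method '%s'", method))
  }
  structure(list(triggered = triggered, method = method, fg_pixels = fg,
                 component_sizes = sizes, largest_bbox = bbox,
                 timestamp = NA_real_, mask = NULL),
            class = "octo_trigger_decision")
}

#' @export
print.octo_trigger_decision <- function(x, ...) {
  cat(sprintf("<trigger %s: method=%s, fg=%d px%s>\n",
              if (x$triggered) "FIRED" else "idle", x$method, x$fg_pixels,
              if (length(x$component_sizes))
                sprintf(", components=%s",
                        paste(x$component_sizes, collapse = "/"))
              else ""))
  invisible(x)
}

#' Strobe schedule around an exposure envelope
#'
#' In `envelope` mode the strobe channel is switched on `pre_strobe_fire`
#' seconds before the exposure starts and off when the exposure ends,
#' capped at `strobe_duration` seconds of total on-time (LED strobes
#' overheat if left on longer). In `off` mode a null schedule is returned;
#' `camera` mode (camera-driven double flash) is hardware-specific and
#' returns a schedule with no timing.
#'
#' @param exposure_start exposure start time (s).
#' @param exposure_len exposure length (s, >= 0).
#' @param s an `octo_settings` configuration.
#' @param channel strobe channel; defaults to the configured
#'   intervalometer channel.
#' @return an `octo_strobe` list: `channel`, `mode`, `on`, `off`.
#' @export
strobe_schedule <- function(exposure_start, exposure_len, s,
                            channel = s$intervalometer$strobe_channel) {
  stopifnot(exposure_len >= 0)
  mode <- s$camera$strobe
  if (mode %in% c("off", "camera")) {
    return(structure(list(channel = channel, mode = mode,
                          on = NA_real_, off = NA_real_),
                     class = "octo_strobe"))
  }
  on <- exposure_start - s$camera$pre_strobe_fire
  off <- min(exposure_start + exposure_len, on + s$camera$strobe_duration)
  structure(list(channel = channel, mode = mode, on = on, off = off),
            class = "octo_strobe")
}

#' @export
print.octo_strobe <- function(x, ...) {
  if (is.na(x$on)) {
    cat(sprintf("<strobe %s: mode=%s (no envelope)>\n", x$channel, x$mode))
  } else {
    cat(sprintf("<strobe %s: on %.3fs off %.3fs (%.3fs)>\n",
                x$channel, x$on, x$off, x$off - x$on))
  }
  invisible(x)
}

#' Capture a full-resolution image
#'
#' Requests a frame from the camera source at the configured resolution
#' tier (L = 1024 x 768, M = 2048 x 1520, H = 4056 x 3040), applies
#' contrast-limited adaptive histogram equalization when `auto_contrast`
#' is enabled, and (when a deployment directory is given) encodes it under
#' `full/` per the configured image type and quality.
#'
#' @param camera a camera source: `function(tier, time)` returning an
#'   `octo_frame` (see [sim_hardware()]).
#' @param s an `octo_settings` configuration.
#' @param time simulated capture time (s since deployment start).
#' @param dir deployment directory; `NULL` skips encoding to disk.
#' @param seq capture sequence number (used in the file name).
#' @param start_time calendar time of deployment start (for ISO-stamped
#'   file names).
#' @param frame optional pre-acquired frame (skips the camera request).
#' @return a list: `frame`, `path` (`NULL` if not stored), `encoding`
#'   (list of `type`, `quality`).
#' @export
capture_full_res <- function(camera, s, time = 0, dir = NULL, seq = 1L,
                             start_time = as.POSIXct("2026-01-01", tz = "UTC"),
                             frame = NULL) {
  f <- frame %||% camera(tier = s$camera$image_resolution, time = time)
  if (isTRUE(s$camera$auto_contrast)) f <- clahe(f)
  type <- s$camera$image_type
  path <- NULL
  if (!is.null(dir)) {
    ext <- switch(type, jpeg = "jpg", png = "png", bmp = "bmp")
    stamp <- format(start_time + time, "%Y%m%dT%H%M%S")
    path <- file.path(dir, "full", sprintf("%s_%04d.%s", stamp, seq, ext))
    write_frame(f, path, type = type, quality = s$camera$image_quality)
  }
  list(frame = f, path = path,
       encoding = list(type = type, quality = s$camera$image_quality))
}
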