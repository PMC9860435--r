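#' @importFrom tibble tibble as_tibble
NULL

# Schema for the settings.cfg configuration. One row per parameter:
# internal group/key, INI section header, type, default, and constraints.
# Every default reproduces the engine's documented stock configuration.
settings_schema <- function() {
  e <- function(...) list(c(...))
  sch <- tibble::tribble(
    ~group, ~key, ~section, ~type, ~default, ~choices, ~lo, ~hi,
    "general", "collection_type", "general_settings", "enum", "trigger_using_red",
      e("still_intervalometer", "trigger_using_red", "trigger_using_ambient"), NA, NA,
    "general", "system_id", "general_settings", "string", "pi_triggercam_001", list(NULL), NA, NA,
    "general", "initial_wait", "general_settings", "integer", 1L, list(NULL), 0, Inf,
    "general", "low_voltage_cutoff", "general_settings", "double", 11, list(NULL), 0, Inf,
    "general", "shutdown_at_end", "general_settings", "boolean", FALSE, list(NULL), NA, NA,
    "general", "shutdown_wifi_on_collection", "general_settings", "boolean", TRUE, list(NULL), NA, NA,
    "intervalometer", "max_images", "intervalometer_settings", "integer", 10L, list(NULL), 1, Inf,
    "intervalometer", "image_interval", "intervalometer_settings", "double", 1, list(NULL), 1e-9, Inf,
    "intervalometer", "strobe_channel", "intervalometer_settings", "enum", "red",
      e("red", "white"), NA, NA,
    "motion", "motion_detect_interval", "motion_detection_settings", "double", 1, list(NULL), 1e-9, Inf,
    "motion", "post_detection_rest", "motion_detection_settings", "double", 5, list(NULL), 0, Inf,
    "motion", "max_runtime", "motion_detection_settings", "double", 60, list(NULL), 0, Inf,
    "motion", "foreground_threshold", "motion_detection_settings", "integer", 8L, list(NULL), 0, 255,
    "motion", "trigger_roi", "motion_detection_settings", "roi", c(20L, 20L, 280L, 200L), list(NULL), NA, NA,
    "motion", "frame_history", "motion_detection_settings", "integer", 25L, list(NULL), 20, 100,
    "motion", "trigger_eval_method", "motion_detection_settings", "enum", "object_size",
      e("object_size", "pixel_total"), NA, NA,
    "motion", "min_object_size", "motion_detection_settings", "integer", 500L, list(NULL), 0, Inf,
    "motion", "min_pixel_count", "motion_detection_settings", "integer", 10000L, list(NULL), 0, Inf,
    "camera", "image_resolution", "camera_configuration", "enum", "m", e("l", "m", "h"), NA, NA,
    "camera", "auto_contrast", "camera_configuration", "boolean", FALSE, list(NULL), NA, NA,
    "camera", "exposure", "camera_configuration", "integer", 0L, list(NULL), 0, Inf,
    "camera", "iso", "camera_configuration", "enum_int", 800L,
      e(100L, 200L, 400L, 800L, 1600L), NA, NA,
    "camera", "strobe", "camera_configuration", "enum", "envelope",
      e("off", "camera", "envelope"), NA, NA,
    "camera", "pre_strobe_fire", "camera_configuration", "double", 0.1, list(NULL), 0, 0.5,
    "camera", "strobe_duration", "camera_configuration", "double", 0.5, list(NULL), 0.5, 2,
    "camera", "image_depth", "camera_configuration", "enum", "monochrome",
      e("color", "monochrome"), NA, NA,
    "camera", "image_type", "camera_configuration", "enum", "jpeg",
      e("jpeg", "png", "bmp"), NA, NA,
    "camera", "image_quality", "camera_configuration", "integer", 95L, list(NULL), 0, 100
  )
  sch$choices <- lapply(sch$choices, function(x) x[[1]])  # unwrap cells
  sch
}

#' Stock engine configuration
#'
#' Returns the complete configuration the engine ships with: every
#' parameter of the four `settings.cfg` sections (general, intervalometer,
#' motion detection, camera) at its stock default. Among them: triggered
#' collection under the red strobe channel, a motion-evaluation interval
#' of 1 s, foreground threshold 8 grey levels, trigger ROI
#' `[20, 20, 280, 200]` on the 320 x 240 trigger-evaluation image, a
#' 25-frame background history, object-size trigger evaluation with a
#' 500 px minimum, medium (2048 x 1520) capture resolution and JPEG
#' quality 95.
#'
#' @return an `octo_settings` object: a named list of four parameter
#'   groups (`general`, `intervalometer`, `motion`, `camera`).
#' @examples
#' s <- default_settings()
#' s$motion$foreground_threshold
#' @export
default_settings <- function() {
  sch <- settings_schema()
  out <- list()
  for (g in unique(sch$group)) out[[g]] <- list()
  for (i in seq_len(nrow(sch))) {
    out[[sch$group[i]]][[sch$key[i]]] <- sch$default[[i]]
  }
  structure(out, class = "octo_settings")
}

#' Parse a settings.cfg configuration
#'
#' Parses INI-dialect text with the four configuration sections
#' (`[general_settings]`, `[intervalometer_settings]`,
#' `[motion_detection_settings]`, `[camera_configuration]`). Any key not
#' present takes its stock default; unknown keys are ignored with a
#' warning; enum values are matched case-insensitively and stored
#' lower-case; out-of-range values and invalid enum options raise a
#' validation error naming the key and its allowed values.
#'
#' The trigger ROI is written as a bracketed list
#' `trigger_roi = [left, bottom, width, height]` in trigger-evaluation
#' image pixels (bottom-left origin). If `image_type` is `png` and
#' `image_quality` is not given, the PNG compression default of 3 is used
#' instead of the JPEG default.
#'
#' @param text character: configuration file content (single string or a
#'   vector of lines).
#' @return an `octo_settings` object.
#' @seealso [read_settings()] to parse from a file, [write_settings()] for
#'   the inverse.
#' @export
parse_settings <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("[;#].*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  sch <- settings_schema()
  s <- default_settings()
  seen <- character()
  section <- NA_character_
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- tolower(gsub("^\\[|\\]$", "", ln))
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      warning(sprintf("ignoring malformed line: '%s'", ln))
      next
    }
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    # keys are unique across sections, so the header is advisory
    row <- which(sch$key == key)
    if (length(row) == 0L) {
      warning(sprintf("unknown settings key '%s' ignored", key))
      next
    }
    s[[sch$group[row]]][[key]] <- parse_value(val, sch[row, ])
    seen <- c(seen, key)
  }
  if (identical(s$camera$image_type, "png") && !"image_quality" %in% seen) {
    s$camera$image_quality <- 3L
  }
  validate_settings(s)
}

settings_error <- function(msg) {
  stop(structure(class = c("octo_validation_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

parse_value <- function(val, row) {
  key <- row$key
  switch(row$type,
    string = val,
    enum = {
      v <- tolower(val)
      if (!v %in% row$choices[[1]]) {
        settings_error(sprintf("invalid value '%s' for '%s'; allowed: %s",
                               val, key, paste(row$choices[[1]], collapse = ", ")))
      }
      v
    },
    enum_int = {
      v <- suppressWarnings(as.integer(val))
      if (is.na(v) || !v %in% row$choices[[1]]) {
        settings_error(sprintf("invalid value '%s' for '%s'; allowed: %s",
                               val, key, paste(row$choices[[1]], collapse = ", ")))
      }
      v
    },
    boolean = {
      v <- tolower(val)
      if (v %in% c("true", "on", "yes", "1")) TRUE
      else if (v %in% c("false", "off", "no", "0")) FALSE
      else settings_error(sprintf(
        "invalid value '%s' for '%s'; allowed: true/false or on/off", val, key))
    },
    integer = {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v) || v != round(v)) {
        settings_error(sprintf("'%s' must be an integer, got '%s'", key, val))
      }
      as.integer(v)
    },
    double = {
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) settings_error(sprintf("'%s' must be numeric, got '%s'", key, val))
      v
    },
    roi = {
      v <- suppressWarnings(as.integer(strsplit(gsub("[][]", "", val), ",")[[1]]))
      if (length(v) != 4L || anyNA(v)) {
        settings_error(sprintf(
          "'%s' must be four integers '[left, bottom, width, height]', got '%s'",
          key, val))
      }
      v
    }
  )
}

#' Validate a configuration
#'
#' Checks every range and enum constraint of the configuration schema:
#' enum fields hold a listed option, numeric fields sit in their stated
#' range, the trigger ROI fits inside the 320 x 240 trigger-evaluation
#' image, and `image_quality` is in 70-100 for JPEG output or 0-9 for PNG.
#' Violations raise an `octo_validation_error` naming the key.
#'
#' @param s an `octo_settings` object.
#' @return `s`, invisibly classed, when valid.
#' @export
validate_settings <- function(s) {
  sch <- settings_schema()
  for (i in seq_len(nrow(sch))) {
    key <- sch$key[i]
    v <- s[[sch$group[i]]][[key]]
    if (is.null(v)) settings_error(sprintf("missing settings key '%s'", key))
    if (sch$type[i] %in% c("enum", "enum_int") && !v %in% sch$choices[[i]]) {
      settings_error(sprintf("invalid value '%s' for '%s'; allowed: %s",
                             v, key, paste(sch$choices[[i]], collapse = ", ")))
    }
    if (sch$type[i] %in% c("integer", "double") &&
        (v < sch$lo[i] || v > sch$hi[i])) {
      settings_error(sprintf("'%s' = %s out of range [%s, %s]",
                             key, v, sch$lo[i], sch$hi[i]))
    }
  }
  roi <- s$motion$trigger_roi
  if (any(roi[1:2] < 0) || any(roi[3:4] < 1) ||
      roi[1] + roi[3] > 320 || roi[2] + roi[4] > 240) {
    settings_error(sprintf(
      "'trigger_roi' [%s] must fit inside the 320x240 TEI grid",
      paste(roi, collapse = ", ")))
  }
  q <- s$camera$image_quality
  if (identical(s$camera$image_type, "jpeg") && (q < 70 || q > 100)) {
    settings_error("'image_quality' must be 70-100 for JPEG output")
  }
  if (identical(s$camera$image_type, "png") && (q < 0 || q > 9)) {
    settings_error("'image_quality' must be 0-9 for PNG output")
  }
  structure(s, class = "octo_settings")
}

#' Serialize a configuration to settings.cfg text
#'
#' The inverse of [parse_settings()]: writes the four INI sections with
#' every parameter, the trigger ROI in its bracketed
#' `[left, bottom, width, height]` form. The round trip
#' `parse_settings(write_settings(s))` is the identity on valid
#' configurations.
#'
#' @param s an `octo_settings` object.
#' @param path optional file to write to.
#' @return the configuration text as a single string (invisibly when
#'   `path` is given).
#' @export
write_settings <- function(s, path = NULL) {
  s <- validate_settings(s)
  sch <- settings_schema()
  out <- character()
  for (sec in unique(sch$section)) {
    out <- c(out, sprintf("[%s]", sec))
    rows <- which(sch$section == sec)
    for (i in rows) {
      v <- s[[sch$group[i]]][[sch$key[i]]]
      txt <- switch(sch$type[i],
        roi = sprintf("[%s]", paste(v, collapse = ", ")),
        boolean = if (v) "true" else "false",
        double = fmt_double(v),
        as.character(v))
      out <- c(out, sprintf("%s = %s", sch$key[i], txt))
    }
    out <- c(out, "")
  }
  txt <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# shortest decimal representation that parses back to the same double
fmt_double <- function(v) {
  for (d in 1:17) {
    s <- formatC(v, digits = d, format = "g")
    if (as.numeric(s) == v) return(s)
  }
  sprintf("%.17g", v)
}

#' @rdname parse_settings
#' @param path path to a `settings.cfg` file.
#' @export
read_settings <- function(path) {
  parse_settings(readLines(path, warn = FALSE))
}

#' Deployment name from a calendar time
#'
#' Each power-up cycle is one deployment, named after its start time as
#' `DMMDDYYYY-Thhmmss` (zero-padded, 24-h clock).
#'
#' @param t a `POSIXct`/`POSIXlt` time.
#' @return the deployment name string.
#' @examples
#' deployment_name(as.POSIXct("2022-07-04 13:05:09", tz = "UTC"))
#' @export
deployment_name <- function(t) {
  format(t, "D%m%d%Y-T%H%M%S")
}

#' @export
print.octo_settings <- function(x, ...) {
  cat("<octo_settings>\n")
  cat(write_settings(x))
  cat("\n")
  invisible(x)
}

# tier letter -> capture dimensions (width, height)
resolution_dims <- function(tier) {
  switch(tolower(tier),
    l = c(1024L, 768L),
    m = c(2048L, 1520L),
    h = c(4056L, 3040L),
    tei = c(320L, 240L),
    stop(sprintf("unknown resolution tier '%s'", tier)))
}
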