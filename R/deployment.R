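#' Simulated hardware for bench deployments
#'
#' Bundles the hardware contracts the deployment engine needs — camera
#' source, voltage sensor, clock, strobe driver and storage — backed by
#' the scene simulator, so full deployments run deterministically against
#' a simulated clock (a 72-hour deployment replays in seconds; no real
#' sleeps).
#'
#' The camera yields the scene frame covering the requested time at any
#' resolution tier (`"tei"`, `"l"`, `"m"`, `"h"`), and `NULL` once the
#' scene is exhausted. The voltage sensor is either a linear discharge
#' (`voltage_start` minus `voltage_rate` volts per hour) or any
#' user-supplied `function(t)`. Storage tracks a finite byte budget.
#'
#' @param scene an `octo_scene`.
#' @param targets list of `octo_target`s.
#' @param voltage voltage model: a `function(t_seconds)` or a numeric
#'   start voltage used with `voltage_rate`.
#' @param voltage_rate discharge rate in volts/hour for the linear model.
#' @param free_bytes initial free storage in bytes.
#' @param start_time calendar time of power-up (drives the deployment
#'   name).
#' @param auto_exposure seconds of exposure the simulated camera reports
#'   when the configuration asks for auto exposure.
#' @return an `octo_hardware` list.
#' @export
sim_hardware <- function(scene, targets = list(), voltage = 12.6,
                         voltage_rate = 0.05, free_bytes = 64e9,
                         start_time = as.POSIXct("2026-03-14 09:00:00",
                                                 tz = "UTC"),
                         auto_exposure = 1 / 30) {
  volt_fn <- if (is.function(voltage)) voltage else {
    v0 <- voltage
    function(t) v0 - voltage_rate * t / 3600
  }
  storage <- new.env(parent = emptyenv())
  storage$free_bytes <- free_bytes
  strobe_log <- new.env(parent = emptyenv())
  strobe_log$schedules <- list()
  camera <- function(tier, time) {
    idx <- floor(time / scene$frame_interval) + 1L
    if (idx > scene$duration || idx < 1L) return(NULL)
    dims <- if (identical(tolower(tier), "tei")) NULL else
      resolution_dims(tier)
    render_frame(scene, targets, idx, dims = dims)
  }
  structure(list(
    camera = camera,
    voltage = volt_fn,
    clock = list(start = start_time),
    strobe = function(schedule) {
      strobe_log$schedules <- c(strobe_log$schedules, list(schedule))
      invisible(schedule)
    },
    strobe_log = strobe_log,
    storage = list(
      free = function() storage$free_bytes,
      consume = function(n) storage$free_bytes <- storage$free_bytes - n
    ),
    auto_exposure = function(time) auto_exposure,
    scene = scene
  ), class = "octo_hardware")
}

#' Hardware backed by a directory of frame images
#'
#' Wraps a directory of still images (sorted by file name, one frame per
#' motion-evaluation interval) in the same hardware contract as
#' [sim_hardware()], so recorded footage can be replayed through the
#' trigger engine. Frames are served at their stored size regardless of
#' the requested tier; the voltage model and storage budget follow
#' [sim_hardware()]'s linear-discharge defaults.
#'
#' @param path directory holding PNG/JPEG/BMP frames.
#' @param frame_interval seconds between successive files.
#' @inheritParams sim_hardware
#' @return an `octo_hardware` list.
#' @export
dir_hardware <- function(path, frame_interval = 1, voltage = 12.6,
                         voltage_rate = 0.05, free_bytes = 64e9,
                         start_time = as.POSIXct("2026-03-14 09:00:00",
                                                 tz = "UTC")) {
  files <- sort(list.files(path, full.names = TRUE,
                           pattern = "\\.(png|jpe?g|bmp)$", ignore.case = TRUE))
  if (!length(files)) stop(sprintf("no frame images found under '%s'", path))
  hw <- sim_hardware(scene_spec(duration = length(files),
                                frame_interval = frame_interval),
                     voltage = voltage, voltage_rate = voltage_rate,
                     free_bytes = free_bytes, start_time = start_time)
  hw$camera <- function(tier, time) {
    idx <- floor(time / frame_interval) + 1L
    if (idx > length(files) || idx < 1L) return(NULL)
    f <- read_frame(files[idx])
    attr(f, "timestamp") <- time
    f
  }
  hw
}

# worst-case encoded image size for the configured capture tier
worst_case_image_bytes <- function(s) {
  d <- resolution_dims(s$camera$image_resolution)
  prod(as.numeric(d)) + 2048
}

#' Exit-condition check
#'
#' Evaluates the deployment exit conditions in fixed priority order:
#' `low_voltage` (measured volts strictly below the cutoff), `disk_full`
#' (free space below one worst-case image), `max_runtime` (elapsed
#' acquisition time beyond the configured trigger-evaluation period, in
#' triggered mode), `max_images` (intervalometer mode), else `"none"`.
#'
#' @param rec a deployment record (or the engine's live state): needs
#'   `mode`, `images_captured`, `t` (current simulated time, s) and
#'   `acq_start` (acquisition start, s).
#' @param hw an `octo_hardware`.
#' @param s an `octo_settings` configuration.
#' @return one of `"low_voltage"`, `"disk_full"`, `"max_runtime"`,
#'   `"max_images"`, `"none"`.
#' @export
check_exit <- function(rec, hw, s) {
  if (hw$voltage(rec$t) < s$general$low_voltage_cutoff) return("low_voltage")
  if (hw$storage$free() < worst_case_image_bytes(s)) return("disk_full")
  if (identical(rec$mode, "triggered") &&
      rec$t - rec$acq_start > s$motion$max_runtime * 60) {
    return("max_runtime")
  }
  if (identical(rec$mode, "intervalometer") &&
      rec$images_captured >= s$intervalometer$max_images) {
    return("max_images")
  }
  "none"
}

#' Run a deployment
#'
#' The engine's power-up-to-shutdown state machine, driven entirely by the
#' simulated clock. On boot it creates the deployment folder set
#' (`<name>/settings.cfg`, `log.csv`, `full/`, `tei/`), snapshots the
#' configuration, logs a boot event and waits `initial_wait` minutes. It
#' then dispatches on the collection mode:
#'
#' * **intervalometer** — captures one full-resolution image every
#'   `image_interval` seconds until `max_images` (or another exit
#'   condition) is reached;
#' * **triggered** — builds the background model from a burn-in of
#'   `frame_history` TEIs, then evaluates one TEI every
#'   `motion_detect_interval` seconds; on a trigger it fires the strobe
#'   envelope, captures a full-resolution image, and rests
#'   `post_detection_rest` minutes before sensing again.
#'
#' Every evaluated TEI is stored under `tei/` with its decision logged, so
#' trigger performance can be re-derived after the deployment; the system
#' voltage is logged with every capture.
#'
#' @param hw an `octo_hardware` (see [sim_hardware()]).
#' @param s an `octo_settings` configuration.
#' @param out_dir writable directory in which the named deployment folder
#'   is created.
#' @param store_images write captures and TEIs to disk (set `FALSE` for
#'   fast bench scoring; the log is written either way).
#' @return an `octo_deployment` record: name, directory, settings
#'   snapshot, counters, trigger times, exit reason, the full event log
#'   (tibble) and the state trace.
#' @export
run_deployment <- function(hw, s, out_dir = tempfile("deploy"),
                           store_images = TRUE) {
  s <- validate_settings(s)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("output directory '%s' is not writable", out_dir))
  }
  name <- deployment_name(hw$clock$start)
  dir <- file.path(out_dir, name)
  ok <- dir.create(dir, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create deployment folder '%s'", dir))
  dir.create(file.path(dir, "full"), showWarnings = FALSE)
  dir.create(file.path(dir, "tei"), showWarnings = FALSE)
  write_settings(s, file.path(dir, "settings.cfg"))

  mode <- if (identical(s$general$collection_type, "still_intervalometer"))
    "intervalometer" else "triggered"
  st <- new.env(parent = emptyenv())
  st$t <- 0
  st$mode <- mode
  st$images_captured <- 0L
  st$teis_evaluated <- 0L
  st$last_trigger <- NA_real_
  st$triggers <- numeric()
  st$acq_start <- NA_real_
  st$log <- list()

  log_event <- function(event, voltage = NA_real_, image = NA_character_,
                        diagnostics = NA_character_) {
    st$log[[length(st$log) + 1L]] <- tibble::tibble(
      time_s = st$t,
      timestamp = format(hw$clock$start + st$t, "%Y-%m-%dT%H:%M:%S"),
      event = event, voltage = voltage,
      free_bytes = hw$storage$free(),
      image = image, diagnostics = diagnostics)
    invisible(NULL)
  }
  log_event("boot", voltage = hw$voltage(0),
            diagnostics = sprintf("mode=%s;system_id=%s;wifi_off=%s",
                                  mode, s$general$system_id,
                                  tolower(s$general$shutdown_wifi_on_collection)))

  st$t <- s$general$initial_wait * 60        # initial wait, simulated
  st$acq_start <- st$t
  exit_reason <- "none"

  capture <- function(frame = NULL) {
    seqno <- st$images_captured + 1L
    cap <- capture_full_res(hw$camera, s, time = st$t,
                            dir = if (store_images) dir else NULL,
                            seq = seqno, start_time = hw$clock$start,
                            frame = frame)
    if (!is.null(cap$path)) hw$storage$consume(file.size(cap$path))
    st$images_captured <- seqno
    log_event("capture", voltage = hw$voltage(st$t),
              image = if (is.null(cap$path)) NA_character_ else
                basename(cap$path))
    cap
  }

  if (mode == "intervalometer") {
    repeat {
      exit_reason <- check_exit(st, hw, s)
      if (exit_reason != "none") break
      f <- hw$camera(tier = s$camera$image_resolution, time = st$t)
      if (is.null(f)) { exit_reason <- "end_of_input"; break }
      if (!identical(s$camera$strobe, "off")) {
        hw$strobe(strobe_schedule(st$t, exposure_seconds(hw, s, st$t), s))
      }
      capture(frame = f)
      st$t <- st$t + s$intervalometer$image_interval
    }
  } else {
    # burn-in: seed the background model from frame_history TEIs
    burn <- list()
    while (length(burn) < s$motion$frame_history) {
      tei <- hw$camera(tier = "tei", time = st$t)
      if (is.null(tei)) { exit_reason <- "end_of_input"; break }
      store_tei(tei, dir, st, hw, store_images)
      log_event("trigger_eval", diagnostics = "burn_in")
      burn[[length(burn) + 1L]] <-
        crop_roi(gaussian_blur(tei, 5L), s$motion$trigger_roi)
      st$t <- st$t + s$motion$motion_detect_interval
    }
    if (exit_reason == "none") {
      model <- mog_init(burn, frame_history = s$motion$frame_history)
      repeat {
        exit_reason <- check_exit(st, hw, s)
        if (exit_reason != "none") break
        tei <- hw$camera(tier = "tei", time = st$t)
        if (is.null(tei)) { exit_reason <- "end_of_input"; break }
        d <- evaluate_tei(model, tei, s)
        st$teis_evaluated <- st$teis_evaluated + 1L
        store_tei(tei, dir, st, hw, store_images)
        log_event("trigger_eval",
                  diagnostics = sprintf("triggered=%s;fg=%d;n_comp=%d",
                                        tolower(d$triggered), d$fg_pixels,
                                        length(d$component_sizes)))
        if (d$triggered) {
          if (!identical(s$camera$strobe, "off")) {
            hw$strobe(strobe_schedule(st$t, exposure_seconds(hw, s, st$t), s))
          }
          capture()
          st$last_trigger <- st$t
          st$triggers <- c(st$triggers, st$t)
          log_event("rest_start",
                    diagnostics = sprintf("rest_minutes=%g",
                                          s$motion$post_detection_rest))
          st$t <- st$t + s$motion$post_detection_rest * 60
        } else {
          st$t <- st$t + s$motion$motion_detect_interval
        }
      }
    }
  }

  log_event("shutdown", voltage = hw$voltage(st$t),
            diagnostics = sprintf("exit=%s;shutdown_at_end=%s", exit_reason,
                                  tolower(s$general$shutdown_at_end)))
  log <- do.call(rbind, st$log)
  utils::write.csv(log, file.path(dir, "log.csv"), row.names = FALSE)

  structure(list(
    name = name, dir = dir, settings = s, start_time = hw$clock$start,
    mode = mode, images_captured = st$images_captured,
    teis_evaluated = st$teis_evaluated,
    last_trigger_time = st$last_trigger, triggers = st$triggers,
    state = "shutdown", exit_reason = exit_reason,
    duration = st$t, log = log,
    state_trace = state_trace_from_log(log),
    shutdown = isTRUE(s$general$shutdown_at_end)
  ), class = "octo_deployment")
}

exposure_seconds <- function(hw, s, t) {
  if (s$camera$exposure > 0) s$camera$exposure / 1e6 else hw$auto_exposure(t)
}

store_tei <- function(tei, dir, st, hw, store_images) {
  if (!store_images) return(invisible(NULL))
  path <- file.path(dir, "tei",
                    sprintf("%s_%06d.png",
                            format(hw$clock$start + st$t, "%Y%m%dT%H%M%S"),
                            st$teis_evaluated + 1L))
  write_frame(tei, path, type = "png")
  hw$storage$consume(file.size(path))
  invisible(path)
}

# pure derivation of the state sequence from the event log; used both for
# live records and for replays so the two are comparable by construction
state_trace_from_log <- function(log) {
  state <- vapply(seq_len(nrow(log)), function(i) {
    switch(log$event[i],
           boot = "waiting",
           trigger_eval = "sensing",
           capture = "capturing",
           rest_start = "resting",
           shutdown = "shutdown",
           "sensing")
  }, character(1))
  tibble::tibble(time_s = log$time_s, state = state)
}

#' Replay a deployment from its on-disk log
#'
#' Reconstructs the deployment record — counters, trigger times, state
#' trace, exit reason — from `log.csv` and the settings snapshot alone.
#' The log is designed to be sufficient for this: a replayed record's
#' state trace is identical to the live one.
#'
#' @param dir a deployment folder created by [run_deployment()].
#' @return an `octo_deployment` record (without in-memory frames).
#' @export
replay_deployment <- function(dir) {
  log <- tibble::as_tibble(utils::read.csv(file.path(dir, "log.csv"),
                                           stringsAsFactors = FALSE))
  log$time_s <- as.numeric(log$time_s)
  log$voltage <- as.numeric(log$voltage)
  log$free_bytes <- as.numeric(log$free_bytes)
  log$image <- as.character(log$image)
  log$diagnostics <- as.character(log$diagnostics)
  log$timestamp <- as.character(log$timestamp)
  s <- read_settings(file.path(dir, "settings.cfg"))
  boot_diag <- log$diagnostics[log$event == "boot"][1]
  mode <- sub(";.*$", "", sub("^mode=", "", boot_diag))
  shut_diag <- log$diagnostics[log$event == "shutdown"]
  exit_reason <- if (length(shut_diag))
    sub(";.*$", "", sub("^exit=", "", shut_diag[1])) else "none"
  triggers <- log$time_s[log$event == "rest_start"]
  evals <- log$event == "trigger_eval" &
    !grepl("burn_in", log$diagnostics, fixed = TRUE)
  structure(list(
    name = basename(normalizePath(dir)), dir = dir, settings = s,
    start_time = as.POSIXct(log$timestamp[1], format = "%Y-%m-%dT%H:%M:%S",
                            tz = "UTC"),
    mode = mode, images_captured = sum(log$event == "capture"),
    teis_evaluated = sum(evals),
    last_trigger_time = if (length(triggers)) max(triggers) else NA_real_,
    triggers = triggers, state = "shutdown", exit_reason = exit_reason,
    duration = max(log$time_s), log = log,
    state_trace = state_trace_from_log(log),
    shutdown = FALSE
  ), class = "octo_deployment")
}

#' @export
print.octo_deployment <- function(x, ...) {
  cat(sprintf(
    "<octo_deployment %s (%s)>\n  %d image(s), %d TEI(s) evaluated, %d trigger(s)\n  exit: %s after %.0f simulated s\n",
    x$name, x$mode, x$images_captured, x$teis_evaluated,
    length(x$triggers), x$exit_reason, x$duration))
  invisible(x)
}
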