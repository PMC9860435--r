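#' Synthetic benthic scene specification
#'
#' Describes the simulator's stand-in for footage from a high-current
#' seafloor site: a static textured background, slow sinusoidal luminance
#' drift (tidal-current / lighting variation), and per-frame additive
#' Gaussian sensor noise. Frames are rendered deterministically from the
#' seed, one frame per motion-evaluation interval, and are independent of
#' rendering order (each frame carries its own noise stream), so the
#' deployment engine can skip frames during rest periods.
#'
#' Stock values model a moderately rough scene: mean grey 120, texture
#' amplitude 10, noise sd 2 grey levels, drift amplitude 6 grey levels
#' with an hour-scale (3600 s) period.
#'
#' @param width,height frame size in pixels (default 320 x 240, the
#'   trigger-evaluation tier).
#' @param mean background mean grey level.
#' @param texture_amp amplitude of the static smooth texture (grey
#'   levels).
#' @param noise_sd per-frame additive Gaussian noise sd (grey levels).
#' @param drift_amp amplitude of the sinusoidal luminance drift (grey
#'   levels).
#' @param drift_period drift period in seconds.
#' @param frame_interval seconds between successive frames (one frame per
#'   motion-evaluation interval).
#' @param duration scene length in frames.
#' @param seed integer seed; the same seed gives bit-identical frames.
#' @return an `octo_scene` specification (texture field precomputed).
#' @export
scene_spec <- function(width = 320L, height = 240L, mean = 120,
                       texture_amp = 10, noise_sd = 2, drift_amp = 6,
                       drift_period = 3600, frame_interval = 1,
                       duration = 600L, seed = 1L) {
  stopifnot(texture_amp >= 0, noise_sd >= 0, drift_amp >= 0,
            drift_period > 0, frame_interval > 0, duration >= 1)
  if (mean - texture_amp - drift_amp < 0 || mean + texture_amp + drift_amp > 255) {
    stop("mean +/- texture_amp +/- drift_amp must stay within [0, 255]")
  }
  texture <- with_frame_seed(seed, 0L, {
    coarse <- matrix(stats::runif(16 * 12, -1, 1), 12, 16)
    up <- bilinear_upsample(coarse, height, width)
    up * texture_amp
  })
  structure(list(width = as.integer(width), height = as.integer(height),
                 mean = mean, texture_amp = texture_amp, noise_sd = noise_sd,
                 drift_amp = drift_amp, drift_period = drift_period,
                 frame_interval = frame_interval,
                 duration = as.integer(duration), seed = as.integer(seed),
                 texture = texture),
            class = "octo_scene")
}

#' @export
print.octo_scene <- function(x, ...) {
  cat(sprintf(
    "<octo_scene %dx%d px, %d frames @ %gs, noise sd %g, drift %g/%gs, seed %d>\n",
    x$width, x$height, x$duration, x$frame_interval, x$noise_sd,
    x$drift_amp, x$drift_period, x$seed))
  invisible(x)
}

#' Moving target specification
#'
#' A hard-edged elliptical target of fixed signed contrast against the
#' local background. The target enters at `entry_frame` centred at
#' `(x0, y0)` (column/row from the top-left). Under the `"linear"` path it
#' moves with constant velocity from entry; under `"dwell"` it holds its
#' entry position for `dwell_frames` frames, then moves. Targets are
#' rasterized without anti-aliasing so truth masks are exact.
#'
#' @param a,b ellipse semi-axes in pixels (x and y).
#' @param contrast signed grey-level offset against the background.
#' @param entry_frame first frame in which the target is drawn.
#' @param x0,y0 entry centre, in pixels.
#' @param vx,vy velocity in pixels/frame.
#' @param path `"linear"` or `"dwell"`.
#' @param dwell_frames frames to hold position under the `"dwell"` path.
#' @return an `octo_target` specification.
#' @export
target_spec <- function(a, b, contrast, entry_frame = 1L, x0, y0,
                        vx = 0, vy = 0, path = c("linear", "dwell"),
                        dwell_frames = 0L) {
  stopifnot(a >= 1, b >= 1)
  structure(list(a = a, b = b, contrast = contrast,
                 entry_frame = as.integer(entry_frame), x0 = x0, y0 = y0,
                 vx = vx, vy = vy, path = match.arg(path),
                 dwell_frames = as.integer(dwell_frames)),
            class = "octo_target")
}

target_centre <- function(tg, frame) {
  dt <- frame - tg$entry_frame
  if (dt < 0) return(NULL)
  if (tg$path == "dwell") dt <- max(0, dt - tg$dwell_frames)
  c(x = tg$x0 + tg$vx * dt, y = tg$y0 + tg$vy * dt)
}

# exact hard-edged ellipse raster on pixel centres
ellipse_mask <- function(cx, cy, a, b, H, W) {
  xs <- matrix(seq_len(W), H, W, byrow = TRUE)
  ys <- matrix(seq_len(H), H, W)
  ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
}

# run a block with a frame-specific RNG stream, restoring global state
with_frame_seed <- function(seed, frame, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed((as.numeric(seed) * 1000003 + frame) %% 2147483647)
  expr
}

bilinear_upsample <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  ry <- seq(1, h, length.out = H)
  rx <- seq(1, w, length.out = W)
  y0 <- pmin(floor(ry), h - 1); x0 <- pmin(floor(rx), w - 1)
  fy <- ry - y0; fx <- rx - x0
  (outer(1 - fy, 1 - fx) * m[cbind(rep(y0, W), rep(x0, each = H))] +
   outer(1 - fy, fx)     * m[cbind(rep(y0, W), rep(x0 + 1, each = H))] +
   outer(fy, 1 - fx)     * m[cbind(rep(y0 + 1, W), rep(x0, each = H))] +
   outer(fy, fx)         * m[cbind(rep(y0 + 1, W), rep(x0 + 1, each = H))]) |>
    matrix(H, W)
}

#' Render one scene frame
#'
#' Deterministically renders frame `frame` of a scene (1-based), with its
#' targets, at an arbitrary output size (the native scene raster is
#' resampled for full-resolution capture tiers; noise is drawn at the
#' output size). Target pixels differ from the local background by
#' exactly the specified contrast before noise.
#'
#' @param scene an `octo_scene`.
#' @param targets list of `octo_target`s.
#' @param frame frame index (1-based).
#' @param dims optional output `c(width, height)`; default native size.
#' @param noise draw per-frame sensor noise (set `FALSE` for the
#'   noise-free render that truth masks are checked against).
#' @return an `octo_frame` stamped with the frame's scene time.
#' @export
render_frame <- function(scene, targets = list(), frame, dims = NULL,
                         noise = TRUE) {
  native <- is.null(dims) ||
    identical(as.integer(dims), c(scene$width, scene$height))
  W <- if (native) scene$width else as.integer(dims[1])
  H <- if (native) scene$height else as.integer(dims[2])
  sx <- W / scene$width; sy <- H / scene$height
  t_s <- (frame - 1) * scene$frame_interval
  drift <- scene$drift_amp * sin(2 * pi * t_s / scene$drift_period)
  tex <- if (native) scene$texture else
    scene$texture[pmin(ceiling(seq_len(H) / sy), scene$height),
                  pmin(ceiling(seq_len(W) / sx), scene$width)]
  px <- scene$mean + tex + drift
  for (tg in targets) {
    ctr <- target_centre(tg, frame)
    if (is.null(ctr)) next
    inside <- ellipse_mask(ctr["x"] * sx, ctr["y"] * sy,
                           tg$a * sx, tg$b * sy, H, W)
    px[inside] <- px[inside] + tg$contrast
  }
  if (noise && scene$noise_sd > 0) {
    px <- px + with_frame_seed(scene$seed, frame,
                               matrix(stats::rnorm(H * W, 0, scene$noise_sd), H, W))
  }
  new_frame(px, timestamp = t_s, tier = if (native) "tei" else "full")
}

#' Generate a frame sequence with ground truth
#'
#' Materialises a scene as a list of frames plus exact per-frame truth:
#' binary target masks, target-present flags, and per-target rasterized
#' areas. Thresholding the noise-free render at half the target contrast
#' reproduces each truth mask exactly. A target that never appears inside
#' the frame raises a warning and contributes no truth.
#'
#' @param scene an `octo_scene`.
#' @param targets list of `octo_target`s.
#' @return a list with `frames` (list of `octo_frame`), and `truth`: a
#'   list with `masks` (per-frame 0/1 matrices), `present` (logical
#'   vector), `areas` (tibble: `frame`, `target`, `area`), and
#'   `frame_interval`.
#' @export
generate_sequence <- function(scene, targets = list()) {
  n <- scene$duration
  frames <- vector("list", n)
  masks <- vector("list", n)
  present <- logical(n)
  areas <- list()
  appeared <- logical(length(targets))
  for (i in seq_len(n)) {
    frames[[i]] <- render_frame(scene, targets, i)
    mk <- matrix(0, scene$height, scene$width)
    for (j in seq_along(targets)) {
      ctr <- target_centre(targets[[j]], i)
      if (is.null(ctr)) next
      inside <- ellipse_mask(ctr["x"], ctr["y"], targets[[j]]$a,
                             targets[[j]]$b, scene$height, scene$width)
      if (any(inside)) {
        appeared[j] <- TRUE
        mk[inside] <- 1
        areas[[length(areas) + 1L]] <-
          tibble::tibble(frame = i, target = j, area = sum(inside))
      }
    }
    masks[[i]] <- mk
    present[i] <- any(mk > 0)
  }
  if (any(!appeared) && length(targets)) {
    warning(sprintf("%d target(s) never entered the frame", sum(!appeared)))
  }
  areas <- if (length(areas)) do.call(rbind, areas) else
    tibble::tibble(frame = integer(), target = integer(), area = integer())
  list(frames = frames,
       truth = list(masks = masks, present = present, areas = areas,
                    frame_interval = scene$frame_interval))
}

#' Read a scene/target specification from a flat config file
#'
#' Parses the INI-style scene description used by the command-line
#' runner's `sim:` sources: one `[scene]` section with [scene_spec()]
#' fields and any number of `[target]` sections with [target_spec()]
#' fields. Unknown keys raise an error naming the section.
#'
#' @param path path to the scene config file.
#' @return a list with `scene` (an `octo_scene`) and `targets` (list of
#'   `octo_target`).
#' @export
read_scene_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("[;#].*$", "", lines))
  lines <- lines[nzchar(lines)]
  blocks <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      if (!is.null(current)) blocks[[length(blocks) + 1L]] <- current
      current <- list(.section = tolower(gsub("^\\[|\\]$", "", ln)))
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(current)) stop("scene config keys must follow a section header")
      key <- tolower(trimws(sub("=.*$", "", ln)))
      val <- trimws(sub("^[^=]*=", "", ln))
      num <- suppressWarnings(as.numeric(val))
      current[[key]] <- if (is.na(num)) tolower(val) else num
    }
  }
  if (!is.null(current)) blocks[[length(blocks) + 1L]] <- current
  secs <- vapply(blocks, `[[`, "", ".section")
  if (sum(secs == "scene") != 1L) {
    stop("scene config needs exactly one [scene] section")
  }
  build <- function(block, fn, what) {
    args <- block[setdiff(names(block), ".section")]
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) {
      stop(sprintf("unknown %s key(s): %s", what, paste(bad, collapse = ", ")))
    }
    do.call(fn, args)
  }
  list(scene = build(blocks[[which(secs == "scene")]], scene_spec, "scene"),
       targets = lapply(blocks[secs == "target"], build, target_spec, "target"))
}

#' Per-frame target presence without materialising frames
#'
#' Computes the `present` flags of [generate_sequence()]'s truth directly
#' from the target geometry (ellipse extent intersected with the frame),
#' so long scenes can be scored without rendering or storing truth masks.
#'
#' @param scene an `octo_scene`.
#' @param targets list of `octo_target`s.
#' @return a truth list (`present`, `frame_interval`) accepted by
#'   [ground_truth_events()].
#' @export
presence_truth <- function(scene, targets) {
  present <- logical(scene$duration)
  for (tg in targets) {
    for (i in tg$entry_frame:scene$duration) {
      ctr <- target_centre(tg, i)
      inside <- ctr["x"] + tg$a >= 1 && ctr["x"] - tg$a <= scene$width &&
        ctr["y"] + tg$b >= 1 && ctr["y"] - tg$b <= scene$height
      if (inside) present[i] <- TRUE
      else if (i > tg$entry_frame + tg$dwell_frames) break # left for good
    }
  }
  list(present = present, frame_interval = scene$frame_interval)
}

#' Expected trigger windows from ground truth
#'
#' Collapses per-frame target presence into maximal presence windows, then
#' marks each window as matchable or not given the engine's post-trigger
#' rest period: walking forward in time, a window whose whole span falls
#' inside the rest shadow cast by the previous matchable window cannot be
#' detected and is flagged unmatchable.
#'
#' @param truth the `truth` element of [generate_sequence()].
#' @param rest_minutes post-trigger rest (minutes).
#' @param detect_interval motion-evaluation interval (seconds).
#' @return a tibble with one row per presence window: `start`, `end`
#'   (seconds), `matchable`, and `expected_trigger` (the earliest
#'   evaluation time that can fire on it; `NA` when unmatchable).
#' @export
ground_truth_events <- function(truth, rest_minutes, detect_interval) {
  pres <- truth$present
  fi <- truth$frame_interval %||% 1
  if (!any(pres)) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          matchable = logical(), expected_trigger = numeric()))
  }
  r <- rle(pres)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  win <- tibble::tibble(start = (starts[on] - 1) * fi,
                        end = (ends[on] - 1) * fi)
  rest_s <- rest_minutes * 60
  avail <- -Inf
  matchable <- logical(nrow(win))
  expected <- rep(NA_real_, nrow(win))
  for (i in seq_len(nrow(win))) {
    t0 <- max(win$start[i], avail)
    t0 <- ceiling(t0 / detect_interval) * detect_interval
    if (t0 <= win$end[i]) {
      matchable[i] <- TRUE
      expected[i] <- t0
      avail <- t0 + rest_s
    }
  }
  win$matchable <- matchable
  win$expected_trigger <- expected
  win
}
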