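# Shared fixtures, built in code at test time.

# burn a background model in over the first `n` frames of a scene, through
# the same blur + crop the trigger pipeline applies
burn_in_model <- function(scene, s = default_settings(), n = s$motion$frame_history,
                          targets = list()) {
  burn <- lapply(seq_len(n), function(i) {
    crop_roi(gaussian_blur(render_frame(scene, targets, i), 5L),
             s$motion$trigger_roi)
  })
  mog_init(burn, frame_history = s$motion$frame_history)
}

# the package's standard per-pixel recovery fixture: a swiftly transiting
# ellipse (20 x 10 px, contrast +50, 20 px/frame) over a low-noise static
# background, entering after the 25-frame burn-in
standard_recovery_fixture <- function(seed = 42) {
  scene <- scene_spec(noise_sd = 2, drift_amp = 0, duration = 40, seed = seed)
  target <- target_spec(a = 20, b = 10, contrast = 50, entry_frame = 26,
                        x0 = 60, y0 = 120, vx = 20)
  list(scene = scene, target = target)
}

# minimal deployment record surface for scoring tests
fake_deployment <- function(triggers, duration, detect_interval = 1,
                            images = length(triggers)) {
  s <- default_settings()
  s$motion$motion_detect_interval <- detect_interval
  structure(list(triggers = triggers, duration = duration, settings = s,
                 images_captured = images),
            class = "octo_deployment")
}

random_valid_settings <- function() {
  sch <- octotrigger:::settings_schema()
  s <- default_settings()
  for (i in seq_len(nrow(sch))) {
    key <- sch$key[i]; grp <- sch$group[i]
    v <- switch(sch$type[i],
      enum = ,
      enum_int = sample(sch$choices[[i]], 1)[[1]],
      boolean = sample(c(TRUE, FALSE), 1),
      string = paste0("sys_", sample.int(1000, 1)),
      integer = as.integer(round(stats::runif(1, max(sch$lo[i], 0),
                                              min(sch$hi[i], 1000)))),
      double = stats::runif(1, max(sch$lo[i], 0.01), min(sch$hi[i], 1000)),
      roi = {
        left <- sample(0:200, 1); bottom <- sample(0:150, 1)
        c(left, bottom, sample.int(320 - left, 1), sample.int(240 - bottom, 1))
      })
    s[[grp]][[key]] <- v
  }
  # keep image_quality consistent with the chosen image_type
  s$camera$image_quality <- switch(s$camera$image_type,
    jpeg = sample(70:100, 1), png = sample(0:9, 1), sample(0:100, 1))
  s
}

# pixel values only, attribute-free (frames carry timestamp/tier metadata)
px_of <- function(f) {
  x <- unclass(f)
  attributes(x) <- list(dim = dim(x))
  x
}
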