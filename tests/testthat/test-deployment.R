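test_that("intervalometer runs capture exactly max_images, evenly spaced", {
  s <- default_settings()
  s$general$collection_type <- "still_intervalometer"
  s$camera$image_type <- "png"       # lossless so on-disk checks are exact
  s$camera$image_quality <- 3L
  s$camera$image_resolution <- "l"
  hw <- sim_hardware(scene_spec(duration = 120, seed = 51))
  rec <- run_deployment(hw, s, out_dir = withr::local_tempdir())

  expect_identical(rec$images_captured, 10L)
  expect_identical(rec$exit_reason, "max_images")
  caps <- rec$log[rec$log$event == "capture", ]
  expect_identical(nrow(caps), 10L)
  expect_equal(caps$time_s, as.numeric(60:69))    # after the 1 min wait
  expect_true(all(diff(caps$time_s) == 1))
  expect_true(all(is.finite(caps$voltage)))       # voltage logged on capture
  expect_identical(length(list.files(file.path(rec$dir, "full"))), 10L)
  expect_true(file.exists(file.path(rec$dir, "settings.cfg")))
  expect_true(file.exists(file.path(rec$dir, "log.csv")))
  expect_match(rec$name, "^D\\d{8}-T\\d{6}$")
})

test_that("triggered runs rest after a trigger with no TEI evaluations", {
  s <- default_settings()
  scene <- scene_spec(duration = 600, seed = 52)
  target <- target_spec(a = 20, b = 10, contrast = 60, entry_frame = 200,
                        x0 = 160, y0 = 120, vx = 3)
  hw <- sim_hardware(scene, list(target))
  rec <- run_deployment(hw, s, out_dir = withr::local_tempdir(),
                        store_images = FALSE)

  expect_identical(length(rec$triggers), 1L)
  expect_identical(rec$images_captured, 1L)
  trig <- rec$triggers[1]
  evals <- rec$log$time_s[rec$log$event == "trigger_eval" &
                            !grepl("burn_in", rec$log$diagnostics)]
  in_rest <- evals[evals > trig &
                     evals < trig + s$motion$post_detection_rest * 60]
  expect_identical(length(in_rest), 0L)
  gap <- min(evals[evals > trig]) - trig
  expect_identical(gap / 60, s$motion$post_detection_rest)

  # triggered decisions carry re-derivable diagnostics
  fired <- rec$log$diagnostics[rec$log$event == "trigger_eval" &
                                 grepl("triggered=true", rec$log$diagnostics)]
  expect_identical(length(fired), 1L)
  expect_match(fired, "fg=\\d+;n_comp=\\d+")
})

test_that("low voltage shuts the deployment down strictly below cutoff", {
  s <- default_settings()
  s$general$collection_type <- "still_intervalometer"
  s$intervalometer$max_images <- 100L
  s$intervalometer$image_interval <- 600
  s$camera$image_resolution <- "l"
  # 12.5 V at boot, crossing 11 V at t = 3600 s
  hw <- sim_hardware(scene_spec(duration = 7200, frame_interval = 60,
                                seed = 53),
                     voltage = function(t) 12.5 - 1.5 * t / 3600)
  rec <- run_deployment(hw, s, out_dir = withr::local_tempdir(),
                        store_images = FALSE)
  expect_identical(rec$exit_reason, "low_voltage")
  # first check after the crossing: capture at 3060 still >= 11 V
  last_cap <- max(rec$log$time_s[rec$log$event == "capture"])
  expect_lt(hw$voltage(rec$duration), 11)
  expect_gte(hw$voltage(last_cap), 11)
})

test_that("exit conditions follow the fixed priority and strict boundaries", {
  s <- default_settings()
  st <- list(t = 0, mode = "triggered", images_captured = 0L, acq_start = 0)
  hw_at <- function(v, free = 64e9) {
    hw <- sim_hardware(scene_spec(duration = 10, seed = 54),
                       voltage = function(t) v, free_bytes = free)
    hw
  }
  expect_identical(check_exit(st, hw_at(10.9), s), "low_voltage")
  expect_identical(check_exit(st, hw_at(11.0), s), "none")  # strict <
  expect_identical(check_exit(st, hw_at(12, free = 1000), s), "disk_full")
  # low voltage outranks a full disk
  expect_identical(check_exit(st, hw_at(10, free = 1000), s), "low_voltage")
  st2 <- st; st2$t <- 61 * 60; st2$acq_start <- 0
  expect_identical(check_exit(st2, hw_at(12), s), "max_runtime")
  st3 <- st; st3$mode <- "intervalometer"; st3$images_captured <- 10L
  expect_identical(check_exit(st3, hw_at(12), s), "max_images")
})

test_that("triggered runs stop at max_runtime", {
  s <- default_settings()
  s$motion$max_runtime <- 2        # minutes
  hw <- sim_hardware(scene_spec(duration = 600, seed = 55))
  rec <- run_deployment(hw, s, out_dir = withr::local_tempdir(),
                        store_images = FALSE)
  expect_identical(rec$exit_reason, "max_runtime")
  expect_lte(rec$duration, 60 + 2 * 60 + 2)   # wait + runtime (+interval)
})

test_that("a deployment can be replayed from its log alone", {
  s <- default_settings()
  scene <- scene_spec(duration = 200, seed = 56)
  target <- target_spec(a = 20, b = 10, contrast = 60, entry_frame = 100,
                        x0 = 160, y0 = 120, vx = 3)
  hw <- sim_hardware(scene, list(target))
  rec <- run_deployment(hw, s, out_dir = withr::local_tempdir())
  rp <- replay_deployment(rec$dir)
  expect_identical(rp$state_trace, rec$state_trace)
  expect_identical(rp$images_captured, rec$images_captured)
  expect_identical(rp$teis_evaluated, rec$teis_evaluated)
  expect_identical(rp$triggers, rec$triggers)
  expect_identical(rp$exit_reason, rec$exit_reason)
  expect_identical(rp$mode, rec$mode)
})

test_that("fixed seed and settings give bit-identical deployments", {
  s <- default_settings()
  s$camera$image_type <- "png"
  s$camera$image_quality <- 3L
  s$camera$image_resolution <- "l"
  scene <- scene_spec(duration = 100, seed = 57)
  target <- target_spec(a = 20, b = 10, contrast = 60, entry_frame = 50,
                        x0 = 160, y0 = 120, vx = 3)
  run_once <- function(dir) {
    run_deployment(sim_hardware(scene, list(target)), s, out_dir = dir)
  }
  a <- run_once(withr::local_tempdir())
  b <- run_once(withr::local_tempdir())
  expect_identical(a$log, b$log)
  fa <- list.files(a$dir, recursive = TRUE)
  fb <- list.files(b$dir, recursive = TRUE)
  expect_identical(fa, fb)
  for (f in fa) {
    expect_identical(unname(tools::md5sum(file.path(a$dir, f))),
                     unname(tools::md5sum(file.path(b$dir, f))))
  }
})

test_that("unwritable output fails before any acquisition", {
  blocker <- withr::local_tempfile()
  writeLines("x", blocker)          # a file where a directory is needed
  hw <- sim_hardware(scene_spec(duration = 10, seed = 58))
  expect_error(
    suppressWarnings(run_deployment(hw, default_settings(),
                                    out_dir = blocker)))
})

test_that("deployment records expose tidy, glance and autoplot views", {
  s <- default_settings()
  s$general$collection_type <- "still_intervalometer"
  s$camera$image_resolution <- "l"
  hw <- sim_hardware(scene_spec(duration = 120, seed = 59))
  rec <- run_deployment(hw, s, out_dir = withr::local_tempdir(),
                        store_images = FALSE)
  expect_identical(tidy(rec), rec$log)
  g <- glance(rec)
  expect_identical(g$images_captured, 10L)
  expect_identical(g$exit_reason, "max_images")
  expect_s3_class(autoplot(rec), "ggplot")
})

test_that("a directory of frames drives the engine like a camera", {
  sc <- scene_spec(width = 320, height = 240, duration = 40, seed = 60,
                   noise_sd = 1)
  dir <- withr::local_tempdir()
  for (i in 1:40) {
    write_frame(render_frame(sc, list(), i),
                file.path(dir, sprintf("frame_%03d.png", i)), type = "png")
  }
  hw <- dir_hardware(dir, frame_interval = 1)
  f <- hw$camera(tier = "tei", time = 3)
  expect_identical(px_of(f), px_of(render_frame(sc, list(), 4)))
  expect_null(hw$camera(tier = "tei", time = 40))

  s <- default_settings()
  s$general$initial_wait <- 0L
  rec <- run_deployment(hw, s, out_dir = withr::local_tempdir(),
                        store_images = FALSE)
  expect_identical(rec$exit_reason, "end_of_input")
  expect_identical(rec$teis_evaluated, 40L - 25L)
  expect_error(dir_hardware(withr::local_tempdir()), "no frame images")
})
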