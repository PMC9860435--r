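test_that("degenerate scenes render as a constant background", {
  sc <- scene_spec(mean = 120, texture_amp = 0, noise_sd = 0, drift_amp = 0,
                   duration = 5, seed = 1)
  gen <- generate_sequence(sc)
  for (f in gen$frames) expect_true(all(unclass(f) == 120))
  expect_false(any(gen$truth$present))
})

test_that("rendering is deterministic in the seed and frame index", {
  sc <- scene_spec(duration = 10, seed = 7)
  expect_identical(unclass(render_frame(sc, list(), 4)),
                   unclass(render_frame(sc, list(), 4)))
  sc2 <- scene_spec(duration = 10, seed = 8)
  expect_false(identical(unclass(render_frame(sc, list(), 4)),
                         unclass(render_frame(sc2, list(), 4))))
  # rendering never disturbs the session RNG stream
  set.seed(99); a <- rnorm(3)
  set.seed(99); invisible(render_frame(sc, list(), 2)); b <- rnorm(3)
  expect_identical(a, b)
})

test_that("rasterized ellipse areas stay within 2% of pi*a*b", {
  cases <- list(c(20, 10), c(7, 5), c(40, 30))
  for (ab in cases) {
    tg <- target_spec(a = ab[1], b = ab[2], contrast = 60, entry_frame = 1,
                      x0 = 160, y0 = 120)
    sc <- scene_spec(noise_sd = 0, duration = 2, seed = 3)
    gen <- generate_sequence(sc, list(tg))
    area <- gen$truth$areas$area[1]
    expect_lt(abs(area - pi * ab[1] * ab[2]) / (pi * ab[1] * ab[2]), 0.02)
  }
})

test_that("background noise matches its specified standard deviation", {
  sc <- scene_spec(width = 24, height = 18, noise_sd = 2, drift_amp = 0,
                   duration = 1000, seed = 5)
  vals <- vapply(1:1000, function(i) unclass(render_frame(sc, list(), i))[7, 9],
                 numeric(1))
  expect_lt(abs(stats::sd(vals) - 2) / 2, 0.10)
})

test_that("targets sit at exactly the specified contrast before noise", {
  tg <- target_spec(a = 15, b = 9, contrast = -40, entry_frame = 1,
                    x0 = 100, y0 = 100)
  sc <- scene_spec(noise_sd = 0, duration = 2, seed = 6)
  with_t <- unclass(render_frame(sc, list(tg), 1, noise = FALSE))
  without <- unclass(render_frame(sc, list(), 1, noise = FALSE))
  gen <- generate_sequence(sc, list(tg))
  inside <- gen$truth$masks[[1]] > 0
  expect_true(all((with_t - without)[inside] == -40))
  expect_true(all((with_t - without)[!inside] == 0))
})

test_that("thresholding the noise-free render at half contrast recovers truth", {
  tg <- target_spec(a = 20, b = 10, contrast = 60, entry_frame = 1,
                    x0 = 160, y0 = 120, vx = 3)
  sc <- scene_spec(noise_sd = 0, duration = 4, seed = 7)
  gen <- generate_sequence(sc, list(tg))
  for (i in 1:4) {
    diff <- unclass(render_frame(sc, list(tg), i, noise = FALSE)) -
      unclass(render_frame(sc, list(), i, noise = FALSE))
    expect_identical((diff >= 30) + 0, gen$truth$masks[[i]] + 0)
  }
})

test_that("dwelling targets hold position before moving", {
  tg <- target_spec(a = 10, b = 10, contrast = 50, entry_frame = 2,
                    x0 = 60, y0 = 60, vx = 5, path = "dwell",
                    dwell_frames = 3)
  sc <- scene_spec(noise_sd = 0, duration = 8, seed = 8)
  gen <- generate_sequence(sc, list(tg))
  expect_identical(gen$truth$masks[[2]], gen$truth$masks[[5]])
  expect_false(identical(gen$truth$masks[[5]], gen$truth$masks[[6]]))
})

test_that("a target that never enters warns and leaves truth empty", {
  tg <- target_spec(a = 5, b = 5, contrast = 50, entry_frame = 1,
                    x0 = 1000, y0 = 1000)
  sc <- scene_spec(noise_sd = 0, duration = 3, seed = 9)
  expect_warning(gen <- generate_sequence(sc, list(tg)), "never entered")
  expect_false(any(gen$truth$present))
  expect_identical(nrow(gen$truth$areas), 0L)
})

test_that("presence flags from geometry agree with rendered truth", {
  tg <- target_spec(a = 12, b = 8, contrast = 50, entry_frame = 5,
                    x0 = 300, y0 = 120, vx = 4)
  sc <- scene_spec(noise_sd = 0, duration = 20, seed = 10)
  gen <- generate_sequence(sc, list(tg))
  fast <- presence_truth(sc, list(tg))
  expect_identical(fast$present, gen$truth$present)
})

test_that("ground-truth events collapse presence into matchable windows", {
  mk <- function(present, fi = 1) list(present = present, frame_interval = fi)

  pres <- logical(300); pres[101:201] <- TRUE
  w <- ground_truth_events(mk(pres), rest_minutes = 5, detect_interval = 1)
  expect_identical(nrow(w), 1L)
  expect_true(w$matchable)
  expect_identical(w$start, 100)
  expect_identical(w$end, 200)

  # two passes 10 s apart with a 5 min rest: second is rest-shadowed
  pres2 <- logical(120); pres2[11:20] <- TRUE; pres2[31:40] <- TRUE
  w2 <- ground_truth_events(mk(pres2), rest_minutes = 5, detect_interval = 1)
  expect_identical(w2$matchable, c(TRUE, FALSE))
  expect_true(is.na(w2$expected_trigger[2]))

  # far enough apart to both be matchable
  pres3 <- logical(700); pres3[11:20] <- TRUE; pres3[401:420] <- TRUE
  w3 <- ground_truth_events(mk(pres3), rest_minutes = 5, detect_interval = 1)
  expect_identical(w3$matchable, c(TRUE, TRUE))

  w4 <- ground_truth_events(mk(logical(50)), 5, 1)
  expect_identical(nrow(w4), 0L)
})

test_that("scene configs parse into scene and target specifications", {
  cfg <- c("[scene]", "width = 64", "height = 48", "noise_sd = 1",
           "duration = 30", "seed = 4", "",
           "[target]", "a = 8", "b = 5", "contrast = 40",
           "entry_frame = 10", "x0 = 30", "y0 = 24", "vx = 2",
           "[target]", "a = 6", "b = 6", "contrast = -30",
           "entry_frame = 20", "x0 = 10", "y0 = 10", "path = dwell",
           "dwell_frames = 4")
  p <- withr::local_tempfile(fileext = ".cfg")
  writeLines(cfg, p)
  parsed <- read_scene_config(p)
  expect_s3_class(parsed$scene, "octo_scene")
  expect_identical(parsed$scene$width, 64L)
  expect_identical(length(parsed$targets), 2L)
  expect_identical(parsed$targets[[1]]$a, 8)
  expect_identical(parsed$targets[[2]]$path, "dwell")
  expect_identical(parsed$targets[[2]]$dwell_frames, 4L)

  writeLines(c("[scene]", "bogus_key = 1"), p)
  expect_error(read_scene_config(p), "bogus_key")
  writeLines("a = 1", p)
  expect_error(read_scene_config(p), "section")
})
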