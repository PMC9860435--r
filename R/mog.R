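#' Per-pixel mixture-of-Gaussians background model
#'
#' Each pixel's intensity history is modelled as a mixture of `K` Gaussian
#' components (weight, mean, variance). Components are ranked by
#' weight/standard-deviation; the top-ranked components whose cumulative
#' weight first reaches the background ratio `T` form the background set.
#' A pixel is background when its value falls within the matching band of
#' a background component; otherwise it is foreground. The matching band
#' is `max(foreground_threshold, 2.5 * sigma_k)` grey levels, so the
#' configured greyscale sensitivity acts as a floor under the conventional
#' 2.5-sigma rule.
#'
#' The model learns online with rate `alpha = 1 / frame_history`: matched
#' components gain weight and move toward the sample; when no component
#' matches, the weakest component is replaced by a new one centred on the
#' sample with high variance and low weight. Weights are kept normalised.
#' The per-pixel sweep is implemented in compiled code.
#'
#' `mog_init()` seeds the model from a burn-in sequence: the first frame
#' initialises component 1 with weight 1 and variance `s2_init`; the
#' remaining frames are applied through the ordinary update.
#'
#' @param frames list of `octo_frame`s (all the same size, already blurred
#'   and ROI-cropped as in the trigger pipeline).
#' @param frame_history number of frames the background memory spans
#'   (learning rate is its reciprocal; stock value 25).
#' @param K components per pixel (default 3).
#' @param T_bg background ratio in (0, 1] (default 0.9).
#' @param s2_init initial/replacement component variance (default 15^2).
#' @param s2_min variance floor in grey^2 (default 4).
#' @param w_new weight given to a replacement component before
#'   renormalisation (default 0.05).
#' @return an `octo_mog` model (an environment: updates mutate it in
#'   place).
#' @export
mog_init <- function(frames, frame_history = 25, K = 3L, T_bg = 0.9,
                     s2_init = 225, s2_min = 4, w_new = 0.05) {
  if (length(frames) < 1) stop("at least one burn-in frame is required")
  dims <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), dims), logical(1)))) {
    stop("all burn-in frames must share the same dimensions")
  }
  if (frame_history < 1) stop("`frame_history` must be >= 1")
  npx <- prod(dims)
  m <- new.env(parent = emptyenv())
  m$H <- dims[1]; m$W <- dims[2]; m$K <- as.integer(K)
  m$alpha <- 1 / frame_history
  m$T_bg <- T_bg
  m$s2_init <- s2_init
  m$s2_min <- s2_min
  m$w_new <- w_new
  m$w <- cbind(rep(1, npx), matrix(0, npx, K - 1))
  m$mu <- cbind(as.vector(unclass(frames[[1]]) + 0), matrix(0, npx, K - 1))
  m$s2 <- matrix(s2_init, npx, K)
  m$frames_seen <- 1L
  class(m) <- "octo_mog"
  for (f in frames[-1]) mog_update_classify(m, f, foreground_threshold = 8)
  m
}

#' @export
print.octo_mog <- function(x, ...) {
  cat(sprintf(
    "<octo_mog %dx%d px, K=%d, alpha=%.4f, T=%.2f, %d frame(s) seen>\n",
    x$W, x$H, x$K, x$alpha, x$T_bg, x$frames_seen))
  invisible(x)
}

#' Classify a frame against the background model and update it
#'
#' Classification uses the pre-update model (a target must not suppress
#' its own detection), then the model absorbs the frame: the matched
#' component's weight grows toward 1 at rate `alpha` while its mean and
#' variance move toward the sample; unmatched pixels replace their weakest
#' component. The model environment is mutated in place.
#'
#' @param model an `octo_mog` model.
#' @param f an `octo_frame` matching the model dimensions.
#' @param foreground_threshold greyscale sensitivity floor (0-255).
#' @return the binary foreground `octo_mask`.
#' @export
mog_update_classify <- function(model, f, foreground_threshold = 8) {
  if (!identical(dim(f)[1:2], c(model$H, model$W))) {
    stop(sprintf("frame %dx%d does not match model %dx%d",
                 ncol(f), nrow(f), model$W, model$H))
  }
  fg <- .mog_step(model$w, model$mu, model$s2,
                  as.vector(unclass(f) + 0),
                  as.numeric(foreground_threshold), model$alpha,
                  model$T_bg, model$s2_init, model$s2_min, model$w_new)
  model$frames_seen <- model$frames_seen + 1L
  new_mask(matrix(fg, model$H, model$W),
           offset = attr(f, "offset") %||% c(0L, 0L))
}

#' Serialize and restore a background model
#'
#' Snapshots the full mixture state (dimensions, K, learning parameters,
#' per-pixel weights/means/variances) to a self-describing plain-text
#' artifact for post-deployment debugging, and restores it.
#'
#' @param model an `octo_mog` model.
#' @param path file to write to / read from.
#' @return `mog_save()` returns `path` invisibly; `mog_load()` the
#'   restored `octo_mog`.
#' @export
mog_save <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("octo_mog_snapshot 1",
               sprintf("H %d", model$H), sprintf("W %d", model$W),
               sprintf("K %d", model$K),
               sprintf("alpha %.17g", model$alpha),
               sprintf("T_bg %.17g", model$T_bg),
               sprintf("s2_init %.17g", model$s2_init),
               sprintf("s2_min %.17g", model$s2_min),
               sprintf("w_new %.17g", model$w_new),
               sprintf("frames_seen %d", model$frames_seen)), con)
  for (nm in c("w", "mu", "s2")) {
    writeLines(paste(nm, paste(sprintf("%.17g", model[[nm]]),
                               collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname mog_save
#' @export
mog_load <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "octo_mog_snapshot")) stop("not a model snapshot")
  hdr <- strsplit(lines[2:10], " ")
  vals <- stats::setNames(vapply(hdr, `[`, "", 2), vapply(hdr, `[`, "", 1))
  m <- new.env(parent = emptyenv())
  m$H <- as.integer(vals["H"]); m$W <- as.integer(vals["W"])
  m$K <- as.integer(vals["K"])
  m$alpha <- as.numeric(vals["alpha"]); m$T_bg <- as.numeric(vals["T_bg"])
  m$s2_init <- as.numeric(vals["s2_init"])
  m$s2_min <- as.numeric(vals["s2_min"])
  m$w_new <- as.numeric(vals["w_new"])
  m$frames_seen <- as.integer(vals["frames_seen"])
  for (ln in lines[11:13]) {
    parts <- strsplit(ln, " ")[[1]]
    m[[parts[1]]] <- matrix(as.numeric(parts[-1]), m$H * m$W, m$K)
  }
  class(m) <- "octo_mog"
  m
}
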