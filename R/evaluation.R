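#' Score a deployment against ground truth
#'
#' Matches the deployment's trigger events one-to-one to the ground-truth
#' presence windows by time overlap. A trigger overlaps a window when it
#' falls within one motion-evaluation interval of the window on either
#' side (the engine samples the scene at that granularity). Triggers are
#' taken in time order and matched greedily to the unmatched overlapping
#' window that ends earliest, which attains a maximum matching for
#' interval overlap. Triggers overlapping no window are false; windows
#' flagged unmatchable (shadowed by a previous trigger's rest period) are
#' excluded from the sensitivity denominator.
#'
#' @param rec an `octo_deployment` from a triggered run.
#' @param windows truth windows from [ground_truth_events()] (tibble with
#'   `start`, `end`, `matchable`).
#' @return an `octo_metrics` list: `expected_events`, `matchable_events`,
#'   `matched_events`, `sensitivity`, `false_triggers`,
#'   `false_trigger_rate` (per hour), `images_captured`,
#'   `intervalometer_equivalent`, plus the per-trigger `matches` tibble.
#' @export
score_deployment <- function(rec, windows) {
  if (nrow(windows) && max(windows$end) > rec$duration) {
    stop("truth windows extend beyond the deployment clock; clock mismatch")
  }
  di <- rec$settings$motion$motion_detect_interval
  trig <- sort(rec$triggers)
  lo <- windows$start - di
  hi <- windows$end + di
  assigned <- rep(NA_integer_, length(trig))
  taken <- logical(nrow(windows))
  for (i in seq_along(trig)) {
    cand <- which(!taken & trig[i] >= lo & trig[i] <= hi)
    if (length(cand)) {
      j <- cand[which.min(windows$end[cand])]
      assigned[i] <- j
      taken[j] <- TRUE
    }
  }
  overlaps_any <- vapply(trig, function(tt) any(tt >= lo & tt <= hi),
                         logical(1))
  false_triggers <- sum(!overlaps_any)
  matchable <- which(windows$matchable)
  matched <- sum(!is.na(assigned) & assigned %in% matchable)
  dur_h <- rec$duration / 3600
  structure(list(
    expected_events = nrow(windows),
    matchable_events = length(matchable),
    matched_events = matched,
    sensitivity = if (length(matchable)) matched / length(matchable) else NA_real_,
    false_triggers = false_triggers,
    false_trigger_rate = if (dur_h > 0) false_triggers / dur_h else NA_real_,
    images_captured = rec$images_captured,
    intervalometer_equivalent = intervalometer_equivalent(dur_h, di),
    matches = tibble::tibble(trigger_time = trig, window = assigned,
                             false = !overlaps_any),
    windows = windows,
    duration_hours = dur_h
  ), class = "octo_metrics")
}

#' @export
print.octo_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<octo_metrics>\n",
           "  events: %d (%d matchable), matched %d -> sensitivity %.3f\n",
           "  false triggers: %d (%.3f/h)\n",
           "  images: %d triggered vs %d intervalometer-equivalent\n"),
    x$expected_events, x$matchable_events, x$matched_events,
    x$sensitivity, x$false_triggers, x$false_trigger_rate,
    x$images_captured, x$intervalometer_equivalent))
  invisible(x)
}

#' Intervalometer-equivalent image count
#'
#' The number of images a fixed-interval time-lapse would have captured
#' over a deployment span — the capture-economics baseline a triggered
#' system is compared against (785 h at a 2 s interval is 1,413,000
#' frames).
#'
#' @param duration_hours deployment span in hours (>= 0).
#' @param interval_seconds time-lapse interval in seconds (> 0).
#' @return the whole number of images, `floor(duration_hours * 3600 /
#'   interval_seconds)`.
#' @examples
#' intervalometer_equivalent(785, 2)
#' @export
intervalometer_equivalent <- function(duration_hours, interval_seconds) {
  if (interval_seconds <= 0) stop("`interval_seconds` must be > 0")
  if (duration_hours < 0) stop("`duration_hours` must be >= 0")
  floor(duration_hours * 3600 / interval_seconds)
}

#' Write a metrics report
#'
#' Writes trigger-performance metrics as a flat CSV plus a short
#' human-readable text report.
#'
#' @param m an `octo_metrics`.
#' @param path base path; `<path>.csv` and `<path>.txt` are written.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(m, path) {
  utils::write.csv(glance(m), paste0(path, ".csv"), row.names = FALSE)
  writeLines(utils::capture.output(print(m)), paste0(path, ".txt"))
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for deployment records and trigger metrics
#'
#' `tidy()` on a deployment record returns the event log as a tibble; on
#' metrics, the per-trigger match table. `glance()` returns a one-row
#' summary in either case.
#'
#' @param x an `octo_deployment` or `octo_metrics`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.octo_deployment <- function(x, ...) x$log

#' @rdname tidy.octo_deployment
#' @export
glance.octo_deployment <- function(x, ...) {
  tibble::tibble(name = x$name, mode = x$mode,
                 images_captured = x$images_captured,
                 teis_evaluated = x$teis_evaluated,
                 triggers = length(x$triggers),
                 exit_reason = x$exit_reason,
                 duration_s = x$duration)
}

#' @rdname tidy.octo_deployment
#' @export
tidy.octo_metrics <- function(x, ...) x$matches

#' @rdname tidy.octo_deployment
#' @export
glance.octo_metrics <- function(x, ...) {
  tibble::tibble(expected_events = x$expected_events,
                 matchable_events = x$matchable_events,
                 matched_events = x$matched_events,
                 sensitivity = x$sensitivity,
                 false_triggers = x$false_triggers,
                 false_trigger_rate = x$false_trigger_rate,
                 images_captured = x$images_captured,
                 intervalometer_equivalent = x$intervalometer_equivalent)
}

#' Deployment and metrics plots
#'
#' `autoplot()` on a deployment record draws the event timeline (one
#' point per logged event over the simulated clock); on metrics it draws
#' the truth windows with trigger times overlaid.
#'
#' @param object an `octo_deployment` or `octo_metrics`.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.octo_deployment <- function(object, ...) {
  log <- object$log
  ggplot2::ggplot(log, ggplot2::aes(x = .data$time_s / 60,
                                    y = .data$event,
                                    colour = .data$event)) +
    ggplot2::geom_point(show.legend = FALSE) +
    ggplot2::labs(x = "simulated time (min)", y = NULL,
                  title = sprintf("Deployment %s (%s, exit: %s)",
                                  object$name, object$mode,
                                  object$exit_reason)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.octo_deployment
#' @export
autoplot.octo_metrics <- function(object, ...) {
  win <- object$windows
  win$window <- seq_len(nrow(win))
  ggplot2::ggplot() +
    ggplot2::geom_rect(data = win,
                       ggplot2::aes(xmin = .data$start / 60,
                                    xmax = .data$end / 60,
                                    ymin = 0, ymax = 1,
                                    fill = .data$matchable),
                       alpha = 0.4) +
    ggplot2::geom_vline(data = object$matches,
                        ggplot2::aes(xintercept = .data$trigger_time / 60),
                        linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "seagreen",
                                          `FALSE` = "grey60"),
                               name = "matchable") +
    ggplot2::labs(x = "simulated time (min)", y = NULL,
                  title = sprintf("sensitivity %.2f, %d false trigger(s)",
                                  object$sensitivity,
                                  object$false_triggers)) +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot

#' @importFrom ggplot2 .data
NULL
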