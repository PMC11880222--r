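## The four exposure scenarios, as piecewise-constant forcing plus
## discrete bolus-dose event schedules over a 2-week (336 h) window.

#' Construct one of the four canonical exposure scenarios
#'
#' 1. Constant continuous inhalation: a constant chemical concentration
#'    in inhaled air (mg/L) for the whole window.
#' 2. Constant continuous oral: a constant delivery rate (mg/h) into the
#'    stomach lumen.
#' 3. Periodic inhalation: constant air concentration for 6 h/day
#'    (09:00-15:00), 5 days/week -- 10 exposure windows over 2 weeks.
#' 4. Periodic oral: bolus doses (mg) into the stomach lumen 6 times per
#'    day at 4-h spacing (02:00, 06:00, ..., 22:00), 7 days/week -- 84
#'    boluses over 2 weeks.
#'
#' Only dose counts, not clock times, are part of the scenario
#' definitions; the window and bolus anchors used here are package
#' conventions, chosen so that every event lies inside the simulated
#' window.
#'
#' @param kind scenario number, 1-4.
#' @param dose_level air concentration (mg/L; kinds 1 and 3), delivery
#'   rate (mg/h; kind 2) or per-bolus mass (mg; kind 4).  Must be >= 0.
#' @param duration_weeks length of the simulated window (weeks).
#' @return object of class `exposure_schedule` with elements `kind`,
#'   `route`, `duration` (h), `dose_level`, `windows` (data.frame
#'   `start`, `end`, `level`), `background_rate` (mg/h) and `events`
#'   (data.frame `time`, `state`, `increment`).
#' @export
make_scenario <- function(kind, dose_level, duration_weeks = 2) {
  if (!kind %in% 1:4) stop("unknown scenario kind: ", kind, call. = FALSE)
  if (!is.numeric(dose_level) || length(dose_level) != 1L || dose_level < 0)
    stop("dose_level must be a single value >= 0", call. = FALSE)
  duration <- duration_weeks * 7 * 24
  no_events <- data.frame(time = numeric(0), state = character(0),
                          increment = numeric(0), stringsAsFactors = FALSE)
  no_windows <- data.frame(start = numeric(0), end = numeric(0),
                           level = numeric(0))
  sched <- switch(as.character(kind),
    "1" = list(route = "inhalation",
               windows = data.frame(start = 0, end = duration,
                                    level = dose_level),
               background_rate = 0, events = no_events),
    "2" = list(route = "oral", windows = no_windows,
               background_rate = dose_level, events = no_events),
    "3" = {
      days <- as.vector(outer(0:4, 7 * (seq_len(duration_weeks) - 1), "+"))
      start <- sort(24 * days + 9)
      list(route = "inhalation",
           windows = data.frame(start = start, end = start + 6,
                                level = dose_level),
           background_rate = 0, events = no_events)
    },
    "4" = {
      days <- 0:(7 * duration_weeks - 1)
      times <- sort(as.vector(outer(c(2, 6, 10, 14, 18, 22), 24 * days, "+")))
      list(route = "oral", windows = no_windows, background_rate = 0,
           events = data.frame(time = times, state = "amt_stomach_lumen",
                               increment = dose_level,
                               stringsAsFactors = FALSE))
    })
  sched$kind <- kind
  sched$duration <- duration
  sched$dose_level <- dose_level
  class(sched) <- "exposure_schedule"
  .validate_schedule(sched)
}

.validate_schedule <- function(s) {
  if (nrow(s$windows)) {
    if (any(s$windows$level < 0)) stop("forcing must be nonnegative",
                                       call. = FALSE)
    if (any(s$windows$end <= s$windows$start))
      stop("window boundaries must be strictly increasing", call. = FALSE)
  }
  if (nrow(s$events)) {
    if (any(s$events$time < 0 | s$events$time > s$duration))
      stop("event times must lie within [0, duration]", call. = FALSE)
  }
  s
}

#' Evaluate the inhalation forcing at a time point
#'
#' Right-continuous piecewise-constant evaluation: the scheduled air
#' concentration if `t` lies inside an exposure window (including its
#' left edge, excluding its right edge), 0 otherwise.
#'
#' @param schedule an [make_scenario()] schedule.
#' @param t time (h), vectorized.
#' @return air concentration(s), mg/L.
#' @export
forcing_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  w <- schedule$windows
  vapply(t, function(ti) {
    hit <- which(w$start <= ti & ti < w$end)
    if (length(hit)) w$level[hit[1L]] else 0
  }, numeric(1))
}

#' Export a schedule's bolus events as CSV
#'
#' @param schedule an `exposure_schedule`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  ev <- schedule$events
  names(ev) <- c("time", "target_state", "increment")
  utils::write.csv(ev, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.exposure_schedule <- function(x, ...) {
  cat("<exposure_schedule> scenario", x$kind, "(", x$route, ")",
      "over", x$duration, "h\n")
  if (nrow(x$windows))
    cat(" ", nrow(x$windows), "exposure window(s) at", x$dose_level, "mg/L\n")
  if (x$background_rate > 0)
    cat("  continuous stomach delivery", x$background_rate, "mg/h\n")
  if (nrow(x$events))
    cat(" ", nrow(x$events), "bolus event(s) of", x$dose_level, "mg\n")
  invisible(x)
}
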