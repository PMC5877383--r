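#' Vehicle state for the telecar simulator
#'
#' Pose on the plane plus the control mode used by the state-machine
#' paradigm. Heading follows the mathematical convention (degrees
#' counter-clockwise from +x, normalized to `[0, 360)`); translations are
#' fixed 12 cm quanta and rotations fixed 45 degree quanta.
#'
#' @param x,y position in cm.
#' @param heading degrees in `[0, 360)`.
#' @param mode `"straight"` or `"rotation"` (state-machine paradigm only).
#' @return a `vehicle_state`.
#' @export
vehicle_state <- function(x = 0, y = 0, heading = 90, mode = "straight") {
  structure(list(x = x, y = y, heading = heading %% 360, mode = mode,
                 stopped = FALSE),
            class = "vehicle_state")
}

#' @export
print.vehicle_state <- function(x, ...) {
  cat(sprintf("<vehicle_state> (%.1f, %.1f) heading %g deg, mode %s%s\n",
              x$x, x$y, x$heading, x$mode, if (x$stopped) " [stopped]" else ""))
  invisible(x)
}

#' Advance the vehicle by one command
#'
#' `forward`/`backward` translate +/-12 cm along the heading, `cw`/`ccw`
#' rotate -/+45 degrees, `stop` holds the pose.
#'
#' @param state a [vehicle_state()].
#' @param command one of `"forward"`, `"backward"`, `"cw"`, `"ccw"`,
#'   `"stop"`.
#' @param step_cm translation quantum, default 12.
#' @param turn_deg rotation quantum, default 45.
#' @return the updated `vehicle_state`.
#' @export
step_vehicle <- function(state, command, step_cm = 12, turn_deg = 45) {
  stopifnot(inherits(state, "vehicle_state"))
  rad <- state$heading * pi / 180
  state$stopped <- FALSE
  switch(command,
    forward = { state$x <- state$x + step_cm * cos(rad)
                state$y <- state$y + step_cm * sin(rad) },
    backward = { state$x <- state$x - step_cm * cos(rad)
                 state$y <- state$y - step_cm * sin(rad) },
    cw = state$heading <- (state$heading - turn_deg) %% 360,
    ccw = state$heading <- (state$heading + turn_deg) %% 360,
    stop = state$stopped <- TRUE,
    stop("unknown command: ", command))
  state
}

#' Map for the telecar course
#'
#' @param side_cm side of the square course, default 40.
#' @param loops number of loops to complete, default 2.
#' @param obstacles list of `c(xmin, xmax, ymin, ymax)` rectangles (cm); a
#'   translation ending inside an obstacle is refused (logged as a
#'   collision-avoidance stop).
#' @return a `telecar_map`.
#' @export
map_config <- function(side_cm = 40, loops = 2, obstacles = list()) {
  structure(list(side_cm = side_cm, loops = loops, obstacles = obstacles),
            class = "telecar_map")
}

#' Control-paradigm configuration
#'
#' Paradigm 2 (fixed moving): a command is issued only when two
#' consecutive analysis windows classify identically; rest maps to
#' backward. Paradigm 3 (channel combination): a command is issued when
#' both channels classify identically, otherwise the vehicle stops.
#' Paradigm 4 (state machine): relaxing toggles between straight-line and
#' rotation modes (only after at least one motion was executed in the
#' current mode), wrist flexion/extension drive the mode's two motions,
#' and fisting stops.
#'
#' @param paradigm 2, 3 or 4.
#' @param window_ms analysis window, default 125 ms.
#' @param overlap_frac sliding-window overlap, default 0.2.
#' @param linear_speed_cm_s translation speed, default 12 (so one 12 cm
#'   quantum costs 1 s).
#' @param angular_speed_rad_s rotation speed, default `0.25 * pi` (one 45
#'   degree quantum costs 1 s).
#' @param step_cm,turn_deg motion quanta.
#' @param map a [map_config()].
#' @return a `paradigm_config`.
#' @export
paradigm_config <- function(paradigm = 2, window_ms = 125, overlap_frac = 0.2,
                            linear_speed_cm_s = 12,
                            angular_speed_rad_s = 0.25 * pi,
                            step_cm = 12, turn_deg = 45,
                            map = map_config()) {
  if (!paradigm %in% 2:4) stop("paradigm must be 2, 3 or 4")
  if (window_ms <= 0 || linear_speed_cm_s <= 0 || angular_speed_rad_s <= 0)
    stop("window and speeds must be positive")
  structure(list(paradigm = paradigm, window_ms = window_ms,
                 overlap_frac = overlap_frac,
                 linear_speed_cm_s = linear_speed_cm_s,
                 angular_speed_rad_s = angular_speed_rad_s,
                 step_cm = step_cm, turn_deg = turn_deg, map = map),
            class = "paradigm_config")
}

MOTION_MAP <- c(MF = "forward", REST = "backward", WE = "cw", WF = "ccw")

in_obstacle <- function(x, y, obstacles) {
  for (ob in obstacles)
    if (x >= ob[1] && x <= ob[2] && y >= ob[3] && y <= ob[4]) return(TRUE)
  FALSE
}

motion_time <- function(command, config) {
  if (command %in% c("forward", "backward"))
    config$step_cm / config$linear_speed_cm_s
  else if (command %in% c("cw", "ccw"))
    (config$turn_deg * pi / 180) / config$angular_speed_rad_s
  else config$window_ms / 1000
}

#' Run a control paradigm over a stream of classified windows
#'
#' Drives the vehicle from per-window class predictions, applying the
#' paradigm's confirmation rule, and accounts travel time at the
#' configured speeds. For paradigm 2 each recognition window costs its
#' duration and each motion its quantum time; for paradigms 3 and 4
#' recording is concurrent with motion, so only stopped windows cost
#' window time.
#'
#' @param intents for paradigms 2 and 4 a character vector of class labels
#'   (`REST`, `MF`, `WE`, `WF`); for paradigm 3 a 2-column matrix or
#'   data.frame of per-channel labels.
#' @param config a [paradigm_config()].
#' @param state starting [vehicle_state()].
#' @return a `session_metrics` list: `travel_time_s`, `command_log`
#'   (data.frame with one row per window), `trajectory` (poses after each
#'   window), `collisions`, `final_state`, `paradigm`.
#' @export
run_paradigm <- function(intents, config, state = vehicle_state()) {
  stopifnot(inherits(config, "paradigm_config"))
  p <- config$paradigm
  if (p == 3) {
    intents <- as.matrix(intents)
    if (ncol(intents) != 2) stop("paradigm 3 needs a 2-column intent stream")
    labs <- intents
  } else {
    labs <- matrix(as.character(intents), ncol = 1)
  }
  if (!all(labs %in% names(MOTION_MAP)))
    stop("unknown label in stream: ",
         paste(unique(labs[!labs %in% names(MOTION_MAP)]), collapse = ", "))
  n <- nrow(labs)
  time_s <- 0
  collisions <- 0L
  motions_in_mode <- 0L
  prev <- NA_character_
  log <- vector("list", n)
  traj <- vector("list", n)
  for (i in seq_len(n)) {
    cmd <- "stop"
    event <- ""
    if (p == 2) {
      lab <- labs[i, 1]
      if (!is.na(prev) && prev == lab) {
        cmd <- MOTION_MAP[[lab]]
        prev <- NA_character_               # a command consumes its pair
      } else prev <- lab
    } else if (p == 3) {
      if (labs[i, 1] == labs[i, 2]) cmd <- MOTION_MAP[[labs[i, 1]]]
    } else {                                # paradigm 4 state machine
      lab <- labs[i, 1]
      if (lab == "REST") {
        if (motions_in_mode >= 1L) {
          state$mode <- if (state$mode == "straight") "rotation" else "straight"
          motions_in_mode <- 0L
          event <- "mode_switch"
        } else event <- "switch_refused"
      } else if (lab == "MF") {
        cmd <- "stop"
      } else if (state$mode == "straight") {
        cmd <- if (lab == "WF") "forward" else "backward"
      } else {
        cmd <- if (lab == "WF") "ccw" else "cw"
      }
    }
    if (cmd %in% c("forward", "backward")) {
      trial <- step_vehicle(state, cmd, config$step_cm, config$turn_deg)
      if (in_obstacle(trial$x, trial$y, config$map$obstacles)) {
        collisions <- collisions + 1L
        event <- "collision_avoided"
        cmd <- "stop"
      }
    }
    state <- step_vehicle(state, cmd, config$step_cm, config$turn_deg)
    if (cmd != "stop" && p == 4) motions_in_mode <- motions_in_mode + 1L
    # time accounting: paradigm 2 pays for every window plus the motion;
    # paradigms 3/4 record concurrently, paying window time only at rest
    time_s <- time_s + if (p == 2) {
      config$window_ms / 1000 + if (cmd == "stop") 0 else motion_time(cmd, config)
    } else {
      if (cmd == "stop") config$window_ms / 1000 else motion_time(cmd, config)
    }
    log[[i]] <- data.frame(window = i,
                           intent = paste(labs[i, ], collapse = "/"),
                           command = cmd, event = event, time_s = time_s,
                           stringsAsFactors = FALSE)
    traj[[i]] <- data.frame(window = i, x = state$x, y = state$y,
                            heading = state$heading, mode = state$mode)
  }
  structure(list(travel_time_s = time_s,
                 command_log = do.call(rbind, log),
                 trajectory = do.call(rbind, traj),
                 collisions = collisions, final_state = state, paradigm = p),
            class = "session_metrics")
}

#' @export
print.session_metrics <- function(x, ...) {
  cat(sprintf("<session_metrics> paradigm %d: %.2f s travel time, %d command windows, %d collisions avoided\n",
              x$paradigm, x$travel_time_s, nrow(x$command_log), x$collisions))
  invisible(x)
}

#' Kinematic lower bound on course completion time
#'
#' Time to trace the route with no recognition overhead: path length over
#' linear speed plus total rotation over angular speed. For a square map
#' the path is `loops * 4 * side` and the rotation `loops * 4` right-angle
#' turns.
#'
#' @param map a [map_config()]; ignored when `path_cm` is given.
#' @param path_cm,turns_deg explicit path length (cm) and total rotation
#'   (degrees), overriding the map geometry.
#' @param linear_speed_cm_s,angular_speed_rad_s speeds as in
#'   [paradigm_config()].
#' @return seconds.
#' @examples
#' ideal_route_time(map_config(40, 2))  # ~42.67 s
#' @export
ideal_route_time <- function(map = map_config(), path_cm = NULL,
                             turns_deg = NULL, linear_speed_cm_s = 12,
                             angular_speed_rad_s = 0.25 * pi) {
  if (linear_speed_cm_s <= 0 || angular_speed_rad_s <= 0)
    stop("speeds must be positive")
  if (is.null(path_cm)) {
    path_cm <- map$loops * 4 * map$side_cm
    turns_deg <- map$loops * 4 * 90
  }
  if (is.null(turns_deg)) turns_deg <- 0
  path_cm / linear_speed_cm_s +
    (turns_deg * pi / 180) / angular_speed_rad_s
}

#' Recognition rate of a control session
#'
#' Paradigm 2: the fraction of windows classified as the prompted
#' movement. Paradigm 3: the fraction of recognition windows in which
#' both channels agree (and, when ground truth is supplied, agree with
#' it). Paradigm 4 has no defined recognition rate (subjects steer by
#' intention), so `NA` is returned.
#'
#' @param predictions label vector (paradigm 2) or 2-column matrix
#'   (paradigm 3).
#' @param truth optional ground-truth intent labels.
#' @param paradigm 2, 3 or 4.
#' @return percentage in `[0, 100]`, or `NA` for paradigm 4.
#' @export
recognition_rate <- function(predictions, truth = NULL, paradigm = 2) {
  if (paradigm == 4) return(NA_real_)
  if (paradigm == 3) {
    predictions <- as.matrix(predictions)
    if (ncol(predictions) != 2) stop("paradigm 3 needs 2 channels")
    agree <- predictions[, 1] == predictions[, 2]
    if (is.null(truth)) return(100 * mean(agree))
    if (length(truth) != nrow(predictions)) stop("length mismatch")
    return(100 * mean(agree & predictions[, 1] == truth))
  }
  if (is.null(truth)) stop("paradigm 2 recognition rate needs ground truth")
  if (length(truth) != length(predictions)) stop("length mismatch")
  100 * mean(predictions == truth)
}
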