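#' Closed-loop soundscape engine
#'
#' The engine turns the animal's tracked position into the tone command the
#' speaker would play. During habituation no tone is delivered regardless of
#' position; during exposure the tone is the one assigned to the role of the
#' quadrant the animal occupies, with the silent role (Q1) mapping to no
#' sound. A quadrant change takes effect only after two consecutive frames in
#' the new quadrant (100 ms at 20 fps), which suppresses tone flicker from
#' centroid jitter at the virtual boundaries. On tracking dropouts the engine
#' holds the last confirmed quadrant.
#'
#' @param debounce_frames Consecutive frames required to confirm a quadrant
#'   change (default 2).
#' @return `engine_init()` returns an opaque engine state list.
#' @seealso [run_session()] to replay a whole trajectory.
#' @export
engine_init <- function(debounce_frames = 2) {
  list(active_role = NA_character_, pending_role = NA_character_,
       pending_n = 0L, last_time = -Inf, debounce_frames = debounce_frames)
}

#' Advance the engine by one frame
#'
#' @param x,y Centroid position in cm, or `NA` on a tracking dropout.
#' @param time_s Session time of the frame; must be non-decreasing across
#'   calls.
#' @param schedule A [phase_schedule()].
#' @param assignment A [soundscape_assignment()].
#' @param state Engine state from [engine_init()] or a previous step.
#' @param arena An [arena_spec()].
#' @return A list `(command, state)`. `command` is `NULL` when nothing
#'   changed, otherwise a list with `time_s`, `tone` (a [tone_spec()]),
#'   and `cause` (the confirmed role label).
#' @export
engine_step <- function(x, y, time_s, schedule, assignment, state,
                        arena = arena_spec()) {
  if (time_s < state$last_time)
    stop(sprintf("time regression: %g s after %g s", time_s, state$last_time),
         call. = FALSE)
  state$last_time <- time_s
  p2r <- physical_to_role(assignment)
  if (!is.na(x) && !is.na(y)) {
    role <- p2r[[assign_quadrant(x, y, arena)]]
    if (is.na(state$active_role)) {
      state$active_role <- role          # first fix confirms immediately
      state$pending_n <- 0L
    } else if (identical(role, state$active_role)) {
      state$pending_n <- 0L
      state$pending_role <- NA_character_
    } else {
      if (identical(role, state$pending_role)) {
        state$pending_n <- state$pending_n + 1L
      } else {
        state$pending_role <- role
        state$pending_n <- 1L
      }
      if (state$pending_n >= state$debounce_frames) {
        state$active_role <- state$pending_role
        state$pending_role <- NA_character_
        state$pending_n <- 0L
      }
    }
  }
  # dropout: hold last confirmed quadrant
  cause <- state$active_role
  tone <- if (is.na(cause) || time_s < schedule$habituation_s)
    tone_spec("silence") else assignment$role_to_tone[[cause]]
  list(command = list(time_s = time_s, tone = tone, cause = cause),
       state = state)
}

#' Replay a trajectory through the closed-loop engine
#'
#' Steps the engine over every frame and records the tone-command
#' transitions: the event log holds only changes (in tone or confirmed
#' quadrant), starting with silence at the first frame. Replay is a pure
#' function of its inputs, so a logged session can be reproduced exactly.
#'
#' @param traj An [trajectory()] covering the full schedule.
#' @param schedule A [phase_schedule()].
#' @param assignment A [soundscape_assignment()].
#' @param arena An [arena_spec()].
#' @param debounce_frames See [engine_init()].
#' @return A data.frame of class `sa_event_log` with columns `time_s`,
#'   `role`, `frequency_khz` (NA for silence) and `spl_db` (NA for silence);
#'   the assignment is attached as an attribute.
#' @export
run_session <- function(traj, schedule, assignment, arena = arena_spec(),
                        debounce_frames = 2) {
  span <- traj$time_s[nrow(traj)] - traj$time_s[1]
  need <- total_duration_s(schedule) - 1 / traj_fps(traj) - 1e-9
  if (span < need)
    stop(sprintf("trajectory (%.1f s) shorter than schedule (%.0f s)",
                 span, total_duration_s(schedule)), call. = FALSE)
  state <- engine_init(debounce_frames)
  n <- nrow(traj)
  times <- numeric(n); roles <- character(n)
  freqs <- numeric(n); spls <- numeric(n)
  k <- 0L
  last_freq <- NA_real_; last_role <- NA_character_
  xs <- ifelse(traj$valid, traj$x_cm, NA_real_)
  ys <- ifelse(traj$valid, traj$y_cm, NA_real_)
  for (i in seq_len(n)) {
    res <- engine_step(xs[i], ys[i], traj$time_s[i], schedule, assignment,
                       state, arena)
    state <- res$state
    cmd <- res$command
    f <- if (is_silence(cmd$tone)) NA_real_ else cmd$tone$frequency_khz
    if (i == 1L || !identical(f, last_freq) ||
        !identical(cmd$cause, last_role)) {
      k <- k + 1L
      times[k] <- cmd$time_s
      roles[k] <- if (is.na(cmd$cause)) NA_character_ else cmd$cause
      freqs[k] <- f
      spls[k] <- if (is_silence(cmd$tone)) NA_real_ else cmd$tone$spl_db
      last_freq <- f; last_role <- cmd$cause
    }
  }
  log <- data.frame(time_s = times[seq_len(k)], role = roles[seq_len(k)],
                    frequency_khz = freqs[seq_len(k)],
                    spl_db = spls[seq_len(k)])
  attr(log, "assignment") <- assignment
  class(log) <- c("sa_event_log", "data.frame")
  log
}

#' Write an engine event log as CSV
#'
#' Columns `time_s, role, frequency_khz, spl_db`; frequency and SPL are
#' empty for silence.
#'
#' @param log An `sa_event_log` from [run_session()].
#' @param path Output CSV path.
#' @export
write_event_log <- function(log, path) {
  df <- as.data.frame(log)
  df$frequency_khz <- ifelse(is.na(df$frequency_khz), "", df$frequency_khz)
  df$spl_db <- ifelse(is.na(df$spl_db), "", df$spl_db)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Per-frame active (debounced) role over a trajectory; used internally by the
# simulator so the agent reacts to the same tone state the engine would emit.
debounced_roles <- function(traj, schedule, assignment, arena,
                            debounce_frames = 2) {
  state <- engine_init(debounce_frames)
  n <- nrow(traj)
  out <- character(n)
  xs <- ifelse(traj$valid, traj$x_cm, NA_real_)
  ys <- ifelse(traj$valid, traj$y_cm, NA_real_)
  for (i in seq_len(n)) {
    res <- engine_step(xs[i], ys[i], traj$time_s[i], schedule, assignment,
                       state, arena)
    state <- res$state
    out[i] <- if (is.na(res$command$cause)) NA_character_ else
      res$command$cause
  }
  out
}
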