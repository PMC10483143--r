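#' Agent model parameters
#'
#' Generative parameters of the simulated mouse: a discrete-time correlated
#' random walk whose heading can be re-oriented toward the silent quadrant
#' while a tone is audible. Speeds are per-frame gamma draws with mean
#' `mean_speed_cm_s / fps`; heading persistence comes from a wrapped-normal
#' turning kernel. Avoidance is a per-second probability of re-orienting
#' toward the silent quadrant's centroid while a tone plays, activating
#' `onset_latency_s` after the first tone exposure (an unbiased wild-type
#' profile has `avoidance_strength = 0`).
#'
#' @param mean_speed_cm_s Mean speed (cm/s).
#' @param speed_shape Gamma shape of the per-frame step-length distribution.
#' @param turn_sd_rad Per-frame heading perturbation SD (radians).
#' @param avoidance_strength Per-second reorientation probability in \[0, 1\].
#' @param onset_latency_s Seconds after first tone exposure before avoidance
#'   activates.
#' @param seed Integer seed; trajectories are deterministic given it.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(mean_speed_cm_s = 4, speed_shape = 2,
                         turn_sd_rad = 0.3, avoidance_strength = 0,
                         onset_latency_s = 0, seed = 1) {
  stopifnot(mean_speed_cm_s > 0, speed_shape > 0, turn_sd_rad >= 0,
            avoidance_strength >= 0, avoidance_strength <= 1,
            onset_latency_s >= 0)
  structure(list(mean_speed_cm_s = mean_speed_cm_s, speed_shape = speed_shape,
                 turn_sd_rad = turn_sd_rad,
                 avoidance_strength = avoidance_strength,
                 onset_latency_s = onset_latency_s, seed = seed),
            class = "agent_params")
}

#' Simulate one agent session
#'
#' Correlated random walk at the camera frame rate, starting at the arena
#' center (where the animal is placed), with reflective walls. The
#' closed-loop engine's debounced quadrant logic runs inline, so the agent
#' reacts to exactly the tone state the engine would emit: while a tone is
#' on and the session time exceeds the first tone exposure plus the onset
#' latency, the heading is reset toward the silent quadrant's centroid
#' (plus noise) with probability `avoidance_strength / fps` per frame.
#'
#' @param params An [agent_params()].
#' @param arena An [arena_spec()].
#' @param schedule A [phase_schedule()].
#' @param assignment A [soundscape_assignment()].
#' @param duration_s Simulated length in seconds (default the full
#'   schedule). Shorter runs are useful for habituation-only studies.
#' @param debounce_frames Engine debounce (see [engine_init()]).
#' @return An [trajectory()] at the arena frame rate, all frames valid.
#' @export
simulate_agent <- function(params, arena = arena_spec(),
                           schedule = phase_schedule(),
                           assignment = soundscape_assignment(),
                           duration_s = NULL, debounce_frames = 2) {
  stopifnot(inherits(params, "agent_params"))
  fps <- arena$fps
  duration_s <- duration_s %||% total_duration_s(schedule)
  n <- round(duration_s * fps)
  W <- arena$width_cm; H <- arena$height_cm
  p2r <- physical_to_role(assignment)
  silent_q <- assignment$role_to_physical[["Q1"]]
  sc <- quadrant_centroid(silent_q, arena)
  with_preserved_seed(params$seed, {
    turns <- stats::rnorm(n, 0, params$turn_sd_rad)
    steps <- stats::rgamma(n, shape = params$speed_shape,
                           scale = params$mean_speed_cm_s /
                             (fps * params$speed_shape))
    avoid_draw <- stats::runif(n) < params$avoidance_strength / fps
    avoid_noise <- stats::rnorm(n, 0, 0.3)
    heading0 <- stats::runif(1, 0, 2 * pi)
  })
  x <- numeric(n); y <- numeric(n)
  cx <- W / 2; cy <- H / 2
  heading <- heading0
  # inline debounce state (physical quadrant labels)
  active_q <- NA_character_; pending_q <- NA_character_; pending_n <- 0L
  first_tone <- NA_real_
  hab <- schedule$habituation_s
  for (i in seq_len(n)) {
    t <- (i - 1) / fps
    x[i] <- cx; y[i] <- cy
    # debounced quadrant update
    q <- QUADRANT_LABELS[1L + (cx >= W / 2) + 2L * (cy >= H / 2)]
    if (is.na(active_q)) {
      active_q <- q
    } else if (q != active_q) {
      if (identical(q, pending_q)) pending_n <- pending_n + 1L
      else { pending_q <- q; pending_n <- 1L }
      if (pending_n >= debounce_frames) {
        active_q <- pending_q; pending_q <- NA_character_; pending_n <- 0L
      }
    } else { pending_q <- NA_character_; pending_n <- 0L }
    tone_on <- t >= hab && active_q != silent_q
    if (tone_on && is.na(first_tone)) first_tone <- t
    heading <- heading + turns[i]
    if (tone_on && avoid_draw[i] && !is.na(first_tone) &&
        t >= first_tone + params$onset_latency_s) {
      heading <- atan2(sc[2] - cy, sc[1] - cx) + avoid_noise[i]
    }
    nx <- cx + steps[i] * cos(heading)
    ny <- cy + steps[i] * sin(heading)
    if (nx < 0) { nx <- -nx; heading <- pi - heading }
    if (nx > W) { nx <- 2 * W - nx; heading <- pi - heading }
    if (ny < 0) { ny <- -ny; heading <- -heading }
    if (ny > H) { ny <- 2 * H - ny; heading <- -heading }
    cx <- nx; cy <- ny
  }
  trajectory(time_s = (seq_len(n) - 1) / fps, x_cm = x, y_cm = y,
             valid = TRUE, fps = fps)
}

#' Dwell-process model parameters
#'
#' A quadrant-level dwell process with exact control of the long-run
#' occupancy: role residencies are exponential with mean `mean_dwell_s` and
#' successive roles are drawn independently from `occupancy`, so the
#' stationary role distribution equals the requested vector. Within a role
#' the position performs a small bounded random walk inside the role's
#' physical quadrant. Used for estimator-recovery tests where the generative
#' occupancy must be known exactly.
#'
#' @param occupancy Named (Q1-Q4) or unnamed length-4 vector on the simplex.
#' @param mean_dwell_s Mean quadrant residency (s).
#' @param step_sd_cm Within-quadrant walk step SD (cm/frame).
#' @param seed Integer seed.
#' @return A list of class `dwell_params`.
#' @export
dwell_params <- function(occupancy = c(Q1 = 0.25, Q2 = 0.25, Q3 = 0.25,
                                       Q4 = 0.25),
                         mean_dwell_s = 15, step_sd_cm = 1, seed = 1) {
  occupancy <- as.numeric(occupancy)
  if (length(occupancy) != 4 || any(occupancy < 0))
    stop("occupancy must be four non-negative weights", call. = FALSE)
  if (abs(sum(occupancy) - 1) > 1e-8)
    stop("occupancy must sum to 1", call. = FALSE)
  stopifnot(mean_dwell_s > 0, step_sd_cm > 0)
  structure(list(occupancy = stats::setNames(occupancy, ROLE_LABELS),
                 mean_dwell_s = mean_dwell_s, step_sd_cm = step_sd_cm,
                 seed = seed),
            class = "dwell_params")
}

#' Simulate a session from the dwell process
#'
#' @param params A [dwell_params()].
#' @param arena An [arena_spec()].
#' @param schedule A [phase_schedule()].
#' @param assignment A [soundscape_assignment()].
#' @param duration_s Simulated length (default the full schedule).
#' @return An [trajectory()], all frames valid.
#' @export
simulate_dwell <- function(params, arena = arena_spec(),
                           schedule = phase_schedule(),
                           assignment = soundscape_assignment(),
                           duration_s = NULL) {
  stopifnot(inherits(params, "dwell_params"))
  fps <- arena$fps
  duration_s <- duration_s %||% total_duration_s(schedule)
  n <- round(duration_s * fps)
  W <- arena$width_cm; H <- arena$height_cm
  hw <- W / 2; hh <- H / 2
  with_preserved_seed(params$seed, {
    n_seg <- ceiling(3 * duration_s / params$mean_dwell_s) + 20
    repeat {
      dwell <- stats::rexp(n_seg, rate = 1 / params$mean_dwell_s)
      if (sum(dwell) >= duration_s) break
      n_seg <- 2 * n_seg
    }
    seg_role <- sample(ROLE_LABELS, n_seg, replace = TRUE,
                       prob = params$occupancy)
    ux <- hw / 2 + cumsum(stats::rnorm(n, 0, params$step_sd_cm))
    uy <- hh / 2 + cumsum(stats::rnorm(n, 0, params$step_sd_cm))
  })
  times <- (seq_len(n) - 1) / fps
  role_idx <- findInterval(times, cumsum(c(0, dwell)))
  roles <- seg_role[role_idx]
  quad <- unname(assignment$role_to_physical[roles])
  # fold one latent walk into the active quadrant's half-box
  fx <- pmin(reflect_into(ux, hw), hw * (1 - 1e-12))
  fy <- pmin(reflect_into(uy, hh), hh * (1 - 1e-12))
  x <- fx + ifelse(quad %in% c("B", "D"), hw, 0)
  y <- fy + ifelse(quad %in% c("C", "D"), hh, 0)
  trajectory(time_s = times, x_cm = x, y_cm = y, valid = TRUE, fps = fps)
}

#' Render synthetic grayscale frames from a trajectory
#'
#' Draws a Gaussian intensity blob (peak 1) at each trajectory position on a
#' dark background, plus optional white noise — the ground-truth input for
#' exercising the centroid tracker. Frames are oriented `[x, y]` with a
#' pixel's coordinate equal to its index (see [extract_centroid()]).
#'
#' @param traj An [trajectory()] (cm coordinates).
#' @param arena An [arena_spec()] with `px_per_cm` set.
#' @param blob_sd_px Blob SD in pixels.
#' @param noise_sd Additive Gaussian noise SD (signal peak is 1).
#' @param seed Seed for the noise.
#' @return A list: `frames` (list of matrices) and `truth_px` (data.frame
#'   of ground-truth pixel positions).
#' @export
render_frames <- function(traj, arena, blob_sd_px = 3, noise_sd = 0,
                          seed = 1) {
  if (is.null(arena$px_per_cm))
    stop("rendering requires px_per_cm calibration", call. = FALSE)
  ppc <- arena$px_per_cm
  nx <- round(arena$width_cm * ppc); ny <- round(arena$height_cm * ppc)
  x0 <- traj$x_cm * ppc; y0 <- traj$y_cm * ppc
  if (any(traj$valid & (x0 < 1 | x0 > nx | y0 < 1 | y0 > ny)))
    stop("blob center falls off the pixel canvas", call. = FALSE)
  ix <- seq_len(nx); iy <- seq_len(ny)
  with_preserved_seed(seed, {
    frames <- lapply(seq_len(nrow(traj)), function(i) {
      f <- if (traj$valid[i])
        outer(exp(-(ix - x0[i])^2 / (2 * blob_sd_px^2)),
              exp(-(iy - y0[i])^2 / (2 * blob_sd_px^2)))
      else matrix(0, nx, ny)
      if (noise_sd > 0)
        f <- f + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
      f
    })
  })
  list(frames = frames,
       truth_px = data.frame(x_px = x0, y_px = y0, valid = traj$valid))
}

#' Built-in simulation profiles
#'
#' Reads the packaged profile file (`inst/extdata/profiles.yaml`): a
#' `wt`-like unbiased agent and a `ko`-like avoider whose defaults place
#' silent-quadrant exposure occupancy in the mid-40s percent range. The
#' tuning constants live in the config file, not in code.
#'
#' @param name `"wt"` or `"ko"` (or any profile present in the file).
#' @param seed Seed to stamp on the returned params.
#' @return An [agent_params()].
#' @export
load_profile <- function(name, seed = 1) {
  path <- system.file("extdata", "profiles.yaml", package = "soundarena")
  prof <- yaml::read_yaml(path)
  if (!name %in% names(prof))
    stop("unknown profile: ", name, " (have: ",
         paste(names(prof), collapse = ", "), ")", call. = FALSE)
  p <- prof[[name]]
  agent_params(mean_speed_cm_s = p$mean_speed_cm_s,
               speed_shape = p$speed_shape,
               turn_sd_rad = p$turn_sd_rad,
               avoidance_strength = p$avoidance_strength,
               onset_latency_s = p$onset_latency_s, seed = seed)
}

#' Simulate a paired WT/KO cohort
#'
#' One counterbalanced soundscape assignment per animal pair, shared by the
#' pair's WT and KO sessions (tone placement is kept constant within a pair
#' and randomized between pairs); per-session seeds are fanned out from the
#' master seed so cohort size changes never reshuffle earlier sessions.
#'
#' @param n_per_genotype Animals per genotype (= number of pairs).
#' @param wt_params,ko_params [agent_params()] templates (their `seed` is
#'   replaced per session).
#' @param arena,schedule As elsewhere.
#' @param seed Master seed.
#' @param tones_khz,spl_db Tone condition (default ultrasound at 70 dB SPL).
#' @return A list of class `sa_cohort` of sessions; each session is a list
#'   `(pair, genotype, assignment, traj)`.
#' @export
simulate_cohort <- function(n_per_genotype, wt_params, ko_params,
                            arena = arena_spec(),
                            schedule = phase_schedule(), seed = 1,
                            tones_khz = ULTRASOUND_KHZ, spl_db = 70) {
  stopifnot(n_per_genotype >= 1)
  assignments <- counterbalance_assignments(n_per_genotype,
                                            seed = child_seed(seed, 1),
                                            tones_khz = tones_khz,
                                            spl_db = spl_db)
  sessions <- list()
  for (i in seq_len(n_per_genotype)) {
    for (g in c("WT", "KO")) {
      p <- if (g == "WT") wt_params else ko_params
      p$seed <- child_seed(seed, 2 * i + (g == "KO"))
      traj <- simulate_agent(p, arena, schedule, assignments[[i]])
      sessions[[length(sessions) + 1]] <-
        list(pair = i, genotype = g, assignment = assignments[[i]],
             traj = traj)
    }
  }
  structure(sessions, class = c("sa_cohort", "list"))
}

#' Tidy per-session metrics for a cohort
#'
#' Runs occupancy (both phases) and the preference index on every session
#' and returns one row per session x phase x role, ready for the
#' statistical battery.
#'
#' @param cohort An `sa_cohort` from [simulate_cohort()].
#' @param schedule,arena As used to simulate.
#' @return A data.frame with columns `pair`, `genotype`, `phase`, `role`,
#'   `fraction`, `pref_index`.
#' @export
cohort_metrics <- function(cohort, schedule = phase_schedule(),
                           arena = arena_spec()) {
  rows <- lapply(cohort, function(s) {
    hab <- occupancy(s$traj, s$assignment, c(0, schedule$habituation_s),
                     arena, "habituation")
    expo <- occupancy(s$traj, s$assignment,
                      c(schedule$habituation_s, total_duration_s(schedule)),
                      arena, "exposure")
    pref <- preference_index(expo, hab)
    rbind(
      data.frame(pair = s$pair, genotype = s$genotype, phase = "habituation",
                 role = ROLE_LABELS, fraction = as.numeric(hab$fraction),
                 pref_index = NA_real_),
      data.frame(pair = s$pair, genotype = s$genotype, phase = "exposure",
                 role = ROLE_LABELS, fraction = as.numeric(expo$fraction),
                 pref_index = as.numeric(pref)))
  })
  do.call(rbind, rows)
}
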