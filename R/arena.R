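#' Arena geometry and calibration
#'
#' Describes the open-field arena used by the sound-arena assay: a square
#' (default 44 x 44 cm) box filmed from above at a fixed frame rate.
#' Coordinates are in cm with the origin at the lower-left corner and y
#' increasing upward. If the tracker emits pixel coordinates, `px_per_cm`
#' supplies the linear calibration (see [pixel_to_cm()]).
#'
#' @param width_cm,height_cm Arena floor dimensions in cm.
#' @param wall_height_cm Wall height in cm (informational only).
#' @param fps Camera frame rate in frames per second.
#' @param px_per_cm Optional pixels-per-cm calibration; `NULL` means inputs
#'   are already in cm.
#' @return An object of class `arena_spec`.
#' @examples
#' arena_spec()                  # the default 44 x 44 cm arena at 20 fps
#' arena_spec(px_per_cm = 10)    # pixel-calibrated variant
#' @export
arena_spec <- function(width_cm = 44, height_cm = 44, wall_height_cm = 30,
                       fps = 20, px_per_cm = NULL) {
  stopifnot(width_cm > 0, height_cm > 0, fps > 0)
  if (!is.null(px_per_cm) && px_per_cm <= 0)
    stop("px_per_cm must be positive when supplied", call. = FALSE)
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 wall_height_cm = wall_height_cm, fps = fps,
                 px_per_cm = px_per_cm),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g x %g cm, %g fps%s\n", x$width_cm, x$height_cm,
              x$fps,
              if (is.null(x$px_per_cm)) "" else
                sprintf(", %g px/cm", x$px_per_cm)))
  invisible(x)
}

# Physical quadrant labels: A lower-left, B lower-right, C upper-left,
# D upper-right.
QUADRANT_LABELS <- c("A", "B", "C", "D")

# Quadrant roles: Q1 silence, Q2-Q4 tone-associated.
ROLE_LABELS <- c("Q1", "Q2", "Q3", "Q4")

AUDIBLE_KHZ <- c(8, 12, 16)
ULTRASOUND_KHZ <- c(20, 24, 28)

#' Tone specification
#'
#' A pure tone at one of the frequencies used in the assay, or silence.
#' Audible-range tones are 8/12/16 kHz; ultrasound tones are 20/24/28 kHz.
#' Sound pressure level must lie in the 50-80 dB SPL range the paradigm
#' covers; silence carries no SPL.
#'
#' @param frequency_khz `"silence"` or one of 8, 12, 16, 20, 24, 28.
#' @param spl_db Sound pressure level in dB SPL, in \[50, 80\]. Must be
#'   absent for silence.
#' @return An object of class `tone_spec`.
#' @export
tone_spec <- function(frequency_khz, spl_db = NULL) {
  if (identical(frequency_khz, "silence")) {
    if (!is.null(spl_db))
      stop("silence has no sound pressure level", call. = FALSE)
    return(structure(list(frequency_khz = "silence", spl_db = NULL),
                     class = "tone_spec"))
  }
  frequency_khz <- as.numeric(frequency_khz)
  if (!frequency_khz %in% c(AUDIBLE_KHZ, ULTRASOUND_KHZ))
    stop("frequency_khz must be 'silence' or one of 8, 12, 16, 20, 24, 28",
         call. = FALSE)
  if (is.null(spl_db) || spl_db < 50 || spl_db > 80)
    stop("spl_db must lie in [50, 80] dB SPL", call. = FALSE)
  structure(list(frequency_khz = frequency_khz, spl_db = spl_db),
            class = "tone_spec")
}

#' @export
print.tone_spec <- function(x, ...) {
  if (identical(x$frequency_khz, "silence")) cat("<tone_spec> silence\n")
  else cat(sprintf("<tone_spec> %g kHz @ %g dB SPL\n",
                   x$frequency_khz, x$spl_db))
  invisible(x)
}

is_silence <- function(tone) identical(tone$frequency_khz, "silence")

#' Phase schedule
#'
#' The session timeline: a habituation phase with no sound delivery
#' regardless of position, followed by the sound-exposure phase. Defaults
#' are 5 min habituation plus 30 min exposure (35 min total).
#'
#' @param habituation_s Habituation duration in seconds (>= 0).
#' @param exposure_s Exposure duration in seconds (> 0).
#' @return An object of class `phase_schedule`.
#' @export
phase_schedule <- function(habituation_s = 300, exposure_s = 1800) {
  stopifnot(habituation_s >= 0, exposure_s > 0)
  structure(list(habituation_s = habituation_s, exposure_s = exposure_s),
            class = "phase_schedule")
}

total_duration_s <- function(schedule)
  schedule$habituation_s + schedule$exposure_s

#' Soundscape assignment
#'
#' Maps quadrant roles to physical quadrants and to tones. Role Q1 is always
#' silent; roles Q2-Q4 carry tones sharing one SPL within a session. The
#' physical placement of roles is what gets counterbalanced between animal
#' pairs; all analysis is reported in role space.
#'
#' @param role_to_physical Named character vector, names `Q1..Q4`, values a
#'   permutation of `A, B, C, D`.
#' @param tones_khz Frequencies for Q2, Q3, Q4 in order (default the
#'   ultrasound set 20/24/28 kHz).
#' @param spl_db Shared SPL for the three tones (default 70 dB SPL, the
#'   ultrasound-condition level; the audible condition used 50 dB SPL).
#' @return An object of class `soundscape_assignment` with elements
#'   `role_to_physical` and `role_to_tone`.
#' @export
soundscape_assignment <- function(role_to_physical = c(Q1 = "A", Q2 = "B",
                                                       Q3 = "C", Q4 = "D"),
                                  tones_khz = ULTRASOUND_KHZ, spl_db = 70) {
  role_to_physical <- role_to_physical[ROLE_LABELS]
  if (anyNA(role_to_physical) ||
      !setequal(role_to_physical, QUADRANT_LABELS))
    stop("role_to_physical must be a bijection Q1..Q4 -> A,B,C,D",
         call. = FALSE)
  if (length(tones_khz) != 3L)
    stop("exactly three tone frequencies are required (roles Q2-Q4)",
         call. = FALSE)
  role_to_tone <- c(list(Q1 = tone_spec("silence")),
                    stats::setNames(lapply(tones_khz, tone_spec, spl_db = spl_db),
                                    c("Q2", "Q3", "Q4")))
  structure(list(role_to_physical = role_to_physical,
                 role_to_tone = role_to_tone),
            class = "soundscape_assignment")
}

#' @export
print.soundscape_assignment <- function(x, ...) {
  cat("<soundscape_assignment>\n")
  for (r in ROLE_LABELS) {
    tone <- x$role_to_tone[[r]]
    lab <- if (is_silence(tone)) "silence" else
      sprintf("%g kHz @ %g dB", tone$frequency_khz, tone$spl_db)
    cat(sprintf("  %s -> %s  (%s)\n", r, x$role_to_physical[[r]], lab))
  }
  invisible(x)
}

# Inverse map: physical quadrant label -> role label.
physical_to_role <- function(assignment) {
  stats::setNames(names(assignment$role_to_physical),
                  unname(assignment$role_to_physical))
}

#' Assign arena coordinates to a physical quadrant
#'
#' The arena is split by its vertical and horizontal midlines into four
#' physical quadrants A (lower-left), B (lower-right), C (upper-left) and
#' D (upper-right). Midline ties follow a half-open rule: `x < width/2` is
#' left, `x >= width/2` is right (and likewise for y), so every in-bounds
#' point maps to exactly one quadrant.
#'
#' @param x,y Coordinates in cm (vectorized).
#' @param arena An [arena_spec()].
#' @return Character vector of quadrant labels.
#' @examples
#' a <- arena_spec()
#' assign_quadrant(11, 11, a)   # "A"
#' assign_quadrant(22, 22, a)   # "D": the midline belongs to the upper/right
#' @export
assign_quadrant <- function(x, y, arena = arena_spec()) {
  bad_x <- !is.na(x) & (x < 0 | x > arena$width_cm)
  bad_y <- !is.na(y) & (y < 0 | y > arena$height_cm)
  if (any(bad_x))
    stop(sprintf("x coordinate out of bounds [0, %g]: %g",
                 arena$width_cm, x[bad_x][1]), call. = FALSE)
  if (any(bad_y))
    stop(sprintf("y coordinate out of bounds [0, %g]: %g",
                 arena$height_cm, y[bad_y][1]), call. = FALSE)
  right <- x >= arena$width_cm / 2
  upper <- y >= arena$height_cm / 2
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x) & !is.na(y)
  out[ok] <- QUADRANT_LABELS[1L + right[ok] + 2L * upper[ok]]
  out
}

# Centroid (cm) of a physical quadrant; used by the avoidance reorientation.
quadrant_centroid <- function(label, arena) {
  hw <- arena$width_cm / 2; hh <- arena$height_cm / 2
  switch(label,
         A = c(hw / 2, hh / 2),
         B = c(hw + hw / 2, hh / 2),
         C = c(hw / 2, hh + hh / 2),
         D = c(hw + hw / 2, hh + hh / 2),
         stop("unknown quadrant label: ", label, call. = FALSE))
}

#' Convert pixel coordinates to arena cm
#'
#' Linear scaling by the arena's `px_per_cm` calibration. The origin is the
#' lower-left arena corner and y increases upward in both systems; no image
#' flip is applied.
#'
#' @param x_px,y_px Pixel coordinates (vectorized).
#' @param arena An [arena_spec()] with `px_per_cm` set.
#' @return A list with elements `x_cm` and `y_cm`.
#' @export
pixel_to_cm <- function(x_px, y_px, arena) {
  if (is.null(arena$px_per_cm))
    stop("arena has no px_per_cm calibration; cannot convert pixel input",
         call. = FALSE)
  x_cm <- x_px / arena$px_per_cm
  y_cm <- y_px / arena$px_per_cm
  bad_x <- !is.na(x_cm) & (x_cm < 0 | x_cm > arena$width_cm)
  bad_y <- !is.na(y_cm) & (y_cm < 0 | y_cm > arena$height_cm)
  if (any(bad_x))
    stop(sprintf("x coordinate maps outside arena [0, %g]: %g cm",
                 arena$width_cm, x_cm[bad_x][1]), call. = FALSE)
  if (any(bad_y))
    stop(sprintf("y coordinate maps outside arena [0, %g]: %g cm",
                 arena$height_cm, y_cm[bad_y][1]), call. = FALSE)
  list(x_cm = x_cm, y_cm = y_cm)
}

#' Counterbalanced tone-to-quadrant assignments for animal pairs
#'
#' Draws one soundscape assignment per WT-KO pair. The silent role's physical
#' quadrant is balanced in blocks of four (each block is a random permutation
#' of A-D; a remainder block is sampled without replacement), so the silent
#' quadrant visits every corner as evenly as the pair count allows. By
#' default the three tone roles are also permuted over the remaining
#' quadrants; with `permute_tones = FALSE` only the silent location is
#' randomized and Q2-Q4 fill the remaining quadrants in label order.
#'
#' @param n_pairs Number of animal pairs (>= 1).
#' @param seed Integer seed; output is a deterministic function of it.
#' @param tones_khz,spl_db Tone set and shared level, as in
#'   [soundscape_assignment()].
#' @param permute_tones Permute Q2-Q4 over the non-silent quadrants too?
#' @return A list of `n_pairs` [soundscape_assignment()] objects.
#' @examples
#' a4 <- counterbalance_assignments(4, seed = 1)
#' sapply(a4, function(s) s$role_to_physical[["Q1"]])  # permutation of A-D
#' @export
counterbalance_assignments <- function(n_pairs, seed,
                                       tones_khz = ULTRASOUND_KHZ,
                                       spl_db = 70, permute_tones = TRUE) {
  stopifnot(n_pairs >= 1)
  with_preserved_seed(seed, {
    n_blocks <- ceiling(n_pairs / 4)
    silent <- unlist(lapply(seq_len(n_blocks),
                            function(i) sample(QUADRANT_LABELS)))[seq_len(n_pairs)]
    lapply(seq_len(n_pairs), function(i) {
      others <- setdiff(QUADRANT_LABELS, silent[i])
      if (permute_tones) others <- sample(others)
      soundscape_assignment(
        role_to_physical = stats::setNames(c(silent[i], others), ROLE_LABELS),
        tones_khz = tones_khz, spl_db = spl_db)
    })
  })
}

#' Read and write session configuration files
#'
#' A flat YAML session config records arena dimensions, frame rate, optional
#' calibration, phase durations, the role-to-quadrant map, the role-to-tone
#' map and the seed, which is everything needed to replay or simulate a
#' session.
#'
#' @param path File path.
#' @return `read_session_config()` returns a list with elements `arena`
#'   ([arena_spec()]), `schedule` ([phase_schedule()]), `assignment`
#'   ([soundscape_assignment()]) and `seed`.
#' @export
read_session_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  arena <- arena_spec(width_cm = cfg$arena$width_cm %||% 44,
                      height_cm = cfg$arena$height_cm %||% 44,
                      wall_height_cm = cfg$arena$wall_height_cm %||% 30,
                      fps = cfg$arena$fps %||% 20,
                      px_per_cm = cfg$arena$px_per_cm)
  schedule <- phase_schedule(cfg$schedule$habituation_s %||% 300,
                             cfg$schedule$exposure_s %||% 1800)
  rp <- unlist(cfg$assignment$role_to_physical)
  tones <- cfg$assignment$tones_khz %||% ULTRASOUND_KHZ
  assignment <- soundscape_assignment(
    role_to_physical = rp[ROLE_LABELS],
    tones_khz = as.numeric(tones),
    spl_db = cfg$assignment$spl_db %||% 70)
  list(arena = arena, schedule = schedule, assignment = assignment,
       seed = cfg$seed %||% 1L)
}

#' @rdname read_session_config
#' @param config A list as returned by `read_session_config()`.
#' @export
write_session_config <- function(config, path) {
  a <- config$arena; s <- config$schedule; asg <- config$assignment
  tones <- vapply(asg$role_to_tone[c("Q2", "Q3", "Q4")],
                  function(t) t$frequency_khz, numeric(1))
  out <- list(
    coordinate_convention = "origin lower-left, cm, y up",
    arena = list(width_cm = a$width_cm, height_cm = a$height_cm,
                 wall_height_cm = a$wall_height_cm, fps = a$fps,
                 px_per_cm = a$px_per_cm),
    schedule = list(habituation_s = s$habituation_s,
                    exposure_s = s$exposure_s),
    assignment = list(role_to_physical = as.list(asg$role_to_physical),
                      tones_khz = as.numeric(tones),
                      spl_db = asg$role_to_tone$Q2$spl_db),
    seed = config$seed)
  yaml::write_yaml(out, path)
  invisible(path)
}
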