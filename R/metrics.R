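#' Per-quadrant occupancy over a time window
#'
#' Counts valid frames whose position falls in each quadrant role over the
#' half-open window `[t0, t1)` and converts counts to seconds (frame count
#' times the frame period) and to fractions of the valid time. Dropout
#' frames are excluded from the denominator.
#'
#' @param traj An [trajectory()].
#' @param assignment A [soundscape_assignment()].
#' @param window Numeric `c(t0, t1)` in seconds, half-open.
#' @param arena An [arena_spec()].
#' @param phase Label stored on the result (`"habituation"`/`"exposure"` or
#'   anything descriptive).
#' @return A list of class `sa_occupancy`: `seconds` and `fraction` (named
#'   by role Q1-Q4), `valid_time_s`, `phase`, `window`.
#' @export
occupancy <- function(traj, assignment, window, arena = arena_spec(),
                      phase = "exposure") {
  stopifnot(length(window) == 2, window[2] > window[1])
  sel <- traj$time_s >= window[1] & traj$time_s < window[2] & traj$valid
  if (!any(sel))
    stop(sprintf("no valid frames in window [%g, %g)", window[1], window[2]),
         call. = FALSE)
  p2r <- physical_to_role(assignment)
  roles <- p2r[assign_quadrant(traj$x_cm[sel], traj$y_cm[sel], arena)]
  counts <- table(factor(roles, levels = ROLE_LABELS))
  period <- 1 / traj_fps(traj)
  seconds <- as.numeric(counts) * period
  names(seconds) <- ROLE_LABELS
  structure(list(seconds = seconds, fraction = seconds / sum(seconds),
                 valid_time_s = sum(seconds), phase = phase, window = window),
            class = "sa_occupancy")
}

#' @export
print.sa_occupancy <- function(x, ...) {
  cat(sprintf("<occupancy> phase %s, window [%g, %g) s, valid %g s\n",
              x$phase, x$window[1], x$window[2], x$valid_time_s))
  print(round(100 * x$fraction, 1))
  invisible(x)
}

#' Silent-quadrant time versus mean tone-quadrant time
#'
#' The headline contrast of the assay: the fraction of time in the silent
#' role (Q1) against the arithmetic mean of the three tone-role fractions.
#' Under indifference both are 0.25.
#'
#' @param occ An `sa_occupancy`.
#' @return Named numeric `c(silent = ..., tone_mean = ...)`.
#' @export
silent_vs_other <- function(occ) {
  c(silent = unname(occ$fraction[["Q1"]]),
    tone_mean = mean(occ$fraction[c("Q2", "Q3", "Q4")]))
}

#' Per-quadrant preference index
#'
#' Time spent in each quadrant during sound exposure minus time spent there
#' during habituation. Because the phases differ in duration (5 vs 30 min by
#' default), the subtraction is done on phase-time fractions and expressed
#' in percentage points, so the four indices always sum to zero.
#'
#' @param occ_exposure,occ_habituation `sa_occupancy` results for the two
#'   phases of one session.
#' @return Named numeric vector (Q1-Q4), percentage points.
#' @export
preference_index <- function(occ_exposure, occ_habituation) {
  if (!identical(names(occ_exposure$fraction),
                 names(occ_habituation$fraction)))
    stop("phase results do not pair: role sets differ", call. = FALSE)
  100 * (occ_exposure$fraction - occ_habituation$fraction)
}

#' Binned occupancy time course
#'
#' Occupancy fractions per role in consecutive time bins: the habituation
#' phase forms a single bin, then the exposure phase is split into bins of
#' `bin_s` (default 5 min, giving 1 + 6 bins on the default schedule). A
#' trailing exposure remainder shorter than `bin_s` becomes a final bin
#' flagged as truncated.
#'
#' @param traj An [trajectory()].
#' @param assignment A [soundscape_assignment()].
#' @param schedule A [phase_schedule()].
#' @param bin_s Bin width in seconds.
#' @param arena An [arena_spec()].
#' @return A list of class `sa_timecourse`: `edges` (bin edges, s),
#'   `fraction` (bins x roles matrix), `valid_time_s` per bin,
#'   `is_habituation` flag per bin, `truncated_last`.
#' @export
binned_timecourse <- function(traj, assignment, schedule, bin_s = 300,
                              arena = arena_spec()) {
  if (bin_s <= 0) stop("bin_s must be positive", call. = FALSE)
  hab <- schedule$habituation_s
  expo <- schedule$exposure_s
  edges <- c(if (hab > 0) 0, seq(hab, hab + expo, by = bin_s))
  if (edges[length(edges)] < hab + expo) edges <- c(edges, hab + expo)
  truncated <- (expo %% bin_s) != 0
  nb <- length(edges) - 1
  frac <- matrix(NA_real_, nb, 4, dimnames = list(NULL, ROLE_LABELS))
  vt <- numeric(nb)
  for (b in seq_len(nb)) {
    occ <- tryCatch(
      occupancy(traj, assignment, c(edges[b], edges[b + 1]), arena),
      error = function(e) NULL)
    if (!is.null(occ)) {
      frac[b, ] <- occ$fraction
      vt[b] <- occ$valid_time_s
    }
  }
  structure(list(edges = edges, fraction = frac, valid_time_s = vt,
                 is_habituation = edges[-length(edges)] < hab,
                 truncated_last = truncated),
            class = "sa_timecourse")
}

#' Area under the occupancy time course
#'
#' Trapezoidal integral of one role's per-bin occupancy fraction against the
#' bin midpoints (in minutes), over the exposure bins only. A constant
#' fraction f over six 5-min bins gives f x 25 fraction-minutes (the
#' midpoints span 2.5 to 27.5 min of exposure).
#'
#' @param tc An `sa_timecourse`.
#' @param role Role label, one of Q1-Q4.
#' @return AUC in fraction-minutes.
#' @export
auc <- function(tc, role) {
  if (!role %in% ROLE_LABELS)
    stop("unknown role: ", role, call. = FALSE)
  keep <- !tc$is_habituation
  if (sum(keep) < 2)
    stop("need at least two exposure bins for an AUC", call. = FALSE)
  edges <- tc$edges
  mid_min <- ((edges[-length(edges)] + edges[-1]) / 2)[keep] / 60
  y <- tc$fraction[keep, role]
  sum(diff(mid_min) * (y[-1] + y[-length(y)]) / 2)
}

#' Distance traveled, total and per quadrant role
#'
#' Sums Euclidean steps between consecutive valid frames; each step is
#' attributed to the role occupied at its starting frame. Steps implying a
#' speed above 100 cm/s (far beyond a mouse's sprint) are discarded as
#' tracking artifacts, as are steps bridging a dropout gap at such speeds.
#'
#' @param traj An [trajectory()].
#' @param assignment A [soundscape_assignment()].
#' @param arena An [arena_spec()].
#' @param window Optional `c(t0, t1)` restriction (half-open).
#' @param max_speed_cm_s Artifact speed cutoff.
#' @return List with `total_cm` and `per_role_cm` (named Q1-Q4).
#' @export
distance_traveled <- function(traj, assignment, arena = arena_spec(),
                              window = NULL, max_speed_cm_s = 100) {
  keep <- traj$valid
  if (!is.null(window))
    keep <- keep & traj$time_s >= window[1] & traj$time_s < window[2]
  t <- traj$time_s[keep]; x <- traj$x_cm[keep]; y <- traj$y_cm[keep]
  if (length(t) < 2)
    stop("need at least two valid frames to measure distance", call. = FALSE)
  step <- sqrt(diff(x)^2 + diff(y)^2)
  ok <- step / diff(t) <= max_speed_cm_s
  p2r <- physical_to_role(assignment)
  start_role <- p2r[assign_quadrant(x[-length(x)], y[-length(y)], arena)]
  per <- tapply(step[ok], factor(start_role[ok], levels = ROLE_LABELS), sum,
                default = 0)
  per <- stats::setNames(as.numeric(per), ROLE_LABELS)
  list(total_cm = sum(step[ok]), per_role_cm = per)
}

#' Spatial occupancy heat map
#'
#' 2-D histogram of the valid positions in seconds per square cell; the
#' matrix total equals the valid tracked time. Cell `[i, j]` covers x in
#' `[(i-1) bin, i bin)` and y likewise, so the matrix is oriented like the
#' arena (first index along x, second along y, y up).
#'
#' @param traj An [trajectory()].
#' @param arena An [arena_spec()].
#' @param bin_cm Cell size in cm.
#' @return Numeric matrix of seconds.
#' @export
heatmap_matrix <- function(traj, arena = arena_spec(), bin_cm = 1) {
  if (bin_cm <= 0) stop("bin_cm must be positive", call. = FALSE)
  sel <- traj$valid
  nx <- ceiling(arena$width_cm / bin_cm)
  ny <- ceiling(arena$height_cm / bin_cm)
  ix <- pmin(pmax(floor(traj$x_cm[sel] / bin_cm), 0), nx - 1) + 1
  iy <- pmin(pmax(floor(traj$y_cm[sel] / bin_cm), 0), ny - 1) + 1
  m <- matrix(0, nx, ny)
  period <- 1 / traj_fps(traj)
  for (k in seq_along(ix)) m[ix[k], iy[k]] <- m[ix[k], iy[k]] + period
  m
}

#' Full per-session analysis
#'
#' Runs the whole readout pipeline on one session: occupancy in both phases,
#' the silent-versus-tone contrast, preference indices, the 5-min binned
#' time course, per-role AUC, distance traveled and the spatial heat map.
#'
#' @param traj An [trajectory()].
#' @param assignment A [soundscape_assignment()].
#' @param schedule A [phase_schedule()].
#' @param arena An [arena_spec()].
#' @param bin_s Time-course bin width (s).
#' @param bin_cm Heat-map cell size (cm).
#' @return A list of class `sa_session_result`.
#' @export
analyze_session <- function(traj, assignment, schedule = phase_schedule(),
                            arena = arena_spec(), bin_s = 300, bin_cm = 1) {
  hab_win <- c(0, schedule$habituation_s)
  exp_win <- c(schedule$habituation_s, total_duration_s(schedule))
  occ_hab <- occupancy(traj, assignment, hab_win, arena, "habituation")
  occ_exp <- occupancy(traj, assignment, exp_win, arena, "exposure")
  tc <- binned_timecourse(traj, assignment, schedule, bin_s, arena)
  structure(list(
    occupancy = list(habituation = occ_hab, exposure = occ_exp),
    silent_vs_other = list(habituation = silent_vs_other(occ_hab),
                           exposure = silent_vs_other(occ_exp)),
    preference_index = preference_index(occ_exp, occ_hab),
    timecourse = tc,
    auc = vapply(ROLE_LABELS, function(r) auc(tc, r), numeric(1)),
    distance = distance_traveled(traj, assignment, arena, window = exp_win),
    heatmap = heatmap_matrix(traj, arena, bin_cm)),
    class = "sa_session_result")
}

#' @export
print.sa_session_result <- function(x, ...) {
  cat("<session_result>\n  exposure occupancy (%):\n")
  print(round(100 * x$occupancy$exposure$fraction, 1))
  cat("  preference index (points):\n")
  print(round(x$preference_index, 1))
  cat(sprintf("  silent-quadrant AUC: %.2f fraction-min; distance: %.0f cm\n",
              x$auc[["Q1"]], x$distance$total_cm))
  invisible(x)
}

#' Tidy per-quadrant summary of a session
#'
#' One row per phase x role with seconds, fraction, preference index, AUC
#' and per-role distance, suitable for concatenation across a cohort.
#'
#' @param result An `sa_session_result`.
#' @param session Session identifier stored in the first column.
#' @return A data.frame.
#' @export
session_table <- function(result, session = "session1") {
  rows <- lapply(c("habituation", "exposure"), function(ph) {
    occ <- result$occupancy[[ph]]
    data.frame(session = session, phase = ph, role = ROLE_LABELS,
               seconds = as.numeric(occ$seconds),
               fraction = as.numeric(occ$fraction),
               pref_index = if (ph == "exposure")
                 as.numeric(result$preference_index) else NA_real_,
               auc = if (ph == "exposure") as.numeric(result$auc)
                 else NA_real_,
               distance_cm = if (ph == "exposure")
                 as.numeric(result$distance$per_role_cm) else NA_real_)
  })
  do.call(rbind, rows)
}
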