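# Shared fixtures: everything is generated in code at test time.

default_assignment <- function() soundscape_assignment()

# Constant-position trajectory.
const_traj <- function(x, y, duration_s, fps = 20) {
  n <- round(duration_s * fps)
  trajectory(time_s = (seq_len(n) - 1) / fps, x_cm = rep(x, n),
             y_cm = rep(y, n), fps = fps)
}

# Uniform random in-bounds trajectory.
random_traj <- function(n, seed, fps = 20, arena = arena_spec()) {
  set.seed(seed)
  trajectory(time_s = (seq_len(n) - 1) / fps,
             x_cm = runif(n, 0, arena$width_cm),
             y_cm = runif(n, 0, arena$height_cm), fps = fps)
}

# Representative interior point of each physical quadrant (44 x 44 arena).
quadrant_point <- function(label) {
  switch(label, A = c(11, 11), B = c(33, 11), C = c(11, 33), D = c(33, 33))
}

# Trajectory visiting the given role sequence (one frame per element),
# parked at the role's quadrant center.
role_traj <- function(roles, assignment, fps = 20) {
  pts <- t(vapply(unname(assignment$role_to_physical[roles]),
                  quadrant_point, numeric(2)))
  trajectory(time_s = (seq_along(roles) - 1) / fps, x_cm = pts[, 1],
             y_cm = pts[, 2], fps = fps)
}

# Independent per-frame occupancy tally: explicit comparisons, no shared
# code with the metrics module.
brute_occupancy_seconds <- function(traj, assignment, window, fps,
                                    arena = arena_spec()) {
  out <- c(Q1 = 0, Q2 = 0, Q3 = 0, Q4 = 0)
  r2p <- assignment$role_to_physical
  for (i in seq_len(nrow(traj))) {
    t <- traj$time_s[i]
    if (t < window[1] || t >= window[2] || !traj$valid[i]) next
    x <- traj$x_cm[i]; y <- traj$y_cm[i]
    q <- if (x < arena$width_cm / 2) {
      if (y < arena$height_cm / 2) "A" else "C"
    } else {
      if (y < arena$height_cm / 2) "B" else "D"
    }
    role <- names(r2p)[r2p == q]
    out[role] <- out[role] + 1 / fps
  }
  out
}

# Independent RM ANOVA sums of squares for a balanced fully-within design
# (columns S, A, B, y).
brute_rm_ss <- function(d) {
  gm <- mean(d$y)
  ns <- nlevels(d$S); na <- nlevels(d$A); nb <- nlevels(d$B)
  m_s <- tapply(d$y, d$S, mean); m_a <- tapply(d$y, d$A, mean)
  m_b <- tapply(d$y, d$B, mean)
  m_sa <- tapply(d$y, list(d$S, d$A), mean)
  m_sb <- tapply(d$y, list(d$S, d$B), mean)
  m_ab <- tapply(d$y, list(d$A, d$B), mean)
  ss_a <- ns * nb * sum((m_a - gm)^2)
  ss_b <- ns * na * sum((m_b - gm)^2)
  ss_s <- na * nb * sum((m_s - gm)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a, rep(1, nb)) -
                       outer(rep(1, na), m_b) + gm)^2)
  ss_sa <- nb * sum((m_sa - outer(m_s, rep(1, na)) -
                       outer(rep(1, ns), m_a) + gm)^2)
  ss_sb <- na * sum((m_sb - outer(m_s, rep(1, nb)) -
                       outer(rep(1, ns), m_b) + gm)^2)
  ss_tot <- sum((d$y - gm)^2)
  ss_sab <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_sa - ss_sb
  list(a = ss_a, b = ss_b, ab = ss_ab, sa = ss_sa, sb = ss_sb,
       sab = ss_sab, total = ss_tot)
}

# Independent one-way ANOVA sums of squares.
brute_anova_ss <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  c(between = ssb, within = ssw, total = sum((all - gm)^2))
}
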