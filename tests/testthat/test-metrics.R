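test_that("occupancy splits time by role and matches a brute-force tally", {
  asg <- default_assignment()
  # one frame per quadrant
  traj <- role_traj(c("Q1", "Q2", "Q3", "Q4"), asg)
  occ <- occupancy(traj, asg, c(0, 0.2))
  expect_equal(as.numeric(occ$fraction), rep(0.25, 4))
  # parked in the silent quadrant
  p <- quadrant_point(asg$role_to_physical[["Q1"]])
  occ1 <- occupancy(const_traj(p[1], p[2], 10), asg, c(0, 10))
  expect_equal(occ1$fraction[["Q1"]], 1.0)
  # 1,000-frame random trajectory against the independent per-frame oracle
  for (s in 1:3) {
    traj <- random_traj(1000, seed = 400 + s)
    traj$valid[sample(1000, 50)] <- FALSE
    occ <- occupancy(traj, asg, c(10, 40))
    expect_equal(occ$seconds,
                 brute_occupancy_seconds(traj, asg, c(10, 40), fps = 20))
  }
  expect_error(occupancy(const_traj(1, 1, 1), asg, c(5, 6)),
               "no valid frames")
})

test_that("occupancy fractions sum to one and seconds to the valid time", {
  asg <- default_assignment()
  for (s in 1:5) {
    traj <- random_traj(500, seed = 500 + s)
    traj$valid[sample(500, 30)] <- FALSE
    occ <- occupancy(traj, asg, c(0, 25))
    expect_equal(sum(occ$fraction), 1, tolerance = 1e-9)
    expect_equal(sum(occ$seconds), occ$valid_time_s, tolerance = 1e-9)
  }
})

test_that("silent-vs-tone contrast averages the three tone quadrants", {
  asg <- default_assignment()
  sym <- occupancy(role_traj(c("Q1", "Q2", "Q3", "Q4"), asg), asg, c(0, 1))
  expect_equal(unname(silent_vs_other(sym)), c(0.25, 0.25))
  # the KO-like split: 46% silence, 18% in each tone quadrant
  roles <- c(rep("Q1", 23), rep("Q2", 9), rep("Q3", 9), rep("Q4", 9))
  occ <- occupancy(role_traj(roles, asg), asg, c(0, 2.5))
  expect_equal(unname(silent_vs_other(occ)), c(0.46, 0.18))
  only_silent <- occupancy(role_traj(rep("Q1", 4), asg), asg, c(0, 0.2))
  expect_equal(unname(silent_vs_other(only_silent)), c(1, 0))
})

test_that("preference index is the percentage-point change from habituation", {
  asg <- default_assignment()
  hab <- occupancy(role_traj(c("Q1", "Q2", "Q3", "Q4"), asg), asg, c(0, 1),
                   phase = "habituation")
  expect_equal(unname(preference_index(hab, hab)), rep(0, 4))
  roles <- c(rep("Q1", 23), rep("Q2", 9), rep("Q3", 9), rep("Q4", 9))
  expo <- occupancy(role_traj(roles, asg), asg, c(0, 2.5))
  pref <- preference_index(expo, hab)
  expect_equal(unname(pref), c(21, -7, -7, -7))
  # compositional identity on arbitrary pairs
  for (s in 1:5) {
    o1 <- occupancy(random_traj(300, seed = 600 + s), asg, c(0, 15))
    o2 <- occupancy(random_traj(300, seed = 700 + s), asg, c(0, 15))
    expect_equal(sum(preference_index(o1, o2)), 0, tolerance = 1e-9)
  }
})

test_that("the default schedule yields one habituation plus six exposure bins", {
  asg <- default_assignment()
  p <- quadrant_point(asg$role_to_physical[["Q2"]])
  traj <- const_traj(p[1], p[2], duration_s = 2100)
  tc <- binned_timecourse(traj, asg, phase_schedule())
  expect_equal(length(tc$edges) - 1, 7)
  expect_identical(tc$is_habituation, c(TRUE, rep(FALSE, 6)))
  expect_false(tc$truncated_last)
  expect_equal(unname(tc$fraction[, "Q2"]), rep(1, 7))
  expect_equal(unname(tc$fraction[, "Q1"]), rep(0, 7))
})

test_that("exposure bins aggregate back to whole-exposure occupancy", {
  asg <- default_assignment()
  sched <- phase_schedule(60, 360)
  dp <- dwell_params(c(0.4, 0.3, 0.2, 0.1), mean_dwell_s = 8, seed = 21)
  traj <- simulate_dwell(dp, schedule = sched)
  tc <- binned_timecourse(traj, asg, sched, bin_s = 60)
  keep <- !tc$is_habituation
  agg <- colSums(tc$fraction[keep, ] * tc$valid_time_s[keep]) /
    sum(tc$valid_time_s[keep])
  whole <- occupancy(traj, asg, c(60, 420))
  expect_equal(agg, whole$fraction, tolerance = 1e-9)
})

test_that("AUC integrates the exposure time course in fraction-minutes", {
  mk_tc <- function(fracs_q1) {
    nb <- length(fracs_q1)
    frac <- cbind(Q1 = c(0.25, fracs_q1),
                  Q2 = (1 - c(0.25, fracs_q1)) / 3,
                  Q3 = (1 - c(0.25, fracs_q1)) / 3,
                  Q4 = (1 - c(0.25, fracs_q1)) / 3)
    structure(list(edges = c(0, seq(300, by = 300, length.out = nb + 1)),
                   fraction = frac, valid_time_s = rep(300, nb + 1),
                   is_habituation = c(TRUE, rep(FALSE, nb)),
                   truncated_last = FALSE),
              class = "sa_timecourse")
  }
  expect_equal(auc(mk_tc(rep(0.25, 6)), "Q1"), 0.25 * 25)
  expect_equal(auc(mk_tc(rep(1, 6)), "Q1"), 25)
  # linear ramp 0 -> 1: trapezoid of midpoint heights 0, .2, ..., 1
  expect_equal(auc(mk_tc(seq(0, 1, by = 0.2)), "Q1"), 12.5)
  expect_error(auc(mk_tc(rep(0.5, 6)), "Q9"), "unknown role")
})

test_that("distance is attributed per role and filters teleport artifacts", {
  asg <- default_assignment()
  still <- const_traj(10, 10, 5)
  expect_equal(distance_traveled(still, asg)$total_cm, 0)
  # straight 10 cm path inside one quadrant
  n <- 21
  line <- trajectory((0:(n - 1)) / 20, x_cm = seq(2, 12, length.out = n),
                     y_cm = rep(5, n), fps = 20)
  d <- distance_traveled(line, asg)
  expect_equal(d$total_cm, 10)
  role_at_start <- physical_to_role_lab <- names(which(
    asg$role_to_physical == "A"))
  expect_equal(unname(d$per_role_cm[role_at_start]), 10)
  # brute-force pairwise oracle
  traj <- random_traj(300, seed = 31)
  traj$valid[c(50:60, 200)] <- FALSE
  got <- distance_traveled(traj, asg, max_speed_cm_s = Inf)
  keep <- which(traj$valid)
  steps <- sqrt(diff(traj$x_cm[keep])^2 + diff(traj$y_cm[keep])^2)
  expect_equal(got$total_cm, sum(steps), tolerance = 1e-9)
  expect_equal(got$total_cm, sum(got$per_role_cm), tolerance = 1e-9)
  # a teleport step (>100 cm/s) is dropped
  tele <- trajectory(c(0, 0.05, 0.1), x_cm = c(1, 2, 40), y_cm = c(1, 1, 40),
                     fps = 20)
  dt <- distance_traveled(tele, asg)
  expect_equal(dt$total_cm, 1)
  expect_error(distance_traveled(const_traj(1, 1, 0.05), asg), "two valid")
})

test_that("heat-map mass equals the valid tracked time", {
  asg <- default_assignment()
  spot <- const_traj(10.5, 30.5, 4)
  m <- heatmap_matrix(spot)
  expect_equal(sum(m != 0), 1)
  expect_equal(m[11, 31], 4)
  for (s in 1:3) {
    traj <- random_traj(400, seed = 800 + s)
    traj$valid[sample(400, 20)] <- FALSE
    m <- heatmap_matrix(traj)
    occ <- occupancy(traj, asg, c(0, 20))
    expect_equal(sum(m), occ$valid_time_s, tolerance = 1e-9)
  }
})

test_that("analyze_session composes all per-session readouts", {
  asg <- default_assignment()
  sched <- phase_schedule(30, 120)
  dp <- dwell_params(c(0.4, 0.2, 0.2, 0.2), mean_dwell_s = 5, seed = 12)
  traj <- simulate_dwell(dp, schedule = sched)
  res <- analyze_session(traj, asg, sched, bin_s = 30)
  expect_s3_class(res, "sa_session_result")
  expect_equal(sum(res$preference_index), 0, tolerance = 1e-9)
  expect_equal(sum(res$occupancy$exposure$fraction), 1, tolerance = 1e-9)
  tab <- session_table(res, "s1")
  expect_equal(nrow(tab), 8)
  expect_equal(sum(tab$fraction[tab$phase == "exposure"]), 1,
               tolerance = 1e-9)
})
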