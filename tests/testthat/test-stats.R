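test_that("Student's t matches the pooled closed form and df pattern", {
  x <- c(1.1, 2.0, 3.2, 2.6)
  same <- students_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  a <- c(1, 2, 3); b <- a + 1
  got <- students_t(a, b)
  # independent closed-form pooled t
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(got$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(got$df, 4)
  expect_equal(got$p_value, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-12)
  # two groups of 25 -> 48 degrees of freedom
  set.seed(9)
  big <- students_t(rnorm(25), rnorm(25))
  expect_equal(big$df, 48)
  expect_error(students_t(1, c(1, 2)), "at least two")
  paired <- students_t(c(1, 2, 3), c(2.5, 3, 5), paired = TRUE)
  expect_equal(paired$df, 2)
  expect_error(students_t(1:3, 1:4, paired = TRUE), "equal group lengths")
})

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  set.seed(17)
  for (rep in 1:5) {
    groups <- lapply(1:4, function(i) rnorm(6, mean = i / 2))
    names(groups) <- paste0("g", 1:4)
    got <- one_way_anova(groups)
    ss <- brute_anova_ss(groups)
    expect_equal(unname(got$ss["between"]), unname(ss["between"]),
                 tolerance = 1e-10)
    expect_equal(unname(got$ss["within"]), unname(ss["within"]),
                 tolerance = 1e-10)
    expect_equal(sum(got$ss), unname(ss["total"]), tolerance = 1e-9)
    F_oracle <- (ss["between"] / 3) / (ss["within"] / 20)
    expect_equal(got$statistic, unname(F_oracle), tolerance = 1e-10)
    expect_equal(got$df, c(3, 20))
  }
  # four groups of 25 -> df (3, 96)
  big <- one_way_anova(lapply(1:4, function(i) rnorm(25)))
  expect_equal(big$df, c(3, 96))
})

test_that("degenerate one-way designs behave as specified", {
  flat <- one_way_anova(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(one_way_anova(list(a = c(1, 1, 1), b = c(2, 2, 2))),
               "degenerate")
  expect_error(one_way_anova(list(a = 1:3)), "two groups")
})

test_that("Tukey HSD agrees with a studentized-range oracle", {
  set.seed(23)
  groups <- lapply(1:3, function(i) rnorm(5, i))
  names(groups) <- c("a", "b", "c")
  got <- one_way_anova(groups)
  ss <- brute_anova_ss(groups)
  mse <- ss["within"] / 12
  q_bc <- abs(mean(groups$c) - mean(groups$b)) / sqrt(mse / 5)
  p_oracle <- ptukey(q_bc, 3, 12, lower.tail = FALSE)
  p_got <- got$posthoc$p_adj[got$posthoc$comparison == "c-b"]
  expect_equal(p_got, unname(p_oracle), tolerance = 1e-8)
})

test_that("an F test on two groups squares the t statistic", {
  set.seed(29)
  for (rep in 1:5) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    ft <- one_way_anova(list(a = a, b = b))
    tt <- students_t(a, b)
    expect_equal(ft$statistic, tt$statistic^2, tolerance = 1e-10)
    expect_equal(ft$p_value, tt$p_value, tolerance = 1e-10)
  }
})

test_that("RM ANOVA matches a manual sums-of-squares oracle", {
  set.seed(37)
  d <- expand.grid(S = factor(paste0("s", 1:3)), A = factor(c("a1", "a2")),
                   B = factor(c("b1", "b2")))
  d$y <- rnorm(nrow(d))
  got <- two_way_rm_anova(d, "S", "A", "B", "y")
  ss <- brute_rm_ss(d)
  eff <- got$effects
  expect_equal(eff$ss[eff$effect == "A"], ss$a, tolerance = 1e-9)
  expect_equal(eff$ss[eff$effect == "B"], ss$b, tolerance = 1e-9)
  expect_equal(eff$ss[eff$effect == "A:B"], ss$ab, tolerance = 1e-9)
  # each effect is tested against its own subject-by-effect stratum
  f_a <- (ss$a / 1) / (ss$sa / 2)
  f_ab <- (ss$ab / 1) / (ss$sab / 2)
  expect_equal(eff$F[eff$effect == "A"], f_a, tolerance = 1e-9)
  expect_equal(eff$F[eff$effect == "A:B"], f_ab, tolerance = 1e-9)
  expect_equal(eff$df1, c(1, 1, 1))
  expect_equal(eff$df2, c(2, 2, 2))
})

test_that("RM sums of squares decompose the total on larger designs", {
  set.seed(41)
  d <- expand.grid(S = factor(paste0("s", 1:6)),
                   A = factor(paste0("a", 1:4)),
                   B = factor(paste0("b", 1:3)))
  d$y <- rnorm(nrow(d))
  got <- two_way_rm_anova(d, "S", "A", "B", "y")
  ss <- brute_rm_ss(d)
  eff <- got$effects
  expect_equal(eff$ss, c(ss$a, ss$b, ss$ab), tolerance = 1e-9)
  expect_equal(eff$ms_error * eff$df2, c(ss$sa, ss$sb, ss$sab),
               tolerance = 1e-9)
  expect_equal(ss$a + ss$b + ss$ab + ss$sa + ss$sb + ss$sab +
                 12 * sum((tapply(d$y, d$S, mean) - mean(d$y))^2),
               ss$total, tolerance = 1e-9)
})

test_that("pure subject offsets produce no treatment effects", {
  d <- expand.grid(S = factor(paste0("s", 1:5)), A = factor(c("a1", "a2")),
                   B = factor(c("b1", "b2", "b3")))
  d$y <- as.numeric(d$S) * 2.5
  got <- two_way_rm_anova(d, "S", "A", "B", "y")
  expect_true(all(abs(got$effects$ss) < 1e-18))
})

test_that("additive synthetic effects are recovered in the cell means", {
  set.seed(43)
  a_eff <- c(a1 = 0, a2 = 2); b_eff <- c(b1 = 0, b2 = 1, b3 = -1)
  d <- expand.grid(S = factor(paste0("s", 1:8)), A = factor(names(a_eff)),
                   B = factor(names(b_eff)))
  d$y <- 5 + a_eff[d$A] + b_eff[d$B] + rnorm(nrow(d), 0, 1e-6)
  got <- two_way_rm_anova(d, "S", "A", "B", "y")
  cm <- got$cells
  expect_equal(cm$mean[cm$A == "a2" & cm$B == "b2"], 5 + 2 + 1,
               tolerance = 1e-4)
  expect_equal(cm$mean[cm$A == "a1" & cm$B == "b3"], 5 - 1,
               tolerance = 1e-4)
})

test_that("incomplete repeated-measures designs are rejected by cell", {
  d <- expand.grid(S = factor(paste0("s", 1:3)), A = factor(c("a1", "a2")),
                   B = factor(c("b1", "b2")))
  d$y <- rnorm(nrow(d))
  expect_error(two_way_rm_anova(d[-1, ], "S", "A", "B", "y"),
               "subject s1, cell \\(a1, b1\\)")
})

test_that("Greenhouse-Geisser epsilon is 1 for two levels and at most 1", {
  set.seed(47)
  d <- expand.grid(S = factor(paste0("s", 1:8)), A = factor(c("a1", "a2")),
                   B = factor(paste0("b", 1:4)))
  d$y <- rnorm(nrow(d))
  got <- two_way_rm_anova(d, "S", "A", "B", "y", gg = TRUE)
  eff <- got$effects
  expect_equal(eff$gg_epsilon[eff$effect == "A"], 1, tolerance = 1e-9)
  expect_true(all(eff$gg_epsilon <= 1 + 1e-9))
  # the correction is conservative whenever the effect is non-trivial
  big_f <- eff$F > 1
  expect_true(all(eff$p_gg[big_f] >= eff$p_value[big_f] - 1e-12))
})

test_that("cell summaries give mean and 95% t-intervals", {
  s <- summarize_cells(list(k = c(1, 1, 1, 1)))
  expect_equal(s$mean, 1)
  expect_equal(s$ci_halfwidth, 0)
  s2 <- summarize_cells(list(k = c(0, 2)))
  expect_equal(s2$mean, 1)
  expect_equal(s2$ci_halfwidth, qt(0.975, 1) * sd(c(0, 2)) / sqrt(2),
               tolerance = 1e-12)
  # width shrinks like 1/sqrt(n)
  set.seed(51)
  base <- rnorm(400)
  w1 <- summarize_cells(list(k = base[1:100]))$ci_halfwidth
  w2 <- summarize_cells(list(k = base))$ci_halfwidth
  expect_lt(w2, w1 / 1.6)
  expect_error(summarize_cells(list(k = 1)), "at least two")
})
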