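#' Two-tailed Student's t-test
#'
#' Unpaired pooled-variance (classical Student) two-tailed t-test by
#' default — the variant whose degrees of freedom match the published
#' pattern (two groups of 25 give t on 48 df) — with a paired option.
#'
#' @param group_a,group_b Numeric response vectors.
#' @param paired Paired test? Requires equal lengths.
#' @return A list of class `sa_test`: `method`, `statistic`, `df`,
#'   `p_value`, `cells` (per-group mean and 95% CI).
#' @export
students_t <- function(group_a, group_b, paired = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least two observations", call. = FALSE)
  if (paired && length(group_a) != length(group_b))
    stop("paired test requires equal group lengths", call. = FALSE)
  ht <- stats::t.test(group_a, group_b, paired = paired, var.equal = TRUE,
                      alternative = "two.sided")
  structure(list(
    method = if (paired) "paired t" else "unpaired pooled-variance t",
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    cells = summarize_cells(list(a = group_a, b = group_b))),
    class = "sa_test")
}

#' One-way ANOVA with Tukey HSD
#'
#' Classical between/within decomposition with F on (k-1, N-k) degrees of
#' freedom, followed by Tukey studentized-range pairwise comparisons.
#' Quadrant-fraction responses are compositional (they sum to 1 across
#' roles within an animal); the test is run as published and the
#' compositional caveat is recorded in the result's `notes` rather than
#' "corrected".
#'
#' @param groups Named list of numeric response vectors (k >= 2, each of
#'   length >= 2).
#' @return An `sa_test` with `ss` (between/within), `posthoc` (Tukey table)
#'   and `cells`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) < 2))
    stop("each group needs at least two observations", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups)))
  k <- length(groups); N <- nrow(df)
  gm <- mean(df$y)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - gm)^2)
  ssw <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  eps <- 1e-12 * max(1, sum(df$y^2))
  if (ssw <= eps && ssb > eps)
    stop("degenerate design: zero within-group variance", call. = FALSE)
  if (ssb <= eps && ssw <= eps) {
    fstat <- 0; p <- 1; tukey <- NULL
  } else {
    fit <- stats::aov(y ~ g, data = df)
    tab <- summary(fit)[[1]]
    fstat <- tab[["F value"]][1]
    p <- tab[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], row.names = NULL)
  }
  structure(list(method = "one-way ANOVA + Tukey HSD",
                 statistic = fstat, df = c(k - 1, N - k), p_value = p,
                 ss = c(between = ssb, within = ssw),
                 posthoc = tukey, cells = summarize_cells(groups),
                 notes = paste("quadrant fractions are compositional",
                               "(sum to 1 within animal); ANOVA applied as",
                               "published")),
            class = "sa_test")
}

#' Two-way repeated-measures ANOVA
#'
#' Both factors within-subject, complete balanced design required. The sums
#' of squares are partitioned into factor A, factor B, the A x B
#' interaction, subjects, and the three subject-by-effect error strata; each
#' effect is tested against its own stratum (the standard univariate RM
#' table). Sphericity is uncorrected by default; Greenhouse-Geisser
#' correction is available via `gg = TRUE`. Tukey pairwise comparisons of
#' each factor's marginal means use that factor's error stratum.
#'
#' @param table Long data.frame with one row per subject x cell.
#' @param subject,factor_a,factor_b,response Column names.
#' @param gg Apply the Greenhouse-Geisser epsilon correction?
#' @return An `sa_test` whose `effects` element is a data.frame with one
#'   row per effect (A, B, A:B): `ss`, `df1`, `df2`, `ms_error`, `F`,
#'   `p_value` (and `gg_epsilon`, `p_gg` when requested).
#' @export
two_way_rm_anova <- function(table, subject = "subject", factor_a = "role",
                             factor_b = "bin", response = "value",
                             gg = FALSE) {
  need <- c(subject, factor_a, factor_b, response)
  if (!all(need %in% names(table)))
    stop("table must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  S <- factor(table[[subject]]); A <- factor(table[[factor_a]])
  B <- factor(table[[factor_b]]); y <- table[[response]]
  counts <- base::table(S, A, B)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "incomplete/unbalanced design: subject %s, cell (%s, %s) has %d rows",
      dimnames(counts)[[1]][bad[1]], dimnames(counts)[[2]][bad[2]],
      dimnames(counts)[[3]][bad[3]],
      counts[bad[1], bad[2], bad[3]]), call. = FALSE)
  }
  d <- data.frame(y = y, S = S, A = A, B = B)
  fit <- stats::aov(y ~ A * B + Error(S / (A * B)), data = d)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tab)))
    err <- nrow(tab)  # residuals row
    c(ss = tab[["Sum Sq"]][i], df1 = tab[["Df"]][i],
      df2 = tab[["Df"]][err], ms_error = tab[["Mean Sq"]][err],
      F = tab[["F value"]][i], p_value = tab[["Pr(>F)"]][i])
  }
  eff <- rbind(A = pick("Error: S:A", "A"),
               B = pick("Error: S:B", "B"),
               `A:B` = pick("Error: S:A:B", "A:B"))
  effects <- data.frame(effect = rownames(eff), eff, row.names = NULL)
  names(effects)[1] <- "effect"
  if (gg) {
    epsA <- gg_epsilon(d, "A")
    epsB <- gg_epsilon(d, "B")
    epsAB <- gg_epsilon(d, "AB")
    effects$gg_epsilon <- c(epsA, epsB, epsAB)
    effects$p_gg <- stats::pf(effects$F,
                              effects$gg_epsilon * effects$df1,
                              effects$gg_epsilon * effects$df2,
                              lower.tail = FALSE)
  }
  posthoc <- list(A = rm_tukey(d, "A", effects),
                  B = rm_tukey(d, "B", effects))
  structure(list(method = paste0("two-way RM ANOVA",
                                 if (gg) " (Greenhouse-Geisser)" else ""),
                 effects = effects, posthoc = posthoc,
                 cells = rm_cell_means(d)),
            class = "sa_test")
}

# Subject x cell response matrix for an effect ("A", "B" or "AB").
rm_cell_matrix <- function(d, effect) {
  if (effect == "A") {
    m <- tapply(d$y, list(d$S, d$A), mean)
  } else if (effect == "B") {
    m <- tapply(d$y, list(d$S, d$B), mean)
  } else {
    m <- tapply(d$y, list(d$S, interaction(d$A, d$B)), mean)
  }
  m
}

# Greenhouse-Geisser epsilon from the covariance of within-subject cells.
gg_epsilon <- function(d, effect) {
  M <- rm_cell_matrix(d, effect)
  V <- stats::cov(M)
  ctr <- function(p) {
    C <- stats::contr.helmert(p)
    qr.Q(qr(C))  # orthonormal columns
  }
  C <- if (effect == "AB")
    kronecker(ctr(nlevels(d$A)), ctr(nlevels(d$B))) else
    ctr(ncol(M))
  W <- t(C) %*% V %*% C
  dgf <- ncol(W)
  (sum(diag(W)))^2 / (dgf * sum(W^2))
}

# Tukey pairwise comparisons of one factor's marginal means, tested against
# that factor's RM error stratum.
rm_tukey <- function(d, effect, effects) {
  f <- if (effect == "A") d$A else d$B
  means <- tapply(d$y, f, mean)
  n_per_mean <- nrow(d) / nlevels(f)
  row <- effects[effects$effect == effect, ]
  se <- sqrt(row$ms_error / n_per_mean)
  lev <- levels(f)
  combs <- utils::combn(lev, 2)
  diffs <- means[combs[2, ]] - means[combs[1, ]]
  q <- abs(diffs) / se
  p <- stats::ptukey(q, nlevels(f), row$df2, lower.tail = FALSE)
  data.frame(comparison = paste(combs[2, ], combs[1, ], sep = "-"),
             diff = as.numeric(diffs), p_adj = as.numeric(p),
             row.names = NULL)
}

rm_cell_means <- function(d) {
  agg <- stats::aggregate(y ~ A + B, data = d, FUN = mean)
  names(agg) <- c("A", "B", "mean")
  agg
}

#' Per-group mean and 95% confidence interval
#'
#' Mean with a two-sided 95% Student-t interval per group, the summary the
#' assay's figures report (mean +/- CI).
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @return Data.frame with `group`, `n`, `mean`, `ci_lo`, `ci_hi`,
#'   `ci_halfwidth`.
#' @export
summarize_cells <- function(groups) {
  if (any(lengths(groups) < 2))
    stop("each cell needs at least two observations for a CI", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  rows <- lapply(names(groups), function(nm) {
    v <- groups[[nm]]; n <- length(v); m <- mean(v)
    hw <- stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
    data.frame(group = nm, n = n, mean = m, ci_lo = m - hw, ci_hi = m + hw,
               ci_halfwidth = hw)
  })
  do.call(rbind, rows)
}

#' @export
print.sa_test <- function(x, ...) {
  cat("<", x$method, ">\n", sep = "")
  if (!is.null(x$effects)) {
    print(x$effects, digits = 4)
  } else {
    cat(sprintf("  statistic = %.4f, df = %s, p = %.4g\n", x$statistic,
                paste(x$df, collapse = ", "), x$p_value))
  }
  invisible(x)
}
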