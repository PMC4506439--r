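test_that("group summaries match direct mean/SEM arithmetic", {
  s <- group_summary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(round(s$sem, 3), 0.577)

  single <- group_summary(5)
  expect_equal(single$mean, 5)
  expect_equal(single$sem, 0)
  expect_false(single$sem_defined)

  set.seed(10)
  x <- rnorm(1000, 10, 2)
  s2 <- group_summary(x)
  expect_identical(s2$mean, mean(x))
  expect_equal(s2$sem, sqrt(sum((x - mean(x))^2) / 999) / sqrt(1000))
  expect_error(group_summary(numeric(0)), "empty")
})

test_that("censored summaries report range flags and exclude limits", {
  lim <- data.frame(lower = 5, upper = 3860)
  high <- data.frame(conc_pg_ml = rep(3860, 5),
                     censor = rep("high", 5))
  s <- censored_summary(high, lim)
  expect_equal(s$censor_state, "above_range")
  expect_equal(s$mean, 3860)

  low <- data.frame(conc_pg_ml = rep(5, 5), censor = rep("low", 5))
  s2 <- censored_summary(low, lim)
  expect_equal(s2$censor_state, "below_range")
  expect_equal(s2$mean, 5)

  clean <- data.frame(conc_pg_ml = c(10, 20, 30), censor = rep("none", 3))
  s3 <- censored_summary(clean, lim)
  ref <- group_summary(c(10, 20, 30))
  expect_equal(s3$mean, ref$mean)
  expect_equal(s3$sem, ref$sem)
  expect_equal(s3$censor_state, "none")

  mixed <- data.frame(conc_pg_ml = c(5, 3860), censor = c("low", "high"))
  expect_error(censored_summary(mixed, lim), "inconsistent")
})

test_that("combined-CCI mean is the sample-size-weighted subgroup mean", {
  mk <- function(n, m) {
    s <- group_summary(m); s$n <- n; s
  }
  # sciatic-nerve IL-6 and MCP-1 subgroup summaries reproduce the printed
  # combined column at 1-decimal rounding
  il6 <- combined_cci_mean(list(mk(5, 151.8), mk(4, 61.4), mk(5, 82.5)))
  expect_equal(round(il6$mean, 1), 101.2)
  expect_equal(il6$n, 14)
  mcp1 <- combined_cci_mean(list(mk(5, 546.8), mk(4, 367.9), mk(5, 391.5)))
  expect_equal(round(mcp1$mean, 1), 440.2)

  same <- combined_cci_mean(list(mk(5, 7), mk(4, 7), mk(5, 7)))
  expect_equal(same$mean, 7)

  # pooled raw values define the combined SEM
  set.seed(4)
  raw <- rnorm(14, 100, 10)
  with_raw <- combined_cci_mean(list(mk(5, 1), mk(4, 1), mk(5, 1)),
                                raw_values = raw)
  expect_equal(with_raw$sem, sd(raw) / sqrt(14))

  cens <- mk(5, 3860); cens$censor_state <- "above_range"
  combined <- combined_cci_mean(list(cens, mk(4, 61.4), mk(5, 82.5)))
  expect_equal(combined$censor_state, "above_range")
})

test_that("one-way ANOVA matches t-squared and brute-force sums of squares", {
  set.seed(20)
  x <- rnorm(8, 0, 1); y <- rnorm(9, 1, 1)
  res <- one_way_anova(list(a = x, b = y))
  t2 <- unname(t.test(x, y, var.equal = TRUE)$statistic^2)
  expect_equal(res$statistic, t2, tolerance = 1e-10)

  groups <- list(g1 = c(1, 2, 3), g2 = c(4, 5, 6), g3 = c(7, 8, 9))
  res3 <- one_way_anova(groups)
  # independent SS decomposition
  all_v <- unlist(groups)
  gm <- mean(all_v)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f_oracle <- (ss_b / 2) / (ss_w / 6)
  expect_equal(res3$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(res3$p_raw, pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical group means with within-group spread: F exactly 0
  null3 <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(null3$statistic, 0)
  expect_equal(null3$p_raw, 1)
  # fully degenerate data: p = 1 by convention
  flat <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_raw, 1)
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("Bonferroni post hoc uses pooled variance and caps at 1", {
  set.seed(30)
  groups <- list(sham = rnorm(5, 0), a = rnorm(5, 0.2), b = rnorm(4, 2),
                 c = rnorm(5, 0.1))
  ph <- bonferroni_posthoc(groups)
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$p_bonferroni, pmin(1, 3 * ph$p_raw))

  # single comparison: adjustment is the identity
  one <- bonferroni_posthoc(groups, comparisons = list(c("sham", "b")))
  expect_equal(one$p_bonferroni, one$p_raw)

  # manual pooled-variance t for one pair
  ns <- lengths(groups)
  mse <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) /
    (sum(ns) - 4)
  t_manual <- (mean(groups$sham) - mean(groups$b)) /
    sqrt(mse * (1 / 5 + 1 / 4))
  expect_equal(one$statistic, t_manual, tolerance = 1e-12)
  expect_equal(one$df, sum(ns) - 4)

  # large raw p cannot exceed 1 after adjustment
  similar <- list(x = c(1, 2, 3), y = c(1.1, 2, 3), z = c(0.9, 2, 3))
  ph2 <- bonferroni_posthoc(similar,
                            comparisons = list(c("x", "y"), c("x", "z")))
  expect_true(all(ph2$p_bonferroni <= 1))
  expect_error(bonferroni_posthoc(groups,
                                  comparisons = list(c("sham", "nope"))),
               "unknown group")
})

test_that("two-way ANOVA decomposes sums of squares correctly", {
  # balanced 2x2 additive layout, duplicated cells: interaction F is 0
  g <- rep(rep(c("A", "B"), each = 2), 2)
  d <- rep(c("1", "2"), each = 4)
  vals <- c(1, 1, 3, 3, 2, 2, 4, 4)  # additive: group +2, day +1
  res <- two_way_anova(vals + rep(c(-0.1, 0.1), 4), g, d)
  expect_equal(res$statistic[res$effect == "group:day"], 0,
               tolerance = 1e-10)

  # balanced 3x6 design vs brute-force balanced two-way decomposition
  set.seed(40)
  groups <- rep(c("g1", "g2", "g3"), each = 6 * 4)
  days <- rep(rep(paste0("d", 1:6), each = 4), 3)
  mu <- c(g1 = 0, g2 = 1, g3 = 3)[groups] + as.integer(factor(days)) * 0.5
  y <- mu + rnorm(length(mu))
  res2 <- two_way_anova(y, groups, days)

  gm <- mean(y)
  ss_g <- sum(tapply(y, groups, function(v) length(v) * (mean(v) - gm)^2))
  ss_d <- sum(tapply(y, days, function(v) length(v) * (mean(v) - gm)^2))
  cell_means <- tapply(y, list(groups, days), mean)
  ss_cells <- 4 * sum((cell_means - gm)^2)
  ss_int <- ss_cells - ss_g - ss_d
  ss_res <- sum((y - cell_means[cbind(groups, days)])^2)
  f_oracle <- c(group = (ss_g / 2) / (ss_res / (72 - 18)),
                day = (ss_d / 5) / (ss_res / (72 - 18)),
                int = (ss_int / 10) / (ss_res / (72 - 18)))
  expect_equal(res2$statistic, unname(f_oracle), tolerance = 1e-10)

  # identical population means at large n: all effects near null
  set.seed(41)
  g0 <- rep(c("A", "B"), each = 600)
  d0 <- rep(rep(c("1", "2"), each = 300), 2)
  res0 <- two_way_anova(rnorm(1200), g0, d0)
  expect_true(all(res0$p_raw > 0.001))
  expect_error(two_way_anova(1:4, rep("A", 4), rep(c("1", "2"), 2)),
               "two levels")
})

test_that("per-day post hoc applies the day-by-pair Bonferroni factor", {
  set.seed(42)
  g <- rep(c("sham", "pd"), each = 12)
  d <- rep(rep(paste0("d", 1:3), each = 4), 2)
  y <- rnorm(24) + ifelse(g == "pd" & d == "d2", 5, 0)
  ph <- per_day_posthoc(y, g, d)
  expect_equal(nrow(ph), 3L)            # 1 pair x 3 days
  expect_equal(ph$p_bonferroni, pmin(1, 3 * ph$p_raw))
  expect_true(ph$p_bonferroni[ph$day == "d2"] < 0.05)
})

test_that("linear regression equals the normal-equation solution", {
  x <- 1:10
  # exact fit triggers base R's perfect-fit note; the values are the point
  perfect <- suppressWarnings(linear_regression(x, 2 * x))
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$intercept, 0)
  expect_equal(perfect$r_squared, 1)

  set.seed(50)
  y <- 3 + 0.5 * x + rnorm(10)
  fit <- linear_regression(x, y)
  # closed form
  beta <- cov(x, y) / var(x)
  alpha <- mean(y) - beta * mean(x)
  ss_res <- sum((y - alpha - beta * x)^2)
  r2 <- 1 - ss_res / sum((y - mean(y))^2)
  expect_equal(fit$slope, beta, tolerance = 1e-12)
  expect_equal(fit$intercept, alpha, tolerance = 1e-12)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)

  set.seed(51)
  null_fit <- linear_regression(rnorm(2000), rnorm(2000))
  expect_lt(null_fit$r_squared, 0.01)
  expect_error(linear_regression(rep(1, 5), rnorm(5)), "constant x")
  expect_error(linear_regression(1:2, 1:2), "at least 3")
})

test_that("BH step-up matches its definition and the reference routine", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.8)),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_adjust(rep(1, 5)), rep(FALSE, 5))
  expect_equal(bh_adjust(0.03), TRUE)

  set.seed(60)
  for (i in 1:300) {
    m <- sample(1:8, 1)
    p <- runif(m)^sample(1:3, 1)
    flags <- bh_adjust(p, q = 0.05)
    expect_identical(flags, unname(p.adjust(p, "BH") <= 0.05))
    # direct evaluation of the step-up definition
    ord <- order(p); sorted <- p[ord]
    istar <- 0L
    for (j in m:1) if (sorted[j] <= j * 0.05 / m) { istar <- j; break }
    manual <- logical(m)
    if (istar > 0) manual[ord[1:istar]] <- TRUE
    expect_identical(flags, manual)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(numeric(0)), "empty")
})

test_that("raising q never removes a BH rejection", {
  set.seed(61)
  for (i in 1:50) {
    p <- runif(sample(2:8, 1))
    prev <- rep(FALSE, length(p))
    for (q in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
      cur <- bh_adjust(p, q)
      expect_true(all(cur[prev]))
      prev <- cur
    }
  }
})

test_that("family-wise adjustment corrects within each family only", {
  res <- data.frame(p_raw = c(0.01, 0.02, 0.04, 0.8, 0.001, 0.9),
                    family_id = c(rep("f1", 4), rep("f2", 2)))
  adj <- adjust_families(res, q = 0.05)
  expect_equal(adj$significant_fdr,
               c(bh_adjust(res$p_raw[1:4]), bh_adjust(res$p_raw[5:6])))
})
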