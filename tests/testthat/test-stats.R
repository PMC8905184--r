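test_that("paired t-test reproduces the published standardized effects", {
  # dz = t / sqrt(n) identity against the printed test statistics
  cases <- list(c(t = 8.91, n = 44, dz = 1.34),
                c(t = 7.43, n = 44, dz = 1.12),
                c(t = 11.05, n = 34, dz = 1.90),
                c(t = 6.15, n = 34, dz = 1.05))
  for (cs in cases) {
    expect_equal(round(cs[["t"]] / sqrt(cs[["n"]]), 2), cs[["dz"]])
  }
  # and on actual data the identity holds to 1e-9
  set.seed(5)
  x <- rnorm(34, 1, 2); y <- rnorm(34)
  tt <- paired_t(x, y)
  expect_equal(tt$dz, tt$statistic / sqrt(tt$n), tolerance = 1e-9)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(tt$statistic, unname(ref$statistic))
  expect_equal(tt$p, ref$p.value)
  expect_equal(tt$ci, as.vector(ref$conf.int))
})

test_that("degenerate paired inputs are flagged, identical inputs null", {
  same <- paired_t(1:10, 1:10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  const <- paired_t(rep(3, 10), rep(1, 10))
  expect_true(const$zero_variance)
  expect_equal(const$statistic, Inf)
})

test_that("one-tailed intervals have a single finite bound", {
  set.seed(6)
  up <- paired_t(rnorm(20, 1), rnorm(20), tail = "upper")
  expect_equal(up$ci[2], Inf)
  expect_true(is.finite(up$ci[1]))
  lo <- paired_t(rnorm(20, 1), rnorm(20), tail = "lower")
  expect_equal(lo$ci[1], -Inf)
  expect_true(is.finite(lo$ci[2]))
})

test_that("repeated-measures ANOVA agrees with car and the t-identity", {
  set.seed(3)
  n <- 12
  d <- tidyr::crossing(participant_id = 1:n, a = c("c", "e"),
                       b = paste0("q", 1:4))
  d$y <- rnorm(nrow(d)) + rep(rnorm(n), each = 8) +
    as.numeric(factor(d$b)) * 0.5
  an <- rm_anova(d, "y", c("a", "b"))
  w <- tidyr::pivot_wider(d, names_from = c("a", "b"), values_from = "y")
  Y <- as.matrix(w[, -1])
  idata <- data.frame(a = factor(rep(c("c", "e"), each = 4)),
                      b = factor(rep(paste0("q", 1:4), 2)))
  s <- suppressWarnings(summary(car::Anova(lm(Y ~ 1), idata = idata,
                                           idesign = ~ a * b, type = 3),
                                multivariate = FALSE))
  u <- s$univariate.tests
  tab <- an$table
  for (eff in c("a", "b", "a:b")) {
    expect_equal(tab$statistic[tab$effect == eff], u[eff, "F value"],
                 tolerance = 1e-8)
    expect_equal(tab$p[tab$effect == eff], u[eff, "Pr(>F)"],
                 tolerance = 1e-8)
  }
  gg <- s$pval.adjustments
  expect_equal(tab$gg_epsilon[tab$effect == "b"], gg["b", "GG eps"],
               tolerance = 1e-8)
  expect_equal(tab$p_gg[tab$effect == "b"], gg["b", "Pr(>F[GG])"],
               tolerance = 1e-8)
  expect_equal(tab$gg_epsilon[tab$effect == "a:b"], gg["a:b", "GG eps"],
               tolerance = 1e-8)
  # partial eta^2 identity for df1 = 1 effects
  Fa <- tab$statistic[tab$effect == "a"]
  expect_equal(tab$pes[tab$effect == "a"], Fa / (Fa + tab$df2[tab$effect == "a"]),
               tolerance = 1e-9)
  # epsilon bounds
  expect_true(all(tab$gg_epsilon >= 1 / (tab$df1) - 1e-9, na.rm = TRUE))
  expect_true(all(tab$gg_epsilon <= 1 + 1e-9, na.rm = TRUE))
})

test_that("2x2 effects equal squared paired t-tests on the contrasts", {
  set.seed(9)
  n <- 15
  d <- tidyr::crossing(participant_id = 1:n, acc = c("c", "e"),
                       win = c("pre", "post"))
  d$y <- rnorm(nrow(d), 100, 10) + (d$acc == "c") * 5
  an <- rm_anova(d, "y", c("acc", "win"))
  w <- tidyr::pivot_wider(d, names_from = c("acc", "win"),
                          values_from = "y")
  t_acc <- paired_t((w$c_pre + w$c_post) / 2, (w$e_pre + w$e_post) / 2)
  expect_equal(an$table$statistic[an$table$effect == "acc"],
               t_acc$statistic^2, tolerance = 1e-9)
  t_int <- paired_t(w$c_pre - w$c_post, w$e_pre - w$e_post)
  expect_equal(an$table$statistic[an$table$effect == "acc:win"],
               t_int$statistic^2, tolerance = 1e-9)
  # duplicated data across a factor: F = 0
  d2 <- tidyr::crossing(participant_id = 1:n, a = c("x", "y"))
  base <- rnorm(n)
  d2$y <- rep(base, each = 2)
  an2 <- rm_anova(d2, "y", "a")
  expect_equal(an2$table$statistic, 0)
  expect_error(rm_anova(d2[-1, ], "y", "a"), "missing")
})

test_that("published F values convert to partial eta squared", {
  expect_equal(round(127.22 / (127.22 + 33), 2), 0.79)
  expect_equal(round(284.70 / (284.70 + 33), 2), 0.90)
})

test_that("ntiles bins by rank with ties to the lower bin", {
  expect_equal(ntiles(1:8, 4), c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(ntiles(rep(7, 6), 4), rep(1L, 6))
  x <- c(5, 1, 9, 3, 7, 2, 8, 4)
  b <- ntiles(x, 4)
  expect_equal(sort(as.vector(table(b))),
               sort(as.vector(table(ntiles(sort(x), 4)))))
  expect_true(max(table(b)) - min(table(b)) <= 1)
  expect_error(ntiles(1:3, 4), "fewer")
})

test_that("correlation test matches the printed t conversion", {
  expect_equal(round(0.22 * sqrt(32 / (1 - 0.22^2)), 2), 1.28)
  set.seed(12)
  x <- rnorm(34); y <- 0.3 * x + rnorm(34)
  ct <- pearson_correlation(x, y, tail = "upper")
  ref <- cor.test(x, y, alternative = "greater")
  expect_equal(ct$r, unname(ref$estimate))
  expect_equal(ct$p, ref$p.value)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_error(pearson_correlation(x, rep(1, 34)), "zero variance")
})

test_that("noncentral-t CI for dz reproduces the published interval", {
  expect_equal(round(ci_dz(1.34, 44), 2), c(0.93, 1.74))
  # symmetric around zero for a null effect
  z <- ci_dz(0, 20)
  expect_equal(z[1], -z[2], tolerance = 1e-6)
  # interval narrows with n
  w20 <- diff(ci_dz(0.8, 20)); w80 <- diff(ci_dz(0.8, 80))
  expect_lt(w80, w20)
})

test_that("JZS Bayes factor matches the independent quadrature oracle", {
  for (cs in list(c(0, 10), c(0.8, 34), c(2.5, 30), c(4, 16), c(6, 44))) {
    expect_equal(keyforce:::.jzs_bf(cs[1], cs[2], 1),
                 oracle_jzs(cs[1], cs[2], 1), tolerance = 1e-4)
  }
  # scale parameter is honoured
  expect_equal(keyforce:::.jzs_bf(2, 25, 0.707),
               oracle_jzs(2, 25, 0.707), tolerance = 1e-4)
  # reciprocal identity and null support direction
  set.seed(30)
  b <- bayes_t_paired(rnorm(50, 0, 1))
  expect_equal(b$bf10 * b$bf01, 1, tolerance = 1e-9)
  expect_gt(b$bf01, 1)
  # monotone in |t| at fixed n
  grid <- vapply(seq(0, 6, by = 0.5), keyforce:::.jzs_bf, 0, n = 34)
  expect_true(all(diff(grid) > 0))
})

test_that("stretched-beta correlation BF reproduces the published value", {
  b <- bayes_correlation(0.22, 34, tail = "upper", width = 1 / 3)
  expect_lt(abs(b$bf10 - 1.31), 0.05)
  expect_equal(b$bf10 * b$bf01, 1, tolerance = 1e-9)
  # direction: null-consistent data favour the null
  expect_lt(bayes_correlation(0, 10)$bf10, 1)
  # monotone in r >= 0 at fixed n
  bfs <- vapply(seq(0, 0.8, by = 0.1), function(r)
    bayes_correlation(r, 34, tail = "upper")$bf10, 0)
  expect_true(all(diff(bfs) > 0))
  expect_error(bayes_correlation(1, 34), "inside")
})

test_that("power solvers reproduce the planned sample sizes", {
  expect_equal(as.integer(solve_power_paired_t(0.93, 0.99)), 23L)
  expect_equal(as.integer(solve_power_paired_t(0.65, 0.95)), 33L)
  # the continuous solution matches power.t.test
  n_cont <- attr(solve_power_paired_t(0.93, 0.99), "n_continuous")
  expect_equal(n_cont, power.t.test(delta = 0.93, sd = 1, power = 0.99,
                                    type = "paired")$n, tolerance = 1e-5)
  # guaranteed-power rounding: power(n) >= target and power(n - 1) < target
  for (cs in list(c(0.93, 0.99), c(0.65, 0.95), c(0.4, 0.8))) {
    n <- as.integer(solve_power_paired_t(cs[1], cs[2], rounding = "ceiling"))
    expect_gte(power_paired_t(n, cs[1]), cs[2])
    expect_lt(power_paired_t(n - 1, cs[1]), cs[2])
  }
  # power nondecreasing in n at fixed d
  p <- vapply(5:40, power_paired_t, 0, d = 0.5)
  expect_true(all(diff(p) > 0))
})

test_that("noncentral-t power agrees with Monte-Carlo rejection rates", {
  set.seed(77)
  n <- 23; d <- 0.93; reps <- 4000
  rej <- mean(replicate(reps, {
    x <- rnorm(n, d, 1)
    abs(mean(x) / (sd(x) / sqrt(n))) > qt(0.975, n - 1)
  }))
  p <- power_paired_t(n, d)
  expect_lt(abs(rej - p), 3 * sqrt(p * (1 - p) / reps))
})

test_that("correlation power solvers expose both approximations", {
  expect_equal(solve_power_correlation(0.81, 0.95, method = "t_fisher"), 11L)
  expect_equal(solve_power_correlation(0.81, 0.95, method = "fisher"), 12L)
  # n shrinks toward the minimum as r grows
  ns <- vapply(c(0.3, 0.5, 0.7, 0.9, 0.99), solve_power_correlation,
               0L, power = 0.95)
  expect_true(all(diff(ns) < 0))
  expect_lte(ns[length(ns)], 5L)
})

test_that("sequential BF trajectory applies the stopping rule", {
  set.seed(8)
  d <- rnorm(40, 2, 1)  # strong effect: BF01 drops below 0.1 quickly
  traj <- bf_trajectory(d)
  expect_true(any(traj$stopped))
  expect_equal(traj$decision[traj$bf01 < 0.1][1], "effect_supported")
  expect_equal(traj$n[nrow(traj)], 40)
})
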