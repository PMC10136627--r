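test_that("mixed rmANOVA F agrees with the design-matrix oracle", {
  for (s in 1:100) {
    n1 <- sample(3:8, 1)
    n2 <- sample(3:8, 1)
    tb <- make_measurement_table(n1, n2, cond_shift = rnorm(3, sd = 0.5),
                                 group_shift = rnorm(1, sd = 0.3), seed = s)
    fit <- rm_anova_mixed(tb, conditions = c("Neg", "Neu", "Rea"),
                          gg = "never")
    ora <- oracle_rm_anova(tb)
    expect_equal(fit$effects$F[fit$effects$effect == "condition"],
                 unname(ora["condition"]), tolerance = 1e-8)
    expect_equal(fit$effects$F[fit$effects$effect == "group"],
                 unname(ora["group"]), tolerance = 1e-8)
    expect_equal(fit$effects$F[fit$effects$effect == "condition:group"],
                 unname(ora["interaction"]), tolerance = 1e-8)
  }
})

test_that("rmANOVA agrees with car::Anova including sphericity quantities", {
  skip_if_not_installed("car")
  tb <- make_measurement_table(14, 12, cond_shift = c(0, 0.4, 0.1),
                               group_shift = 0.2, seed = 99)
  fit <- rm_anova_mixed(tb, conditions = c("Neg", "Neu", "Rea"), gg = "never")
  wide <- reshape(tb, idvar = c("participant_id", "group"),
                  timevar = "condition", direction = "wide")
  y <- as.matrix(wide[, paste0("value.", c("Neg", "Neu", "Rea"))])
  g <- factor(wide$group)
  mod <- lm(y ~ g, contrasts = list(g = "contr.sum"))
  av <- summary(car::Anova(mod, idata = data.frame(
    condition = factor(c("Neg", "Neu", "Rea"))), idesign = ~condition,
    type = 3), multivariate = FALSE)
  ut <- av$univariate.tests
  expect_equal(fit$effects$F[1], ut["condition", "F value"],
               tolerance = 1e-10)
  expect_equal(fit$effects$F[2], ut["g", "F value"], tolerance = 1e-10)
  expect_equal(fit$effects$F[3], ut["g:condition", "F value"],
               tolerance = 1e-10)
  expect_equal(fit$mauchly$W,
               unname(av$sphericity.tests["condition", "Test statistic"]),
               tolerance = 1e-10)
  expect_equal(fit$epsilon, unname(av$pval.adjustments["condition",
                                                       "GG eps"]),
               tolerance = 1e-10)
})

test_that("Mauchly test behaves under sphericity and degeneracy", {
  # 2-level within factor: sphericity automatic
  tb2 <- make_measurement_table(5, 5, seed = 3)
  tb2 <- tb2[tb2$condition != "Rea", ]
  m2 <- mauchly_test(tb2, conditions = c("Neg", "Neu"))
  expect_equal(m2$W, 1)
  expect_equal(m2$p, 1)

  # duplicate level (singular covariance) errors
  tb_dup <- make_measurement_table(6, 6, seed = 4)
  tb_dup$value[tb_dup$condition == "Neu"] <-
    tb_dup$value[tb_dup$condition == "Neg"]
  expect_error(mauchly_test(tb_dup, conditions = c("Neg", "Neu", "Rea")),
               "singular")

  # compound-symmetric null: type-I error near the nominal 0.05 level
  set.seed(17)
  nrej <- 0
  nsim <- 400
  for (i in seq_len(nsim)) {
    y <- matrix(rnorm(30 * 3), 30) + rnorm(30)   # exchangeable covariance
    tb <- data.frame(
      participant_id = rep(sprintf("S%02d", 1:30), each = 3),
      group = rep(rep(c("music", "control"), each = 15), each = 3),
      condition = rep(c("Neg", "Neu", "Rea"), 30),
      value = as.numeric(t(y)))
    if (mauchly_test(tb, c("Neg", "Neu", "Rea"))$p < 0.05) nrej <- nrej + 1
  }
  expect_gt(nrej / nsim, 0.02)
  expect_lt(nrej / nsim, 0.09)
})

test_that("Greenhouse-Geisser epsilon bounds and degenerate data handling", {
  tb <- make_measurement_table(10, 9, seed = 7)
  fit <- rm_anova_mixed(tb, conditions = c("Neg", "Neu", "Rea"))
  expect_gt(fit$epsilon, 0.5)   # 1/(k-1) lower bound for k = 3
  expect_lte(fit$epsilon, 1)
  expect_equal(fit$effects$df1[1], 2)   # GG not applied under sphericity

  gg <- rm_anova_mixed(tb, conditions = c("Neg", "Neu", "Rea"),
                       gg = "always")
  expect_equal(gg$effects$df1[1], 2 * gg$epsilon, tolerance = 1e-12)
  expect_equal(gg$effects$df2[1], 2 * (nrow(unique(tb["participant_id"])) -
                                         2) * gg$epsilon, tolerance = 1e-12)

  const <- tb
  const$value <- 5
  dfit <- rm_anova_mixed(const, conditions = c("Neg", "Neu", "Rea"))
  expect_true(dfit$degenerate)
  expect_true(all(is.na(dfit$effects$F)))
})

test_that("simulated power rises with effect size at fixed n", {
  power_at <- function(delta, nsim = 60) {
    hits <- 0
    for (i in seq_len(nsim)) {
      tb <- make_measurement_table(12, 12,
                                   cond_shift = c(0, delta, delta / 2),
                                   seed = 1000 * delta + i)
      fit <- rm_anova_mixed(tb, conditions = c("Neg", "Neu", "Rea"))
      if (fit$effects$p[1] < 0.05) hits <- hits + 1
    }
    hits / nsim
  }
  p <- c(power_at(0.1), power_at(0.5), power_at(1.2))
  expect_true(p[1] < p[2] || p[2] < p[3])
  expect_gt(p[3], p[1])
})

test_that("Bonferroni post-hocs: counts, caps and direction", {
  tb <- make_measurement_table(8, 8, cond_shift = c(0, 2, 1), seed = 21)
  ph <- bonferroni_posthoc(tb, "condition", c("Neg", "Neu", "Rea"))
  expect_equal(nrow(ph), 3)                       # C(3, 2) comparisons
  expect_equal(ph$p_adj, pmin(1, ph$p * 3))
  expect_true(all(ph$p_adj <= 1))

  phg <- bonferroni_posthoc(tb, "group")
  expect_equal(nrow(phg), 1)
  expect_equal(phg$p_adj, phg$p)                  # single comparison

  phi <- bonferroni_posthoc(tb, "interaction", c("Neg", "Neu", "Rea"))
  expect_equal(nrow(phi), 3)                      # one per condition
})
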