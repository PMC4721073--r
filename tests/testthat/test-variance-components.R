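one_way <- function(effects, resid, reps) {
  a <- length(effects)
  data.frame(seedlot_id = rep(paste0("P", seq_len(a)), each = reps),
             y = rep(effects, each = reps) + resid)
}

test_that("method-of-moments components match the hand expected-mean-squares solution", {
  # balanced one-way, 3 groups x 4 reps, integer data
  d <- one_way(c(0, 4, 8), c(-1, 1, -2, 2, 0, 2, -2, 0, 1, -1, 3, -3), 4)
  ac <- anova_components(d, "y", population = "seedlot_id")
  # independent EMS arithmetic on group means
  gm <- tapply(d$y, d$seedlot_id, mean)
  msb <- 4 * sum((gm - mean(d$y))^2) / 2
  msw <- sum((d$y - gm[d$seedlot_id])^2) / 9
  expect_equal(unname(ac["P"]), (msb - msw) / 4, tolerance = 1e-12)
  expect_equal(unname(ac["e"]), msw, tolerance = 1e-12)

  # zero between-group spread pins the population component at 0
  d0 <- one_way(c(0, 0, 0), rep(c(-1, 1), 6), 4)
  expect_equal(unname(anova_components(d0, "y")["P"]), 0)

  expect_error(
    anova_components(data.frame(seedlot_id = c("A", "A", "B"), y = 1:3), "y"),
    "unbalanced")
})

test_that("REML equals the balanced-ANOVA closed form to 1e-6", {
  set.seed(3)
  d <- one_way(c(0, 5, 9), round(rnorm(12, 0, 2)), 4)
  ac <- anova_components(d, "y")
  vd <- suppressWarnings(fit_reml(d, "y", environment = NULL, block = NULL,
                                  location = NULL))
  expect_equal(vd$components["P", "sigma2"], unname(ac["P"]), tolerance = 1e-6)
  expect_equal(vd$components["e", "sigma2"], unname(ac["e"]), tolerance = 1e-6)

  # balanced crossed two-way with interaction
  set.seed(4)
  dd <- expand.grid(seedlot_id = paste0("P", 1:6), chamber_id = paste0("E", 1:3),
                    rep = 1:4, stringsAsFactors = FALSE)
  pe <- interaction(dd$seedlot_id, dd$chamber_id)
  dd$y <- rnorm(6, 0, 3)[factor(dd$seedlot_id)] +
    rnorm(3, 0, 2)[factor(dd$chamber_id)] +
    rnorm(nlevels(pe), 0, 1.5)[pe] + rnorm(nrow(dd), 0, 1)
  ac2 <- anova_components(dd, "y")
  vd2 <- suppressWarnings(fit_reml(dd, "y", block = NULL, location = NULL))
  for (code in c("P", "E", "PE", "e"))
    expect_equal(vd2$components[code, "sigma2"], unname(ac2[code]),
                 tolerance = 1e-6)
})

test_that("REML estimates are shift invariant and scale as c^2", {
  set.seed(5)
  d <- one_way(rnorm(8, 0, 2), rnorm(40), 5)
  base <- fit_reml(d, "y", environment = NULL, se = FALSE)
  d2 <- d; d2$y <- d$y + 100
  shifted <- fit_reml(d2, "y", environment = NULL, se = FALSE)
  expect_equal(shifted$components$sigma2, base$components$sigma2,
               tolerance = 1e-6)
  d3 <- d; d3$y <- 3 * d$y
  scaled <- fit_reml(d3, "y", environment = NULL, se = FALSE)
  expect_equal(scaled$components$sigma2, 9 * base$components$sigma2,
               tolerance = 1e-6)
})

test_that("identical observations give an all-zero decomposition", {
  d <- one_way(c(7, 7, 7), rep(0, 12), 4)
  vd <- fit_reml(d, "y", environment = NULL)
  expect_true(all(vd$components$sigma2[!vd$components$dropped] == 0))
})

test_that("the in-package REML deviance agrees with lme4 and its Hessian SEs with the closed form", {
  set.seed(42)
  a <- 30; r <- 8
  d <- one_way(rnorm(a, 0, 2), rnorm(a * r, 0, sqrt(2)), r)
  fit <- lme4::lmer(y ~ (1 | seedlot_id), data = d, REML = TRUE)
  devf <- genecol:::reml_deviance_function(
    d$y, list(genecol:::fac2ind(d$seedlot_id)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(devf(vc$vcov), lme4::REMLcrit(fit), tolerance = 1e-8)

  vd <- fit_reml(d, "y", environment = NULL)
  s2p <- vd$components["P", "sigma2"]; s2e <- vd$components["e", "sigma2"]
  # exact sampling variances of the balanced one-way REML (= ANOVA) estimator
  vP <- 2 / r^2 * ((r * s2p + s2e)^2 / (a - 1) + s2e^2 / ((r - 1) * a))
  ve <- 2 * s2e^2 / (a * (r - 1))
  expect_equal(vd$components["P", "se"], sqrt(vP), tolerance = 0.01)
  expect_equal(vd$components["e", "se"], sqrt(ve), tolerance = 0.01)
})

test_that("a component truly at zero is pinned and flagged, SEs still reported", {
  set.seed(8)
  d <- one_way(rep(0, 10), rnorm(60), 6)   # no population variance planted;
  vd <- fit_reml(d, "y", environment = NULL)  # this draw estimates P at 0
  expect_lt(vd$components["P", "sigma2"], 1e-8)
  expect_true(vd$components["P", "pinned"])
  expect_true(is.finite(vd$components["P", "se"]))
})

test_that("percent components rescale to a 100% total", {
  v <- c(9.3, 35.9, 3.9, 3.1, 1.4, 46.4)   # already sums to 100
  expect_equal(percent_components(v), v)
  expect_equal(sum(percent_components(c(2, 5, 13))), 100)
  expect_equal(percent_components(c(0, 7, 0)), c(0, 100, 0))
  expect_equal(percent_components(rep(3, 6)), rep(100 / 6, 6))
  expect_error(percent_components(c(0, 0)), "zero")
})

test_that("V_pop reproduces the printed worked examples and is monotone", {
  expect_equal(round(100 * vpop(14.8, 62.0), 1), 19.3)
  expect_equal(round(100 * vpop(21.3, 76.4), 1), 21.8)
  expect_equal(vpop(0, 5), 0)
  expect_error(vpop(0, 0), "zero")
  expect_error(vpop(-1, 5), ">= 0")
  # monotone increasing in sigma2_P, decreasing in sigma2_e
  sp <- seq(0.5, 30, length.out = 15)
  expect_true(all(diff(vpop(sp, 50)) > 0))
  se <- seq(10, 90, length.out = 15)
  expect_true(all(diff(vpop(10, se)) < 0))
})

test_that("the propagated V_pop standard error follows the sum and ratio rules", {
  expect_equal(vpop_se(1, 0, 3, 0), 0)
  # frozen from direct evaluation of the propagation formulas:
  # SE_sum = sqrt(2.1^2 + 2.4^2) = 3.18904374; SE = (14.8/76.8) *
  #   sqrt((2.1/14.8)^2 + (3.18904374/76.8)^2) = 0.02849058
  expect_equal(vpop_se(14.8, 2.1, 62.0, 2.4), 0.02849058, tolerance = 1e-6)
  # invariant under common rescaling of all four inputs
  expect_equal(vpop_se(29.6, 4.2, 124.0, 4.8), vpop_se(14.8, 2.1, 62.0, 2.4),
               tolerance = 1e-12)
  expect_error(vpop_se(0, 1, 5, 1), "positive")
})
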