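# independent sums-of-squares oracle for a one-factor within design,
# written from the definitional formulas
ss_oracle_oneway <- function(y, subj, fac) {
  gm <- mean(y)
  m_f <- tapply(y, fac, mean); m_s <- tapply(y, subj, mean)
  m_sf <- tapply(y, list(subj, fac), mean)
  n_s <- length(unique(subj)); n_f <- length(unique(fac))
  ss_f <- n_s * sum((m_f - gm)^2)
  resid <- sweep(sweep(m_sf, 2, m_f), 1, m_s) + gm
  ss_err <- sum(resid^2)
  list(F = (ss_f / (n_f - 1)) / (ss_err / ((n_s - 1) * (n_f - 1))),
       df1 = n_f - 1, df2 = (n_s - 1) * (n_f - 1),
       eta = ss_f / (ss_f + ss_err))
}

test_that("two-level rm-ANOVA F equals the squared paired t", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(6:14, 1)
    d <- data.frame(s = rep(1:n, 2), f = rep(c("a", "b"), each = n),
                    y = rnorm(2 * n))
    res <- rm_anova(d, "y", "s", "f")
    tt <- t.test(d$y[d$f == "a"], d$y[d$f == "b"], paired = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p, tt$p.value, tolerance = 1e-9)
    expect_equal(res$epsilon, 1)
  }
})

test_that("identical condition means give F ~ 0", {
  d <- expand.grid(s = 1:6, f = c("a", "b", "c"))
  d$y <- rnorm(6)[d$s]  # subject effect only
  res <- rm_anova(d, "y", "s", "f", correction = "never")
  expect_lt(res$F, 1e-20)
})

test_that("three-level design matches the brute-force SS decomposition and aov", {
  set.seed(12)
  n <- 10
  d <- expand.grid(s = factor(1:n), f = factor(c("x", "y", "z")))
  d$y <- rnorm(3 * n) + rep(c(0, 0.5, 0.2), each = n) + rnorm(n)[d$s]
  res <- rm_anova(d, "y", "s", "f", correction = "never")
  orc <- ss_oracle_oneway(d$y, d$s, d$f)
  expect_equal(res$F, orc$F, tolerance = 1e-9)
  expect_equal(res$df_num, orc$df1)
  expect_equal(res$df_den, orc$df2)
  expect_equal(res$partial_eta_sq, orc$eta, tolerance = 1e-9)
  # aov Error-strata cross-check
  fit <- summary(aov(y ~ f + Error(s / f), data = d))
  Ftab <- fit[["Error: s:f"]][[1]]
  expect_equal(res$F, Ftab["f", "F value"], tolerance = 1e-9)
})

test_that("two-way within design: all effects match aov", {
  set.seed(30)
  n <- 8
  d <- expand.grid(s = factor(1:n), a = factor(c("a1", "a2", "a3")),
                   b = factor(c("b1", "b2")))
  d$y <- rnorm(nrow(d)) + as.numeric(d$a) * 0.4 +
    as.numeric(d$a) * as.numeric(d$b) * 0.2
  res <- rm_anova(d, "y", "s", c("a", "b"), correction = "never")
  fit <- summary(aov(y ~ a * b + Error(s / (a * b)), data = d))
  expect_equal(res$F[res$effect == "a"],
               fit[["Error: s:a"]][[1]]["a", "F value"], tolerance = 1e-9)
  expect_equal(res$F[res$effect == "b"],
               fit[["Error: s:b"]][[1]]["b", "F value"], tolerance = 1e-9)
  expect_equal(res$F[res$effect == "a:b"],
               fit[["Error: s:a:b"]][[1]]["a:b", "F value"], tolerance = 1e-9)
})

test_that("Greenhouse-Geisser epsilon matches the car reference", {
  set.seed(44)
  n <- 12
  wide <- matrix(rnorm(n * 3), n, 3) %*% chol(matrix(c(1, .7, .2,
                                                       .7, 1, .5,
                                                       .2, .5, 1), 3))
  d <- data.frame(s = factor(rep(1:n, 3)),
                  f = factor(rep(c("l1", "l2", "l3"), each = n)),
                  y = as.vector(wide))
  res <- rm_anova(d, "y", "s", "f", correction = "always")
  idata <- data.frame(f = factor(c("l1", "l2", "l3")))
  mod <- car::Anova(lm(wide ~ 1), idata = idata, idesign = ~f, type = 3)
  s <- summary(mod, multivariate = FALSE)
  gg_car <- s$pval.adjustments["f", "GG eps"]
  mauchly_car <- s$sphericity.tests["f", "p-value"]
  expect_equal(res$epsilon, unname(gg_car), tolerance = 1e-6)
  expect_equal(res$sphericity_p, unname(mauchly_car), tolerance = 1e-6)
})

test_that("null p-values are uniform (KS) for two-level designs", {
  set.seed(60)
  ps <- replicate(600, {
    n <- 10
    d <- data.frame(s = rep(1:n, 2), f = rep(c("a", "b"), each = n),
                    y = rnorm(2 * n))
    rm_anova(d, "y", "s", "f")$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("partial eta squared is invariant to affine response rescaling", {
  set.seed(9)
  d <- expand.grid(s = factor(1:8), f = factor(c("a", "b", "c")))
  d$y <- rnorm(24)
  e1 <- rm_anova(d, "y", "s", "f", correction = "never")$partial_eta_sq
  d$y <- 3.7 * d$y - 11
  e2 <- rm_anova(d, "y", "s", "f", correction = "never")$partial_eta_sq
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("missing cells are rejected with an informative error", {
  d <- expand.grid(s = 1:4, f = c("a", "b"))
  d$y <- rnorm(8)
  expect_error(rm_anova(d[-1, ], "y", "s", "f"), "missing cell")
})

test_that("Bonferroni display convention and post-hoc flags", {
  mc <- multiple_comparisons(0.05, 8)
  expect_equal(mc$corrected_alpha, 0.00625)
  expect_equal(mc$corrected_alpha_display, 0.0063)
  set.seed(2)
  x <- rnorm(12, 1); y <- rnorm(12)
  out <- posthoc_t(list(big = list(x = x, y = y),
                        null = list(x = y, y = y)),
                   multiple_comparisons(0.05, 2))
  # closed form d-bar / (s_d / sqrt(n)) via the independent t.test route
  tt <- t.test(x, y, paired = TRUE)
  expect_equal(out$t[1], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(out$t[2], 0)
  expect_equal(out$p[2], 1)
  expect_false(out$significant[2])
})

test_that("Hedges g_rm follows its definitional formula", {
  x1 <- c(10, 12, 14, 16, 18, 20)
  x2 <- c(9, 13, 12, 17, 16, 21)
  # step-by-step hand computation
  s1 <- sd(x1); s2 <- sd(x2); r <- cor(x1, x2)
  g_hand <- (mean(x1) - mean(x2)) / sqrt(s1^2 + s2^2 - 2 * r * s1 * s2) *
    sqrt(2 * (1 - r)) * (1 - 3 / (4 * 5 - 1))
  out <- hedges_g_rm(x1, x2)
  expect_equal(out$g_rm, g_hand, tolerance = 1e-12)
  expect_equal(out$r_pair, r)
  # antisymmetry and null cases
  expect_equal(hedges_g_rm(x2, x1)$g_rm, -g_hand, tolerance = 1e-12)
  # equal means (different scores) -> g = 0
  expect_equal(hedges_g_rm(x1, x1 + c(-1, 1, -1, 1, -1, 1))$g_rm, 0)
  expect_warning(g0 <- hedges_g_rm(x1, x1 + 5), "denominator")
  expect_true(is.na(g0$g_rm))
})
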