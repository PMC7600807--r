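test_that("region means reduce to single voxels, constants, and brute force", {
  st <- make_stack(3, 3, grid = c(3L, 3L, 2L), seed = 20)
  one <- rep(FALSE, ncol(st$data)); one[5] <- TRUE
  expect_equal(unname(region_means(st, one)), unname(st$data[, 5]))

  st2 <- st; st2$data[] <- 7.5
  expect_equal(unname(region_means(st2, rep(TRUE, ncol(st2$data)))),
               rep(7.5, 6))

  region <- seq_len(ncol(st$data)) %% 3 == 1
  brute <- vapply(seq_len(nrow(st$data)),
                  function(i) mean(st$data[i, region]), numeric(1))
  expect_equal(unname(region_means(st, region)), brute, tolerance = 1e-12)

  expect_error(region_means(st, rep(FALSE, ncol(st$data))), "empty")
})

test_that("Cohen's D for unequal variances follows its definition", {
  expect_equal(cohens_d_unequal(5, 3, 5, 8), 0)
  expect_equal(cohens_d_unequal(0, 2, 1, 2), 1 / sqrt(2))
  expect_equal(round(cohens_d_unequal(-258, 1952, 402, 68216), 2), 3.52)
  expect_error(cohens_d_unequal(1, 0, 2, 0), "undefined")
})

test_that("Welch test matches the textbook formula and handles identity", {
  vals <- c(4, 7, 9, 4, 7, 9)
  labs <- rep(c("control", "patient"), each = 3)
  w <- welch_ttest(vals, labs)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)

  set.seed(23)
  v2 <- rnorm(12); l2 <- rep(c("control", "patient"), each = 6)
  w2 <- welch_ttest(v2, l2)
  o <- welch_oracle(v2[l2 == "patient"], v2[l2 == "control"])
  expect_equal(w2$t, o$t, tolerance = 1e-10)
  expect_equal(w2$df, o$df, tolerance = 1e-10)
  expect_equal(w2$p, o$p, tolerance = 1e-10)

  expect_error(welch_ttest(c(1, 2, 3), c("control", "patient", "patient")),
               ">= 2 subjects")
})

test_that("whole-thalamus summary moments give the published Welch p of 0.01", {
  ctl <- sample_with_moments(16, -57, 342, seed = 61)
  pat <- sample_with_moments(16, -41, 242, seed = 62)
  w <- welch_ttest(c(ctl, pat), rep(c("control", "patient"), each = 16))
  expect_equal(round(w$p, 2), 0.01)
})

test_that("effect-coded regression interpolates exact generative coefficients", {
  set.seed(24)
  g <- rep(c(1, -1), each = 8)
  x <- runif(16, 3, 17)
  y <- 5 + 3 * g + 2 * x + 1 * g * x
  labs <- ifelse(g > 0, "patient", "control")
  fit <- suppressWarnings(effect_coded_regression(y, x, labs))
  expect_equal(fit$coefficients$estimate,
               c(5, -3, 3, 2, -1, 1), tolerance = 1e-10)
})

test_that("group deviations are exact mirror pairs sharing one standard error", {
  set.seed(25)
  labs <- rep(c("control", "patient"), each = 10)
  x <- runif(20, 3, 17)
  y <- rnorm(20, 10 + 2 * x + 3 * (labs == "patient") * x, 5)
  tab <- effect_coded_regression(y, x, labs)$coefficients
  expect_equal(tab$estimate[2], -tab$estimate[3])
  expect_equal(tab$estimate[5], -tab$estimate[6])
  expect_equal(tab$std_error[2], tab$std_error[3])
  expect_equal(tab$std_error[5], tab$std_error[6])
  expect_equal(tab$p[5], tab$p[6])
})

test_that("estimates and standard errors match a normal-equations oracle", {
  set.seed(26)
  labs <- rep(c("control", "patient"), 8)
  x <- runif(16, 3, 17)
  y <- rnorm(16, 4 + x, 3)
  fit <- effect_coded_regression(y, x, labs)
  g <- ifelse(labs == "patient", 1, -1)
  X <- cbind(1, g, x, g * x)
  o <- ls_oracle(X, matrix(y))
  sigma2 <- sum(o$resid^2) / (16 - 4)
  se <- sqrt(diag(o$cov_unscaled) * sigma2)
  # package rows 1,3,4,6 are (Intercept, g, x, g:x) in patient orientation
  expect_equal(fit$coefficients$estimate[c(1, 3, 4, 6)], as.vector(o$coef),
               tolerance = 1e-8)
  expect_equal(fit$coefficients$std_error[c(1, 3, 4, 6)], unname(se),
               tolerance = 1e-8)
})

test_that("sequential ANCOVA decomposes the total sum of squares", {
  set.seed(27)
  labs <- rep(c("control", "patient"), each = 16)
  x <- c(runif(16, 7.1, 16.7), runif(16, 3.4, 17))
  y <- rnorm(32, -170 + 24 * x + 29 * (labs == "patient") * x, 117)
  an <- ancova_table(y, x, labs)
  expect_equal(an$term, c("Group", "Age", "Group x Age", "Error"))
  expect_equal(an$df, c(1, 1, 1, 28))           # n - 4 = 28 for 32 subjects
  expect_equal(sum(an$df), 31)
  expect_equal(sum(an$sum_sq), sum((y - mean(y))^2), tolerance = 1e-8)
})

test_that("interaction F equals the squared effect-coded t", {
  set.seed(28)
  labs <- rep(c("control", "patient"), each = 12)
  x <- runif(24, 3, 17)
  y <- rnorm(24, 5 + x + 2 * (labs == "patient") * x, 10)
  an <- ancova_table(y, x, labs)
  ec <- effect_coded_regression(y, x, labs)
  t_int <- ec$coefficients$t[ec$coefficients$term == "da Patients"]
  expect_equal(an$F[3], t_int^2, tolerance = 1e-8)
  expect_equal(an$p[3], ec$coefficients$p[6], tolerance = 1e-8)
})

test_that("group-only responses put no sequential SS on Age or interaction", {
  labs <- rep(c("control", "patient"), each = 8)
  x <- c(seq(4, 16, length.out = 8), seq(5, 15, length.out = 8))
  y <- ifelse(labs == "patient", 10, -10)
  an <- suppressWarnings(ancova_table(y, x, labs))
  expect_lt(an$sum_sq[2], 1e-16 * an$sum_sq[1])
  expect_lt(an$sum_sq[3], 1e-16 * an$sum_sq[1])
})

test_that("the additive-model age p agrees with a direct sequential fit", {
  set.seed(29)
  labs <- rep(c("control", "patient"), each = 10)
  x <- runif(20, 3, 17)
  y <- rnorm(20, 2 * x, 8)
  p <- anova_age_effect(y, x, labs)
  ref <- anova(lm(y ~ factor(labs) + x))
  expect_equal(p, ref$`Pr(>F)`[2], tolerance = 1e-12)

  # noiseless age-linear response with equal slopes: essentially zero p
  y2 <- 3 * x
  expect_lt(suppressWarnings(anova_age_effect(y2, x, labs)), 1e-12)
})

test_that("null ANCOVA p-values are approximately uniform", {
  set.seed(30)
  ps <- replicate(300, {
    labs <- rep(c("control", "patient"), each = 10)
    x <- runif(20, 3, 17)
    y <- rnorm(20)
    ancova_table(y, x, labs)$p[1:3]
  })
  for (row in 1:3) {
    expect_gt(suppressWarnings(ks.test(ps[row, ], "punif"))$p.value, 0.001)
  }
})

test_that("adding a constant shifts intercepts but no other statistic", {
  set.seed(31)
  labs <- rep(c("control", "patient"), each = 12)
  x <- runif(24, 3, 17)
  y <- rnorm(24, 10 + 3 * x + 5 * (labs == "patient"), 6)
  r1 <- stats_report(y, x, labs)
  r2 <- stats_report(y + 1000, x, labs)
  expect_equal(r2$cohens_d, r1$cohens_d)
  expect_equal(r2$welch$p, r1$welch$p)
  expect_equal(r2$anova_age_p, r1$anova_age_p)
  expect_equal(r2$ancova$F[1:3], r1$ancova$F[1:3])
  t1 <- r1$effect_coded$coefficients; t2 <- r2$effect_coded$coefficients
  expect_equal(t2$estimate[t2$term == "Slope a"],
               t1$estimate[t1$term == "Slope a"])
  expect_equal(t2$estimate[t2$term == "Intercept b"],
               t1$estimate[t1$term == "Intercept b"] + 1000)
})

test_that("the report's Cohen's D is consistent with its own group summary", {
  set.seed(32)
  labs <- rep(c("control", "patient"), each = 9)
  x <- runif(18, 3, 17)
  y <- rnorm(18, ifelse(labs == "patient", 30, 0), 10)
  rep_ <- stats_report(y, x, labs)
  gs <- rep_$group_summary
  expect_equal(rep_$cohens_d,
               cohens_d_unequal(gs$control$mean, gs$control$variance,
                                gs$patient$mean, gs$patient$variance))
  expect_true(all(c(rep_$welch$p, rep_$anova_age_p,
                    rep_$effect_coded$coefficients$p) > 0))
})
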