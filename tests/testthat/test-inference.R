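# Bayesian bands, ANOVA components, group differences, effect summaries.

fit_demo <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- withr::with_seed(31, {
        day <- c(0, 160, sample(0:160, 598, replace = TRUE))
        grp <- rep(c("PEER", "control"), 300)
        mu <- 100 + 20 * sin(2 * pi * day / 160) +
          15 * (grp == "PEER") * sin(pi * day / 160)
        data.frame(day = day, group = grp, y = rnorm(600, mu, 10))
      })
      cache <<- pa_ssanova(y ~ day + group, d, family = "gaussian")
    }
    cache
  }
})

test_that("posterior sd is positive, edge-inflated and shrinks with n", {
  fit <- fit_demo()
  sd <- posterior_sd(fit, 0:160, "PEER")
  expect_true(all(sd > 0))
  expect_gt(mean(sd[c(1:5, 157:161)]), mean(sd[75:85]))
  # noiseless limit
  fit0 <- fit
  fit0$dispersion <- 0
  expect_equal(max(posterior_sd(fit0, 0:160, "PEER")), 0)
  # doubling n on the same design shrinks the posterior sd
  d2 <- withr::with_seed(32, {
    day <- c(0, 160, sample(0:160, 1198, replace = TRUE))
    grp <- rep(c("PEER", "control"), 600)
    mu <- 100 + 20 * sin(2 * pi * day / 160) +
      15 * (grp == "PEER") * sin(pi * day / 160)
    data.frame(day = day, group = grp, y = rnorm(1200, mu, 10))
  })
  fit2 <- pa_ssanova(y ~ day + group, d2, family = "gaussian")
  expect_lt(median(posterior_sd(fit2, 0:160, "PEER")),
            median(posterior_sd(fit, 0:160, "PEER")))
  # a non-converged fit refuses to produce bands
  bad <- fit
  bad$converged <- FALSE
  expect_error(posterior_sd(bad, 0:160, "PEER"), "converge")
  expect_error(predict_band(bad, "PEER", 0:160), "converge")
})

test_that("bands use the requested Normal quantile and stay positive for Gamma", {
  fit <- fit_demo()
  b <- predict_band(fit, "control", 0:160, level = 0.95)
  sd <- posterior_sd(fit, 0:160, "control")
  expect_equal(max(abs((b$hi - b$fit) / sd - qnorm(0.975))), 0,
               tolerance = 1e-6)
  expect_true(all(b$lo <= b$fit & b$fit <= b$hi))
  expect_error(predict_band(fit, "control", 0:160, level = 1.2), "level")

  dg <- withr::with_seed(33, {
    day <- c(0, 60, sample(0:60, 198, replace = TRUE))
    grp <- rep(c("PEER", "control"), 100)
    mu <- exp(1 + 0.5 * sin(2 * pi * day / 60) + 0.3 * (grp == "PEER"))
    data.frame(day = day, group = grp, y = rgamma(200, 2, scale = mu / 2))
  })
  fg <- pa_ssanova(y ~ day + group, dg, family = "gamma")
  bg <- predict_band(fg, "PEER", 0:60)
  expect_true(all(bg$lo > 0))
  expect_true(all(bg$lo <= bg$fit & bg$fit <= bg$hi))
})

test_that("workout-day band arithmetic equals the parametric jump", {
  d <- withr::with_seed(34, {
    day <- c(0, 160, sample(0:160, 598, replace = TRUE))
    grp <- rep(c("PEER", "control"), 300)
    wd <- seq(3, 52, by = 7)
    z <- as.numeric(day %in% wd & grp == "PEER")
    mu <- 100 + 20 * sin(2 * pi * day / 160) + 25 * z
    data.frame(day = day, group = grp, workout = z,
               y = rnorm(600, mu, 8))
  })
  fit <- pa_ssanova(y ~ day + group, d, workout = "workout")
  wd <- seq(3, 52, by = 7)
  b1 <- predict_band(fit, "PEER", wd, include_z = TRUE, workout_days = wd)
  b0 <- predict_band(fit, "PEER", wd, include_z = FALSE)
  expect_equal(b1$fit - b0$fit, rep(fit$beta_z, length(wd)))
})

test_that("ANOVA components satisfy the side conditions and reassemble the fit", {
  fit <- fit_demo()
  days <- 0:160
  cP <- ssanova_components(fit, days, "PEER")
  cC <- ssanova_components(fit, days, "control")
  prP <- predict(fit, data.frame(day = days, group = "PEER"), include_z = FALSE)
  expect_lt(max(abs(cP$eta0 + cP$eta1 + cP$eta2 + cP$eta12 - prP)), 1e-8)
  # group-side conditions are exact under +-1/2 coding
  expect_equal(cP$eta2, -cC$eta2)
  expect_lt(max(abs(cP$eta12 + cC$eta12)), 1e-12)
  # the time main effect averages out over the grid
  expect_lt(abs(mean(cP$eta1)), 0.02 * max(abs(cP$eta1)) + 1e-8)
})

test_that("group difference matches the contrast algebra and its window average", {
  fit <- fit_demo()
  days <- 0:160
  gd <- group_difference(fit, days)
  cP <- ssanova_components(fit, days, "PEER")
  expect_equal(gd$diff, 2 * (cP$eta2 + cP$eta12))
  expect_true(all(gd$sd > 0))
  records <- data.frame(participant_id = rep(c("a", "b", "c", "d"), 25),
                        group = rep(c("PEER", "control"), 50),
                        day = rep(0:24, each = 4), y = rnorm(100, 100))
  ws <- window_summary(fit, records, "y", 0:55)
  expect_equal(ws$mean_daily_diff, mean(gd$diff[days %in% 0:55]))
})

test_that("no-group-effect data keep the difference band around zero", {
  d <- null_gaussian_data(600, seed = 35, sd = 15)
  fit <- pa_ssanova(y ~ day + group, d)
  gd <- group_difference(fit, 0:160)
  expect_gte(mean(gd$lo <= 0 & gd$hi >= 0), 0.90)
})

test_that("with no interaction the estimated interaction stays within noise", {
  # posterior sd of the interaction component alone: zero out the other
  # columns of the evaluation matrix
  sd_eta12 <- function(fit, days) {
    tt <- scale_time(days, fit$domain)
    K <- passanova:::cubic_kernel_matrix(tt, fit$basis_t)
    E12 <- cbind(0, 0, 0, k1(tt) * 0.5,
                 fit$theta[2] * 0.5 * sweep(K, 2, fit$basis_gc, "*"))
    passanova:::posterior_sd_rows(fit, E12)
  }
  hits <- 0L
  for (r in 1:10) {
    d <- withr::with_seed(400 + r, {
      day <- c(0, 160, sample(0:160, 398, replace = TRUE))
      grp <- rep(c("PEER", "control"), 200)
      # group main effect but no time x group interaction
      mu <- 80 + 25 * sin(2 * pi * day / 160) + 10 * (grp == "PEER")
      data.frame(day = day, group = grp, y = rnorm(400, mu, 12))
    })
    fit <- pa_ssanova(y ~ day + group, d)
    cP <- ssanova_components(fit, 0:160, "PEER")
    sd12 <- sd_eta12(fit, 0:160)
    if (mean(abs(cP$eta12) <= 1.96 * sd12) >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("percent change reproduces the printed effect arithmetic", {
  expect_equal(percent_change(-53.09, 795), -6.7)
  expect_equal(percent_change(0.15, 1.09), 13.8)
  expect_equal(percent_change(0.21, 7.43), 2.8)
  expect_error(percent_change(10, 0), "positive")
  expect_error(percent_change(10, -5), "positive")
})

test_that("Cohen's d matches its pooled-variance definition", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(4.2, 5.5, 3.3, 6.1); b <- c(5.0, 4.4, 6.6)
  expect_equal(cohens_d(a + 10, b + 10), cohens_d(a, b))
  expect_error(cohens_d(numeric(0), b), "nonempty")
  expect_error(cohens_d(c(1, 1), c(1, 1)), "positive")
})

test_that("window summaries recover an injected constant group offset", {
  d <- withr::with_seed(36, {
    day <- c(0, 160, sample(0:160, 598, replace = TRUE))
    grp <- rep(c("PEER", "control"), 300)
    mu <- 700 + 30 * sin(2 * pi * day / 160) - 30 * (grp == "PEER")
    data.frame(participant_id = paste0(grp, rep(1:30, 20)),
               group = grp, day = day, sed = rnorm(600, mu, 40))
  })
  fit <- pa_ssanova(sed ~ day + group, d)
  ws <- window_summary(fit, d, "sed", 0:55)
  expect_gte(ws$mean_daily_diff, -40)
  expect_lte(ws$mean_daily_diff, -20)
  expect_lt(ws$ci95["lo"], ws$mean_daily_diff)
  expect_gt(ws$ci95["hi"], ws$mean_daily_diff)
  # self-consistent percent change
  expect_equal(ws$pct_change,
               percent_change(ws$mean_daily_diff, ws$baseline))
  expect_lt(ws$cohens_d, 0)
  expect_error(window_summary(fit, d, "sed", integer(0)), "empty")
  expect_error(window_summary(fit, d, "sed", 500:600), "outside")
})
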