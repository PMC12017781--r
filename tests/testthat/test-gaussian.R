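# Penalized least-squares engine: assembly, solving, smoother trace, GCV.

test_that("assembled design has the right block shapes", {
  des <- toy_design(10, seed = 5)
  b <- passanova:::assemble_system(des$tt, des$gc, NULL, c(1, 1))
  expect_equal(ncol(b$S), 4)
  expect_lte(b$q, 10)
  desz <- toy_design(30, seed = 5)
  z <- as.numeric(desz$gc > 0 & cumsum(desz$gc > 0) <= 4)
  bz <- passanova:::assemble_system(desz$tt, desz$gc, z, c(1, 1))
  expect_equal(ncol(bz$S), 5)
  expect_equal(mean(diag(bz$R)), 1, tolerance = 1e-6)
})

test_that("data in the null space are reproduced exactly at any lambda", {
  des <- toy_design(25, seed = 7)
  y <- 2 - 3 * passanova::k1(des$tt) + 0.8 * des$gc
  b <- passanova:::assemble_system(des$tt, des$gc, NULL, c(1, 1),
                                   n_basis = 25)
  xp <- passanova:::system_xprod(b, y)
  for (lam in c(1e-4, 1e-1, 1e2)) {
    sol <- passanova:::penalized_solve(b, xp, lam)
    expect_lt(max(abs(sol$d - c(2, -3, 0.8, 0))), 1e-6)
    expect_lt(sqrt(sum(sol$c^2)), 1e-6)
  }
})

test_that("heavy smoothing collapses to least squares on the unpenalized columns", {
  des <- toy_design(40, seed = 8, workout = TRUE)
  y <- withr::with_seed(8, rnorm(40, 10 * sin(2 * pi * des$tt), 2))
  b <- passanova:::assemble_system(des$tt, des$gc, des$z, c(1, 1))
  xp <- passanova:::system_xprod(b, y)
  sol <- passanova:::penalized_solve(b, xp, 1e9)
  ls <- stats::lm.fit(b$S, y)
  expect_lt(max(abs(drop(xp$X %*% sol$coef) - ls$fitted.values)), 1e-4)
})

test_that("penalized solve matches a brute-force optimizer oracle", {
  des <- toy_design(6, seed = 42)
  y <- withr::with_seed(42, rnorm(6, sin(2 * pi * des$tt), 0.5))
  b <- toy_blocks(des)
  xp <- passanova:::system_xprod(b, y)
  sol <- passanova:::penalized_solve(b, xp, 0.01)
  orc <- oracle_pls(y, b$S, b$Q, b$R, 0.01)
  expect_lt(max(abs(drop(xp$X %*% sol$coef) - orc$fitted)), 1e-6)
  # stationarity of the normal equations
  resid_ne <- xp$XtWy - (xp$XtWX + b$n * 0.01 * xp$P) %*% sol$coef
  expect_lt(max(abs(resid_ne)), 1e-8 * sqrt(sum(y^2)))
})

test_that("smoother trace hits its limits and decreases in lambda", {
  des <- toy_design(30, seed = 9)
  y <- withr::with_seed(9, rnorm(30))
  b <- toy_blocks(des)
  xp <- passanova:::system_xprod(b, y)
  expect_equal(passanova:::influence_trace(b, xp, 1e12), 4, tolerance = 1e-4)
  # interpolation limit at a size where the normal equations stay well posed
  des10 <- list(tt = seq(0.02, 0.98, length.out = 10),
                gc = rep(c(0.5, -0.5), 5), z = NULL)
  b10 <- toy_blocks(des10)
  xp10 <- passanova:::system_xprod(b10, withr::with_seed(90, rnorm(10)))
  expect_equal(passanova:::influence_trace(b10, xp10, 1e-12), 10,
               tolerance = 1e-3)
  traces <- sapply(10^seq(-8, 2, by = 1),
                   function(l) passanova:::influence_trace(b, xp, l))
  expect_true(all(diff(traces) <= 1e-10))
  # explicit-smoother oracle: apply the smoother to each unit vector
  lam <- 1e-3
  A_diag <- sapply(seq_len(30), function(j) {
    ej <- numeric(30); ej[j] <- 1
    xpj <- passanova:::system_xprod(b, ej)
    drop(xp$X[j, ] %*% passanova:::penalized_solve(b, xpj, lam)$coef)
  })
  expect_equal(passanova:::influence_trace(b, xp, lam), sum(A_diag),
               tolerance = 1e-8)
})

test_that("GCV behaves at its closed-form limits and is deterministic", {
  des <- toy_design(30, seed = 10)
  b <- toy_blocks(des)
  # constant response: the intercept fits perfectly, V = 0
  y0 <- rep(3.7, 30)
  xp0 <- passanova:::system_xprod(b, y0)
  expect_lt(passanova:::gcv_score(b, xp0, 1), 1e-9)
  # heavy-smoothing limit equals the parametric least-squares GCV
  y <- withr::with_seed(10, rnorm(30, 5 * des$tt, 1))
  xp <- passanova:::system_xprod(b, y)
  rss_ls <- sum(stats::lm.fit(b$S, y)$residuals^2)
  v_ls <- (rss_ls / 30) / (1 - 4 / 30)^2
  expect_equal(passanova:::gcv_score(b, xp, 1e10), v_ls, tolerance = 1e-6)
  grid <- seq(-6, 2, length.out = 21)
  v1 <- sapply(grid, function(l) passanova:::gcv_score(b, xp, 10^l))
  v2 <- sapply(grid, function(l) passanova:::gcv_score(b, xp, 10^l))
  expect_true(all(is.finite(v1)))
  expect_identical(v1, v2)
})

test_that("lambda selection refines the grid minimum and flags boundaries", {
  des <- toy_design(60, seed = 12)
  y <- withr::with_seed(12, rnorm(60, 10 * sin(2 * pi * des$tt), 1))
  b <- toy_blocks(des)
  xp <- passanova:::system_xprod(b, y)
  grid <- seq(-8, 2, length.out = 21)
  sel <- passanova:::select_lambda(b, xp, grid)
  v_grid <- min(sapply(grid, function(l) passanova:::gcv_score(b, xp, 10^l)))
  expect_lte(sel$gcv, v_grid)
  expect_false(sel$boundary)
  # a grid whose minimiser sits at the edge is reported as a boundary
  sel_edge <- passanova:::select_lambda(b, xp, seq(1, 2, length.out = 5))
  expect_true(sel_edge$boundary)
  expect_match(sel_edge$log, "boundary")
  sel2 <- passanova:::select_lambda(b, xp, grid)
  expect_identical(sel$lambda, sel2$lambda)
})

test_that("constant-mean data give a flat fitted curve", {
  d <- null_gaussian_data(300, seed = 13, sd = 15,
                          truth = function(t) rep(120, length(t)))
  fit <- pa_ssanova(y ~ day + group, d, family = "gaussian")
  days <- 0:160
  pr <- predict(fit, data.frame(day = days, group = "PEER"))
  sd <- posterior_sd(fit, days, "PEER")
  expect_true(all(abs(pr - 120) <= 2 * sd + 2 * stats::sd(d$y) / sqrt(300)))
  expect_lt(diff(range(pr)), 3 * max(sd))
})

test_that("single-group data are rejected and short series are rejected", {
  d <- null_gaussian_data(50, seed = 14)
  d$group <- "PEER"
  expect_error(pa_ssanova(y ~ day + group, d), "two observed levels")
  expect_error(pa_ssanova(y ~ day + group,
                          null_gaussian_data(30, seed = 14)[1:10, ]),
               "at least 20")
})

test_that("the workout term is an exactly additive parametric shift", {
  des <- withr::with_seed(15, {
    day <- c(0, 160, sample(0:160, 398, replace = TRUE))
    grp <- rep(c("PEER", "control"), 200)
    wd <- seq(3, 52, by = 7)
    z <- as.numeric(day %in% wd & grp == "PEER")
    y <- 100 + 25 * sin(2 * pi * day / 160) + 30 * z + rnorm(400, 0, 10)
    data.frame(day = day, group = grp, workout = z, y = y)
  })
  fit <- pa_ssanova(y ~ day + group, des, workout = "workout",
                    family = "gaussian")
  expect_true(fit$has_z)
  nd <- data.frame(day = 10, group = "PEER", workout = 1)
  p1 <- predict(fit, nd, include_z = TRUE)
  p0 <- predict(fit, nd, include_z = FALSE)
  expect_equal(p1 - p0, fit$beta_z)
  # too few workout observations: term dropped with a logged note
  d2 <- des
  idx <- which(d2$workout == 1)
  d2$workout[idx[-(1:2)]] <- 0
  fit2 <- pa_ssanova(y ~ day + group, d2, workout = "workout")
  expect_false(fit2$has_z)
  expect_match(paste(fit2$log, collapse = " "), "dropped")
})

test_that("prediction refuses to extrapolate outside the fitted domain", {
  d <- null_gaussian_data(100, seed = 16)
  fit <- pa_ssanova(y ~ day + group, d)
  expect_error(predict(fit, data.frame(day = 200, group = "PEER")),
               "outside domain")
})
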