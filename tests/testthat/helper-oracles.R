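# Brute-force oracles and small fixture builders shared across tests.
# The oracles minimise the penalized objectives directly with a generic
# quasi-Newton optimizer; they never touch the package's linear-algebra path.

# minimise (1/n)||y - X par||^2 + lambda * c' R c  over par = (d, c)
oracle_pls <- function(y, S, Q, R, lambda) {
  n <- length(y); p <- ncol(S); q <- ncol(Q)
  X <- cbind(S, Q)
  obj <- function(par) {
    r <- y - drop(X %*% par)
    cc <- par[(p + 1):(p + q)]
    sum(r^2) / n + lambda * drop(crossprod(cc, R %*% cc))
  }
  gr <- function(par) {
    r <- y - drop(X %*% par)
    cc <- par[(p + 1):(p + q)]
    g <- -2 * drop(crossprod(X, r)) / n
    g[(p + 1):(p + q)] <- g[(p + 1):(p + q)] + 2 * lambda * drop(R %*% cc)
    g
  }
  fit <- stats::optim(rep(0, p + q), obj, gr, method = "BFGS",
                      control = list(maxit = 10000, reltol = 1e-16))
  list(par = fit$par, fitted = drop(X %*% fit$par), value = fit$value)
}

# minimise (1/n) sum(y exp(-eta) + eta) + (lambda/2) c' R c
oracle_gamma <- function(y, S, Q, R, lambda, start = NULL) {
  n <- length(y); p <- ncol(S); q <- ncol(Q)
  X <- cbind(S, Q)
  obj <- function(par) {
    eta <- drop(X %*% par)
    cc <- par[(p + 1):(p + q)]
    mean(y * exp(-eta) + eta) + (lambda / 2) * drop(crossprod(cc, R %*% cc))
  }
  gr <- function(par) {
    eta <- drop(X %*% par)
    cc <- par[(p + 1):(p + q)]
    g <- drop(crossprod(X, 1 - y * exp(-eta))) / n
    g[(p + 1):(p + q)] <- g[(p + 1):(p + q)] + lambda * drop(R %*% cc)
    g
  }
  if (is.null(start)) { start <- rep(0, p + q); start[1] <- log(mean(y)) }
  fit <- stats::optim(start, obj, gr, method = "BFGS",
                      control = list(maxit = 20000, reltol = 1e-16))
  list(par = fit$par, fitted = drop(X %*% fit$par), value = fit$value)
}

# small two-group design on scaled time, optionally with workout days
toy_design <- function(n, seed, workout = FALSE) {
  withr::with_seed(seed, {
    tt <- sort(runif(n))
    gc <- sample(c(0.5, -0.5), n, replace = TRUE)
    z <- if (workout) {
      # flag the first few treatment-arm points so the column is never empty
      as.numeric(gc > 0 & cumsum(gc > 0) <= max(3, floor(n / 8)))
    } else NULL
    list(tt = tt, gc = gc, z = z)
  })
}

# assemble full-basis blocks through the package (q = n)
toy_blocks <- function(des, theta = c(1, 1)) {
  passanova:::assemble_system(des$tt, des$gc, des$z, theta,
                              n_basis = length(des$tt))
}

# cohort records where both arms share one smooth truth (no group effect)
null_gaussian_data <- function(n, seed, sd = 20, truth = function(t) 50 * sin(2 * pi * t)) {
  withr::with_seed(seed, {
    day <- c(0, 160, sample(0:160, n - 2, replace = TRUE))
    grp <- rep(c("PEER", "control"), length.out = n)
    y <- truth(day / 160) + rnorm(n, 0, sd)
    data.frame(day = day, group = grp, y = y)
  })
}
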