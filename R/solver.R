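# Weighted penalized least-squares engine shared by the Gaussian fit and the
# Gamma IRLS inner loop.
#
# Model:  y_i ~ S_i d + Q_i c,  penalty  lambda * c' R c,
# with S the unpenalized block (null basis plus optional workout indicator),
# Q the cross-kernel between data points and a random subset basis, and R the
# penalty Gram on the basis points (rescaled to unit mean diagonal, so the
# lambda grid is comparable across datasets).  Normal equations:
#   [S'WS  S'WQ       ] [d]   [S'Wy]
#   [Q'WS  Q'WQ + nlR ] [c] = [Q'Wy]
# Ridge jitter stabilises the rank-deficiency caused by duplicated design
# points (many participants share a (day, group)).

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# default subset-basis size: full n for small problems, O(n^{2/9}) beyond
default_n_basis <- function(n) min(n, ceiling(10 * n^(2 / 9)) + 30L)

#' Fitting control parameters
#'
#' Collects the numerical knobs of \code{\link{pa_ssanova}}.
#'
#' @param lambda_grid log10 smoothing-parameter grid (after rescaling the
#'   penalty Gram to unit mean diagonal); default 21 points on \eqn{[-8, 2]}.
#' @param n_basis subset-basis size; default
#'   \eqn{\min(n, \lceil 10 n^{2/9}\rceil + 30)}.
#' @param basis_seed RNG seed used to sample the basis points (recorded in the
#'   fit for reproducibility).
#' @param theta per-term scale multipliers \code{c(time_main, interaction)}.
#' @param theta_refine if \code{TRUE}, run two alternating theta/lambda GCV
#'   sweeps over the interaction scale (off by default; a single lambda with
#'   fixed thetas is the standard fit).
#' @param gs_tol golden-section refinement tolerance in log10 lambda.
#' @param jitter ridge jitter added to Gram diagonals.
#' @param max_iter maximum outer Newton iterations for the Gamma fit.
#' @param epsilon relative objective-change convergence tolerance (Gamma).
#' @param lambda_freeze outer iteration after which the Gamma fit stops
#'   re-selecting lambda, guaranteeing a fixed objective to converge on.
#' @param min_workout_obs minimum workout-day observations required to
#'   estimate the partial-spline coefficient; below it the term is dropped
#'   with a logged warning.
#' @return a list of class \code{"pa_control"}.
#' @export
pa_control <- function(lambda_grid = seq(-8, 2, length.out = 21),
                       n_basis = NULL, basis_seed = 20230801L,
                       theta = c(1, 1), theta_refine = FALSE,
                       gs_tol = 1e-3, jitter = 1e-10,
                       max_iter = 30L, epsilon = 1e-6, lambda_freeze = 5L,
                       min_workout_obs = 3L) {
  stopifnot(all(diff(lambda_grid) > 0), all(theta >= 0), jitter >= 0)
  structure(list(lambda_grid = lambda_grid, n_basis = n_basis,
                 basis_seed = basis_seed, theta = theta,
                 theta_refine = theta_refine, gs_tol = gs_tol,
                 jitter = jitter, max_iter = max_iter, epsilon = epsilon,
                 lambda_freeze = lambda_freeze,
                 min_workout_obs = min_workout_obs),
            class = "pa_control")
}

# Assemble design blocks for scaled times tt, contrasts gc, optional workout
# indicator z.  Returns S (n x p), Q (n x q), R (q x q, unit mean diagonal),
# the penalty scale absorbed into lambda, and the basis bookkeeping.
assemble_system <- function(tt, gc, z = NULL, theta = c(1, 1),
                            n_basis = NULL, basis_seed = 20230801L,
                            jitter = 1e-10) {
  n <- length(tt)
  S <- null_basis(tt, gc)
  has_z <- !is.null(z)
  if (has_z) S <- cbind(S, workout = z)
  if (n < ncol(S) + 2L)
    stop("assemble_system: too few observations for the null-space dimension")
  if (qr(S)$rank < ncol(S))
    stop("assemble_system: unpenalized design is rank deficient (fewer distinct design points than null-space dimension)")
  # sample basis anchors among the distinct (t, g) design points: duplicated
  # anchors (participants sharing a day) would make the penalty Gram singular
  uniq <- !duplicated(cbind(tt, gc))
  pool <- which(uniq)
  q <- if (is.null(n_basis)) default_n_basis(n) else min(n_basis, n)
  q <- min(q, length(pool))
  idx <- with_seed(basis_seed, sort(pool[sample.int(length(pool), q)]))
  tb <- tt[idx]; gb <- gc[idx]
  Q <- term_gram(tt, gc, tb, gb, theta)
  R <- term_gram(tb, gb, tb, gb, theta)
  scale <- mean(diag(R))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  R <- R / scale
  R <- (R + t(R)) / 2 + jitter * diag(q)
  list(S = S, Q = Q, R = R, penalty_scale = scale, basis_idx = idx,
       basis_t = tb, basis_gc = gb, n = n, p = ncol(S), q = q,
       has_z = has_z, theta = theta, jitter = jitter)
}

# Precompute the lambda-free cross-products for one weight vector.
system_xprod <- function(blocks, y, w = NULL) {
  X <- cbind(blocks$S, blocks$Q)
  if (is.null(w)) {
    XtWX <- crossprod(X)
    XtWy <- crossprod(X, y)
    ytWy <- sum(y^2)
    sumw <- blocks$n
  } else {
    Xw <- X * sqrt(w)
    XtWX <- crossprod(Xw)
    XtWy <- crossprod(X, w * y)
    ytWy <- sum(w * y^2)
    sumw <- sum(w)
  }
  P <- matrix(0, blocks$p + blocks$q, blocks$p + blocks$q)
  P[(blocks$p + 1):(blocks$p + blocks$q),
    (blocks$p + 1):(blocks$p + blocks$q)] <- blocks$R
  list(X = X, XtWX = XtWX, XtWy = XtWy, ytWy = ytWy, P = P, w = w,
       sumw = sumw)
}

# Solve the penalized normal equations at one lambda.  Returns coefficients,
# the system matrix M (kept for Bayesian covariances), weighted RSS and the
# smoother trace.
penalized_solve <- function(blocks, xp, lambda) {
  stopifnot(lambda > 0)
  M0 <- xp$XtWX + blocks$n * lambda * xp$P
  # ridge relative to the data cross-product (not the penalty-inflated M),
  # escalated only if the factorization fails
  base <- mean(diag(xp$XtWX)) * max(blocks$jitter, 1e-16)
  coef <- M <- NULL
  for (k in 0:7) {
    # M is positive definite in exact arithmetic (the penalty Gram carries
    # its own jitter); ridge only when the factorization actually fails
    Mj <- if (k == 0) M0 else M0 + (base * 10^(k - 1)) * diag(nrow(M0))
    ch <- tryCatch(chol(Mj), error = function(e) NULL)
    if (!is.null(ch)) {
      coef <- backsolve(ch, forwardsolve(t(ch), xp$XtWy))
      M <- Mj
      break
    }
  }
  if (is.null(coef))
    stop("penalized_solve: system singular even after ridge jitter; check for degenerate design")
  rss_w <- drop(xp$ytWy - 2 * crossprod(coef, xp$XtWy) +
                  crossprod(coef, xp$XtWX %*% coef))
  rss_w <- max(rss_w, 0)
  tr <- sum(diag(backsolve(ch, forwardsolve(t(ch), xp$XtWX))))
  d <- coef[seq_len(blocks$p)]
  cc <- coef[(blocks$p + 1):(blocks$p + blocks$q)]
  list(d = d, c = cc, coef = coef, M = M, M_chol = ch, rss_w = rss_w,
       trace_A = tr)
}

# Smoother trace tr A(lambda); p + 1[z] <= tr <= n, non-increasing in lambda.
influence_trace <- function(blocks, xp, lambda) {
  penalized_solve(blocks, xp, lambda)$trace_A
}

# GCV score V(lambda) = (n^-1 ||W^1/2 (I-A) y||^2) / (n^-1 tr(I-A))^2
gcv_score <- function(blocks, xp, lambda) {
  sol <- penalized_solve(blocks, xp, lambda)
  n <- blocks$n
  den <- 1 - sol$trace_A / n
  if (den <= 0)
    stop("gcv_score: degenerate smoother, tr(I - A) <= 0")
  (sol$rss_w / n) / den^2
}

# Grid minimisation of V followed by golden-section refinement inside the
# bracketing interval.  Returns lambda, the achieved V, and a boundary flag.
select_lambda <- function(blocks, xp, log10_grid = seq(-8, 2, length.out = 21),
                          gs_tol = 1e-3) {
  V <- vapply(log10_grid, function(l) gcv_score(blocks, xp, 10^l), 0)
  i <- which.min(V)
  boundary <- i == 1L || i == length(log10_grid)
  if (boundary) {
    return(list(lambda = 10^log10_grid[i], gcv = V[i], boundary = TRUE,
                log = sprintf("GCV minimiser at grid boundary log10(lambda) = %.2f",
                              log10_grid[i])))
  }
  f <- function(l) gcv_score(blocks, xp, 10^l)
  gr <- (sqrt(5) - 1) / 2
  a <- log10_grid[i - 1L]; b <- log10_grid[i + 1L]
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > gs_tol) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  lstar <- if (f1 <= f2) x1 else x2
  vstar <- min(f1, f2)
  if (vstar > V[i]) { lstar <- log10_grid[i]; vstar <- V[i] }
  list(lambda = 10^lstar, gcv = vstar, boundary = FALSE, log = NULL)
}

# One alternating theta/lambda GCV sweep: with lambda fixed, grid-search the
# interaction-term scale, then re-select lambda.  Used only when
# control$theta_refine is TRUE.
refine_theta <- function(tt, gc, z, y, w, control, theta, n_basis) {
  log_mult <- seq(-2, 2, length.out = 9)
  for (sweep in 1:2) {
    blocks <- assemble_system(tt, gc, z, theta, n_basis,
                              control$basis_seed, control$jitter)
    xp <- system_xprod(blocks, y, w)
    sel <- select_lambda(blocks, xp, control$lambda_grid, control$gs_tol)
    scores <- vapply(log_mult, function(lm) {
      th <- c(theta[1], theta[2] * 10^lm)
      b2 <- assemble_system(tt, gc, z, th, n_basis,
                            control$basis_seed, control$jitter)
      x2 <- system_xprod(b2, y, w)
      gcv_score(b2, x2, sel$lambda)
    }, 0)
    theta <- c(theta[1], theta[2] * 10^log_mult[which.min(scores)])
  }
  theta
}
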