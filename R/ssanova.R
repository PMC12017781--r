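# User-facing fitting function and S3 methods.

#' Smoothing spline ANOVA for two-arm daily activity series
#'
#' Fits the time x group smoothing spline ANOVA model
#' \deqn{\eta(t, g) = \eta_0 + \eta_1(t) + \eta_2(g) + \eta_{12}(t, g)}
#' to daily physical-activity minutes, with an optional partial-spline
#' (parametric) workout-day indicator whose coefficient \eqn{\beta} captures
#' the discrete jump on group-exercise days.  Near-symmetric outcomes
#' (sedentary, light-active minutes) use the Gaussian family: the grand mean
#' is removed, and coefficients minimise the penalized least-squares
#' criterion \eqn{n^{-1}\sum_i (y_i - z_i\beta - \eta(x_i))^2 + \lambda J(\eta)}
#' with \eqn{\lambda} chosen by generalized cross-validation (GCV).
#' Right-skewed outcomes (fairly/very-active minutes) use the Gamma family
#' with log link, minimising the penalized negative log-likelihood
#' \eqn{n^{-1}\sum_i (y_i e^{-\eta_i} + \eta_i)/\sigma^2 + (\lambda/2) J(\eta)}
#' by Newton iteration (IRLS) with GCV on the working data at each step.
#'
#' The group main effect is a single parametric \eqn{\pm 1/2} contrast (a
#' two-level factor has no smooth part); the penalized terms are the smooth
#' time main effect and the smooth time x group interaction.  Fitted
#' functions are expanded over kernel sections at a random subset of the
#' design points (size \eqn{\min(n, \lceil 10 n^{2/9} \rceil + 30)}), which
#' keeps large cohorts tractable.
#'
#' @param formula two-sided formula \code{outcome ~ time + group}: one
#'   numeric time variable (study day) and one two-level group factor, in
#'   either order.
#' @param data data frame holding the formula variables (and the workout
#'   column if named).
#' @param family \code{"gaussian"} or \code{"gamma"}.
#' @param workout optional: name of a 0/1 workout-day indicator column in
#'   \code{data}, or a 0/1 vector of length \code{nrow(data)}.  Nonzero
#'   entries are only allowed in the treatment group.
#' @param domain optional \code{\link{time_domain}} or length-2 numeric; the
#'   study window over which time is scaled to \eqn{[0,1]}.  Default: the
#'   observed range of the time variable.
#' @param treat label of the treatment arm (coded +1/2); default
#'   \code{"PEER"} if present among the group levels, otherwise the last
#'   level.
#' @param zero_policy how zero minutes are made Gamma-compatible:
#'   \code{"offset"} adds \code{zero_offset} to every response (default,
#'   reversible at prediction time), \code{"drop"} removes zero records,
#'   \code{"none"} requires all-positive input.
#' @param zero_offset minutes added under the offset policy (default 0.5).
#' @param control a \code{\link{pa_control}} list.
#' @return an object of class \code{"pa_ssanova"}; see
#'   \code{\link{predict.pa_ssanova}}, \code{\link{predict_band}},
#'   \code{\link{ssanova_components}}, \code{\link{group_difference}}.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_peer = 6, n_control = 6, n_days = 60,
#'                                   seed = 1))
#' fit <- pa_ssanova(sedentary_min ~ day + group, data = sim$records,
#'                   workout = "workout", family = "gaussian")
#' fit
pa_ssanova <- function(formula, data, family = c("gaussian", "gamma"),
                       workout = NULL, domain = NULL, treat = NULL,
                       zero_policy = c("offset", "drop", "none"),
                       zero_offset = 0.5, control = pa_control()) {
  family <- match.arg(family)
  zero_policy <- match.arg(zero_policy)
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  if (ncol(mf) != 3L)
    stop("pa_ssanova: formula must be 'outcome ~ time + group' with exactly two covariates")
  y <- mf[[1L]]
  rhs <- mf[-1L]
  is_num <- vapply(rhs, is.numeric, TRUE)
  if (sum(is_num) != 1L)
    stop("pa_ssanova: need exactly one numeric time variable and one group factor")
  day <- rhs[[which(is_num)]]
  grp <- as.character(rhs[[which(!is_num)]])
  levs <- sort(unique(grp))
  if (length(levs) != 2L)
    stop("pa_ssanova: group variable must have exactly two observed levels (single-group data leaves the interaction unidentifiable)")
  if (is.null(treat)) treat <- if ("PEER" %in% levs) "PEER" else levs[2L]
  if (!treat %in% levs) stop("pa_ssanova: 'treat' is not an observed group level")
  ctrl_lev <- setdiff(levs, treat)

  z <- NULL
  dropped_rows <- attr(mf, "na.action")
  if (!is.null(workout)) {
    z <- if (is.character(workout) && length(workout) == 1L) {
      if (!workout %in% names(data))
        stop(sprintf("pa_ssanova: workout column '%s' not found", workout))
      data[[workout]]
    } else as.numeric(workout)
    if (length(z) != nrow(data))
      stop("pa_ssanova: workout indicator length must match nrow(data)")
    if (!is.null(dropped_rows)) z <- z[-dropped_rows]
    if (!all(z %in% c(0, 1))) stop("pa_ssanova: workout indicator must be 0/1")
    if (any(z == 1 & grp != treat))
      stop("pa_ssanova: workout = 1 is only allowed in the treatment group")
  }

  if (length(y) < 20L)
    stop("pa_ssanova: need at least 20 records")
  if (is.null(domain)) domain <- time_domain(min(day), max(day))
  if (is.numeric(domain) && length(domain) == 2L)
    domain <- time_domain(domain[1L], domain[2L])
  tt <- scale_time(day, domain)
  gc <- group_contrast(grp, treat = treat, ctrl = ctrl_lev)

  fit_log <- character(0)
  if (!is.null(z) && sum(z) < control$min_workout_obs) {
    fit_log <- c(fit_log, sprintf(
      "workout term dropped: only %d workout-day observation(s) (< %d)",
      sum(z), control$min_workout_obs))
    z <- NULL
  }

  core <- if (family == "gaussian") {
    fit_gaussian_core(y, tt, gc, z, control)
  } else {
    fit_gamma_core(y, tt, gc, z, control, zero_policy, zero_offset)
  }

  if (!is.null(core$zero_keep) && !all(core$zero_keep)) {
    keep <- core$zero_keep
    y <- y[keep]; day <- day[keep]; grp <- grp[keep]
    tt <- tt[keep]; gc <- gc[keep]
    if (!is.null(z)) z <- z[keep]
  }
  core$log <- c(fit_log, core$log)
  out <- c(core, list(call = cl, family = family, domain = domain,
                      treat = treat, control_lev = ctrl_lev, group = grp,
                      day = day, y = y, t_scaled = tt, gc = gc, z = z,
                      control = control))
  class(out) <- "pa_ssanova"
  out
}

# evaluation matrix [null basis (+z) | kernel block] for new points
eval_matrix <- function(fit, tt, gc, z = NULL) {
  S <- null_basis(tt, gc)
  if (fit$has_z) {
    if (is.null(z)) z <- rep(0, length(tt))
    S <- cbind(S, workout = z)
  }
  Q <- term_gram(tt, gc, fit$basis_t, fit$basis_gc, fit$theta)
  cbind(S, Q)
}

#' Predict from a fitted activity SSANOVA
#'
#' Evaluates \eqn{\hat\eta} (plus the workout-day jump and, for Gaussian
#' fits, the centering offset) at new time/group points.  No extrapolation:
#' days outside the fitted domain are an error.
#'
#' @param object a \code{"pa_ssanova"} fit.
#' @param newdata data frame with columns \code{day}, \code{group}, and
#'   optionally \code{workout}; default: the training design.
#' @param type \code{"response"} (minutes; Gamma fits are exponentiated and
#'   the zero-handling offset removed) or \code{"link"} (linear predictor).
#' @param include_z include the parametric workout-day term.
#' @param se.fit also return pointwise posterior standard errors on the link
#'   scale.
#' @param ... unused.
#' @return numeric vector, or list \code{(fit, se.fit)}.
#' @export
predict.pa_ssanova <- function(object, newdata = NULL,
                               type = c("response", "link"),
                               include_z = TRUE, se.fit = FALSE, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    tt <- object$t_scaled; gc <- object$gc
    z <- if (is.null(object$z)) rep(0, length(tt)) else object$z
  } else {
    tt <- scale_time(newdata$day, object$domain)
    gc <- group_contrast(newdata$group, treat = object$treat,
                         ctrl = object$control_lev)
    z <- if ("workout" %in% names(newdata)) as.numeric(newdata$workout)
         else rep(0, length(tt))
  }
  if (!include_z) z <- rep(0, length(tt))
  E <- eval_matrix(object, tt, gc, z)
  eta <- drop(E %*% object$coef_vec) + object$mean_offset
  out <- if (type == "response" && object$family == "gamma")
    exp(eta) - object$zero_offset else eta
  if (!se.fit) return(out)
  list(fit = out, se.fit = posterior_sd_rows(object, E))
}

#' @export
fitted.pa_ssanova <- function(object, ...) {
  predict.pa_ssanova(object, type = "response")
}

#' Residuals of an activity SSANOVA fit
#'
#' @param object a \code{"pa_ssanova"} fit.
#' @param type \code{"response"} (observed minus fitted minutes),
#'   \code{"pearson"} (response residual divided by the fitted mean for the
#'   Gamma family, unchanged for Gaussian), or \code{"working"}.
#' @param ... unused.
#' @export
residuals.pa_ssanova <- function(object,
                                 type = c("response", "pearson", "working"),
                                 ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  y <- object$y
  r <- y - mu
  if (object$family == "gamma") {
    yfit <- y + object$zero_offset   # scale the model actually saw
    mufit <- mu + object$zero_offset
    if (type == "pearson") return((yfit - mufit) / mufit)
    if (type == "working") {
      eta <- predict(object, type = "link")
      w <- pmax(yfit * exp(-eta), 1e-10)
      return((yfit * exp(-eta) - 1) / w)
    }
    return(r)
  }
  if (type == "pearson") return(r / sqrt(object$dispersion))
  r
}

#' @export
coef.pa_ssanova <- function(object, ...) {
  nm <- c("const", "time", "group", "time:group")
  if (object$has_z) nm <- c(nm, "workout")
  stats::setNames(object$d, nm)
}

#' @export
print.pa_ssanova <- function(x, digits = 4, ...) {
  cat("Smoothing spline ANOVA fit (", x$family, " family)\n", sep = "")
  cat(sprintf("  n = %d observations, groups %s (+1/2) vs %s (-1/2)\n",
              length(x$y), x$treat, x$control_lev))
  cat(sprintf("  lambda (GCV) = %.4g, effective df = %.2f, dispersion = %.4g\n",
              x$lambda, x$trace_A, x$dispersion))
  if (x$has_z)
    cat(sprintf("  workout-day coefficient beta = %.*f%s\n", digits, x$beta_z,
                if (x$family == "gamma") "  (log scale)" else ""))
  if (x$family == "gamma")
    cat(sprintf("  IRLS: %d outer iterations, converged = %s\n",
                x$iter, x$converged))
  if (length(x$log)) cat("  notes:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.pa_ssanova <- function(object, ...) {
  out <- list(fit = object)
  if (object$has_z) {
    ej <- numeric(nrow(object$M)); ej[object$p] <- 1
    half <- forwardsolve(t(object$M_chol), ej)
    se <- sqrt(object$dispersion * sum(half^2))
    out$beta_z <- c(estimate = object$beta_z, se = se,
                    z = object$beta_z / se,
                    p = 2 * stats::pnorm(-abs(object$beta_z / se)))
  }
  out$gcv <- object$gcv
  class(out) <- "summary.pa_ssanova"
  out
}

#' @export
print.summary.pa_ssanova <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  GCV at the selected lambda: %.6g\n", x$gcv))
  if (!is.null(x$beta_z))
    cat(sprintf("  workout effect: %.4f (se %.4f, z = %.2f, p = %.3g)\n",
                x$beta_z["estimate"], x$beta_z["se"], x$beta_z["z"],
                x$beta_z["p"]))
  invisible(x)
}

#' Simulate responses from a fitted activity SSANOVA
#'
#' Draws new outcome vectors at the training design from the fitted family:
#' Gaussian with the estimated dispersion, or Gamma with shape
#' \eqn{1/\hat\sigma^2} and the fitted means.
#'
#' @param object a \code{"pa_ssanova"} fit.
#' @param nsim number of replicate response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data frame with \code{nsim} columns.
#' @export
simulate.pa_ssanova <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() {
    mu <- predict(object, type = "link")
    n <- length(mu)
    if (object$family == "gaussian")
      stats::rnorm(n, mu, sqrt(object$dispersion))
    else {
      shape <- 1 / object$dispersion
      stats::rgamma(n, shape = shape, scale = exp(mu) / shape) -
        object$zero_offset
    }
  }
  sims <- if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
          else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted activity SSANOVA
#'
#' Draws the data cloud and the fitted curves with 95% Bayesian bands for
#' both groups over the study window.
#'
#' @param x a \code{"pa_ssanova"} fit.
#' @param days day grid; default every day of the fitted domain.
#' @param level band level.
#' @param ... passed to \code{plot}.
#' @export
plot.pa_ssanova <- function(x, days = NULL,
                            level = 0.95, ...) {
  if (is.null(days))
    days <- seq(x$domain$day_min, x$domain$day_max, by = 1)
  cols <- c("#D55E00", "#0072B2")
  groups <- c(x$treat, x$control_lev)
  bands <- lapply(groups, function(g) predict_band(x, g, days, level = level))
  ylim <- range(unlist(lapply(bands, function(b) c(b$lo, b$hi))), x$y)
  graphics::plot(x$day, x$y, pch = 16, cex = 0.3, col = "grey70",
                 xlab = "study day", ylab = "minutes/day", ylim = ylim, ...)
  for (i in 1:2) {
    b <- bands[[i]]
    graphics::polygon(c(b$day, rev(b$day)), c(b$lo, rev(b$hi)),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(b$day, b$fit, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = groups, col = cols, lwd = 2, bty = "n")
  invisible(x)
}
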