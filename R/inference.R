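# Bayesian confidence bands, ANOVA-component extraction, group-difference
# curves and intervention-effect summaries.
#
# Interpreting the penalized fit as a posterior mean under a Gaussian-process
# prior, the posterior covariance of the coefficient vector is
# dispersion * M^{-1} with M the (weighted) penalized normal-equation matrix,
# so Var(eta_hat(x)) = dispersion * e(x)' M^{-1} e(x) for the evaluation row
# e(x).  Such bands are known to have approximately nominal coverage averaged
# across the function.

# pointwise posterior sd for rows of an evaluation matrix
posterior_sd_rows <- function(fit, E) {
  half <- forwardsolve(t(fit$M_chol), t(E))   # M = R'R, rows E M^-1 E'
  sqrt(pmax(fit$dispersion * colSums(half^2), 0))
}

# variance of a linear functional g' coef
posterior_var_functional <- function(fit, g) {
  half <- forwardsolve(t(fit$M_chol), g)
  drop(fit$dispersion * sum(half^2))
}

#' Pointwise posterior standard deviation of the fitted curve
#'
#' @param fit a converged \code{"pa_ssanova"} fit.
#' @param days day grid.
#' @param group group label.
#' @param workout optional 0/1 indicator per day.
#' @return numeric vector of link-scale posterior standard deviations.
#' @export
posterior_sd <- function(fit, days, group, workout = NULL) {
  if (!isTRUE(fit$converged))
    stop("posterior_sd: fit did not converge; bands would be unreliable")
  tt <- scale_time(days, fit$domain)
  gc <- group_contrast(rep(group, length(days)), treat = fit$treat,
                       ctrl = fit$control_lev)
  E <- eval_matrix(fit, tt, gc, workout)
  posterior_sd_rows(fit, E)
}

#' 95% Bayesian confidence band for one group's fitted curve
#'
#' Computes \eqn{\hat\eta \pm z_{level} \cdot sd} on the linear-predictor
#' scale; Gamma-family bands are exponentiated to the minutes scale and
#' corrected for the zero-handling offset.  When \code{include_z} is set,
#' configured workout days carry the parametric jump.
#'
#' @param fit a converged \code{"pa_ssanova"} fit.
#' @param group group label.
#' @param days integer day grid within the fitted domain.
#' @param level band level in (0, 1); default 0.95.
#' @param include_z include workout-day jumps (treatment group only).
#' @param workout_days integer days carrying the jump; default: the fitted
#'   workout days.
#' @return data frame of class \code{"prediction_band"} with columns
#'   \code{day}, \code{fit}, \code{lo}, \code{hi}, \code{group}.
#' @export
predict_band <- function(fit, group, days, level = 0.95, include_z = TRUE,
                         workout_days = NULL) {
  if (level <= 0 || level >= 1) stop("predict_band: level must be in (0, 1)")
  if (!isTRUE(fit$converged))
    stop("predict_band: fit did not converge")
  z <- rep(0, length(days))
  if (include_z && fit$has_z && group == fit$treat) {
    if (is.null(workout_days))
      workout_days <- if (is.null(fit$z)) integer(0)
                      else sort(unique(fit$day[fit$z == 1]))
    z[days %in% workout_days] <- 1
  }
  tt <- scale_time(days, fit$domain)
  gc <- group_contrast(rep(group, length(days)), treat = fit$treat,
                       ctrl = fit$control_lev)
  E <- eval_matrix(fit, tt, gc, z)
  eta <- drop(E %*% fit$coef_vec) + fit$mean_offset
  sd <- posterior_sd_rows(fit, E)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  lo <- eta - zq * sd
  hi <- eta + zq * sd
  if (fit$family == "gamma") {
    eta <- exp(eta) - fit$zero_offset
    lo <- exp(lo) - fit$zero_offset
    hi <- exp(hi) - fit$zero_offset
  }
  structure(data.frame(day = days, fit = eta, lo = lo, hi = hi,
                       group = group, row.names = NULL),
            class = c("prediction_band", "data.frame"))
}

#' Functional ANOVA components of the fitted surface
#'
#' Decomposes \eqn{\hat\eta(t,g)} into the constant \eqn{\eta_0} (including
#' any centering offset), the time main effect \eqn{\eta_1(t)}, the group
#' main effect \eqn{\eta_2(g)} and the time x group interaction
#' \eqn{\eta_{12}(t,g)}, respecting the zero-mean side conditions of the
#' \eqn{\pm 1/2} contrast coding.  The components sum to the prediction
#' without the parametric workout term.
#'
#' @param fit a converged \code{"pa_ssanova"} fit.
#' @param days day grid.
#' @param group group label (affects \eqn{\eta_2}, \eqn{\eta_{12}}).
#' @return data frame with columns \code{day}, \code{group}, \code{eta0},
#'   \code{eta1}, \code{eta2}, \code{eta12} (link scale).
#' @export
ssanova_components <- function(fit, days, group) {
  if (!isTRUE(fit$converged)) stop("ssanova_components: fit did not converge")
  tt <- scale_time(days, fit$domain)
  gcv_ <- group_contrast(rep(group, length(days)), treat = fit$treat,
                         ctrl = fit$control_lev)
  d <- fit$d
  Kt <- cubic_kernel_matrix(tt, fit$basis_t)
  th <- fit$theta
  # smooth parts: theta1*K carries the time main effect, the contrast-weighted
  # tensor part carries the interaction
  s_time <- th[1] * drop(Kt %*% fit$c)
  s_int <- th[2] * gcv_ * drop(Kt %*% (fit$basis_gc * fit$c))
  data.frame(day = days, group = group,
             eta0 = d[1] + fit$mean_offset,
             eta1 = d[2] * k1(tt) + s_time,
             eta2 = d[3] * gcv_,
             eta12 = d[4] * k1(tt) * gcv_ + s_int,
             row.names = NULL)
}

#' Group-difference curve (treatment minus control) with 95% band
#'
#' The smooth difference \eqn{\hat\eta(t, PEER) - \hat\eta(t, control)}
#' (excluding workout-day jumps) with its posterior standard deviation.
#' For Gamma fits the difference is reported on both the log scale and the
#' minutes scale (delta method).
#'
#' @param fit a converged \code{"pa_ssanova"} fit.
#' @param days day grid.
#' @param level band level.
#' @return data frame with columns \code{day}, \code{diff}, \code{sd},
#'   \code{lo}, \code{hi} on the minutes scale and, for Gamma fits,
#'   \code{diff_link}, \code{sd_link}, \code{lo_link}, \code{hi_link}.
#' @export
group_difference <- function(fit, days, level = 0.95) {
  if (!isTRUE(fit$converged)) stop("group_difference: fit did not converge")
  tt <- scale_time(days, fit$domain)
  m <- length(days)
  gP <- group_contrast(rep(fit$treat, m), fit$treat, fit$control_lev)
  gC <- group_contrast(rep(fit$control_lev, m), fit$treat, fit$control_lev)
  EP <- eval_matrix(fit, tt, gP, NULL)
  EC <- eval_matrix(fit, tt, gC, NULL)
  zq <- stats::qnorm(1 - (1 - level) / 2)
  D <- EP - EC
  dlink <- drop(D %*% fit$coef_vec)
  sdlink <- posterior_sd_rows(fit, D)
  out <- data.frame(day = days, diff = dlink, sd = sdlink,
                    lo = dlink - zq * sdlink, hi = dlink + zq * sdlink,
                    row.names = NULL)
  if (fit$family == "gamma") {
    muP <- exp(drop(EP %*% fit$coef_vec))
    muC <- exp(drop(EC %*% fit$coef_vec))
    G <- muP * EP - muC * EC        # delta-method gradient rows
    dresp <- muP - muC              # offsets cancel in the difference
    sdresp <- posterior_sd_rows(fit, G)
    out <- data.frame(day = days, diff = dresp, sd = sdresp,
                      lo = dresp - zq * sdresp, hi = dresp + zq * sdresp,
                      diff_link = dlink, sd_link = sdlink,
                      lo_link = dlink - zq * sdlink,
                      hi_link = dlink + zq * sdlink, row.names = NULL)
  }
  out
}

#' Percent change relative to a baseline level
#'
#' \eqn{100 \cdot \Delta / \mathrm{baseline}}, signed by the direction of
#' change and rounded to one decimal for reporting.
#'
#' @param mean_daily_diff change in minutes/day.
#' @param baseline baseline minutes/day, must be positive.
#' @param digits decimals kept (default 1).
#' @return signed percent.
#' @export
#' @examples
#' percent_change(-53.09, 795)   # -6.7
#' percent_change(0.15, 1.09)    # 13.8
percent_change <- function(mean_daily_diff, baseline, digits = 1) {
  if (!is.finite(baseline) || baseline <= 0)
    stop("percent_change: baseline must be positive")
  round(100 * mean_daily_diff / baseline, digits)
}

#' Cohen's d standardized mean difference
#'
#' \eqn{(\bar a - \bar b) / s_p} with the pooled standard deviation
#' \eqn{s_p = \sqrt{((n_a-1)s_a^2 + (n_b-1)s_b^2) / (n_a+n_b-2)}}.
#'
#' @param a,b numeric samples (here: participant-level window means).
#' @return standardized difference.
#' @export
#' @examples
#' cohens_d(c(1, 2, 3), c(2, 3, 4))   # -1
cohens_d <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop("cohens_d: both samples must be nonempty")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (!is.finite(sp2) || sp2 <= 0)
    stop("cohens_d: pooled variance must be positive")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Windowed intervention-effect summary
#'
#' Averages the group-difference curve (minutes scale) over the days of a
#' study window; its 95% CI comes from the posterior covariance of that
#' average.  Percent change is taken against a baseline level (default: the
#' treatment group's first-week mean of the raw outcome), and Cohen's d is
#' computed from participant-level window means to avoid pseudo-replication.
#'
#' @param fit a converged \code{"pa_ssanova"} fit.
#' @param records data frame with \code{participant_id}, \code{group},
#'   \code{day} and the outcome column the fit used.
#' @param outcome outcome column name in \code{records}.
#' @param window integer vector of days (e.g. \code{0:55} for an 8-week
#'   intervention).
#' @param label window label stored in the summary.
#' @param baseline baseline minutes/day for percent change; default computed
#'   from the treatment group's days 0--6.
#' @param level CI level.
#' @return list of class \code{"effect_summary"}.
#' @export
window_summary <- function(fit, records, outcome, window,
                           label = "intervention", baseline = NULL,
                           level = 0.95) {
  if (length(window) == 0) stop("window_summary: empty window")
  window <- window[window >= fit$domain$day_min & window <= fit$domain$day_max]
  if (length(window) == 0) stop("window_summary: window outside study domain")
  tt <- scale_time(window, fit$domain)
  m <- length(window)
  gP <- group_contrast(rep(fit$treat, m), fit$treat, fit$control_lev)
  gC <- group_contrast(rep(fit$control_lev, m), fit$treat, fit$control_lev)
  EP <- eval_matrix(fit, tt, gP, NULL)
  EC <- eval_matrix(fit, tt, gC, NULL)
  if (fit$family == "gamma") {
    muP <- exp(drop(EP %*% fit$coef_vec))
    muC <- exp(drop(EC %*% fit$coef_vec))
    diff_curve <- muP - muC
    g <- colMeans(muP * EP - muC * EC)
  } else {
    diff_curve <- drop((EP - EC) %*% fit$coef_vec)
    g <- colMeans(EP - EC)
  }
  est <- mean(diff_curve)
  se <- sqrt(posterior_var_functional(fit, g))
  zq <- stats::qnorm(1 - (1 - level) / 2)

  if (is.null(baseline)) {
    base_rows <- records$group == fit$treat & records$day >= 0 &
      records$day <= 6
    baseline <- mean(records[[outcome]][base_rows])
  }
  pct <- if (is.finite(baseline) && baseline > 0)
    percent_change(est, baseline) else NA_real_

  in_win <- records$day %in% window
  pm <- tapply(records[[outcome]][in_win],
               records$participant_id[in_win], mean)
  pg <- tapply(as.character(records$group[in_win]),
               records$participant_id[in_win], function(g) g[1])
  d <- tryCatch(cohens_d(pm[pg == fit$treat], pm[pg != fit$treat]),
                error = function(e) NA_real_)

  structure(list(outcome = outcome, window = label,
                 window_days = range(window),
                 mean_daily_diff = est, se = se,
                 ci95 = c(lo = est - zq * se, hi = est + zq * se),
                 baseline = baseline, pct_change = pct, cohens_d = d),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("%s (%s window, days %d-%d):\n", x$outcome, x$window,
              x$window_days[1], x$window_days[2]))
  cat(sprintf("  mean daily difference %.2f min/day (95%% CI [%.2f, %.2f])\n",
              x$mean_daily_diff, x$ci95[1], x$ci95[2]))
  cat(sprintf("  %.1f%% change vs baseline %.2f min/day; Cohen's d = %.2f\n",
              x$pct_change, x$baseline, x$cohens_d))
  invisible(x)
}
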