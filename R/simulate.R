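# Synthetic two-arm Fitbit-like cohort generator.
#
# Emulates the statistical structure the analysis assumes: two arms followed
# daily over a 23-week window (8-week intervention + follow-up), smooth
# group-specific trends, discrete jumps on weekly workout days in the
# treatment arm during the intervention, near-symmetric sedentary/light
# minutes (truncated Gaussian) and right-skewed fairly/very-active minutes
# (Gamma), plus sporadic missing days.

#' Per-outcome simulation parameters
#'
#' @param family \code{"gaussian"} or \code{"gamma"}.
#' @param baseline mean minutes/day at study entry (both arms).
#' @param effect peak treatment-vs-control difference in minutes/day, reached
#'   mid-intervention and decaying through follow-up (negative for sedentary
#'   time).
#' @param jump workout-day jump: additive minutes for Gaussian outcomes, a
#'   log-scale coefficient (multiplier \code{exp(jump)}) for Gamma outcomes.
#' @param sd Gaussian noise standard deviation (minutes).
#' @param shape Gamma shape parameter (right-skew: skewness
#'   \eqn{2/\sqrt{shape}}).
#' @param drift relative amplitude of the gentle secular trend shared by both
#'   arms.
#' @return list of outcome parameters.
#' @export
outcome_params <- function(family = c("gaussian", "gamma"), baseline,
                           effect = 0, jump = 0, sd = NULL, shape = NULL,
                           drift = 0.02) {
  family <- match.arg(family)
  if (baseline <= 0 || baseline > 1440)
    stop("outcome_params: baseline must be in (0, 1440]")
  if (family == "gaussian" && is.null(sd))
    stop("outcome_params: Gaussian outcome needs 'sd'")
  if (family == "gamma" && (is.null(shape) || shape <= 0))
    stop("outcome_params: Gamma outcome needs positive 'shape'")
  list(family = family, baseline = baseline, effect = effect, jump = jump,
       sd = sd, shape = shape, drift = drift)
}

#' Cohort simulation configuration
#'
#' Defaults mirror the study design the generator emulates: arms of 33 and 31
#' participants, a 161-day (23-week) window with an 8-week intervention,
#' one weekly workout day, and outcome baselines of 795 (sedentary), 200
#' (light), 7.43 (fairly active) and 1.09 (very active) minutes/day.  Peak
#' treatment effects are set so the intervention-window average difference is
#' about -53, +12, +0.21 and +0.15 min/day respectively.
#'
#' @param n_peer,n_control participants per arm.
#' @param n_days study days (default 161 = 23 weeks).
#' @param intervention_weeks weeks of the intervention period (default 8).
#' @param workout_weekday 0-based day-of-week index of the weekly workout.
#' @param missing_rate per-record missingness probability, in [0, 0.5).
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @param outcomes named list of \code{\link{outcome_params}} for
#'   \code{sedentary_min}, \code{light_min}, \code{fairly_min},
#'   \code{very_min}.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_peer = 33, n_control = 31, n_days = 161,
                       intervention_weeks = 8, workout_weekday = 3,
                       missing_rate = 0.05, seed = 1,
                       outcomes = default_outcomes()) {
  if (n_days < 14) stop("sim_config: n_days must be at least 14")
  if (missing_rate < 0 || missing_rate >= 0.5)
    stop("sim_config: missing_rate must be in [0, 0.5)")
  stopifnot(n_peer >= 1, n_control >= 1, intervention_weeks >= 1)
  structure(list(n_peer = n_peer, n_control = n_control, n_days = n_days,
                 intervention_weeks = intervention_weeks,
                 workout_weekday = workout_weekday %% 7,
                 missing_rate = missing_rate, seed = seed,
                 outcomes = outcomes),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_outcomes <- function() {
  list(
    sedentary_min = outcome_params("gaussian", baseline = 795, effect = -66,
                                   jump = -40, sd = 90),
    light_min = outcome_params("gaussian", baseline = 200, effect = 15,
                               jump = 20, sd = 60),
    fairly_min = outcome_params("gamma", baseline = 7.43, effect = 0.26,
                                jump = log(1.5), shape = 1.5),
    very_min = outcome_params("gamma", baseline = 1.09, effect = 0.19,
                              jump = log(1.5), shape = 1.2)
  )
}

#' Workout days implied by a simulation configuration
#'
#' One fixed weekday during the intervention weeks only.
#'
#' @param config a \code{\link{sim_config}}.
#' @return integer vector of study days.
#' @export
workout_days <- function(config) {
  last <- 7 * config$intervention_weeks - 1
  days <- seq(0, min(last, config$n_days - 1))
  days[days %% 7 == config$workout_weekday]
}

# unit-peak effect profile: 0 at day 0, peak 1 at mid-intervention, smooth
# decay through follow-up (< 20% of peak by the end of a 23-week window)
effect_bump <- function(day, intervention_days) {
  mid <- intervention_days / 2
  u <- day / mid
  u * exp(1 - u)
}

#' Ground-truth mean surfaces for a simulated cohort
#'
#' Returns the true mean functions the generator draws from: control arm
#' follows a gentle secular trend around the baseline; the treatment arm adds
#' a smooth bump peaking mid-intervention and decaying toward control during
#' follow-up, plus the workout-day jump.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{"true_model"}: \code{mean_fun(outcome, day,
#'   group, workout)} evaluating true mean minutes, \code{beta_z_true} named
#'   vector of workout jumps (log scale for Gamma outcomes), and
#'   \code{workout_days}.
#' @export
make_true_eta <- function(config) {
  idays <- 7 * config$intervention_weeks
  wdays <- workout_days(config)
  outcomes <- config$outcomes
  n_days <- config$n_days
  mean_fun <- function(outcome, day, group, workout = NULL) {
    par <- outcomes[[outcome]]
    if (is.null(par)) stop("make_true_eta: unknown outcome ", outcome)
    if (is.null(workout)) workout <- as.numeric(day %in% wdays & group == "PEER")
    base <- par$baseline * (1 + par$drift * sin(2 * pi * day / n_days))
    mu <- base + par$effect * effect_bump(day, idays) * (group == "PEER")
    if (par$family == "gaussian") mu + par$jump * workout
    else mu * exp(par$jump * workout)
  }
  structure(list(mean_fun = mean_fun,
                 beta_z_true = vapply(outcomes, function(p) p$jump, 0),
                 workout_days = wdays, config = config),
            class = "true_model")
}

#' Simulate a two-arm daily-activity cohort
#'
#' Draws one record per participant-day (minus sporadic missing days):
#' Gaussian outcomes are truncated to \eqn{[0, 1440]} minutes, Gamma outcomes
#' use the configured shape with mean equal to the true surface, and the four
#' categories are proportionally rescaled on the rare days their sum exceeds
#' 1440 minutes.  Byte-identical across runs with the same seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{records} (long-format data frame with columns
#'   \code{participant_id}, \code{group}, \code{day}, \code{workout} and the
#'   four outcome columns) and \code{truth} (a \code{\link{make_true_eta}}
#'   model).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- make_true_eta(config)
  for (nm in names(config$outcomes)) {
    mx <- max(truth$mean_fun(nm, 0:(config$n_days - 1), "PEER"))
    if (mx > 1440)
      stop(sprintf("simulate_cohort: infeasible outcome '%s' (true mean %.0f > 1440)",
                   nm, mx))
  }
  ids <- c(sprintf("P%02d", seq_len(config$n_peer)),
           sprintf("C%02d", seq_len(config$n_control)))
  grp <- rep(c("PEER", "control"), c(config$n_peer, config$n_control))
  days <- 0:(config$n_days - 1)
  grid <- data.frame(
    participant_id = rep(ids, each = config$n_days),
    group = rep(grp, each = config$n_days),
    day = rep(days, length(ids)), stringsAsFactors = FALSE)
  records <- with_seed(config$seed, {
    keep <- stats::runif(nrow(grid)) >= config$missing_rate
    g <- grid[keep, , drop = FALSE]
    g$workout <- as.numeric(g$day %in% truth$workout_days & g$group == "PEER")
    for (nm in names(config$outcomes)) {
      par <- config$outcomes[[nm]]
      mu <- truth$mean_fun(nm, g$day, g$group, g$workout)
      g[[nm]] <- if (par$family == "gaussian") {
        pmin(pmax(stats::rnorm(nrow(g), mu, par$sd), 0), 1440)
      } else {
        stats::rgamma(nrow(g), shape = par$shape, scale = mu / par$shape)
      }
    }
    g
  })
  tot <- rowSums(records[names(config$outcomes)])
  over <- tot > 1440
  if (any(over)) {
    records[over, names(config$outcomes)] <-
      records[over, names(config$outcomes)] * (1440 / tot[over])
  }
  rownames(records) <- NULL
  list(records = records, truth = truth)
}

#' Write / read the pipeline's activity CSV
#'
#' The on-disk schema is the exact header
#' \code{participant_id,group,day,sedentary_min,light_min,fairly_min,very_min}.
#' \code{write_activity_csv} drops any extra columns (e.g. the simulator's
#' \code{workout} flag, which the analysis reconstructs from the study
#' config); the pair round-trips losslessly.
#'
#' @param records data frame of activity records.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_activity_csv <- function(records, path) {
  cols <- c("participant_id", "group", "day", "sedentary_min", "light_min",
            "fairly_min", "very_min")
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop("write_activity_csv: missing column(s): ",
         paste(missing, collapse = ", "))
  utils::write.csv(records[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
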