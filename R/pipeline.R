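# End-to-end pipeline: read activity CSV + study config, fit the four
# outcome models with their family assignments, emit prediction bands,
# component decompositions and effect summaries.

ACTIVITY_COLS <- c("participant_id", "group", "day", "sedentary_min",
                   "light_min", "fairly_min", "very_min")
OUTCOME_COLS <- ACTIVITY_COLS[4:7]

#' Study analysis configuration
#'
#' @param intervention_start_day,intervention_end_day,followup_end_day
#'   integer day boundaries, \code{start <= end <= followup_end}.
#' @param workout_days explicit integer list of treatment-group workout days.
#' @param family_map named character vector mapping outcome columns to
#'   \code{"gaussian"}/\code{"gamma"}; defaults: sedentary/light Gaussian,
#'   fairly/very Gamma.
#' @param zero_policy,zero_offset zero handling for Gamma outcomes (see
#'   \code{\link{zero_handling}}).
#' @param baseline_definition \code{"treat_week0"} (default: treatment-arm
#'   mean over days 0--6) or a named numeric vector of baselines per outcome.
#' @param treat treatment-arm label.
#' @param control a \code{\link{pa_control}} list.
#' @return list of class \code{"study_config"}.
#' @export
study_config <- function(intervention_start_day = 0,
                         intervention_end_day = 55,
                         followup_end_day = 160,
                         workout_days = seq(3, 52, by = 7),
                         family_map = c(sedentary_min = "gaussian",
                                        light_min = "gaussian",
                                        fairly_min = "gamma",
                                        very_min = "gamma"),
                         zero_policy = "offset", zero_offset = 0.5,
                         baseline_definition = "treat_week0",
                         treat = "PEER", control = pa_control()) {
  stopifnot(intervention_start_day <= intervention_end_day,
            intervention_end_day <= followup_end_day)
  if (!all(OUTCOME_COLS %in% names(family_map)))
    stop("study_config: family_map must cover all four outcome columns")
  if (!all(family_map %in% c("gaussian", "gamma")))
    stop("study_config: families must be 'gaussian' or 'gamma'")
  structure(list(intervention_start_day = intervention_start_day,
                 intervention_end_day = intervention_end_day,
                 followup_end_day = followup_end_day,
                 workout_days = as.integer(workout_days),
                 family_map = family_map, zero_policy = zero_policy,
                 zero_offset = zero_offset,
                 baseline_definition = baseline_definition,
                 treat = treat, control = control),
            class = "study_config")
}

#' Read a study config from YAML
#'
#' Any field of \code{\link{study_config}} may appear in the file; omitted
#' fields keep their defaults.
#'
#' @param path YAML file path.
#' @return a \code{"study_config"}.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("read_study_config: unknown field(s): ",
         paste(unknown, collapse = ", "))
  if (!is.null(raw$family_map)) raw$family_map <- unlist(raw$family_map)
  if (!is.null(raw$workout_days)) raw$workout_days <- unlist(raw$workout_days)
  do.call(study_config, raw)
}

#' Read and validate the pipeline's activity CSV
#'
#' Checks the exact column set, positive day budget (all minutes in
#' \eqn{[0, 1440]}), known group labels and uniqueness of
#' \code{(participant_id, day)}; accepts ISO-8601 dates in the \code{day}
#' column, converted to 0-based elapsed days.
#'
#' @param path CSV path.
#' @param treat,ctrl accepted group labels.
#' @return validated data frame.
#' @export
read_activity_csv <- function(path, treat = "PEER", ctrl = "control") {
  if (!file.exists(path)) stop("read_activity_csv: no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(ACTIVITY_COLS, names(tab))
  if (length(missing))
    stop("read_activity_csv: missing column(s): ",
         paste(missing, collapse = ", "))
  tab <- tab[ACTIVITY_COLS]
  if (nrow(tab) == 0) return(tab)
  if (is.character(tab$day)) {
    dates <- as.Date(tab$day)
    if (any(is.na(dates)))
      stop("read_activity_csv: 'day' must be integer study days or ISO-8601 dates (first bad row: ",
           which(is.na(dates))[1], ")")
    tab$day <- as.integer(dates - min(dates))
  }
  bad_grp <- !tab$group %in% c(treat, ctrl)
  if (any(bad_grp))
    stop(sprintf("read_activity_csv: unknown group label '%s' at row %d",
                 tab$group[which(bad_grp)[1]], which(bad_grp)[1]))
  for (col in OUTCOME_COLS) {
    bad <- !is.finite(tab[[col]]) | tab[[col]] < 0 | tab[[col]] > 1440
    if (any(bad))
      stop(sprintf("read_activity_csv: column '%s' out of [0, 1440] at row %d",
                   col, which(bad)[1]))
  }
  key <- paste(tab$participant_id, tab$day)
  if (anyDuplicated(key))
    stop(sprintf("read_activity_csv: duplicated (participant_id, day) at row %d",
                 anyDuplicated(key)))
  tab
}

#' Run the four-outcome SSANOVA analysis
#'
#' Fits each outcome with its mapped family and the partial-spline workout
#' term, then produces per-group prediction bands on the full day grid,
#' ANOVA components, the group-difference curve, and effect summaries for the
#' intervention and follow-up windows.  A failing outcome is marked failed
#' and the others proceed.
#'
#' @param records validated activity table (see
#'   \code{\link{read_activity_csv}}).
#' @param config a \code{\link{study_config}}.
#' @return list of class \code{"pa_results"}: per-outcome entries with
#'   \code{fit}, \code{bands}, \code{components}, \code{difference},
#'   \code{effects}, \code{log}.
#' @export
run_activity_analysis <- function(records, config) {
  stopifnot(inherits(config, "study_config"))
  if (length(unique(records$group)) < 2)
    stop("run_activity_analysis: both arms must be present")
  day_grid <- seq(min(records$day), config$followup_end_day)
  records$workout <- as.numeric(records$day %in% config$workout_days &
                                  records$group == config$treat)
  domain <- time_domain(min(records$day),
                        max(config$followup_end_day, max(records$day)))
  iw <- seq(config$intervention_start_day, config$intervention_end_day)
  fw <- seq(config$intervention_end_day + 1, config$followup_end_day)
  ctrl_lev <- setdiff(unique(records$group), config$treat)[1]

  out <- lapply(OUTCOME_COLS, function(outcome) {
    fam <- config$family_map[[outcome]]
    res <- tryCatch({
      fit <- pa_ssanova(stats::reformulate(c("day", "group"), outcome),
                        data = records, family = fam, workout = "workout",
                        domain = domain, treat = config$treat,
                        zero_policy = config$zero_policy,
                        zero_offset = config$zero_offset,
                        control = config$control)
      baseline <- if (is.numeric(config$baseline_definition))
        config$baseline_definition[[outcome]] else NULL
      bands <- rbind(
        predict_band(fit, config$treat, day_grid,
                     workout_days = config$workout_days),
        predict_band(fit, ctrl_lev, day_grid))
      bands <- cbind(outcome = outcome, as.data.frame(bands))
      comps <- rbind(ssanova_components(fit, day_grid, config$treat),
                     ssanova_components(fit, day_grid, ctrl_lev))
      comps <- cbind(outcome = outcome, comps)
      effects <- list(
        intervention = window_summary(fit, records, outcome, iw,
                                      "intervention", baseline),
        followup = window_summary(fit, records, outcome, fw,
                                  "followup", baseline))
      list(outcome = outcome, family = fam, failed = FALSE, fit = fit,
           bands = bands, components = comps,
           difference = cbind(outcome = outcome,
                              group_difference(fit, day_grid)),
           effects = effects,
           log = c(sprintf(
             "%s [%s]: lambda = %.4g, trace_A = %.2f, dispersion = %.4g, beta_z = %s, converged = %s",
             outcome, fam, fit$lambda, fit$trace_A, fit$dispersion,
             if (fit$has_z) sprintf("%.4f", fit$beta_z) else "dropped",
             fit$converged), fit$log))
    }, error = function(e) {
      list(outcome = outcome, family = fam, failed = TRUE,
           log = sprintf("%s [%s]: FAILED: %s", outcome, fam,
                         conditionMessage(e)))
    })
    res
  })
  names(out) <- OUTCOME_COLS
  structure(list(outcomes = out, config = config, day_grid = day_grid),
            class = "pa_results")
}

#' @export
print.pa_results <- function(x, ...) {
  cat("Activity SSANOVA analysis:",
      sum(!vapply(x$outcomes, `[[`, TRUE, "failed")), "of",
      length(x$outcomes), "outcomes fitted\n")
  for (o in x$outcomes) {
    cat("\n")
    if (o$failed) { cat(" ", o$log, "\n"); next }
    print(o$effects$intervention)
    print(o$effects$followup)
  }
  invisible(x)
}

effects_to_list <- function(bundle) {
  lapply(bundle$outcomes, function(o) {
    if (o$failed) return(list(failed = TRUE, log = o$log))
    lapply(o$effects, function(e) list(
      outcome = e$outcome, window = e$window,
      window_days = as.integer(e$window_days),
      mean_daily_diff = round(e$mean_daily_diff, 2),
      ci95 = round(unname(e$ci95), 2),
      baseline = round(e$baseline, 2),
      pct_change = e$pct_change,
      cohens_d = round(e$cohens_d, 2)))
  })
}

#' Write analysis outputs to a directory
#'
#' Emits \code{predictions.csv} (outcome, group, day, fit, lo95, hi95),
#' \code{components.csv}, \code{effects.json} and \code{run_log.txt};
#' deterministic given the same inputs.
#'
#' @param bundle a \code{"pa_results"} bundle.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- Filter(function(o) !o$failed, bundle$outcomes)
  preds <- do.call(rbind, lapply(ok, `[[`, "bands"))
  if (!is.null(preds)) {
    names(preds)[names(preds) == "lo"] <- "lo95"
    names(preds)[names(preds) == "hi"] <- "hi95"
    utils::write.csv(preds[c("outcome", "group", "day", "fit", "lo95", "hi95")],
                     file.path(out_dir, "predictions.csv"), row.names = FALSE)
  }
  comps <- do.call(rbind, lapply(ok, `[[`, "components"))
  if (!is.null(comps))
    utils::write.csv(comps, file.path(out_dir, "components.csv"),
                     row.names = FALSE)
  jsonlite::write_json(effects_to_list(bundle),
                       file.path(out_dir, "effects.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(unlist(lapply(bundle$outcomes, `[[`, "log")),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Human-readable report of written results
#'
#' @param results_dir directory produced by \code{\link{write_results}}.
#' @return the effects list, invisibly.
#' @export
report_results <- function(results_dir) {
  path <- file.path(results_dir, "effects.json")
  if (!file.exists(path)) stop("report_results: no effects.json in ", results_dir)
  eff <- jsonlite::read_json(path)
  for (nm in names(eff)) {
    o <- eff[[nm]]
    if (isTRUE(o$failed)) { cat(nm, ": FAILED\n"); next }
    for (w in o) {
      cat(sprintf("%-14s %-12s %8.2f min/day  [%6.2f, %6.2f]  %6.1f%%  d=%5.2f\n",
                  w$outcome, w$window, w$mean_daily_diff, w$ci95[[1]],
                  w$ci95[[2]], w$pct_change, w$cohens_d))
    }
  }
  invisible(eff)
}
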