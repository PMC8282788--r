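#' Validate worm-level lifespan records
#'
#' Lifespan experiments are recorded long-format, one row per worm:
#' `experiment_id`, `condition`, `worm_id`, `event_day` (days from L4,
#' t = 0), and `status`. Recognized statuses: `died`,
#' `excluded_internal_hatching` (matricidal hatching; removed from all
#' calculations), `excluded_other` (lost/crawled off), and `alive_at_end`
#' (carrying the last scoring day).
#'
#' @param df Data frame with the five columns above.
#' @return The validated data frame with class `lifespan_records` prepended.
#' @export
lifespan_records <- function(df) {
  need <- c("experiment_id", "condition", "worm_id", "event_day", "status")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_domain("lifespan records lack column(s): ",
                paste(missing_cols, collapse = ", "))
  ok_status <- c("died", "excluded_internal_hatching", "excluded_other",
                 "alive_at_end")
  bad <- setdiff(unique(as.character(df$status)), ok_status)
  if (length(bad))
    stop_domain("unknown status value(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(df$event_day) | df$event_day < 0))
    stop_domain("event_day must be finite and >= 0")
  df <- as.data.frame(df)
  if (!inherits(df, "lifespan_records")) class(df) <- c("lifespan_records", class(df))
  df
}

#' Read a long-format lifespan CSV
#'
#' @param path CSV with columns `experiment_id`, `condition`, `worm_id`,
#'   `event_day`, `status`.
#' @return A `lifespan_records` data frame.
#' @export
read_lifespan_csv <- function(path) {
  lifespan_records(read.csv(path, stringsAsFactors = FALSE))
}

#' Build a fraction-alive survival curve from worm records
#'
#' Worms with an excluded status are removed from the denominator entirely
#' (they are not censored): the effective cohort is the worms that died or
#' were alive at the final scoring. The curve gives the percentage of that
#' cohort alive at each scoring day:
#' `100 * (n_effective - deaths at or before day d) / n_effective`.
#'
#' @param records Worm-level records, one experiment and condition (see
#'   [lifespan_records()]; a plain data frame with the right columns works).
#' @param scoring_days Increasing numeric vector of days at which the curve is
#'   evaluated; defaults to day 0 plus every observed death day.
#' @param method `"exclude"` (default; drop exclusions from the denominator)
#'   or `"km"` (Kaplan-Meier product-limit estimate treating exclusions and
#'   worms alive at the end as right-censored, via the survival package).
#' @return An object of class `survival_curve`: list with `days`,
#'   `fraction_alive` (percent), `n_effective`, `n_excluded`, `method`.
#' @examples
#' rec <- data.frame(experiment_id = "e1", condition = "ctrl",
#'                   worm_id = 1:10, event_day = c(rep(5, 3), rep(10, 7)),
#'                   status = "died")
#' build_curve(rec, scoring_days = c(0, 5, 10))$fraction_alive
#' @export
build_curve <- function(records, scoring_days = NULL,
                        method = c("exclude", "km")) {
  method <- match.arg(method)
  records <- lifespan_records(records)
  if (length(unique(records$experiment_id)) > 1L ||
      length(unique(records$condition)) > 1L)
    stop_domain("build_curve expects one experiment and condition; see pool_experiments()")
  excluded <- grepl("^excluded", records$status)
  kept <- records[!excluded, , drop = FALSE]
  if (nrow(kept) == 0L)
    stop_domain("empty cohort after removing excluded worms")
  if (is.null(scoring_days))
    scoring_days <- sort(unique(c(0, kept$event_day[kept$status == "died"])))
  if (is.unsorted(scoring_days, strictly = TRUE))
    stop_domain("scoring_days must be strictly increasing")
  if (method == "exclude") {
    deaths <- kept$event_day[kept$status == "died"]
    n_eff <- nrow(kept)
    frac <- vapply(scoring_days,
                   function(d) 100 * (n_eff - sum(deaths <= d)) / n_eff,
                   numeric(1))
  } else {
    # right-censor exclusions and survivors at their last recorded day
    time <- records$event_day
    event <- as.integer(records$status == "died")
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    step <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
    frac <- 100 * step(scoring_days)
    n_eff <- nrow(records)
  }
  structure(list(days = as.numeric(scoring_days),
                 fraction_alive = as.numeric(frac),
                 n_effective = n_eff,
                 n_excluded = sum(excluded),
                 method = method),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> n = %d (%d excluded), %d scoring days, %s denominator\n",
              x$n_effective, x$n_excluded, length(x$days), x$method))
  invisible(x)
}

#' Pool worms from several experiments into a composite curve
#'
#' Composite survival plots pool the worms of all experiments into one cohort
#' before the curve is built (a worm-weighted composite: an experiment with
#' more worms contributes proportionally more), evaluated on the union of
#' scoring days.
#'
#' @param records Worm-level records from one condition, any number of
#'   experiments.
#' @inheritParams build_curve
#' @return A `survival_curve` for the pooled cohort.
#' @export
pool_experiments <- function(records, scoring_days = NULL,
                             method = c("exclude", "km")) {
  records <- lifespan_records(records)
  if (length(unique(records$condition)) > 1L)
    stop_domain("pool_experiments expects a single condition")
  pooled <- records
  pooled$experiment_id <- "pooled"
  build_curve(pooled, scoring_days = scoring_days, method = method)
}

# Boltzmann sigmoid: S(t) = A2 + (A1 - A2) / (1 + exp((t - x0) / dx))
boltzmann <- function(t, A1, A2, x0, dx) {
  A2 + (A1 - A2) / (1 + exp((t - x0) / dx))
}

#' Fit a Boltzmann sigmoid to a survival curve
#'
#' Least-squares fit of `S(t) = A2 + (A1 - A2) / (1 + exp((t - x0)/dx))` to
#' the fraction-alive points. With `fix_asymptotes = TRUE` (default) the
#' asymptotes are pinned at `A1 = 100`, `A2 = 0` — every worm starts alive and
#' eventually dies — and only the inflection `x0` (days) and slope scale `dx`
#' (days) are free; the fitted median lifespan is then `x0` exactly. The free
#' mode, for truncated experiments, fits all four parameters and solves
#' `S(t) = 50` for the median.
#'
#' Initialization is deterministic and data-driven: `x0` starts at the scoring
#' day whose survival is nearest 50%, and `dx` at half the day-span between
#' the points nearest 25% and 75% survival, clamped to at least 0.5 d.
#' Optimization uses Levenberg-Marquardt least squares.
#'
#' @param curve A `survival_curve`, or any list/data frame with `days` and
#'   `fraction_alive` (percent).
#' @param fix_asymptotes Pin `A1 = 100`, `A2 = 0`?
#' @return An object of class `boltzmann_fit`: `A1`, `A2`, `x0`, `dx`, `rss`,
#'   `median_lifespan`, `n_points`, `fixed_asymptotes`.
#' @examples
#' d <- seq(0, 30, by = 2)
#' cv <- list(days = d, fraction_alive = 100 / (1 + exp((d - 15) / 2)))
#' fit_boltzmann(cv)
#' @export
fit_boltzmann <- function(curve, fix_asymptotes = TRUE) {
  days <- curve$days
  pct <- curve$fraction_alive
  stopifnot(length(days) == length(pct))
  if (length(days) < 4L)
    stop_domain("need at least 4 curve points to fit a sigmoid")
  if (min(pct) >= 50 || max(pct) <= 50)
    stop_domain("degenerate curve: survival must span both sides of 50%")
  x0_init <- days[which.min(abs(pct - 50))]
  dx_init <- max((days[which.min(abs(pct - 25))] -
                  days[which.min(abs(pct - 75))]) / 2, 0.5)
  df <- data.frame(t = days, y = pct)
  fit <- tryCatch({
    if (fix_asymptotes) {
      minpack.lm::nlsLM(y ~ boltzmann(t, 100, 0, x0, dx), data = df,
                        start = list(x0 = x0_init, dx = dx_init),
                        lower = c(x0 = 0, dx = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ boltzmann(t, A1, A2, x0, dx), data = df,
                        start = list(A1 = 100, A2 = 0, x0 = x0_init, dx = dx_init),
                        lower = c(A1 = 0, A2 = -Inf, x0 = 0, dx = 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    stop_domain("Boltzmann fit failed (", conditionMessage(e),
                "); init x0 = ", x0_init, ", dx = ", dx_init,
                "; n = ", length(days), " points spanning ",
                round(min(pct), 1), "-", round(max(pct), 1), "%")
  })
  cf <- coef(fit)
  A1 <- if (fix_asymptotes) 100 else unname(cf["A1"])
  A2 <- if (fix_asymptotes) 0 else unname(cf["A2"])
  x0 <- unname(cf["x0"]); dx <- unname(cf["dx"])
  median_lifespan <- if (A2 < 50 && A1 > 50)
    x0 + dx * log((A1 - A2) / (50 - A2) - 1) else NA_real_
  structure(list(A1 = A1, A2 = A2, x0 = x0, dx = dx,
                 rss = sum(resid(fit)^2),
                 median_lifespan = median_lifespan,
                 n_points = length(days),
                 fixed_asymptotes = fix_asymptotes),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> x0 = %.2f d, dx = %.2f d, A1 = %.1f, A2 = %.1f (rss %.3g)\n  median lifespan = %.2f d%s\n",
    x$x0, x$dx, x$A1, x$A2, x$rss, x$median_lifespan,
    if (x$fixed_asymptotes) " [asymptotes fixed at 100/0]" else ""))
  invisible(x)
}

# per-experiment lifespan statistic for one condition
lifespan_stat_one <- function(records, stat, scoring_days = NULL) {
  if (stat == "mean") {
    deaths <- records$event_day[records$status == "died"]
    if (!length(deaths)) stop_domain("no deaths recorded; mean lifespan undefined")
    if (any(records$status == "alive_at_end"))
      warning("worms alive at the final scoring are ignored by the mean statistic",
              call. = FALSE)
    mean(deaths)
  } else {
    fit_boltzmann(build_curve(records, scoring_days = scoring_days))$median_lifespan
  }
}

#' Compare lifespans of a treated condition against control
#'
#' For each experiment shared between the two conditions, computes a lifespan
#' statistic per arm — the mean day of death, or the median from the Boltzmann
#' fit (default, matching the headline use of median lifespan) — and the
#' percent change `100 * (treated - control) / control`. Reports the mean and
#' sample SD (m - 1 denominator) of the percent changes across experiments.
#' The paired two-tailed Student t-test is computed on the per-experiment
#' *mean* lifespans (the convention for comparing lifespan experiments);
#' `t = mean(d) / (sd(d)/sqrt(m))` with `df = m - 1`.
#'
#' @param control,treated Worm-level records for the two conditions; they must
#'   share at least two `experiment_id`s.
#' @param stat Per-experiment statistic for the percent change: `"median"`
#'   (Boltzmann-fit median, default) or `"mean"` (mean day of death).
#' @return An object of class `lifespan_comparison`: `per_experiment` data
#'   frame (`experiment_id`, `control_stat`, `treated_stat`, `pct_change`),
#'   `mean_pct_change`, `sd_pct_change`, `t_stat`, `df`, `p_two_tailed`,
#'   `stat`, plus `sd_basis = "across experiments"` metadata flagging that the
#'   +/- SD is the spread across experiments, not propagated fit uncertainty.
#' @examples
#' ctrl <- data.frame(experiment_id = rep(c("e1", "e2"), each = 4),
#'                    condition = "ctrl", worm_id = 1:8,
#'                    event_day = c(10, 12, 14, 16, 11, 13, 15, 17),
#'                    status = "died")
#' trt <- ctrl; trt$condition <- "trt"; trt$event_day <- ctrl$event_day - 2
#' compare_conditions(ctrl, trt, stat = "mean")
#' @export
compare_conditions <- function(control, treated, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  control <- lifespan_records(control)
  treated <- lifespan_records(treated)
  shared <- sort(intersect(unique(control$experiment_id),
                           unique(treated$experiment_id)))
  if (length(shared) < 2L)
    stop_domain("paired comparison needs >= 2 shared experiments; found ",
                length(shared))
  per <- lapply(shared, function(ex) {
    rc <- control[control$experiment_id == ex, , drop = FALSE]
    rt <- treated[treated$experiment_id == ex, , drop = FALSE]
    cs <- lifespan_stat_one(rc, stat)
    ts <- lifespan_stat_one(rt, stat)
    data.frame(experiment_id = ex, control_stat = cs, treated_stat = ts,
               pct_change = 100 * (ts - cs) / cs,
               control_mean = lifespan_stat_one(rc, "mean"),
               treated_mean = lifespan_stat_one(rt, "mean"),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  m <- nrow(per)
  d <- per$treated_mean - per$control_mean
  if (sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
    if (mean(d) == 0)
      warning("identical per-experiment means; t = 0, p = 1 by convention",
              call. = FALSE)
  } else {
    tt <- t.test(per$treated_mean, per$control_mean, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(
    per_experiment = per[, c("experiment_id", "control_stat", "treated_stat",
                             "pct_change")],
    mean_pct_change = mean(per$pct_change),
    sd_pct_change = sd(per$pct_change),
    t_stat = t_stat, df = m - 1L, p_two_tailed = p,
    stat = stat, sd_basis = "across experiments"
  ), class = "lifespan_comparison")
}

#' @export
print.lifespan_comparison <- function(x, ...) {
  cat(sprintf(
    "<lifespan_comparison> %d experiments, %s statistic\n  lifespan change: %+.1f%% \u00b1 %.1f%% (SD across experiments)\n  paired t = %.3f, df = %d, two-tailed p = %.3g\n",
    nrow(x$per_experiment), x$stat, x$mean_pct_change, x$sd_pct_change,
    x$t_stat, x$df, x$p_two_tailed))
  invisible(x)
}

#' Format a percent-change result in reporting style
#'
#' @param x A `lifespan_comparison`.
#' @param digits Decimal places.
#' @return A string like `"-10.2% ± 3.1%"`.
#' @export
format_pct_change <- function(x, digits = 1) {
  stopifnot(inherits(x, "lifespan_comparison"))
  sprintf("%+.*f%% \u00b1 %.*f%%", digits, x$mean_pct_change,
          digits, x$sd_pct_change)
}
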