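#' Stress-assay survival outcome
#'
#' Survival rate after an acute challenge (oxidant, heat, tunicamycin):
#' the ratio of worms alive at assessment to the total challenged, as a
#' percentage.
#'
#' @param n_alive,n_total Counts; `0 <= n_alive <= n_total`, `n_total > 0`.
#' @param condition Optional label.
#' @return A list of class `stress_outcome` with `condition`, `n_total`,
#'   `n_alive`, `pct_survival`.
#' @examples
#' stress_survival(30, 40)$pct_survival  # 75
#' @export
stress_survival <- function(n_alive, n_total, condition = NA_character_) {
  if (!is_count(n_alive) || !is_count(n_total))
    stop_domain("counts must be non-negative integers")
  if (n_total == 0) stop_domain("n_total must be positive")
  if (n_alive > n_total) stop_domain("n_alive exceeds n_total")
  structure(list(condition = condition, n_total = as.integer(n_total),
                 n_alive = as.integer(n_alive),
                 pct_survival = 100 * n_alive / n_total),
            class = "stress_outcome")
}

#' Aggregate replicate stress-survival fractions
#'
#' Replicate experiments are summarized as mean percent survival ± SEM
#' (`SD / sqrt(r)` over the r replicate fractions), the convention for
#' replicate stress assays.
#'
#' @param n_alive,n_total Equal-length vectors of per-replicate counts.
#' @param condition Optional label.
#' @return List of class `stress_summary`: `condition`, `n_replicates`,
#'   `pct_survival` (per replicate), `mean_pct`, `sem_pct`.
#' @examples
#' stress_survival_summary(c(30, 32, 28), c(40, 40, 40))
#' @export
stress_survival_summary <- function(n_alive, n_total, condition = NA_character_) {
  stopifnot(length(n_alive) == length(n_total), length(n_alive) >= 1L)
  pct <- mapply(function(a, t) stress_survival(a, t)$pct_survival, n_alive, n_total)
  structure(list(condition = condition, n_replicates = length(pct),
                 pct_survival = as.numeric(pct),
                 mean_pct = mean(pct),
                 sem_pct = if (length(pct) > 1) sd(pct) / sqrt(length(pct)) else NA_real_),
            class = "stress_summary")
}

#' @export
print.stress_summary <- function(x, ...) {
  cat(sprintf("<stress_summary> %s: %.1f%% \u00b1 %.2f%% SEM (%d replicates)\n",
              if (is.na(x$condition)) "" else x$condition,
              x$mean_pct, x$sem_pct, x$n_replicates))
  invisible(x)
}

#' Fit a DTNB/GSH linear calibration curve
#'
#' Ordinary least-squares line `absorbance = slope * concentration +
#' intercept` through thiol standards (glutathione reacted with Ellman's
#' reagent, absorbance read at 412 nm). A valid DTNB curve has positive
#' slope; a non-positive fitted slope sets `valid = FALSE` rather than
#' erroring, so that degenerate plates are visible in reports.
#'
#' @param standards Data frame with columns `concentration` (µM
#'   GSH-equivalent thiol) and `absorbance` (A412).
#' @return List of class `calibration_curve`: `standards`, `slope`,
#'   `intercept`, `r2`, `valid`.
#' @examples
#' fit_calibration(data.frame(concentration = c(0, 50, 100),
#'                            absorbance = c(0, 0.5, 1.0)))
#' @export
fit_calibration <- function(standards) {
  stopifnot(all(c("concentration", "absorbance") %in% names(standards)))
  standards <- standards[complete.cases(standards[, c("concentration", "absorbance")]), ]
  if (length(unique(standards$concentration)) < 2L)
    stop_domain("degenerate design: need >= 2 distinct standard concentrations")
  fit <- lm(absorbance ~ concentration, data = standards)
  cf <- coef(fit)
  tss <- sum((standards$absorbance - mean(standards$absorbance))^2)
  r2 <- if (tss > 0) 1 - sum(resid(fit)^2) / tss else NA_real_
  slope <- unname(cf["concentration"])
  structure(list(standards = standards, slope = slope,
                 intercept = unname(cf["(Intercept)"]),
                 r2 = r2, valid = slope > 0),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> A412 = %.4g * conc + %.4g (r2 = %.4f)%s\n",
              x$slope, x$intercept, x$r2,
              if (x$valid) "" else " [INVALID: non-positive slope]"))
  invisible(x)
}

#' Quantify reduced thiols from absorbance, normalized to protein
#'
#' Inverts the calibration line, `conc = (A412 - intercept) / slope`, scales
#' by the assay volume factor (the lysate-aliquot to reaction-volume ratio,
#' supplied by the user because it is protocol-specific), and divides by the
#' protein mass so results are comparable across samples. Absorbances below
#' the intercept floor at zero with a warning rather than reporting negative
#' thiol.
#'
#' @param absorbance A412 reading(s).
#' @param curve A valid `calibration_curve`.
#' @param protein_mg Protein mass per sample (mg, from a BCA assay); positive.
#' @param volume_factor Multiplicative scaling from reaction concentration to
#'   per-sample amount (default 1, i.e. results in concentration units per mg).
#' @return Thiol content per mg protein (numeric, same length as
#'   `absorbance`).
#' @export
quantify_thiols <- function(absorbance, curve, protein_mg, volume_factor = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!curve$valid) stop_domain("calibration curve is invalid (non-positive slope)")
  if (any(!is.finite(protein_mg)) || any(protein_mg <= 0))
    stop_domain("protein_mg must be positive")
  conc <- (absorbance - curve$intercept) / curve$slope
  if (any(conc < 0)) {
    if (any(conc < -1e-9))  # numerically-zero negatives floor silently
      warning("absorbance below calibration intercept; flooring thiol content at 0",
              call. = FALSE)
    conc <- pmax(conc, 0)
  }
  conc * volume_factor / protein_mg
}

#' Box-plot style summary of a measurement group
#'
#' The summary convention used for per-worm fluorescence intensities: median,
#' 25th/75th percentile box, 5th/95th percentile whiskers, plus min, max and
#' mean. Percentiles use linear interpolation between order statistics by
#' default (`quantile` type 7, the spreadsheet/plotting-software convention);
#' the type is configurable and recorded in the output.
#'
#' @param values Numeric vector, `n >= 1`.
#' @param group Optional label.
#' @param quantile_type Passed to [stats::quantile()].
#' @return List of class `assay_summary`: `group`, `n`, `mean`, `median`,
#'   `q25`, `q75`, `p5`, `p95`, `min`, `max`, `quantile_type`.
#' @examples
#' summarize_group(1:10)
#' @export
summarize_group <- function(values, group = NA_character_, quantile_type = 7) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_domain("empty measurement group")
  q <- quantile(values, probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                type = quantile_type, names = FALSE)
  structure(list(group = group, n = length(values),
                 mean = mean(values), median = q[3],
                 q25 = q[2], q75 = q[4], p5 = q[1], p95 = q[5],
                 min = min(values), max = max(values),
                 quantile_type = quantile_type),
            class = "assay_summary")
}

#' @export
as.data.frame.assay_summary <- function(x, ...) {
  data.frame(group = x$group, n = x$n, mean = x$mean, median = x$median,
             q25 = x$q25, q75 = x$q75, p5 = x$p5, p95 = x$p95,
             min = x$min, max = x$max, stringsAsFactors = FALSE)
}

#' @export
print.assay_summary <- function(x, ...) {
  cat(sprintf(
    "<assay_summary> %s (n = %d): median %.3g [box %.3g-%.3g, whiskers %.3g-%.3g], mean %.3g\n",
    if (is.na(x$group)) "" else x$group, x$n, x$median, x$q25, x$q75,
    x$p5, x$p95, x$mean))
  invisible(x)
}

#' Summarize measurement groups from a long table
#'
#' @param df Data frame with columns `group` and `value`.
#' @param quantile_type See [summarize_group()].
#' @return Data frame, one row per group, columns as in [summarize_group()].
#' @export
summarize_groups <- function(df, quantile_type = 7) {
  stopifnot(all(c("group", "value") %in% names(df)))
  groups <- unique(as.character(df$group))
  do.call(rbind, lapply(groups, function(g) {
    as.data.frame(summarize_group(df$value[df$group == g], group = g,
                                  quantile_type = quantile_type))
  }))
}

#' Two-tailed t-test with the zero-variance convention
#'
#' Thin wrapper around [stats::t.test()] exposing the flags used throughout
#' this package: paired or unpaired, and Student's pooled-variance statistic
#' by default (Welch by `equal_var = FALSE`). Always two-tailed. When both
#' groups are constant with equal means — where `t.test` itself errors — the
#' convention `t = 0, p = 1` is returned with a warning; constant groups with
#' different means return `p = 0` with infinite `t`.
#'
#' @param a,b Numeric vectors (`n >= 2` each; equal length when paired).
#' @param paired Paired test on `a - b`?
#' @param equal_var Assume equal variances (Student's pooled t)?
#' @return List with `t`, `df`, `p`.
#' @examples
#' two_tailed_t(c(1, 2, 3), c(3, 4, 5))  # t = -2.449, df = 4
#' @export
two_tailed_t <- function(a, b, paired = FALSE, equal_var = TRUE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (paired && length(a) != length(b))
    stop_domain("paired test needs equal-length groups")
  degenerate <- if (paired) sd(a - b) == 0 else sd(a) == 0 && sd(b) == 0
  if (degenerate) {
    delta <- if (paired) mean(a - b) else mean(a) - mean(b)
    if (delta == 0) {
      warning("zero variance with equal means; returning t = 0, p = 1 by convention",
              call. = FALSE)
      return(list(t = 0, df = NA_real_, p = 1))
    }
    warning("zero variance with unequal means; returning p = 0", call. = FALSE)
    return(list(t = sign(delta) * Inf, df = NA_real_, p = 0))
  }
  tt <- t.test(a, b, paired = paired, var.equal = equal_var,
               alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
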