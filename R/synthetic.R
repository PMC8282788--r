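#' Generate two gene sets with a planted overlap
#'
#' Constructs, deterministically for a given seed, a pair of gene sets over
#' the universe `g000001 ... gN` whose intersection has *exactly*
#' `k_planted` genes: the first set is `n1` genes sampled uniformly; the
#' second takes `k_planted` genes from inside the first and `n2 - k_planted`
#' from outside it. The planted representation factor is therefore
#' `k_planted * N / (n1 * n2)` by construction, which makes the generator an
#' oracle for the whole overlap pipeline.
#'
#' @param N Universe size.
#' @param n1,n2 Set sizes.
#' @param k_planted Planted overlap count, `<= min(n1, n2)`; additionally
#'   `n2 - k_planted <= N - n1` must hold for the outside draw to be feasible.
#' @param seed Integer seed.
#' @return List with `set1`, `set2` (both `gene_set`), and the scenario
#'   parameters including `rf_planted`.
#' @examples
#' sc <- gen_overlap_sets(2000, 100, 150, k_planted = 30, seed = 1)
#' length(intersect(sc$set1$genes, sc$set2$genes))  # exactly 30
#' @export
gen_overlap_sets <- function(N, n1, n2, k_planted, seed = 1) {
  check_overlap_counts(n1, n2, N, k_planted)
  if (n2 - k_planted > N - n1)
    stop_domain("infeasible scenario: n2 - k_planted (", n2 - k_planted,
                ") exceeds N - n1 (", N - n1, ")")
  set.seed(seed)
  universe <- sprintf("g%06d", seq_len(N))
  g1 <- sample(universe, n1)
  outside <- setdiff(universe, g1)
  g2 <- c(if (k_planted > 0) sample(g1, k_planted) else character(0),
          if (n2 - k_planted > 0) sample(outside, n2 - k_planted) else character(0))
  list(set1 = gene_set("planted_set1", g1, universe_size = N, normalize = FALSE),
       set2 = gene_set("planted_set2", g2, universe_size = N, normalize = FALSE),
       N = N, n1 = n1, n2 = n2, k_planted = k_planted,
       rf_planted = k_planted * N / (n1 * n2), seed = seed)
}

#' Generate a synthetic DE table
#'
#' Per-gene log2 fold changes drawn from a normal null, with a chosen subset
#' of genes given a planted shift, plus two-sided p-values from the z score.
#' Useful for exercising thresholding; it simulates at the log2FC summary
#' level only (no read counts).
#'
#' @param n_genes Number of genes (`gene_id` = `g000001 ...`).
#' @param null_sd SD of the null log2FC distribution.
#' @param planted Optional data frame with columns `gene_id`, `log2fc` of
#'   planted true effects (overrides the null draw for those genes).
#' @param seed Integer seed.
#' @return A `de_table`.
#' @export
gen_de_table <- function(n_genes, null_sd = 0.5, planted = NULL, seed = 1) {
  set.seed(seed)
  ids <- sprintf("G%06d", seq_len(n_genes))
  lfc <- rnorm(n_genes, 0, null_sd)
  if (!is.null(planted)) {
    idx <- match(normalize_gene_ids(planted$gene_id), ids)
    if (anyNA(idx)) stop_domain("planted gene ids outside the simulated universe")
    lfc[idx] <- planted$log2fc
  }
  z <- lfc / null_sd
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(gene_id = ids, log2fc = lfc, pvalue = p,
                    padj = pmin(p * n_genes / rank(p), 1),  # BH-style, for plumbing only
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Simulate worm lifespan cohorts with logistic death times
#'
#' Death times are drawn from a logistic distribution with location `x0`
#' (days; `x0 * treatment_factor` for the treated arm) and scale `dx`, so
#' that the true survival function is exactly the Boltzmann sigmoid
#' `100 / (1 + exp((t - x0)/dx))` that the lifespan module fits — the
#' generator's parameters are directly recoverable. Draws are left-truncated
#' at 0 (negative times resampled), then rounded *up* to the next scoring day
#' (deaths are discovered at plate scoring, so the recorded fraction alive at
#' each scoring day is an unbiased sample of the true survival there). A
#' fraction of worms is marked `excluded_internal_hatching` at a uniform
#' random day before their death. `method = "gompertz"` substitutes Gompertz
#' death times with the same median and comparable spread, for
#' misspecification testing.
#'
#' @param n_worms Worms per condition per experiment.
#' @param x0 True median lifespan (days) of the control arm.
#' @param dx True logistic scale (days).
#' @param scoring_interval Days between scorings (plates are typically scored
#'   every 2-3 days).
#' @param pct_excluded Percent of worms with internal hatching, `[0, 100)`.
#' @param treatment_factor Multiplicative effect on the treated median; set
#'   `NULL` for a control-only cohort.
#' @param n_experiments Number of independent experiments.
#' @param seed Integer master seed (per-experiment streams are derived from
#'   it).
#' @param method `"logistic"` (default) or `"gompertz"`.
#' @return A `lifespan_records` data frame with conditions `"control"` and
#'   (unless `treatment_factor` is `NULL`) `"treated"`.
#' @examples
#' rec <- gen_lifespan_cohort(50, x0 = 15, dx = 2, seed = 7)
#' table(rec$condition)
#' @export
gen_lifespan_cohort <- function(n_worms, x0 = 15, dx = 2, scoring_interval = 2,
                                pct_excluded = 0, treatment_factor = 1,
                                n_experiments = 1, seed = 1,
                                method = c("logistic", "gompertz")) {
  method <- match.arg(method)
  stopifnot(x0 > 0, dx > 0, scoring_interval > 0,
            pct_excluded >= 0, pct_excluded < 100)
  conditions <- if (is.null(treatment_factor)) "control" else c("control", "treated")
  out <- list()
  for (e in seq_len(n_experiments)) {
    set.seed(seed + 104729L * (e - 1L))  # independent per-experiment stream
    for (cond in conditions) {
      loc <- if (cond == "treated") x0 * treatment_factor else x0
      t_death <- draw_death_times(n_worms, loc, dx, method)
      day <- ceiling(t_death / scoring_interval) * scoring_interval
      day[day <= 0] <- scoring_interval
      status <- rep("died", n_worms)
      n_excl <- round(n_worms * pct_excluded / 100)
      if (n_excl > 0) {
        idx <- sample(n_worms, n_excl)
        status[idx] <- "excluded_internal_hatching"
        # hatching observed at a random scoring day before the would-be death
        day[idx] <- pmax(scoring_interval,
                         ceiling(runif(n_excl, 0, day[idx]) / scoring_interval) *
                           scoring_interval)
      }
      out[[length(out) + 1L]] <- data.frame(
        experiment_id = sprintf("exp%02d", e), condition = cond,
        worm_id = sprintf("%s_%s_w%04d", sprintf("exp%02d", e), cond,
                          seq_len(n_worms)),
        event_day = day, status = status, stringsAsFactors = FALSE)
    }
  }
  lifespan_records(do.call(rbind, out))
}

draw_death_times <- function(n, location, scale, method) {
  draw <- function(m) {
    if (method == "logistic") rlogis(m, location, scale)
    else {
      # Gompertz via inverse CDF, shape b chosen so the median matches `location`
      b <- 0.15
      a <- b * log(2) / (exp(b * location) - 1)
      u <- runif(m)
      log(1 - b / a * log(1 - u)) / b
    }
  }
  t <- draw(n)
  while (any(t <= 0)) t[t <= 0] <- draw(sum(t <= 0))  # left-truncate at 0
  t
}

#' Generate normally distributed assay measurement groups
#'
#' Independent normal draws per group, deterministically for a given seed;
#' emulates per-worm fluorescence intensity tables.
#'
#' @param groups Data frame with columns `label`, `mean`, `sd` (`>= 0`), `n`
#'   (`>= 1`).
#' @param seed Integer seed.
#' @return Data frame with columns `group`, `value`.
#' @examples
#' g <- data.frame(label = c("LB", "DB"), mean = c(100, 60), sd = 15, n = 50)
#' head(gen_assay_groups(g, seed = 3))
#' @export
gen_assay_groups <- function(groups, seed = 1) {
  stopifnot(all(c("label", "mean", "sd", "n") %in% names(groups)),
            all(groups$sd >= 0), all(groups$n >= 1))
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    data.frame(group = as.character(groups$label[i]),
               value = rnorm(groups$n[i], groups$mean[i], groups$sd[i]),
               stringsAsFactors = FALSE)
  }))
}
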