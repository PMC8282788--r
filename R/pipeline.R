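# condition classes used by the CLI to map errors to exit codes
stop_config <- function(...) {
  stop(structure(class = c("thiolspan_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
stop_data <- function(...) {
  stop(structure(class = c("thiolspan_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Build an analysis configuration
#'
#' Bundles the knobs shared by the pipelines: the gene universe size, named
#' differential-expression threshold presets, the lifespan statistic, the
#' percentile convention, a seed, and the I/O sections consumed by
#' [run_overlap_pipeline()] and [run_lifespan_pipeline()]. Configurations
#' round-trip losslessly through YAML ([read_analysis_config()] /
#' [write_analysis_config()]).
#'
#' @param universe_size Gene-universe size (default [CELEGANS_UNIVERSE]).
#' @param lifespan_stat `"median"` or `"mean"` (see [compare_conditions()]).
#' @param percentile_convention `quantile` type for assay summaries.
#' @param seed Integer seed recorded in reports and used by any simulation
#'   the pipelines perform.
#' @param overlap,lifespan,assay Optional named lists: the module sections
#'   (see the pipeline functions for the keys each consumes).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(universe_size = CELEGANS_UNIVERSE,
                            lifespan_stat = c("median", "mean"),
                            percentile_convention = 7,
                            seed = 1,
                            overlap = NULL, lifespan = NULL, assay = NULL) {
  lifespan_stat <- match.arg(lifespan_stat)
  if (!is_count(universe_size) || universe_size < 1)
    stop_config("universe_size must be a positive integer")
  structure(list(universe_size = as.integer(universe_size),
                 lifespan_stat = lifespan_stat,
                 percentile_convention = percentile_convention,
                 seed = as.integer(seed),
                 overlap = overlap, lifespan = lifespan, assay = assay),
            class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_analysis_config` returns an `analysis_config`;
#'   `write_analysis_config` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  keep <- intersect(names(raw), names(formals(analysis_config)))
  do.call(analysis_config, raw[keep])
}

#' @rdname read_analysis_config
#' @param config An `analysis_config`.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# resolve a threshold section (preset name or explicit fields) to a spec
resolve_threshold <- function(x) {
  if (inherits(x, "threshold_spec")) return(x)
  if (is.character(x) && length(x) == 1L) return(threshold_preset(x))
  if (is.list(x)) {
    preset <- x$preset
    if (!is.null(preset)) return(threshold_preset(preset, direction = x$direction %||% "both"))
    return(threshold_spec(direction = x$direction %||% "both",
                          min_abs_log2fc = x$min_abs_log2fc %||% 0,
                          max_padj = x$max_padj,
                          top_n = x$top_n,
                          rank_key = x$rank_key %||% "log2fc"))
  }
  stop_config("cannot interpret threshold specification")
}

# read a reference set file: GMT (list) or one-gene-per-line (single set)
read_reference_sets <- function(path) {
  if (!file.exists(path)) stop_config("reference set file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) read_gmt(path) else list(read_gene_list(path))
}

#' Run the gene-set overlap pipeline
#'
#' Computes overlap reports from an `analysis_config`'s `overlap` section,
#' which may contain any of:
#' \describe{
#'   \item{`counts`}{list of entries `label`, `k`, `n1`, `n2` (and optional
#'     `N`): direct audits of printed counts, no gene lists needed.}
#'   \item{`de_table` + `reference_sets` + `threshold`}{a DE table path (with
#'     optional `column_map`), a GMT or gene-list path, and a threshold
#'     (preset name or explicit fields): the thresholded set is overlapped
#'     against every reference set.}
#'   \item{`set_pairs`}{list of entries `a`, `b` naming GMT/gene-list files
#'     to overlap directly.}
#' }
#' An empty section yields an empty report (not an error). When `out_dir` is
#' given, writes `overlap_report.tsv` plus a JSON provenance sidecar embedding
#' the resolved config, package version and seed.
#'
#' @param config An `analysis_config`.
#' @param out_dir Optional output directory (created if needed).
#' @return Data frame of overlap reports (one row per comparison; columns as
#'   [as.data.frame.overlap_result()]), invisibly when writing.
#' @export
run_overlap_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  ov <- config$overlap
  N <- config$universe_size
  rows <- list()
  for (entry in ov$counts %||% list()) {
    res <- overlap_from_counts(entry$k, entry$n1, entry$n2, entry$N %||% N,
                               labels = c(entry$label %||% "set1", "counts"))
    rows[[length(rows) + 1L]] <- as.data.frame(res)
  }
  if (!is.null(ov$de_table)) {
    de_path <- if (is.list(ov$de_table)) ov$de_table$path else ov$de_table
    if (!file.exists(de_path)) stop_config("DE table not found: ", de_path)
    cmap <- ov$de_table$column_map
    tab <- if (is.null(cmap)) read_de_table(de_path)
           else read_de_table(de_path, column_map = unlist(cmap))
    spec <- resolve_threshold(ov$threshold %||% "fold2")
    de_set <- threshold_set(tab, spec, name = ov$de_set_name %||% "de_set",
                            universe_size = N)
    for (ref in read_reference_sets(ov$reference_sets)) {
      ref$universe_size <- N
      rows[[length(rows) + 1L]] <- as.data.frame(overlap_report(de_set, ref, N = N))
    }
  }
  for (pair in ov$set_pairs %||% list()) {
    a <- read_reference_sets(pair$a)[[1]]
    b <- read_reference_sets(pair$b)[[1]]
    rows[[length(rows) + 1L]] <- as.data.frame(overlap_report(a, b, N = N))
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set1 = character(0), set2 = character(0), k = integer(0),
               n1 = integer(0), n2 = integer(0), N = integer(0),
               expected = numeric(0), rf = numeric(0),
               p_exact = numeric(0), p_normal = numeric(0))
  report$rf_printed <- round(report$rf, 1)  # RF at the customary 1 d.p.
  if (!is.null(out_dir)) {
    write_report(report, config, out_dir, "overlap_report")
    return(invisible(report))
  }
  report
}

#' Run the lifespan pipeline
#'
#' From the config's `lifespan` section (`input`: long-format CSV path;
#' `control`: control condition label; `treated`: character vector of treated
#' condition labels, optional): builds the composite (worm-pooled) survival
#' curve and Boltzmann fit for every condition, and a [compare_conditions()]
#' comparison of each treated condition against control, formatted in the
#' reporting style `"+x% ± y%"`. With a single condition, only curves and
#' fits are produced.
#'
#' @inheritParams run_overlap_pipeline
#' @return List with `curves` (named list of `survival_curve`), `fits` (named
#'   list of `boltzmann_fit`), `comparisons` (named list of
#'   `lifespan_comparison`), `summary` (data frame). Writes
#'   `lifespan_report.tsv` + JSON provenance when `out_dir` is given.
#' @export
run_lifespan_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  ls_cfg <- config$lifespan
  if (is.null(ls_cfg$input)) stop_config("lifespan section needs an 'input' CSV path")
  if (!file.exists(ls_cfg$input)) stop_config("lifespan input not found: ", ls_cfg$input)
  records <- read_lifespan_csv(ls_cfg$input)
  conditions <- unique(records$condition)
  curves <- fits <- list()
  for (cond in conditions) {
    rc <- records[records$condition == cond, , drop = FALSE]
    curves[[cond]] <- pool_experiments(rc)
    fits[[cond]] <- tryCatch(fit_boltzmann(curves[[cond]]),
                             error = function(e) NULL)
  }
  control <- ls_cfg$control %||% conditions[[1]]
  if (!control %in% conditions)
    stop_data("control condition '", control, "' absent from input")
  treated <- ls_cfg$treated %||% setdiff(conditions, control)
  comparisons <- list()
  for (cond in intersect(treated, conditions)) {
    comparisons[[cond]] <- compare_conditions(
      records[records$condition == control, , drop = FALSE],
      records[records$condition == cond, , drop = FALSE],
      stat = config$lifespan_stat)
  }
  summary_df <- do.call(rbind,
    lapply(conditions, function(cond) {
      f <- fits[[cond]]
      data.frame(condition = cond, n_effective = curves[[cond]]$n_effective,
                 n_excluded = curves[[cond]]$n_excluded,
                 median_lifespan = if (is.null(f)) NA_real_ else f$median_lifespan,
                 x0 = if (is.null(f)) NA_real_ else f$x0,
                 dx = if (is.null(f)) NA_real_ else f$dx,
                 pct_change = NA_real_, sd_pct_change = NA_real_,
                 pct_change_label = NA_character_, p_paired = NA_real_,
                 stringsAsFactors = FALSE)
    }))
  rownames(summary_df) <- NULL
  for (cond in names(comparisons)) {
    cmp <- comparisons[[cond]]
    i <- summary_df$condition == cond
    summary_df$pct_change[i] <- cmp$mean_pct_change
    summary_df$sd_pct_change[i] <- cmp$sd_pct_change
    summary_df$pct_change_label[i] <- format_pct_change(cmp)
    summary_df$p_paired[i] <- cmp$p_two_tailed
  }
  if (!is.null(out_dir)) write_report(summary_df, config, out_dir, "lifespan_report")
  list(curves = curves, fits = fits, comparisons = comparisons,
       summary = summary_df)
}

# TSV + JSON provenance pair; the JSON embeds the resolved config so every
# report can be audited for its thresholds and universe size
write_report <- function(df, config, out_dir, stem) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(out_dir, paste0(stem, ".tsv"))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(tool = "thiolspan",
               version = as.character(packageVersion("thiolspan")),
               seed = config$seed,
               config = unclass(config),
               rows = nrow(df))
  jsonlite::write_json(meta, file.path(out_dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(tsv)
}
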