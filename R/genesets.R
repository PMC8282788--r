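#' Construct a gene set
#'
#' A `gene_set` is a named collection of unique gene identifiers within a
#' declared gene universe. Identifiers are canonicalized (whitespace trimmed,
#' upper-cased) by default so that mixed-case WormBase/common names from
#' published lists match; disable with `normalize = FALSE`.
#'
#' @param name Label for the set.
#' @param genes Character vector of gene identifiers; duplicates collapsed.
#' @param universe_size Positive integer count of background genes, or `NA` if
#'   not yet declared (e.g. straight after reading a GMT file).
#' @param normalize Canonicalize identifiers before deduplication?
#' @return An object of class `gene_set` with elements `name`, `genes`
#'   (unique, in first-occurrence order) and `universe_size`.
#' @examples
#' gene_set("daf16_targets", c("sod-3", "mtl-1", "SOD-3"))
#' @export
gene_set <- function(name, genes, universe_size = NA_integer_, normalize = TRUE) {
  stopifnot(is.character(name) || is.factor(name), length(name) == 1L)
  genes <- normalize_gene_ids(genes, normalize)
  genes <- genes[!is.na(genes) & nzchar(genes)]
  genes <- unique(genes)
  if (!is.na(universe_size)) {
    if (!is_count(universe_size) || universe_size < 1)
      stop_domain("universe_size must be a positive integer")
    if (length(genes) > universe_size)
      stop_domain("gene set larger than its declared universe (",
                  length(genes), " > ", universe_size, ")")
    universe_size <- as.integer(universe_size)
  }
  structure(list(name = as.character(name), genes = genes,
                 universe_size = universe_size),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes (universe %s)\n", x$name,
              length(x$genes),
              if (is.na(x$universe_size)) "unset" else x$universe_size))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read gene sets from a GMT file
#'
#' GMT is the tab-separated gene-set dialect: each line holds a set name, a
#' description, then one field per gene. Duplicate genes within a line are
#' collapsed with a warning. `universe_size` is left unset; declare it later
#' (it is an analysis choice, not a file property).
#'
#' @param path Path to a GMT file.
#' @param normalize Canonicalize identifiers (see [gene_set()])?
#' @return List of `gene_set` objects, one per non-empty line.
#' @seealso [write_gmt()], [read_gene_list()]
#' @export
read_gmt <- function(path, normalize = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop_domain("malformed GMT line ", i, " in '", path,
                  "': fewer than 3 tab-separated fields")
    genes <- fields[-(1:2)]
    norm <- normalize_gene_ids(genes, normalize)
    norm <- norm[!is.na(norm) & nzchar(norm)]
    if (anyDuplicated(norm))
      warning(sprintf("GMT line %d ('%s'): %d duplicate gene id(s) collapsed",
                      i, fields[[1]], sum(duplicated(norm))), call. = FALSE)
    out[[i]] <- gene_set(fields[[1]], genes, normalize = normalize)
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets A `gene_set` or list of them.
#' @param path Output path.
#' @param description Description field (second GMT column) recycled per set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-gene-per-line text file as a gene set
#'
#' @param path Path to a plain-text file, one gene identifier per line; blank
#'   lines and lines starting with `#` are skipped.
#' @param name Set label; defaults to the file name without extension.
#' @inheritParams gene_set
#' @return A `gene_set`.
#' @export
read_gene_list <- function(path, name = NULL, universe_size = NA_integer_,
                           normalize = TRUE) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  gene_set(name, lines, universe_size = universe_size, normalize = normalize)
}

#' Read a differential-expression table
#'
#' Reads a TSV/CSV of per-gene differential-expression results (the output of
#' a DESeq2-style analysis; this package consumes such tables, it does not
#' produce them). Column names are configurable through `column_map`; the
#' defaults match DESeq2 result exports. Rows whose log2 fold change cannot be
#' parsed are dropped with a warning stating the count.
#'
#' @param path Path to a delimited file with a header. Files ending in `.csv`
#'   are read as comma-separated, anything else as tab-separated.
#' @param column_map Named character vector mapping the roles `gene_id`,
#'   `log2fc`, `pvalue`, `padj` to column names in the file. `pvalue`/`padj`
#'   may be omitted or name absent columns only if set to `NA`.
#' @param normalize Canonicalize gene identifiers?
#' @return A `data.frame` of class `de_table` with columns `gene_id`,
#'   `log2fc`, `pvalue`, `padj` (missing p columns filled with `NA`).
#' @export
read_de_table <- function(path,
                          column_map = c(gene_id = "gene_id",
                                         log2fc = "log2FoldChange",
                                         pvalue = "pvalue",
                                         padj = "padj"),
                          normalize = TRUE) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) read.csv else read.delim
  raw <- reader(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "log2fc")
  for (role in need) {
    cm <- column_map[[role]]
    if (is.null(cm) || is.na(cm) || !cm %in% names(raw))
      stop_domain("configuration error: column for '", role,
                  "' (", column_map[[role]] %||% "<unset>",
                  ") not found in ", path)
  }
  get_col <- function(role) {
    cm <- column_map[[role]]
    if (is.null(cm) || is.na(cm) || !cm %in% names(raw)) rep(NA_real_, nrow(raw))
    else suppressWarnings(as.numeric(raw[[cm]]))
  }
  out <- data.frame(
    gene_id = normalize_gene_ids(raw[[column_map[["gene_id"]]]], normalize),
    log2fc = suppressWarnings(as.numeric(raw[[column_map[["log2fc"]]]])),
    pvalue = get_col("pvalue"),
    padj = get_col("padj"),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(out$log2fc)
  if (any(bad)) {
    warning(sprintf("dropped %d row(s) with unparsable log2 fold change", sum(bad)),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup))
    stop_domain("duplicate gene_id in DE table: ",
                paste(unique(dup), collapse = ", "))
  for (p in c("pvalue", "padj")) {
    ok <- is.na(out[[p]]) | (out[[p]] >= 0 & out[[p]] <= 1)
    if (!all(ok)) stop_domain("'", p, "' outside [0,1] in ", path)
  }
  rownames(out) <- NULL
  class(out) <- c("de_table", "data.frame")
  out
}

#' Specify a differential-expression threshold
#'
#' Encodes the selection rules used to turn a DE table into a gene set:
#' a direction, a strict magnitude bound on the log2 fold change, an optional
#' adjusted-p cutoff, and an optional top-n rank truncation. A published
#' ">k fold" criterion corresponds to `min_abs_log2fc = log2(k)` with a
#' *strict* inequality.
#'
#' @param direction One of `"up"`, `"down"`, `"both"`.
#' @param min_abs_log2fc Non-negative magnitude bound; genes pass when
#'   `|log2fc| > min_abs_log2fc` (strict) in the requested direction.
#' @param max_padj Optional adjusted-p cutoff (`padj <= max_padj`); `NULL`
#'   (default) applies no p filter, matching set descriptions that state only
#'   a fold-change bound.
#' @param top_n Optional rank truncation applied after filtering.
#' @param rank_key Ranking used for `top_n`: `"log2fc"` (|log2fc| descending),
#'   `"pvalue"` or `"padj"` (ascending).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(direction = c("both", "up", "down"),
                           min_abs_log2fc = 0,
                           max_padj = NULL,
                           top_n = NULL,
                           rank_key = c("log2fc", "pvalue", "padj")) {
  direction <- match.arg(direction)
  rank_key <- match.arg(rank_key)
  stopifnot(is.numeric(min_abs_log2fc), length(min_abs_log2fc) == 1L,
            min_abs_log2fc >= 0)
  if (!is.null(max_padj)) {
    stopifnot(is.numeric(max_padj), length(max_padj) == 1L)
    if (max_padj <= 0 || max_padj > 1)
      stop_domain("max_padj must lie in (0, 1]")
  }
  if (!is.null(top_n)) {
    if (!is_count(top_n) || top_n < 1) stop_domain("top_n must be a positive integer")
    top_n <- as.integer(top_n)
  }
  structure(list(direction = direction, min_abs_log2fc = min_abs_log2fc,
                 max_padj = max_padj, top_n = top_n, rank_key = rank_key),
            class = "threshold_spec")
}

#' Named threshold presets
#'
#' `fold2` selects |log2fc| > 1 (a ">2 fold" change); `log2_0.5` and
#' `log2_1.0` select |log2fc| > 0.5 and > 1.0 respectively.
#'
#' @param name Preset name.
#' @param direction Passed through to [threshold_spec()].
#' @return A `threshold_spec`.
#' @export
threshold_preset <- function(name = c("fold2", "log2_0.5", "log2_1.0"),
                             direction = "both") {
  name <- match.arg(name)
  cut <- switch(name, fold2 = 1, log2_0.5 = 0.5, log2_1.0 = 1)
  threshold_spec(direction = direction, min_abs_log2fc = cut)
}

#' Build a gene set from a DE table by thresholding
#'
#' Applies direction + strict magnitude (+ optional adjusted-p) filters, then
#' an optional top-n rank truncation. Ties at the top-n boundary are broken by
#' lexicographic gene id so that set construction is deterministic. Asking for
#' more genes than pass the filters returns all passing genes with a warning.
#'
#' @param table A `de_table` (see [read_de_table()]) or data.frame with
#'   columns `gene_id`, `log2fc` and optionally `pvalue`, `padj`.
#' @param spec A [threshold_spec()].
#' @param name Label for the resulting set.
#' @param universe_size Background size recorded on the set.
#' @return A `gene_set`.
#' @examples
#' tab <- data.frame(gene_id = c("a", "b", "c", "d"),
#'                   log2fc = c(-1.5, -0.8, 2.1, -1.0))
#' threshold_set(tab, threshold_spec("down", min_abs_log2fc = 1), "dn")$genes
#' @export
threshold_set <- function(table, spec, name, universe_size = NA_integer_) {
  stopifnot(inherits(spec, "threshold_spec"),
            all(c("gene_id", "log2fc") %in% names(table)))
  lfc <- table$log2fc
  keep <- switch(spec$direction,
    up = lfc > spec$min_abs_log2fc,
    down = lfc < -spec$min_abs_log2fc,
    both = abs(lfc) > spec$min_abs_log2fc
  )
  if (!is.null(spec$max_padj)) {
    padj <- if ("padj" %in% names(table)) table$padj else rep(NA_real_, nrow(table))
    keep <- keep & !is.na(padj) & padj <= spec$max_padj
  }
  keep[is.na(keep)] <- FALSE
  sel <- table[keep, , drop = FALSE]
  if (!is.null(spec$top_n)) {
    key <- switch(spec$rank_key,
      log2fc = -abs(sel$log2fc),
      pvalue = if ("pvalue" %in% names(sel)) sel$pvalue else
        stop_domain("rank_key 'pvalue' but table has no pvalue column"),
      padj = if ("padj" %in% names(sel)) sel$padj else
        stop_domain("rank_key 'padj' but table has no padj column")
    )
    ord <- order(key, sel$gene_id)  # lexicographic gene_id breaks ties
    sel <- sel[ord, , drop = FALSE]
    if (spec$top_n > nrow(sel)) {
      warning(sprintf("top_n = %d exceeds the %d genes passing filters; returning all",
                      spec$top_n, nrow(sel)), call. = FALSE)
    } else {
      sel <- sel[seq_len(spec$top_n), , drop = FALSE]
    }
  }
  gene_set(name, sel$gene_id, universe_size = universe_size, normalize = FALSE)
}

#' Intersect two gene sets
#'
#' @param a,b `gene_set` objects (identifiers are assumed already
#'   canonicalized by their constructors).
#' @return A `gene_set` named `"a \u2229 b"` whose universe is taken from the
#'   inputs (they must agree when both are declared).
#' @export
intersect_sets <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  ua <- a$universe_size; ub <- b$universe_size
  if (!is.na(ua) && !is.na(ub) && ua != ub)
    stop_domain("gene sets declare different universe sizes (", ua, " vs ", ub, ")")
  gene_set(paste(a$name, "\u2229", b$name),
           intersect(a$genes, b$genes),
           universe_size = if (!is.na(ua)) ua else ub,
           normalize = FALSE)
}
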