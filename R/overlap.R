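#' Expected overlap of two independent gene sets
#'
#' For sets of sizes `n1` and `n2` drawn independently from a universe of `N`
#' genes, the expected number of shared genes is `n1 * n2 / N` (the mean of
#' the hypergeometric overlap distribution). Returned at full precision.
#'
#' @param n1,n2 Set sizes (positive integers, each `<= N`).
#' @param N Universe size (positive integer).
#' @return The expected overlap, a real number.
#' @examples
#' expected_overlap(500, 1382, 20470)  # 33.757...
#' @export
expected_overlap <- function(n1, n2, N) {
  check_overlap_counts(n1, n2, N)
  if (n1 <= 0 || n2 <= 0) stop_domain("n1 and n2 must be positive")
  n1 * n2 / N
}

# shared validation for the overlap statistics
check_overlap_counts <- function(n1, n2, N, k = NULL) {
  for (v in list(n1 = n1, n2 = n2, N = N))
    if (!is_count(v)) stop_domain("set and universe sizes must be non-negative integers")
  if (N == 0) stop_domain("universe size N must be positive")
  if (n1 > N || n2 > N)
    stop_domain("set size exceeds universe size (n1=", n1, ", n2=", n2, ", N=", N, ")")
  if (!is.null(k)) {
    if (!is_count(k)) stop_domain("k must be a non-negative integer")
    if (k > min(n1, n2))
      stop_domain("overlap k=", k, " exceeds min(n1, n2)=", min(n1, n2))
  }
  invisible(TRUE)
}

#' Representation factor of an observed overlap
#'
#' The representation factor (RF) is the observed overlap count divided by the
#' overlap expected for two independent sets drawn from a common universe:
#' `RF = k / (n1 * n2 / N) = k * N / (n1 * n2)`. RF > 1 indicates more overlap
#' than chance; RF < 1 less. Full precision is returned; formatted reports
#' round to one decimal place (see [format.overlap_result()]).
#'
#' @param k Observed overlap count (`0 <= k <= min(n1, n2)`).
#' @inheritParams expected_overlap
#' @return The representation factor, a real number.
#' @examples
#' representation_factor(189, 500, 1382, 20470)  # 5.6 at 1 d.p.
#' @export
representation_factor <- function(k, n1, n2, N) {
  check_overlap_counts(n1, n2, N, k)
  k / expected_overlap(n1, n2, N)
}

#' Exact hypergeometric upper-tail probability of an overlap
#'
#' Probability of observing `k` or more shared genes between independent sets
#' of sizes `n1` and `n2` drawn from a universe of `N` genes:
#' `P(X >= k)` with `X ~ Hypergeometric(N, n1, n2)`. Each probability mass
#' term is evaluated in log space from log-gamma binomial coefficients and the
#' tail is accumulated by log-sum-exp, so extreme enrichments (p well below
#' double underflow of a single naive factorial ratio) remain accurate. The
#' result is clipped to [0, 1].
#'
#' @inheritParams representation_factor
#' @param log_p Return the natural log of the tail probability instead.
#' @return `P(X >= k)`, or its log when `log_p = TRUE`.
#' @examples
#' hypergeom_tail_p(5, 5, 5, 10)   # 1/252
#' hypergeom_tail_p(0, 50, 50, 100)  # 1: tail at zero
#' @export
hypergeom_tail_p <- function(k, n1, n2, N, log_p = FALSE) {
  check_overlap_counts(n1, n2, N, k)
  lo <- max(0L, n1 + n2 - N)  # smallest feasible overlap
  hi <- min(n1, n2)
  if (k <= lo) return(if (log_p) 0 else 1)
  i <- k:hi
  log_terms <- log_choose(n1, i) + log_choose(N - n1, n2 - i) - log_choose(N, n2)
  lp <- logsumexp(log_terms)
  lp <- min(lp, 0)
  if (log_p) lp else min(max(exp(lp), 0), 1)
}

#' Normal approximation to the hypergeometric tail probability
#'
#' Upper-tail standard-normal probability of
#' `z = (k - mu - c) / sigma`, where `mu = n1*n2/N` and
#' `sigma^2 = n1*n2*(N-n1)*(N-n2) / (N^2*(N-1))` are the hypergeometric mean
#' and variance, and `c = 0.5` applies the continuity correction (default on,
#' standard practice when approximating a discrete distribution).
#'
#' @inheritParams representation_factor
#' @param continuity Apply the 0.5 continuity correction?
#' @return An upper-tail probability in [0, 1]. When the variance is zero
#'   (degenerate cases such as `n1 = N`), returns 1 if `k <= mu` else 0, with
#'   a warning.
#' @export
normal_approx_p <- function(k, n1, n2, N, continuity = TRUE) {
  check_overlap_counts(n1, n2, N, k)
  mu <- n1 * n2 / N
  sigma2 <- hypergeom_variance(n1, n2, N)
  if (sigma2 <= 0) {
    warning("degenerate overlap distribution (zero variance); returning a point-mass tail",
            call. = FALSE)
    return(if (k <= mu) 1 else 0)
  }
  cc <- if (continuity) 0.5 else 0
  pnorm((k - mu - cc) / sqrt(sigma2), lower.tail = FALSE)
}

hypergeom_variance <- function(n1, n2, N) {
  if (N <= 1) return(0)
  n1 <- as.numeric(n1); n2 <- as.numeric(n2); N <- as.numeric(N)
  n1 * n2 * (N - n1) * (N - n2) / (N^2 * (N - 1))
}

#' Overlap statistics from printed counts
#'
#' Computes the full overlap report — expected overlap, representation factor,
#' exact hypergeometric tail probability and its normal approximation — from
#' the four counts alone. This is the form used to audit published overlap
#' figures, where `k`, `n1`, `n2` and `N` are printed but the gene lists are
#' not.
#'
#' @inheritParams representation_factor
#' @param continuity Continuity correction for the normal approximation.
#' @param labels Optional character vector of length 2 naming the two sets.
#' @return An object of class `overlap_result`: a list with fields `k`, `n1`,
#'   `n2`, `N`, `expected`, `rf`, `mu`, `sigma2`, `p_exact`, `p_normal`,
#'   `labels`.
#' @examples
#' overlap_from_counts(189, 500, 1382, 20470)
#' @export
overlap_from_counts <- function(k, n1, n2, N = CELEGANS_UNIVERSE,
                                continuity = TRUE, labels = c("set1", "set2")) {
  check_overlap_counts(n1, n2, N, k)
  if (n1 <= 0 || n2 <= 0) stop_domain("n1 and n2 must be positive")
  expected <- expected_overlap(n1, n2, N)
  structure(list(
    k = as.integer(k), n1 = as.integer(n1), n2 = as.integer(n2), N = as.integer(N),
    expected = expected,
    rf = k / expected,
    mu = expected,
    sigma2 = hypergeom_variance(n1, n2, N),
    p_exact = hypergeom_tail_p(k, n1, n2, N),
    p_normal = normal_approx_p(k, n1, n2, N, continuity = continuity),
    labels = as.character(labels)
  ), class = "overlap_result")
}

#' Overlap report for two gene sets
#'
#' Intersects two gene sets and computes the overlap statistics against a
#' fixed gene universe. The universe size defaults to the sets' declared
#' universe, falling back to [CELEGANS_UNIVERSE].
#'
#' @param a,b `gene_set` objects.
#' @param N Universe size; `NULL` takes the sets' declared universe.
#' @param continuity Continuity correction for the normal approximation.
#' @return An `overlap_result` (see [overlap_from_counts()]).
#' @export
overlap_report <- function(a, b, N = NULL, continuity = TRUE) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  if (is.null(N)) {
    declared <- c(a$universe_size, b$universe_size)
    declared <- declared[!is.na(declared)]
    if (length(declared) && length(unique(declared)) > 1L)
      stop_domain("gene sets declare different universe sizes")
    N <- if (length(declared)) declared[[1]] else CELEGANS_UNIVERSE
  }
  k <- length(intersect(a$genes, b$genes))
  overlap_from_counts(k, length(a$genes), length(b$genes), N,
                      continuity = continuity, labels = c(a$name, b$name))
}

#' @export
format.overlap_result <- function(x, ...) {
  sprintf(
    "overlap %s vs %s: k = %d (n1 = %d, n2 = %d, N = %d)\n  expected = %.3f, RF = %.1f\n  p_exact = %.3g, p_normal = %.3g",
    x$labels[1], x$labels[2], x$k, x$n1, x$n2, x$N, x$expected, x$rf,
    x$p_exact, x$p_normal)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.data.frame.overlap_result <- function(x, ...) {
  data.frame(set1 = x$labels[1], set2 = x$labels[2],
             k = x$k, n1 = x$n1, n2 = x$n2, N = x$N,
             expected = x$expected, rf = x$rf,
             p_exact = x$p_exact, p_normal = x$p_normal,
             stringsAsFactors = FALSE)
}
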