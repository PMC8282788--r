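# fixtures built in code, used across test files

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# brute-force hypergeometric upper tail by exact pmf summation with plain
# binomial coefficients (independent of the package's log-gamma path)
tail_p_bruteforce <- function(k, n1, n2, N) {
  lo <- max(0, n1 + n2 - N)
  hi <- min(n1, n2)
  if (k <= lo) return(1)
  i <- k:hi
  sum(choose(n1, i) * choose(N - n1, n2 - i)) / choose(N, n2)
}

# small deterministic lifespan cohort: deaths at given days, one experiment
make_cohort <- function(days, status = "died", experiment = "e1",
                        condition = "ctrl") {
  data.frame(experiment_id = experiment, condition = condition,
             worm_id = paste0(experiment, "_", condition, "_", seq_along(days)),
             event_day = days,
             status = rep_len(status, length(days)),
             stringsAsFactors = FALSE)
}

# noiseless Boltzmann curve points
sigmoid_curve <- function(x0, dx, days = seq(0, 40, by = 2), A1 = 100, A2 = 0) {
  list(days = days,
       fraction_alive = A2 + (A1 - A2) / (1 + exp((days - x0) / dx)))
}
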