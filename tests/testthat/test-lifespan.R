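test_that("survival curves count deaths against the post-exclusion denominator", {
  rec <- make_cohort(c(rep(5, 3), rep(10, 7)))
  cv <- build_curve(rec, scoring_days = c(0, 5, 10))
  expect_equal(cv$fraction_alive, c(100, 70, 0))
  expect_equal(cv$n_effective, 10)

  # internal-hatching worms leave the denominator entirely
  rec2 <- rbind(make_cohort(rep(4, 8)),
                make_cohort(c(2, 3))[, ])
  rec2$status[9:10] <- "excluded_internal_hatching"
  rec2$worm_id <- paste0("w", 1:10)
  cv2 <- build_curve(rec2, scoring_days = c(0, 4))
  expect_equal(cv2$n_effective, 8)
  expect_equal(cv2$n_excluded, 2)
  expect_equal(cv2$fraction_alive, c(100, 0))

  expect_error(build_curve(rec2[9:10, ]), "empty cohort")
  expect_error(build_curve(rec, scoring_days = c(0, 10, 5)), "increasing")
})

test_that("curves start at 100 and never increase", {
  for (s in 1:5) {
    rec <- gen_lifespan_cohort(80, x0 = 12, dx = 3, pct_excluded = 10,
                               treatment_factor = NULL, seed = s)
    cv <- pool_experiments(rec, scoring_days = sort(unique(c(0, rec$event_day))))
    expect_equal(cv$fraction_alive[1], 100)
    expect_true(all(diff(cv$fraction_alive) <= 0))
  }
})

test_that("empirical curve of a large logistic cohort tracks the true sigmoid", {
  rec <- gen_lifespan_cohort(200, x0 = 15, dx = 2, scoring_interval = 2,
                             treatment_factor = NULL, seed = 9)
  days <- sort(unique(c(0, rec$event_day)))
  cv <- build_curve(rec, scoring_days = days)
  truth <- 100 / (1 + exp((days - 15) / 2))
  # binomial sampling band: generous 4 * sqrt(p(1-p)/n) * 100
  band <- 4 * sqrt(pmax(truth / 100 * (1 - truth / 100), 1e-4) / 200) * 100
  expect_true(all(abs(cv$fraction_alive - truth) <= pmax(band, 6)))
})

test_that("Boltzmann fit recovers noiseless parameters and is translation-equivariant", {
  f <- fit_boltzmann(sigmoid_curve(15, 2))
  expect_equal(f$x0, 15, tolerance = 1e-6)
  expect_equal(f$dx, 2, tolerance = 1e-6)
  expect_equal(f$median_lifespan, 15, tolerance = 1e-6)
  expect_lt(f$rss, 1e-10)

  shifted <- sigmoid_curve(15, 2, days = seq(0, 40, by = 2) )
  shifted$days <- shifted$days + 3
  f3 <- fit_boltzmann(shifted)
  expect_equal(f3$median_lifespan, f$median_lifespan + 3, tolerance = 1e-6)

  # free-asymptote mode recovers a truncated curve's median via S(t) = 50
  part <- sigmoid_curve(15, 2, days = seq(0, 40, 2), A1 = 100, A2 = 10)
  ff <- fit_boltzmann(part, fix_asymptotes = FALSE)
  expect_equal(ff$A2, 10, tolerance = 1e-4)
  expect_equal(ff$median_lifespan, 15 + 2 * log(90 / 40 - 1), tolerance = 1e-4)
})

test_that("degenerate or tiny curves are rejected with informative errors", {
  expect_error(fit_boltzmann(list(days = c(0, 2, 4), fraction_alive = c(100, 60, 0))),
               "at least 4")
  expect_error(fit_boltzmann(list(days = 0:5, fraction_alive = rep(100, 6))),
               "degenerate")
  expect_error(fit_boltzmann(list(days = 0:5, fraction_alive = rep(10, 6))),
               "degenerate")
})

test_that("fits on synthetic cohorts recover the planted median", {
  x0s <- vapply(1:20, function(s) {
    rec <- gen_lifespan_cohort(200, x0 = 15, dx = 2, scoring_interval = 2,
                               treatment_factor = NULL, seed = 100 + s)
    cv <- build_curve(rec, scoring_days = sort(unique(c(0, rec$event_day))))
    fit_boltzmann(cv)$x0
  }, numeric(1))
  expect_lt(abs(mean(x0s) - 15) / 15, 0.02)
})

test_that("pooling experiments weights by worm count", {
  one <- make_cohort(c(10, 12, 14, 16, 18))
  two <- make_cohort(c(10, 12, 14, 16, 18), experiment = "e2")
  # identical experiments: composite equals either alone
  cv1 <- build_curve(one)
  cvp <- pool_experiments(rbind(one, two), scoring_days = cv1$days)
  expect_equal(cvp$fraction_alive, cv1$fraction_alive)
  # single experiment: identity
  expect_equal(pool_experiments(one, scoring_days = cv1$days)$fraction_alive,
               cv1$fraction_alive)

  # unequal cohorts: composite median sits nearer the bigger experiment
  small <- make_cohort(rep(c(8, 10, 12), c(3, 4, 3)))            # n=10, median 10
  big <- make_cohort(rep(c(18, 20, 22), c(9, 12, 9)),
                     experiment = "e2")                          # n=30, median 20
  days <- sort(unique(c(0, small$event_day, big$event_day)))
  comp <- pool_experiments(rbind(small, big), scoring_days = days)
  pooled_median <- days[which(comp$fraction_alive <= 50)[1]]
  expect_gt(pooled_median, 15)  # closer to 20 than the unweighted 15
})

test_that("Kaplan-Meier mode censors instead of excluding", {
  rec <- make_cohort(c(5, 5, 10, 10, 10))
  rec$status[1] <- "excluded_other"
  km <- build_curve(rec, scoring_days = c(0, 5, 10), method = "km")
  # product-limit with deaths-before-censorings at ties: S(5) = 4/5
  expect_equal(km$fraction_alive, c(100, 80, 0))
})

test_that("paired comparison matches the closed-form t on per-experiment differences", {
  # three experiments whose mean lifespans differ by exactly 1, 2, 3 days
  ctrl <- rbind(make_cohort(c(10, 12), "died", "e1"),
                make_cohort(c(11, 13), "died", "e2"),
                make_cohort(c(12, 14), "died", "e3"))
  trt <- rbind(make_cohort(c(11, 13), "died", "e1", "trt"),
               make_cohort(c(13, 15), "died", "e2", "trt"),
               make_cohort(c(15, 17), "died", "e3", "trt"))
  cmp <- compare_conditions(ctrl, trt, stat = "mean")
  expect_equal(cmp$t_stat, 2 / (1 / sqrt(3)), tolerance = 1e-6)   # 3.4641
  expect_equal(cmp$df, 2L)
  expect_equal(cmp$p_two_tailed, 2 * pt(-sqrt(12), 2), tolerance = 1e-9)
  expect_equal(cmp$per_experiment$pct_change,
               100 * c(1 / 11, 2 / 12, 3 / 13), tolerance = 1e-9)

  # identical arms: all-zero percent change with the zero-variance convention
  expect_warning(null_cmp <- compare_conditions(ctrl, ctrl, stat = "mean"),
                 "convention")
  expect_equal(null_cmp$mean_pct_change, 0)
  expect_equal(null_cmp$t_stat, 0)
  expect_equal(null_cmp$p_two_tailed, 1)

  # swapping arms negates the percent changes
  rev_cmp <- compare_conditions(trt, ctrl, stat = "mean")
  expect_equal(sign(rev_cmp$per_experiment$pct_change),
               -sign(cmp$per_experiment$pct_change))

  expect_error(compare_conditions(ctrl[ctrl$experiment_id == "e1", ], trt),
               ">= 2 shared experiments")
})

test_that("a planted multiplicative treatment effect is recovered as percent change", {
  rec <- gen_lifespan_cohort(100, x0 = 15, dx = 2, treatment_factor = 0.9,
                             n_experiments = 10, seed = 77)
  cmp <- compare_conditions(rec[rec$condition == "control", ],
                            rec[rec$condition == "treated", ], stat = "median")
  se <- cmp$sd_pct_change / sqrt(nrow(cmp$per_experiment))
  expect_lt(abs(cmp$mean_pct_change - (-10)), 3 * se + 1)
  expect_lt(cmp$p_two_tailed, 0.01)
  expect_match(format_pct_change(cmp), "^-\\d+\\.\\d%")
})
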