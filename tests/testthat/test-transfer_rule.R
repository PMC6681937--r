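test_that("the truncated-exponential family is a proper density", {
  for (delta in c(0.1, 0.26, 2)) {
    expect_equal(stats::integrate(dtruncexp, 0, 1, delta = delta)$value, 1,
                 tolerance = 1e-8)
    expect_equal(ptruncexp(qtruncexp(c(0.2, 0.9), delta), delta),
                 c(0.2, 0.9), tolerance = 1e-12)
    expect_equal(stats::integrate(function(x) x * dtruncexp(x, delta),
                                  0, 1)$value,
                 truncexp_mean(delta), tolerance = 1e-8)
  }
})

test_that("transfer fractions and potentials follow their definitions", {
  # f1 loads 8, passes 2 to a1, then passes 0.9 more:
  # at that event the donor holds 6/10, the recipient 2/5
  sched <- colony_schedule(
    data.frame(time = 1:3, donor = c("SOURCE", "f1", "f1"),
               recipient = c("f1", "a1", "a1"), volume = c(8, 2, 0.9)))
  trace <- track_provenance(sched)
  caps <- c(f1 = 10, a1 = 5)
  fr <- compute_transfer_fractions(trace, caps)
  row <- fr[fr$event_index == 3, ]
  expect_equal(row$v_max, 3)
  expect_equal(row$v_tilde, 0.3)
  expect_equal(row$d, 0.6)
  expect_equal(row$r, 0.4)
  expect_equal(row$p, 0.36)
  expect_true(row$forager_donor)

  # a full recipient gives v_max = 0: excluded but counted
  caps_full <- c(f1 = 10, a1 = 2)
  fr2 <- compute_transfer_fractions(trace, caps_full)
  expect_equal(attr(fr2, "n_excluded_vmax0"), 1)
  expect_false(3 %in% fr2$event_index)

  # missing capacities are skipped and counted
  fr3 <- compute_transfer_fractions(trace, c(f1 = 10))
  expect_equal(nrow(fr3), 0)
  expect_equal(attr(fr3, "n_missing_capacity"), 2)
})

test_that("delta MLE agrees with a grid-search likelihood oracle", {
  set.seed(42)
  x <- rtruncexp(5000, 0.26)
  fit <- fit_delta_mle(x)
  expect_lt(abs(fit$delta - 0.26), 0.01)
  # independent oracle: profile the log-likelihood on a fine grid
  grid <- seq(0.15, 0.40, by = 1e-4)
  ll <- vapply(grid, function(d) sum(log(dtruncexp(x, d))), numeric(1))
  expect_lt(abs(fit$delta - grid[which.max(ll)]), 2e-4)
  expect_equal(fit$c_delta, 1 / (1 - exp(-1 / fit$delta)))
})

test_that("boundary samples are flagged rather than force-fitted", {
  expect_error(fit_delta_mle(numeric(0)), "empty")
  expect_true(fit_delta_mle(rep(0, 5))$degenerate)
  unb <- fit_delta_mle(c(0.4, 0.5, 0.6, 0.7))  # mean 0.55 >= 0.5
  expect_true(unb$unbounded)
  expect_identical(unb$delta, Inf)
  # zeros are excluded as non-transfers and counted
  fit <- fit_delta_mle(c(0, 0, rtruncexp(500, 0.2)))
  expect_equal(fit$n_zero, 2L)
  expect_equal(fit$n, 500L)
})

test_that("per-bin fits are flat when the rule is p-independent", {
  col <- small_colony(seed = 10, n_ants = 40, n_foragers = 4,
                      n_events = 1500)
  trace <- track_provenance(col$schedule)
  fr <- compute_transfer_fractions(trace, col$capacities)
  bins <- binned_rule_fit(fr)
  fitted <- bins[bins$fitted, ]
  expect_gte(nrow(fitted), 2)
  expect_true(all(abs(fitted$delta - 0.26) < 0.12))
  expect_true(all(fitted$r_squared > 0.5))
  # a single all-covering bin reduces to the plain MLE
  one <- binned_rule_fit(fr, bin_edges = c(0, 1))
  expect_equal(one$delta, fit_delta_mle(fr$v_tilde)$delta)
  # undersized bins are flagged, not fitted
  tiny <- binned_rule_fit(fr[1:10, ], bin_edges = c(0, 1))
  expect_false(tiny$fitted)
})

test_that("directionality statistics classify events as designed", {
  # all transfers at detection error -> everything ambiguous
  ev <- data.frame(time = 1:3, donor = c("SOURCE", "f1", "a1"),
                   recipient = c("f1", "a1", "a2"),
                   volume = c(1, 0.004, 0.001))
  trace <- track_provenance(colony_schedule(ev))
  caps <- c(f1 = 1, a1 = 1, a2 = 1)
  ds <- directionality_stats(trace, caps, epsilon = 0.01)
  expect_equal(ds$forager_nonforager$frac_ambiguous, 1)
  expect_equal(ds$nonforager_nonforager$frac_ambiguous, 1)

  col <- small_colony(seed = 11, n_events = 400)
  tr <- track_provenance(col$schedule)
  ds2 <- directionality_stats(tr, col$capacities)
  fn <- ds2$forager_nonforager
  expect_equal(fn$frac_forager_donor + fn$frac_forager_recipient +
                 fn$frac_ambiguous, 1, tolerance = 1e-12)
  # the generator only ever uses foragers as donors
  expect_equal(fn$frac_forager_recipient, 0)
  expect_gt(fn$frac_forager_donor, 0.5)

  # invariant to a uniform rescaling of volumes and capacities
  ev2 <- col$schedule$events
  ev2$volume <- ev2$volume * 50
  tr2 <- track_provenance(colony_schedule(ev2))
  ds3 <- directionality_stats(tr2, col$capacities * 50)
  expect_equal(ds3, ds2)
})

test_that("two-sample KS behaves at its extremes", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
  expect_equal(ks_two_sample(x, x + 10)$statistic, 1)
  expect_error(ks_two_sample(numeric(0), x), "empty")
})
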