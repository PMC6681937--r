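test_that("shannon entropy matches closed-form cases and validates input", {
  expect_equal(shannon_entropy(c(0.5, 0.5), base = 2), 1)
  expect_equal(shannon_entropy(c(1, 0)), 0)
  # a 3:1 crop is about 0.81 bits, i.e. ~80% of the 1-bit maximum
  expect_equal(shannon_entropy(c(0.75, 0.25), base = 2), 0.8112781,
               tolerance = 1e-6)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")
  expect_error(shannon_entropy(c(0.5, 0.4)), "sum to 1")
  # base change: bits = nats / ln 2
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(shannon_entropy(p, base = 2),
               shannon_entropy(p) / log(2))
})

test_that("types entropy hits its bounds in the designed cases", {
  # five foragers contributing equally -> log 5
  ev <- data.frame(
    time = 1:10,
    donor = c(paste0("SOURCE"), "f1", "SOURCE", "f2", "SOURCE", "f3",
              "SOURCE", "f4", "SOURCE", "f5"),
    recipient = c("f1", "a1", "f2", "a2", "f3", "a3", "f4", "a4", "f5",
                  "a5"),
    volume = 1)
  trace <- track_provenance(colony_schedule(ev))
  expect_equal(types_entropy(trace), log(5))
  expect_equal(types_entropy(trace, base = 2), log2(5))
  # a single active forager -> 0
  one <- track_provenance(colony_schedule(data.frame(
    time = 1:2, donor = c("SOURCE", "f1"), recipient = c("f1", "a1"),
    volume = 1)))
  expect_equal(types_entropy(one), 0)
  # undefined while the non-forager pool is empty
  expect_error(types_entropy(one, index = 1), "Z = 0")
})

test_that("mixing entropy spans pure crops to perfect blending", {
  # every loaded ant pure-typed -> H_mix = 0
  pure <- track_provenance(tiny_schedule())
  expect_equal(mixing_entropy(pure, 4)$H_mix, 0)
  # identical crop blends matching the global distribution -> H_mix = H_types
  ev <- data.frame(
    time = 1:6,
    donor = c("SOURCE", "SOURCE", "f1", "f1", "f2", "f2"),
    recipient = c("f1", "f2", "a1", "a2", "a1", "a2"),
    volume = c(4, 2, 2, 2, 1, 1))
  blended <- track_provenance(colony_schedule(ev))
  expect_equal(mixing_entropy(blended)$H_mix, types_entropy(blended),
               tolerance = 1e-12)
  # and the weighted-average definition holds on an arbitrary trace
  col <- small_colony(seed = 6)
  trace <- track_provenance(col$schedule)
  me <- mixing_entropy(trace)
  snap <- provenance_at(trace)
  manual <- sum(snap$P_a[!is.na(me$h_a)] * me$h_a[!is.na(me$h_a)])
  expect_equal(me$H_mix, manual, tolerance = 1e-12)
  expect_true(all(me$h_a >= 0 & me$h_a <= log(3) + 1e-12, na.rm = TRUE))
})

test_that("overall mixing entropy factorises when forager crops are pure", {
  trace <- track_provenance(tiny_schedule())
  # right after the source trips all food sits in pure forager crops
  expect_equal(overall_mixing_entropy(trace, 2), 0)
  col <- small_colony(seed = 7)
  tr <- track_provenance(col$schedule)
  k <- length(tr$Z)
  expect_equal(overall_mixing_entropy(tr, k),
               tr$P_colony[k] * mixing_entropy(tr, k)$H_mix,
               tolerance = 1e-9)
  # direct weighted-sum evaluation agrees
  n_all <- tr$amounts[k, , ]
  totals <- rowSums(n_all)
  h <- apply(n_all[totals > 0, ], 1, function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p))
  })
  expect_equal(overall_mixing_entropy(tr, k),
               sum(totals[totals > 0] * h) / tr$M[k], tolerance = 1e-12)
})

test_that("entropy trajectories respect the conditioning bound", {
  col <- small_colony(seed = 8, n_events = 250)
  trace <- track_provenance(col$schedule)
  et <- entropy_trace(trace)
  ok <- !is.na(et$H_mix)
  expect_true(any(ok))
  expect_true(all(et$H_mix[ok] <= et$H_types[ok] + 1e-9))
  expect_true(all(et$H_types[ok] <= log(3) + 1e-9))
  norm <- entropy_trace(trace, normalize = TRUE)
  expect_true(all(norm$H_types[ok] <= 1 + 1e-9))
  expect_equal(norm$H_mix[ok], et$H_mix[ok] / log(3), tolerance = 1e-12)
  expect_true(is.finite(attr(norm, "mean_h_norm")))
})

test_that("largest-events entropy follows its defining cases", {
  expect_equal(largest_events_entropy(3.2, n = 5), 0)
  expect_equal(largest_events_entropy(rep(2, 4), n = 4), log(4))
  # only the n largest events count
  expect_equal(largest_events_entropy(c(8, 8, 0.001, 0.001), n = 2), log(2))
  expect_error(largest_events_entropy(numeric(0), n = 3), "undefined")
  col <- small_colony(seed = 9)
  dist <- largest_events_distribution(col$schedule)
  expect_true(all(dist >= 0 & dist <= log(3) + 1e-12))
})

test_that("geometric sequence entropy evaluates in closed form", {
  expect_equal(geometric_mix_entropy(0.5, 2, base = 2),
               -(2 / 3) * log2(2 / 3) - (1 / 3) * log2(1 / 3),
               tolerance = 1e-12)
  # almost all mass lands in the first event as delta -> 1
  expect_lt(geometric_mix_entropy(1 - 1e-9, 5), 1e-6)
  expect_error(geometric_mix_entropy(0, 5), "delta")
  expect_error(geometric_mix_entropy(1.2, 5), "delta")
  expect_error(geometric_mix_entropy(0.5, 0), "n must")
})
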