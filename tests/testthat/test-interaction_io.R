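test_that("reading a well-formed table yields a sorted schedule", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "colony_id,time_s,donor,recipient,volume,ambiguous",
    "A,5,a1,a2,0.5,FALSE",
    "A,1,SOURCE,f1,1.0,FALSE",
    "A,3,f1,a1,0.8,FALSE"
  ), path)
  sched <- read_interactions(path)
  expect_s3_class(sched, "colony_schedule")
  expect_equal(nrow(sched$events), 3)
  expect_equal(sched$events$time, c(1, 3, 5))
  expect_equal(sched$events$donor, c("SOURCE", "f1", "a1"))
  expect_setequal(sched$ants, c("f1", "a1", "a2"))
  expect_equal(sched$foragers, "f1")
})

test_that("multi-colony files yield one schedule per colony", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "colony_id,time_s,donor,recipient,volume",
    "A,1,SOURCE,f1,1",
    "B,1,SOURCE,f2,1",
    "B,2,f2,a1,0.5"
  ), path)
  scheds <- read_interactions(path)
  expect_named(scheds, c("A", "B"))
  expect_equal(nrow(scheds$B$events), 2)
})

test_that("malformed input is rejected with a useful message", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("colony_id,time_s,donor,recipient",
               "A,1,SOURCE,f1"), path)
  expect_error(read_interactions(path), "volume")

  expect_error(
    colony_schedule(data.frame(time = 1, donor = "a1", recipient = "a2",
                               volume = -1)),
    "negative volume at row 1")
  expect_error(
    colony_schedule(data.frame(time = c(1, 2), donor = c("SOURCE", "a1"),
                               recipient = c("f1", "a1"),
                               volume = c(1, 0.1))),
    "donor equals recipient at row 2")
  expect_error(
    colony_schedule(data.frame(time = 1, donor = "a1",
                               recipient = "SOURCE", volume = 1)),
    "SOURCE")
  expect_error(
    colony_schedule(data.frame(time = -2, donor = "SOURCE",
                               recipient = "f1", volume = 1)),
    "negative time")
})

test_that("write/read round trip preserves every field exactly", {
  col <- small_colony(seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_interactions(col$schedule, path)
  back <- read_interactions(path)
  expect_identical(back$events$donor, col$schedule$events$donor)
  expect_identical(back$events$recipient, col$schedule$events$recipient)
  expect_identical(back$events$volume, col$schedule$events$volume)
  expect_identical(back$events$time, col$schedule$events$time)
  expect_identical(back$events$ambiguous, col$schedule$events$ambiguous)
  expect_identical(back$foragers, col$schedule$foragers)
})

test_that("forager identification follows SOURCE events unless overridden", {
  sched <- tiny_schedule()
  expect_equal(identify_foragers(sched), c("f1", "f2"))
  # idempotent and stable under re-construction with shuffled equal times
  ev <- sched$events
  ev$time <- rep(1, nrow(ev))
  resorted <- colony_schedule(ev[c(2, 1, 4, 3, 6, 5), ])
  expect_equal(identify_foragers(resorted), c("f1", "f2"))
  expect_equal(identify_foragers(sched, override = "a9"), "a9")
  no_src <- colony_schedule(data.frame(
    time = 1, donor = "a1", recipient = "a2", volume = 0.3))
  expect_error(identify_foragers(no_src), "no foragers identifiable")
})

test_that("generator-designated foragers are recovered from the schedule", {
  col <- generate_colony(synthetic_colony_config(
    n_ants = 40, n_foragers = 5, n_events = 300, seed = 9))
  expect_equal(identify_foragers(col$schedule),
               sort(col$truth$foragers))
  expect_length(identify_foragers(col$schedule), 5)
})

test_that("capacity estimates are max observed load, bounded by the truth", {
  sched <- tiny_schedule()
  trace <- track_provenance(sched)
  caps <- estimate_capacities(trace)
  # f1 peaks at 4 right after its source trip
  expect_equal(unname(caps["f1"]), 4)
  # never-loaded ants are flagged undefined
  ev <- rbind(sched$events,
              data.frame(time = 7, donor = "a1", recipient = "a3",
                         volume = 0, ambiguous = FALSE))
  trace2 <- track_provenance(colony_schedule(ev))
  caps2 <- estimate_capacities(trace2)
  expect_true(is.na(caps2["a3"]))
  expect_true("a3" %in% attr(caps2, "undefined"))

  col <- small_colony(seed = 2, n_events = 400)
  est <- estimate_capacities(track_provenance(col$schedule))
  defined <- !is.na(est)
  expect_true(all(est[defined] <= col$capacities[names(est)[defined]] + 1e-9))
})
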