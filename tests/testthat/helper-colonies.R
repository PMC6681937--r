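# Shared fixtures, all generated in code.

# small seeded synthetic colony for fast tests
small_colony <- function(seed = 1, n_ants = 25, n_foragers = 3,
                         n_events = 150, ...) {
  generate_colony(synthetic_colony_config(
    n_ants = n_ants, n_foragers = n_foragers, n_events = n_events,
    seed = seed, ...))
}

# a tiny hand-written schedule: two foragers load at the source, then feed
# two workers, who then exchange
tiny_schedule <- function() {
  colony_schedule(data.frame(
    time = 1:6,
    donor = c("SOURCE", "SOURCE", "f1", "f2", "f1", "a1"),
    recipient = c("f1", "f2", "a1", "a2", "a2", "a2"),
    volume = c(4, 4, 2, 2, 1, 0.5)
  ), colony_id = "tiny")
}

expect_trace_equal <- function(trace, truth, tol = 1e-9) {
  ants <- sort(trace$ants)
  types <- sort(trace$foragers)
  expect_lt(max(abs(trace$amounts[, ants, types] -
                      truth$amounts[, ants, types])), tol)
}
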