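#' Configuration for the synthetic colony generator
#'
#' The generator emulates the statistical structure of a famine-relief
#' feeding experiment: all crops start empty; a small forager subset
#' alternates between loading at the external source and unloading into the
#' nest; forager→non-forager and non-forager→non-forager events occur in a
#' roughly 1:1.9 ratio; ant-to-ant volumes follow the truncated-exponential
#' rule \eqn{v = \tilde v \cdot v_{max}}, \eqn{\tilde v \sim p_\delta}; and
#' transfers respect finite per-ant crop capacities.
#'
#' @param n_ants total ants (default 70).
#' @param n_foragers foragers / food types (default 5).
#' @param capacity either a single number (common capacity, default 1) or
#'   `list(kind = "lognormal", meanlog =, sdlog =)` for heterogeneous
#'   capacities.
#' @param delta transfer-rule scale (default 0.26).
#' @param source_load volume a forager takes per source trip, capped by her
#'   free space (default: her capacity).
#' @param reload_threshold a forager returns to the source when her load
#'   drops below this fraction of her capacity (default 0.2).
#' @param forager_event_frac probability that an event involves a forager
#'   (source trip or unloading); default 713/2070.
#' @param n_events total number of events (default 700).
#' @param seed integer seed.
#' @return object of class `synthetic_colony_config`.
#' @export
synthetic_colony_config <- function(n_ants = 70, n_foragers = 5,
                                    capacity = 1, delta = 0.26,
                                    source_load = NULL,
                                    reload_threshold = 0.2,
                                    forager_event_frac = 713 / 2070,
                                    n_events = 700, seed = 1) {
  stopifnot(n_foragers >= 1, n_foragers < n_ants, delta > 0,
            n_events >= 1, reload_threshold >= 0, reload_threshold <= 1)
  if (is.numeric(capacity)) {
    stopifnot(length(capacity) == 1, capacity > 0)
  } else {
    stopifnot(is.list(capacity), identical(capacity$kind, "lognormal"),
              is.numeric(capacity$meanlog), is.numeric(capacity$sdlog))
  }
  structure(list(n_ants = n_ants, n_foragers = n_foragers,
                 capacity = capacity, delta = delta,
                 source_load = source_load,
                 reload_threshold = reload_threshold,
                 forager_event_frac = forager_event_frac,
                 n_events = n_events, seed = seed),
            class = "synthetic_colony_config")
}

#' Generate a synthetic colony with ground-truth provenance
#'
#' Draws a schedule under the configured statistical structure while keeping
#' its own event-by-event provenance bookkeeping (a per-type accumulation
#' loop, written independently of the tracker's vectorised update), so the
#' output can serve as an oracle for [track_provenance()].
#'
#' @param config a [synthetic_colony_config()].
#' @return list with elements `schedule` (a `colony_schedule` whose
#'   `capacities` are the true ones), `truth` (a `provenance_trace` recorded
#'   by the generator), `capacities` (named numeric), `v_tilde` (the latent
#'   transfer fractions actually drawn, zero-volume draws included) and
#'   `config`.
#' @examples
#' col <- generate_colony(synthetic_colony_config(n_ants = 20, n_events = 100))
#' col$schedule
#' @export
generate_colony <- function(config) {
  stopifnot(inherits(config, "synthetic_colony_config"))
  set.seed(config$seed)
  n_f <- config$n_foragers
  n_a <- config$n_ants
  width <- max(3L, nchar(as.character(n_a)))
  foragers <- sprintf("f%0*d", width, seq_len(n_f))
  workers <- sprintf("a%0*d", width, seq_len(n_a - n_f))
  ants <- c(foragers, workers)
  caps <- if (is.numeric(config$capacity)) {
    stats::setNames(rep(config$capacity, n_a), ants)
  } else {
    stats::setNames(stats::rlnorm(n_a, config$capacity$meanlog,
                                  config$capacity$sdlog), ants)
  }
  source_load <- config$source_load
  # generator-side bookkeeping: per-ant, per-type amounts updated type by type
  truth <- matrix(0, n_a, n_f, dimnames = list(ants, foragers))
  k <- config$n_events
  amounts <- array(0, dim = c(k, n_a, n_f),
                   dimnames = list(NULL, ants, foragers))
  times <- cumsum(stats::rexp(k, rate = 1 / 10))
  ev_donor <- ev_recipient <- character(k)
  ev_volume <- numeric(k)
  v_tilde_drawn <- numeric(0)

  for (i in seq_len(k)) {
    if (stats::runif(1) < config$forager_event_frac) {
      f <- sample.int(n_f, 1)
      f_lab <- foragers[f]
      load_f <- 0
      for (t in seq_len(n_f)) load_f <- load_f + truth[f, t]
      if (load_f < config$reload_threshold * caps[f_lab]) {
        # source trip: pure own-type food, capped by free crop space
        take <- if (is.null(source_load)) caps[f_lab] - load_f else
          min(source_load, caps[f_lab] - load_f)
        truth[f, f] <- truth[f, f] + take
        ev_donor[i] <- SOURCE_LABEL
        ev_recipient[i] <- f_lab
        ev_volume[i] <- take
        amounts[i, , ] <- truth
        next
      }
      donor <- f
      recipient <- n_f + sample.int(n_a - n_f, 1)
    } else {
      pair <- n_f + sample.int(n_a - n_f, 2)
      donor <- pair[1]; recipient <- pair[2]
    }
    load_d <- 0
    for (t in seq_len(n_f)) load_d <- load_d + truth[donor, t]
    load_r <- 0
    for (t in seq_len(n_f)) load_r <- load_r + truth[recipient, t]
    v_max <- max(0, min(load_d, caps[ants[recipient]] - load_r))
    vt <- rtruncexp(1, config$delta)
    v <- vt * v_max
    if (v_max > 0) v_tilde_drawn <- c(v_tilde_drawn, vt)
    if (v > 0) {
      frac <- v / load_d
      for (t in seq_len(n_f)) {
        moved <- frac * truth[donor, t]
        truth[donor, t] <- truth[donor, t] - moved
        truth[recipient, t] <- truth[recipient, t] + moved
      }
    }
    ev_donor[i] <- ants[donor]
    ev_recipient[i] <- ants[recipient]
    ev_volume[i] <- v
    amounts[i, , ] <- truth
  }

  events <- data.frame(time = times, donor = ev_donor,
                       recipient = ev_recipient, volume = ev_volume,
                       ambiguous = FALSE, stringsAsFactors = FALSE)
  schedule <- colony_schedule(events, colony_id = "synthetic",
                              capacities = caps)
  truth_trace <- .build_trace(amounts,
                              matrix(0, n_a, n_f,
                                     dimnames = list(ants, foragers)),
                              schedule$events, ants, foragers, "synthetic")
  list(schedule = schedule, truth = truth_trace, capacities = caps,
       v_tilde = v_tilde_drawn, config = config)
}
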