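#' Specify an interaction rule for hybrid simulation
#'
#' Hybrid simulations keep the empirical interaction schedule (who met whom,
#' in what order) and replace the recorded directions/volumes with a model
#' rule:
#' \describe{
#'   \item{`empirical_replay`}{apply the recorded events unchanged.}
#'   \item{`stochastic_empirical`}{direction uniform at random on the
#'     recorded pair; volume \eqn{v = \tilde v \cdot v_{max}} with
#'     \eqn{\tilde v} drawn from the truncated-exponential rule with scale
#'     `delta`.}
#'   \item{`maximal_mixing`}{both ants pool their crops and split equally,
#'     leaving identical loads and compositions; crop capacities are
#'     deliberately ignored for this rule.}
#'   \item{`max_transfer`}{the recorded donor transfers the full
#'     \eqn{v_{max}}.}
#'   \item{`no_secondary`}{forager-donor events use the stochastic rule with
#'     `delta`; events whose recorded donor is a non-forager transfer
#'     nothing.}
#' }
#'
#' @param kind one of `"empirical_replay"`, `"stochastic_empirical"`,
#'   `"maximal_mixing"`, `"max_transfer"`, `"no_secondary"`.
#' @param delta scale of the truncated-exponential rule for the stochastic
#'   kinds (default 0.26).
#' @return object of class `rule_spec` with `kind`, `delta`,
#'   `respects_capacity`.
#' @export
rule_spec <- function(kind = c("empirical_replay", "stochastic_empirical",
                               "maximal_mixing", "max_transfer",
                               "no_secondary"),
                      delta = 0.26) {
  kind <- match.arg(kind)
  stopifnot(delta >= 0)
  structure(list(kind = kind, delta = delta,
                 respects_capacity = kind != "maximal_mixing"),
            class = "rule_spec")
}

#' @export
print.rule_spec <- function(x, ...) {
  cat("rule_spec: ", x$kind,
      if (x$kind %in% c("stochastic_empirical", "no_secondary")) {
        paste0(" (delta = ", x$delta, ")")
      } else "",
      if (!x$respects_capacity) " [capacities ignored]" else "",
      "\n", sep = "")
  invisible(x)
}

#' Replay a schedule under a substituted interaction rule
#'
#' Walks the schedule event by event, replacing each recorded ant-to-ant
#' interaction by the rule's direction and volume while propagating food-type
#' provenance exactly as [track_provenance()] does. SOURCE feedings are
#' always replayed as recorded, so the food inflow is identical across rules.
#' Under capacity-respecting rules an event whose \eqn{v_{max}} is zero
#' transfers nothing. Because the substituted rule generally unloads foragers
#' more slowly than the record did, a replayed source feeding can push a
#' forager's crop transiently above her capacity; rule-generated transfers
#' always respect the recipient's free space.
#'
#' @param schedule a `colony_schedule`.
#' @param rule a [rule_spec()].
#' @param capacities named per-ant capacities; required for the
#'   capacity-respecting rules, ignored by `maximal_mixing`.
#' @param seed optional integer seed for the stochastic rules.
#' @param tol transfer tolerance, as in [track_provenance()].
#' @return a `provenance_trace` whose `events` hold the realised directions
#'   and volumes.
#' @export
simulate_schedule <- function(schedule, rule, capacities = NULL,
                              seed = NULL, tol = 1e-9) {
  stopifnot(inherits(schedule, "colony_schedule"),
            inherits(rule, "rule_spec"))
  if (!is.null(seed)) set.seed(seed)
  needs_caps <- rule$kind %in% c("stochastic_empirical", "max_transfer",
                                 "no_secondary")
  if (needs_caps && is.null(capacities)) {
    stop("rule '", rule$kind, "' requires capacities")
  }
  foragers <- schedule$foragers
  if (length(foragers) == 0) foragers <- identify_foragers(schedule)
  state <- unclass_state(crop_state(schedule$ants, foragers))
  ants <- rownames(state)
  ev <- schedule$events
  k <- nrow(ev)
  amounts <- array(0, dim = c(k, length(ants), ncol(state)),
                   dimnames = list(NULL, ants, colnames(state)))
  realized <- ev
  for (i in seq_len(k)) {
    donor <- ev$donor[i]; recipient <- ev$recipient[i]
    if (donor == SOURCE_LABEL) {
      state <- .transfer(state, donor, recipient, ev$volume[i], tol)
      amounts[i, , ] <- state
      next
    }
    if (rule$kind == "empirical_replay") {
      v <- ev$volume[i]
    } else if (rule$kind == "maximal_mixing") {
      v_d <- sum(state[donor, ]); v_r <- sum(state[recipient, ])
      pooled <- (state[donor, ] + state[recipient, ]) / 2
      state[donor, ] <- pooled
      state[recipient, ] <- pooled
      amounts[i, , ] <- state
      # net volume that changed hands: half the load difference
      realized$volume[i] <- abs(v_d - v_r) / 2
      next
    } else {
      if (rule$kind == "stochastic_empirical" &&
          stats::runif(1) < 0.5) {
        tmp <- donor; donor <- recipient; recipient <- tmp
      }
      v_max <- max(0, min(sum(state[donor, ]),
                          capacities[recipient] - sum(state[recipient, ])))
      v <- switch(rule$kind,
        stochastic_empirical = rtruncexp(1, rule$delta) * v_max,
        max_transfer = v_max,
        no_secondary = if (donor %in% foragers) {
          rtruncexp(1, rule$delta) * v_max
        } else 0
      )
    }
    state <- .transfer(state, donor, recipient, v, tol)
    amounts[i, , ] <- state
    realized$donor[i] <- donor
    realized$recipient[i] <- recipient
    realized$volume[i] <- v
  }
  .build_trace(amounts, matrix(0, length(ants), ncol(state),
                               dimnames = dimnames(state)),
               realized, ants, foragers, schedule$colony_id)
}

#' Shuffle ant identities in a schedule
#'
#' Randomises the interaction network while preserving its gross statistics:
#' all ant-label slots of ant-to-ant events are permuted uniformly at random,
#' which keeps the number of events, their timestamps and every ant's total
#' number of interaction slots; SOURCE feedings are left untouched.
#' Self-pairings created by the permutation are repaired by swapping one slot
#' with another random event.
#'
#' @param schedule a `colony_schedule`.
#' @param seed optional integer seed.
#' @return a new `colony_schedule` with shuffled identities.
#' @export
shuffle_identities <- function(schedule, seed = NULL) {
  stopifnot(inherits(schedule, "colony_schedule"))
  if (!is.null(seed)) set.seed(seed)
  ev <- schedule$events
  aa <- which(ev$donor != SOURCE_LABEL)
  slots <- c(ev$donor[aa], ev$recipient[aa])
  perm <- sample(slots)
  n <- length(aa)
  donors <- perm[seq_len(n)]
  recips <- perm[n + seq_len(n)]
  # repair self-pairings by swapping with a random other recipient slot
  guard <- 0L
  repeat {
    clash <- which(donors == recips)
    if (length(clash) == 0 || guard > 1000L) break
    for (i in clash) {
      j <- sample.int(n, 1)
      tmp <- recips[i]; recips[i] <- recips[j]; recips[j] <- tmp
    }
    guard <- guard + 1L
  }
  if (any(donors == recips)) {
    stop("could not repair self-pairings after shuffling")
  }
  ev$donor[aa] <- donors
  ev$recipient[aa] <- recips
  colony_schedule(ev, colony_id = schedule$colony_id,
                  foragers = schedule$foragers,
                  capacities = schedule$capacities)
}

#' Ensemble of hybrid simulations
#'
#' Runs `n_reps` independent replicates of [simulate_schedule()] (replicate
#' `r` uses seed `base_seed + r`) and summarises the mixing and types entropy
#' trajectories by their per-index mean and standard deviation.
#'
#' @param schedule a `colony_schedule`.
#' @param rule a [rule_spec()].
#' @param n_reps number of replicates.
#' @param base_seed integer; replicate seeds are `base_seed + 1 ... + n_reps`.
#' @param capacities per-ant capacities (as in [simulate_schedule()]).
#' @param normalize normalise entropies by \eqn{\log |F|}.
#' @return data.frame of class `ensemble_trace` with columns `event_index`,
#'   `mean_H_mix`, `sd_H_mix`, `mean_H_types`, `sd_H_types`; attributes
#'   `final_H_mix` (vector over replicates), `rule`, `n_reps`, `base_seed`.
#' @export
run_ensemble <- function(schedule, rule, n_reps = 30, base_seed = 1,
                         capacities = NULL, normalize = FALSE) {
  stopifnot(n_reps >= 1)
  h_mix <- h_types <- NULL
  final_h <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    tr <- simulate_schedule(schedule, rule, capacities = capacities,
                            seed = base_seed + r)
    et <- entropy_trace(tr, normalize = normalize)
    if (is.null(h_mix)) {
      h_mix <- matrix(NA_real_, n_reps, nrow(et))
      h_types <- matrix(NA_real_, n_reps, nrow(et))
    }
    h_mix[r, ] <- et$H_mix
    h_types[r, ] <- et$H_types
    final_h[r] <- et$H_mix[nrow(et)]
  }
  out <- data.frame(
    event_index = seq_len(ncol(h_mix)),
    mean_H_mix = colMeans(h_mix, na.rm = TRUE),
    sd_H_mix = apply(h_mix, 2, stats::sd, na.rm = TRUE),
    mean_H_types = colMeans(h_types, na.rm = TRUE),
    sd_H_types = apply(h_types, 2, stats::sd, na.rm = TRUE)
  )
  attr(out, "final_H_mix") <- final_h
  attr(out, "rule") <- rule
  attr(out, "n_reps") <- n_reps
  attr(out, "base_seed") <- base_seed
  class(out) <- c("ensemble_trace", "data.frame")
  out
}
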