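#' Create an empty crop state
#'
#' The crop state is the ants-by-food-types matrix \eqn{n_{f,a}} of food
#' amounts, where a food "type" is labelled by the forager that first
#' collected it at the source. Rows are ants (foragers and non-foragers),
#' columns are types (one per forager). Famine-relief initial conditions are
#' all-zero crops.
#'
#' @param ants character vector of all ant labels.
#' @param foragers character vector of forager labels (a subset of `ants`).
#' @return a numeric matrix of class `crop_state`, ants x types, all zeros,
#'   with attribute `foragers`.
#' @export
crop_state <- function(ants, foragers) {
  foragers <- sort(unique(as.character(foragers)))
  ants <- sort(unique(c(as.character(ants), foragers)))
  if (length(foragers) == 0) stop("at least one forager is required")
  m <- matrix(0, nrow = length(ants), ncol = length(foragers),
              dimnames = list(ant = ants, type = foragers))
  structure(m, foragers = foragers, class = c("crop_state", "matrix", "array"))
}

# Core transfer update shared by the tracker and the hybrid simulator.
# Moves `volume` from donor to recipient, splitting it across types in
# proportion to the donor's current composition; SOURCE feedings add pure
# own-type food to a forager. Tiny float negatives (|x| < tol) are clamped.
.transfer <- function(state, donor, recipient, volume, tol) {
  if (volume == 0) return(state)
  if (donor == SOURCE_LABEL) {
    if (!(recipient %in% colnames(state))) {
      stop("SOURCE recipient '", recipient, "' is not a forager/food type")
    }
    state[recipient, recipient] <- state[recipient, recipient] + volume
    return(state)
  }
  v_donor <- sum(state[donor, ])
  if (volume > v_donor + tol) {
    stop("infeasible transfer: volume ", format(volume),
         " exceeds donor load ", format(v_donor))
  }
  frac <- min(volume / v_donor, 1)
  moved <- frac * state[donor, ]
  state[donor, ] <- state[donor, ] - moved
  state[recipient, ] <- state[recipient, ] + moved
  state[state < 0 & state > -tol] <- 0
  if (any(state < 0)) {
    stop("negative crop amount beyond tolerance after transfer")
  }
  state
}

#' Apply one interaction to a crop state
#'
#' Implements the provenance update: the receiver gains the fraction
#' \eqn{v / V_{donor}} of the donor's crop, type by type,
#' \deqn{n'_{recv}(f) = n_{recv}(f) + \frac{v}{V_{donor}} n_{donor}(f),}
#' so the donated droplet carries the donor's current type composition. The
#' droplets-per-volume scale is arbitrary and cancels in all derived
#' probabilities. SOURCE events add `volume` of the recipient's own pure type.
#'
#' @param state a `crop_state` matrix.
#' @param event list or one-row data.frame with `donor`, `recipient`,
#'   `volume`.
#' @param tol absolute tolerance for clamping float negatives and for the
#'   feasibility check `volume <= donor load`.
#' @return the updated `crop_state`.
#' @examples
#' st <- crop_state(c("a1", "f1", "f2"), c("f1", "f2"))
#' st["f1", "f1"] <- 4; st["f1", "f2"] <- 4; st["a1", "f1"] <- 2
#' st <- apply_interaction(st, list(donor = "f1", recipient = "a1", volume = 2))
#' st["a1", ]  # f1: 3, f2: 1
#' @export
apply_interaction <- function(state, event, tol = 1e-9) {
  stopifnot(inherits(state, "crop_state"))
  donor <- as.character(event$donor)
  recipient <- as.character(event$recipient)
  volume <- as.numeric(event$volume)
  if (volume < 0) stop("volume must be non-negative")
  if (donor == recipient) stop("donor equals recipient")
  if (donor != SOURCE_LABEL && !(donor %in% rownames(state))) {
    stop("unknown donor '", donor, "'")
  }
  if (!(recipient %in% rownames(state))) {
    stop("unknown recipient '", recipient, "'")
  }
  out <- .transfer(unclass_state(state), donor, recipient, volume, tol)
  structure(out, foragers = attr(state, "foragers"),
            class = c("crop_state", "matrix", "array"))
}

unclass_state <- function(state) {
  attr(state, "class") <- NULL
  attr(state, "foragers") <- NULL
  state
}

# Assemble a provenance_trace object from the per-event crop snapshots.
# `amounts` is a K x ants x types array of post-event states.
.build_trace <- function(amounts, initial, events, ants, foragers,
                         colony_id = "colony") {
  nonforagers <- setdiff(ants, foragers)
  k <- dim(amounts)[1]
  loads <- if (k > 0) {
    apply(amounts, c(1, 2), sum)
  } else {
    matrix(0, 0, length(ants), dimnames = list(NULL, ants))
  }
  Z <- rowSums(loads[, nonforagers, drop = FALSE])
  M <- rowSums(loads)
  structure(
    list(colony_id = colony_id, events = events, ants = ants,
         foragers = foragers, nonforagers = nonforagers,
         amounts = amounts, initial = initial,
         Z = Z, M = M, P_colony = ifelse(M > 0, Z / M, 0)),
    class = "provenance_trace"
  )
}

#' Track food-type provenance through an interaction schedule
#'
#' Propagates the crop state through every event in order, recording the full
#' ants-by-types composition after each interaction. From this trace all the
#' distributional quantities of the analysis are available: the share of the
#' non-forager food pool held by each ant (\eqn{P_a = n_a / Z}), the joint
#' type-by-ant distribution (\eqn{P_{f,a} = n_{f,a} / Z}), the colony-wide
#' type distribution (\eqn{P_f = \sum_a P_{f,a}}) and the colony satiation
#' level (\eqn{P_{colony} = Z / M}). The pool \eqn{Z} sums over non-foragers
#' only; \eqn{M} sums over all ants including foragers.
#'
#' @param schedule a `colony_schedule`.
#' @param initial optional `crop_state` to start from; default all-empty crops
#'   (famine relief).
#' @param zero_ambiguous if `TRUE`, events flagged ambiguous are applied with
#'   zero volume (they are near-detection-error contacts).
#' @param tol clamping/feasibility tolerance passed to the transfer update.
#' @return an object of class `provenance_trace` with elements `amounts`
#'   (events x ants x types array of post-event states), `initial`, `Z`, `M`,
#'   `P_colony`, `events`, `ants`, `foragers`, `nonforagers`.
#' @seealso [provenance_at()], [crop_composition()], [entropy_trace()]
#' @export
track_provenance <- function(schedule, initial = NULL,
                             zero_ambiguous = FALSE, tol = 1e-9) {
  stopifnot(inherits(schedule, "colony_schedule"))
  foragers <- schedule$foragers
  if (length(foragers) == 0) foragers <- identify_foragers(schedule)
  if (is.null(initial)) {
    initial <- crop_state(schedule$ants, foragers)
  }
  state <- unclass_state(initial)
  ants <- rownames(state)
  ev <- schedule$events
  k <- nrow(ev)
  amounts <- array(0, dim = c(k, length(ants), ncol(state)),
                   dimnames = list(NULL, ants, colnames(state)))
  vols <- ev$volume
  if (zero_ambiguous) vols[ev$ambiguous] <- 0
  for (i in seq_len(k)) {
    state <- tryCatch(
      .transfer(state, ev$donor[i], ev$recipient[i], vols[i], tol),
      error = function(e) {
        stop("event ", i, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    amounts[i, , ] <- state
  }
  .build_trace(amounts, unclass_state(initial), ev, ants, foragers,
               schedule$colony_id)
}

#' @export
print.provenance_trace <- function(x, ...) {
  k <- length(x$Z)
  cat("provenance_trace '", x$colony_id, "': ", k, " events, ",
      length(x$ants), " ants (", length(x$foragers), " foragers/types)\n",
      sep = "")
  if (k > 0) {
    cat(sprintf("  final: M = %.4g, Z = %.4g, P_colony = %.3f\n",
                x$M[k], x$Z[k], x$P_colony[k]))
  }
  invisible(x)
}

#' Distributional snapshot of a trace at one event index
#'
#' @param trace a `provenance_trace`.
#' @param index event index (default: last event).
#' @return list with `P_a` (named, non-foragers), `P_fa` (non-foragers x
#'   types), `P_f` (named over types), `Z`, `M`, `P_colony`. When `Z = 0` the
#'   probability entries are `NA`.
#' @export
provenance_at <- function(trace, index = length(trace$Z)) {
  stopifnot(inherits(trace, "provenance_trace"))
  stopifnot(index >= 1, index <= length(trace$Z))
  nf <- trace$nonforagers
  n_fa <- matrix(trace$amounts[index, nf, ], nrow = length(nf),
                 dimnames = list(nf, dimnames(trace$amounts)[[3]]))
  Z <- trace$Z[index]
  if (Z > 0) {
    P_fa <- n_fa / Z
    P_a <- rowSums(P_fa)
    P_f <- colSums(P_fa)
  } else {
    P_fa <- n_fa * NA_real_
    P_a <- stats::setNames(rep(NA_real_, length(nf)), nf)
    P_f <- stats::setNames(rep(NA_real_, length(trace$foragers)),
                           trace$foragers)
  }
  list(P_a = P_a, P_fa = P_fa, P_f = P_f, Z = Z, M = trace$M[index],
       P_colony = trace$P_colony[index])
}

#' Crop composition of one ant at one event index
#'
#' The conditional distribution \eqn{P(f \mid A = a) = P_{f,a} / P_a}: the
#' mixture of food types inside ant `a`'s crop.
#'
#' @param trace a `provenance_trace`.
#' @param ant ant label.
#' @param index event index (default: last event).
#' @return named non-negative numeric vector over food types, summing to 1.
#' @export
crop_composition <- function(trace, ant, index = length(trace$Z)) {
  stopifnot(inherits(trace, "provenance_trace"))
  if (!(ant %in% trace$ants)) stop("unknown ant '", ant, "'")
  n_f <- trace$amounts[index, ant, ]
  total <- sum(n_f)
  if (total <= 0) {
    stop("composition undefined: ant '", ant, "' holds no food at index ",
         index)
  }
  n_f / total
}

#' Per-ant total crop loads at one event index
#'
#' @param trace a `provenance_trace`.
#' @param index event index (default: last event).
#' @return named numeric vector of total loads for every ant.
#' @export
crop_loads <- function(trace, index = length(trace$Z)) {
  stopifnot(inherits(trace, "provenance_trace"))
  if (index == 0) return(rowSums(trace$initial))
  apply(trace$amounts[index, , , drop = FALSE], 2, sum)
}

#' Export a provenance trace as a tidy long table
#'
#' @param trace a `provenance_trace`.
#' @param indices event indices to include (default: all).
#' @return data.frame with columns `event_index`, `ant`, `food_type`,
#'   `amount`.
#' @export
trace_to_long <- function(trace, indices = seq_along(trace$Z)) {
  stopifnot(inherits(trace, "provenance_trace"))
  grid <- expand.grid(event_index = indices, ant = trace$ants,
                      food_type = trace$foragers, stringsAsFactors = FALSE)
  grid$amount <- as.vector(trace$amounts[indices, , , drop = FALSE])
  grid[order(grid$event_index, grid$ant, grid$food_type), , drop = FALSE]
}
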