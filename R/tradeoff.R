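#' Configuration for the deterministic-transfer trade-off model
#'
#' The trade-off model strips the empirical system down to its capacity
#' constraint: all ants share one capacity, interactions occur at random, and
#' every transfer moves the deterministic fraction \eqn{\tilde\delta} of the
#' feasible volume, \eqn{v = \tilde\delta \cdot v_{max}}. Each forager starts
#' holding all the food she will ever supply (her own pure type), so the
#' colony total `M` is conserved and the colony state
#' \eqn{P_{colony} = Z / M} climbs from 0 towards 1 as food disseminates.
#'
#' @param n_ants total number of ants.
#' @param n_foragers number of foragers (food types).
#' @param capacity common crop capacity (crop-volume units, default 1).
#' @param M total food; defaults to `n_foragers * capacity` (foragers start
#'   exactly full). Must not exceed `n_foragers * capacity`.
#' @param delta_tilde deterministic transfer fraction in (0, 1].
#' @param mean_interactions average number of interactions per ant; the run
#'   length is `mean_interactions * n_ants / 2` events.
#' @param forager_event_frac probability that an event is forager-to-
#'   non-forager rather than non-forager-to-non-forager. Default 713/2070,
#'   the pooled empirical class ratio (≈ 1:1.9).
#' @param n_reps ensemble size for [sweep_delta()].
#' @param seed integer seed.
#' @return object of class `tradeoff_config`.
#' @export
tradeoff_config <- function(n_ants = 70, n_foragers = 5, capacity = 1,
                            M = n_foragers * capacity, delta_tilde = 0.26,
                            mean_interactions = 18,
                            forager_event_frac = 713 / 2070,
                            n_reps = 30, seed = 1) {
  stopifnot(n_foragers >= 1, n_foragers < n_ants, capacity > 0,
            delta_tilde > 0, delta_tilde <= 1,
            forager_event_frac >= 0, forager_event_frac <= 1,
            mean_interactions > 0, n_reps >= 1)
  if (M > n_foragers * capacity + 1e-12) {
    stop("infeasible config: M exceeds what the foragers can hold (",
         n_foragers * capacity, ")")
  }
  if (M > (n_ants - n_foragers) * capacity) {
    stop("infeasible config: M exceeds total non-forager capacity")
  }
  structure(list(n_ants = n_ants, n_foragers = n_foragers,
                 capacity = capacity, M = M, delta_tilde = delta_tilde,
                 mean_interactions = mean_interactions,
                 forager_event_frac = forager_event_frac,
                 n_reps = n_reps, seed = seed),
            class = "tradeoff_config")
}

#' Simulate one run of the trade-off model
#'
#' Each step draws the event class (forager→non-forager with probability
#' `forager_event_frac`), then a uniformly random eligible pair; foragers
#' never receive. The transfer volume is the deterministic
#' \eqn{v = \tilde\delta \cdot v_{max}} with
#' \eqn{v_{max} = \min(\text{donor load}, \text{recipient free space})}.
#' Direction among non-forager pairs is uniform. Per-step outputs are the
#' colony state, the mixing entropy over non-foragers, the overall mixing
#' entropy over all ants and the across-ant spread of crop entropies.
#'
#' @param config a [tradeoff_config()].
#' @param seed optional seed overriding `config$seed`.
#' @param base logarithm base for entropies.
#' @return data.frame of class `tradeoff_trace` with columns `step`,
#'   `P_colony`, `H_mix`, `H_mix_overall`, `sd_h_a`; one row per
#'   interaction.
#' @export
simulate_tradeoff <- function(config, seed = config$seed, base = exp(1)) {
  stopifnot(inherits(config, "tradeoff_config"))
  if (!is.null(seed)) set.seed(seed)
  nf_count <- config$n_ants - config$n_foragers
  n_types <- config$n_foragers
  cap <- config$capacity
  # rows 1..n_foragers are foragers, the rest non-foragers
  crops <- matrix(0, config$n_ants, n_types)
  per_forager <- config$M / n_types
  crops[cbind(seq_len(n_types), seq_len(n_types))] <- per_forager
  n_steps <- ceiling(config$mean_interactions * config$n_ants / 2)
  nf_idx <- n_types + seq_len(nf_count)

  out <- data.frame(step = seq_len(n_steps), P_colony = NA_real_,
                    H_mix = NA_real_, H_mix_overall = NA_real_,
                    sd_h_a = NA_real_)
  for (s in seq_len(n_steps)) {
    if (stats::runif(1) < config$forager_event_frac) {
      donor <- sample.int(n_types, 1)
      recipient <- nf_idx[sample.int(nf_count, 1)]
    } else {
      pair <- nf_idx[sample.int(nf_count, 2)]
      donor <- pair[1]; recipient <- pair[2]
    }
    v_max <- max(0, min(sum(crops[donor, ]), cap - sum(crops[recipient, ])))
    v <- config$delta_tilde * v_max
    if (v > 0) {
      frac <- v / sum(crops[donor, ])
      moved <- frac * crops[donor, ]
      crops[donor, ] <- crops[donor, ] - moved
      crops[recipient, ] <- crops[recipient, ] + moved
    }
    loads <- rowSums(crops)
    Z <- sum(loads[nf_idx])
    # vectorised per-crop entropies; empty crops -> NA
    P <- crops / pmax(loads, .Machine$double.xmin)
    L <- P * log(P, base = base)
    L[crops == 0] <- 0
    h_all <- -rowSums(L)
    h_all[loads <= 0] <- NA_real_
    loaded_nf <- nf_idx[loads[nf_idx] > 0]
    H_mix <- if (Z > 0) {
      sum(loads[loaded_nf] * h_all[loaded_nf]) / Z
    } else NA_real_
    loaded <- which(loads > 0)
    H_ov <- sum(loads[loaded] * h_all[loaded]) / config$M
    out$P_colony[s] <- Z / config$M
    out$H_mix[s] <- H_mix
    out$H_mix_overall[s] <- H_ov
    out$sd_h_a[s] <- stats::sd(h_all[loaded])
  }
  class(out) <- c("tradeoff_trace", "data.frame")
  out
}

#' Sweep the transfer fraction of the trade-off model
#'
#' Runs `config$n_reps` replicates of [simulate_tradeoff()] at each grid
#' value of \eqn{\tilde\delta} and summarises the endpoint (final
#' interaction) of each trajectory. Accumulation (`P_colony`) rises with
#' \eqn{\tilde\delta} while non-forager mixing (`H_mix`) falls; their
#' product `H_mix_overall` peaks at intermediate \eqn{\tilde\delta}.
#'
#' @param config a [tradeoff_config()]; its `delta_tilde` is overridden by
#'   the grid.
#' @param delta_grid numeric vector of \eqn{\tilde\delta} values in (0, 1].
#' @return data.frame of class `tradeoff_sweep`: one row per grid value with
#'   mean and sd of the endpoint `P_colony`, `H_mix`, `H_mix_overall`,
#'   `sd_h_a` over replicates.
#' @export
sweep_delta <- function(config, delta_grid = seq(0.05, 1, length.out = 20)) {
  stopifnot(inherits(config, "tradeoff_config"))
  if (any(delta_grid <= 0 | delta_grid > 1)) {
    stop("delta_grid must lie in (0, 1]")
  }
  rows <- lapply(seq_along(delta_grid), function(i) {
    cfg <- config
    cfg$delta_tilde <- delta_grid[i]
    ends <- vapply(seq_len(config$n_reps), function(r) {
      tr <- simulate_tradeoff(cfg,
                              seed = config$seed + (i - 1) * config$n_reps + r)
      last <- tr[nrow(tr), ]
      c(last$P_colony, last$H_mix, last$H_mix_overall, last$sd_h_a)
    }, numeric(4))
    data.frame(
      delta_tilde = delta_grid[i],
      P_colony_mean = mean(ends[1, ]), P_colony_sd = stats::sd(ends[1, ]),
      H_mix_mean = mean(ends[2, ]), H_mix_sd = stats::sd(ends[2, ]),
      H_mix_overall_mean = mean(ends[3, ]),
      H_mix_overall_sd = stats::sd(ends[3, ]),
      sd_h_a_mean = mean(ends[4, ], na.rm = TRUE),
      sd_h_a_sd = stats::sd(ends[4, ], na.rm = TRUE)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tradeoff_sweep", "data.frame")
  out
}
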