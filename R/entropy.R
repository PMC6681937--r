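#' Shannon entropy of a finite distribution
#'
#' \eqn{H(p) = -\sum_i p_i \log p_i} with the convention
#' \eqn{0 \log 0 = 0}. Natural log by default; pass `base = 2` for bits.
#'
#' @param p non-negative numeric vector summing to 1 (within `tol`).
#' @param base logarithm base (default `exp(1)`, nats).
#' @param tol tolerance on the sum-to-one check.
#' @return entropy in log-`base` units.
#' @examples
#' shannon_entropy(c(0.5, 0.5), base = 2)   # 1 bit
#' shannon_entropy(c(0.75, 0.25), base = 2) # ~0.81 bits (a 3:1 crop)
#' @export
shannon_entropy <- function(p, base = exp(1), tol = 1e-9) {
  if (any(p < 0)) stop("negative probability mass")
  if (abs(sum(p) - 1) > tol) {
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
  }
  nz <- p > 0
  -sum(p[nz] * log(p[nz], base = base))
}

#' Types entropy at one event index
#'
#' Entropy of the colony-wide partition of the non-forager food pool into
#' food types, \eqn{H_{types} = -\sum_f P_f \log P_f}. Bounded above by
#' \eqn{\log |F|}, saturated only when all foragers contributed equally;
#' it is the ceiling on any mixing entropy.
#'
#' @param trace a `provenance_trace`.
#' @param index event index (default: last).
#' @param base logarithm base.
#' @return \eqn{H_{types}} in log-`base` units.
#' @export
types_entropy <- function(trace, index = length(trace$Z), base = exp(1)) {
  snap <- provenance_at(trace, index)
  if (!(snap$Z > 0)) stop("types entropy undefined: Z = 0 at index ", index)
  shannon_entropy(snap$P_f, base = base)
}

#' Mixing entropy and per-crop entropies at one event index
#'
#' Each loaded ant's crop entropy is
#' \eqn{h^a_{mix} = H(F \mid A = a) = -\sum_f P(f|a) \log P(f|a)}; the colony
#' mixing entropy is their load-weighted average over non-foragers,
#' \eqn{H_{mix} = H(F|A) = \sum_a P_a\, h^a_{mix}}. Zero means every crop is
#' pure; equality with \eqn{H_{types}} means every crop matches the colony
#' type distribution (perfect blending). Ants with empty crops carry zero
#' weight and get `NA` crop entropy.
#'
#' @param trace a `provenance_trace`.
#' @param index event index (default: last).
#' @param base logarithm base.
#' @return list with `H_mix` and `h_a` (named vector over non-foragers).
#' @export
mixing_entropy <- function(trace, index = length(trace$Z), base = exp(1)) {
  snap <- provenance_at(trace, index)
  if (!(snap$Z > 0)) stop("mixing entropy undefined: Z = 0 at index ", index)
  h_a <- .crop_entropies(snap$P_fa, base)
  w <- snap$P_a
  list(H_mix = sum(w[!is.na(h_a)] * h_a[!is.na(h_a)]), h_a = h_a)
}

# Per-row entropies of a (rows x types) amount/probability matrix; NA for
# empty rows.
.crop_entropies <- function(n_fa, base) {
  totals <- rowSums(n_fa)
  h <- rep(NA_real_, nrow(n_fa))
  names(h) <- rownames(n_fa)
  for (i in which(totals > 0)) {
    h[i] <- shannon_entropy(n_fa[i, ] / totals[i], base = base)
  }
  h
}

#' Overall mixing entropy (all ants, foragers included)
#'
#' \eqn{H^{overall}_{mix} = \sum_{a \in A \cup F} \tilde P_a\, h^a_{mix}}
#' with \eqn{\tilde P_a = n_a / M}. When forager crops are pure (their crop
#' entropy is zero) this factorises as
#' \eqn{H^{overall}_{mix} = P_{colony} \cdot H_{mix}}, separating the
#' dissemination component from the blending component.
#'
#' @param trace a `provenance_trace`.
#' @param index event index (default: last).
#' @param base logarithm base.
#' @return \eqn{H^{overall}_{mix}} in log-`base` units.
#' @export
overall_mixing_entropy <- function(trace, index = length(trace$Z),
                                   base = exp(1)) {
  stopifnot(inherits(trace, "provenance_trace"))
  M <- trace$M[index]
  if (!(M > 0)) stop("overall mixing entropy undefined: M = 0 at index ",
                     index)
  n_fa <- matrix(trace$amounts[index, , ], nrow = length(trace$ants),
                 dimnames = list(trace$ants, trace$foragers))
  h_a <- .crop_entropies(n_fa, base)
  w <- rowSums(n_fa) / M
  sum(w[!is.na(h_a)] * h_a[!is.na(h_a)])
}

#' Entropy trajectory of a provenance trace
#'
#' Computes, at every event index, the types entropy, the mixing entropy,
#' their ratio, the colony satiation level \eqn{P_{colony}} and the overall
#' mixing entropy. Indices where the non-forager pool is still empty
#' (\eqn{Z = 0}) yield `NA` entropies. Final-index per-crop entropies, their
#' unweighted mean and standard deviation (both normalised by
#' \eqn{\log |F|}) are attached as attributes `h_a_final`, `mean_h_norm`,
#' `sd_h_norm`.
#'
#' @param trace a `provenance_trace`.
#' @param base logarithm base.
#' @param normalize if `TRUE`, divide all entropies by \eqn{\log |F|} so
#'   that traces from colonies with different forager counts are comparable.
#' @return data.frame of class `entropy_trace` with columns `event_index`,
#'   `H_types`, `H_mix`, `ratio`, `P_colony`, `H_mix_overall`.
#' @export
entropy_trace <- function(trace, base = exp(1), normalize = FALSE) {
  stopifnot(inherits(trace, "provenance_trace"))
  k <- length(trace$Z)
  nf <- trace$nonforagers
  types <- trace$foragers
  H_types <- H_mix <- H_ov <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    if (trace$Z[i] > 0) {
      n_fa <- matrix(trace$amounts[i, nf, ], nrow = length(nf))
      P_f <- colSums(n_fa) / trace$Z[i]
      H_types[i] <- shannon_entropy(P_f, base = base)
      totals <- rowSums(n_fa)
      h <- numeric(length(totals))
      loaded <- which(totals > 0)
      for (j in loaded) {
        p <- n_fa[j, ] / totals[j]
        nz <- p > 0
        h[j] <- -sum(p[nz] * log(p[nz], base = base))
      }
      H_mix[i] <- sum(totals * h) / trace$Z[i]
    }
    if (trace$M[i] > 0) {
      n_all <- matrix(trace$amounts[i, , ], nrow = length(trace$ants))
      totals <- rowSums(n_all)
      h <- numeric(length(totals))
      for (j in which(totals > 0)) {
        p <- n_all[j, ] / totals[j]
        nz <- p > 0
        h[j] <- -sum(p[nz] * log(p[nz], base = base))
      }
      H_ov[i] <- sum(totals * h) / trace$M[i]
    }
  }
  scale <- if (normalize) log(length(types), base = base) else 1
  out <- data.frame(
    event_index = seq_len(k),
    H_types = H_types / scale,
    H_mix = H_mix / scale,
    ratio = ifelse(H_types > 0, H_mix / H_types, NA_real_),
    P_colony = trace$P_colony,
    H_mix_overall = H_ov / scale
  )
  if (k > 0 && trace$Z[k] > 0) {
    h_fin <- mixing_entropy(trace, k, base = base)$h_a
    h_norm <- h_fin / log(length(types), base = base)
    attr(out, "h_a_final") <- h_fin
    attr(out, "mean_h_norm") <- mean(h_norm, na.rm = TRUE)
    attr(out, "sd_h_norm") <- stats::sd(h_norm[!is.na(h_norm)])
  }
  class(out) <- c("entropy_trace", "data.frame")
  out
}

#' Entropy generated by an ant's largest receiving events
#'
#' Because each receiving interaction delivers a sizeable fraction of the free
#' crop space, an ant's final crop composition is dominated by a handful of
#' large events. This statistic is the Shannon entropy of the normalised
#' volumes of the `n` largest receiving events (by default `n` = number of
#' foragers), each event counted as one component.
#'
#' @param volumes numeric vector of an ant's received volumes.
#' @param n number of largest events to keep.
#' @param base logarithm base.
#' @return entropy in log-`base` units; 0 for a single event.
#' @export
largest_events_entropy <- function(volumes, n, base = exp(1)) {
  volumes <- volumes[volumes > 0]
  if (length(volumes) == 0) stop("no receiving events: entropy undefined")
  top <- sort(volumes, decreasing = TRUE)[seq_len(min(n, length(volumes)))]
  shannon_entropy(top / sum(top), base = base)
}

#' Largest-events entropies for every non-forager in a schedule
#'
#' @param schedule a `colony_schedule`.
#' @param n number of largest events per ant (default: number of foragers).
#' @param base logarithm base.
#' @return named numeric vector over non-foragers with at least one receiving
#'   event.
#' @export
largest_events_distribution <- function(schedule, n = NULL, base = exp(1)) {
  stopifnot(inherits(schedule, "colony_schedule"))
  foragers <- schedule$foragers
  if (is.null(n)) n <- length(foragers)
  ev <- schedule$events
  recv <- ev[ev$recipient %in% setdiff(schedule$ants, foragers) &
               ev$volume > 0, , drop = FALSE]
  vols <- split(recv$volume, recv$recipient)
  vapply(vols, largest_events_entropy, numeric(1), n = n, base = base)
}

#' Entropy of the geometric mixing sequence
#'
#' Under the transfer rule an ant receives, on average, a geometrically
#' decreasing series of volumes \eqn{m_j = \delta (1 - \delta)^{j-1}},
#' \eqn{j = 1, \dots, n}: each event fills the typical fraction `delta` of the
#' remaining free space. The entropy of this normalised sequence predicts the
#' typical crop entropy from `delta` alone.
#'
#' @param delta typical transfer fraction, in (0, 1).
#' @param n sequence length (number of events; conventionally the number of
#'   foragers).
#' @param base logarithm base.
#' @return entropy in log-`base` units.
#' @export
geometric_mix_entropy <- function(delta, n, base = exp(1)) {
  if (!(delta > 0 && delta < 1)) stop("delta must lie strictly in (0, 1)")
  if (n < 1) stop("n must be >= 1")
  m <- delta * (1 - delta)^(seq_len(n) - 1)
  shannon_entropy(m / sum(m), base = base)
}
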