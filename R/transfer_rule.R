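#' Per-event transfer fractions and potentials
#'
#' For every ant-to-ant event, computes the maximal transferable volume
#' \eqn{v_{max} = \min(\text{donor load},\ \text{recipient free space})}, the
#' realised fraction \eqn{\tilde v = v / v_{max}}, the donor and recipient
#' fullness \eqn{d, r} (load as a fraction of own capacity) and the volume
#' potential \eqn{p = d (1 - r)} used as a binning covariate. Crop loads are
#' taken immediately before each event. Events with \eqn{v_{max} = 0} and
#' events missing a capacity are excluded and counted in attributes.
#'
#' @param trace a `provenance_trace`.
#' @param capacities named numeric vector of per-ant capacities.
#' @return data.frame with one row per usable ant-to-ant event: columns
#'   `event_index`, `donor`, `recipient`, `d`, `r`, `p`, `v_max`, `v`,
#'   `v_tilde`, `clipped`, `forager_donor`, `forager_recipient`; attributes
#'   `n_excluded_vmax0` and `n_missing_capacity`. Fractions marginally above
#'   1 are clipped to 1 and flagged.
#' @export
compute_transfer_fractions <- function(trace, capacities) {
  stopifnot(inherits(trace, "provenance_trace"))
  ev <- trace$events
  k <- nrow(ev)
  loads_before <- .loads_before(trace)
  rows <- vector("list", k)
  n_vmax0 <- 0L
  n_nocap <- 0L
  for (i in seq_len(k)) {
    donor <- ev$donor[i]
    recipient <- ev$recipient[i]
    if (donor == SOURCE_LABEL) next
    cap_d <- capacities[donor]
    cap_r <- capacities[recipient]
    if (is.na(cap_d) || is.na(cap_r)) {
      n_nocap <- n_nocap + 1L
      next
    }
    load_d <- loads_before[i, donor]
    load_r <- loads_before[i, recipient]
    v_max <- min(load_d, cap_r - load_r)
    if (v_max <= 0) {
      n_vmax0 <- n_vmax0 + 1L
      next
    }
    v_tilde <- ev$volume[i] / v_max
    clipped <- v_tilde > 1
    rows[[i]] <- data.frame(
      event_index = i, donor = donor, recipient = recipient,
      d = load_d / cap_d, r = load_r / cap_r,
      p = (load_d / cap_d) * (1 - load_r / cap_r),
      v_max = v_max, v = ev$volume[i], v_tilde = min(v_tilde, 1),
      clipped = clipped,
      forager_donor = donor %in% trace$foragers,
      forager_recipient = recipient %in% trace$foragers,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(event_index = integer(0), donor = character(0),
                      recipient = character(0), d = numeric(0),
                      r = numeric(0), p = numeric(0), v_max = numeric(0),
                      v = numeric(0), v_tilde = numeric(0),
                      clipped = logical(0), forager_donor = logical(0),
                      forager_recipient = logical(0))
  }
  rownames(out) <- NULL
  if (sum(out$clipped) > 0) {
    warning(sum(out$clipped), " transfer fraction(s) exceeded 1 and were ",
            "clipped")
  }
  attr(out, "n_excluded_vmax0") <- n_vmax0
  attr(out, "n_missing_capacity") <- n_nocap
  out
}

# total crop load of every ant immediately before each event
.loads_before <- function(trace) {
  k <- length(trace$Z)
  loads_after <- apply(trace$amounts, c(1, 2), sum)
  before <- rbind(rowSums(trace$initial), loads_after)[seq_len(k), ,
                                                       drop = FALSE]
  colnames(before) <- trace$ants
  before
}

#' Fit the truncated-exponential transfer rule by maximum likelihood
#'
#' The scale `delta` of [dtruncexp()] solves the score equation
#' \eqn{\bar{\tilde v} = \delta - e^{-1/\delta}/(1 - e^{-1/\delta})}
#' (sample mean equals the model mean), found by bracketed root-finding.
#' The family's mean approaches 1/2 from below as `delta` grows, so samples
#' with mean at or above 1/2 have no finite maximiser: the fit is reported
#' with `unbounded = TRUE` (the uniform limit). Zero fractions are excluded
#' as non-transfers and counted.
#'
#' @param v_tilde numeric vector of transfer fractions in \eqn{[0, 1]}.
#' @return object of class `transfer_rule_fit`: `delta`, `c_delta`, `n`
#'   (fractions used), `n_zero` (excluded zeros), `mean_v_tilde`, `loglik`,
#'   `unbounded`, `degenerate` flags.
#' @examples
#' set.seed(1)
#' fit_delta_mle(rtruncexp(2000, 0.26))
#' @export
fit_delta_mle <- function(v_tilde) {
  if (length(v_tilde) == 0) stop("empty sample")
  if (any(v_tilde < 0 | v_tilde > 1)) {
    stop("transfer fractions must lie in [0, 1]")
  }
  n_zero <- sum(v_tilde == 0)
  x <- v_tilde[v_tilde > 0]
  if (length(x) == 0) {
    return(structure(list(delta = NA_real_, c_delta = NA_real_, n = 0L,
                          n_zero = n_zero, mean_v_tilde = 0,
                          loglik = NA_real_, unbounded = FALSE,
                          degenerate = TRUE),
                     class = "transfer_rule_fit"))
  }
  if (length(x) < 2) stop("need at least 2 positive fractions")
  m <- mean(x)
  if (m >= 0.5) {
    return(structure(list(delta = Inf, c_delta = 1, n = length(x),
                          n_zero = n_zero, mean_v_tilde = m,
                          loglik = 0, unbounded = TRUE, degenerate = FALSE),
                     class = "transfer_rule_fit"))
  }
  score <- function(delta) truncexp_mean(delta) - m
  delta <- stats::uniroot(score, lower = 1e-8, upper = 1e4,
                          tol = 1e-12)$root
  c_delta <- 1 / (1 - exp(-1 / delta))
  ll <- sum(log(dtruncexp(x, delta)))
  structure(list(delta = delta, c_delta = c_delta, n = length(x),
                 n_zero = n_zero, mean_v_tilde = m, loglik = ll,
                 unbounded = FALSE, degenerate = FALSE),
            class = "transfer_rule_fit")
}

#' @export
print.transfer_rule_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("transfer_rule_fit: degenerate (all fractions zero)\n")
  } else if (isTRUE(x$unbounded)) {
    cat("transfer_rule_fit: unbounded delta (sample mean ",
        sprintf("%.3f", x$mean_v_tilde), " >= 0.5; uniform limit), n = ",
        x$n, "\n", sep = "")
  } else {
    cat(sprintf(
      "transfer_rule_fit: delta = %.4f (c_delta = %.3f), n = %d (+%d zero), mean v~ = %.3f\n",
      x$delta, x$c_delta, x$n, x$n_zero, x$mean_v_tilde))
  }
  invisible(x)
}

#' Transfer-rule fits per transfer-potential bin
#'
#' Bins events by the volume potential \eqn{p = d(1-r)} and fits `delta`
#' within each bin, with an R-squared of the fitted exponential density
#' against the binned empirical density of \eqn{\tilde v}. If the rule acts
#' on the fraction \eqn{\tilde v} rather than on the absolute volume, the
#' per-bin deltas are flat in \eqn{p}.
#'
#' @param fractions data.frame from [compute_transfer_fractions()].
#' @param bin_edges increasing break points over `p` (default quartile cuts
#'   `c(0, .25, .5, .75, 1)`).
#' @param min_n minimum events per bin to attempt a fit (default 30).
#' @param density_breaks number of histogram cells over \eqn{\tilde v} used
#'   for the R-squared diagnostic.
#' @return data.frame with one row per bin: `p_lo`, `p_hi`, `n`, `delta`,
#'   `r_squared`, `fitted` (FALSE for undersized bins).
#' @export
binned_rule_fit <- function(fractions, bin_edges = c(0, 0.25, 0.5, 0.75, 1),
                            min_n = 30, density_breaks = 20) {
  stopifnot(is.numeric(bin_edges), length(bin_edges) >= 2,
            all(diff(bin_edges) > 0))
  x <- fractions[fractions$v_tilde > 0, , drop = FALSE]
  bins <- cut(x$p, breaks = bin_edges, include.lowest = TRUE)
  out <- lapply(seq_len(length(bin_edges) - 1), function(b) {
    sel <- x$v_tilde[as.integer(bins) == b]
    row <- data.frame(p_lo = bin_edges[b], p_hi = bin_edges[b + 1],
                      n = length(sel), delta = NA_real_,
                      r_squared = NA_real_, fitted = FALSE)
    if (length(sel) >= min_n) {
      fit <- fit_delta_mle(sel)
      row$delta <- fit$delta
      row$fitted <- !fit$unbounded && !fit$degenerate
      if (row$fitted) {
        h <- graphics::hist(sel, breaks = seq(0, 1,
                                              length.out = density_breaks + 1),
                            plot = FALSE)
        emp <- h$density
        mod <- dtruncexp(h$mids, fit$delta)
        row$r_squared <- 1 - sum((emp - mod)^2) / sum((emp - mean(emp))^2)
      }
    }
    row
  })
  do.call(rbind, out)
}

#' Interaction-direction statistics
#'
#' Classifies ant-to-ant events into forager/non-forager and
#' non-forager/non-forager pairs, and summarises who donates. Events whose
#' volume is at or below `epsilon * min(capacity of the pair)` are treated as
#' direction-ambiguous (at the detection error), as are events flagged
#' ambiguous in the schedule. For forager/non-forager events the summary
#' gives the fractions with the forager as (unambiguous) donor, the forager
#' as recipient, and ambiguous. For non-forager pairs it gives, among
#' unambiguous events with unequal loads, the fraction in which the
#' relatively fuller ant (load as a fraction of own capacity) donated, and
#' separately the fraction in which the absolutely fuller ant donated.
#'
#' @param trace a `provenance_trace`.
#' @param capacities named numeric per-ant capacities.
#' @param epsilon detection threshold in fraction-of-capacity units
#'   (default 0.01).
#' @return list with components `forager_nonforager` and
#'   `nonforager_nonforager`, each holding counts and fractions.
#' @export
directionality_stats <- function(trace, capacities, epsilon = 0.01) {
  stopifnot(inherits(trace, "provenance_trace"))
  ev <- trace$events
  loads_before <- .loads_before(trace)
  foragers <- trace$foragers
  aa <- which(ev$donor != SOURCE_LABEL)

  fn_total <- 0L; fn_donor <- 0L; fn_recip <- 0L; fn_amb <- 0L
  nn_total <- 0L; nn_amb <- 0L
  nn_rel_eval <- 0L; nn_rel_fuller <- 0L
  nn_abs_eval <- 0L; nn_abs_fuller <- 0L

  for (i in aa) {
    donor <- ev$donor[i]; recipient <- ev$recipient[i]
    cap_d <- capacities[donor]; cap_r <- capacities[recipient]
    if (is.na(cap_d) || is.na(cap_r)) next
    amb <- isTRUE(ev$ambiguous[i]) ||
      ev$volume[i] <= epsilon * min(cap_d, cap_r)
    f_d <- donor %in% foragers
    f_r <- recipient %in% foragers
    if (xor(f_d, f_r)) {
      fn_total <- fn_total + 1L
      if (amb) fn_amb <- fn_amb + 1L
      else if (f_d) fn_donor <- fn_donor + 1L
      else fn_recip <- fn_recip + 1L
    } else if (!f_d && !f_r) {
      nn_total <- nn_total + 1L
      if (amb) {
        nn_amb <- nn_amb + 1L
      } else {
        d_rel <- loads_before[i, donor] / cap_d
        r_rel <- loads_before[i, recipient] / cap_r
        if (d_rel != r_rel) {
          nn_rel_eval <- nn_rel_eval + 1L
          if (d_rel > r_rel) nn_rel_fuller <- nn_rel_fuller + 1L
        }
        d_abs <- loads_before[i, donor]
        r_abs <- loads_before[i, recipient]
        if (d_abs != r_abs) {
          nn_abs_eval <- nn_abs_eval + 1L
          if (d_abs > r_abs) nn_abs_fuller <- nn_abs_fuller + 1L
        }
      }
    }
  }
  list(
    forager_nonforager = list(
      n = fn_total,
      frac_forager_donor = if (fn_total > 0) fn_donor / fn_total else NA,
      frac_forager_recipient = if (fn_total > 0) fn_recip / fn_total else NA,
      frac_ambiguous = if (fn_total > 0) fn_amb / fn_total else NA
    ),
    nonforager_nonforager = list(
      n = nn_total,
      frac_ambiguous = if (nn_total > 0) nn_amb / nn_total else NA,
      frac_fuller_donates = if (nn_rel_eval > 0) {
        nn_rel_fuller / nn_rel_eval
      } else NA,
      n_fuller_eval = nn_rel_eval,
      frac_abs_fuller_donates = if (nn_abs_eval > 0) {
        nn_abs_fuller / nn_abs_eval
      } else NA,
      n_abs_fuller_eval = nn_abs_eval
    )
  )
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Thin wrapper around [stats::ks.test()] returning the statistic and
#' asymptotic p-value; used to compare transfer-fraction samples (e.g.
#' forager-donor versus non-forager-donor events).
#'
#' @param x,y numeric samples.
#' @return list with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}
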