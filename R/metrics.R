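#' Firing rates from a spike table
#'
#' Counts spikes per neuron inside a time window and divides by the window
#' length. Only neurons present in the spike table appear (a neuron with no
#' spikes anywhere is unknown to the table); protocol results report full
#' rate matrices instead.
#'
#' @param spikes Tibble with columns `population`, `neuron`, `time_ms`
#'   (and optionally `trial`).
#' @param window_start,window_end Window bounds in ms (start inclusive,
#'   end exclusive).
#' @return Tibble with `population`, `neuron` (and `trial` if present) and
#'   `rate_hz`.
#' @export
firing_rate <- function(spikes, window_start, window_end) {
  if (window_end <= window_start) {
    stop("empty rate window: [", window_start, ", ", window_end, ")",
         call. = FALSE)
  }
  keys <- intersect(c("trial", "population", "neuron"), names(spikes))
  spikes |>
    dplyr::filter(.data$time_ms >= window_start,
                  .data$time_ms < window_end) |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), name = "n_spikes") |>
    dplyr::mutate(rate_hz = .data$n_spikes * 1000 /
                    (window_end - window_start)) |>
    dplyr::select(-"n_spikes")
}

#' Entropy reduction and multi-information of a population rate table
#'
#' Quantifies statistical dependence among projection-neuron responses over
#' a stimulus set. The entropy-reduction statistic is
#' `ER = 1/2 log((2*pi*e)^p |Sigma|) - 1/2 log((2*pi*e)^p) = 1/2 log|Sigma|`
#' with `Sigma` the across-stimulus covariance of the `p` neurons' rates.
#' Because `ER` mixes dependence with per-neuron variances, the nonnegative
#' multi-information `-1/2 log|R|` on the correlation matrix `R` is reported
#' alongside; it is exactly zero for uncorrelated activity and grows with
#' correlation, and is the quantity used for monotone decorrelation checks.
#' A small shrinkage `lambda` is added to the diagonal for stability.
#'
#' @param rates Matrix of firing rates, rows = stimuli, columns = neurons.
#' @param lambda Diagonal shrinkage added to the covariance (and, scaled,
#'   to the correlation) before taking determinants.
#' @return List with `er` (1/2 log|Sigma|, nats) and `multi_information`
#'   (-1/2 log|R|, nats, >= 0 up to shrinkage).
#' @export
entropy_reduction <- function(rates, lambda = 1e-6) {
  rates <- as.matrix(rates)
  if (nrow(rates) < 2) stop("need at least 2 stimuli rows", call. = FALSE)
  p <- ncol(rates)
  sigma <- stats::cov(rates) + diag(lambda, p)
  detS <- determinant(sigma, logarithm = TRUE)
  if (detS$sign <= 0) stop("covariance is singular after shrinkage",
                           call. = FALSE)
  R <- rate_correlation(rates)
  detR <- determinant(R + diag(lambda, p), logarithm = TRUE)
  list(er = 0.5 * as.numeric(detS$modulus),
       multi_information = max(0, -0.5 * as.numeric(detR$modulus)))
}

#' Multi-information of a rate table
#'
#' Shorthand for `entropy_reduction(rates)$multi_information`.
#' @inheritParams entropy_reduction
#' @return Non-negative scalar (nats).
#' @export
multi_information <- function(rates, lambda = 1e-6) {
  entropy_reduction(rates, lambda)$multi_information
}

#' Angular distance between two population activity vectors
#'
#' `arccos` of the cosine similarity between two firing-rate vectors,
#' clipped into \[-1, 1\] before `acos`. Scale-invariant; 0 for identical
#' directions, pi/2 for orthogonal patterns.
#'
#' @param p1,p2 Non-zero numeric rate vectors of equal length.
#' @return Angle in radians, in \[0, pi\].
#' @export
angular_distance <- function(p1, p2) {
  n1 <- sqrt(sum(p1^2)); n2 <- sqrt(sum(p2^2))
  if (n1 == 0 || n2 == 0) {
    stop("angular distance undefined for a zero vector", call. = FALSE)
  }
  acos(pmin(pmax(sum(p1 * p2) / (n1 * n2), -1), 1))
}

#' Treves-Rolls population sparseness index
#'
#' `SI = (sum(r)/n)^2 / (sum(r^2)/n)`: 1 for perfectly uniform activity,
#' `1/n` for one-hot activity. Lower values mean sparser population codes.
#'
#' @param r Non-negative, not-all-zero rate vector.
#' @return Scalar in \[1/n, 1\].
#' @export
sparseness_index <- function(r) {
  if (all(r == 0)) stop("sparseness undefined for all-zero rates",
                        call. = FALSE)
  n <- length(r)
  (sum(r) / n)^2 / (sum(r^2) / n)
}

#' Pearson correlation matrix of a rate table
#'
#' Correlations across stimuli between neuron pairs; columns with zero
#' variance (constant rate over all stimuli) get 0 off-diagonal and 1 on
#' the diagonal by convention.
#'
#' @inheritParams entropy_reduction
#' @return Symmetric matrix with unit diagonal.
#' @export
rate_correlation <- function(rates) {
  rates <- as.matrix(rates)
  sds <- apply(rates, 2, sd)
  ok <- sds > 0
  p <- ncol(rates)
  R <- diag(1, p)
  if (sum(ok) >= 2) R[ok, ok] <- cor(rates[, ok, drop = FALSE])
  R
}

#' Two-sample t-test over a cohort of simulated bees
#'
#' Welch's unpaired t-test by default; the paired variant is used when the
#' two conditions come from the same bees (as in conditioning cohorts,
#' where each bee contributes both a CS+ and a CS- test rate). The effect
#' size is Cohen's d (paired: mean difference over the sd of differences).
#'
#' @param group_a,group_b Numeric vectors of per-bee rates.
#' @param paired Use the paired test.
#' @return Tibble with `t`, `df`, `p_value`, `effect_size`, `mean_a`,
#'   `mean_b`.
#' @export
cohort_ttest <- function(group_a, group_b, paired = FALSE) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (paired) stopifnot(length(group_a) == length(group_b))
  if (isTRUE(all.equal(as.numeric(group_a), as.numeric(group_b)))) {
    return(tibble(t = 0, df = NA_real_, p_value = 1,
                  effect_size = 0, mean_a = mean(group_a),
                  mean_b = mean(group_b)))
  }
  degenerate <- if (paired) {
    sd(group_a - group_b) == 0
  } else {
    sd(group_a) == 0 && sd(group_b) == 0
  }
  if (degenerate) {
    # constant data with unequal means: separation is exact
    return(tibble(t = sign(mean(group_a) - mean(group_b)) * Inf,
                  df = NA_real_, p_value = 0, effect_size = Inf,
                  mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  tt <- t.test(group_a, group_b, paired = paired)
  eff <- if (paired) {
    d <- group_a - group_b
    mean(d) / sd(d)
  } else {
    (mean(group_a) - mean(group_b)) /
      sqrt((stats::var(group_a) + stats::var(group_b)) / 2)
  }
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, effect_size = eff,
         mean_a = mean(group_a), mean_b = mean(group_b))
}
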