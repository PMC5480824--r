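# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @export
tidy.conditioning_result <- function(x, ...) x$trials

#' @export
glance.conditioning_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$test_summary, names_from = "stimulus",
                             values_from = "mean_rate",
                             names_prefix = "test_rate_")
  dplyr::bind_cols(
    tibble(mode = x$mode,
           n_train_rounds = max(x$trials$round, na.rm = TRUE)),
    wide)
}

#' @export
tidy.exposure_result <- function(x, ...) x$decorrelation

#' @export
glance.exposure_result <- function(x, ...) {
  d <- x$decorrelation
  tibble(
    n_stimuli = x$n_stimuli, gin_level = format(x$gin_level),
    mi_start = if (nrow(d)) d$multi_information[1] else NA_real_,
    mi_end = if (nrow(d)) d$multi_information[nrow(d)] else NA_real_,
    er_start = if (nrow(d)) d$er[1] else NA_real_,
    er_end = if (nrow(d)) d$er[nrow(d)] else NA_real_
  )
}

#' @export
tidy.cohort_result <- function(x, ...) x$bees

#' @export
glance.cohort_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(mode = x$mode, control = x$control, n_bees = x$n_bees),
    x$test,
    tibble(frac_correct = mean(x$bees$test_rewarded >
                                 x$bees$test_unrewarded),
           pre_p_value = x$pre$p_value))
}

#' @export
tidy.generalization_result <- function(x, ...) x$rates

#' @export
glance.generalization_result <- function(x, ...) {
  A <- abs(x$K - t(x$K))
  tibble(n_odors = nrow(x$K), asymmetry = max(A),
         diag_mean = mean(diag(x$K)), offdiag_mean = mean(x$K[row(x$K) !=
                                                                col(x$K)]))
}

#' @export
autoplot.exposure_result <- function(object, ...) {
  ggplot2::ggplot(object$decorrelation,
                  ggplot2::aes(x = .data$checkpoint,
                               y = .data$multi_information)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "odour presentations",
                  y = "multi-information of PN code (nats)",
                  title = paste0("Decorrelation by exposure (GIN ",
                                 format(object$gin_level), ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.conditioning_result <- function(object, ...) {
  d <- dplyr::mutate(object$trials,
                     presentation = dplyr::row_number(),
                     phase = factor(.data$phase,
                                    levels = c("pre", "train", "test")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$presentation,
                                  y = .data$lhn_rate,
                                  colour = .data$stimulus,
                                  shape = .data$rewarded)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_grid(. ~ phase, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "presentation", y = "LHN rate (Hz)",
                  title = paste("Conditioning:", object$mode)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cohort_result <- function(object, ...) {
  d <- tidyr::pivot_longer(object$bees,
                           c("test_rewarded", "test_unrewarded"),
                           names_to = "condition", values_to = "rate")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$rate)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$bee), alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = NULL, y = "LHN test rate (Hz)",
                  title = paste0(object$mode, " (", object$control,
                                 " connectivity), n = ", object$n_bees)) +
    ggplot2::theme_minimal()
}

#' Spike raster plot
#'
#' @param spikes Spike tibble from [simulate_trial()].
#' @param schedule Optional [trial_schedule()] used to shade the stimulus
#'   window.
#' @return A ggplot object.
#' @export
plot_spike_raster <- function(spikes, schedule = trial_schedule()) {
  p <- ggplot2::ggplot(spikes,
                       ggplot2::aes(x = .data$time_ms, y = .data$neuron))
  if (!is.null(schedule)) {
    p <- p + ggplot2::annotate("rect", xmin = schedule$stim_onset,
                               xmax = schedule$stim_offset, ymin = -Inf,
                               ymax = Inf, alpha = 0.1, fill = "orange")
  }
  p + ggplot2::geom_point(shape = "|", size = 1.5) +
    ggplot2::facet_grid(population ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}
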