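#' Plot stop-signal delay trajectories
#'
#' Shows the staircase at work: SSD against stop-trial order for a handful
#' of participants, converging on the delay where stopping succeeds half
#' the time.
#'
#' @param trials Trial records from [simulate_sst()].
#' @param participants Participant ids to show (default: the first 4).
#' @return A ggplot object.
#' @export
plot_ssd_trajectory <- function(trials, participants = NULL) {
  d <- trials |>
    dplyr::filter(.data$is_stop) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(stop_trial = dplyr::row_number()) |>
    dplyr::ungroup()
  participants <- participants %||% head(unique(d$participant_id), 4)
  d <- dplyr::filter(d, .data$participant_id %in% participants)
  ggplot(d, aes(x = .data$stop_trial, y = .data$ssd_ms,
                colour = .data$participant_id)) +
    geom_step() +
    labs(x = "Stop trial (presentation order)",
         y = "Stop-signal delay (ms)", colour = "Participant") +
    theme_minimal()
}

#' @describeIn predict_grid Plot a prediction grid: predicted values (with
#'   95% CI ribbons where available) against the ADHD trait score, by sex
#'   and age.
#' @param object An `sst_prediction_grid`.
#' @param ... Unused.
#' @export
autoplot.sst_prediction_grid <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$trait, y = .data$predicted,
                          colour = .data$sex, group = .data$sex)) +
    geom_line() + geom_point() +
    facet_grid(measure ~ age, scales = "free_y",
               labeller = labeller(age = function(a) paste("Age", a))) +
    labs(x = "ADHD trait score (reversed SWAN)",
         y = "Predicted value (ms)", colour = "Sex") +
    theme_minimal()
  if (all(c("ci_low", "ci_high") %in% names(object))) {
    p <- p + geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 4, alpha = 0.6)
  }
  p
}

#' @describeIn fit_trait_model Plot the model's predicted-value grid.
#' @param object An `sst_trait_fit`.
#' @export
autoplot.sst_trait_fit <- function(object, ...) {
  autoplot(predict_grid(object))
}

#' Plot heritability estimates with confidence intervals
#'
#' @param h2_table A tibble as produced in `run_pipeline()$h2_table`
#'   (columns `trait`, `h2`, `ci_low`, `ci_high`).
#' @return A ggplot object.
#' @export
plot_heritability <- function(h2_table) {
  ggplot(h2_table, aes(x = .data$trait, y = .data$h2)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.15) +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = NULL, y = expression(h^2)) +
    theme_minimal()
}
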