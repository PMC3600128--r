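#' Summarise go-trial performance
#'
#' Computes per-participant go statistics over no-signal (go) trials only:
#' accuracy (correct responses over all go trials, so omissions count as
#' inaccurate), and the mean and sample SD of reaction time over
#' responded-and-correct go trials.
#'
#' @param trials Trial records as produced by [simulate_sst()] (or read with
#'   [read_sst_trials()]). Practice trials (`block == 0`) are ignored.
#'
#' @return A tibble with one row per participant: `participant_id`, `n_go`,
#'   `go_accuracy`, `gort_mean`, `gort_sd`. Participants with no responded go
#'   trial get `NA` statistics.
#' @examples
#' trials <- simulate_sst(3, seed = 1)
#' summarize_go(trials)
#' @export
summarize_go <- function(trials) {
  trials |>
    dplyr::filter(.data$block > 0, !.data$is_stop) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_go = dplyr::n(),
      go_accuracy = sum(.data$responded & .data$correct, na.rm = TRUE) / dplyr::n(),
      gort_mean = mean(.data$rt_ms[.data$responded & .data$correct %in% TRUE]),
      gort_sd = sd(.data$rt_ms[.data$responded & .data$correct %in% TRUE]),
      .groups = "drop"
    )
}

#' Integration-method estimate of stop-signal reaction time
#'
#' Rank-orders the no-signal reaction times and takes the RT at rank
#' `ceiling((1 - p_inhibit) * n)`: the point in the go distribution below
#' which responses escape inhibition (all slower responses would have been
#' stopped, all faster ones executed). SSRT is that quantile minus the mean
#' stop-signal delay.
#'
#' @param go_rts Reaction times (ms) of responded no-signal trials.
#' @param p_inhibit Proportion of stop trials successfully inhibited; must be
#'   strictly between 0 and 1 (participants at 0 or 1 fail the standard
#'   validity filter in any case).
#' @param mean_ssd Mean stop-signal delay (ms) over presented stop trials.
#'
#' @return SSRT in ms.
#' @examples
#' integration_ssrt(c(300, 400, 500, 600, 700), p_inhibit = 0.6,
#'                  mean_ssd = 200) # 200
#' @export
integration_ssrt <- function(go_rts, p_inhibit, mean_ssd) {
  go_rts <- go_rts[!is.na(go_rts)]
  if (length(go_rts) == 0) abort("`go_rts` must be non-empty.")
  if (is.na(p_inhibit) || p_inhibit <= 0 || p_inhibit >= 1) {
    abort("`p_inhibit` must lie strictly between 0 and 1 for the integration estimate.")
  }
  n <- length(go_rts)
  k <- min(max(ceiling((1 - p_inhibit) * n), 1L), n)
  sort(go_rts)[k] - mean_ssd
}

#' Score stop-signal task trial records
#'
#' Reduces trial-level records to one summary row per participant: go
#' accuracy, go reaction time mean/SD (GoRT, GoRTSD), probability of
#' inhibition, mean stop-signal delay, and the integration-method SSRT.
#' Practice trials (block 0) are excluded from all statistics; the mean delay
#' is taken over experimental stop trials. The go-RT distribution used for
#' the integration quantile consists of all responded no-signal trials
#' (failed-stop responses are never ranked).
#'
#' @param trials Trial records as produced by [simulate_sst()].
#' @param expected_trials Number of experimental trials a complete session
#'   contains (classically 96); participants with fewer are flagged
#'   incomplete.
#'
#' @return A tibble with one row per participant: counts, go statistics,
#'   `p_inhibit`, `mean_ssd`, `ssrt` (NA when the estimate is undefined,
#'   i.e. no responded go trial or `p_inhibit` at 0 or 1), and `complete`.
#' @examples
#' trials <- simulate_sst(4, seed = 1)
#' score_sst(trials)
#' @export
score_sst <- function(trials, expected_trials = 96) {
  ex <- dplyr::filter(trials, .data$block > 0)
  ex |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_go = sum(!.data$is_stop),
      n_stop = sum(.data$is_stop),
      go_accuracy = sum(!.data$is_stop & .data$responded & .data$correct,
                        na.rm = TRUE) / pmax(sum(!.data$is_stop), 1L),
      gort_mean = mean(.data$rt_ms[!.data$is_stop & .data$responded &
                                     .data$correct %in% TRUE]),
      gort_sd = sd(.data$rt_ms[!.data$is_stop & .data$responded &
                                 .data$correct %in% TRUE]),
      p_inhibit = mean(!.data$responded[.data$is_stop]),
      mean_ssd = mean(.data$ssd_ms[.data$is_stop]),
      ssrt = score_ssrt_one(
        .data$rt_ms[!.data$is_stop & .data$responded],
        mean(!.data$responded[.data$is_stop]),
        mean(.data$ssd_ms[.data$is_stop])
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(complete = .data$n_trials >= expected_trials)
}

# NA-returning wrapper used inside grouped summaries.
score_ssrt_one <- function(go_rts, p_inhibit, mean_ssd) {
  go_rts <- go_rts[!is.na(go_rts)]
  if (length(go_rts) == 0 || is.na(p_inhibit) ||
      p_inhibit <= 0 || p_inhibit >= 1) {
    return(NA_real_)
  }
  integration_ssrt(go_rts, p_inhibit, mean_ssd)
}

#' Validity rule for stop-signal task performance
#'
#' The standard exclusion thresholds: participants are invalid when go
#' accuracy is below 66%, mean go RT is below 100 ms (guessing), or the
#' probability of inhibition falls outside \[0.20, 0.80\]. A strict variant
#' narrows the inhibition band to \[0.40, 0.60\] (the region where the
#' tracking assumption is tightest); the strict band must nest inside the
#' standard one.
#'
#' @param min_go_accuracy Minimum go accuracy (proportion).
#' @param min_gort Minimum mean go RT (ms).
#' @param p_inhibit_bounds Standard inclusive bounds on `p_inhibit`.
#' @param strict_p_inhibit_bounds Strict bounds, nested within the standard.
#'
#' @return An object of class `validity_rule`.
#' @export
validity_rule <- function(min_go_accuracy = 0.66, min_gort = 100,
                          p_inhibit_bounds = c(0.20, 0.80),
                          strict_p_inhibit_bounds = c(0.40, 0.60)) {
  if (strict_p_inhibit_bounds[1] < p_inhibit_bounds[1] ||
      strict_p_inhibit_bounds[2] > p_inhibit_bounds[2]) {
    abort("strict bounds must be nested within the standard bounds.")
  }
  structure(
    list(
      min_go_accuracy = min_go_accuracy, min_gort = min_gort,
      p_inhibit_bounds = p_inhibit_bounds,
      strict_p_inhibit_bounds = strict_p_inhibit_bounds
    ),
    class = "validity_rule"
  )
}

#' Apply performance validity filters
#'
#' Flags each scored participant as valid or invalid with accumulated reason
#' codes: `accuracy` (go accuracy below threshold), `gort` (mean go RT below
#' threshold, indicating guessing), `p_inhibit` (inhibition rate outside the
#' allowed band), `incomplete` (fewer than the scheduled experimental
#' trials), `unscorable` (no responded go trial).
#'
#' @param summaries Output of [score_sst()].
#' @param rule A [validity_rule()].
#' @param strict Use the strict inhibition band instead of the standard one?
#'
#' @return `summaries` with `valid` (logical) and `exclusion_reasons`
#'   (comma-separated codes, `""` when valid) appended.
#' @export
apply_validity_filters <- function(summaries, rule = validity_rule(),
                                   strict = FALSE) {
  bounds <- if (strict) rule$strict_p_inhibit_bounds else rule$p_inhibit_bounds
  reasons <- function(acc, gort, p, complete) {
    r <- character(0)
    if (is.na(gort)) r <- c(r, "unscorable")
    if (!is.na(acc) && acc < rule$min_go_accuracy) r <- c(r, "accuracy")
    if (!is.na(gort) && gort < rule$min_gort) r <- c(r, "gort")
    if (is.na(p) || p < bounds[1] || p > bounds[2]) r <- c(r, "p_inhibit")
    if (!complete) r <- c(r, "incomplete")
    paste(r, collapse = ",")
  }
  summaries |>
    dplyr::mutate(
      exclusion_reasons = purrr::pmap_chr(
        list(.data$go_accuracy, .data$gort_mean, .data$p_inhibit,
             .data$complete),
        reasons
      ),
      valid = .data$exclusion_reasons == ""
    )
}

#' Tally exclusions by reason
#'
#' @param summaries Output of [apply_validity_filters()] (optionally with a
#'   `medicated` column, tallied as its own category).
#' @return A tibble of reason codes and counts, plus rows for the total
#'   excluded and the valid remainder.
#' @export
exclusion_tally <- function(summaries) {
  reasons <- summaries$exclusion_reasons
  if ("medicated" %in% names(summaries)) {
    reasons <- ifelse(summaries$medicated %in% TRUE & reasons == "",
                      "medication", reasons)
  }
  codes <- unlist(strsplit(reasons[reasons != ""], ","))
  tly <- tibble(reason = names(table(codes)), n = as.integer(table(codes)))
  dplyr::bind_rows(
    tly,
    tibble(reason = "any_exclusion", n = sum(reasons != "")),
    tibble(reason = "included", n = sum(reasons == ""))
  )
}

#' Correct SSRT for stimulant medication
#'
#' Stimulant medication shortens SSRT; to estimate the untreated value of a
#' medicated participant, the observed SSRT is lengthened by
#' `effect_size * reference_sd`, where the reference SD is the SSRT standard
#' deviation among unmedicated valid participants and the default effect
#' size of 0.75 reflects published effects of a moderate stimulant dose on
#' stop-task performance.
#'
#' @param ssrt Observed SSRT (ms); vectorised.
#' @param reference_sd Positive reference SD (ms).
#' @param medicated Logical; vectorised.
#' @param effect_size Standardised medication effect (default 0.75).
#'
#' @return Adjusted SSRT (ms): unchanged for unmedicated participants.
#' @examples
#' adjust_for_medication(280, reference_sd = 100, medicated = TRUE) # 355
#' @export
adjust_for_medication <- function(ssrt, reference_sd, medicated,
                                  effect_size = 0.75) {
  if (!is.numeric(reference_sd) || any(reference_sd <= 0)) {
    abort("`reference_sd` must be positive.")
  }
  ifelse(medicated, ssrt + effect_size * reference_sd, ssrt)
}
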