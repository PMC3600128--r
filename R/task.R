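#' Race-model parameters for a stop-signal task session
#'
#' Bundles the generating parameters of the independent horse-race model:
#' an ex-Gaussian go-process finishing-time distribution, a truncated-normal
#' stop-process latency, go error/omission rates, and the staircase settings
#' for the stop-signal delay (SSD).
#'
#' Defaults are calibrated so that a typical simulated participant has a mean
#' go reaction time near 599 ms with within-person variability near 159 ms,
#' the scale observed in large community samples of children performing the
#' task.
#'
#' @param go_mu,go_sigma,go_tau Ex-Gaussian parameters (ms) of the go-process
#'   finishing time: Normal(mu, sigma) + Exponential(tau). Mean is
#'   `go_mu + go_tau`; SD is `sqrt(go_sigma^2 + go_tau^2)`.
#' @param go_error_rate Probability that an executed go response presses the
#'   wrong key.
#' @param go_omission_rate Probability that the go process never finishes
#'   within the response window (no response recorded).
#' @param ssrt_mean,ssrt_sd Mean and SD (ms) of the stop-process latency
#'   (stop-signal reaction time), normal truncated at zero.
#' @param initial_ssd Starting stop-signal delay (ms); the classic value is
#'   250 ms.
#' @param ssd_step Staircase step (ms); the delay moves up after a successful
#'   stop and down after a failed stop, by this amount (classically 50 ms).
#' @param ssd_floor Minimum SSD (ms). A delay cannot be negative; 0 by
#'   default.
#' @param response_window Time allowed for a go response (ms); 3000 by
#'   default.
#'
#' @return An object of class `race_params` (a validated named list).
#' @examples
#' race_params()
#' race_params(ssrt_mean = 320)
#' @export
race_params <- function(go_mu = 489, go_sigma = 115, go_tau = 110,
                        go_error_rate = 0.03, go_omission_rate = 0.01,
                        ssrt_mean = 280, ssrt_sd = 50,
                        initial_ssd = 250, ssd_step = 50, ssd_floor = 0,
                        response_window = 3000) {
  p <- list(
    go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
    go_error_rate = go_error_rate, go_omission_rate = go_omission_rate,
    ssrt_mean = ssrt_mean, ssrt_sd = ssrt_sd,
    initial_ssd = initial_ssd, ssd_step = ssd_step, ssd_floor = ssd_floor,
    response_window = response_window
  )
  validate_race_params(p)
  structure(p, class = "race_params")
}

validate_race_params <- function(p) {
  lat <- c("go_mu", "go_sigma", "go_tau", "ssrt_mean", "ssrt_sd")
  for (nm in lat) {
    if (any(p[[nm]] <= 0)) abort(sprintf("`%s` must be positive.", nm))
  }
  for (nm in c("go_error_rate", "go_omission_rate")) {
    if (any(p[[nm]] < 0 | p[[nm]] > 1)) {
      abort(sprintf("`%s` must lie in [0, 1].", nm))
    }
  }
  if (any(p$ssd_step < 0)) abort("`ssd_step` must be non-negative.")
  if (any(p$ssd_floor < 0)) abort("`ssd_floor` must be non-negative.")
  if (any(p$response_window <= p$initial_ssd)) {
    abort("`response_window` must exceed `initial_ssd`.")
  }
  invisible(p)
}

#' Build a stop-signal task trial schedule
#'
#' Lays out a session as a tibble of trials: an optional practice block
#' (block 0) followed by `blocks` experimental blocks of `trials_per_block`
#' trials. A fixed fraction `stop_rate` of each block's trials carries the
#' stop signal, with stop positions randomised within block; the two go
#' stimuli ("X"/"O") are balanced within each block to within one trial.
#'
#' The classic session is four experimental blocks of 24 trials with stop
#' signals on 25% of trials (72 go and 24 stop trials), preceded by a
#' 24-trial practice block (18 go, 6 stop).
#'
#' @param blocks Number of experimental blocks.
#' @param trials_per_block Trials per block. `stop_rate * trials_per_block`
#'   must be a whole number.
#' @param stop_rate Proportion of stop trials per block.
#' @param seed Optional integer seed; the schedule is deterministic given it.
#' @param practice Include a practice block (labelled block 0) with the same
#'   trial count and stop rate?
#'
#' @return A tibble with columns `block` (0 = practice), `trial`,
#'   `go_stimulus`, `is_stop`.
#' @examples
#' sched <- build_schedule(blocks = 4, trials_per_block = 24, seed = 1)
#' sum(sched$is_stop & sched$block > 0) # 24 stop trials
#' @export
build_schedule <- function(blocks = 4, trials_per_block = 24,
                           stop_rate = 0.25, seed = NULL, practice = TRUE) {
  if (blocks < 1) abort("`blocks` must be at least 1.")
  n_stop <- stop_rate * trials_per_block
  if (abs(n_stop - round(n_stop)) > 1e-8) {
    abort("`stop_rate * trials_per_block` must be a whole number.")
  }
  n_stop <- as.integer(round(n_stop))
  with_seed_or_rng(seed, {
    block_ids <- if (practice) c(0L, seq_len(blocks)) else seq_len(blocks)
    purrr::map(block_ids, function(b) {
      is_stop <- logical(trials_per_block)
      is_stop[sample.int(trials_per_block, n_stop)] <- TRUE
      n_x <- ceiling(trials_per_block / 2)
      stim <- sample(c(rep("X", n_x), rep("O", trials_per_block - n_x)))
      tibble(
        block = b, trial = seq_len(trials_per_block),
        go_stimulus = stim, is_stop = is_stop
      )
    }) |> purrr::list_rbind()
  })
}

#' Dynamic staircase update of the stop-signal delay
#'
#' After a successful stop the delay increases by `step` (making the next
#' stop harder); after a failed stop it decreases by `step`, clamped at
#' `floor`. This one-up/one-down tracker converges on the delay at which the
#' probability of stopping is approximately 0.50.
#'
#' @param current_ssd Current delay (ms); must be at least `floor`.
#' @param inhibited Logical: was the response successfully stopped?
#' @param step Step size (ms); non-negative.
#' @param floor Minimum delay (ms).
#'
#' @return Updated delay (ms). Vectorised over all arguments.
#' @examples
#' staircase_update(250, TRUE)  # 300
#' staircase_update(250, FALSE) # 200
#' staircase_update(0, FALSE)   # clamped at 0
#' @export
staircase_update <- function(current_ssd, inhibited, step = 50, floor = 0) {
  if (any(step < 0)) abort("`step` must be non-negative.")
  if (any(current_ssd < floor)) abort("`current_ssd` must be at least `floor`.")
  ifelse(inhibited, current_ssd + step, pmax(current_ssd - step, floor))
}

# Truncated-at-zero normal draws, vectorised over mean/sd (recycled).
rtnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  guard <- 0L
  while (length(bad) > 0 && guard < 100L) {
    x[bad] <- rnorm(length(bad), rep_len(mean, n)[bad], rep_len(sd, n)[bad])
    bad <- bad[x[bad] <= 0]
    guard <- guard + 1L
  }
  if (length(bad) > 0) x[bad] <- rep_len(mean, n)[bad] # pathological sd
  x
}

# Core vectorised race simulation. `params_tbl` has one row per participant
# with race-parameter columns; stop positions are randomised per participant
# and the SSD staircase runs across stop trials in presentation order
# (practice included, so the experimental blocks start from a settled delay).
simulate_race <- function(params_tbl, blocks = 4, trials_per_block = 24,
                          stop_rate = 0.25, practice = TRUE) {
  P <- nrow(params_tbl)
  n_stop_blk <- as.integer(round(stop_rate * trials_per_block))
  if (abs(stop_rate * trials_per_block - n_stop_blk) > 1e-8) {
    abort("`stop_rate * trials_per_block` must be a whole number.")
  }
  block_ids <- if (practice) c(0L, seq_len(blocks)) else seq_len(blocks)
  B <- length(block_ids)
  T_total <- B * trials_per_block
  S_total <- B * n_stop_blk

  gp <- function(nm) rep_len(params_tbl[[nm]], P)
  go_mu <- gp("go_mu"); go_sigma <- gp("go_sigma"); go_tau <- gp("go_tau")
  err <- gp("go_error_rate"); omis <- gp("go_omission_rate")
  ssrt_mu <- gp("ssrt_mean"); ssrt_sd <- gp("ssrt_sd")
  ssd0 <- gp("initial_ssd"); step <- gp("ssd_step"); floor_ <- gp("ssd_floor")
  win <- gp("response_window")

  # Stop-trial mask, P x T (per participant, per block)
  stop_mask <- matrix(FALSE, P, T_total)
  for (b in seq_len(B)) {
    off <- (b - 1L) * trials_per_block
    for (i in seq_len(P)) {
      stop_mask[i, off + sample.int(trials_per_block, n_stop_blk)] <- TRUE
    }
  }

  # Go finishing times (ex-Gaussian), omissions as infinite finish
  go_finish <- matrix(rnorm(P * T_total, go_mu, go_sigma) +
                        rexp(P * T_total, rate = 1 / go_tau), P, T_total)
  go_finish[go_finish < 1] <- 1
  go_finish[matrix(runif(P * T_total), P, T_total) < omis] <- Inf
  correct_draw <- matrix(runif(P * T_total), P, T_total) >= err

  # Stop-process latencies and the staircase across stop trials in order
  ssrt_draw <- matrix(rtnorm_pos(P * S_total, ssrt_mu, ssrt_sd), P, S_total)
  stop_pos <- matrix(0L, P, S_total)
  for (i in seq_len(P)) stop_pos[i, ] <- which(stop_mask[i, ])

  ssd_mat <- matrix(NA_real_, P, S_total)
  resp_stop <- matrix(NA, P, S_total)
  ssd <- ssd0
  rows <- seq_len(P)
  for (k in seq_len(S_total)) {
    gf <- go_finish[cbind(rows, stop_pos[, k])]
    stop_finish <- ssd + ssrt_draw[, k]
    responded <- gf < stop_finish & gf <= win
    ssd_mat[, k] <- ssd
    resp_stop[, k] <- responded
    ssd <- staircase_update(ssd, !responded, step, floor_)
  }

  # Assemble the long trial table
  responded <- is.finite(go_finish) & go_finish <= win
  ssd_full <- matrix(NA_real_, P, T_total)
  idx <- cbind(rep(rows, S_total), as.vector(stop_pos))
  ssd_full[idx] <- as.vector(ssd_mat)
  responded[idx] <- as.vector(resp_stop)

  rt <- go_finish
  rt[!responded] <- NA_real_
  correct <- ifelse(responded, correct_draw, NA)

  block_col <- rep(block_ids, each = trials_per_block)
  trial_col <- rep(seq_len(trials_per_block), times = B)
  tibble(
    participant_id = rep(params_tbl$participant_id, each = T_total),
    block = rep(block_col, times = P),
    trial = rep(trial_col, times = P),
    is_stop = as.vector(t(stop_mask)),
    ssd_ms = as.vector(t(ssd_full)),
    responded = as.vector(t(responded)),
    correct = as.vector(t(correct)),
    rt_ms = round(as.vector(t(rt)), 1)
  )
}

#' Simulate stop-signal task sessions for a cohort
#'
#' Runs the independent horse-race model for every participant: on each trial
#' the go process (ex-Gaussian finishing time) races the stop process
#' (stop-signal latency started `ssd` ms after the go stimulus); a response
#' is emitted only if the go process wins and finishes inside the response
#' window. The stop-signal delay follows the one-up/one-down staircase across
#' stop trials in presentation order.
#'
#' @param participants A data frame with a `participant_id` column plus any
#'   race-parameter columns (see [race_params()]); missing parameter columns
#'   are filled with the defaults. A bare integer is shorthand for that many
#'   participants with default parameters.
#' @param blocks,trials_per_block,stop_rate,practice Session layout, as in
#'   [build_schedule()].
#' @param seed Optional integer seed; output is deterministic given it.
#'
#' @return A tibble of trial records: `participant_id`, `block` (0 =
#'   practice), `trial`, `is_stop`, `ssd_ms` (stop trials only), `responded`,
#'   `correct` (responded trials only), `rt_ms` (responded trials only).
#' @examples
#' trials <- simulate_sst(5, seed = 1)
#' dplyr::count(trials, is_stop)
#' @export
simulate_sst <- function(participants, blocks = 4, trials_per_block = 24,
                         stop_rate = 0.25, practice = TRUE, seed = NULL) {
  if (is.numeric(participants) && length(participants) == 1) {
    participants <- tibble(
      participant_id = sprintf("p%04d", seq_len(participants))
    )
  }
  if (!"participant_id" %in% names(participants)) {
    abort("`participants` must have a `participant_id` column.")
  }
  defaults <- unclass(race_params())
  for (nm in names(defaults)) {
    if (!nm %in% names(participants)) participants[[nm]] <- defaults[[nm]]
  }
  validate_race_params(as.list(participants[names(defaults)]))
  with_seed_or_rng(seed, {
    simulate_race(participants, blocks, trials_per_block, stop_rate, practice)
  })
}

#' Simulate one participant on an explicit schedule
#'
#' Runs the horse race over the trials of a schedule produced by
#' [build_schedule()]. The per-block stop counts of the schedule are honoured
#' (stop positions are re-randomised per simulation run; the race dynamics
#' depend only on the ordered sequence of stop trials).
#'
#' @param schedule A schedule tibble from [build_schedule()].
#' @param params A [race_params()] object.
#' @param seed Optional integer seed.
#' @param participant_id Identifier for the output records.
#'
#' @return A tibble of trial records (see [simulate_sst()]).
#' @examples
#' sched <- build_schedule(seed = 1)
#' trials <- simulate_participant(sched, race_params(), seed = 2)
#' @export
simulate_participant <- function(schedule, params = race_params(),
                                 seed = NULL, participant_id = "p0001") {
  stopifnot(all(c("block", "trial", "is_stop") %in% names(schedule)))
  blocks <- sum(unique(schedule$block) > 0)
  tpb <- max(schedule$trial)
  n_stop_blk <- sum(schedule$is_stop & schedule$block == max(schedule$block))
  ptbl <- tibble(participant_id = participant_id)
  for (nm in names(unclass(params))) ptbl[[nm]] <- params[[nm]]
  simulate_sst(ptbl,
    blocks = blocks, trials_per_block = tpb,
    stop_rate = n_stop_blk / tpb, practice = 0L %in% schedule$block,
    seed = seed
  )
}
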