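# Shared fixtures, built in code.

# Near-deterministic race parameters: degenerate latency distributions let
# race outcomes be forced exactly.
forced_params <- function(go_mu, ssrt_mean) {
  race_params(
    go_mu = go_mu, go_sigma = 1e-6, go_tau = 1e-6,
    go_error_rate = 0, go_omission_rate = 0,
    ssrt_mean = ssrt_mean, ssrt_sd = 1e-6
  )
}

# Hand-built trial table for counting checks: one participant, n_correct
# correct go responses, n_omit omissions, n_err wrong-key responses, and a
# block of stop trials with the given inhibition outcomes.
make_trials <- function(go_rts_correct = numeric(0), n_omit = 0, n_err = 0,
                        stop_inhibited = logical(0), ssd = 250,
                        id = "p1") {
  go <- tibble::tibble(
    rt_ms = c(go_rts_correct, rep(NA, n_omit), seq_len(n_err) * 10 + 500),
    responded = c(rep(TRUE, length(go_rts_correct)), rep(FALSE, n_omit),
                  rep(TRUE, n_err)),
    correct = c(rep(TRUE, length(go_rts_correct)), rep(NA, n_omit),
                rep(FALSE, n_err)),
    is_stop = FALSE, ssd_ms = NA_real_
  )
  st <- tibble::tibble(
    rt_ms = ifelse(stop_inhibited, NA_real_, 400),
    responded = !stop_inhibited,
    correct = ifelse(stop_inhibited, NA, TRUE),
    is_stop = TRUE,
    ssd_ms = rep_len(ssd, length(stop_inhibited))
  )
  out <- dplyr::bind_rows(go, st)
  out$participant_id <- id
  out$block <- 1L
  out$trial <- seq_len(nrow(out))
  out
}

# Sibling-pair cohort with exact sibling trait duplication or independent
# traits, for boundary/null variance-component checks.
make_sib_pairs <- function(n_pairs, sib_copy = FALSE, seed = 1) {
  withr::with_seed(seed, {
    fam <- rep(sprintf("f%04d", seq_len(n_pairs)), each = 2)
    y <- if (sib_copy) rep(rnorm(n_pairs), each = 2) else rnorm(2 * n_pairs)
    tibble::tibble(
      participant_id = paste0(fam, "_", rep(1:2, n_pairs)),
      family_id = fam,
      age = runif(2 * n_pairs, 6, 18),
      sex = factor(sample(c("female", "male"), 2 * n_pairs, TRUE),
                   levels = c("female", "male")),
      y = y
    )
  })
}

# Dense-matrix ML oracle for the univariate sibling model: exact MVN
# log-likelihood with the full block covariance, intercept-only mean
# profiled by GLS, maximised by two-stage grid refinement over
# (sigmaA^2, sigmaE^2). Fully independent of the package's profiled,
# Helmert-transformed path.
dense_h2_oracle <- function(y, fam, X = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  K <- outer(fam, fam, function(a, b) ifelse(a == b, 0.5, 0)) + diag(0.5, n)
  ll <- function(sa2, se2) {
    Sig <- sa2 * K + se2 * diag(n)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    Si <- chol2inv(ch)
    beta <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
    r <- y - X %*% beta
    -sum(log(diag(ch))) - 0.5 * drop(t(r) %*% Si %*% r) -
      0.5 * n * log(2 * pi)
  }
  tot <- var(y)
  lo <- c(1e-4 * tot, 1e-4 * tot)
  hi <- c(3 * tot, 3 * tot)
  best <- c(tot / 2, tot / 2)
  for (stage in 1:4) {
    sa_grid <- seq(lo[1], hi[1], length.out = 41)
    se_grid <- seq(lo[2], hi[2], length.out = 41)
    vals <- outer(sa_grid, se_grid, Vectorize(ll))
    ix <- which(vals == max(vals), arr.ind = TRUE)[1, ]
    best <- c(sa_grid[ix[1]], se_grid[ix[2]])
    span <- c(diff(range(sa_grid)) / 10, diff(range(se_grid)) / 10)
    lo <- pmax(best - span, 1e-6 * tot)
    hi <- best + span
  }
  list(sigma2_a = best[1], sigma2_e = best[2],
       h2 = best[1] / sum(best), loglik = ll(best[1], best[2]))
}
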