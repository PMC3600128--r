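#' Specification of a synthetic family cohort
#'
#' Configures the generator that emulates a community family sample for
#' stop-signal-task studies: sibships of 2-5 children (proportions as
#' observed in large sibling cohorts), ages 6-18, four latent traits with
#' additive-genetic sibling structure, an 18-item ADHD rating (SWAN-style,
#' reversed so +54 is maximal ADHD traits), and a mapping from latent traits
#' to race-model parameters so that higher ADHD-related liabilities yield
#' longer SSRT, slower go responses and greater response variability.
#'
#' The four latent traits are `adhd` (the rated trait liability), `inh`
#' (response-inhibition liability, drives SSRT), `lat` (response latency)
#' and `var` (response variability). Each has unit residual variance after
#' covariate effects; sibling genetic correlation is exactly 0.5 times the
#' genetic covariance.
#'
#' @param n_families Number of sibships.
#' @param family_size_weights Named weights for family sizes (default the
#'   2:3:4:5 proportions 3081:387:35:4 seen in a large sibling sample).
#' @param age_range Ages are uniform on this interval (years).
#' @param prop_male Proportion of boys (default 0.499).
#' @param h2 Named heritabilities per latent trait.
#' @param rhog,rhoe Genetic and environmental correlation matrices over the
#'   traits (symmetric, unit diagonal; the implied genetic and environmental
#'   covariance matrices must be positive semi-definite).
#' @param age_effects,male_effects Named per-trait covariate slopes on the
#'   latent (unit-SD) scale: effect per year of `age - 12`, and the
#'   male-female shift.
#' @param swan_mean,swan_sd Target mean and SD of the reversed SWAN total
#'   score (defaults -5.8 and 16.3, typical of a general population sample).
#' @param swan_item_sd SD of per-item rating noise on the 7-point scale.
#' @param medicated_rate Proportion reporting recent stimulant treatment
#'   (default 0.026); medicated children are generated with stimulant-
#'   shortened SSRT so the correction path is exercisable.
#' @param medication_effect Standardised SSRT shortening in medicated
#'   children (default 0.75).
#' @param invalid_rate Baseline probability of invalid task performance
#'   (guessing, quitting, never stopping), biased toward younger, higher-
#'   trait boys.
#' @param incomplete_rate Probability a session is interrupted before the
#'   scheduled trials finish.
#'
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_families = 200)
#' spec$h2
#' @export
cohort_spec <- function(n_families = 3507,
                        family_size_weights = c("2" = 3081, "3" = 387,
                                                "4" = 35, "5" = 4),
                        age_range = c(6, 18),
                        prop_male = 0.499,
                        h2 = c(adhd = 0.38, inh = 0.31, lat = 0.26,
                               var = 0.28),
                        rhog = default_rhog(),
                        rhoe = default_rhoe(),
                        age_effects = c(adhd = -0.02, inh = -0.06,
                                        lat = -0.08, var = -0.06),
                        male_effects = c(adhd = 0.15, inh = -0.05,
                                         lat = -0.10, var = -0.10),
                        swan_mean = -5.8, swan_sd = 16.3,
                        swan_item_sd = 0.9,
                        medicated_rate = 0.026, medication_effect = 0.75,
                        invalid_rate = 0.06, incomplete_rate = 0.02) {
  traits <- names(h2)
  if (is.null(traits) || length(traits) < 1) {
    abort("`h2` must be a named vector of per-trait heritabilities.")
  }
  if (any(h2 < 0 | h2 > 1)) abort("`h2` entries must lie in [0, 1].")
  if (any(family_size_weights < 0) || sum(family_size_weights) <= 0) {
    abort("`family_size_weights` must be non-negative with positive sum.")
  }
  align <- function(M, nm) {
    if (!is.null(dimnames(M)) && all(traits %in% rownames(M))) {
      M <- M[traits, traits, drop = FALSE]
    }
    if (!all(dim(M) == length(traits))) {
      abort(sprintf("`%s` must be a %d x %d matrix over the traits in `h2`.",
                    nm, length(traits), length(traits)))
    }
    if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8)) ||
        !isTRUE(all.equal(unname(diag(M)), rep(1, ncol(M))))) {
      abort(sprintf("`%s` must be symmetric with unit diagonal.", nm))
    }
    M
  }
  rhog <- align(rhog, "rhog")
  rhoe <- align(rhoe, "rhoe")
  check_psd <- function(R, scale, label) {
    q <- length(traits)
    S <- diag(sqrt(scale), q) %*% R %*% diag(sqrt(scale), q)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      off <- abs(R); diag(off) <- 0
      bad <- which(off == max(off), arr.ind = TRUE)[1, ]
      abort(sprintf(
        "implied %s covariance is not positive semi-definite (check pair %s-%s).",
        label, traits[bad[1]], traits[bad[2]]
      ))
    }
  }
  check_psd(rhog, h2, "genetic")
  check_psd(rhoe, 1 - h2, "environmental")
  structure(
    list(
      n_families = n_families, family_size_weights = family_size_weights,
      age_range = age_range, prop_male = prop_male,
      traits = traits, h2 = h2, rhog = rhog, rhoe = rhoe,
      age_effects = age_effects, male_effects = male_effects,
      swan_mean = swan_mean, swan_sd = swan_sd, swan_item_sd = swan_item_sd,
      medicated_rate = medicated_rate, medication_effect = medication_effect,
      invalid_rate = invalid_rate, incomplete_rate = incomplete_rate
    ),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_rhog <- function() {
  tr <- c("adhd", "inh", "lat", "var")
  M <- matrix(c(
    1.00, 0.18, -0.12, 0.05,
    0.18, 1.00, -0.11, 0.42,
    -0.12, -0.11, 1.00, 0.71,
    0.05, 0.42, 0.71, 1.00
  ), 4, 4, dimnames = list(tr, tr))
  M
}

#' @rdname cohort_spec
#' @export
default_rhoe <- function() {
  tr <- c("adhd", "inh", "lat", "var")
  M <- matrix(c(
    1.00, 0.25, 0.05, 0.05,
    0.25, 1.00, -0.05, 0.20,
    0.05, -0.05, 1.00, 0.60,
    0.05, 0.20, 0.60, 1.00
  ), 4, 4, dimnames = list(tr, tr))
  M
}

#' Generate a sibling pedigree with covariates
#'
#' Draws family sizes from the configured weights, ages uniformly over the
#' age range, and sexes by the configured ratio. Individuals are full
#' siblings within a family and unrelated across families.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return A tibble: `participant_id`, `family_id`, `age` (years, one
#'   decimal), `sex` (factor female/male).
#' @examples
#' ped <- generate_pedigree(cohort_spec(n_families = 50), seed = 1)
#' table(table(ped$family_id))
#' @export
generate_pedigree <- function(spec, seed = NULL) {
  with_seed_or_rng(seed, {
    w <- spec$family_size_weights
    sizes <- as.integer(names(w))[
      sample.int(length(w), spec$n_families, replace = TRUE,
                 prob = w / sum(w))
    ]
    fam <- rep(sprintf("f%05d", seq_len(spec$n_families)), times = sizes)
    n <- length(fam)
    tibble(
      participant_id = sprintf("%s_c%d", fam,
                               unlist(lapply(sizes, seq_len))),
      family_id = fam,
      age = round(runif(n, spec$age_range[1], spec$age_range[2]), 1),
      sex = factor(ifelse(runif(n) < spec$prop_male, "male", "female"),
                   levels = c("female", "male"))
    )
  })
}

#' Generate latent traits with additive-genetic sibling structure
#'
#' For each trait, an individual's genetic value is
#' `sqrt(0.5) * a_family + sqrt(0.5) * a_individual` with both factors drawn
#' from the configured genetic covariance, so the sibling genetic
#' correlation is exactly 0.5; environmental deviations are independent
#' across individuals with the configured environmental covariance.
#' Covariate effects (age, sex) are added to the mean. Each latent phenotype
#' has unit residual variance, so a trait with heritability h2 has expected
#' sibling correlation 0.5 * h2 after covariate removal.
#'
#' @param pedigree Output of [generate_pedigree()].
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return `pedigree` with one `latent_<trait>` column per configured trait.
#' @export
generate_traits <- function(pedigree, spec, seed = NULL) {
  q <- length(spec$traits)
  SG <- diag(sqrt(spec$h2), q) %*% spec$rhog %*% diag(sqrt(spec$h2), q)
  SE <- diag(sqrt(1 - spec$h2), q) %*% spec$rhoe %*%
    diag(sqrt(1 - spec$h2), q)
  # Matrix square roots via eigen (covariances may be singular, e.g. rhog 1)
  msqrt <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), q) %*% t(e$vectors)
  }
  LG <- msqrt(SG)
  LE <- msqrt(SE)
  n <- nrow(pedigree)
  fam_idx <- match(pedigree$family_id, unique(pedigree$family_id))
  nf <- max(fam_idx)
  with_seed_or_rng(seed, {
    a_fam <- matrix(rnorm(nf * q), nf, q) %*% LG
    a_ind <- matrix(rnorm(n * q), n, q) %*% LG
    e_ind <- matrix(rnorm(n * q), n, q) %*% LE
    g <- sqrt(0.5) * a_fam[fam_idx, , drop = FALSE] + sqrt(0.5) * a_ind
    lat <- g + e_ind
    male <- as.numeric(pedigree$sex == "male")
    for (j in seq_len(q)) {
      tr <- spec$traits[j]
      lat[, j] <- lat[, j] +
        (spec$age_effects[[tr]] %||% 0) * (pedigree$age - 12) +
        (spec$male_effects[[tr]] %||% 0) * male
    }
    colnames(lat) <- paste0("latent_", spec$traits)
    dplyr::bind_cols(pedigree, as_tibble(lat))
  })
}

#' Generate SWAN-style ADHD trait ratings from a latent liability
#'
#' Produces 18 item scores on the reversed 7-point scale (-3..+3, higher =
#' more ADHD traits) by discretising a shifted normal around the latent
#' value, then sums them: nine inattention items, nine
#' hyperactivity-impulsivity items, total = IA + HI by construction. Totals
#' are bounded in \[-54, 54\] and subscales in \[-27, 27\] on every draw.
#' The internal latent scale is shrunk so that the *total* SD matches
#' `swan_sd` despite item noise and rounding.
#'
#' @param latent Standardised latent ADHD liability (vector).
#' @param spec A [cohort_spec()] (supplies `swan_mean`, `swan_sd`,
#'   `swan_item_sd`).
#' @param seed Optional integer seed.
#' @return A tibble: `swan_total`, `swan_inattention`,
#'   `swan_hyperimpulsive` (integers, reversed scale).
#' @examples
#' generate_swan(c(-2, 0, 2), cohort_spec(n_families = 10), seed = 1)
#' @export
generate_swan <- function(latent, spec = cohort_spec(), seed = NULL) {
  if (any(!is.finite(latent))) abort("`latent` must be finite.")
  n_items <- 18L
  noise_var <- n_items * spec$swan_item_sd^2 + n_items / 12
  lat_sd <- sqrt(max(spec$swan_sd^2 - noise_var, 1))
  centre <- spec$swan_mean + lat_sd * latent
  n <- length(latent)
  with_seed_or_rng(seed, {
    items <- matrix(
      pmin(pmax(round(rep(centre / n_items, n_items) +
                        rnorm(n * n_items, 0, spec$swan_item_sd)), -3L), 3L),
      n, n_items
    )
    ia <- as.integer(rowSums(items[, 1:9, drop = FALSE]))
    hi <- as.integer(rowSums(items[, 10:18, drop = FALSE]))
    tibble(
      swan_total = ia + hi,
      swan_inattention = ia,
      swan_hyperimpulsive = hi
    )
  })
}

#' Map latent traits, age and sex to race-model parameters
#'
#' A deterministic linear calibration from the inhibition, latency and
#' variability liabilities (expressed in ADHD-trait-equivalent units, i.e.
#' latent SD times 16.3) to the generating race parameters. The default
#' calibration makes predicted SSRT rise by about 138 ms and GoRTSD by about
#' 51 ms from trait -54 to +54 at age 6, with shallower gradients at 18;
#' both fall with age, and boys are slightly faster — the gradient pattern
#' of predicted stop-task values in large community samples. Target
#' GoRT mean and SD are converted to ex-Gaussian parameters with
#' `tau = 0.69 * sd`.
#'
#' @param data A tibble with columns `latent_inh`, `latent_lat`,
#'   `latent_var`, `age`, `sex`.
#' @param spec A [cohort_spec()] (used for trait scaling).
#' @param trait_slope,demo_slope Multipliers on the trait gradients and the
#'   demographic (age, sex) gradients; 1 keeps the default calibration, 0
#'   removes the dependence (with both at 0 every individual gets identical
#'   baseline parameters).
#' @return `data` with race-parameter columns appended (see
#'   [race_params()]).
#' @export
traits_to_race_params <- function(data, spec = cohort_spec(),
                                  trait_slope = 1, demo_slope = 1) {
  male <- as.numeric(data$sex == "male") * demo_slope
  agec <- (data$age - 12) * demo_slope
  age6 <- (data$age - 6) * demo_slope
  Ti <- 16.3 * data$latent_inh * trait_slope
  Tl <- 16.3 * data$latent_lat * trait_slope
  Tv <- 16.3 * data$latent_var * trait_slope

  ssrt_t <- 337.25 + (0.9213 - 0.05942 * agec) * Ti - 21.625 * agec +
    male * (-30 + 2.5 * age6)
  gort_t <- 640.75 + (0.2361 - 0.00694 * agec) * Tl - 18.27 * agec +
    male * (-42 + 4.083 * age6)
  gsd_t <- 181.5 + (0.3704 - 0.01698 * agec) * Tv - 8.17 * agec +
    male * (-17 + 1.5 * age6)

  ssrt_t <- pmax(ssrt_t, 80)
  gsd_t <- pmax(gsd_t, 30)
  tau <- 0.69 * gsd_t
  sigma <- sqrt(1 - 0.69^2) * gsd_t
  mu <- pmax(gort_t - tau, 120)

  data |>
    dplyr::mutate(
      go_mu = mu, go_sigma = sigma, go_tau = tau,
      go_error_rate = 0.03, go_omission_rate = 0.01,
      ssrt_mean = ssrt_t, ssrt_sd = 50,
      initial_ssd = 250, ssd_step = 50, ssd_floor = 0,
      response_window = 3000
    )
}

#' Generate a complete synthetic family cohort
#'
#' Chains [generate_pedigree()], [generate_traits()], [generate_swan()] and
#' [traits_to_race_params()], then injects medicated children (stimulant-
#' shortened SSRT parameters), invalid performers (guessers with sub-100 ms
#' responses, quitters who stop responding, non-stoppers whose stop process
#' is far too slow — all biased toward younger, higher-trait boys) and
#' interrupted sessions, so that downstream exclusion accounting is
#' exercised the way real cohorts exercise it.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed; the cohort is deterministic given it.
#' @return A tibble with one row per child: pedigree columns, latent traits,
#'   SWAN scores, `medicated`, `performer_type`
#'   (`typical`/`guesser`/`quitter`/`nonstopper`), `interrupted`, and
#'   race-parameter columns.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_families = 100), seed = 1)
#' dplyr::count(cohort, performer_type)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!all(c("adhd", "inh", "lat", "var") %in% spec$traits)) {
    abort("`generate_cohort()` needs the four standard traits adhd, inh, lat, var.")
  }
  ped <- generate_pedigree(spec, seed = child_seed(seed, 1))
  ped <- generate_traits(ped, spec, seed = child_seed(seed, 2))
  swan <- generate_swan(ped$latent_adhd, spec, seed = child_seed(seed, 3))
  cohort <- dplyr::bind_cols(ped, swan) |>
    traits_to_race_params(spec)
  with_seed_or_rng(child_seed(seed, 4), {
    n <- nrow(cohort)
    cohort$medicated <- runif(n) < spec$medicated_rate
    sd_ssrt <- sd(cohort$ssrt_mean)
    cohort$ssrt_mean <- ifelse(
      cohort$medicated,
      pmax(cohort$ssrt_mean - spec$medication_effect * sd_ssrt, 80),
      cohort$ssrt_mean
    )
    # invalid performance, biased toward younger, higher-trait boys
    lin <- stats::qlogis(pmin(pmax(spec$invalid_rate, 1e-6), 1 - 1e-6)) +
      0.4 * scale(-cohort$age)[, 1] + 0.4 * cohort$latent_adhd +
      0.3 * as.numeric(cohort$sex == "male")
    is_invalid <- runif(n) < stats::plogis(lin)
    type <- rep("typical", n)
    type[is_invalid] <- sample(c("guesser", "quitter", "nonstopper"),
                               sum(is_invalid), replace = TRUE)
    cohort$performer_type <- type
    g <- type == "guesser"
    cohort$go_mu[g] <- 70; cohort$go_sigma[g] <- 25; cohort$go_tau[g] <- 25
    cohort$go_error_rate[g] <- 0.45
    q <- type == "quitter"
    cohort$go_omission_rate[q] <- 0.45
    ns <- type == "nonstopper"
    cohort$ssrt_mean[ns] <- 1400; cohort$ssrt_sd[ns] <- 150
    cohort$interrupted <- runif(n) < spec$incomplete_rate
    cohort
  })
}
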