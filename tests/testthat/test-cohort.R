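test_that("pedigrees follow the configured size distribution", {
  spec <- cohort_spec(n_families = 3507)
  ped <- generate_pedigree(spec, seed = 1)
  # expected cohort size: mean family size 7483/3507 under the default
  # weights, so about 7483 individuals at 3507 families
  expect_lt(abs(nrow(ped) - 7483), 150)
  expect_equal(dplyr::n_distinct(ped$family_id), 3507)
  expect_true(all(ped$age >= 6 & ped$age <= 18))
  expect_true(all(table(ped$family_id) >= 2))

  only2 <- cohort_spec(n_families = 40, family_size_weights = c("2" = 1))
  ped2 <- generate_pedigree(only2, seed = 2)
  expect_true(all(table(ped2$family_id) == 2))

  expect_identical(generate_pedigree(spec, seed = 3),
                   generate_pedigree(spec, seed = 3))
})

test_that("latent traits carry the configured sibling correlation", {
  spec <- cohort_spec(n_families = 4000,
                      h2 = c(adhd = 0.31, inh = 0, lat = 0.26, var = 0.28),
                      age_effects = c(adhd = 0, inh = 0, lat = 0, var = 0),
                      male_effects = c(adhd = 0, inh = 0, lat = 0, var = 0))
  ped <- generate_pedigree(spec, seed = 4)
  tr <- generate_traits(ped, spec, seed = 5)
  sib_cor <- function(x, fam) {
    d <- tibble::tibble(x = x, fam = fam) |>
      dplyr::group_by(fam) |>
      dplyr::filter(dplyr::n() >= 2) |>
      dplyr::slice_head(n = 2) |>
      dplyr::mutate(pos = dplyr::row_number()) |>
      tidyr::pivot_wider(names_from = pos, values_from = x)
    stats::cor(d$`1`, d$`2`)
  }
  # expected sibling correlation is half the heritability
  expect_equal(sib_cor(tr$latent_adhd, tr$family_id), 0.155,
               tolerance = 0.035)
  expect_lt(abs(sib_cor(tr$latent_inh, tr$family_id)), 0.04)
  expect_equal(var(tr$latent_adhd), 1, tolerance = 0.07)
})

test_that("perfect genetic and environmental correlation duplicates traits", {
  tr4 <- c("adhd", "inh", "lat", "var")
  ones <- function(rho_ai) {
    M <- diag(4); dimnames(M) <- list(tr4, tr4)
    M["adhd", "inh"] <- M["inh", "adhd"] <- rho_ai
    M
  }
  spec <- cohort_spec(n_families = 300,
                      h2 = c(adhd = 0.4, inh = 0.4, lat = 0.3, var = 0.3),
                      rhog = ones(1), rhoe = ones(1),
                      age_effects = c(adhd = 0, inh = 0, lat = 0, var = 0),
                      male_effects = c(adhd = 0, inh = 0, lat = 0, var = 0))
  ped <- generate_pedigree(spec, seed = 6)
  tr <- generate_traits(ped, spec, seed = 7)
  expect_equal(stats::cor(tr$latent_adhd, tr$latent_inh), 1,
               tolerance = 1e-8)
})

test_that("SWAN scores honour bounds, additivity and target moments", {
  spec <- cohort_spec(n_families = 3000)
  lat <- withr::with_seed(8, rnorm(6000))
  sw <- generate_swan(lat, spec, seed = 9)
  expect_true(all(sw$swan_total >= -54 & sw$swan_total <= 54))
  expect_true(all(sw$swan_inattention >= -27 & sw$swan_inattention <= 27))
  expect_true(all(sw$swan_hyperimpulsive >= -27 &
                    sw$swan_hyperimpulsive <= 27))
  expect_identical(sw$swan_total,
                   sw$swan_inattention + sw$swan_hyperimpulsive)
  expect_true(all(sw$swan_total == round(sw$swan_total)))
  expect_equal(mean(sw$swan_total), -5.8, tolerance = 0.8)
  expect_equal(sd(sw$swan_total), 16.3, tolerance = 1)
  # saturation at the extreme tail and symmetry at zero
  hi <- generate_swan(rep(6, 50), spec, seed = 10)
  expect_gt(mean(hi$swan_total), 50)
  mid <- generate_swan(rep(0.3558, 2000), spec, seed = 11)
  expect_lt(abs(mean(mid$swan_total)), 2.5)
  expect_error(generate_swan(c(1, NA), spec), "finite")
})

test_that("the race-parameter map matches its calibration targets", {
  grid <- tidyr::expand_grid(
    latent_inh = c(-54, 54) / 16.3, age = c(6, 18),
    sex = factor("female", levels = c("female", "male"))
  ) |>
    dplyr::mutate(latent_lat = latent_inh, latent_var = latent_inh)
  rp <- traits_to_race_params(grid)
  ssrt_at <- function(tr, age) {
    rp$ssrt_mean[grid$latent_inh == tr / 16.3 & grid$age == age]
  }
  # trait gradient ~138 ms at age 6, shallower at 18; decreasing with age
  expect_equal(ssrt_at(54, 6) - ssrt_at(-54, 6), 138, tolerance = 1)
  expect_equal(ssrt_at(54, 18) - ssrt_at(-54, 18), 61, tolerance = 1.5)
  expect_lt(ssrt_at(-54, 18), ssrt_at(-54, 6))
  expect_lt(ssrt_at(54, 18), ssrt_at(54, 6))
  # go-process targets reproduce GoRT mean and SD cells
  gort <- rp$go_mu + rp$go_tau
  gsd <- sqrt(rp$go_sigma^2 + rp$go_tau^2)
  expect_equal(gort[grid$latent_inh == -54 / 16.3 & grid$age == 6], 735,
               tolerance = 1)
  expect_equal(gsd[grid$latent_inh == 54 / 16.3 & grid$age == 6], 256,
               tolerance = 1)
  # monotone in trait
  expect_gt(ssrt_at(54, 6), ssrt_at(-54, 6))
  # zero gradients collapse to identical baseline parameters
  flat <- traits_to_race_params(grid, trait_slope = 0, demo_slope = 0)
  expect_equal(length(unique(flat$ssrt_mean)), 1)
  expect_equal(length(unique(flat$go_mu)), 1)
})

test_that("cohort generation is deterministic and labels special groups", {
  spec <- cohort_spec(n_families = 200)
  c1 <- generate_cohort(spec, seed = 12)
  c2 <- generate_cohort(spec, seed = 12)
  expect_identical(c1, c2)
  expect_true(all(c1$performer_type %in%
                    c("typical", "guesser", "quitter", "nonstopper")))
  # medicated children have shorter generating SSRT than matched typicals
  med <- c1$medicated & c1$performer_type == "typical"
  if (any(med)) {
    expect_lt(mean(c1$ssrt_mean[med]),
              mean(c1$ssrt_mean[!c1$medicated &
                                  c1$performer_type == "typical"]))
  }
})

test_that("invalid covariance structures are rejected", {
  tr4 <- c("adhd", "inh", "lat", "var")
  bad <- diag(4); dimnames(bad) <- list(tr4, tr4)
  bad["adhd", "inh"] <- 0.9; bad["inh", "adhd"] <- 0.9
  bad["adhd", "lat"] <- 0.9; bad["lat", "adhd"] <- 0.9
  bad["inh", "lat"] <- -0.9; bad["lat", "inh"] <- -0.9
  expect_error(cohort_spec(rhog = bad), "positive semi-definite")
  asym <- diag(4); dimnames(asym) <- list(tr4, tr4)
  asym[1, 2] <- 0.5
  expect_error(cohort_spec(rhog = asym), "symmetric")
  expect_error(cohort_spec(h2 = c(adhd = 1.2, inh = 0.3, lat = 0.2,
                                  var = 0.2)), "\\[0, 1\\]")
})

test_that("round-trip: simulate and score recovers generator gradients", {
  spec <- cohort_spec(n_families = 600)
  cohort <- generate_cohort(spec, seed = 13)
  typical <- dplyr::filter(cohort, performer_type == "typical", !medicated)
  sc <- score_sst(simulate_sst(typical, seed = 14)) |>
    apply_validity_filters() |>
    dplyr::left_join(
      dplyr::select(typical, participant_id, latent_inh, latent_var,
                    swan_total),
      by = "participant_id"
    ) |>
    dplyr::filter(valid)
  # measured SSRT rises with the inhibition liability; GoRTSD with the
  # variability liability (end-to-end sign preservation)
  expect_gt(stats::cor(sc$ssrt, sc$latent_inh), 0.1)
  expect_gt(stats::cor(sc$gort_sd, sc$latent_var), 0.1)
  expect_gt(stats::cor(sc$ssrt, sc$swan_total), 0)
})
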