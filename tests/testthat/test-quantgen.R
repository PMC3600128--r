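test_that("ML variance components match dense grid search on toy pedigrees", {
  # 6 individuals in three sibling pairs: the profiled Helmert-transform ML
  # must agree with an exhaustive dense-covariance grid search
  withr::with_seed(12, {
    fam <- rep(c("f1", "f2", "f3"), each = 2)
    g <- rep(rnorm(3, 0, 0.8), each = 2) + rnorm(6, 0, 0.5)
    d <- tibble::tibble(participant_id = as.character(1:6), family_id = fam,
                        y = g)
  })
  fit <- univariate_h2(d, "y", covariates = character(0))
  oracle <- dense_h2_oracle(d$y, d$family_id)
  expect_equal(fit$sigma2_a, oracle$sigma2_a, tolerance = 1e-3)
  expect_equal(fit$sigma2_e, oracle$sigma2_e, tolerance = 1e-3)
  expect_equal(fit$h2, oracle$h2, tolerance = 1e-3)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)

  # a second configuration, mixed family sizes 2 + 3 with stronger sharing
  withr::with_seed(31, {
    fam2 <- c("a", "a", "b", "b", "b")
    g2 <- rep(rnorm(2, 0, 1.2), times = c(2, 3)) + rnorm(5, 0, 0.4)
    d2 <- tibble::tibble(family_id = fam2, y = g2)
  })
  fit2 <- univariate_h2(d2, "y", covariates = character(0))
  oracle2 <- dense_h2_oracle(d2$y, d2$family_id)
  expect_equal(fit2$h2, oracle2$h2, tolerance = 1e-3)
  expect_equal(fit2$loglik, oracle2$loglik, tolerance = 1e-6)
})

test_that("bivariate likelihood equals the dense stacked-normal likelihood", {
  withr::with_seed(3, {
    fam <- rep(c("f1", "f2", "f3"), c(2, 3, 2))
    n <- length(fam)
    d <- tibble::tibble(family_id = fam, age = runif(n, 6, 18),
                        sex = factor(sample(c("female", "male"), n, TRUE),
                                     levels = c("female", "male")),
                        y1 = rnorm(n), y2 = rnorm(n))
  })
  dense_nll <- function(par, d) {
    h2 <- par[1:2]; sp2 <- exp(par[3:4]); rg <- par[5]; re <- par[6]
    sa <- sqrt(h2 * sp2); se_ <- sqrt((1 - h2) * sp2)
    G <- matrix(c(sa[1]^2, rg * sa[1] * sa[2], rg * sa[1] * sa[2],
                  sa[2]^2), 2)
    E <- matrix(c(se_[1]^2, re * se_[1] * se_[2], re * se_[1] * se_[2],
                  se_[2]^2), 2)
    K <- outer(d$family_id, d$family_id,
               function(a, b) ifelse(a == b, 0.5, 0)) + diag(0.5, nrow(d))
    Sig <- kronecker(G, K) + kronecker(E, diag(nrow(d)))
    X1 <- model.matrix(~ age + sex, d)
    X <- rbind(cbind(X1, 0 * X1), cbind(0 * X1, X1))
    y <- c(d$y1, d$y2)
    Si <- solve(Sig)
    beta <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% y)
    r <- y - X %*% beta
    as.numeric(0.5 * (determinant(Sig)$modulus + t(r) %*% Si %*% r +
                        length(y) * log(2 * pi)))
  }
  inp <- stoprace:::build_vc_inputs(d, c("y1", "y2"), c("age", "sex"),
                                    "family_id")
  Y <- cbind(inp$data$y1, inp$data$y2)
  tr <- stoprace:::vc_transform(cbind(Y, inp$X), inp$data$family_id)
  zY <- tr$Z[, 1:2]; zX <- tr$Z[, -(1:2)]; lambda <- tr$lambda
  groups <- lapply(sort(unique(lambda)), function(l) {
    sel <- lambda == l
    list(lambda = l, m = sum(sel),
         CXX = crossprod(zX[sel, , drop = FALSE]),
         CXY = crossprod(zX[sel, , drop = FALSE], zY[sel, , drop = FALSE]),
         CYY = crossprod(zY[sel, , drop = FALSE]))
  })
  for (par in list(c(0.4, 0.3, log(1.2), log(0.8), 0.5, -0.2),
                   c(0.1, 0.9, log(0.5), log(2.1), -0.7, 0.3),
                   c(0.5, 0.5, 0, 0, 0, 0))) {
    expect_equal(stoprace:::biv_nll(par, groups, ncol(zX)),
                 dense_nll(par, d), tolerance = 1e-8)
  }
})

test_that("duplicated sibling traits drive h2 to the upper boundary", {
  d <- make_sib_pairs(300, sib_copy = TRUE)
  fit <- univariate_h2(d, "y", covariates = character(0))
  expect_equal(fit$h2, 1, tolerance = 1e-6)
  expect_lt(fit$p_value, 1e-10)
})

test_that("family-independent traits give near-zero, non-significant h2", {
  ests <- numeric(10); ps <- numeric(10)
  for (i in 1:10) {
    d <- make_sib_pairs(400, sib_copy = FALSE, seed = 100 + i)
    fit <- univariate_h2(d, "y", covariates = c("age", "sex"))
    ests[i] <- fit$h2; ps[i] <- fit$p_value
  }
  expect_lt(mean(ests), 0.08)
  expect_gte(sum(ps > 0.05), 9)
})

test_that("heritability recovery at realistic scale, with plausible SE", {
  cohort <- generate_cohort(cohort_spec(n_families = 2000), seed = 51)
  fit <- univariate_h2(cohort, "latent_inh")
  expect_lt(abs(fit$h2 - 0.31), 2 * fit$se)
  expect_gt(fit$se, 0.02)
  expect_lt(fit$se, 0.06)
  expect_lt(fit$p_value, 1e-6)
  ci <- fit$ci
  expect_true(ci[1] <= fit$h2 && fit$h2 <= ci[2])
})

test_that("h2 confidence intervals follow the clamped normal formula", {
  expect_equal(h2_confidence_interval(0.31, 0.03),
               c(0.31 - qnorm(0.975) * 0.03, 0.31 + qnorm(0.975) * 0.03),
               tolerance = 1e-12)
  expect_equal(round(h2_confidence_interval(0.31, 0.03), 4),
               c(0.2512, 0.3688))
  # interval collapses to the point estimate as alpha -> 1
  ci_tight <- h2_confidence_interval(0.31, 0.03, alpha = 1 - 1e-9)
  expect_equal(ci_tight, c(0.31, 0.31), tolerance = 1e-6)
  expect_equal(h2_confidence_interval(0.02, 0.03)[1], 0)
  expect_equal(h2_confidence_interval(0.99, 0.03)[2], 1)
  expect_error(h2_confidence_interval(0.3, -0.1), "positive")
  expect_error(h2_confidence_interval(0.3, 0.03, alpha = 2), "alpha")
})

test_that("the phenotypic-correlation decomposition identity holds", {
  expect_equal(decompose_rhop(0.5, 0.9, 0, 0), 0)
  expect_equal(decompose_rhop(1, 1, 0.63, -0.9), 0.63)
  expect_equal(decompose_rhop(0.31, 0.28, 0.42, 0.10),
               0.42 * sqrt(0.31) * sqrt(0.28) +
                 0.10 * sqrt(0.69) * sqrt(0.72))
})

test_that("bivariate fits recover generating correlations and satisfy the
           decomposition", {
  cohort <- generate_cohort(cohort_spec(n_families = 2000), seed = 77)
  bv <- bivariate_fit(cohort, "latent_inh", "latent_var")
  expect_lt(abs(bv$rhog - 0.42), 2 * bv$rhog_se)
  expect_lt(abs(bv$rhoe - 0.20), 0.15)
  expect_equal(
    bv$rhop, decompose_rhop(bv$h2_1, bv$h2_2, bv$rhog, bv$rhoe),
    tolerance = 1e-6
  )
  expect_lte(abs(bv$rhog), 1)
  expect_true(bv$h2_1 >= 0 && bv$h2_1 <= 1)
})

test_that("identical genetic factors push rhog to the +1 boundary", {
  rg <- default_rhog(); rg["adhd", "inh"] <- rg["inh", "adhd"] <- 1
  rg["adhd", "lat"] <- rg["lat", "adhd"] <- rg["inh", "lat"]
  rg["adhd", "var"] <- rg["var", "adhd"] <- rg["inh", "var"]
  spec <- cohort_spec(n_families = 1200,
                      h2 = c(adhd = 0.4, inh = 0.4, lat = 0.26, var = 0.28),
                      rhog = rg)
  cohort <- generate_cohort(spec, seed = 8)
  bv <- bivariate_fit(cohort, "latent_adhd", "latent_inh")
  expect_gt(bv$rhog, 0.9)
  expect_lt(bv$p_rhog_zero, 1e-6)
})

test_that("null genetic and environmental correlations are recovered", {
  spec <- cohort_spec(n_families = 1200, rhog = diag(4) |>
                        `dimnames<-`(list(c("adhd", "inh", "lat", "var"),
                                          c("adhd", "inh", "lat", "var"))),
                      rhoe = diag(4) |>
                        `dimnames<-`(list(c("adhd", "inh", "lat", "var"),
                                          c("adhd", "inh", "lat", "var"))))
  cohort <- generate_cohort(spec, seed = 9)
  bv <- bivariate_fit(cohort, "latent_inh", "latent_var")
  expect_lt(abs(bv$rhog), 2 * bv$rhog_se + 1e-6)
  expect_lt(abs(bv$rhoe), 0.1)
  expect_gt(bv$p_rhog_zero, 0.01)
})

test_that("estimates are invariant to family order and affine rescaling", {
  cohort <- generate_cohort(cohort_spec(n_families = 400), seed = 13)
  fit <- univariate_h2(cohort, "latent_inh")
  shuffled <- cohort[withr::with_seed(1, sample(nrow(cohort))), ]
  fit_sh <- univariate_h2(shuffled, "latent_inh")
  expect_equal(fit_sh$h2, fit$h2, tolerance = 1e-6)
  rescaled <- dplyr::mutate(cohort, latent_inh = 3 * latent_inh + 7)
  fit_rs <- univariate_h2(rescaled, "latent_inh")
  expect_equal(fit_rs$h2, fit$h2, tolerance = 1e-6)
  expect_equal(fit_rs$sigma2_a, 9 * fit$sigma2_a, tolerance = 1e-4)
})

test_that("a null covariate barely moves the estimate", {
  cohort <- generate_cohort(cohort_spec(n_families = 1000), seed = 14)
  cohort$junk <- withr::with_seed(2, rnorm(nrow(cohort)))
  f0 <- univariate_h2(cohort, "latent_inh")
  f1 <- univariate_h2(cohort, "latent_inh",
                      covariates = c("age", "sex", "junk"))
  expect_lt(abs(f0$h2 - f1$h2), 0.02)
})

test_that("degenerate pedigrees are refused", {
  d <- tibble::tibble(family_id = as.character(1:50),
                      y = rnorm(50))
  expect_error(univariate_h2(d, "y", covariates = character(0)),
               "singleton")
  expect_error(
    univariate_h2(make_sib_pairs(20), "nope", covariates = character(0)),
    "not found"
  )
})

test_that("tidy and glance methods expose the fit", {
  d <- make_sib_pairs(200, sib_copy = FALSE, seed = 5)
  fit <- univariate_h2(d, "y")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(td$estimate[td$term == "h2"], fit$h2)
  gl <- glance(fit)
  expect_equal(gl$n_families, 200)
})
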