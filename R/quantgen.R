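#' @name quantgen
#' @title Sibling variance-components estimation
#' @description
#' Maximum-likelihood variance components for family data of full siblings
#' (expected additive-genetic relationship 0.5 within family, 0 across).
#' The phenotype model is `y = X beta + g + e` with
#' `Cov(y) = sigmaA^2 K + sigmaE^2 I`, where `K` is the block-diagonal
#' kinship-derived relationship matrix (1 on the diagonal, 0.5 between
#' sibs). Heritability is `h2 = sigmaA^2 / (sigmaA^2 + sigmaE^2)`, the
#' genetic share of the residual phenotypic variance after covariates.
#'
#' Within a family of size n, `K = 0.5 I + 0.5 J` is compound-symmetric, so
#' an orthogonal per-family (Helmert) rotation diagonalises the covariance:
#' the family-mean component has relationship eigenvalue `(n + 1) / 2` and
#' each of the n - 1 contrasts has eigenvalue `1/2`. The likelihood then
#' factorises over independent scalar (univariate) or 2x2 (bivariate)
#' components, covariate effects are profiled out by generalised least
#' squares, and the univariate problem reduces to a one-dimensional
#' maximisation over h2.
NULL

# Orthogonal per-family rotation of columns of cbind(y, X).
# Returns rotated columns plus the relationship eigenvalue per component.
vc_transform <- function(Y, fam) {
  fam <- as.character(fam)
  ord <- order(fam)
  Y <- Y[ord, , drop = FALSE]
  fam <- fam[ord]
  sizes <- as.integer(table(fam)[unique(fam)])
  out <- matrix(NA_real_, nrow(Y), ncol(Y))
  lambda <- numeric(nrow(Y))
  row0 <- 0L
  for (s in sort(unique(sizes))) {
    fams_s <- which(sizes == s)
    # rows of all size-s families, family-major
    starts <- cumsum(c(0L, sizes))[fams_s]
    rows <- as.vector(outer(seq_len(s), starts, `+`))
    Qs <- diag(1, s)
    if (s > 1) {
      H <- stats::contr.helmert(s)
      Qs <- cbind(rep(1 / sqrt(s), s), sweep(H, 2, sqrt(colSums(H^2)), "/"))
    }
    Ys <- Y[rows, , drop = FALSE]
    nf <- length(fams_s)
    Z <- matrix(NA_real_, length(rows), ncol(Y))
    for (c in seq_len(ncol(Y))) {
      Z[, c] <- as.vector(crossprod(Qs, matrix(Ys[, c], nrow = s)))
    }
    lam <- rep(c(0.5 + 0.5 * s, rep(0.5, s - 1L)), times = nf)
    out[seq_along(rows) + row0, ] <- Z
    lambda[seq_along(rows) + row0] <- lam
    row0 <- row0 + length(rows)
  }
  list(Z = out, lambda = lambda, n = nrow(Y),
       n_families = length(sizes), sizes = sizes)
}

# Profile log-likelihood of h2 for one trait: beta and total variance are
# maximised in closed form given h2.
uni_profile_ll <- function(h2, zy, zX, lambda) {
  v <- h2 * (lambda - 1) + 1
  w <- 1 / v
  A <- crossprod(zX, zX * w)
  b <- crossprod(zX, zy * w)
  beta <- solve(A, b)
  r <- zy - zX %*% beta
  n <- length(zy)
  s2 <- sum(w * r^2) / n
  ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(v)) + n)
  list(ll = ll, beta = beta, s2 = s2, A = A)
}

build_vc_inputs <- function(data, traits, covariates, family) {
  if (!family %in% names(data)) {
    abort(sprintf("column `%s` not found in `data`.", family))
  }
  missing_cols <- setdiff(c(traits, covariates), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  keep <- stats::complete.cases(data[, c(traits, covariates), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  X <- if (length(covariates) == 0) {
    matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    model.matrix(stats::reformulate(covariates), data = data)
  }
  if (nrow(X) != nrow(data)) {
    abort("covariates contain missing values after filtering; this is a bug.")
  }
  if (qr(X)$rank < ncol(X)) abort("covariate design matrix is rank-deficient.")
  list(data = data, X = X)
}

#' Univariate heritability by maximum-likelihood variance components
#'
#' Estimates the narrow-sense heritability of a trait from full-sibling
#' families, with covariates entering the mean model simultaneously with the
#' variance estimation. Returns the ML estimate of h2, its standard error
#' from the curvature of the profile log-likelihood, an asymptotic normal
#' confidence interval (see [h2_confidence_interval()]), and a
#' likelihood-ratio test of `h2 = 0` using the boundary 1/2:1/2 mixture of
#' chi-square(0) and chi-square(1).
#'
#' Singleton families are retained: they carry no kinship signal but inform
#' the covariate effects and the total variance.
#'
#' @param data A data frame with one row per individual.
#' @param trait Name of the trait column (approximately continuous).
#' @param covariates Character vector of covariate column names (default age
#'   and sex); may be empty.
#' @param family Name of the family-identifier column.
#' @param alpha Level for the confidence interval.
#'
#' @return An object of class `h2_fit` with elements `h2`, `se`, `ci`,
#'   `p_value`, `loglik`, `loglik_null`, `sigma2_total`, `sigma2_a`,
#'   `sigma2_e`, `covariate_effects` (tibble), `n_individuals`,
#'   `n_families`, `trait`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_families = 300), seed = 1)
#' fit <- univariate_h2(cohort, "latent_inh")
#' fit$h2
#' @export
univariate_h2 <- function(data, trait, covariates = c("age", "sex"),
                          family = "family_id", alpha = 0.05) {
  inp <- build_vc_inputs(data, trait, covariates, family)
  y <- inp$data[[trait]]
  tr <- vc_transform(cbind(y, inp$X), inp$data[[family]])
  if (all(tr$sizes == 1L)) {
    abort("all families are singletons: h2 is unidentifiable.")
  }
  zy <- tr$Z[, 1]
  zX <- tr$Z[, -1, drop = FALSE]
  lambda <- tr$lambda
  ll_fun <- function(h2) uni_profile_ll(h2, zy, zX, lambda)$ll

  opt <- optimize(ll_fun, interval = c(0, 1), maximum = TRUE, tol = 1e-9)
  cand <- c(opt$maximum, 0, 1)
  lls <- vapply(cand, ll_fun, numeric(1))
  h2_hat <- cand[which.max(lls)]
  ll_hat <- max(lls)
  ll0 <- ll_fun(0)

  at_hat <- uni_profile_ll(h2_hat, zy, zX, lambda)
  s2 <- at_hat$s2

  # SE from profile-likelihood curvature (observed information)
  h <- 1e-3
  se <- NA_real_
  if (h2_hat > 2 * h && h2_hat < 1 - 2 * h) {
    d2 <- (ll_fun(h2_hat + h) - 2 * ll_hat + ll_fun(h2_hat - h)) / h^2
    if (is.finite(d2) && d2 < 0) se <- sqrt(-1 / d2)
  }

  lrt <- max(0, 2 * (ll_hat - ll0))
  p <- if (lrt <= 1e-12) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)

  beta <- drop(at_hat$beta)
  beta_vcov <- solve(at_hat$A) * s2
  cov_tbl <- tibble(
    term = colnames(inp$X),
    estimate = beta,
    std_error = sqrt(diag(beta_vcov))
  )

  structure(
    list(
      h2 = h2_hat, se = se,
      ci = if (is.na(se)) c(NA_real_, NA_real_) else
        h2_confidence_interval(h2_hat, se, alpha),
      p_value = p, loglik = ll_hat, loglik_null = ll0,
      sigma2_total = s2, sigma2_a = h2_hat * s2,
      sigma2_e = (1 - h2_hat) * s2,
      covariate_effects = cov_tbl,
      n_individuals = tr$n, n_families = tr$n_families,
      trait = trait, covariates = covariates, alpha = alpha
    ),
    class = "h2_fit"
  )
}

#' Asymptotic confidence interval for a heritability estimate
#'
#' The symmetric normal interval `h2 +/- z(alpha/2) * SE`, clamped to
#' \[0, 1\] since heritability is a proportion.
#'
#' @param h2 Point estimate.
#' @param se Positive standard error.
#' @param alpha Level (default 0.05 for a 95% interval).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' h2_confidence_interval(0.31, 0.03) # 0.2512 0.3688
#' @export
h2_confidence_interval <- function(h2, se, alpha = 0.05) {
  if (!is.numeric(se) || se <= 0) abort("`se` must be positive.")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1.")
  }
  z <- qnorm(1 - alpha / 2)
  c(max(0, h2 - z * se), min(1, h2 + z * se))
}

#' Phenotypic correlation implied by the bivariate decomposition
#'
#' The phenotypic correlation between two traits decomposes into genetic and
#' environmental parts:
#' `RhoP = Rhog * sqrt(h1^2) * sqrt(h2^2) + Rhoe * sqrt(1 - h1^2) * sqrt(1 - h2^2)`.
#'
#' @param h2_1,h2_2 Heritabilities of the two traits, in \[0, 1\].
#' @param rhog Genetic correlation, in \[-1, 1\].
#' @param rhoe Environmental correlation, in \[-1, 1\].
#' @return The implied phenotypic correlation.
#' @examples
#' decompose_rhop(0.31, 0.28, 0.42, 0.10)
#' @export
decompose_rhop <- function(h2_1, h2_2, rhog, rhoe) {
  stopifnot(h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1,
            abs(rhog) <= 1, abs(rhoe) <= 1)
  rhog * sqrt(h2_1) * sqrt(h2_2) + rhoe * sqrt(1 - h2_1) * sqrt(1 - h2_2)
}

# Negative log-likelihood of the bivariate model at
# par = (h2_1, h2_2, log sigmaP1^2, log sigmaP2^2, rhog, rhoe),
# with the two mean vectors profiled out by GLS. `groups` holds per-distinct-
# eigenvalue sufficient statistics.
biv_nll <- function(par, groups, p) {
  # finite-difference probes (optimHess) may step just outside the box
  h2 <- pmin(pmax(par[1:2], 0), 1)
  sp2 <- exp(par[3:4])
  rg <- min(max(par[5], -1), 1)
  re <- min(max(par[6], -1), 1)
  sa <- sqrt(h2 * sp2); se_ <- sqrt((1 - h2) * sp2)
  G <- matrix(c(sa[1]^2, rg * sa[1] * sa[2], rg * sa[1] * sa[2], sa[2]^2), 2)
  E <- matrix(c(se_[1]^2, re * se_[1] * se_[2], re * se_[1] * se_[2],
                se_[2]^2), 2)
  Ws <- vector("list", length(groups))
  lds <- numeric(length(groups))
  A <- matrix(0, 2 * p, 2 * p)
  b <- numeric(2 * p)
  i1 <- seq_len(p); i2 <- p + i1
  for (g in seq_along(groups)) {
    gr <- groups[[g]]
    M <- gr$lambda * G + E
    dt <- M[1, 1] * M[2, 2] - M[1, 2]^2
    if (!is.finite(dt) || dt <= 1e-300 || M[1, 1] <= 0 || M[2, 2] <= 0) {
      return(1e10)
    }
    W <- matrix(c(M[2, 2], -M[1, 2], -M[1, 2], M[1, 1]), 2) / dt
    Ws[[g]] <- W
    lds[g] <- log(dt)
    A[i1, i1] <- A[i1, i1] + W[1, 1] * gr$CXX
    A[i1, i2] <- A[i1, i2] + W[1, 2] * gr$CXX
    A[i2, i1] <- A[i2, i1] + W[2, 1] * gr$CXX
    A[i2, i2] <- A[i2, i2] + W[2, 2] * gr$CXX
    b[i1] <- b[i1] + W[1, 1] * gr$CXY[, 1] + W[1, 2] * gr$CXY[, 2]
    b[i2] <- b[i2] + W[2, 1] * gr$CXY[, 1] + W[2, 2] * gr$CXY[, 2]
  }
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(1e10)
  B <- cbind(beta[i1], beta[i2])
  nll <- 0
  for (g in seq_along(groups)) {
    gr <- groups[[g]]
    Sr <- gr$CYY - crossprod(B, gr$CXY) - crossprod(gr$CXY, B) +
      crossprod(B, gr$CXX %*% B)
    nll <- nll + 0.5 * (gr$m * (2 * log(2 * pi) + lds[g]) +
                          sum(Ws[[g]] * Sr))
  }
  if (!is.finite(nll)) return(1e10)
  nll
}

#' Bivariate variance components: genetic and environmental correlations
#'
#' Fits the bivariate sibling model by maximum likelihood: within a person
#' the cross-trait covariance is `rhog * sigmaA1 * sigmaA2 +
#' rhoe * sigmaE1 * sigmaE2`, between sibs it is `0.5 * rhog * sigmaA1 *
#' sigmaA2`. Estimates per-trait heritabilities jointly with the genetic
#' (`rhog`) and environmental (`rhoe`) correlations, tests `rhog = 0` by
#' likelihood ratio, and reports the decomposition-implied phenotypic
#' correlation.
#'
#' @inheritParams univariate_h2
#' @param trait1,trait2 Trait column names (measured on the same
#'   individuals; rows with either missing are dropped).
#' @param n_starts Number of optimiser starts (multi-start guards against
#'   local optima).
#'
#' @return An object of class `rhog_fit` with elements `h2_1`, `h2_2`,
#'   `rhog`, `rhog_se`, `rhoe`, `rhop`, `p_rhog_zero`, `loglik`,
#'   `boundary` (logical: `rhog` at +/-1), `identifiable` (FALSE when a
#'   trait's h2 collapses to 0, leaving `rhog` unidentified), sample sizes.
#' @export
bivariate_fit <- function(data, trait1, trait2,
                          covariates = c("age", "sex"),
                          family = "family_id", n_starts = 3) {
  inp <- build_vc_inputs(data, c(trait1, trait2), covariates, family)
  Y <- cbind(inp$data[[trait1]], inp$data[[trait2]])
  tr <- vc_transform(cbind(Y, inp$X), inp$data[[family]])
  if (all(tr$sizes == 1L)) {
    abort("all families are singletons: variance components are unidentifiable.")
  }
  zY <- tr$Z[, 1:2, drop = FALSE]
  zX <- tr$Z[, -(1:2), drop = FALSE]
  p <- ncol(zX)
  lambda <- tr$lambda

  groups <- lapply(sort(unique(lambda)), function(l) {
    sel <- lambda == l
    list(
      lambda = l, m = sum(sel),
      CXX = crossprod(zX[sel, , drop = FALSE]),
      CXY = crossprod(zX[sel, , drop = FALSE], zY[sel, , drop = FALSE]),
      CYY = crossprod(zY[sel, , drop = FALSE])
    )
  })

  # Starting values: univariate fits and the OLS-residual correlation
  u1 <- univariate_h2(inp$data, trait1, covariates, family)
  u2 <- univariate_h2(inp$data, trait2, covariates, family)
  r1 <- stats::lm.fit(inp$X, Y[, 1])$residuals
  r2 <- stats::lm.fit(inp$X, Y[, 2])$residuals
  r_emp <- stats::cor(r1, r2)
  base <- c(min(max(u1$h2, 0.02), 0.98), min(max(u2$h2, 0.02), 0.98),
            log(u1$sigma2_total), log(u2$sigma2_total))
  starts <- list(
    c(base, r_emp, r_emp),
    c(base, 0.9 * sign(r_emp + 1e-12), 0),
    c(base, 0, r_emp)
  )[seq_len(max(1, n_starts))]

  obj <- function(par) biv_nll(par, groups, p)
  lower <- c(0, 0, -30, -30, -1, -1)
  upper <- c(1, 1, 30, 30, 1, 1)
  fits <- lapply(starts, function(st) {
    tryCatch(
      optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) list(value = Inf)
    )
  })
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  if (!is.finite(best$value)) abort("bivariate likelihood optimisation failed.")
  par <- best$par
  ll_hat <- -best$value

  h2_1 <- par[1]; h2_2 <- par[2]; rhog <- par[5]; rhoe <- par[6]
  identifiable <- h2_1 > 1e-4 && h2_2 > 1e-4
  boundary <- abs(abs(rhog) - 1) < 1e-6

  # LRT for rhog = 0 (rhog interior to [-1, 1]: plain 1-df chi-square)
  obj0 <- function(par5) obj(c(par5[1:4], 0, par5[5]))
  fit0 <- optim(c(par[1:4], par[6]), obj0, method = "L-BFGS-B",
                lower = lower[-5], upper = upper[-5],
                control = list(maxit = 500))
  lrt <- max(0, 2 * (ll_hat - (-fit0$value)))
  p_rhog <- pchisq(lrt, df = 1, lower.tail = FALSE)

  rhog_se <- NA_real_
  if (identifiable && !boundary) {
    H <- tryCatch(optimHess(par, obj), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && is.finite(V[5, 5]) && V[5, 5] > 0) {
        rhog_se <- sqrt(V[5, 5])
      }
    }
  }

  structure(
    list(
      h2_1 = h2_1, h2_2 = h2_2,
      rhog = if (identifiable) rhog else NA_real_,
      rhog_se = rhog_se, rhoe = rhoe,
      rhop = if (identifiable) decompose_rhop(h2_1, h2_2, rhog, rhoe)
             else NA_real_,
      p_rhog_zero = if (identifiable) p_rhog else NA_real_,
      loglik = ll_hat, boundary = boundary, identifiable = identifiable,
      n_individuals = tr$n, n_families = tr$n_families,
      trait1 = trait1, trait2 = trait2, covariates = covariates
    ),
    class = "rhog_fit"
  )
}

#' @export
print.h2_fit <- function(x, ...) {
  cat(sprintf(
    "Heritability of %s: h2 = %.3f (SE %.3f), 95%% CI [%.3f, %.3f], p = %.3g\n",
    x$trait, x$h2, x$se, x$ci[1], x$ci[2], x$p_value
  ))
  cat(sprintf("  %d individuals in %d families; covariates: %s\n",
              x$n_individuals, x$n_families,
              if (length(x$covariates)) paste(x$covariates, collapse = ", ")
              else "none"))
  invisible(x)
}

#' @export
print.rhog_fit <- function(x, ...) {
  cat(sprintf(
    "Bivariate variance components for %s and %s\n", x$trait1, x$trait2
  ))
  cat(sprintf("  h2: %.3f / %.3f\n", x$h2_1, x$h2_2))
  if (!x$identifiable) {
    cat("  rhog unidentifiable (a heritability is at the 0 boundary)\n")
  } else {
    cat(sprintf("  rhog = %.3f (SE %s)%s, p[rhog = 0] = %.3g\n",
                x$rhog,
                if (is.na(x$rhog_se)) "NA" else sprintf("%.3f", x$rhog_se),
                if (x$boundary) " [boundary]" else "", x$p_rhog_zero))
    cat(sprintf("  rhoe = %.3f, implied rhop = %.3f\n", x$rhoe, x$rhop))
  }
  invisible(x)
}

#' @rdname univariate_h2
#' @param x An `h2_fit` object.
#' @param ... Unused.
#' @export
tidy.h2_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = "h2", estimate = x$h2, std_error = x$se,
           p_value = x$p_value),
    x$covariate_effects |> dplyr::mutate(p_value = NA_real_)
  )
}

#' @rdname univariate_h2
#' @export
glance.h2_fit <- function(x, ...) {
  tibble(
    trait = x$trait, h2 = x$h2, se = x$se,
    ci_low = x$ci[1], ci_high = x$ci[2], p_value = x$p_value,
    sigma2_a = x$sigma2_a, sigma2_e = x$sigma2_e,
    logLik = x$loglik, n_individuals = x$n_individuals,
    n_families = x$n_families
  )
}

#' @rdname bivariate_fit
#' @param x An `rhog_fit` object.
#' @param ... Unused.
#' @export
tidy.rhog_fit <- function(x, ...) {
  tibble(
    term = c("h2_1", "h2_2", "rhog", "rhoe", "rhop"),
    estimate = c(x$h2_1, x$h2_2, x$rhog, x$rhoe, x$rhop),
    std_error = c(NA, NA, x$rhog_se, NA, NA),
    p_value = c(NA, NA, x$p_rhog_zero, NA, NA)
  )
}

#' @rdname bivariate_fit
#' @export
glance.rhog_fit <- function(x, ...) {
  tibble(
    trait1 = x$trait1, trait2 = x$trait2,
    h2_1 = x$h2_1, h2_2 = x$h2_2, rhog = x$rhog, rhog_se = x$rhog_se,
    rhoe = x$rhoe, rhop = x$rhop, p_rhog_zero = x$p_rhog_zero,
    boundary = x$boundary, identifiable = x$identifiable,
    logLik = x$loglik, n_individuals = x$n_individuals,
    n_families = x$n_families
  )
}
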