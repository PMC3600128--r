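#' Reverse a raw SWAN total score
#'
#' Raw SWAN totals run from +54 (all strengths) to -54 (all weaknesses); for
#' analysis they are reversed so that higher scores mean higher ADHD traits.
#'
#' @param raw_total Raw total score(s) in \[-54, 54\].
#' @return `-raw_total`.
#' @examples
#' reverse_swan(-54) # +54, the most severe trait score
#' @export
reverse_swan <- function(raw_total) {
  if (any(abs(raw_total) > 54, na.rm = TRUE)) {
    abort("`raw_total` must lie in [-54, 54].")
  }
  -raw_total
}

#' Fit a family mixed model of a log stop-task outcome on ADHD traits
#'
#' Regresses the natural log of an SST outcome (SSRT, GoRT or GoRTSD) on
#' demographic and trait terms with a family random intercept, selecting
#' fixed effects by forward stepwise entry: main effects (trait, age, sex)
#' enter in order of likelihood-ratio p-value while below `entry_alpha`;
#' higher-order terms (`age^2`, `age:sex`, `age^2:sex`) are then assessed,
#' each only when its constituent main effects were selected. The log
#' transform normalises the positively skewed residuals of raw reaction-time
#' outcomes. Models of GoRTSD control for log GoRT by default, because
#' latency and variability are highly correlated.
#'
#' @param cohort A data frame with the response column, a `family_id`
#'   column, `age`, `sex`, and the trait column.
#' @param response One of `"ssrt"`, `"gort_mean"`, `"gort_sd"` (or any
#'   positive numeric column).
#' @param trait Name of the (reversed) ADHD trait column; default
#'   `"swan_total"`.
#' @param entry_alpha Significance level for stepwise entry (default 0.05).
#' @param control_gort Add log `gort_mean` as a covariate; defaults to TRUE
#'   for the `gort_sd` response and FALSE otherwise.
#' @param higher_order Assess the higher-order terms after the main effects?
#'
#' @return An object of class `sst_trait_fit`: the final REML `lmer` fit
#'   plus the selected terms, variance components and covariate ranges.
#'   Methods: [tidy()], [glance()], [predict_grid()], [autoplot()].
#' @export
fit_trait_model <- function(cohort, response = c("ssrt", "gort_mean",
                                                 "gort_sd"),
                            trait = "swan_total", entry_alpha = 0.05,
                            control_gort = NULL, higher_order = TRUE) {
  response <- if (is.character(response)) response[1] else response
  needed <- c(response, trait, "age", "sex", "family_id")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  if (is.null(control_gort)) control_gort <- identical(response, "gort_sd")
  if (control_gort && !"gort_mean" %in% names(cohort)) {
    abort("`control_gort = TRUE` needs a `gort_mean` column.")
  }

  d <- cohort |>
    dplyr::filter(!is.na(.data[[response]]), .data[[response]] > 0,
                  !is.na(.data[[trait]]), !is.na(.data$age),
                  !is.na(.data$sex))
  d$..y <- log(d[[response]])
  d$..trait <- d[[trait]]
  d$sex <- as.factor(d$sex)
  if (control_gort) {
    d <- dplyr::filter(d, !is.na(.data$gort_mean), .data$gort_mean > 0)
    d$..log_gort <- log(d$gort_mean)
  }

  base_terms <- if (control_gort) "..log_gort" else character(0)
  mains <- c("..trait", "age", "sex")
  fit_ml <- function(terms) {
    rhs <- paste(c("1", terms, "(1 | family_id)"), collapse = " + ")
    suppressMessages(lme4::lmer(
      as.formula(paste("..y ~", rhs)), data = d, REML = FALSE,
      control = lme4::lmerControl(check.conv.singular = "ignore")
    ))
  }

  selected <- base_terms
  current <- fit_ml(selected)
  step_in <- function(candidates, selected, current) {
    repeat {
      if (length(candidates) == 0) break
      ps <- vapply(candidates, function(tm) {
        p <- tryCatch({
          m1 <- fit_ml(c(selected, tm))
          anova(current, m1)$`Pr(>Chisq)`[2]
        }, error = function(e) NA_real_)
        if (is.na(p)) Inf else p
      }, numeric(1))
      best <- which.min(ps)
      if (ps[best] >= entry_alpha) break
      selected <- c(selected, candidates[best])
      current <- fit_ml(selected)
      candidates <- candidates[-best]
    }
    list(selected = selected, fit = current)
  }
  st <- step_in(mains, selected, current)
  selected <- st$selected; current <- st$fit

  if (higher_order) {
    ho <- character(0)
    if ("age" %in% selected) ho <- c(ho, "I(age^2)")
    if (all(c("age", "sex") %in% selected)) {
      ho <- c(ho, "age:sex", "I(age^2):sex")
    }
    if (length(ho) > 0) {
      st <- step_in(ho, selected, current)
      selected <- st$selected; current <- st$fit
    }
  }

  rhs <- paste(c("1", selected, "(1 | family_id)"), collapse = " + ")
  final <- suppressMessages(lmerTest::lmer(
    as.formula(paste("..y ~", rhs)), data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  fe <- lme4::fixef(final)
  X <- lme4::getME(final, "X")
  if (qr(X)$rank < ncol(X)) {
    abort(paste0("collinear fixed-effect terms: ",
                 paste(colnames(X), collapse = ", ")))
  }
  vc <- lme4::VarCorr(final)
  structure(
    list(
      response = response, trait = trait, terms = selected,
      formula = paste("log(", response, ") ~", rhs),
      fit = final, entry_alpha = entry_alpha,
      control_gort = control_gort,
      family_variance = as.numeric(vc$family_id[1]),
      residual_variance = sigma(final)^2,
      ranges = list(age = range(d$age), trait = range(d$..trait)),
      sex_levels = levels(d$sex),
      mean_log_gort = if (control_gort) mean(d$..log_gort) else NULL,
      n = nrow(d), n_families = dplyr::n_distinct(d$family_id)
    ),
    class = "sst_trait_fit"
  )
}

#' @export
print.sst_trait_fit <- function(x, ...) {
  cat("Family mixed model of", x$response, "(log scale)\n")
  cat("  formula:", x$formula, "\n")
  cat(sprintf("  n = %d in %d families; family var %.4f, residual var %.4f\n",
              x$n, x$n_families, x$family_variance, x$residual_variance))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @rdname fit_trait_model
#' @param x An `sst_trait_fit` object.
#' @param ... Unused.
#' @export
tidy.sst_trait_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(
    term = sub("^\\.\\.trait$", x$trait, rownames(co)),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p_value = co[, "Pr(>|t|)"]
  )
}

#' @rdname fit_trait_model
#' @export
glance.sst_trait_fit <- function(x, ...) {
  tibble(
    response = x$response, scale = "log",
    n = x$n, n_families = x$n_families,
    family_variance = x$family_variance,
    residual_variance = x$residual_variance,
    icc = x$family_variance / (x$family_variance + x$residual_variance),
    logLik = as.numeric(logLik(x$fit)),
    AIC = stats::AIC(x$fit)
  )
}

#' Predicted-value grid from a trait model
#'
#' Evaluates the fitted model at a grid of age, sex and trait values with
#' the family random effect at zero, back-transforming by exponentiation
#' (the predicted median on the original ms scale). The 95% interval comes
#' from the linear-predictor standard error; `pred_sd` is the SD of a single
#' new observation implied by the model (linear-predictor variance plus
#' family and residual variance, mapped through the log-normal).
#'
#' @param fit An [fit_trait_model()] object.
#' @param ages,traits Numeric grid values (defaults: the age extremes 6 and
#'   18, trait extremes -54 and +54).
#' @param sexes Sex levels (default: both levels from the fit).
#'
#' @return A tibble of class `sst_prediction_grid`: `measure`, `sex`, `age`,
#'   `trait`, `predicted`, `ci_low`, `ci_high`, `pred_sd` (all ms).
#' @export
predict_grid <- function(fit, ages = c(6, 18), sexes = NULL,
                         traits = c(-54, 54)) {
  if (!inherits(fit, "sst_trait_fit")) abort("`fit` must be an sst_trait_fit.")
  sexes <- sexes %||% fit$sex_levels
  grid <- tidyr::expand_grid(sex = factor(sexes, levels = fit$sex_levels),
                             age = ages, trait = traits)
  if (any(ages < fit$ranges$age[1] | ages > fit$ranges$age[2]) ||
      any(traits < fit$ranges$trait[1] | traits > fit$ranges$trait[2])) {
    warn("grid extends beyond the fitted covariate range; extrapolating.")
  }
  nd <- grid |> dplyr::mutate(..trait = .data$trait)
  if (fit$control_gort) nd$..log_gort <- fit$mean_log_gort
  Terms <- stats::delete.response(stats::terms(
    lme4::nobars(stats::formula(fit$fit))
  ))
  X <- model.matrix(Terms, data = nd)
  beta <- lme4::fixef(fit$fit)
  V <- as.matrix(vcov(fit$fit))
  eta <- unname(drop(X %*% beta))
  se_lin <- unname(sqrt(rowSums((X %*% V) * X)))
  s2_obs <- se_lin^2 + fit$family_variance + fit$residual_variance
  z <- qnorm(0.975)
  out <- grid |>
    dplyr::mutate(
      measure = fit$response,
      predicted = exp(eta),
      ci_low = exp(eta - z * se_lin),
      ci_high = exp(eta + z * se_lin),
      pred_sd = exp(eta + s2_obs / 2) * sqrt(exp(s2_obs) - 1),
      .before = 1
    ) |>
    dplyr::relocate("measure", "sex", "age", "trait")
  class(out) <- c("sst_prediction_grid", class(out))
  out
}

#' Approximate Cohen's effect size between two predicted cells
#'
#' Standardises the difference between two model-predicted values by the
#' single-observation SDs of the cells. The default `"pooled"` mode divides
#' by `sqrt((sd1^2 + sd2^2) / 2)`, the usual pooled Cohen's d denominator
#' for equal-weight cells. The `"printed"` mode divides by
#' `sqrt(|sd1^2 - sd2^2|)` — a denominator that appears in some reports but
#' degenerates when the two cells have similar dispersion; it is retained
#' for fidelity and errors out in that degenerate case.
#'
#' @param pred1,pred2 Predicted values (ms).
#' @param sd1,sd2 Positive single-observation SDs (ms).
#' @param mode `"pooled"` (default) or `"printed"`.
#' @return The standardised effect size.
#' @examples
#' effect_size(536, 398, 93.24, 93.24) # ~1.48
#' @export
effect_size <- function(pred1, pred2, sd1, sd2,
                        mode = c("pooled", "printed")) {
  mode <- match.arg(mode)
  if (any(c(sd1, sd2) <= 0)) abort("SDs must be positive.")
  denom2 <- switch(mode,
    pooled = (sd1^2 + sd2^2) / 2,
    printed = abs(sd1^2 - sd2^2)
  )
  if (mode == "printed" && denom2 <= .Machine$double.eps) {
    abort("printed-mode denominator is zero (sd1 == sd2); use mode = \"pooled\".")
  }
  (pred1 - pred2) / sqrt(denom2)
}

#' Difference between two cells of a prediction grid
#'
#' Selects two cells of a prediction grid by named values (e.g.
#' `list(measure = "ssrt", sex = "female", age = 6, trait = 54)`) and
#' returns `predicted(a) - predicted(b)`.
#'
#' @param grid A prediction grid (from [predict_grid()] or
#'   [sst_reference_grid()]).
#' @param cell_a,cell_b Named lists selecting exactly one row each.
#' @param digits Optional rounding of the difference.
#' @return The difference in ms.
#' @examples
#' g <- sst_reference_grid()
#' cell_difference(g,
#'   list(measure = "ssrt", sex = "female", age = 6, trait = 54),
#'   list(measure = "ssrt", sex = "female", age = 6, trait = -54))
#' @export
cell_difference <- function(grid, cell_a, cell_b, digits = NULL) {
  pick <- function(cell) {
    sel <- rep(TRUE, nrow(grid))
    for (nm in names(cell)) {
      if (!nm %in% names(grid)) abort(sprintf("no grid column `%s`.", nm))
      sel <- sel & (as.character(grid[[nm]]) == as.character(cell[[nm]]))
    }
    if (sum(sel) != 1) {
      abort(sprintf("selector matches %d cells; it must match exactly 1.",
                    sum(sel)))
    }
    grid$predicted[sel]
  }
  d <- pick(cell_a) - pick(cell_b)
  if (!is.null(digits)) d <- round(d, digits)
  d
}

#' Reference grid of predicted stop-task values
#'
#' Predicted SSRT, GoRT and GoRTSD (with 95% confidence intervals) by sex,
#' ADHD trait extremes (-54, +54) and age extremes (6, 18), as reported for
#' a large community sample of children and adolescents. Useful as a worked
#' example for [cell_difference()] and as the calibration target of the
#' synthetic generator.
#'
#' @return A tibble of class `sst_prediction_grid` with columns `measure`
#'   (`ssrt`, `gort`, `gortsd`), `sex`, `age`, `trait`, `predicted`,
#'   `ci_low`, `ci_high`.
#' @export
sst_reference_grid <- function() {
  path <- system.file("extdata", "stop_task_reference_grid.csv",
                      package = "stoprace", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           measure = "c", sex = "c", age = "d",
                           trait = "d", predicted = "d",
                           ci_low = "d", ci_high = "d"
                         ))
  class(out) <- c("sst_prediction_grid", class(out))
  out
}
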