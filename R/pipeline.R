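#' Run the full generate - simulate - score - model - heritability pipeline
#'
#' Orchestrates the whole analysis on a synthetic family cohort: generate
#' the cohort, simulate stop-signal sessions, score and filter them, compare
#' included and excluded participants, fit the log-scale trait models with
#' prediction grids, and estimate univariate heritabilities plus pairwise
#' genetic correlations on the sibling subset. Every stage derives its own
#' seed from the master seed, so identical `(spec, seed)` reproduce the run
#' exactly.
#'
#' Medicated participants are excluded from the primary analyses (the
#' default); `medication = "adjust"` instead retains them with SSRT
#' lengthened by `spec$medication_effect` times the SD of SSRT among
#' unmedicated valid participants, as a sensitivity path.
#'
#' @param spec A [cohort_spec()].
#' @param rule A [validity_rule()].
#' @param seed Master integer seed.
#' @param stages Subset of `c("model", "heritability")` to run after
#'   simulation and scoring (both by default).
#' @param strict Use the strict inhibition band when filtering?
#' @param medication `"exclude"` (default) or `"adjust"`.
#' @param heritability_traits Columns to estimate h2 for.
#' @param rhog_pairs List of character pairs for bivariate fits; defaults to
#'   all pairs of `heritability_traits`.
#' @param covariates Covariates for the variance-component fits.
#'
#' @return An object of class `sst_run_report`: a list with `cohort`,
#'   `summaries` (scored + filtered, joined to the cohort), `exclusions`
#'   (tally), `group_comparison`, `trait_fits`, `grids`, `h2_table`,
#'   `rhog_table`, and `provenance`.
#' @examples
#' \donttest{
#' report <- run_pipeline(cohort_spec(n_families = 200), seed = 1)
#' report$h2_table
#' }
#' @export
run_pipeline <- function(spec = cohort_spec(), rule = validity_rule(),
                         seed = NULL,
                         stages = c("model", "heritability"),
                         strict = FALSE,
                         medication = c("exclude", "adjust"),
                         heritability_traits = c("swan_total", "ssrt",
                                                 "gort_mean", "gort_sd"),
                         rhog_pairs = NULL,
                         covariates = c("age", "sex")) {
  medication <- match.arg(medication)

  cohort <- generate_cohort(spec, seed = child_seed(seed, 11))
  trials <- simulate_sst(cohort, seed = child_seed(seed, 12))

  # interrupted sessions stop at a random point before the end
  if (any(cohort$interrupted)) {
    cut_at <- withr::with_seed(
      child_seed(seed, 13) %||% sample.int(1e6, 1),
      setNames(sample(20:90, sum(cohort$interrupted), replace = TRUE),
               cohort$participant_id[cohort$interrupted])
    )
    trials <- trials |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::mutate(..expidx = cumsum(.data$block > 0)) |>
      dplyr::ungroup() |>
      dplyr::filter(
        !(.data$participant_id %in% names(cut_at)) |
          .data$..expidx <= cut_at[.data$participant_id]
      ) |>
      dplyr::select(-"..expidx")
  }

  summaries <- score_sst(trials) |>
    apply_validity_filters(rule, strict = strict) |>
    dplyr::left_join(
      cohort |> dplyr::select(
        "participant_id", "family_id", "age", "sex",
        dplyr::any_of(c("swan_total", "swan_inattention",
                        "swan_hyperimpulsive", "medicated",
                        "performer_type", "latent_adhd"))
      ),
      by = "participant_id"
    )

  if (medication == "adjust") {
    ref_sd <- sd(summaries$ssrt[summaries$valid & !summaries$medicated],
                 na.rm = TRUE)
    summaries <- summaries |>
      dplyr::mutate(ssrt = adjust_for_medication(
        .data$ssrt, ref_sd, .data$medicated %in% TRUE,
        spec$medication_effect
      ))
    summaries$in_analysis <- summaries$valid
  } else {
    summaries$in_analysis <- summaries$valid & !summaries$medicated
  }

  exclusions <- exclusion_tally(summaries)
  group_comparison <- compare_groups(summaries)

  analysis <- dplyr::filter(summaries, .data$in_analysis)

  trait_fits <- list()
  grids <- list()
  if ("model" %in% stages) {
    for (resp in intersect(c("ssrt", "gort_mean", "gort_sd"),
                           names(analysis))) {
      fit <- fit_trait_model(analysis, response = resp)
      trait_fits[[resp]] <- fit
      grids[[resp]] <- predict_grid(fit)
    }
  }

  h2_table <- NULL
  rhog_table <- NULL
  if ("heritability" %in% stages) {
    h2_table <- purrr::map(
      intersect(heritability_traits, names(analysis)),
      function(tr) glance(univariate_h2(analysis, tr, covariates))
    ) |> purrr::list_rbind()
    if (is.null(rhog_pairs)) {
      trs <- intersect(heritability_traits, names(analysis))
      rhog_pairs <- utils::combn(trs, 2, simplify = FALSE)
    }
    rhog_table <- purrr::map(
      rhog_pairs,
      function(pr) glance(bivariate_fit(analysis, pr[1], pr[2], covariates))
    ) |> purrr::list_rbind()
  }

  structure(
    list(
      cohort = cohort, summaries = summaries, exclusions = exclusions,
      group_comparison = group_comparison,
      trait_fits = trait_fits, grids = grids,
      h2_table = h2_table, rhog_table = rhog_table,
      provenance = list(
        seed = seed, n_families = spec$n_families,
        n_individuals = nrow(cohort), strict = strict,
        medication = medication, timestamp = format(Sys.time()),
        package_version = as.character(utils::packageVersion("stoprace"))
      )
    ),
    class = "sst_run_report"
  )
}

#' Compare included and excluded participants
#'
#' Included-versus-excluded means (trait, age) with Welch t-tests and the
#' proportion of boys with a two-sample proportion test — the standard
#' sample-characteristics accounting that shows excluded cases tend to be
#' younger, more often male, and higher in ADHD traits.
#'
#' @param summaries Scored, filtered summaries joined to cohort covariates
#'   (needs `in_analysis` or `valid`, plus `swan_total`, `age`, `sex`).
#' @return A tibble: `variable`, `included_mean`, `excluded_mean`,
#'   `statistic`, `p_value`, and counts. Test columns are `NA` when no one
#'   was excluded.
#' @export
compare_groups <- function(summaries) {
  incl_col <- if ("in_analysis" %in% names(summaries)) "in_analysis" else "valid"
  inc <- summaries[[incl_col]]
  n_ex <- sum(!inc)
  row_for <- function(name, x) {
    if (n_ex == 0 || length(unique(x[!inc])) < 2) {
      return(tibble(variable = name, included_mean = mean(x[inc], na.rm = TRUE),
                    excluded_mean = if (n_ex) mean(x[!inc], na.rm = TRUE)
                                    else NA_real_,
                    statistic = NA_real_, p_value = NA_real_))
    }
    tt <- t.test(x[inc], x[!inc])
    tibble(variable = name, included_mean = mean(x[inc], na.rm = TRUE),
           excluded_mean = mean(x[!inc], na.rm = TRUE),
           statistic = unname(tt$statistic), p_value = tt$p.value)
  }
  male <- as.numeric(summaries$sex == "male")
  prop_row <- if (n_ex > 0) {
    pt <- suppressWarnings(prop.test(
      c(sum(male[inc], na.rm = TRUE), sum(male[!inc], na.rm = TRUE)),
      c(sum(inc), n_ex)
    ))
    tibble(variable = "prop_male", included_mean = pt$estimate[1],
           excluded_mean = pt$estimate[2],
           statistic = unname(pt$statistic), p_value = pt$p.value)
  } else {
    tibble(variable = "prop_male", included_mean = mean(male, na.rm = TRUE),
           excluded_mean = NA_real_, statistic = NA_real_,
           p_value = NA_real_)
  }
  dplyr::bind_rows(
    row_for("swan_total", summaries$swan_total),
    row_for("age", summaries$age),
    prop_row
  ) |>
    dplyr::mutate(n_included = sum(inc), n_excluded = n_ex)
}

#' @export
print.sst_run_report <- function(x, ...) {
  cat("Stop-signal task pipeline report\n")
  cat(sprintf("  cohort: %d children in %d families (seed %s)\n",
              x$provenance$n_individuals, x$provenance$n_families,
              x$provenance$seed %||% "none"))
  cat("\nExclusion accounting:\n")
  print(x$exclusions, n = Inf)
  cat("\nIncluded vs excluded:\n")
  print(x$group_comparison, n = Inf)
  if (!is.null(x$h2_table)) {
    cat("\nHeritability estimates:\n")
    print(dplyr::select(x$h2_table, "trait", "h2", "se", "ci_low",
                        "ci_high", "p_value"), n = Inf)
  }
  if (!is.null(x$rhog_table)) {
    cat("\nGenetic correlations:\n")
    print(dplyr::select(x$rhog_table, "trait1", "trait2", "rhog",
                        "rhog_se", "rhoe", "p_rhog_zero"), n = Inf)
  }
  invisible(x)
}
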