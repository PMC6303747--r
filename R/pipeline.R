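# End-to-end orchestration: simulate (or read) assay and trial tables,
# estimate correction factors, run per-female paternity estimation and
# exclusions, pool P2 by subgroup, fit the OLRE GLMM with post hoc marginal
# means, and bundle everything with provenance.

trial_mandatory_cols <- c("female_id", "generation", "mating_order",
                          "sterilization_order", "interval_h", "eggs_total",
                          "eggs_hatched_obs", "eggs_clear_obs")

#' Read a double-mating trials CSV
#'
#' Validates mandatory columns, enum levels and the count identity
#' `eggs_hatched_obs + eggs_clear_obs == eggs_total`. Unknown columns are
#' kept (with a warning) as covariates; missing values are empty fields.
#'
#' @param path CSV path.
#' @return validated trials data frame.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(trial_mandatory_cols, names(df))
  if (length(miss))
    stop("trials file missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  known <- c(trial_mandatory_cols, "true_P2", "true_m2_eggs",
             "true_brown_eggs")
  extra <- setdiff(names(df), known)
  covariate_like <- grepl("_mg$|_s$", extra)
  if (any(!covariate_like))
    warning("unrecognized column(s) kept as-is: ",
            paste(extra[!covariate_like], collapse = ", "), call. = FALSE)
  validate_trials(df)
  df
}

#' Read a fertility-assay CSV
#' @param path CSV path.
#' @return validated assay records.
#' @export
read_assays <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_assay_records(df)
  df
}

#' Write a table to CSV (round-trip stable)
#' @param df data frame.
#' @param path output path.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full paternity-analysis pipeline
#'
#' Either simulates an experiment from a [sim_config()] or reads trial and
#' assay CSVs, then runs: correction-factor estimation -> per-female
#' paternity -> exclusions -> pooled P2 by (interval x mating order) ->
#' OLRE binomial GLMM on the kept females -> marginal means with Tukey
#' contrasts. Deterministic given the seed.
#'
#' @param sim_cfg a [sim_config()] (simulation mode), or NULL.
#' @param trials,assays data frames or CSV paths (data mode; ignored when
#'   `sim_cfg` is given).
#' @param policy an [exclusion_policy()].
#' @param fixed_terms fixed effects for the GLMM.
#' @param shared_group optional shared random-intercept column.
#' @param n_nodes quadrature nodes.
#' @param seed integer seed (simulation mode).
#' @param outdir optional directory; when given, writes `assays.csv`,
#'   `trials.csv`, `factors.csv`, `paternity.csv`, `pooled_p2.csv`,
#'   `exclusions.csv` and `fit_summary.json` there.
#' @return a `report_bundle` list: `factors`, `paternity`, `kept`,
#'   `exclusion_log`, `pooled_p2`, `fit`, `posthoc`, `provenance`.
#' @export
run_pipeline <- function(sim_cfg = NULL, trials = NULL, assays = NULL,
                         policy = exclusion_policy(),
                         fixed_terms = c("mating_order", "interval_h"),
                         shared_group = NULL, n_nodes = 31L,
                         seed = 1L, outdir = NULL) {
  if (!is.null(sim_cfg)) {
    if (!is.null(trials) || !is.null(assays))
      stop("give either a sim_cfg or input tables, not both", call. = FALSE)
    sim <- simulate_experiment(sim_cfg, seed)
    trials <- sim$trials
    assays <- simulate_fertility_assays(sim_cfg, seed)
  } else {
    if (is.character(trials)) trials <- read_trials(trials)
    if (is.character(assays)) assays <- read_assays(assays)
    if (is.null(trials) || is.null(assays))
      stop("data mode needs both trials and assays", call. = FALSE)
    validate_trials(trials)
    validate_assay_records(assays)
  }

  factors <- estimate_correction_factors(assays)
  paternity <- estimate_trials(trials, factors, policy)
  excl <- apply_exclusions(paternity, policy)
  pooled <- pool_p2(excl$kept, keys = c("interval_h", "mating_order"))
  fit <- fit_olre_binomial_glmm(excl$kept, fixed_terms = fixed_terms,
                                shared_group = shared_group,
                                n_nodes = n_nodes)
  ph <- marginal_means(fit, intersect(fixed_terms, names(fit$xlevels))[1])

  bundle <- list(
    factors = factors, paternity = paternity, kept = excl$kept,
    exclusion_log = excl$log, pooled_p2 = pooled,
    fit = fit, posthoc = ph,
    provenance = list(
      seed = as.integer(seed),
      mode = if (is.null(sim_cfg)) "data" else "simulation",
      n_trials = nrow(trials), n_kept = nrow(excl$kept),
      package_version = as.character(utils::packageVersion("spermP2")))
  )
  class(bundle) <- "report_bundle"
  if (!is.null(outdir)) write_bundle(bundle, trials, assays, outdir)
  bundle
}

write_bundle <- function(bundle, trials, assays, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_table(assays, file.path(outdir, "assays.csv"))
  write_table(trials, file.path(outdir, "trials.csv"))
  write_table(as.data.frame(bundle$factors), file.path(outdir, "factors.csv"))
  write_table(bundle$paternity, file.path(outdir, "paternity.csv"))
  write_table(bundle$pooled_p2, file.path(outdir, "pooled_p2.csv"))
  write_table(bundle$exclusion_log, file.path(outdir, "exclusions.csv"))
  fit <- bundle$fit
  jsonlite::write_json(
    list(coef = as.list(fit$coef), se = as.list(fit$se),
         p_value = as.list(fit$p_value),
         sigma_olre = fit$sigma_olre, sigma_group = fit$sigma_group,
         loglik = fit$loglik, aic = fit$aic, n_obs = fit$n_obs,
         converged = fit$converged, provenance = bundle$provenance),
    file.path(outdir, "fit_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Sterile-male-technique paternity analysis (",
      x$provenance$mode, " mode, seed ", x$provenance$seed, ")\n", sep = "")
  cat(sprintf("  %d trials, %d kept, %d excluded\n",
              x$provenance$n_trials, x$provenance$n_kept,
              nrow(x$exclusion_log)))
  cat("\nPooled P2 by interval x mating order:\n")
  pp <- x$pooled_p2
  pp$P2_pooled <- round(pp$P2_pooled, 2)
  print(pp, row.names = FALSE)
  cat("\n")
  print(x$fit)
  invisible(x)
}

#' Example data: published assay and trial summary counts
#'
#' Small plain-text example tables shipped with the package, taken from a
#' published seed-beetle sterile-male double-mating study: the six-stratum
#' fertility-assay totals behind the correction factors, the pooled
#' second-male paternity totals per (interval x mating order) subgroup, and
#' the female remating counts per interval.
#'
#' @param which one of `"assays"`, `"pooled_counts"`, `"remating"`.
#' @return data frame.
#' @export
example_data <- function(which = c("assays", "pooled_counts", "remating")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("example_", which, ".csv"),
                      package = "spermP2", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
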