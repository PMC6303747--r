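# Synthetic double-mating experiment generator.
#
# Emulates a sterile-male-technique sperm-competition experiment: focal
# females are double mated in a balanced design (mating order MP/PM,
# sterilization order NR/RN, inter-mating interval 0/24/48 h), lay a batch of
# eggs after the second mating, and each egg's hatch outcome is governed by
# the sire-specific fertilities p (normal male) and z (sterile male) of the
# trial's stratum. A small fraction of hatched eggs are "brown" (hatched but
# showing only a brown larval head dot) and are mis-scored as clear, which is
# the scoring error the downstream brown-egg reallocation corrects.

#' Simulation configuration with known truth
#'
#' Builds the configuration object for the synthetic experiment generator.
#' Defaults reproduce the study conditions of a seed-beetle
#' (*Callosobruchus maculatus*) double-mating experiment: 64 focal females,
#' near-balanced mating and sterilization orders, intervals 0/24/48 h,
#' logit-scale treatment effects on true P2, and per-stratum fertility
#' correction factors.
#'
#' @param n_females number of double-mated focal females.
#' @param prop_PM probability a female is assigned the PM mating order
#'   (polyandrous-mother's son first).
#' @param prop_RN probability a female is assigned the RN sterilization order
#'   (sterile male first).
#' @param interval_probs length-3 probabilities (summing to 1) of the 0, 24
#'   and 48 h inter-mating intervals.
#' @param beta0,beta_PM,beta_24,beta_48 logit-scale intercept and effects of
#'   mating order PM and intervals 24/48 h on true P2.
#' @param sigma_olre SD of the per-trial logit deviation (the latent
#'   overdispersion the observation-level random effect absorbs).
#' @param sigma_gen SD of the shared generation intercept.
#' @param n_generations number of female generations.
#' @param p_cells,z_cells,brown_cells named numeric vectors over the six
#'   strata `"NR_0","NR_24","NR_48","RN_0","RN_24","RN_48"` giving true
#'   normal-male fertility p, sterile-male fertility z and the brown-egg
#'   proportion. Must satisfy `p > z` in every cell.
#' @param egg_mean,egg_dispersion mean and dispersion (negative-binomial
#'   `size`) of the per-female post-second-mating egg count, truncated at 1.
#' @param assay_eggs_per_cell eggs laid per sire type in each stratum of the
#'   fertility assays.
#' @param behavior_means data frame of behavioral-covariate distributions
#'   (columns `trait`, `role`, `treatment`, `mean`, `sd`); see
#'   [default_behavior_means()].
#' @param covariate_missing_rate fraction of behavioral covariate entries
#'   recorded as missing.
#' @param seed default integer seed (individual generator calls may override).
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_experiment()], [simulate_fertility_assays()]
#' @export
sim_config <- function(n_females = 64,
                       prop_PM = 29 / 64,
                       prop_RN = 33 / 64,
                       interval_probs = c(25, 23, 16) / 64,
                       beta0 = 0.09,
                       beta_PM = 0.47,
                       beta_24 = 0.82,
                       beta_48 = 0.51,
                       sigma_olre = 0.5,
                       sigma_gen = 0.2,
                       n_generations = 4,
                       p_cells = default_fertility_cells()$p,
                       z_cells = default_fertility_cells()$z,
                       brown_cells = default_fertility_cells()$brown,
                       egg_mean = 45,
                       egg_dispersion = 10,
                       assay_eggs_per_cell = 600,
                       behavior_means = default_behavior_means(),
                       covariate_missing_rate = 0.047,
                       seed = 1L) {
  cfg <- list(
    n_females = n_females, prop_PM = prop_PM, prop_RN = prop_RN,
    interval_probs = interval_probs,
    beta0 = beta0, beta_PM = beta_PM, beta_24 = beta_24, beta_48 = beta_48,
    sigma_olre = sigma_olre, sigma_gen = sigma_gen,
    n_generations = n_generations,
    p_cells = p_cells, z_cells = z_cells, brown_cells = brown_cells,
    egg_mean = egg_mean, egg_dispersion = egg_dispersion,
    assay_eggs_per_cell = assay_eggs_per_cell,
    behavior_means = behavior_means,
    covariate_missing_rate = covariate_missing_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, field, msg) {
    if (!all(ok)) stop("invalid sim_config field '", field, "': ", msg,
                       call. = FALSE)
  }
  chk(cfg$n_females >= 1, "n_females", "must be >= 1")
  chk(cfg$prop_PM >= 0 && cfg$prop_PM <= 1, "prop_PM", "must be in [0, 1]")
  chk(cfg$prop_RN >= 0 && cfg$prop_RN <= 1, "prop_RN", "must be in [0, 1]")
  chk(length(cfg$interval_probs) == 3 && all(cfg$interval_probs >= 0) &&
        abs(sum(cfg$interval_probs) - 1) < 1e-8,
      "interval_probs", "must be 3 non-negative values summing to 1")
  chk(cfg$sigma_olre >= 0, "sigma_olre", "must be >= 0")
  chk(cfg$sigma_gen >= 0, "sigma_gen", "must be >= 0")
  chk(cfg$n_generations >= 1, "n_generations", "must be >= 1")
  for (nm in c("p_cells", "z_cells", "brown_cells")) {
    chk(setequal(names(cfg[[nm]]), cell_keys()), nm,
        paste("must be named over", paste(cell_keys(), collapse = ", ")))
    chk(all(cfg[[nm]] >= 0 & cfg[[nm]] <= 1), nm, "must be in [0, 1]")
  }
  keys <- cell_keys()
  chk(all(cfg$p_cells[keys] > cfg$z_cells[keys]), "p_cells",
      "p must exceed z in every cell")
  chk(cfg$egg_mean > 0, "egg_mean", "must be > 0")
  chk(cfg$egg_dispersion > 0, "egg_dispersion", "must be > 0")
  chk(cfg$assay_eggs_per_cell >= 0, "assay_eggs_per_cell", "must be >= 0")
  chk(cfg$covariate_missing_rate >= 0 && cfg$covariate_missing_rate < 1,
      "covariate_missing_rate", "must be in [0, 1)")
  invisible(cfg)
}

cell_keys <- function() {
  paste(rep(c("NR", "RN"), each = 3), rep(c(0, 24, 48), 2), sep = "_")
}

cell_key <- function(order, interval_h) paste(order, interval_h, sep = "_")

#' Default per-stratum fertility parameters
#'
#' True fertilities used as generator defaults: normal-male fertility `p`,
#' residual sterile-male fertility `z` (incomplete sterilization) and the
#' brown-egg proportion, for each sterilization order x inter-mating interval
#' stratum. Values match published seed-beetle mating-assay estimates.
#'
#' @return list with named vectors `p`, `z`, `brown` over the six strata.
#' @export
default_fertility_cells <- function() {
  keys <- cell_keys()
  list(
    p = stats::setNames(c(0.988, 0.979, 0.976, 0.988, 0.988, 0.988), keys),
    z = stats::setNames(c(0.068, 0.064, 0.089, 0.068, 0.050, 0.031), keys),
    brown = stats::setNames(c(0.046, 0.042, 0.049, 0.046, 0.035, 0.028), keys)
  )
}

#' Default behavioral-covariate distributions
#'
#' Gaussian means/SDs per (mating role x maternal treatment) for ejaculate
#' size, copulation latency, kicking latency, kicking duration and copulation
#' duration, plus pre-mating male weight per treatment. Means and standard
#' errors are seeded from published values (SD recovered as SE * sqrt(33),
#' the approximate per-group sample size).
#'
#' @return data frame with columns `trait`, `role`, `treatment`, `mean`, `sd`.
#' @export
default_behavior_means <- function() {
  se_n <- sqrt(33)
  tab <- rbind(
    data.frame(trait = "ejaculate_mg", role = "first",
               treatment = c("M", "P"), mean = c(0.32, 0.37),
               se = c(0.02, 0.03)),
    data.frame(trait = "cop_latency_s", role = "first",
               treatment = c("M", "P"), mean = c(88.9, 97.2),
               se = c(15.3, 14.4)),
    data.frame(trait = "kick_latency_s", role = "first",
               treatment = c("M", "P"), mean = c(252.9, 307.1),
               se = c(11.8, 25.5)),
    data.frame(trait = "kick_duration_s", role = "first",
               treatment = c("M", "P"), mean = c(139.7, 166.3),
               se = c(23.3, 22.4)),
    data.frame(trait = "cop_duration_s", role = "first",
               treatment = c("M", "P"), mean = c(401.9, 473.4),
               se = c(23.7, 30.4)),
    data.frame(trait = "ejaculate_mg", role = "second",
               treatment = c("M", "P"), mean = c(0.31, 0.23),
               se = c(0.03, 0.02)),
    data.frame(trait = "cop_latency_s", role = "second",
               treatment = c("M", "P"), mean = c(232.0, 175.7),
               se = c(28.7, 22.3)),
    data.frame(trait = "kick_latency_s", role = "second",
               treatment = c("M", "P"), mean = c(251.7, 238.5),
               se = c(24.1, 22.0)),
    data.frame(trait = "kick_duration_s", role = "second",
               treatment = c("M", "P"), mean = c(174.4, 135.5),
               se = c(30.5, 20.3)),
    data.frame(trait = "cop_duration_s", role = "second",
               treatment = c("M", "P"), mean = c(435.1, 374.3),
               se = c(30.1, 25.0)),
    data.frame(trait = "weight_mg", role = "either",
               treatment = c("M", "P"), mean = c(3.66, 3.86),
               se = c(0.07, 0.08))
  )
  tab$sd <- tab$se * se_n
  tab$se <- NULL
  tab
}

# Deterministic per-stage sub-seed so assays and trials are independently
# reproducible from one global seed. Kept below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(trials = 101L, assays = 211L, behaviors = 307L)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[stage]]
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Inverse logit
#' @param x numeric vector on the logit scale.
#' @return probabilities.
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Expected hatch proportion after a double mating
#'
#' The mixture model of the sterile-male technique: a proportion `P_R` of
#' eggs are sired by the sterile male and hatch with probability `z`
#' (incomplete sterilization); the remainder are sired by the normal male and
#' hatch with probability `p`, so the expected hatch proportion is
#' `x = P_R * z + (1 - P_R) * p`.
#'
#' @param P_R proportion of eggs sired by the sterile male, in \[0, 1\].
#' @param p normal-male fertility, in (z, 1\].
#' @param z sterile-male fertility, in \[0, p).
#' @return expected hatch proportion x.
#' @seealso [invert_boorman_parker()] for the inverse.
#' @export
expected_hatch <- function(P_R, p, z) {
  if (any(p <= z)) stop("normal fertility p must exceed sterile fertility z",
                        call. = FALSE)
  if (any(P_R < 0 | P_R > 1)) stop("P_R must lie in [0, 1]", call. = FALSE)
  P_R * z + (1 - P_R) * p
}

#' Simulate a double-mating sperm-competition experiment
#'
#' Draws a full set of double-mating trials with latent truth. For each
#' female: design labels (mating order, sterilization order, interval) are
#' drawn per the configured balance; true P2 is the inverse logit of
#' `beta0 + beta_PM*[PM] + beta_24*[24h] + beta_48*[48h] + generation
#' intercept + per-trial deviation`; the post-second-mating egg count is
#' negative binomial truncated at 1; each egg is sired by the second male
#' with probability true P2; eggs hatch with the sire's stratum fertility (p
#' or z); each hatched egg is brown with the stratum's brown probability and
#' is then recorded as clear in the observed columns, mimicking the scoring
#' error of the real experiment. Behavioral covariates are independent
#' Gaussians with entries knocked out at the configured missing rate.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; defaults to `cfg$seed`. Identical `(cfg, seed)`
#'   give identical output.
#' @return list with `trials` (a data frame, one row per female, observed
#'   columns plus latent `true_P2`, `true_m2_eggs`, `true_brown_eggs`) and
#'   `truth` (the generating parameters echoed back).
#' @export
simulate_experiment <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  n <- cfg$n_females
  trials <- with_seed(derive_seed(seed, "trials"), {
    mating_order <- ifelse(stats::runif(n) < cfg$prop_PM, "PM", "MP")
    sterilization_order <- ifelse(stats::runif(n) < cfg$prop_RN, "RN", "NR")
    interval_h <- sample(c(0L, 24L, 48L), n, replace = TRUE,
                         prob = cfg$interval_probs)
    generation <- sample(seq_len(cfg$n_generations), n, replace = TRUE)
    gen_eff <- stats::rnorm(cfg$n_generations, 0, cfg$sigma_gen)[generation]
    olre <- stats::rnorm(n, 0, cfg$sigma_olre)
    eta <- cfg$beta0 + cfg$beta_PM * (mating_order == "PM") +
      cfg$beta_24 * (interval_h == 24) + cfg$beta_48 * (interval_h == 48) +
      gen_eff + olre
    true_P2 <- inv_logit(eta)
    eggs_total <- pmax(1L, stats::rnbinom(n, size = cfg$egg_dispersion,
                                          mu = cfg$egg_mean))
    true_m2_eggs <- stats::rbinom(n, eggs_total, true_P2)

    key <- cell_key(sterilization_order, interval_h)
    p <- cfg$p_cells[key]
    z <- cfg$z_cells[key]
    brown <- cfg$brown_cells[key]
    # sterile male is second under NR, first under RN
    m2_sterile <- sterilization_order == "NR"
    p_m2 <- ifelse(m2_sterile, z, p)
    p_m1 <- ifelse(m2_sterile, p, z)
    hatched_m2 <- stats::rbinom(n, true_m2_eggs, p_m2)
    hatched_m1 <- stats::rbinom(n, eggs_total - true_m2_eggs, p_m1)
    hatched_true <- hatched_m1 + hatched_m2
    true_brown_eggs <- stats::rbinom(n, hatched_true, brown)
    eggs_hatched_obs <- hatched_true - true_brown_eggs
    eggs_clear_obs <- eggs_total - eggs_hatched_obs

    data.frame(
      female_id = sprintf("F%03d", seq_len(n)),
      generation = paste0("G", generation),
      mating_order = mating_order,
      sterilization_order = sterilization_order,
      interval_h = interval_h,
      eggs_total = eggs_total,
      eggs_hatched_obs = as.integer(eggs_hatched_obs),
      eggs_clear_obs = as.integer(eggs_clear_obs),
      true_P2 = true_P2,
      true_m2_eggs = as.integer(true_m2_eggs),
      true_brown_eggs = as.integer(true_brown_eggs),
      stringsAsFactors = FALSE
    )
  })
  trials <- cbind(trials,
                  simulate_behaviors(cfg, trials,
                                     derive_seed(seed, "behaviors")))
  list(trials = trials,
       truth = cfg[c("beta0", "beta_PM", "beta_24", "beta_48",
                     "sigma_olre", "sigma_gen", "p_cells", "z_cells",
                     "brown_cells")])
}

# Behavioral covariates: independent Gaussians per (role x maternal
# treatment); which treatment occupies which role follows the mating order
# (MP: monandrous-mother's son first). Missingness is injected at random into
# the behavioral (not weight) columns.
simulate_behaviors <- function(cfg, trials, seed) {
  bm <- cfg$behavior_means
  n <- nrow(trials)
  with_seed(seed, {
    treat1 <- ifelse(trials$mating_order == "MP", "M", "P")
    treat2 <- ifelse(trials$mating_order == "MP", "P", "M")
    draw <- function(trait, role, treat) {
      out <- numeric(n)
      for (tr in c("M", "P")) {
        row <- bm[bm$trait == trait & bm$role == role & bm$treatment == tr, ]
        idx <- treat == tr
        out[idx] <- stats::rnorm(sum(idx), row$mean, row$sd)
      }
      pmax(out, 0)
    }
    cov <- data.frame(
      male1_weight_mg = draw("weight_mg", "either", treat1),
      male2_weight_mg = draw("weight_mg", "either", treat2),
      ejaculate1_mg = draw("ejaculate_mg", "first", treat1),
      ejaculate2_mg = draw("ejaculate_mg", "second", treat2),
      cop_latency1_s = draw("cop_latency_s", "first", treat1),
      cop_latency2_s = draw("cop_latency_s", "second", treat2),
      kick_latency1_s = draw("kick_latency_s", "first", treat1),
      kick_latency2_s = draw("kick_latency_s", "second", treat2),
      kick_duration1_s = draw("kick_duration_s", "first", treat1),
      kick_duration2_s = draw("kick_duration_s", "second", treat2),
      cop_duration1_s = draw("cop_duration_s", "first", treat1),
      cop_duration2_s = draw("cop_duration_s", "second", treat2)
    )
    behav_cols <- setdiff(names(cov), c("male1_weight_mg", "male2_weight_mg"))
    if (cfg$covariate_missing_rate > 0) {
      for (cl in behav_cols) {
        miss <- stats::runif(n) < cfg$covariate_missing_rate
        cov[[cl]][miss] <- NA_real_
      }
    }
    cov
  })
}

#' Simulate fertility correction-factor assays
#'
#' Generates the single-sire mating assays used to estimate the correction
#' factors: for every sterilization order x interval stratum,
#' `assay_eggs_per_cell` eggs are laid by normal-male-mated females (hatching
#' with probability `p_cells`) and the same number by sterile-male-mated
#' females (hatching with probability `z_cells`); hatched eggs are brown with
#' the stratum's brown probability. Unlike the double-mating trials, brown
#' eggs ARE recorded here — that is what makes the reallocation correction
#' estimable.
#'
#' @inheritParams simulate_experiment
#' @return data frame of assay records with columns `sterilization_order`,
#'   `interval_h`, `male_type`, `eggs_laid`, `eggs_hatched`, `eggs_brown`.
#' @export
simulate_fertility_assays <- function(cfg, seed = cfg$seed) {
  validate_sim_config(cfg)
  with_seed(derive_seed(seed, "assays"), {
    grid <- expand.grid(sterilization_order = c("NR", "RN"),
                        interval_h = c(0L, 24L, 48L),
                        male_type = c("normal", "sterile"),
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$sterilization_order, grid$interval_h,
                       grid$male_type), ]
    rownames(grid) <- NULL
    key <- cell_key(grid$sterilization_order, grid$interval_h)
    hatch_p <- ifelse(grid$male_type == "normal",
                      cfg$p_cells[key], cfg$z_cells[key])
    grid$eggs_laid <- rep(as.integer(cfg$assay_eggs_per_cell), nrow(grid))
    grid$eggs_hatched <- stats::rbinom(nrow(grid), grid$eggs_laid, hatch_p)
    grid$eggs_brown <- stats::rbinom(nrow(grid), grid$eggs_hatched,
                                     cfg$brown_cells[key])
    grid
  })
}
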