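# Per-trial paternity estimation by the sterile-male technique.
#
# The observed hatch proportion x after a double mating is a two-component
# mixture: eggs sired by the sterile male hatch with probability z, eggs
# sired by the normal male with probability p, so x = P_R*z + (1-P_R)*p and
# the sterile-male paternity share is recovered as P_R = (p - x)/(p - z).
# P2 (second-male paternity) is P_R when the sterile male mated second (NR)
# and 1 - P_R when he mated first (RN). Before the inversion, the observed
# clear count is corrected for brown eggs: hatched eggs mis-scored as clear
# at a stratum-specific rate estimated from the assays.

#' Exclusion policy for paternity estimates
#'
#' @param min_eggs minimum post-second-mating egg count; females below it are
#'   flagged `low_eggs` and excluded (default 10).
#' @param out_of_bounds how to treat P2 estimates outside \[0, 1\]:
#'   `"exclude"` (default), `"clamp"` to the boundary, or `"keep_flagged"`
#'   (kept, flagged, clamped only for egg attribution).
#' @param overrides female ids to retain despite an out-of-bounds flag (their
#'   P2 is clamped for attribution and they carry `kept_by_override`).
#' @return an `exclusion_policy` list.
#' @export
exclusion_policy <- function(min_eggs = 10,
                             out_of_bounds = c("exclude", "clamp",
                                               "keep_flagged"),
                             overrides = character()) {
  out_of_bounds <- match.arg(out_of_bounds)
  stopifnot(min_eggs >= 0)
  structure(list(min_eggs = min_eggs, out_of_bounds = out_of_bounds,
                 overrides = as.character(overrides)),
            class = "exclusion_policy")
}

#' Reallocate mis-scored brown eggs
#'
#' Hatched eggs showing only a brown larval head dot are scored as clear in
#' double-mating trials. The correction estimates the expected brown count as
#' `brown_prop * eggs_total` (clamped at the observed clear count so the
#' corrected clear count cannot go negative), adds it to the hatched count
#' and subtracts it from the clear count. Counts stay fractional here;
#' rounding happens only at egg attribution.
#'
#' @param hatched_obs,clear_obs,eggs_total observed counts,
#'   `hatched_obs + clear_obs == eggs_total`.
#' @param brown_prop stratum brown-egg proportion in \[0, 1).
#' @return list with `hatched_corr`, `clear_corr`, `brown_est`.
#' @export
brown_reallocate <- function(hatched_obs, clear_obs, eggs_total, brown_prop) {
  if (any(c(hatched_obs, clear_obs, eggs_total) < 0))
    stop("egg counts must be non-negative", call. = FALSE)
  if (any(hatched_obs + clear_obs != eggs_total))
    stop("hatched_obs + clear_obs must equal eggs_total", call. = FALSE)
  if (any(brown_prop < 0 | brown_prop >= 1))
    stop("brown_prop must lie in [0, 1)", call. = FALSE)
  brown_est <- pmin(brown_prop * eggs_total, clear_obs)
  list(hatched_corr = hatched_obs + brown_est,
       clear_corr = clear_obs - brown_est,
       brown_est = brown_est)
}

#' Invert the hatch-proportion mixture (Boorman-Parker)
#'
#' Solves `x = P_R*z + (1-P_R)*p` for the sterile-male paternity share:
#' `P_R = (p - x)/(p - z)`. The boundary conditions hold by construction
#' (`x = p` gives 0, `x = z` gives 1). No clamping: when x falls outside
#' \[z, p\] (sampling noise, fertility misestimation) P_R falls outside
#' \[0, 1\] and is flagged downstream.
#'
#' @param x observed (corrected) hatch proportion.
#' @param p normal-male fertility.
#' @param z sterile-male fertility, `z < p`.
#' @return P_R, possibly outside \[0, 1\].
#' @seealso [expected_hatch()] for the forward model.
#' @export
invert_boorman_parker <- function(x, p, z) {
  if (any(p <= z)) stop("normal fertility p must exceed sterile fertility z",
                        call. = FALSE)
  (p - x) / (p - z)
}

#' Convert sterile-male share to second-male paternity
#'
#' @param P_R sterile-male paternity share.
#' @param sterilization_order `"NR"` (sterile male second, P2 = P_R) or
#'   `"RN"` (normal male second, P2 = 1 - P_R).
#' @return P2. Out-of-bounds values propagate for downstream flagging.
#' @export
p_r_to_p2 <- function(P_R, sterilization_order) {
  if (!all(sterilization_order %in% c("NR", "RN")))
    stop("sterilization_order must be 'NR' or 'RN'", call. = FALSE)
  ifelse(sterilization_order == "NR", P_R, 1 - P_R)
}

# round half away from zero; base round() is round-half-even
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Attribute eggs to the two sires
#'
#' Multiplies P2 by the total eggs laid after the second mating and rounds to
#' a whole number (half away from zero, symmetric between the two males) to
#' give each male's egg count.
#'
#' @param P2 second-male paternity in \[0, 1\] (clamp or exclude first).
#' @param eggs_total eggs laid after the second mating.
#' @return list with `eggs_m1`, `eggs_m2` (integers summing to `eggs_total`).
#' @export
attribute_eggs <- function(P2, eggs_total) {
  if (any(P2 < 0 | P2 > 1))
    stop("P2 outside [0, 1]: clamp or exclude before attribution",
         call. = FALSE)
  eggs_m2 <- as.integer(round_half_away(P2 * eggs_total))
  list(eggs_m1 = as.integer(eggs_total) - eggs_m2, eggs_m2 = eggs_m2)
}

flag_string <- function(...) {
  fl <- c(...)
  if (length(fl) == 0) "" else paste(fl, collapse = ";")
}

#' Test for a flag on paternity estimates
#' @param estimates data frame of paternity estimates.
#' @param flag flag name (`"low_eggs"`, `"p2_above_1"`, `"p2_below_0"`,
#'   `"kept_by_override"`).
#' @return logical vector.
#' @export
has_flag <- function(estimates, flag) {
  vapply(strsplit(estimates$flags, ";", fixed = TRUE),
         function(f) flag %in% f, logical(1))
}

#' Estimate P2 for a set of double-mating trials
#'
#' The per-female pipeline: look up the trial's stratum in the fertility
#' table, reallocate brown eggs, form the corrected hatch proportion
#' `x_corrected = hatched_corr / eggs_total`, invert the mixture to P_R, map
#' to P2 by sterilization order, flag low egg counts and out-of-bounds
#' estimates per the policy, and attribute egg counts to the two sires for
#' retained females.
#'
#' @param trials data frame of trials (columns `female_id`, `mating_order`,
#'   `sterilization_order`, `interval_h`, `eggs_total`, `eggs_hatched_obs`,
#'   `eggs_clear_obs`; extra columns are carried through untouched).
#' @param table a `fertility_table`.
#' @param policy an [exclusion_policy()].
#' @return data frame of paternity estimates, one row per female: `x_raw`,
#'   `brown_est`, `x_corrected`, `P_R`, `P2` (unclamped), `P2_attr` (value
#'   used for attribution, NA when excluded), `eggs_m1`, `eggs_m2`, `flags`,
#'   `kept`, plus the design columns.
#' @export
estimate_trials <- function(trials, table, policy = exclusion_policy()) {
  validate_trials(trials)
  n <- nrow(trials)
  idx <- match(paste(trials$sterilization_order, trials$interval_h),
               paste(table$sterilization_order, table$interval_h))
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    stop("no fertility-table cell for ", trials$sterilization_order[i], "/",
         trials$interval_h[i], " h", call. = FALSE)
  }
  cell <- as.data.frame(table)[idx, , drop = FALSE]
  re <- brown_reallocate(trials$eggs_hatched_obs, trials$eggs_clear_obs,
                         trials$eggs_total, cell$brown)
  x_raw <- trials$eggs_hatched_obs / trials$eggs_total
  x_corrected <- re$hatched_corr / trials$eggs_total
  P_R <- invert_boorman_parker(x_corrected, cell$p, cell$z)
  P2 <- p_r_to_p2(P_R, trials$sterilization_order)

  low <- trials$eggs_total < policy$min_eggs
  above <- P2 > 1
  below <- P2 < 0
  override <- trials$female_id %in% policy$overrides & (above | below) & !low
  flags <- character(n)
  for (i in seq_len(n))
    flags[i] <- flag_string(
      if (low[i]) "low_eggs",
      if (above[i]) "p2_above_1",
      if (below[i]) "p2_below_0",
      if (override[i]) "kept_by_override")

  kept <- !low & (!(above | below) |
                    policy$out_of_bounds %in% c("clamp", "keep_flagged") |
                    override)
  P2_attr <- ifelse(kept, pmin(pmax(P2, 0), 1), NA_real_)
  eggs_m2 <- rep(NA_integer_, n)
  eggs_m1 <- rep(NA_integer_, n)
  if (any(kept)) {
    at <- attribute_eggs(P2_attr[kept], trials$eggs_total[kept])
    eggs_m2[kept] <- at$eggs_m2
    eggs_m1[kept] <- at$eggs_m1
  }
  est <- data.frame(
    female_id = trials$female_id,
    mating_order = trials$mating_order,
    sterilization_order = trials$sterilization_order,
    interval_h = trials$interval_h,
    eggs_total = trials$eggs_total,
    x_raw = x_raw, brown_est = re$brown_est, x_corrected = x_corrected,
    P_R = P_R, P2 = P2, P2_attr = P2_attr,
    eggs_m1 = eggs_m1, eggs_m2 = eggs_m2,
    flags = flags, kept = kept,
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(trials), names(est))
  if (length(extra)) est <- cbind(est, trials[extra])
  rownames(est) <- NULL
  est
}

#' Partition paternity estimates into kept and excluded sets
#'
#' @param estimates output of [estimate_trials()].
#' @param policy the [exclusion_policy()] used (for reporting overrides
#'   absent from the data).
#' @return list with `kept`, `excluded` (data frames) and `log` (one row per
#'   excluded female with the reason).
#' @export
apply_exclusions <- function(estimates, policy = exclusion_policy()) {
  absent <- setdiff(policy$overrides, estimates$female_id)
  if (length(absent))
    warning("override id(s) not present in estimates: ",
            paste(absent, collapse = ", "), call. = FALSE)
  kept <- estimates[estimates$kept, , drop = FALSE]
  excluded <- estimates[!estimates$kept, , drop = FALSE]
  log <- data.frame(female_id = excluded$female_id,
                    reason = excluded$flags,
                    stringsAsFactors = FALSE)
  list(kept = kept, excluded = excluded, log = log)
}

#' Pool P2 across females within subgroups
#'
#' Pooled P2 per group = (total eggs attributed to second males) / (total
#' eggs laid), over attributed (kept) females.
#'
#' @param estimates paternity estimates with attributed egg counts.
#' @param keys grouping column names (e.g. `c("interval_h", "mating_order")`);
#'   empty for grand totals.
#' @return data frame with group keys, `n_females`, `eggs_m2`, `eggs_total`,
#'   `P2_pooled`.
#' @export
pool_p2 <- function(estimates, keys = c("interval_h", "mating_order")) {
  est <- estimates[!is.na(estimates$eggs_m2), , drop = FALSE]
  if (nrow(est) < nrow(estimates))
    warning(nrow(estimates) - nrow(est),
            " unattributed estimate(s) omitted from pooling", call. = FALSE)
  if (length(keys) == 0) {
    return(data.frame(n_females = nrow(est),
                      eggs_m2 = sum(est$eggs_m2),
                      eggs_total = sum(est$eggs_total),
                      P2_pooled = sum(est$eggs_m2) / sum(est$eggs_total)))
  }
  split_by <- interaction(est[keys], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(est, split_by), function(g) {
    out <- g[1, keys, drop = FALSE]
    out$n_females <- nrow(g)
    out$eggs_m2 <- sum(g$eggs_m2)
    out$eggs_total <- sum(g$eggs_total)
    out$P2_pooled <- out$eggs_m2 / out$eggs_total
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

validate_trials <- function(trials) {
  need <- c("female_id", "mating_order", "sterilization_order", "interval_h",
            "eggs_total", "eggs_hatched_obs", "eggs_clear_obs")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stop("trials missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- !trials$mating_order %in% c("MP", "PM")
  if (any(bad))
    stop("row ", which(bad)[1], ": invalid mating_order level '",
         trials$mating_order[which(bad)[1]], "'", call. = FALSE)
  bad <- !trials$sterilization_order %in% c("NR", "RN")
  if (any(bad))
    stop("row ", which(bad)[1], ": invalid sterilization_order level '",
         trials$sterilization_order[which(bad)[1]], "'", call. = FALSE)
  bad <- !trials$interval_h %in% c(0, 24, 48)
  if (any(bad))
    stop("row ", which(bad)[1], ": invalid interval_h '",
         trials$interval_h[which(bad)[1]], "'", call. = FALSE)
  bad <- trials$eggs_hatched_obs + trials$eggs_clear_obs != trials$eggs_total
  if (any(bad))
    stop("row ", which(bad)[1],
         ": eggs_hatched_obs + eggs_clear_obs != eggs_total", call. = FALSE)
  if (anyDuplicated(trials$female_id))
    stop("duplicated female_id in trials", call. = FALSE)
  invisible(trials)
}
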