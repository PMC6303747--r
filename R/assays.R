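# Correction-factor estimation from single-sire mating assays.
#
# The sterile-male technique needs three per-stratum correction factors:
#   p     - normal-male fertility (hatch proportion after a normal mating)
#   z     - sterile-male fertility (residual hatch, incomplete sterilization)
#   brown - proportion of laid eggs that hatch but show only a brown larval
#           head dot and are mis-scored as clear in the double-mating trials
# Each is estimated per sterilization order x inter-mating interval cell by
# ratio-of-sums pooling of the cell's assay records. p and z use only the
# matching sire type; the brown proportion pools all eggs laid in the cell.

required_assay_cols <- c("sterilization_order", "interval_h", "male_type",
                         "eggs_laid", "eggs_hatched", "eggs_brown")

validate_assay_records <- function(records) {
  missing <- setdiff(required_assay_cols, names(records))
  if (length(missing))
    stop("assay records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  bad <- !records$sterilization_order %in% c("NR", "RN")
  if (any(bad))
    stop("invalid sterilization_order level: ",
         records$sterilization_order[which(bad)[1]], call. = FALSE)
  bad <- !records$interval_h %in% c(0, 24, 48)
  if (any(bad))
    stop("invalid interval_h level: ", records$interval_h[which(bad)[1]],
         call. = FALSE)
  bad <- !records$male_type %in% c("normal", "sterile")
  if (any(bad))
    stop("invalid male_type level: ", records$male_type[which(bad)[1]],
         call. = FALSE)
  if (any(records$eggs_hatched > records$eggs_laid))
    stop("eggs_hatched exceeds eggs_laid in an assay record", call. = FALSE)
  if (any(records$eggs_brown > records$eggs_hatched))
    stop("eggs_brown exceeds eggs_hatched in an assay record", call. = FALSE)
  if (any(records$eggs_laid < 0))
    stop("negative egg counts in assay records", call. = FALSE)
  invisible(records)
}

#' Estimate fertility correction factors from assay records
#'
#' Pools assay records into a per-stratum fertility table: for each
#' sterilization order x interval cell, `p` = total hatched / total laid over
#' normal-male records, `z` = the same over sterile-male records, and the
#' brown-egg proportion = total brown / total laid over all the cell's
#' records. Raw numerators and denominators are retained. Pooling is
#' ratio-of-sums, so splitting a record into parts with the same totals
#' leaves the table unchanged.
#'
#' @param records data frame of assay records (columns `sterilization_order`,
#'   `interval_h`, `male_type`, `eggs_laid`, `eggs_hatched`, `eggs_brown`).
#' @param cells strata that must be present; defaults to all six.
#' @return a `fertility_table`: data frame keyed by (order, interval) with
#'   `p`, `p_num`, `p_den`, `z`, `z_num`, `z_den`, `brown`, `brown_num`,
#'   `brown_den`.
#' @examples
#' rec <- data.frame(
#'   sterilization_order = "NR", interval_h = 0,
#'   male_type = c("normal", "sterile"),
#'   eggs_laid = c(660, 637), eggs_hatched = c(652, 43),
#'   eggs_brown = c(60, 0))
#' estimate_correction_factors(rec, cells = data.frame(
#'   sterilization_order = "NR", interval_h = 0))
#' @export
estimate_correction_factors <- function(records, cells = NULL) {
  validate_assay_records(records)
  if (is.null(cells))
    cells <- expand.grid(sterilization_order = c("NR", "RN"),
                         interval_h = c(0L, 24L, 48L),
                         stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    ord <- cells$sterilization_order[i]
    int <- cells$interval_h[i]
    sub <- records[records$sterilization_order == ord &
                     records$interval_h == int, ]
    norm <- sub[sub$male_type == "normal", ]
    ster <- sub[sub$male_type == "sterile", ]
    if (nrow(norm) == 0 || sum(norm$eggs_laid) == 0 ||
        nrow(ster) == 0 || sum(ster$eggs_laid) == 0)
      stop("insufficient assay data for cell ", ord, "/", int, " h",
           call. = FALSE)
    p_num <- sum(norm$eggs_hatched); p_den <- sum(norm$eggs_laid)
    z_num <- sum(ster$eggs_hatched); z_den <- sum(ster$eggs_laid)
    b_num <- sum(sub$eggs_brown);    b_den <- sum(sub$eggs_laid)
    data.frame(sterilization_order = ord, interval_h = as.integer(int),
               p = p_num / p_den, p_num = p_num, p_den = p_den,
               z = z_num / z_den, z_num = z_num, z_den = z_den,
               brown = b_num / b_den, brown_num = b_num, brown_den = b_den,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, out)
  bad <- tab$p <= tab$z
  if (any(bad))
    stop("p <= z in cell ", tab$sterilization_order[which(bad)[1]], "/",
         tab$interval_h[which(bad)[1]],
         " h: paternity inversion undefined", call. = FALSE)
  class(tab) <- c("fertility_table", "data.frame")
  tab
}

#' Build a fertility table from known proportions and counts
#'
#' Constructs a `fertility_table` directly from per-cell numerators and
#' denominators (e.g. published assay totals), bypassing record pooling.
#'
#' @param df data frame with columns `sterilization_order`, `interval_h`,
#'   `p_num`, `p_den`, `z_num`, `z_den`, `brown_num`, `brown_den`.
#' @return a `fertility_table`.
#' @export
fertility_table <- function(df) {
  need <- c("sterilization_order", "interval_h", "p_num", "p_den",
            "z_num", "z_den", "brown_num", "brown_den")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(df[c("p_den", "z_den", "brown_den")] <= 0))
    stop("denominators must be positive", call. = FALSE)
  df$p <- df$p_num / df$p_den
  df$z <- df$z_num / df$z_den
  df$brown <- df$brown_num / df$brown_den
  if (any(df$p <= df$z))
    stop("p <= z in a cell: paternity inversion undefined", call. = FALSE)
  tab <- df[c("sterilization_order", "interval_h", "p", "p_num", "p_den",
              "z", "z_num", "z_den", "brown", "brown_num", "brown_den")]
  class(tab) <- c("fertility_table", "data.frame")
  tab
}

#' Look up a stratum's correction factors
#'
#' @param table a `fertility_table`.
#' @param order sterilization order, `"NR"` or `"RN"`.
#' @param interval_h inter-mating interval in hours (0, 24 or 48).
#' @return one-row data frame with the cell's `p`, `z`, `brown` (and counts).
#' @export
lookup_cell <- function(table, order, interval_h) {
  stopifnot(inherits(table, "fertility_table"))
  hit <- table$sterilization_order == order & table$interval_h == interval_h
  if (sum(hit) != 1)
    stop("no fertility-table cell for ", order, "/", interval_h, " h",
         call. = FALSE)
  table[hit, , drop = FALSE]
}
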