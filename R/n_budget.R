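## Unit conventions used everywhere in the package:
##   N amounts in Tg N per year (1 Tg = 1e12 g = 1e9 kg),
##   areas in Mha (1 Mha = 1e6 ha), per-area rates in kg N per ha per year.
## Mha * kg/ha = 1e6 ha * kg/ha = 1e9 g = 1e-3 Tg, hence the single
## conversion constant below. No intermediate rounding anywhere: values are
## rounded only at report rendering.
MHA_KG_TO_TG <- 1e-3

n_source_cols <- c("fertilizer_n", "manure_n", "crop_residue_n",
                   "deposition_n", "bnf_n")

#' Annual nitrogen source records
#'
#' Builds a data frame of annual nitrogen inputs to global agriculture, one
#' row per year, with the five sources of the total-N budget: synthetic
#' fertilizer, animal manure, crop residue, atmospheric deposition and
#' biological N fixation (BNF), all in Tg N per year. Optional columns carry
#' the agricultural and pulse-crop areas (Mha) used by the per-area
#' estimators [deposition_n()] and [bnf_n()].
#'
#' @param year Integer vector of calendar years.
#' @param fertilizer_n,manure_n,crop_residue_n,deposition_n,bnf_n Numeric
#'   vectors, Tg N per year, all non-negative.
#' @param area_agri,area_pulse Optional numeric vectors, Mha;
#'   `area_pulse <= area_agri` where both are present.
#' @return A validated data frame with class `ngtp_sources`.
#' @seealso [read_n_sources()], [total_n_input()], [anchor_records()]
#' @examples
#' n_sources(2010, 113.40, 34.02, 31.79, 14.33, 27.16)
#' @export
n_sources <- function(year, fertilizer_n, manure_n, crop_residue_n,
                      deposition_n, bnf_n, area_agri = NULL,
                      area_pulse = NULL) {
  df <- data.frame(year = as.integer(year), fertilizer_n = fertilizer_n,
                   manure_n = manure_n, crop_residue_n = crop_residue_n,
                   deposition_n = deposition_n, bnf_n = bnf_n)
  if (!is.null(area_agri)) df$area_agri <- area_agri
  if (!is.null(area_pulse)) df$area_pulse <- area_pulse
  validate_n_sources(df)
}

#' Validate a nitrogen source table
#'
#' Checks the schema and invariants of an annual N-source table: the five
#' source columns are present, numeric and non-negative, and
#' `area_pulse <= area_agri` wherever both areas are given.
#'
#' @param df A data frame with columns `year`, `fertilizer_n`, `manure_n`,
#'   `crop_residue_n`, `deposition_n`, `bnf_n` and optionally `area_agri`,
#'   `area_pulse`.
#' @return `df` with class `ngtp_sources` added; errors on violation.
#' @export
validate_n_sources <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop("nitrogen source input must be a data frame with at least one row",
         call. = FALSE)
  }
  missing_cols <- setdiff(c("year", n_source_cols), names(df))
  if (length(missing_cols)) {
    stop("nitrogen source table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (nm in n_source_cols) {
    v <- df[[nm]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("column '", nm, "' must be numeric with no missing values",
           call. = FALSE)
    }
    if (any(v < 0)) {
      stop("column '", nm, "' contains negative N amounts", call. = FALSE)
    }
  }
  if (all(c("area_agri", "area_pulse") %in% names(df))) {
    both <- !is.na(df$area_agri) & !is.na(df$area_pulse)
    if (any(df$area_pulse[both] > df$area_agri[both])) {
      stop("area_pulse exceeds area_agri", call. = FALSE)
    }
  }
  if (!inherits(df, "ngtp_sources")) {
    class(df) <- c("ngtp_sources", class(df))
  }
  df
}

#' Read an annual nitrogen source table from CSV
#'
#' Expects one row per year with header
#' `year,fertilizer_n,manure_n,crop_residue_n,deposition_n,bnf_n` and
#' optionally `area_agri,area_pulse`; N amounts in Tg N, areas in Mha.
#' Comment lines starting with `#` are ignored.
#'
#' @param path Path to the CSV file.
#' @return A validated `ngtp_sources` data frame.
#' @export
read_n_sources <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#")
  validate_n_sources(df)
}

#' Total annual nitrogen input
#'
#' The total N input to global agriculture is the plain sum of the five
#' sources: fertilizer + manure + crop residue + atmospheric deposition +
#' BNF, with no rounding.
#'
#' @param records An `ngtp_sources` data frame (or anything
#'   [validate_n_sources()] accepts).
#' @return Numeric vector, Tg N per year, one value per row.
#' @examples
#' rec <- n_sources(2010, 113.40, 34.02, 31.79, 14.33, 27.16)
#' total_n_input(rec)  # 220.70
#' @export
total_n_input <- function(records) {
  records <- validate_n_sources(records)
  rowSums(as.matrix(records[n_source_cols]))
}

#' Per-area budget rates
#'
#' Rates for the per-area estimators of atmospheric deposition and BNF, in
#' kg N per ha per year. The published totals, not these rates, are the
#' primary entry path; the rates exist to reconstruct deposition and BNF
#' where only areas are known.
#'
#' @param deposition_rate kg N deposited per ha of agricultural land per
#'   year.
#' @param bnf_rate_pulse,bnf_rate_nonpulse kg N fixed per ha per year on
#'   pulse and non-pulse cropland.
#' @return A validated list of class `ngtp_rates`.
#' @export
budget_rates <- function(deposition_rate, bnf_rate_pulse, bnf_rate_nonpulse) {
  x <- list(deposition_rate = deposition_rate,
            bnf_rate_pulse = bnf_rate_pulse,
            bnf_rate_nonpulse = bnf_rate_nonpulse)
  for (nm in names(x)) {
    if (!is.numeric(x[[nm]]) || length(x[[nm]]) != 1L || x[[nm]] < 0) {
      stop("rate '", nm, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  structure(x, class = "ngtp_rates")
}

#' Atmospheric deposition N from area
#'
#' `deposition_n = area_agri * deposition_rate`, converted from
#' Mha times kg/ha to Tg (factor 1e-3).
#'
#' @param area_agri Agricultural area, Mha, non-negative.
#' @param rates A [budget_rates()] object.
#' @return Tg N per year.
#' @examples
#' deposition_n(1000, budget_rates(3.12, 80, 5))  # 3.12 Tg N
#' @export
deposition_n <- function(area_agri, rates) {
  stopifnot(inherits(rates, "ngtp_rates"))
  if (any(area_agri < 0)) stop("area_agri must be non-negative", call. = FALSE)
  area_agri * rates$deposition_rate * MHA_KG_TO_TG
}

#' Biological N fixation from areas
#'
#' `bnf_n = area_pulse * bnf_rate_pulse +
#' (area_agri - area_pulse) * bnf_rate_nonpulse`, converted from Mha times
#' kg/ha to Tg (factor 1e-3).
#'
#' @param area_agri,area_pulse Areas in Mha, `0 <= area_pulse <= area_agri`.
#' @param rates A [budget_rates()] object.
#' @return Tg N per year.
#' @examples
#' bnf_n(100, 100, budget_rates(3, 80, 5))  # 8 Tg N
#' @export
bnf_n <- function(area_agri, area_pulse, rates) {
  stopifnot(inherits(rates, "ngtp_rates"))
  if (any(area_pulse < 0) || any(area_agri < 0)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  if (any(area_pulse > area_agri)) {
    stop("area_pulse exceeds area_agri", call. = FALSE)
  }
  (area_pulse * rates$bnf_rate_pulse +
     (area_agri - area_pulse) * rates$bnf_rate_nonpulse) * MHA_KG_TO_TG
}

#' Source shares of the total N input
#'
#' Fraction of the annual total contributed by each of the five sources.
#'
#' @param records An `ngtp_sources` data frame.
#' @return A data frame with `year` and one fractional column per source;
#'   rows sum to 1.
#' @examples
#' rec <- n_sources(2010, 113.40, 34.02, 31.79, 14.33, 27.16)
#' round(100 * source_shares(rec)$fertilizer_n, 2)  # 51.38
#' @export
source_shares <- function(records) {
  records <- validate_n_sources(records)
  total <- total_n_input(records)
  if (any(total <= 0)) {
    stop("source shares are undefined for a zero total N input",
         call. = FALSE)
  }
  shares <- as.data.frame(as.matrix(records[n_source_cols]) / total)
  cbind(year = records$year, shares)
}
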