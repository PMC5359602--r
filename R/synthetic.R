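#' Benchmark 1961 and 2010 nitrogen source records
#'
#' The two published global N-source records the package is calibrated
#' against, in Tg N per year: 1961 (fertilizer 11.59, manure 24.20, crop
#' residue 14.05, deposition 3.12, BNF 21.98) and 2010 (113.40, 34.02,
#' 31.79, 14.33, 27.16). They are the default anchors of the synthetic
#' series generator and the inputs of [reproduction_report()].
#'
#' @return An `ngtp_sources` data frame with two rows.
#' @examples
#' total_n_input(anchor_records())  # 74.94, 220.70
#' @export
anchor_records <- function() {
  n_sources(
    year = c(1961L, 2010L),
    fertilizer_n = c(11.59, 113.40),
    manure_n = c(24.20, 34.02),
    crop_residue_n = c(14.05, 31.79),
    deposition_n = c(3.12, 14.33),
    bnf_n = c(21.98, 27.16)
  )
}

#' Specification of a synthetic annual N-source series
#'
#' Describes a FAOSTAT-like annual series between two anchor records: a
#' per-source trajectory shape interpolating the anchors exactly, plus
#' optional multiplicative lognormal noise. Defaults emulate the historical
#' record: roughly tenfold exponential growth for fertilizer N and gentler
#' linear growth for the other four sources.
#'
#' @param start_year,end_year Calendar years, `start_year < end_year`.
#' @param anchors An `ngtp_sources` data frame with exactly two rows giving
#'   the start- and end-year records; defaults to [anchor_records()].
#' @param trajectory Named character vector mapping each source to one of
#'   `"linear"`, `"exponential"`, `"logistic"`. Unnamed scalar recycles to
#'   all sources.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   noise, `0 <= noise_cv < 0.5`; 0 disables noise.
#' @param seed Integer seed making the generated series reproducible.
#' @return A validated list of class `ngtp_series_spec`.
#' @seealso [generate_series()]
#' @export
series_spec <- function(start_year = 1961L, end_year = 2010L,
                        anchors = anchor_records(),
                        trajectory = c(fertilizer_n = "exponential",
                                       manure_n = "linear",
                                       crop_residue_n = "linear",
                                       deposition_n = "linear",
                                       bnf_n = "linear"),
                        noise_cv = 0, seed = 1L) {
  if (length(trajectory) == 1L && is.null(names(trajectory))) {
    trajectory <- stats::setNames(rep(trajectory, length(n_source_cols)),
                                  n_source_cols)
  }
  x <- list(start_year = as.integer(start_year),
            end_year = as.integer(end_year),
            anchors = validate_n_sources(anchors),
            trajectory = trajectory, noise_cv = noise_cv,
            seed = as.integer(seed))
  if (x$start_year >= x$end_year) {
    stop("start_year must precede end_year", call. = FALSE)
  }
  if (nrow(x$anchors) != 2L) {
    stop("anchors must contain exactly two records (start and end)",
         call. = FALSE)
  }
  missing_traj <- setdiff(n_source_cols, names(x$trajectory))
  if (length(missing_traj)) {
    stop("trajectory missing for source(s): ",
         paste(missing_traj, collapse = ", "), call. = FALSE)
  }
  ok <- x$trajectory[n_source_cols] %in%
    c("linear", "exponential", "logistic")
  if (!all(ok)) {
    stop("trajectories must be 'linear', 'exponential' or 'logistic'",
         call. = FALSE)
  }
  if (!is.numeric(x$noise_cv) || x$noise_cv < 0 || x$noise_cv >= 0.5) {
    stop("noise_cv must lie in [0, 0.5)", call. = FALSE)
  }
  structure(x, class = "ngtp_series_spec")
}

## Shape functions on u in [0, 1] interpolating a -> b with s(0)=a, s(1)=b.
## Exponential uses the exact growth ratio b/a (falls back to linear when a
## is 0); logistic is a normalized sigmoid with steepness 10, so anchors are
## hit exactly.
interpolate_source <- function(a, b, u, shape) {
  switch(shape,
    linear = a + (b - a) * u,
    exponential = if (a > 0 && b > 0) a * (b / a)^u else a + (b - a) * u,
    logistic = {
      g <- function(v) 1 / (1 + exp(-10 * (v - 0.5)))
      a + (b - a) * (g(u) - g(0)) / (g(1) - g(0))
    },
    stop("unknown trajectory shape: ", shape, call. = FALSE)
  )
}

#' Generate a synthetic annual N-source series
#'
#' Produces one record per year between the spec's anchor years, with each
#' source following its trajectory between the anchor values. With
#' `noise_cv = 0` the first and last records equal the anchors exactly and
#' linear/exponential trajectories are monotone. Noise, when enabled, is
#' multiplicative lognormal with unit mean and the requested coefficient of
#' variation, independent across years and sources; any value that would go
#' negative is clipped at zero (lognormal noise itself cannot produce one).
#' The same seed always yields the identical series; the generator restores
#' the caller's RNG state.
#'
#' @param spec An [series_spec()] object.
#' @return An `ngtp_sources` data frame with one row per year.
#' @examples
#' s <- generate_series(series_spec(noise_cv = 0))
#' nrow(s)  # 50
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "ngtp_series_spec"))
  years <- spec$start_year:spec$end_year
  u <- (years - spec$start_year) / (spec$end_year - spec$start_year)
  out <- data.frame(year = years)
  for (nm in n_source_cols) {
    out[[nm]] <- interpolate_source(spec$anchors[[nm]][1],
                                    spec$anchors[[nm]][2],
                                    u, spec$trajectory[[nm]])
  }
  if (spec$noise_cv > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    set.seed(spec$seed)
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    for (nm in n_source_cols) {
      noise <- stats::rlnorm(length(years), meanlog = -sdlog^2 / 2,
                             sdlog = sdlog)
      out[[nm]] <- pmax(out[[nm]] * noise, 0)
    }
  }
  validate_n_sources(out)
}
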