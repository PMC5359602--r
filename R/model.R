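#' Nitrogen-use GTP accounting model
#'
#' The central entry point of the package. An `ngtp` object bundles the
#' model parameters — emission/uptake factors, GTP coefficient intervals and
#' the range policy collapsing them — and, when an annual N-source table is
#' supplied, the full accounting computed from it: total N budget, gas
#' fluxes, and the CO2-equivalent warming/cooling decomposition with net GTP
#' at each requested horizon.
#'
#' The model chain is deterministic and linear in the annual total N input:
#' \deqn{N_T = N_{SN} + N_{AM} + N_{CR} + N_{AD} + N_{BNF}}
#' \deqn{F_g = N_T \cdot EF_g \cdot m_g}
#' \deqn{GTP_{net} = \sum_{warming} F_g |k_{g,t}| - \sum_{cooling} F_g |k_{g,t}|}
#' where \eqn{m_g} is the element-to-molecule mass conversion and
#' \eqn{k_{g,t}} the GTP coefficient of gas \eqn{g} at horizon \eqn{t}.
#'
#' @param data Optional annual N-source table (an `ngtp_sources` data frame,
#'   a plain data frame with the same columns, or a CSV path).
#' @param factors An [ngtp_factors()] object.
#' @param coefficients An [ngtp_coefficients()] object.
#' @param policy Range policy, `"low"`, `"mid"` or `"high"`; default
#'   `"mid"`, the only policy consistent with the published reference
#'   values.
#' @param horizons Integer vector, a subset of `c(20, 100)`.
#' @return An object of class `ngtp` with components `factors`,
#'   `coefficients`, `policy`, `horizons` and — when `data` is given —
#'   `sources`, `fluxes` (see [annual_fluxes()]) and `gtp` (rows of
#'   [annual_gtp()] stacked over horizons).
#' @seealso [predict.ngtp()], [simulate.ngtp()], [run_pipeline()]
#' @examples
#' m <- ngtp(anchor_records())
#' summary(m)
#' @export
ngtp <- function(data = NULL, factors = ngtp_factors(),
                 coefficients = ngtp_coefficients(), policy = "mid",
                 horizons = c(20L, 100L)) {
  stopifnot(inherits(factors, "ngtp_factors"),
            inherits(coefficients, "ngtp_coefficients"))
  policy <- match.arg(policy, c("low", "mid", "high"))
  horizons <- as.integer(horizons)
  if (length(horizons) == 0L || !all(horizons %in% c(20L, 100L))) {
    stop("horizons must be a non-empty subset of c(20, 100)", call. = FALSE)
  }
  obj <- structure(list(factors = factors, coefficients = coefficients,
                        policy = policy, horizons = horizons),
                   class = "ngtp")
  if (!is.null(data)) {
    if (is.character(data)) data <- read_n_sources(data)
    obj$sources <- validate_n_sources(data)
    obj$fluxes <- annual_fluxes(obj$sources, factors)
    gtp <- lapply(horizons, function(h) {
      annual_gtp(obj$fluxes, h, coefficients, policy)
    })
    obj$gtp <- do.call(rbind, gtp)
  }
  obj
}

#' @export
print.ngtp <- function(x, ...) {
  cat("Nitrogen-use GTP accounting model\n")
  cat("  range policy:", x$policy,
      "| horizons:", paste(x$horizons, collapse = ", "), "years\n")
  if (is.null(x$sources)) {
    cat("  no data attached; use predict() or supply data to ngtp()\n")
  } else {
    yr <- range(x$sources$year)
    cat(sprintf("  %d year(s) of data (%d-%d)\n", nrow(x$sources),
                yr[1], yr[2]))
    for (h in x$horizons) {
      g <- x$gtp[x$gtp$horizon == h, ]
      cat(sprintf("  net GTP%d: %s Tg CO2e\n", h,
                  paste(sprintf("%.2f", g$net), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Resolved GTP coefficients of a model
#'
#' @param object An [ngtp()] model.
#' @param ... Unused.
#' @return A pathway-by-horizon matrix of signed scalar coefficients under
#'   the model's range policy (kg CO2e per kg of each pathway's mass basis).
#' @export
coef.ngtp <- function(object, ...) {
  m <- sapply(c(20, 100), function(h) {
    sapply(gtp_pathways, function(p) {
      resolve_coefficient(object$coefficients, p, h, object$policy)
    })
  })
  colnames(m) <- c("gtp20", "gtp100")
  m
}

#' Apply a GTP model to new annual data
#'
#' Runs the budget, flux and GTP stages of a fitted-parameter model on a new
#' annual N-source table without modifying the model.
#'
#' @param object An [ngtp()] model.
#' @param newdata An annual N-source table (data frame or CSV path).
#' @param type `"gtp"` (default; the decomposition over the model's
#'   horizons), `"flux"` (gas fluxes) or `"budget"` (total N input per
#'   year).
#' @param ... Unused.
#' @return A data frame (`type = "gtp"` or `"flux"`) or a numeric vector
#'   (`type = "budget"`).
#' @examples
#' m <- ngtp()
#' predict(m, anchor_records(), type = "budget")
#' @export
predict.ngtp <- function(object, newdata, type = c("gtp", "flux", "budget"),
                         ...) {
  type <- match.arg(type)
  if (is.character(newdata)) newdata <- read_n_sources(newdata)
  newdata <- validate_n_sources(newdata)
  if (type == "budget") return(total_n_input(newdata))
  fx <- annual_fluxes(newdata, object$factors)
  if (type == "flux") return(fx)
  do.call(rbind, lapply(object$horizons, function(h) {
    annual_gtp(fx, h, object$coefficients, object$policy)
  }))
}

#' @export
summary.ngtp <- function(object, ...) {
  if (is.null(object$gtp)) {
    stop("no data attached to the model; supply data to ngtp() first",
         call. = FALSE)
  }
  periods <- lapply(object$horizons, function(h) {
    period_summary(object$gtp[object$gtp$horizon == h, ])
  })
  structure(list(model = object,
                 periods = stats::setNames(periods,
                                           paste0("gtp", object$horizons))),
            class = "summary.ngtp")
}

#' @export
print.summary.ngtp <- function(x, ...) {
  print(x$model)
  cat("\n")
  for (p in x$periods) print(p)
  invisible(x)
}

#' Plot the net GTP trajectory of a model
#'
#' Base-graphics view of annual net GTP (and optionally the warming and
#' cooling totals) against year, one panel per horizon.
#'
#' @param x An [ngtp()] model with data attached.
#' @param components Logical; also draw the warming and cooling totals.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ngtp <- function(x, components = FALSE, ...) {
  if (is.null(x$gtp)) {
    stop("no data attached to the model", call. = FALSE)
  }
  hs <- x$horizons
  old <- graphics::par(mfrow = c(1, length(hs)))
  on.exit(graphics::par(old))
  for (h in hs) {
    g <- x$gtp[x$gtp$horizon == h, ]
    ylim <- range(0, g$net, if (components) c(g$warming_total,
                                              -g$cooling_total))
    graphics::plot(g$year, g$net, type = "l", lwd = 2, ylim = ylim,
                   xlab = "Year", ylab = "Tg CO2e",
                   main = sprintf("Net GTP%d of N use", h), ...)
    if (components) {
      graphics::lines(g$year, g$warming_total, lty = 2, col = "red3")
      graphics::lines(g$year, -g$cooling_total, lty = 2, col = "blue3")
      graphics::legend("topleft", bty = "n", lty = c(1, 2, 2), lwd = c(2, 1, 1),
                       col = c("black", "red3", "blue3"),
                       legend = c("net", "warming", "cooling (negated)"))
    }
    graphics::abline(h = 0, col = "grey70")
  }
  invisible(x)
}

#' Simulate synthetic annual N-source series from a model
#'
#' Draws FAOSTAT-like annual series from the synthetic generator (see
#' [generate_series()]), anchored by default at the published 1961/2010
#' records. Each simulation gets its own sub-seed, so the whole draw is
#' reproducible from `seed`.
#'
#' @param object An [ngtp()] model (its parameters are not used by the
#'   generator but keep the call generic-compatible).
#' @param nsim Number of series to draw.
#' @param seed Integer seed; when `NULL` the spec's own seed is used for the
#'   first draw.
#' @param spec A [series_spec()]; its `seed` field is overridden per draw.
#' @param ... Unused.
#' @return A list of `nsim` `ngtp_sources` data frames.
#' @export
simulate.ngtp <- function(object, nsim = 1, seed = NULL,
                          spec = series_spec(), ...) {
  base_seed <- if (is.null(seed)) spec$seed else as.integer(seed)
  lapply(seq_len(nsim), function(i) {
    spec$seed <- base_seed + i - 1L
    generate_series(spec)
  })
}
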