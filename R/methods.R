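#' @export
print.gmediate <- function(x, ...) {
  cat("Interventional mediation analysis (parametric g-computation)\n")
  cat("  persons:", x$n_persons, "  periods:", x$n_periods,
      "  MC runs:", x$config$n_mc_runs, "\n")
  cat("  selection:", x$config$selection, "\n")
  fin <- x$effects[x$effects$stratum == "overall" &
                     x$effects$period == x$n_periods, ]
  cat(sprintf("  final-horizon risks: always %.1f%%, never %.1f%% (RD %.1f pp",
              100 * fin$risk_always, 100 * fin$risk_never, fin$rd))
  if (!is.na(fin$rr)) cat(sprintf(", RR %.2f", fin$rr))
  cat(")\n")
  if ("ie_pct_all" %in% names(fin) && !is.na(fin$ie_pct_all))
    cat(sprintf("  overall indirect effect: %.1f%% of the overall effect\n",
                fin$ie_pct_all))
  invisible(x)
}

#' Summarize an interventional mediation fit
#'
#' Formats risks, risk differences/ratios and indirect-effect percentages
#' at the yearly horizons (risks and RD to 1 decimal of a percent, RR to 2
#' decimals, indirect effects to 1 decimal), per stratum.
#'
#' @param object a `gmediate` fit.
#' @param ... unused.
#' @return A `data.frame` (class `summary.gmediate`) of the rounded
#'   quantities at yearly horizons; full precision stays in
#'   `object$effects`.
#' @export
summary.gmediate <- function(object, ...) {
  eff <- object$effects[!is.na(object$effects$year), , drop = FALSE]
  out <- data.frame(stratum = eff$stratum, year = eff$year,
                    risk_always = round(100 * eff$risk_always, 1),
                    risk_never = round(100 * eff$risk_never, 1),
                    rd = round(eff$rd, 1), rr = round(eff$rr, 2),
                    stringsAsFactors = FALSE)
  for (col in grep("^ie_pct_", names(eff), value = TRUE))
    out[[col]] <- round(eff[[col]], 1)
  class(out) <- c("summary.gmediate", "data.frame")
  out
}

#' @export
print.summary.gmediate <- function(x, ...) {
  cat("Interventional effects by follow-up year",
      "(risks and RD in %, indirect effects in % of the overall effect)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gmediate <- function(object, response = NULL, ...) {
  mm <- object$models$models
  if (!is.null(response)) mm <- mm[response]
  lapply(mm, function(per_t)
    lapply(per_t, function(e) if (is.null(e)) NULL else e$coef))
}

#' Plot counterfactual cumulative risk curves
#'
#' Base-graphics plot of the averaged cumulative mortality risk per period
#' for each simulated scenario of one stratum.
#'
#' @param x a `gmediate` fit.
#' @param stratum stratum label (default `"overall"`).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gmediate <- function(x, stratum = "overall", ...) {
  curves <- x$curves[[stratum]]
  if (is.null(curves)) stop("unknown stratum: ", stratum)
  np <- length(curves[[1L]]$risk)
  m <- 100 * vapply(curves, `[[`, numeric(np), "risk")
  graphics::matplot(seq_len(np), m, type = "l", lty = 1,
                    xlab = "period (half-years)",
                    ylab = "cumulative mortality (%)",
                    main = paste("Counterfactual risk curves,", stratum),
                    ...)
  graphics::legend("topleft", legend = colnames(m), lty = 1,
                   col = seq_len(ncol(m)), bty = "n", cex = 0.8)
  invisible(x)
}

#' Predict counterfactual risks for a new baseline population
#'
#' Re-simulates the fitted models under a scenario for new baseline
#' covariates.
#'
#' @param object a `gmediate` fit.
#' @param newdata baseline covariate `data.frame`.
#' @param scenario a `med_scenario` (default: always exposed).
#' @param n_mc_runs,seed simulation controls.
#' @param ... unused.
#' @return A `risk_curve`.
#' @export
predict.gmediate <- function(object, newdata,
                             scenario = scenario_always(),
                             n_mc_runs = object$config$n_mc_runs,
                             seed = object$seed, ...) {
  run_scenarios(object$models, newdata, list(scenario),
                n_mc_runs = n_mc_runs, seed = seed)$curves[[scenario$name]]
}
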