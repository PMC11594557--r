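#' Interventional overall effect at a follow-up horizon
#'
#' Contrast of cumulative mortality between the always-exposed and
#' never-exposed scenarios at a yearly horizon (year y is period 2y on the
#' half-year grid): the risk difference in percentage points,
#' `RD = 100 * (risk_A - risk_B)`, and the risk ratio
#' `RR = risk_A / risk_B` (undefined and flagged when `risk_B = 0`).
#' Scalar risks may be passed directly, in which case `year` is ignored.
#'
#' @param risk_a,risk_b `risk_curve`s (always / never exposed) or scalar
#'   risks.
#' @param year follow-up year at which to evaluate curve inputs.
#' @return List with `risk_a`, `risk_b`, `rd` (percentage points), `rr`,
#'   `year` and `rr_defined`.
#' @examples
#' overall_effect(0.065, 0.053)  # rd = 1.2 pp, rr = 1.23
#' @export
overall_effect <- function(risk_a, risk_b, year = NULL) {
  ra <- risk_at(risk_a, year)
  rb <- risk_at(risk_b, year)
  rr_def <- rb > 0
  list(risk_a = ra, risk_b = rb, rd = 100 * (ra - rb),
       rr = if (rr_def) ra / rb else NA_real_,
       year = if (is.null(year)) NA_integer_ else year,
       rr_defined = rr_def)
}

risk_at <- function(x, year) {
  if (inherits(x, "risk_curve")) {
    if (is.null(year)) stop("year required for a risk curve")
    p <- 2L * year
    if (p < 1L || p > length(x$risk))
      stop("year ", year, " outside the follow-up horizon")
    return(x$risk[p])
  }
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x <= 1)
  x
}

#' Interventional indirect effect as a percentage of the overall effect
#'
#' `100 * (risk_A - risk_shifted) / (risk_A - risk_B)`: the percentage of
#' the overall effect removed by shifting the mediator distribution(s) to
#' their never-exposed conditionals (scenario C for all mediators jointly,
#' scenario D for a single mediator). Undefined (flagged `NA`) when the
#' overall-effect denominator is below `floor` in absolute value, as at
#' early horizons where the scenario risks have not yet separated.
#'
#' @param risk_a,risk_b,risk_shifted `risk_curve`s or scalar risks.
#' @param year follow-up year for curve inputs.
#' @param floor minimum `|risk_A - risk_B|` for a defined ratio.
#' @return Percentage (scalar), `NA` with attribute `reason` when
#'   undefined.
#' @export
indirect_effect_pct <- function(risk_a, risk_b, risk_shifted, year = NULL,
                                floor = 1e-6) {
  ra <- risk_at(risk_a, year)
  rb <- risk_at(risk_b, year)
  rs <- risk_at(risk_shifted, year)
  if (abs(ra - rb) < floor)
    return(structure(NA_real_, reason = "overall effect below floor"))
  100 * (ra - rs) / (ra - rb)
}

## ---- main estimator -------------------------------------------------------

#' Interventional mediation analysis by parametric g-computation
#'
#' The central estimator: fits the per-interval logistic models on a
#' person-period panel ([fit_models()]), forward-simulates the
#' counterfactual scenarios — always exposed (A), never exposed (B), all
#' mediators shifted (C), and each mediator shifted singly (D) — on the
#' panel's baseline population ([run_scenarios()]), and assembles per-period
#' risks, overall effects and indirect-effect percentages. With `strata`,
#' the entire pipeline (model fitting included) is rerun within each
#' stratum in addition to the overall analysis.
#'
#' @param panel person-period panel (from [build_panel()] or
#'   [generate_cohort()]).
#' @param registry condition registry (default: attached to panel).
#' @param selection model selection mode, see [fit_models()].
#' @param include_interactions stepwise interaction screening flag.
#' @param contemporaneous sensitivity option: exposure at t as candidate in
#'   other conditions' onset models at t.
#' @param min_events sparse-cell threshold, see [fit_models()].
#' @param n_mc_runs Monte Carlo runs to average (default 4).
#' @param mc_scale baseline replication factor per run.
#' @param scenarios optional scenario list (default: full A/B/C/D battery).
#' @param strata character vector among `"sex"`, `"age_group"`; `NULL` for
#'   the overall analysis only.
#' @param crn share uniform draws across scenarios within each Monte Carlo
#'   run (common random numbers; cancels simulation noise in scenario
#'   contrasts such as indirect-effect percentages; default `FALSE`,
#'   independent draws per scenario).
#' @param seed integer master seed.
#' @param warm optional `med_model_set` seeding the optimizer, see
#'   [fit_models()]; used internally by [gmediate_boot()].
#' @param tol optimizer convergence tolerance passed to [fit_models()].
#' @return Object of class `gmediate`: components `models`, `curves`
#'   (per stratum, named list of `risk_curve`s), `effects` (long-format
#'   `data.frame`: stratum, period, year, risks, `rd`, `rr`, and one
#'   `ie_pct_*` column per shifted scenario), `config`, `n_persons`.
#' @examples
#' panel <- generate_cohort(default_scm_params("tiny"), n = 2000, seed = 1)
#' fit <- gmediate(panel, selection = "full", n_mc_runs = 1, seed = 1)
#' summary(fit)
#' @export
gmediate <- function(panel, registry = attr(panel, "registry"),
                     selection = "stepwise_aic",
                     include_interactions = TRUE, contemporaneous = FALSE,
                     min_events = 25L, n_mc_runs = 4L, mc_scale = 1L,
                     scenarios = NULL, strata = NULL, crn = FALSE,
                     seed = 1L, warm = NULL, tol = 1e-8) {
  if (is.null(registry)) registry <- condition_registry()
  if (!nrow(panel)) stop("empty panel")
  # canonical row order: results do not depend on input row ordering
  panel <- panel[order(panel$person_id, panel$t), , drop = FALSE]
  if (!is.null(strata) &&
      !all(strata %in% c("sex", "age_group")))
    stop("strata must be among 'sex', 'age_group'")
  cfg <- list(selection = selection,
              include_interactions = include_interactions,
              contemporaneous = contemporaneous, min_events = min_events,
              n_mc_runs = n_mc_runs, mc_scale = mc_scale,
              strata = strata, crn = crn, seed = seed)
  n_periods <- max(panel$t)

  run_one <- function(sub, label) {
    models <- fit_models(sub, registry, selection = selection,
                         include_interactions = include_interactions,
                         contemporaneous = contemporaneous,
                         min_events = min_events, n_periods = n_periods,
                         warm = if (label == "overall") warm, tol = tol)
    baseline <- sub[sub$t == 1L,
                    c("sex", "age_at_enrollment", "age_group",
                      "population_group"), drop = FALSE]
    sc <- if (is.null(scenarios)) default_scenarios(registry) else scenarios
    nms <- vapply(sc, `[[`, "", "name")
    if (!all(c("always", "never") %in% nms))
      stop("scenario battery must include 'always' and 'never'")
    risks <- run_scenarios(models, baseline, sc, n_mc_runs = n_mc_runs,
                           mc_scale = mc_scale, crn = crn,
                           seed = derive_seed(seed, "stratum", label))
    list(label = label, models = models, risks = risks,
         effects = effects_table(risks$curves, registry, label))
  }

  overall <- run_one(panel, "overall")
  strata_runs <- list()
  if (!is.null(strata)) {
    key <- interaction(panel[strata], drop = TRUE, sep = ":")
    for (lev in levels(key)) {
      sub <- panel[key == lev, , drop = FALSE]
      if (!any(sub$death == 1)) {
        warning("stratum ", lev, " has no deaths; estimates undefined")
        next
      }
      strata_runs[[lev]] <- run_one(sub, lev)
    }
  }

  effects <- do.call(rbind, c(list(overall$effects),
                              lapply(strata_runs, `[[`, "effects")))
  rownames(effects) <- NULL
  structure(list(call = match.call(), registry = registry, config = cfg,
                 models = overall$models,
                 curves = c(list(overall = overall$risks$curves),
                            lapply(strata_runs, function(r) r$risks$curves)),
                 effects = effects,
                 n_persons = length(unique(panel$person_id)),
                 n_periods = n_periods, seed = seed),
            class = "gmediate")
}

# Long-format effects table from a named list of averaged risk curves.
effects_table <- function(curves, registry, label) {
  np <- length(curves[["always"]]$risk)
  shifted <- setdiff(names(curves), c("always", "never"))
  out <- data.frame(stratum = label, period = seq_len(np),
                    year = ifelse(seq_len(np) %% 2L == 0L,
                                  seq_len(np) / 2, NA),
                    risk_always = curves[["always"]]$risk,
                    risk_never = curves[["never"]]$risk,
                    stringsAsFactors = FALSE)
  out$rd <- 100 * (out$risk_always - out$risk_never)
  out$rr <- ifelse(out$risk_never > 0,
                   out$risk_always / out$risk_never, NA_real_)
  for (s in shifted) {
    col <- paste0("ie_pct_", sub("^shift_", "", s))
    denom <- out$risk_always - out$risk_never
    out[[col]] <- ifelse(abs(denom) < 1e-6, NA_real_,
                         100 * (out$risk_always - curves[[s]]$risk) / denom)
  }
  out
}

## ---- bootstrap ------------------------------------------------------------

#' Cluster bootstrap confidence intervals for all reported quantities
#'
#' Nonparametric bootstrap resampling whole persons with replacement (all of
#' a person's rows travel together), rerunning the full estimation pipeline
#' — model fitting included — on every replicate, and taking percentile
#' 2.5/97.5 bounds of each reported quantity. Replicates that fail (e.g.
#' empty risk sets) are recorded and excluded; more than 20% failures
#' aborts.
#'
#' @param panel person-period panel.
#' @param ... arguments passed on to [gmediate()] (selection, scenarios,
#'   `n_mc_runs`, ...). Stratified bootstrap is not supported; run strata
#'   separately.
#' @param n_boot number of bootstrap replicates (>= 2; default 200).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @param fast labeled fast mode: replicate refits are warm-started from the
#'   point estimate and use a relaxed optimizer tolerance (1e-6); with
#'   `selection = "full"` the fitted term lists are identical by
#'   construction, so only the iteration path changes. Default `FALSE`
#'   (full-rigor refits).
#' @return Object of class `gmediate_boot`: `point` (the [gmediate()] fit on
#'   the original panel), `ci` (data.frame of lower/upper bounds per
#'   stratum/period/quantity), `replicates` (matrix, one row per successful
#'   replicate), `n_fail`.
#' @export
gmediate_boot <- function(panel, ..., n_boot = 200L, seed = 1L,
                          level = 0.95, fast = FALSE) {
  stopifnot(n_boot >= 2L)
  point <- gmediate(panel, ..., seed = derive_seed(seed, "point"))
  ids <- sort(unique(panel$person_id))
  idx_by_person <- split(seq_len(nrow(panel)), panel$person_id)
  idx_by_person <- idx_by_person[match(as.character(ids),
                                       names(idx_by_person))]
  stat_names <- effects_stat_names(point$effects)
  reps <- matrix(NA_real_, n_boot, length(stat_names),
                 dimnames = list(NULL, stat_names))
  n_fail <- 0L
  fail_msgs <- character(0)
  set.seed(derive_seed(seed, "resample"))
  draw_ids <- replicate(n_boot,
                        sample.int(length(ids), replace = TRUE),
                        simplify = FALSE)
  for (b in seq_len(n_boot)) {
    take <- idx_by_person[draw_ids[[b]]]
    rows <- unlist(take, use.names = FALSE)
    rep_panel <- panel[rows, , drop = FALSE]
    rep_panel$person_id <- rep(seq_along(take), lengths(take))
    attr(rep_panel, "registry") <- attr(panel, "registry")
    res <- tryCatch(
      gmediate(rep_panel, ..., seed = derive_seed(seed, "boot", b),
               warm = point$models,
               tol = if (fast) 1e-6 else 1e-8),
      error = function(e) e)
    if (inherits(res, "error")) {
      n_fail <- n_fail + 1L
      fail_msgs <- c(fail_msgs, conditionMessage(res))
      next
    }
    v <- effects_stat_vector(res$effects)
    reps[b, names(v)] <- v
  }
  if (n_fail > 0.2 * n_boot)
    stop("more than 20% of bootstrap replicates failed (", n_fail, "/",
         n_boot, "): ", fail_msgs[1L])
  reps <- reps[rowSums(!is.na(reps)) > 0L, , drop = FALSE]
  alpha <- (1 - level) / 2
  ci <- t(apply(reps, 2L, stats::quantile,
                probs = c(alpha, 1 - alpha), na.rm = TRUE, type = 7))
  ci_df <- data.frame(quantity = rownames(ci), lower = ci[, 1L],
                      upper = ci[, 2L], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(point = point, ci = ci_df, replicates = reps,
                 n_boot = n_boot, n_fail = n_fail, level = level,
                 fast = fast, seed = seed),
            class = "gmediate_boot")
}

# Flatten an effects table to a named statistic vector (and its names).
effects_stat_vector <- function(eff) {
  qcols <- setdiff(names(eff), c("stratum", "period", "year"))
  m <- as.matrix(eff[qcols])
  nm <- as.vector(t(outer(paste(eff$stratum, eff$period, sep = "."),
                          qcols, paste, sep = ".")))
  stats::setNames(as.vector(t(m)), nm)
}

effects_stat_names <- function(eff) names(effects_stat_vector(eff))

#' @export
print.gmediate_boot <- function(x, ...) {
  cat("Cluster bootstrap:", nrow(x$replicates), "successful replicates",
      paste0("(", x$n_fail, " failed)"),
      if (isTRUE(x$fast)) "[fast mode]" else "", "\n")
  print(x$point)
  invisible(x)
}

#' @export
confint.gmediate_boot <- function(object, parm, level = 0.95, ...) {
  object$ci
}
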