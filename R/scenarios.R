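#' Counterfactual scenario definitions
#'
#' A scenario fixes the exposure trajectory for every simulated individual
#' (constant 0 or 1 over follow-up) and optionally overrides the exposure
#' value fed into specific mediator models from a shift-start period onward.
#' The built-ins reproduce the four scenario types of the interventional
#' effects analysis:
#' \describe{
#'   \item{A — `scenario_always()`}{exposure 1 throughout; mediators and
#'     confounders drawn from their models under exposure 1.}
#'   \item{B — `scenario_never()`}{exposure 0 throughout.}
#'   \item{C — `scenario_shift_all(registry)`}{exposure 1, but from period 2
#'     onward every mediator model receives exposure input 0, so mediators
#'     are drawn from the conditional distributions that would prevail
#'     without exposure, given survival to the previous period within the
#'     scenario. Confounder models keep exposure input 1; the mediator shift
#'     still flows into confounders and other mediators at t + 1 through the
#'     lagged state.}
#'   \item{D_m — `scenario_shift_one(m)`}{as C but overriding only mediator
#'     `m`'s model.}
#' }
#' Overrides may target mediator models only — never the death model nor the
#' confounder models.
#'
#' @param name scenario label.
#' @param exposure constant exposure value, 0 or 1.
#' @param overrides named numeric vector: mediator name -> exposure value
#'   substituted into that mediator's model.
#' @param shift_start first period at which overrides apply (default 2; at
#'   period 1 onset models have no exposure input under the lag assumption).
#' @return An object of class `med_scenario`.
#' @export
scenario_definition <- function(name, exposure, overrides = numeric(0),
                                shift_start = 2L) {
  stopifnot(exposure %in% c(0, 1), shift_start >= 1L)
  if (length(overrides) && (is.null(names(overrides)) ||
                            !all(nzchar(names(overrides)))))
    stop("overrides must be a named vector (mediator -> exposure value)")
  structure(list(name = name, exposure = exposure,
                 overrides = overrides,
                 shift_start = as.integer(shift_start)),
            class = "med_scenario")
}

#' @rdname scenario_definition
#' @export
scenario_always <- function() scenario_definition("always", 1)

#' @rdname scenario_definition
#' @export
scenario_never <- function() scenario_definition("never", 0)

#' @rdname scenario_definition
#' @param registry condition registry supplying the mediator list.
#' @export
scenario_shift_all <- function(registry = condition_registry()) {
  scenario_definition("shift_all", 1,
                      stats::setNames(rep(0, length(registry$mediators)),
                                      registry$mediators))
}

#' @rdname scenario_definition
#' @param mediator single mediator whose model is shifted.
#' @export
scenario_shift_one <- function(mediator) {
  scenario_definition(paste0("shift_", mediator), 1,
                      stats::setNames(0, mediator))
}

#' @export
print.med_scenario <- function(x, ...) {
  cat("Scenario", x$name, "- exposure =", x$exposure)
  if (length(x$overrides))
    cat(", overrides [", paste(names(x$overrides), "->", x$overrides,
                               collapse = ", "),
        "] from t =", x$shift_start)
  cat("\n")
  invisible(x)
}

# The standard scenario battery: A, B, C and one D per mediator.
default_scenarios <- function(registry) {
  sc <- list(scenario_always(), scenario_never(),
             scenario_shift_all(registry))
  for (m in registry$mediators) sc <- c(sc, list(scenario_shift_one(m)))
  stats::setNames(sc, vapply(sc, `[[`, "", "name"))
}

#' Simulate a counterfactual scenario by parametric g-computation
#'
#' Forward Monte Carlo simulation of every baseline individual through the
#' fitted (or true) per-interval models under a scenario: exposure fixed to
#' the scenario value at every period; each not-yet-present condition drawn
#' from its period-t model evaluated on the simulated history, with the
#' scenario's override substituted for the exposure input of shifted
#' mediator models from the shift-start period; conditions carry forward;
#' death drawn from the period-t death model on the full time-t state (with
#' the scenario exposure, never overridden); death absorbs; censoring is
#' switched off entirely.
#'
#' @param models a `med_model_set` (fitted, or a truth via
#'   [as_model_set()]).
#' @param baseline `data.frame` of baseline covariates (`sex`,
#'   `age_at_enrollment` or `age_group`, `population_group`), one row per
#'   simulated individual.
#' @param scenario a `med_scenario`.
#' @param seed integer seed.
#' @param uniforms optional pre-drawn uniforms (from [draw_uniforms()]) for
#'   common-random-number comparisons across scenarios; overrides `seed`.
#' @return An object of class `risk_curve`: cumulative mortality risk per
#'   period.
#' @export
simulate_scenario <- function(models, baseline, scenario, seed = 1L,
                              uniforms = NULL) {
  stopifnot(inherits(models, "med_model_set"),
            inherits(scenario, "med_scenario"))
  reg <- models$registry
  bad <- setdiff(names(scenario$overrides), reg$mediators)
  if (length(bad))
    stop("overrides may target mediator models only: ",
         paste(bad, collapse = ", "))
  n <- nrow(baseline)
  if (!n) stop("baseline must be nonempty")
  if (!"age_group" %in% names(baseline))
    baseline$age_group <- age_group_of(baseline$age_at_enrollment)
  B <- baseline_design(baseline)
  conds <- reg$conditions
  expo <- reg$exposure
  expo_cur <- paste0(expo, "_cur")
  a <- scenario$exposure
  if (is.null(uniforms)) set.seed(derive_seed(seed, "simulate",
                                              scenario$name))

  S <- matrix(0L, n, length(conds), dimnames = list(NULL, conds))
  S[, expo] <- as.integer(a)
  alive <- rep(TRUE, n)
  risk <- numeric(models$n_periods)
  dead_total <- 0L

  u <- function(t, response) {
    if (is.null(uniforms)) stats::runif(n)
    else uniforms[[t]][[response]]
  }

  for (t in seq_len(models$n_periods)) {
    Sprev <- S
    for (cn in setdiff(conds, expo)) {
      entry <- models$models[[cn]][[t]]
      if (is.null(entry)) stop("no model for ", cn, " at t = ", t)
      # full-length uniform draw keeps the stream identical whatever the
      # state; probabilities are only evaluated on the at-risk rows
      uu <- u(t, cn)
      at_risk <- which(alive & Sprev[, cn] == 0L)
      if (!length(at_risk)) next
      # exposure input seen by this condition's model
      ov <- scenario$overrides
      x_in <- if (cn %in% names(ov) && t >= scenario$shift_start)
        ov[[cn]] else a
      get_col <- function(nm) {
        if (nm == expo || nm == expo_cur)
          return(rep.int(x_in, length(at_risk)))
        if (nm %in% colnames(B)) return(B[at_risk, nm])
        if (nm %in% conds) return(Sprev[at_risk, nm])
        if (nm == "period") return(rep.int(as.numeric(t), length(at_risk)))
        stop("missing covariate in simulation: ", nm)
      }
      p <- entry_prob(entry, get_col, length(at_risk))
      S[at_risk, cn] <- as.integer(uu[at_risk] < p)
    }
    dentry <- models$models[[reg$outcome]][[t]]
    if (is.null(dentry)) stop("no death model at t = ", t)
    uu <- u(t, reg$outcome)
    live <- which(alive)
    get_cur <- function(nm) {
      if (nm == expo) return(rep.int(as.numeric(a), length(live)))
      if (nm %in% colnames(B)) return(B[live, nm])
      if (nm %in% conds) return(S[live, nm])
      if (nm == "period") return(rep.int(as.numeric(t), length(live)))
      stop("missing covariate in simulation: ", nm)
    }
    p_d <- entry_prob(dentry, get_cur, length(live))
    died <- live[uu[live] < p_d]
    alive[died] <- FALSE
    dead_total <- dead_total + length(died)
    risk[t] <- dead_total / n
  }
  structure(list(scenario = scenario$name, risk = risk, n = n, run = NA),
            class = "risk_curve")
}

#' @export
print.risk_curve <- function(x, digits = 4, ...) {
  cat("Cumulative mortality risk, scenario", x$scenario,
      if (!is.na(x$n)) paste0("(n = ", x$n, ")"), "\n")
  print(round(stats::setNames(x$risk, seq_along(x$risk)), digits))
  invisible(x)
}

#' Pre-draw shared uniforms for common-random-number comparisons
#'
#' One uniform per (individual, period, response); passing the same object
#' to [simulate_scenario()] for several scenarios makes their Monte Carlo
#' noise cancel in contrasts.
#'
#' @param models `med_model_set` (for responses and periods).
#' @param n number of individuals.
#' @param seed integer seed.
#' @return Nested list `[[t]][[response]]` of uniform vectors.
#' @export
draw_uniforms <- function(models, n, seed) {
  set.seed(derive_seed(seed, "crn"))
  reg <- models$registry
  responses <- c(setdiff(reg$conditions, reg$exposure), reg$outcome)
  lapply(seq_len(models$n_periods), function(t)
    stats::setNames(lapply(responses, function(r) stats::runif(n)),
                    responses))
}

#' Run and average scenarios over Monte Carlo runs
#'
#' Simulates each scenario `n_mc_runs` times on the baseline population
#' (each row replicated `mc_scale` times) with independent substreams per
#' run, and averages the per-period risks across runs.
#'
#' @param models `med_model_set`.
#' @param baseline baseline covariate `data.frame`.
#' @param scenarios list of `med_scenario` (default: A, B, C and one D per
#'   mediator).
#' @param n_mc_runs Monte Carlo repetitions to average (default 4).
#' @param mc_scale replication factor of the baseline population per run.
#' @param seed integer seed.
#' @param crn use common random numbers across scenarios within a run
#'   (default `FALSE`: independent draws).
#' @return Object of class `scenario_risks`: `curves` (named list of
#'   averaged `risk_curve`s) and `runs` (per-run curves).
#' @export
run_scenarios <- function(models, baseline, scenarios = NULL,
                          n_mc_runs = 4L, mc_scale = 1L, seed = 1L,
                          crn = FALSE) {
  stopifnot(n_mc_runs >= 1L, mc_scale >= 1L)
  reg <- models$registry
  if (is.null(scenarios)) scenarios <- default_scenarios(reg)
  if (inherits(scenarios, "med_scenario")) scenarios <- list(scenarios)
  nm <- vapply(scenarios, `[[`, "", "name")
  names(scenarios) <- nm
  if (mc_scale > 1L)
    baseline <- baseline[rep(seq_len(nrow(baseline)), mc_scale), ,
                         drop = FALSE]
  runs <- vector("list", n_mc_runs)
  for (r in seq_len(n_mc_runs)) {
    us <- if (crn) draw_uniforms(models, nrow(baseline),
                                 derive_seed(seed, "run", r)) else NULL
    runs[[r]] <- lapply(scenarios, function(sc) {
      cv <- simulate_scenario(models, baseline, sc,
                              seed = derive_seed(seed, "run", r, sc$name),
                              uniforms = us)
      cv$run <- r
      cv
    })
  }
  curves <- lapply(nm, function(s) {
    rk <- rowMeans(vapply(runs, function(rr) rr[[s]]$risk,
                          numeric(models$n_periods)))
    structure(list(scenario = s, risk = rk,
                   n = nrow(baseline) * n_mc_runs, run = NA),
              class = "risk_curve")
  })
  names(curves) <- nm
  structure(list(curves = curves, runs = runs, n_mc_runs = n_mc_runs,
                 mc_scale = mc_scale, seed = seed),
            class = "scenario_risks")
}

#' Write per-scenario risk curves as CSV
#'
#' Long format with one row per (scenario, run, period): the per-run curves
#' followed by the across-run average (`run = "mean"`).
#'
#' @param x a `scenario_risks` object from [run_scenarios()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_risk_curves <- function(x, path) {
  stopifnot(inherits(x, "scenario_risks"))
  rows <- list()
  for (r in seq_along(x$runs))
    for (cv in x$runs[[r]])
      rows[[length(rows) + 1L]] <-
        data.frame(scenario = cv$scenario, run = as.character(r),
                   t = seq_along(cv$risk), risk = cv$risk)
  for (cv in x$curves)
    rows[[length(rows) + 1L]] <-
      data.frame(scenario = cv$scenario, run = "mean",
                 t = seq_along(cv$risk), risk = cv$risk)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.scenario_risks <- function(x, digits = 4, ...) {
  np <- length(x$curves[[1]]$risk)
  m <- t(vapply(x$curves, `[[`, numeric(np), "risk"))
  colnames(m) <- seq_len(np)
  cat("Averaged cumulative mortality risks (", x$n_mc_runs,
      " MC run(s))\n", sep = "")
  print(round(m, digits))
  invisible(x)
}
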