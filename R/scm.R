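#' Parameters of the generative structural causal model
#'
#' A fully specified discrete-time structural causal model over the registry's
#' conditions: logistic initial-state models (period 1, baseline covariates
#' only), logistic transition models applied while a condition is undiagnosed
#' (covariates: baseline plus all condition indicators at t-1, plus the
#' exposure at t when `contemporaneous_exposure` is on), a logistic death
#' model on the full time-t state, and a censoring hazard (intercept-only by
#' default, i.e. noninformative). Conditions are chronic: once diagnosed, an
#' indicator stays 1. The model is the ground truth behind the synthetic
#' cohort generator and the two validation oracles.
#'
#' Coefficient vectors are named; allowed names are `"(Intercept)"`, the
#' baseline design terms (`female`, `age40`, `pop_*`), condition names
#' (meaning the lagged indicator in transition models and the current
#' indicator in the death model), and `"<exposure>_cur"` for the
#' contemporaneous-exposure option.
#'
#' @param registry a [condition_registry()].
#' @param n_periods number of discrete periods (default 16, i.e. 8 years of
#'   half-year intervals).
#' @param init named list: condition -> named coefficient vector over baseline
#'   terms (period-1 prevalence model).
#' @param trans named list: condition -> named coefficient vector over
#'   baseline terms and lagged condition indicators.
#' @param death named coefficient vector over baseline terms and current
#'   condition indicators.
#' @param censor named coefficient vector for the per-period censoring hazard.
#' @param baseline list with elements `p_female`, `p_age40`, `pop_probs`
#'   (named over population groups), `age_mean`, `age_sd`.
#' @param contemporaneous_exposure if `TRUE`, condition transition models may
#'   include the exposure measured in the same period (`"<exposure>_cur"`).
#' @param seed default seed stored with the parameters.
#' @return An object of class `scm_params`.
#' @seealso [default_scm_params()] for ready-made presets.
#' @export
scm_params <- function(registry, n_periods, init, trans, death, censor,
                       baseline, contemporaneous_exposure = FALSE,
                       seed = 1L) {
  stopifnot(inherits(registry, "med_registry"), n_periods >= 1)
  conds <- registry$conditions
  expo_cur <- paste0(registry$exposure, "_cur")
  chk <- function(coefs, allowed, what) {
    if (is.null(names(coefs)) || !all(nzchar(names(coefs))))
      stop("unnamed coefficients in ", what)
    slopes <- coefs[setdiff(names(coefs), "(Intercept)")]
    if (!all(is.finite(slopes)) || anyNA(coefs))
      stop("non-finite coefficients in ", what)
    bad <- setdiff(names(coefs), allowed)
    if (length(bad))
      stop("unknown terms in ", what, ": ", paste(bad, collapse = ", "))
  }
  base_allowed <- c("(Intercept)", baseline_terms())
  trans_allowed <- c(base_allowed, conds,
                     if (contemporaneous_exposure) expo_cur)
  if (!setequal(names(init), conds) || !setequal(names(trans), conds))
    stop("init and trans must have one entry per non-outcome condition")
  for (cn in conds) {
    chk(init[[cn]], base_allowed, paste0("init$", cn))
    chk(trans[[cn]], trans_allowed, paste0("trans$", cn))
  }
  chk(death, c(base_allowed, conds), "death")
  chk(censor, c(base_allowed, conds), "censor")
  if (!contemporaneous_exposure) {
    for (cn in conds)
      if (expo_cur %in% names(trans[[cn]]))
        stop("contemporaneous exposure term present but option is off")
  }
  stopifnot(is.numeric(baseline$p_female), is.numeric(baseline$p_age40),
            abs(sum(baseline$pop_probs) - 1) < 1e-8,
            setequal(names(baseline$pop_probs), POP_LEVELS))
  structure(list(registry = registry, n_periods = as.integer(n_periods),
                 init = init[conds], trans = trans[conds], death = death,
                 censor = censor, baseline = baseline,
                 contemporaneous_exposure = isTRUE(contemporaneous_exposure),
                 seed = as.integer(seed)),
            class = "scm_params")
}

#' @export
print.scm_params <- function(x, ...) {
  cat("Structural causal model parameters\n")
  cat("  conditions:", paste(x$registry$conditions, collapse = ", "), "\n")
  cat("  periods:   ", x$n_periods, "\n")
  cat("  contemporaneous exposure:", x$contemporaneous_exposure, "\n")
  invisible(x)
}

#' Ready-made generative model presets
#'
#' Four presets of the generative truth used throughout testing and
#' validation:
#' \describe{
#'   \item{`paperlike`}{full default registry (MDD exposure, six disease
#'     mediators, two time-dependent confounders), 16 half-year periods,
#'     coefficients coarsely calibrated so that the cohort composition
#'     resembles a large South African insured population: about 52% female,
#'     about 44% aged 40+, about 15% ever diagnosed with the exposure during
#'     follow-up, 8-year counterfactual mortality risk in the mid single
#'     digits, and end-of-follow-up disease prevalences of a few to thirty
#'     percent.}
#'   \item{`null_exposure`}{`paperlike` with every exposure coefficient set
#'     to zero in every model: the sharp null, no effect pathway at all.}
#'   \item{`null_mediation`}{`paperlike` with exposure coefficients zeroed in
#'     all mediator and confounder models but a nonzero exposure coefficient
#'     kept in the death model: a pure direct effect, nothing mediated.}
#'   \item{`tiny`}{one mediator (`cvd`), one confounder (`hypertension`),
#'     3 periods, large hazards; small enough for exact enumeration of the
#'     full state space.}
#' }
#'
#' @param preset one of `"paperlike"`, `"null_exposure"`, `"null_mediation"`,
#'   `"tiny"`.
#' @param seed default seed stored with the parameters.
#' @return An object of class `scm_params`.
#' @examples
#' p <- default_scm_params("tiny")
#' p$n_periods
#' @export
default_scm_params <- function(preset = c("paperlike", "null_exposure",
                                          "null_mediation", "tiny"),
                               seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "tiny") return(tiny_scm(seed))
  p <- paperlike_scm(seed)
  if (preset == "null_exposure") {
    for (cn in p$registry$conditions)
      p$trans[[cn]]["mdd"] <- 0
    p$death["mdd"] <- 0
  } else if (preset == "null_mediation") {
    for (cn in c(p$registry$mediators, p$registry$confounders))
      p$trans[[cn]]["mdd"] <- 0
  }
  p
}

# Coefficients coarsely calibrated against published cohort margins:
# ~52% female, 44% aged 40+, ~15% ever exposed, end-of-follow-up disease
# prevalences (HIV 8%, TB 2%, diabetes/CKD 13%, CVD 10%, chronic respiratory
# 10%, cancer 4%, hypertension 30%, anxiety 17%), ~3.5% deaths under a
# median follow-up of ~3 years, 8-year counterfactual risks near 5-6%.
paperlike_scm <- function(seed = 1L) {
  reg <- condition_registry()
  b <- function(...) c(...)
  init <- list(
    mdd = b("(Intercept)" = -3.55, female = 0.55, age40 = 0.15,
            pop_white = 0.55, pop_unknown = -0.10),
    hypertension = b("(Intercept)" = -3.10, female = 0.05, age40 = 1.70,
                     pop_white = 0.15),
    anxiety = b("(Intercept)" = -3.30, female = 0.50, age40 = 0.20,
                pop_white = 0.45),
    hiv = b("(Intercept)" = -3.10, female = 0.25, age40 = 0.10,
            pop_white = -1.60, pop_indian_asian = -1.00, pop_unknown = -0.40),
    tb = b("(Intercept)" = -5.40, female = -0.15, age40 = 0.20,
           pop_white = -1.00),
    diabetes_ckd = b("(Intercept)" = -4.10, female = -0.05, age40 = 1.60,
                     pop_indian_asian = 0.60),
    cvd = b("(Intercept)" = -4.40, female = -0.15, age40 = 1.70),
    chronic_respiratory = b("(Intercept)" = -3.50, female = 0.10,
                            age40 = 0.50),
    cancer = b("(Intercept)" = -5.30, female = 0.10, age40 = 1.40,
               pop_white = 0.30)
  )
  trans <- list(
    mdd = b("(Intercept)" = -5.00, female = 0.55, age40 = 0.10,
            pop_white = 0.55, anxiety = 1.10, hypertension = 0.25,
            cvd = 0.30, cancer = 0.40, chronic_respiratory = 0.25),
    hypertension = b("(Intercept)" = -4.20, female = 0.05, age40 = 1.60,
                     mdd = 0.25, diabetes_ckd = 0.70, cvd = 0.60,
                     anxiety = 0.20),
    anxiety = b("(Intercept)" = -4.50, female = 0.45, age40 = 0.15,
                mdd = 0.80, pop_white = 0.40, cvd = 0.25,
                chronic_respiratory = 0.25),
    hiv = b("(Intercept)" = -4.90, female = 0.25, age40 = -0.10,
            pop_white = -1.60, pop_indian_asian = -1.00, pop_unknown = -0.40,
            mdd = 0.08, tb = 1.20),
    tb = b("(Intercept)" = -6.40, female = -0.15, age40 = 0.15,
           pop_white = -1.00, mdd = 0.12, hiv = 1.70,
           chronic_respiratory = 0.50),
    diabetes_ckd = b("(Intercept)" = -5.40, female = -0.05, age40 = 1.50,
                     pop_indian_asian = 0.60, mdd = 0.10,
                     hypertension = 0.90, cvd = 0.40),
    cvd = b("(Intercept)" = -5.80, female = -0.15, age40 = 1.70, mdd = 0.15,
            hypertension = 0.90, diabetes_ckd = 0.60, anxiety = 0.15),
    chronic_respiratory = b("(Intercept)" = -5.10, female = 0.10,
                            age40 = 0.50, mdd = 0.12, tb = 0.80,
                            anxiety = 0.20),
    cancer = b("(Intercept)" = -6.50, female = 0.10, age40 = 1.40,
               pop_white = 0.30, mdd = 0.09, chronic_respiratory = 0.25)
  )
  death <- b("(Intercept)" = -8.25, female = -0.30, age40 = 1.95,
             mdd = 0.12, hiv = 1.20, tb = 1.50, diabetes_ckd = 0.90,
             cvd = 1.05, chronic_respiratory = 0.70, cancer = 1.80,
             hypertension = 0.30, anxiety = 0.10)
  censor <- b("(Intercept)" = stats::qlogis(0.10))
  baseline <- list(p_female = 0.517, p_age40 = 0.444,
                   pop_probs = c(black_african = 0.517,
                                 mixed_ancestry = 0.064, white = 0.181,
                                 indian_asian = 0.045, unknown = 0.193),
                   age_mean = 39.3, age_sd = 15.3)
  scm_params(reg, 16L, init, trans, death, censor, baseline, FALSE, seed)
}

# One mediator, one confounder, 3 periods, large hazards: the full state
# space (baseline strata x 2^2 condition states x 3 periods) is exactly
# enumerable, which makes this the workhorse for oracle cross-checks.
tiny_scm <- function(seed = 1L) {
  reg <- condition_registry(exposure = "mdd", mediators = "cvd",
                            confounders = "hypertension")
  init <- list(
    mdd = c("(Intercept)" = stats::qlogis(0.10), female = 0.40),
    hypertension = c("(Intercept)" = stats::qlogis(0.15), age40 = 1.00),
    cvd = c("(Intercept)" = stats::qlogis(0.08), female = -0.20,
            age40 = 0.80)
  )
  trans <- list(
    mdd = c("(Intercept)" = stats::qlogis(0.05), female = 0.40,
            hypertension = 0.30),
    hypertension = c("(Intercept)" = stats::qlogis(0.08), age40 = 0.80,
                     mdd = 0.40, cvd = 0.50),
    cvd = c("(Intercept)" = stats::qlogis(0.06), female = -0.20,
            age40 = 0.80, mdd = 0.70, hypertension = 0.50)
  )
  death <- c("(Intercept)" = stats::qlogis(0.02), female = -0.20,
             age40 = 1.00, mdd = 0.50, cvd = 0.90, hypertension = 0.40)
  censor <- c("(Intercept)" = stats::qlogis(0.05))
  baseline <- list(p_female = 0.52, p_age40 = 0.45,
                   pop_probs = c(black_african = 0.50, mixed_ancestry = 0.06,
                                 white = 0.20, indian_asian = 0.05,
                                 unknown = 0.19),
                   age_mean = 39.3, age_sd = 15.3)
  scm_params(reg, 3L, init, trans, death, censor, baseline, FALSE, seed)
}

#' Serialize / restore generative-model parameters
#'
#' Writes an `scm_params` truth as a structured JSON key tree (registry,
#' coefficient vectors by model, baseline distribution) and reads it back.
#'
#' @param params an `scm_params` object.
#' @param path file path.
#' @return `read_scm_params` returns the `scm_params`; the writer returns
#'   `path` invisibly.
#' @export
write_scm_params <- function(params, path) {
  stopifnot(inherits(params, "scm_params"))
  reg <- params$registry
  obj <- list(registry = list(exposure = reg$exposure,
                              mediators = reg$mediators,
                              confounders = reg$confounders,
                              outcome = reg$outcome),
              n_periods = params$n_periods,
              init = lapply(params$init, as.list),
              trans = lapply(params$trans, as.list),
              death = as.list(params$death),
              censor = as.list(params$censor),
              baseline = list(p_female = params$baseline$p_female,
                              p_age40 = params$baseline$p_age40,
                              pop_probs = as.list(params$baseline$pop_probs),
                              age_mean = params$baseline$age_mean,
                              age_sd = params$baseline$age_sd),
              contemporaneous_exposure = params$contemporaneous_exposure,
              seed = params$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scm_params
#' @export
read_scm_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  reg <- condition_registry(exposure = obj$registry$exposure,
                            mediators = unlist(obj$registry$mediators),
                            confounders = unlist(obj$registry$confounders),
                            outcome = obj$registry$outcome)
  bl <- obj$baseline
  bl$pop_probs <- unlist(bl$pop_probs)
  scm_params(reg, obj$n_periods,
             init = lapply(obj$init, unlist),
             trans = lapply(obj$trans, unlist),
             death = unlist(obj$death), censor = unlist(obj$censor),
             baseline = bl,
             contemporaneous_exposure = isTRUE(obj$contemporaneous_exposure),
             seed = obj$seed)
}

## ---- evaluation of truth coefficients -------------------------------------

# eta for a named coefficient vector against a design environment: `get_col`
# maps a term name to a numeric vector (or scalar).
eval_coef_eta <- function(coefs, get_col, n) {
  eta <- rep.int(if ("(Intercept)" %in% names(coefs))
    unname(coefs[["(Intercept)"]]) else 0, n)
  for (nm in setdiff(names(coefs), "(Intercept)"))
    eta <- eta + coefs[[nm]] * get_col(nm)
  eta
}

## ---- baseline sampling ----------------------------------------------------

# Sample baseline covariates from the ScmParams baseline distribution.  Age
# is drawn from a normal truncated to the age group's range so that the
# binary age-group margin is exactly p_age40 (the structural models depend on
# age only through the group indicator).
sample_baseline <- function(params, n) {
  bl <- params$baseline
  female <- stats::rbinom(n, 1L, bl$p_female)
  age40 <- stats::rbinom(n, 1L, bl$p_age40)
  pg <- sample(POP_LEVELS, n, replace = TRUE, prob = bl$pop_probs)
  lo <- ifelse(age40 == 1L, 40, 18)
  hi <- ifelse(age40 == 1L, 90, 39.999)
  plo <- stats::pnorm(lo, bl$age_mean, bl$age_sd)
  phi <- stats::pnorm(hi, bl$age_mean, bl$age_sd)
  u <- stats::runif(n, plo, phi)
  age <- floor(stats::qnorm(u, bl$age_mean, bl$age_sd))
  age <- pmin(pmax(age, lo), floor(hi))
  data.frame(sex = SEX_LEVELS[female + 1L],
             age_at_enrollment = as.integer(age),
             age_group = AGE_LEVELS[age40 + 1L],
             population_group = pg,
             stringsAsFactors = FALSE)
}

## ---- cohort generation ----------------------------------------------------

#' Generate a synthetic longitudinal cohort from the known truth
#'
#' Simulates `n` individuals forward through the structural causal model:
#' period-1 condition states from the initial-state models given baseline
#' covariates; for t >= 2 each still-undiagnosed condition from its
#' transition model given the full t-1 state (and the current-period
#' exposure when the contemporaneous option is on); then censoring from the
#' censoring hazard (never in the final period, which ends follow-up
#' administratively); then, for the uncensored, death from the death model
#' on the full time-t state. A person who leaves the cohort in period t
#' exits before the period's death outcome is realized, so censored rows
#' carry no survival information and the estimation risk sets can drop them
#' without bias. Diagnosed conditions are carried forward; death and
#' censoring are terminal.
#'
#' @param params an [scm_params()] truth.
#' @param n number of individuals (may be 0).
#' @param seed integer seed; defaults to the seed stored in `params`.
#' @return A person-period panel `data.frame` (see [build_panel()] for the
#'   schema) that always passes [validate_panel()].
#' @examples
#' panel <- generate_cohort(default_scm_params("tiny"), n = 100, seed = 1)
#' head(panel)
#' @export
generate_cohort <- function(params, n, seed = params$seed) {
  stopifnot(inherits(params, "scm_params"))
  if (n < 0) stop("n must be >= 0")
  reg <- params$registry
  conds <- reg$conditions
  k <- length(conds)
  if (n == 0) return(empty_panel(reg))
  set.seed(derive_seed(seed, "generate"))
  bl <- sample_baseline(params, n)
  B <- baseline_design(bl)
  expo_cur <- paste0(reg$exposure, "_cur")

  S <- matrix(0L, n, k, dimnames = list(NULL, conds))
  active <- rep(TRUE, n)          # alive and uncensored entering period t
  rows <- vector("list", params$n_periods)

  for (t in seq_len(params$n_periods)) {
    idx <- which(active)
    if (!length(idx)) break
    Sprev <- S                     # state at end of t-1 (snapshot)
    getter <- function(nm) {
      if (nm %in% colnames(B)) return(B[idx, nm])
      if (nm %in% conds) return(Sprev[idx, nm])
      if (nm == expo_cur) return(S[idx, reg$exposure])
      stop("unknown term: ", nm)
    }
    for (cn in conds) {
      coefs <- if (t == 1L) params$init[[cn]] else params$trans[[cn]]
      at_risk <- Sprev[idx, cn] == 0L
      p <- stats::plogis(eval_coef_eta(coefs, getter, length(idx)))
      draw <- as.integer(stats::runif(length(idx)) < p)
      S[idx, cn] <- ifelse(at_risk, draw, 1L)
    }
    get_cur <- function(nm) {
      if (nm %in% colnames(B)) return(B[idx, nm])
      if (nm %in% conds) return(S[idx, nm])
      stop("unknown term: ", nm)
    }
    # Censoring is resolved before the death draw: a person who leaves the
    # cohort during period t exits before the period's death outcome is
    # realized, so censored rows carry no survival information about t and
    # can be dropped from death risk sets without bias (the default hazard
    # is intercept-only, i.e. noninformative).
    p_c <- stats::plogis(eval_coef_eta(params$censor, get_cur, length(idx)))
    cens <- stats::runif(length(idx)) < p_c
    if (t == params$n_periods) cens[] <- FALSE
    p_d <- stats::plogis(eval_coef_eta(params$death, get_cur, length(idx)))
    died <- !cens & stats::runif(length(idx)) < p_d

    rows[[t]] <- data.frame(person_id = idx, t = t,
                            bl[idx, , drop = FALSE],
                            S[idx, , drop = FALSE],
                            death = as.integer(died),
                            censored = as.integer(cens),
                            row.names = NULL, stringsAsFactors = FALSE)
    active[idx[died | cens]] <- FALSE
  }
  panel <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  panel <- panel[order(panel$person_id, panel$t), , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "registry") <- reg
  panel
}

empty_panel <- function(registry) {
  cols <- c("person_id", "t", "sex", "age_at_enrollment", "age_group",
            "population_group", registry$conditions, "death", "censored")
  panel <- as.data.frame(setNames(rep(list(integer(0)), length(cols)), cols))
  panel$sex <- character(0)
  panel$age_group <- character(0)
  panel$population_group <- character(0)
  attr(panel, "registry") <- registry
  panel
}

## ---- event-record export --------------------------------------------------

#' Export a person-period panel as per-person event records
#'
#' Inverse of [build_panel()] under the interval-midpoint date convention:
#' enrollment at `origin_date`, first-diagnosis and death dates at the
#' midpoint of the period in which the indicator first turns 1 (or death
#' occurs), exit at the midpoint of a censoring period or at the end of the
#' final period for administrative end of follow-up. Rebuilding a panel from
#' the exported records reproduces the panel exactly.
#'
#' @param panel a valid person-period panel.
#' @param origin_date enrollment date for every person (`Date` or
#'   ISO-8601 string).
#' @param interval_days length of one discrete period in days.
#' @param registry the condition registry; defaults to the one attached to
#'   the panel.
#' @return A `data.frame` of event records (one row per person) with columns
#'   `person_id`, baseline covariates, `enrollment_date`, `exit_date`,
#'   `death_date`, and `dx_<condition>` date columns.
#' @export
export_event_records <- function(panel, origin_date = as.Date("2011-01-01"),
                                 interval_days = 182L,
                                 registry = attr(panel, "registry")) {
  if (is.null(registry)) registry <- condition_registry()
  origin <- as.Date(origin_date)
  conds <- registry$conditions
  ids <- unique(panel$person_id)
  first_rows <- panel[match(ids, panel$person_id), , drop = FALSE]
  sp <- split(seq_len(nrow(panel)), panel$person_id)
  sp <- sp[match(as.character(ids), names(sp))]

  midpoint <- function(t) origin + floor((t - 0.5) * interval_days)
  n <- length(ids)
  exit_date <- rep(origin, n)
  death_date <- rep(as.Date(NA), n)
  dx <- as.data.frame(lapply(conds, function(cn) rep(as.Date(NA), n)))
  names(dx) <- paste0("dx_", conds)

  for (i in seq_len(n)) {
    r <- sp[[i]]
    tt <- panel$t[r]
    last <- r[which.max(tt)]
    Tlast <- panel$t[last]
    if (panel$death[last] == 1L) {
      death_date[i] <- midpoint(Tlast)
      exit_date[i] <- death_date[i]
    } else if (panel$censored[last] == 1L) {
      exit_date[i] <- midpoint(Tlast)
    } else {
      exit_date[i] <- origin + Tlast * interval_days
    }
    for (cn in conds) {
      v <- panel[[cn]][r]
      if (any(v == 1L))
        dx[[paste0("dx_", cn)]][i] <- midpoint(min(tt[v == 1L]))
    }
  }
  out <- data.frame(person_id = ids,
                    first_rows[, c("sex", "age_at_enrollment",
                                   "population_group"), drop = FALSE],
                    enrollment_date = origin,
                    exit_date = exit_date,
                    death_date = death_date,
                    dx, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "registry") <- registry
  out
}
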