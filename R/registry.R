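#' Condition registry: roles of the tracked conditions
#'
#' The analysis tracks a set of chronic conditions, each with a role: exactly
#' one binary exposure (major depressive disorder in the default registry),
#' a set of disease mediators, a set of time-dependent confounders, and one
#' absorbing outcome (death). Mediators and confounders are modelled with the
#' same machinery; they differ only in how counterfactual scenarios intervene
#' on them (mediator distributions may be shifted, confounder distributions
#' never are).
#'
#' @param exposure name of the exposure condition.
#' @param mediators character vector of mediator condition names.
#' @param confounders character vector of time-dependent confounder names.
#' @param outcome name of the absorbing outcome.
#' @return An object of class `med_registry`.
#' @examples
#' condition_registry()
#' @export
condition_registry <- function(exposure = "mdd",
                               mediators = c("hiv", "tb", "diabetes_ckd",
                                             "cvd", "chronic_respiratory",
                                             "cancer"),
                               confounders = c("hypertension", "anxiety"),
                               outcome = "death") {
  stopifnot(length(exposure) == 1L, length(outcome) == 1L,
            length(mediators) >= 1L)
  nm <- c(exposure, confounders, mediators, outcome)
  if (anyDuplicated(nm))
    stop("condition names must be unique across roles")
  if (!all(grepl("^[a-z][a-z0-9_]*$", nm)))
    stop("condition names must be lowercase identifiers")
  reserved <- c("death", "censored", "person_id", "t", "sex", "age_group",
                "age_at_enrollment", "population_group", "period")
  bad <- intersect(c(exposure, confounders, mediators), reserved)
  if (length(bad))
    stop("reserved column names used as conditions: ",
         paste(bad, collapse = ", "))
  structure(list(exposure = exposure,
                 mediators = mediators,
                 confounders = confounders,
                 outcome = outcome,
                 # draw order within a period: exposure first (needed when the
                 # contemporaneous-exposure option is on), then confounders,
                 # then mediators; distributionally irrelevant under the lag
                 # assumption, fixed for reproducibility.
                 conditions = c(exposure, confounders, mediators)),
            class = "med_registry")
}

#' @export
print.med_registry <- function(x, ...) {
  cat("Condition registry\n")
  cat("  exposure:    ", x$exposure, "\n")
  cat("  confounders: ", paste(x$confounders, collapse = ", "), "\n")
  cat("  mediators:   ", paste(x$mediators, collapse = ", "), "\n")
  cat("  outcome:     ", x$outcome, "\n")
  invisible(x)
}

## ---- baseline covariate encoding ------------------------------------------

# Fixed reference levels (recorded in model-set metadata): male, under40,
# black_african.
POP_LEVELS <- c("black_african", "mixed_ancestry", "white", "indian_asian",
                "unknown")
SEX_LEVELS <- c("male", "female")
AGE_LEVELS <- c("under40", "40plus")

baseline_terms <- function() {
  c("female", "age40",
    paste0("pop_", POP_LEVELS[-1L]))
}

# Build the one-hot baseline design matrix from the categorical columns
# (sex, age_group, population_group).  `df` may be a panel or a baseline
# table; rows map one-to-one to output rows.
baseline_design <- function(df) {
  if (!all(c("sex", "age_group", "population_group") %in% names(df)))
    stop("need columns sex, age_group, population_group")
  sex <- as.character(df$sex)
  ag <- as.character(df$age_group)
  pg <- as.character(df$population_group)
  if (!all(sex %in% SEX_LEVELS)) stop("invalid sex values")
  if (!all(ag %in% AGE_LEVELS)) stop("invalid age_group values")
  if (!all(pg %in% POP_LEVELS)) stop("invalid population_group values")
  out <- cbind(female = as.numeric(sex == "female"),
               age40 = as.numeric(ag == "40plus"))
  for (p in POP_LEVELS[-1L])
    out <- cbind(out, as.numeric(pg == p))
  colnames(out) <- baseline_terms()
  out
}

# Derived age group from age at enrollment.
age_group_of <- function(age) ifelse(age < 40, "under40", "40plus")

# Deterministic derived seed < 2^31 for named substreams.
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}
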