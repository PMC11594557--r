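# Shared fixtures, built once per test run and cached across files.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

tiny_truth <- function() cached("tiny", default_scm_params("tiny"))

tiny_panel <- function()
  cached("tiny_panel", generate_cohort(tiny_truth(), n = 2000, seed = 42))

tiny_registry <- function() tiny_truth()$registry

# Random event records with messy features: prevalent diagnoses (dates
# before enrollment), deaths, dates on period boundaries.
random_records <- function(n, seed, registry = tiny_registry(),
                           max_days = 3 * 365) {
  set.seed(seed)
  origin <- as.Date("2012-03-01")
  enr <- origin + sample.int(400, n, replace = TRUE)
  fu <- sample.int(max_days, n, replace = TRUE)
  dead <- runif(n) < 0.25
  death <- as.Date(ifelse(dead, enr + pmin(fu, sample.int(max_days, n,
                                                          replace = TRUE)),
                          NA), origin = "1970-01-01")
  exit <- as.Date(ifelse(dead, death, enr + fu), origin = "1970-01-01")
  rec <- data.frame(
    person_id = seq_len(n),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age_at_enrollment = sample(18:85, n, replace = TRUE),
    population_group = sample(c("black_african", "white", "unknown"), n,
                              replace = TRUE),
    enrollment_date = enr, exit_date = exit, death_date = death,
    stringsAsFactors = FALSE)
  for (cn in registry$conditions) {
    has <- runif(n) < 0.4
    # offsets may be negative (prevalent at entry) or on a boundary
    off <- sample(c(-200:-1, 0, 1:900), n, replace = TRUE)
    rec[[paste0("dx_", cn)]] <-
      as.Date(ifelse(has, enr + off, NA), origin = "1970-01-01")
  }
  attr(rec, "registry") <- registry
  rec
}

risk_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)
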