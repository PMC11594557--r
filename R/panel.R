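#' Build a discrete-time person-period panel from event records
#'
#' Discretizes follow-up into half-open periods of `interval_days` days from
#' each person's enrollment date: period t covers days
#' `[(t-1)*interval_days, t*interval_days)`. A condition indicator is 1 at t
#' iff its first diagnosis date falls before the end of period t (diagnoses
#' predating enrollment are prevalent from t = 1); indicators are therefore
#' nondecreasing (chronicity). Death is flagged in the period containing the
#' death date and is terminal; a person exiting for another reason is flagged
#' censored in the period containing the exit date when that period precedes
#' the administrative horizon. Follow-up is truncated at `n_periods`.
#'
#' @param records event records, one row per person, with columns
#'   `person_id`, `sex`, `age_at_enrollment`, `population_group`,
#'   `enrollment_date`, `exit_date`, optional `death_date`, and one
#'   `dx_<condition>` date column per registry condition (ISO-8601; `NA` or
#'   empty = absent).
#' @param interval_days days per period (default 182, approximating 6
#'   months deterministically).
#' @param n_periods maximum number of periods (default 16, i.e. 8 years).
#' @param registry the condition registry; defaults to the registry attached
#'   to `records`, else [condition_registry()].
#' @param lookback_days diagnoses more than this many days before enrollment
#'   are clamped to period 1 with a warning (default `Inf`: any pre-enrollment
#'   diagnosis is silently prevalent).
#' @return A person-period `data.frame` with columns `person_id`, `t`,
#'   `sex`, `age_at_enrollment`, `age_group`, `population_group`, one 0/1
#'   column per condition, `death`, `censored`.
#' @examples
#' rec <- data.frame(person_id = 1, sex = "female", age_at_enrollment = 35,
#'                   population_group = "white",
#'                   enrollment_date = as.Date("2011-01-01"),
#'                   exit_date = as.Date("2013-06-30"),
#'                   death_date = as.Date(NA),
#'                   dx_mdd = as.Date("2011-09-01"))
#' build_panel(rec, registry = condition_registry(mediators = "cvd",
#'                                                confounders = "anxiety"))
#' @export
build_panel <- function(records, interval_days = 182L, n_periods = 16L,
                        registry = NULL, lookback_days = Inf) {
  if (is.null(registry)) registry <- attr(records, "registry")
  if (is.null(registry)) registry <- condition_registry()
  stopifnot(interval_days > 0, n_periods >= 1)
  conds <- registry$conditions
  need <- c("person_id", "sex", "age_at_enrollment", "population_group",
            "enrollment_date", "exit_date")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$person_id)) stop("person_id must be unique")
  to_date <- function(x) {
    if (inherits(x, "Date")) return(x)
    x <- as.character(x)
    x[!nzchar(x) | is.na(x)] <- NA
    as.Date(x)
  }
  enr <- to_date(records$enrollment_date)
  ext <- to_date(records$exit_date)
  dth <- if ("death_date" %in% names(records))
    to_date(records$death_date) else rep(as.Date(NA), nrow(records))
  if (any(is.na(enr) | is.na(ext))) stop("enrollment/exit dates required")
  if (any(ext < enr)) stop("exit_date before enrollment_date")

  # reject records whose death predates enrollment
  bad_death <- !is.na(dth) & dth < enr
  if (any(bad_death)) {
    warning(sum(bad_death), " record(s) with death before enrollment rejected")
    records <- records[!bad_death, , drop = FALSE]
    enr <- enr[!bad_death]; ext <- ext[!bad_death]; dth <- dth[!bad_death]
  }
  np <- nrow(records)
  if (np == 0L) return(empty_panel(registry))

  exit_day <- as.integer(ext - enr)
  death_day <- ifelse(is.na(dth), NA_integer_, as.integer(dth - enr))
  exit_per <- exit_day %/% interval_days + 1L
  death_per <- death_day %/% interval_days + 1L

  dx_day <- matrix(NA_integer_, np, length(conds),
                   dimnames = list(NULL, conds))
  for (cn in conds) {
    col <- paste0("dx_", cn)
    if (col %in% names(records)) {
      d <- to_date(records[[col]])
      dx_day[, cn] <- ifelse(is.na(d), NA_integer_, as.integer(d - enr))
    }
  }
  too_early <- !is.na(dx_day) & dx_day < -lookback_days
  if (any(too_early)) {
    warning(sum(too_early), " diagnosis date(s) beyond the look-back window",
            " clamped to period 1")
    dx_day[too_early] <- 0L
  }
  # first period in which each condition indicator is 1
  dx_per <- pmax(dx_day %/% interval_days + 1L, 1L)

  term <- pmin(exit_per, n_periods)
  has_death <- !is.na(death_per) & death_per <= pmin(exit_per, n_periods)
  term[has_death] <- death_per[has_death]

  pid <- rep(records$person_id, term)
  tt <- sequence(term)
  row_of <- rep(seq_len(np), term)
  panel <- data.frame(
    person_id = pid, t = tt,
    sex = as.character(records$sex)[row_of],
    age_at_enrollment = records$age_at_enrollment[row_of],
    age_group = age_group_of(records$age_at_enrollment[row_of]),
    population_group = as.character(records$population_group)[row_of],
    stringsAsFactors = FALSE)
  for (cn in conds)
    panel[[cn]] <- as.integer(!is.na(dx_per[row_of, cn]) &
                                tt >= dx_per[row_of, cn])
  is_last <- tt == term[row_of]
  panel$death <- as.integer(is_last & has_death[row_of])
  panel$censored <- as.integer(is_last & !has_death[row_of] &
                                 exit_per[row_of] == term[row_of] &
                                 term[row_of] < n_periods)
  attr(panel, "registry") <- registry
  panel
}

#' Validate person-period panel invariants
#'
#' Checks, without mutating anything: per-person contiguity of periods from
#' t = 1; chronic carry-forward (condition indicators nondecreasing within
#' person); absorbing death (death only in a person's final row); censoring
#' terminal and mutually exclusive with death.
#'
#' @param panel a person-period `data.frame`.
#' @param registry the condition registry (default: attached to panel).
#' @return A list of class `panel_validation` with elements `pass` (logical)
#'   and `violations` (data.frame with columns `invariant`, `person_id`).
#' @export
validate_panel <- function(panel, registry = attr(panel, "registry")) {
  if (is.null(registry)) registry <- condition_registry()
  conds <- registry$conditions
  viol <- list()
  add <- function(inv, ids) {
    if (length(ids))
      viol[[length(viol) + 1L]] <<- data.frame(invariant = inv,
                                               person_id = unique(ids))
  }
  if (nrow(panel)) {
    o <- order(panel$person_id, panel$t)
    p <- panel[o, , drop = FALSE]
    sp <- split(seq_len(nrow(p)), p$person_id)
    contig <- vapply(sp, function(r) identical(as.integer(p$t[r]),
                                               seq_along(r)), logical(1))
    add("contiguous_periods", names(sp)[!contig])
    last_row <- vapply(sp, function(r) r[length(r)], integer(1))
    for (cn in conds) {
      dec <- vapply(sp, function(r) any(diff(p[[cn]][r]) < 0), logical(1))
      add("chronic_carry_forward", names(sp)[dec])
    }
    early_death <- vapply(sp, function(r)
      any(p$death[r][-length(r)] == 1), logical(1))
    add("absorbing_death", names(sp)[early_death])
    early_cens <- vapply(sp, function(r)
      any(p$censored[r][-length(r)] == 1), logical(1))
    add("terminal_censoring", names(sp)[early_cens])
    both <- p$death == 1 & p$censored == 1
    add("death_censoring_exclusive", p$person_id[both])
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(invariant = character(0), person_id = character(0))
  structure(list(pass = nrow(violations) == 0L, violations = violations),
            class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  if (x$pass) cat("Panel validation: PASS\n")
  else {
    cat("Panel validation: FAIL\n")
    tab <- table(x$violations$invariant)
    for (nm in names(tab))
      cat("  ", nm, ": ", tab[[nm]], " person(s)\n", sep = "")
  }
  invisible(x)
}

#' Read / write panel and event-record CSV files
#'
#' Plain-CSV serialization of the two tabular formats. Dates are ISO-8601;
#' empty cells encode absent dates.
#'
#' @param x panel or records `data.frame`.
#' @param path file path.
#' @param registry registry to attach when reading.
#' @return `read_panel_csv` / `read_records_csv` return the `data.frame`
#'   with the registry attached; the writers return the path invisibly.
#' @name panel_io
NULL

#' @rdname panel_io
#' @export
write_panel_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname panel_io
#' @export
read_panel_csv <- function(path, registry = condition_registry()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(x, "registry") <- registry
  x
}

#' @rdname panel_io
#' @export
read_records_csv <- function(path, registry = condition_registry()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in grep("^dx_|_date$", names(x), value = TRUE)) {
    v <- as.character(x[[cn]])
    v[is.na(v) | !nzchar(v)] <- NA
    x[[cn]] <- as.Date(v)
  }
  attr(x, "registry") <- registry
  x
}
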