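## Per-interval logistic models for death and condition onset.
##
## The death model for period t conditions on all condition indicators at t
## (including the exposure) and the baseline covariates; an onset model for a
## condition at period t >= 2 conditions on all indicators at t-1 and the
## baseline covariates (plus the exposure at t under the contemporaneous
## option), and at t = 1 on the baseline covariates only.  Risk sets follow
## chronicity: only persons still undiagnosed (and uncensored, alive) enter
## an onset model.

# Lagged condition matrix aligned with panel rows (NA at t = 1).  Relies on
# carried-forward indicators, so it must be computed on the ordered panel.
panel_lag_matrix <- function(panel, registry) {
  if (is.numeric(panel$person_id)) {
    np <- max(panel$t) + 1
    key <- panel$person_id * np + panel$t
    prev <- match(key - 1, key)
  } else {
    key <- paste(panel$person_id, panel$t)
    prev <- match(paste(panel$person_id, panel$t - 1L), key)
  }
  out <- matrix(NA_integer_, nrow(panel), length(registry$conditions),
                dimnames = list(NULL, registry$conditions))
  ok <- !is.na(prev)
  for (cn in registry$conditions)
    out[ok, cn] <- panel[[cn]][prev[ok]]
  out
}

#' Rows at risk for a response in a given period
#'
#' For the death response: all period-t rows with `censored == 0`. For a
#' condition response: period-t rows with `censored == 0` whose condition
#' indicator was still 0 entering the period (everyone is at risk at t = 1).
#' Persons already dead or censored before t contribute no period-t row, so
#' they are excluded by construction.
#'
#' @param panel person-period panel.
#' @param response `"death"` or a condition name.
#' @param t period index.
#' @param registry condition registry (default: attached to panel).
#' @return Integer vector of panel row indices.
#' @export
at_risk_rows <- function(panel, response, t,
                         registry = attr(panel, "registry")) {
  if (is.null(registry)) registry <- condition_registry()
  if (t < 1L || t > max(panel$t, 0L)) stop("period out of range: ", t)
  here <- panel$t == t & panel$censored == 0
  if (response == registry$outcome) return(which(here))
  if (!response %in% registry$conditions)
    stop("unknown response: ", response)
  if (t == 1L) return(which(here))
  lag <- panel_lag_matrix(panel, registry)
  which(here & lag[, response] == 0L)
}

# Same filter against a precomputed lag matrix (used in fitting loops).
at_risk_rows_lag <- function(panel, response, t, registry, lag) {
  here <- panel$t == t & panel$censored == 0
  if (response == registry$outcome || t == 1L) return(which(here))
  which(here & lag[, response] == 0L)
}

## ---- fast logistic fitting ------------------------------------------------

# Logistic fit with an explicit intercept column.  Returns named
# coefficients, AIC (deviance + 2 * #parameters) and convergence flag.
# Plain IRLS on the .lm.fit C path for speed; rank-deficient or
# non-converging cases fall back to stats::glm.fit.
fast_logit <- function(X, y, tol = 1e-8, start = NULL) {
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  n <- length(y)
  if (is.null(start)) {
    mu0 <- min(max(mean(y), 1e-6), 1 - 1e-6)
    beta <- c(stats::qlogis(mu0), numeric(p - 1L))
    eta <- rep.int(beta[1L], n)
  } else {
    beta <- numeric(p)
    hit <- match(colnames(Xi), names(start))
    beta[!is.na(hit)] <- start[hit[!is.na(hit)]]
    eta <- drop(Xi %*% beta)
  }
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(40L)) {
    mu <- 1 / (1 + exp(-eta))
    if (any(mu < 1e-10)) mu[mu < 1e-10] <- 1e-10
    if (any(mu > 1 - 1e-10)) mu[mu > 1 - 1e-10] <- 1 - 1e-10
    dev <- -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
    if (abs(dev - dev_old) / (0.1 + abs(dev)) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
    w <- sqrt(mu * (1 - mu))
    z <- eta + (y - mu) / (mu * (1 - mu))
    fit <- .lm.fit(Xi * w, z * w)
    if (fit$rank < p) return(glm_logit(Xi, y, tol))   # aliased columns
    beta[fit$pivot] <- fit$coefficients
    eta <- drop(Xi %*% beta)
  }
  if (!converged) return(glm_logit(Xi, y, tol))
  names(beta) <- colnames(Xi)
  list(coef = beta, aic = dev + 2 * p, deviance = dev, converged = TRUE)
}

glm_logit <- function(Xi, y, tol = 1e-8) {
  fit <- suppressWarnings(
    stats::glm.fit(Xi, y, family = stats::binomial(),
                   control = list(epsilon = tol, maxit = 100)))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(coef = cf, aic = fit$aic, deviance = fit$deviance,
       converged = fit$converged)
}

# Expand a term list (mains and "a:b" interactions) into a design matrix
# given the matrix of candidate main-effect columns.
expand_terms <- function(M, terms) {
  if (!length(terms)) return(matrix(numeric(0), nrow(M), 0))
  cols <- lapply(terms, function(tm) {
    pr <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    if (length(pr) == 1L) M[, pr] else M[, pr[1L]] * M[, pr[2L]]
  })
  out <- do.call(cbind, cols)
  colnames(out) <- terms
  out
}

canon_int <- function(a, b) paste(sort(c(a, b)), collapse = ":")

col_varies <- function(X) {
  if (!nrow(X)) return(rep(FALSE, ncol(X)))
  vapply(seq_len(ncol(X)), function(j) {
    cj <- X[, j]
    any(cj != cj[1L])
  }, logical(1))
}

#' Forward-backward stepwise logistic regression by AIC
#'
#' Starts from the intercept-only model and alternates single-term moves:
#' at each step the candidate additions (any unselected main effect; any
#' two-way interaction whose two main effects are both selected) and
#' deletions (any selected interaction; any selected main effect not
#' contained in a selected interaction) are scored by AIC
#' (deviance + 2 * number of parameters), and the best strictly improving
#' move is accepted. Stops when no move improves AIC or at `step_cap`
#' moves. Ties are broken by lexicographic term name, so the procedure is
#' deterministic given the data. Zero-variance candidates are dropped up
#' front; terms whose estimates diverge (perfect separation) are dropped
#' from the final model and flagged.
#'
#' @param y 0/1 response vector.
#' @param x numeric matrix of candidate main-effect columns (named).
#' @param include_interactions consider two-way interactions of selected
#'   main effects.
#' @param step_cap maximum number of accepted moves.
#' @param tol minimum AIC improvement counted as strict.
#' @return List with `terms` (selected, possibly with `"a:b"` interaction
#'   names), `coef` (named, including `"(Intercept)"`), `aic`, `trace`
#'   (accepted moves), `dropped` (zero-variance or separated candidates),
#'   `converged`.
#' @export
stepwise_aic <- function(y, x, include_interactions = TRUE, step_cap = 50L,
                         tol = 1e-8) {
  stopifnot(length(y) >= 1L, ncol(x) >= 1L)
  keep <- col_varies(x)
  dropped <- colnames(x)[!keep]
  M <- x[, keep, drop = FALSE]
  cand <- sort(colnames(M))
  cur <- character(0)
  fit0 <- fast_logit(M[, character(0), drop = FALSE], y)
  cur_fit <- fit0
  trace <- character(0)

  score <- function(terms) fast_logit(expand_terms(M, terms), y)

  for (step in seq_len(step_cap)) {
    moves <- character(0)
    mains_in <- cur[!grepl(":", cur)]
    ints_in <- cur[grepl(":", cur)]
    # additions
    moves <- c(moves, paste0("+", setdiff(cand, mains_in), recycle0 = TRUE))
    if (include_interactions && length(mains_in) >= 2L) {
      pairs <- utils::combn(sort(mains_in), 2L)
      ints <- apply(pairs, 2L, function(p) canon_int(p[1L], p[2L]))
      moves <- c(moves, paste0("+", setdiff(ints, ints_in), recycle0 = TRUE))
    }
    # deletions: interactions freely; mains only if hierarchy allows
    free_mains <- mains_in[!vapply(mains_in, function(m)
      any(vapply(strsplit(ints_in, ":", fixed = TRUE),
                 function(p) m %in% p, logical(1))), logical(1))]
    moves <- c(moves, paste0("-", c(ints_in, free_mains), recycle0 = TRUE))
    moves <- moves[order(substring(moves, 2L))]
    if (!length(moves)) break

    best <- NULL; best_aic <- cur_fit$aic
    for (mv in moves) {
      tm <- substring(mv, 2L)
      new_terms <- if (startsWith(mv, "+")) c(cur, tm) else setdiff(cur, tm)
      f <- score(new_terms)
      if (f$aic < best_aic - tol) {
        best <- list(terms = new_terms, fit = f, move = mv)
        best_aic <- f$aic
      }
    }
    if (is.null(best)) break
    cur <- best$terms
    cur_fit <- best$fit
    trace <- c(trace, best$move)
  }

  # divergent coefficients signal separation: drop and refit
  sep <- names(cur_fit$coef)[abs(cur_fit$coef) > 15 &
                               names(cur_fit$coef) != "(Intercept)"]
  if (length(sep)) {
    bad_main <- unique(unlist(strsplit(sep, ":", fixed = TRUE)))
    cur <- cur[!vapply(strsplit(cur, ":", fixed = TRUE),
                       function(p) any(p %in% bad_main), logical(1))]
    cur_fit <- score(cur)
    dropped <- c(dropped, sep)
  }
  list(terms = sort(cur), coef = cur_fit$coef, aic = cur_fit$aic,
       trace = trace, dropped = dropped, converged = cur_fit$converged)
}

## ---- model-set fitting ----------------------------------------------------

model_entry <- function(response, t, terms, coef, fallback = "none",
                        n = NA_integer_, events = NA_integer_,
                        converged = TRUE, rate = NULL, dropped = character(0)) {
  list(response = response, t = t, terms = terms, coef = coef,
       fallback = fallback, n = n, events = events, converged = converged,
       rate = rate, dropped = dropped)
}

# Candidate main-effect matrix for (response, t).  `condm` holds the
# current condition indicators as a double matrix, `lag` their lagged
# values, `B` the baseline design.
candidate_matrix <- function(condm, rows, response, t, registry, B, lag,
                             contemporaneous) {
  conds <- registry$conditions
  if (response == registry$outcome) {
    X <- cbind(condm[rows, , drop = FALSE], B[rows, , drop = FALSE])
  } else if (t == 1L) {
    X <- B[rows, , drop = FALSE]
  } else {
    X <- cbind(lag[rows, setdiff(conds, response), drop = FALSE],
               B[rows, , drop = FALSE])
    if (contemporaneous && response != registry$exposure) {
      X <- cbind(X, condm[rows, registry$exposure])
      colnames(X)[ncol(X)] <- paste0(registry$exposure, "_cur")
    }
  }
  storage.mode(X) <- "double"
  X
}

#' Fit the full per-interval model set on a panel
#'
#' Fits, for every period, the death model and one onset model per
#' condition (exposure included), on the chronicity-respecting risk sets of
#' [at_risk_rows()]. Selection is `"stepwise_aic"` (forward-backward with
#' optional two-way interactions), `"full"` (all candidate main effects) or
#' `"intercept_only"`. Sparse cells fall back, in order, to a model pooled
#' over periods with `period` as a covariate, then to the empirical event
#' rate; the fallback used is recorded per entry.
#'
#' @param panel person-period panel.
#' @param registry condition registry (default: attached to panel).
#' @param selection model selection mode.
#' @param include_interactions consider two-way interactions (stepwise only;
#'   default `TRUE`, matching all-possible-two-way-interaction screening).
#' @param contemporaneous also offer the exposure measured at t as a
#'   candidate in every other condition's onset model (sensitivity analysis;
#'   default `FALSE`, the lag-only assumption).
#' @param min_events minimum events (and non-events) for a per-period fit.
#' @param n_periods number of periods (default: max `t` in panel).
#' @param step_cap,tol stepwise controls, see [stepwise_aic()].
#' @param warm optional `med_model_set` whose coefficients seed the
#'   optimizer (used by the bootstrap, where replicates sit close to the
#'   point estimate; the optimum is unchanged, only the iteration count).
#'   Full-selection fits only.
#' @return An object of class `med_model_set`.
#' @export
fit_models <- function(panel, registry = attr(panel, "registry"),
                       selection = c("stepwise_aic", "full", "intercept_only"),
                       include_interactions = TRUE,
                       contemporaneous = FALSE, min_events = 25L,
                       n_periods = max(panel$t), step_cap = 50L, tol = 1e-8,
                       warm = NULL) {
  selection <- match.arg(selection)
  if (is.null(registry)) registry <- condition_registry()
  if (!nrow(panel)) stop("empty panel")
  panel <- panel[order(panel$person_id, panel$t), , drop = FALSE]
  B <- baseline_design(panel)
  lag <- panel_lag_matrix(panel, registry)
  responses <- c(registry$outcome, registry$conditions)
  condm <- as.matrix(panel[registry$conditions])
  storage.mode(condm) <- "double"
  death_vec <- as.numeric(panel$death)
  uncens <- which(panel$censored == 0)
  rows_t <- split(uncens, panel$t[uncens])
  risk_rows <- function(response, t) {
    h <- rows_t[[as.character(t)]]
    if (is.null(h)) return(integer(0))
    if (response == registry$outcome || t == 1L) return(h)
    h[lag[h, response] == 0]
  }

  fit_one <- function(X, y, start = NULL) {
    switch(selection,
           stepwise_aic = stepwise_aic(y, X, include_interactions,
                                       step_cap, tol),
           full = {
             keep <- col_varies(X)
             f <- fast_logit(X[, keep, drop = FALSE], y, tol, start)
             list(terms = colnames(X)[keep], coef = f$coef, aic = f$aic,
                  dropped = colnames(X)[!keep], converged = f$converged)
           },
           intercept_only = {
             f <- fast_logit(X[, character(0), drop = FALSE], y, tol)
             list(terms = character(0), coef = f$coef, aic = f$aic,
                  dropped = character(0), converged = f$converged)
           })
  }

  warm_coef <- function(response, t) {
    if (is.null(warm)) return(NULL)
    mm <- warm$models[[response]]
    if (is.null(mm) || t > length(mm)) return(NULL)
    e <- mm[[t]]
    if (is.null(e) || !length(e$coef)) NULL else e$coef
  }
  warm_coef_pooled <- function(response) {
    if (is.null(warm)) return(NULL)
    mm <- warm$models[[response]]
    if (is.null(mm)) return(NULL)
    for (e in mm)
      if (!is.null(e) && identical(e$fallback, "pooled") && length(e$coef))
        return(e$coef)
    NULL
  }

  models <- list()
  pooled_cache <- list()
  pooled_fit <- function(response) {
    if (!is.null(pooled_cache[[response]]))
      return(pooled_cache[[response]])
    tset <- if (response == registry$outcome) seq_len(n_periods)
            else seq_len(n_periods)[-1L]
    rows <- unlist(lapply(tset, function(tt) risk_rows(response, tt)))
    if (!length(rows)) {
      ent <- model_entry(response, NA_integer_, character(0), numeric(0),
                         fallback = "empirical_rate",
                         n = 0L, events = 0L, rate = 0)
    } else {
      y <- if (response == registry$outcome) death_vec[rows]
           else condm[rows, response]
      ev <- sum(y)
      if (min(ev, length(y) - ev) < min_events) {
        ent <- model_entry(response, NA_integer_, character(0), numeric(0),
                           fallback = "empirical_rate", n = length(rows),
                           events = ev, rate = ev / length(rows))
      } else {
        X <- candidate_matrix(condm, rows, response,
                              if (response == registry$outcome) 1L else 2L,
                              registry, B, lag, contemporaneous)
        X <- cbind(X, period = as.double(panel$t[rows]))
        f <- fit_one(X, y, warm_coef_pooled(response))
        ent <- model_entry(response, NA_integer_, f$terms, f$coef,
                           fallback = "pooled", n = length(rows),
                           events = ev, converged = f$converged,
                           dropped = f$dropped)
      }
    }
    pooled_cache[[response]] <<- ent
    ent
  }

  for (response in responses) {
    per_t <- vector("list", n_periods)
    for (t in seq_len(n_periods)) {
      rows <- risk_rows(response, t)
      y <- if (response == registry$outcome) death_vec[rows]
           else condm[rows, response]
      ev <- sum(y)
      if (!length(rows) || min(ev, length(rows) - ev) < min_events) {
        # the pooled fallback spans the periods that share this response's
        # candidate set; the period-1 initial-state model of a condition has
        # its own structure (baseline only, no lags), so a sparse period-1
        # cell falls back to the empirical rate instead
        if (response != registry$outcome && t == 1L && length(rows)) {
          per_t[[t]] <- model_entry(response, 1L, character(0), numeric(0),
                                    fallback = "empirical_rate",
                                    n = length(rows), events = ev,
                                    rate = ev / length(rows))
        } else {
          ent <- pooled_fit(response)
          ent$t <- t
          per_t[[t]] <- ent
        }
        next
      }
      X <- candidate_matrix(condm, rows, response, t, registry, B, lag,
                            contemporaneous)
      f <- fit_one(X, y, warm_coef(response, t))
      per_t[[t]] <- model_entry(response, t, f$terms, f$coef,
                                n = length(rows), events = ev,
                                converged = f$converged, dropped = f$dropped)
    }
    models[[response]] <- per_t
  }

  structure(list(registry = registry, n_periods = as.integer(n_periods),
                 contemporaneous = contemporaneous, selection = selection,
                 include_interactions = include_interactions,
                 min_events = min_events,
                 reference_levels = c(sex = "male", age_group = "under40",
                                      population_group = "black_african"),
                 models = models),
            class = "med_model_set")
}

#' @export
print.med_model_set <- function(x, ...) {
  cat("Per-interval logistic model set\n")
  cat("  responses:", paste(names(x$models), collapse = ", "), "\n")
  cat("  periods:  ", x$n_periods, "  selection:", x$selection, "\n")
  fb <- unlist(lapply(x$models, function(mm)
    vapply(mm, function(e) e$fallback, character(1))))
  if (any(fb != "none"))
    cat("  fallbacks:", sum(fb == "pooled"), "pooled,",
        sum(fb == "empirical_rate"), "empirical-rate\n")
  invisible(x)
}

#' Wrap a known truth as a model set
#'
#' Re-expresses [scm_params()] coefficients as a `med_model_set` so that the
#' g-computation engine can simulate directly from the generative truth —
#' the basis of oracle cross-checks and of [oracle_simulate_risk()].
#'
#' @param params an `scm_params` truth.
#' @return A `med_model_set`.
#' @export
as_model_set <- function(params) {
  stopifnot(inherits(params, "scm_params"))
  reg <- params$registry
  models <- list()
  mk <- function(response, t, coefs)
    model_entry(response, t, setdiff(names(coefs), "(Intercept)"),
                coefs, fallback = "none")
  models[[reg$outcome]] <- lapply(seq_len(params$n_periods), function(t)
    mk(reg$outcome, t, params$death))
  for (cn in reg$conditions)
    models[[cn]] <- lapply(seq_len(params$n_periods), function(t)
      mk(cn, t, if (t == 1L) params$init[[cn]] else params$trans[[cn]]))
  structure(list(registry = reg, n_periods = params$n_periods,
                 contemporaneous = params$contemporaneous_exposure,
                 selection = "truth", include_interactions = FALSE,
                 min_events = 0L,
                 reference_levels = c(sex = "male", age_group = "under40",
                                      population_group = "black_african"),
                 models = models),
            class = "med_model_set")
}

## ---- prediction -----------------------------------------------------------

# eta for a model entry; get_col(term) -> numeric vector for every main term.
entry_eta <- function(entry, get_col, n) {
  cf <- entry$coef
  eta <- rep.int(if ("(Intercept)" %in% names(cf))
    unname(cf[["(Intercept)"]]) else 0, n)
  for (nm in setdiff(names(cf), "(Intercept)")) {
    pr <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    v <- get_col(pr[1L])
    if (length(pr) == 2L) v <- v * get_col(pr[2L])
    eta <- eta + cf[[nm]] * v
  }
  eta
}

entry_prob <- function(entry, get_col, n) {
  if (entry$fallback == "empirical_rate") return(rep.int(entry$rate, n))
  unname(stats::plogis(entry_eta(entry, get_col, n)))
}

#' Predicted probability from a fitted entry
#'
#' Evaluates the inverse-logit linear predictor of one `(response, period)`
#' model on new rows. Interaction terms are products of their two main
#' columns. Rows may carry the raw categorical baseline columns (`sex`,
#' `age_group`, `population_group`), which are one-hot encoded against the
#' recorded reference levels, or the encoded dummy columns directly.
#'
#' @param model a model entry (`model_set$models[[response]][[t]]`) or an
#'   `med_model_set` together with `response` and `t`.
#' @param newdata `data.frame` (or named list of equal-length vectors)
#'   supplying every selected term's inputs.
#' @param response,t used to pick the entry when `model` is a model set.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_prob <- function(model, newdata, response = NULL, t = NULL) {
  entry <- model
  if (inherits(model, "med_model_set")) {
    stopifnot(!is.null(response), !is.null(t))
    entry <- model$models[[response]][[t]]
    if (is.null(entry)) stop("no model for ", response, " at t = ", t)
  }
  nd <- as.data.frame(newdata, stringsAsFactors = FALSE)
  n <- nrow(nd)
  Bm <- NULL
  if (all(c("sex", "age_group", "population_group") %in% names(nd)))
    Bm <- baseline_design(nd)
  get_col <- function(nm) {
    if (nm %in% names(nd)) return(as.numeric(nd[[nm]]))
    if (!is.null(Bm) && nm %in% colnames(Bm)) return(Bm[, nm])
    stop("missing covariate: ", nm)
  }
  entry_prob(entry, get_col, n)
}

## ---- serialization --------------------------------------------------------

#' Write / read a fitted model set as JSON
#'
#' Serializes every `(response, period)` entry (terms, coefficients,
#' fallback, counts) plus registry and metadata, so scenarios can be
#' simulated later without refitting.
#'
#' @param models a `med_model_set`.
#' @param path file path.
#' @return `read_model_set` returns the `med_model_set`; the writer returns
#'   `path` invisibly.
#' @export
write_model_set <- function(models, path) {
  obj <- unclass(models)
  obj$registry <- unclass(obj$registry)
  # named coefficient vectors must serialize as JSON objects, not arrays
  obj$models <- lapply(obj$models, function(mm) lapply(mm, function(e) {
    e$coef <- as.list(e$coef)
    e
  }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_set
#' @export
read_model_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  reg <- condition_registry(exposure = obj$registry$exposure,
                            mediators = unlist(obj$registry$mediators),
                            confounders = unlist(obj$registry$confounders),
                            outcome = obj$registry$outcome)
  fix_entry <- function(e) {
    e$coef <- unlist(e$coef)
    e$terms <- as.character(unlist(e$terms))
    e$dropped <- as.character(unlist(e$dropped))
    e$rate <- if (is.null(e$rate)) NULL else as.numeric(e$rate)
    e
  }
  models <- lapply(obj$models, function(mm) lapply(mm, fix_entry))
  structure(list(registry = reg, n_periods = as.integer(obj$n_periods),
                 contemporaneous = isTRUE(obj$contemporaneous),
                 selection = obj$selection,
                 include_interactions = isTRUE(obj$include_interactions),
                 min_events = as.integer(obj$min_events),
                 reference_levels = unlist(obj$reference_levels),
                 models = models),
            class = "med_model_set")
}
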