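# Per-interval logistic models, risk sets and stepwise selection.

test_that("risk sets agree with a brute-force row filter", {
  panel <- tiny_panel()
  reg <- tiny_registry()
  # brute force: loop persons, track state independently
  brute <- function(response, t) {
    keep <- logical(nrow(panel))
    for (i in seq_len(nrow(panel))) {
      if (panel$t[i] != t || panel$censored[i] == 1L) next
      if (response == "death") { keep[i] <- TRUE; next }
      if (t == 1L) { keep[i] <- TRUE; next }
      prev <- which(panel$person_id == panel$person_id[i] &
                      panel$t == t - 1L)
      keep[i] <- panel[[response]][prev] == 0L
    }
    which(keep)
  }
  for (resp in c("death", "mdd", "cvd", "hypertension"))
    for (t in 1:3)
      expect_identical(at_risk_rows(panel, resp, t, reg), brute(resp, t))
  expect_error(at_risk_rows(panel, "nope", 1, reg), "unknown response")
  expect_error(at_risk_rows(panel, "death", 9, reg), "out of range")
})

test_that("chronicity empties the risk set once everyone is diagnosed", {
  panel <- tiny_panel()
  everyone <- panel
  everyone$cvd <- 1L
  expect_length(at_risk_rows(everyone, "cvd", 2, tiny_registry()), 0L)
})

test_that("stepwise selects a strong true effect and stays deterministic", {
  set.seed(101)
  n <- 5000
  x <- cbind(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.5),
             c = rbinom(n, 1, 0.3))
  y <- rbinom(n, 1, plogis(-2 + 2 * x[, "a"]))
  f1 <- stepwise_aic(y, x)
  expect_true("a" %in% f1$terms)
  f2 <- stepwise_aic(y, x)
  expect_identical(f1$terms, f2$terms)     # deterministic and idempotent
  expect_identical(f1$coef, f2$coef)
})

test_that("null candidates are retained at the rate AIC theory predicts", {
  # a null candidate enters iff its deviance drop exceeds 2, which happens
  # with probability P(chisq_1 > 2) ~= 0.157; with two independent null
  # candidates the intercept-only model is kept ~71% of the time
  kept <- vapply(1:100, function(s) {
    set.seed(s)
    x <- cbind(a = rbinom(1500, 1, 0.4), b = rbinom(1500, 1, 0.5))
    y <- rbinom(1500, 1, 0.15)
    length(stepwise_aic(y, x)$terms) == 0L
  }, logical(1))
  p0 <- (1 - pchisq(2, 1, lower.tail = FALSE))^2
  expect_lt(abs(mean(kept) - p0), 3 * sqrt(p0 * (1 - p0) / 100))
})

test_that("AIC bookkeeping: equal dimension implies deviance ordering", {
  set.seed(3)
  n <- 800
  x <- cbind(a = rbinom(n, 1, 0.4), b = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(-1 + x[, "a"]))
  fa <- gmediate:::fast_logit(x[, "a", drop = FALSE], y)
  fb <- gmediate:::fast_logit(x[, "b", drop = FALSE], y)
  expect_lt(fa$deviance, fb$deviance)
  expect_lt(fa$aic, fb$aic)
  expect_equal(fa$aic - fa$deviance, fb$aic - fb$deviance)
})

test_that("zero-variance and separated candidates are dropped with a flag", {
  set.seed(8)
  n <- 400
  x <- cbind(a = rbinom(n, 1, 0.4), z = rep(1, n))
  y <- rbinom(n, 1, 0.3)
  f <- stepwise_aic(y, x)
  expect_true("z" %in% f$dropped)

  sep <- cbind(s = c(rep(0, 200), rep(1, 200)))
  ysep <- c(rbinom(200, 1, 0.2), rep(1, 200))  # perfect predictor
  fs <- stepwise_aic(ysep, sep)
  expect_false("s" %in% fs$terms)
})

test_that("predicted probabilities follow the inverse-logit closed forms", {
  e0 <- gmediate:::model_entry("death", 1, character(0),
                               c(`(Intercept)` = 0))
  expect_equal(predict_prob(e0, data.frame(x = 1)), 0.5)
  e1 <- gmediate:::model_entry("death", 1, "x",
                               c(`(Intercept)` = 0, x = 1))
  expect_equal(predict_prob(e1, data.frame(x = 1)), 1 / (1 + exp(-1)))
  eint <- gmediate:::model_entry("death", 1, c("a", "b", "a:b"),
                                 c(`(Intercept)` = 0, a = 1, b = 1,
                                   `a:b` = -2))
  expect_equal(predict_prob(eint, data.frame(a = 1, b = 1)), plogis(0))
  er <- gmediate:::model_entry("death", 1, character(0), numeric(0),
                               fallback = "empirical_rate", rate = 3 / 60)
  expect_equal(predict_prob(er, data.frame(a = 1:5)), rep(0.05, 5))
  expect_error(predict_prob(e1, data.frame(z = 1)), "missing covariate")
})

test_that("fit_models covers every response-period cell with metadata", {
  panel <- tiny_panel()
  reg <- tiny_registry()
  ms <- fit_models(panel, reg, selection = "full", min_events = 5)
  expect_setequal(names(ms$models), c("death", reg$conditions))
  expect_true(all(lengths(ms$models) == 3L))
  ent <- ms$models$death[[2]]
  expect_true(is.finite(ent$coef["(Intercept)"]))
  expect_gt(ent$n, 0)

  # sparse cells fall back and say so
  small <- generate_cohort(tiny_truth(), n = 60, seed = 9)
  ms2 <- fit_models(small, reg, selection = "full", min_events = 25)
  fb <- unlist(lapply(ms2$models, function(mm)
    vapply(mm, `[[`, "", "fallback")))
  expect_true(any(fb != "none"))
})

test_that("contemporaneous option adds the exposure to onset candidates", {
  p <- tiny_truth()
  panel <- generate_cohort(p, n = 3000, seed = 12)
  ms <- fit_models(panel, p$registry, selection = "full",
                   contemporaneous = TRUE, min_events = 5)
  expect_true("mdd_cur" %in% ms$models$cvd[[2]]$terms)
  expect_false("mdd_cur" %in% ms$models$mdd[[2]]$terms)
  expect_false("mdd_cur" %in% ms$models$death[[2]]$terms)
})

test_that("full-selection fits recover the generative coefficients", {
  p <- tiny_truth()
  panel <- generate_cohort(p, n = 20000, seed = 31)
  ms <- fit_models(panel, p$registry, selection = "full", min_events = 10)
  truth <- as_model_set(p)
  hits <- 0L; total <- 0L
  for (resp in names(ms$models)) for (t in 1:3) {
    ent <- ms$models[[resp]][[t]]
    rows <- at_risk_rows(panel, resp, t, p$registry)
    y <- if (resp == "death") panel$death[rows] else panel[[resp]][rows]
    condm <- as.matrix(panel[p$registry$conditions])
    storage.mode(condm) <- "double"
    X <- cbind(1, gmediate:::expand_terms(
      gmediate:::candidate_matrix(condm, rows, resp, t, p$registry,
                                  gmediate:::baseline_design(panel),
                                  gmediate:::panel_lag_matrix(panel,
                                                              p$registry),
                                  FALSE), ent$terms))
    # observed-information standard errors, computed independently
    pr <- plogis(as.numeric(X %*% c(ent$coef["(Intercept)"],
                                    ent$coef[ent$terms])))
    W <- pr * (1 - pr)
    se <- sqrt(diag(solve(t(X) %*% (W * X))))
    names(se) <- c("(Intercept)", ent$terms)
    tr <- truth$models[[resp]][[t]]$coef
    for (nm in names(tr)) {
      est <- if (nm %in% names(ent$coef)) ent$coef[[nm]] else 0
      s <- if (nm %in% names(se)) se[[nm]] else NA
      if (is.na(s)) next
      total <- total + 1L
      hits <- hits + as.integer(abs(est - tr[[nm]]) <= 3 * s)
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("model sets survive a JSON round trip", {
  panel <- tiny_panel()
  ms <- fit_models(panel, tiny_registry(), selection = "full",
                   min_events = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_set(ms, f)
  back <- read_model_set(f)
  nd <- data.frame(sex = "female", age_group = "40plus",
                   population_group = "white", mdd = 1, cvd = 0,
                   hypertension = 1)
  for (t in 1:3)
    expect_equal(predict_prob(back, nd, "death", t),
                 predict_prob(ms, nd, "death", t))
  expect_identical(back$models$cvd[[2]]$terms, ms$models$cvd[[2]]$terms)
})
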