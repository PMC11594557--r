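# Effect contrasts, the gmediate estimator, and the cluster bootstrap.

test_that("overall effect reproduces printed-risk arithmetic", {
  eff <- overall_effect(0.065, 0.053)
  expect_equal(round(eff$rr, 2), 1.23)
  expect_equal(eff$rd, 1.2, tolerance = 1e-9)
  men <- overall_effect(0.078, 0.061)
  expect_equal(round(men$rr, 2), 1.28)
  same <- overall_effect(0.04, 0.04)
  expect_equal(same$rd, 0)
  expect_equal(same$rr, 1)
  degen <- overall_effect(0.01, 0)
  expect_false(degen$rr_defined)
  expect_true(is.na(degen$rr))
  expect_equal(degen$rd, 1)
})

test_that("indirect-effect percentages follow their defining identities", {
  expect_equal(indirect_effect_pct(0.06, 0.05, 0.06), 0)
  expect_equal(indirect_effect_pct(0.06, 0.05, 0.05), 100)
  out <- indirect_effect_pct(0.05, 0.05 - 1e-9, 0.05)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "floor")

  # against enumerated truth: same formula evaluated by hand
  p <- tiny_truth()
  rA <- oracle_enumerate_risk(p, scenario_always())$risk[3]
  rB <- oracle_enumerate_risk(p, scenario_never())$risk[3]
  rC <- oracle_enumerate_risk(p, scenario_shift_all(p$registry))$risk[3]
  expect_equal(indirect_effect_pct(rA, rB, rC),
               100 * (rA - rC) / (rA - rB))
})

test_that("curve-based effects evaluate year y at period 2y", {
  rc <- structure(list(scenario = "always",
                       risk = c(0.01, 0.02, 0.03, 0.05), n = 10, run = NA),
                  class = "risk_curve")
  rb <- structure(list(scenario = "never",
                       risk = c(0.01, 0.015, 0.02, 0.04), n = 10, run = NA),
                  class = "risk_curve")
  eff <- overall_effect(rc, rb, year = 2)
  expect_equal(eff$risk_a, 0.05)
  expect_equal(eff$risk_b, 0.04)
  expect_error(overall_effect(rc, rb, year = 3), "horizon")
})

test_that("gmediate assembles a coherent effects table", {
  fit <- cached("tiny_fit",
                gmediate(tiny_panel(), tiny_registry(), selection = "full",
                         min_events = 10, n_mc_runs = 2, seed = 5))
  eff <- fit$effects
  expect_setequal(unique(eff$stratum), "overall")
  expect_identical(eff$period, 1:3)
  a <- fit$curves$overall$always$risk
  b <- fit$curves$overall$never$risk
  expect_equal(eff$rd, 100 * (a - b))
  expect_equal(eff$rr, a / b)
  cc <- fit$curves$overall$shift_all$risk
  expect_equal(eff$ie_pct_all, 100 * (a - cc) / (a - b))
  s <- summary(fit)
  expect_s3_class(s, "summary.gmediate")
  expect_identical(s$year, 1)            # periods 2 of 3 is the only year
})

test_that("results are invariant to panel row order and reproducible", {
  panel <- tiny_panel()
  fit1 <- gmediate(panel, tiny_registry(), selection = "full",
                   min_events = 10, n_mc_runs = 1, seed = 5)
  perm <- panel[sample.int(nrow(panel)), ]
  fit2 <- gmediate(perm, tiny_registry(), selection = "full",
                   min_events = 10, n_mc_runs = 1, seed = 5)
  expect_equal(fit1$effects, fit2$effects, tolerance = 1e-12)
})

test_that("stratified runs refit the pipeline within each stratum", {
  panel <- generate_cohort(tiny_truth(), n = 4000, seed = 6)
  fit <- gmediate(panel, tiny_registry(), selection = "full",
                  min_events = 10, n_mc_runs = 1, strata = "sex", seed = 2)
  expect_setequal(unique(fit$effects$stratum),
                  c("overall", "male", "female"))
  m <- fit$effects[fit$effects$stratum == "male" & fit$effects$period == 3, ]
  f <- fit$effects[fit$effects$stratum == "female" &
                     fit$effects$period == 3, ]
  expect_false(isTRUE(all.equal(m$risk_always, f$risk_always)))
})

test_that("cluster bootstrap is reproducible and percentile bounds match an
          order-statistic oracle", {
  panel <- generate_cohort(tiny_truth(), n = 800, seed = 14)
  boot <- gmediate_boot(panel, registry = tiny_registry(),
                        selection = "full", min_events = 10,
                        n_mc_runs = 1, n_boot = 40, seed = 3)
  expect_identical(boot$n_fail, 0L)
  expect_identical(nrow(boot$replicates), 40L)

  boot2 <- gmediate_boot(panel, registry = tiny_registry(),
                         selection = "full", min_events = 10,
                         n_mc_runs = 1, n_boot = 40, seed = 3)
  expect_identical(boot$ci, boot2$ci)

  # independent percentile oracle: sort and linear interpolation (type 7)
  v <- boot$replicates[, "overall.3.rd"]
  s <- sort(v)
  manual <- function(p) {
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
  }
  row <- boot$ci[boot$ci$quantity == "overall.3.rd", ]
  expect_equal(row$lower, manual(0.025))
  expect_equal(row$upper, manual(0.975))

  # point estimate inside a 95% interval of its own sampling distribution
  pt <- boot$point$effects
  rd_pt <- pt$rd[pt$period == 3]
  expect_gte(rd_pt, row$lower - 5)
  expect_lte(rd_pt, row$upper + 5)
})

test_that("full-selection pipeline recovers the enumerated IE share", {
  p <- tiny_truth()
  panel <- generate_cohort(p, n = 20000, seed = 31)
  fit <- gmediate(panel, p$registry, selection = "full", min_events = 10,
                  n_mc_runs = 2, crn = TRUE, seed = 8)
  rA <- oracle_enumerate_risk(p, scenario_always())$risk[3]
  rB <- oracle_enumerate_risk(p, scenario_never())$risk[3]
  rC <- oracle_enumerate_risk(p, scenario_shift_all(p$registry))$risk[3]
  truth_ie <- 100 * (rA - rC) / (rA - rB)
  est <- fit$effects$ie_pct_all[fit$effects$period == 3]
  expect_lt(abs(est - truth_ie), 5)
  expect_lt(abs(fit$effects$risk_always[fit$effects$period == 3] - rA),
            0.01)
})
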