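# Counterfactual scenario simulation (the g-computation engine).

baseline_of <- function(panel)
  panel[panel$t == 1L, c("sex", "age_at_enrollment", "age_group",
                         "population_group")]

test_that("a zero-probability death model forces a zero risk curve", {
  p <- tiny_truth()
  p$death["(Intercept)"] <- -Inf
  rc <- simulate_scenario(as_model_set(p), baseline_of(tiny_panel()),
                          scenario_always(), seed = 1)
  expect_identical(rc$risk, rep(0, 3))
})

test_that("simulation from the true models matches exact enumeration", {
  p <- tiny_truth()
  ms <- as_model_set(p)
  set.seed(77)
  bl <- gmediate:::sample_baseline(p, 150000)
  for (sc in list(scenario_always(), scenario_never(),
                  scenario_shift_all(p$registry),
                  scenario_shift_one("cvd"))) {
    enum <- oracle_enumerate_risk(p, sc)
    sim <- simulate_scenario(ms, bl, sc, seed = 5)
    se <- risk_se(enum$risk, 150000)
    expect_true(all(abs(sim$risk - enum$risk) <= 3 * se),
                info = sc$name)
  }
})

test_that("oracle simulation converges to the enumerated truth", {
  p <- tiny_truth()
  sc <- scenario_always()
  enum <- oracle_enumerate_risk(p, sc)
  sim <- oracle_simulate_risk(p, sc, n_mc = 120000, seed = 3)
  expect_true(all(abs(sim$risk - enum$risk)
                  <= 3 * risk_se(enum$risk, 120000)))
})

test_that("enumerated scenarios collapse under the sharp null", {
  p0 <- default_scm_params("tiny")
  for (cn in p0$registry$conditions) p0$trans[[cn]]["mdd"] <- 0
  p0$death["mdd"] <- 0
  rA <- oracle_enumerate_risk(p0, scenario_always())
  rB <- oracle_enumerate_risk(p0, scenario_never())
  rC <- oracle_enumerate_risk(p0, scenario_shift_all(p0$registry))
  rD <- oracle_enumerate_risk(p0, scenario_shift_one("cvd"))
  expect_equal(rA$risk, rB$risk, tolerance = 1e-12)
  expect_equal(rA$risk, rC$risk, tolerance = 1e-12)
  expect_equal(rA$risk, rD$risk, tolerance = 1e-12)
})

test_that("null mediation makes shifts vacuous but keeps a direct effect", {
  p <- default_scm_params("tiny")
  p$trans$cvd["mdd"] <- 0       # no exposure -> mediator pathway
  rA <- oracle_enumerate_risk(p, scenario_always())
  rB <- oracle_enumerate_risk(p, scenario_never())
  rC <- oracle_enumerate_risk(p, scenario_shift_all(p$registry))
  rD <- oracle_enumerate_risk(p, scenario_shift_one("cvd"))
  expect_equal(rA$risk, rC$risk, tolerance = 1e-12)
  expect_equal(rA$risk, rD$risk, tolerance = 1e-12)
  expect_gt(rA$risk[3], rB$risk[3])   # direct effect remains
})

test_that("shifts reproduce 'always' under CRN when mediation is null", {
  p <- default_scm_params("tiny")
  p$trans$cvd["mdd"] <- 0
  ms <- as_model_set(p)
  bl <- baseline_of(tiny_panel())
  us <- draw_uniforms(ms, nrow(bl), seed = 4)
  rA <- simulate_scenario(ms, bl, scenario_always(), uniforms = us)
  rC <- simulate_scenario(ms, bl, scenario_shift_all(p$registry),
                          uniforms = us)
  expect_identical(rA$risk, rC$risk)
})

test_that("risk curves are nondecreasing and order-invariant", {
  p <- tiny_truth()
  ms <- as_model_set(p)
  bl <- baseline_of(tiny_panel())
  us <- draw_uniforms(ms, nrow(bl), seed = 6)
  rc <- simulate_scenario(ms, bl, scenario_always(), uniforms = us)
  expect_true(all(diff(rc$risk) >= 0))
  expect_true(all(rc$risk >= 0 & rc$risk <= 1))

  # permuting individuals together with their uniform streams changes nothing
  perm <- sample.int(nrow(bl))
  us_p <- lapply(us, function(per_t) lapply(per_t, function(v) v[perm]))
  rc_p <- simulate_scenario(ms, bl[perm, , drop = FALSE],
                            scenario_always(), uniforms = us_p)
  expect_equal(rc$risk, rc_p$risk, tolerance = 1e-12)
})

test_that("run averaging is the arithmetic mean of per-run curves", {
  p <- tiny_truth()
  ms <- as_model_set(p)
  bl <- baseline_of(tiny_panel())[1:500, ]
  rs <- run_scenarios(ms, bl, list(scenario_always()), n_mc_runs = 4,
                      seed = 13)
  per_run <- vapply(rs$runs, function(r) r$always$risk, numeric(3))
  expect_equal(rs$curves$always$risk, rowMeans(per_run))

  one <- run_scenarios(ms, bl, list(scenario_always()), n_mc_runs = 1,
                       seed = 13)
  direct <- simulate_scenario(ms, bl, scenario_always(),
                              seed = gmediate:::derive_seed(13, "run", 1,
                                                            "always"))
  expect_identical(one$curves$always$risk, direct$risk)
})

test_that("Monte Carlo error shrinks like one over root scale", {
  p <- tiny_truth()
  ms <- as_model_set(p)
  bl <- baseline_of(tiny_panel())[1:400, ]
  final_risk <- function(mc_scale, seed)
    run_scenarios(ms, bl, list(scenario_always()), n_mc_runs = 1,
                  mc_scale = mc_scale, seed = seed)$curves$always$risk[3]
  r1 <- vapply(1:30, function(s) final_risk(1, s), numeric(1))
  r4 <- vapply(1:30, function(s) final_risk(4, s + 500), numeric(1))
  ratio <- sd(r4) / sd(r1)
  expect_lt(ratio, 0.75)   # expected 0.5 at quadruple scale
  expect_gt(ratio, 0.3)
})

test_that("scenario overrides may target mediator models only", {
  p <- tiny_truth()
  bad <- scenario_definition("bad", 1, c(hypertension = 0))
  expect_error(simulate_scenario(as_model_set(p), baseline_of(tiny_panel()),
                                 bad), "mediator")
  expect_error(oracle_enumerate_risk(p, bad), "mediator")
})

test_that("enumeration refuses state spaces beyond its guard", {
  p <- default_scm_params("paperlike")
  expect_error(oracle_enumerate_risk(p, scenario_always()),
               "too large")
})

test_that("risk-curve CSV export carries per-run and averaged curves", {
  p <- tiny_truth()
  rs <- run_scenarios(as_model_set(p), baseline_of(tiny_panel())[1:300, ],
                      list(scenario_always(), scenario_never()),
                      n_mc_runs = 2, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_risk_curves(rs, f)
  d <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_setequal(unique(d$run), c("1", "2", "mean"))
  avg <- d[d$scenario == "always" & d$run == "mean", ]
  expect_equal(avg$risk, rs$curves$always$risk)
})
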