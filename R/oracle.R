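#' Exact scenario risk by enumeration of the full state space
#'
#' Computes the cumulative mortality risk of a counterfactual scenario
#' under a known truth exactly, with no Monte Carlo error: the discrete
#' baseline strata (sex x age group x population group) are enumerated with
#' their probabilities, and within each stratum the probability mass over
#' all condition-state histories is propagated period by period (conditions
#' are conditionally independent given the previous state; diagnosed
#' conditions carry forward; death absorbs; censoring plays no role under
#' the scenario intervention). Guarded to small state spaces: at most 4
#' non-exposure conditions and 4 periods.
#'
#' @param params `scm_params` truth.
#' @param scenario `med_scenario`.
#' @return `risk_curve` with exact per-period cumulative risks.
#' @export
oracle_enumerate_risk <- function(params, scenario) {
  stopifnot(inherits(params, "scm_params"),
            inherits(scenario, "med_scenario"))
  reg <- params$registry
  free <- setdiff(reg$conditions, reg$exposure)
  if (length(free) > 4L || params$n_periods > 4L)
    stop("state space too large to enumerate (> 4 conditions or > 4 periods)")
  bad <- setdiff(names(scenario$overrides), reg$mediators)
  if (length(bad)) stop("overrides may target mediator models only")
  k <- length(free)
  expo <- reg$exposure
  expo_cur <- paste0(expo, "_cur")
  a <- scenario$exposure

  states <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(states) <- free
  ns <- nrow(states)

  bl <- params$baseline
  strata <- expand.grid(female = 0:1, age40 = 0:1, pop = POP_LEVELS,
                        stringsAsFactors = FALSE)
  strata$w <- ifelse(strata$female == 1, bl$p_female, 1 - bl$p_female) *
    ifelse(strata$age40 == 1, bl$p_age40, 1 - bl$p_age40) *
    bl$pop_probs[strata$pop]

  risk <- numeric(params$n_periods)

  for (s in seq_len(nrow(strata))) {
    if (strata$w[s] == 0) next
    bvals <- c(female = strata$female[s], age40 = strata$age40[s],
               stats::setNames(as.numeric(POP_LEVELS[-1L] == strata$pop[s]),
                               paste0("pop_", POP_LEVELS[-1L])))
    make_get <- function(Sprev, x_in) {
      force(Sprev); force(x_in)
      function(nm) {
        if (nm == expo || nm == expo_cur) return(rep(x_in, nrow(Sprev)))
        if (nm %in% names(bvals)) return(rep(bvals[[nm]], nrow(Sprev)))
        if (nm %in% free) return(Sprev[, nm])
        stop("unknown term in enumeration: ", nm)
      }
    }
    x_input <- function(cn, t) {
      if (cn %in% names(scenario$overrides) && t >= scenario$shift_start)
        scenario$overrides[[cn]] else a
    }
    # onset probability of each condition given each previous state
    onset_prob <- function(t, Sprev) {
      p <- matrix(0, nrow(Sprev), k, dimnames = list(NULL, free))
      for (j in seq_len(k)) {
        cn <- free[j]
        coefs <- if (t == 1L) params$init[[cn]] else params$trans[[cn]]
        g <- make_get(Sprev, x_input(cn, t))
        p[, j] <- stats::plogis(eval_coef_eta(coefs, g, nrow(Sprev)))
      }
      p
    }
    # death probability per state (time-invariant coefficients)
    pd <- stats::plogis(eval_coef_eta(params$death,
                                      make_get(states, a), ns))

    # period 1: initial-state models are baseline-only
    p1 <- onset_prob(1L, states[1L, , drop = FALSE])[1L, ]
    alive_mass <- apply(states, 1L, function(sv)
      prod(ifelse(sv == 1, p1, 1 - p1)))

    cum <- sum(alive_mass * pd)
    risk[1] <- risk[1] + strata$w[s] * cum
    alive_mass <- alive_mass * (1 - pd)

    for (t in seq_len(params$n_periods)[-1L]) {
      p_on <- onset_prob(t, states)
      P <- matrix(0, ns, ns)
      for (i in seq_len(ns)) {
        si <- states[i, ]
        for (j in seq_len(ns)) {
          sj <- states[j, ]
          if (any(si == 1 & sj == 0)) next   # carry-forward
          pr <- 1
          for (m in seq_len(k)) {
            if (si[m] == 1) next             # already diagnosed
            pr <- pr * if (sj[m] == 1) p_on[i, m] else 1 - p_on[i, m]
          }
          P[i, j] <- pr
        }
      }
      alive_mass <- as.numeric(alive_mass %*% P)
      cum <- cum + sum(alive_mass * pd)
      risk[t] <- risk[t] + strata$w[s] * cum
      alive_mass <- alive_mass * (1 - pd)
    }
  }
  structure(list(scenario = scenario$name, risk = risk, n = NA_integer_,
                 run = NA), class = "risk_curve")
}

#' Scenario risk by large-sample simulation from the truth
#'
#' Ground truth at non-enumerable scale: forward-simulates `n_mc`
#' individuals from the known generative model under a scenario (baseline
#' covariates drawn from the truth's baseline distribution; censoring off).
#' Converges to [oracle_enumerate_risk()] as `n_mc` grows.
#'
#' @param params `scm_params` truth.
#' @param scenario `med_scenario`.
#' @param n_mc number of simulated individuals (> 0).
#' @param seed integer seed.
#' @return `risk_curve`.
#' @export
oracle_simulate_risk <- function(params, scenario, n_mc, seed = 1L) {
  stopifnot(inherits(params, "scm_params"))
  if (n_mc <= 0) stop("n_mc must be > 0")
  set.seed(derive_seed(seed, "oracle-baseline", scenario$name))
  baseline <- sample_baseline(params, n_mc)
  simulate_scenario(as_model_set(params), baseline, scenario,
                    seed = derive_seed(seed, "oracle-sim"))
}
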