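test_that("outcome_integral matches constants and a refined-grid oracle", {
  traj <- structure(list(times = seq(0, 10, length.out = 6),
                         states = matrix(1, 6, 2,
                                         dimnames = list(NULL, c("S", "R")))),
                    class = "trajectory")
  expect_equal(outcome_integral(traj, c("S", "R"), 2), 10)

  # SIR with no infected individuals stays put: integral of (S+R)/N is T
  sir <- fixture("sir")
  ra <- rate_assignment(sir, u0 = c(S = 1, I = 0, R = 0))
  tr <- simulate_ode(sir, ra, c(0, 10), 51)
  expect_equal(outcome_integral(tr, c("S", "R"), 1), 10, tolerance = 1e-9)

  # refined-grid quadrature oracle on a fitted-scale SIR run
  ra2 <- rate_assignment(sir, u0 = c(S = 0.99, I = 0.01, R = 0))
  coarse <- outcome_integral(simulate_ode(sir, ra2, c(0, 30), 201),
                             c("S", "R"), 1)
  fine <- outcome_integral(simulate_ode(sir, ra2, c(0, 30), 4001),
                           c("S", "R"), 1)
  expect_lt(abs(coarse - fine) / abs(fine), 1e-4)

  expect_error(outcome_integral(tr, "nope", 1), "unknown species")
  expect_error(outcome_integral(tr, character(), 1), "non-empty")
  expect_error(outcome_integral(tr, "S", 0), "> 0")
})

test_that("sensitivities agree with a Richardson step-halving oracle", {
  sir <- fixture("sir")
  ra <- rate_assignment(sir, u0 = c(S = 0.99, I = 0.01, R = 0))
  rep_ <- sensitivity(sir, ra, c("S", "R"), t_span = c(0, 30))
  Jfun <- function(beta) {
    tra <- ra; tra$beta <- beta
    outcome_integral(simulate_ode(sir, tra, c(0, 30), 201), c("S", "R"), 1)
  }
  for (t in 1:2) {
    oracle <- oracle_richardson(Jfun, ra$beta, t, 1e-3 * max(abs(ra$beta[t]), 1))
    expect_lt(abs(rep_$per_transition[t] - oracle) / abs(oracle), 1e-4)
  }
  # slowing recovery keeps people infectious longer: dJ/d(recovery) > 0
  expect_gt(rep_$per_transition[["recovery"]], 0)
  expect_lt(rep_$per_transition[["infection"]], 0)
})

test_that("transitions disconnected from the outcome have zero sensitivity", {
  net <- petri_net(c("S", "I", "R", "X", "Y"),
                   c("infection", "recovery", "drift"),
                   data.frame(species = c(1, 2, 2, 4), transition = c(1, 1, 2, 3)),
                   data.frame(species = c(2, 2, 3, 5), transition = c(1, 1, 2, 3)))
  ra <- rate_assignment(net, c(0.3, 0.1, 0.7),
                        c(S = 0.99, I = 0.01, R = 0, X = 1, Y = 0))
  rep_ <- sensitivity(net, ra, c("S", "R"), total = 1, t_span = c(0, 10))
  expect_lt(abs(rep_$per_transition[["drift"]]), 1e-10)
})

test_that("sensitivity scales linearly with the outcome functional", {
  sir <- fixture("sir")
  ra <- rate_assignment(sir, u0 = c(S = 0.99, I = 0.01, R = 0))
  a <- sensitivity(sir, ra, c("S", "R"), total = 1, t_span = c(0, 20))
  b <- sensitivity(sir, ra, c("S", "R"), total = 2, t_span = c(0, 20))
  expect_lt(max(abs(a$per_transition - 2 * b$per_transition)), 1e-10)
})

test_that("rates are recovered from noiseless synthetic data within 1%", {
  sir <- fixture("sir")
  truth <- rate_assignment(sir, u0 = c(S = 0.99, I = 0.01, R = 0))
  obs <- synthetic_observations(sir, truth, times = seq(0, 20, 1),
                                observed = c("I", "R"))
  start <- rate_assignment(sir, beta = c(1, 1), u0 = truth$u0)
  fit <- fit_rates(sir, obs, start,
                   free_rates = c("infection", "recovery"),
                   bounds = list(infection = c(0.001, 10),
                                 recovery = c(0.001, 10)),
                   seed = 7)
  expect_lt(abs(fit$estimates[["infection"]] - 0.3) / 0.3, 0.01)
  expect_lt(abs(fit$estimates[["recovery"]] - 0.1) / 0.1, 0.01)
  expect_true(all(fit$loss <= fit$start_losses))

  fit2 <- fit_rates(sir, obs, start,
                    free_rates = c("infection", "recovery"),
                    bounds = list(infection = c(0.001, 10),
                                  recovery = c(0.001, 10)),
                    seed = 7)
  expect_identical(fit$estimates, fit2$estimates)  # determinism contract
})

test_that("recovery within 5% under 1% multiplicative noise", {
  sir <- fixture("sir")
  truth <- rate_assignment(sir, u0 = c(S = 0.99, I = 0.01, R = 0))
  obs <- synthetic_observations(sir, truth, times = seq(0, 20, 1),
                                observed = c("I", "R"),
                                noise_cv = 0.01, seed = 42)
  fit <- fit_rates(sir, obs, rate_assignment(sir, c(1, 1), truth$u0),
                   free_rates = c("infection", "recovery"),
                   bounds = list(infection = c(0.001, 10),
                                 recovery = c(0.001, 10)),
                   seed = 7, n_starts = 4)
  expect_lt(abs(fit$estimates[["infection"]] - 0.3) / 0.3, 0.05)
  expect_lt(abs(fit$estimates[["recovery"]] - 0.1) / 0.1, 0.05)
})

test_that("degenerate and malformed fit requests are handled", {
  sir <- fixture("sir")
  truth <- rate_assignment(sir, u0 = c(S = 0.99, I = 0.01, R = 0))
  obs <- synthetic_observations(sir, truth, times = 0:5, observed = "I")
  res <- fit_rates(sir, obs, truth)
  expect_identical(res$ra, truth)
  expect_lt(res$loss, 1e-10)
  expect_error(fit_rates(sir, obs, truth, free_rates = "infection"),
               "bounds")
  bad_obs <- observations(0:5, data.frame(Z = rep(1, 6)))
  expect_error(fit_rates(sir, bad_obs, truth), "not in the model")
})

test_that("initial values can be free parameters", {
  sir <- fixture("sir")
  truth <- rate_assignment(sir, u0 = c(S = 0.99, I = 0.01, R = 0))
  obs <- synthetic_observations(sir, truth, times = seq(0, 20, 1),
                                observed = c("I", "R"))
  start <- rate_assignment(sir, u0 = c(S = 0.99, I = 0.05, R = 0))
  fit <- fit_rates(sir, obs, start, free_init = "I",
                   bounds = list(I = c(1e-4, 0.5)), seed = 3, n_starts = 4)
  expect_lt(abs(fit$estimates[["I"]] - 0.01) / 0.01, 0.01)
})
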