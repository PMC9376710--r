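#' Outcome functional: time integral of a population fraction
#'
#' Integrates (sum of a subset of species) / total over the trajectory's
#' time range by the trapezoidal rule. The canonical use is the integral
#' of the non-infectious proportion of the population over an epidemic
#' simulation, a policy-relevant outcome.
#'
#' @param traj a `trajectory`.
#' @param species_subset character vector of species labels to sum.
#' @param total positive normalizing constant (e.g. total population).
#' @return numeric scalar.
#' @export
outcome_integral <- function(traj, species_subset, total) {
  if (length(species_subset) == 0L) stop_opetri("species_subset must be non-empty")
  if (!is.numeric(total) || total <= 0) stop_opetri("total must be > 0")
  miss <- setdiff(species_subset, colnames(traj$states))
  if (length(miss) > 0)
    stop_opetri("unknown species label(s): ", paste(miss, collapse = ", "))
  y <- rowSums(traj$states[, species_subset, drop = FALSE]) / total
  t <- traj$times
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Sensitivity of an outcome to the transition rates
#'
#' Computes dJ/d beta_t for every transition by central finite
#' differences with per-parameter step h = 1e-4 * max(|beta_t|, 1),
#' where J is the trapezoidal integral of the chosen species subset
#' fraction over a mass-action ODE simulation. Deterministic.
#'
#' @param net a valid `petri_net`.
#' @param ra a `rate_assignment`.
#' @param species_subset labels defining the outcome, as in
#'   [outcome_integral()].
#' @param total normalizing constant; defaults to `sum(ra$u0)`.
#' @param t_span length-2 time span of the underlying simulation.
#' @param n_points report points of the underlying simulation.
#' @param h_rel relative finite-difference step (default 1e-4).
#' @return object of class `sensitivity_report`: list with `outcome`
#'   (J at `ra`), `per_transition` (named numeric dJ/d beta) and
#'   `step_sizes` (named numeric).
#' @export
sensitivity <- function(net, ra, species_subset, total = sum(ra$u0),
                        t_span, n_points = 201L, h_rel = 1e-4) {
  J <- function(beta) {
    tra <- ra; tra$beta <- beta
    outcome_integral(simulate_ode(net, tra, t_span, n_points),
                     species_subset, total)
  }
  base <- J(ra$beta)
  labels <- net$transitions$label
  h <- h_rel * pmax(abs(ra$beta), 1)
  grad <- numeric(length(labels))
  for (t in seq_along(labels)) {
    bp <- ra$beta; bp[t] <- bp[t] + h[t]
    bm <- ra$beta; bm[t] <- bm[t] - h[t]
    grad[t] <- (J(bp) - J(bm)) / (2 * h[t])
  }
  names(grad) <- labels; names(h) <- labels
  structure(list(outcome = base, per_transition = grad, step_sizes = h),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("outcome J = %.6g\n", x$outcome))
  cat("sensitivities dJ/dbeta:\n")
  for (nm in names(x$per_transition))
    cat(sprintf("  %-20s % .6g\n", nm, x$per_transition[[nm]]))
  invisible(x)
}

#' Trajectory observations for calibration
#'
#' @param times increasing numeric observation times.
#' @param values data frame or matrix, one column per observed species
#'   label, one row per time.
#' @return object of class `observations` with fields `times`, `values`
#'   (data frame) and `observed` (labels).
#' @export
observations <- function(times, values) {
  values <- as.data.frame(values)
  if (length(times) != nrow(values))
    stop_opetri("times and values must have matching lengths")
  if (any(diff(times) <= 0)) stop_opetri("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = values,
                 observed = colnames(values)),
            class = "observations")
}

#' Generate synthetic observations from a model
#'
#' Simulates the mass-action ODE and records the chosen species at the
#' requested times, optionally with multiplicative Gaussian noise; the
#' standard workflow for parameter-recovery experiments.
#'
#' @param net a valid `petri_net`.
#' @param ra a `rate_assignment` (the ground truth).
#' @param times observation times.
#' @param observed species labels to record.
#' @param noise_cv coefficient of variation of multiplicative Gaussian
#'   noise (0 = noiseless).
#' @param seed seed used when `noise_cv > 0`.
#' @return an `observations` object.
#' @export
synthetic_observations <- function(net, ra, times, observed,
                                   noise_cv = 0, seed = 1L) {
  traj <- simulate_ode(net, ra, range(times), n_points = 401L)
  vals <- sapply(observed, function(lab)
    stats::approx(traj$times, traj$states[, lab], xout = times)$y)
  vals <- as.data.frame(vals)
  colnames(vals) <- observed
  if (noise_cv > 0) {
    set.seed(as.integer(seed))
    for (j in seq_along(vals))
      vals[[j]] <- vals[[j]] * (1 + noise_cv * stats::rnorm(nrow(vals)))
  }
  observations(times, vals)
}

# Sum-of-squares loss of a candidate assignment against observations.
# Integrates at exactly the observation times (u0 applies at the first);
# tolerances are looser than the reporting integrator: the loss surface
# only needs to be smooth well below the residuals that matter.
fit_loss <- function(net, ra, obs) {
  f <- vectorfield(net, ra$beta)
  sol <- deSolve::ode(y = ra$u0, times = obs$times,
                      func = function(t, y, parms) list(f(y)),
                      parms = NULL, method = "ode45",
                      rtol = 1e-6, atol = 1e-8)
  loss <- 0
  for (lab in obs$observed)
    loss <- loss + sum((sol[, lab] - obs$values[[lab]])^2)
  loss
}

#' Fit transition rates (and initial values) to observations
#'
#' Bounded least squares on the observed species trajectories: the loss
#' is the unweighted sum of squared residuals at the observation times.
#' The free set may mix transition rates and initial populations (both
#' are estimated in practice). Optimization is multi-start: `n_starts`
#' seeded log-uniform draws within the bounds, each refined with
#' L-BFGS-B; the best refined fit is returned. Repeated calls with the
#' same seed are bit-identical.
#'
#' @param net a valid `petri_net`.
#' @param obs an `observations` object; every observed label must be a
#'   species of `net`.
#' @param ra a `rate_assignment` providing the fixed rates and initial
#'   values.
#' @param free_rates transition labels whose rates are estimated.
#' @param free_init species labels whose initial values are estimated.
#' @param bounds named list mapping each free name to `c(lower, upper)`
#'   with `lower > 0` (starts are log-uniform).
#' @param seed integer seed for the multi-start draws.
#' @param n_starts number of starts (default 8).
#' @return list with `ra` (fitted `rate_assignment`), `estimates`
#'   (named numeric of the free parameters), `loss`, `start_losses`
#'   (refined loss per start) and `starts` (matrix of start points).
#' @export
fit_rates <- function(net, obs, ra, free_rates = character(),
                      free_init = character(), bounds = list(),
                      seed = 1L, n_starts = 8L) {
  miss <- setdiff(obs$observed, net$species$label)
  if (length(miss) > 0)
    stop_opetri("observed label(s) not in the model: ", paste(miss, collapse = ", "))
  free <- c(free_rates, free_init)
  if (length(free) == 0L)
    return(list(ra = ra, estimates = numeric(0), loss = fit_loss(net, ra, obs),
                start_losses = numeric(0), starts = NULL))
  for (nm in free) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2 || b[1] <= 0 || b[2] <= b[1])
      stop_opetri("free parameter '", nm,
                  "' needs bounds c(lower, upper) with 0 < lower < upper")
  }
  lower <- vapply(free, function(nm) bounds[[nm]][1], numeric(1))
  upper <- vapply(free, function(nm) bounds[[nm]][2], numeric(1))

  apply_free <- function(x) {
    cand <- ra
    for (k in seq_along(free_rates)) cand$beta[free_rates[k]] <- x[k]
    for (k in seq_along(free_init))
      cand$u0[free_init[k]] <- x[length(free_rates) + k]
    cand
  }
  objective <- function(x) fit_loss(net, apply_free(x), obs)

  set.seed(as.integer(seed))
  starts <- matrix(exp(stats::runif(n_starts * length(free),
                                    rep(log(lower), each = n_starts),
                                    rep(log(upper), each = n_starts))),
                   nrow = n_starts, dimnames = list(NULL, free))
  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fits[[i]] <- stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                              lower = lower, upper = upper,
                              control = list(factr = 1e4))
  }
  losses <- vapply(fits, function(f) f$value, numeric(1))
  best <- which.min(losses)
  est <- fits[[best]]$par
  names(est) <- free
  list(ra = apply_free(est), estimates = est, loss = losses[best],
       start_losses = losses, starts = starts)
}
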