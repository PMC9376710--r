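#' Rate assignment for a Petri net
#'
#' Bundles the rate constants (one per transition) and initial
#' concentrations or counts (one per species) needed to simulate a net.
#'
#' @param net a valid `petri_net`.
#' @param beta numeric vector of nonnegative rate constants; may be named
#'   by transition label, otherwise in transition order. Defaults to the
#'   rates stored on the net's transitions.
#' @param u0 numeric vector of nonnegative initial values; may be named by
#'   species label, otherwise in species order.
#' @return object of class `rate_assignment` with numeric fields `beta`
#'   and `u0`, named and complete over the net's tables.
#' @export
rate_assignment <- function(net, beta = NULL, u0) {
  resolve <- function(x, labels, what) {
    if (is.null(x)) stop_opetri("missing ", what)
    if (!is.null(names(x)) && any(names(x) != "")) {
      miss <- setdiff(labels, names(x))
      if (length(miss) > 0)
        stop_opetri(what, " incomplete: missing ", paste(miss, collapse = ", "))
      x <- x[labels]
    } else if (length(x) != length(labels)) {
      stop_opetri(what, " must have one value per row (", length(labels), ")")
    }
    x <- as.numeric(x)
    if (any(is.na(x) | x < 0)) stop_opetri(what, " must be nonnegative and complete")
    names(x) <- labels
    x
  }
  if (is.null(beta)) beta <- net$transitions$rate
  structure(list(beta = resolve(beta, net$transitions$label, "beta"),
                 u0 = resolve(u0, net$species$label, "u0")),
            class = "rate_assignment")
}

#' Mass-action vector field of a Petri net
#'
#' Applies the law of mass action: transition t fires with flux
#' phi_t = beta_t * prod over its input species of u_s^m(s,t), where
#' m(s, t) is the input multiplicity (stoichiometric coefficient). The
#' derivative of species s sums + phi_t over transitions producing s and
#' - phi_t over transitions consuming it, with multiplicity. No clipping
#' is applied: negative states are a modelling diagnostic, not an error.
#'
#' @param net a valid `petri_net`.
#' @param beta rate constants, one per transition (optionally named by
#'   transition label).
#' @return a function `u -> du` on numeric state vectors of length equal
#'   to the species count.
#' @export
vectorfield <- function(net, beta) {
  m <- stoichiometry_matrices(net)
  labels <- net$transitions$label
  if (!is.null(names(beta)) && any(names(beta) != "")) beta <- beta[labels]
  beta <- as.numeric(beta)
  if (length(beta) != nrow(net$transitions) || any(is.na(beta)))
    stop_opetri("beta must supply one rate per transition")
  stoich <- m$outputs - m$inputs
  ns <- nrow(net$species)
  function(u) {
    if (length(u) != ns)
      stop_opetri("state vector length ", length(u), " != species count ", ns)
    phi <- beta * apply(u ^ m$inputs, 2, prod)
    drop(stoich %*% phi)
  }
}

new_trajectory <- function(times, states, labels) {
  colnames(states) <- labels
  structure(list(times = times, states = states), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d time points on [%g, %g], %d species (%s)\n",
              length(x$times), min(x$times), max(x$times), ncol(x$states),
              paste(colnames(x$states), collapse = ", ")))
  invisible(x)
}

#' Deterministic ODE simulation of a Petri net
#'
#' Integrates the mass-action vector field with an adaptive
#' Dormand-Prince Runge-Kutta scheme (deSolve's `ode45`), rtol 1e-8 /
#' atol 1e-10, and reports the solution at evenly spaced times.
#'
#' @param net a valid `petri_net`.
#' @param ra a `rate_assignment`.
#' @param t_span length-2 numeric, start and end time.
#' @param n_points number of report times (evenly spaced, ends included).
#' @param rtol,atol integrator tolerances.
#' @return a `trajectory` (fields `times`, `states`).
#' @export
simulate_ode <- function(net, ra, t_span, n_points = 101L,
                         rtol = 1e-8, atol = 1e-10) {
  f <- vectorfield(net, ra$beta)
  times <- seq(t_span[1], t_span[2], length.out = n_points)
  sol <- deSolve::ode(y = ra$u0, times = times,
                      func = function(t, y, parms) list(f(y)),
                      parms = NULL, method = "ode45", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop_opetri("ODE integration failed: istate = ", attr(sol, "istate")[1])
  new_trajectory(sol[, 1], unname(sol[, -1, drop = FALSE]), net$species$label)
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Samples one realization of the continuous-time Markov jump process of
#' the net. Propensities use falling factorials of the token counts
#' (a_t = beta_t * prod n_s (n_s - 1) ... (n_s - m + 1)), the standard
#' stochastic convention, which deliberately differs from the plain
#' powers of the deterministic mass-action semantics. Waiting times are
#' drawn by inverse transform from a single seeded stream, so runs are
#' bit-reproducible.
#'
#' @param net a valid `petri_net`.
#' @param ra a `rate_assignment` whose `u0` are nonnegative integers.
#' @param t_max stop time.
#' @param seed integer seed (mandatory).
#' @return data frame with columns `time` and `transition` (label), one
#'   row per firing event, in time order; zero rows if nothing can fire.
#' @export
gillespie_simulate <- function(net, ra, t_max, seed) {
  if (missing(seed) || is.null(seed)) stop_opetri("seed is mandatory")
  if (any(ra$u0 != round(ra$u0)))
    stop_opetri("gillespie_simulate requires integer initial counts")
  set.seed(as.integer(seed))
  m <- stoichiometry_matrices(net)
  stoich <- m$outputs - m$inputs
  nt <- nrow(net$transitions)
  n <- round(unname(ra$u0))
  # Per-transition input species and multiplicities, precomputed once.
  in_idx <- lapply(seq_len(nt), function(t) which(m$inputs[, t] > 0L))
  in_mult <- lapply(seq_len(nt), function(t) m$inputs[in_idx[[t]], t])
  t_now <- 0
  cap <- 1024L; ev_t <- numeric(cap); ev_i <- integer(cap); k <- 0L
  a <- numeric(nt)
  repeat {
    for (t in seq_len(nt)) {
      p <- ra$beta[[t]]
      idx <- in_idx[[t]]; mult <- in_mult[[t]]
      for (q in seq_along(idx)) {
        x <- n[idx[q]]
        for (r in seq_len(mult[q])) p <- p * (x - r + 1)
      }
      a[t] <- p
    }
    a0 <- sum(a)
    if (a0 <= 0) break
    t_now <- t_now - log(stats::runif(1)) / a0
    if (t_now > t_max) break
    pick <- findInterval(stats::runif(1) * a0, cumsum(a)) + 1L
    n <- n + stoich[, pick]
    k <- k + 1L
    if (k > cap) {
      cap <- cap * 2L
      length(ev_t) <- cap; length(ev_i) <- cap
    }
    ev_t[k] <- t_now; ev_i[k] <- pick
  }
  data.frame(time = ev_t[seq_len(k)],
             transition = net$transitions$label[ev_i[seq_len(k)]],
             stringsAsFactors = FALSE)
}
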