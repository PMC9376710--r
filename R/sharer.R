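#' Open dynamical systems (resource sharers)
#'
#' A resource sharer is a general open ODE: a list of named state
#' variables, a vector of ports exposing some of them, named parameters,
#' and a field mapping (time, state, params) to the derivative vector.
#' Sharers compose along a UWD by identifying exposed variables wired to
#' a common junction and summing the rates of change of identified
#' variables.
#'
#' @param state_labels character vector of state names.
#' @param ports integer vector of state indices exposed through the
#'   interface (one port each, in order).
#' @param field function `(t, u, params) -> du` with `length(du)` equal
#'   to the state count.
#' @param params named numeric vector of default parameter values.
#' @return object of class `resource_sharer`.
#' @export
resource_sharer <- function(state_labels, ports = integer(), field,
                            params = numeric()) {
  ports <- as.integer(ports)
  if (any(ports < 1L | ports > length(state_labels)))
    stop_opetri("port index out of range")
  structure(list(state_labels = as.character(state_labels), ports = ports,
                 params = params, field = field),
            class = "resource_sharer")
}

#' Delay sharer: a resource sharer whose field reads the history
#'
#' Adds a list of fixed positive delays tau_k. The field receives a
#' fourth argument `hist`, a matrix with one column per declared delay
#' holding the lagged state u(t - tau_k). A system with a formally empty
#' delay list represents an ODE coerced into the DDE world (see
#' [ode_to_dde()]); a literal zero delay is not allowed.
#'
#' @inheritParams resource_sharer
#' @param delays numeric vector of strictly positive delays.
#' @param field function `(t, u, params, hist) -> du`.
#' @return object of class `c("delay_sharer", "resource_sharer")`.
#' @export
delay_sharer <- function(state_labels, ports = integer(), field,
                         params = numeric(), delays = numeric()) {
  if (any(delays <= 0))
    stop_opetri("delays must be strictly positive; represent a zero delay by ode_to_dde()")
  s <- resource_sharer(state_labels, ports, field, params)
  s$delays <- as.numeric(delays)
  class(s) <- c("delay_sharer", "resource_sharer")
  s
}

#' Coerce an ODE sharer to a (trivially) delayed sharer
#'
#' The resulting delay sharer has an empty delay list and a field that
#' ignores the history, so simulation results are identical. This is the
#' coercion used when ODE and DDE submodels are mixed in one composite.
#'
#' @param s a `resource_sharer`.
#' @return a `delay_sharer` with `delays = numeric(0)`.
#' @export
ode_to_dde <- function(s) {
  if (inherits(s, "delay_sharer")) return(s)
  delay_sharer(s$state_labels, s$ports,
               field = function(t, u, params, hist) s$field(t, u, params),
               params = s$params, delays = numeric(0))
}

# Merge parameter namespaces by name; a collision with different values
# is an error (the UWD junctions, not parameter names, carry sharing).
merge_params <- function(plist) {
  merged <- numeric(0)
  for (p in plist) {
    if (length(p) == 0) next
    for (nm in names(p)) {
      if (nm %in% names(merged) && !isTRUE(all.equal(merged[[nm]], p[[nm]])))
        stop_opetri("parameter name collision with different values: ", nm)
      merged[nm] <- p[[nm]]
    }
  }
  merged
}

# Accumulate dub into du at positions idx, accumulating duplicates.
scatter_add <- function(du, idx, dub) {
  if (!anyDuplicated(idx)) {
    du[idx] <- du[idx] + dub
  } else {
    for (i in seq_along(idx)) du[idx[i]] <- du[idx[i]] + dub[i]
  }
  du
}

#' Compose resource sharers along a UWD
#'
#' One component per box, with one port per box-port in port order.
#' Composite states are the junction classes (junction label and order
#' win) followed by unshared states; the composite field routes the
#' composite state to each component, evaluates the component fields and
#' sums the contributions on identified variables. If any component is a
#' `delay_sharer`, the others are coerced via [ode_to_dde()] and the
#' result is a `delay_sharer` whose delay list is the sorted,
#' deduplicated concatenation of the component delays.
#'
#' @param d a valid `uwd`.
#' @param components list of `resource_sharer` / `delay_sharer`, one per
#'   box.
#' @return the composite sharer, with attribute `state_map` (list per
#'   component: local state index -> composite state index).
#' @export
sharer_oapply <- function(d, components) {
  nb <- nrow(d$boxes)
  if (length(components) != nb)
    stop_opetri("expected ", nb, " components (one per box), got ",
                length(components))
  n_states <- vapply(components, function(s) length(s$state_labels), integer(1))
  exposed <- lapply(components, function(s) s$ports)
  local_labels <- unlist(lapply(components, function(s) s$state_labels),
                         use.names = FALSE)
  glue <- glue_states(d, n_states, exposed, local_labels %||% character(0))
  glue$labels <- make.unique(glue$labels, sep = "_")
  params <- merge_params(lapply(components, function(s) s$params))
  any_delay <- any(vapply(components, inherits, logical(1), "delay_sharer"))

  state_of <- glue$state_of
  if (!any_delay) {
    fields <- lapply(components, function(s) s$field)
    field <- function(t, u, params) {
      du <- numeric(glue$n_total)
      for (b in seq_len(nb)) {
        idx <- state_of[[b]]
        du <- scatter_add(du, idx, fields[[b]](t, u[idx], params))
      }
      du
    }
    out <- resource_sharer(glue$labels, glue$outer_states, field, params)
  } else {
    comps <- lapply(components, ode_to_dde)
    delays <- sort(unique(unlist(lapply(comps, function(s) s$delays))))
    slot <- lapply(comps, function(s) match(s$delays, delays))
    field <- function(t, u, params, hist) {
      du <- numeric(glue$n_total)
      for (b in seq_len(nb)) {
        idx <- state_of[[b]]
        hb <- hist[idx, slot[[b]], drop = FALSE]
        du <- scatter_add(du, idx, comps[[b]]$field(t, u[idx], params, hb))
      }
      du
    }
    out <- delay_sharer(glue$labels, glue$outer_states, field, params,
                        delays = delays)
  }
  attr(out, "state_map") <- state_of
  out
}

#' Interpret an open Petri net as a resource sharer
#'
#' One state per species, one port per (singleton) foot, and the
#' mass-action vector field as dynamics. Reinterpretation commutes with
#' composition: composing Petri nets and then taking mass action equals
#' taking mass action componentwise and composing the sharers.
#'
#' @param o an `open_petri_net` (or a closed `petri_net`).
#' @param beta rate constants, one per transition.
#' @return a `resource_sharer`.
#' @export
petri_to_sharer <- function(o, beta = NULL) {
  if (inherits(o, "petri_net")) o <- make_open(o, list())
  if (any(o$feet != 1L))
    stop_opetri("petri_to_sharer requires singleton feet")
  if (is.null(beta)) beta <- o$net$transitions$rate
  f <- vectorfield(o$net, beta)
  resource_sharer(o$net$species$label,
                  ports = vapply(o$legs, function(l) l[1L], integer(1)),
                  field = function(t, u, params) unname(f(u)))
}

#' Simulate a resource sharer or delay sharer
#'
#' ODE sharers are integrated with the adaptive Dormand-Prince scheme
#' (deSolve `ode45`). Delay sharers are integrated with deSolve's DDE
#' solver; history lookups at or before the start time use the supplied
#' history function, later lookups interpolate the accumulated solution.
#'
#' @param s a `resource_sharer` or `delay_sharer`.
#' @param params named numeric overrides merged over `s$params`.
#' @param u0 numeric initial state (length = state count). For a delay
#'   sharer it defaults to `history(t0)`.
#' @param t_span length-2 numeric time span.
#' @param n_points number of evenly spaced report times.
#' @param history for delay sharers with nonempty delays: a constant
#'   numeric vector or a function of time defined on
#'   `[t0 - max(delays), t0]`.
#' @param rtol,atol integrator tolerances.
#' @return a `trajectory`.
#' @export
simulate_sharer <- function(s, params = NULL, u0 = NULL, t_span,
                            n_points = 101L, history = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  pars <- s$params
  if (!is.null(params)) for (nm in names(params)) pars[nm] <- params[[nm]]
  times <- seq(t_span[1], t_span[2], length.out = n_points)
  t0 <- t_span[1]
  n <- length(s$state_labels)

  is_dde <- inherits(s, "delay_sharer") && length(s$delays) > 0L
  if (is_dde) {
    if (is.null(history) && is.null(u0))
      stop_opetri("a delay sharer needs a history (constant vector or function)")
    hfun <- if (is.function(history)) history
            else if (!is.null(history)) { h <- as.numeric(history); function(t) h }
            else { h <- as.numeric(u0); function(t) h }
    if (is.null(u0)) u0 <- hfun(t0)
    nd <- length(s$delays)
    func <- function(t, y, parms) {
      hist <- matrix(0, n, nd)
      for (k in seq_len(nd)) {
        tk <- t - s$delays[k]
        hist[, k] <- if (tk <= t0) hfun(tk) else deSolve::lagvalue(tk)
      }
      list(s$field(t, y, pars, hist))
    }
    sol <- deSolve::dede(y = as.numeric(u0), times = times, func = func,
                         parms = NULL, rtol = rtol, atol = atol)
  } else {
    if (is.null(u0)) {
      if (is.null(history)) stop_opetri("u0 is required for an ODE sharer")
      u0 <- if (is.function(history)) history(t0) else history
    }
    f <- if (inherits(s, "delay_sharer"))
      function(t, y, parms) list(s$field(t, y, pars, matrix(0, n, 0)))
    else
      function(t, y, parms) list(s$field(t, y, pars))
    sol <- deSolve::ode(y = as.numeric(u0), times = times, func = f,
                        parms = NULL, method = "ode45",
                        rtol = rtol, atol = atol)
  }
  if (attr(sol, "istate")[1] < 0)
    stop_opetri("integration failed: istate = ", attr(sol, "istate")[1])
  new_trajectory(sol[, 1], unname(sol[, -1, drop = FALSE]), s$state_labels)
}

#' @export
print.resource_sharer <- function(x, ...) {
  kind <- if (inherits(x, "delay_sharer")) "delay_sharer" else "resource_sharer"
  cat(sprintf("%s: states (%s), %d ports%s\n", kind,
              paste(x$state_labels, collapse = ", "), length(x$ports),
              if (inherits(x, "delay_sharer"))
                sprintf(", delays (%s)", paste(x$delays, collapse = ", "))
              else ""))
  invisible(x)
}
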