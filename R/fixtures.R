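# Built-in model library. Every model exercised by the package's tests
# and examples is constructed here programmatically: classic compartmental
# nets (SIR, SIS, vaccination), the cross-exposure wiring, type systems
# for infectious and vector-borne disease, stratification schemes
# (quarantine, age, flux and simple-trip metapopulation movement) and the
# Ross-Macdonald host/vector/bloodmeal decomposition as Petri nets, ODE
# sharers and a delayed variant.

fixture_catalog <- list(
  sir = "SIR compartmental net (infection 0.3, recovery 0.1)",
  sis = "SIS compartmental net (infection 0.3, recovery 0.1)",
  vivr = "SIR-isomorphic net for a vaccinated population (V, Iv, R)",
  cross_exposure = "vaccination plus cross transmission between vaccinated and unvaccinated",
  sviivr_components = "wiring diagram + three open components whose composite is the SVIIvR model",
  uwd_sviivr = "three-box wiring diagram gluing SIR, VIvR and cross-exposure (10 ports, 5 junctions)",
  uwd_host_vector = "three-box host/vector/bloodmeal wiring diagram sharing IH and IV",
  uwd_host_vector_hier = "hierarchical host/vector wiring: outer diagram + vector-dynamics inner diagram + its flattening",
  p_infectious = "infectious-disease type system: one place type; disease-status, strata-change and interaction transition types",
  p_vector_borne = "vector-borne type system: host and vector place types; interactions only between them",
  sir_typed = "SIR with strata self-loops, typed by p_infectious",
  sis_typed = "SIS with strata self-loops, typed by p_infectious",
  host_vector_sis = "host/vector SIS net validly typed by p_vector_borne",
  host_vector_sis_forbidden = "host/vector SIS plus two transitions that admit no typing (species change, vector-to-vector infection)",
  quarantine = "quarantine stratification scheme typed by p_infectious",
  age = "two-group age stratification scheme typed by p_infectious",
  flux = "flux metapopulation movement scheme on n patches, typed by p_infectious",
  simple_trip = "simple-trip movement scheme on n patches (current patch x residence), typed by p_infectious",
  ross_macdonald_petri = "Ross-Macdonald decomposition as open Petri nets + wiring diagram",
  ross_macdonald_ode = "Ross-Macdonald decomposition as ODE resource sharers + wiring diagram",
  ross_macdonald_dde = "Ross-Macdonald decomposition with a delayed bloodmeal (vector incubation) + wiring diagram"
)

#' List the built-in fixture catalog
#' @return data frame with columns `name` and `description`.
#' @export
fixture_names <- function() {
  data.frame(name = names(fixture_catalog),
             description = unlist(fixture_catalog, use.names = FALSE),
             stringsAsFactors = FALSE)
}

arcs <- function(species, transition) data.frame(species = species,
                                                 transition = transition)

fixture_sir <- function() petri_net(
  species = c("S", "I", "R"),
  transitions = c("infection", "recovery"),
  input_arcs = arcs(c(1, 2, 2), c(1, 1, 2)),
  output_arcs = arcs(c(2, 2, 3), c(1, 1, 2)),
  rates = c(0.3, 0.1))

fixture_sis <- function() petri_net(
  species = c("S", "I"),
  transitions = c("infection", "recovery"),
  input_arcs = arcs(c(1, 2, 2), c(1, 1, 2)),
  output_arcs = arcs(c(2, 2, 1), c(1, 1, 2)),
  rates = c(0.3, 0.1))

fixture_vivr <- function() petri_net(
  species = c("V", "Iv", "R"),
  transitions = c("infection_v", "recovery_v"),
  input_arcs = arcs(c(1, 2, 2), c(1, 1, 2)),
  output_arcs = arcs(c(2, 2, 3), c(1, 1, 2)),
  rates = c(0.05, 0.1))

fixture_cross_exposure <- function() petri_net(
  species = c("S", "I", "V", "Iv"),
  transitions = c("vaccination", "exposure_u", "exposure_v"),
  input_arcs = arcs(c(1, 1, 4, 3, 2), c(1, 2, 2, 3, 3)),
  output_arcs = arcs(c(3, 2, 4, 4, 2), c(1, 2, 2, 3, 3)),
  rates = c(0.05, 0.1, 0.02))

fixture_uwd_sviivr <- function() uwd(
  boxes = c("sir", "vivr", "cross_exposure"),
  junctions = c("S", "I", "R", "V", "Iv"),
  ports = data.frame(box = c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3),
                     junction = c(1, 2, 3, 4, 5, 3, 1, 2, 4, 5)))

fixture_sviivr_components <- function() list(
  uwd = fixture_uwd_sviivr(),
  components = list(
    make_open(fixture_sir(), list(1L, 2L, 3L)),
    make_open(fixture_vivr(), list(1L, 2L, 3L)),
    make_open(fixture_cross_exposure(), list(1L, 2L, 3L, 4L))))

fixture_uwd_host_vector <- function() uwd(
  boxes = c("host", "vector", "bloodmeal"),
  junctions = c("IH", "IV"),
  ports = data.frame(box = c(1, 2, 3, 3), junction = c(1, 2, 1, 2)))

fixture_uwd_host_vector_hier <- function() {
  outer <- uwd(
    boxes = c("host", "vector", "bloodmeal"),
    junctions = c("SH", "SV", "EV", "IH", "IV"),
    ports = data.frame(box = c(1, 1, 2, 2, 2, 3, 3, 3, 3, 3),
                       junction = c(1, 4, 2, 3, 5, 1, 2, 3, 4, 5)))
  inner <- uwd(
    boxes = c("aquatic", "adult"),
    junctions = c("SV", "EV", "IV"),
    ports = data.frame(box = c(1, 2, 2, 2), junction = c(1, 1, 2, 3)),
    outer_ports = data.frame(junction = c(1, 2, 3)))
  flat <- uwd(
    boxes = c("host", "bloodmeal", "aquatic", "adult"),
    junctions = c("SH", "SV", "EV", "IH", "IV"),
    ports = data.frame(box = c(1, 1, 2, 2, 2, 2, 2, 3, 4, 4, 4),
                       junction = c(1, 4, 1, 2, 3, 4, 5, 2, 2, 3, 5)))
  list(outer = outer, inner = inner, box = 2L, flat = flat)
}

fixture_p_infectious <- function() petri_net(
  species = "pop",
  transitions = c("disease", "strata", "interact"),
  input_arcs = arcs(c(1, 1, 1, 1), c(1, 2, 3, 3)),
  output_arcs = arcs(c(1, 1, 1, 1), c(1, 2, 3, 3)))

fixture_p_vector_borne <- function() petri_net(
  species = c("host", "vector"),
  transitions = c("host_disease", "vector_disease", "interact"),
  input_arcs = arcs(c(1, 2, 1, 2), c(1, 2, 3, 3)),
  output_arcs = arcs(c(1, 2, 1, 2), c(1, 2, 3, 3)))

fixture_sir_typed <- function() {
  net <- petri_net(
    species = c("S", "I", "R"),
    transitions = c("infection", "recovery", "strata_S", "strata_I", "strata_R"),
    input_arcs = arcs(c(1, 2, 2, 1, 2, 3), c(1, 1, 2, 3, 4, 5)),
    output_arcs = arcs(c(2, 2, 3, 1, 2, 3), c(1, 1, 2, 3, 4, 5)),
    rates = c(0.3, 0.1, 0, 0, 0))
  derive_typing(net, fixture_p_infectious(),
                species_types = rep("pop", 3),
                transition_types = c("interact", "disease", "strata",
                                     "strata", "strata"))
}

fixture_sis_typed <- function() {
  net <- petri_net(
    species = c("S", "I"),
    transitions = c("infection", "recovery", "strata_S", "strata_I"),
    input_arcs = arcs(c(1, 2, 2, 1, 2), c(1, 1, 2, 3, 4)),
    output_arcs = arcs(c(2, 2, 1, 1, 2), c(1, 1, 2, 3, 4)),
    rates = c(0.3, 0.1, 0, 0))
  derive_typing(net, fixture_p_infectious(),
                species_types = rep("pop", 2),
                transition_types = c("interact", "disease", "strata", "strata"))
}

fixture_host_vector_sis <- function() {
  net <- petri_net(
    species = c("SH", "IH", "SV", "IV"),
    transitions = c("host_infection", "host_recovery", "vector_infection"),
    input_arcs = arcs(c(1, 4, 2, 3, 2), c(1, 1, 2, 3, 3)),
    output_arcs = arcs(c(2, 4, 1, 4, 2), c(1, 1, 2, 3, 3)))
  derive_typing(net, fixture_p_vector_borne(),
                species_types = c("host", "host", "vector", "vector"),
                transition_types = c("interact", "host_disease", "interact"))
}

fixture_host_vector_sis_forbidden <- function() {
  net <- petri_net(
    species = c("SH", "IH", "SV", "IV"),
    transitions = c("host_infection", "host_recovery", "vector_infection",
                    "species_change", "vector_vector_infection"),
    input_arcs = arcs(c(1, 4, 2, 3, 2, 1, 4, 3), c(1, 1, 2, 3, 3, 4, 5, 5)),
    output_arcs = arcs(c(2, 4, 1, 4, 2, 3, 4, 4), c(1, 1, 2, 3, 3, 4, 5, 5)))
  attr(net, "intended_species_types") <- c(SH = "host", IH = "host",
                                           SV = "vector", IV = "vector")
  net
}

fixture_quarantine <- function() {
  net <- petri_net(
    species = c("Q", "nQ"),
    transitions = c("enter_quarantine", "leave_quarantine", "contact_nQ",
                    "disease_Q", "disease_nQ"),
    input_arcs = arcs(c(2, 1, 2, 2, 1, 2), c(1, 2, 3, 3, 4, 5)),
    output_arcs = arcs(c(1, 2, 2, 2, 1, 2), c(1, 2, 3, 3, 4, 5)))
  derive_typing(net, fixture_p_infectious(),
                species_types = c("pop", "pop"),
                transition_types = c("strata", "strata", "interact",
                                     "disease", "disease"))
}

fixture_age <- function(directions = c("child_child", "adult_adult",
                                       "child_adult", "adult_child")) {
  ends <- list(child_child = c(1, 1), adult_adult = c(2, 2),
               child_adult = c(1, 2), adult_child = c(2, 1))
  directions <- match.arg(directions, names(ends), several.ok = TRUE)
  sp <- integer(); tr <- integer(); labels <- character()
  k <- 0L
  in_s <- integer(); in_t <- integer(); out_s <- integer(); out_t <- integer()
  for (d in directions) {
    k <- k + 1L
    labels <- c(labels, paste0("contact_", d))
    e <- ends[[d]]  # (infector, infectee); arc order puts the infector first
    in_s <- c(in_s, e); in_t <- c(in_t, k, k)
    out_s <- c(out_s, e); out_t <- c(out_t, k, k)
  }
  labels <- c(labels, "disease_child", "disease_adult")
  in_s <- c(in_s, 1, 2); in_t <- c(in_t, k + 1L, k + 2L)
  out_s <- c(out_s, 1, 2); out_t <- c(out_t, k + 1L, k + 2L)
  net <- petri_net(species = c("child", "adult"), transitions = labels,
                   input_arcs = arcs(in_s, in_t),
                   output_arcs = arcs(out_s, out_t))
  derive_typing(net, fixture_p_infectious(),
                species_types = c("pop", "pop"),
                transition_types = c(rep("interact", length(directions)),
                                     "disease", "disease"))
}

fixture_flux <- function(n = 2L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  patches <- paste0("patch", seq_len(n))
  labels <- character(); types <- character()
  in_s <- integer(); in_t <- integer(); out_s <- integer(); out_t <- integer()
  k <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    k <- k + 1L
    labels <- c(labels, sprintf("move_%d_%d", i, j)); types <- c(types, "strata")
    in_s <- c(in_s, i); in_t <- c(in_t, k)
    out_s <- c(out_s, j); out_t <- c(out_t, k)
  }
  for (i in seq_len(n)) {
    k <- k + 1L
    labels <- c(labels, sprintf("contact_%d", i)); types <- c(types, "interact")
    in_s <- c(in_s, i, i); in_t <- c(in_t, k, k)
    out_s <- c(out_s, i, i); out_t <- c(out_t, k, k)
  }
  for (i in seq_len(n)) {
    k <- k + 1L
    labels <- c(labels, sprintf("disease_%d", i)); types <- c(types, "disease")
    in_s <- c(in_s, i); in_t <- c(in_t, k)
    out_s <- c(out_s, i); out_t <- c(out_t, k)
  }
  net <- petri_net(species = patches, transitions = labels,
                   input_arcs = arcs(in_s, in_t),
                   output_arcs = arcs(out_s, out_t))
  derive_typing(net, fixture_p_infectious(), rep("pop", n), types)
}

fixture_simple_trip <- function(n = 2L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  # place (i, j): currently in patch i, residence patch j
  place <- function(i, j) (i - 1L) * n + j
  places <- sprintf("P%d%d", rep(seq_len(n), each = n), rep(seq_len(n), n))
  labels <- character(); types <- character()
  in_s <- integer(); in_t <- integer(); out_s <- integer(); out_t <- integer()
  k <- 0L
  for (j in seq_len(n)) for (i in seq_len(n)) for (m in seq_len(n)) if (i != m) {
    k <- k + 1L
    labels <- c(labels, sprintf("travel_%d%d_%d%d", i, j, m, j))
    types <- c(types, "strata")
    in_s <- c(in_s, place(i, j)); in_t <- c(in_t, k)
    out_s <- c(out_s, place(m, j)); out_t <- c(out_t, k)
  }
  for (i in seq_len(n)) for (j1 in seq_len(n)) for (j2 in seq_len(n)) {
    k <- k + 1L
    labels <- c(labels, sprintf("contact_%d%d_%d%d", i, j1, i, j2))
    types <- c(types, "interact")
    in_s <- c(in_s, place(i, j1), place(i, j2)); in_t <- c(in_t, k, k)
    out_s <- c(out_s, place(i, j1), place(i, j2)); out_t <- c(out_t, k, k)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k <- k + 1L
    labels <- c(labels, sprintf("disease_%d%d", i, j)); types <- c(types, "disease")
    in_s <- c(in_s, place(i, j)); in_t <- c(in_t, k)
    out_s <- c(out_s, place(i, j)); out_t <- c(out_t, k)
  }
  net <- petri_net(species = places, transitions = labels,
                   input_arcs = arcs(in_s, in_t),
                   output_arcs = arcs(out_s, out_t))
  derive_typing(net, fixture_p_infectious(), rep("pop", n * n), types)
}

# Default Ross-Macdonald parameters: biting rate a (bites per vector per
# day), infection efficacies b (vector to host) and c (host to vector),
# host recovery rate r, vector mortality g (per day), populations H, V.
ross_default_params <- c(a = 0.3, b = 0.5, c = 0.5, g = 0.1, r = 0.05,
                         H = 1000, V = 10000)

sharer_ross_host <- function(params = ross_default_params["r"]) {
  resource_sharer("IH", ports = 1L,
                  field = function(t, u, p) -p[["r"]] * u[1],
                  params = params)
}

sharer_ross_vector <- function(params = ross_default_params["g"]) {
  resource_sharer("IV", ports = 1L,
                  field = function(t, u, p) -p[["g"]] * u[1],
                  params = params)
}

sharer_ross_bloodmeal <- function(params = ross_default_params[c("a", "b", "c", "H", "V")]) {
  resource_sharer(c("IH", "IV"), ports = c(1L, 2L),
                  field = function(t, u, p) {
                    c(p[["a"]] * p[["b"]] * u[2] / p[["H"]] * (p[["H"]] - u[1]),
                      p[["a"]] * p[["c"]] * u[1] / p[["H"]] * (p[["V"]] - u[2]))
                  },
                  params = params)
}

# Delayed bloodmeal: new vector infections reflect the host prevalence
# one incubation period tau ago, discounted by vector survival exp(-g tau).
sharer_ross_bloodmeal_delay <- function(tau,
    params = ross_default_params[c("a", "b", "c", "g", "H", "V")]) {
  delay_sharer(c("IH", "IV"), ports = c(1L, 2L),
               field = function(t, u, p, hist) {
                 c(p[["a"]] * p[["b"]] * u[2] / p[["H"]] * (p[["H"]] - u[1]),
                   p[["a"]] * p[["c"]] * hist[1, 1] / p[["H"]] *
                     (p[["V"]] - hist[2, 1]) * exp(-p[["g"]] * tau))
               },
               params = params, delays = tau)
}

fixture_ross_macdonald_ode <- function() list(
  uwd = fixture_uwd_host_vector(),
  components = list(sharer_ross_host(), sharer_ross_vector(),
                    sharer_ross_bloodmeal()))

fixture_ross_macdonald_dde <- function(tau = 10) list(
  uwd = fixture_uwd_host_vector(),
  components = list(sharer_ross_host(), sharer_ross_vector(),
                    sharer_ross_bloodmeal_delay(tau)))

fixture_ross_macdonald_petri <- function() {
  host <- petri_net(species = "IH", transitions = "host_recovery",
                    input_arcs = arcs(1, 1), output_arcs = NULL,
                    rates = 0.05)
  vector <- petri_net(species = "IV", transitions = "vector_death",
                      input_arcs = arcs(1, 1), output_arcs = NULL,
                      rates = 0.1)
  bloodmeal <- petri_net(
    species = c("SH", "IH", "SV", "IV"),
    transitions = c("host_infection", "vector_infection"),
    input_arcs = arcs(c(1, 4, 3, 2), c(1, 1, 2, 2)),
    output_arcs = arcs(c(2, 4, 4, 2), c(1, 1, 2, 2)),
    rates = c(1e-4, 1e-4))
  list(uwd = fixture_uwd_host_vector(),
       components = list(make_open(host, list(1L)),
                         make_open(vector, list(1L)),
                         make_open(bloodmeal, list(2L, 4L))))
}

#' Build a model from the fixture catalog
#'
#' @param name catalog name; see [fixture_names()] for the listing.
#' @param n patch count for `flux` and `simple_trip` (default 2).
#' @param tau incubation delay for `ross_macdonald_dde` (default 10).
#' @param directions interaction directions for `age`.
#' @return a freshly built, validated model object; its class depends on
#'   the fixture (Petri net, typed net, UWD, or a list of wiring diagram
#'   plus components).
#' @export
fixture <- function(name, n = NULL, tau = NULL, directions = NULL) {
  builders <- list(
    sir = fixture_sir, sis = fixture_sis, vivr = fixture_vivr,
    cross_exposure = fixture_cross_exposure,
    sviivr_components = fixture_sviivr_components,
    uwd_sviivr = fixture_uwd_sviivr,
    uwd_host_vector = fixture_uwd_host_vector,
    uwd_host_vector_hier = fixture_uwd_host_vector_hier,
    p_infectious = fixture_p_infectious,
    p_vector_borne = fixture_p_vector_borne,
    sir_typed = fixture_sir_typed, sis_typed = fixture_sis_typed,
    host_vector_sis = fixture_host_vector_sis,
    host_vector_sis_forbidden = fixture_host_vector_sis_forbidden,
    quarantine = fixture_quarantine, age = fixture_age,
    flux = fixture_flux, simple_trip = fixture_simple_trip,
    ross_macdonald_petri = fixture_ross_macdonald_petri,
    ross_macdonald_ode = fixture_ross_macdonald_ode,
    ross_macdonald_dde = fixture_ross_macdonald_dde)
  if (!name %in% names(builders))
    stop_opetri("unknown fixture '", name, "'; available: ",
                paste(names(builders), collapse = ", "))
  opts <- list()
  if (name %in% c("flux", "simple_trip") && !is.null(n)) opts$n <- n
  if (name == "ross_macdonald_dde" && !is.null(tau)) opts$tau <- tau
  if (name == "age" && !is.null(directions)) opts$directions <- directions
  do.call(builders[[name]], opts)
}
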