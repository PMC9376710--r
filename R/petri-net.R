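#' Whole-grain Petri nets
#'
#' A whole-grain Petri net is given by four finite linked tables: species
#' (places), transitions, input arcs and output arcs. Each arc records the
#' species and transition it connects; arc multiplicity encodes
#' stoichiometry, so an infection transition that consumes one susceptible
#' and one infected individual and produces two infected individuals has
#' two input arcs and two output arcs.
#'
#' @param species character vector of species labels (pairwise distinct).
#' @param transitions character vector of transition labels (pairwise
#'   distinct), or a data frame with columns `label` and optionally `rate`.
#' @param input_arcs,output_arcs two-column data frames (or matrices) with
#'   columns `species` and `transition`, each row one arc, 1-based indices
#'   into the species and transition tables.
#' @param rates optional numeric vector of nonnegative rate constants, one
#'   per transition (recycled NA allowed). Rates are carried along by
#'   composition but ignored by morphisms and isomorphism.
#'
#' @return An object of class `petri_net`: a list with data-frame fields
#'   `species`, `transitions`, `input_arcs`, `output_arcs`.
#' @examples
#' sir <- petri_net(
#'   species = c("S", "I", "R"),
#'   transitions = c("infection", "recovery"),
#'   input_arcs = data.frame(species = c(1, 2, 2), transition = c(1, 1, 2)),
#'   output_arcs = data.frame(species = c(2, 2, 3), transition = c(1, 1, 2)),
#'   rates = c(0.3, 0.1)
#' )
#' validate_petri(sir)
#' @export
petri_net <- function(species = character(), transitions = character(),
                      input_arcs = NULL, output_arcs = NULL, rates = NULL) {
  sp <- data.frame(label = as.character(species), stringsAsFactors = FALSE)
  if (is.data.frame(transitions)) {
    tr <- data.frame(label = as.character(transitions$label),
                     rate = if ("rate" %in% names(transitions))
                       as.numeric(transitions$rate)
                     else rep(NA_real_, nrow(transitions)),
                     stringsAsFactors = FALSE)
  } else {
    tr <- data.frame(label = as.character(transitions),
                     rate = rep(NA_real_, length(transitions)),
                     stringsAsFactors = FALSE)
  }
  if (!is.null(rates)) tr$rate <- as.numeric(rates)
  as_arcs <- function(a) {
    if (is.null(a)) return(data.frame(species = integer(), transition = integer()))
    a <- as.data.frame(a)
    data.frame(species = as.integer(a$species), transition = as.integer(a$transition))
  }
  net <- structure(list(species = sp, transitions = tr,
                        input_arcs = as_arcs(input_arcs),
                        output_arcs = as_arcs(output_arcs)),
                   class = "petri_net")
  viol <- validate_petri(net)
  if (length(viol) > 0L)
    stop_opetri("invalid petri_net: ", paste(viol, collapse = "; "))
  net
}

#' Validate a Petri net
#'
#' Checks the structural invariants: arc indices in range, labels pairwise
#' distinct per table, rates nonnegative where present. Violations are
#' returned as human-readable strings, never raised.
#'
#' @param net a `petri_net` (or a bare list with the same fields).
#' @return character vector of violations; empty when the net is valid.
#' @export
validate_petri <- function(net) {
  viol <- character()
  ns <- nrow(net$species)
  nt <- nrow(net$transitions)
  check_arcs <- function(arcs, tabname) {
    v <- character()
    for (i in seq_len(nrow(arcs))) {
      s <- arcs$species[i]; t <- arcs$transition[i]
      if (is.na(s) || s < 1L || s > ns)
        v <- c(v, sprintf("%s row %d: species index %s out of range [1, %d]",
                          tabname, i, s, ns))
      if (is.na(t) || t < 1L || t > nt)
        v <- c(v, sprintf("%s row %d: transition index %s out of range [1, %d]",
                          tabname, i, t, nt))
    }
    v
  }
  viol <- c(viol, check_arcs(net$input_arcs, "input_arcs"),
            check_arcs(net$output_arcs, "output_arcs"))
  if (anyDuplicated(net$species$label))
    viol <- c(viol, sprintf("species: duplicate label(s) %s",
                            paste(unique(net$species$label[duplicated(net$species$label)]),
                                  collapse = ", ")))
  if (anyDuplicated(net$transitions$label))
    viol <- c(viol, sprintf("transitions: duplicate label(s) %s",
                            paste(unique(net$transitions$label[duplicated(net$transitions$label)]),
                                  collapse = ", ")))
  bad_rate <- which(!is.na(net$transitions$rate) & net$transitions$rate < 0)
  for (i in bad_rate)
    viol <- c(viol, sprintf("transitions row %d: negative rate %g", i,
                            net$transitions$rate[i]))
  viol
}

#' Stoichiometry of one transition
#'
#' Returns the input and output multisets of a transition: the multiplicity
#' of species s among the inputs is the number of input arcs joining s to
#' the transition (the stoichiometric coefficient), and likewise for
#' outputs.
#'
#' @param net a `petri_net`.
#' @param t transition index (1-based).
#' @return list with named integer vectors `inputs` and `outputs`
#'   (species-label names, zero entries dropped).
#' @export
transition_stoichiometry <- function(net, t) {
  nt <- nrow(net$transitions)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 1L || t > nt)
    stop_opetri("transition index out of range [1, ", nt, "]: ", t)
  t <- as.integer(t)
  labels <- net$species$label
  list(
    inputs  = count_multiset(net$input_arcs$species[net$input_arcs$transition == t], labels),
    outputs = count_multiset(net$output_arcs$species[net$output_arcs$transition == t], labels)
  )
}

# Species x transition multiplicity matrices (inputs and outputs); the
# backbone of mass-action semantics and conservation checks.
stoichiometry_matrices <- function(net) {
  ns <- nrow(net$species); nt <- nrow(net$transitions)
  m_in <- matrix(0L, ns, nt, dimnames = list(net$species$label, net$transitions$label))
  m_out <- m_in
  for (i in seq_len(nrow(net$input_arcs)))
    m_in[net$input_arcs$species[i], net$input_arcs$transition[i]] <-
      m_in[net$input_arcs$species[i], net$input_arcs$transition[i]] + 1L
  for (i in seq_len(nrow(net$output_arcs)))
    m_out[net$output_arcs$species[i], net$output_arcs$transition[i]] <-
      m_out[net$output_arcs$species[i], net$output_arcs$transition[i]] + 1L
  list(inputs = m_in, outputs = m_out)
}

#' @export
print.petri_net <- function(x, ...) {
  cat(sprintf("petri_net: %d species, %d transitions, %d input arcs, %d output arcs\n",
              nrow(x$species), nrow(x$transitions),
              nrow(x$input_arcs), nrow(x$output_arcs)))
  if (nrow(x$species) > 0)
    cat("  species:", paste(x$species$label, collapse = ", "), "\n")
  for (t in seq_len(nrow(x$transitions))) {
    st <- transition_stoichiometry(x, t)
    fmt <- function(m) if (length(m) == 0) "0" else
      paste(ifelse(m > 1, paste0(m, " "), ""), names(m), sep = "", collapse = " + ")
    rate <- x$transitions$rate[t]
    cat(sprintf("  %s: %s -> %s%s\n", x$transitions$label[t],
                fmt(st$inputs), fmt(st$outputs),
                if (is.na(rate)) "" else sprintf("  (rate %g)", rate)))
  }
  invisible(x)
}
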