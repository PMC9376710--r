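#' Morphisms between Petri nets
#'
#' A morphism maps species, transitions, input arcs and output arcs of a
#' domain net to a codomain net so that arcs respect sources and targets
#' (commuting squares) and arities are preserved: over each domain
#' transition the arc maps restrict to bijections onto the arcs of the
#' image transition. Arity preservation is what stops, say, a two-in
#' two-out infection transition from being typed as a unary transition.
#' Morphisms are purely combinatorial: labels and rates are ignored.
#'
#' @param species_map,transition_map,input_arc_map,output_arc_map integer
#'   vectors (1-based) mapping rows of the domain tables to rows of the
#'   codomain tables.
#' @return An object of class `petri_morphism`.
#' @export
petri_morphism <- function(species_map = integer(), transition_map = integer(),
                           input_arc_map = integer(), output_arc_map = integer()) {
  structure(list(species_map = as.integer(species_map),
                 transition_map = as.integer(transition_map),
                 input_arc_map = as.integer(input_arc_map),
                 output_arc_map = as.integer(output_arc_map)),
            class = "petri_morphism")
}

#' Identity morphism on a Petri net
#' @param net a `petri_net`.
#' @return the identity `petri_morphism` on `net`.
#' @export
identity_morphism <- function(net) {
  petri_morphism(seq_len(nrow(net$species)), seq_len(nrow(net$transitions)),
                 seq_len(nrow(net$input_arcs)), seq_len(nrow(net$output_arcs)))
}

#' Compose two Petri-net morphisms
#' @param g,f morphisms; the composite applies `f` first, then `g`.
#' @return the composite `petri_morphism` g o f.
#' @export
compose_morphism <- function(g, f) {
  petri_morphism(g$species_map[f$species_map],
                 g$transition_map[f$transition_map],
                 g$input_arc_map[f$input_arc_map],
                 g$output_arc_map[f$output_arc_map])
}

# Arc indices incident to each transition, in arc-table order.
arcs_by_transition <- function(arcs, nt) {
  out <- vector("list", nt)
  for (t in seq_len(nt)) out[[t]] <- which(arcs$transition == t)
  out
}

#' Check a morphism between two Petri nets
#'
#' Verifies index ranges, the commuting squares for input and output arcs,
#' and arity preservation (fibrewise bijectivity of the arc maps over each
#' transition).
#'
#' @param f a `petri_morphism`.
#' @param dom,cod valid `petri_net` objects.
#' @return list with `ok` (logical) and `violations` (character vector).
#'   Mismatched map lengths are a structural error and are raised.
#' @export
check_morphism <- function(f, dom, cod) {
  if (length(f$species_map) != nrow(dom$species) ||
      length(f$transition_map) != nrow(dom$transitions) ||
      length(f$input_arc_map) != nrow(dom$input_arcs) ||
      length(f$output_arc_map) != nrow(dom$output_arcs))
    stop_opetri("morphism map lengths do not match the domain table sizes")

  viol <- character()
  rng <- function(map, n, what) {
    bad <- which(is.na(map) | map < 1L | map > n)
    vapply(bad, function(i) sprintf("%s[%d] = %s out of codomain range [1, %d]",
                                    what, i, map[i], n), character(1))
  }
  viol <- c(viol,
            rng(f$species_map, nrow(cod$species), "species_map"),
            rng(f$transition_map, nrow(cod$transitions), "transition_map"),
            rng(f$input_arc_map, nrow(cod$input_arcs), "input_arc_map"),
            rng(f$output_arc_map, nrow(cod$output_arcs), "output_arc_map"))
  if (length(viol) > 0L) return(list(ok = FALSE, violations = viol))

  sq <- function(darcs, carcs, amap, what) {
    v <- character()
    for (i in seq_len(nrow(darcs))) {
      j <- amap[i]
      if (carcs$species[j] != f$species_map[darcs$species[i]])
        v <- c(v, sprintf("%s row %d: species square does not commute", what, i))
      if (carcs$transition[j] != f$transition_map[darcs$transition[i]])
        v <- c(v, sprintf("%s row %d: transition square does not commute", what, i))
    }
    v
  }
  viol <- c(viol, sq(dom$input_arcs, cod$input_arcs, f$input_arc_map, "input_arcs"),
            sq(dom$output_arcs, cod$output_arcs, f$output_arc_map, "output_arcs"))

  dom_in <- arcs_by_transition(dom$input_arcs, nrow(dom$transitions))
  dom_out <- arcs_by_transition(dom$output_arcs, nrow(dom$transitions))
  cod_in <- arcs_by_transition(cod$input_arcs, nrow(cod$transitions))
  cod_out <- arcs_by_transition(cod$output_arcs, nrow(cod$transitions))
  for (t in seq_len(nrow(dom$transitions))) {
    t2 <- f$transition_map[t]
    img_in <- f$input_arc_map[dom_in[[t]]]
    if (length(img_in) != length(cod_in[[t2]]) ||
        !setequal(img_in, cod_in[[t2]]) || anyDuplicated(img_in))
      viol <- c(viol, sprintf(
        "transition %d: input arcs are not mapped bijectively onto input arcs of %d (arity violation)",
        t, t2))
    img_out <- f$output_arc_map[dom_out[[t]]]
    if (length(img_out) != length(cod_out[[t2]]) ||
        !setequal(img_out, cod_out[[t2]]) || anyDuplicated(img_out))
      viol <- c(viol, sprintf(
        "transition %d: output arcs are not mapped bijectively onto output arcs of %d (arity violation)",
        t, t2))
  }
  list(ok = length(viol) == 0L, violations = viol)
}

#' Enumerate all morphisms between two Petri nets
#'
#' Exhaustive, duplicate-free backtracking search over transitions in
#' decreasing-arity order, pruning on species-map consistency, with
#' results in lexicographic order of (species_map, transition_map,
#' input_arc_map, output_arc_map). Worst case is exponential; intended for
#' the small nets that arise as type systems and disease fixtures.
#'
#' @param dom,cod valid `petri_net` objects.
#' @param fix_species optional integer vector (length = domain species
#'   count, NA = free) pre-binding part of the species map; used to search
#'   for typings respecting intended species types.
#' @param injective require species and transition maps to be injective
#'   (used by the isomorphism check).
#' @param max_results stop after this many morphisms.
#' @return list of `petri_morphism` objects (possibly empty).
#' @export
find_morphisms <- function(dom, cod, fix_species = NULL, injective = FALSE,
                           max_results = Inf) {
  ns <- nrow(dom$species); nt <- nrow(dom$transitions)
  cns <- nrow(cod$species); cnt <- nrow(cod$transitions)
  dom_in <- arcs_by_transition(dom$input_arcs, nt)
  dom_out <- arcs_by_transition(dom$output_arcs, nt)
  cod_in <- arcs_by_transition(cod$input_arcs, cnt)
  cod_out <- arcs_by_transition(cod$output_arcs, cnt)

  smap <- rep(NA_integer_, ns)
  if (!is.null(fix_species)) {
    stopifnot(length(fix_species) == ns)
    smap <- as.integer(fix_species)
  }
  tmap <- rep(NA_integer_, nt)
  imap <- rep(NA_integer_, nrow(dom$input_arcs))
  omap <- rep(NA_integer_, nrow(dom$output_arcs))
  s_used <- rep(FALSE, cns)  # only consulted when injective
  if (injective) for (s2 in smap[!is.na(smap)]) s_used[s2] <- TRUE

  arity <- vapply(seq_len(nt), function(t)
    length(dom_in[[t]]) + length(dom_out[[t]]), integer(1))
  t_order <- order(-arity, seq_len(nt))
  results <- list()

  env <- environment()

  # Try to bind domain species s -> codomain species s2; returns TRUE and
  # records an undo flag when a fresh binding was made, FALSE on conflict.
  bind_species <- function(s, s2) {
    cur <- env$smap[s]
    if (!is.na(cur)) return(if (cur == s2) 0L else -1L)  # 0: no new binding
    if (injective && env$s_used[s2]) return(-1L)
    env$smap[s] <- s2
    if (injective) env$s_used[s2] <- TRUE
    1L
  }
  unbind_species <- function(s) {
    if (injective) env$s_used[env$smap[s]] <- FALSE
    env$smap[s] <- NA_integer_
  }

  # Assign the arcs of dom transition t to arcs of cod transition t2 by
  # trying every bijection, first inputs then outputs, then continue().
  try_arcs <- function(darcs, carcs, amap_name, arcs_dom, arcs_cod, continue) {
    n <- length(arcs_dom)
    for (p in permutations(n)) {
      bound <- integer(0)
      ok <- TRUE
      for (j in seq_len(n)) {
        a <- arcs_dom[j]; a2 <- arcs_cod[p[j]]
        res <- bind_species(darcs$species[a], carcs$species[a2])
        if (res < 0L) { ok <- FALSE; break }
        if (res > 0L) bound <- c(bound, darcs$species[a])
        env[[amap_name]][arcs_dom[j]] <- a2
      }
      if (ok) continue()
      for (s in bound) unbind_species(s)
    }
  }

  recurse_t <- function(k) {
    if (length(results) >= max_results) return()
    if (k > nt) { assign_free_species(which(is.na(env$smap)), 1L); return() }
    t <- t_order[k]
    for (t2 in seq_len(cnt)) {
      if (length(results) >= max_results) return()
      if (injective && t2 %in% env$tmap) next
      if (length(cod_in[[t2]]) != length(dom_in[[t]])) next
      if (length(cod_out[[t2]]) != length(dom_out[[t]])) next
      env$tmap[t] <- t2
      try_arcs(dom$input_arcs, cod$input_arcs, "imap", dom_in[[t]], cod_in[[t2]],
               function() {
                 try_arcs(dom$output_arcs, cod$output_arcs, "omap",
                          dom_out[[t]], cod_out[[t2]],
                          function() recurse_t(k + 1L))
               })
      env$tmap[t] <- NA_integer_
    }
  }

  # Species not touched by any arc can map anywhere; enumerate.
  assign_free_species <- function(free, j) {
    if (length(results) >= max_results) return()
    if (j > length(free)) {
      results[[length(results) + 1L]] <<-
        petri_morphism(env$smap, env$tmap, env$imap, env$omap)
      return()
    }
    s <- free[j]
    for (s2 in seq_len(cns)) {
      if (bind_species(s, s2) == 1L) {
        assign_free_species(free, j + 1L)
        unbind_species(s)
      }
    }
  }

  recurse_t(1L)

  if (length(results) > 1L) {
    key <- vapply(results, function(m)
      paste(sprintf("%05d", c(m$species_map, m$transition_map,
                              m$input_arc_map, m$output_arc_map)),
            collapse = ""), character(1))
    results <- results[order(key)]
    results <- results[!duplicated(key[order(key)])]
  }
  results
}

#' Are two Petri nets isomorphic?
#'
#' True when an invertible morphism exists; labels and rates are ignored.
#' An injective morphism between nets with equal table sizes is
#' automatically invertible, which is what the search exploits.
#'
#' @param a,b valid `petri_net` objects.
#' @return logical scalar.
#' @export
petri_isomorphic <- function(a, b) {
  if (nrow(a$species) != nrow(b$species) ||
      nrow(a$transitions) != nrow(b$transitions) ||
      nrow(a$input_arcs) != nrow(b$input_arcs) ||
      nrow(a$output_arcs) != nrow(b$output_arcs)) return(FALSE)
  length(find_morphisms(a, b, injective = TRUE, max_results = 1)) > 0L
}
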