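#' Open Petri nets (structured multicospans)
#'
#' An open Petri net is a Petri net together with a list of feet (finite
#' interface sets) and legs (maps from each foot into the species table)
#' exposing places for gluing. Composition along a wiring diagram
#' identifies exposed places wired to a common junction.
#'
#' @param net a valid `petri_net`.
#' @param exposed list of integer vectors of species indices, one per
#'   foot; each entry becomes a foot of that cardinality with the given
#'   leg. An empty list gives a closed system.
#' @return object of class `open_petri_net` with fields `net`, `feet`
#'   (integer cardinalities) and `legs` (list of integer vectors).
#' @examples
#' sir <- fixture("sir")
#' open_sir <- make_open(sir, list(1L, 2L, 3L))
#' @export
make_open <- function(net, exposed = list()) {
  ns <- nrow(net$species)
  legs <- lapply(exposed, function(e) {
    e <- as.integer(e)
    if (any(is.na(e) | e < 1L | e > ns))
      stop_opetri("exposed species index out of range [1, ", ns, "]")
    e
  })
  structure(list(net = net,
                 feet = vapply(legs, length, integer(1)),
                 legs = legs),
            class = "open_petri_net")
}

#' @export
print.open_petri_net <- function(x, ...) {
  cat(sprintf("open_petri_net with %d feet over:\n", length(x$feet)))
  for (i in seq_along(x$legs))
    cat(sprintf("  foot %d -> {%s}\n", i,
                paste(x$net$species$label[x$legs[[i]]], collapse = ", ")))
  print(x$net)
  invisible(x)
}

# Shared gluing engine for oapply (Petri) and sharer_oapply (dynamics).
# Takes the UWD, per-component counts of "states" (species), and the list
# of per-component exposed indices (one singleton per port, in port
# order). Returns the quotient bookkeeping:
#   n_total      composite state count
#   state_of     list per component: local index -> composite index
#   labels       composite labels (junction label if merged, else original)
#   outer_states composite index per outer port
glue_states <- function(d, n_states, exposed, local_labels) {
  nb <- nrow(d$boxes)
  if (length(n_states) != nb)
    stop_opetri("expected one component per box: got ", length(n_states),
                " components for ", nb, " boxes")
  offs <- cumsum(c(0L, n_states))
  total <- offs[nb + 1L]
  nj <- nrow(d$junctions)

  # union-find over junction slots (1..nj) then all component states.
  parent <- uf_new(nj + total)
  for (b in seq_len(nb)) {
    pb <- ports_of_box(d, b)
    if (length(exposed[[b]]) != length(pb))
      stop_opetri("component ", b, " exposes ", length(exposed[[b]]),
                  " feet but box ", b, " has ", length(pb), " ports")
    for (q in seq_along(pb)) {
      j <- d$ports$junction[pb[q]]
      s <- exposed[[b]][q]
      parent <- uf_union(parent, j, nj + offs[b] + s)  # junction node is root
    }
  }
  roots <- uf_roots(parent)

  used_j <- unique(d$ports$junction)
  outer_j <- unique(d$outer_ports$junction)
  # Junction classes appear first in junction order; a portless junction
  # survives (as an isolated place) only when it is an outer junction.
  lead_j <- Filter(function(j) {
    r <- roots[j]
    min(which(roots == r)) == j && (j %in% used_j || j %in% outer_j)
  }, seq_len(nj))
  # States not glued to any junction keep (component, local) order.
  free_states <- Filter(function(k) !(roots[nj + k] %in% roots[seq_len(nj)]),
                        seq_len(total))

  class_index <- integer(nj + total)
  labels <- character(length(lead_j) + length(free_states))
  nxt <- 0L
  for (j in lead_j) {
    nxt <- nxt + 1L
    class_index[roots == roots[j]] <- nxt
    labels[nxt] <- d$junctions$label[j]
  }
  for (k in free_states) {
    nxt <- nxt + 1L
    class_index[nj + k] <- nxt
    labels[nxt] <- local_labels[k]
  }

  state_of <- lapply(seq_len(nb), function(b)
    class_index[nj + offs[b] + seq_len(n_states[b])])
  list(n_total = nxt,
       state_of = state_of,
       labels = labels,
       outer_states = class_index[d$outer_ports$junction])
}

#' Compose open Petri nets along a UWD
#'
#' The operad-algebra action: given a wiring diagram and one open Petri
#' net per box (with one singleton foot per port, in port order), glues
#' the disjoint union of the component nets by identifying places exposed
#' at ports wired to the same junction. Transitions and arcs are never
#' merged; transition counts add. Merged places take the junction's label
#' (the UWD is the shared vocabulary); unmerged places keep their own.
#' The composite exposes one singleton foot per outer port of the diagram.
#'
#' @param d a valid `uwd`.
#' @param components list of `open_petri_net`, one per box.
#' @return the composite `open_petri_net`, with attributes
#'   `species_map` and `transition_map` (lists per component mapping local
#'   indices to composite indices) for downstream bookkeeping.
#' @export
oapply <- function(d, components) {
  nb <- nrow(d$boxes)
  if (length(components) != nb)
    stop_opetri("expected ", nb, " components (one per box), got ",
                length(components))
  for (b in seq_len(nb)) {
    if (any(components[[b]]$feet != 1L))
      stop_opetri("component ", b, " has a non-singleton foot; ",
                  "composition requires each port to expose exactly one place")
  }
  n_states <- vapply(components, function(o) nrow(o$net$species), integer(1))
  exposed <- lapply(components, function(o)
    vapply(o$legs, function(l) l[1L], integer(1)))
  local_labels <- unlist(lapply(components, function(o) o$net$species$label),
                         use.names = FALSE)
  glue <- glue_states(d, n_states, exposed, local_labels %||% character(0))
  # Unexposed places from different components may share a label; keep the
  # composite's species labels pairwise distinct deterministically.
  glue$labels <- make.unique(glue$labels, sep = "_")

  # Resolve label for a merged class: junction label wins, but if the class
  # got the junction label and a species label collides elsewhere the
  # tables stay distinct because classes are unique rows.
  t_off <- 0L
  trans <- data.frame(label = character(), rate = numeric())
  in_arcs <- data.frame(species = integer(), transition = integer())
  out_arcs <- in_arcs
  transition_map <- vector("list", nb)
  for (b in seq_len(nb)) {
    net <- components[[b]]$net
    ntb <- nrow(net$transitions)
    transition_map[[b]] <- t_off + seq_len(ntb)
    trans <- rbind(trans, net$transitions)
    smap <- glue$state_of[[b]]
    in_arcs <- rbind(in_arcs, data.frame(
      species = smap[net$input_arcs$species],
      transition = net$input_arcs$transition + t_off))
    out_arcs <- rbind(out_arcs, data.frame(
      species = smap[net$output_arcs$species],
      transition = net$output_arcs$transition + t_off))
    t_off <- t_off + ntb
  }
  # Composite transition labels must stay distinct; qualify duplicates
  # with the component box label.
  if (anyDuplicated(trans$label)) {
    dup <- trans$label %in% trans$label[duplicated(trans$label)]
    box_of <- rep(seq_len(nb), vapply(transition_map, length, integer(1)))
    trans$label[dup] <- paste(d$boxes$label[box_of[dup]], trans$label[dup],
                              sep = ".")
    if (anyDuplicated(trans$label))
      trans$label <- make.unique(trans$label, sep = "_")
  }

  net <- petri_net(species = glue$labels, transitions = trans,
                   input_arcs = in_arcs, output_arcs = out_arcs)
  out <- make_open(net, as.list(glue$outer_states))
  attr(out, "species_map") <- glue$state_of
  attr(out, "transition_map") <- transition_map
  out
}
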