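#' Typed Petri nets
#'
#' A typed Petri net is a Petri net together with a morphism into a
#' type-system net. The typing assigns every place, transition and arc a
#' type and preserves arities, which lets the type system act as a
#' guardrail: e.g. with an infectious-disease type system (one place
#' type; unary infection-status and strata-change transition types; a
#' binary interaction type) an interaction transition is forced to have
#' two inputs and two outputs, and every typed net conserves total
#' population under mass action.
#'
#' @param net,type_net valid `petri_net` objects.
#' @param typing a `petri_morphism` from `net` to `type_net`.
#' @param check validate the typing on construction (default TRUE).
#' @return object of class `typed_petri_net`.
#' @export
typed_petri <- function(net, type_net, typing, check = TRUE) {
  tp <- structure(list(net = net, type_net = type_net, typing = typing),
                  class = "typed_petri_net")
  if (check) {
    res <- check_typing(tp)
    if (!res$ok)
      stop_opetri("invalid typing: ", paste(res$violations, collapse = "; "))
  }
  tp
}

#' Check the typing morphism of a typed Petri net
#'
#' @param tp a `typed_petri_net`.
#' @return list with `ok` and `violations`, as [check_morphism()].
#' @export
check_typing <- function(tp) {
  check_morphism(tp$typing, tp$net, tp$type_net)
}

#' @export
print.typed_petri_net <- function(x, ...) {
  cat("typed_petri_net over type system:\n")
  print(x$type_net)
  cat("underlying net (types in brackets):\n")
  cat(sprintf("  species: %s\n", paste(
    sprintf("%s[%s]", x$net$species$label,
            x$type_net$species$label[x$typing$species_map]), collapse = ", ")))
  cat(sprintf("  transitions: %s\n", paste(
    sprintf("%s[%s]", x$net$transitions$label,
            x$type_net$transitions$label[x$typing$transition_map]),
    collapse = ", ")))
  invisible(x)
}

#' Derive a typing morphism from species and transition type assignments
#'
#' Completes a typing from the two assignments that carry the modelling
#' intent: arc maps are filled in deterministically (first fit in table
#' order) so that each transition's arcs biject with the arcs of its type
#' transition and the species squares commute. An explicit arc map can be
#' supplied to select a specific direction, e.g. which interaction port
#' is the infector.
#'
#' @param net,type_net valid `petri_net` objects.
#' @param species_types integer vector or character vector of type-species
#'   (labels resolved against `type_net`), one per species of `net`.
#' @param transition_types integer or character vector, one per
#'   transition of `net`.
#' @param input_arc_map,output_arc_map optional explicit arc maps.
#' @return a `typed_petri_net`.
#' @export
derive_typing <- function(net, type_net, species_types, transition_types,
                          input_arc_map = NULL, output_arc_map = NULL) {
  resolve <- function(x, labels, n, what) {
    if (is.character(x)) x <- match(x, labels)
    x <- as.integer(x)
    if (length(x) != n || any(is.na(x)))
      stop_opetri("could not resolve ", what, " type assignment")
    x
  }
  smap <- resolve(species_types, type_net$species$label,
                  nrow(net$species), "species")
  tmap <- resolve(transition_types, type_net$transitions$label,
                  nrow(net$transitions), "transition")
  fill_arcs <- function(darcs, carcs, explicit, what) {
    if (!is.null(explicit)) return(as.integer(explicit))
    amap <- rep(NA_integer_, nrow(darcs))
    for (t in seq_len(nrow(net$transitions))) {
      mine <- which(darcs$transition == t)
      theirs <- which(carcs$transition == tmap[t])
      taken <- rep(FALSE, length(theirs))
      for (a in mine) {
        want <- smap[darcs$species[a]]
        hit <- which(!taken & carcs$species[theirs] == want)
        if (length(hit) == 0L)
          stop_opetri("no valid typing: ", what, " arc ", a, " of transition '",
                      net$transitions$label[t], "' has no free type arc of species type '",
                      type_net$species$label[want], "'")
        taken[hit[1L]] <- TRUE
        amap[a] <- theirs[hit[1L]]
      }
      if (length(mine) != length(theirs))
        stop_opetri("no valid typing: transition '", net$transitions$label[t],
                    "' has ", length(mine), " ", what, " arcs but its type has ",
                    length(theirs), " (arity violation)")
    }
    amap
  }
  typing <- petri_morphism(
    smap, tmap,
    fill_arcs(net$input_arcs, type_net$input_arcs, input_arc_map, "input"),
    fill_arcs(net$output_arcs, type_net$output_arcs, output_arc_map, "output"))
  typed_petri(net, type_net, typing)
}

#' Type-checked composition of typed open Petri nets
#'
#' Composes as [oapply()] but with the constraint that places identified
#' at a junction must share a species type; the composite then carries a
#' well-defined induced typing. A type clash raises an error naming the
#' junction and the offending species.
#'
#' @param d a valid `uwd`.
#' @param components list (one per box) of lists with fields `open` (an
#'   `open_petri_net`) and `typing` (a `petri_morphism` of its net into
#'   `type_net`).
#' @param type_net the shared type-system net.
#' @return a `typed_petri_net` for the composite; its underlying net
#'   equals the untyped [oapply()] composite.
#' @export
typed_oapply <- function(d, components, type_net) {
  for (b in seq_along(components)) {
    res <- check_morphism(components[[b]]$typing, components[[b]]$open$net,
                          type_net)
    if (!res$ok)
      stop_opetri("component ", b, " is not validly typed: ",
                  res$violations[1])
  }
  opens <- lapply(components, function(c) c$open)
  comp <- oapply(d, opens)
  smaps <- attr(comp, "species_map")

  # Induced species typing: all members of a class must share a type.
  ns <- nrow(comp$net$species)
  sp_type <- rep(NA_integer_, ns)
  owner <- rep(NA_character_, ns)
  for (b in seq_along(components)) {
    ty <- components[[b]]$typing$species_map
    for (s in seq_along(smaps[[b]])) {
      cls <- smaps[[b]][s]
      lab <- opens[[b]]$net$species$label[s]
      if (is.na(sp_type[cls])) {
        sp_type[cls] <- ty[s]; owner[cls] <- lab
      } else if (sp_type[cls] != ty[s]) {
        jlab <- comp$net$species$label[cls]
        stop_opetri("type clash at junction '", jlab, "': species '",
                    owner[cls], "' has type '",
                    type_net$species$label[sp_type[cls]],
                    "' but species '", lab, "' has type '",
                    type_net$species$label[ty[s]], "'")
      }
    }
  }
  typing <- petri_morphism(
    sp_type,
    unlist(lapply(components, function(c) c$typing$transition_map)),
    unlist(lapply(components, function(c) c$typing$input_arc_map)),
    unlist(lapply(components, function(c) c$typing$output_arc_map)))
  typed_petri(comp$net, type_net, typing)
}

#' Stratify one typed model by another (pullback)
#'
#' The stratified model of a disease model and a stratification scheme
#' typed by the same type system is their pullback: places are pairs of
#' places with the same type, transitions are pairs of same-typed
#' transitions, and arcs are pairs of arcs lying over the same type arc,
#' with sources and targets computed componentwise (well-defined because
#' both typings respect sources and targets). Labels are joined with
#' `"_"`; pairs are ordered lexicographically by (disease index, strata
#' index). The result is typed by the composite of the first projection
#' with the disease typing, and both projections are returned as
#' attributes `proj_disease` and `proj_strata`.
#'
#' Stratification is associative and commutative up to isomorphism, so
#' the order in which strata (quarantine, age, patches, ...) are applied
#' does not affect the final model.
#'
#' @param disease,strata `typed_petri_net` objects over the identical
#'   type system.
#' @param check validate the induced typing of the result (default TRUE).
#' @return a `typed_petri_net` with attributes `proj_disease` and
#'   `proj_strata` (both `petri_morphism`).
#' @export
stratify <- function(disease, strata, check = TRUE) {
  if (!petri_isomorphic(disease$type_net, strata$type_net) ||
      !identical(disease$type_net$species$label, strata$type_net$species$label) ||
      !identical(disease$type_net$transitions$label, strata$type_net$transitions$label))
    stop_opetri("disease and strata must be typed by the identical type net")

  pair_rows <- function(tyA, tyB) {
    # all (i, j) with equal type, lexicographic in (i, j)
    out <- list()
    for (i in seq_along(tyA)) {
      js <- which(tyB == tyA[i])
      for (j in js) out[[length(out) + 1L]] <- c(i, j)
    }
    if (length(out) == 0L) matrix(integer(0), 0, 2)
    else do.call(rbind, out)
  }
  A <- disease; B <- strata
  sp <- pair_rows(A$typing$species_map, B$typing$species_map)
  tr <- pair_rows(A$typing$transition_map, B$typing$transition_map)
  in_a <- pair_rows(A$typing$input_arc_map, B$typing$input_arc_map)
  out_a <- pair_rows(A$typing$output_arc_map, B$typing$output_arc_map)

  sp_index <- function(i, j) which(sp[, 1] == i & sp[, 2] == j)
  tr_index <- function(i, j) which(tr[, 1] == i & tr[, 2] == j)

  mk_arcs <- function(pairs, arcsA, arcsB) {
    if (nrow(pairs) == 0L)
      return(data.frame(species = integer(), transition = integer()))
    data.frame(
      species = vapply(seq_len(nrow(pairs)), function(k)
        sp_index(arcsA$species[pairs[k, 1]], arcsB$species[pairs[k, 2]]),
        integer(1)),
      transition = vapply(seq_len(nrow(pairs)), function(k)
        tr_index(arcsA$transition[pairs[k, 1]], arcsB$transition[pairs[k, 2]]),
        integer(1)))
  }

  join <- function(la, lb) paste(la, lb, sep = "_")
  net <- petri_net(
    species = if (nrow(sp) == 0) character() else
      join(A$net$species$label[sp[, 1]], B$net$species$label[sp[, 2]]),
    transitions = if (nrow(tr) == 0) character() else
      join(A$net$transitions$label[tr[, 1]], B$net$transitions$label[tr[, 2]]),
    input_arcs = mk_arcs(in_a, A$net$input_arcs, B$net$input_arcs),
    output_arcs = mk_arcs(out_a, A$net$output_arcs, B$net$output_arcs))

  proj <- function(col) {
    petri_morphism(
      if (nrow(sp) == 0) integer() else sp[, col],
      if (nrow(tr) == 0) integer() else tr[, col],
      if (nrow(in_a) == 0) integer() else in_a[, col],
      if (nrow(out_a) == 0) integer() else out_a[, col])
  }
  p1 <- proj(1); p2 <- proj(2)
  typing <- compose_morphism(A$typing, p1)
  out <- typed_petri(net, A$type_net, typing, check = check)
  attr(out, "proj_disease") <- p1
  attr(out, "proj_strata") <- p2
  out
}
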