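# JSON serialization. All documents carry a "schema" tag; indices are
# 0-based on disk (documented schema convention) and 1-based in memory.

schema_of <- function(obj) {
  if (inherits(obj, "open_petri_net")) "open-petri-v1"
  else if (inherits(obj, "typed_petri_net")) "typed-petri-v1"
  else if (inherits(obj, "petri_net")) "petri-v1"
  else if (inherits(obj, "uwd")) "uwd-v1"
  else if (inherits(obj, "rate_assignment")) "rates-v1"
  else stop_opetri("cannot serialize objects of class ",
                   paste(class(obj), collapse = "/"))
}

petri_tables <- function(net) {
  list(
    species = lapply(net$species$label, function(l) list(label = l)),
    transitions = lapply(seq_len(nrow(net$transitions)), function(t) {
      r <- net$transitions$rate[t]
      if (is.na(r)) list(label = net$transitions$label[t])
      else list(label = net$transitions$label[t], rate = r)
    }),
    input_arcs = lapply(seq_len(nrow(net$input_arcs)), function(i)
      list(species = net$input_arcs$species[i] - 1L,
           transition = net$input_arcs$transition[i] - 1L)),
    output_arcs = lapply(seq_len(nrow(net$output_arcs)), function(i)
      list(species = net$output_arcs$species[i] - 1L,
           transition = net$output_arcs$transition[i] - 1L)))
}

morphism_maps <- function(f) {
  list(species_map = as.list(f$species_map - 1L),
       transition_map = as.list(f$transition_map - 1L),
       input_arc_map = as.list(f$input_arc_map - 1L),
       output_arc_map = as.list(f$output_arc_map - 1L))
}

#' Save a model to a JSON document
#'
#' Petri nets (`petri-v1`), open Petri nets (`open-petri-v1`), UWDs
#' (`uwd-v1`), typed Petri nets (`typed-petri-v1`) and rate assignments
#' (`rates-v1`) round-trip losslessly, labels included. Indices are
#' 0-based on disk.
#'
#' @param obj the model object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(obj, path) {
  doc <- switch(schema_of(obj),
    "petri-v1" = c(list(schema = "petri-v1"), petri_tables(obj)),
    "open-petri-v1" = c(list(schema = "open-petri-v1"), petri_tables(obj$net),
                        list(feet = lapply(obj$legs, function(l) as.list(l - 1L)))),
    "uwd-v1" = list(
      schema = "uwd-v1",
      boxes = lapply(obj$boxes$label, function(l) list(label = l)),
      ports = lapply(seq_len(nrow(obj$ports)), function(i)
        list(box = obj$ports$box[i] - 1L,
             junction = obj$ports$junction[i] - 1L)),
      junctions = lapply(obj$junctions$label, function(l) list(label = l)),
      outer_ports = lapply(obj$outer_ports$junction, function(j)
        list(junction = j - 1L))),
    "typed-petri-v1" = list(schema = "typed-petri-v1",
                            net = petri_tables(obj$net),
                            type_net = petri_tables(obj$type_net),
                            typing = morphism_maps(obj$typing)),
    "rates-v1" = list(schema = "rates-v1", beta = as.list(obj$beta),
                      u0 = as.list(obj$u0)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

need <- function(doc, field, where) {
  if (is.null(doc[[field]]))
    stop_opetri("schema error at ", where, ": missing '", field, "'")
  doc[[field]]
}

tables_to_petri <- function(doc, where) {
  sp <- need(doc, "species", where)
  tr <- need(doc, "transitions", where)
  ia <- need(doc, "input_arcs", where)
  oa <- need(doc, "output_arcs", where)
  get_arc <- function(rows, tab) {
    data.frame(
      species = vapply(rows, function(r)
        as.integer(need(r, "species", paste0(where, ".", tab))) + 1L, integer(1)),
      transition = vapply(rows, function(r)
        as.integer(need(r, "transition", paste0(where, ".", tab))) + 1L, integer(1)))
  }
  petri_net(
    species = vapply(sp, function(r) as.character(need(r, "label",
      paste0(where, ".species"))), character(1)),
    transitions = vapply(tr, function(r) as.character(need(r, "label",
      paste0(where, ".transitions"))), character(1)),
    input_arcs = get_arc(ia, "input_arcs"),
    output_arcs = get_arc(oa, "output_arcs"),
    rates = vapply(tr, function(r) as.numeric(r$rate %||% NA_real_), numeric(1)))
}

maps_to_morphism <- function(doc, where) {
  g <- function(f) as.integer(unlist(need(doc, f, where))) + 1L
  petri_morphism(g("species_map"), g("transition_map"),
                 g("input_arc_map"), g("output_arc_map"))
}

#' Load a model from a JSON document
#'
#' Dispatches on the document's `schema` tag; malformed documents raise a
#' schema error naming the offending path.
#'
#' @param path JSON file path.
#' @return the model object.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path)
  schema <- need(doc, "schema", "$")
  switch(schema,
    "petri-v1" = tables_to_petri(doc, "$"),
    "open-petri-v1" = {
      net <- tables_to_petri(doc, "$")
      feet <- lapply(need(doc, "feet", "$"), function(l)
        as.integer(unlist(l)) + 1L)
      make_open(net, feet)
    },
    "uwd-v1" = {
      ports <- need(doc, "ports", "$")
      uwd(
        boxes = vapply(need(doc, "boxes", "$"), function(r)
          as.character(need(r, "label", "$.boxes")), character(1)),
        ports = data.frame(
          box = vapply(ports, function(r)
            as.integer(need(r, "box", "$.ports")) + 1L, integer(1)),
          junction = vapply(ports, function(r)
            as.integer(need(r, "junction", "$.ports")) + 1L, integer(1))),
        junctions = vapply(need(doc, "junctions", "$"), function(r)
          as.character(need(r, "label", "$.junctions")), character(1)),
        outer_ports = data.frame(junction = vapply(
          doc$outer_ports %||% list(), function(r)
            as.integer(need(r, "junction", "$.outer_ports")) + 1L, integer(1))))
    },
    "typed-petri-v1" = {
      net <- tables_to_petri(need(doc, "net", "$"), "$.net")
      type_net <- tables_to_petri(need(doc, "type_net", "$"), "$.type_net")
      typed_petri(net, type_net,
                  maps_to_morphism(need(doc, "typing", "$"), "$.typing"))
    },
    "rates-v1" = structure(
      list(beta = unlist(need(doc, "beta", "$")),
           u0 = unlist(need(doc, "u0", "$"))),
      class = "rate_assignment"),
    stop_opetri("schema error at $: unknown schema '", schema, "'"))
}

#' Export a model as Graphviz DOT
#'
#' Petri nets: species as circles, transitions as squares, input arcs
#' drawn species to transition and output arcs transition to species,
#' with multiplicities as edge labels. UWDs: boxes as rounded rectangles,
#' junctions as dots, wires as undirected edges. An optional named
#' `heat` vector (e.g. a sensitivity report's `per_transition`) colours
#' transitions red (positive) or blue (negative).
#'
#' @param obj a `petri_net` or `uwd` (typed/open nets export their
#'   underlying net).
#' @param heat optional named numeric vector over transition labels.
#' @return character scalar of DOT source.
#' @export
export_dot <- function(obj, heat = NULL) {
  if (inherits(obj, "open_petri_net")) obj <- obj$net
  if (inherits(obj, "typed_petri_net")) obj <- obj$net
  if (inherits(obj, "petri_net")) {
    lines <- c("digraph petri {", "  rankdir=LR;")
    for (s in seq_len(nrow(obj$species)))
      lines <- c(lines, sprintf("  s%d [label=\"%s\", shape=circle];",
                                s, obj$species$label[s]))
    for (t in seq_len(nrow(obj$transitions))) {
      col <- ""
      if (!is.null(heat)) {
        v <- heat[[obj$transitions$label[t]]] %||% 0
        if (is.na(v)) v <- 0
        scaled <- if (max(abs(heat), na.rm = TRUE) > 0)
          v / max(abs(heat), na.rm = TRUE) else 0
        # red for positive sensitivity, blue for negative
        col <- sprintf(", style=filled, fillcolor=\"%s\"",
                       grDevices::rgb(1 - max(0, -scaled), 1 - abs(scaled),
                                      1 - max(0, scaled)))
      }
      lines <- c(lines, sprintf("  t%d [label=\"%s\", shape=square%s];",
                                t, obj$transitions$label[t], col))
    }
    edge <- function(arcs, species_first) {
      key <- paste(arcs$species, arcs$transition)
      for (k in unique(key)) {
        i <- which(key == k)[1]
        m <- sum(key == k)
        lab <- if (m > 1) sprintf(" [label=\"%d\"]", m) else ""
        lines <<- c(lines, if (species_first)
          sprintf("  s%d -> t%d%s;", arcs$species[i], arcs$transition[i], lab)
        else
          sprintf("  t%d -> s%d%s;", arcs$transition[i], arcs$species[i], lab))
      }
    }
    edge(obj$input_arcs, TRUE)
    edge(obj$output_arcs, FALSE)
    paste(c(lines, "}"), collapse = "\n")
  } else if (inherits(obj, "uwd")) {
    lines <- c("graph uwd {", "  layout=neato;")
    for (b in seq_len(nrow(obj$boxes)))
      lines <- c(lines, sprintf("  b%d [label=\"%s\", shape=box, style=rounded];",
                                b, obj$boxes$label[b]))
    for (j in seq_len(nrow(obj$junctions)))
      lines <- c(lines, sprintf("  j%d [label=\"%s\", shape=point, width=0.12];",
                                j, obj$junctions$label[j]))
    for (p in seq_len(nrow(obj$ports)))
      lines <- c(lines, sprintf("  b%d -- j%d;", obj$ports$box[p],
                                obj$ports$junction[p]))
    for (o in seq_len(nrow(obj$outer_ports)))
      lines <- c(lines, sprintf("  outer%d [shape=plaintext, label=\"\"]; outer%d -- j%d;",
                                o, o, obj$outer_ports$junction[o]))
    paste(c(lines, "}"), collapse = "\n")
  } else {
    stop_opetri("export_dot supports petri_net and uwd objects")
  }
}

#' Write a trajectory as CSV
#'
#' Header is `time,<species labels...>`, one row per report time.
#' @param traj a `trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectory observations from CSV
#'
#' Expects a header `time,<label>,...`; every non-time column is an
#' observed species.
#' @param path CSV path.
#' @return an `observations` object.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df))
    stop_opetri("observations CSV needs a 'time' column")
  observations(df$time, df[, setdiff(names(df), "time"), drop = FALSE])
}
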