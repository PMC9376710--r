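#' Undirected wiring diagrams
#'
#' A UWD is the composition syntax: a set of boxes (slots for subsystems),
#' a set of ports (attachment points, each assigned to a box) and a set of
#' junctions (shared variables, each port is wired to one junction). An
#' optional outer-port table exposes junctions as the interface of the
#' composite; a diagram with no outer ports composes to a closed system.
#'
#' @param boxes character vector of box labels.
#' @param ports data frame (or matrix) with columns `box` and `junction`,
#'   1-based indices.
#' @param junctions character vector of junction labels.
#' @param outer_ports optional data frame with column `junction`, or an
#'   integer vector of junction indices.
#' @return An object of class `uwd`.
#' @export
uwd <- function(boxes = character(), ports = NULL, junctions = character(),
                outer_ports = NULL) {
  as_ports <- function(p) {
    if (is.null(p)) return(data.frame(box = integer(), junction = integer()))
    p <- as.data.frame(p)
    data.frame(box = as.integer(p$box), junction = as.integer(p$junction))
  }
  if (is.numeric(outer_ports)) outer_ports <- data.frame(junction = outer_ports)
  op <- if (is.null(outer_ports)) data.frame(junction = integer())
        else data.frame(junction = as.integer(as.data.frame(outer_ports)$junction))
  d <- structure(list(boxes = data.frame(label = as.character(boxes),
                                         stringsAsFactors = FALSE),
                      ports = as_ports(ports),
                      junctions = data.frame(label = as.character(junctions),
                                             stringsAsFactors = FALSE),
                      outer_ports = op),
                 class = "uwd")
  bad <- validate_uwd(d)
  bad <- bad[!startsWith(bad, "warning")]
  if (length(bad) > 0L) stop_opetri("invalid uwd: ", paste(bad, collapse = "; "))
  d
}

#' Validate a UWD
#'
#' Index-range checks for ports and outer ports. A junction wired to no
#' port is legal but reported as a `"warning: ..."` entry.
#'
#' @param d a `uwd`.
#' @return character vector: violations, plus warning entries prefixed
#'   `"warning:"`. Empty iff fully clean.
#' @export
validate_uwd <- function(d) {
  viol <- character()
  nb <- nrow(d$boxes); nj <- nrow(d$junctions)
  for (i in seq_len(nrow(d$ports))) {
    if (is.na(d$ports$box[i]) || d$ports$box[i] < 1L || d$ports$box[i] > nb)
      viol <- c(viol, sprintf("ports row %d: box index %s out of range [1, %d]",
                              i, d$ports$box[i], nb))
    if (is.na(d$ports$junction[i]) || d$ports$junction[i] < 1L || d$ports$junction[i] > nj)
      viol <- c(viol, sprintf("ports row %d: junction index %s out of range [1, %d]",
                              i, d$ports$junction[i], nj))
  }
  for (i in seq_len(nrow(d$outer_ports))) {
    j <- d$outer_ports$junction[i]
    if (is.na(j) || j < 1L || j > nj)
      viol <- c(viol, sprintf("outer_ports row %d: junction index %s out of range [1, %d]",
                              i, j, nj))
  }
  if (length(viol) == 0L) {
    isolated <- setdiff(seq_len(nj), unique(d$ports$junction))
    for (j in isolated)
      viol <- c(viol, sprintf("warning: junction %d (%s) is wired to no port",
                              j, d$junctions$label[j]))
  }
  viol
}

#' Box, port and junction counts of a UWD
#' @param d a valid `uwd`.
#' @return named integer vector `c(boxes =, ports =, junctions =)`.
#' @export
uwd_summary <- function(d) {
  c(boxes = nrow(d$boxes), ports = nrow(d$ports), junctions = nrow(d$junctions))
}

# Ports of box b, in port-table order.
ports_of_box <- function(d, b) which(d$ports$box == b)

#' Hierarchical substitution of one UWD into a box of another
#'
#' Replaces a box of `outer` by the diagram `inner`, merging inner
#' junctions with outer junctions along the correspondence between
#' `inner`'s outer ports and the ports of the replaced box. The result is
#' the flattened diagram of the two-level specification. Ordering is
#' deterministic: surviving outer boxes first (original order) then inner
#' boxes; outer junctions first then unmerged inner junctions. Junction
#' labels of the outer diagram win on merge.
#'
#' @param outer a valid `uwd`.
#' @param box index of the box of `outer` to replace.
#' @param inner a valid `uwd` whose outer-port count equals the port count
#'   of the replaced box.
#' @param port_correspondence integer vector: entry k gives the port of
#'   `box` (as an index into the box's ports, in port order) matched with
#'   the k-th outer port of `inner`. Defaults to the identity order.
#' @return the flattened `uwd`.
#' @export
uwd_substitute <- function(outer, box, inner, port_correspondence = NULL) {
  bports <- ports_of_box(outer, box)
  k <- nrow(inner$outer_ports)
  if (k != length(bports))
    stop_opetri("arity mismatch: inner exposes ", k, " outer ports but box ",
                box, " has ", length(bports), " ports")
  pc <- port_correspondence %||% seq_len(k)
  if (length(pc) != k || anyDuplicated(pc) || any(pc < 1L | pc > k))
    stop_opetri("port_correspondence must be a bijection on ", k, " ports")

  njo <- nrow(outer$junctions); nji <- nrow(inner$junctions)
  # union-find over outer junctions (1..njo) then inner junctions (njo+1..)
  parent <- uf_new(njo + nji)
  for (q in seq_len(k)) {
    jo <- outer$ports$junction[bports[pc[q]]]
    ji <- inner$outer_ports$junction[q]
    parent <- uf_union(parent, jo, njo + ji)  # outer root wins
  }
  roots <- uf_roots(parent)
  keep <- sort(unique(roots))
  class_of <- match(roots, keep)
  labels <- character(length(keep))
  for (i in seq_along(keep)) {
    members <- which(roots == keep[i])
    out_members <- members[members <= njo]
    labels[i] <- if (length(out_members) > 0)
      outer$junctions$label[min(out_members)]
    else inner$junctions$label[min(members) - njo]
  }

  keep_boxes <- setdiff(seq_len(nrow(outer$boxes)), box)
  new_box_of_outer <- match(seq_len(nrow(outer$boxes)), keep_boxes)
  n_outer_boxes <- length(keep_boxes)

  po <- outer$ports[outer$ports$box != box, , drop = FALSE]
  ports <- data.frame(
    box = c(new_box_of_outer[po$box], inner$ports$box + n_outer_boxes),
    junction = c(class_of[po$junction], class_of[njo + inner$ports$junction]))
  uwd(boxes = c(outer$boxes$label[keep_boxes], inner$boxes$label),
      ports = ports,
      junctions = labels,
      outer_ports = data.frame(junction = class_of[outer$outer_ports$junction]))
}

#' Are two UWDs isomorphic?
#'
#' Bijections on boxes, junctions (and implicitly ports) commuting with the
#' port assignments and preserving the outer interface; labels ignored.
#' Brute-force over box and junction bijections — fine at fixture scale.
#'
#' @param a,b valid `uwd` objects.
#' @return logical scalar.
#' @export
uwd_isomorphic <- function(a, b) {
  if (nrow(a$boxes) != nrow(b$boxes) || nrow(a$ports) != nrow(b$ports) ||
      nrow(a$junctions) != nrow(b$junctions) ||
      nrow(a$outer_ports) != nrow(b$outer_ports)) return(FALSE)
  nb <- nrow(a$boxes); nj <- nrow(a$junctions)
  cnt <- function(d, b_, j_) sum(d$ports$box == b_ & d$ports$junction == j_)
  outer_cnt <- function(d, j_) sum(d$outer_ports$junction == j_)
  for (pb in permutations(nb)) {
    ok_b <- all(vapply(seq_len(nb), function(x)
      length(ports_of_box(a, x)) == length(ports_of_box(b, pb[x])), logical(1)))
    if (!ok_b) next
    for (pj in permutations(nj)) {
      ok <- TRUE
      for (x in seq_len(nb)) {
        for (y in seq_len(nj)) {
          if (cnt(a, x, y) != cnt(b, pb[x], pj[y])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok && all(vapply(seq_len(nj), function(y)
        outer_cnt(a, y) == outer_cnt(b, pj[y]), logical(1))))
        return(TRUE)
    }
  }
  nb == 0L && nj == 0L
}

#' @export
print.uwd <- function(x, ...) {
  s <- uwd_summary(x)
  cat(sprintf("uwd: %d boxes, %d ports, %d junctions, %d outer ports\n",
              s["boxes"], s["ports"], s["junctions"], nrow(x$outer_ports)))
  for (b in seq_len(nrow(x$boxes))) {
    js <- x$ports$junction[ports_of_box(x, b)]
    cat(sprintf("  %s(%s)\n", x$boxes$label[b],
                paste(x$junctions$label[js], collapse = ", ")))
  }
  if (nrow(x$outer_ports) > 0)
    cat("  outer:", paste(x$junctions$label[x$outer_ports$junction],
                          collapse = ", "), "\n")
  invisible(x)
}
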