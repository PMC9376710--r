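# Independent oracles used by the tests. These deliberately use different
# algorithms from the package internals (equivalence-closure sweeps
# instead of union-find, naive product enumeration instead of pruned
# backtracking, refined grids / Richardson extrapolation instead of the
# production quadrature and differences).

# Brute-force gluing oracle: predicts the composite's species and
# transition counts by computing the equivalence closure of "exposed at
# ports wired to the same junction" with repeated sweeps.
oracle_glue_counts <- function(d, components) {
  n_states <- vapply(components, function(o) nrow(o$net$species), integer(1))
  offs <- cumsum(c(0L, n_states))
  total <- offs[length(offs)]
  cls <- seq_len(total)
  # collect related pairs
  pairs <- list()
  for (j in seq_len(nrow(d$junctions))) {
    members <- integer()
    for (b in seq_len(nrow(d$boxes))) {
      pb <- which(d$ports$box == b)
      for (q in seq_along(pb)) {
        if (d$ports$junction[pb[q]] == j)
          members <- c(members, offs[b] + components[[b]]$legs[[q]][1])
      }
    }
    if (length(members) > 1)
      for (k in 2:length(members))
        pairs[[length(pairs) + 1L]] <- c(members[1], members[k])
  }
  repeat {
    changed <- FALSE
    for (p in pairs) {
      a <- cls[p[1]]; b <- cls[p[2]]
      if (a != b) { cls[cls == b] <- a; changed <- TRUE }
    }
    if (!changed) break
  }
  portless_outer <- setdiff(unique(d$outer_ports$junction),
                            unique(d$ports$junction))
  list(species = length(unique(cls)) + length(portless_outer),
       transitions = sum(vapply(components, function(o)
         nrow(o$net$transitions), integer(1))))
}

# Naive exhaustive morphism enumeration: grids over all species and
# transition maps, then per-transition enumeration of every arc function,
# filtered by commuting squares and fibrewise bijectivity.
oracle_morphisms <- function(dom, cod) {
  ns <- nrow(dom$species); nt <- nrow(dom$transitions)
  cns <- nrow(cod$species); cnt <- nrow(cod$transitions)
  if ((ns > 0 && cns == 0) || (nt > 0 && cnt == 0)) return(list())
  grid <- function(n, k) {
    # all length-n vectors over 1..k
    if (n == 0) return(list(integer(0)))
    out <- list(integer(0))
    for (i in seq_len(n)) {
      out <- unlist(lapply(out, function(v) lapply(seq_len(k), function(x) c(v, x))),
                    recursive = FALSE)
    }
    out
  }
  all_funs <- function(from, to) {
    # all maps from index set `from` into index set `to`
    if (length(from) == 0) return(list(integer(0)))
    out <- list(integer(0))
    for (i in seq_along(from)) {
      out <- unlist(lapply(out, function(v) lapply(to, function(x) c(v, x))),
                    recursive = FALSE)
    }
    out
  }
  res <- list()
  for (smap in grid(ns, cns)) for (tmap in grid(nt, cnt)) {
    if (nt == 0) {
      res[[length(res) + 1L]] <- petri_morphism(smap, integer(0),
                                                integer(0), integer(0))
      next
    }
    per_t_in <- vector("list", nt); per_t_out <- vector("list", nt)
    feasible <- TRUE
    for (t in seq_len(nt)) {
      din <- which(dom$input_arcs$transition == t)
      cin <- which(cod$input_arcs$transition == tmap[t])
      cand <- Filter(function(f) {
        length(f) == length(cin) && !anyDuplicated(f) && setequal(f, cin) &&
          all(cod$input_arcs$species[f] == smap[dom$input_arcs$species[din]])
      }, all_funs(din, cin))
      if (length(din) != length(cin) || length(cand) == 0) {
        if (length(din) == 0 && length(cin) == 0) cand <- list(integer(0))
        else { feasible <- FALSE; break }
      }
      per_t_in[[t]] <- cand
      dout <- which(dom$output_arcs$transition == t)
      cout <- which(cod$output_arcs$transition == tmap[t])
      cand <- Filter(function(f) {
        length(f) == length(cout) && !anyDuplicated(f) && setequal(f, cout) &&
          all(cod$output_arcs$species[f] == smap[dom$output_arcs$species[dout]])
      }, all_funs(dout, cout))
      if (length(dout) != length(cout) || length(cand) == 0) {
        if (length(dout) == 0 && length(cout) == 0) cand <- list(integer(0))
        else { feasible <- FALSE; break }
      }
      per_t_out[[t]] <- cand
    }
    if (!feasible) next
    combos <- expand.grid(c(lapply(per_t_in, seq_along),
                            lapply(per_t_out, seq_along)))
    for (r in seq_len(nrow(combos))) {
      imap <- rep(NA_integer_, nrow(dom$input_arcs))
      omap <- rep(NA_integer_, nrow(dom$output_arcs))
      for (t in seq_len(nt)) {
        din <- which(dom$input_arcs$transition == t)
        imap[din] <- per_t_in[[t]][[combos[r, t]]]
        dout <- which(dom$output_arcs$transition == t)
        omap[dout] <- per_t_out[[t]][[combos[r, nt + t]]]
      }
      res[[length(res) + 1L]] <- petri_morphism(smap, tmap, imap, omap)
    }
  }
  res
}

morphism_key <- function(m) paste(c(m$species_map, -1, m$transition_map, -1,
                                    m$input_arc_map, -1, m$output_arc_map),
                                  collapse = ",")

# Pullback size oracle: counts same-typed pairs table by table from the
# typing maps alone.
oracle_pullback_sizes <- function(A, B) {
  cnt <- function(tyA, tyB) sum(vapply(tyA, function(x) sum(tyB == x), integer(1)))
  c(species = cnt(A$typing$species_map, B$typing$species_map),
    transitions = cnt(A$typing$transition_map, B$typing$transition_map),
    input_arcs = cnt(A$typing$input_arc_map, B$typing$input_arc_map),
    output_arcs = cnt(A$typing$output_arc_map, B$typing$output_arc_map))
}

# Richardson step-halving oracle for dJ/dbeta_t.
oracle_richardson <- function(Jfun, beta, t, h) {
  D <- function(hh) {
    bp <- beta; bp[t] <- bp[t] + hh
    bm <- beta; bm[t] <- bm[t] - hh
    (Jfun(bp) - Jfun(bm)) / (2 * hh)
  }
  (4 * D(h / 2) - D(h)) / 3
}

# Random small open-Petri instance under a given seed, for gluing
# property tests.
random_open_instance <- function(seed) {
  set.seed(seed)
  nb <- sample(1:3, 1); nj <- sample(1:4, 1)
  ports <- data.frame(box = integer(), junction = integer())
  for (b in seq_len(nb)) {
    np <- sample(0:2, 1)
    if (np > 0)
      ports <- rbind(ports, data.frame(box = b,
                                       junction = sample(nj, np, replace = TRUE)))
  }
  d <- uwd(boxes = paste0("b", seq_len(nb)), ports = ports,
           junctions = paste0("j", seq_len(nj)))
  components <- lapply(seq_len(nb), function(b) {
    np <- sum(ports$box == b)
    ns <- max(np, sample(1:3, 1))
    ntr <- sample(0:2, 1)
    ia <- oa <- NULL
    if (ntr > 0) {
      ia <- data.frame(species = sample(ns, ntr, replace = TRUE),
                       transition = seq_len(ntr))
      oa <- data.frame(species = sample(ns, ntr, replace = TRUE),
                       transition = seq_len(ntr))
    }
    net <- petri_net(paste0("c", b, "s", seq_len(ns)),
                     if (ntr > 0) paste0("c", b, "t", seq_len(ntr)) else character(),
                     ia, oa)
    make_open(net, as.list(sample(ns, np, replace = TRUE)))
  })
  list(uwd = d, components = components)
}
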