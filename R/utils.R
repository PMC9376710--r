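# Small internal helpers shared across modules.

# Union-find with path compression; parents is an integer vector 1..n.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

# Resolve every element to its root (flattened representative vector).
uf_roots <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

# All permutations of 1..n as a list of integer vectors. n is tiny here
# (arc arities), so the factorial growth is harmless.
permutations <- function(n) {
  if (n == 0L) return(list(integer(0)))
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations(n - 1L)
    prev <- setdiff(seq_len(n), i)
    for (p in rest) out[[length(out) + 1L]] <- c(i, prev[p])
  }
  out
}

# Multiplicity count: named integer vector over labels, dropping zeros.
count_multiset <- function(idx, labels) {
  tab <- table(factor(idx, levels = seq_along(labels)))
  counts <- as.integer(tab)
  names(counts) <- labels
  counts[counts > 0L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_opetri <- function(...) stop(..., call. = FALSE)
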