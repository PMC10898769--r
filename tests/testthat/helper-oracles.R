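# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorised code paths.

# All-pairs hop distances by per-source breadth-first search over
# explicit neighbour lists.
brute_distances <- function(adj) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] != 0))
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(nbrs[frontier]))
      nxt <- nxt[!is.finite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# Long-range field by explicit shell enumeration.
brute_long_range <- function(y, adj, i, l_max = Inf) {
  D <- brute_distances(adj)
  total <- 0
  for (j in seq_along(y)) {
    l <- D[i, j]
    if (is.finite(l) && l >= 2 && l <= l_max) total <- total + y[j] / l
  }
  total
}

# Betweenness by enumerating every shortest path with a depth-first
# walk constrained to geodesic length.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- brute_distances(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] != 0))
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (w in nbrs[[v]]) {
        if (!(w %in% path) && length(path) - 1 + 1 + D[w, t] == D[s, t]) {
          walk(c(path, w))
        }
      }
    }
    walk(s)
    out
  }
  bt <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t]) || D[s, t] < 2) next
      ps <- paths_between(s, t)
      inner <- unlist(lapply(ps, function(p) p[-c(1, length(p))]))
      for (v in unique(inner)) {
        bt[v] <- bt[v] + sum(inner == v) / length(ps)
      }
    }
  }
  bt
}

# Local clustering by direct triangle counting.
brute_clustering <- function(adj) {
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] != 0) tri <- tri + 1
      }
    }
    2 * tri / (k * (k - 1))
  })
}

# Random symmetric 0/1 adjacency with no self-loops.
random_adjacency <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  A + t(A)
}

# Signed network from a plain weight matrix.
make_net <- function(A) signed_network(A)

# Unit-weight network from an edge list on n nodes.
net_from_edges <- function(n, edges) {
  A <- matrix(0, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  signed_network(A)
}
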