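#' Signed acquaintance network
#'
#' A symmetric weighted adjacency matrix over `n` agents. Positive weights
#' are friendly bonds, negative weights hostile ones. A separate logical
#' presence matrix `L` records which pairs ever held a link (links are
#' never removed, only added by rewiring); entries whose weight is exactly
#' zero behave as absent for degrees, neighbourhoods and path distances.
#'
#' @param A Symmetric numeric matrix with zero diagonal.
#' @param L Optional logical presence matrix; defaults to `A != 0`.
#' @return An object of class `signed_network` with elements `n`, `A`, `L`.
#' @export
signed_network <- function(A, L = NULL) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("`A` must be a square matrix", call. = FALSE)
  }
  if (any(A != t(A))) stop("`A` must be symmetric", call. = FALSE)
  if (any(diag(A) != 0)) stop("`A` must have a zero diagonal", call. = FALSE)
  if (is.null(L)) L <- A != 0
  storage.mode(A) <- "double"
  diag(L) <- FALSE
  structure(list(n = nrow(A), A = A, L = L), class = "signed_network")
}

#' Initial random acquaintance network
#'
#' Draws `floor(n * k_avg / 2)` distinct links uniformly at random among
#' the `n` agents, all with equal weight 1: at the start of a run nobody
#' is an enemy yet.
#'
#' @inheritParams model_params
#' @param weight Initial weight of every link.
#' @return A [signed_network()] with mean degree `2 * floor(n*k_avg/2) / n`.
#' @examples
#' set.seed(1)
#' net <- init_random_network(25, 6)
#' sum(net$A != 0) / 2 # 75 links
#' @export
init_random_network <- function(n, k_avg, weight = 1) {
  check_scalar(n, "n", lower = 2, integer = TRUE)
  check_scalar(k_avg, "k_avg", lower = 0, upper = n - 1, strict_lower = TRUE)
  m <- floor(n * k_avg / 2)
  pairs <- which(upper.tri(matrix(TRUE, n, n)))
  chosen <- sample(length(pairs), m)
  A <- matrix(0, n, n)
  A[pairs[chosen]] <- weight
  A <- A + t(A)
  signed_network(A)
}

# Active skeleton: links present and currently nonzero.
net_skeleton <- function(net) net$L & net$A != 0

#' Agent degrees on the active skeleton
#'
#' @param net A [signed_network()].
#' @return Integer vector of per-agent degrees (nonzero-weight links).
#' @export
net_degree <- function(net) as.integer(rowSums(net_skeleton(net)))

#' All-pairs hop distances on the active skeleton
#'
#' Breadth-first hop counts on the unweighted skeleton of nonzero-weight
#' links (hostile links still carry information). Unreachable pairs get
#' `Inf`.
#'
#' @param net A [signed_network()] or a logical adjacency matrix.
#' @return An `n x n` numeric matrix of hop counts.
#' @export
hop_distances <- function(net) {
  adj <- if (inherits(net, "signed_network")) net_skeleton(net) else net
  n <- nrow(adj)
  num <- adj * 1
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  frontier <- adj
  known <- adj | diag(n) > 0
  D[adj] <- 1
  l <- 1L
  while (any(frontier) && l < n) {
    l <- l + 1L
    frontier <- ((frontier %*% num) > 0) & !known
    if (!any(frontier)) break
    D[frontier] <- l
    known <- known | frontier
  }
  D
}

#' @export
print.signed_network <- function(x, ...) {
  skel <- net_skeleton(x)
  cat("Signed network:", x$n, "agents,", sum(skel) / 2, "active links (",
      sum(x$A < 0) / 2, "negative )\n")
  invisible(x)
}

#' Convert a signed network to an igraph graph
#'
#' @param net A [signed_network()].
#' @param states Optional agent states; attached as node attributes
#'   `x`, `y`, `alpha`.
#' @param positive_only Keep only positive-weight links.
#' @return An undirected `igraph` graph with edge attribute `weight`.
#' @export
as_igraph_signed <- function(net, states = NULL, positive_only = FALSE) {
  A <- net$A
  if (positive_only) A[A < 0] <- 0
  A[!net$L] <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  if (!is.null(states)) {
    g <- igraph::set_vertex_attr(g, "x", value = states$x)
    g <- igraph::set_vertex_attr(g, "y", value = states$y)
    g <- igraph::set_vertex_attr(g, "alpha", value = states$alpha)
  }
  g
}
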