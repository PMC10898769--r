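#' Per-agent network indicators
#'
#' The four single-agent indicators entering the fitness score, each
#' normalised to `[0, 1]`:
#' \itemize{
#'   \item `bt` betweenness centrality, divided by its combinatorial
#'     maximum `(n - 1)(n - 2) / 2`;
#'   \item `cl` local clustering coefficient (0 for degree below 2);
#'   \item `kdeg` degree divided by `n - 1`;
#'   \item `strength` absolute signed row sum `|sum_j A[i, j]|`, divided
#'     by the cohort maximum (0 when all bonds cancel).
#' }
#' Betweenness, clustering and degree are computed on the unweighted
#' skeleton of positive-weight links — the friendly acquaintance
#' structure; strength uses the full signed matrix.
#'
#' @param net A [signed_network()], typically the final state of a run.
#' @return A data frame with columns `agent`, `bt`, `cl`, `kdeg`,
#'   `strength`.
#' @export
node_indicators <- function(net) {
  n <- net$n
  pos <- net$A
  pos[pos < 0 | !net$L] <- 0
  g <- igraph::graph_from_adjacency_matrix(pos != 0, mode = "undirected")
  bt_max <- (n - 1) * (n - 2) / 2
  bt <- if (bt_max > 0) igraph::betweenness(g, directed = FALSE) / bt_max
        else rep(0, n)
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  cl[is.na(cl)] <- 0
  kdeg <- igraph::degree(g) / (n - 1)
  s <- abs(rowSums(net$A * net$L))
  strength <- if (max(s) > 0) s / max(s) else rep(0, n)
  data.frame(agent = seq_len(n), bt = bt, cl = cl, kdeg = kdeg,
             strength = strength)
}

#' Fitness score
#'
#' Weighted mean of the four normalised indicators; with the default
#' equal weights this is `(bt + cl + kdeg + strength) / 4`. Setting a
#' weight to zero drops that indicator, which makes ablations over
#' indicator subsets a pure configuration change.
#'
#' @param ind Indicator data frame from [node_indicators()].
#' @param weights Four nonnegative coefficients summing to 1, in the
#'   order `bt`, `cl`, `kdeg`, `strength`.
#' @return Numeric fitness vector in `[0, 1]`.
#' @examples
#' net <- signed_network(matrix(1, 4, 4) - diag(4)) # K4
#' fitness(node_indicators(net)) # 0.75 for every node
#' @export
fitness <- function(ind, weights = rep(1 / 4, 4)) {
  if (length(weights) != 4 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must be 4 nonnegative numbers summing to 1",
         call. = FALSE)
  }
  as.vector(as.matrix(ind[, c("bt", "cl", "kdeg", "strength")]) %*% weights)
}

#' Homophily distance matrix
#'
#' Pairwise absolute fitness differences,
#' `Delta[i, j] = |fit(i) - fit(j)|`: small values mark the most similar
#' (most homophilic) pairs used to designate friends, large values the
#' most dissimilar ones used to fill foe lists.
#'
#' @param fit Fitness vector from [fitness()].
#' @return A symmetric, zero-diagonal `n x n` matrix.
#' @export
homophily_delta <- function(fit) {
  abs(outer(fit, fit, `-`))
}

#' Finalise a run for designation
#'
#' Convenience wrapper computing indicators, fitness and the homophily
#' matrix from a finished simulation.
#'
#' @param trace A [run_simulation()] trace.
#' @param weights Fitness weights, see [fitness()].
#' @return A list with `net`, `indicators`, `fit`, `delta`.
#' @export
finalize_run <- function(trace, weights = rep(1 / 4, 4)) {
  ind <- node_indicators(trace$net)
  fit <- fitness(ind, weights)
  list(net = trace$net, indicators = ind, fit = fit,
       delta = homophily_delta(fit))
}
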