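#' Agent states
#'
#' Per-agent state of the opinion dynamics: the private opinion `x`, the
#' public (apparent) opinion `y`, both in `[-1, 1]`, and the crowd
#' attitude `alpha` in `[-1, 1]`, fixed over a run (`alpha > 0` follows
#' the aggregated public information, `alpha < 0` opposes it).
#'
#' @param x,y,alpha Numeric vectors of equal length, entries in `[-1, 1]`.
#' @return An object of class `agent_states`.
#' @export
agent_states <- function(x, y, alpha) {
  n <- length(x)
  if (length(y) != n || length(alpha) != n) {
    stop("`x`, `y` and `alpha` must have equal length", call. = FALSE)
  }
  for (nm in c("x", "y", "alpha")) {
    v <- get(nm)
    if (any(!is.finite(v)) || any(abs(v) > 1)) {
      stop("`", nm, "` must lie in [-1, 1]", call. = FALSE)
    }
  }
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 alpha = as.numeric(alpha), n = n),
            class = "agent_states")
}

#' Disclosure matrix
#'
#' The signal an agent passes to each neighbour: a blend of its own
#' private opinion and the neighbour's public face,
#' `W[i, j] = tau * x_i + (1 - tau) * y_j` on linked pairs, zero
#' elsewhere. With `tau = 1` an agent broadcasts its private state; with
#' `tau = 0` it merely echoes the other's public position.
#'
#' @param states An [agent_states()] (the time `t - 1` state).
#' @param net A [signed_network()].
#' @param tau Openness in `[0, 1]`.
#' @return An `n x n` numeric matrix, zero on unlinked pairs.
#' @export
disclosure <- function(states, net, tau) {
  check_scalar(tau, "tau", lower = 0, upper = 1)
  if (states$n != net$n) {
    stop("state vector length (", states$n, ") does not match network size (",
         net$n, ")", call. = FALSE)
  }
  W <- outer(tau * states$x, (1 - tau) * states$y, `+`)
  W[!net_skeleton(net)] <- 0
  W
}

#' Public opinion update
#'
#' The apparent position each agent projects: the degree-normalised mean
#' of its row of the disclosure matrix (`"row"` convention) or of its
#' column (`"column"` convention). Isolated agents keep their previous
#' public opinion.
#'
#' @param W Disclosure matrix from [disclosure()].
#' @param net A [signed_network()].
#' @param y_prev Previous public opinion vector, used for degree-0 agents.
#' @param convention `"row"` or `"column"` (see [model_params()]).
#' @return Numeric vector `y` with `|y_i| <= 1` for bounded inputs.
#' @export
public_opinion <- function(W, net, y_prev = NULL,
                           convention = c("row", "column")) {
  convention <- match.arg(convention)
  k <- net_degree(net)
  tot <- if (convention == "row") rowSums(W) else colSums(W)
  y <- ifelse(k > 0, tot / pmax(k, 1), 0)
  if (any(k == 0)) {
    if (is.null(y_prev)) {
      stop("`y_prev` is required when isolated agents are present",
           call. = FALSE)
    }
    y[k == 0] <- y_prev[k == 0]
  }
  y
}

#' Short-range interaction field
#'
#' Sum of the signals an agent receives from its first neighbours:
#' `f_s(i) = sum_j W[j, i]` under the `"row"` convention (incoming
#' column), `sum_j W[i, j]` under `"column"`. Empty neighbourhoods give 0.
#'
#' @inheritParams public_opinion
#' @param i Optional agent index; by default the whole vector is returned.
#' @return Numeric vector (or scalar when `i` is given), `|f_s(i)| <= k_i`.
#' @export
short_range_field <- function(W, net, i = NULL,
                              convention = c("row", "column")) {
  convention <- match.arg(convention)
  fs <- if (convention == "row") colSums(W) else rowSums(W)
  if (is.null(i)) fs else fs[i]
}

#' Long-range interaction field
#'
#' Aggregated public information reaching an agent from beyond its direct
#' neighbourhood: every agent at hop distance `l` in `[2, l_max]`
#' contributes its public opinion damped linearly with distance,
#' `f_l(i) = sum y_j / l`. First neighbours and unreachable agents
#' contribute nothing.
#'
#' @param y Public opinion vector.
#' @param net A [signed_network()].
#' @param l_max `"diameter"` (include every reachable shell) or an
#'   integer `>= 2`.
#' @param i Optional agent index.
#' @param dist Optional precomputed [hop_distances()] matrix.
#' @return Numeric vector (or scalar when `i` is given).
#' @export
long_range_field <- function(y, net, l_max = "diameter", i = NULL,
                             dist = NULL) {
  if (is.null(dist)) dist <- hop_distances(net)
  lm <- if (identical(l_max, "diameter")) Inf else l_max
  if (!identical(lm, Inf)) check_scalar(lm, "l_max", lower = 2)
  w <- 1 / dist
  w[dist < 2 | dist > lm | !is.finite(dist)] <- 0
  fl <- as.vector(w %*% y)
  if (is.null(i)) fl else fl[i]
}

#' Link-growth kernel
#'
#' Symmetric function of the private and public opinions at a link's two
#' endpoints that drives the link weight up or down:
#' `T = |(x_i + x_j)/2 + 3 (y_i + y_j)/2| - 1`, ranging from -1 (full
#' disagreement) to 3 (full public and private agreement).
#'
#' @param x_i,x_j,y_i,y_j Opinions in `[-1, 1]`; vectorised.
#' @return The kernel value(s) in `[-1, 3]`.
#' @examples
#' link_kernel(1, 1, 1, 1)    # 3
#' link_kernel(1, -1, 1, -1)  # -1
#' @export
link_kernel <- function(x_i, x_j, y_i, y_j) {
  vals <- c(x_i, x_j, y_i, y_j)
  if (any(!is.finite(vals)) || any(abs(vals) > 1)) {
    stop("opinions must lie in [-1, 1]", call. = FALSE)
  }
  abs((x_i + x_j) / 2 + 3 * (y_i + y_j) / 2) - 1
}

#' One synchronous Euler step
#'
#' Advances states and link weights by `dt`. Everything is computed from
#' the time `t - 1` state: the disclosure matrix, the public opinions,
#' both interaction fields, then the private-opinion update
#' `x <- clip(x + (f_s |x| + alpha f_l) dt, -1, 1)` and the link update
#' `A <- A + D * T * dt` on every present link. The kernel is evaluated
#' once per unordered pair, so `A` stays exactly symmetric.
#'
#' @param states An [agent_states()].
#' @param net A [signed_network()].
#' @param params A [model_params()].
#' @param dist Optional precomputed hop-distance matrix for the current
#'   skeleton (recomputed when omitted).
#' @return A list with elements `states` and `net` at time `t`.
#' @export
euler_step <- function(states, net, params, dist = NULL) {
  W <- disclosure(states, net, params$tau)
  y_new <- public_opinion(W, net, y_prev = states$y,
                          convention = params$y_convention)
  fs <- short_range_field(W, net, convention = params$y_convention)
  fl <- long_range_field(states$y, net, l_max = params$l_max, dist = dist)

  x_new <- states$x + (fs * abs(states$x) + states$alpha * fl) * params$dt
  if (any(!is.finite(x_new))) {
    stop("non-finite private opinion encountered; dynamics diverged",
         call. = FALSE)
  }
  x_new <- pmin(pmax(x_new, -1), 1)
  y_new <- pmin(pmax(y_new, -1), 1)

  Tk <- abs(outer(states$x, states$x, `+`) / 2 +
              3 * outer(states$y, states$y, `+`) / 2) - 1
  A <- net$A
  A[net$L] <- A[net$L] + params$D * Tk[net$L] * params$dt

  list(states = agent_states(x_new, y_new, states$alpha),
       net = signed_network(A, net$L))
}

#' Rewire the network after a check window
#'
#' Counts the links whose weight is negative now but was non-negative at
#' the previous check, and adds the same number of fresh links of weight
#' `new_link_weight` between currently unlinked pairs, preferring the
#' pair with the lowest degree sum (ties broken at random). Hostile links
#' are never removed; they keep evolving and mark the real enemies.
#'
#' @param net A [signed_network()].
#' @param prev_A Weight matrix snapshot at the previous rewiring check.
#' @param new_link_weight Weight of the added links.
#' @return A list: `net` (rewired network), `n_newly_negative`, and
#'   `added` (two-column matrix of new link endpoints).
#' @export
rewire <- function(net, prev_A, new_link_weight = 1) {
  up <- upper.tri(net$A)
  newly_neg <- net$L & up & net$A < 0 & prev_A >= 0
  m <- sum(newly_neg)
  added <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  if (m == 0) {
    return(list(net = net, n_newly_negative = 0L, added = added))
  }
  A <- net$A
  L <- net$L
  deg <- as.integer(rowSums(L & A != 0))
  for (r in seq_len(m)) {
    open <- which(!L & up, arr.ind = TRUE)
    if (nrow(open) == 0) {
      warning("no unlinked pairs left; added ", r - 1L, " of ", m,
              " replacement links", call. = FALSE)
      break
    }
    score <- deg[open[, 1]] + deg[open[, 2]]
    best <- which(score == min(score))
    pick <- if (length(best) == 1) best else best[sample.int(length(best), 1)]
    i <- open[pick, 1]; j <- open[pick, 2]
    A[i, j] <- A[j, i] <- new_link_weight
    L[i, j] <- L[j, i] <- TRUE
    deg[c(i, j)] <- deg[c(i, j)] + 1L
    added <- rbind(added, c(i, j))
  }
  list(net = signed_network(A, L), n_newly_negative = as.integer(m),
       added = added)
}

#' Run the coupled opinion/link simulation
#'
#' Initialises private and public opinions and the crowd attitudes
#' uniformly on `[-1, 1]`, draws the random acquaintance network, then
#' iterates [euler_step()] for `n_steps` iterations with [rewire()] every
#' `rewire_interval` iterations. Identical parameters and seed give a
#' bit-identical trace.
#'
#' @param params A [model_params()].
#' @return An object of class `simulation_trace`: `params`, `alpha`,
#'   `snapshots` (list of `iteration`, `x`, `y`, `A` records at the
#'   configured stride, first entry the initial condition), `rewire_events`
#'   (data frame with `iteration`, `n_newly_negative`, `links_added`),
#'   `states` and `net` (final), and `n_links` (final active link count).
#' @examples
#' tr <- run_simulation(model_params(n = 10, k_avg = 3, n_steps = 100,
#'                                   seed = 42))
#' max(abs(tr$states$x))
#' @export
run_simulation <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n
  net <- init_random_network(n, params$k_avg)
  states <- agent_states(x = stats::runif(n, -1, 1),
                         y = stats::runif(n, -1, 1),
                         alpha = stats::runif(n, -1, 1))

  snapshots <- list(list(iteration = 0L, x = states$x, y = states$y,
                         A = net$A))
  rewire_events <- list()
  prev_A <- net$A
  skel <- net_skeleton(net)
  dist <- hop_distances(skel)

  for (it in seq_len(params$n_steps)) {
    stepped <- euler_step(states, net, params, dist = dist)
    states <- stepped$states
    net <- stepped$net

    if (it %% params$rewire_interval == 0) {
      rw <- rewire(net, prev_A, params$new_link_weight)
      net <- rw$net
      rewire_events[[length(rewire_events) + 1L]] <-
        data.frame(iteration = it,
                   n_newly_negative = rw$n_newly_negative,
                   links_added = nrow(rw$added))
      prev_A <- net$A
    }

    new_skel <- net_skeleton(net)
    if (!identical(new_skel, skel)) {
      skel <- new_skel
      dist <- hop_distances(skel)
    }

    if (it %% params$record_stride == 0 || it == params$n_steps) {
      snapshots[[length(snapshots) + 1L]] <-
        list(iteration = it, x = states$x, y = states$y, A = net$A)
    }
  }

  structure(
    list(params = params, alpha = states$alpha, snapshots = snapshots,
         rewire_events = if (length(rewire_events))
           do.call(rbind, rewire_events)
         else data.frame(iteration = integer(0),
                         n_newly_negative = integer(0),
                         links_added = integer(0)),
         states = states, net = net,
         n_links = sum(net_skeleton(net)) / 2),
    class = "simulation_trace"
  )
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat("Simulation trace:", x$params$n, "agents,", x$params$n_steps,
      "iterations\n")
  cat("  final links:", x$n_links, "(", sum(x$net$A < 0) / 2, "negative )\n")
  cat("  rewiring events:", nrow(x$rewire_events), "; links added:",
      sum(x$rewire_events$links_added), "\n")
  invisible(x)
}

#' Per-link weight time series from a trace
#'
#' Long-format history of every recorded link weight, the numerical
#' analogue of plotting each link's weight against time.
#'
#' @param trace A [run_simulation()] trace.
#' @return A data frame with columns `iteration`, `i`, `j`, `weight`,
#'   one row per present link per recorded snapshot.
#' @export
link_weight_history <- function(trace) {
  L <- trace$net$L
  up <- which(L & upper.tri(L), arr.ind = TRUE)
  do.call(rbind, lapply(trace$snapshots, function(s) {
    data.frame(iteration = s$iteration, i = up[, 1], j = up[, 2],
               weight = s$A[cbind(up[, 1], up[, 2])])
  }))
}
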