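#' Simulation parameters
#'
#' Bundle and validate every scalar knob of the coupled opinion/link
#' dynamics. The defaults reproduce the reference study conditions for a
#' school-class-sized group: 25 agents, mean degree 6, openness
#' `tau = 0.8`, Euler step `dt = 0.002`, 5000 iterations with rewiring
#' every 50 iterations.
#'
#' @param n Number of agents (at least 2).
#' @param k_avg Target mean degree of the initial random network,
#'   `0 < k_avg <= n - 1`. The initial link count is
#'   `floor(n * k_avg / 2)`.
#' @param tau Openness: the fraction of the private opinion an agent
#'   discloses to a neighbour, in `[0, 1]`.
#' @param D Time-scale constant of the linear link-weight growth (positive).
#' @param dt Euler time step (positive).
#' @param n_steps Number of Euler iterations.
#' @param rewire_interval Iterations between rewiring events.
#' @param l_max Longest hop distance contributing to the long-range field:
#'   either the string `"diameter"` (every reachable shell at distance two
#'   or more contributes) or a fixed integer `>= 2`.
#' @param new_link_weight Weight assigned to links created by rewiring.
#' @param y_convention Orientation convention for the disclosure matrix
#'   `W`: under `"row"` (default) the public opinion of agent `i` is the
#'   mean of row `i` of `W` (the signals `i` emits) and the short-range
#'   field sums the incoming column `W[j, i]`; `"column"` swaps the two
#'   readings.
#' @param record_stride Record a state/network snapshot every this many
#'   iterations (the initial and final states are always recorded).
#' @param seed Optional RNG seed; runs with the same seed are identical.
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params(n = 25, k_avg = 6, tau = 0.8, n_steps = 200, seed = 1)
#' p$tau
#' @export
model_params <- function(n = 25, k_avg = 6, tau = 0.8, D = 1, dt = 0.002,
                         n_steps = 5000, rewire_interval = 50,
                         l_max = "diameter", new_link_weight = 1,
                         y_convention = c("row", "column"),
                         record_stride = 50, seed = NULL) {
  y_convention <- match.arg(y_convention)
  check_scalar(n, "n", lower = 2, integer = TRUE)
  check_scalar(k_avg, "k_avg", lower = 0, upper = n - 1, strict_lower = TRUE)
  check_scalar(tau, "tau", lower = 0, upper = 1)
  check_scalar(D, "D", lower = 0, strict_lower = TRUE)
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  check_scalar(n_steps, "n_steps", lower = 0, integer = TRUE)
  check_scalar(rewire_interval, "rewire_interval", lower = 1, integer = TRUE)
  check_scalar(record_stride, "record_stride", lower = 1, integer = TRUE)
  check_scalar(new_link_weight, "new_link_weight")
  if (is.character(l_max)) {
    if (!identical(l_max, "diameter")) {
      stop("`l_max` must be \"diameter\" or an integer >= 2, got \"",
           l_max, "\"", call. = FALSE)
    }
  } else {
    check_scalar(l_max, "l_max", lower = 2, integer = TRUE)
  }
  if (!is.null(seed)) check_scalar(seed, "seed", integer = TRUE)

  structure(
    list(n = as.integer(n), k_avg = k_avg, tau = tau, D = D, dt = dt,
         n_steps = as.integer(n_steps),
         rewire_interval = as.integer(rewire_interval),
         l_max = l_max, new_link_weight = new_link_weight,
         y_convention = y_convention,
         record_stride = as.integer(record_stride),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "model_params"
  )
}

# Scalar validation with messages that name the offending field and bound.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  if (integer && x != round(x)) {
    stop("`", name, "` must be an integer, got ", x, call. = FALSE)
  }
  if (strict_lower) {
    if (x <= lower) {
      stop("`", name, "` must be > ", lower, ", got ", x, call. = FALSE)
    }
  } else if (x < lower) {
    stop("`", name, "` must be >= ", lower, ", got ", x, call. = FALSE)
  }
  if (x > upper) {
    stop("`", name, "` must be <= ", upper, ", got ", x, call. = FALSE)
  }
  invisible(x)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model parameters (", x$n, " agents)\n", sep = "")
  cat(sprintf("  k_avg = %g, tau = %g, D = %g, dt = %g\n",
              x$k_avg, x$tau, x$D, x$dt))
  cat(sprintf("  n_steps = %d, rewire every %d, l_max = %s\n",
              x$n_steps, x$rewire_interval, format(x$l_max)))
  cat(sprintf("  y convention = %s, seed = %s\n", x$y_convention,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}
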