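# sample() on a length-1 vector would draw from 1:x; this always treats
# `x` as the candidate set.
sample_vec <- function(x, size = length(x)) x[sample.int(length(x), size)]

#' Specification of a synthetic mention-network fixture
#'
#' Describes the shape of a survey outcome without running the opinion
#' dynamics, so the summary-statistics layer can be exercised on data
#' with known properties. `"quota"` style mimics a forced-choice survey
#' (every agent emits exactly `q` mentions of each type); `"threshold"`
#' style mimics free choice with variable out-degrees, a controllable
#' fraction of agents untouched by foe mentions, and optional
#' reciprocity targets. The free-choice defaults follow the empirical
#' regime of classroom surveys: about 4.7 friend nominations per
#' respondent, about one foe nomination, and roughly half the class
#' never named a foe.
#'
#' @param n Number of agents.
#' @param protocol_style `"quota"` or `"threshold"`.
#' @param q Mentions per type and agent (quota style), `2q <= n - 1`.
#' @param friend_mean_out,foe_mean_out Mean out-degrees (threshold
#'   style); per-agent out-degrees are Poisson draws capped at `n - 1`.
#' @param reciprocity Optional target fraction of edges in mutual dyads,
#'   applied per type, achieved within 0.05 where feasible.
#' @param zero_foe_fraction Optional fraction of agents with no foe
#'   mentions, in or out (threshold style), realised within one agent.
#' @param seed Optional RNG seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n = 25, protocol_style = c("quota", "threshold"),
                         q = 4, friend_mean_out = 4.7, foe_mean_out = 1,
                         reciprocity = NULL, zero_foe_fraction = NULL,
                         seed = NULL) {
  protocol_style <- match.arg(protocol_style)
  check_scalar(n, "n", lower = 3, integer = TRUE)
  check_scalar(q, "q", lower = 1, integer = TRUE)
  if (protocol_style == "quota" && 2 * q > n - 1) {
    stop("`q` infeasible: need 2 * q <= n - 1", call. = FALSE)
  }
  if (!is.null(reciprocity)) {
    check_scalar(reciprocity, "reciprocity", lower = 0, upper = 1)
  }
  if (!is.null(zero_foe_fraction)) {
    check_scalar(zero_foe_fraction, "zero_foe_fraction", lower = 0, upper = 1)
  }
  check_scalar(friend_mean_out, "friend_mean_out", lower = 0)
  check_scalar(foe_mean_out, "foe_mean_out", lower = 0)
  structure(list(n = as.integer(n), protocol_style = protocol_style,
                 q = as.integer(q), friend_mean_out = friend_mean_out,
                 foe_mean_out = foe_mean_out, reciprocity = reciprocity,
                 zero_foe_fraction = zero_foe_fraction, seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic mention network
#'
#' @param spec A [fixture_spec()].
#' @return A [mention_network()] honouring the spec: exact out-degrees
#'   under quota style, the requested zero-foe agent count within one
#'   agent, and any reciprocity target within 0.05 where feasible.
#' @examples
#' mn <- generate_fixture(fixture_spec(n = 25, q = 4, seed = 1))
#' nrow(mn$edges) # 200
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n

  if (spec$protocol_style == "quota") {
    friend_sets <- vector("list", n)
    foe_sets <- vector("list", n)
    for (i in seq_len(n)) {
      pick <- sample_vec(setdiff(seq_len(n), i), 2 * spec$q)
      friend_sets[[i]] <- pick[seq_len(spec$q)]
      foe_sets[[i]] <- pick[spec$q + seq_len(spec$q)]
    }
    if (!is.null(spec$reciprocity)) {
      friend_sets <- tune_reciprocity(friend_sets, spec$reciprocity,
                                      forbidden = foe_sets,
                                      allowed_targets = seq_len(n))
      foe_sets <- tune_reciprocity(foe_sets, spec$reciprocity,
                                   forbidden = friend_sets,
                                   allowed_targets = seq_len(n))
    }
  } else {
    zf <- if (is.null(spec$zero_foe_fraction)) 0 else spec$zero_foe_fraction
    n_zero <- round(zf * n)
    if (n_zero > n - 2 && zf < 1) n_zero <- n - 2
    zero_set <- if (n_zero > 0) sample_vec(seq_len(n), n_zero) else integer(0)
    active <- setdiff(seq_len(n), zero_set)

    friend_out <- pmin(stats::rpois(n, spec$friend_mean_out), n - 1)
    friend_sets <- lapply(seq_len(n), function(i) {
      sample_vec(setdiff(seq_len(n), i), friend_out[i])
    })

    foe_sets <- rep(list(integer(0)), n)
    if (length(active) >= 2) {
      foe_out <- integer(n)
      foe_out[active] <- pmin(stats::rpois(length(active),
                                           spec$foe_mean_out),
                              length(active) - 1)
      # give every active agent at least one incoming foe mention, then
      # spend the remaining capacity at random
      need <- sample_vec(active)
      capacity <- foe_out
      for (tgt in need) {
        src <- active[capacity[active] > 0 & active != tgt]
        if (length(src) == 0) {
          src_all <- active[active != tgt]
          src <- src_all[sample.int(length(src_all), 1)]
          capacity[src] <- capacity[src] # out-degree bumped below
          foe_out[src] <- foe_out[src] + 1L
        } else {
          src <- src[sample.int(length(src), 1)]
          capacity[src] <- capacity[src] - 1L
        }
        foe_sets[[src]] <- c(foe_sets[[src]], tgt)
      }
      for (i in active) {
        extra <- foe_out[i] - length(foe_sets[[i]])
        if (extra > 0) {
          cand <- setdiff(active, c(i, foe_sets[[i]]))
          foe_sets[[i]] <- c(foe_sets[[i]],
                             sample_vec(cand, min(extra, length(cand))))
        }
      }
    }
    # friend/foe disjointness per source
    for (i in seq_len(n)) {
      friend_sets[[i]] <- setdiff(friend_sets[[i]], foe_sets[[i]])
    }
    if (!is.null(spec$reciprocity)) {
      friend_sets <- tune_reciprocity(friend_sets, spec$reciprocity,
                                      forbidden = foe_sets,
                                      allowed_targets = seq_len(n))
      foe_sets <- tune_reciprocity(foe_sets, spec$reciprocity,
                                   forbidden = friend_sets,
                                   allowed_targets = active,
                                   allowed_sources = active)
    }
  }

  to_edges <- function(sets, type) {
    src <- rep(seq_len(n), lengths(sets))
    data.frame(source = src, target = unlist(sets),
               type = rep(type, length(src)))
  }
  edges <- rbind(to_edges(friend_sets, "friend"), to_edges(foe_sets, "foe"))
  mention_network(edges, n = n, protocol = spec$protocol_style,
                  params = unclass(spec))
}

# Local-search repair of out-neighbour sets toward a reciprocity target.
# Out-degrees are preserved; `forbidden[[i]]` lists targets i must avoid
# (the other mention type), `allowed_targets`/`allowed_sources` restrict
# the agents that may receive/emit edges of this type.
tune_reciprocity <- function(sets, target, forbidden,
                             allowed_targets, allowed_sources = NULL,
                             tol = 0.05) {
  n <- length(sets)
  if (is.null(allowed_sources)) allowed_sources <- seq_len(n)
  frac <- function(sets) {
    e <- sum(lengths(sets))
    if (e == 0) return(0)
    mut <- 0
    for (i in seq_len(n)) {
      for (j in sets[[i]]) if (j > i && i %in% sets[[j]]) mut <- mut + 1
    }
    2 * mut / e
  }
  cur <- frac(sets)
  total <- sum(lengths(sets))
  if (total == 0) return(sets)
  max_iter <- 60L * total
  it <- 0L
  while (abs(cur - target) > tol && it < max_iter) {
    it <- it + 1L
    moved <- FALSE
    order_i <- sample_vec(allowed_sources)
    if (cur < target) {
      # move A: reciprocate an unreturned i -> j by letting j redirect a
      # non-mutual out-edge back to i
      for (i in order_i) {
        for (j in sample_vec(sets[[i]])) {
          if (i %in% sets[[j]] || !(j %in% allowed_sources)) next
          if (i %in% forbidden[[j]] || !(i %in% allowed_targets)) next
          drop <- setdiff(sets[[j]], i)
          drop <- drop[!vapply(drop, function(k) j %in% sets[[k]],
                               logical(1))]
          if (length(drop) == 0) next
          k <- drop[sample.int(length(drop), 1)]
          sets[[j]] <- c(setdiff(sets[[j]], k), i)
          moved <- TRUE
          break
        }
        if (moved) break
      }
      # move B: two sources each holding a redirectable non-mutual
      # out-edge point them at each other, forming a fresh mutual dyad
      if (!moved) {
        droppable <- function(i) {
          d <- sets[[i]][!vapply(sets[[i]], function(k) i %in% sets[[k]],
                                 logical(1))]
          d
        }
        frustrated <- order_i[vapply(order_i, function(i)
          length(droppable(i)) > 0, logical(1))]
        frustrated <- intersect(frustrated, allowed_targets)
        for (i in frustrated) {
          for (j in setdiff(frustrated, c(i, sets[[i]], forbidden[[i]]))) {
            if (i %in% c(sets[[j]], forbidden[[j]])) next
            ki <- sample_vec(droppable(i), 1)
            kj <- sample_vec(droppable(j), 1)
            sets[[i]] <- c(setdiff(sets[[i]], ki), j)
            sets[[j]] <- c(setdiff(sets[[j]], kj), i)
            moved <- TRUE
            break
          }
          if (moved) break
        }
      }
    } else {
      # break a mutual dyad: redirect j -> i to a fresh non-mutual target
      for (i in order_i) {
        for (j in sample_vec(sets[[i]])) {
          if (!(i %in% sets[[j]]) || !(j %in% allowed_sources)) next
          cand <- setdiff(allowed_targets, c(j, sets[[j]], forbidden[[j]]))
          cand <- cand[!vapply(cand, function(k) j %in% sets[[k]],
                               logical(1))]
          if (length(cand) == 0) next
          k <- cand[sample.int(length(cand), 1)]
          sets[[j]] <- c(setdiff(sets[[j]], i), k)
          moved <- TRUE
          break
        }
        if (moved) break
      }
    }
    if (!moved) break
    cur <- frac(sets)
  }
  if (abs(cur - target) > tol) {
    warning(sprintf(
      "reciprocity target %.2f not reachable; realised %.2f", target, cur),
      call. = FALSE)
  }
  sets
}
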