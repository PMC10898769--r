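#' Directed friend/foe mention network
#'
#' The outcome of a sociometric survey: directed, typed nomination edges.
#' Self-mentions are forbidden and a respondent never names the same
#' classmate both friend and foe.
#'
#' @param edges Data frame with integer columns `source`, `target` and a
#'   character column `type` (`"friend"` or `"foe"`).
#' @param n Number of agents.
#' @param agents Optional character agent identifiers (length `n`);
#'   defaults to `"a1" ... "an"`.
#' @param protocol Provenance tag, e.g. `"quota"` or `"threshold"`.
#' @param params Named list of protocol parameters (provenance only).
#' @return An object of class `mention_network`.
#' @export
mention_network <- function(edges, n, agents = NULL, protocol = NA_character_,
                            params = list()) {
  stopifnot(is.data.frame(edges),
            all(c("source", "target", "type") %in% names(edges)))
  edges <- data.frame(source = as.integer(edges$source),
                      target = as.integer(edges$target),
                      type = as.character(edges$type))
  if (nrow(edges)) {
    if (any(!edges$type %in% c("friend", "foe"))) {
      stop("edge `type` must be \"friend\" or \"foe\"", call. = FALSE)
    }
    bad <- which(edges$source == edges$target)
    if (length(bad)) {
      stop("self-mention in edge row(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(edges$source < 1 | edges$source > n |
            edges$target < 1 | edges$target > n)) {
      stop("edge endpoints must lie in 1..n", call. = FALSE)
    }
    key <- paste(edges$source, edges$target, edges$type)
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop("duplicate mention in edge row(s) ", paste(dup, collapse = ", "),
           call. = FALSE)
    }
    pair <- paste(edges$source, edges$target)
    both <- intersect(pair[edges$type == "friend"],
                      pair[edges$type == "foe"])
    if (length(both)) {
      stop("pair(s) mentioned as both friend and foe: ",
           paste(both, collapse = "; "), call. = FALSE)
    }
  }
  if (is.null(agents)) agents <- paste0("a", seq_len(n))
  stopifnot(length(agents) == n)
  structure(list(n = as.integer(n), agents = as.character(agents),
                 edges = edges, protocol = protocol, params = params),
            class = "mention_network")
}

#' @export
print.mention_network <- function(x, ...) {
  cat("Mention network (", x$protocol, " protocol): ", x$n, " agents, ",
      sum(x$edges$type == "friend"), " friend / ",
      sum(x$edges$type == "foe"), " foe mentions\n", sep = "")
  invisible(x)
}

#' Fixed-quota designation (forced-choice protocol)
#'
#' Emulates a survey where every respondent must name exactly `q` friends
#' and `q` foes. Foes of agent `i` are its negative bonds, most negative
#' first, truncated at `q`; when fewer than `q` negative bonds exist the
#' list is completed with the classmates of largest homophily distance
#' not already designated. Friends are the `q` classmates of smallest
#' homophily distance among those not designated foes, so the two lists
#' stay disjoint. Ties are broken at random.
#'
#' @param delta Homophily matrix from [homophily_delta()].
#' @param net A [signed_network()] (final bond weights).
#' @param q Mentions per type; requires `2 * q <= n - 1`.
#' @param seed Optional RNG seed for tie-breaking.
#' @return A [mention_network()] in which every agent has friend and foe
#'   out-degree exactly `q`.
#' @export
designate_fixed_quota <- function(delta, net, q = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(delta)
  check_scalar(q, "q", lower = 1, integer = TRUE)
  if (2 * q > n - 1) {
    stop("quota infeasible: need 2 * q <= n - 1 to keep friend and foe ",
         "lists disjoint (q = ", q, ", n = ", n, ")", call. = FALSE)
  }
  A <- net$A * net$L
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    tie <- stats::runif(n)
    # foes from concrete negative bonds, most negative first
    neg <- others[A[i, others] < 0]
    neg <- neg[order(A[i, neg], tie[neg])]
    foes <- utils::head(neg, q)
    # friends: smallest homophily distance among non-foes
    cand <- setdiff(others, foes)
    friends <- cand[order(delta[i, cand], tie[cand])][seq_len(q)]
    # fill foes with the most dissimilar remaining classmates
    if (length(foes) < q) {
      fill_cand <- setdiff(others, c(friends, foes))
      fill <- fill_cand[order(-delta[i, fill_cand], tie[fill_cand])]
      foes <- c(foes, utils::head(fill, q - length(foes)))
    }
    rows[[i]] <- data.frame(
      source = i, target = c(friends, foes),
      type = rep(c("friend", "foe"), c(length(friends), length(foes))))
  }
  mention_network(do.call(rbind, rows), n = n, protocol = "quota",
                  params = list(q = q, seed = seed))
}

#' Threshold set for the personal-criterion protocol
#'
#' @param beta1 Friend threshold on the homophily distance.
#' @param beta2 Foe threshold on the bond weight.
#' @param p1,p2 Percentiles that produced `beta1` / `beta2`.
#' @param eps_halfwidth Half-width of the per-agent uniform noise added
#'   to both thresholds (one draw per agent).
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(beta1, beta2, p1 = NA_real_, p2 = NA_real_,
                          eps_halfwidth = 0.5) {
  check_scalar(beta1, "beta1")
  check_scalar(beta2, "beta2")
  check_scalar(eps_halfwidth, "eps_halfwidth", lower = 0)
  structure(list(beta1 = beta1, beta2 = beta2, p1 = p1, p2 = p2,
                 eps_halfwidth = eps_halfwidth),
            class = "threshold_set")
}

#' Calibrate designation thresholds on an ensemble of runs
#'
#' Pools the upper-triangle homophily distances of every run and sets
#' `beta1` at their `p1`-th percentile; pools every present final bond
#' weight and sets `beta2` at their `p2`-th percentile. Percentiles use
#' linear interpolation of order statistics ([stats::quantile()] type 7).
#'
#' @param runs List of finalised runs from [finalize_run()] (each with
#'   elements `delta` and `net`).
#' @param p1 Percentile for the friend threshold (default 12).
#' @param p2 Percentile for the foe threshold (default 30).
#' @param eps_halfwidth Per-agent threshold noise half-width (default 0.5).
#' @param beta2_pool `"all"` pools every present link weight;
#'   `"negative_only"` restricts the pool to hostile links.
#' @return A [threshold_set()].
#' @export
calibrate_thresholds <- function(runs, p1 = 12, p2 = 30,
                                 eps_halfwidth = 0.5,
                                 beta2_pool = c("all", "negative_only")) {
  beta2_pool <- match.arg(beta2_pool)
  check_scalar(p1, "p1", lower = 0, upper = 100)
  check_scalar(p2, "p2", lower = 0, upper = 100)
  if (length(runs) == 0) stop("empty calibration ensemble", call. = FALSE)
  delta_pool <- unlist(lapply(runs, function(r) r$delta[upper.tri(r$delta)]))
  a_pool <- unlist(lapply(runs, function(r) {
    w <- r$net$A[r$net$L & upper.tri(r$net$A) & r$net$A != 0]
    if (beta2_pool == "negative_only") w[w < 0] else w
  }))
  if (length(delta_pool) == 0 || length(a_pool) == 0) {
    stop("empty calibration pool", call. = FALSE)
  }
  threshold_set(beta1 = pool_percentile(delta_pool, p1),
                beta2 = pool_percentile(a_pool, p2),
                p1 = p1, p2 = p2, eps_halfwidth = eps_halfwidth)
}

#' Percentile of a pooled sample
#'
#' Linear interpolation of order statistics: `p = 0` gives the pool
#' minimum, `p = 100` the maximum (the convention of
#' [stats::quantile()] type 7).
#'
#' @param pool Numeric vector.
#' @param p Percentile in `[0, 100]`.
#' @return The interpolated percentile value.
#' @examples
#' pool_percentile(1:10, 30) # 3.7
#' @export
pool_percentile <- function(pool, p) {
  if (length(pool) == 0) stop("empty pool", call. = FALSE)
  check_scalar(p, "p", lower = 0, upper = 100)
  unname(stats::quantile(pool, probs = p / 100, type = 7, names = FALSE))
}

#' Personal-threshold designation (free-choice protocol)
#'
#' Emulates a survey where each respondent applies their own cutoff. A
#' shared per-agent noise term `eps_i`, uniform on
#' `[-eps_halfwidth, eps_halfwidth]`, shifts both calibrated thresholds:
#' agent `i` names `j` a friend when `delta[i, j] < beta1 + eps_i` and a
#' foe when the bond `A[i, j]` exists and `A[i, j] < beta2 + eps_i`. A
#' classmate satisfying both conditions is recorded as a foe (hostile
#' bonds reflect concrete negative interactions). Out-degrees vary by
#' agent and may be zero.
#'
#' @param delta Homophily matrix.
#' @param net A [signed_network()].
#' @param thresholds A [threshold_set()].
#' @param seed Optional RNG seed for the noise draws.
#' @return A [mention_network()].
#' @export
designate_threshold <- function(delta, net, thresholds, seed = NULL) {
  stopifnot(inherits(thresholds, "threshold_set"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(delta)
  hw <- thresholds$eps_halfwidth
  eps <- stats::runif(n, -hw, hw)
  A <- net$A
  linked <- net_skeleton(net)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    foes <- others[linked[i, others] & A[i, others] < thresholds$beta2 + eps[i]]
    friends <- others[delta[i, others] < thresholds$beta1 + eps[i]]
    friends <- setdiff(friends, foes)
    if (length(friends) + length(foes) == 0) next
    rows[[i]] <- data.frame(
      source = i, target = c(friends, foes),
      type = rep(c("friend", "foe"), c(length(friends), length(foes))))
  }
  edges <- if (all(vapply(rows, is.null, logical(1)))) {
    data.frame(source = integer(0), target = integer(0),
               type = character(0))
  } else {
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }
  mention_network(edges, n = n, protocol = "threshold",
                  params = list(beta1 = thresholds$beta1,
                                beta2 = thresholds$beta2,
                                eps_halfwidth = hw, seed = seed))
}
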