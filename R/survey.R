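#' Mentions received per agent
#'
#' In-degree by mention type: the survey response variable is the summed
#' number of times each class member is listed as friend or foe by the
#' whole group.
#'
#' @param mn A [mention_network()].
#' @return Data frame with columns `agent`, `friend_in`, `foe_in`
#'   (zero for unmentioned agents).
#' @export
mention_counts <- function(mn) {
  stopifnot(inherits(mn, "mention_network"))
  count_type <- function(type) {
    tabulate(mn$edges$target[mn$edges$type == type], nbins = mn$n)
  }
  data.frame(agent = seq_len(mn$n),
             friend_in = count_type("friend"),
             foe_in = count_type("foe"))
}

#' Cumulative distribution of mention counts
#'
#' Relative accumulated frequency: for each observed count value `v`,
#' the fraction of agents that received at most `v` mentions. The table
#' is a non-decreasing, right-continuous step function ending at 1.
#'
#' @param counts Integer vector of per-agent mention counts.
#' @return Data frame with columns `value` and `cum_freq`.
#' @examples
#' cumulative_distribution(c(0, 0, 1, 2))
#' @export
cumulative_distribution <- function(counts) {
  if (length(counts) == 0) stop("empty count vector", call. = FALSE)
  v <- sort(unique(counts))
  data.frame(value = v,
             cum_freq = vapply(v, function(z) mean(counts <= z), numeric(1)))
}

#' Reciprocity of a mention network
#'
#' Counts, per type, the unordered pairs that name each other in kind
#' (both `i -> j` and `j -> i` of the same type). The fraction is the
#' share of edges of that type sitting in a mutual dyad.
#'
#' @param mn A [mention_network()].
#' @return Data frame with columns `type`, `edges`, `mutual_pairs`,
#'   `fraction`.
#' @export
reciprocity_summary <- function(mn) {
  stopifnot(inherits(mn, "mention_network"))
  per_type <- lapply(c(friend = "friend", foe = "foe"), function(tp) {
    e <- mn$edges[mn$edges$type == tp, , drop = FALSE]
    m <- nrow(e)
    if (m == 0) return(c(edges = 0, mutual = 0, fraction = 0))
    fwd <- paste(e$source, e$target)
    rev <- paste(e$target, e$source)
    mutual <- sum(fwd %in% rev) / 2
    c(edges = m, mutual = mutual, fraction = 2 * mutual / m)
  })
  data.frame(type = names(per_type),
             edges = vapply(per_type, `[[`, numeric(1), "edges"),
             mutual_pairs = vapply(per_type, `[[`, numeric(1), "mutual"),
             fraction = vapply(per_type, `[[`, numeric(1), "fraction"),
             row.names = NULL)
}

#' Survey summary of a mention network
#'
#' Bundles the per-agent in-mention counts, the cumulative distribution
#' per type, reciprocity, the fraction of agents with zero mentions, and
#' the maximum mention count per type.
#'
#' @param mn A [mention_network()].
#' @return An object of class `survey_summary`.
#' @export
survey_summary <- function(mn) {
  counts <- mention_counts(mn)
  structure(
    list(protocol = mn$protocol,
         n_agents = mn$n,
         counts = counts,
         cdf = list(friend = cumulative_distribution(counts$friend_in),
                    foe = cumulative_distribution(counts$foe_in)),
         reciprocity = reciprocity_summary(mn),
         zero_fraction = c(friend = mean(counts$friend_in == 0),
                           foe = mean(counts$foe_in == 0)),
         max_mentions = c(friend = max(counts$friend_in),
                          foe = max(counts$foe_in))),
    class = "survey_summary"
  )
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("Survey summary (", x$protocol, "), ", x$n_agents, " agents\n",
      sep = "")
  cat(sprintf("  mean mentions received: friend %.2f, foe %.2f\n",
              mean(x$counts$friend_in), mean(x$counts$foe_in)))
  cat(sprintf("  zero-mention fraction:  friend %.2f, foe %.2f\n",
              x$zero_fraction["friend"], x$zero_fraction["foe"]))
  cat(sprintf("  reciprocity fraction:   friend %.2f, foe %.2f\n",
              x$reciprocity$fraction[x$reciprocity$type == "friend"],
              x$reciprocity$fraction[x$reciprocity$type == "foe"]))
  invisible(x)
}

#' Pool mention networks across simulation runs
#'
#' Concatenates the per-agent in-mention counts of several runs of the
#' same protocol before forming the cumulative distributions, the way an
#' ensemble of simulated classrooms is compared with data pooled over
#' real classrooms.
#'
#' @param runs List of [mention_network()] objects sharing a protocol.
#' @return A `survey_summary` over the pooled agents; its `reciprocity`
#'   aggregates mutual pairs and edges across runs.
#' @export
ensemble_summary <- function(runs) {
  if (length(runs) == 0) stop("empty ensemble", call. = FALSE)
  protos <- unique(vapply(runs, function(r) as.character(r$protocol),
                          character(1)))
  if (length(protos) > 1) {
    stop("cannot pool mixed protocols: ", paste(protos, collapse = ", "),
         call. = FALSE)
  }
  counts <- do.call(rbind, lapply(runs, mention_counts))
  recips <- lapply(runs, reciprocity_summary)
  pool_rec <- do.call(rbind, recips)
  rec <- do.call(rbind, lapply(c("friend", "foe"), function(tp) {
    d <- pool_rec[pool_rec$type == tp, , drop = FALSE]
    data.frame(type = tp, edges = sum(d$edges),
               mutual_pairs = sum(d$mutual_pairs),
               fraction = if (sum(d$edges) > 0)
                 2 * sum(d$mutual_pairs) / sum(d$edges) else 0)
  }))
  row.names(rec) <- NULL
  structure(
    list(protocol = protos, n_agents = nrow(counts), counts = counts,
         cdf = list(friend = cumulative_distribution(counts$friend_in),
                    foe = cumulative_distribution(counts$foe_in)),
         reciprocity = rec,
         zero_fraction = c(friend = mean(counts$friend_in == 0),
                           foe = mean(counts$foe_in == 0)),
         max_mentions = c(friend = max(counts$friend_in),
                          foe = max(counts$foe_in))),
    class = "survey_summary"
  )
}

#' Kolmogorov-Smirnov distance between two count distributions
#'
#' Supremum over the merged support of the absolute difference of the
#' two cumulative step functions (no continuity correction): a
#' quantitative counterpart to overlaying two mention-count CDFs.
#'
#' @param F1,F2 CDF tables from [cumulative_distribution()].
#' @return The KS statistic in `[0, 1]`.
#' @export
distribution_distance <- function(F1, F2) {
  if (nrow(F1) == 0 || nrow(F2) == 0) stop("empty CDF table", call. = FALSE)
  support <- sort(unique(c(F1$value, F2$value)))
  eval_cdf <- function(tab, v) {
    idx <- findInterval(v, tab$value)
    ifelse(idx == 0, 0, tab$cum_freq[pmax(idx, 1)])
  }
  max(abs(eval_cdf(F1, support) - eval_cdf(F2, support)))
}

#' Mean local clustering of one mention type
#'
#' Local clustering coefficient averaged over all agents (isolates count
#' as zero), computed on the undirected simple graph of edges of the
#' requested type. Used to contrast the tightly clustered friendship
#' structure with the more diffuse enmity structure.
#'
#' @param mn A [mention_network()].
#' @param type `"friend"` or `"foe"`.
#' @return Mean local clustering coefficient in `[0, 1]`.
#' @export
mention_clustering <- function(mn, type = c("friend", "foe")) {
  type <- match.arg(type)
  e <- mn$edges[mn$edges$type == type, c("source", "target")]
  g <- igraph::graph_from_data_frame(e, directed = TRUE,
                                     vertices = data.frame(seq_len(mn$n)))
  g <- igraph::as_undirected(g, mode = "collapse")
  cl <- igraph::transitivity(g, type = "local", isolates = "zero")
  cl[is.na(cl)] <- 0
  mean(cl)
}
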