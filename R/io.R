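#' Write a mention network as edge-list CSV
#'
#' Columns `source,target,type`, one row per directed mention, UTF-8,
#' LF line endings. Agent identifiers are the network's opaque string
#' ids; the integer index mapping is recoverable from the roster order.
#'
#' @param mn A [mention_network()].
#' @param path Output file path.
#' @param roster_path Optional path for a one-column roster CSV
#'   (`agent_id`) listing every agent, including unmentioned ones.
#' @return `path`, invisibly.
#' @export
write_mention_csv <- function(mn, path, roster_path = NULL) {
  stopifnot(inherits(mn, "mention_network"))
  out <- data.frame(source = mn$agents[mn$edges$source],
                    target = mn$agents[mn$edges$target],
                    type = mn$edges$type)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  if (!is.null(roster_path)) {
    utils::write.csv(data.frame(agent_id = mn$agents), roster_path,
                     row.names = FALSE, quote = FALSE, eol = "\n")
  }
  invisible(path)
}

#' Read a mention network from edge-list CSV
#'
#' Expects a header `source,target,type` with `type` in
#' `{friend, foe}`. Unless a roster is supplied, the agent set is
#' inferred as the sorted union of endpoint identifiers. Malformed rows
#' (self-mentions, unknown types, duplicates) are reported with their
#' row number.
#'
#' @param path CSV file path.
#' @param roster Optional character vector of agent ids (fixes `n` and
#'   the id-to-index mapping, and allows unmentioned agents).
#' @return A [mention_network()].
#' @export
read_mention_csv <- function(path, roster = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("source", "target", "type")
  if (!all(need %in% names(df))) {
    stop("mention CSV must have header columns source,target,type",
         call. = FALSE)
  }
  bad_type <- which(!df$type %in% c("friend", "foe"))
  if (length(bad_type)) {
    stop("unknown mention type in row(s) ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  }
  bad_self <- which(df$source == df$target)
  if (length(bad_self)) {
    stop("self-mention in row(s) ", paste(bad_self, collapse = ", "),
         call. = FALSE)
  }
  agents <- if (is.null(roster)) sort(unique(c(df$source, df$target)))
            else as.character(roster)
  unknown <- setdiff(c(df$source, df$target), agents)
  if (length(unknown)) {
    stop("agents absent from roster: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  edges <- data.frame(source = match(df$source, agents),
                      target = match(df$target, agents),
                      type = df$type)
  mention_network(edges, n = length(agents), agents = agents,
                  protocol = "imported")
}

#' Export a network as GraphML
#'
#' Signed networks are written undirected with a `weight` edge attribute
#' and, when states are given, `x`, `y`, `alpha` node attributes.
#' Mention networks are written directed with a `type` edge attribute.
#'
#' @param x A [signed_network()] or [mention_network()].
#' @param path Output file path.
#' @param states Optional [agent_states()] for signed networks.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(x, path, states = NULL) {
  g <- if (inherits(x, "signed_network")) {
    as_igraph_signed(x, states = states)
  } else if (inherits(x, "mention_network")) {
    g <- igraph::graph_from_data_frame(
      x$edges[, c("source", "target", "type")], directed = TRUE,
      vertices = data.frame(name = seq_len(x$n), label = x$agents))
    g
  } else {
    stop("`x` must be a signed_network or mention_network", call. = FALSE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a mention network from GraphML
#'
#' @param path GraphML file written by [write_graphml()].
#' @return A [mention_network()].
#' @export
read_mention_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_edgelist(g, names = FALSE)
  agents <- igraph::vertex_attr(g, "label")
  if (is.null(agents)) agents <- igraph::vertex_attr(g, "name")
  edges <- data.frame(source = el[, 1], target = el[, 2],
                      type = igraph::edge_attr(g, "type"))
  mention_network(edges, n = igraph::vcount(g), agents = agents,
                  protocol = "imported")
}

# ModelParams fields accepted in configuration files.
config_fields <- c("n", "k_avg", "tau", "D", "dt", "n_steps",
                   "rewire_interval", "l_max", "new_link_weight",
                   "y_convention", "record_stride", "seed")

#' Read simulation parameters from a YAML or JSON config file
#'
#' The file mirrors [model_params()] field for field; every invariant is
#' validated and unknown keys are rejected (typo guard).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [model_params()].
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be a .yaml or .json file", call. = FALSE)
  }
  unknown <- setdiff(names(cfg), config_fields)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(model_params, cfg)
}

#' Write a default configuration template
#'
#' @param path Output path (`.yaml` or `.json`); the written defaults
#'   round-trip through [read_config()] unchanged.
#' @return `path`, invisibly.
#' @export
write_config_template <- function(path) {
  p <- model_params()
  cfg <- p[config_fields[config_fields %in% names(p)]]
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' Export a simulation trace to CSV files
#'
#' Writes the recorded snapshots in long format: per-agent states as
#' `states.csv` (`iteration,agent,x,y,alpha`) and adjacency snapshots as
#' `weights.csv` (`iteration,i,j,weight`, upper triangle of present
#' links), plus the rewiring event log as `rewire_events.csv`.
#'
#' @param trace A [run_simulation()] trace.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trace_csv <- function(trace, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  states <- do.call(rbind, lapply(trace$snapshots, function(s) {
    data.frame(iteration = s$iteration, agent = seq_along(s$x),
               x = s$x, y = s$y, alpha = trace$alpha)
  }))
  utils::write.csv(states, file.path(dir, "states.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  utils::write.csv(link_weight_history(trace),
                   file.path(dir, "weights.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  utils::write.csv(trace$rewire_events, file.path(dir, "rewire_events.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(dir)
}

#' Serialise a survey summary to JSON
#'
#' @param s A [survey_summary()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(s, path) {
  stopifnot(inherits(s, "survey_summary"))
  jsonlite::write_json(unclass(s), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
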