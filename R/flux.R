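#' Build a reprogramming state-transition graph with per-state fluxes
#'
#' Evolves `n_init` random initial states under the target condition with the
#' recipe applied transiently, keeps the traversal graph, and counts for every
#' state how many reprogramming paths pass through it. Only paths terminating
#' in the target class count as reprogramming paths; other trajectories
#' contribute their states to the graph but not to the path counts. The
#' normalized flux of a state is its path count divided by the number of
#' states in the graph.
#'
#' @param net a `regnet` or compiled network.
#' @param rec a [recipe()] (transient), or `NULL` for the wild-type switch.
#' @param to_cond the target [condition()] the cells are moved into.
#' @param target_class `"cell_cycle"` or `"sporulation"`.
#' @param scheme a [classification_scheme()].
#' @param n_init random initial states (default 10000).
#' @param seed integer seed.
#' @return list: `graph` (a `state_graph`), `flux` (data.frame key,
#'   paths_through, normalized_flux), `n_paths` (reprogramming paths),
#'   `n_states`, `n_excluded` (non-reprogramming or non-converged paths).
#' @export
reprogramming_graph <- function(net, rec, to_cond,
                                target_class = c("cell_cycle", "sporulation"),
                                scheme, n_init = 10000L, seed = 1L,
                                max_steps = 10000L) {
  target_class <- match.arg(target_class)
  cn <- compile_network(net)
  set.seed(as.integer(seed))
  cl <- merge_clamps(to_cond, NULL)
  ci <- if (length(cl)) node_index(cn$net, names(cl)) else integer()
  roots <- random_states(cn, n_init, ci, as.numeric(cl))
  overrides <- if (!is.null(rec)) recipe_values(rec) else NULL
  run <- run_roots(cn, roots, to_cond, overrides = overrides,
                   max_steps = max_steps)
  cls <- attractor_classes(run, cn, scheme)
  tb <- run$table
  is_path <- tb$converged & (cls[tb$attractor] %0% "other") == target_class
  paths <- new.env(parent = emptyenv(), hash = TRUE)
  states <- new.env(parent = emptyenv(), hash = TRUE)
  flux_edges <- new.env(parent = emptyenv(), hash = TRUE)
  add_state <- function(k) {
    if (!exists(k, envir = states, inherits = FALSE))
      assign(k, get(k, envir = run$engine$bank, inherits = FALSE), envir = states)
  }
  for (i in seq_len(nrow(tb))) {
    if (!tb$converged[i]) next
    k <- run$root_keys[i]
    len <- tb$d[i] + tb$period[i]
    seen <- character(0)
    for (s in seq_len(len)) {
      add_state(k)
      if (is_path[i]) seen <- c(seen, k)
      nk <- get(k, envir = run$engine$succ, inherits = FALSE)
      ek <- paste(k, nk, sep = "\r")
      assign(ek, (get0(ek, envir = flux_edges, inherits = FALSE) %||% 0L) + 1L,
             envir = flux_edges)
      k <- nk
    }
    add_state(k)
    if (is_path[i]) {
      for (kk in unique(c(seen, k)))
        assign(kk, (get0(kk, envir = paths, inherits = FALSE) %||% 0L) + 1L,
               envir = paths)
    }
  }
  keys <- ls(states)
  S <- do.call(rbind, lapply(keys, function(k) get(k, envir = states)))
  rownames(S) <- keys; colnames(S) <- cn$ids
  ek <- ls(flux_edges)
  parts <- strsplit(ek, "\r", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, "", 1), to = vapply(parts, `[`, "", 2),
    flux = vapply(ek, function(e) get(e, envir = flux_edges), integer(1)),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  graph <- structure(list(states = S, edges = edges,
                          roots = unique(run$root_keys),
                          attractor_keys = unique(tb$attractor[tb$converged]),
                          condition = if (is.null(to_cond)) "none" else to_cond$name,
                          clamps = cl), class = "state_graph")
  n_states <- length(keys)
  pth <- vapply(keys, function(k) get0(k, envir = paths, inherits = FALSE) %||% 0L,
                integer(1))
  flux <- data.frame(key = keys, paths_through = pth,
                     normalized_flux = pth / n_states,
                     stringsAsFactors = FALSE)
  rownames(flux) <- NULL
  list(graph = graph, flux = flux, n_paths = sum(is_path),
       n_states = n_states, n_excluded = sum(!is_path))
}

#' Identify transition states shared across reprogramming graphs
#'
#' Aggregates the per-graph flux records of an ensemble of recipes: a state is
#' accepted as a transition state when its cumulative reprogramming-path count
#' across the graphs reaches `min_paths` and its normalized flux averaged over
#' all graphs (absent = 0) exceeds `min_mean_flux`. Raising either threshold
#' can only shrink the accepted set.
#'
#' @param flux_list list of results from [reprogramming_graph()] (or of their
#'   `flux` data.frames).
#' @param min_paths cumulative path-count threshold (default 9000).
#' @param min_mean_flux mean normalized-flux threshold (default 0.05).
#' @param per_graph if `TRUE`, require `min_paths` within a single graph
#'   instead of cumulatively.
#' @return object of class `transition_state_report`: `candidates` (key,
#'   total_paths, mean_flux, n_graphs_present), `accepted` (subset),
#'   `thresholds`.
#' @export
find_transition_states <- function(flux_list, min_paths = 9000L,
                                   min_mean_flux = 0.05, per_graph = FALSE) {
  stopifnot(length(flux_list) >= 1)
  fl <- lapply(flux_list, function(x) if (is.data.frame(x)) x else x$flux)
  all_keys <- unique(unlist(lapply(fl, `[[`, "key")))
  total <- stats::setNames(numeric(length(all_keys)), all_keys)
  maxg <- total; fluxsum <- total; present <- total
  for (f in fl) {
    total[f$key] <- total[f$key] + f$paths_through
    maxg[f$key] <- pmax(maxg[f$key], f$paths_through)
    fluxsum[f$key] <- fluxsum[f$key] + f$normalized_flux
    present[f$key] <- present[f$key] + 1
  }
  mean_flux <- fluxsum / length(fl)
  cand <- data.frame(key = all_keys, total_paths = as.numeric(total),
                     max_graph_paths = as.numeric(maxg),
                     mean_flux = as.numeric(mean_flux),
                     n_graphs_present = as.integer(present),
                     stringsAsFactors = FALSE)
  cand <- cand[order(-cand$mean_flux), , drop = FALSE]
  rownames(cand) <- NULL
  path_ok <- if (per_graph) cand$max_graph_paths >= min_paths
             else cand$total_paths >= min_paths
  accepted <- cand[path_ok & cand$mean_flux > min_mean_flux, , drop = FALSE]
  structure(list(candidates = cand, accepted = accepted,
                 thresholds = list(min_paths = min_paths,
                                   min_mean_flux = min_mean_flux,
                                   per_graph = per_graph)),
            class = "transition_state_report")
}

#' @export
print.transition_state_report <- function(x, ...) {
  cat("<transition_state_report>", nrow(x$accepted), "transition state(s) of",
      nrow(x$candidates), "candidates",
      sprintf("(paths >= %d%s, mean flux > %g)\n", x$thresholds$min_paths,
              if (x$thresholds$per_graph) " per graph" else " cumulative",
              x$thresholds$min_mean_flux))
  invisible(x)
}

#' Export a state-transition graph
#'
#' Lossless export of states (key, bit string, attractor/root annotation) and
#' edges with flux. `graphml` uses igraph; `tsv` writes `<path>_nodes.tsv` and
#' `<path>_edges.tsv`; `dot` writes a Graphviz digraph.
#'
#' @param graph a `state_graph`.
#' @param path destination (file for graphml/dot, prefix for tsv).
#' @param format `"graphml"`, `"tsv"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "tsv", "dot")) {
  format <- match.arg(format)
  stopifnot(nrow(graph$states) > 0)
  keys <- rownames(graph$states)
  bits <- apply(graph$states, 1, paste, collapse = "")
  is_attr <- keys %in% graph$attractor_keys
  is_root <- keys %in% graph$roots
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      graph$edges, directed = TRUE,
      vertices = data.frame(name = keys, bits = bits,
                            attractor = is_attr, root = is_root,
                            stringsAsFactors = FALSE))
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "tsv") {
    utils::write.table(
      data.frame(key = keys, bits = bits, attractor = is_attr, root = is_root,
                 stringsAsFactors = FALSE),
      paste0(path, "_nodes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(graph$edges, paste0(path, "_edges.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines("digraph state_graph {", con)
    writeLines(sprintf('  "%s" [bits="%s"%s%s];', keys, bits,
                       ifelse(is_attr, ' attractor="1"', ""),
                       ifelse(is_root, ' root="1"', "")), con)
    writeLines(sprintf('  "%s" -> "%s" [flux=%d];',
                       graph$edges$from, graph$edges$to, graph$edges$flux), con)
    writeLines("}", con)
  }
  invisible(path)
}

#' Import a state-transition graph written by [export_graph()]
#'
#' @param path file (graphml) or prefix (tsv).
#' @param format `"graphml"` or `"tsv"`.
#' @return a `state_graph` (condition/clamp metadata is not round-tripped).
#' @export
import_graph <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    v <- igraph::as_data_frame(g, "vertices")
    e <- igraph::as_data_frame(g, "edges")
    nodes <- data.frame(key = v$name, bits = v$bits,
                        attractor = as.logical(v$attractor),
                        root = as.logical(v$root), stringsAsFactors = FALSE)
    edges <- data.frame(from = e$from, to = e$to, flux = as.integer(e$flux),
                        stringsAsFactors = FALSE)
  } else {
    nodes <- utils::read.delim(paste0(path, "_nodes.tsv"),
                               colClasses = c(key = "character", bits = "character"),
                               stringsAsFactors = FALSE)
    edges <- utils::read.delim(paste0(path, "_edges.tsv"),
                               colClasses = c(from = "character", to = "character"),
                               stringsAsFactors = FALSE)
  }
  S <- do.call(rbind, lapply(strsplit(nodes$bits, ""), as.numeric))
  rownames(S) <- nodes$key
  structure(list(states = S, edges = edges, roots = nodes$key[nodes$root],
                 attractor_keys = nodes$key[nodes$attractor],
                 condition = NA_character_, clamps = numeric(0)),
            class = "state_graph")
}
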