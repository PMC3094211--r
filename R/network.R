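#' @keywords internal
"_PACKAGE"

NODE_KINDS <- c("protein", "logic_and", "gene_group", "pathway", "phenotype", "signal")
SELF_MODES <- c("degradation", "sustaining", "activation")
# kinds whose inputs are combined by conjunction rather than the weighted sum
CONJUNCTION_KINDS <- c("logic_and", "phenotype")

#' Construct a regulatory network
#'
#' A `regnet` holds an ordered node table (the order defines the state-vector
#' index), a signed edge list and the designation of condition-signal nodes.
#' Nodes carry a `kind` (protein, logic_and, gene_group, pathway, phenotype,
#' signal) and a `self_mode` controlling the tie-break when activating and
#' repressing inputs cancel: self-degradation turns the node off,
#' self-sustaining keeps its state, self-activation turns it on. Inputs of
#' `logic_and` and `phenotype` nodes are combined by conjunction (all parents
#' must be on), so edges into them must be activating.
#'
#' @param nodes data.frame with columns `id`, `label`, `kind`, `self_mode` and
#'   optionally `perturbable` (logical; defaults to `kind == "protein"`).
#' @param edges data.frame with columns `source`, `target`, `sign` (+1
#'   activation, -1 repression); extra columns (e.g. `provenance`) are kept.
#' @param signals named list with any of `growth`, `sporulation`, `cell_size`
#'   (signal node ids) and `spor_node` (the phenotype node); entries may be
#'   `NULL` for networks without them.
#' @param name optional network name.
#' @return a validated object of class `regnet`.
#' @export
regnet <- function(nodes, edges = NULL, signals = list(), name = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$label)) nodes$label <- nodes$id
  if (is.null(nodes$self_mode)) nodes$self_mode <- "sustaining"
  if (is.null(nodes$kind)) nodes$kind <- "protein"
  if (is.null(nodes$perturbable)) nodes$perturbable <- nodes$kind == "protein"
  nodes$perturbable <- as.logical(nodes$perturbable)
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges$sign <- as.integer(edges$sign)
  }
  signals <- signals[!vapply(signals, is.null, logical(1))]
  net <- structure(list(nodes = nodes, edges = edges, signals = signals,
                        name = name), class = "regnet")
  validate_network(net)
  net
}

#' Validate a regulatory network
#'
#' Checks the structural invariants: unique node ids, closed vocabularies for
#' kind and self-mode, edge endpoints declared, no duplicate (source, target)
#' pairs, no incoming edges on signal nodes, only activating edges into
#' conjunction (logic_and/phenotype) nodes, and distinct growth/sporulation
#' signals. Errors name the offending record.
#'
#' @param net a `regnet`.
#' @return `net`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_network <- function(net) {
  nodes <- net$nodes
  edges <- net$edges
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup)) stop("duplicate node id: ", paste(unique(dup), collapse = ", "))
  bad <- setdiff(unique(nodes$kind), NODE_KINDS)
  if (length(bad)) stop("unknown node kind: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(nodes$self_mode), SELF_MODES)
  if (length(bad)) stop("unknown self_mode: ", paste(bad, collapse = ", "))
  if (nrow(edges)) {
    miss <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
    if (length(miss)) stop("edge references undeclared node: ",
                           paste(miss, collapse = ", "))
    if (!all(edges$sign %in% c(-1L, 1L)))
      stop("edge sign must be +1 or -1")
    key <- paste(edges$source, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      d <- edges[duplicated(key), , drop = FALSE]
      stop("duplicate edge: ", d$source[1], " -> ", d$target[1])
    }
    sig <- nodes$id[nodes$kind == "signal"]
    bad <- intersect(unique(edges$target), sig)
    if (length(bad)) stop("signal node has incoming edge: ",
                          paste(bad, collapse = ", "))
    conj <- nodes$id[nodes$kind %in% CONJUNCTION_KINDS]
    bad <- edges$target %in% conj & edges$sign != 1L
    if (any(bad)) stop("repressing edge into conjunction node: ",
                       edges$source[bad][1], " -> ", edges$target[bad][1])
  }
  for (s in c("growth", "sporulation", "cell_size", "spor_node")) {
    v <- net$signals[[s]]
    if (!is.null(v) && !v %in% nodes$id)
      stop("signal designation '", s, "' names unknown node: ", v)
  }
  g <- net$signals$growth; sp <- net$signals$sporulation
  if (!is.null(g) && !is.null(sp) && identical(g, sp))
    stop("growth and sporulation signals must be distinct")
  invisible(net)
}

#' @export
print.regnet <- function(x, ...) {
  kinds <- table(factor(x$nodes$kind, levels = NODE_KINDS))
  cat("<regnet>", if (!is.null(x$name)) x$name else "", "\n")
  cat("  nodes:", nrow(x$nodes),
      sprintf("(%s)", paste(sprintf("%d %s", kinds[kinds > 0],
                                    names(kinds)[kinds > 0]), collapse = ", ")), "\n")
  cat("  edges:", nrow(x$edges),
      sprintf("(%d activating, %d repressing)",
              sum(x$edges$sign == 1), sum(x$edges$sign == -1)), "\n")
  if (length(x$signals))
    cat("  signals:", paste(names(x$signals), unlist(x$signals),
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

node_index <- function(net, ids) {
  ix <- match(ids, net$nodes$id)
  if (anyNA(ix)) stop("unknown node id: ", paste(ids[is.na(ix)], collapse = ", "))
  ix
}

#' Nodes eligible for perturbation in recipe searches
#'
#' @param net a `regnet`.
#' @return character vector of perturbable node ids (by default the protein
#'   nodes, unless the node table flags otherwise).
#' @export
perturbable_nodes <- function(net) {
  net$nodes$id[net$nodes$perturbable]
}
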