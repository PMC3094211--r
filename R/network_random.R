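#' Degree-preserving randomization of a signed network
#'
#' Rewires the network by sign-stratified double-edge swaps: two edges of the
#' same sign exchange their targets, provided the exchange creates neither a
#' self-loop nor a duplicate (source, target) pair. The swap preserves, for
#' every node, the in-degree, out-degree, number of incoming activators and
#' number of incoming repressors. Edges terminating at conjunction nodes
#' (logic_and, phenotype) are never touched, mirroring the constraint that
#' the inputs of AND-type nodes keep their curated wiring; node self-modes
#' and the signal designations are untouched as well.
#'
#' @param net a `regnet`.
#' @param seed integer seed; the result is deterministic given the seed.
#' @param n_swaps number of attempted swaps (default `10 * nrow(net$edges)`).
#' @return a rewired `regnet`. If no legal swap exists the input is returned
#'   with a warning rather than an error.
#' @export
randomize_network <- function(net, seed, n_swaps = 10L * nrow(net$edges)) {
  stopifnot(n_swaps >= 0)
  edges <- net$edges
  conj <- net$nodes$id[net$nodes$kind %in% CONJUNCTION_KINDS]
  swappable <- which(!(edges$target %in% conj))
  if (length(swappable) < 2 || n_swaps == 0) {
    if (length(swappable) < 2) warning("fewer than 2 swappable edges; network returned unchanged")
    return(net)
  }
  set.seed(as.integer(seed))
  src <- edges$source; tgt <- edges$target; sgn <- edges$sign
  pair_key <- function(s, t) paste(s, t, sep = "\r")
  existing <- new.env(parent = emptyenv())
  for (k in pair_key(src, tgt)) assign(k, TRUE, envir = existing)
  by_sign <- split(swappable, sgn[swappable])
  done <- 0L; attempts <- 0L; max_attempts <- max(100L, 100L * n_swaps)
  while (done < n_swaps && attempts < max_attempts) {
    attempts <- attempts + 1L
    pool <- by_sign[[sample(length(by_sign), 1L)]]
    if (length(pool) < 2) next
    ij <- sample(pool, 2L)
    i <- ij[1]; j <- ij[2]
    if (tgt[i] == tgt[j]) next
    # exchanged targets: i gets tgt[j], j gets tgt[i]
    if (src[i] == tgt[j] || src[j] == tgt[i]) next
    k1 <- pair_key(src[i], tgt[j]); k2 <- pair_key(src[j], tgt[i])
    if (exists(k1, envir = existing, inherits = FALSE) ||
        exists(k2, envir = existing, inherits = FALSE)) next
    rm(list = c(pair_key(src[i], tgt[i]), pair_key(src[j], tgt[j])), envir = existing)
    tmp <- tgt[i]; tgt[i] <- tgt[j]; tgt[j] <- tmp
    assign(k1, TRUE, envir = existing); assign(k2, TRUE, envir = existing)
    done <- done + 1L
  }
  if (done == 0L) {
    warning("no legal swap found; network returned unchanged")
    return(net)
  }
  edges$target <- tgt
  out <- net
  out$edges <- edges
  validate_network(out)
  out
}

#' Generate a random synthetic regulatory network
#'
#' Draws a simple directed network (no self-loops, no duplicate edges) over
#' protein nodes with a given edge density and activator fraction, assigning
#' self-modes from a mixing distribution. Used as a first-class fixture
#' generator for property tests and null experiments.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param edge_density fraction of the `n_nodes * (n_nodes - 1)` possible
#'   directed edges to realize (0 < density <= 1).
#' @param activator_fraction expected fraction of activating (+1) edges.
#' @param self_mode_mix named numeric vector of weights over
#'   `c("degradation", "sustaining", "activation")`.
#' @param seed integer seed; the network is deterministic given the seed.
#' @return a validated `regnet` with `round(n_nodes*(n_nodes-1)*edge_density)`
#'   edges.
#' @export
generate_synthetic_network <- function(n_nodes, edge_density = 0.15,
                                       activator_fraction = 0.7,
                                       self_mode_mix = c(degradation = 0.4,
                                                         sustaining = 0.4,
                                                         activation = 0.2),
                                       seed = 1L) {
  stopifnot(n_nodes >= 2, edge_density > 0, edge_density <= 1,
            activator_fraction >= 0, activator_fraction <= 1)
  set.seed(as.integer(seed))
  ids <- sprintf("n%02d", seq_len(n_nodes))
  modes <- names(self_mode_mix)
  stopifnot(all(modes %in% SELF_MODES), sum(self_mode_mix) > 0)
  nodes <- data.frame(
    id = ids, label = ids, kind = "protein",
    self_mode = sample(modes, n_nodes, replace = TRUE, prob = self_mode_mix),
    stringsAsFactors = FALSE)
  n_possible <- n_nodes * (n_nodes - 1L)
  n_edges <- max(1L, round(n_possible * edge_density))
  # enumerate ordered pairs excluding the diagonal, sample without replacement
  pair <- arrayInd(sample.int(n_possible, n_edges), .dim = c(n_nodes, n_nodes - 1L))
  srcs <- pair[, 1]
  tgts <- pair[, 2] + (pair[, 2] >= pair[, 1])  # skip the diagonal
  edges <- data.frame(
    source = ids[srcs], target = ids[tgts],
    sign = ifelse(stats::runif(n_edges) < activator_fraction, 1L, -1L),
    stringsAsFactors = FALSE)
  regnet(nodes, edges, name = sprintf("synthetic_n%d_seed%d", n_nodes, as.integer(seed)))
}

#' Signed-degree audit of a network
#'
#' Per-node 4-tuple (in-degree, out-degree, incoming activators, incoming
#' repressors), used to verify that randomization preserves the signed degree
#' sequence.
#'
#' @param net a `regnet`.
#' @return data.frame keyed by node id.
#' @export
degree_audit <- function(net) {
  ids <- net$nodes$id
  e <- net$edges
  tab <- function(x) {
    t <- table(factor(x, levels = ids))
    as.integer(t)
  }
  data.frame(id = ids,
             in_degree = tab(e$target),
             out_degree = tab(e$source),
             in_activators = tab(e$target[e$sign == 1L]),
             in_repressors = tab(e$target[e$sign == -1L]),
             stringsAsFactors = FALSE)
}
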