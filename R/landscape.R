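#' Build a sampled state-transition graph
#'
#' Starts from the seed states (e.g. states on reprogramming paths), includes
#' every state on their evolving paths to the attractor under the condition
#' (with the recipe's transient overrides applied to the seeds), and pads the
#' graph with states from randomly sampled evolving paths until it holds
#' `pad_to` states or no new states are reachable. Edge flux counts tally how
#' many recorded paths traverse each deterministic transition.
#'
#' @param net a `regnet` or compiled network.
#' @param seed_states matrix of seed states (rows) or a single state vector.
#' @param cond a [condition()].
#' @param rec optional [recipe()] applied transiently to the seed states.
#' @param pad_to target number of states (default 10000).
#' @param seed integer seed for the padding samples.
#' @return object of class `state_graph`: `states` (matrix with key rownames),
#'   `edges` (data.frame from, to, flux), `roots`, `attractor_keys`,
#'   `condition`.
#' @export
build_state_graph <- function(net, seed_states, cond = NULL, rec = NULL,
                              pad_to = 10000L, seed = 1L, max_steps = 10000L) {
  cn <- compile_network(net)
  if (is.null(dim(seed_states))) seed_states <- matrix(seed_states, 1)
  set.seed(as.integer(seed))
  cl <- merge_clamps(cond, NULL)
  ci <- if (length(cl)) node_index(cn$net, names(cl)) else integer()
  overrides <- if (!is.null(rec)) recipe_values(rec) else NULL

  flux <- new.env(parent = emptyenv(), hash = TRUE)  # "from\rto" -> count
  states <- new.env(parent = emptyenv(), hash = TRUE)
  attractor_keys <- character(0)
  roots <- character(0)
  n_states <- 0L

  absorb <- function(run) {
    tb <- run$table
    for (i in which(tb$converged)) {
      k <- run$root_keys[i]
      path_len <- tb$d[i] + tb$period[i]
      for (s in seq_len(path_len)) {
        if (!exists(k, envir = states, inherits = FALSE)) {
          assign(k, get(k, envir = run$engine$bank, inherits = FALSE),
                 envir = states)
          n_states <<- n_states + 1L
        }
        nk <- get(k, envir = run$engine$succ, inherits = FALSE)
        ek <- paste(k, nk, sep = "\r")
        assign(ek, (get0(ek, envir = flux, inherits = FALSE) %||% 0L) + 1L,
               envir = flux)
        k <- nk
      }
      if (!exists(k, envir = states, inherits = FALSE)) {
        assign(k, get(k, envir = run$engine$bank, inherits = FALSE),
               envir = states)
        n_states <<- n_states + 1L
      }
    }
    canon <- unique(tb$attractor[tb$converged])
    attractor_keys <<- union(attractor_keys, canon)
  }

  run <- run_roots(cn, seed_states, cond, overrides = overrides,
                   max_steps = max_steps)
  roots <- unique(run$root_keys)
  absorb(run)
  tries <- 0L
  while (n_states < pad_to && tries < 50L) {
    tries <- tries + 1L
    m <- min(1000L, pad_to)
    extra <- random_states(cn, m, ci, as.numeric(cl))
    before <- n_states
    absorb(run_roots(cn, extra, cond, max_steps = max_steps))
    if (n_states == before) break
  }
  keys <- ls(states)
  S <- do.call(rbind, lapply(keys, function(k) get(k, envir = states)))
  rownames(S) <- keys; colnames(S) <- cn$ids
  ek <- ls(flux)
  parts <- strsplit(ek, "\r", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, "", 1), to = vapply(parts, `[`, "", 2),
    flux = vapply(ek, function(e) get(e, envir = flux), integer(1)),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(states = S, edges = edges, roots = roots,
                 attractor_keys = attractor_keys,
                 condition = if (is.null(cond)) "none" else cond$name,
                 clamps = cl), class = "state_graph")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.state_graph <- function(x, ...) {
  cat("<state_graph>", nrow(x$states), "states,", nrow(x$edges), "transitions;",
      length(x$attractor_keys), "attractor(s);", "condition", x$condition, "\n")
  invisible(x)
}

#' Noisy transition matrix over a state graph with a pseudo-state
#'
#' For each graph state the deterministic successor is computed from the
#' update rule; each node then takes its deterministic next value with
#' probability `(1 - c) / (1 + exp(-mu * |F|)) + c/2` when its input sum F is
#' nonzero, and `(1 - c) + c/2` (toward the mode-resolved value) on a tie;
#' clamped nodes are noiseless. The probability of moving to a state `j` is
#' the product of its per-node bit probabilities, evaluated for every in-graph
#' state within Hamming radius `radius` of the deterministic successor;
#' the remaining mass goes to a pseudo-state that collectively represents all
#' out-of-graph states and returns uniformly to the graph. Every row sums to
#' one.
#'
#' @param graph a `state_graph`.
#' @param net the network it was built from.
#' @param cond the [condition()] used to build it.
#' @param mu sharpness of the noisy threshold (default 5).
#' @param c noise floor in \[0, 1) (default 0.001).
#' @param radius Hamming truncation radius around the deterministic successor
#'   (default 2); farther in-graph states fold into the pseudo-state.
#' @return object of class `transition_matrix`: sparse row-stochastic `T` of
#'   dimension `(n+1) x (n+1)` (last row/column = pseudo-state), `keys`,
#'   `mu`, `c`.
#' @export
transition_matrix <- function(graph, net, cond = NULL, mu = 5, c = 0.001,
                              radius = 2L) {
  stopifnot(mu >= 0, c >= 0, c < 1)
  cn <- compile_network(net)
  S <- graph$states
  nS <- nrow(S); nn <- ncol(S)
  keys <- rownames(S)
  index <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nS)) assign(keys[i], i, envir = index)
  cl <- merge_clamps(cond, NULL)
  ci <- if (length(cl)) node_index(cn$net, names(cl)) else integer()
  succ <- step_batch(cn, S, ci, as.numeric(cl))
  F <- S %*% cn$tW
  # per-node probability of taking the deterministic bit
  p_det <- (1 - c) / (1 + exp(-mu * abs(F))) + c / 2
  p_det[F == 0] <- (1 - c) + c / 2
  for (j in cn$conj) p_det[, j] <- (1 - c) + c / 2  # conjunction is mode-resolved
  if (length(ci)) p_det[, ci] <- 1                  # clamps are noiseless
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  flip_sets <- list(integer(0))
  if (radius >= 1) flip_sets <- c(flip_sets, lapply(seq_len(nn), function(a) a))
  if (radius >= 2 && nn >= 2) {
    pairs <- utils::combn(nn, 2)
    flip_sets <- c(flip_sets, lapply(seq_len(ncol(pairs)), function(a) pairs[, a]))
  }
  for (i in seq_len(nS)) {
    base <- prod(p_det[i, ])
    ratio <- (1 - p_det[i, ]) / p_det[i, ]
    row_j <- integer(0); row_p <- numeric(0)
    for (fs in flip_sets) {
      tgt <- succ[i, ]
      if (length(fs)) tgt[fs] <- 1 - tgt[fs]
      if (length(intersect(fs, ci))) next  # cannot flip a clamped node
      k <- state_keys(tgt)
      jj <- get0(k, envir = index, inherits = FALSE)
      if (is.null(jj)) next
      p <- base * prod(ratio[fs])
      row_j <- c(row_j, jj); row_p <- c(row_p, p)
    }
    resid <- max(0, 1 - sum(row_p))
    trip_i <- c(trip_i, rep(i, length(row_j)), i)
    trip_j <- c(trip_j, row_j, nS + 1L)
    trip_x <- c(trip_x, row_p, resid)
  }
  # pseudo-state: uniform return to the in-graph states
  trip_i <- c(trip_i, rep(nS + 1L, nS))
  trip_j <- c(trip_j, seq_len(nS))
  trip_x <- c(trip_x, rep(1 / nS, nS))
  T <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(nS + 1L, nS + 1L))
  structure(list(T = T, keys = c(keys, ".pseudo"), mu = mu, c = c,
                 radius = radius), class = "transition_matrix")
}

#' Steady-state probabilities by power iteration
#'
#' Iterates `p <- p T` from the uniform distribution until the L1 change
#' drops below `tol`, renormalizing each step. The default tolerance is
#' conservative because the per-iteration change understates the remaining
#' distance to the fixed point when the spectral gap is small.
#'
#' @param T a `transition_matrix` or a plain row-stochastic matrix.
#' @param tol L1 convergence tolerance on the per-iteration change
#'   (default 1e-12).
#' @param max_iter iteration budget (default 100000).
#' @return named probability vector with attributes `converged`, `iterations`,
#'   `residual`.
#' @export
steady_state <- function(T, tol = 1e-12, max_iter = 100000L) {
  keys <- NULL
  if (inherits(T, "transition_matrix")) { keys <- T$keys; T <- T$T }
  n <- nrow(T)
  rs <- Matrix::rowSums(T)
  if (any(abs(rs - 1) > 1e-8)) stop("matrix is not row-stochastic")
  p <- rep(1 / n, n)
  it <- 0L; resid <- Inf
  while (it < max_iter) {
    it <- it + 1L
    p1 <- as.numeric(p %*% T)
    p1 <- p1 / sum(p1)
    resid <- sum(abs(p1 - p))
    p <- p1
    if (resid < tol) break
  }
  if (!is.null(keys)) names(p) <- keys
  attr(p, "converged") <- resid < tol
  attr(p, "iterations") <- it
  attr(p, "residual") <- resid
  p
}

#' Potentials from steady-state probabilities across conditions
#'
#' Averages per-state steady-state probabilities over the supplied condition
#' runs (states absent under a condition contribute probability zero) and
#' reports the potential `U = -ln(p_mean)`; states with zero mean probability
#' get `U = Inf`.
#'
#' @param p_list named list of steady-state vectors (names = condition names),
#'   each named by state key (pseudo-state entries are kept as `.pseudo`).
#' @return data.frame: key, one probability column per condition, `p_mean`,
#'   `U`.
#' @export
potential <- function(p_list) {
  stopifnot(length(p_list) >= 1)
  keys <- Reduce(union, lapply(p_list, names))
  cols <- lapply(p_list, function(p) as.numeric(p[keys] %0% 0))
  P <- do.call(cbind, cols)
  colnames(P) <- names(p_list)
  p_mean <- rowMeans(P)
  U <- ifelse(p_mean > 0, -log(p_mean), Inf)
  out <- data.frame(key = keys, P, p_mean = p_mean, U = U,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}
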