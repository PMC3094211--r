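`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent brute-force oracle for the synchronous update rule, written as a
# plain per-node loop over the edge list (no weight matrix, no batching) so it
# shares no code path with the package engine.

oracle_step <- function(net, state, clamps = NULL) {
  ids <- net$nodes$id
  s <- as.numeric(state)
  out <- numeric(length(s))
  for (i in seq_along(ids)) {
    id <- ids[i]
    kind <- net$nodes$kind[i]
    inc <- net$edges[net$edges$target == id, , drop = FALSE]
    if (kind %in% c("logic_and", "phenotype")) {
      out[i] <- if (nrow(inc) == 0) 0
        else as.numeric(all(s[match(inc$source, ids)] == 1))
    } else {
      f <- if (nrow(inc)) sum(inc$sign * s[match(inc$source, ids)]) else 0
      out[i] <- if (f > 0) 1 else if (f < 0) 0 else
        switch(net$nodes$self_mode[i],
               degradation = 0, sustaining = s[i], activation = 1)
    }
  }
  if (length(clamps)) out[match(names(clamps), ids)] <- as.numeric(clamps)
  out
}

# full trajectory with cycle detection, by linear search over visited states
oracle_evolve <- function(net, state, clamps = NULL, max_steps = 1000) {
  seen <- list(as.numeric(state))
  s <- as.numeric(state)
  if (length(clamps)) s[match(names(clamps), net$nodes$id)] <- as.numeric(clamps)
  seen[[1]] <- s
  for (t in seq_len(max_steps)) {
    s <- oracle_step(net, s, clamps)
    for (j in seq_along(seen)) {
      if (all(seen[[j]] == s)) {
        cyc <- do.call(rbind, seen[j:length(seen)])
        return(list(states = do.call(rbind, seen), cycle = cyc,
                    steps_to_attractor = j - 1L, period = nrow(cyc),
                    converged = TRUE))
      }
    }
    seen[[length(seen) + 1L]] <- s
  }
  list(states = do.call(rbind, seen), cycle = NULL,
       steps_to_attractor = NA_integer_, period = NA_integer_,
       converged = FALSE)
}

# exhaustive basin tally over all assignments of the free nodes
oracle_enumerate <- function(net, clamps = NULL, max_steps = 1000) {
  ids <- net$nodes$id
  free <- setdiff(seq_along(ids), match(names(clamps), ids))
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), length(free))))
  keys <- character(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    s <- numeric(length(ids))
    s[free] <- grid[r, ]
    ev <- oracle_evolve(net, s, clamps, max_steps)
    cyc_keys <- apply(ev$cycle, 1, paste, collapse = "")
    keys[r] <- min(cyc_keys)
  }
  table(keys)
}

# small deterministic toy networks used across tests
toy_mutual_activation <- function() {
  regnet(data.frame(id = c("a", "b"), kind = "protein",
                    self_mode = "sustaining"),
         data.frame(source = c("a", "b"), target = c("b", "a"),
                    sign = c(1L, 1L)))
}

toy_chain <- function(n = 3, sign = 1L, mode = "degradation") {
  ids <- letters[seq_len(n)]
  regnet(data.frame(id = ids, kind = "protein", self_mode = mode),
         data.frame(source = ids[-n], target = ids[-1],
                    sign = rep(sign, n - 1L)))
}

random_net <- function(seed, n = 8, density = 0.25) {
  generate_synthetic_network(n, edge_density = density,
                             activator_fraction = 0.6, seed = seed)
}
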