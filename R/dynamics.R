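## Synchronous Boolean dynamics.
##
## Update rule: for a non-conjunction node i, F_i = sum_j a_ij * S_j(t) over
## its signed inputs; S_i(t+1) = 1 if F_i > 0, 0 if F_i < 0, and on a tie
## (F_i = 0) the node's self-mode decides: degradation -> 0, sustaining ->
## S_i(t), activation -> 1. Conjunction nodes (logic_and, phenotype) take the
## product of their parents' previous states. Clamped nodes hold their clamp
## value at every step.

#' Compile a network for fast simulation
#'
#' Precomputes the signed weight matrix, conjunction parent lists, tie-break
#' mode masks and signal indices. All simulation entry points accept either a
#' `regnet` or its compiled form.
#'
#' @param net a `regnet`.
#' @return an object of class `regnet_compiled`.
#' @export
compile_network <- function(net) {
  if (inherits(net, "regnet_compiled")) return(net)
  validate_network(net)
  n <- nrow(net$nodes)
  ids <- net$nodes$id
  conj <- which(net$nodes$kind %in% CONJUNCTION_KINDS)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- net$edges
  if (nrow(e)) {
    ti <- match(e$target, ids); si <- match(e$source, ids)
    keep <- !(ti %in% conj)
    W[cbind(ti[keep], si[keep])] <- e$sign[keep]
  }
  conj_parents <- lapply(conj, function(i)
    match(e$source[e$target == ids[i]], ids))
  mode <- match(net$nodes$self_mode, SELF_MODES) - 1L  # 0 deg, 1 sus, 2 act
  structure(list(
    n = n, ids = ids, tW = t(W),
    conj = conj, conj_parents = conj_parents,
    sus_cols = setdiff(which(mode == 1L), conj),
    act_cols = setdiff(which(mode == 2L), conj),
    signal_idx = which(net$nodes$kind == "signal"),
    net = net), class = "regnet_compiled")
}

## one synchronous update of an m x n batch of states
step_batch <- function(cn, S, clamp_idx = integer(), clamp_val = integer()) {
  m <- nrow(S)
  F <- S %*% cn$tW
  nxt <- (F > 0) * 1
  if (length(cn$sus_cols) || length(cn$act_cols)) {
    Z <- F == 0
    for (j in cn$act_cols) nxt[, j] <- nxt[, j] + Z[, j]
    for (j in cn$sus_cols) nxt[, j] <- nxt[, j] + Z[, j] * S[, j]
  }
  for (k in seq_along(cn$conj)) {
    p <- cn$conj_parents[[k]]
    nxt[, cn$conj[k]] <- if (length(p) == 0) 0
      else (rowSums(S[, p, drop = FALSE]) == length(p)) * 1
  }
  if (length(clamp_idx))
    nxt[, clamp_idx] <- rep(clamp_val, each = m)
  nxt
}

#' One synchronous update of a network state
#'
#' Applies transient overrides to the input state, performs one update, and
#' enforces clamps on the result.
#'
#' @param net a `regnet` or compiled network.
#' @param state binary vector over the network's nodes (declaration order).
#' @param clamps named 0/1 vector of permanently fixed nodes.
#' @param overrides named 0/1 vector applied to the input state before the
#'   update (t = 0 semantics).
#' @return the successor state (named binary vector).
#' @export
step <- function(net, state, clamps = NULL, overrides = NULL) {
  cn <- compile_network(net)
  s <- as_state(cn, state)
  if (length(overrides)) s[node_index(cn$net, names(overrides))] <- as.numeric(overrides)
  ci <- if (length(clamps)) node_index(cn$net, names(clamps)) else integer()
  out <- step_batch(cn, matrix(s, 1), ci, as.numeric(clamps))[1, ]
  stats::setNames(out, cn$ids)
}

as_state <- function(cn, state) {
  if (!is.null(names(state)) && length(state) != cn$n)
    stop("state length ", length(state), " does not match network size ", cn$n)
  s <- as.numeric(state)
  if (length(s) != cn$n) stop("state length ", length(s),
                              " does not match network size ", cn$n)
  if (!all(s %in% c(0, 1))) stop("state must be binary")
  s
}

#' Compact key encoding of network states
#'
#' Packs the bit rows of a state matrix into strings of 30-bit integer chunks;
#' the encoding is a bijection with the bit vectors for a fixed network.
#'
#' @param S state matrix (rows = states) or a single state vector.
#' @return character vector of keys.
#' @export
state_keys <- function(S) {
  if (is.null(dim(S))) S <- matrix(S, 1)
  n <- ncol(S)
  starts <- seq(1, n, by = 30)
  parts <- lapply(starts, function(b) {
    ix <- b:min(b + 29, n)
    as.vector(S[, ix, drop = FALSE] %*% 2^(seq_along(ix) - 1))
  })
  do.call(paste, c(parts, sep = "."))
}

#' Decode a state key back to bits
#' @param key key produced by [state_keys()].
#' @param n number of nodes.
#' @return binary vector of length `n`.
#' @export
key_to_state <- function(key, n) {
  chunks <- as.numeric(strsplit(key, ".", fixed = TRUE)[[1]])
  bits <- numeric(0)
  sizes <- diff(c(seq(1, n, by = 30), n + 1))
  for (b in seq_along(chunks)) {
    v <- chunks[b]
    bits <- c(bits, (v %/% 2^(0:(sizes[b] - 1))) %% 2)
  }
  bits
}

#' Define a simulation condition
#'
#' A condition clamps the two mutually exclusive environment signal nodes
#' (growth, sporulation) and fixes the cell-size checkpoint signal off, with
#' an optional pulse at t = 0 used to launch the excited (START) trajectory.
#' Networks lacking the named signal nodes simply get no clamps.
#'
#' @param net a `regnet` or compiled network.
#' @param name `"growth"`, `"sporulation"` or `"none"`.
#' @param cell_size `"off"` (free-running sampling) or `"pulse"` (signal on in
#'   the initial state only).
#' @return an object of class `sim_condition` with `clamps` and `overrides`.
#' @export
condition <- function(net, name = c("growth", "sporulation", "none"),
                      cell_size = c("off", "pulse")) {
  name <- match.arg(name); cell_size <- match.arg(cell_size)
  sig <- compile_network(net)$net$signals
  clamps <- numeric(0)
  if (!is.null(sig$growth))
    clamps[sig$growth] <- if (name == "growth") 1 else 0
  if (!is.null(sig$sporulation))
    clamps[sig$sporulation] <- if (name == "sporulation") 1 else 0
  overrides <- numeric(0)
  if (!is.null(sig$cell_size)) {
    clamps[sig$cell_size] <- 0
    if (cell_size == "pulse") overrides[sig$cell_size] <- 1
  }
  structure(list(name = name, clamps = clamps, overrides = overrides,
                 cell_size_protocol = cell_size), class = "sim_condition")
}

## merge condition clamps with mutation clamps (mutation wins on conflict)
merge_clamps <- function(cond, clamps) {
  out <- if (is.null(cond)) numeric(0) else cond$clamps
  if (length(clamps)) out[names(clamps)] <- as.numeric(clamps)
  out
}

## ---- successor-map engine -------------------------------------------------
## Shared core: learn the deterministic successor map over all states reachable
## from a set of roots (batched matrix updates, each distinct state stepped
## once), then resolve every root's attractor, period and evolving distance by
## pointer-chasing with memoization.

closure_engine <- function(cn, roots, clamp_idx, clamp_val, max_steps = 10000L) {
  # roots are taken as-is: t0 overrides may legitimately disagree with the
  # clamps, which re-assert themselves from the first update onward
  if (is.null(dim(roots))) roots <- matrix(roots, 1)
  succ <- new.env(parent = emptyenv(), hash = TRUE)
  bank <- new.env(parent = emptyenv(), hash = TRUE)
  rk <- state_keys(roots)
  frontier <- roots[!duplicated(rk), , drop = FALSE]
  fk <- rk[!duplicated(rk)]
  iter <- 0L
  while (nrow(frontier) > 0 && iter < max_steps) {
    iter <- iter + 1L
    S1 <- step_batch(cn, frontier, clamp_idx, clamp_val)
    k1 <- state_keys(S1)
    for (i in seq_along(fk)) {
      assign(fk[i], frontier[i, ], envir = bank)
      assign(fk[i], k1[i], envir = succ)
    }
    new_ix <- which(!duplicated(k1) &
                    !vapply(k1, exists, logical(1), envir = succ, inherits = FALSE))
    frontier <- S1[new_ix, , drop = FALSE]
    fk <- k1[new_ix]
  }
  list(succ = succ, bank = bank, roots = rk, exhausted = nrow(frontier) > 0)
}

## resolve attractor/distance for a set of keys given a successor map
resolve_keys <- function(keys, succ) {
  res <- new.env(parent = emptyenv(), hash = TRUE)   # key -> list(attr, d, period)
  attrs <- new.env(parent = emptyenv(), hash = TRUE) # canonical key -> cycle keys
  out_attr <- character(length(keys)); out_d <- integer(length(keys))
  out_per <- integer(length(keys)); out_conv <- logical(length(keys))
  for (qi in seq_along(keys)) {
    k <- keys[qi]
    walk <- character(0); pos <- new.env(parent = emptyenv(), hash = TRUE)
    hit <- NULL
    while (TRUE) {
      r <- get0(k, envir = res, inherits = FALSE)
      if (!is.null(r)) { hit <- r; break }
      p <- get0(k, envir = pos, inherits = FALSE)
      if (!is.null(p)) {  # new cycle found within this walk
        cyc <- walk[p:length(walk)]
        canon <- min(cyc)
        rot <- which(cyc == canon)
        assign(canon, c(cyc[rot:length(cyc)], cyc[seq_len(rot - 1L)]), envir = attrs)
        per <- length(cyc)
        for (i in p:length(walk))
          assign(walk[i], list(attr = canon, d = 0L, period = per), envir = res)
        hit <- list(attr = canon, d = 0L, period = per)
        walk <- walk[seq_len(p - 1L)]
        break
      }
      nk <- get0(k, envir = succ, inherits = FALSE)
      if (is.null(nk)) { hit <- list(attr = NA_character_, d = NA_integer_, period = NA_integer_); break }
      walk <- c(walk, k); assign(k, length(walk), envir = pos)
      k <- nk
    }
    if (length(walk) && !is.na(hit$attr)) {
      base <- hit$d
      for (i in rev(seq_along(walk))) {
        base <- base + 1L
        assign(walk[i], list(attr = hit$attr, d = base, period = hit$period), envir = res)
      }
    } else if (length(walk)) {
      for (i in seq_along(walk))
        assign(walk[i], hit, envir = res)
    }
    r <- get(keys[qi], envir = res, inherits = FALSE)
    out_attr[qi] <- r$attr; out_d[qi] <- r$d; out_per[qi] <- r$period
    out_conv[qi] <- !is.na(r$attr)
  }
  list(table = data.frame(key = keys, attractor = out_attr, d = out_d,
                          period = out_per, converged = out_conv,
                          stringsAsFactors = FALSE),
       res = res, attractors = attrs)
}

attractor_object <- function(canon, cycle_keys, bank, n, basin_count = NA_integer_) {
  states <- do.call(rbind, lapply(cycle_keys, function(k)
    get(k, envir = bank, inherits = FALSE)))
  structure(list(key = canon, keys = cycle_keys, states = states,
                 period = length(cycle_keys), basin_count = basin_count),
            class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat("<attractor>", if (x$period == 1) "fixed point" else
      paste0("cycle, period ", x$period),
      if (!is.na(x$basin_count)) paste0("; basin count ", x$basin_count) else "", "\n")
  invisible(x)
}

#' Evolve a network from an initial state
#'
#' Iterates the synchronous update under the condition's clamps (plus any
#' permanent mutation clamps), applying transient overrides to the initial
#' state only, until a previously visited state recurs. The trailing segment
#' of the trajectory is the attractor (a fixed point or a cycle).
#'
#' @param net a `regnet` or compiled network.
#' @param init initial binary state (declaration order).
#' @param cond a [condition()], or `NULL` for no signal clamps.
#' @param overrides named 0/1 vector applied at t = 0 only.
#' @param clamps named 0/1 vector of permanent clamps (mutations).
#' @param max_steps step budget; exceeding it yields `converged = FALSE`
#'   rather than silent truncation.
#' @return object of class `trajectory`: `states` (matrix, one row per step up
#'   to and including the full attractor), `attractor`, `steps_to_attractor`,
#'   `converged`.
#' @export
evolve <- function(net, init, cond = NULL, overrides = NULL, clamps = NULL,
                   max_steps = 10000L) {
  cn <- compile_network(net)
  s <- as_state(cn, init)
  cl <- merge_clamps(cond, clamps)
  ci <- if (length(cl)) node_index(cn$net, names(cl)) else integer()
  if (length(ci)) s[ci] <- as.numeric(cl)
  ov <- c(if (!is.null(cond)) cond$overrides else numeric(0), overrides)
  if (length(ov)) s[node_index(cn$net, names(ov))] <- as.numeric(ov)
  eng <- closure_engine(cn, matrix(s, 1), ci, as.numeric(cl), max_steps)
  k0 <- state_keys(matrix(s, 1))
  r <- resolve_keys(k0, eng$succ)
  row <- r$table[1, ]
  if (!row$converged) {
    return(structure(list(states = matrix(s, 1, dimnames = list(NULL, cn$ids)),
                          keys = k0, attractor = NULL,
                          steps_to_attractor = NA_integer_, converged = FALSE),
                     class = "trajectory"))
  }
  cyc <- get(row$attractor, envir = r$attractors, inherits = FALSE)
  att <- attractor_object(row$attractor, cyc, eng$bank, cn$n)
  # reconstruct the visited sequence: transient prefix + one pass of the cycle
  keys <- character(row$d + att$period)
  k <- k0
  for (i in seq_len(row$d)) { keys[i] <- k; k <- get(k, envir = eng$succ) }
  keys[(row$d + 1):(row$d + att$period)] <-
    c(k, if (att$period > 1) {
      kk <- k; out <- character(att$period - 1)
      for (i in seq_len(att$period - 1)) { kk <- get(kk, envir = eng$succ); out[i] <- kk }
      out
    })
  states <- do.call(rbind, lapply(keys, function(kk)
    get(kk, envir = eng$bank, inherits = FALSE)))
  colnames(states) <- cn$ids
  structure(list(states = states, keys = keys, attractor = att,
                 steps_to_attractor = row$d, converged = TRUE),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", nrow(x$states), "states;",
      if (x$converged) sprintf("reaches %s attractor after %d steps",
                               if (x$attractor$period == 1) "fixed-point"
                               else sprintf("period-%d", x$attractor$period),
                               x$steps_to_attractor)
      else "did not converge within the step budget", "\n")
  invisible(x)
}

## random initial states: free nodes uniform, clamped nodes at clamp value
random_states <- function(cn, m, clamp_idx, clamp_val) {
  S <- matrix(sample(c(0, 1), m * cn$n, replace = TRUE), m, cn$n)
  if (length(clamp_idx)) S[, clamp_idx] <- rep(clamp_val, each = m)
  S
}

## shared worker: evolve a set of root states to their attractors
run_roots <- function(cn, roots, cond = NULL, overrides = NULL, clamps = NULL,
                      max_steps = 10000L) {
  cl <- merge_clamps(cond, clamps)
  ci <- if (length(cl)) node_index(cn$net, names(cl)) else integer()
  if (length(ci)) roots[, ci] <- rep(as.numeric(cl), each = nrow(roots))
  ov <- c(if (!is.null(cond)) cond$overrides else numeric(0), overrides)
  if (length(ov)) {
    oi <- node_index(cn$net, names(ov))
    roots[, oi] <- rep(as.numeric(ov), each = nrow(roots))
  }
  eng <- closure_engine(cn, roots, ci, as.numeric(cl), max_steps)
  rk <- state_keys(roots)
  r <- resolve_keys(unique(rk), eng$succ)
  tab <- r$table[match(rk, r$table$key), ]
  rownames(tab) <- NULL
  list(engine = eng, resolved = r, root_keys = rk, table = tab)
}

## assemble attractor objects with basin tallies from a run_roots() result
collect_attractors <- function(run, n) {
  tab <- run$table[run$table$converged, , drop = FALSE]
  counts <- table(tab$attractor)
  lapply(names(counts), function(canon)
    attractor_object(canon,
                     get(canon, envir = run$resolved$attractors, inherits = FALSE),
                     run$engine$bank, n, as.integer(counts[[canon]])))
}

#' Sample attractors and basin fractions
#'
#' Draws uniform random initial states (signal nodes fixed by the condition),
#' evolves each to its attractor, and accumulates basin tallies in batches
#' until the per-class fractions change by less than `tol` between consecutive
#' cumulative tallies, or until `cap` states have been sampled.
#'
#' @param net a `regnet` or compiled network.
#' @param cond a [condition()].
#' @param seed integer seed (deterministic result).
#' @param batch states added per convergence check (default 5000).
#' @param tol maximum change in any class fraction to accept convergence
#'   (default 0.01).
#' @param cap maximum number of sampled states.
#' @param scheme optional [classification_scheme()]; when supplied, fractions
#'   are tracked per phenotype class (sporulation / cell_cycle / other),
#'   otherwise per attractor.
#' @param clamps named 0/1 vector of permanent mutation clamps.
#' @param overrides named 0/1 vector applied to every initial state at t = 0.
#' @param max_steps per-trajectory step budget.
#' @return object of class `sampling_result`: `attractors` (list with basin
#'   counts and class labels), `fractions` (per class), `n_sampled`, `seed`,
#'   `converged`, `n_unconverged`.
#' @export
sample_attractors <- function(net, cond = NULL, seed = 1L, batch = 5000L,
                              tol = 0.01, cap = 100000L, scheme = NULL,
                              clamps = NULL, overrides = NULL,
                              max_steps = 10000L) {
  stopifnot(batch >= 1, cap >= batch)
  cn <- compile_network(net)
  set.seed(as.integer(seed))
  cl <- merge_clamps(cond, clamps)
  ci <- if (length(cl)) node_index(cn$net, names(cl)) else integer()
  counts <- integer(0)       # per attractor key
  n_sampled <- 0L; n_uncv <- 0L
  prev_frac <- NULL; converged <- FALSE
  runs <- list()
  while (n_sampled < cap) {
    m <- min(batch, cap - n_sampled)
    roots <- random_states(cn, m, ci, as.numeric(cl))
    run <- run_roots(cn, roots, cond, overrides, clamps, max_steps)
    runs[[length(runs) + 1L]] <- run
    tb <- run$table
    n_uncv <- n_uncv + sum(!tb$converged)
    tt <- table(tb$attractor[tb$converged])
    for (k in names(tt)) counts[k] <- (if (k %in% names(counts)) counts[k] else 0L) + tt[[k]]
    n_sampled <- n_sampled + m
    frac <- class_fractions(counts, runs, cn, scheme)
    if (!is.null(prev_frac)) {
      all_cls <- union(names(frac), names(prev_frac))
      delta <- abs(frac[all_cls] %0% 0 - prev_frac[all_cls] %0% 0)
      if (all(delta < tol)) { converged <- TRUE; break }
    }
    prev_frac <- frac
  }
  atts <- list()
  for (run in runs) {
    for (a in collect_attractors(run, cn$n)) {
      if (is.null(atts[[a$key]])) { a$basin_count <- 0L; atts[[a$key]] <- a }
    }
  }
  for (k in names(counts)) atts[[k]]$basin_count <- counts[[k]]
  if (!is.null(scheme))
    for (k in names(atts)) atts[[k]]$class <- classify_attractor(atts[[k]], scheme)
  structure(list(attractors = atts,
                 fractions = class_fractions(counts, runs, cn, scheme),
                 n_sampled = n_sampled, seed = as.integer(seed),
                 converged = converged, n_unconverged = n_uncv),
            class = "sampling_result")
}

`%0%` <- function(x, default) { x[is.na(x)] <- default; x }

class_fractions <- function(counts, runs, cn, scheme) {
  total <- sum(counts)
  if (total == 0) return(numeric(0))
  if (is.null(scheme)) return(counts / total)
  cls <- vapply(names(counts), function(k) {
    for (run in runs) {
      cyc <- get0(k, envir = run$resolved$attractors, inherits = FALSE)
      if (!is.null(cyc))
        return(classify_attractor(
          attractor_object(k, cyc, run$engine$bank, cn$n), scheme))
    }
    "other"
  }, character(1))
  out <- tapply(counts, cls, sum) / total
  stats::setNames(as.numeric(out), names(out))
}

#' @export
print.sampling_result <- function(x, ...) {
  cat("<sampling_result>", x$n_sampled, "states sampled;",
      length(x$attractors), "attractors;",
      if (x$converged) "fractions converged" else "fraction tolerance not reached", "\n")
  if (length(x$fractions)) {
    f <- sort(x$fractions, decreasing = TRUE)
    for (i in seq_len(min(6, length(f))))
      cat(sprintf("  %-24s %.3f\n", names(f)[i], f[i]))
  }
  invisible(x)
}

#' Exhaustively enumerate attractors and exact basin sizes
#'
#' Evolves every assignment of the free (non-clamped) nodes and tallies exact
#' basin counts; the oracle against which the sampling engine is tested.
#'
#' @inheritParams sample_attractors
#' @param limit refuse networks with more than this many free nodes
#'   (default 22).
#' @return a `sampling_result` with exact counts (`n_sampled = 2^n_free`).
#' @export
enumerate_attractors <- function(net, cond = NULL, scheme = NULL,
                                 clamps = NULL, limit = 22L,
                                 max_steps = 100000L) {
  cn <- compile_network(net)
  cl <- merge_clamps(cond, clamps)
  ci <- if (length(cl)) node_index(cn$net, names(cl)) else integer()
  free <- setdiff(seq_len(cn$n), ci)
  if (length(free) > limit)
    stop("network has ", length(free), " free nodes; exhaustive enumeration ",
         "is limited to ", limit)
  m <- 2^length(free)
  S <- matrix(0, m, cn$n)
  if (length(free)) {
    bits <- as.matrix(expand.grid(rep(list(c(0, 1)), length(free))))
    S[, free] <- bits
  }
  if (length(ci)) S[, ci] <- rep(as.numeric(cl), each = m)
  run <- run_roots(cn, S, cond, NULL, clamps, max_steps)
  tb <- run$table
  counts <- integer(0)
  tt <- table(tb$attractor[tb$converged])
  for (k in names(tt)) counts[k] <- tt[[k]]
  atts <- list()
  for (a in collect_attractors(run, cn$n)) atts[[a$key]] <- a
  if (!is.null(scheme))
    for (k in names(atts)) atts[[k]]$class <- classify_attractor(atts[[k]], scheme)
  structure(list(attractors = atts,
                 fractions = class_fractions(counts, list(run), cn, scheme),
                 n_sampled = m, seed = NA_integer_,
                 converged = TRUE, n_unconverged = sum(!tb$converged)),
            class = "sampling_result")
}

#' Largest-basin attractor from random sampling
#'
#' @inheritParams sample_attractors
#' @param n_init number of sampled initial states.
#' @return the attractor with the largest sampled basin.
#' @export
largest_attractor <- function(net, cond = NULL, n_init = 10000L, seed = 1L,
                              max_steps = 10000L) {
  sr <- sample_attractors(net, cond, seed = seed, batch = n_init, tol = 1,
                          cap = n_init, max_steps = max_steps)
  counts <- vapply(sr$attractors, function(a) a$basin_count, integer(1))
  sr$attractors[[which.max(counts)]]
}

#' Identify cycling marker nodes along the excited trajectory
#'
#' Finds the largest-basin attractor under the condition, launches the excited
#' trajectory from it (cell-size signal pulsed at t = 0), and returns the
#' protein-kind nodes whose value changes at least once along that trajectory,
#' together with their values in the largest attractor. These markers define
#' the cell-cycle (stationary G1) attractor class.
#'
#' @inheritParams sample_attractors
#' @param n_init samples used to locate the largest attractor.
#' @return list with `markers` (node ids), `reference` (named 0/1 vector of
#'   their attractor values), `attractor`, `trajectory`.
#' @export
identify_cyclic_markers <- function(net, cond = NULL, n_init = 10000L,
                                    seed = 1L, max_steps = 10000L) {
  cn <- compile_network(net)
  att <- largest_attractor(net, cond, n_init = n_init, seed = seed,
                           max_steps = max_steps)
  pulse <- condition(cn, if (is.null(cond)) "none" else cond$name,
                     cell_size = "pulse")
  tr <- evolve(cn, att$states[1, ], pulse, max_steps = max_steps)
  changing <- apply(tr$states, 2, function(v) length(unique(v)) > 1)
  prot <- cn$net$nodes$kind == "protein"
  markers <- cn$ids[changing & prot]
  ref <- stats::setNames(att$states[1, match(markers, cn$ids)], markers)
  list(markers = markers, reference = ref, attractor = att, trajectory = tr)
}
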