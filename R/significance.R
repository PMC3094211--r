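#' Null distribution of a network metric over degree-preserving randomizations
#'
#' Evaluates a metric on an ensemble of [randomize_network()] draws. Draw `i`
#' uses seed `seed + i` (counter-based), so draw `i` is independent of the
#' ensemble size. Reports the ensemble mean and standard deviation, a
#' parametric normal-tail p-value for an observed value, and the
#' add-one-smoothed empirical p-value `(1 + #{null >= observed}) / (n + 1)`.
#'
#' @param net a `regnet`.
#' @param metric function mapping a network to a single numeric value.
#' @param n_random ensemble size (default 1000).
#' @param seed base integer seed.
#' @param observed observed value on the curated network; defaults to
#'   `metric(net)`.
#' @param n_swaps swaps per randomization (passed to [randomize_network()]).
#' @return object of class `null_distribution`: `values`, `mean`, `sd`,
#'   `observed`, `z`, `p_parametric` (upper tail), `p_empirical`,
#'   `n_failed` (draws where the metric errored, excluded).
#' @export
null_distribution <- function(net, metric, n_random = 1000L, seed = 1L,
                              observed = NULL, n_swaps = 10L * nrow(net$edges)) {
  stopifnot(is.function(metric), n_random >= 1)
  if (is.null(observed)) observed <- metric(net)
  values <- rep(NA_real_, n_random)
  failed <- 0L
  for (i in seq_len(n_random)) {
    rn <- randomize_network(net, seed = as.integer(seed) + i, n_swaps = n_swaps)
    v <- tryCatch(metric(rn), error = function(e) NA_real_)
    if (is.na(v)) failed <- failed + 1L
    values[i] <- v
  }
  ok <- values[!is.na(values)]
  m <- mean(ok); s <- stats::sd(ok)
  z <- if (isTRUE(s > 0)) (observed - m) / s else NA_real_
  structure(list(values = values, mean = m, sd = s, observed = observed,
                 z = z,
                 p_parametric = if (is.na(z)) NA_real_ else stats::pnorm(z, lower.tail = FALSE),
                 p_empirical = (1 + sum(ok >= observed)) / (length(ok) + 1),
                 n = length(ok), n_failed = failed, seed = as.integer(seed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution>", x$n, "draws; mean", signif(x$mean, 4),
      "sd", signif(x$sd, 4), "\n  observed", signif(x$observed, 4),
      "-> z", signif(x$z, 4), "; parametric p", signif(x$p_parametric, 3),
      "; empirical p", signif(x$p_empirical, 3), "\n")
  invisible(x)
}

#' Random structural perturbation of a network
#'
#' Applies `k` random edits — adding an edge, deleting an edge, or flipping an
#' edge's direction — for robustness sweeps of the attractor basins. Edges
#' into conjunction (logic_and, phenotype) and signal nodes are protected, as
#' are their existing inputs for deletion/flip. If fewer than `k` feasible
#' edits are found within bounded retries, the partial result is returned with
#' a warning.
#'
#' @param net a `regnet`.
#' @param op `"add_edge"`, `"delete_edge"` or `"flip_direction"`.
#' @param k number of edits (default 1).
#' @param seed integer seed.
#' @return the edited `regnet` with attribute `n_applied`.
#' @export
structural_perturbation <- function(net, op = c("add_edge", "delete_edge",
                                                "flip_direction"),
                                    k = 1L, seed = 1L) {
  op <- match.arg(op)
  stopifnot(k >= 1)
  set.seed(as.integer(seed))
  protected_targets <- net$nodes$id[net$nodes$kind %in%
                                      c(CONJUNCTION_KINDS, "signal")]
  edges <- net$edges
  applied <- 0L; tries <- 0L; max_tries <- 200L * k
  while (applied < k && tries < max_tries) {
    tries <- tries + 1L
    if (op == "add_edge") {
      src <- sample(net$nodes$id, 1)
      tgt <- sample(setdiff(net$nodes$id, c(src, protected_targets)), 1)
      if (any(edges$source == src & edges$target == tgt)) next
      row <- edges[0, , drop = FALSE]
      row[1, c("source", "target")] <- c(src, tgt)
      row$sign[1] <- sample(c(-1L, 1L), 1)
      edges <- rbind(edges, row)
      applied <- applied + 1L
    } else {
      free <- which(!(edges$target %in% protected_targets))
      if (!length(free)) break
      ei <- if (length(free) == 1) free else sample(free, 1)
      if (op == "delete_edge") {
        edges <- edges[-ei, , drop = FALSE]
        applied <- applied + 1L
      } else {
        s <- edges$source[ei]; t <- edges$target[ei]
        if (s %in% protected_targets) next
        if (any(edges$source == t & edges$target == s)) next
        edges$source[ei] <- t; edges$target[ei] <- s
        applied <- applied + 1L
      }
    }
  }
  if (applied < k)
    warning("only ", applied, " of ", k, " edits were feasible")
  out <- net
  rownames(edges) <- NULL
  out$edges <- edges
  validate_network(out)
  attr(out, "n_applied") <- applied
  out
}
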