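#' Construct a perturbation recipe
#'
#' A recipe is a set of 1 to `max_size` distinct protein nodes each assigned a
#' direction: `OE` (overexpression, node set to 1) or `KD` (knockdown, node
#' set to 0). `transient` recipes override the initial state only (the
#' iPS-style perturbation); `clamped` recipes hold the values at every step
#' (deletion / constitutive overexpression).
#'
#' @param perturbations named character vector, e.g.
#'   `c(GCN5 = "OE", RPD3 = "KD")`, or a recipe string `"GCN5:OE+RPD3:KD"`.
#' @param mode `"transient"` or `"clamped"`.
#' @return object of class `recipe`.
#' @export
recipe <- function(perturbations, mode = c("transient", "clamped")) {
  mode <- match.arg(mode)
  if (is.character(perturbations) && is.null(names(perturbations)) &&
      length(perturbations) == 1) {
    parts <- strsplit(strsplit(perturbations, "+", fixed = TRUE)[[1]], ":", fixed = TRUE)
    perturbations <- stats::setNames(vapply(parts, `[`, "", 2),
                                     vapply(parts, `[`, "", 1))
  }
  stopifnot(length(perturbations) >= 1,
            all(perturbations %in% c("OE", "KD")),
            !anyDuplicated(names(perturbations)))
  structure(list(perturbations = perturbations, mode = mode), class = "recipe")
}

#' @export
format.recipe <- function(x, ...) {
  paste(paste0(names(x$perturbations), ":", x$perturbations), collapse = "+")
}

#' @export
print.recipe <- function(x, ...) {
  cat("<recipe>", format(x), sprintf("(%s)\n", x$mode)); invisible(x)
}

recipe_values <- function(rec) {
  stats::setNames(ifelse(rec$perturbations == "OE", 1, 0),
                  names(rec$perturbations))
}

#' Count all perturbation recipes
#'
#' Closed form for the number of knockdown/overexpression combinations of 1 to
#' `max_size` of `n` proteins: `sum_k choose(n, k) * 2^k`.
#'
#' @param n number of perturbable proteins.
#' @param max_size maximum recipe size (default 4).
#' @return the exact count.
#' @export
recipe_count <- function(n, max_size = 4L) {
  k <- seq_len(min(max_size, n))
  sum(choose(n, k) * 2^k)
}

#' Enumerate perturbation recipes
#'
#' Yields every subset of 1..`max_size` perturbable nodes crossed with all
#' direction assignments, each exactly once, in a deterministic order (sizes
#' ascending, node combinations in `combn` order, direction assignments in
#' binary order with KD = 0, OE = 1). For large spaces use the chunked
#' iterator to screen in shards.
#'
#' @param perturbable character vector of perturbable node ids.
#' @param max_size maximum recipe size.
#' @param materialize return the full list of recipe strings (only allowed
#'   when the count is at most `limit`).
#' @param limit guard for materialization (default 2e5).
#' @return list with `count` and either `recipes` (character vector of recipe
#'   strings) or `next_chunk(m)`, a closure returning the next `m` recipe
#'   strings (`NULL` when exhausted).
#' @export
enumerate_recipes <- function(perturbable, max_size = 4L, materialize = TRUE,
                              limit = 200000L) {
  stopifnot(length(perturbable) >= 1, max_size >= 1)
  n <- length(perturbable)
  count <- recipe_count(n, max_size)
  gen_state <- new.env()
  gen_state$k <- 1L
  gen_state$combos <- utils::combn(n, 1L)
  gen_state$ci <- 1L
  gen_state$dirs <- 0L
  next_one <- function() {
    repeat {
      if (gen_state$k > min(max_size, n)) return(NULL)
      if (gen_state$ci > ncol(gen_state$combos)) {
        gen_state$k <- gen_state$k + 1L
        if (gen_state$k > min(max_size, n)) return(NULL)
        gen_state$combos <- utils::combn(n, gen_state$k)
        gen_state$ci <- 1L; gen_state$dirs <- 0L
        next
      }
      k <- gen_state$k
      if (gen_state$dirs >= 2^k) {
        gen_state$ci <- gen_state$ci + 1L; gen_state$dirs <- 0L
        next
      }
      nodes <- perturbable[gen_state$combos[, gen_state$ci]]
      bits <- (gen_state$dirs %/% 2^(0:(k - 1))) %% 2
      gen_state$dirs <- gen_state$dirs + 1L
      return(paste(paste0(nodes, ":", ifelse(bits == 1, "OE", "KD")),
                   collapse = "+"))
    }
  }
  next_chunk <- function(m) {
    out <- character(0)
    while (length(out) < m) {
      r <- next_one()
      if (is.null(r)) break
      out <- c(out, r)
    }
    if (length(out)) out else NULL
  }
  if (materialize) {
    if (count > limit)
      stop("recipe space has ", count, " members; use materialize = FALSE")
    list(count = count, recipes = next_chunk(count))
  } else {
    list(count = count, next_chunk = next_chunk)
  }
}

#' Potency of a reprogramming recipe
#'
#' Samples random initial states, applies the recipe (transient override at
#' t = 0, or permanent clamps for clamped recipes), evolves under the
#' condition, and classifies the attractors. Potency is the fraction reaching
#' the target class; the reprogramming flag records whether the perturbation
#' reverses the wild-type preference, i.e. whether the target-class fraction
#' strictly exceeds the opposite class's fraction.
#'
#' @param net a `regnet` or compiled network.
#' @param rec a [recipe()], or `NULL` for the wild-type baseline.
#' @param cond a [condition()].
#' @param target_class `"sporulation"` or `"cell_cycle"`.
#' @param scheme a [classification_scheme()].
#' @param n sampled initial states (default 10000).
#' @param seed integer seed.
#' @return list: `potency`, `fractions` (per class), `reprogramming` flag.
#' @export
potency <- function(net, rec, cond, target_class = c("sporulation", "cell_cycle"),
                    scheme, n = 10000L, seed = 1L, max_steps = 10000L) {
  target_class <- match.arg(target_class)
  cn <- compile_network(net)
  overrides <- NULL; clamps <- NULL
  if (!is.null(rec)) {
    v <- recipe_values(rec)
    if (rec$mode == "transient") overrides <- v else clamps <- v
  }
  sr <- sample_attractors(cn, cond, seed = seed, batch = n, tol = 1, cap = n,
                          scheme = scheme, clamps = clamps,
                          overrides = overrides, max_steps = max_steps)
  frac <- sr$fractions
  pot <- as.numeric(frac[target_class] %0% 0)
  opposite <- setdiff(c("sporulation", "cell_cycle"), target_class)
  list(potency = pot, fractions = frac,
       reprogramming = pot > as.numeric(frac[opposite] %0% 0))
}

#' Evolving distance of a state to its attractor
#'
#' Number of synchronous steps from the state to the first attractor state
#' under the condition (0 for attractor states).
#'
#' @inheritParams potency
#' @param state binary state vector.
#' @return list: `d`, `attractor_key`, `converged`.
#' @export
evolving_distance <- function(net, state, cond = NULL, clamps = NULL,
                              max_steps = 10000L) {
  tr <- evolve(net, state, cond, clamps = clamps, max_steps = max_steps)
  list(d = tr$steps_to_attractor,
       attractor_key = if (tr$converged) tr$attractor$key else NA_character_,
       converged = tr$converged)
}

#' Harvest sporulation-committed states and reprogrammed-fraction curves
#'
#' Evolves random initial states under the sporulation condition, keeps the
#' initial and on-path states of trajectories converging to sporulation
#' attractors (de-duplicated by state key) with their evolving distance `d` to
#' the attractor, then re-evolves every harvested state under the growth
#' condition — optionally with a recipe — and tallies the fraction
#' reprogrammed (reaching cell-cycle attractors) per distance bin. States with
#' `d` at most `commit_depth` that the bare condition switch fails to
#' reprogram form the committed set.
#'
#' @param net a `regnet` or compiled network.
#' @param scheme a [classification_scheme()].
#' @param n_init random initial states to harvest from (default 10000).
#' @param rec optional [recipe()] applied (transiently) together with the
#'   condition switch.
#' @param commit_depth maximum evolving distance for commitment (default 4).
#' @param seed integer seed.
#' @param max_d largest distance bin reported.
#' @return object of class `commitment_set`: `states` data.frame (key, d,
#'   reprogrammed_switch_only, committed), `curve` data.frame (d, n,
#'   fraction_reprogrammed) for the wild-type switch or recipe run,
#'   `state_bank` (matrix of the harvested states).
#' @export
commitment_analysis <- function(net, scheme, n_init = 10000L, rec = NULL,
                                commit_depth = 4L, seed = 1L, max_d = 20L,
                                max_steps = 10000L) {
  cn <- compile_network(net)
  set.seed(as.integer(seed))
  spor <- condition(cn, "sporulation")
  ci <- if (length(spor$clamps)) node_index(cn$net, names(spor$clamps)) else integer()
  roots <- random_states(cn, n_init, ci, as.numeric(spor$clamps))
  run <- run_roots(cn, roots, spor, max_steps = max_steps)
  # classify attractors; keep states on paths into sporulation attractors
  keep_attr <- character(0)
  for (a in collect_attractors(run, cn$n))
    if (classify_attractor(a, scheme) == "sporulation")
      keep_attr <- c(keep_attr, a$key)
  all_keys <- ls(run$resolved$res)
  info <- lapply(all_keys, function(k) get(k, envir = run$resolved$res))
  attr_of <- vapply(info, function(x) x$attr %0% NA_character_, character(1))
  d_of <- vapply(info, function(x) as.integer(x$d %0% NA_integer_), integer(1))
  sel <- !is.na(attr_of) & attr_of %in% keep_attr
  keys <- all_keys[sel]; d <- d_of[sel]
  if (!length(keys))
    return(structure(list(states = data.frame(), curve = data.frame(),
                          state_bank = NULL), class = "commitment_set"))
  bank <- do.call(rbind, lapply(keys, function(k)
    get(k, envir = run$engine$bank, inherits = FALSE)))
  rownames(bank) <- keys
  # switch to growth (optionally + recipe), re-evolve every harvested state
  grow <- condition(cn, "growth")
  overrides <- if (!is.null(rec)) recipe_values(rec) else NULL
  run2 <- run_roots(cn, bank, grow, overrides = overrides, max_steps = max_steps)
  cls2 <- attractor_classes(run2, cn, scheme)
  reprog <- cls2[run2$table$attractor] %0% "other" == "cell_cycle" &
    run2$table$converged
  dcap <- pmin(d, max_d)
  curve <- do.call(rbind, lapply(sort(unique(dcap)), function(dd) {
    ix <- dcap == dd
    data.frame(d = dd, n = sum(ix), fraction_reprogrammed = mean(reprog[ix]))
  }))
  committed <- d <= commit_depth & !reprog
  if (!is.null(rec)) {
    # committed is defined against the bare condition switch
    run_wt <- run_roots(cn, bank, grow, max_steps = max_steps)
    cls_wt <- attractor_classes(run_wt, cn, scheme)
    reprog_wt <- cls_wt[run_wt$table$attractor] %0% "other" == "cell_cycle" &
      run_wt$table$converged
    committed <- d <= commit_depth & !reprog_wt
  }
  structure(list(
    states = data.frame(key = keys, d = d,
                        reprogrammed = as.logical(reprog),
                        committed = as.logical(committed),
                        stringsAsFactors = FALSE),
    curve = curve, state_bank = bank), class = "commitment_set")
}

## class label per attractor key present in a run
attractor_classes <- function(run, cn, scheme) {
  atts <- collect_attractors(run, cn$n)
  stats::setNames(vapply(atts, classify_attractor, character(1), scheme = scheme),
                  vapply(atts, function(a) a$key, character(1)))
}

#' Reprogramming efficiency on committed states
#'
#' Fraction of sporulation-committed states that a recipe (applied
#' transiently, with the condition switched to growth) converts to cell-cycle
#' attractors.
#'
#' @param net a `regnet` or compiled network.
#' @param rec a [recipe()].
#' @param committed a `commitment_set` from [commitment_analysis()].
#' @param scheme a [classification_scheme()].
#' @param n states sampled from the committed set (default 10000); sampled
#'   with replacement, with a flag, when the set is smaller.
#' @param seed integer seed.
#' @return fraction in \[0, 1\] with attribute `resampled`.
#' @export
efficiency <- function(net, rec, committed, scheme, n = 10000L, seed = 1L,
                       max_steps = 10000L) {
  cn <- compile_network(net)
  keys <- committed$states$key[committed$states$committed]
  if (!length(keys)) stop("committed set is empty")
  set.seed(as.integer(seed))
  resampled <- length(keys) < n
  pick <- if (resampled) sample(keys, n, replace = TRUE)
    else sample(keys, n)
  S <- committed$state_bank[pick, , drop = FALSE]
  grow <- condition(cn, "growth")
  run <- run_roots(cn, S, grow, overrides = recipe_values(rec),
                   max_steps = max_steps)
  cls <- attractor_classes(run, cn, scheme)
  eff <- mean(cls[run$table$attractor] %0% "other" == "cell_cycle" &
                run$table$converged)
  structure(eff, resampled = resampled)
}

#' Heterogeneity profile over reference attractors
#'
#' Fractions of random initial states converging to each of a fixed list of
#' reference attractors (the wild type's cell-cycle attractors). Cell-cycle
#' attractors not on the reference list are tallied in the `unmatched`
#' attribute.
#'
#' @param net a `regnet` or compiled network.
#' @param rec optional [recipe()] (transient) applied to every initial state.
#' @param reference character vector of reference attractor keys.
#' @param cond a [condition()] (growth for the curated use case).
#' @param scheme a [classification_scheme()].
#' @param n sampled initial states.
#' @param seed integer seed.
#' @return named numeric vector (class `heterogeneity_profile`) over the
#'   reference keys, fractions of sampled states; attributes `unmatched`
#'   (fraction in off-list cell-cycle attractors) and `n`.
#' @export
heterogeneity_profile <- function(net, rec = NULL, reference, cond, scheme,
                                  n = 10000L, seed = 1L, max_steps = 10000L) {
  cn <- compile_network(net)
  overrides <- if (!is.null(rec)) recipe_values(rec) else NULL
  sr <- sample_attractors(cn, cond, seed = seed, batch = n, tol = 1, cap = n,
                          overrides = overrides, max_steps = max_steps)
  counts <- vapply(sr$attractors, function(a) a$basin_count, integer(1))
  keys <- names(sr$attractors)
  prof <- stats::setNames(numeric(length(reference)), reference)
  hit <- intersect(keys, reference)
  prof[hit] <- counts[hit] / sr$n_sampled
  cls <- vapply(sr$attractors, classify_attractor, character(1), scheme = scheme)
  unmatched <- sum(counts[cls == "cell_cycle" & !keys %in% reference]) / sr$n_sampled
  structure(prof, class = "heterogeneity_profile", unmatched = unmatched,
            n = sr$n_sampled)
}

#' Heterogeneity deviation between two profiles
#'
#' Total-variation distance between the profiles after renormalizing each over
#' the shared reference attractors: `0.5 * sum(|w - x|)`. Zero iff the
#' renormalized profiles coincide; one for disjoint support.
#'
#' @param w,x profiles over the same attractor list (named vectors).
#' @return deviation in \[0, 1\].
#' @export
heterogeneity_deviation <- function(w, x) {
  if (is.null(names(w)) || is.null(names(x)) ||
      !identical(sort(names(w)), sort(names(x))))
    stop("profiles must cover the same attractor list")
  x <- x[names(w)]
  wn <- if (sum(w) > 0) w / sum(w) else w
  xn <- if (sum(x) > 0) x / sum(x) else x
  0.5 * sum(abs(wn - xn))
}

#' Pareto-optimal recipes for efficiency versus heterogeneity deviation
#'
#' Non-dominated subset maximizing efficiency and minimizing deviation; a
#' recipe is dominated when another is at least as good on both criteria and
#' strictly better on one. Result ordered by decreasing efficiency.
#'
#' @param scores data.frame with columns `efficiency` and `deviation` (other
#'   columns, e.g. `recipe`, are carried through).
#' @return the non-dominated rows.
#' @export
pareto_front <- function(scores) {
  if (!NROW(scores)) return(scores)
  eff <- scores$efficiency; dev <- scores$deviation
  keep <- vapply(seq_along(eff), function(i) {
    dom <- (eff >= eff[i] & dev <= dev[i]) & (eff > eff[i] | dev < dev[i])
    !any(dom)
  }, logical(1))
  out <- scores[keep, , drop = FALSE]
  out[order(-out$efficiency, out$deviation), , drop = FALSE]
}

#' Frequencies of individual perturbations in a recipe list
#'
#' Occurrences of each (node, direction) pair divided by the total number of
#' perturbation slots across the list; the frequencies sum to one.
#'
#' @param recipes list of [recipe()] objects or recipe strings.
#' @return data.frame (node, direction, frequency), ordered by decreasing
#'   frequency.
#' @export
perturbation_frequencies <- function(recipes) {
  stopifnot(length(recipes) >= 1)
  recs <- lapply(recipes, function(r) if (inherits(r, "recipe")) r else recipe(r))
  slots <- do.call(rbind, lapply(recs, function(r)
    data.frame(node = names(r$perturbations),
               direction = unname(r$perturbations),
               stringsAsFactors = FALSE)))
  tab <- stats::aggregate(list(count = rep(1L, nrow(slots))),
                          slots[c("node", "direction")], sum)
  tab$frequency <- tab$count / nrow(slots)
  tab <- tab[order(-tab$frequency, tab$node), c("node", "direction", "frequency")]
  rownames(tab) <- NULL
  tab
}

#' Screen a set of recipes for potency
#'
#' Evaluates [potency()] for each recipe (character strings or objects) and
#' returns a score table sorted by decreasing potency. This is the shardable
#' unit of the exhaustive search: feed it chunks from
#' [enumerate_recipes()]`$next_chunk`.
#'
#' @inheritParams potency
#' @param recipes character vector of recipe strings (transient mode).
#' @return data.frame: recipe, potency, reprogramming flag.
#' @export
screen_recipes <- function(net, recipes, cond, target_class, scheme,
                           n = 1000L, seed = 1L, max_steps = 10000L) {
  cn <- compile_network(net)
  rows <- lapply(seq_along(recipes), function(i) {
    p <- potency(cn, recipe(recipes[[i]]), cond, target_class, scheme,
                 n = n, seed = seed, max_steps = max_steps)
    data.frame(recipe = if (is.character(recipes[[i]])) recipes[[i]]
               else format(recipes[[i]]),
               potency = p$potency, reprogramming = p$reprogramming,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$potency), , drop = FALSE]
}
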