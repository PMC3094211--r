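#' Marker-based attractor classification scheme
#'
#' An attractor is called `sporulation` when the sporulation phenotype node is
#' on, `cell_cycle` when every marker node matches its reference value in the
#' largest growth-condition attractor (all other nodes free), and `other`
#' otherwise. The marker set is normally derived with
#' [identify_cyclic_markers()].
#'
#' @param net a `regnet` or compiled network (supplies the phenotype node id).
#' @param markers character vector of marker node ids.
#' @param reference named 0/1 vector: marker values in the reference
#'   (stationary G1) attractor.
#' @param spor_node id of the sporulation phenotype node; defaults to the
#'   network's `spor_node` signal designation.
#' @return object of class `classification_scheme`.
#' @export
classification_scheme <- function(net, markers, reference,
                                  spor_node = NULL) {
  cn <- compile_network(net)
  if (is.null(spor_node)) spor_node <- cn$net$signals$spor_node
  stopifnot(all(markers %in% cn$ids),
            all(names(reference) == markers),
            all(reference %in% c(0, 1)))
  structure(list(spor_node = spor_node, markers = markers,
                 reference = reference, ids = cn$ids),
            class = "classification_scheme")
}

#' Derive a classification scheme from the network's own dynamics
#'
#' Convenience wrapper: runs [identify_cyclic_markers()] under the growth
#' condition and packages the result as a [classification_scheme()].
#'
#' @inheritParams identify_cyclic_markers
#' @return a `classification_scheme`.
#' @export
derive_scheme <- function(net, n_init = 10000L, seed = 1L, max_steps = 10000L) {
  cn <- compile_network(net)
  mk <- identify_cyclic_markers(cn, condition(cn, "growth"), n_init = n_init,
                                seed = seed, max_steps = max_steps)
  classification_scheme(cn, mk$markers, mk$reference)
}

#' Classify an attractor as sporulation, cell cycle or other
#'
#' Sporulation takes precedence: the phenotype node must be on in every state
#' of the attractor. Cell cycle requires every marker node to equal its
#' reference value in every attractor state. Everything else is `other`, so
#' the three classes partition the attractor set.
#'
#' @param attr an `attractor`.
#' @param scheme a [classification_scheme()].
#' @return one of `"sporulation"`, `"cell_cycle"`, `"other"`.
#' @export
classify_attractor <- function(attr, scheme) {
  S <- attr$states
  if (!is.null(scheme$spor_node)) {
    si <- match(scheme$spor_node, scheme$ids)
    if (all(S[, si] == 1)) return("sporulation")
  }
  mi <- match(scheme$markers, scheme$ids)
  if (length(mi) &&
      all(S[, mi, drop = FALSE] == rep(scheme$reference, each = nrow(S))))
    return("cell_cycle")
  "other"
}

#' Sporulation fraction of a (possibly mutated) network
#'
#' Fraction of random initial states whose attractor has the sporulation
#' phenotype node on; mutation clamps are applied permanently at every step.
#'
#' @param net a `regnet` or compiled network.
#' @param mutation named 0/1 vector of clamped nodes (0 = deletion,
#'   1 = overexpression); `NULL` for wild type.
#' @param cond a [condition()].
#' @param n number of sampled initial states (default 10000).
#' @param seed integer seed.
#' @param scheme optional classification scheme (defaults to SPOR-on call).
#' @return fraction in \[0, 1\].
#' @export
sporulation_fraction <- function(net, mutation = NULL, cond = NULL,
                                 n = 10000L, seed = 1L, scheme = NULL) {
  cn <- compile_network(net)
  if (is.null(scheme)) {
    spor <- cn$net$signals$spor_node
    if (is.null(spor)) stop("network has no sporulation phenotype node designated")
    scheme <- classification_scheme(cn, character(0),
                                    stats::setNames(numeric(0), character(0)),
                                    spor_node = spor)
  }
  sr <- sample_attractors(cn, cond, seed = seed, batch = n, tol = 1, cap = n,
                          scheme = scheme, clamps = mutation)
  as.numeric(sr$fractions["sporulation"] %0% 0)
}

#' Predicted Prespo/Spore ratio
#'
#' Ratio of the wild-type to the mutant sporulation fraction: mutants that
#' sporulate less than wild type score above 1 (sporulation deficient), like
#' the experimental ratio of cells not completing to completing sporulation.
#'
#' @param f_wt wild-type sporulation fraction (> 0).
#' @param f_mut mutant sporulation fraction.
#' @return `f_wt / f_mut`; if `f_mut` is 0 an `Inf` sentinel carrying
#'   attribute `undefined = TRUE` (rank statistics tolerate it).
#' @export
predicted_prespo_spore_ratio <- function(f_wt, f_mut) {
  if (any(f_wt <= 0)) stop("wild-type sporulation fraction must be positive")
  out <- f_wt / f_mut
  if (any(f_mut == 0)) attr(out, "undefined") <- TRUE
  out
}

#' Phase weight matrix
#'
#' Weights `w[i, j]` in \[0, 1\] give the contribution of marker node `i` to
#' cell-cycle phase `j`; a node that is on contributes `w`, a node that is off
#' contributes `1 - w`, and the per-phase score is the product over markers.
#'
#' @param w numeric matrix, rows = marker node ids, columns = phases.
#' @param phases ordered phase names (default START, G1, S, G2, M,
#'   stationary_G1).
#' @return object of class `phase_weights`.
#' @export
phase_weights <- function(w, phases = CC_PHASES) {
  w <- as.matrix(w)
  stopifnot(ncol(w) == length(phases), all(w >= 0 & w <= 1),
            !is.null(rownames(w)))
  colnames(w) <- phases
  structure(list(w = w, phases = phases), class = "phase_weights")
}

CC_PHASES <- c("START", "G1", "S", "G2", "M", "stationary_G1")

#' Derive phase weights from a labeled trajectory
#'
#' Implements the initialization-plus-fine-tuning rule for the phase weights.
#' Starting from the biological (excited) trajectory with each state labeled
#' by phase, a node active in phase `j` gets weight near 1 and an inactive
#' node weight near 0 (phase-mean activity mapped onto \[`lo`, `hi`\]). The
#' weights are then fine-tuned — mirroring the manual adjustment of weights
#' like 1 to 0.8 or 0 to 0.1 — by small deterministic corrections until every
#' trajectory state is assigned to its own phase: a misassigned state pulls
#' its true phase's weights toward the state and pushes the winning wrong
#' phase's weights away.
#'
#' @param states trajectory state matrix (columns named by node).
#' @param labels phase label per state (values from `phases`).
#' @param markers marker node ids (rows of the result).
#' @param phases ordered phase names.
#' @param hi,lo initialization targets for fully-on / fully-off weights
#'   (defaults 0.9 / 0.1).
#' @param calibrate fine-tune until the training states assign correctly
#'   (default TRUE).
#' @param rate,max_rounds calibration step size and iteration budget.
#' @return a [phase_weights()] object; attribute `calibrated` reports whether
#'   every training state is assigned to its labeled phase.
#' @export
derive_phase_weights <- function(states, labels, markers,
                                 phases = CC_PHASES, hi = 0.9, lo = 0.1,
                                 calibrate = TRUE, rate = 0.15,
                                 max_rounds = 200L) {
  stopifnot(length(labels) == nrow(states), all(labels %in% phases),
            all(markers %in% colnames(states)))
  w <- sapply(phases, function(ph) {
    rows <- which(labels == ph)
    if (!length(rows)) return(rep(lo, length(markers)))
    lo + (hi - lo) * colMeans(states[rows, markers, drop = FALSE])
  })
  rownames(w) <- markers
  pw <- phase_weights(w, phases)
  ok <- FALSE
  if (calibrate) {
    S <- states[, markers, drop = FALSE]
    for (round in seq_len(max_rounds)) {
      ok <- TRUE
      for (i in seq_len(nrow(S))) {
        a <- assign_phase(S[i, ], pw)
        if (identical(a$phase, labels[i]) && !a$tie) next
        ok <- FALSE
        tw <- pw$w[, labels[i]]
        pw$w[, labels[i]] <- pmin(0.98, pmax(0.02, tw + rate * (S[i, ] - tw)))
        if (!is.na(a$phase) && a$phase != labels[i]) {
          ww <- pw$w[, a$phase]
          pw$w[, a$phase] <- pmin(0.98, pmax(0.02, ww - rate * (S[i, ] - ww)))
        }
      }
      if (ok) break
    }
  }
  attr(pw, "calibrated") <- ok
  pw
}

#' Assign a state to a cell-cycle phase
#'
#' Per-phase raw score: product over marker nodes of `w[i, j]` when the node
#' is on and `1 - w[i, j]` when off. Scores are normalized to sum to one
#' across phases; the phase is the argmax, ties resolved to the earliest
#' phase in canonical order with a `tie` flag.
#'
#' @param state named binary vector (or full network state with named
#'   entries covering the markers).
#' @param weights a [phase_weights()].
#' @return list: `phase` (or `NA` with `unassignable = TRUE` when every raw
#'   score is zero), `scores` (normalized, named by phase), `tie`.
#' @export
assign_phase <- function(state, weights) {
  w <- weights$w
  s <- state[rownames(w)]
  if (anyNA(s)) stop("state does not cover all marker nodes")
  contrib <- w * s + (1 - w) * (1 - s)
  raw <- apply(contrib, 2, prod)
  if (all(raw == 0))
    return(list(phase = NA_character_, scores = raw, tie = FALSE,
                unassignable = TRUE))
  scores <- raw / sum(raw)
  top <- which(scores == max(scores))
  list(phase = weights$phases[top[1]], scores = scores,
       tie = length(top) > 1, unassignable = FALSE)
}

#' Viability call for a mutant strain
#'
#' Evolves the network from the START state (largest growth attractor with the
#' cell-size signal pulsed at t = 0) with the mutation clamped permanently,
#' assigns each trajectory state to a phase, collapses consecutive repeats,
#' and calls the strain viable iff (i) the trajectory converges to a
#' cell-cycle attractor and (ii) the collapsed phase sequence is
#' START, G1, S, G2, M, stationary G1 with an optional G1 between M and
#' stationary G1 (phase durations are not constrained).
#'
#' @param net a `regnet` or compiled network.
#' @param mutation named 0/1 clamp vector; `NULL` for wild type.
#' @param scheme a [classification_scheme()].
#' @param weights a [phase_weights()].
#' @param start_state optional START-launch state (defaults to the largest
#'   growth attractor found by sampling).
#' @param n_init,seed,max_steps sampling controls for locating the largest
#'   attractor when `start_state` is missing.
#' @return list: `viable`, `phase_sequence` (collapsed), `reason`,
#'   `trajectory`.
#' @export
check_viability <- function(net, mutation = NULL, scheme, weights,
                            start_state = NULL, n_init = 10000L, seed = 1L,
                            max_steps = 10000L) {
  cn <- compile_network(net)
  grow <- condition(cn, "growth", cell_size = "pulse")
  if (is.null(start_state)) {
    att <- largest_attractor(cn, condition(cn, "growth"), n_init = n_init,
                             seed = seed, max_steps = max_steps)
    start_state <- att$states[1, ]
  }
  tr <- evolve(cn, start_state, grow, clamps = mutation, max_steps = max_steps)
  if (!tr$converged)
    return(list(viable = FALSE, phase_sequence = character(0),
                reason = "no attractor", trajectory = tr))
  # drop the launch state (size signal on, marker values still stationary G1):
  # the excitation is only visible from the next step on
  S <- if (nrow(tr$states) > 1) tr$states[-1, , drop = FALSE] else tr$states
  phases <- vapply(seq_len(nrow(S)), function(i) {
    a <- assign_phase(stats::setNames(S[i, ], cn$ids), weights)
    if (isTRUE(a$unassignable)) "unassignable" else a$phase
  }, character(1))
  seq_collapsed <- rle(phases)$values
  ok_order <- identical(seq_collapsed, c("START", "G1", "S", "G2", "M", "stationary_G1")) ||
    identical(seq_collapsed, c("START", "G1", "S", "G2", "M", "G1", "stationary_G1"))
  ok_attr <- classify_attractor(tr$attractor, scheme) == "cell_cycle"
  viable <- ok_order && ok_attr
  reason <- if (viable) "ok"
    else if (!ok_attr) "did not converge to the cell-cycle attractor"
    else "phase order violated"
  list(viable = viable, phase_sequence = seq_collapsed, reason = reason,
       trajectory = tr)
}

#' Matthews correlation coefficient
#'
#' @param tp,tn,fp,fn non-negative confusion counts (or pass a single list /
#'   vector with those names as `tp`).
#' @return MCC in \[-1, 1\]; 0 when any denominator factor is zero.
#' @export
mcc <- function(tp, tn, fp, fn) {
  if (is.list(tp) || (length(tp) == 4 && !missing(tp) && missing(tn))) {
    x <- unlist(tp); tn <- x[["tn"]]; fp <- x[["fp"]]; fn <- x[["fn"]]; tp <- x[["tp"]]
  }
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  ((tp * tn) - (fp * fn)) / sqrt(denom)
}

#' Evaluate predictions against an experimental table
#'
#' Joins predictions and experimental values on shared mutant identifiers and
#' reports Pearson r (with its t-test p-value on n - 2 degrees of freedom),
#' Spearman rho, and — for binary viable/inviable data — accuracy and MCC.
#' Non-finite predicted ratios (infinite Prespo/Spore sentinels) are kept for
#' the rank statistics and dropped, with a flag, from the Pearson pair set.
#'
#' @param predictions named numeric or character vector (names = mutant ids),
#'   or a data.frame with columns `mutant_id`, `value`.
#' @param table experimental data: a data.frame with `mutant_id`, `value`, or
#'   a path to such a TSV.
#' @return list: `n`, `pearson_r`, `p_value`, `spearman_rho`, `accuracy`,
#'   `mcc` (the last two `NA` for numeric tables).
#' @export
evaluate_against_table <- function(predictions, table) {
  as_tbl <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x))
      x <- utils::read.delim(x, stringsAsFactors = FALSE)
    if (is.data.frame(x)) stats::setNames(x$value, x$mutant_id) else x
  }
  pred <- as_tbl(predictions); obs <- as_tbl(table)
  shared <- intersect(names(pred), names(obs))
  if (length(shared) < 3) stop("fewer than 3 shared mutants")
  p <- pred[shared]; o <- obs[shared]
  if (is.numeric(p) && is.numeric(o)) {
    fin <- is.finite(p) & is.finite(o)
    ct <- stats::cor.test(p[fin], o[fin], method = "pearson")
    rho <- stats::cor(p, o, method = "spearman")
    list(n = length(shared), pearson_r = unname(ct$estimate),
         p_value = ct$p.value, spearman_rho = rho,
         accuracy = NA_real_, mcc = NA_real_,
         dropped_nonfinite = sum(!fin))
  } else {
    p <- as.character(p); o <- as.character(o)
    pos <- "viable"
    tp <- sum(p == pos & o == pos); tn <- sum(p != pos & o != pos)
    fp <- sum(p == pos & o != pos); fn <- sum(p != pos & o == pos)
    list(n = length(shared), pearson_r = NA_real_, p_value = NA_real_,
         spearman_rho = NA_real_,
         accuracy = (tp + tn) / length(shared),
         mcc = mcc(tp, tn, fp, fn), dropped_nonfinite = 0L)
  }
}
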