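test_that("the update rule follows the signed-sum threshold and self-modes", {
  # one activator on, no repressor: F = 1 -> on
  net <- toy_chain(2)
  s <- step(net, c(1, 0))
  expect_equal(unname(s["b"]), 1)
  # F = 0 tie-break per self-mode, for a node currently on and off
  for (mode in c("degradation", "sustaining", "activation")) {
    iso <- regnet(data.frame(id = "x", kind = "protein", self_mode = mode))
    on  <- unname(step(iso, 1)["x"])
    off <- unname(step(iso, 0)["x"])
    expected <- switch(mode, degradation = c(0, 0), sustaining = c(1, 0),
                       activation = c(1, 1))
    expect_equal(c(on, off), expected)
  }
  # balanced activation and repression is a tie
  bal <- regnet(data.frame(id = c("p", "q", "r"), kind = "protein",
                           self_mode = c("sustaining", "sustaining", "degradation")),
                data.frame(source = c("p", "q"), target = c("r", "r"),
                           sign = c(1L, -1L)))
  expect_equal(unname(step(bal, c(1, 1, 1))["r"]), 0)
})

test_that("all-zero state is a fixed point when nothing self-activates", {
  net <- random_net(4)
  net$nodes$self_mode[net$nodes$self_mode == "activation"] <- "degradation"
  s0 <- rep(0, nrow(net$nodes))
  expect_equal(unname(step(net, s0)), s0)
  tr <- evolve(net, s0)
  expect_equal(tr$steps_to_attractor, 0)
  expect_equal(tr$attractor$period, 1)
})

test_that("conjunction nodes require every parent on", {
  net <- regnet(data.frame(id = c("a", "b", "x"),
                           kind = c("protein", "protein", "logic_and"),
                           self_mode = "sustaining"),
                data.frame(source = c("a", "b"), target = c("x", "x"),
                           sign = c(1L, 1L)))
  expect_equal(unname(step(net, c(1, 1, 0))["x"]), 1)
  expect_equal(unname(step(net, c(1, 0, 0))["x"]), 0)
  expect_equal(unname(step(net, c(0, 0, 1))["x"]), 0)
})

test_that("clamped nodes never deviate from their clamp", {
  net <- random_net(11, n = 7)
  cl <- c(n03 = 1, n05 = 0)
  set.seed(1)
  for (rep in 1:20) {
    s0 <- sample(c(0, 1), 7, replace = TRUE)
    tr <- evolve(net, s0, clamps = cl)
    expect_true(all(tr$states[, "n03"] == 1))
    expect_true(all(tr$states[, "n05"] == 0))
  }
})

test_that("trajectories match the independent brute-force oracle", {
  for (seed in c(1, 2, 3, 7, 19)) {
    net <- random_net(seed, n = 6, density = 0.3)
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
    for (r in seq_len(nrow(grid))) {
      got <- evolve(net, grid[r, ])
      want <- oracle_evolve(net, grid[r, ])
      expect_equal(got$steps_to_attractor, want$steps_to_attractor)
      expect_equal(got$attractor$period, want$period)
      # identical visited prefix
      expect_equal(unname(got$states[seq_len(min(nrow(got$states),
                                                 nrow(want$states))), ]),
                   unname(want$states[seq_len(min(nrow(got$states),
                                                  nrow(want$states))), ]))
    }
  }
})

test_that("attractor closure: one update maps each cycle state to the next", {
  for (seed in 1:10) {
    net <- random_net(seed, n = 9, density = 0.2)
    sr <- sample_attractors(net, seed = seed, batch = 200, cap = 200, tol = 1)
    for (a in sr$attractors) {
      p <- a$period
      for (i in seq_len(p)) {
        nxt <- step(net, a$states[i, ])
        expect_equal(unname(nxt), unname(a$states[(i %% p) + 1, ]))
      }
    }
  }
})

test_that("sampled basin fractions converge to the exhaustive enumeration", {
  for (seed in c(5, 23)) {
    net <- random_net(seed, n = 10, density = 0.25)
    exact <- enumerate_attractors(net)
    sr <- sample_attractors(net, seed = 99, batch = 2000, cap = 2000, tol = 1)
    for (key in names(sr$fractions)) {
      p <- exact$fractions[key]
      expect_false(is.na(p))
      se <- sqrt(p * (1 - p) / 2000)
      expect_lt(abs(sr$fractions[key] - p), max(3 * se, 0.02))
    }
  }
})

test_that("a single-global-fixed-point network converges at the first check", {
  net <- toy_chain(5)  # feed-forward chain, self-degradation: all-off sink
  sr <- sample_attractors(net, seed = 1, batch = 100, cap = 1000, tol = 0.01)
  expect_true(sr$converged)
  expect_length(sr$attractors, 1)
  expect_equal(unname(sr$fractions), 1)
  expect_equal(sr$n_sampled, 200)  # two batches: first comparison converges
})

test_that("mutual-activation pair matches the enumeration oracle", {
  # hand/oracle enumeration: 00 is fixed; 01 and 10 each turn the silent
  # partner on (one active activator, F = 1), so they join 11 -> basins {1, 3}
  en <- enumerate_attractors(toy_mutual_activation())
  counts <- sort(vapply(en$attractors, function(a) a$basin_count, integer(1)))
  expect_equal(unname(counts), c(1L, 3L))
  keys <- names(en$attractors)
  expect_setequal(keys, c(state_keys(c(0, 0)), state_keys(c(1, 1))))
  oracle <- oracle_enumerate(toy_mutual_activation())
  expect_equal(sort(as.integer(oracle)), c(1L, 3L))
})

test_that("one-node self-activating network has a single on fixed point", {
  net <- regnet(data.frame(id = "x", kind = "protein", self_mode = "activation"))
  en <- enumerate_attractors(net)
  expect_length(en$attractors, 1)
  expect_equal(en$attractors[[1]]$states[1, 1], 1)
  expect_equal(en$attractors[[1]]$basin_count, 2L)
})

test_that("enumeration refuses oversized networks, naming the limit", {
  net <- random_net(1, n = 12)
  expect_error(enumerate_attractors(net, limit = 10L), "limited to 10")
})

test_that("the cell-cycle core reproduces its known basin structure", {
  net <- yeast_cc11()
  en <- enumerate_attractors(net, condition(net, "none"))
  counts <- sort(vapply(en$attractors, function(a) a$basin_count, integer(1)),
                 decreasing = TRUE)
  # seven fixed points; the stationary G1 state dominates with basin 1764
  expect_equal(unname(counts), c(1764L, 151L, 109L, 9L, 7L, 7L, 1L))
  g1 <- en$attractors[[names(counts)[1]]]$states[1, ]
  names(g1) <- net$nodes$id
  expect_equal(unname(g1[c("CDH1", "SIC1")]), c(1, 1))
  expect_equal(sum(g1), 2)
})

test_that("the excited trajectory traverses the canonical phase order", {
  net <- yeast_cc11()
  en <- enumerate_attractors(net, condition(net, "none"))
  counts <- vapply(en$attractors, function(a) a$basin_count, integer(1))
  g1 <- en$attractors[[which.max(counts)]]$states[1, ]
  tr <- evolve(net, g1, condition(net, "none", cell_size = "pulse"))
  expect_equal(tr$attractor$key, en$attractors[[which.max(counts)]]$key)
  phases <- rle(label_cc_phases(tr$states))$values
  expect_equal(phases, c("START", "G1", "S", "G2", "M", "G1", "stationary_G1"))
})

test_that("cyclic markers are the changing protein nodes, with edge cases", {
  # network whose excited trajectory is constant -> empty marker set
  frozen <- regnet(data.frame(id = c("CS", "a"),
                              kind = c("signal", "protein"),
                              self_mode = "sustaining"),
                   signals = list(cell_size = "CS"))
  mk <- identify_cyclic_markers(frozen, condition(frozen, "none"),
                                n_init = 50, seed = 1)
  expect_length(mk$markers, 0)
  # one transiently pulsed node is exactly the marker
  puls <- regnet(data.frame(id = c("CS", "a", "b"),
                            kind = c("signal", "protein", "protein"),
                            self_mode = c("sustaining", "degradation",
                                          "degradation")),
                 data.frame(source = c("CS", "a"), target = c("a", "b"),
                            sign = c(1L, 1L)),
                 signals = list(cell_size = "CS"))
  mk <- identify_cyclic_markers(puls, condition(puls, "none"),
                                n_init = 50, seed = 1)
  expect_setequal(mk$markers, c("a", "b"))
  expect_equal(unname(mk$reference), c(0, 0))
})

test_that("growth and sporulation signals are mutually exclusive", {
  net <- yeast56()
  for (nm in c("growth", "sporulation", "none")) {
    cond <- condition(net, nm)
    cl <- cond$clamps
    expect_lt(cl[["GROWTH"]] + cl[["SPOR_COND"]], 2)
  }
})

test_that("state keys are a bijection for wide networks", {
  set.seed(42)
  S <- matrix(sample(c(0, 1), 40 * 56, replace = TRUE), 40, 56)
  keys <- state_keys(S)
  expect_equal(anyDuplicated(keys), anyDuplicated(S))
  for (i in c(1, 17, 40))
    expect_equal(key_to_state(keys[i], 56), S[i, ])
})

test_that("non-convergence within the step budget is reported explicitly", {
  # 3-cycle rotor: period-3 attractor found normally, flagged at tiny budget
  rot <- regnet(data.frame(id = c("a", "b", "c"), kind = "protein",
                           self_mode = "degradation"),
                data.frame(source = c("a", "b", "c"), target = c("b", "c", "a"),
                           sign = 1L))
  tr <- evolve(rot, c(1, 0, 0))
  expect_true(tr$converged)
  expect_equal(tr$attractor$period, 3)
  tr2 <- evolve(rot, c(1, 0, 0), max_steps = 1L)
  expect_false(tr2$converged)
  expect_true(is.na(tr2$steps_to_attractor))
})
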