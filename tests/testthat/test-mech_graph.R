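# MFPT-based transition statistics, mechanism-graph construction,
# progressive lumping and rate-limiting-step identification.

test_that("alternating two-state trajectory has MFPT 1 ns and rate 1/ns", {
  st <- state_trajectory(0:99, rep(c("A", "B"), 50))
  ps <- pairwise_transition_stats(st)
  expect_equal(ps$mfpt["A", "B"], 1)
  expect_equal(ps$rate["B", "A"], 1)
  expect_equal(ps$counts["A", "B"], 50)
  expect_equal(ps$counts["B", "A"], 49)   # trajectory ends in B
  expect_equal(ps$net_flux["A", "B"], 1)
})

test_that("MFPTs equal the brute-force scan oracle on random trajectories", {
  set.seed(29)
  for (k in 1:12) {
    n_states <- sample(2:6, 1)
    n <- sample(c(50, 200, 500), 1)
    codes <- sample(LETTERS[1:n_states], n, replace = TRUE)
    times <- seq(0, by = 0.2, length.out = n)
    st <- state_trajectory(times, codes)
    ps <- pairwise_transition_stats(st)
    oracle <- mfpt_oracle(codes, times)
    expect_equal(ps$mfpt[rownames(oracle), colnames(oracle)], oracle,
                 tolerance = 1e-12)
  }
})

test_that("a rate is absent (not zero) when no passage completes", {
  st <- state_trajectory(0:3, c("A", "A", "B", "B"))
  ps <- pairwise_transition_stats(st)
  expect_true(is.na(ps$mfpt["B", "A"]))  # B never returns to A
  expect_false(is.finite(ps$rate["B", "A"]))
  expect_equal(ps$mfpt["A", "B"], 2)     # single completed passage
})

test_that("replicas pool passage times, not per-replica rates", {
  # replica 1: one A->B passage of 1 ns; replica 2: one of 9 ns.
  # pooling passages gives MFPT 5 ns; averaging rates would give 0.56/ns.
  r1 <- state_trajectory(0:1, c("A", "B"))
  r2 <- state_trajectory(seq(0, 9, by = 1), c("A", rep("C", 8), "B"))
  ps <- pairwise_transition_stats(list(r1, r2))
  expect_equal(ps$mfpt["A", "B"], 5)
  expect_equal(ps$rate["A", "B"], 0.2)
})

test_that("two-state CTMC MFPT matches the analytic 1/k over seeds", {
  k_ab <- 0.5
  est <- vapply(1:10, function(s) {
    sim <- simulate_ctmc(ctmc_spec(c("A", "B"),
                                   matrix(c(-k_ab, k_ab, 0.5, -0.5), 2, 2,
                                          byrow = TRUE),
                                   stride = 0.02, duration = 1000,
                                   seed = 200 + s))
    pairwise_transition_stats(sim$trajectory)$mfpt["A", "B"]
  }, 0)
  sem <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1 / k_ab), 3 * sem + 0.02)
})

test_that("graph nodes carry populations and ion-count classes", {
  st <- state_trajectory(0:9, rep(c("WKKK0K", "WKK0KK"), 5))
  ps <- pairwise_transition_stats(st)
  pop <- state_populations(st, n_boot = 100, seed = 1)
  g <- build_mechanism_graph(ps, pop)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(sort(g$nodes$n_ions), c(4L, 4L))  # both are 4-ion codes
  expect_equal(g$nodes$population[g$nodes$state == "WKKK0K"],
               pop$fraction[pop$code == "WKKK0K"])
  # S1-S4 window variant: both codes hold 3 ions inside the filter proper
  g2 <- build_mechanism_graph(ps, pop, ion_positions = 2:5)
  expect_equal(sort(g2$nodes$n_ions), c(3L, 3L))
})

test_that("progressive lumping follows the hand-traced 3-state chain", {
  # A<->B exchange every 0.1 ns (rate 10/ns); C is visited rarely and
  # dwells 3 ns, so after the A-B merge no remaining rate exceeds 1/ns
  base <- c(rep(c("A", "B"), 10), rep("C", 30))
  codes <- rep(base, 40)
  st <- state_trajectory((seq_along(codes) - 1) * 0.1, codes)
  g <- lump_graph(st, cutoff = 1)
  expect_equal(nrow(g$nodes), 2)
  expect_true("A+B" %in% g$nodes$state)
  expect_equal(sort(unlist(g$nodes$members[g$nodes$state == "A+B"])),
               c("A", "B"))
  # populations of lumped nodes are sums of member populations
  expect_equal(g$nodes$population[g$nodes$state == "A+B"],
               mean(codes %in% c("A", "B")), tolerance = 1e-12)

  # cutoff above all rates: no lumping; far below: single node
  g_hi <- lump_graph(st, cutoff = 1e6)
  expect_equal(sort(g_hi$nodes$state), c("A", "B", "C"))
  g_lo <- lump_graph(st, cutoff = 1e-6)
  expect_equal(nrow(g_lo$nodes), 1)
  expect_equal(sort(unlist(g_lo$nodes$members)), c("A", "B", "C"))
})

test_that("lumping is monotone in the cutoff", {
  sim <- test_channel_run(seed = 21, duration = 40, n_ions = 60)
  st <- discretize_trajectory(sim$frames, sim$geometry)
  cutoffs <- c(50, 10, 3, 1)
  sizes <- vapply(cutoffs, function(cf) nrow(lump_graph(st, cf)$nodes), 0)
  expect_true(all(diff(sizes) <= 0))  # lower cutoff -> never fewer merges
  # lumped populations always sum to 1
  for (cf in cutoffs) {
    g <- lump_graph(st, cf)
    expect_equal(sum(g$nodes$population), 1, tolerance = 1e-12)
  }
})

test_that("flux is conserved at every node within trajectory end effects", {
  sim <- test_channel_run(seed = 31, duration = 60, n_ions = 80)
  st <- discretize_trajectory(sim$frames, sim$geometry)
  ps <- pairwise_transition_stats(st)
  # for every state, sum of outgoing net fluxes is zero within +-1
  imbalance <- rowSums(ps$net_flux)
  expect_true(all(abs(imbalance) <= 1))
})

test_that("rate-limiting step: unique slow edge carrying the flux wins", {
  # unidirectional permeation cycle A -> B -> C -> A with B -> C slow
  states <- c("A", "B", "C")
  Q <- matrix(c(-3.0, 3.0, 0.001,
                0.001, -0.301, 0.3,
                3.0, 0.001, -3.001), 3, 3, byrow = TRUE)
  sim <- simulate_ctmc(ctmc_spec(states, Q, stride = 0.05, duration = 3000,
                                 seed = 77))
  ps <- pairwise_transition_stats(sim$trajectory)
  pop <- state_populations(sim$trajectory, n_boot = 100, seed = 1)
  g <- build_mechanism_graph(ps, pop)
  cycle_flux <- max(abs(g$edges$net_flux))
  rls <- rate_limiting_step(g, total_flux = cycle_flux)
  expect_identical(rls$from, "B")
  expect_identical(rls$to, "C")
  expect_false(rls$below_threshold)
  expect_gte(rls$flux_fraction, 0.5)
})

test_that("designed CTMC bottleneck is recovered across seeds", {
  states <- c("WKKK0K", "WKK0KK", "WKKKK0")
  # cycle WKKK0K -> WKK0KK (slow, designed bottleneck) -> WKKKK0 -> back
  Q <- matrix(c(-0.4004, 0.4, 0.0004,
                0.0004, -4.0004, 4.0,
                4.0, 0.0004, -4.0004), 3, 3, byrow = TRUE)
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_ctmc(ctmc_spec(states, Q, stride = 0.05, duration = 800,
                                   seed = 300 + s))
    ps <- pairwise_transition_stats(sim$trajectory)
    pop <- state_populations(sim$trajectory, n_boot = 100, seed = s)
    g <- build_mechanism_graph(ps, pop)
    rls <- rate_limiting_step(g, total_flux = max(abs(g$edges$net_flux)))
    if (rls$from == "WKKK0K" && rls$to == "WKK0KK") hits <- hits + 1
  }
  expect_equal(hits, 20)
})

test_that("zero-flux graphs take the warning path", {
  st <- state_trajectory(0:99, rep(c("A", "B"), 50))
  ps <- pairwise_transition_stats(st)
  g <- build_mechanism_graph(ps, c(A = 0.5, B = 0.5))
  expect_warning(rls <- rate_limiting_step(g, total_flux = 0), "maximal-flux")
  expect_true(rls$below_threshold)
})

test_that("a graph cut across the cycle carries the permeation count", {
  # each completed A->B->C->A cycle is one permeation; the net flux
  # across any single cycle edge equals the number of completions
  states <- c("A", "B", "C")
  Q <- matrix(c(-1.001, 1.0, 0.001,
                0.001, -1.001, 1.0,
                1.0, 0.001, -1.001), 3, 3, byrow = TRUE)
  sim <- simulate_ctmc(ctmc_spec(states, Q, stride = 0.02, duration = 500,
                                 seed = 55))
  ps <- pairwise_transition_stats(sim$trajectory)
  # every cut of the cycle carries the same net flux within +-1 event
  fluxes <- c(ps$net_flux["A", "B"], ps$net_flux["B", "C"],
              ps$net_flux["C", "A"])
  expect_lte(diff(range(fluxes)), 1)
  # and it tracks the jump-level cycle completions (brief state visits
  # shorter than the observation stride are invisible to the sampled chain)
  jumps <- sim$jumps
  completions <- sum(jumps$from == "C" & jumps$to == "A") -
    sum(jumps$from == "A" & jumps$to == "C")
  expect_gt(min(fluxes), 0)
  expect_equal(mean(fluxes), completions, tolerance = 0.05)
})

test_that("graph exports are well-formed JSON and DOT", {
  sim <- test_channel_run(seed = 8, duration = 20, n_ions = 40)
  st <- discretize_trajectory(sim$frames, sim$geometry)
  g <- lump_graph(st, cutoff = 5)
  fj <- tempfile(fileext = ".json")
  fd <- tempfile(fileext = ".dot")
  write_graph_json(g, fj)
  write_graph_dot(g, fd)
  parsed <- jsonlite::read_json(fj)
  expect_equal(length(parsed$nodes), nrow(g$nodes))
  expect_equal(length(parsed$edges), nrow(g$edges))
  expect_equal(parsed$lump_cutoff, 5)
  dot <- readLines(fd)
  expect_identical(dot[1], "digraph mechanism {")
  expect_identical(dot[length(dot)], "}")
})
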