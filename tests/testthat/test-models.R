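test_that("ca_step matches an exhaustive rule-bit oracle for all 256 rules", {
  set.seed(1)
  for (rule in 0:255) {
    state <- sample(0:1, 16, replace = TRUE)
    expect_identical(ca_step(state, rule), ca_step_oracle(state, rule),
                     label = paste("rule", rule))
  }
  # rule 0 annihilates everything; rule 90 is the XOR of the two neighbors
  expect_identical(ca_step(c(1, 0, 1, 1, 0), 0), rep(0L, 5))
  set.seed(2)
  for (k in 1:10) {
    s <- sample(0:1, 12, replace = TRUE)
    xor_oracle <- as.integer(xor(c(s[12], s[-12]), c(s[-1], s[1])))
    expect_identical(ca_step(s, 90), xor_oracle)
  }
  expect_error(ca_step(c(0, 2, 1), 110), "binary")
})

test_that("rule 110 follows its transition table and decimal encoding", {
  # neighborhoods 111,110,...,000 must map to 0,1,1,0,1,1,1,0
  nbhd_out <- function(rule, l, c, r) {
    ca_step(c(l, c, r), rule)[2L]   # middle cell of a 3-ring sees (l, c, r)
  }
  outs <- integer(8)
  k <- 1L
  for (l in c(1, 0)) for (c in c(1, 0)) for (r in c(1, 0)) {
    outs[k] <- nbhd_out(110, l, c, r)
    k <- k + 1L
  }
  expect_identical(outs, c(0L, 1L, 1L, 0L, 1L, 1L, 1L, 0L))
  # reading those outputs back as a binary number recovers the rule's name
  expect_identical(sum(outs * 2^(7:0)), 110)
})

test_that("cellular_automaton is deterministic and shaped (steps x ncells)", {
  a <- cellular_automaton(110, ncells = 30, steps = 20, seed = 5)
  b <- cellular_automaton(110, ncells = 30, steps = 20, seed = 5)
  expect_identical(a, b)
  expect_identical(dim(a), c(20L, 30L))
  expect_true(all(a %in% 0:1))
  c2 <- cellular_automaton(110, ncells = 30, steps = 20, seed = 6)
  expect_false(identical(a, c2))
})

test_that("rule 90 from a centered seed grows the XOR (Sierpinski) pattern", {
  n <- 33L; k <- 8L
  init <- integer(n); init[17L] <- 1L
  pat <- cellular_automaton(90, ncells = n, steps = k, initial_state = init)
  # independent recurrence: s[t+1][i] = xor of the two neighbors, periodic
  s <- init
  for (t in seq_len(k - 1L)) {
    s <- as.integer(xor(c(s[n], s[-n]), c(s[-1L], s[1L])))
    expect_identical(pat[t + 1L, ], s)
  }
})

test_that("the optimizer objective evaluates to its frozen reference values", {
  expect_identical(objective(0), 45872)
  expect_identical(objective(-4), 191948)
  expect_true(all(is.finite(objective(seq(-100, 100, by = 0.5)))))
})

test_that("greedy optimization improves monotonically and respects its seed", {
  env <- quiet_env("opt", automatic_storing = FALSE)
  env$traj$add_parameter("x", 0.0)
  res <- greedy_optimize(env, ngen = 5L, popsize = 40L, sigma = 0.5, seed = 3L)
  expect_identical(env$traj$n_runs(), 200L)
  expect_false(is.unsorted(res$best_vals))
  expect_gt(res$best_val, objective(0))  # it moved off the start point
  expect_identical(res$best_val, objective(res$best_x))
  # per-generation bests are recorded as results
  g1 <- env$traj$get_node("results.generations.gen_001")
  expect_identical(g1$get_item("best_val"), res$best_vals[1])
  # degenerate sampler: sigma 0 pins every sample to the current best
  env2 <- quiet_env("opt0", automatic_storing = FALSE)
  env2$traj$add_parameter("x", 0.0)
  res2 <- greedy_optimize(env2, ngen = 3L, popsize = 5L, sigma = 0, seed = 3L)
  expect_identical(res2$best_x, 0)
  expect_identical(unique(res2$best_vals), objective(0))
})

test_that("a decoupled LIF neuron fires at the closed-form interspike interval", {
  tau <- 10; I0 <- 1.1; VT <- 1; dt <- 0.1
  sim <- lif_simulate(n_neurons = 1L, tau = tau, I0 = I0, VT = VT, w = 0,
                      p_conn = 0, dt = dt, duration = 300, v_init = 0)
  isi <- diff(sim$spikes$time)
  theory <- tau * log(I0 / (I0 - VT))
  expect_true(all(abs(isi - theory) <= 2 * dt))
  # subthreshold input never fires
  quiet <- lif_simulate(n_neurons = 1L, tau = tau, I0 = 0.9, VT = VT, w = 0,
                        p_conn = 0, dt = dt, duration = 300, v_init = 0)
  expect_identical(nrow(quiet$spikes), 0L)
  expect_error(lif_simulate(dt = 0), "dt")
})

test_that("stronger inhibition never increases the spike count (fixed seed)", {
  counts <- vapply(c(0, -0.05, -0.2, -0.5), function(w) {
    nrow(lif_simulate(n_neurons = 50L, w = w, duration = 200,
                      seed = 11L)$spikes)
  }, numeric(1))
  expect_false(is.unsorted(rev(counts)))
  expect_gt(counts[1], counts[4])
})

test_that("the LIF experiment stores raster and voltage trace per weight", {
  res <- run_lif_experiment(filename = tmp_h5(), duration = 100,
                            n_neurons = 40L, log_level = "error")
  traj <- res$env$traj
  expect_identical(traj$n_runs(), 3L)
  traj$set_current_run(0L)
  spikes <- traj$get("results.runs.crun.spikes")
  expect_s3_class(spikes, "data.frame")
  expect_identical(names(spikes), c("time", "neuron"))
  vtrace <- traj$get("results.runs.crun.vtrace")
  expect_identical(length(vtrace), 1001L)   # duration/dt + initial sample
  traj$set_current_run(-1L)
})
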