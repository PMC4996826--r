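# Bundled example models: a scalar multiplication, elementary cellular
# automata, a greedy stochastic optimizer and a plain-numerics leaky
# integrate-and-fire network. They double as documentation of the intended
# workflow and as the package's end-to-end test surface.

# Evaluate fn with a locally seeded RNG, restoring global RNG state.
with_local_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

## ---- multiply --------------------------------------------------------------

#' Multiplication model
#'
#' The minimal example model: reads parameters `x` and `y`, computes
#' `z = x * y`, adds it as a per-run result and returns it.
#' @param traj the [Trajectory] (first argument by contract).
#' @return the product `z`.
#' @export
model_multiply <- function(traj) {
  z <- traj$get("x") * traj$get("y")
  traj$add_result("z", z, comment = "I am the product of two values!")
  z
}

## ---- elementary cellular automata -----------------------------------------

#' One update step of an elementary cellular automaton
#'
#' Each of the `n` binary cells is updated from its 3-cell neighborhood
#' (left neighbor, itself, right neighbor) by the transition rule encoded in
#' `rule_number`: bit `b = 4*s_left + 2*s_center + s_right` — i.e. the
#' neighborhood read as a 3-bit binary number — of `rule_number` gives the
#' next state. Boundary conditions are periodic: cell 0 sees cell `n-1` as
#' its left neighbor and cell `n-1` sees cell 0 on the right. There are 256
#' such rules; rule 110 is the famous Turing-complete one.
#'
#' @param state integer/numeric vector of 0s and 1s, length >= 3.
#' @param rule_number integer in `[0, 255]`.
#' @return the next state (integer vector of 0/1).
#' @export
ca_step <- function(state, rule_number) {
  if (!all(state %in% c(0, 1)))
    stop("ca_step: state must be binary (0/1)")
  stopifnot(length(state) >= 3L, rule_number >= 0, rule_number <= 255)
  s <- as.integer(state)
  left <- c(s[length(s)], s[-length(s)])
  right <- c(s[-1L], s[1L])
  idx <- 4L * left + 2L * s + right
  bitwAnd(bitwShiftR(as.integer(rule_number), idx), 1L)
}

#' Simulate an elementary cellular automaton
#'
#' Iterates [ca_step()] for `steps` time steps and returns the full cell
#' pattern: a `steps x ncells` binary matrix whose row `t` holds the state
#' at time `t - 1` (row 1 is the initial condition). The initial state is
#' either given explicitly or drawn uniformly at random from a generator
#' seeded with `seed`, which makes the pattern fully reproducible.
#'
#' @param rule_number transition rule in `[0, 255]`.
#' @param ncells number of cells `n >= 3`.
#' @param steps number of time steps `k >= 1`.
#' @param seed RNG seed for the random initial condition.
#' @param initial_state optional explicit binary start state of length
#'   `ncells` (overrides `seed`).
#' @return integer matrix of shape `(steps, ncells)` with entries 0/1.
#' @export
cellular_automaton <- function(rule_number, ncells = 200L, steps = 200L,
                               seed = 42L, initial_state = NULL) {
  stopifnot(ncells >= 3L, steps >= 1L)
  row0 <- if (!is.null(initial_state)) {
    stopifnot(length(initial_state) == ncells)
    as.integer(initial_state)
  } else {
    with_local_seed(seed, function() sample(0:1, ncells, replace = TRUE))
  }
  pattern <- matrix(0L, nrow = steps, ncol = ncells)
  pattern[1L, ] <- row0
  if (steps > 1L)
    for (t in seq_len(steps - 1L))
      pattern[t + 1L, ] <- ca_step(pattern[t, ], rule_number)
  pattern
}

#' Cellular-automaton model wrapper
#'
#' Passes the trajectory parameters `rule_number`, `ncells`, `steps` and
#' `seed` to [cellular_automaton()] and stores the full cell pattern as the
#' per-run result `pattern`.
#' @param traj the [Trajectory].
#' @return `NULL`, invisibly (results live in the tree).
#' @export
model_cellular_automaton <- function(traj) {
  pattern <- cellular_automaton(
    rule_number = traj$get("rule_number"), ncells = traj$get("ncells"),
    steps = traj$get("steps"), seed = traj$get("seed"))
  traj$add_result("pattern", pattern, comment = "full cell pattern")
  invisible(NULL)
}

## ---- greedy stochastic optimizer ------------------------------------------

#' Objective function of the optimizer example
#'
#' The sixth-order polynomial
#' `f(x) = -(x + 4)^6 + 5 (x - 10)^4 - 2 (x - 4)^2 + x`,
#' maximized by the greedy stochastic search in [greedy_optimize()].
#' @param x real input.
#' @return `f(x)`.
#' @export
objective <- function(x) {
  -(x + 4)^6 + 5 * (x - 10)^4 - 2 * (x - 4)^2 + x
}

#' Objective-evaluation model
#'
#' Returns `objective(x)` for the run's explored `x`; results are passed
#' back to the outer scope for post-processing instead of being stored.
#' @param traj the [Trajectory].
#' @return the objective value.
#' @export
model_objective <- function(traj) {
  objective(traj$get("x"))
}

#' Greedy stochastic maximization by alternating run and post-processing
#'
#' Adaptive exploration: each generation samples `popsize` points from a
#' normal distribution of width `sigma` centered at the best point found so
#' far, expands the trajectory with them, executes the pending runs, scans
#' the returned values and keeps the maximum. The per-generation best is
#' recorded as a result (`results/generations/gen_XXX`); the best value is
#' non-decreasing across generations by construction.
#'
#' @param env a [RunEnvironment] whose trajectory has a parameter `x`.
#' @param ngen number of generations. @param popsize samples per generation.
#' @param sigma width of the sampling distribution. @param seed RNG seed.
#' @return list with `best_x`, `best_val` and the per-generation
#'   `best_vals` vector.
#' @export
greedy_optimize <- function(env, ngen = 30L, popsize = 200L, sigma = 0.5,
                            seed = 42L) {
  stopifnot(ngen >= 1L, popsize >= 1L, sigma >= 0)
  traj <- env$traj
  best_x <- traj$get_node("parameters.x")$default()
  best_val <- objective(best_x)
  best_vals <- numeric(ngen)
  with_local_seed(seed, function() {
    for (g in seq_len(ngen)) {
      xs <- stats::rnorm(popsize, mean = best_x, sd = sigma)
      traj$expand(list(x = xs))
      outcomes <- env$run(model_objective)
      for (oc in outcomes) {
        if (oc$returned > best_val) {
          best_val <<- oc$returned
          best_x <<- traj$get_node("parameters.x")$value_at(oc$index)
        }
      }
      best_vals[g] <<- best_val
      traj$add_result(sprintf("generations.gen_%03d", g),
                      best_x = best_x, best_val = best_val,
                      comment = "best point of this generation")
    }
  })
  traj$add_result("final", best_x = best_x, best_val = best_val,
                  comment = "overall best point")
  list(best_x = best_x, best_val = best_val, best_vals = best_vals)
}

## ---- leaky integrate-and-fire network -------------------------------------

#' Simulate a randomly coupled inhibitory LIF network
#'
#' A homogeneous population of leaky integrate-and-fire neurons: each
#' membrane voltage relaxes toward the static input `I0` with time constant
#' `tau` (`dV/dt = (I0 - V)/tau`), plus instantaneous synaptic kicks of
#' weight `w` from presynaptic spikes. When `V >= VT` the neuron emits a
#' spike and resets to 0. Neurons are randomly connected with probability
#' `p_conn` (no self-connections); only inhibitory coupling (`w <= 0`) is
#' considered, with `w = 0` giving the decoupled population. Integration is
#' forward Euler with step `dt`; spikes detected at step `t` are delivered
#' to their targets at step `t + 1`. Initial voltages are uniform in
#' `[0, VT)` unless given explicitly.
#'
#' @param n_neurons population size.
#' @param tau membrane time constant (ms).
#' @param I0 static input (voltage units).
#' @param VT spiking threshold.
#' @param w synaptic weight, `w <= 0`.
#' @param p_conn connection probability in `[0, 1]`.
#' @param dt integration step (ms), `0 < dt`.
#' @param duration simulated time (ms).
#' @param seed RNG seed for connectivity and initial voltages.
#' @param v_init optional explicit initial voltage vector.
#' @return list with `spikes` (data.frame of `time`, `neuron` [0-based]) and
#'   `vtrace` (voltage of neuron 0 at every step, starting at t = 0).
#' @export
lif_simulate <- function(n_neurons = 100L, tau = 10, I0 = 1.1, VT = 1,
                         w = -0.02, p_conn = 0.1, dt = 0.1, duration = 500,
                         seed = 42L, v_init = NULL) {
  if (dt <= 0) stop("lif_simulate: dt must be positive")
  stopifnot(w <= 0, p_conn >= 0, p_conn <= 1, tau > 0, n_neurons >= 1L)
  nsteps <- as.integer(round(duration / dt))
  with_local_seed(seed, function() {
    conn <- matrix(stats::runif(n_neurons^2) < p_conn, n_neurons, n_neurons)
    diag(conn) <- FALSE  # conn[j, i]: j presynaptic to i (j -> i)
    v <- v_init %||% stats::runif(n_neurons, 0, VT)
    spike_t <- numeric(0)
    spike_i <- integer(0)
    vtrace <- numeric(nsteps + 1L)
    vtrace[1L] <- v[1L]
    prev_spiked <- logical(n_neurons)
    alpha <- dt / tau
    for (st in seq_len(nsteps)) {
      v <- v + alpha * (I0 - v)
      if (any(prev_spiked) && w != 0)
        v <- v + w * as.numeric(colSums(conn[prev_spiked, , drop = FALSE]))
      spiked <- v >= VT
      if (any(spiked)) {
        t_now <- st * dt
        spike_t <- c(spike_t, rep(t_now, sum(spiked)))
        spike_i <- c(spike_i, which(spiked) - 1L)
        v[spiked] <- 0
      }
      prev_spiked <- spiked
      vtrace[st + 1L] <- v[1L]
    }
    list(spikes = data.frame(time = spike_t, neuron = spike_i),
         vtrace = vtrace)
  })
}

#' LIF network model wrapper
#'
#' Reads the network parameters from the trajectory (grouped paths such as
#' `neuron.tau` and `syn.w`), runs [lif_simulate()] and stores the spike
#' raster (`spikes`) and the voltage trace of neuron 0 (`vtrace`) as per-run
#' results.
#' @param traj the [Trajectory].
#' @return number of spikes, invisibly.
#' @export
model_lif <- function(traj) {
  sim <- lif_simulate(
    n_neurons = traj$get("n_neurons"), tau = traj$get("neuron.tau"),
    I0 = traj$get("neuron.I0"), VT = traj$get("neuron.VT"),
    w = traj$get("syn.w"), p_conn = traj$get("syn.p_conn"),
    dt = traj$get("sim.dt"), duration = traj$get("sim.duration"),
    seed = traj$get("seed"))
  traj$add_result("spikes", sim$spikes, comment = "spike raster (time, neuron)")
  traj$add_result("vtrace", sim$vtrace, comment = "voltage trace of neuron 0")
  invisible(nrow(sim$spikes))
}
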