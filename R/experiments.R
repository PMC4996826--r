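# End-to-end experiment drivers wiring the example models into environments.
# Each returns the environment and the collected outcomes so that callers
# (tests, the command line, analysis scripts) can inspect both the returned
# values and the stored trees.

#' Run the multiplication experiment
#'
#' Explores the Cartesian product `{1, 2, 3, 4} x {6, 7, 8}` of the two
#' factors (twelve points, first factor cycling fastest) and executes
#' [model_multiply()] for every point.
#'
#' @param filename HDF5 file path.
#' @param trajectory_name trajectory name.
#' @param x_values,y_values explored value sequences.
#' @param ... further configuration for [run_environment()].
#' @return list with `env` and `outcomes` (list of `list(index, returned)`).
#' @export
run_multiply_experiment <- function(filename = tempfile(fileext = ".h5"),
                                    trajectory_name = "multiply",
                                    x_values = c(1, 2, 3, 4),
                                    y_values = c(6, 7, 8), ...) {
  env <- run_environment(trajectory = trajectory_name, filename = filename, ...)
  env$traj$add_parameter("x", 1.0, comment = "I am the first dimension!")
  env$traj$add_parameter("y", 1.0, comment = "I am the second dimension!")
  env$traj$explore(cartesian_product(list(x = x_values, y = y_values)))
  outcomes <- env$run(model_multiply)
  list(env = env, outcomes = outcomes)
}

#' Run the cellular-automata experiment
#'
#' Explores the transition-rule number over a list of rules (by default the
#' six showcase rules 10, 30, 90, 110, 184 and 190) and stores the full
#' cell pattern of each run.
#'
#' @param filename HDF5 file path.
#' @param trajectory_name trajectory name.
#' @param rules explored rule numbers.
#' @param ncells,steps,seed automaton configuration.
#' @param ... further configuration for [run_environment()] (e.g.
#'   `multiproc = TRUE, ncores = 4`).
#' @return list with `env` and `outcomes`.
#' @export
run_ca_experiment <- function(filename = tempfile(fileext = ".h5"),
                              trajectory_name = "cellular_automata",
                              rules = c(10L, 30L, 90L, 110L, 184L, 190L),
                              ncells = 200L, steps = 200L, seed = 42L, ...) {
  env <- run_environment(trajectory = trajectory_name, filename = filename, ...)
  traj <- env$traj
  traj$add_parameter("rule_number", 0L, comment = "decimal transition rule")
  traj$add_parameter("ncells", as.integer(ncells), comment = "number of cells")
  traj$add_parameter("steps", as.integer(steps), comment = "time steps")
  traj$add_parameter("seed", as.integer(seed), comment = "RNG seed")
  traj$explore(list(rule_number = as.integer(rules)))
  outcomes <- env$run(model_cellular_automaton)
  list(env = env, outcomes = outcomes)
}

#' Run the adaptive-optimization experiment
#'
#' Alternates run and post-processing phases: every generation expands the
#' trajectory with freshly sampled points around the current best and
#' executes only the pending runs. Automatic storing is off — nothing is
#' written during the runs; the trajectory is stored manually once at the
#' end.
#'
#' @param filename HDF5 file path.
#' @param trajectory_name trajectory name.
#' @param ngen,popsize,sigma,seed optimizer configuration (see
#'   [greedy_optimize()]).
#' @param ... further configuration for [run_environment()].
#' @return list with `env`, `outcomes` (the optimizer summary) and
#'   `best` (list of `best_x`, `best_val`).
#' @export
run_optimizer_experiment <- function(filename = tempfile(fileext = ".h5"),
                                     trajectory_name = "optimization",
                                     ngen = 30L, popsize = 200L, sigma = 0.5,
                                     seed = 42L, ...) {
  env <- run_environment(trajectory = trajectory_name, filename = filename,
                         automatic_storing = FALSE, log_level = "error", ...)
  env$traj$add_parameter("x", 0.0, comment = "the explored dimension")
  env$traj$add_parameter("ngen", as.integer(ngen))
  env$traj$add_parameter("popsize", as.integer(popsize))
  env$traj$add_parameter("sigma", sigma)
  best <- greedy_optimize(env, ngen = ngen, popsize = popsize, sigma = sigma,
                          seed = seed)
  store_trajectory(env$traj, filename)
  list(env = env, best = best)
}

#' Run the LIF-network experiment
#'
#' Explores the inhibitory synaptic weight over `w_values` and stores the
#' spike raster and a voltage trace per run.
#'
#' @param filename HDF5 file path.
#' @param trajectory_name trajectory name.
#' @param w_values explored synaptic weights (all `<= 0`).
#' @param n_neurons,tau,I0,VT,p_conn,dt,duration,seed network configuration
#'   (see [lif_simulate()]).
#' @param ... further configuration for [run_environment()].
#' @return list with `env` and `outcomes` (spike counts per run).
#' @export
run_lif_experiment <- function(filename = tempfile(fileext = ".h5"),
                               trajectory_name = "lif_network",
                               w_values = c(-0.01, -0.05, -0.1),
                               n_neurons = 100L, tau = 10, I0 = 1.1, VT = 1,
                               p_conn = 0.1, dt = 0.1, duration = 500,
                               seed = 42L, ...) {
  env <- run_environment(trajectory = trajectory_name, filename = filename, ...)
  traj <- env$traj
  traj$add_parameter("n_neurons", as.integer(n_neurons),
                     comment = "population size")
  traj$add_parameter("neuron.tau", tau, comment = "membrane time constant (ms)")
  traj$add_parameter("neuron.I0", I0, comment = "static input")
  traj$add_parameter("neuron.VT", VT, comment = "spiking threshold")
  traj$add_parameter("syn.w", w_values[[1]], comment = "synaptic weight")
  traj$add_parameter("syn.p_conn", p_conn, comment = "connection probability")
  traj$add_parameter("sim.dt", dt, comment = "integration step (ms)")
  traj$add_parameter("sim.duration", duration, comment = "simulated time (ms)")
  traj$add_parameter("seed", as.integer(seed), comment = "RNG seed")
  traj$explore(list("syn.w" = w_values))
  outcomes <- env$run(model_lif)
  list(env = env, outcomes = outcomes)
}
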