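# Shared fixtures. Everything is generated in code; no stored test data.

tmp_h5 <- function() tempfile(fileext = ".h5")

quiet_env <- function(name, filename = tmp_h5(), ...) {
  run_environment(trajectory = name, filename = filename,
                  log_level = "error", ...)
}

# A trajectory exploring the product grid of the multiplication example.
make_multiply_traj <- function(name = "multiply") {
  traj <- trajectory(name)
  traj$add_parameter("x", 1.0, comment = "I am the first dimension!")
  traj$add_parameter("y", 1.0, comment = "I am the second dimension!")
  traj$explore(cartesian_product(list(x = c(1, 2, 3, 4), y = c(6, 7, 8))))
  traj
}

# The showcase rule exploration of the cellular-automata example.
ca_rules <- c(10L, 30L, 90L, 110L, 184L, 190L)

# One value of every built-in kind (results accept all of them; the
# parameter-compatible subset excludes dict and frame).
all_kind_values <- function() {
  list(
    bool = TRUE, int = 3L, float = 1.5, complex = 2 + 3i, str = "hello",
    bool_vec = c(TRUE, FALSE, TRUE), int_vec = 1:4,
    float_vec = c(0.5, 1.5, 2.5), complex_vec = c(1 + 2i, 3 - 4i),
    str_vec = c("a", "bb", "ccc"),
    bool_mat = matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2),
    int_mat = matrix(1:6, 2, 3),
    float_mat = matrix(seq(0.1, 0.6, by = 0.1), 2, 3),
    complex_mat = matrix(c(1 + 1i, 2 - 2i, 3 + 3i, 4 - 4i), 2, 2),
    str_mat = matrix(c("u", "v", "w", "x"), 2, 2),
    bool_list = list(TRUE, FALSE), int_list = list(1L, 2L, 3L),
    float_list = list(1.5, 2.5), complex_list = list(1i, 2 + 0i),
    str_list = list("p", "q"),
    dict = list(a = 1L, b = "two", nested = list(c = 3.5)),
    frame = data.frame(u = c(1.5, 2.5), v = c("a", "b"), w = 1:2,
                       stringsAsFactors = FALSE)
  )
}

# Independent cellular-automaton oracle: an explicit 8-entry lookup table
# built from the rule bits, applied cell by cell with a plain loop.
ca_step_oracle <- function(state, rule_number) {
  table <- integer(8)
  for (b in 0:7) table[b + 1L] <- as.integer((rule_number %/% 2^b) %% 2)
  n <- length(state)
  out <- integer(n)
  for (i in seq_len(n)) {
    l <- state[if (i == 1L) n else i - 1L]
    r <- state[if (i == n) 1L else i + 1L]
    out[i] <- table[4L * l + 2L * state[i] + r + 1L]
  }
  out
}

# Count in-memory tree nodes of a trajectory (groups, leaves and links).
count_nodes <- function(traj) {
  n <- 0L
  walk <- function(node) {
    n <<- n + 1L
    if (inherits(node, "GroupNode")) for (ch in node$children) walk(ch)
  }
  for (ch in traj$root_node()$children) walk(ch)
  n
}

# Dotted paths of all in-memory tree nodes.
node_paths <- function(traj) {
  acc <- character(0)
  walk <- function(node) {
    acc <<- c(acc, node$full_name)
    if (inherits(node, "GroupNode")) for (ch in node$children) walk(ch)
  }
  for (ch in traj$root_node()$children) walk(ch)
  sort(acc)
}
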