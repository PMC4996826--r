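test_that("parameters auto-create groups and are frozen once runs start", {
  traj <- trajectory("t")
  traj$add_parameter("x", 1.0, comment = "I am the first dimension!")
  traj$add_parameter("syn.w", -0.5)
  expect_s3_class(traj$get_node("parameters.syn"), "GroupNode")
  expect_identical(traj$get("syn.w"), -0.5)
  expect_error(traj$add_parameter("x", 2.0), class = "name_collision_error")
  traj$explore(list(x = c(1, 2)))
  traj$begin_run(0L); traj$end_run()
  expect_error(traj$add_parameter("late", 1.0), class = "run_phase_error")
})

test_that("results land under the current run inside a run context", {
  traj <- trajectory("t")
  traj$add_parameter("x", 1.0)
  traj$explore(list(x = c(1, 2, 3)))
  traj$begin_run(2L)
  traj$add_result("z", 21.0)
  traj$end_run()
  expect_identical(traj$get("results.runs.run_00000002.z"), 21.0)
  traj$add_result("final", best_x = 1.0, best_val = 2.0)
  node <- traj$get_node("results.final")
  expect_identical(node$get_item("best_x"), 1.0)
  expect_error(traj$add_result("final", 1), class = "name_collision_error")
})

test_that("natural naming elides unique groups and flags ambiguity", {
  traj <- trajectory("t")
  traj$add_parameter("sub.deep.x", 1.5)
  # shortcut equals the full explicit path
  expect_identical(traj$get("x"), traj$get("parameters.sub.deep.x"))
  expect_identical(traj$get("deep.x"), 1.5)
  expect_error(traj$get("nonexistent"), class = "not_found_error")
  # two distinct matches at the same minimal depth are ambiguous
  traj$add_result("a.val", 1)
  traj$add_result("b.val", 2)
  expect_error(traj$get("val"), class = "ambiguous_name_error")
  expect_identical(traj$get("a.val"), 1)
  # names are validated
  expect_error(traj$add_parameter("1bad", 1), class = "name_collision_error")
  expect_error(traj$add_parameter("crun", 1), class = "name_collision_error")
})

test_that("links alias nodes and chains are capped", {
  traj <- trajectory("t")
  traj$add_result("final", 42)
  traj$add_link("", "best", "results.final")
  expect_identical(traj$get("best"), traj$get("results.final"))
  expect_error(traj$add_link("", "bad", "results.missing"),
               class = "not_found_error")
  # a chain of nine links exceeds the eight-hop cap
  traj$add_link("", "l9", "results.final")
  for (k in 8:1)
    traj$add_link("", paste0("l", k), paste0("l", k + 1L))
  expect_error(traj$get("l1"), class = "link_depth_error")
  expect_identical(traj$get("l2"), 42)
})

test_that("exploration installs equal-length ranges and pending runs", {
  traj <- make_multiply_traj()
  expect_identical(traj$n_runs(), 12L)
  expect_identical(traj$run_table()$name[3], "run_00000002")
  expect_false(any(traj$run_table()$completed))
  expect_error(trajectory("e")$explore(list(x = 1:2)),
               class = "not_found_error")
  t2 <- trajectory("t2")
  t2$add_parameter("x", 1.0); t2$add_parameter("y", 1.0)
  expect_error(t2$explore(list(x = c(1, 2), y = c(1, 2, 3))),
               class = "length_mismatch_error")
  t3 <- trajectory("t3")
  t3$add_parameter("rule_number", 0L)
  t3$explore(list(rule_number = ca_rules))
  expect_identical(t3$n_runs(), 6L)
})

test_that("cartesian_product enumerates with the first parameter fastest", {
  cp <- cartesian_product(list(x = c(1.0, 2.0, 3.0, 4.0),
                               y = c(6.0, 7.0, 8.0)))
  expect_length(cp$x, 12L)
  expect_identical(c(cp$x[1], cp$y[1]), c(1.0, 6.0))
  expect_identical(c(cp$x[2], cp$y[2]), c(2.0, 6.0))
  expect_identical(c(cp$x[12], cp$y[12]), c(4.0, 8.0))
  # single parameter: identity
  expect_identical(cartesian_product(list(x = c(5, 7)))$x, c(5, 7))
  # three binary factors enumerate like a 3-bit counter, first listed fastest
  cp3 <- cartesian_product(list(a = 0:1, b = 0:1, c = 0:1))
  oracle <- list(a = integer(0), b = integer(0), c = integer(0))
  for (cc in 0:1) for (bb in 0:1) for (aa in 0:1) {
    oracle$a <- c(oracle$a, aa); oracle$b <- c(oracle$b, bb)
    oracle$c <- c(oracle$c, cc)
  }
  expect_identical(cp3, oracle)
  expect_error(cartesian_product(list(x = numeric(0))),
               class = "empty_range_error")
})

test_that("expand appends points with continuing run indices", {
  traj <- trajectory("t")
  traj$add_parameter("x", 0.0)
  traj$expand(list(x = as.numeric(1:200)))  # behaves like explore when fresh
  expect_identical(traj$n_runs(), 200L)
  traj$expand(list(x = as.numeric(201:400)))
  expect_identical(traj$n_runs(), 400L)
  expect_identical(traj$run_table()$index[201], 200L)
  expect_identical(traj$run_table()$name[400], "run_00000399")
  traj$add_parameter("other", 1.0)
  expect_error(traj$expand(list(other = c(1, 2))),
               class = "exploration_mismatch_error")
  expect_error(traj$expand(list(x = c(1, 2), other = c(1, 2))),
               class = "exploration_mismatch_error")
})

test_that("run iteration binds explored parameters and restores the pointer", {
  traj <- trajectory("ca")
  traj$add_parameter("rule_number", 0L)
  traj$explore(list(rule_number = ca_rules))
  seen <- unlist(traj$iter_runs(function(rn) traj$get("rule_number")))
  expect_identical(seen, ca_rules)
  expect_identical(traj$current_run_index(), -1L)
  names_seen <- traj$iter_runs(function(rn) rn)
  expect_identical(unlist(names_seen), run_table <- traj$run_table()$name)
  # manual pointer selection drives crun
  traj$set_current_run(2L)
  expect_identical(traj$get("rule_number"), 90L)
  traj$begin_run(2L)
  traj$add_result("probe", 1L)
  traj$end_run()
  traj$set_current_run(2L)
  expect_identical(traj$get("results.runs.crun.probe"), 1L)
  traj$set_current_run(-1L)
  expect_error(traj$get("results.runs.crun.probe"),
               class = "not_found_error")
})

test_that("predicate filtering equals brute-force filtering", {
  traj <- trajectory("ca")
  traj$add_parameter("rule_number", 0L)
  traj$add_parameter("offset", 0.0)
  traj$explore(list(rule_number = ca_rules,
                    offset = as.numeric(seq_along(ca_rules))))
  got <- traj$find_run_indices("rule_number", function(r) r > 30 && r < 120)
  expect_identical(got, c(2L, 3L))
  # brute-force oracle over all indices, two parameters
  pred <- function(r, o) (r %% 4 == 2) || o > 5
  oracle <- Filter(function(i) {
    pred(ca_rules[i + 1L], as.numeric(i + 1L))
  }, 0:5)
  got2 <- traj$find_run_indices(c("rule_number", "offset"), pred)
  expect_identical(got2, as.integer(oracle))
  expect_identical(traj$find_run_indices("rule_number", function(r) TRUE), 0:5)
  expect_identical(traj$find_run_indices("rule_number", function(r) FALSE),
                   integer(0))
  expect_error(traj$find_run_indices("missing", function(r) TRUE),
               class = "not_found_error")
  t2 <- trajectory("t2"); t2$add_parameter("u", 1.0)
  t2$add_parameter("v", 1.0); t2$explore(list(u = c(1, 2)))
  expect_error(t2$find_run_indices("v", function(v) TRUE),
               class = "unexplored_parameter_error")
})

test_that("merging appends re-indexed runs and can drop duplicate points", {
  make <- function(name, vals) {
    tr <- trajectory(name)
    tr$add_parameter("r", 0L)
    tr$explore(list(r = vals))
    for (i in seq_along(vals) - 1L) {
      tr$begin_run(i); tr$add_result("z", vals[i + 1L] * 10L); tr$end_run()
      tr$mark_run(i, 0.01)
    }
    tr
  }
  a <- make("a", c(1L, 2L))
  b <- make("b", c(2L, 3L))
  merge_trajectories(a, b)
  expect_identical(a$n_runs(), 4L)
  expect_identical(a$run_table()$name[3], "run_00000002")
  expect_identical(a$get("results.runs.run_00000002.z"), 20L)
  expect_identical(a$get("results.runs.run_00000003.z"), 30L)
  # duplicate removal: merging identical trajectories changes nothing
  c1 <- make("c1", c(1L, 2L)); c2 <- make("c2", c(1L, 2L))
  merge_trajectories(c1, c2, remove_duplicates = TRUE)
  expect_identical(c1$n_runs(), 2L)
  # merged count = La + Lb - duplicates
  d1 <- make("d1", c(1L, 2L)); d2 <- make("d2", c(2L, 3L))
  merge_trajectories(d1, d2, remove_duplicates = TRUE)
  expect_identical(d1$n_runs(), 3L)
  # different spaces are rejected
  e1 <- make("e1", c(1L, 2L))
  e2 <- trajectory("e2"); e2$add_parameter("other", 0L)
  e2$explore(list(other = c(1L, 2L)))
  expect_error(merge_trajectories(e1, e2), class = "space_mismatch_error")
})

test_that("run-table length always equals every explored range length", {
  traj <- trajectory("inv")
  traj$add_parameter("a", 0.0)
  traj$add_parameter("b", 0L)
  traj$explore(list(a = c(1, 2, 3), b = c(4L, 5L, 6L)))
  check <- function() {
    for (p in traj$explored_names())
      expect_identical(traj$get_node(p)$range_length(), traj$n_runs())
  }
  check()
  traj$expand(list(a = c(9, 10), b = c(7L, 8L)))
  check()
})
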