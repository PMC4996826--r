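test_that("the environment executes every explored point and sorts outcomes", {
  env <- quiet_env("multiply")
  env$traj$add_parameter("x", 1.0)
  env$traj$add_parameter("y", 1.0)
  env$traj$explore(cartesian_product(list(x = c(1, 2, 3, 4), y = c(6, 7, 8))))
  out <- env$run(model_multiply)
  expect_length(out, 12L)
  expect_identical(vapply(out, `[[`, integer(1), "index"), 0:11)
  expect_identical(vapply(out, `[[`, numeric(1), "returned"),
                   c(6, 12, 18, 24, 7, 14, 21, 28, 8, 16, 24, 32))
  expect_true(all(env$traj$run_table()$completed))
  # results were stored per run
  back <- load_trajectory(env$filename, level = "skeleton")
  expect_identical(back$get("results.runs.run_00000002.z"), 18)
  expect_error(quiet_env("empty")$run(model_multiply),
               class = "no_exploration_error")
})

test_that("sequential and parallel execution produce identical outcomes and trees", {
  run_one <- function(multiproc, ncores) {
    env <- quiet_env(paste0("ca", multiproc, ncores),
                     multiproc = multiproc, ncores = ncores)
    traj <- env$traj
    traj$add_parameter("rule_number", 0L)
    traj$add_parameter("ncells", 40L)
    traj$add_parameter("steps", 40L)
    traj$add_parameter("seed", 7L)
    traj$explore(list(rule_number = ca_rules))
    env$run(model_cellular_automaton)
    env
  }
  es <- run_one(FALSE, 1L)
  ep <- run_one(TRUE, 4L)
  e1 <- run_one(TRUE, 1L)
  for (i in 0:5) {
    q <- sprintf("results.runs.run_%08d.pattern", i)
    expect_identical(es$traj$get(q), ep$traj$get(q))
    expect_identical(es$traj$get(q), e1$traj$get(q))
  }
  # stored trees match too (dataset-level equality in the HDF5 files)
  for (i in 0:5) {
    rel <- sprintf("results/runs/run_%08d/pattern/pattern", i)
    p_s <- rhdf5::h5read(es$filename, paste0("caFALSE1/", rel))
    p_p <- rhdf5::h5read(ep$filename, paste0("caTRUE4/", rel))
    expect_identical(p_s, p_p)
  }
})

test_that("unserializable payloads are rejected before the pool starts", {
  env <- quiet_env("serial_check", multiproc = TRUE, ncores = 2L)
  env$traj$add_parameter("x", 1.0)
  env$traj$explore(list(x = c(1, 2)))
  con <- file(tempfile(), "w")
  on.exit(close(con))
  leaky <- local({
    handle <- con
    function(traj) { handle; traj$get("x") }
  })
  err <- tryCatch(env$run(leaky), serialization_error = function(e) e)
  expect_s3_class(err, "serialization_error")
  expect_match(conditionMessage(err), "connection")
})

test_that("a failing run is logged, siblings continue, first error re-raised", {
  env <- quiet_env("failing")
  env$traj$add_parameter("x", 1.0)
  env$traj$explore(list(x = c(1, 2, 3, 4)))
  flaky <- function(traj) {
    if (traj$get("x") == 2) stop("boom at two")
    traj$get("x") * 10
  }
  err <- tryCatch(suppressMessages(env$run(flaky)),
                  run_failed_error = function(e) e)
  expect_s3_class(err, "run_failed_error")
  expect_identical(err$index, 1L)
  rt <- env$traj$run_table()
  expect_identical(rt$completed, c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(rt$failed, c(FALSE, TRUE, FALSE, FALSE))
  log_txt <- readLines(env$error_log_file())
  expect_true(any(grepl("boom at two", log_txt)))
  main_txt <- readLines(env$main_log_file())
  expect_true(any(grepl("boom at two", main_txt)))
})

test_that("resume executes exactly the previously incomplete runs", {
  f <- tmp_h5()
  env <- quiet_env("resume_demo", filename = f)
  env$traj$add_parameter("x", 1.0)
  env$traj$add_parameter("y", 1.0)
  env$traj$explore(cartesian_product(list(x = c(1, 2, 3, 4), y = c(6, 7, 8))))
  crash_after <- function(traj) {
    if (traj$current_run_index() >= 7) stop("simulated crash")
    traj$get("x") * traj$get("y")
  }
  try(suppressMessages(env$run(crash_after)), silent = TRUE)
  # a fresh session picks the trajectory up from the file
  revived <- load_trajectory(f, level = "skeleton")
  expect_identical(sum(revived$run_table()$completed), 7L)
  env2 <- quiet_env(revived, filename = f)
  out <- env2$resume(model_multiply)
  expect_identical(vapply(out, `[[`, integer(1), "index"), 7:11)
  final <- load_trajectory(f, level = "skeleton")
  expect_identical(sum(final$run_table()$completed), 12L)
  # resuming a finished trajectory does nothing
  expect_length(env2$resume(model_multiply), 0L)
  # resuming without exploration is an error
  e3 <- quiet_env("unexplored")
  e3$traj$add_parameter("x", 1.0)
  expect_error(e3$resume(model_multiply), class = "no_exploration_error")
})

test_that("disabling automatic storing keeps the run phase write-free", {
  env <- quiet_env("nostore", automatic_storing = FALSE)
  env$traj$add_parameter("x", 1.0)
  env$traj$explore(list(x = c(1, 2, 3)))
  out <- env$run(function(traj) {
    traj$add_result("z", traj$get("x") * 2)
    traj$get("x")
  })
  expect_false(file.exists(env$filename))
  # a subsequent manual store persists everything added during the runs
  store_trajectory(env$traj, env$filename)
  back <- load_trajectory(env$filename, level = "full")
  expect_identical(back$get("results.runs.run_00000001.z"), 4)
  expect_identical(sum(back$run_table()$completed), 3L)
})

test_that("progress reports state completion and mean-runtime ETA", {
  expect_identical(progress_report(6, 12, 2),
                   "6/12 runs completed (50.0%), ETA 12.0 s")
  expect_match(progress_report(12, 12, 2), "ETA 0.0 s", fixed = TRUE)
  # interval 0: one report per run; large interval: first and last only
  run_with_interval <- function(interval, name) {
    env <- run_environment(trajectory = name, filename = tmp_h5(),
                           log_level = "info", report_interval = interval,
                           automatic_storing = FALSE)
    env$traj$add_parameter("x", 1.0)
    env$traj$explore(list(x = as.numeric(1:6)))
    env$run(function(traj) traj$get("x"))
    sum(grepl("runs completed", readLines(env$main_log_file())))
  }
  expect_identical(run_with_interval(0, "everyrun"), 6L)
  expect_lte(run_with_interval(3600, "rarely"), 2L)
})

test_that("log files separate severity levels", {
  env <- run_environment(trajectory = "loglevels", filename = tmp_h5(),
                         log_level = "error", automatic_storing = FALSE)
  env$traj$add_parameter("x", 1.0)
  env$traj$explore(list(x = c(1, 2)))
  env$run(function(traj) traj$get("x"))
  expect_identical(length(readLines(env$error_log_file())), 0L)
  main <- readLines(env$main_log_file())
  expect_false(any(grepl("INFO", main)))
  # info level writes run bookkeeping to the main log only
  env2 <- run_environment(trajectory = "loginfo", filename = tmp_h5(),
                          log_level = "info", automatic_storing = FALSE)
  env2$traj$add_parameter("x", 1.0)
  env2$traj$explore(list(x = c(1, 2)))
  env2$run(function(traj) traj$get("x"))
  expect_true(any(grepl("INFO", readLines(env2$main_log_file()))))
  expect_identical(length(readLines(env2$error_log_file())), 0L)
})
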