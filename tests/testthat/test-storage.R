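make_rich_traj <- function(name = "rich") {
  traj <- trajectory(name, comment = "round-trip fixture")
  traj$add_parameter("x", 1.0, comment = "scalar dimension")
  traj$add_parameter("grp.flag", TRUE)
  traj$add_config("ncores", 2L)
  traj$explore(list(x = c(1.5, 2.5, 3.5)))
  traj$begin_run(1L)
  vals <- all_kind_values()
  for (tag in names(vals)) traj$add_result(paste0("bag.", tag), vals[[tag]])
  traj$end_run()
  traj$mark_run(1L, 0.25)
  traj$add_link("results", "best", "results.runs.run_00000001.bag.float")
  traj$annotate("parameters.x", note = "annotated", level = 2L)
  traj
}

test_that("store/load round-trips every supported type tag exactly", {
  traj <- make_rich_traj()
  f <- tmp_h5()
  store_trajectory(traj, f)
  back <- load_trajectory(f, level = "full", auto_load = FALSE)
  vals <- all_kind_values()
  for (tag in setdiff(names(vals), "frame")) {
    expect_identical(back$get(paste0("results.runs.run_00000001.bag.", tag)),
                     vals[[tag]], label = tag)
  }
  expect_equal(back$get("results.runs.run_00000001.bag.frame"), vals$frame)
  # type tags survive verbatim
  for (tag in names(vals)) {
    leaf <- back$get_node(paste0("results.runs.run_00000001.bag.", tag))
    expect_identical(leaf$item_tags()[[tag]], tag)
  }
  # metadata survives: comments, annotations, run table, explored ranges
  expect_identical(back$comment, "round-trip fixture")
  expect_identical(back$get_node("parameters.x")$comment, "scalar dimension")
  ann <- back$get_node("parameters.x")$annotations
  expect_identical(ann[sort(names(ann))],
                   list(level = 2L, note = "annotated"))
  expect_identical(back$explored_names(), "parameters.x")
  expect_identical(back$get_node("parameters.x")$range(),
                   list(1.5, 2.5, 3.5))
  rt <- back$run_table()
  expect_identical(rt$completed, c(FALSE, TRUE, FALSE))
  expect_equal(rt$runtime_seconds[2], 0.25)
  expect_identical(back$get("results.best"),
                   back$get("results.runs.run_00000001.bag.float"))
})

test_that("the HDF5 hierarchy maps one-to-one onto the tree", {
  traj <- make_rich_traj("mapping")
  f <- tmp_h5()
  store_trajectory(traj, f)
  listing <- rhdf5::h5ls(f, recursive = TRUE)
  grp <- listing[listing$otype == "H5I_GROUP", , drop = FALSE]
  full <- paste0(grp$group, ifelse(grp$group == "/", "", "/"), grp$name)
  prefix <- "/mapping/"
  rel <- substring(full[startsWith(full, prefix)], nchar(prefix) + 1L)
  rel <- rel[!startsWith(rel, "overview")]
  kinds <- vapply(rel, function(rp) {
    nk <- rhdf5::h5readAttributes(f, paste0("mapping/", rp))$node_kind
    if (is.null(nk)) "" else as.character(nk)
  }, character(1))
  h5_nodes <- sort(gsub("/", ".", rel[kinds %in%
                                        c("group", "parameter", "result", "link")]))
  expect_identical(h5_nodes, node_paths(traj))
})

test_that("load levels are monotone: skeleton within structure within full", {
  traj <- make_rich_traj("levels")
  f <- tmp_h5()
  store_trajectory(traj, f)
  sk <- load_trajectory(f, level = "skeleton", auto_load = FALSE)
  st <- load_trajectory(f, level = "structure", auto_load = FALSE)
  fu <- load_trajectory(f, level = "full", auto_load = FALSE)
  expect_true(all(node_paths(sk) %in% node_paths(st)))
  expect_true(all(node_paths(st) %in% node_paths(fu)))
  expect_lt(count_nodes(sk), count_nodes(st))
  expect_identical(count_nodes(st), count_nodes(fu))
  # skeleton still knows the run table and explored ranges
  expect_identical(sk$n_runs(), 3L)
  expect_identical(sk$get_node("parameters.x")$range(), list(1.5, 2.5, 3.5))
  # structure stubs carry metadata but no payload
  stub <- st$get_node("results.runs.run_00000001.bag.int")
  expect_false(stub$loaded)
  expect_error(st$get("results.runs.run_00000001.bag.int"),
               class = "not_found_error")
})

test_that("skeleton plus auto-load answers any query like a full load", {
  traj <- make_rich_traj("lazy")
  f <- tmp_h5()
  store_trajectory(traj, f)
  lazy <- load_trajectory(f, level = "skeleton", auto_load = TRUE)
  full <- load_trajectory(f, level = "full", auto_load = FALSE)
  queries <- c("x", "results.runs.run_00000001.bag.int", "bag.dict",
               "results.best", "grp.flag", "ncores")
  for (q in queries)
    expect_identical(lazy$get(q), full$get(q), label = q)
  # the lazy path did hit the disk; the full path never does on resolve
  expect_gt(lazy$storage$n_read_items, 0L)
  before <- full$storage$n_read_items
  for (q in queries) invisible(full$get(q))
  expect_identical(full$storage$n_read_items, before)
  # with auto_load disabled, misses advise explicit loading
  cold <- load_trajectory(f, level = "skeleton", auto_load = FALSE)
  err <- tryCatch(cold$get("results.runs.run_00000001.bag.int"),
                  not_found_error = function(e) e)
  expect_match(conditionMessage(err), "auto_load|explicitly")
})

test_that("storing is idempotent and partial stores touch only their subtree", {
  traj <- make_rich_traj("partial")
  f <- tmp_h5()
  svc <- store_trajectory(traj, f)
  w0 <- svc$n_write_items
  store_trajectory(traj)          # nothing changed
  expect_identical(svc$n_write_items, w0)
  # post-processing adds one result; manual partial storage writes only it
  traj$add_result("final", best_x = 1.0, best_val = 99.0)
  store_node(traj, "results.final")
  expect_true(length(svc$last_store_paths) > 0L)
  expect_true(all(startsWith(svc$last_store_paths, "partial/results/final")))
  back <- load_trajectory(f, level = "full")
  expect_identical(back$get_node("results.final")$get_item("best_val"), 99.0)
  # repeating the partial store writes nothing further
  store_node(traj, "results.final")
  expect_identical(svc$last_store_paths, character(0))
  expect_error(store_node(traj, "results.missing"), class = "not_found_error")
})

test_that("stored data cannot be deleted or replaced", {
  traj <- make_rich_traj("nodelete")
  f <- tmp_h5()
  svc <- store_trajectory(traj, f)
  expect_error(svc$delete_node(traj, "results.runs.run_00000001.bag.int"),
               class = "unsupported_operation_error")
})

test_that("storing an unregistered custom kind fails with its tag", {
  traj <- trajectory("orphan")
  p <- traj$add_parameter("c", 1.0)
  p$type_tag <- "mystery"   # simulate a container whose codec is absent
  err <- tryCatch(store_trajectory(traj, tmp_h5()),
                  unknown_tag_error = function(e) e)
  expect_s3_class(err, "unknown_tag_error")
  expect_match(conditionMessage(err), "mystery")
})

test_that("expanded ranges are appended on re-store and reload intact", {
  traj <- trajectory("grow")
  traj$add_parameter("x", 0.0)
  traj$explore(list(x = c(1, 2)))
  f <- tmp_h5()
  store_trajectory(traj, f)
  traj$expand(list(x = c(3, 4)))
  store_trajectory(traj)
  back <- load_trajectory(f, level = "skeleton")
  expect_identical(back$n_runs(), 4L)
  expect_identical(back$get_node("parameters.x")$range(), list(1, 2, 3, 4))
})
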