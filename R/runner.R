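LOG_LEVELS <- c(debug = 10L, info = 20L, warning = 30L, error = 40L)

#' Progress report text for a batch of runs
#'
#' The remaining-time estimate is the arithmetic mean runtime of the
#' completed runs multiplied by the number of remaining runs.
#'
#' @param n_completed runs completed so far.
#' @param n_total total number of runs in the batch.
#' @param mean_runtime_seconds mean runtime of the completed runs.
#' @return a one-line report string.
#' @examples
#' progress_report(6, 12, 2)   # "6/12 runs completed (50.0%), ETA 12.0 s"
#' @export
progress_report <- function(n_completed, n_total, mean_runtime_seconds) {
  eta <- mean_runtime_seconds * (n_total - n_completed)
  sprintf("%d/%d runs completed (%.1f%%), ETA %.1f s",
          n_completed, n_total, 100 * n_completed / n_total, eta)
}

# Recursive scan for objects that cannot cross a process boundary.
find_unserializable <- function(x, path = "payload",
                                seen = new.env(parent = emptyenv())) {
  if (inherits(x, "connection")) return(sprintf("%s (connection)", path))
  if (typeof(x) == "externalptr") return(sprintf("%s (external pointer)", path))
  if (is.function(x)) {
    e <- environment(x)
    if (!is.null(e) && !isNamespace(e) && !identical(e, globalenv()) &&
        !identical(e, baseenv())) {
      key <- format(e)
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        for (nm in ls(e, all.names = TRUE)) {
          v <- tryCatch(get(nm, envir = e, inherits = FALSE),
                        error = function(e) NULL)
          bad <- find_unserializable(v, sprintf("%s$%s", path, nm), seen)
          if (!is.null(bad)) return(bad)
        }
      }
    }
    return(NULL)
  }
  if (is.list(x) && !is.object(x)) {
    nms <- names(x) %||% as.character(seq_along(x))
    for (k in seq_along(x)) {
      bad <- find_unserializable(x[[k]], sprintf("%s$%s", path, nms[[k]]), seen)
      if (!is.null(bad)) return(bad)
    }
  }
  NULL
}

#' Run environment: scheduler for parameter explorations
#'
#' The environment embeds a user model — a function taking the trajectory
#' as its first argument — and executes it once per explored point, serially
#' or on a fork-based worker pool. It books per-run completion and runtime,
#' triggers automatic per-run storage, writes a full log and a dedicated
#' error log, and reports progress with a remaining-time estimate.
#'
#' Runs are independent by contract: a worker receives a pruned trajectory
#' view holding each parameter at its single value for that run and no
#' results, and ships its per-run result leaves back to the master, which is
#' the only process that writes to the HDF5 file. The framework never seeds
#' global random number generators; models must derive any seeds from their
#' parameters.
#'
#' @examples
#' env <- run_environment(trajectory = "mul", filename = tempfile(fileext = ".h5"))
#' env$traj$add_parameter("x", 1.0)
#' env$traj$add_parameter("y", 1.0)
#' env$traj$explore(cartesian_product(list(x = c(1, 2, 3, 4), y = c(6, 7, 8))))
#' out <- env$run(model_multiply)
#' out[[2]]  # list(index = 1, returned = 12)
#' @export
RunEnvironment <- R6::R6Class("RunEnvironment",
  public = list(
    #' @field traj the managed [Trajectory].
    traj = NULL,
    #' @field filename HDF5 file the trajectory is stored to.
    filename = NULL,
    #' @field multiproc run models on a worker pool.
    multiproc = FALSE,
    #' @field ncores worker count when `multiproc` is enabled.
    ncores = 1L,
    #' @field automatic_storing store each run's results right after the run.
    automatic_storing = TRUE,
    #' @field log_level minimum severity written to the main log.
    log_level = "info",
    #' @field log_dir directory holding the two log files.
    log_dir = NULL,
    #' @field report_interval minimum seconds between progress reports.
    report_interval = 10,

    #' @description Create an environment (and its trajectory, log files and
    #'   storage binding).
    #' @param trajectory a [Trajectory] or a name for a fresh one.
    #' @param filename HDF5 file path (default: under `tempdir()`).
    #' @param multiproc enable the worker pool. @param ncores pool size.
    #' @param automatic_storing store results after every individual run.
    #' @param log_level `"debug"`, `"info"`, `"warning"` or `"error"`.
    #' @param log_dir log directory (default: under `tempdir()`).
    #' @param report_interval seconds between progress reports; reports are
    #'   emitted at most once per interval, or after every run when single
    #'   runs take longer than the interval.
    #' @param registry container-kind registry for a fresh trajectory.
    initialize = function(trajectory = "trajectory", filename = NULL,
                          multiproc = FALSE, ncores = 1L,
                          automatic_storing = TRUE, log_level = "info",
                          log_dir = NULL, report_interval = 10,
                          registry = default_registry()) {
      stopifnot(ncores >= 1L)
      self$traj <- if (inherits(trajectory, "Trajectory")) trajectory
                   else Trajectory$new(trajectory, registry = registry)
      self$filename <- filename %||%
        file.path(tempdir(), paste0(self$traj$name, ".h5"))
      self$multiproc <- isTRUE(multiproc)
      self$ncores <- as.integer(ncores)
      self$automatic_storing <- isTRUE(automatic_storing)
      stopifnot(log_level %in% names(LOG_LEVELS))
      self$log_level <- log_level
      self$log_dir <- log_dir %||%
        file.path(tempdir(), "trajspace_logs", self$traj$name)
      self$report_interval <- report_interval
      private$setup_logging()
    },

    #' @description Execute the model for every pending (not yet completed)
    #'   run, in index order. Results added by the model inside a run land
    #'   under `results/runs/run_XXXXXXXX`; returned values are collected.
    #'   A failing run is logged, marked failed and does not abort its
    #'   siblings; after all runs the first failure is re-raised.
    #' @param model `function(traj, ...)`.
    #' @param ... further arguments passed through to the model.
    #' @return list of `list(index, returned)`, ascending in index.
    run = function(model, ...) {
      if (self$traj$n_runs() == 0L)
        ts_abort("no_exploration_error",
                 "trajectory has no exploration; call explore() first")
      pending <- self$traj$pending_runs()
      if (length(pending) == 0L) {
        self$log("info", "no pending runs")
        return(list())
      }
      self$log("info", sprintf("starting %d run(s) [%s]", length(pending),
                               if (self$multiproc)
                                 sprintf("multiprocessing, ncores=%d",
                                         self$ncores) else "serial"))
      if (self$multiproc) private$run_pool(model, pending, ...)
      else private$run_serial(model, pending, ...)
    },

    #' @description Execute only the runs a previous (crashed or halted)
    #'   session left incomplete. Completed runs are untouched.
    #' @param model `function(traj, ...)`. @param ... passed to the model.
    #' @return outcomes of the previously incomplete runs.
    resume = function(model, ...) {
      self$run(model, ...)
    },

    #' @description Write a line to the logs (error-level lines also go to
    #'   the dedicated error log).
    #' @param level severity. @param msg text.
    log = function(level, msg) {
      lv <- LOG_LEVELS[[level]]
      line <- sprintf("%s %-7s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                      toupper(level), msg)
      if (lv >= LOG_LEVELS[[self$log_level]])
        cat(line, "\n", file = private$main_log, append = TRUE, sep = "")
      if (lv >= LOG_LEVELS[["error"]]) {
        cat(line, "\n", file = private$error_log, append = TRUE, sep = "")
        message(line)
      }
      invisible(self)
    },

    #' @description Path of the full log file.
    main_log_file = function() private$main_log,

    #' @description Path of the error-only log file.
    error_log_file = function() private$error_log,

    #' @description The storage service bound to `filename`.
    storage = function() {
      if (is.null(self$traj$storage) ||
          !identical(self$traj$storage$filename, self$filename))
        self$traj$storage <- Hdf5StorageService$new(self$filename)
      self$traj$storage
    }
  ),

  private = list(
    main_log = NULL,
    error_log = NULL,
    last_report = -Inf,

    setup_logging = function() {
      ok <- dir.create(self$log_dir, recursive = TRUE, showWarnings = FALSE)
      if (!dir.exists(self$log_dir))
        ts_abort("io_error",
                 sprintf("cannot create log directory '%s'", self$log_dir))
      private$main_log <- file.path(self$log_dir,
                                    paste0(self$traj$name, "_main.log"))
      private$error_log <- file.path(self$log_dir,
                                     paste0(self$traj$name, "_errors.log"))
      for (fl in c(private$main_log, private$error_log))
        if (!file.exists(fl)) file.create(fl)
    },

    maybe_report = function(n_done, n_total, runtimes) {
      mean_rt <- if (length(runtimes)) mean(runtimes) else 0
      now <- as.numeric(Sys.time())
      due <- (now - private$last_report) >= self$report_interval ||
        mean_rt >= self$report_interval || n_done == n_total
      if (due) {
        private$last_report <- now
        self$log("info", progress_report(n_done, n_total, mean_rt))
      }
    },

    finish_run = function(i, runtime, failed) {
      self$traj$mark_run(i, runtime, failed = failed)
      if (self$automatic_storing) self$storage()$store_run(self$traj, i)
    },

    raise_failures = function(failures) {
      if (length(failures) == 0L) return(invisible(NULL))
      first <- failures[[1L]]
      ts_abort("run_failed_error",
               sprintf("run %d failed: %s (%d run(s) failed in total)",
                       first$index, first$message, length(failures)),
               index = first$index)
    },

    run_serial = function(model, pending, ...) {
      svc <- NULL
      if (self$automatic_storing) {
        svc <- self$storage()
        svc$store_tree(self$traj)
        svc$begin_session()
        on.exit(svc$end_session(), add = TRUE)
      }
      outcomes <- list()
      failures <- list()
      runtimes <- numeric(0)
      total <- length(pending)
      done <- 0L
      for (i in pending) {
        self$log("debug", sprintf("starting %s", run_name(i)))
        self$traj$begin_run(i)
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(list(value = model(self$traj, ...)),
                        error = function(e) list(error = e))
        rt <- proc.time()[["elapsed"]] - t0
        self$traj$end_run()
        failed <- !is.null(res$error)
        if (failed) {
          msg <- conditionMessage(res$error)
          self$log("error", sprintf("%s failed: %s", run_name(i), msg))
          failures[[length(failures) + 1L]] <- list(index = i, message = msg)
        } else {
          outcomes[[length(outcomes) + 1L]] <-
            list(index = i, returned = res$value)
          runtimes <- c(runtimes, rt)
        }
        private$finish_run(i, rt, failed)
        done <- done + 1L
        private$maybe_report(done, total, runtimes)
      }
      if (self$automatic_storing) svc$store_run_table(self$traj)
      private$raise_failures(failures)
      outcomes[order(vapply(outcomes, `[[`, integer(1), "index"))]
    },

    run_pool = function(model, pending, ...) {
      args <- list(...)
      bad <- find_unserializable(list(model = model, args = args))
      if (!is.null(bad))
        ts_abort("serialization_error",
                 sprintf("cannot ship %s to worker processes", bad))
      payloads <- lapply(pending, function(i) prune_for_run(self$traj, i))
      t0 <- proc.time()[["elapsed"]]
      raw <- parallel::mclapply(payloads, function(pl)
        run_worker(pl, model, args), mc.cores = self$ncores,
        mc.preschedule = TRUE)
      outcomes <- list()
      failures <- list()
      runtimes <- numeric(0)
      if (self$automatic_storing) {
        svc <- self$storage()
        svc$store_tree(self$traj)
        svc$begin_session()
        on.exit(svc$end_session(), add = TRUE)
      }
      for (k in seq_along(raw)) {
        i <- pending[[k]]
        w <- raw[[k]]
        if (!is.list(w) || !is.null(w$error)) {
          msg <- if (is.list(w)) w$error else as.character(w)
          self$log("error", sprintf("%s failed: %s", run_name(i), msg))
          failures[[length(failures) + 1L]] <- list(index = i, message = msg)
          private$finish_run(i, 0, failed = TRUE)
          next
        }
        for (leaf in w$results) {
          parts <- split_path(leaf$full_name)
          parent <- self$traj$ensure_group_internal(parts[-length(parts)])
          r <- Result$new(leaf$full_name, comment = leaf$comment,
                          registry = self$traj$registry)
          r$annotations <- leaf$annotations
          r$set_items_internal(leaf$items, leaf$tags)
          r$stored <- FALSE
          parent$add_child(r)
        }
        outcomes[[length(outcomes) + 1L]] <-
          list(index = i, returned = w$returned)
        runtimes <- c(runtimes, w$runtime)
        private$finish_run(i, w$runtime, failed = FALSE)
        private$maybe_report(k, length(pending), runtimes)
      }
      if (self$automatic_storing) self$storage()$store_run_table(self$traj)
      private$raise_failures(failures)
      outcomes[order(vapply(outcomes, `[[`, integer(1), "index"))]
    }
  )
)

#' Create a run environment
#'
#' Convenience constructor for [RunEnvironment]; accepts the same
#' configuration as the class initializer.
#' @param ... see [RunEnvironment] `$new()`.
#' @return a [RunEnvironment].
#' @export
run_environment <- function(...) RunEnvironment$new(...)

# Pruned trajectory view for one run: parameters (and config) collapsed to
# the single value of that run, no results. Keeps serialization minimal and
# enforces run independence.
prune_for_run <- function(traj, i) {
  collect <- function(group) {
    out <- list()
    walk <- function(node) {
      if (inherits(node, "Parameter")) {
        out[[length(out) + 1L]] <<- list(
          full_name = node$full_name, value = node$value_at(i),
          comment = node$comment,
          tag = if (is_builtin_tag(node$type_tag)) NULL else node$type_tag)
        return()
      }
      if (inherits(node, "GroupNode")) for (ch in node$children) walk(ch)
    }
    g <- traj$walk(group)
    if (!is.null(g)) walk(g)
    out
  }
  list(name = traj$name, index = i, n_total = traj$n_runs(),
       params = collect("parameters"), config = collect("config"))
}

# Worker body: rebuild a minimal trajectory, execute the model inside the
# run context, harvest per-run result leaves.
run_worker <- function(payload, model, args) {
  tryCatch({
    traj <- Trajectory$new(payload$name)
    for (p in payload$params) {
      parts <- split_path(p$full_name)[-1L]
      traj$add_parameter(paste(parts, collapse = "."), p$value,
                         comment = p$comment, type_tag = p$tag)
    }
    for (p in payload$config) {
      parts <- split_path(p$full_name)[-1L]
      traj$add_config(paste(parts, collapse = "."), p$value,
                      comment = p$comment, type_tag = p$tag)
    }
    n <- payload$n_total
    traj$set_run_table_internal(data.frame(
      index = seq_len(n) - 1L, name = run_name(seq_len(n) - 1L),
      completed = FALSE, failed = FALSE, runtime_seconds = 0,
      finished_at = "", stringsAsFactors = FALSE))
    traj$begin_run(payload$index)
    t0 <- proc.time()[["elapsed"]]
    returned <- do.call(model, c(list(traj), args))
    rt <- proc.time()[["elapsed"]] - t0
    traj$end_run()
    leaves <- list()
    walk <- function(node) {
      if (inherits(node, "Result")) {
        leaves[[length(leaves) + 1L]] <<- list(
          full_name = node$full_name, comment = node$comment,
          items = node$items(), tags = node$item_tags(),
          annotations = node$annotations)
        return()
      }
      if (inherits(node, "GroupNode")) for (ch in node$children) walk(ch)
    }
    res_grp <- traj$walk("results")
    if (!is.null(res_grp)) walk(res_grp)
    list(index = payload$index, returned = returned, results = leaves,
         runtime = rt, error = NULL)
  }, error = function(e) list(index = payload$index,
                              error = conditionMessage(e)))
}
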