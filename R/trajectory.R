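LINK_HOP_CAP <- 8L

#' Trajectory: the container for one parameter exploration
#'
#' A trajectory is the rooted tree that jointly manages all parameters and
#' results of one numerical experiment, together with the run table that
#' books one record per explored point of the parameter space. The tree has
#' three reserved top-level groups: `parameters`, `results` and `config`.
#' Group nodes structure the space, leaf nodes are [Parameter] and [Result]
#' containers, and link nodes alias other nodes.
#'
#' Content is recalled by *natural naming*: dotted queries such as
#' `traj$get("results.runs.crun.pattern")`, where unique intermediate groups
#' may be elided (`traj$get("x")` finds `parameters.x`). The token `crun`
#' maps to the currently selected run. For an explored parameter the query
#' returns the range value of the selected run, or the default when no run
#' is selected (`current_run_index == -1`).
#'
#' @examples
#' traj <- trajectory("demo")
#' traj$add_parameter("x", 1.0, comment = "I am the first dimension!")
#' traj$add_parameter("y", 1.0)
#' traj$explore(cartesian_product(list(x = c(1, 2, 3, 4), y = c(6, 7, 8))))
#' traj$n_runs()
#' @export
Trajectory <- R6::R6Class("Trajectory",
  public = list(
    #' @field name identifier of the trajectory (HDF5 root group name).
    name = NULL,
    #' @field comment free-text description.
    comment = "",
    #' @field auto_load when file-backed, load missing nodes on demand.
    auto_load = FALSE,
    #' @field storage the attached storage service (or `NULL`).
    storage = NULL,
    #' @field registry container-kind registry used for (un)packing values.
    registry = NULL,

    #' @description Create an empty trajectory.
    #' @param name identifier (valid name component).
    #' @param comment free text.
    #' @param registry container-kind registry.
    initialize = function(name = "trajectory", comment = "",
                          registry = default_registry()) {
      check_component(name, "trajectory name")
      self$name <- name
      self$comment <- comment
      self$registry <- registry
      private$root <- GroupNode$new(name, full_name = "")
      for (g in c("parameters", "results", "config"))
        private$root$children[[g]] <- GroupNode$new(g, full_name = g)
      private$struct_level <- 2L
    },

    ## ---- construction ------------------------------------------------------

    #' @description Add a parameter leaf under `parameters/`. Intermediate
    #'   groups are auto-created. Parameters can only be introduced before
    #'   the individual simulation runs are started.
    #' @param path dotted path relative to the parameters group.
    #' @param default the default value.
    #' @param comment free text.
    #' @param type_tag explicit tag for registered custom kinds.
    #' @return the new [Parameter], invisibly.
    add_parameter = function(path, default, comment = "", type_tag = NULL) {
      if (private$runs_started)
        ts_abort("run_phase_error",
                 "parameters cannot be added after runs have started")
      parts <- check_user_path(path)
      full <- paste(c("parameters", parts), collapse = ".")
      parent <- private$ensure_group(c("parameters", parts[-length(parts)]))
      p <- Parameter$new(full, default, comment = comment,
                         type_tag = type_tag, registry = self$registry)
      parent$add_child(p)
      invisible(p)
    },

    #' @description Add a result leaf. Inside a run context the leaf lands
    #'   under `results/runs/run_XXXXXXXX/<path>`; outside, under
    #'   `results/<path>`. Results can be added at any time.
    #' @param path dotted path. @param ... item values: one unnamed value is
    #'   stored under the leaf's own name; named values become named items.
    #' @param comment free text.
    #' @param type_tag explicit custom tag applied to every given item.
    #' @return the new [Result], invisibly.
    add_result = function(path, ..., comment = "", type_tag = NULL) {
      parts <- check_user_path(path, allow_run_names = TRUE)
      prefix <- if (private$in_run && private$idx >= 0L)
        c("results", "runs", run_name(private$idx)) else "results"
      full <- paste(c(prefix, parts), collapse = ".")
      parent <- private$ensure_group(c(prefix, parts[-length(parts)]))
      if (!is.null(parent$children[[parts[length(parts)]]]))
        ts_abort("name_collision_error",
                 sprintf("result '%s' already exists", full))
      r <- Result$new(full, comment = comment, registry = self$registry)
      vals <- list(...)
      nms <- names(vals) %||% rep("", length(vals))
      leaf_nm <- parts[length(parts)]
      for (k in seq_along(vals)) {
        nm <- if (nzchar(nms[[k]])) nms[[k]] else leaf_nm
        r$set_item(nm, vals[[k]], type_tag = type_tag)
      }
      parent$add_child(r)
      invisible(r)
    },

    #' @description Add a configuration leaf under `config/`. Configuration
    #'   entries behave like parameters (typed, lockable) but are never
    #'   explored and may be added at any time.
    #' @param path dotted path relative to the config group.
    #' @param value the value. @param comment free text.
    #' @param type_tag explicit tag for registered custom kinds.
    #' @return the new [Parameter] leaf, invisibly.
    add_config = function(path, value, comment = "", type_tag = NULL) {
      parts <- check_user_path(path)
      full <- paste(c("config", parts), collapse = ".")
      parent <- private$ensure_group(c("config", parts[-length(parts)]))
      p <- Parameter$new(full, value, comment = comment,
                         type_tag = type_tag, registry = self$registry)
      parent$add_child(p)
      invisible(p)
    },

    #' @description Add a link node aliasing an existing group or leaf.
    #' @param group_path dotted path of the group to hold the link ("" for
    #'   the root). @param name link name. @param target_path full explicit
    #'   dotted path of the target node (must exist).
    add_link = function(group_path, name, target_path) {
      check_component(name, "link name")
      tgt <- private$walk_path(split_path(target_path))
      if (is.null(tgt))
        ts_abort("not_found_error",
                 sprintf("link target '%s' does not exist", target_path))
      parent <- if (nzchar(group_path))
        private$ensure_group(split_path(group_path)) else private$root
      full <- if (nzchar(group_path)) paste(group_path, name, sep = ".") else name
      parent$add_child(LinkNode$new(name, full, target_path))
      invisible(self)
    },

    #' @description Attach a small annotation to any node.
    #' @param path full dotted path. @param ... named annotation values.
    annotate = function(path, ...) {
      node <- self$get_node(path)
      ann <- list(...)
      stopifnot(length(ann) > 0L, !is.null(names(ann)), all(nzchar(names(ann))))
      node$annotations[names(ann)] <- ann
      node$stored <- FALSE
      invisible(self)
    },

    ## ---- exploration -------------------------------------------------------

    #' @description Explore the parameter space: install ranges and create
    #'   one pending run record per point. All sequences must share one
    #'   length; run indices start at 0.
    #' @param spec named list mapping parameter paths to value sequences.
    explore = function(spec) {
      if (length(private$explored) > 0L)
        ts_abort("exploration_mismatch_error",
                 "trajectory already explored; use expand() to add points")
      params <- private$resolve_spec_params(spec)
      lens <- vapply(spec, function(v) length(if (is.list(v)) v else as.list(v)),
                     integer(1))
      if (length(unique(lens)) != 1L)
        ts_abort("length_mismatch_error",
                 sprintf("exploration sequences differ in length: %s",
                         paste(lens, collapse = ", ")))
      L <- lens[[1L]]
      if (L < 1L)
        ts_abort("empty_range_error", "exploration sequences must be nonempty")
      for (k in seq_along(params)) params[[k]]$set_range(spec[[k]])
      private$explored <- vapply(params, function(p) p$full_name, character(1))
      private$append_runs(L)
      invisible(self)
    },

    #' @description Expand an explored trajectory with new points (or behave
    #'   like `explore()` on an unexplored one). The spec must name exactly
    #'   the already-explored parameters; new pending run records continue
    #'   the index sequence.
    #' @param spec named list mapping parameter paths to value sequences.
    expand = function(spec) {
      if (length(private$explored) == 0L) return(self$explore(spec))
      params <- private$resolve_spec_params(spec)
      fulls <- vapply(params, function(p) p$full_name, character(1))
      if (!setequal(fulls, private$explored))
        ts_abort("exploration_mismatch_error",
                 "expand() must name exactly the already-explored parameters")
      lens <- vapply(spec, function(v) length(if (is.list(v)) v else as.list(v)),
                     integer(1))
      if (length(unique(lens)) != 1L)
        ts_abort("length_mismatch_error",
                 "expansion sequences differ in length")
      for (k in seq_along(params)) params[[k]]$append_range(spec[[k]])
      private$append_runs(lens[[1L]])
      private$run_table_stored <- FALSE
      invisible(self)
    },

    #' @description Iterate all runs in index order. Before each step the
    #'   current run pointer is set to the run's index, so natural-naming
    #'   requests for explored parameters and `crun` result paths bind to
    #'   that run; afterwards the pointer is restored to -1.
    #' @param fn optional callback `function(run_name)`; its return values
    #'   are collected. Without a callback the run names are returned.
    #' @return list of callback results (or character vector of run names).
    iter_runs = function(fn = NULL) {
      n <- length(private$rt_index)
      on.exit(private$idx <- -1L)
      if (is.null(fn)) {
        private$idx <- -1L
        return(private$rt_name[seq_len(n)])
      }
      out <- vector("list", n)
      for (i in seq_len(n)) {
        private$idx <- private$rt_index[[i]]
        out[[i]] <- fn(private$rt_name[[i]])
      }
      out
    },

    #' @description Indices of runs whose explored values satisfy a
    #'   predicate. Evaluates in-memory ranges only; never touches disk.
    #' @param param_paths paths of explored parameters.
    #' @param predicate `function(v1, v2, ...)` returning `TRUE`/`FALSE`.
    #' @return ascending integer vector of matching 0-based run indices.
    find_run_indices = function(param_paths, predicate) {
      params <- lapply(param_paths, function(p) {
        node <- self$get_node(p)
        if (!inherits(node, "Parameter"))
          ts_abort("not_found_error", sprintf("'%s' is not a parameter", p))
        if (!node$is_explored())
          ts_abort("unexplored_parameter_error",
                   sprintf("parameter '%s' is not explored", node$full_name))
        node
      })
      n <- self$n_runs()
      hits <- integer(0)
      for (i in seq_len(n) - 1L) {
        vals <- lapply(params, function(p) p$value_at(i))
        if (isTRUE(do.call(predicate, vals))) hits <- c(hits, i)
      }
      hits
    },

    ## ---- natural naming ----------------------------------------------------

    #' @description Resolve a natural-naming query to a value or node.
    #'   Single-item result leaves and parameters resolve to their values;
    #'   groups and multi-item results resolve to the node object.
    #' @param query dotted query, possibly with elided intermediate groups
    #'   and the `crun` token.
    get = function(query) {
      node <- private$resolve_query(query)
      private$extract(node)
    },

    #' @description Resolve a query to the tree node itself (no value
    #'   extraction, no parameter locking; stubs are returned as-is).
    #' @param query dotted query.
    get_node = function(query) {
      private$resolve_query(query, need_payload = FALSE)
    },

    #' @description Whether a query resolves without error.
    #' @param query dotted query.
    has = function(query) {
      tryCatch({ private$resolve_query(query); TRUE },
               trajspace_error = function(e) FALSE)
    },

    ## ---- run bookkeeping ---------------------------------------------------

    #' @description The run table: one record per explored point.
    #' @return data.frame with columns index, name, completed, failed,
    #'   runtime_seconds, finished_at.
    run_table = function() {
      data.frame(index = private$rt_index, name = private$rt_name,
                 completed = private$rt_completed, failed = private$rt_failed,
                 runtime_seconds = private$rt_runtime,
                 finished_at = private$rt_finished,
                 stringsAsFactors = FALSE)
    },

    #' @description One run record as a list (cheap row access).
    #' @param i 0-based run index.
    run_record = function(i) {
      pos <- i + 1L
      list(index = private$rt_index[pos], name = private$rt_name[pos],
           completed = private$rt_completed[pos],
           failed = private$rt_failed[pos],
           runtime_seconds = private$rt_runtime[pos],
           finished_at = private$rt_finished[pos])
    },

    #' @description 0-based indices of runs not yet completed.
    pending_runs = function() {
      private$rt_index[!private$rt_completed]
    },

    #' @description Number of runs (= length of every explored range).
    n_runs = function() length(private$rt_index),

    #' @description Dotted full paths of the explored parameters, in
    #'   exploration order.
    explored_names = function() private$explored,

    #' @description The current run pointer (-1 = no run selected).
    current_run_index = function() private$idx,

    #' @description Select a run (or -1 to undo): explored parameters then
    #'   resolve to that run's values and `crun` maps to its run name.
    #' @param i run index in `{-1} U [0, n_runs)`.
    set_current_run = function(i) {
      i <- as.integer(i)
      if (i < -1L || i >= self$n_runs())
        ts_abort("index_error", sprintf("run index %d out of range", i))
      private$idx <- i
      invisible(self)
    },

    #' @description Enter the run context of run `i` (used by the run
    #'   environment): sets the run pointer, routes `add_result()` under the
    #'   run group, and makes parameter reads lock their containers.
    #' @param i run index.
    begin_run = function(i) {
      if (i < 0L || i >= self$n_runs())
        ts_abort("index_error", sprintf("run index %d out of range", i))
      private$idx <- as.integer(i)
      private$in_run <- TRUE
      private$runs_started <- TRUE
      invisible(self)
    },

    #' @description Leave the run context and restore the pointer to -1.
    end_run = function() {
      private$idx <- -1L
      private$in_run <- FALSE
      invisible(self)
    },

    #' @description Whether a run context is active.
    in_run_context = function() private$in_run,

    #' @description Mark a run completed (or failed) with its runtime.
    #' @param i run index. @param runtime_seconds elapsed wall time.
    #' @param failed whether the model raised an error.
    mark_run = function(i, runtime_seconds, failed = FALSE) {
      pos <- i + 1L
      private$rt_completed[pos] <- !failed
      private$rt_failed[pos] <- failed
      private$rt_runtime[pos] <- runtime_seconds
      private$rt_finished[pos] <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
      private$run_table_stored <- FALSE
      invisible(self)
    },

    #' @description Append one run record with the next free index (used by
    #'   merging).
    #' @param completed,failed flags. @param runtime_seconds elapsed time.
    #' @param finished_at timestamp string.
    append_run_record = function(completed = FALSE, failed = FALSE,
                                 runtime_seconds = 0, finished_at = "") {
      private$append_runs(1L)
      n <- length(private$rt_index)
      private$rt_completed[n] <- completed
      private$rt_failed[n] <- failed
      private$rt_runtime[n] <- runtime_seconds
      private$rt_finished[n] <- finished_at
      invisible(self)
    },

    #' @description Internal: restore run table state (storage loader).
    #' @param tbl data.frame as returned by `run_table()`.
    set_run_table_internal = function(tbl) {
      private$rt_index <- as.integer(tbl$index)
      private$rt_name <- as.character(tbl$name)
      private$rt_completed <- as.logical(tbl$completed)
      private$rt_failed <- as.logical(tbl$failed)
      private$rt_runtime <- as.numeric(tbl$runtime_seconds)
      private$rt_finished <- as.character(tbl$finished_at)
      if (any(private$rt_completed)) private$runs_started <- TRUE
      invisible(self)
    },

    #' @description Internal: restore explored-name list (storage loader).
    #' @param names character vector of dotted parameter paths.
    set_explored_internal = function(names) {
      private$explored <- names
      invisible(self)
    },

    #' @description Internal: mark how much structure is in memory
    #'   (0 skeleton, 1 structure stubs, 2 full).
    #' @param level integer 0..2.
    set_structure_level = function(level) {
      private$struct_level <- as.integer(level)
      invisible(self)
    },

    #' @description Internal structure level (see `set_structure_level`).
    structure_level = function() private$struct_level,

    #' @description Whether the run-table needs re-persisting.
    run_table_dirty = function() !private$run_table_stored,

    #' @description Mark the run table persisted.
    mark_run_table_stored = function() {
      private$run_table_stored <- TRUE
      invisible(self)
    },

    #' @description Mark every node (and the run table) as not yet
    #'   persisted, forcing the next store to rewrite the whole tree (used
    #'   when storing to a fresh file).
    mark_tree_unstored = function() {
      walk <- function(node) {
        node$stored <- FALSE
        if (inherits(node, "GroupNode")) for (ch in node$children) walk(ch)
      }
      for (ch in private$root$children) walk(ch)
      private$run_table_stored <- FALSE
      invisible(self)
    },

    #' @description The root group node (internal; used by storage/merge).
    root_node = function() private$root,

    #' @description Walk an explicit full path; `NULL` when absent. Links
    #'   along the way are dereferenced.
    #' @param path dotted full path.
    walk = function(path) private$walk_path(split_path(path)),

    #' @description Ensure a chain of groups exists (internal helper for
    #'   storage and merging).
    #' @param parts character vector of components.
    ensure_group_internal = function(parts) private$ensure_group(parts),

    #' @description Store the trajectory through the attached storage
    #'   service (convenience wrapper; see [store_trajectory()]).
    #' @param filename HDF5 file path; defaults to the attached one.
    store = function(filename = NULL) {
      store_trajectory(self, filename)
    }
  ),

  private = list(
    root = NULL,
    idx = -1L,
    in_run = FALSE,
    runs_started = FALSE,
    explored = character(0),
    struct_level = 2L,
    run_table_stored = FALSE,
    rt_index = integer(0),
    rt_name = character(0),
    rt_completed = logical(0),
    rt_failed = logical(0),
    rt_runtime = numeric(0),
    rt_finished = character(0),

    append_runs = function(n) {
      start <- length(private$rt_index)
      new_idx <- seq.int(start, length.out = n)
      private$rt_index <- c(private$rt_index, as.integer(new_idx))
      private$rt_name <- c(private$rt_name, run_name(new_idx))
      private$rt_completed <- c(private$rt_completed, rep(FALSE, n))
      private$rt_failed <- c(private$rt_failed, rep(FALSE, n))
      private$rt_runtime <- c(private$rt_runtime, rep(0, n))
      private$rt_finished <- c(private$rt_finished, rep("", n))
      private$run_table_stored <- FALSE
    },

    resolve_spec_params = function(spec) {
      if (length(spec) == 0L || is.null(names(spec)) || any(!nzchar(names(spec))))
        ts_abort("length_mismatch_error",
                 "exploration spec must be a nonempty named list")
      lapply(names(spec), function(p) {
        node <- private$resolve_query(p)
        if (!inherits(node, "Parameter"))
          ts_abort("not_found_error",
                   sprintf("'%s' does not name a parameter", p))
        node
      })
    },

    ensure_group = function(parts) {
      node <- private$root
      trail <- character(0)
      for (p in parts) {
        trail <- c(trail, p)
        nxt <- node$children[[p]]
        if (is.null(nxt)) {
          nxt <- GroupNode$new(p, full_name = paste(trail, collapse = "."))
          node$add_child(nxt)
        } else if (!inherits(nxt, "GroupNode")) {
          ts_abort("name_collision_error",
                   sprintf("'%s' exists and is not a group",
                           paste(trail, collapse = ".")))
        }
        node <- nxt
      }
      node
    },

    walk_path = function(parts, deref_last = TRUE) {
      node <- private$root
      for (k in seq_along(parts)) {
        if (!inherits(node, "GroupNode")) return(NULL)
        node <- node$children[[parts[[k]]]]
        if (is.null(node)) return(NULL)
        if (inherits(node, "LinkNode") && (k < length(parts) || deref_last))
          node <- private$deref_link(node)
      }
      node
    },

    deref_link = function(node, hops = 0L) {
      while (inherits(node, "LinkNode")) {
        hops <- hops + 1L
        if (hops > LINK_HOP_CAP)
          ts_abort("link_depth_error",
                   sprintf("link chain exceeds %d hops at '%s'",
                           LINK_HOP_CAP, node$full_name))
        tgt <- private$walk_path(split_path(node$target), deref_last = FALSE)
        if (is.null(tgt))
          ts_abort("not_found_error",
                   sprintf("dangling link '%s' -> '%s'",
                           node$full_name, node$target))
        node <- tgt
      }
      node
    },

    # Breadth-first search below `node` for children named `name`; returns
    # all matches at the minimal depth. Links are matched by name but not
    # traversed through.
    bfs_find = function(node, name) {
      queue <- list(list(n = node, d = 0L))
      found <- list()
      found_depth <- Inf
      while (length(queue) > 0L) {
        head <- queue[[1L]]; queue <- queue[-1L]
        if (head$d >= found_depth) next
        if (!inherits(head$n, "GroupNode")) next
        for (ch in head$n$children) {
          if (identical(node_name(ch), name)) {
            d <- head$d + 1L
            if (d < found_depth) { found <- list(ch); found_depth <- d }
            else if (d == found_depth) found <- c(found, list(ch))
          }
        }
        for (ch in head$n$children)
          if (inherits(ch, "GroupNode"))
            queue <- c(queue, list(list(n = ch, d = head$d + 1L)))
      }
      found
    },

    resolve_query = function(query, retried = FALSE, need_payload = TRUE) {
      stopifnot(is.character(query), length(query) == 1L)
      tokens <- split_path(query)
      tokens <- vapply(tokens, function(t) {
        if (identical(t, "crun")) {
          if (private$idx < 0L)
            ts_abort("not_found_error",
                     "'crun' used but no current run is selected (index -1)")
          run_name(private$idx)
        } else t
      }, character(1))
      candidates <- list(private$root)
      for (t in tokens) {
        next_set <- list()
        best_depth <- Inf
        for (cand in candidates) {
          cand <- private$deref_link(cand)
          hits <- private$bfs_find(cand, t)
          if (length(hits) > 0L)
            next_set <- c(next_set, hits)
        }
        if (length(next_set) == 0L)
          return(private$resolve_miss(query, t, retried, need_payload))
        candidates <- unique(next_set)
      }
      if (length(candidates) > 1L)
        ts_abort("ambiguous_name_error",
                 sprintf(paste0("query '%s' is ambiguous (%d distinct matches ",
                                "at minimal depth); use a longer path"),
                         query, length(candidates)))
      node <- private$deref_link(candidates[[1L]])
      if (need_payload && is_leaf_node(node) && !node$loaded)
        return(private$load_or_miss(node, query, retried))
      node
    },

    resolve_miss = function(query, token, retried, need_payload = TRUE) {
      if (!retried && !is.null(self$storage) && private$struct_level < 1L &&
          self$auto_load) {
        self$storage$load_structure(self)
        return(private$resolve_query(query, retried = TRUE,
                                     need_payload = need_payload))
      }
      hint <- if (!is.null(self$storage) && !self$auto_load)
        "; data may reside on disk - enable auto_load or load it explicitly"
      else ""
      ts_abort("not_found_error",
               sprintf("'%s' not found (failed at component '%s')%s",
                       query, token, hint))
    },

    load_or_miss = function(node, query, retried) {
      if (!is.null(self$storage) && self$auto_load) {
        self$storage$load_node(self, node$full_name)
        return(node)
      }
      ts_abort("not_found_error",
               sprintf(paste0("'%s' resolved to '%s' whose data is not in ",
                              "memory; enable auto_load or load the node ",
                              "explicitly"), query, node$full_name))
    },

    extract = function(node) {
      if (inherits(node, "Parameter")) {
        val <- if (node$is_explored() && private$idx >= 0L)
          node$value_at(private$idx) else node$default()
        if (private$in_run) node$lock()
        return(val)
      }
      if (inherits(node, "Result")) {
        sv <- node$single_value()
        if (!is.null(sv)) return(sv)
        return(node)
      }
      node
    }
  )
)

#' Create a trajectory
#'
#' Convenience constructor for [Trajectory].
#' @param name identifier. @param comment free text.
#' @param registry container-kind registry.
#' @return a new [Trajectory].
#' @export
trajectory <- function(name = "trajectory", comment = "",
                       registry = default_registry()) {
  Trajectory$new(name, comment, registry)
}

#' Cartesian product of exploration sequences
#'
#' Builds a grid exploration from per-parameter value sequences: the output
#' sequences all have length `prod(lengths)` and enumerate every
#' combination, with the first parameter in `order` cycling fastest. For
#' `list(x = c(1, 2, 3, 4), y = c(6, 7, 8))` the points run
#' `(1,6), (2,6), (3,6), (4,6), (1,7), ...` — twelve in total.
#'
#' @param spec named list mapping parameter paths to value sequences.
#' @param order character vector of the spec names; the first cycles
#'   fastest. Defaults to the insertion order of `spec`.
#' @return a named list of matched-length sequences, suitable for
#'   `Trajectory$explore()`.
#' @export
cartesian_product <- function(spec, order = names(spec)) {
  stopifnot(is.list(spec), !is.null(names(spec)), setequal(order, names(spec)))
  as_elems <- function(v) if (is.list(v)) v else as.list(v)
  elems <- lapply(spec, as_elems)
  lens <- vapply(elems, length, integer(1))
  if (any(lens == 0L))
    ts_abort("empty_range_error",
             "cartesian_product() sequences must be nonempty")
  idx_grid <- do.call(expand.grid, c(lapply(lens[order], seq_len),
                                     KEEP.OUT.ATTRS = FALSE))
  names(idx_grid) <- order
  out <- lapply(names(spec), function(nm) {
    vals <- elems[[nm]][idx_grid[[nm]]]
    if (!is.list(spec[[nm]])) unlist(vals) else vals
  })
  names(out) <- names(spec)
  out
}
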