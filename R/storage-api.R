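#' Store a trajectory into an HDF5 file
#'
#' Persists the whole tree, run table and metadata through a
#' [Hdf5StorageService]. Unchanged nodes are skipped, so repeated calls are
#' idempotent.
#'
#' @param traj a [Trajectory].
#' @param filename HDF5 file path; defaults to the file the trajectory is
#'   already attached to.
#' @return the storage service, invisibly.
#' @export
store_trajectory <- function(traj, filename = NULL) {
  svc <- traj$storage
  if (!is.null(filename)) {
    if (is.null(svc) || !identical(svc$filename, filename)) {
      svc <- Hdf5StorageService$new(filename)
      traj$mark_tree_unstored()  # fresh target: nothing is persisted there
    }
  }
  if (is.null(svc))
    ts_abort("io_error",
             "no filename given and trajectory has no attached storage")
  svc$store_tree(traj)
  invisible(svc)
}

#' Store one node (subtree) of a trajectory
#'
#' Manual partial storage: only the named subtree, the run table and the
#' root metadata are (re)written; sibling groups are untouched.
#'
#' @param traj a [Trajectory] with attached storage (or `filename` given).
#' @param path full explicit dotted path of the node.
#' @param filename optional HDF5 file path.
#' @return the storage service, invisibly.
#' @export
store_node <- function(traj, path, filename = NULL) {
  svc <- traj$storage
  if (!is.null(filename) && (is.null(svc) || !identical(svc$filename, filename)))
    svc <- Hdf5StorageService$new(filename)
  if (is.null(svc))
    ts_abort("io_error",
             "no filename given and trajectory has no attached storage")
  svc$store_node(traj, path)
  traj$storage <- svc
  invisible(svc)
}

#' Load a trajectory from an HDF5 file
#'
#' Restores a trajectory at one of three levels: `"skeleton"` (root
#' metadata, run table and the explored parameters with their ranges only),
#' `"structure"` (adds empty group/leaf stubs for the whole tree) or
#' `"full"` (adds all payload data). With `auto_load`, any natural-naming
#' request that misses the in-memory tree is handed to the storage service,
#' which loads the node from disk on the fly — no explicit loading is
#' necessary even after a skeleton-level load.
#'
#' @param filename HDF5 file path.
#' @param name trajectory (root group) name; may be omitted when the file
#'   holds exactly one trajectory.
#' @param level `"skeleton"`, `"structure"` or `"full"`.
#' @param registry container-kind registry; must know every custom tag
#'   stored in the file.
#' @param auto_load enable transparent on-demand loading (default `TRUE`).
#' @return a [Trajectory].
#' @export
load_trajectory <- function(filename, name = NULL,
                            level = c("full", "structure", "skeleton"),
                            registry = default_registry(),
                            auto_load = TRUE) {
  level <- match.arg(level)
  if (!file.exists(filename))
    ts_abort("io_error", sprintf("file '%s' does not exist", filename))
  roots <- rhdf5::h5ls(filename, recursive = FALSE)
  roots <- roots$name[roots$otype == "H5I_GROUP"]
  if (is.null(name)) {
    if (length(roots) != 1L)
      ts_abort("not_found_error",
               sprintf("file holds %d trajectories; specify a name",
                       length(roots)))
    name <- roots[[1L]]
  } else if (!name %in% roots) {
    ts_abort("not_found_error",
             sprintf("no trajectory '%s' in file '%s'", name, filename))
  }
  svc <- Hdf5StorageService$new(filename)
  traj <- Trajectory$new(name, registry = registry)
  traj$storage <- svc
  traj$auto_load <- auto_load
  traj$set_structure_level(0L)

  at <- rhdf5::h5readAttributes(filename, name)
  if (!is.null(at$comment)) traj$comment <- as.character(at$comment)
  runs_path <- paste0(name, "/overview/runs")
  info <- rhdf5::h5ls(filename, recursive = TRUE)
  info_full <- paste0(info$group, ifelse(info$group == "/", "", "/"), info$name)
  if (paste0("/", runs_path) %in% info_full) {
    col <- function(nm) as.vector(rhdf5::h5read(filename,
                                                paste0(runs_path, "/", nm)))
    tbl <- data.frame(index = col("index"), name = col("name"),
                      completed = as.logical(col("completed")),
                      failed = as.logical(col("failed")),
                      runtime_seconds = col("runtime_seconds"),
                      finished_at = col("finished_at"),
                      stringsAsFactors = FALSE)
    tbl$finished_at[tbl$finished_at == "-"] <- ""
    traj$set_run_table_internal(tbl)
  }
  explored <- as.character(at$explored_names %||% character(0))
  if (length(explored) > 0L) {
    for (p in explored) svc$load_node(traj, p)
    traj$set_explored_internal(explored)
  }
  if (level %in% c("structure", "full")) svc$load_structure(traj)
  if (level == "full") svc$load_all(traj)
  traj$mark_run_table_stored()
  traj
}
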