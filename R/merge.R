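#' Merge two trajectories residing in the same parameter space
#'
#' Appends the runs of `traj_b` to `traj_a`: explored ranges are extended,
#' run records are re-indexed to continue `traj_a`'s sequence, and the
#' per-run result subtrees of `traj_b` are re-rooted under the new run
#' names. Both trajectories must have identical parameter leaf sets,
#' identical explored-parameter sets and matching type tags.
#'
#' @param traj_a target [Trajectory] (modified in place and returned).
#' @param traj_b source [Trajectory]; its per-run results must be in memory
#'   (load it at full level when it comes from a file).
#' @param remove_duplicates when `TRUE`, runs of `traj_b` whose explored
#'   point exactly (bitwise) equals an existing point of `traj_a` are
#'   skipped.
#' @return `traj_a`, invisibly.
#' @export
merge_trajectories <- function(traj_a, traj_b, remove_duplicates = FALSE) {
  leaves_of <- function(traj, group) {
    acc <- new.env(parent = emptyenv())
    walk <- function(node) {
      if (is_leaf_node(node)) { acc[[node$full_name]] <- node; return() }
      if (inherits(node, "GroupNode")) for (ch in node$children) walk(ch)
    }
    g <- traj$walk(group)
    if (!is.null(g)) walk(g)
    acc
  }
  pa <- leaves_of(traj_a, "parameters")
  pb <- leaves_of(traj_b, "parameters")
  if (!setequal(ls(pa), ls(pb)))
    ts_abort("space_mismatch_error",
             "trajectories have different parameter leaf sets")
  for (nm in ls(pa)) {
    if (!identical(pa[[nm]]$type_tag, pb[[nm]]$type_tag))
      ts_abort("space_mismatch_error",
               sprintf("parameter '%s' has mismatched type tags", nm))
  }
  if (!setequal(traj_a$explored_names(), traj_b$explored_names()))
    ts_abort("space_mismatch_error",
             "trajectories explore different parameter sets")

  explored <- traj_a$explored_names()
  pa_exp <- lapply(explored, function(nm) pa[[nm]])
  pb_exp <- lapply(explored, function(nm) pb[[nm]])
  La <- traj_a$n_runs()
  Lb <- traj_b$n_runs()
  a_points <- lapply(seq_len(La) - 1L, function(i)
    lapply(pa_exp, function(p) p$value_at(i)))
  rt_b <- traj_b$run_table()

  appended <- 0L
  for (j in seq_len(Lb) - 1L) {
    point <- lapply(pb_exp, function(p) p$value_at(j))
    if (remove_duplicates &&
        any(vapply(a_points, function(ap) values_equal(ap, point), logical(1))))
      next
    new_idx <- La + appended
    for (k in seq_along(pa_exp)) pa_exp[[k]]$append_range(point[k])
    traj_a$append_run_record(
      completed = rt_b$completed[j + 1L], failed = rt_b$failed[j + 1L],
      runtime_seconds = rt_b$runtime_seconds[j + 1L],
      finished_at = rt_b$finished_at[j + 1L])
    src <- traj_b$walk(paste0("results.runs.", run_name(j)))
    if (!is.null(src))
      copy_subtree(traj_a, src, c("results", "runs", run_name(new_idx)))
    appended <- appended + 1L
  }
  invisible(traj_a)
}

# Deep-copy a subtree under a new path prefix inside `traj`. `parts` names
# the destination of `src` itself.
copy_subtree <- function(traj, src, parts) {
  full <- paste(parts, collapse = ".")
  if (inherits(src, "GroupNode")) {
    dst <- traj$ensure_group_internal(parts)
    dst$comment <- src$comment
    dst$annotations <- src$annotations
    for (ch in src$children)
      copy_subtree(traj, ch, c(parts, node_name(ch)))
    return(invisible(dst))
  }
  parent <- traj$ensure_group_internal(parts[-length(parts)])
  if (inherits(src, "LinkNode")) {
    parent$add_child(LinkNode$new(src$name, full, src$target))
  } else {
    parent$add_child(src$copy_as(full))
  }
  invisible(NULL)
}
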