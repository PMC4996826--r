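#' Parameter container
#'
#' A leaf holding one dimension of the parameter space: a single default
#' value, an optional exploration range (the ordered sequence of values the
#' parameter takes across runs), a lock flag and a type tag recording the
#' stored kind. Once a parameter value has been used by a simulation run it
#' is locked against further mutation; accidental mid-simulation changes of
#' a parameter are notoriously hard to track down, so unlocking is explicit
#' and emits a warning.
#'
#' @details Ranges are type-homogeneous: every element must carry the same
#' type tag as the default value, because all elements live in the same
#' dimension of the parameter space. After runs have been executed over a
#' range it may only grow (via trajectory expansion), never be rewritten.
#'
#' @export
Parameter <- R6::R6Class("Parameter",
  public = list(
    #' @field full_name dotted path of the leaf inside the trajectory tree.
    full_name = NULL,
    #' @field comment free-text description of the parameter.
    comment = "",
    #' @field locked whether mutation is currently rejected.
    locked = FALSE,
    #' @field type_tag tag string of the stored kind (see [infer_type_tag()]).
    type_tag = NULL,
    #' @field annotations named list of small annotation values.
    annotations = list(),
    #' @field loaded `FALSE` for stubs whose payload still resides on disk.
    loaded = TRUE,
    #' @field stored `TRUE` once persisted and unchanged since.
    stored = FALSE,

    #' @description Create a parameter leaf.
    #' @param full_name dotted path of the leaf.
    #' @param default initial value (may be `NULL` for a disk stub).
    #' @param comment free-text comment.
    #' @param type_tag explicit tag (required for registered custom kinds).
    #' @param registry container-kind registry used for tag validation.
    initialize = function(full_name, default = NULL, comment = "",
                          type_tag = NULL, registry = default_registry()) {
      self$full_name <- full_name
      self$comment <- comment
      private$registry <- registry
      if (!is.null(default)) self$set_value(default, type_tag = type_tag)
    },

    #' @description Set (replace) the default value.
    #' @param v the new value; must be of a supported kind.
    #' @param type_tag explicit tag for custom kinds.
    set_value = function(v, type_tag = NULL) {
      private$assert_unlocked()
      tag <- check_value_tag(v, type_tag, result_kind = FALSE,
                             registry = private$registry)
      if (!is.null(private$range_) && !identical(tag, self$type_tag))
        ts_abort("heterogeneous_range_error",
                 sprintf("new default kind '%s' differs from range kind '%s'",
                         tag, self$type_tag))
      private$default_ <- v
      self$type_tag <- tag
      self$loaded <- TRUE
      self$stored <- FALSE
      invisible(self)
    },

    #' @description Read the default value.
    default = function() private$default_,

    #' @description Install an exploration range.
    #' @param values nonempty atomic vector or list; every element must have
    #'   the same type tag as the default.
    set_range = function(values) {
      private$assert_unlocked()
      self$locked <- FALSE
      private$range_ <- private$validate_range(values)
      self$stored <- FALSE
      invisible(self)
    },

    #' @description Append values to an existing range (trajectory
    #'   expansion). Bypasses the lock: expansion is a sanctioned append,
    #'   not a rewrite.
    #' @param values values to append, same kind as the range.
    append_range = function(values) {
      private$range_ <- c(private$range_ %||% list(),
                          private$validate_range(values))
      self$stored <- FALSE
      invisible(self)
    },

    #' @description Whether the parameter is explored (has a range).
    is_explored = function() !is.null(private$range_),

    #' @description The exploration range as a list (or `NULL`).
    range = function() private$range_,

    #' @description Length of the range (0 if unexplored).
    range_length = function() length(private$range_ %||% list()),

    #' @description Value of the parameter for one run.
    #' @param run_index 0-based run index. For an explored parameter the
    #'   index selects the range element; for an unexplored parameter the
    #'   default is returned regardless of the index.
    value_at = function(run_index) {
      if (is.null(private$range_)) return(private$default_)
      if (run_index < 0L || run_index >= length(private$range_))
        ts_abort("index_error",
                 sprintf("run index %d out of bounds for range of length %d",
                         run_index, length(private$range_)))
      private$range_[[run_index + 1L]]
    },

    #' @description Lock the parameter against mutation.
    lock = function() { self$locked <- TRUE; invisible(self) },

    #' @description Explicitly unlock; emits a warning because silent
    #'   parameter changes are a classic source of irreproducible runs.
    unlock = function() {
      if (self$locked)
        warning(sprintf("unlocking parameter '%s'", self$full_name),
                call. = FALSE)
      self$locked <- FALSE
      invisible(self)
    },

    #' @description Drop the range (used when splicing loaded state).
    clear_range = function() { private$range_ <- NULL; invisible(self) },

    #' @description Deep copy with a new tree path.
    #' @param full_name dotted path for the copy.
    copy_as = function(full_name = self$full_name) {
      p <- Parameter$new(full_name, comment = self$comment,
                         registry = private$registry)
      p$type_tag <- self$type_tag
      p$annotations <- self$annotations
      p$locked <- self$locked
      p$set_value_internal(private$default_, self$type_tag)
      if (!is.null(private$range_)) p$set_range_internal(private$range_)
      p
    },

    #' @description Internal: install a value without lock/validation checks
    #'   (used by the storage loader).
    #' @param v value. @param tag its tag.
    set_value_internal = function(v, tag) {
      private$default_ <- v
      self$type_tag <- tag
      self$loaded <- TRUE
      invisible(self)
    },

    #' @description Internal: install a range without checks (loader).
    #' @param values list of range elements.
    set_range_internal = function(values) {
      private$range_ <- values
      invisible(self)
    }
  ),
  private = list(
    default_ = NULL,
    range_ = NULL,
    registry = NULL,

    assert_unlocked = function() {
      if (self$locked)
        ts_abort("locked_error",
                 sprintf(paste0("parameter '%s' is locked (already in use); ",
                                "unlock() it explicitly to mutate"),
                         self$full_name))
    },

    validate_range = function(values) {
      if (is.atomic(values) && is.null(dim(values)))
        values <- as.list(values)
      if (!is.list(values) || length(values) == 0L)
        ts_abort("empty_range_error",
                 sprintf("range for '%s' must be a nonempty sequence",
                         self$full_name))
      tags <- vapply(values, function(v)
        tryCatch(check_value_tag(v, NULL, FALSE, private$registry),
                 trajspace_error = function(e) NA_character_), character(1))
      if (anyNA(tags) || length(unique(tags)) != 1L)
        ts_abort("heterogeneous_range_error",
                 sprintf("range elements for '%s' must all share one kind",
                         self$full_name))
      if (!is.null(self$type_tag) && !identical(tags[[1L]], self$type_tag))
        ts_abort("heterogeneous_range_error",
                 sprintf("range kind '%s' incompatible with default kind '%s'",
                         tags[[1L]], self$type_tag))
      values
    }
  )
)

#' Result container
#'
#' A leaf holding a named bag of result items produced by one simulation run
#' or by post-processing. Results are less restrictive than parameters: in
#' addition to the scalar/vector/matrix/list kinds they accept named lists
#' (mappings) and data frames.
#'
#' @export
Result <- R6::R6Class("Result",
  public = list(
    #' @field full_name dotted path of the leaf inside the trajectory tree.
    full_name = NULL,
    #' @field comment free-text description.
    comment = "",
    #' @field annotations named list of small annotation values.
    annotations = list(),
    #' @field loaded `FALSE` for stubs whose payload still resides on disk.
    loaded = TRUE,
    #' @field stored `TRUE` once persisted and unchanged since.
    stored = FALSE,

    #' @description Create a result leaf.
    #' @param full_name dotted path. @param comment free text.
    #' @param registry container-kind registry.
    initialize = function(full_name, comment = "",
                          registry = default_registry()) {
      self$full_name <- full_name
      self$comment <- comment
      private$registry <- registry
    },

    #' @description Add one named item.
    #' @param name item name (valid path component, unique in the leaf).
    #' @param value the item value. @param type_tag explicit custom tag.
    set_item = function(name, value, type_tag = NULL) {
      check_component(name, "item name")
      if (!is.null(private$items_[[name]]))
        ts_abort("name_collision_error",
                 sprintf("item '%s' already exists in result '%s'",
                         name, self$full_name))
      tag <- check_value_tag(value, type_tag, result_kind = TRUE,
                             registry = private$registry)
      private$items_[[name]] <- value
      private$tags_[[name]] <- tag
      self$loaded <- TRUE
      self$stored <- FALSE
      invisible(self)
    },

    #' @description Item value by name.
    #' @param name item name.
    get_item = function(name) {
      if (is.null(private$items_[[name]]))
        ts_abort("not_found_error",
                 sprintf("result '%s' has no item '%s'", self$full_name, name))
      private$items_[[name]]
    },

    #' @description Named list of all items.
    items = function() private$items_,

    #' @description Named list of per-item type tags.
    item_tags = function() private$tags_,

    #' @description Number of items.
    n_items = function() length(private$items_),

    #' @description If the leaf holds exactly one item, its value, else NULL.
    single_value = function() {
      if (length(private$items_) == 1L) private$items_[[1L]] else NULL
    },

    #' @description Deep copy with a new tree path.
    #' @param full_name dotted path for the copy.
    copy_as = function(full_name = self$full_name) {
      r <- Result$new(full_name, comment = self$comment,
                      registry = private$registry)
      r$annotations <- self$annotations
      r$set_items_internal(private$items_, private$tags_)
      r
    },

    #' @description Internal: bulk-install items (loader).
    #' @param items named list. @param tags named list of tags.
    set_items_internal = function(items, tags) {
      private$items_ <- items
      private$tags_ <- tags
      self$loaded <- TRUE
      invisible(self)
    }
  ),
  private = list(
    items_ = list(),
    tags_ = list(),
    registry = NULL
  )
)

`%||%` <- function(a, b) if (is.null(a)) b else a
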