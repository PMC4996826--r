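# Tree plumbing: group nodes and link nodes. Leaves are Parameter/Result
# containers (see containers.R). Groups and leaves alone cannot form cycles;
# links may alias other nodes and are chased with a bounded hop count.

GroupNode <- R6::R6Class("GroupNode",
  public = list(
    name = NULL,
    full_name = NULL,
    comment = "",
    annotations = list(),
    children = NULL,
    stored = FALSE,
    initialize = function(name, full_name = name, comment = "") {
      self$name <- name
      self$full_name <- full_name
      self$comment <- comment
      self$children <- list()
    },
    add_child = function(node) {
      nm <- node_name(node)
      if (!is.null(self$children[[nm]]))
        ts_abort("name_collision_error",
                 sprintf("'%s' already exists under '%s'", nm, self$full_name))
      self$children[[nm]] <- node
      self$stored <- FALSE
      invisible(node)
    },
    child = function(name) self$children[[name]]
  )
)

LinkNode <- R6::R6Class("LinkNode",
  public = list(
    name = NULL,
    full_name = NULL,
    target = NULL,
    stored = FALSE,
    initialize = function(name, full_name, target) {
      self$name <- name
      self$full_name <- full_name
      self$target <- target
    }
  )
)

node_kind <- function(node) {
  if (inherits(node, "GroupNode")) "group"
  else if (inherits(node, "LinkNode")) "link"
  else if (inherits(node, "Parameter")) "parameter"
  else if (inherits(node, "Result")) "result"
  else stop("not a tree node")
}

is_leaf_node <- function(node) inherits(node, c("Parameter", "Result"))

node_short_name <- function(node) {
  parts <- strsplit(node$full_name, ".", fixed = TRUE)[[1L]]
  parts[[length(parts)]]
}

# Leaves (Parameter/Result) carry only full_name; groups/links carry name.
node_name <- function(node) {
  if (!is.null(node$name)) node$name else node_short_name(node)
}
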