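# Type tags identify the stored kind of every data item so that a value
# written to disk decodes back to an object of the same R type: a length-1
# double stays a scalar "float", an integer matrix stays an "int_mat", a
# homogeneous unnamed list stays a list. Results additionally accept named
# lists ("dict") and data frames ("frame").

SCALAR_TAGS <- c(bool = "logical", int = "integer", float = "double",
                 complex = "complex", str = "character")

base_tag_for <- function(v) {
  switch(typeof(v),
    logical = "bool", integer = "int", double = "float",
    complex = "complex", character = "str", NA_character_)
}

is_scalar_value <- function(v) {
  is.atomic(v) && length(v) == 1L && is.null(dim(v)) && !is.na(base_tag_for(v))
}

#' Infer the type tag of a value
#'
#' @param v a candidate value.
#' @param result_kind if `TRUE`, additionally allow the result-only kinds:
#'   named lists (`"dict"`) and data frames (`"frame"`).
#' @return a tag string such as `"float"`, `"int_vec"`, `"float_mat"`,
#'   `"str_list"`, `"dict"` or `"frame"`.
#' @details Supported kinds are scalars of type logical, integer, double,
#'   complex and character; 1-D atomic vectors and 2-D matrices thereof;
#'   homogeneous non-nested unnamed lists of such scalars; and, for results
#'   only, named lists and data frames. Anything else (nested or
#'   heterogeneous lists, higher-dimensional arrays, functions, `NULL`)
#'   signals an `unsupported_type_error`.
#' @export
infer_type_tag <- function(v, result_kind = FALSE) {
  if (is.data.frame(v)) {
    if (!result_kind)
      ts_abort("unsupported_type_error",
               "data frames are accepted by results only")
    return("frame")
  }
  if (is.list(v)) {
    nm <- names(v)
    if (!is.null(nm) && all(nzchar(nm))) {
      if (!result_kind)
        ts_abort("unsupported_type_error",
                 "named lists (mappings) are accepted by results only")
      return("dict")
    }
    if (length(v) == 0L)
      ts_abort("unsupported_type_error", "empty lists are not supported")
    if (!all(vapply(v, is_scalar_value, logical(1))))
      ts_abort("unsupported_type_error",
               "lists must be non-nested and contain scalar elements only")
    tags <- vapply(v, base_tag_for, character(1))
    if (length(unique(tags)) != 1L)
      ts_abort("unsupported_type_error",
               sprintf("heterogeneous list (element kinds: %s)",
                       paste(unique(tags), collapse = ", ")))
    return(paste0(tags[[1L]], "_list"))
  }
  if (is.atomic(v) && !is.null(v)) {
    base <- base_tag_for(v)
    if (is.na(base))
      ts_abort("unsupported_type_error",
               sprintf("unsupported atomic type '%s'", typeof(v)))
    if (!is.null(dim(v))) {
      if (length(dim(v)) != 2L)
        ts_abort("unsupported_type_error",
                 "only 1-D vectors and 2-D matrices are supported")
      return(paste0(base, "_mat"))
    }
    if (length(v) == 1L) return(base)
    return(paste0(base, "_vec"))
  }
  ts_abort("unsupported_type_error",
           sprintf("values of class '%s' are not supported",
                   paste(class(v), collapse = "/")))
}

builtin_tags <- function() {
  base <- names(SCALAR_TAGS)
  c(base, paste0(base, "_vec"), paste0(base, "_mat"), paste0(base, "_list"),
    "dict", "frame")
}

is_builtin_tag <- function(tag) tag %in% builtin_tags()

# Bitwise value equality: explored points are user-specified literals, so
# floats compare exactly, never by tolerance.
values_equal <- function(a, b) identical(a, b)

## ---- custom container-kind registry ---------------------------------------

#' Create an empty container-kind registry
#'
#' A registry maps custom tag strings to encoder/decoder pairs. The default
#' package-wide registry is returned by [default_registry()]. A loader must
#' be handed a registry that knows every custom tag present in a file,
#' mirroring the way custom container constructors must be importable at
#' load time.
#' @return an environment usable as a registry.
#' @export
new_registry <- function() new.env(parent = emptyenv())

.ts_registry <- new_registry()

#' The package-wide default container-kind registry
#' @return the registry environment used when none is passed explicitly.
#' @export
default_registry <- function() .ts_registry

#' Register a custom container kind
#'
#' Extends the set of storable value kinds. `encode` must map a custom value
#' to one of the built-in kinds (see [infer_type_tag()]); `decode` inverts
#' it, such that `decode(encode(v))` compares equal to `v`.
#'
#' @param tag a new tag string (not one of the built-in tags).
#' @param encode function(value) -> built-in-supported value.
#' @param decode function(encoded) -> original value.
#' @param registry the registry to extend (default: package-wide registry).
#' @return the registry, invisibly.
#' @export
register_container_kind <- function(tag, encode, decode,
                                    registry = default_registry()) {
  stopifnot(is.character(tag), length(tag) == 1L,
            is.function(encode), is.function(decode))
  if (is_builtin_tag(tag) || !is.null(registry[[tag]]))
    ts_abort("duplicate_tag_error",
             sprintf("container kind '%s' is already registered", tag))
  registry[[tag]] <- list(encode = encode, decode = decode)
  invisible(registry)
}

lookup_codec <- function(tag, registry) {
  codec <- if (!is.null(registry)) registry[[tag]] else NULL
  if (is.null(codec))
    ts_abort("unknown_tag_error",
             sprintf(paste0("unknown container kind '%s'; register it with ",
                            "register_container_kind() before loading"), tag),
             tag = tag)
  codec
}

# Validate a value against a tag (built-in or registered custom).
check_value_tag <- function(v, tag = NULL, result_kind = FALSE,
                            registry = default_registry()) {
  if (is.null(tag)) return(infer_type_tag(v, result_kind = result_kind))
  if (is_builtin_tag(tag)) {
    inferred <- infer_type_tag(v, result_kind = result_kind)
    if (!identical(inferred, tag))
      ts_abort("unsupported_type_error",
               sprintf("value has kind '%s' but tag '%s' was requested",
                       inferred, tag))
    return(tag)
  }
  lookup_codec(tag, registry)  # errors if unknown
  tag
}
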