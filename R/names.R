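# Naming rules for tree components. Names double as attribute-style path
# components in natural-naming queries, so they are restricted to
# identifier-like strings and must avoid the tokens the resolver reserves.

RUN_NAME_PATTERN <- "^run_[0-9]{8}$"

run_name <- function(index) sprintf("run_%08d", index)

is_valid_component <- function(name) {
  is.character(name) && length(name) == 1L && !is.na(name) &&
    grepl("^[A-Za-z_][A-Za-z0-9_]*$", name) &&
    name != "crun" && !grepl(RUN_NAME_PATTERN, name)
}

check_component <- function(name, what = "name") {
  if (!is_valid_component(name))
    ts_abort("name_collision_error",
             sprintf(paste0("invalid %s '%s': must match [A-Za-z_][A-Za-z0-9_]* ",
                            "and not be a reserved token (crun, run_XXXXXXXX)"),
                     what, name))
  invisible(name)
}

split_path <- function(path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1L]]
  if (length(parts) == 0L || any(!nzchar(parts)))
    ts_abort("not_found_error", sprintf("malformed path '%s'", path))
  parts
}

# Path components allowed inside the results branch additionally include
# generated run names.
check_user_path <- function(path, allow_run_names = FALSE) {
  parts <- split_path(path)
  for (p in parts) {
    if (allow_run_names && grepl(RUN_NAME_PATTERN, p)) next
    check_component(p)
  }
  parts
}
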