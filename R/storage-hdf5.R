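# HDF5 persistence. The trajectory tree maps one-to-one onto the HDF5 group
# hierarchy: every tree node is a group at the corresponding path, tagged by
# a node_kind attribute (group / parameter / result / link). Leaf payloads
# are datasets inside the leaf's group, each carrying a type_tag attribute
# so values decode back to their exact R kind. Run bookkeeping lives in a
# compound dataset at <root>/overview/runs, which carries no node_kind and
# is therefore invisible to the tree loader.

H5_ATTR_PREFIX_ANN <- "ann__"

#' HDF5 storage service
#'
#' Persists and recalls (sub)trees of a [Trajectory] in a single HDF5 file.
#' All writes go through one handle (single-writer rule; runs are stored
#' sequentially even when executed in parallel). Storing is idempotent for
#' unchanged nodes; loading never mutates the file. Deleting or replacing
#' stored user data is unsupported and raises an
#' `unsupported_operation_error`.
#'
#' The service counts item-level reads and writes (`n_read_items`,
#' `n_write_items`) and records the HDF5 paths touched by the most recent
#' store call (`last_store_paths`), which makes lazy-loading and partial
#' storage behaviour observable.
#'
#' @export
Hdf5StorageService <- R6::R6Class("Hdf5StorageService",
  public = list(
    #' @field filename path of the HDF5 file.
    filename = NULL,
    #' @field n_write_items count of item-level dataset writes.
    n_write_items = 0L,
    #' @field n_read_items count of item-level dataset reads.
    n_read_items = 0L,
    #' @field last_store_paths HDF5 paths written by the last store call.
    last_store_paths = character(0),

    #' @description Create a service bound to one file.
    #' @param filename HDF5 file path.
    initialize = function(filename) {
      self$filename <- filename
    },

    #' @description Open a write session (creates the file if missing).
    #'   Sessions nest; the file handle is shared until the outermost
    #'   `end_session()`. Batch operations (a run loop) keep one session
    #'   open to avoid reopening the file per run.
    begin_session = function() {
      if (private$depth == 0L) {
        if (!file.exists(self$filename)) {
          dir.create(dirname(self$filename), recursive = TRUE,
                     showWarnings = FALSE)
          ok <- rhdf5::h5createFile(self$filename)
          if (!isTRUE(ok))
            ts_abort("io_error",
                     sprintf("cannot create HDF5 file '%s'", self$filename))
        }
        private$fid <- rhdf5::H5Fopen(self$filename)
      }
      private$depth <- private$depth + 1L
      invisible(self)
    },

    #' @description Close the write session opened by `begin_session()`.
    end_session = function() {
      private$depth <- private$depth - 1L
      if (private$depth <= 0L) {
        private$depth <- 0L
        if (!is.null(private$fid)) {
          rhdf5::H5Fclose(private$fid)
          private$fid <- NULL
        }
      }
      invisible(self)
    },

    #' @description Store the full trajectory tree (skipping unchanged
    #'   nodes), the run table and the root metadata.
    #' @param traj the [Trajectory].
    store_tree = function(traj) {
      self$last_store_paths <- character(0)
      self$begin_session()
      on.exit(self$end_session())
      private$ensure_root(traj)
      for (ch in traj$root_node()$children)
        private$store_subtree(traj, ch)
      private$write_root_meta(traj)
      self$store_run_table(traj)
      traj$storage <- self
      invisible(self)
    },

    #' @description Store the result subtree of one run plus the run table
    #'   (the per-run storage step of the execution environment; root
    #'   metadata is left untouched).
    #' @param traj the [Trajectory]. @param i run index.
    store_run = function(traj, i) {
      self$begin_session()
      on.exit(self$end_session())
      run_grp <- paste0("results.runs.", run_name(i))
      node <- traj$walk(run_grp)
      if (!is.null(node)) {
        runs_grp <- paste0(traj$name, "/results/runs")
        if (!rhdf5::H5Lexists(private$fid, runs_grp)) {
          rhdf5::h5createGroup(private$fid, runs_grp)
          private$set_attrs(runs_grp, list(node_kind = "group"))
        }
        private$store_subtree(traj, node)
      }
      if (private$table_len == traj$n_runs()) private$store_run_row(traj, i)
      else self$store_run_table(traj)
      invisible(self)
    },

    #' @description Store one subtree only (manual partial storage), plus
    #'   the run table and root metadata.
    #' @param traj the [Trajectory]. @param path full explicit dotted path.
    store_node = function(traj, path) {
      node <- traj$walk(path)
      if (is.null(node))
        ts_abort("not_found_error",
                 sprintf("no node at '%s' to store", path))
      self$last_store_paths <- character(0)
      self$begin_session()
      on.exit(self$end_session())
      private$ensure_root(traj)
      # materialise the parent group chain on disk without touching siblings
      parts <- split_path(path)
      if (length(parts) > 1L) {
        trail <- character(0)
        for (p in parts[-length(parts)]) {
          trail <- c(trail, p)
          gp <- private$h5path(traj, paste(trail, collapse = "."))
          if (!rhdf5::H5Lexists(private$fid, gp)) {
            rhdf5::h5createGroup(private$fid, gp)
            node_mem <- traj$walk(paste(trail, collapse = "."))
            kind <- if (is.null(node_mem)) "group" else node_kind(node_mem)
            private$set_attrs(gp, list(node_kind = kind))
          }
        }
      }
      private$store_subtree(traj, node, force = FALSE)
      private$write_root_meta(traj)
      self$store_run_table(traj)
      invisible(self)
    },

    #' @description Persist the whole run table (one dataset per column
    #'   under `overview/runs`, recreated when the run count changed).
    #' @param traj the [Trajectory].
    store_run_table = function(traj) {
      n <- traj$n_runs()
      if (n == 0L || !traj$run_table_dirty()) return(invisible(self))
      self$begin_session()
      on.exit(self$end_session())
      fid <- private$fid
      ov <- paste0(traj$name, "/overview")
      if (!rhdf5::H5Lexists(fid, ov)) rhdf5::h5createGroup(fid, ov)
      rg <- paste0(ov, "/runs")
      recreate <- !rhdf5::H5Lexists(fid, rg) ||
        !identical(as.integer(rhdf5::h5readAttributes(fid, rg)$n_runs), n)
      if (recreate) {
        if (rhdf5::H5Lexists(fid, rg)) rhdf5::H5Ldelete(fid, rg)
        rhdf5::h5createGroup(fid, rg)
        rhdf5::h5createDataset(fid, paste0(rg, "/name"), dims = n,
                               storage.mode = "character", size = 16L)
        rhdf5::h5createDataset(fid, paste0(rg, "/finished_at"), dims = n,
                               storage.mode = "character", size = 24L)
        for (col in c("index", "completed", "failed"))
          rhdf5::h5createDataset(fid, paste0(rg, "/", col), dims = n,
                                 storage.mode = "integer")
        rhdf5::h5createDataset(fid, paste0(rg, "/runtime_seconds"), dims = n,
                               storage.mode = "double")
        private$set_attrs(rg, list(n_runs = n))
      }
      tbl <- traj$run_table()
      tbl$finished_at[!nzchar(tbl$finished_at)] <- "-"
      rhdf5::h5write(as.integer(tbl$index), fid, paste0(rg, "/index"))
      rhdf5::h5write(tbl$name, fid, paste0(rg, "/name"))
      rhdf5::h5write(as.integer(tbl$completed), fid, paste0(rg, "/completed"))
      rhdf5::h5write(as.integer(tbl$failed), fid, paste0(rg, "/failed"))
      rhdf5::h5write(tbl$runtime_seconds, fid, paste0(rg, "/runtime_seconds"))
      rhdf5::h5write(tbl$finished_at, fid, paste0(rg, "/finished_at"))
      private$table_len <- n
      traj$mark_run_table_stored()
      invisible(self)
    },

    #' @description Deleting or replacing stored data is not supported.
    #' @param traj the [Trajectory]. @param path dotted path.
    delete_node = function(traj, path) {
      ts_abort("unsupported_operation_error",
               "deleting or replacing stored data is not supported")
    },

    #' @description Load the structure level into a skeleton-loaded
    #'   trajectory: stub nodes for every group, leaf and link, without
    #'   payload data.
    #' @param traj the [Trajectory].
    load_structure = function(traj) {
      if (traj$structure_level() >= 1L) return(invisible(traj))
      private$with_read(function(fid) {
        listing <- rhdf5::h5ls(fid, recursive = TRUE)
        grp <- listing[listing$otype == "H5I_GROUP", , drop = FALSE]
        full <- paste0(grp$group, ifelse(grp$group == "/", "", "/"), grp$name)
        prefix <- paste0("/", traj$name, "/")
        rel <- substring(full[startsWith(full, prefix)], nchar(prefix) + 1L)
        rel <- rel[!startsWith(rel, "overview")]
        rel <- rel[order(lengths(strsplit(rel, "/", fixed = TRUE)))]
        leaf_prefixes <- character(0)
        for (rp in rel) {
          if (length(leaf_prefixes) > 0L &&
              any(startsWith(rp, paste0(leaf_prefixes, "/")))) next
          at <- private$read_attrs(fid, paste0("/", traj$name, "/", rp))
          kind <- as.character(at$node_kind %||% "")
          parts <- strsplit(rp, "/", fixed = TRUE)[[1L]]
          dotted <- paste(parts, collapse = ".")
          if (identical(kind, "group")) {
            g <- traj$ensure_group_internal(parts)
            private$apply_common_attrs(g, at)
            g$stored <- TRUE
            next
          }
          leaf_prefixes <- c(leaf_prefixes, rp)
          if (!kind %in% c("parameter", "result", "link")) next  # payload
          parent <- traj$ensure_group_internal(parts[-length(parts)])
          nm <- parts[length(parts)]
          if (!is.null(parent$children[[nm]])) next  # already in memory
          if (identical(kind, "link")) {
            parent$add_child(LinkNode$new(nm, dotted, as.character(at$target)))
            next
          }
          stub <- if (identical(kind, "parameter")) {
            p <- Parameter$new(dotted, registry = traj$registry)
            p$type_tag <- as.character(at$type_tag)
            p$locked <- as.integer(at$locked %||% 0L) > 0L
            p
          } else {
            Result$new(dotted, registry = traj$registry)
          }
          private$apply_common_attrs(stub, at)
          stub$loaded <- FALSE
          stub$stored <- TRUE
          parent$add_child(stub)
        }
      })
      traj$set_structure_level(1L)
      invisible(traj)
    },

    #' @description Load one node (and, for groups, its whole subtree) with
    #'   payload data, splicing it into the in-memory tree.
    #' @param traj the [Trajectory]. @param path full explicit dotted path.
    load_node = function(traj, path) {
      private$with_read(function(fid) {
        h5p <- private$h5path(traj, path)
        if (!rhdf5::H5Lexists(fid, h5p))
          ts_abort("not_found_error",
                   sprintf("'%s' does not exist in file '%s'",
                           path, self$filename))
        private$load_into(traj, fid, path)
      })
      invisible(traj)
    },

    #' @description Load payloads for every leaf still unloaded in memory.
    #' @param traj the [Trajectory].
    load_all = function(traj) {
      self$load_structure(traj)
      private$with_read(function(fid) {
        walk <- function(node) {
          if (is_leaf_node(node)) {
            if (!node$loaded) private$load_into(traj, fid, node$full_name)
            return()
          }
          if (inherits(node, "GroupNode")) for (ch in node$children) walk(ch)
        }
        for (ch in traj$root_node()$children) walk(ch)
      })
      traj$set_structure_level(2L)
      invisible(traj)
    }
  ),

  private = list(
    fid = NULL,
    depth = 0L,
    table_len = -1L,

    # single-row run-table update (avoids rewriting a growing table per run)
    # Minimal per-run bookkeeping write: the completion flag is what a
    # crash-resume needs; runtimes and timestamps are flushed by the full
    # table write at the end of the batch.
    store_run_row = function(traj, i) {
      fid <- private$fid
      rg <- paste0(traj$name, "/overview/runs")
      rec <- traj$run_record(i)
      pos <- list(i + 1L)
      rhdf5::h5write(as.integer(rec$completed), fid,
                     paste0(rg, "/completed"), index = pos)
      if (rec$failed)
        rhdf5::h5write(1L, fid, paste0(rg, "/failed"), index = pos)
    },

    write_root_meta = function(traj) {
      attrs <- list(format_version = "1", trajectory_name = traj$name,
                    comment = traj$comment, n_runs = traj$n_runs())
      if (length(traj$explored_names()) > 0L)
        attrs$explored_names <- traj$explored_names()
      private$set_attrs(traj$name, attrs)
    },

    h5path = function(traj, dotted) {
      if (!nzchar(dotted)) return(traj$name)
      paste0(traj$name, "/", gsub(".", "/", dotted, fixed = TRUE))
    },

    with_read = function(fn) {
      if (!file.exists(self$filename))
        ts_abort("io_error", sprintf("file '%s' does not exist", self$filename))
      if (!is.null(private$fid)) return(fn(private$fid))
      fid <- rhdf5::H5Fopen(self$filename, flags = "H5F_ACC_RDONLY")
      on.exit(rhdf5::H5Fclose(fid))
      fn(fid)
    },

    set_attrs = function(path, attrs, fresh = FALSE) {
      oid <- rhdf5::H5Oopen(private$fid, path)
      on.exit(rhdf5::H5Oclose(oid))
      for (nm in names(attrs)) {
        v <- attrs[[nm]]
        if (is.logical(v)) v <- as.integer(v)
        if (!fresh && rhdf5::H5Aexists(oid, nm)) rhdf5::H5Adelete(oid, nm)
        rhdf5::h5writeAttribute(v, oid, nm)
      }
    },

    node_attrs = function(node) {
      attrs <- list(node_kind = node_kind(node))
      cm <- if (!is.null(node$comment)) node$comment else ""
      if (nzchar(cm)) attrs$comment <- cm
      if (!inherits(node, "LinkNode")) {
        for (nm in names(node$annotations)) {
          attrs[[paste0(H5_ATTR_PREFIX_ANN, nm)]] <- node$annotations[[nm]]
        }
      }
      attrs
    },

    ensure_root = function(traj) {
      if (!rhdf5::H5Lexists(private$fid, traj$name))
        rhdf5::h5createGroup(private$fid, traj$name)
      for (g in c("parameters", "results", "config")) {
        gp <- paste0(traj$name, "/", g)
        if (!rhdf5::H5Lexists(private$fid, gp)) {
          rhdf5::h5createGroup(private$fid, gp)
          private$set_attrs(gp, list(node_kind = "group"))
        }
      }
    },

    ensure_h5_group = function(path) {
      if (!rhdf5::H5Lexists(private$fid, path))
        rhdf5::h5createGroup(private$fid, path)
    },

    store_subtree = function(traj, node, force = FALSE) {
      h5p <- private$h5path(traj, node$full_name)
      if (inherits(node, "GroupNode")) {
        private$ensure_h5_group(h5p)
        if (!node$stored || force) {
          private$set_attrs(h5p, private$node_attrs(node))
          node$stored <- TRUE
          self$last_store_paths <- c(self$last_store_paths, h5p)
        }
        for (ch in node$children) private$store_subtree(traj, ch, force)
        return(invisible(NULL))
      }
      if (node$stored && !force) return(invisible(NULL))
      fresh <- !rhdf5::H5Lexists(private$fid, h5p)
      if (fresh) rhdf5::h5createGroup(private$fid, h5p)
      if (inherits(node, "LinkNode")) {
        private$set_attrs(h5p, c(private$node_attrs(node),
                                 list(target = node$target)), fresh = fresh)
      } else if (inherits(node, "Parameter")) {
        if (!node$loaded) return(invisible(NULL))  # stub: nothing newer here
        attrs <- private$node_attrs(node)
        attrs$type_tag <- node$type_tag
        attrs$locked <- as.integer(node$locked)
        attrs$explored <- as.integer(node$is_explored())
        private$set_attrs(h5p, attrs, fresh = fresh)
        if (!fresh) private$delete_if_exists(paste0(h5p, "/default"))
        private$write_item(paste0(h5p, "/default"), node$default(),
                           node$type_tag, traj$registry, fresh = fresh)
        if (!fresh) private$delete_if_exists(paste0(h5p, "/range"))
        if (node$is_explored())
          private$write_range(paste0(h5p, "/range"), node$range(),
                              node$type_tag, traj$registry)
      } else {  # Result
        if (!node$loaded) return(invisible(NULL))
        attrs <- private$node_attrs(node)
        items <- node$items()
        tags <- node$item_tags()
        if (length(items) > 0L) attrs$item_order <- names(items)
        private$set_attrs(h5p, attrs, fresh = fresh)
        for (nm in names(items)) {
          ip <- paste0(h5p, "/", nm)
          if (!fresh) private$delete_if_exists(ip)
          private$write_item(ip, items[[nm]], tags[[nm]], traj$registry,
                             fresh = fresh)
        }
      }
      node$stored <- TRUE
      self$last_store_paths <- c(self$last_store_paths, h5p)
      invisible(NULL)
    },

    delete_if_exists = function(path) {
      # internal bookkeeping rewrites only (range growth, re-stored leaves);
      # user-facing deletion is rejected in delete_node()
      if (rhdf5::H5Lexists(private$fid, path))
        rhdf5::H5Ldelete(private$fid, path)
    },

    ## ---- item encoding -----------------------------------------------------

    write_item = function(path, value, tag, registry, fresh = FALSE) {
      self$n_write_items <- self$n_write_items + 1L
      self$last_store_paths <- c(self$last_store_paths, path)
      if (!is_builtin_tag(tag)) {
        codec <- lookup_codec(tag, registry)
        inner <- codec$encode(value)
        inner_tag <- infer_type_tag(inner, result_kind = TRUE)
        private$write_payload(path, inner, inner_tag, registry)
        private$set_attrs(path, list(type_tag = tag, inner_tag = inner_tag),
                          fresh = fresh)
        return(invisible(NULL))
      }
      private$write_payload(path, value, tag, registry)
      private$set_attrs(path, list(type_tag = tag), fresh = fresh)
      invisible(NULL)
    },

    write_payload = function(path, value, tag, registry) {
      fid <- private$fid
      base <- sub("_(vec|mat|list)$", "", tag)
      if (tag == "dict") {
        private$ensure_h5_group(path)
        private$set_attrs(path, list(key_order = names(value) %||% character(0)))
        for (nm in names(value)) {
          itag <- infer_type_tag(value[[nm]], result_kind = TRUE)
          private$write_item(paste0(path, "/", nm), value[[nm]], itag, registry)
        }
        return(invisible(NULL))
      }
      if (tag == "frame") {
        private$ensure_h5_group(path)
        private$set_attrs(path, list(column_order = names(value)))
        for (nm in names(value)) {
          col <- value[[nm]]
          itag <- infer_type_tag(col, result_kind = FALSE)
          private$write_item(paste0(path, "/", nm), col, itag, registry)
        }
        return(invisible(NULL))
      }
      if (base == "complex" && grepl("_mat$", tag)) {
        private$ensure_h5_group(path)
        rhdf5::h5write(Re(value), fid, paste0(path, "/re"))
        rhdf5::h5write(Im(value), fid, paste0(path, "/im"))
        return(invisible(NULL))
      }
      v <- value
      if (grepl("_list$", tag)) v <- unlist(v)
      if (base == "bool") v <- if (is.matrix(v)) {
        m <- v; storage.mode(m) <- "integer"; m
      } else as.integer(v)
      if (base == "complex") {
        v <- if (length(v) == 1L && !grepl("_(vec|list)$", tag))
          c(Re(v), Im(v)) else rbind(Re(v), Im(v))
      }
      private$write_dataset(path, v)
      invisible(NULL)
    },

    # zlib level 4 for payloads over 1 KiB, contiguous below
    write_dataset = function(path, v) {
      fid <- private$fid
      nbytes <- if (is.character(v)) sum(nchar(v)) else length(v) * 8L
      if (!is.character(v) && nbytes > 1024) {
        dims <- if (is.null(dim(v))) length(v) else dim(v)
        chunk <- pmin(dims, if (length(dims) == 1L) 16384L else c(512L, 512L))
        rhdf5::h5createDataset(fid, path, dims = dims,
                               storage.mode = storage.mode(v),
                               chunk = chunk, level = 4L)
      }
      rhdf5::h5write(v, fid, path)
    },

    write_range = function(path, values, tag, registry) {
      if (all(vapply(values, is_scalar_value, logical(1))) &&
          is_builtin_tag(tag) && !tag %in% c("dict", "frame")) {
        v <- unlist(values)
        if (is.logical(v)) v <- as.integer(v)
        if (is.complex(v)) v <- rbind(Re(v), Im(v))
        private$write_dataset(path, v)
        private$set_attrs(path, list(range_tag = tag, range_layout = "flat",
                                     range_length = length(values)))
      } else {
        private$ensure_h5_group(path)
        private$set_attrs(path, list(range_layout = "elements",
                                     range_length = length(values)))
        for (k in seq_along(values)) {
          etag <- if (is_builtin_tag(tag)) tag else tag
          private$write_item(sprintf("%s/e_%06d", path, k - 1L),
                             values[[k]], etag, registry)
        }
      }
      self$n_write_items <- self$n_write_items + 1L
      invisible(NULL)
    },

    ## ---- item decoding -----------------------------------------------------

    read_attrs = function(fid, path) {
      rhdf5::h5readAttributes(fid, path)
    },

    read_item = function(fid, path, registry) {
      self$n_read_items <- self$n_read_items + 1L
      at <- private$read_attrs(fid, path)
      tag <- as.character(at$type_tag)
      if (!is_builtin_tag(tag)) {
        codec <- lookup_codec(tag, registry)
        inner <- private$read_payload(fid, path, as.character(at$inner_tag),
                                      registry)
        return(codec$decode(inner))
      }
      private$read_payload(fid, path, tag, registry)
    },

    read_payload = function(fid, path, tag, registry) {
      base <- sub("_(vec|mat|list)$", "", tag)
      at <- private$read_attrs(fid, path)
      if (tag == "dict") {
        keys <- as.character(at$key_order)
        out <- lapply(keys, function(nm)
          private$read_item(fid, paste0(path, "/", nm), registry))
        names(out) <- keys
        return(out)
      }
      if (tag == "frame") {
        cols <- as.character(at$column_order)
        out <- lapply(cols, function(nm)
          private$read_item(fid, paste0(path, "/", nm), registry))
        names(out) <- cols
        return(data.frame(out, stringsAsFactors = FALSE))
      }
      if (base == "complex" && grepl("_mat$", tag)) {
        re <- rhdf5::h5read(fid, paste0(path, "/re"))
        im <- rhdf5::h5read(fid, paste0(path, "/im"))
        return(matrix(complex(real = re, imaginary = im), nrow = nrow(re)))
      }
      raw <- rhdf5::h5read(fid, path)
      private$decode_atomic(raw, tag)
    },

    decode_atomic = function(raw, tag) {
      base <- sub("_(vec|mat|list)$", "", tag)
      is_mat <- grepl("_mat$", tag)
      v <- raw
      if (base == "complex") {
        if (grepl("_(vec|list)$", tag)) {
          v <- complex(real = raw[1, ], imaginary = raw[2, ])
        } else {
          v <- complex(real = raw[1], imaginary = raw[2])
        }
      } else if (!is_mat) {
        v <- as.vector(v)
      } else {
        dim(v) <- dim(raw)
      }
      if (base == "bool") {
        if (is_mat) { m <- v; storage.mode(m) <- "logical"; v <- m }
        else v <- as.logical(v)
      }
      if (base == "str" && !is_mat) v <- as.character(v)
      if (grepl("_list$", tag)) v <- as.list(v)
      v
    },

    read_range = function(fid, path, registry) {
      at <- private$read_attrs(fid, path)
      if (identical(as.character(at$range_layout), "flat")) {
        tag <- as.character(at$range_tag)
        raw <- rhdf5::h5read(fid, path)
        v <- private$decode_atomic(raw, paste0(tag, "_list"))
        # elements are scalars of kind `tag`
        return(v)
      }
      n <- as.integer(at$range_length)
      lapply(seq_len(n) - 1L, function(k)
        private$read_item(fid, sprintf("%s/e_%06d", path, k), registry))
    },

    ## ---- node loading ------------------------------------------------------

    load_into = function(traj, fid, dotted) {
      h5p <- private$h5path(traj, dotted)
      at <- private$read_attrs(fid, h5p)
      kind <- as.character(at$node_kind %||% "group")
      parts <- split_path(dotted)
      if (kind == "group") {
        g <- traj$ensure_group_internal(parts)
        private$apply_common_attrs(g, at)
        g$stored <- TRUE
        gid <- rhdf5::H5Gopen(fid, h5p)
        listing <- rhdf5::h5ls(gid, recursive = FALSE)
        rhdf5::H5Gclose(gid)
        subs <- listing$name[listing$otype == "H5I_GROUP"]
        for (nm in subs)
          private$load_into(traj, fid, paste(c(parts, nm), collapse = "."))
        return(invisible(NULL))
      }
      parent <- traj$ensure_group_internal(parts[-length(parts)])
      nm <- parts[length(parts)]
      existing <- parent$children[[nm]]
      if (kind == "link") {
        if (is.null(existing))
          parent$add_child(LinkNode$new(nm, dotted,
                                        as.character(at$target)))
        return(invisible(NULL))
      }
      if (kind == "parameter") {
        p <- existing
        if (is.null(p)) {
          p <- Parameter$new(dotted, registry = traj$registry)
          parent$add_child(p)
        }
        private$apply_common_attrs(p, at)
        p$type_tag <- as.character(at$type_tag)
        p$locked <- as.integer(at$locked %||% 0L) > 0L
        val <- private$read_item(fid, paste0(h5p, "/default"), traj$registry)
        p$set_value_internal(val, as.character(at$type_tag))
        if (as.integer(at$explored %||% 0L) > 0L)
          p$set_range_internal(private$read_range(fid, paste0(h5p, "/range"),
                                                  traj$registry))
        p$stored <- TRUE
        return(invisible(NULL))
      }
      if (kind == "result") {
        r <- existing
        if (is.null(r)) {
          r <- Result$new(dotted, registry = traj$registry)
          parent$add_child(r)
        }
        private$apply_common_attrs(r, at)
        item_names <- as.character(at$item_order %||% character(0))
        items <- list(); tags <- list()
        for (inm in item_names) {
          ip <- paste0(h5p, "/", inm)
          items[[inm]] <- private$read_item(fid, ip, traj$registry)
          iat <- private$read_attrs(fid, ip)
          tags[[inm]] <- as.character(iat$type_tag)
        }
        r$set_items_internal(items, tags)
        r$stored <- TRUE
        return(invisible(NULL))
      }
      ts_abort("io_error", sprintf("unknown node kind '%s' at '%s'", kind, h5p))
    },

    apply_common_attrs = function(node, at) {
      if (!is.null(at$comment)) node$comment <- as.character(at$comment)
      ann_names <- grep(paste0("^", H5_ATTR_PREFIX_ANN), names(at), value = TRUE)
      for (an in ann_names) {
        v <- at[[an]]
        if (is.array(v) && length(v) == 1L) v <- as.vector(v)
        node$annotations[[substring(an, nchar(H5_ATTR_PREFIX_ANN) + 1L)]] <- v
      }
    }
  )
)
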