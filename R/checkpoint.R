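# Checkpoints: a directory holding the parameter map (scope -> array), the
# step number, the fully resolved configuration text, and optional run state
# (RNG streams, optimizer moments) so training can resume exactly.

#' Save a checkpoint
#'
#' Writes `parameters.rds` (step, scope -> array map, optional run state) and
#' `config.ini` (the fully resolved configuration, defaults included) into
#' `path`.  The embedded configuration alone is sufficient to re-launch
#' inference.
#'
#' @param store a [vx_param_store()] (or a `vx_network` plus its store, see
#'   `...`).
#' @param step iteration number.
#' @param config a resolved config object from [parse_config()], or `NULL`.
#' @param path checkpoint directory (created).
#' @param run_state optional list (RNG snapshots, optimizer state) for exact
#'   resume.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(store, step, config = NULL, path, run_state = NULL) {
  vp_assert(inherits(store, "vx_param_store"), "store must be a vx_param_store")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  pm <- lapply(setNames(store$order, store$order), function(s) store$params[[s]])
  saveRDS(list(step = as.integer(step), parameter_map = pm,
               run_state = run_state),
          file.path(path, "parameters.rds"))
  if (!is.null(config)) {
    writeLines(format_config(config), file.path(path, "config.ini"))
  }
  invisible(path)
}

#' Restore a checkpoint
#'
#' Reads a checkpoint directory and optionally renames parameter scopes, so
#' that a named block's weights can be loaded into a differently named block
#' of identical shape (`scope_renames = c("net/level0" = "net2/encoder")`
#' renames every scope under the old prefix).
#'
#' @param path checkpoint directory.
#' @param scope_renames named character vector, old prefix -> new prefix.
#' @return a `checkpoint` list: `step`, `parameter_map`, `config`
#'   (re-parsed resolved config or `NULL`), `run_state`.
#' @export
restore_checkpoint <- function(path, scope_renames = NULL) {
  f <- file.path(path, "parameters.rds")
  vp_assert(file.exists(f), "no checkpoint at %s", path)
  ck <- readRDS(f)
  pm <- ck$parameter_map
  if (!is.null(scope_renames)) {
    vp_assert(!is.null(names(scope_renames)), "scope_renames must be named old -> new")
    for (old in names(scope_renames)) {
      hits <- startsWith(names(pm), old)
      if (!any(hits)) vp_stop("unmatched scope in renames: '%s'", old)
      names(pm)[hits] <- paste0(scope_renames[[old]],
                                substring(names(pm)[hits], nchar(old) + 1L))
    }
  }
  cfg_file <- file.path(path, "config.ini")
  cfg <- if (file.exists(cfg_file)) parse_config(cfg_file) else NULL
  structure(list(step = ck$step, parameter_map = pm, config = cfg,
                 run_state = ck$run_state), class = "checkpoint")
}

#' Assign checkpoint parameters into a store
#'
#' Every entry of the checkpoint's (possibly renamed) parameter map is
#' written into the store; an existing scope with a different shape raises
#' an error listing the scope and both shapes.
#'
#' @param store a [vx_param_store()].
#' @param checkpoint a `checkpoint` or a bare parameter map.
#' @return the store, invisibly.
#' @export
apply_checkpoint <- function(store, checkpoint) {
  pm <- if (inherits(checkpoint, "checkpoint")) checkpoint$parameter_map else checkpoint
  for (s in names(pm)) {
    new <- pm[[s]]
    if (!is.null(store$params[[s]])) {
      old_d <- dim(store$params[[s]]) %||% length(store$params[[s]])
      new_d <- dim(new) %||% length(new)
      if (!identical(as.integer(old_d), as.integer(new_d))) {
        vp_stop("shape mismatch restoring scope '%s': checkpoint %s vs network %s",
                s, paste(new_d, collapse = "x"), paste(old_d, collapse = "x"))
      }
    } else {
      store$order <- c(store$order, s)
    }
    store$params[[s]] <- new
  }
  invisible(store)
}
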