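# INI-style configuration: parse, validate against the key schema, fill every
# default in (the resolved config is fully explicit and is what checkpoints
# embed), serialize back to INI text.

# key schema: type in {int, num, num2, int3, intvec, numvec, bool, str, enum}
config_schema <- function() {
  list(
    system = list(
      action = list(type = "enum", choices = c("train", "inference",
                                               "evaluation", "linear_interpolation"),
                    default = NULL, mandatory = TRUE),
      model_dir = list(type = "str", default = NULL, mandatory = TRUE),
      seed = list(type = "int", default = 42L)
    ),
    network = list(
      name = list(type = "str", default = "reference_segnet"),
      n_classes = list(type = "int", default = 2L),
      depth = list(type = "int", default = 2L),
      growth = list(type = "int", default = 8L),
      n_blocks = list(type = "int", default = 2L)
    ),
    training = list(
      lr = list(type = "num", default = 1e-3),
      iterations = list(type = "int", default = 100L),
      loss = list(type = "enum", choices = c("dice", "rmse"), default = "dice"),
      samples_per_volume = list(type = "int", default = 1L),
      save_every = list(type = "int", default = 100L),
      spatial_window_size = list(type = "int3", default = c(16L, 16L, 16L)),
      augmentation = list(type = "bool", default = FALSE),
      rotation_range = list(type = "num2", default = c(-10, 10)),
      scaling_range = list(type = "num2", default = c(90, 110)),
      flip_axes = list(type = "intvec", default = integer(0)),
      normalisation = list(type = "enum", choices = c("meanvar", "none"),
                           default = "meanvar"),
      label_section = list(type = "str", default = "label"),
      target_section = list(type = "str", default = "target")
    ),
    inference = list(
      spatial_window_size = list(type = "int3", default = c(16L, 16L, 16L)),
      border = list(type = "int3", default = c(0L, 0L, 0L)),
      sampler = list(type = "enum", choices = c("grid", "resize"),
                     default = "grid"),
      output_dir = list(type = "str", default = ""),
      output_kind = list(type = "enum", choices = c("label", "continuous"),
                         default = "label"),
      save_probabilities = list(type = "bool", default = FALSE)
    ),
    evaluation = list(
      metrics = list(type = "str", default = ""),
      labels = list(type = "intvec", default = integer(0)),
      spacing_units = list(type = "enum", choices = c("voxels", "mm"),
                           default = "voxels")
    )
  )
}

data_section_schema <- function() {
  list(
    path = list(type = "str", default = ""),
    pattern = list(type = "str", default = ""),
    csv = list(type = "str", default = ""),
    interpolation = list(type = "enum", choices = c("linear", "nearest"),
                         default = NULL)  # filled per section name
  )
}

parse_ini <- function(lines) {
  out <- list()
  sec <- NULL
  for (i in seq_along(lines)) {
    ln <- sub("[;#].*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.+\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[sec]])) out[[sec]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      vp_assert(!is.null(sec), "config line %d outside any [section]: %s", i, ln)
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[sec]][[trimws(kv[1])]] <- trimws(kv[2])
    } else {
      vp_stop("malformed config line %d: %s", i, ln)
    }
  }
  out
}

convert_value <- function(raw, spec, section, key) {
  if (is.null(raw)) return(spec$default)
  if (!is.character(raw)) return(raw)  # already typed (programmatic override)
  bad <- function() vp_stop("invalid value for %s.%s: '%s'", section, key, raw)
  toks <- strsplit(trimws(raw), "[,[:space:]]+")[[1]]
  switch(spec$type,
    int = { v <- suppressWarnings(as.integer(toks)); if (length(v) != 1 || anyNA(v)) bad(); v },
    num = { v <- suppressWarnings(as.numeric(toks)); if (length(v) != 1 || anyNA(v)) bad(); v },
    num2 = { v <- suppressWarnings(as.numeric(toks)); if (anyNA(v) || !length(v) %in% 1:2) bad();
             if (length(v) == 1) rep(v, 2) else v },
    int3 = { v <- suppressWarnings(as.integer(toks)); if (anyNA(v) || !length(v) %in% c(1, 3)) bad();
             if (length(v) == 1) rep(v, 3L) else v },
    intvec = { if (identical(toks, character(0)) || identical(raw, "")) integer(0)
               else { v <- suppressWarnings(as.integer(toks)); if (anyNA(v)) bad(); v } },
    numvec = { v <- suppressWarnings(as.numeric(toks)); if (anyNA(v)) bad(); v },
    bool = { if (!tolower(raw) %in% c("true", "false", "on", "off", "yes", "no", "1", "0")) bad();
             tolower(raw) %in% c("true", "on", "yes", "1") },
    str = raw,
    enum = { if (!raw %in% spec$choices) vp_stop(
               "invalid value for %s.%s: '%s' (choices: %s)", section, key, raw,
               paste(spec$choices, collapse = ", ")); raw })
}

#' Parse and resolve a pipeline configuration
#'
#' Reads an INI-style configuration file, applies command-line overrides
#' (which win over file values), validates every key against the schema
#' (unknown keys are an error, not a warning) and fills in all defaults, so
#' the resolved object is fully explicit.  Sections other than
#' `[system] [network] [training] [inference] [evaluation]` are data-source
#' sections (keys: `path`, `pattern`, `csv`, `interpolation`).
#'
#' @param file path to the INI file, or a `voxpipe_config` (returned
#'   unchanged after applying overrides).
#' @param cli_overrides named character vector/list, names `"section.key"`.
#' @return a `voxpipe_config`: named list of sections with `data` holding
#'   the data-source sections.
#' @export
parse_config <- function(file, cli_overrides = NULL) {
  if (inherits(file, "voxpipe_config") && is.null(cli_overrides)) return(file)
  if (inherits(file, "voxpipe_config")) {
    raw <- c(lapply(file[names(file) != "data"], function(s) lapply(s, identity)),
             file$data)
  } else {
    vp_assert(file.exists(file), "config file not found: %s", file)
    raw <- parse_ini(readLines(file))
  }
  for (ov in names(cli_overrides)) {
    parts <- strsplit(ov, ".", fixed = TRUE)[[1]]
    vp_assert(length(parts) == 2, "override '%s' must be section.key", ov)
    if (is.null(raw[[parts[1]]])) raw[[parts[1]]] <- list()
    raw[[parts[1]]][[parts[2]]] <- cli_overrides[[ov]]
  }
  schema <- config_schema()
  out <- list()
  for (sec in names(schema)) {
    keys <- schema[[sec]]
    given <- raw[[sec]] %||% list()
    unknown <- setdiff(names(given), names(keys))
    vp_assert(length(unknown) == 0, "unknown key(s) in [%s]: %s", sec,
              paste(unknown, collapse = ", "))
    out[[sec]] <- lapply(setNames(names(keys), names(keys)), function(k)
      convert_value(given[[k]], keys[[k]], sec, k))
  }
  # mandatory keys
  for (k in c("action", "model_dir")) {
    if (is.null(out$system[[k]]) || identical(out$system[[k]], "")) {
      vp_stop("missing mandatory key: system.%s", k)
    }
  }
  # data sections
  dsch <- data_section_schema()
  data_secs <- setdiff(names(raw), names(schema))
  vp_assert(length(data_secs) >= 1, "missing mandatory data section (e.g. [image])")
  out$data <- list()
  for (sec in data_secs) {
    given <- raw[[sec]]
    unknown <- setdiff(names(given), names(dsch))
    vp_assert(length(unknown) == 0, "unknown key(s) in [%s]: %s", sec,
              paste(unknown, collapse = ", "))
    entry <- lapply(setNames(names(dsch), names(dsch)), function(k)
      convert_value(given[[k]], dsch[[k]], sec, k))
    if (is.null(entry$interpolation)) {
      entry$interpolation <- if (sec %in% c("label", "weight")) "nearest" else "linear"
    }
    vp_assert(nzchar(entry$csv) || (nzchar(entry$path) && nzchar(entry$pattern)),
              "data section [%s] needs either csv or path + pattern", sec)
    out$data[[sec]] <- entry
  }
  structure(out, class = "voxpipe_config")
}

#' Serialize a resolved configuration to INI text
#'
#' @param config a `voxpipe_config`.
#' @return character vector of INI lines (all defaults explicit).
#' @export
format_config <- function(config) {
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
               collapse = " ")
  }
  lines <- character(0)
  secs <- c(config[names(config) != "data"], config$data)
  for (sec in names(secs)) {
    lines <- c(lines, sprintf("[%s]", sec))
    for (k in names(secs[[sec]])) {
      v <- secs[[sec]][[k]]
      if (is.null(v)) next
      lines <- c(lines, sprintf("%s = %s", k, fmt(v)))
    }
    lines <- c(lines, "")
  }
  lines
}

#' @export
print.voxpipe_config <- function(x, ...) {
  cat(paste(format_config(x), collapse = "\n"))
  invisible(x)
}
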