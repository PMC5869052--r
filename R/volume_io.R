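NIFTI_EXT_RE <- "\\.nii(\\.gz)?$"

#' In-memory image volume with spatial metadata
#'
#' The basic data container of the pipeline: a 5-axis voxel array in
#' `(x, y, z, time, channel)` layout (singleton axes allowed) together with
#' the 4x4 voxel-to-world affine (mm), voxel spacing, anatomical orientation
#' codes and the pipeline section the volume belongs to.  Coordinates are
#' 0-based and half-open throughout the package; the spatial axes are ordered
#' `(x, y, z)` as stored in the NIfTI array.
#'
#' @param data numeric array with 3 to 5 dimensions; reshaped to 5 axes.
#'   A 4D input is interpreted as `(x, y, z, channel)`, i.e. the 4th axis
#'   holds modalities.
#' @param affine 4x4 voxel-to-world matrix (mm); must be invertible.
#' @param section one of `"image"`, `"label"`, `"weight"`, `"inferred"`.
#' @param modality_names channel labels; defaults to `"mod1"`, `"mod2"`, ...
#' @return an object of class `image_volume` with fields `data`, `affine`,
#'   `spacing`, `axcodes`, `section`, `modality_names`.
#' @export
image_volume <- function(data, affine = diag(4), section = "image",
                         modality_names = NULL) {
  d <- dim(data) %||% length(data)
  vp_assert(length(d) >= 1 && length(d) <= 5, "data must have 1 to 5 dimensions")
  d5 <- switch(as.character(length(d)),
    "1" = c(d, 1L, 1L, 1L, 1L),
    "2" = c(d, 1L, 1L, 1L),
    "3" = c(d, 1L, 1L),
    "4" = c(d[1:3], 1L, d[4]),  # 4th axis = channels
    "5" = d)
  dim(data) <- d5
  vp_assert(all(d5[1:3] >= 1), "spatial dims must be >= 1")
  affine <- as.matrix(affine)
  vp_assert(all(dim(affine) == c(4, 4)), "affine must be 4x4")
  vp_assert(abs(det(affine)) > .Machine$double.eps, "affine must be invertible")
  section <- match.arg(section, c("image", "label", "weight", "inferred"))
  nc <- d5[5]
  if (is.null(modality_names)) modality_names <- paste0("mod", seq_len(nc))
  vp_assert(length(modality_names) == nc,
            "channel count (%d) != length(modality_names) (%d)", nc, length(modality_names))
  structure(list(
    data = data,
    affine = affine,
    spacing = affine_spacing(affine),
    axcodes = affine_axcodes(affine),
    section = section,
    modality_names = as.character(modality_names)
  ), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %s  spacing %s mm  axcodes %s  channels: %s\n",
              x$section, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(x$axcodes, collapse = ""),
              paste(x$modality_names, collapse = ",")))
  invisible(x)
}

affine_spacing <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

# orientation letter of each array axis: the dominant world direction its
# column points to (+x=R, -x=L, +y=A, -y=P, +z=S, -z=I)
affine_axcodes <- function(affine) {
  pos <- c("R", "A", "S"); neg <- c("L", "P", "I")
  vapply(1:3, function(i) {
    col <- affine[1:3, i]
    k <- which.max(abs(col))
    if (col[k] >= 0) pos[k] else neg[k]
  }, character(1))
}

# spatial shape helper
vol_shape <- function(vol) dim(vol$data)[1:3]

# drop the (singleton) time axis, giving an (x,y,z,channel) array
vol_array4 <- function(vol) {
  d <- dim(vol$data)
  vp_assert(d[4] == 1L, "operation requires a single time point (got %d)", d[4])
  array(vol$data, dim = d[c(1:3, 5)])
}

#' Discover corresponding dataset files by filename pattern
#'
#' Scans a directory for NIfTI files and groups them into subjects by
#' filename-substring matching, one pattern list per pipeline section.  The
#' subject ID is the filename after stripping the matched pattern substring
#' and the NIfTI extensions.  Subjects missing any section are excluded and
#' reported via a warning; two files resolving to the same (subject, section)
#' pair raise an error naming both.
#'
#' @param search_path directory to scan (non-recursive).
#' @param section_patterns named list, section name -> character vector of
#'   filename substrings, e.g. `list(image = "_T1", label = "_seg")`.
#' @param section_specs optional named list of per-section options
#'   (`interpolation`); defaults: nearest for label/weight, linear otherwise.
#' @return a `dataset_index`: ordered (alphabetical) map subject ->
#'   section -> file path, plus per-section specs.
#' @export
discover_dataset <- function(search_path, section_patterns, section_specs = NULL) {
  vp_assert(dir.exists(search_path), "search path does not exist: %s", search_path)
  vp_assert(length(section_patterns) >= 1 && !is.null(names(section_patterns)),
            "at least one named section pattern is required")
  files <- list.files(search_path, pattern = NIFTI_RE_FILES, full.names = TRUE)
  sections <- names(section_patterns)
  tab <- list()  # tab[[section]][[subject]] = path
  for (sec in sections) tab[[sec]] <- list()
  for (f in files) {
    base <- sub(NIFTI_EXT_RE, "", basename(f))
    for (sec in sections) {
      for (pat in section_patterns[[sec]]) {
        if (grepl(pat, base, fixed = TRUE)) {
          subj <- sub(pat, "", base, fixed = TRUE)
          if (!is.null(tab[[sec]][[subj]])) {
            vp_stop("ambiguous files for subject '%s', section '%s': %s and %s",
                    subj, sec, tab[[sec]][[subj]], f)
          }
          tab[[sec]][[subj]] <- f
          break
        }
      }
    }
  }
  all_subjects <- sort(unique(unlist(lapply(tab, names))))
  complete <- all_subjects[vapply(all_subjects, function(s)
    all(vapply(sections, function(sec) !is.null(tab[[sec]][[s]]), logical(1))),
    logical(1))]
  incomplete <- setdiff(all_subjects, complete)
  if (length(incomplete) > 0) {
    warning(sprintf("excluding %d subject(s) missing a section: %s",
                    length(incomplete), paste(incomplete, collapse = ", ")),
            call. = FALSE)
  }
  if (length(complete) == 0) vp_stop("zero subjects found in %s", search_path)
  subjects <- lapply(setNames(complete, complete), function(s)
    lapply(setNames(sections, sections), function(sec) tab[[sec]][[s]]))
  new_dataset_index(subjects, sections, section_specs, incomplete)
}

NIFTI_RE_FILES <- "\\.nii(\\.gz)?$"

default_section_spec <- function(section) {
  list(interpolation = if (section %in% c("label", "weight")) "nearest" else "linear")
}

new_dataset_index <- function(subjects, sections, section_specs = NULL,
                              incomplete = character(0)) {
  specs <- lapply(setNames(sections, sections), function(sec) {
    sp <- default_section_spec(sec)
    if (!is.null(section_specs[[sec]])) sp[names(section_specs[[sec]])] <- section_specs[[sec]]
    sp$section <- if (sec %in% c("image", "label", "weight")) sec else "image"
    sp
  })
  structure(list(subjects = subjects, section_specs = specs,
                 incomplete = incomplete),
            class = "dataset_index")
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index> %d subject(s), sections: %s\n",
              length(x$subjects), paste(names(x$section_specs), collapse = ", ")))
  invisible(x)
}

#' Convert a dataset index to a tibble
#'
#' @param x a `dataset_index`.
#' @param ... unused.
#' @return a tibble with one row per subject and one column per section path.
#' @export
as_tibble.dataset_index <- function(x, ...) {
  secs <- names(x$section_specs)
  cols <- c(list(subject_id = names(x$subjects)),
            lapply(setNames(secs, secs), function(sec)
              vapply(x$subjects, function(s) s[[sec]], character(1))))
  tibble::as_tibble(cols)
}

#' Load a dataset index from an explicit CSV manifest
#'
#' The CSV must have a header row `subject_id,<section>,<section>,...`; rows
#' become subjects in file order and relative paths are resolved against the
#' CSV's own directory.
#'
#' @param csv_path path to the manifest.
#' @param section_specs optional per-section options, as in
#'   [discover_dataset()].
#' @return a `dataset_index`.
#' @export
load_manifest <- function(csv_path, section_specs = NULL) {
  vp_assert(file.exists(csv_path), "manifest not found: %s", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE, check.names = FALSE)
  vp_assert("subject_id" %in% names(df), "manifest must have a subject_id column")
  sections <- setdiff(names(df), "subject_id")
  vp_assert(length(sections) >= 1, "manifest must name at least one section column")
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup) > 0) vp_stop("duplicate subject_id in manifest: %s",
                               paste(unique(dup), collapse = ", "))
  base_dir <- dirname(normalizePath(csv_path))
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  subjects <- list()
  for (i in seq_len(nrow(df))) {
    sid <- as.character(df$subject_id[i])
    row <- list()
    for (sec in sections) {
      p <- resolve(as.character(df[[sec]][i]))
      if (!file.exists(p)) vp_stop("missing file for %s,%s: %s", sid, sec, p)
      row[[sec]] <- p
    }
    subjects[[sid]] <- row
  }
  new_dataset_index(subjects, sections, section_specs)
}

#' Load a NIfTI volume with its spatial metadata
#'
#' Reads a NIfTI-1 file into an [image_volume()].  3D files become
#' `(x,y,z,1,1)`, 4D files are interpreted as multi-modal with the 4th axis as
#' channels, 5D files are taken as `(x,y,z,time,channel)`.  Label volumes are
#' checked for NaN voxels and loaded without value change.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param section_spec list with at least `section`; see
#'   [default_section_spec] values used by the readers.
#' @return an `image_volume`.
#' @export
load_volume <- function(path, section_spec = list(section = "image")) {
  vp_assert(file.exists(path), "volume not found: %s", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) vp_stop("cannot read NIfTI volume %s: %s",
                                              path, conditionMessage(e)))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # drop RNifti's internal attributes
  section <- section_spec$section %||% "image"
  if (section == "label" && anyNA(arr)) vp_stop("NaN voxels in label volume %s", path)
  vol <- image_volume(arr, affine = aff, section = section,
                      modality_names = section_spec$modality_names)
  vol
}

#' Write an image volume as NIfTI
#'
#' The spatial header (sform affine) is copied from `reference`; trailing
#' singleton axes are squeezed so a plain 3D volume round-trips as a 3D file.
#' Integer label volumes are written losslessly.
#'
#' @param vol an `image_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param reference `image_volume` supplying the affine to copy (default:
#'   `vol` itself).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, reference = vol) {
  vp_assert(inherits(vol, "image_volume"), "vol must be an image_volume")
  d <- dim(vol$data)
  arr <- vol$data
  if (d[4] == 1L && d[5] == 1L) {
    dim(arr) <- d[1:3]
  } else if (d[4] == 1L) {
    dim(arr) <- d[c(1:3, 5)]
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(reference$affine, code = 2L))
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) vp_stop("cannot write %s: %s", path,
                                       conditionMessage(e)))
  invisible(path)
}

#' Reorient volumes to a common orientation and concatenate channels
#'
#' Each volume is reoriented by pure axis permutation and flips (no
#' resampling) to `target_axcodes`, with the affine updated consistently;
#' channels are then concatenated in input order.
#'
#' @param volumes list of `image_volume` sharing spatial shape after
#'   reorientation.
#' @param target_axcodes 3 orientation letters, e.g. `c("R","A","S")`.
#' @return a single multi-channel `image_volume`.
#' @export
reorient_and_concat <- function(volumes, target_axcodes = c("R", "A", "S")) {
  vp_assert(length(volumes) >= 1, "need at least one volume")
  re <- lapply(volumes, reorient_volume, target_axcodes = target_axcodes)
  shapes <- vapply(re, vol_shape, integer(3))
  if (length(re) > 1 && any(shapes[, -1, drop = FALSE] != shapes[, 1])) {
    vp_stop("spatial shapes differ after reorientation: %s",
            paste(apply(shapes, 2, paste, collapse = "x"), collapse = " vs "))
  }
  nt <- dim(re[[1]]$data)[4]
  arrs <- lapply(re, function(v) v$data)
  total_c <- sum(vapply(arrs, function(a) dim(a)[5], integer(1)))
  out <- array(0, dim = c(shapes[, 1], nt, total_c))
  at <- 0L
  for (a in arrs) {
    nc <- dim(a)[5]
    out[, , , , at + seq_len(nc)] <- a
    at <- at + nc
  }
  image_volume(out, affine = re[[1]]$affine, section = re[[1]]$section,
               modality_names = unlist(lapply(re, function(v) v$modality_names)))
}

opposite_code <- c(R = "L", L = "R", A = "P", P = "A", S = "I", I = "S")

#' @rdname reorient_and_concat
#' @param vol an `image_volume`.
#' @export
reorient_volume <- function(vol, target_axcodes = c("R", "A", "S")) {
  target_axcodes <- toupper(strsplit(paste(target_axcodes, collapse = ""), "")[[1]])
  vp_assert(length(target_axcodes) == 3, "target_axcodes must have 3 letters")
  cur <- vol$axcodes
  perm <- integer(3); flip <- logical(3)
  for (j in 1:3) {
    i <- which(cur == target_axcodes[j])
    if (length(i) == 1) { perm[j] <- i; flip[j] <- FALSE }
    else {
      i <- which(cur == opposite_code[[target_axcodes[j]]])
      vp_assert(length(i) == 1, "cannot map orientation %s to %s",
                paste(cur, collapse = ""), paste(target_axcodes, collapse = ""))
      perm[j] <- i; flip[j] <- TRUE
    }
  }
  d <- dim(vol$data)
  arr <- aperm(vol$data, c(perm, 4L, 5L))
  nd <- dim(arr)
  idx <- lapply(1:3, function(j) if (flip[j]) rev(seq_len(nd[j])) else seq_len(nd[j]))
  arr <- arr[idx[[1]], idx[[2]], idx[[3]], , , drop = FALSE]
  # affine: new column j = +-old column perm[j]; flips shift the origin
  aff <- diag(4)
  for (j in 1:3) {
    col <- vol$affine[1:3, perm[j]]
    n <- d[perm[j]]
    if (flip[j]) {
      aff[1:3, j] <- -col
      aff[1:3, 4] <- aff[1:3, 4] + col * (n - 1)
    } else {
      aff[1:3, j] <- col
    }
  }
  aff[1:3, 4] <- aff[1:3, 4] + vol$affine[1:3, 4]
  image_volume(arr, affine = aff, section = vol$section,
               modality_names = vol$modality_names)
}

#' Load all sections of one subject
#'
#' @param index a `dataset_index`.
#' @param subject_id subject to load.
#' @return named list of `image_volume`, one per section.
#' @export
load_subject <- function(index, subject_id) {
  vp_assert(inherits(index, "dataset_index"), "index must be a dataset_index")
  entry <- index$subjects[[subject_id]]
  vp_assert(!is.null(entry), "unknown subject: %s", subject_id)
  lapply(setNames(names(entry), names(entry)), function(sec)
    load_volume(entry[[sec]], index$section_specs[[sec]]))
}
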