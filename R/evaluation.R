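# Segmentation evaluation: overlap, volume, surface-distance and
# region-wise metrics, per subject and per label, reported as a tidy table.

# accept image_volume or plain array, return 3D array
as_label_array <- function(x) {
  if (inherits(x, "image_volume")) x <- x$data
  d <- dim(x) %||% length(x)
  array(x, dim = d[1:3])
}

#' Voxel-wise confusion counts for one label
#'
#' Binarizes both volumes at `== label_value` and counts true/false
#' positives/negatives.
#'
#' @param seg,ref integer label arrays (or `image_volume`s) of equal spatial
#'   shape.
#' @param label_value label to evaluate.
#' @return list with `tp`, `fp`, `tn`, `fn` (summing to the voxel count).
#' @export
confusion_counts <- function(seg, ref, label_value) {
  s <- as_label_array(seg) == label_value
  r <- as_label_array(ref) == label_value
  vp_assert(identical(dim(s), dim(r)), "seg and ref shapes differ")
  tp <- sum(s & r)
  list(tp = tp, fp = sum(s) - tp, fn = sum(r) - tp,
       tn = sum(!s & !r))
}

#' Overlap metrics from confusion counts
#'
#' Dice, Jaccard, voxel-wise sensitivity, specificity and accuracy.
#' Undefined 0/0 ratios are reported as `NaN`, never dropped.
#'
#' @param c a list with `tp`, `fp`, `tn`, `fn` (see [confusion_counts()]).
#' @return named list of the five metrics, each in `[0, 1]` or `NaN`.
#' @export
overlap_metrics <- function(c) {
  ratio <- function(num, den) if (den == 0) NaN else num / den
  total <- c$tp + c$fp + c$tn + c$fn
  list(dice = ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn),
       jaccard = ratio(c$tp, c$tp + c$fp + c$fn),
       sensitivity = ratio(c$tp, c$tp + c$fn),
       specificity = ratio(c$tn, c$tn + c$fp),
       accuracy = ratio(c$tp + c$tn, total))
}

#' Volume metrics
#'
#' Foreground volume in mm^3 (`count * prod(spacing)`) and the relative
#' volume difference `|V_seg - V_ref| / V_ref` (NaN when the reference is
#' empty).
#'
#' @inheritParams confusion_counts
#' @param spacing 3 positive voxel spacings (mm).
#' @return list with `volume_mm3` (of `seg`) and
#'   `relative_volume_difference`.
#' @export
volume_metrics <- function(seg, ref, spacing = c(1, 1, 1), label_value = 1) {
  vp_assert(all(spacing > 0), "spacing must be positive")
  vs <- sum(as_label_array(seg) == label_value) * prod(spacing)
  vr <- sum(as_label_array(ref) == label_value) * prod(spacing)
  list(volume_mm3 = vs,
       relative_volume_difference = if (vr == 0) NaN else abs(vs - vr) / vr)
}

# surface voxels: foreground with at least one six-connected background
# neighbour (the outside of the array counts as background)
surface_mask <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask
  inner <- function(dx, dy, dz)
    pad[1 + dx + seq_len(d[1]), 1 + dy + seq_len(d[2]), 1 + dz + seq_len(d[3])]
  nbg <- !inner(1, 0, 0) | !inner(-1, 0, 0) |
         !inner(0, 1, 0) | !inner(0, -1, 0) |
         !inner(0, 0, 1) | !inner(0, 0, -1)
  mask & nbg
}

#' Symmetric surface distances
#'
#' The surface of each mask is the set of foreground voxels with a
#' six-connected background neighbour.  Distances are Euclidean between
#' voxel centres, scaled per axis by `spacing`, from each surface voxel of
#' one mask to the nearest surface voxel of the other; the two directed
#' distance sets are pooled.  Reported: mean absolute distance (mean of the
#' pooled values), Hausdorff (their maximum) and the 95th percentile
#' Hausdorff (linear-interpolation percentile of the pooled values).
#'
#' @inheritParams volume_metrics
#' @return list with `mean_absolute_distance`, `hausdorff`, `hausdorff95`
#'   (all `NaN` if either mask is empty).
#' @export
surface_distances <- function(seg, ref, spacing = c(1, 1, 1), label_value = 1) {
  s <- as_label_array(seg) == label_value
  r <- as_label_array(ref) == label_value
  vp_assert(identical(dim(s), dim(r)), "seg and ref shapes differ")
  if (!any(s) || !any(r)) {
    return(list(mean_absolute_distance = NaN, hausdorff = NaN,
                hausdorff95 = NaN, empty_mask = TRUE))
  }
  cs <- which(surface_mask(s), arr.ind = TRUE) - 1
  cr <- which(surface_mask(r), arr.ind = TRUE) - 1
  storage.mode(cs) <- "double"; storage.mode(cr) <- "double"
  pooled <- c(cpp_nn_distances(cs, cr, as.numeric(spacing)),
              cpp_nn_distances(cr, cs, as.numeric(spacing)))
  list(mean_absolute_distance = mean(pooled),
       hausdorff = max(pooled),
       hausdorff95 = unname(quantile(pooled, 0.95, type = 7)),
       empty_mask = FALSE)
}

#' Region-wise detection metrics
#'
#' Connected components are found under 26-connectivity.  A reference
#' component is detected when the fraction of its voxels overlapped by the
#' segmentation foreground is at least `overlap_fraction_threshold` (any
#' positive overlap with the default threshold 0).  A segmentation component
#' overlapping no reference component is a region false positive.
#'
#' @inheritParams volume_metrics
#' @param overlap_fraction_threshold detection threshold on the overlapped
#'   fraction of a reference component (default 0: any overlap).
#' @return list with `detection_rate`, `region_sensitivity`,
#'   `region_specificity`, `region_accuracy`.
#' @export
region_metrics <- function(seg, ref, overlap_fraction_threshold = 0,
                           label_value = 1) {
  s <- as_label_array(seg) == label_value
  r <- as_label_array(ref) == label_value
  vp_assert(identical(dim(s), dim(r)), "seg and ref shapes differ")
  lr <- cpp_label_components_26(r, dim(r))
  ls <- cpp_label_components_26(s, dim(s))
  n_ref <- max(lr); n_seg <- max(ls)
  detected <- 0L
  if (n_ref > 0) {
    for (k in seq_len(n_ref)) {
      comp <- lr == k
      frac <- sum(s[comp]) / sum(comp)
      hit <- if (overlap_fraction_threshold == 0) frac > 0
             else frac >= overlap_fraction_threshold
      if (hit) detected <- detected + 1L
    }
  }
  region_fp <- 0L
  if (n_seg > 0) {
    for (k in seq_len(n_seg)) {
      if (!any(r[ls == k])) region_fp <- region_fp + 1L
    }
  }
  detection_rate <- if (n_ref == 0) NaN else detected / n_ref
  list(detection_rate = detection_rate,
       region_sensitivity = detection_rate,
       region_specificity = if (n_seg == 0) NaN else 1 - region_fp / n_seg,
       region_accuracy = if (n_ref + n_seg == 0) NaN else
         (detected + (n_seg - region_fp)) / (n_ref + n_seg))
}

#' Descriptive statistics of a segmented region
#'
#' Spatial descriptors (volume, surface area as the spacing-weighted count of
#' six-connected foreground/background face transitions, surface/volume
#' ratio, compactness `S^1.5 / V`) and intensity statistics (mean, quartiles,
#' moment skewness `m3 / m2^1.5`) of the image voxels inside the mask.
#'
#' @param seg binary/label array or `image_volume` (foreground at
#'   `label_value`).
#' @param image intensity array or `image_volume` of the same spatial shape.
#' @param spacing 3 positive voxel spacings (mm).
#' @param label_value foreground label.
#' @return named list of descriptors.
#' @export
descriptive_stats <- function(seg, image, spacing = c(1, 1, 1), label_value = 1) {
  m <- as_label_array(seg) == label_value
  img <- as_label_array(image)
  vp_assert(any(m), "empty mask")
  vp_assert(identical(dim(m), dim(img)), "seg and image shapes differ")
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- m
  shifted <- function(dx, dy, dz)
    pad[1 + dx + seq_len(d[1]), 1 + dy + seq_len(d[2]), 1 + dz + seq_len(d[3])]
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  surf <- sum(m & !shifted(1, 0, 0)) * face_area[1] +
          sum(m & !shifted(-1, 0, 0)) * face_area[1] +
          sum(m & !shifted(0, 1, 0)) * face_area[2] +
          sum(m & !shifted(0, -1, 0)) * face_area[2] +
          sum(m & !shifted(0, 0, 1)) * face_area[3] +
          sum(m & !shifted(0, 0, -1)) * face_area[3]
  vol <- sum(m) * prod(spacing)
  x <- img[m]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(volume_mm3 = vol,
       surface_mm2 = surf,
       surface_volume_ratio = surf / vol,
       compactness = surf^1.5 / vol,
       intensity_mean = mu,
       intensity_q25 = q[1],
       intensity_median = q[2],
       intensity_q75 = q[3],
       intensity_skewness = if (m2 > 0) m3 / m2^1.5 else 0)
}

default_eval_metrics <- c("dice", "jaccard", "sensitivity", "specificity",
                          "accuracy", "volume_mm3",
                          "relative_volume_difference",
                          "mean_absolute_distance", "hausdorff",
                          "hausdorff95", "detection_rate")

# all metrics for one (seg, ref, label) as a named numeric vector
label_metrics <- function(seg, ref, label_value, spacing, metrics) {
  out <- list()
  ov <- overlap_metrics(confusion_counts(seg, ref, label_value))
  vm <- volume_metrics(seg, ref, spacing, label_value)
  out <- c(ov, vm)
  if (any(metrics %in% c("mean_absolute_distance", "hausdorff", "hausdorff95"))) {
    sd <- surface_distances(seg, ref, spacing, label_value)
    out <- c(out, sd[c("mean_absolute_distance", "hausdorff", "hausdorff95")])
  }
  if (any(metrics %in% c("detection_rate", "region_sensitivity",
                         "region_specificity", "region_accuracy"))) {
    out <- c(out, region_metrics(seg, ref, label_value = label_value))
  }
  unlist(out[metrics])
}

#' Evaluate inferred segmentations against references
#'
#' For every subject, loads the reference label volume from the index and
#' the inferred segmentation `<subject_id><suffix>` from `seg_dir`, computes
#' the requested metrics per label, and appends one aggregate row per
#' (label, metric) holding the median over subjects.
#'
#' @param index a `dataset_index` with a `label` section (the references).
#' @param seg_dir directory of inferred segmentations.
#' @param config optional list: `metrics` (names from
#'   `r paste(default_eval_metrics, collapse=", ")`), `labels` (label values;
#'   default: all nonzero labels in the first reference), `suffix`
#'   (default `"_niftynet_out.nii.gz"`), `spacing_units` (`"mm"` uses each
#'   reference's voxel spacing, `"voxels"` unit spacing; default voxels).
#' @return a tibble `(subject_id, label, metric, value)`; aggregate median
#'   rows carry subject_id `"median"`.  Written to CSV if `config$csv_path`
#'   is set.
#' @export
evaluate_subjects <- function(index, seg_dir, config = list()) {
  vp_assert(inherits(index, "dataset_index"), "index must be a dataset_index")
  vp_assert("label" %in% names(index$section_specs),
            "index must have a 'label' section with reference segmentations")
  metrics <- config$metrics %||% default_eval_metrics
  bad <- setdiff(metrics, c(default_eval_metrics, "region_sensitivity",
                            "region_specificity", "region_accuracy"))
  vp_assert(length(bad) == 0, "unknown metric(s): %s", paste(bad, collapse = ", "))
  suffix <- config$suffix %||% "_niftynet_out.nii.gz"
  units <- config$spacing_units %||% "voxels"
  rows <- list()
  labels <- config$labels
  for (sid in names(index$subjects)) {
    ref_vol <- load_volume(index$subjects[[sid]][["label"]],
                           index$section_specs[["label"]])
    seg_path <- file.path(seg_dir, paste0(sid, suffix))
    if (!file.exists(seg_path)) vp_stop("missing segmentation for subject '%s': %s",
                                        sid, seg_path)
    seg_vol <- load_volume(seg_path, list(section = "label"))
    spacing <- if (units == "mm") ref_vol$spacing else c(1, 1, 1)
    if (is.null(labels)) {
      labels <- sort(setdiff(unique(as.vector(as_label_array(ref_vol))), 0))
    }
    for (lv in labels) {
      vals <- label_metrics(seg_vol, ref_vol, lv, spacing, metrics)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = sid, label = lv, metric = metrics,
        value = unname(vals[metrics]))
    }
  }
  report <- dplyr::bind_rows(rows)
  agg <- stats::aggregate(value ~ label + metric, data = report,
                          FUN = stats::median, na.action = NULL)
  agg <- tibble::tibble(subject_id = "median", label = agg$label,
                        metric = agg$metric, value = agg$value)
  report <- dplyr::bind_rows(report, agg)
  if (!is.null(config$csv_path)) {
    utils::write.csv(report, config$csv_path, row.names = FALSE)
  }
  report
}
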