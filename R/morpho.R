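#' Segment a 3-D image stack into cell records
#'
#' Thresholds the stack at a fraction of its maximum intensity, labels
#' 26-connected foreground components, discards components smaller than
#' `min_voxels`, and measures each remaining component. The soma area of a
#' component is its maximal single-plane cross-section: the largest in-plane
#' voxel count over z, times `voxel_size^2`. This approximates measuring each
#' cell at its widest confocal plane.
#'
#' @param stack A `synthetic_stack`, a 3-D intensity array (x-y-z order), or
#'   the path to a multi-page TIFF.
#' @param intensity_threshold Fraction of the stack maximum (0 < t < 1);
#'   voxels with intensity >= t * max are foreground.
#' @param min_voxels Minimum component size in voxels. The default (50 voxels
#'   at 1-um voxels, the volume of a ~4.6-um-diameter sphere) rejects noise
#'   specks; scale it by `voxel_size^-3` for finer grids.
#' @param volume The [imaging_volume()]; taken from the stack when it is a
#'   `synthetic_stack`, otherwise inferred from the array dimensions with the
#'   given `voxel_size`.
#' @param voxel_size Voxel edge in um, used only when `stack` is an array or
#'   a file path.
#' @return Data frame of cell records: `cell_id`, `x`, `y`, `z` (centroid,
#'   um), `soma_area_um2`, `voxel_count`, `assigned_class` (all
#'   `"unassigned"`; see [classify_cells()]).
#' @export
segment_stack <- function(stack, intensity_threshold = 0.5, min_voxels = 50,
                          volume = NULL, voxel_size = 1) {
  if (inherits(stack, "synthetic_stack")) {
    volume <- stack$volume
    arr <- stack$intensities
  } else if (is.character(stack)) {
    arr <- read_stack(stack)
  } else if (is.array(stack) && length(dim(stack)) == 3) {
    arr <- stack
  } else {
    stop_arg("`stack` must be a synthetic_stack, a 3-D array, or a TIFF path")
  }
  if (length(arr) == 0) stop_arg("empty stack")
  if (!is.numeric(intensity_threshold) || intensity_threshold <= 0 ||
      intensity_threshold >= 1)
    stop_arg("`intensity_threshold` must be strictly between 0 and 1")
  check_number(min_voxels, "min_voxels", positive = TRUE)
  if (is.null(volume)) {
    d <- dim(arr)
    volume <- imaging_volume(d[1] * voxel_size, d[2] * voxel_size,
                             d[3] * voxel_size, voxel_size)
  }
  vs <- volume$voxel_size
  empty <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), soma_area_um2 = numeric(0),
                      voxel_count = integer(0),
                      assigned_class = character(0),
                      stringsAsFactors = FALSE)

  mx <- max(arr)
  if (mx <= 0) return(empty)
  mask <- arr >= intensity_threshold * mx
  lab <- label_components_3d(as.logical(mask), dim(arr))
  if (lab$n_components == 0) return(empty)

  keep <- which(lab$voxel_count >= min_voxels)
  if (length(keep) == 0) return(empty)
  remap <- integer(lab$n_components)
  remap[keep] <- seq_along(keep)
  lv <- lab$labels
  fg <- lv > 0L
  lv[fg] <- remap[lv[fg]]
  labels <- array(lv, dim = dim(arr))

  # max single-plane cross-section per kept component
  k <- length(keep)
  max_plane <- numeric(k)
  for (z in seq_len(dim(arr)[3])) {
    pl <- labels[, , z]
    cnt <- tabulate(pl[pl > 0L], nbins = k)
    max_plane <- pmax(max_plane, cnt)
  }

  cx <- (lab$sum_x[keep] / lab$voxel_count[keep] + 0.5) * vs
  cy <- (lab$sum_y[keep] / lab$voxel_count[keep] + 0.5) * vs
  cz <- (lab$sum_z[keep] / lab$voxel_count[keep] + 0.5) * vs
  rec <- data.frame(cell_id = seq_len(k), x = cx, y = cy, z = cz,
                    soma_area_um2 = max_plane * vs^2,
                    voxel_count = as.integer(lab$voxel_count[keep]),
                    assigned_class = "unassigned",
                    stringsAsFactors = FALSE)
  # centroids of 26-connected components are necessarily interior, but keep
  # the documented edge rule explicit
  inside <- rec$x >= 0 & rec$x <= volume$x_extent &
    rec$y >= 0 & rec$y <= volume$y_extent &
    rec$z >= 0 & rec$z <= volume$z_extent
  rec <- rec[inside, , drop = FALSE]
  rec$cell_id <- seq_len(nrow(rec))
  rownames(rec) <- NULL
  rec
}

#' Soma-area classification rule
#'
#' Cells with soma area strictly greater than `threshold` are classified as
#' neurons, all others (including exact ties) as glia, so the rule is a total
#' partition. 200 um^2 is the operational cutoff separating the two
#' morphological populations.
#'
#' @param threshold Soma-area cutoff in um^2.
#' @export
classification_rule <- function(threshold = 200) {
  check_number(threshold, "threshold", positive = TRUE)
  structure(list(threshold = threshold), class = "classification_rule")
}

#' Classify segmented cells as neurons or glia by soma area
#'
#' @param records Data frame of cell records with a `soma_area_um2` column
#'   (e.g. from [segment_stack()]).
#' @param rule A [classification_rule()].
#' @return `records` with `assigned_class` set to `"neuron"`
#'   (`soma_area_um2 > threshold`) or `"glia"` (otherwise).
#' @export
classify_cells <- function(records, rule = classification_rule()) {
  if (!inherits(rule, "classification_rule"))
    stop_arg("`rule` must be a classification_rule")
  if (!is.data.frame(records) || is.null(records$soma_area_um2))
    stop_arg("`records` must be a data frame with a soma_area_um2 column")
  if (nrow(records) > 0 &&
      (any(is.na(records$soma_area_um2)) || any(records$soma_area_um2 <= 0)))
    stop_arg("every record needs a positive soma_area_um2")
  records$assigned_class <- ifelse(records$soma_area_um2 > rule$threshold,
                                   "neuron", "glia")
  records
}

#' Count classified cells
#'
#' @param records Data frame of classified cell records.
#' @return Named integer vector `c(neuron_count, glia_count)`; the two always
#'   sum to `nrow(records)`.
#' @export
count_cells <- function(records) {
  if (!is.data.frame(records)) stop_arg("`records` must be a data frame")
  cls <- records$assigned_class
  if (nrow(records) > 0 &&
      (is.null(cls) || !all(cls %in% c("neuron", "glia"))))
    stop_arg("all records must be classified as 'neuron' or 'glia' (run classify_cells first)")
  c(neuron_count = sum(cls == "neuron"),
    glia_count = sum(cls == "glia"))
}

#' Locate the break in a bimodal soma-area histogram
#'
#' Bins the areas on a histogram grid anchored at multiples of `bin_size`,
#' finds the two modes (the global maximum bin and, among the remaining local
#' maxima, the one with the largest peak prominence), and returns the midpoint
#' of the minimum-count bin strictly between them. When several bins tie for
#' the minimum -- the usual case when the two populations are separated by an
#' empty gap -- the tied bin whose midpoint is closest to the midpoint of the
#' two mode centers is reported, i.e. the center of the valley as seen from
#' the modes. Peak prominence (height above the deepest valley toward the
#' global mode) is used for the second mode so that sampling bumps on the
#' flank of a mode are not mistaken for a separate population.
#'
#' @param areas Numeric vector of soma areas (um^2), length >= 2.
#' @param bin_size Histogram bin width in um^2 (default 18, the bin width
#'   used for the pooled-distribution histogram this detector reproduces).
#' @return The break area in um^2, or `NA_real_` when the histogram has no
#'   second separated mode (unimodal input: "no break").
#' @export
find_bimodal_break <- function(areas, bin_size = 18) {
  areas <- as.numeric(areas)
  if (length(areas) < 2 || any(!is.finite(areas)))
    stop_arg("`areas` must be >= 2 finite values")
  check_number(bin_size, "bin_size", positive = TRUE)

  lo <- floor(min(areas) / bin_size) * bin_size
  idx <- pmin(floor((areas - lo) / bin_size) + 1L,
              ceiling((max(areas) - lo) / bin_size))
  idx <- pmax(idx, 1L)
  counts <- tabulate(idx)
  nb <- length(counts)
  if (nb < 3) return(NA_real_)

  # collapse plateau runs, find local maxima among runs
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  is_peak <- vapply(seq_len(nr), function(i) {
    left <- if (i > 1) r$values[i - 1] else -Inf
    right <- if (i < nr) r$values[i + 1] else -Inf
    r$values[i] > left && r$values[i] > right && r$values[i] > 0
  }, logical(1))
  peaks <- which(is_peak)
  if (length(peaks) < 2) return(NA_real_)

  mode1 <- peaks[which.max(r$values[peaks])]
  others <- setdiff(peaks, mode1)
  prom <- vapply(others, function(p) {
    rng <- if (p < mode1) (p + 1):(mode1 - 1) else (mode1 + 1):(p - 1)
    if (length(rng) == 0) return(-Inf)
    r$values[p] - min(r$values[rng])
  }, numeric(1))
  if (all(!is.finite(prom)) || max(prom) <= 0) return(NA_real_)
  mode2 <- others[which.max(prom)]

  left <- min(mode1, mode2); right <- max(mode1, mode2)
  valley_bins <- (ends[left] + 1L):(starts[right] - 1L)
  if (ends[left] + 1L > starts[right] - 1L) return(NA_real_)
  vmin <- min(counts[valley_bins])
  if (vmin >= min(r$values[mode1], r$values[mode2])) return(NA_real_)
  cand <- valley_bins[counts[valley_bins] == vmin]

  mid_of <- function(i) lo + (i - 0.5) * bin_size
  center1 <- mid_of((starts[mode1] + ends[mode1]) / 2)
  center2 <- mid_of((starts[mode2] + ends[mode2]) / 2)
  target <- (center1 + center2) / 2
  cand_mid <- mid_of(cand)
  cand_mid[which.min(abs(cand_mid - target))]
}
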