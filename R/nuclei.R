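#' Segment nuclei from the nuclear channel
#'
#' Smooth, threshold (Otsu by default), compute the anisotropic distance
#' transform inside the nuclear mask, seed at its prominent maxima and split
#' touching nuclei by the seeded watershed, then size-filter at
#' nucleus-scale bounds. An empty channel yields zero labels.
#'
#' @param nuclear an [image_volume()] of the nuclear stain.
#' @param params a [segmentation_params()]; see [nucleus_params()] for
#'   nucleus-scale defaults.
#' @return a [label_volume()].
#' @export
segment_nuclei <- function(nuclear, params = nucleus_params()) {
  stopifnot(inherits(nuclear, "image_volume"))
  sm <- gaussian_blur3d(nuclear$data, params$smooth_sigma,
                        unclass(nuclear$spacing))
  rng <- range(sm)
  if (params$threshold_method == "otsu" &&
      diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    # constant (e.g. all-zero) channel: nothing to segment
    return(label_volume(array(0L, dim(nuclear$data)), nuclear$spacing))
  }
  thr <- if (params$threshold_method == "otsu") otsu_threshold(sm)
         else params$fixed_threshold
  nmask <- sm > thr
  if (!any(nmask))
    return(label_volume(array(0L, dim(nuclear$data)), nuclear$spacing))
  dist <- interior_distance(!nmask, nuclear$spacing)
  seeds <- find_seeds(dist, params, nuclear$spacing)
  lab <- .watershed_cpp(as.vector(dist), as.vector(nmask),
                        as.integer((seeds$z - 1L) +
                                     dim(nmask)[1] * (seeds$y - 1L) +
                                     dim(nmask)[1] * dim(nmask)[2] *
                                       (seeds$x - 1L)),
                        seq_len(nrow(seeds)), dim(nmask))
  dim(lab) <- dim(nmask)
  size_filter(label_volume(lab, nuclear$spacing), params)$labels
}

#' Assign each nucleus to a cell
#'
#' A nucleus goes to the cell label owning the plurality of its voxels
#' (background counts as a candidate: a nucleus lying mostly outside any
#' cell gets `cell_label` 0). If the winner owns less than half of the
#' nucleus' voxels the assignment is kept but flagged ambiguous.
#'
#' @param nuclei,cells [label_volume()] on the same grid.
#' @return data frame of nucleus records: `nucleus_label`, `cell_label`,
#'   `volume_um3`, `centroid_z_um`/`_y_um`/`_x_um`, `ambiguous_flag`.
#' @export
assign_nuclei <- function(nuclei, cells) {
  stopifnot(inherits(nuclei, "label_volume"), inherits(cells, "label_volume"),
            identical(dim(nuclei$labels), dim(cells$labels)))
  dims <- dim(nuclei$labels)
  sp <- unclass(nuclei$spacing)
  vv <- prod(sp)
  idx <- which(nuclei$labels > 0L)
  if (!length(idx))
    return(data.frame(nucleus_label = integer(), cell_label = integer(),
                      volume_um3 = numeric(), centroid_z_um = numeric(),
                      centroid_y_um = numeric(), centroid_x_um = numeric(),
                      ambiguous_flag = logical()))
  nl <- nuclei$labels[idx]
  cl <- cells$labels[idx]
  zyx <- index_to_zyx(idx, dims)
  recs <- lapply(split(seq_along(idx), nl), function(ii) {
    tab <- table(cl[ii])
    cand <- as.integer(names(tab))
    o <- order(cand) # numeric label order, so ties go to the smaller label
    cand <- cand[o]
    cnt <- as.integer(tab)[o]
    win <- cand[which.max(cnt)]
    frac <- max(cnt) / length(ii)
    data.frame(nucleus_label = nl[ii[1]],
               cell_label = win,
               volume_um3 = length(ii) * vv,
               centroid_z_um = mean((zyx[ii, 1] - 1) * sp[1]),
               centroid_y_um = mean((zyx[ii, 2] - 1) * sp[2]),
               centroid_x_um = mean((zyx[ii, 3] - 1) * sp[3]),
               ambiguous_flag = frac < 0.5)
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$nucleus_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

NUCLEATION_CLASSES <- c("anucleate", "mononucleated", "binucleated",
                        "multinucleated")

#' Classify each cell by its nucleus count
#'
#' Counts assigned nuclei per cell and maps 0/1/2/>=3 to
#' anucleate/mononucleated/binucleated/multinucleated. Multinucleated cells
#' trigger a warning (more than two nuclei per cell is not expected in this
#' tissue and usually indicates an under-split cell), and anucleate cells
#' are flagged as likely segmentation errors.
#'
#' @param cells a [label_volume()] of segmented cells.
#' @param assignments nucleus records from [assign_nuclei()].
#' @return data frame of cell records (`cell_label`, `volume_um3`,
#'   `nucleus_count`, `nucleation_class`, `nucleus_labels`, `border_flag`,
#'   `curated_flag`), with a `summary` attribute holding counts per class.
#' @export
classify_nucleation <- function(cells, assignments) {
  stopifnot(inherits(cells, "label_volume"))
  present <- labels_present(cells)
  bad <- setdiff(assignments$cell_label, c(0L, present))
  if (length(bad))
    stop("assignments reference unknown cell label(s): ",
         paste(bad, collapse = ", "))
  vv <- voxel_volume(cells$spacing)
  sizes <- tabulate(cells$labels[cells$labels > 0L], nbins = max(present, 1L))
  out <- data.frame(cell_label = present,
                    volume_um3 = sizes[present] * vv,
                    nucleus_count = 0L,
                    nucleation_class = NA_character_,
                    nucleus_labels = "",
                    border_flag = FALSE,
                    curated_flag = FALSE,
                    stringsAsFactors = FALSE)
  asg <- assignments[assignments$cell_label %in% present, , drop = FALSE]
  if (nrow(asg)) {
    cnt <- table(asg$cell_label)
    out$nucleus_count[match(as.integer(names(cnt)), out$cell_label)] <-
      as.integer(cnt)
    nls <- vapply(split(asg$nucleus_label, asg$cell_label),
                  function(v) paste(sort(v), collapse = ";"), "")
    out$nucleus_labels[match(as.integer(names(nls)), out$cell_label)] <- nls
  }
  out$nucleation_class <- NUCLEATION_CLASSES[pmin(out$nucleus_count, 3L) + 1L]
  n_multi <- sum(out$nucleus_count >= 3L)
  if (n_multi)
    warning(n_multi, " cell(s) with more than two nuclei (multinucleated): ",
            "not expected in this tissue; check the segmentation")
  smry <- table(factor(out$nucleation_class, levels = NUCLEATION_CLASSES))
  attr(out, "summary") <- smry
  out
}

#' Score per-nucleus marker intensity and positivity
#'
#' For every marker channel, computes the mean intensity over each nucleus'
#' voxels and calls the nucleus positive iff that mean exceeds the channel
#' threshold (global Otsu on the channel by default, or a fixed value per
#' channel). A constant (e.g. all-zero) channel yields all-negative calls.
#'
#' @param nuclei a [label_volume()] of segmented nuclei.
#' @param marker_channels list of [image_volume()] sharing the grid.
#' @param records nucleus records from [assign_nuclei()]; scored columns are
#'   appended.
#' @param threshold_rule `"otsu"` or a named numeric vector of fixed
#'   thresholds (one per channel name).
#' @return `records` with two columns per marker channel `<name>`:
#'   `mean_<name>` and `positive_<name>`.
#' @export
score_markers <- function(nuclei, marker_channels, records,
                          threshold_rule = "otsu") {
  stopifnot(inherits(nuclei, "label_volume"))
  if (inherits(marker_channels, "image_volume"))
    marker_channels <- list(marker_channels)
  idx <- which(nuclei$labels > 0L)
  nl <- nuclei$labels[idx]
  for (ch in marker_channels) {
    stopifnot(identical(dim(ch$data), dim(nuclei$labels)))
    nm <- sub("^marker:", "", ch$channel_name)
    thr <- channel_threshold(ch$data, nm, threshold_rule)
    mi <- vapply(split(ch$data[idx], nl), mean, 0)
    ord <- match(records$nucleus_label, as.integer(names(mi)))
    records[[paste0("mean_", nm)]] <- as.numeric(mi[ord])
    records[[paste0("positive_", nm)]] <- as.numeric(mi[ord]) > thr
  }
  records
}

channel_threshold <- function(data, name, threshold_rule) {
  if (is.numeric(threshold_rule)) {
    thr <- if (!is.null(names(threshold_rule)) && name %in%
               names(threshold_rule)) threshold_rule[[name]]
           else if (length(threshold_rule) == 1L) threshold_rule[[1L]]
           else stop("no fixed threshold given for channel '", name, "'")
    return(thr)
  }
  if (!identical(threshold_rule, "otsu"))
    stop("threshold_rule must be \"otsu\" or a (named) numeric vector")
  rng <- range(data)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2])))
    return(rng[2]) # constant channel: nothing exceeds it, all negative
  otsu_threshold(data)
}

#' Marker positivity by nucleation class
#'
#' A cell counts as marker-positive iff at least one of its nuclei is
#' positive (an EdU-labelled binucleated cell is one positive cell). Returns
#' the fraction of positive cells per nucleation class; classes with no
#' cells report an undefined (`NA`) fraction, not zero.
#'
#' @param cells cell records from [classify_nucleation()].
#' @param nuclei nucleus records scored by [score_markers()].
#' @param marker marker channel name (e.g. `"EdU"`).
#' @return data frame `nucleation_class`, `n`, `n_positive`,
#'   `fraction_positive`.
#' @export
edu_distribution <- function(cells, nuclei, marker = "EdU") {
  col <- paste0("positive_", marker)
  if (!col %in% names(nuclei))
    stop("marker '", marker, "' has not been scored; run score_markers()")
  pos_by_cell <- vapply(split(nuclei[[col]], nuclei$cell_label), any, TRUE)
  cell_pos <- pos_by_cell[as.character(cells$cell_label)]
  cell_pos[is.na(cell_pos)] <- FALSE # cells with no nuclei
  cls <- factor(cells$nucleation_class, levels = NUCLEATION_CLASSES)
  n <- as.integer(table(cls))
  npos <- as.integer(tapply(cell_pos, cls, sum, default = 0L))
  data.frame(nucleation_class = NUCLEATION_CLASSES, n = n,
             n_positive = npos,
             fraction_positive = ifelse(n > 0, npos / n, NA_real_))
}

#' Detect candidate cell-fusion events from reporter colours
#'
#' In a mutually exclusive multi-colour lineage reporter, a cell expressing
#' two or more colours would indicate fusion of two labelled cells. Scores
#' the mean intensity of every reporter channel over each cell's voxels,
#' calls a colour expressed iff the mean exceeds the channel threshold, and
#' returns the labels of cells expressing at least two colours.
#'
#' @param cell_labels a [label_volume()] of segmented cells.
#' @param reporter_channels list of at least two reporter [image_volume()].
#' @param threshold_rule as in [score_markers()].
#' @return integer vector of fusion-candidate cell labels (empty when no
#'   cell expresses two colours), with the per-cell expression matrix as
#'   attribute `"expressed"`.
#' @export
detect_fusion_candidates <- function(cell_labels, reporter_channels,
                                     threshold_rule = "otsu") {
  stopifnot(inherits(cell_labels, "label_volume"),
            length(reporter_channels) >= 2L)
  idx <- which(cell_labels$labels > 0L)
  cl <- cell_labels$labels[idx]
  labs <- sort(unique(cl))
  expressed <- matrix(FALSE, length(labs), length(reporter_channels),
                      dimnames = list(labs, vapply(reporter_channels,
                                                   `[[`, "", "channel_name")))
  for (ci in seq_along(reporter_channels)) {
    ch <- reporter_channels[[ci]]
    stopifnot(identical(dim(ch$data), dim(cell_labels$labels)))
    thr <- channel_threshold(ch$data, ch$channel_name, threshold_rule)
    mi <- vapply(split(ch$data[idx], cl), mean, 0)
    expressed[, ci] <- mi[as.character(labs)] > thr
  }
  out <- labs[rowSums(expressed) >= 2L]
  attr(out, "expressed") <- expressed
  out
}
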