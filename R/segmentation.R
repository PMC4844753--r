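#' Segmentation parameters
#'
#' Tunables of the membrane-seeded watershed. All lengths are physical
#' (micrometres) and are converted to voxel units through the image spacing,
#' so the same parameters apply across anisotropic grids.
#'
#' @param smooth_sigma Gaussian smoothing sigma `(z, y, x)` in um applied
#'   before thresholding.
#' @param threshold_method `"otsu"` (global Otsu on the smoothed image) or
#'   `"fixed"`.
#' @param fixed_threshold intensity threshold, used iff
#'   `threshold_method = "fixed"`.
#' @param h_maxima prominence (um of distance) below which local maxima of
#'   the interior distance field are suppressed when seeding.
#' @param min_seed_separation minimum physical distance between seeds, um;
#'   of two close seeds the deeper one is kept (greedy).
#' @param size_min,size_max physical volume bounds, um^3; labels outside the
#'   range are removed by [size_filter()].
#' @param exclude_border if `TRUE`, [size_filter()] also removes labels
#'   touching any array face.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma = c(0.4, 0.2, 0.2),
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NA_real_,
                                h_maxima = 2.0, min_seed_separation = 6,
                                size_min = 200, size_max = 20000,
                                exclude_border = TRUE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(length(smooth_sigma) == 3, all(smooth_sigma >= 0),
            h_maxima >= 0, min_seed_separation >= 0, size_min < size_max)
  if (threshold_method == "fixed" && !is.finite(fixed_threshold))
    stop("threshold_method = 'fixed' requires a finite fixed_threshold")
  structure(list(smooth_sigma = as.numeric(smooth_sigma),
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold, h_maxima = h_maxima,
                 min_seed_separation = min_seed_separation,
                 size_min = size_min, size_max = size_max,
                 exclude_border = isTRUE(exclude_border)),
            class = "segmentation_params")
}

#' Nucleus-scale segmentation parameters
#'
#' Same machinery as [segmentation_params()] with bounds matched to nuclear
#' volumes (defaults 30-800 um^3, about radii 1.9-5.8 um) and no border
#' exclusion.
#' @param ... overrides passed to [segmentation_params()].
#' @export
nucleus_params <- function(...) {
  defaults <- list(size_min = 30, size_max = 800, exclude_border = FALSE,
                   h_maxima = 1.0, min_seed_separation = 4)
  args <- utils::modifyList(defaults, list(...))
  do.call(segmentation_params, args)
}

#' Binary membrane mask
#'
#' Smooth the membrane channel with a physical-unit Gaussian and apply a
#' global threshold; the mask is `TRUE` where membrane signal is present.
#'
#' @param membrane an [image_volume()] of the membrane stain.
#' @param params a [segmentation_params()].
#' @return logical 3D array on the same grid.
#' @export
membrane_mask <- function(membrane, params = segmentation_params()) {
  stopifnot(inherits(membrane, "image_volume"),
            inherits(params, "segmentation_params"))
  sm <- gaussian_blur3d(membrane$data, params$smooth_sigma,
                        unclass(membrane$spacing))
  thr <- if (params$threshold_method == "otsu") otsu_threshold(sm)
         else params$fixed_threshold
  sm > thr
}

#' Distance from every interior voxel to the nearest membrane
#'
#' Anisotropy-aware Euclidean distance (in micrometres) from each
#' non-membrane voxel to the nearest membrane voxel. The array faces are
#' treated as membrane: a virtual membrane layer sits one voxel step outside
#' each face, so an empty mask still yields finite distances and interiors
#' open to the boundary are closed off. Membrane voxels have distance 0.
#'
#' @param mask logical 3D membrane mask.
#' @param spacing a [voxel_spacing()].
#' @return numeric 3D distance field, um.
#' @export
interior_distance <- function(mask, spacing) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L,
            inherits(spacing, "voxel_spacing"))
  if (all(mask)) stop("mask has no interior: every voxel is membrane")
  dims <- dim(mask)
  sp <- unclass(spacing)
  d <- sqrt(.edt_sq_cpp(as.vector(mask), dims, sp))
  dim(d) <- dims
  # distance to the virtual membrane layer just outside each face
  face <- pmin(
    outer(outer(pmin(seq_len(dims[1]), dims[1]:1) * sp[1],
                rep(Inf, dims[2]), pmin),
          rep(Inf, dims[3]), pmin),
    outer(outer(rep(Inf, dims[1]),
                pmin(seq_len(dims[2]), dims[2]:1) * sp[2], pmin),
          rep(Inf, dims[3]), pmin),
    outer(outer(rep(Inf, dims[1]), rep(Inf, dims[2]), pmin),
          pmin(seq_len(dims[3]), dims[3]:1) * sp[3], pmin))
  pmin(d, face)
}

#' Seed points furthest from all membranes
#'
#' Seeds are the local maxima of the interior distance field that survive
#' prominence (h-maxima) suppression at depth `h_maxima`, thinned so that
#' any two seeds are at least `min_seed_separation` apart (greedy: the
#' deeper maximum is kept; exact ties are broken towards the
#' lexicographically smallest `(z, y, x)`). A plateau of equal maximal
#' distance yields a single seed at its lexicographically smallest voxel.
#'
#' @param distance distance field from [interior_distance()].
#' @param params a [segmentation_params()].
#' @param spacing a [voxel_spacing()] (used for the physical separation).
#' @return data frame with columns `z, y, x` (1-based voxel indices) and
#'   `distance` (um), ordered by decreasing distance; zero rows if the field
#'   has no positive maxima.
#' @export
find_seeds <- function(distance, params = segmentation_params(),
                       spacing = NULL) {
  stopifnot(length(dim(distance)) == 3L)
  dims <- dim(distance)
  if (is.null(spacing)) spacing <- voxel_spacing(1, 1, 1)
  sp <- unclass(spacing)
  mask <- distance > 0
  if (!any(mask))
    return(data.frame(z = integer(), y = integer(), x = integer(),
                      distance = numeric()))
  idx <- .prominent_maxima_cpp(as.vector(distance), as.vector(mask), dims,
                               params$h_maxima)
  zyx <- index_to_zyx(idx, dims)
  val <- distance[idx]
  keep <- logical(length(idx))
  pz <- (zyx[, 1] - 1) * sp[1]
  py <- (zyx[, 2] - 1) * sp[2]
  px <- (zyx[, 3] - 1) * sp[3]
  min_sep2 <- params$min_seed_separation^2
  for (i in seq_along(idx)) { # already ordered deepest-first, lex tie-break
    ki <- which(keep)
    if (!length(ki)) { keep[i] <- TRUE; next }
    d2 <- (pz[ki] - pz[i])^2 + (py[ki] - py[i])^2 + (px[ki] - px[i])^2
    if (all(d2 >= min_sep2)) keep[i] <- TRUE
  }
  out <- data.frame(z = zyx[keep, 1], y = zyx[keep, 2], x = zyx[keep, 3],
                    distance = val[keep])
  rownames(out) <- NULL
  out
}

#' Marker-controlled watershed into cells
#'
#' Floods the negated interior-distance field from the seed points,
#' restricted to non-membrane voxels with 6-connectivity. Each seed grows
#' one label (1, 2, ... in seed order); membrane voxels remain background 0.
#' Flooding is deepest-first, so the result does not depend on traversal
#' order; voxels equidistant between basins go to the basin whose seed has
#' the smaller label id.
#'
#' @param membrane an [image_volume()] (provides the grid and spacing).
#' @param mask logical membrane mask from [membrane_mask()].
#' @param seeds data frame from [find_seeds()].
#' @param params a [segmentation_params()] (unused tunables are ignored
#'   here; kept for a uniform interface).
#' @param distance optionally the precomputed [interior_distance()] field.
#' @return a [label_volume()].
#' @export
watershed_cells <- function(membrane, mask, seeds,
                            params = segmentation_params(),
                            distance = NULL) {
  stopifnot(inherits(membrane, "image_volume"), is.logical(mask))
  dims <- dim(mask)
  if (nrow(seeds) > 0) {
    on_mem <- mask[cbind(seeds$z, seeds$y, seeds$x)]
    if (any(on_mem))
      stop("seed(s) ", paste(which(on_mem), collapse = ", "),
           " lie on membrane voxels")
  }
  if (is.null(distance))
    distance <- interior_distance(mask, membrane$spacing)
  idx0 <- (seeds$z - 1L) + dims[1] * (seeds$y - 1L) +
    dims[1] * dims[2] * (seeds$x - 1L)
  lab <- .watershed_cpp(as.vector(distance), as.vector(!mask),
                        as.integer(idx0), seq_len(nrow(seeds)), dims)
  dim(lab) <- dims
  label_volume(lab, membrane$spacing)
}

#' Remove labels outside physical size bounds
#'
#' Labels whose physical volume falls below `size_min` or above `size_max`
#' are set to background, as are (optionally) labels touching any array
#' face; kept labels are unchanged. A removal log is returned alongside.
#'
#' @param cells a [label_volume()].
#' @param params a [segmentation_params()].
#' @return list with `labels` (filtered [label_volume()]) and `removed`
#'   (data frame `label`, `volume_um3`, `reason` in
#'   `c("too_small", "too_large", "touches_border")`).
#' @export
size_filter <- function(cells, params = segmentation_params()) {
  stopifnot(inherits(cells, "label_volume"))
  lab <- cells$labels
  vv <- voxel_volume(cells$spacing)
  mx <- max(lab)
  if (mx == 0L)
    return(list(labels = cells,
                removed = data.frame(label = integer(),
                                     volume_um3 = numeric(),
                                     reason = character())))
  vols <- tabulate(lab[lab > 0L], nbins = mx) * vv
  present <- which(vols > 0)
  reason <- rep(NA_character_, mx)
  reason[present[vols[present] < params$size_min]] <- "too_small"
  reason[present[vols[present] > params$size_max]] <- "too_large"
  if (params$exclude_border) {
    dims <- dim(lab)
    border <- unique(c(lab[c(1, dims[1]), , ], lab[, c(1, dims[2]), ],
                       lab[, , c(1, dims[3])]))
    border <- setdiff(border, 0L)
    reason[border[is.na(reason[border])]] <- "touches_border"
  }
  drop <- which(!is.na(reason))
  if (length(drop)) {
    keep_mask <- !(lab %in% drop)
    lab[!keep_mask] <- 0L
  }
  list(labels = label_volume(lab, cells$spacing),
       removed = data.frame(label = drop,
                            volume_um3 = vols[drop],
                            reason = reason[drop],
                            row.names = NULL, stringsAsFactors = FALSE))
}

#' Full membrane-to-cells segmentation
#'
#' Convenience chain: [membrane_mask()] -> [interior_distance()] ->
#' [find_seeds()] -> [watershed_cells()] -> [size_filter()].
#'
#' @param membrane an [image_volume()] of the membrane stain.
#' @param params a [segmentation_params()].
#' @return list with `labels` ([label_volume()]), `removed` (removal log),
#'   `seeds`, and `mask`.
#' @export
segment_cells <- function(membrane, params = segmentation_params()) {
  mask <- membrane_mask(membrane, params)
  dist <- interior_distance(mask, membrane$spacing)
  seeds <- find_seeds(dist, params, membrane$spacing)
  ws <- watershed_cells(membrane, mask, seeds, params, distance = dist)
  filt <- size_filter(ws, params)
  list(labels = filt$labels, removed = filt$removed, seeds = seeds,
       mask = mask)
}

#' Match segmented labels to ground-truth labels one-to-one
#'
#' Computes the intersection-over-union (IoU) of every overlapping
#' (truth, predicted) label pair and greedily pairs them by decreasing IoU,
#' each label used at most once. At the usual acceptance level (IoU >= 0.5)
#' a predicted label can overlap at most one truth label that well, so the
#' greedy pairing coincides with the optimal assignment.
#'
#' @param pred,truth [label_volume()] on the same grid.
#' @param iou_min minimum IoU for a pair to count as matched.
#' @return data frame `truth_label`, `pred_label`, `iou`, matched pairs only.
#' @export
match_labels <- function(pred, truth, iou_min = 0.7) {
  stopifnot(inherits(pred, "label_volume"), inherits(truth, "label_volume"),
            identical(dim(pred$labels), dim(truth$labels)))
  p <- as.vector(pred$labels)
  t <- as.vector(truth$labels)
  sel <- p > 0L | t > 0L
  p <- p[sel]; t <- t[sel]
  mxp <- max(p, 1L)
  key <- as.numeric(t) * (mxp + 1) + p
  cnt <- table(key[p > 0L & t > 0L])
  if (!length(cnt)) return(data.frame(truth_label = integer(),
                                      pred_label = integer(),
                                      iou = numeric()))
  k <- as.numeric(names(cnt))
  tl <- floor(k / (mxp + 1)); pl <- k - tl * (mxp + 1)
  inter <- as.numeric(cnt)
  sz_t <- tabulate(t[t > 0L])
  sz_p <- tabulate(p[p > 0L])
  iou <- inter / (sz_t[tl] + sz_p[pl] - inter)
  ord <- order(-iou, tl, pl)
  used_t <- logical(max(tl)); used_p <- logical(max(pl))
  rows <- list()
  for (i in ord) {
    if (iou[i] < iou_min) break
    if (used_t[tl[i]] || used_p[pl[i]]) next
    used_t[tl[i]] <- TRUE; used_p[pl[i]] <- TRUE
    rows[[length(rows) + 1L]] <- c(tl[i], pl[i], iou[i])
  }
  if (!length(rows)) return(data.frame(truth_label = integer(),
                                       pred_label = integer(),
                                       iou = numeric()))
  m <- do.call(rbind, rows)
  data.frame(truth_label = as.integer(m[, 1]), pred_label = as.integer(m[, 2]),
             iou = m[, 3])
}
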