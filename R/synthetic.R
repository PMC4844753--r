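#' Specification of a synthetic alveolar scene
#'
#' Describes one confocal-like 3D scene of a mammary alveolus: a spherical
#' monolayer (shell) of secretory cells around a lumen, each cell carrying
#' one or two nuclei. Defaults emulate a lactating-gland alveolus at a desk
#' scale: cells of a few thousand cubic micrometres on an anisotropic
#' confocal grid.
#'
#' @param alveolus_radius outer shell radius, um.
#' @param lumen_radius inner (lumen) radius, um; must satisfy
#'   `lumen_radius + 2 * nucleus_radius <= alveolus_radius`.
#' @param n_cells number of cells tiling the shell.
#' @param p_binucleated probability that a cell carries two nuclei. The
#'   default 0.77 emulates established lactation, where binucleated cells
#'   predominate; use ~0 for mid-pregnancy scenes.
#' @param nucleus_radius nuclear radius, um.
#' @param membrane_thickness nominal membrane thickness, um (rendered at
#'   voxel resolution, so the realized thickness is quantized to the grid).
#' @param lipid_droplet if `TRUE`, a spherical signal void is carved into
#'   each cell on the apical side and nuclei shift towards the basal surface
#'   (the late-pregnancy configuration); if `FALSE` nuclei sit mid-shell.
#' @param droplet_radius lipid droplet radius, um.
#' @param psf_sigma Gaussian point-spread-function sigma `(z, y, x)`, um.
#' @param read_sd Gaussian read-noise standard deviation (intensity units).
#' @param photons photon-scaling factor of the shot-noise model; recorded
#'   intensity is `Poisson(signal * photons) / photons` plus read noise.
#' @param spacing a [voxel_spacing()]; default `(1.0, 0.5, 0.5)` um.
#' @param marker_probs named list, marker name -> `c(p_positive_mono,
#'   p_positive_bi)`: per-class probability that a cell (and hence each of
#'   its nuclei) is positive for the marker.
#' @param reporter_colors number of mutually exclusive lineage-reporter
#'   colour channels (0 = reporters off). Each cell expresses exactly one
#'   colour, as in a multi-colour confetti-style reporter.
#' @param bi_volume_scale relative target volume of binucleated cells
#'   (1 = cell size independent of nucleation, the default; > 1 makes
#'   binucleated cells larger, for demonstration of volume comparisons).
#' @param seed integer seed; the same spec and seed give bit-identical
#'   channels and truth.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(alveolus_radius = 40, lumen_radius = 25, n_cells = 40,
                       p_binucleated = 0.77, nucleus_radius = 4,
                       membrane_thickness = 1, lipid_droplet = FALSE,
                       droplet_radius = 3, psf_sigma = c(0.6, 0.2, 0.2),
                       read_sd = 0.02, photons = 100,
                       spacing = voxel_spacing(1.0, 0.5, 0.5),
                       marker_probs = NULL, reporter_colors = 0L,
                       bi_volume_scale = 1, seed = 42L) {
  stopifnot(alveolus_radius > 0, lumen_radius > 0,
            lumen_radius < alveolus_radius,
            n_cells >= 1, nucleus_radius > 0, membrane_thickness > 0,
            p_binucleated >= 0, p_binucleated <= 1,
            read_sd >= 0, photons > 0, bi_volume_scale > 0,
            reporter_colors >= 0,
            inherits(spacing, "voxel_spacing"), length(psf_sigma) == 3)
  if (lumen_radius + 2 * nucleus_radius > alveolus_radius)
    stop("infeasible packing: lumen_radius + 2*nucleus_radius exceeds ",
         "alveolus_radius; nuclei cannot fit inside the shell")
  if (!is.null(marker_probs)) {
    stopifnot(is.list(marker_probs), !is.null(names(marker_probs)))
    for (p in marker_probs)
      stopifnot(length(p) == 2, all(p >= 0), all(p <= 1))
  }
  r_mid <- (alveolus_radius + lumen_radius) / 2
  # characteristic tangential cell width on the mid-shell sphere
  cell_width <- sqrt(4 * pi * r_mid^2 / n_cells)
  sep <- 2 * nucleus_radius * 1.05
  if (cell_width < sep + nucleus_radius)
    stop("infeasible packing: ", n_cells, " cells on a shell of mid-radius ",
         signif(r_mid, 3), " um leaves a cell width of ",
         signif(cell_width, 3),
         " um, too small to hold two separated nuclei of radius ",
         nucleus_radius, " um")
  structure(list(alveolus_radius = alveolus_radius,
                 lumen_radius = lumen_radius, n_cells = as.integer(n_cells),
                 p_binucleated = p_binucleated,
                 nucleus_radius = nucleus_radius,
                 membrane_thickness = membrane_thickness,
                 lipid_droplet = isTRUE(lipid_droplet),
                 droplet_radius = droplet_radius,
                 psf_sigma = as.numeric(psf_sigma), read_sd = read_sd,
                 photons = photons, spacing = spacing,
                 marker_probs = marker_probs,
                 reporter_colors = as.integer(reporter_colors),
                 bi_volume_scale = bi_volume_scale, seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(paste0("scene_spec: %d cells on shell %g-%g um, ",
                     "p(binucleated)=%g, nucleus r=%g um, seed=%d\n"),
              x$n_cells, x$lumen_radius, x$alveolus_radius,
              x$p_binucleated, x$nucleus_radius, x$seed))
  invisible(x)
}

# quasi-uniform directions on the unit sphere (Fibonacci lattice), rotated
# by a random orthogonal matrix so different seeds give different tilings
fibonacci_sphere <- function(n, rotate = TRUE) {
  i <- seq_len(n) - 1
  zf <- (2 * i + 1) / n - 1
  rho <- sqrt(pmax(0, 1 - zf^2))
  ga <- pi * (3 - sqrt(5))
  th <- ga * i
  dirs <- cbind(z = zf, y = rho * sin(th), x = rho * cos(th))
  if (rotate) {
    q <- qr(matrix(stats::rnorm(9), 3, 3))
    R <- qr.Q(q)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    dirs <- dirs %*% R
  }
  dirs
}

#' Generate a synthetic alveolar scene with ground truth
#'
#' Cells are the geodesic Voronoi regions (computed in physical coordinates
#' on the spherical shell) of `n_cells` quasi-uniform seed directions,
#' clipped to the shell between `lumen_radius` and `alveolus_radius`. Each
#' cell receives one nucleus or two non-overlapping nuclei (Bernoulli draw at
#' `p_binucleated`), placed on the mid-shell sphere; binucleated pairs sit
#' symmetric about the cell centre along the cell's longest shell-tangent
#' axis. The membrane channel renders inter-cell boundaries plus the apical
#' and basal surfaces; the nuclear channel renders the union of nuclei;
#' optional marker channels are nuclear-localized and reporter channels
#' cytoplasmic. Rendered channels are convolved with an anisotropic Gaussian
#' PSF and corrupted by signal-scaled Poisson noise plus Gaussian read noise
#' (skipped when `render_noise = FALSE`), then clipped to the detector range
#' `[0, 1]`.
#'
#' @param spec a [scene_spec()].
#' @param render if `FALSE`, return only the ground truth (label volumes and
#'   per-object records); no image channels are rendered. Much faster for
#'   statistical simulations that need truth populations, not pixels.
#' @param render_noise if `FALSE`, apply the PSF but no noise (a
#'   "noiseless render"): useful to separate optics from detection noise.
#' @param force_nucleus_count test hook: force this nucleus count on every
#'   cell (e.g. 3 to exercise the multinucleated path); overrides the
#'   Bernoulli draw.
#' @return a list with `channels` (list of [image_volume()]; empty when
#'   `render = FALSE`) and `truth` (class `scene_truth`: `cell_labels`,
#'   `nucleus_labels` as [label_volume()], data frames `cells` and `nuclei`,
#'   and the generating `spec`).
#' @export
generate_scene <- function(spec, render = TRUE, render_noise = TRUE,
                           force_nucleus_count = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed,
                   generate_scene_impl(spec, render, render_noise,
                                       force_nucleus_count))
}

generate_scene_impl <- function(spec, render, render_noise,
                                force_nucleus_count) {
  sp <- unclass(spec$spacing)
  half <- spec$alveolus_radius + 2 * max(spec$psf_sigma) + 2 * max(sp)
  dims <- as.integer(2 * ceiling(half / sp) + 1)
  ax <- axis_coords(dims, sp)
  ctr <- vapply(ax, function(v) mean(range(v)), 0)

  dz2 <- (ax$z - ctr[1])^2
  dy2 <- (ax$y - ctr[2])^2
  dx2 <- (ax$x - ctr[3])^2
  r2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
  shell <- r2 >= spec$lumen_radius^2 & r2 <= spec$alveolus_radius^2

  n <- spec$n_cells
  dirs <- fibonacci_sphere(n)

  nucleus_count <- if (!is.null(force_nucleus_count))
    rep.int(as.integer(force_nucleus_count), n)
  else
    1L + stats::rbinom(n, 1L, spec$p_binucleated)
  bi <- nucleus_count >= 2L
  # weighted geodesic Voronoi: weight > 1 enlarges a cell's angular region
  w <- ifelse(bi & spec$bi_volume_scale != 1, sqrt(spec$bi_volume_scale), 1)

  shell_idx <- which(shell)
  zyx <- index_to_zyx(shell_idx, dims)
  pz <- ax$z[zyx[, 1]] - ctr[1]
  py <- ax$y[zyx[, 2]] - ctr[2]
  px <- ax$x[zyx[, 3]] - ctr[3]
  rr <- sqrt(pz^2 + py^2 + px^2)
  U <- cbind(pz, py, px) / rr
  lab_shell <- integer(length(shell_idx))
  chunk <- 100000L
  for (s in seq(1L, length(shell_idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(shell_idx))
    dot <- U[s:e, , drop = FALSE] %*% t(dirs)
    ang <- acos(pmin(pmax(dot, -1), 1))
    if (any(w != 1)) ang <- sweep(ang, 2L, w, "/")
    lab_shell[s:e] <- max.col(-ang, ties.method = "first")
  }
  cell_labels <- array(0L, dims)
  cell_labels[shell_idx] <- lab_shell

  vv <- prod(sp)
  counts <- tabulate(lab_shell, nbins = n)
  # physical centroids per cell
  cz <- vapply(seq_len(n), function(k) mean(pz[lab_shell == k]), 0)
  cy <- vapply(seq_len(n), function(k) mean(py[lab_shell == k]), 0)
  cx <- vapply(seq_len(n), function(k) mean(px[lab_shell == k]), 0)

  # --- nuclei -----------------------------------------------------------------
  r_nuc <- spec$nucleus_radius
  sep <- 2 * r_nuc * 1.05 # centre separation: disjoint, near-touching pair
  r_place <- if (spec$lipid_droplet) {
    # droplet occupies the apical side; nuclei pushed towards the basal surface
    spec$alveolus_radius - r_nuc - spec$membrane_thickness
  } else {
    (spec$alveolus_radius + spec$lumen_radius) / 2
  }

  split_idx <- split(seq_along(shell_idx), lab_shell)
  nuc_centers <- list()
  nuc_cell <- integer(0)
  for (k in seq_len(n)) {
    u <- dirs[k, ]
    if (nucleus_count[k] == 1L) {
      ctrs <- matrix(u * r_place, nrow = 1)
    } else {
      # longest tangential axis from the cell's own voxel cloud
      ii <- split_idx[[as.character(k)]]
      if (length(ii) > 2000L) ii <- ii[seq(1L, length(ii), length.out = 2000L)]
      P <- cbind(pz[ii], py[ii], px[ii])
      P <- P - matrix(u, nrow(P), 3, byrow = TRUE) * drop(P %*% u) # tangent
      ev <- eigen(crossprod(scale(P, scale = FALSE)), symmetric = TRUE)
      t1 <- ev$vectors[, 1]
      m <- nucleus_count[k]
      offs <- (seq_len(m) - (m + 1) / 2) * sep # symmetric about the centre
      ctrs <- t(vapply(offs, function(o) {
        p <- u * r_place + t1 * o
        p / sqrt(sum(p^2)) * r_place # keep centres on the placement sphere
      }, numeric(3)))
    }
    for (j in seq_len(nrow(ctrs))) {
      nuc_centers[[length(nuc_centers) + 1L]] <- ctrs[j, ]
      nuc_cell <- c(nuc_cell, k)
    }
  }

  nucleus_labels <- array(0L, dims)
  n_nuc <- length(nuc_centers)
  nuc_vol <- numeric(n_nuc)
  for (j in seq_len(n_nuc)) {
    cc <- nuc_centers[[j]] + ctr
    zi <- which(abs(ax$z - cc[1]) <= r_nuc)
    yi <- which(abs(ax$y - cc[2]) <= r_nuc)
    xi <- which(abs(ax$x - cc[3]) <= r_nuc)
    if (!length(zi) || !length(yi) || !length(xi)) next
    d2 <- outer(outer((ax$z[zi] - cc[1])^2, (ax$y[yi] - cc[2])^2, "+"),
                (ax$x[xi] - cc[3])^2, "+")
    sub <- cell_labels[zi, yi, xi, drop = FALSE]
    inside <- d2 <= r_nuc^2 & sub == nuc_cell[j] # clip to the owning cell
    tmp <- nucleus_labels[zi, yi, xi, drop = FALSE]
    tmp[inside] <- j
    nucleus_labels[zi, yi, xi] <- tmp
    nuc_vol[j] <- sum(inside) * vv
  }

  # --- per-object truth -------------------------------------------------------
  classes <- c("anucleate", "mononucleated", "binucleated", "multinucleated")
  nucleation_class <- classes[pmin(nucleus_count, 3L) + 1L]
  reporter_color <- if (spec$reporter_colors > 0L)
    sample.int(spec$reporter_colors, n, replace = TRUE) else rep(NA_integer_, n)

  cells <- data.frame(
    cell_label = seq_len(n),
    volume_um3 = counts * vv,
    nucleus_count = nucleus_count,
    nucleation_class = nucleation_class,
    nucleus_labels = vapply(seq_len(n), function(k)
      paste(which(nuc_cell == k), collapse = ";"), ""),
    reporter_color = reporter_color,
    stringsAsFactors = FALSE
  )
  nuclei <- data.frame(
    nucleus_label = seq_len(n_nuc),
    cell_label = nuc_cell,
    volume_um3 = nuc_vol,
    centroid_z_um = vapply(nuc_centers, `[`, 0, 1) + ctr[1],
    centroid_y_um = vapply(nuc_centers, `[`, 0, 2) + ctr[2],
    centroid_x_um = vapply(nuc_centers, `[`, 0, 3) + ctr[3],
    stringsAsFactors = FALSE
  )

  marker_names <- names(spec$marker_probs)
  for (m in marker_names) {
    p <- spec$marker_probs[[m]]
    pos_cell <- stats::runif(n) < ifelse(bi, p[2], p[1])
    cells[[paste0("marker_", m)]] <- pos_cell
    nuclei[[paste0("marker_", m)]] <- pos_cell[nuc_cell]
  }

  truth <- structure(
    list(cell_labels = label_volume(cell_labels, spec$spacing),
         nucleus_labels = label_volume(nucleus_labels, spec$spacing),
         cells = cells, nuclei = nuclei, spec = spec),
    class = "scene_truth")

  if (!render)
    return(list(channels = list(), truth = truth))

  # --- channel rendering ------------------------------------------------------
  amp <- 0.8 # structure amplitude; leaves headroom below detector saturation
  membrane_ind <- membrane_indicator(cell_labels, shell, dims, sp,
                                     spec$membrane_thickness)
  raw <- list()
  raw[["membrane"]] <- amp * membrane_ind
  raw[["nuclear"]] <- amp * (nucleus_labels > 0L)
  for (m in marker_names) {
    pos_nuc <- which(nuclei[[paste0("marker_", m)]])
    ch <- array(0, dims)
    ch[nucleus_labels %in% pos_nuc & nucleus_labels > 0L] <- amp
    raw[[paste0("marker:", m)]] <- ch
  }
  if (spec$reporter_colors > 0L) {
    for (col in seq_len(spec$reporter_colors)) {
      ch <- array(0, dims)
      ch[cell_labels %in% which(reporter_color == col)] <- amp
      raw[[paste0("reporter:", col)]] <- ch
    }
  }
  if (spec$lipid_droplet) {
    # one spherical signal void per cell on the apical side
    void <- array(FALSE, dims)
    r_d <- spec$droplet_radius
    for (k in seq_len(n)) {
      cc <- dirs[k, ] * (spec$lumen_radius + spec$membrane_thickness + r_d) +
        ctr
      zi <- which(abs(ax$z - cc[1]) <= r_d)
      yi <- which(abs(ax$y - cc[2]) <= r_d)
      xi <- which(abs(ax$x - cc[3]) <= r_d)
      if (!length(zi) || !length(yi) || !length(xi)) next
      d2 <- outer(outer((ax$z[zi] - cc[1])^2, (ax$y[yi] - cc[2])^2, "+"),
                  (ax$x[xi] - cc[3])^2, "+")
      tmp <- void[zi, yi, xi, drop = FALSE]
      tmp[d2 <= r_d^2] <- TRUE
      void[zi, yi, xi] <- tmp
    }
    for (nm in names(raw)) raw[[nm]][void] <- 0
  }

  channels <- vector("list", length(raw))
  for (ci in seq_along(raw)) {
    a <- gaussian_blur3d(raw[[ci]], spec$psf_sigma, sp)
    if (render_noise) {
      shot <- stats::rpois(length(a), as.vector(a) * spec$photons) /
        spec$photons
      a <- array(stats::rnorm(length(a), shot, spec$read_sd), dims)
      a <- pmin(pmax(a, 0), 1)
      dim(a) <- dims
    }
    channels[[ci]] <- image_volume(quantize16(a), spec$spacing,
                                   channel_name = names(raw)[ci])
  }
  names(channels) <- names(raw)
  list(channels = channels, truth = truth)
}

# Binary indicator of membranes: inter-cell interfaces (marked one-sided so
# each interface is a single voxel layer) plus the apical and basal shell
# surfaces, dilated to the nominal thickness where the grid allows.
membrane_indicator <- function(cell_labels, shell, dims, sp, thickness) {
  M <- array(FALSE, dims)
  mark_axis <- function(M, axis) {
    n <- dims[axis]
    idx_lo <- lapply(dims, seq_len)
    idx_hi <- idx_lo
    idx_lo[[axis]] <- seq_len(n - 1L)
    idx_hi[[axis]] <- 2:n
    a <- do.call(`[`, c(list(cell_labels), idx_lo))
    b <- do.call(`[`, c(list(cell_labels), idx_hi))
    cellcell <- a != b & a > 0L & b > 0L
    lo_face <- (a > 0L & b == 0L) | cellcell
    hi_face <- (a == 0L & b > 0L)
    sub <- do.call(`[`, c(list(M), idx_lo))
    do.call(`[<-`, c(list(M), idx_lo, list(sub | lo_face))) -> M
    sub <- do.call(`[`, c(list(M), idx_hi))
    do.call(`[<-`, c(list(M), idx_hi, list(sub | hi_face))) -> M
    M
  }
  for (axis in 1:3) M <- mark_axis(M, axis)
  dil <- (thickness - min(sp)) / 2
  if (dil > 0) {
    d2 <- .edt_sq_cpp(as.vector(M), dims, sp)
    M <- array(d2 <= dil^2 + 1e-9, dims)
  }
  M
}

#' @export
print.scene_truth <- function(x, ...) {
  tab <- table(x$cells$nucleation_class)
  cat(sprintf("scene_truth: %d cells (%s), %d nuclei\n",
              nrow(x$cells),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              nrow(x$nuclei)))
  invisible(x)
}
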