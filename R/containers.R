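#' Physical voxel spacing
#'
#' Confocal stacks are almost always anisotropic: the axial (z) step is
#' coarser than the lateral (y, x) pixel size. Every physical measurement in
#' this package (volumes, distances, seed separations) is computed from the
#' spacing, never from voxel counts alone.
#'
#' @param dz,dy,dx physical length of one voxel step along z, y, x, in
#'   micrometres; each must be strictly positive.
#' @return an object of class `voxel_spacing`: a named numeric vector
#'   `c(dz=, dy=, dx=)`.
#' @export
#' @examples
#' voxel_spacing(1, 0.5, 0.5)
voxel_spacing <- function(dz, dy, dx) {
  s <- c(dz = as.numeric(dz), dy = as.numeric(dy), dx = as.numeric(dx))
  if (any(!is.finite(s)) || any(s <= 0))
    stop("voxel spacing must be three strictly positive, finite lengths (um)")
  structure(s, class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing (um): dz=%g, dy=%g, dx=%g\n", x[1], x[2], x[3]))
  invisible(x)
}

#' Physical volume of one voxel in cubic micrometres
#' @param spacing a [voxel_spacing()].
#' @return scalar, dz*dy*dx in um^3.
#' @export
voxel_volume <- function(spacing) prod(unclass(spacing))

#' Single-channel 3D image
#'
#' One channel of a confocal stack: a 3D array of non-negative intensities
#' indexed `[z, y, x]` with physical voxel spacing attached. This is the raw
#' material of every image operation in the package.
#'
#' @param data 3D numeric array, dim `(nz, ny, nx)`, finite non-negative.
#' @param spacing a [voxel_spacing()].
#' @param channel_name text tag such as `"membrane"`, `"nuclear"`,
#'   `"marker:EdU"` or `"reporter:1"`.
#' @return an object of class `image_volume` (list: `data`, `spacing`,
#'   `channel_name`).
#' @export
image_volume <- function(data, spacing, channel_name = "channel") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("image data must be a 3D array indexed (z, y, x)")
  if (!all(is.finite(data)))
    stop("image intensities must be finite")
  stopifnot(inherits(spacing, "voxel_spacing"))
  structure(list(data = data, spacing = spacing,
                 channel_name = as.character(channel_name)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_volume '%s': %d x %d x %d (z,y,x), range [%g, %g]\n",
              x$channel_name, d[1], d[2], d[3], min(x$data), max(x$data)))
  print(x$spacing)
  invisible(x)
}

#' Labelled 3D partition
#'
#' Integer labels on the same grid as a source image; 0 is background. Used
#' for segmented cells and segmented nuclei.
#'
#' @param labels 3D integer array, dim `(nz, ny, nx)`, values >= 0.
#' @param spacing a [voxel_spacing()].
#' @return an object of class `label_volume` (list: `labels`, `spacing`).
#' @export
label_volume <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array indexed (z, y, x)")
  if (is.double(labels)) {
    storage.mode(labels) <- "integer"
  }
  if (anyNA(labels) || min(labels) < 0L)
    stop("labels must be non-negative integers (0 = background)")
  stopifnot(inherits(spacing, "voxel_spacing"))
  structure(list(labels = labels, spacing = spacing), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  labs <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("label_volume: %d x %d x %d (z,y,x), %d labels\n",
              d[1], d[2], d[3], length(labs)))
  print(x$spacing)
  invisible(x)
}

#' Labels present in a label volume (background excluded)
#' @param lv a [label_volume()].
#' @return sorted integer vector of nonzero labels.
#' @export
labels_present <- function(lv) {
  stopifnot(inherits(lv, "label_volume"))
  sort(setdiff(unique(as.vector(lv$labels)), 0L))
}

# --- internal grid helpers ---------------------------------------------------

# physical coordinates of voxel centres along each axis (first voxel at 0)
axis_coords <- function(dims, spacing) {
  list(z = (seq_len(dims[1]) - 1) * spacing[1],
       y = (seq_len(dims[2]) - 1) * spacing[2],
       x = (seq_len(dims[3]) - 1) * spacing[3])
}

# convert a linear index into 1-based (z, y, x) matrix
index_to_zyx <- function(idx, dims) {
  idx0 <- idx - 1L
  z <- idx0 %% dims[1]
  y <- (idx0 %/% dims[1]) %% dims[2]
  x <- idx0 %/% (dims[1] * dims[2])
  cbind(z = z + 1L, y = y + 1L, x = x + 1L)
}

# Separable Gaussian smoothing on a 3D array. sigma is per-axis in
# micrometres and converted to voxel units through the spacing; kernels are
# truncated at 3 sigma and renormalised at the array edges so a constant
# image is preserved exactly. sigma entries that are zero (or below a tenth
# of a voxel) leave that axis untouched.
gaussian_blur3d <- function(a, sigma_um, spacing) {
  dims <- dim(a)
  kern_mat <- function(n, sigma_vox) {
    r <- ceiling(3 * sigma_vox)
    offs <- (-r):r
    w <- exp(-0.5 * (offs / sigma_vox)^2)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + offs
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- w[ok] / sum(w[ok])
    }
    K
  }
  for (axis in 1:3) {
    sv <- sigma_um[axis] / spacing[axis]
    if (sv < 0.1) next
    K <- kern_mat(dims[axis], sv)
    perm <- c(axis, setdiff(1:3, axis))
    b <- aperm(a, perm)
    db <- dim(b)
    b <- K %*% matrix(b, db[1], db[2] * db[3])
    dim(b) <- db
    a <- aperm(b, order(perm))
  }
  a
}

# Global Otsu threshold on a numeric vector/array (256-bin histogram over the
# observed range). Returns the threshold value; voxels strictly above it are
# foreground. Errors on (near-)constant input, where no threshold exists.
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (!all(is.finite(rng)) || diff(rng) <= .Machine$double.eps * max(1, abs(rng[2])))
    stop("cannot compute an Otsu threshold on a constant image; ",
         "use a fixed threshold instead")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  sb2 <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

# snap intensities to the 16-bit detector grid k/65535 (the storage
# resolution of the TIFF writer), so freshly generated channels round-trip
# bit-exactly through write_stack/read_stack
quantize16 <- function(x) round(x * 65535) / 65535
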