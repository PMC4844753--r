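#' Write a multi-channel 3D stack to TIFF
#'
#' Channels are written as one multi-page 16-bit TIFF (pages ordered
#' channel-major: all z-planes of channel 1, then channel 2, ...). Physical
#' voxel spacing, channel names and per-channel intensity scaling are stored
#' in a JSON metadata sidecar (`<path>.meta.json`) written next to the image,
#' and are required to read the stack back.
#'
#' Intensities are stored at 16-bit depth (the native resolution of typical
#' confocal detectors) on the grid `k / 65535` in `[0, 1]`; channels whose
#' range exceeds `[0, 1]` are affinely rescaled on write and restored on
#' read (recorded as `offset`/`scale` in the sidecar). Data already on the
#' 16-bit grid -- e.g. anything produced by [generate_scene()] -- round-trips
#' bit-exactly.
#'
#' @param volumes a list of [image_volume()] sharing shape and spacing, or a
#'   single `image_volume`.
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @seealso [read_stack()]
#' @export
write_stack <- function(volumes, path) {
  if (inherits(volumes, "image_volume")) volumes <- list(volumes)
  stopifnot(length(volumes) >= 1L,
            all(vapply(volumes, inherits, TRUE, "image_volume")))
  dims <- dim(volumes[[1]]$data)
  sp <- volumes[[1]]$spacing
  for (v in volumes) {
    if (!identical(dim(v$data), dims))
      stop("all channels must share the same (z, y, x) shape")
    if (!isTRUE(all.equal(unclass(v$spacing), unclass(sp))))
      stop("all channels must share the same voxel spacing")
  }
  pages <- list()
  meta_ch <- list()
  for (ci in seq_along(volumes)) {
    d <- volumes[[ci]]$data
    lo <- min(d); hi <- max(d)
    if (lo >= 0 && hi <= 1) {
      offset <- 0; scale <- 1
    } else {
      offset <- lo
      scale <- if (hi > lo) hi - lo else 1
      d <- (d - offset) / scale
    }
    meta_ch[[ci]] <- list(name = volumes[[ci]]$channel_name,
                          offset = offset, scale = scale)
    for (z in seq_len(dims[1])) pages[[length(pages) + 1L]] <- d[z, , ]
  }
  meta <- list(
    format = "alveolus3d-stack",
    axes = "zyx",
    dim = as.integer(dims),
    spacing_um = list(dz = unname(sp[1]), dy = unname(sp[2]),
                      dx = unname(sp[3])),
    channels = meta_ch
  )
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW",
                  reduce = FALSE)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".meta.json")

#' Read a multi-channel 3D stack written by [write_stack()]
#'
#' @param path TIFF file path.
#' @param spacing_override optional [voxel_spacing()]; if supplied it wins
#'   over the sidecar metadata (with a warning when the two conflict).
#' @param allow_single_slice set `TRUE` to accept a file with a single
#'   z-plane; otherwise a 2D-only file is an error, since a slice cannot
#'   support 3D morphometry.
#' @return list of [image_volume()], one per channel.
#' @export
read_stack <- function(path, spacing_override = NULL,
                       allow_single_slice = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path))

  if (is.null(meta)) {
    if (is.null(spacing_override))
      stop("stack has no spacing metadata (missing sidecar '",
           sidecar_path(path),
           "' with field 'spacing_um') and no spacing_override was given")
    nz <- length(pages)
    n_ch <- 1L
    ch_meta <- list(list(name = "channel", offset = 0, scale = 1))
    spacing <- spacing_override
  } else {
    dims <- as.integer(unlist(meta$dim))
    nz <- dims[1]
    n_ch <- length(meta$channels)
    if (length(pages) != nz * n_ch)
      stop("page count does not match sidecar metadata")
    ch_meta <- meta$channels
    spacing <- voxel_spacing(meta$spacing_um$dz, meta$spacing_um$dy,
                             meta$spacing_um$dx)
    if (!is.null(spacing_override)) {
      if (!isTRUE(all.equal(unclass(spacing), unclass(spacing_override),
                            check.attributes = FALSE)))
        warning("spacing_override conflicts with stored metadata; ",
                "the override wins")
      spacing <- spacing_override
    }
  }
  if (nz == 1L && !allow_single_slice)
    stop("file holds a single z-plane; pass allow_single_slice = TRUE ",
         "if this is intentional")

  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  out <- vector("list", n_ch)
  for (ci in seq_len(n_ch)) {
    a <- array(0, dim = c(nz, ny, nx))
    for (z in seq_len(nz)) a[z, , ] <- pages[[(ci - 1L) * nz + z]]
    off <- ch_meta[[ci]]$offset %||% 0
    sc <- ch_meta[[ci]]$scale %||% 1
    if (off != 0 || sc != 1) a <- a * sc + off
    out[[ci]] <- image_volume(a, spacing,
                              channel_name = ch_meta[[ci]]$name %||% "channel")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a label volume to TIFF
#'
#' Stored as 16-bit pages with the label count and spacing in the sidecar.
#'
#' @param lv a [label_volume()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(lv, path) {
  stopifnot(inherits(lv, "label_volume"))
  mx <- max(lv$labels)
  if (mx > 65535L) stop("more than 65535 labels cannot be stored as 16-bit")
  dims <- dim(lv$labels)
  pages <- lapply(seq_len(dims[1]),
                  function(z) lv$labels[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW",
                  reduce = FALSE)
  sp <- lv$spacing
  jsonlite::write_json(
    list(format = "alveolus3d-labels", axes = "zyx",
         dim = as.integer(dims), max_label = as.integer(mx),
         spacing_um = list(dz = unname(sp[1]), dy = unname(sp[2]),
                           dx = unname(sp[3]))),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a label volume written by [write_labels()]
#' @param path TIFF file path.
#' @return a [label_volume()].
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta <- jsonlite::read_json(sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- as.integer(unlist(meta$dim))
  a <- array(0L, dim = dims)
  for (z in seq_len(dims[1]))
    a[z, , ] <- as.integer(round(pages[[z]] * 65535))
  label_volume(a, voxel_spacing(meta$spacing_um$dz, meta$spacing_um$dy,
                                meta$spacing_um$dx))
}

# fixed, documented column orders for the per-object tables
CELL_RECORD_COLUMNS <- c("cell_label", "volume_um3", "nucleus_count",
                         "nucleation_class", "nucleus_labels",
                         "reporter_colors_expressed", "border_flag",
                         "curated_flag")
NUCLEUS_RECORD_COLUMNS <- c("nucleus_label", "cell_label", "volume_um3",
                            "centroid_z_um", "centroid_y_um", "centroid_x_um",
                            "ambiguous_flag")

#' Export per-object records to CSV
#'
#' Writes cell or nucleus records with a fixed, documented column order
#' (leading columns `CELL_RECORD_COLUMNS` / `NUCLEUS_RECORD_COLUMNS`, then
#' any extra columns such as per-marker scores, in their data-frame order)
#' and full floating-point precision, so volumes survive a round trip
#' through the file.
#'
#' @param records data frame of cell or nucleus records.
#' @param path output CSV path.
#' @param allow_empty permit writing a header-only file for zero records.
#' @return `path`, invisibly.
#' @export
export_table <- function(records, path, allow_empty = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L && !allow_empty)
    stop("refusing to write an empty table; pass allow_empty = TRUE")
  lead <- if ("nucleus_label" %in% names(records) &&
              !"nucleation_class" %in% names(records))
    NUCLEUS_RECORD_COLUMNS else CELL_RECORD_COLUMNS
  lead <- intersect(lead, names(records))
  records <- records[, c(lead, setdiff(names(records), lead)), drop = FALSE]
  num <- vapply(records, is.double, TRUE)
  records[num] <- lapply(records[num], function(x) {
    # full precision: shortest representation that round-trips a double
    vapply(x, function(v) if (is.na(v)) NA_character_ else
      format(v, digits = 17, scientific = FALSE, trim = TRUE), "")
  })
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a record CSV written by [export_table()]
#' @param path CSV path.
#' @return data frame.
#' @export
import_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
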