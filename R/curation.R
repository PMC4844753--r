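#' Per-cell, per-slice validation table
#'
#' The file-based counterpart of interactive slice-by-slice validation: each
#' row gives a verdict for one cell at one z-plane. Pairs not listed default
#' to `valid`, so a table only needs the problematic slices.
#'
#' @param cell_label integer cell labels.
#' @param z_index integer z-plane indices (1-based).
#' @param verdict character, each one of `"valid"`, `"invalid"`,
#'   `"missing"`.
#' @return an object of class `validation_table` (a data frame).
#' @export
validation_table <- function(cell_label = integer(), z_index = integer(),
                             verdict = character()) {
  stopifnot(length(cell_label) == length(z_index),
            length(z_index) == length(verdict),
            all(verdict %in% c("valid", "invalid", "missing")))
  tab <- data.frame(cell_label = as.integer(cell_label),
                    z_index = as.integer(z_index),
                    verdict = as.character(verdict),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab[c("cell_label", "z_index")]))
    stop("duplicate (cell_label, z_index) pairs in validation table")
  class(tab) <- c("validation_table", class(tab))
  tab
}

#' Read a validation table from CSV
#' @param path CSV with columns `cell_label`, `z_index`, `verdict`.
#' @return a [validation_table()].
#' @export
read_validation_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validation_table(d$cell_label, d$z_index, d$verdict)
}

#' Keep only selected cells
#'
#' Realizes the "mask of only the cells of interest": labels not in `keep`
#' become background; kept labels are unchanged.
#'
#' @param cells a [label_volume()].
#' @param keep integer vector of labels to keep (must all exist).
#' @return a [label_volume()].
#' @export
select_cells <- function(cells, keep) {
  stopifnot(inherits(cells, "label_volume"))
  keep <- as.integer(keep)
  present <- labels_present(cells)
  unknown <- setdiff(keep, present)
  if (length(unknown))
    stop("unknown label(s) in keep: ", paste(unknown, collapse = ", "))
  lab <- cells$labels
  lab[!(lab %in% keep)] <- 0L
  label_volume(lab, cells$spacing)
}

# signed 2D Euclidean distance field of a binary cross-section (negative
# inside, positive outside, physical units from (dy, dx))
signed_distance_2d <- function(section, dy, dx) {
  dims3 <- c(1L, nrow(section), ncol(section))
  sp3 <- c(1, dy, dx)
  d_out <- sqrt(.edt_sq_cpp(as.vector(section), dims3, sp3))
  d_in <- sqrt(.edt_sq_cpp(as.vector(!section), dims3, sp3))
  out <- ifelse(as.vector(section), -d_in, d_out)
  matrix(out, nrow(section), ncol(section))
}

#' Rebuild invalid slices by signed-distance interpolation
#'
#' For each cell and each slice marked `invalid` or `missing`, the
#' cross-section is rebuilt from the two nearest flanking slices judged
#' valid: the rebuilt section at `z` is the sub-zero level set of the linear
#' blend of the flanking sections' 2D signed Euclidean distance fields, with
#' weight `(z - z1) / (z2 - z1)`. Shape-based interpolation of this kind
#' morphs smoothly between the flanking outlines (two disks of different
#' radius interpolate to a disk of intermediate radius).
#'
#' Valid slices are untouched, so cells with no flagged slices are
#' bit-identical before and after, and applying the operation twice equals
#' applying it once. A rebuilt voxel claimed by two cells goes to the cell
#' whose blended signed distance is more negative (ties to the smaller
#' label); voxels already carrying another cell's valid section are never
#' overwritten. A flagged slice with no valid flanking slice on one side is
#' left empty and reported.
#'
#' @param cells a [label_volume()].
#' @param table a [validation_table()].
#' @return list with `labels` (curated [label_volume()]) and `flags`
#'   (data frame `cell_label`, `z_index`, `action` in
#'   `c("rebuilt", "emptied")`).
#' @export
interpolate_slices <- function(cells, table) {
  stopifnot(inherits(cells, "label_volume"),
            inherits(table, "validation_table"))
  lab <- cells$labels
  dims <- dim(lab)
  sp <- unclass(cells$spacing)
  if (nrow(table) && any(table$z_index < 1L | table$z_index > dims[1]))
    stop("z_index outside the grid")
  present <- labels_present(cells)
  bad <- table[table$verdict != "valid", , drop = FALSE]
  bad <- bad[bad$cell_label %in% present, , drop = FALSE]
  if (!nrow(bad))
    return(list(labels = cells,
                flags = data.frame(cell_label = integer(),
                                   z_index = integer(),
                                   action = character())))

  # slices where each affected cell has voxels
  has_vox <- function(cl) which(apply(lab == cl, 1, any))
  flags <- list()
  # plan: per affected slice, per cell, a blended signed-distance section
  rebuild <- list() # key "cell|z" -> list(cell, z, sdf)
  for (cl in unique(bad$cell_label)) {
    zs_bad <- sort(bad$z_index[bad$cell_label == cl])
    zs_cell <- has_vox(cl)
    valid_zs <- setdiff(zs_cell, zs_bad)
    for (z in zs_bad) {
      lo <- valid_zs[valid_zs < z]
      hi <- valid_zs[valid_zs > z]
      if (!length(lo) || !length(hi)) {
        flags[[length(flags) + 1L]] <- data.frame(cell_label = cl,
                                                  z_index = z,
                                                  action = "emptied")
        rebuild[[paste(cl, z, sep = "|")]] <- list(cell = cl, z = z,
                                                   sdf = NULL)
        next
      }
      z1 <- max(lo); z2 <- min(hi)
      s1 <- signed_distance_2d(lab[z1, , ] == cl, sp[2], sp[3])
      s2 <- signed_distance_2d(lab[z2, , ] == cl, sp[2], sp[3])
      wgt <- (z - z1) / (z2 - z1)
      rebuild[[paste(cl, z, sep = "|")]] <-
        list(cell = cl, z = z, sdf = (1 - wgt) * s1 + wgt * s2)
      flags[[length(flags) + 1L]] <- data.frame(cell_label = cl, z_index = z,
                                                action = "rebuilt")
    }
  }

  # apply per slice: clear flagged cells' voxels, then write claims by
  # most-negative blended distance
  by_z <- split(rebuild, vapply(rebuild, function(r) r$z, 0))
  for (zc in names(by_z)) {
    z <- as.integer(zc)
    plane <- lab[z, , ]
    cls <- vapply(by_z[[zc]], function(r) r$cell, 0)
    plane[plane %in% cls] <- 0L
    best_sdf <- array(Inf, dim = dim(plane))
    best_cl <- array(0L, dim = dim(plane))
    for (r in by_z[[zc]]) {
      if (is.null(r$sdf)) next
      claim <- r$sdf < 0 & plane == 0L
      better <- claim & (r$sdf < best_sdf |
                           (r$sdf == best_sdf & r$cell < best_cl))
      best_sdf[better] <- r$sdf[better]
      best_cl[better] <- r$cell
    }
    plane[best_cl > 0L] <- best_cl[best_cl > 0L]
    lab[z, , ] <- plane
  }
  flags <- do.call(rbind, flags)
  rownames(flags) <- NULL
  for (i in which(flags$action == "emptied"))
    message("slice ", flags$z_index[i], " of cell ", flags$cell_label[i],
            " has no valid flanking slice on one side; left empty")
  list(labels = label_volume(lab, cells$spacing), flags = flags)
}
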