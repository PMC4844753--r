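#' Physical volume of every label
#'
#' Volume is voxel count times the physical voxel volume (dz*dy*dx). This
#' deliberately counts voxels rather than fitting a smoothed surface, so it
#' is exact on the grid: label volumes plus background always sum to the
#' grid volume.
#'
#' @param cells a [label_volume()].
#' @return named numeric vector, label -> volume in um^3 (empty when there
#'   are no labels).
#' @export
cell_volumes <- function(cells) {
  stopifnot(inherits(cells, "label_volume"))
  lab <- cells$labels[cells$labels > 0L]
  if (!length(lab)) return(stats::setNames(numeric(0), character(0)))
  vv <- voxel_volume(cells$spacing)
  cnt <- tabulate(lab)
  present <- which(cnt > 0L)
  stats::setNames(cnt[present] * vv, present)
}

#' Compare cell volumes between nucleation classes
#'
#' Summarises volumes per group (n, mean, s.e.m., retained individual
#' volumes) and tests mononucleated against binucleated cells with Welch's
#' two-sample t-test (default; the variance of the two classes need not be
#' equal) or the Mann-Whitney test. The test needs at least two cells in
#' each of the two classes; otherwise summaries are returned and the test
#' is skipped with a notice.
#'
#' @param records cell records (from [classify_nucleation()] or the scene
#'   truth) with columns `volume_um3` and `nucleation_class`.
#' @param method `"welch"` or `"wilcoxon"`.
#' @return object of class `volume_comparison`: list with `summaries` (data
#'   frame per class), `statistic`, `p_value`, `method`; `statistic` and
#'   `p_value` are `NA` when the test was skipped.
#' @export
compare_volumes <- function(records, method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(all(c("volume_um3", "nucleation_class") %in% names(records)))
  cls <- factor(records$nucleation_class, levels = NUCLEATION_CLASSES)
  vols <- split(records$volume_um3, cls)
  summaries <- data.frame(
    nucleation_class = NUCLEATION_CLASSES,
    n = vapply(vols, length, 0L),
    mean_volume_um3 = vapply(vols, function(v)
      if (length(v)) mean(v) else NA_real_, 0),
    sem_volume_um3 = vapply(vols, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_, 0),
    row.names = NULL
  )
  mono <- vols[["mononucleated"]]
  bi <- vols[["binucleated"]]
  statistic <- p_value <- NA_real_
  if (length(mono) >= 2 && length(bi) >= 2 &&
      (stats::sd(mono) > 0 || stats::sd(bi) > 0)) {
    ht <- if (method == "welch")
      stats::t.test(bi, mono, var.equal = FALSE)
    else stats::wilcox.test(bi, mono, exact = FALSE)
    statistic <- unname(ht$statistic)
    p_value <- ht$p.value
  } else if (length(mono) >= 2 && length(bi) >= 2) {
    # both groups constant: identical groups compare as equal
    statistic <- if (method == "welch") 0 else length(mono) * length(bi) / 2
    p_value <- 1
  } else {
    message("fewer than two mono- or binucleated cells: test skipped")
  }
  structure(list(summaries = summaries, statistic = statistic,
                 p_value = p_value, method = method,
                 volumes = vols),
            class = "volume_comparison")
}

#' @export
print.volume_comparison <- function(x, ...) {
  cat("cell-volume comparison (", x$method, " test)\n", sep = "")
  s <- x$summaries[x$summaries$n > 0, , drop = FALSE]
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-14s n=%3d  mean=%8.1f um^3  sem=%.1f\n",
                s$nucleation_class[i], s$n[i], s$mean_volume_um3[i],
                if (is.na(s$sem_volume_um3[i])) 0 else s$sem_volume_um3[i]))
  if (!is.na(x$p_value))
    cat(sprintf("  binucleated vs mononucleated: statistic=%.3f, p=%.3g\n",
                x$statistic, x$p_value))
  invisible(x)
}

#' Binucleation fraction per unit and pooled
#'
#' Computes, per unit (alveolus or sample), the fraction of counted cells
#' that are binucleated: binucleated / (mono + bi + multinucleated);
#' anucleate segments are excluded from the denominator as segmentation
#' artefacts. Units with fewer than `min_cells` counted cells are dropped
#' (and reported), then the across-unit mean and s.e.m. are pooled.
#'
#' @param records cell records with `cell_label` and `nucleation_class`.
#' @param units named vector or data frame mapping every `cell_label` to a
#'   unit id (names or a `cell_label` column).
#' @param min_cells minimum counted cells for a unit to enter the pool.
#' @return list with `per_unit` (data frame `unit`, `n_cells`,
#'   `fraction_binucleated`), `dropped_units`, `mean_fraction`,
#'   `sem_fraction`, `n_units`.
#' @export
binucleation_fraction <- function(records, units, min_cells = 5L) {
  if (is.data.frame(units)) {
    stopifnot(all(c("cell_label", "unit") %in% names(units)))
    map <- stats::setNames(units$unit, units$cell_label)
  } else {
    map <- units
  }
  u <- map[as.character(records$cell_label)]
  if (anyNA(u)) stop("every counted cell needs a unit assignment")
  counted <- records$nucleation_class %in%
    c("mononucleated", "binucleated", "multinucleated")
  recs <- records[counted, , drop = FALSE]
  u <- u[counted]
  per <- lapply(split(seq_len(nrow(recs)), u), function(ii) {
    data.frame(n_cells = length(ii),
               fraction_binucleated =
                 mean(recs$nucleation_class[ii] == "binucleated"))
  })
  per_unit <- do.call(rbind, per)
  per_unit <- data.frame(unit = names(per), per_unit, row.names = NULL,
                         stringsAsFactors = FALSE)
  small <- per_unit$n_cells < min_cells
  dropped <- per_unit$unit[small]
  kept <- per_unit[!small, , drop = FALSE]
  f <- kept$fraction_binucleated
  list(per_unit = kept, dropped_units = dropped,
       mean_fraction = if (length(f)) mean(f) else NA_real_,
       sem_fraction = if (length(f) > 1) stats::sd(f) / sqrt(length(f))
                      else NA_real_,
       n_units = nrow(kept))
}
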