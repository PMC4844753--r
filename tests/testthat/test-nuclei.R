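# render one or more solid ellipsoid "nuclei" into an image channel
render_blobs <- function(centres, radius, dims = c(24, 48, 48),
                         sp = c(1, 0.5, 0.5), value = 0.8) {
  a <- array(0, dims)
  ax <- alveolus3d:::axis_coords(dims, sp)
  for (i in seq_len(nrow(centres))) {
    d2 <- outer(outer((ax$z - centres[i, 1])^2, (ax$y - centres[i, 2])^2,
                      "+"), (ax$x - centres[i, 3])^2, "+")
    a[d2 <= radius^2] <- value
  }
  image_volume(a, do.call(voxel_spacing, as.list(sp)), "nuclear")
}

test_that("segment_nuclei finds separated and touching nuclei", {
  expect_identical(
    length(labels_present(segment_nuclei(render_blobs(
      matrix(numeric(0), 0, 3), 4) ))), 0L)
  two <- render_blobs(rbind(c(12, 8, 8), c(12, 16, 16)), 4)
  lab <- segment_nuclei(two)
  expect_identical(length(labels_present(lab)), 2L)
  rec <- assign_nuclei(lab, label_volume(array(0L, dim(lab$labels)),
                                         lab$spacing))
  # centroids within one voxel of the construction
  got <- rec[order(rec$centroid_y_um), ]
  expect_lt(max(abs(got$centroid_z_um - c(12, 12))), 1)
  expect_lt(max(abs(got$centroid_y_um - c(8, 16))), 1)
  # touching pair at centre distance 1.5 r still splits in two
  touching <- render_blobs(rbind(c(12, 12, 9), c(12, 12, 15)), 4)
  expect_identical(length(labels_present(segment_nuclei(touching))), 2L)
})

test_that("assign_nuclei applies the plurality and ambiguity rules", {
  sp <- voxel_spacing(1, 1, 1)
  cells <- array(0L, c(4, 10, 10))
  cells[, 1:6, ] <- 3L; cells[, 7:10, ] <- 5L
  nuc <- array(0L, c(4, 10, 10))
  nuc[2, 4:8, 3] <- 1L # 60/40 split across cells 3 and 5
  nuc[3, 2:3, 5] <- 2L # entirely inside cell 3
  rec <- assign_nuclei(label_volume(nuc, sp), label_volume(cells, sp))
  expect_identical(rec$cell_label, c(3L, 3L))
  expect_identical(rec$ambiguous_flag, c(FALSE, FALSE))
  expect_identical(rec$volume_um3, c(5, 2))
  # 40/30/30 split: assigned to the plurality winner but flagged
  cells[, 1:4, ] <- 3L; cells[, 5:7, ] <- 5L; cells[, 8:10, ] <- 6L
  nuc2 <- array(0L, c(4, 10, 10))
  nuc2[2, 1:10, 3] <- 1L
  rec2 <- assign_nuclei(label_volume(nuc2, sp), label_volume(cells, sp))
  expect_identical(rec2$cell_label, 3L)
  expect_true(rec2$ambiguous_flag)
  # a nucleus lying mostly over background is unassigned (cell 0)
  cells0 <- array(0L, c(4, 10, 10)); cells0[, 1:2, ] <- 7L
  rec3 <- assign_nuclei(label_volume(nuc2, sp), label_volume(cells0, sp))
  expect_identical(rec3$cell_label, 0L)
})

test_that("classify_nucleation maps counts to classes and conserves nuclei", {
  sp <- voxel_spacing(1, 1, 1)
  cells <- array(0L, c(2, 6, 8))
  cells[, 1:2, ] <- 1L; cells[, 3:4, ] <- 2L; cells[, 5:6, ] <- 3L
  asg <- data.frame(nucleus_label = 1:6,
                    cell_label = c(1L, 2L, 2L, 3L, 3L, 3L))
  expect_warning(rec <- classify_nucleation(label_volume(cells, sp), asg),
                 "multinucleated")
  expect_identical(rec$nucleation_class,
                   c("mononucleated", "binucleated", "multinucleated"))
  expect_identical(sum(rec$nucleus_count), 6L)
  expect_identical(rec$nucleus_labels, c("1", "2;3", "4;5;6"))
  # permutation invariance: shuffling the assignment rows changes nothing
  rec2 <- suppressWarnings(
    classify_nucleation(label_volume(cells, sp), asg[sample(6), ]))
  expect_identical(rec$nucleation_class, rec2$nucleation_class)
  # an unreferenced cell is anucleate
  asg3 <- asg[asg$cell_label != 2L, , drop = FALSE]
  rec3 <- suppressWarnings(classify_nucleation(label_volume(cells, sp), asg3))
  expect_identical(rec3$nucleation_class[rec3$cell_label == 2L], "anucleate")
  expect_error(classify_nucleation(label_volume(cells, sp),
                                   data.frame(nucleus_label = 1L,
                                              cell_label = 99L)),
               "unknown cell")
})

test_that("marker scoring is thresholded per channel as documented", {
  nucvol <- render_blobs(rbind(c(12, 8, 8), c(12, 16, 16)), 4)
  lab <- segment_nuclei(nucvol)
  rec <- assign_nuclei(lab, label_volume(array(0L, dim(lab$labels)),
                                         lab$spacing))
  dims <- dim(lab$labels)
  zero <- image_volume(array(0, dims), lab$spacing, "marker:EdU")
  r0 <- score_markers(lab, list(zero), rec)
  expect_true(all(!r0$positive_EdU))
  # one truth-positive nucleus at 10x background
  pos <- array(0.05, dims)
  pos[lab$labels == rec$nucleus_label[which.min(rec$centroid_y_um)]] <- 0.5
  ch <- image_volume(pos, lab$spacing, "marker:EdU")
  r1 <- score_markers(lab, list(ch), rec, threshold_rule = "otsu")
  expect_identical(r1$positive_EdU, r1$centroid_y_um < 12)
  # fixed threshold above the global maximum: everything negative
  r2 <- score_markers(lab, list(ch), rec, threshold_rule = c(EdU = 2))
  expect_true(all(!r2$positive_EdU))
})

test_that("edu_distribution applies the any-nucleus rule per class", {
  cells <- data.frame(cell_label = 1:3,
                      nucleation_class = c("mononucleated", "binucleated",
                                           "binucleated"))
  nuclei <- data.frame(nucleus_label = 1:5,
                       cell_label = c(1L, 2L, 2L, 3L, 3L),
                       positive_EdU = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  d <- edu_distribution(cells, nuclei, "EdU")
  expect_identical(d$fraction_positive[d$nucleation_class == "mononucleated"],
                   1)
  expect_identical(d$fraction_positive[d$nucleation_class == "binucleated"],
                   0.5)
  # empty class reports NA, not zero
  expect_true(is.na(
    d$fraction_positive[d$nucleation_class == "multinucleated"]))
  expect_identical(d$n[d$nucleation_class == "multinucleated"], 0L)
  expect_error(edu_distribution(cells, nuclei, "CC3"), "not been scored")
})

test_that("edu fractions recover the generator marker probabilities", {
  # 400 cells across several alveoli at marker_probs mono 0.1 / bi 0.6
  cells <- list(); nuclei <- list()
  for (i in 1:8) {
    s <- generate_scene(scene_spec(
      p_binucleated = 0.5, n_cells = 50, seed = 200L + i,
      spacing = voxel_spacing(2, 1, 1),
      marker_probs = list(EdU = c(0.1, 0.6))), render = FALSE)
    cc <- s$truth$cells; nn <- s$truth$nuclei
    cc$cell_label <- cc$cell_label + 1000L * i
    nn$cell_label <- nn$cell_label + 1000L * i
    nn$nucleus_label <- nn$nucleus_label + 1000L * i
    cells[[i]] <- cc; nuclei[[i]] <- nn
  }
  cells <- do.call(rbind, cells); nuclei <- do.call(rbind, nuclei)
  nuclei$positive_EdU <- nuclei$marker_EdU
  d <- edu_distribution(cells, nuclei, "EdU")
  for (cls in c("mononucleated", "binucleated")) {
    row <- d[d$nucleation_class == cls, ]
    p <- if (cls == "mononucleated") 0.1 else 0.6
    ci <- binom_ci(round(p * row$n), row$n, 0.99)
    expect_gte(row$fraction_positive, ci[1])
    expect_lte(row$fraction_positive, ci[2])
  }
})

test_that("fusion detection flags only multi-colour cells", {
  scn <- generate_scene(small_scene_spec(seed = 21, reporter_colors = 4L))
  reporters <- scn$channels[grepl("^reporter:", names(scn$channels))]
  cells <- scn$truth$cell_labels
  expect_length(detect_fusion_candidates(cells, reporters), 0L)
  # paint one cell into a second colour: exactly that label is returned
  victim <- scn$truth$cells$cell_label[1]
  col <- scn$truth$cells$reporter_color[1]
  other <- (col %% 4) + 1
  painted <- reporters
  d <- painted[[other]]$data
  d[cells$labels == victim] <- 0.8
  painted[[other]] <- image_volume(d, painted[[other]]$spacing,
                                   painted[[other]]$channel_name)
  hits <- detect_fusion_candidates(cells, painted)
  expect_identical(as.integer(hits), victim)
  # all-zero channels: no candidates
  zeros <- lapply(reporters[1:2], function(ch)
    image_volume(array(0, dim(ch$data)), ch$spacing, ch$channel_name))
  expect_length(detect_fusion_candidates(cells, zeros), 0L)
})
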