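test_that("membrane_mask thresholds as documented", {
  sp <- voxel_spacing(1, 1, 1)
  zeros <- image_volume(array(0, c(6, 6, 6)), sp)
  p_fixed <- segmentation_params(threshold_method = "fixed",
                                 fixed_threshold = 0.5,
                                 smooth_sigma = c(0, 0, 0))
  expect_false(any(membrane_mask(zeros, p_fixed)))
  expect_error(membrane_mask(zeros, segmentation_params()), "Otsu")
  # bimodal {0, 100}: otsu splits exactly at the upper class
  a <- array(0, c(6, 6, 6)); a[3:4, , ] <- 100
  bim <- image_volume(a, sp)
  p0 <- segmentation_params(smooth_sigma = c(0, 0, 0))
  expect_identical(membrane_mask(bim, p0), a == 100)
})

test_that("interior_distance matches closed forms and the stated convention", {
  m <- array(FALSE, c(25, 9, 9)); m[10, , ] <- TRUE
  d <- interior_distance(m, voxel_spacing(1, 1, 1))
  expect_identical(d[13, 5, 5], 3)
  expect_identical(d[10, 5, 5], 0)
  # empty mask: distance to the nearest face (virtual membrane outside)
  d0 <- interior_distance(array(FALSE, c(9, 9, 9)), voxel_spacing(1, 1, 1))
  expect_identical(d0[5, 5, 5], 5)
  expect_identical(d0[1, 5, 5], 1)
  expect_error(interior_distance(array(TRUE, c(3, 3, 3)),
                                 voxel_spacing(1, 1, 1)), "interior")
})

test_that("interior_distance equals the brute-force all-pairs oracle", {
  set.seed(42)
  sp_list <- list(c(1, 1, 1), c(1, 0.5, 0.5), c(2, 0.7, 0.4))
  for (rep in 1:6) {
    sp <- sp_list[[(rep - 1) %% 3 + 1]]
    m <- array(runif(9^3) < 0.05, c(9, 9, 9))
    d <- interior_distance(m, do.call(voxel_spacing, as.list(sp)))
    expect_equal(d, brute_distance(m, sp), tolerance = 1e-12)
  }
})

test_that("find_seeds returns per-component argmaxima with stated tie-breaks", {
  # one spherical interior: a single seed at the centre
  m <- !digitize_sphere(6, c(0, 0, 0), c(1, 1, 1))
  d <- interior_distance(m, voxel_spacing(1, 1, 1))
  s <- find_seeds(d, segmentation_params(h_maxima = 1,
                                         min_seed_separation = 2),
                  voxel_spacing(1, 1, 1))
  expect_identical(nrow(s), 1L)
  ctr <- (dim(m) + 1) / 2
  expect_true(all(abs(as.numeric(s[1, 1:3]) - ctr) <= 1))

  # two disjoint spherical interiors: one seed per component at its argmax
  m2 <- array(TRUE, c(17, 17, 37))
  co <- arrayInd(seq_len(prod(dim(m2))), dim(m2))
  ins1 <- rowSums(sweep(co, 2, c(9, 9, 9))^2) < 36
  ins2 <- rowSums(sweep(co, 2, c(9, 9, 29))^2) < 36
  m2[ins1 | ins2] <- FALSE
  d2 <- interior_distance(m2, voxel_spacing(1, 1, 1))
  s2 <- find_seeds(d2, segmentation_params(h_maxima = 1,
                                           min_seed_separation = 2),
                   voxel_spacing(1, 1, 1))
  expect_identical(nrow(s2), 2L)
  expect_setequal(s2$x, c(9L, 29L))
  expect_true(all(s2$distance == max(d2)))

  # plateau: a 1x1x3 ridge of equal maximal distance yields one seed at the
  # lexicographically smallest ridge voxel
  v <- array(0, c(5, 5, 7)); v[3, 3, 3:5] <- 2; v[3, 3, 2] <- 1
  s3 <- find_seeds(v, segmentation_params(h_maxima = 0,
                                          min_seed_separation = 0))
  expect_identical(nrow(s3), 1L)
  expect_identical(as.integer(s3[1, 1:3]), c(3L, 3L, 3L))

  # a flat zero field has no positive maxima: empty seed list, no error
  s4 <- find_seeds(array(0, c(4, 4, 4)), segmentation_params())
  expect_identical(nrow(s4), 0L)
})

test_that("watershed equals flood-fill components with one seed per component", {
  # deterministic small example: a 1x9x9 grid bisected by a membrane line
  m <- array(FALSE, c(1, 9, 9)); m[1, 5, ] <- TRUE
  sp <- voxel_spacing(1, 1, 1)
  d <- interior_distance(m, sp)
  seeds <- data.frame(z = c(1L, 1L), y = c(3L, 7L), x = c(5L, 5L),
                      distance = d[cbind(c(1, 1), c(3, 7), c(5, 5))])
  mem <- image_volume(array(0, dim(m)), sp)
  ws <- watershed_cells(mem, m, seeds)
  comp <- flood_components(!m)
  expect_identical(ws$labels > 0L, !m)
  expect_identical(ws$labels[1, 1:4, ],
                   array(1L, c(4, 9)))
  expect_identical(ws$labels[1, 6:9, ], array(2L, c(4, 9)))
  expect_identical(unname(table(ws$labels[!m])), unname(table(comp[!m])))

  # property: 100 random 7x7x7 masks, one seed per component
  set.seed(7)
  for (i in 1:100) {
    mk <- array(runif(7^3) < 0.35, c(7, 7, 7))
    comp <- flood_components(!mk)
    n_comp <- max(comp)
    if (n_comp == 0L) next
    dd <- interior_distance(mk, sp)
    seed_rows <- do.call(rbind, lapply(seq_len(n_comp), function(k) {
      ii <- which(comp == k)
      pick <- ii[which.max(dd[ii])]
      co <- arrayInd(pick, dim(mk))
      data.frame(z = co[1], y = co[2], x = co[3], distance = dd[pick])
    }))
    ws <- watershed_cells(image_volume(array(0, dim(mk)), sp), mk, seed_rows)
    # labels must coincide with components up to the seed ordering
    expect_identical(ws$labels > 0L, !mk)
    for (k in seq_len(n_comp))
      expect_identical(unique(ws$labels[comp == k]), k)
  }
})

test_that("watershed rejects seeds on membrane and is deterministic", {
  m <- array(FALSE, c(3, 5, 5)); m[2, , ] <- TRUE
  sp <- voxel_spacing(1, 1, 1)
  mem <- image_volume(array(0, dim(m)), sp)
  bad <- data.frame(z = 2L, y = 3L, x = 3L, distance = 0)
  expect_error(watershed_cells(mem, m, bad), "membrane")
  good <- data.frame(z = c(1L, 3L), y = c(3L, 3L), x = c(3L, 3L),
                     distance = c(1, 1))
  a <- watershed_cells(mem, m, good)
  b <- watershed_cells(mem, m, good)
  expect_identical(a$labels, b$labels)
})

test_that("size_filter removes by physical volume and border contact", {
  sp <- voxel_spacing(1, 0.5, 0.5) # 0.25 um^3 per voxel
  lab <- array(0L, c(12, 12, 12))
  lab[6, 6, 1:10] <- 1L                 # 10 voxels = 2.5 um^3
  lab[2:11, 2:11, 11:12] <- 2L          # 200 voxels = 50 um^3... touches x face
  lv <- label_volume(lab, sp)
  out <- size_filter(lv, segmentation_params(size_min = 100,
                                             exclude_border = FALSE))
  expect_identical(sort(out$removed$label), c(1L, 2L))
  expect_true(all(out$removed$reason == "too_small"))
  # identity configuration changes nothing
  ident <- size_filter(lv, segmentation_params(size_min = 0, size_max = Inf,
                                               exclude_border = FALSE))
  expect_identical(ident$labels$labels, lab)
  expect_identical(nrow(ident$removed), 0L)
  # border exclusion flags the face-touching label separately
  out2 <- size_filter(lv, segmentation_params(size_min = 1, size_max = Inf,
                                              exclude_border = TRUE))
  expect_identical(out2$removed$reason[out2$removed$label == 2L],
                   "touches_border")
  # monotonicity: raising size_min never increases the kept-label count
  kept <- vapply(c(0, 1, 3, 30, 60), function(smin) {
    length(labels_present(size_filter(lv, segmentation_params(
      size_min = smin, exclude_border = FALSE))$labels))
  }, 0L)
  expect_true(all(diff(kept) <= 0))
})

test_that("the fixture membrane mask closely matches the true membrane", {
  scn <- fixture_scene()
  ind <- alveolus3d:::membrane_indicator(
    scn$truth$cell_labels$labels, NULL,
    dim(scn$channels$membrane$data),
    unclass(scn$channels$membrane$spacing), 1)
  msk <- membrane_mask(scn$channels$membrane)
  jac <- sum(msk & ind) / sum(msk | ind)
  expect_gte(jac, 0.8)
})

test_that("no true cell is removed by the default size filter", {
  scn <- fixture_scene()
  seg <- fixture_segmentation()
  m <- match_labels(seg$labels, scn$truth$cell_labels, iou_min = 0.5)
  # all 40 true cells survive filtering and are recovered
  expect_identical(nrow(m), 40L)
  # removed labels are background slivers (lumen, exterior), never cells:
  # no removed label overlaps any true cell majority-wise
  expect_true(all(seg$removed$reason %in%
                    c("too_small", "too_large", "touches_border")))
})
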