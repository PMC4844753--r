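# Independent oracles and shared fixtures. Oracles are deliberately naive
# (brute force / breadth-first) so they share no code with the implementation
# they check.

# brute-force anisotropic distance: all-pairs minimum over membrane voxels,
# including the virtual membrane layer one voxel step outside each face
brute_distance <- function(mask, sp) {
  dims <- dim(mask)
  co <- arrayInd(seq_len(prod(dims)), dims) # (z, y, x) rows... arrayInd: dim1 fastest
  fg <- co[as.vector(mask), , drop = FALSE]
  face <- function(v) min(v[1] * sp[1], (dims[1] + 1 - v[1]) * sp[1],
                          v[2] * sp[2], (dims[2] + 1 - v[2]) * sp[2],
                          v[3] * sp[3], (dims[3] + 1 - v[3]) * sp[3])
  d <- apply(co, 1, function(v) {
    db <- face(v)
    if (nrow(fg)) {
      dm <- sqrt(min(((fg[, 1] - v[1]) * sp[1])^2 +
                       ((fg[, 2] - v[2]) * sp[2])^2 +
                       ((fg[, 3] - v[3]) * sp[3])^2))
      db <- min(db, dm)
    }
    db
  })
  d[as.vector(mask)] <- 0
  array(d, dims)
}

# 6-connected components of a logical array by breadth-first flood fill
flood_components <- function(open) {
  dims <- dim(open)
  lab <- array(0L, dims)
  nb <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
              c(0, 0, -1), c(0, 0, 1))
  cur <- 0L
  for (start in which(open & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- arrayInd(queue[1], dims)
      queue <- queue[-1]
      for (k in 1:6) {
        w <- v + nb[k, , drop = FALSE]
        if (any(w < 1L) || any(w > dims)) next
        if (open[w] && lab[w] == 0L) {
          lab[w] <- cur
          queue <- c(queue, (w[1]) + dims[1] * (w[2] - 1L) +
                       dims[1] * dims[2] * (w[3] - 1L))
        }
      }
    }
  }
  lab
}

# Welch t statistic and two-sided p value from the textbook formulas
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# exact binomial confidence interval (Clopper-Pearson)
binom_ci <- function(k, n, level = 0.99) {
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo, hi)
}

# digitize a sphere of radius r at the default anisotropic spacing, centred
# at `centre` (physical coordinates), into a grid just containing it
digitize_sphere <- function(r, centre, sp = c(1, 0.5, 0.5)) {
  ext <- r + 2 * max(sp)
  dims <- as.integer(ceiling(2 * ext / sp))
  z <- (seq_len(dims[1]) - 1) * sp[1] - ext + centre[1]
  y <- (seq_len(dims[2]) - 1) * sp[2] - ext + centre[2]
  x <- (seq_len(dims[3]) - 1) * sp[3] - ext + centre[3]
  d2 <- outer(outer(z^2, y^2, "+"), x^2, "+")
  array(d2 <= r^2, dims)
}

# --- cached fixtures (generated once per test run) ---------------------------

.fixture_env <- new.env(parent = emptyenv())

# the default fixture scene: 40 cells, seed 42, rendered with noise
fixture_scene <- function() {
  if (is.null(.fixture_env$scene))
    .fixture_env$scene <- generate_scene(scene_spec(seed = 42L))
  .fixture_env$scene
}

fixture_segmentation <- function() {
  if (is.null(.fixture_env$seg)) {
    t0 <- Sys.time()
    .fixture_env$seg <- segment_cells(fixture_scene()$channels$membrane)
    .fixture_env$seg_seconds <-
      as.numeric(Sys.time() - t0, units = "secs")
  }
  .fixture_env$seg
}

# a small scene (15 cells on a 25-um alveolus) for expensive render tests
small_scene_spec <- function(...) {
  scene_spec(alveolus_radius = 25, lumen_radius = 14, n_cells = 15,
             nucleus_radius = 3.5, ...)
}
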