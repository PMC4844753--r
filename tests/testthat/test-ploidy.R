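test_that("population specs validate probabilities", {
  expect_error(population_spec(p_G0G1 = 0.5, p_S = 0.1, p_G2M = 0.1,
                               p_binucleated = 0.1), "sum to 1")
  expect_s3_class(population_spec(), "population_spec")
})

test_that("noiseless sampling gives exact contents and loss removes cells", {
  s <- sample_dna_contents(population_spec(n_cells = 500, p_G0G1 = 0.6,
                                           p_S = 0, p_G2M = 0.2,
                                           p_binucleated = 0.2,
                                           stain_cv = 0, seed = 2))
  expect_true(all(s$measured_fluor %in% c(2, 4)))
  expect_identical(s$measured_fluor == 4,
                   s$true_state %in% c("G2M", "binucleated"))
  # every binucleated cell lost: empty output
  s0 <- sample_dna_contents(population_spec(n_cells = 200, p_G0G1 = 0,
                                            p_S = 0, p_G2M = 0,
                                            p_binucleated = 1,
                                            p_loss_binucleated = 1, seed = 3))
  expect_identical(nrow(s0), 0L)
  # determinism under the spec seed
  sp <- population_spec(n_cells = 1000, seed = 17)
  expect_identical(sample_dna_contents(sp), sample_dna_contents(sp))
})

test_that("dissociation loss renormalises the surviving fractions", {
  # closed form: f_surv = p_bi (1 - p_loss) / (1 - p_bi p_loss)
  sp <- population_spec(n_cells = 100000L, p_G0G1 = 0.6, p_S = 0,
                        p_G2M = 0, p_binucleated = 0.4,
                        p_loss_binucleated = 0.5, seed = 4)
  s <- sample_dna_contents(sp)
  f <- mean(s$true_state == "binucleated")
  expected <- 0.4 * 0.5 / (0.6 + 0.4 * 0.5)
  se <- sqrt(expected * (1 - expected) / nrow(s))
  expect_lt(abs(f - expected), 3 * se)
  # monotonicity: surviving binucleated fraction decreases with p_loss
  fr <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(pl) {
    ss <- sample_dna_contents(population_spec(
      n_cells = 20000L, p_G0G1 = 0.6, p_S = 0, p_G2M = 0,
      p_binucleated = 0.4, p_loss_binucleated = pl, seed = 5))
    if (nrow(ss)) mean(ss$true_state == "binucleated") else 0
  }, 0)
  expect_true(all(diff(fr) < 0))
  # measured-vs-true discrepancy: any loss biases the survivor fraction
  # below the in-tissue probability
  expect_true(all(fr[-1] < 0.4))
})

test_that("fixed-window gating is exact on noiseless data", {
  s <- data.frame(measured_fluor = c(2, 2, 4, 4))
  g <- gate_2n_4n(s, method = "windows")
  expect_identical(g$frac_2N, 0.5)
  expect_identical(g$frac_4N, 0.5)
  expect_equal(g$frac_other, 0, tolerance = 1e-12)
  # all cells G0G1: everything 2N
  g1 <- gate_2n_4n(data.frame(measured_fluor = rep(2, 10)),
                   method = "windows")
  expect_identical(g1$frac_2N, 1)
})

test_that("midpoint gating finds the modes and errors when unimodal", {
  sp <- population_spec(n_cells = 50000L, p_G0G1 = 0.8, p_S = 0,
                        p_G2M = 0.1, p_binucleated = 0.1, stain_cv = 0.05,
                        seed = 6)
  g <- gate_2n_4n(sample_dna_contents(sp))
  expect_lt(abs(g$boundaries[["mode_2N"]] - 2), 0.1)
  expect_lt(abs(g$boundaries[["mode_4N"]] - 4), 0.2)
  expect_lt(abs(g$frac_4N - 0.2), 0.01)
  uni <- sample_dna_contents(population_spec(n_cells = 5000L, p_G0G1 = 1,
                                             p_S = 0, p_G2M = 0,
                                             p_binucleated = 0,
                                             stain_cv = 0.05, seed = 7))
  expect_error(gate_2n_4n(uni), "windows")
  expect_error(gate_2n_4n(data.frame(measured_fluor = rep(2, 10))),
               "at least 100")
})

test_that("S-phase cells fall between fixed windows", {
  sp <- population_spec(n_cells = 100000L, p_G0G1 = 0.75, p_S = 0.1,
                        p_G2M = 0.1, p_binucleated = 0.05, stain_cv = 0.02,
                        seed = 8)
  s <- sample_dna_contents(sp)
  g <- gate_2n_4n(s, method = "windows", window_2n = c(1.5, 2.5),
                  window_4n = c(3.5, 4.5))
  # S-phase content is Uniform(2, 4), so the half of S-phase cells with
  # content inside (2.5, 3.5) falls between the windows; the outer halves
  # land inside the 2N/4N windows themselves
  p_between <- 0.1 / 2
  se <- sqrt(p_between * (1 - p_between) / nrow(s))
  expect_lt(abs(g$frac_other - p_between), 3 * se + 0.005)
})

test_that("decompose_4n subtracts the imaging-derived binucleated fraction", {
  g <- structure(list(frac_2N = 0.83, frac_4N = 0.17, frac_other = 0,
                      boundaries = c(boundary = 3), n = 1000L,
                      method = "windows"),
                 class = "gate_result")
  d <- decompose_4n(g, 0.12)
  expect_equal(d$est_G2M_fraction, 0.05, tolerance = 1e-12)
  expect_equal(d$est_binucleated_fraction_of_4N, 0.12 / 0.17,
               tolerance = 1e-12)
  # imaging fraction zero: the whole 4N peak is G2/M
  expect_identical(decompose_4n(g, 0)$est_G2M_fraction, 0.17)
  # in-tissue fraction with loss correction
  d2 <- decompose_4n(g, 0.2, p_loss_binucleated = 0.5)
  expect_equal(d2$binucleated_fraction_used, 0.2 * 0.5 / (1 - 0.2 * 0.5),
               tolerance = 1e-12)
  expect_error(decompose_4n(g, 0.5), "exceeds")
  expect_warning(
    out <- decompose_4n(structure(list(frac_4N = 0.1, frac_2N = 0.9,
                                       frac_other = 0, n = 10L,
                                       method = "windows"),
                                  class = "gate_result"), 0.11),
    "clipped")
  expect_identical(out$est_G2M_fraction, 0)
})

test_that("recovered G2/M matches the generator truth", {
  sp <- population_spec(n_cells = 100000L, p_G0G1 = 0.8, p_S = 0,
                        p_G2M = 0.08, p_binucleated = 0.12,
                        stain_cv = 0.05, seed = 9)
  s <- sample_dna_contents(sp)
  g <- gate_2n_4n(s)
  d <- decompose_4n(g, mean(s$true_state == "binucleated"))
  se <- sqrt(0.08 * 0.92 / nrow(s))
  expect_lt(abs(d$est_G2M_fraction - 0.08), 3 * se + 0.005)
})
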