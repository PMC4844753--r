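#' Population specification for in-silico DNA-content cytometry
#'
#' Describes a dissociated epithelial population by its cell-cycle and
#' nucleation composition. Total DNA content in genome equivalents: G0/G1
#' cells carry 2N, S-phase cells between 2N and 4N (uniform), G2/M cells 4N,
#' and binucleated cells (two 2N nuclei) also 4N -- by total fluorescence a
#' binucleated cell is indistinguishable from a G2/M cell, which is exactly
#' why an imaging-based binucleation count is needed to decompose the 4N
#' peak. `p_loss_binucleated` models the fragility of the large binucleated
#' cells at tissue dissociation: each is destroyed (lost from the measured
#' sample) with that probability.
#'
#' @param n_cells number of cells before dissociation loss.
#' @param p_G0G1,p_S,p_G2M,p_binucleated state probabilities; must sum to 1.
#' @param stain_cv multiplicative coefficient of variation of the DNA stain
#'   measurement (default 0.05, a well-resolved DNA dye histogram).
#' @param p_loss_binucleated probability in `[0, 1]` that a binucleated cell
#'   is lost at dissociation.
#' @param seed integer seed.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_cells = 10000L, p_G0G1 = 0.9, p_S = 0,
                            p_G2M = 0.05, p_binucleated = 0.05,
                            stain_cv = 0.05, p_loss_binucleated = 0,
                            seed = 1L) {
  p <- c(G0G1 = p_G0G1, S = p_S, G2M = p_G2M, binucleated = p_binucleated)
  stopifnot(n_cells >= 1, all(p >= 0), stain_cv >= 0,
            p_loss_binucleated >= 0, p_loss_binucleated <= 1)
  if (abs(sum(p) - 1) > 1e-9)
    stop("state probabilities must sum to 1 (got ", sum(p), ")")
  structure(list(n_cells = as.integer(n_cells), p = p, stain_cv = stain_cv,
                 p_loss_binucleated = p_loss_binucleated,
                 seed = as.integer(seed)),
            class = "population_spec")
}

DNA_STATES <- c("G0G1", "S", "G2M", "binucleated")

#' Simulate measured DNA contents of a dissociated population
#'
#' Draws each cell's state categorically, applies dissociation loss to
#' binucleated cells (lost cells are absent from the output, so surviving
#' fractions are renormalised), assigns true DNA content (G0/G1 = 2;
#' S ~ Uniform(2, 4); G2/M = binucleated = 4 genome equivalents) and
#' measures fluorescence as `true_content * LogNormal(0, sigma)` with sigma
#' set so the multiplicative CV equals `stain_cv`. Deterministic under the
#' spec seed.
#'
#' @param spec a [population_spec()].
#' @return data frame (`dna_content_sample`): `true_state`, `true_content`,
#'   `measured_fluor`; zero rows if every cell is lost.
#' @export
sample_dna_contents <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  withr::with_seed(spec$seed, {
    state <- sample(DNA_STATES, spec$n_cells, replace = TRUE, prob = spec$p)
    lost <- state == "binucleated" &
      stats::runif(spec$n_cells) < spec$p_loss_binucleated
    state <- state[!lost]
    n <- length(state)
    content <- numeric(n)
    content[state == "G0G1"] <- 2
    content[state == "G2M" | state == "binucleated"] <- 4
    ns <- sum(state == "S")
    if (ns) content[state == "S"] <- stats::runif(ns, 2, 4)
    sigma <- sqrt(log(1 + spec$stain_cv^2))
    fluor <- content * stats::rlnorm(n, 0, sigma)
    structure(data.frame(true_state = state, true_content = content,
                         measured_fluor = fluor, stringsAsFactors = FALSE),
              class = c("dna_content_sample", "data.frame"))
  })
}

#' Gate a DNA-content histogram into 2N and 4N fractions
#'
#' `method = "midpoint"` locates the two dominant modes of the fluorescence
#' density (expected near 2 and 4), places the 2N/4N boundary at the
#' minimum-density point between them, and sets symmetric outer bounds at
#' mode +/- 3 stain-widths (robust MAD width per peak) to exclude debris;
#' it errors on an effectively unimodal histogram, where no boundary exists,
#' advising fixed windows. `method = "windows"` counts cells inside two
#' configured fluorescence intervals. Fractions are over surviving cells.
#'
#' @param samples data frame from [sample_dna_contents()] (or any with a
#'   `measured_fluor` column).
#' @param method `"midpoint"` or `"windows"`.
#' @param window_2n,window_4n numeric length-2 intervals for
#'   `method = "windows"`.
#' @return object of class `gate_result`: list with `frac_2N`, `frac_4N`,
#'   `frac_other` (summing to 1), `boundaries` (named fluorescence bounds)
#'   and `n`.
#' @export
gate_2n_4n <- function(samples, method = c("midpoint", "windows"),
                       window_2n = c(1.5, 2.5), window_4n = c(3.5, 4.5)) {
  method <- match.arg(method)
  x <- samples$measured_fluor
  stopifnot(is.numeric(x), all(x > 0))
  n <- length(x)
  if (method == "midpoint") {
    if (n < 100)
      stop("midpoint gating needs at least 100 samples")
    den <- stats::density(x, n = 512)
    y <- den$y
    loc <- which(diff(sign(diff(y))) == -2) + 1L # interior local maxima
    if (length(loc) < 2L)
      stop("fluorescence histogram is unimodal; midpoint gating cannot ",
           "place a 2N/4N boundary -- use method = \"windows\"")
    top <- loc[order(y[loc], decreasing = TRUE)][1:2]
    m1 <- den$x[min(top)]; m2 <- den$x[max(top)]
    if (y[max(top)] < 0.05 * y[min(top)])
      stop("second mode is negligible; histogram effectively unimodal -- ",
           "use method = \"windows\"")
    between <- den$x > m1 & den$x < m2
    valley <- den$x[between][which.min(y[between])]
    w1 <- stats::mad(x[x < valley], center = m1)
    w2 <- stats::mad(x[x >= valley], center = m2)
    lo <- m1 - 3 * w1
    hi <- m2 + 3 * w2
    frac_2N <- mean(x >= lo & x < valley)
    frac_4N <- mean(x >= valley & x <= hi)
    bounds <- c(lower_2N = lo, boundary = valley, upper_4N = hi,
                mode_2N = m1, mode_4N = m2)
  } else {
    stopifnot(length(window_2n) == 2, length(window_4n) == 2,
              window_2n[1] < window_2n[2], window_4n[1] < window_4n[2],
              window_2n[2] <= window_4n[1])
    frac_2N <- mean(x >= window_2n[1] & x <= window_2n[2])
    frac_4N <- mean(x >= window_4n[1] & x <= window_4n[2])
    bounds <- c(lower_2N = window_2n[1], upper_2N = window_2n[2],
                lower_4N = window_4n[1], upper_4N = window_4n[2])
  }
  structure(list(frac_2N = frac_2N, frac_4N = frac_4N,
                 frac_other = 1 - frac_2N - frac_4N,
                 boundaries = bounds, n = n, method = method),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("DNA-content gate (%s, n=%d): 2N %.1f%%, 4N %.1f%%, other %.1f%%\n",
              x$method, x$n, 100 * x$frac_2N, 100 * x$frac_4N,
              100 * x$frac_other))
  invisible(x)
}

#' Decompose the 4N peak into G2/M and binucleated contributions
#'
#' The 4N peak of a DNA-content histogram mixes G2/M cells with binucleated
#' cells. Given an imaging-derived binucleation fraction, the G2/M fraction
#' is estimated by subtraction: `est_G2M = frac_4N - f`, where `f` is the
#' binucleated fraction among the measured (surviving) cells. If the
#' imaging fraction refers to intact tissue and a dissociation-loss
#' probability is supplied, it is first converted to the surviving-sample
#' scale: `f_surv = f (1 - p_loss) / (1 - f p_loss)`. A negative estimate is
#' clipped to zero with a warning.
#'
#' @param gate a `gate_result` from [gate_2n_4n()].
#' @param confocal_binucleated_fraction binucleated fraction of all cells
#'   measured by 3D imaging, in `[0, 1]`.
#' @param p_loss_binucleated optional dissociation-loss probability used to
#'   correct an in-tissue imaging fraction to the dissociated sample.
#' @param tolerance slack allowed when the (corrected) imaging fraction
#'   exceeds `frac_4N`.
#' @return list with `est_G2M_fraction`, `est_binucleated_fraction_of_4N`,
#'   and `binucleated_fraction_used` (after any loss correction).
#' @export
decompose_4n <- function(gate, confocal_binucleated_fraction,
                         p_loss_binucleated = NULL, tolerance = 0.02) {
  stopifnot(inherits(gate, "gate_result"),
            confocal_binucleated_fraction >= 0,
            confocal_binucleated_fraction <= 1)
  f <- confocal_binucleated_fraction
  if (!is.null(p_loss_binucleated)) {
    stopifnot(p_loss_binucleated >= 0, p_loss_binucleated <= 1)
    f <- f * (1 - p_loss_binucleated) / (1 - f * p_loss_binucleated)
  }
  if (f > gate$frac_4N + tolerance)
    stop("binucleated fraction (", signif(f, 3),
         ") exceeds the 4N fraction (", signif(gate$frac_4N, 3),
         ") beyond tolerance; check the loss correction")
  est <- gate$frac_4N - f
  if (est < 0) {
    warning("estimated G2/M fraction below zero; clipped to 0")
    est <- 0
  }
  list(est_G2M_fraction = est,
       est_binucleated_fraction_of_4N =
         if (gate$frac_4N > 0) min(f / gate$frac_4N, 1) else NA_real_,
       binucleated_fraction_used = f)
}
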