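#' Find G1/G2 peaks in a fluorescence distribution
#'
#' Gaussian kernel density estimate (Silverman's rule-of-thumb bandwidth
#' unless one is supplied); the two highest local maxima are returned with
#' the lower assigned to G1 (cells in G1 carry half the G2 DNA content).
#' A warning is emitted when the G2/G1 ratio falls outside [1.7, 2.3],
#' which usually indicates a mis-identified peak.
#'
#' @param sample a [fluorescence_sample()] (needs >= 100 cells).
#' @param bandwidth optional kernel bandwidth passed to [stats::density()].
#' @return list with `g1_peak`, `g2_peak` and `ratio`.
#' @export
cytometry_peaks <- function(sample, bandwidth = NULL) {
  v <- sample$values
  if (length(v) < 100L)
    bt_stop("config", "need >= 100 cells for peak finding (got %d)", length(v))
  d <- stats::density(v, bw = bandwidth %||% "nrd0")
  locmax <- which(diff(sign(diff(d$y))) == -2) + 1L
  # numeric wiggles in near-zero tails are not peaks
  locmax <- locmax[d$y[locmax] > 0.01 * max(d$y)]
  if (length(locmax) < 2L) {
    mode <- if (length(locmax) == 1L) d$x[locmax] else d$x[which.max(d$y)]
    stop(structure(
      class = c("brewtrace_single_peak", "error", "condition"),
      list(message = sprintf("density is unimodal (mode at %.3g)", mode),
           call = sys.call(), mode = mode)))
  }
  top2 <- locmax[order(d$y[locmax], decreasing = TRUE)[1:2]]
  peaks <- sort(d$x[top2])
  ratio <- peaks[2] / peaks[1]
  if (ratio < 1.7 || ratio > 2.3)
    bt_warn("G2/G1 peak ratio %.2f outside [1.7, 2.3]", ratio)
  list(g1_peak = peaks[1], g2_peak = peaks[2], ratio = ratio)
}

#' Infer DNA content relative to a haploid control
#'
#' @param sample_g1 G1 peak fluorescence of the sample.
#' @param haploid_control_g1 G1 peak fluorescence of a haploid control
#'   strain measured in the same run.
#' @return list with `estimate` (real-valued genome equivalents) and
#'   `ploidy` (nearest integer).
#' @export
infer_dna_content <- function(sample_g1, haploid_control_g1) {
  check_scalar(sample_g1, "sample_g1", 1e-12)
  check_scalar(haploid_control_g1, "haploid_control_g1", 1e-12)
  est <- sample_g1 / haploid_control_g1
  list(estimate = est, ploidy = as.integer(round(est)))
}

#' Infer ploidy from the alternate-allele frequency spectrum
#'
#' Histograms the per-site alternate-allele support fractions on a grid
#' (bins centered on multiples of `grid`), finds modes as local maxima
#' above 50% of the global maximum, and reports the smallest ploidy `p`
#' whose expected dosage fractions `{i/p, i = 1..p-1}` cover every mode to
#' within `grid/2`. Peaks at 0.25 / 0.5 / 0.75 therefore yield ploidy 4,
#' and a single 0.5 peak yields ploidy 2.
#'
#' @param frequencies numeric vector of alternate-allele frequencies in
#'   (0, 1); fixed sites must be excluded. At least 500 values required.
#' @param grid histogram bin width (default 0.05).
#' @param max_ploidy largest ploidy considered.
#' @return list with `modes` (bin centers), `ploidy` (integer or `NA` when
#'   undetermined) and `histogram` (data.table of bin centers and counts).
#' @export
allele_frequency_modes <- function(frequencies, grid = 0.05, max_ploidy = 16L) {
  f <- frequencies[!is.na(frequencies)]
  if (any(f <= 0 | f >= 1))
    bt_stop("format", "frequencies must lie strictly in (0, 1)")
  if (length(f) < 500L)
    bt_stop("config", "need >= 500 frequencies (got %d)", length(f))
  centers <- seq(0, 1, by = grid)
  counts <- tabulate(pmin(pmax(round(f / grid), 0), length(centers) - 1L) + 1L,
                     nbins = length(centers))
  n <- length(counts)
  left <- c(-Inf, counts[-n])
  right <- c(counts[-1], -Inf)
  is_mode <- counts > left & counts > right & counts > 0.5 * max(counts)
  modes <- centers[is_mode]
  hist <- data.table(center = centers, count = counts)
  if (length(modes) == 0L) {
    bt_warn("no allele-frequency mode found; ploidy undetermined")
    return(list(modes = numeric(0), ploidy = NA_integer_, histogram = hist))
  }
  ploidy <- NA_integer_
  for (p in 2:max_ploidy) {
    expect <- (1:(p - 1)) / p
    if (all(vapply(modes, function(m) any(abs(m - expect) <= grid / 2 + 1e-9),
                   logical(1)))) { ploidy <- p; break }
  }
  if (is.na(ploidy)) bt_warn("modes fit no ploidy <= %d", max_ploidy)
  list(modes = modes, ploidy = ploidy, histogram = hist)
}

#' Spore viability from tetrad dissection counts
#'
#' @param tetrad_colony_counts integer vector of viable colonies (0-4) per
#'   dissected tetrad.
#' @return viability fraction in [0, 1].
#' @export
spore_viability <- function(tetrad_colony_counts) {
  x <- tetrad_colony_counts
  if (length(x) == 0L) bt_stop("config", "no tetrads supplied")
  if (any(is.na(x)) || any(x != floor(x)) || any(x < 0 | x > 4))
    bt_stop("format", "counts must be integers in 0..4")
  sum(x) / (4 * length(x))
}
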