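#' Simulate a logistic growth curve
#'
#' `OD(t) = K / (1 + ((K - od0)/od0) * exp(-r t)) + Normal(0, noise_sd)`,
#' sampled every `dt` hours over `horizon` hours (97 timepoints at the
#' 15-minute / 24-hour defaults).
#'
#' @param r per-hour intrinsic growth rate.
#' @param K carrying capacity (OD units).
#' @param od0 initial OD.
#' @param dt sampling interval in hours (default 0.25 = 15 min).
#' @param horizon total duration in hours.
#' @param noise_sd OD measurement noise standard deviation.
#' @param seed integer RNG seed.
#' @param strain,condition labels carried on the curve.
#' @return a [growth_curve()].
#' @export
simulate_growth_curve <- function(r, K = 1.2, od0 = 0.1, dt = 0.25,
                                  horizon = 24, noise_sd = 0, seed = NULL,
                                  strain = "sim", condition = NA) {
  check_scalar(K, "K", 1e-12); check_scalar(od0, "od0", 1e-12)
  times <- seq(0, horizon, by = dt)
  with_seed(seed, {
    od <- K / (1 + ((K - od0) / od0) * exp(-r * times))
    if (noise_sd > 0) od <- od + rnorm(length(od), 0, noise_sd)
    growth_curve(times, od, strain = strain, condition = condition)
  })
}

#' Flow-cytometry fluorescence sample
#' @param values per-cell fluorescence intensities (must be positive).
#' @param strain strain identifier.
#' @export
fluorescence_sample <- function(values, strain = "strain") {
  if (any(values <= 0)) bt_stop("format", "fluorescence values must be > 0")
  structure(list(values = as.numeric(values), strain = strain),
            class = "FluorescenceSample")
}

#' Simulate a two-population (G1/G2) fluorescence sample
#'
#' Mixture of `Normal(g1_mean, cv*g1_mean)` and
#' `Normal(2*g1_mean, cv*2*g1_mean)` with weight `g2_fraction` on the
#' second component: cells in G2 carry twice the G1 DNA content.
#'
#' @param g1_mean mean fluorescence of the G1 population (arbitrary units).
#' @param cv coefficient of variation of each component.
#' @param g2_fraction fraction of cells in G2.
#' @param n_cells number of cells (respected exactly).
#' @param seed integer RNG seed.
#' @return a [fluorescence_sample()].
#' @export
simulate_cytometry <- function(g1_mean = 200, cv = 0.03, g2_fraction = 0.4,
                               n_cells = 5000, seed = NULL) {
  check_scalar(g2_fraction, "g2_fraction", 0, 1)
  with_seed(seed, {
    n2 <- rbinom(1, n_cells, g2_fraction)
    v <- c(rnorm(n_cells - n2, g1_mean, cv * g1_mean),
           rnorm(n2, 2 * g1_mean, cv * 2 * g1_mean))
    v <- pmax(v, 1e-6)
    fluorescence_sample(sample(v), strain = "sim")
  })
}

#' Structural-variant call set
#'
#' @param calls data.frame with `chrom`, `pos`, `class`, `support`.
#' @param strain strain identifier.
#' @param depth genome-wide fold coverage of the underlying read set.
#' @export
sv_callset <- function(calls, strain = "strain", depth = 0) {
  SV_CLASSES <- c("deletion", "insertion", "tandem_duplication",
                  "interspersed_duplication", "inversion")
  x <- as.data.table(calls)
  for (col in c("chrom", "pos", "class", "support"))
    if (!col %in% names(x)) bt_stop("format", "calls lack column '%s'", col)
  if (nrow(x) && !all(x$class %in% SV_CLASSES))
    bt_stop("format", "unknown SV class: %s",
            paste(setdiff(unique(x$class), SV_CLASSES), collapse = ", "))
  if (nrow(x) && any(x$support < 0)) bt_stop("format", "support must be >= 0")
  structure(list(strain = strain, depth = depth, calls = x[]),
            class = "SVCallSet")
}

#' @export
print.SVCallSet <- function(x, ...) {
  cat(sprintf("SVCallSet '%s' (%.0fX): %d calls\n",
              x$strain, x$depth, nrow(x$calls)))
  invisible(x)
}

#' Simulate a pair of SV call sets with controlled sharing
#'
#' A fraction of calls is duplicated into both sets with positions
#' perturbed by `Normal(0, jitter_sd)`; the remainder are placed uniformly
#' and independently in each set. Serves as the null/alternative generator
#' for the proximity statistic.
#'
#' @param n_calls calls per set.
#' @param shared_fraction fraction of calls present in both sets.
#' @param jitter_sd positional jitter (bp) applied to the shared calls in
#'   the second set.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param classes SV class vocabulary to draw from.
#' @param depth_a,depth_b nominal coverage depths attached to the two sets.
#' @param seed integer RNG seed.
#' @return list with `a`, `b` (two [sv_callset()]s) and `n_shared`.
#' @export
simulate_sv_callsets <- function(n_calls = 100, shared_fraction = 0.5,
                                 jitter_sd = 100, chrom_lengths,
                                 classes = c("deletion", "insertion",
                                             "tandem_duplication"),
                                 depth_a = 59, depth_b = 9, seed = NULL) {
  check_scalar(shared_fraction, "shared_fraction", 0, 1)
  if (is.null(names(chrom_lengths)))
    bt_stop("config", "chrom_lengths must be named")
  with_seed(seed, {
    n_shared <- round(shared_fraction * n_calls)
    draw_calls <- function(n) {
      ch <- sample(names(chrom_lengths), n, replace = TRUE,
                   prob = chrom_lengths)
      data.table(chrom = ch,
                 pos = floor(runif(n) * chrom_lengths[ch]),
                 class = sample(classes, n, replace = TRUE))
    }
    shared <- draw_calls(n_shared)
    priv_a <- draw_calls(n_calls - n_shared)
    priv_b <- draw_calls(n_calls - n_shared)
    shared_b <- data.table::copy(shared)
    if (jitter_sd > 0 && n_shared > 0) {
      shared_b[, pos := pmin(pmax(round(pos + rnorm(.N, 0, jitter_sd)), 0),
                             chrom_lengths[chrom] - 1)]
    }
    mk <- function(calls, strain, depth) {
      calls[, support := pmax(1L, rpois(.N, 0.4 * depth))]
      sv_callset(calls[order(chrom, pos)], strain = strain, depth = depth)
    }
    list(a = mk(rbind(shared, priv_a), "setA", depth_a),
         b = mk(rbind(shared_b, priv_b), "setB", depth_b),
         n_shared = n_shared)
  })
}

#' Read / write SV call sets as BED-like TSV
#' @param s an [sv_callset()].
#' @param path file path.
#' @export
write_sv_calls <- function(s, path) {
  writeLines(sprintf("#strain=%s depth=%g", s$strain, s$depth), path)
  fwrite(s$calls, path, sep = "\t", col.names = TRUE, append = TRUE)
  invisible(path)
}

#' @rdname write_sv_calls
#' @param strain,depth overrides when the file carries no header line.
#' @export
read_sv_calls <- function(path, strain = NULL, depth = NULL) {
  first <- readLines(path, n = 1)
  skip <- 0L
  if (startsWith(first, "#")) {
    strain <- strain %||% sub("^#strain=(\\S+).*", "\\1", first)
    depth <- depth %||% as.numeric(sub(".*depth=([0-9.]+).*", "\\1", first))
    skip <- 1L
  }
  x <- fread(path, sep = "\t", skip = skip, header = TRUE)
  sv_callset(x, strain = strain %||% "strain", depth = depth %||% 0)
}
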