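#' Coverage track container
#'
#' Normalized read depth in fixed non-overlapping windows; value 1.0
#' corresponds to the strain's baseline ploidy.
#'
#' @param windows data.frame with `chrom`, `start`, `end`, `value`.
#' @param strain strain identifier.
#' @param window window size in bp (default 250).
#' @return object of class `CoverageTrack`.
#' @export
coverage_track <- function(windows, strain = "strain", window = 250L) {
  w <- as.data.table(windows)
  for (col in c("chrom", "start", "end", "value"))
    if (!col %in% names(w)) bt_stop("format", "windows lack column '%s'", col)
  if (nrow(w) == 0L) bt_stop("empty", "coverage track has no windows")
  if (any(w$value < 0)) bt_stop("format", "coverage values must be >= 0")
  w <- w[order(chrom, start)]
  overlap <- w[, any(start[-1] < end[-.N]), by = chrom][V1 == TRUE]
  if (nrow(overlap)) bt_stop("format", "overlapping windows on %s",
                             paste(overlap$chrom, collapse = ", "))
  structure(list(strain = strain, window = as.integer(window), windows = w[]),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat(sprintf("CoverageTrack '%s': %d windows of %d bp on %d chromosome(s)\n",
              x$strain, nrow(x$windows), x$window,
              length(unique(x$windows$chrom))))
  invisible(x)
}

#' Configuration for the coverage simulator
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param baseline_ploidy genome-wide copy number of unaffected windows.
#' @param events data.frame (`chrom`, `start`, `end`, `copy_number`) of
#'   injected CNVs; may be `NULL`.
#' @param slope chromosome-end bias coefficient `b`: the expected log2
#'   coverage increases linearly with the normalized distance `x` from the
#'   chromosome midpoint (`x = 0`) to its end (`x = 1`).
#' @param noise_sd standard deviation of per-window log2 coverage noise.
#' @param window window size in bp.
#' @param seed integer RNG seed.
#' @export
coverage_sim_config <- function(chrom_lengths, baseline_ploidy = 4L,
                                events = NULL, slope = 0, noise_sd = 0.05,
                                window = 250L, seed = NULL) {
  if (is.null(names(chrom_lengths)))
    bt_stop("config", "chrom_lengths must be named")
  if (window <= 0) bt_stop("config", "window must be positive")
  if (!is.null(events)) {
    ev <- as.data.table(events)
    if (any(!ev$chrom %in% names(chrom_lengths)) ||
        any(ev$start < 0) || any(ev$end > chrom_lengths[ev$chrom]))
      bt_stop("config", "events must lie within chromosomes")
  }
  structure(list(chrom_lengths = chrom_lengths,
                 baseline_ploidy = as.integer(baseline_ploidy),
                 events = if (is.null(events)) NULL else as.data.table(events),
                 slope = slope, noise_sd = noise_sd,
                 window = as.integer(window), seed = seed),
            class = "CoverageSimConfig")
}

#' Simulate a normalized coverage track
#'
#' Window value is `(copy_number / baseline_ploidy) * 2^(b*x) * 2^eps`,
#' where `x` is the normalized distance of the window center from the
#' chromosome midpoint and `eps ~ Normal(0, noise_sd)`. A window takes an
#' event's copy number when its midpoint falls inside the event. Only full
#' windows are emitted (a trailing partial window is dropped).
#'
#' @param cfg a [coverage_sim_config()].
#' @return a [coverage_track()].
#' @export
simulate_coverage <- function(cfg) {
  stopifnot(inherits(cfg, "CoverageSimConfig"))
  with_seed(cfg$seed, {
    out <- lapply(names(cfg$chrom_lengths), function(ch) {
      len <- cfg$chrom_lengths[[ch]]
      n <- floor(len / cfg$window)
      if (n == 0L) return(NULL)
      start <- (seq_len(n) - 1) * cfg$window
      end <- start + cfg$window
      center <- (start + end) / 2
      x <- abs(center - len / 2) / (len / 2)
      cn <- rep(cfg$baseline_ploidy, n)
      if (!is.null(cfg$events)) {
        ev <- cfg$events[chrom == ch]
        for (i in seq_len(nrow(ev)))
          cn[center >= ev$start[i] & center < ev$end[i]] <- ev$copy_number[i]
      }
      eps <- if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else 0
      value <- (cn / cfg$baseline_ploidy) * 2^(cfg$slope * x) * 2^eps
      data.table(chrom = ch, start = start, end = end, value = value)
    })
    coverage_track(rbindlist(out), strain = "sim", window = cfg$window)
  })
}

#' Write / read a coverage track as bedGraph
#'
#' @param track a [coverage_track()].
#' @param path file path.
#' @export
write_bedgraph <- function(track, path) {
  fwrite(track$windows[, .(chrom, start = as.integer(start),
                           end = as.integer(end), value)],
         path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param strain,window passed to [coverage_track()].
#' @export
read_bedgraph <- function(path, strain = "strain", window = 250L) {
  x <- fread(path, header = FALSE, sep = "\t",
             col.names = c("chrom", "start", "end", "value"))
  coverage_track(x, strain = strain, window = window)
}
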