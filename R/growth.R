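#' Growth curve container
#'
#' @param times hours, strictly increasing, uniformly spaced (15-minute
#'   plate-reader intervals by default).
#' @param od optical density readings (OD595).
#' @param strain strain identifier.
#' @param condition condition label (e.g. CoCl2 concentration in mM).
#' @export
growth_curve <- function(times, od, strain = "strain", condition = NA) {
  if (length(times) != length(od))
    bt_stop("format", "times and od must have equal length")
  if (length(times) < 5L) bt_stop("format", "need >= 5 timepoints")
  if (any(diff(times) <= 0)) bt_stop("format", "times must be strictly increasing")
  structure(list(times = as.numeric(times), od = as.numeric(od),
                 strain = strain, condition = condition),
            class = "GrowthCurve")
}

#' @export
print.GrowthCurve <- function(x, ...) {
  cat(sprintf("GrowthCurve '%s'%s: %d points over %.2g h, OD %.3g-%.3g\n",
              x$strain,
              if (is.na(x$condition)) "" else sprintf(" [%s]", x$condition),
              length(x$times), max(x$times), min(x$od), max(x$od)))
  invisible(x)
}

#' Sliding-window percentile growth rate
#'
#' Fits an ordinary least-squares slope of OD against time in every run of
#' `window` consecutive timepoints, keeps windows whose Pearson correlation
#' exceeds `r_min` (signed, so declining windows never pass; a window with
#' zero OD variance gets `r := 0` and is excluded), and reports the
#' linear-interpolated `percentile`-th percentile of the kept slopes. For a
#' noiseless logistic curve this approaches the maximum slope `r*K/4`.
#'
#' @param curve a [growth_curve()].
#' @param window window width in timepoints.
#' @param r_min minimum (signed) Pearson correlation for a window to count.
#' @param percentile percentile of kept slopes reported (default 98).
#' @return list with `rate` (OD per hour; 0 when no window passes),
#'   `n_kept` (windows that passed) and `flagged` (`TRUE` when no window
#'   passed).
#' @export
growth_rate <- function(curve, window = 5L, r_min = 0.8, percentile = 98) {
  t <- curve$times; y <- curve$od
  n <- length(t)
  if (n < window) bt_stop("config", "need >= %d timepoints (got %d)", window, n)
  nw <- n - window + 1L
  slopes <- numeric(nw); rs <- numeric(nw)
  for (i in seq_len(nw)) {
    idx <- i:(i + window - 1L)
    tt <- t[idx]; yy <- y[idx]
    vy <- stats::var(yy)
    if (vy == 0) { slopes[i] <- 0; rs[i] <- 0; next }
    ct <- stats::cov(tt, yy)
    slopes[i] <- ct / stats::var(tt)
    rs[i] <- ct / sqrt(stats::var(tt) * vy)
  }
  kept <- slopes[rs > r_min]
  if (length(kept) == 0L)
    return(list(rate = 0, n_kept = 0L, flagged = TRUE))
  list(rate = pct_linear(kept, percentile), n_kept = length(kept),
       flagged = FALSE)
}

#' Dose-response summary across strains and conditions
#'
#' Aggregates replicate growth rates per strain x condition cell and ranks
#' strains within each condition by mean rate (descending).
#'
#' @param curves list of [growth_curve()] objects carrying `strain` and
#'   `condition` labels.
#' @param ... passed to [growth_rate()].
#' @return list with `table` (data.table: strain, condition, n, mean_rate,
#'   sd_rate) and `ranking` (data.table: condition, rank, strain).
#' @export
dose_response <- function(curves, ...) {
  if (length(curves) == 0L) bt_stop("config", "no curves supplied")
  rows <- rbindlist(lapply(curves, function(cv) {
    gr <- growth_rate(cv, ...)
    data.table(strain = cv$strain, condition = cv$condition, rate = gr$rate)
  }))
  tab <- rows[, .(n = .N, mean_rate = mean(rate),
                  sd_rate = if (.N > 1L) stats::sd(rate) else 0),
              by = .(strain, condition)]
  rank_tab <- tab[order(condition, -mean_rate),
                  .(rank = seq_len(.N), strain = strain), by = condition]
  list(table = tab[], ranking = rank_tab[])
}

#' Read a plate-reader TSV (time column + one column per well)
#'
#' @param path TSV with a `time` column (hours) and one OD column per well.
#' @param well_map optional data.frame (`well`, `strain`, `condition`)
#'   assigning labels; wells absent from the map are skipped.
#' @return list of [growth_curve()] objects.
#' @export
read_plate_tsv <- function(path, well_map = NULL) {
  x <- fread(path, sep = "\t", header = TRUE)
  tcol <- names(x)[1]
  wells <- setdiff(names(x), tcol)
  if (!is.null(well_map)) {
    wm <- as.data.table(well_map)
    wells <- intersect(wells, wm$well)
  }
  lapply(wells, function(w) {
    strain <- w; condition <- NA
    if (!is.null(well_map)) {
      row <- wm[well == w][1]
      strain <- row$strain; condition <- row$condition
    }
    growth_curve(x[[tcol]], x[[w]], strain = strain, condition = condition)
  })
}
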