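#' Normalize raw window depth by the genome-wide median
#'
#' After normalization the track median is 1, so 1.0 corresponds to the
#' strain's baseline ploidy.
#'
#' @param track a [coverage_track()] whose `value` column is raw depth, or
#'   a data.frame with `chrom`, `start`, `end`, `value`.
#' @return a [coverage_track()] with normalized values.
#' @export
normalize_coverage <- function(track) {
  if (!inherits(track, "CoverageTrack"))
    track <- coverage_track(track)
  w <- data.table::copy(track$windows)
  med <- stats::median(w$value)
  if (med <= 0) bt_stop("empty", "median raw depth is zero")
  w[, value := value / med]
  coverage_track(w, strain = track$strain, window = track$window)
}

#' Chromosome-end coverage slope and strain keep/drop decision
#'
#' Detects the chromosome-end coverage artifact: a linear model of
#' `y = log2(normalized coverage)` (clamped to `[-2, 2]`; zero-coverage
#' windows floor at -2) against `x = normalized distance of the window
#' center from its chromosome midpoint` (`x = 0` at the midpoint, `x = 1`
#' at either end), pooled over all chromosomes. Strains with a fitted
#' slope strictly below `-threshold` or strictly above `threshold` are
#' flagged for removal; a slope of exactly +/-0.15 keeps the strain.
#'
#' @param track a normalized [coverage_track()].
#' @param threshold slope magnitude beyond which the strain is dropped.
#' @return list with `slope` and `keep` (logical).
#' @export
end_slope <- function(track, threshold = 0.15) {
  w <- track$windows
  parts <- w[, {
    len <- max(end)
    center <- (start + end) / 2
    .(x = abs(center - len / 2) / (len / 2), value = value)
  }, by = chrom]
  y <- log2(pmax(parts$value, 2^-2))
  y <- pmin(y, 2)
  b <- unname(coef(stats::lm(y ~ parts$x))[2])
  # strict inequality, with a hair of numeric slack so a slope of exactly
  # +/-threshold keeps the strain
  eps <- 1e-9
  list(slope = b, keep = !(b < -threshold - eps || b > threshold + eps))
}

#' Call copy-number-variant segments from a normalized coverage track
#'
#' Each window is classified to the integer copy number
#' `round(value * ploidy)`, clipped to `[0, 2 * ploidy]`. Candidate
#' segments are maximal runs of windows in which more than `purity` of
#' windows share one non-baseline class, at least `min_length` bp long
#' (40 windows at the 250 bp / 10 kb defaults). Runs of the same class are
#' merged across gaps as long as the merged stretch stays above the purity
#' threshold; segment boundaries are trimmed to the outermost
#' class-concordant windows. Each candidate is then tested with a
#' two-sided Wilcoxon rank-sum test of its member-window values against
#' all baseline-classified windows of the same strain and kept at
#' `p < alpha`. When fewer than `min_baseline` baseline windows exist the
#' test is skipped and the segment flagged `untested`.
#'
#' @param track a normalized [coverage_track()].
#' @param ploidy baseline (genome-wide) integer ploidy.
#' @param min_length minimum reported segment length in bp.
#' @param purity minimum fraction of windows sharing the segment class.
#' @param alpha Wilcoxon significance threshold.
#' @param min_baseline minimum baseline windows required to run the test.
#' @param smooth_k running-median width (windows) applied before copy-number
#'   classification; the rank test still uses raw window values. At baseline
#'   ploidy 4 a one-copy gain moves coverage only 25%, so per-window
#'   rounding of raw values would break the >90% concordance rule at
#'   realistic noise; a 3-window median restores it without moving
#'   boundaries by more than one window. Set to 1 to disable.
#' @return data.table of segments: `chrom`, `start`, `end`, `type`
#'   (`gain`/`loss`), `copy_number`, `n_windows`, `p_value`, `untested`.
#' @export
call_cnv_segments <- function(track, ploidy, min_length = 10000,
                              purity = 0.9, alpha = 0.05,
                              min_baseline = 100, smooth_k = 3L) {
  if (!is_count(ploidy) || ploidy < 1) bt_stop("config", "bad ploidy")
  w <- data.table::copy(track$windows)
  w[, smoothed := if (.N >= smooth_k && smooth_k > 1L)
      stats::runmed(value, smooth_k, endrule = "median") else value,
    by = chrom]
  w[, copy_class := pmin(pmax(as.integer(round(smoothed * ploidy)), 0L),
                         as.integer(2 * ploidy))]
  baseline_vals <- w[copy_class == ploidy, value]
  min_windows <- ceiling(min_length / track$window)

  out <- list()
  for (ch in unique(w$chrom)) {
    wc <- w[chrom == ch]
    for (cl in setdiff(unique(wc$copy_class), ploidy)) {
      v <- which(wc$copy_class == cl)
      if (length(v) == 0L) next
      # merge consecutive class-c runs while the purity of the whole merged
      # span stays above the threshold; then trim isolated single-window
      # strays at the edges so noise does not stretch boundaries
      dv <- diff(v)
      run_end_i <- c(which(dv > 1L), length(v))
      run_start_i <- c(1L, head(run_end_i, -1L) + 1L)
      runs <- data.table(first = v[run_start_i], last = v[run_end_i],
                         size = run_end_i - run_start_i + 1L)
      close_seg <- function(rr) {
        # drop edge runs of size 1 separated by more than one window
        while (nrow(rr) >= 2L && rr$size[1] == 1L &&
               rr$first[2] - rr$last[1] > 2L) rr <- rr[-1]
        while (nrow(rr) >= 2L && rr$size[nrow(rr)] == 1L &&
               rr$first[nrow(rr)] - rr$last[nrow(rr) - 1L] > 2L)
          rr <- rr[-nrow(rr)]
        if (sum(rr$size) < 2L) return(NULL)
        list(first = rr$first[1], last = rr$last[nrow(rr)],
             count = sum(rr$size))
      }
      segs <- list()
      cur <- runs[1]
      for (ri in seq_len(nrow(runs))[-1]) {
        cand_count <- sum(cur$size) + runs$size[ri]
        cand_span <- runs$last[ri] - cur$first[1] + 1L
        if (cand_count / cand_span > purity) {
          cur <- rbind(cur, runs[ri])
        } else {
          segs <- c(segs, list(close_seg(cur)))
          cur <- runs[ri]
        }
      }
      segs <- c(segs, list(close_seg(cur)))
      for (sg in segs) {
        if (is.null(sg)) next
        nwin <- sg$last - sg$first + 1L
        seg_len <- wc$end[sg$last] - wc$start[sg$first]
        if (nwin < min_windows || seg_len < min_length) next
        vals <- wc$value[sg$first:sg$last]
        untested <- length(baseline_vals) < min_baseline
        p <- NA_real_
        if (!untested) {
          p <- suppressWarnings(
            stats::wilcox.test(vals, baseline_vals, exact = FALSE)$p.value)
          if (!(p < alpha)) next
        }
        out <- c(out, list(data.table(
          chrom = ch, start = wc$start[sg$first], end = wc$end[sg$last],
          type = if (cl > ploidy) "gain" else "loss",
          copy_number = cl, n_windows = nwin, p_value = p,
          untested = untested)))
      }
    }
  }
  if (length(out) == 0L)
    return(data.table(chrom = character(), start = numeric(), end = numeric(),
                      type = character(), copy_number = integer(),
                      n_windows = integer(), p_value = numeric(),
                      untested = logical()))
  rbindlist(out)[order(chrom, start)]
}

#' Relatedness-pruned CNV frequencies per group
#'
#' Estimates the population frequency of each reference CNV within strain
#' groups while controlling for clonal redundancy: in each of
#' `n_resamples` rounds, strains are visited in random order and greedily
#' retained while their kinship with every already-retained strain stays
#' below `kin_max`; any group left empty then receives one random member.
#' A retained strain is a carrier of a reference CNV when it has a
#' same-type segment whose intersection covers at least `overlap_min` of
#' the reference CNV length. The reported frequency is the mean of
#' carriers/retained per group over the resamples.
#'
#' @param segments data.table of called segments with a `strain` column
#'   (as from [call_cnv_segments()], row-bound across strains).
#' @param groups named character vector mapping strain to group.
#' @param kinship symmetric kinship matrix covering all strains.
#' @param reference_cnvs data.table (`chrom`, `start`, `end`, `type`,
#'   optional `id`) of reference CNVs whose frequencies are wanted.
#' @param n_resamples,kin_max,overlap_min tuning parameters.
#' @param seed integer RNG seed.
#' @return data.table: `cnv_id`, `group`, `frequency`.
#' @export
cnv_group_frequency <- function(segments, groups, kinship, reference_cnvs,
                                n_resamples = 20L, kin_max = 0.18,
                                overlap_min = 0.75, seed = NULL) {
  strains <- names(groups)
  if (is.null(strains)) bt_stop("config", "groups must be a named vector")
  missing_k <- setdiff(strains, rownames(kinship))
  if (length(missing_k))
    bt_stop("config", "strain(s) absent from kinship matrix: %s",
            paste(missing_k, collapse = ", "))
  ref <- as.data.table(reference_cnvs)
  if (!"id" %in% names(ref))
    ref[, id := sprintf("cnv%03d", seq_len(nrow(ref)))]
  segs <- as.data.table(segments)

  carrier <- matrix(FALSE, length(strains), nrow(ref),
                    dimnames = list(strains, ref$id))
  for (i in seq_len(nrow(ref))) {
    need <- overlap_min * (ref$end[i] - ref$start[i])
    hit <- segs[chrom == ref$chrom[i] & type == ref$type[i] &
                pmin(end, ref$end[i]) - pmax(start, ref$start[i]) >= need]
    carrier[unique(hit$strain[hit$strain %in% strains]), i] <- TRUE
  }

  freq_sum <- matrix(0, length(unique(groups)), nrow(ref),
                     dimnames = list(sort(unique(groups)), ref$id))
  for (r in seq_len(n_resamples)) {
    sel <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, r), {
      ord <- sample(strains)
      kept <- character(0)
      for (s in ord) {
        if (length(kept) == 0L || all(kinship[s, kept] < kin_max))
          kept <- c(kept, s)
      }
      for (gr in unique(groups)) {
        members <- strains[groups == gr]
        if (!any(members %in% kept))
          kept <- c(kept, sample(members, 1))
      }
      kept
    })
    for (gr in rownames(freq_sum)) {
      sel_g <- sel[groups[sel] == gr]
      freq_sum[gr, ] <- freq_sum[gr, ] +
        colMeans(carrier[sel_g, , drop = FALSE])
    }
  }
  freq <- freq_sum / n_resamples
  out <- data.table(
    cnv_id = rep(colnames(freq), each = nrow(freq)),
    group = rep(rownames(freq), ncol(freq)),
    frequency = as.vector(freq))
  out[]
}

#' Mean normalized coverage per gene
#'
#' A window contributes to a gene when the two intervals intersect by at
#' least 1 bp; genes with no overlapping window get `NA`.
#'
#' @param track a normalized [coverage_track()].
#' @param genes data.table (`chrom`, `start`, `end`, `label`).
#' @return named numeric vector of per-gene mean coverage.
#' @export
gene_coverage <- function(track, genes) {
  g <- as.data.table(genes)
  if (!"label" %in% names(g)) g[, label := sprintf("gene%04d", seq_len(nrow(g)))]
  w <- track$windows
  vapply(seq_len(nrow(g)), function(i) {
    hit <- w[chrom == g$chrom[i] & start < g$end[i] & end > g$start[i], value]
    if (length(hit)) mean(hit) else NA_real_
  }, numeric(1)) |> stats::setNames(g$label)
}

#' Average-linkage clustering of strains on gene-coverage profiles
#'
#' @param cov_matrix strains x genes numeric matrix (e.g. rows of
#'   [gene_coverage()] outputs).
#' @return an [stats::hclust] object (euclidean distance, average linkage).
#' @export
cluster_strains_by_coverage <- function(cov_matrix) {
  stats::hclust(stats::dist(cov_matrix, method = "euclidean"),
                method = "average")
}
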