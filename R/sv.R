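#' Filter SV calls by read support
#'
#' Calls supported by fewer reads than 15% of the genome-wide coverage
#' depth are removed (a call with support exactly at the threshold is
#' kept). With zero recorded depth all calls are kept with a warning.
#'
#' @param s an [sv_callset()].
#' @param min_support_fraction support threshold as a fraction of depth.
#' @return filtered `SVCallSet`.
#' @export
filter_sv_support <- function(s, min_support_fraction = 0.15) {
  if (s$depth <= 0) {
    bt_warn("call set '%s' has no depth; support filter skipped", s$strain)
    return(s)
  }
  thr <- min_support_fraction * s$depth
  sv_callset(s$calls[support >= thr], strain = s$strain, depth = s$depth)
}

#' Randomly subsample reads to a target depth
#'
#' Each read is kept independently with probability
#' `target_depth / current_depth`, emulating depth-equalizing subsampling
#' before SV calling.
#'
#' @param reads a data.table of reads (any columns) or a
#'   [split_read_set()].
#' @param current_depth,target_depth fold coverages.
#' @param seed integer RNG seed.
#' @return object of the same type with a subset of reads; for a
#'   `SplitReadSet` the `total_read_bases` is recomputed.
#' @export
subsample_reads <- function(reads, current_depth, target_depth, seed = NULL) {
  check_scalar(current_depth, "current_depth", 1e-12)
  pr <- min(target_depth / current_depth, 1)
  if (inherits(reads, "SplitReadSet")) {
    ids <- unique(reads$records$read_id)
    keep <- with_seed(seed, ids[runif(length(ids)) < pr])
    r <- reads$records[read_id %in% keep]
    per_read <- unique(r[, .(read_id, read_len)])
    return(split_read_set(r, reads$genome_length, sum(per_read$read_len)))
  }
  r <- as.data.table(reads)
  with_seed(seed, r[runif(.N) < pr])
}

#' Distances from each call to the closest same-class call in a mate set
#'
#' For every call of class `sv_class` in `a`, the minimum absolute
#' distance to a same-class call of `b` on the same chromosome. A call
#' with no same-chromosome mate is assigned its chromosome's length as a
#' documented sentinel, keeping distributions comparable in size. The
#' statistic is asymmetric in `(a, b)`.
#'
#' @param a,b two [sv_callset()]s.
#' @param sv_class SV class to compare.
#' @param chrom_lengths named numeric vector (sentinel values).
#' @return numeric vector of distances (possibly empty).
#' @export
proximity_distribution <- function(a, b, sv_class, chrom_lengths) {
  qa <- a$calls[class == sv_class]
  if (nrow(qa) == 0L) return(numeric(0))
  qb <- b$calls[class == sv_class]
  mates_by_chrom <- split(qb$pos, qb$chrom)
  no_mate <- !qa$chrom %in% names(mates_by_chrom)
  if (any(no_mate) && any(!qa$chrom[no_mate] %in% names(chrom_lengths)))
    bt_stop("config", "chromosome '%s' has no recorded length",
            setdiff(qa$chrom[no_mate], names(chrom_lengths))[1])
  out <- numeric(nrow(qa))
  out[no_mate] <- as.numeric(chrom_lengths[qa$chrom[no_mate]])
  for (ch in intersect(unique(qa$chrom), names(mates_by_chrom))) {
    mates <- sort(mates_by_chrom[[ch]])
    sel <- which(qa$chrom == ch)
    p <- qa$pos[sel]
    # nearest sorted neighbor via findInterval
    i <- findInterval(p, mates)
    lo <- ifelse(i >= 1L, abs(p - mates[pmax(i, 1L)]), Inf)
    hi <- ifelse(i < length(mates), abs(mates[pmin(i + 1L, length(mates))] - p), Inf)
    out[sel] <- pmin(lo, hi)
  }
  out
}

#' Mann-Whitney right-shift tests of proximity distributions
#'
#' Each test distribution is compared to the reference-pair distribution
#' with a Mann-Whitney U test (normal approximation with tie correction),
#' by default one-sided against the alternative that the test distribution
#' is stochastically larger (shifted toward larger distances).
#' Benjamini-Hochberg correction is applied across all supplied tests;
#' `right_shifted` flags tests with FDR q below `fdr_alpha`. `u_ratio`
#' scales the U statistic by its null expectation `n_x * n_ref / 2`, so 1
#' means no shift.
#'
#' @param tests named list of numeric distance vectors
#'   (pair x class distributions).
#' @param reference reference-pair distance vector (non-empty).
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @param fdr_alpha FDR threshold for flagging.
#' @return data.table: `name`, `n`, `u`, `u_ratio`, `p_value`, `fdr_q`,
#'   `right_shifted`.
#' @export
proximity_tests <- function(tests, reference, alternative = "greater",
                            fdr_alpha = 0.05) {
  if (length(reference) == 0L) bt_stop("config", "reference distances empty")
  if (is.null(names(tests)) || any(names(tests) == ""))
    bt_stop("config", "tests must be a named list")
  rows <- rbindlist(lapply(names(tests), function(nm) {
    x <- tests[[nm]]
    if (length(x) == 0L)
      return(data.table(name = nm, n = 0L, u = NA_real_, u_ratio = NA_real_,
                        p_value = NA_real_))
    wt <- suppressWarnings(stats::wilcox.test(
      x, reference, alternative = alternative, exact = FALSE, correct = TRUE))
    u <- unname(wt$statistic)
    data.table(name = nm, n = length(x), u = u,
               u_ratio = u / (length(x) * length(reference) / 2),
               p_value = wt$p.value)
  }))
  rows[, fdr_q := p.adjust(p_value, method = "BH")]
  rows[, right_shifted := !is.na(fdr_q) & fdr_q < fdr_alpha]
  rows[]
}
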