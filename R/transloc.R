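#' Select translocation-informative split reads
#'
#' Keeps reads that (i) have at least one supplementary alignment, (ii)
#' have no secondary alignment, and (iii) whose alignment segments span
#' exactly two distinct chromosomes — the signature of a read crossing an
#' interchromosomal junction with unambiguous mapping.
#'
#' @param s a [split_read_set()].
#' @return a `SplitReadSet` restricted to the selected reads.
#' @export
select_split_reads <- function(s) {
  r <- s$records
  if (nrow(r) == 0L) return(s)
  per <- r[, .(n_supp = sum(flag == "supplementary"),
               n_sec = sum(flag == "secondary"),
               n_chrom = data.table::uniqueN(chrom)), by = read_id]
  keep <- per[n_supp >= 1L & n_sec == 0L & n_chrom == 2L, read_id]
  split_read_set(r[read_id %in% keep], s$genome_length, s$total_read_bases)
}

#' Interchromosomal contact matrix from split reads
#'
#' Each selected split read contributes one count to the pair of 20 kb
#' bins holding the midpoints of its two chromosome segments (per
#' chromosome, the longest segment is used). Counts are converted to an
#' approximate fraction of genome-wide coverage depth
#' `D = total_read_bases / genome_length`, so a fraction near 0.5 suggests
#' a rearrangement on half the haplotypes.
#'
#' @param s a selected [split_read_set()] (see [select_split_reads()]).
#' @param bin_size bin width in bp.
#' @return object of class `ContactMatrix`: `bin_size`, `depth` and
#'   `entries` (data.table `chromA`, `binA`, `chromB`, `binB`, `count`,
#'   `fraction` with `(chromA, binA) < (chromB, binB)` lexicographically).
#' @export
contact_matrix <- function(s, bin_size = 20000L) {
  D <- s$total_read_bases / s$genome_length
  r <- s$records[flag != "secondary"]
  if (nrow(r) > 0L)
    r <- r[, if (data.table::uniqueN(chrom) == 2L) .SD, by = read_id]
  if (nrow(r) == 0L) {
    return(structure(list(bin_size = as.integer(bin_size), depth = D,
                          entries = data.table(chromA = character(),
                                               binA = integer(),
                                               chromB = character(),
                                               binB = integer(),
                                               count = integer(),
                                               fraction = numeric())),
                     class = "ContactMatrix"))
  }
  r[, seg_len := end - start]
  best <- r[order(-seg_len), .SD[1], by = .(read_id, chrom)]
  pairs <- best[, {
    mid <- floor((start + end) / 2)
    bin <- as.integer(mid %/% bin_size)
    o <- order(chrom, bin)
    .(chromA = chrom[o[1]], binA = bin[o[1]],
      chromB = chrom[o[2]], binB = bin[o[2]])
  }, by = read_id]
  entries <- pairs[, .(count = .N), by = .(chromA, binA, chromB, binB)]
  entries[, fraction := count / D]
  structure(list(bin_size = as.integer(bin_size), depth = D,
                 entries = entries[order(chromA, binA, chromB, binB)]),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %d bin pairs (%d kb bins, depth %.1fX)\n",
              nrow(x$entries), x$bin_size %/% 1000L, x$depth))
  invisible(x)
}

#' Detect translocation candidates in a contact matrix
#'
#' Reports bin pairs supported by at least `min_reads` reads and a
#' coverage fraction of at least `min_fraction`, after removing bin pairs
#' present in a control mask (built from a collinear control dataset to
#' absorb artifactual split-mapping signals). Adjacent significant bin
#' pairs (within one bin on both chromosomes) are merged into a single
#' candidate represented by its strongest entry.
#'
#' @param m a [contact_matrix()].
#' @param min_reads minimum supporting reads.
#' @param min_fraction minimum fraction of coverage depth.
#' @param control optional `ContactMatrix` whose entries mask candidates.
#' @return data.table of candidates: `chromA`, `binA`, `chromB`, `binB`,
#'   `count` (total over merged entries), `fraction` (max).
#' @export
detect_translocations <- function(m, min_reads = 3L, min_fraction = 0.15,
                                  control = NULL) {
  e <- m$entries[count >= min_reads & fraction >= min_fraction]
  if (!is.null(control) && nrow(control$entries) > 0L && nrow(e) > 0L) {
    mask_keys <- control$entries[, paste(chromA, binA, chromB, binB)]
    e <- e[!paste(chromA, binA, chromB, binB) %in% mask_keys]
  }
  if (nrow(e) == 0L)
    return(data.table(chromA = character(), binA = integer(),
                      chromB = character(), binB = integer(),
                      count = integer(), fraction = numeric()))
  e <- e[order(chromA, chromB, binA, binB)]
  e[, comp := 0L]
  comp_id <- 0L
  for (i in seq_len(nrow(e))) {
    if (e$comp[i] != 0L) next
    comp_id <- comp_id + 1L
    queue <- i
    while (length(queue)) {
      k <- queue[1]; queue <- queue[-1]
      if (e$comp[k] != 0L) next
      e[k, comp := comp_id]
      nb <- which(e$comp == 0L & e$chromA == e$chromA[k] &
                    e$chromB == e$chromB[k] &
                    abs(e$binA - e$binA[k]) <= 1L &
                    abs(e$binB - e$binB[k]) <= 1L)
      queue <- c(queue, nb)
    }
  }
  merged <- e[, {
    top <- which.max(count)
    .(chromA = chromA[top], binA = binA[top],
      chromB = chromB[top], binB = binB[top],
      count = sum(count), fraction = max(fraction))
  }, by = comp][, comp := NULL]
  merged[]
}

#' Demote alignment segments made ambiguous by dispersed repeats
#'
#' Emulates repeat-induced mapping ambiguity without running an aligner:
#' any alignment segment lying entirely within a repeat feature that has a
#' same-strand homologous copy elsewhere (same `family`, >= 2 copies) is
#' non-unique and is demoted to a secondary alignment, which later causes
#' [select_split_reads()] to discard the whole read.
#'
#' @param s a [split_read_set()] in reference coordinates.
#' @param reference the reference `GenomeModel` whose `repeat_element`
#'   features define the ambiguous loci.
#' @return the `SplitReadSet` with affected segments reflagged.
#' @export
demote_repeat_segments <- function(s, reference) {
  reps <- reference$features[kind == "repeat_element" & !is.na(family)]
  if (nrow(reps) == 0L) return(s)
  multi <- reps[, .N, by = .(family, strand)][N >= 2L]
  reps <- reps[paste(family, strand) %in% multi[, paste(family, strand)]]
  if (nrow(reps) == 0L) return(s)
  r <- data.table::copy(s$records)
  for (i in seq_len(nrow(reps))) {
    inside <- r$chrom == reps$chrom[i] & r$start >= reps$start[i] &
      r$end <= reps$end[i]
    if (any(inside)) r[inside, flag := "secondary"]
  }
  split_read_set(r, s$genome_length, s$total_read_bases)
}

#' Power of split-read translocation detection at repeat vs genic loci
#'
#' For each breakpoint pair and replicate: simulate the reciprocal
#' translocation, simulate error-free long reads from the rearranged
#' genome, keep reads within the `[min_len, max_len]` length window,
#' demote repeat-ambiguous segments ([demote_repeat_segments()]), then run
#' the select / bin / detect pipeline and score whether the true junction
#' bin pair is recovered (within one bin on each chromosome). Power per
#' breakpoint label is the fraction of detecting replicates.
#'
#' @param reference a `GenomeModel` whose repeat features define mapping
#'   ambiguity.
#' @param breakpoints list of `list(a = interval, b = interval, label =
#'   "repeat"|"genic")` with intervals as in [simulate_translocation()].
#' @param read_cfg a [read_sim_config()].
#' @param n_replicates replicates per breakpoint pair.
#' @param min_len,max_len read-length window (bp) applied before analysis.
#' @param min_reads,min_fraction detection thresholds.
#' @param bin_size contact-matrix bin width.
#' @param seed integer RNG seed.
#' @return data.table: `label`, `power`, `n_replicates`, `n_pairs`.
#' @export
power_experiment <- function(reference, breakpoints, read_cfg,
                             n_replicates = 10L, min_len = 8000,
                             max_len = 20000, min_reads = 3L,
                             min_fraction = 0.15, bin_size = 20000L,
                             seed = NULL) {
  if (!is_count(n_replicates) || n_replicates < 1)
    bt_stop("config", "n_replicates must be a positive integer")
  rows <- list()
  k <- 0L
  for (bp in breakpoints) {
    tr <- simulate_translocation(reference, bp$a, bp$b)
    junc <- tr$junctions[nrow(tr$junctions)]
    true_bins <- data.table(
      chrom = c(junc$chromA, junc$chromB),
      bin = as.integer(c(junc$posA %/% bin_size, junc$posB %/% bin_size)))
    o <- order(true_bins$chrom)
    for (rep_i in seq_len(n_replicates)) {
      k <- k + 1L
      cfg <- read_cfg
      cfg$seed <- if (is.null(seed)) NULL else derive_seed(seed, k)
      sim <- simulate_long_reads(tr, cfg)
      s <- filter_reads_by_length(sim$split, min_len, max_len)
      s <- demote_repeat_segments(s, reference)
      cand <- detect_translocations(contact_matrix(select_split_reads(s),
                                                   bin_size),
                                    min_reads, min_fraction)
      hit <- nrow(cand) > 0L && any(
        cand$chromA == true_bins$chrom[o[1]] &
        cand$chromB == true_bins$chrom[o[2]] &
        abs(cand$binA - true_bins$bin[o[1]]) <= 1L &
        abs(cand$binB - true_bins$bin[o[2]]) <= 1L)
      rows <- c(rows, list(data.table(label = bp$label, hit = hit)))
    }
  }
  res <- rbindlist(rows)
  res[, .(power = mean(hit), n_replicates = .N,
          n_pairs = .N / n_replicates), by = label]
}
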