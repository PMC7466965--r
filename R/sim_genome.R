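#' Reciprocal translocation between two chromosomes
#'
#' Exchanges the chromosome arms distal to an internal cut point of each
#' breakpoint interval (fractional offset `cut`; the default 0.5 places the
#' junction at the interval midpoint, so when the intervals are full-length
#' repeat elements both products carry chimeric but full-length copies).
#' Total genome length is conserved, feature coordinates are remapped
#' (features straddling a cut are split), and a coordinate map from the
#' rearranged genome back to the original reference is maintained, so the
#' operation can be composed and used as an exact alignment oracle.
#'
#' @param genome a `GenomeModel`, or the result of a previous
#'   `simulate_translocation()` call (maps are then composed).
#' @param bpA,bpB breakpoint intervals: lists/rows with `chrom`, `start`,
#'   `end` (0-based half-open) on two different chromosomes.
#' @param cut fractional offset of the junction within each interval.
#' @return list of class `RearrangedGenome`: `genome` (the derived
#'   `GenomeModel`), `map` (data.table mapping derived intervals to
#'   reference intervals) and `junctions` (reference-space cut coordinates).
#' @export
simulate_translocation <- function(genome, bpA, bpB, cut = 0.5) {
  prev_map <- NULL
  prev_junc <- NULL
  if (inherits(genome, "RearrangedGenome")) {
    prev_map <- genome$map
    prev_junc <- genome$junctions
    genome <- genome$genome
  }
  bpA <- as.list(bpA); bpB <- as.list(bpB)
  if (bpA$chrom == bpB$chrom)
    bt_stop("unsupported", "breakpoints must lie on different chromosomes")
  check_scalar(cut, "cut", 0, 1)
  lens <- genome$lengths
  cutA <- round(bpA$start + cut * (bpA$end - bpA$start))
  cutB <- round(bpB$start + cut * (bpB$end - bpB$start))
  chA <- bpA$chrom; chB <- bpB$chrom
  lenA <- lens[[chA]]; lenB <- lens[[chB]]
  if (cutA <= 0 || cutA >= lenA || cutB <= 0 || cutB >= lenB)
    bt_stop("range", "cut point outside chromosome body")

  new_lens <- lens
  new_lens[[chA]] <- cutA + (lenB - cutB)
  new_lens[[chB]] <- cutB + (lenA - cutA)

  # map: derived coordinates -> this genome's coordinates
  step_map <- rbindlist(list(
    data.table(chrom = chA, start = 0, end = cutA, ref_chrom = chA, ref_start = 0),
    data.table(chrom = chA, start = cutA, end = new_lens[[chA]],
               ref_chrom = chB, ref_start = cutB),
    data.table(chrom = chB, start = 0, end = cutB, ref_chrom = chB, ref_start = 0),
    data.table(chrom = chB, start = cutB, end = new_lens[[chB]],
               ref_chrom = chA, ref_start = cutA),
    rbindlist(lapply(setdiff(names(lens), c(chA, chB)), function(ch)
      data.table(chrom = ch, start = 0, end = lens[[ch]],
                 ref_chrom = ch, ref_start = 0)))
  ))

  new_seq <- NULL
  if (!is.null(genome$seq)) {
    new_seq <- genome$seq
    splice <- function(s1, c1, s2, c2, l2)
      Biostrings::xscat(Biostrings::subseq(s1, 1L, c1),
                        Biostrings::subseq(s2, c2 + 1L, l2))
    sA <- genome$seq[[chA]]; sB <- genome$seq[[chB]]
    new_seq[[chA]] <- splice(sA, cutA, sB, cutB, lenB)
    new_seq[[chB]] <- splice(sB, cutB, sA, cutA, lenA)
  }

  new_feats <- remap_features(genome$features, chA, chB, cutA, cutB, new_lens)
  derived <- if (is.null(new_seq)) genome_model(new_lens, new_feats)
             else genome_model(new_seq, new_feats)

  map <- if (is.null(prev_map)) step_map else compose_maps(step_map, prev_map)
  junc <- rbind(prev_junc,
                data.table(chromA = chA, posA = cutA, chromB = chB, posB = cutB))
  structure(list(genome = derived, map = map, junctions = junc),
            class = "RearrangedGenome")
}

remap_features <- function(feats, chA, chB, cutA, cutB, new_lens) {
  if (nrow(feats) == 0L) return(feats)
  pieces <- lapply(seq_len(nrow(feats)), function(i) {
    f <- feats[i]
    if (!f$chrom %in% c(chA, chB)) return(f)
    cutp <- if (f$chrom == chA) cutA else cutB
    src <- f$chrom
    dst <- if (src == chA) chB else chA
    dst_cut <- if (src == chA) cutB else cutA
    parts <- list()
    if (f$start < cutp) {  # proximal part stays
      parts <- c(parts, list(data.table(
        chrom = src, start = f$start, end = min(f$end, cutp),
        strand = f$strand, kind = f$kind,
        id = if (f$end > cutp) paste0(f$id, "_L") else f$id,
        family = f$family)))
    }
    if (f$end > cutp) {    # distal part moves to the partner chromosome
      parts <- c(parts, list(data.table(
        chrom = dst, start = dst_cut + max(f$start, cutp) - cutp,
        end = dst_cut + f$end - cutp,
        strand = f$strand, kind = f$kind,
        id = if (f$start < cutp) paste0(f$id, "_R") else f$id,
        family = f$family)))
    }
    rbindlist(parts)
  })
  rbindlist(pieces)
}

#' Compose two coordinate maps
#'
#' `map_a` maps space 2 -> space 1; `map_b` maps space 1 -> space 0.
#' The result maps space 2 -> space 0.
#' @noRd
compose_maps <- function(map_a, map_b) {
  out <- lapply(seq_len(nrow(map_a)), function(i) {
    seg <- map_a[i]
    pieces <- map_interval(map_b, seg$ref_chrom, seg$ref_start,
                           seg$ref_start + (seg$end - seg$start))
    pieces[, `:=`(chrom = seg$chrom,
                  start = seg$start + (src_start - seg$ref_start),
                  end = seg$start + (src_end - seg$ref_start))]
    pieces[, .(chrom, start, end, ref_chrom, ref_start)]
  })
  m <- rbindlist(out)
  m[order(chrom, start)]
}

#' Map an interval through a coordinate map
#'
#' @param map data.table (`chrom`, `start`, `end`, `ref_chrom`, `ref_start`).
#' @param chrom,start,end query interval in the map's source space.
#' @return data.table with one row per mapped piece: `src_start`, `src_end`
#'   (the query sub-interval) and `ref_chrom`, `ref_start`, `ref_end`.
#' @export
map_interval <- function(map, chrom, start, end) {
  hit <- map$chrom == chrom & map$end > start & map$start < end
  segs <- map[which(hit)]
  if (nrow(segs) == 0L)
    return(data.table(src_start = numeric(), src_end = numeric(),
                      ref_chrom = character(), ref_start = numeric(),
                      ref_end = numeric()))
  s <- pmax(segs$start, start)
  e <- pmin(segs$end, end)
  data.table(src_start = s, src_end = e,
             ref_chrom = segs$ref_chrom,
             ref_start = segs$ref_start + (s - segs$start),
             ref_end = segs$ref_start + (e - segs$start))[order(src_start)]
}

# ---------------------------------------------------------------------------

#' Configuration for the long-read simulator
#'
#' Lengths are Normal(`length_mean`, `length_sd`) truncated to
#' `[min_len, max_len]`; read starts are uniform over the genome. The
#' defaults mirror a CLR-like length profile (mean 3 kb, sd 2.3 kb) at a
#' desk-scale depth.
#'
#' @param depth target fold coverage.
#' @param length_mean,length_sd read length distribution (bp).
#' @param min_len,max_len truncation bounds (bp).
#' @param seed integer RNG seed.
#' @export
read_sim_config <- function(depth = 60, length_mean = 3000, length_sd = 2300,
                            min_len = 100, max_len = 50000, seed = NULL) {
  if (min_len > max_len) bt_stop("config", "min_len must be <= max_len")
  check_scalar(depth, "depth", 1e-9)
  structure(list(depth = depth, length_mean = length_mean,
                 length_sd = length_sd, min_len = min_len,
                 max_len = max_len, seed = seed),
            class = "ReadSimConfig")
}

#' Split-read alignment record container
#'
#' PAF-like tabular records of read alignment segments in reference space,
#' with `primary` / `supplementary` / `secondary` flags.
#'
#' @param records data.frame with columns `read_id`, `read_len`,
#'   `read_start`, `read_end`, `chrom`, `start`, `end`, `strand`, `flag`.
#' @param genome_length total reference length (bp).
#' @param total_read_bases total sequenced bases represented by the set.
#' @export
split_read_set <- function(records, genome_length, total_read_bases) {
  r <- as.data.table(records)
  need <- c("read_id", "read_len", "read_start", "read_end",
            "chrom", "start", "end", "strand", "flag")
  for (col in need)
    if (!col %in% names(r)) bt_stop("format", "records lack column '%s'", col)
  if (nrow(r) && (any(r$read_start < 0) || any(r$read_end > r$read_len)))
    bt_stop("format", "read intervals must lie within [0, read_len)")
  if (nrow(r) && !all(r$flag %in% c("primary", "supplementary", "secondary")))
    bt_stop("format", "unknown alignment flag")
  structure(list(records = r[], genome_length = genome_length,
                 total_read_bases = total_read_bases),
            class = "SplitReadSet")
}

#' @export
print.SplitReadSet <- function(x, ...) {
  cat(sprintf("SplitReadSet: %d records from %d reads (%.1fX over %.0f bp)\n",
              nrow(x$records), length(unique(x$records$read_id)),
              x$total_read_bases / x$genome_length, x$genome_length))
  invisible(x)
}

#' Simulate error-free long reads with exact reference mappings
#'
#' Reads are drawn from the (possibly rearranged) genome until the total
#' base count reaches `depth * genome_length`. Each read's reference-space
#' alignment segments are computed exactly from the rearrangement map: the
#' longest segment is flagged `primary`, the others `supplementary`; no
#' secondary alignments are produced (the simulator is an exact-coordinate
#' oracle, not an error model). Segments shorter than `min_seg` bp are
#' dropped, as a real aligner would not report them.
#'
#' @param genome a `GenomeModel` or `RearrangedGenome`.
#' @param cfg a [read_sim_config()].
#' @param min_seg minimum reported alignment segment length (bp).
#' @return list with `reads` (data.table `read_id`, `chrom`, `start`, `len`
#'   in the sequenced genome's coordinates) and `split` (a
#'   [split_read_set()] in reference coordinates).
#' @export
simulate_long_reads <- function(genome, cfg = read_sim_config(), min_seg = 50) {
  map <- NULL
  if (inherits(genome, "RearrangedGenome")) {
    map <- genome$map
    genome <- genome$genome
  }
  lens <- genome$lengths
  if (length(lens) == 0L || sum(lens) == 0) bt_stop("empty", "empty genome")
  if (is.null(map)) {
    map <- rbindlist(lapply(names(lens), function(ch)
      data.table(chrom = ch, start = 0, end = lens[[ch]],
                 ref_chrom = ch, ref_start = 0)))
  }
  G <- sum(lens)
  target <- cfg$depth * G
  with_seed(cfg$seed, {
    draw <- function(n) {
      len <- pmin(pmax(round(rnorm(n, cfg$length_mean, cfg$length_sd)),
                       cfg$min_len), cfg$max_len)
      ch <- sample(names(lens), n, replace = TRUE, prob = lens)
      len <- pmin(len, lens[ch])
      start <- floor(runif(n) * (lens[ch] - len + 1))
      data.table(chrom = ch, start = start, len = len)
    }
    mean_len <- min(max(cfg$length_mean, cfg$min_len), cfg$max_len)
    reads <- draw(ceiling(target / mean_len * 1.3) + 10)
    while (sum(reads$len) < target) reads <- rbind(reads, draw(1000))
    k <- which(cumsum(reads$len) >= target)[1]
    reads <- reads[seq_len(k)]
    reads[, read_id := sprintf("read%07d", .I)]

    # Vectorized fast path: reads contained in a single map segment.
    m <- map[order(chrom, start)]
    seg_of <- function(ch, p) {
      idx <- integer(length(p))
      for (cc in unique(ch)) {
        rows <- which(m$chrom == cc)
        sel <- ch == cc
        idx[sel] <- rows[findInterval(p[sel], m$start[rows])]
      }
      idx
    }
    i1 <- seg_of(reads$chrom, reads$start)
    i2 <- seg_of(reads$chrom, reads$start + reads$len - 1)
    simple <- i1 == i2
    recs_simple <- if (any(simple)) {
      rs <- reads[simple]
      seg <- i1[simple]
      data.table(read_id = rs$read_id, read_len = rs$len,
                 read_start = 0, read_end = as.numeric(rs$len),
                 chrom = m$ref_chrom[seg],
                 start = m$ref_start[seg] + (rs$start - m$start[seg]),
                 end = m$ref_start[seg] + (rs$start - m$start[seg]) + rs$len,
                 strand = "+", flag = "primary")
    } else NULL
    recs_split <- lapply(which(!simple), function(i) {
      r <- reads[i]
      pieces <- map_interval(m, r$chrom, r$start, r$start + r$len)
      pieces <- pieces[src_end - src_start >= min_seg]
      if (nrow(pieces) == 0L) return(NULL)
      seg_len <- pieces$src_end - pieces$src_start
      flag <- rep("supplementary", nrow(pieces))
      flag[which.max(seg_len)] <- "primary"
      data.table(read_id = r$read_id, read_len = r$len,
                 read_start = pieces$src_start - r$start,
                 read_end = pieces$src_end - r$start,
                 chrom = pieces$ref_chrom, start = pieces$ref_start,
                 end = pieces$ref_end, strand = "+", flag = flag)
    })
    split <- split_read_set(rbindlist(c(list(recs_simple), recs_split)),
                            genome_length = G,
                            total_read_bases = sum(reads$len))
    list(reads = reads[], split = split)
  })
}

#' Filter a split-read set by read length
#'
#' Mirrors the read-length window applied before structural-variant calling
#' (8-20 kb by convention).
#' @param s a [split_read_set()].
#' @param min_len,max_len inclusive read length bounds (bp).
#' @return a filtered `SplitReadSet` with `total_read_bases` recomputed from
#'   the retained reads.
#' @export
filter_reads_by_length <- function(s, min_len = 8000, max_len = 20000) {
  r <- s$records[read_len >= min_len & read_len <= max_len]
  per_read <- unique(r[, .(read_id, read_len)])
  split_read_set(r, s$genome_length, sum(per_read$read_len))
}

#' Read / write PAF-like alignment segment tables
#'
#' Columns: read_id, read_len, read_start, read_end, chrom, start, end,
#' strand, flag.
#' @param s a [split_read_set()].
#' @param path file path.
#' @export
write_split_reads <- function(s, path) {
  hdr <- sprintf("#genome_length=%.0f total_read_bases=%.0f",
                 s$genome_length, s$total_read_bases)
  writeLines(hdr, path)
  fwrite(s$records, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' @rdname write_split_reads
#' @param genome_length,total_read_bases overrides when the file carries no
#'   header line.
#' @export
read_split_reads <- function(path, genome_length = NULL,
                             total_read_bases = NULL) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#")) {
    vals <- regmatches(first, gregexpr("[0-9.]+", first))[[1]]
    genome_length <- genome_length %||% as.numeric(vals[1])
    total_read_bases <- total_read_bases %||% as.numeric(vals[2])
  }
  r <- fread(path, header = FALSE, sep = "\t", skip = if (startsWith(first, "#")) 1L else 0L,
             col.names = c("read_id", "read_len", "read_start", "read_end",
                           "chrom", "start", "end", "strand", "flag"))
  if (is.null(genome_length) || is.null(total_read_bases))
    bt_stop("format", "genome_length/total_read_bases missing")
  split_read_set(r, genome_length, total_read_bases)
}
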