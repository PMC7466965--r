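#' Genome model: chromosomes plus annotated features
#'
#' A light container for a (possibly sequence-free) genome. Chromosomes are
#' an ordered set of names with lengths, optionally carrying sequence.
#' Features are intervals in 0-based half-open coordinates with a `kind`
#' (`gene`, `repeat_element` or `cds`), an `id`, and an optional `family`
#' used to group dispersed repeat copies (e.g. Ty retrotransposon families).
#'
#' @param chromosomes either a named numeric vector of chromosome lengths
#'   (bp), a named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param features optional data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`), `kind`, `id` and optionally
#'   `family`.
#' @return an object of class `GenomeModel` with elements `lengths`
#'   (named numeric), `seq` (`DNAStringSet` or `NULL`) and `features`
#'   (data.table).
#' @export
genome_model <- function(chromosomes, features = NULL) {
  if (inherits(chromosomes, "DNAStringSet")) {
    seqs <- chromosomes
    lens <- stats::setNames(as.numeric(Biostrings::width(seqs)), names(seqs))
  } else if (is.character(chromosomes)) {
    if (is.null(names(chromosomes)))
      bt_stop("format", "chromosome sequences must be named")
    seqs <- Biostrings::DNAStringSet(chromosomes)
    lens <- stats::setNames(as.numeric(nchar(chromosomes)), names(chromosomes))
  } else if (is.numeric(chromosomes)) {
    if (is.null(names(chromosomes)))
      bt_stop("format", "chromosome lengths must be named")
    seqs <- NULL
    lens <- chromosomes
  } else {
    bt_stop("format", "unsupported 'chromosomes' type")
  }
  if (any(lens <= 0)) bt_stop("format", "chromosome lengths must be positive")

  feats <- normalize_features(features, lens)
  structure(list(lengths = lens, seq = seqs, features = feats),
            class = "GenomeModel")
}

normalize_features <- function(features, lens) {
  if (is.null(features) || nrow(features) == 0L) {
    return(data.table(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), kind = character(), id = character(),
                      family = character()))
  }
  f <- as.data.table(features)
  for (col in c("chrom", "start", "end")) {
    if (!col %in% names(f)) bt_stop("format", "features lack column '%s'", col)
  }
  if (!"strand" %in% names(f)) f[, strand := "+"]
  if (!"kind" %in% names(f)) f[, kind := "gene"]
  if (!"id" %in% names(f)) f[, id := sprintf("feat%05d", seq_len(nrow(f)))]
  if (!"family" %in% names(f)) f[, family := NA_character_]
  f <- f[, .(chrom = as.character(chrom), start = as.numeric(start),
             end = as.numeric(end), strand = as.character(strand),
             kind = as.character(kind), id = as.character(id),
             family = as.character(family))]
  if (any(!f$chrom %in% names(lens)))
    bt_stop("format", "feature chromosome not in genome: %s",
            paste(unique(setdiff(f$chrom, names(lens))), collapse = ", "))
  if (any(f$start < 0) || any(f$start >= f$end))
    bt_stop("format", "feature intervals must satisfy 0 <= start < end")
  if (any(f$end > lens[f$chrom]))
    bt_stop("format", "feature interval exceeds chromosome length")
  f[]
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat(sprintf("GenomeModel: %d chromosomes, %.0f bp total, %d features%s\n",
              length(x$lengths), sum(x$lengths), nrow(x$features),
              if (is.null(x$seq)) " (lengths only)" else " (with sequence)"))
  invisible(x)
}

#' Chromosome lengths of a GenomeModel
#' @param genome a [genome_model()] object.
#' @return named numeric vector of lengths in bp.
#' @export
chrom_lengths <- function(genome) genome$lengths

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @param features optional feature table as in [genome_model()].
#' @return a `GenomeModel` carrying sequence.
#' @export
read_genome_fasta <- function(path, features = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_model(seqs, features)
}

#' Write a GenomeModel's sequence to FASTA
#' @param genome a `GenomeModel` with sequence.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$seq)) bt_stop("format", "genome carries no sequence")
  Biostrings::writeXStringSet(genome$seq, path)
  invisible(path)
}

#' Read a BED-like interval file
#'
#' BED is 0-based half-open, which matches the package's internal convention,
#' so coordinates pass through untouched. Columns beyond the sixth are
#' ignored.
#'
#' @param path BED3-BED6 file (tab-separated, no header).
#' @return data.table with columns `chrom`, `start`, `end`, `label`, `value`,
#'   `strand` (an "IntervalSet").
#' @export
read_bed <- function(path) {
  x <- fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(x) < 3L) bt_stop("format", "BED file needs at least 3 columns")
  out <- data.table(
    chrom = as.character(x[[1]]), start = as.numeric(x[[2]]),
    end = as.numeric(x[[3]]),
    label = if (ncol(x) >= 4L) as.character(x[[4]]) else NA_character_,
    value = if (ncol(x) >= 5L) suppressWarnings(as.numeric(x[[5]])) else NA_real_,
    strand = if (ncol(x) >= 6L) as.character(x[[6]]) else "+"
  )
  if (any(out$start < 0) || any(out$start >= out$end))
    bt_stop("format", "BED intervals must satisfy 0 <= start < end")
  out[]
}

#' Write intervals as BED6
#' @param intervals data.table as returned by [read_bed()].
#' @param path output file.
#' @export
write_bed <- function(intervals, path) {
  x <- as.data.table(intervals)
  out <- data.table(
    chrom = x$chrom, start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    label = if ("label" %in% names(x)) ifelse(is.na(x$label), ".", x$label) else ".",
    value = if ("value" %in% names(x)) ifelse(is.na(x$value), ".", as.character(x$value)) else ".",
    strand = if ("strand" %in% names(x)) x$strand else "+"
  )
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Concatenate coding sequences into a single coordinate system
#'
#' Builds the coordinate frame used for popgen statistics on coding sites:
#' single-interval, pairwise non-overlapping CDS features are laid end to end
#' in genomic order, with minus-strand features read reverse-complemented.
#' The returned map is invertible.
#'
#' @param genome a `GenomeModel`.
#' @param features data.frame of CDS intervals (`chrom`, `start`, `end`,
#'   optional `strand`, `id`).
#' @return object of class `ConcatCDS` with the per-CDS offset table and
#'   total length. Use [concat_to_genome()] / [genome_to_concat()] to map
#'   coordinates and [concat_sequence()] to extract the spliced sequence.
#' @export
concatenate_cds <- function(genome, features) {
  f <- normalize_features(features, genome$lengths)
  if (nrow(f) == 0L) bt_stop("format", "no CDS features supplied")
  chrom_rank <- stats::setNames(seq_along(genome$lengths), names(genome$lengths))
  f <- f[order(chrom_rank[chrom], start)]
  # overlap check within chromosomes
  bad <- f[, {
    n <- .N
    if (n > 1L && any(start[-1] < end[-n])) .(offender = id[c(which(start[-1] < end[-n]) + 1L)])
    else .(offender = character(0))
  }, by = chrom]
  if (nrow(bad) > 0L)
    bt_stop("overlap", "overlapping CDS records: %s",
            paste(bad$offender, collapse = ", "))
  f[, len := end - start]
  f[, concat_end := cumsum(len)]
  f[, concat_start := concat_end - len]
  structure(list(map = f[], total_length = sum(f$len)), class = "ConcatCDS")
}

#' @export
print.ConcatCDS <- function(x, ...) {
  cat(sprintf("ConcatCDS: %d CDS, %.0f bp concatenated\n",
              nrow(x$map), x$total_length))
  invisible(x)
}

#' Map concatenated coordinates back to the genome
#' @param ccds a [concatenate_cds()] object.
#' @param pos 0-based positions in the concatenation.
#' @return data.table with `chrom`, `pos` (0-based genome position) and
#'   `strand` of the source CDS.
#' @export
concat_to_genome <- function(ccds, pos) {
  m <- ccds$map
  if (any(pos < 0 | pos >= ccds$total_length))
    bt_stop("range", "position outside concatenation")
  idx <- findInterval(pos, m$concat_start)
  off <- pos - m$concat_start[idx]
  gpos <- ifelse(m$strand[idx] == "-", m$end[idx] - 1 - off, m$start[idx] + off)
  data.table(chrom = m$chrom[idx], pos = gpos, strand = m$strand[idx])
}

#' Map genome coordinates into the concatenation
#' @param ccds a [concatenate_cds()] object.
#' @param chrom,pos genome coordinates (0-based).
#' @return numeric vector of concatenated positions; `NA` where the position
#'   falls in no CDS.
#' @export
genome_to_concat <- function(ccds, chrom, pos) {
  m <- ccds$map
  out <- rep(NA_real_, length(pos))
  for (i in seq_len(nrow(m))) {
    hit <- chrom == m$chrom[i] & pos >= m$start[i] & pos < m$end[i]
    if (!any(hit)) next
    out[hit] <- if (m$strand[i] == "-") {
      m$concat_start[i] + (m$end[i] - 1 - pos[hit])
    } else {
      m$concat_start[i] + (pos[hit] - m$start[i])
    }
  }
  out
}

#' Extract the spliced, strand-corrected concatenated sequence
#' @param genome a `GenomeModel` with sequence.
#' @param ccds a [concatenate_cds()] object.
#' @return a single [Biostrings::DNAString] of the concatenation.
#' @export
concat_sequence <- function(genome, ccds) {
  if (is.null(genome$seq)) bt_stop("format", "genome carries no sequence")
  m <- ccds$map
  parts <- lapply(seq_len(nrow(m)), function(i) {
    s <- Biostrings::subseq(genome$seq[[m$chrom[i]]], m$start[i] + 1L, m$end[i])
    if (m$strand[i] == "-") Biostrings::reverseComplement(s) else s
  })
  Reduce(Biostrings::xscat, parts)
}
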