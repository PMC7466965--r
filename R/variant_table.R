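#' Polyploid variant table
#'
#' Sites-by-strains genotype container. Genotypes are stored as canonical
#' sorted allele-index strings (`"0/0/1/1"`); `NA` marks a missing genotype.
#' Each strain has a fixed ploidy and every non-missing genotype must carry
#' exactly that many alleles. Coordinates are 0-based internally and
#' converted at the VCF boundary.
#'
#' @param sites data.frame with `chrom`, `pos` (0-based), `ref`, `alt`
#'   (comma-separated alternate alleles).
#' @param gt character matrix (sites x strains) of `/`-separated allele
#'   indices; `NA` = missing. Unsorted genotypes are canonicalized.
#' @param ploidy named integer vector (one entry per strain). If omitted it
#'   is inferred from genotype arity.
#' @param site_ann optional data.frame of per-site annotations (e.g. `QD`,
#'   `MQ`, `SYN`).
#' @param gq,dp optional numeric matrices of per-genotype quality and depth.
#' @return an object of class `VariantTable`.
#' @export
variant_table <- function(sites, gt, ploidy = NULL, site_ann = NULL,
                          gq = NULL, dp = NULL) {
  sites <- as.data.table(sites)
  for (col in c("chrom", "pos", "ref", "alt"))
    if (!col %in% names(sites)) bt_stop("format", "sites lack column '%s'", col)
  gt <- as.matrix(gt)
  if (nrow(gt) != nrow(sites))
    bt_stop("format", "gt rows (%d) != sites (%d)", nrow(gt), nrow(sites))
  if (is.null(colnames(gt)))
    bt_stop("format", "gt matrix must have strain names as colnames")
  strains <- colnames(gt)

  gt <- apply(gt, 2, canonical_gt)
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = nrow(sites),
                                   dimnames = list(NULL, strains))

  arity <- gt_arity(gt)
  inferred <- infer_ploidy(arity, strains, sites)
  if (is.null(ploidy)) {
    ploidy <- inferred
  } else {
    ploidy <- ploidy[strains]
    bad <- !is.na(inferred) & inferred != ploidy
    if (any(bad))
      bt_stop("ploidy", "declared ploidy conflicts with genotype arity for %s",
              paste(strains[bad], collapse = ", "))
  }
  if (any(is.na(ploidy)))
    bt_stop("ploidy", "cannot infer ploidy for strain(s) with no genotypes: %s",
            paste(strains[is.na(ploidy)], collapse = ", "))

  alts <- strsplit(as.character(sites$alt), ",", fixed = TRUE)
  sites[, multiallelic := lengths(alts) > 1L]
  sites[, is_snp := nchar(ref) == 1L &
          vapply(alts, function(a) all(nchar(a) == 1L), logical(1))]

  structure(list(
    sites = sites[], gt = gt,
    ploidy = stats::setNames(as.integer(ploidy), strains),
    site_ann = if (!is.null(site_ann)) as.data.table(site_ann) else NULL,
    gq = gq, dp = dp
  ), class = "VariantTable")
}

canonical_gt <- function(g) {
  out <- rep(NA_character_, length(g))
  ok <- !is.na(g) & !grepl(".", g, fixed = TRUE)
  if (any(ok)) {
    parts <- strsplit(g[ok], "[/|]")
    out[ok] <- vapply(parts, function(a)
      paste(sort(as.integer(a)), collapse = "/"), character(1))
  }
  out
}

gt_arity <- function(gt) {
  a <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- !is.na(gt)
  a[ok] <- lengths(strsplit(gt[ok], "/", fixed = TRUE))
  a
}

infer_ploidy <- function(arity, strains, sites) {
  vapply(seq_along(strains), function(j) {
    u <- unique(arity[!is.na(arity[, j]), j])
    if (length(u) == 0L) return(NA_integer_)
    if (length(u) > 1L) {
      i <- which(arity[, j] == u[2])[1]
      bt_stop("ploidy",
              "inconsistent genotype arity for strain '%s' (site %s:%d): %s",
              strains[j], sites$chrom[i], as.integer(sites$pos[i]),
              paste(u, collapse = " vs "))
    }
    as.integer(u)
  }, integer(1))
}

#' @export
print.VariantTable <- function(x, ...) {
  cat(sprintf("VariantTable: %d sites x %d strains (ploidy %s)\n",
              nrow(x$sites), length(x$ploidy),
              paste(sprintf("%s=%d", names(x$ploidy), x$ploidy), collapse = ", ")))
  invisible(x)
}

#' Strain names of a VariantTable
#' @param vt a `VariantTable`.
#' @export
vt_strains <- function(vt) names(vt$ploidy)

#' Alternate-allele dosage matrix
#'
#' Counts non-reference alleles per genotype (any alternate allele index).
#' @param vt a `VariantTable`.
#' @return integer matrix sites x strains, `NA` where missing.
#' @export
alt_dosage <- function(vt) {
  d <- matrix(NA_integer_, nrow(vt$gt), ncol(vt$gt), dimnames = dimnames(vt$gt))
  ok <- !is.na(vt$gt)
  d[ok] <- vapply(strsplit(vt$gt[ok], "/", fixed = TRUE),
                  function(a) sum(a != "0"), integer(1))
  d
}

#' Collapse polyploid genotypes to diploid-like classes
#'
#' Class 0 = homozygous reference, 1 = heterozygous (any mixed genotype),
#' 2 = homozygous alternate. Used by the KING kinship estimator.
#' @param vt a `VariantTable`.
#' @return integer matrix sites x strains with values 0/1/2 and `NA`.
#' @export
genotype_classes <- function(vt) {
  d <- alt_dosage(vt)
  p <- matrix(rep(vt$ploidy, each = nrow(d)), nrow(d))
  cls <- ifelse(d == 0L, 0L, ifelse(d == p, 2L, 1L))
  cls
}

# ---------------------------------------------------------------------------
# VCF I/O (VariantAnnotation does the parsing; we convert at the boundary)

VCF_INFO_NUMERIC <- c("QD", "MQ", "MQRankSum", "ReadPosRankSum", "FS", "SOR")
VCF_INFO_FLAGS <- c("SYN")

#' Read a VCF into a VariantTable
#'
#' Ploidy is inferred per strain from genotype arity; mixed arity within a
#' strain is an error. Multiallelic sites and indels are retained but
#' flagged (`multiallelic`, `is_snp`) so downstream statistics can exclude
#' them. Recognized INFO annotations (`QD`, `MQ`, `MQRankSum`,
#' `ReadPosRankSum`, `FS`, `SOR`, flag `SYN`) and FORMAT fields `GQ`/`RGQ`
#' and `DP` are carried along.
#'
#' @param path a VCF 4.x file (plain text or gzipped).
#' @return a [variant_table()].
#' @export
read_variant_table <- function(path) {
  v <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) bt_stop("format", "malformed VCF '%s': %s",
                                path, conditionMessage(e))
  )
  g <- VariantAnnotation::geno(v)
  if (!"GT" %in% names(g)) bt_stop("format", "VCF lacks GT field")
  gt <- g$GT
  gt[gt %in% c(".", "")] <- NA_character_

  rr <- SummarizedExperiment::rowRanges(v)
  alts <- VariantAnnotation::alt(v)
  alt_chr <- vapply(as.list(alts), function(a) paste(as.character(a), collapse = ","),
                    character(1))
  sites <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr) - 1,
    ref = as.character(VariantAnnotation::ref(v)),
    alt = alt_chr
  )

  info <- VariantAnnotation::info(v)
  ann <- NULL
  keep <- intersect(c(VCF_INFO_NUMERIC, VCF_INFO_FLAGS), colnames(info))
  if (length(keep) > 0L) {
    ann <- as.data.table(lapply(keep, function(k) {
      x <- info[[k]]
      if (is.list(x)) x <- vapply(x, function(e) if (length(e)) e[[1]] else NA_real_, numeric(1))
      x
    }))
    data.table::setnames(ann, keep)
  }

  gq <- NULL
  if ("GQ" %in% names(g)) gq <- suppressWarnings(matrix(as.numeric(g$GQ), nrow(gt), dimnames = dimnames(gt)))
  if ("RGQ" %in% names(g)) {
    rgq <- suppressWarnings(matrix(as.numeric(g$RGQ), nrow(gt), dimnames = dimnames(gt)))
    gq <- if (is.null(gq)) rgq else ifelse(is.na(gq), rgq, gq)
  }
  dp <- if ("DP" %in% names(g))
    suppressWarnings(matrix(as.numeric(g$DP), nrow(gt), dimnames = dimnames(gt))) else NULL

  variant_table(sites, gt, site_ann = ann, gq = gq, dp = dp)
}

#' Write a VariantTable as VCF 4.2
#' @param vt a `VariantTable`.
#' @param path output file.
#' @export
write_variant_table <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (ch in unique(vt$sites$chrom)) {
    len <- max(vt$sites$pos[vt$sites$chrom == ch]) + 1000
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch, as.integer(len)), con)
  }
  ann <- vt$site_ann
  if (!is.null(ann)) {
    for (k in intersect(VCF_INFO_NUMERIC, names(ann)))
      writeLines(sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", k, k), con)
    for (k in intersect(VCF_INFO_FLAGS, names(ann)))
      writeLines(sprintf("##INFO=<ID=%s,Number=0,Type=Flag,Description=\"%s\">", k, k), con)
  }
  writeLines(c(
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Float,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Float,Description=\"Read depth\">"), con)
  strains <- vt_strains(vt)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", strains), collapse = "\t"), con)

  info_str <- rep(".", nrow(vt$sites))
  if (!is.null(ann)) {
    parts <- lapply(names(ann), function(k) {
      x <- ann[[k]]
      if (is.logical(x)) ifelse(!is.na(x) & x, k, NA_character_)
      else ifelse(is.na(x), NA_character_, sprintf("%s=%g", k, x))
    })
    info_str <- apply(do.call(cbind, parts), 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r)) paste(r, collapse = ";") else "."
    })
  }
  fmt_geno <- function(j) {
    g <- vt$gt[, j]
    miss <- paste(rep(".", vt$ploidy[j]), collapse = "/")
    g[is.na(g)] <- miss
    gq <- if (!is.null(vt$gq)) ifelse(is.na(vt$gq[, j]), ".", sprintf("%g", vt$gq[, j])) else "."
    dp <- if (!is.null(vt$dp)) ifelse(is.na(vt$dp[, j]), ".", sprintf("%g", vt$dp[, j])) else "."
    paste(g, gq, dp, sep = ":")
  }
  geno_cols <- vapply(seq_along(strains), fmt_geno,
                      character(nrow(vt$sites)))
  if (!is.matrix(geno_cols)) geno_cols <- matrix(geno_cols, nrow = nrow(vt$sites))
  body <- cbind(vt$sites$chrom, as.integer(vt$sites$pos) + 1L, ".",
                vt$sites$ref, vt$sites$alt, ".", ".", info_str, "GT:GQ:DP",
                geno_cols)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Project genotypes of one strain onto the reference sequence
#'
#' Produces one sequence per haplotype copy: the reference with alternate
#' alleles substituted at called SNP sites. Unphased genotypes are assigned
#' to haplotype copies in sorted-allele order (all downstream statistics are
#' allele-count based, so phase is irrelevant). Missing genotypes, and any
#' positions listed in `mask_pos`, become the ambiguity base `N` in every
#' haplotype. Sites whose alleles exceed 1 bp are excluded with a warning.
#'
#' @param reference a `GenomeModel` with sequence.
#' @param vt a `VariantTable`.
#' @param strain strain name.
#' @param mask_pos optional data.frame (`chrom`, `pos`, 0-based) of
#'   positions to force to `N` (e.g. filter failures).
#' @return list of `p` [Biostrings::DNAStringSet] objects (one per haplotype
#'   copy, each named by chromosome).
#' @export
project_genotypes <- function(reference, vt, strain, mask_pos = NULL) {
  if (is.null(reference$seq)) bt_stop("format", "reference carries no sequence")
  if (!strain %in% vt_strains(vt)) bt_stop("format", "unknown strain '%s'", strain)
  p <- vt$ploidy[[strain]]
  if (!p %in% c(2L, 4L))
    bt_warn("projection intended for ploidy 2 or 4 (got %d)", p)

  sites <- vt$sites
  gts <- vt$gt[, strain]
  allele_tab <- strsplit(paste(sites$ref, sites$alt, sep = ","), ",", fixed = TRUE)
  too_long <- vapply(allele_tab, function(a) any(nchar(a) != 1L), logical(1))
  if (any(too_long))
    bt_warn("excluding %d non-SNP site(s) from projection", sum(too_long))

  haps <- vector("list", p)
  for (h in seq_len(p)) haps[[h]] <- Biostrings::DNAStringSet(reference$seq)

  for (ch in unique(sites$chrom)) {
    sel <- which(sites$chrom == ch & !too_long)
    if (length(sel) == 0L) next
    pos1 <- sites$pos[sel] + 1L  # 1-based for Biostrings
    gt_here <- gts[sel]
    miss <- is.na(gt_here)
    if (!is.null(mask_pos)) {
      mp <- as.data.table(mask_pos)
      miss <- miss | (sites$pos[sel] %in% mp$pos[mp$chrom == ch])
    }
    alleles <- vector("list", length(sel))
    alleles[!miss] <- strsplit(gt_here[!miss], "/", fixed = TRUE)
    for (h in seq_len(p)) {
      idx <- rep(NA_integer_, length(sel))
      idx[!miss] <- vapply(alleles[!miss], function(a) as.integer(a[h]),
                           integer(1))
      # reference-allele copies keep the reference base untouched
      change <- miss | (!is.na(idx) & idx > 0L)
      if (!any(change)) next
      base <- ifelse(miss[change], "N",
                     mapply(function(tab, i) tab[i + 1L],
                            allele_tab[sel][change], idx[change]))
      haps[[h]][[ch]] <- Biostrings::replaceLetterAt(
        haps[[h]][[ch]], pos1[change], paste(base, collapse = ""))
    }
  }
  names(haps) <- paste0(strain, "_hap", seq_len(p))
  haps
}
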