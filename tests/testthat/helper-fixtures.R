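# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write into tempdir().

#' Write a small VCF and return its path
write_test_vcf <- function(records, strains = c("s1", "s2"),
                           info_fields = c("QD", "MQ", "SYN"),
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrI,length=100000>",
    "##contig=<ID=chrII,length=100000>",
    if ("QD" %in% info_fields) "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
    if ("MQ" %in% info_fields) "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"m\">",
    if ("SYN" %in% info_fields) "##INFO=<ID=SYN,Number=0,Type=Flag,Description=\"s\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", strains), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_rec <- function(chrom, pos1, ref, alt, info, ...) {
  paste(c(chrom, pos1, ".", ref, alt, "100", ".", info, "GT:GQ:DP", ...),
        collapse = "\t")
}

#' Build a VariantTable directly from a dosage matrix (biallelic SNPs)
vt_from_dosage <- function(dosage, ploidy, chrom = "chrI",
                           pos = seq_len(nrow(dosage)) * 10, syn = NULL) {
  gt_of <- function(d, p) {
    ifelse(is.na(d), NA_character_,
           vapply(d, function(x)
             paste(c(rep("0", p - x), rep("1", x)), collapse = "/"), ""))
  }
  gt <- vapply(seq_len(ncol(dosage)),
               function(j) gt_of(dosage[, j], ploidy[j]),
               character(nrow(dosage)))
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = nrow(dosage))
  colnames(gt) <- colnames(dosage)
  variant_table(
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T"),
    gt, ploidy = stats::setNames(ploidy, colnames(dosage)),
    site_ann = if (!is.null(syn)) data.frame(SYN = syn) else NULL)
}

#' Toy four-chromosome reference with a two-copy same-strand repeat family
toy_reference <- function() {
  feats <- data.frame(
    chrom = c("chrI", "chrII"), start = c(100000, 150000),
    end = c(106000, 156000), strand = "+", kind = "repeat_element",
    id = c("TY1_A", "TY1_B"), family = "Ty1")
  genome_model(c(chrI = 3e5, chrII = 3e5, chrIII = 3e5, chrIV = 3e5), feats)
}

repeat_breakpoint <- function()
  list(a = list(chrom = "chrI", start = 100000, end = 106000),
       b = list(chrom = "chrII", start = 150000, end = 156000),
       label = "repeat")

genic_breakpoint <- function()
  list(a = list(chrom = "chrIII", start = 200000, end = 201500),
       b = list(chrom = "chrIV", start = 80000, end = 81500),
       label = "genic")

#' Mean silhouette of a 2-group labelling on euclidean coordinates
mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- mean(d[i, labels != labels[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

#' Exhaustive minimum-evolution oracle: best topology over all unrooted
#' trees by OLS branch lengths (independent of the neighbor-joining path)
min_evolution_tree <- function(d) {
  labs <- rownames(d)
  topos <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  best <- NULL; best_len <- Inf
  for (i in seq_along(topos)) {
    tr <- topos[[i]]  # [[ dispatch restores compressed tip labels
    X <- as.matrix(phangorn::designTree(tr))
    # design rows follow dist order over the tree's own tip ordering
    dv <- as.vector(stats::as.dist(d[tr$tip.label, tr$tip.label]))
    b <- tryCatch(solve(crossprod(X), crossprod(X, dv)),
                  error = function(e) NULL)
    if (is.null(b)) next
    len <- sum(b)
    if (len < best_len) { best_len <- len; best <- tr }
  }
  best
}
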