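#' Genotype filtering policy
#'
#' Hard site filters on variant-caller annotations plus per-genotype
#' quality/depth masking, in the GATK hard-filtering idiom: sites with
#' `QD < qd_min`, `MQ < mq_min`, `MQRankSum < mqranksum_min`,
#' `FS > fs_max`, `SOR > sor_max` or `ReadPosRankSum < readpos_min` are
#' removed; genotypes with quality below `gq_min` phred or depth below
#' `dp_min` reads are masked; finally sites with more than
#' `max_missing_fraction` missing genotypes, indels and multiallelic sites
#' are removed. `drop_fs_sor` waives the strand filters (FisherStrand,
#' StrandOddsRatio), which are unstable with single-read support. A
#' threshold set to `NA` waives its filter.
#'
#' @param qd_min,mq_min,mqranksum_min,fs_max,sor_max,readpos_min site-level
#'   thresholds.
#' @param gq_min,dp_min genotype-level thresholds (phred / reads).
#' @param max_missing_fraction maximum tolerated per-site missing fraction.
#' @param drop_fs_sor waive the FS and SOR filters.
#' @export
filter_policy <- function(qd_min = 2, mq_min = 40, mqranksum_min = -12.5,
                          fs_max = 60, sor_max = 3, readpos_min = -8.0,
                          gq_min = 20, dp_min = 10,
                          max_missing_fraction = 0.10, drop_fs_sor = FALSE) {
  check_scalar(max_missing_fraction, "max_missing_fraction", 0, 1)
  structure(list(qd_min = qd_min, mq_min = mq_min,
                 mqranksum_min = mqranksum_min, fs_max = fs_max,
                 sor_max = sor_max, readpos_min = readpos_min,
                 gq_min = gq_min, dp_min = dp_min,
                 max_missing_fraction = max_missing_fraction,
                 drop_fs_sor = drop_fs_sor),
            class = "FilterPolicy")
}

#' Apply a filtering policy to a variant table
#'
#' @param vt a [variant_table()].
#' @param policy a [filter_policy()].
#' @return the filtered `VariantTable` (sites removed, genotypes masked).
#' @export
filter_genotypes <- function(vt, policy = filter_policy()) {
  stopifnot(inherits(policy, "FilterPolicy"))
  ann <- vt$site_ann
  n <- nrow(vt$sites)
  keep <- rep(TRUE, n)

  site_rules <- list(
    list(col = "QD", thr = policy$qd_min, dir = "lt"),
    list(col = "MQ", thr = policy$mq_min, dir = "lt"),
    list(col = "MQRankSum", thr = policy$mqranksum_min, dir = "lt"),
    list(col = "ReadPosRankSum", thr = policy$readpos_min, dir = "lt"),
    list(col = "FS", thr = policy$fs_max, dir = "gt", strand = TRUE),
    list(col = "SOR", thr = policy$sor_max, dir = "gt", strand = TRUE)
  )
  for (rule in site_rules) {
    if (isTRUE(rule$strand) && policy$drop_fs_sor) next
    if (is.na(rule$thr)) next
    if (is.null(ann) || !rule$col %in% names(ann)) {
      if (isTRUE(rule$strand))
        bt_stop("config",
                "annotation '%s' absent; set drop_fs_sor = TRUE to waive",
                rule$col)
      bt_stop("config", "annotation '%s' absent and filter not waived (NA)",
              rule$col)
    }
    x <- ann[[rule$col]]
    fail <- if (rule$dir == "lt") x < rule$thr else x > rule$thr
    fail[is.na(fail)] <- FALSE  # unannotated sites pass, GATK-style
    keep <- keep & !fail
  }

  gt <- vt$gt
  if (!is.na(policy$gq_min) || !is.na(policy$dp_min)) {
    if (is.null(vt$gq) && is.null(vt$dp)) {
      bt_warn("no GQ/DP annotations; genotype masking skipped")
    } else {
      mask <- matrix(FALSE, nrow(gt), ncol(gt))
      if (!is.null(vt$gq) && !is.na(policy$gq_min))
        mask <- mask | (!is.na(vt$gq) & vt$gq < policy$gq_min)
      if (!is.null(vt$dp) && !is.na(policy$dp_min))
        mask <- mask | (!is.na(vt$dp) & vt$dp < policy$dp_min)
      gt[mask] <- NA_character_
    }
  }

  miss_frac <- rowMeans(is.na(gt))
  keep <- keep & miss_frac <= policy$max_missing_fraction
  keep <- keep & vt$sites$is_snp & !vt$sites$multiallelic

  variant_table(vt$sites[keep, .(chrom, pos, ref, alt)],
                gt[keep, , drop = FALSE], ploidy = vt$ploidy,
                site_ann = if (!is.null(ann)) ann[keep] else NULL,
                gq = if (!is.null(vt$gq)) vt$gq[keep, , drop = FALSE] else NULL,
                dp = if (!is.null(vt$dp)) vt$dp[keep, , drop = FALSE] else NULL)
}

#' Identity-by-state matrix
#'
#' Per strain pair, the mean over shared non-missing sites of
#' `1 - |x_i - x_j| / 2`, where `x` is the alternate-allele dosage rescaled
#' to `[0, 2]` (dosage divided by half the ploidy), so the statistic is
#' comparable across ploidies. Diagonal is exactly 1.
#'
#' @param vt a [variant_table()].
#' @return symmetric numeric matrix in `[0, 1]`.
#' @export
ibs_matrix <- function(vt) {
  d <- alt_dosage(vt)
  x <- sweep(d, 2, vt$ploidy / 2, `/`)
  strains <- vt_strains(vt)
  k <- length(strains)
  m <- matrix(NA_real_, k, k, dimnames = list(strains, strains))
  for (i in seq_len(k)) {
    m[i, i] <- 1
    for (j in seq_len(k)[-seq_len(i)]) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      m[i, j] <- m[j, i] <-
        if (any(ok)) mean(1 - abs(x[ok, i] - x[ok, j]) / 2) else NA_real_
    }
  }
  m
}

#' KING-robust kinship matrix
#'
#' The method-of-moments estimator applied to diploid-collapsed genotypes
#' (any mixed polyploid genotype counts as heterozygous):
#' `phi = (N_het,het - 2 N_opposite_hom) / (N_het(i) + N_het(j))`, counted
#' over shared non-missing sites. Self-kinship is 0.5 by construction; a
#' pair with no heterozygous sites is undefined (`NA`).
#'
#' @param vt a [variant_table()].
#' @return symmetric numeric matrix with diagonal 0.5.
#' @export
king_kinship <- function(vt) {
  cls <- genotype_classes(vt)
  strains <- vt_strains(vt)
  k <- length(strains)
  m <- matrix(NA_real_, k, k, dimnames = list(strains, strains))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- !is.na(cls[, i]) & !is.na(cls[, j])
      ci <- cls[ok, i]; cj <- cls[ok, j]
      n_hh <- sum(ci == 1L & cj == 1L)
      n_opp <- sum((ci == 0L & cj == 2L) | (ci == 2L & cj == 0L))
      denom <- sum(ci == 1L) + sum(cj == 1L)
      m[i, j] <- m[j, i] <-
        if (denom > 0) (n_hh - 2 * n_opp) / denom else NA_real_
    }
    m[i, i] <- 0.5
  }
  m
}

#' Neighbor-joining tree from a dissimilarity matrix
#'
#' Classical Saitou-Nei neighbor joining (as implemented in \pkg{ape});
#' unrooted, branch lengths not clamped. The conventional input is
#' `1 - ibs_matrix(vt)`.
#'
#' @param d symmetric dissimilarity matrix.
#' @return an [ape::nj()] `phylo` object.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d))) bt_stop("format", "matrix must be symmetric")
  ape::nj(stats::as.dist(d))
}

#' Principal component analysis of genotype dosages
#'
#' Per-site dosage fractions (dosage / ploidy) are mean-centred and scaled
#' by `sqrt(p (1 - p))` with `p` the mean fraction; monomorphic sites are
#' dropped and missing genotypes mean-imputed. Coordinates are eigenvectors
#' of the strain covariance scaled by the root eigenvalues, with the sign
#' convention that each component's largest-magnitude coordinate is
#' positive.
#'
#' @param vt a [variant_table()].
#' @param n_components number of components returned.
#' @return list with `coords` (strains x components) and `explained`
#'   (proportion of variance per component).
#' @export
pca_genotypes <- function(vt, n_components = 10L) {
  d <- alt_dosage(vt)
  g <- sweep(d, 2, vt$ploidy, `/`)     # allele fraction per strain
  g <- t(g)                            # strains x sites
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
  poly <- mu > 0 & mu < 1 & apply(g, 2, stats::var) > 0
  if (!any(poly)) bt_stop("config", "no polymorphic sites for PCA")
  g <- g[, poly, drop = FALSE]; mu <- mu[poly]
  m <- sweep(sweep(g, 2, mu, `-`), 2, sqrt(mu * (1 - mu)), `/`)
  cv <- tcrossprod(m) / ncol(m)
  e <- eigen(cv, symmetric = TRUE)
  k <- min(n_components, sum(e$values > 1e-12))
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  for (j in seq_len(k)) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- vt_strains(vt)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords,
       explained = e$values[seq_len(k)] / sum(pmax(e$values, 0)))
}

#' Diversity and divergence statistics from polyploid genotypes
#'
#' Every strain contributes all of its `p` alleles. Within-strain
#' heterozygosity is the mean pairwise difference among its own alleles
#' (`d (p - d) / C(p, 2)` per site); `d_xy` is the mean difference between
#' alleles drawn from two different strains (`p_i p_j` cross pairs); group
#' `pi` pools all alleles of the group's strains. All statistics are
#' per-site, divided by `total_sites`.
#'
#' Note the finite-ploidy subtlety: for two strains with identical
#' genotypes, `d_xy` equals `2 f (1 - f)` summed per site (allele draws
#' from two independent pools), which differs from within-strain
#' heterozygosity by the factor `p / (p - 1)`.
#'
#' @param vt a [variant_table()]; indels and multiallelic sites are
#'   excluded.
#' @param groups optional named character vector mapping strain to group
#'   (for pooled `pi`).
#' @param site_mask optional logical vector selecting sites (e.g. a `SYN`
#'   annotation).
#' @param total_sites denominator: total callable sites of the masked
#'   class. Defaults to the number of (masked) rows, which is only correct
#'   when the table includes monomorphic sites.
#' @return list with `het` (named per-strain vector), `dxy` (strain
#'   matrix) and `pi` (named per-group vector, when `groups` given).
#' @export
diversity_stats <- function(vt, groups = NULL, site_mask = NULL,
                            total_sites = NULL) {
  use <- vt$sites$is_snp & !vt$sites$multiallelic
  if (!is.null(site_mask)) use <- use & site_mask
  S <- total_sites %||% sum(use)
  if (S <= 0) bt_stop("config", "no usable sites")
  d <- alt_dosage(vt)[use, , drop = FALSE]
  p <- vt$ploidy
  strains <- vt_strains(vt)

  het <- vapply(strains, function(s) {
    ds <- d[!is.na(d[, s]), s]
    pp <- p[[s]]
    if (pp < 2) return(0)
    sum(ds * (pp - ds)) / choose(pp, 2) / S
  }, numeric(1))

  k <- length(strains)
  dxy <- matrix(NA_real_, k, k, dimnames = list(strains, strains))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- !is.na(d[, i]) & !is.na(d[, j])
      di <- d[ok, i]; dj <- d[ok, j]
      dxy[i, j] <- dxy[j, i] <-
        sum(di * (p[j] - dj) + (p[i] - di) * dj) / (p[i] * p[j]) / S
    }
  }

  pi_g <- NULL
  if (!is.null(groups)) {
    pi_g <- vapply(unique(groups), function(gr) {
      members <- names(groups)[groups == gr]
      dm <- d[, members, drop = FALSE]
      contrib <- apply(dm, 1, function(row) {
        ok <- !is.na(row)
        n <- sum(p[members][ok]); a <- sum(row[ok])
        if (n < 2) return(0)
        a * (n - a) / choose(n, 2)
      })
      sum(contrib) / S
    }, numeric(1))
  }
  list(het = het, dxy = dxy, pi = pi_g)
}
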