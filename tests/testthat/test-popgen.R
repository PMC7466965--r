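test_that("filter_genotypes applies site, genotype and missingness rules", {
  path <- write_test_vcf(c(
    vcf_rec("chrI", 10, "A", "T", "QD=5;MQ=50", "0/0/0/1:50:30", "0/1:40:20"),
    vcf_rec("chrI", 20, "C", "G", "QD=1.5;MQ=50", "0/0/0/1:50:30", "0/1:40:20"),
    vcf_rec("chrI", 30, "G", "A", "QD=5;MQ=39", "0/0/0/1:50:30", "0/1:40:20"),
    vcf_rec("chrI", 40, "G", "A", "QD=5;MQ=50", "0/0/1/1:50:9", "0/1:40:20"),
    vcf_rec("chrI", 50, "G", "A,C", "QD=5;MQ=50", "0/0/1/2:50:30", "0/1:40:20"),
    vcf_rec("chrI", 60, "G", "GA", "QD=5;MQ=50", "0/0/1/1:50:30", "0/1:40:20")))
  vt <- read_variant_table(path)
  # MQRankSum/ReadPosRankSum absent and not waived -> configuration error
  expect_error(filter_genotypes(vt, filter_policy(drop_fs_sor = TRUE)),
               class = "brewtrace_config")
  pol <- filter_policy(drop_fs_sor = TRUE, mqranksum_min = NA,
                       readpos_min = NA, max_missing_fraction = 0.5)
  fv <- filter_genotypes(vt, pol)
  # QD 1.5 and MQ 39 removed; multiallelic and indel removed; the DP 9
  # genotype masked (site kept at 50% missing tolerance)
  expect_equal(fv$sites$pos, c(9, 39))
  expect_true(is.na(fv$gt[2, "s1"]))
  expect_false(is.na(fv$gt[2, "s2"]))
  # with the default 10% missing tolerance the masked site goes too
  fv2 <- filter_genotypes(vt, filter_policy(drop_fs_sor = TRUE,
                                            mqranksum_min = NA,
                                            readpos_min = NA))
  expect_equal(fv2$sites$pos, 9)
})

test_that("ibs_matrix follows the rescaled-dosage definition", {
  # identical genotypes -> 1; opposite homozygotes -> 0
  d <- matrix(c(0L, 4L, 0L, 4L,   0L, 4L, 4L, 0L), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  m <- ibs_matrix(vt_from_dosage(d, c(4L, 4L)))
  expect_equal(diag(m), c(a = 1, b = 1))
  expect_equal(m["a", "b"], 0.5)  # half the sites equal, half opposite
  dopp <- matrix(c(0L, 4L, 4L, 0L), ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
  expect_equal(ibs_matrix(vt_from_dosage(dopp, c(4L, 4L)))["a", "b"], 0)
  # diploid dosages 1 vs 2 at a site -> site score 0.5
  d12 <- matrix(c(1L, 2L), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(ibs_matrix(vt_from_dosage(d12, c(2L, 2L)))["a", "b"], 0.5)
})

test_that("king_kinship matches the method-of-moments formula", {
  # N_het,het = 4, N_opp = 1, N_het each = 6 -> (4 - 2) / 12
  da <- c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 2L, 0L)
  db <- c(1L, 1L, 1L, 1L, 0L, 2L, 1L, 0L, 1L)
  vt <- vt_from_dosage(cbind(a = da, b = db), c(2L, 2L))
  m <- king_kinship(vt)
  expect_equal(m["a", "b"], 2 / 12)
  expect_equal(diag(m), c(a = 0.5, b = 0.5))
  # two fixed-difference inbred lines -> negative kinship
  dfix <- matrix(c(rep(0L, 5), rep(1L, 2), rep(2L, 5), rep(1L, 2)), ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
  expect_lt(king_kinship(vt_from_dosage(dfix, c(2L, 2L)))["a", "b"], 0)
  # no heterozygous sites in a pair -> undefined
  dh <- matrix(c(0L, 2L, 2L, 0L), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_true(is.na(king_kinship(vt_from_dosage(dh, c(2L, 2L)))["a", "b"]))
})

test_that("king self-kinship is exactly 0.5 and ibs diagonal exactly 1", {
  sim <- simulate_population(pop_sim_config(
    n_syn_sites = 2e4, n_nonsyn_sites = 0, mu = 1e-7, T_outgroup = 1e5,
    T_split = 3e4, theta_anc = 0.01, seed = 4))
  expect_identical(unname(diag(king_kinship(sim$vt))), c(0.5, 0.5))
  expect_identical(unname(diag(ibs_matrix(sim$vt))), c(1, 1))
})

test_that("nj_tree agrees with the 3-taxon closed form and is label-stable", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 4
  d["B", "C"] <- d["C", "B"] <- 5
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)

  # permuting the input order leaves the topology unchanged
  set.seed(5)
  tree5 <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
  dm <- ape::cophenetic.phylo(tree5)
  perm <- sample(rownames(dm))
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("nj_tree equals exhaustive minimum evolution on additive matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:5, 1)
    true_tree <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    d <- ape::cophenetic.phylo(true_tree)
    nj <- ape::unroot(nj_tree(d))
    me <- ape::unroot(min_evolution_tree(d))
    expect_equal(ape::dist.topo(nj, me), 0, ignore_attr = TRUE)
  }
})

test_that("pca_genotypes separates populations and respects duplicates", {
  set.seed(6)
  n_sites <- 400
  p1 <- runif(n_sites, 0.1, 0.9)
  p2 <- pmin(pmax(p1 + sample(c(-0.4, 0.4), n_sites, TRUE), 0.02), 0.98)
  dose <- function(p) rbinom(n_sites, 4, p)
  strains <- c(sprintf("x%d", 1:6), sprintf("y%d", 1:6))
  d <- cbind(vapply(1:6, function(i) dose(p1), integer(n_sites)),
             vapply(1:6, function(i) dose(p2), integer(n_sites)))
  colnames(d) <- strains
  vt <- vt_from_dosage(d, rep(4L, 12))
  pc <- pca_genotypes(vt, 4)
  expect_gt(mean_silhouette(pc$coords[, 1, drop = FALSE],
                            rep(c("x", "y"), each = 6)), 0.8)
  expect_lte(sum(pc$explained), 1 + 1e-9)

  # duplicated strain lands on identical coordinates
  d2 <- cbind(d, dup = d[, 1])
  vt2 <- vt_from_dosage(d2, rep(4L, 13))
  pc2 <- pca_genotypes(vt2, 3)
  expect_equal(pc2$coords["dup", ], pc2$coords[strains[1], ],
               tolerance = 1e-9)
})

test_that("diversity_stats counts allele pairs combinatorially", {
  # monomorphic -> all zero
  d0 <- matrix(0L, 5, 2, dimnames = list(NULL, c("a", "b")))
  s0 <- diversity_stats(vt_from_dosage(d0, c(4L, 4L)), total_sites = 100)
  expect_true(all(s0$het == 0) && all(s0$dxy == 0))

  # one tetraploid {2 ref, 2 alt} site over 100 sites
  d1 <- matrix(c(2L), 1, 1, dimnames = list(NULL, "a"))
  s1 <- diversity_stats(vt_from_dosage(d1, 4L), total_sites = 100)
  expect_equal(unname(s1$het["a"]), (4 / 6) / 100)

  # identical strains: dxy equals the with-replacement heterozygosity
  # 2 f (1 - f), i.e. within-strain het scaled by (p - 1) / p
  d2 <- matrix(c(2L, 2L), 1, 2, dimnames = list(NULL, c("a", "b")))
  s2 <- diversity_stats(vt_from_dosage(d2, c(4L, 4L)), total_sites = 100)
  expect_equal(s2$dxy["a", "b"], 2 * 0.5 * 0.5 / 100)
  expect_equal(s2$dxy["a", "b"], unname(s2$het["a"]) * 3 / 4)
})

test_that("branch_fraction reproduces the hand-computed toy case", {
  # S = 100: 29 shared + 1 focal-private + 2 relative-private fixed variants
  # -> c_focal = 1, c_rel = 2, d_pair = 30/100, f = 0.015 / 0.15 = 0.10
  df <- c(rep(4L, 29), 4L, 0L, 0L)
  dr <- c(rep(4L, 29), 0L, 4L, 4L)
  vt <- vt_from_dosage(cbind(focal = df, relative = dr), c(4L, 4L))
  est <- branch_fraction(vt, s_sites = 100)
  expect_equal(est$c_focal, 1L)
  expect_equal(est$c_rel, 2L)
  expect_equal(est$d_pair, 0.30)
  expect_equal(est$f, 0.10)
  expect_equal(est$T_split, est$f * est$T_out)

  # focal == relative -> f = 0
  vt0 <- vt_from_dosage(cbind(focal = df, relative = df), c(4L, 4L))
  est0 <- branch_fraction(vt0, s_sites = 100)
  expect_equal(est0$c_focal + est0$c_rel, 0L)
  expect_equal(est0$f, 0)

  # label swap leaves f unchanged when counts are symmetric
  dsym <- cbind(focal = c(rep(4L, 20), 4L, 0L),
                relative = c(rep(4L, 20), 0L, 4L))
  vts <- vt_from_dosage(dsym, c(4L, 4L))
  expect_equal(branch_fraction(vts, s_sites = 100)$f,
               branch_fraction(vts, focal = "relative",
                               relative = "focal", s_sites = 100)$f)

  expect_error(branch_fraction(vt, s_sites = 0), class = "brewtrace_config")
})

test_that("clock conversion and year bounds are exact arithmetic", {
  expect_equal(clock_generations(0), 0)
  expect_equal(clock_generations(2 * 1.67e-10), 1)
  # inverse identity at the published mutation rate
  T0 <- 1.4e7
  expect_equal(clock_generations(2 * 1.67e-10 * T0), T0)
  expect_identical(generations_to_years(0), c(years_min = 0, years_max = 0))
  expect_identical(generations_to_years(2920), c(years_min = 1, years_max = 19))
})
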